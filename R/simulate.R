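#' Thermal source on the ground plane
#'
#' A moving infrared source: a disk-shaped body footprint with a time-varying
#' position, radius and radiation intensity, sampled at the node's rate.
#'
#' @param trajectory `T x 2` matrix of ground positions (m).
#' @param intensity Radiation intensity per time step (arbitrary units);
#'   recycled if scalar.
#' @param extent_radius Footprint radius (m) per time step; recycled if
#'   scalar. Default 0.25.
#' @param sampling_rate Hz.
#' @return Object of class `thermal_source`.
#' @export
thermal_source <- function(trajectory, intensity = 1, extent_radius = 0.25,
                           sampling_rate = 25) {
  trajectory <- as.matrix(trajectory)
  stopifnot(ncol(trajectory) == 2, nrow(trajectory) >= 1)
  T_ <- nrow(trajectory)
  intensity <- rep_len(intensity, T_)
  extent_radius <- rep_len(extent_radius, T_)
  if (any(extent_radius <= 0)) stop("extent_radius must be > 0")
  structure(list(trajectory = trajectory, intensity = intensity,
                 extent_radius = extent_radius,
                 sampling_rate = sampling_rate),
            class = "thermal_source")
}

# equal-area polar quadrature offsets over the unit disk
.footprint_quadrature <- function(n_r = 8, n_th = 16) {
  r <- sqrt((seq_len(n_r) - 0.5) / n_r)
  th <- 2 * pi * (seq_len(n_th) - 0.5) / n_th
  list(x = as.vector(outer(r, cos(th))), y = as.vector(outer(r, sin(th))),
       w = 1 / (n_r * n_th))
}

#' Per-cell raw signals of a thermal source
#'
#' Integrates the source's radiation over each sampling cell: at every time
#' step the contribution of cell `i` is the source intensity times the area
#' fraction of the footprint disk overlapping that cell. Fractions are
#' computed with a fixed equal-area quadrature grid over the footprint, so
#' they sum to 1 while the footprint lies inside the field of view and drop
#' towards 0 as it leaves.
#'
#' @param source A [thermal_source()].
#' @param partition A `cell_partition` from [build_partition()].
#' @param n_r,n_th Radial and angular quadrature resolution of the footprint.
#' @return `L x T` matrix of per-cell signals (pre-filter).
#' @export
cell_signals <- function(source, partition, n_r = 8, n_th = 16) {
  stopifnot(inherits(source, "thermal_source"),
            inherits(partition, "cell_partition"))
  q <- .footprint_quadrature(n_r, n_th)
  T_ <- nrow(source$trajectory)
  L <- partition$n_cells
  Q <- length(q$x)
  # all (time, quadrature point) coordinates at once
  px <- outer(source$trajectory[, 1], rep(1, Q)) +
    outer(source$extent_radius, q$x)
  py <- outer(source$trajectory[, 2], rep(1, Q)) +
    outer(source$extent_radius, q$y)
  cell <- locate_cells(as.vector(px), as.vector(py), partition)
  tt <- rep(seq_len(T_), times = Q)
  keep <- !is.na(cell)
  S <- matrix(0, L, T_)
  if (any(keep)) {
    lin <- cell[keep] + L * (tt[keep] - 1L)
    counts <- tabulate(lin, nbins = L * T_)
    S[] <- counts * q$w
  }
  sweep(S, 2, source$intensity, `*`)
}

#' PIR impulse response
#'
#' A pyroelectric detector responds to *changes* in incident radiation: its
#' transfer function has zero DC gain. The response is modeled as a
#' first-order Butterworth high-pass (the differentiating pyroelectric +
#' input-stage coupling) cascaded with a first-order low-pass (the element's
#' thermal/electrical smoothing), both applied causally.
#'
#' @param high_cutoff_hz High-pass cutoff (Hz), default 0.1.
#' @param low_cutoff_hz Low-pass cutoff (Hz), default 5.
#' @param gain Output gain, default 1.
#' @return Object of class `impulse_response`.
#' @export
impulse_response <- function(high_cutoff_hz = 0.1, low_cutoff_hz = 5,
                             gain = 1) {
  stopifnot(high_cutoff_hz > 0, low_cutoff_hz > high_cutoff_hz, gain > 0)
  structure(list(high_cutoff_hz = high_cutoff_hz,
                 low_cutoff_hz = low_cutoff_hz, gain = gain),
            class = "impulse_response")
}

#' Apply the PIR impulse response to signals
#'
#' @param x Numeric vector or matrix (rows = channels, columns = time).
#' @param h An [impulse_response()].
#' @param sampling_rate Hz.
#' @return Filtered signals, same shape as `x`.
#' @export
apply_impulse_response <- function(x, h, sampling_rate) {
  stopifnot(inherits(h, "impulse_response"))
  nyq <- sampling_rate / 2
  if (h$low_cutoff_hz >= nyq) stop("low_cutoff_hz must be below Nyquist")
  hp <- signal::butter(1, h$high_cutoff_hz / nyq, type = "high")
  lp <- signal::butter(1, h$low_cutoff_hz / nyq, type = "low")
  # the detector has settled on the scene before the recording starts: run
  # the filter to steady state on the initial value, then discard that pad
  # (the high-pass time constant is ~1.6 s at the 0.1 Hz default)
  n_settle <- ceiling(10 * sampling_rate)
  f1 <- function(v) {
    v <- c(rep(v[1], n_settle), v)
    v <- signal::filter(hp, v)
    v <- h$gain * as.numeric(signal::filter(lp, v))
    v[-seq_len(n_settle)]
  }
  if (is.matrix(x)) t(apply(x, 1, f1)) else f1(x)
}

#' Activity script
#'
#' Kinematic description of one emulated activity under the node: one of
#' falling, sitting down, standing up, walking or jogging, with per-repetition
#' randomized parameters (entry geometry, speed, transient timing) drawn from
#' the script's own seed.
#'
#' @param activity One of `"falling"`, `"sitting_down"`, `"standing_up"`,
#'   `"walking"`, `"jogging"`.
#' @param subject_id Integer subject identifier (metadata).
#' @param seed Integer seed; the script's trajectory is a deterministic
#'   function of `(activity, parameters, seed)`.
#' @param speed_mult,intensity_mult,extent_mult Subject-level multipliers on
#'   speed, radiation intensity and footprint radius (height/build proxies).
#' @param pad_s Quiet padding (s) before and after the active phase.
#' @return Object of class `activity_script`.
#' @export
activity_script <- function(activity, subject_id = 1L, seed = 1L,
                            speed_mult = 1, intensity_mult = 1,
                            extent_mult = 1, pad_s = 1.0) {
  activity <- match.arg(activity, c("falling", "sitting_down", "standing_up",
                                    "walking", "jogging"))
  structure(list(activity = activity, subject_id = as.integer(subject_id),
                 seed = as.integer(seed), speed_mult = speed_mult,
                 intensity_mult = intensity_mult, extent_mult = extent_mult,
                 pad_s = pad_s),
            class = "activity_script")
}

# smooth 0->1 ramp
.smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

#' Realize an activity script as a thermal source
#'
#' Translates the script into a sampled trajectory, intensity profile and
#' footprint profile, emulating a recording room with a fixed layout (the
#' activities repeat at stereotyped places, as in a furnished room with one
#' chair and one clear walking lane, with per-repetition jitter).
#' Walking/jogging are straight passes along the room's walking lane (0.8-1.2
#' and 1.8-2.5 m/s, either direction, jittered laterally); sitting down /
#' standing up are 1.5-2.5 s intensity ramps (down to / up from a seated
#' level) at the chair position with a small postural sway; falling is a
#' 0.4-0.7 s transient anywhere near the room center, with 0.5-1 m
#' displacement in a random direction, a footprint that doubles (body
#' elongating on the ground) and a sharp intensity swing, followed by
#' stillness.
#'
#' @param script An [activity_script()].
#' @param config A [partition_config()] (for the field radius and rate).
#' @return A [thermal_source()].
#' @export
script_trajectory <- function(script, config = partition_config()) {
  stopifnot(inherits(script, "activity_script"))
  fs <- config$sampling_rate
  R <- config$fov_radius
  base_extent <- 0.25 * script$extent_mult
  rng <- .with_seed(script$seed, function() {
    list(u = stats::runif(12), ph = stats::runif(1, 0, 2 * pi))
  })
  u <- rng$u
  act <- script$activity
  lane_angle <- pi / 6               # fixed walking lane across the room
  chair <- 1.2 * c(cos(3.8), sin(3.8))  # fixed chair position

  if (act %in% c("walking", "jogging")) {
    speed <- switch(act,
                    walking = 0.8 + 0.4 * u[1],
                    jogging = 1.8 + 0.7 * u[1]) * script$speed_mult
    ang <- lane_angle + stats::qunif(u[3], -0.15, 0.15)
    offset <- stats::qunif(u[2], -0.4, 0.4)   # lateral lane jitter
    dirsgn <- if (u[8] < 0.5) 1 else -1       # either direction along lane
    along <- c(cos(ang), sin(ang)) * dirsgn
    perp <- c(-sin(ang), cos(ang))
    half <- sqrt(R^2 - offset^2) + 0.3        # just beyond the field of view
    p0 <- offset * perp - half * along
    p1 <- offset * perp + half * along
    dur <- 2 * half / speed
    n_pad <- round(script$pad_s * fs)
    n_act <- max(2L, round(dur * fs))
    frac <- seq(0, 1, length.out = n_act)
    traj <- cbind(p0[1] + frac * (p1[1] - p0[1]),
                  p0[2] + frac * (p1[2] - p0[2]))
    traj <- rbind(matrix(rep(traj[1, ], n_pad), ncol = 2, byrow = TRUE),
                  traj,
                  matrix(rep(traj[n_act, ], n_pad), ncol = 2, byrow = TRUE))
    inten <- rep(script$intensity_mult, nrow(traj))
    ext <- rep(base_extent, nrow(traj))
  } else {
    # localized activities: chair-bound ramps or a fall near the center
    if (act == "falling") {
      # falls happen where the person is: on the walking lane (tripping)
      # or at the chair (collapsing while sitting down / getting up)
      if (u[9] < 0.5) {
        along <- c(cos(lane_angle), sin(lane_angle))
        perp <- c(-sin(lane_angle), cos(lane_angle))
        pos <- stats::qunif(u[4], -2, 2) * along +
          stats::qunif(u[5], -0.4, 0.4) * perp
      } else {
        pos <- chair + 0.3 * c(stats::qunif(u[4], -1, 1),
                               stats::qunif(u[5], -1, 1))
      }
      dur <- 0.4 + 0.3 * u[6]
      pre_s <- 0.3
    } else {
      pos <- chair + 0.15 * c(stats::qunif(u[4], -1, 1),
                              stats::qunif(u[5], -1, 1))
      dur <- 1.5 + u[6]
      pre_s <- 0.2
    }
    post_s <- 0.5
    n_pad <- round(script$pad_s * fs)
    n_pre <- round(pre_s * fs)
    n_act <- max(2L, round(dur * fs))
    n_post <- round(post_s * fs)
    T_ <- n_pad + n_pre + n_act + n_post + n_pad
    tt <- seq_len(T_)
    t_act0 <- n_pad + n_pre
    frac <- .smoothstep((tt - t_act0) / n_act)
    # small postural sway while the person is upright and moving
    sway_amp <- 0.04
    sway <- sway_amp * sin(2 * pi * 0.8 * tt / fs + rng$ph) *
      (tt > n_pad & tt <= t_act0 + n_act)
    if (act == "falling") {
      disp <- 0.5 + 0.5 * u[7]
      fall_dir <- 2 * pi * u[8]              # falls go any which way
      ddir <- c(cos(fall_dir), sin(fall_dir))
      traj <- cbind(pos[1] + frac * disp * ddir[1] + sway,
                    pos[2] + frac * disp * ddir[2])
      # the radiating profile drops to a collapsed level within the fall
      inten <- script$intensity_mult * (1 - 0.45 * frac)
      ext <- base_extent * (1 + frac)        # footprint doubles
    } else {
      lo <- 0.45
      lvl <- if (act == "sitting_down") 1 + (lo - 1) * frac
             else lo + (1 - lo) * frac
      traj <- cbind(pos[1] + sway, pos[2] + 0 * sway)
      inten <- script$intensity_mult * lvl
      ext <- rep(base_extent, T_)
    }
  }
  thermal_source(traj, intensity = inten, extent_radius = ext,
                 sampling_rate = fs)
}

# run fn() under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Simulate one multichannel PIR stream
#'
#' Runs the full sensing model: per-cell integration of the source's
#' radiation, visibility modulation by the binary measure matrix `V`
#' (channel j = sum of its visible cells' signals), the PIR impulse response,
#' additive Gaussian sensor noise, clipping and signed ADC quantization.
#'
#' @param script An [activity_script()].
#' @param partition,V From [build_partition()].
#' @param h An [impulse_response()].
#' @param noise_sd Sensor noise s.d. in pre-quantization signal units.
#' @param clip Full-scale amplitude: values are clipped to `[-clip, clip]`
#'   and mapped onto the signed ADC range.
#' @param seed Optional integer; overrides the script's seed for the noise
#'   draw (the trajectory always follows the script's own seed).
#' @return Object of class `sensor_stream`: integer `M x T` matrix of ADC
#'   counts plus metadata.
#' @export
simulate_stream <- function(script, partition, V, h = impulse_response(),
                            noise_sd = 0.02, clip = 2.0, seed = NULL) {
  stopifnot(noise_sd >= 0)
  cfg <- partition$config
  src <- script_trajectory(script, cfg)
  if (nrow(src$trajectory) < 1) stop("zero-duration script")
  S <- cell_signals(src, partition)
  X <- V %*% S                          # M x T
  X <- apply_impulse_response(X, h, cfg$sampling_rate)
  nseed <- if (is.null(seed)) script$seed else seed
  noise_seed <- as.integer((as.numeric(nseed) + 500009) %% 2147483647)
  noise <- .with_seed(noise_seed, function()
    matrix(stats::rnorm(length(X), sd = noise_sd), nrow(X), ncol(X)))
  X <- X + noise
  qmax <- 2^(cfg$adc_bits - 1) - 1
  vals <- round(pmin(pmax(X, -clip), clip) / clip * qmax)  # half-to-even
  storage.mode(vals) <- "integer"
  structure(list(values = vals, sampling_rate = cfg$sampling_rate,
                 metadata = list(subject = script$subject_id,
                                 activity = script$activity,
                                 seed = nseed,
                                 sampling_rate = cfg$sampling_rate,
                                 adc_bits = cfg$adc_bits)),
            class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("sensor_stream: %d channels x %d samples @ %g Hz (%s, subject %s)\n",
              nrow(x$values), ncol(x$values), x$sampling_rate,
              x$metadata$activity %||% "?", x$metadata$subject %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate the full synthetic activity dataset
#'
#' Emulates the reference recording campaign: `n_subjects` subjects each
#' perform every activity `reps_per_activity` times under a 7-sensor node at
#' 25 Hz with 8-bit quantization (defaults: 8 subjects x 5 activities x 10
#' repetitions = 400 streams, 80 of them falls). Subject-level kinematic
#' variability (speed, radiated intensity, footprint) is drawn once per
#' subject from the seeded generator; activity labels are kept in stream
#' metadata only, for evaluation.
#'
#' @param n_subjects,reps_per_activity Counts (>= 1).
#' @param activities Character vector from the activity vocabulary.
#' @param seed Integer master seed; the whole dataset is a deterministic
#'   function of the configuration and this seed.
#' @param config A [partition_config()].
#' @param h,noise_sd,clip Passed to [simulate_stream()].
#' @return List of `sensor_stream` objects.
#' @export
generate_dataset <- function(n_subjects = 8,
                             activities = c("falling", "sitting_down",
                                            "standing_up", "walking",
                                            "jogging"),
                             reps_per_activity = 10, seed = 1L,
                             config = partition_config(),
                             h = impulse_response(), noise_sd = 0.02,
                             clip = 2.0) {
  stopifnot(n_subjects >= 1, reps_per_activity >= 1, length(activities) >= 1)
  known <- c("falling", "sitting_down", "standing_up", "walking", "jogging")
  if (!all(activities %in% known))
    stop("unknown activity: ", paste(setdiff(activities, known), collapse = ", "))
  pv <- build_partition(config)
  plan <- .with_seed(seed, function() {
    traits <- data.frame(
      subject = seq_len(n_subjects),
      speed_mult = stats::runif(n_subjects, 0.9, 1.1),
      intensity_mult = stats::runif(n_subjects, 0.8, 1.2),
      extent_mult = stats::runif(n_subjects, 0.9, 1.1))
    n <- n_subjects * length(activities) * reps_per_activity
    list(traits = traits, stream_seeds = sample.int(2^31 - 2, n))
  })
  streams <- vector("list",
                    n_subjects * length(activities) * reps_per_activity)
  i <- 0L
  for (subj in seq_len(n_subjects)) {
    tr <- plan$traits[subj, ]
    for (act in activities) {
      for (rep_ in seq_len(reps_per_activity)) {
        i <- i + 1L
        sc <- activity_script(act, subject_id = subj,
                              seed = plan$stream_seeds[i],
                              speed_mult = tr$speed_mult,
                              intensity_mult = tr$intensity_mult,
                              extent_mult = tr$extent_mult)
        streams[[i]] <- simulate_stream(sc, pv$partition, pv$V, h = h,
                                        noise_sd = noise_sd, clip = clip)
      }
    }
  }
  streams
}
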