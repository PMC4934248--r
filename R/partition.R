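#' Reference-structure partition configuration
#'
#' Describes the geometry of a ceiling-mounted PIR node whose sensors' fields
#' of view are modulated by two kinds of opaque masks: fan-shaped masks that
#' restrict a sensor to one angular sector of the monitored disk, and ring
#' masks that narrow a sensor's cone so it sees only the ground out to a given
#' projected radius. Together the masks partition the floor into sampling
#' cells with distinct sensor-visibility signatures.
#'
#' @param fov_radius Radius (m) of the monitored disk on the floor.
#' @param n_fan_masks Number of fan-masked sensors; each covers one angular
#'   sector of width `2*pi/n_fan_masks`.
#' @param ring_radii Projected ground radii (m) of the ring-masked sensors,
#'   strictly decreasing, all below `fov_radius`.
#' @param center_radius Radius (m) of the central occlusion disk directly
#'   under the node, invisible to the fan-masked sensors. Set to 0 to omit
#'   the central cell (only sensible when ring sensors are absent too).
#' @param mount_height Mounting height (m) of the node; metadata only, the
#'   partition is expressed in ground-plane coordinates.
#' @param sampling_rate Sampling rate (Hz) of the sensor ADC.
#' @param adc_bits ADC resolution (bits); streams are quantized to signed
#'   `adc_bits`-bit integers.
#'
#' @return An object of class `partition_config`.
#' @examples
#' cfg <- partition_config()
#' pv <- build_partition(cfg)
#' dim(pv$V)  # 7 x 17
#' @export
partition_config <- function(fov_radius = 3.0, n_fan_masks = 4,
                             ring_radii = c(2.4, 1.6, 0.8),
                             center_radius = 0.3, mount_height = 3.0,
                             sampling_rate = 25, adc_bits = 8) {
  if (n_fan_masks < 1) stop("n_fan_masks must be >= 1")
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (fov_radius <= 0) stop("fov_radius must be > 0")
  if (length(ring_radii) > 0) {
    if (any(ring_radii <= 0) || any(ring_radii >= fov_radius))
      stop("ring_radii must be positive and below fov_radius")
    if (any(diff(ring_radii) >= 0))
      stop("ring_radii must be strictly decreasing")
    if (center_radius >= min(ring_radii))
      stop("center_radius must be below the smallest ring radius")
  }
  if (center_radius < 0 || center_radius >= fov_radius)
    stop("center_radius must be in [0, fov_radius)")
  structure(list(fov_radius = fov_radius, n_fan_masks = n_fan_masks,
                 ring_radii = ring_radii, center_radius = center_radius,
                 mount_height = mount_height, sampling_rate = sampling_rate,
                 adc_bits = adc_bits),
            class = "partition_config")
}

#' Build the sampling-cell partition and visibility matrix
#'
#' Divides the monitored disk into `L` pairwise-disjoint cells — a central
#' disk (when `center_radius > 0`) plus `n_fan_masks` angular sectors times
#' `length(ring_radii) + 1` radial bands — and derives the binary visibility
#' matrix `V` (sensors x cells). Fan sensor `s` sees exactly the cells of its
#' sector (excluding the central disk); ring sensor `k` sees every cell whose
#' radial interval lies inside its ring radius, including the central disk.
#' With the defaults (4 fans, 3 rings, central disk) this yields the 7-sensor,
#' 17-cell node: 4 one-hot sector bits crossed with 4 nested ring-membership
#' patterns, plus the no-fan/all-rings central signature, so all 17 columns of
#' `V` are distinct.
#'
#' @param config A [partition_config()].
#' @return A list with components `partition` (class `cell_partition`: a data
#'   frame of cells in polar coordinates plus the boundary vectors) and `V`
#'   (binary matrix, `M x L`).
#' @export
build_partition <- function(config = partition_config()) {
  stopifnot(inherits(config, "partition_config"))
  n_fan <- config$n_fan_masks
  n_ring <- length(config$ring_radii)
  has_center <- config$center_radius > 0
  if (!has_center && n_ring > 0)
    stop("a central disk is required when ring sensors are present")

  # radial band boundaries, ascending, from the central-disk edge outwards
  bnd <- c(config$center_radius, sort(config$ring_radii), config$fov_radius)
  n_band <- length(bnd) - 1
  sector_width <- 2 * pi / n_fan

  cells <- data.frame(
    cell = integer(0), sector = integer(0), band = integer(0),
    theta_lo = numeric(0), theta_hi = numeric(0),
    r_lo = numeric(0), r_hi = numeric(0))
  if (has_center) {
    cells <- rbind(cells, data.frame(cell = 1L, sector = 0L, band = 0L,
                                     theta_lo = 0, theta_hi = 2 * pi,
                                     r_lo = 0, r_hi = config$center_radius))
  }
  idx <- nrow(cells)
  for (s in seq_len(n_fan)) {
    for (b in seq_len(n_band)) {
      idx <- idx + 1L
      cells <- rbind(cells, data.frame(
        cell = idx, sector = s, band = b,
        theta_lo = (s - 1) * sector_width, theta_hi = s * sector_width,
        r_lo = bnd[b], r_hi = bnd[b + 1]))
    }
  }
  L <- nrow(cells)

  M <- n_fan + n_ring
  V <- matrix(0L, M, L)
  for (s in seq_len(n_fan)) {
    V[s, cells$sector == s] <- 1L
  }
  for (k in seq_len(n_ring)) {
    sees <- cells$r_hi <= config$ring_radii[k] + 1e-12
    V[n_fan + k, sees] <- 1L
  }
  rownames(V) <- c(paste0("fan", seq_len(n_fan)),
                   if (n_ring) paste0("ring", seq_len(n_ring)))
  colnames(V) <- paste0("cell", seq_len(L))
  if (any(colSums(V) == 0)) stop("partition yields an invisible cell")
  if (anyDuplicated(t(V)) > 0)
    warning("visibility matrix has duplicate cell signatures")

  partition <- structure(
    list(cells = cells, n_cells = L, boundaries = bnd,
         sector_width = sector_width, config = config),
    class = "cell_partition")
  list(partition = partition, V = V)
}

#' @export
print.cell_partition <- function(x, ...) {
  cat("cell_partition:", x$n_cells, "cells,",
      x$config$n_fan_masks, "sectors x", length(x$boundaries) - 1,
      "radial bands", if (x$config$center_radius > 0) "+ central disk" else "",
      "\n")
  invisible(x)
}

#' Locate ground-plane points in the cell partition
#'
#' @param x,y Cartesian coordinates (m), node nadir at the origin.
#' @param partition A `cell_partition`.
#' @return Integer cell indices; `NA` for points outside the field of view.
#' @export
locate_cells <- function(x, y, partition) {
  cfg <- partition$config
  r <- sqrt(x^2 + y^2)
  theta <- atan2(y, x) %% (2 * pi)
  n_fan <- cfg$n_fan_masks
  n_band <- length(partition$boundaries) - 1
  has_center <- cfg$center_radius > 0
  sector <- pmin(floor(theta / partition$sector_width), n_fan - 1) + 1L
  # band 0 = central disk, bands 1..n_band between successive boundaries
  band <- findInterval(r, partition$boundaries, left.open = TRUE)
  if (!has_center) band[band == 0L] <- 1L  # only r == 0 exactly
  cell <- if (has_center) {
    ifelse(band == 0L, 1L, 1L + (sector - 1L) * n_band + band)
  } else {
    (sector - 1L) * n_band + band
  }
  cell[r > cfg$fov_radius] <- NA_integer_
  as.integer(cell)
}
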