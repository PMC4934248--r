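test_that("a contained source deposits all signal in its own cell", {
  pv <- default_node()
  # deep inside sector 1, outer band, footprint well contained
  pos <- 2.7 * c(cos(pi / 4), sin(pi / 4))
  src <- thermal_source(matrix(rep(pos, 5), ncol = 2, byrow = TRUE),
                        intensity = 2, extent_radius = 0.1)
  S <- cell_signals(src, pv$partition)
  cell <- locate_cells(pos[1], pos[2], pv$partition)
  expect_equal(S[cell, ], rep(2, 5))
  expect_true(all(S[-cell, ] == 0))
})

test_that("a source straddling a sector boundary splits evenly", {
  pv <- default_node()
  # the boundary between sectors 1 and 2 lies along the positive y axis
  pos <- c(0, 2.0)
  src <- thermal_source(matrix(pos, ncol = 2), intensity = 1,
                        extent_radius = 0.15)
  S <- cell_signals(src, pv$partition, n_r = 32, n_th = 64)
  active <- which(S[, 1] > 0)
  expect_length(active, 2)
  expect_equal(S[active[1], 1], S[active[2], 1], tolerance = 1e-6)
  expect_equal(sum(S[, 1]), 1, tolerance = 1e-9)
})

test_that("overlap fractions conserve the source while inside the field", {
  pv <- default_node()
  set.seed(7)
  traj <- cbind(runif(40, -2.5, 2.5), runif(40, -2.5, 2.5))
  src <- thermal_source(traj, intensity = 1, extent_radius = 0.25)
  S <- cell_signals(src, pv$partition)
  sums <- colSums(S)
  expect_true(all(sums <= 1 + 1e-9))
  fully_inside <- sqrt(rowSums(traj^2)) <= 3 - 0.25
  expect_equal(sums[fully_inside], rep(1, sum(fully_inside)),
               tolerance = 1e-9)
  # agrees with a much finer rasterization of the footprint
  S_fine <- cell_signals(src, pv$partition, n_r = 40, n_th = 80)
  expect_lt(max(abs(S - S_fine)), 0.05)
})

test_that("the impulse response suppresses constant radiation", {
  h <- impulse_response()
  x <- rep(3.5, 500)
  y <- apply_impulse_response(x, h, 25)
  expect_lt(max(abs(y[250:500])), 1e-3)
})

test_that("a stationary source produces only noise-level output", {
  pv <- default_node()
  sc <- activity_script("sitting_down", seed = 3)
  # zero noise, constant intensity: override by building the source directly
  pos <- c(1, 1)
  src <- thermal_source(matrix(rep(pos, 100), ncol = 2, byrow = TRUE),
                        intensity = 1)
  S <- cell_signals(src, pv$partition)
  X <- apply_impulse_response(pv$V %*% S, impulse_response(), 25)
  expect_lt(max(abs(X[, 30:100])), 1e-3)
})

test_that("a walk between sectors energizes exactly the visited fans", {
  pv <- default_node()
  # straight path from sector 1 to sector 3 through the centre
  traj <- cbind(seq(2.5, -2.5, length.out = 120),
                seq(2.49, -2.49, length.out = 120))
  src <- thermal_source(traj, intensity = 1)
  S <- cell_signals(src, pv$partition)
  X <- apply_impulse_response(pv$V %*% S, impulse_response(), 25)
  energy <- rowSums(X^2)
  visited <- sort(unique(locate_cells(traj[, 1], traj[, 2], pv$partition)))
  visited_sectors <- unique(pv$partition$cells$sector[visited])
  on_path <- which(seq_len(4) %in% visited_sectors)
  off_path <- setdiff(1:4, on_path)
  expect_true(min(energy[on_path]) > 100 * max(energy[off_path], 0))
})

test_that("streams are deterministic given the script and quantized to range", {
  pv <- default_node()
  sc <- activity_script("walking", seed = 11)
  a <- simulate_stream(sc, pv$partition, pv$V)
  b <- simulate_stream(sc, pv$partition, pv$V)
  expect_identical(a$values, b$values)
  expect_true(all(abs(a$values) <= 127))
  expect_equal(nrow(a$values), 7)
  expect_type(a$values[1], "integer")
  # a different seed gives a different stream
  d <- simulate_stream(activity_script("walking", seed = 12),
                       pv$partition, pv$V)
  expect_false(identical(a$values, d$values))
})

test_that("dataset generation respects the experiment design", {
  small <- generate_dataset(n_subjects = 2, activities = c("falling",
                                                           "walking"),
                            reps_per_activity = 3, seed = 5)
  expect_length(small, 12)
  acts <- vapply(small, function(s) s$metadata$activity, "")
  expect_equal(sum(acts == "falling"), 6)
  one <- generate_dataset(n_subjects = 1, activities = "walking",
                          reps_per_activity = 1, seed = 5)
  expect_length(one, 1)
  # same seed reproduces byte-identical values; different seed does not
  again <- generate_dataset(n_subjects = 2, activities = c("falling",
                                                           "walking"),
                            reps_per_activity = 3, seed = 5)
  expect_identical(lapply(small, `[[`, "values"),
                   lapply(again, `[[`, "values"))
  other <- generate_dataset(n_subjects = 2, activities = c("falling",
                                                           "walking"),
                            reps_per_activity = 3, seed = 6)
  expect_false(identical(lapply(small, `[[`, "values"),
                         lapply(other, `[[`, "values")))
  expect_error(generate_dataset(activities = "cartwheel"), "unknown activity")
})
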