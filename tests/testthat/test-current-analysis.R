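ion_frames <- function(...) {
  # build a trajectory tibble from per-frame lists: list(time, id, q, z)
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(time = r[[1]], ion = r[[2]], charge = r[[3]],
               x = 0, y = 0, z = r[[4]])
  }))
}

test_that("a full-pore single-ion step gives exactly one charge per ps", {
  tr <- ion_trajectory(ion_frames(list(0, 1, 1, -17.9), list(1, 1, 1, 18.1)))
  ct <- instantaneous_current(tr)
  expect_equal(ct$current, 160.2177)
  expect_identical(nrow(ct), 1L)
})

test_that("opposite charges moving oppositely both add positive current", {
  tr <- ion_trajectory(ion_frames(
    list(0, 1:2, c(1, -1), c(0, 5)),
    list(1, 1:2, c(1, -1), c(3, 2))))
  ct <- instantaneous_current(tr)
  one <- 1 * 3 / 36 * 160.2177
  expect_equal(ct$current, one + (-1) * (-3) / 36 * 160.2177)
})

test_that("negating all charges negates the trace exactly", {
  it <- gen_ion_trajectory(frames = 50, seed = 8)
  flipped <- as.data.frame(it)
  flipped$charge <- -flipped$charge
  it2 <- ion_trajectory(flipped, lz = attr(it, "lz"),
                        box_z = attr(it, "box_z"))
  expect_equal(instantaneous_current(it2)$current,
               -instantaneous_current(it)$current)
})

test_that("reversing frame order negates the integrated current", {
  # keep every ion inside the slab so membership is frame-symmetric
  set.seed(3)
  n <- 8; frames <- 30
  df <- do.call(rbind, lapply(seq_len(frames), function(f) {
    data.frame(time = f - 1, ion = 1:n, charge = rep(c(1, -1), n / 2),
               x = 0, y = 0,
               z = sin(f / 5 + 1:n) * 10)
  }))
  fwd <- instantaneous_current(ion_trajectory(df))
  rev_df <- df
  rev_df$time <- max(df$time) - df$time
  bwd <- instantaneous_current(ion_trajectory(rev_df))
  expect_equal(sum(bwd$current), -sum(fwd$current), tolerance = 1e-12)
})

test_that("ions missing from the next frame are skipped with a counted warning", {
  df <- rbind(ion_frames(list(0, 1:2, c(1, 1), c(0, 5))),
              ion_frames(list(1, 1, 1, 3)),
              ion_frames(list(2, 1:2, c(1, 1), c(6, 7))))
  expect_warning(ct <- instantaneous_current(ion_trajectory(df)),
                 regexp = "1 ion-frame",
                 class = "porepass_missing_ion_warning")
  expect_equal(ct$current[1], 3 / 36 * 160.2177)
})

test_that("the displacement estimator is unbiased on drift-diffusion ensembles", {
  means <- sapply(1:5, function(seed) {
    it <- gen_ion_trajectory(n_ions = 20, drift = 2.5, diffusion = 2,
                             frames = 400, seed = seed)
    mean(instantaneous_current(it)$current)
  })
  truth <- attr(gen_ion_trajectory(frames = 2, seed = 1), "truth")
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - truth$expected_current_na), 3 * se)
})

test_that("slab membership is strict at the faces", {
  df <- ion_frames(list(0, 1:3, c(1, 1, 1), c(0, 18, -18.000001)),
                   list(1, 1:3, c(1, 1, 1), c(1, 19, -17)))
  cnt <- count_pore_ions(ion_trajectory(df))
  expect_equal(cnt$count[1], 1)   # z = 0 in; z = +18 and z < -18 out
})

test_that("uniform occupancy matches the slab fraction", {
  it <- gen_ion_trajectory(n_ions = 40, drift = 1, diffusion = 3,
                           frames = 300, box = c(40, 40, 80), lz = 36,
                           seed = 12)
  cnt <- count_pore_ions(it)
  expected <- 40 * 36 / 80
  se <- sqrt(40 * (36 / 80) * (1 - 36 / 80)) / sqrt(nrow(cnt) / 10)
  expect_lt(abs(mean(cnt$count) - expected), 3 * se)
})

test_that("a constant series passes the low-pass filter unchanged", {
  tr <- current_trace(0:999, rep(3.5, 1000))
  out <- lowpass(tr, filter_spec(5))
  expect_equal(out$current, rep(3.5, 1000))
  expect_identical(attr(out, "filter_applied")$cutoff_ghz, 5)
})

test_that("gain at the cutoff matches the two-pass Butterworth value", {
  t <- 0:19999
  x <- sin(2 * pi * 0.005 * t)    # 5 GHz at 1 ps sampling
  out <- lowpass(current_trace(t, x), filter_spec(5))
  core <- 2000:18000
  amp <- sqrt(2 * mean(out$current[core]^2))
  expect_equal(amp, 0.5, tolerance = 0.02)
  # and the mean of a stationary noisy series is preserved to 0.1%
  set.seed(4)
  y <- 10 + rnorm(20000)
  out2 <- lowpass(y, filter_spec(2), delta_t = 1)
  expect_lt(abs(mean(out2) - mean(y)) / abs(mean(y)), 1e-3)
  expect_lt(var(out2), var(y))
})

test_that("cutoffs at or above Nyquist are rejected", {
  tr <- current_trace(0:99, rnorm(100))
  expect_error(lowpass(tr, filter_spec(500)), class = "porepass_input_error")
  expect_error(lowpass(tr, filter_spec(600)), class = "porepass_input_error")
})

test_that("histograms bin traces, honour masks and reject empty input", {
  tr <- current_trace(0:99, rep(2, 100))
  h <- current_histogram(tr, bins = 10)
  expect_identical(sum(h$count > 0), 1L)
  expect_equal(sum(h$count), 100)

  two <- current_trace(0:199, rep(c(1, 9), each = 100))
  h2 <- current_histogram(two, bins = 16)
  occupied <- h2[h2$count > 0, ]
  expect_identical(nrow(occupied), 2L)
  expect_lt(abs(occupied$mid[1] - 1), diff(h2$bin_left[1:2]))
  expect_lt(abs(occupied$mid[2] - 9), diff(h2$bin_left[1:2]))

  masked <- current_histogram(two, bins = 16, exclude = list(c(0, 99)))
  expect_equal(sum(masked$count), 100)
  expect_error(current_histogram(two, exclude = list(c(0, 199))),
               class = "porepass_input_error")
})

test_that("filtering a two-level trace keeps the mode locations", {
  set.seed(9)
  levels <- rep(rep(c(10, 60), 10), each = 100)
  tr <- current_trace(seq_along(levels) - 1, levels + rnorm(length(levels)))
  filt <- lowpass(tr, filter_spec(50, order = 2))
  h <- current_histogram(filt, bins = 30)
  width <- diff(h$bin_left[1:2])
  peaks <- h$mid[order(h$count, decreasing = TRUE)][1:2]
  expect_lt(abs(min(peaks) - 10), width)
  expect_lt(abs(max(peaks) - 60), width)
})

test_that("dipole alignment follows the hand-computed two-charge dipole", {
  atoms <- data.frame(time = rep(0:1, each = 2), charge = c(1, -1, 1, -1),
                      x = 0, y = 0, z = c(2, -2, -2, 2))
  dp <- dipole_trace(atoms)
  expect_equal(dp$pz, c(4, -4))
  expect_identical(dp$aligned, c(TRUE, FALSE))
})

test_that("conditioned histograms partition the frames", {
  tr <- current_trace(0:99, rnorm(100))
  dp_all <- data.frame(time = 0:99, charge = 1, x = 0, y = 0, z = 1)
  dp <- dipole_trace(dp_all)
  both <- dipole_conditioned_histograms(tr, dp, bins = 8)
  expect_equal(sum(both$count[both$alignment == "aligned"]), 100)
  expect_equal(sum(both$count[both$alignment == "anti_aligned"]), 0)

  # random flags on a constant current: identical single-bin shapes
  const <- current_trace(0:99, rep(5, 100))
  set.seed(2)
  flags <- sample(c(TRUE, FALSE), 100, replace = TRUE)
  dp2 <- structure(tibble::tibble(time = 0:99, px = 0, py = 0,
                                  pz = ifelse(flags, 1, -1),
                                  aligned = flags),
                   class = c("dipole_trace", "tbl_df", "tbl", "data.frame"))
  hh <- dipole_conditioned_histograms(const, dp2, bins = 5)
  al <- hh[hh$alignment == "aligned", ]
  an <- hh[hh$alignment == "anti_aligned", ]
  expect_identical(which(al$count > 0), which(an$count > 0))
  expect_equal(sum(al$count), sum(flags))

  # misaligned time axes are an error
  dp3 <- dipole_trace(data.frame(time = 50:80, charge = 1, x = 0, y = 0,
                                 z = 1))
  expect_error(dipole_conditioned_histograms(tr, dp3),
               class = "porepass_input_error")
})

test_that("center-of-mass tracking is the mass-weighted mean", {
  atoms <- data.frame(time = rep(0, 2), z = c(-5, 5), mass = c(1, 1),
                      x = 0, y = 0)
  atoms <- rbind(atoms, data.frame(time = 1, z = 7, mass = 2, x = 0, y = 0))
  com <- com_track(atoms)
  expect_equal(com$z_com, c(0, 7))

  set.seed(5)
  rnd <- data.frame(time = rep(0:9, each = 6), z = rnorm(60),
                    mass = runif(60, 1, 16))
  com2 <- com_track(rnd)
  byhand <- sapply(0:9, function(t) {
    sel <- rnd$time == t
    sum(rnd$z[sel] * rnd$mass[sel]) / sum(rnd$mass[sel])
  })
  expect_equal(com2$z_com, byhand)
  expect_error(com_track(transform(rnd, mass = 0)),
               class = "porepass_input_error")
})

test_that("trajectories round-trip through the column-text format", {
  it <- gen_ion_trajectory(n_ions = 6, frames = 20, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ion_trajectory(it, path)
  back <- read_ion_trajectory(path, lz = attr(it, "lz"),
                              box_z = attr(it, "box_z"))
  expect_equal(back$z, it$z, tolerance = 1e-9)
  expect_equal(instantaneous_current(back)$current,
               instantaneous_current(it)$current, tolerance = 1e-6)
})
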