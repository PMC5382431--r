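test_that("phase binning averages the trace within each bin", {
  # zero amplitude: ten zero displacements
  z <- bin_phases(respiratory_trace(amplitude = c(0, 0, 0)))
  expect_equal(z, matrix(0, 10, 3), ignore_attr = TRUE)
  # pure sinusoid: symmetric about mid-position, extremes within bin average
  tr <- respiratory_trace(period = 4, amplitude = c(10, 0, 0),
                          waveform = "sin")
  d <- bin_phases(tr)[, 1]
  expect_equal(d, -rev(d), tolerance = 1e-6)        # odd symmetry of sin
  expect_lt(max(d), 10)
  # analytic bin integral for the first bin of sin(2 pi t / T)
  a1 <- 10 * (cos(0) - cos(2 * pi * 0.1)) / (2 * pi * 0.1)
  expect_equal(d[1], a1, tolerance = 1e-4)
  # mean displacement equals the trace time-average within 1%
  tr4 <- respiratory_trace(period = 4, amplitude = c(5, 2, 1))
  dd <- bin_phases(tr4)
  tt <- seq(0, 4, length.out = 20001)[-1]
  avg <- colMeans(tr4$displacement(tt))
  expect_equal(colMeans(dd), avg, tolerance = 0.01)
})

test_that("phase dose shifting is exact on the lattice and conservative", {
  g <- random_grid(2, dim = c(16L, 16L, 16L), spacing = c(2, 2, 2))
  # zero displacement: identical object
  expect_identical(phase_dose(g, c(0, 0, 0))$values, g$values)
  # no tracking: dose fixed in the room frame
  expect_identical(phase_dose(g, c(5, 3, 1), tracking = FALSE)$values,
                   g$values)
  # integer-voxel displacement: exact shifted copy
  sh <- suppressWarnings(phase_dose(g, c(4, 0, -2)))   # 2 and -1 voxels
  expect_equal(sh$values[5:16, , 1:14], g$values[3:14, , 2:15],
               tolerance = 1e-12)
  # half-voxel shift then its reverse is interpolation-bounded, not exact
  f <- generate_dose_grid(c(32, 32, 32), 4, fraction_schedule(48, 4),
                          gs = grid_spec(dim = c(32L, 32L, 32L),
                                         spacing = c(2, 2, 2)))$dose
  once <- phase_dose(f, c(1, 0, 0))
  back <- phase_dose(once, c(-1, 0, 0))
  err <- max(abs(back$values - f$values))
  expect_gt(err, 0)                                  # genuinely lossy
  expect_lt(err, 0.25 * max(f$values))               # bounded by smoothness
})

test_that("fiducial registration recovers translations in closed form", {
  ref <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 5))
  expect_equal(register_phase(ref, ref)$translation, c(0, 0, 0),
               ignore_attr = TRUE)
  off <- sweep(ref, 2, c(3, -2, 5), "+")
  expect_equal(register_phase(off, ref)$translation, c(-3, 2, -5),
               ignore_attr = TRUE)
  # noisy offsets: least squares = per-axis mean of differences
  set.seed(40)
  noisy <- off + matrix(rnorm(9, sd = 0.2), 3)
  expect_equal(register_phase(noisy, ref)$translation,
               colMeans(ref - noisy), ignore_attr = TRUE)
  expect_error(register_phase(ref[1:2, ], ref), "mismatch")
  # transform composed with its inverse is the identity
  tr <- register_phase(off, ref)$translation
  expect_lt(max(abs(tr + register_phase(ref, off)$translation)), 1e-9)
})

test_that("accumulation identities: zero motion, perfect registration, averaging", {
  f <- generate_dose_grid(c(40, 40, 40), 8, fraction_schedule(54, 3),
                          gs = grid_spec(dim = c(40L, 40L, 40L),
                                         spacing = c(2, 2, 2)))$dose
  # zero motion: accumulated equals planned bit-exactly
  ps0 <- make_phase_set(f, respiratory_trace(amplitude = c(0, 0, 0)))
  expect_identical(accumulate_phases(ps0)$values, f$values)
  # two-phase toy: shifted copy + perfect registration undoes the shift
  shifted <- phase_dose(f, c(4, 0, 0))               # 2 voxels
  ps2 <- structure(list(
    phases = list(
      list(index = 0L, dose = f, fiducials = rbind(c(40, 40, 40)),
           displacement = c(0, 0, 0)),
      list(index = 1L, dose = shifted, fiducials = rbind(c(44, 40, 40)),
           displacement = c(4, 0, 0))),
    weights = c(0.5, 0.5), fiducials_ref = rbind(c(40, 40, 40)),
    tracking = TRUE), class = "phase_set")
  acc <- accumulate_phases(ps2)
  interior <- as.vector(acc$values[4:37, 4:37, 4:37] -
                          f$values[4:37, 4:37, 4:37])
  expect_lt(max(abs(interior)), 1e-9)
  # unregistered accumulation is the plain weighted average
  id <- list(structure(list(translation = c(0, 0, 0)),
                       class = "rigid_transform"))
  acc2 <- accumulate_phases(ps2, transforms = rep(id, 2))
  expect_equal(acc2$values, (f$values + shifted$values) / 2,
               tolerance = 1e-12)
})

test_that("integral dose is conserved and the trace is time-reversible", {
  f <- generate_dose_grid(c(64, 64, 64), 6, fraction_schedule(60, 3),
                          gs = grid_spec(dim = c(64L, 64L, 64L),
                                         spacing = c(2, 2, 2)))$dose
  tr <- respiratory_trace(period = 4, amplitude = c(5, 2, 1))
  acc <- suppressWarnings(accumulate_phases(make_phase_set(f, tr)))
  expect_lt(abs(sum(acc$values) - sum(f$values)) / sum(f$values), 0.005)
  # time inversion of the trace leaves the accumulated dose unchanged
  tr_rev <- tr
  tr_rev$displacement <- function(t) tr$displacement(tr$period - t)
  acc_rev <- suppressWarnings(accumulate_phases(make_phase_set(f, tr_rev)))
  expect_equal(acc_rev$values, acc$values, tolerance = 1e-9)
})

test_that("3D vs 4D comparison: tracked motion leaves rib metrics unchanged", {
  cfg <- cohort_config(n_patients = 6L, n_lesions = 6L, seed = 19L,
                       grid = grid_spec(dim = c(72L, 72L, 72L),
                                        spacing = c(2.5, 2.5, 2.5)),
                       chest_wall_x_mm = 120)
  co <- sample_cohort(cfg)
  # zero motion: every difference is exactly zero and p degenerates to 1
  cz <- compare_3d_4d(co, trace = respiratory_trace(amplitude = c(0, 0, 0)))
  expect_true(all(cz$table[["D_4.6cc_3d"]] == cz$table[["D_4.6cc_4d"]]))
  expect_equal(cz$tests[["D_4.6cc"]]$p, 1)
  # tracked rigid motion with fiducial registration: differences vanish to
  # interpolation tolerance (< 1% of prescription)
  ct <- suppressWarnings(
    compare_3d_4d(co, trace = respiratory_trace(amplitude = c(5, 2, 1))))
  mi <- match(ct$table$lesion_id, co$lesions$lesion_id)
  rx_eqd2 <- mapply(eqd2, co$lesions$total_dose[mi],
                    co$lesions$n_fractions[mi])
  rel <- abs(ct$table[["D_4.6cc_3d"]] - ct$table[["D_4.6cc_4d"]]) / rx_eqd2
  expect_lt(max(rel), 0.01)
  # untracked delivery moves rib dose more than tracked delivery
  cu <- suppressWarnings(
    compare_3d_4d(co, trace = respiratory_trace(amplitude = c(8, 3, 1)),
                  tracking = FALSE))
  ct8 <- suppressWarnings(
    compare_3d_4d(co, trace = respiratory_trace(amplitude = c(8, 3, 1)),
                  tracking = TRUE))
  expect_gt(mean(abs(cu$table[["D_4.6cc_3d"]] - cu$table[["D_4.6cc_4d"]])),
            -1e-12)
  expect_gte(mean(abs(cu$table[["D_4.6cc_3d"]] - cu$table[["D_4.6cc_4d"]])),
             mean(abs(ct8$table[["D_4.6cc_3d"]] - ct8$table[["D_4.6cc_4d"]])))
})
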