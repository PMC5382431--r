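small_gs <- grid_spec(dim = c(64L, 64L, 64L), spacing = c(2, 2, 2))

test_that("synthetic dose grid realises the planning constraints", {
  sch <- fraction_schedule(60, 3)
  res <- generate_dose_grid(c(60.3, 63.2, 64.9), 5.90, schedule = sch,
                            falloff_per_mm = 0.10, gs = small_gs)
  # hot spot: prescription / 0.8
  expect_equal(max(res$dose$values), 75)
  # GTV mask volume within one voxel volume of the requested 5.90 cc
  expect_lt(abs(mask_volume_cc(res$gtv) - 5.90), prod(small_gs$spacing) / 1000)
  # PTV surface receives the prescription; outside decays at 10%/mm:
  # 10 mm outside the PTV the dose is 60 * 0.9^10 = 20.9 Gy
  r_p <- res$r_gtv + 4
  probe <- c(60.3 + r_p + 10, 63.2, 64.9)
  ijk <- round((probe - small_gs$origin) / small_gs$spacing) + 1
  got <- res$dose$values[ijk[1], ijk[2], ijk[3]]
  vc <- (ijk - 1) * 2                              # probe voxel centre
  d_probe <- sqrt(sum((vc - c(60.3, 63.2, 64.9))^2)) - r_p
  expect_equal(got, 60 * 0.9^d_probe, tolerance = 1e-9)
  expect_lt(abs(got - 60 * 0.9^10), 60 * 0.9^10 * 0.4)
  # PTV contains the GTV
  expect_true(all(res$gtv$member_idx %in% res$ptv$member_idx))
  # sizing error when the falloff region does not fit
  expect_error(generate_dose_grid(c(6, 64, 64), 5.9, sch, gs = small_gs),
               "too small|outside")
})

test_that("rib cage geometry is disjoint and volumetrically correct", {
  expect_length(generate_rib_cage(0L, gs = small_gs), 0L)
  gs1 <- grid_spec(dim = c(128L, 128L, 128L), spacing = c(1, 1, 1))
  ribs <- generate_rib_cage(6L, rib_radius_mm = 5, rib_pitch_mm = 18,
                            chest_wall_x_mm = 64, gs = gs1)
  expect_length(ribs, 6L)
  idx <- unlist(lapply(ribs, `[[`, "member_idx"))
  expect_identical(anyDuplicated(idx), 0L)          # pairwise disjoint
  # tube volume vs analytic pi r^2 L within 10% at 1 mm spacing
  L <- diff(c(20, 127 - 20))                        # default y margins
  for (r in ribs) {
    analytic <- pi * 25 * (1 + L) / 1000
    expect_lt(abs(mask_volume_cc(r) - analytic) / analytic, 0.10)
  }
  expect_error(generate_rib_cage(4L, rib_radius_mm = 10, rib_pitch_mm = 15,
                                 gs = gs1), "overlap")
})

test_that("cohort sampling is seed-deterministic and hits its marginals", {
  cfg <- cohort_config(seed = 77L)
  a <- sample_cohort(cfg)
  b <- sample_cohort(cfg)
  expect_identical(a$lesions, b$lesions)            # bit-identical regeneration
  expect_identical(a$patients, b$patients)
  expect_equal(nrow(a$lesions), 49L)
  expect_equal(nrow(a$patients), 39L)
  expect_true(all(a$lesions$n_fractions %in% 3:6))
  expect_true(all(a$lesions$total_dose >= 45 & a$lesions$total_dose <= 66))
  expect_true(all(a$patients$age >= 40 & a$patients$age <= 95))

  # marginal recovery at n = 2000 (covariates only; no grids needed)
  big <- sample_cohort(cohort_config(n_patients = 2000L, n_lesions = 2000L,
                                     seed = 78L))
  expect_lt(abs(median(big$lesions$gtv_volume) - 5.90) / 5.90, 0.15)
  expect_lt(abs(median(big$lesions$rib_distance) - 0.25) / 0.25, 0.15)
  expect_lt(abs(mean(big$patients$sex == "male") - 0.59), 0.05)
  expect_lt(abs(mean(big$lesions$location == "middle_lower") - 0.612), 0.05)
})

test_that("rib-voxel fast path equals the full-grid DVH route", {
  cfg <- cohort_config(n_patients = 4L, n_lesions = 4L, seed = 9L,
                       grid = grid_spec(dim = c(96L, 96L, 96L),
                                        spacing = c(2, 2, 2)))
  co <- sample_cohort(cfg)
  com <- compute_cohort_metrics(co)
  for (i in seq_len(4)) {
    full <- lesion_dose_grid(co, i)
    e <- eqd2_convert(full$dose,
                      fraction_schedule(co$lesions$total_dose[i],
                                        co$lesions$n_fractions[i]))
    sel <- select_irradiated_ribs(e, co$ribs, 10)
    if (!length(sel)) {
      expect_true(is.na(com$lesions[["D_max"]][i]))
      next
    }
    union_idx <- unlist(lapply(sel, `[[`, "member_idx"))
    dvh <- ribdose:::dvh_from_values(e$values[union_idx],
                                     voxel_volume_cc(full$dose))
    fam <- metric_row(metric_sweep(dvh))
    for (cn in c("D_max", "D_0.1cc", "D_4.6cc", "V_50", "V_160"))
      expect_equal(com$lesions[[cn]][i], fam[[cn]], tolerance = 1e-8)
  }
})

test_that("outcome sampler honours its null, threshold and censoring contracts", {
  set.seed(1)
  les <- data.frame("D_4.6cc" = runif(2000, 40, 280), check.names = FALSE)
  # zero slope: event probability independent of dose
  null <- sample_outcomes(les, hazard = list(scale = 150, shape = 1.5,
                                             slope = 0, threshold = 140,
                                             metric = "D_4.6cc"), seed = 2L)
  expect_gt(chisq.test(table(les[["D_4.6cc"]] > 140, null$event))$p.value,
            0.01)
  # steep slope at 140: fracture fraction above the cutoff strictly greater
  alt <- sample_outcomes(les, hazard = list(scale = 150, shape = 1.5,
                                            slope = 0.5, threshold = 140,
                                            metric = "D_4.6cc"), seed = 3L)
  expect_gt(mean(alt$event[les[["D_4.6cc"]] > 140]),
            mean(alt$event[les[["D_4.6cc"]] <= 140]))
  # all censoring before any possible event time: zero observed events
  none <- sample_outcomes(les, hazard = list(scale = 1e9, shape = 1.5,
                                             slope = 0, threshold = 140,
                                             metric = "D_4.6cc"),
                          followup = list(median = 20, sdlog = 0.3,
                                          range = c(6, 84)), seed = 4L)
  expect_equal(sum(none$event), 0L)
  # determinism and precondition
  again <- sample_outcomes(les, hazard = list(scale = 150, shape = 1.5,
                                              slope = 0.5, threshold = 140,
                                              metric = "D_4.6cc"), seed = 3L)
  expect_identical(again$time, alt$time)
  les_na <- les; les_na[["D_4.6cc"]][1] <- NA
  expect_error(sample_outcomes(les_na), "missing")
})

test_that("a Cox fit on synthetic lesions recovers the planted hazard slope", {
  cfg <- cohort_config(n_patients = 500L, n_lesions = 500L, seed = 31L,
                       grid = grid_spec(dim = c(96L, 96L, 96L),
                                        spacing = c(2, 2, 2)))
  co <- compute_cohort_metrics(sample_cohort(cfg))
  les <- sample_outcomes(co$lesions, hazard = cfg$hazard,
                         seed = 32L, na_metric_zero = TRUE)
  excess <- pmax(0, ifelse(is.na(les[["D_4.6cc"]]), 0,
                           les[["D_4.6cc"]]) - 140)
  fit <- cox_fit(data.frame(excess = excess), les$time, les$event)
  expect_true(fit$converged)
  expect_lt(abs(fit$table$coef - cfg$hazard$slope), 2 * fit$table$se)
})
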