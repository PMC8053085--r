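test_that("fit_saturation round-trips generating parameters", {
  # noiseless closed loops over several parameter sets
  for (p in list(c(kd = 2.5e-9, s0 = 100, smax = 600),
                 c(kd = 2.0e-8, s0 = 0, smax = 50),
                 c(kd = 1.1e-5, s0 = -20, smax = 300))) {
    conc <- p[["kd"]] / 10 * 2^(0:8)
    spec <- binding_sim_spec(type = "titration", kd = p[["kd"]],
                             s0 = p[["s0"]], smax = p[["smax"]],
                             conc_M = conc, noise_sd = 0)
    fit <- fit_saturation(generate_binding(spec))
    expect_equal(fit$kd, p[["kd"]], tolerance = 1e-4)
    expect_equal(fit$s0, p[["s0"]], tolerance = 1e-4)
    expect_equal(fit$smax, p[["smax"]], tolerance = 1e-4)
  }

  # half-saturation: the model passes through (s0 + smax)/2 at c = Kd
  fit <- fit_saturation(generate_binding(binding_sim_spec(
    type = "titration", kd = 2.5e-9, noise_sd = 0)))
  half <- fit$s0 + (fit$smax - fit$s0) * fit$kd / (fit$kd + fit$kd)
  expect_equal(half, (fit$s0 + fit$smax) / 2, tolerance = 1e-10)

  # 2% noise on the standard grid: Kd typically within 15% (median
  # over fixed seeds; single draws can land in the ~35% tail)
  err <- vapply(1:25, function(seed) {
    noisy <- generate_binding(binding_sim_spec(
      type = "titration", kd = 2.5e-9, noise_sd = 0.02 * 500, seed = seed))
    abs(fit_saturation(noisy)$kd - 2.5e-9) / 2.5e-9
  }, numeric(1))
  expect_lt(median(err), 0.15)

  expect_error(fit_saturation(titration_curve(c(1e-9, 2e-9, 4e-9), 1:3)),
               ">= 4 concentrations")
  # a titration that never approaches saturation is flagged: the
  # fitted Kd exceeds the top concentration
  cc <- 1e-9 * 2^(0:5)
  unsat <- titration_curve(cc, 100 + 500 * cc / (5e-7 + cc))
  expect_warning(fit_saturation(unsat), "plateau")
})

test_that("fit_itc_one_site recovers the Wiseman isotherm", {
  spec <- binding_sim_spec(type = "itc", kd = 40e-9, n = 0.2,
                           delta_h = -10, offset = -0.2, noise_sd = 0)
  expt <- generate_binding(spec)
  fit <- fit_itc_one_site(expt)
  expect_equal(fit$n, 0.2, tolerance = 0.01)
  expect_equal(fit$kd, 40e-9, tolerance = 0.01)
  expect_equal(fit$delta_h, -10, tolerance = 0.01)
  expect_equal(fit$offset, -0.2, tolerance = 0.01)

  # thermodynamic identity holds to machine precision
  expect_identical(fit$delta_g, fit$delta_h + fit$minus_t_delta_s)
  expect_equal(fit$delta_g, 1.987e-3 * (273.15 + 15) * log(fit$kd),
               tolerance = 1e-12)

  # mass balance: baseline-corrected heats at saturation sum to
  # n * dH * (cell moles), independently of the fitting route
  heats <- expt$heats_ucal - (-0.2)
  total <- sum(heats) / 1e9                      # kcal
  expect_equal(total, 0.2 * (-10) * 20e-6 * 1.4e-3, tolerance = 0.02)

  # null enthalpy: every injection heat equals the dilution offset
  e0 <- generate_binding(binding_sim_spec(type = "itc", delta_h = 0,
                                          offset = -0.3, noise_sd = 0))
  expect_equal(e0$heats_ucal, rep(-0.3, 25), tolerance = 1e-12)

  # c-value outside [1, 1000] is flagged but still fitted
  loose <- generate_binding(binding_sim_spec(type = "itc", kd = 1e-3,
                                             n = 0.2, delta_h = -10,
                                             noise_sd = 0))
  expect_warning(fit_loose <- fit_itc_one_site(loose), "c-value")
  expect_true(is.finite(fit_loose$kd))
})

test_that("replicate aggregation reproduces the published table rows", {
  # BAF WT fluorescence replicates
  s <- aggregate_replicates("BAF WT", "fluorescence", "48 nt dsDNA",
                            c(2.10, 1.40, 4.20, 2.20, 2.80) * 1e-9)
  expect_equal(s$mean_kd, 2.54e-9, tolerance = 1e-12)
  expect_equal(s$sd_kd, 1.05e-9, tolerance = 0.005)
  # two-replicate SD follows the sample convention |x1 - x2|/sqrt(2)
  s2 <- aggregate_replicates("pBAF", "fluorescence", "48 nt dsDNA",
                             c(12.0, 9.40) * 1e-6)
  expect_equal(s2$mean_kd, 10.7e-6, tolerance = 1e-12)
  expect_equal(s2$sd_kd, abs(12.0 - 9.40) / sqrt(2) * 1e-6, tolerance = 1e-12)
  # single replicate: SD undefined
  s1 <- aggregate_replicates("x", "fluorescence", "y", 5e-8)
  expect_equal(s1$mean_kd, 5e-8)
  expect_true(is.na(s1$sd_kd))
  expect_error(aggregate_replicates("x", "itc", "y", numeric()), "one replicate")
})

test_that("fold_change propagates replicate uncertainty", {
  wt <- aggregate_replicates("BAF WT", "fluorescence", "48 nt dsDNA",
                             c(2.10, 1.40, 4.20, 2.20, 2.80) * 1e-9)
  pb <- aggregate_replicates("pBAF", "fluorescence", "48 nt dsDNA",
                             c(12.0, 9.40) * 1e-6)
  expect_equal(fold_change(wt, wt)$ratio, 1.0)
  fc <- fold_change(pb, wt)
  expect_equal(fc$ratio, 10.7e-6 / 2.54e-9, tolerance = 1e-12)
  expect_gt(fc$ratio, 4000)   # the ~5000-fold affinity loss, to order of magnitude
  expect_lt(fc$ratio, 5000)
  rel <- sqrt((pb$sd_kd / sqrt(2) / pb$mean_kd)^2 +
                (wt$sd_kd / sqrt(5) / wt$mean_kd)^2)
  expect_equal(fc$ratio_se, fc$ratio * rel, tolerance = 1e-12)
  # plain arithmetic case
  a <- aggregate_replicates("a", "itc", "x", 1e-6)
  b <- aggregate_replicates("b", "itc", "x", 2e-9)
  expect_equal(fold_change(a, b)$ratio, 500)
})

test_that("the shipped replicate table loads, flags the typo and summarises", {
  expect_message(reps <- baf_affinity_replicates(), "exponent sign")
  expect_equal(sum(reps$corrected), 1)
  expect_equal(reps$kd_M[reps$corrected], 3.00e-9)
  expect_true(all(reps$kd_M > 0 & reps$kd_M < 1e-3))

  sums <- baf_affinity_summaries(reps)
  wt_itc <- sums[sums$label == "BAF WT" & sums$method == "itc" &
                   sums$ligand == "48 nt dsDNA", ]
  expect_equal(wt_itc$mean_kd, mean(c(37.7, 44.4)) * 1e-9, tolerance = 1e-12)
})

test_that("titration and ITC readers parse the documented formats", {
  tpath <- tempfile(fileext = ".csv")
  write.csv(data.frame(conc_M = 1.6e-9 * 2^(0:7), signal = 1:8), tpath,
            row.names = FALSE)
  curve <- read_titration(tpath)
  expect_s3_class(curve, "titration_curve")
  expect_equal(length(curve$analyte_conc_M), 8)

  ipath <- tempfile(fileext = ".csv")
  write.csv(data.frame(injection_index = 1:10, volume_uL = 10,
                       heat_ucal = rnorm(10)), ipath, row.names = FALSE)
  hpath <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(cell_conc_M = 20e-6, syringe_conc_M = 100e-6,
                        cell_volume_mL = 1.4, temperature_C = 15), hpath)
  expt <- read_itc(ipath, hpath)
  expect_s3_class(expt, "itc_experiment")
  expect_equal(expt$cell_volume_L, 1.4e-3)
  expect_equal(length(expt$heats_ucal), 10)
})
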