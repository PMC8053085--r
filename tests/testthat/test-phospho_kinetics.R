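test_that("model_consecutive matches its limits and an ODE oracle", {
  m0 <- model_consecutive(0, 2, 0.5)
  expect_equal(unlist(m0[, c("f_a", "f_b", "f_c")]), c(f_a = 1, f_b = 0, f_c = 0))

  # absorbing intermediate: k2 = 0, large t
  m_abs <- model_consecutive(100, 2, 0)
  expect_equal(m_abs$f_b, 1, tolerance = 1e-12)
  expect_equal(m_abs$f_c, 0, tolerance = 1e-12)

  # analytic degenerate limit k1 = k2 = 1 at t = 1
  m_deg <- model_consecutive(1, 1, 1)
  expect_equal(m_deg$f_b, exp(-1), tolerance = 1e-12)

  # cross-check the closed form against RK4 integration of the rate
  # equations at a few (t, k1, k2)
  for (p in list(c(0.5, 2, 0.5), c(1.5, 1, 1), c(2, 10, 1.4))) {
    ode <- ode_consecutive(p[1], p[2], p[3], dt = 1e-3)
    m <- model_consecutive(p[1], p[2], p[3])
    expect_equal(unname(unlist(m[, c("f_a", "f_b", "f_c")])),
                 unname(ode), tolerance = 1e-8)
  }
})

test_that("fractions are conserved and continuous across the degeneracy", {
  set.seed(5)
  for (i in 1:50) {
    t <- runif(1, 0, 10); k1 <- runif(1, 0, 5); k2 <- runif(1, 0, 5)
    m <- model_consecutive(t, k1, k2)
    expect_equal(m$f_a + m$f_b + m$f_c, 1, tolerance = 1e-12)
    expect_true(all(unlist(m[, c("f_a", "f_b", "f_c")]) >= -1e-12))
  }
  # continuity when |k1 - k2| crosses the switch tolerance: the limit
  # branch (just inside) and exact branch (just outside) must agree
  t <- seq(0, 5, by = 0.25)
  k <- 1.7
  just_out <- model_consecutive(t, k, k * (1 + 1.001e-6))
  just_in <- model_consecutive(t, k, k * (1 + 0.999e-6))
  expect_lt(max(abs(just_out$f_b - just_in$f_b)), 1e-8)

  # intermediate maximum: closed form vs numerical maximisation
  for (p in list(c(2, 0.5), c(10, 1.4), c(1, 0.9))) {
    mx <- intermediate_maximum(p[1], p[2])
    num <- optimize(function(t) model_consecutive(t, p[1], p[2])$f_b,
                    c(0, 20), maximum = TRUE)
    expect_equal(mx$f_b_max, num$objective, tolerance = 1e-7)
    expect_equal(mx$t_max, num$maximum, tolerance = 1e-4)
  }
})

test_that("species_fractions normalises, averages and masks", {
  # one residue, intensities (3, 1, 0) -> (0.75, 0.25, 0)
  tri <- species_triplets(data.frame(
    residue_id = c(1, 1, 1, 2, 2, 2), atom_group = "bb",
    species = rep(c("A", "B", "C"), 2),
    shift_n = c(110, 112, 114, 120, 122, 124),
    shift_h = c(7.5, 7.7, 7.9, 8.5, 8.7, 8.9)))
  pl1 <- make_pl(c(NA, NA), shift_n = c(110, 112), shift_h = c(7.5, 7.7),
                 intensity = c(3, 1))
  s1 <- spectrum_series(0, list(pl1))
  fr1 <- species_fractions(s1, species_triplets(tri[tri$residue_id == 1, ]))
  expect_equal(unlist(fr1[, c("f_a", "f_b", "f_c")]),
               c(f_a = 0.75, f_b = 0.25, f_c = 0))

  # two residues with fractions (1,0,0) and (0.5,0.5,0): unweighted mean
  pl2 <- make_pl(c(NA, NA, NA),
                 shift_n = c(110, 120, 122), shift_h = c(7.5, 8.5, 8.7),
                 intensity = c(4, 2, 2))
  fr2 <- species_fractions(spectrum_series(0, list(pl2)), tri)
  expect_equal(unlist(fr2[, c("f_a", "f_b", "f_c")]),
               c(f_a = 0.75, f_b = 0.25, f_c = 0))
  expect_equal(fr2$n_residues_used, 2L)

  # t = 0 with only species-A peaks -> (1, 0, 0)
  pl0 <- make_pl(c(NA, NA), shift_n = c(110, 120), shift_h = c(7.5, 8.5),
                 intensity = c(5, 5))
  fr0 <- species_fractions(spectrum_series(0, list(pl0)), tri)
  expect_equal(unlist(fr0[, c("f_a", "f_b", "f_c")]),
               c(f_a = 1, f_b = 0, f_c = 0))

  # all triplets dark at a time point is an error
  dark <- make_pl(NA, shift_n = 135, shift_h = 12, intensity = 1)
  expect_error(
    suppressWarnings(species_fractions(spectrum_series(0, list(dark)), tri)),
    "zero total intensity")

  # unresolvable triplet positions are rejected up front
  expect_error(species_triplets(data.frame(
    residue_id = 1, atom_group = "bb", species = c("A", "B", "C"),
    shift_n = c(110, 110.1, 114), shift_h = c(7.5, 7.51, 7.9))),
    "not resolvable")
})

test_that("site occupancy traces normalise to the di-phospho plateau", {
  # k1 >> k2: the transient mono trace must exceed 70% before decaying
  spec <- kinetics_sim_spec(k1 = 8, k2 = 0.8, noise_cv = 0,
                            detection_floor = 0, time_hours = seq(0, 6, 0.25))
  g <- generate_kinetics_series(spec)
  tri12 <- g$triplets[g$triplets$residue_id == 12, ]
  tri27 <- g$triplets[g$triplets$residue_id == 27, ]
  psites <- data.frame(
    trace = c("pSer4_mono", "pSer4_di", "pThr3"),
    shift_n = c(tri12$shift_n[tri12$species == "B"],
                tri12$shift_n[tri12$species == "C"],
                tri27$shift_n[tri27$species == "C"]),
    shift_h = c(tri12$shift_h[tri12$species == "B"],
                tri12$shift_h[tri12$species == "C"],
                tri27$shift_h[tri27$species == "C"]))
  occ <- site_occupancy(g$series, psites)
  expect_gt(max(occ$pSer4_mono), 70)
  expect_lt(occ$pSer4_mono[nrow(occ)], 10)      # decays back towards 0
  expect_gt(occ$pSer4_di[nrow(occ)], 95)        # reaches its plateau
  expect_equal(mean(tail(occ$pThr3, 2)), 100)   # plateau anchor by construction

  # scale invariance: scaling every intensity leaves percentages unchanged
  scaled <- g$series
  for (i in seq_along(scaled$peak_lists)) {
    scaled$peak_lists[[i]]$peaks$intensity <-
      scaled$peak_lists[[i]]$peaks$intensity * 37.5
  }
  occ2 <- site_occupancy(scaled, psites)
  expect_equal(occ2$pSer4_mono, occ$pSer4_mono, tolerance = 1e-12)
})

test_that("consecutive-kinetics fitting recovers generating rates", {
  # noiseless closed loop at (2.0, 0.5) over 9 points / 4 h
  g <- generate_kinetics_series(kinetics_sim_spec(
    k1 = 2, k2 = 0.5, noise_cv = 0, detection_floor = 0))
  fr <- species_fractions(g$series, g$triplets)
  fit <- fit_consecutive_kinetics(fr)
  expect_equal(fit$k1, 2, tolerance = 1e-6)
  expect_equal(fit$k2, 0.5, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  expect_equal(fit$a0, 1)

  # 2% noise, fixed seed: within 10% relative
  g2 <- generate_kinetics_series(kinetics_sim_spec(
    k1 = 2, k2 = 0.5, noise_cv = 0.02, seed = 42))
  fit2 <- fit_consecutive_kinetics(species_fractions(g2$series, g2$triplets))
  expect_lt(abs(fit2$k1 - 2) / 2, 0.10)
  expect_lt(abs(fit2$k2 - 0.5) / 0.5, 0.10)

  # no-reaction limit: an all-A series drives k1 to its zero bound
  flat <- fraction_series(seq(0, 4, 0.5), f_a = rep(1, 9),
                          f_b = rep(0, 9), f_c = rep(0, 9))
  fit0 <- suppressWarnings(fit_consecutive_kinetics(flat))
  expect_lt(fit0$k1, 1e-6)

  expect_error(fit_consecutive_kinetics(flat[1:3, ]), "4 time points")
})
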