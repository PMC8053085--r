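#' Saturation-binding titration curve
#'
#' Signal versus analyte concentration for a surface assay in which the
#' ligand (dye-labelled dsDNA) is immobilised and the analyte is flowed
#' continuously, so the free analyte concentration equals the total --
#' no depletion term is needed.
#'
#' @param analyte_conc_M analyte concentrations (M); at least 4 values
#'   spanning at least one order of magnitude are required for a fit.
#' @param signal fluorescence signal (arbitrary units).
#' @param temperature_c assay temperature (default 10).
#' @return object of class `titration_curve`.
#' @export
titration_curve <- function(analyte_conc_M, signal, temperature_c = 10) {
  stopifnot(length(analyte_conc_M) == length(signal))
  if (any(analyte_conc_M <= 0)) stopf("concentrations must be positive")
  ord <- order(analyte_conc_M)
  structure(list(analyte_conc_M = analyte_conc_M[ord], signal = signal[ord],
                 temperature_c = temperature_c),
            class = "titration_curve")
}

#' Single-site ITC experiment
#'
#' Injection schedule and integrated heats of an isothermal titration
#' calorimetry run: a macromolecule at `cell_conc_M` in the cell is
#' titrated with ligand at `syringe_conc_M`.
#'
#' @param cell_conc_M cell (macromolecule) concentration (M).
#' @param syringe_conc_M syringe (titrant) concentration (M).
#' @param cell_volume_L active cell volume (L), e.g. 1.4e-3 for a VP-ITC.
#' @param injection_volumes_L per-injection volumes (L); >= 8 injections.
#' @param heats_ucal integrated heat per injection (microcalories).
#' @param temperature_c experiment temperature (default 15).
#' @return object of class `itc_experiment`.
#' @export
itc_experiment <- function(cell_conc_M, syringe_conc_M, cell_volume_L,
                           injection_volumes_L, heats_ucal,
                           temperature_c = 15) {
  if (cell_conc_M <= 0 || syringe_conc_M <= 0 || cell_volume_L <= 0) {
    stopf("concentrations and cell volume must be positive")
  }
  if (length(injection_volumes_L) != length(heats_ucal)) {
    stopf("injection_volumes_L and heats_ucal must have equal length")
  }
  if (length(heats_ucal) < 8) stopf("need >= 8 injections")
  if (any(injection_volumes_L <= 0)) stopf("injection volumes must be positive")
  structure(list(cell_conc_M = cell_conc_M, syringe_conc_M = syringe_conc_M,
                 cell_volume_L = cell_volume_L,
                 injection_volumes_L = injection_volumes_L,
                 heats_ucal = heats_ucal, temperature_c = temperature_c),
            class = "itc_experiment")
}

# Forward single-site ITC model: per-injection heats (ucal) with the
# standard displaced-volume dilution correction. dh in kcal/mol,
# offset in ucal per injection.
itc_forward_heats <- function(n, kd, dh_kcal, offset, expt) {
  v0 <- expt$cell_volume_L
  vi <- cumsum(expt$injection_volumes_L)
  mt <- expt$cell_conc_M * (1 - vi / (2 * v0)) / (1 + vi / (2 * v0))
  xt <- expt$syringe_conc_M * (vi / v0) / (1 + vi / (2 * v0))
  xr <- xt / (n * mt)
  kr <- kd / (n * mt)
  # cumulative heat content of the cell (kcal -> ucal via 1e9? no:
  # dh [kcal/mol] * mol = kcal; 1 kcal = 1e9 ucal)
  q <- n * mt * dh_kcal * v0 / 2 *
    (1 + xr + kr - sqrt((1 + xr + kr)^2 - 4 * xr)) * 1e9
  qprev <- c(0, q[-length(q)])
  dv <- expt$injection_volumes_L
  q - qprev + dv / v0 * (q + qprev) / 2 + offset
}

binding_fit <- function(method, kd, kd_se, n = 1, n_se = NA_real_,
                        delta_h = NA_real_, delta_h_se = NA_real_,
                        offset = NA_real_, s0 = NA_real_, smax = NA_real_,
                        s0_se = NA_real_, smax_se = NA_real_,
                        temperature_c, rss, c_value = NA_real_,
                        converged = TRUE) {
  tk <- temperature_c + .T0_K
  delta_g <- .R_KCAL * tk * log(kd)
  structure(list(method = method, kd = kd, kd_se = kd_se, n = n, n_se = n_se,
                 delta_h = delta_h, delta_h_se = delta_h_se, offset = offset,
                 s0 = s0, smax = smax, s0_se = s0_se, smax_se = smax_se,
                 temperature_c = temperature_c, temperature_k = tk,
                 delta_g = delta_g,
                 minus_t_delta_s = delta_g - delta_h,
                 rss = rss, c_value = c_value, converged = converged),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> %s at %g C\n", x$method, x$temperature_c))
  cat(sprintf("  Kd = %.4g +/- %.2g M\n", x$kd, x$kd_se))
  if (x$method == "itc") {
    cat(sprintf("  n = %.3g +/- %.2g, dH = %.4g kcal/mol, c = %.3g\n",
                x$n, x$n_se, x$delta_h, x$c_value))
    cat(sprintf("  dG = %.4g, -TdS = %.4g kcal/mol\n",
                x$delta_g, x$minus_t_delta_s))
  } else {
    cat(sprintf("  s0 = %.4g, smax = %.4g, dG = %.4g kcal/mol\n",
                x$s0, x$smax, x$delta_g))
  }
  invisible(x)
}

#' Fit a hyperbolic saturation-binding isotherm
#'
#' Least squares of `signal = s0 + (smax - s0) * c / (Kd + c)` with Kd
#' optimised on the log scale. Gross outliers (absolute residual beyond
#' 5 residual SDs) are rejected once with a warning and the fit is
#' repeated. A fitted Kd above the top concentration triggers a
#' poorly-constrained-plateau warning.
#'
#' @param curve a [titration_curve()]; needs >= 4 concentrations
#'   spanning >= 1 order of magnitude.
#' @return a `binding_fit` (method `"fluorescence"`, stoichiometry
#'   fixed at 1; `delta_h`/`-TdS` undefined).
#' @export
fit_saturation <- function(curve) {
  stopifnot(inherits(curve, "titration_curve"))
  cc <- curve$analyte_conc_M
  y <- curve$signal
  if (length(cc) < 4 || max(cc) / min(cc) < 10) {
    stopf("need >= 4 concentrations spanning >= 1 order of magnitude")
  }
  s0_0 <- y[1]
  smax_0 <- y[length(y)]
  half <- (s0_0 + smax_0) / 2
  kd_0 <- tryCatch({
    k <- suppressWarnings(stats::approx(y, cc, xout = half, ties = "ordered")$y)
    if (is.finite(k) && k > 0) k else stats::median(cc)
  }, error = function(e) stats::median(cc))

  do_fit <- function(cc, y) {
    resid_fn <- function(par) {
      s0 <- par[1]; smax <- par[2]; kd <- exp(par[3])
      y - (s0 + (smax - s0) * cc / (kd + cc))
    }
    lm_least_squares(c(s0_0, smax_0, log(kd_0)), resid_fn,
                     lower = c(-Inf, -Inf, log(min(cc) * 1e-6)),
                     upper = c(Inf, Inf, log(max(cc) * 1e6)))
  }
  fit <- do_fit(cc, y)
  # 5-sigma gross-outlier screen
  sig <- sqrt(fit$rss / fit$dof)
  out <- sig > 0 & abs(fit$residuals) > 5 * sig
  if (any(out)) {
    warnf("rejecting %d gross outlier(s) beyond 5 sigma", sum(out))
    cc <- cc[!out]; y <- y[!out]
    fit <- do_fit(cc, y)
  }
  if (!fit$converged) warnf("saturation fit did not converge")
  kd <- exp(fit$par[3])
  if (kd > max(cc)) {
    warnf("fitted Kd (%.3g M) exceeds the top concentration (%.3g M): plateau poorly constrained",
          kd, max(cc))
  }
  binding_fit("fluorescence", kd = kd, kd_se = kd * fit$se[3],
              s0 = fit$par[1], smax = fit$par[2],
              s0_se = fit$se[1], smax_se = fit$se[2],
              temperature_c = curve$temperature_c, rss = fit$rss,
              converged = fit$converged)
}

#' Fit a single-site ITC isotherm
#'
#' Fits the 1:1 Wiseman isotherm -- per-injection heats derived from
#' the binding polynomial with dilution-corrected running
#' concentrations -- for stoichiometry `n`, `Kd`, binding enthalpy
#' `dH` and a constant dilution-heat offset. The first injection is
#' excluded by default (common instrument artifact). `dG = RT ln Kd`
#' and `-TdS = dG - dH` are derived at the experiment temperature, so
#' the identity `dG = dH - TdS` holds by construction. A Wiseman
#' c-value (`n * [cell] / Kd`) outside [1, 1000] is flagged as
#' unreliable but the fit is still returned.
#'
#' @param expt an [itc_experiment()].
#' @param drop_first exclude the first injection from the fit
#'   (default TRUE).
#' @return a `binding_fit` (method `"itc"`).
#' @export
fit_itc_one_site <- function(expt, drop_first = TRUE) {
  stopifnot(inherits(expt, "itc_experiment"))
  keep <- seq_along(expt$heats_ucal)
  if (drop_first) keep <- keep[-1]

  # initial guesses: offset from the saturated tail, n from the molar
  # ratio at the steepest heat change, dH from the early plateau heights
  h <- expt$heats_ucal
  v0 <- expt$cell_volume_L
  vi <- cumsum(expt$injection_volumes_L)
  mt <- expt$cell_conc_M * (1 - vi / (2 * v0)) / (1 + vi / (2 * v0))
  xt <- expt$syringe_conc_M * (vi / v0) / (1 + vi / (2 * v0))
  ratio <- xt / mt
  tail_idx <- utils::tail(seq_along(h), 3)
  offset_0 <- mean(h[tail_idx])
  dh_corr <- h - offset_0
  dh_0 <- sum(dh_corr[keep]) / 1e9 / (expt$cell_conc_M * v0)  # kcal/mol, rough
  if (!is.finite(dh_0) || dh_0 == 0) dh_0 <- -1
  slope <- abs(diff(dh_corr))
  n_0 <- ratio[which.max(slope)]
  if (!is.finite(n_0) || n_0 <= 0) n_0 <- 1
  kd_0 <- expt$cell_conc_M / 10

  resid_fn <- function(par) {
    n <- exp(par[1]); kd <- exp(par[2])
    pred <- itc_forward_heats(n, kd, par[3], par[4], expt)
    (h - pred)[keep]
  }
  fit <- lm_least_squares(
    c(log(n_0), log(kd_0), dh_0, offset_0), resid_fn,
    lower = c(log(1e-3), log(1e-15), -1e4, -Inf),
    upper = c(log(1e3), log(1), 1e4, Inf))
  if (!fit$converged) warnf("ITC fit did not converge (RSS %.3g)", fit$rss)
  n <- exp(fit$par[1]); kd <- exp(fit$par[2])
  c_value <- n * expt$cell_conc_M / kd
  if (c_value < 1 || c_value > 1000) {
    warnf("Wiseman c-value %.3g outside [1, 1000]: fit unreliable", c_value)
  }
  binding_fit("itc", kd = kd, kd_se = kd * fit$se[2],
              n = n, n_se = n * fit$se[1],
              delta_h = fit$par[3], delta_h_se = fit$se[3],
              offset = fit$par[4], temperature_c = expt$temperature_c,
              rss = fit$rss, c_value = c_value, converged = fit$converged)
}

#' Aggregate replicate dissociation constants
#'
#' Arithmetic mean and sample (n-1) standard deviation of replicate Kd
#' measurements; the SD is undefined for a single replicate. The
#' sample convention is the one consistent with two-replicate SDs of
#' the form |x1 - x2|/sqrt(2).
#'
#' @param label construct name (e.g. "BAF WT").
#' @param method `"fluorescence"` or `"itc"`.
#' @param ligand ligand description (e.g. "48 nt dsDNA").
#' @param replicate_kds replicate Kd values (M), length >= 1.
#' @return object of class `affinity_summary`.
#' @export
aggregate_replicates <- function(label, method = c("fluorescence", "itc"),
                                 ligand, replicate_kds) {
  method <- match.arg(method)
  if (length(replicate_kds) < 1) stopf("need at least one replicate")
  if (any(replicate_kds <= 0)) stopf("Kd values must be positive")
  n <- length(replicate_kds)
  structure(list(label = label, method = method, ligand = ligand,
                 replicate_kds = replicate_kds,
                 mean_kd = mean(replicate_kds),
                 sd_kd = if (n > 1) stats::sd(replicate_kds) else NA_real_,
                 n_replicates = n),
            class = "affinity_summary")
}

#' @export
print.affinity_summary <- function(x, ...) {
  cat(sprintf("<affinity_summary> %s / %s / %s: Kd = %.3g M (SD %.3g, n = %d)\n",
              x$label, x$method, x$ligand, x$mean_kd, x$sd_kd, x$n_replicates))
  invisible(x)
}

#' Fold change between two affinity summaries
#'
#' Ratio of mean Kd values (numerator over denominator) with a relative
#' standard error propagated in quadrature from the standard errors of
#' the two means (SD/sqrt(n)); undefined when either summary has a
#' single replicate.
#'
#' @param summary_num,summary_den [aggregate_replicates()] objects.
#' @return list with `ratio` and `ratio_se`.
#' @export
fold_change <- function(summary_num, summary_den) {
  stopifnot(inherits(summary_num, "affinity_summary"),
            inherits(summary_den, "affinity_summary"))
  if (summary_den$mean_kd <= 0) stopf("denominator mean must be > 0")
  ratio <- summary_num$mean_kd / summary_den$mean_kd
  rel <- function(s) {
    if (s$n_replicates > 1) (s$sd_kd / sqrt(s$n_replicates)) / s$mean_kd
    else NA_real_
  }
  r1 <- rel(summary_num); r2 <- rel(summary_den)
  ratio_se <- if (is.na(r1) || is.na(r2)) NA_real_
              else ratio * sqrt(r1^2 + r2^2)
  list(ratio = ratio, ratio_se = ratio_se)
}

#' Read a titration CSV (conc_M, signal)
#'
#' @param path CSV with header `conc_M,signal`.
#' @param temperature_c assay temperature.
#' @return a [titration_curve()].
#' @export
read_titration <- function(path, temperature_c = 10) {
  df <- utils::read.csv(path)
  if (!all(c("conc_M", "signal") %in% names(df))) {
    stopf("titration CSV must have header conc_M,signal")
  }
  titration_curve(df$conc_M, df$signal, temperature_c)
}

#' Read an ITC experiment (injection CSV plus YAML header)
#'
#' @param csv_path CSV with header `injection_index,volume_uL,heat_ucal`.
#' @param header_path YAML with keys `cell_conc_M`, `syringe_conc_M`,
#'   `cell_volume_mL`, `temperature_C`.
#' @return an [itc_experiment()].
#' @export
read_itc <- function(csv_path, header_path) {
  df <- utils::read.csv(csv_path)
  needed <- c("injection_index", "volume_uL", "heat_ucal")
  if (!all(needed %in% names(df))) {
    stopf("ITC CSV must have header %s", paste(needed, collapse = ","))
  }
  hd <- yaml::read_yaml(header_path)
  for (k in c("cell_conc_M", "syringe_conc_M", "cell_volume_mL", "temperature_C")) {
    if (is.null(hd[[k]])) stopf("ITC header is missing key '%s'", k)
  }
  df <- df[order(df$injection_index), ]
  itc_experiment(cell_conc_M = hd$cell_conc_M,
                 syringe_conc_M = hd$syringe_conc_M,
                 cell_volume_L = hd$cell_volume_mL * 1e-3,
                 injection_volumes_L = df$volume_uL * 1e-6,
                 heats_ucal = df$heat_ucal,
                 temperature_c = hd$temperature_C)
}
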