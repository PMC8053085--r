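#' Fit a mono-exponential relaxation decay
#'
#' Nonlinear least squares of \eqn{I(\tau) = I_0 e^{-R\tau}} to a
#' per-residue pseudo-3D decay. Replicates are pooled into the fit as
#' repeated observations (not pre-averaged), so the residual scatter --
#' and hence the SE, taken from the fit covariance -- reflects the
#' replicate noise. Starting values come from a log-linear regression
#' on the positive intensities.
#'
#' @param delay_s relaxation delays in seconds (>= 3 distinct values).
#' @param intensity peak intensities, same length as `delay_s`.
#' @return list with `rate` (per second), `rate_se`, `i0`, `i0_se`,
#'   `rss`, `n`.
#' @export
fit_rate <- function(delay_s, intensity) {
  stopifnot(length(delay_s) == length(intensity))
  keep <- is.finite(delay_s) & is.finite(intensity)
  delay_s <- delay_s[keep]; intensity <- intensity[keep]
  if (length(unique(delay_s)) < 3) stopf("need >= 3 distinct delay points")
  if (all(intensity <= 0)) stopf("all intensities are non-positive")
  pos <- intensity > 0
  co <- stats::coef(stats::lm(log(intensity[pos]) ~ delay_s[pos]))
  i0_0 <- exp(co[1])
  r_0 <- max(-co[2], 0)
  resid_fn <- function(par) intensity - par[1] * exp(-par[2] * delay_s)
  fit <- lm_least_squares(c(i0_0, r_0), resid_fn,
                          lower = c(0, 0), upper = c(Inf, Inf))
  if (!fit$converged) warnf("relaxation fit did not converge (RSS %.3g)", fit$rss)
  list(rate = fit$par[2], rate_se = fit$se[2],
       i0 = fit$par[1], i0_se = fit$se[1],
       rss = fit$rss, n = length(delay_s))
}

#' Heteronuclear 1H->15N nOe ratio
#'
#' Ratio of saturated to unsaturated peak intensities from interleaved
#' NOE/NONOE experiments. With replicated pairs the nOe is the mean of
#' the per-replicate ratios and the SE is the sample SD of the ratios
#' divided by sqrt(n). Values near 0.8 indicate a rigid backbone amide
#' at high field; the theoretical ceiling is about 1.1 (warned above).
#'
#' @param sat_intensity intensities with 1H saturation (vector over
#'   replicates).
#' @param nosat_intensity reference intensities without saturation;
#'   recycled if a single value is given.
#' @return list with `noe`, `noe_se`, `n`.
#' @export
compute_noe <- function(sat_intensity, nosat_intensity) {
  if (length(nosat_intensity) == 1) {
    nosat_intensity <- rep(nosat_intensity, length(sat_intensity))
  }
  stopifnot(length(sat_intensity) == length(nosat_intensity))
  if (any(nosat_intensity <= 0)) stopf("reference (NONOE) intensity must be > 0")
  ratios <- sat_intensity / nosat_intensity
  noe <- mean(ratios)
  n <- length(ratios)
  se <- if (n > 1) stats::sd(ratios) / sqrt(n) else NA_real_
  if (noe > 1.1) warnf("nOe %.3g exceeds the theoretical limit (~1.1)", noe)
  list(noe = noe, noe_se = se, n = n)
}

#' Read a relaxation intensity table
#'
#' CSV with columns `residue`, `experiment` (`R1`, `R2` or `noe`),
#' `delay_s` (empty for nOe rows), `sat` (TRUE/FALSE, nOe rows only),
#' `replicate`, `intensity`.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_relaxation_table <- function(path) {
  if (!file.exists(path)) stopf("relaxation table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("residue", "experiment", "delay_s", "sat", "replicate", "intensity")
  if (!all(needed %in% names(df))) {
    stopf("relaxation table must have columns %s", paste(needed, collapse = ", "))
  }
  if (!all(df$experiment %in% c("R1", "R2", "noe"))) {
    stopf("experiment must be one of R1, R2, noe")
  }
  df$sat <- as.logical(df$sat)
  df
}

#' Fit R1, R2 and nOe for every residue of a relaxation table
#'
#' @param table data.frame in the [read_relaxation_table()] schema.
#' @param expected_residues residues that should be observable; those
#'   absent from `table` are reported with `observable = FALSE`
#'   (exchange-broadened amides that yield no cross-peak). Default:
#'   only the residues present.
#' @return data.frame of class `relaxation_records` with per-residue
#'   `r1`, `r2`, `noe` (+ SEs) and `observable`.
#' @export
fit_relaxation <- function(table, expected_residues = NULL) {
  present <- sort(unique(table$residue))
  resids <- if (is.null(expected_residues)) present
            else sort(unique(c(expected_residues)))
  rec <- data.frame(residue_id = resids,
                    r1 = NA_real_, r1_se = NA_real_,
                    r2 = NA_real_, r2_se = NA_real_,
                    noe = NA_real_, noe_se = NA_real_,
                    observable = resids %in% present)
  for (i in seq_len(nrow(rec))) {
    rid <- rec$residue_id[i]
    if (!rec$observable[i]) next
    for (expt in c("R1", "R2")) {
      d <- table[table$residue == rid & table$experiment == expt, ]
      if (nrow(d) == 0) next
      f <- fit_rate(d$delay_s, d$intensity)
      if (expt == "R1") {
        rec$r1[i] <- f$rate; rec$r1_se[i] <- f$rate_se
      } else {
        rec$r2[i] <- f$rate; rec$r2_se[i] <- f$rate_se
      }
    }
    d <- table[table$residue == rid & table$experiment == "noe", ]
    if (nrow(d) > 0) {
      reps <- sort(unique(d$replicate))
      sat <- vapply(reps, function(r) {
        mean(d$intensity[d$replicate == r & d$sat])
      }, numeric(1))
      nos <- vapply(reps, function(r) {
        mean(d$intensity[d$replicate == r & !d$sat])
      }, numeric(1))
      keep <- is.finite(sat) & is.finite(nos)
      if (any(keep)) {
        nv <- compute_noe(sat[keep], nos[keep])
        rec$noe[i] <- nv$noe; rec$noe_se[i] <- nv$noe_se
      }
    }
  }
  class(rec) <- unique(c("relaxation_records", class(rec)))
  rec
}

trim_stats <- function(x, trim = 0.1) {
  x <- sort(x[is.finite(x)])
  k <- floor(length(x) * trim)
  if (k > 0) x <- x[(k + 1):(length(x) - k)]
  list(mean = mean(x), sd = stats::sd(x))
}

#' Classify backbone dynamics from relaxation rates
#'
#' Operationalises the qualitative relaxation signatures: elevated R2
#' flags slow (microsecond-millisecond) exchange; elevated R1 together
#' with a low nOe flags fast (picosecond-nanosecond) flexibility; an
#' nOe close to 0.8 with unremarkable rates is a rigid amide. Cohort
#' baselines are 10%-trimmed means and SDs over the observed residues,
#' so a flexible tail does not inflate the baseline. Precedence:
#' unobservable > slow_exchange > fast_flexible > rigid > unclassified.
#'
#' @param records a `relaxation_records` data.frame ([fit_relaxation()]).
#' @param sd_factor exceedance threshold in cohort SD units (default 2).
#' @param noe_flexible nOe below which an R1-exceeding residue is
#'   fast_flexible (default 0.65).
#' @param noe_rigid nOe at or above which a quiet residue is rigid
#'   (default 0.75).
#' @param trim trimming fraction for the cohort statistics (default 0.1).
#' @return `records` with a `dynamics_class` factor column and the
#'   cohort statistics in `attr(, "cohort")`.
#' @export
classify_dynamics <- function(records, sd_factor = 2, noe_flexible = 0.65,
                              noe_rigid = 0.75, trim = 0.1) {
  obs <- records[records$observable & is.finite(records$r1) &
                   is.finite(records$r2) & is.finite(records$noe), ]
  if (nrow(obs) < 5) stopf("need >= 5 observed residues for cohort statistics")
  st_r1 <- trim_stats(obs$r1, trim)
  st_r2 <- trim_stats(obs$r2, trim)
  cls <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (!r$observable) { cls[i] <- "unobservable"; next }
    high_r2 <- is.finite(r$r2) && r$r2 > st_r2$mean + sd_factor * st_r2$sd
    high_r1 <- is.finite(r$r1) && r$r1 > st_r1$mean + sd_factor * st_r1$sd
    low_noe <- is.finite(r$noe) && r$noe < noe_flexible
    if (high_r2) cls[i] <- "slow_exchange"
    else if (high_r1 && low_noe) cls[i] <- "fast_flexible"
    else if (is.finite(r$noe) && r$noe >= noe_rigid) cls[i] <- "rigid"
    else cls[i] <- "unclassified"
  }
  records$dynamics_class <- factor(
    cls, levels = c("rigid", "fast_flexible", "slow_exchange",
                    "unobservable", "unclassified"))
  attr(records, "cohort") <- list(r1 = st_r1, r2 = st_r2,
                                  sd_factor = sd_factor,
                                  noe_flexible = noe_flexible,
                                  noe_rigid = noe_rigid, trim = trim)
  records
}

#' Write per-residue relaxation results to CSV
#'
#' @param records a `relaxation_records` data.frame.
#' @param path output path.
#' @export
write_relaxation <- function(records, path) {
  df <- records
  if (!is.null(df$dynamics_class)) df$dynamics_class <- as.character(df$dynamics_class)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
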