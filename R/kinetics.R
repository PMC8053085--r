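#' Consecutive two-step first-order kinetic model
#'
#' Closed-form species fractions for the irreversible scheme
#' A -> B -> C (non- -> mono- -> di-phosphorylated protein) under
#' pseudo-first-order conditions (catalytic kinase, no phosphatase):
#' \deqn{f_A = e^{-k_1 t}}
#' \deqn{f_B = \frac{k_1}{k_2 - k_1}(e^{-k_1 t} - e^{-k_2 t})}
#' \deqn{f_C = 1 - f_A - f_B}
#' The intermediate term is evaluated as
#' \eqn{f_B = k_1 e^{-k_1 t} \cdot (1 - e^{-(k_2-k_1)t})/(k_2-k_1)}
#' via `expm1` for numerical stability; below the degeneracy switch
#' (relative rate difference under 1e-6) the analytic limit
#' \eqn{f_B = k_1 t e^{-k_1 t}} with its first two series corrections
#' in \eqn{(k_2-k_1)t} is used, so the branch change is continuous well
#' below 1e-8.
#'
#' @param t times in hours (vectorised), >= 0.
#' @param k1 rate of the first phosphorylation (Ser4), per hour.
#' @param k2 rate of the second phosphorylation (Thr3), per hour.
#' @return data.frame with columns `time_hours`, `f_a`, `f_b`, `f_c`;
#'   fractions lie in \[0, 1\] and sum to 1.
#' @export
model_consecutive <- function(t, k1, k2) {
  stopifnot(all(t >= 0), k1 >= 0, k2 >= 0)
  f_a <- exp(-k1 * t)
  d <- k2 - k1
  if (abs(d) < 1e-6 * max(k1, k2, .Machine$double.eps)) {
    # analytic k1 -> k2 limit with series corrections in d*t
    f_b <- k1 * exp(-k1 * t) * t * (1 - d * t / 2 + (d * t)^2 / 6)
  } else {
    f_b <- k1 * exp(-k1 * t) * (-expm1(-d * t)) / d
  }
  f_b <- pmin(pmax(f_b, 0), 1)
  data.frame(time_hours = t, f_a = f_a, f_b = f_b, f_c = 1 - f_a - f_b)
}

#' Peak-position triplets of the three phosphorylation species
#'
#' One reporter residue contributes three well-separated peak
#' positions: non- (A), mono- (B) and di-phosphorylated (C) species.
#' The default reporters mirror the residues whose peaks shift most --
#' Ala12, Gly27 and the Trp84 indole side chain -- but any set is
#' accepted.
#'
#' @param triplets data.frame with columns `residue_id`, `atom_group`,
#'   `species` (`"A"|"B"|"C"`), `shift_n`, `shift_h` (three rows per
#'   residue).
#' @param tol_h,tol_n tolerances the positions must exceed pairwise.
#' @return data.frame of class `species_triplets`.
#' @export
species_triplets <- function(triplets, tol_h = 0.05, tol_n = 0.5) {
  needed <- c("residue_id", "atom_group", "species", "shift_n", "shift_h")
  if (!all(needed %in% names(triplets))) {
    stopf("triplets must have columns %s", paste(needed, collapse = ", "))
  }
  for (rid in unique(triplets$residue_id)) {
    tr <- triplets[triplets$residue_id == rid, ]
    if (!setequal(tr$species, c("A", "B", "C"))) {
      stopf("residue %s must define species A, B and C", rid)
    }
    for (i in 1:2) for (j in (i + 1):3) {
      sep_h <- abs(tr$shift_h[i] - tr$shift_h[j]) > tol_h
      sep_n <- abs(tr$shift_n[i] - tr$shift_n[j]) > tol_n
      if (!(sep_h || sep_n)) {
        stopf("residue %s: species %s and %s are not resolvable at tol (%g, %g)",
              rid, tr$species[i], tr$species[j], tol_h, tol_n)
      }
    }
  }
  class(triplets) <- unique(c("species_triplets", class(triplets)))
  triplets
}

# Intensity at a given position: nearest peak within the tolerance box,
# 0 when none.
intensity_at <- function(pl, shift_n, shift_h, tol_h, tol_n) {
  p <- pl$peaks
  dh <- abs(p$shift_h - shift_h)
  dn <- abs(p$shift_n - shift_n)
  ok <- which(dh <= tol_h & dn <= tol_n)
  if (!length(ok)) return(0)
  d <- sqrt(dh[ok]^2 + (dn[ok] / 5)^2)
  p$intensity[ok[which.min(d)]]
}

#' Species fractions from a real-time HSQC series
#'
#' For each reporter residue and time point, the intensities at the
#' three species positions (0 when no peak lies within the tolerance
#' box) are normalised to their sum; per-time-point fractions are the
#' unweighted mean over residues. A residue whose triplet sum is zero
#' at a time point is excluded there; a time point where all residues
#' are excluded is an error.
#'
#' @param series a [spectrum_series()].
#' @param triplets a [species_triplets()] data.frame.
#' @param tol_h,tol_n matching tolerances in ppm.
#' @return data.frame of class `fraction_series` with columns
#'   `time_hours`, `f_a`, `f_b`, `f_c`, `n_residues_used`; the
#'   per-residue fractions are kept in `attr(, "per_residue")`.
#' @export
species_fractions <- function(series, triplets, tol_h = 0.05, tol_n = 0.5) {
  stopifnot(inherits(series, "spectrum_series"))
  if (!inherits(triplets, "species_triplets")) {
    triplets <- species_triplets(triplets, tol_h, tol_n)
  }
  rids <- unique(triplets$residue_id)
  nt <- length(series$time_hours)
  per <- expand.grid(time_hours = series$time_hours, residue_id = rids,
                     KEEP.OUT.ATTRS = FALSE)
  per$f_a <- per$f_b <- per$f_c <- NA_real_
  for (it in seq_len(nt)) {
    pl <- series$peak_lists[[it]]
    for (rid in rids) {
      tr <- triplets[triplets$residue_id == rid, ]
      ints <- vapply(c("A", "B", "C"), function(sp) {
        row <- tr[tr$species == sp, ]
        intensity_at(pl, row$shift_n, row$shift_h, tol_h, tol_n)
      }, numeric(1))
      s <- sum(ints)
      k <- per$time_hours == series$time_hours[it] & per$residue_id == rid
      if (s > 0) {
        per$f_a[k] <- ints[1] / s
        per$f_b[k] <- ints[2] / s
        per$f_c[k] <- ints[3] / s
      }
    }
  }
  agg <- data.frame(time_hours = series$time_hours, f_a = NA_real_,
                    f_b = NA_real_, f_c = NA_real_, n_residues_used = 0L)
  for (it in seq_len(nt)) {
    k <- per$time_hours == series$time_hours[it] & !is.na(per$f_a)
    if (!any(k)) {
      stopf("all residue triplets have zero total intensity at t = %g h",
            series$time_hours[it])
    }
    agg$f_a[it] <- mean(per$f_a[k])
    agg$f_b[it] <- mean(per$f_b[k])
    agg$f_c[it] <- mean(per$f_c[k])
    agg$n_residues_used[it] <- sum(k)
  }
  attr(agg, "per_residue") <- per
  class(agg) <- unique(c("fraction_series", class(agg)))
  agg
}

#' Build a fraction series from bare fractions
#'
#' Convenience constructor (used by the generators and for externally
#' tabulated fractions). Fractions are renormalised to sum to 1 and
#' validated.
#'
#' @param time_hours increasing times.
#' @param f_a,f_b,f_c species fractions per time point.
#' @param n_residues_used bookkeeping column (default 1).
#' @return A `fraction_series` data.frame.
#' @export
fraction_series <- function(time_hours, f_a, f_b, f_c, n_residues_used = 1L) {
  s <- f_a + f_b + f_c
  if (any(s <= 0)) stopf("fractions must have a positive sum at every time point")
  out <- data.frame(time_hours = time_hours, f_a = f_a / s, f_b = f_b / s,
                    f_c = f_c / s, n_residues_used = n_residues_used)
  if (any(out$f_a < 0 | out$f_b < 0 | out$f_c < 0)) {
    stopf("fractions must be non-negative")
  }
  class(out) <- unique(c("fraction_series", class(out)))
  out
}

#' Phosphosite occupancy traces normalised to plateau
#'
#' Follows the intensities of the phosphosite reporter peaks --
#' pSer4 in the mono-phosphorylated species, pSer4 and pThr3 in the
#' di-phosphorylated species -- and converts them to percentages.
#' The two di-phospho traces are each normalised to their own plateau
#' (mean of their last two time points); the transient mono-pSer4
#' trace, whose own plateau is ~0, is normalised to the di-pSer4
#' plateau (the same spin, so intensities are comparable). In a
#' sequential reaction the mono trace rises (to ~75% when the first
#' step is much faster than the second) and then decays back towards 0.
#'
#' @param series a [spectrum_series()].
#' @param psite_peaks data.frame with columns `trace`
#'   (`"pSer4_mono"`, `"pSer4_di"`, `"pThr3"`), `shift_n`, `shift_h`.
#' @param tol_h,tol_n matching tolerances.
#' @return data.frame `time_hours`, `pSer4_mono`, `pSer4_di`, `pThr3`
#'   (percent).
#' @export
site_occupancy <- function(series, psite_peaks, tol_h = 0.05, tol_n = 0.5) {
  stopifnot(inherits(series, "spectrum_series"))
  traces <- c("pSer4_mono", "pSer4_di", "pThr3")
  if (!all(traces %in% psite_peaks$trace)) {
    stopf("psite_peaks must define traces %s", paste(traces, collapse = ", "))
  }
  nt <- length(series$time_hours)
  raw <- sapply(traces, function(tr) {
    row <- psite_peaks[psite_peaks$trace == tr, ][1, ]
    vapply(series$peak_lists, intensity_at, numeric(1),
           shift_n = row$shift_n, shift_h = row$shift_h,
           tol_h = tol_h, tol_n = tol_n)
  })
  if (nt < 2) stopf("need at least two time points")
  plateau <- function(v) mean(v[c(nt - 1, nt)])
  p_di_s4 <- plateau(raw[, "pSer4_di"])
  p_di_t3 <- plateau(raw[, "pThr3"])
  if (p_di_s4 <= 0 || p_di_t3 <= 0) {
    stopf("di-phospho plateau intensity is zero; cannot normalise")
  }
  data.frame(time_hours = series$time_hours,
             pSer4_mono = 100 * raw[, "pSer4_mono"] / p_di_s4,
             pSer4_di = 100 * raw[, "pSer4_di"] / p_di_s4,
             pThr3 = 100 * raw[, "pThr3"] / p_di_t3)
}

#' Fit the consecutive kinetic model to species fractions
#'
#' Weighted least squares of all three fraction traces simultaneously
#' against [model_consecutive()]. Rates are optimised on the log scale
#' (hence bounded to be positive); standard errors come from the fit
#' covariance by the delta method. Initial guesses: `k1` from the
#' half-life of the unphosphorylated trace, `k2 = k1/3`.
#'
#' @param fractions a `fraction_series` data.frame.
#' @param weights optional per-time-point weights (recycled over the
#'   three traces); default equal weights.
#' @param fit_t0 also fit a dead-time offset `t0` (hours) between
#'   kinase addition and the first spectrum; default FALSE (t0 = 0).
#' @return Object of class `kinetic_fit`: `k1`, `k2` (per hour), their
#'   SEs, `a0` (initial unphosphorylated fraction, fixed at 1), `t0`,
#'   `rss`, and a `fitted(t)` evaluator.
#' @export
fit_consecutive_kinetics <- function(fractions, weights = NULL, fit_t0 = FALSE) {
  t <- fractions$time_hours
  if (length(t) < 4) stopf("need at least 4 time points")
  obs <- as.matrix(fractions[, c("f_a", "f_b", "f_c")])
  if (any(!is.finite(obs)) || any(obs < -1e-9 | obs > 1 + 1e-9)) {
    stopf("fractions must be finite and within [0, 1]")
  }
  w <- if (is.null(weights)) rep(1, length(t)) else weights
  sw <- sqrt(rep(w, times = 3))

  # k1 guess: interpolated half-life of the A trace
  t_half <- if (any(obs[, 1] < 0.5)) {
    i <- which(obs[, 1] < 0.5)[1]
    if (i == 1) max(t[1], diff(range(t)) / 20) else {
      stats::approx(obs[c(i - 1, i), 1], t[c(i - 1, i)], xout = 0.5)$y
    }
  } else max(t)
  k1_0 <- max(log(2) / t_half, 1e-4)

  resid_fn <- function(par) {
    k1 <- exp(par[1]); k2 <- exp(par[2])
    t0 <- if (fit_t0) par[3] else 0
    m <- model_consecutive(pmax(t - t0, 0), k1, k2)
    sw * (c(obs[, 1], obs[, 2], obs[, 3]) - c(m$f_a, m$f_b, m$f_c))
  }
  par0 <- c(log(k1_0), log(k1_0 / 3))
  lower <- c(log(1e-8), log(1e-8))
  upper <- c(log(1e4), log(1e4))
  if (fit_t0) {
    par0 <- c(par0, 0)
    lower <- c(lower, -max(t))
    upper <- c(upper, max(t))
  }
  fit <- lm_least_squares(par0, resid_fn, lower, upper)
  if (!fit$converged) {
    warnf("kinetic fit did not converge (RSS %.3g, guesses k1=%.3g k2=%.3g)",
          fit$rss, k1_0, k1_0 / 3)
  }
  k1 <- exp(fit$par[1]); k2 <- exp(fit$par[2])
  t0 <- if (fit_t0) fit$par[3] else 0
  out <- list(k1 = k1, k2 = k2,
              k1_se = k1 * fit$se[1], k2_se = k2 * fit$se[2],
              a0 = 1, t0 = t0,
              t0_se = if (fit_t0) fit$se[3] else NA_real_,
              rss = fit$rss, converged = fit$converged,
              fitted = function(t) model_consecutive(pmax(t - t0, 0), k1, k2),
              n_time_points = length(t))
  class(out) <- "kinetic_fit"
  out
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> consecutive A -> B -> C\n"))
  cat(sprintf("  k1 = %.4g +/- %.2g h^-1 (Ser4)\n", x$k1, x$k1_se))
  cat(sprintf("  k2 = %.4g +/- %.2g h^-1 (Thr3)\n", x$k2, x$k2_se))
  if (x$t0 != 0) cat(sprintf("  t0 = %.3g h\n", x$t0))
  cat(sprintf("  RSS = %.4g over %d time points%s\n", x$rss, x$n_time_points,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Time and height of the intermediate-species maximum
#'
#' For `k1 != k2` the mono-phosphorylated fraction peaks at
#' `t* = log(k1/k2)/(k1 - k2)` with height
#' `(k2/k1)^(k2/(k1-k2))`; the degenerate limit gives `t* = 1/k` and
#' height `1/e`.
#'
#' @param k1,k2 rates (per hour).
#' @return list with `t_max` (hours) and `f_b_max`.
#' @export
intermediate_maximum <- function(k1, k2) {
  stopifnot(k1 > 0, k2 > 0)
  if (abs(k1 - k2) < 1e-6 * max(k1, k2)) {
    k <- (k1 + k2) / 2
    list(t_max = 1 / k, f_b_max = exp(-1))
  } else {
    list(t_max = log(k1 / k2) / (k1 - k2),
         f_b_max = (k2 / k1)^(k2 / (k1 - k2)))
  }
}
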