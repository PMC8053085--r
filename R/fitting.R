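# Internal nonlinear least-squares machinery shared by all fits.
#
# A compact Levenberg-Marquardt with box constraints is used instead of
# stats::nls because the round-trip tests fit noiseless (zero-residual)
# data, on which nls' step-halving aborts. Jacobians are central
# differences; parameter uncertainties come from the usual linearised
# covariance sigma^2 (J'J)^-1.

num_jacobian <- function(fn, par, eps = 1e-6) {
  r0 <- fn(par)
  J <- matrix(0, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(abs(par[j]), 1e-4)
    pp <- pm <- par
    pp[j] <- par[j] + h
    pm[j] <- par[j] - h
    J[, j] <- (fn(pp) - fn(pm)) / (2 * h)
  }
  J
}

#' @noRd
lm_least_squares <- function(par, resid_fn,
                             lower = rep(-Inf, length(par)),
                             upper = rep(Inf, length(par)),
                             max_iter = 200L, ftol = 1e-14, ptol = 1e-12) {
  par <- pmin(pmax(unname(par), lower), upper)
  r <- resid_fn(par)
  cost <- sum(r^2)
  lambda <- 1e-3
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    J <- num_jacobian(resid_fn, par)
    A <- crossprod(J)
    g <- crossprod(J, r)
    improved <- FALSE
    for (try in 1:25) {
      Areg <- A + lambda * diag(pmax(diag(A), 1e-12), nrow(A))
      step <- tryCatch(solve(Areg, g), error = function(e) NULL)
      if (is.null(step)) {
        lambda <- lambda * 10
        next
      }
      par_new <- pmin(pmax(par - drop(step), lower), upper)
      r_new <- resid_fn(par_new)
      cost_new <- sum(r_new^2)
      if (is.finite(cost_new) && cost_new <= cost) {
        rel_drop <- (cost - cost_new) / max(cost, .Machine$double.xmin)
        rel_step <- max(abs(par_new - par) / pmax(abs(par), 1e-8))
        par <- par_new
        r <- r_new
        cost <- cost_new
        lambda <- max(lambda / 10, 1e-12)
        improved <- TRUE
        if (rel_drop < ftol || rel_step < ptol || cost < 1e-300) converged <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!improved || converged) {
      converged <- converged || !improved
      break
    }
  }
  J <- num_jacobian(resid_fn, par)
  A <- crossprod(J)
  dof <- max(length(r) - length(par), 1L)
  sigma2 <- cost / dof
  cov <- tryCatch(sigma2 * solve(A), error = function(e) {
    matrix(NA_real_, length(par), length(par))
  })
  se <- sqrt(pmax(diag(cov), 0))
  list(par = par, se = se, cov = cov, rss = cost, dof = dof,
       converged = converged, iterations = iter, residuals = r)
}

# Evaluate an expression with a temporary RNG state derived from `seed`,
# restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Gas constant in kcal mol^-1 K^-1 and Celsius -> Kelvin offset.
.R_KCAL <- 1.987e-3
.T0_K <- 273.15

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
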