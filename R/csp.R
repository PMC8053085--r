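#' Per-residue chemical shift perturbations between two states
#'
#' For every backbone amide present in `state_a`, the combined 1H/15N
#' shift perturbation against `state_b` is
#' \deqn{\Delta\delta = \sqrt{(\delta_{HN,A}-\delta_{HN,B})^2 +
#'   (\delta_{N,A}-\delta_{N,B})^2/25}}
#' the conventional weighting that scales the 15N dispersion onto the
#' 1H scale. Residues with no partner in `state_b` (e.g. exchange
#' broadened after the perturbation) get `csp_class = "missing"` rather
#' than an imputed zero.
#'
#' @param state_a,state_b [peak_list()] objects (e.g. unmodified and
#'   phosphorylated protein). Both must be non-empty.
#' @param tol_h,tol_n matching tolerances passed to [match_peaks()]
#'   (used only for unassigned peaks; assigned peaks pair by residue).
#' @param thresholds classification thresholds, see [classify_csp()].
#' @param include_sidechains keep side-chain NH entries (default FALSE;
#'   they are excluded from backbone summaries unless requested).
#' @return data.frame of class `csp_records` with columns `residue_id`,
#'   `atom_group`, `delta_ppm`, `csp_class`.
#' @export
compute_csp <- function(state_a, state_b, tol_h = 0.05, tol_n = 0.5,
                        thresholds = c(0.15, 0.5, 1.0, 2.0),
                        include_sidechains = FALSE) {
  stopifnot(inherits(state_a, "peak_list"), inherits(state_b, "peak_list"))
  if (nrow(state_a$peaks) == 0 || nrow(state_b$peaks) == 0) {
    stopf("both peak lists must be non-empty")
  }
  m <- match_peaks(state_a, state_b, tol_h, tol_n)
  m <- m[!is.na(m$residue_id), , drop = FALSE]
  if (!include_sidechains) m <- m[m$atom_group == "bb", , drop = FALSE]
  delta <- ifelse(m$matched,
                  sqrt((m$ref_shift_h - m$qry_shift_h)^2 +
                         (m$ref_shift_n - m$qry_shift_n)^2 / 25),
                  NA_real_)
  rec <- data.frame(residue_id = m$residue_id, atom_group = m$atom_group,
                    delta_ppm = delta, stringsAsFactors = FALSE)
  rec <- rec[order(rec$residue_id), ]
  rownames(rec) <- NULL
  classify_csp(rec, thresholds)
}

csp_class_labels <- function(thresholds) {
  if (length(thresholds) == 4 &&
      isTRUE(all.equal(thresholds, c(0.15, 0.5, 1.0, 2.0)))) {
    c("unshifted", "shifted", "large", "very_large", "extreme")
  } else {
    c("unshifted", paste0("gt_", format(thresholds, trim = TRUE)))
  }
}

#' Classify chemical shift perturbations
#'
#' Assigns each record the highest threshold class its perturbation
#' exceeds, using strict inequalities: a value exactly at a threshold
#' falls in the lower class. The default thresholds
#' (0.15, 0.5, 1.0, 2.0 ppm) give the classes
#' unshifted / shifted / large / very_large / extreme; unmatched
#' residues are "missing".
#'
#' @param records a `csp_records` data.frame (or any data.frame with a
#'   `delta_ppm` column).
#' @param thresholds strictly increasing ppm thresholds.
#' @return `records` with `csp_class` (factor) filled; idempotent.
#' @export
classify_csp <- function(records, thresholds = c(0.15, 0.5, 1.0, 2.0)) {
  if (length(thresholds) < 1 || any(diff(thresholds) <= 0)) {
    stopf("thresholds must be strictly increasing")
  }
  labels <- csp_class_labels(thresholds)
  d <- records$delta_ppm
  if (any(d < 0, na.rm = TRUE)) stopf("delta_ppm must be >= 0")
  idx <- vapply(d, function(x) {
    if (is.na(x)) return(NA_integer_)
    sum(x > thresholds) + 1L
  }, integer(1))
  cls <- ifelse(is.na(idx), "missing", labels[idx])
  records$csp_class <- factor(cls, levels = c(labels, "missing"))
  class(records) <- unique(c("csp_records", class(records)))
  records
}

#' Fraction of residues shifting beyond a cutoff
#'
#' Counts records with perturbation strictly greater than `cutoff`
#' among the non-missing records; missing residues are excluded from
#' the denominator (zero-imputation would understate perturbation).
#'
#' @param records a `csp_records` data.frame.
#' @param cutoff ppm cutoff (default 0.15).
#' @return A fraction in \[0, 1\].
#' @export
fraction_shifted <- function(records, cutoff = 0.15) {
  d <- records$delta_ppm
  n_obs <- sum(!is.na(d))
  if (n_obs == 0) stopf("all records are missing")
  sum(d > cutoff, na.rm = TRUE) / n_obs
}

#' Intensity-loss filter for complex-formation mapping
#'
#' Compares per-residue peak intensities of a labelled component alone
#' and in the presence of binding partners, to identify residues whose
#' peaks decrease by more than `threshold` (default 80%) -- the
#' intensity-loss criterion used to map ternary-complex formation.
#' Residues that vanish from the complexed spectrum get a loss of 1;
#' residues with zero reference intensity are skipped with a warning.
#'
#' @param reference,complexed [peak_list()] objects.
#' @param threshold loss fraction in (0, 1); default 0.8.
#' @param tol_h,tol_n matching tolerances.
#' @return data.frame with `residue_id`, `i_ref`, `i_complex`,
#'   `loss_fraction` (floored at 0) and logical `bound_flag`.
#' @export
intensity_loss_filter <- function(reference, complexed, threshold = 0.8,
                                  tol_h = 0.05, tol_n = 0.5) {
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0, 1)")
  m <- match_peaks(reference, complexed, tol_h, tol_n)
  m <- m[!is.na(m$residue_id), , drop = FALSE]
  zero <- m$ref_intensity == 0
  if (any(zero)) {
    warnf("skipping %d residue(s) with zero reference intensity", sum(zero))
    m <- m[!zero, , drop = FALSE]
  }
  loss <- ifelse(m$matched,
                 pmax(0, 1 - m$qry_intensity / m$ref_intensity), 1)
  data.frame(residue_id = m$residue_id, atom_group = m$atom_group,
             i_ref = m$ref_intensity, i_complex = ifelse(m$matched, m$qry_intensity, 0),
             loss_fraction = loss, bound_flag = loss > threshold,
             stringsAsFactors = FALSE)
}

#' Write chemical-shift-perturbation records to CSV
#'
#' @param records a `csp_records` data.frame.
#' @param path output path.
#' @export
write_csp <- function(records, path) {
  utils::write.csv(
    data.frame(residue = records$residue_id,
               delta_ppm = records$delta_ppm,
               csp_class = as.character(records$csp_class)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
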