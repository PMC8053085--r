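#' Assembled 2D 1H-15N peak list
#'
#' A `peak_list` holds picked, assigned amide cross-peaks of one
#' heteronuclear single-quantum coherence (HSQC) spectrum: one row per
#' N-H group with its 15N and 1H chemical shifts (ppm) and a peak
#' intensity in arbitrary units. Residue numbering is 1-based on the
#' native 89-aa BAF sequence (the N-terminal construct residue is
#' residue 1); side-chain NH peaks (e.g. the Trp84 indole) carry
#' `atom_group = "sc"`. Unassigned peaks have `residue_id = NA`.
#'
#' @param peaks data.frame with columns `residue_id` (integer or NA),
#'   `atom_group` (`"bb"` backbone amide or `"sc"` side chain),
#'   `shift_n` (ppm), `shift_h` (ppm), `intensity` (>= 0); an optional
#'   `assignment` column preserves the verbatim assignment string.
#' @param label free-text label (species or time-point name).
#' @param field_mhz spectrometer 1H frequency (default 700 MHz).
#' @param temperature_c,ph sample conditions recorded as metadata.
#'
#' @details Amide peaks are validated against typical ranges
#'   (1H within 5-13 ppm, 15N within 100-140 ppm; a warning is emitted
#'   outside). At most one backbone-amide peak per residue is allowed;
#'   residues may be absent (prolines, exchange-broadened amides).
#'
#' @return An object of class `peak_list`.
#' @export
peak_list <- function(peaks, label = "", field_mhz = 700,
                      temperature_c = 30, ph = 7.2) {
  needed <- c("residue_id", "atom_group", "shift_n", "shift_h", "intensity")
  if (!is.data.frame(peaks) || !all(needed %in% names(peaks))) {
    stopf("`peaks` must be a data.frame with columns %s",
          paste(needed, collapse = ", "))
  }
  peaks <- as.data.frame(peaks, stringsAsFactors = FALSE)
  peaks$residue_id <- as.integer(peaks$residue_id)
  peaks$atom_group <- as.character(peaks$atom_group)
  if (!all(peaks$atom_group %in% c("bb", "sc"))) {
    stopf("atom_group must be 'bb' or 'sc'")
  }
  if (is.null(peaks$assignment)) {
    peaks$assignment <- ifelse(
      is.na(peaks$residue_id), "?-?",
      paste0("X", peaks$residue_id,
             ifelse(peaks$atom_group == "bb", "N-H", "sc")))
  }
  if (any(!is.finite(peaks$intensity)) || any(peaks$intensity < 0)) {
    stopf("peak intensities must be finite and non-negative")
  }
  bb <- peaks[peaks$atom_group == "bb" & !is.na(peaks$residue_id), ]
  if (anyDuplicated(bb$residue_id)) {
    dup <- unique(bb$residue_id[duplicated(bb$residue_id)])
    stopf("duplicate backbone-amide assignment for residue(s) %s",
          paste(dup, collapse = ", "))
  }
  out_of_range <- peaks$shift_h < 5 | peaks$shift_h > 13 |
    peaks$shift_n < 100 | peaks$shift_n > 140
  if (any(out_of_range)) {
    warnf("%d peak(s) outside typical amide shift ranges (1H 5-13 ppm, 15N 100-140 ppm)",
          sum(out_of_range))
  }
  structure(
    list(label = label,
         peaks = peaks[, c("residue_id", "atom_group", "assignment",
                           "shift_n", "shift_h", "intensity")],
         field_mhz = field_mhz, temperature_c = temperature_c, ph = ph),
    class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> '%s': %d peaks (%d backbone), %g MHz, %g C, pH %g\n",
              x$label, nrow(x$peaks),
              sum(x$peaks$atom_group == "bb"), x$field_mhz,
              x$temperature_c, x$ph))
  invisible(x)
}

# Parse a Sparky assignment like "G27N-H", "W84NE1-HE1" or "?-?".
parse_assignment <- function(s) {
  if (grepl("^\\?", s)) {
    return(list(residue_id = NA_integer_, atom_group = "bb"))
  }
  m <- regmatches(s, regexec("^([A-Za-z]*)([0-9]+)(.*)$", s))[[1]]
  if (length(m) == 0) return(NULL)
  res <- as.integer(m[3])
  atoms <- toupper(m[4])
  ag <- if (atoms %in% c("", "N-H", "N-HN", "H-N", "NH")) "bb"
        else if (identical(tolower(m[4]), "sc")) "sc"
        else "sc"
  list(residue_id = res, atom_group = ag)
}

#' Read a peak list from disk
#'
#' Two dialects are supported: `"sparky"`, whitespace-delimited columns
#' `Assignment  w1(15N)  w2(1H)  Height` (a leading header line starting
#' with "Assignment" is skipped), and `"csv"` with header
#' `residue,atom,shift_n_ppm,shift_h_ppm,intensity` where `atom` is
#' `bb`/`sc` (an empty `residue` means unassigned).
#'
#' @param path file path.
#' @param dialect `"sparky"` (default) or `"csv"`.
#' @param ... metadata passed on to [peak_list()] (`label`, `field_mhz`, ...).
#' @return A [peak_list()].
#' @export
read_peak_list <- function(path, dialect = c("sparky", "csv"), ...) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("peak list file not found: %s", path)
  if (dialect == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    needed <- c("residue", "atom", "shift_n_ppm", "shift_h_ppm", "intensity")
    if (!all(needed %in% names(df))) {
      stopf("CSV peak list %s must have header %s", path,
            paste(needed, collapse = ","))
    }
    if (nrow(df) == 0) warnf("empty peak list: %s", path)
    peaks <- data.frame(
      residue_id = suppressWarnings(as.integer(df$residue)),
      atom_group = ifelse(df$atom %in% c("bb", "sc"), df$atom, "bb"),
      shift_n = as.numeric(df$shift_n_ppm),
      shift_h = as.numeric(df$shift_h_ppm),
      intensity = as.numeric(df$intensity),
      stringsAsFactors = FALSE)
    return(peak_list(peaks, ...))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines) & !grepl("^\\s*Assignment", lines)
  rows <- which(keep)
  if (length(rows) == 0) {
    warnf("empty peak list: %s", path)
    return(peak_list(data.frame(residue_id = integer(), atom_group = character(),
                                shift_n = numeric(), shift_h = numeric(),
                                intensity = numeric()), ...))
  }
  recs <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    ln <- rows[i]
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4) stopf("%s:%d: unparseable row (need 4 columns): '%s'",
                               path, ln, lines[ln])
    asg <- parse_assignment(tok[1])
    vals <- suppressWarnings(as.numeric(tok[2:4]))
    if (is.null(asg) || any(is.na(vals))) {
      stopf("%s:%d: unparseable row: '%s'", path, ln, lines[ln])
    }
    recs[[i]] <- data.frame(residue_id = asg$residue_id,
                            atom_group = asg$atom_group,
                            assignment = tok[1],
                            shift_n = vals[1], shift_h = vals[2],
                            intensity = vals[3], stringsAsFactors = FALSE)
  }
  peak_list(do.call(rbind, recs), ...)
}

#' Write a peak list to disk
#'
#' Inverse of [read_peak_list()]: chemical shifts are written with 3
#' decimal places and intensities with 6 significant figures, so a
#' read/write/read round trip preserves both at that precision.
#'
#' @param x a [peak_list()].
#' @param path output path.
#' @param dialect `"sparky"` or `"csv"`.
#' @export
write_peak_list <- function(x, path, dialect = c("sparky", "csv")) {
  dialect <- match.arg(dialect)
  p <- x$peaks
  if (dialect == "csv") {
    df <- data.frame(residue = ifelse(is.na(p$residue_id), "", p$residue_id),
                     atom = p$atom_group,
                     shift_n_ppm = sprintf("%.3f", p$shift_n),
                     shift_h_ppm = sprintf("%.3f", p$shift_h),
                     intensity = sprintf("%.6g", p$intensity))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    lines <- c(" Assignment  w1  w2  Height",
               sprintf("%s %.3f %.3f %.6g",
                       p$assignment, p$shift_n, p$shift_h, p$intensity))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Match peaks between two spectra
#'
#' Peaks carrying the same assignment (residue and atom group) in both
#' lists are paired directly. Remaining unassigned query peaks are then
#' paired greedily to the nearest unused reference peak within the
#' tolerance box, ranked by the combined distance
#' sqrt(dH^2 + (dN/5)^2); each reference peak is used at most once.
#' Reference peaks with no partner are flagged absent -- absences are
#' data (exchange broadening), not errors.
#'
#' @param reference,query [peak_list()] objects.
#' @param tol_h,tol_n matching tolerances in ppm (defaults 0.05 / 0.5,
#'   typical 700-MHz linewidths).
#' @return data.frame with one row per reference peak: `residue_id`,
#'   `atom_group`, reference and query shifts/intensities, combined
#'   `distance` and logical `matched`.
#' @export
match_peaks <- function(reference, query, tol_h = 0.05, tol_n = 0.5) {
  stopifnot(inherits(reference, "peak_list"), inherits(query, "peak_list"))
  if (tol_h <= 0 || tol_n <= 0) stopf("tolerances must be positive")
  ref <- reference$peaks
  qry <- query$peaks
  n <- nrow(ref)
  out <- data.frame(residue_id = ref$residue_id, atom_group = ref$atom_group,
                    ref_shift_n = ref$shift_n, ref_shift_h = ref$shift_h,
                    ref_intensity = ref$intensity,
                    qry_shift_n = NA_real_, qry_shift_h = NA_real_,
                    qry_intensity = NA_real_, distance = NA_real_,
                    matched = FALSE, stringsAsFactors = FALSE)
  used_q <- rep(FALSE, nrow(qry))
  # 1) pair by assignment
  for (i in seq_len(n)) {
    if (is.na(ref$residue_id[i])) next
    j <- which(!used_q & !is.na(qry$residue_id) &
                 qry$residue_id == ref$residue_id[i] &
                 qry$atom_group == ref$atom_group[i])
    if (length(j)) {
      j <- j[1]
      used_q[j] <- TRUE
      out$qry_shift_n[i] <- qry$shift_n[j]
      out$qry_shift_h[i] <- qry$shift_h[j]
      out$qry_intensity[i] <- qry$intensity[j]
      out$distance[i] <- sqrt((ref$shift_h[i] - qry$shift_h[j])^2 +
                                ((ref$shift_n[i] - qry$shift_n[j]) / 5)^2)
      out$matched[i] <- TRUE
    }
  }
  # 2) greedy positional pairing of unassigned query peaks
  free_q <- which(!used_q & is.na(qry$residue_id))
  free_r <- which(!out$matched)
  if (length(free_q) && length(free_r)) {
    cand <- expand.grid(r = free_r, q = free_q)
    dh <- abs(ref$shift_h[cand$r] - qry$shift_h[cand$q])
    dn <- abs(ref$shift_n[cand$r] - qry$shift_n[cand$q])
    ok <- dh <= tol_h & dn <= tol_n
    cand <- cand[ok, , drop = FALSE]
    cand$d <- sqrt(dh[ok]^2 + (dn[ok] / 5)^2)
    cand <- cand[order(cand$d), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      i <- cand$r[k]; j <- cand$q[k]
      if (out$matched[i] || used_q[j]) next
      used_q[j] <- TRUE
      out$qry_shift_n[i] <- qry$shift_n[j]
      out$qry_shift_h[i] <- qry$shift_h[j]
      out$qry_intensity[i] <- qry$intensity[j]
      out$distance[i] <- cand$d[k]
      out$matched[i] <- TRUE
    }
  }
  out
}
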