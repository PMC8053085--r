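#' Time-resolved series of HSQC peak lists
#'
#' Orders one [peak_list()] per reaction time point (hours since kinase
#' addition). Time points must be unique and are sorted ascending; the
#' spacing need not be uniform (spectra are typically acquired every
#' 30 min).
#'
#' @param time_hours numeric vector of times, first >= 0.
#' @param peak_lists list of [peak_list()], same length as `time_hours`.
#' @return An object of class `spectrum_series`.
#' @export
spectrum_series <- function(time_hours, peak_lists) {
  if (length(time_hours) != length(peak_lists)) {
    stopf("time_hours and peak_lists must have equal length")
  }
  if (!all(vapply(peak_lists, inherits, logical(1), "peak_list"))) {
    stopf("peak_lists must all be peak_list objects")
  }
  if (anyDuplicated(time_hours)) {
    stopf("duplicate time points: %s",
          paste(unique(time_hours[duplicated(time_hours)]), collapse = ", "))
  }
  if (length(time_hours) && min(time_hours) < 0) stopf("time points must be >= 0")
  ord <- order(time_hours)
  structure(list(time_hours = as.numeric(time_hours[ord]),
                 peak_lists = peak_lists[ord]),
            class = "spectrum_series")
}

#' @export
print.spectrum_series <- function(x, ...) {
  cat(sprintf("<spectrum_series> %d time points over %g h\n",
              length(x$time_hours), max(x$time_hours, 0)))
  invisible(x)
}

#' @export
length.spectrum_series <- function(x) length(x$time_hours)

#' Read a spectrum series from a YAML manifest
#'
#' The manifest lists (time, file) pairs:
#' ```yaml
#' series:
#'   dialect: sparky
#'   time_hours: [0, 0.5, 1.0]
#'   files: [t0.list, t05.list, t10.list]
#' ```
#' Relative file paths are resolved against the manifest location. The
#' returned series is sorted by time; duplicate time points or a file
#' error (annotated with its time point) abort the read.
#'
#' @param manifest path to the YAML manifest.
#' @return A [spectrum_series()].
#' @export
read_series <- function(manifest) {
  if (!file.exists(manifest)) stopf("manifest not found: %s", manifest)
  cfg <- yaml::read_yaml(manifest)
  s <- cfg$series
  if (is.null(s) || is.null(s$time_hours) || is.null(s$files)) {
    stopf("manifest must define series.time_hours and series.files")
  }
  tt <- as.numeric(unlist(s$time_hours))
  ff <- as.character(unlist(s$files))
  if (length(tt) != length(ff)) {
    stopf("series.time_hours and series.files differ in length")
  }
  if (anyDuplicated(tt)) {
    stopf("manifest has duplicate time points: %s",
          paste(unique(tt[duplicated(tt)]), collapse = ", "))
  }
  dialect <- if (is.null(s$dialect)) "sparky" else s$dialect
  base <- dirname(normalizePath(manifest))
  pls <- vector("list", length(ff))
  for (i in seq_along(ff)) {
    path <- if (grepl("^(/|[A-Za-z]:)", ff[i])) ff[i] else file.path(base, ff[i])
    pls[[i]] <- tryCatch(
      read_peak_list(path, dialect = dialect, label = sprintf("t=%gh", tt[i])),
      error = function(e) stopf("at t = %g h (%s): %s", tt[i], ff[i],
                                conditionMessage(e)))
  }
  spectrum_series(tt, pls)
}

#' Write a spectrum series (peak lists plus manifest)
#'
#' Writes one peak-list file per time point into `dir` and a
#' `manifest.yaml` that [read_series()] can consume.
#'
#' @param x a [spectrum_series()].
#' @param dir output directory (created if needed).
#' @param dialect peak-list dialect.
#' @return The manifest path, invisibly.
#' @export
write_series <- function(x, dir, dialect = c("sparky", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "spectrum_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (dialect == "csv") "csv" else "list"
  files <- sprintf("t%03d.%s", seq_along(x$time_hours) - 1L, ext)
  for (i in seq_along(files)) {
    write_peak_list(x$peak_lists[[i]], file.path(dir, files[i]), dialect)
  }
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(series = list(dialect = dialect,
                                      time_hours = x$time_hours,
                                      files = files)), manifest)
  invisible(manifest)
}
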