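# Reading, writing, binning and normalizing unit-resolution EI spectra.

#' Construct a raw (unbinned) mass spectrum
#'
#' A raw spectrum is a list of centroided peaks (m/z, intensity) plus
#' identifying metadata. Intensities are in arbitrary instrument units;
#' normalization happens later, after nominal-mass binning.
#'
#' @param mz numeric vector of m/z values (Da), all > 0.
#' @param intensity numeric vector of non-negative intensities, same length.
#' @param spectrum_id non-empty identifier, unique within a collection.
#' @param compound compound label (free text).
#' @param truth one of `"known_positive"`, `"known_negative"`, `"unknown"`.
#' @param source originating laboratory/instrument label.
#' @return An object of class `raw_spectrum`.
#' @seealso [bin_to_nominal()], [read_msp()]
#' @export
raw_spectrum <- function(mz, intensity, spectrum_id, compound = "",
                         truth = c("unknown", "known_positive", "known_negative"),
                         source = "") {
  truth <- match.arg(truth)
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("`mz` and `intensity` must have the same length", call. = FALSE)
  if (any(!is.finite(mz)) || any(mz <= 0))
    stop("all m/z values must be finite and > 0", call. = FALSE)
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("all intensities must be finite and >= 0", call. = FALSE)
  if (!is.character(spectrum_id) || length(spectrum_id) != 1L || !nzchar(spectrum_id))
    stop("`spectrum_id` must be a non-empty string", call. = FALSE)
  structure(
    list(peaks = data.frame(mz = mz, intensity = intensity),
         meta = list(spectrum_id = spectrum_id, compound = compound,
                     truth = truth, source = source)),
    class = "raw_spectrum")
}

#' @export
print.raw_spectrum <- function(x, ...) {
  cat(sprintf("raw_spectrum '%s' (%s, %s): %d peaks, m/z %.1f-%.1f\n",
              x$meta$spectrum_id, x$meta$compound, x$meta$truth,
              nrow(x$peaks), min(x$peaks$mz), max(x$peaks$mz)))
  invisible(x)
}

#' Construct a nominal (unit-resolution, normalized) spectrum
#'
#' Channels map integer nominal m/z to relative abundance in percent of the
#' base peak; a non-empty spectrum always has its maximum at exactly 100.
#'
#' @param channels named numeric vector; names are integer m/z (Da), values
#'   relative abundances. Normalized on construction.
#' @param meta metadata list as in [raw_spectrum()].
#' @return An object of class `nominal_spectrum`.
#' @export
nominal_spectrum <- function(channels, meta) {
  if (length(channels)) {
    mz <- as.integer(names(channels))
    if (any(is.na(mz))) stop("channel names must be integer m/z", call. = FALSE)
    channels <- normalize_to_base_peak(channels)
    channels <- channels[order(mz)]
  }
  structure(list(channels = channels, meta = meta), class = "nominal_spectrum")
}

#' @export
print.nominal_spectrum <- function(x, ...) {
  bp <- names(x$channels)[which.max(x$channels)]
  cat(sprintf("nominal_spectrum '%s' (%s, %s): %d channels, base peak m/z %s\n",
              x$meta$spectrum_id, x$meta$compound, x$meta$truth,
              length(x$channels), bp %||% "-"))
  invisible(x)
}

#' Normalize channel intensities to percent of the base peak
#'
#' Scales a channel vector so that the most intense channel (the base peak)
#' is exactly 100; ratios between channels are preserved. Idempotent and
#' invariant to multiplying all intensities by a positive constant.
#'
#' @param channels named numeric vector of non-negative intensities with at
#'   least one positive value.
#' @return The rescaled vector (max exactly 100).
#' @export
normalize_to_base_peak <- function(channels) {
  if (!length(channels) || max(channels) <= 0)
    stop("cannot normalize: spectrum has no positive-intensity channel", call. = FALSE)
  if (any(channels < 0))
    stop("negative channel intensities are not allowed", call. = FALSE)
  100 * channels / max(channels)
}

#' Bin a raw spectrum to nominal (integer) m/z and normalize
#'
#' Peaks whose m/z round (half-up) to the same integer are summed — summing
#' conserves ion current within a unit-mass channel — and the binned spectrum
#' is then normalized to its base peak at 100%.
#'
#' @param s a [raw_spectrum()].
#' @return A [nominal_spectrum()] carrying the same metadata.
#' @export
bin_to_nominal <- function(s) {
  stopifnot(inherits(s, "raw_spectrum"))
  if (!nrow(s$peaks)) stop("cannot bin an empty spectrum", call. = FALSE)
  bins <- round_half_up(s$peaks$mz)
  summed <- tapply(s$peaks$intensity, bins, sum)
  channels <- as.numeric(summed)
  names(channels) <- names(summed)
  nominal_spectrum(channels, s$meta)
}

# ---- MSP text format ------------------------------------------------------

#' Read spectra from an MSP (NIST text) file
#'
#' Accepts the common MSP dialect: records separated by blank lines, a
#' mandatory `Name:` header, optional `Comment:` and `Num Peaks:` headers,
#' then peak lines of "mz intensity" pairs separated by whitespace or
#' semicolons. Metadata written by [write_msp()] (`spectrum_id`, `truth`,
#' `source` as `key=value` pairs in the comment) is recovered; a record
#' without them gets `truth = "unknown"` and a positional id.
#'
#' @param path path to an MSP file.
#' @return List of [raw_spectrum()] objects in file order (empty file gives
#'   an empty list).
#' @export
read_msp <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  rec_name <- NULL; rec_comment <- ""; rec_mz <- numeric(); rec_int <- numeric()
  rec_start <- 0L
  flush_record <- function() {
    if (is.null(rec_name) && !length(rec_mz)) return(invisible())
    if (is.null(rec_name))
      stop(sprintf("MSP record starting near line %d has no 'Name:' header",
                   rec_start), call. = FALSE)
    meta <- parse_msp_comment(rec_comment)
    id <- meta$spectrum_id %||% sprintf("%s_%04d", rec_name, length(spectra) + 1L)
    spectra[[length(spectra) + 1L]] <<- raw_spectrum(
      rec_mz, rec_int, spectrum_id = id,
      compound = meta$compound %||% rec_name,
      truth = meta$truth %||% "unknown",
      source = meta$source %||% "")
    rec_name <<- NULL; rec_comment <<- ""; rec_mz <<- numeric(); rec_int <<- numeric()
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) { flush_record(); next }
    if (!length(rec_mz) && is.null(rec_name)) rec_start <- i
    if (grepl("^Name\\s*:", line, ignore.case = TRUE)) {
      rec_name <- trimws(sub("^Name\\s*:", "", line, ignore.case = TRUE))
    } else if (grepl("^Comment[s]?\\s*:", line, ignore.case = TRUE)) {
      rec_comment <- trimws(sub("^Comment[s]?\\s*:", "", line, ignore.case = TRUE))
    } else if (grepl("^Num\\s*Peaks\\s*:", line, ignore.case = TRUE)) {
      # informational; peak count is validated implicitly by parsing
    } else if (grepl("^[A-Za-z][A-Za-z_ ]*:", line)) {
      # unrecognized header (Formula:, MW:, ...) — ignored
    } else {
      tok <- strsplit(line, "[;,[:space:]]+")[[1]]
      tok <- tok[nzchar(tok)]
      val <- suppressWarnings(as.numeric(tok))
      if (length(tok) < 2L || length(tok) %% 2L != 0L || any(is.na(val)))
        stop(sprintf("malformed MSP peak line %d: '%s'", i, line), call. = FALSE)
      idx <- seq(1L, length(val), by = 2L)
      rec_mz <- c(rec_mz, val[idx]); rec_int <- c(rec_int, val[idx + 1L])
    }
  }
  flush_record()
  spectra
}

parse_msp_comment <- function(comment) {
  out <- list()
  if (!nzchar(comment)) return(out)
  for (part in strsplit(comment, ";")[[1]]) {
    kv <- strsplit(trimws(part), "=")[[1]]
    if (length(kv) == 2L) out[[trimws(kv[[1]])]] <- trimws(kv[[2]])
  }
  out
}

#' Write spectra to an MSP (NIST text) file
#'
#' Emits UTF-8 text with one record per spectrum: `Name:` (compound),
#' a `Comment:` carrying `spectrum_id`/`truth`/`source` as `key=value`
#' pairs, `Num Peaks:` and peak lines at 6 significant digits. Round trips
#' through [read_msp()] losslessly at that precision.
#'
#' @param spectra list of [raw_spectrum()] objects.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_msp <- function(spectra, path) {
  stopifnot(is.list(spectra))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (s in spectra) {
    stopifnot(inherits(s, "raw_spectrum"))
    name <- if (nzchar(s$meta$compound)) s$meta$compound else s$meta$spectrum_id
    header <- c(
      sprintf("Name: %s", name),
      sprintf("Comment: spectrum_id=%s; truth=%s; source=%s; compound=%s",
              s$meta$spectrum_id, s$meta$truth, s$meta$source, s$meta$compound),
      sprintf("Num Peaks: %d", nrow(s$peaks)),
      sprintf("%s %s",
              formatC(s$peaks$mz, digits = 6, format = "g"),
              formatC(s$peaks$intensity, digits = 6, format = "g")),
      "")
    writeLines(enc2utf8(header), con, useBytes = TRUE)
  }
  invisible(path)
}

# ---- CSV peak tables ------------------------------------------------------

#' Read spectra from a CSV peak table
#'
#' Two dialects are accepted (header required in both):
#' \describe{
#'   \item{long}{columns `spectrum_id`, `mz`, `intensity` and optionally
#'     `compound`, `truth`, `source`; one row per peak.}
#'   \item{wide}{one row per spectrum; columns `spectrum_id`, optionally
#'     `compound`/`truth`/`source`, then integer m/z columns of intensities.}
#' }
#'
#' @param path path to a CSV file.
#' @param format `"long"`, `"wide"`, or `"auto"` (detected from the header).
#' @return List of [raw_spectrum()] objects.
#' @export
read_peaks_csv <- function(path, format = c("auto", "long", "wide")) {
  format <- match.arg(format)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"spectrum_id" %in% names(df))
    stop("CSV peak table must have a 'spectrum_id' column", call. = FALSE)
  if (format == "auto")
    format <- if (all(c("mz", "intensity") %in% names(df))) "long" else "wide"
  get_meta <- function(rows, col, default) {
    if (col %in% names(df)) as.character(rows[[col]][1]) else default
  }
  if (format == "long") {
    if (!all(c("mz", "intensity") %in% names(df)))
      stop("long-format CSV needs 'mz' and 'intensity' columns", call. = FALSE)
    ids <- unique(df$spectrum_id)
    lapply(ids, function(id) {
      rows <- df[df$spectrum_id == id, , drop = FALSE]
      raw_spectrum(rows$mz, rows$intensity, spectrum_id = as.character(id),
                   compound = get_meta(rows, "compound", ""),
                   truth = get_meta(rows, "truth", "unknown"),
                   source = get_meta(rows, "source", ""))
    })
  } else {
    meta_cols <- intersect(c("spectrum_id", "compound", "truth", "source"), names(df))
    mz_cols <- setdiff(names(df), meta_cols)
    mz <- suppressWarnings(as.numeric(mz_cols))
    if (any(is.na(mz)))
      stop("wide-format CSV: non-metadata columns must be numeric m/z", call. = FALSE)
    lapply(seq_len(nrow(df)), function(i) {
      inten <- as.numeric(df[i, mz_cols])
      keep <- inten > 0
      raw_spectrum(mz[keep], inten[keep],
                   spectrum_id = as.character(df$spectrum_id[i]),
                   compound = get_meta(df[i, , drop = FALSE], "compound", ""),
                   truth = get_meta(df[i, , drop = FALSE], "truth", "unknown"),
                   source = get_meta(df[i, , drop = FALSE], "source", ""))
    })
  }
}

#' Bin and normalize a collection of raw spectra
#'
#' Convenience wrapper applying [bin_to_nominal()] to each element and
#' checking spectrum-id uniqueness.
#'
#' @param spectra list of [raw_spectrum()] objects.
#' @return List of [nominal_spectrum()] objects.
#' @export
as_nominal <- function(spectra) {
  ids <- vapply(spectra, function(s) s$meta$spectrum_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate spectrum ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  lapply(spectra, bin_to_nominal)
}
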