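# Consensus spectrum, top-K peak panel, and labeled abundance matrices.

#' Select the K most abundant panel channels from training spectra
#'
#' The panel is defined by the consensus (mean) spectrum of the training set:
#' the K channels with largest mean relative abundance, ordered by descending
#' mean. Ties in mean abundance are broken by ascending m/z so the panel is
#' deterministic. Channels absent from a spectrum count as abundance 0 in the
#' mean ("reverse search" logic: absence is informative).
#'
#' @param training list of [nominal_spectrum()] objects.
#' @param k number of panel channels (>= 2 in normal use).
#' @return Integer vector of nominal m/z values, class `peak_panel`.
#' @export
select_top_k <- function(training, k) {
  stopifnot_scalar_number(k, "k")
  means <- channel_means(training)
  if (k > length(means))
    stop(sprintf("k = %d exceeds the %d channels observed in training", k,
                 length(means)), call. = FALSE)
  mz <- as.integer(names(means))
  ord <- order(-means, mz)
  structure(mz[ord][seq_len(k)], class = "peak_panel")
}

# Mean abundance per channel over the union of channels, missing -> 0.
channel_means <- function(training) {
  stopifnot(length(training) >= 1L)
  all_mz <- sort(unique(unlist(lapply(training, function(s) as.integer(names(s$channels))))))
  if (!length(all_mz)) stop("training spectra have no channels", call. = FALSE)
  acc <- setNames(numeric(length(all_mz)), all_mz)
  for (s in training) {
    v <- s$channels
    acc[names(v)] <- acc[names(v)] + v
  }
  acc / length(training)
}

#' Build the consensus (exemplar) spectrum of a training set
#'
#' The consensus spectrum is the traditional exemplar: per panel channel, the
#' arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' relative abundances across replicate training spectra. Channels missing
#' from a spectrum contribute 0.
#'
#' @param training list of [nominal_spectrum()] objects (>= 2).
#' @param panel a `peak_panel` from [select_top_k()] (or integer m/z vector).
#' @return Object of class `consensus_spectrum`: data frame with columns
#'   `mz`, `mean`, `sd` (panel order) and attribute `n`.
#' @export
build_consensus <- function(training, panel) {
  if (length(training) < 2L)
    stop("at least 2 training spectra are required for a consensus", call. = FALSE)
  m <- assemble_matrix(training, panel)
  structure(
    data.frame(mz = as.integer(panel),
               mean = colMeans(m),
               sd = apply(m, 2, sd),
               row.names = NULL),
    n = nrow(m), class = c("consensus_spectrum", "data.frame"))
}

#' @export
print.consensus_spectrum <- function(x, ...) {
  cat(sprintf("consensus_spectrum: %d channels, n = %d training spectra\n",
              nrow(x), attr(x, "n")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Assemble the panel abundance matrix from spectra
#'
#' One row per spectrum (rownames = spectrum ids), one column per panel
#' channel in panel order. Panel channels absent from a spectrum are true
#' zeros; channels outside the panel are dropped. Truth labels travel as the
#' `"truth"` attribute (named by spectrum id).
#'
#' @param spectra list of [nominal_spectrum()] objects.
#' @param panel a `peak_panel` (or integer m/z vector).
#' @return Numeric matrix of class `abundance_matrix` with attribute `truth`.
#' @export
assemble_matrix <- function(spectra, panel) {
  panel <- as.integer(panel)
  if (anyDuplicated(panel)) stop("panel channels must be unique", call. = FALSE)
  ids <- vapply(spectra, function(s) s$meta$spectrum_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate spectrum ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  m <- matrix(0, nrow = length(spectra), ncol = length(panel),
              dimnames = list(ids, as.character(panel)))
  for (i in seq_along(spectra)) {
    v <- spectra[[i]]$channels
    hit <- intersect(names(v), colnames(m))
    m[i, hit] <- v[hit]
  }
  truth <- vapply(spectra, function(s) s$meta$truth, character(1))
  structure(m, truth = setNames(truth, ids),
            class = c("abundance_matrix", class(m)))
}

#' Truth labels of an abundance matrix
#' @param m an `abundance_matrix`.
#' @return Character vector of truth labels, named by spectrum id.
#' @export
truth_labels <- function(m) {
  tr <- attr(m, "truth")
  if (is.null(tr)) setNames(rep("unknown", nrow(m)), rownames(m)) else tr
}

#' Subset the rows of an abundance matrix, keeping truth labels
#' @param m an `abundance_matrix`.
#' @param rows row indices, ids, or a logical vector.
#' @return The row-subsetted `abundance_matrix`.
#' @export
subset_rows <- function(m, rows) {
  out <- unclass(m)[rows, , drop = FALSE]
  structure(out, truth = truth_labels(m)[rownames(out)],
            class = class(m))
}

#' Write / read an abundance matrix as wide CSV
#'
#' Columns: `spectrum_id`, `truth`, then one integer m/z column per panel
#' channel.
#'
#' @param m an `abundance_matrix`.
#' @param path CSV file path.
#' @return `write_matrix_csv` returns `path` invisibly; `read_matrix_csv`
#'   returns an `abundance_matrix`.
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(spectrum_id = rownames(m), truth = unname(truth_labels(m)),
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(unclass(m), check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  mz_cols <- setdiff(names(df), c("spectrum_id", "truth"))
  m <- as.matrix(df[, mz_cols, drop = FALSE])
  rownames(m) <- df$spectrum_id
  structure(m, truth = setNames(df$truth, df$spectrum_id),
            class = c("abundance_matrix", class(m)))
}
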