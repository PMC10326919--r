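# Spectral similarity and dissimilarity measures between measured and
# predicted abundance vectors: MAR, Euclidean distance, cosine dot product,
# and the weighted NIST-style match score.

#' Weighting specification for the NIST-style match score
#'
#' Weighted variables are formed from peak abundance and m/z as
#' `abundance^x * (m/z)^y`; the cosine between two weighted vectors is then
#' scaled by `scale` so a perfect match attains the ceiling. Defaults are the
#' classic exponents x = 0.6, y = 3 with a 999 ceiling.
#'
#' @param x abundance exponent (dimensionless).
#' @param y m/z exponent (dimensionless).
#' @param scale score ceiling (> 0).
#' @return Object of class `weight_spec`.
#' @export
weight_spec <- function(x = 0.6, y = 3, scale = 999) {
  stopifnot_scalar_number(x, "x"); stopifnot_scalar_number(y, "y")
  stopifnot_scalar_number(scale, "scale")
  if (scale <= 0) stop("`scale` must be > 0", call. = FALSE)
  structure(list(x = x, y = y, scale = scale), class = "weight_spec")
}

resolve_vectors <- function(record) {
  if (inherits(record, "prediction_record"))
    list(a = record$predicted, b = record$measured)
  else stop("expected a prediction_record", call. = FALSE)
}

#' Mean absolute residual (MAR)
#'
#' Mean of |predicted - measured| over the K panel ions, in percent of the
#' base peak. Unlike an RMS error it does not grow with the number of panel
#' ions, so MARs are comparable across panel sizes.
#'
#' @param record a `prediction_record` from [predict.easi_model()], or a
#'   numeric vector of residuals.
#' @return Non-negative scalar (% of base peak).
#' @export
mar <- function(record) {
  r <- if (is.numeric(record)) record else resolve_vectors(record)$a - resolve_vectors(record)$b
  r <- as.numeric(r)
  if (!length(r)) stop("empty residual vector", call. = FALSE)
  mean(abs(r))
}

#' Euclidean distance between predicted and measured vectors
#'
#' Square root of the sum of squared residuals over the panel ions.
#'
#' @inheritParams mar
#' @return Non-negative scalar (% of base peak).
#' @export
euclidean_distance <- function(record) {
  r <- if (is.numeric(record)) record else resolve_vectors(record)$a - resolve_vectors(record)$b
  if (!length(r)) stop("empty residual vector", call. = FALSE)
  sqrt(sum(r^2))
}

#' Cosine (dot product) similarity between two abundance vectors
#'
#' The cosine of the angle between the two vectors:
#' `sum(a * b) / (||a|| * ||b||)`, in [-1, 1].
#'
#' @param a,b numeric vectors of equal length with positive norm.
#' @return Scalar in [-1, 1].
#' @export
dot_product <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-norm vector in dot product", call. = FALSE)
  sum(a * b) / (na * nb)
}

#' Weighted NIST-style match score
#'
#' Each abundance is floored at 0 (fractional powers of negative EASI
#' predictions are undefined), raised to the abundance exponent and
#' multiplied by m/z raised to the m/z exponent; the cosine between the two
#' weighted vectors is scaled to the ceiling. Identical non-degenerate
#' spectra score exactly `w$scale` (999 by default).
#'
#' @param a,b numeric K-vectors of abundances in panel order.
#' @param panel integer m/z values of the K channels (a `peak_panel` or
#'   plain integer vector).
#' @param w a [weight_spec()].
#' @return Scalar in [-scale, scale].
#' @export
nist_score <- function(a, b, panel, w = weight_spec()) {
  panel <- as.numeric(panel)
  if (length(a) != length(panel) || length(b) != length(panel))
    stop("vectors and panel must have equal length", call. = FALSE)
  wa <- pmax(a, 0)^w$x * panel^w$y
  wb <- pmax(b, 0)^w$x * panel^w$y
  if (all(wa == 0) || all(wb == 0))
    stop("all-zero weighted vector in NIST score", call. = FALSE)
  w$scale * dot_product(wa, wb)
}

#' Score query spectra against an EASI model
#'
#' Runs [predict.easi_model()] for every query row and assembles the
#' requested similarity/dissimilarity measures into a long-form data frame,
#' one row per spectrum and approach.
#'
#' @param model an `easi_model`.
#' @param queries an `abundance_matrix` of query spectra (panel order).
#' @param metrics subset of `c("mar", "euclid", "dot", "nist")`.
#' @param approach `"easi"`, `"consensus"`, or both.
#' @param w [weight_spec()] for the NIST score.
#' @return Data frame: `spectrum_id`, `truth`, `approach`, one column per
#'   metric.
#' @export
score_spectra <- function(model, queries,
                          metrics = c("mar", "euclid", "dot", "nist"),
                          approach = c("easi", "consensus"),
                          w = weight_spec()) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  approach <- match.arg(approach, several.ok = TRUE)
  out <- list()
  for (ap in approach) {
    records <- predict(model, queries, approach = ap)
    df <- data.frame(
      spectrum_id = vapply(records, `[[`, character(1), "spectrum_id"),
      truth = vapply(records, `[[`, character(1), "truth"),
      approach = ap, row.names = NULL)
    if ("mar" %in% metrics)
      df$mar <- vapply(records, mar, numeric(1))
    if ("euclid" %in% metrics)
      df$euclid <- vapply(records, euclidean_distance, numeric(1))
    if ("dot" %in% metrics)
      df$dot <- vapply(records, function(r) dot_product(r$predicted, r$measured),
                       numeric(1))
    if ("nist" %in% metrics)
      df$nist <- vapply(records, function(r)
        nist_score(r$predicted, r$measured, model$panel, w), numeric(1))
    out[[ap]] <- df
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
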