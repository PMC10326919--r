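# Covariance model of the training cloud, Mahalanobis distances of query
# spectra, and the chi-square outlier test.

#' Fit the training mean and covariance model
#'
#' Computes the mean vector and sample covariance matrix (n - 1 denominator)
#' of the training abundance matrix. Zero-variance channels (the base peak,
#' fixed at 100 across replicates) are dropped from the retained set before
#' any inversion. If the training count is not comfortably larger than the
#' retained dimension (n < K + 1) the covariance is singular; a warning is
#' issued and distance computation falls back to the Moore-Penrose
#' pseudo-inverse.
#'
#' @param matrix an `abundance_matrix` of training rows (n >= 2).
#' @return Object of class `covariance_model`: `mean` (named), `covariance`
#'   (K x K on retained channels), `retained` (integer m/z kept), `dropped`,
#'   `n`, `pseudo_inverse` flag.
#' @export
fit_covariance <- function(matrix) {
  n <- nrow(matrix)
  if (n < 2L) stop("at least 2 training rows are required", call. = FALSE)
  v <- apply(matrix, 2, var)
  keep <- v > ZERO_VAR_TOL
  if (!any(keep)) stop("all channels have zero variance", call. = FALSE)
  m <- unclass(matrix)[, keep, drop = FALSE]
  pseudo <- FALSE
  if (n < ncol(m) + 1L) {
    warning(sprintf("n = %d training rows for %d retained channels: covariance is singular, using pseudo-inverse",
                    n, ncol(m)), call. = FALSE)
    pseudo <- TRUE
  }
  structure(list(
    mean = colMeans(m),
    covariance = stats::cov(m),
    retained = as.integer(colnames(m)),
    dropped = as.integer(colnames(matrix)[!keep]),
    n = n,
    pseudo_inverse = pseudo), class = "covariance_model")
}

#' @export
print.covariance_model <- function(x, ...) {
  cat(sprintf("covariance_model: %d retained channels (%d dropped as zero-variance), n = %d\n",
              length(x$retained), length(x$dropped), x$n))
  invisible(x)
}

#' Mahalanobis distance of query spectra to the training cloud
#'
#' The Euclidean distance after whitening by the training covariance:
#' `sqrt((x - xbar)' C^-1 (x - xbar))`, interpretable as the number of
#' multivariate standard deviations from the training mean. Solved through
#' the Cholesky factor of C rather than an explicit inverse; if C is
#' singular, the Moore-Penrose pseudo-inverse is used when `pseudo_inverse`
#' is allowed (set automatically by [fit_covariance()] for
#' under-determined training sets), otherwise an error is raised.
#'
#' @param model a `covariance_model`.
#' @param query a named numeric vector covering the retained channels, or an
#'   `abundance_matrix`/matrix with those columns; extra (dropped) channels
#'   are ignored.
#' @param pseudo_inverse override the model's pseudo-inverse flag.
#' @return Numeric vector of distances (one per query row), >= 0.
#' @export
mahalanobis_distance <- function(model, query, pseudo_inverse = model$pseudo_inverse) {
  stopifnot(inherits(model, "covariance_model"))
  if (is.numeric(query) && is.null(dim(query)))
    query <- matrix(query, nrow = 1, dimnames = list(NULL, names(query)))
  cols <- as.character(model$retained)
  if (!all(cols %in% colnames(query)))
    stop("query lacks retained channels: ",
         paste(setdiff(cols, colnames(query)), collapse = ", "), call. = FALSE)
  x <- unclass(query)[, cols, drop = FALSE]
  centered <- sweep(x, 2, model$mean, "-")
  ch <- tryCatch(chol(model$covariance), error = function(e) NULL)
  if (!is.null(ch) && !pseudo_inverse) {
    # whiten: z = L^-T (x - xbar); d = ||z||
    z <- backsolve(ch, t(centered), transpose = TRUE)
    d2 <- colSums(z^2)
  } else {
    if (!pseudo_inverse)
      stop("covariance matrix is singular; re-fit with more training spectra or enable pseudo_inverse",
           call. = FALSE)
    cinv <- MASS::ginv(model$covariance)
    d2 <- rowSums((centered %*% cinv) * centered)
  }
  sqrt(pmax(d2, 0))
}

#' Chi-square outlier test on a Mahalanobis distance
#'
#' Under multivariate normality the squared Mahalanobis distance of a new
#' observation is approximately chi-square distributed with df equal to the
#' number of retained channels. A spectrum is flagged as an outlier when its
#' squared distance exceeds the upper-alpha chi-square quantile. With a
#' 20-channel panel whose base peak is dropped, df = 19 and alpha = 0.05
#' give a critical value of about 30.1.
#'
#' @param distance Mahalanobis distance(s) (not squared).
#' @param df degrees of freedom (>= 1), typically the retained channel count.
#' @param alpha significance level in (0, 1).
#' @return List: `critical_value` (on the squared-distance scale) and
#'   `is_outlier` (logical, per distance).
#' @export
chi2_outlier_test <- function(distance, df, alpha = 0.05) {
  stopifnot_scalar_number(df, "df"); stopifnot_scalar_number(alpha, "alpha")
  if (df < 1) stop("`df` must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (any(distance < 0)) stop("distances must be >= 0", call. = FALSE)
  crit <- qchisq(1 - alpha, df = df)
  list(critical_value = crit, is_outlier = distance^2 > crit)
}
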