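# EASI: one stepwise general linear model per panel ion.
#
# Each panel ion is iteratively treated as the dependent variable and the
# remaining panel ions are candidate covariates, entered/removed by partial-F
# tests until no change. Within a query spectrum, each ion's abundance is then
# predicted from the other measured ions of that same spectrum, so predictions
# track the query's own instrument state instead of a fixed exemplar.

ZERO_VAR_TOL <- 1e-10

# F-tests on an exact linear dependence trigger a "perfect fit" warning from
# add1/drop1; that degenerate case is handled deliberately (the perfect
# covariate is kept), so the warning is muffled and all others pass through.
quiet_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' Fit one panel-ion model by bidirectional stepwise least squares
#'
#' Forward-entry / backward-removal selection on partial-F tests: at each
#' step the candidate with the smallest partial-F p-value enters if
#' p < `p_enter`, then any included covariate whose p-value exceeds
#' `p_remove` is removed; iteration stops when neither test changes the
#' model. Zero-variance covariates (e.g. the base peak, fixed at 100) are
#' excluded from candidacy; a zero-variance *target* yields a constant model
#' (intercept only, R-squared defined as 0). Candidates that would make the
#' design singular are refused and selection continues.
#'
#' @param matrix an `abundance_matrix` of training rows (see
#'   [assemble_matrix()]).
#' @param target the panel channel (integer m/z) to model.
#' @param p_enter entry threshold on the partial-F p-value (default 0.05).
#' @param p_remove removal threshold (default 0.10); must be >= `p_enter`.
#' @return Object of class `ion_model`: target, intercept, named coefficient
#'   vector (channels), `r_squared`, `residual_sd`, `n`.
#' @export
fit_stepwise <- function(matrix, target, p_enter = 0.05, p_remove = 0.10) {
  target <- as.integer(target)
  cols <- colnames(matrix)
  if (!as.character(target) %in% cols)
    stop(sprintf("target channel %d is not in the panel", target), call. = FALSE)
  n <- nrow(matrix)
  if (n < 3L) stop("at least 3 training rows are required", call. = FALSE)
  if (p_remove < p_enter)
    stop("`p_remove` must be >= `p_enter`", call. = FALSE)

  y <- matrix[, as.character(target)]
  cand_mz <- setdiff(cols, as.character(target))
  cand_mz <- cand_mz[apply(matrix[, cand_mz, drop = FALSE], 2, var) > ZERO_VAR_TOL]
  if (length(cand_mz) && n < length(cand_mz) + 10L)
    warning(sprintf("only %d rows for %d candidate covariates; stepwise selection may be unstable",
                    n, length(cand_mz)), call. = FALSE)

  if (var(y) <= ZERO_VAR_TOL || !length(cand_mz))
    return(constant_ion_model(target, y))

  df <- as.data.frame(unclass(matrix)[, cand_mz, drop = FALSE])
  names(df) <- paste0("m", cand_mz)
  df$.y <- y
  banned <- character(0)          # candidates refused for singularity
  fit <- lm(.y ~ 1, data = df)
  repeat {
    changed <- FALSE
    # forward entry
    avail <- setdiff(paste0("m", cand_mz), c(names(coef(fit)), banned))
    if (length(avail)) {
      scope <- stats::as.formula(paste("~ . +", paste(avail, collapse = " + ")))
      a1 <- tryCatch(quiet_perfect_fit(add1(fit, scope = scope, test = "F")),
                     error = function(e) NULL)
      if (!is.null(a1)) {
        p <- a1[["Pr(>F)"]]; names(p) <- rownames(a1)
        p <- p[avail][!is.na(p[avail])]
        while (length(p) && min(p) < p_enter) {
          term <- names(p)[which.min(p)]
          new_fit <- stats::update(fit, stats::as.formula(paste(". ~ . +", term)))
          if (anyNA(coef(new_fit))) {      # singular design with this term
            banned <- c(banned, term)
            p <- p[names(p) != term]
            next
          }
          fit <- new_fit; changed <- TRUE
          break
        }
      }
    }
    # backward removal
    if (length(attr(stats::terms(fit), "term.labels"))) {
      d1 <- quiet_perfect_fit(drop1(fit, test = "F"))
      p <- d1[["Pr(>F)"]]; names(p) <- rownames(d1)
      p <- p[setdiff(names(p), "<none>")]
      p <- p[!is.na(p)]
      if (length(p) && max(p) > p_remove) {
        term <- names(p)[which.max(p)]
        fit <- stats::update(fit, stats::as.formula(paste(". ~ . -", term)))
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  sm <- quiet_perfect_fit(summary(fit))
  beta <- coef(fit)
  covars <- setdiff(names(beta), "(Intercept)")
  coefs <- setNames(unname(beta[covars]), sub("^m", "", covars))
  structure(list(
    target = target,
    intercept = unname(beta[["(Intercept)"]]),
    coefficients = coefs,
    r_squared = if (length(covars)) sm$r.squared else 0,
    residual_sd = sm$sigma,
    n = n), class = "ion_model")
}

constant_ion_model <- function(target, y) {
  structure(list(target = as.integer(target), intercept = mean(y),
                 coefficients = setNames(numeric(0), character(0)),
                 r_squared = 0, residual_sd = sd(y), n = length(y)),
            class = "ion_model")
}

#' @export
print.ion_model <- function(x, ...) {
  cat(sprintf("ion_model m/z %d: intercept %.3f, %d covariates, R2 = %.4f, residual sd = %.3f\n",
              x$target, x$intercept, length(x$coefficients), x$r_squared,
              x$residual_sd))
  if (length(x$coefficients)) {
    cat("  covariates (m/z): ",
        paste(sprintf("%s: %+0.3f", names(x$coefficients), x$coefficients),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Fit the full EASI model on replicate training spectra
#'
#' Runs [fit_stepwise()] once per panel channel, with the other K - 1
#' channels as candidate covariates, and computes the consensus (mean/sd)
#' statistics from the same rows. All training rows should be replicates of
#' the target compound.
#'
#' @param matrix an `abundance_matrix` of known-positive training rows.
#' @param p_enter,p_remove stepwise thresholds, see [fit_stepwise()].
#' @return Object of class `easi_model`: `panel` (integer m/z), `ion_models`
#'   (one `ion_model` per channel, in panel order), `consensus` (data frame
#'   mz/mean/sd with attribute `n`), `settings`.
#' @export
fit_easi <- function(matrix, p_enter = 0.05, p_remove = 0.10) {
  if (nrow(matrix) < 3L)
    stop("at least 3 training spectra are required", call. = FALSE)
  tr <- truth_labels(matrix)
  if (any(tr == "known_negative"))
    warning("training matrix contains known_negative rows; EASI expects replicates of the target compound",
            call. = FALSE)
  panel <- as.integer(colnames(matrix))
  ion_models <- lapply(panel, function(ch)
    fit_stepwise(matrix, ch, p_enter = p_enter, p_remove = p_remove))
  names(ion_models) <- as.character(panel)
  cons <- structure(
    data.frame(mz = panel, mean = unname(colMeans(matrix)),
               sd = unname(apply(matrix, 2, sd)), row.names = NULL),
    n = nrow(matrix), class = c("consensus_spectrum", "data.frame"))
  structure(list(panel = panel, ion_models = ion_models, consensus = cons,
                 settings = list(p_enter = p_enter, p_remove = p_remove),
                 training = list(n = nrow(matrix),
                                 checksum = matrix_checksum(matrix))),
            class = "easi_model")
}

#' @export
print.easi_model <- function(x, ...) {
  r2 <- vapply(x$ion_models, `[[`, numeric(1), "r_squared")
  nc <- vapply(x$ion_models, function(m) length(m$coefficients), integer(1))
  cat(sprintf("easi_model: %d panel ions, trained on %d spectra\n",
              length(x$panel), x$training$n))
  cat(sprintf("  covariates per ion: %d-%d (median %0.f); R2 median %.3f (min %.3f)\n",
              min(nc), max(nc), stats::median(nc), stats::median(r2), min(r2)))
  invisible(x)
}

# Cheap content checksum (31-base rolling hash mod 2^31 - 1 over rounded
# values) to tag which training set a persisted model came from.
matrix_checksum <- function(m) {
  txt <- paste(c(rownames(m), colnames(m), formatC(unclass(m), digits = 8, format = "g")),
               collapse = "|")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Predict panel-ion abundances for query spectra
#'
#' Under `approach = "consensus"` the prediction is the training-set mean
#' spectrum, identical for every query. Under `approach = "easi"` each
#' channel is predicted from the query's own measured abundances of the
#' other channels through its fitted linear model; predictions are *not*
#' clipped to [0, 100] — out-of-range predictions are informative for
#' negatives. Residuals are predicted minus measured.
#'
#' @param object an `easi_model` from [fit_easi()].
#' @param newdata an `abundance_matrix` (or a single named numeric vector in
#'   panel order) of query spectra.
#' @param approach `"easi"` or `"consensus"`.
#' @param ... unused.
#' @return A list of `prediction_record` objects (one per query row), each
#'   with `spectrum_id`, `truth`, `approach`, and named K-vectors `measured`,
#'   `predicted`, `residuals`.
#' @export
predict.easi_model <- function(object, newdata, approach = c("easi", "consensus"), ...) {
  approach <- match.arg(approach)
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1,
                      dimnames = list("query", names(newdata) %||%
                                        as.character(object$panel)))
  }
  if (!identical(as.integer(colnames(newdata)), object$panel))
    stop("query columns do not match the model's peak panel", call. = FALSE)
  truth <- truth_labels(newdata)
  k <- length(object$panel)
  records <- vector("list", nrow(newdata))
  cons_mean <- setNames(object$consensus$mean, as.character(object$panel))
  for (i in seq_len(nrow(newdata))) {
    x <- setNames(as.numeric(newdata[i, ]), colnames(newdata))
    if (approach == "consensus") {
      pred <- cons_mean
    } else {
      pred <- vapply(object$ion_models, function(mod) {
        if (!length(mod$coefficients)) return(mod$intercept)
        mod$intercept + sum(mod$coefficients * x[names(mod$coefficients)])
      }, numeric(1))
      names(pred) <- names(cons_mean)
    }
    records[[i]] <- structure(
      list(spectrum_id = rownames(newdata)[i], truth = unname(truth[i]),
           approach = approach, measured = x, predicted = pred,
           residuals = pred - x),
      class = "prediction_record")
  }
  names(records) <- rownames(newdata)
  records
}

#' @export
print.prediction_record <- function(x, ...) {
  cat(sprintf("prediction_record '%s' (%s, %s): K = %d, MAR = %.3f%%\n",
              x$spectrum_id, x$truth, x$approach, length(x$measured),
              mean(abs(x$residuals))))
  invisible(x)
}

# ---- JSON persistence -----------------------------------------------------

#' Persist / restore an EASI model as JSON
#'
#' The JSON file stores the panel, each ion's intercept and coefficient map,
#' R-squared and residual sd, the consensus statistics, the stepwise settings
#' and a training-set checksum.
#'
#' @param model an `easi_model`.
#' @param path JSON file path.
#' @return `write_easi_model` returns `path` invisibly; `read_easi_model`
#'   returns the restored `easi_model`.
#' @export
write_easi_model <- function(model, path) {
  obj <- list(
    format = "easispec-model",
    panel = model$panel,
    ion_models = lapply(model$ion_models, function(m) list(
      target = m$target, intercept = m$intercept,
      coefficients = as.list(m$coefficients),
      r_squared = m$r_squared, residual_sd = m$residual_sd, n = m$n)),
    consensus = list(mz = model$consensus$mz, mean = model$consensus$mean,
                     sd = model$consensus$sd, n = attr(model$consensus, "n")),
    settings = model$settings,
    training = model$training)
  if (!is.null(model$covariance_model)) {
    cm <- model$covariance_model
    obj$covariance_model <- list(
      mean = as.list(cm$mean), covariance = unclass(cm$covariance),
      retained = cm$retained, dropped = cm$dropped, n = cm$n,
      pseudo_inverse = cm$pseudo_inverse)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_easi_model
#' @export
read_easi_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "easispec-model"))
    stop("not an easispec model file: ", path, call. = FALSE)
  ion_models <- lapply(obj$ion_models, function(m) {
    coefs <- unlist(m$coefficients)
    if (is.null(coefs)) coefs <- setNames(numeric(0), character(0))
    structure(list(target = as.integer(m$target), intercept = m$intercept,
                   coefficients = coefs, r_squared = m$r_squared,
                   residual_sd = m$residual_sd, n = m$n),
              class = "ion_model")
  })
  names(ion_models) <- as.character(obj$panel)
  cons <- structure(
    data.frame(mz = as.integer(obj$consensus$mz), mean = obj$consensus$mean,
               sd = obj$consensus$sd, row.names = NULL),
    n = obj$consensus$n, class = c("consensus_spectrum", "data.frame"))
  model <- structure(list(panel = as.integer(obj$panel), ion_models = ion_models,
                          consensus = cons, settings = obj$settings,
                          training = obj$training),
                     class = "easi_model")
  if (!is.null(obj$covariance_model)) {
    cm <- obj$covariance_model
    cov <- as.matrix(cm$covariance)
    dimnames(cov) <- list(as.character(cm$retained), as.character(cm$retained))
    model$covariance_model <- structure(
      list(mean = setNames(unlist(cm$mean), as.character(cm$retained)),
           covariance = cov, retained = as.integer(cm$retained),
           dropped = as.integer(cm$dropped), n = cm$n,
           pseudo_inverse = isTRUE(cm$pseudo_inverse)),
      class = "covariance_model")
  }
  model
}
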