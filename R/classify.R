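# Binary classification of labeled score sets: confusion matrices, ROC/AUC,
# precision-recall, zero-false-positive thresholds, and the supervised
# stepwise logistic classifier on EASI residuals.

#' Construct a labeled score set
#'
#' A score set pairs one score per spectrum with its truth label and records
#' the score's polarity: `"similarity"` (higher score means positive, e.g.
#' dot product, NIST score) or `"dissimilarity"` (lower score means
#' positive, e.g. MAR, Euclidean or Mahalanobis distance).
#'
#' @param spectrum_id character vector of ids.
#' @param truth `"known_positive"` / `"known_negative"` per spectrum.
#' @param score numeric scores.
#' @param polarity `"similarity"` or `"dissimilarity"`.
#' @return Object of class `score_set` (a data frame with a `polarity`
#'   attribute).
#' @export
score_set <- function(spectrum_id, truth, score,
                      polarity = c("similarity", "dissimilarity")) {
  polarity <- match.arg(polarity)
  stopifnot(length(spectrum_id) == length(truth),
            length(truth) == length(score))
  if (!all(truth %in% c("known_positive", "known_negative")))
    stop("truth labels must be known_positive or known_negative", call. = FALSE)
  structure(data.frame(spectrum_id = as.character(spectrum_id),
                       truth = as.character(truth), score = as.numeric(score),
                       stringsAsFactors = FALSE),
            polarity = polarity, class = c("score_set", "data.frame"))
}

# Scores oriented so that higher always means "call positive".
oriented_scores <- function(scores) {
  s <- scores$score
  if (attr(scores, "polarity") == "dissimilarity") s <- -s
  s
}

#' Confusion counts at a decision threshold
#'
#' Similarity polarity predicts positive when score >= threshold;
#' dissimilarity polarity when score <= threshold (thresholds are inclusive
#' on the positive side).
#'
#' @param scores a [score_set()].
#' @param threshold decision threshold on the score scale.
#' @return Object of class `confusion_counts`: `tp`, `tn`, `fp`, `fn` plus
#'   derived `tpr`, `tnr`, `fpr`, `precision`, `accuracy`.
#' @export
confusion_at_threshold <- function(scores, threshold) {
  stopifnot(inherits(scores, "score_set"))
  pos_call <- if (attr(scores, "polarity") == "similarity")
    scores$score >= threshold else scores$score <= threshold
  is_pos <- scores$truth == "known_positive"
  counts <- list(tp = sum(pos_call & is_pos), tn = sum(!pos_call & !is_pos),
                 fp = sum(pos_call & !is_pos), fn = sum(!pos_call & is_pos))
  counts$tpr <- if (sum(is_pos)) counts$tp / sum(is_pos) else NaN
  counts$tnr <- if (sum(!is_pos)) counts$tn / sum(!is_pos) else NaN
  counts$fpr <- 1 - counts$tnr
  counts$precision <- if (counts$tp + counts$fp) counts$tp / (counts$tp + counts$fp) else NaN
  counts$accuracy <- (counts$tp + counts$tn) / length(is_pos)
  structure(counts, threshold = threshold, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("threshold %.6g: TP %d, TN %d, FP %d, FN %d | TPR %.1f%%, TNR %.1f%%, accuracy %.1f%%\n",
              attr(x, "threshold"), x$tp, x$tn, x$fp, x$fn,
              100 * x$tpr, 100 * x$tnr, 100 * x$accuracy))
  invisible(x)
}

#' Receiver operating characteristic curve and AUC
#'
#' Sweeps every distinct score as a decision threshold (plus infinite
#' sentinels) and integrates the area under the TPR-vs-FPR curve by the
#' trapezoid rule. Because one point is placed per distinct score, the
#' trapezoid AUC equals the Mann-Whitney probability that a random positive
#' outscores a random negative, with ties counted 1/2.
#'
#' @param scores a [score_set()] containing both classes.
#' @return Object of class `roc_curve`: `points` (data frame threshold /
#'   tpr / fpr) and `auc`.
#' @export
roc_curve <- function(scores) {
  stopifnot(inherits(scores, "score_set"))
  is_pos <- scores$truth == "known_positive"
  if (!any(is_pos) || all(is_pos))
    stop("ROC construction needs both truth classes", call. = FALSE)
  s <- oriented_scores(scores)
  npos <- sum(is_pos); nneg <- sum(!is_pos)
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(s >= t & is_pos) / npos, numeric(1))
  fpr <- vapply(thr, function(t) sum(s >= t & !is_pos) / nneg, numeric(1))
  tpr <- c(0, tpr, 1); fpr <- c(0, fpr, 1)
  thr_out <- c(Inf, thr, -Inf)
  if (attr(scores, "polarity") == "dissimilarity") thr_out <- -thr_out
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(points = data.frame(threshold = thr_out, tpr = tpr, fpr = fpr),
                 auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d points, AUC = %.6f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Precision-recall curve
#'
#' Precision and recall at every distinct decision threshold. Thresholds
#' predicting zero positives have undefined precision and are omitted. A
#' perfect classifier's curve passes through (recall 1, precision 1).
#'
#' @param scores a [score_set()] containing both classes.
#' @return Object of class `pr_curve`: `points` (threshold / recall /
#'   precision, swept from strict to permissive).
#' @export
pr_curve <- function(scores) {
  stopifnot(inherits(scores, "score_set"))
  is_pos <- scores$truth == "known_positive"
  if (!any(is_pos) || all(is_pos))
    stop("PR construction needs both truth classes", call. = FALSE)
  s <- oriented_scores(scores)
  npos <- sum(is_pos)
  thr <- sort(unique(s), decreasing = TRUE)
  pts <- lapply(thr, function(t) {
    called <- s >= t
    if (!any(called)) return(NULL)
    data.frame(threshold = t, recall = sum(called & is_pos) / npos,
               precision = sum(called & is_pos) / sum(called))
  })
  pts <- do.call(rbind, pts)
  if (attr(scores, "polarity") == "dissimilarity") pts$threshold <- -pts$threshold
  structure(list(points = pts), class = "pr_curve")
}

#' Most permissive threshold with zero false positives
#'
#' Finds the decision threshold that admits no known negative while
#' accepting as many known positives as possible: the midpoint between the
#' extreme known-negative score and the nearest known-positive score beyond
#' it (just above the max KN for similarity scores, just below the min KN
#' for dissimilarity scores). If no positive lies beyond the negatives'
#' extreme, the returned threshold still excludes all negatives and TP is 0.
#'
#' @param scores a [score_set()] containing both classes.
#' @return List: `threshold` and the resulting [confusion_at_threshold()]
#'   counts (always `fp = 0`).
#' @export
zero_fp_threshold <- function(scores) {
  stopifnot(inherits(scores, "score_set"))
  is_pos <- scores$truth == "known_positive"
  if (!any(is_pos) || all(is_pos))
    stop("zero-FP threshold needs both truth classes", call. = FALSE)
  sim <- attr(scores, "polarity") == "similarity"
  kp <- scores$score[is_pos]; kn <- scores$score[!is_pos]
  if (sim) {
    edge <- max(kn)
    admissible <- kp[kp > edge]
    threshold <- if (length(admissible)) (edge + min(admissible)) / 2 else edge + 1
  } else {
    edge <- min(kn)
    admissible <- kp[kp < edge]
    threshold <- if (length(admissible)) (edge + max(admissible)) / 2 else edge - 1
  }
  list(threshold = threshold,
       counts = confusion_at_threshold(scores, threshold))
}

# ---- supervised logistic classifier on EASI residuals ---------------------

#' Stepwise binary logistic regression on EASI residuals
#'
#' Fits a supervised classifier separating known positives from known
#' negatives using the per-channel EASI residuals as candidate predictors.
#' Selection is bidirectional stepwise on likelihood-ratio tests (enter the
#' candidate with the smallest LRT p-value if p < `p_enter`; remove any
#' included term with p > `p_remove`). The response is coded 1 for known
#' negatives, so the fitted probability is small for the target compound
#' (the target class sits below the decision threshold). If the selected
#' model separates the classes completely — where plain maximum likelihood
#' diverges — the coefficients are refit by Firth-penalized likelihood and
#' the `method` tag records it.
#'
#' @param records list of `prediction_record`s (EASI approach) with truth
#'   labels in both classes.
#' @param p_enter,p_remove likelihood-ratio p-value thresholds.
#' @param threshold decision threshold on the predicted probability
#'   (default 0.5).
#' @return Object of class `residual_logit`: `selected` (integer m/z),
#'   `intercept`, `coefficients` (per % residual), `threshold`, `method`
#'   (`"ml"` or `"firth"`).
#' @export
fit_residual_logit <- function(records, p_enter = 0.05, p_remove = 0.10,
                               threshold = 0.5) {
  truth <- vapply(records, `[[`, character(1), "truth")
  if (!all(truth %in% c("known_positive", "known_negative")))
    stop("all records must carry known_positive/known_negative truth", call. = FALSE)
  y <- as.numeric(truth == "known_negative")
  if (length(unique(y)) < 2L)
    stop("both truth classes are required to fit the classifier", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must be in (0, 1)", call. = FALSE)
  res <- t(vapply(records, `[[`, records[[1]]$residuals, "residuals"))
  panel <- colnames(res)
  keep <- apply(res, 2, var) > ZERO_VAR_TOL
  df <- as.data.frame(res[, keep, drop = FALSE])
  names(df) <- paste0("r", panel[keep])
  df$.y <- y

  fit <- suppressWarnings(glm(.y ~ 1, family = binomial(), data = df))
  repeat {
    changed <- FALSE
    avail <- setdiff(names(df)[names(df) != ".y"],
                     names(coef(fit)))
    if (length(avail)) {
      scope <- stats::as.formula(paste("~ . +", paste(avail, collapse = " + ")))
      a1 <- suppressWarnings(add1(fit, scope = scope, test = "LRT"))
      p <- a1[["Pr(>Chi)"]]; names(p) <- rownames(a1)
      p <- p[avail][!is.na(p[avail])]
      if (length(p) && min(p) < p_enter) {
        term <- names(p)[which.min(p)]
        fit <- suppressWarnings(stats::update(fit, stats::as.formula(paste(". ~ . +", term))))
        changed <- TRUE
      }
    }
    if (length(attr(stats::terms(fit), "term.labels"))) {
      d1 <- suppressWarnings(drop1(fit, test = "LRT"))
      p <- d1[["Pr(>Chi)"]]; names(p) <- rownames(d1)
      p <- p[setdiff(names(p), "<none>")]
      p <- p[!is.na(p)]
      if (length(p) && max(p) > p_remove) {
        term <- names(p)[which.max(p)]
        fit <- suppressWarnings(stats::update(fit, stats::as.formula(paste(". ~ . -", term))))
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  sel_terms <- attr(stats::terms(fit), "term.labels")
  method <- "ml"
  beta <- coef(fit)
  fitted_p <- fitted(fit)
  separated <- any(fitted_p < 1e-8 | fitted_p > 1 - 1e-8) || anyNA(beta) ||
    max(abs(beta)) > 50
  if (separated) {
    X <- cbind(`(Intercept)` = 1,
               as.matrix(df[, sel_terms, drop = FALSE]))
    beta <- firth_logit(X, y)
    method <- "firth"
  }
  covars <- setdiff(names(beta), "(Intercept)")
  structure(list(
    selected = as.integer(sub("^r", "", covars)),
    intercept = unname(beta[["(Intercept)"]]),
    coefficients = setNames(unname(beta[covars]), sub("^r", "", covars)),
    threshold = threshold,
    method = method), class = "residual_logit")
}

#' @export
print.residual_logit <- function(x, ...) {
  cat(sprintf("residual_logit (%s): %d residual channels (m/z %s), threshold %.2f\n",
              x$method, length(x$selected),
              paste(x$selected, collapse = ", "), x$threshold))
  invisible(x)
}

# Firth-penalized logistic regression via Newton iteration on the modified
# score U = X'(y - p + h (1/2 - p)), h = leverage under the working weights.
# Handles complete separation, where ordinary ML estimates diverge.
firth_logit <- function(X, y, maxit = 200, tol = 1e-10) {
  beta <- numeric(ncol(X)); names(beta) <- colnames(X)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    Xw <- X * sqrt(w)
    XtWX <- crossprod(Xw)
    XtWX_inv <- tryCatch(solve(XtWX), error = function(e) MASS::ginv(XtWX))
    h <- rowSums((Xw %*% XtWX_inv) * Xw)
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    step <- drop(XtWX_inv %*% U)
    # dampen large steps for stability
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(U)) < tol || max(abs(step)) < tol) break
  }
  beta
}

#' Classify a query spectrum with the residual logistic model
#'
#' Evaluates the logistic probability on the record's EASI residuals for the
#' selected channels. Low probability means the target compound: the call is
#' `known_positive` when probability < threshold, `known_negative`
#' otherwise (a probability exactly at the threshold is classified
#' negative).
#'
#' @param model a `residual_logit` from [fit_residual_logit()].
#' @param record a `prediction_record` (EASI approach) with residuals for
#'   all selected channels.
#' @return List: `probability`, `class`.
#' @export
classify_logit <- function(model, record) {
  chans <- as.character(model$selected)
  r <- record$residuals[chans]
  if (anyNA(r) || length(r) != length(chans))
    stop("record lacks residuals for selected channels: ",
         paste(setdiff(chans, names(record$residuals)), collapse = ", "),
         call. = FALSE)
  p <- plogis(model$intercept + sum(model$coefficients[chans] * r))
  list(probability = p,
       class = if (p < model$threshold) "known_positive" else "known_negative")
}

#' Full classifier report for a labeled score set
#'
#' Bundles the ROC curve with AUC, the precision-recall curve, and the
#' zero-false-positive operating point.
#'
#' @param scores a [score_set()].
#' @return List: `polarity`, `n_positive`, `n_negative`, `auc`, `roc`
#'   points, `pr` points, `zero_fp` (threshold + counts).
#' @export
evaluate_scores <- function(scores) {
  roc <- roc_curve(scores)
  pr <- pr_curve(scores)
  zfp <- zero_fp_threshold(scores)
  list(polarity = attr(scores, "polarity"),
       n_positive = sum(scores$truth == "known_positive"),
       n_negative = sum(scores$truth == "known_negative"),
       auc = roc$auc,
       roc = roc$points,
       pr = pr$points,
       zero_fp = list(threshold = zfp$threshold,
                      counts = unclass(zfp$counts)[c("tp", "tn", "fp", "fn",
                                                     "tpr", "tnr", "fpr",
                                                     "precision", "accuracy")]))
}
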