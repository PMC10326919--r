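# Confusion counts, ROC/AUC, precision-recall, zero-FP thresholds, and the
# stepwise logistic classifier on EASI residuals.

toy_scores <- function(kp, kn, polarity = "similarity") {
  score_set(spectrum_id = sprintf("s%d", seq_along(c(kp, kn))),
            truth = rep(c("known_positive", "known_negative"),
                        c(length(kp), length(kn))),
            score = c(kp, kn), polarity = polarity)
}

# O(n^2) pairwise Mann-Whitney oracle (ties count 1/2), independent of the
# sweep-based implementation.
auc_oracle <- function(scores) {
  s <- scores$score
  if (attr(scores, "polarity") == "dissimilarity") s <- -s
  kp <- s[scores$truth == "known_positive"]
  kn <- s[scores$truth == "known_negative"]
  tot <- 0
  for (p in kp) for (q in kn)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(kp) * length(kn))
}

test_that("confusion counts match exhaustive enumeration", {
  ss <- toy_scores(kp = c(0.99, 0.96), kn = c(0.95, 0.90))
  c1 <- confusion_at_threshold(ss, 0.96)
  expect_equal(c1[c("tp", "tn", "fp", "fn")], list(tp = 2L, tn = 2L, fp = 0L, fn = 0L))
  c2 <- confusion_at_threshold(ss, 0.97)
  expect_equal(c2[c("tp", "tn", "fp", "fn")], list(tp = 1L, tn = 2L, fp = 0L, fn = 1L))
  # threshold below every similarity score: everything called positive
  c3 <- confusion_at_threshold(ss, 0.5)
  expect_equal(c3$fn, 0L); expect_equal(c3$tn, 0L)
  expect_equal(c3$tp + c3$tn + c3$fp + c3$fn, 4L)
  # dissimilarity polarity flips the comparison
  sd <- toy_scores(kp = c(1, 2), kn = c(5, 8), polarity = "dissimilarity")
  c4 <- confusion_at_threshold(sd, 2)
  expect_equal(c4[c("tp", "tn", "fp", "fn")], list(tp = 2L, tn = 2L, fp = 0L, fn = 0L))
})

test_that("ROC AUC is 1 for perfect separation and errors on one class", {
  ss <- toy_scores(kp = c(0.99, 0.96, 0.97), kn = c(0.95, 0.90),
                   polarity = "similarity")
  expect_equal(roc_curve(ss)$auc, 1.0)
  sd <- toy_scores(kp = c(0.5, 1.2), kn = c(6, 9), polarity = "dissimilarity")
  expect_equal(roc_curve(sd)$auc, 1.0)
  one_class <- score_set("a", "known_positive", 1, "similarity")
  expect_error(roc_curve(one_class), "both")
  expect_error(pr_curve(one_class), "both")
})

test_that("trapezoid AUC equals the pairwise Mann-Whitney oracle with ties", {
  set.seed(55)
  for (i in 1:40) {
    npos <- sample(1:25, 1); nneg <- sample(1:25, 1)
    # rounding forces ties within and across classes
    kp <- round(rnorm(npos, 1, 1), sample(0:1, 1))
    kn <- round(rnorm(nneg, 0, 1), sample(0:1, 1))
    pol <- sample(c("similarity", "dissimilarity"), 1)
    ss <- toy_scores(kp, kn, polarity = pol)
    expect_equal(roc_curve(ss)$auc, auc_oracle(ss), tolerance = 1e-12)
  }
})

test_that("ROC curves are monotone and invariant to polarity + sign flips", {
  set.seed(56)
  kp <- rnorm(20, 1); kn <- rnorm(15)
  a <- roc_curve(toy_scores(kp, kn, "similarity"))
  b <- roc_curve(toy_scores(-kp, -kn, "dissimilarity"))
  expect_equal(a$auc, b$auc, tolerance = 1e-12)
  expect_equal(a$points$tpr, b$points$tpr)
  expect_equal(a$points$fpr, b$points$fpr)
  expect_true(all(diff(a$points$fpr) >= 0))
  expect_true(all(diff(a$points$tpr) >= 0))
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(57)
  kp <- rnorm(40, 1.2); kn <- rnorm(60)
  ss <- toy_scores(kp, kn, "similarity")
  ref <- suppressMessages(pROC::auc(
    response = ss$truth == "known_positive", predictor = ss$score,
    direction = "<", quiet = TRUE))
  expect_equal(roc_curve(ss)$auc, as.numeric(ref), tolerance = 1e-10)
})

test_that("precision-recall reaches (1, 1) for perfect classifiers", {
  ss <- toy_scores(kp = c(5, 6, 7), kn = c(1, 2), polarity = "similarity")
  pts <- pr_curve(ss)$points
  expect_true(any(pts$recall == 1 & pts$precision == 1))
  # recall never decreases as the threshold loosens
  expect_true(all(diff(pts$recall) >= 0))
})

test_that("all-equal scores give a single PR point at the prevalence", {
  ss <- toy_scores(kp = c(3, 3, 3), kn = c(3, 3), polarity = "similarity")
  pts <- pr_curve(ss)$points
  expect_equal(nrow(pts), 1L)
  expect_equal(pts$precision, 3 / 5)
  expect_equal(pts$recall, 1)
})

test_that("PR points match exhaustive enumeration on a toy set", {
  ss <- toy_scores(kp = c(0.9, 0.8, 0.6), kn = c(0.7, 0.5), "similarity")
  pts <- pr_curve(ss)$points
  # thresholds 0.9, 0.8, 0.7, 0.6, 0.5 ->
  expected <- data.frame(
    threshold = c(0.9, 0.8, 0.7, 0.6, 0.5),
    recall = c(1/3, 2/3, 2/3, 1, 1),
    precision = c(1, 1, 2/3, 3/4, 3/5))
  expect_equal(pts, expected, tolerance = 1e-12)
})

test_that("zero-FP threshold is midpoint-placed, exact and permissive-maximal", {
  ss <- toy_scores(kp = c(0.96, 0.99), kn = c(0.90, 0.95), "similarity")
  z <- zero_fp_threshold(ss)
  expect_gt(z$threshold, 0.95); expect_lte(z$threshold, 0.96)
  expect_equal(z$counts$fp, 0L); expect_equal(z$counts$tp, 2L)

  # overlap extreme: max KN >= max KP leaves no admissible positives
  ov <- toy_scores(kp = c(0.90, 0.93), kn = c(0.95), "similarity")
  zo <- zero_fp_threshold(ov)
  expect_equal(zo$counts$fp, 0L); expect_equal(zo$counts$tp, 0L)

  # dissimilarity: threshold strictly below the minimum KN
  sd <- toy_scores(kp = c(0.9, 1.8, 2.3), kn = c(5.75, 8, 11), "dissimilarity")
  zd <- zero_fp_threshold(sd)
  expect_lt(zd$threshold, 5.75)
  expect_equal(zd$counts$fp, 0L); expect_equal(zd$counts$tp, 3L)

  # property: fp = 0 always, and any more permissive threshold admits an FP
  set.seed(60)
  for (i in 1:25) {
    kp <- rnorm(sample(2:15, 1), 1); kn <- rnorm(sample(2:15, 1))
    pol <- sample(c("similarity", "dissimilarity"), 1)
    sset <- toy_scores(kp, kn, pol)
    zz <- zero_fp_threshold(sset)
    expect_equal(zz$counts$fp, 0L)
    eps <- 1e-9
    looser <- if (pol == "similarity") min(zz$threshold - eps, max(kn))
              else max(zz$threshold + eps, min(kn))
    expect_gte(confusion_at_threshold(sset, looser)$fp, 1L)
  }
})

# ---- residual logistic classifier ----------------------------------------

shifted_records <- function(n_pos = 40, n_neg = 15, shift_chan = "94",
                            shift = 8, seed = 71) {
  set.seed(seed)
  chans <- c("94", "96", "152", "155")
  mk <- function(i, truth, res) {
    structure(list(spectrum_id = sprintf("%s_%d", truth, i), truth = truth,
                   approach = "easi", measured = res * 0, predicted = res,
                   residuals = stats::setNames(res, chans)),
              class = "prediction_record")
  }
  pos <- lapply(seq_len(n_pos), function(i)
    mk(i, "known_positive", rnorm(4, 0, 0.5)))
  neg <- lapply(seq_len(n_neg), function(i) {
    r <- rnorm(4, 0, 0.5)
    r[chans == shift_chan] <- r[chans == shift_chan] + shift
    mk(i, "known_negative", r)
  })
  c(pos, neg)
}

test_that("a single shifted residual channel is selected and separates fully", {
  recs <- shifted_records()
  fit <- fit_residual_logit(recs)
  expect_identical(fit$selected, 94L)
  expect_identical(fit$method, "firth")   # complete separation forces penalization
  calls <- vapply(recs, function(r) classify_logit(fit, r)$class, character(1))
  truth <- vapply(recs, `[[`, character(1), "truth")
  expect_identical(calls, truth)
  # target class sits below the 0.5 probability threshold
  p_pos <- vapply(recs[truth == "known_positive"],
                  function(r) classify_logit(fit, r)$probability, numeric(1))
  expect_true(all(p_pos < 0.5))
})

test_that("identical residual distributions give an intercept-only model", {
  set.seed(72)
  chans <- c("94", "96")
  mk <- function(i, truth) {
    r <- stats::setNames(rnorm(2, 0, 1), chans)
    structure(list(spectrum_id = paste0(truth, i), truth = truth,
                   approach = "easi", measured = r * 0, predicted = r,
                   residuals = r), class = "prediction_record")
  }
  recs <- c(lapply(1:30, mk, truth = "known_positive"),
            lapply(1:30, mk, truth = "known_negative"))
  fit <- fit_residual_logit(recs)
  expect_length(fit$selected, 0)
  expect_identical(fit$method, "ml")
})

test_that("classifier input validation and tie rule", {
  recs <- shifted_records()
  expect_error(fit_residual_logit(recs[1:40]), "both truth classes")
  expect_error(fit_residual_logit(recs, threshold = 1.5), "threshold")
  # zero-coefficient boundary: probability exactly at threshold -> negative
  null_fit <- structure(list(selected = 94L, intercept = 0,
                             coefficients = c(`94` = 0), threshold = 0.5,
                             method = "ml"), class = "residual_logit")
  out <- classify_logit(null_fit, recs[[1]])
  expect_equal(out$probability, 0.5)
  expect_identical(out$class, "known_negative")
  # missing selected channels are an error
  bad <- recs[[1]]; bad$residuals <- bad$residuals[c("96", "152", "155")]
  expect_error(classify_logit(null_fit, bad), "lacks residuals")
})

test_that("logistic probability is monotone in a positively weighted residual", {
  fit <- structure(list(selected = 94L, intercept = -1,
                        coefficients = c(`94` = 2), threshold = 0.5,
                        method = "ml"), class = "residual_logit")
  mk <- function(v) structure(
    list(spectrum_id = "m", truth = "unknown", approach = "easi",
         measured = 0, predicted = v, residuals = c(`94` = v)),
    class = "prediction_record")
  probs <- vapply(seq(-3, 3, by = 0.5),
                  function(v) classify_logit(fit, mk(v))$probability, numeric(1))
  expect_true(all(diff(probs) > 0))
})

test_that("evaluate_scores bundles AUC, curves and the zero-FP point", {
  ss <- toy_scores(kp = c(1, 2, 3), kn = c(8, 9), polarity = "dissimilarity")
  rep <- evaluate_scores(ss)
  expect_equal(rep$auc, 1)
  expect_equal(rep$zero_fp$counts$fp, 0L)
  expect_equal(rep$n_positive, 3)
  expect_equal(rep$polarity, "dissimilarity")
})
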