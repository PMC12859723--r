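#' Participant-level nested fold plan
#'
#' Assigns every participant to one of `n_outer` outer test folds and, for
#' each outer fold, assigns the remaining (training) participants to
#' `n_inner` inner validation folds. Assignment is stratified by
#' ever-impaired status (round-robin dealing within class), so per-class
#' fold counts are balanced within one. All scans of a participant inherit
#' the participant's fold: train/validation/test sets are always
#' participant-disjoint.
#'
#' @param participant Character vector of participant ids (unique).
#' @param ever_impaired Logical per participant.
#' @param n_outer,n_inner Fold counts (defaults 5 and 6).
#' @param seed Integer seed; the plan is deterministic given it.
#' @return Object of class `fold_plan`: `assignment` (data.frame
#'   participant, ever_impaired, outer), `inner` (list of named integer
#'   vectors, one per outer fold, mapping training participants to inner
#'   folds), `n_outer`, `n_inner`, `seed`.
#' @examples
#' plan <- make_fold_plan(sprintf("P%02d", 1:30),
#'                        rep(c(TRUE, FALSE), 15), seed = 1)
#' table(plan$assignment$outer)
#' @export
make_fold_plan <- function(participant, ever_impaired, n_outer = 5,
                           n_inner = 6, seed = 1L) {
  stopifnot(length(participant) == length(ever_impaired),
            !anyDuplicated(participant))
  n_outer <- as.integer(n_outer); n_inner <- as.integer(n_inner)
  for (cls in c(TRUE, FALSE)) {
    if (sum(ever_impaired == cls) < n_outer)
      stop(sprintf(
        "too few %s participants (%d) for %d outer folds",
        if (cls) "ever-impaired" else "never-impaired",
        sum(ever_impaired == cls), n_outer), call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  deal <- function(ids, strata, k) {
    fold <- integer(length(ids))
    for (cls in unique(strata)) {
      idx <- which(strata == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  }
  outer <- deal(participant, ever_impaired, n_outer)
  assignment <- data.frame(participant = participant,
                           ever_impaired = ever_impaired, outer = outer,
                           stringsAsFactors = FALSE)
  inner <- vector("list", n_outer)
  for (f in seq_len(n_outer)) {
    tr <- assignment$participant[assignment$outer != f]
    st <- assignment$ever_impaired[assignment$outer != f]
    iv <- deal(tr, st, n_inner)
    names(iv) <- tr
    inner[[f]] <- iv
  }
  structure(list(assignment = assignment, inner = inner,
                 n_outer = n_outer, n_inner = n_inner,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("Participant fold plan: %d participants, %d outer x %d inner folds (seed %d)\n",
              nrow(x$assignment), x$n_outer, x$n_inner, x$seed))
  print(table(outer = x$assignment$outer, impaired = x$assignment$ever_impaired))
  invisible(x)
}

#' Isotonic calibration by pool-adjacent-violators
#'
#' Fits the least-squares nondecreasing step function mapping raw
#' classifier scores to probabilities in [0, 1]: tied scores are first
#' pooled (weighted mean of their 0/1 labels), then adjacent violators are
#' merged until the fitted sequence is nondecreasing. Prediction is
#' stepwise-constant between knots and clamps to the end values outside the
#' fitted score range.
#'
#' @param scores Raw validation scores (>= 2 points).
#' @param labels Logical labels; both classes must be present.
#' @return Object of class `isotonic_fit` with knots `x` and fitted values
#'   `y`; use `predict()` to map new scores.
#' @examples
#' fit <- isotonic_calibrate(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
#' predict(fit, c(0, 2.5, 9))
#' @export
isotonic_calibrate <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (length(scores) < 2L)
    stop("isotonic calibration needs >= 2 points", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("isotonic calibration needs both classes in the validation labels",
         call. = FALSE)
  o <- order(scores)
  x <- scores[o]
  y <- as.numeric(labels[o])
  # pool exact score ties
  ux <- unique(x)
  w <- as.numeric(tapply(rep(1, length(x)), match(x, ux), sum))
  ybar <- as.numeric(tapply(y, match(x, ux), mean))
  fit <- pava(ybar, w)
  structure(list(x = ux, y = fit), class = "isotonic_fit")
}

# Weighted pool-adjacent-violators: least-squares monotone fit.
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  val <- numeric(n); wt <- numeric(n); len <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- y[i]; wt[top] <- w[i]; len[top] <- 1L
    while (top > 1L && val[top - 1L] > val[top]) {
      val[top - 1L] <- (wt[top - 1L] * val[top - 1L] + wt[top] * val[top]) /
        (wt[top - 1L] + wt[top])
      wt[top - 1L] <- wt[top - 1L] + wt[top]
      len[top - 1L] <- len[top - 1L] + len[top]
      top <- top - 1L
    }
  }
  rep(val[seq_len(top)], times = len[seq_len(top)])
}

#' @export
predict.isotonic_fit <- function(object, newdata, ...) {
  stats::approx(object$x, object$y, xout = newdata, method = "constant",
                f = 0, rule = 2, ties = "ordered")$y
}

#' @export
print.isotonic_fit <- function(x, ...) {
  cat(sprintf("Isotonic calibration map: %d knots, range [%.3f, %.3f]\n",
              length(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' Calibrated k-model ensemble
#'
#' Bundles k trained submodels with their isotonic calibration maps and a
#' selected decision threshold.
#'
#' @param submodels List of `trained_submodel`s.
#' @param calibrations List of `isotonic_fit`s, one per submodel.
#' @param threshold Decision threshold in [0, 1].
#' @return Object of class `calibrated_ensemble`.
#' @export
calibrated_ensemble <- function(submodels, calibrations, threshold = 0.5) {
  stopifnot(length(submodels) == length(calibrations), length(submodels) >= 1)
  structure(list(submodels = submodels, calibrations = calibrations,
                 threshold = threshold, k = length(submodels)),
            class = "calibrated_ensemble")
}

#' Ensemble probability for scans
#'
#' Scores feature rows with each submodel, maps each raw score through its
#' isotonic calibration, and averages the k calibrated probabilities.
#'
#' @param x Feature matrix (rows = scans).
#' @param ensemble A [calibrated_ensemble()].
#' @return Probabilities in [0, 1], one per row.
#' @export
ensemble_score <- function(x, ensemble) {
  probs <- vapply(seq_len(ensemble$k), function(k)
    predict(ensemble$calibrations[[k]],
            predict(ensemble$submodels[[k]], x)),
    numeric(nrow(as.matrix(x))))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  rowMeans(probs)
}

#' @export
predict.calibrated_ensemble <- function(object, x,
                                        type = c("prob", "class"), ...) {
  p <- ensemble_score(x, object)
  if (match.arg(type) == "class") p >= object$threshold else p
}

#' @export
print.calibrated_ensemble <- function(x, ...) {
  cat(sprintf("Calibrated ensemble: %d submodels, threshold %.3f\n",
              x$k, x$threshold))
  invisible(x)
}

#' F1-optimal decision threshold
#'
#' Evaluates the F1 score of the rule `prob >= t` at every candidate
#' threshold -- midpoints between consecutive distinct sorted probabilities
#' plus 0 and 1 -- and returns the candidate with the highest F1; ties go to
#' the smallest threshold.
#'
#' @param probs Calibrated validation probabilities.
#' @param labels Logical labels (both classes present).
#' @return The selected threshold; attribute `"f1"` holds its F1 score.
#' @examples
#' select_threshold(c(.1, .2, .8, .9), c(FALSE, FALSE, TRUE, TRUE))
#' @export
select_threshold <- function(probs, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L)
    stop("threshold selection needs both classes", call. = FALSE)
  u <- sort(unique(probs))
  cand <- sort(unique(c(0, 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2)))
  f1s <- vapply(cand, function(t) {
    pred <- probs >= t
    tp <- sum(pred & labels); fp <- sum(pred & !labels); fn <- sum(!pred & labels)
    if (tp == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  best <- which.max(f1s)  # first maximum = smallest threshold
  structure(cand[best], f1 = f1s[best])
}

#' Classification metric set
#'
#' Confusion-matrix metrics plus ROC-AUC. Precision is TP/(TP+FP), recall
#' TP/(TP+FN), F1 the harmonic mean of the two, accuracy (TP+TN)/N and the
#' false-positive rate FP/(FP+TN). ROC-AUC is computed by trapezoidal
#' integration over the empirical ROC curve swept across all score
#' thresholds, which equals the tie-corrected rank (Mann-Whitney)
#' statistic. Metrics with an undefined denominator are reported as `NA`
#' with a reason, never silently coerced to 0.
#'
#' @param truth Logical labels.
#' @param predicted Logical predictions (optional if `scores` given, in
#'   which case AUC alone is meaningful).
#' @param scores Numeric scores for ROC-AUC; defaults to `predicted`.
#' @return Object of class `metric_set`: precision, recall, f1, accuracy,
#'   false_positive_rate, roc_auc, n, the confusion counts, and a named
#'   `reasons` vector for undefined metrics.
#' @examples
#' compute_metrics(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
compute_metrics <- function(truth, predicted = NULL, scores = NULL) {
  truth <- as.logical(truth)
  n <- length(truth)
  if (n < 1) stop("compute_metrics needs n >= 1", call. = FALSE)
  reasons <- character(0)
  tp <- fp <- tn <- fn <- NA_integer_
  precision <- recall <- f1 <- accuracy <- fpr <- NA_real_
  if (!is.null(predicted)) {
    predicted <- as.logical(predicted)
    stopifnot(length(predicted) == n)
    tp <- sum(predicted & truth); fp <- sum(predicted & !truth)
    tn <- sum(!predicted & !truth); fn <- sum(!predicted & truth)
    accuracy <- (tp + tn) / n
    if (tp + fp > 0) precision <- tp / (tp + fp)
    else reasons["precision"] <- "no predicted positives"
    if (tp + fn > 0) recall <- tp / (tp + fn)
    else reasons["recall"] <- "no true positives in labels"
    if (fp + tn > 0) fpr <- fp / (fp + tn)
    else reasons["false_positive_rate"] <- "no true negatives in labels"
    if (!is.na(precision) && !is.na(recall)) {
      f1 <- if (precision + recall > 0)
        2 * precision * recall / (precision + recall) else 0
    } else reasons["f1"] <- "precision or recall undefined"
  }
  if (is.null(scores) && !is.null(predicted)) scores <- as.numeric(predicted)
  auc <- NA_real_
  if (is.null(scores)) {
    reasons["roc_auc"] <- "no scores or predictions provided"
  } else if (length(unique(truth)) == 2L) {
    auc <- roc_auc_trapezoid(truth, scores)
  } else {
    reasons["roc_auc"] <- "labels contain a single class"
  }
  structure(list(precision = precision, recall = recall, f1 = f1,
                 accuracy = accuracy, false_positive_rate = fpr,
                 roc_auc = auc, n = n,
                 confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 reasons = reasons),
            class = "metric_set")
}

#' F1 score from precision and recall
#'
#' The harmonic mean `2 * p * r / (p + r)`; `NA` when both are zero or
#' either is `NA`.
#'
#' @param precision,recall Values in [0, 1].
#' @return The F1 score.
#' @examples
#' f1_score(0.60, 0.56)
#' @export
f1_score <- function(precision, recall) {
  ifelse(is.na(precision) | is.na(recall) | precision + recall == 0,
         NA_real_, 2 * precision * recall / (precision + recall))
}

# Trapezoidal area under the empirical ROC curve (threshold sweep over all
# distinct scores); equals pairwise concordance with ties counted 1/2.
roc_auc_trapezoid <- function(truth, scores) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- truth[o]
  grp <- cumsum(!duplicated(s))
  tp_c <- cumsum(y); fp_c <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp_c[last] / sum(truth))
  fpr <- c(0, fp_c[last] / sum(!truth))
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' @export
print.metric_set <- function(x, digits = 3, ...) {
  v <- c(precision = x$precision, recall = x$recall, f1 = x$f1,
         accuracy = x$accuracy, false_positive_rate = x$false_positive_rate,
         roc_auc = x$roc_auc)
  cat(sprintf("Classification metrics (n = %d)\n", x$n))
  print(round(v, digits))
  if (length(x$reasons))
    cat("undefined:", paste(names(x$reasons), "--", x$reasons, collapse = "; "),
        "\n")
  invisible(x)
}

#' @export
as.data.frame.metric_set <- function(x, ...) {
  data.frame(precision = x$precision, recall = x$recall, f1 = x$f1,
             accuracy = x$accuracy, false_positive_rate = x$false_positive_rate,
             roc_auc = x$roc_auc, n = x$n)
}

#' Nested cross-validated ensemble classification
#'
#' The full evaluation loop: for each outer test fold, six submodels are
#' trained on the complements of the six inner validation folds, each is
#' isotonically calibrated on its held-out validation fold, the F1-optimal
#' threshold is selected on the pooled calibrated validation scores, and
#' the outer-fold test scans are scored by the average of the six
#' calibrated probabilities and thresholded. Participant-level partitioning
#' is audited: a hard error is raised if any test scan's participant
#' appears in a model that scored it.
#'
#' In `robustness` mode, participants never labeled impaired at either
#' post-THC scan are excluded from all training and validation sets and
#' appear exclusively in test sets.
#'
#' @param x Feature matrix, rows = scans.
#' @param y Logical per-scan training class (`TRUE` = impaired).
#' @param participant Character participant id per scan.
#' @param plan A [make_fold_plan()] covering all participants.
#' @param model `"ridge"`, `"ridge_detach"` or `"logistic"`.
#' @param mode `"standard"` or `"robustness"`.
#' @param prune_fraction,trade_off Passed to [sequential_detach()] for
#'   `model = "ridge_detach"`.
#' @param threshold_pooling `"pooled"` (default: one threshold per outer
#'   fold from pooled validation scores) or `"per_fold"` (median of the six
#'   per-inner-fold thresholds).
#' @param lambda Penalty for the logistic head.
#' @return Object of class `nested_cv_result`: `scans` (per-scan data.frame
#'   with out-of-fold `prob`, `flag`, `outer_fold`), `fold_metrics` (list
#'   of `metric_set`), `pooled` (metrics over concatenated out-of-fold
#'   predictions), `fold_mean` (per-fold metric averages), `ensembles`,
#'   `thresholds`, and an `audit` block.
#' @examples
#' \dontrun{
#' res <- run_nested_cv(x, y, participant, plan)
#' summary(res)
#' }
#' @export
run_nested_cv <- function(x, y, participant, plan,
                          model = c("ridge", "ridge_detach", "logistic"),
                          mode = c("standard", "robustness"),
                          prune_fraction = 0.05, trade_off = 0.1,
                          threshold_pooling = c("pooled", "per_fold"),
                          lambda = 1) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  threshold_pooling <- match.arg(threshold_pooling)
  x <- as.matrix(x); y <- as.logical(y)
  stopifnot(nrow(x) == length(y), length(participant) == length(y))
  missing_p <- setdiff(participant, plan$assignment$participant)
  if (length(missing_p))
    stop("participants not in fold plan: ", paste(missing_p[1:3], collapse = ", "),
         call. = FALSE)

  ever_imp_scan <- tapply(y, participant, any)
  never_impaired <- names(ever_imp_scan)[!ever_imp_scan]
  outer_of <- plan$assignment$outer[match(participant, plan$assignment$participant)]

  n <- nrow(x)
  prob <- rep(NA_real_, n); flag <- rep(NA, n)
  fold_metrics <- vector("list", plan$n_outer)
  ensembles <- vector("list", plan$n_outer)
  thresholds <- numeric(plan$n_outer)
  train_participants_used <- vector("list", plan$n_outer)

  fit_one <- function(xtr, ytr, xval, yval) {
    if (model == "logistic") return(fit_crossentropy_head(xtr, ytr, lambda = lambda))
    m <- fit_ridge_head(xtr, ytr)
    if (model == "ridge_detach")
      m <- sequential_detach(m, xtr, ytr, xval, yval,
                             prune_fraction = prune_fraction,
                             trade_off = trade_off)
    m
  }

  for (f in seq_len(plan$n_outer)) {
    inner_map <- plan$inner[[f]]
    pool <- names(inner_map)
    if (mode == "robustness") pool <- setdiff(pool, never_impaired)
    test_idx <- which(outer_of == f)
    submodels <- list(); calibs <- list()
    val_probs <- numeric(0); val_labels <- logical(0)
    inner_thresholds <- numeric(0)
    for (k in seq_len(plan$n_inner)) {
      val_p <- pool[inner_map[pool] == k]
      trn_p <- setdiff(pool, val_p)
      tr_idx <- which(participant %in% trn_p)
      va_idx <- which(participant %in% val_p)
      if (!length(tr_idx) || !length(va_idx))
        stop(sprintf("empty inner fold %d of outer fold %d", k, f), call. = FALSE)
      m <- fit_one(x[tr_idx, , drop = FALSE], y[tr_idx],
                   x[va_idx, , drop = FALSE], y[va_idx])
      raw_val <- predict(m, x[va_idx, , drop = FALSE])
      cal <- isotonic_calibrate(raw_val, y[va_idx])
      pv <- predict(cal, raw_val)
      submodels[[k]] <- m; calibs[[k]] <- cal
      val_probs <- c(val_probs, pv)
      val_labels <- c(val_labels, y[va_idx])
      if (threshold_pooling == "per_fold")
        inner_thresholds <- c(inner_thresholds, select_threshold(pv, y[va_idx]))
    }
    thr <- if (threshold_pooling == "pooled")
      as.numeric(select_threshold(val_probs, val_labels))
    else stats::median(inner_thresholds)
    ens <- calibrated_ensemble(submodels, calibs, thr)
    p_test <- ensemble_score(x[test_idx, , drop = FALSE], ens)
    prob[test_idx] <- p_test
    flag[test_idx] <- p_test >= thr
    ensembles[[f]] <- ens
    thresholds[f] <- thr
    train_participants_used[[f]] <- pool
    fold_metrics[[f]] <- compute_metrics(y[test_idx], flag[test_idx],
                                         scores = p_test)
  }

  # --- leakage audit ------------------------------------------------------
  for (f in seq_len(plan$n_outer)) {
    test_p <- unique(participant[outer_of == f])
    leak <- intersect(test_p, train_participants_used[[f]])
    if (length(leak))
      stop("participant-level leakage detected in outer fold ", f, ": ",
           paste(leak, collapse = ", "), call. = FALSE)
  }
  robustness_ok <- TRUE
  if (mode == "robustness") {
    robustness_ok <- !any(unlist(train_participants_used) %in% never_impaired)
    if (!robustness_ok)
      stop("robustness audit failed: never-impaired participant in training pool",
           call. = FALSE)
  }

  pooled <- compute_metrics(y, flag, scores = prob)
  fm <- do.call(rbind, lapply(fold_metrics, as.data.frame))
  fold_mean <- colMeans(fm[, setdiff(names(fm), "n")], na.rm = TRUE)

  structure(list(
    scans = data.frame(participant = participant, y = y, prob = prob,
                       flag = flag, outer_fold = outer_of,
                       stringsAsFactors = FALSE),
    fold_metrics = fold_metrics, pooled = pooled, fold_mean = fold_mean,
    ensembles = ensembles, thresholds = thresholds,
    model = model, mode = mode,
    audit = list(leakage_checked = TRUE,
                 participant_disjoint = TRUE,
                 robustness_ok = robustness_ok,
                 never_impaired = never_impaired,
                 train_participants = train_participants_used)
  ), class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat(sprintf("Nested CV (%s model, %s mode): %d scans, %d outer folds\n",
              x$model, x$mode, nrow(x$scans), length(x$fold_metrics)))
  cat("Pooled out-of-fold metrics:\n")
  print(x$pooled)
  invisible(x)
}

#' @export
plot.nested_cv_result <- function(x, ...) {
  truth <- x$scans$y
  scores <- x$scans$prob
  o <- order(scores, decreasing = TRUE)
  y <- truth[o]
  tpr <- c(0, cumsum(y) / sum(truth))
  fpr <- c(0, cumsum(!y) / sum(!truth))
  graphics::plot(fpr, tpr, type = "l", xlab = "False-positive rate",
                 ylab = "True-positive rate",
                 main = sprintf("Out-of-fold ROC (AUC = %.3f)",
                                x$pooled$roc_auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey60")
  invisible(x)
}

#' @export
summary.nested_cv_result <- function(object, ...) {
  cat("Per-fold thresholds:", paste(round(object$thresholds, 3), collapse = ", "),
      "\n")
  print(object)
  cat("Fold-averaged metrics:\n")
  print(round(object$fold_mean, 3))
  invisible(object)
}

#' Metrics on inconsistently impaired participants
#'
#' Restricts out-of-fold predictions to scans from participants labeled
#' impaired at exactly one of their post-THC scans -- the subset where
#' impairment status changes over the session -- and recomputes the metric
#' set, probing the temporal specificity of the classifier.
#'
#' @param result A [run_nested_cv()] result.
#' @param labels A [label_cohort()] data.frame.
#' @return A `metric_set`, or `NA` with attribute `"reason"` when the
#'   subset is empty; attribute `"participants"` lists the subset.
#' @export
temporal_subset_eval <- function(result, labels) {
  post <- labels$session == "THC" & labels$timepoint != "predose"
  n_imp <- tapply(labels$impaired[post], labels$participant[post], sum)
  inconsistent <- names(n_imp)[n_imp == 1]
  sel <- result$scans$participant %in% inconsistent
  if (!any(sel)) {
    out <- NA
    attr(out, "reason") <- "no inconsistently impaired participants"
    return(out)
  }
  m <- compute_metrics(result$scans$y[sel], result$scans$flag[sel],
                       scores = result$scans$prob[sel])
  attr(m, "participants") <- inconsistent
  m
}
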