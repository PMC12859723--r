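test_that("fold plans partition participants with stratified balance", {
  ids <- sprintf("P%02d", 1:30)
  imp <- rep(c(TRUE, FALSE), 15)
  plan <- make_fold_plan(ids, imp, n_outer = 5, n_inner = 6, seed = 4)
  expect_identical(plan, make_fold_plan(ids, imp, 5, 6, seed = 4))

  # 30 participants / 5 folds -> 6 per fold; 15/15 classes -> 3 impaired each
  tab <- table(plan$assignment$outer)
  expect_true(all(tab == 6))
  imp_per_fold <- tapply(plan$assignment$ever_impaired, plan$assignment$outer,
                         sum)
  expect_true(all(imp_per_fold == 3))
  expect_false(anyDuplicated(plan$assignment$participant) > 0)

  # inner folds partition exactly the training participants of each outer
  for (f in 1:5) {
    trn <- plan$assignment$participant[plan$assignment$outer != f]
    expect_setequal(names(plan$inner[[f]]), trn)
    expect_true(all(plan$inner[[f]] %in% 1:6))
    inner_imp <- tapply(
      plan$assignment$ever_impaired[match(names(plan$inner[[f]]),
                                          plan$assignment$participant)],
      plan$inner[[f]], sum)
    expect_lte(diff(range(inner_imp)), 1)  # balanced within one
  }

  expect_error(make_fold_plan(ids[1:8], rep(c(TRUE, FALSE), 4), n_outer = 5),
               "too few")
})

test_that("pool-adjacent-violators reproduces textbook cases", {
  fit <- isotonic_calibrate(1:4, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(fit$y, c(0, 0, 1, 1))
  # one violation: both pooled to the mean
  fit2 <- isotonic_calibrate(1:2, c(TRUE, FALSE))
  expect_equal(fit2$y, c(0.5, 0.5))
  # prediction: stepwise with clamping outside the fitted range
  expect_equal(predict(fit, c(-10, 1.5, 10)), c(0, 0, 1))
  expect_error(isotonic_calibrate(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  expect_error(isotonic_calibrate(1, TRUE), ">= 2")
})

test_that("PAVA attains the exhaustive monotone-step optimum", {
  for (s in 1:100) {
    set.seed(s)
    n <- sample(4:12, 1)
    scores <- sample(seq(0, 2, by = 0.25), n, replace = TRUE)  # with ties
    labels <- runif(n) < 0.5
    if (length(unique(labels)) < 2) labels[1:2] <- c(TRUE, FALSE)
    fit <- isotonic_calibrate(scores, labels)
    # SSE of the PAVA fit over the raw points
    o <- order(scores)
    pred <- predict(fit, scores[o])
    sse <- sum((as.numeric(labels[o]) - pred)^2)
    expect_lt(abs(sse - isotonic_bruteforce_sse(scores, labels)), 1e-12)
    expect_true(all(diff(fit$y) >= -1e-12))          # nondecreasing
    expect_true(all(fit$y >= 0 & fit$y <= 1))
  }
})

test_that("ensemble scores average the calibrated submodels", {
  x <- matrix(c(0.5), 1, 1)
  ens1 <- calibrated_ensemble(list(identity_submodel(), identity_submodel()),
                              list(constant_isotonic(1), constant_isotonic(1)))
  expect_equal(ensemble_score(x, ens1), 1)
  ens2 <- calibrated_ensemble(list(identity_submodel(), identity_submodel()),
                              list(constant_isotonic(0.2), constant_isotonic(0.6)))
  expect_equal(ensemble_score(x, ens2), 0.4)
  ens2r <- calibrated_ensemble(rev(ens2$submodels), rev(ens2$calibrations))
  expect_equal(ensemble_score(x, ens2r), ensemble_score(x, ens2))
})

test_that("threshold selection is F1-optimal over all real thresholds", {
  # perfectly separated: the smallest candidate inside the gap is returned
  thr <- select_threshold(c(.1, .2, .8, .9), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(as.numeric(thr), 0.5)
  expect_equal(attr(thr, "f1"), 1)

  # degenerate all-equal probabilities: tie rule gives threshold 0
  # (all-positive prediction beats all-negative on F1)
  thr0 <- select_threshold(rep(0.5, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(as.numeric(thr0), 0)

  # exhaustive check against a dense threshold grid on small instances
  for (s in 1:50) {
    set.seed(s)
    n <- sample(3:10, 1)
    p <- round(runif(n), 2)
    y <- runif(n) < 0.5
    if (length(unique(y)) < 2) y[1:2] <- c(TRUE, FALSE)
    thr <- select_threshold(p, y)
    f1_at <- function(t) {
      pred <- p >= t
      tp <- sum(pred & y)
      if (tp == 0) 0 else 2 * tp / (2 * tp + sum(pred & !y) + sum(!pred & y))
    }
    grid <- sort(unique(c(0, 1, p, p - 1e-9, p + 1e-9, seq(0, 1, by = 0.001))))
    expect_gte(attr(thr, "f1") + 1e-12, max(sapply(grid, f1_at)))
    expect_equal(f1_at(as.numeric(thr)), attr(thr, "f1"))
  }
})

test_that("metrics match brute-force confusion counting", {
  # all four single-point cases
  for (truth in c(TRUE, FALSE)) for (pred in c(TRUE, FALSE)) {
    m <- compute_metrics(truth, pred)
    o <- metrics_bruteforce(truth, pred)
    for (nm in names(o)) expect_equal(m[[nm]], o[[nm]], info = nm)
  }
  # random 20-point cases
  for (s in 1:25) {
    set.seed(s)
    truth <- runif(20) < 0.4
    pred <- runif(20) < 0.5
    m <- compute_metrics(truth, pred)
    o <- metrics_bruteforce(truth, pred)
    for (nm in names(o)) expect_equal(m[[nm]], o[[nm]], info = nm)
  }
  # perfect prediction
  y <- c(TRUE, TRUE, FALSE, FALSE)
  m <- compute_metrics(y, y)
  expect_equal(m$precision, 1); expect_equal(m$recall, 1)
  expect_equal(m$f1, 1); expect_equal(m$accuracy, 1)
  expect_equal(m$false_positive_rate, 0); expect_equal(m$roc_auc, 1)
  # undefined denominators carry reasons, never silent zeros
  m2 <- compute_metrics(c(FALSE, FALSE), c(FALSE, FALSE))
  expect_true(is.na(m2$precision))
  expect_true(is.na(m2$recall))
  expect_match(m2$reasons[["precision"]], "no predicted positives")
  expect_true(is.na(m2$roc_auc))
})

test_that("trapezoidal ROC-AUC equals pairwise concordance with ties", {
  for (s in 1:30) {
    set.seed(s)
    truth <- runif(50) < 0.3
    if (length(unique(truth)) < 2) truth[1:2] <- c(TRUE, FALSE)
    scores <- sample(round(rnorm(50), 1), 50)  # plenty of ties
    m <- compute_metrics(truth, truth, scores = scores)
    expect_lt(abs(m$roc_auc - auc_concordance(truth, scores)), 1e-12)
  }
})


test_that("nested CV recovers a strong effect and audits leakage", {
  d <- simulate_feature_cohort(signal = 3, seed = 5)
  plan <- make_fold_plan(names(d$ever), as.logical(d$ever), seed = 6)
  res <- run_nested_cv(d$x, d$y, d$participant, plan, model = "ridge")
  expect_gte(res$pooled$roc_auc, 0.85)
  expect_true(all(!is.na(res$scans$prob)))
  expect_true(all(res$scans$prob >= 0 & res$scans$prob <= 1))
  expect_true(res$audit$leakage_checked)
  # independent audit: no test participant in its own fold's training pool
  for (f in seq_along(res$audit$train_participants)) {
    test_p <- unique(d$participant[res$scans$outer_fold == f])
    expect_length(intersect(test_p, res$audit$train_participants[[f]]), 0)
  }
})

test_that("nested CV is at chance under a null effect", {
  aucs <- vapply(1:10, function(s) {
    d <- simulate_feature_cohort(signal = 0, seed = 100 + s)
    plan <- make_fold_plan(names(d$ever), as.logical(d$ever), seed = s)
    run_nested_cv(d$x, d$y, d$participant, plan, model = "ridge")$pooled$roc_auc
  }, numeric(1))
  expect_gte(mean(aucs), 0.40)
  expect_lte(mean(aucs), 0.60)
})

test_that("robustness mode keeps never-impaired participants out of training", {
  d <- simulate_feature_cohort(signal = 3, seed = 7)
  plan <- make_fold_plan(names(d$ever), as.logical(d$ever), seed = 8)
  res <- run_nested_cv(d$x, d$y, d$participant, plan, model = "ridge",
                       mode = "robustness")
  never <- names(d$ever)[!d$ever]
  for (pool in res$audit$train_participants)
    expect_length(intersect(pool, never), 0)
  expect_true(res$audit$robustness_ok)
  # never-impaired participants are still scored (exclusively as test cases)
  expect_true(all(!is.na(res$scans$prob[d$participant %in% never])))
})

test_that("the detached-kernel and logistic heads run through the same loop", {
  d <- simulate_feature_cohort(n_participants = 24, signal = 3, seed = 9)
  plan <- make_fold_plan(names(d$ever), as.logical(d$ever),
                         n_outer = 3, n_inner = 3, seed = 10)
  for (mod in c("ridge_detach", "logistic")) {
    res <- run_nested_cv(d$x, d$y, d$participant, plan, model = mod,
                         prune_fraction = 0.2)
    expect_gte(res$pooled$roc_auc, 0.8)
  }
})

test_that("temporal subset evaluation matches manual enumeration", {
  labels <- data.frame(
    participant = rep(c("A", "B", "C", "D"), each = 3),
    session = "THC",
    timepoint = rep(c("predose", "postdose1", "postdose2"), 4),
    impaired = c(FALSE, TRUE, FALSE,   # A: inconsistent
                 FALSE, TRUE, TRUE,    # B: consistent
                 FALSE, FALSE, FALSE,  # C: never
                 FALSE, FALSE, TRUE))  # D: inconsistent
  res <- list(scans = data.frame(
    participant = rep(c("A", "B", "C", "D"), each = 2),
    y = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
    prob = c(.9, .2, .8, .7, .1, .3, .6, .4),
    flag = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)))
  m <- temporal_subset_eval(res, labels)
  expect_s3_class(m, "metric_set")
  expect_identical(sort(attr(m, "participants")), c("A", "D"))
  expect_equal(m$n, 4)  # two scans each from A and D
  # all participants consistent/never -> empty subset with a reason
  labels2 <- labels
  labels2$impaired[labels2$participant == "A"] <- c(FALSE, TRUE, TRUE)
  labels2$impaired[labels2$participant == "D"] <- FALSE
  m2 <- temporal_subset_eval(res, labels2)
  expect_true(is.na(m2[1]))
  expect_match(attr(m2, "reason"), "no inconsistently impaired")
  # when everyone is inconsistently impaired the subset is the full sample
  labels3 <- labels
  labels3$impaired <- rep(c(FALSE, TRUE, FALSE), 4)
  m3 <- temporal_subset_eval(res, labels3)
  full <- compute_metrics(res$scans$y, res$scans$flag, scores = res$scans$prob)
  expect_equal(as.data.frame(m3), as.data.frame(full))
})
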