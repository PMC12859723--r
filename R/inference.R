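#' Paired stratified bootstrap comparison of two classifiers
#'
#' Compares two classifiers on the shared test scans for which both produced
#' predictions. Each of `n_boot` resamples draws, with replacement, exactly
#' the original number of positive indices from the positives and negative
#' indices from the negatives (stratified resampling preserving the class
#' proportion); all six metrics are computed for both classifiers on each
#' resample and their paired differences (A - B) collected. Per metric the
#' observed difference, percentile 95% CI, bootstrap SE, and the one-sided
#' bootstrap p value -- the proportion of bootstrap differences less than or
#' equal to 0 -- are reported. For metrics where smaller is better (the
#' false-positive rate) the mirrored one-sided p (proportion >= 0) is also
#' reported, clearly labeled. Resamples on which a metric is undefined are
#' excluded for that metric and counted.
#'
#' @param labels Logical ground truth on the shared scans (both classes
#'   present).
#' @param preds_a,scores_a Predictions (logical) and scores for classifier A.
#' @param preds_b,scores_b Same for classifier B.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param metrics Metric names to compare (default all six).
#' @return Object of class `bootstrap_comparison`: a data.frame `table`
#'   with columns metric, observed_a, observed_b, difference, ci_low,
#'   ci_high, se, p_value, p_value_mirrored, n_resamples_used; plus `seed`,
#'   `n_shared_scans`, `n_boot`.
#' @examples
#' set.seed(1)
#' y <- rep(c(TRUE, FALSE), c(20, 80))
#' sa <- rnorm(100, as.numeric(y)); sb <- rnorm(100, as.numeric(y))
#' cmp <- paired_bootstrap(y, sa > .5, sa, sb > .5, sb, n_boot = 100, seed = 1)
#' @export
paired_bootstrap <- function(labels, preds_a, scores_a, preds_b, scores_b,
                             n_boot = 1000, seed = 1L,
                             metrics = c("precision", "recall", "f1",
                                         "accuracy", "false_positive_rate",
                                         "roc_auc")) {
  labels <- as.logical(labels)
  n <- length(labels)
  stopifnot(length(preds_a) == n, length(scores_a) == n,
            length(preds_b) == n, length(scores_b) == n)
  if (length(unique(labels)) < 2L)
    stop("paired bootstrap needs both classes in the labels", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  pos <- which(labels); neg <- which(!labels)
  metric_vec <- function(idx) {
    ma <- compute_metrics(labels[idx], as.logical(preds_a)[idx],
                          scores = scores_a[idx])
    mb <- compute_metrics(labels[idx], as.logical(preds_b)[idx],
                          scores = scores_b[idx])
    va <- unlist(ma[metrics]); vb <- unlist(mb[metrics])
    rbind(a = va, b = vb)
  }
  obs <- metric_vec(seq_len(n))

  diffs <- matrix(NA_real_, n_boot, length(metrics),
                  dimnames = list(NULL, metrics))
  for (b in seq_len(n_boot)) {
    idx <- c(pos[sample.int(length(pos), length(pos), replace = TRUE)],
             neg[sample.int(length(neg), length(neg), replace = TRUE)])
    mv <- metric_vec(idx)
    diffs[b, ] <- mv["a", ] - mv["b", ]
  }

  tab <- do.call(rbind, lapply(metrics, function(m) {
    d <- diffs[, m]
    used <- d[!is.na(d)]
    if (!length(used)) {
      return(data.frame(metric = m, observed_a = obs["a", m],
                        observed_b = obs["b", m],
                        difference = obs["a", m] - obs["b", m],
                        ci_low = NA_real_, ci_high = NA_real_, se = NA_real_,
                        p_value = NA_real_, p_value_mirrored = NA_real_,
                        n_resamples_used = 0L, stringsAsFactors = FALSE))
    }
    q <- stats::quantile(used, c(0.025, 0.975), names = FALSE, type = 7)
    data.frame(metric = m, observed_a = obs["a", m], observed_b = obs["b", m],
               difference = obs["a", m] - obs["b", m],
               ci_low = q[1], ci_high = q[2], se = stats::sd(used),
               p_value = mean(used <= 0),
               p_value_mirrored = mean(used >= 0),
               n_resamples_used = length(used), stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(table = tab, seed = as.integer(seed),
                 n_shared_scans = n, n_boot = n_boot),
            class = "bootstrap_comparison")
}

#' @export
print.bootstrap_comparison <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Paired stratified bootstrap (%d resamples, %d shared scans, seed %d)\n",
    x$n_boot, x$n_shared_scans, x$seed))
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Within-participant condition contrasts
#'
#' Estimates condition means of a per-scan outcome (impairment probability,
#' heart-rate change, DEQ rating) with a random-intercept-style estimator:
#' participant means are removed (within-participant centering), condition
#' effects are the across-participant averages of the centered condition
#' means, and contrasts between conditions are reported with percentile
#' cluster-bootstrap CIs (resampling participants).
#'
#' @param values Numeric outcome per scan.
#' @param participant Participant id per scan.
#' @param condition Condition label per scan (e.g. `"predose"`,
#'   `"placebo"`, `"THC-impaired"`, `"THC-not-impaired"`).
#' @param pairs List of length-2 character vectors naming the contrasts;
#'   default: THC-impaired against each other condition present, plus
#'   placebo vs predose.
#' @param n_boot Cluster-bootstrap resamples (default 2000).
#' @param conf_level Confidence level.
#' @param seed Integer seed.
#' @return Data.frame of class `contrast_estimates`: condition_a,
#'   condition_b, estimate (a - b), ci_low, ci_high, n_participants; rows
#'   with fewer than 2 participants in a condition carry `NA` and a reason.
#' @examples
#' d <- expand.grid(p = sprintf("P%02d", 1:10), cond = c("placebo", "THC-impaired"))
#' v <- rnorm(nrow(d)) + 2 * (d$cond == "THC-impaired")
#' condition_contrasts(v, d$p, d$cond, n_boot = 200, seed = 1)
#' @export
condition_contrasts <- function(values, participant, condition,
                                pairs = NULL, n_boot = 2000,
                                conf_level = 0.95, seed = 1L) {
  stopifnot(length(values) == length(participant),
            length(values) == length(condition))
  condition <- as.character(condition)
  participant <- as.character(participant)
  conds <- unique(condition)
  if (length(conds) < 2L)
    stop("need >= 2 conditions with data", call. = FALSE)
  if (is.null(pairs)) {
    pairs <- list()
    if ("THC-impaired" %in% conds)
      for (cc in setdiff(conds, "THC-impaired"))
        pairs[[length(pairs) + 1L]] <- c("THC-impaired", cc)
    if (all(c("placebo", "predose") %in% conds))
      pairs[[length(pairs) + 1L]] <- c("placebo", "predose")
    if (!length(pairs))
      pairs <- list(conds[1:2])
  }

  # condition effects from within-participant-centered condition means
  cond_effects <- function(ids) {
    rows <- which(participant %in% ids)
    v <- values[rows]; p <- participant[rows]; cc <- condition[rows]
    pm <- tapply(v, p, mean)
    vc <- v - pm[p]
    # per participant x condition mean of centered values, then average
    # across participants within condition
    agg <- tapply(vc, list(p, cc), mean)
    colMeans(agg, na.rm = TRUE)
  }
  obs <- cond_effects(unique(participant))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  ids <- unique(participant)
  boot <- matrix(NA_real_, n_boot, length(obs),
                 dimnames = list(NULL, names(obs)))
  for (b in seq_len(n_boot)) {
    samp <- sample(ids, length(ids), replace = TRUE)
    # cluster bootstrap: duplicated participants contribute repeatedly
    rows <- unlist(lapply(samp, function(id) which(participant == id)))
    v <- values[rows]
    p <- rep(seq_along(samp), times = vapply(samp, function(id)
      sum(participant == id), integer(1)))
    cc <- condition[rows]
    pm <- tapply(v, p, mean)
    vc <- v - pm[as.character(p)]
    agg <- tapply(vc, list(p, cc), mean)
    eff <- colMeans(agg, na.rm = TRUE)
    boot[b, names(eff)] <- eff
  }

  alpha <- (1 - conf_level) / 2
  out <- do.call(rbind, lapply(pairs, function(pr) {
    a <- pr[1]; bb <- pr[2]
    n_a <- length(unique(participant[condition == a]))
    n_b <- length(unique(participant[condition == bb]))
    if (n_a < 2 || n_b < 2 || !(a %in% names(obs)) || !(bb %in% names(obs))) {
      return(data.frame(condition_a = a, condition_b = bb,
                        estimate = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_,
                        n_participants = min(n_a, n_b),
                        reason = "condition with < 2 participants",
                        stringsAsFactors = FALSE))
    }
    d <- boot[, a] - boot[, bb]
    d <- d[!is.na(d)]
    q <- stats::quantile(d, c(alpha, 1 - alpha), names = FALSE)
    data.frame(condition_a = a, condition_b = bb,
               estimate = obs[a] - obs[bb], ci_low = q[1], ci_high = q[2],
               n_participants = length(unique(
                 participant[condition %in% c(a, bb)])),
               reason = NA_character_, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("contrast_estimates", "data.frame")
  out
}

#' Dosing-condition outcome values per scan timepoint
#'
#' Builds the per-scan-timepoint data used for condition contrasts:
#' heart-rate change from predose baseline (via the same windowed rule as
#' [algorithm_flag()]), the "feel drug" DEQ rating, and the dosing
#' condition label -- `predose`, `placebo`, `THC-impaired` or
#' `THC-not-impaired` (the latter two per the impairment labels).
#'
#' @param cohort An `fnirs_cohort`.
#' @param labels A [label_cohort()] data.frame.
#' @return Data.frame: participant, session, timepoint, condition, dhr
#'   (bpm), deq_feel (0-100).
#' @export
scan_condition_values <- function(cohort, labels) {
  lat <- cohort$latent
  lkey <- paste(labels$participant, labels$session, labels$timepoint)
  out <- vector("list", nrow(lat))
  for (i in seq_len(nrow(lat))) {
    r <- lat[i, ]
    ph <- cohort$physiology[cohort$physiology$participant == r$participant &
                              cohort$physiology$session == r$session, ]
    if (r$timepoint == "predose") {
      dhr <- 0; deq <- ph$deq1[ph$time_min == 0][1]; cond <- "predose"
    } else {
      fl <- algorithm_flag(ph, r$timepoint)
      dhr <- attr(fl, "dHR"); deq <- attr(fl, "deq_feel")
      imp <- labels$impaired[match(paste(r$participant, r$session, r$timepoint),
                                   lkey)]
      cond <- if (r$session == "placebo") "placebo"
              else if (isTRUE(imp)) "THC-impaired" else "THC-not-impaired"
    }
    out[[i]] <- data.frame(participant = r$participant, session = r$session,
                           timepoint = r$timepoint, condition = cond,
                           dhr = dhr, deq_feel = deq,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Per-channel classification importance
#'
#' Trains the random-kernel ridge classifier on one channel's HbO series at
#' a time and reports the mean validation ROC-AUC across inner folds,
#' ordered by montage channel. Channels carrying the impairment signature
#' score above uninformative channels.
#'
#' @param hbo_list List of samples x channels HbO matrices, one per scan
#'   (aligned with `y` and `participant`).
#' @param y Logical per-scan class.
#' @param participant Participant id per scan.
#' @param plan A [make_fold_plan()].
#' @param n_kernels Kernels per single-channel bank.
#' @param outer_folds Outer folds over which to average (default: all).
#' @param seed Seed for the kernel banks.
#' @return Numeric vector of mean validation AUC, one per channel.
#' @export
channel_importance <- function(hbo_list, y, participant, plan,
                               n_kernels = 200, outer_folds = NULL,
                               seed = 1L) {
  n_channels <- ncol(hbo_list[[1]])
  len <- nrow(hbo_list[[1]])
  if (is.null(outer_folds)) outer_folds <- seq_len(plan$n_outer)
  out <- numeric(n_channels)
  for (ch in seq_len(n_channels)) {
    bank <- sample_kernels(n_kernels, len, 1L, seed = seed)
    feats <- t(vapply(hbo_list, function(m)
      kernel_transform(m[, ch, drop = FALSE], bank),
      numeric(2L * n_kernels)))
    aucs <- c()
    for (f in outer_folds) {
      inner_map <- plan$inner[[f]]
      pool <- names(inner_map)
      for (k in seq_len(plan$n_inner)) {
        val_p <- pool[inner_map[pool] == k]
        trn_p <- setdiff(pool, val_p)
        tr <- which(participant %in% trn_p)
        va <- which(participant %in% val_p)
        if (length(unique(y[tr])) < 2L || length(unique(y[va])) < 2L) next
        m <- fit_ridge_head(feats[tr, , drop = FALSE], y[tr])
        s <- predict(m, feats[va, , drop = FALSE])
        aucs <- c(aucs, roc_auc_trapezoid(y[va], s))
      }
    }
    out[ch] <- mean(aucs)
  }
  names(out) <- sprintf("ch%02d", seq_len(n_channels))
  out
}
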