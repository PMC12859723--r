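# Small cohort configuration for fast tests; override any field via ...
tiny_config <- function(...) {
  args <- list(n_participants = 6, scan_minutes = 1, scan_types = "resting",
               artifact_prob = 0, instrument_noise_sd = 0, seed = 42)
  user <- list(...)
  args[names(user)] <- user
  do.call(cohort_config, args)
}

# Independent brute-force oracle for the dilated-convolution features:
# plain nested loops, no shared code with the compiled path.
naive_kernel_features <- function(x, ker) {
  n <- nrow(x)
  klen <- length(ker$weights)
  span <- (klen - 1) * ker$dilation
  pad <- if (ker$padding) span %/% 2 else 0
  pos <- (-pad):(n - 1 + pad - span)
  vals <- vapply(pos, function(t0) {
    s <- ker$bias
    for (c in ker$channels) {
      for (j in seq_len(klen)) {
        idx <- t0 + (j - 1) * ker$dilation
        if (idx >= 0 && idx < n) s <- s + ker$weights[j] * x[idx + 1, c]
      }
    }
    s
  }, numeric(1))
  c(ppv = mean(vals > 0), max = max(vals))
}

# Pairwise-concordance (Mann-Whitney) AUC oracle, ties counted 1/2.
auc_concordance <- function(truth, scores) {
  pos <- scores[truth]
  neg <- scores[!truth]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Exhaustive monotone-step-function oracle for isotonic regression:
# enumerate all contiguous partitions of the (tie-aggregated) points, fit
# block means, keep monotone fits, return the minimum weighted SSE.
isotonic_bruteforce_sse <- function(scores, labels) {
  o <- order(scores)
  x <- scores[o]; y <- as.numeric(labels[o])
  ux <- unique(x)
  g <- match(x, ux)
  w <- as.numeric(tapply(rep(1, length(x)), g, sum))
  ybar <- as.numeric(tapply(y, g, mean))
  # SSE of raw points about their tie-group means is fixed; add block SSE
  base_sse <- sum((y - ybar[g])^2)
  m <- length(ux)
  best <- Inf
  for (mask in 0:(2^(m - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(m - 2))) > 0)
    bounds <- c(0, cuts, m)
    fit <- numeric(m)
    ok <- TRUE
    prev <- -Inf
    for (b in seq_len(length(bounds) - 1)) {
      idx <- (bounds[b] + 1):bounds[b + 1]
      mu <- sum(w[idx] * ybar[idx]) / sum(w[idx])
      if (mu < prev) { ok <- FALSE; break }
      fit[idx] <- mu
      prev <- mu
    }
    if (!ok) next
    sse <- base_sse + sum(w * (ybar - fit)^2)
    if (sse < best) best <- sse
  }
  best
}

# Confusion-matrix metric oracle by direct counting.
metrics_bruteforce <- function(truth, pred) {
  tp <- sum(truth & pred); fp <- sum(!truth & pred)
  tn <- sum(!truth & !pred); fn <- sum(truth & !pred)
  list(
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    accuracy = (tp + tn) / length(truth),
    false_positive_rate = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
    f1 = if (tp + fp > 0 && tp + fn > 0) {
      p <- tp / (tp + fp); r <- tp / (tp + fn)
      if (p + r > 0) 2 * p * r / (p + r) else 0
    } else NA_real_
  )
}

# Minimal hand-built trained submodel scoring a single feature linearly.
identity_submodel <- function() {
  structure(list(kind = "ridge", mu = 0, s = 1, w = 1, active = 1L,
                 n_features = 1L),
            class = c("ridge_head", "trained_submodel"))
}

# Isotonic map that outputs a constant probability.
constant_isotonic <- function(p) {
  structure(list(x = c(0, 1), y = c(p, p)), class = "isotonic_fit")
}

# Feature-level synthetic cohort (no fNIRS generation) for fast CV tests.
simulate_feature_cohort <- function(n_participants = 30, scans_each = 4,
                                    signal = 2, p_imp = 0.5, seed = 1) {
  set.seed(seed)
  ids <- sprintf("P%02d", seq_len(n_participants))
  ever <- runif(n_participants) < p_imp
  participant <- rep(ids, each = scans_each)
  y <- as.logical(rep(ever, each = scans_each) &
                    (seq_len(n_participants * scans_each) %% scans_each < 2))
  x <- cbind(ifelse(y, signal, 0) + rnorm(length(y)),
             matrix(rnorm(length(y) * 9), ncol = 9))
  list(x = x, y = y, participant = participant,
       ever = tapply(y, participant, any)[ids])
}
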