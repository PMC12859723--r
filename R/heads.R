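# Internal ridge solve on standardized features; dual form when p > n.
ridge_solve <- function(xs, y, lambda) {
  n <- nrow(xs); p <- ncol(xs)
  if (p > n) {
    k <- tcrossprod(xs)
    alpha <- solve(k + diag(lambda, n), y)
    drop(crossprod(xs, alpha))
  } else {
    drop(solve(crossprod(xs) + diag(lambda, p), crossprod(xs, y)))
  }
}

#' Fit a ridge-regularized linear scoring head
#'
#' Closed-form ridge regression on standardized features with class-balanced
#' target encoding (positives mapped to the negative-class proportion,
#' negatives to minus the positive-class proportion, so the two classes pull
#' with equal total weight). The penalty is chosen from `lambda_grid` by the
#' exact leave-one-out (PRESS) score computed from a single SVD. The raw
#' score is the unbounded linear response; its sign is the class boundary.
#'
#' @param x Feature matrix (rows = scans).
#' @param y Logical labels (`TRUE` = impaired).
#' @param lambda_grid Candidate ridge penalties.
#' @return Object of class `c("ridge_head", "trained_submodel")` with
#'   `predict()` support; stores centers/scales, weights, the selected
#'   lambda and the training scores.
#' @examples
#' x <- matrix(rnorm(60), 30, 2); y <- x[, 1] + rnorm(30, 0, .1) > 0
#' fit <- fit_ridge_head(x, y)
#' head(predict(fit, x))
#' @export
fit_ridge_head <- function(x, y, lambda_grid = 10^seq(-3, 3, length.out = 10)) {
  x <- as.matrix(x); y <- as.logical(y)
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class", call. = FALSE)
  n <- nrow(x)
  mu <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, s, "/")
  n_pos <- sum(y)
  yt <- ifelse(y, (n - n_pos) / n, -n_pos / n)

  sv <- svd(xs)
  uy <- crossprod(sv$u, yt)
  press <- vapply(lambda_grid, function(lam) {
    shrink <- sv$d^2 / (sv$d^2 + lam)
    fitted <- sv$u %*% (shrink * uy)
    h <- rowSums(sweep(sv$u^2, 2, shrink, "*"))
    mean(((yt - fitted) / pmax(1e-12, 1 - h))^2)
  }, numeric(1))
  lambda <- lambda_grid[which.min(press)]
  w <- drop(sv$v %*% ((sv$d / (sv$d^2 + lambda)) * uy))

  fit <- structure(list(
    kind = "ridge", mu = mu, s = s, w = w, lambda = lambda,
    active = seq_len(ncol(x)), n_features = ncol(x),
    encoding = c(pos = (n - n_pos) / n, neg = -n_pos / n)
  ), class = c("ridge_head", "trained_submodel"))
  fit$training_scores <- predict(fit, x)
  fit
}

#' Score new scans with a trained head
#'
#' @param object A `trained_submodel` (ridge or logistic head).
#' @param x Feature matrix with the same columns the head was trained on.
#' @param ... Unused.
#' @return Numeric raw scores (linear response for ridge, log-odds for the
#'   logistic head); larger means more impaired-like.
#' @export
predict.trained_submodel <- function(object, x, ...) {
  x <- as.matrix(x)
  a <- object$active
  xs <- sweep(sweep(x[, a, drop = FALSE], 2, object$mu[a]), 2, object$s[a], "/")
  drop(xs %*% object$w) + if (!is.null(object$intercept)) object$intercept else 0
}

#' @export
coef.trained_submodel <- function(object, ...) {
  # weights on the original feature scale, plus the implied intercept
  w <- object$w / object$s[object$active]
  b <- -sum(w * object$mu[object$active]) +
    if (!is.null(object$intercept)) object$intercept else 0
  out <- c(`(Intercept)` = b, w)
  names(out)[-1] <- if (!is.null(names(object$mu)))
    names(object$mu)[object$active] else paste0("f", object$active)
  out
}

#' @export
print.trained_submodel <- function(x, ...) {
  cat(sprintf("%s head: %d/%d active features%s\n",
              x$kind, length(x$active), x$n_features,
              if (!is.null(x$lambda)) sprintf(", lambda = %.4g", x$lambda) else ""))
  invisible(x)
}

#' Sequential feature detachment
#'
#' Iteratively prunes a trained ridge head: at each step the fraction
#' `prune_fraction` of active features with the smallest absolute
#' standardized weight (|weight| x feature SD) is removed, the head is refit
#' at the stored penalty, and validation accuracy (sign rule) is recorded.
#' Pruning proceeds until a single feature remains; the returned model uses
#' the mask from the step maximizing
#' `validation accuracy - trade_off * fraction retained`. With
#' `trade_off = 0` the selected step is the accuracy argmax (first maximum,
#' i.e. the largest feature set among ties).
#'
#' @param model A fitted [fit_ridge_head()].
#' @param x,y Training features / logical labels.
#' @param x_val,y_val Validation features / labels used to score each step.
#' @param prune_fraction Fraction of active features removed per step.
#' @param trade_off Retained-fraction penalty `c` in the selection rule.
#' @return The refit model with a pruned `active` mask and a `detach`
#'   element (per-step record and selected step).
#' @examples
#' x <- matrix(rnorm(400), 50, 8); y <- x[, 1] > 0
#' m <- fit_ridge_head(x, y)
#' m2 <- sequential_detach(m, x, y, x, y, prune_fraction = 0.25)
#' @export
sequential_detach <- function(model, x, y, x_val, y_val,
                              prune_fraction = 0.05, trade_off = 0.1) {
  stopifnot(inherits(model, "ridge_head"))
  x <- as.matrix(x); x_val <- as.matrix(x_val)
  y <- as.logical(y); y_val <- as.logical(y_val)
  p_total <- model$n_features
  lambda <- model$lambda

  refit <- function(active) {
    m2 <- model
    m2$active <- active
    xs <- sweep(sweep(x[, active, drop = FALSE], 2, model$mu[active]),
                2, model$s[active], "/")
    n <- nrow(x); n_pos <- sum(y)
    yt <- ifelse(y, (n - n_pos) / n, -n_pos / n)
    m2$w <- ridge_solve(xs, yt, lambda)
    m2
  }
  val_acc <- function(m) mean((predict(m, x_val) > 0) == y_val)

  active <- model$active
  cur <- model
  steps <- data.frame(step = 0L, n_active = length(active),
                      val_accuracy = val_acc(cur))
  masks <- list(active)
  step <- 0L
  while (length(active) > 1L) {
    n_drop <- max(1L, floor(prune_fraction * length(active)))
    n_drop <- min(n_drop, length(active) - 1L)
    imp <- abs(cur$w)  # standardized features: |w| already includes SD
    active <- active[order(imp)][-seq_len(n_drop)]
    active <- sort(active)
    cur <- refit(active)
    step <- step + 1L
    steps <- rbind(steps, data.frame(step = step, n_active = length(active),
                                     val_accuracy = val_acc(cur)))
    masks[[step + 1L]] <- active
  }
  crit <- steps$val_accuracy - trade_off * steps$n_active / p_total
  sel <- which.max(crit)
  out <- refit(masks[[sel]])
  out$detach <- list(steps = steps, selected_step = steps$step[sel],
                     masks = masks, prune_fraction = prune_fraction,
                     trade_off = trade_off)
  out$training_scores <- predict(out, x)
  out
}

#' Fit a cross-entropy (logistic) linear head
#'
#' L2-penalized logistic regression on standardized features, fit by
#' iteratively reweighted least squares from a zero initialization (fully
#' deterministic). The intercept is unpenalized. The raw score is the
#' log-odds of impairment.
#'
#' @param x Feature matrix.
#' @param y Logical labels.
#' @param lambda L2 penalty on the weights.
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the max absolute gradient.
#' @return Object of class `c("logistic_head", "trained_submodel")`.
#' @examples
#' x <- matrix(rnorm(80), 40, 2); y <- x[, 1] > 0
#' fit <- fit_crossentropy_head(x, y)
#' @export
fit_crossentropy_head <- function(x, y, lambda = 1, max_iter = 100,
                                  tol = 1e-8) {
  x <- as.matrix(x); y <- as.logical(y)
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class", call. = FALSE)
  mu <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, s, "/")
  n <- nrow(xs); p <- ncol(xs)
  beta <- numeric(p); b0 <- 0
  yn <- as.numeric(y)
  for (it in seq_len(max_iter)) {
    eta <- drop(xs %*% beta) + b0
    prob <- 1 / (1 + exp(-eta))
    g_w <- drop(crossprod(xs, yn - prob)) - lambda * beta
    g_0 <- sum(yn - prob)
    if (max(abs(c(g_w, g_0))) < tol) break
    wts <- pmax(1e-10, prob * (1 - prob))
    xa <- cbind(1, xs)
    hess <- crossprod(xa * wts, xa) + diag(c(0, rep(lambda, p)))
    delta <- solve(hess, c(g_0, g_w))
    b0 <- b0 + delta[1]
    beta <- beta + delta[-1]
    if (it == max_iter)
      stop(sprintf(
        "logistic head failed to converge in %d iterations (max |grad| = %.3g)",
        max_iter, max(abs(c(g_w, g_0)))), call. = FALSE)
  }
  fit <- structure(list(
    kind = "logistic", mu = mu, s = s, w = beta, intercept = b0,
    lambda = lambda, active = seq_len(p), n_features = p
  ), class = c("logistic_head", "trained_submodel"))
  fit$training_scores <- predict(fit, x)
  fit
}

#' Parallel feature extraction (4 submodel blocks)
#'
#' Computes the concatenated feature blocks of the parallel-extraction
#' classifier for one scan: (1) per-channel moments (mean, SD, skewness,
#' excess kurtosis) of HbO and HbR; (2) per-channel band powers (mean
#' periodogram density in 0.01-0.04, 0.04-0.08 and 0.08-0.15 Hz) of HbO and
#' HbR; (3) the upper triangle of the HbO cross-channel correlation matrix
#' (entries involving a zero-variance channel are set to 0 by convention);
#' (4) a small random-kernel pool. Block boundaries are recorded in the
#' `"blocks"` attribute.
#'
#' @param hemo A `hemo_series` (or list with `hbo`/`hbr` matrices).
#' @param sample_rate Hz.
#' @param bands 2 x nb matrix of band edges in Hz (columns = bands).
#' @param pool_kernels Size of the kernel pool block.
#' @param pool_seed Seed for the pool bank (fixed so features align across
#'   scans).
#' @return Named numeric feature vector with attribute `"blocks"`.
#' @examples
#' cfg <- cohort_config(n_participants = 4, scan_minutes = 1,
#'                      scan_types = "resting", seed = 1)
#' coh <- generate_cohort(cfg)
#' hs <- preprocess_scan(coh$scans[[1]], coh$montage, cfg$sample_rate)
#' length(parallel_features(hs, cfg$sample_rate))
#' @export
parallel_features <- function(hemo, sample_rate,
                              bands = rbind(c(0.01, 0.04, 0.08),
                                            c(0.04, 0.08, 0.15)),
                              pool_kernels = 64, pool_seed = 42L) {
  hbo <- hemo$hbo; hbr <- hemo$hbr
  nc <- ncol(hbo)

  moments <- function(m, tag) {
    out <- apply(m, 2, function(col) {
      mu <- mean(col); sdv <- stats::sd(col)
      if (sdv == 0) return(c(mean = mu, sd = 0, skew = 0, kurt = 0))
      z <- (col - mu) / sdv
      c(mean = mu, sd = sdv, skew = mean(z^3), kurt = mean(z^4) - 3)
    })
    v <- as.vector(out)
    names(v) <- paste0(tag, "_ch", rep(seq_len(ncol(m)), each = 4), "_",
                       rep(rownames(out), ncol(m)))
    v
  }
  band_pow <- function(m, tag) {
    n <- nrow(m)
    f <- fft_freqs(n, sample_rate)
    out <- apply(m, 2, function(col) {
      p <- Mod(stats::fft(col - mean(col)))^2 / n
      vapply(seq_len(ncol(bands)), function(b) {
        sel <- abs(f) >= bands[1, b] & abs(f) < bands[2, b]
        if (!any(sel)) 0 else mean(p[sel])
      }, numeric(1))
    })
    v <- as.vector(out)
    names(v) <- paste0(tag, "_ch", rep(seq_len(ncol(m)), each = ncol(bands)),
                       "_band", rep(seq_len(ncol(bands)), ncol(m)))
    v
  }
  b1 <- c(moments(hbo, "hbo"), moments(hbr, "hbr"))
  b2 <- c(band_pow(hbo, "hbo"), band_pow(hbr, "hbr"))

  sds <- apply(hbo, 2, stats::sd)
  cm <- suppressWarnings(stats::cor(hbo))
  cm[!is.finite(cm)] <- 0
  cm[sds == 0, ] <- 0
  cm[, sds == 0] <- 0
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  b3 <- cm[upper.tri(cm)]
  names(b3) <- sprintf("cor_ch%d_ch%d", ut[, 1], ut[, 2])

  bank <- sample_kernels(pool_kernels, nrow(hbo), 2L * nc, seed = pool_seed)
  b4 <- kernel_transform(cbind(hbo, hbr), bank)
  names(b4) <- paste0("pool_", names(b4))

  out <- c(b1, b2, b3, b4)
  attr(out, "blocks") <- c(moments = length(b1), band_power = length(b2),
                           correlation = length(b3), kernel_pool = length(b4))
  out
}
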