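test_that("kernel banks are reproducible and structurally valid", {
  b1 <- sample_kernels(1000, 500, 8, seed = 3)
  b2 <- sample_kernels(1000, 500, 8, seed = 3)
  expect_identical(b1, b2)
  expect_length(b1$kernels, 1000)
  for (k in b1$kernels) {
    expect_true(length(k$weights) %in% c(7, 9, 11))
    expect_lt(abs(sum(k$weights)), 1e-12)          # mean-centered
    expect_lte((length(k$weights) - 1) * k$dilation, 499)
    expect_true(all(k$channels %in% 1:8))
    expect_false(anyDuplicated(k$channels) > 0)
  }
  expect_error(sample_kernels(0, 100, 2), "n_kernels")
})

test_that("the kernel transform matches a brute-force convolution oracle", {
  set.seed(14)
  x <- matrix(rnorm(60 * 3), 60, 3)
  bank <- sample_kernels(40, 60, 3, seed = 7)
  feats <- kernel_transform(x, bank)
  for (k in seq_along(bank$kernels)) {
    ref <- naive_kernel_features(x, bank$kernels[[k]])
    expect_lt(abs(feats[2 * k - 1] - ref["ppv"]), 1e-10)
    expect_lt(abs(feats[2 * k] - ref["max"]), 1e-10)
  }
})

test_that("PPV follows the strict positivity convention", {
  pos_kernel <- structure(list(
    kernels = list(list(weights = rep(1, 7), bias = 0, dilation = 1L,
                        padding = FALSE, channels = 1L)),
    n_channels = 1L, series_length = 50L, seed = 0L), class = "kernel_bank")
  f <- kernel_transform(matrix(2, 50, 1), pos_kernel)
  expect_equal(unname(f[1]), 1)   # all-positive sums
  f0 <- kernel_transform(matrix(0, 50, 1), pos_kernel)
  expect_equal(unname(f0[1]), 0)  # zeros with zero bias: strict ">"
  expect_error(kernel_transform(matrix(1, 3, 1), pos_kernel), "shorter")
})

test_that("ridge head degenerates properly and separates separable data", {
  set.seed(15)
  x <- cbind(c(rnorm(20, 2), rnorm(20, -2)), rnorm(40))
  y <- rep(c(TRUE, FALSE), each = 20)
  # huge penalty: weights -> 0, scores -> constant
  m_inf <- fit_ridge_head(x, y, lambda_grid = 1e12)
  expect_lt(max(abs(m_inf$w)), 1e-6)
  expect_lt(diff(range(m_inf$training_scores)), 1e-6)
  # separable data at small penalty: perfect training accuracy
  m <- fit_ridge_head(x, y, lambda_grid = 1e-3)
  expect_equal(mean((m$training_scores > 0) == y), 1)
  expect_error(fit_ridge_head(x, rep(TRUE, 40)), "single class")
})

test_that("ridge treats duplicated feature columns symmetrically", {
  set.seed(16)
  x <- matrix(rnorm(60), 30, 2)
  y <- x[, 1] + 0.3 * rnorm(30) > 0
  xd <- cbind(x, x)
  m <- fit_ridge_head(xd, y, lambda_grid = 1)
  # weights split equally between the two copies
  expect_lt(max(abs(m$w[1:2] - m$w[3:4])), 1e-8)
  # swapping the duplicate blocks leaves predictions invariant
  m2 <- fit_ridge_head(cbind(x, x)[, c(3, 4, 1, 2)], y, lambda_grid = 1)
  expect_lt(max(abs(predict(m, xd) - predict(m2, xd[, c(3, 4, 1, 2)]))), 1e-8)
})

test_that("sequential detachment prunes noise before informative features", {
  frac_noise_first <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 80
    y <- rep(c(TRUE, FALSE), each = n / 2)
    info <- sapply(1:3, function(i) ifelse(y, 1, -1) + rnorm(n, 0, 0.3))
    noise <- matrix(rnorm(n * 17), n, 17)
    x <- cbind(info, noise)
    m <- fit_ridge_head(x, y, lambda_grid = 1)
    d <- sequential_detach(m, x, y, x, y, prune_fraction = 0.04)
    # removal order from consecutive per-step masks (one feature per step)
    masks <- d$detach$masks
    order_removed <- unlist(lapply(seq_along(masks)[-1], function(i)
      setdiff(masks[[i - 1]], masks[[i]])))
    first_info <- match(TRUE, order_removed <= 3)
    if (is.na(first_info)) first_info <- length(order_removed) + 1L
    # fraction of the 17 noise features pruned before any informative one
    sum(order_removed[seq_len(first_info - 1)] > 3) / 17
  }, numeric(1))
  # across seeds, pruning overwhelmingly removes noise features
  expect_gte(mean(frac_noise_first), 0.8)
})

test_that("detachment step arithmetic and selection rule behave as specified", {
  set.seed(18)
  x <- matrix(rnorm(40 * 5), 40, 5)
  y <- x[, 1] > 0
  m <- fit_ridge_head(x, y, lambda_grid = 1)
  d <- sequential_detach(m, x, y, x, y, prune_fraction = 0.2)
  # one feature removed per step on 5 features: exactly 4 steps to the floor
  expect_equal(max(d$detach$steps$step), 4)
  expect_equal(min(d$detach$steps$n_active), 1)
  expect_true(all(diff(d$detach$steps$n_active) < 0))  # monotone shrinkage

  # trade_off = 0 selects the accuracy argmax
  d0 <- sequential_detach(m, x, y, x, y, prune_fraction = 0.2, trade_off = 0)
  st <- d0$detach$steps
  expect_equal(d0$detach$selected_step, st$step[which.max(st$val_accuracy)])
})

test_that("parallel features have the documented block structure", {
  set.seed(19)
  hemo <- structure(list(hbo = matrix(rnorm(400 * 20), 400, 20),
                         hbr = matrix(rnorm(400 * 20), 400, 20)),
                    class = "hemo_series")
  f <- parallel_features(hemo, 10)
  blocks <- attr(f, "blocks")
  expect_equal(unname(blocks["moments"]), 20 * 2 * 4)
  expect_equal(unname(blocks["band_power"]), 20 * 2 * 3)
  expect_equal(unname(blocks["correlation"]), 20 * 19 / 2)
  expect_equal(unname(blocks["kernel_pool"]), 2 * 64)
  expect_length(f, sum(blocks))

  # zero-variance channel: correlation entries defined as 0
  hemo$hbo[, 4] <- 1
  f2 <- parallel_features(hemo, 10)
  cor_block <- f2[grepl("^cor_", names(f2))]
  expect_true(all(cor_block[grepl("ch4($|_)", names(cor_block))] == 0))
})

test_that("white-noise scans have flat band powers after bandwidth normalization", {
  set.seed(20)
  hemo <- structure(list(hbo = matrix(rnorm(5000 * 10), 5000, 10),
                         hbr = matrix(rnorm(5000 * 10), 5000, 10)),
                    class = "hemo_series")
  f <- parallel_features(hemo, 10)
  bands <- sapply(1:3, function(b)
    mean(f[grepl(sprintf("^hbo_ch\\d+_band%d$", b), names(f))]))
  expect_lt(max(bands) / min(bands), 1.35)
})

test_that("cross-entropy head is symmetric, penalized and at its optimum", {
  set.seed(21)
  x_half <- matrix(rnorm(40), 20, 2) + 2
  x <- rbind(x_half, -x_half)          # exactly symmetric design
  y <- rep(c(TRUE, FALSE), each = 20)
  m <- fit_crossentropy_head(x, y, lambda = 1)
  expect_lt(abs(m$intercept), 1e-8)

  # separable data: the penalty keeps weights finite
  xs <- cbind(c(rnorm(15, 3), rnorm(15, -3)))
  ys <- rep(c(TRUE, FALSE), each = 15)
  ms <- fit_crossentropy_head(xs, ys, lambda = 0.5)
  expect_true(all(is.finite(ms$w)))
  expect_lt(max(abs(ms$w)), 50)

  # numeric gradient of the penalized log-likelihood vanishes at the fit
  xstd <- sweep(sweep(x, 2, m$mu), 2, m$s, "/")
  nll <- function(par) {
    eta <- drop(xstd %*% par[-1]) + par[1]
    -sum(y * eta - log1p(exp(eta))) + 0.5 * 1 * sum(par[-1]^2)
  }
  par0 <- c(m$intercept, m$w)
  g <- numeric(length(par0))
  h <- 1e-6
  for (j in seq_along(par0)) {
    e <- rep(0, length(par0)); e[j] <- h
    g[j] <- (nll(par0 + e) - nll(par0 - e)) / (2 * h)
  }
  expect_lt(max(abs(g)), 1e-4)
  expect_error(fit_crossentropy_head(x, rep(FALSE, 40)), "single class")
})
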