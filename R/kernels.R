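#' Sample a random convolutional kernel bank
#'
#' Draws kernels following the random convolutional-kernel transform
#' convention: lengths sampled uniformly from {7, 9, 11}, weights standard
#' normal then mean-centered, bias uniform on (-1, 1), dilation log-uniform
#' so that the dilated span fits the series, padding on/off with equal
#' probability, and a random channel subset (size log-uniform in the number
#' of channels) to which the shared weights are applied and summed.
#'
#' @param n_kernels Number of kernels (>= 1).
#' @param series_length Length (samples) of the series the bank will see.
#' @param n_channels Number of input channels.
#' @param seed Integer seed; the bank is reproducible from it.
#' @param lengths Candidate kernel lengths.
#' @return Object of class `kernel_bank`: list of kernels (each with
#'   `weights`, `bias`, `dilation`, `padding`, `channels`) plus metadata.
#' @examples
#' bank <- sample_kernels(10, 600, 4, seed = 1)
#' length(bank$kernels)
#' @export
sample_kernels <- function(n_kernels, series_length, n_channels, seed = 1L,
                           lengths = c(7L, 9L, 11L)) {
  if (n_kernels < 1) stop("n_kernels must be >= 1", call. = FALSE)
  if (series_length < max(lengths))
    stop("series_length shorter than the smallest kernel", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  kernels <- vector("list", n_kernels)
  for (k in seq_len(n_kernels)) {
    len <- sample(lengths, 1)
    w <- stats::rnorm(len)
    w <- w - mean(w)
    max_exp <- log2((series_length - 1) / (len - 1))
    dil <- as.integer(2^stats::runif(1, 0, max(0, max_exp)))
    dil <- max(1L, min(dil, as.integer((series_length - 1) / (len - 1))))
    nch <- max(1L, min(n_channels,
                       as.integer(2^stats::runif(1, 0, log2(n_channels + 1)))))
    kernels[[k]] <- list(
      weights = w,
      bias = stats::runif(1, -1, 1),
      dilation = dil,
      padding = stats::runif(1) < 0.5,
      channels = sort(sample.int(n_channels, nch))
    )
  }
  structure(list(kernels = kernels, n_channels = n_channels,
                 series_length = series_length, seed = as.integer(seed)),
            class = "kernel_bank")
}

#' @export
print.kernel_bank <- function(x, ...) {
  cat(sprintf("Random kernel bank: %d kernels, %d channels, series length %d, seed %d\n",
              length(x$kernels), x$n_channels, x$series_length, x$seed))
  invisible(x)
}

#' Random-kernel feature transform
#'
#' Applies every kernel in the bank to a multichannel series via dilated
#' convolution (shared weights summed over the kernel's channel subset) and
#' emits two features per kernel: PPV, the fraction of convolution outputs
#' strictly greater than zero, and the maximum output.
#'
#' @param x Samples x channels numeric matrix, or a `hemo_series` (in which
#'   case HbO and HbR channels are concatenated column-wise).
#' @param bank A [sample_kernels()] bank.
#' @return Numeric feature vector of length `2 * n_kernels`, named
#'   `k<i>_ppv` / `k<i>_max`.
#' @examples
#' bank <- sample_kernels(5, 100, 2, seed = 1)
#' kernel_transform(matrix(rnorm(200), 100, 2), bank)
#' @export
kernel_transform <- function(x, bank) {
  x <- as_series_matrix(x)
  if (ncol(x) != bank$n_channels)
    stop(sprintf("bank expects %d channels, got %d", bank$n_channels, ncol(x)),
         call. = FALSE)
  span <- max(vapply(bank$kernels, function(k)
    (length(k$weights) - 1L) * k$dilation + 1L, integer(1)))
  if (nrow(x) < span)
    stop(sprintf("series length %d shorter than maximum kernel span %d",
                 nrow(x), span), call. = FALSE)
  feats <- kernel_transform_cpp(x, bank$kernels)
  names(feats) <- as.vector(rbind(
    sprintf("k%d_ppv", seq_along(bank$kernels)),
    sprintf("k%d_max", seq_along(bank$kernels))))
  feats
}

as_series_matrix <- function(x) {
  if (inherits(x, "hemo_series")) x <- cbind(x$hbo, x$hbr)
  as.matrix(x)
}
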