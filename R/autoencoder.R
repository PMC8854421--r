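#' Autoencoder training specification
#'
#' Architecture and optimization settings for the denoising autoencoder: a
#' dense encoder mapping the input through a rectified hidden layer to a
#' linear bottleneck (default width 32, the recommended latent size for
#' expression denoising), mirrored by the decoder, trained by
#' backpropagation on the squared reconstruction error with full-batch
#' Adam. Biases start at zero and weights at scaled Gaussian values drawn
#' from the seed, so training is fully deterministic.
#'
#' @param bottleneck Latent width (default 32).
#' @param hidden Hidden layer width of encoder and decoder (default 64).
#' @param epochs Training epochs (default 300).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed Integer seed for the weight initialization.
#' @return A list of class `autoencoder_spec`.
#' @export
autoencoder_spec <- function(bottleneck = 32, hidden = 64, epochs = 300,
                             learning_rate = 1e-3, seed = 1L) {
  stopifnot(bottleneck >= 1, hidden >= 1, epochs >= 1, learning_rate > 0)
  structure(list(bottleneck = as.integer(bottleneck),
                 hidden = as.integer(hidden),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "autoencoder_spec")
}

#' Denoise an expression matrix with a dense autoencoder
#'
#' Trains `encoder(x) -> z -> decoder(z) -> x'` on the rows of `m`
#' (observations x features), minimizing the mean squared reconstruction
#' error, and returns the reconstruction. Because the bottleneck is much
#' narrower than the feature space, the network keeps the dominant
#' covarying structure and discards feature-wise noise.
#'
#' @param m Numeric matrix, observations (spots) x features (genes),
#'   at least 50 observations, no missing values.
#' @param spec An [autoencoder_spec()].
#' @return The reconstructed matrix (same shape as `m`), with the per-epoch
#'   training loss attached as attribute `loss`.
#' @export
autoencoder_denoise <- function(m, spec = autoencoder_spec()) {
  stopifnot(inherits(spec, "autoencoder_spec"))
  x <- as.matrix(m)
  if (anyNA(x)) stop("input contains NA")
  if (nrow(x) < 50) stop("need at least 50 observations")
  n <- nrow(x)
  d <- ncol(x)
  h <- spec$hidden
  p <- spec$bottleneck

  set.seed(spec$seed)
  init <- function(nin, nout) matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  W <- list(init(d, h), init(h, p), init(p, h), init(h, d))
  b <- list(numeric(h), numeric(p), numeric(h), numeric(d))

  adam_m <- lapply(c(W, b), function(z) z * 0)
  adam_v <- adam_m
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- spec$learning_rate
  relu <- function(z) pmax(z, 0)
  loss_hist <- numeric(spec$epochs)

  for (epoch in seq_len(spec$epochs)) {
    a1 <- relu(sweep(x %*% W[[1]], 2, b[[1]], `+`))
    z  <- sweep(a1 %*% W[[2]], 2, b[[2]], `+`)
    a3 <- relu(sweep(z %*% W[[3]], 2, b[[3]], `+`))
    xr <- sweep(a3 %*% W[[4]], 2, b[[4]], `+`)
    err <- xr - x
    loss <- mean(err^2)
    if (!is.finite(loss)) stop("training loss diverged at epoch ", epoch,
                               " (loss = ", loss, "); lower the learning rate")
    loss_hist[epoch] <- loss

    g_xr <- 2 * err / (n * d)
    g_W4 <- crossprod(a3, g_xr); g_b4 <- colSums(g_xr)
    g_a3 <- tcrossprod(g_xr, W[[4]]) * (a3 > 0)
    g_W3 <- crossprod(z, g_a3);  g_b3 <- colSums(g_a3)
    g_z  <- tcrossprod(g_a3, W[[3]])
    g_W2 <- crossprod(a1, g_z);  g_b2 <- colSums(g_z)
    g_a1 <- tcrossprod(g_z, W[[2]]) * (a1 > 0)
    g_W1 <- crossprod(x, g_a1);  g_b1 <- colSums(g_a1)

    grads <- list(g_W1, g_W2, g_W3, g_W4, g_b1, g_b2, g_b3, g_b4)
    params <- c(W, b)
    for (k in seq_along(params)) {
      adam_m[[k]] <- beta1 * adam_m[[k]] + (1 - beta1) * grads[[k]]
      adam_v[[k]] <- beta2 * adam_v[[k]] + (1 - beta2) * grads[[k]]^2
      mhat <- adam_m[[k]] / (1 - beta1^epoch)
      vhat <- adam_v[[k]] / (1 - beta2^epoch)
      params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
    }
    W <- params[1:4]
    b <- params[5:8]
  }

  a1 <- relu(sweep(x %*% W[[1]], 2, b[[1]], `+`))
  z  <- sweep(a1 %*% W[[2]], 2, b[[2]], `+`)
  a3 <- relu(sweep(z %*% W[[3]], 2, b[[3]], `+`))
  xr <- sweep(a3 %*% W[[4]], 2, b[[4]], `+`)
  dimnames(xr) <- dimnames(x)
  attr(xr, "loss") <- loss_hist
  xr
}
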