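#' Single-hidden-layer autoencoder
#'
#' Trains a fully-connected autoencoder `input(p) -> hidden(latent, sigmoid)
#' -> output(p, sigmoid)` by mini-batch backpropagation with the Adam update,
#' minimizing the mean squared reconstruction error
#' `loss = mean((X - X_hat)^2)` over all matrix entries. Inputs are expected
#' to lie in `[0, 1]` (binary associations, complement scores and
#' similarities all do), so the sigmoid output range needs no rescaling.
#' Training is fully deterministic for a fixed `seed` (weight initialization
#' and batch shuffling both derive from it).
#'
#' @param x numeric matrix, samples in rows (n x p), all entries finite.
#' @param latent_dim hidden-layer width; must be smaller than `ncol(x)`.
#' @param epochs number of passes over the data (default 200).
#' @param batch_size mini-batch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed integer seed controlling initialization and shuffling.
#' @return an object of class `gclda_autoencoder`: weight matrices `W1`,
#'   `b1`, `W2`, `b2`, the training settings, and `loss_history`, the
#'   full-data MSE recorded after every epoch (element 0 is the
#'   pre-training loss).
#' @seealso [encode()] to apply the trained encoder.
#' @export
train_autoencoder <- function(x, latent_dim, epochs = 200, batch_size = 32,
                              learning_rate = 1e-3, seed = 1) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (!all(is.finite(x))) stop("features must be finite")
  n <- nrow(x); p <- ncol(x)
  if (latent_dim >= p)
    stop(sprintf("latent_dim (%d) must be smaller than the input width (%d)",
                 latent_dim, p))
  stopifnot(latent_dim >= 1, n >= 1, epochs >= 1, batch_size >= 1)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  r1 <- sqrt(6 / (p + latent_dim))
  W1 <- matrix(stats::runif(p * latent_dim, -r1, r1), p, latent_dim)
  b1 <- numeric(latent_dim)
  W2 <- matrix(stats::runif(latent_dim * p, -r1, r1), latent_dim, p)
  b2 <- numeric(p)

  # Adam state
  adam <- lapply(list(W1, b1, W2, b2), function(w) list(m = w * 0, v = w * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t <- 0L

  full_mse <- function() {
    h <- .sigmoid(sweep(x %*% W1, 2, b1, "+"))
    out <- .sigmoid(sweep(h %*% W2, 2, b2, "+"))
    mean((x - out)^2)
  }
  loss_history <- numeric(epochs + 1L)
  loss_history[1L] <- full_mse()

  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      nb <- length(idx)

      h <- .sigmoid(sweep(xb %*% W1, 2, b1, "+"))
      out <- .sigmoid(sweep(h %*% W2, 2, b2, "+"))

      # d loss / d preactivation, loss = mean over nb*p entries
      d_out <- 2 * (out - xb) * out * (1 - out) / (nb * p)
      d_h <- (d_out %*% t(W2)) * h * (1 - h)

      g <- list(t(xb) %*% d_h, colSums(d_h), t(h) %*% d_out, colSums(d_out))
      t <- t + 1L
      upd <- function(w, st, gr) {
        st$m <- beta1 * st$m + (1 - beta1) * gr
        st$v <- beta2 * st$v + (1 - beta2) * gr^2
        mhat <- st$m / (1 - beta1^t)
        vhat <- st$v / (1 - beta2^t)
        list(w = w - learning_rate * mhat / (sqrt(vhat) + eps), st = st)
      }
      u <- upd(W1, adam[[1]], g[[1]]); W1 <- u$w; adam[[1]] <- u$st
      u <- upd(b1, adam[[2]], g[[2]]); b1 <- u$w; adam[[2]] <- u$st
      u <- upd(W2, adam[[3]], g[[3]]); W2 <- u$w; adam[[3]] <- u$st
      u <- upd(b2, adam[[4]], g[[4]]); b2 <- u$w; adam[[4]] <- u$st
    }
    loss_history[epoch + 1L] <- full_mse()
  }

  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 input_dim = p, latent_dim = latent_dim,
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, seed = seed,
                 loss_history = loss_history),
            class = "gclda_autoencoder")
}

#' Encode features with a trained autoencoder
#'
#' Applies the hidden layer of a trained [train_autoencoder()] model to map
#' each row of `x` from the raw width to the latent width. The map is
#' deterministic and row-wise: permuting input rows permutes output rows
#' identically.
#'
#' @param encoder a `gclda_autoencoder`.
#' @param x numeric matrix with `ncol(x) == encoder$input_dim`.
#' @return numeric matrix (n x latent_dim), preserving row names.
#' @export
encode <- function(encoder, x) {
  stopifnot(inherits(encoder, "gclda_autoencoder"), is.matrix(x))
  if (ncol(x) != encoder$input_dim)
    stop(sprintf("feature width %d does not match encoder input_dim %d",
                 ncol(x), encoder$input_dim))
  out <- .sigmoid(sweep(x %*% encoder$W1, 2, encoder$b1, "+"))
  rownames(out) <- rownames(x)
  out
}

#' @export
print.gclda_autoencoder <- function(x, ...) {
  cat(sprintf(
    "<gclda_autoencoder> %d -> %d -> %d, %d epochs, MSE %.3g -> %.3g\n",
    x$input_dim, x$latent_dim, x$input_dim, x$epochs,
    x$loss_history[1L], x$loss_history[length(x$loss_history)]))
  invisible(x)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
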