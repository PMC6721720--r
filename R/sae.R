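# Stacked autoencoder used to compress heterogeneous raw attributes to a
# uniform 64-dimensional space: one ReLU encoder/decoder pair trained by
# Adam on mean squared reconstruction error.

relu <- function(x) pmax(x, 0)

#' Train a rectifier autoencoder
#'
#' Fits `x_hat = g(f(x))` with `f(x) = relu(x W1 + b1)` mapping to `latent`
#' dimensions and `g(h) = relu(h W2 + b2)` mapping back, minimizing mean
#' squared reconstruction error with mini-batch Adam.  All raw node
#' attributes in this package are nonnegative, so the rectified decoder
#' output can reconstruct them.  Deterministic under a fixed seed.
#'
#' @param x Numeric matrix, rows are samples (n >= 2), all entries finite.
#' @param latent Bottleneck width (default 64); at most `ncol(x)`.
#' @param epochs Training epochs (default 100).
#' @param seed Integer seed for initialization and batch shuffling.
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Mini-batch size (default 32).
#' @return An object of class `man_sae` holding the weights, the per-epoch
#'   loss history (`loss[1]` is the pre-training loss) and dimensions.
#' @export
train_sae <- function(x, latent = 64, epochs = 100, seed = 1,
                      learning_rate = 1e-3, batch_size = 32) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite entries in input", call. = FALSE)
  n <- nrow(x); d <- ncol(x)
  if (n < 2) stop("need at least 2 rows", call. = FALSE)
  if (d < latent)
    stop("input dimension (", d, ") below latent dimension (", latent, ")",
         call. = FALSE)
  with_seed(seed, {
    # He initialization suits the rectifier units.
    W1 <- matrix(rnorm(d * latent, sd = sqrt(2 / d)), d, latent)
    b1 <- rep(0.01, latent)
    W2 <- matrix(rnorm(latent * d, sd = sqrt(2 / latent)), latent, d)
    # start decoder outputs at the feature means: keeps the rectified
    # output units in their active regime from the first step
    b2 <- colMeans(x)
    params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    m <- lapply(params, function(p) p * 0)
    v <- lapply(params, function(p) p * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t_step <- 0L

    loss_of <- function(p) {
      h <- relu(sweep(x %*% p$W1, 2, p$b1, `+`))
      xh <- relu(sweep(h %*% p$W2, 2, p$b2, `+`))
      mean((x - xh)^2)
    }
    loss <- numeric(epochs + 1)
    loss[1] <- loss_of(params)

    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      starts <- seq(1, n, by = batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1, n)]
        xb <- x[idx, , drop = FALSE]
        nb <- nrow(xb)
        z1 <- sweep(xb %*% params$W1, 2, params$b1, `+`)
        h <- relu(z1)
        z2 <- sweep(h %*% params$W2, 2, params$b2, `+`)
        xh <- relu(z2)
        d2 <- (2 / (nb * ncol(xb))) * (xh - xb) * (z2 > 0)
        gW2 <- crossprod(h, d2)
        gb2 <- colSums(d2)
        d1 <- (d2 %*% t(params$W2)) * (z1 > 0)
        gW1 <- crossprod(xb, d1)
        gb1 <- colSums(d1)
        grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
        t_step <- t_step + 1L
        for (k in names(params)) {
          m[[k]] <- beta1 * m[[k]] + (1 - beta1) * grads[[k]]
          v[[k]] <- beta2 * v[[k]] + (1 - beta2) * grads[[k]]^2
          mh <- m[[k]] / (1 - beta1^t_step)
          vh <- v[[k]] / (1 - beta2^t_step)
          params[[k]] <- params[[k]] - learning_rate * mh / (sqrt(vh) + eps)
        }
      }
      loss[ep + 1] <- loss_of(params)
    }
    structure(c(params,
                list(loss = loss, input_dim = d, latent = latent,
                     epochs = epochs, seed = seed)),
              class = "man_sae")
  })
}

#' @export
print.man_sae <- function(x, ...) {
  cat("Rectifier autoencoder:", x$input_dim, "->", x$latent, "->",
      x$input_dim, "\n  loss:", signif(x$loss[1], 4), "->",
      signif(x$loss[length(x$loss)], 4), "over", x$epochs, "epochs\n")
  invisible(x)
}

#' Encode or reconstruct through a trained autoencoder
#'
#' @param object A `man_sae`.
#' @param newdata Matrix with `input_dim` columns.
#' @param type `"latent"` (default) for the bottleneck representation,
#'   `"reconstruction"` for the decoded output.
#' @param ... Unused.
#' @return A numeric matrix.
#' @export
predict.man_sae <- function(object, newdata, type = c("latent", "reconstruction"),
                            ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  stopifnot(ncol(newdata) == object$input_dim)
  h <- relu(sweep(newdata %*% object$W1, 2, object$b1, `+`))
  if (type == "latent") return(h)
  relu(sweep(h %*% object$W2, 2, object$b2, `+`))
}
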