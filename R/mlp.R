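# Minimal feed-forward regressor with two ReLU hidden layers, trained
# full-batch with Adam on standardized inputs/targets. Sized for the small
# cohorts this package works with (n in the hundreds, p <= 50), where a
# dedicated deep-learning runtime would be overkill.

mlp_fit <- function(x, y, hidden = c(32L, 16L), epochs = 300L, lr = 0.01,
                    l2 = 1e-4, seed = 1L) {
  x <- as.matrix(x)
  xc <- colMeans(x)
  xs <- apply(x, 2, stats::sd)
  xs[xs == 0] <- 1
  xz <- sweep(sweep(x, 2, xc), 2, xs, "/")
  yc <- mean(y)
  ys <- stats::sd(y)
  if (is.na(ys) || ys == 0) ys <- 1
  yz <- (y - yc) / ys

  sizes <- c(ncol(x), hidden, 1L)
  L <- length(sizes) - 1L
  with_seed(seed, {
    W <- lapply(seq_len(L), function(l) {
      matrix(rnorm(sizes[l] * sizes[l + 1], 0, sqrt(2 / sizes[l])),
             sizes[l], sizes[l + 1])
    })
    b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(bb) bb * 0); vb <- mb
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    n <- nrow(xz)
    for (ep in seq_len(epochs)) {
      # forward
      a <- vector("list", L + 1L)
      a[[1]] <- xz
      for (l in seq_len(L)) {
        z <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], "+")
        a[[l + 1]] <- if (l < L) pmax(z, 0) else z
      }
      pred <- drop(a[[L + 1]])
      # backward (MSE loss)
      delta <- matrix(2 * (pred - yz) / n, ncol = 1)
      for (l in rev(seq_len(L))) {
        gW <- crossprod(a[[l]], delta) + l2 * W[[l]]
        gb <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
        }
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
        mhW <- mW[[l]] / (1 - b1^ep); vhW <- vW[[l]] / (1 - b2^ep)
        mhb <- mb[[l]] / (1 - b1^ep); vhb <- vb[[l]] / (1 - b2^ep)
        W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + eps)
        b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
      }
    }
    structure(list(W = W, b = b, xc = xc, xs = xs, yc = yc, ys = ys, L = L),
              class = "bloom_mlp")
  })
}

mlp_predict <- function(model, x) {
  x <- as.matrix(x)
  a <- sweep(sweep(x, 2, model$xc), 2, model$xs, "/")
  for (l in seq_len(model$L)) {
    z <- sweep(a %*% model$W[[l]], 2, model$b[[l]], "+")
    a <- if (l < model$L) pmax(z, 0) else z
  }
  drop(a) * model$ys + model$yc
}
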