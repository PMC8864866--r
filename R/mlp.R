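# Minimal fully connected network for binary classification: ReLU hidden
# layers, sigmoid output, binary cross-entropy, full-batch Adam, optional
# inverted dropout on hidden activations. Deterministic under a fixed seed
# (single-threaded base-R matrix ops). Shared by the detector's region
# scorer, the per-cell classifier heads and the single-layer ensemble net.

mlp_init <- function(dims, seed) {
  set.seed(seed)
  layers <- list()
  for (i in seq_len(length(dims) - 1L)) {
    fan_in <- dims[i]
    layers[[i]] <- list(
      W = matrix(stats::rnorm(fan_in * dims[i + 1L], 0, sqrt(2 / fan_in)),
        fan_in, dims[i + 1L]
      ),
      b = rep(0, dims[i + 1L])
    )
  }
  list(layers = layers, dims = dims)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_forward <- function(net, X, dropout = 0, training = FALSE) {
  acts <- list(X)
  masks <- list()
  n_layers <- length(net$layers)
  A <- X
  for (i in seq_len(n_layers)) {
    Z <- sweep(A %*% net$layers[[i]]$W, 2, net$layers[[i]]$b, "+")
    if (i < n_layers) {
      A <- pmax(Z, 0)
      if (training && dropout > 0) {
        m <- matrix(stats::runif(length(A)) >= dropout, nrow(A), ncol(A)) /
          (1 - dropout)
        A <- A * m
        masks[[i]] <- m
      }
    } else {
      A <- sigmoid(Z)
    }
    acts[[i + 1L]] <- A
  }
  list(out = A[, 1L], acts = acts, masks = masks)
}

mlp_backward <- function(net, fwd, y) {
  n <- length(y)
  n_layers <- length(net$layers)
  grads <- vector("list", n_layers)
  delta <- matrix(fwd$acts[[n_layers + 1L]][, 1L] - y, ncol = 1L) / n
  for (i in rev(seq_len(n_layers))) {
    A_prev <- fwd$acts[[i]]
    grads[[i]] <- list(
      W = crossprod(A_prev, delta),
      b = colSums(delta)
    )
    if (i > 1L) {
      delta <- delta %*% t(net$layers[[i]]$W)
      act <- fwd$acts[[i]]
      if (length(fwd$masks) >= i - 1L && !is.null(fwd$masks[[i - 1L]])) {
        delta <- delta * fwd$masks[[i - 1L]]
      }
      delta <- delta * (act > 0)
    }
  }
  grads
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Full-batch Adam. Returns the net plus the per-epoch loss trace.
mlp_train <- function(net, X, y, epochs, lr = 0.01, dropout = 0,
                      weight_decay = 0, seed = 1L) {
  set.seed(seed)
  m <- purrr::map(net$layers, function(l) list(W = l$W * 0, b = l$b * 0))
  v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss_trace <- numeric(epochs)
  for (e in seq_len(epochs)) {
    fwd <- mlp_forward(net, X, dropout = dropout, training = TRUE)
    loss_trace[e] <- bce_loss(fwd$out, y)
    grads <- mlp_backward(net, fwd, y)
    for (i in seq_along(net$layers)) {
      gW <- grads[[i]]$W + weight_decay * net$layers[[i]]$W
      m[[i]]$W <- b1 * m[[i]]$W + (1 - b1) * gW
      v[[i]]$W <- b2 * v[[i]]$W + (1 - b2) * gW^2
      m[[i]]$b <- b1 * m[[i]]$b + (1 - b1) * grads[[i]]$b
      v[[i]]$b <- b2 * v[[i]]$b + (1 - b2) * grads[[i]]$b^2
      mhW <- m[[i]]$W / (1 - b1^e); vhW <- v[[i]]$W / (1 - b2^e)
      mhb <- m[[i]]$b / (1 - b1^e); vhb <- v[[i]]$b / (1 - b2^e)
      net$layers[[i]]$W <- net$layers[[i]]$W - lr * mhW / (sqrt(vhW) + eps)
      net$layers[[i]]$b <- net$layers[[i]]$b - lr * mhb / (sqrt(vhb) + eps)
    }
  }
  list(net = net, loss_trace = loss_trace)
}

mlp_predict <- function(net, X) {
  mlp_forward(net, X, training = FALSE)$out
}

# Feature standardization helpers shared by all learned stages.
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-8] <- 1
  list(mu = mu, sd = sd)
}

apply_scaler <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$mu, "-"), 2, scaler$sd, "/")
}
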