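# ---- minimal dense-network machinery -----------------------------------
#
# All models in the package (feature generator F, classifier C, domain
# discriminator D, translation generators G/G', image discriminators Ds/Dt)
# are small fully-connected networks on flattened pixel vectors, trained by
# hand-written backprop with Adam. Sizes are desk-scale by design; every
# forward/backward reduces to a handful of BLAS matrix products.

clamp01_eps <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Initialise a dense multilayer perceptron
#'
#' He-scaled Gaussian weights, zero biases. Uses the current RNG state, so
#' wrap in a seeded context for reproducibility.
#'
#' @param sizes integer vector of layer widths, input first, output last.
#' @param zero_out if `TRUE` the final layer's weights and bias are zero
#'   (used for residual generators that must start at the identity map).
#' @return an object of class `dttl_mlp`.
#' @keywords internal
mlp_init <- function(sizes, zero_out = FALSE) {
  stopifnot(length(sizes) >= 2L)
  n_lay <- length(sizes) - 1L
  W <- vector("list", n_lay)
  b <- vector("list", n_lay)
  for (l in seq_len(n_lay)) {
    fan_in <- sizes[l]
    sd <- sqrt(2 / fan_in)
    W[[l]] <- matrix(stats::rnorm(fan_in * sizes[l + 1L], sd = sd),
                     fan_in, sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  if (zero_out) {
    W[[n_lay]][] <- 0
    b[[n_lay]][] <- 0
  }
  structure(list(W = W, b = b, sizes = sizes), class = "dttl_mlp")
}

# Forward pass. X is n x p. Hidden activations are ReLU; the raw output
# (pre-activation) is returned — callers apply softmax/sigmoid themselves so
# that loss gradients can be fused analytically.
# dropout: keep-probability complement applied to hidden layers when
# train = TRUE (inverted dropout; draws from the current RNG).
add_bias <- function(M, b) M + rep(b, each = nrow(M))

mlp_forward <- function(net, X, dropout = 0, train = FALSE) {
  n_lay <- length(net$W)
  acts <- vector("list", n_lay + 1L)
  masks <- vector("list", n_lay)
  acts[[1L]] <- X
  for (l in seq_len(n_lay)) {
    Z <- add_bias(acts[[l]] %*% net$W[[l]], net$b[[l]])
    if (l < n_lay) {
      A <- Z * (Z > 0)
      if (train && dropout > 0) {
        keep <- 1 - dropout
        m <- matrix(stats::runif(length(A)) < keep, nrow(A), ncol(A)) / keep
        A <- A * m
        masks[[l]] <- m
      }
      acts[[l + 1L]] <- A
    } else {
      acts[[l + 1L]] <- Z
    }
  }
  list(out = acts[[n_lay + 1L]],
       cache = list(acts = acts, masks = masks, net = net))
}

# Backward pass. dZ is the gradient of the loss w.r.t. the final layer's
# pre-activation output (n x out). Returns parameter gradients and the
# gradient w.r.t. the input X.
mlp_backward <- function(cache, dZ) {
  net <- cache$net
  acts <- cache$acts
  masks <- cache$masks
  n_lay <- length(net$W)
  gW <- vector("list", n_lay)
  gb <- vector("list", n_lay)
  delta <- dZ
  for (l in rev(seq_len(n_lay))) {
    gW[[l]] <- crossprod(acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(net$W[[l]])
      A <- acts[[l]]
      if (!is.null(masks[[l - 1L]])) delta <- delta * masks[[l - 1L]]
      delta <- delta * (A > 0)
    } else {
      delta <- delta %*% t(net$W[[l]])
    }
  }
  list(W = gW, b = gb, dX = delta)
}

# ---- Adam ---------------------------------------------------------------

adam_new <- function(net) {
  zW <- lapply(net$W, function(w) w * 0)
  zb <- lapply(net$b, function(v) v * 0)
  list(mW = zW, vW = zW, mb = zb, vb = zb, t = 0L)
}

# One Adam step with decoupled L2 weight decay on the weight matrices.
adam_step <- function(net, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (l in seq_along(net$W)) {
    gW <- grads$W[[l]]
    if (weight_decay > 0) gW <- gW + weight_decay * net$W[[l]]
    opt$mW[[l]] <- beta1 * opt$mW[[l]] + (1 - beta1) * gW
    opt$vW[[l]] <- beta2 * opt$vW[[l]] + (1 - beta2) * gW * gW
    net$W[[l]] <- net$W[[l]] -
      lr * (opt$mW[[l]] / bc1) / (sqrt(opt$vW[[l]] / bc2) + eps)
    gb <- grads$b[[l]]
    opt$mb[[l]] <- beta1 * opt$mb[[l]] + (1 - beta1) * gb
    opt$vb[[l]] <- beta2 * opt$vb[[l]] + (1 - beta2) * gb * gb
    net$b[[l]] <- net$b[[l]] -
      lr * (opt$mb[[l]] / bc1) / (sqrt(opt$vb[[l]] / bc2) + eps)
  }
  list(net = net, opt = opt)
}

# ---- residual image generator ------------------------------------------
#
# G(x) = clip01(x + up(MLP(x))) with a tanh hidden layer, a zero-initialised
# output layer (so an untrained generator is exactly the identity on [0,1]
# images) and, by default, a coarse residual: the MLP emits one value per
# k x k block which is upsampled to pixels. Coarse residuals are spatially
# coherent at lesion scale — the encoder-decoder bottleneck of this
# desk-scale design. The clip uses a straight-through subgradient (zero
# where the pre-clip value leaves [0,1]).

gen_init <- function(p, hidden = 32L, grid = 4L) {
  s <- as.integer(sqrt(p))
  U <- NULL
  out_dim <- p
  if (grid > 1L && s %% grid == 0L) {
    U <- t(pool_matrix(s, grid)) * (grid * grid)  # replicate blocks
    out_dim <- (s %/% grid)^2
  }
  net <- mlp_init(c(p, hidden, out_dim), zero_out = TRUE)
  net$U <- U
  class(net) <- c("dttl_generator", class(net))
  net
}

gen_forward <- function(net, X) {
  Z1 <- add_bias(X %*% net$W[[1L]], net$b[[1L]])
  H <- tanh(Z1)
  R <- add_bias(H %*% net$W[[2L]], net$b[[2L]])
  if (!is.null(net$U)) R <- R %*% net$U
  pre <- X + R
  Y <- pmin(pmax(pre, 0), 1)
  list(out = Y, cache = list(X = X, H = H, pre = pre, net = net))
}

gen_backward <- function(cache, dY) {
  net <- cache$net
  mask <- (cache$pre > 0) & (cache$pre < 1)
  dpre <- dY * mask
  dR <- if (is.null(net$U)) dpre else dpre %*% t(net$U)
  gW2 <- crossprod(cache$H, dR)
  gb2 <- colSums(dR)
  dH <- dR %*% t(net$W[[2L]])
  dZ1 <- dH * (1 - cache$H^2)
  gW1 <- crossprod(cache$X, dZ1)
  gb1 <- colSums(dZ1)
  dX <- dpre + dZ1 %*% t(net$W[[1L]])
  list(W = list(gW1, gW2), b = list(gb1, gb2), dX = dX)
}

# deterministic substream seeds derived from a user seed; kept < 2^31
derive_seed <- function(seed, stage) {
  offsets <- c(cohort = 11L, cda = 101L, cmt = 211L, btl = 307L,
               split = 401L, init = 503L, eval = 601L)
  stopifnot(stage %in% names(offsets))
  (as.integer(seed) %% 1000000L) * 2017L + offsets[[stage]]
}

# fixed average-pooling matrix: (s*s) x (s/k)^2, each column averages a
# k x k block; a parameter-free linear front end shared by classifier and
# discriminator heads.
pool_matrix <- function(s, k) {
  if (k <= 1L || s %% k != 0L) return(NULL)
  m <- s %/% k
  P <- matrix(0, s * s, m * m)
  for (bj in seq_len(m)) {
    for (bi in seq_len(m)) {
      rows <- as.vector(outer((bi - 1L) * k + seq_len(k),
                              ((bj - 1L) * k + seq_len(k) - 1L) * s, "+"))
      P[rows, (bj - 1L) * m + bi] <- 1 / (k * k)
    }
  }
  P
}
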