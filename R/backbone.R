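# Tiny trainable backbones.
#
# The classification branches are backbone-agnostic; in this package the
# registered backbones are small fully-connected networks (flattened
# pixels -> optional ReLU hidden layer -> logits) trained with Adam.
# They are deliberately small: the synthetic scenes carry purely spatial
# signal, and desk-scale determinism matters more than capacity. The
# registry keeps the branch code independent of the backbone choice, so
# larger architectures can be slotted in where compute allows.

.backbones <- list(
  linear = integer(0),
  tiny_mlp = 32L,
  tiny_mlp_wide = 64L
)

#' Registered backbone identifiers
#'
#' @return character vector of backbone names usable in
#'   [branch_config()] and [compare_backbones()].
#' @export
backbone_registry <- function() names(.backbones)

.net_init <- function(backbone, n_in, n_out) {
  hidden <- .backbones[[backbone]]
  if (is.null(hidden)) stop("unregistered backbone: ", backbone)
  sizes <- c(n_in, hidden, n_out)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    fan_in <- sizes[l]
    W[[l]] <- matrix(stats::rnorm(fan_in * sizes[l + 1L], 0,
                                  sqrt(2 / fan_in)),
                     nrow = fan_in)
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b)
}

# forward pass; returns logits and layer activations for backprop
.net_forward <- function(params, X) {
  L <- length(params$W)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  A <- X
  for (l in seq_len(L)) {
    Z <- sweep(A %*% params$W[[l]], 2L, params$b[[l]], "+")
    A <- if (l < L) pmax(Z, 0) else Z
    acts[[l + 1L]] <- A
  }
  list(logits = A, acts = acts)
}

# gradient of the loss w.r.t. parameters given dL/dlogits
.net_backward <- function(params, fwd, dlogits) {
  L <- length(params$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- dlogits
  for (l in rev(seq_len(L))) {
    A_prev <- fwd$acts[[l]]
    gW[[l]] <- crossprod(A_prev, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(params$W[[l]])) * (fwd$acts[[l]] > 0)
    }
  }
  list(W = gW, b = gb)
}

.adam_init <- function(params) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero_like(params$W), vW = zero_like(params$W),
       mb = zero_like(params$b), vb = zero_like(params$b), t = 0L)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(params$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    params$W[[l]] <- params$W[[l]] -
      lr * (state$mW[[l]] / bc1) / (sqrt(state$vW[[l]] / bc2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    params$b[[l]] <- params$b[[l]] -
      lr * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Numerically stable logistic function
#' @param x numeric.
#' @return `1 / (1 + exp(-x))`.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

# element-wise sigmoid binary cross-entropy on logits (mean over all
# elements), plus gradient w.r.t. logits
.loss_bce_logits <- function(logits, Y) {
  n <- length(logits)
  val <- sum(pmax(logits, 0) - logits * Y + log1p(exp(-abs(logits)))) / n
  grad <- (sigmoid(logits) - Y) / n
  list(value = val, grad = grad)
}

# two-class softmax cross-entropy; y in {0,1} indexes the positive class
# column 2
.loss_softmax2 <- function(logits, y) {
  stopifnot(ncol(logits) == 2L)
  n <- nrow(logits)
  m <- pmax(logits[, 1L], logits[, 2L])
  lse <- m + log(exp(logits[, 1L] - m) + exp(logits[, 2L] - m))
  picked <- ifelse(y == 1, logits[, 2L], logits[, 1L])
  val <- mean(lse - picked)
  P <- exp(logits - cbind(lse, lse))
  onehot <- cbind(1 - y, y)
  list(value = val, grad = (P - onehot) / n)
}

#' Two-class softmax probability of the disease class
#'
#' Maps the binary branch's two logits (background, disease) to the
#' probability of the disease class.
#'
#' @param logits `n x 2` matrix (column 2 = disease class).
#' @return numeric vector of probabilities.
#' @export
softmax2_prob <- function(logits) {
  stopifnot(ncol(logits) == 2L)
  as.numeric(1 / (1 + exp(logits[, 1L] - logits[, 2L])))
}
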