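# Small neural-network primitives shared by the autoencoder and the scorer.
# All parameters live in flat named lists of base-R matrices/vectors, and
# gradients are computed by hand-written backpropagation -- keeping the
# package dependency-free and every update bit-reproducible under set.seed.

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

.relu <- function(x) (x > 0) * x
.lrelu <- function(x, slope = 0.01) { pos <- x > 0; x * pos + (slope * x) * !pos }
.lrelu_grad <- function(x, slope = 0.01) slope + (1 - slope) * (x > 0)

.sigmoid <- function(x) 1 / (1 + exp(-x))

# row-wise softmax of a matrix
.softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

# Adam state for a named list of parameter arrays
.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One Adam step; returns list(params, state)
.adam_step <- function(params, grads, state, lr = 1e-3,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# accumulate grads (sum of two named lists)
.grad_add <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- (a[[nm]] %||% 0) + b[[nm]]
  a
}
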