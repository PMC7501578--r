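# Numerical primitives shared by the language model, the lattice encoder and
# the CRF. All stochastic initialization goes through with_seed() so that a
# single integer seed reproduces a run bit-for-bit.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so library code never perturbs the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# log(sum(exp(x))), numerically stable
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise softmax of a matrix
softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# Uniform init in +/- sqrt(6/(fan_in+fan_out)) (Glorot), the convention of the
# lattice-LSTM lineage for gate matrices.
init_matrix <- function(nrow, ncol) {
  r <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -r, r), nrow = nrow, ncol = ncol)
}

init_vector <- function(n) numeric(n)

# ---- parameter trees -------------------------------------------------------
# Parameters and their gradients are nested lists of numeric arrays with the
# same shape; these helpers map over the leaves.

param_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- param_map2(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}

param_map <- function(a, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- param_map(a[[i]], f)
    out
  } else f(a)
}

param_zeros_like <- function(a) param_map(a, function(x) x * 0)

param_sumsq <- function(a) {
  if (is.list(a)) sum(vapply(a, param_sumsq, numeric(1))) else sum(a^2)
}

#' Clip a gradient tree to a global L2 norm
#'
#' @param grads nested list of numeric arrays.
#' @param max_norm norm bound; `Inf` disables clipping.
#' @return the (possibly rescaled) gradient tree.
#' @export
clip_global_norm <- function(grads, max_norm = 5) {
  if (!is.finite(max_norm)) return(grads)
  nrm <- sqrt(param_sumsq(grads))
  if (nrm <= max_norm || nrm == 0) return(grads)
  param_map(grads, function(x) x * (max_norm / nrm))
}

# plain SGD step: params - lr * grads; optional fused global-norm clipping
# (one tree traversal instead of clip-then-update)
sgd_step <- function(params, grads, lr, max_norm = Inf) {
  if (is.finite(max_norm)) {
    nrm <- sqrt(param_sumsq(grads))
    if (nrm > max_norm && nrm > 0) lr <- lr * (max_norm / nrm)
  }
  param_map2(params, grads, function(p, g) p - lr * g)
}

# ---- Adam ------------------------------------------------------------------
# Used for language-model pretraining (the tagger itself uses SGD with decay,
# the study's optimizer).

adam_init <- function(params) {
  list(m = param_zeros_like(params), v = param_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-2, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- param_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- param_map2(state$m, state$v,
                    function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  list(params = param_map2(params, upd, function(p, u) p - u), state = state)
}
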