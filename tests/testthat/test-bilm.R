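small_bilm <- function(vocab = c("a", "b", "c", "d"), seed = 3L) {
  with_seed(seed, bilm_init(vocab, emb_dim = 6L, hidden_dim = 5L,
                            proj_dim = 3L, n_layers = 2L))
}

test_that("layer stack has L + 1 layers of combined-direction vectors", {
  bl <- with_seed(1, bilm_init(letters[1:6]))  # full-size defaults
  chars <- c("a", "b", "c", "d", "e")
  st <- bilm_representations(chars, bl)
  expect_length(st, 3L)                        # token layer + 2 recurrent
  for (l in st) expect_equal(dim(l), c(5L, 100L))
  # layer 0 is exactly the token embedding rows
  ids <- unname(bl$vocab[chars])
  expect_identical(st[[1]], bl$emb[ids, ])
  # deterministic: same input twice gives bit-identical stacks
  expect_identical(bilm_representations(chars, bl), st)
})

test_that("directional states are causal", {
  bl <- small_bilm(seed = 11)
  base <- c("a", "b", "c", "d", "a", "b")
  st0 <- bilm_representations(base, bl)
  P <- bl$proj_dim
  # perturb character k+1: forward halves at positions <= k unchanged,
  # backward halves at positions > k+1 unchanged
  for (k in c(2L, 4L)) {
    pert <- base
    pert[k + 1L] <- "d"
    st1 <- bilm_representations(pert, bl)
    for (l in 2:3) {
      expect_equal(st1[[l]][1:k, 1:P], st0[[l]][1:k, 1:P], tolerance = 1e-12)
      if (k + 2L <= length(base))
        expect_equal(st1[[l]][(k + 2L):length(base), (P + 1L):(2L * P)],
                     st0[[l]][(k + 2L):length(base), (P + 1L):(2L * P)],
                     tolerance = 1e-12)
    }
  }
  expect_error(bilm_representations(character(0), bl), "empty")
})

test_that("uniform output distribution gives per-token loss 2 log V", {
  bl <- small_bilm()
  bl$W_s[] <- 0; bl$b_s[] <- 0
  V <- length(bl$vocab)
  expect_equal(bilm_nll(list(c("a", "b", "c")), bl), 2 * log(V),
               tolerance = 1e-10)
  # single-character sentence: both conditionals are unconditional; finite
  l1 <- bilm_nll(list("a"), small_bilm())
  expect_true(is.finite(l1) && l1 > 0)
})

test_that("scalar mix equals the direct weighted sum and obeys its limits", {
  bl <- small_bilm(seed = 21)
  st <- bilm_representations(c("a", "c", "b"), bl)
  set.seed(5)
  mix <- list(s_logits = rnorm(3), gamma = 0.8)
  got <- scalar_mix(st, mix)
  s <- exp(mix$s_logits) / sum(exp(mix$s_logits))
  want <- 0.8 * (s[1] * st[[1]] + s[2] * st[[2]] + s[3] * st[[3]])
  expect_equal(got, want, tolerance = 1e-12)
  # gamma = 0 -> zero vectors
  expect_equal(scalar_mix(st, list(s_logits = rnorm(3), gamma = 0)),
               st[[1]] * 0)
  # dominant logit selects its layer
  sel <- scalar_mix(st, list(s_logits = c(0, 50, 0), gamma = 1))
  expect_equal(sel, st[[2]], tolerance = 1e-6)
  expect_error(scalar_mix(st, list(s_logits = c(0, 0), gamma = 1)), "weights")
})

test_that("scalar-mix gradients match finite differences", {
  bl <- small_bilm(seed = 31)
  st <- bilm_representations(c("b", "d"), bl)
  set.seed(6)
  mix <- list(s_logits = rnorm(3), gamma = 1.3)
  D <- matrix(rnorm(length(scalar_mix(st, mix))), nrow = 2L)
  loss <- function(m) sum(D * scalar_mix(st, m))
  g <- latticeNER:::scalar_mix_grad(st, mix, D)
  eps <- 1e-7
  for (j in 1:3) {
    m2 <- mix; m2$s_logits[j] <- m2$s_logits[j] + eps
    expect_equal(g$s_logits[j], (loss(m2) - loss(mix)) / eps, tolerance = 1e-4)
  }
  m2 <- mix; m2$gamma <- m2$gamma + eps
  expect_equal(g$gamma, (loss(m2) - loss(mix)) / eps, tolerance = 1e-4)
})

test_that("language-model training reduces the loss and is reproducible", {
  sents <- generate_lm_corpus(n_sentences = 12L, n_patterns = 2L,
                              pattern_len = 8L, alphabet_size = 6L, seed = 2L)
  f0 <- train_bilm(sents, epochs = 0L, seed = 9L, emb_dim = 6L,
                   hidden_dim = 5L, proj_dim = 3L)
  expect_length(f0$history, 0L)
  # zero epochs returns the seeded initialization unchanged
  expect_identical(f0$params$emb,
                   bilm_init(sort(unique(unlist(sents))), 6L, 5L, 3L, 2L,
                             seed = 9L)$emb)
  f1 <- train_bilm(sents, epochs = 15L, seed = 9L, emb_dim = 6L,
                   hidden_dim = 5L, proj_dim = 3L)
  expect_lt(f1$history[15L], f1$history[1L])
  f2 <- train_bilm(sents, epochs = 15L, seed = 9L, emb_dim = 6L,
                   hidden_dim = 5L, proj_dim = 3L)
  expect_identical(f1$history, f2$history)
})

test_that("full language-model gradients match finite differences", {
  bl <- small_bilm(vocab = c("a", "b", "c"), seed = 41)
  sents <- list(c("a", "b", "c"), c("b", "a"))
  r <- latticeNER:::bilm_batch(sents, bl, want_grads = TRUE)
  eps <- 1e-6
  check <- function(w, g, setter, label) {
    idx <- seq_along(w)
    if (length(idx) > 12L) {
      set.seed(nchar(label))
      idx <- sort(sample(idx, 12L))
    }
    for (i in idx) {
      b2 <- setter(i, eps)
      fd <- (bilm_nll(sents, b2) - r$loss) / eps
      expect_equal(g[i], fd, tolerance = 1e-3, label = paste(label, i))
    }
  }
  check(bl$emb, r$grads$emb,
        function(i, e) { b <- bl; b$emb[i] <- b$emb[i] + e; b }, "emb")
  check(bl$W_s, r$grads$W_s,
        function(i, e) { b <- bl; b$W_s[i] <- b$W_s[i] + e; b }, "W_s")
  for (dir in c("fwd", "bwd")) for (l in 1:2) for (nm in c("W", "P")) {
    check(bl[[dir]][[l]][[nm]], r$grads[[dir]][[l]][[nm]],
          function(i, e) { b <- bl; b[[dir]][[l]][[nm]][i] <-
            b[[dir]][[l]][[nm]][i] + e; b },
          paste(dir, l, nm))
  }
})
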