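# scalar toy parameters (H = 1, input dim 1, word dim 1) used by the
# hand-evaluation oracles; gate rows are [input; forget; output; candidate]
toy_params <- function() {
  list(W_c = rbind(c(0.5, -0.3), c(0.2, 0.1), c(-0.4, 0.6), c(0.7, 0.2)),
       b_c = c(0.1, -0.2, 0.3, 0),
       W_w = rbind(c(0.4, -0.1), c(0.3, 0.2), c(-0.5, 0.6)),
       b_w = c(0.05, -0.1, 0.2),
       W_l = matrix(c(0.25, -0.35), 1L), b_l = 0.15,
       input_dim = 1L, hidden_dim = 1L, word_dim = 1L)
}

zero_params <- function(d = 2L, H = 2L, dw = 2L) {
  list(W_c = matrix(0, 4 * H, d + H), b_c = numeric(4 * H),
       W_w = matrix(0, 3 * H, dw + H), b_w = numeric(3 * H),
       W_l = matrix(0, H, d + H), b_l = numeric(H),
       input_dim = d, hidden_dim = H, word_dim = dw)
}

test_that("word cell follows the gate equations and has no output gate", {
  # zero parameters: gates sigma(0) = 0.5, candidate tanh(0) = 0
  p <- zero_params()
  cb <- c(0.8, -0.4)
  expect_equal(word_cell(c(1, 2), c(0.1, 0.2), cb, p), 0.5 * cb)
  # zero candidate weights and c_b = 0 give a zero cell
  expect_equal(word_cell(c(1, 2), c(3, -1), c(0, 0), p), c(0, 0))
  # scalar toy vs hand evaluation of the word-cell formulas
  p <- toy_params()
  x_w <- 0.6; h_b <- -0.2; c_b <- 0.9
  i_w <- plogis(0.4 * x_w - 0.1 * h_b + 0.05)
  f_w <- plogis(0.3 * x_w + 0.2 * h_b - 0.1)
  g_w <- tanh(-0.5 * x_w + 0.6 * h_b + 0.2)
  expect_equal(word_cell(x_w, h_b, c_b, p), f_w * c_b + i_w * g_w,
               tolerance = 1e-12)
  # structurally: the cell is returned bare -- no hidden output exists
  expect_length(word_cell(x_w, h_b, c_b, p), 1L)
})

test_that("char step without word cells is exactly the standard LSTM update", {
  set.seed(21)
  for (i in 1:10) {
    H <- 3L; d <- 4L
    p <- with_seed(i, lattice_init(d, H, 2L))
    x <- rnorm(d); h0 <- rnorm(H); c0 <- rnorm(H)
    st <- char_step(x, h0, c0, list(), p)
    # direct formula evaluation from (h0, c0)
    a <- drop(p$W_c %*% c(x, h0)) + p$b_c
    cc <- plogis(a[(H + 1):(2 * H)]) * c0 + plogis(a[1:H]) * tanh(a[(3 * H + 1):(4 * H)])
    expect_equal(st$c, cc, tolerance = 1e-12)
    expect_equal(st$h, plogis(a[(2 * H + 1):(3 * H)]) * tanh(cc), tolerance = 1e-12)
    expect_null(st$alphas)
  }
})

test_that("equal combine and input logits split the cell half-and-half", {
  p <- zero_params()
  cw <- c(0.7, -0.3)
  st <- char_step(c(1, 1), c(0, 0), c(0.5, 0.5), list(cw), p)
  # all logits zero: alpha = 1/2 each; candidate tanh(0) = 0
  expect_equal(st$alphas, matrix(0.5, 2L, 2L))
  expect_equal(st$c, 0.5 * cw)
  expect_equal(colSums(st$alphas), c(1, 1))
})

test_that("a merge step matches scalar hand evaluation of the full equations", {
  p <- toy_params()
  x <- 0.3; h0 <- 0.2; c0 <- -0.5; cw <- 0.45
  a_i <- 0.5 * x - 0.3 * h0 + 0.1
  a_f <- 0.2 * x + 0.1 * h0 - 0.2
  a_o <- -0.4 * x + 0.6 * h0 + 0.3
  a_g <- 0.7 * x + 0.2 * h0
  l_w <- 0.25 * x - 0.35 * cw + 0.15
  aw <- exp(l_w) / (exp(l_w) + exp(a_i))   # word weight
  ac <- 1 - aw
  c_t <- aw * cw + ac * tanh(a_g)
  h_t <- plogis(a_o) * tanh(c_t)
  st <- char_step(x, h0, c0, list(cw), p)
  expect_equal(st$c, c_t, tolerance = 1e-12)
  expect_equal(st$h, h_t, tolerance = 1e-12)
  expect_equal(drop(st$alphas), c(aw, ac), tolerance = 1e-12)
})

test_that("empty lexicon reduces the encoder to a plain LSTM", {
  set.seed(31)
  for (i in 1:20) {
    d <- 5L; H <- 4L; n <- sample(2:9, 1L)
    p <- with_seed(100 + i, lattice_init(d, H, 3L))
    X <- matrix(rnorm(n * d), n)
    expect_equal(lattice_encode(X, NULL, NULL, p),
                 reference_lstm(X, p$W_c, p$b_c, H), tolerance = 1e-6)
  }
})

test_that("the worked four-character lattice merges both word cells at the end", {
  lx <- build_lexicon(c("胃体", "粘膜", "胃体粘膜"))
  chars <- strsplit("胃体粘膜", "")[[1]]
  m <- lexicon_match(chars, lx)
  p <- with_seed(8, lattice_init(3L, 3L, 2L))
  X <- with_seed(9, matrix(rnorm(12), 4L))
  XW <- with_seed(10, matrix(rnorm(nrow(m) * 2L), nrow(m)))
  cache <- latticeNER:::lattice_forward(X, m, XW, p)
  # last character: word cells for 粘膜 (2,4) and 胃体粘膜 (0,4) merge there
  mc <- cache$mcache[[4]]
  expect_true(mc$merge)
  expect_length(mc$inc, 2L)
  expect_equal(sort(m$begin[mc$inc]), c(0L, 2L))
  # position 2 merges 胃体 (0,2) only
  expect_length(cache$mcache[[2]]$inc, 1L)
  # merge weights sum to one elementwise
  expect_equal(colSums(mc$alphas), rep(1, 3L), tolerance = 1e-6)
})

test_that("combine weights are normalized at every merge of random lattices", {
  set.seed(41)
  checked <- 0L
  for (i in 1:40) {
    d <- 3L; H <- 3L; n <- sample(4:10, 1L)
    p <- with_seed(200 + i, lattice_init(d, H, 2L))
    nm <- sample(1:4, 1L)
    b <- sample(0:(n - 3L), nm, replace = TRUE)
    e <- pmin(b + sample(2:3, nm, replace = TRUE), n)
    m <- unique(data.frame(begin = b, end = e, term_id = seq_along(b)))
    m <- m[m$end - m$begin >= 2L, , drop = FALSE]
    m <- m[order(m$end, m$begin), , drop = FALSE]
    if (!nrow(m)) next
    X <- matrix(rnorm(n * d), n)
    XW <- matrix(rnorm(nrow(m) * 2L), nrow(m))
    cache <- latticeNER:::lattice_forward(X, m, XW, p)
    for (t in seq_len(n)) {
      mc <- cache$mcache[[t]]
      if (isTRUE(mc$merge)) {
        expect_equal(colSums(mc$alphas), rep(1, H), tolerance = 1e-6)
        checked <- checked + 1L
      }
    }
  }
  expect_gte(checked, 20L)
})

test_that("the forward pass is invariant to the order of same-endpoint matches", {
  set.seed(51)
  d <- 3L; H <- 3L; n <- 6L
  p <- with_seed(300, lattice_init(d, H, 2L))
  X <- matrix(rnorm(n * d), n)
  m <- data.frame(begin = c(0L, 2L, 1L), end = c(6L, 6L, 6L), term_id = 1:3)
  XW <- matrix(rnorm(6L), 3L)
  H1 <- lattice_encode(X, m, XW, p)
  perm <- c(3L, 1L, 2L)
  H2 <- lattice_encode(X, m[perm, ], XW[perm, ], p)
  expect_equal(H1, H2, tolerance = 1e-12)
})

test_that("bidirectional encoding has the right shape and symmetry", {
  d <- 3L; H <- 4L
  p <- with_seed(400, lattice_init(d, H, 2L))
  for (n in c(1L, 2L, 7L)) {
    X <- with_seed(n, matrix(rnorm(n * d), n))
    out <- lattice_encode_bidirectional(X, NULL, NULL, p, p)
    expect_equal(dim(out), c(n, 2L * H))
  }
  # palindromic input with tied parameters: outputs mirror across directions
  Xp <- rbind(c(1, 2, 3), c(4, 5, 6), c(1, 2, 3))
  out <- lattice_encode_bidirectional(Xp, NULL, NULL, p, p)
  expect_equal(out[, 1:H], out[3:1, (H + 1):(2 * H)], tolerance = 1e-12)
  # single character: both directions see the same step
  X1 <- matrix(c(0.3, -1, 2), 1L)
  o1 <- lattice_encode_bidirectional(X1, NULL, NULL, p, p)
  expect_equal(o1[, 1:H], o1[, (H + 1):(2 * H)], tolerance = 1e-12)
})

test_that("analytic lattice gradients match finite differences on a toy lattice", {
  # 2 characters, one match covering both
  d <- 3L; H <- 2L; dw <- 2L; n <- 2L
  p <- with_seed(500, lattice_init(d, H, dw))
  X <- with_seed(501, matrix(rnorm(n * d), n))
  m <- data.frame(begin = 0L, end = 2L, term_id = 1L)
  XW <- with_seed(502, matrix(rnorm(dw), 1L))
  loss_of <- function(pp, XX, XXW) {
    cache <- latticeNER:::lattice_forward(XX, m, XXW, pp)
    sum(cache$H^2)   # simple smooth functional of the hidden states
  }
  cache <- latticeNER:::lattice_forward(X, m, XW, p)
  bk <- latticeNER:::lattice_backward(cache, 2 * cache$H, p)
  eps <- 1e-6
  base <- loss_of(p, X, XW)
  for (nm in c("W_c", "b_c", "W_w", "b_w", "W_l", "b_l")) {
    for (i in seq_along(p[[nm]])) {
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps
      fd <- (loss_of(p2, X, XW) - base) / eps
      an <- bk$grads[[nm]][i]
      expect_equal(an, fd, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
  for (i in seq_along(X)) {
    X2 <- X; X2[i] <- X2[i] + eps
    expect_equal(bk$dX[i], (loss_of(p, X2, XW) - base) / eps, tolerance = 1e-4)
  }
  for (i in seq_along(XW)) {
    W2 <- XW; W2[i] <- W2[i] + eps
    expect_equal(bk$dXW[i], (loss_of(p, X, W2) - base) / eps, tolerance = 1e-4)
  }
})

test_that("input representation concatenates static and contextual parts", {
  tab <- random_embedding_table(c("a", "b"), 4L, seed = 1L)
  elmo <- matrix(1:6 / 10, 2L, 3L)
  r <- build_input_representation(c("a", "b"), tab, elmo)
  expect_equal(ncol(r$X), 7L)
  expect_equal(r$X[, 1:4], emb_rows(tab, c("a", "b")))
  expect_equal(r$X[, 5:7], elmo)
  # contextual part disabled
  r0 <- build_input_representation(c("a", "b"), tab)
  expect_equal(ncol(r0$X), 4L)
  # eval mode (training = FALSE) ignores dropout and is deterministic
  r1 <- build_input_representation(c("a", "b"), tab, elmo, dropout_rate = 0.5)
  expect_equal(r1$X, r$X)
  expect_null(r1$mask)
  expect_error(build_input_representation(c("a", "b"), tab, elmo[1, , drop = FALSE]),
               "length")
})
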