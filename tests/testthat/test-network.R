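test_that("reference LSTM step reproduces analytic zero-weight cases", {
  zeros <- function(n) rep(0, n)
  p <- lstm_cell_params(hidden = 3, input = 2, init = zeros)
  s0 <- list(C = zeros(3), h = zeros(3))
  s1 <- reference_lstm_step(p, s0, c(1, -1))
  # all gates 0.5, candidate 0 -> state stays 0
  expect_equal(s1$C, zeros(3))
  expect_equal(s1$h, zeros(3))
  # with C = c: C' = 0.5 c, h' = 0.5 tanh(0.5 c)
  s2 <- reference_lstm_step(p, list(C = rep(2, 3), h = zeros(3)), c(1, -1))
  expect_equal(s2$C, rep(1, 3))
  expect_equal(s2$h, rep(0.5 * tanh(1), 3))
})

test_that("reference LSTM step enforces dimensional consistency", {
  p <- lstm_cell_params(hidden = 3, input = 2)
  expect_error(reference_lstm_step(p, list(C = rep(0, 3), h = rep(0, 3)), c(1, 2, 3)),
               "W_forget")
})

test_that("hidden states stay in (-1, 1) after any update", {
  set.seed(31)
  p <- lstm_cell_params(hidden = 5, input = 4, init = function(n) rnorm(n, sd = 3))
  s <- list(C = rnorm(5, sd = 4), h = tanh(rnorm(5)))
  for (t in 1:10) {
    s <- reference_lstm_step(p, s, rnorm(4))
    expect_true(all(abs(s$h) < 1))
  }
})

test_that("vectorized LSTM trajectory equals the per-gate reference cell", {
  set.seed(32)
  Hd <- 5; Ed <- 4; L <- 12
  W <- matrix(rnorm((Hd + Ed) * 4 * Hd, sd = 0.4), Hd + Ed, 4 * Hd)
  b <- rnorm(4 * Hd, sd = 0.2)
  slice <- function(k) t(W[, (k - 1) * Hd + 1:Hd])
  ref <- list(W_forget = slice(1), W_input = slice(2), W_cell = slice(3),
              W_output = slice(4), b_forget = b[1:Hd], b_input = b[Hd + 1:Hd],
              b_cell = b[2 * Hd + 1:Hd], b_output = b[3 * Hd + 1:Hd])
  X <- lapply(1:L, function(t) matrix(rnorm(Ed), 1, Ed))
  out <- amylstm:::cell_forward("lstm", list(W = W, b = b), X, matrix(1, 1, L))
  s <- list(C = rep(0, Hd), h = rep(0, Hd))
  for (t in 1:L) {
    s <- reference_lstm_step(ref, s, drop(X[[t]]))
    expect_equal(drop(out$H[[t]]), s$h, tolerance = 1e-12)
  }
})

test_that("attention pooling matches the direct softmax oracle and handles masks", {
  set.seed(33)
  H <- matrix(rnorm(7 * 6), 7, 6)
  ap <- attention_params(6, seed = 2)
  mask <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  got <- attention_pool(H, ap, mask)
  want <- oracle_softmax_pool(H, t(ap$W_k), ap$b_k, ap$u_s, mask)
  expect_equal(got$alpha, want$alpha, tolerance = 1e-6)
  expect_equal(got$V, want$V, tolerance = 1e-6)
  expect_equal(sum(got$alpha), 1, tolerance = 1e-6)
  expect_true(all(got$alpha[!mask] == 0))

  # n = 1: weight 1, V = h regardless of parameters
  h1 <- matrix(rnorm(6), 1, 6)
  expect_equal(attention_pool(h1, ap)$alpha, 1)
  expect_equal(attention_pool(h1, ap)$V, drop(h1))

  # identical states: uniform weights over unmasked positions
  Hsame <- matrix(rep(rnorm(6), each = 5), 5, 6)
  got2 <- attention_pool(Hsame, ap, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(got2$alpha, c(1, 1, 1, 0, 0) / 3)
  expect_equal(got2$V, drop(Hsame[1, ]))

  expect_error(attention_pool(H, ap, rep(FALSE, 7)), "all-masked")
})

test_that("the default architecture exposes vocab 21, embedding 100, pooled width 128", {
  cfg <- model_config()
  m <- build_model(cfg, seed = 1)
  expect_equal(cfg$vocab_size, 21L)
  expect_equal(dim(m$params$E), c(21L, 100L))
  expect_equal(amylstm:::pooled_dim(cfg), 128L)
  expect_equal(dim(m$params$att_Wk), c(128L, 128L))
  expect_length(m$params$att_us, 128L)
  expect_equal(all(m$params$E[1, ] == 0), TRUE)  # pad row frozen at zero
  expect_error(model_config(cell = "transformer"))
})

test_that("forward predictions are probabilities, deterministic, and padding-invariant", {
  set.seed(34)
  recs <- tibble::tibble(id = paste0("s", 1:6),
                         sequence = vapply(sample(5:40, 6), random_seq, character(1)),
                         label = rep(0:1, 3))
  for (cell in c("lstm", "gru", "rnn")) {
    m <- build_model(tiny_model_config(cell = cell), seed = 4)
    p1 <- predict_proba(m, recs)
    p2 <- predict_proba(m, recs)
    expect_identical(p1$prob, p2$prob)
    expect_true(all(p1$prob > 0 & p1$prob < 1))

    b <- tokenize(recs)
    bpad <- b
    bpad$indices <- cbind(b$indices, matrix(0L, nrow(b$indices), 7))
    bpad$mask <- cbind(b$mask, matrix(FALSE, nrow(b$mask), 7))
    expect_equal(predict_proba(m, bpad)$prob, p1$prob, tolerance = 1e-12)
  }
  # single length-1 sequence gives one finite probability
  m1 <- build_model(tiny_model_config(), seed = 5)
  expect_true(is.finite(predict_proba(m1, tibble::tibble(id = "x", sequence = "A"))$prob))
})

test_that("attention weights form a distribution over unmasked positions; padding leaves them unchanged", {
  set.seed(35)
  recs <- tibble::tibble(id = c("a", "b"), sequence = c(random_seq(15), random_seq(9)))
  m <- build_model(tiny_model_config(), seed = 6)
  att <- predict_attention(m, recs)
  sums <- tapply(att$alpha, att$id, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-6)
  expect_equal(sum(att$id == "b"), 9L)

  b <- tokenize(recs)
  bpad <- b
  bpad$indices <- cbind(b$indices, matrix(0L, 2, 5))
  bpad$mask <- cbind(b$mask, matrix(FALSE, 2, 5))
  att2 <- predict_attention(m, bpad)
  expect_equal(att2$alpha, att$alpha, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences for every cell and pooling", {
  set.seed(36)
  recs <- tibble::tibble(id = paste0("s", 1:4),
                         sequence = c("ACDEFG", "MKV", "QQNNYW", "ACACAC"),
                         label = c(1L, 0L, 1L, 0L))
  batch <- tokenize(recs)
  ns <- asNamespace("amylstm")
  eps <- 1e-5
  for (cell in c("lstm", "gru", "rnn")) for (att in c(TRUE, FALSE)) {
    cfg <- model_config(cell = cell, attention = att, embed_dim = 5L,
                        hidden_per_direction = 4L, fc_hidden = 3L)
    m <- build_model(cfg, seed = 7)
    p <- m$params
    fw <- ns$model_forward(p, cfg, m$state, batch, train = TRUE)
    gr <- ns$model_backward(p, cfg, fw$cache, fw$prob, batch$labels)
    for (nm in names(gr)) {
      candidates <- if (nm == "E") which(row(p$E) != 1L) else seq_along(p[[nm]])
      ix <- sample(candidates, min(3L, length(candidates)))
      for (i in ix) {
        bump <- function(delta) {
          pp <- p; pp[[nm]][i] <- pp[[nm]][i] + delta
          ns$bce_loss(ns$model_forward(pp, cfg, m$state, batch, train = TRUE)$prob,
                      batch$labels)
        }
        num <- (bump(eps) - bump(-eps)) / (2 * eps)
        expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                     label = sprintf("%s/%s grad[%d] (%s)", cell, att, i, nm))
      }
    }
  }
})

test_that("one Adam step on a single batch decreases its loss", {
  set.seed(37)
  recs <- tibble::tibble(id = paste0("s", 1:4),
                         sequence = vapply(rep(12, 4), random_seq, character(1)),
                         label = c(1L, 1L, 0L, 0L))
  batch <- tokenize(recs)
  ns <- asNamespace("amylstm")
  cfg <- tiny_model_config()
  m <- build_model(cfg, seed = 8)
  p <- m$params
  opt <- ns$adam_init(p, lr = 1e-3)
  fw <- ns$model_forward(p, cfg, m$state, batch, train = TRUE)
  loss0 <- ns$bce_loss(fw$prob, batch$labels)
  gr <- ns$model_backward(p, cfg, fw$cache, fw$prob, batch$labels)
  p2 <- ns$adam_step(opt, p, gr)$params
  fw2 <- ns$model_forward(p2, cfg, fw$state, batch, train = TRUE)
  loss1 <- ns$bce_loss(fw2$prob, batch$labels)
  expect_lt(loss1, loss0)
})

test_that("out-of-vocabulary token indices are rejected", {
  m <- build_model(tiny_model_config(), seed = 9)
  b <- tokenize("ACDE")
  b$indices[1, 1] <- 21L
  expect_error(predict_proba(m, b), "vocabulary")
})
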