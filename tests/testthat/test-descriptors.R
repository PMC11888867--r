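test_that("CTD group tables partition the 20 residues under every attribute", {
  for (gr in oracle_ctd_groups()) {
    all_res <- unlist(strsplit(gr, ""))
    expect_length(all_res, 20L)
    expect_setequal(all_res, AA_ORACLE)
  }
})

test_that("AAC matches hand cases and the counting oracle", {
  a <- aac("AAAA")
  expect_equal(unname(a[1]), 1)
  expect_equal(sum(a), 1)
  expect_equal(unname(aac("ACDEFGHIKLMNPQRSTVWY")), rep(0.05, 20))
  # order-insensitive
  expect_equal(aac("ACD"), aac("DCA"))
  set.seed(21)
  for (i in 1:20) {
    s <- random_seq(50)
    expect_equal(unname(aac(s)), unname(oracle_aac(s)), tolerance = 1e-12)
  }
  # unknown tokens excluded from counts and normalizer
  expect_equal(aac("AA??"), aac("AA"))
  expect_error(aac(""), "empty")
})

test_that("DDE matches the closed form on 'AA' and the brute-force oracle", {
  d <- dde("AA")
  tm <- (4 / 61)^2
  expect_equal(unname(d["DDE.AA"]), (1 - tm) / sqrt(tm * (1 - tm)))
  set.seed(22)
  for (i in 1:10) {
    s <- random_seq(80)
    expect_equal(unname(dde(s)), oracle_dde(s), tolerance = 1e-10)
  }
  expect_error(dde("A"), "at least 2")
})

test_that("observed dipeptide fractions in DDE are a normalized distribution", {
  # reconstruct Dc from the standardized output and check it sums to 1
  set.seed(23)
  s <- random_seq(60)
  n <- 60
  d <- dde(s)
  pairs <- names(d)
  ci <- c(A = 4, C = 2, D = 2, E = 2, F = 2, G = 4, H = 2, I = 3, K = 2, L = 6,
          M = 1, N = 2, P = 4, Q = 2, R = 6, S = 6, T = 4, V = 4, W = 1, Y = 2) / 61
  tm <- ci[substr(pairs, 5, 5)] * ci[substr(pairs, 6, 6)]
  dc <- unname(d) * sqrt(tm * (1 - tm) / (n - 1)) + tm
  expect_equal(sum(dc), 1, tolerance = 1e-9)
})

test_that("CTDC and CTDD match hand cases and brute-force group scans", {
  g <- ctdc("GGGG")
  for (attr_start in seq(1, 39, by = 3)) {
    expect_setequal(round(g[attr_start + 0:2], 12), c(1, 0, 0))
  }
  d1 <- ctdd("G")
  expect_true(all(d1 %in% c(0, 100)))
  set.seed(24)
  for (i in 1:10) {
    s <- random_seq(60)
    expect_equal(unname(ctdc(s)), oracle_ctdc(s), tolerance = 1e-12)
    expect_equal(unname(ctdd(s)), oracle_ctdd(s), tolerance = 1e-10)
  }
  expect_true(all(ctdc(random_seq(40)) >= 0 & ctdc(random_seq(40)) <= 1))
  expect_true(all(ctdd(random_seq(40)) >= 0 & ctdd(random_seq(40)) <= 100))
})

test_that("within each CTDC attribute the three group fractions sum to 1", {
  set.seed(25)
  v <- ctdc(random_seq(75))
  sums <- tapply(v, rep(1:13, each = 3), sum)
  expect_equal(as.numeric(sums), rep(1, 13), tolerance = 1e-9)
})

test_that("APAAC reduces to AAC at lambda 0, stays finite on homopolymers, matches the oracle", {
  s <- random_seq(40)
  expect_equal(unname(apaac(s, lambda = 0L)), unname(aac(s)))
  expect_true(all(is.finite(apaac("GGGGGGGGGG", lambda = 3L))))
  set.seed(26)
  for (i in 1:10) {
    s <- random_seq(40)
    expect_equal(unname(apaac(s, lambda = 4L, weight = 0.05)),
                 unname(oracle_apaac(s, 4L, 0.05)), tolerance = 1e-10)
  }
  expect_error(apaac("ACD", lambda = 5L), "length 3 <= lambda 5")
})

test_that("descriptor dimensionality depends only on the descriptor, not the sequence", {
  set.seed(27)
  for (s in c("ACDEFGHIKL", random_seq(33), random_seq(170))) {
    expect_length(aac(s), 20L)
    expect_length(dde(s), 400L)
    expect_length(ctdc(s), 39L)
    expect_length(ctdd(s), 195L)
    expect_length(apaac(s, lambda = 4L), 28L)
    expect_length(apaac(s, lambda = 7L), 34L)
    for (f in list(aac, dde, ctdc, ctdd)) expect_true(all(is.finite(f(s))))
  }
})

test_that("all descriptors except AAC are permutation-sensitive", {
  s1 <- "ACDEFGHIKLACDEFGHIKL"
  s2 <- withr::with_seed(1, paste0(sample(strsplit(s1, "")[[1]]), collapse = ""))
  expect_equal(aac(s1), aac(s2))
  expect_false(isTRUE(all.equal(unname(dde(s1)), unname(dde(s2)))))
  expect_false(isTRUE(all.equal(unname(ctdd(s1)), unname(ctdd(s2)))))
  expect_false(isTRUE(all.equal(unname(apaac(s1)), unname(apaac(s2)))))
})

test_that("featurize builds a wide tibble keyed by id and label", {
  recs <- tibble::tibble(id = c("a", "b"), sequence = c("ACDEFGHIKL", "MMMMKKKKVV"),
                         label = c(1L, 0L))
  ft <- featurize(recs, "aac")
  expect_equal(dim(ft), c(2L, 22L))
  expect_equal(ft$label, c(1L, 0L))
  expect_equal(unname(unlist(ft[1, -(1:2)])), unname(aac("ACDEFGHIKL")))
})
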