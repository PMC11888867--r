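# Independent brute-force oracles used across the suite. These deliberately
# recompute every quantity from its definition with naive loops, sharing no
# code with the package internals they check.

AA_ORACLE <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_seq <- function(n, alphabet = AA_ORACLE) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

oracle_aac <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  chars <- chars[chars %in% AA_ORACLE]
  vapply(AA_ORACLE, function(a) sum(chars == a) / length(chars), numeric(1))
}

oracle_dde <- function(seq) {
  codons <- c(A = 4, C = 2, D = 2, E = 2, F = 2, G = 4, H = 2, I = 3, K = 2,
              L = 6, M = 1, N = 2, P = 4, Q = 2, R = 6, S = 6, T = 4, V = 4,
              W = 1, Y = 2)
  chars <- strsplit(seq, "")[[1]]
  chars <- chars[chars %in% AA_ORACLE]
  n <- length(chars)
  out <- numeric(400)
  k <- 0
  for (a1 in AA_ORACLE) for (a2 in AA_ORACLE) {
    k <- k + 1
    obs <- 0
    for (i in seq_len(n - 1)) if (chars[i] == a1 && chars[i + 1] == a2) obs <- obs + 1
    dc <- obs / (n - 1)
    tm <- (codons[[a1]] / 61) * (codons[[a2]] / 61)
    tv <- tm * (1 - tm) / (n - 1)
    out[k] <- (dc - tm) / sqrt(tv)
  }
  out
}

# group tables re-entered independently from the same published partitions
oracle_ctd_groups <- function() {
  list(
    hydrophobicity_PRAM900101 = c("RKEDQN", "GASTPHY", "CLVIMFW"),
    hydrophobicity_ARGP820101 = c("QSTNGDE", "RAHCKMV", "LYPFIW"),
    hydrophobicity_ZIMJ680101 = c("QNGSWTDERA", "HMCKV", "LPFYI"),
    hydrophobicity_PONP930101 = c("KPDESNQT", "GRHA", "YMFWLCVI"),
    hydrophobicity_CASG920101 = c("KDEQPSRNTG", "AHYMLV", "FIWC"),
    hydrophobicity_ENGD860101 = c("RDKENQHYP", "SGTAW", "CVLIMF"),
    hydrophobicity_FASG890101 = c("KERSQD", "NTPG", "AYHWVMFLIC"),
    normwaalsvolume           = c("GASTPDC", "NVEQIL", "MHKFRYW"),
    polarity                  = c("LIFWCMVY", "PATGS", "HQRKNED"),
    polarizability            = c("GASDT", "CPNVEQIL", "KMHFRYW"),
    charge                    = c("KR", "ANCQGHILMFPSTWYV", "DE"),
    secondarystruct           = c("EALMQKRH", "VIYCWFT", "GNPSD"),
    solventaccess             = c("ALFCGIVW", "RKQEND", "MPSTHY")
  )
}

oracle_ctdc <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  chars <- chars[chars %in% AA_ORACLE]
  unlist(lapply(oracle_ctd_groups(), function(gr) {
    vapply(gr, function(g) {
      mean(chars %in% strsplit(g, "")[[1]])
    }, numeric(1))
  }), use.names = FALSE)
}

oracle_ctdd <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  chars <- chars[chars %in% AA_ORACLE]
  n <- length(chars)
  unlist(lapply(oracle_ctd_groups(), function(gr) {
    unlist(lapply(gr, function(g) {
      pos <- which(chars %in% strsplit(g, "")[[1]])
      if (length(pos) == 0) return(rep(0, 5))
      picks <- c(1, pmax(1, floor(length(pos) * c(0.25, 0.5, 0.75, 1))))
      100 * pos[picks] / n
    }))
  }), use.names = FALSE)
}

oracle_apaac <- function(seq, lambda, weight) {
  h1raw <- c(A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48,
             H = -0.40, I = 1.38, K = -1.50, L = 1.06, M = 0.64, N = -0.78,
             P = 0.12, Q = -0.85, R = -2.53, S = -0.18, T = -0.05, V = 1.08,
             W = 0.81, Y = 0.26)
  h2raw <- c(A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0,
             H = -0.5, I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2,
             P = 0.0, Q = 0.2, R = 3.0, S = 0.3, T = -0.4, V = -1.5,
             W = -3.4, Y = -2.3)
  std <- function(h) (h - mean(h)) / sqrt(sum((h - mean(h))^2) / 20)
  h1 <- std(h1raw[AA_ORACLE]); h2 <- std(h2raw[AA_ORACLE])
  chars <- strsplit(seq, "")[[1]]
  chars <- chars[chars %in% AA_ORACLE]
  n <- length(chars)
  tau <- c()
  for (j in seq_len(lambda)) {
    t1 <- 0; t2 <- 0
    for (i in seq_len(n - j)) {
      t1 <- t1 + h1[[chars[i]]] * h1[[chars[i + j]]]
      t2 <- t2 + h2[[chars[i]]] * h2[[chars[i + j]]]
    }
    tau <- c(tau, t1 / (n - j), t2 / (n - j))
  }
  f <- vapply(AA_ORACLE, function(a) sum(chars == a) / n, numeric(1))
  denom <- 1 + weight * sum(tau)
  c(f / denom, weight * tau / denom)
}

oracle_softmax_pool <- function(H, W_k, b_k, u_s, mask) {
  n <- nrow(H)
  scores <- numeric(n)
  for (k in seq_len(n)) {
    u <- tanh(W_k %*% H[k, ] + b_k)
    scores[k] <- sum(u * u_s)
  }
  e <- ifelse(mask, exp(scores), 0)
  alpha <- e / sum(e)
  V <- numeric(ncol(H))
  for (k in seq_len(n)) V <- V + alpha[k] * H[k, ]
  list(V = V, alpha = alpha)
}

oracle_auroc <- function(scores, labels) {
  ps <- scores[labels == 1]; ns <- scores[labels == 0]
  tot <- 0
  for (p in ps) for (q in ns) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(ps) * length(ns))
}

# labeled scores realizing a given confusion matrix at threshold 0.5
scores_for_confusion <- function(tp, fp, fn, tn) {
  list(scores = c(rep(0.9, tp), rep(0.9, fp), rep(0.1, fn), rep(0.1, tn)),
       labels = c(rep(1, tp), rep(0, fp), rep(1, fn), rep(0, tn)))
}

tiny_model_config <- function(cell = "lstm", attention = TRUE) {
  model_config(cell = cell, attention = attention, embed_dim = 8L,
               hidden_per_direction = 6L, fc_hidden = 4L)
}
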