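sigmoid <- function(x) 1 / (1 + exp(-x))

# add a bias vector b to every row of matrix G (column-major recycling)
add_bias <- function(G, b) {
  G + rep(b, each = nrow(G))
}

# uniform init in [-k, k], the usual recurrent-layer default
runif_mat <- function(nr, nc, k) {
  matrix(stats::runif(nr * nc, -k, k), nr, nc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
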