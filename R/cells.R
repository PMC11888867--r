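# Batched recurrent cells (RNN / GRU / LSTM) with masking and analytic
# backprop. Each forward runs one direction over a padded batch; a boolean
# mask makes padded timesteps carry the previous state through unchanged, so
# hidden trajectories (and hence gradients) are invariant to padding length.
#
# Conventions: X is a list over timesteps of n x input matrices; mask is an
# n x L logical matrix with all TRUE entries leading; H[[t]] is the hidden
# state at position t after its update. For a reversed pass the recurrence
# visits t = L..1, so H[[t]] is the backward-direction state at position t.

cell_param_names <- function(cell, direction) {
  base <- switch(cell,
                 lstm = c("W", "b"),
                 rnn  = c("W", "b"),
                 gru  = c("Wi", "Wh", "bi", "bh"),
                 stop("unknown cell type: ", cell, call. = FALSE))
  paste0(direction, "_", base)
}

init_cell_params <- function(cell, input_dim, hidden) {
  k <- 1 / sqrt(hidden)
  switch(cell,
    lstm = list(W = runif_mat(hidden + input_dim, 4L * hidden, k),
                b = stats::runif(4L * hidden, -k, k)),
    rnn  = list(W = runif_mat(hidden + input_dim, hidden, k),
                b = stats::runif(hidden, -k, k)),
    gru  = list(Wi = runif_mat(input_dim, 3L * hidden, k),
                Wh = runif_mat(hidden, 3L * hidden, k),
                bi = stats::runif(3L * hidden, -k, k),
                bh = stats::runif(3L * hidden, -k, k)))
}

cell_forward <- function(cell, p, X, mask, reverse = FALSE) {
  n <- nrow(mask); L <- ncol(mask)
  hidden <- switch(cell, lstm = ncol(p$W) / 4L, gru = ncol(p$Wh) / 3L,
                   rnn = ncol(p$W))
  times <- if (reverse) rev(seq_len(L)) else seq_len(L)
  h <- matrix(0, n, hidden)
  C <- matrix(0, n, hidden)
  H <- vector("list", L)
  cache <- vector("list", L)
  i1 <- seq_len(hidden); i2 <- hidden + i1; i3 <- 2L * hidden + i1; i4 <- 3L * hidden + i1

  for (t in times) {
    m <- mask[, t]
    if (cell == "lstm") {
      a <- cbind(h, X[[t]])
      G <- add_bias(a %*% p$W, p$b)
      f <- sigmoid(G[, i1, drop = FALSE]); i <- sigmoid(G[, i2, drop = FALSE])
      g <- tanh(G[, i3, drop = FALSE]);    o <- sigmoid(G[, i4, drop = FALSE])
      Cc <- f * C + i * g
      tc <- tanh(Cc)
      hc <- o * tc
      cache[[t]] <- list(a = a, f = f, i = i, g = g, o = o,
                         Cprev = C, tc = tc, m = m)
      C <- m * Cc + (1 - m) * C
    } else if (cell == "gru") {
      Gi <- add_bias(X[[t]] %*% p$Wi, p$bi)
      Gh <- add_bias(h %*% p$Wh, p$bh)
      r <- sigmoid(Gi[, i1, drop = FALSE] + Gh[, i1, drop = FALSE])
      z <- sigmoid(Gi[, i2, drop = FALSE] + Gh[, i2, drop = FALSE])
      q <- Gh[, i3, drop = FALSE]
      nc <- tanh(Gi[, i3, drop = FALSE] + r * q)
      hc <- (1 - z) * nc + z * h
      cache[[t]] <- list(x = X[[t]], hprev = h, r = r, z = z, q = q, nc = nc, m = m)
    } else { # rnn
      a <- cbind(h, X[[t]])
      hc <- tanh(add_bias(a %*% p$W, p$b))
      cache[[t]] <- list(a = a, hc = hc, m = m)
    }
    h <- m * hc + (1 - m) * h
    H[[t]] <- h
  }
  list(H = H, h_last = h, cache = cache, times = times, hidden = hidden)
}

# dH: list over positions of n x hidden gradients (or NULL entries);
# dh_last: gradient on the final state (after the whole pass), or NULL.
cell_backward <- function(cell, p, fwd, dH, dh_last = NULL) {
  L <- length(fwd$H)
  hidden <- fwd$hidden
  n <- nrow(fwd$H[[1]])
  input_dim <- switch(cell, gru = nrow(p$Wi),
                      nrow(p$W) - hidden)
  i1 <- seq_len(hidden); i2 <- hidden + i1; i3 <- 2L * hidden + i1; i4 <- 3L * hidden + i1

  grads <- purrr::map(p, function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x)))
  dX <- vector("list", L)
  dh <- if (is.null(dh_last)) matrix(0, n, hidden) else dh_last
  dC <- matrix(0, n, hidden)

  for (t in rev(fwd$times)) {
    if (!is.null(dH[[t]])) dh <- dh + dH[[t]]
    cc <- fwd$cache[[t]]
    m <- cc$m
    dhc <- m * dh
    dh_prev <- (1 - m) * dh
    if (cell == "lstm") {
      dCc <- m * dC + dhc * cc$o * (1 - cc$tc^2)
      dC <- (1 - m) * dC + dCc * cc$f
      do_ <- dhc * cc$tc
      df <- dCc * cc$Cprev
      di <- dCc * cc$g
      dg <- dCc * cc$i
      dG <- cbind(df * cc$f * (1 - cc$f), di * cc$i * (1 - cc$i),
                  dg * (1 - cc$g^2), do_ * cc$o * (1 - cc$o))
      grads$W <- grads$W + crossprod(cc$a, dG)
      grads$b <- grads$b + colSums(dG)
      da <- tcrossprod(dG, p$W)
      dh <- dh_prev + da[, i1, drop = FALSE]
      dX[[t]] <- da[, hidden + seq_len(input_dim), drop = FALSE]
    } else if (cell == "gru") {
      dz <- dhc * (cc$hprev - cc$nc)
      dnc <- dhc * (1 - cc$z)
      dh_prev <- dh_prev + dhc * cc$z
      dnpre <- dnc * (1 - cc$nc^2)
      dr <- dnpre * cc$q
      dq <- dnpre * cc$r
      drpre <- dr * cc$r * (1 - cc$r)
      dzpre <- dz * cc$z * (1 - cc$z)
      dGi <- cbind(drpre, dzpre, dnpre)
      dGh <- cbind(drpre, dzpre, dq)
      grads$Wi <- grads$Wi + crossprod(cc$x, dGi)
      grads$Wh <- grads$Wh + crossprod(cc$hprev, dGh)
      grads$bi <- grads$bi + colSums(dGi)
      grads$bh <- grads$bh + colSums(dGh)
      dh <- dh_prev + tcrossprod(dGh, p$Wh)
      dX[[t]] <- tcrossprod(dGi, p$Wi)
    } else { # rnn
      dpre <- dhc * (1 - cc$hc^2)
      grads$W <- grads$W + crossprod(cc$a, dpre)
      grads$b <- grads$b + colSums(dpre)
      da <- tcrossprod(dpre, p$W)
      dh <- dh_prev + da[, i1, drop = FALSE]
      dX[[t]] <- da[, hidden + seq_len(input_dim), drop = FALSE]
    }
  }
  list(grads = grads, dX = dX)
}
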