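#' Model configuration
#'
#' Architecture hyperparameters for the recurrent amyloid classifier:
#' embedding over the 21-token vocabulary, a (bi)directional recurrent
#' encoder, attention pooling (or final-state pooling), and a fully
#' connected head with 1-D batch normalization. With defaults the pooled
#' representation is 2 x 64 = 128 wide.
#'
#' @param vocab_size Vocabulary size (default 21: 20 residues + pad/unknown).
#' @param embed_dim Embedding dimension (default 100).
#' @param cell Recurrent cell: `"lstm"`, `"gru"` or `"rnn"`.
#' @param bidirectional Run the encoder in both directions (default `TRUE`).
#' @param hidden_per_direction Hidden units per direction (default 64).
#' @param attention Use attention pooling (default `TRUE`); when `FALSE` the
#'   concatenated final forward/backward states are pooled instead.
#' @param fc_hidden Width of the hidden fully connected layer (default 64).
#' @param max_len Tokenizer truncation limit carried with the model.
#' @return An `amyl_config` list.
#' @export
model_config <- function(vocab_size = 21L, embed_dim = 100L,
                         cell = c("lstm", "gru", "rnn"),
                         bidirectional = TRUE, hidden_per_direction = 64L,
                         attention = TRUE, fc_hidden = 64L, max_len = 1000L) {
  cell <- match.arg(cell)
  stopifnot(vocab_size >= 2L, embed_dim >= 1L, hidden_per_direction >= 1L,
            fc_hidden >= 1L, max_len >= 1L)
  structure(list(vocab_size = as.integer(vocab_size),
                 embed_dim = as.integer(embed_dim), cell = cell,
                 bidirectional = isTRUE(bidirectional),
                 hidden_per_direction = as.integer(hidden_per_direction),
                 attention = isTRUE(attention),
                 fc_hidden = as.integer(fc_hidden),
                 max_len = as.integer(max_len)),
            class = "amyl_config")
}

pooled_dim <- function(config) {
  config$hidden_per_direction * (1L + config$bidirectional)
}

#' Build a randomly initialized classifier model
#'
#' Assembles the pipeline embedding -> recurrent encoder -> attention pool
#' (or final-state pooling) -> FC -> BatchNorm1D -> ReLU -> FC -> sigmoid.
#' The pad/unknown embedding row is pinned at zero and never trained, so
#' together with masked recurrence and masked attention the model is exactly
#' invariant to padding length.
#'
#' @param config An [model_config()] object.
#' @param seed Integer seed for weight initialization.
#' @return An `amyl_model`: list with `config`, `params` (trainable arrays)
#'   and `state` (batch-norm running statistics).
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "amyl_config"))
  params <- withr::with_seed(seed, init_model_params(config))
  structure(list(config = config, params = params,
                 state = list(bn_mean = numeric(config$fc_hidden),
                              bn_var = rep(1, config$fc_hidden),
                              bn_eps = 1e-5, bn_momentum = 0.1)),
            class = "amyl_model")
}

init_model_params <- function(config) {
  D <- pooled_dim(config)
  p <- list(E = rbind(0, runif_mat(config$vocab_size - 1L, config$embed_dim, 1)))
  dirs <- c("fwd", if (config$bidirectional) "bwd")
  for (d in dirs) {
    cp <- init_cell_params(config$cell, config$embed_dim, config$hidden_per_direction)
    names(cp) <- paste0(d, "_", names(cp))
    p <- c(p, cp)
  }
  if (config$attention) {
    k <- 1 / sqrt(D)
    p$att_Wk <- runif_mat(D, D, k)
    p$att_bk <- stats::runif(D, -k, k)
    p$att_us <- stats::runif(D, -k, k)
  }
  kf <- 1 / sqrt(D)
  p$fc1_W <- runif_mat(D, config$fc_hidden, kf)
  p$fc1_b <- stats::runif(config$fc_hidden, -kf, kf)
  p$bn_gamma <- rep(1, config$fc_hidden)
  p$bn_beta <- numeric(config$fc_hidden)
  k2 <- 1 / sqrt(config$fc_hidden)
  p$fc2_W <- runif_mat(config$fc_hidden, 1L, k2)
  p$fc2_b <- stats::runif(1L, -k2, k2)
  p
}

#' @export
print.amyl_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<amyl_model> %s%s%s: vocab %d, embed %d, hidden %d/dir (pooled %d), fc %d\n",
              if (cfg$bidirectional) "bi-" else "", cfg$cell,
              if (cfg$attention) " + attention" else "",
              cfg$vocab_size, cfg$embed_dim, cfg$hidden_per_direction,
              pooled_dim(cfg), cfg$fc_hidden))
  invisible(x)
}

# Full forward pass. train = TRUE uses batch statistics for BN (and updates
# running stats in the returned state); eval mode uses running statistics.
model_forward <- function(params, config, state, batch, train = FALSE) {
  idx <- batch$indices; mask <- 1 * batch$mask
  n <- nrow(idx); L <- ncol(idx)
  if (any(idx >= config$vocab_size)) {
    stop("token index out of vocabulary (>= ", config$vocab_size, ")", call. = FALSE)
  }
  X <- lapply(seq_len(L), function(t) params$E[idx[, t] + 1L, , drop = FALSE])

  fwd <- cell_forward(config$cell,
                      params_for_direction(params, config$cell, "fwd"),
                      X, mask, reverse = FALSE)
  bwd <- if (config$bidirectional) {
    cell_forward(config$cell, params_for_direction(params, config$cell, "bwd"),
                 X, mask, reverse = TRUE)
  }
  H <- lapply(seq_len(L), function(t) {
    if (is.null(bwd)) fwd$H[[t]] else cbind(fwd$H[[t]], bwd$H[[t]])
  })

  if (config$attention) {
    D <- pooled_dim(config)
    U <- vector("list", L)
    S <- matrix(-Inf, n, L)
    for (t in seq_len(L)) {
      U[[t]] <- tanh(add_bias(H[[t]] %*% params$att_Wk, params$att_bk))
      S[, t] <- U[[t]] %*% params$att_us
    }
    S[batch$mask == 0] <- -Inf
    Smax <- apply(S, 1, max)
    A <- exp(S - Smax)
    A[batch$mask == 0] <- 0
    A <- A / rowSums(A)
    V <- matrix(0, n, D)
    for (t in seq_len(L)) V <- V + A[, t] * H[[t]]
    att_cache <- list(U = U, A = A)
  } else {
    # final-state pooling: forward state frozen at the true end by the carry
    # mask; backward state at position 1 spans the whole sequence
    V <- if (is.null(bwd)) fwd$h_last else cbind(fwd$h_last, bwd$h_last)
    att_cache <- NULL
  }

  Z1 <- add_bias(V %*% params$fc1_W, params$fc1_b)
  if (train) {
    if (n < 2L) stop("batch normalization needs batch size >= 2 in training", call. = FALSE)
    mu <- colMeans(Z1)
    va <- colMeans(Z1^2) - mu^2
    mom <- state$bn_momentum
    state$bn_mean <- (1 - mom) * state$bn_mean + mom * mu
    state$bn_var <- (1 - mom) * state$bn_var + mom * va * n / (n - 1)
  } else {
    mu <- state$bn_mean
    va <- state$bn_var
  }
  sd_ <- sqrt(va + state$bn_eps)
  xhat <- sweep(sweep(Z1, 2, mu, "-"), 2, sd_, "/")
  bnout <- add_bias(xhat * rep(params$bn_gamma, each = n), params$bn_beta)
  R <- pmax(bnout, 0)
  z2 <- drop(add_bias(R %*% params$fc2_W, params$fc2_b))
  prob <- sigmoid(z2)

  list(prob = prob, state = state,
       cache = list(X = X, fwd = fwd, bwd = bwd, H = H, att = att_cache,
                    V = V, Z1 = Z1, xhat = xhat, sd_ = sd_, bnout = bnout,
                    R = R, idx = idx, mask = mask, n = n, L = L))
}

params_for_direction <- function(params, cell, direction) {
  nm <- cell_param_names(cell, direction)
  out <- params[nm]
  names(out) <- sub(paste0("^", direction, "_"), "", nm)
  out
}

bce_loss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Backward pass for mean BCE loss; returns gradients for every trainable
# parameter (same names/shapes as params).
model_backward <- function(params, config, cache, prob, y) {
  n <- cache$n; L <- cache$L
  D <- pooled_dim(config)
  grads <- list()

  dz2 <- matrix((prob - y) / n, ncol = 1)           # sigmoid + BCE shortcut
  grads$fc2_W <- crossprod(cache$R, dz2)
  grads$fc2_b <- sum(dz2)
  dR <- tcrossprod(dz2, params$fc2_W)
  dbn <- dR * (cache$bnout > 0)
  grads$bn_gamma <- colSums(dbn * cache$xhat)
  grads$bn_beta <- colSums(dbn)
  dxhat <- dbn * rep(params$bn_gamma, each = n)
  # batch statistics were used in training mode; backprop through them
  dz1 <- sweep(dxhat, 2, colMeans(dxhat), "-") -
    cache$xhat * rep(colMeans(dxhat * cache$xhat), each = n)
  dz1 <- sweep(dz1, 2, cache$sd_, "/")
  grads$fc1_W <- crossprod(cache$V, dz1)
  grads$fc1_b <- colSums(dz1)
  dV <- tcrossprod(dz1, params$fc1_W)

  dH <- vector("list", L)
  dh_last_fwd <- dh_last_bwd <- NULL
  if (config$attention) {
    A <- cache$att$A
    dA <- matrix(0, n, L)
    for (t in seq_len(L)) {
      dH[[t]] <- A[, t] * dV
      dA[, t] <- rowSums(dV * cache$H[[t]])
    }
    dS <- A * (dA - rowSums(A * dA))
    grads$att_Wk <- matrix(0, D, D)
    grads$att_bk <- numeric(D)
    grads$att_us <- numeric(D)
    for (t in seq_len(L)) {
      if (all(dS[, t] == 0)) next
      U <- cache$att$U[[t]]
      grads$att_us <- grads$att_us + drop(crossprod(U, dS[, t]))
      dU <- dS[, t] %*% t(params$att_us)
      dpre <- dU * (1 - U^2)
      grads$att_Wk <- grads$att_Wk + crossprod(cache$H[[t]], dpre)
      grads$att_bk <- grads$att_bk + colSums(dpre)
      dH[[t]] <- dH[[t]] + tcrossprod(dpre, params$att_Wk)
    }
  } else {
    hd <- config$hidden_per_direction
    dh_last_fwd <- dV[, seq_len(hd), drop = FALSE]
    if (config$bidirectional) dh_last_bwd <- dV[, hd + seq_len(hd), drop = FALSE]
  }

  hd <- config$hidden_per_direction
  dH_fwd <- lapply(dH, function(g) if (is.null(g)) NULL else g[, seq_len(hd), drop = FALSE])
  dH_bwd <- if (config$bidirectional) {
    lapply(dH, function(g) if (is.null(g)) NULL else g[, hd + seq_len(hd), drop = FALSE])
  }

  pf <- params_for_direction(params, config$cell, "fwd")
  bf <- cell_backward(config$cell, pf, cache$fwd, dH_fwd, dh_last_fwd)
  for (nm in names(bf$grads)) grads[[paste0("fwd_", nm)]] <- bf$grads[[nm]]
  dX <- bf$dX
  if (config$bidirectional) {
    pb <- params_for_direction(params, config$cell, "bwd")
    bb <- cell_backward(config$cell, pb, cache$bwd, dH_bwd, dh_last_bwd)
    for (nm in names(bb$grads)) grads[[paste0("bwd_", nm)]] <- bb$grads[[nm]]
    for (t in seq_len(L)) dX[[t]] <- dX[[t]] + bb$dX[[t]]
  }

  dE <- matrix(0, config$vocab_size, config$embed_dim)
  for (t in seq_len(L)) {
    gt <- rowsum(dX[[t]], group = cache$idx[, t])
    rows <- as.integer(rownames(gt)) + 1L
    dE[rows, ] <- dE[rows, ] + gt
  }
  dE[1, ] <- 0  # pad/unknown embedding is frozen at zero
  grads$E <- dE
  grads
}

#' Predict amyloid probabilities
#'
#' Runs the model in evaluation mode (batch-norm running statistics, no
#' dropout anywhere) and returns one probability per sequence.
#'
#' @param model An `amyl_model` (possibly trained) or `amyl_fit`.
#' @param new_data A record tibble or an `amyl_batch`.
#' @return A tibble with `id`, `prob` and `pred` (label at threshold 0.5),
#'   plus `label` when known.
#' @export
predict_proba <- function(model, new_data) {
  model <- as_amyl_model(model)
  batch <- as_amyl_batch(new_data, model$config)
  out <- model_forward(model$params, model$config, model$state, batch, train = FALSE)
  tibble::tibble(id = batch$ids %||% paste0("s", seq_along(out$prob)),
                 label = if (is.null(batch$labels)) NA_integer_ else batch$labels,
                 prob = unname(out$prob),
                 pred = as.integer(out$prob >= 0.5))
}

#' Extract attention weights
#'
#' @inheritParams predict_proba
#' @return A tibble in long form: `id`, `position`, `residue`, `alpha`.
#'   Padded positions are omitted (their weight is exactly 0).
#' @export
predict_attention <- function(model, new_data) {
  model <- as_amyl_model(model)
  if (!model$config$attention) stop("model was built without attention", call. = FALSE)
  batch <- as_amyl_batch(new_data, model$config)
  out <- model_forward(model$params, model$config, model$state, batch, train = FALSE)
  A <- out$cache$att$A
  seqs <- detokenize(batch)
  ids <- batch$ids %||% paste0("s", seq_len(nrow(A)))
  purrr::map_dfr(seq_len(nrow(A)), function(i) {
    len <- batch$lengths[i]
    tibble::tibble(id = ids[i], position = seq_len(len),
                   residue = strsplit(seqs[i], "")[[1]],
                   alpha = A[i, seq_len(len)])
  })
}

as_amyl_model <- function(x) {
  if (inherits(x, "amyl_fit")) x$model
  else if (inherits(x, "amyl_model")) x
  else stop("expected an amyl_model or amyl_fit", call. = FALSE)
}

as_amyl_batch <- function(x, config) {
  if (inherits(x, "amyl_batch")) x else tokenize(x, max_len = config$max_len)
}
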