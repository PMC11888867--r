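#' Training configuration
#'
#' The optimization protocol: Adam at learning rate 0.001, binary
#' cross-entropy loss, up to 40 epochs, with the returned weights taken from
#' the epoch of minimum validation loss.
#'
#' @param learning_rate Adam step size (default 0.001).
#' @param max_epochs Maximum training epochs (default 40).
#' @param batch_size Minibatch size (default 32; a trailing singleton batch
#'   is merged into its predecessor so batch normalization always sees at
#'   least 2 samples).
#' @param seed Integer seed covering initialization and shuffling.
#' @return An `amyl_train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, max_epochs = 40L,
                         batch_size = 32L, seed = 1L) {
  stopifnot(learning_rate > 0, max_epochs >= 1L, batch_size >= 2L)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "amyl_train_config")
}

#' Train the recurrent classifier
#'
#' Minimizes mean binary cross-entropy with Adam over minibatches, computing
#' the validation loss after every epoch and returning the weights from the
#' epoch where it was lowest. Fully reproducible given the seed.
#'
#' @param train_data,val_data Labeled record tibbles (or `amyl_batch`es).
#' @param config An [model_config()].
#' @param train_cfg A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return An `amyl_fit`: list with `model` (best-epoch weights), `history`
#'   (tibble of per-epoch train/val losses), `best_epoch`, `config` and
#'   `train_config`.
#' @export
train <- function(train_data, val_data, config = model_config(),
                  train_cfg = train_config(), verbose = FALSE) {
  train_batch <- as_amyl_batch(train_data, config)
  val_batch <- as_amyl_batch(val_data, config)
  if (is.null(train_batch$labels) || is.null(val_batch$labels)) {
    stop("training and validation data must be labeled", call. = FALSE)
  }
  n <- nrow(train_batch$indices)
  if (n < 2L) stop("training set must have at least 2 sequences", call. = FALSE)

  withr::with_seed(train_cfg$seed, {
    params <- init_model_params(config)
    state <- list(bn_mean = numeric(config$fc_hidden),
                  bn_var = rep(1, config$fc_hidden),
                  bn_eps = 1e-5, bn_momentum = 0.1)
    opt <- adam_init(params, lr = train_cfg$learning_rate)

    history <- vector("list", train_cfg$max_epochs)
    best <- list(val_loss = Inf, params = params, state = state, epoch = 0L)

    for (epoch in seq_len(train_cfg$max_epochs)) {
      perm <- sample.int(n)
      chunks <- split(perm, ceiling(seq_along(perm) / train_cfg$batch_size))
      if (length(chunks) > 1L && length(chunks[[length(chunks)]]) == 1L) {
        k <- length(chunks)
        chunks[[k - 1L]] <- c(chunks[[k - 1L]], chunks[[k]])
        chunks[[k]] <- NULL
      }
      epoch_loss <- 0
      for (ch in chunks) {
        b <- batch_subset(train_batch, ch)
        fw <- model_forward(params, config, state, b, train = TRUE)
        state <- fw$state
        loss <- bce_loss(fw$prob, b$labels)
        if (!is.finite(loss)) {
          stop("training diverged (non-finite loss) at epoch ", epoch, call. = FALSE)
        }
        grads <- model_backward(params, config, fw$cache, fw$prob, b$labels)
        upd <- adam_step(opt, params, grads)
        params <- upd$params
        params$E[1, ] <- 0
        opt <- upd$opt
        epoch_loss <- epoch_loss + loss * length(ch)
      }
      train_loss <- epoch_loss / n
      val_fw <- model_forward(params, config, state, val_batch, train = FALSE)
      val_loss <- bce_loss(val_fw$prob, val_batch$labels)
      if (!is.finite(val_loss)) {
        stop("training diverged (non-finite validation loss) at epoch ", epoch,
             call. = FALSE)
      }
      history[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = train_loss,
                                         val_loss = val_loss)
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch, train_loss, val_loss))
      }
      if (val_loss < best$val_loss) {
        best <- list(val_loss = val_loss, params = params, state = state,
                     epoch = epoch)
      }
    }
  })

  model <- structure(list(config = config, params = best$params,
                          state = best$state),
                     class = "amyl_model")
  structure(list(model = model,
                 history = dplyr::bind_rows(history),
                 best_epoch = best$epoch,
                 config = config, train_config = train_cfg),
            class = "amyl_fit")
}

#' @export
print.amyl_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf("trained %d epochs, best validation loss %.4f at epoch %d\n",
              nrow(x$history), min(x$history$val_loss), x$best_epoch))
  invisible(x)
}

# --- Adam ---------------------------------------------------------------

adam_init <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = purrr::map(params, zero_like), v = purrr::map(params, zero_like))
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g * g
    params[[nm]] <- params[[nm]] -
      opt$lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
  }
  list(opt = opt, params = params)
}
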