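#' Reference LSTM cell step
#'
#' A literal, per-gate implementation of the LSTM recurrence used as the
#' package's ground truth for the vectorized training cell:
#' \deqn{f_t = \sigma(W_{forget}[h_{t-1}, x_t] + b_{forget})}
#' \deqn{i_t = \sigma(W_{input}[h_{t-1}, x_t] + b_{input})}
#' \deqn{O_t = \sigma(W_{output}[h_{t-1}, x_t] + b_{output})}
#' \deqn{L_t = \tanh(W_{cell}[h_{t-1}, x_t] + b_{cell})}
#' \deqn{C_t = f_t C_{t-1} + i_t L_t, \quad h_t = O_t \tanh(C_t)}
#'
#' @param params A list with weight matrices `W_forget`, `W_input`,
#'   `W_output`, `W_cell` (each `hidden x (hidden + input)`, acting on the
#'   concatenation `[h, x]`) and bias vectors `b_forget`, `b_input`,
#'   `b_output`, `b_cell` (each length `hidden`).
#' @param state A list with cell state `C` and hidden state `h` (numeric
#'   vectors of length `hidden`).
#' @param x Input vector at the current timestep.
#' @return The updated state: a list with `C` and `h`.
#' @examples
#' p <- lstm_cell_params(hidden = 2, input = 3, init = function(n) rep(0, n))
#' reference_lstm_step(p, list(C = c(0, 0), h = c(0, 0)), c(1, 2, 3))$h
#' @export
reference_lstm_step <- function(params, state, x) {
  hx <- c(state$h, x)
  dims_ok <- vapply(params[c("W_forget", "W_input", "W_output", "W_cell")],
                    function(W) ncol(W) == length(hx) && nrow(W) == length(state$h),
                    logical(1))
  if (!all(dims_ok)) {
    stop("dimension mismatch in ", names(dims_ok)[!dims_ok][1],
         ": expected ", length(state$h), " x ", length(hx), call. = FALSE)
  }
  f <- sigmoid(drop(params$W_forget %*% hx) + params$b_forget)
  i <- sigmoid(drop(params$W_input  %*% hx) + params$b_input)
  o <- sigmoid(drop(params$W_output %*% hx) + params$b_output)
  l <- tanh(drop(params$W_cell %*% hx) + params$b_cell)
  C <- f * state$C + i * l
  list(C = C, h = o * tanh(C))
}

#' Construct reference LSTM cell parameters
#'
#' @param hidden Hidden dimension.
#' @param input Input dimension.
#' @param init A function `n -> numeric(n)` drawing initial values
#'   (default standard normal).
#' @return Parameter list for [reference_lstm_step()].
#' @export
lstm_cell_params <- function(hidden, input, init = stats::rnorm) {
  W <- function() matrix(init(hidden * (hidden + input)), hidden, hidden + input)
  b <- function() init(hidden)
  list(W_forget = W(), W_input = W(), W_output = W(), W_cell = W(),
       b_forget = b(), b_input = b(), b_output = b(), b_cell = b())
}

#' Attention pooling over hidden states
#'
#' Scores each position's hidden state through a learned tanh transform
#' against a context vector, softmax-normalizes the scores over unmasked
#' positions, and returns the weighted sum of hidden states:
#' \deqn{u_k = \tanh(W_k h_k + b_k), \quad
#'       \alpha_k = \frac{\exp(u_k^T u_s)}{\sum_j \exp(u_j^T u_s)}, \quad
#'       V = \sum_k \alpha_k h_k.}
#' Masked-out (padded) positions receive weight exactly 0.
#'
#' @param H Matrix of hidden states, one row per position (`n x d`).
#' @param params List with `W_k` (`d x d`), `b_k` (length `d`) and the
#'   context vector `u_s` (length `d`); see [attention_params()].
#' @param mask Logical vector of length `n`; `TRUE` marks real positions.
#' @return A list with `V` (length-`d` context vector) and `alpha`
#'   (length-`n` weights summing to 1 over unmasked positions).
#' @examples
#' H <- matrix(rnorm(12), 3, 4)
#' ap <- attention_params(4, seed = 1)
#' attention_pool(H, ap)$alpha
#' @export
attention_pool <- function(H, params, mask = rep(TRUE, nrow(H))) {
  stopifnot(is.matrix(H), length(mask) == nrow(H))
  if (!any(mask)) stop("attention over an all-masked (empty) sequence", call. = FALSE)
  U <- tanh(add_bias(H %*% params$W_k, params$b_k))
  s <- drop(U %*% params$u_s)
  s[!mask] <- -Inf
  e <- exp(s - max(s))
  alpha <- e / sum(e)
  list(V = drop(crossprod(H, alpha)), alpha = alpha)
}

#' @rdname attention_pool
#' @param d Hidden-state width.
#' @param seed Seed for the random initialization.
#' @export
attention_params <- function(d, seed = NULL) {
  draw <- function() {
    k <- 1 / sqrt(d)
    list(W_k = runif_mat(d, d, k), b_k = stats::runif(d, -k, k),
         u_s = stats::runif(d, -k, k))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
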