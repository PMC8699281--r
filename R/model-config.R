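# Model and training configuration, closed-form parameter accounting, and
# the warmup/decay learning-rate schedule.

#' Encoder-decoder model hyperparameters
#'
#' Defaults correspond to the full-scale peaks-to-SMILES translation model:
#' 12 + 12 layers of width 1024 with 16 attention heads, feed-forward width
#' 4096, 20% dropout, a bin-index input embedding over 50,000 m/z bins (plus
#' one padding row), and a 69-token SMILES output vocabulary. Positions are
#' encoded with fixed sinusoids (no learned positional parameters) and the
#' output projection is untied from the target embedding.
#'
#' @param n_encoder_layers,n_decoder_layers Number of layers (default 12).
#' @param d_model Embedding/sub-layer width (default 1024).
#' @param n_heads Attention heads; must divide `d_model` (default 16).
#' @param d_ff Position-wise feed-forward width (default 4096).
#' @param dropout Dropout probability in [0, 1) (default 0.20).
#' @param n_bins Input vocabulary size = number of m/z bins (default 50000).
#' @param vocab_size Output vocabulary size (default 69).
#' @param max_input_len Maximum number of input bins (default 100).
#' @param max_output_len Maximum SMILES token length at decode (default 150).
#' @return List of class `model_config`.
#' @export
model_config <- function(n_encoder_layers = 12L, n_decoder_layers = 12L,
                         d_model = 1024L, n_heads = 16L, d_ff = 4096L,
                         dropout = 0.20, n_bins = 50000L, vocab_size = 69L,
                         max_input_len = 100L, max_output_len = 150L) {
  if (d_model %% n_heads != 0L)
    stop("d_model (", d_model, ") must be divisible by n_heads (", n_heads, ")")
  stopifnot(dropout >= 0, dropout < 1, n_encoder_layers >= 1,
            n_decoder_layers >= 1, vocab_size >= 5, n_bins >= 1)
  structure(list(n_encoder_layers = as.integer(n_encoder_layers),
                 n_decoder_layers = as.integer(n_decoder_layers),
                 d_model = as.integer(d_model), n_heads = as.integer(n_heads),
                 d_ff = as.integer(d_ff), dropout = dropout,
                 n_bins = as.integer(n_bins),
                 vocab_size = as.integer(vocab_size),
                 max_input_len = as.integer(max_input_len),
                 max_output_len = as.integer(max_output_len)),
            class = "model_config")
}

#' Count trainable parameters
#'
#' For a `model_config` the count is computed in closed form without
#' allocating any weights; for a built `seq2seq_model` the actual parameter
#' arrays are summed. The two agree exactly.
#'
#' Per layer: an attention block holds the packed query/key/value input
#' projections and the output projection (`4 d^2 + 4 d`); the feed-forward
#' block holds `2 d d_ff + d_ff + d`; each layer norm holds gain and bias
#' (`2 d`). Encoder layers have one attention block and two norms, decoder
#' layers two attention blocks (self and cross) and three norms. Embeddings
#' add `(n_bins + 1) d` (input, with padding row) and `vocab_size * d`
#' (target); the untied output projection adds `d vocab_size + vocab_size`.
#'
#' @param x A [model_config()] or a model built by [build_model()].
#' @return Total number of trainable scalars.
#' @export
count_parameters <- function(x) UseMethod("count_parameters")

#' @export
count_parameters.model_config <- function(x) {
  d <- as.numeric(x$d_model)
  dff <- as.numeric(x$d_ff)
  v <- as.numeric(x$vocab_size)
  attn <- 4 * d * d + 4 * d
  ffn <- 2 * d * dff + dff + d
  ln <- 2 * d
  enc <- attn + ffn + 2 * ln
  dec <- 2 * attn + ffn + 3 * ln
  (x$n_bins + 1) * d + v * d +
    x$n_encoder_layers * enc + x$n_decoder_layers * dec +
    d * v + v
}

#' @export
count_parameters.seq2seq_model <- function(x) {
  total <- 0
  walk <- function(node) {
    if (is.list(node)) lapply(node, walk)
    else total <<- total + length(node)
    invisible(NULL)
  }
  walk(x$params)
  total
}

#' Optimization settings
#'
#' Adam with the standard transformer warmup/decay schedule. The learning
#' rate is scaled linearly with the batch size relative to `base_batch`, so
#' the defaults (896/896) give a scale factor of 1.
#'
#' @param batch_size Samples per batch (default 896).
#' @param beta1,beta2,eps Adam moments and stabilizer (0.9, 0.98, 1e-9).
#' @param warmup_steps Linear warmup length in optimizer steps (default
#'   8000).
#' @param base_batch Reference batch size for learning-rate scaling
#'   (default 896).
#' @param patience Epochs without validation improvement before stopping
#'   (default 10).
#' @param max_epochs Upper bound on training epochs (default 100).
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @return List of class `train_config`.
#' @export
train_config <- function(batch_size = 896L, beta1 = 0.9, beta2 = 0.98,
                         eps = 1e-9, warmup_steps = 8000L,
                         base_batch = 896L, patience = 10L,
                         max_epochs = 100L, seed = 1L) {
  stopifnot(warmup_steps >= 1L, patience >= 1L, batch_size >= 1L,
            base_batch >= 1L, max_epochs >= 1L)
  structure(list(batch_size = as.integer(batch_size), beta1 = beta1,
                 beta2 = beta2, eps = eps,
                 warmup_steps = as.integer(warmup_steps),
                 base_batch = as.integer(base_batch),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Warmup/decay learning rate at a given optimizer step
#'
#' `rate = factor * d_model^-0.5 * min(step^-0.5, step * warmup^-1.5)` with
#' `factor = batch_size / base_batch`: linear warmup to the peak at
#' `step = warmup_steps`, then inverse-square-root decay.
#'
#' @param step Optimizer step, >= 1.
#' @param d_model Model width.
#' @param config A [train_config()].
#' @return Learning rate.
#' @export
lr_schedule <- function(step, d_model, config = train_config()) {
  if (any(step < 1)) stop("step must be >= 1")
  factor <- config$batch_size / config$base_batch
  factor * d_model^-0.5 *
    pmin(step^-0.5, step * config$warmup_steps^-1.5)
}
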