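# Encoder-decoder attention network for bins-to-SMILES translation,
# implemented directly on base R matrices with hand-written reverse-mode
# gradients and an Adam optimizer. The architecture is the standard
# post-norm transformer: multi-head scaled dot-product attention, residual
# connections with layer norm, position-wise ReLU feed-forward blocks,
# sinusoidal positions, and an untied output projection.

sinusoid_positions <- function(max_len, d) {
  pos <- matrix(0, max_len, d)
  position <- 0:(max_len - 1)
  for (i in seq_len(ceiling(d / 2))) {
    freq <- 1 / 10000^((2 * (i - 1)) / d)
    pos[, 2 * i - 1] <- sin(position * freq)
    if (2 * i <= d) pos[, 2 * i] <- cos(position * freq)
  }
  pos
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

init_attn <- function(d) list(Wq = glorot(d, d), bq = numeric(d),
                              Wk = glorot(d, d), bk = numeric(d),
                              Wv = glorot(d, d), bv = numeric(d),
                              Wo = glorot(d, d), bo = numeric(d))
init_ffn <- function(d, dff) list(W1 = glorot(d, dff), b1 = numeric(dff),
                                  W2 = glorot(dff, d), b2 = numeric(d))
init_ln <- function(d) list(g = rep(1, d), b = numeric(d))

#' Build an encoder-decoder translation model
#'
#' Allocates and initializes all trainable parameters for the architecture
#' described in [model_config()]. Initialization is Glorot-uniform for
#' projection matrices and scaled normal for embeddings, controlled by
#' `seed`.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return List of class `seq2seq_model` with elements `config`, `params`
#'   and `posenc` (fixed sinusoidal position table, not trainable).
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  d <- config$d_model
  with_seed(seed, {
    params <- list(
      emb_in = matrix(stats::rnorm((config$n_bins + 1) * d, sd = 1 / sqrt(d)),
                      config$n_bins + 1, d),
      emb_out = matrix(stats::rnorm(config$vocab_size * d, sd = 1 / sqrt(d)),
                       config$vocab_size, d),
      enc = lapply(seq_len(config$n_encoder_layers), function(i)
        list(attn = init_attn(d), ln1 = init_ln(d),
             ffn = init_ffn(d, config$d_ff), ln2 = init_ln(d))),
      dec = lapply(seq_len(config$n_decoder_layers), function(i)
        list(self = init_attn(d), ln1 = init_ln(d),
             cross = init_attn(d), ln2 = init_ln(d),
             ffn = init_ffn(d, config$d_ff), ln3 = init_ln(d))),
      proj = list(W = glorot(d, config$vocab_size),
                  b = numeric(config$vocab_size))
    )
  })
  structure(list(config = config, params = params,
                 posenc = sinusoid_positions(
                   max(config$max_input_len, config$max_output_len) + 1L, d)),
            class = "seq2seq_model")
}

#' @export
print.seq2seq_model <- function(x, ...) {
  cat("<seq2seq_model> ", x$config$n_encoder_layers, "+",
      x$config$n_decoder_layers, " layers, width ", x$config$d_model,
      ", ", format(count_parameters(x), big.mark = ","),
      " trainable parameters\n", sep = "")
  invisible(x)
}

# -- functional blocks (forward returns out + cache, backward returns grads) --

linear_fwd <- function(X, W, b) {
  list(out = X %*% W + rep(b, each = nrow(X)), X = X)
}

linear_bwd <- function(cache, W, dY) {
  list(dX = dY %*% t(W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

ln_eps <- 1e-5

ln_fwd <- function(X, p) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + ln_eps)
  xhat <- xc * inv
  list(out = sweep(xhat, 2L, p$g, "*") + rep(p$b, each = nrow(X)),
       xhat = xhat, inv = inv)
}

ln_bwd <- function(cache, p, dY) {
  dxhat <- sweep(dY, 2L, p$g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- cache$inv * (dxhat - m1 - cache$xhat * m2)
  list(dX = dX, dg = colSums(dY * cache$xhat), db = colSums(dY))
}

ffn_fwd <- function(X, p) {
  l1 <- linear_fwd(X, p$W1, p$b1)
  H <- pmax(l1$out, 0)
  l2 <- linear_fwd(H, p$W2, p$b2)
  list(out = l2$out, X = X, H = H)
}

ffn_bwd <- function(cache, p, dY) {
  dH <- dY %*% t(p$W2)
  dW2 <- crossprod(cache$H, dY)
  db2 <- colSums(dY)
  dH[cache$H <= 0] <- 0
  list(dX = dH %*% t(p$W1), grads = list(
    W1 = crossprod(cache$X, dH), b1 = colSums(dH), W2 = dW2, b2 = db2))
}

# Multi-head attention over a flat batch. Xq is (B*Sq, d) with sample-major
# rows; Xkv is (B*Skv, d). kv_mask is a (B, Skv) logical matrix of real key
# positions; causal additionally hides future positions (requires Sq ==
# Skv).
attn_fwd <- function(p, Xq, Xkv, B, Sq, Skv, nh, kv_mask, causal = FALSE) {
  d <- ncol(Xq)
  dh <- d %/% nh
  Q <- Xq %*% p$Wq + rep(p$bq, each = nrow(Xq))
  K <- Xkv %*% p$Wk + rep(p$bk, each = nrow(Xkv))
  V <- Xkv %*% p$Wv + rep(p$bv, each = nrow(Xkv))
  O <- matrix(0, nrow(Xq), d)
  Pcache <- vector("list", B * nh)
  scale <- 1 / sqrt(dh)
  for (b in seq_len(B)) {
    rq <- ((b - 1L) * Sq + 1L):(b * Sq)
    rk <- ((b - 1L) * Skv + 1L):(b * Skv)
    hide <- !kv_mask[b, ]
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(Q[rq, cols, drop = FALSE],
                      K[rk, cols, drop = FALSE]) * scale
      if (any(hide)) S[, hide] <- -1e30
      if (causal) S[.row(dim(S)) < .col(dim(S))] <- -1e30
      P <- exp(S - max(S))
      P <- P / rowSums(P)
      Pcache[[(b - 1L) * nh + h]] <- P
      O[rq, cols] <- P %*% V[rk, cols, drop = FALSE]
    }
  }
  out <- O %*% p$Wo + rep(p$bo, each = nrow(O))
  list(out = out, Q = Q, K = K, V = V, O = O, P = Pcache,
       Xq = Xq, Xkv = Xkv, B = B, Sq = Sq, Skv = Skv, nh = nh)
}

attn_bwd <- function(p, cache, dOut) {
  B <- cache$B; Sq <- cache$Sq; Skv <- cache$Skv; nh <- cache$nh
  d <- ncol(cache$Xq)
  dh <- d %/% nh
  scale <- 1 / sqrt(dh)
  dO <- dOut %*% t(p$Wo)
  dWo <- crossprod(cache$O, dOut)
  dbo <- colSums(dOut)
  dQ <- matrix(0, nrow(cache$Xq), d)
  dK <- matrix(0, nrow(cache$Xkv), d)
  dV <- matrix(0, nrow(cache$Xkv), d)
  for (b in seq_len(B)) {
    rq <- ((b - 1L) * Sq + 1L):(b * Sq)
    rk <- ((b - 1L) * Skv + 1L):(b * Skv)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      P <- cache$P[[(b - 1L) * nh + h]]
      dOb <- dO[rq, cols, drop = FALSE]
      dP <- tcrossprod(dOb, cache$V[rk, cols, drop = FALSE])
      dV[rk, cols] <- dV[rk, cols] + crossprod(P, dOb)
      dS <- P * (dP - rowSums(dP * P))
      dQ[rq, cols] <- dQ[rq, cols] +
        dS %*% cache$K[rk, cols, drop = FALSE] * scale
      dK[rk, cols] <- dK[rk, cols] +
        crossprod(dS, cache$Q[rq, cols, drop = FALSE]) * scale
    }
  }
  list(
    dXq = dQ %*% t(p$Wq),
    dXkv = dK %*% t(p$Wk) + dV %*% t(p$Wv),
    grads = list(Wq = crossprod(cache$Xq, dQ), bq = colSums(dQ),
                 Wk = crossprod(cache$Xkv, dK), bk = colSums(dK),
                 Wv = crossprod(cache$Xkv, dV), bv = colSums(dV),
                 Wo = dWo, bo = dbo))
}

drop_fwd <- function(X, p_drop, training) {
  if (!training || p_drop <= 0) return(list(out = X, mask = NULL))
  mask <- matrix(stats::rbinom(length(X), 1L, 1 - p_drop) / (1 - p_drop),
                 nrow(X), ncol(X))
  list(out = X * mask, mask = mask)
}

drop_bwd <- function(cache, dY) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

# -- batch assembly -----------------------------------------------------------

# Turn a list of training samples into padded index matrices. Encoder rows
# are 1-based bin indices into emb_in (pad row = n_bins + 1); decoder input
# rows are 1-based token ids into emb_out; labels are 1-based token ids with
# 0 marking ignored (padding) positions.
make_batch <- function(samples, config, vocab) {
  B <- length(samples)
  enc_lens <- vapply(samples, function(s) length(s$bins), integer(1))
  Se <- max(enc_lens, 1L)
  tgt <- lapply(samples, `[[`, "target")
  dec_lens <- lengths(tgt) - 1L  # [sos, t..., eos] -> L-1 steps
  Sd <- max(dec_lens)
  enc <- matrix(config$n_bins + 1L, B, Se)
  enc_mask <- matrix(FALSE, B, Se)
  dec_in <- matrix(vocab$pad + 1L, B, Sd)
  dec_mask <- matrix(FALSE, B, Sd)
  labels <- matrix(0L, B, Sd)
  for (b in seq_len(B)) {
    nb <- enc_lens[b]
    if (nb > 0L) {
      enc[b, seq_len(nb)] <- samples[[b]]$bins + 1L
      enc_mask[b, seq_len(nb)] <- TRUE
    }
    ids <- tgt[[b]]
    L <- length(ids)
    dec_in[b, seq_len(L - 1L)] <- ids[-L] + 1L
    labels[b, seq_len(L - 1L)] <- ids[-1L] + 1L
    dec_mask[b, seq_len(L - 1L)] <- TRUE
  }
  list(enc = enc, enc_mask = enc_mask, dec_in = dec_in,
       dec_mask = dec_mask, labels = labels, B = B, Se = Se, Sd = Sd)
}

# -- full forward / backward --------------------------------------------------

encoder_fwd <- function(model, batch, training = FALSE) {
  p <- model$params; cfg <- model$config
  d <- cfg$d_model
  B <- batch$B; Se <- batch$Se
  tok <- as.integer(t(batch$enc))  # sample-major flat order
  X <- p$emb_in[tok, , drop = FALSE] * sqrt(d) +
    model$posenc[rep(seq_len(Se), B), , drop = FALSE]
  dr0 <- drop_fwd(X, cfg$dropout, training)
  X <- dr0$out
  layers <- vector("list", cfg$n_encoder_layers)
  for (l in seq_len(cfg$n_encoder_layers)) {
    lp <- p$enc[[l]]
    a <- attn_fwd(lp$attn, X, X, B, Se, Se, cfg$n_heads, batch$enc_mask)
    da <- drop_fwd(a$out, cfg$dropout, training)
    n1 <- ln_fwd(X + da$out, lp$ln1)
    f <- ffn_fwd(n1$out, lp$ffn)
    df <- drop_fwd(f$out, cfg$dropout, training)
    n2 <- ln_fwd(n1$out + df$out, lp$ln2)
    layers[[l]] <- list(a = a, da = da, n1 = n1, f = f, df = df, n2 = n2)
    X <- n2$out
  }
  list(memory = X, tok = tok, dr0 = dr0, layers = layers)
}

decoder_fwd <- function(model, batch, memory, training = FALSE) {
  p <- model$params; cfg <- model$config
  d <- cfg$d_model
  B <- batch$B; Sd <- batch$Sd; Se <- batch$Se
  tok <- as.integer(t(batch$dec_in))
  X <- p$emb_out[tok, , drop = FALSE] * sqrt(d) +
    model$posenc[rep(seq_len(Sd), B), , drop = FALSE]
  dr0 <- drop_fwd(X, cfg$dropout, training)
  X <- dr0$out
  layers <- vector("list", cfg$n_decoder_layers)
  for (l in seq_len(cfg$n_decoder_layers)) {
    lp <- p$dec[[l]]
    a1 <- attn_fwd(lp$self, X, X, B, Sd, Sd, cfg$n_heads, batch$dec_mask,
                   causal = TRUE)
    d1 <- drop_fwd(a1$out, cfg$dropout, training)
    n1 <- ln_fwd(X + d1$out, lp$ln1)
    a2 <- attn_fwd(lp$cross, n1$out, memory, B, Sd, Se, cfg$n_heads,
                   batch$enc_mask)
    d2 <- drop_fwd(a2$out, cfg$dropout, training)
    n2 <- ln_fwd(n1$out + d2$out, lp$ln2)
    f <- ffn_fwd(n2$out, lp$ffn)
    d3 <- drop_fwd(f$out, cfg$dropout, training)
    n3 <- ln_fwd(n2$out + d3$out, lp$ln3)
    layers[[l]] <- list(a1 = a1, d1 = d1, n1 = n1, a2 = a2, d2 = d2,
                        n2 = n2, f = f, d3 = d3, n3 = n3)
    X <- n3$out
  }
  logits <- X %*% p$proj$W + rep(p$proj$b, each = nrow(X))
  list(out = X, logits = logits, tok = tok, dr0 = dr0, layers = layers)
}

# Token-averaged cross-entropy over valid label positions, with gradient.
xent_loss <- function(logits, labels_flat) {
  valid <- which(labels_flat > 0L)
  lv <- logits[valid, , drop = FALSE]
  m <- apply(lv, 1L, max)
  P <- exp(lv - m)
  P <- P / rowSums(P)
  idx <- cbind(seq_along(valid), labels_flat[valid])
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  dlv <- P
  dlv[idx] <- dlv[idx] - 1
  dlogits <- matrix(0, nrow(logits), ncol(logits))
  dlogits[valid, ] <- dlv / length(valid)
  list(loss = loss, dlogits = dlogits, n_tokens = length(valid))
}

model_forward <- function(model, batch, training = FALSE) {
  enc <- encoder_fwd(model, batch, training)
  dec <- decoder_fwd(model, batch, enc$memory, training)
  labels_flat <- as.integer(t(batch$labels))
  ce <- xent_loss(dec$logits, labels_flat)
  list(loss = ce$loss, n_tokens = ce$n_tokens, enc = enc, dec = dec,
       ce = ce, batch = batch)
}

#' Save a model checkpoint
#'
#' The checkpoint embeds the full [model_config()] alongside the weights,
#' so [load_checkpoint()] needs no external configuration.
#'
#' @param model A `seq2seq_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#'
#' @param path Checkpoint file path.
#' @return A `seq2seq_model`.
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "seq2seq_model"))
    stop(path, " is not a model checkpoint")
  model
}

model_backward <- function(model, fwd) {
  p <- model$params; cfg <- model$config
  d <- cfg$d_model
  batch <- fwd$batch
  B <- batch$B; Se <- batch$Se; Sd <- batch$Sd

  # output projection
  dX <- fwd$ce$dlogits %*% t(p$proj$W)
  gproj <- list(W = crossprod(fwd$dec$out, fwd$ce$dlogits),
                b = colSums(fwd$ce$dlogits))

  # decoder stack
  gdec <- vector("list", cfg$n_decoder_layers)
  dMemory <- matrix(0, nrow(fwd$enc$memory), d)
  for (l in rev(seq_len(cfg$n_decoder_layers))) {
    lp <- p$dec[[l]]
    cl <- fwd$dec$layers[[l]]
    b3 <- ln_bwd(cl$n3, lp$ln3, dX)
    dff_out <- drop_bwd(cl$d3, b3$dX)
    fb <- ffn_bwd(cl$f, lp$ffn, dff_out)
    dn2 <- b3$dX + fb$dX
    b2 <- ln_bwd(cl$n2, lp$ln2, dn2)
    dcross_out <- drop_bwd(cl$d2, b2$dX)
    ab2 <- attn_bwd(lp$cross, cl$a2, dcross_out)
    dMemory <- dMemory + ab2$dXkv
    dn1 <- b2$dX + ab2$dXq
    b1 <- ln_bwd(cl$n1, lp$ln1, dn1)
    dself_out <- drop_bwd(cl$d1, b1$dX)
    ab1 <- attn_bwd(lp$self, cl$a1, dself_out)
    dX <- b1$dX + ab1$dXq + ab1$dXkv
    gdec[[l]] <- list(self = ab1$grads,
                      ln1 = list(g = b1$dg, b = b1$db),
                      cross = ab2$grads,
                      ln2 = list(g = b2$dg, b = b2$db),
                      ffn = fb$grads,
                      ln3 = list(g = b3$dg, b = b3$db))
  }
  dX <- drop_bwd(fwd$dec$dr0, dX)
  agg <- rowsum(dX * sqrt(d), fwd$dec$tok)
  gemb_out <- matrix(0, cfg$vocab_size, d)
  gemb_out[as.integer(rownames(agg)), ] <- agg

  # encoder stack
  genc <- vector("list", cfg$n_encoder_layers)
  dX <- dMemory
  for (l in rev(seq_len(cfg$n_encoder_layers))) {
    lp <- p$enc[[l]]
    cl <- fwd$enc$layers[[l]]
    b2 <- ln_bwd(cl$n2, lp$ln2, dX)
    dff_out <- drop_bwd(cl$df, b2$dX)
    fb <- ffn_bwd(cl$f, lp$ffn, dff_out)
    dn1 <- b2$dX + fb$dX
    b1 <- ln_bwd(cl$n1, lp$ln1, dn1)
    dattn_out <- drop_bwd(cl$da, b1$dX)
    ab <- attn_bwd(lp$attn, cl$a, dattn_out)
    dX <- b1$dX + ab$dXq + ab$dXkv
    genc[[l]] <- list(attn = ab$grads,
                      ln1 = list(g = b1$dg, b = b1$db),
                      ffn = fb$grads,
                      ln2 = list(g = b2$dg, b = b2$db))
  }
  dX <- drop_bwd(fwd$enc$dr0, dX)
  agg <- rowsum(dX * sqrt(d), fwd$enc$tok)
  gemb_in <- matrix(0, cfg$n_bins + 1L, d)
  gemb_in[as.integer(rownames(agg)), ] <- agg

  list(emb_in = gemb_in, emb_out = gemb_out, enc = genc, dec = gdec,
       proj = gproj)
}

# -- optimizer ----------------------------------------------------------------

tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1]])) {
    out <- lapply(seq_along(trees[[1]]), function(i)
      do.call(tree_map, c(list(f), lapply(trees, `[[`, i))))
    names(out) <- names(trees[[1]])
    out
  } else {
    do.call(f, trees)
  }
}

adam_init <- function(params) {
  zeros <- function(x) {
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  }
  list(m = tree_map(zeros, params), v = tree_map(zeros, params), t = 0L)
}

adam_step <- function(params, grads, state, lr, tc) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) tc$beta1 * m + (1 - tc$beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) tc$beta2 * v + (1 - tc$beta2) * g * g,
                      state$v, grads)
  c1 <- 1 / (1 - tc$beta1^state$t)
  c2 <- 1 / (1 - tc$beta2^state$t)
  params <- tree_map(function(p, m, v)
    p - lr * (m * c1) / (sqrt(v * c2) + tc$eps),
    params, state$m, state$v)
  list(params = params, state = state)
}

# -- training loop ------------------------------------------------------------

dataset_loss <- function(model, samples, vocab, chunk = 256L) {
  total <- 0; n <- 0L
  for (i in seq(1L, length(samples), by = chunk)) {
    sub <- samples[i:min(i + chunk - 1L, length(samples))]
    fwd <- model_forward(model, make_batch(sub, model$config, vocab),
                         training = FALSE)
    total <- total + fwd$loss * fwd$n_tokens
    n <- n + fwd$n_tokens
  }
  total / n
}

#' Train the model with validation-loss checkpointing
#'
#' Minimizes next-token cross-entropy (nats/token) with causal masking in
#' the decoder and padding masking throughout, using Adam under the
#' warmup/decay schedule of [lr_schedule()]. After every epoch the
#' validation loss is computed; the returned model carries the weights of
#' the best-validation epoch, and training stops early after
#' `config$patience` epochs without improvement.
#'
#' @param model A [build_model()] result.
#' @param train_ds,val_ds `training_dataset`s sharing one vocabulary.
#' @param config A [train_config()].
#' @param verbose Print per-epoch losses (default FALSE).
#' @return List: `model` (best checkpoint), `history` (data frame with
#'   `epoch`, `train_loss`, `val_loss`, `lr`), `best_epoch`.
#' @export
train_model <- function(model, train_ds, val_ds = NULL,
                        config = train_config(), verbose = FALSE) {
  if (!length(train_ds$samples)) stop("empty training set")
  if (model$config$vocab_size != train_ds$vocab$size)
    stop("vocabulary size mismatch between dataset and model")
  vocab <- train_ds$vocab
  state <- adam_init(model$params)
  history <- list()
  best_val <- Inf
  best_params <- model$params
  best_epoch <- 0L
  since_best <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      idx <- sample(length(train_ds$samples))
      epoch_loss <- 0; epoch_tokens <- 0L
      lr_last <- NA_real_
      for (start in seq(1L, length(idx), by = config$batch_size)) {
        take <- idx[start:min(start + config$batch_size - 1L, length(idx))]
        batch <- make_batch(train_ds$samples[take], model$config, vocab)
        fwd <- model_forward(model, batch, training = TRUE)
        grads <- model_backward(model, fwd)
        lr_last <- lr_schedule(state$t + 1L, model$config$d_model, config)
        upd <- adam_step(model$params, grads, state, lr_last, config)
        model$params <- upd$params
        state <- upd$state
        epoch_loss <- epoch_loss + fwd$loss * fwd$n_tokens
        epoch_tokens <- epoch_tokens + fwd$n_tokens
      }
      train_loss <- epoch_loss / epoch_tokens
      val_loss <- if (!is.null(val_ds) && length(val_ds$samples))
        dataset_loss(model, val_ds$samples, vocab) else train_loss
      history[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                     val_loss = val_loss, lr = lr_last)
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2e",
                        epoch, train_loss, val_loss, lr_last))
      if (val_loss < best_val) {
        best_val <- val_loss
        best_params <- model$params
        best_epoch <- epoch
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= config$patience) break
      }
    }
  })
  model$params <- best_params
  list(model = model, history = do.call(rbind, history),
       best_epoch = best_epoch)
}
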