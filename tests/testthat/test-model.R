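# Architecture accounting, the learning-rate schedule, gradient
# correctness, and training/decoding behaviour at tiny scale.

test_that("parameter counting matches independent arithmetic across configs", {
  set.seed(2)
  for (i in 1:20) {
    nh <- sample(c(1L, 2L, 4L), 1)
    d <- nh * sample(c(4L, 8L, 16L), 1)
    cfg <- model_config(n_encoder_layers = sample(1:3, 1),
                        n_decoder_layers = sample(1:3, 1),
                        d_model = d, n_heads = nh,
                        d_ff = sample(c(16L, 64L), 1),
                        dropout = 0, n_bins = sample(100:2000, 1),
                        vocab_size = sample(10:70, 1))
    expect_identical(count_parameters(cfg),
                     oracle_param_count(cfg$n_encoder_layers,
                                        cfg$n_decoder_layers, cfg$d_model,
                                        cfg$d_ff, cfg$n_bins,
                                        cfg$vocab_size))
  }
})

test_that("closed-form count equals the instantiated model's count", {
  cfg <- model_config(n_encoder_layers = 2L, n_decoder_layers = 2L,
                      d_model = 32L, n_heads = 4L, d_ff = 64L, dropout = 0,
                      n_bins = 1000L, vocab_size = 20L)
  m <- build_model(cfg, seed = 1)
  expect_identical(count_parameters(m), count_parameters(cfg))
})

test_that("growing the output vocabulary by one adds 2*d_model + 1 parameters", {
  base <- tiny_model_config()
  plus <- tiny_model_config(vocab_size = 13L)
  expect_identical(count_parameters(plus) - count_parameters(base),
                   2 * base$d_model + 1)
})

test_that("width must be divisible by the head count", {
  expect_error(model_config(d_model = 30L, n_heads = 4L), "divisible")
})

test_that("the learning-rate schedule warms up then decays", {
  tc <- train_config(batch_size = 896, base_batch = 896,
                     warmup_steps = 8000)
  w <- tc$warmup_steps
  # the two min() branches cross exactly at the warmup step
  expect_equal(w^-0.5, w * w^-1.5)
  expect_equal(lr_schedule(1, 1024, tc), 1024^-0.5 * 8000^-1.5)
  steps <- c(1, 10, 100, 1000, 4000, 7999)
  expect_false(is.unsorted(lr_schedule(steps, 1024, tc)))
  after <- c(8000, 9000, 20000, 1e5)
  expect_false(is.unsorted(rev(lr_schedule(after, 1024, tc))))
  expect_error(lr_schedule(0, 1024, tc), ">= 1")
  # linear batch scaling
  tc2 <- train_config(batch_size = 448, base_batch = 896)
  expect_equal(lr_schedule(100, 1024, tc2), lr_schedule(100, 1024, tc) / 2)
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, seed = 5)
  batch <- ms2mol:::make_batch(tiny_samples(), cfg, tiny_vocab())
  fwd <- ms2mol:::model_forward(m, batch)
  gr <- ms2mol:::model_backward(m, fwd)
  eps <- 1e-6
  probe <- list(
    list(list("enc", 1L, "attn", "Wq"), cbind(2L, 3L)),
    list(list("enc", 1L, "ffn", "W1"), cbind(1L, 5L)),
    list(list("dec", 1L, "self", "Wk"), cbind(3L, 2L)),
    list(list("dec", 1L, "cross", "Wv"), cbind(5L, 1L)),
    list(list("dec", 1L, "ln3", "g"), 4L),
    list(list("emb_in"), cbind(6L, 2L)),
    list(list("emb_out"), cbind(5L, 3L)),
    list(list("proj", "W"), cbind(7L, 8L))
  )
  for (p in probe) {
    path <- p[[1]]
    idx <- p[[2]]
    get_leaf <- function(tree) Reduce(function(t, k) t[[k]], path, tree)
    set_leaf <- function(tree, val) {
      leaf <- get_leaf(tree)
      leaf[idx] <- val
      assign_path <- function(t, ks, v) {
        if (!length(ks)) return(v)
        t[[ks[[1]]]] <- assign_path(t[[ks[[1]]]], ks[-1], v)
        t
      }
      assign_path(tree, path, leaf)
    }
    g_analytic <- get_leaf(gr)[idx]
    v0 <- get_leaf(m$params)[idx]
    mp <- m; mp$params <- set_leaf(m$params, v0 + eps)
    mm <- m; mm$params <- set_leaf(m$params, v0 - eps)
    g_numeric <- (ms2mol:::model_forward(mp, batch)$loss -
                    ms2mol:::model_forward(mm, batch)$loss) / (2 * eps)
    expect_equal(g_analytic, g_numeric, tolerance = 1e-4,
                 label = paste(unlist(path), collapse = "/"))
  }
})

test_that("training is seeded-deterministic and checkpoints the best epoch", {
  cfg <- tiny_model_config()
  ds <- structure(list(samples = tiny_samples(), vocab = tiny_vocab()),
                  class = "training_dataset")
  tc <- train_config(batch_size = 3, base_batch = 3, warmup_steps = 20,
                     patience = 100, max_epochs = 15, seed = 9)
  r1 <- train_model(build_model(cfg, seed = 9), ds, ds, tc)
  r2 <- train_model(build_model(cfg, seed = 9), ds, ds, tc)
  expect_identical(r1$history$train_loss, r2$history$train_loss)
  expect_identical(r1$best_epoch,
                   r1$history$epoch[which.min(r1$history$val_loss)])
  expect_lte(min(r1$history$val_loss),
             r1$history$val_loss[nrow(r1$history)])
})

test_that("vocabulary size mismatches are rejected", {
  ds <- structure(list(samples = tiny_samples(), vocab = tiny_vocab()),
                  class = "training_dataset")
  m <- build_model(tiny_model_config(vocab_size = 20L), seed = 1)
  expect_error(train_model(m, ds), "mismatch")
})

test_that("sampling is seeded, sized, and counts invalid outputs", {
  m <- build_model(tiny_model_config(vocab_size = 69L), seed = 3)
  v <- smiles_vocabulary()
  p1 <- sample_predictions(m, c(5L, 20L), n_runs = 8, seed = 4, vocab = v)
  p2 <- sample_predictions(m, c(5L, 20L), n_runs = 8, seed = 4, vocab = v)
  expect_identical(p1$raw_outputs, p2$raw_outputs)
  expect_length(p1$raw_outputs, 8L)
  expect_identical(sum(p1$unique_canonical) + p1$n_invalid, 8L)
  expect_gt(p1$uniqueness_ratio, 0)
  expect_lte(p1$uniqueness_ratio, 1)
  expect_error(sample_predictions(m, c(5L), n_runs = 0), ">= 1")
  expect_error(sample_predictions(m, integer(0), n_runs = 2), "empty")
})

test_that("checkpoints embed the configuration and restore the model", {
  m <- build_model(tiny_model_config(), seed = 6)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_identical(back$config, m$config)
  expect_identical(back$params, m$params)
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(1:3, bad)
  expect_error(load_checkpoint(bad), "not a model checkpoint")
})

test_that("formula filtering retains only mass- or formula-compatible predictions", {
  pred <- structure(list(
    raw_outputs = c("Nc1ccnc(=O)[nH]1", "CCO"),
    n_runs = 2L, n_invalid = 0L,
    unique_canonical = c("Nc1ccnc(=O)[nH]1" = 1L, "CCO" = 1L),
    uniqueness_ratio = 1), class = "prediction_set")
  # cytosine's protonated ion at generous tolerance
  got <- formula_filter(pred, precursor_mz = 112.0505, ppm = 25)
  expect_identical(names(got$formula_filtered),
                   canonicalize("Nc1ccnc(=O)[nH]1"))
  # exact formula match
  got2 <- formula_filter(pred, target_formula = "C2H6O")
  expect_identical(names(got2$formula_filtered), "CCO")
  # nothing compatible -> explicit no-prediction outcome
  got3 <- formula_filter(pred, target_formula = "C10H10")
  expect_true(got3$no_prediction)
  empty <- structure(list(raw_outputs = character(0), n_runs = 1L,
                          n_invalid = 1L,
                          unique_canonical = integer(0),
                          uniqueness_ratio = 0), class = "prediction_set")
  expect_true(formula_filter(empty, target_formula = "CH4")$no_prediction)
})
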