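tiny_cfg <- function() {
  model_config(n_layers = 2L, n_heads = 2L, hidden_dim = 8L, max_len = 12L,
               ff_dim = 12L)
}

test_that("analytic gradients match finite differences everywhere", {
  vocab <- lca_vocabulary(1L)
  model <- init_model(tiny_cfg(), vocab, shift = 1L, seed = 11)
  set.seed(7)
  model$params$W_cls <- matrix(rnorm(16, sd = 0.1), 8, 2)
  model$params$b_cls <- rnorm(2, sd = 0.1)
  enc <- encode_batch(c("ACGTAGG", "ACG", "TTTTACGTA"), vocab,
                      shift = 1, max_len = 12)
  y <- c(1L, 0L, 1L)
  fwd <- lysotyper:::model_forward(model, enc$ids, enc$mask,
                                   keep_cache = TRUE)
  bk <- lysotyper:::model_backward(model, fwd, y)
  lossfun <- function(m) {
    f <- lysotyper:::model_forward(m, enc$ids, enc$mask)
    -mean(log(f$probs[cbind(1:3, y + 1)]))
  }
  eps <- 1e-6
  worst <- 0
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      up <- model; up$params[[nm]][i] <- p[i] + eps
      dn <- model; dn$params[[nm]][i] <- p[i] - eps
      num <- (lossfun(up) - lossfun(dn)) / (2 * eps)
      ana <- bk$grads[[nm]][i]
      worst <- max(worst, abs(num - ana) / max(1e-7, abs(num) + abs(ana)))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("probabilities are a valid two-class distribution", {
  vocab <- lca_vocabulary(6L)
  model <- init_model(model_config_tiny(max_len = 64L), vocab, shift = 2L,
                      seed = 12)
  enc <- encode_batch(c(random_dna(100, seed = 13), random_dna(60, seed = 14)),
                      vocab, shift = 2, max_len = 64)
  fwd <- lysotyper:::model_forward(model, enc$ids, enc$mask)
  expect_true(all(fwd$probs >= 0 & fwd$probs <= 1))
  expect_equal(rowSums(fwd$probs), rep(1, 2), tolerance = 1e-12)
})

test_that("a zeroed final linear layer predicts exactly p = 0.5", {
  vocab <- lca_vocabulary(6L)
  model <- init_model(model_config_tiny(max_len = 64L), vocab, shift = 2L,
                      seed = 15)
  model$params$W_cls <- matrix(0, model$config$hidden_dim, 2)
  model$params$b_cls <- c(0, 0)
  enc <- encode_batch(c(random_dna(80, seed = 16), random_dna(120, seed = 17)),
                      vocab, shift = 2, max_len = 64)
  fwd <- lysotyper:::model_forward(model, enc$ids, enc$mask)
  expect_equal(fwd$probs, matrix(0.5, 2, 2), ignore_attr = TRUE)
})

test_that("PAD positions contribute nothing: extra padding leaves output unchanged", {
  vocab <- lca_vocabulary(6L)
  model <- init_model(model_config_tiny(max_len = 200L), vocab, shift = 2L,
                      seed = 18)
  s <- random_dna(150, seed = 19)
  enc_short <- encode_batch(s, vocab, shift = 2, max_len = 80)
  enc_long <- encode_batch(s, vocab, shift = 2, max_len = 200)
  p1 <- lysotyper:::model_forward(model, enc_short$ids, enc_short$mask)$probs
  p2 <- lysotyper:::model_forward(model, enc_long$ids, enc_long$mask)$probs
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("pooling weights over real positions sum to 1 with 0 on PAD", {
  vocab <- lca_vocabulary(6L)
  model <- init_model(model_config_tiny(max_len = 64L), vocab, shift = 2L,
                      seed = 20)
  enc <- encode_batch(c(random_dna(50, seed = 21), random_dna(100, seed = 22)),
                      vocab, shift = 2, max_len = 64)
  fwd <- lysotyper:::model_forward(model, enc$ids, enc$mask,
                                   keep_cache = TRUE)
  Tn <- fwd$Tn
  alpha <- matrix(fwd$cache$alpha, nrow = Tn)
  mask <- t(enc$mask[, seq_len(Tn)])
  expect_equal(colSums(alpha), c(1, 1), tolerance = 1e-12)
  expect_true(all(alpha[mask == 0] == 0))
})

test_that("prediction is invariant to batch size and preserves order", {
  model <- get_cached_tiny_model()
  set.seed(23)
  segs <- data.frame(contig_id = "c", start = 0, end = 512, strand = "+",
                     seq = vapply(1:7, function(i) random_dna(512), ""),
                     label = NA_character_, stringsAsFactors = FALSE)
  p1 <- predict_segments(model, segs, batch_size = 1)
  p64 <- predict_segments(model, segs, batch_size = 64)
  expect_equal(p1$p_virulent, p64$p_virulent, tolerance = 1e-5)
  expect_identical(p1$seq, segs$seq)
  expect_equal(p1$p_virulent + p1$p_temperate, rep(1, 7), tolerance = 1e-12)
})

test_that("segments shorter than k get neutral flagged predictions", {
  model <- get_cached_tiny_model()
  segs <- data.frame(contig_id = "c", start = 0, end = 4, strand = "+",
                     seq = c("ACG", random_dna(512, seed = 24)),
                     stringsAsFactors = FALSE)
  pr <- predict_segments(model, segs)
  expect_equal(pr$p_virulent[1], 0.5)
  expect_true(pr$flagged[1])
  expect_false(pr$flagged[2])
})

test_that("training is bitwise deterministic for a fixed seed", {
  vocab <- lca_vocabulary(6L)
  set.seed(25)
  segs <- data.frame(seq = vapply(1:48, function(i) random_dna(128), ""),
                     label = rep(c("virulent", "temperate"), 24),
                     stringsAsFactors = FALSE)
  run <- function() {
    m <- init_model(model_config(1L, 2L, 16L, max_len = 68L, ff_dim = 32L),
                    vocab, shift = 2L, seed = 31)
    train_classifier(m, segs, cfg = train_config(learning_rate = 1e-3,
                                                 batch_size = 16L,
                                                 epochs = 1L, seed = 32),
                     quiet = TRUE)
  }
  m1 <- run()
  m2 <- run()
  expect_identical(m1$history$train_loss, m2$history$train_loss)
  expect_identical(m1$params$W_cls, m2$params$W_cls)
})

test_that("single-class training sets are rejected", {
  segs <- data.frame(seq = c("ACGTACGTACGT", "TTTTACGTACGT"),
                     label = c("virulent", "virulent"),
                     stringsAsFactors = FALSE)
  vocab <- lca_vocabulary(6L)
  m <- init_model(tiny_cfg(), vocab, shift = 1L)
  expect_error(train_classifier(m, segs, cfg = train_config()),
               "both classes")
})

test_that("training separates motif-marked segments from background", {
  # two fully separable segment populations marked by disjoint motifs
  set.seed(33)
  vmotif <- "GATTACAGATTACA"
  tmotif <- "CCGGTTAACCGGTT"
  plant <- function(motif) {
    s <- random_dna(128)
    at <- sample(1:(128 - nchar(motif)), 1)
    paste0(substr(s, 1, at - 1), motif,
           substr(s, at + nchar(motif), 128))
  }
  segs <- data.frame(
    seq = c(vapply(1:100, function(i) plant(vmotif), ""),
            vapply(1:100, function(i) plant(tmotif), "")),
    label = rep(c("virulent", "temperate"), each = 100),
    stringsAsFactors = FALSE)
  sel <- sample(200)
  train <- segs[sel[1:160], ]
  val <- segs[sel[161:200], ]
  vocab <- lca_vocabulary(6L)
  m <- init_model(model_config(2L, 4L, 64L, max_len = 68L), vocab,
                  shift = 2L, seed = 34)
  m <- train_classifier(m, train, val,
                        cfg = train_config(learning_rate = 2e-3,
                                           batch_size = 16L, epochs = 5L,
                                           seed = 35),
                        quiet = TRUE)
  h <- m$history
  # loss decreases over the first epochs and the model separates the classes
  expect_lt(h$train_loss[3], h$train_loss[1])
  expect_gte(max(h$val_auc), 0.95)
  expect_gte(max(h$val_balacc), 0.90)
  # a training exemplar is recalled correctly after convergence
  pr <- predict_segments(m, train[train$label == "virulent", ][1:10, ])
  expect_gt(mean(pr$p_virulent), 0.5)
})

test_that("shuffled labels keep validation near chance and loss near ln 2", {
  set.seed(36)
  segs <- data.frame(seq = vapply(1:160, function(i) random_dna(128), ""),
                     label = sample(rep(c("virulent", "temperate"), 80)),
                     stringsAsFactors = FALSE)
  vocab <- lca_vocabulary(6L)
  m <- init_model(model_config(1L, 2L, 32L, max_len = 68L), vocab,
                  shift = 2L, seed = 37)
  m <- train_classifier(m, segs[1:120, ], segs[121:160, ],
                        cfg = train_config(learning_rate = 1e-3,
                                           batch_size = 16L, epochs = 2L,
                                           seed = 38),
                        quiet = TRUE)
  h <- m$history
  expect_lt(abs(h$val_balacc[nrow(h)] - 0.5), 0.12)
  expect_lt(abs(h$train_loss[nrow(h)] - log(2)), 0.1)
})

test_that("model checkpoints round-trip through save/load exactly", {
  model <- get_cached_tiny_model()
  dir <- withr::local_tempdir()
  save_model(model, dir)
  back <- load_model(dir)
  for (nm in names(model$params)) {
    expect_equal(back$params[[nm]], model$params[[nm]],
                 tolerance = 0, info = nm)
  }
  expect_equal(back$tokenizer, model$tokenizer)
  s <- random_dna(512, seed = 39)
  segs <- data.frame(contig_id = "c", start = 0, end = 512, strand = "+",
                     seq = s, stringsAsFactors = FALSE)
  expect_equal(predict_segments(model, segs)$p_virulent,
               predict_segments(back, segs)$p_virulent)
})

test_that("out-of-range token ids and empty batches are rejected", {
  vocab <- lca_vocabulary(6L)
  model <- init_model(model_config_tiny(max_len = 16L), vocab, shift = 2L)
  ids <- matrix(c(2L, 9999L, 3L, 0L), 1, 4)
  mask <- matrix(c(1L, 1L, 1L, 0L), 1, 4)
  expect_error(lysotyper:::model_forward(model, ids, mask), "vocabulary")
  expect_error(predict_segments(model,
                                data.frame(seq = character(0))[0, , drop = FALSE]),
               "no segments")
})
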