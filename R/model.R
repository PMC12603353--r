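# Compact transformer encoder for segment-level lifestyle classification.
#
# The network is a pre-norm transformer: embeddings (token + learned absolute
# position), n_layers blocks of masked multi-head self-attention and a GELU
# feed-forward, a final layer norm, then an attention-style pooling head with
# a single learnable scoring vector and a linear map to two logits
# (temperate = class 0, virulent = class 1; virulent is the positive class).
# Forward, backward and the AdamW step are written in base R matrix algebra
# so training is fully deterministic on one device for a fixed seed.

LN_EPS <- 1e-5

#' Model architecture configuration
#'
#' @param n_layers number of transformer blocks.
#' @param n_heads attention heads (`hidden_dim` must be divisible by it).
#' @param hidden_dim width of token representations.
#' @param max_len maximum encoded token length (incl. `[CLS]`/`[SEP]`).
#' @param dropout dropout fraction on the residual branches during training.
#' @param ff_dim feed-forward inner width (default `4 * hidden_dim`).
#' @return A `model_config` list.
#' @details Two presets are provided: [model_config_tiny()], a desk-scale
#'   model (2 layers, 4 heads, width 64) that trains on a CPU in minutes, and
#'   [model_config_full()] with 6 layers and 6 attention heads matching the
#'   full-scale architecture class.
#' @export
model_config <- function(n_layers = 2L, n_heads = 4L, hidden_dim = 64L,
                         max_len = 260L, dropout = 0, ff_dim = NULL) {
  if (hidden_dim %% n_heads != 0L) {
    stop("`hidden_dim` must be divisible by `n_heads`")
  }
  if (is.null(ff_dim)) ff_dim <- 4L * hidden_dim
  structure(list(n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 hidden_dim = as.integer(hidden_dim),
                 max_len = as.integer(max_len),
                 dropout = dropout,
                 ff_dim = as.integer(ff_dim)),
            class = "model_config")
}

#' @rdname model_config
#' @export
model_config_tiny <- function(max_len = 260L, dropout = 0) {
  model_config(2L, 4L, 64L, max_len = max_len, dropout = dropout)
}

#' @rdname model_config
#' @export
model_config_full <- function(max_len = 512L, dropout = 0.1) {
  model_config(6L, 6L, 384L, max_len = max_len, dropout = dropout)
}

#' Training configuration
#'
#' @param learning_rate AdamW step size (default `1e-4`).
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param seed RNG seed controlling initialization-independent parts of
#'   training (shuffling, dropout); identical seed + data give identical loss
#'   traces on one device.
#' @param weight_decay decoupled weight decay applied to weight matrices.
#' @param warmup_frac fraction of total steps over which the learning rate
#'   ramps linearly from 0 to `learning_rate` (stabilizes early attention
#'   training); 0 disables warmup.
#' @param schedule learning-rate schedule after warmup: `"cosine"` decays to
#'   zero over the remaining steps, `"constant"` holds the peak rate.
#' @param clip_norm global gradient-norm clipping threshold (`Inf` disables).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 32L,
                         epochs = 5L, seed = 42L, weight_decay = 0.01,
                         warmup_frac = 0.1,
                         schedule = c("cosine", "constant"),
                         clip_norm = 1) {
  if (learning_rate <= 0) stop("`learning_rate` must be positive")
  if (batch_size < 1L) stop("`batch_size` must be >= 1")
  if (warmup_frac < 0 || warmup_frac >= 1) {
    stop("`warmup_frac` must lie in [0, 1)")
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 seed = as.integer(seed),
                 weight_decay = weight_decay,
                 warmup_frac = warmup_frac,
                 schedule = match.arg(schedule),
                 clip_norm = clip_norm),
            class = "train_config")
}

#' Initialize a lifestyle classification model
#'
#' Weights (including the classification head) are drawn N(0, 0.02^2) and
#' biases start at zero. Zeroing `W_cls` by hand yields a model that
#' predicts exactly p = 0.5 for every input.
#'
#' @param config a [model_config()].
#' @param vocab an [lca_vocabulary()] the model is bound to.
#' @param shift LCA tokenizer shift bound to the model.
#' @param seed seed for weight initialization.
#' @return An object of class `lysotyper_model`.
#' @export
init_model <- function(config = model_config_tiny(), vocab = lca_vocabulary(6L),
                       shift = 2L, seed = 1L) {
  set.seed(seed)
  d <- config$hidden_dim
  ff <- config$ff_dim
  V <- vocab$size
  rmat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
  p <- list(emb = rmat(V, d), pos = rmat(config$max_len, d))
  for (l in seq_len(config$n_layers)) {
    p[[sprintf("l%d_ln1_g", l)]] <- rep(1, d)
    p[[sprintf("l%d_ln1_b", l)]] <- rep(0, d)
    p[[sprintf("l%d_Wq", l)]] <- rmat(d, d)
    p[[sprintf("l%d_bq", l)]] <- rep(0, d)
    p[[sprintf("l%d_Wk", l)]] <- rmat(d, d)
    p[[sprintf("l%d_bk", l)]] <- rep(0, d)
    p[[sprintf("l%d_Wv", l)]] <- rmat(d, d)
    p[[sprintf("l%d_bv", l)]] <- rep(0, d)
    p[[sprintf("l%d_Wo", l)]] <- rmat(d, d)
    p[[sprintf("l%d_bo", l)]] <- rep(0, d)
    p[[sprintf("l%d_ln2_g", l)]] <- rep(1, d)
    p[[sprintf("l%d_ln2_b", l)]] <- rep(0, d)
    p[[sprintf("l%d_W1", l)]] <- rmat(d, ff)
    p[[sprintf("l%d_b1", l)]] <- rep(0, ff)
    p[[sprintf("l%d_W2", l)]] <- rmat(ff, d)
    p[[sprintf("l%d_b2", l)]] <- rep(0, d)
  }
  p$lnf_g <- rep(1, d)
  p$lnf_b <- rep(0, d)
  p$pool_v <- stats::rnorm(d, sd = 0.02)
  p$pool_b <- 0
  # small random classifier init: a zero matrix here would block gradient
  # flow into the encoder until the head moves away from zero
  p$W_cls <- rmat(d, 2L)
  p$b_cls <- rep(0, 2L)
  structure(list(params = p, config = config,
                 tokenizer = list(k = vocab$k, shift = as.integer(shift),
                                  max_len = config$max_len),
                 vocab = vocab, history = NULL),
            class = "lysotyper_model")
}

#' @export
print.lysotyper_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "<lysotyper_model> %d layers, %d heads, dim %d | k=%d shift=%d max_len=%d | %s parameters\n",
    x$config$n_layers, x$config$n_heads, x$config$hidden_dim,
    x$tokenizer$k, x$tokenizer$shift, x$tokenizer$max_len,
    format(np, big.mark = ",")))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epoch(s); last val balanced accuracy %.3f\n",
                nrow(x$history),
                x$history$val_balacc[nrow(x$history)]))
  }
  invisible(x)
}

add_bias <- function(M, b) .add_bias(M, b)

# sigmoid-approximation GELU (Hendrycks-Gimpel): z * sigmoid(1.702 z).
# Chosen over the exact Phi-based form because a fused exp() pass is
# several-fold cheaper than pnorm() on the large activation matrices of the
# training loop. Implemented in C++ (src/attention.cpp).
gelu <- function(z) .gelu_fwd(z)
gelu_grad <- function(z) .gelu_bwd(z)

# numerically stabilized row softmax; a single global max shift preserves
# exact row-wise results (exp(-Inf) = 0 handles masked entries).
row_softmax <- function(S) {
  mx <- max(S)
  if (!is.finite(mx)) mx <- 0
  E <- exp(S - mx)
  E / rowSums(E)
}

ln_forward <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + LN_EPS)
  xhat <- xc * inv
  list(Y = add_bias(xhat * rep(g, each = nrow(X)), b), xhat = xhat, inv = inv)
}

ln_backward <- function(dY, cache, g) {
  n <- nrow(dY)
  dxhat <- dY * rep(g, each = n)
  dX <- cache$inv *
    (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dX = dX,
       dg = colSums(dY * cache$xhat),
       db = colSums(dY))
}

# Forward pass over a batch. `ids` and `mask` are B x T integer matrices
# (0-based token ids). Sequences are processed at the batch's maximal real
# length; trailing all-PAD columns are dropped, which cannot change results
# because PAD keys carry -Inf attention scores and zero pooling weight.
model_forward <- function(model, ids, mask, training = FALSE,
                          keep_cache = FALSE) {
  p <- model$params
  cfg <- model$config
  B <- nrow(ids)
  if (B == 0L) stop("empty batch")
  if (max(ids) >= model$vocab$size || min(ids) < 0L) {
    stop("token id out of vocabulary range")
  }
  Tmax <- max(which(colSums(mask) > 0L))
  ids <- ids[, seq_len(Tmax), drop = FALSE]
  mask <- mask[, seq_len(Tmax), drop = FALSE]
  Tn <- Tmax
  d <- cfg$hidden_dim
  H <- cfg$n_heads
  dh <- d %/% H
  drop_p <- if (training) cfg$dropout else 0

  ids_vec <- as.vector(t(ids))          # rows grouped by sample
  mask_vec <- as.vector(t(mask))
  X <- p$emb[ids_vec + 1L, , drop = FALSE] +
    p$pos[rep(seq_len(Tn), B), , drop = FALSE]

  scale <- 1 / sqrt(dh)

  caches <- if (keep_cache) vector("list", cfg$n_layers) else NULL

  for (l in seq_len(cfg$n_layers)) {
    X_in <- X
    ln1 <- ln_forward(X, p[[sprintf("l%d_ln1_g", l)]],
                      p[[sprintf("l%d_ln1_b", l)]])
    Hh <- ln1$Y
    Q <- add_bias(Hh %*% p[[sprintf("l%d_Wq", l)]], p[[sprintf("l%d_bq", l)]])
    K <- add_bias(Hh %*% p[[sprintf("l%d_Wk", l)]], p[[sprintf("l%d_bk", l)]])
    Vv <- add_bias(Hh %*% p[[sprintf("l%d_Wv", l)]], p[[sprintf("l%d_bv", l)]])
    O <- .attn_forward(Q, K, Vv, mask, H, scale)
    attn_out <- add_bias(O %*% p[[sprintf("l%d_Wo", l)]],
                         p[[sprintf("l%d_bo", l)]])
    drop1 <- NULL
    if (drop_p > 0) {
      drop1 <- matrix(stats::rbinom(length(attn_out), 1L, 1 - drop_p) /
                        (1 - drop_p), nrow(attn_out), ncol(attn_out))
      attn_out <- attn_out * drop1
    }
    X <- X_in + attn_out
    X_mid <- X
    ln2 <- ln_forward(X, p[[sprintf("l%d_ln2_g", l)]],
                      p[[sprintf("l%d_ln2_b", l)]])
    H2 <- ln2$Y
    Z1 <- add_bias(H2 %*% p[[sprintf("l%d_W1", l)]],
                   p[[sprintf("l%d_b1", l)]])
    F1 <- gelu(Z1)
    F2 <- add_bias(F1 %*% p[[sprintf("l%d_W2", l)]],
                   p[[sprintf("l%d_b2", l)]])
    drop2 <- NULL
    if (drop_p > 0) {
      drop2 <- matrix(stats::rbinom(length(F2), 1L, 1 - drop_p) /
                        (1 - drop_p), nrow(F2), ncol(F2))
      F2 <- F2 * drop2
    }
    X <- X_mid + F2
    if (keep_cache) {
      caches[[l]] <- list(X_in = X_in, ln1 = ln1, Hh = Hh, Q = Q, K = K,
                          Vv = Vv, O = O, drop1 = drop1, X_mid = X_mid,
                          ln2 = ln2, H2 = H2, Z1 = Z1, F1 = F1,
                          drop2 = drop2)
    }
  }

  lnf <- ln_forward(X, p$lnf_g, p$lnf_b)
  Hf <- lnf$Y
  u <- as.vector(Hf %*% p$pool_v) + p$pool_b
  u[mask_vec == 0L] <- -Inf
  um <- matrix(u, nrow = Tn)             # column per sample
  umax <- apply(um, 2L, max)
  E <- exp(um - rep(umax, each = Tn))
  alpha_m <- E / rep(colSums(E), each = Tn)
  alpha <- as.vector(alpha_m)
  pooled <- rowsum(Hf * alpha, group = rep(seq_len(B), each = Tn))
  logits <- add_bias(pooled %*% p$W_cls, p$b_cls)
  probs <- row_softmax(logits)

  out <- list(probs = probs, logits = logits, Tn = Tn, B = B)
  if (keep_cache) {
    out$cache <- list(layers = caches, lnf = lnf, Hf = Hf, alpha = alpha,
                      pooled = pooled, ids_vec = ids_vec,
                      mask_vec = mask_vec, mask = mask)
  }
  out
}

# Cross-entropy loss and full parameter gradients for one batch.
# `y` is 0/1 (temperate/virulent). Returns list(loss, grads).
model_backward <- function(model, fwd, y) {
  p <- model$params
  cfg <- model$config
  cache <- fwd$cache
  B <- fwd$B
  Tn <- fwd$Tn
  d <- cfg$hidden_dim
  H <- cfg$n_heads
  dh <- d %/% H
  scale <- 1 / sqrt(dh)

  probs <- fwd$probs
  idx <- cbind(seq_len(B), y + 1L)
  loss <- -mean(log(pmax(probs[idx], 1e-300)))
  dlogits <- probs
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / B

  g <- list()
  pooled <- cache$pooled
  Hf <- cache$Hf
  alpha <- cache$alpha
  grp <- rep(seq_len(B), each = Tn)

  g$W_cls <- crossprod(pooled, dlogits)
  g$b_cls <- colSums(dlogits)
  dpooled <- tcrossprod(dlogits, p$W_cls)   # B x d

  DP <- dpooled[grp, , drop = FALSE]
  dalpha <- rowSums(Hf * DP)
  s <- rowsum(alpha * dalpha, grp)
  du <- alpha * (dalpha - s[grp, 1L])
  dHf <- alpha * DP + outer(du, p$pool_v)
  g$pool_v <- as.vector(crossprod(Hf, du))
  g$pool_b <- sum(du)

  lb <- ln_backward(dHf, cache$lnf, p$lnf_g)
  g$lnf_g <- lb$dg
  g$lnf_b <- lb$db
  dX <- lb$dX

  for (l in rev(seq_len(cfg$n_layers))) {
    cl <- cache$layers[[l]]
    # feed-forward branch
    dF2 <- dX
    if (!is.null(cl$drop2)) dF2 <- dF2 * cl$drop2
    g[[sprintf("l%d_W2", l)]] <- crossprod(cl$F1, dF2)
    g[[sprintf("l%d_b2", l)]] <- colSums(dF2)
    dF1 <- tcrossprod(dF2, p[[sprintf("l%d_W2", l)]])
    dZ1 <- dF1 * gelu_grad(cl$Z1)
    g[[sprintf("l%d_W1", l)]] <- crossprod(cl$H2, dZ1)
    g[[sprintf("l%d_b1", l)]] <- colSums(dZ1)
    dH2 <- tcrossprod(dZ1, p[[sprintf("l%d_W1", l)]])
    lb2 <- ln_backward(dH2, cl$ln2, p[[sprintf("l%d_ln2_g", l)]])
    g[[sprintf("l%d_ln2_g", l)]] <- lb2$dg
    g[[sprintf("l%d_ln2_b", l)]] <- lb2$db
    dX_mid <- dX + lb2$dX
    # attention branch
    dattn <- dX_mid
    if (!is.null(cl$drop1)) dattn <- dattn * cl$drop1
    g[[sprintf("l%d_Wo", l)]] <- crossprod(cl$O, dattn)
    g[[sprintf("l%d_bo", l)]] <- colSums(dattn)
    dO <- tcrossprod(dattn, p[[sprintf("l%d_Wo", l)]])
    ab <- .attn_backward(cl$Q, cl$K, cl$Vv, dO, cache$mask, H, scale)
    dQ <- ab$dQ
    dK <- ab$dK
    dV <- ab$dV
    g[[sprintf("l%d_Wq", l)]] <- crossprod(cl$Hh, dQ)
    g[[sprintf("l%d_bq", l)]] <- colSums(dQ)
    g[[sprintf("l%d_Wk", l)]] <- crossprod(cl$Hh, dK)
    g[[sprintf("l%d_bk", l)]] <- colSums(dK)
    g[[sprintf("l%d_Wv", l)]] <- crossprod(cl$Hh, dV)
    g[[sprintf("l%d_bv", l)]] <- colSums(dV)
    dHh <- tcrossprod(dQ, p[[sprintf("l%d_Wq", l)]]) +
      tcrossprod(dK, p[[sprintf("l%d_Wk", l)]]) +
      tcrossprod(dV, p[[sprintf("l%d_Wv", l)]])
    lb1 <- ln_backward(dHh, cl$ln1, p[[sprintf("l%d_ln1_g", l)]])
    g[[sprintf("l%d_ln1_g", l)]] <- lb1$dg
    g[[sprintf("l%d_ln1_b", l)]] <- lb1$db
    dX <- dX_mid + lb1$dX
  }

  # embeddings: accumulate by token id / by position
  demb <- matrix(0, model$vocab$size, d)
  acc <- rowsum(dX, group = cache$ids_vec)
  demb[as.integer(rownames(acc)) + 1L, ] <- acc
  g$emb <- demb
  dpos <- matrix(0, cfg$max_len, d)
  pacc <- rowsum(dX, group = rep(seq_len(Tn), B))
  dpos[seq_len(Tn), ] <- pacc
  g$pos <- dpos

  list(loss = loss, grads = g)
}

adamw_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

# Global-norm gradient clipping: scales all gradients so their joint L2
# norm is at most `max_norm`; stabilizes high-learning-rate training.
clip_gradients <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (is.finite(total) && total > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  grads
}

adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.98, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    wd <- if (is.matrix(params[[nm]])) weight_decay else 0
    params[[nm]] <- params[[nm]] - lr * (upd + wd * params[[nm]])
  }
  list(params = params, state = state)
}

label_to_class <- function(label) {
  y <- ifelse(label == "virulent", 1L, 0L)
  if (anyNA(y)) stop("segments must carry 'virulent'/'temperate' labels")
  as.integer(y)
}

#' Train the segment classifier
#'
#' Minimizes mean cross-entropy with AdamW. Validation balanced accuracy is
#' logged each epoch and the best-validation checkpoint is retained. Fully
#' reproducible for a fixed seed, data and device.
#'
#' @param model an [init_model()] result.
#' @param train_segments labeled segment `data.frame` (columns `seq`,
#'   `label`).
#' @param val_segments optional labeled validation segments.
#' @param cfg a [train_config()].
#' @param quiet suppress per-epoch progress messages.
#' @return The trained model; `$history` holds the per-epoch loss/metric
#'   trace.
#' @export
train_classifier <- function(model, train_segments, val_segments = NULL,
                             cfg = train_config(), quiet = FALSE) {
  y <- label_to_class(train_segments$label)
  if (length(unique(y)) < 2L) {
    stop("training data must contain both classes")
  }
  set.seed(cfg$seed)
  enc <- encode_batch(train_segments$seq, model$vocab,
                      shift = model$tokenizer$shift,
                      max_len = model$tokenizer$max_len)
  venc <- NULL
  vy <- NULL
  if (!is.null(val_segments)) {
    venc <- encode_batch(val_segments$seq, model$vocab,
                         shift = model$tokenizer$shift,
                         max_len = model$tokenizer$max_len)
    vy <- label_to_class(val_segments$label)
  }
  n <- nrow(enc$ids)
  state <- adamw_init(model$params)
  best <- list(score = -Inf, params = model$params)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), val_balacc = numeric(0),
                     val_auc = numeric(0))
  steps_per_epoch <- length(seq.int(1L, n, by = cfg$batch_size))
  warmup_steps <- max(1, ceiling(cfg$warmup_frac * cfg$epochs *
                                   steps_per_epoch))
  step <- 0L

  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    losses <- numeric(0)
    starts <- seq.int(1L, n, by = cfg$batch_size)
    for (s in starts) {
      sel <- perm[s:min(s + cfg$batch_size - 1L, n)]
      fwd <- model_forward(model, enc$ids[sel, , drop = FALSE],
                           enc$mask[sel, , drop = FALSE],
                           training = TRUE, keep_cache = TRUE)
      bk <- model_backward(model, fwd, y[sel])
      if (!is.finite(bk$loss)) {
        stop(sprintf("non-finite loss at epoch %d step %d; aborting",
                     epoch, which(starts == s)))
      }
      step <- step + 1L
      total_steps <- cfg$epochs * steps_per_epoch
      lr_t <- if (step <= warmup_steps && cfg$warmup_frac > 0) {
        cfg$learning_rate * step / warmup_steps
      } else if (cfg$schedule == "cosine") {
        prog <- (step - warmup_steps) / max(1, total_steps - warmup_steps)
        cfg$learning_rate * 0.5 * (1 + cos(pi * min(1, prog)))
      } else {
        cfg$learning_rate
      }
      grads <- if (is.finite(cfg$clip_norm)) {
        clip_gradients(bk$grads, cfg$clip_norm)
      } else bk$grads
      st <- adamw_step(model$params, grads, state,
                       lr = lr_t,
                       weight_decay = cfg$weight_decay)
      model$params <- st$params
      state <- st$state
      losses <- c(losses, bk$loss)
    }
    val_loss <- NA_real_
    val_balacc <- NA_real_
    val_auc <- NA_real_
    if (!is.null(venc)) {
      ev <- evaluate_encoded(model, venc, vy, batch_size = cfg$batch_size)
      val_loss <- ev$loss
      val_balacc <- ev$balacc
      val_auc <- ev$auc
      # checkpoint selection by AUC: robust to probability drift
      if (!is.na(val_auc) && val_auc > best$score) {
        best <- list(score = val_auc, params = model$params)
      }
    }
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = mean(losses),
                                   val_loss = val_loss,
                                   val_balacc = val_balacc,
                                   val_auc = val_auc))
    if (!quiet) {
      message(sprintf(
        "epoch %d | train loss %.4f | val loss %s | val bal.acc %s | val AUC %s",
        epoch, mean(losses),
        ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss)),
        ifelse(is.na(val_balacc), "-", sprintf("%.3f", val_balacc)),
        ifelse(is.na(val_auc), "-", sprintf("%.3f", val_auc))))
    }
  }
  if (is.finite(best$score)) model$params <- best$params
  model$history <- hist
  model
}

# Loss, balanced accuracy (at 0.5) and rank AUC of a model on pre-encoded
# segments. The AUC is threshold-free and therefore insensitive to the
# global probability drift that background segments acquire in training.
evaluate_encoded <- function(model, enc, y, batch_size = 32L) {
  n <- nrow(enc$ids)
  probs <- matrix(NA_real_, n, 2L)
  for (s in seq.int(1L, n, by = batch_size)) {
    sel <- s:min(s + batch_size - 1L, n)
    fwd <- model_forward(model, enc$ids[sel, , drop = FALSE],
                         enc$mask[sel, , drop = FALSE])
    probs[sel, ] <- fwd$probs
  }
  loss <- -mean(log(pmax(probs[cbind(seq_len(n), y + 1L)], 1e-300)))
  pred <- as.integer(probs[, 2L] >= 0.5)
  sens <- mean(pred[y == 1L] == 1L)
  spec <- mean(pred[y == 0L] == 0L)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  auc <- if (n1 > 0L && n0 > 0L) {
    r <- rank(probs[, 2L])
    (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else NA_real_
  list(loss = loss, balacc = (sens + spec) / 2, auc = auc,
       p_virulent = probs[, 2L])
}

#' Per-segment lifestyle probabilities
#'
#' Tokenizes segments with the model's bound tokenizer settings and runs the
#' encoder in batches. Output order matches input order. Segments shorter
#' than the tokenizer's k cannot be tokenized; they receive a neutral
#' p = 0.5 and are flagged.
#'
#' @param model a trained `lysotyper_model`.
#' @param segments segment `data.frame` with at least a `seq` column.
#' @param batch_size forward-pass batch size.
#' @return `segments` with added columns `p_virulent`, `p_temperate`,
#'   `flagged`.
#' @export
predict_segments <- function(model, segments, batch_size = 32L) {
  if (nrow(segments) == 0L) stop("no segments to predict")
  seqs <- segments$seq
  ok <- nchar(seqs) >= model$vocab$k
  p_vir <- rep(0.5, length(seqs))
  if (any(ok)) {
    enc <- encode_batch(seqs[ok], model$vocab,
                        shift = model$tokenizer$shift,
                        max_len = model$tokenizer$max_len)
    n <- sum(ok)
    pv <- numeric(n)
    for (s in seq.int(1L, n, by = batch_size)) {
      sel <- s:min(s + batch_size - 1L, n)
      fwd <- model_forward(model, enc$ids[sel, , drop = FALSE],
                           enc$mask[sel, , drop = FALSE])
      pv[sel] <- fwd$probs[, 2L]
    }
    p_vir[ok] <- pv
  }
  out <- segments
  out$p_virulent <- p_vir
  out$p_temperate <- 1 - p_vir
  out$flagged <- !ok
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a directory holding the parameters (full-precision JSON)
#' and a JSON sidecar with the architecture, tokenizer binding and a
#' vocabulary hash, so a loaded model is bit-identical to the saved one.
#'
#' @param model a `lysotyper_model`.
#' @param dir checkpoint directory (created if needed).
#' @return `dir` (save) or the restored model (load).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sidecar <- list(
    config = unclass(model$config),
    tokenizer = model$tokenizer,
    vocab_k = model$vocab$k,
    vocab_hash = unname(mm3_hash64(paste(model$vocab$tokens,
                                         collapse = ","), 0L))
  )
  jsonlite::write_json(sidecar, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  # parameters as %.17g strings: bit-exact IEEE round-trip through text
  ser <- lapply(model$params, function(p) {
    list(dim = if (is.matrix(p)) dim(p) else length(p),
         values = sprintf("%.17g", as.vector(p)))
  })
  jsonlite::write_json(ser, file.path(dir, "params.json"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "model.json"),
                                 simplifyVector = TRUE)
  cfg <- do.call(model_config, sidecar$config[c("n_layers", "n_heads",
                                                "hidden_dim", "max_len",
                                                "dropout", "ff_dim")])
  vocab <- lca_vocabulary(sidecar$vocab_k)
  model <- init_model(cfg, vocab, shift = sidecar$tokenizer$shift)
  raw <- jsonlite::read_json(file.path(dir, "params.json"),
                             simplifyVector = TRUE)
  for (nm in names(model$params)) {
    tmpl <- model$params[[nm]]
    entry <- raw[[nm]]
    val <- as.numeric(entry$values)
    stopifnot(length(val) == length(tmpl))
    if (is.matrix(tmpl)) {
      val <- matrix(val, nrow = nrow(tmpl), ncol = ncol(tmpl))
    }
    model$params[[nm]] <- val
  }
  model
}
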