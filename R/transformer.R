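#' @title Encoder-decoder transformer in base R
#'
#' @description
#' A compact transformer (pre-layer-norm variant: residual + sublayer on the
#' normalized input, with a final normalization before the output
#' projection) implemented directly in R matrix code with hand-derived
#' backpropagation. The encoder embeds integer m/z tokens through a learned
#' embedding over the m/z vocabulary (mathematically identical to a one-hot
#' matrix times a weight matrix) plus sinusoidal positions; the decoder is
#' autoregressive over the 44-token SMILES dictionary with masked
#' self-attention and cross-attention onto the encoder memory. Training uses
#' stochastic gradient descent (optional momentum) with teacher forcing and
#' `<PAD>`-masked cross-entropy.
#'
#' The full-scale configuration mirrors the reference setup (6+6 layers,
#' 8 heads, width 512); the `"toy"` preset (2+2 layers, width 64) is the
#' test and demonstration surface, small enough to train on a CPU in
#' seconds.
#'
#' @name transformer
NULL

#' Sequence-model configuration
#'
#' @param preset `"full"` (6+6 layers, width 512, 8 heads, feed-forward
#'   2048) or `"toy"` (2+2 layers, width 64, 4 heads, feed-forward 128).
#' @param enc_layers,dec_layers,d_model,n_heads,d_ff architecture overrides.
#' @param seq_len fixed target length (100).
#' @param mz_vocab encoder vocabulary size: integer m/z tokens `0 ..
#'   mz_vocab - 1` (default 50001, i.e. up to m/z 500.00).
#' @param lr learning rate (full preset default 0.001).
#' @param momentum SGD momentum (0 = plain SGD).
#' @param batch_size minibatch size (full preset default 150).
#' @param optimizer `"sgd"` (momentum SGD, the full-scale default) or
#'   `"adam"`; the toy preset defaults to Adam, which reaches memorization
#'   on CPU-scale data in a few hundred epochs where plain SGD stalls.
#' @param clip_norm global gradient-norm clip (Inf disables; toy preset
#'   default 1 for stability at its higher learning rate).
#' @param lr_decay multiplicative learning-rate decay applied every
#'   `decay_every` epochs (1 disables).
#' @param decay_every epochs between decay steps.
#' @return a `seq_model_config`.
#' @export
model_config <- function(preset = c("toy", "full"), enc_layers = NULL,
                         dec_layers = NULL, d_model = NULL, n_heads = NULL,
                         d_ff = NULL, seq_len = 100L, mz_vocab = 50001L,
                         lr = NULL, momentum = NULL, batch_size = NULL,
                         optimizer = NULL, clip_norm = NULL, lr_decay = NULL,
                         decay_every = NULL) {
  preset <- match.arg(preset)
  def <- if (preset == "full") {
    list(enc_layers = 6L, dec_layers = 6L, d_model = 512L, n_heads = 8L,
         d_ff = 2048L, lr = 0.001, momentum = 0, batch_size = 150L,
         optimizer = "sgd", clip_norm = Inf, lr_decay = 1, decay_every = 1L)
  } else {
    list(enc_layers = 2L, dec_layers = 2L, d_model = 64L, n_heads = 4L,
         d_ff = 128L, lr = 0.003, momentum = 0.9, batch_size = 2L,
         optimizer = "adam", clip_norm = 1, lr_decay = 0.5, decay_every = 80L)
  }
  cfg <- list(preset = preset,
              enc_layers = enc_layers %||% def$enc_layers,
              dec_layers = dec_layers %||% def$dec_layers,
              d_model = d_model %||% def$d_model,
              n_heads = n_heads %||% def$n_heads,
              d_ff = d_ff %||% def$d_ff,
              seq_len = as.integer(seq_len),
              mz_vocab = as.integer(mz_vocab),
              lr = lr %||% def$lr,
              momentum = momentum %||% def$momentum,
              batch_size = batch_size %||% def$batch_size,
              optimizer = optimizer %||% def$optimizer,
              clip_norm = clip_norm %||% def$clip_norm,
              lr_decay = lr_decay %||% def$lr_decay,
              decay_every = decay_every %||% def$decay_every)
  stopifnot(cfg$d_model %% cfg$n_heads == 0L)
  structure(cfg, class = "seq_model_config")
}

# ---- parameter initialization -------------------------------------------

.tf_init_params <- function(cfg, vocab_out = 44L) {
  d <- cfg$d_model
  # Xavier-scaled normal init; embeddings use a fixed modest scale
  mat <- function(nr, nc, scale = NULL) {
    if (is.null(scale)) scale <- sqrt(2 / (nr + nc))
    matrix(stats::rnorm(nr * nc, 0, scale), nr, nc)
  }
  layer_attn <- function() list(Wq = mat(d, d), Wk = mat(d, d),
                                Wv = mat(d, d), Wo = mat(d, d))
  layer_ln <- function() list(g = rep(1, d), b = rep(0, d))
  layer_ff <- function() list(W1 = mat(d, cfg$d_ff), b1 = rep(0, cfg$d_ff),
                              W2 = mat(cfg$d_ff, d), b2 = rep(0, d))
  enc <- lapply(seq_len(cfg$enc_layers), function(i) {
    list(ln1 = layer_ln(), attn = layer_attn(), ln2 = layer_ln(),
         ff = layer_ff())
  })
  dec <- lapply(seq_len(cfg$dec_layers), function(i) {
    list(ln1 = layer_ln(), self = layer_attn(), ln2 = layer_ln(),
         cross = layer_attn(), ln3 = layer_ln(), ff = layer_ff())
  })
  list(emb_in = mat(cfg$mz_vocab, d, 0.05), emb_out = mat(vocab_out, d, 0.05),
       enc = enc, dec = dec,
       ln_enc = layer_ln(), ln_dec = layer_ln(),
       Wout = mat(d, vocab_out), bout = rep(0, vocab_out))
}

.tf_pe_cache <- new.env(parent = emptyenv())

.tf_posenc <- function(len, d) {
  key <- paste0(len, "x", d)
  hit <- .tf_pe_cache[[key]]
  if (!is.null(hit)) return(hit)
  pos <- matrix(0, len, d)
  p <- seq_len(len) - 1
  for (i in seq_len(d %/% 2)) {
    f <- 1 / (10000^((2 * (i - 1)) / d))
    pos[, 2 * i - 1] <- sin(p * f)
    pos[, 2 * i] <- cos(p * f)
  }
  .tf_pe_cache[[key]] <- pos
  pos
}

.tf_causal_mask <- function(n) {
  key <- paste0("m", n)
  hit <- .tf_pe_cache[[key]]
  if (!is.null(hit)) return(hit)
  mask <- matrix(0, n, n)
  mask[upper.tri(mask)] <- -1e9
  .tf_pe_cache[[key]] <- mask
  mask
}

.add_bias <- function(x, b) x + rep(b, each = nrow(x))

# ---- forward/backward primitives ----------------------------------------

.ln_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  sd <- sqrt(v + eps)
  xhat <- xc / sd
  list(y = .add_bias(xhat * rep(g, each = nrow(x)), b),
       xhat = xhat, sd = sd)
}

.ln_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- dy * rep(g, each = nrow(dy))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) / cache$sd
  list(dx = dx, dg = dg, db = db)
}

.softmax_rows <- function(z) {
  z <- z - z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z)
  e / rowSums(e)
}

# multi-head attention: queries from xq, keys/values from xkv
.attn_fwd <- function(xq, xkv, p, n_heads, mask = NULL) {
  d <- ncol(xq)
  dk <- d %/% n_heads
  Q <- xq %*% p$Wq; K <- xkv %*% p$Wk; V <- xkv %*% p$Wv
  heads <- vector("list", n_heads)
  O <- matrix(0, nrow(xq), d)
  for (h in seq_len(n_heads)) {
    ix <- ((h - 1) * dk + 1):(h * dk)
    S <- tcrossprod(Q[, ix, drop = FALSE], K[, ix, drop = FALSE]) / sqrt(dk)
    if (!is.null(mask)) S <- S + mask
    A <- .softmax_rows(S)
    O[, ix] <- A %*% V[, ix, drop = FALSE]
    heads[[h]] <- A
  }
  list(y = O %*% p$Wo, Q = Q, K = K, V = V, A = heads, O = O,
       xq = xq, xkv = xkv)
}

.attn_bwd <- function(dy, cache, p, n_heads) {
  d <- ncol(cache$xq)
  dk <- d %/% n_heads
  dWo <- crossprod(cache$O, dy)
  dO <- tcrossprod(dy, p$Wo)
  dQ <- matrix(0, nrow(cache$xq), d)
  dK <- matrix(0, nrow(cache$xkv), d)
  dV <- matrix(0, nrow(cache$xkv), d)
  for (h in seq_len(n_heads)) {
    ix <- ((h - 1) * dk + 1):(h * dk)
    A <- cache$A[[h]]
    dOh <- dO[, ix, drop = FALSE]
    dA <- tcrossprod(dOh, cache$V[, ix, drop = FALSE])
    dV[, ix] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(dA * A))
    dS <- dS / sqrt(dk)
    dQ[, ix] <- dS %*% cache$K[, ix, drop = FALSE]
    dK[, ix] <- crossprod(dS, cache$Q[, ix, drop = FALSE])
  }
  list(dxq = tcrossprod(dQ, p$Wq),
       dxkv = tcrossprod(dK, p$Wk) + tcrossprod(dV, p$Wv),
       dWq = crossprod(cache$xq, dQ), dWk = crossprod(cache$xkv, dK),
       dWv = crossprod(cache$xkv, dV), dWo = dWo)
}

.ff_fwd <- function(x, p) {
  h <- .add_bias(x %*% p$W1, p$b1)
  r <- pmax(h, 0)
  list(y = .add_bias(r %*% p$W2, p$b2), x = x, r = r)
}

.ff_bwd <- function(dy, cache, p) {
  dW2 <- crossprod(cache$r, dy)
  db2 <- colSums(dy)
  dr <- tcrossprod(dy, p$W2)
  dh <- dr * (cache$r > 0)
  list(dx = tcrossprod(dh, p$W1), dW1 = crossprod(cache$x, dh),
       db1 = colSums(dh), dW2 = dW2, db2 = db2)
}

# ---- full forward -------------------------------------------------------

.tf_encode <- function(params, cfg, enc_tokens) {
  d <- cfg$d_model
  rows <- enc_tokens + 1L
  # no positional encoding on the encoder side: a peak list is a set, and
  # adding positions would only inject meaningless order information
  x <- params$emb_in[rows, , drop = FALSE] * sqrt(d)
  caches <- vector("list", cfg$enc_layers)
  for (l in seq_len(cfg$enc_layers)) {
    p <- params$enc[[l]]
    c1 <- .ln_fwd(x, p$ln1$g, p$ln1$b)
    a <- .attn_fwd(c1$y, c1$y, p$attn, cfg$n_heads)
    x1 <- x + a$y
    c2 <- .ln_fwd(x1, p$ln2$g, p$ln2$b)
    f <- .ff_fwd(c2$y, p$ff)
    x <- x1 + f$y
    caches[[l]] <- list(c1 = c1, a = a, c2 = c2, f = f)
  }
  cf <- .ln_fwd(x, params$ln_enc$g, params$ln_enc$b)
  list(memory = cf$y, caches = caches, final = cf, rows = rows)
}

.tf_decode <- function(params, cfg, memory, dec_tokens) {
  d <- cfg$d_model
  Td <- length(dec_tokens)
  rows <- dec_tokens + 1L
  x <- params$emb_out[rows, , drop = FALSE] * sqrt(d) + .tf_posenc(Td, d)
  mask <- .tf_causal_mask(Td)
  caches <- vector("list", cfg$dec_layers)
  for (l in seq_len(cfg$dec_layers)) {
    p <- params$dec[[l]]
    c1 <- .ln_fwd(x, p$ln1$g, p$ln1$b)
    a1 <- .attn_fwd(c1$y, c1$y, p$self, cfg$n_heads, mask = mask)
    x1 <- x + a1$y
    c2 <- .ln_fwd(x1, p$ln2$g, p$ln2$b)
    a2 <- .attn_fwd(c2$y, memory, p$cross, cfg$n_heads)
    x2 <- x1 + a2$y
    c3 <- .ln_fwd(x2, p$ln3$g, p$ln3$b)
    f <- .ff_fwd(c3$y, p$ff)
    x <- x2 + f$y
    caches[[l]] <- list(c1 = c1, a1 = a1, c2 = c2, a2 = a2, c3 = c3, f = f)
  }
  cf <- .ln_fwd(x, params$ln_dec$g, params$ln_dec$b)
  logits <- .add_bias(cf$y %*% params$Wout, params$bout)
  list(logits = logits, caches = caches, final = cf, rows = rows)
}

# loss + full backward pass for one (spectrum, target) pair.
# Returns list(loss, grads) where grads mirrors the params structure.
.tf_loss_and_grads <- function(params, cfg, enc_tokens, target, pad_idx = 0L) {
  enc <- .tf_encode(params, cfg, enc_tokens)
  # teacher forcing: input is target shifted right
  eff <- max(which(target != pad_idx))  # last real token (the <EOS>)
  dec_in <- target[seq_len(eff - 1L)]
  dec_out <- target[2:eff]
  dec <- .tf_decode(params, cfg, enc$memory, dec_in)
  probs <- .softmax_rows(dec$logits)
  n <- length(dec_out)
  ll <- -sum(log(pmax(probs[cbind(seq_len(n), dec_out + 1L)], 1e-12))) / n
  dlogits <- probs
  dlogits[cbind(seq_len(n), dec_out + 1L)] <-
    dlogits[cbind(seq_len(n), dec_out + 1L)] - 1
  dlogits <- dlogits / n

  g <- .tf_zero_grads(params)
  d <- cfg$d_model

  # output head
  g$Wout <- crossprod(dec$final$y, dlogits)
  g$bout <- colSums(dlogits)
  dx <- tcrossprod(dlogits, params$Wout)
  lb <- .ln_bwd(dx, dec$final, params$ln_dec$g)
  g$ln_dec$g <- lb$dg; g$ln_dec$b <- lb$db
  dx <- lb$dx
  dmem <- matrix(0, nrow(enc$memory), d)

  for (l in rev(seq_len(cfg$dec_layers))) {
    p <- params$dec[[l]]; cc <- dec$caches[[l]]
    fb <- .ff_bwd(dx, cc$f, p$ff)
    g$dec[[l]]$ff <- list(W1 = fb$dW1, b1 = fb$db1, W2 = fb$dW2, b2 = fb$db2)
    l3 <- .ln_bwd(fb$dx, cc$c3, p$ln3$g)
    g$dec[[l]]$ln3 <- list(g = l3$dg, b = l3$db)
    dx2 <- dx + l3$dx
    ab <- .attn_bwd(dx2, cc$a2, p$cross, cfg$n_heads)
    g$dec[[l]]$cross <- list(Wq = ab$dWq, Wk = ab$dWk, Wv = ab$dWv, Wo = ab$dWo)
    dmem <- dmem + ab$dxkv
    l2 <- .ln_bwd(ab$dxq, cc$c2, p$ln2$g)
    g$dec[[l]]$ln2 <- list(g = l2$dg, b = l2$db)
    dx1 <- dx2 + l2$dx
    sb <- .attn_bwd(dx1, cc$a1, p$self, cfg$n_heads)
    g$dec[[l]]$self <- list(Wq = sb$dWq, Wk = sb$dWk, Wv = sb$dWv, Wo = sb$dWo)
    l1 <- .ln_bwd(sb$dxq + sb$dxkv, cc$c1, p$ln1$g)
    g$dec[[l]]$ln1 <- list(g = l1$dg, b = l1$db)
    dx <- dx1 + l1$dx
  }
  g$emb_out_rows <- dec$rows
  g$emb_out_grad <- dx * sqrt(d)

  # encoder backward
  le <- .ln_bwd(dmem, enc$final, params$ln_enc$g)
  g$ln_enc$g <- le$dg; g$ln_enc$b <- le$db
  dx <- le$dx
  for (l in rev(seq_len(cfg$enc_layers))) {
    p <- params$enc[[l]]; cc <- enc$caches[[l]]
    fb <- .ff_bwd(dx, cc$f, p$ff)
    g$enc[[l]]$ff <- list(W1 = fb$dW1, b1 = fb$db1, W2 = fb$dW2, b2 = fb$db2)
    l2 <- .ln_bwd(fb$dx, cc$c2, p$ln2$g)
    g$enc[[l]]$ln2 <- list(g = l2$dg, b = l2$db)
    dx1 <- dx + l2$dx
    ab <- .attn_bwd(dx1, cc$a, p$attn, cfg$n_heads)
    g$enc[[l]]$attn <- list(Wq = ab$dWq, Wk = ab$dWk, Wv = ab$dWv, Wo = ab$dWo)
    l1 <- .ln_bwd(ab$dxq + ab$dxkv, cc$c1, p$ln1$g)
    g$enc[[l]]$ln1 <- list(g = l1$dg, b = l1$db)
    dx <- dx1 + l1$dx
  }
  g$emb_in_rows <- enc$rows
  g$emb_in_grad <- dx * sqrt(d)
  list(loss = ll, grads = g)
}

.tf_zero_grads <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  g <- list(enc = lapply(params$enc, zero_like),
            dec = lapply(params$dec, zero_like),
            ln_enc = zero_like(params$ln_enc),
            ln_dec = zero_like(params$ln_dec),
            Wout = params$Wout * 0, bout = params$bout * 0)
  g
}

# accumulate b into a (same shape), recursively
.tf_add_grads <- function(a, b) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- .tf_add_grads(a[[nm]], b[[nm]])
    a
  } else a + b
}

.tf_sumsq <- function(x) {
  if (is.list(x)) sum(vapply(x, .tf_sumsq, numeric(1))) else sum(x^2)
}

.tf_scale_grads <- function(x, f) {
  if (is.list(x)) lapply(x, .tf_scale_grads, f = f) else x * f
}

#' Count trainable parameters
#' @param model a trained model or the result of internal initialization.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  params <- if (!is.null(model$params)) model$params else model
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else n <<- n + length(x)
    invisible(NULL)
  }
  walk(params[setdiff(names(params), character(0))])
  n
}

#' Train the spectrum-to-SMILES model
#'
#' Teacher-forced training with `<PAD>`-masked cross-entropy under SGD
#' (optional momentum). Fully reproducible under a fixed seed: identical
#' (seed, data, config) give identical weights and loss trace.
#'
#' @param dataset list of pairs `list(spectrum = integer m/z tokens,
#'   target = length-100 index vector)` (see [make_training_set()]).
#' @param cfg a [model_config()].
#' @param epochs number of passes over the data.
#' @param seed RNG seed for initialization and shuffling.
#' @param verbose print the loss every 25 epochs.
#' @return a `seq_model`: list with `params`, `cfg`, `dict`, `loss_trace`,
#'   `n_parameters`.
#' @export
train_seq_model <- function(dataset, cfg = model_config("toy"), epochs = 100L,
                            seed = 1L, verbose = FALSE) {
  stopifnot(length(dataset) >= 1L)
  dict <- build_token_dictionary()
  set.seed(seed)
  params <- .tf_init_params(cfg, vocab_out = length(dict))
  vel <- NULL
  loss_trace <- numeric(epochs)
  n <- length(dataset)
  lr_now <- cfg$lr
  t_step <- 0L
  emb_in_state <- list(m = params$emb_in * 0, v = params$emb_in * 0)
  emb_out_state <- list(m = params$emb_out * 0, v = params$emb_out * 0)
  for (ep in seq_len(epochs)) {
    if (ep > 1L && cfg$lr_decay < 1 && (ep - 1L) %% cfg$decay_every == 0L) {
      lr_now <- lr_now * cfg$lr_decay
    }
    ord <- sample(n)
    ep_loss <- 0
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    for (bt in batches) {
      acc <- NULL
      emb_in_upd <- list()
      emb_out_upd <- list()
      for (i in bt) {
        r <- .tf_loss_and_grads(params, cfg, dataset[[i]]$spectrum,
                                dataset[[i]]$target)
        ep_loss <- ep_loss + r$loss
        core <- r$grads[c("enc", "dec", "ln_enc", "ln_dec", "Wout", "bout")]
        acc <- if (is.null(acc)) core else .tf_add_grads(acc, core)
        emb_in_upd[[length(emb_in_upd) + 1L]] <-
          list(rows = r$grads$emb_in_rows, g = r$grads$emb_in_grad)
        emb_out_upd[[length(emb_out_upd) + 1L]] <-
          list(rows = r$grads$emb_out_rows, g = r$grads$emb_out_grad)
      }
      scale <- 1 / length(bt)
      if (is.finite(cfg$clip_norm)) {
        gss <- .tf_sumsq(acc) * scale^2 +
          sum(vapply(emb_in_upd, function(u) sum(u$g^2), numeric(1))) * scale^2 +
          sum(vapply(emb_out_upd, function(u) sum(u$g^2), numeric(1))) * scale^2
        gn <- sqrt(gss)
        if (gn > cfg$clip_norm) {
          cf <- cfg$clip_norm / gn
          acc <- .tf_scale_grads(acc, cf)
          emb_in_upd <- lapply(emb_in_upd, function(u) { u$g <- u$g * cf; u })
          emb_out_upd <- lapply(emb_out_upd, function(u) { u$g <- u$g * cf; u })
        }
      }
      t_step <- t_step + 1L
      adam <- identical(cfg$optimizer, "adam")
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      bc <- if (adam) {
        sqrt(1 - b2^t_step) / (1 - b1^t_step)
      } else 1
      # one updater over the (list-structured) dense parameters: momentum
      # SGD or Adam, selected by the config
      upd <- function(pp, gg, vv) {
        if (is.list(pp)) {
          out_p <- pp; out_v <- vv
          for (nm in names(pp)) {
            r <- upd(pp[[nm]], gg[[nm]],
                     if (is.null(vv)) NULL else vv[[nm]])
            out_p[[nm]] <- r$p
            out_v[[nm]] <- r$v
          }
          list(p = out_p, v = out_v)
        } else if (adam) {
          m0 <- if (is.null(vv)) pp * 0 else vv$m
          v0 <- if (is.null(vv)) pp * 0 else vv$v
          gsc <- gg * scale
          m1 <- b1 * m0 + (1 - b1) * gsc
          v1 <- b2 * v0 + (1 - b2) * gsc^2
          list(p = pp - lr_now * bc * m1 / (sqrt(v1) + eps),
               v = list(m = m1, v = v1))
        } else {
          vnew <- cfg$momentum * (if (is.null(vv)) 0 else vv) -
            lr_now * gg * scale
          list(p = pp + vnew, v = vnew)
        }
      }
      core_names <- c("enc", "dec", "ln_enc", "ln_dec", "Wout", "bout")
      r <- upd(params[core_names], acc, vel)
      params[core_names] <- r$p
      vel <- r$v
      # embedding updates touch only the rows seen in the batch ("lazy"
      # state for Adam: moments advance only on touched rows)
      emb_step <- function(mat, state, upds) {
        for (u in upds) {
          # a token can occur at several positions: sum its row gradients
          # (duplicate-index matrix assignment would silently drop all but
          # the last contribution)
          ag <- rowsum(u$g * scale, group = u$rows)
          rows_u <- as.integer(rownames(ag))
          if (adam) {
            state$m[rows_u, ] <- b1 * state$m[rows_u, ] + (1 - b1) * ag
            state$v[rows_u, ] <- b2 * state$v[rows_u, ] + (1 - b2) * ag^2
            mat[rows_u, ] <- mat[rows_u, ] -
              lr_now * bc * state$m[rows_u, ] /
              (sqrt(state$v[rows_u, ]) + eps)
          } else {
            mat[rows_u, ] <- mat[rows_u, ] - lr_now * ag
          }
        }
        list(mat = mat, state = state)
      }
      r_in <- emb_step(params$emb_in, emb_in_state, emb_in_upd)
      params$emb_in <- r_in$mat; emb_in_state <- r_in$state
      r_out <- emb_step(params$emb_out, emb_out_state, emb_out_upd)
      params$emb_out <- r_out$mat; emb_out_state <- r_out$state
    }
    loss_trace[ep] <- ep_loss / n
    if (verbose && ep %% 25L == 0L) {
      message(sprintf("epoch %d loss %.4f", ep, loss_trace[ep]))
    }
  }
  structure(list(params = params, cfg = cfg, dict = dict,
                 loss_trace = loss_trace,
                 n_parameters = count_parameters(list(params = params))),
            class = "seq_model")
}

#' @export
print.seq_model <- function(x, ...) {
  cat("<seq_model> ", x$cfg$preset, " preset: ", x$cfg$enc_layers, "+",
      x$cfg$dec_layers, " layers, width ", x$cfg$d_model, ", ",
      format(x$n_parameters, big.mark = ","), " parameters; final loss ",
      sprintf("%.4f", utils::tail(x$loss_trace, 1)), "\n", sep = "")
  invisible(x)
}

# one autoregressive decode; returns SMILES or NA if invalid tokens emitted
.tf_decode_run <- function(model, enc_tokens, mode, temperature, prefix_idx) {
  dict <- model$dict
  pad <- dict[["<PAD>"]]; sos <- dict[["<SOS>"]]; eos <- dict[["<EOS>"]]
  enc <- .tf_encode(model$params, model$cfg, enc_tokens)
  seq_idx <- c(sos, prefix_idx)
  for (step in seq_len(model$cfg$seq_len - length(seq_idx))) {
    dec <- .tf_decode(model$params, model$cfg, enc$memory, seq_idx)
    logits <- dec$logits[nrow(dec$logits), ]
    nxt <- if (mode == "greedy") {
      which.max(logits) - 1L
    } else {
      pr <- exp((logits - max(logits)) / temperature)
      pr <- pr / sum(pr)
      sample.int(length(pr), 1L, prob = pr) - 1L
    }
    if (nxt == eos) break
    seq_idx <- c(seq_idx, nxt)
  }
  out <- seq_idx[-1]
  out <- out[out != pad]
  names(dict)[match(out, dict)]
}

#' Generate candidate SMILES from a spectrum
#'
#' Runs the decoder `n_runs` times. `"greedy"` takes the argmax token at
#' every step and is deterministic (one distinct candidate regardless of
#' `n_runs`); `"sample"` draws from the temperature-scaled distribution,
#' yielding a frequency-weighted candidate list. Outputs that do not parse
#' as SMILES are discarded and counted.
#'
#' @param model a trained `seq_model`.
#' @param spectrum integer m/z tokens (an `encoded_spectrum` or plain
#'   integer vector).
#' @param n_runs number of decode runs (default 100).
#' @param mode `"greedy"` or `"sample"`.
#' @param temperature softmax temperature for sampling (default 1).
#' @param seed RNG seed for sampling mode.
#' @return data.frame `smiles`, `frequency` (class `candidate_list`),
#'   attribute `n_invalid`.
#' @export
generate_candidates <- function(model, spectrum, n_runs = 100L,
                                mode = c("greedy", "sample"),
                                temperature = 1.0, seed = NULL) {
  stopifnot(inherits(model, "seq_model"), n_runs >= 1L)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  outs <- character(0)
  n_eff <- if (mode == "greedy") 1L else n_runs
  for (r in seq_len(n_eff)) {
    tokens <- .tf_decode_run(model, as.integer(spectrum), mode, temperature,
                             integer(0))
    outs <- c(outs, detokenize_smiles(tokens))
  }
  if (mode == "greedy") outs <- rep(outs, n_runs)
  valid <- vapply(outs, is_valid_smiles, logical(1), USE.NAMES = FALSE)
  n_invalid <- sum(!valid)
  outs <- outs[valid]
  if (!length(outs)) {
    res <- data.frame(smiles = character(0), frequency = integer(0))
  } else {
    tb <- sort(table(outs), decreasing = TRUE)
    res <- data.frame(smiles = names(tb), frequency = as.integer(tb),
                      stringsAsFactors = FALSE)
  }
  structure(res, n_invalid = n_invalid,
            class = c("candidate_list", "data.frame"))
}

#' Re-predict a structure from a trusted fragment prefix
#'
#' The decoder is forced through `<SOS>` plus the tokenized fragment, then
#' free-runs greedily; the output is guaranteed to begin with the fragment
#' verbatim. Used to extend a confidently annotated substructure into a
#' full candidate.
#'
#' @param model a trained `seq_model`.
#' @param spectrum integer m/z tokens.
#' @param fragment_prefix SMILES prefix to preserve (tokenizable, < 98
#'   tokens).
#' @return generated SMILES string beginning with `fragment_prefix`.
#' @export
reseed_generate <- function(model, spectrum, fragment_prefix = "") {
  stopifnot(inherits(model, "seq_model"))
  prefix_tokens <- if (nzchar(fragment_prefix)) {
    tokenize_smiles(fragment_prefix)
  } else character(0)
  if (any(prefix_tokens %in% c("<EOS>", "<PAD>", "<SOS>"))) {
    stop("prefix must not contain special tokens")
  }
  if (length(prefix_tokens) >= 98L) stop("prefix too long")
  prefix_idx <- unname(model$dict[prefix_tokens])
  tokens <- .tf_decode_run(model, as.integer(spectrum), "greedy", 1,
                           prefix_idx)
  detokenize_smiles(tokens)
}
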