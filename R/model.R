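#' Transformer encoder configuration
#'
#' Hyperparameters of the channel-token Transformer encoder used for
#' seizure classification. Each EEG channel's 12-value rhythm-energy
#' vector is one token ("channel embedding"); no positional encoding is
#' applied, so the model is equivariant in the channel dimension and the
#' max-pooled classifier is fully channel-permutation invariant. The
#' token width equals the feature width (`d_model = 12`), so no input
#' projection is needed.
#'
#' Defaults mirror the published architecture: `h = 3` attention heads
#' with `d_k = d_v = d_model / h = 4`, `n_layers = 6` stacked encoder
#' layers, a 2-class softmax head. The per-layer feed-forward width
#' (`ff_hidden`) and the classifier-head width (`mlp_hidden`), the
#' optimiser and its schedule are not part of the published description
#' and are exposed here with conventional defaults.
#'
#' @param d_model token embedding width (feature count per channel).
#' @param h number of attention heads; must divide `d_model`.
#' @param d_k,d_v per-head query/key and value widths; both must equal
#'   `d_model / h`.
#' @param n_layers number of stacked encoder layers (>= 1).
#' @param ff_hidden hidden width of each layer's feed-forward MLP.
#' @param mlp_hidden hidden width of the classifier head MLP.
#' @param n_classes number of output classes (2: non-seizure, seizure).
#' @param dropout dropout rate applied during training to the attention
#'   output and feed-forward hidden activations (0 disables).
#' @param block `"printed"` uses the residual form
#'   `S_i = S_{i-1} + y_i + MLP(LN(y_i))` with `y_i = MSA(LN(S_{i-1}))`;
#'   `"standard"` uses the conventional pre-LN block
#'   `S_i = S' + MLP(LN(S'))`, `S' = S_{i-1} + MSA(LN(S_{i-1}))`.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param val_fraction fraction of the training set held out for early
#'   stopping.
#' @param seed integer seed controlling initialisation, the
#'   validation split, shuffling and dropout; fixing it makes training
#'   bit-for-bit reproducible.
#' @return An object of class `"encoder_config"`.
#' @export
encoder_config <- function(d_model = 12L, h = 3L, d_k = NULL, d_v = NULL,
                           n_layers = 6L, ff_hidden = 48L, mlp_hidden = 32L,
                           n_classes = 2L, dropout = 0,
                           block = c("printed", "standard"),
                           lr = 1e-3, batch_size = 32L, max_epochs = 200L,
                           patience = 10L, val_fraction = 0.2, seed = 1L) {
  block <- match.arg(block)
  d_model <- as.integer(d_model); h <- as.integer(h)
  if (d_model %% h != 0) stop("h = ", h, " must divide d_model = ", d_model)
  if (is.null(d_k)) d_k <- d_model %/% h
  if (is.null(d_v)) d_v <- d_model %/% h
  if (d_k != d_model / h || d_v != d_model / h) {
    stop("constraint d_k = d_v = d_model / h violated: d_model/h = ",
         d_model / h, ", got d_k = ", d_k, ", d_v = ", d_v)
  }
  if (n_layers < 1) stop("need at least one encoder layer")
  if (n_classes != 2L) stop("binary classifier: n_classes must be 2")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(d_model = d_model, h = h, d_k = as.integer(d_k),
                 d_v = as.integer(d_v), n_layers = as.integer(n_layers),
                 ff_hidden = as.integer(ff_hidden),
                 mlp_hidden = as.integer(mlp_hidden),
                 n_classes = as.integer(n_classes), dropout = dropout,
                 block = block, lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "encoder_config")
}

#' @export
print.encoder_config <- function(x, ...) {
  cat("Transformer encoder config: d_model=", x$d_model, ", h=", x$h,
      " heads (d_k=d_v=", x$d_k, "), L=", x$n_layers,
      " layers, block=", x$block, "\n",
      "  ff_hidden=", x$ff_hidden, ", head mlp_hidden=", x$mlp_hidden,
      ", dropout=", x$dropout, "\n",
      "  Adam lr=", x$lr, ", batch=", x$batch_size, ", max_epochs=",
      x$max_epochs, ", patience=", x$patience, ", seed=", x$seed, "\n",
      sep = "")
  invisible(x)
}

#' Number of trainable parameters of an encoder configuration
#'
#' Closed-form count: each layer holds two LayerNorms (2 d each), the
#' per-head Q/K/V projections (no biases), the output projection with
#' bias, and the feed-forward MLP; the head MLP adds its two affine maps.
#'
#' @param config an [encoder_config()].
#' @return Integer parameter count.
#' @export
n_encoder_params <- function(config) {
  d <- config$d_model; dk <- config$d_k; dv <- config$d_v
  h <- config$h; ff <- config$ff_hidden; mh <- config$mlp_hidden
  per_layer <- 2 * d +                       # LN1
    h * (d * dk + d * dk + d * dv) +         # W_Q, W_K, W_V per head
    (h * dv * d + d) +                       # W_O + bias
    2 * d +                                  # LN2
    (d * ff + ff) + (ff * d + d)             # feed-forward
  head <- (d * mh + mh) + (mh * config$n_classes + config$n_classes)
  as.integer(config$n_layers * per_layer + head)
}

# ---- parameter initialisation --------------------------------------------

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

init_params <- function(config) {
  d <- config$d_model; dk <- config$d_k; dv <- config$d_v
  layers <- lapply(seq_len(config$n_layers), function(i) {
    heads <- lapply(seq_len(config$h), function(j) {
      list(Wq = glorot(d, dk), Wk = glorot(d, dk), Wv = glorot(d, dv))
    })
    list(ln1_g = rep(1, d), ln1_b = rep(0, d),
         heads = heads,
         Wo = glorot(config$h * dv, d), bo = rep(0, d),
         ln2_g = rep(1, d), ln2_b = rep(0, d),
         W1 = glorot(d, config$ff_hidden), b1 = rep(0, config$ff_hidden),
         W2 = glorot(config$ff_hidden, d), b2 = rep(0, d))
  })
  head <- list(W1 = glorot(d, config$mlp_hidden),
               b1 = rep(0, config$mlp_hidden),
               W2 = glorot(config$mlp_hidden, config$n_classes),
               b2 = rep(0, config$n_classes))
  list(layers = layers, head = head)
}

# recursive map over parallel nested parameter lists (leaves are numeric)
map_params <- function(f, ...) {
  args <- list(...)
  if (is.list(args[[1]])) {
    out <- vector("list", length(args[[1]]))
    names(out) <- names(args[[1]])
    for (i in seq_along(out)) {
      out[[i]] <- do.call(map_params,
                          c(list(f), lapply(args, `[[`, i)))
    }
    out
  } else {
    do.call(f, args)
  }
}

zero_like <- function(p) map_params(function(x) x * 0, p)

# ---- layer primitives ----------------------------------------------------

LN_EPS <- 1e-5

layernorm_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + LN_EPS)
  xhat <- xc * inv
  list(out = sweep(xhat, 2L, g, "*") + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dout, cache, g) {
  xhat <- cache$xhat; inv <- cache$inv
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  dxhat <- sweep(dout, 2L, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * inv
  list(dx = dx, dg = dg, db = db)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Scaled dot-product self-attention of one head
#'
#' Computes `softmax(Q K' / sqrt(d_k)) V` with `Q = S W_Q`, `K = S W_K`,
#' `V = S W_V` for a single token matrix. Every attention row is a
#' probability distribution over the input tokens (rows sum to 1).
#'
#' @param S numeric matrix, tokens x `d_model`.
#' @param Wq,Wk,Wv projection matrices `d_model x d_k` / `d_k` / `d_v`.
#' @return List with `out` (tokens x `d_v`) and `A` (tokens x tokens
#'   attention weights).
#' @export
self_attention <- function(S, Wq, Wk, Wv) {
  if (ncol(S) != nrow(Wq) || ncol(S) != nrow(Wk) || ncol(S) != nrow(Wv)) {
    stop("projection width mismatch: tokens have ", ncol(S), " features")
  }
  Q <- S %*% Wq; K <- S %*% Wk; V <- S %*% Wv
  A <- softmax_rows(Q %*% t(K) / sqrt(ncol(Wq)))
  list(out = A %*% V, A = A, Q = Q, K = K, V = V)
}

#' Multi-head self-attention
#'
#' Runs `h` parallel [self_attention()] heads and maps the concatenated
#' head outputs through the output projection `W_O`.
#'
#' @param S numeric matrix, tokens x `d_model`.
#' @param layer list with elements `heads` (list of per-head `Wq`, `Wk`,
#'   `Wv`), `Wo` and `bo`, as stored in a fitted model's parameters.
#' @return List with `out` (tokens x `d_model`), `A` (list of per-head
#'   attention matrices) and `concat`.
#' @export
multi_head_attention <- function(S, layer) {
  hs <- lapply(layer$heads, function(hp) {
    self_attention(S, hp$Wq, hp$Wk, hp$Wv)
  })
  concat <- do.call(cbind, lapply(hs, `[[`, "out"))
  out <- concat %*% layer$Wo + rep(layer$bo, each = nrow(S))
  list(out = out, A = lapply(hs, `[[`, "A"), heads = hs, concat = concat)
}

relu <- function(x) x * (x > 0)

dropout_mask <- function(dim1, dim2, rate) {
  if (rate <= 0) return(NULL)
  matrix(stats::rbinom(dim1 * dim2, 1L, 1 - rate), dim1, dim2) / (1 - rate)
}

# ---- encoder forward -----------------------------------------------------

#' Run the Transformer encoder forward
#'
#' Iterates the encoder layers over a feature map (channels x `d_model`)
#' and records every layer's per-head attention matrices. With the
#' `"printed"` block each layer computes `y = MSA(LN(S))` and returns
#' `S + y + MLP(LN(y))`; with `"standard"` it returns the conventional
#' pre-LN residual block.
#'
#' @param S0 numeric matrix, channels x `d_model`.
#' @param params model parameters (as in a fitted [seizure_transformer()]).
#' @param config the [encoder_config()].
#' @param training apply dropout (training mode) if configured.
#' @return List with `S` (encoded channels x `d_model`), `attention`
#'   (list over layers of lists over heads of channel x channel
#'   matrices), and an internal cache used by backpropagation.
#' @export
encoder_forward <- function(S0, params, config, training = FALSE) {
  if (ncol(S0) != config$d_model) {
    stop("input width ", ncol(S0), " != d_model ", config$d_model)
  }
  S <- S0
  caches <- vector("list", config$n_layers)
  attn <- vector("list", config$n_layers)
  rate <- if (training) config$dropout else 0
  for (i in seq_len(config$n_layers)) {
    lp <- params$layers[[i]]
    ln1 <- layernorm_fwd(S, lp$ln1_g, lp$ln1_b)
    msa <- multi_head_attention(ln1$out, lp)
    y <- msa$out
    dm1 <- dropout_mask(nrow(y), ncol(y), rate)
    if (!is.null(dm1)) y <- y * dm1
    if (config$block == "printed") {
      ln2 <- layernorm_fwd(y, lp$ln2_g, lp$ln2_b)
    } else {
      Smid <- S + y
      ln2 <- layernorm_fwd(Smid, lp$ln2_g, lp$ln2_b)
    }
    Hff_pre <- ln2$out %*% lp$W1 + rep(lp$b1, each = nrow(S))
    Hff <- relu(Hff_pre)
    dm2 <- dropout_mask(nrow(Hff), ncol(Hff), rate)
    if (!is.null(dm2)) Hff <- Hff * dm2
    M <- Hff %*% lp$W2 + rep(lp$b2, each = nrow(S))
    Snew <- if (config$block == "printed") S + y + M else Smid + M
    if (any(!is.finite(Snew))) {
      stop("non-finite activations in encoder layer ", i)
    }
    caches[[i]] <- list(S_in = S, ln1 = ln1, msa = msa, y = y,
                        ln2 = ln2, Hff_pre = Hff_pre, Hff = Hff,
                        dm1 = dm1, dm2 = dm2,
                        Smid = if (config$block == "standard") Smid else NULL)
    attn[[i]] <- msa$A
    S <- Snew
  }
  list(S = S, attention = attn, caches = caches)
}

#' Classify an encoded feature map
#'
#' Max-pools the encoder output over the channel (token) dimension,
#' passes the pooled `d_model` vector through the MLP head and a softmax,
#' and returns the class probabilities `(non-seizure, seizure)`.
#'
#' @param S_L encoder output, channels x `d_model`.
#' @param head_params head parameter list (`W1`, `b1`, `W2`, `b2`).
#' @return Named probability vector of length 2 summing to 1.
#' @export
classify <- function(S_L, head_params) {
  if (!is.matrix(S_L) || nrow(S_L) < 1) stop("empty channel dimension")
  pooled <- apply(S_L, 2L, max)
  hid <- relu(drop(pooled %*% head_params$W1) + head_params$b1)
  logits <- drop(hid %*% head_params$W2) + head_params$b2
  p <- exp(logits - max(logits))
  p <- p / sum(p)
  names(p) <- c("non_seizure", "seizure")
  p
}

# full forward with cache: returns prob, loss grad hooks
model_forward <- function(x, params, config, training = FALSE) {
  enc <- encoder_forward(x, params, config, training)
  S_L <- enc$S
  pooled <- apply(S_L, 2L, max)
  argmax <- apply(S_L, 2L, which.max)
  hid_pre <- drop(pooled %*% params$head$W1) + params$head$b1
  hid <- relu(hid_pre)
  logits <- drop(hid %*% params$head$W2) + params$head$b2
  p <- exp(logits - max(logits)); p <- p / sum(p)
  list(prob = p, enc = enc, pooled = pooled, argmax = argmax,
       hid_pre = hid_pre, hid = hid)
}

# ---- backward ------------------------------------------------------------

# gradient of cross-entropy loss -log p[y+1] w.r.t. all parameters,
# for one sample. fw = model_forward(..., training) output.
model_backward <- function(x, y, fw, params, config) {
  g <- zero_like(params)
  p <- fw$prob
  dlogits <- p
  dlogits[y + 1L] <- dlogits[y + 1L] - 1
  g$head$W2 <- outer(fw$hid, dlogits)
  g$head$b2 <- dlogits
  dhid <- drop(params$head$W2 %*% dlogits) * (fw$hid_pre > 0)
  g$head$W1 <- outer(fw$pooled, dhid)
  g$head$b1 <- dhid
  dpooled <- drop(params$head$W1 %*% dhid)
  dS <- matrix(0, nrow(x), config$d_model)
  for (j in seq_len(config$d_model)) {
    dS[fw$argmax[j], j] <- dpooled[j]
  }
  for (i in rev(seq_len(config$n_layers))) {
    cc <- fw$enc$caches[[i]]
    lp <- params$layers[[i]]
    gl <- g$layers[[i]]
    n <- nrow(dS)
    # through M = Hff W2 + b2
    dM <- dS
    gl$W2 <- t(cc$Hff) %*% dM
    gl$b2 <- colSums(dM)
    dHff <- dM %*% t(lp$W2)
    if (!is.null(cc$dm2)) dHff <- dHff * cc$dm2
    dHff_pre <- dHff * (cc$Hff_pre > 0)
    gl$W1 <- t(cc$ln2$out) %*% dHff_pre
    gl$b1 <- colSums(dHff_pre)
    dln2_out <- dHff_pre %*% t(lp$W1)
    ln2b <- layernorm_bwd(dln2_out, cc$ln2, lp$ln2_g)
    gl$ln2_g <- ln2b$dg
    gl$ln2_b <- ln2b$db
    if (config$block == "printed") {
      dy <- dS + ln2b$dx           # residual y + through LN2(y)
      dS_in <- dS                  # residual S_{i-1}
    } else {
      dSmid <- dS + ln2b$dx
      dy <- dSmid
      dS_in <- dSmid
    }
    if (!is.null(cc$dm1)) dy <- dy * cc$dm1
    # through y = concat Wo + bo
    gl$Wo <- t(cc$msa$concat) %*% dy
    gl$bo <- colSums(dy)
    dconcat <- dy %*% t(lp$Wo)
    dZ <- matrix(0, n, config$d_model)
    for (hh in seq_len(config$h)) {
      cols <- ((hh - 1) * config$d_v + 1):(hh * config$d_v)
      dH <- dconcat[, cols, drop = FALSE]
      hd <- cc$msa$heads[[hh]]
      hp <- lp$heads[[hh]]
      dA <- dH %*% t(hd$V)
      dV <- t(hd$A) %*% dH
      # softmax rows jacobian
      dScore <- hd$A * (dA - rowSums(dA * hd$A))
      dScore <- dScore / sqrt(config$d_k)
      dQ <- dScore %*% hd$K
      dK <- t(dScore) %*% hd$Q
      Z <- cc$ln1$out
      gl$heads[[hh]]$Wq <- t(Z) %*% dQ
      gl$heads[[hh]]$Wk <- t(Z) %*% dK
      gl$heads[[hh]]$Wv <- t(Z) %*% dV
      dZ <- dZ + dQ %*% t(hp$Wq) + dK %*% t(hp$Wk) + dV %*% t(hp$Wv)
    }
    ln1b <- layernorm_bwd(dZ, cc$ln1, lp$ln1_g)
    gl$ln1_g <- ln1b$dg
    gl$ln1_b <- ln1b$db
    g$layers[[i]] <- gl
    dS <- dS_in + ln1b$dx
  }
  g
}

# cross-entropy loss for one sample
sample_loss <- function(prob, y) -log(max(prob[y + 1L], 1e-12))
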