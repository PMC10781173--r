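test_that("configuration enforces the head-width constraint and L >= 1", {
  cfg <- encoder_config()
  expect_equal(cfg$d_k, 4L)
  expect_equal(cfg$d_v, 4L)
  expect_equal(cfg$d_model / cfg$h, 4)
  expect_error(encoder_config(d_k = 6), "d_k = d_v = d_model / h")
  expect_error(encoder_config(h = 5), "must divide")
  expect_error(encoder_config(n_layers = 0), "at least one")
})

test_that("parameter count matches the closed form", {
  for (cfg in list(encoder_config(),
                   encoder_config(d_model = 6, h = 2, n_layers = 3,
                                  ff_hidden = 10, mlp_hidden = 5))) {
    set.seed(1)
    expect_equal(length(unlist(init_params(cfg))), n_encoder_params(cfg))
  }
})

test_that("self-attention is a softmax-weighted value mix", {
  set.seed(31)
  d <- 4
  # single token: weight is exactly 1, output = S W_V
  S1 <- matrix(rnorm(d), 1, d)
  Wq <- matrix(rnorm(d * 2), d, 2); Wk <- matrix(rnorm(d * 2), d, 2)
  Wv <- matrix(rnorm(d * 2), d, 2)
  sa1 <- self_attention(S1, Wq, Wk, Wv)
  expect_equal(unname(sa1$A), matrix(1, 1, 1))
  expect_equal(sa1$out, S1 %*% Wv)
  # two tokens: compare against hand-computed arithmetic
  S2 <- matrix(rnorm(2 * d), 2, d)
  sa2 <- self_attention(S2, Wq, Wk, Wv)
  Q <- S2 %*% Wq; K <- S2 %*% Wk; V <- S2 %*% Wv
  sc <- Q %*% t(K) / sqrt(2)
  A <- t(apply(sc, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expect_equal(sa2$A, A, tolerance = 1e-12)
  expect_equal(sa2$out, A %*% V, tolerance = 1e-12)
  # attention rows always sum to 1
  S8 <- matrix(rnorm(8 * d), 8, d)
  expect_equal(unname(rowSums(self_attention(S8, Wq, Wk, Wv)$A)),
               rep(1, 8), tolerance = 1e-12)
  expect_error(self_attention(matrix(0, 2, 3), Wq, Wk, Wv), "mismatch")
})

test_that("multi-head attention concatenates heads through W_O", {
  set.seed(32)
  cfg <- encoder_config()
  params <- init_params(cfg)
  layer <- params$layers[[1]]
  S <- matrix(rnorm(5 * 12), 5, 12)
  mh <- multi_head_attention(S, layer)
  expect_equal(dim(mh$out), c(5L, 12L))
  # tied heads produce identical concat blocks
  tied <- layer
  tied$heads <- rep(list(layer$heads[[1]]), 3)
  mt <- multi_head_attention(S, tied)
  expect_equal(mt$concat[, 1:4], mt$concat[, 5:8])
  expect_equal(mt$concat[, 1:4], mt$concat[, 9:12])
  # h = 1 reduces to a single self-attention followed by W_O
  cfg1 <- encoder_config(d_model = 4, h = 1, ff_hidden = 8, mlp_hidden = 4)
  p1 <- init_params(cfg1)
  l1 <- p1$layers[[1]]
  m1 <- multi_head_attention(S[, 1:4], l1)
  sa <- self_attention(S[, 1:4], l1$heads[[1]]$Wq, l1$heads[[1]]$Wk,
                       l1$heads[[1]]$Wv)
  expect_equal(m1$out, sa$out %*% l1$Wo + rep(l1$bo, each = 5))
})

test_that("zero attention and MLP weights leave a pure residual path", {
  cfg <- encoder_config(n_layers = 3)
  set.seed(33)
  params <- init_params(cfg)
  params <- map_params(function(x) x * 0, params)
  for (i in seq_len(cfg$n_layers)) {       # LayerNorm gains back to 1
    params$layers[[i]]$ln1_g <- rep(1, 12)
    params$layers[[i]]$ln2_g <- rep(1, 12)
  }
  S0 <- matrix(rnorm(6 * 12), 6, 12)
  out <- encoder_forward(S0, params, cfg)
  expect_equal(out$S, S0)
})

test_that("attention rows sum to one at every layer and head", {
  set.seed(34)
  cfg <- encoder_config()
  params <- init_params(cfg)
  out <- encoder_forward(matrix(rnorm(23 * 12), 23, 12), params, cfg)
  for (layer in out$attention) {
    for (A in layer) {
      expect_equal(unname(rowSums(A)), rep(1, 23), tolerance = 1e-6)
      expect_true(all(A >= 0 & A <= 1))
    }
  }
})

test_that("classifier output is a proper, channel-permutation-invariant distribution", {
  set.seed(35)
  cfg <- encoder_config()
  params <- init_params(cfg)
  S_L <- matrix(rnorm(23 * 12), 23, 12)
  p <- classify(S_L, params$head)
  expect_equal(sum(p), 1)
  expect_true(all(p > 0 & p < 1))
  expect_equal(classify(S_L[sample(23), ], params$head), p)
  # duplicated channels do not change the max-pooled probabilities
  expect_equal(classify(S_L[c(1:23, 7, 7), ], params$head), p)
  expect_error(classify(matrix(nrow = 0, ncol = 12), params$head), "empty")
})

test_that("backpropagation matches numerical gradients", {
  for (blk in c("printed", "standard")) {
    cfg <- encoder_config(d_model = 6, h = 2, n_layers = 2, ff_hidden = 7,
                          mlp_hidden = 5, block = blk)
    set.seed(36)
    params <- init_params(cfg)
    x <- matrix(rnorm(4 * 6), 4, 6)
    fw <- model_forward(x, params, cfg)
    an <- unlist(model_backward(x, 1L, fw, params, cfg))
    flat <- unlist(params)
    eps <- 1e-6
    pick <- unique(round(seq(1, length(flat), length.out = 80)))
    num <- vapply(pick, function(k) {
      vp <- flat; vm <- flat
      vp[k] <- vp[k] + eps; vm[k] <- vm[k] - eps
      (sample_loss(model_forward(x, utils::relist(vp, params), cfg)$prob, 1L) -
         sample_loss(model_forward(x, utils::relist(vm, params), cfg)$prob, 1L)) /
        (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(num - an[pick]) /
                    pmax(1e-6, abs(num) + abs(an[pick]))), 1e-5)
  }
})

test_that("training separates two Gaussian classes and logs its descent", {
  fixture <- small_trained_model()
  fit <- fixture$model
  gm <- fixture$data
  set.seed(37)
  held <- gaussian_maps(25, seed = 99)
  acc <- mean(predict(fit, held$maps, type = "class") == held$labels)
  expect_gt(acc, 0.95)
  # smoothed loss trajectory is non-increasing overall
  tl <- fit$history$train_loss
  sm <- stats::filter(tl, rep(1 / 3, 3), sides = 2)
  sm <- sm[!is.na(sm)]
  expect_lt(sm[length(sm)], sm[1])
  expect_s3_class(fit, "seizure_transformer")
  expect_output(print(fit), "Transformer")
  expect_output(print(summary(fit)), "Trainable parameters")
})

test_that("training refuses a single-class dataset and d_model mismatches", {
  maps <- lapply(1:6, function(i) matrix(rnorm(24), 2, 12))
  expect_error(seizure_transformer(maps, rep(1L, 6), tiny_config()),
               "single class")
  expect_error(seizure_transformer(lapply(maps, function(m) m[, 1:6]),
                                   rep(0:1, 3), tiny_config()),
               "d_model")
})

test_that("identical seeds reproduce training bit for bit", {
  gm <- gaussian_maps(10, seed = 5)
  cfg <- encoder_config(n_layers = 2, ff_hidden = 8, mlp_hidden = 4,
                        max_epochs = 5, patience = 5, seed = 3)
  f1 <- seizure_transformer(gm$maps, gm$labels, cfg, normalize = FALSE)
  f2 <- seizure_transformer(gm$maps, gm$labels, cfg, normalize = FALSE)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$history, f2$history)
})

test_that("full-model probabilities are channel-permutation invariant", {
  fixture <- small_trained_model()
  fit <- fixture$model
  set.seed(38)
  for (i in 1:5) {
    m <- matrix(rnorm(6 * 12), 6, 12)
    p0 <- predict(fit, m)
    pp <- predict(fit, m[sample(6), ])
    expect_equal(pp, p0, tolerance = 1e-10)
  }
})

test_that("channel attention sums heads then averages columns", {
  # uniform attention gives equal weights
  A_unif <- matrix(1 / 3, 3, 3)
  state <- list(list(A_unif, A_unif, A_unif))
  expect_equal(channel_attention(state), rep(1, 3))
  # hand-built 3x3 example
  A1 <- matrix(c(.5, .3, .2, .2, .6, .2, .1, .1, .8), 3, 3, byrow = TRUE)
  A2 <- diag(3)
  A3 <- matrix(1 / 3, 3, 3)
  state <- list(list(matrix(1 / 3, 3, 3)), list(A1, A2, A3))  # last layer used
  S <- A1 + A2 + A3
  expect_equal(channel_attention(state), colMeans(S))
  # via a fitted model: one weight per channel, nonnegative
  fixture <- small_trained_model()
  w <- channel_attention(fixture$model, fixture$data$maps[[1]])
  expect_length(w, 4L)
  expect_true(all(w >= 0))
})
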