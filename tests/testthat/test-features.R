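test_that("band scheme validates contiguity and ordering", {
  expect_equal(nrow(band_scheme()$bands), 6L)
  expect_error(band_scheme(data.frame(name = c("a", "b"),
                                      low = c(1, 6), high = c(4, 10))),
               "contiguous")
  expect_error(band_scheme(data.frame(name = "a", low = 4, high = 4)),
               "high > low")
})

test_that("compression yields 12 values, band-major, half-open bands", {
  # all-ones matrix over rows 1-49, 1024 columns: each unit value is
  # (#rows in band) x 512 columns
  tf <- fake_tf(matrix(1 + 0i, 49, 1024), freqs = 1:49)
  v <- compress_subbands(tf)
  expect_length(v, 12L)
  expect_equal(unname(v[1]), 3 * 512)          # delta, rows 1-3, first half
  expect_equal(unname(v[2]), 3 * 512)
  expect_equal(unname(v[3]), 4 * 512)          # theta, rows 4-7
  expect_equal(unname(v[7]), 18 * 512)         # beta, rows 12-29
  expect_equal(unname(v[11]), 10 * 512)        # gamma2, rows 40-49
  expect_equal(names(v)[1:3], c("delta.t1", "delta.t2", "theta.t1"))
  # zero matrix compresses to zeros
  expect_equal(unname(compress_subbands(fake_tf(matrix(0i, 49, 8), 1:49))),
               rep(0, 12))
})

test_that("compression rejects matrices not covering the scheme", {
  tf <- fake_tf(matrix(1 + 0i, 30, 64), freqs = 1:30)
  expect_error(compress_subbands(tf), "cover")
})

test_that("energy is additive: the 12 units partition the band total", {
  set.seed(21)
  x <- rnorm(256)
  tf <- stockwell(x, 256, 1, 49)
  v <- compress_subbands(tf)
  expect_equal(sum(v), sum(Mod(tf$values)^2))
})

test_that("feature map has one 12-feature row per channel, in order", {
  set.seed(22)
  seg <- matrix(rnorm(3 * 256), 3, 256,
                dimnames = list(c("A", "B", "C"), NULL))
  fm <- build_feature_map(seg, fs = 256)
  expect_equal(dim(fm), c(3L, 12L))
  expect_equal(rownames(fm), c("A", "B", "C"))
  # matches the single-channel compression path exactly
  plan <- st_plan(256, 256, 1, 49)
  ref <- compress_subbands(stockwell(seg[2, ], 256, 1, 49, plan = plan))
  expect_equal(unname(fm[2, ]), unname(ref), tolerance = 1e-12)
  # duplicating a channel duplicates its feature row
  fm2 <- build_feature_map(seg[c(1, 1, 2, 3), ], fs = 256)
  expect_equal(fm2[1, ], fm2[2, ])
  # a zero channel yields a zero row
  fm3 <- build_feature_map(matrix(0, 1, 256), fs = 256)
  expect_equal(unname(fm3[1, ]), rep(0, 12))
})

test_that("scaling the signal by a scales every feature by a^2", {
  set.seed(23)
  seg <- matrix(rnorm(2 * 256), 2, 256)
  f1 <- build_feature_map(seg, 256)
  f3 <- build_feature_map(3 * seg, 256)
  expect_equal(f3, 9 * f1, tolerance = 1e-10)
})

test_that("permuting channels permutes feature rows identically", {
  set.seed(24)
  seg <- matrix(rnorm(5 * 256), 5, 256)
  perm <- c(4, 1, 5, 2, 3)
  f <- build_feature_map(seg, 256)
  fp <- build_feature_map(seg[perm, ], 256)
  expect_equal(unname(fp), unname(f[perm, ]), tolerance = 1e-12)
})

test_that("normalisation fits, applies and round-trips as an affine map", {
  set.seed(25)
  maps <- lapply(1:8, function(i) matrix(rexp(4 * 12), 4, 12))
  nf <- normalize_features(maps)
  pooled <- do.call(rbind, nf$maps)
  expect_equal(unname(colMeans(pooled)), rep(0, 12), tolerance = 1e-10)
  expect_equal(unname(apply(pooled, 2, sd)), rep(1, 12), tolerance = 1e-10)
  # applying saved stats to held-out data is the stored affine transform
  new_map <- matrix(rexp(4 * 12), 4, 12)
  out <- normalize_features(new_map, stats = nf$stats)$maps
  manual <- sweep(sweep(log10(1 + new_map), 2, nf$stats$center), 2,
                  nf$stats$scale, "/")
  expect_equal(out, manual)
  # identity mode returns input unchanged
  expect_identical(normalize_features(new_map, method = "none")$maps,
                   new_map)
  # zero-variance feature clamps scale with a warning
  degen <- lapply(1:3, function(i) cbind(matrix(rexp(2 * 11), 2, 11), 5))
  expect_warning(nd <- normalize_features(degen), "zero-variance")
  expect_equal(nd$stats$scale[12], 1)
})

test_that("feature CSV round-trips maps and labels", {
  set.seed(26)
  maps <- lapply(1:3, function(i) {
    m <- matrix(rnorm(2 * 12), 2, 12,
                dimnames = list(c("C3-P3", "C4-P4"), NULL))
    colnames(m) <- paste0("f", 1:12)
    m
  })
  labels <- c(0L, 1L, 0L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(maps, labels, path)
  back <- read_features_csv(path)
  expect_equal(back$labels, as.numeric(labels))
  expect_equal(back$maps[[2]], maps[[2]], tolerance = 1e-12)
  expect_equal(rownames(back$maps[[1]]), c("C3-P3", "C4-P4"))
})
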