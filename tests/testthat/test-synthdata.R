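test_that("generator is reproducible and annotates what it injects", {
  r1 <- generate_eeg_record(60, n_channels = 3, n_seizures = 0, seed = 4)
  expect_equal(nrow(r1$annotations), 0L)
  expect_equal(dim(r1$signal), c(3L, 60 * 256))
  r2 <- generate_eeg_record(120, n_channels = 2, n_seizures = 1,
                            seizure_duration_s = c(10, 20), gap_s = 20,
                            seed = 9)
  r3 <- generate_eeg_record(120, n_channels = 2, n_seizures = 1,
                            seizure_duration_s = c(10, 20), gap_s = 20,
                            seed = 9)
  expect_identical(r2$signal, r3$signal)
  expect_identical(r2$annotations, r3$annotations)
  expect_equal(nrow(r2$annotations), 1L)
  expect_true(all(r2$annotations$end_s <= 120))
})

test_that("explicit seizure tables are validated", {
  bad <- data.frame(start_s = c(10, 20), end_s = c(25, 40))
  expect_error(generate_eeg_record(60, 2, seizures = bad, seed = 1),
               "overlap")
  expect_error(generate_eeg_record(60, 2,
                                   seizures = data.frame(start_s = 50,
                                                         end_s = 70),
                                   seed = 1), "outside")
  expect_error(generate_eeg_record(30, 2, n_seizures = 3,
                                   seizure_duration_s = c(20, 30),
                                   seed = 1), "too short")
})

test_that("ictal spans carry at least 3x the 3-30 Hz band energy", {
  rec <- generate_eeg_record(300, n_channels = 3, n_seizures = 1,
                             seizure_duration_s = c(40, 60), gap_s = 60,
                             seed = 14)
  ann <- rec$annotations
  mid_ictal <- floor((ann$start_s[1] + ann$end_s[1]) / 2 / 4) * 4
  band_energy <- function(start_s) {
    seg <- rec$signal[, (start_s * 256 + 1):(start_s * 256 + 1024)]
    fm <- build_feature_map(seg, 256)
    # theta+alpha+beta columns approximate the 3-30 Hz span
    mean(rowSums(fm[, 3:8]))
  }
  expect_gt(band_energy(mid_ictal) / band_energy(8), 3)
})

test_that("segmentation follows the overlap protocol and discards straddlers", {
  ann <- data.frame(start_s = 60, end_s = 70)   # 10-s seizure
  rec <- generate_eeg_record(200, n_channels = 2, seizures = ann, seed = 3)
  ds <- segment_record(rec, mode = "all")
  ictal <- ds$times[ds$labels == 1L]
  expect_equal(ictal, c(60, 62, 64, 66))        # 4 windows at 2-s stride
  inter <- ds$times[ds$labels == 0L]
  # interictal windows: 4-s stride, never intersecting the annotation
  expect_true(all(diff(inter) >= 4))
  expect_true(all(inter + 4 <= 60 | inter >= 70))
  # every ictal window lies entirely within the annotation
  expect_true(all(ictal >= 60 & ictal + 4 <= 70))
})

test_that("a seizure exactly one window long yields exactly one ictal window", {
  ann <- data.frame(start_s = 40, end_s = 44)
  rec <- generate_eeg_record(100, n_channels = 2, seizures = ann, seed = 3)
  ds <- segment_record(rec, mode = "all")
  expect_equal(sum(ds$labels == 1L), 1L)
  expect_equal(ds$times[ds$labels == 1L], 40)
})

test_that("balanced mode equalises class counts deterministically", {
  rec <- generate_eeg_record(400, n_channels = 2, n_seizures = 2,
                             seizure_duration_s = c(20, 30), gap_s = 40,
                             seed = 6)
  b1 <- segment_record(rec, mode = "balanced", seed = 2)
  b2 <- segment_record(rec, mode = "balanced", seed = 2)
  expect_equal(sum(b1$labels == 0L), sum(b1$labels == 1L))
  expect_identical(b1$times, b2$times)
})

test_that("train/test split partitions the dataset 3:1", {
  rec <- generate_eeg_record(420, n_channels = 2, n_seizures = 1,
                             seizure_duration_s = c(30, 40), gap_s = 60,
                             seed = 8)
  ds <- segment_record(rec, mode = "all")
  n <- length(ds$segments)
  sp <- split_train_test(ds, ratio = 0.75, seed = 5)
  expect_equal(length(sp$train$segments), round(0.75 * n))
  expect_equal(length(sp$train$segments) + length(sp$test$segments), n)
  # same seed, same split; union preserves the original multiset of times
  sp2 <- split_train_test(ds, ratio = 0.75, seed = 5)
  expect_identical(sp$train$times, sp2$train$times)
  expect_equal(sort(c(sp$train$times, sp$test$times)), ds$times)
  expect_error(split_train_test(ds, ratio = 1.2), "in \\(0, 1\\)")
})

test_that("contiguous featurization covers the record without overlap", {
  rec <- generate_eeg_record(64, n_channels = 2, seed = 10)
  fr <- featurize_record(rec)
  expect_equal(fr$times, seq(0, 60, by = 4))
  expect_length(fr$maps, 16L)
  expect_equal(dim(fr$maps[[1]]), c(2L, 12L))
})
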