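make_test_volume <- function(n = 8) {
  set.seed(31)
  chans <- lapply(c(PD = 1, T2W = 2, FLAIR = 3, T1pre = 4, T1post = 5),
                  function(s) matrix(rnorm(n * n, mean = s), n, n))
  mpmri_volume(chans)
}

test_that("stack_channels flattens to one row per voxel, one column per channel", {
  vol <- make_test_volume(8)
  f <- stack_channels(vol, normalize = "none")
  expect_equal(dim(f$X), c(64, 4))
  expect_equal(colnames(f$X), c("PD", "T2W", "FLAIR", "T1pre"))
  expect_equal(f$X[, "FLAIR"], as.vector(vol$channels$FLAIR))
})

test_that("T1post as an embedding input is a contract violation", {
  vol <- make_test_volume()
  expect_error(stack_channels(vol, c("PD", "T1post")), "ground-truth")
})

test_that("a constant channel z-scores to zero with a warning", {
  vol <- make_test_volume()
  vol$channels$PD[] <- 7
  expect_warning(f <- stack_channels(vol), "zero variance")
  expect_true(all(f$X[, "PD"] == 0))
})

test_that("brain mask restricts rows and the inverse map round-trips", {
  vol <- make_test_volume(8)
  mask <- matrix(FALSE, 8, 8); mask[3:6, 3:6] <- TRUE
  vol$brain_mask <- mask
  f <- stack_channels(vol, normalize = "none")
  expect_equal(nrow(f$X), 16)
  img <- embedding_to_image(f$X[, "T2W"], f)
  expect_equal(img[mask], vol$channels$T2W[mask])
  expect_true(all(img[!mask] == min(f$X[, "T2W"])))
})

test_that("embedding_to_image places values by the inverse map", {
  vol <- mpmri_volume(list(PD = matrix(0, 2, 2)))
  f <- stack_channels(vol, "PD", normalize = "none")
  img <- embedding_to_image(c(1, 2, 3, 4), f)
  expect_equal(matrix(as.numeric(img), 2, 2), matrix(1:4, 2, 2))
})

test_that("polarity flips so high-FLAIR voxels render bright", {
  set.seed(4)
  anchor <- c(rep(0, 90), rep(10, 10))          # last 10 = lesion-like
  y <- c(rnorm(90, 5), rnorm(10, -5))           # lesions dark before flip
  vol <- mpmri_volume(list(PD = matrix(0, 10, 10)))
  f <- stack_channels(vol, "PD", normalize = "none")
  img <- embedding_to_image(y, f, anchor = anchor)
  expect_true(attr(img, "flipped"))
  expect_gt(mean(img[91:100]), mean(img[1:90]))
})

test_that("subtraction image is the clipped post-pre difference", {
  vol <- make_test_volume()
  vol$channels$T1post <- vol$channels$T1pre
  expect_true(all(subtraction_image(vol) == 0))
  vol$channels$T1post[3, 3] <- vol$channels$T1pre[3, 3] + 10
  vol$channels$T1post[5, 5] <- vol$channels$T1pre[5, 5] - 10  # artifact
  s <- subtraction_image(vol)
  expect_equal(s[3, 3], 10)
  expect_equal(s[5, 5], 0)
  expect_equal(sum(s != 0), 1)
  vol$channels$T1post <- NULL
  expect_error(subtraction_image(vol), "T1post")
})

test_that("absolute threshold reproduces the stated example", {
  img <- matrix(c(0, 0, 10, 10), 2)
  m <- binarize(img, "absolute", t = 5)
  expect_equal(as.integer(m), c(0L, 0L, 1L, 1L))
  expect_equal(attr(m, "threshold"), 5)
})

test_that("Otsu on a constant (e.g. all-zero) image warns and returns empty", {
  expect_warning(m <- binarize(matrix(0, 4, 4), "otsu"), "constant")
  expect_equal(sum(m), 0)
})

test_that("Otsu splits a well-separated bimodal sample between the modes", {
  set.seed(12)
  v <- c(rnorm(300, 0, 0.5), rnorm(200, 10, 0.5))
  img <- matrix(v, 25, 20)
  m <- binarize(img, "otsu")
  thr <- attr(m, "threshold")
  expect_gt(thr, 2)
  expect_lt(thr, 8)
  expect_equal(sum(m), 200)
})

test_that("exact Otsu agrees with an independent histogram implementation", {
  # independent oracle: coarse histogram Otsu on binned data
  otsu_hist <- function(v, bins = 512) {
    h <- hist(v, breaks = seq(min(v), max(v), length.out = bins + 1),
              plot = FALSE)
    w <- h$counts / sum(h$counts)
    mids <- h$mids
    best <- -Inf; thr <- NA
    for (i in 1:(bins - 1)) {
      w0 <- sum(w[1:i]); w1 <- 1 - w0
      if (w0 == 0 || w1 == 0) next
      m0 <- sum(w[1:i] * mids[1:i]) / w0
      m1 <- sum(w[(i + 1):bins] * mids[(i + 1):bins]) / w1
      s <- w0 * w1 * (m0 - m1)^2
      if (s > best) { best <- s; thr <- h$breaks[i + 1] }
    }
    thr
  }
  set.seed(77)
  v <- c(rnorm(500, 0), rnorm(300, 6, 2))
  expect_equal(nldrmri:::otsu_threshold(v), otsu_hist(v), tolerance = 0.05)
})

test_that("binarization is idempotent at the recorded threshold", {
  set.seed(9)
  img <- matrix(runif(64), 8, 8)
  m1 <- binarize(img, "otsu")
  m2 <- binarize(matrix(as.numeric(m1), 8, 8), "absolute",
                 t = 0.5)
  expect_equal(as.integer(m2), as.integer(m1))
})

test_that("percentile threshold keeps the expected pixel fraction", {
  img <- matrix(seq_len(100), 10, 10)
  m <- binarize(img, "percentile", p = 90)
  expect_equal(sum(m), 10)
})

test_that("block-mean resampling averages blocks and rejects upsampling", {
  img <- matrix(1, 8, 8)
  expect_true(all(resample_image(img, 4) == 1))
  chk <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  expect_true(all(resample_image(chk, 4) == 0.5))
  m <- matrix(seq_len(16), 4, 4)
  r <- resample_image(m, 2)
  expect_equal(r[1, 1], mean(m[1:2, 1:2]))
  expect_equal(r[2, 2], mean(m[3:4, 3:4]))
  expect_error(resample_image(m, 8), "upsampling")
  expect_error(resample_image(matrix(0, 6, 6), 4), "divide")
})

test_that("masks resample by majority vote to {0,1}", {
  mask <- matrix(0L, 4, 4)
  mask[1:2, 1:2] <- 1L           # full block -> 1
  mask[3, 3] <- 1L               # 1/4 block -> 0
  r <- resample_image(structure(mask, class = c("lesion_mask", "matrix")), 2)
  expect_equal(sort(unique(as.vector(r))), c(0L, 1L))
  expect_equal(r[1, 1], 1L)
  expect_equal(r[2, 2], 0L)
})
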