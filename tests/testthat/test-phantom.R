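test_that("phantom generation is a pure function of its spec", {
  a <- make_phantom(quick_spec(5))
  b <- make_phantom(quick_spec(5))
  expect_identical(a$channels, b$channels)
  expect_identical(a$labels, b$labels)
  c <- make_phantom(quick_spec(6))
  expect_false(identical(a$channels$PD, c$channels$PD))
})

test_that("ground-truth masks nest: active within lesions within white matter", {
  p <- make_phantom(quick_spec(2))
  expect_true(all(p$active_mask <= p$lesion_mask))
  # lesion pixels replaced WM, so they sit inside the brain, off-GM/CSF
  expect_true(all(p$labels[p$lesion_mask == 1] %in% c(4L, 5L)))
  expect_true(all(p$brain_mask[p$lesion_mask == 1]))
  expect_equal(sum(p$active_mask),
               sum(p$labels == 5L))
})

test_that("noise-free subtraction support equals the active mask exactly", {
  p <- make_phantom(quick_spec(3, noise_scale = 0))
  s <- subtraction_image(p)
  expect_equal(as.integer(s > 0), as.integer(p$active_mask))
  # any threshold inside (0, enhancement) reproduces the active mask
  for (t in c(1e-6, 5, p$spec$enhancement - 1e-6)) {
    m <- binarize(s, "absolute", t = t)
    expect_equal(as.integer(m), as.integer(p$active_mask))
  }
})

test_that("only active lesions enhance; inactive lesions have pre = post", {
  p <- make_phantom(quick_spec(4, noise_scale = 0))
  inact <- p$labels == 4L
  expect_equal(p$channels$T1post[inact], p$channels$T1pre[inact])
  act <- p$labels == 5L
  expect_true(all(p$channels$T1post[act] - p$channels$T1pre[act] ==
                    p$spec$enhancement))
})

test_that("an active fraction of zero leaves the subimage empty", {
  p <- make_phantom(quick_spec(5, active_fraction = 0, noise_scale = 0))
  expect_equal(sum(p$active_mask), 0)
  s <- subtraction_image(p)
  expect_true(all(s == 0))
  expect_warning(m <- binarize(s, "otsu"), "constant")
  expect_warning(d <- dice(m, p$active_mask), "both masks empty")
  expect_equal(d$dice, 1)
})

test_that("infeasible lesion placement fails with a clear error", {
  expect_error(
    make_phantom(phantom_spec(grid = 64, n_lesions = 60,
                              lesion_radius = c(30, 40))),
    "could not place"
  )
})

test_that("rician noise and bias field options produce valid volumes", {
  p <- make_phantom(quick_spec(6, noise_model = "rician",
                               bias_amplitude = 0.2))
  expect_true(all(sapply(p$channels, function(m) all(is.finite(m)))))
  expect_true(all(p$channels$T2W >= 0))  # magnitudes are non-negative
})

test_that("activity is jointly but not marginally separable (calibration)", {
  ba_best <- function(x, y) {
    ts <- quantile(x, seq(0.02, 0.98, by = 0.02), names = FALSE)
    best <- 0.5
    for (t in ts) {
      ba <- (mean(x[y] > t) + mean(x[!y] <= t)) / 2
      best <- max(best, ba, 1 - ba)
    }
    best
  }
  for (s in 1:3) {
    p <- make_phantom(phantom_spec(seed = s))  # full default conditions
    lab <- as.vector(p$labels)
    les <- lab %in% c(4L, 5L)
    y <- lab[les] == 5L
    X <- sapply(c("PD", "T2W", "FLAIR", "T1pre"),
                function(ch) as.vector(p$channels[[ch]])[les])
    singles <- apply(X, 2, ba_best, y = y)
    expect_lte(max(singles), 0.75)
    two <- ba_best((X[, "FLAIR"] - X[, "T1pre"]) / sqrt(2), y)
    expect_gte(two, 0.95)
  }
})

test_that("cohorts are deterministic, distinct, and jittered", {
  co1 <- make_cohort(quick_spec(), n_subjects = 5, seed = 11)
  co2 <- make_cohort(quick_spec(), n_subjects = 5, seed = 11)
  expect_identical(co1[[3]]$channels, co2[[3]]$channels)
  expect_false(identical(co1[[1]]$channels$PD, co1[[2]]$channels$PD))
  n_lesions <- sapply(co1, function(p) nrow(p$lesions))
  expect_gt(length(unique(n_lesions)), 1)
})
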