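test_that("Dice endpoints and midpoint behave as printed", {
  A <- rand_mask(); A[1, 1] <- 1
  expect_equal(dice(A, A)$dice, 1)
  B <- matrix(0L, 16, 16); B[1, 2] <- 1L
  A2 <- matrix(0L, 16, 16); A2[1, 1] <- 1L
  expect_equal(dice(A2, B)$dice, 0)
  # |A| = |B| = 100, overlap 50 -> 0.5
  A3 <- matrix(0L, 20, 20); A3[1:100] <- 1L
  B3 <- matrix(0L, 20, 20); B3[51:150] <- 1L
  r <- dice(A3, B3)
  expect_equal(r$dice, 0.5)
  expect_equal(r$tp, 50)
  expect_equal(r$fp, 50)
  expect_equal(r$fn, 50)
})

test_that("both-empty masks score 1 with a warning", {
  z <- matrix(0L, 4, 4)
  expect_warning(r <- dice(z, z), "both masks empty")
  expect_equal(r$dice, 1)
})

test_that("grid mismatch is a contract violation", {
  expect_error(dice(matrix(0, 2, 2), matrix(0, 3, 3)), "same grid")
})

test_that("Dice is symmetric, bounded, and equals the set formula", {
  set.seed(15)
  for (i in 1:100) {
    A <- rand_mask(10, runif(1, 0.05, 0.6))
    B <- rand_mask(10, runif(1, 0.05, 0.6))
    rab <- suppressWarnings(dice(A, B))
    rba <- suppressWarnings(dice(B, A))
    expect_identical(rab$dice, rba$dice)
    expect_gte(rab$dice, 0)
    expect_lte(rab$dice, 1)
    expect_equal(rab$dice, dice_set_form(A, B), tolerance = 1e-15)
  }
})

test_that("growing the intersection at fixed sizes never lowers Dice", {
  n <- 100
  base <- numeric(0)
  for (ov in c(0, 25, 50, 75, 100)) {
    A <- matrix(0L, 20, 20); A[1:n] <- 1L
    B <- matrix(0L, 20, 20); B[(n - ov + 1):(2 * n - ov)] <- 1L
    base <- c(base, suppressWarnings(dice(A, B))$dice)
  }
  expect_true(all(diff(base) >= 0))
})

test_that("DS = 1 only for identical non-empty masks", {
  A <- rand_mask(8, 0.4)
  B <- A
  B[which(A == 1)[1]] <- 0L
  expect_lt(dice(A, B)$dice, 1)
})

test_that("cohort summary reduces to the order statistics it claims", {
  r1 <- tibble::tibble(dice = 0.5)
  s1 <- cohort_summary(r1)
  expect_equal(s1$median_dice, 0.5)
  expect_equal(s1$sd_dice, 0)
  r3 <- tibble::tibble(dice = c(0.6, 0.8, 1.0))
  s3 <- cohort_summary(r3)
  expect_equal(s3$median_dice, 0.8)
  expect_equal(s3$sd_dice, sd(c(0.6, 0.8, 1.0)))
  expect_error(cohort_summary(r3[0, ]), "empty")
  # grouped by method when present
  rm <- tibble::tibble(method = rep(c("isomap", "lle"), each = 3),
                       dice = c(0.7, 0.8, 0.9, 0.4, 0.5, 0.6))
  sm <- cohort_summary(rm)
  expect_equal(nrow(sm), 2)
  expect_equal(sm$median_dice[sm$method == "lle"], 0.5)
})

test_that("a single-value sweep reduces to one result row", {
  p <- make_phantom(quick_spec(1, noise_scale = 0))
  sw <- k_sensitivity_sweep(p, "isomap", k_values = 100)
  expect_equal(nrow(sw), 1)
  expect_s3_class(sw, "sweep_report")
  sm <- summary(sw)
  expect_equal(sm$median_dice, sw$dice)
  expect_equal(sm$sd_dice, 0)
})

test_that("sweep summaries are recomputable from the grid", {
  p <- make_phantom(quick_spec(2, noise_scale = 0))
  sw <- k_sensitivity_sweep(p, "isomap", k_values = c(50, 100, 150))
  expect_equal(summary(sw)$median_dice, median(sw$dice))
  expect_equal(summary(sw)$sd_dice, sd(sw$dice))
})
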