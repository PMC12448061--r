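fake_series <- function(vol, pitch_um = 3) {
  structure(list(volume = vol, pitch_um = pitch_um, extent_mm = 8,
                 n_rep = dim(vol)[3]),
            class = "oct_scan_series")
}

test_that("speckle variance uses the population convention", {
  # identical repeats: zero everywhere
  v <- array(rep(matrix(1:12, 3, 4), 3), c(3, 4, 3, 1))
  sv <- speckle_variance(fake_series(v))
  expect_true(all(sv$values == 0))
  expect_equal(sv$variance_divisor, 3)

  # repeats {1, 3, 5}: population variance 8/3
  v[1, 1, , 1] <- c(1, 3, 5)
  sv <- speckle_variance(fake_series(v))
  expect_equal(sv$values[1, 1, 1], 8 / 3)

  # invariant to a common additive offset per pixel
  v2 <- v + array(rep(matrix(rnorm(12), 3, 4), 3), c(3, 4, 3, 1))
  expect_equal(speckle_variance(fake_series(v2))$values, sv$values,
               tolerance = 1e-12)
})

test_that("flow pixels dominate static pixels in the OCT-A image", {
  g <- gen_oct_series(treated_fraction_retained = 1, seed = 7)
  sv <- speckle_variance(g$untreated)
  flow <- matrix(FALSE, dim(sv$values)[1], dim(sv$values)[2] *
                   dim(sv$values)[3])
  act <- seq_along(g$truth$vessel_cols)
  for (k in act) {
    rows_k <- g$truth$seg_top[k]:(g$truth$seg_top[k] + g$truth$seg_px[k] - 1)
    rows_k <- rows_k[rows_k <= nrow(flow)]
    flow[rows_k, g$truth$vessel_cols[k]] <- TRUE
  }
  vals <- matrix(aperm(sv$values, c(1, 2, 3)), nrow(flow))
  expect_gte(mean(vals[flow]) / mean(vals[!flow]), 5)
})

test_that("vessel density is the gated mean with linear scaling", {
  v <- array(rnorm(60 * 8 * 3 * 2, 10, 1), c(60, 8, 3, 2))
  sv <- speckle_variance(fake_series(v))
  expect_identical(vessel_density(sv, c(0, 1e5)), mean(sv$values))

  sv2 <- sv; sv2$values <- 2 * sv$values
  expect_equal(vessel_density(sv2, c(60, 120)),
               2 * vessel_density(sv, c(60, 120)))

  zero <- sv; zero$values[] <- 0
  expect_identical(vessel_density(zero), 0)

  # lateral permutation invariance: density is an area aggregate
  svp <- sv; svp$values <- sv$values[, sample(8), , drop = FALSE]
  expect_equal(vessel_density(svp, c(60, 120)), vessel_density(sv, c(60, 120)))

  expect_error(vessel_density(sv, c(1e4, 2e4)), "gate")
})

test_that("density rises with the programmed vessel areal fraction", {
  dens <- vapply(c(0.05, 0.10, 0.20), function(vf) {
    g <- gen_oct_series(vessel_fraction = vf, seed = 99)
    vessel_density(speckle_variance(g$untreated))
  }, numeric(1))
  expect_true(all(diff(dens) > 0))
})

test_that("percent reduction handles the reference points", {
  expect_identical(percent_reduction(1, 1), 0)
  expect_identical(percent_reduction(0, 2), 100)
  expect_equal(percent_reduction(0.548, 1), 45.2)
  expect_error(percent_reduction(1, 0), "positive")
})

test_that("paired comparison matches the textbook t statistic", {
  a <- c(1.00, 0.80, 0.95)
  b <- c(0.55, 0.50, 0.60)
  res <- paired_compare(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  p_hand <- 2 * pt(-abs(t_hand), df = 2)
  expect_equal(res$t, t_hand)
  expect_equal(res$p_value, p_hand)
  expect_identical(res$df, 2)

  # identical groups
  same <- paired_compare(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$t, 0)
  expect_identical(same$p_value, 1)

  # constant non-zero differences: degenerate, not infinite
  deg <- paired_compare(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p_value))

  expect_error(paired_compare(1, 1), "at least 2")
  expect_error(paired_compare(1:3, 1:4), "paired")
})

test_that("programmed density reductions are recovered in order", {
  est <- vapply(c(0, 30, 60), function(red) {
    mean(vapply(1:3, function(s) {
      g <- gen_oct_series(treated_fraction_retained = 1 - red / 100,
                          seed = 1000 + 10 * red + s)
      du <- vessel_density(speckle_variance(g$untreated))
      dt <- vessel_density(speckle_variance(g$treated))
      percent_reduction(dt, du)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  expect_lt(max(abs(est - c(0, 30, 60))), 3)
})
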