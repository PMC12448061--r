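test_that("baseline statistics recover the generating distribution", {
  # constant stack: zero SD everywhere
  const <- frame_stack(array(7, c(8, 8, 5)))
  bl <- fit_baseline(const, mask = matrix(FALSE, 8, 8))
  expect_true(all(bl$sd == 0))
  expect_true(all(bl$mu == 7))

  # Gaussian stack: per-pixel mean and SD within 3 standard errors
  set.seed(42)
  n <- 200
  fr <- array(rnorm(16 * 16 * n, mean = 50, sd = 5), c(16, 16, n))
  bl <- fit_baseline(frame_stack(fr), mask = matrix(FALSE, 16, 16))
  se_mu <- 5 / sqrt(n)
  se_sd <- 5 / sqrt(2 * (n - 1))
  expect_lt(abs(mean(bl$mu) - 50), 3 * se_mu / sqrt(255))
  expect_lt(abs(mean(bl$sd) - 5), 3 * se_sd / sqrt(255) + 5 / (4 * n))

  expect_error(fit_baseline(frame_stack(array(1, c(4, 4, 1)))), "2 baseline")
})

test_that("frame detection applies the k-sigma rule with masking", {
  mu <- matrix(10, 6, 6); sd_ <- matrix(2, 6, 6)
  mask <- matrix(FALSE, 6, 6); mask[1:3, 1:3] <- TRUE
  bl <- structure(list(mu = mu, sd = sd_, mask = mask, k = 3,
                       global = FALSE), class = "acd_baseline")

  # frame at the baseline mean: silent
  expect_false(detect_frame(mu, bl)$flagged)

  # one unmasked pixel at mu + 3.5 sigma: flagged with count 1
  f <- mu; f[5, 5] <- 10 + 3.5 * 2
  d <- detect_frame(f, bl)
  expect_true(d$flagged)
  expect_identical(d$n_suprathreshold_pixels, 1L)

  # same excursion inside the mask: ignored
  f2 <- mu; f2[2, 2] <- 10 + 10 * 2
  expect_false(detect_frame(f2, bl)$flagged)

  expect_error(detect_frame(matrix(0, 3, 3), bl), "shape")
})

test_that("cavitation probability is the flagged-frame fraction, exactly", {
  mu <- matrix(10, 6, 6); sd_ <- matrix(1, 6, 6)
  bl <- structure(list(mu = mu, sd = sd_, mask = matrix(FALSE, 6, 6),
                       k = 3, global = FALSE), class = "acd_baseline")
  fr <- array(10, c(6, 6, 100))
  hot <- sample(100, 30)
  for (i in hot) fr[3, 3, i] <- 20
  cp <- cavitation_probability(frame_stack(fr), bl)
  expect_identical(as.numeric(cp), 0.30)
  expect_identical(sort(attr(cp, "flagged")), sort(hot))

  # no frame exceeds threshold
  expect_identical(as.numeric(cavitation_probability(
    frame_stack(array(10, c(6, 6, 10))), bl)), 0)

  # invariance under frame reordering
  perm <- frame_stack(fr[, , sample(100)])
  expect_identical(as.numeric(cavitation_probability(perm, bl)),
                   as.numeric(cp))
})

test_that("raising k never increases CP", {
  g0 <- gen_bmode_stack(p_event = 0, seed = 21)
  g <- gen_bmode_stack(p_event = 0.4, event_contrast = 4, seed = 22)
  cps <- vapply(c(1, 2, 3, 5, 8), function(k) {
    bl <- fit_baseline(g0$stack, k = k)
    as.numeric(cavitation_probability(g$stack, bl))
  }, numeric(1))
  expect_true(all(diff(cps) <= 0))
})

test_that("detection separates events from baseline at default contrast", {
  bl <- fit_baseline(gen_bmode_stack(p_event = 0, seed = 31)$stack)
  det <- truth <- logical(0)
  for (s in 1:5) {
    g <- gen_bmode_stack(p_event = 0.5, seed = 31 + s)
    det <- c(det, vapply(seq_len(g$stack$n_frames), function(i)
      detect_frame(g$stack$frames[, , i], bl)$flagged, logical(1)))
    truth <- c(truth, g$truth)
  }
  expect_gte(sum(det & truth) / sum(truth), 0.95)    # sensitivity
  expect_gte(sum(!det & !truth) / sum(!truth), 0.95) # specificity
})

test_that("cp_map assembles per-stack probabilities with labels", {
  bl <- fit_baseline(gen_bmode_stack(p_event = 0, seed = 41)$stack)
  stacks <- list(
    gen_bmode_stack(p_event = 0, pressure_MPa = 0.4, fluence_mJcm2 = 0,
                    seed = 42)$stack,
    gen_bmode_stack(p_event = 0.6, pressure_MPa = 0.8, fluence_mJcm2 = 100,
                    seed = 43)$stack)
  mp <- cp_map(stacks, bl)
  expect_equal(nrow(mp), 2)
  expect_identical(mp$cp[1], 0)
  # map cells equal cavitation_probability applied cell-wise
  expect_identical(mp$cp[2], as.numeric(
    cavitation_probability(stacks[[2]], bl)))
  expect_error(cp_map(stacks, list(bl)), "one per stack")
})
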