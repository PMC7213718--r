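test_that("half-maximum alignment recovers constructed and noisy delays", {
  tr <- toy_ap(pcl = 600)
  self <- align_half_max(tr, tr)
  expect_equal(self$shift, 0)
  expect_equal(self$candidate$v, self$reference$v)

  delayed <- ap_trace(tr$time, c(rep(tr$v[1], 7), tr$v[1:(length(tr$v) - 7)]),
                      pcl = 600)
  al <- align_half_max(tr, delayed)
  expect_equal(al$shift, -7, tolerance = 0.05)

  set.seed(11)
  shifts <- replicate(20, {
    noisy <- add_noise(delayed, 28)
    align_half_max(tr, noisy)$shift
  })
  expect_true(all(abs(shifts + 7) < 0.5))

  flat <- ap_trace(1:100, rep(-80, 100), pcl = 100)
  expect_false(align_half_max(tr, flat)$ok)
})

test_that("affine renormalization solves the least-squares problem exactly", {
  model <- toy_ap(pcl = 500)
  ref <- ap_trace(model$time, 2 * model$v + 3, pcl = 500)
  fit <- lsq_rescale(ref, model)
  expect_equal(fit$alpha, 0.5, tolerance = 1e-12)
  expect_equal(fit$beta, -1.5, tolerance = 1e-10)
  expect_equal(fit$rescaled$v, model$v, tolerance = 1e-9)

  ident <- lsq_rescale(model, model)
  expect_equal(ident$alpha, 1); expect_equal(ident$beta, 0)

  # brute-force grid oracle on a short trace
  short <- ap_trace(0:99, model$v[1:100], pcl = 500)
  cand <- ap_trace(0:99, 0.8 * model$v[1:100] - 12, pcl = 500)
  fit2 <- lsq_rescale(short, cand)
  grid_a <- seq(fit2$alpha - 0.01, fit2$alpha + 0.01, length.out = 81)
  grid_b <- seq(fit2$beta - 1, fit2$beta + 1, length.out = 81)
  sse <- outer(grid_a, grid_b, Vectorize(function(a, b)
    sum((a * short$v + b - cand$v)^2)))
  best <- which(sse == min(sse), arr.ind = TRUE)
  expect_equal(grid_a[best[1]], fit2$alpha, tolerance = 1e-3)
  expect_equal(grid_b[best[2]], fit2$beta, tolerance = 0.05)

  expect_error(lsq_rescale(ap_trace(1:10, rep(1, 10)), ap_trace(1:10, 1:10)),
               "zero-variance")
})

test_that("RMSE obeys its closed forms and the law of large numbers", {
  tr <- toy_ap(pcl = 2000)
  expect_equal(ap_rmse(tr, tr), 0)
  off <- ap_trace(tr$time, tr$v + 6, pcl = 2000)
  expect_equal(ap_rmse(tr, off), 6)
  set.seed(4)
  noisy <- ap_trace(tr$time, tr$v + rnorm(length(tr$v), 0, 6.039), pcl = 2000)
  expect_equal(ap_rmse(tr, noisy), 6.039, tolerance = 0.05)
  expect_error(ap_rmse(tr, ap_trace(1:10, 1:10)), "equal length")
})

test_that("fitness is a weighted unnormalized sum with amplitude discarding", {
  pcls <- c(300, 1000)
  bl <- toy_baselines(pcls)
  cands <- lapply(pcls, function(p) toy_ap(toy_reference() * toy_truth(), p))
  perfect <- ap_fitness(bl, cands)
  expect_equal(perfect$total, 0)
  expect_false(perfect$penalized)

  # constant offsets give per-PCL RMSEs {2,4}; equal unit weights sum to 6
  shifted <- list(ap_trace(cands[[1]]$time, cands[[1]]$v + 2, pcl = 300),
                  ap_trace(cands[[2]]$time, cands[[2]]$v + 4, pcl = 1000))
  bl2 <- baseline_set(cands, mode = "absolute")
  expect_equal(ap_fitness(bl2, shifted)$total, 6)

  # amplitude below 30 mV at one PCL discards the organism
  small <- cands
  small[[2]] <- ap_trace(cands[[2]]$time, cands[[2]]$v * 0.2, pcl = 1000)
  expect_equal(ap_fitness(bl2, small)$total, 1000)
  expect_true(ap_fitness(bl2, small)$penalized)

  # failed simulation at one PCL likewise
  expect_equal(ap_fitness(bl2, list(cands[[1]], NULL))$total, 1000)
})

test_that("optical-mode fitness is invariant to affine transforms and shifts of the input", {
  pcls <- c(300, 1000)
  model <- lapply(pcls, function(p) toy_ap(toy_reference() * toy_truth(), p))
  warp <- function(tr, a, b, lag) {
    v <- a * tr$v + b
    v <- c(rep(v[1], lag), v[1:(length(v) - lag)])
    ap_trace(tr$time, v, pcl = tr$pcl, normalized = TRUE)
  }
  bl_plain <- baseline_set(model, mode = "optical")
  bl_warp <- baseline_set(list(warp(model[[1]], 0.013, 0.6, 4),
                               warp(model[[2]], 0.013, 0.6, 4)),
                          mode = "optical")
  f1 <- ap_fitness(bl_plain, model)$total
  f2 <- ap_fitness(bl_warp, model)$total
  expect_equal(f1, 0, tolerance = 1e-8)
  expect_lt(f2, 0.15)   # residual only from resampling the shifted copy
})

test_that("upstroke masking removes a single contiguous depolarization prefix", {
  tr <- toy_ap(pcl = 500)
  keep <- cardiofit:::upstroke_mask(tr)
  drop_idx <- which(!keep)
  expect_true(length(drop_idx) > 0)
  expect_equal(drop_idx, seq_len(length(drop_idx)))  # contiguous prefix
  expect_true(all(tr$v[drop_idx] < -20))
})

test_that("biomarkers behave on constructed pulses and under affine maps", {
  sq <- square_ap(width = 100)
  bm <- ap_biomarkers(sq, 80)
  expect_equal(bm$apd, 100, tolerance = 2)
  expect_equal(bm$rmp, -85, tolerance = 0.5)
  expect_equal(bm$amplitude, 115, tolerance = 0.5)

  tr <- toy_ap(pcl = 1000)
  a <- ap_biomarkers(tr, 80)$apd
  tr2 <- ap_trace(tr$time, 0.007 * tr$v + 0.4, pcl = 1000)
  b <- ap_biomarkers(tr2, 80)$apd
  expect_equal(a, b, tolerance = 1e-6)

  # never repolarizes to 90% within the window -> undefined marker
  ramp <- ap_trace(0:199, c(rep(-80, 20), rep(30, 180)), pcl = 200)
  expect_true(is.na(ap_biomarkers(ramp, 90)$apd))
})

test_that("noise injection hits the requested SNR and infinite SNR is a no-op", {
  tr <- toy_ap(pcl = 2000)
  long <- ap_trace(rep(0:1999, 5) + rep(0:4 * 2000, each = 2000),
                   rep(tr$v, 5), pcl = 2000)
  noisy <- add_noise(long, 20, seed = 3)
  expect_equal(measure_snr(long, noisy), 20, tolerance = 0.5)
  expect_identical(add_noise(tr, Inf), tr)
  # same seed, same realization
  expect_identical(add_noise(tr, 28, seed = 9)$v, add_noise(tr, 28, seed = 9)$v)
  # 28 vs 20 dB noise-sigma ratio is 10^(8/20)
  s28 <- sd(add_noise(long, 28, seed = 5)$v - long$v)
  s20 <- sd(add_noise(long, 20, seed = 5)$v - long$v)
  expect_equal(s20 / s28, 10^(8 / 20), tolerance = 0.05)
})

test_that("the 60 Hz notch removes a mains tone without touching the passband", {
  t <- 0:2999
  tone <- sin(2 * pi * 60 * t / 1000)
  tr <- ap_trace(t, tone, pcl = 3000)
  out <- notch_60hz(tr)
  expect_lt(max(abs(out$v[500:2500])), 0.05)
  slow <- ap_trace(t, sin(2 * pi * 5 * t / 1000), pcl = 3000)
  out2 <- notch_60hz(slow)
  expect_equal(out2$v[500:2500], slow$v[500:2500], tolerance = 0.01)
  expect_error(notch_60hz(ap_trace(seq(0, 990, by = 10), rnorm(100))), "200 Hz")
})

test_that("ensemble averaging is exact for identical beats and improves SNR as 10log10(N)", {
  tr <- toy_ap(pcl = 500)
  expect_equal(ensemble_average(list(tr, tr, tr))$v, tr$v)
  set.seed(21)
  n <- 16
  noisy <- lapply(seq_len(n), function(i) add_noise(tr, 20))
  avg <- ensemble_average(noisy)
  gain <- measure_snr(tr, avg) - 20
  expect_equal(gain, 10 * log10(n), tolerance = 2)
  expect_error(ensemble_average(list()), "at least one")
})
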