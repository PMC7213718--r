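test_that("population initialization is deterministic, bounded and log-uniform", {
  spec <- genome_spec("cell", pcls = c(500, 1000))
  cfg <- ga_config(population = 30, generations = 1, mode = "cell")
  set.seed(5); p1 <- init_population(cfg, spec)
  set.seed(5); p2 <- init_population(cfg, spec)
  expect_identical(lapply(p1, `[[`, "genome"), lapply(p2, `[[`, "genome"))
  g <- t(vapply(p1, `[[`, numeric(length(spec$names)), "genome"))
  expect_true(all(g >= matrix(spec$lower, 30, ncol(g), byrow = TRUE)))
  expect_true(all(g <= matrix(spec$upper, 30, ncol(g), byrow = TRUE)))
  expect_equal(length(spec$names), 13 + 2 * 2)

  set.seed(6)
  cfg2 <- ga_config(population = 2000, generations = 1, mode = "cell")
  big <- init_population(cfg2, genome_spec("cell", pcls = 1000))
  mult <- vapply(big, function(o) o$genome[["gKr"]], numeric(1))
  # log-uniform on [0.01, 4]: median = sqrt(0.01 * 4) = 0.2
  expect_equal(median(mult), 0.2, tolerance = 0.15)
})

test_that("SBX degenerates for identical parents and preserves the per-gene mean", {
  spec <- genome_spec("toy")
  g <- stats::setNames(c(1.2, 0.8, 1.1, 0.9), spec$names)
  set.seed(1)
  same <- sbx_crossover(g, g, spec = spec)
  expect_equal(same[[1]], g); expect_equal(same[[2]], g)

  g2 <- stats::setNames(c(0.5, 1.5, 2.0, 0.7), spec$names)
  set.seed(2)
  for (i in 1:50) {
    ch <- sbx_crossover(g, g2, spec = spec)
    expect_equal(ch[[1]] + ch[[2]], g + g2, tolerance = 1e-12)
  }
})

test_that("SBX spread factors follow the order-eta polynomial law", {
  set.seed(8)
  eta <- 10
  b <- sbx_spread(1e5, eta)
  # analytic CDF: F(b) = b^(eta+1)/2 for b <= 1, 1 - b^-(eta+1)/2 above
  cdf <- function(q) ifelse(q <= 1, q^(eta + 1) / 2, 1 - q^(-(eta + 1)) / 2)
  ks <- suppressWarnings(ks.test(b, cdf))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(b <= 1), 0.5, tolerance = 0.01)
})

test_that("Cauchy vector mutation moves all genes, honors bounds, and has HWHM near gamma", {
  spec <- genome_spec("cell", pcls = 1000)
  mid <- (spec$lower + spec$upper) / 2
  set.seed(12)
  in_bounds <- TRUE; moved_all <- TRUE
  for (i in 1:2000) {
    g <- cauchy_vector_mutation(mid, 0.18, spec)
    in_bounds <- in_bounds && all(g >= spec$lower - 1e-9) &&
      all(g <= spec$upper + 1e-9)
    if (i <= 50) moved_all <- moved_all && all(g != mid)
  }
  expect_true(in_bounds)
  expect_true(moved_all)

  # step magnitude in normalized units: median |r| of Cauchy(0, gamma) = gamma
  set.seed(13)
  steps <- replicate(2e4, {
    g <- cauchy_vector_mutation(mid, 0.18, spec)
    sqrt(sum(((g - mid) / spec$base)^2))
  })
  # bound truncation trims the tails slightly, so allow a few percent
  expect_equal(median(steps), 0.18, tolerance = 0.08)
})

test_that("point mutation only touches a subset of genes", {
  spec <- genome_spec("toy")
  mid <- (spec$lower + spec$upper) / 2
  set.seed(3)
  hits <- replicate(500, sum(cauchy_point_mutation(mid, 0.18, 0.1, spec) != mid))
  expect_equal(mean(hits), 0.4, tolerance = 0.15)   # 4 genes x p = 0.1
  expect_true(all(hits <= 4))
})

test_that("tournament selection matches exact enumeration at n = 4", {
  mk <- function(f) list(genome = c(x = f), states = NULL, fitness = f)
  pop <- lapply(c(1, 2, 3, 4), mk)
  # exact expected pool composition over all permutation pairs
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  p4 <- perms(1:4)
  counts <- numeric(4)
  for (a in p4) for (b in p4) {
    w <- ifelse(a <= b, a, b)      # fitness equals index
    for (x in w) counts[x] <- counts[x] + 1
  }
  expected <- counts / length(p4)^2   # expected copies per pool
  set.seed(30)
  emp <- numeric(4)
  best_in_pool <- TRUE
  nrep <- 4000
  for (i in seq_len(nrep)) {
    pool <- tournament_select(pop)
    f <- vapply(pool, `[[`, numeric(1), "fitness")
    for (x in f) emp[x] <- emp[x] + 1
    best_in_pool <- best_in_pool && any(f == 1)
  }
  expect_equal(emp / nrep, expected, tolerance = 0.05)
  # the strict best always enters the pool under the two-shuffled-copies scheme
  expect_true(best_in_pool)

  f <- c(5, 1, 7, 3)
  pop2 <- lapply(f, mk)
  set.seed(31)
  pool <- tournament_select(pop2)
  expect_lte(mean(vapply(pool, `[[`, numeric(1), "fitness")), mean(f))
})

test_that("elitism replaces the worst and guarantees monotone best fitness on a static problem", {
  mk <- function(f) list(genome = c(x = f), states = NULL, fitness = f)
  offspring <- lapply(c(10, 2, 8, 4, 6), mk)
  elites <- lapply(c(1, 3), mk)
  nxt <- elitism_replace(elites, offspring)
  fits <- sort(vapply(nxt, `[[`, numeric(1), "fitness"))
  expect_equal(fits, c(1, 2, 3, 4, 6))
  expect_identical(elitism_replace(list(), offspring), offspring)
  expect_error(elitism_replace(lapply(1:5, mk), offspring), "smaller")

  bl <- toy_baselines()
  cfg <- ga_config(population = 20, generations = 25, mode = "toy")
  set.seed(40)
  res <- run_ga(cfg, bl)
  expect_true(all(diff(res$history$best) <= 1e-12))
})

test_that("genome bounds survive arbitrary operator sequences (fuzz)", {
  spec <- genome_spec("cell", pcls = c(300, 2000))
  cfg <- ga_config(population = 6, generations = 1, mode = "cell")
  set.seed(50)
  pop <- init_population(cfg, spec)
  gs <- lapply(pop, `[[`, "genome")
  for (i in 1:300) {
    op <- sample(3, 1)
    if (op == 1) {
      idx <- sample(6, 2)
      ch <- sbx_crossover(gs[[idx[1]]], gs[[idx[2]]], spec = spec)
      gs[[idx[1]]] <- ch[[1]]; gs[[idx[2]]] <- ch[[2]]
    } else if (op == 2) {
      j <- sample(6, 1)
      gs[[j]] <- cauchy_vector_mutation(gs[[j]], 0.18, spec)
    } else {
      j <- sample(6, 1)
      gs[[j]] <- cauchy_point_mutation(gs[[j]], 0.18, 0.3, spec)
    }
  }
  for (g in gs) {
    expect_true(all(g >= spec$lower - 1e-9))
    expect_true(all(g <= spec$upper + 1e-9))
  }
})

test_that("evaluation writes reached slow concentrations back into the genome", {
  bl0 <- make_baselines(scaling_factors(), pcls = 500, settle_s = 2,
                        mode = "absolute")
  spec <- genome_spec("cell", pcls = 500)
  cfg <- ga_config(population = 2, generations = 1, mode = "cell",
                   n_beats = 3)
  set.seed(60)
  org <- init_population(cfg, spec)[[1]]
  org$genome[1:13] <- 1   # baseline scaling; far-from-steady slow genes remain
  org$genome[["nai_500"]] <- 12
  org$genome[["cansr_500"]] <- 4.5
  ev <- evaluate_organism(org, bl0, cfg, spec)
  expect_true(is.finite(ev$fitness))
  # slow genes move from the imposed values toward the model trajectory
  expect_lt(ev$genome[["cansr_500"]], 4.5)
  expect_equal(ev$states[[1]][["nai"]], ev$genome[["nai_500"]])

  # a non-steady organism drifts: same genome evaluated twice changes fitness
  ev2 <- evaluate_organism(ev, bl0, cfg, spec)
  expect_false(isTRUE(all.equal(ev$fitness, ev2$fitness)))
})

test_that("state persistence alone drives an organism toward pacing steady state", {
  bl <- make_baselines(scaling_factors(), pcls = 500, settle_s = 300,
                       mode = "absolute")
  spec <- genome_spec("cell", pcls = 500)
  cfg <- ga_config(population = 2, generations = 1, mode = "cell")
  org <- init_population(cfg, spec)[[1]]
  org$genome[1:13] <- 1            # right conductances, wrong slow state
  org$genome[["nai_500"]] <- 14
  org$genome[["cansr_500"]] <- 5
  fits <- numeric(25)
  for (k in 1:25) {
    org <- evaluate_organism(org, bl, cfg, spec)
    fits[k] <- org$fitness
  }
  # repeated evaluation (9 beats each) walks the persisted state toward the
  # baseline steady state: fitness and the [Na+]i distance both shrink
  expect_true(all(diff(fits) < 0))
  expect_lt(fits[25], fits[1] / 2)
  truth_nai <- attr(bl, "truth")$nai[["500"]]
  expect_lt(abs(org$genome[["nai_500"]] - truth_nai), abs(14 - truth_nai) / 2)
})

test_that("the toy truth genome evaluates to zero fitness on its own baselines", {
  bl <- toy_baselines()
  spec <- genome_spec("toy", pcls = bl$pcls)
  cfg <- ga_config(population = 2, generations = 1, mode = "toy")
  org <- list(genome = toy_truth(), states = NULL, fitness = Inf)
  ev <- evaluate_organism(org, bl, cfg, spec)
  expect_equal(ev$fitness, 0, tolerance = 1e-10)
})

test_that("the full GA run is reproducible and recovers toy parameters", {
  bl <- toy_baselines()
  cfg <- ga_config(population = 24, generations = 30, mode = "toy")
  set.seed(70); r1 <- run_ga(cfg, bl, snapshot_at = c(10, 30))
  set.seed(70); r2 <- run_ga(cfg, bl)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best$genome, r2$best$genome)
  expect_lt(r1$best$fitness, 30)   # order-of-magnitude sanity at tiny scale
  expect_equal(names(r1$snapshots), c("10", "30"))
  expect_equal(dim(r1$snapshots[["10"]]), c(24, 4))
})
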