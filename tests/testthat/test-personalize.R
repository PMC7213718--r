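test_that("expression rescaling is local, multiplicative and invertible", {
  expr <- expression_fixture()
  fitted <- scaling_factors(gKr = 0.7, gNa = 1.4)

  same <- rescale_by_expression(fitted, expr, "P1", "P2")
  expect_equal(unclass(same), unclass(fitted))

  expr2 <- expr
  expr2["SCN5A", "P2"] <- 2 * expr2["SCN5A", "P1"]
  doubled <- rescale_by_expression(fitted, expr2, "P1", "P2")
  expect_equal(doubled[["gNa"]], 2 * fitted[["gNa"]])
  expect_equal(doubled[setdiff(scaling_names(), "gNa")],
               unclass(fitted)[setdiff(scaling_names(), "gNa")])

  set.seed(101)
  expr3 <- expr
  expr3[, "P2"] <- expr3[, "P1"] * runif(13, 0.3, 3)
  there <- rescale_by_expression(fitted, expr3, "P1", "P2")
  back <- rescale_by_expression(there, expr3, "P2", "P1")
  expect_equal(unclass(back), unclass(fitted), tolerance = 1e-12)
})

test_that("rescaling may leave the search range but respects validity limits", {
  expr <- expression_fixture()
  expr["KCNH2", "P2"] <- expr["KCNH2", "P1"] * 8
  fitted <- scaling_factors(gKr = 1.5)
  out <- rescale_by_expression(fitted, expr, "P1", "P2")
  expect_equal(out[["gKr"]], 12)    # beyond the GA's [0.01, 4]: allowed
  expect_warning(
    clipped <- rescale_by_expression(fitted, expr, "P1", "P2",
                                     limits = c(0.01, 10)),
    "clipped")
  expect_equal(clipped[["gKr"]], 10)
})

test_that("rescaling errors are explicit about the offending gene", {
  expr <- expression_fixture()
  expr["RYR2", "P1"] <- 0
  expect_error(rescale_by_expression(scaling_factors(), expr, "P1", "P2"),
               "RYR2")
  expr2 <- expression_fixture()[-3, ]
  expect_error(rescale_by_expression(scaling_factors(), expr2, "P1", "P2"),
               "KCNJ2")
})

test_that("expression tables round-trip through TSV", {
  expr <- expression_fixture()
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- read_expression_table(path)
  expect_equal(back, expr)
})

test_that("synthetic baselines carry their truth and respect the SNR switch", {
  bl <- make_baselines(scaling_factors(), pcls = c(500, 1000), settle_s = 3,
                       mode = "optical")
  truth <- attr(bl, "truth")
  expect_equal(truth$scaling, rep(1, 13), ignore_attr = TRUE)
  expect_equal(names(truth$nai), c("500", "1000"))
  expect_true(all(vapply(bl$traces, function(tr) tr$normalized, logical(1))))
  expect_true(all(vapply(bl$traces, function(tr)
    min(tr$v) == 0 && max(tr$v) == 1, logical(1))))

  bl_inf <- make_baselines(scaling_factors(), pcls = 500, settle_s = 3,
                           snr_db = Inf, seed = 4, mode = "absolute")
  bl_clean <- make_baselines(scaling_factors(), pcls = 500, settle_s = 3,
                             mode = "absolute")
  expect_equal(bl_inf$traces[[1]]$v, bl_clean$traces[[1]]$v)
})

test_that("steady APD restitution is monotone and responds to ICaL block", {
  pcls <- c(400, 700, 1200)
  rc <- restitution_curve(scaling_factors(), pcls, settle_s = 20)
  expect_true(all(is.finite(rc$apd)))
  expect_true(all(diff(rc$apd) > 0))
  rc_block <- restitution_curve(scaling_factors(PCaL = 0.5), pcls,
                                settle_s = 20)
  expect_true(all(rc_block$apd < rc$apd))
})

test_that("the truth organism scores near-zero fitness on its own baselines", {
  bl <- make_baselines(scaling_factors(), pcls = 600, settle_s = 30,
                       mode = "optical")
  truth <- attr(bl, "truth")
  res <- integrate_cell(truth$final_states[[1]], scaling_factors(),
                        duration = 600, stim_times = 0, pcl = 600)
  fit <- ap_fitness(bl, list(res$trace))
  expect_lt(fit$total, 0.5)
})
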