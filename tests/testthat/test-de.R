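test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(51)
  for (i in 1:5) {
    p <- runif(50)
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q[order(p)] == cummax(q[order(p)])))  # monotone in p
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.5, NA)), "0, 1")
})

test_that("compare_nested recovers a strong spiked slope with direction", {
  cfg <- small_config(seed = 52)
  design <- simulate_design(cfg)
  reg <- assemble_regressors(design, simulate_environment(cfg))
  set.seed(52)
  z <- scale(reg$TAW)[, 1]
  tree <- factor(design$TREE)
  y <- 5 + 1.5 * z + rnorm(nlevels(tree), sd = 0.5)[tree] +
    rnorm(nrow(design), sd = 0.5)
  res <- compare_nested(y, c("TAW", "TEMPERATURE", "DAYLENGTH", "PROVENANCE"),
                        "TAW", design, reg)
  expect_lt(res$p, 1e-10)
  expect_gt(res$dR2, 0.2)
  expect_gt(res$dAIC, 10)          # dropping a real term costs AIC
  expect_identical(res$slope_sign, "+")

  # a useless term: dAIC typically in [-2, 0], dR2 near zero
  y0 <- 5 + rnorm(nlevels(tree), sd = 0.5)[tree] + rnorm(nrow(design), 0.5)
  res0 <- compare_nested(y0, c("TAW", "PROVENANCE"), "TAW", design, reg)
  expect_lt(abs(res0$dR2), 0.1)
  expect_gt(res0$dAIC, -2.5)
  expect_error(
    compare_nested(y, c("TAW"), "DAYLENGTH", design, reg), "not among")
})

test_that("date/provenance family tests interaction then main effects", {
  cfg <- small_config(seed = 53)
  st <- simulate_study(cfg)
  norm <- normalize_counts(st$counts, st$library_totals)
  de <- run_date_provenance(norm$expr, st$samples)
  expect_setequal(unique(de$term), c("DATE:PROVENANCE", "DATE", "PROVENANCE"))
  expect_equal(nrow(de), 3 * nrow(norm$expr))
  expect_true(all(de$p >= 0 & de$p <= 1))
  expect_true(all(de$q >= de$p - 1e-12))
  expect_identical(de$responder, de$q < 0.01)
  # simulated DATE variance (30% of total) makes many transcripts date-responsive
  expect_gt(mean(de$responder[de$term == "DATE"]), 0.3)
  # no interaction was simulated: interaction calls stay rare
  expect_lte(mean(de$responder[de$term == "DATE:PROVENANCE"]), 0.02)
})

test_that("environmental family applies the FDR and effect-size gates", {
  cfg <- sim_config(
    n_transcripts = 120,
    variance_fractions = c(tree = 0.40, date = 0, provenance = 0.12,
                           site = 0, residual = 0.48),
    decorrelate_regressors = TRUE,
    seed = 54)
  st <- simulate_study(cfg)
  norm <- normalize_counts(st$counts, st$library_totals)
  de <- run_environment(norm$expr, st$samples, st$regressors)
  env <- de[de$term %in% c("TAW", "TEMPERATURE", "DAYLENGTH"), ]
  expect_identical(env$responder, env$q < 0.01 & env$dR2 > 0.2)
  prov <- de[de$term == "PROVENANCE", ]
  expect_identical(prov$responder, prov$q < 0.01)
  expect_true(all(env$slope_sign %in% c("+", "-")))

  # recorded truth is recovered with the right directions
  rsets <- responder_sets(de)
  for (r in names(st$truth$responders)) {
    tr <- st$truth$responders[[r]]
    tr <- tr[tr$transcript_id %in% rownames(norm$expr), ]
    up_called <- rsets[[paste0(r, "_up")]]
    sens <- mean(tr$transcript_id[tr$direction == "up"] %in% up_called)
    if (sum(tr$direction == "up") >= 3) expect_gte(sens, 0.6)
  }
  called <- unique(unlist(rsets[setdiff(names(rsets),
                                        c("PROVENANCE_up", "PROVENANCE_down"))]))
  truth <- unique(unlist(lapply(st$truth$responders,
                                function(x) x$transcript_id)))
  expect_gte(mean(intersect(truth, rownames(norm$expr)) %in% called), 0.75)
})

test_that("the environmental family refuses collinear regressors", {
  cfg <- small_config(seed = 55)
  st <- simulate_study(cfg)
  reg <- st$regressors
  reg$TEMPERATURE <- reg$TAW  # perfect collinearity
  norm <- normalize_counts(st$counts, st$library_totals)
  expect_error(run_environment(norm$expr[1:2, ], st$samples, reg),
               "collinear")
})
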