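test_that("design generation follows the common-garden layout", {
  # 8 trees/provenance split over 2 sites, 4 dates/site, no missingness
  cfg <- sim_config(n_trees_per_provenance = 8, missingness = 0,
                    n_transcripts = 2, seed = 41)
  d <- simulate_design(cfg)
  expect_equal(nrow(d), 64)
  expect_equal(length(unique(d$DATE)), 8)
  # each tree belongs to exactly one provenance and one site
  per_tree <- unique(d[, c("TREE", "PROVENANCE", "SITE")])
  expect_equal(nrow(per_tree), length(unique(d$TREE)))
  # dates are site-specific
  expect_equal(length(intersect(d$DATE[d$SITE == "wiesloch"],
                                d$DATE[d$SITE == "schluchsee"])), 0)

  # the field study's missingness: 128 cells down to 75 libraries
  cfg2 <- sim_config(n_trees_per_provenance = 16, n_transcripts = 2, seed = 42)
  expect_equal(nrow(simulate_design(cfg2)), 75)

  # minimal design still carries all four factor labels
  cfg3 <- sim_config(n_trees_per_provenance = 1, n_dates_per_site = 1,
                     missingness = 0, n_transcripts = 2, seed = 43)
  d3 <- simulate_design(cfg3)
  expect_true(all(c("TREE", "PROVENANCE", "SITE", "DATE") %in% names(d3)))
  expect_true(all(table(d3$TREE) == 1))

  expect_error(sim_config(n_trees_per_provenance = 0), "invalid config")
  expect_error(sim_config(n_dates_per_site = 0), "invalid config")
  expect_error(sim_config(variance_fractions = c(tree = 0.5, date = 0.2,
                                                 provenance = 0.2, site = 0.2,
                                                 residual = 0.1)),
               "sum to 1")
})

test_that("synthetic environment has solstice-peaked day length and bounded TAW", {
  cfg <- sim_config(n_transcripts = 2, seed = 44)
  env <- simulate_environment(cfg)
  for (s in unique(env$site)) {
    es <- env[env$site == s, ]
    expect_equal(es$date[which.max(es$day_length)], as.Date("2010-06-21"))
    expect_true(all(es$taw >= 0 & es$taw <= 100))
  }
  # zero noise: midday temperature is exactly the seasonal sinusoid
  sp <- list(wiesloch = list(latitude = 49.5, temp_mean = 9.9,
                             temp_amplitude = 10, temp_noise_sd = 0,
                             taw_mean = 40, taw_sd = 4, taw_autocorr = 0.95))
  env0 <- simulate_environment(cfg, site_params = sp)
  doy <- as.integer(format(env0$date, "%j"))
  expect_equal(env0$midday_temp,
               9.9 + 10 * cos(2 * pi * (doy - 200) / 365.25),
               tolerance = 1e-12)
  expect_equal(env0$midday_temp, env0$daily_mean_temp, tolerance = 1e-12)

  expect_error(
    simulate_environment(cfg, date_range = as.Date(c("2010-05-20",
                                                     "2010-10-31"))),
    "invalid range")
})

test_that("count generation is reproducible and records truth faithfully", {
  cfg <- small_config(seed = 45)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))

  # every library in counts appears exactly once in samples
  expect_identical(colnames(s1$counts), s1$samples$library_id)
  expect_false(any(duplicated(s1$samples$library_id)))

  # every transcript with a nonzero true slope is recorded
  nz <- rownames(s1$truth$slopes)[rowSums(s1$truth$slopes != 0) > 0]
  rec <- unlist(lapply(s1$truth$responders, function(x) x$transcript_id))
  expect_setequal(nz, rec)

  # zero slope magnitude: no responders recorded
  cfg0 <- small_config(slope_magnitude = 0, seed = 46)
  s0 <- simulate_study(cfg0)
  expect_equal(sum(s0$truth$slopes != 0), 0)
})

test_that("realized random-effect variances track the configured fractions", {
  cfg <- sim_config(n_transcripts = 500, seed = 47)
  st <- simulate_counts(simulate_design(cfg), simulate_environment(cfg), cfg)
  for (f in c("tree", "date")) {
    med <- median(st$truth$realized_variance[[f]])
    expect_equal(med, st$truth$sigma2[[f]], tolerance = 0.35)
  }
})

test_that("annotation generator plants enrichment and coherent best-hit groups", {
  cfg <- small_config(seed = 48)
  st <- simulate_study(cfg)
  expect_gt(nrow(st$go$enriched_truth), 0)
  expect_true(all(st$go$enriched_truth$term %in% st$go$ontology$terms$id))
  # best-hit groups partition all transcripts
  expect_identical(sort(names(st$go$besthit)), sort(rownames(st$counts)))

  # odds of 1: nothing is truly enriched
  cfg1 <- small_config(go_enrichment_odds = 1, seed = 49)
  st1 <- simulate_study(cfg1)
  expect_equal(nrow(st1$go$enriched_truth), 0)

  # the toy ontology is a DAG at least 3 levels deep
  anc <- term_ancestors(st$go$ontology)
  expect_gte(max(lengths(anc)), 3)
})

test_that("study fixtures round-trip through the TSV/OBO writers", {
  cfg <- sim_config(n_trees_per_provenance = 4, n_transcripts = 20,
                    missingness = 0, seed = 50)
  st <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_identical(read_counts(file.path(dir, "counts.tsv")), st$counts)
  samp <- read_samples(file.path(dir, "samples.tsv"))
  expect_equal(samp$library_id, st$samples$library_id)
  ont <- read_obo(file.path(dir, "ontology.obo"))
  expect_identical(ont$terms$id, st$go$ontology$terms$id)
  expect_identical(ont$parents[order(names(ont$parents))],
                   st$go$ontology$parents[order(names(st$go$ontology$parents))])
  ann <- read_annotation(file.path(dir, "go_annotation.tsv"))
  expect_identical(ann[order(names(ann))],
                   st$go$annotation[order(names(st$go$annotation))])
})
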