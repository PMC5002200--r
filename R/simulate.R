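#' Configuration for a synthetic common-garden expression study
#'
#' Defines the study design and the generative model for a synthetic
#' repeated-measures RNA-Seq experiment: two provenances grown at two common
#' gardens, trees sampled on four site-specific dates, negative-binomial
#' counts whose log-scale variance is partitioned among TREE, DATE,
#' PROVENANCE, SITE and residual noise, and a tunable subset of transcripts
#' with linear responses to the environmental regressors.
#'
#' Defaults emulate the motivating field study: 16 trees per provenance
#' (8 per provenance at each of two sites), 4 sampling dates per site
#' (8 DATE levels), missingness bringing 128 potential libraries down to 75,
#' variance fractions ordered TREE > DATE > PROVENANCE > SITE, responder
#' fractions of 15/10/16 percent for TAW/TEMPERATURE/DAYLENGTH, and library
#' sizes of 10-40 million aligned reads.
#'
#' @param n_trees_per_provenance trees per provenance, split evenly across
#'   the two sites.
#' @param n_dates_per_site sampling dates per site (DATE levels are
#'   site-specific, so there are twice this many levels).
#' @param missingness fraction of (tree, date) cells dropped uniformly at
#'   random (default 53/128, keeping 75 of 128 libraries).
#' @param variance_fractions named fractions (`tree`, `date`, `provenance`,
#'   `site`, `residual`) of the total log-scale variance; must be
#'   non-negative and sum to 1.
#' @param total_log_sd total log2-scale standard deviation apportioned by
#'   `variance_fractions` (default 1).
#' @param n_transcripts number of simulated transcripts.
#' @param responder_fractions named fractions (`TAW`, `TEMPERATURE`,
#'   `DAYLENGTH`) of transcripts with a nonzero slope for that regressor;
#'   responder sets are disjoint.
#' @param slope_magnitude absolute slope in log2 units per standardized
#'   regressor unit (sign drawn at random per responder).
#' @param dispersion negative-binomial dispersion (`size = 1/dispersion`).
#'   The default 0.05 is the technical/within-library overdispersion only:
#'   biological variation is carried by the explicit random effects, and the
#'   counting noise this dispersion implies on the log2 scale
#'   (`(log2 e)^2 * dispersion ~ 0.10`) must fit inside the configured
#'   residual fraction for the variance decomposition to be realizable.
#' @param mean_log_expression baseline log2 counts-per-million around which
#'   per-transcript baselines are drawn.
#' @param library_size_range range of aligned-read totals; sizes are drawn
#'   log-uniformly.
#' @param besthit_group_sizes named probabilities of best-hit group sizes
#'   (names are the sizes).
#' @param go_n_categories number of leaf GO categories in the toy ontology.
#' @param go_category_size_range min/max transcripts per leaf category.
#' @param go_n_enriched number of categories seeded with responder
#'   enrichment.
#' @param go_enrichment_odds odds by which matched responders are favoured
#'   when filling an enriched category (1 = no enrichment).
#' @param collinear_site_taw if `TRUE`, TAW is generated to track SITE
#'   (distant site means, little weather noise) to exercise the VIF
#'   exclusion rule.
#' @param decorrelate_regressors if `TRUE`, the realized TAW, TEMPERATURE
#'   and DAYLENGTH columns are replaced by their Gram-Schmidt
#'   orthogonalization (in that order, rescaled to the original SDs) before
#'   truth slopes are applied, and the regressor table carries the
#'   decorrelated values.  With only 8 environmental design points, chance
#'   correlation between regressors is substantial for any weather draw;
#'   this mode emulates a campaign in which the three drivers separated
#'   cleanly and is the intended setting for power and error-rate recovery
#'   experiments, where design collinearity would otherwise confound the
#'   property being measured.
#' @param seed integer seed; all generation is reproducible from it.
#' @return A validated list of class `plast_config`.
#' @export
sim_config <- function(n_trees_per_provenance = 16,
                       n_dates_per_site = 4,
                       missingness = 53 / 128,
                       variance_fractions = c(tree = 0.40, date = 0.30,
                                              provenance = 0.12, site = 0.07,
                                              residual = 0.11),
                       total_log_sd = 1.0,
                       n_transcripts = 1000,
                       responder_fractions = c(TAW = 0.15,
                                               TEMPERATURE = 0.10,
                                               DAYLENGTH = 0.16),
                       slope_magnitude = 1.0,
                       dispersion = 0.05,
                       mean_log_expression = 5,
                       library_size_range = c(10e6, 40e6),
                       besthit_group_sizes = c("1" = 0.7, "2" = 0.2,
                                               "3" = 0.1),
                       go_n_categories = 30,
                       go_category_size_range = c(15, 40),
                       go_n_enriched = 4,
                       go_enrichment_odds = 8,
                       collinear_site_taw = FALSE,
                       decorrelate_regressors = FALSE,
                       seed = 1L) {
  cfg <- as.list(environment())
  need <- c("tree", "date", "provenance", "site", "residual")
  if (!all(need %in% names(cfg$variance_fractions)))
    stop("invalid config: variance_fractions needs entries ",
         paste(need, collapse = ", "))
  vf <- cfg$variance_fractions[need]
  if (any(vf < 0) || abs(sum(vf) - 1) > 1e-8)
    stop("invalid config: variance fractions must be >= 0 and sum to 1")
  rf <- cfg$responder_fractions
  if (any(rf < 0 | rf > 1))
    stop("invalid config: responder fractions must lie in [0, 1]")
  if (cfg$n_trees_per_provenance < 1 || cfg$n_dates_per_site < 1)
    stop("invalid config: tree and date counts must be positive")
  if (cfg$missingness < 0 || cfg$missingness >= 1)
    stop("invalid config: missingness must lie in [0, 1)")
  if (cfg$dispersion <= 0 || cfg$total_log_sd <= 0)
    stop("invalid config: dispersion and total_log_sd must be positive")
  if (abs(sum(cfg$besthit_group_sizes) - 1) > 1e-8)
    stop("invalid config: best-hit group size probabilities must sum to 1")
  structure(cfg, class = "plast_config")
}

# sampling dates: the two sites' 2010 campaigns when 4 dates are requested,
# otherwise evenly spaced dates offset between sites
.site_dates <- function(n) {
  if (n == 4) {
    list(schluchsee = as.Date(c("2010-05-27", "2010-06-30",
                                "2010-07-28", "2010-09-15")),
         wiesloch = as.Date(c("2010-05-12", "2010-06-16",
                              "2010-07-14", "2010-09-08")))
  } else {
    base <- as.Date("2010-05-12") + round(seq(0, 126, length.out = n))
    list(schluchsee = base + 15, wiesloch = base)
  }
}

#' Generate the sampling design of a synthetic study
#'
#' One potential library per (tree, site-specific date) combination; each
#' tree belongs to one provenance and one site, with each provenance split
#' evenly across the two sites.  A missingness fraction drops cells
#' uniformly at random (the field study lost libraries to RNA quality).
#'
#' @param config a [sim_config()] object.
#' @return A sample table: `library_id`, `TREE`, `PROVENANCE`, `SITE`,
#'   `DATE` (site-specific level), `date` (Date).
#' @export
simulate_design <- function(config) {
  stopifnot(inherits(config, "plast_config"))
  set.seed(config$seed + 1L)
  provs <- c("AR", "LA")          # Salmon Arm (interior), Cameron Lake (coast)
  sites <- c("schluchsee", "wiesloch")
  dates <- .site_dates(config$n_dates_per_site)
  trees <- list()
  for (pv in provs) {
    nt <- config$n_trees_per_provenance
    site_of <- rep(sites, c(ceiling(nt / 2), floor(nt / 2)))
    trees[[pv]] <- data.frame(
      TREE = sprintf("%s_%s_T%02d", pv, substr(site_of, 1, 1), seq_len(nt)),
      PROVENANCE = pv, SITE = site_of, stringsAsFactors = FALSE)
  }
  trees <- do.call(rbind, trees)
  rows <- lapply(seq_len(nrow(trees)), function(i) {
    dd <- dates[[trees$SITE[i]]]
    data.frame(TREE = trees$TREE[i], PROVENANCE = trees$PROVENANCE[i],
               SITE = trees$SITE[i],
               DATE = paste0(toupper(substr(trees$SITE[i], 1, 1)), "_", dd),
               date = dd, stringsAsFactors = FALSE)
  })
  design <- do.call(rbind, rows)
  if (config$missingness > 0) {
    n_keep <- max(1L, round(nrow(design) * (1 - config$missingness)))
    design <- design[sort(sample.int(nrow(design), n_keep)), , drop = FALSE]
  }
  design <- data.frame(
    library_id = paste0(design$TREE, "_", format(design$date, "%Y%m%d")),
    design, stringsAsFactors = FALSE)
  rownames(design) <- NULL
  design
}

#' Generate daily environment series for both sites
#'
#' Daily mean temperature is a seasonal sinusoid (peak around day 200) plus
#' Gaussian noise; midday (10:00-14:00 mean) temperature is the same
#' sinusoid with its own, larger, synoptic noise (default SD 4 degrees C:
#' midday temperature varies far more day-to-day than the daily mean, which
#' keeps the detrended TEMPERATURE regressor dominated by weather rather
#' than by the residual seasonal trend, as in field data where the three
#' regressors are mutually uncorrelated).  Day length comes from the standard
#' solar-declination formula at the site latitude, so it is maximal on the
#' June solstice.  Total available soil water (TAW) is a mean-reverting
#' AR(1) series clamped to `taw_bounds`; in the collinear mode the site
#' means are pushed apart and the noise shrunk so SITE tracks TAW.
#'
#' @param config a [sim_config()] object.
#' @param site_params optional list per site with elements `latitude`,
#'   `temp_mean`, `temp_amplitude`, `temp_noise_sd`, `taw_mean`, `taw_sd`,
#'   `taw_autocorr`.
#' @param date_range range of daily dates; must cover every sampling date
#'   plus at least 28 days before the first.
#' @param taw_bounds lower/upper clamp for TAW.
#' @return Long data.frame: `site`, `date`, `daily_mean_temp`,
#'   `midday_temp`, `day_length`, `taw`.
#' @export
simulate_environment <- function(config, site_params = NULL,
                                 date_range = as.Date(c("2010-04-01",
                                                        "2010-10-31")),
                                 taw_bounds = c(0, 100)) {
  stopifnot(inherits(config, "plast_config"))
  set.seed(config$seed + 2L)
  sampling <- do.call(c, .site_dates(config$n_dates_per_site))
  if (as.Date(date_range[1]) > min(sampling) - 28 ||
      as.Date(date_range[2]) < max(sampling))
    stop("invalid range: environment series must cover all sampling dates ",
         "plus at least 28 days before the first")
  if (is.null(site_params)) {
    site_params <- list(
      schluchsee = list(latitude = 47.84, temp_mean = 6.1,
                        temp_amplitude = 9, temp_noise_sd = 4,
                        taw_mean = 80, taw_sd = 4, taw_autocorr = 0.95),
      wiesloch = list(latitude = 49.5, temp_mean = 9.9,
                      temp_amplitude = 10, temp_noise_sd = 4,
                      taw_mean = 40, taw_sd = 4, taw_autocorr = 0.95))
    if (config$collinear_site_taw) {
      site_params$schluchsee$taw_mean <- 90
      site_params$schluchsee$taw_sd <- 1.5
      site_params$wiesloch$taw_mean <- 20
      site_params$wiesloch$taw_sd <- 1.5
    }
  }
  days <- seq(as.Date(date_range[1]), as.Date(date_range[2]), by = "day")
  doy <- as.integer(format(days, "%j"))
  out <- lapply(names(site_params), function(s) {
    pp <- site_params[[s]]
    seasonal <- pp$temp_mean +
      pp$temp_amplitude * cos(2 * pi * (doy - 200) / 365.25)
    decl <- (23.44 * pi / 180) * sin(2 * pi * (doy - 81) / 365.25)
    cosH <- pmin(pmax(-tan(pp$latitude * pi / 180) * tan(decl), -1), 1)
    day_length <- (24 / pi) * acos(cosH)
    taw <- numeric(length(days))
    taw[1] <- pp$taw_mean
    innov <- stats::rnorm(length(days), 0, pp$taw_sd)
    for (t in seq_along(days)[-1])
      taw[t] <- pp$taw_mean +
        pp$taw_autocorr * (taw[t - 1] - pp$taw_mean) + innov[t]
    taw <- pmin(pmax(taw, taw_bounds[1]), taw_bounds[2])
    data.frame(site = s, date = days,
               daily_mean_temp = seasonal +
                 stats::rnorm(length(days), 0, pp$temp_noise_sd),
               midday_temp = seasonal +
                 stats::rnorm(length(days), 0, pp$temp_noise_sd),
               day_length = day_length, taw = taw,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Generate counts and ground truth for a synthetic study
#'
#' For transcript i and library j the log2 mean is
#' `baseline_i + u_tree + u_date + u_provenance + u_site +
#' sum_r slope_ir * z_rj`, with random intercepts drawn per transcript with
#' variances given by the configured fractions of `total_log_sd^2` and
#' slopes applied to the standardized regressors.  Counts are
#' negative-binomial with library-size offsets (log-uniform totals).  All
#' ground truth (slopes, responder sets, per-factor realized variances) is
#' recorded.
#'
#' @param design sample table from [simulate_design()].
#' @param environment environment series from [simulate_environment()].
#' @param config a [sim_config()] object.
#' @return A list of class `plast_study`: `counts`, `library_totals`,
#'   `samples`, `environment`, `regressors`, `truth` (list with `slopes`
#'   matrix, per-regressor responder data.frames with direction, theoretical
#'   `sigma2`, realized per-factor variances), and `config`.
#' @export
simulate_counts <- function(design, environment, config) {
  stopifnot(inherits(config, "plast_config"))
  set.seed(config$seed + 3L)
  reg <- assemble_regressors(design, environment)
  if (isTRUE(config$decorrelate_regressors)) {
    cols <- c("TAW", "TEMPERATURE", "DAYLENGTH")
    for (k in 2:3) {
      prev <- as.matrix(reg[cols[seq_len(k - 1)]])
      x <- reg[[cols[k]]]
      r <- stats::lm.fit(cbind(1, prev), x)$residuals
      reg[[cols[k]]] <- mean(x) + r * stats::sd(x) / stats::sd(r)
    }
  }
  n <- nrow(design)
  ntx <- config$n_transcripts
  tx <- sprintf("PUT%05d", seq_len(ntx))
  zscore <- function(x) (x - mean(x)) / stats::sd(x)
  Z <- rbind(TAW = zscore(reg$TAW), TEMPERATURE = zscore(reg$TEMPERATURE),
             DAYLENGTH = zscore(reg$DAYLENGTH))
  # disjoint responder sets with random slope signs
  regs <- c("TAW", "TEMPERATURE", "DAYLENGTH")
  slopes <- matrix(0, ntx, 3, dimnames = list(tx, regs))
  pool <- seq_len(ntx)
  responders <- list()
  for (r in regs) {
    k <- round(config$responder_fractions[[r]] * ntx)
    pick <- if (k > 0) sort(sample(pool, k)) else integer(0)
    pool <- setdiff(pool, pick)
    sgn <- sample(c(-1, 1), length(pick), replace = TRUE)
    slopes[pick, r] <- config$slope_magnitude * sgn
    responders[[r]] <- data.frame(
      transcript_id = tx[pick], slope = slopes[pick, r],
      direction = ifelse(sgn > 0, "up", "down"), stringsAsFactors = FALSE)
  }
  vf <- config$variance_fractions
  v_tot <- config$total_log_sd^2
  fac <- list(tree = factor(design$TREE), date = factor(design$DATE),
              provenance = factor(design$PROVENANCE),
              site = factor(design$SITE))
  eta <- matrix(stats::rnorm(ntx, config$mean_log_expression, 1.5),
                ntx, n) # baseline, recycled across libraries
  realized <- list()
  u_store <- list()
  for (f in names(fac)) {
    nl <- nlevels(fac[[f]])
    U <- matrix(stats::rnorm(ntx * nl, 0, sqrt(vf[[f]] * v_tot)), ntx, nl)
    eta <- eta + U[, as.integer(fac[[f]]), drop = FALSE]
    realized[[f]] <- if (nl > 1) apply(U, 1, stats::var) else rep(0, ntx)
    u_store[[f]] <- U
  }
  eta <- eta + slopes %*% Z
  # the negative-binomial draw itself adds ~ (log2 e)^2 * dispersion of
  # log2-scale variance; charge it against the residual budget so the
  # configured fractions describe the observed log scale
  v_nb <- log2(exp(1))^2 * config$dispersion
  v_gauss <- max(vf[["residual"]] * v_tot - v_nb, 0)
  eta <- eta + matrix(stats::rnorm(ntx * n, 0, sqrt(v_gauss)), ntx, n)
  totals <- exp(stats::runif(n, log(config$library_size_range[1]),
                             log(config$library_size_range[2])))
  mu <- 2^eta %*% diag(totals / 1e6)
  counts <- matrix(stats::rnbinom(ntx * n, mu = as.vector(mu),
                                  size = 1 / config$dispersion),
                   ntx, n, dimnames = list(tx, design$library_id))
  storage.mode(counts) <- "integer"
  structure(list(
    counts = counts,
    library_totals = setNames(round(totals), design$library_id),
    samples = design,
    environment = environment,
    regressors = reg,
    truth = list(slopes = slopes, responders = responders,
                 sigma2 = setNames(vf * v_tot, names(vf)),
                 realized_variance = realized),
    config = config
  ), class = "plast_study")
}

#' Generate GO annotation, a toy ontology and best-hit groups
#'
#' Builds a small is_a DAG (root, two intermediate levels, leaf categories)
#' in OBO-compatible form, assigns transcripts to leaf categories, seeds a
#' configurable number of categories with responder transcripts of one
#' (regressor, direction) pair at the configured odds, and partitions
#' transcripts into best-hit groups whose members share responder status
#' (redundant fragments of one gene respond alike).
#'
#' @param study a `plast_study` from [simulate_counts()].
#' @param config a [sim_config()] object.
#' @return The study with an added `go` element: `ontology`
#'   (`plast_ontology`), `annotation` (named list transcript -> direct
#'   terms), `besthit` (named vector transcript -> group id), and
#'   `enriched_truth` (data.frame of planted (term, regressor, direction)).
#' @export
simulate_annotation <- function(study, config) {
  stopifnot(inherits(study, "plast_study"), inherits(config, "plast_config"))
  set.seed(config$seed + 4L)
  tx <- rownames(study$counts)
  nleaf <- config$go_n_categories
  ids <- sprintf("GO:%07d", seq_len(1 + 3 + 6 + nleaf))
  root <- ids[1]; lvl1 <- ids[2:4]; lvl2 <- ids[5:10]
  leaves <- ids[-(1:10)]
  parents <- list()
  parents[[root]] <- character(0)
  for (t in lvl1) parents[[t]] <- root
  for (i in seq_along(lvl2))
    parents[[lvl2[i]]] <- unique(c(lvl1[(i - 1) %% 3 + 1],
                                   if (i %% 2 == 0) lvl1[i %% 3 + 1]))
  for (i in seq_along(leaves))
    parents[[leaves[i]]] <- unique(sample(lvl2, sample(1:2, 1)))
  ontology <- structure(list(
    terms = data.frame(
      id = ids,
      name = c("biological_process", paste0("branch_", seq_along(lvl1)),
               paste0("process_", seq_along(lvl2)),
               paste0("leaf_category_", seq_along(leaves))),
      namespace = "biological_process", stringsAsFactors = FALSE),
    parents = parents), class = "plast_ontology")

  # responder labels per transcript: first matching (regressor, direction)
  label <- setNames(rep("none", length(tx)), tx)
  for (r in names(study$truth$responders)) {
    rr <- study$truth$responders[[r]]
    label[rr$transcript_id] <- paste0(r, "_", rr$direction)
  }
  # planted enrichment: pick leaves and (regressor, direction) pairs;
  # odds of 1 means no category is truly enriched
  n_enr <- if (config$go_enrichment_odds == 1) 0L
           else min(config$go_n_enriched, nleaf)
  enr_leaves <- sample(leaves, n_enr)
  dirs <- expand.grid(regressor = names(study$truth$responders),
                      direction = c("up", "down"),
                      stringsAsFactors = FALSE)
  dirs <- dirs[sample(nrow(dirs), n_enr, replace = n_enr > nrow(dirs)), ,
               drop = FALSE]
  membership <- list()
  for (i in seq_along(leaves)) {
    size <- sample(config$go_category_size_range[1]:
                     config$go_category_size_range[2], 1)
    size <- min(size, length(tx))
    j <- match(leaves[i], enr_leaves)
    w <- rep(1, length(tx))
    if (!is.na(j) && config$go_enrichment_odds != 1) {
      target <- paste0(dirs$regressor[j], "_", dirs$direction[j])
      w[label == target] <- config$go_enrichment_odds
    }
    membership[[leaves[i]]] <- sample(tx, size, prob = w)
  }
  annotation <- split(
    rep(names(membership), lengths(membership)), unlist(membership))
  enriched_truth <- if (n_enr > 0)
    data.frame(term = enr_leaves, regressor = dirs$regressor,
               direction = dirs$direction, stringsAsFactors = FALSE)
  else data.frame(term = character(0), regressor = character(0),
                  direction = character(0))

  # best-hit groups: partition within responder classes so group members
  # share responder status
  sizes <- as.integer(names(config$besthit_group_sizes))
  besthit <- character(0)
  gid <- 0L
  for (cl in unique(label)) {
    members <- sample(names(label)[label == cl])
    while (length(members) > 0) {
      k <- min(sample(sizes, 1, prob = config$besthit_group_sizes),
               length(members))
      gid <- gid + 1L
      besthit[members[seq_len(k)]] <- sprintf("BH%05d", gid)
      members <- members[-seq_len(k)]
    }
  }
  study$go <- list(ontology = ontology, annotation = annotation,
                   besthit = besthit[tx],
                   enriched_truth = enriched_truth)
  names(study$go$besthit) <- tx
  study
}

#' Generate a complete synthetic study
#'
#' Runs design, environment, counts and annotation generation; identical
#' seed and config give byte-identical output.
#'
#' @param config a [sim_config()] object.
#' @return A `plast_study` with counts, samples, environment, regressors,
#'   GO fixtures and full ground truth.
#' @export
simulate_study <- function(config = sim_config()) {
  design <- simulate_design(config)
  env <- simulate_environment(config)
  study <- simulate_counts(design, env, config)
  simulate_annotation(study, config)
}
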