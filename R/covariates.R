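#' Detrended sampling-day temperature
#'
#' The TEMPERATURE regressor is the sampling-day midday (10:00-14:00 mean)
#' air temperature minus the trailing four-week running average of daily
#' mean temperature.  The 28-day window ends at and includes the sampling
#' day: future weather cannot influence sampled tissue, so the window is
#' trailing.  Centering removes the seasonal trend that would otherwise
#' confound temperature with photoperiod.
#'
#' @param env environment series for one site: data.frame with columns
#'   `date` (Date), `daily_mean_temp`, `midday_temp`.
#' @param sampling_date Date of sampling.
#' @param window trailing window length in days (default 28).
#' @return Temperature deviation in degrees C.
#' @export
detrend_temperature <- function(env, sampling_date, window = 28) {
  sampling_date <- as.Date(sampling_date)
  days <- seq(sampling_date - (window - 1), sampling_date, by = "day")
  i <- match(days, as.Date(env$date))
  if (anyNA(i))
    stop("insufficient data: the ", window, "-day window ending ",
         sampling_date, " is not fully covered by the environment series")
  midday <- env$midday_temp[match(sampling_date, as.Date(env$date))]
  midday - mean(env$daily_mean_temp[i])
}

#' Signed photoperiod deviation from the solstice
#'
#' The DAYLENGTH regressor is the deviation of the day length from the
#' solstice day length, signed by season: positive before (and on) June 21,
#' negative after, so the regressor is zero at the solstice and its sign
#' tracks lengthening versus shortening days.
#'
#' @param day_length_hours day length on the sampling day (hours).
#' @param sampling_date Date of sampling.
#' @param solstice_date Date of the summer solstice (default June 21 of the
#'   sampling year).
#' @param solstice_length day length at the solstice (hours); must be at
#'   least `day_length_hours`.
#' @return Signed deviation in hours.
#' @export
daylength_regressor <- function(day_length_hours, sampling_date,
                                solstice_date = NULL, solstice_length) {
  sampling_date <- as.Date(sampling_date)
  if (is.null(solstice_date))
    solstice_date <- as.Date(paste0(format(sampling_date, "%Y"), "-06-21"))
  if (day_length_hours > solstice_length + 1e-8)
    stop("day length exceeds the solstice day length")
  magnitude <- max(solstice_length - day_length_hours, 0)
  if (sampling_date <= as.Date(solstice_date)) magnitude else -magnitude
}

#' Assemble the per-library regressor table
#'
#' Joins each library to its site's environment series on the sampling date
#' and derives TAW (sampling-day value), TEMPERATURE (detrended midday
#' temperature), DAYLENGTH (signed solstice deviation), dummy-coded
#' PROVENANCE and SITE (reference level = alphabetically first), and the
#' site-specific DATE factor level.  SITE is computed so it can be
#' VIF-checked, but the environmental model family excludes it.
#'
#' @param samples sample table with columns `library_id`, `TREE`,
#'   `PROVENANCE`, `SITE`, `DATE`, `date` (Date of sampling).
#' @param env environment series for all sites: data.frame with columns
#'   `site`, `date`, `daily_mean_temp`, `midday_temp`, `day_length`, `taw`.
#' @param window trailing window for temperature detrending (days).
#' @return A data.frame with one row per library: `library_id`, `TAW`,
#'   `TEMPERATURE`, `DAYLENGTH`, `PROVENANCE` (0/1), `SITE` (0/1), `DATE`.
#' @export
assemble_regressors <- function(samples, env, window = 28) {
  env$date <- as.Date(env$date)
  samples$date <- as.Date(samples$date)
  prov_ref <- sort(unique(as.character(samples$PROVENANCE)))[1]
  site_ref <- sort(unique(as.character(samples$SITE)))[1]
  out <- vector("list", nrow(samples))
  for (j in seq_len(nrow(samples))) {
    se <- env[env$site == as.character(samples$SITE[j]), , drop = FALSE]
    i <- match(samples$date[j], se$date)
    if (is.na(i))
      stop("library '", samples$library_id[j], "': sampling date ",
           samples$date[j], " absent from the environment series of site ",
           samples$SITE[j])
    year <- format(samples$date[j], "%Y")
    solstice <- as.Date(paste0(year, "-06-21"))
    i_sol <- match(solstice, se$date)
    sol_len <- if (!is.na(i_sol)) se$day_length[i_sol] else max(se$day_length)
    out[[j]] <- data.frame(
      library_id = samples$library_id[j],
      TAW = se$taw[i],
      TEMPERATURE = detrend_temperature(se, samples$date[j], window),
      DAYLENGTH = daylength_regressor(se$day_length[i], samples$date[j],
                                      solstice, sol_len),
      PROVENANCE = as.numeric(as.character(samples$PROVENANCE[j]) != prov_ref),
      SITE = as.numeric(as.character(samples$SITE[j]) != site_ref),
      DATE = as.character(samples$DATE[j]),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R2_k)` where `R2_k` is from the ordinary least-squares
#' regression of column `k` on the remaining columns.  Columns with
#' `VIF > 10` indicate multicollinearity (the rule that excluded SITE from
#' the environmental models when it tracked TAW).
#'
#' @param X numeric matrix or data.frame of regressor columns (at least 2,
#'   none constant).
#' @return Named vector of VIFs (`Inf` for perfectly collinear columns).
#' @export
variance_inflation <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 columns")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(apply(X, 2, stats::sd) == 0))
    stop("VIF undefined for constant columns: ",
         paste(colnames(X)[apply(X, 2, stats::sd) == 0], collapse = ", "))
  vapply(seq_len(ncol(X)), function(k) {
    fit <- stats::lm.fit(cbind(1, X[, -k, drop = FALSE]), X[, k])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, k] - mean(X[, k]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> setNames(colnames(X))
}
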