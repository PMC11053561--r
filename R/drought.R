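# Microcosm drought analysis: RWC trajectories by planting density,
# water-loss rates, time spent below a low-water threshold, and
# post-rewetting recovery of weight and Fv/Fm.

#' Cosm drought time series
#'
#' One microcosm's observation record: cosm weight (and optionally the
#' chlorophyll-fluorescence ratio Fv/Fm) by day, with the planting
#' density and the drought/rewetting windows.
#'
#' @param cosm_id,species Identifiers.
#' @param n_plants Number of plants in the cosm.
#' @param areal_density Plants per cm^2 (see [areal_density()]).
#' @param group `"control"` (standing water throughout) or `"drought"`.
#' @param observations Data frame with strictly increasing `day`,
#'   `weight_g`, and optionally `fvfm` in `[0, 1]`.
#' @param dry_weight Total oven-dry plant weight (g, > 0), measured at
#'   the end of the experiment.
#' @param drought_window,rewet_window Length-2 numeric `(start_day,
#'   end_day)`.
#' @return An object of class `cosm_series`.
#' @export
cosm_series <- function(cosm_id, species, n_plants, areal_density = NA_real_,
                        group = c("drought", "control"), observations,
                        dry_weight, drought_window, rewet_window) {
  group <- match.arg(group)
  stopifnot(is.data.frame(observations),
            all(c("day", "weight_g") %in% names(observations)))
  if (is.unsorted(observations$day, strictly = TRUE))
    stop("observation days must be strictly increasing")
  if (dry_weight <= 0) stop("`dry_weight` must be > 0 (g)")
  if ("fvfm" %in% names(observations)) {
    fv <- observations$fvfm
    if (any(!is.na(fv) & (fv < 0 | fv > 1)))
      stop("fvfm values must lie in [0, 1]")
  }
  structure(
    list(cosm_id = as.character(cosm_id), species = as.character(species),
         n_plants = as.integer(n_plants), areal_density = areal_density,
         group = group, observations = observations, dry_weight = dry_weight,
         drought_window = as.numeric(drought_window),
         rewet_window = as.numeric(rewet_window)),
    class = "cosm_series"
  )
}

#' Areal planting density
#'
#' @param n_plants Plant count (>= 0).
#' @param area_cm2 Cross-sectional area available to the plants (cm^2,
#'   > 0); 20 cm^2 for the standard vertical microcosm, so 10-40 plants
#'   give 0.5-2.0 plants per cm^2.
#' @return Density in plants per cm^2.
#' @export
areal_density <- function(n_plants, area_cm2 = 20) {
  if (any(area_cm2 <= 0)) stop("`area_cm2` must be > 0")
  if (any(n_plants < 0)) stop("`n_plants` must be >= 0")
  n_plants / area_cm2
}

#' RWC trajectory of a cosm
#'
#' Converts the weight record to relative water content per observation:
#' `RWC = (weight - tare - dry) / dry * 100`, using the end-of-experiment
#' dry weight. Reported both per cosm and per plant (the per-plant column
#' divides the water mass by `n_plants` before normalising by the
#' per-plant dry weight; with equal plants the two are identical, they
#' are kept separate and labelled to avoid ambiguity).
#'
#' @param series A [cosm_series()].
#' @param tare_g Container tare weight (g); required, there is no
#'   default.
#' @return An object of class `drought_summary` holding the trajectory
#'   (`rwc` data frame with `day`, `rwc`, `rwc_per_plant`, and `fvfm`
#'   when present) plus the series metadata; rate/threshold/recovery
#'   fields are filled by [loss_rate()], [time_below()] and [recovery()].
#' @export
rwc_trajectory <- function(series, tare_g) {
  stopifnot(inherits(series, "cosm_series"))
  if (missing(tare_g) || is.null(tare_g) || is.na(tare_g))
    stop("`tare_g` (container tare weight) is required")
  wet <- series$observations$weight_g - tare_g
  if (any(wet < 0))
    stop("tare exceeds recorded cosm weight; check `tare_g`")
  rwc <- relative_water_content(wet, series$dry_weight)
  traj <- data.frame(day = series$observations$day, rwc = rwc,
                     rwc_per_plant = rwc)  # equal plants: same value, labelled
  if ("fvfm" %in% names(series$observations))
    traj$fvfm <- series$observations$fvfm
  structure(
    list(cosm_id = series$cosm_id, species = series$species,
         n_plants = series$n_plants, areal_density = series$areal_density,
         group = series$group, rwc = traj,
         drought_window = series$drought_window,
         rewet_window = series$rewet_window,
         loss_rate = NULL, time_below = NULL, threshold = NULL,
         recovery_ratio_weight = NULL, recovery_ratio_fvfm = NULL),
    class = "drought_summary"
  )
}

#' @export
print.drought_summary <- function(x, ...) {
  cat(sprintf("<drought_summary> %s (%s, %d plants, %s)\n",
              x$cosm_id, x$species, x$n_plants, x$group))
  cat(sprintf("  %d observations, RWC %.4g .. %.4g %%\n",
              nrow(x$rwc), min(x$rwc$rwc), max(x$rwc$rwc)))
  if (!is.null(x$loss_rate))
    cat(sprintf("  loss rate %.4g %%/day\n", x$loss_rate))
  invisible(x)
}

#' Water-loss rate within a window
#'
#' The default statistic is the slope of the least-squares line of RWC on
#' day within the drought window (water content falls steadily over
#' time, so a linear rate summarises it well); an exponential-decay fit
#' is available behind `method = "exponential"`, returning the fitted
#' rate constant.
#'
#' @param x A `drought_summary` (from [rwc_trajectory()]) or a data frame
#'   with `day` and `rwc`.
#' @param window Length-2 `(start_day, end_day)`; defaults to the
#'   summary's drought window.
#' @param method `"linear"` (slope, % per day) or `"exponential"`
#'   (decay constant per day of an exponential-to-floor fit).
#' @return For a `drought_summary` input, the summary with `loss_rate`,
#'   `loss_rate_se` and `loss_rate_fit` filled; for a data-frame input, a
#'   list with `rate`, `se`, `method` and the fit object.
#' @export
loss_rate <- function(x, window = NULL, method = c("linear", "exponential")) {
  method <- match.arg(method)
  is_summary <- inherits(x, "drought_summary")
  traj <- if (is_summary) x$rwc else x
  stopifnot(is.data.frame(traj), all(c("day", "rwc") %in% names(traj)))
  window <- window %||% (if (is_summary) x$drought_window else
    range(traj$day))
  sel <- traj$day >= window[1] & traj$day <= window[2]
  d <- traj[sel, , drop = FALSE]
  if (nrow(d) < 3L) stop("need >= 3 observations in the window to fit a rate")
  if (method == "linear") {
    fit <- lm(rwc ~ day, data = d)
    rate <- unname(coef(fit)[2])
    # suppressWarnings: noise-free simulated lines fit perfectly and lm's
    # summary warns about the zero residual variance
    se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  } else {
    r0 <- max(d$rwc); fl <- min(d$rwc)
    k0 <- 1 / max(diff(range(d$day)), 1)
    # warnOnly + suppressWarnings: an exact (zero-residual) decay, as
    # produced by the noise-free simulator, trips nls convergence checks
    # even though the estimates are exact
    fit <- suppressWarnings(
      nls(rwc ~ fl_ + (r0_ - fl_) * exp(-k * (day - min(d$day))),
          data = d,
          start = list(fl_ = fl, r0_ = r0, k = k0),
          control = list(maxiter = 500, warnOnly = TRUE)))
    rate <- unname(coef(fit)[["k"]])
    se <- tryCatch(summary(fit)$coefficients["k", 2], error = function(e) NA_real_)
  }
  if (is_summary) {
    x$loss_rate <- rate; x$loss_rate_se <- se
    x$loss_rate_method <- method; x$loss_rate_fit <- fit
    x
  } else {
    list(rate = rate, se = se, method = method, fit = fit)
  }
}

#' Time spent below a low-water threshold
#'
#' Total time (days) with RWC strictly below `threshold`, integrating the
#' trajectory with linear interpolation between observations to locate
#' crossing times. Monotone non-increasing in the threshold by
#' construction.
#'
#' @param x A `drought_summary` or a data frame with `day` and `rwc`.
#' @param threshold Low-water threshold in % RWC (default 100).
#' @param window Optional `(start, end)` restriction (days).
#' @return For a `drought_summary` input, the summary with `time_below`
#'   and `threshold` filled; otherwise the time in days.
#' @export
time_below <- function(x, threshold = 100, window = NULL) {
  is_summary <- inherits(x, "drought_summary")
  traj <- if (is_summary) x$rwc else x
  stopifnot(is.data.frame(traj), all(c("day", "rwc") %in% names(traj)))
  if (!nrow(traj)) stop("empty trajectory")
  if (!is.null(window)) {
    sel <- traj$day >= window[1] & traj$day <= window[2]
    traj <- traj[sel, , drop = FALSE]
    if (!nrow(traj)) stop("no observations in the window")
  }
  t <- traj$day; r <- traj$rwc
  total <- 0
  for (i in seq_len(length(t) - 1)) {
    dt <- t[i + 1] - t[i]
    r0 <- r[i]; r1 <- r[i + 1]
    b0 <- r0 < threshold; b1 <- r1 < threshold
    if (b0 && b1) {
      total <- total + dt
    } else if (b0 != b1) {
      frac <- (threshold - r0) / (r1 - r0)  # crossing position in [0, 1]
      total <- total + dt * (if (b0) frac else 1 - frac)
    }
  }
  if (is_summary) {
    x$time_below <- total; x$threshold <- threshold
    x
  } else total
}

#' Post-rewetting recovery ratios
#'
#' The pre-drought baseline is the mean of all observations before the
#' drought window opens; the recovery ratio is the last observation in
#' the rewetting window divided by that baseline, for RWC and (when
#' present) Fv/Fm. A ratio of 1 means full return to the pre-drought
#' condition.
#'
#' @param x A `drought_summary` (from [rwc_trajectory()]).
#' @return The summary with `recovery_ratio_weight` and (when Fv/Fm is
#'   present) `recovery_ratio_fvfm` filled.
#' @export
recovery <- function(x) {
  stopifnot(inherits(x, "drought_summary"))
  traj <- x$rwc
  pre <- traj[traj$day < x$drought_window[1], , drop = FALSE]
  if (!nrow(pre)) stop("no pre-drought baseline observations")
  rw <- traj[traj$day > x$rewet_window[1] & traj$day <= x$rewet_window[2], ,
             drop = FALSE]
  if (!nrow(rw)) stop("rewetting window contains no observations")
  final <- rw[nrow(rw), , drop = FALSE]
  x$recovery_ratio_weight <- final$rwc / mean(pre$rwc)
  if ("fvfm" %in% names(traj) && !all(is.na(traj$fvfm))) {
    x$recovery_ratio_fvfm <- final$fvfm / mean(pre$fvfm)
  }
  x
}

#' Density effect on drought dynamics
#'
#' Orders the cosms of each species by planting density and tests whether
#' drought resilience improves with density: a Jonckheere-style
#' permutation trend test for a decreasing magnitude of the water-loss
#' rate across ordered densities (and, when available, decreasing time
#' below the low-water threshold), plus the two-sample normality-gated
#' comparison between the lowest and highest density where group sizes
#' allow.
#'
#' @param summaries List of `drought_summary` objects with `loss_rate`
#'   filled (see [loss_rate()]); each species needs at least two density
#'   levels.
#' @param n_perm Permutations for the trend test (default 999).
#' @param seed Optional integer seed for the permutation draws.
#' @return A list keyed by species, each with `by_density` (data frame of
#'   loss rates and time-below by density), `trend_loss_rate`,
#'   `trend_time_below` (when available), and `extremes_comparison`
#'   (lowest vs highest density, or `NULL` if groups are too small).
#' @export
density_effect <- function(summaries, n_perm = 999, seed = NULL) {
  stopifnot(length(summaries) > 0,
            all(vapply(summaries, inherits, logical(1), "drought_summary")))
  if (any(vapply(summaries, function(s) is.null(s$loss_rate), logical(1))))
    stop("run loss_rate() on every summary first")
  species <- vapply(summaries, `[[`, character(1), "species")
  out <- list()
  for (sp in unique(species)) {
    ss <- summaries[species == sp]
    dens <- vapply(ss, `[[`, integer(1), "n_plants")
    if (length(unique(dens)) < 2L)
      stop(sprintf("species %s has a single density level; need >= 2", sp))
    rate <- vapply(ss, `[[`, numeric(1), "loss_rate")
    tb <- vapply(ss, function(s) s$time_below %||% NA_real_, numeric(1))
    by_density <- data.frame(
      n_plants = dens, areal_density = vapply(ss, `[[`, numeric(1), "areal_density"),
      loss_rate = rate, abs_loss_rate = abs(rate), time_below = tb)
    by_density <- by_density[order(by_density$n_plants), ]
    trend_rate <- jonckheere_test(abs(rate), dens, alternative = "decreasing",
                                  n_perm = n_perm,
                                  seed = substream_seed(seed, paste0(sp, "rate")))
    trend_tb <- if (!all(is.na(tb)))
      jonckheere_test(tb, dens, alternative = "decreasing", n_perm = n_perm,
                      seed = substream_seed(seed, paste0(sp, "tb")))
    lo <- min(dens); hi <- max(dens)
    a <- abs(rate)[dens == lo]; b <- abs(rate)[dens == hi]
    extremes <- if (length(a) >= 3L && length(b) >= 3L)
      tryCatch(compare_groups(a, b), error = function(e) NULL)
    out[[sp]] <- list(by_density = by_density,
                      trend_loss_rate = trend_rate,
                      trend_time_below = trend_tb,
                      extremes_comparison = extremes)
  }
  out
}
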