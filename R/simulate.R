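# Simulated tabular records: centrifugation ledgers built from labelled
# water pools, and microcosm drought time series with a density-dependent
# drying rate.

#' Labelled water pools for a simulated plant
#'
#' A plant's stored water is split into four compartments reflecting where
#' Sphagnum holds water: capillary water on and between the branches
#' (`branch_capillary`), water in the spaces between neighbouring stems
#' (`interstem`), water inside the dead hyaline storage cells (`hyaline`),
#' and intracellular water (`intracellular`). Each pool drains completely
#' once the applied relative centrifugal force reaches its threshold;
#' loosely held water drains first, so thresholds must be ordered
#' `branch_capillary <= interstem <= hyaline <= intracellular`. The hyaline
#' and intracellular thresholds default far above a gentle-centrifugation
#' schedule, since that water is held by surface tension and capillarity
#' and is not recovered by mild spinning.
#'
#' @param branch_capillary,interstem,hyaline,intracellular Pool masses in
#'   grams.
#' @param thresholds Named numeric vector of release thresholds
#'   (g-units of relative centrifugal force) for the four pools.
#' @param noise_sd Standard deviation (g) of measurement noise added to
#'   each released-water weight (truncated so masses stay non-negative).
#' @return An object of class `water_pools`.
#' @export
water_pools <- function(branch_capillary = 0.9, interstem = 0.5,
                        hyaline = 0.35, intracellular = 0.15,
                        thresholds = c(branch_capillary = 15, interstem = 60,
                                       hyaline = 600, intracellular = 5000),
                        noise_sd = 0) {
  masses <- c(branch_capillary = branch_capillary, interstem = interstem,
              hyaline = hyaline, intracellular = intracellular)
  if (any(masses < 0)) stop("pool masses must be >= 0 (g)")
  need <- c("branch_capillary", "interstem", "hyaline", "intracellular")
  if (!all(need %in% names(thresholds)))
    stop("`thresholds` must name all four pools")
  thresholds <- thresholds[need]
  if (any(thresholds <= 0)) stop("release thresholds must be positive (g-force)")
  if (is.unsorted(thresholds))
    stop("thresholds must be ordered branch_capillary <= interstem <= hyaline <= intracellular (loosest water drains first)")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(list(masses = masses, thresholds = thresholds, noise_sd = noise_sd),
            class = "water_pools")
}

#' Simulate one centrifugation run
#'
#' Spins a simulated saturated plant through a schedule of increasing
#' centrifugal forces. At force `f`, every pool whose threshold is at or
#' below `f` and that has not yet drained releases its full mass;
#' measurement noise (zero-mean Gaussian, truncated so no released mass is
#' negative and no more water leaves than the plant holds) is then added
#' per interval. Before noise, the ledger conserves mass exactly:
#' saturated weight = dry weight + retained water + total released water.
#'
#' @param pools A [water_pools()] object.
#' @param forces Strictly increasing centrifugal forces (g-units); the
#'   default is a gentle 5-min-per-step schedule of 17, 66, 149 and 266 g.
#' @param dry_weight Oven-dry weight of the plant (g).
#' @param plant_id,species,treatment Metadata carried into the record.
#' @param seed Optional integer seed for the measurement noise.
#' @return A [centrifuge_record()].
#' @export
simulate_centrifuge_run <- function(pools, forces = c(17, 66, 149, 266),
                                    dry_weight, plant_id = "sim",
                                    species = "synthetic",
                                    treatment = "intact", seed = NULL) {
  stopifnot(inherits(pools, "water_pools"))
  if (dry_weight <= 0) stop("`dry_weight` must be > 0 (g)")
  forces <- as.numeric(forces)
  if (length(forces) < 1L || is.unsorted(forces, strictly = TRUE))
    stop("`forces` must be strictly increasing (g-units)")
  total_water <- sum(pools$masses)
  saturated <- dry_weight + total_water

  drained <- rep(FALSE, length(pools$masses))
  released <- numeric(length(forces))
  for (i in seq_along(forces)) {
    due <- pools$thresholds <= forces[i] & !drained
    released[i] <- sum(pools$masses[due])
    drained <- drained | due
  }
  if (pools$noise_sd > 0) {
    noise <- with_seed(seed, rnorm(length(forces), 0, pools$noise_sd))
    avail <- total_water
    for (i in seq_along(forces)) {
      released[i] <- min(max(0, released[i] + noise[i]), avail)
      avail <- avail - released[i]
    }
  }
  centrifuge_record(
    plant_id = plant_id, species = species, treatment = treatment,
    saturated_weight = saturated, forces = forces, released = released,
    dry_weight = dry_weight
  )
}

#' Drought simulation parameters
#'
#' Closed form of the simulated microcosm drying/rewetting trajectory.
#' During drought, relative water content (RWC, %) decays exponentially
#' towards a residual floor:
#' \deqn{RWC(t) = floor + (RWC_0 - floor)\, e^{-k(n)\,t},\qquad
#'       k(n) = \frac{base}{RWC_0 - floor}\; a^{\,n - 10}}
#' so that `loss_rate_base` is the initial loss rate in % per day at the
#' reference density of 10 plants per cosm, and each added plant
#' multiplies the rate constant by the attenuation factor `a` — denser
#' cosms dry more slowly by construction. On rewetting, RWC relaxes back
#' to its initial value with time constant `rewet_days / 5`, so recovery
#' is essentially complete within the rewetting window.
#'
#' @param initial_rwc Saturated RWC at the start (%; default 1200).
#' @param loss_rate_base Initial water loss rate at the 10-plant
#'   reference density (% per day; default 145, which keeps the drying
#'   curve quasi-linear over a three-week drought).
#' @param density_attenuation Multiplicative attenuation of the rate
#'   constant per added plant (dimensionless in (0, 1]; default 0.97).
#' @param floor_rwc Residual RWC that cannot be lost by evaporation
#'   (%; default 50 — plants hold part of their weight in water even when
#'   air-dry).
#' @param drought_days,rewet_days,baseline_days Lengths of the drought,
#'   rewetting and pre-drought baseline phases (days; defaults 21, 7, 7).
#' @param observation_interval Days between observations (default 3.5,
#'   i.e. twice weekly).
#' @param dry_weight_per_plant Oven-dry weight per plant (g; default 0.04).
#' @param tare_g Container tare weight (g; default 10).
#' @param noise_sd Weighing noise (g; default 0.02), truncated so cosm
#'   weight never falls below tare + dry weight (RWC never negative).
#' @param rng_seed Integer seed.
#' @return An object of class `drought_sim_params`.
#' @export
drought_sim_params <- function(initial_rwc = 1200, loss_rate_base = 145,
                               density_attenuation = 0.97, floor_rwc = 50,
                               drought_days = 21, rewet_days = 7,
                               baseline_days = 7, observation_interval = 3.5,
                               dry_weight_per_plant = 0.04, tare_g = 10,
                               noise_sd = 0.02, rng_seed = 1L) {
  if (loss_rate_base <= 0) stop("`loss_rate_base` must be > 0 (% per day)")
  if (density_attenuation <= 0 || density_attenuation > 1)
    stop("`density_attenuation` must be in (0, 1]")
  if (floor_rwc < 0 || floor_rwc >= initial_rwc)
    stop("`floor_rwc` must be in [0, initial_rwc)")
  if (observation_interval <= 0) stop("`observation_interval` must be > 0 (days)")
  if (dry_weight_per_plant <= 0) stop("`dry_weight_per_plant` must be > 0 (g)")
  structure(
    list(initial_rwc = initial_rwc, loss_rate_base = loss_rate_base,
         density_attenuation = density_attenuation, floor_rwc = floor_rwc,
         drought_days = drought_days, rewet_days = rewet_days,
         baseline_days = baseline_days,
         observation_interval = observation_interval,
         dry_weight_per_plant = dry_weight_per_plant, tare_g = tare_g,
         noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
    class = "drought_sim_params"
  )
}

# Noise-free closed-form RWC trajectory at observation days.
drought_rwc_closed_form <- function(params, n_plants, days) {
  t0 <- params$baseline_days
  t1 <- t0 + params$drought_days
  k <- params$loss_rate_base / (params$initial_rwc - params$floor_rwc) *
    params$density_attenuation^(n_plants - 10)
  rwc <- numeric(length(days))
  pre <- days <= t0
  rwc[pre] <- params$initial_rwc
  dr <- days > t0 & days <= t1
  rwc[dr] <- params$floor_rwc +
    (params$initial_rwc - params$floor_rwc) * exp(-k * (days[dr] - t0))
  rwc_end <- params$floor_rwc +
    (params$initial_rwc - params$floor_rwc) * exp(-k * params$drought_days)
  rw <- days > t1
  tau_r <- params$rewet_days / 5
  rwc[rw] <- params$initial_rwc -
    (params$initial_rwc - rwc_end) * exp(-(days[rw] - t1) / tau_r)
  rwc
}

#' Simulate a microcosm drought time series
#'
#' Generates one cosm's weight (and chlorophyll-fluorescence Fv/Fm)
#' trajectory through baseline, drought and rewetting phases using the
#' closed form documented in [drought_sim_params()]. With
#' `density_attenuation = 1` the trajectory is independent of `n_plants`;
#' with attenuation `< 1`, RWC at every drought time point is
#' monotonically non-decreasing in `n_plants` by construction. Control
#' cosms stand in water and hold their initial RWC throughout.
#'
#' @param params A [drought_sim_params()].
#' @param n_plants Number of plants in the cosm (>= 1).
#' @param group `"drought"` or `"control"`.
#' @param species,cosm_id Metadata carried into the series.
#' @param area_cm2 Cross-sectional area of the cosm (cm^2, default 20).
#' @param with_fvfm Also simulate an Fv/Fm trajectory (a saturating
#'   logistic link from RWC to photosystem II efficiency; heuristic, not a
#'   photosynthesis model).
#' @return A [cosm_series()].
#' @export
simulate_drought_cosm <- function(params, n_plants, group = c("drought", "control"),
                                  species = "synthetic", cosm_id = NULL,
                                  area_cm2 = 20, with_fvfm = TRUE) {
  stopifnot(inherits(params, "drought_sim_params"))
  n_plants <- as.integer(n_plants)
  if (n_plants < 1L) stop("`n_plants` must be >= 1")
  group <- match.arg(group)
  t0 <- params$baseline_days
  t1 <- t0 + params$drought_days
  t2 <- t1 + params$rewet_days
  days <- seq(0, t2, by = params$observation_interval)
  rwc <- if (group == "drought") drought_rwc_closed_form(params, n_plants, days)
         else rep(params$initial_rwc, length(days))

  id <- cosm_id %||% sprintf("%s_n%02d_%s", species, n_plants, group)
  dry_weight <- n_plants * params$dry_weight_per_plant
  weight <- params$tare_g + dry_weight * (1 + rwc / 100)
  if (params$noise_sd > 0) {
    noise <- with_seed(substream_seed(params$rng_seed, paste0("w", id)),
                       rnorm(length(days), 0, params$noise_sd))
    weight <- pmax(weight + noise, params$tare_g + dry_weight)
  }
  fvfm <- NULL
  if (with_fvfm) {
    fvfm <- 0.78 / (1 + exp(-(rwc - 150) / 60))
    if (params$noise_sd > 0) {
      fn <- with_seed(substream_seed(params$rng_seed, paste0("f", id)),
                      rnorm(length(days), 0, 0.01))
      fvfm <- pmin(1, pmax(0, fvfm + fn))
    }
  }
  cosm_series(
    cosm_id = id,
    species = species, n_plants = n_plants,
    areal_density = areal_density(n_plants, area_cm2), group = group,
    observations = if (is.null(fvfm)) data.frame(day = days, weight_g = weight)
                   else data.frame(day = days, weight_g = weight, fvfm = fvfm),
    dry_weight = dry_weight,
    drought_window = c(t0, t1), rewet_window = c(t1, t2)
  )
}
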