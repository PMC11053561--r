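#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study material.
#
# Emulates the three kinds of records the downstream analyses consume:
#   (a) centrifugation ledgers for four synthetic Sphagnum-like species
#       (intact plants plus the three branch-removal treatments),
#   (b) voxel phantoms: one branched single plant per species and one
#       colony core per species at its field stem density,
#   (c) cosm drought time series at 10/20/30/40 plants per cosm.
# Everything is seeded; outputs land under results/ (tables) and
# scratch/volumes/ (voxel stacks, which are bulky and regenerable).

suppressMessages(library(mossmetrics))

seed <- 20240409L
dir.create("results", showWarnings = FALSE)
dir.create("scratch/volumes", showWarnings = FALSE, recursive = TRUE)

# Four synthetic species spanning the observed morphology range: pool
# species are large with long dense branches and sparse colonies;
# hummock species are slender with short branches and dense colonies.
species_traits <- data.frame(
  species = c("S. robustum", "S. medium", "S. gracile", "S. tenue"),
  # water pools (g per plant at saturation)
  branch_capillary = c(1.15, 0.90, 0.75, 0.55),
  interstem = c(0.60, 0.50, 0.42, 0.30),
  hyaline = c(0.40, 0.35, 0.32, 0.28),
  intracellular = c(0.17, 0.15, 0.14, 0.12),
  dry_weight = c(0.115, 0.100, 0.095, 0.085),
  # plant geometry (um)
  branch_length_um = c(5200, 4000, 3200, 2400),
  n_spreading = c(14, 12, 10, 8),
  n_pendent = c(10, 8, 8, 6),
  # colony field density (plants per cm^2)
  field_density = c(1.2, 1.65, 1.9, 0.6)
)

## (a) centrifugation ledgers --------------------------------------------------
set.seed(seed)  # session stream drives the per-plant dry-weight jitter
treatments <- c("intact", "no_pendent", "no_spreading", "no_branches")
records <- list()
for (i in seq_len(nrow(species_traits))) {
  tr <- species_traits[i, ]
  for (treat in treatments) {
    masses <- c(tr$branch_capillary, tr$interstem, tr$hyaline, tr$intracellular)
    # dissection removes the water held by the removed branch type:
    # pendent branches carry ~40% of branch-capillary water, spreading ~60%;
    # removing both also destroys the inter-plant capillary spaces
    if (treat == "no_pendent") masses[1] <- masses[1] * 0.6
    if (treat == "no_spreading") masses[1] <- masses[1] * 0.4
    if (treat == "no_branches") { masses[1] <- 0; masses[2] <- masses[2] * 0.2 }
    for (p in 1:10) {
      # water pools scale with the plant's biomass, modulated by an
      # independent per-plant storage-capacity factor: per-gram capacity
      # varies between plants but is unrelated to dry weight, so
      # saturated RWC and dry weight stay uncorrelated
      dw_plant <- tr$dry_weight * exp(rnorm(1, 0, 0.08))
      capacity <- exp(rnorm(1, 0, 0.10))
      scale_p <- dw_plant / tr$dry_weight * capacity
      pools <- water_pools(masses[1] * scale_p, masses[2] * scale_p,
                           masses[3] * scale_p, masses[4] * scale_p,
                           noise_sd = 0.01)
      records[[length(records) + 1]] <- simulate_centrifuge_run(
        pools, dry_weight = dw_plant,
        plant_id = sprintf("%s_%s_%02d", abbreviate(tr$species, 6), treat, p),
        species = tr$species, treatment = treat,
        seed = seed + i * 1000 + match(treat, treatments) * 100 + p)
    }
  }
}
write_centrifuge_csv(records, "results/centrifuge_ledger.csv")
message(sprintf("wrote %d centrifugation records (%d plants x %d treatments x 4 species)",
                length(records), 10, length(treatments)))

## (b) voxel phantoms ----------------------------------------------------------
for (i in seq_len(nrow(species_traits))) {
  tr <- species_traits[i, ]
  plant <- generate_voxel_phantom(phantom_spec(
    "branched_plant", grid_dims = c(96, 72, 72), voxel_spacing = 180,
    stem_length_um = 15000, stem_radius_um = 420,
    n_spreading = tr$n_spreading, n_pendent = tr$n_pendent,
    branch_length_um = tr$branch_length_um, branch_radius_um = 240,
    rng_seed = seed + i), noise_sd = 8)
  write_volume(plant$grid,
               sprintf("scratch/volumes/plant_%s.nrrd", abbreviate(tr$species, 6)))
  core <- generate_voxel_phantom(phantom_spec(
    "colony_core", grid_dims = c(40, 100, 100), voxel_spacing = 760,
    core_diameter_um = 73000, stem_density_cm2 = tr$field_density,
    stem_length_um = 28000, stem_radius_um = 1300,
    rng_seed = seed + 100 + i), noise_sd = 8)
  write_volume(core$grid,
               sprintf("scratch/volumes/core_%s.nrrd", abbreviate(tr$species, 6)))
}
message("wrote 4 single-plant and 4 colony-core phantom volumes (NRRD)")

## (c) cosm drought series -----------------------------------------------------
# drying speed and attenuation vary by species: pool/lawn species start
# wetter and dry slower; hummock species dry faster but pack denser
drying <- data.frame(
  species = species_traits$species,
  initial_rwc = c(1500, 1200, 1000, 1400),
  loss_rate_base = c(120, 150, 160, 125),
  density_attenuation = c(0.96, 0.97, 0.97, 0.955)
)
all_series <- list()
for (i in seq_len(nrow(drying))) {
  dr <- drying[i, ]
  for (n in c(10, 20, 30, 40)) {
    for (k in 1:6) {
      group <- if (k <= 2) "control" else "drought"
      par <- drought_sim_params(
        initial_rwc = dr$initial_rwc, loss_rate_base = dr$loss_rate_base,
        density_attenuation = dr$density_attenuation,
        rng_seed = seed + i * 10000 + n * 100 + k)
      all_series[[length(all_series) + 1]] <- simulate_drought_cosm(
        par, n, group = group, species = dr$species,
        cosm_id = sprintf("%s_n%02d_%s%d", abbreviate(dr$species, 6), n, group, k))
    }
  }
}
names(all_series) <- vapply(all_series, `[[`, character(1), "cosm_id")
write_cosm_csv(all_series, "results/cosm_series.csv")
dw <- vapply(all_series, `[[`, numeric(1), "dry_weight")
write.csv(data.frame(cosm_id = names(dw), dry_weight_g = dw),
          "results/cosm_dry_weights.csv", row.names = FALSE)
message(sprintf("wrote %d cosm series (4 species x 4 densities x 6 cosms)",
                length(all_series)))

cfg <- structure(modifyList(config_defaults(), list(seed = seed)),
                 class = "run_config")
write_config(cfg, "results/run_config.yaml")
write_manifest("results", config = cfg,
               inputs = c("results/centrifuge_ledger.csv", "results/cosm_series.csv"),
               seed = seed)
message("stage 1 complete; manifest written to results/manifest.json")
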