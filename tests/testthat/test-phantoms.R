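# Voxel phantoms and their analytic ground truth, plus the simulated
# centrifugation and drought generators.

test_that("phantom generation is deterministic under a fixed seed", {
  sp <- phantom_spec("sphere", grid_dims = 32, voxel_spacing = 100,
                     radius_um = 1200, rng_seed = 11L)
  a <- generate_voxel_phantom(sp, noise_sd = 12)
  b <- generate_voxel_phantom(sp, noise_sd = 12)
  expect_identical(a$grid$intensities, b$grid$intensities)
  expect_identical(a$truth$mask, b$truth$mask)
  # serialization is byte-identical too
  expect_identical(serialize(a$grid, NULL), serialize(b$grid, NULL))
  # a different seed changes the noise
  sp2 <- phantom_spec("sphere", grid_dims = 32, voxel_spacing = 100,
                      radius_um = 1200, rng_seed = 12L)
  c2 <- generate_voxel_phantom(sp2, noise_sd = 12)
  expect_false(identical(a$grid$intensities, c2$grid$intensities))
})

test_that("cuboid phantom volume is exact by construction", {
  sp <- phantom_spec("cuboid", grid_dims = 14, voxel_spacing = 100,
                     edge_um = 1000)
  ph <- generate_voxel_phantom(sp)
  expect_identical(sum(ph$truth$mask), 1000L)
  expect_equal(ph$truth$analytic_volume_mm3, 1.0)
  expect_equal(ph$truth$analytic_surface_area_mm2, 6.0)
  expect_equal(ph$truth$analytic_porosity, 0)
  # foreground/background levels are the documented constants
  expect_setequal(unique(as.vector(ph$grid$intensities)), c(30, 200))
})

test_that("sphere phantom voxel count matches the brute-force inclusion oracle", {
  r_vox <- 21
  sp <- phantom_spec("sphere", grid_dims = 2 * r_vox + 5, voxel_spacing = 50,
                     radius_um = 50 * r_vox)
  ph <- generate_voxel_phantom(sp)
  expect_identical(sum(ph$truth$mask), oracle_ball_voxel_count(r_vox))
  # voxel-count volume within 2% of the closed form at r >= 20 voxels
  vol_mm3 <- sum(ph$truth$mask) * prod(ph$grid$spacing) * 1e-9
  expect_lt(abs(vol_mm3 / ph$truth$analytic_volume_mm3 - 1), 0.02)
})

test_that("hollow cylinder truth includes its internal void fraction", {
  sp <- phantom_spec("hollow_cylinder", grid_dims = c(40, 50, 50),
                     voxel_spacing = 100, outer_radius_um = 2000,
                     inner_radius_um = 1000, length_um = 3000)
  ph <- generate_voxel_phantom(sp)
  expect_equal(ph$truth$analytic_porosity, 0.25)  # (ri/ro)^2
  expect_equal(ph$truth$analytic_volume_mm3, pi * (4 - 1) * 3,  # pi(ro^2-ri^2)L in mm
               tolerance = 1e-12)
})

test_that("a branched plant with zero branches is exactly a bare stem cylinder", {
  sp <- phantom_spec("branched_plant", grid_dims = c(60, 30, 30),
                     voxel_spacing = 200, stem_length_um = 9000,
                     stem_radius_um = 500, n_spreading = 0, n_pendent = 0)
  ph <- generate_voxel_phantom(sp)
  # independent cylinder rasterization: distance to the vertical axis
  d <- sp$grid_dims; spc <- sp$voxel_spacing
  zc <- (seq_len(d[1]) - 1) * spc[1]; yc <- (seq_len(d[2]) - 1) * spc[2]
  xc <- (seq_len(d[3]) - 1) * spc[3]
  ctr <- (d - 1) * spc / 2
  top <- ((d[1] - 1) * spc[1] - 9000) / 2
  radial <- outer((yc - ctr[2])^2, (xc - ctr[3])^2, "+") <= 500^2
  axial <- zc >= top & zc <= top + 9000
  expect_identical(ph$truth$mask, outer(axial, radial, "&"))
})

test_that("branches add material and respect their angles qualitatively", {
  base <- list(grid_dims = c(90, 64, 64), voxel_spacing = 200,
               stem_length_um = 16000, stem_radius_um = 400,
               branch_length_um = 4000, branch_radius_um = 250)
  bare <- generate_voxel_phantom(do.call(phantom_spec,
    c(list("branched_plant", n_spreading = 0, n_pendent = 0), base)))
  spreading <- generate_voxel_phantom(do.call(phantom_spec,
    c(list("branched_plant", n_spreading = 10, n_pendent = 0), base)))
  pendent <- generate_voxel_phantom(do.call(phantom_spec,
    c(list("branched_plant", n_spreading = 0, n_pendent = 10), base)))
  expect_gt(sum(spreading$truth$mask), sum(bare$truth$mask))
  expect_gt(sum(pendent$truth$mask), sum(bare$truth$mask))
  # spreading branches reach farther laterally than appressed pendent ones
  lateral_extent <- function(m) {
    yx <- which(apply(m, 2, any))
    diff(range(yx))
  }
  expect_gt(lateral_extent(spreading$truth$mask),
            lateral_extent(pendent$truth$mask))
})

test_that("geometry exceeding the grid is rejected naming the axis", {
  expect_error(
    phantom_spec("sphere", grid_dims = 20, voxel_spacing = 100,
                 radius_um = 2000),
    "exceeds grid bounds along axis"
  )
  expect_error(
    phantom_spec("cuboid", grid_dims = c(10, 100, 100), voxel_spacing = 100,
                 edge_um = c(5000, 1000, 1000)),
    "axis z"
  )
})

test_that("colony cores place stems at the requested density", {
  mk <- function(dens) {
    generate_voxel_phantom(phantom_spec(
      "colony_core", grid_dims = c(20, 96, 96), voxel_spacing = 800,
      core_diameter_um = 73000, stem_density_cm2 = dens,
      stem_length_um = 10000, stem_radius_um = 1200, rng_seed = 5L))
  }
  lo <- mk(0.6); hi <- mk(1.9)
  area_cm2 <- pi * 3.65^2
  expect_equal(nrow(attr(lo$truth$mask, "stem_centres")), round(0.6 * area_cm2))
  expect_equal(nrow(attr(hi$truth$mask, "stem_centres")), round(1.9 * area_cm2))
  # all stems lie inside the core circle, pairwise separated
  ctr <- c(95 / 2 * 800, 95 / 2 * 800)
  pts <- attr(hi$truth$mask, "stem_centres")
  rr <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  expect_true(all(rr <= 36500 - 1200 + 1e-6))
  dd <- as.matrix(dist(pts)); diag(dd) <- Inf
  expect_gt(min(dd), 1200)  # no fused interior stems at this density
})

test_that("sequential dart placement nests colonies across densities", {
  # fixed min separation and no boundary ring: identical proposal stream,
  # so the sparse colony's stems are a prefix of the dense colony's
  mk <- function(dens) {
    ph <- generate_voxel_phantom(phantom_spec(
      "colony_core", grid_dims = c(10, 96, 96), voxel_spacing = 800,
      core_diameter_um = 73000, stem_density_cm2 = dens,
      stem_length_um = 6000, stem_radius_um = 1200,
      min_separation_um = 4000, boundary_ring = FALSE, rng_seed = 5L))
    unname(attr(ph$truth$mask, "stem_centres"))
  }
  c_lo <- mk(0.6); c_hi <- mk(1.9)
  expect_equal(c_lo, c_hi[seq_len(nrow(c_lo)), ])
})

## ----------------------------------------------------- centrifuge simulator

test_that("pool thresholds gate water release as a hand-traced ledger", {
  pools <- water_pools(branch_capillary = 0.1, interstem = 0.2,
                       hyaline = 0.3, intracellular = 0.5,
                       thresholds = c(branch_capillary = 10, interstem = 50,
                                      hyaline = 200, intracellular = 300))
  rec <- simulate_centrifuge_run(pools, c(17, 66, 149, 266), dry_weight = 0.2)
  # 17g drains the 10-threshold pool, 66g the 50, nothing at 149, 266
  # drains the 200-threshold pool; the 300-threshold pool never drains
  expect_equal(unname(rec$released), c(0.1, 0.2, 0, 0.3))
  expect_equal(rec$saturated_weight, 0.2 + 1.1)
})

test_that("thresholds above the schedule release nothing", {
  pools <- water_pools(thresholds = c(branch_capillary = 500, interstem = 600,
                                      hyaline = 700, intracellular = 800))
  rec <- simulate_centrifuge_run(pools, c(17, 66, 149, 266), dry_weight = 0.1)
  expect_equal(unname(rec$released), rep(0, 4))
})

test_that("noise-free ledgers conserve mass exactly across seeded records", {
  set.seed(99)
  for (i in 1:25) {
    masses <- sort(runif(4, 0, 1))
    pools <- water_pools(branch_capillary = masses[1], interstem = masses[2],
                         hyaline = masses[3], intracellular = masses[4],
                         thresholds = c(branch_capillary = 15, interstem = 60,
                                        hyaline = 120, intracellular = 250))
    dw <- runif(1, 0.05, 0.4)
    rec <- simulate_centrifuge_run(pools, c(17, 66, 149, 266), dry_weight = dw)
    retained <- sum(pools$masses[pools$thresholds > 266])
    expect_equal(dw + retained + sum(rec$released), rec$saturated_weight,
                 tolerance = 1e-12)
  }
})

test_that("measurement noise never breaks non-negativity or the water budget", {
  pools <- water_pools(noise_sd = 0.05)
  for (s in 1:10) {
    rec <- simulate_centrifuge_run(pools, dry_weight = 0.1, seed = s)
    expect_true(all(rec$released >= 0))
    expect_lte(sum(rec$released), rec$saturated_weight - rec$dry_weight + 1e-12)
  }
  expect_error(simulate_centrifuge_run(pools, dry_weight = -1), "dry_weight")
  expect_error(simulate_centrifuge_run(pools, forces = c(66, 17), dry_weight = 1),
               "strictly increasing")
})

test_that("pool threshold ordering is enforced (loosest water drains first)", {
  expect_error(
    water_pools(thresholds = c(branch_capillary = 100, interstem = 60,
                               hyaline = 600, intracellular = 5000)),
    "loosest water drains first")
})

## -------------------------------------------------------- drought simulator

test_that("attenuation off makes density irrelevant; on, denser cosms stay wetter", {
  par_off <- drought_sim_params(density_attenuation = 1, noise_sd = 0)
  t10 <- simulate_drought_cosm(par_off, 10)$observations
  t40 <- simulate_drought_cosm(par_off, 40)$observations
  # same RWC trajectory (weights differ by dry mass, RWC identical)
  rwc10 <- (t10$weight_g - 10 - 0.4) / 0.4 * 100
  rwc40 <- (t40$weight_g - 10 - 1.6) / 1.6 * 100
  expect_equal(rwc10, rwc40, tolerance = 1e-12)

  par_on <- drought_sim_params(noise_sd = 0)
  prev <- NULL
  for (n in c(10, 20, 30, 40)) {
    cs <- simulate_drought_cosm(par_on, n)
    rwc <- (cs$observations$weight_g - 10 - cs$dry_weight) / cs$dry_weight * 100
    if (!is.null(prev)) expect_true(all(rwc >= prev - 1e-9))
    prev <- rwc
  }
})

test_that("the generator's own rate is recoverable from noise-free output", {
  par <- drought_sim_params(noise_sd = 0)
  for (n in c(10, 30)) {
    cs <- simulate_drought_cosm(par, n)
    traj <- rwc_trajectory(cs, tare_g = par$tare_g)
    fit <- loss_rate(traj$rwc, window = cs$drought_window, method = "exponential")
    k_true <- par$loss_rate_base / (par$initial_rwc - par$floor_rwc) *
      par$density_attenuation^(n - 10)
    expect_lt(abs(fit$rate / k_true - 1), 0.10)
    # implied base rate at the reference density
    base_hat <- fit$rate * (par$initial_rwc - par$floor_rwc) /
      par$density_attenuation^(n - 10)
    expect_lt(abs(base_hat / par$loss_rate_base - 1), 0.10)
  }
})

test_that("control cosms hold their initial water content", {
  par <- drought_sim_params(noise_sd = 0.02)
  cs <- simulate_drought_cosm(par, 20, group = "control")
  rwc <- (cs$observations$weight_g - 10 - cs$dry_weight) / cs$dry_weight * 100
  # band: weighing noise only (sd 0.02 g on 0.8 g dry weight = 2.5% RWC)
  expect_true(all(abs(rwc - par$initial_rwc) < 6 * 0.02 / cs$dry_weight * 100))
})

test_that("simulated series are valid cosm_series and deterministic", {
  par <- drought_sim_params()
  a <- simulate_drought_cosm(par, 20)
  b <- simulate_drought_cosm(par, 20)
  expect_s3_class(a, "cosm_series")
  expect_identical(a, b)
  expect_true(all(a$observations$fvfm >= 0 & a$observations$fvfm <= 1))
})
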