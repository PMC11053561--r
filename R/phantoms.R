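# Synthetic voxel phantoms with analytic ground truth. These stand in for
# the physical specimens of the imaging experiments: analytic solids
# (sphere, cuboid, hollow cylinder) exercise the volume / surface-area /
# hull estimators against closed forms, while the procedural shapes
# (branched plant, colony core) emulate Sphagnum geometry -- a vertical
# stem with spreading branches held at a wide angle from the stem axis and
# pendent branches appressed against it, and cores of many stems packed at
# a controlled areal density inside a circular holder.

#' Phantom specification
#'
#' Describes a synthetic specimen to be voxelized by
#' [generate_voxel_phantom()]. All physical parameters are in micrometres
#' (angles in degrees, densities in plants per cm^2). The same spec and
#' seed always produce a bit-identical grid.
#'
#' @param shape_kind One of `"sphere"`, `"cuboid"`, `"hollow_cylinder"`,
#'   `"branched_plant"`, `"colony_core"`.
#' @param grid_dims Integer vector, voxels per axis `(z, y, x)`.
#' @param voxel_spacing µm per voxel, scalar (isotropic) or length 3
#'   `(z, y, x)`.
#' @param ... Geometry parameters by kind:
#'   sphere: `radius_um`;
#'   cuboid: `edge_um` (scalar or length-3 `(z, y, x)`);
#'   hollow_cylinder: `outer_radius_um`, `inner_radius_um`, `length_um`;
#'   branched_plant: `stem_length_um`, `stem_radius_um`, `n_spreading`,
#'     `n_pendent`, `branch_length_um`, `branch_radius_um`,
#'     `spreading_angle_deg` (default 80, measured from the stem axis),
#'     `pendent_angle_deg` (default 10, appressed);
#'   colony_core: `core_diameter_um` (default 73000, the diameter of a
#'     core holder), `stem_density_cm2`, `stem_length_um`,
#'     `stem_radius_um`, `min_separation_um` (default half the mean
#'     inter-stem spacing), `boundary_ring` (default `TRUE`: a
#'     deterministic ring of stems at the core wall, as in a core cut
#'     from a continuous cushion).
#' @param rng_seed Integer seed controlling stochastic placement/noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape_kind, grid_dims, voxel_spacing, ...,
                         rng_seed = 1L) {
  shape_kind <- match.arg(shape_kind,
    c("sphere", "cuboid", "hollow_cylinder", "branched_plant", "colony_core"))
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) == 1L) grid_dims <- rep(grid_dims, 3L)
  if (length(grid_dims) != 3L || any(grid_dims < 1L))
    stop("`grid_dims` must be positive voxel counts along (z, y, x)")
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) == 1L) voxel_spacing <- rep(voxel_spacing, 3L)
  if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0))
    stop("`voxel_spacing` must be positive (um)")
  geom <- list(...)
  bad <- vapply(geom, function(v) is.numeric(v) && any(v < 0), logical(1))
  if (any(bad))
    stop("geometry parameters must be non-negative: ", paste(names(geom)[bad], collapse = ", "))
  spec <- structure(
    list(shape_kind = shape_kind, grid_dims = grid_dims,
         voxel_spacing = voxel_spacing, geom = geom,
         rng_seed = as.integer(rng_seed)),
    class = "phantom_spec"
  )
  check_phantom_fit(spec)
  spec
}

# Verify the nominal geometry fits inside grid_dims * voxel_spacing,
# naming the offending axis.
check_phantom_fit <- function(spec) {
  ext <- spec$grid_dims * spec$voxel_spacing  # physical extent (z, y, x) um
  g <- spec$geom
  need <- switch(spec$shape_kind,
    sphere = rep(2 * req(g, "radius_um"), 3),
    cuboid = {
      e <- as.numeric(req(g, "edge_um")); if (length(e) == 1L) e <- rep(e, 3)
      e
    },
    hollow_cylinder = c(req(g, "length_um"),
                        2 * req(g, "outer_radius_um"),
                        2 * req(g, "outer_radius_um")),
    branched_plant = {
      reach <- req(g, "stem_radius_um") +
        if ((g$n_spreading %||% 0) + (g$n_pendent %||% 0) > 0)
          (g$branch_length_um %||% 0) + (g$branch_radius_um %||% 0) else 0
      c(req(g, "stem_length_um"), 2 * reach, 2 * reach)
    },
    colony_core = c(req(g, "stem_length_um"),
                    g$core_diameter_um %||% 73000,
                    g$core_diameter_um %||% 73000)
  )
  axis_names <- c("z", "y", "x")
  over <- need > ext + 1e-9
  if (any(over))
    stop(sprintf(
      "phantom geometry exceeds grid bounds along axis %s (needs %.4g um, grid extent %.4g um)",
      paste(axis_names[over], collapse = ","), max(need[over]), min(ext[over])))
  invisible(spec)
}

req <- function(lst, name) {
  v <- lst[[name]]
  if (is.null(v)) stop(sprintf("phantom geometry parameter `%s` is required", name))
  if (any(v <= 0)) stop(sprintf("phantom geometry parameter `%s` must be > 0", name))
  v
}

#' Generate a voxel phantom and its analytic ground truth
#'
#' Rasterizes a [phantom_spec()] onto a voxel lattice. Foreground voxels
#' are set to `foreground_level`, background voxels to
#' `background_level`, with optional additive Gaussian noise; the levels
#' are fixed, documented constants so that the default segmentation
#' threshold is deterministic.
#'
#' @param spec A [phantom_spec()].
#' @param noise_sd Standard deviation (intensity units) of additive
#'   Gaussian noise; 0 for a clean phantom.
#' @param foreground_level,background_level Intensity constants (defaults
#'   200 and 30 on an 8-bit-like scale).
#' @return A list with `grid` (a [voxel_grid()]), `truth` (a
#'   `phantom_truth` list: `analytic_volume_mm3`, `analytic_surface_area_mm2`
#'   for analytic solids else `NA`, `analytic_hull_volume_mm3` (equal to the
#'   volume for convex solids), `analytic_porosity` (0 for convex solids),
#'   and `mask`, the generative foreground mask), and `spec`.
#' @export
generate_voxel_phantom <- function(spec, noise_sd = 0,
                                   foreground_level = 200,
                                   background_level = 30) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_dims; sp <- spec$voxel_spacing
  zc <- axis_coords(d[1], sp[1]); yc <- axis_coords(d[2], sp[2]); xc <- axis_coords(d[3], sp[3])
  ctr <- (d - 1) * sp / 2
  g <- spec$geom

  built <- with_seed(spec$rng_seed, switch(spec$shape_kind,
    sphere = {
      r <- req(g, "radius_um")
      mask <- outer(outer((zc - ctr[1])^2, (yc - ctr[2])^2, "+"), (xc - ctr[3])^2, "+") <= r^2
      v <- 4 / 3 * pi * r^3 * 1e-9
      list(mask = mask, volume = v, area = 4 * pi * r^2 * 1e-6,
           hull = v, porosity = 0, convex = TRUE)
    },
    cuboid = {
      e <- as.numeric(req(g, "edge_um")); if (length(e) == 1L) e <- rep(e, 3)
      mask <- outer(outer(abs(zc - ctr[1]) < e[1] / 2, abs(yc - ctr[2]) < e[2] / 2, "&"),
                    abs(xc - ctr[3]) < e[3] / 2, "&")
      v <- prod(e) * 1e-9
      area <- 2 * (e[1] * e[2] + e[1] * e[3] + e[2] * e[3]) * 1e-6
      list(mask = mask, volume = v, area = area, hull = v, porosity = 0, convex = TRUE)
    },
    hollow_cylinder = {
      ro <- req(g, "outer_radius_um"); ri <- g$inner_radius_um %||% 0
      L <- req(g, "length_um")
      if (ri >= ro) stop("inner radius must be smaller than outer radius")
      r2 <- outer((yc - ctr[2])^2, (xc - ctr[3])^2, "+")
      ring <- r2 <= ro^2 & r2 >= ri^2
      mask <- outer(abs(zc - ctr[1]) < L / 2, ring, "&")
      v <- pi * (ro^2 - ri^2) * L * 1e-9
      area <- (2 * pi * (ro + ri) * L + 2 * pi * (ro^2 - ri^2)) * 1e-6
      list(mask = mask, volume = v, area = area,
           hull = pi * ro^2 * L * 1e-9,
           porosity = if (ri > 0) ri^2 / ro^2 else 0, convex = ri == 0)
    },
    branched_plant = {
      mask <- rasterize_plant(d, sp, ctr[2:3], g)
      list(mask = mask, volume = sum(mask) * voxel_volume_mm3(sp),
           area = NA_real_, hull = NA_real_, porosity = NA_real_, convex = FALSE)
    },
    colony_core = {
      mask <- rasterize_colony(d, sp, ctr[2:3], g)
      list(mask = mask, volume = sum(mask) * voxel_volume_mm3(sp),
           area = NA_real_, hull = NA_real_, porosity = NA_real_, convex = FALSE)
    }
  ))

  intens <- array(background_level, dim = d)
  intens[built$mask] <- foreground_level
  if (noise_sd > 0) {
    intens <- intens + with_seed(substream_seed(spec$rng_seed, "noise"),
                                 array(rnorm(prod(d), 0, noise_sd), dim = d))
  }
  truth <- structure(
    list(analytic_volume_mm3 = built$volume,
         analytic_surface_area_mm2 = built$area,
         analytic_hull_volume_mm3 = built$hull,
         analytic_porosity = built$porosity,
         convex = built$convex,
         mask = built$mask),
    class = "phantom_truth"
  )
  list(grid = voxel_grid(intens, sp), truth = truth, spec = spec)
}

# OR a flat-capped cylinder around segment p0 -> p1 (physical um,
# (z, y, x)) into mask: voxel centres whose axial projection falls within
# the segment and whose radial distance to the axis is <= radius.
paint_cylinder <- function(mask, sp, p0, p1, radius) {
  d <- dim(mask)
  lo <- pmin(p0, p1) - radius; hi <- pmax(p0, p1) + radius
  i_lo <- pmax(1L, floor(lo / sp) + 1L)
  i_hi <- pmin(d, ceiling(hi / sp) + 1L)
  if (any(i_lo > i_hi)) return(mask)
  zi <- i_lo[1]:i_hi[1]; yi <- i_lo[2]:i_hi[2]; xi <- i_lo[3]:i_hi[3]
  zc <- (zi - 1) * sp[1]; yc <- (yi - 1) * sp[2]; xc <- (xi - 1) * sp[3]
  pts <- cbind(rep(zc, times = length(yc) * length(xc)),
               rep(rep(yc, each = length(zc)), times = length(xc)),
               rep(xc, each = length(zc) * length(yc)))
  dvec <- p1 - p0
  len2 <- sum(dvec^2)
  rel <- sweep(pts, 2, p0)
  t <- if (len2 > 0) as.vector(rel %*% dvec) / len2 else rep(0, nrow(rel))
  closest <- outer(t, dvec)
  dist2 <- rowSums((rel - closest)^2)
  inside <- t >= 0 & t <= 1 & dist2 <= radius^2
  inside <- array(inside, dim = c(length(zi), length(yi), length(xi)))
  mask[zi, yi, xi] <- mask[zi, yi, xi] | inside
  mask
}

# Branched plant: vertical stem from the apex down, with spreading and
# pendent branches attached at alternating azimuths (golden-angle spacing,
# deterministic). Angles are measured from the downward stem axis.
rasterize_plant <- function(d, sp, centre_yx, g, mask = NULL,
                            apex_um = NULL) {
  L <- req(g, "stem_length_um"); rs <- req(g, "stem_radius_um")
  nspr <- as.integer(g$n_spreading %||% 0); npen <- as.integer(g$n_pendent %||% 0)
  if (is.null(mask)) mask <- array(FALSE, dim = d)
  top <- apex_um %||% max(0, ((d[1] - 1) * sp[1] - L) / 2)
  p_top <- c(top, centre_yx[1], centre_yx[2])
  p_base <- p_top + c(L, 0, 0)
  mask <- paint_cylinder(mask, sp, p_top, p_base, rs)
  if (nspr + npen > 0) {
    bl <- req(g, "branch_length_um"); rb <- req(g, "branch_radius_um")
    a_spr <- (g$spreading_angle_deg %||% 80) * pi / 180
    a_pen <- (g$pendent_angle_deg %||% 10) * pi / 180
    golden <- pi * (3 - sqrt(5))
    angles <- c(rep(a_spr, nspr), rep(a_pen, npen))
    nb <- nspr + npen
    # attachment points spread along the stem below a small capitulum offset
    frac <- (seq_len(nb) - 0.5) / nb
    for (k in seq_len(nb)) {
      att <- p_top + c(0.08 * L + 0.84 * L * frac[k], 0, 0)
      phi <- (k - 1) * golden
      dir <- c(cos(angles[k]), sin(angles[k]) * cos(phi), sin(angles[k]) * sin(phi))
      mask <- paint_cylinder(mask, sp, att, att + bl * dir, rb)
    }
  }
  mask
}

# Colony core: stems at a target areal density inside a circular holder.
# An optional deterministic boundary ring sits at the core wall (a core
# cut from a cushion has plants out to the wall); interior stems are
# placed by seeded Poisson-disc (dart-throwing) sampling. Placement is
# sequential, so cores generated from the same spec with increasing
# density share their first stems (nested colonies).
rasterize_colony <- function(d, sp, centre_yx, g) {
  dia <- g$core_diameter_um %||% 73000
  dens <- req(g, "stem_density_cm2")               # plants per cm^2
  L <- req(g, "stem_length_um"); rs <- req(g, "stem_radius_um")
  R <- dia / 2
  area_cm2 <- pi * (R / 1e4)^2
  n_target <- max(1L, round(dens * area_cm2))
  mean_spacing_um <- 1e4 / sqrt(dens)
  min_sep <- g$min_separation_um %||% (0.5 * mean_spacing_um)
  ring <- isTRUE(g$boundary_ring %||% TRUE)

  pts <- matrix(numeric(0), 0, 2)
  if (ring) {
    # ring spacing follows the bulk density so the wall is neither
    # denser nor sparser than the interior; never exceed the stem budget
    n_ring <- min(n_target,
                  max(3L, floor(2 * pi * (R - rs) / mean_spacing_um)))
    th <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
    pts <- cbind(centre_yx[1] + (R - rs) * cos(th),
                 centre_yx[2] + (R - rs) * sin(th))
  }
  n_free <- n_target - nrow(pts)
  if (n_free > 0) {
    attempts <- 0L; max_attempts <- 2000L * n_free
    while (nrow(pts) < n_target && attempts < max_attempts) {
      attempts <- attempts + 1L
      u <- runif(2, -1, 1)
      if (sum(u^2) > 1) next
      cand <- centre_yx + (R - rs) * u
      if (nrow(pts) == 0L ||
          min((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) >= min_sep^2) {
        pts <- rbind(pts, cand)
      }
    }
    if (nrow(pts) < n_target)
      warning(sprintf(
        "colony placement saturated at %d of %d stems (min separation %.0f um)",
        nrow(pts), n_target, min_sep))
  }

  mask <- array(FALSE, dim = d)
  top <- max(0, ((d[1] - 1) * sp[1] - L) / 2)
  for (k in seq_len(nrow(pts))) {
    mask <- paint_cylinder(mask, sp,
                           c(top, pts[k, 1], pts[k, 2]),
                           c(top + L, pts[k, 1], pts[k, 2]), rs)
  }
  attr(mask, "stem_centres") <- pts
  mask
}
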