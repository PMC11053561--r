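# Shared readers and writers: voxel volumes (NRRD, MetaImage, TIFF with a
# JSON spacing sidecar), validated CSV tables for centrifugation ledgers
# and cosm time series, run configuration and reproducibility manifests.
# Voxel spacing is always read from metadata and never assumed.

## ---------------------------------------------------------------- volumes

nrrd_type_map <- c(double = "double", float = "float",
                   uchar = "uint8", `unsigned char` = "uint8",
                   short = "int16", ushort = "uint16",
                   `unsigned short` = "uint16", int = "int32",
                   uint = "uint32", `unsigned int` = "uint32")

read_bin_typed <- function(con, type, n, endian) {
  switch(type,
    double = readBin(con, "double", n, size = 8, endian = endian),
    float = readBin(con, "double", n, size = 4, endian = endian),
    uint8 = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    int16 = as.numeric(readBin(con, "integer", n, size = 2, signed = TRUE, endian = endian)),
    uint16 = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE, endian = endian)),
    int32 = as.numeric(readBin(con, "integer", n, size = 4, endian = endian)),
    uint32 = {
      v <- readBin(con, "integer", n, size = 4, endian = endian)
      ifelse(v < 0, v + 2^32, as.numeric(v))
    },
    stop("unsupported element type: ", type))
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD000[1-9]$", magic)) stop("corrupt NRRD header (bad magic): ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0L) stop("corrupt NRRD header (no blank line before data)")
    if (line == "") break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexpr("^[^:]+:=?", line))
    key <- tolower(trimws(sub(":=?$", "", kv)))
    val <- trimws(sub("^[^:]+:=?", "", line))
    fields[[key]] <- val
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3D NRRD volumes are supported")
  spacing <- NULL
  if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    spacing <- vapply(vecs, function(v) {
      nums <- as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
      sqrt(sum(nums^2))
    }, numeric(1))
  }
  if (is.null(spacing) || any(is.na(spacing)))
    stop("NRRD file carries no voxel spacing (spacings/space directions); refusing to assume isotropy: ", path)
  type_raw <- tolower(fields$type %||% "double")
  type <- nrrd_type_map[[type_raw]] %||% stop("unsupported NRRD type: ", type_raw)
  endian <- fields$endian %||% "little"
  enc <- tolower(fields$encoding %||% "raw")
  n <- prod(sizes)
  if (enc == "raw") {
    vals <- read_bin_typed(con, type, n, endian)
  } else if (enc %in% c("gzip", "gz")) {
    comp <- readBin(con, "raw", n = file.info(path)$size)
    rawdata <- memDecompress(comp, type = "gzip")
    rcon <- rawConnection(rawdata)
    on.exit(close(rcon), add = TRUE)
    vals <- read_bin_typed(rcon, type, n, endian)
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(vals) != n) stop("truncated NRRD data: ", path)
  # NRRD stores the fastest axis first; our arrays are [z, y, x] with z
  # fastest in column-major order, so sizes map directly to dim.
  voxel_grid(array(vals, dim = sizes), spacing)
}

write_nrrd <- function(grid, path) {
  d <- dim(grid$intensities)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# mossmetrics voxel volume; axes fastest-to-slowest = z (apex at index 0), y, x",
           "type: double", "dimension: 3",
           paste("sizes:", paste(d, collapse = " ")),
           paste("spacings:", paste(format(grid$spacing, digits = 17), collapse = " ")),
           "units: \"um\" \"um\" \"um\"",
           "encoding: raw", "endian: little", "")
  writeLines(hdr, con)
  writeBin(as.vector(grid$intensities), con, size = 8, endian = "little")
  invisible(path)
}

mha_type_map <- c(MET_DOUBLE = "double", MET_FLOAT = "float",
                  MET_UCHAR = "uint8", MET_SHORT = "int16",
                  MET_USHORT = "uint16", MET_INT = "int32",
                  MET_UINT = "uint32")

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0L) stop("corrupt MetaImage header: ", path)
    eq <- regexpr("=", line)
    if (eq < 0) stop("corrupt MetaImage header line: ", line)
    key <- trimws(substr(line, 1, eq - 1))
    val <- trimws(substr(line, eq + 1, nchar(line)))
    fields[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (as.integer(fields$NDims %||% 0) != 3L)
    stop("only 3D MetaImage volumes are supported")
  sizes <- as.integer(strsplit(fields$DimSize, "\\s+")[[1]])
  if (is.null(fields$ElementSpacing))
    stop("MetaImage file carries no ElementSpacing; refusing to assume isotropy: ", path)
  spacing <- as.numeric(strsplit(fields$ElementSpacing, "\\s+")[[1]])
  if (isTRUE(toupper(fields$CompressedData %||% "FALSE") == "TRUE"))
    stop("compressed MetaImage data is not supported")
  type <- mha_type_map[[fields$ElementType %||% "MET_DOUBLE"]] %||%
    stop("unsupported MetaImage element type")
  endian <- if (toupper(fields$BinaryDataByteOrderMSB %||% "FALSE") == "TRUE")
    "big" else "little"
  n <- prod(sizes)
  if (identical(fields$ElementDataFile, "LOCAL")) {
    vals <- read_bin_typed(con, type, n, endian)
  } else {
    raw_path <- file.path(dirname(path), fields$ElementDataFile)
    if (!file.exists(raw_path))
      stop("MetaImage data file not found: ", raw_path)
    rcon <- file(raw_path, "rb")
    on.exit(close(rcon), add = TRUE)
    vals <- read_bin_typed(rcon, type, n, endian)
  }
  if (length(vals) != n) stop("truncated MetaImage data: ", path)
  voxel_grid(array(vals, dim = sizes), spacing)
}

write_metaimage <- function(grid, path) {
  d <- dim(grid$intensities)
  raw_name <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           paste("DimSize =", paste(d, collapse = " ")),
           paste("ElementSpacing =", paste(format(grid$spacing, digits = 17), collapse = " ")),
           "ElementType = MET_DOUBLE",
           paste("ElementDataFile =", raw_name))
  writeLines(hdr, path)
  rcon <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(rcon))
  writeBin(as.vector(grid$intensities), rcon, size = 8, endian = "little")
  invisible(path)
}

tiff_sidecar_path <- function(path) paste0(path, ".json")

read_tiff_volume <- function(path) {
  sidecar <- tiff_sidecar_path(path)
  if (!file.exists(sidecar))
    stop("TIFF volumes need a JSON spacing sidecar named <file>.json (here: ",
         basename(sidecar),
         ") with fields spacing_um [z,y,x] and intensity_scale; none found")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$spacing_um))
    stop("sidecar ", basename(sidecar), " carries no spacing_um field")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(length(pages), dim(pages[[1]]))
  arr <- array(0, dim = d)
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  scale <- meta$intensity_scale %||% 1
  voxel_grid(arr * scale, as.numeric(meta$spacing_um))
}

write_tiff_volume <- function(grid, path) {
  d <- dim(grid$intensities)
  top <- max(grid$intensities, 1e-12)
  pages <- lapply(seq_len(d[1]), function(i)
    pmin(pmax(grid$intensities[i, , ] / top, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(spacing_um = grid$spacing, intensity_scale = top,
         axis_order = "zyx", slice_axis = "z", schema_version = "1.0"),
    tiff_sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a voxel volume
#'
#' Reads NRRD (`.nrrd`), MetaImage (`.mhd`/`.mha`) or multi-page TIFF
#' (`.tif`/`.tiff`, which requires a `<file>.json` sidecar carrying the
#' voxel spacing). A file without voxel spacing metadata is a hard error:
#' spacing is never silently assumed.
#'
#' @param path Path to the volume file.
#' @return A [voxel_grid()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    nrrd = read_nrrd(path),
    mhd = , mha = read_metaimage(path),
    tif = , tiff = read_tiff_volume(path),
    stop("unrecognised volume format: .", ext,
         " (supported: .nrrd, .mhd/.mha, .tif/.tiff + JSON sidecar)"))
}

#' Write a voxel volume
#'
#' Format follows the extension: NRRD (lossless, preferred), MetaImage
#' (`.mhd` header + `.raw`), or multi-page float TIFF plus a JSON sidecar
#' with the spacing and intensity scale (intensities are stored scaled to
#' `[0, 1]`, so the round trip is exact only up to float32 resolution).
#'
#' @param grid A [voxel_grid()].
#' @param path Output path ending in `.nrrd`, `.mhd`, `.tif` or `.tiff`.
#' @return The path, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    nrrd = write_nrrd(grid, path),
    mhd = write_metaimage(grid, path),
    tif = , tiff = write_tiff_volume(grid, path),
    stop("unrecognised volume format: .", ext))
}

## ----------------------------------------------------------------- tables

centrifuge_schema <- c(plant_id = "character", species = "character",
                       treatment = "character", saturated_weight_g = "numeric",
                       force_g = "numeric", released_g = "numeric",
                       post_spin_weight_g = "numeric", dry_weight_g = "numeric")

cosm_schema <- c(cosm_id = "character", species = "character",
                 n_plants = "integer", group = "character", day = "numeric",
                 weight_g = "numeric", fvfm = "numeric")

check_schema <- function(df, schema, path) {
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols))
    stop("schema mismatch in ", basename(path), ": missing columns ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(df), names(schema))
  if (length(extra))
    stop("schema mismatch in ", basename(path), ": unknown columns ",
         paste(extra, collapse = ", "))
  for (col in names(schema)) {
    target <- schema[[col]]
    v <- df[[col]]
    if (target %in% c("numeric", "integer")) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(conv))
      if (length(bad))
        stop(sprintf("column %s in %s is not numeric at row(s) %s",
                     col, basename(path), paste(utils::head(bad, 5), collapse = ", ")))
      df[[col]] <- if (target == "integer") as.integer(conv) else conv
    } else df[[col]] <- as.character(v)
  }
  df
}

#' Read and validate a centrifugation ledger CSV
#'
#' Long format, one row per (plant, force), with the versioned header
#' `plant_id, species, treatment, saturated_weight_g, force_g,
#' released_g, post_spin_weight_g, dry_weight_g`. Validation covers
#' types, non-negative released masses, strictly increasing forces and
#' constant per-plant weights, with row diagnostics; duplicate
#' `(plant_id, force_g)` pairs are rejected.
#'
#' @param path CSV path.
#' @return List of [centrifuge_record()]s (named by plant id), with the
#'   parsed data frame as attribute `"table"`.
#' @export
read_centrifuge_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  df <- check_schema(df, centrifuge_schema, path)
  bad <- which(df$released_g < 0)
  if (length(bad))
    stop("negative released_g at row(s) ", paste(bad + 1L, collapse = ", "),
         " of ", basename(path))
  key <- paste(df$plant_id, df$force_g)
  if (anyDuplicated(key))
    stop("duplicate (plant_id, force_g) at row(s) ",
         paste(which(duplicated(key)) + 1L, collapse = ", "), " of ", basename(path))
  recs <- lapply(split(df, df$plant_id), function(p) {
    p <- p[order(p$force_g), , drop = FALSE]
    for (col in c("species", "treatment", "saturated_weight_g", "dry_weight_g")) {
      if (length(unique(p[[col]])) != 1L)
        stop(sprintf("plant %s has inconsistent %s values", p$plant_id[1], col))
    }
    post <- unique(p$post_spin_weight_g)
    post <- post[!is.na(post)]
    centrifuge_record(
      plant_id = p$plant_id[1], species = p$species[1],
      treatment = p$treatment[1],
      saturated_weight = p$saturated_weight_g[1],
      forces = p$force_g, released = p$released_g,
      dry_weight = p$dry_weight_g[1],
      post_spin_weight = if (length(post) == 1L) post else NULL)
  })
  attr(recs, "table") <- df
  recs
}

#' Write centrifugation records to the ledger CSV schema
#'
#' @param records List of [centrifuge_record()]s.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_centrifuge_csv <- function(records, path) {
  rows <- lapply(records, function(r) {
    data.frame(plant_id = r$plant_id, species = r$species,
               treatment = r$treatment,
               saturated_weight_g = r$saturated_weight,
               force_g = r$forces, released_g = unname(r$released),
               post_spin_weight_g = r$post_spin_weight %||% NA_real_,
               dry_weight_g = r$dry_weight)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a cosm time-series CSV
#'
#' Header: `cosm_id, species, n_plants, group, day, weight_g, fvfm`
#' (long format, one row per observation; `fvfm` may be empty).
#'
#' @param path CSV path.
#' @param drought_window,rewet_window Experiment windows `(start_day,
#'   end_day)`, shared by all cosms in the file.
#' @param dry_weights Named numeric vector of per-cosm total dry weights
#'   (g), measured at the end of the experiment; names are cosm ids.
#' @param area_cm2 Cosm cross-sectional area (default 20).
#' @return List of [cosm_series()] objects, with the parsed data frame as
#'   attribute `"table"`.
#' @export
read_cosm_csv <- function(path, drought_window, rewet_window, dry_weights,
                          area_cm2 = 20) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  df <- check_schema(df, cosm_schema, path)
  bad <- which(!is.na(df$fvfm) & (df$fvfm < 0 | df$fvfm > 1))
  if (length(bad))
    stop("fvfm outside [0, 1] at row(s) ", paste(bad + 1L, collapse = ", "),
         " of ", basename(path))
  series <- lapply(split(df, df$cosm_id), function(cc) {
    cc <- cc[order(cc$day), , drop = FALSE]
    id <- cc$cosm_id[1]
    if (!id %in% names(dry_weights))
      stop("no dry weight supplied for cosm ", id)
    obs <- data.frame(day = cc$day, weight_g = cc$weight_g)
    if (!all(is.na(cc$fvfm))) obs$fvfm <- cc$fvfm
    cosm_series(cosm_id = id, species = cc$species[1],
                n_plants = cc$n_plants[1],
                areal_density = areal_density(cc$n_plants[1], area_cm2),
                group = cc$group[1], observations = obs,
                dry_weight = dry_weights[[id]],
                drought_window = drought_window, rewet_window = rewet_window)
  })
  attr(series, "table") <- df
  series
}

#' Write cosm series to the time-series CSV schema
#'
#' @param series List of [cosm_series()] objects.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_cosm_csv <- function(series, path) {
  rows <- lapply(series, function(s) {
    data.frame(cosm_id = s$cosm_id, species = s$species,
               n_plants = s$n_plants, group = s$group,
               day = s$observations$day, weight_g = s$observations$weight_g,
               fvfm = if ("fvfm" %in% names(s$observations))
                 s$observations$fvfm else NA_real_)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

## ------------------------------------------------------------------ config

#' Default run configuration
#'
#' The documented defaults for every stage parameter: segmentation
#' (`threshold_method`, `min_component_size`), cropping (`crop_mm`), the
#' centrifugation force schedule (`forces`, g-units), the drought
#' analysis (`tare_g`, `low_water_threshold`), and resampling sizes
#' (`n_boot`, `n_perm`).
#'
#' @return Named list of defaults.
#' @export
config_defaults <- function() {
  list(schema_version = "1.0", seed = 1L,
       threshold_method = "otsu",
       min_component_size = 27L, crop_mm = 40,
       forces = c(17, 66, 149, 266),
       tare_g = 10, low_water_threshold = 100,
       n_boot = 10000L, n_perm = 999L)
}

# Optional keys with no default value (absent means "unset").
config_optional_keys <- c("fixed_threshold")

#' Read a run configuration (YAML or JSON)
#'
#' Unknown keys are rejected rather than ignored, so a typo in a config
#' file cannot silently fall back to a default. Missing keys take the
#' documented defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A named list of class `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unrecognised config format: .", ext))
  defaults <- config_defaults()
  unknown <- setdiff(names(cfg), c(names(defaults), config_optional_keys))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  structure(modifyList(defaults, cfg), class = "run_config")
}

#' Write a run configuration
#'
#' @param config A `run_config` or plain named list with known keys.
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  unknown <- setdiff(names(config),
                     c(names(config_defaults()), config_optional_keys))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  ext <- tolower(tools::file_ext(path))
  cfg <- unclass(config)
  switch(ext,
    yaml = , yml = yaml::write_yaml(cfg, path),
    json = jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                                null = "null"),
    stop("unrecognised config format: .", ext))
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records everything needed to reproduce a deterministic run bit for
#' bit: package version, seed, an MD5 hash of the effective
#' configuration, and MD5 hashes of the input files.
#'
#' @param out_dir Directory for `manifest.json`.
#' @param config The effective configuration list.
#' @param inputs Character vector of input file paths.
#' @param seed The run seed.
#' @return Path to the manifest, invisibly.
#' @export
write_manifest <- function(out_dir, config = config_defaults(),
                           inputs = character(0), seed = config$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  input_hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    package = "mossmetrics",
    version = as.character(packageVersion("mossmetrics")),
    seed = seed, config_md5 = cfg_hash, inputs_md5 = input_hashes,
    r_version = R.version.string,
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
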