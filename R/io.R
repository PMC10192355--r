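#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text ASCII grid (header `ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value`, then rows from north to south). Written atomically
#' (temp file then rename).
#'
#' @param mat Matrix indexed `[ix, iy]` with `iy = 1` the southernmost row.
#' @param file Output path.
#' @param resolution Cell size (m).
#' @param xll,yll Lower-left corner coordinates.
#' @param na_value NODATA code (default -9999).
#' @export
write_ascii_grid <- function(mat, file, resolution = 1, xll = 0, yll = 0,
                             na_value = -9999) {
  tmp <- paste0(file, ".tmp")
  con <- file(tmp, "w")
  on.exit(if (!is.null(con)) close(con), add = TRUE)
  writeLines(c(
    paste("ncols", nrow(mat)),
    paste("nrows", ncol(mat)),
    paste("xllcorner", xll),
    paste("yllcorner", yll),
    paste("cellsize", resolution),
    paste("NODATA_value", na_value)), con)
  m <- mat
  m[!is.finite(m)] <- na_value
  # north row first: iy = ncol(mat) down to 1; values west to east
  for (iy in rev(seq_len(ncol(m))))
    writeLines(paste(m[, iy], collapse = " "), con)
  close(con); con <- NULL
  file.rename(tmp, file)
  invisible(file)
}

#' Read an ESRI ASCII grid
#'
#' @param file Path to an ASCII grid.
#' @return A list: `mat` (indexed `[ix, iy]`, `iy = 1` southernmost),
#'   `resolution`, `xll`, `yll`.
#' @export
read_ascii_grid <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file)
  lines <- readLines(file)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  for (need in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[need]])) stop("malformed ASCII grid header: missing ", need)
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  nx <- hdr$ncols; ny <- hdr$nrows
  if (length(vals) != nx * ny) stop("ASCII grid value count mismatch")
  # file rows run north to south; matrix rows run west to east
  m <- matrix(vals, nrow = nx, ncol = ny)[, ny:1, drop = FALSE]
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  list(mat = m, resolution = hdr$cellsize,
       xll = hdr$xllcorner %||% 0, yll = hdr$yllcorner %||% 0)
}

geojson_feature <- function(geometry, properties = NULL) {
  list(type = "Feature",
       properties = properties %||% setNames(list(), character(0)),
       geometry = geometry)
}

write_geojson <- function(features, file) {
  fc <- list(type = "FeatureCollection", features = features)
  tmp <- paste0(file, ".tmp")
  jsonlite::write_json(fc, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  file.rename(tmp, file)
  invisible(file)
}

read_geojson <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file)
  jsonlite::fromJSON(file, simplifyVector = FALSE)
}

closed_ring <- function(poly) {
  rbind(poly, poly[1, , drop = FALSE])
}

coords_to_matrix <- function(cc) {
  t(vapply(cc, function(p) c(p[[1]], p[[2]]), numeric(2)))
}

#' Write an urban model to a directory
#'
#' Serialises the vector parts as GeoJSON (`buildings.geojson` polygons,
#' `destinations.geojson` points, `roads.geojson` linestrings), the land-use
#' raster as an ESRI ASCII grid (`landuse.asc`, integer category codes
#' 0 other / 1 road / 2 building / 3 water) and the scalar metadata as
#' `meta.json`. All writes are atomic.
#'
#' @param urban An `urban_model`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_urban <- function(urban, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ascii_grid(urban$landuse, file.path(dir, "landuse.asc"),
                   urban$resolution, urban$bounds[1], urban$bounds[2])
  blds <- lapply(seq_along(urban$buildings), function(k) {
    ring <- closed_ring(urban$buildings[[k]])
    geojson_feature(list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(r) ring[r, ]))),
                    properties = list(id = k))
  })
  write_geojson(blds, file.path(dir, "buildings.geojson"))
  dst <- lapply(seq_len(nrow(urban$destinations)), function(k) {
    geojson_feature(list(type = "Point",
                         coordinates = urban$destinations[k, ]),
                    properties = list(id = k))
  })
  write_geojson(dst, file.path(dir, "destinations.geojson"))
  rds <- lapply(seq_along(urban$roads), function(k) {
    ln <- urban$roads[[k]]
    geojson_feature(list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(ln)),
                                              function(r) ln[r, ])),
                    properties = list(id = k))
  })
  write_geojson(rds, file.path(dir, "roads.geojson"))
  meta <- list(style = urban$style, bounds = urban$bounds,
               resolution = urban$resolution, coast_side = urban$coast_side,
               inundation_depth_fraction = urban$inundation_depth_fraction)
  tmp <- file.path(dir, "meta.json.tmp")
  jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, file.path(dir, "meta.json"))
  invisible(dir)
}

#' Read an urban model from a directory
#'
#' Counterpart of [write_urban()]. Validates that raster and metadata bounds
#' agree and that every destination lies on a road cell outside the
#' inundation zone.
#'
#' @param dir Directory written by [write_urban()].
#' @return An `urban_model`.
#' @export
read_urban <- function(dir) {
  meta_file <- file.path(dir, "meta.json")
  if (!file.exists(meta_file)) stop("missing meta.json in ", dir)
  meta <- jsonlite::fromJSON(meta_file)
  ras <- read_ascii_grid(file.path(dir, "landuse.asc"))
  nx <- nrow(ras$mat); ny <- ncol(ras$mat)
  if (abs(nx * ras$resolution - (meta$bounds[3] - meta$bounds[1])) > 1e-6 ||
      abs(ny * ras$resolution - (meta$bounds[4] - meta$bounds[2])) > 1e-6)
    stop("raster extent disagrees with metadata bounds")
  if (!file.exists(file.path(dir, "destinations.geojson")))
    stop("missing destinations.geojson in ", dir)
  dst <- read_geojson(file.path(dir, "destinations.geojson"))
  destinations <- t(vapply(dst$features, function(f) {
    c(f$geometry$coordinates[[1]], f$geometry$coordinates[[2]])
  }, numeric(2)))
  blds <- read_geojson(file.path(dir, "buildings.geojson"))
  buildings <- lapply(blds$features, function(f) {
    ring <- coords_to_matrix(f$geometry$coordinates[[1]])
    ring[-nrow(ring), , drop = FALSE]  # drop closing vertex
  })
  rds <- read_geojson(file.path(dir, "roads.geojson"))
  roads <- lapply(rds$features, function(f) coords_to_matrix(f$geometry$coordinates))
  lu <- ras$mat
  storage.mode(lu) <- "integer"
  model <- structure(list(
    bounds = as.numeric(meta$bounds), resolution = ras$resolution,
    landuse = lu, buildings = buildings, destinations = destinations,
    roads = roads, coast_side = meta$coast_side,
    inundation_depth_fraction = meta$inundation_depth_fraction,
    style = meta$style, params = NULL
  ), class = "urban_model")
  validate_urban(model)
  model
}

#' Write a reproducibility manifest for a run or ensemble
#'
#' @param config A `sim_config`.
#' @param path Output JSON path.
#' @param extra Named list of extra fields (e.g. per-run seeds).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, extra = list()) {
  man <- c(list(
    package = "evacsim",
    version = as.character(utils::packageVersion("evacsim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    n_agents = config$n_agents,
    horizon = config$horizon,
    record_interval = config$record_interval,
    leader_fraction = config$leader_fraction,
    restrict_to_inundation = config$restrict_to_inundation,
    retain_evacuated_influence = config$retain_evacuated_influence,
    comm = config$comm[c("mu", "radius", "comm_interval", "threshold",
                         "leader_attitude")],
    move = unclass(config$move),
    city = if (!is.null(config$urban$params)) unclass(config$urban$params)
           else list(style = config$urban$style),
    cost_table = as.list(config$cost_table)
  ), extra)
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(man, tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, path)
  invisible(path)
}

#' Summarise ensembles as tables and box plots
#'
#' Produces the box-plot convention used throughout: median line, box at the
#' quartiles (linear-interpolation percentile rule), whiskers at the most
#' extreme values within 1.5 IQR, remaining points as fliers.
#'
#' @param ensembles Named list of `ensemble_result` objects.
#' @param out_dir Optional directory; writes `summary.csv`,
#'   `per_run_metrics.csv` and `completion_boxplot.png` when given.
#' @return A list: `summary` data.frame (one row per ensemble) and `plot`
#'   (a ggplot object).
#' @export
report <- function(ensembles, out_dir = NULL) {
  stopifnot(length(ensembles) >= 1)
  if (is.null(names(ensembles)) || any(names(ensembles) == ""))
    names(ensembles) <- paste0("ensemble_", seq_along(ensembles))
  summ <- do.call(rbind, lapply(names(ensembles), function(nm) {
    s <- ensembles[[nm]]$summary
    data.frame(ensemble = nm, n_runs = s$n, median = s$median,
               q1 = s$q1, q3 = s$q3, whisker_lo = s$whisker_lo,
               whisker_hi = s$whisker_hi, n_fliers = length(s$fliers))
  }))
  per_run <- do.call(rbind, lapply(names(ensembles), function(nm) {
    cbind(ensemble = nm, ensembles[[nm]]$metrics)
  }))
  plt <- ggplot2::ggplot(per_run,
                         ggplot2::aes(x = ensemble, y = completion)) +
    ggplot2::geom_boxplot(coef = 1.5) +
    ggplot2::labs(x = NULL, y = "evacuation completion ratio") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summ, file.path(out_dir, "summary.csv"), row.names = FALSE)
    utils::write.csv(per_run, file.path(out_dir, "per_run_metrics.csv"),
                     row.names = FALSE)
    ggplot2::ggsave(file.path(out_dir, "completion_boxplot.png"), plt,
                    width = 5, height = 4, dpi = 150)
  }
  list(summary = summ, per_run = per_run, plot = plt)
}
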