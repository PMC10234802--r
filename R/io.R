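#' Write a grid as GeoJSON polygons
#'
#' One Polygon feature per cell, properties `cell_id`, `row`, `col`;
#' `cell_size`, `nrows`, `ncols` stored as foreign members at the top level.
#' Coordinates are abstract planar meters (no CRS).
#'
#' @param grid An `fs_grid`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_grid_geojson <- function(grid, path) {
  cells <- grid$cells
  feats <- lapply(seq_len(nrow(cells)), function(i) {
    c <- cells[i, ]
    ring <- list(c(c$xmin, c$ymin), c(c$xmax, c$ymin), c(c$xmax, c$ymax),
                 c(c$xmin, c$ymax), c(c$xmin, c$ymin))
    list(type = "Feature",
         properties = list(cell_id = c$cell_id, row = c$row, col = c$col),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  obj <- list(type = "FeatureCollection",
              nrows = grid$nrows, ncols = grid$ncols,
              cell_size = grid$cell_size, features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a grid written by [write_grid_geojson()]
#' @param path GeoJSON file.
#' @return An `fs_grid`.
#' @export
read_grid_geojson <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  generate_grid(obj$nrows, obj$ncols, obj$cell_size)
}

#' Write routes as GeoJSON linestrings
#'
#' One LineString feature per route with properties `route_id` and
#' `depot_ids`.
#'
#' @param routes Route list.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_routes_geojson <- function(routes, path) {
  feats <- lapply(routes, function(rt) {
    list(type = "Feature",
         properties = list(route_id = rt$route_id,
                           depot_ids = as.list(rt$depot_ids)),
         geometry = list(
           type = "LineString",
           coordinates = lapply(seq_len(nrow(rt$coords)),
                                function(i) unname(rt$coords[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read routes written by [write_routes_geojson()]
#' @param path GeoJSON file.
#' @param grid Optional `fs_grid`; if given, per-cell clip lengths are
#'   precomputed on each route.
#' @return Route list.
#' @export
read_routes_geojson <- function(path, grid = NULL) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  routes <- lapply(obj$features, function(f) {
    coords <- do.call(rbind, lapply(f$geometry$coordinates, unlist))
    colnames(coords) <- c("x", "y")
    list(route_id = f$properties$route_id,
         depot_ids = unlist(f$properties$depot_ids),
         coords = coords)
  })
  if (!is.null(grid)) {
    for (i in seq_along(routes)) {
      routes[[i]]$cell_lengths <- route_cell_lengths(routes[[i]]$coords, grid)
    }
  }
  routes
}

#' Read/write a simulation config as YAML
#'
#' Plain-text key-value serialization of a `sim_config`.
#'
#' @param cfg A `sim_config`.
#' @param path File path.
#' @return `read_sim_config()` returns a validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  plain <- unclass(cfg)
  # yaml drops names on atomic vectors; keep named fields as maps
  for (nm in c("traffic_meanlog", "traffic_sdlog", "calendar")) {
    plain[[nm]] <- as.list(plain[[nm]])
  }
  plain$dgp$sigma <- as.list(plain$dgp$sigma)
  plain$fuel_shares <- list(years = rownames(cfg$fuel_shares),
                            fuels = colnames(cfg$fuel_shares),
                            values = apply(cfg$fuel_shares, 1, as.list,
                                           simplify = FALSE))
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  plain <- yaml::read_yaml(path)
  fs <- plain$fuel_shares
  m <- do.call(rbind, lapply(fs$values, function(v) unlist(v)))
  rownames(m) <- fs$years
  plain$fuel_shares <- m[, fs$fuels, drop = FALSE]
  for (nm in c("traffic_meanlog", "traffic_sdlog", "calendar")) {
    plain[[nm]] <- unlist(plain[[nm]])
  }
  plain$dgp$beta <- lapply(plain$dgp$beta, unlist)
  plain$dgp$sigma <- unlist(plain$dgp$sigma)
  plain$dgp$terms <- unlist(plain$dgp$terms)
  base <- sim_config()
  known <- intersect(names(plain), names(base))
  do.call(sim_config, plain[known])
}

#' Write a run manifest
#'
#' Records the seed, package version, timestamp and the MD5 digest of every
#' file emitted by a pipeline command, so outputs can be verified against
#' the run that produced them.
#'
#' @param out_dir Directory whose files are digested.
#' @param seed Seed used for the run.
#' @param extra Optional named list merged into the manifest.
#' @return Path of the written `manifest.json`, invisibly.
#' @export
write_manifest <- function(out_dir, seed, extra = list()) {
  files <- setdiff(list.files(out_dir), "manifest.json")
  digests <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(digests) <- files
  manifest <- c(list(package = "fleetshift",
                     version = as.character(utils::packageVersion("fleetshift")),
                     created = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"),
                     seed = seed, files = digests), extra)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
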