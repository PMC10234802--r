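#' Clean-bus definitions
#'
#' Two classification rules are supported. The broad rule counts
#' hybrid-electric, CNG and ULSD buses as clean, plus any bus of model year
#' `vintage_cutoff` (2007) or later regardless of fuel; the narrow rule counts
#' hybrid-electric and CNG buses only, with no vintage provision.
#'
#' @param name `"broad"` or `"narrow"`.
#' @return A list of class `clean_definition` with fields `name`,
#'   `clean_fuels`, `vintage_cutoff` (`NULL` for narrow).
#' @examples
#' clean_definition("broad")$clean_fuels   # hybrid, CNG, ULSD
#' @export
clean_definition <- function(name = c("broad", "narrow")) {
  name <- match.arg(name)
  if (name == "broad") {
    def <- list(name = "broad", clean_fuels = c("hybrid", "CNG", "ULSD"),
                vintage_cutoff = 2007L)
  } else {
    def <- list(name = "narrow", clean_fuels = c("hybrid", "CNG"),
                vintage_cutoff = NULL)
  }
  structure(def, class = "clean_definition")
}

#' Default set of clean definitions (broad and narrow)
#' @return Named list of `clean_definition` objects.
#' @export
clean_definitions <- function() {
  list(broad = clean_definition("broad"), narrow = clean_definition("narrow"))
}

bus_fuel_types <- c("diesel", "ULSD", "CNG", "hybrid")

#' Classify a bus as clean or not
#'
#' A bus is clean iff its fuel type is in the definition's clean set, or the
#' definition carries a vintage cutoff and the model year is at or above it.
#'
#' @param fuel_type Character vector of fuel types (from
#'   `"diesel"`, `"ULSD"`, `"CNG"`, `"hybrid"`).
#' @param model_year Integer vector of model years.
#' @param definition A `clean_definition`.
#' @return Logical vector.
#' @examples
#' is_clean("diesel", 2008, clean_definition("broad"))    # TRUE (vintage)
#' is_clean("diesel", 2008, clean_definition("narrow"))   # FALSE
#' is_clean("ULSD", 2003, clean_definition("broad"))      # TRUE
#' @export
is_clean <- function(fuel_type, model_year, definition) {
  stopifnot(inherits(definition, "clean_definition"))
  bad <- setdiff(unique(fuel_type), bus_fuel_types)
  if (length(bad)) {
    stop("unknown fuel type(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(bus_fuel_types, collapse = ", "), ")",
         call. = FALSE)
  }
  out <- fuel_type %in% definition$clean_fuels
  if (!is.null(definition$vintage_cutoff)) {
    out <- out | (model_year >= definition$vintage_cutoff)
  }
  out
}

#' Clean fraction of one depot's roster
#'
#' @param roster data.frame with columns `fuel_type`, `model_year`, `count`
#'   for a single depot-year (extra columns ignored).
#' @param definition A `clean_definition`.
#' @return Fraction of the depot's buses that are clean, in `[0, 1]`.
#' @export
depot_clean_fraction <- function(roster, definition) {
  total <- sum(roster$count)
  if (!is.finite(total) || total <= 0) {
    stop("depot roster has zero buses; a depot with no buses cannot serve routes",
         call. = FALSE)
  }
  clean <- sum(roster$count[is_clean(roster$fuel_type, roster$model_year,
                                     definition)])
  clean / total
}

#' Clean fraction for a route served by one or more depots
#'
#' Bus types are evenly apportioned from each depot serving the route: the
#' route's clean fraction is the unweighted mean of its depots' clean
#' fractions, regardless of depot size.
#'
#' @param depot_ids Character vector of depots serving the route.
#' @param rosters Roster table for the whole system (columns `depot_id`,
#'   `year`, `fuel_type`, `model_year`, `count`).
#' @param year Study year to look up.
#' @param definition A `clean_definition`.
#' @return Route-level clean fraction in `[0, 1]`.
#' @export
route_clean_fraction <- function(depot_ids, rosters, year, definition) {
  fr <- vapply(depot_ids, function(d) {
    r <- rosters[rosters$depot_id == d & rosters$year == year, , drop = FALSE]
    if (nrow(r) == 0L) {
      stop("no roster for depot ", d, " in year ", year, call. = FALSE)
    }
    depot_clean_fraction(r, definition)
  }, numeric(1))
  mean(fr)
}

#' Study calendar
#'
#' @param weekdays,weekend_days Day counts; must sum to 365 or 366.
#' @return List of class `fs_calendar`.
#' @export
default_calendar <- function(weekdays = 261, weekend_days = 104) {
  tot <- weekdays + weekend_days
  if (!(tot %in% c(365, 366))) {
    stop("calendar day counts must sum to 365 or 366 (got ", tot, ")",
         call. = FALSE)
  }
  structure(list(weekdays = weekdays, weekend_days = weekend_days),
            class = "fs_calendar")
}

#' Average annual number of buses serving a route
#'
#' Computed from published weekday and weekend daily trip frequencies:
#' `weekday_trips * n_weekdays + weekend_trips * n_weekend_days`.
#'
#' @param weekday_trips,weekend_trips Trips per day (nonnegative, vectorized).
#' @param calendar An `fs_calendar` (default 261 weekdays / 104 weekend days).
#' @return Buses per year.
#' @examples
#' annual_bus_count(10, 5)   # 3130
#' @export
annual_bus_count <- function(weekday_trips, weekend_trips,
                             calendar = default_calendar()) {
  stopifnot(inherits(calendar, "fs_calendar"))
  if (any(weekday_trips < 0) || any(weekend_trips < 0)) {
    stop("service frequencies must be nonnegative", call. = FALSE)
  }
  weekday_trips * calendar$weekdays + weekend_trips * calendar$weekend_days
}

#' Clip a route polyline to grid cells
#'
#' Returns the length of polyline falling in each intersected grid cell; cells
#' not touched are absent. Lengths are exact (parametric clipping against the
#' grid lines, not sampling) and sum to the total polyline length. A segment
#' lying exactly on a shared cell edge is assigned to the cell with the
#' lexicographically smaller `(row, col)` — a measure-zero tie-break; total
#' length is conserved either way.
#'
#' @param coords Numeric matrix (n x 2) of polyline vertices in meters, or a
#'   route object with a `coords` element.
#' @param grid An `fs_grid`; the polyline must lie inside its extent.
#' @return Named numeric vector of lengths (m); names are cell ids.
#' @export
route_cell_lengths <- function(coords, grid) {
  stopifnot(is_fs_grid(grid))
  if (is.list(coords) && !is.null(coords$coords)) coords <- coords$coords
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L || nrow(coords) < 2L) {
    stop("`coords` must be an n x 2 matrix with n >= 2", call. = FALSE)
  }
  cs <- grid$cell_size
  ext <- grid$extent
  tol <- 1e-9 * cs
  if (any(coords[, 1] < ext["xmin"] - tol | coords[, 1] > ext["xmax"] + tol |
          coords[, 2] < ext["ymin"] - tol | coords[, 2] > ext["ymax"] + tol)) {
    stop("route polyline extends outside the grid envelope", call. = FALSE)
  }
  acc <- new.env(parent = emptyenv())
  lens <- numeric(n_cells(grid))
  for (s in seq_len(nrow(coords) - 1L)) {
    p0 <- coords[s, ]; p1 <- coords[s + 1L, ]
    dx <- p1[1] - p0[1]; dy <- p1[2] - p0[2]
    L <- sqrt(dx * dx + dy * dy)
    if (L == 0) next
    ts <- c(0, 1)
    if (dx != 0) {
      ks <- seq.int(ceiling(min(p0[1], p1[1]) / cs), floor(max(p0[1], p1[1]) / cs))
      ts <- c(ts, (ks * cs - p0[1]) / dx)
    }
    if (dy != 0) {
      ks <- seq.int(ceiling(min(p0[2], p1[2]) / cs), floor(max(p0[2], p1[2]) / cs))
      ts <- c(ts, (ks * cs - p0[2]) / dy)
    }
    ts <- sort(unique(pmin(1, pmax(0, ts))))
    ts <- ts[c(TRUE, diff(ts) > 1e-12)]
    tm <- (ts[-length(ts)] + ts[-1]) / 2
    mx <- p0[1] + tm * dx
    my <- p0[2] + tm * dy
    col <- .axis_index(mx, cs, grid$ncols)
    row <- .axis_index(my, cs, grid$nrows)
    ids <- row * grid$ncols + col + 1L
    seglen <- diff(ts) * L
    for (k in seq_along(ids)) lens[ids[k]] <- lens[ids[k]] + seglen[k]
  }
  hit <- which(lens > 0)
  stats::setNames(lens[hit], as.character(hit))
}

# Map a coordinate to a 0-based cell index along one axis. Points exactly on
# an interior grid line go to the lower-index cell (the lexicographic
# boundary rule); outside indices are clamped to the envelope.
.axis_index <- function(x, cs, nmax) {
  u <- x / cs
  idx <- floor(u)
  on_line <- abs(u - round(u)) < 1e-9
  idx[on_line] <- round(u[on_line]) - 1
  as.integer(pmin(pmax(idx, 0), nmax - 1L))
}

#' Per-cell bus VMT for one study year
#'
#' Annual bus vehicle-meters traveled in a cell is the route length clipped to
#' the cell times the average annual number of buses on the route, summed over
#' routes; clean VMT additionally weights each route by its depot-apportioned
#' clean fraction under each definition.
#'
#' @param routes List of route objects (`route_id`, `depot_ids`, `coords`,
#'   optionally precomputed `cell_lengths`).
#' @param schedules data.frame with columns `route_id`, `year`,
#'   `weekday_trips`, `weekend_trips`.
#' @param rosters Roster table (see [route_clean_fraction()]).
#' @param grid An `fs_grid`.
#' @param year Study year.
#' @param definitions Named list of `clean_definition`s.
#' @param calendar An `fs_calendar`.
#' @return data.frame with one row per grid cell: `cell_id`, `total_vmt`, and
#'   `clean_vmt_<definition>` columns (meters per year).
#' @export
cell_bus_vmt <- function(routes, schedules, rosters, grid, year,
                         definitions = clean_definitions(),
                         calendar = default_calendar()) {
  n <- n_cells(grid)
  total <- numeric(n)
  clean <- lapply(definitions, function(d) numeric(n))
  for (rt in routes) {
    sch <- schedules[schedules$route_id == rt$route_id &
                       schedules$year == year, , drop = FALSE]
    if (nrow(sch) == 0L) {
      stop("no service schedule for route ", rt$route_id, " in year ", year,
           call. = FALSE)
    }
    buses <- annual_bus_count(sch$weekday_trips[1], sch$weekend_trips[1],
                              calendar)
    lens <- rt$cell_lengths
    if (is.null(lens)) lens <- route_cell_lengths(rt$coords, grid)
    ids <- as.integer(names(lens))
    total[ids] <- total[ids] + lens * buses
    for (nm in names(definitions)) {
      frac <- route_clean_fraction(rt$depot_ids, rosters, year,
                                   definitions[[nm]])
      clean[[nm]][ids] <- clean[[nm]][ids] + lens * buses * frac
    }
  }
  out <- data.frame(cell_id = seq_len(n), total_vmt = total)
  for (nm in names(definitions)) out[[paste0("clean_vmt_", nm)]] <- clean[[nm]]
  out
}

#' Change in the clean proportion of bus VMT between two years
#'
#' `clean2/total2 - clean1/total1` wherever both years have positive total bus
#' VMT; cells without service in both years get 0 (and are flagged unserved by
#' the exposure table). Always in `[-1, 1]`.
#'
#' @param clean1,total1 Clean and total bus VMT in the first year (vectors).
#' @param clean2,total2 Same for the second year.
#' @return Numeric vector of proportion differences.
#' @examples
#' delta_prop_clean(25, 100, 50, 100)   # 0.25
#' @export
delta_prop_clean <- function(clean1, total1, clean2, total2) {
  both <- total1 > 0 & total2 > 0
  out <- numeric(length(total1))
  out[both] <- clean2[both] / total2[both] - clean1[both] / total1[both]
  out
}

#' Full per-cell exposure table for a two-year study
#'
#' Runs [cell_bus_vmt()] for both study years, derives the clean-shift
#' statistic under each definition, flags served cells (positive total bus VMT
#' in both years), and adds a bus-stop proxy (count of route polyline vertices
#' in the cell; approximate, descriptive only).
#'
#' @inheritParams cell_bus_vmt
#' @param years Length-2 vector of study years (chronological).
#' @return data.frame keyed by `cell_id` with per-year VMT columns
#'   (`total_vmt_<year>`, `clean_vmt_<def>_<year>`),
#'   `delta_prop_clean_<def>`, `served`, and `stop_proxy`.
#' @export
compute_cell_exposure <- function(routes, schedules, rosters, grid,
                                  years = c(2009, 2014),
                                  definitions = clean_definitions(),
                                  calendar = default_calendar()) {
  stopifnot(length(years) == 2L)
  y1 <- cell_bus_vmt(routes, schedules, rosters, grid, years[1],
                     definitions, calendar)
  y2 <- cell_bus_vmt(routes, schedules, rosters, grid, years[2],
                     definitions, calendar)
  out <- data.frame(cell_id = y1$cell_id)
  out[[paste0("total_vmt_", years[1])]] <- y1$total_vmt
  out[[paste0("total_vmt_", years[2])]] <- y2$total_vmt
  for (nm in names(definitions)) {
    out[[paste0("clean_vmt_", nm, "_", years[1])]] <- y1[[paste0("clean_vmt_", nm)]]
    out[[paste0("clean_vmt_", nm, "_", years[2])]] <- y2[[paste0("clean_vmt_", nm)]]
    out[[paste0("delta_prop_clean_", nm)]] <-
      delta_prop_clean(y1[[paste0("clean_vmt_", nm)]], y1$total_vmt,
                       y2[[paste0("clean_vmt_", nm)]], y2$total_vmt)
  }
  out$served <- y1$total_vmt > 0 & y2$total_vmt > 0
  stops <- numeric(n_cells(grid))
  cs <- grid$cell_size
  for (rt in routes) {
    col <- .axis_index(rt$coords[, 1], cs, grid$ncols)
    row <- .axis_index(rt$coords[, 2], cs, grid$nrows)
    ids <- row * grid$ncols + col + 1L
    tab <- table(ids)
    idx <- as.integer(names(tab))
    stops[idx] <- stops[idx] + as.integer(tab)
  }
  out$stop_proxy <- stops
  out
}
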