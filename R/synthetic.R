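#' Configuration for the synthetic city generator
#'
#' Returns the default simulation configuration, a list of class
#' `sim_config`. Defaults encode the study conditions the pipeline is meant
#' to emulate: a 50 x 50 grid of 300 m cells; roughly 40% of cells with no
#' bus service; a citywide fleet of 5838 buses in the first study year and
#' 5730 in the second; fuel shares of 65.3%/57.7% ULSD, 22.0%/29.2% hybrid,
#' 10% CNG in both years (conventional diesel takes the remainder); a
#' post-2007 vintage share rising from 16.9% to 48.7%; truck routes far more
#' prevalent on served cells; log-normal (right-skewed) total traffic that is
#' heavier where buses run; and pollutant-change surfaces drawn from a
#' spatial-error process with known coefficients (`dgp`).
#'
#' @param ... Named overrides of any default field.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    nrows = 50L, ncols = 50L, cell_size = 300,
    years = c(2009L, 2014L),
    # depots / routes
    n_depots = 12L,
    routes_per_depot = c(5L, 9L),
    route_length_cells = c(25L, 50L),
    p_route_shared = 0.15,
    walk_momentum = 0.7,
    fraction_cells_unserved = 0.40,
    # service frequencies (trips/day) and year-2 drift factor range
    weekday_trips = c(40, 240),
    weekend_trips = c(20, 160),
    service_drift = c(0.9, 1.1),
    # fleet
    fleet_total = c(5838L, 5730L),
    fuel_shares = rbind(
      `2009` = c(diesel = 0.027, ULSD = 0.653, CNG = 0.100, hybrid = 0.220),
      `2014` = c(diesel = 0.031, ULSD = 0.577, CNG = 0.100, hybrid = 0.292)
    ),
    post2007_share = c(0.169, 0.487),
    vintage_cutoff = 2007L,
    bus_service_life = 12L,
    depot_concentration = 12,
    # covariates
    p_truck_served = 0.65,
    p_truck_unserved = 0.10,
    traffic_meanlog = c(served = 22.4, unserved = 20.6),
    traffic_sdlog = c(served = 1.0, unserved = 1.5),
    # outcome DGP: y = X beta + u, (I - lambda W) u = eps
    dgp = list(
      terms = c("delta_prop_clean", "log_total_traffic", "truck_route"),
      definition = "broad",
      beta = list(d_no  = c(-3.0,  -0.05,  -0.001,  -0.03),
                  d_no2 = c(-3.5,  -0.02,  -0.0005,  0.002),
                  d_bc  = c(-0.18,  0.005, -2e-05,   0.002)),
      lambda = 0.5,
      sigma = c(d_no = 1.0, d_no2 = 0.8, d_bc = 0.03)
    ),
    weights_type = "queen",
    calendar = c(weekdays = 261, weekend_days = 104)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) {
    stop("unknown sim_config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  cfg <- structure(cfg, class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks each field and reports every invalid field by name.
#'
#' @param cfg A `sim_config` (or plain list with the same fields).
#' @return The config, invisibly; errors on invalid fields.
#' @export
validate_sim_config <- function(cfg) {
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(cfg$nrows >= 2 && cfg$ncols >= 2, "nrows/ncols: must be >= 2")
  chk(cfg$cell_size > 0, "cell_size: must be positive")
  chk(length(cfg$years) == 2 && cfg$years[1] < cfg$years[2],
      "years: need two increasing years")
  chk(cfg$n_depots >= 1, "n_depots: must be >= 1")
  chk(all(cfg$routes_per_depot >= 1) && length(cfg$routes_per_depot) == 2,
      "routes_per_depot: need a positive range")
  chk(cfg$fraction_cells_unserved >= 0 && cfg$fraction_cells_unserved <= 1,
      "fraction_cells_unserved: must be in [0, 1]")
  chk(all(cfg$fleet_total > 0), "fleet_total: must be positive")
  shares_ok <- is.matrix(cfg$fuel_shares) && nrow(cfg$fuel_shares) == 2 &&
    all(cfg$fuel_shares >= 0) &&
    all(abs(rowSums(cfg$fuel_shares) - 1) < 1e-8)
  chk(shares_ok, "fuel_shares: each year's proportions must sum to 1")
  chk(all(cfg$post2007_share >= 0 & cfg$post2007_share <= 1),
      "post2007_share: must be in [0, 1]")
  chk(all(c(cfg$p_truck_served, cfg$p_truck_unserved) >= 0 &
            c(cfg$p_truck_served, cfg$p_truck_unserved) <= 1),
      "p_truck_*: must be probabilities")
  chk(abs(cfg$dgp$lambda) < 1, "dgp$lambda: must be strictly inside (-1, 1)")
  chk(all(unlist(cfg$dgp$sigma) >= 0), "dgp$sigma: must be nonnegative")
  chk(all(lengths(cfg$dgp$beta) == length(cfg$dgp$terms) + 1),
      "dgp$beta: each vector needs one entry per term plus the intercept")
  if (length(errs)) {
    stop("invalid sim_config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(cfg)
}

#' Place depots and trace bus routes over the grid
#'
#' Depots are placed on distinct random cells. Each depot originates a number
#' of routes drawn from `routes_per_depot`; a route is a lattice walk through
#' cell centers starting at its depot, keeping its heading with probability
#' `walk_momentum` and never immediately reversing, reflected at the grid
#' boundary. A route is served by its originating depot and, with probability
#' `p_route_shared`, by one additional depot; when there are at least two
#' depots, at least one route is forced to be shared. Weekday/weekend service
#' frequencies are drawn per route for the first study year and drifted by a
#' uniform factor for the second.
#'
#' @param grid An `fs_grid`.
#' @param config A `sim_config`.
#' @param seed Optional integer seed (omit to continue the current RNG
#'   stream).
#' @return List with `depots` (data.frame `depot_id`, `cell_id`, `row`,
#'   `col`), `routes` (list of route objects with `route_id`, `depot_ids`,
#'   `coords`, precomputed `cell_lengths`), and `schedules` (data.frame).
#' @export
generate_depots_and_routes <- function(grid, config, seed = NULL) {
  stopifnot(is_fs_grid(grid))
  if (!is.null(seed)) set.seed(seed)
  n <- n_cells(grid)
  if (n < 1) stop("empty grid", call. = FALSE)
  cs <- grid$cell_size
  nd <- config$n_depots
  depot_cells <- sample.int(n, nd)
  depots <- data.frame(
    depot_id = sprintf("D%02d", seq_len(nd)),
    cell_id = depot_cells,
    row = grid$cells$row[depot_cells],
    col = grid$cells$col[depot_cells]
  )

  nroutes_per <- sample(config$routes_per_depot[1]:config$routes_per_depot[2],
                        nd, replace = TRUE)
  routes <- list()
  rid <- 0L
  # headings: 1=E, 2=N, 3=W, 4=S
  drc <- rbind(E = c(0L, 1L), N = c(1L, 0L), W = c(0L, -1L), S = c(-1L, 0L))
  for (d in seq_len(nd)) {
    for (k in seq_len(nroutes_per[d])) {
      rid <- rid + 1L
      len <- sample(config$route_length_cells[1]:config$route_length_cells[2], 1)
      r <- depots$row[d]; c <- depots$col[d]
      heading <- sample.int(4L, 1)
      path <- matrix(0L, nrow = len, ncol = 2)
      path[1, ] <- c(r, c)
      for (s in seq_len(len - 1L)) {
        repeat {
          if (stats::runif(1) < config$walk_momentum) h <- heading
          else h <- sample(setdiff(1:4, ((heading + 1L) %% 4L) + 1L), 1)
          r2 <- r + drc[h, 1]; c2 <- c + drc[h, 2]
          if (r2 >= 0 && r2 < grid$nrows && c2 >= 0 && c2 < grid$ncols) break
          heading <- sample.int(4L, 1)  # blocked at the boundary: re-aim
        }
        heading <- h; r <- r2; c <- c2
        path[s + 1L, ] <- c(r, c)
      }
      coords <- cbind(x = (path[, 2] + 0.5) * cs, y = (path[, 1] + 0.5) * cs)
      dep <- depots$depot_id[d]
      if (nd >= 2 && stats::runif(1) < config$p_route_shared) {
        dep <- c(dep, sample(depots$depot_id[-d], 1))
      }
      routes[[rid]] <- list(route_id = sprintf("R%03d", rid),
                            depot_ids = dep, coords = coords)
    }
  }
  if (nd >= 2 && !any(vapply(routes, function(r) length(r$depot_ids) > 1,
                             logical(1)))) {
    routes[[1]]$depot_ids <- c(routes[[1]]$depot_ids,
                               sample(setdiff(depots$depot_id,
                                              routes[[1]]$depot_ids), 1))
  }
  for (i in seq_along(routes)) {
    routes[[i]]$cell_lengths <- route_cell_lengths(routes[[i]]$coords, grid)
  }

  y1 <- config$years[1]; y2 <- config$years[2]
  wd <- stats::runif(length(routes), config$weekday_trips[1],
                     config$weekday_trips[2])
  we <- stats::runif(length(routes), config$weekend_trips[1],
                     config$weekend_trips[2])
  drift <- stats::runif(length(routes), config$service_drift[1],
                        config$service_drift[2])
  schedules <- data.frame(
    route_id = rep(vapply(routes, `[[`, character(1), "route_id"), 2),
    year = rep(c(y1, y2), each = length(routes)),
    weekday_trips = c(wd, wd * drift),
    weekend_trips = c(we, we * drift)
  )
  list(depots = depots, routes = routes, schedules = schedules)
}

#' Generate depot fleet rosters for both study years
#'
#' Citywide fuel-share and vintage targets are realized per depot with
#' depot-level heterogeneity: each depot-year draws its fuel-share vector
#' from a Dirichlet distribution centered on the citywide target (total
#' concentration `depot_concentration`), after which all depots' shares are
#' shifted by a common vector so the fleet-size-weighted mean matches the
#' target exactly; vintage shares are handled the same way via a Beta draw.
#' Counts are then multinomial within depots, and model years uniform within
#' the pre-cutoff service-life window or the post-cutoff window.
#'
#' @param depots Depot table from [generate_depots_and_routes()].
#' @param config A `sim_config` (uses `fleet_total`, `fuel_shares`,
#'   `post2007_share`, `vintage_cutoff`, `bus_service_life`,
#'   `depot_concentration`).
#' @param seed Optional integer seed.
#' @return data.frame with columns `depot_id`, `year`, `fuel_type`,
#'   `model_year`, `count`.
#' @export
generate_fleet_rosters <- function(depots, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  shares <- config$fuel_shares
  if (any(abs(rowSums(shares) - 1) > 1e-8)) {
    stop("fuel share targets must sum to 1 within each year", call. = FALSE)
  }
  nd <- nrow(depots)
  out <- list()
  for (iy in seq_along(config$years)) {
    year <- config$years[iy]
    total <- config$fleet_total[iy]
    target <- shares[iy, ]
    sizes <- as.integer(stats::rmultinom(1, total, rep(1 / nd, nd)))
    p <- .rdirichlet(nd, config$depot_concentration * target)
    colnames(p) <- names(target)
    # recenter so the size-weighted citywide mean hits the target
    adj <- target - colSums(p * sizes) / total
    p <- sweep(p, 2, adj, `+`)
    p[p < 0] <- 0
    p <- p / rowSums(p)
    q <- stats::rbeta(nd, config$depot_concentration * config$post2007_share[iy],
                      config$depot_concentration * (1 - config$post2007_share[iy]))
    q <- q + (config$post2007_share[iy] - sum(q * sizes) / total)
    q <- pmin(pmax(q, 0), 1)
    pre_years <- (year - config$bus_service_life + 1L):(config$vintage_cutoff - 1L)
    post_years <- config$vintage_cutoff:year
    for (d in seq_len(nd)) {
      cnt <- as.integer(stats::rmultinom(1, sizes[d], p[d, ]))
      for (f in seq_along(target)) {
        if (cnt[f] == 0) next
        npost <- stats::rbinom(1, cnt[f], q[d])
        npre <- cnt[f] - npost
        my <- c(
          if (npre > 0) as.integer(stats::rmultinom(1, npre,
            rep(1 / length(pre_years), length(pre_years)))) else integer(0),
          if (npost > 0) as.integer(stats::rmultinom(1, npost,
            rep(1 / length(post_years), length(post_years)))) else integer(0)
        )
        yrs <- c(if (npre > 0) pre_years else integer(0),
                 if (npost > 0) post_years else integer(0))
        keep <- my > 0
        if (any(keep)) {
          out[[length(out) + 1L]] <- data.frame(
            depot_id = depots$depot_id[d], year = year,
            fuel_type = names(target)[f], model_year = yrs[keep],
            count = my[keep]
          )
        }
      }
    }
  }
  ros <- do.call(rbind, out)
  rownames(ros) <- NULL
  ros
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Generate per-cell traffic and truck-route covariates
#'
#' Truck-route presence is Bernoulli with a higher probability in cells
#' touched by at least one bus route; total traffic VMT (meters/year) is
#' log-normal with a higher log-mean in served cells, reproducing the
#' co-occurrence of bus service with truck routes and heavy traffic and the
#' strong right skew of traffic volumes.
#'
#' @param grid An `fs_grid`.
#' @param routes Route list (with precomputed `cell_lengths`).
#' @param config A `sim_config`.
#' @param seed Optional integer seed.
#' @return data.frame with `cell_id`, `route_served` (logical: any route
#'   touches the cell), `truck_route` (0/1), `traffic_vmt` (m/year).
#' @export
generate_covariates <- function(grid, routes, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_cells(grid)
  served <- logical(n)
  for (rt in routes) {
    lens <- rt$cell_lengths
    if (is.null(lens)) lens <- route_cell_lengths(rt$coords, grid)
    served[as.integer(names(lens))] <- TRUE
  }
  p_truck <- ifelse(served, config$p_truck_served, config$p_truck_unserved)
  truck <- stats::rbinom(n, 1, p_truck)
  meanlog <- ifelse(served, config$traffic_meanlog["served"],
                    config$traffic_meanlog["unserved"])
  sdlog <- ifelse(served, config$traffic_sdlog["served"],
                  config$traffic_sdlog["unserved"])
  traffic <- stats::rlnorm(n, meanlog, sdlog)
  data.frame(cell_id = seq_len(n), route_served = served,
             truck_route = truck, traffic_vmt = traffic)
}

#' Draw a pollutant-change surface from the spatial-error process
#'
#' Generates `y = X beta + u` with `u = lambda W u + eps`,
#' `eps ~ N(0, sigma^2 I)`, computed exactly by solving the sparse system
#' `(I - lambda W) u = eps`.
#'
#' @param grid An `fs_grid` (consistency check only).
#' @param X Design matrix (n x p).
#' @param w An `fs_weights` over the same grid, row-standardized.
#' @param beta Coefficient vector (length p).
#' @param lambda Spatial parameter, `|lambda| < 1`.
#' @param sigma Error standard deviation (>= 0).
#' @param seed Optional integer seed.
#' @return List with `y` (length-n vector), and `truth` (list: `beta`,
#'   `lambda`, `sigma`, `u` latent errors, `eps` innovations).
#' @export
generate_pollutant_change <- function(grid, X, w, beta, lambda, sigma,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  n <- n_cells(grid)
  if (nrow(X) != n || w$n != n) {
    stop("X and weights must match the grid cell count", call. = FALSE)
  }
  if (length(beta) != ncol(X)) {
    stop("length(beta) must equal ncol(X)", call. = FALSE)
  }
  if (abs(lambda) >= 1) stop("|lambda| must be < 1", call. = FALSE)
  if (sigma < 0) stop("`sigma` must be nonnegative", call. = FALSE)
  eps <- stats::rnorm(n, 0, sigma)
  if (lambda == 0) {
    u <- eps
  } else {
    A <- Matrix::Diagonal(n) - lambda * w$W
    u <- as.numeric(Matrix::solve(A, eps))
  }
  y <- as.numeric(X %*% beta) + u
  list(y = y, truth = list(beta = beta, lambda = lambda, sigma = sigma,
                           u = u, eps = eps))
}

#' Simulate a complete synthetic city
#'
#' End-to-end generator: grid, depots and routes with service schedules,
#' depot fleet rosters for both study years, per-cell covariates, the
#' per-cell exposure table (bus VMT and clean shift under both definitions),
#' and pollutant-change surfaces for NO, NO2 and BC drawn from the
#' spatial-error data-generating process. The truth record (DGP coefficients
#' and latent errors) is kept alongside the data for parameter-recovery
#' testing.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed; required so no run has implicit randomness.
#' @param weights Optional prebuilt `fs_weights` for the config's grid
#'   (reused across many simulations for speed).
#' @return Object of class `fs_city`: list with `grid`, `depots`, `routes`,
#'   `schedules`, `rosters`, `covariates`, `exposure`, `surfaces`
#'   (data.frame `cell_id`, `d_no`, `d_no2`, `d_bc`), `truth`, `config`,
#'   `seed`.
#' @export
simulate_city <- function(config = sim_config(), seed, weights = NULL) {
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required: simulations must not draw implicit randomness",
         call. = FALSE)
  }
  validate_sim_config(config)
  set.seed(seed)
  grid <- generate_grid(config$nrows, config$ncols, config$cell_size)
  net <- generate_depots_and_routes(grid, config)
  rosters <- generate_fleet_rosters(net$depots, config)
  cal <- default_calendar(config$calendar[["weekdays"]],
                          config$calendar[["weekend_days"]])
  exposure <- compute_cell_exposure(net$routes, net$schedules, rosters, grid,
                                    years = config$years, calendar = cal)
  covariates <- generate_covariates(grid, net$routes, config)
  if (is.null(weights)) {
    weights <- build_queen_weights(grid, config$weights_type)
  }
  X <- dgp_design_matrix(exposure, covariates, config)
  surfaces <- data.frame(cell_id = seq_len(n_cells(grid)))
  truth <- list(lambda = config$dgp$lambda, terms = colnames(X),
                beta = config$dgp$beta, sigma = config$dgp$sigma,
                u = list())
  for (poll in names(config$dgp$beta)) {
    sim <- generate_pollutant_change(
      grid, X, weights, config$dgp$beta[[poll]], config$dgp$lambda,
      config$dgp$sigma[[poll]]
    )
    surfaces[[poll]] <- sim$y
    truth$u[[poll]] <- sim$truth$u
  }
  structure(
    list(grid = grid, depots = net$depots, routes = net$routes,
         schedules = net$schedules, rosters = rosters,
         covariates = covariates, exposure = exposure, surfaces = surfaces,
         truth = truth, config = config, seed = seed),
    class = "fs_city"
  )
}

# Design matrix of the outcome DGP: intercept + configured terms, with the
# same transforms the analysis applies (log1p on traffic/bus VMT in meters).
dgp_design_matrix <- function(exposure, covariates, config) {
  dpc <- exposure[[paste0("delta_prop_clean_", config$dgp$definition)]]
  cols <- list(`(Intercept)` = rep(1, nrow(exposure)))
  for (term in config$dgp$terms) {
    cols[[term]] <- switch(
      term,
      delta_prop_clean = dpc,
      log_total_traffic = log1p(covariates$traffic_vmt),
      truck_route = covariates$truck_route,
      log_bus_vmt_2009 = log1p(exposure[[paste0("total_vmt_", config$years[1])]]),
      stop("unknown DGP term: ", term, call. = FALSE)
    )
  }
  do.call(cbind, cols)
}

#' @export
print.fs_city <- function(x, ...) {
  cat(sprintf("<fs_city> seed %d: %d cells, %d depots, %d routes, %.1f%% unserved\n",
              x$seed, n_cells(x$grid), nrow(x$depots), length(x$routes),
              100 * mean(!x$covariates$route_served)))
  invisible(x)
}
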