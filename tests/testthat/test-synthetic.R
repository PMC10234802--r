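test_that("generators are bit-identical under a fixed seed", {
  cfg <- small_config()
  a <- simulate_city(cfg, seed = 123)
  b <- simulate_city(cfg, seed = 123)
  expect_identical(a$routes, b$routes)
  expect_identical(a$rosters, b$rosters)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$surfaces, b$surfaces)
  c <- simulate_city(cfg, seed = 124)
  expect_false(identical(a$surfaces$d_no, c$surfaces$d_no))
})

test_that("simulation requires an explicit seed and a valid config", {
  expect_error(simulate_city(small_config()), "seed")
  expect_error(sim_config(fraction_cells_unserved = 1.4), "fraction_cells_unserved")
  bad_shares <- sim_config()$fuel_shares
  bad_shares[1, 1] <- bad_shares[1, 1] + 0.2
  expect_error(sim_config(fuel_shares = bad_shares), "sum to 1")
  expect_error(sim_config(nonsense = 1), "unknown")
})

test_that("route network matches depot assignment rules", {
  cfg <- small_config()
  grid <- generate_grid(cfg$nrows, cfg$ncols, cfg$cell_size)
  net <- generate_depots_and_routes(grid, cfg, seed = 9)
  ndep <- vapply(net$routes, function(r) length(r$depot_ids), integer(1))
  expect_true(all(ndep %in% 1:2))
  expect_true(any(ndep == 2))   # forced when >= 2 depots
  # single depot: every route has exactly one server
  cfg1 <- small_config(n_depots = 1L, p_route_shared = 0.9)
  net1 <- generate_depots_and_routes(generate_grid(15, 15), cfg1, seed = 9)
  expect_true(all(vapply(net1$routes, function(r) length(r$depot_ids),
                         integer(1)) == 1L))
  # walks stay on cell centers inside the grid
  for (rt in net$routes) {
    expect_true(all(rt$coords %% cfg$cell_size == cfg$cell_size / 2))
    expect_true(all(rt$coords >= 0 & rt$coords <= 15 * cfg$cell_size))
  }
})

test_that("realized unserved fraction stays near its target on the default grid", {
  cfg <- sim_config()
  w <- build_queen_weights(generate_grid(cfg$nrows, cfg$ncols, cfg$cell_size))
  uns <- vapply(1:5, function(i) {
    city <- simulate_city(cfg, seed = 7100 + i, weights = w)
    mean(!city$covariates$route_served)
  }, numeric(1))
  expect_true(all(uns >= cfg$fraction_cells_unserved - 0.10 &
                    uns <= cfg$fraction_cells_unserved + 0.10))
})

test_that("fleet rosters hit citywide share targets and stay stable in size", {
  cfg <- sim_config()
  depots <- data.frame(depot_id = sprintf("D%02d", 1:12))
  set.seed(55)
  for (rep in 1:5) {
    ros <- generate_fleet_rosters(depots, cfg)
    for (iy in 1:2) {
      y <- cfg$years[iy]
      r <- ros[ros$year == y, ]
      tot <- sum(r$count)
      expect_equal(tot, cfg$fleet_total[iy])
      shares <- vapply(colnames(cfg$fuel_shares), function(f)
        sum(r$count[r$fuel_type == f]) / tot, numeric(1))
      expect_true(all(abs(shares - cfg$fuel_shares[iy, ]) <= 0.03))
      post <- sum(r$count[r$model_year >= cfg$vintage_cutoff]) / tot
      expect_true(abs(post - cfg$post2007_share[iy]) <= 0.03)
    }
  }
  # totals approximately stable across years
  expect_true(abs(diff(cfg$fleet_total)) / cfg$fleet_total[1] < 0.05)
})

test_that("an all-diesel fleet has zero narrow-clean buses everywhere", {
  shares <- rbind(`2009` = c(diesel = 1, ULSD = 0, CNG = 0, hybrid = 0),
                  `2014` = c(diesel = 1, ULSD = 0, CNG = 0, hybrid = 0))
  cfg <- small_config(fuel_shares = shares, post2007_share = c(0, 0))
  city <- simulate_city(cfg, seed = 3)
  expect_true(all(city$exposure$clean_vmt_narrow_2009 == 0))
  expect_true(all(city$exposure$clean_vmt_narrow_2014 == 0))
  expect_true(all(city$exposure$clean_vmt_broad_2009 == 0))  # no post-2007 either
})

test_that("covariates co-occur with bus service as configured", {
  cfg <- sim_config()
  w <- build_queen_weights(generate_grid(cfg$nrows, cfg$ncols, cfg$cell_size))
  city <- simulate_city(cfg, seed = 808, weights = w)
  cov <- city$covariates
  p_s <- mean(cov$truck_route[cov$route_served])
  p_u <- mean(cov$truck_route[!cov$route_served])
  expect_true(abs(p_s - cfg$p_truck_served) <= 0.05)
  expect_true(abs(p_u - cfg$p_truck_unserved) <= 0.05)
  expect_true(mean(log(cov$traffic_vmt[cov$route_served])) >
                mean(log(cov$traffic_vmt[!cov$route_served])))
  expect_true(all(cov$traffic_vmt > 0))
  # strong right skew: mean well above the median within each service group
  for (grp in list(cov$traffic_vmt[cov$route_served],
                   cov$traffic_vmt[!cov$route_served])) {
    expect_gt(mean(grp) / median(grp), 1.3)
  }
})

test_that("pollutant-change DGP has the stated independence and noiseless limits", {
  g <- generate_grid(12, 12)
  w <- build_queen_weights(g)
  n <- 144
  X <- cbind(1, stats::rnorm(n))
  beta <- c(-2, 0.5)
  # lambda = 0: residual variance approaches sigma^2
  sim0 <- generate_pollutant_change(g, X, w, beta, 0, 1.5, seed = 21)
  expect_equal(stats::var(sim0$y - X %*% beta)[1], 1.5^2, tolerance = 0.3)
  # sigma = 0: exact mean surface
  simz <- generate_pollutant_change(g, X, w, beta, 0.7, 0, seed = 22)
  expect_equal(simz$y, as.numeric(X %*% beta))
  # noiseless generation inverts by least squares to machine precision
  bhat <- qr.coef(qr(X), simz$y)
  expect_equal(unname(bhat), beta, tolerance = 1e-12)
  expect_error(generate_pollutant_change(g, X, w, beta, 1.0, 1, seed = 1),
               "lambda")
  expect_error(generate_pollutant_change(g, X[1:10, ], w, beta, 0.5, 1,
                                         seed = 1), "match")
})

test_that("positive lambda induces positive spatial autocorrelation", {
  g <- generate_grid(20, 20)
  w <- build_queen_weights(g)
  X <- matrix(1, 400, 1)
  set.seed(31)
  mor <- replicate(100, {
    sim <- generate_pollutant_change(g, X, w, 0, 0.5, 1)
    moran_i(sim$y, w$B)
  })
  expect_gte(sum(mor > 0), 95)
})
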