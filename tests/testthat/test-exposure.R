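broad <- clean_definition("broad")
narrow <- clean_definition("narrow")

test_that("clean classification follows fuel sets and the vintage cutoff", {
  expect_true(is_clean("diesel", 2008, broad))    # vintage rule
  expect_false(is_clean("diesel", 2008, narrow))  # no vintage rule
  expect_true(is_clean("ULSD", 2003, broad))
  expect_false(is_clean("ULSD", 2003, narrow))
  expect_true(is_clean("hybrid", 1999, narrow))
  expect_false(is_clean("diesel", 2006, broad))
  expect_error(is_clean("kerosene", 2010, broad), "unknown fuel")
})

test_that("depot clean fractions are count-weighted and reject empty rosters", {
  r <- make_roster("D1", 2009, hybrid_2005 = 50, diesel_2005 = 50)
  expect_equal(depot_clean_fraction(r, narrow), 0.5)
  expect_equal(depot_clean_fraction(make_roster("D1", 2009, CNG_2009 = 7),
                                    narrow), 1.0)
  r2 <- make_roster("D1", 2009, CNG_2001 = 1, ULSD_2001 = 2, diesel_2001 = 1)
  expect_equal(depot_clean_fraction(r2, broad), 0.75)
  expect_error(depot_clean_fraction(make_roster("D1", 2009, diesel_2001 = 0),
                                    broad), "zero buses")
})

test_that("route clean fraction is the unweighted depot mean", {
  rosters <- rbind(
    make_roster("A", 2009, hybrid_2001 = 20, diesel_2001 = 80),   # 0.2
    make_roster("B", 2009, hybrid_2001 = 60, diesel_2001 = 40),   # 0.6
    make_roster("C", 2009, hybrid_2001 = 100)                     # 1.0
  )
  expect_equal(route_clean_fraction(c("A", "B"), rosters, 2009, narrow), 0.4)
  expect_equal(route_clean_fraction("B", rosters, 2009, narrow), 0.6)
  # size is ignored: A has 100 buses, C has 100, B has 100 -> plain mean
  expect_equal(route_clean_fraction(c("A", "B", "C"), rosters, 2009, narrow),
               (0.2 + 0.6 + 1.0) / 3)
  expect_error(route_clean_fraction(c("A", "Z"), rosters, 2009, narrow),
               "depot Z.*2009")
})

test_that("annual bus counts follow the weekday/weekend calendar", {
  expect_equal(annual_bus_count(10, 5), 3130)
  expect_equal(annual_bus_count(1, 1), 365)
  expect_equal(annual_bus_count(0, 0), 0)
  expect_error(annual_bus_count(-1, 0), "nonnegative")
  expect_error(default_calendar(250, 100), "365 or 366")
  leap <- default_calendar(262, 104)
  expect_equal(annual_bus_count(1, 1, leap), 366)
})

test_that("polyline clipping matches exact geometry on simple shapes", {
  g <- generate_grid(2, 2, 300)
  # 600 m horizontal through two cell centers
  lens <- route_cell_lengths(rbind(c(0, 150), c(600, 150)), g)
  expect_equal(unname(lens[c("1", "2")]), c(300, 300))
  # full diagonal of one 300 m cell
  lens2 <- route_cell_lengths(rbind(c(0, 0), c(300, 300)), g)
  expect_equal(sum(lens2), 300 * sqrt(2))
  expect_equal(unname(lens2["1"]), 300 * sqrt(2))
  expect_error(route_cell_lengths(rbind(c(-10, 0), c(300, 300)), g),
               "outside the grid")
})

test_that("segments on a shared edge go to the lexicographically smaller cell", {
  g <- generate_grid(2, 2, 300)
  # vertical line on the shared x = 300 boundary: lower (row, col) is col 0
  lens <- route_cell_lengths(rbind(c(300, 0), c(300, 600)), g)
  expect_equal(sum(lens), 600)
  expect_equal(sort(names(lens)), c("1", "3"))   # cells (0,0) and (1,0)
  # horizontal line on y = 300: assigned to row 0
  lens2 <- route_cell_lengths(rbind(c(0, 300), c(600, 300)), g)
  expect_equal(sum(lens2), 600)
  expect_equal(sort(names(lens2)), c("1", "2"))
})

test_that("clip lengths conserve total polyline length on random routes", {
  set.seed(404)
  g <- generate_grid(8, 8, 300)
  for (i in 1:25) {
    pts <- cbind(runif(6, 0, 8 * 300), runif(6, 0, 8 * 300))
    lens <- route_cell_lengths(pts, g)
    total <- sum(sqrt(rowSums(diff(pts)^2)))
    expect_equal(sum(lens), total, tolerance = 1e-9)
  }
})

test_that("clipping agrees with fine midpoint sampling", {
  set.seed(7)
  g <- generate_grid(6, 6, 300)
  pts <- cbind(runif(5, 50, 1750), runif(5, 50, 1750))
  exact <- route_cell_lengths(pts, g)
  approx <- brute_cell_lengths(pts, g, step = 0.05)
  common <- intersect(names(exact), names(approx))
  expect_true(all(abs(exact[common] - approx[common]) <
                    pmax(0.2, 1e-3 * exact[common])))
})

test_that("cell VMT is length x annual buses x clean fraction, additive", {
  g <- generate_grid(2, 2, 300)
  rosters <- make_roster("A", 2009, hybrid_2001 = 25, diesel_2001 = 75)
  rt <- list(route_id = "R1", depot_ids = "A",
             coords = rbind(c(0, 150), c(300, 150)))
  # 10/day weekday only on a 261/104 calendar = 2610 buses/year
  sch <- data.frame(route_id = "R1", year = 2009,
                    weekday_trips = 10, weekend_trips = 0)
  v <- cell_bus_vmt(list(rt), sch, rosters, g, 2009,
                    definitions = list(narrow = narrow))
  expect_equal(v$total_vmt[1], 300 * 2610)
  expect_equal(v$clean_vmt_narrow[1], 300 * 2610 * 0.25)
  expect_equal(v$total_vmt[3:4], c(0, 0))
  # additivity: two identical routes double everything
  rt2 <- rt; rt2$route_id <- "R2"
  sch2 <- rbind(sch, data.frame(route_id = "R2", year = 2009,
                                weekday_trips = 10, weekend_trips = 0))
  v2 <- cell_bus_vmt(list(rt, rt2), sch2, rosters, g, 2009,
                     definitions = list(narrow = narrow))
  expect_equal(v2$total_vmt, 2 * v$total_vmt)
  expect_equal(v2$clean_vmt_narrow, 2 * v$clean_vmt_narrow)
})

test_that("delta_prop_clean computes the printed difference of proportions", {
  expect_equal(delta_prop_clean(25, 100, 50, 100), 0.25)
  expect_equal(delta_prop_clean(40, 80, 100, 200), 0)
  expect_equal(delta_prop_clean(100, 100, 0, 50), -1)
  # no service in one year -> 0
  expect_equal(delta_prop_clean(0, 0, 50, 100), 0)
  expect_equal(delta_prop_clean(c(25, 0), c(100, 0), c(50, 10), c(100, 20)),
               c(0.25, 0))
})

test_that("exposure table flags served cells and orders narrow <= broad", {
  cfg <- small_config()
  city <- simulate_city(cfg, seed = 5)
  ex <- city$exposure
  expect_true(all(ex$clean_vmt_narrow_2009 <= ex$clean_vmt_broad_2009 + 1e-9))
  expect_true(all(ex$clean_vmt_narrow_2014 <= ex$clean_vmt_broad_2014 + 1e-9))
  expect_true(all(ex$clean_vmt_broad_2009 <= ex$total_vmt_2009 + 1e-9))
  expect_true(all(abs(ex$delta_prop_clean_broad) <= 1))
  expect_true(all(ex$delta_prop_clean_broad[!ex$served] == 0))
  expect_equal(ex$served, ex$total_vmt_2009 > 0 & ex$total_vmt_2014 > 0)
})

test_that("scaling every frequency by k scales VMT by k, leaves shift alone", {
  cfg <- small_config()
  city <- simulate_city(cfg, seed = 31)
  sch_k <- city$schedules
  sch_k$weekday_trips <- 3 * sch_k$weekday_trips
  sch_k$weekend_trips <- 3 * sch_k$weekend_trips
  ex1 <- compute_cell_exposure(city$routes, city$schedules, city$rosters,
                               city$grid)
  ex3 <- compute_cell_exposure(city$routes, sch_k, city$rosters, city$grid)
  expect_equal(ex3$total_vmt_2009, 3 * ex1$total_vmt_2009)
  expect_equal(ex3$clean_vmt_broad_2014, 3 * ex1$clean_vmt_broad_2014)
  expect_equal(ex3$delta_prop_clean_broad, ex1$delta_prop_clean_broad)
  expect_equal(ex3$delta_prop_clean_narrow, ex1$delta_prop_clean_narrow)
})

test_that("swapping a dirty bus for a clean one never lowers clean VMT", {
  g <- generate_grid(2, 2, 300)
  rosters <- rbind(
    make_roster("A", 2009, hybrid_2005 = 10, diesel_2005 = 10),
    make_roster("A", 2014, hybrid_2005 = 10, diesel_2005 = 10)
  )
  rt <- list(route_id = "R1", depot_ids = "A",
             coords = rbind(c(0, 150), c(600, 150)))
  sch <- data.frame(route_id = "R1", year = c(2009, 2014),
                    weekday_trips = 10, weekend_trips = 4)
  before <- compute_cell_exposure(list(rt), sch, rosters, g)
  # move one 2014 diesel to hybrid
  swapped <- rosters
  swapped$count[swapped$year == 2014] <- c(11, 9)
  after <- compute_cell_exposure(list(rt), sch, swapped, g)
  expect_true(all(after$clean_vmt_narrow_2014 >= before$clean_vmt_narrow_2014))
  expect_true(all(after$clean_vmt_broad_2014 >= before$clean_vmt_broad_2014))
  expect_true(all(after$delta_prop_clean_narrow >=
                    before$delta_prop_clean_narrow))
  expect_equal(after$total_vmt_2014, before$total_vmt_2014)
})
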