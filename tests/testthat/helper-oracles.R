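# Independent oracles and small fixtures shared across test files.

# Dense brute-force SEM log-likelihood: direct determinant of (I - lambda W),
# no eigenvalue shortcut. Stays independent of sem_loglik().
dense_sem_loglik <- function(y, X, W, beta, lambda, sigma2) {
  n <- length(y)
  A <- diag(n) - lambda * as.matrix(W)
  r <- as.numeric(A %*% (y - as.matrix(X) %*% beta))
  -(n / 2) * log(2 * pi * sigma2) +
    as.numeric(determinant(A, logarithm = TRUE)$modulus) -
    sum(r^2) / (2 * sigma2)
}

# Brute-force polyline-in-cell lengths by midpoint sampling at `step` meters.
brute_cell_lengths <- function(coords, grid, step = 0.1) {
  coords <- as.matrix(coords)
  seglen <- sqrt(rowSums(diff(coords)^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  d <- seq(step / 2, total, by = step)
  seg <- findInterval(d, cum, rightmost.closed = TRUE)
  seg[seg > length(seglen)] <- length(seglen)
  t <- (d - cum[seg]) / seglen[seg]
  px <- coords[seg, 1] + t * (coords[seg + 1, 1] - coords[seg, 1])
  py <- coords[seg, 2] + t * (coords[seg + 1, 2] - coords[seg, 2])
  cs <- grid$cell_size
  col <- pmin(pmax(floor(px / cs), 0), grid$ncols - 1)
  row <- pmin(pmax(floor(py / cs), 0), grid$nrows - 1)
  ids <- row * grid$ncols + col + 1
  tab <- table(ids)
  setNames(as.numeric(tab) * step, names(tab))
}

# Brute-force Moran's I with the binary neighbor matrix.
moran_i <- function(x, B) {
  z <- x - mean(x)
  n <- length(x)
  s0 <- sum(B)
  (n / s0) * as.numeric(t(z) %*% (as.matrix(B) %*% z)) / sum(z^2)
}

# Small, fast synthetic-city configuration for unit tests (not the study
# defaults; those are exercised in the acceptance suite).
small_config <- function(...) {
  sim_config(nrows = 15L, ncols = 15L, n_depots = 3L,
             routes_per_depot = c(2L, 4L), route_length_cells = c(8L, 16L),
             fleet_total = c(600L, 590L), ...)
}

# Minimal roster table builder: counts named like "hybrid_2010".
make_roster <- function(depot_id, year, ...) {
  kv <- list(...)
  parts <- strsplit(names(kv), "_", fixed = TRUE)
  data.frame(depot_id = depot_id, year = year,
             fuel_type = vapply(parts, `[[`, character(1), 1),
             model_year = as.integer(vapply(parts, `[[`, character(1), 2)),
             count = as.numeric(unlist(kv)))
}
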