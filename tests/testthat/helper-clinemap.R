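# Shared fixtures and independent oracles, built in code.

R_KM <- clinemap::EARTH_RADIUS_KM

.xyz <- function(lat, lon) {
  la <- lat * pi / 180; lo <- lon * pi / 180
  c(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
}

# Brute-force nearest-point oracle: scan n evenly spaced points along
# the great-circle segment (spherical linear interpolation) and return
# the minimum distance and its along-position. Independent of the
# package's cross-/along-track formulas.
brute_force_project_seg <- function(lat, lon, lat1, lon1, lat2, lon2,
                                    n = 1e5) {
  a <- .xyz(lat1, lon1); b <- .xyz(lat2, lon2)
  omega <- acos(min(max(sum(a * b), -1), 1))
  tt <- seq(0, 1, length.out = n)
  pts <- (outer(sin((1 - tt) * omega), a) + outer(sin(tt * omega), b)) /
    sin(omega)
  p <- .xyz(lat, lon)
  d <- acos(pmin(pmax(drop(pts %*% p), -1), 1)) * R_KM
  i <- which.min(d)
  list(cross = d[i], along = tt[i] * omega * R_KM)
}

# Brute-force scan over a whole (possibly multi-segment) transect.
brute_force_project_transect <- function(t, lat, lon, n_per_seg = 2e4) {
  wp <- t$waypoints
  best <- list(cross = Inf, along = NA_real_)
  for (s in seq_len(nrow(wp) - 1)) {
    r <- brute_force_project_seg(lat, lon, wp[s, 1], wp[s, 2],
                                 wp[s + 1, 1], wp[s + 1, 2], n_per_seg)
    if (r$cross < best$cross)
      best <- list(cross = r$cross, along = t$cum_len[s] + r$along)
  }
  best
}

# Random cross-/along-track test case with an interior projection:
# built with the direct (destination-point) problem, which is a
# different formula family from the cross-/along-track equations under
# test.
random_track_case <- function() {
  lat1 <- runif(1, -60, 60); lon1 <- runif(1, -150, 150)
  brg <- runif(1, -pi, pi)
  len <- runif(1, 500, 9500)
  p2 <- dest_point(lat1, lon1, brg, len)
  d_along <- runif(1, 0.05, 0.95) * len
  d_cross <- runif(1, -2000, 2000)
  foot <- dest_point(lat1, lon1, brg, d_along)
  brg_at_foot <- initial_bearing(foot$lat, foot$lon, p2$lat, p2$lon)
  p <- dest_point(foot$lat, foot$lon, brg_at_foot + pi / 2, d_cross)
  list(lat = p$lat, lon = p$lon, lat1 = lat1, lon1 = lon1,
       lat2 = p2$lat, lon2 = p2$lon, len = len)
}

# Binomial cells on a known cline, sampled at the allele level.
simulate_cline_cells <- function(x, params, spec = cline_model_spec(),
                                 n = 100) {
  p <- cline_value(x, params, spec)
  data.frame(along_km = x,
             qhat = stats::rbinom(length(x), 2 * n, p) / (2 * n),
             n = n)
}

# Scalar per-cell log-likelihood oracle (plain loop, no vectorisation).
loglik_scalar_oracle <- function(params, spec, cells, mult = 2,
                                 eps = 1e-6) {
  s <- 0
  for (i in seq_len(nrow(cells))) {
    p <- cline_value(cells$along_km[i], params, spec)
    p <- min(max(p, eps), 1 - eps)
    q <- cells$qhat[i]
    s <- s + mult * cells$n[i] * (q * log(p) + (1 - q) * log(1 - p))
  }
  s
}

# Environmental cell table simulated under the spatial GLS model
# itself: y = X beta + MVN(0, sigma2 * sqrt(v v') exp(-D / rho)).
simulate_gls_cells <- function(n = 100, beta = c(0.5, -0.02), rho = 5,
                               sigma2 = 0.01) {
  cells <- data.frame(
    lon_idx = seq_len(n), lat_idx = seq_len(n),
    centre_lon = runif(n, 0, 40), centre_lat = runif(n, -25, 25),
    n_records = sample(1:50, n, replace = TRUE))
  cells$bio01 <- 30 - 0.45 * abs(cells$centre_lat) + rnorm(n)
  D <- as.matrix(dist(cells[, c("centre_lon", "centre_lat")]))
  v <- 1 / cells$n_records
  S <- sigma2 * (sqrt(v) %o% sqrt(v)) * exp(-D / rho)
  diag(S) <- sigma2 * v
  cells$y <- beta[1] + beta[2] * cells$bio01 +
    drop(crossprod(chol(S), rnorm(n)))
  cells
}

# Direct dense multivariate-normal log-density oracle using
# determinant() and solve() (the implementation uses a Cholesky
# profile path).
mvn_loglik_oracle <- function(y, mu, S) {
  n <- length(y)
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  r <- y - mu
  -0.5 * (n * log(2 * pi) + ld + drop(crossprod(r, solve(S, r))))
}

# Toy record data.frame used across record/grid tests.
toy_records_df <- function() {
  data.frame(
    record_id = c("r1", "r2", "r3", "c1", "c2"),
    source = c("research", "research", "research", "citizen", "citizen"),
    date = c("1950-05-01", NA, "2001-07-21", "2019-03-03", NA),
    lat = c(-1.3, -1.3, -1.9, -1.0, 35.5),
    lon = c(36.8, 36.9, 37.2, 36.5, -5.2),
    locusA = c("rec", "dom", "dom", "rec", "dom"),
    locusB = c("dom", "dom", NA, NA, "rec"),
    locusC = c("rec", "rec", "dom", "dom", NA),
    stringsAsFactors = FALSE)
}

# A small, fast synthetic world for pipeline tests.
small_world <- function(n_records = 2000, seed = 99) {
  world_spec(n_records = n_records, seed = seed)
}
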