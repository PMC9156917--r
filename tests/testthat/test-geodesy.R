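test_that("haversine distance matches closed forms and geosphere", {
  expect_equal(gc_distance(0, 0, 0, 0), 0)
  expect_equal(gc_distance(0, 0, 0, 90), pi * R_KM / 2)
  expect_equal(gc_distance(0, 0, 1, 0), pi * R_KM / 180)
  # symmetry
  expect_equal(gc_distance(10, 20, -30, 150), gc_distance(-30, 150, 10, 20))
  # independent implementation check on random pairs
  set.seed(3)
  lat1 <- runif(50, -80, 80); lon1 <- runif(50, -179, 179)
  lat2 <- runif(50, -80, 80); lon2 <- runif(50, -179, 179)
  ref <- geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                  r = R_KM * 1000) / 1000
  expect_equal(gc_distance(lat1, lon1, lat2, lon2), ref, tolerance = 1e-9)
})

test_that("triangle inequality holds on random triples", {
  set.seed(4)
  for (i in 1:100) {
    p <- matrix(c(runif(3, -85, 85), runif(3, -179, 179)), ncol = 2)
    d12 <- gc_distance(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
    d23 <- gc_distance(p[2, 1], p[2, 2], p[3, 1], p[3, 2])
    d13 <- gc_distance(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
    expect_lte(d13, d12 + d23 + 1e-9)
  }
})

test_that("initial bearing gives the cardinal directions", {
  expect_equal(initial_bearing(0, 0, 0, 10), pi / 2)
  expect_equal(initial_bearing(0, 0, 10, 0), 0)
  expect_equal(abs(initial_bearing(0, 0, -10, 0)), pi)
  expect_error(initial_bearing(5, 5, 5, 5), "identical")
})

test_that("cross- and along-track distances match meridian arc closed forms", {
  # equatorial segment, point 1 degree north at lon 45
  xt <- cross_track(1, 45, 0, 0, 0, 90)
  expect_equal(abs(xt), pi * R_KM / 180, tolerance = 1e-6)
  # mirrored point: same magnitude, opposite sign
  expect_equal(cross_track(-1, 45, 0, 0, 0, 90), -xt, tolerance = 1e-9)
  # point on the path
  expect_equal(cross_track(0, 30, 0, 0, 0, 90), 0, tolerance = 1e-9)
  at <- along_track(1, 45, 0, 0, 0, 90)
  expect_equal(at, pi * R_KM / 4, tolerance = 1e-3)
  expect_equal(along_track(0, 0, 0, 0, 0, 90), 0)
  expect_equal(along_track(0, 90, 0, 0, 0, 90), pi * R_KM / 2,
               tolerance = 1e-6)
  # behind the start: negative along-track
  expect_lt(along_track(0, -10, 0, 0, 0, 90), 0)
})

test_that("cross/along track agree with geosphere on random cases", {
  set.seed(5)
  for (i in 1:50) {
    cs <- random_track_case()
    xt <- cross_track(cs$lat, cs$lon, cs$lat1, cs$lon1, cs$lat2, cs$lon2)
    at <- along_track(cs$lat, cs$lon, cs$lat1, cs$lon1, cs$lat2, cs$lon2)
    ref_xt <- geosphere::dist2gc(c(cs$lon1, cs$lat1), c(cs$lon2, cs$lat2),
                                 c(cs$lon, cs$lat), r = R_KM * 1000,
                                 sign = TRUE) / 1000
    expect_equal(abs(xt), abs(ref_xt), tolerance = 1e-6)
    # along-track against the independent dense scan (geosphere's own
    # along-track routine is only km-accurate)
    bf <- brute_force_project_seg(cs$lat, cs$lon, cs$lat1, cs$lon1,
                                  cs$lat2, cs$lon2, n = 5e4)
    expect_lt(abs(at - bf$along), 1)
  }
})

test_that("projection agrees with the brute-force nearest-point scan", {
  set.seed(6)
  for (i in 1:60) {
    cs <- random_track_case()
    xt <- cross_track(cs$lat, cs$lon, cs$lat1, cs$lon1, cs$lat2, cs$lon2)
    at <- along_track(cs$lat, cs$lon, cs$lat1, cs$lon1, cs$lat2, cs$lon2)
    bf <- brute_force_project_seg(cs$lat, cs$lon, cs$lat1, cs$lon1,
                                  cs$lat2, cs$lon2, n = 2e4)
    expect_lt(abs(abs(xt) - bf$cross), 1)
    expect_lt(abs(at - bf$along), 1)
  }
})

test_that("transects validate their waypoints and measure length", {
  t <- transect("eq", rbind(c(0, 0), c(0, 10), c(0, 30)))
  expect_equal(transect_length(t), pi * R_KM / 6, tolerance = 1e-9)
  expect_error(transect("bad", rbind(c(0, 0), c(0, 0))), "distinct")
  expect_error(transect("bad", rbind(c(0, 0))), "at least two")
})

test_that("transect JSON round-trips", {
  t <- transect("se-africa", rbind(c(-5, 20), c(-15, 30), c(-25, 31)),
                corridor_km = 450)
  path <- withr::local_tempfile(fileext = ".json")
  write_transect(t, path)
  t2 <- read_transect(path)
  expect_equal(t2$waypoints, t$waypoints)
  expect_equal(t2$corridor_km, 450)
  expect_equal(t2$name, t$name)
})

test_that("cell projection keeps corridor cells with cumulative positions", {
  # grid cells on the equator around a two-segment equatorial transect
  df <- data.frame(
    record_id = sprintf("r%02d", 1:40), source = "research", date = NA,
    lat = rep(c(0.5, 0.5, 0.5, 9, 30), each = 8),
    lon = rep(c(10.5, 20.5, 30.5, 20.5, 90.5), each = 8),
    locusA = rep(c("rec", "dom"), 20), locusB = "dom", locusC = "dom")
  grid <- build_grid(as_colour_records(df), grid_spec(1))
  t <- transect("eq", rbind(c(0, 10), c(0, 25), c(0, 35)))
  pc <- project_cells(grid, t, "A")
  # the cell at lat 30 is far outside the 450 km corridor; lat 9 is
  # ~945 km off; three equatorial cells remain
  expect_equal(nrow(pc), 3)
  expect_true(all(abs(pc$cross_km) <= 450))
  expect_true(all(pc$along_km >= 0 & pc$along_km <= transect_length(t)))
  expect_equal(pc$along_km, sort(pc$along_km))
  # cell centred on the second segment gets cumulative along-track
  expect_gt(max(pc$along_km), gc_distance(0, 10, 0, 25))
  # against the dense scan over the whole transect
  for (i in seq_len(nrow(pc))) {
    cell <- grid$cells[grid$cells$lon_idx == pc$cell_lon_idx[i] &
                         grid$cells$lat_idx == pc$cell_lat_idx[i], ]
    bf <- brute_force_project_transect(t, cell$centre_lat, cell$centre_lon)
    expect_lt(abs(abs(pc$cross_km[i]) - bf$cross), 1)
    expect_lt(abs(pc$along_km[i] - bf$along), 1)
  }
})

test_that("projection is invariant under transect reversal", {
  t <- transect("fwd", rbind(c(-5, 20), c(-15, 30), c(-25, 31)))
  tr <- transect("rev", t$waypoints[3:1, ])
  L <- transect_length(t)
  pts <- data.frame(lat = c(-7, -12, -20), lon = c(22, 28, 32))
  for (i in seq_len(nrow(pts))) {
    a <- clinemap:::.project_point(t, pts$lat[i], pts$lon[i])
    b <- clinemap:::.project_point(tr, pts$lat[i], pts$lon[i])
    expect_equal(unname(a["along"]), L - unname(b["along"]), tolerance = 1e-6)
    expect_equal(unname(a["cross"]), -unname(b["cross"]), tolerance = 1e-6)
  }
})

test_that("cells beyond the corridor or transect ends are excluded", {
  df <- data.frame(
    record_id = c("a", "b"), source = "research", date = NA,
    lat = c(5.5, 0.5), lon = c(20.5, 50.5),
    locusA = "rec", locusB = "dom", locusC = "dom")
  grid <- build_grid(as_colour_records(df), grid_spec(1))
  t <- transect("eq", rbind(c(0, 10), c(0, 35)))
  # 5.5 deg off path (~600 km) and beyond the east end: nothing left
  expect_error(project_cells(grid, t, "A"), "corridor")
})
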