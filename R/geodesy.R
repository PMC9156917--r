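# Spherical great-circle geometry on the mean-radius Earth sphere.
# All distances in kilometres, all angles in radians internally,
# coordinates in decimal degrees at the interface.

#' Mean Earth radius (km) used throughout
#'
#' IUGG mean radius of the Earth sphere, 6371.0088 km. All great-circle
#' distances in the package are computed on this sphere.
#' @export
EARTH_RADIUS_KM <- 6371.0088

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.check_latlon <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    stop("non-finite coordinate")
  if (any(lat < -90 | lat > 90))
    stop("latitude out of range [-90, 90]")
  if (any(lon < -180 | lon >= 180))
    stop("longitude out of range [-180, 180)")
  invisible(TRUE)
}

#' Great-circle (haversine) distance
#'
#' Distance between two points on a sphere of radius
#' [EARTH_RADIUS_KM], by the haversine formula. Vectorised over
#' coordinates (recycled to a common length).
#'
#' @param lat1,lon1 first point, decimal degrees.
#' @param lat2,lon2 second point, decimal degrees.
#' @return distance in km.
#' @examples
#' gc_distance(0, 0, 0, 90)  # quarter circumference, ~10007.5 km
#' @export
gc_distance <- function(lat1, lon1, lat2, lon2) {
  phi1 <- .deg2rad(lat1); phi2 <- .deg2rad(lat2)
  dphi <- .deg2rad(lat2 - lat1)
  dlam <- .deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Initial bearing of the great circle from one point to another
#'
#' Forward azimuth at the first point, in radians in (-pi, pi],
#' measured clockwise from north.
#'
#' @inheritParams gc_distance
#' @return bearing in radians.
#' @export
initial_bearing <- function(lat1, lon1, lat2, lon2) {
  if (any(lat1 == lat2 & lon1 == lon2))
    stop("initial bearing undefined for identical points")
  phi1 <- .deg2rad(lat1); phi2 <- .deg2rad(lat2)
  dlam <- .deg2rad(lon2 - lon1)
  y <- sin(dlam) * cos(phi2)
  x <- cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dlam)
  atan2(y, x)
}

#' Signed cross-track distance from a point to a great-circle segment
#'
#' Perpendicular great-circle distance from `p` to the great circle
#' through `seg_start` and `seg_end`. The sign distinguishes the two
#' sides of the path (positive to the right of the direction of
#' travel).
#'
#' @param lat,lon the point, degrees.
#' @param lat1,lon1 segment start, degrees.
#' @param lat2,lon2 segment end, degrees.
#' @return signed distance in km.
#' @export
cross_track <- function(lat, lon, lat1, lon1, lat2, lon2) {
  d13 <- gc_distance(lat1, lon1, lat, lon)
  near_antipode <- abs(d13 - pi * EARTH_RADIUS_KM) < 1e-6
  if (any(near_antipode))
    stop("point antipodal to segment start: cross-track undefined")
  out <- numeric(length(d13))
  at_start <- d13 == 0
  if (any(!at_start)) {
    th13 <- initial_bearing(lat1, lon1, lat, lon)[!at_start]
    th12 <- initial_bearing(lat1, lon1, lat2, lon2)
    d <- d13[!at_start]
    out[!at_start] <- asin(sin(d / EARTH_RADIUS_KM) * sin(th13 - th12)) *
      EARTH_RADIUS_KM
  }
  out
}

#' Along-track distance of a point's projection onto a segment
#'
#' Distance from `seg_start` to the point on the great circle through
#' the segment that is nearest to `p`. Negative when the projection
#' falls behind the segment start.
#'
#' @inheritParams cross_track
#' @return along-track distance in km (signed).
#' @export
along_track <- function(lat, lon, lat1, lon1, lat2, lon2) {
  d13 <- gc_distance(lat1, lon1, lat, lon)
  dxt <- cross_track(lat, lon, lat1, lon1, lat2, lon2)
  ratio <- cos(d13 / EARTH_RADIUS_KM) / cos(dxt / EARTH_RADIUS_KM)
  ratio <- pmin(pmax(ratio, -1), 1)
  dat <- acos(ratio) * EARTH_RADIUS_KM
  # sign: projection behind the start iff the point lies in the back
  # half-plane of the start, i.e. |bearing difference| > pi/2
  behind <- rep(FALSE, length(dat))
  nz <- d13 > 0
  if (any(nz)) {
    th13 <- initial_bearing(lat1, lon1, lat, lon)[nz]
    th12 <- initial_bearing(lat1, lon1, lat2, lon2)
    dth <- (th13 - th12 + pi) %% (2 * pi) - pi
    behind[nz] <- abs(dth) > pi / 2
  }
  ifelse(behind, -dat, dat)
}

#' Destination point given start, bearing and distance
#'
#' Solves the direct problem on the sphere: the point reached by
#' travelling `dist_km` along the great circle leaving `p` with the
#' given initial bearing.
#'
#' @param lat,lon start point, degrees.
#' @param bearing initial bearing, radians clockwise from north.
#' @param dist_km distance to travel, km.
#' @return list with `lat` and `lon` (degrees, lon in [-180, 180)).
#' @export
dest_point <- function(lat, lon, bearing, dist_km) {
  phi1 <- .deg2rad(lat); lam1 <- .deg2rad(lon)
  delta <- dist_km / EARTH_RADIUS_KM
  phi2 <- asin(sin(phi1) * cos(delta) + cos(phi1) * sin(delta) * cos(bearing))
  lam2 <- lam1 + atan2(
    sin(bearing) * sin(delta) * cos(phi1),
    cos(delta) - sin(phi1) * sin(phi2)
  )
  lon2 <- (.rad2deg(lam2) + 180) %% 360 - 180
  list(lat = .rad2deg(phi2), lon = lon2)
}

#' Construct a transect
#'
#' A transect is an ordered sequence of waypoints joined by
#' great-circle segments, with a corridor half-width defining which
#' grid cells are close enough to be projected onto it.
#'
#' @param name transect label.
#' @param waypoints numeric matrix or data.frame with columns `lat`,
#'   `lon` (degrees), at least two rows; consecutive waypoints must be
#'   distinct.
#' @param corridor_km corridor half-width in km (default 450).
#' @return an object of class `transect` with precomputed segment
#'   lengths and cumulative distances.
#' @export
transect <- function(name, waypoints, corridor_km = 450) {
  wp <- as.matrix(waypoints)
  if (is.null(colnames(wp))) colnames(wp) <- c("lat", "lon")
  wp <- wp[, c("lat", "lon"), drop = FALSE]
  storage.mode(wp) <- "double"
  if (nrow(wp) < 2) stop("a transect needs at least two waypoints")
  .check_latlon(wp[, "lat"], wp[, "lon"])
  n <- nrow(wp)
  seg_len <- gc_distance(wp[-n, "lat"], wp[-n, "lon"],
                         wp[-1, "lat"], wp[-1, "lon"])
  if (any(seg_len == 0)) stop("consecutive waypoints must be distinct")
  if (!is.numeric(corridor_km) || corridor_km <= 0)
    stop("corridor_km must be positive")
  structure(
    list(name = as.character(name), waypoints = wp,
         corridor_km = corridor_km,
         seg_len = seg_len, cum_len = c(0, cumsum(seg_len))),
    class = "transect")
}

#' @export
print.transect <- function(x, ...) {
  cat("transect '", x$name, "': ", nrow(x$waypoints), " waypoints, ",
      sprintf("%.1f", transect_length(x)), " km, corridor +/- ",
      x$corridor_km, " km\n", sep = "")
  invisible(x)
}

#' Total length of a transect in km
#' @param t a [transect].
#' @export
transect_length <- function(t) sum(t$seg_len)

#' Read / write a transect as JSON
#'
#' The on-disk form is `{"name": str, "waypoints": [[lat, lon], ...],
#' "corridor_km": num}`.
#'
#' @param path file path.
#' @return `read_transect` returns a [transect].
#' @export
read_transect <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  wp <- matrix(as.numeric(t(x$waypoints)), ncol = 2, byrow = TRUE,
               dimnames = list(NULL, c("lat", "lon")))
  transect(x$name, wp, corridor_km = if (is.null(x$corridor_km)) 450 else x$corridor_km)
}

#' @rdname read_transect
#' @param t a [transect].
#' @export
write_transect <- function(t, path) {
  jsonlite::write_json(
    list(name = t$name,
         waypoints = lapply(seq_len(nrow(t$waypoints)),
                            function(i) as.numeric(t$waypoints[i, ])),
         corridor_km = t$corridor_km),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Project a single point onto a transect: nearest point on the path,
# considering perpendicular feet that fall inside a segment and the
# waypoints themselves (which are the nearest path points for points
# "off the corner" between segments or beyond the ends).
# Returns c(along_km, cross_km) where |cross_km| is the distance to the
# nearest path point and the sign is taken from the governing segment.
.project_point <- function(t, lat, lon) {
  wp <- t$waypoints
  nseg <- nrow(wp) - 1
  best_d <- Inf; best_along <- NA_real_; best_signed <- NA_real_
  for (s in seq_len(nseg)) {
    xt <- cross_track(lat, lon, wp[s, 1], wp[s, 2], wp[s + 1, 1], wp[s + 1, 2])
    at <- along_track(lat, lon, wp[s, 1], wp[s, 2], wp[s + 1, 1], wp[s + 1, 2])
    if (at >= 0 && at <= t$seg_len[s] && abs(xt) < best_d) {
      best_d <- abs(xt)
      best_along <- t$cum_len[s] + at
      best_signed <- xt
    }
  }
  # interior waypoints are the nearest path points for cells in the
  # wedge between two segments; points beyond the terminal waypoints
  # have no projection and are excluded (NA)
  if (nrow(wp) > 2) {
    interior <- 2:(nrow(wp) - 1)
    dw <- gc_distance(wp[interior, 1], wp[interior, 2], lat, lon)
    iw <- which.min(dw)
    if (dw[iw] < best_d) {
      best_d <- dw[iw]
      k <- interior[iw]
      best_along <- t$cum_len[k]
      xt <- cross_track(lat, lon, wp[k, 1], wp[k, 2], wp[k + 1, 1], wp[k + 1, 2])
      best_signed <- if (xt == 0) 0 else sign(xt) * best_d
    }
  }
  c(along = best_along, cross = best_signed)
}

#' Project grid cells onto a transect
#'
#' For every occupied grid cell with a defined allele-frequency
#' estimate at `locus`, computes the signed cross-track distance from
#' the cell centre to the transect path and the cumulative along-track
#' position of the nearest path point. Cells farther than the corridor
#' half-width are dropped.
#'
#' @param grid a [build_grid] result.
#' @param t a [transect].
#' @param locus one of `"A"`, `"B"`, `"C"`.
#' @return data.frame with columns `cell_lon_idx`, `cell_lat_idx`,
#'   `along_km`, `cross_km`, `n`, `qhat`, ordered by `along_km`.
#' @export
project_cells <- function(grid, t, locus = c("A", "B", "C")) {
  locus <- match.arg(locus)
  stopifnot(inherits(t, "transect"))
  cells <- grid$cells
  ncol_ <- paste0(locus, "_n")
  qcol <- paste0(locus, "_qhat")
  keep <- cells[[ncol_]] > 0
  cells <- cells[keep, , drop = FALSE]
  if (nrow(cells) == 0) stop("no cells scored at locus ", locus)
  proj <- t(vapply(seq_len(nrow(cells)), function(i)
    .project_point(t, cells$centre_lat[i], cells$centre_lon[i]),
    numeric(2)))
  inside <- !is.na(proj[, "cross"]) & abs(proj[, "cross"]) <= t$corridor_km
  if (!any(inside)) stop("no grid cells within the transect corridor")
  out <- data.frame(
    cell_lon_idx = cells$lon_idx[inside],
    cell_lat_idx = cells$lat_idx[inside],
    along_km = proj[inside, "along"],
    cross_km = proj[inside, "cross"],
    n = cells[[ncol_]][inside],
    qhat = cells[[qcol]][inside])
  out[order(out$along_km), , drop = FALSE]
}
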