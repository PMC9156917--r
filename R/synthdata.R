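# Synthetic record generator: georeferenced butterfly records with
# dominance-scored calls at three loci whose recessive allele
# frequencies follow known geographic clines, sampled with
# heterogeneous effort from a mixture of hotspots, from two record
# sources with source-dependent missingness, plus parametric
# environmental covariate surfaces. The generator provides ground
# truth for every downstream stage of the pipeline.

#' Synthetic world specification
#'
#' Defines the generating process for [sample_records()] and
#' [attach_environment()]. Defaults emulate the structure of a global
#' polymorphism survey: ~20 000 records, about a third from citizen
#' science, sampling effort concentrated in hotspots along an
#' east-west axis, three independent fully dominant loci with clinal
#' recessive-allele frequencies along a shared great-circle axis, and
#' half of the citizen records unscorable at the B locus (background
#' colour is not visible on photographed wing undersides).
#'
#' @param n_records number of records to draw.
#' @param loci named list (names `"A"`, `"B"`, `"C"`); each element a
#'   list with `axis` (a [transect] giving the cline axis), `params`
#'   (a [cline_params]), `spec` (a [cline_model_spec]) and
#'   `orientation` (`"increasing"` or `"decreasing"` recessive-allele
#'   frequency along the axis).
#' @param hotspots data.frame with columns `lat`, `lon`, `spread`
#'   (s.d. in degrees) and `weight`; record locations are drawn from
#'   this Gaussian mixture (no land/ocean mask).
#' @param source_mix fraction of citizen-science records.
#' @param b_missing_citizen probability that a citizen record's B call
#'   is missing.
#' @param env_model list with fields `bio01_intercept`,
#'   `bio01_lat_slope`, `bio01_sd` (annual mean temperature, degrees C,
#'   as a linear function of absolute latitude plus Gaussian noise),
#'   `bio20_slope`, `bio20_sd` (solar radiation, W m-2, linear in
#'   bio01), `bio12_intercept`, `bio12_lat_slope`, `bio12_sd` (annual
#'   precipitation, mm), and `bio28_cor` (target correlation of the
#'   soil moisture index with bio12).
#' @param seed RNG seed for [sample_records()].
#' @return object of class `world_spec`.
#' @export
world_spec <- function(n_records = 20000,
                       loci = default_world_loci(),
                       hotspots = default_world_hotspots(),
                       source_mix = 0.32,
                       b_missing_citizen = 0.5,
                       env_model = default_env_model(),
                       seed = 20220601) {
  stopifnot(n_records >= 1,
            source_mix >= 0, source_mix <= 1,
            b_missing_citizen >= 0, b_missing_citizen <= 1,
            all(hotspots$weight > 0), all(hotspots$spread > 0),
            identical(sort(names(loci)), c("A", "B", "C")))
  structure(list(n_records = as.integer(n_records), loci = loci,
                 hotspots = hotspots, source_mix = source_mix,
                 b_missing_citizen = b_missing_citizen,
                 env_model = env_model, seed = seed),
            class = "world_spec")
}

#' @rdname world_spec
#' @param axis shared cline axis for the three default loci.
#' @export
default_world_loci <- function(axis = transect("synthetic-axis",
                                               rbind(c(0, 10), c(0, 45)))) {
  list(
    A = list(axis = axis, params = cline_params(1000, 400),
             spec = cline_model_spec(), orientation = "increasing"),
    B = list(axis = axis, params = cline_params(1800, 800),
             spec = cline_model_spec(), orientation = "increasing"),
    C = list(axis = axis, params = cline_params(2500, 400),
             spec = cline_model_spec(), orientation = "increasing"))
}

#' @rdname world_spec
#' @export
default_world_hotspots <- function() {
  data.frame(lat = c(4, -3, 2, -6, 1),
             lon = c(12, 20, 28, 36, 43),
             spread = c(4, 4, 4, 4, 4),
             weight = c(1, 1.5, 1, 2, 1.5))
}

#' @rdname world_spec
#' @export
default_env_model <- function() {
  list(bio01_intercept = 30, bio01_lat_slope = -0.45, bio01_sd = 1,
       bio20_intercept = 180, bio20_slope = 2, bio20_sd = 5,
       bio12_intercept = 1400, bio12_lat_slope = -25, bio12_sd = 150,
       bio28_cor = 0.9)
}

#' True local recessive-allele frequency in a synthetic world
#'
#' Projects the point onto the locus's cline axis and evaluates the
#' cline at the along-axis position; points projecting beyond the axis
#' ends are clamped to the nearest end value.
#'
#' @param lat,lon location, degrees (vectorised).
#' @param world a [world_spec].
#' @param locus `"A"`, `"B"` or `"C"`.
#' @return frequency in \[0, 1\].
#' @export
local_allele_freq <- function(lat, lon, world, locus = c("A", "B", "C")) {
  locus <- match.arg(locus)
  lc <- world$loci[[locus]]
  ax <- lc$axis
  L <- transect_length(ax)
  wp <- ax$waypoints
  along <- vapply(seq_along(lat), function(i) {
    best <- Inf; best_along <- NA_real_
    for (s in seq_len(nrow(wp) - 1)) {
      at <- along_track(lat[i], lon[i], wp[s, 1], wp[s, 2],
                        wp[s + 1, 1], wp[s + 1, 2])
      at_cl <- min(max(at, 0), ax$seg_len[s])
      # distance from the point to its clamped projection foot
      foot_dist <- if (at >= 0 && at <= ax$seg_len[s]) {
        abs(cross_track(lat[i], lon[i], wp[s, 1], wp[s, 2],
                        wp[s + 1, 1], wp[s + 1, 2]))
      } else {
        k <- if (at < 0) s else s + 1
        gc_distance(wp[k, 1], wp[k, 2], lat[i], lon[i])
      }
      if (foot_dist < best) {
        best <- foot_dist
        best_along <- ax$cum_len[s] + at_cl
      }
    }
    best_along
  }, 0)
  q <- cline_value(along, lc$params, lc$spec)
  if (lc$orientation == "decreasing") q <- 1 - q
  q
}

#' Draw a synthetic record dataset
#'
#' Locations come from the hotspot Gaussian mixture (latitudes clamped
#' to bounds, longitudes wrapped). At each locus the genotype class is
#' drawn under Hardy-Weinberg equilibrium at the local recessive
#' allele frequency: recessive-homozygote with probability `q^2`, else
#' the dominant class. Citizen records lose their B call with
#' probability `b_missing_citizen`. Fully reproducible under the
#' world's seed.
#'
#' @param world a [world_spec].
#' @return a `colour_records` data.frame; the generating truth is kept
#'   in the `world` attribute.
#' @export
sample_records <- function(world) {
  set.seed(world$seed)
  n <- world$n_records
  hs <- world$hotspots
  comp <- sample.int(nrow(hs), n, replace = TRUE, prob = hs$weight)
  lat <- stats::rnorm(n, hs$lat[comp], hs$spread[comp])
  lon <- stats::rnorm(n, hs$lon[comp], hs$spread[comp])
  lat <- pmin(pmax(lat, -89.999), 89.999)
  lon <- (lon + 180) %% 360 - 180
  source <- ifelse(stats::runif(n) < world$source_mix, "citizen", "research")
  df <- data.frame(record_id = sprintf("syn%06d", seq_len(n)),
                   source = source,
                   date = NA_character_,
                   lat = lat, lon = lon,
                   stringsAsFactors = FALSE)
  for (locus in c("A", "B", "C")) {
    q <- local_allele_freq(lat, lon, world, locus)
    call <- ifelse(stats::runif(n) < q^2, "rec", "dom")
    if (locus == "B") {
      drop <- source == "citizen" &
        stats::runif(n) < world$b_missing_citizen
      call[drop] <- NA_character_
    }
    df[[paste0("locus", locus)]] <- call
  }
  out <- as_colour_records(df, provenance = "synthetic")
  attr(out, "world") <- world
  out
}

# Record-level covariate surfaces: linear functions of absolute
# latitude plus Gaussian noise, with bio20 constructed from bio01 and
# bio28 constructed to hit the target correlation with bio12 at the
# record level. Deterministic under the world's seed.
.synth_env_records <- function(ds, world) {
  set.seed(world$seed + 1L)
  em <- world$env_model
  n <- nrow(ds)
  bio01 <- em$bio01_intercept + em$bio01_lat_slope * abs(ds$lat) +
    stats::rnorm(n, 0, em$bio01_sd)
  bio20 <- em$bio20_intercept + em$bio20_slope * (bio01 - 25) +
    stats::rnorm(n, 0, em$bio20_sd)
  bio12 <- em$bio12_intercept + em$bio12_lat_slope * abs(ds$lat) +
    stats::rnorm(n, 0, em$bio12_sd)
  z12 <- (bio12 - mean(bio12)) / stats::sd(bio12)
  rho <- em$bio28_cor
  z28 <- rho * z12 + sqrt(1 - rho^2) * stats::rnorm(n)
  bio28 <- pmin(pmax(0.5 + 0.2 * z28, 0), 1)
  data.frame(bio01 = bio01, bio20 = bio20, bio12 = bio12, bio28 = bio28)
}

#' Attach synthetic environmental covariates to a frequency grid
#'
#' Covariate values are generated from the world's environmental model
#' at each record location and averaged per grid cell, mirroring how
#' raster covariates are extracted at record locations before cell
#' averaging. The response `y` is the per-cell dominant-class (dark
#' morph) genotype frequency at the chosen locus.
#'
#' @param ds the `colour_records` dataset the grid was built from.
#' @param grid the [build_grid()] result for `ds`.
#' @param world a [world_spec].
#' @param locus response locus (default `"B"`).
#' @param response `"dominant_class"` (default) or `"recessive_class"`.
#' @param min_n minimum scored records for a cell to be included.
#' @return data.frame with columns `lon_idx`, `lat_idx`, `y`,
#'   `n_records`, `bio01`, `bio20`, `bio12`, `bio28`, `centre_lon`,
#'   `centre_lat`.
#' @export
attach_environment <- function(ds, grid, world, locus = "B",
                               response = c("dominant_class",
                                            "recessive_class"),
                               min_n = 1) {
  response <- match.arg(response)
  ev <- .synth_env_records(ds, world)
  bio01 <- ev$bio01; bio20 <- ev$bio20
  bio12 <- ev$bio12; bio28 <- ev$bio28

  idx <- assign_cell(ds$lat, ds$lon, grid$spec)
  key <- paste(idx$lon_idx, idx$lat_idx, sep = ":")
  cells <- grid$cells
  ckey <- paste(cells$lon_idx, cells$lat_idx, sep = ":")
  g <- factor(key, levels = ckey)
  avg <- function(x) as.numeric(tapply(x, g, mean, default = NA_real_))
  ncol_ <- paste0(locus, "_n"); fcol <- paste0(locus, "_frec")
  y <- cells[[fcol]]
  if (response == "dominant_class") y <- 1 - y
  out <- data.frame(lon_idx = cells$lon_idx, lat_idx = cells$lat_idx,
                    y = y, n_records = cells[[ncol_]],
                    bio01 = avg(bio01), bio20 = avg(bio20),
                    bio12 = avg(bio12), bio28 = avg(bio28),
                    centre_lon = cells$centre_lon,
                    centre_lat = cells$centre_lat)
  out[out$n_records >= min_n & !is.na(out$y), , drop = FALSE]
}

.world_to_list <- function(world) {
  loci <- lapply(world$loci, function(lc) {
    list(axis = list(name = lc$axis$name,
                     waypoints = lapply(seq_len(nrow(lc$axis$waypoints)),
                                        function(i)
                                          as.numeric(lc$axis$waypoints[i, ])),
         corridor_km = lc$axis$corridor_km),
         params = unclass(lc$params),
         spec = list(scaling = lc$spec$scaling, tails = lc$spec$tails),
         orientation = lc$orientation)
  })
  list(n_records = world$n_records, loci = loci,
       hotspots = as.list(world$hotspots),
       source_mix = world$source_mix,
       b_missing_citizen = world$b_missing_citizen,
       env_model = world$env_model, seed = world$seed)
}

.world_from_list <- function(x) {
  loci <- lapply(x$loci, function(lc) {
    wp <- matrix(unlist(lc$axis$waypoints), ncol = 2, byrow = TRUE,
                 dimnames = list(NULL, c("lat", "lon")))
    list(axis = transect(lc$axis$name, wp,
                         corridor_km = lc$axis$corridor_km),
         params = do.call(cline_params, lc$params),
         spec = cline_model_spec(lc$spec$scaling, lc$spec$tails),
         orientation = lc$orientation)
  })
  world_spec(n_records = x$n_records, loci = loci,
             hotspots = as.data.frame(lapply(x$hotspots, unlist)),
             source_mix = x$source_mix,
             b_missing_citizen = x$b_missing_citizen,
             env_model = x$env_model, seed = x$seed)
}

#' Read / write a world specification (YAML or JSON by extension)
#'
#' Round-trips every generator parameter, including the per-locus
#' cline axes and parameters.
#'
#' @param path file path; a `.json` extension selects JSON, anything
#'   else YAML.
#' @export
read_world <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  .world_from_list(x)
}

#' @rdname read_world
#' @param world a [world_spec].
#' @export
write_world <- function(world, path) {
  x <- .world_to_list(world)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(x, path)
  invisible(path)
}
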