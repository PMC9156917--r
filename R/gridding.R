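# Aggregation of records into latitude/longitude grid cells and
# Hardy-Weinberg allele-frequency estimation from dominance-scored
# genotype classes.
#
# With full dominance only two genotype classes are observable: the
# homozygous recessive class (frequency q^2 under HWE at recessive
# allele frequency q) and the dominant class (heterozygote + dominant
# homozygote, frequency 1 - q^2). The per-cell estimator is therefore
# q_hat = sqrt(n_recessive / n_scored), with genotype counts pooled
# within the cell.

#' Grid specification
#'
#' Cells are half-open squares `[lo, lo + size)` in both axes, anchored
#' at (-180, -90). The analyses in this package use 4- or 2-degree
#' cells; any cell size that divides 360 evenly is accepted.
#'
#' @param cell_size cell edge in degrees.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(cell_size = 4) {
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("cell_size must be a positive number")
  if (abs(360 / cell_size - round(360 / cell_size)) > 1e-9)
    stop("cell_size must divide 360 evenly")
  structure(list(cell_size = cell_size, origin = c(lon = -180, lat = -90)),
            class = "grid_spec")
}

#' Map coordinates to grid-cell indices
#'
#' Index pair `(lon_idx, lat_idx)` with
#' `lon_idx = floor((lon + 180)/size)` and
#' `lat_idx = floor((lat + 90)/size)`; boundary points belong to the
#' higher cell (half-open convention). The north pole (lat 90) is
#' folded into the top row.
#'
#' @param lat,lon coordinates in degrees (vectorised).
#' @param spec a [grid_spec].
#' @return data.frame with columns `lon_idx`, `lat_idx` (0-based).
#' @export
assign_cell <- function(lat, lon, spec = grid_spec()) {
  .check_latlon(lat, lon)
  size <- spec$cell_size
  lon_idx <- floor((lon + 180) / size)
  lat_idx <- pmin(floor((lat + 90) / size), 180 / size - 1)
  data.frame(lon_idx = as.integer(lon_idx), lat_idx = as.integer(lat_idx))
}

.cell_centre <- function(lon_idx, lat_idx, spec) {
  size <- spec$cell_size
  list(lon = -180 + (lon_idx + 0.5) * size,
       lat = -90 + (lat_idx + 0.5) * size)
}

#' Build a per-cell frequency grid from a record dataset
#'
#' Groups records into grid cells and, for each occupied cell and
#' locus, counts scored records and recessive-class records, the
#' recessive genotype-class frequency `f_rec = n_rec / n_scored`, and
#' the HWE recessive allele frequency `q_hat = sqrt(f_rec)`. Cells
#' unscored at a locus carry `NA` frequencies there. Records missing at
#' all three loci still count towards cell occupancy totals.
#'
#' @param ds a `colour_records` data.frame.
#' @param spec a [grid_spec].
#' @return object of class `frequency_grid`: list with `spec` and
#'   `cells`, a data.frame with one row per occupied cell.
#' @export
build_grid <- function(ds, spec = grid_spec()) {
  if (nrow(ds) == 0) stop("empty dataset")
  idx <- assign_cell(ds$lat, ds$lon, spec)
  key <- paste(idx$lon_idx, idx$lat_idx, sep = ":")
  ukey <- sort(unique(key))
  g <- factor(key, levels = ukey)

  cells <- do.call(rbind, strsplit(ukey, ":", fixed = TRUE))
  cells <- data.frame(lon_idx = as.integer(cells[, 1]),
                      lat_idx = as.integer(cells[, 2]))
  ctr <- .cell_centre(cells$lon_idx, cells$lat_idx, spec)
  cells$centre_lon <- ctr$lon
  cells$centre_lat <- ctr$lat
  cells$n_total <- as.integer(table(g))
  cells$n_research <- as.integer(tapply(ds$source == "research", g, sum,
                                        default = 0))
  cells$n_citizen <- as.integer(tapply(ds$source == "citizen", g, sum,
                                       default = 0))
  for (locus in .LOCI) {
    call <- ds[[paste0("locus", locus)]]
    n <- as.integer(tapply(!is.na(call), g, sum, default = 0))
    nrec <- as.integer(tapply(!is.na(call) & call == "rec", g, sum,
                              default = 0))
    frec <- ifelse(n > 0, nrec / n, NA_real_)
    cells[[paste0(locus, "_n")]] <- n
    cells[[paste0(locus, "_nrec")]] <- nrec
    cells[[paste0(locus, "_frec")]] <- frec
    cells[[paste0(locus, "_qhat")]] <- sqrt(frec)
  }
  structure(list(spec = spec, cells = cells), class = "frequency_grid")
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat("frequency_grid: ", nrow(x$cells), " occupied ",
      x$spec$cell_size, "-degree cells, ",
      sum(x$cells$n_total), " records\n", sep = "")
  invisible(x)
}

#' Write / read a frequency grid as CSV
#'
#' One row per occupied cell with the columns of `grid$cells`.
#'
#' @param grid a `frequency_grid`.
#' @param path CSV file path.
#' @export
write_grid <- function(grid, path) {
  utils::write.csv(grid$cells, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_grid
#' @param cell_size cell size in degrees of the stored grid.
#' @export
read_grid <- function(path, cell_size = 4) {
  cells <- utils::read.csv(path)
  structure(list(spec = grid_spec(cell_size), cells = cells),
            class = "frequency_grid")
}

#' Classify a frequency as near-fixed, polymorphic or near-absent
#'
#' A frequency above 0.95 is classed `near_fixed`, one between 0.05 and
#' 0.95 inclusive `polymorphic`, and one below 0.05 `near_absent`.
#'
#' @param freq numeric vector of frequencies in \[0, 1\].
#' @param lo,hi class thresholds (defaults 0.05 and 0.95).
#' @return factor with levels `near_absent`, `polymorphic`,
#'   `near_fixed`.
#' @export
classify_fixation <- function(freq, lo = 0.05, hi = 0.95) {
  if (any(is.na(freq))) stop("undefined frequency")
  if (any(freq < 0 | freq > 1)) stop("frequency outside [0, 1]")
  stopifnot(0 < lo, lo < hi, hi < 1)
  factor(ifelse(freq > hi, "near_fixed",
                ifelse(freq >= lo, "polymorphic", "near_absent")),
         levels = c("near_absent", "polymorphic", "near_fixed"))
}

#' Percentage of grid cells in each fixation class at a locus
#'
#' Classifies the chosen per-cell frequency at one locus over all cells
#' with at least `min_n` scored records there, and reports the
#' percentage of those cells in each class.
#'
#' @param grid a `frequency_grid`.
#' @param locus `"A"`, `"B"` or `"C"`.
#' @param min_n minimum scored records for a cell to enter the
#'   denominator (default 1).
#' @param freq which frequency to classify: the recessive genotype
#'   class (`"recessive_class"`, default), the dominant class
#'   (`"dominant_class"` = 1 - f_rec), the recessive allele (`"q_hat"`)
#'   or the dominant allele (`"p_hat"` = 1 - q_hat).
#' @inheritParams classify_fixation
#' @return list with `percent` (named numeric, sums to 100),
#'   `n_cells`, and the per-cell classification.
#' @export
fixation_summary <- function(grid, locus = c("A", "B", "C"), min_n = 1,
                             freq = c("recessive_class", "dominant_class",
                                      "q_hat", "p_hat"),
                             lo = 0.05, hi = 0.95) {
  locus <- match.arg(locus)
  freq <- match.arg(freq)
  stopifnot(min_n >= 1)
  cells <- grid$cells
  keep <- cells[[paste0(locus, "_n")]] >= min_n
  if (!any(keep)) stop("no cell with n_scored >= min_n at locus ", locus)
  f <- cells[[paste0(locus, "_frec")]][keep]
  f <- switch(freq,
              recessive_class = f,
              dominant_class = 1 - f,
              q_hat = sqrt(f),
              p_hat = 1 - sqrt(f))
  cls <- classify_fixation(f, lo = lo, hi = hi)
  pct <- 100 * table(cls) / length(cls)
  list(percent = c(pct), n_cells = length(cls), class = cls,
       locus = locus, freq = freq)
}

#' Regression concordance of genotype frequencies between two sources
#'
#' Ordinary least-squares regression of the per-cell recessive
#' genotype-class frequency in one grid (e.g. citizen-science records)
#' on the same quantity in another (e.g. research records), over cells
#' scored in both.
#'
#' @param grid_x predictor grid (research).
#' @param grid_y response grid (citizen).
#' @param locus `"A"`, `"B"` or `"C"`.
#' @param min_n minimum scored records per cell in each grid.
#' @return list with `slope`, `intercept`, `r_squared`, `p`, `n_cells`.
#' @export
source_concordance <- function(grid_x, grid_y, locus = c("A", "B", "C"),
                               min_n = 1) {
  locus <- match.arg(locus)
  ncol_ <- paste0(locus, "_n"); fcol <- paste0(locus, "_frec")
  x <- grid_x$cells[grid_x$cells[[ncol_]] >= min_n,
                    c("lon_idx", "lat_idx", fcol)]
  y <- grid_y$cells[grid_y$cells[[ncol_]] >= min_n,
                    c("lon_idx", "lat_idx", fcol)]
  m <- merge(x, y, by = c("lon_idx", "lat_idx"))
  if (nrow(m) < 3) stop("fewer than 3 cells scored in both grids")
  fx <- m[[paste0(fcol, ".x")]]; fy <- m[[paste0(fcol, ".y")]]
  fit <- stats::lm(fy ~ fx)
  s <- suppressWarnings(summary(fit))  # perfect fits are legitimate here
  pval <- if (s$sigma == 0) 0 else stats::pf(s$fstatistic[1], s$fstatistic[2],
                                             s$fstatistic[3], lower.tail = FALSE)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       p = unname(pval),
       n_cells = nrow(m))
}
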