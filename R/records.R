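# Occurrence records with dominance-scored phenotype-class calls.
#
# Each record is one georeferenced butterfly with, at each of the three
# colour-pattern loci (A: hindwing white, B: background colour,
# C: forewing tip), a call of "rec" (homozygous recessive class),
# "dom" (dominant class: heterozygote or dominant homozygote, which are
# phenotypically indistinguishable) or NA (not scorable).

.LOCI <- c("A", "B", "C")
.LOCUS_COLS <- c("locusA", "locusB", "locusC")
.SOURCES <- c("research", "citizen")
.RECORD_COLS <- c("record_id", "source", "date", "lat", "lon",
                  "locusA", "locusB", "locusC")

.new_records <- function(df, provenance = character()) {
  rownames(df) <- NULL
  structure(df, class = c("colour_records", "data.frame"),
            provenance = provenance)
}

#' Assemble a validated record dataset from a data.frame
#'
#' Validates each row (coordinate bounds, source and locus-call
#' vocabulary, unique record ids) and returns the valid rows as a
#' `colour_records` data.frame. Invalid rows are dropped and reported
#' in the `rejected` attribute with row numbers and reasons.
#' Longitudes of exactly 180 are normalised to -180.
#'
#' @param df data.frame with columns `record_id`, `source`, `date`,
#'   `lat`, `lon`, `locusA`, `locusB`, `locusC`. Locus calls are
#'   `"rec"`, `"dom"`, or missing (`NA` or `""`); `source` is
#'   `"research"` or `"citizen"`; `date` is free-form and unused by any
#'   computation.
#' @param provenance free-text metadata attached to the dataset.
#' @return a `colour_records` data.frame; attribute `rejected` is a
#'   data.frame with columns `row` and `reason` (empty if all rows
#'   valid).
#' @export
as_colour_records <- function(df, provenance = character()) {
  missing_cols <- setdiff(.RECORD_COLS, names(df))
  if (length(missing_cols) > 0)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, .RECORD_COLS]
  df$record_id <- as.character(df$record_id)
  df$source <- as.character(df$source)
  df$date <- as.character(df$date)
  df$lat <- suppressWarnings(as.numeric(df$lat))
  df$lon <- suppressWarnings(as.numeric(df$lon))
  for (col in .LOCUS_COLS) {
    v <- as.character(df[[col]])
    v[!is.na(v) & v == ""] <- NA_character_
    v[!is.na(v) & v == "NA"] <- NA_character_
    df[[col]] <- v
  }
  df$lon[!is.na(df$lon) & df$lon == 180] <- -180

  reasons <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) {
    new <- bad & is.na(reasons)
    reasons[new] <<- why
  }
  flag(is.na(df$lat), "unparseable latitude")
  flag(is.na(df$lon), "unparseable longitude")
  flag(!is.na(df$lat) & (df$lat < -90 | df$lat > 90), "latitude out of range")
  flag(!is.na(df$lon) & (df$lon < -180 | df$lon >= 180), "longitude out of range")
  flag(!(df$source %in% .SOURCES), "unknown source")
  for (col in .LOCUS_COLS)
    flag(!is.na(df[[col]]) & !(df[[col]] %in% c("rec", "dom")),
         paste0("invalid ", col, " call"))
  flag(is.na(df$record_id) | df$record_id == "", "missing record_id")
  flag(duplicated(df$record_id), "duplicate record_id")

  bad <- !is.na(reasons)
  rejected <- data.frame(row = which(bad), reason = reasons[bad],
                         stringsAsFactors = FALSE)
  if (nrow(rejected) > 0)
    message(nrow(rejected), " row(s) rejected during validation")
  out <- .new_records(df[!bad, , drop = FALSE], provenance)
  attr(out, "rejected") <- rejected
  out
}

#' Read occurrence records from CSV
#'
#' Reads the record CSV dialect (columns
#' `record_id,source,date,lat,lon,locusA,locusB,locusC`; locus fields
#' in `{rec, dom, NA}`; `NA` or empty meaning missing) and validates
#' every row via [as_colour_records()].
#'
#' @param path CSV file path.
#' @return a `colour_records` data.frame.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = c("NA", ""), fileEncoding = "UTF-8")
  as_colour_records(df, provenance = paste0("read from ", path))
}

#' @rdname read_records
#' @param ds a `colour_records` data.frame.
#' @export
write_records <- function(ds, path) {
  out <- as.data.frame(ds)[, .RECORD_COLS]
  # 17 significant digits so coordinates round-trip bit-identically
  out$lat <- formatC(out$lat, digits = 17, format = "g")
  out$lon <- formatC(out$lon, digits = 17, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.colour_records <- function(x, ...) {
  cat("colour_records: ", nrow(x), " records (",
      sum(x$source == "research"), " research, ",
      sum(x$source == "citizen"), " citizen)\n", sep = "")
  NextMethod()
}

#' Per-source record counts and per-locus scored counts
#'
#' @param ds a `colour_records` data.frame.
#' @return data.frame with one row per source plus a `total` row and
#'   columns `n_records`, `A_scored`, `B_scored`, `C_scored`.
#' @export
summarize_sources <- function(ds) {
  stopifnot(nrow(ds) > 0)
  one <- function(sub) {
    c(n_records = nrow(sub),
      A_scored = sum(!is.na(sub$locusA)),
      B_scored = sum(!is.na(sub$locusB)),
      C_scored = sum(!is.na(sub$locusC)))
  }
  rows <- rbind(
    research = one(ds[ds$source == "research", , drop = FALSE]),
    citizen = one(ds[ds$source == "citizen", , drop = FALSE]),
    total = one(ds))
  data.frame(source = rownames(rows), rows, row.names = NULL)
}
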