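#' Default column schema for sample tables
#'
#' Maps the fields a sample table must provide to CSV column names.
#' @return named character vector.
#' @export
sample_schema <- function() {
  c(sample_id = "sample_id", longitude = "longitude_dd",
    latitude = "latitude_dd", sr_ratio = "sr87_sr86",
    sample_type = "sample_type", source = "source", reference = "reference")
}

#' Read a georeferenced table of bioavailable 87Sr/86Sr measurements
#'
#' Rows with unparseable coordinates or isotope ratios, or with coordinates
#' outside valid lon/lat ranges, are excluded and reported in the
#' `"rejections"` attribute rather than silently dropped. Ratios outside the
#' plausible bioavailable range (0.70, 0.90) raise a warning but are kept.
#'
#' @param path CSV file path.
#' @param schema named map from canonical field names to the file's column
#'   names; see [sample_schema()]. `sample_id`, `longitude`, `latitude` and
#'   `sr_ratio` are mandatory, the rest optional.
#' @return a `data.frame` of class `sr_samples` with columns `sample_id`,
#'   `longitude`, `latitude`, `sr_ratio`, `sample_type`, `source`,
#'   `reference` and attribute `rejections` (a data.frame of row, reason).
#' @export
read_samples <- function(path, schema = sample_schema()) {
  if (!file.exists(path)) stop("sample file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  mandatory <- c("sample_id", "longitude", "latitude", "sr_ratio")
  missing_cols <- setdiff(schema[mandatory], names(raw))
  if (length(missing_cols) > 0)
    stop("configuration error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(raw) == 0) stop("input error: sample table is empty", call. = FALSE)
  get <- function(field, default = NA_character_) {
    col <- schema[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]]
    else rep(default, nrow(raw))
  }
  out <- data.frame(
    sample_id = as.character(get("sample_id")),
    longitude = suppressWarnings(as.numeric(get("longitude"))),
    latitude = suppressWarnings(as.numeric(get("latitude"))),
    sr_ratio = suppressWarnings(as.numeric(get("sr_ratio"))),
    sample_type = as.character(get("sample_type", "other")),
    source = as.character(get("source", "new")),
    reference = as.character(get("reference", "")),
    stringsAsFactors = FALSE)
  reasons <- character(nrow(out))
  bad_num <- is.na(out$longitude) | is.na(out$latitude) | is.na(out$sr_ratio)
  reasons[bad_num] <- "unparseable coordinate or ratio"
  bad_rng <- !bad_num & (abs(out$latitude) > 90 | abs(out$longitude) > 180)
  reasons[bad_rng] <- "coordinate outside valid lon/lat range"
  keep <- reasons == ""
  rejections <- data.frame(row = which(!keep), reason = reasons[!keep],
                           stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0)
    stop("input error: no valid rows after parsing", call. = FALSE)
  odd <- out$sr_ratio <= 0.70 | out$sr_ratio >= 0.90
  if (any(odd))
    warning(sum(odd), " sample(s) with 87Sr/86Sr outside (0.70, 0.90)",
            call. = FALSE)
  class(out) <- c("sr_samples", "data.frame")
  attr(out, "rejections") <- rejections
  out
}

#' Descriptive statistics of a sample table
#'
#' The summary reported for combined bioavailable Sr datasets: range, mean,
#' standard deviation and quartiles of the isotope ratios plus counts by
#' provenance and sample type.
#'
#' @param samples an `sr_samples` table (or any data.frame with the same
#'   columns).
#' @return a list with elements `n`, `n_by_source`, `n_by_type`, `min`,
#'   `max`, `mean`, `sd`, `q1`, `q3`.
#' @export
summarize_samples <- function(samples) {
  r <- samples$sr_ratio
  q <- stats::quantile(r, c(0.25, 0.75), names = FALSE)
  list(n = length(r),
       n_by_source = table(samples$source),
       n_by_type = table(samples$sample_type),
       min = min(r), max = max(r),
       mean = mean(r), sd = stats::sd(r),
       q1 = q[1], q3 = q[2])
}

#' @export
print.sr_samples <- function(x, ...) {
  s <- summarize_samples(x)
  cat(sprintf("sr_samples: %d records, 87Sr/86Sr in [%.5f, %.5f], mean %.5f (sd %.5f)\n",
              s$n, s$min, s$max, s$mean, s$sd))
  rej <- attr(x, "rejections")
  if (!is.null(rej) && nrow(rej) > 0)
    cat(sprintf("  %d rejected row(s) on read; see attr(x, 'rejections')\n",
                nrow(rej)))
  NextMethod()
}

#' Write a sample table to CSV using the default schema
#'
#' @param samples an `sr_samples` table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  out <- data.frame(sample_id = samples$sample_id,
                    longitude_dd = samples$longitude,
                    latitude_dd = samples$latitude,
                    sr87_sr86 = samples$sr_ratio,
                    sample_type = samples$sample_type,
                    source = samples$source,
                    reference = samples$reference)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
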