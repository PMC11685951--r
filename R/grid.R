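#' Grid specification for a regular raster
#'
#' Describes a regular, north-up grid by its lower-left corner, cell size and
#' dimensions. Cells are addressed row-major from the north-west corner
#' (row 1 = northernmost row). Point-in-cell assignment uses half-open cell
#' intervals with the west and north edges inclusive, so every point in the
#' grid extent belongs to exactly one cell.
#'
#' @param n_rows,n_cols grid dimensions (positive integers).
#' @param xll,yll coordinates of the lower-left (south-west) corner of the
#'   grid extent, in CRS units (decimal degrees for lon/lat grids).
#' @param cellsize cell edge length in CRS units (square cells).
#' @param crs coordinate reference system identifier; `"EPSG:4326"` marks a
#'   geographic lon/lat grid, anything else is treated as projected.
#' @param nodata sentinel written to raster files for missing cells. In
#'   memory missing cells are always `NA`.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, xll, yll, cellsize,
                      crs = "EPSG:4326", nodata = -9999) {
  stopifnot(n_rows >= 1, n_cols >= 1, cellsize > 0, is.finite(xll),
            is.finite(yll))
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 xll = xll, yll = yll, cellsize = cellsize,
                 crs = crs, nodata = nodata),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells, cellsize %g, origin (%g, %g), %s\n",
              x$n_rows, x$n_cols, x$cellsize, x$xll, x$yll, x$crs))
  invisible(x)
}

spec_equal <- function(a, b, tol = 1e-9) {
  isTRUE(a$n_rows == b$n_rows) && isTRUE(a$n_cols == b$n_cols) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol && identical(a$crs, b$crs)
}

is_lonlat <- function(spec) {
  grepl("4326|WGS84|lonlat|longlat", spec$crs, ignore.case = TRUE)
}

#' Single-band grid
#'
#' A numeric matrix (`n_rows` x `n_cols`, row 1 northernmost) bound to a
#' [grid_spec()]. Missing cells are `NA`.
#'
#' @param values numeric matrix of dimension `n_rows` x `n_cols`.
#' @param spec a [grid_spec()].
#' @return an object of class `sr_grid`.
#' @export
sr_grid <- function(values, spec) {
  values <- as.matrix(values)
  if (!identical(dim(values), c(spec$n_rows, spec$n_cols)))
    stop("grid values do not match spec dimensions", call. = FALSE)
  structure(list(values = values, spec = spec), class = "sr_grid")
}

#' @export
print.sr_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("sr_grid: %d x %d, %d NA cells, range [%s, %s]\n",
              nrow(v), ncol(v), sum(is.na(v)),
              format(suppressWarnings(min(v, na.rm = TRUE))),
              format(suppressWarnings(max(v, na.rm = TRUE)))))
  invisible(x)
}

# Row (from north) and column of points; NA outside the extent.
# West/north edges inclusive, east/south exclusive (half-open cells).
cell_rowcol <- function(spec, x, y) {
  ytop <- spec$yll + spec$n_rows * spec$cellsize
  col <- floor((x - spec$xll) / spec$cellsize) + 1L
  row <- floor((ytop - y) / spec$cellsize) + 1L
  row[y == ytop] <- 1L  # north edge of the grid belongs to row 1
  bad <- col < 1L | col > spec$n_cols | row < 1L | row > spec$n_rows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = row, col = col)
}

# Cell-center coordinates for row-major cell addressing.
cell_centers <- function(spec, row, col) {
  ytop <- spec$yll + spec$n_rows * spec$cellsize
  cbind(x = spec$xll + (col - 0.5) * spec$cellsize,
        y = ytop - (row - 0.5) * spec$cellsize)
}

# Row-major linear index from (row, col).
cell_index <- function(spec, row, col) (row - 1L) * spec$n_cols + col

index_rowcol <- function(spec, idx) {
  cbind(row = (idx - 1L) %/% spec$n_cols + 1L,
        col = (idx - 1L) %% spec$n_cols + 1L)
}

# Distance between point (x0, y0) and a matrix of points; great-circle metres
# on lon/lat grids, Euclidean CRS units otherwise.
point_distances <- function(spec, x0, y0, pts) {
  if (is_lonlat(spec)) {
    geosphere::distHaversine(c(x0, y0), pts)
  } else {
    sqrt((pts[, 1] - x0)^2 + (pts[, 2] - y0)^2)
  }
}

#' Write a grid as an ESRI ASCII raster
#'
#' The payload is written in `%.17g` so that `double` values round-trip
#' bit-exactly. Grid metadata that the ASCII header cannot carry (CRS,
#' layer kind) goes to a JSON sidecar `<path>.aux.json`.
#'
#' @param grid an [sr_grid()].
#' @param path output file path (conventionally `.asc`).
#' @param kind `"continuous"` or `"categorical"`; stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, kind = "continuous") {
  spec <- grid$spec
  v <- grid$values
  v[is.na(v)] <- spec$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("NCOLS %d", spec$n_cols),
               sprintf("NROWS %d", spec$n_rows),
               sprintf("XLLCORNER %.17g", spec$xll),
               sprintf("YLLCORNER %.17g", spec$yll),
               sprintf("CELLSIZE %.17g", spec$cellsize),
               sprintf("NODATA_VALUE %.17g", spec$nodata)), con)
  for (r in seq_len(spec$n_rows))
    writeLines(paste(sprintf("%.17g", v[r, ]), collapse = " "), con)
  jsonlite::write_json(list(crs = spec$crs, kind = kind),
                       paste0(path, ".aux.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path file written by [write_ascii_grid()] (or any ESRI ASCII grid;
#'   a missing sidecar defaults to WGS84 lon/lat, continuous).
#' @return an [sr_grid()]; the layer kind is attached as attribute `"kind"`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    kv <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[toupper(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("NCOLS", "NROWS", "XLLCORNER", "YLLCORNER", "CELLSIZE")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  nodata <- if (!is.null(hdr$NODATA_VALUE)) hdr$NODATA_VALUE else -9999
  vals <- scan(path, skip = 6L, quiet = TRUE)
  nr <- as.integer(hdr$NROWS); nc <- as.integer(hdr$NCOLS)
  if (length(vals) != nr * nc)
    stop("ASCII grid payload size mismatch in ", path, call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  crs <- "EPSG:4326"; kind <- "continuous"
  aux <- paste0(path, ".aux.json")
  if (file.exists(aux)) {
    meta <- jsonlite::read_json(aux)
    if (!is.null(meta$crs)) crs <- meta$crs
    if (!is.null(meta$kind)) kind <- meta$kind
  }
  g <- sr_grid(m, grid_spec(nr, nc, hdr$XLLCORNER, hdr$YLLCORNER,
                            hdr$CELLSIZE, crs = crs, nodata = nodata))
  attr(g, "kind") <- kind
  g
}

#' Bundle aligned predictor layers
#'
#' @param layers named list of [sr_grid()] sharing one [grid_spec()].
#' @param kinds character vector (`"continuous"`/`"categorical"`), one per
#'   layer, recycled names from `layers` if unnamed.
#' @return object of class `predictor_stack`.
#' @export
predictor_stack <- function(layers, kinds) {
  if (is.null(names(layers)) || any(names(layers) == ""))
    stop("all layers must be named", call. = FALSE)
  spec <- layers[[1]]$spec
  for (nm in names(layers)) {
    if (!spec_equal(layers[[nm]]$spec, spec))
      stop("alignment error: layer '", nm,
           "' does not share the stack's grid", call. = FALSE)
  }
  kinds <- rep_len(kinds, length(layers))
  if (!all(kinds %in% c("continuous", "categorical")))
    stop("kinds must be 'continuous' or 'categorical'", call. = FALSE)
  names(kinds) <- names(layers)
  for (nm in names(layers)[kinds == "categorical"]) {
    v <- layers[[nm]]$values
    if (any(v[!is.na(v)] != round(v[!is.na(v)])))
      stop("categorical layer '", nm, "' holds non-integer codes",
           call. = FALSE)
  }
  structure(list(layers = layers, kinds = kinds, spec = spec),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("predictor_stack: %d layers on a %d x %d grid\n",
              length(x$layers), x$spec$n_rows, x$spec$n_cols))
  for (nm in names(x$layers))
    cat(sprintf("  %-24s %s\n", nm, x$kinds[[nm]]))
  invisible(x)
}

#' Write every layer of a stack to a directory
#'
#' One `<name>.asc` (plus sidecar) per layer.
#' @param stack a [predictor_stack()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(stack$layers))
    write_ascii_grid(stack$layers[[nm]], file.path(dir, paste0(nm, ".asc")),
                     kind = stack$kinds[[nm]])
  invisible(dir)
}

#' Read all `.asc` layers in a directory as a stack
#'
#' @param dir directory holding `*.asc` files written by [write_stack()].
#' @return a [predictor_stack()].
#' @export
read_stack <- function(dir) {
  if (!dir.exists(dir))
    stop("configuration error: predictor directory not found: ", dir,
         call. = FALSE)
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  if (length(files) == 0)
    stop("no .asc layers found in ", dir, call. = FALSE)
  layers <- list(); kinds <- character()
  for (f in files) {
    g <- read_ascii_grid(f)
    nm <- sub("\\.asc$", "", basename(f))
    layers[[nm]] <- g
    kinds[nm] <- attr(g, "kind")
  }
  predictor_stack(layers, kinds)
}

# Flatten a stack to a cells x layers data.frame in row-major cell order.
stack_table <- function(stack) {
  out <- lapply(stack$layers, function(g) as.vector(t(g$values)))
  as.data.frame(out, optional = TRUE)
}

# Build an sr_grid from a row-major cell vector.
grid_from_vector <- function(v, spec) {
  sr_grid(matrix(v, nrow = spec$n_rows, ncol = spec$n_cols, byrow = TRUE),
          spec)
}
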