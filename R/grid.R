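#' Define a raster grid
#'
#' A grid describes the common georeferencing of all layers in an analysis:
#' dimensions, square cell size (km), the outer corner of the top-left cell,
#' and a validity mask. All layers in a stack must share one grid; operations
#' across layers on different grids are refused.
#'
#' The coordinate convention is row-major with the origin at the top-left:
#' cell (row, col) (1-based) has its centre at
#' `origin + ((col - 0.5) * cell_size, -(row - 0.5) * cell_size)`.
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param cell_size cell edge length in km (> 0). Default 1 km, the working
#'   resolution of the analysis (matching the ~1 km2 satellite hotspot
#'   footprint).
#' @param origin numeric length-2, (x, y) of the outer corner of the top-left
#'   cell, in km; default `c(0, n_rows * cell_size)`, placing the lower-left
#'   corner of the grid at (0, 0).
#' @param mask logical matrix `n_rows x n_cols`; `TRUE` marks valid cells.
#'   Default all valid.
#' @return an object of class `fire_grid`.
#' @export
fire_grid <- function(n_rows, n_cols, cell_size = 1, origin = NULL,
                      mask = NULL) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.null(origin)) origin <- c(0, n_rows * cell_size)
  stopifnot(n_rows >= 1L, n_cols >= 1L, cell_size > 0, length(origin) == 2L)
  if (is.null(mask)) mask <- matrix(TRUE, n_rows, n_cols)
  if (!is.logical(mask) || !all(dim(mask) == c(n_rows, n_cols)))
    stop("mask must be a logical n_rows x n_cols matrix")
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin), mask = mask),
            class = "fire_grid")
}

#' @export
print.fire_grid <- function(x, ...) {
  cat(sprintf("<fire_grid> %d x %d cells, %.3g km cell size, %d masked\n",
              x$n_rows, x$n_cols, x$cell_size, sum(!x$mask)))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Cell-centre coordinates
#'
#' @param grid a `fire_grid`.
#' @param cells integer cell indices (column-major over the value matrix);
#'   default all cells.
#' @return two-column matrix of (x, y) in km.
#' @export
cell_centers <- function(grid, cells = seq_len(n_cells(grid))) {
  row <- (cells - 1L) %% grid$n_rows + 1L
  col <- (cells - 1L) %/% grid$n_rows + 1L
  cbind(x = grid$origin[1] + (col - 0.5) * grid$cell_size,
        y = grid$origin[2] - (row - 0.5) * grid$cell_size)
}

#' Test whether two grids are the same georeferencing
#' @param a,b `fire_grid` objects.
#' @param tol relative tolerance on cell size and origin.
#' @export
same_grid <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$cell_size - b$cell_size) <= tol * max(1, a$cell_size) &&
    all(abs(a$origin - b$origin) <= tol * max(1, abs(a$origin), abs(b$origin))) &&
    identical(a$mask, b$mask)
}

stop_grid_mismatch <- function(what = "layers") {
  stop(sprintf("grid mismatch: %s must share the same grid", what),
       call. = FALSE)
}

#' Create a raster layer
#'
#' A layer carries one value per grid cell plus metadata. Masked cells hold
#' `NA`; operations propagate the mask (no silent zeros).
#'
#' @param grid a `fire_grid`.
#' @param values numeric matrix (or vector recycled to the grid shape).
#'   Categorical layers use non-negative integer codes.
#' @param name layer identifier.
#' @param kind `"continuous"` or `"categorical"`.
#' @param codes for categorical layers, the declared integer codes; default
#'   the sorted unique unmasked values.
#' @param units free-text unit string kept as metadata.
#' @return an object of class `fire_layer`.
#' @export
fire_layer <- function(grid, values, name = "layer",
                       kind = c("continuous", "categorical"),
                       codes = NULL, units = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "fire_grid"))
  if (!is.matrix(values)) values <- matrix(values, grid$n_rows, grid$n_cols)
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols)))
    stop("values shape does not match grid")
  values[!grid$mask] <- NA_real_
  v <- values[grid$mask]
  if (any(!is.finite(v)))
    stop("non-finite values on unmasked cells in layer '", name, "'")
  if (kind == "categorical") {
    if (any(v < 0) || any(v != round(v)))
      stop("categorical layer values must be non-negative integer codes")
    if (is.null(codes)) codes <- sort(unique(as.integer(v)))
    if (!all(as.integer(v) %in% codes))
      stop("categorical layer contains undeclared codes")
  }
  structure(list(grid = grid, name = name, kind = kind,
                 values = values, codes = codes, units = units),
            class = "fire_layer")
}

#' @export
print.fire_layer <- function(x, ...) {
  v <- x$values[x$grid$mask]
  cat(sprintf("<fire_layer> '%s' (%s) %d x %d", x$name, x$kind,
              x$grid$n_rows, x$grid$n_cols))
  if (x$kind == "continuous")
    cat(sprintf("  range [%.4g, %.4g]", min(v), max(v)))
  else cat(sprintf("  codes {%s}", paste(x$codes, collapse = ",")))
  cat("\n"); invisible(x)
}

layer_values <- function(layer, cells = NULL) {
  if (is.null(cells)) layer$values else layer$values[cells]
}

#' Stack layers on a shared grid
#'
#' @param ... `fire_layer` objects (or a single list of them).
#' @return an object of class `fire_stack` (named list of layers + grid).
#' @export
fire_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && !inherits(layers[[1]], "fire_layer"))
    layers <- layers[[1]]
  stopifnot(length(layers) >= 1L,
            all(vapply(layers, inherits, TRUE, "fire_layer")))
  grid <- layers[[1]]$grid
  for (l in layers) if (!same_grid(grid, l$grid)) stop_grid_mismatch()
  nm <- vapply(layers, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("layer names must be unique")
  names(layers) <- nm
  structure(list(grid = grid, layers = layers), class = "fire_stack")
}

#' @export
print.fire_stack <- function(x, ...) {
  cat(sprintf("<fire_stack> %d layers on %d x %d grid: %s\n",
              length(x$layers), x$grid$n_rows, x$grid$n_cols,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' @export
names.fire_stack <- function(x) names(x$layers)

#' @export
`[[.fire_stack` <- function(x, i) x$layers[[i]]

stack_replace <- function(stack, name, layer) {
  if (!same_grid(stack$grid, layer$grid)) stop_grid_mismatch()
  layer$name <- name
  stack$layers[[name]] <- layer
  stack
}

# matrix of raw variable values: cells x variables
stack_values <- function(stack, vars = names(stack$layers), cells = NULL) {
  out <- vapply(vars, function(v) {
    l <- stack$layers[[v]]
    if (is.null(l)) stop("missing variable in stack: ", v)
    as.numeric(if (is.null(cells)) l$values else l$values[cells])
  }, numeric(if (is.null(cells)) n_cells(stack$grid) else length(cells)))
  if (!is.matrix(out)) out <- matrix(out, ncol = length(vars),
                                     dimnames = list(NULL, vars))
  out
}

#' Read a raster layer from disk
#'
#' Supports the ESRI ASCII grid format (plain-text header + row-major values,
#' top row first). Nodata sentinel cells become masked cells.
#'
#' @param path file path.
#' @param format raster format; only `"ascii_grid"` is available.
#' @param name,kind,codes,units passed to [fire_layer()].
#' @return a `fire_layer`.
#' @export
read_raster <- function(path, format = c("ascii_grid", "geotiff"),
                        name = NULL, kind = "continuous", codes = NULL,
                        units = NULL) {
  format <- match.arg(format)
  if (format == "geotiff")
    stop("GeoTIFF I/O is not available in this build; use format 'ascii_grid'")
  if (!file.exists(path)) stop("cannot read raster: no such file: ", path)
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  repeat {
    pos <- seek(con)
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("malformed ASCII grid (no data rows): ", path)
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 2L && grepl("^[A-Za-z_]+$", tok[1])) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
    } else { seek(con, pos); break }
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header missing fields (", paste(need, collapse = ", "),
         "): ", path)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(con, what = numeric(), quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("ASCII grid has %d values, expected %d: %s",
                 length(vals), nr * nc, path))
  m <- matrix(vals, nr, nc, byrow = TRUE)   # file is row-major, top first
  mask <- is.finite(m) & m != nodata
  m[!mask] <- NA_real_
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0
  grid <- fire_grid(nr, nc, hdr$cellsize,
                    origin = c(xll, yll + nr * hdr$cellsize), mask = mask)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  fire_layer(grid, m, name = name, kind = kind, codes = codes, units = units)
}

#' Write a raster layer to disk
#'
#' @param layer a `fire_layer`.
#' @param path output path.
#' @param format only `"ascii_grid"`.
#' @param nodata sentinel written at masked cells.
#' @return `invisible(path)`.
#' @export
write_raster <- function(layer, path, format = c("ascii_grid", "geotiff"),
                         nodata = -9999) {
  format <- match.arg(format)
  if (format == "geotiff")
    stop("GeoTIFF I/O is not available in this build; use format 'ascii_grid'")
  g <- layer$grid
  m <- layer$values
  m[!g$mask] <- nodata
  hdr <- c(sprintf("ncols %d", g$n_cols),
           sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %.10g", g$origin[1]),
           sprintf("yllcorner %.10g", g$origin[2] - g$n_rows * g$cell_size),
           sprintf("cellsize %.10g", g$cell_size),
           sprintf("NODATA_value %.10g", nodata))
  rows <- apply(m, 1L, function(r) paste(sprintf("%.10g", r), collapse = " "))
  ok <- tryCatch({
    writeLines(c(hdr, rows), path); TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write raster to: ", path)
  invisible(path)
}

#' Aggregate a fine binary layer to coarse fractions
#'
#' Converts a fine-resolution 0/1 layer (e.g. a deforestation or land-cover
#' indicator map) to the fraction of set cells in each `factor x factor`
#' block, the standard post-processing of fine change maps to percent cover
#' at the model resolution. The coarse global mean equals the fine global
#' mean exactly; a coarse cell is masked whenever any contributing fine cell
#' is masked.
#'
#' @param fine a `fire_layer` whose unmasked values are all 0 or 1.
#' @param factor positive integer block size; fine dimensions must be exactly
#'   divisible (no silent cropping).
#' @param name output layer name.
#' @return continuous `fire_layer` on the coarse grid, values in \[0, 1\].
#' @export
aggregate_fraction <- function(fine, factor, name = paste0(fine$name, "_frac")) {
  stopifnot(inherits(fine, "fire_layer"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be a positive integer")
  g <- fine$grid
  if (g$n_rows %% factor != 0L || g$n_cols %% factor != 0L)
    stop(sprintf("fine dimensions %d x %d not divisible by factor %d",
                 g$n_rows, g$n_cols, factor))
  v <- fine$values[g$mask]
  if (any(v != 0 & v != 1)) stop("fine layer must be binary (0/1)")
  nr <- g$n_rows %/% factor; nc <- g$n_cols %/% factor
  a <- array(fine$values, dim = c(factor, nr, factor, nc))
  coarse <- apply(a, c(2, 4), mean)           # NA propagates the mask
  mask <- apply(array(g$mask, dim = c(factor, nr, factor, nc)), c(2, 4), all)
  cg <- fire_grid(nr, nc, g$cell_size * factor, origin = g$origin, mask = mask)
  coarse[!mask] <- NA_real_
  fire_layer(cg, coarse, name = name, kind = "continuous", units = "fraction")
}
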