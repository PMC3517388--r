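#' Georeferenced raster grid
#'
#' `new_grid()` builds the package's raster container: a rectangular matrix of
#' cell values together with the map georeference (projected coordinates in
#' meters). Row 1 is the northernmost row, columns run west to east, and a
#' cell's location is its center. `origin_x`/`origin_y` give the outer
#' (north-west) corner of cell (1, 1). Missing cells are stored as `NA` in the
#' matrix; `nodata` is the sentinel used on disk.
#'
#' @param values Numeric matrix (row 1 = north). `NA` marks nodata cells.
#' @param origin_x,origin_y Map coordinates (m) of the north-west corner of
#'   the grid. Defaults place the south-west corner at (0, 0).
#' @param cell_size Cell edge length in meters (> 0); cells are square.
#' @param nodata Sentinel value used when writing to disk. Must not collide
#'   with a valid class code of a categorical grid.
#' @param kind `"continuous"` (elevation, population, minutes) or
#'   `"categorical"` (class codes; integer-valued, never interpolated).
#' @return An object of class `phc_grid`.
#' @examples
#' g <- new_grid(matrix(1:6, 2, 3), cell_size = 90, kind = "categorical")
#' dim(g$values)
#' @export
new_grid <- function(values, origin_x = 0, origin_y = NULL, cell_size = 90,
                     nodata = -9999, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || length(values) == 0L) {
    stop("`values` must be a non-empty matrix", call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("`cell_size` must be a single positive number (meters)", call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (is.null(origin_y)) origin_y <- nrow(values) * cell_size
  if (kind == "categorical") {
    v <- values[!is.na(values)]
    if (length(v) && any(v != round(v))) {
      stop("categorical grids must hold integer class codes", call. = FALSE)
    }
    if (length(v) && any(v == nodata)) {
      stop("nodata sentinel collides with a class code", call. = FALSE)
    }
  }
  structure(
    list(values = values, origin_x = origin_x, origin_y = origin_y,
         cell_size = cell_size, nodata = nodata, kind = kind),
    class = "phc_grid"
  )
}

#' @export
print.phc_grid <- function(x, ...) {
  cat(sprintf("<phc_grid [%s]> %d x %d cells @ %g m, NW corner (%g, %g), %d nodata\n",
              x$kind, nrow(x$values), ncol(x$values), x$cell_size,
              x$origin_x, x$origin_y, sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.phc_grid <- function(x) dim(x$values)

is_grid <- function(x) inherits(x, "phc_grid")

#' Test whether two grids share the same georeference
#'
#' Grids are aligned iff they have identical origin, cell size and shape.
#' Every multi-layer stage of the pipeline requires aligned inputs and fails
#' fast on misalignment rather than resampling silently; resampling is an
#' explicit step ([resample_to()]).
#'
#' @param a,b `phc_grid` objects.
#' @param tol Numeric tolerance on origin/cell-size comparison (meters).
#' @return `TRUE` or `FALSE`.
#' @export
grids_aligned <- function(a, b, tol = 1e-6) {
  stopifnot(is_grid(a), is_grid(b))
  all(dim(a$values) == dim(b$values)) &&
    abs(a$origin_x - b$origin_x) < tol &&
    abs(a$origin_y - b$origin_y) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

stop_unaligned <- function(a, b, what = "grids") {
  if (!grids_aligned(a, b)) {
    stop(sprintf("%s are not aligned (origin/cell size/shape differ); resample explicitly with resample_to()", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Map coordinates of cell centers
#'
#' @param grid A `phc_grid`.
#' @param row,col Cell indices (1-based, row 1 = north).
#' @return For `cell_to_xy()`, a list with `x` and `y`; for `xy_to_cell()`,
#'   a list with `row` and `col` (`NA` outside the grid).
#' @export
cell_to_xy <- function(grid, row, col) {
  list(x = grid$origin_x + (col - 0.5) * grid$cell_size,
       y = grid$origin_y - (row - 0.5) * grid$cell_size)
}

#' @rdname cell_to_xy
#' @param x,y Map coordinates (m).
#' @export
xy_to_cell <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1L
  row <- floor((grid$origin_y - y) / grid$cell_size) + 1L
  bad <- is.na(row) | is.na(col) | row < 1L | col < 1L |
    row > nrow(grid$values) | col > ncol(grid$values)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Read a raster grid from an ESRI ASCII file
#'
#' Supports the plain-text ESRI ASCII grid format (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, optional `NODATA_value` header
#' followed by rows north to south). Categorical grids are read verbatim,
#' never interpolated. Headers declaring rectangular (non-square) cells
#' (`dx`/`dy`) are rejected.
#'
#' @param path File path (`.asc`).
#' @inheritParams new_grid
#' @return A `phc_grid`.
#' @export
read_grid <- function(path, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]", parts[1]) &&
        !is.na(suppressWarnings(as.numeric(parts[2])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows")
  if (!all(need %in% names(hdr))) stop("not an ESRI ASCII grid: ", path, call. = FALSE)
  if (all(c("dx", "dy") %in% names(hdr))) {
    if (hdr$dx != hdr$dy) stop("non-square cells (dx != dy) are not supported", call. = FALSE)
    hdr$cellsize <- hdr$dx
  }
  if (is.null(hdr$cellsize)) stop("header lacks cellsize", call. = FALSE)
  if (!is.null(hdr$xllcenter)) hdr$xllcorner <- hdr$xllcenter - hdr$cellsize / 2
  if (!is.null(hdr$yllcenter)) hdr$yllcorner <- hdr$yllcenter - hdr$cellsize / 2
  nodata <- hdr$nodata_value %||% -9999
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  body <- paste(lines[(i + 1L):length(lines)], collapse = " ")
  vals <- as.numeric(strsplit(trimws(body), "\\s+")[[1]])
  if (length(vals) != nr * nc) {
    stop(sprintf("expected %d values, found %d in %s", nr * nc, length(vals), path),
         call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  new_grid(m,
           origin_x = hdr$xllcorner %||% 0,
           origin_y = (hdr$yllcorner %||% 0) + nr * hdr$cellsize,
           cell_size = hdr$cellsize, nodata = nodata, kind = kind)
}

#' Write a raster grid to an ESRI ASCII file
#'
#' Integer-valued grids round-trip bit-faithfully; continuous grids are
#' written with enough digits to round-trip within 1e-6. `NA` cells are
#' written as the grid's nodata sentinel.
#'
#' @param grid A `phc_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(is_grid(grid))
  v <- grid$values
  if (length(v) == 0L) stop("empty grid", call. = FALSE)
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", grid$origin_x),
    sprintf("yllcorner %.10g", grid$origin_y - nr * grid$cell_size),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", grid$nodata)
  )
  vv <- v
  vv[is.na(vv)] <- grid$nodata
  int_like <- all(vv == round(vv))
  fmt <- if (int_like) "%d" else "%.12g"
  rows <- vapply(seq_len(nr), function(r) {
    x <- vv[r, ]
    paste(if (int_like) sprintf(fmt, as.integer(x)) else sprintf(fmt, x),
          collapse = " ")
  }, character(1))
  con <- file(path, open = "wb")  # fixed \n EOLs for byte-identical output
  on.exit(close(con))
  writeLines(c(hdr, rows), con, sep = "\n")
  invisible(path)
}

#' Resample a grid onto a target alignment
#'
#' Nearest-neighbour resampling (required for categorical grids) picks, for
#' each target cell center, the value of the source cell containing it, so no
#' class code absent from the source can appear. Bilinear resampling
#' (continuous grids only) interpolates between the four surrounding source
#' cell centers, clamping at the source edge.
#'
#' @param grid Source `phc_grid`.
#' @param target A `phc_grid` used as alignment template, or a list with
#'   `origin_x`, `origin_y`, `cell_size`, `nrow`, `ncol`.
#' @param method `"nearest"` or `"bilinear"`.
#' @return A `phc_grid` aligned to `target`.
#' @export
resample_to <- function(grid, target, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  stopifnot(is_grid(grid))
  if (grid$kind == "categorical" && method == "bilinear") {
    stop("bilinear resampling is not defined for categorical grids; use method = \"nearest\"",
         call. = FALSE)
  }
  tg <- if (is_grid(target)) {
    list(origin_x = target$origin_x, origin_y = target$origin_y,
         cell_size = target$cell_size, nrow = nrow(target$values),
         ncol = ncol(target$values))
  } else target
  nr <- tg$nrow; nc <- tg$ncol
  cx <- tg$origin_x + (seq_len(nc) - 0.5) * tg$cell_size
  cy <- tg$origin_y - (seq_len(nr) - 0.5) * tg$cell_size
  out <- matrix(NA_real_, nr, nc)
  if (method == "nearest") {
    src_col <- floor((cx - grid$origin_x) / grid$cell_size) + 1L
    src_row <- floor((grid$origin_y - cy) / grid$cell_size) + 1L
    src_col <- pmin(pmax(src_col, 1L), ncol(grid$values))
    src_row <- pmin(pmax(src_row, 1L), nrow(grid$values))
    out[, ] <- grid$values[cbind(rep(src_row, times = nc),
                                 rep(src_col, each = nr))]
  } else {
    # fractional position in source-cell-center lattice (0-based)
    gx <- (cx - (grid$origin_x + grid$cell_size / 2)) / grid$cell_size
    gy <- ((grid$origin_y - grid$cell_size / 2) - cy) / grid$cell_size
    gx <- pmin(pmax(gx, 0), ncol(grid$values) - 1)
    gy <- pmin(pmax(gy, 0), nrow(grid$values) - 1)
    x0 <- pmin(floor(gx), ncol(grid$values) - 2); x0 <- pmax(x0, 0)
    y0 <- pmin(floor(gy), nrow(grid$values) - 2); y0 <- pmax(y0, 0)
    if (ncol(grid$values) == 1L) x0 <- rep(0, nc)
    if (nrow(grid$values) == 1L) y0 <- rep(0, nr)
    fx <- gx - x0; fy <- gy - y0
    X0 <- rep(x0 + 1L, each = nr); FX <- rep(fx, each = nr)
    Y0 <- rep(y0 + 1L, times = nc); FY <- rep(fy, times = nc)
    v <- grid$values
    X1 <- pmin(X0 + 1L, ncol(v)); Y1 <- pmin(Y0 + 1L, nrow(v))
    out[, ] <- (1 - FX) * (1 - FY) * v[cbind(Y0, X0)] +
      FX * (1 - FY) * v[cbind(Y0, X1)] +
      (1 - FX) * FY * v[cbind(Y1, X0)] +
      FX * FY * v[cbind(Y1, X1)]
  }
  new_grid(out, origin_x = tg$origin_x, origin_y = tg$origin_y,
           cell_size = tg$cell_size, nodata = grid$nodata, kind = grid$kind)
}

#' Tidy a grid into a long tibble
#'
#' One row per cell with indices, map coordinates of the cell center and the
#' cell value; convenient for dplyr summaries and ggplot2.
#'
#' @param x A `phc_grid`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `x`, `y`, `value`.
#' @importFrom tibble as_tibble
#' @export
as_tibble.phc_grid <- function(x, ...) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  row <- rep(seq_len(nr), times = nc)
  col <- rep(seq_len(nc), each = nr)
  xy <- cell_to_xy(x, row, col)
  vals <- as.vector(x$values)
  tibble::tibble(row = row, col = col, x = xy$x, y = xy$y, value = vals)
}

#' Quick-look raster plot
#'
#' @param object A `phc_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.phc_grid <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)")
  if (object$kind == "categorical") {
    p + ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$value))) +
      ggplot2::labs(fill = "class")
  } else {
    p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_viridis_c(na.value = "grey90")
  }
}
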