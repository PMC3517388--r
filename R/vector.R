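#' Vector layer (points, lines or polygons) with attributes
#'
#' A thin tabular vector model: a tibble with one row per feature, a
#' `geometry` list-column and any number of attribute columns. Geometries are
#' lists of numeric matrices with columns x, y (one matrix per part/ring;
#' points are 1-row matrices). Coordinates are projected meters.
#'
#' @param geometry List of geometries; each geometry a matrix or a list of
#'   matrices (rings for polygons, parts for multi-lines).
#' @param data Tibble/data frame of feature attributes (may be empty).
#' @param type `"point"`, `"line"` or `"polygon"`.
#' @return A tibble of class `phc_vector` with attribute `geometry_type`.
#' @export
new_vector_layer <- function(geometry, data = NULL, type = c("point", "line", "polygon")) {
  type <- match.arg(type)
  geometry <- lapply(geometry, function(g) {
    if (is.matrix(g)) g <- list(g)
    lapply(g, function(m) {
      m <- as.matrix(m)
      if (ncol(m) != 2L || !is.numeric(m) || any(!is.finite(m))) {
        stop("geometries must be finite numeric x,y matrices", call. = FALSE)
      }
      colnames(m) <- c("x", "y")
      m
    })
  })
  out <- if (is.null(data) || ncol(as.data.frame(data)) == 0L) {
    tibble::tibble(.rows = length(geometry))
  } else tibble::as_tibble(data)
  if (nrow(out) != length(geometry)) {
    stop("attribute table and geometry list lengths differ", call. = FALSE)
  }
  out$geometry <- geometry
  class(out) <- c("phc_vector", class(out))
  attr(out, "geometry_type") <- type
  out
}

geometry_type <- function(layer) attr(layer, "geometry_type")

#' Read a GeoJSON vector layer
#'
#' Supports FeatureCollections of Point, LineString, MultiLineString, Polygon
#' and MultiPolygon geometries. Feature properties become attribute columns.
#'
#' @param path Path to a `.geojson` file.
#' @return A `phc_vector` layer.
#' @export
read_vector <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- js$features %||% list()
  to_mat <- function(coords) {
    do.call(rbind, lapply(coords, function(p) c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
  }
  geoms <- list(); props <- list(); types <- character(0)
  for (f in feats) {
    g <- f$geometry
    gt <- g$type
    geom <- switch(gt,
      Point = list(matrix(c(as.numeric(g$coordinates[[1]]),
                            as.numeric(g$coordinates[[2]])), 1, 2)),
      LineString = list(to_mat(g$coordinates)),
      MultiLineString = lapply(g$coordinates, to_mat),
      Polygon = lapply(g$coordinates, to_mat),
      MultiPolygon = unlist(lapply(g$coordinates, function(p) lapply(p, to_mat)),
                            recursive = FALSE),
      stop("unsupported geometry type: ", gt, call. = FALSE)
    )
    geoms[[length(geoms) + 1L]] <- geom
    props[[length(props) + 1L]] <- lapply(f$properties %||% list(),
                                          function(v) if (is.null(v)) NA else v)
    types <- c(types, gt)
  }
  type <- if (all(types %in% "Point")) "point"
    else if (all(types %in% c("LineString", "MultiLineString"))) "line"
    else if (all(types %in% c("Polygon", "MultiPolygon"))) "polygon"
    else stop("mixed geometry types in ", path, call. = FALSE)
  keys <- unique(unlist(lapply(props, names)))
  data <- if (length(keys)) {
    tibble::as_tibble(lapply(stats::setNames(keys, keys), function(k) {
      unlist(lapply(props, function(p) {
        v <- p[[k]]
        if (is.null(v) || length(v) != 1L) NA else v
      }), use.names = FALSE)
    }))
  } else NULL
  new_vector_layer(geoms, data, type)
}

#' Write a vector layer to GeoJSON
#'
#' @param layer A `phc_vector`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vector <- function(layer, path) {
  type <- geometry_type(layer)
  attrs <- layer[setdiff(names(layer), "geometry")]
  class(attrs) <- class(tibble::tibble())
  coords_of <- function(m) lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
  feats <- lapply(seq_len(nrow(layer)), function(i) {
    parts <- layer$geometry[[i]]
    geom <- switch(type,
      point = list(type = "Point", coordinates = c(parts[[1]][1, 1], parts[[1]][1, 2])),
      line = if (length(parts) == 1L) {
        list(type = "LineString", coordinates = coords_of(parts[[1]]))
      } else {
        list(type = "MultiLineString", coordinates = lapply(parts, coords_of))
      },
      polygon = list(type = "Polygon", coordinates = lapply(parts, coords_of))
    )
    pr <- if (ncol(attrs)) as.list(attrs[i, ]) else stats::setNames(list(), character(0))
    list(type = "Feature", geometry = geom, properties = pr)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats), path,
                       auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

# Supercover traversal of one segment through the cell lattice; returns the
# (row, col) cells touched, the rule that keeps 90 m rasterized roads connected.
trace_segment <- function(grid, x0, y0, x1, y1) {
  cs <- grid$cell_size
  u0 <- (x0 - grid$origin_x) / cs; v0 <- (grid$origin_y - y0) / cs
  u1 <- (x1 - grid$origin_x) / cs; v1 <- (grid$origin_y - y1) / cs
  cx <- floor(u0); cy <- floor(v0)
  ex <- floor(u1); ey <- floor(v1)
  cells <- matrix(NA_real_, nrow = abs(ex - cx) + abs(ey - cy) + 2L, ncol = 2)
  k <- 1L; cells[k, ] <- c(cy, cx)
  du <- u1 - u0; dv <- v1 - v0
  step_x <- sign(du); step_y <- sign(dv)
  t_max_x <- if (du != 0) ((cx + (step_x > 0)) - u0) / du else Inf
  t_max_y <- if (dv != 0) ((cy + (step_y > 0)) - v0) / dv else Inf
  t_dx <- if (du != 0) abs(1 / du) else Inf
  t_dy <- if (dv != 0) abs(1 / dv) else Inf
  guard <- 4L * (abs(ex - cx) + abs(ey - cy) + 2L)
  while ((cx != ex || cy != ey) && guard > 0L) {
    if (t_max_x < t_max_y) {
      cx <- cx + step_x; t_max_x <- t_max_x + t_dx
    } else {
      cy <- cy + step_y; t_max_y <- t_max_y + t_dy
    }
    k <- k + 1L
    if (k > nrow(cells)) cells <- rbind(cells, matrix(NA_real_, nrow(cells), 2))
    cells[k, ] <- c(cy, cx)
    guard <- guard - 1L
  }
  cells <- cells[seq_len(k), , drop = FALSE] + 1  # to 1-based (row, col)
  keep <- cells[, 1] >= 1 & cells[, 1] <= nrow(grid$values) &
    cells[, 2] >= 1 & cells[, 2] <= ncol(grid$values)
  cells[keep, , drop = FALSE]
}

#' Rasterize line features onto a grid ("all touched" rule)
#'
#' Every cell a line passes through is marked, so thin diagonal roads remain
#' 8-connected at 90 m resolution, which the least-cost search requires.
#'
#' @param layer A line `phc_vector`.
#' @param grid Target `phc_grid` (alignment template).
#' @return A tibble with columns `feature`, `row`, `col` (deduplicated per
#'   feature).
#' @export
rasterize_lines <- function(layer, grid) {
  stopifnot(geometry_type(layer) == "line")
  out <- vector("list", nrow(layer))
  for (i in seq_len(nrow(layer))) {
    parts <- layer$geometry[[i]]
    cells <- do.call(rbind, lapply(parts, function(m) {
      do.call(rbind, lapply(seq_len(nrow(m) - 1L), function(j) {
        trace_segment(grid, m[j, 1], m[j, 2], m[j + 1, 1], m[j + 1, 2])
      }))
    }))
    cells <- unique(cells)
    out[[i]] <- tibble::tibble(feature = i,
                               row = as.integer(cells[, 1]),
                               col = as.integer(cells[, 2]))
  }
  dplyr::bind_rows(out)
}

# Even-odd point-in-polygon over a list of rings; vectorized over points.
points_in_polygon <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (m in rings) {
    n <- nrow(m)
    j <- n
    for (i in seq_len(n)) {
      x1 <- m[j, 1]; y1 <- m[j, 2]; x2 <- m[i, 1]; y2 <- m[i, 2]
      crosses <- ((y1 > py) != (y2 > py)) &
        (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
      crosses[is.na(crosses)] <- FALSE
      inside <- xor(inside, crosses)
      j <- i
    }
  }
  inside
}

#' Rasterize polygon features onto a grid (cell-center containment)
#'
#' A cell belongs to a polygon iff its center lies inside (even-odd rule,
#' holes respected).
#'
#' @inheritParams rasterize_lines
#' @param layer A polygon `phc_vector`.
#' @return A tibble with columns `feature`, `row`, `col`.
#' @export
rasterize_polygons <- function(layer, grid) {
  stopifnot(geometry_type(layer) == "polygon")
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  row <- rep(seq_len(nr), times = nc); col <- rep(seq_len(nc), each = nr)
  xy <- cell_to_xy(grid, row, col)
  out <- vector("list", nrow(layer))
  for (i in seq_len(nrow(layer))) {
    rings <- layer$geometry[[i]]
    # bounding-box prefilter keeps the even-odd test cheap on large grids
    bb <- do.call(rbind, rings)
    cand <- xy$x >= min(bb[, 1]) & xy$x <= max(bb[, 1]) &
      xy$y >= min(bb[, 2]) & xy$y <= max(bb[, 2])
    idx <- which(cand)
    if (length(idx)) {
      hit <- points_in_polygon(xy$x[idx], xy$y[idx], rings)
      idx <- idx[hit]
    }
    out[[i]] <- tibble::tibble(feature = i, row = row[idx], col = col[idx])
  }
  dplyr::bind_rows(out)
}
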