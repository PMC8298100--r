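# Cell-shape descriptors from closed outline polygons.
#
# Contours are simple closed polygons in um (typically hand-drawn outlines of
# migrating cells). Descriptors: area, perimeter, equivalent-ellipse axes
# from exact polygon moments, mirror symmetry about the major axis, convex
# hull metrics, bounding-box extent, and centroid-to-boundary distances.
# The symmetry overlap area is computed by scanline rasterization of both
# polygons on a shared grid; for an exactly mirror-symmetric polygon the two
# rasters coincide and the score is exactly 1.

#' Create a cell contour
#'
#' Validates and normalizes a closed polygon: at least 3 vertices, simple
#' (non-self-intersecting), counterclockwise orientation. A duplicated
#' closing vertex is dropped.
#'
#' @param x,y Vertex coordinates in um, in order around the outline.
#' @param cell_id,experiment_id,condition Labels.
#' @return An object of class `cell_contour`.
#' @export
cell_contour <- function(x, y, cell_id = NA, experiment_id = NA, condition = NA) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (anyNA(x) || anyNA(y) || !all(is.finite(c(x, y)))) {
    stop("contour coordinates must be finite", call. = FALSE)
  }
  n <- length(x)
  if (n >= 4L && x[1L] == x[n] && y[1L] == y[n]) {
    x <- x[-n]; y <- y[-n]; n <- n - 1L
  }
  if (n < 3L) stop("a contour needs >= 3 vertices", call. = FALSE)
  if (!polygon_is_simple(x, y)) stop("contour is self-intersecting", call. = FALSE)
  a <- polygon_signed_area(x, y)
  if (abs(a) < .Machine$double.eps * max(abs(c(x, y, 1)))^2) {
    stop("degenerate (zero-area) contour", call. = FALSE)
  }
  if (a < 0) { x <- rev(x); y <- rev(y) }
  structure(list(x = x, y = y, cell_id = cell_id, experiment_id = experiment_id,
                 condition = condition), class = "cell_contour")
}

#' @export
print.cell_contour <- function(x, ...) {
  cat(sprintf("<cell_contour> %d vertices, area %.3g um^2", length(x$x),
              abs(polygon_signed_area(x$x, x$y))))
  if (!is.na(x$cell_id)) cat(sprintf(" [%s]", x$cell_id))
  cat("\n")
  invisible(x)
}

polygon_signed_area <- function(x, y) {
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

# O(n^2) vectorized segment-intersection simplicity test
polygon_is_simple <- function(x, y) {
  n <- length(x)
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- pairs[, 1L]; j <- pairs[, 2L]
  adjacent <- (j - i == 1L) | (i == 1L & j == n)
  i <- i[!adjacent]; j <- j[!adjacent]
  if (!length(i)) return(TRUE)
  cr <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  d1 <- cr(x[i], y[i], x2[i], y2[i], x[j], y[j])
  d2 <- cr(x[i], y[i], x2[i], y2[i], x2[j], y2[j])
  d3 <- cr(x[j], y[j], x2[j], y2[j], x[i], y[i])
  d4 <- cr(x[j], y[j], x2[j], y2[j], x2[i], y2[i])
  proper <- (d1 * d2 < 0) & (d3 * d4 < 0)
  touch <- (d1 == 0 & on_segment(x[i], y[i], x2[i], y2[i], x[j], y[j])) |
           (d2 == 0 & on_segment(x[i], y[i], x2[i], y2[i], x2[j], y2[j])) |
           (d3 == 0 & on_segment(x[j], y[j], x2[j], y2[j], x[i], y[i])) |
           (d4 == 0 & on_segment(x[j], y[j], x2[j], y2[j], x2[i], y2[i]))
  !any(proper | touch)
}

on_segment <- function(ax, ay, bx, by, px, py) {
  px >= pmin(ax, bx) & px <= pmax(ax, bx) & py >= pmin(ay, by) & py <= pmax(ay, by)
}

#' Polygon area and perimeter
#'
#' Shoelace area (absolute value) and total edge length including the
#' closing edge.
#'
#' @param contour A [cell_contour()].
#' @return A list with `area` (um^2) and `perimeter` (um).
#' @examples
#' sq <- cell_contour(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' polygon_area_perimeter(sq)
#' @export
polygon_area_perimeter <- function(contour) {
  stopifnot(inherits(contour, "cell_contour"))
  x <- contour$x; y <- contour$y
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  list(area = abs(polygon_signed_area(x, y)),
       perimeter = sum(sqrt((xn - x)^2 + (yn - y)^2)))
}

# exact area-weighted moments of the polygon interior
polygon_moments <- function(x, y) {
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cross <- x * yn - xn * y
  A <- sum(cross) / 2
  cx <- sum((x + xn) * cross) / (6 * A)
  cy <- sum((y + yn) * cross) / (6 * A)
  Ix <- sum((y^2 + y * yn + yn^2) * cross) / 12       # integral of y^2
  Iy <- sum((x^2 + x * xn + xn^2) * cross) / 12       # integral of x^2
  Ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cross) / 24
  list(area = A, cx = cx, cy = cy,
       mu_xx = Iy / A - cx^2, mu_yy = Ix / A - cy^2, mu_xy = Ixy / A - cx * cy)
}

#' Principal axes of a contour
#'
#' Axis lengths of the ellipse with the same exact area-weighted second
#' central moments as the polygon interior: length = 4 * sqrt(eigenvalue).
#'
#' @param contour A [cell_contour()].
#' @return A list with `major_axis`, `minor_axis` (um), `orientation`
#'   (radians of the major axis), `aspect_ratio` (minor/major, <= 1), and
#'   `isotropic` (TRUE when the moment tensor is degenerate and the
#'   orientation is arbitrary).
#' @export
principal_axes <- function(contour) {
  stopifnot(inherits(contour, "cell_contour"))
  m <- polygon_moments(contour$x, contour$y)
  tr <- m$mu_xx + m$mu_yy
  det_ <- m$mu_xx * m$mu_yy - m$mu_xy^2
  disc <- sqrt(max(tr^2 / 4 - det_, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  iso <- disc <= 1e-12 * tr
  orientation <- if (iso) 0 else 0.5 * atan2(2 * m$mu_xy, m$mu_xx - m$mu_yy)
  list(major_axis = 4 * sqrt(max(l1, 0)), minor_axis = 4 * sqrt(max(l2, 0)),
       orientation = orientation, aspect_ratio = sqrt(max(l2, 0) / l1),
       isotropic = iso)
}

# scanline rasterization of a polygon onto a shared grid; grid is a list
# with x0, y0, px, nx, ny; returns an ny x nx logical matrix
rasterize_polygon <- function(x, y, grid) {
  xs <- grid$x0 + (seq_len(grid$nx) - 0.5) * grid$px
  ys <- grid$y0 + (seq_len(grid$ny) - 0.5) * grid$px
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  out <- matrix(FALSE, grid$ny, grid$nx)
  for (r in seq_len(grid$ny)) {
    yy <- ys[r]
    crosses <- (y <= yy & yn > yy) | (yn <= yy & y > yy)
    if (!any(crosses)) next
    xi <- x[crosses] + (yy - y[crosses]) * (xn[crosses] - x[crosses]) /
      (yn[crosses] - y[crosses])
    xi <- sort(xi)
    for (k in seq(1L, length(xi) - 1L, by = 2L)) {
      out[r, xs > xi[k] & xs < xi[k + 1L]] <- TRUE
    }
  }
  out
}

#' Mirror symmetry about the major axis
#'
#' Reflects the contour across its major axis through the centroid and
#' returns the overlap fraction `area(A intersect reflect(A)) / area(A)`
#' (default), or the union variant `area(A) / area(A union reflect(A))`.
#' Both equal 1 exactly for a mirror-symmetric outline and decrease as the
#' outline departs from symmetry. Intersection and union areas come from
#' scanline rasterization of both polygons on a shared grid.
#'
#' @param contour A [cell_contour()].
#' @param variant `"overlap"` (default) or `"union"`.
#' @param resolution Grid pixel size in um; default scales the longer
#'   bounding-box side to 400 px.
#' @return Symmetry score in `(0, 1]`.
#' @export
symmetry <- function(contour, variant = c("overlap", "union"), resolution = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(contour, "cell_contour"))
  m <- polygon_moments(contour$x, contour$y)
  ax <- principal_axes(contour)
  u <- c(cos(ax$orientation), sin(ax$orientation))
  dx <- contour$x - m$cx; dy <- contour$y - m$cy
  par_ <- dx * u[1L] + dy * u[2L]
  perp <- -dx * u[2L] + dy * u[1L]
  rx <- m$cx + par_ * u[1L] + perp * u[2L]   # reflected: perp component negated
  ry <- m$cy + par_ * u[2L] - perp * u[1L]
  allx <- c(contour$x, rx); ally <- c(contour$y, ry)
  px <- resolution %||% (max(diff(range(allx)), diff(range(ally))) / 400)
  grid <- list(x0 = min(allx) - px, y0 = min(ally) - px, px = px,
               nx = ceiling(diff(range(allx)) / px) + 2L,
               ny = ceiling(diff(range(ally)) / px) + 2L)
  inA <- rasterize_polygon(contour$x, contour$y, grid)
  inR <- rasterize_polygon(rx, ry, grid)
  nA <- sum(inA)
  if (nA == 0L) stop("contour rasterized to zero pixels; decrease `resolution`",
                     call. = FALSE)
  switch(variant,
         overlap = sum(inA & inR) / nA,
         union = nA / sum(inA | inR))
}

#' Convex hull metrics
#'
#' @param contour A [cell_contour()].
#' @return A list with `convex_area` (um^2 of the vertex convex hull),
#'   `solidity` (area / convex area), and `extent` (area / axis-aligned
#'   bounding-box area).
#' @export
convexity_metrics <- function(contour) {
  stopifnot(inherits(contour, "cell_contour"))
  ap <- polygon_area_perimeter(contour)
  hull <- chull(contour$x, contour$y)
  hx <- contour$x[hull]; hy <- contour$y[hull]
  convex_area <- abs(polygon_signed_area(hx, hy))
  bbox <- diff(range(contour$x)) * diff(range(contour$y))
  list(convex_area = convex_area, solidity = ap$area / convex_area,
       extent = ap$area / bbox)
}

#' Centroid-to-boundary distances
#'
#' Maximum distance from the area centroid to any vertex, and minimum
#' distance from the centroid to any boundary edge.
#'
#' @param contour A [cell_contour()].
#' @return A list with `max_center_distance`, `min_center_distance` (um),
#'   and `centroid_inside` (flag; distances are still computed when the
#'   centroid falls outside a highly concave outline).
#' @export
center_distances <- function(contour) {
  stopifnot(inherits(contour, "cell_contour"))
  m <- polygon_moments(contour$x, contour$y)
  x <- contour$x; y <- contour$y
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  dmax <- sqrt(max((x - m$cx)^2 + (y - m$cy)^2))
  ex <- xn - x; ey <- yn - y
  tt <- pmin(pmax(((m$cx - x) * ex + (m$cy - y) * ey) / (ex^2 + ey^2), 0), 1)
  dmin <- sqrt(min((x + tt * ex - m$cx)^2 + (y + tt * ey - m$cy)^2))
  inside <- point_in_polygon(m$cx, m$cy, x, y)
  list(max_center_distance = dmax, min_center_distance = dmin,
       centroid_inside = inside)
}

point_in_polygon <- function(px, py, x, y) {
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  crosses <- (y <= py & yn > py) | (yn <= py & y > py)
  if (!any(crosses)) return(FALSE)
  xi <- x[crosses] + (py - y[crosses]) * (xn[crosses] - x[crosses]) /
    (yn[crosses] - y[crosses])
  sum(xi > px) %% 2L == 1L
}

#' All shape descriptors of one contour
#'
#' @param contour A [cell_contour()].
#' @param symmetry_variant Passed to [symmetry()].
#' @return One-row data frame with the contour labels and all descriptors.
#' @export
shape_descriptors <- function(contour, symmetry_variant = "overlap") {
  ap <- polygon_area_perimeter(contour)
  ax <- principal_axes(contour)
  cv <- convexity_metrics(contour)
  cd <- center_distances(contour)
  data.frame(cell_id = contour$cell_id, experiment_id = contour$experiment_id,
             condition = contour$condition,
             area = ap$area, perimeter = ap$perimeter,
             major_axis = ax$major_axis, minor_axis = ax$minor_axis,
             aspect_ratio = ax$aspect_ratio,
             symmetry = symmetry(contour, symmetry_variant),
             convex_area = cv$convex_area, solidity = cv$solidity,
             extent = cv$extent,
             max_center_distance = cd$max_center_distance,
             min_center_distance = cd$min_center_distance,
             centroid_inside = cd$centroid_inside)
}

#' Descriptor table for a cohort of contours
#'
#' One row per valid contour; failing contours are reported in the
#' `"failures"` attribute rather than aborting the cohort. When the cohort
#' carries condition and experiment labels with two or more conditions, a
#' superplot test on cell area (experiment means, Student's t or Dunnett) is
#' attached as attribute `"area_test"`.
#'
#' @param contours List of [cell_contour()]s.
#' @param symmetry_variant Passed to [symmetry()].
#' @param control Control condition for > 2 conditions.
#' @return Data frame of descriptors.
#' @export
shape_table <- function(contours, symmetry_variant = "overlap", control = NULL) {
  if (inherits(contours, "cell_contour")) contours <- list(contours)
  if (!length(contours)) stop("no contours supplied", call. = FALSE)
  rows <- list(); failures <- character(0)
  for (i in seq_along(contours)) {
    res <- tryCatch(shape_descriptors(contours[[i]], symmetry_variant),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      id <- contours[[i]]$cell_id
      if (is.null(id) || is.na(id)) id <- i
      failures <- c(failures, sprintf("contour %s: %s", id, res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (!length(rows)) stop("all contours failed:\n", paste(failures, collapse = "\n"),
                          call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  conds <- unique(out$condition[!is.na(out$condition)])
  if (length(conds) >= 2L && !all(is.na(out$experiment_id))) {
    attr(out, "area_test") <- tryCatch(
      superplot_summary(out, "area", control = control),
      error = function(e) conditionMessage(e))
  }
  out
}

#' Read contours from tidy delimited text
#'
#' Columns: `cell_id`, `vertex_index`, `x_um`, `y_um`, optionally
#' `experiment_id` and `condition`.
#'
#' @param path File path.
#' @return A list of [cell_contour()]s.
#' @export
read_contours <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("cell_id", "vertex_index", "x_um", "y_um")
  if (!all(req %in% names(d))) {
    stop("contour file needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  lapply(split(d, d$cell_id), function(g) {
    g <- g[order(g$vertex_index), ]
    cell_contour(g$x_um, g$y_um, cell_id = g$cell_id[1L],
                 experiment_id = if ("experiment_id" %in% names(g)) g$experiment_id[1L] else NA,
                 condition = if ("condition" %in% names(g)) g$condition[1L] else NA)
  })
}

#' Write contours as tidy delimited text
#' @param contours List of [cell_contour()]s.
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_contours <- function(contours, path) {
  if (inherits(contours, "cell_contour")) contours <- list(contours)
  rows <- lapply(seq_along(contours), function(i) {
    ct <- contours[[i]]
    data.frame(cell_id = if (is.na(ct$cell_id)) sprintf("cell%03d", i) else ct$cell_id,
               experiment_id = ct$experiment_id, condition = ct$condition,
               vertex_index = seq_along(ct$x), x_um = ct$x, y_um = ct$y)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
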