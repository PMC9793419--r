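#' Rasterize per-slice cell outline annotations into a 3D label volume
#'
#' Converts manually drawn per-z-slice cell outlines (simple polygons in pixel
#' coordinates, the Fiji-style annotation format) into a 3D integer label
#' volume, or passes a label-mask annotation through. Excluded z-slices
#' (typically the uppermost and lowermost slices of a stack, where cells are
#' flattened or out of focus) are zeroed. If no explicit exclusion set is
#' given and `auto_exclude` is `TRUE`, slices where a cell's outlined area
#' falls below half of that cell's maximal per-slice area are excluded for
#' that cell.
#'
#' Polygon filling uses the pixel-centre convention: pixel `(iy, ix)`
#' (0-based) belongs to a polygon when its centre `(iy + 0.5, ix + 0.5)` lies
#' inside (even-odd rule). An axis-aligned square of side `s` px therefore
#' fills exactly `s^2` pixels per slice. Cells sharing an edge rasterize
#' without conflict; a pixel claimed by two cells is tolerated (first-listed
#' cell wins) only when its centre sits within half a pixel of the second
#' polygon's boundary, otherwise the interiors genuinely overlap and an
#' annotation-conflict error is raised. Self-intersecting polygons are
#' rejected.
#'
#' @param annotation Either a 3D integer label array (passthrough path), or a
#'   list with elements `cells` (list of `list(cell_id =, slices = list(
#'   list(z =, y =, x =)))`, 0-based slice index, vertices in pixel
#'   coordinates) and optional `excluded_slices` (0-based z indices). See
#'   [read_annotation_json()].
#' @param shape Output dimensions `c(nz, ny, nx)`.
#' @param excluded_slices Optional 0-based z indices overriding the
#'   annotation's own set.
#' @param auto_exclude Apply the half-maximal-area exclusion rule when no
#'   explicit exclusion set exists (default `TRUE`).
#' @return Integer 3D label array with attribute `excluded_slices`.
#' @export
rasterize_annotation <- function(annotation, shape, excluded_slices = NULL,
                                 auto_exclude = TRUE) {
  shape <- as.integer(shape)
  if (is.array(annotation) && is.numeric(annotation)) {
    labels <- array(as.integer(annotation), dim(annotation))
    if (!all(dim(labels) == shape)) stopf("label-mask shape does not match `shape`")
    excl <- excluded_slices %||% attr(annotation, "excluded_slices") %||% integer(0)
  } else {
    if (is.null(annotation$cells)) stopf("annotation needs a `cells` list or a label array")
    labels <- array(0L, shape)
    owner_interior <- array(FALSE, shape)  # centre strictly in interior (not near edge)
    for (cell in annotation$cells) {
      cid <- as.integer(cell$cell_id)
      for (sl in cell$slices) {
        z <- as.integer(sl$z)
        if (z < 0L || z >= shape[1]) stopf("slice z=%d outside stack (nz=%d)", z, shape[1])
        vy <- as.numeric(sl$y); vx <- as.numeric(sl$x)
        if (length(vy) < 3L || length(vy) != length(vx))
          stopf("cell %d slice %d: polygon needs >= 3 vertices", cid, z)
        if (polygon_self_intersects(vy, vx))
          stopf("geometry error: cell %d slice %d polygon self-intersects", cid, z)
        fill <- polygon_fill(vy, vx, shape[2], shape[3])
        if (!any(fill$inside)) next
        near <- fill$near_edge
        zi <- z + 1L
        plane <- labels[zi, , ]
        taken <- plane != 0L & fill$inside
        if (any(taken)) {
          # tolerated only where the centre hugs this polygon's boundary
          bad <- taken & !near
          if (any(bad))
            stopf("annotation conflict: cell %d overlaps cell %d interior on slice %d (%d px)",
                  cid, plane[which(bad)[1]], z, sum(bad))
        }
        claim <- fill$inside & plane == 0L
        plane[claim] <- cid
        labels[zi, , ] <- plane
      }
    }
    excl <- excluded_slices %||% annotation$excluded_slices %||% NULL
    if (is.null(excl) && auto_exclude) {
      excl <- integer(0)
      for (cid in sort(unique(labels[labels > 0L]))) {
        areas <- apply(labels == cid, 1L, sum)
        weak <- which(areas > 0L & areas < 0.5 * max(areas)) - 1L
        for (z in weak) {
          plane <- labels[z + 1L, , ]
          plane[plane == cid] <- 0L
          labels[z + 1L, , ] <- plane
        }
      }
    }
    excl <- excl %||% integer(0)
  }
  excl <- sort(unique(as.integer(excl)))
  if (any(excl < 0L | excl >= shape[1]))
    stopf("excluded_slices must be 0-based z indices inside the stack")
  if (length(excl)) labels[excl + 1L, , ] <- 0L
  attr(labels, "excluded_slices") <- excl
  labels
}

# even-odd point-in-polygon for all pixel centres in the bounding box;
# also flags centres within 0.5 px of the polygon boundary
polygon_fill <- function(vy, vx, ny, nx) {
  inside <- matrix(FALSE, ny, nx)
  near <- matrix(FALSE, ny, nx)
  ylo <- max(1L, floor(min(vy)) ); yhi <- min(ny, ceiling(max(vy)))
  xlo <- max(1L, floor(min(vx)) ); xhi <- min(nx, ceiling(max(vx)))
  if (ylo > yhi || xlo > xhi) return(list(inside = inside, near_edge = near))
  ys <- (ylo:yhi) - 0.5; xs <- (xlo:xhi) - 0.5
  py <- rep(ys, times = length(xs)); px <- rep(xs, each = length(ys))
  n <- length(vy)
  cross <- integer(length(py))
  mind2 <- rep(Inf, length(py))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    y1 <- vy[i]; x1 <- vx[i]; y2 <- vy[j]; x2 <- vx[j]
    # ray casting along +x
    cond <- ((y1 > py) != (y2 > py))
    if (any(cond)) {
      xint <- x1 + (py[cond] - y1) / (y2 - y1) * (x2 - x1)
      hit <- xint > px[cond]
      cr <- cross[cond]; cr[hit] <- cr[hit] + 1L; cross[cond] <- cr
    }
    # squared distance to segment
    dy <- y2 - y1; dx <- x2 - x1
    len2 <- dy * dy + dx * dx
    t <- if (len2 == 0) rep(0, length(py)) else
      pmin(pmax(((py - y1) * dy + (px - x1) * dx) / len2, 0), 1)
    d2 <- (py - (y1 + t * dy))^2 + (px - (x1 + t * dx))^2
    mind2 <- pmin(mind2, d2)
  }
  m_in <- matrix(FALSE, length(ys), length(xs)); m_in[] <- (cross %% 2L) == 1L
  m_nr <- matrix(FALSE, length(ys), length(xs)); m_nr[] <- mind2 <= 0.25
  inside[ylo:yhi, xlo:xhi] <- m_in
  near[ylo:yhi, xlo:xhi] <- m_nr
  list(inside = inside, near_edge = near)
}

polygon_self_intersects <- function(vy, vx) {
  n <- length(vy)
  seg <- cbind(vy, vx, vy[c(2:n, 1)], vx[c(2:n, 1)])
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through closure
      if (segments_cross(seg[i, ], seg[j, ])) return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(a, b) {
  d <- function(p1y, p1x, p2y, p2x, p3y, p3x)
    (p2x - p1x) * (p3y - p1y) - (p2y - p1y) * (p3x - p1x)
  d1 <- d(a[1], a[2], a[3], a[4], b[1], b[2])
  d2 <- d(a[1], a[2], a[3], a[4], b[3], b[4])
  d3 <- d(b[1], b[2], b[3], b[4], a[1], a[2])
  d4 <- d(b[1], b[2], b[3], b[4], a[3], a[4])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Read or write per-slice polygon annotations as JSON
#'
#' The JSON schema mirrors the in-memory annotation list:
#' `{"shape": [nz, ny, nx], "excluded_slices": [...],`
#' `"cells": [{"cell_id": 1, "slices": [{"z": 0, "y": [...], "x": [...]}]}]}`.
#'
#' @param path File path.
#' @return `read_annotation_json()`: the annotation list.
#' @export
read_annotation_json <- function(path) {
  ann <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  ann
}

#' @rdname read_annotation_json
#' @param annotation Annotation list to serialize.
#' @export
write_annotation_json <- function(annotation, path) {
  jsonlite::write_json(annotation, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
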