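#' Traced root geometry
#'
#' Holds the manually traced (or simulated) root: an ordered centreline with
#' cumulative arc length `s_um` starting at 0 at the tip, and a closed, simple
#' boundary polygon. All coordinates in um. `s_offset_um` shifts arc lengths
#' for tiles that image a mature root segment away from the tip; when it is
#' positive the tile contains no tip and `s_um` starts at the offset.
#'
#' @param centreline Data frame with columns `x_um`, `y_um`, ordered tip-first.
#' @param boundary Data frame with columns `x_um`, `y_um` (closed polygon;
#'   the closing edge from last to first vertex is implicit).
#' @param s_offset_um Arc length of the first centreline vertex (0 = tip in
#'   this tile).
#' @return A `root_geometry` object.
#' @export
root_geometry <- function(centreline, boundary, s_offset_um = 0) {
  centreline <- as_tibble(centreline)
  boundary <- as_tibble(boundary)
  stopifnot(all(c("x_um", "y_um") %in% names(centreline)),
            nrow(centreline) >= 2, s_offset_um >= 0)
  if (nrow(boundary) < 3) abort("boundary polygon needs at least 3 vertices")
  s <- arc_length(as.matrix(centreline[, c("x_um", "y_um")]))
  if (any(diff(s) <= 0)) abort("centreline has repeated vertices")
  centreline$s_um <- s + s_offset_um
  structure(list(centreline = centreline, boundary = boundary,
                 s_offset_um = s_offset_um,
                 tip_um = unlist(centreline[1, c("x_um", "y_um")])),
            class = "root_geometry")
}

#' @export
print.root_geometry <- function(x, ...) {
  cat(sprintf("<root_geometry> centreline %d vertices, length %.1f um%s\n",
              nrow(x$centreline), max(x$centreline$s_um) - x$s_offset_um,
              if (x$s_offset_um > 0)
                sprintf(" (arc-length offset %.1f um)", x$s_offset_um) else ""))
  invisible(x)
}

root_length_um <- function(geometry) max(geometry$centreline$s_um)

# Resample the centreline to (approximately) uniform spacing, carrying arc
# length. Used so 'distance from the tip' is read off the nearest vertex.
resample_centreline <- function(geometry, spacing_um) {
  cl <- geometry$centreline
  s <- cl$s_um
  s_new <- unique(c(seq(min(s), max(s), by = spacing_um), max(s)))
  tibble(x_um = stats::approx(s, cl$x_um, xout = s_new)$y,
         y_um = stats::approx(s, cl$y_um, xout = s_new)$y,
         s_um = s_new)
}

# Arc length (um from the tip) of the centreline vertex nearest each point.
# points: matrix/data frame with x_um, y_um. Chunked to bound memory.
da_nearest <- function(points, geometry, spacing_um = NULL) {
  pts <- as.matrix(as.data.frame(points)[, c("x_um", "y_um")])
  if (nrow(pts) == 0) return(numeric(0))
  spacing_um <- spacing_um %||% attr(geometry, "default_spacing") %||% NULL
  cl <- if (is.null(spacing_um)) geometry$centreline
        else resample_centreline(geometry, spacing_um)
  V <- as.matrix(cl[, c("x_um", "y_um")])
  out <- numeric(nrow(pts))
  chunk <- max(1L, floor(5e6 / nrow(V)))
  for (i0 in seq(1L, nrow(pts), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, nrow(pts))
    d2 <- outer(pts[idx, 1], V[, 1], "-")^2 + outer(pts[idx, 2], V[, 2], "-")^2
    out[idx] <- cl$s_um[max.col(-d2, ties.method = "first")]
  }
  out
}

#' Rasterize a root boundary polygon onto the pixel grid
#'
#' A pixel belongs to the root when its center falls inside the boundary
#' polygon (even-odd rule). This is the single rasterization rule used both
#' by the synthetic generator and by segmentation, so synthetic ground truth
#' and recovered masks agree exactly.
#'
#' @param geometry A [root_geometry()].
#' @param dim Integer `c(nx, ny)` grid size in pixels.
#' @param pixel_size_um Pixel size in um.
#' @return Logical `nx` x `ny` matrix.
#' @export
rasterize_root <- function(geometry, dim, pixel_size_um) {
  bnd <- as.matrix(geometry$boundary[, c("x_um", "y_um")])
  if (nrow(bnd) < 3) abort("boundary polygon is empty or degenerate")
  if (any(!is.finite(bnd))) abort("boundary polygon has non-finite vertices")
  nx <- dim[1]; ny <- dim[2]
  cx <- px_centers(nx, pixel_size_um)
  cy <- px_centers(ny, pixel_size_um)
  # restrict the point-in-polygon test to the polygon's bounding box
  ix <- which(cx >= min(bnd[, 1]) - pixel_size_um & cx <= max(bnd[, 1]) + pixel_size_um)
  iy <- which(cy >= min(bnd[, 2]) - pixel_size_um & cy <= max(bnd[, 2]) + pixel_size_um)
  mask <- matrix(FALSE, nx, ny)
  if (length(ix) && length(iy)) {
    pts <- cbind(rep(cx[ix], times = length(iy)),
                 rep(cy[iy], each = length(ix)))
    inside <- mgcv::in.out(bnd, pts)
    mask[as.matrix(expand.grid(ix, iy))] <- inside
  }
  mask
}

# Overlay the rasterized root onto a label map: ROOT overrides every
# classifier label inside the traced polygon.
#' Overlay the traced root region onto a label map
#'
#' Pixels inside the root boundary polygon become `ROOT`, overriding any
#' classifier output there (the root is traced manually and is authoritative).
#'
#' @param labelmap Integer matrix of class codes (see [argmax_classify()]).
#' @param geometry A [root_geometry()].
#' @param pixel_size_um Pixel size in um.
#' @return The label map with root pixels set to the `ROOT` code.
#' @export
overlay_root <- function(labelmap, geometry, pixel_size_um) {
  mask <- rasterize_root(geometry, dim(labelmap), pixel_size_um)
  labelmap[mask] <- ROOT_CODE
  labelmap
}
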