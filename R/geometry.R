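#' Construct a 2D nucleoid domain
#'
#' The nucleoid surface is modeled as a 2D domain on which McdA binds and
#' cargos move: either a rounded rectangle (a rectangle with two spherical
#' caps at the ends of its long axis, i.e. a stadium/discorectangle, the
#' rod-shaped nucleoid of *S. elongatus*) or a circle (coccoid nucleoid).
#' The origin is the domain centroid and the long axis is x. `length` is the
#' tip-to-tip extent along x and `width` the short-axis extent (= cap
#' diameter). Defaults mirror the wild-type geometries used throughout:
#' a 2.5 um by 0.6 um rounded rectangle and a 1.7 um circle.
#'
#' Internally both kinds are represented as the Minkowski sum of a segment of
#' half-length `c` on the x axis with a disk of radius `r` (`c = 0` for a
#' circle), which gives uniform containment and reflection code.
#'
#' @param kind `"rounded_rectangle"` or `"circle"`.
#' @param length,width Tip-to-tip length and width in um (rounded rectangle).
#' @param diameter Diameter in um (circle).
#' @return An object of class `nucleoid_geometry` with fields `kind`, the
#'   input dimensions, the half segment length `c`, cap radius `r`, and
#'   `area` (um^2).
#' @examples
#' make_geometry("rounded_rectangle", length = 2.5, width = 0.6)
#' make_geometry("circle", diameter = 1.7)
#' @export
make_geometry <- function(kind = c("rounded_rectangle", "circle"),
                          length = NULL, width = NULL, diameter = NULL) {
  kind <- match.arg(kind)
  if (kind == "rounded_rectangle") {
    if (is.null(length) || is.null(width))
      stop("rounded_rectangle requires `length` and `width`")
    if (!is.finite(length) || !is.finite(width) || length <= 0 || width <= 0)
      stop("geometry dimensions must be positive and finite")
    if (length < width)
      stop("rounded_rectangle requires length >= width (got length = ",
           length, ", width = ", width, ")")
    g <- list(kind = kind, length = length, width = width,
              c = (length - width) / 2, r = width / 2)
    g$area <- (length - width) * width + pi * g$r^2
  } else {
    if (is.null(diameter))
      stop("circle requires `diameter`")
    if (!is.finite(diameter) || diameter <= 0)
      stop("geometry dimensions must be positive and finite")
    g <- list(kind = kind, diameter = diameter, c = 0, r = diameter / 2)
    g$area <- pi * g$r^2
  }
  class(g) <- "nucleoid_geometry"
  g
}

#' @export
print.nucleoid_geometry <- function(x, ...) {
  if (x$kind == "rounded_rectangle") {
    cat(sprintf("<nucleoid_geometry> rounded rectangle %.3g x %.3g um (area %.4g um^2)\n",
                x$length, x$width, x$area))
  } else {
    cat(sprintf("<nucleoid_geometry> circle, diameter %.3g um (area %.4g um^2)\n",
                x$diameter, x$area))
  }
  invisible(x)
}

#' Default rod-shaped nucleoid (2.5 um x 0.6 um rounded rectangle)
#' @return A `nucleoid_geometry`.
#' @export
geom_rod <- function() make_geometry("rounded_rectangle", length = 2.5, width = 0.6)

#' Default circular nucleoid (1.7 um diameter)
#' @return A `nucleoid_geometry`.
#' @export
geom_circle <- function() make_geometry("circle", diameter = 1.7)

# distance from (x, y) to the core segment [(-c,0),(c,0)]; vectorized
seg_dist <- function(geom, x, y) {
  cx <- pmin(pmax(x, -geom$c), geom$c)
  sqrt((x - cx)^2 + y^2)
}

#' Point containment test
#'
#' @param geom A [make_geometry()] object.
#' @param x,y Coordinates in um; `x` may be an n x 2 matrix (then `y` is
#'   ignored). Vectorized.
#' @return Logical vector: `TRUE` iff the point is inside or on the boundary.
#' @export
geom_contains <- function(geom, x, y = NULL) {
  stopifnot(inherits(geom, "nucleoid_geometry"))
  if (is.matrix(x)) { y <- x[, 2]; x <- x[, 1] }
  stopifnot(all(is.finite(x)), all(is.finite(y)), length(x) == length(y))
  seg_dist(geom, x, y) <= geom$r + 1e-12
}

#' Maximum extent of the domain along its longest axis (um)
#' @param geom A `nucleoid_geometry`.
#' @return The tip-to-tip length (rounded rectangle) or diameter (circle).
#' @export
geom_extent <- function(geom) 2 * (geom$c + geom$r)

#' Reflect a proposed displacement back into the domain
#'
#' Implements the reflective boundary condition: a step from `p_from` (inside)
#' to `p_to` that crosses the boundary is specularly reflected about the local
#' boundary tangent at the crossing point, iteratively until the endpoint lies
#' inside. Deterministic given its inputs.
#'
#' @param geom A `nucleoid_geometry`.
#' @param p_from Numeric length-2 start point, must be inside the domain.
#' @param p_to Numeric length-2 proposed end point.
#' @param max_iter Reflection iteration cap; after the cap the point is
#'   projected just inside the boundary (only reachable for pathological
#'   grazing steps).
#' @return A length-2 point inside the domain. Equals `p_to` when `p_to` is
#'   already inside.
#' @export
reflect_into <- function(geom, p_from, p_to, max_iter = 16L) {
  stopifnot(inherits(geom, "nucleoid_geometry"),
            length(p_from) == 2, length(p_to) == 2,
            all(is.finite(p_from)), all(is.finite(p_to)))
  if (seg_dist(geom, p_from[1], p_from[2]) > geom$r + 1e-9)
    stop("reflect_into: p_from lies outside the domain")
  disp <- sqrt(sum((p_to - p_from)^2))
  if (disp > geom_extent(geom))
    stop("reflect_into: displacement ", signif(disp, 3),
         " um exceeds the domain extent; timestep is unstable")
  .Call(`_mcdpos_cpp_reflect_into`, geom$c, geom$r,
        as.numeric(p_from), as.numeric(p_to), as.integer(max_iter))
}

#' Discretize the nucleoid into a square lattice of McdA binding sites
#'
#' Site centers sit on the grid `(i * spacing, j * spacing)` for integer
#' `(i, j)` (so the origin is always a site center) and only in-domain
#' centers are kept. All sites start empty.
#'
#' @param geom A `nucleoid_geometry`.
#' @param spacing Grid spacing in um (default 0.02, sub-cargo resolution).
#' @return An object of class `mcda_lattice`: fields `spacing`, site
#'   coordinates `x`, `y`, grid indices `i`, `j`, logical `occupied` and
#'   `tethered` vectors, and `n_sites`.
#' @examples
#' lat <- build_lattice(geom_rod(), spacing = 0.05)
#' lat$n_sites
#' @export
build_lattice <- function(geom, spacing = 0.02) {
  stopifnot(inherits(geom, "nucleoid_geometry"))
  if (!is.finite(spacing) || spacing <= 0)
    stop("lattice spacing must be positive")
  xmax <- geom$c + geom$r
  imax <- floor(xmax / spacing + 1e-9)
  jmax <- floor(geom$r / spacing + 1e-9)
  grid <- expand.grid(i = seq.int(-imax, imax), j = seq.int(-jmax, jmax))
  gx <- grid$i * spacing
  gy <- grid$j * spacing
  keep <- geom_contains(geom, gx, gy)
  if (!any(keep)) stop("lattice spacing too large: no site fits the domain")
  lat <- list(spacing = spacing,
              x = gx[keep], y = gy[keep],
              i = as.integer(grid$i[keep]), j = as.integer(grid$j[keep]),
              occupied = logical(sum(keep)),
              tethered = logical(sum(keep)),
              n_sites = sum(keep))
  class(lat) <- "mcda_lattice"
  lat
}

#' @export
print.mcda_lattice <- function(x, ...) {
  cat(sprintf("<mcda_lattice> %d sites, spacing %.3g um, %d occupied (%d tethered)\n",
              x$n_sites, x$spacing, sum(x$occupied), sum(x$tethered)))
  invisible(x)
}

#' Number of occupied sites on a lattice
#' @param lattice An `mcda_lattice`.
#' @return Integer count.
#' @export
occupied_count <- function(lattice) sum(lattice$occupied)
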