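#' Arena geometry for a two-zone oblong self-administration arena
#'
#' Describes the oblong arena used for single-fly operant sessions. The long
#' axis (`x`) is split at `boundary` into the region of self-administration
#' (ROSA), where presence triggers stimulus delivery through a port at that
#' end, and the non-self-administration region (NoSA), whose end carries the
#' vacuum port. Coordinates follow image convention: origin at the top-left,
#' `x` along the long axis, `y` down, all in physical units unless stated
#' otherwise.
#'
#' The default dimensions are placeholders for a generic oblong chamber; real
#' analyses should supply the measured arena via the arguments or
#' [read_geometry()].
#'
#' @param length Arena extent along the long axis (physical units, > 0).
#' @param width Arena extent along the short axis (> 0).
#' @param boundary Position on the long axis splitting ROSA from NoSA.
#'   Defaults to `boundary_frac * length`.
#' @param boundary_frac Fraction of `length` at which to place the boundary
#'   when `boundary` is not given (default 0.5: half the chamber).
#' @param rosa_side Which end of the long axis is ROSA: `"high"` (x >
#'   boundary) or `"low"` (x < boundary).
#' @param rosa_port,nosa_port Length-2 numeric `c(x, y)` port locations.
#'   Default: centered on the short axis at the corresponding end wall.
#' @param px_per_unit Pixel-to-physical calibration scalar (> 0): how many
#'   pixels per physical unit.
#' @param boundary_to Region that claims points lying exactly on the
#'   boundary. Default `"nosa"`: the stimulus valve should not open on the
#'   exact boundary (conservative onset); set `"rosa"` for the opposite
#'   convention.
#' @return An object of class `arena_geometry`.
#' @examples
#' g <- arena_geometry(length = 10, width = 2)
#' assign_region(7.3, 1.0, g)
#' depth_toward_port(7.5, g, "ROSA")
#' @export
arena_geometry <- function(length = 10, width = 2, boundary = NULL,
                           boundary_frac = 0.5,
                           rosa_side = c("high", "low"),
                           rosa_port = NULL, nosa_port = NULL,
                           px_per_unit = 10,
                           boundary_to = c("nosa", "rosa")) {
  rosa_side <- match.arg(rosa_side)
  boundary_to <- match.arg(boundary_to)
  stopifnot(is.numeric(length), length > 0, is.numeric(width), width > 0)
  if (is.null(boundary)) boundary <- boundary_frac * length
  if (!(boundary > 0 && boundary < length))
    stop("`boundary` must lie strictly inside (0, length)")
  if (!(is.numeric(px_per_unit) && px_per_unit > 0))
    stop("`px_per_unit` must be a positive scalar")
  rosa_x <- if (rosa_side == "high") length else 0
  nosa_x <- if (rosa_side == "high") 0 else length
  if (is.null(rosa_port)) rosa_port <- c(rosa_x, width / 2)
  if (is.null(nosa_port)) nosa_port <- c(nosa_x, width / 2)
  check_port <- function(p, nm) {
    if (!(is.numeric(p) && base::length(p) == 2 && all(is.finite(p))))
      stop(sprintf("`%s` must be a finite c(x, y) pair", nm))
    if (p[1] < 0 || p[1] > length || p[2] < 0 || p[2] > width)
      stop(sprintf("`%s` lies outside the arena rectangle", nm))
  }
  check_port(rosa_port, "rosa_port")
  check_port(nosa_port, "nosa_port")
  structure(
    list(length = length, width = width, boundary = boundary,
         rosa_side = rosa_side, rosa_port = as.numeric(rosa_port),
         nosa_port = as.numeric(nosa_port), px_per_unit = px_per_unit,
         boundary_to = boundary_to),
    class = "arena_geometry")
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat(sprintf(
    "<arena_geometry> %g x %g, boundary at %g (ROSA = %s-x side, boundary -> %s)\n",
    x$length, x$width, x$boundary, x$rosa_side, toupper(x$boundary_to)))
  cat(sprintf("  ROSA port (%g, %g); NoSA port (%g, %g); %g px/unit\n",
              x$rosa_port[1], x$rosa_port[2], x$nosa_port[1], x$nosa_port[2],
              x$px_per_unit))
  invisible(x)
}

check_inside <- function(x, y, g, frame = NULL) {
  bad <- which(!(is.finite(x) & is.finite(y) &
                   x >= 0 & x <= g$length & y >= 0 & y <= g$width))
  if (length(bad)) {
    id <- if (is.null(frame)) bad[1] - 1L else frame[bad[1]]
    stop(sprintf("point outside arena at frame %s: (%.4g, %.4g)",
                 id, x[bad[1]], y[bad[1]]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Assign points to ROSA or NoSA
#'
#' Labels positions with the region they occupy. Points strictly past the
#' boundary on the ROSA side are ROSA; everything else, including points
#' exactly on the boundary under the default convention, is NoSA (see
#' `boundary_to` in [arena_geometry()]).
#'
#' @param x,y Numeric position vectors (physical units, recycled).
#' @param g An [arena_geometry()].
#' @param frame Optional frame indices used in out-of-bounds error messages.
#' @return Character vector of `"ROSA"` / `"NoSA"` labels.
#' @export
assign_region <- function(x, y = 0, g, frame = NULL) {
  check_inside(x, rep_len(y, length(x)), g, frame)
  in_rosa <- region_mask(x, g)
  ifelse(in_rosa, "ROSA", "NoSA")
}

# Logical ROSA membership along the long axis; no bounds checking.
region_mask <- function(x, g) {
  if (g$rosa_side == "high") {
    if (g$boundary_to == "nosa") x > g$boundary else x >= g$boundary
  } else {
    if (g$boundary_to == "nosa") x < g$boundary else x <= g$boundary
  }
}

#' Signed penetration depth toward a region's port
#'
#' Signed distance along the long axis from the ROSA/NoSA boundary toward the
#' named region's port: positive when the point is inside that region,
#' negative on the other side, zero exactly on the boundary. This is the
#' "depth" session metric (maximum proximity to the delivery port); it is
#' monotone in port proximity in an oblong arena and insensitive to lateral
#' wobble. Set `metric = "euclidean"` for straight-line distance travelled
#' toward the port instead (port distance at the boundary minus port distance
#' at the point, so the sign convention is preserved).
#'
#' @inheritParams assign_region
#' @param region `"ROSA"` or `"NoSA"`.
#' @param metric `"axis"` (default) or `"euclidean"`.
#' @return Numeric vector of signed depths (physical units).
#' @export
depth_toward_port <- function(x, g, region = c("ROSA", "NoSA"),
                              y = NULL, metric = c("axis", "euclidean")) {
  region <- match.arg(region)
  metric <- match.arg(metric)
  if (metric == "axis") {
    toward_high <- (g$rosa_side == "high") == (region == "ROSA")
    if (toward_high) x - g$boundary else g$boundary - x
  } else {
    if (is.null(y)) stop("`y` is required for the euclidean depth metric")
    port <- if (region == "ROSA") g$rosa_port else g$nosa_port
    d_pt <- sqrt((x - port[1])^2 + (y - port[2])^2)
    d_boundary <- sqrt((g$boundary - port[1])^2 + (y - port[2])^2)
    d_boundary - d_pt
  }
}

#' Convert a pixel length to physical units
#'
#' Linear calibration: `px / px_per_unit`.
#'
#' @param px Pixel length(s), >= 0 for lengths (signed values allowed for
#'   coordinates).
#' @param g An [arena_geometry()] carrying `px_per_unit`.
#' @return Length(s) in physical units.
#' @export
calibrate <- function(px, g) {
  if (!(g$px_per_unit > 0)) stop("non-positive calibration factor")
  px / g$px_per_unit
}

#' Read arena geometry from a YAML or JSON config file
#'
#' Recognized keys: `length`, `width`, `boundary` or `boundary_frac`,
#' `rosa_side`, `rosa_port`, `nosa_port`, `px_per_unit`, `boundary_to`.
#' Missing keys fall back to the [arena_geometry()] defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `arena_geometry`.
#' @export
read_geometry <- function(path) {
  cfg <- read_config(path)
  allowed <- c("length", "width", "boundary", "boundary_frac", "rosa_side",
               "rosa_port", "nosa_port", "px_per_unit", "boundary_to")
  extra <- setdiff(names(cfg), allowed)
  if (length(extra))
    warning("ignoring unknown geometry keys: ", paste(extra, collapse = ", "))
  do.call(arena_geometry, cfg[intersect(names(cfg), allowed)])
}

read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
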