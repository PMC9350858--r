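#' Signed-distance-function primitives and CSG combinators
#'
#' Constructors for implicit shapes. Every node evaluates to a signed
#' Euclidean distance: negative inside the shape, zero on its surface,
#' positive outside. Exact primitives are 1-Lipschitz and satisfy the eikonal
#' property `|grad D| = 1` away from the medial axis, which is what makes
#' sphere tracing safe: a step of length `|D|` can never cross a surface.
#'
#' Primitives are defined in a canonical local frame (centred at the origin,
#' cylinder axis along z). `center` is a convenience that wraps the node in a
#' rigid [sdf_transform()]. Only rigid transforms are offered because they
#' preserve the exact-distance property; scaling/twisting would not.
#'
#' `sdf_smooth_union()` uses the quadratic polynomial smooth-minimum with
#' blend radius `k`: it equals the plain union whenever `|d1 - d2| >= k` and
#' is a bounded (conservative) distance, not an exact one, inside the blend.
#'
#' @param r radius (cm, > 0).
#' @param center optional translation of the shape's local origin (cm).
#' @param half box half-extents, length-3 (cm, > 0).
#' @param a,b capsule segment endpoints (cm); must be distinct.
#' @param half_height cylinder half-height along its local z axis (cm, > 0).
#' @param x,y child nodes to combine.
#' @param k smooth-union blend radius (cm, > 0).
#' @param node child node to transform.
#' @param rotation 3x3 proper orthonormal matrix mapping the child's local
#'   frame into the world frame.
#' @param translation length-3 translation (cm).
#'
#' @return An object of class `sdf_node`.
#' @examples
#' s <- sdf_sphere(0.5)
#' sdf_distance(s, c(0, 0, 0))    # -0.5 at the centre
#' shell <- sdf_subtraction(sdf_cylinder(2, 1.75), sdf_cylinder(2.1, 1.55))
#' @name sdf_primitives
NULL

new_sdf <- function(.kind, ...) {
  # dotted formal: a literal `k =` argument must not partially match it
  structure(c(list(kind = .kind), list(...)), class = "sdf_node")
}

maybe_center <- function(node, center) {
  stopifnot(is.numeric(center), length(center) == 3L, all(is.finite(center)))
  if (all(center == 0)) node
  else sdf_transform(node, translation = center)
}

#' @rdname sdf_primitives
#' @export
sdf_sphere <- function(r, center = c(0, 0, 0)) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("sphere radius r must be a positive scalar")
  maybe_center(new_sdf("sphere", r = r), center)
}

#' @rdname sdf_primitives
#' @export
sdf_box <- function(half, center = c(0, 0, 0)) {
  if (!is.numeric(half) || length(half) != 3L || any(!is.finite(half)) || any(half <= 0))
    stop("box half-extents must be three positive numbers")
  maybe_center(new_sdf("box", half = as.numeric(half)), center)
}

#' @rdname sdf_primitives
#' @export
sdf_capsule <- function(a, b, r) {
  stopifnot(is.numeric(a), length(a) == 3L, is.numeric(b), length(b) == 3L)
  if (!is.numeric(r) || length(r) != 1L || r <= 0)
    stop("capsule radius r must be a positive scalar")
  if (sqrt(sum((b - a)^2)) == 0) stop("capsule segment is degenerate (a == b)")
  new_sdf("capsule", a = as.numeric(a), b = as.numeric(b), r = r)
}

#' @rdname sdf_primitives
#' @export
sdf_cylinder <- function(half_height, r, center = c(0, 0, 0)) {
  if (!is.numeric(half_height) || length(half_height) != 1L || half_height <= 0)
    stop("cylinder half_height must be a positive scalar")
  if (!is.numeric(r) || length(r) != 1L || r <= 0)
    stop("cylinder radius r must be a positive scalar")
  maybe_center(new_sdf("cylinder", half_height = half_height, r = r), center)
}

#' @rdname sdf_primitives
#' @export
sdf_union <- function(x, y) {
  stopifnot(inherits(x, "sdf_node"), inherits(y, "sdf_node"))
  new_sdf("union", children = list(x, y))
}

#' @rdname sdf_primitives
#' @export
sdf_smooth_union <- function(x, y, k) {
  stopifnot(inherits(x, "sdf_node"), inherits(y, "sdf_node"))
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("smooth_union blend radius k must be a positive scalar")
  new_sdf("smooth_union", k = k, children = list(x, y))
}

#' @rdname sdf_primitives
#' @export
sdf_intersection <- function(x, y) {
  stopifnot(inherits(x, "sdf_node"), inherits(y, "sdf_node"))
  new_sdf("intersection", children = list(x, y))
}

#' @rdname sdf_primitives
#' @export
sdf_subtraction <- function(x, y) {
  stopifnot(inherits(x, "sdf_node"), inherits(y, "sdf_node"))
  new_sdf("subtraction", children = list(x, y))
}

#' @rdname sdf_primitives
#' @export
sdf_transform <- function(node, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(node, "sdf_node"))
  check_rotation(rotation)
  stopifnot(is.numeric(translation), length(translation) == 3L,
            all(is.finite(translation)))
  new_sdf("transform", rotation = rotation,
          translation = as.numeric(translation), children = list(node))
}

check_rotation <- function(R) {
  if (!is.matrix(R) || any(dim(R) != c(3L, 3L)) || !is.numeric(R))
    stop("rotation must be a numeric 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    stop("rotation matrix is not orthonormal")
  if (abs(det(R) - 1) > 1e-8)
    stop("rotation matrix must be proper (det = +1, right-handed)")
  invisible(TRUE)
}

#' Evaluate a signed distance field
#'
#' @param node an `sdf_node`.
#' @param p a length-3 point or an n x 3 matrix of points (cm, world frame).
#' @return Signed distance(s) in cm: negative inside, positive outside.
#' @export
sdf_distance <- function(node, p) {
  stopifnot(inherits(node, "sdf_node"))
  p <- as_points(p)
  d <- cpp_sdf_eval(unclass_tree(node), p)
  if (nrow(p) == 1L) d[[1L]] else d
}

as_points <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 3L) stop("points must be a length-3 vector or an n x 3 matrix")
    storage.mode(p) <- "double"
    p
  } else {
    if (length(p) != 3L) stop("points must be a length-3 vector or an n x 3 matrix")
    matrix(as.numeric(p), nrow = 1L)
  }
}

# strip S3 classes so Rcpp sees plain lists all the way down
unclass_tree <- function(node) {
  node <- unclass(node)
  if (!is.null(node$children))
    node$children <- lapply(node$children, unclass_tree)
  node
}

#' Surface normal by central differences
#'
#' The gradient of a signed distance field on the zero level set is the
#' outward unit surface normal. It is estimated by central differences with
#' step `h` and then normalised. A zero gradient (a medial-axis point, e.g.
#' the exact centre of a box) is an error.
#'
#' @param node an `sdf_node`.
#' @param p a point near the surface (cm).
#' @param h finite-difference step (cm). The default 1e-6 cm is much smaller
#'   than mm-scale features yet far above double-precision noise.
#' @return Outward unit normal (length-3).
#' @export
surface_normal <- function(node, p, h = 1e-6) {
  stopifnot(inherits(node, "sdf_node"))
  cpp_sdf_normal(unclass_tree(node), as.numeric(p), h)
}

#' Combine two signed distances with a CSG operator
#'
#' Scalar CSG algebra on distance values: `union = min`,
#' `intersection = max`, `subtraction = max(d1, -d2)` and `smooth_union` the
#' quadratic smooth-minimum `min(d1, d2) - h^2 k / 4` with
#' `h = max(k - |d1 - d2|, 0) / k`.
#'
#' @param kind one of `"union"`, `"intersection"`, `"subtraction"`,
#'   `"smooth_union"`.
#' @param d1,d2 signed distances (cm); vectorised.
#' @param k blend radius for `smooth_union` (cm, > 0).
#' @return Combined signed distance(s) in cm.
#' @export
csg_combine <- function(kind, d1, d2, k = NULL) {
  switch(kind,
    union = pmin(d1, d2),
    intersection = pmax(d1, d2),
    subtraction = pmax(d1, -d2),
    smooth_union = {
      if (is.null(k) || !is.numeric(k) || k <= 0)
        stop("smooth_union needs a blend radius k > 0")
      h <- pmax(k - abs(d1 - d2), 0) / k
      pmin(d1, d2) - h * h * k / 4
    },
    stop(sprintf("unknown CSG kind: '%s'", kind))
  )
}

#' Map a world point into a rigidly transformed local frame
#'
#' Returns the inverse-transformed point `t(R) %*% (p - translation)` so that
#' a child SDF defined in its local frame can be evaluated at a world point.
#' Rigid maps preserve distances, so the transformed field is still an exact
#' SDF.
#'
#' @param p world point (length-3, cm).
#' @param rotation 3x3 proper orthonormal local-to-world rotation.
#' @param translation length-3 translation (cm).
#' @return The point expressed in the local frame.
#' @export
transform_point <- function(p, rotation = diag(3), translation = c(0, 0, 0)) {
  check_rotation(rotation)
  as.numeric(crossprod(rotation, as.numeric(p) - as.numeric(translation)))
}

#' @export
print.sdf_node <- function(x, ...) {
  describe <- function(nd, ind) {
    pad <- strrep("  ", ind)
    extra <- switch(nd$kind,
      sphere = sprintf("r = %g", nd$r),
      box = sprintf("half = (%g, %g, %g)", nd$half[1], nd$half[2], nd$half[3]),
      capsule = sprintf("r = %g", nd$r),
      cylinder = sprintf("hh = %g, r = %g", nd$half_height, nd$r),
      smooth_union = sprintf("k = %g", nd$k),
      transform = sprintf("t = (%g, %g, %g)", nd$translation[1],
                          nd$translation[2], nd$translation[3]),
      "")
    cat(pad, nd$kind, if (nzchar(extra)) paste0(" [", extra, "]"), "\n", sep = "")
    for (ch in nd$children %||% list()) describe(ch, ind + 1L)
  }
  describe(x, 0L)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
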