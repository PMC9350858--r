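#' Scene assembly
#'
#' A scene is a list of material regions (an SDF root plus an
#' [optical_medium()] and an integer layer priority), an axis-aligned
#' bounding box whose exterior terminates photon packets, an ambient medium
#' filling space not claimed by any region, and the sphere-tracing surface
#' threshold `delta_s`.
#'
#' Where regions overlap (e.g. vessels embedded in a tissue slab) the medium
#' of the highest `layer` wins; ties go to the earlier-declared region. The
#' bounding box itself is not a refractive interface: packets that reach it
#' simply escape.
#'
#' @param ... one or more regions created with [sdf_region()] (or a single
#'   list of them).
#' @param bbox_center,bbox_half centre and half-extents of the bounding box
#'   (cm).
#' @param ambient [optical_medium()] outside every region (default: vacuum
#'   with n = 1).
#' @param delta_s sphere-tracing surface threshold (cm, > 0). Must be far
#'   smaller than the smallest geometric feature; default 1e-6 cm.
#' @param normal_h central-difference step for surface normals (cm); defaults
#'   to `delta_s`.
#' @param step_cap maximum sphere-tracing steps per packet, bounding the
#'   grazing-incidence pathology; capped packets are tallied, not dropped
#'   silently.
#' @return An object of class `mcrt_scene`.
#' @examples
#' sc <- scene(
#'   sdf_region(sdf_sphere(0.5), optical_medium(mu_s = 20, g = 0)),
#'   bbox_half = c(1, 1, 1)
#' )
#' @export
scene <- function(..., bbox_center = c(0, 0, 0), bbox_half,
                  ambient = optical_medium(), delta_s = 1e-6,
                  normal_h = delta_s, step_cap = 1e6) {
  regions <- list(...)
  if (length(regions) == 1L && !inherits(regions[[1L]], "sdf_region") &&
      is.list(regions[[1L]]))
    regions <- regions[[1L]]
  if (!all(vapply(regions, inherits, logical(1), "sdf_region")))
    stop("scene regions must be created with sdf_region()")
  stopifnot(is.numeric(bbox_center), length(bbox_center) == 3L,
            is.numeric(bbox_half), length(bbox_half) == 3L)
  if (any(bbox_half <= 0)) stop("bbox half-extents must be > 0")
  if (!is_medium(ambient)) stop("ambient must be an optical_medium")
  if (!is.numeric(delta_s) || delta_s <= 0) stop("delta_s must be > 0")
  sc <- structure(
    list(
      regions = lapply(regions, function(r)
        list(node = unclass_tree(r$node), medium = medium_as_list(r$medium),
             layer = as.integer(r$layer), name = r$name)),
      bbox = list(center = as.numeric(bbox_center), half = as.numeric(bbox_half)),
      ambient = medium_as_list(ambient),
      delta_s = delta_s, normal_h = normal_h, step_cap = step_cap
    ),
    class = "mcrt_scene"
  )
  check_regions_inside(sc)
  sc
}

#' Declare a material region
#'
#' @param node an [sdf_node][sdf_primitives] defining the region (interior =
#'   negative distance).
#' @param medium the region's [optical_medium()].
#' @param layer integer priority used where regions overlap; higher wins.
#' @param name optional label used in printouts.
#' @return An object of class `sdf_region`.
#' @export
sdf_region <- function(node, medium, layer = 0L, name = NULL) {
  stopifnot(inherits(node, "sdf_node"))
  if (!is_medium(medium)) stop("medium must be an optical_medium")
  structure(list(node = node, medium = medium, layer = as.integer(layer),
                 name = name),
            class = "sdf_region")
}

# coarse guard: sample each bbox face; a region interior reaching the face
# means the shape pokes out of the simulation volume
check_regions_inside <- function(sc, n = 5L) {
  ctr <- sc$bbox$center; hf <- sc$bbox$half
  u <- seq(-1, 1, length.out = n)
  gr <- as.matrix(expand.grid(u, u))
  faces <- rbind(
    cbind(1, gr[, 1], gr[, 2]), cbind(-1, gr[, 1], gr[, 2]),
    cbind(gr[, 1], 1, gr[, 2]), cbind(gr[, 1], -1, gr[, 2]),
    cbind(gr[, 1], gr[, 2], 1), cbind(gr[, 1], gr[, 2], -1))
  pts <- sweep(sweep(faces, 2, hf, "*"), 2, ctr, "+")
  for (i in seq_along(sc$regions)) {
    d <- cpp_sdf_eval(sc$regions[[i]]$node, pts)
    if (any(d < 0))
      warning(sprintf("region %d reaches the scene bounding box; photons will be cut off there", i))
  }
  invisible(sc)
}

scene_as_list <- function(sc) unclass(sc)

#' Nearest surface in a scene
#'
#' Returns the minimum over all regions of the *unsigned* distance to their
#' surfaces, which is the sphere-tracing marching step: using the magnitude
#' means the same loop traces both inside and outside shapes.
#'
#' @param sc an [scene()].
#' @param p a world point (length-3, cm).
#' @return A list with `distance` (cm, >= 0) and `region` (index of the
#'   arg-min region).
#' @export
scene_distance <- function(sc, p) {
  stopifnot(inherits(sc, "mcrt_scene"))
  if (length(sc$regions) == 0L) stop("scene has no regions")
  cpp_scene_distance(scene_as_list(sc), as.numeric(p))
}

#' Medium at a point
#'
#' Among regions whose SDF is negative at `p`, the one with the highest
#' layer (earliest declared on ties) provides the medium; if none, the
#' ambient medium. Points outside the bounding box are an error.
#'
#' @param sc an [scene()].
#' @param p a world point (length-3, cm) inside the bounding box.
#' @return An [optical_medium()].
#' @export
medium_at <- function(sc, p) {
  stopifnot(inherits(sc, "mcrt_scene"))
  idx <- cpp_region_at(scene_as_list(sc), as.numeric(p))
  m <- if (idx == 0L) sc$ambient else sc$regions[[idx]]$medium
  do.call(optical_medium, m)
}

region_index_at <- function(sc, p) {
  cpp_region_at(scene_as_list(sc), as.numeric(p))
}

#' Rasterise a scene onto a voxel grid
#'
#' Labels each voxel with the index of the region claiming its centre
#' (0 = ambient), following the same layer rule as [medium_at()]. Intended
#' for export and visual checks only -- transport never uses voxels.
#'
#' @param sc an [scene()].
#' @param grid a [fluence_grid()] (must lie inside the bounding box).
#' @return An integer array of dimension `grid$dims`.
#' @export
rasterize <- function(sc, grid) {
  stopifnot(inherits(sc, "mcrt_scene"), inherits(grid, "fluence_grid"))
  lo <- grid$origin
  hi <- grid$origin + grid$dims * grid$spacing
  blo <- sc$bbox$center - sc$bbox$half
  bhi <- sc$bbox$center + sc$bbox$half
  if (any(lo < blo - 1e-12) || any(hi > bhi + 1e-12))
    stop("rasterisation grid exceeds the scene bounding box")
  v <- cpp_rasterize(scene_as_list(sc), grid$dims, grid$origin, grid$spacing)
  array(v, dim = grid$dims)
}

#' @export
print.mcrt_scene <- function(x, ...) {
  cat(sprintf("<mcrt_scene> %d region(s), bbox half = (%g, %g, %g) cm, delta_s = %g cm\n",
              length(x$regions), x$bbox$half[1], x$bbox$half[2], x$bbox$half[3],
              x$delta_s))
  for (i in seq_along(x$regions)) {
    r <- x$regions[[i]]
    cat(sprintf("  [%d] %s layer %d: mu_s = %g, mu_a = %g, g = %g, n = %g\n",
                i, r$name %||% r$node$kind, r$layer, r$medium$mu_s,
                r$medium$mu_a, r$medium$g, r$medium$n))
  }
  invisible(x)
}
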