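#' Fluence recording grid
#'
#' An axis-aligned voxel lattice that accumulates `weight x path length`
#' (cm) per voxel during transport -- the path-length fluence estimator.
#' Voxels are half-open intervals `[edge, next edge)`; a point exactly on
#' the upper grid edge belongs to the last voxel.
#'
#' @param lower,upper opposite corners of the grid (cm, length-3).
#' @param dims number of voxels per axis (length-3 integers).
#' @return An object of class `fluence_grid` with `dims`, `origin` (= lower
#'   corner) and `spacing` (cm/voxel).
#' @export
fluence_grid <- function(lower, upper, dims) {
  stopifnot(is.numeric(lower), length(lower) == 3L,
            is.numeric(upper), length(upper) == 3L,
            length(dims) == 3L)
  dims <- as.integer(dims)
  if (any(dims < 1L)) stop("grid dims must be >= 1")
  if (any(upper <= lower)) stop("upper must exceed lower on every axis")
  structure(list(dims = dims, origin = as.numeric(lower),
                 spacing = (as.numeric(upper) - as.numeric(lower)) / dims),
            class = "fluence_grid")
}

voxel_volume <- function(grid) prod(grid$spacing)

grid_as_list <- function(grid) unclass(grid)[c("dims", "origin", "spacing")]

#' Deposit a path segment into an accumulator
#'
#' Splits the segment `p0 -> p1` at voxel faces by 3D digital differential
#' analysis and credits each voxel with `weight x` (sub-segment length
#' inside it), so the total deposited equals `weight x |p1 - p0|` exactly
#' (up to clipping at the grid boundary). This is the estimator used
#' internally by [mcrt_run()]; it is exposed for testing and custom tallies.
#'
#' @param grid a [fluence_grid()].
#' @param p0,p1 segment endpoints (cm).
#' @param weight statistical weight of the packet.
#' @param accum optional existing accumulator array (dimension `grid$dims`);
#'   a zero array is created when omitted.
#' @return The updated accumulator array.
#' @export
deposit_path <- function(grid, p0, p1, weight = 1, accum = NULL) {
  stopifnot(inherits(grid, "fluence_grid"))
  if (is.null(accum)) accum <- array(0, dim = grid$dims)
  if (!identical(dim(accum), grid$dims)) stop("accumulator dims do not match grid")
  out <- cpp_deposit_path(grid$dims, grid$origin, grid$spacing,
                          as.numeric(accum), as.numeric(p0), as.numeric(p1),
                          weight)
  array(out, dim = grid$dims)
}

#' Convert an accumulated run into fluence
#'
#' Per-voxel fluence is `accumulator x source_power / (n_photons x voxel
#' volume)`: with the path-length estimator the expected accumulator per
#' packet is the fluence integrated over the voxel, so this normalisation
#' yields fluence rate in (source power units) cm^-2.
#'
#' @param run an [mcrt_run()] result carrying an accumulator, or a raw
#'   accumulator array.
#' @param grid the [fluence_grid()] used in the run (taken from `run` when
#'   available).
#' @param n_photons number of launched packets (taken from `run` when
#'   available).
#' @param source_power total source power (W); default 1.
#' @return An object of class `fluence_volume`: the fluence array plus grid
#'   metadata.
#' @export
finalize_fluence <- function(run, grid = NULL, n_photons = NULL,
                             source_power = 1) {
  if (inherits(run, "mcrt_run")) {
    if (is.null(run$accumulator)) stop("run was executed without a grid")
    grid <- grid %||% run$grid
    n_photons <- n_photons %||% run$n_photons
    acc <- run$accumulator
  } else {
    acc <- run
  }
  if (is.null(grid) || is.null(n_photons)) stop("grid and n_photons are required")
  if (n_photons <= 0) stop("n_photons must be positive")
  structure(list(
    fluence = acc * source_power / (n_photons * voxel_volume(grid)),
    grid = grid, n_photons = n_photons, source_power = source_power
  ), class = "fluence_volume")
}

#' Absorbed power density map
#'
#' Multiplies the fluence by the absorption coefficient of the medium at
#' each voxel centre: `A = fluence x mu_a` (power per unit volume).
#'
#' @param fv a [finalize_fluence()] result.
#' @param sc the [scene()] the fluence was computed in.
#' @return An array of absorbed power density with the grid's dimensions.
#' @export
absorption_map <- function(fv, sc) {
  stopifnot(inherits(fv, "fluence_volume"), inherits(sc, "mcrt_scene"))
  labels <- rasterize(sc, fv$grid)
  mua <- c(sc$ambient$mu_a,
           vapply(sc$regions, function(r) r$medium$mu_a, numeric(1)))
  fv$fluence * array(mua[labels + 1L], dim = fv$grid$dims)
}

#' Depth profile of a fluence volume
#'
#' Averages fluence over transverse voxels at each depth along one axis.
#'
#' @param fv a [finalize_fluence()] result.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param i,j optional index vectors selecting the transverse voxels to
#'   average over (defaults: all), e.g. a central window away from lateral
#'   edges.
#' @return A data frame with the voxel-centre coordinate along `axis` and
#'   the mean `fluence`.
#' @export
depth_profile <- function(fv, axis = "z", i = NULL, j = NULL) {
  stopifnot(inherits(fv, "fluence_volume"))
  ax <- match(axis, c("x", "y", "z"))
  if (is.na(ax)) stop("axis must be one of 'x', 'y', 'z'")
  tr <- setdiff(1:3, ax)
  d <- fv$grid$dims
  i <- i %||% seq_len(d[tr[1]])
  j <- j %||% seq_len(d[tr[2]])
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  idx[[tr[1]]] <- i
  idx[[tr[2]]] <- j
  sub <- fv$fluence[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  prof <- apply(sub, ax, mean)
  coord <- fv$grid$origin[ax] + (seq_len(d[ax]) - 0.5) * fv$grid$spacing[ax]
  out <- data.frame(coord = coord, fluence = prof)
  names(out)[1] <- axis
  out
}
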