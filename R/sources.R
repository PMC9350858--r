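#' Photon sources
#'
#' Launch distributions for photon packets. Three kinds are provided:
#'
#' * `source_isotropic_point()` -- a fixed position emitting uniformly over
#'   the unit sphere (`cos(theta) = 2u - 1`, azimuth uniform).
#' * `source_uniform_top()` -- positions uniform over an axis-aligned
#'   rectangle, all packets collimated along `direction` (default `-z`);
#'   models uniform illumination of a slab's top face.
#' * `source_collimated_strip()` -- a collimated sheet beam of finite width:
#'   positions uniform over a rectangle spanned by `u_axis` (the width
#'   direction) and `v_axis`.
#'
#' Packets are emitted with unit statistical weight; the medium at the launch
#' point (via [medium_at()]) becomes the packet's starting medium. Emission
#' positions must lie inside the scene bounding box.
#'
#' @param origin emitting point / rectangle centre (cm).
#' @param half rectangle half-extents along `u_axis` and `v_axis` (cm).
#' @param direction unit propagation direction for collimated sources.
#' @param width full beam width along `u_axis` (cm).
#' @param u_axis,v_axis unit vectors spanning the emitting rectangle.
#' @return An object of class `mcrt_source`.
#' @name sources
NULL

#' @rdname sources
#' @export
source_isotropic_point <- function(origin = c(0, 0, 0)) {
  stopifnot(is.numeric(origin), length(origin) == 3L)
  structure(list(kind = "isotropic_point", origin = as.numeric(origin)),
            class = "mcrt_source")
}

#' @rdname sources
#' @export
source_uniform_top <- function(origin, half, direction = c(0, 0, -1),
                               u_axis = c(1, 0, 0), v_axis = c(0, 1, 0)) {
  rectangle_source(origin, half, direction, u_axis, v_axis)
}

#' @rdname sources
#' @export
source_collimated_strip <- function(origin, width, half_v = 0,
                                    direction = c(0, 0, -1),
                                    u_axis = c(1, 0, 0), v_axis = c(0, 1, 0)) {
  rectangle_source(origin, c(width / 2, half_v), direction, u_axis, v_axis)
}

#' @rdname sources
#' @param half_v rectangle half-extent along `v_axis` (cm); 0 collapses the
#'   strip to a line source.
rectangle_source <- function(origin, half, direction, u_axis, v_axis) {
  stopifnot(is.numeric(origin), length(origin) == 3L,
            is.numeric(half), length(half) == 2L, all(half >= 0),
            is.numeric(direction), length(direction) == 3L)
  structure(list(kind = "rectangle", origin = as.numeric(origin),
                 half = as.numeric(half), direction = as.numeric(direction),
                 u_axis = as.numeric(u_axis), v_axis = as.numeric(v_axis)),
            class = "mcrt_source")
}

#' Draw launch states from a source
#'
#' Uses the same per-packet random substreams as [mcrt_run()], so
#' `emit(src, n, seed)` reproduces exactly the launch states of a transport
#' run with the same seed.
#'
#' @param source an `mcrt_source`.
#' @param n number of packets.
#' @param seed integer seed.
#' @return A list with `position` and `direction`, both n x 3 matrices.
#' @export
emit <- function(source, n, seed = 1L) {
  stopifnot(inherits(source, "mcrt_source"))
  cpp_emit(unclass(source), as.integer(n), as.numeric(seed))
}
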