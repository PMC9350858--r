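#' Run a Monte Carlo transport simulation
#'
#' Launches `n_photons` packets from `source` and propagates each with the
#' sphere-tracing optical-depth integration loop:
#'
#' 1. draw an optical depth `tau = -log(u)`;
#' 2. compare the interaction distance `tau / mu_t` with the distance
#'    `d_sdf` to the nearest implicit surface (regions and bounding box,
#'    unsigned, so the loop works inside and outside shapes);
#' 3. if the interaction comes first, advance there and scatter (with
#'    probability albedo, Henyey-Greenstein) or terminate as absorbed;
#' 4. otherwise march by `d_sdf`, decrementing `tau` by `d_sdf x mu_t`;
#' 5. when `d_sdf` falls below the surface threshold `delta_s`, probe the
#'    media on both sides: if the refractive index changes, reflect with the
#'    Fresnel probability or refract via Snell's law on the exact implicit
#'    surface; otherwise slide through. The remaining `tau` is retained
#'    across boundaries (it is rescaled implicitly by the new medium's
#'    `mu_t`).
#' 6. a packet outside the bounding box escapes; the per-packet step cap
#'    guards against grazing-incidence stalls.
#'
#' Transport is analog: packets carry unit weight and are terminated on
#' absorption (no weight decay/roulette), which pairs naturally with the
#' path-length fluence estimator and keeps packet accounting exact:
#' `launched = absorbed + escaped + capped + degenerate`.
#'
#' Runs are reproducible: packet `i` always consumes its own random
#' substream derived from `(seed, i)`.
#'
#' @param sc a [scene()].
#' @param source an `mcrt_source` (see [sources]).
#' @param n_photons number of packets to launch.
#' @param seed integer seed for all randomness in the run.
#' @param grid optional [fluence_grid()]; when given, every path segment is
#'   deposited into its accumulator.
#' @param record_exits keep per-packet terminal positions/directions.
#' @return An object of class `mcrt_run` with packet tallies (`n_absorbed`,
#'   `n_escaped`, `n_capped`, `n_degenerate`), per-packet `n_scatters` and
#'   terminal codes, the raw `accumulator` array (when `grid` given), and
#'   exit states (when requested).
#' @examples
#' sc <- scene(sdf_region(sdf_sphere(0.5), optical_medium(mu_s = 2, g = 0)),
#'             bbox_half = c(1, 1, 1))
#' r <- mcrt_run(sc, source_isotropic_point(), n_photons = 100, seed = 7)
#' mean(r$n_scatters)
#' @export
mcrt_run <- function(sc, source, n_photons, seed = 1L, grid = NULL,
                     record_exits = FALSE) {
  stopifnot(inherits(sc, "mcrt_scene"), inherits(source, "mcrt_source"))
  n_photons <- as.integer(n_photons)
  if (n_photons < 1L) stop("n_photons must be >= 1")
  gl <- if (!is.null(grid)) {
    stopifnot(inherits(grid, "fluence_grid"))
    grid_as_list(grid)
  } else NULL
  res <- cpp_run_mcrt(scene_as_list(sc), unclass(source), n_photons,
                      as.numeric(seed), gl, record_exits)
  if (!is.null(grid)) res$accumulator <- array(res$accumulator, dim = grid$dims)
  res$terminal <- factor(res$terminal, levels = c(3L, 7L, 8L, 9L),
                         labels = c("absorbed", "escaped", "step_cap_killed",
                                    "degenerate_normal"))
  res$n_photons <- n_photons
  res$seed <- seed
  res$grid <- grid
  class(res) <- "mcrt_run"
  res
}

#' @export
print.mcrt_run <- function(x, ...) {
  cat(sprintf(
    "<mcrt_run> %d packets (seed %s): %d absorbed, %d escaped, %d capped, %d degenerate\n",
    x$n_photons, format(x$seed), x$n_absorbed, x$n_escaped, x$n_capped,
    x$n_degenerate))
  cat(sprintf("  mean scatterings per packet: %.4g\n", mean(x$n_scatters)))
  invisible(x)
}

#' Trace a single photon packet
#'
#' Propagates one packet while logging every event (launch, march, scatter,
#' absorb, boundary pass-through, reflect, refract, escape) with its
#' position and the region label after the event. Used for debugging and for
#' the transport oracles (analytic ray-surface hit points, no-tunneling
#' audits).
#'
#' @param sc a [scene()].
#' @param position,direction launch state (cm / unit vector).
#' @param seed integer seed.
#' @param substream which packet substream to consume (mirrors packet index
#'   in [mcrt_run()]).
#' @param burn uniform draws to discard before transport; set to 2 with the
#'   launch state from [emit()] to replay exactly the history of packet
#'   `substream + 1` of an [mcrt_run()] (both source kinds draw twice).
#' @return A list with a data frame `history` (event, x, y, z, region),
#'   the terminal event name, scatter count and exit state.
#' @export
propagate_trace <- function(sc, position, direction, seed = 1L, substream = 0L,
                            burn = 0L) {
  stopifnot(inherits(sc, "mcrt_scene"))
  res <- cpp_propagate_trace(scene_as_list(sc), as.numeric(position),
                             as.numeric(direction), as.numeric(seed),
                             as.integer(substream), as.integer(burn))
  labels <- c("launch", "march", "scatter", "absorb", "pass", "reflect",
              "refract", "escape", "step_cap", "degenerate_normal")
  history <- data.frame(
    event = labels[res$event + 1L],
    x = res$position[, 1], y = res$position[, 2], z = res$position[, 3],
    region = res$region
  )
  list(history = history, terminal = labels[res$terminal + 1L],
       n_scatters = res$n_scatters, exit_position = res$exit_position,
       exit_direction = res$exit_direction)
}
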