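#' Load a run configuration
#'
#' Reads a JSON scene configuration: a `scene` block (ambient medium,
#' bounding box, surface threshold, list of shapes with media and layers),
#' a `source` block, an optional `grid` block, plus `n_photons` and `seed`.
#' All lengths are cm. Unknown keys anywhere in the file are rejected so
#' typos fail loudly, and a shape without a complete `medium`
#' (`mu_s`, `mu_a`, `g`, `n`) is a named error.
#'
#' Shape entries mirror the [sdf_primitives] constructors: leaf kinds
#' `sphere` (`r`, optional `center`), `box` (`half`), `capsule`
#' (`a`, `b`, `r`), `cylinder` (`half_height`, `r`); CSG kinds `union`,
#' `smooth_union` (`k`), `intersection`, `subtraction` with a two-element
#' `children` list; and `transform` (`rotation` as a 3x3 row-major array,
#' `translation`, one child).
#'
#' @param path path to a JSON configuration file.
#' @return An object of class `mcrt_config` with parsed `scene`, `source`,
#'   `grid` (or NULL), `n_photons`, `seed`, `record_exits` and the raw
#'   configuration list (used for lossless re-serialisation).
#' @seealso [write_config()], [run_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  check_keys(raw, c("scene", "source", "grid", "n_photons", "seed",
                    "record_exits", "output"), "top level")
  for (k in c("scene", "source", "n_photons", "seed"))
    if (is.null(raw[[k]])) stop("config is missing required key '", k, "'")

  sb <- raw$scene
  check_keys(sb, c("ambient", "bbox", "delta_s", "normal_h", "step_cap",
                   "shapes"), "scene")
  if (is.null(sb$bbox) || is.null(sb$shapes)) stop("scene needs 'bbox' and 'shapes'")
  check_keys(sb$bbox, c("center", "half"), "scene.bbox")
  regions <- lapply(seq_along(sb$shapes), function(i) {
    sh <- sb$shapes[[i]]
    if (is.null(sh$medium))
      stop(sprintf("shape %d ('%s') is missing its 'medium' block", i,
                   sh$kind %||% "?"))
    med <- parse_config_medium(sh$medium, sprintf("shape %d", i))
    node <- parse_config_shape(sh[setdiff(names(sh), c("medium", "layer", "name"))],
                               sprintf("shape %d", i))
    sdf_region(node, med, layer = sh$layer %||% 0L, name = sh$name)
  })
  ambient <- if (is.null(sb$ambient)) optical_medium()
             else parse_config_medium(sb$ambient, "scene.ambient")
  sc <- scene(regions,
              bbox_center = unlist(sb$bbox$center %||% c(0, 0, 0)),
              bbox_half = unlist(sb$bbox$half),
              ambient = ambient,
              delta_s = sb$delta_s %||% 1e-6,
              normal_h = sb$normal_h %||% (sb$delta_s %||% 1e-6),
              step_cap = sb$step_cap %||% 1e6)

  src <- parse_config_source(raw$source)
  grid <- if (!is.null(raw$grid)) {
    check_keys(raw$grid, c("lower", "upper", "dims"), "grid")
    fluence_grid(unlist(raw$grid$lower), unlist(raw$grid$upper),
                 unlist(raw$grid$dims))
  } else NULL

  structure(list(scene = sc, source = src, grid = grid,
                 n_photons = as.integer(raw$n_photons),
                 seed = raw$seed,
                 record_exits = isTRUE(raw$record_exits),
                 output = raw$output, raw = raw),
            class = "mcrt_config")
}

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop(sprintf("unknown key(s) in %s: %s", where, paste(extra, collapse = ", ")))
  invisible(TRUE)
}

parse_config_medium <- function(m, where) {
  check_keys(m, c("mu_s", "mu_a", "g", "n"), paste0(where, ".medium"))
  missing <- setdiff(c("mu_s", "mu_a", "g", "n"), names(m))
  if (length(missing))
    stop(sprintf("%s medium is missing field(s): %s", where,
                 paste(missing, collapse = ", ")))
  optical_medium(mu_s = m$mu_s, mu_a = m$mu_a, g = m$g, n = m$n)
}

parse_config_shape <- function(sh, where) {
  kind <- sh$kind %||% stop(where, ": shape has no 'kind'")
  leaf_keys <- list(sphere = c("r", "center"), box = c("half", "center"),
                    capsule = c("a", "b", "r"),
                    cylinder = c("half_height", "r", "center"))
  if (kind %in% names(leaf_keys)) {
    check_keys(sh, c("kind", leaf_keys[[kind]]), where)
    switch(kind,
      sphere = sdf_sphere(sh$r, center = unlist(sh$center %||% c(0, 0, 0))),
      box = sdf_box(unlist(sh$half), center = unlist(sh$center %||% c(0, 0, 0))),
      capsule = sdf_capsule(unlist(sh$a), unlist(sh$b), sh$r),
      cylinder = sdf_cylinder(sh$half_height, sh$r,
                              center = unlist(sh$center %||% c(0, 0, 0))))
  } else if (kind %in% c("union", "intersection", "subtraction", "smooth_union")) {
    check_keys(sh, c("kind", "k", "children"), where)
    ch <- sh$children %||% stop(where, ": CSG shape needs 'children'")
    if (length(ch) != 2L) stop(where, ": CSG shape needs exactly 2 children")
    a <- parse_config_shape(ch[[1]], paste0(where, ".children[1]"))
    b <- parse_config_shape(ch[[2]], paste0(where, ".children[2]"))
    switch(kind,
      union = sdf_union(a, b),
      intersection = sdf_intersection(a, b),
      subtraction = sdf_subtraction(a, b),
      smooth_union = sdf_smooth_union(a, b, sh$k %||%
                                        stop(where, ": smooth_union needs 'k'")))
  } else if (kind == "transform") {
    check_keys(sh, c("kind", "rotation", "translation", "children"), where)
    ch <- sh$children %||% stop(where, ": transform needs one child")
    rot <- if (is.null(sh$rotation)) diag(3)
           else matrix(unlist(sh$rotation), 3, 3, byrow = TRUE)
    sdf_transform(parse_config_shape(ch[[1]], paste0(where, ".children[1]")),
                  rotation = rot,
                  translation = unlist(sh$translation %||% c(0, 0, 0)))
  } else {
    stop(where, ": unknown shape kind '", kind, "'")
  }
}

parse_config_source <- function(s) {
  kind <- s$kind %||% stop("source has no 'kind'")
  if (kind == "isotropic_point") {
    check_keys(s, c("kind", "origin"), "source")
    source_isotropic_point(unlist(s$origin))
  } else if (kind %in% c("uniform_top", "rectangle")) {
    check_keys(s, c("kind", "origin", "half", "direction", "u_axis", "v_axis"),
               "source")
    source_uniform_top(unlist(s$origin), unlist(s$half),
                       direction = unlist(s$direction %||% c(0, 0, -1)),
                       u_axis = unlist(s$u_axis %||% c(1, 0, 0)),
                       v_axis = unlist(s$v_axis %||% c(0, 1, 0)))
  } else if (kind == "collimated_strip") {
    check_keys(s, c("kind", "origin", "width", "half_v", "direction",
                    "u_axis", "v_axis"), "source")
    source_collimated_strip(unlist(s$origin), s$width,
                            half_v = s$half_v %||% 0,
                            direction = unlist(s$direction %||% c(0, 0, -1)),
                            u_axis = unlist(s$u_axis %||% c(1, 0, 0)),
                            v_axis = unlist(s$v_axis %||% c(0, 1, 0)))
  } else {
    stop("unknown source kind '", kind, "'")
  }
}

#' Re-serialise a configuration
#'
#' Writes the configuration back to JSON. The raw parsed list is emitted, so
#' `load_config(write_config(cfg, f))` round-trips losslessly.
#'
#' @param cfg an `mcrt_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "mcrt_config"))
  jsonlite::write_json(cfg$raw, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Execute a configuration
#'
#' Runs the transport described by a loaded configuration and, when an
#' output directory is given, writes the fluence volume
#' ([write_volume()]), a run summary JSON (tallies, seed, timing) and an
#' echo of the effective configuration.
#'
#' @param cfg an `mcrt_config` from [load_config()].
#' @param out_dir optional output directory (created if needed); defaults to
#'   the config's `output` entry.
#' @return The [mcrt_run()] result, invisibly.
#' @export
run_config <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "mcrt_config"))
  out_dir <- out_dir %||% cfg$output
  t0 <- proc.time()[["elapsed"]]
  run <- mcrt_run(cfg$scene, cfg$source, cfg$n_photons, seed = cfg$seed,
                  grid = cfg$grid, record_exits = cfg$record_exits)
  elapsed <- proc.time()[["elapsed"]] - t0
  message(sprintf("%d packets in %.2f s (%.0f packets/s); step-cap kills: %d",
                  cfg$n_photons, elapsed, cfg$n_photons / max(elapsed, 1e-9),
                  run$n_capped))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(cfg$grid)) {
      fv <- finalize_fluence(run)
      write_volume(fv, file.path(out_dir, "fluence.raw"),
                   quantity = "fluence", units = "W cm^-2 per unit source power")
    }
    summary <- list(n_photons = cfg$n_photons, seed = cfg$seed,
                    n_absorbed = run$n_absorbed, n_escaped = run$n_escaped,
                    n_capped = run$n_capped, n_degenerate = run$n_degenerate,
                    mean_scatters = mean(run$n_scatters),
                    elapsed_s = elapsed)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_config(cfg, file.path(out_dir, "config_echo.json"))
  }
  invisible(run)
}

#' Read / write capsule tables
#'
#' Plain-text delimited tables describing vessel-like networks: one row per
#' segment with columns `x1 y1 z1 x2 y2 z2 radius` (cm). A header line is
#' optional on read and always written.
#'
#' @param path file path.
#' @param capsules a data frame with the seven columns above.
#' @return `read_capsule_table()` returns the validated data frame;
#'   `write_capsule_table()` returns `path` invisibly.
#' @name capsule_table
#' @export
read_capsule_table <- function(path) {
  if (!file.exists(path)) stop("capsule table not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*-?[0-9.]", first)
  df <- read.table(path, header = has_header)
  if (ncol(df) != 7L)
    stop("capsule table must have 7 columns (x1 y1 z1 x2 y2 z2 radius), got ",
         ncol(df))
  names(df) <- c("x1", "y1", "z1", "x2", "y2", "z2", "radius")
  validate_capsules(df)
}

#' @rdname capsule_table
#' @export
write_capsule_table <- function(capsules, path) {
  capsules <- validate_capsules(capsules)
  write.table(capsules, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write volumes as raw arrays with JSON sidecars
#'
#' Volumes (fluence, absorption, rasterised labels) are stored as flat
#' binary doubles in native byte order plus a `<path>.json` sidecar holding
#' `dims`, `spacing` (cm), `origin` (cm), `quantity` and `units`. The
#' round-trip is bit exact; a sidecar whose `dims` disagree with the file
#' size is an error.
#'
#' @param vol a `fluence_volume`, or a numeric array (then `grid` must be
#'   given).
#' @param path path for the binary payload; the sidecar goes to
#'   `<path>.json`.
#' @param grid a [fluence_grid()] when `vol` is a bare array.
#' @param quantity,units metadata strings recorded in the sidecar.
#' @return `write_volume()` returns `path` invisibly; `read_volume()`
#'   returns a list with the `volume` array and the sidecar metadata.
#' @name volume_io
#' @export
write_volume <- function(vol, path, grid = NULL, quantity = "fluence",
                         units = "W cm^-2") {
  if (inherits(vol, "fluence_volume")) {
    grid <- vol$grid
    arr <- vol$fluence
  } else {
    if (is.null(grid)) stop("grid is required when writing a bare array")
    arr <- vol
  }
  if (!identical(dim(arr), grid$dims)) stop("array dims do not match grid")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(arr), con, size = 8)
  jsonlite::write_json(
    list(dims = grid$dims, spacing = grid$spacing, origin = grid$origin,
         quantity = quantity, units = units, storage = "float64 native"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname volume_io
#' @export
read_volume <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(side))
    stop("volume payload or sidecar missing for ", path)
  meta <- jsonlite::fromJSON(side)
  dims <- as.integer(meta$dims)
  n <- prod(dims)
  if (file.size(path) != 8 * n)
    stop(sprintf("sidecar dims %s imply %d bytes but file has %d",
                 paste(dims, collapse = "x"), 8 * n, file.size(path)))
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n, size = 8)
  list(volume = array(v, dim = dims), meta = meta)
}
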