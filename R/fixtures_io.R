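# Deterministic fixtures and plain-text serialization (YAML configs, CSV
# link sets and recordings) so every module is testable without downloads.

.flk_schema <- "fibrolink/v1"

#' Named deterministic fixtures
#'
#' Small, fully determined geometry/link/config bundles used by the tests
#' and examples:
#' \describe{
#'   \item{tiny_strip}{60 x 12 strip, no scar.}
#'   \item{small_circle}{100 x 100 lattice with a 0.5 cm circular scar.}
#'   \item{line_scar}{200 x 60 strip with a 5-column line scar.}
#'   \item{paper_circle}{200 x 200 lattice with the 2 cm circular scar of
#'     the full study geometry (scar radius 80 grid points).}
#' }
#' @param name fixture name.
#' @param link_fixture \code{"none"}, \code{"deterministic_bridge"}
#'   (line-scar wiring) or \code{"seeded_random"} (Poisson links,
#'   lambda = 50, l_max = 2.5 mm).
#' @param seed RNG seed for random link fixtures.
#' @param n_units unit count for random link fixtures (default scales with
#'   the scar size).
#' @return list: \code{geom}, \code{links} (or NULL), \code{cfg}.
#' @export
make_fixture <- function(name = c("tiny_strip", "small_circle",
                                  "line_scar", "paper_circle"),
                         link_fixture = c("none", "deterministic_bridge",
                                          "seeded_random"),
                         seed = 1, n_units = NULL) {
  name <- match.arg(name)
  link_fixture <- match.arg(link_fixture)
  geom <- switch(name,
    tiny_strip = tissue_geometry(60, 12, scar_shape = "none"),
    small_circle = tissue_geometry(100, 100, scar_shape = "circle",
                                   scar_radius_cm = 0.5),
    line_scar = tissue_geometry(200, 60, scar_shape = "line"),
    paper_circle = tissue_geometry(200, 200, scar_shape = "circle",
                                   scar_radius_cm = 2))
  links <- switch(link_fixture,
    none = NULL,
    deterministic_bridge = {
      if (geom$scar_shape != "line")
        stop("deterministic_bridge needs the line_scar fixture")
      make_line_scar_links(geom)
    },
    seeded_random = {
      if (!any(geom$scar)) stop("random links need a scar")
      if (is.null(n_units))
        n_units <- max(100L, round(0.75 * sum(geom$scar)))
      generate_links(geom, n_units, lambda = 50, l_max = 2.5, seed = seed)
    })
  cfg <- sim_config(geom, links, gs = 4, duration = 1000, seed = seed)
  list(geom = geom, links = links, cfg = cfg)
}

#' Serialize a link set to tabular text
#'
#' One row per attachment (unit_id, role proximal/distal, grid i, j,
#' Gs in nS), preceded by a YAML metadata header. Round-trips losslessly.
#' @param links \code{\link{link_set}}.
#' @param path output file.
#' @export
write_links <- function(links, path) {
  meta <- list(schema = .flk_schema, kind = "link_set",
               n_units = links$n_units, lambda = links$lambda,
               l_max = links$l_max,
               seed = if (is.na(links$seed)) "NA" else links$seed,
               gs = links$gs, pool = links$pool,
               realisation = if (is.na(links$realisation)) "NA" else
                 links$realisation,
               nx = links$nx, ny = links$ny, dx = links$dx)
  hdr <- paste0("# ", strsplit(yaml::as.yaml(meta), "\n")[[1]])
  deg <- lengths(links$distal)
  pij <- .pt_ij(links$proximal, links$nx)
  rows <- data.frame(unit_id = seq_len(links$n_units), role = "proximal",
                     grid_i = pij[, 1], grid_j = pij[, 2],
                     gs_ns = links$gs)
  if (sum(deg) > 0) {
    dpts <- unlist(links$distal, use.names = FALSE)
    dij <- .pt_ij(dpts, links$nx)
    rows <- rbind(rows, data.frame(
      unit_id = rep.int(seq_len(links$n_units), deg), role = "distal",
      grid_i = dij[, 1], grid_j = dij[, 2], gs_ns = links$gs))
  }
  rows <- rows[order(rows$unit_id, rows$role != "proximal", rows$grid_i,
                     rows$grid_j), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a link set written by \code{\link{write_links}}
#' @param path file path.
#' @return \code{\link{link_set}}.
#' @export
read_links <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^# ", lines)
  meta <- yaml::yaml.load(paste(sub("^# ", "", lines[hdr]),
                                collapse = "\n"))
  if (!identical(meta$schema, .flk_schema))
    stop("unsupported link-set schema: ", meta$schema)
  tab <- read.csv(textConnection(lines[!hdr]))
  prox_rows <- tab[tab$role == "proximal", ]
  prox_rows <- prox_rows[order(prox_rows$unit_id), ]
  proximal <- .pt_index(prox_rows$grid_i, prox_rows$grid_j, meta$nx)
  distal <- rep(list(integer()), meta$n_units)
  drows <- tab[tab$role == "distal", ]
  if (nrow(drows)) {
    dp <- .pt_index(drows$grid_i, drows$grid_j, meta$nx)
    sp <- split(dp, drows$unit_id)
    distal[as.integer(names(sp))] <- lapply(sp, as.integer)
  }
  structure(list(proximal = as.integer(proximal), distal = distal,
                 n_units = meta$n_units, lambda = meta$lambda,
                 l_max = meta$l_max,
                 seed = if (identical(meta$seed, "NA")) NA_integer_ else
                   meta$seed,
                 gs = meta$gs, pool = meta$pool,
                 realisation = if (identical(meta$realisation, "NA"))
                   NA_integer_ else meta$realisation,
                 nx = meta$nx, ny = meta$ny, dx = meta$dx),
            class = "link_set")
}

#' Serialize a tissue geometry
#'
#' Geometries are fully determined by their shape parameters, so only
#' those are stored (YAML); reading rebuilds the geometry, which is
#' bit-identical by construction.
#' @param geom \code{\link{tissue_geometry}}.
#' @param path output file.
#' @export
write_geometry <- function(geom, path) {
  meta <- list(schema = .flk_schema, kind = "tissue_geometry",
               nx = geom$nx, ny = geom$ny, dx = geom$dx,
               scar_shape = geom$scar_shape,
               scar_radius_cm = if (is.na(geom$scar_radius_cm)) "NA" else
                 geom$scar_radius_cm,
               scar_cols = geom$scar_cols, d_reg = geom$d_reg)
  writeLines(yaml::as.yaml(meta), path)
  invisible(path)
}

#' Read a geometry written by \code{\link{write_geometry}}
#' @param path file path.
#' @return \code{\link{tissue_geometry}}.
#' @export
read_geometry <- function(path) {
  meta <- yaml::yaml.load_file(path)
  if (!identical(meta$schema, .flk_schema))
    stop("unsupported geometry schema: ", meta$schema)
  tissue_geometry(meta$nx, meta$ny, dx = meta$dx,
                  scar_shape = meta$scar_shape,
                  scar_radius_cm = if (identical(meta$scar_radius_cm, "NA"))
                    2 else meta$scar_radius_cm,
                  scar_cols = unlist(meta$scar_cols),
                  d_reg = meta$d_reg)
}

#' Serialize a simulation configuration (YAML)
#'
#' Stores every numerical setting plus the geometry spec; the link set is
#' stored separately (\code{\link{write_links}}).
#' @param cfg \code{\link{sim_config}}.
#' @param path output file.
#' @export
write_sim_config <- function(cfg, path) {
  scalar <- cfg[setdiff(names(cfg), c("geom", "links"))]
  scalar <- lapply(scalar, function(x) if (length(x) == 1 && is.na(x))
    "NA" else x)
  meta <- list(schema = .flk_schema, kind = "sim_config",
               geometry = list(nx = cfg$geom$nx, ny = cfg$geom$ny,
                               dx = cfg$geom$dx,
                               scar_shape = cfg$geom$scar_shape,
                               scar_radius_cm =
                                 if (is.na(cfg$geom$scar_radius_cm)) "NA"
                                 else cfg$geom$scar_radius_cm,
                               scar_cols = cfg$geom$scar_cols,
                               d_reg = cfg$geom$d_reg),
               settings = scalar,
               has_links = !is.null(cfg$links))
  writeLines(yaml::as.yaml(meta), path)
  invisible(path)
}

#' Read a configuration written by \code{\link{write_sim_config}}
#' @param path file path.
#' @param links optional \code{\link{link_set}} to re-attach.
#' @return \code{\link{sim_config}}.
#' @export
read_sim_config <- function(path, links = NULL) {
  meta <- yaml::yaml.load_file(path)
  if (!identical(meta$schema, .flk_schema))
    stop("unsupported config schema: ", meta$schema)
  g <- meta$geometry
  geom <- tissue_geometry(g$nx, g$ny, dx = g$dx, scar_shape = g$scar_shape,
                          scar_radius_cm = if (identical(g$scar_radius_cm,
                                                         "NA")) 2 else
                            g$scar_radius_cm,
                          scar_cols = unlist(g$scar_cols), d_reg = g$d_reg)
  s <- meta$settings
  s <- lapply(s, function(x) if (identical(x, "NA")) NA else x)
  sim_config(geom, links = links, gs = s$gs, nf = s$nf, dt = s$dt,
             duration = s$duration, scar_mode = s$scar_mode, vfr = s$vfr,
             snapshot_dt = s$snapshot_dt, line_dt = s$line_dt,
             equilibrate_ms = s$equilibrate_ms, stim_amp = s$stim_amp,
             stim_dur = s$stim_dur, act_threshold = s$act_threshold,
             act_lockout = s$act_lockout, max_act = s$max_act,
             rush_larsen = s$rush_larsen, seed = s$seed)
}

#' Write the portable parts of a recording to a directory
#'
#' Writes a manifest (YAML: schema, configuration, provenance), the
#' sampling-line traces (CSV) and the activation log (CSV). Field
#' snapshots are bulk arrays and are not serialized here.
#' @param rec \code{\link{run_tissue}} recording.
#' @param dir output directory (created).
#' @export
write_recording <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sim_config(rec$cfg, file.path(dir, "config.yaml"))
  if (!is.null(rec$cfg$links))
    write_links(rec$cfg$links, file.path(dir, "links.csv"))
  manifest <- list(schema = .flk_schema, kind = "recording",
                   t_end = rec$t_end,
                   stopped = rec$stopped,
                   stop_time = if (is.na(rec$stop_time)) "NA" else
                     rec$stop_time,
                   balance_max = rec$balance_max,
                   protocol = unclass(rec$protocol)[
                     !vapply(unclass(rec$protocol), is.null, TRUE)])
  writeLines(yaml::as.yaml(manifest), file.path(dir, "manifest.yaml"))
  if (!is.null(rec$line_v)) {
    tab <- data.frame(time_ms = rec$line_t,
                      format(rec$line_v, digits = 17, trim = TRUE))
    names(tab) <- c("time_ms", paste0("cell_", seq_len(ncol(rec$line_v))))
    write.csv(tab, file.path(dir, "line_trace.csv"), row.names = FALSE,
              quote = FALSE)
  }
  acts <- which(!is.na(rec$act), arr.ind = TRUE)
  if (nrow(acts)) {
    ij <- .pt_ij(acts[, 1], rec$cfg$geom$nx)
    atab <- data.frame(point = acts[, 1], i = ij[, 1], j = ij[, 2],
                       beat = acts[, 2],
                       time_ms = rec$act[acts])
    atab <- atab[order(atab$point, atab$beat), ]
  } else {
    atab <- data.frame(point = integer(), i = integer(), j = integer(),
                       beat = integer(), time_ms = numeric())
  }
  write.csv(atab, file.path(dir, "activations.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(dir)
}

#' Read back a recording directory
#'
#' Restores the serialized parts (config, links, line traces, activation
#' log) written by \code{\link{write_recording}}.
#' @param dir recording directory.
#' @return list with \code{cfg}, \code{line_t}, \code{line_v}, \code{act},
#'   \code{n_act}, \code{t_end}.
#' @export
read_recording <- function(dir) {
  manifest <- yaml::yaml.load_file(file.path(dir, "manifest.yaml"))
  if (!identical(manifest$schema, .flk_schema))
    stop("unsupported recording schema: ", manifest$schema)
  links <- if (file.exists(file.path(dir, "links.csv")))
    read_links(file.path(dir, "links.csv")) else NULL
  cfg <- read_sim_config(file.path(dir, "config.yaml"), links = links)
  line_t <- numeric(); line_v <- NULL
  lt_path <- file.path(dir, "line_trace.csv")
  if (file.exists(lt_path)) {
    tab <- read.csv(lt_path)
    line_t <- tab$time_ms
    line_v <- as.matrix(tab[, -1, drop = FALSE])
    dimnames(line_v) <- NULL
  }
  atab <- read.csv(file.path(dir, "activations.csv"))
  npts <- cfg$geom$nx * cfg$geom$ny
  act <- matrix(NA_real_, npts, cfg$max_act)
  if (nrow(atab)) act[cbind(atab$point, atab$beat)] <- atab$time_ms
  n_act <- as.integer(rowSums(!is.na(act)))
  list(cfg = cfg, line_t = line_t, line_v = line_v, act = act,
       n_act = n_act, t_end = manifest$t_end)
}

#' Serialize a cell-model parameter set (YAML)
#'
#' One human-readable key-value file per variant; the three study variants
#' ship with the package under \code{extdata/} (\code{shallow_myocyte},
#' \code{fibroblast_depolarized}, \code{fibroblast_hyperpolarized}).
#' @param params \code{\link{myocyte_params}} or
#'   \code{\link{fibroblast_params}}.
#' @param path output file.
#' @export
write_cell_params <- function(params, path) {
  kind <- if (inherits(params, "myocyte_params")) "myocyte_params"
          else if (inherits(params, "fibroblast_params")) "fibroblast_params"
          else stop("not a cell parameter set")
  meta <- list(schema = .flk_schema, kind = kind,
               params = lapply(unclass(params), function(x)
                 if (length(x) == 1 && is.na(x)) "NA" else x))
  writeLines(yaml::as.yaml(meta, precision = 15), path)
  invisible(path)
}

#' Read a cell-model parameter set written by \code{\link{write_cell_params}}
#' @param path file path, or the name of a shipped variant
#'   (\code{"shallow_myocyte"}, \code{"fibroblast_depolarized"},
#'   \code{"fibroblast_hyperpolarized"}).
#' @return parameter object of the stored class.
#' @export
read_cell_params <- function(path) {
  if (!file.exists(path)) {
    shipped <- system.file("extdata", paste0(path, ".yaml"),
                           package = "fibrolink")
    if (nzchar(shipped)) path <- shipped
  }
  meta <- yaml::yaml.load_file(path)
  if (!identical(meta$schema, .flk_schema))
    stop("unsupported cell-parameter schema: ", meta$schema)
  p <- lapply(meta$params, function(x) if (identical(x, "NA")) NA else x)
  structure(p, class = meta$kind)
}
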