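config_defaults <- function() {
  list(
    trajectory = NULL, format = "pdb", topology = NULL,
    lambda_samples = NULL, reference = NULL,
    tail_fraction = 0.10, seed = 1L, output_dir = "cdtraj_out",
    dt = 10, t0 = 0,
    geometry = list(convention = "cross_ring"),
    hydration = list(edges = c(0, 0.5, 0.8, 0.9, 1.0), rdf_bin_width = 0.02),
    hbonds = list(r_cut = 0.35, angle_cut = 30),
    shape = list(weighting = "mass", kappa2_support = c(0, 0.5), bins = 50L),
    fel = list(bins = 60L, kT = 2.577),
    energetics = list(kT = 2.577, n_boot = 200L),
    binding = list(d_insert = 0.35, d_surface = 0.80, max_angle = 45)
  )
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), rejects unknown keys (no
#' silent typo tolerance), range-checks parameters, and materializes all
#' defaults so the effective configuration is fully explicit.
#'
#' @param config path to a YAML file, or a named list.
#' @param check_paths verify that referenced input files exist.
#' @return validated configuration list of class \code{run_config}.
#' @export
validate_config <- function(config, check_paths = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stopf("config must be a file path or a named list")
  def <- config_defaults()
  errs <- character()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    errs <- c(errs, sprintf("unknown config key '%s'", unknown))
  for (blk in c("geometry", "hydration", "hbonds", "shape", "fel",
                "energetics", "binding")) {
    if (!is.null(config[[blk]])) {
      bad <- setdiff(names(config[[blk]]), names(def[[blk]]))
      if (length(bad)) errs <- c(errs, sprintf("unknown key '%s.%s'", blk, bad))
      def[[blk]][names(config[[blk]])] <- config[[blk]]
    }
  }
  top <- setdiff(intersect(names(config), names(def)),
                 c("geometry", "hydration", "hbonds", "shape", "fel",
                   "energetics", "binding"))
  def[top] <- config[top]
  cfg <- def
  if (!is.null(cfg$tail_fraction) &&
      (!is.numeric(cfg$tail_fraction) || cfg$tail_fraction <= 0 ||
       cfg$tail_fraction > 1))
    errs <- c(errs, "'tail_fraction' must be in (0, 1]")
  ed <- cfg$hydration$edges
  if (any(ed < 0) || is.unsorted(ed, strictly = TRUE))
    errs <- c(errs, "'hydration.edges' must be non-negative and strictly increasing")
  if (cfg$hbonds$r_cut <= 0) errs <- c(errs, "'hbonds.r_cut' must be > 0")
  if (cfg$hbonds$angle_cut <= 0) errs <- c(errs, "'hbonds.angle_cut' must be > 0")
  if (cfg$fel$kT <= 0) errs <- c(errs, "'fel.kT' must be > 0")
  if (check_paths) {
    for (key in c("trajectory", "topology", "lambda_samples", "reference")) {
      p <- cfg[[key]]
      if (!is.null(p) && !file.exists(p))
        errs <- c(errs, sprintf("'%s' path does not exist: %s", key, p))
    }
  }
  if (length(errs)) stopf("invalid configuration:\n  - %s",
                          paste(errs, collapse = "\n  - "))
  class(cfg) <- "run_config"
  cfg
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run every analysis stage over one trajectory
#'
#' Executes geometry, shape, hydration (when waters are annotated),
#' hydrogen bonds (when donors are annotated), binding classification (when
#' a guest is annotated), the free-energy landscape, and the TI/BAR
#' estimators (when lambda samples are provided), all over the same tail
#' window, and writes per-frame and summary TSV tables plus a JSON run
#' report listing every emitted file with its checksum.
#'
#' @param config a \code{\link{validate_config}} result, YAML path, or list.
#' @return the run report (list), invisibly; files under
#'   \code{config$output_dir}.
#' @export
run_all <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  if (is.null(cfg$trajectory) || is.null(cfg$topology))
    stopf("config must name a trajectory and a topology")
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  topo <- read_topology(cfg$topology)
  traj <- read_trajectory(cfg$trajectory, cfg$format, topo,
                          dt = cfg$dt, t0 = cfg$t0)
  win <- tail_window(traj, cfg$tail_fraction)
  set.seed(cfg$seed)
  files <- character(); warnings <- character(); stages <- character()
  emit <- function(df, name) {
    files <<- c(files, write_tsv(df, file.path(cfg$output_dir, name)))
  }
  stage <- function(name, expr) {
    r <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    stages <<- c(stages, name)
    r
  }

  geo <- stage("geometry", rim_geometry(traj, topo, window = win,
                                        convention = cfg$geometry$convention))
  emit(geo$per_frame, "geometry_per_frame.tsv")
  emit(geo$summary, "geometry_summary.tsv")

  shp <- stage("shape", shape_series(traj, topo, weighting = cfg$shape$weighting,
                                     window = win))
  emit(shp, "shape_per_frame.tsv")
  k2d <- descriptor_density(shp$kappa2, support = cfg$shape$kappa2_support,
                            bins = cfg$shape$bins)
  emit(data.frame(kappa2 = k2d$grid, density = k2d$density), "kappa2_density.tsv")
  bd <- descriptor_density(shp$b, support = c(0, max(shp$b) * 1.0001),
                           bins = cfg$shape$bins)
  emit(data.frame(b = bd$grid, density = bd$density), "b_density.tsv")

  if (length(topo$water_oxygens)) {
    hyd <- stage("hydration", shell_counts(traj, topo, edges = cfg$hydration$edges,
                                           window = win))
    emit(hyd$summary, "hydration_summary.tsv")
    gr <- stage("rdf", rdf(traj, topo, bin_width = cfg$hydration$rdf_bin_width,
                           window = win))
    emit(gr, "rdf.tsv")
  } else warnings <- c(warnings, "no water oxygens annotated; hydration skipped")

  if (length(topo$hydrogens)) {
    hb <- stage("hbonds", pair_counts(traj, topo, r_cut = cfg$hbonds$r_cut,
                                      angle_cut = cfg$hbonds$angle_cut,
                                      window = win))
    emit(hb$summary, "hbonds_summary.tsv")
  } else warnings <- c(warnings, "no donors/hydrogens annotated; hbonds skipped")

  if (length(topo$guest_atoms) >= 2L) {
    bind <- stage("binding", classify_binding(traj, topo,
                                              d_insert = cfg$binding$d_insert,
                                              d_surface = cfg$binding$d_surface,
                                              max_angle = cfg$binding$max_angle))
    emit(bind, "binding_per_frame.tsv")
  }

  ref <- NULL
  if (!is.null(cfg$reference)) {
    rtraj <- read_trajectory(cfg$reference, cfg$format, topo)
    grp <- which(atom_group_labels(topo) == "CD")
    ref <- frame_coords(rtraj, 1L)[grp, , drop = FALSE]
  }
  cv <- stage("fel", cv_series(traj, topo, reference = ref, window = win))
  emit(cv, "cv_per_frame.tsv")
  land <- fel_2d(cv, kT = cfg$fel$kT, bins = cfg$fel$bins)
  fl <- land$F; fl[is.na(fl)] <- Inf
  emit(as.data.frame(fl), "fel_matrix.tsv")

  energetics <- NULL
  if (!is.null(cfg$lambda_samples)) {
    ls <- read_lambda_samples(cfg$lambda_samples)
    energetics <- list()
    if (!is.null(ls$dhdl))
      energetics$TI <- stage("ti", ti_integrate(ls, n_boot = cfg$energetics$n_boot,
                                                seed = cfg$seed))
    if (!is.null(ls$forward) && !is.null(ls$reverse))
      energetics$BAR <- stage("bar", bar_estimate(ls, kT = cfg$energetics$kT,
                                                  n_boot = cfg$energetics$n_boot,
                                                  seed = cfg$seed))
    fe <- do.call(rbind, lapply(names(energetics), function(m)
      data.frame(method = m, dG = energetics[[m]]$dG, se = energetics[[m]]$se)))
    emit(fe, "free_energy.tsv")
  }

  report <- list(
    tool = "cdtraj", version = as.character(utils::packageVersion("cdtraj")),
    seed = cfg$seed,
    n_frames = n_frames(traj),
    window = list(fraction = win$fraction, start = win$start, end = win$end,
                  n = length(win$frames)),
    stages = stages,
    config = unclass(cfg),
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))),
    warnings = warnings)
  jsonlite::write_json(report, file.path(cfg$output_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(report)
}
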