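# Reproducible experiment driver: config parsing, seeded staged pipeline,
# manifest with checksums.

#' Load a pipeline run configuration
#'
#' Reads a nested YAML configuration (or accepts an equivalent named list)
#' describing a full pipeline run. Recognized blocks and keys (defaults in
#' parentheses):
#' \describe{
#'   \item{tree}{`source` ("generate" or "file"); for generate:
#'     `domain_size` (100), `n_terminals` (500), `inlet_radius` (3),
#'     `seed` (1); for file: `path`.}
#'   \item{flow}{`pin_mmhg` (100), `pout_mmhg` (0).}
#'   \item{mesh}{`n` (4), `size` (= tree domain size) for a structured
#'     cube, or `path` to a legacy-VTK tet mesh.}
#'   \item{fields}{`nc` (2), `rev_radius` (5), `model` ("II"),
#'     `inclusion_rule` ("midpoint").}
#'   \item{material}{any [material_params()] argument.}
#'   \item{solver}{any [solver_config()] argument.}
#'   \item{validate}{`include_comp1` (TRUE).}
#' }
#'
#' @param config path to a YAML file, or a named list.
#' @return a validated `run_config` list.
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  dflt <- list(
    tree = list(source = "generate", domain_size = 100, n_terminals = 500,
                inlet_radius = 3, seed = 1),
    flow = list(pin_mmhg = 100, pout_mmhg = 0),
    mesh = list(n = 4, size = NULL),
    fields = list(nc = 2, rev_radius = 5, model = "II",
                  inclusion_rule = "midpoint"),
    material = list(),
    solver = list(),
    validate = list(include_comp1 = TRUE)
  )
  for (blk in names(dflt)) {
    user <- config[[blk]]
    if (!is.null(user)) dflt[[blk]][names(user)] <- user
  }
  cfg <- dflt
  if (cfg$tree$source == "file" && !file.exists(cfg$tree$path %||% ""))
    stop("tree file not found: ", cfg$tree$path)
  if (!is.null(cfg$mesh$path) && !file.exists(cfg$mesh$path))
    stop("mesh file not found: ", cfg$mesh$path)
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the staged perfusion pipeline
#'
#' Executes tree -> flow -> fields -> solve -> validate, writing each
#' stage's artifact and a manifest with MD5 checksums so that a rerun with
#' the same configuration reproduces the outputs bit for bit.
#'
#' @param config a [run_config()] (or path / list accepted by it).
#' @param out_dir output directory (created if needed).
#' @param quiet suppress stage messages.
#' @return the manifest list, invisibly; artifacts are written to
#'   `out_dir` (`tree.csv`, `flow.csv`, `fields.vtk`, `solution.vtk`,
#'   `report.json`, `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, quiet = TRUE) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  say <- function(...) if (!quiet) message(...)
  t_start <- proc.time()[["elapsed"]]
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    say("stage ", name, " done (",
        stages[[name]]$seconds, " s)")
    out
  }

  nw <- stage("tree", function() {
    nw <- if (cfg$tree$source == "generate")
      generate_cco_tree(cfg$tree$domain_size, cfg$tree$n_terminals,
                        cfg$tree$inlet_radius, seed = cfg$tree$seed)
    else read_network(cfg$tree$path)
    write_network(nw, file.path(out_dir, "tree.csv"))
    nw
  })
  stages$tree$file <- "tree.csv"

  params <- do.call(material_params, cfg$material)
  sconfig <- do.call(solver_config, cfg$solver)

  flow <- stage("flow", function() {
    bcs <- flow_bcs(cfg$flow$pin_mmhg, cfg$flow$pout_mmhg, params$mu,
                    units = "mmHg")
    flow <- solve_poiseuille(nw, bcs)
    tab <- data.frame(
      segment_id = nw$segments$id,
      q_mm3_s = flow$q, p_prox_pa = flow$p_prox,
      p_dist_pa = flow$p_dist, p_mean_pa = flow$p_seg_mean)
    utils::write.csv(tab, file.path(out_dir, "flow.csv"), row.names = FALSE)
    flow
  })
  stages$flow$file <- "flow.csv"

  mesh <- if (!is.null(cfg$mesh$path)) read_mesh_vtk(cfg$mesh$path) else
    build_cube_mesh(cfg$mesh$n, cfg$mesh$size %||% cfg$tree$domain_size)

  fields <- stage("fields", function() {
    zeta <- hierarchy_parameters(nw)
    sc <- partition_compartments(zeta, nw$segments$radius, cfg$fields$nc)
    fields <- parameterize_porous_fields(
      nw, flow, sc, mesh,
      rev_spec(cfg$fields$rev_radius, cfg$fields$inclusion_rule),
      model = cfg$fields$model, mu = params$mu)
    write_fields_vtk(fields, mesh, file.path(out_dir, "fields.vtk"))
    fields
  })
  stages$fields$file <- "fields.vtk"

  sol <- stage("solve", function() {
    sol <- newton_solve(mesh, fields, params, sconfig)
    pd <- list(u = sol$u, p = sol$p)
    for (i in 2:fields$nc) pd[[paste0("m_", i)]] <- sol$m[, i - 1L]
    write_mesh_vtk(mesh, file.path(out_dir, "solution.vtk"), point_data = pd)
    sol
  })
  stages$solve$file <- "solution.vtk"

  report <- stage("validate", function() {
    val <- validate_solution(nw, flow, sol, fields, mesh, params,
                             include_comp1 = cfg$validate$include_comp1)
    report <- list(
      Perr = val$Perr,
      newton_iterations = sol$iterations,
      q_inlet_mm3_s = flow$q_inlet,
      n_segments = nrow(nw$segments),
      n_terminals = n_terminals(nw, perfused_only = TRUE),
      nc = fields$nc, model = fields$model,
      rev_radius_mm = fields$rev$radius)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report
  })
  stages$validate$file <- "report.json"

  files <- vapply(stages, function(s) s$file, character(1))
  checksums <- tools::md5sum(file.path(out_dir, files))
  names(checksums) <- files
  manifest <- list(
    package_version = as.character(utils::packageVersion("poroperf")),
    config = unclass(cfg),
    stages = stages,
    checksums = as.list(checksums),
    total_seconds = round(proc.time()[["elapsed"]] - t_start, 3)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
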