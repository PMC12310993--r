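#' Run configuration
#'
#' Collects paths and model constants for an end-to-end run. Defaults are the
#' model's canonical values: inlet pressure 93.33 mmHg, blood viscosity
#' 0.04 g/cm/s, blood density 1.06 g/cm^3, tissue density 1.04 g/mL,
#' CBF 0.8/0.2/0.5 mL/min/g (gray/white/other), perforator capture distance
#' 3 mm, centerline spacing 0.5 mm, truncation sweep 0 to 1.0 mm in 0.05 mm
#' steps.
#'
#' @param network_path,mesh_path input files (`NULL` to use a synthetic
#'   phantom).
#' @param model `"tessellation"` or `"murray"`.
#' @param cbf_scheme `"regional"` or `"uniform"`.
#' @param inlet_pressure_mmHg,mu,rho_blood,d_max_mm,spacing_mm model knobs.
#' @param sweep_rmax_mm,sweep_step_mm sensitivity sweep grid.
#' @param seed seed for synthetic geometry.
#' @param out_dir output directory (`NULL`: no files written).
#' @return list of class `perfterra_config`.
#' @export
perfterra_config <- function(network_path = NULL, mesh_path = NULL,
                             model = c("tessellation", "murray"),
                             cbf_scheme = c("regional", "uniform"),
                             inlet_pressure_mmHg = 93.33,
                             mu = 0.04, rho_blood = 1.06,
                             d_max_mm = 3.0, spacing_mm = 0.5,
                             sweep_rmax_mm = 1.0, sweep_step_mm = 0.05,
                             seed = 1L, out_dir = NULL) {
  structure(list(network_path = network_path, mesh_path = mesh_path,
                 model = match.arg(model), cbf_scheme = match.arg(cbf_scheme),
                 inlet_pressure_mmHg = inlet_pressure_mmHg, mu = mu,
                 rho_blood = rho_blood, d_max_mm = d_max_mm,
                 spacing_mm = spacing_mm, sweep_rmax_mm = sweep_rmax_mm,
                 sweep_step_mm = sweep_step_mm, seed = seed,
                 out_dir = out_dir),
            class = "perfterra_config")
}

#' End-to-end pipeline
#'
#' load (or synthesise) geometry -> resample -> select sources -> tessellate
#' -> territory demands -> midpoint/outlet sinks -> steady solve ->
#' distribution; or the Murray's-law variant of the boundary model with the
#' same solve. When `out_dir` is set, writes per-source and per-segment CSVs,
#' a distribution JSON and a manifest (config echo + package version).
#'
#' @param config a [perfterra_config()].
#' @return list with `network`, `mesh`, `sources`, `assignment`, `sinks`,
#'   `solution`, `distribution` (sources/assignment are `NULL` for the
#'   Murray model).
#' @export
run_pipeline <- function(config = perfterra_config()) {
  table <- default_tissue_table(config$cbf_scheme)
  constants <- fluid_constants(rho = config$rho_blood, mu = config$mu)
  if (is.null(config$network_path)) {
    ph <- make_phantom("toy_cow", seed = config$seed,
                       spacing = config$spacing_mm)
    network <- ph$network
    mesh <- ph$mesh
  } else {
    network <- load_network(config$network_path)
    if (!is.null(config$spacing_mm)) {
      network <- resample_centerline(network, config$spacing_mm)
    }
    mesh <- load_mesh(config$mesh_path)
  }
  stage <- function(name, expr) {
    tryCatch(expr, perfterra_error = function(e) {
      stop_perfterra("stage '", name, "': ", conditionMessage(e),
                     class = class(e)[1])
    })
  }
  if (config$model == "tessellation") {
    sources <- stage("select_sources",
                     select_sources(network, mesh, config$d_max_mm))
    assignment <- stage("tessellate", tessellate(mesh, sources))
    assignment <- stage("territory_demand",
                        territory_demand(assignment, mesh, table))
    sinks <- stage("aggregate_segment_sinks",
                   aggregate_segment_sinks(sources, assignment, network))
  } else {
    sources <- NULL; assignment <- NULL
    sinks <- stage("murray_flows",
                   murray_flows(outlet_radii(network),
                                total_demand(mesh, table)))
  }
  bcs <- boundary_conditions(network, sinks, config$inlet_pressure_mmHg)
  solution <- stage("solve_steady_flow",
                    solve_steady_flow(build_system(network, bcs, constants)))
  distribution <- compute_distribution(solution, network)
  res <- list(network = network, mesh = mesh, sources = sources,
              assignment = assignment, sinks = sinks, solution = solution,
              distribution = distribution)
  if (!is.null(config$out_dir)) write_run_outputs(res, config)
  res
}

write_run_outputs <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(...) file.path(config$out_dir, ...)
  if (!is.null(res$assignment) && !is.null(res$assignment$summary)) {
    write.csv(res$assignment$summary, f("sources.csv"), row.names = FALSE)
    write.csv(data.frame(element_id = seq_along(res$assignment$element_source),
                         source_id = res$assignment$element_source),
              f("territories.csv"), row.names = FALSE)
  }
  ed <- res$solution$edges
  pn <- setNames(res$solution$nodes$pressure_mmHg,
                 as.character(res$solution$nodes$node_id))
  seg_csv <- data.frame(segment_id = ed$segment_id, part = ed$part,
                        label = ed$label, Q_mL_per_min = ed$Q_mL_per_min,
                        p_proximal_mmHg = pn[as.character(ed$from)],
                        p_distal_mmHg = pn[as.character(ed$to)])
  write.csv(seg_csv, f("segments.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(arteries = res$distribution$arteries,
         inlets = res$distribution$inlets,
         missing = res$distribution$missing),
    f("distribution.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  cfg <- unclass(config)
  jsonlite::write_json(
    list(config = cfg[!vapply(cfg, is.null, logical(1))],
         package_version = as.character(utils::packageVersion("perfterra"))),
    f("manifest.json"), auto_unbox = TRUE)
  invisible(config$out_dir)
}
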