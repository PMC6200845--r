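#' Configuration for the end-to-end mapping pipeline
#'
#' Collects and validates everything [run_pipeline()] needs. Defaults follow
#' the reference workflow: logarithmic covariance, exponent grid
#' `0,1,2,3,4,10,25,50` with the nearest-neighbour anchor at 50, and no
#' control-point optimisation.
#'
#' @param source_mesh path to the source solid layer (LS-Dyna keyword).
#' @param target_mesh path to the target surface mesh.
#' @param landmarks_source,landmarks_target paths to matched landmark CSVs.
#' @param out_mesh output path for the target mesh with
#'   `*ELEMENT_SHELL_THICKNESS` cards.
#' @param report optional path for the JSON run report.
#' @param covariance Kriging kernel, see [kriging_covariance()].
#' @param optimize run [optimize_control_points()] before morphing.
#' @param betas exponent grid; must contain 0 and `beta_max`.
#' @param beta_max nearest-neighbour anchor.
#' @param beta exponent for the output projection; `NULL` (default) uses
#'   the sweep's selected tradeoff value.
#' @param rescale condition the Kriging solve on unit-diagonal coordinates.
#' @param verbose log stage progress to stderr.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(source_mesh, target_mesh,
                            landmarks_source, landmarks_target,
                            out_mesh, report = NULL,
                            covariance = "logarithmic", optimize = FALSE,
                            betas = c(0, 1, 2, 3, 4, 10, 25, 50),
                            beta_max = max(betas), beta = NULL,
                            rescale = FALSE, verbose = FALSE) {
  cfg <- list(source_mesh = source_mesh, target_mesh = target_mesh,
              landmarks_source = landmarks_source,
              landmarks_target = landmarks_target,
              out_mesh = out_mesh, report = report,
              covariance = covariance, optimize = isTRUE(optimize),
              betas = sort(unique(as.numeric(betas))),
              beta_max = as.numeric(beta_max), beta = beta,
              rescale = isTRUE(rescale), verbose = isTRUE(verbose))
  if (any(cfg$betas < 0)) abort("pipeline_config: beta values must be >= 0")
  if (!0 %in% cfg$betas) abort("pipeline_config: beta grid must contain 0")
  if (!cfg$beta_max %in% cfg$betas) {
    abort("pipeline_config: beta grid must contain beta_max")
  }
  if (!is.null(cfg$beta) && cfg$beta < 0) {
    abort("pipeline_config: output beta must be >= 0")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @param ... overrides applied on top of the file values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  do.call(pipeline_config, vals)
}

#' Run the full thickness-mapping pipeline
#'
#' Executes extract -> (optional control-point optimisation) -> Kriging
#' morph -> beta sweep -> projection -> `*ELEMENT_SHELL_THICKNESS` output,
#' and assembles a run report (morph quality, accuracy/smoothness table,
#' selected exponent, thickness summaries). Any stage failure is re-raised
#' with the stage name and partially written outputs are removed.
#'
#' @param config a [pipeline_config()] (or a YAML path accepted by
#'   [read_pipeline_config()]).
#' @return Invisibly, a list of class `pipeline_result`: the report (also
#'   written as JSON when `config$report` is set) plus the fitted objects
#'   (`model`, `quality`, `sweep`, `field`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  log_msg <- function(...) if (config$verbose) message("[cortimap] ", ...)
  outputs <- c(config$out_mesh, config$report)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      for (p in outputs) if (!is.null(p) && file.exists(p)) unlink(p)
      abort(paste0("pipeline stage '", name, "': ", conditionMessage(e)))
    })
  }

  log_msg("reading inputs")
  inp <- stage("read", {
    layer <- read_mesh(config$source_mesh)
    if (!inherits(layer, "solid_shell_layer")) {
      abort("source mesh is not a one-element-thick solid layer")
    }
    target <- read_mesh(config$target_mesh)
    if (!inherits(target, "surface_mesh")) abort("target mesh is not a surface mesh")
    list(layer = layer, target = target,
         lm_src = read_landmarks(config$landmarks_source),
         lm_tgt = read_landmarks(config$landmarks_target))
  })

  log_msg("extracting source thickness")
  field_src <- stage("extract", nodal_thickness(inp$layer))

  lm_src <- inp$lm_src
  lm_tgt <- inp$lm_tgt
  opt <- NULL
  if (config$optimize) {
    log_msg("optimizing control points")
    opt <- stage("optimize",
                 optimize_control_points(lm_src, lm_tgt,
                                         kind = config$covariance,
                                         rescale = config$rescale))
    lm_src <- opt$source
    lm_tgt <- opt$target
  }

  log_msg("fitting and applying Kriging morph")
  morph <- stage("morph", {
    model <- fit_kriging(lm_src, lm_tgt, kind = config$covariance,
                         rescale = config$rescale)
    src_surface <- outer_surface(inp$layer)
    morphed <- morph_mesh(src_surface, model)
    quality <- morph_quality(morphed, inp$target,
                             apply_kriging(lm_src, model), lm_tgt)
    list(model = model, morphed = morphed, quality = quality)
  })

  log_msg("sweeping beta")
  sweep <- stage("sweep", {
    src_nodes <- dplyr::inner_join(
      morph$morphed$nodes, field_src[, c("node_id", "thickness")],
      by = "node_id")
    beta_sweep(inp$target, src_nodes,
               betas = config$betas, beta_max = config$beta_max)
  })
  beta_out <- config$beta %||% sweep$selected_beta

  log_msg("projecting at beta = ", format(beta_out))
  field_out <- stage("project", {
    src_nodes <- dplyr::inner_join(
      morph$morphed$nodes, field_src[, c("node_id", "thickness")],
      by = "node_id")
    project_thickness(inp$target, src_nodes, beta = beta_out)
  })

  log_msg("writing outputs")
  report <- stage("write", {
    write_shell_thickness(inp$target, field_out, config$out_mesh)
    rep <- list(
      source_thickness = as.list(thickness_summary(field_src)),
      morph_quality = as.list(glance(morph$quality)),
      control_points = if (!is.null(opt)) as.list(glance(opt)) else NULL,
      sweep = as.data.frame(sweep$table),
      selected_beta = sweep$selected_beta,
      output_beta = beta_out,
      projected_thickness = as.list(thickness_summary(field_out)),
      out_mesh = config$out_mesh)
    if (!is.null(config$report)) {
      jsonlite::write_json(rep, config$report, auto_unbox = TRUE,
                           digits = NA, null = "null", dataframe = "rows")
    }
    rep
  })

  invisible(structure(
    list(report = report, model = morph$model, quality = morph$quality,
         optimization = opt, sweep = sweep, field = field_out),
    class = "pipeline_result"))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  morph: mean q %.3f mm (max %.3f)\n",
              x$quality$mean_q, x$quality$max_q))
  cat(sprintf("  selected beta: %.3g; output beta: %.3g\n",
              x$report$selected_beta, x$report$output_beta))
  s <- x$report$projected_thickness
  cat(sprintf("  projected thickness: mean %.3f mm [%.3f, %.3f]\n",
              s$mean, s$min, s$max))
  invisible(x)
}
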