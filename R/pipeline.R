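# Config-driven orchestration: synthetic data (or CSV/GeoJSON inputs) ->
# sample filter -> recoding -> descriptives -> four-model sequence ->
# road-network accessibility -> Jenks district classification, with a run
# log carrying the exclusion accounting and model convergence.

#' Build a pipeline configuration
#'
#' @param synthetic an \code{\link{sim_config}} (or NULL when
#'   \code{records_csv}/\code{geography_dir} are given).
#' @param records_csv path to a women-records CSV (used when
#'   \code{synthetic} is NULL).
#' @param geography_dir directory of GeoJSON layers (used when
#'   \code{synthetic} is NULL and spatial is enabled).
#' @param stages named logical list enabling stages: descriptives, model,
#'   spatial, classify.
#' @param nq quadrature nodes for the model stage.
#' @param tolerance_km facility snapping tolerance.
#' @param breaks travel-time band upper bounds (minutes).
#' @param barriers apply lake barriers.
#' @param jenks_k total Jenks classes.
#' @param seed master seed (overrides the synthetic config's).
#' @return list of class \code{mcp_pipeline_config}.
#' @export
pipeline_config <- function(synthetic = sim_config(),
                            records_csv = NULL, geography_dir = NULL,
                            stages = list(descriptives = TRUE, model = TRUE,
                                          spatial = TRUE, classify = TRUE),
                            nq = 7L, tolerance_km = 15,
                            breaks = c(30, 45, 60, 90, 180, 240),
                            barriers = TRUE, jenks_k = 5, seed = NULL) {
  if (is.null(synthetic) && is.null(records_csv)) {
    stop("either a synthetic block or a records CSV is required", call. = FALSE)
  }
  if (!is.null(synthetic) && !is.null(records_csv)) {
    stop("give exactly one of: synthetic block, records CSV", call. = FALSE)
  }
  if (!is.null(seed) && !is.null(synthetic)) synthetic$seed <- as.integer(seed)
  structure(list(synthetic = synthetic, records_csv = records_csv,
                 geography_dir = geography_dir,
                 stages = modifyList(list(descriptives = TRUE, model = TRUE,
                                          spatial = TRUE, classify = TRUE),
                                     stages),
                 nq = nq, tolerance_km = tolerance_km, breaks = breaks,
                 barriers = barriers, jenks_k = jenks_k,
                 seed = seed %||% (if (!is.null(synthetic)) synthetic$seed else 1L)),
            class = "mcp_pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML mirrors \code{\link{pipeline_config}}; a \code{synthetic}
#' mapping is passed to \code{\link{sim_config}}.
#'
#' @param path YAML file.
#' @return an \code{mcp_pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- if (!is.null(y$synthetic)) do.call(sim_config, y$synthetic) else NULL
  args <- y[setdiff(names(y), "synthetic")]
  do.call(pipeline_config, c(list(synthetic = syn), args))
}

#' Run the full analysis pipeline
#'
#' @param config an \code{mcp_pipeline_config}.
#' @param outdir output directory for CSV/GeoJSON artefacts and the run
#'   log; NULL for in-memory only.
#' @param quiet suppress console progress lines.
#' @return invisibly, a report bundle: analytic records, descriptives,
#'   model sequence, access report, classification and the log lines.
#' @export
run_pipeline <- function(config, outdir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "mcp_pipeline_config"))
  logl <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    logl <<- c(logl, line)
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_stage(name, conditionMessage(e))
    })
  }
  bundle <- list()

  women <- stage("data", {
    if (!is.null(config$synthetic)) {
      say("simulating %d districts (seed %d)",
          config$synthetic$n_districts, config$synthetic$seed)
      simulate_women(config$synthetic)
    } else {
      say("reading records from %s", config$records_csv)
      read.csv(config$records_csv, stringsAsFactors = FALSE)
    }
  })

  analytic <- stage("filter", apply_sample_filter(women))
  acc <- attr(analytic, "accounting")
  say("screening: %d women in, %d non-users excluded, %d pregnant users excluded, %d analytic",
      acc$n_input, acc$n_excluded_nonuser, acc$n_excluded_pregnant,
      acc$n_analytic)
  stopifnot(acc$n_input - acc$n_excluded_nonuser - acc$n_excluded_pregnant ==
              acc$n_analytic)

  coding <- stage("coding", {
    cw <- code_women(analytic)
    cs <- aggregate_community(cw)
    list(coded = add_community_vars(cw, cs), community = cs)
  })
  coded <- coding$coded
  bundle$community <- coding$community
  bundle$accounting <- acc
  bundle$coded <- coded
  say("coded %d analytic records; modern share %.1f%%", nrow(coded),
      100 * mean(coded$outcome_modern, na.rm = TRUE))

  if (isTRUE(config$stages$descriptives)) {
    bundle$descriptives <- stage("descriptives", {
      vars <- c(individual_terms(), community_terms())
      tabs <- lapply(vars, function(v) crosstab(coded, v))
      names(tabs) <- vars
      sel <- select_variables(tabs, data = coded)
      say("bivariate screening kept %d of %d variables (p < 0.05)",
          length(sel), length(vars))
      list(crosstabs = tabs, selected = sel)
    })
  }

  if (isTRUE(config$stages$model)) {
    bundle$models <- stage("model", {
      seq_ <- run_model_sequence(coded, nq = config$nq)
      ok <- !vapply(seq_$fits, is.null, logical(1))
      say("model sequence: %d/4 fits converged; lowest AIC: %s",
          sum(vapply(seq_$fits[ok], function(f) f$converged, logical(1))),
          if (is.na(seq_$best)) "none" else seq_$comparison$model[seq_$best])
      seq_
    })
    # marginal effects come from the best-fitting covariate model (the
    # empty model has none to report)
    aics <- bundle$models$comparison$aic
    cand <- setdiff(which(!is.na(aics)), 1L)
    if (length(cand)) {
      best_cov <- cand[which.min(aics[cand])]
      bundle$ame <- stage("model", average_marginal_effects(
        bundle$models$fits[[best_cov]], coded))
    }
  }

  geo <- NULL
  if (isTRUE(config$stages$spatial) || isTRUE(config$stages$classify)) {
    geo <- stage("geography", {
      if (!is.null(config$synthetic)) {
        simulate_geography(config$synthetic, config$tolerance_km)
      } else if (!is.null(config$geography_dir)) {
        read_geography_geojson(config$geography_dir)
      } else NULL
    })
    bundle$geography <- geo
  }

  if (isTRUE(config$stages$spatial) && !is.null(geo)) {
    bundle$access <- stage("spatial", {
      gr <- build_road_graph(geo$roads)
      if (isTRUE(config$barriers) && length(geo$lakes)) {
        gr <- apply_barriers(gr, geo$lakes)
        say("barriers removed %d edges", length(attr(gr, "removed_edges")))
      }
      gr <- snap_facilities(gr, geo$facilities, config$tolerance_km)
      say("facilities: %d located, %d unlocated (tolerance %g km)",
          nrow(gr$facilities), nrow(gr$unlocated), config$tolerance_km)
      surface <- travel_time_surface(gr, config$breaks)
      centroids <- geo$districts$centroids
      pts <- centroids[match(as.character(coded$district_id),
                             centroids$district_id), ]
      pts$district_id <- as.character(coded$district_id)
      rep_ <- district_access_report(surface, pts)
      list(graph = gr, surface = surface, report = rep_)
    })
  }

  if (isTRUE(config$stages$classify)) {
    bundle$classification <- stage("classify", {
      dv <- data.frame(district_id = bundle$community$district_id,
                       value = bundle$community$share_national_modern_pct,
                       stringsAsFactors = FALSE)
      jr <- classify_districts(dv, k = config$jenks_k)
      say("Jenks: %d classes, top bound %.2f%%", jr$k, max(jr$breaks))
      jr
    })
  }

  bundle$log <- logl
  if (!is.null(outdir)) write_bundle(bundle, coded, outdir, config)
  invisible(bundle)
}

write_bundle <- function(bundle, coded, outdir, config) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, file) write.csv(df, file.path(outdir, file),
                                       row.names = FALSE, na = "NA")
  wcsv(coded, "coded_records.csv")
  wcsv(bundle$community, "district_summaries.csv")
  if (!is.null(bundle$descriptives)) {
    t1 <- do.call(rbind, lapply(bundle$descriptives$crosstabs, function(x)
      data.frame(variable = x$variable, x$table,
                 chi_square = x$chi_square, p_value = x$p_value,
                 stringsAsFactors = FALSE)))
    wcsv(t1, "table1.csv")
  }
  if (!is.null(bundle$models)) {
    wcsv(bundle$models$comparison, "model_comparison.csv")
    if (!is.null(bundle$ame)) wcsv(bundle$ame, "marginal_effects.csv")
  }
  if (!is.null(bundle$access)) {
    wcsv(bundle$access$report, "district_access.csv")
    wcsv(bundle$access$surface$nodes, "access_surface.csv")
  }
  if (!is.null(bundle$classification)) {
    wcsv(bundle$classification$assignments, "district_classes.csv")
  }
  if (!is.null(bundle$geography)) {
    write_geography_geojson(bundle$geography, file.path(outdir, "geojson"))
  }
  writeLines(bundle$log, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}
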