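#' Configuration for an end-to-end pipeline run
#'
#' Defaults reproduce the canonical analysis settings: 10 m cells, a
#' 15 km randomized representative buffer, 50 perimeter nodes in the
#' 8-neighbour pairwise mode, 900 m / 300 m suborder scales, and 999
#' permutations. Smaller values are appropriate for demonstration runs on
#' synthetic landscapes.
#'
#' @param landscape a [landscape_config()] (synthetic input), or an
#'   existing categorical [grid_raster()] via `land_raster`.
#' @param land_raster optional pre-built land-cover raster; overrides
#'   `landscape`.
#' @param sites optional pond site data.frame (`id`, `x`, `y`, `type`);
#'   generated synthetically when `NULL`.
#' @param n_stormwater,n_natural synthetic site counts (defaults 41, 8).
#' @param scheme resistance scheme (default [default_resistance_scheme()]).
#' @param buffer_width_m edge-correction buffer width (default 15000).
#' @param buffer_ratio target low/medium/high ratio for the buffer; `NULL`
#'   (default) uses the study area's own observed ratio.
#' @param n_nodes perimeter node count (default 50).
#' @param neighbourhood raster graph neighbourhood, 4 or 8 (default 8).
#' @param scales named suborder radii; `NULL` (default) selects them from
#'   `flight_table` with [select_scale()].
#' @param flight_table flight-distance table (default
#'   [synthetic_flight_table()]).
#' @param community a [community_config()], or `NULL` for defaults.
#' @param log10_floor floor for the log10 current transform (default 1e-12).
#' @param permutations RDA permutations (default 999).
#' @param seed single global seed; per-stage seeds are derived from it.
#' @param out_dir directory for artifacts and the manifest, or `NULL` to
#'   keep everything in memory.
#' @param stop_after last stage to execute: one of `"landscape"`,
#'   `"resistance"`, `"current"`, `"metrics"`, `"community"`, `"stats"`.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(landscape = NULL, land_raster = NULL, sites = NULL,
                            n_stormwater = 41, n_natural = 8,
                            scheme = default_resistance_scheme(),
                            buffer_width_m = 15000, buffer_ratio = NULL,
                            n_nodes = 50, neighbourhood = 8, scales = NULL,
                            flight_table = synthetic_flight_table(),
                            community = NULL, log10_floor = 1e-12,
                            permutations = 999, seed = 1, out_dir = NULL,
                            stop_after = "stats") {
  stages <- c("landscape", "resistance", "current", "metrics", "community",
              "stats")
  stop_after <- match.arg(stop_after, stages)
  if (is.null(landscape) && is.null(land_raster)) {
    landscape <- landscape_config(200, 200, seed = seed)
  }
  structure(list(landscape = landscape, land_raster = land_raster,
                 sites = sites, n_stormwater = n_stormwater,
                 n_natural = n_natural, scheme = scheme,
                 buffer_width_m = buffer_width_m, buffer_ratio = buffer_ratio,
                 n_nodes = n_nodes, neighbourhood = neighbourhood,
                 scales = scales, flight_table = flight_table,
                 community = community, log10_floor = log10_floor,
                 permutations = permutations, seed = seed, out_dir = out_dir,
                 stop_after = stop_after, stages = stages),
            class = "pipeline_config")
}

# deterministic per-stage seeds derived from the global seed (kept < 2^31)
stage_seeds <- function(seed, stages) {
  setNames(as.integer((as.numeric(seed) * 131 + 7 * seq_along(stages)) %%
                        .Machine$integer.max), stages)
}

#' Run the connectivity analysis pipeline end to end
#'
#' Executes, in order: synthetic landscape generation (or ingestion of a
#' supplied raster), resistance classification with edge-correction buffer
#' and perimeter nodes, pairwise circuit solving into a mean current map,
#' per-pond metric extraction at the suborder scales, synthetic community
#' generation (when no observed community is supplied), and the
#' GLM + RDA statistical battery. All randomness derives from the single
#' global seed, so identical configs give identical outputs; when
#' `out_dir` is set, every intermediate artifact is written (ASCII grids
#' and CSVs) along with a JSON manifest of seeds, stage timings, object
#' summaries and file checksums.
#'
#' @param config a [pipeline_config()].
#' @return a list of class `pipeline_run` with the stage outputs present up
#'   to `stop_after` (`land`, `sites`, `resistance`, `buffered`, `nodes`,
#'   `current_map`, `metrics`, `community`, `battery`) plus `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- stage_seeds(config$seed, config$stages)
  run <- list(manifest = list(seed = config$seed, stage_seeds = as.list(seeds),
                              timings = list(), counts = list(),
                              settings = list(
                                buffer_width_m = config$buffer_width_m,
                                n_nodes = config$n_nodes,
                                neighbourhood = config$neighbourhood,
                                permutations = config$permutations,
                                log10_floor = config$log10_floor)))
  last <- match(config$stop_after, config$stages)
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
    run$manifest$timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  # stage 1: landscape + sites
  run$land <- tick("landscape", {
    if (!is.null(config$land_raster)) config$land_raster
    else {
      lc <- config$landscape
      lc$seed <- seeds[["landscape"]]
      generate_landscape(lc)
    }
  })
  run$sites <- if (!is.null(config$sites)) config$sites else {
    generate_sites(run$land, config$n_stormwater, config$n_natural,
                   seed = seeds[["landscape"]] + 1L)
  }
  run$manifest$counts$cells <- prod(dim(run$land))
  run$manifest$counts$sites <- nrow(run$sites)
  if (last < 2) return(finish_run(run, config))

  # stage 2: resistance + buffer + nodes
  run$resistance <- tick("resistance", classify_resistance(run$land, config$scheme))
  ratio <- config$buffer_ratio %||% unname(resistance_proportions(run$resistance))
  run$buffered <- add_random_buffer(run$resistance, config$buffer_width_m,
                                    target_ratio = ratio,
                                    seed = seeds[["resistance"]])
  run$nodes <- place_perimeter_nodes(run$buffered, config$n_nodes,
                                     seed = seeds[["resistance"]] + 1L)
  run$manifest$counts$buffer_cells <- sum(!run$buffered$study_mask)
  run$manifest$counts$study_ratio <- as.list(round(ratio, 4))
  if (last < 3) return(finish_run(run, config))

  # stage 3: mean current map
  run$current_map <- tick("current", {
    graph <- build_raster_graph(run$buffered, config$neighbourhood)
    mean_current_map(graph, run$nodes, log10_floor = config$log10_floor)
  })
  run$manifest$counts$n_pairs <- attr(run$current_map, "n_pairs")
  if (last < 4) return(finish_run(run, config))

  # stage 4: site metrics at the suborder scales
  run$metrics <- tick("metrics", {
    scales <- config$scales %||% c(
      Anisoptera = select_scale(config$flight_table, "Anisoptera"),
      Zygoptera = select_scale(config$flight_table, "Zygoptera"))
    run$manifest$counts$scales <- as.list(scales)
    habitat <- patch_centroids(run$land)
    pts <- rbind(habitat[, c("x", "y")], run$sites[, c("x", "y")])
    compute_site_metrics(run$current_map, run$sites, pts,
                         scales = unname(scales),
                         self_tolerance = run$land$cell_size / 2)
  })
  if (last < 5) return(finish_run(run, config))

  # stage 5: community (synthetic unless supplied)
  run$community <- tick("community", {
    if (inherits(config$community, "community_matrix")) config$community
    else {
      cc <- config$community %||% community_config(
        n_sites = nrow(run$sites))
      cc$seed <- seeds[["community"]]
      generate_community(run$metrics, cc)
    }
  })
  run$manifest$counts$species <- ncol(run$community$counts)
  if (last < 6) return(finish_run(run, config))

  # stage 6: statistical battery
  run$battery <- tick("stats", {
    scales <- unlist(run$manifest$counts$scales)
    run_model_battery(run$metrics, run$community, scales = scales,
                      permutations = config$permutations,
                      seed = seeds[["stats"]])
  })
  run$manifest$counts$glm_models <- nrow(run$battery$glm_table)
  run$manifest$counts$rda_models <- length(run$battery$rda_results)
  finish_run(run, config)
}

# write artifacts + manifest when an output directory is configured
finish_run <- function(run, config) {
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    paths <- character(0)
    wr_csv <- function(df, name) {
      p <- file.path(od, name)
      utils::write.csv(df, p, row.names = FALSE)
      paths <<- c(paths, p)
    }
    if (!is.null(run$land)) {
      p <- file.path(od, "land_cover.asc")
      write_ascii_grid(run$land, p); paths <- c(paths, p)
      wr_csv(run$sites, "pond_sites.csv")
    }
    if (!is.null(run$buffered)) {
      p <- file.path(od, "resistance_buffered.asc")
      write_ascii_grid(run$buffered, p); paths <- c(paths, p)
      wr_csv(run$nodes, "perimeter_nodes.csv")
    }
    if (!is.null(run$current_map)) {
      p <- file.path(od, "mean_current.asc")
      write_ascii_grid(run$current_map, p); paths <- c(paths, p)
    }
    if (!is.null(run$metrics)) wr_csv(run$metrics, "site_metrics.csv")
    if (!is.null(run$community)) {
      wr_csv(data.frame(pond_id = rownames(run$community$counts),
                        run$community$counts, check.names = FALSE),
             "community_counts.csv")
    }
    if (!is.null(run$battery)) {
      wr_csv(run$battery$glm_table, "glm_table.csv")
      wr_csv(run$battery$rda_table, "rda_table.csv")
      wr_csv(data.frame(
        model = rep(names(run$battery$rda_results),
                    vapply(run$battery$rda_results,
                           function(r) length(r$species_scores), 0L)),
        species = unlist(lapply(run$battery$rda_results,
                                function(r) names(r$species_scores))),
        score = unlist(lapply(run$battery$rda_results,
                              function(r) unname(r$species_scores)))),
        "rda_species_scores.csv")
    }
    run$manifest$checksums <- as.list(tools::md5sum(paths))
    names(run$manifest$checksums) <- basename(paths)
    jsonlite::write_json(run$manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  class(run) <- "pipeline_run"
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  done <- intersect(c("land", "resistance", "current_map", "metrics",
                      "community", "battery"), names(x))
  cat("pipeline_run with stages:", paste(done, collapse = " -> "), "\n")
  str(x$manifest$counts, give.attr = FALSE)
  invisible(x)
}
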