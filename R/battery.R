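# residual diagnostics reported as statistics rather than plots:
# skewness of residuals (normality) and the p-value of a variance-trend
# regression of squared residuals on fitted values (homogeneity)
residual_diagnostics <- function(fit) {
  r <- stats::residuals(fit)
  f <- stats::fitted(fit)
  s <- stats::sd(r)
  skew <- if (s > 0) mean((r - mean(r))^3) / s^3 else 0
  var_trend_p <- if (stats::sd(f) > 0) {
    summary(stats::lm(r^2 ~ f))$coefficients[2, 4]
  } else NA_real_
  c(resid_skewness = skew, var_trend_p = var_trend_p)
}

#' Run the full statistical battery
#'
#' Fits the twelve Gaussian models — \{abundance, Shannon diversity,
#' species richness\} x \{mean current, number of neighbours\} for
#' dragonflies at their scale and damselflies at theirs — plus four
#' redundancy analyses (\{mean current, neighbours\} x suborder). Before
#' fitting, the standard deviation of current is screened as a candidate
#' uninformative parameter against each response and its keep/drop decision
#' reported. Residual diagnostics are attached to every model row.
#'
#' @param metrics tidy metrics data.frame from [compute_site_metrics()]
#'   (keyed by `pond_id`, `scale_m`).
#' @param community a `community_matrix` (or bare count matrix with
#'   `suborder_vec`).
#' @param scales named radii per suborder, default
#'   `c(Anisoptera = 900, Zygoptera = 300)`; must exist in `metrics`.
#' @param permutations RDA permutations (default 999).
#' @param seed RNG seed for the permutation tests.
#' @param suborder_vec suborder annotation when `community` is a matrix.
#' @return list of class `model_battery`: `glm_table` (12 rows with
#'   estimates, R-squared, p, log-likelihood, diagnostics and the
#'   sd-current screening decision), `rda_results` (named list of 4
#'   [tb_rda()] objects), `rda_table` (their summary rows), and
#'   `sd_screening`.
#' @export
run_model_battery <- function(metrics, community,
                              scales = c(Anisoptera = 900, Zygoptera = 300),
                              permutations = 999, seed = 1,
                              suborder_vec = NULL) {
  stopifnot(is.data.frame(metrics),
            all(c("pond_id", "scale_m", "mean_current", "sd_current",
                  "n_neighbours") %in% names(metrics)))
  counts <- counts_of(community)
  sub <- suborder_of(community, suborder_vec)
  for (so in names(scales)) {
    if (!any(sub == so)) stop(sprintf("no species with suborder '%s'", so))
    if (!any(metrics$scale_m == scales[[so]])) {
      stop(sprintf("metrics table has no rows at the %s scale (%g m)",
                   so, scales[[so]]))
    }
  }

  responses <- c(abundance = site_abundance, shannon = site_shannon,
                 richness = site_richness)
  predictors <- c("mean_current", "n_neighbours")
  glm_rows <- list()
  screening <- list()
  rda_results <- list()

  for (so in names(scales)) {
    msub <- metrics[metrics$scale_m == scales[[so]], , drop = FALSE]
    msub <- msub[match(rownames(counts), msub$pond_id), , drop = FALSE]
    if (any(is.na(msub$pond_id))) {
      stop("metrics table does not cover every community site")
    }
    for (resp_name in names(responses)) {
      y <- responses[[resp_name]](counts, so, suborder_vec = sub)
      for (pred in predictors) {
        row <- fit_gaussian_glm(y, msub[[pred]],
                                response_name = sprintf("%s_%s", so, resp_name),
                                predictor_name = pred)
        fit <- attr(row, "fit")
        diag <- residual_diagnostics(fit)
        row$resid_skewness <- diag[["resid_skewness"]]
        row$var_trend_p <- diag[["var_trend_p"]]
        row$scale_m <- scales[[so]]
        glm_rows[[length(glm_rows) + 1]] <- row
      }
      # screen sd of current as an added parameter alongside mean current
      full <- stats::lm(y ~ msub$mean_current + msub$sd_current)
      reduced <- stats::lm(y ~ msub$mean_current)
      sc <- screen_uninformative(full, reduced)
      screening[[sprintf("%s_%s", so, resp_name)]] <- sc
    }
    for (pred in predictors) {
      key <- sprintf("%s_%s", so, pred)
      rda_results[[key]] <- tb_rda(
        subset_suborder(counts, so, suborder_vec = sub),
        msub[[pred]], permutations = permutations, seed = seed)
    }
  }

  glm_table <- do.call(rbind, glm_rows)
  rownames(glm_table) <- NULL
  glm_table$sd_current_decision <- vapply(
    glm_table$response, function(k) screening[[k]]$decision, character(1))
  rda_table <- do.call(rbind, lapply(names(rda_results), function(k) {
    r <- rda_results[[k]]
    data.frame(model = k, r_squared = r$r_squared,
               adj_r_squared = r$adj_r_squared, pseudo_f = r$pseudo_f,
               p_value = r$p_value, permutations = r$permutations,
               stringsAsFactors = FALSE)
  }))
  structure(list(glm_table = glm_table, rda_results = rda_results,
                 rda_table = rda_table, sd_screening = screening,
                 scales = scales),
            class = "model_battery")
}

#' @export
print.model_battery <- function(x, ...) {
  cat(sprintf("model battery: %d Gaussian models, %d redundancy analyses\n",
              nrow(x$glm_table), length(x$rda_results)))
  print(x$glm_table[, c("response", "predictor", "slope", "r_squared",
                        "p_value")], digits = 3)
  cat("\nRDA summaries:\n")
  print(x$rda_table, digits = 3)
  invisible(x)
}
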