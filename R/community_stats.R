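# helpers to accept either a community_matrix or a bare counts matrix
counts_of <- function(x) if (inherits(x, "community_matrix")) x$counts else x
suborder_of <- function(x, suborder_vec = NULL) {
  if (inherits(x, "community_matrix")) x$suborder else suborder_vec
}

subset_suborder <- function(x, suborder, suborder_vec = NULL) {
  counts <- counts_of(x)
  sub <- suborder_of(x, suborder_vec)
  if (is.null(sub)) stop("suborder annotation required")
  keep <- names(sub)[sub == suborder]
  if (length(keep) == 0) stop(sprintf("no species with suborder '%s'", suborder))
  counts[, keep, drop = FALSE]
}

#' Per-site estimated abundance of a suborder
#'
#' Row sums of the count matrix over the suborder's species (the site total
#' of per-species estimated abundances).
#'
#' @param x a `community_matrix` or a site-by-species count matrix.
#' @param suborder `"Anisoptera"` or `"Zygoptera"`.
#' @param suborder_vec species-named suborder vector when `x` is a bare matrix.
#' @return named numeric vector, one total per site.
#' @export
site_abundance <- function(x, suborder, suborder_vec = NULL) {
  rowSums(subset_suborder(x, suborder, suborder_vec))
}

#' Per-site species richness of a suborder
#'
#' @inheritParams site_abundance
#' @return named integer vector of counts of species observed (> 0) per site.
#' @export
site_richness <- function(x, suborder, suborder_vec = NULL) {
  rowSums(subset_suborder(x, suborder, suborder_vec) > 0)
}

#' Per-site Shannon diversity of a suborder (nats)
#'
#' `H = -sum p_i ln p_i` over the suborder's species proportions at each
#' site; sites with zero total are assigned 0.
#'
#' @inheritParams site_abundance
#' @return named numeric vector of diversities in nats.
#' @export
site_shannon <- function(x, suborder, suborder_vec = NULL) {
  m <- subset_suborder(x, suborder, suborder_vec)
  apply(m, 1, function(row) {
    tot <- sum(row)
    if (tot == 0) return(0)
    p <- row[row > 0] / tot
    -sum(p * log(p))
  })
}

#' Gaussian linear model of a response on one predictor
#'
#' Ordinary least squares (`stats::lm`, Gaussian likelihood) of one
#' community response on one connectivity predictor, reported as a one-row
#' summary: intercept and slope estimates, R-squared, the two-sided t-test
#' p-value of the slope, log-likelihood and n.
#'
#' @param response,predictor numeric vectors of equal length (n >= 3, finite).
#' @param response_name,predictor_name labels used in the output row.
#' @return a one-row data.frame; the fitted `lm` object is attached as
#'   `attr(., "fit")`.
#' @export
fit_gaussian_glm <- function(response, predictor,
                             response_name = deparse(substitute(response)),
                             predictor_name = deparse(substitute(predictor))) {
  stopifnot(length(response) == length(predictor), length(response) >= 3)
  if (!all(is.finite(response)) || !all(is.finite(predictor))) {
    stop("response and predictor must be finite")
  }
  if (stats::sd(predictor) == 0) stop("predictor has zero variance")
  fit <- stats::lm(response ~ predictor)
  sm <- summary(fit)
  out <- data.frame(
    response = response_name, predictor = predictor_name,
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2, 4],
    log_lik = as.numeric(stats::logLik(fit)),
    n = length(response), stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}

#' Screen an added parameter for informativeness
#'
#' Compares nested Gaussian models on identical data and recommends
#' dropping the extra parameter when it fails to improve the log-likelihood
#' by at least `threshold` (default 1.92, the improvement at which an added
#' parameter starts paying its AIC penalty) — the rule used to discard the
#' standard deviation of current as an uninformative parameter.
#'
#' @param full,reduced fitted `lm` objects on the same response, `full`
#'   having the extra parameter(s).
#' @param threshold minimum log-likelihood improvement to keep (default 1.92).
#' @return list with `decision` (`"keep"`/`"drop"`), both log-likelihoods
#'   and `delta`.
#' @export
screen_uninformative <- function(full, reduced, threshold = 1.92) {
  stopifnot(inherits(full, "lm"), inherits(reduced, "lm"))
  if (stats::nobs(full) != stats::nobs(reduced)) {
    stop("models must be fitted to identical data")
  }
  ll_full <- as.numeric(stats::logLik(full))
  ll_red <- as.numeric(stats::logLik(reduced))
  delta <- ll_full - ll_red
  list(decision = if (delta < threshold) "drop" else "keep",
       log_lik_full = ll_full, log_lik_reduced = ll_red,
       delta = delta, threshold = threshold)
}

#' Hellinger transformation of a count matrix
#'
#' `y'_ij = sqrt(y_ij / row_total_i)`: the square root of relative
#' abundance, which downweights zeros and makes Euclidean-based ordination
#' appropriate for sparse count data. Each nonzero row of the result has
#' unit sum of squares; all-zero rows stay zero and raise a warning.
#'
#' @param m non-negative site-by-species count matrix.
#' @return transformed numeric matrix of the same shape.
#' @export
hellinger <- function(m) {
  m <- counts_of(m)
  stopifnot(is.matrix(m), all(m >= 0))
  tot <- rowSums(m)
  if (any(tot == 0)) warning(sprintf("%d all-zero row(s) left as zeros", sum(tot == 0)))
  tot[tot == 0] <- 1
  sqrt(sweep(m, 1, tot, "/"))
}

#' Transformation-based redundancy analysis on one predictor
#'
#' Hellinger-transforms the community matrix (optional), column-centres it,
#' and constrains it on a single centred predictor: fitted values are the
#' per-species least-squares projections on the predictor, the constrained
#' R-squared is SS(fitted)/SS(total), adjusted by Ezekiel's formula
#' `1 - (1 - R^2)(n - 1)/(n - m - 1)`, with pseudo-F
#' `(R^2/m) / ((1 - R^2)/(n - m - 1))`. Significance is assessed by
#' permuting site rows of the predictor (seeded) and recomputing F, with
#' `p = (#{F_perm >= F_obs} + 1)/(B + 1)`. Species scores are covariances
#' of the (transformed, centred) species columns with the standardized
#' constraining axis.
#'
#' @param m site-by-species count matrix or `community_matrix`.
#' @param predictor per-site numeric vector, finite and non-constant.
#' @param permutations number of permutations B (default 999).
#' @param seed RNG seed for the permutations (required for reproducibility).
#' @param transform apply the Hellinger transformation first (default TRUE).
#' @return object of class `tb_rda`: `r_squared`, `adj_r_squared`,
#'   `pseudo_f`, `p_value`, `permutations`, `species_scores`,
#'   `site_scores`, `n`, `transform`.
#' @export
tb_rda <- function(m, predictor, permutations = 999, seed = 1,
                   transform = TRUE) {
  m <- counts_of(m)
  stopifnot(is.matrix(m), nrow(m) >= 3, nrow(m) == length(predictor))
  if (!all(is.finite(predictor))) stop("predictor must be finite")
  if (stats::sd(predictor) == 0) stop("predictor is constant")
  Y <- if (transform) hellinger(m) else m
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  x <- predictor - mean(predictor)
  ss_tot <- sum(Yc^2)
  if (ss_tot == 0) stop("community matrix has no variance")
  xtx <- sum(x^2)
  ss_fit_for <- function(xv) sum(crossprod(xv, Yc)^2) / sum(xv^2)
  ss_fit <- ss_fit_for(x)
  n <- nrow(Y); mpar <- 1
  r2 <- ss_fit / ss_tot
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - mpar - 1)
  fstat <- (r2 / mpar) / ((1 - r2) / (n - mpar - 1))

  # vectorized permutation test: each permuted predictor column against Yc
  perm_f <- with_seed(seed, {
    P <- vapply(seq_len(permutations), function(i) x[sample.int(n)],
                numeric(n))
    ss_fit_p <- rowSums(crossprod(P, Yc)^2) / xtx
    r2p <- ss_fit_p / ss_tot
    (r2p / mpar) / ((1 - r2p) / (n - mpar - 1))
  })
  p <- (sum(perm_f >= fstat - 1e-12) + 1) / (permutations + 1)

  axis <- x / stats::sd(x)
  scores <- as.numeric(crossprod(Yc, axis)) / (n - 1)
  names(scores) <- colnames(Y)
  structure(list(r_squared = r2, adj_r_squared = adj_r2, pseudo_f = fstat,
                 p_value = p, permutations = permutations,
                 species_scores = scores, site_scores = axis, n = n,
                 transform = transform, seed = seed),
            class = "tb_rda")
}

#' @export
print.tb_rda <- function(x, ...) {
  cat(sprintf(
    "tb-RDA (1 constraint, n = %d): R2 = %.4f, adj R2 = %.4f, F = %.3f, p = %.4g (%d permutations)\n",
    x$n, x$r_squared, x$adj_r_squared, x$pseudo_f, x$p_value, x$permutations))
  invisible(x)
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided rank-sum test with midranks for ties: exact p by enumeration
#' when the combined sample size is at most 12 and there are no ties,
#' otherwise the normal approximation with tie and continuity corrections.
#' The method used is recorded.
#'
#' @param a,b numeric vectors (each non-empty).
#' @return list `statistic` (W), `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 12) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Pearson correlation between two predictors
#'
#' @param a,b numeric vectors of equal length (n >= 3).
#' @return sample Pearson correlation coefficient.
#' @export
predictor_correlation <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  stats::cor(a, b)
}
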