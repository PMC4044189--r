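#' Fit the full analysis chain to a simulated cohort
#'
#' For each participant: builds the multi-run design matrix, fits the
#' (optionally prewhitened) GLM to every node, converts condition betas to
#' percent signal change, and selects stimulus-responsive nodes by the
#' hemisphere-wise FDR-corrected one-sided responsiveness contrast. Per
#' area, the selected nodes' psc values are averaged within participant
#' and normalized into an [area_coherence_response()] matrix.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param whiten Prewhiten with the per-node ARMA(1,1) estimate.
#' @param fdr_q FDR level for node selection.
#' @param use_motion Include the motion nuisance columns.
#' @return An object of class `cohort_fit`: a list with `responses` (one
#'   `area_response` per area), `node_psc` (per area: per participant, a
#'   list with `psc` matrix over all nodes, `selected`, `meridian_distance`,
#'   `hemisphere`) and `design_dim`.
#' @export
analyze_cohort <- function(cohort, whiten = TRUE, fdr_q = 0.001,
                           use_motion = TRUE) {
  stopifnot(inherits(cohort, "glass_cohort"))
  n_ppt <- length(cohort$participants)
  node_psc <- stats::setNames(
    lapply(cohort$areas, function(a) vector("list", n_ppt)), cohort$areas)
  design_dim <- NULL
  for (p in seq_len(n_ppt)) {
    ppt <- cohort$participants[[p]]
    design <- build_design_matrix(
      ppt$timelines, if (use_motion) ppt$motion else NULL,
      cohort$protocol, cohort$hemo)
    design_dim <- dim(design$X)
    for (a in cohort$areas) {
      dat <- ppt$areas[[a]]
      n_nodes <- ncol(dat$Y)
      psc <- matrix(NA_real_, n_nodes, length(design$conditions),
                    dimnames = list(NULL, design$conditions))
      pvals <- numeric(n_nodes)
      for (j in seq_len(n_nodes)) {
        fit <- fit_node_glm(dat$Y[, j], design, whiten = whiten)
        psc[j, ] <- betas_to_psc(fit)
        pvals[j] <- node_responsiveness(fit)$p
      }
      selected <- select_responsive_nodes(pvals, dat$hemisphere, fdr_q)
      node_psc[[a]][[p]] <- list(psc = psc, p_responsive = pvals,
                                 selected = selected,
                                 meridian_distance = dat$meridian_distance,
                                 hemisphere = dat$hemisphere)
    }
  }
  responses <- stats::setNames(lapply(cohort$areas, function(a) {
    area_coherence_response(
      lapply(node_psc[[a]], function(d) d$psc[d$selected, , drop = FALSE]),
      area = a)
  }), cohort$areas)
  structure(list(responses = responses, node_psc = node_psc,
                 design_dim = design_dim, areas = cohort$areas),
            class = "cohort_fit")
}

#' @export
print.cohort_fit <- function(x, ...) {
  cat(sprintf("Cohort GLM fit: %d areas, design matrix %d x %d\n",
              length(x$areas), x$design_dim[1], x$design_dim[2]))
  for (a in x$areas) {
    m <- x$responses[[a]]
    d <- mean(m[, ncol(m)] - m[, 1])
    cat(sprintf("  %-5s mean full-vs-zero difference: %+.3f psc\n", a, d))
  }
  invisible(x)
}

#' Trend table over areas
#'
#' Computes the linear, quadratic and cubic trend coefficients and
#' permutation p-values for each area's coherence response matrix.
#'
#' @param fit A [analyze_cohort()] result.
#' @param n_iterations Permutation iterations per test.
#' @return Data frame with columns `area`, `trend`, `coefficient`,
#'   `p_two_tailed`.
#' @export
trend_table <- function(fit, n_iterations = 1e4) {
  stopifnot(inherits(fit, "cohort_fit"))
  contrasts <- orthogonal_contrasts(4)
  out <- list()
  for (a in fit$areas) {
    for (tr in names(contrasts)) {
      res <- permutation_trend_test(fit$responses[[a]], contrasts[[tr]],
                                    n_iterations = n_iterations)
      out[[length(out) + 1L]] <- data.frame(
        area = a, trend = tr, coefficient = res$coefficient,
        p_two_tailed = res$p_two_tailed)
    }
  }
  do.call(rbind, out)
}
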