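#' Legendre polynomial drift regressors
#'
#' Legendre polynomials P0..Pmax evaluated on `n_volumes` points equally
#' spaced over `[-1, 1]`, used to model slow per-run scanner drift.
#'
#' @param n_volumes Number of time points.
#' @param max_degree Highest polynomial degree (up to 3).
#' @return `n_volumes x (max_degree + 1)` matrix with columns `P0..Pmax`.
#' @export
legendre_regressors <- function(n_volumes, max_degree = 3) {
  stopifnot(max_degree >= 0, max_degree <= 3)
  if (n_volumes < max_degree + 1) {
    stop("need at least max_degree + 1 time points", call. = FALSE)
  }
  x <- if (n_volumes == 1) 0 else seq(-1, 1, length.out = n_volumes)
  P <- cbind(P0 = rep(1, n_volumes), P1 = x,
             P2 = (3 * x^2 - 1) / 2, P3 = (5 * x^3 - 3 * x) / 2)
  P[, seq_len(max_degree + 1), drop = FALSE]
}

#' Build the multi-run GLM design matrix
#'
#' One hemodynamic regressor per stimulus condition spanning all runs,
#' per-run Legendre drift blocks (degrees 0..3, zero outside their own
#' run), and six motion nuisance columns concatenated across runs and
#' standardized per run. The first `censor_volumes_per_run` rows of each
#' run are dropped from the design (and must be dropped from the data; see
#' [fit_node_glm()]). For the default protocol with 12 runs this is the
#' 2016 x 58 matrix (168 retained rows per run; 4 + 48 + 6 columns).
#'
#' @param timelines List of [build_run_timeline()] results, one per run.
#' @param motion List of `n_volumes x 6` motion matrices, one per run, or
#'   `NULL` to omit motion columns.
#' @param protocol A [block_protocol()].
#' @param hemo A [hemo_params()].
#' @return An object of class `design_matrix`: a list with the matrix `X`,
#'   index vectors `condition_cols`, `drift_cols`, `motion_cols`,
#'   `run_rows` (list of retained row indices per run, into `X`),
#'   `keep_volumes` (indices of retained volumes in the concatenated
#'   uncensored series) and `conditions`.
#' @export
build_design_matrix <- function(timelines, motion = NULL,
                                protocol = block_protocol(),
                                hemo = hemo_params()) {
  n_runs <- length(timelines)
  stopifnot(n_runs >= 1)
  if (!is.null(motion)) stopifnot(length(motion) == n_runs)
  conds <- timelines[[1]]$conditions
  n_vol <- vapply(timelines, function(tl) tl$n_volumes, integer(1))
  cens <- protocol$censor_volumes_per_run
  if (any(n_vol <= cens)) stop("run shorter than censor window", call. = FALSE)

  cond_blocks <- vector("list", n_runs)
  drift_blocks <- vector("list", n_runs)
  motion_blocks <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    keep <- (cens + 1L):n_vol[r]
    C <- sapply(conds, function(cc) {
      condition_regressor(timelines[[r]], cc, hemo, tr = protocol$tr)
    })
    cond_blocks[[r]] <- C[keep, , drop = FALSE]
    drift_blocks[[r]] <- legendre_regressors(n_vol[r], 3)[keep, , drop = FALSE]
    if (!is.null(motion)) {
      m <- motion[[r]]
      if (nrow(m) != n_vol[r] || ncol(m) != 6) {
        stop("motion matrix for run ", r, " must be n_volumes x 6",
             call. = FALSE)
      }
      m <- scale(m)
      m[is.nan(m)] <- 0
      motion_blocks[[r]] <- m[keep, , drop = FALSE]
    }
  }
  X_cond <- do.call(rbind, cond_blocks)
  n_keep <- vapply(cond_blocks, nrow, integer(1))
  total <- sum(n_keep)
  X_drift <- matrix(0, total, 4L * n_runs)
  offsets <- c(0L, cumsum(n_keep))
  for (r in seq_len(n_runs)) {
    rows <- (offsets[r] + 1L):offsets[r + 1L]
    X_drift[rows, (r - 1L) * 4L + 1:4] <- drift_blocks[[r]]
  }
  colnames(X_drift) <- paste0("run", rep(seq_len(n_runs), each = 4),
                              "_P", rep(0:3, n_runs))
  X <- cbind(X_cond, X_drift)
  motion_cols <- integer(0)
  if (!is.null(motion)) {
    X_mot <- do.call(rbind, motion_blocks)
    colnames(X_mot) <- paste0("motion", 1:6)
    motion_cols <- ncol(X) + 1:6
    X <- cbind(X, X_mot)
  }
  run_rows <- lapply(seq_len(n_runs),
                     function(r) (offsets[r] + 1L):offsets[r + 1L])
  keep_volumes <- unlist(lapply(seq_len(n_runs), function(r) {
    sum(n_vol[seq_len(r - 1L)]) + (cens + 1L):n_vol[r]
  }))
  structure(list(X = X,
                 condition_cols = seq_along(conds),
                 drift_cols = length(conds) + seq_len(4L * n_runs),
                 motion_cols = motion_cols,
                 run_rows = run_rows,
                 keep_volumes = keep_volumes,
                 conditions = conds),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("GLM design matrix: %d rows x %d columns\n",
              nrow(x$X), ncol(x$X)))
  cat(sprintf("  %d condition, %d drift, %d motion regressors; %d runs\n",
              length(x$condition_cols), length(x$drift_cols),
              length(x$motion_cols), length(x$run_rows)))
  invisible(x)
}

#' @export
dim.design_matrix <- function(x) dim(x$X)

# ARMA(1,1) innovation filter applied independently per run segment.
# For each run: z_t = x_t - a x_{t-1} (z_1 = x_1), then
# e_t = z_t - b e_{t-1} computed recursively. Identity when a = b = 0.
whiten_series <- function(x, a, b, run_rows) {
  if (!is.matrix(x)) {
    out <- x
    for (rows in run_rows) {
      seg <- x[rows]
      n <- length(seg)
      z <- seg
      if (n > 1) z[-1] <- seg[-1] - a * seg[-n]
      if (b != 0) z <- as.numeric(stats::filter(z, -b, method = "recursive"))
      out[rows] <- z
    }
    return(out)
  }
  out <- x
  for (rows in run_rows) {
    seg <- x[rows, , drop = FALSE]
    n <- nrow(seg)
    z <- seg
    if (n > 1) z[-1, ] <- seg[-1, , drop = FALSE] - a * seg[-n, , drop = FALSE]
    if (b != 0 && n > 1) {
      # stats::filter handles the columns of a matrix in one call
      z <- unname(as.matrix(stats::filter(z, -b, method = "recursive")))
    }
    out[rows, ] <- z
  }
  out
}

#' Estimate ARMA(1,1) noise coefficients from pooled residuals
#'
#' Maximizes the conditional Gaussian likelihood (conditional sum of
#' squares of the innovations, computed independently within each run so
#' run boundaries are respected), initialized from moment matching on the
#' pooled lag-1/lag-2 autocorrelations and constrained to the
#' stationarity/invertibility box. Falls back to the moment estimate with
#' a warning if the optimizer fails or the residuals are degenerate.
#'
#' @param residuals Numeric vector of pooled residuals.
#' @param run_rows List of index vectors delimiting runs; defaults to one
#'   run spanning the series.
#' @param bound Box constraint on |a| and |b|.
#' @return Named numeric vector `c(a = , b = )`.
#' @export
estimate_arma11 <- function(residuals, run_rows = list(seq_along(residuals)),
                            bound = 0.95) {
  x <- as.numeric(residuals)
  if (length(x) < 50) stop("need at least 50 residual points", call. = FALSE)
  if (stats::sd(x) == 0) {
    warning("constant residuals; falling back to white-noise estimate",
            call. = FALSE)
    return(c(a = 0, b = 0))
  }
  # pooled lag-1/lag-2 autocorrelations across runs
  num1 <- num2 <- den <- 0
  for (rows in run_rows) {
    seg <- x[rows] - mean(x[rows])
    n <- length(seg)
    den <- den + sum(seg^2)
    if (n > 1) num1 <- num1 + sum(seg[-1] * seg[-n])
    if (n > 2) num2 <- num2 + sum(seg[-(1:2)] * seg[-((n - 1):n)])
  }
  r1 <- num1 / den
  r2 <- num2 / den
  a0 <- if (abs(r1) > 1e-8) max(-bound, min(bound, r2 / r1)) else 0
  css <- function(par) {
    e <- whiten_series(x, par[1], par[2], run_rows)
    sum(e^2)
  }
  # two starts guard against the a = -b cancellation ridge (any point on
  # it is observationally white noise)
  starts <- if (abs(a0) > 0.02) list(c(0, 0), c(a0, 0)) else list(c(0, 0))
  fits <- lapply(starts, function(start) {
    tryCatch(
      stats::optim(start, css, method = "L-BFGS-B",
                   lower = c(-bound, -bound), upper = c(bound, bound),
                   control = list(factr = 1e9)),
      error = function(e) NULL)
  })
  fits <- Filter(function(f) !is.null(f) && f$convergence == 0, fits)
  if (length(fits) == 0) {
    warning("ARMA(1,1) likelihood optimization failed; ",
            "using moment estimates", call. = FALSE)
    return(c(a = a0, b = 0))
  }
  # candidate estimates, including the degenerate white-noise model; when
  # a candidate is within the chi-square(2) 95% band of the best
  # concentrated log-likelihood (n log SS), prefer the most parsimonious
  # -- this resolves the cancellation ridge to (0, 0)
  cand <- c(lapply(fits, `[[`, "par"), list(c(0, 0)))
  n_obs <- length(x)
  ll <- vapply(cand, function(p) n_obs * log(css(p)), numeric(1))
  keep <- which(ll <= min(ll) + stats::qchisq(0.95, 2))
  size <- vapply(cand[keep], function(p) sum(abs(p)), numeric(1))
  best <- cand[keep][[which.min(size)]]
  c(a = best[1], b = best[2])
}

#' Fit the GLM to one node's timecourse
#'
#' Ordinary least squares, optionally followed by ARMA(1,1) prewhitening:
#' the noise coefficients are estimated from the OLS residuals
#' ([estimate_arma11()]) and the model is refit by generalized least
#' squares, implemented as OLS on the innovation-filtered data and design
#' (filtering applied per run). With estimated coefficients (0, 0) the
#' whitened fit equals OLS exactly.
#'
#' @param y Node timecourse: either the full concatenated uncensored
#'   series (censored rows are dropped using the design's bookkeeping) or
#'   a vector already matching the design's rows.
#' @param design A [build_design_matrix()] result.
#' @param whiten Whether to prewhiten (two-pass GLS).
#' @return An object of class `node_glm` with components `betas`,
#'   `residuals` (raw scale), `fitted`, `arma`, `baseline_mean`, `sigma2`,
#'   `cov_unscaled`, `df_residual`, and the column bookkeeping from the
#'   design.
#' @export
fit_node_glm <- function(y, design, whiten = TRUE) {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$X
  if (length(y) == nrow(X)) {
    yk <- as.numeric(y)
  } else if (length(y) >= max(design$keep_volumes)) {
    yk <- as.numeric(y)[design$keep_volumes]
  } else {
    stop("length of y matches neither the censored nor the full series",
         call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)
  beta <- qr.coef(qrX, yk)
  arma <- c(a = 0, b = 0)
  if (whiten) {
    res0 <- yk - as.numeric(X %*% beta)
    arma <- suppressWarnings(estimate_arma11(res0, design$run_rows))
    if (any(arma != 0)) {
      Xw <- whiten_series(X, arma["a"], arma["b"], design$run_rows)
      yw <- as.numeric(whiten_series(yk, arma["a"], arma["b"],
                                     design$run_rows))
      qrX <- qr(Xw)
      if (qrX$rank < ncol(Xw)) {
        stop("whitened design matrix is rank deficient", call. = FALSE)
      }
      beta <- qr.coef(qrX, yw)
      res_w <- yw - as.numeric(Xw %*% beta)
    } else {
      res_w <- res0
    }
  } else {
    res_w <- yk - as.numeric(X %*% beta)
  }
  names(beta) <- colnames(X)
  fitted <- as.numeric(X %*% beta)
  df_res <- nrow(X) - ncol(X)
  R <- qr.R(qrX)
  cov_unscaled <- chol2inv(R)
  baseline_mean <- mean(X[, design$drift_cols, drop = FALSE] %*%
                          beta[design$drift_cols])
  structure(list(betas = beta,
                 residuals = yk - fitted,
                 fitted = fitted,
                 arma = arma,
                 sigma2 = sum(res_w^2) / df_res,
                 cov_unscaled = cov_unscaled,
                 df_residual = df_res,
                 baseline_mean = baseline_mean,
                 condition_cols = design$condition_cols,
                 conditions = design$conditions),
            class = "node_glm")
}

#' @export
print.node_glm <- function(x, ...) {
  cat("Prewhitened node GLM fit\n")
  cat(sprintf("  ARMA(1,1): a = %.3f, b = %.3f; residual df = %d\n",
              x$arma["a"], x$arma["b"], x$df_residual))
  cat(sprintf("  baseline (drift) level: %.2f\n", x$baseline_mean))
  cat("  condition betas:\n")
  print(round(x$betas[x$condition_cols], 4))
  invisible(x)
}

#' @export
coef.node_glm <- function(object, ...) object$betas

#' @export
residuals.node_glm <- function(object, ...) object$residuals

#' @export
fitted.node_glm <- function(object, ...) object$fitted

#' Convert condition betas to percent signal change
#'
#' Divides each condition beta by the node's baseline level -- the mean of
#' the fitted drift-only (Legendre) timecourse -- and scales by 100.
#' Invariant to rescaling the raw signal.
#'
#' @param fit A [fit_node_glm()] result.
#' @return Named numeric vector of psc values, one per condition.
#' @export
betas_to_psc <- function(fit) {
  stopifnot(inherits(fit, "node_glm"))
  if (!is.finite(fit$baseline_mean) || fit$baseline_mean <= 0) {
    stop("baseline level must be positive for psc conversion", call. = FALSE)
  }
  psc <- 100 * fit$betas[fit$condition_cols] / fit$baseline_mean
  names(psc) <- fit$conditions
  psc
}

#' Responsiveness t-statistic of a node
#'
#' Tests the all-stimulus-versus-baseline contrast (unweighted sum of the
#' condition betas) against zero using the whitened fit's variance.
#'
#' @param fit A [fit_node_glm()] result.
#' @return List with `t`, one-sided `p` (for the > 0 alternative) and
#'   `df`.
#' @export
node_responsiveness <- function(fit) {
  stopifnot(inherits(fit, "node_glm"))
  cvec <- numeric(length(fit$betas))
  cvec[fit$condition_cols] <- 1
  est <- sum(cvec * fit$betas)
  se <- sqrt(fit$sigma2 * drop(t(cvec) %*% fit$cov_unscaled %*% cvec))
  tval <- est / se
  list(t = tval, p = stats::pt(tval, fit$df_residual, lower.tail = FALSE),
       df = fit$df_residual)
}

#' Select stimulus-responsive nodes by FDR within hemisphere
#'
#' Benjamini-Hochberg correction of the one-sided responsiveness p-values,
#' applied separately within each hemisphere group, at level `q`.
#'
#' @param p_values Numeric vector of one-sided p-values, one per node.
#' @param hemispheres Group label per node (correction is run within each
#'   label separately).
#' @param q FDR level.
#' @return Logical vector: `TRUE` for selected nodes.
#' @export
select_responsive_nodes <- function(p_values, hemispheres, q = 0.001) {
  stopifnot(length(p_values) == length(hemispheres), q > 0, q < 1)
  sel <- logical(length(p_values))
  for (h in unique(hemispheres)) {
    idx <- which(hemispheres == h)
    if (length(idx) == 0) next
    sel[idx] <- stats::p.adjust(p_values[idx], method = "BH") < q
  }
  sel
}

#' Assemble a participant-by-condition area response matrix
#'
#' For each participant, percent-signal-change values are averaged over
#' that participant's selected nodes per condition, then normalized by
#' subtracting the participant's mean across the stimulus conditions (so
#' every row sums to zero).
#'
#' @param psc_by_participant List (one element per participant) of
#'   `nodes x conditions` psc matrices for the selected nodes; a
#'   participant with zero rows is an error.
#' @param area Area label.
#' @return An object of class `area_response`: a `participants x
#'   conditions` matrix with attributes `area` and `n_nodes_selected`.
#' @export
area_coherence_response <- function(psc_by_participant, area = "") {
  n_nodes <- vapply(psc_by_participant,
                    function(m) nrow(as.matrix(m)), integer(1))
  if (any(n_nodes == 0)) {
    stop("no selected nodes for participant(s) ",
         paste(which(n_nodes == 0), collapse = ", "), " in area ", area,
         call. = FALSE)
  }
  rows <- t(vapply(psc_by_participant,
                   function(m) colMeans(as.matrix(m)),
                   numeric(ncol(as.matrix(psc_by_participant[[1]])))))
  rows <- rows - rowMeans(rows)
  structure(rows, class = c("area_response", "matrix", "array"),
            area = area, n_nodes_selected = n_nodes)
}

#' @export
print.area_response <- function(x, ...) {
  cat(sprintf("Area coherence response matrix%s: %d participants x %d conditions\n",
              if (nzchar(attr(x, "area"))) paste0(" (", attr(x, "area"), ")") else "",
              nrow(x), ncol(x)))
  print(round(unclass(x), 4))
  cat("  nodes selected per participant:",
      paste(attr(x, "n_nodes_selected"), collapse = ", "), "\n")
  invisible(x)
}
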