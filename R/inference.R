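#' Integer orthogonal polynomial contrast vectors
#'
#' Linear, quadratic and cubic trend contrasts for `k` equally spaced
#' levels, scaled to the conventional smallest-integer weights. For k = 4
#' these are `[-3, -1, +1, +3]`, `[+1, -1, -1, +1]` and `[-1, +3, -3, +1]`.
#' Each vector sums to zero and the vectors are mutually orthogonal.
#'
#' @param k Number of ordered levels (at least 2).
#' @return Named list of integer vectors (`linear`, and where `k` allows,
#'   `quadratic`, `cubic`).
#' @export
orthogonal_contrasts <- function(k) {
  if (k < 2) stop("need at least 2 levels", call. = FALSE)
  cp <- stats::contr.poly(k)
  degrees <- seq_len(min(3L, k - 1L))
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  out <- lapply(degrees, function(d) {
    v <- cp[, d] / min(abs(cp[abs(cp[, d]) > 1e-9, d]))
    # smallest multiplier making the normalized weights integral
    for (m in 1:1000) {
      if (all(abs(m * v - round(m * v)) < 1e-6)) { v <- round(m * v); break }
    }
    as.integer(v / Reduce(gcd2, abs(v[v != 0])))
  })
  stats::setNames(out, c("linear", "quadratic", "cubic")[degrees])
}

#' Group trend coefficient of a coherence response matrix
#'
#' The per-participant dot product of the (normalized) psc row with the
#' contrast weights, averaged across participants. Because the weights sum
#' to zero, the coefficient is invariant to adding any per-participant
#' constant.
#'
#' @param matrix A `participants x conditions` matrix (e.g. an
#'   [area_coherence_response()]).
#' @param weights Contrast weight vector, length `ncol(matrix)`.
#' @return Scalar coefficient.
#' @export
trend_coefficient <- function(matrix, weights) {
  m <- as.matrix(matrix)
  if (ncol(m) != length(weights)) {
    stop("contrast length does not match the number of conditions",
         call. = FALSE)
  }
  mean(m %*% weights)
}

#' Permutation test of a trend coefficient
#'
#' Builds the null distribution by independently permuting each
#' participant's condition values on every iteration (exchangeability of
#' conditions within participant under the null of no coherence effect)
#' and recomputing the group coefficient. The one-tailed p-value counts
#' null coefficients as or more extreme than the observed one in the
#' observed direction, with add-one correction
#' `(1 + count) / (n_iterations + 1)`; the two-tailed p doubles it
#' (capped at 1).
#'
#' @param matrix A `participants x conditions` matrix.
#' @param weights Contrast weight vector.
#' @param n_iterations Number of permutation iterations.
#' @param exhaustive If `TRUE`, enumerate all joint permutations instead
#'   of sampling (feasible only for very few participants); the p-value is
#'   then `count / total` without the add-one correction.
#' @return An object of class `trend_result`: list with `coefficient`,
#'   `p_one_tailed`, `p_two_tailed`, `observed_direction`, `n_iterations`.
#' @export
permutation_trend_test <- function(matrix, weights, n_iterations = 1e4,
                                   exhaustive = FALSE) {
  m <- as.matrix(matrix)
  k <- ncol(m)
  n_ppt <- nrow(m)
  if (n_ppt < 2) stop("need at least 2 participants", call. = FALSE)
  if (k != length(weights)) {
    stop("contrast length does not match the number of conditions",
         call. = FALSE)
  }
  obs <- mean(m %*% weights)
  perms <- all_permutations(k)
  # value of each participant's row under each of the k! permutations
  pv <- vapply(seq_len(nrow(perms)),
               function(p) as.numeric(m[, perms[p, ], drop = FALSE] %*% weights),
               numeric(n_ppt))
  pv <- matrix(pv, n_ppt)  # ppt x perm

  dir <- sign(obs)
  if (exhaustive) {
    grid <- as.matrix(expand.grid(rep(list(seq_len(nrow(perms))), n_ppt)))
    nulls <- rowMeans(sapply(seq_len(n_ppt), function(i) pv[i, grid[, i]]))
    n_it <- nrow(grid)
    extreme <- if (dir >= 0) sum(nulls >= obs) else sum(nulls <= obs)
    p1 <- extreme / n_it
  } else {
    n_it <- as.integer(n_iterations)
    idx <- matrix(sample.int(nrow(perms), n_ppt * n_it, replace = TRUE),
                  n_ppt, n_it)
    vals <- matrix(pv[cbind(rep(seq_len(n_ppt), n_it), as.vector(idx))],
                   n_ppt, n_it)
    nulls <- colMeans(vals)
    extreme <- if (dir >= 0) sum(nulls >= obs) else sum(nulls <= obs)
    p1 <- (1 + extreme) / (n_it + 1)
  }
  if (obs == 0) p1 <- 1
  structure(list(coefficient = obs,
                 p_one_tailed = p1,
                 p_two_tailed = min(1, 2 * p1),
                 observed_direction = dir,
                 n_iterations = n_it),
            class = "trend_result")
}

# all k! permutations of 1:k as a (k! x k) matrix, built by inserting k
# into every position of each (k-1)-permutation
all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, k * nrow(sub), k)
  row <- 1L
  for (s in seq_len(nrow(sub))) {
    for (pos in seq_len(k)) {
      out[row, ] <- append(sub[s, ], k, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf(
    "Permutation trend test: coefficient %+.4f, two-tailed p = %.4g (%d iterations)\n",
    x$coefficient, x$p_two_tailed, x$n_iterations))
  invisible(x)
}

#' Trend analysis binned by meridian distance
#'
#' Groups an area's nodes by the angular distance of their visual-field
#' preference from the vertical meridian, and runs the area-level
#' pipeline (participant averaging, normalization, permutation trend
#' test) within each bin. Used to check that the V3 coherence effect is
#' not confined to nodes bordering the mid-level areas near the vertical
#' meridian.
#'
#' @param area_nodes One area's per-participant node data as produced by
#'   [analyze_cohort()] (`node_psc[[area]]`): a list with elements `psc`,
#'   `selected` and `meridian_distance` per participant.
#' @param bin_edges Increasing break points partitioning `[0, 90]`.
#' @param weights Contrast weight vector.
#' @param n_iterations Permutation iterations per bin.
#' @return A list with one element per bin, each either a `trend_result`
#'   (with attribute `bin` giving the edges) or `NULL` if some
#'   participant has no selected node in the bin.
#' @export
binned_trend_analysis <- function(area_nodes,
                                  bin_edges = c(0, 22.5, 45, 67.5, 90),
                                  weights = orthogonal_contrasts(4)$linear,
                                  n_iterations = 1e4) {
  stopifnot(length(bin_edges) >= 2, !is.unsorted(bin_edges))
  n_bins <- length(bin_edges) - 1L
  out <- vector("list", n_bins)
  names(out) <- paste0("[", bin_edges[-length(bin_edges)], ",",
                       bin_edges[-1], ")")
  for (b in seq_len(n_bins)) {
    lo <- bin_edges[b]; hi <- bin_edges[b + 1L]
    per_ppt <- lapply(area_nodes, function(d) {
      in_bin <- d$meridian_distance >= lo &
        (d$meridian_distance < hi | (b == n_bins & d$meridian_distance <= hi))
      d$psc[d$selected & in_bin, , drop = FALSE]
    })
    if (any(vapply(per_ppt, nrow, integer(1)) == 0)) {
      out[b] <- list(NULL)
      next
    }
    resp <- area_coherence_response(per_ppt)
    res <- permutation_trend_test(resp, weights, n_iterations = n_iterations)
    attr(res, "bin") <- c(lo, hi)
    out[[b]] <- res
  }
  out
}
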