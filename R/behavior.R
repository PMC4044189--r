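#' Discretize event times into binary bins
#'
#' Bin `i` (1-based) is 1 iff at least one event falls in
#' `[(i-1) w, i w)`.
#'
#' @param times Event times (seconds), within `[0, duration)`.
#' @param duration Series duration (seconds).
#' @param bin_width Bin width (seconds).
#' @return Integer 0/1 vector of length `ceiling(duration / bin_width)`.
#' @export
bin_events <- function(times, duration, bin_width = 0.1) {
  if (any(times < 0 | times >= duration)) {
    stop("event times must lie within [0, duration)", call. = FALSE)
  }
  n_bins <- as.integer(ceiling(duration / bin_width))
  out <- integer(n_bins)
  out[unique(as.integer(floor(times / bin_width)) + 1L)] <- 1L
  out
}

#' Lagged target-response correlations per stimulus condition
#'
#' For each condition and response lag, the Pearson correlation (phi
#' coefficient, as the series are binary) between the target train and the
#' response train shifted by the lag, restricted to bins whose active
#' block has that condition label (attribution follows the target bin);
#' lagged indices running past the end of the series are dropped.
#'
#' @param target,response Equal-length binary series (runs concatenated).
#' @param condition_bins Condition label per bin.
#' @param lags Lags in seconds; default 15 lags, 0 to 1.4 s.
#' @param bin_width Bin width (seconds).
#' @return An object of class `lag_correlation`: a `conditions x lags`
#'   matrix of correlations (`NA` where a restriction has zero variance),
#'   with attribute `lags`.
#' @export
lagged_correlation <- function(target, response, condition_bins,
                               lags = seq(0, 1.4, by = 0.1),
                               bin_width = 0.1) {
  n <- length(target)
  stopifnot(length(response) == n, length(condition_bins) == n)
  conds <- setdiff(unique(condition_bins), "blank")
  out <- matrix(NA_real_, length(conds), length(lags),
                dimnames = list(conds, sprintf("%.1f", lags)))
  for (li in seq_along(lags)) {
    shift <- as.integer(round(lags[li] / bin_width))
    idx <- seq_len(n - shift)
    for (ci in seq_along(conds)) {
      sel <- idx[condition_bins[idx] == conds[ci]]
      if (length(sel) < 2) next
      tg <- target[sel]
      rs <- response[sel + shift]
      if (stats::sd(tg) == 0 || stats::sd(rs) == 0) next
      out[ci, li] <- stats::cor(tg, rs)
    }
  }
  structure(out, class = c("lag_correlation", "matrix", "array"),
            lags = lags)
}

#' Two-way repeated-measures ANOVA on lag correlations
#'
#' Condition (fixed) by lag (fixed) by participant (random) ANOVA on a
#' complete balanced table of correlations: one observation per
#' participant, condition and lag. Each fixed effect is tested against
#' its interaction with the random participant factor (condition against
#' condition:participant, lag against lag:participant, condition:lag
#' against condition:lag:participant). A pooled-error variant -- all
#' three participant-interaction strata pooled into one error term -- is
#' additionally reported, clearly labeled.
#'
#' @param data Data frame with columns `participant`, `condition`, `lag`
#'   and `r` (the correlation), complete and balanced.
#' @return An object of class `rm_anova`: list with `table` (per-effect
#'   SS, df, error SS/df, F, p), `pooled` (same effects against the
#'   pooled error), and `ss_total`.
#' @export
two_way_rm_anova <- function(data) {
  stopifnot(all(c("participant", "condition", "lag", "r") %in% names(data)))
  P <- factor(data$participant)
  A <- factor(data$condition)
  B <- factor(data$lag)
  y <- data$r
  np <- nlevels(P); na <- nlevels(A); nb <- nlevels(B)
  if (nrow(data) != np * na * nb || anyNA(y)) {
    stop("data must be a complete balanced participant x condition x lag table",
         call. = FALSE)
  }
  if (np < 2) stop("need at least 2 participants", call. = FALSE)
  gm <- mean(y)
  mean_of <- function(...) tapply(y, list(...), mean)
  mP <- mean_of(P); mA <- mean_of(A); mB <- mean_of(B)
  mPA <- mean_of(P, A); mPB <- mean_of(P, B); mAB <- mean_of(A, B)
  ss <- function(m, mult) mult * sum((m - gm)^2)
  ss_P <- ss(mP, na * nb)
  ss_A <- ss(mA, np * nb)
  ss_B <- ss(mB, np * na)
  # interaction SS from cell means
  ss_PA <- nb * sum((mPA - outer(mP, mA, "+") + gm)^2)
  ss_PB <- na * sum((mPB - outer(mP, mB, "+") + gm)^2)
  ss_AB <- np * sum((mAB - outer(mA, mB, "+") + gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_PAB <- ss_tot - ss_P - ss_A - ss_B - ss_PA - ss_PB - ss_AB

  df_A <- na - 1; df_B <- nb - 1; df_AB <- df_A * df_B
  df_PA <- df_A * (np - 1); df_PB <- df_B * (np - 1)
  df_PAB <- df_AB * (np - 1)

  fp <- function(ss_eff, df_eff, ss_err, df_err) {
    if (ss_err <= 0 || df_err <= 0) return(c(NA_real_, NA_real_))
    Fv <- (ss_eff / df_eff) / (ss_err / df_err)
    c(Fv, stats::pf(Fv, df_eff, df_err, lower.tail = FALSE))
  }
  rows <- rbind(
    condition = c(ss_A, df_A, ss_PA, df_PA, fp(ss_A, df_A, ss_PA, df_PA)),
    lag = c(ss_B, df_B, ss_PB, df_PB, fp(ss_B, df_B, ss_PB, df_PB)),
    `condition:lag` = c(ss_AB, df_AB, ss_PAB, df_PAB,
                        fp(ss_AB, df_AB, ss_PAB, df_PAB)))
  tab <- as.data.frame(rows)
  names(tab) <- c("ss", "df", "ss_error", "df_error", "F", "p")
  tab$effect <- rownames(rows)
  tab <- tab[, c("effect", "ss", "df", "ss_error", "df_error", "F", "p")]
  rownames(tab) <- NULL

  ss_pool <- ss_PA + ss_PB + ss_PAB
  df_pool <- df_PA + df_PB + df_PAB
  pooled <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    v <- fp(tab$ss[i], tab$df[i], ss_pool, df_pool)
    data.frame(effect = tab$effect[i], ss = tab$ss[i], df = tab$df[i],
               ss_error = ss_pool, df_error = df_pool, F = v[1], p = v[2])
  }))

  structure(list(table = tab, pooled = pooled,
                 ss_participant = ss_P, df_participant = np - 1,
                 ss_total = ss_tot),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Two-way repeated-measures ANOVA",
      "(effects tested against their participant interactions)\n")
  tab <- x$table
  tab$F <- round(tab$F, 2)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  cat("pooled-error variant:\n")
  pl <- x$pooled
  pl$F <- round(pl$F, 2)
  pl$p <- signif(pl$p, 3)
  print(pl[, c("effect", "df", "df_error", "F", "p")], row.names = FALSE)
  invisible(x)
}

#' Behavioral analysis of a simulated cohort's fixation task
#'
#' Concatenates each participant's runs, computes the per-condition lagged
#' correlations, and runs the repeated-measures ANOVA over participants,
#' conditions and lags.
#'
#' @param trains List (participants) of lists (runs) of
#'   [simulate_behavior_run()] results.
#' @param lags Lags in seconds.
#' @param bin_width Bin width (seconds).
#' @return List with `correlations` (long data frame: participant,
#'   condition, lag, r) and `anova` (an `rm_anova`).
#' @export
behavior_analysis <- function(trains, lags = seq(0, 1.4, by = 0.1),
                              bin_width = 0.1) {
  long <- list()
  for (p in seq_along(trains)) {
    target <- unlist(lapply(trains[[p]], `[[`, "target_bins"))
    response <- unlist(lapply(trains[[p]], `[[`, "response_bins"))
    cond <- unlist(lapply(trains[[p]], `[[`, "condition_bins"))
    lc <- lagged_correlation(target, response, cond, lags, bin_width)
    long[[p]] <- data.frame(
      participant = p,
      condition = rep(rownames(lc), ncol(lc)),
      lag = rep(attr(lc, "lags"), each = nrow(lc)),
      r = as.vector(lc))
  }
  correlations <- do.call(rbind, long)
  anova <- two_way_rm_anova(correlations)
  list(correlations = correlations, anova = anova)
}
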