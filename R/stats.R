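#' Wilcoxon signed rank test for paired screen-time comparisons
#'
#' Two-sided Wilcoxon signed rank test on paired differences `y - x`.
#' Zero differences are removed first (Wilcoxon convention) and tied
#' absolute differences are mid-ranked. In `"auto"` mode the p-value is
#' exact — from the signed-rank null distribution, equivalent to
#' enumerating all 2^m sign assignments — when at most 25 nonzero
#' differences remain and their magnitudes are tie-free (the signed-rank
#' distribution is then valid); with ties in the magnitudes, direct
#' sign-flip enumeration over the mid-ranks is used for up to 16 nonzero
#' differences, and beyond that a normal approximation with tie and
#' continuity corrections. `"exact"` and `"approx"` force a method
#' (forced exact under ties is limited to m = 16 by enumeration cost).
#'
#' @param x,y Paired numeric vectors (e.g. subjective and objective
#'   minutes/day); with `y = NULL`, `x` is taken as the differences.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @param exact_max Largest m for which auto mode uses the exact
#'   distribution.
#' @return A list `statistic` (V, sum of positive ranks), `p_value`,
#'   `n_used` (pairs after zero removal), `method`, `degenerate`. When all
#'   differences are zero the result is degenerate: no p-value is
#'   produced.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 mode = c("auto", "exact", "approx"),
                                 exact_max = 25) {
  mode <- match.arg(mode)
  d <- if (is.null(y)) x else y - x
  stopifnot(is.numeric(d))
  d <- d[!is.na(d)]
  if (length(d) == 0) stop("no paired observations", call. = FALSE)
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, n_used = 0L,
                method = "degenerate", degenerate = TRUE))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0

  use_exact <- switch(mode,
                      auto = m <= exact_max && (!ties || m <= 16),
                      exact = TRUE,
                      approx = FALSE)
  if (use_exact && !ties) {
    res <- suppressWarnings(
      stats::wilcox.test(d, mu = 0, exact = TRUE, correct = TRUE))
    method <- "exact"
    p <- res$p.value
  } else if (use_exact) {
    if (m > 16) {
      stop("exact mode with tied |differences| requires m <= 16 ",
           "(direct enumeration); use mode = 'approx'", call. = FALSE)
    }
    p <- exact_p_by_enumeration(r, v)
    method <- "exact_enumeration"
  } else {
    res <- suppressWarnings(
      stats::wilcox.test(d, mu = 0, exact = FALSE, correct = TRUE))
    method <- "normal_approximation"
    p <- res$p.value
  }
  list(statistic = unname(v), p_value = p, n_used = m,
       method = method, degenerate = FALSE)
}

# Two-sided p by enumerating all 2^m sign assignments of the (mid-)ranks;
# symmetric-tail counting: P(|V - mu| >= |v - mu|).
exact_p_by_enumeration <- function(ranks, v) {
  m <- length(ranks)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  vs <- as.vector(signs %*% ranks)
  mu <- sum(ranks) / 2
  mean(abs(vs - mu) >= abs(v - mu) - 1e-12)
}

#' Paired t-test on screen-time differences
#'
#' Classical paired t on `y - x` with `n - 1` degrees of freedom. The
#' published comparison tables flag significance from paired t-tests, so
#' it is computed alongside the (primary) Wilcoxon test.
#'
#' @param x,y Paired numeric vectors.
#' @return A list `statistic`, `df`, `p_value`, `n`.
#' @export
paired_t <- function(x, y) {
  d <- y - x
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2) stop("paired t needs at least 2 pairs", call. = FALSE)
  if (stats::sd(d) == 0) {
    stop("paired t undefined: differences have zero variance", call. = FALSE)
  }
  res <- stats::t.test(d, mu = 0)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, n = n)
}

#' Correlation between subjective and objective screen time
#'
#' Spearman's rank correlation (Pearson on mid-ranks, p from the
#' asymptotic t approximation) or Pearson's product-moment correlation,
#' two-sided.
#'
#' @param x,y Paired numeric vectors, `n >= 3`.
#' @param kind `"spearman"` (default) or `"pearson"`.
#' @return A list `estimate`, `p_value`, `n`, `kind`.
#' @export
rank_correlation <- function(x, y, kind = c("spearman", "pearson")) {
  kind <- match.arg(kind)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("correlation needs at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  res <- suppressWarnings(
    stats::cor.test(x, y, method = kind, exact = FALSE))
  list(estimate = unname(res$estimate), p_value = res$p.value,
       n = n, kind = kind)
}

#' Paired subjective-vs-objective comparison for one grid cell
#'
#' Means and sample SDs of both measures, Wilcoxon signed rank (primary
#' test), paired t, Spearman and Pearson correlations, and the mean
#' discrepancy `objective - subjective` (positive means the participant
#' under-reported relative to the sensor). The flag follows the primary
#' test: `"significant"` when p < `alpha`, `"borderline"` when
#' `alpha <= p <` `borderline`, else `"ns"`. Degenerate or inapplicable
#' tests (n too small, zero variance) yield `NA` statistics rather than
#' errors so a whole sensitivity grid never dies on one empty cell.
#'
#' @param subjective,objective Paired minutes/day vectors.
#' @param alpha Significance level (two-sided).
#' @param borderline Upper edge of the borderline band.
#' @return A one-row tibble (see [run_grid()] for the columns).
#' @export
compare_cell <- function(subjective, objective, alpha = 0.05,
                         borderline = 0.10) {
  ok <- !is.na(subjective) & !is.na(objective)
  subjective <- subjective[ok]
  objective <- objective[ok]
  n <- length(subjective)
  na_cell <- tibble::tibble(
    n = n, subj_mean = NA_real_, subj_sd = NA_real_,
    obj_mean = NA_real_, obj_sd = NA_real_, discrepancy = NA_real_,
    wilcoxon_v = NA_real_, p_wilcoxon = NA_real_,
    t_stat = NA_real_, p_t = NA_real_,
    spearman_rho = NA_real_, p_spearman = NA_real_,
    pearson_r = NA_real_, p_pearson = NA_real_,
    flag = "ns"
  )
  if (n == 0) return(na_cell)

  out <- na_cell
  out$subj_mean <- mean(subjective)
  out$subj_sd <- if (n >= 2) stats::sd(subjective) else NA_real_
  out$obj_mean <- mean(objective)
  out$obj_sd <- if (n >= 2) stats::sd(objective) else NA_real_
  out$discrepancy <- out$obj_mean - out$subj_mean

  w <- wilcoxon_signed_rank(subjective, objective)
  if (!w$degenerate) {
    out$wilcoxon_v <- w$statistic
    out$p_wilcoxon <- w$p_value
  }
  tt <- try_stat(paired_t(subjective, objective))
  if (!is.null(tt)) {
    out$t_stat <- tt$statistic
    out$p_t <- tt$p_value
  }
  sp <- try_stat(rank_correlation(subjective, objective, "spearman"))
  if (!is.null(sp)) {
    out$spearman_rho <- sp$estimate
    out$p_spearman <- sp$p_value
  }
  pe <- try_stat(rank_correlation(subjective, objective, "pearson"))
  if (!is.null(pe)) {
    out$pearson_r <- pe$estimate
    out$p_pearson <- pe$p_value
  }
  p <- out$p_wilcoxon
  out$flag <- if (is.na(p)) "ns" else if (p < alpha) "significant" else
    if (p < borderline) "borderline" else "ns"
  out
}

try_stat <- function(expr) {
  tryCatch(expr, error = function(e) NULL)
}

#' Correlation panel across continuous-usage cut-points
#'
#' Extracts, at one fixed notification cut-point, the subjective-objective
#' correlation for every continuous-usage cap and both day types — the
#' published correlation figure is this panel at the 20 s cut-point.
#'
#' @param grid A `screenstate_grid` from [run_grid()].
#' @param cutpoint_s Notification cut-point to slice at (default 20 s).
#' @param daily_rule Which daily-rule arm to use.
#' @param kind `"spearman"` or `"pearson"` columns to surface.
#' @return A tibble `day_type, cap_h, n, estimate, p_value` with one row
#'   per cap level per day type.
#' @export
correlation_panel <- function(grid, cutpoint_s = 20,
                              daily_rule = "include_all",
                              kind = c("spearman", "pearson")) {
  kind <- match.arg(kind)
  est_col <- if (kind == "spearman") "spearman_rho" else "pearson_r"
  p_col <- if (kind == "spearman") "p_spearman" else "p_pearson"
  g <- grid[grid$cutpoint_s == cutpoint_s & grid$daily_rule == daily_rule, ,
            drop = FALSE]
  if (nrow(g) == 0) {
    stop("no grid cells at cutpoint ", cutpoint_s, " under rule ",
         daily_rule, call. = FALSE)
  }
  tibble::tibble(
    day_type = g$day_type,
    cap_h = g$cap_h,
    n = g$n,
    estimate = g[[est_col]],
    p_value = g[[p_col]]
  )
}
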