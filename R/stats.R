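#' Exact two-sided Fisher test for a 2 x 2 table
#'
#' Exact hypergeometric test computed from scratch by enumerating every
#' table consistent with the observed margins. The two-sided p-value follows
#' the sum-of-small-probabilities convention: the sum of the probabilities of
#' all tables whose probability does not exceed that of the observed table
#' (a relative tolerance of 1e-7 treats numerically tied tables as tied).
#' Probabilities come from log-factorials, so large counts stay exact to
#' double precision.
#'
#' @param a,b,c,d non-negative integer cell counts; rows are groups, columns
#'   outcome present/absent, i.e. the table is `rbind(c(a, b), c(c, d))`.
#' @return the two-sided p-value.
#' @examples
#' fisher_exact_two_sided(13, 3, 1, 11) # prints as 0.0003
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers")
  }
  n <- a + b + c + d
  if (n < 1) stop("table total must be >= 1")
  r1 <- a + b
  c1 <- a + c
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) {
    return(1) # a zero margin admits a single table
  }
  lfact <- lgamma(seq_len(n + 1)) # lfact[k + 1] = log(k!)
  lf <- function(k) lfact[k + 1]
  log_p_table <- function(x) {
    # P(X = x) for cell a under fixed margins (hypergeometric)
    lf(r1) + lf(n - r1) + lf(c1) + lf(n - c1) - lf(n) -
      (lf(x) + lf(r1 - x) + lf(c1 - x) + lf(n - r1 - c1 + x))
  }
  support <- max(0, r1 + c1 - n):min(r1, c1)
  logp <- vapply(support, log_p_table, numeric(1))
  obs <- logp[support == a]
  sum(exp(logp[logp <= obs + log(1 + 1e-7)]))
}

#' Sholl area-under-curve group comparison
#'
#' Summarizes each cell's normalized 10-bin Sholl profile by the trapezoidal
#' area under the curve (bins plotted against bin midpoints of normalized
#' radial distance), then compares the two groups of per-cell AUCs with a
#' two-sample Student's t-test.
#'
#' @param group_a,group_b lists (or matrices, cells in rows) of 10-bin
#'   normalized Sholl profiles, one per cell; each group needs >= 2 cells.
#' @param var_equal pooled-variance t-test when `TRUE` (default); Welch
#'   otherwise.
#' @return list with `auc_a`, `auc_b` (per-cell AUCs), group `mean`/`sem`,
#'   and `t_statistic`, `df`, `p_value`.
#' @export
sholl_auc_compare <- function(group_a, group_b, var_equal = TRUE) {
  auc_a <- sholl_auc_each(group_a)
  auc_b <- sholl_auc_each(group_b)
  if (length(auc_a) < 2 || length(auc_b) < 2) {
    stop("each group needs >= 2 cells for a t-test on AUCs")
  }
  tt <- stats::t.test(auc_a, auc_b, var.equal = var_equal)
  list(auc_a = auc_a, auc_b = auc_b,
       mean = c(a = mean(auc_a), b = mean(auc_b)),
       sem = c(a = stats::sd(auc_a) / sqrt(length(auc_a)),
               b = stats::sd(auc_b) / sqrt(length(auc_b))),
       t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Trapezoidal area under a normalized Sholl profile
#'
#' @param bins numeric length 10 of binned mean intersection counts.
#' @return area over the bin-midpoint grid (normalized radial distance
#'   0.05 to 0.95).
#' @export
sholl_auc <- function(bins) {
  if (length(bins) != 10) stop("expected 10 normalized Sholl bins")
  midpoints <- (seq_len(10) - 0.5) / 10
  pracma::trapz(midpoints, bins)
}

sholl_auc_each <- function(group) {
  if (is.matrix(group)) group <- asplit(group, 1)
  vapply(group, sholl_auc, numeric(1))
}

#' Compare groups of scalar measurements
#'
#' The comparison conventions used throughout: two groups by a Student's
#' t-test (pooled variance by default, Welch by flag); three or more groups
#' by one-way ANOVA with Tukey's honest significant difference for pairwise
#' comparisons; distribution-level comparisons by Kruskal-Wallis (with tie
#' correction). Group summaries are reported as mean and SEM.
#'
#' @param values numeric measurements.
#' @param groups group labels, same length.
#' @param design `"two_group"`, `"multi_group"` or `"distribution"`.
#' @param var_equal for `two_group`: pooled variance when `TRUE` (default).
#' @return list with `design`, per-group `summary` (n, mean, sem) and the
#'   design-specific statistics: `t_statistic`/`df`/`p_value`,
#'   `F_statistic`/`p_value` + `tukey` table, or `H_statistic`/`p_value`.
#' @export
group_compare <- function(values, groups,
                          design = c("two_group", "multi_group", "distribution"),
                          var_equal = TRUE) {
  design <- match.arg(design)
  groups <- factor(groups)
  if (length(values) != length(groups)) stop("values/groups length mismatch")
  k <- nlevels(groups)
  if (design == "two_group" && k != 2) stop("two_group design needs exactly 2 groups")
  if (design == "multi_group" && k < 3) stop("multi_group design needs >= 3 groups")
  if (k < 2) stop("need >= 2 groups")
  summary_df <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)))
  }))
  out <- list(design = design, summary = summary_df)
  if (design == "two_group") {
    v1 <- values[groups == levels(groups)[1]]
    v2 <- values[groups == levels(groups)[2]]
    tt <- stats::t.test(v1, v2, var.equal = var_equal)
    out$t_statistic <- unname(tt$statistic)
    out$df <- unname(tt$parameter)
    out$p_value <- tt$p.value
  } else if (design == "multi_group") {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    out$F_statistic <- an[["F value"]][1]
    out$p_value <- an[["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$groups
    out$tukey <- data.frame(comparison = rownames(tk),
                            diff = tk[, "diff"], p_adj = tk[, "p adj"],
                            row.names = NULL)
  } else {
    kw <- stats::kruskal.test(values, groups)
    out$H_statistic <- unname(kw$statistic)
    out$df <- unname(kw$parameter)
    out$p_value <- kw$p.value
  }
  out
}
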