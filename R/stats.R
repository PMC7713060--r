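# Nonparametric group comparisons used downstream of the diffusion
# summaries: Mann-Whitney U for two groups (exact by enumeration at small
# n, with midrank tie handling; tie-corrected normal approximation
# otherwise), Kruskal-Wallis for several groups, and two post-hoc variants
# (Dunn's test, and Tukey HSD on ranks).

new_test_result <- function(statistic, p_value, method, group_sizes) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(list(statistic = statistic, p_value = min(p_value, 1),
                 method = method, group_sizes = group_sizes),
            class = "fcs_test")
}

#' @export
print.fcs_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n", x$method,
              x$statistic, x$p_value, paste(x$group_sizes, collapse = ", ")))
  invisible(x)
}

# U statistic of sample x vs y from midranks.
u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x)
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples with midrank tie
#' handling. For `n1 + n2 <= 12` the p-value is exact, by enumeration of
#' all group assignments of the pooled midranks (valid under ties); for
#' larger samples the tie-corrected normal approximation of
#' [stats::wilcox.test()] is used.
#'
#' @param x,y Numeric samples (non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (alternative: x shifted less/greater than y).
#' @return An object of class `fcs_test` with the U statistic of `x`.
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  U <- u_statistic(x, y)
  if (n1 + n2 <= 12L) {
    combs <- utils::combn(n1 + n2, n1)
    r <- rank(c(x, y))
    us <- apply(combs, 2L, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    eps <- 1e-9
    p <- switch(alternative,
      two.sided = mean(abs(us - mu) >= abs(U - mu) - eps),
      greater   = mean(us >= U - eps),
      less      = mean(us <= U + eps))
    method <- "Mann-Whitney U (exact, enumeration)"
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = alternative, exact = FALSE,
                         correct = FALSE))
    p <- wt$p.value
    method <- "Mann-Whitney U (normal approximation, tie-corrected)"
  }
  new_test_result(U, p, method, c(n1, n2))
}

#' Kruskal-Wallis rank test across several groups
#'
#' Tie-corrected H statistic with a chi-squared p-value (delegating to
#' [stats::kruskal.test()]); the degenerate all-identical case is reported
#' as H = 0, p = 1 rather than an undefined statistic.
#'
#' @param groups A list of numeric vectors, each with >= 2 observations;
#'   at least 2 groups.
#' @return An object of class `fcs_test`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) < 2L)) stop("each group needs >= 2 observations")
  vals <- unlist(groups)
  if (length(unique(vals)) == 1L)
    return(new_test_result(0, 1, "Kruskal-Wallis (degenerate: all values equal)",
                           lengths(groups)))
  kt <- stats::kruskal.test(groups)
  new_test_result(unname(kt$statistic), kt$p.value, "Kruskal-Wallis",
                  lengths(groups))
}

#' Pairwise post-hoc comparisons after Kruskal-Wallis
#'
#' Two variants: `"dunn"` (Dunn's z-tests on mean ranks with the pooled
#' tie-corrected rank variance, p-values adjusted by `p_adjust`), and
#' `"tukey_on_ranks"` (Tukey's HSD applied to the rank-transformed data —
#' provided because this label is sometimes used after Kruskal-Wallis even
#' though it is not a standard rank procedure).
#'
#' @param groups Named list of numeric vectors.
#' @param method `"dunn"` (default) or `"tukey_on_ranks"`.
#' @param p_adjust Adjustment for [stats::p.adjust()] in the Dunn variant
#'   (default "holm"; Tukey HSD is already familywise).
#' @return A data.frame with one row per pair: `group1`, `group2`,
#'   `statistic`, `p_value`, `method`.
#' @export
posthoc_pairwise <- function(groups, method = c("dunn", "tukey_on_ranks"),
                             p_adjust = "holm") {
  method <- match.arg(method)
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  vals <- unlist(groups)
  grp <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  N <- length(vals)
  pairs <- utils::combn(names(groups), 2L)

  if (method == "dunn") {
    r <- rank(vals)
    rbar <- tapply(r, grp, mean)
    ties <- table(vals)
    tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
    z <- p <- numeric(ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      na <- sum(grp == a); nb <- sum(grp == b)
      sd_ab <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / na + 1 / nb))
      z[j] <- (rbar[[a]] - rbar[[b]]) / sd_ab
      p[j] <- 2 * stats::pnorm(-abs(z[j]))
    }
    data.frame(group1 = pairs[1, ], group2 = pairs[2, ], statistic = z,
               p_value = stats::p.adjust(p, p_adjust),
               method = paste0("dunn/", p_adjust))
  } else {
    fit <- stats::aov(rank(vals) ~ grp)
    tk <- stats::TukeyHSD(fit)$grp
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    data.frame(group1 = vapply(nm, `[`, "", 2L),
               group2 = vapply(nm, `[`, "", 1L),
               statistic = tk[, "diff"], p_value = tk[, "p adj"],
               method = "tukey_on_ranks", row.names = NULL)
  }
}
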