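#' Two-group and k-group comparison tests
#'
#' The descriptive-table tests: Mann-Whitney (Wilcoxon rank-sum, normal
#' approximation without continuity correction) and Kruskal-Wallis for
#' continuous variables; chi-square (without Yates correction) and Fisher's
#' exact test (2 x 2 only) for categorical ones. All p-values are two-sided.
#'
#' @param values Continuous values (`mann_whitney`, `kruskal`) or a
#'   categorical vector (`chisq`, `fisher`).
#' @param groups Group labels, same length as `values`.
#' @param kind One of `"mann_whitney"`, `"kruskal"`, `"chisq"`, `"fisher"`.
#' @return An `mbs_test`.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3, 4), c("a", "a", "b", "b"), "mann_whitney")
compare_groups <- function(values, groups,
                           kind = c("mann_whitney", "kruskal", "chisq",
                                    "fisher")) {
  kind <- match.arg(kind)
  if (length(values) != length(groups)) stop("length mismatch")
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  switch(kind,
    mann_whitney = {
      if (!is.numeric(values)) stop("mann_whitney expects continuous values")
      if (nlevels(groups) != 2L) stop("mann_whitney compares exactly 2 groups")
      w <- wilcox.test(values[groups == levels(groups)[1L]],
                       values[groups == levels(groups)[2L]],
                       exact = FALSE, correct = FALSE)
      new_mbs_test(statistic = unname(w$statistic), df = NA,
                   p_value = w$p.value, method = "Mann-Whitney")
    },
    kruskal = {
      if (!is.numeric(values)) stop("kruskal expects continuous values")
      k <- kruskal.test(values, groups)
      new_mbs_test(statistic = unname(k$statistic),
                   df = unname(k$parameter), p_value = k$p.value,
                   method = "Kruskal-Wallis")
    },
    chisq = {
      tab <- table(values, groups)
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      if (min(ct$expected) < 1) {
        warning("expected cell count below 1; Fisher's exact test recommended")
      }
      new_mbs_test(statistic = unname(ct$statistic),
                   df = unname(ct$parameter), p_value = ct$p.value,
                   method = "chi-square")
    },
    fisher = {
      tab <- table(values, groups)
      if (!all(dim(tab) == c(2L, 2L))) {
        stop("fisher is restricted to 2 x 2 tables")
      }
      ft <- fisher.test(tab)
      new_mbs_test(statistic = NA_real_, df = NA, p_value = ft$p.value,
                   method = "Fisher exact")
    })
}
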