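#' Two-stage Cox screen of dichotomized candidate genes
#'
#' Stage 1 fits, per gene, a univariate Cox model on the high-expression
#' indicator (expression strictly above the gene's cutpoint); a hazard ratio
#' above 1 therefore means high expression predicts death, below 1 that low
#' expression does. Genes with a stage-1 p-value at or below `alpha` are
#' carried — one at a time — into stage 2, a Cox model adjusting for the
#' clinical confounders: age (continuous, years), gender, and IPSS-R coded
#' as binary low (very-low + low) versus non-low (intermediate + high +
#' very-high). A gene is `selected` when its stage-2 p-value is also at or
#' below `alpha` (boundary inclusive).
#'
#' Complete-case analysis: patients missing any requested confounder are
#' dropped before fitting (the count is reported via `message()` and stored
#' as an attribute). A gene whose fit fails or shows a monotone likelihood
#' is marked `failed` with a warning and the screen continues.
#'
#' @param cohort An `mbs_cohort` (healthy-donor rows are excluded).
#' @param cutpoints Named list of [optimal_cutpoint()] results, or a named
#'   numeric vector of cutpoint values, covering every screened gene.
#' @param genes Genes to screen (default: `names(cutpoints)`).
#' @param confounders Subset of `c("age", "gender", "ipssr")` used in
#'   stage 2 (default all three).
#' @param alpha Two-sided selection threshold at both stages (default 0.05).
#' @param ties Tie handling for the Cox fits.
#' @return `data.frame` of class `mbs_screening`, one row per gene, with
#'   cutpoint, direction, group sizes, univariate and multivariate HR / 95%
#'   CI / p, and `selected` / `failed` flags. Attributes: `alpha`,
#'   `confounders`, `n_used`, `n_dropped`, `ties`.
#' @export
screen_genes <- function(cohort, cutpoints, genes = NULL,
                         confounders = c("age", "gender", "ipssr"),
                         alpha = 0.05, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(inherits(cohort, "mbs_cohort"))
  if (length(confounders)) {
    confounders <- match.arg(confounders, c("age", "gender", "ipssr"),
                             several.ok = TRUE)
  }
  cohort <- cohort_patients(cohort)
  cuts <- normalize_cutpoints(cutpoints)
  genes <- genes %||% names(cuts)
  missing_cuts <- setdiff(genes, names(cuts))
  if (length(missing_cuts)) {
    stop("no cutpoint supplied for gene(s): ",
         paste(missing_cuts, collapse = ", "))
  }
  missing_expr <- setdiff(genes, rownames(cohort$expression))
  if (length(missing_expr)) {
    stop("gene(s) absent from expression matrix: ",
         paste(missing_expr, collapse = ", "))
  }
  cl <- cohort$clinical
  conf <- build_confounders(cl, confounders)
  keep <- if (ncol(conf)) complete.cases(conf) else rep(TRUE, nrow(cl))
  n_dropped <- sum(!keep)
  if (n_dropped) {
    message("screen_genes: dropped ", n_dropped,
            " patient(s) with missing confounders (complete-case analysis)")
  }
  cl <- cl[keep, , drop = FALSE]
  conf <- conf[keep, , drop = FALSE]
  expr <- cohort$expression[, keep, drop = FALSE]

  rows <- lapply(genes, function(g) {
    cut <- cuts[[g]]
    z <- as.numeric(expr[g, ] > cut)
    out <- data.frame(
      gene = g, cutpoint = cut, direction = NA_character_,
      n_high = as.integer(sum(z)), n_low = as.integer(sum(1 - z)),
      hr_uni = NA_real_, lower_uni = NA_real_, upper_uni = NA_real_,
      p_uni = NA_real_, hr_multi = NA_real_, lower_multi = NA_real_,
      upper_multi = NA_real_, p_multi = NA_real_,
      selected = FALSE, failed = FALSE, stringsAsFactors = FALSE)
    fit1 <- tryCatch(
      cox_fit(cl$os_time, cl$os_event, data.frame(z = z), ties = ties),
      error = function(e) e)
    if (inherits(fit1, "error") || any(fit1$monotone)) {
      warning("univariate fit failed for gene ", g, "; marked failed")
      out$failed <- TRUE
      return(out)
    }
    t1 <- fit1$terms[fit1$terms$term == "z", ]
    out$hr_uni <- t1$hr; out$lower_uni <- t1$lower
    out$upper_uni <- t1$upper; out$p_uni <- t1$p
    out$direction <- if (t1$beta < 0) "low_is_risk" else "high_is_risk"
    if (t1$p > alpha) return(out)  # stage-1 gate: never fitted in stage 2
    fit2 <- tryCatch(
      cox_fit(cl$os_time, cl$os_event, cbind(data.frame(z = z), conf),
              ties = ties),
      error = function(e) e)
    if (inherits(fit2, "error") || fit2$monotone[["z"]]) {
      warning("multivariate fit failed for gene ", g, "; marked failed")
      out$failed <- TRUE
      return(out)
    }
    t2 <- fit2$terms[fit2$terms$term == "z", ]
    out$hr_multi <- t2$hr; out$lower_multi <- t2$lower
    out$upper_multi <- t2$upper; out$p_multi <- t2$p
    out$selected <- t2$p <= alpha
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(res, class = c("mbs_screening", "data.frame"),
            alpha = alpha, confounders = confounders,
            n_used = nrow(cl), n_dropped = n_dropped, ties = ties)
}

normalize_cutpoints <- function(cutpoints) {
  if (is.numeric(cutpoints)) {
    if (is.null(names(cutpoints))) stop("cutpoints must be named by gene")
    return(as.list(cutpoints))
  }
  if (is.list(cutpoints)) {
    vals <- lapply(cutpoints, function(cp) {
      if (inherits(cp, "mbs_cutpoint")) cp$cutpoint else as.numeric(cp)
    })
    nms <- names(cutpoints) %||% vapply(cutpoints, function(cp) {
      if (inherits(cp, "mbs_cutpoint")) cp$gene else NA_character_
    }, character(1))
    if (is.null(names(vals)) || any(!nzchar(nms)) || anyNA(nms)) {
      names(vals) <- nms
    }
    if (anyNA(names(vals)) || any(!nzchar(names(vals)))) {
      stop("cutpoints must be named by gene")
    }
    return(vals)
  }
  stop("cutpoints must be a named list or numeric vector")
}

build_confounders <- function(clinical, confounders) {
  out <- data.frame(row.names = seq_len(nrow(clinical)))
  if ("age" %in% confounders) {
    if (!"age" %in% names(clinical)) stop("confounder 'age' not in cohort")
    out$age <- clinical$age
  }
  if ("gender" %in% confounders) {
    if (!"gender" %in% names(clinical)) stop("confounder 'gender' not in cohort")
    out$gender <- factor(clinical$gender, levels = c("female", "male"))
  }
  if ("ipssr" %in% confounders) {
    if (!"ipssr" %in% names(clinical)) stop("confounder 'ipssr' not in cohort")
    nonlow <- ifelse(is.na(clinical$ipssr), NA,
                     !clinical$ipssr %in% c("very-low", "low"))
    out$ipssr_nonlow <- as.numeric(nonlow)
  }
  out
}

#' Tier percentages with sum-preserving rounding
#'
#' Converts tier counts to integer percentages that add up to 100: each
#' share is rounded to the nearest integer and any rounding excess or
#' deficit is absorbed by the largest category. With the reported tier
#' counts 28/60/71 of 159 this reproduces the printed 18/38/44 partition.
#'
#' @param counts Named integer vector of tier counts.
#' @return Named integer vector of percentages summing to 100.
#' @export
#' @examples
#' tier_percentages(c(favourable = 28, intermediate = 60, adverse = 71))
tier_percentages <- function(counts) {
  if (any(counts < 0) || sum(counts) == 0) stop("counts must be non-negative")
  pct <- 100 * counts / sum(counts)
  r <- round(pct)
  excess <- sum(r) - 100L
  if (excess != 0L) {
    big <- which.max(counts)
    r[big] <- r[big] - excess
  }
  setNames(as.integer(r), names(counts))
}
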