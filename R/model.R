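#' Assemble a molecular-based score from a screening table
#'
#' One component per selected gene. The risk direction of a component is the
#' expression state whose multivariate hazard ratio exceeds 1: high
#' expression when `hr_multi > 1`, low expression otherwise. Components are
#' ordered alphabetically by gene, independent of screening order. The tier
#' rule is the frozen reference rule — score 0 = favourable, 1 =
#' intermediate, >= 2 = adverse.
#'
#' @param screening An `mbs_screening` table from [screen_genes()].
#' @param cutpoints Optional [optimal_cutpoint()] list used to record the
#'   cutpoint-selection metric for provenance.
#' @return Object of class `mbs_model`.
#' @export
build_mbs <- function(screening, cutpoints = NULL) {
  stopifnot(inherits(screening, "mbs_screening"))
  sel <- screening[screening$selected & !screening$failed, , drop = FALSE]
  if (nrow(sel) == 0L) {
    stop("no gene passed both screening stages: a score cannot be built")
  }
  comp <- data.frame(
    gene = sel$gene,
    cutpoint = sel$cutpoint,
    direction = ifelse(sel$hr_multi > 1, "high_is_risk", "low_is_risk"),
    stringsAsFactors = FALSE
  )
  comp <- comp[order(comp$gene, method = "radix"), , drop = FALSE]
  rownames(comp) <- NULL
  if (nrow(comp) < 2L) {
    warning("model has a single component: the adverse tier (score >= 2) ",
            "is unattainable under the frozen tier rule")
  }
  metric <- NA_character_
  if (!is.null(cutpoints)) {
    mets <- unique(vapply(cutpoints, function(cp) {
      if (inherits(cp, "mbs_cutpoint")) cp$metric else NA_character_
    }, character(1)))
    mets <- mets[!is.na(mets)]
    if (length(mets) == 1L) metric <- mets
  }
  new_mbs_model(components = comp,
                alpha = attr(screening, "alpha"),
                metric = metric,
                confounders = attr(screening, "confounders"))
}

#' Construct an MBS model from known components
#'
#' Builds a scoring model directly from a table of components — for example
#' the published five-gene panel with cohort-specific cutpoints, or a
#' simulation's ground-truth panel — bypassing the screening stage.
#'
#' @param components `data.frame` with columns `gene`, `cutpoint` and
#'   `direction` (`"high_is_risk"` / `"low_is_risk"`).
#' @param alpha Selection threshold recorded for provenance.
#' @param metric Cutpoint-selection metric recorded for provenance.
#' @param confounders Confounders recorded for provenance.
#' @return An `mbs_model`.
#' @export
#' @examples
#' comp <- data.frame(gene = c("PKM", "ACLY"), cutpoint = c(7.2, 6.3),
#'                    direction = c("high_is_risk", "low_is_risk"))
#' mbs_model(comp)
mbs_model <- function(components, alpha = 0.05, metric = NA_character_,
                      confounders = character(0)) {
  new_mbs_model(components = components[, c("gene", "cutpoint", "direction")],
                alpha = alpha, metric = metric, confounders = confounders)
}

new_mbs_model <- function(components, alpha, metric = NA_character_,
                          confounders = character(0),
                          tier_rule = list(favourable = 0L, intermediate = 1L,
                                           adverse_min = 2L)) {
  stopifnot(is.data.frame(components),
            all(c("gene", "cutpoint", "direction") %in% names(components)),
            all(components$direction %in% .directions))
  if (anyDuplicated(components$gene)) stop("duplicate component genes")
  structure(list(components = components, tier_rule = tier_rule,
                 alpha = alpha, metric = metric,
                 confounders = confounders),
            class = "mbs_model")
}

#' @export
print.mbs_model <- function(x, ...) {
  cat(sprintf("<mbs_model> %d component(s), tiers {%d -> favourable, %d -> intermediate, >=%d -> adverse}\n",
              nrow(x$components), x$tier_rule$favourable,
              x$tier_rule$intermediate, x$tier_rule$adverse_min))
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Score patients and assign risk tiers
#'
#' A patient's score is the number of model components whose risk condition
#' holds: expression strictly above the cutpoint for `high_is_risk`
#' components, at-or-below for `low_is_risk`. Tiers follow the model's tier
#' rule (reference: 0 favourable, 1 intermediate, >= 2 adverse).
#'
#' @param model An `mbs_model`.
#' @param cohort An `mbs_cohort`; every model gene must be present.
#' @return `data.frame` of class `mbs_risk` with columns `patient_id`,
#'   `score` (integer) and `tier` (factor favourable < intermediate <
#'   adverse).
#' @export
score_patients <- function(model, cohort) {
  stopifnot(inherits(model, "mbs_model"), inherits(cohort, "mbs_cohort"))
  comp <- model$components
  missing <- setdiff(comp$gene, rownames(cohort$expression))
  if (length(missing)) {
    stop("model gene(s) absent from cohort: ", paste(missing, collapse = ", "))
  }
  expr <- cohort$expression
  risk <- vapply(seq_len(nrow(comp)), function(j) {
    x <- expr[comp$gene[j], ]
    if (comp$direction[j] == "high_is_risk") as.integer(x > comp$cutpoint[j])
    else as.integer(x <= comp$cutpoint[j])
  }, integer(ncol(expr)))
  if (is.null(dim(risk))) risk <- matrix(risk, nrow = ncol(expr))
  score <- as.integer(rowSums(risk))
  out <- data.frame(patient_id = colnames(expr), score = score,
                    tier = assign_tier(score, model$tier_rule),
                    stringsAsFactors = FALSE)
  structure(out, class = c("mbs_risk", "data.frame"), model = model)
}

assign_tier <- function(score, tier_rule) {
  tier <- ifelse(score <= tier_rule$favourable, .tier_levels[1L],
                 ifelse(score <= tier_rule$intermediate, .tier_levels[2L],
                        .tier_levels[3L]))
  factor(tier, levels = .tier_levels)
}
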