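#' Assemble a cohort from expression and clinical components
#'
#' A cohort couples a genes-by-samples expression matrix with one clinical
#' record per patient. Sample identifiers (matrix column names) and patient
#' identifiers must be in bijection and in the same order; use
#' [align_cohort()] to establish that from raw inputs.
#'
#' @param expression Numeric matrix, genes in rows (unique rownames), samples
#'   in columns (unique colnames), no missing values.
#' @param clinical `data.frame` with at least `patient_id`, `os_time` (months,
#'   positive), `os_event` (0/1). Optional columns: `age`, `gender`
#'   (`"female"`/`"male"`), `ipssr` (one of [ipssr_levels()]), `group_label`,
#'   and any extra covariates.
#' @return An object of class `mbs_cohort`: a list with elements `expression`
#'   and `clinical`.
#' @export
#' @examples
#' expr <- matrix(rnorm(6), 2, 3,
#'                dimnames = list(c("PKM", "ACLY"), c("P1", "P2", "P3")))
#' clin <- data.frame(patient_id = c("P1", "P2", "P3"),
#'                    os_time = c(12, 30.5, 7), os_event = c(1, 0, 1))
#' coh <- new_cohort(expr, clin)
#' n_patients(coh)
new_cohort <- function(expression, clinical) {
  if (!is.matrix(expression) || !is.numeric(expression)) {
    stop("`expression` must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(expression)) || is.null(colnames(expression))) {
    stop("`expression` must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(expression))) {
    stop("duplicate gene identifiers in `expression`; collapse probes first")
  }
  if (anyDuplicated(colnames(expression))) {
    stop("duplicate sample identifiers in `expression`")
  }
  if (anyNA(expression)) {
    stop("`expression` contains missing values; see read_expression(na_action=)")
  }
  clinical <- validate_clinical(clinical)
  if (nrow(clinical) != ncol(expression) ||
      !identical(clinical$patient_id, colnames(expression))) {
    stop("sample ids and patient ids must match one-to-one and in order; ",
         "use align_cohort()")
  }
  structure(list(expression = expression, clinical = clinical),
            class = "mbs_cohort")
}

#' @rdname new_cohort
#' @param cohort An `mbs_cohort`.
#' @export
n_patients <- function(cohort) {
  stopifnot(inherits(cohort, "mbs_cohort"))
  nrow(cohort$clinical)
}

#' Subset of a cohort carrying survival information
#'
#' Rows labelled `"healthy-donor"` in an optional `group_label` column (e.g.
#' reference donors used only for expression comparisons) are excluded from
#' survival-based stages.
#'
#' @param cohort An `mbs_cohort`.
#' @return An `mbs_cohort` restricted to patients.
#' @export
cohort_patients <- function(cohort) {
  stopifnot(inherits(cohort, "mbs_cohort"))
  cl <- cohort$clinical
  if (!"group_label" %in% names(cl)) return(cohort)
  keep <- is.na(cl$group_label) | cl$group_label != "healthy-donor"
  if (all(keep)) return(cohort)
  out <- list(expression = cohort$expression[, keep, drop = FALSE],
              clinical = cl[keep, , drop = FALSE])
  rownames(out$clinical) <- NULL
  structure(out, class = "mbs_cohort")
}

validate_clinical <- function(clinical) {
  if (!is.data.frame(clinical)) stop("`clinical` must be a data.frame")
  need <- c("patient_id", "os_time", "os_event")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) {
    stop("clinical table is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  clinical$patient_id <- trimws(as.character(clinical$patient_id))
  if (anyDuplicated(clinical$patient_id)) {
    stop("duplicated patient ids: ",
         paste(unique(clinical$patient_id[duplicated(clinical$patient_id)]),
               collapse = ", "))
  }
  bad <- !is.finite(clinical$os_time) | clinical$os_time <= 0
  if (any(bad)) {
    stop("non-positive or non-finite os_time for patient(s): ",
         paste(clinical$patient_id[bad], collapse = ", "))
  }
  if (!all(clinical$os_event %in% c(0, 1))) {
    stop("os_event must be 0 or 1")
  }
  clinical$os_event <- as.integer(clinical$os_event)
  if ("gender" %in% names(clinical)) {
    g <- tolower(trimws(as.character(clinical$gender)))
    g[!g %in% c("female", "male")] <- NA_character_
    clinical$gender <- g
  }
  if ("ipssr" %in% names(clinical)) {
    clinical$ipssr <- normalize_ipssr(clinical$ipssr)
  }
  rownames(clinical) <- NULL
  clinical
}

normalize_ipssr <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[ _]+", "-", x)
  x[!x %in% ipssr_levels()] <- NA_character_
  x
}

#' @export
print.mbs_cohort <- function(x, ...) {
  cat(sprintf("<mbs_cohort> %d genes x %d samples\n",
              nrow(x$expression), ncol(x$expression)))
  cl <- x$clinical
  pat <- cohort_patients(x)$clinical
  cat(sprintf("  patients with survival: %d (%d events)\n",
              nrow(pat), sum(pat$os_event)))
  if ("group_label" %in% names(cl)) {
    cat("  groups:", paste(sprintf("%s=%d", names(table(cl$group_label)),
                                   table(cl$group_label)), collapse = ", "),
        "\n")
  }
  invisible(x)
}
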