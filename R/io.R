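#' Read a normalized expression matrix from delimited text
#'
#' Expects genes in rows and samples in columns: the first column holds the
#' gene (or probe) symbol and the header row holds sample identifiers — the
#' layout of GEO series-matrix derived tables. Values are log-scale
#' normalized intensities; no normalization is performed here. Genes
#' represented by multiple probes are collapsed row-wise by the per-sample
#' median when `collapse = "median"`.
#'
#' @param path Path to a TSV or CSV file (delimiter auto-detected from the
#'   header line, or forced via `sep`).
#' @param collapse `"median"` (default) collapses duplicate gene symbols by
#'   the per-sample median; `"none"` errors on duplicates.
#' @param na_action What to do with genes containing missing values:
#'   `"drop"` (default, with a warning), `"impute"` per-gene median
#'   imputation, or `"error"`.
#' @param sep Optional field delimiter override.
#' @return Numeric matrix, genes x samples, unique rownames.
#' @export
read_expression <- function(path, collapse = c("median", "none"),
                            na_action = c("drop", "impute", "error"),
                            sep = NULL) {
  collapse <- match.arg(collapse)
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop("expression file not found: ", path)
  sep <- sep %||% sniff_sep(path)
  raw <- read.csv(path, sep = sep, header = TRUE, check.names = FALSE,
                  colClasses = "character", strip.white = TRUE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("empty expression matrix in ", path)
  }
  ids <- trimws(raw[[1L]])
  sample_ids <- trimws(colnames(raw)[-1L])
  if (any(sample_ids == "") || anyDuplicated(sample_ids)) {
    stop("malformed header in ", path, ": sample ids must be unique and non-empty")
  }
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  missing_like <- vals == "" | toupper(vals) == "NA"
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !missing_like, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric expression value at gene '%s', sample '%s'",
                 ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  }
  dimnames(num) <- list(NULL, sample_ids)

  if (anyDuplicated(ids)) {
    if (collapse == "none") {
      stop("duplicate gene symbols present and collapse = \"none\"")
    }
    num <- collapse_probes(num, ids)
  } else {
    rownames(num) <- ids
  }

  has_na <- apply(num, 1L, anyNA)
  if (any(has_na)) {
    if (na_action == "error") {
      stop("missing expression values for gene(s): ",
           paste(rownames(num)[has_na], collapse = ", "))
    } else if (na_action == "drop") {
      warning(sum(has_na), " gene(s) with missing values dropped: ",
              paste(head(rownames(num)[has_na], 5L), collapse = ", "))
      num <- num[!has_na, , drop = FALSE]
    } else {
      for (i in which(has_na)) {
        num[i, is.na(num[i, ])] <- median(num[i, ], na.rm = TRUE)
      }
    }
  }
  if (nrow(num) == 0L) stop("no genes left after filtering in ", path)
  num
}

collapse_probes <- function(mat, ids) {
  groups <- split(seq_along(ids), ids)
  out <- matrix(NA_real_, nrow = length(groups), ncol = ncol(mat),
                dimnames = list(names(groups), colnames(mat)))
  for (k in seq_along(groups)) {
    i <- groups[[k]]
    out[k, ] <- if (length(i) == 1L) mat[i, ]
                else apply(mat[i, , drop = FALSE], 2L, median)
  }
  # keep first-appearance order of gene symbols
  out[unique(ids), , drop = FALSE]
}

#' Read a clinical table
#'
#' Reads one row per patient with overall-survival time (months), event
#' indicator and optional covariates. Mandatory fields failing validation are
#' errors; unparseable optional fields become missing values.
#'
#' @param path Path to a TSV or CSV file.
#' @param column_map Named character vector mapping standard field names
#'   (`patient_id`, `os_time`, `os_event`, `age`, `gender`, `ipssr`,
#'   `group_label`) to column names in the file. Unmapped standard names are
#'   looked up verbatim. All other file columns are carried along unchanged.
#' @param sep Optional field delimiter override.
#' @return A validated clinical `data.frame`.
#' @export
read_clinical <- function(path, column_map = NULL, sep = NULL) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  sep <- sep %||% sniff_sep(path)
  raw <- read.csv(path, sep = sep, header = TRUE, check.names = FALSE,
                  colClasses = "character", strip.white = TRUE)
  std <- c("patient_id", "os_time", "os_event", "age", "gender", "ipssr",
           "group_label")
  map <- setNames(std, std)
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), std)
    if (length(unknown)) {
      stop("column_map refers to unknown field(s): ",
           paste(unknown, collapse = ", "))
    }
    map[names(column_map)] <- unname(column_map)
  }
  for (field in c("patient_id", "os_time", "os_event")) {
    if (!map[[field]] %in% names(raw)) {
      stop("mandatory column '", map[[field]], "' (", field,
           ") not found in ", path)
    }
  }
  out <- data.frame(patient_id = trimws(raw[[map[["patient_id"]]]]),
                    stringsAsFactors = FALSE)
  out$os_time <- parse_num(raw[[map[["os_time"]]]])
  ev <- parse_num(raw[[map[["os_event"]]]])
  if (any(is.na(ev)) || !all(ev %in% c(0, 1))) {
    stop("os_event must be 0 or 1 for every patient")
  }
  out$os_event <- as.integer(ev)
  for (field in c("age", "gender", "ipssr", "group_label")) {
    col <- map[[field]]
    if (col %in% names(raw)) {
      out[[field]] <- if (field == "age") parse_num(raw[[col]]) else raw[[col]]
    }
  }
  used <- unname(map[map %in% names(raw)])
  extras <- setdiff(names(raw), used)
  for (col in extras) out[[col]] <- type.convert(raw[[col]], as.is = TRUE)
  validate_clinical(out)
}

parse_num <- function(x) suppressWarnings(as.numeric(trimws(x)))

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Align expression and clinical components into a cohort
#'
#' Matching is by exact string identity after whitespace trimming. Under
#' `policy = "intersect"` only shared identifiers are kept (counts reported
#' via `message()`); under `"strict"` any mismatch is an error naming the
#' unmatched identifiers. Output ordering follows the clinical table.
#'
#' @param expression Genes x samples numeric matrix (see [read_expression()]).
#' @param clinical Clinical `data.frame` (see [read_clinical()]).
#' @param policy `"intersect"` (default) or `"strict"`.
#' @return An [new_cohort()] object.
#' @export
align_cohort <- function(expression, clinical,
                         policy = c("intersect", "strict")) {
  policy <- match.arg(policy)
  clinical <- validate_clinical(clinical)
  colnames(expression) <- trimws(colnames(expression))
  if (anyDuplicated(colnames(expression))) {
    stop("duplicate sample ids in expression matrix")
  }
  shared <- intersect(clinical$patient_id, colnames(expression))
  if (length(shared) == 0L) {
    stop("no overlap between expression sample ids and clinical patient ids")
  }
  only_expr <- setdiff(colnames(expression), clinical$patient_id)
  only_clin <- setdiff(clinical$patient_id, colnames(expression))
  if (policy == "strict" && (length(only_expr) || length(only_clin))) {
    stop("unmatched identifiers under strict alignment: ",
         paste(head(c(only_expr, only_clin), 10L), collapse = ", "))
  }
  if (length(only_expr) || length(only_clin)) {
    message(sprintf(
      "align_cohort: kept %d shared ids (dropped %d expression-only, %d clinical-only)",
      length(shared), length(only_expr), length(only_clin)))
  }
  clin <- clinical[clinical$patient_id %in% shared, , drop = FALSE]
  expr <- expression[, clin$patient_id, drop = FALSE]
  new_cohort(expr, clin)
}

#' Serialize / restore a fitted MBS model
#'
#' Models are written as human-readable JSON recording the component genes,
#' their cutpoints (in decimal and in C99 hex float notation so values
#' round-trip bit-identically), risk directions, and the tier rule.
#'
#' @param model An `mbs_model` from [build_mbs()].
#' @param path Destination / source file path.
#' @return `write_mbs_model()` returns `path` invisibly; `read_mbs_model()`
#'   returns the restored `mbs_model`.
#' @export
write_mbs_model <- function(model, path) {
  stopifnot(inherits(model, "mbs_model"))
  comp <- model$components
  payload <- list(
    format = "mbscore-model",
    version = 1L,
    metric = model$metric,
    alpha = model$alpha,
    confounders = as.list(model$confounders),
    tier_rule = model$tier_rule,
    components = lapply(seq_len(nrow(comp)), function(i) {
      list(gene = comp$gene[i],
           direction = comp$direction[i],
           cutpoint = comp$cutpoint[i],
           cutpoint_hex = sprintf("%a", comp$cutpoint[i]))
    })
  )
  write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_mbs_model
#' @export
read_mbs_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  x <- read_json(path, simplifyVector = FALSE)
  if (!identical(x$format, "mbscore-model")) {
    stop("not an mbscore model file: ", path)
  }
  if (!identical(as.integer(x$version), 1L)) {
    stop("unsupported model file version: ", x$version)
  }
  need <- c("metric", "alpha", "tier_rule", "components")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("model file missing field(s): ",
                         paste(miss, collapse = ", "))
  comps <- x$components
  if (length(comps) == 0L) stop("model file has no components")
  comp <- do.call(rbind, lapply(comps, function(cp) {
    if (is.null(cp$gene) || is.null(cp$direction) ||
        (is.null(cp$cutpoint) && is.null(cp$cutpoint_hex))) {
      stop("model component missing gene, direction or cutpoint")
    }
    if (!cp$direction %in% .directions) {
      stop("invalid risk direction '", cp$direction, "'; must be one of: ",
           paste(.directions, collapse = ", "))
    }
    cut <- if (!is.null(cp$cutpoint_hex)) as.numeric(cp$cutpoint_hex)
           else as.numeric(cp$cutpoint)
    data.frame(gene = cp$gene, cutpoint = cut, direction = cp$direction,
               stringsAsFactors = FALSE)
  }))
  rule <- x$tier_rule
  if (is.null(rule$favourable) || is.null(rule$intermediate) ||
      is.null(rule$adverse_min)) {
    stop("model file tier_rule must give favourable, intermediate, adverse_min")
  }
  new_mbs_model(components = comp,
                alpha = as.numeric(x$alpha),
                metric = as.character(x$metric),
                confounders = unlist(x$confounders) %||% character(0),
                tier_rule = list(favourable = as.integer(rule$favourable),
                                 intermediate = as.integer(rule$intermediate),
                                 adverse_min = as.integer(rule$adverse_min)))
}
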