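#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end pipeline. Inputs are either a
#' pair of files (expression + clinical) or a [simulation_config()]. Every
#' method constant is a default here, never hard-coded downstream:
#' selection threshold `alpha = 0.05` (two-sided, both screening stages),
#' frozen tier rule {0, 1, >= 2}, bootstrap sizes `R = 1000` (tier survival)
#' and `R = 10000` (delta-AUC), horizons 24 and 36 months.
#'
#' @param expression_file,clinical_file Input files (ignored when
#'   `simulation` is given).
#' @param simulation Optional [simulation_config()] to generate the cohort.
#' @param genes Candidate genes (default [mbs_gene_panel()]); genes absent
#'   from the expression matrix are dropped with a log entry.
#' @param alpha Two-sided selection threshold for both screening stages.
#' @param min_group_frac Minimum per-side group fraction for cutpoints.
#' @param metric Cutpoint criterion, `"youden"` or `"concordance"`.
#' @param ties Cox tie handling.
#' @param boot_km_R,boot_auc_R Bootstrap replicate counts.
#' @param horizons Survival horizons in months.
#' @param baseline_score Clinical comparator for the delta-AUC analysis;
#'   currently `"ipssr"` (categories coded 1-5) or `NULL` to skip.
#' @param column_map Optional [read_clinical()] column map.
#' @param align_policy Cohort alignment policy.
#' @param seed Top-level seed; stage sub-streams are derived from it.
#' @param out_dir Output directory (created if needed).
#' @return Object of class `mbs_run_config`.
#' @export
run_config <- function(expression_file = NULL, clinical_file = NULL,
                       simulation = NULL, genes = mbs_gene_panel(),
                       alpha = 0.05, min_group_frac = 0.10,
                       metric = c("youden", "concordance"),
                       ties = c("efron", "breslow"),
                       boot_km_R = 1000L, boot_auc_R = 10000L,
                       horizons = c(24, 36), baseline_score = "ipssr",
                       column_map = NULL,
                       align_policy = c("intersect", "strict"),
                       seed = 1L, out_dir) {
  metric <- match.arg(metric)
  ties <- match.arg(ties)
  align_policy <- match.arg(align_policy)
  if (is.null(simulation)) {
    if (is.null(expression_file) || is.null(clinical_file)) {
      stop("provide either `simulation` or both input files")
    }
    for (f in c(expression_file, clinical_file)) {
      if (!file.exists(f)) stop("input file not found: ", f)
    }
  } else {
    stopifnot(inherits(simulation, "mbs_sim_config"))
  }
  if (missing(out_dir)) stop("`out_dir` is required")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(
    expression_file = expression_file, clinical_file = clinical_file,
    simulation = simulation, genes = genes, alpha = alpha,
    min_group_frac = min_group_frac, metric = metric, ties = ties,
    boot_km_R = as.integer(boot_km_R), boot_auc_R = as.integer(boot_auc_R),
    horizons = horizons, baseline_score = baseline_score,
    column_map = column_map, align_policy = align_policy,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "mbs_run_config")
}

#' Run the full scoring pipeline
#'
#' Sequences data loading (or simulation), per-gene cutpoint search,
#' two-stage Cox screening, score assembly, patient scoring, per-tier
#' survival summaries (plus group-wise expression comparisons when a
#' `group_label` column distinguishes e.g. healthy donors from patients),
#' and internal validation (bootstrap tier survival, delta-AUC against the
#' baseline score, final multivariable model). All tables are written to
#' `config$out_dir` together with a machine-readable manifest recording the
#' seed, a configuration hash, package/R versions, stage log and counts.
#' A stage failure aborts the run with the stage name, after persisting the
#' partial outputs and the manifest.
#'
#' @param config An [run_config()] object.
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `cutpoints`, `screening`, `model`, `assignment`, `bootstrap`,
#'   `auc_comparison`, `multivariable`, `manifest`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "mbs_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = "mbscore", version = as.character(packageVersion("mbscore")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, config = config_fingerprint(config),
    config_hash = hash_config(config), stages = character(0),
    log = character(0), status = "running"
  )
  res <- list()
  note <- function(msg) manifest$log <<- c(manifest$log, msg)
  finish_stage <- function(name) manifest$stages <<- c(manifest$stages, name)
  write_manifest <- function() {
    write_json(manifest, file.path(config$out_dir, "manifest.json"),
               auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  }
  run_stage <- function(name, expr) {
    out <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        manifest$status <<- "failed"
        manifest$failed_stage <<- name
        manifest$error <<- conditionMessage(e)
        write_manifest()
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      message = function(m) {
        note(sub("\n$", "", conditionMessage(m)))
        invokeRestart("muffleMessage")
      },
      warning = function(w) {
        note(paste("warning:", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    finish_stage(name)
    out
  }
  tsv <- function(df, name) {
    write.table(df, file.path(config$out_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  # -- load ------------------------------------------------------------
  res$cohort <- run_stage("load", {
    if (!is.null(config$simulation)) {
      sim <- simulate_cohort(config$simulation)
      res$truth <- sim$truth
      sim$cohort
    } else {
      expr <- read_expression(config$expression_file)
      clin <- read_clinical(config$clinical_file, config$column_map)
      align_cohort(expr, clin, config$align_policy)
    }
  })
  patients <- cohort_patients(res$cohort)
  genes <- intersect(config$genes, rownames(patients$expression))
  if (length(genes) < length(config$genes)) {
    note(sprintf("%d configured gene(s) absent from the expression matrix",
                 length(config$genes) - length(genes)))
  }
  if (length(genes) == 0L) {
    manifest$status <- "failed"; manifest$failed_stage <- "load"
    write_manifest()
    stop("pipeline stage 'load' failed: no configured gene found",
         call. = FALSE)
  }

  # -- cutpoints -------------------------------------------------------
  res$cutpoints <- run_stage("cutpoints", {
    cl <- patients$clinical
    cuts <- list()
    for (g in genes) {
      cp <- tryCatch(
        optimal_cutpoint(patients$expression[g, ], cl$os_time, cl$os_event,
                         min_group_frac = config$min_group_frac,
                         metric = config$metric, gene = g),
        error = function(e) {
          note(sprintf("cutpoint failed for %s: %s", g, conditionMessage(e)))
          NULL
        })
      if (!is.null(cp)) cuts[[g]] <- cp
    }
    if (!length(cuts)) stop("no gene yielded an admissible cutpoint")
    tsv(do.call(rbind, lapply(cuts, function(cp)
      data.frame(gene = cp$gene, cutpoint = cp$cutpoint,
                 direction = cp$direction, metric = cp$metric,
                 metric_value = cp$metric_value, n_high = cp$n_high,
                 n_low = cp$n_low))), "cutpoints.tsv")
    cuts
  })

  # -- screen ----------------------------------------------------------
  res$screening <- run_stage("screen", {
    sc <- screen_genes(res$cohort, res$cutpoints, alpha = config$alpha,
                       ties = config$ties)
    tsv(as.data.frame(sc), "screening.tsv")
    sc
  })

  # -- build -----------------------------------------------------------
  res$model <- run_stage("build", {
    m <- build_mbs(res$screening, res$cutpoints)
    write_mbs_model(m, file.path(config$out_dir, "model.json"))
    m
  })

  # -- score -----------------------------------------------------------
  res$assignment <- run_stage("score", {
    a <- score_patients(res$model, res$cohort)
    tsv(as.data.frame(a), "scores.tsv")
    a
  })

  # -- survival summaries ---------------------------------------------
  run_stage("survival", {
    dat <- merge_assignment(res$cohort, res$assignment)
    rows <- lapply(split(dat, droplevels(dat$tier)), function(d) {
      km <- km_fit(d$os_time, d$os_event)
      s <- survival_at(km, config$horizons)
      cbind(data.frame(tier = as.character(d$tier[1L]), n = nrow(d),
                       events = sum(d$os_event),
                       median_os = ifelse(is.na(km$median_time),
                                          "not reached",
                                          format(km$median_time,
                                                 digits = 6))),
            setNames(as.data.frame(t(s)),
                     sprintf("os_%dmo", config$horizons)))
    })
    tiers_tab <- do.call(rbind, rows)
    counts <- table(factor(dat$tier, levels = .tier_levels))
    present <- counts > 0
    tiers_tab$percent <- tier_percentages(counts[present])[tiers_tab$tier]
    tsv(tiers_tab, "tiers.tsv")
    if (nlevels(droplevels(dat$tier)) >= 2L) {
      lr <- logrank(dat$os_time, dat$os_event, dat$tier)
      manifest$logrank <- list(chisq = lr$statistic, df = lr$df,
                                p = lr$p_value)
    }
    cl_all <- res$cohort$clinical
    if ("group_label" %in% names(cl_all) &&
        length(unique(stats::na.omit(cl_all$group_label))) >= 2L) {
      cmp <- do.call(rbind, lapply(genes, function(g) {
        x <- res$cohort$expression[g, ]
        grp <- cl_all$group_label
        med <- tapply(x, grp, median)
        tst <- compare_groups(x, grp, "mann_whitney")
        data.frame(gene = g,
                   median_a = med[1L], median_b = med[2L],
                   group_a = names(med)[1L], group_b = names(med)[2L],
                   p = tst$p_value)
      }))
      tsv(cmp, "expression_groups.tsv")
    }
    NULL
  })

  # -- validate --------------------------------------------------------
  run_stage("validate", {
    bs <- bootstrap_km(res$cohort, res$assignment, R = config$boot_km_R,
                       horizons = config$horizons,
                       seed = derive_seed(config$seed, "bootstrap-km"))
    res$bootstrap <- bs
    bt <- bs$table
    bt$original <- 100 * bt$original
    bt$boot_mean <- 100 * bt$boot_mean
    bt$lower <- 100 * bt$lower
    bt$upper <- 100 * bt$upper
    names(bt) <- c("tier", "horizon_months", "original_pct", "boot_mean_pct",
                   "ci_lower_pct", "ci_upper_pct", "n_missing")
    tsv(bt, "bootstrap_os.tsv")
    manifest$bootstrap_kruskal <- setNames(
      as.list(bs$p_values$kruskal_p), sprintf("h%d", bs$horizons))

    dat <- merge_assignment(res$cohort, res$assignment)
    if (identical(config$baseline_score, "ipssr") &&
        "ipssr" %in% names(dat) && any(!is.na(dat$ipssr))) {
      cc <- !is.na(dat$ipssr)
      if (sum(!cc)) note(sprintf(
        "delta-AUC: dropped %d patient(s) without IPSS-R", sum(!cc)))
      d <- dat[cc, , drop = FALSE]
      ipssr_num <- match(d$ipssr, ipssr_levels())
      ac <- compare_auc_bootstrap(d$os_event, d$score, ipssr_num,
                                  R = config$boot_auc_R,
                                  seed = derive_seed(config$seed,
                                                     "delta-auc"))
      res$auc_comparison <- ac
      tsv(data.frame(
        measure = c("auc_mbs", "auc_baseline", "delta_auc"),
        value = c(ac$auc_a, ac$auc_b, ac$delta),
        ci_lower = c(NA, NA, ac$lower), ci_upper = c(NA, NA, ac$upper),
        p = c(NA, NA, ac$p_value)), "auc_comparison.tsv")
    } else {
      note("delta-AUC skipped: no baseline score available")
    }

    if (any(dat$tier == "favourable")) {
      mv <- tryCatch(final_multivariable(res$cohort, res$assignment),
                     error = function(e) {
                       note(paste("multivariable model skipped:",
                                  conditionMessage(e)))
                       NULL
                     })
      if (!is.null(mv)) {
        res$multivariable <- mv
        tab <- mv$fit$terms
        tab$monotone <- mv$fit$monotone[tab$term]
        tsv(tab[, c("term", "hr", "lower", "upper", "wald_chisq", "p",
                    "monotone")], "multivariable.tsv")
      }
    } else {
      note("multivariable model skipped: favourable tier empty")
    }
    NULL
  })

  manifest$status <- "ok"
  manifest$n_patients <- nrow(patients$clinical)
  manifest$n_genes_screened <- length(res$cutpoints)
  manifest$n_selected <- sum(res$screening$selected)
  write_manifest()
  res$manifest <- manifest
  invisible(res)
}

# the config fields that determine results (paths and out_dir excluded,
# so runs differing only in output location hash identically)
config_fingerprint <- function(config) {
  list(alpha = config$alpha, min_group_frac = config$min_group_frac,
       metric = config$metric, ties = config$ties,
       boot_km_R = config$boot_km_R, boot_auc_R = config$boot_auc_R,
       horizons = config$horizons, baseline_score = config$baseline_score,
       seed = config$seed, genes = config$genes,
       simulated = !is.null(config$simulation))
}

hash_config <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_json(config_fingerprint(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(md5sum(tmp))
}
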