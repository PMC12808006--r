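#' Configuration for a full pipeline run
#'
#' Exactly one of `input` (path to a cohort CSV) or `generator` (a
#' [generator_spec()]) must be given; `seed` is mandatory. Desk-scale
#' protocol defaults (20 runs of 5 starts) are set here; the full published
#' protocol (200 runs of 25 starts, k in 2..20) is reached by overriding
#' them.
#'
#' @param input Optional path to a cohort CSV.
#' @param generator Optional `generator_spec`.
#' @param k Cluster count for the main solution.
#' @param k_range Optional integer range (e.g. `2:8`); when given, the
#'   selection curve is computed and written as well.
#' @param n_runs,recurrence_threshold,extension_runs,n_starts,max_iter
#'   Protocol parameters.
#' @param weight_factor Multiplier on the domain weight for the main run.
#' @param sensitivity_factors Weight multipliers for the sensitivity stage
#'   (set `NULL` to skip).
#' @param seed Master seed (mandatory).
#' @param out_dir Output directory for the results bundle.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input = NULL, generator = NULL, k = 4L,
                       k_range = NULL, n_runs = 20L,
                       recurrence_threshold = 10L, extension_runs = 10L,
                       n_starts = 5L, max_iter = 100L, weight_factor = 1,
                       sensitivity_factors = c(0.5, 2), seed, out_dir) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(input) == is.null(generator)) {
    stop("exactly one of `input` and `generator` must be given")
  }
  if (!is.null(generator)) stopifnot(inherits(generator, "generator_spec"))
  structure(list(input = input, generator = generator, k = as.integer(k),
                 k_range = k_range, n_runs = as.integer(n_runs),
                 recurrence_threshold = as.integer(recurrence_threshold),
                 extension_runs = as.integer(extension_runs),
                 n_starts = as.integer(n_starts),
                 max_iter = as.integer(max_iter),
                 weight_factor = weight_factor,
                 sensitivity_factors = sensitivity_factors,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

stage_log <- function(con, stage, t0, ...) {
  line <- sprintf("stage=%s elapsed=%.2fs %s", stage,
                  as.numeric(Sys.time()) - t0,
                  paste(sprintf("%s=%s", names(list(...)), unlist(list(...))),
                        collapse = " "))
  writeLines(line, con)
  message(line)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the whole workflow in order: load or simulate the cohort,
#' build the weighted design (sociodemographics never enter the clustering;
#' they are used only to describe the clusters), optionally compute the
#' selection curve over `k_range`, run the stability protocol at `k`,
#' profile the clusters, and run the weight sensitivity analysis. Every
#' intermediate artifact is written to `out_dir` as CSV/JSON plus a manifest
#' recording the package version, seed and configuration. Identical
#' configurations give identical bundles.
#'
#' @param config A [run_config()].
#' @return The output directory path, invisibly; artifacts on disk.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  log_con <- file(out("run.log"), open = "wt")
  on.exit(close(log_con))
  t0 <- as.numeric(Sys.time())
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 4L)

  if (!is.null(config$generator)) {
    sim <- generate_cohort(config$generator)
    cohort <- sim$cohort
    utils::write.csv(data.frame(person_id = cohort$person_id,
                                true_label = sim$labels),
                     out("true_labels.csv"), row.names = FALSE)
    write_cohort(cohort, out("cohort.csv"))
    stage_log(log_con, "simulate", t0, n = cohort_size(cohort))
  } else {
    cohort <- read_cohort(config$input)
    stage_log(log_con, "load", t0, n = cohort_size(cohort))
  }

  design <- build_design(cohort, weight_factor = config$weight_factor)
  write_scaling(design, out("scaling.json"))
  stage_log(log_con, "preprocess", t0, weight = format(design$weight))

  if (!is.null(config$k_range)) {
    sc <- selection_curve(design, min(config$k_range), max(config$k_range),
                          n_runs = config$n_runs,
                          recurrence_threshold = config$recurrence_threshold,
                          extension_runs = config$extension_runs,
                          n_starts = config$n_starts,
                          max_iter = config$max_iter, seed = seeds[1])
    utils::write.csv(sc$curve, out("selection_curve.csv"), row.names = FALSE)
    grDevices::pdf(out("selection_curve.pdf"), width = 9, height = 3.2)
    plot(sc)
    grDevices::dev.off()
    stage_log(log_con, "select_k", t0,
              ch_argmax = suggest_k(sc)[["ch_index"]],
              silhouette_argmax = suggest_k(sc)[["silhouette"]])
  }

  report <- stability_protocol(design, config$k, n_runs = config$n_runs,
                               recurrence_threshold = config$recurrence_threshold,
                               extension_runs = config$extension_runs,
                               n_starts = config$n_starts,
                               max_iter = config$max_iter, seed = seeds[2])
  utils::write.csv(data.frame(person_id = cohort$person_id,
                              cluster = report$best$assignments),
                   out("assignments.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(k = report$best$k, wcss = report$best$wcss,
         n_runs_total = report$n_runs_total, min_count = report$min_count,
         extended = report$extended, converged = report$best$converged),
    out("protocol_report.json"), auto_unbox = TRUE, digits = NA)
  stage_log(log_con, "cluster", t0, k = config$k,
            wcss = format(report$best$wcss), min_count = report$min_count)

  prof <- cluster_profiles(cohort, report$best$assignments)
  utils::write.csv(prof$sizes, out("cluster_sizes.csv"), row.names = FALSE)
  utils::write.csv(prof$prevalence, out("prevalence_oe.csv"), row.names = FALSE)
  utils::write.csv(prof$utilization_means, out("utilization_means.csv"),
                   row.names = FALSE)
  utils::write.csv(prof$condition_counts, out("condition_counts.csv"),
                   row.names = FALSE)
  utils::write.csv(prof$sociodemo, out("sociodemo_profile.csv"),
                   row.names = FALSE)
  utils::write.csv(prof$portfolios_with_rf, out("portfolios_with_rf.csv"),
                   row.names = FALSE)
  utils::write.csv(prof$portfolios_without_rf, out("portfolios_without_rf.csv"),
                   row.names = FALSE)
  stage_log(log_con, "profile", t0, clusters = nrow(prof$sizes))

  if (!is.null(config$sensitivity_factors)) {
    sens <- weight_sensitivity(cohort, config$k,
                               factors = config$sensitivity_factors,
                               base = report, n_runs = config$n_runs,
                               recurrence_threshold = config$recurrence_threshold,
                               extension_runs = config$extension_runs,
                               n_starts = config$n_starts,
                               max_iter = config$max_iter, seed = seeds[3])
    for (i in seq_along(sens$factors)) {
      utils::write.csv(as.data.frame(sens$results[[i]]$confusion),
                       out(sprintf("confusion_factor_%s.csv", sens$factors[i])),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      stats::setNames(lapply(sens$results, function(r) r$agreement_pct),
                      paste0("factor_", sens$factors)),
      out("sensitivity_agreement.json"), auto_unbox = TRUE, digits = NA)
    stage_log(log_con, "sensitivity", t0,
              agreement = paste(vapply(sens$results,
                                       function(r) format(r$agreement_pct),
                                       character(1)), collapse = "/"))
  }

  cfg <- config
  cfg$generator <- if (!is.null(config$generator)) "generator_spec" else NULL
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("morbiclust")),
         seed = config$seed, config = unclass(cfg)),
    out("manifest.json"), auto_unbox = TRUE, digits = NA, null = "null")
  stage_log(log_con, "done", t0)
  invisible(config$out_dir)
}
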