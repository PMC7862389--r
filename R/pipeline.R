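# End-to-end orchestration: simulate or load a paired dataset, apply the
# depth filter with paired propagation, then run the RSA, differential,
# pair-comparison and stratification stages and aggregate a report.

#' Build a run configuration
#'
#' Either `design` (a [simulation_design()] or a list of its arguments, for
#' a synthetic run) or the three input paths must be provided.
#'
#' @param design Simulation design for synthetic runs, or `NULL`.
#' @param counts_16s,counts_shotgun,metadata Input paths for runs on real
#'   tables, or `NULL`.
#' @param min_reads Shotgun read-depth threshold of the quality filter.
#' @param alpha Adjusted-p significance threshold.
#' @param day_compartment_subset Compartment restriction for the day
#'   contrast (`"caeca"`, `"crop"` or `NULL` to pool).
#' @param out_dir Output directory for `report.json` (`NULL`: no file).
#' @param seed Seed recorded in the report; for synthetic runs it overrides
#'   the design seed.
#' @return A `run_config` list.
#' @export
run_config <- function(design = NULL, counts_16s = NULL,
                       counts_shotgun = NULL, metadata = NULL,
                       min_reads = 500000, alpha = 0.05,
                       day_compartment_subset = NULL,
                       out_dir = NULL, seed = 1L) {
  if (is.null(design)) {
    paths <- c(counts_16s, counts_shotgun, metadata)
    if (length(paths) < 3)
      stop("provide either a simulation design or all three input paths")
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
  } else if (!inherits(design, "simulation_design")) {
    design <- do.call(simulation_design, design)
  }
  structure(list(design = design, counts_16s = counts_16s,
                 counts_shotgun = counts_shotgun, metadata = metadata,
                 min_reads = min_reads, alpha = alpha,
                 day_compartment_subset = day_compartment_subset,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys are the arguments of [run_config()].
#' @param ... Overrides applied on top of the file's keys.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  do.call(run_config, cfg)
}

log_stage <- function(verbose, ...) {
  if (verbose) message(sprintf("[metacompare] %s", sprintf(...)))
}

#' Run the full comparison workflow
#'
#' Executes, in order: dataset simulation (or loading), RSA skewness with
#' the paired 16S-vs-shotgun t-test (on all pairs, before filtering), the
#' read-depth quality filter with paired propagation, per-strategy
#' differential abundance for the compartment and day contrasts with the
#' cross-strategy concordance tables, the per-pair detection analysis with
#' the intercept-vs-depth correlation (low-depth pairs included), and the
#' silhouette stratification of the four genus subsets. Fully
#' deterministic under a fixed seed.
#'
#' @param config A [run_config()].
#' @param verbose Log stage progress to stderr.
#' @return The report: a nested list with elements `config`, `samples`,
#'   `skewness`, `quality_filter`, `differential`, `concordance`,
#'   `detection`, `stratification`. Written as `report.json` under
#'   `config$out_dir` when set.
#' @export
run_all <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$design)) {
    design <- config$design
    design$seed <- config$seed
    log_stage(verbose, "simulating paired dataset (seed %d)", design$seed)
    dataset <- generate_paired_dataset(design)
    set <- dataset$set
  } else {
    log_stage(verbose, "reading %s / %s", config$counts_16s,
              config$counts_shotgun)
    set <- read_profile_set(config$counts_16s, config$counts_shotgun,
                            config$metadata)
    dataset <- NULL
  }
  paired <- pair_profiles(set)
  log_stage(verbose, "%d profiles, %d pairs, %d unpaired",
            length(set$profiles), length(paired$pairs),
            length(paired$unpaired))

  skew <- skewness_table(set, "genus")
  skew_test <- paired_skewness_test(paired$pairs, "genus")
  log_stage(verbose, "paired skewness t = %.3f, p = %.3g",
            skew_test$t, skew_test$p)

  filt <- quality_filter(set, config$min_reads)
  fset <- filt$included
  fpairs <- pair_profiles(fset)$pairs
  log_stage(verbose, "quality filter: %d samples excluded, %d pairs kept",
            nrow(filt$excluded), length(fpairs))

  differential <- list()
  concordance <- list()
  for (ct in c("compartment", "day")) {
    res <- list()
    for (s in c("16S", "shotgun")) {
      r <- diff_abundance_set(
        fset, s, ct,
        compartment_subset = if (ct == "day")
          config$day_compartment_subset else NULL)
      res[[s]] <- r
      log_stage(verbose, "%s %s: %d/%d genera significant (padj < %g)",
                ct, s, sum(r$padj < config$alpha, na.rm = TRUE),
                sum(!is.na(r$padj)), config$alpha)
    }
    differential[[ct]] <- list(
      n_significant_16s = sum(res[["16S"]]$padj < config$alpha,
                              na.rm = TRUE),
      n_significant_shotgun = sum(res[["shotgun"]]$padj < config$alpha,
                                  na.rm = TRUE),
      results = res)
    concordance[[ct]] <- concordance_analysis(res[["16S"]],
                                              res[["shotgun"]],
                                              alpha = config$alpha)
  }

  pair_table <- pair_comparison_table(fpairs)
  # the intercept-depth relationship deliberately includes low-depth pairs
  all_fits <- lapply(paired$pairs, function(pr)
    tryCatch(detection_limit_fit(pr), error = function(e) NULL))
  all_fits <- Filter(Negate(is.null), all_fits)
  idc <- if (length(all_fits) >= 3) intercept_depth_correlation(all_fits)
         else list(r = NA_real_, p = NA_real_, n = length(all_fits),
                   defined = FALSE)
  log_stage(verbose, "detection: mean r = %.3f, intercept-depth r = %.3f",
            mean(pair_table$r, na.rm = TRUE), idc$r)

  strat <- stratification_analysis(fset)

  report <- list(
    config = list(min_reads = config$min_reads, alpha = config$alpha,
                  seed = config$seed,
                  synthetic = !is.null(config$design)),
    samples = list(n_profiles = length(set$profiles),
                   n_pairs = length(paired$pairs),
                   n_unpaired = length(paired$unpaired),
                   n_pairs_retained = length(fpairs)),
    skewness = list(per_sample = skew, paired_test = skew_test),
    quality_filter = list(excluded = filt$excluded,
                          n_excluded = nrow(filt$excluded)),
    differential = lapply(differential, function(d)
      d[c("n_significant_16s", "n_significant_shotgun")]),
    concordance = lapply(concordance, function(cc)
      cc[c("table", "n_common", "pearson_r", "slope", "intercept")]),
    detection = list(per_pair = pair_table,
                     intercept_depth = idc[c("r", "p", "n")]),
    stratification = strat
  )
  if (!is.null(dataset)) report$ground_truth <- dataset$truth
  full <- list(report = report, differential_results = differential,
               set = set, filtered_set = fset)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      report[setdiff(names(report), "ground_truth")],
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
    log_stage(verbose, "report written to %s",
              file.path(config$out_dir, "report.json"))
  }
  invisible(full)
}
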