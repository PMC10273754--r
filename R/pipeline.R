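#' Analysis run configuration
#'
#' Collects and validates every tunable of the end-to-end analysis. The
#' defaults reproduce the protocol shape of the reference analysis: delays 1
#' to 5, densities 5% to 50% in steps of 1%, 10000 permutations, FDR level
#' 0.05, and the 1.5-IQR outlier screen on each modelled outcome. Delay 0 is
#' refused because the anti-symmetric component of a zero-lag correlation
#' matrix is identically zero.
#'
#' @param delays Positive integer delays.
#' @param d_min,d_max,step Density grid in `(0, 1)`.
#' @param n_permutations Permutations per group contrast.
#' @param q FDR level.
#' @param seed Integer seed governing all randomness of the run.
#' @param measures Subset of `c("clustering", "global_efficiency")`.
#' @param outcomes Metadata columns modelled as dependent variables.
#' @param covariates Covariate columns for the association models.
#' @param iqr_k Outlier-screen multiplier.
#' @param apoe_covariate Add APOE e4 copy number as a covariate.
#' @return A validated list of class `asy_run_config`.
#' @export
run_config <- function(delays = 1:5, d_min = 0.05, d_max = 0.50,
                       step = 0.01, n_permutations = 10000, q = 0.05,
                       seed = 1L,
                       measures = c("clustering", "global_efficiency"),
                       outcomes = c("global_abeta_suvr", "braak12_suvr",
                                    "braak34_suvr", "braak56_suvr",
                                    "ADAS13", "ADASQ4", "mPACC", "CF",
                                    "TrailA", "TrailB"),
                       covariates = c("age", "sex", "education",
                                      "diagnosis"),
                       iqr_k = 1.5, apoe_covariate = FALSE) {
  abort_if(any(delays < 1), "delays must be >= 1 (delay 0 carries no directional information)")
  abort_if(d_min <= 0 || d_min >= d_max || d_max >= 1 || step <= 0,
           "invalid density bounds")
  abort_if(n_permutations < 1, "n_permutations must be >= 1")
  abort_if(q <= 0 || q >= 1, "q must be in (0, 1)")
  measures <- match.arg(measures, several.ok = TRUE)
  structure(list(delays = as.integer(delays), d_min = d_min, d_max = d_max,
                 step = step, n_permutations = as.integer(n_permutations),
                 q = q, seed = as.integer(seed), measures = measures,
                 outcomes = outcomes, covariates = covariates,
                 iqr_k = iqr_k, apoe_covariate = isTRUE(apoe_covariate)),
            class = "asy_run_config")
}

#' @rdname run_config
#' @param path YAML file whose top-level keys override the defaults.
#' @export
read_run_config <- function(path) {
  abort_if(!file.exists(path), "config file '%s' not found", path)
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  abort_if(length(unknown) > 0, "unknown config key(s): %s",
           paste(unknown, collapse = ", "))
  y$delays <- unlist(y$delays)
  y$measures <- unlist(y$measures)
  y$outcomes <- unlist(y$outcomes)
  y$covariates <- unlist(y$covariates)
  do.call(run_config, y[!vapply(y, is.null, TRUE)])
}

#' Run the full delayed-connectivity analysis
#'
#' Executes, per subject and delay, the chain delayed correlation ->
#' anti-symmetric decomposition -> directed network -> density sweep -> AUC;
#' then compares all group pairs by permutation tests with FDR control, and
#' fits AIC-selected quadratic association models per outcome and delay on
#' the amyloid-positive subjects. Identical inputs, configuration and seed
#' give identical outputs.
#'
#' @param cohort An `asy_cohort`, or a path to a directory written by
#'   [write_cohort()].
#' @param config An [run_config()] object.
#' @param out_dir Optional output directory; when given, writes
#'   `auc_table.csv`, `comparison_table.csv`, `model_table.csv` and
#'   `summary.json`.
#' @param verbose Progress messages.
#' @return A list of class `asy_run_result` with elements `auc_table`,
#'   `comparison_table`, `model_table`, `fits`, and (when written) `files`.
#' @export
run_analysis <- function(cohort, config = run_config(), out_dir = NULL,
                         verbose = FALSE) {
  abort_if(!inherits(config, "asy_run_config"), "config must come from run_config()")
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  missing_cols <- setdiff(c(config$outcomes, config$covariates),
                          names(cohort$subjects))
  abort_if(length(missing_cols) > 0,
           "metadata is missing column(s): %s",
           paste(missing_cols, collapse = ", "))
  t0 <- Sys.time()
  auc_table <- cohort_auc_table(
    cohort, delays = config$delays, measures = config$measures,
    d_min = config$d_min, d_max = config$d_max, step = config$step,
    verbose = verbose)
  comparison <- compare_all_groups(
    auc_table, n_permutations = config$n_permutations,
    seed = config$seed, q = config$q)
  assoc <- maybe_with_seed(config$seed + 1L, associate_network_measures(
    cohort, auc_table, outcomes = config$outcomes,
    covariates = config$covariates,
    apoe_covariate = config$apoe_covariate,
    iqr_k = config$iqr_k, q = config$q))
  wall <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  result <- structure(list(auc_table = auc_table,
                           comparison_table = comparison,
                           model_table = assoc$table, fits = assoc$fits,
                           config = config, wall_seconds = wall),
                      class = "asy_run_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(auc_table = file.path(out_dir, "auc_table.csv"),
               comparison_table = file.path(out_dir, "comparison_table.csv"),
               model_table = file.path(out_dir, "model_table.csv"),
               summary = file.path(out_dir, "summary.json"))
    readr::write_csv(auc_table, files[["auc_table"]])
    readr::write_csv(tibble::as_tibble(comparison),
                     files[["comparison_table"]])
    readr::write_csv(assoc$table, files[["model_table"]])
    jsonlite::write_json(
      list(package = "asymnet",
           version = as.character(utils::packageVersion("asymnet")),
           config = unclass(config), wall_seconds = wall,
           n_subjects = nrow(cohort$subjects),
           files = as.list(files[1:3])),
      files[["summary"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
    result$files <- files
    for (f in files) abort_if(!file.exists(f), "output '%s' missing", f)
  }
  result
}

#' @export
print.asy_run_result <- function(x, ...) {
  cat(sprintf(
    "<asy_run_result> %d AUC rows, %d contrasts (%d significant), %d models (%d significant)\n",
    nrow(x$auc_table), nrow(x$comparison_table),
    sum(x$comparison_table$significant), nrow(x$model_table),
    sum(x$model_table$significant)))
  invisible(x)
}
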