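#' Simulate a lagged vector-autoregressive time-series matrix
#'
#' Draws one subject's region-by-timepoint signal from the stable VAR process
#' `x(t) = sum_l B_l x(t - l) + e(t)` with Gaussian innovations, where the
#' `B_l` encode the directed lagged couplings (and optionally a common
#' diagonal AR(1) term for within-region autocorrelation). The process is
#' started from zeros and a burn-in stretch is discarded so the returned
#' segment is approximately stationary.
#'
#' @param n_regions,n_timepoints Dimensions of the returned matrix.
#' @param couplings Coupling table ([couplings()]); may have zero rows for a
#'   pure-noise process.
#' @param noise_sd Innovation standard deviation (> 0).
#' @param seed Optional integer; identical seed and inputs reproduce the
#'   matrix bit-for-bit.
#' @param ar1 Common diagonal autoregressive coefficient (default 0).
#' @param burn_in Number of initial steps discarded.
#' @param tr_seconds Sampling interval in seconds, stored as an attribute
#'   (one time step corresponds to one repetition time; 3 s by default).
#' @return An `n_regions x n_timepoints` numeric matrix with region labels as
#'   row names and attribute `tr_seconds`.
#' @examples
#' ts <- simulate_var_timeseries(5, 300, noise_sd = 1, seed = 7)
#' dim(ts)
#' @export
simulate_var_timeseries <- function(n_regions, n_timepoints,
                                    couplings = NULL, noise_sd = 1,
                                    seed = NULL, ar1 = 0, burn_in = 100L,
                                    tr_seconds = 3) {
  abort_if(n_regions < 1 || n_timepoints < 1, "dimensions must be positive")
  abort_if(noise_sd <= 0, "noise_sd must be > 0")
  if (is.null(couplings)) couplings <- couplings()
  couplings <- validate_couplings(couplings, n_regions)
  max_lag <- if (nrow(couplings)) max(couplings$lag) else as.integer(ar1 != 0)
  abort_if(max_lag >= n_timepoints,
           "largest coupling lag (%d) must be below n_timepoints (%d)",
           max_lag, n_timepoints)
  if (max_lag > 0) {
    rho <- coupling_spectral_radius(couplings, n_regions, ar1 = ar1)
    abort_if(rho >= 1,
             "unstable coupling set: companion spectral radius %.4f >= 1", rho)
  }
  B <- coupling_matrices(couplings, n_regions, ar1 = ar1)
  L <- length(B)
  total <- n_timepoints + burn_in
  maybe_with_seed(seed, {
    x <- matrix(stats::rnorm(n_regions * total, sd = noise_sd),
                n_regions, total)
    if (L > 0) {
      for (t in seq(L + 1L, total)) {
        acc <- x[, t]
        for (l in seq_len(L)) acc <- acc + B[[l]] %*% x[, t - l]
        x[, t] <- acc
      }
    }
    out <- x[, burn_in + seq_len(n_timepoints), drop = FALSE]
    rownames(out) <- region_names(n_regions)
    attr(out, "tr_seconds") <- tr_seconds
    out
  })
}

#' Assign diagnostic groups from amyloid PET status
#'
#' Classifies subjects along the Alzheimer's continuum from their clinical
#' diagnosis (CN / MCI / AD) and global amyloid-beta SUVR, using the
#' conventional amyloid-positivity cut-off of SUVR strictly greater than 1.11.
#' MCI and AD subjects without amyloid pathology fall outside the continuum
#' and are labelled `"excluded"`.
#'
#' @param diagnosis Character vector with values in `"CN"`, `"MCI"`, `"AD"`.
#' @param global_abeta_suvr Positive global amyloid SUVR values.
#' @return A factor with levels `CN_Abeta_neg`, `CN_Abeta_pos`,
#'   `MCI_Abeta_pos`, `AD_Abeta_pos`, `excluded`.
#' @examples
#' classify_group(c("CN", "MCI", "CN"), c(1.0, 1.05, 1.3))
#' @export
classify_group <- function(diagnosis, global_abeta_suvr) {
  abort_if(!all(diagnosis %in% c("CN", "MCI", "AD")),
           "unknown diagnosis label(s): %s",
           paste(setdiff(diagnosis, c("CN", "MCI", "AD")), collapse = ", "))
  abort_if(any(global_abeta_suvr <= 0), "SUVR values must be positive")
  pos <- global_abeta_suvr > 1.11
  out <- dplyr::case_when(
    diagnosis == "CN" & !pos ~ "CN_Abeta_neg",
    diagnosis == "CN" & pos ~ "CN_Abeta_pos",
    diagnosis == "MCI" & pos ~ "MCI_Abeta_pos",
    diagnosis == "AD" & pos ~ "AD_Abeta_pos",
    TRUE ~ "excluded"
  )
  factor(out, levels = group_levels(TRUE))
}

group_levels <- function(with_excluded = FALSE) {
  lv <- c("CN_Abeta_neg", "CN_Abeta_pos", "MCI_Abeta_pos", "AD_Abeta_pos")
  if (with_excluded) c(lv, "excluded") else lv
}

group_diagnosis <- c(CN_Abeta_neg = "CN", CN_Abeta_pos = "CN",
                     MCI_Abeta_pos = "MCI", AD_Abeta_pos = "AD")

#' Group specification for a synthetic cohort
#'
#' @param name Group label, one of `CN_Abeta_neg`, `CN_Abeta_pos`,
#'   `MCI_Abeta_pos`, `AD_Abeta_pos`.
#' @param n_subjects Number of subjects to draw.
#' @param couplings Coupling template ([couplings()] or
#'   [small_world_couplings()]) shared, up to per-subject jitter, by the
#'   group's subjects.
#' @param noise_sd Innovation standard deviation of the group's VAR process.
#' @return A list of class `asy_group_spec`.
#' @export
group_spec <- function(name, n_subjects, couplings, noise_sd = 1) {
  abort_if(!name %in% group_levels(), "unknown group name '%s'", name)
  abort_if(n_subjects < 1, "n_subjects must be >= 1")
  abort_if(noise_sd <= 0, "noise_sd must be > 0")
  structure(list(name = name, n_subjects = as.integer(n_subjects),
                 couplings = validate_couplings(couplings),
                 noise_sd = noise_sd),
            class = "asy_group_spec")
}

#' Quadratic outcome link
#'
#' Describes how a (possibly noisy) outcome is generated from a network
#' measure: `outcome = intercept + linear * m + quadratic * m^2 +
#' sum(covariate_coefs * covariates) + noise`. This is the generative twin of
#' the quadratic association models fitted by [fit_quadratic_model()].
#'
#' @param intercept,linear,quadratic Real coefficients.
#' @param covariate_coefs Named numeric vector mapping metadata column names
#'   to linear effects (may be empty).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @return A list of class `asy_quadratic_link`.
#' @export
quadratic_link <- function(intercept = 0, linear = 0, quadratic = 0,
                           covariate_coefs = c(), noise_sd = 0) {
  abort_if(noise_sd < 0, "noise_sd must be >= 0")
  structure(list(intercept = intercept, linear = linear,
                 quadratic = quadratic,
                 covariate_coefs = covariate_coefs, noise_sd = noise_sd),
            class = "asy_quadratic_link")
}

# group-level covariate and biomarker location parameters, loosely matched to
# typical amyloid-PET cohort composition (order CN-, CN+, MCI+, AD+)
cohort_reference_table <- function() {
  tibble::tribble(
    ~variable,      ~CN_Abeta_neg, ~CN_Abeta_pos, ~MCI_Abeta_pos, ~AD_Abeta_pos, ~sd,
    "braak12_suvr",  1.1,           1.1,           1.3,            1.5,          0.15,
    "braak34_suvr",  1.1,           1.2,           1.2,            1.4,          0.15,
    "braak56_suvr",  1.0,           1.0,           1.1,            1.1,          0.10,
    "ADAS13",        12.0,          13.3,          19.3,           32.3,         5.0,
    "ADASQ4",        2.0,           3.0,           5.0,            8.0,          1.5,
    "mPACC",         1.5,          -0.4,          -3.9,          -14.9,          4.0,
    "CF",            22.0,          22.0,          16.0,           13.5,         5.0,
    "TrailA",        30.0,          32.0,          39.0,           51.5,        12.0,
    "TrailB",        75.0,          85.0,         110.0,          160.0,        30.0
  )
}

# APOE e4 copy-number probabilities per group (0 / 1 / 2 copies)
apoe_probs <- list(
  CN_Abeta_neg  = c(63, 17, 1),
  CN_Abeta_pos  = c(19, 16, 1),
  MCI_Abeta_pos = c(14, 10, 7),
  AD_Abeta_pos  = c(11, 6, 1)
)

draw_subject_metadata <- function(group, subject_id) {
  ref <- cohort_reference_table()
  med <- stats::setNames(ref[[group]], ref$variable)
  sds <- stats::setNames(ref$sd, ref$variable)
  abeta_pos <- group != "CN_Abeta_neg"
  suvr <- if (abeta_pos) stats::runif(1, 1.12, 1.6) else stats::runif(1, 0.9, 1.11)
  vals <- stats::rnorm(length(med), med, sds)
  names(vals) <- names(med)
  vals[c("braak12_suvr", "braak34_suvr", "braak56_suvr")] <-
    pmax(vals[c("braak12_suvr", "braak34_suvr", "braak56_suvr")], 0.7)
  p <- apoe_probs[[group]]
  tibble::tibble(
    subject_id = subject_id,
    diagnosis = unname(group_diagnosis[group]),
    group = group,
    global_abeta_suvr = suvr,
    braak12_suvr = vals[["braak12_suvr"]],
    braak34_suvr = vals[["braak34_suvr"]],
    braak56_suvr = vals[["braak56_suvr"]],
    age = stats::rnorm(1, 76, 7),
    sex = sample(c("M", "F"), 1),
    education = round(pmin(pmax(stats::rnorm(1, 16, 3), 8), 22)),
    apoe4_copies = sample(0:2, 1, prob = p / sum(p)),
    ADAS13 = vals[["ADAS13"]], ADASQ4 = vals[["ADASQ4"]],
    mPACC = vals[["mPACC"]], CF = vals[["CF"]],
    TrailA = vals[["TrailA"]], TrailB = vals[["TrailB"]]
  )
}

# jitter each coupling strength multiplicatively; rescale if the jittered set
# drifts too close to instability
jitter_couplings <- function(cp, n_regions, jitter_sd, ar1) {
  if (nrow(cp) == 0 || jitter_sd == 0) return(cp)
  fac <- pmin(pmax(1 + stats::rnorm(nrow(cp), 0, jitter_sd), 0.5), 1.5)
  cp$strength <- cp$strength * fac
  rho <- coupling_spectral_radius(cp, n_regions, ar1 = ar1)
  if (rho >= 0.95) cp$strength <- cp$strength * (0.9 / rho)
  cp
}

#' Simulate a synthetic cohort with known directed structure
#'
#' Draws, for every subject of every group, a VAR time series from the group's
#' coupling template (with multiplicative per-subject strength jitter so
#' within-group network variance is nonzero) together with demographic,
#' biomarker and cognitive metadata whose locations differ by group. Amyloid
#' SUVRs are drawn on the correct side of the 1.11 positivity cut-off, and the
#' stored group label always equals [classify_group()] applied to the drawn
#' diagnosis and SUVR.
#'
#' @param groups List of [group_spec()] objects (unique names).
#' @param n_regions,n_timepoints Time-series dimensions shared by all subjects.
#' @param seed Integer seed; the whole cohort is a pure function of
#'   (design, seed).
#' @param jitter_sd Standard deviation of the multiplicative coupling jitter.
#' @param ar1 Common within-region AR(1) coefficient (see
#'   [simulate_var_timeseries()]).
#' @param tr_seconds Sampling interval in seconds.
#' @return A list of class `asy_cohort` with elements `subjects` (tibble, one
#'   row per subject), `timeseries` (named list of matrices) and `design`.
#' @examples
#' g <- group_spec("CN_Abeta_neg", 3,
#'                 small_world_couplings(12, seed = 1))
#' coh <- simulate_cohort(list(g), n_regions = 12, n_timepoints = 80, seed = 1)
#' coh$subjects$group
#' @export
simulate_cohort <- function(groups, n_regions, n_timepoints, seed,
                            jitter_sd = 0.1, ar1 = 0.3, tr_seconds = 3) {
  abort_if(length(groups) == 0, "design must contain at least one group")
  nm <- vapply(groups, function(g) g$name, "")
  abort_if(anyDuplicated(nm) > 0, "group names must be unique")
  maybe_with_seed(seed, {
    subjects <- list()
    timeseries <- list()
    sid <- 0L
    for (g in groups) {
      for (k in seq_len(g$n_subjects)) {
        sid <- sid + 1L
        id <- sprintf("sub%04d", sid)
        cp <- jitter_couplings(g$couplings, n_regions, jitter_sd, ar1)
        timeseries[[id]] <- simulate_var_timeseries(
          n_regions, n_timepoints, cp, noise_sd = g$noise_sd,
          ar1 = ar1, tr_seconds = tr_seconds)
        subjects[[sid]] <- draw_subject_metadata(g$name, id)
      }
    }
    subjects <- dplyr::bind_rows(subjects)
    stopifnot(identical(
      as.character(classify_group(subjects$diagnosis,
                                  subjects$global_abeta_suvr)),
      subjects$group))
    structure(list(subjects = subjects, timeseries = timeseries,
                   design = list(groups = groups, n_regions = n_regions,
                                 n_timepoints = n_timepoints, seed = seed,
                                 jitter_sd = jitter_sd, ar1 = ar1,
                                 tr_seconds = tr_seconds)),
              class = "asy_cohort")
  })
}

#' @export
print.asy_cohort <- function(x, ...) {
  cat(sprintf("<asy_cohort> %d subjects, %d regions x %d timepoints\n",
              nrow(x$subjects), x$design$n_regions, x$design$n_timepoints))
  print(table(x$subjects$group))
  invisible(x)
}

#' Attach a quadratic outcome to a cohort
#'
#' Stores, under `outcome_name` in the subject table, a variable generated
#' from per-subject measure values through a [quadratic_link()].
#'
#' @param cohort An `asy_cohort`.
#' @param measure_values Named numeric vector, one value per `subject_id`.
#' @param link A [quadratic_link()].
#' @param outcome_name Column name for the new outcome.
#' @param seed Optional seed for the noise draws.
#' @return The cohort with the outcome column added.
#' @export
attach_quadratic_outcome <- function(cohort, measure_values, link,
                                     outcome_name, seed = NULL) {
  ids <- cohort$subjects$subject_id
  missing <- setdiff(ids, names(measure_values))
  abort_if(length(missing) > 0, "missing measure values for: %s",
           paste(utils::head(missing, 5), collapse = ", "))
  m <- unname(measure_values[ids])
  y <- link$intercept + link$linear * m + link$quadratic * m^2
  for (cv in names(link$covariate_coefs)) {
    abort_if(!cv %in% names(cohort$subjects),
             "covariate '%s' not in subject table", cv)
    y <- y + link$covariate_coefs[[cv]] * cohort$subjects[[cv]]
  }
  y <- maybe_with_seed(seed, y + stats::rnorm(length(y), 0, link$noise_sd))
  cohort$subjects[[outcome_name]] <- y
  cohort
}
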