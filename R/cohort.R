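# Synthetic patient-level cohorts mirroring the statistical structure of the
# real-world FNAC series: Milan category frequencies, per-category risk of
# malignancy, anatomic site mix. Site is drawn independently of category (no
# category-by-site cross-tabulation is published; independence is the minimal
# assumption).

#' Generate a synthetic FNAC cohort
#'
#' Draws `n` independent patient records: anatomic site from `site_mix`,
#' Milan category from `category_dist`, and true malignancy as a Bernoulli
#' draw with the category's risk of malignancy, so
#' `P(malignant | category) = rom[category]` by construction.
#'
#' @param params A [model_parameters()] object.
#' @param n Cohort size (>= 0).
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @return Data frame with columns `patient_id`, `site`
#'   (`"parotid"`/`"submandibular"`), `category` (factor over
#'   [milan_categories()]) and `malignant` (logical).
#' @export
#' @examples
#' cohort <- generate_cohort(builtin_parameters("1c"), n = 1289, seed = 1)
#' table(cohort$category)
generate_cohort <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "model_parameters"))
  if (length(n) != 1 || !is.finite(n) || n < 0) {
    stop("n must be >= 0", call. = FALSE)
  }
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  cats <- milan_categories()
  category <- if (n > 0) {
    factor(sample(cats, n, replace = TRUE,
                  prob = unname(params$category_dist[cats])),
           levels = cats)
  } else {
    factor(character(), levels = cats)
  }
  site <- ifelse(stats::runif(n) < params$site_mix,
                 "parotid", "submandibular")
  malignant <- stats::runif(n) < unname(params$rom[as.character(category)])
  data.frame(patient_id = seq_len(n),
             site = as.character(site),
             category = category,
             malignant = as.logical(malignant))
}

# Clopper-Pearson exact binomial interval
clopper_pearson <- function(x, n, conf_level = 0.99) {
  alpha <- 1 - conf_level
  lower <- ifelse(x == 0, 0, stats::qbeta(alpha / 2, x, n - x + 1))
  upper <- ifelse(x == n, 1, stats::qbeta(1 - alpha / 2, x + 1, n - x))
  cbind(lower = lower, upper = upper)
}

#' Estimate category frequencies and risks of malignancy from a cohort
#'
#' Computes, per Milan category, the empirical frequency and the empirical
#' malignancy fraction with exact (Clopper-Pearson) binomial confidence
#' intervals. Exact intervals are used because the rarest categories
#' (V, VI) have small expected counts at realistic cohort sizes. When the
#' generating parameters are supplied, per-cell coverage indicators are added.
#'
#' @param cohort A data frame from [generate_cohort()] (or imported with the
#'   same columns).
#' @param truth Optional [model_parameters()] the cohort was generated from.
#' @param conf_level Confidence level for the intervals (default 0.99).
#' @return A `recovery_report` data frame with one row per category:
#'   `n_cat`, `freq`, `freq_lower`, `freq_upper`, `n_malignant`, `rom`,
#'   `rom_lower`, `rom_upper`, and - when `truth` is given - `freq_true`,
#'   `rom_true`, `freq_covered`, `rom_covered`. ROM cells are `NA` for
#'   categories absent from the cohort.
#' @export
estimate_parameters <- function(cohort, truth = NULL, conf_level = 0.99) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    stop("cohort must be a non-empty data frame", call. = FALSE)
  }
  stopifnot(all(c("category", "malignant") %in% names(cohort)))
  cats <- milan_categories()
  category <- factor(as.character(cohort$category), levels = cats)
  n <- nrow(cohort)
  n_cat <- as.integer(table(category))
  n_mal <- as.integer(tapply(cohort$malignant, category, sum, default = 0L))
  freq_ci <- clopper_pearson(n_cat, n, conf_level)
  rom_ci <- clopper_pearson(n_mal, pmax(n_cat, 1L), conf_level)
  rom_ci[n_cat == 0, ] <- NA_real_
  out <- data.frame(
    category = cats,
    n_cat = n_cat,
    freq = n_cat / n,
    freq_lower = freq_ci[, "lower"],
    freq_upper = freq_ci[, "upper"],
    n_malignant = n_mal,
    rom = ifelse(n_cat > 0, n_mal / n_cat, NA_real_),
    rom_lower = rom_ci[, "lower"],
    rom_upper = rom_ci[, "upper"])
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "model_parameters"))
    out$freq_true <- unname(truth$category_dist[cats])
    out$rom_true <- unname(truth$rom[cats])
    out$freq_covered <- out$freq_lower <= out$freq_true &
      out$freq_true <= out$freq_upper
    out$rom_covered <- ifelse(is.na(out$rom),
                              NA,
                              out$rom_lower <= out$rom_true &
                                out$rom_true <= out$rom_upper)
  }
  attr(out, "conf_level") <- conf_level
  attr(out, "n") <- n
  class(out) <- c("recovery_report", class(out))
  out
}

#' Seeded coverage simulation for the recovery harness
#'
#' Repeatedly generates cohorts from `params`, estimates frequencies and ROMs
#' with exact intervals, and counts cells whose interval fails to cover the
#' generating value. With exact binomial intervals the per-cell failure rate
#' is at most `1 - conf_level` by construction; the simulation verifies this
#' end to end through the generator and estimator.
#'
#' @param params Generating [model_parameters()].
#' @param n Cohort size per replicate.
#' @param reps Number of replicates.
#' @param conf_level Interval confidence level.
#' @param seed Master seed; replicate `r` uses `seed + r`.
#' @return List with `failure_rate`, `n_checks` (covered cells assessed),
#'   `n_failures`, `nominal` (`1 - conf_level`), `reps`, `n`.
#' @export
coverage_simulation <- function(params, n = 2000, reps = 500,
                                conf_level = 0.99, seed = 1) {
  failures <- 0L
  checks <- 0L
  for (r in seq_len(reps)) {
    cohort <- generate_cohort(params, n, seed = seed + r)
    rep_ <- estimate_parameters(cohort, truth = params,
                                conf_level = conf_level)
    cover <- c(rep_$freq_covered, rep_$rom_covered)
    cover <- cover[!is.na(cover)]
    checks <- checks + length(cover)
    failures <- failures + sum(!cover)
  }
  list(failure_rate = failures / checks, n_checks = checks,
       n_failures = failures, nominal = 1 - conf_level,
       reps = reps, n = n)
}

#' Cohort CSV round trip
#'
#' `write_cohort_csv()`/`read_cohort_csv()` persist a cohort with columns
#' `patient_id, site, category, malignant`.
#'
#' @param cohort A cohort data frame.
#' @param path CSV file path.
#' @return The reader returns the cohort data frame; the writer returns
#'   `path` invisibly.
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort[, c("patient_id", "site", "category", "malignant")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$category <- factor(df$category, levels = milan_categories())
  df$malignant <- as.logical(df$malignant)
  df
}
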