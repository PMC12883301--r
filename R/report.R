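# Scenario grid runner and reporting: the tabular equivalent of the model's
# headline results, plus the descriptive complication table (which never
# enters the simulation) and the published per-case means for calibration.

# deterministic sub-seed for run k of a grid; keeps every derived seed a
# valid 32-bit integer
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) * 10007 + 7919 * k) %% 2147483562) + 1L
}

#' Run the full model-by-scenario grid
#'
#' For every requested model, simulates the upfront-surgery arm once and the
#' FNAC-first arm at every requested category-IVa surgery rate, with
#' deterministically derived per-run sub-seeds, and tabulates cohort
#' statistics alongside the exact tree expectation and the savings
#' arithmetic.
#'
#' @param models Subset of `c("1a", "1b", "1c")`, or a named list of
#'   [model_parameters()] objects for user-defined models.
#' @param iva_rates IVa surgery rates to run (non-empty, each in `[0, 1]`).
#' @param n Cohort size per run (>= 1).
#' @param seed Master seed; run `k` of the grid uses a sub-seed derived as
#'   `(seed * 10007 + 7919 k) mod 2147483562 + 1`, so arms are independently
#'   reproducible.
#' @param costs_list Optional named list of [cost_table()] overrides keyed by
#'   model id.
#' @param completion Completion mode for the upfront arm, see
#'   [build_upfront_arm()].
#' @return Data frame with one row per (model, arm, IVa rate): `model`,
#'   `arm`, `iva_rate` (`NA` for the upfront arm), `currency`, `n`, `seed`,
#'   `mean`, `sd`, `se`, `median`, `q025`, `q975`, `expected` (analytic),
#'   and for FNAC rows `upfront_mean`, `absolute_saving`, `percent_saving`,
#'   `percent_saving_truncated`.
#' @export
#' @examples
#' res <- run_scenarios(models = "1b", iva_rates = c(1, 0), n = 2000, seed = 7)
#' res[, c("model", "arm", "iva_rate", "mean", "percent_saving_truncated")]
run_scenarios <- function(models = c("1a", "1b", "1c"),
                          iva_rates = c(1, 0.7, 0),
                          n = 10000, seed = 1,
                          costs_list = NULL,
                          completion = c("append", "replace")) {
  completion <- match.arg(completion)
  if (length(models) == 0) stop("models must be non-empty", call. = FALSE)
  if (length(iva_rates) == 0) {
    stop("iva_rates must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(iva_rates) | iva_rates < 0 | iva_rates > 1)) {
    stop("iva_rates: every rate must be in [0, 1]", call. = FALSE)
  }
  if (length(n) != 1 || !is.finite(n) || n < 1) {
    stop("n must be >= 1", call. = FALSE)
  }
  params_list <- if (is.list(models)) {
    models
  } else {
    stats::setNames(lapply(models, builtin_parameters), models)
  }
  rows <- list()
  k <- 0L
  for (id in names(params_list)) {
    params <- params_list[[id]]
    costs <- costs_list[[id]] %||% builtin_cost_table(params$currency)
    spec <- arm_spec(params, costs)

    up_tree <- build_upfront_arm(spec, completion = completion)
    k <- k + 1L
    up_seed <- derive_seed(seed, k)
    up <- simulate_tree(up_tree, n = n, seed = up_seed)
    rows[[length(rows) + 1L]] <- data.frame(
      model = id, arm = "upfront_surgery", iva_rate = NA_real_,
      currency = costs$currency, n = n, seed = up_seed,
      mean = up$mean, sd = up$sd, se = up$se,
      median = up$median, q025 = up$q025, q975 = up$q975,
      expected = expected_cost(up_tree, validate = FALSE),
      upfront_mean = NA_real_, absolute_saving = NA_real_,
      percent_saving = NA_real_, percent_saving_truncated = NA_real_)

    for (rate in iva_rates) {
      tree <- build_fnac_arm(spec, iva_surgery_rate = rate)
      k <- k + 1L
      run_seed <- derive_seed(seed, k)
      fn <- simulate_tree(tree, n = n, seed = run_seed)
      red <- compare_arms(up, fn)
      rows[[length(rows) + 1L]] <- data.frame(
        model = id, arm = "fnac_first", iva_rate = rate,
        currency = costs$currency, n = n, seed = run_seed,
        mean = fn$mean, sd = fn$sd, se = fn$se,
        median = fn$median, q025 = fn$q025, q975 = fn$q975,
        expected = expected_cost(tree, validate = FALSE),
        upfront_mean = up$mean,
        absolute_saving = red$absolute_saving,
        percent_saving = red$percent_saving,
        percent_saving_truncated = red$percent_saving_truncated)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "master_seed") <- seed
  out
}

#' Write scenario results and run metadata
#'
#' Writes `results.csv` (monetary columns additionally rounded to whole
#' currency units in `*_rounded` companions) and `metadata.json` (master
#' seed, n, parameter fingerprint, package version, timestamp). The results
#' file contains no timestamp, so re-running with an identical seed and
#' parameters reproduces it byte for byte.
#'
#' @param results Data frame from [run_scenarios()].
#' @param dir Output directory (created if missing).
#' @param format `"csv"` (default) or `"json"` for the results table.
#' @return Character vector of written file paths, invisibly.
#' @export
write_scenario_results <- function(results, dir, format = c("csv", "json")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- results
  for (col in c("mean", "median", "absolute_saving")) {
    out[[paste0(col, "_rounded")]] <- round(out[[col]])
  }
  results_path <- file.path(dir,
                            paste0("results.", format))
  if (format == "csv") {
    utils::write.csv(out, results_path, row.names = FALSE)
  } else {
    jsonlite::write_json(out, results_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  meta <- list(master_seed = attr(results, "master_seed"),
               n = unique(results$n),
               models = unique(results$model),
               iva_rates = unique(results$iva_rate[!is.na(results$iva_rate)]),
               package_version =
                 as.character(utils::packageVersion("milancost")),
               timestamp = format(Sys.time(), tz = "UTC",
                                  usetz = TRUE))
  meta_path <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(results_path, meta_path))
}

#' Binned cost histogram for re-plotting
#'
#' Exports the per-case cost distribution of a simulated cohort as binned
#' counts, the tabular equivalent of a cost histogram.
#'
#' @param summary A [simulate_tree()] result.
#' @param breaks Passed to [hist()] (number of bins or break vector).
#' @return Data frame with `bin_lower`, `bin_upper`, `count`.
#' @export
cost_histogram <- function(summary, breaks = 50) {
  stopifnot(inherits(summary, "sim_summary"))
  h <- graphics::hist(summary$costs, breaks = breaks, plot = FALSE)
  data.frame(bin_lower = utils::head(h$breaks, -1),
             bin_upper = utils::tail(h$breaks, -1),
             count = h$counts)
}

#' Descriptive complication rates for the modeled procedures
#'
#' Literature-reported complication rates, as ranges or point values. Kept
#' purely descriptive: complication costs are deliberately *not* part of the
#' simulation (rates vary too widely across patient collectives, and leaving
#' them out keeps the FNAC arm's advantage conservative, since revision and
#' complication burden falls mainly on the surgical pathway).
#'
#' @return Data frame with `procedure` and `complication_rate_pct`
#'   (as printed, e.g. `"< 1"`, `"3.4-7.7"`).
#' @export
complication_table <- function() {
  data.frame(
    procedure = c("fnac",
                  "partial_parotidectomy",
                  "submandibulectomy",
                  "total_parotidectomy_nd",
                  "submandibulectomy_nd",
                  "neck_dissection"),
    complication_rate_pct = c("< 1", "3.5", "3.4-7.7", "13.9",
                              "11-52", "11-52"))
}

#' Published per-case mean costs of the original analysis
#'
#' The per-case Monte Carlo mean costs reported by the study this package
#' re-implements, for calibration comparison only: nothing in the simulation
#' reads these values. Models: `1a` (MSRSGC estimates, USD), `1b` (MSRSGC
#' estimates, EUR), `1c` (real-world data, EUR).
#'
#' @return Data frame with `model`, `arm`, `iva_rate`, `published_mean`,
#'   `currency`.
#' @export
published_costs <- function() {
  data.frame(
    model = rep(c("1a", "1b", "1c"), each = 4),
    arm = rep(c("upfront_surgery", "fnac_first", "fnac_first", "fnac_first"),
              3),
    iva_rate = rep(c(NA, 1, 0.7, 0), 3),
    published_mean = c(17472, 11866, 9947, 4377,
                       8018, 5553, 4825, 2681,
                       7988, 5510, 4618, 2034),
    currency = rep(c("USD", "EUR", "EUR"), each = 4))
}

#' Calibration comparison against the published means
#'
#' Joins a [run_scenarios()] table with [published_costs()] and reports the
#' absolute and relative deviation of every simulated mean from its published
#' counterpart. This is a calibration report, not a validation: the original
#' figure-level node probabilities are not published numerically, so the
#' built-in parameter sets use the documented fallback assumptions (see the
#' methods vignette).
#'
#' @param results Data frame from [run_scenarios()].
#' @return Data frame with the matched rows plus `published_mean`,
#'   `deviation` and `relative_deviation`.
#' @export
calibration_report <- function(results) {
  pub <- published_costs()
  key <- function(df) {
    paste(df$model, df$arm, ifelse(is.na(df$iva_rate), "-", df$iva_rate))
  }
  idx <- match(key(results), key(pub))
  out <- results[!is.na(idx), ]
  out$published_mean <- pub$published_mean[idx[!is.na(idx)]]
  out$deviation <- out$mean - out$published_mean
  out$relative_deviation <- out$deviation / out$published_mean
  rownames(out) <- NULL
  out
}
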