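# Seeded Monte Carlo cohort simulation. One uniform draw resolves each chance
# node against the cumulative branch probabilities in declared branch order,
# so a cohort is bit-reproducible for a fixed (tree, n, seed).

# single root-to-terminal walk using the current RNG state
walk_tree <- function(root, keep_events = TRUE) {
  cost <- 0
  n_fnac <- 0L
  n_surgeries <- 0L
  malignant <- FALSE
  events <- character()
  node <- root
  repeat {
    cost <- cost + node$cost
    if (keep_events) events <- c(events, node$label)
    if (length(node$tags)) {
      if ("fnac" %in% node$tags) n_fnac <- n_fnac + 1L
      if ("surgery" %in% node$tags) n_surgeries <- n_surgeries + 1L
      if ("malignant" %in% node$tags) malignant <- TRUE
    }
    if (node$kind == "terminal") break
    if (node$kind == "decision") {
      node <- node$branches[[node$chosen]]$node
    } else {
      u <- stats::runif(1)
      acc <- 0
      nb <- length(node$branches)
      pick <- nb
      for (i in seq_len(nb)) {
        acc <- acc + node$branches[[i]]$prob
        if (u <= acc) {
          pick <- i
          break
        }
      }
      node <- node$branches[[pick]]$node
    }
  }
  list(events = events, total_cost = cost, is_malignant = malignant,
       n_fnac = n_fnac, n_surgeries = n_surgeries)
}

#' Sample one patient trajectory from a decision tree
#'
#' Walks the tree from the root, resolving every chance node with a single
#' uniform draw from the current RNG stream compared against the cumulative
#' branch probabilities in declared order. Deterministic given the RNG state.
#'
#' @param tree A validated [decision_tree()] or `milan_node`.
#' @return An object of class `trajectory`: list with `events` (visited node
#'   labels in order), `total_cost`, `is_malignant`, `n_fnac`, `n_surgeries`.
#' @export
sample_trajectory <- function(tree) {
  structure(walk_tree(as_root(tree)), class = "trajectory")
}

#' Monte Carlo cohort simulation of a strategy arm
#'
#' Simulates `n` independent patient trajectories through the tree and
#' summarizes the per-case cost distribution. The default cohort size is
#' 10,000. Results are bit-reproducible for a fixed `(tree, n, seed)`.
#'
#' @param tree A validated [decision_tree()] (or bare node).
#' @param n Number of simulated patients (>= 1).
#' @param seed Integer seed applied via [set.seed()]; `NULL` continues the
#'   current RNG stream.
#' @param keep_trajectories Retain per-patient event sequences (needed for
#'   [export_trajectories()]); off by default to keep the summary light.
#' @return An object of class `sim_summary`: cohort statistics (`mean`, `sd`,
#'   `se = sd/sqrt(n)`, `median`, `q025`, `q975`), the per-patient `costs`
#'   vector, per-patient flags, arm metadata and the seed.
#' @export
#' @examples
#' tree <- builtin_arm("1b", "fnac_first", iva_surgery_rate = 1)
#' simulate_tree(tree, n = 2000, seed = 42)
simulate_tree <- function(tree, n = 10000, seed = NULL,
                          keep_trajectories = FALSE) {
  if (length(n) != 1 || !is.finite(n) || n < 1) {
    stop("n must be >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  stop_if_invalid(tree)
  root <- as_root(tree)
  if (!is.null(seed)) set.seed(seed)
  costs <- numeric(n)
  malignant <- logical(n)
  n_fnac <- integer(n)
  n_surgeries <- integer(n)
  trajectories <- if (keep_trajectories) vector("list", n)
  for (i in seq_len(n)) {
    tr <- walk_tree(root, keep_events = keep_trajectories)
    costs[i] <- tr$total_cost
    malignant[i] <- tr$is_malignant
    n_fnac[i] <- tr$n_fnac
    n_surgeries[i] <- tr$n_surgeries
    if (keep_trajectories) trajectories[[i]] <- tr
  }
  q <- stats::quantile(costs, c(0.025, 0.5, 0.975), names = FALSE)
  meta <- if (inherits(tree, "decision_tree")) tree else
    list(currency = NA_character_, model_id = NA_character_,
         arm = NA_character_, iva_surgery_rate = NA_real_)
  structure(list(n = n, seed = seed,
                 mean = mean(costs), sd = stats::sd(costs),
                 se = stats::sd(costs) / sqrt(n),
                 median = q[2], q025 = q[1], q975 = q[3],
                 costs = costs,
                 is_malignant = malignant, n_fnac = n_fnac,
                 n_surgeries = n_surgeries,
                 trajectories = trajectories,
                 currency = meta$currency, model_id = meta$model_id,
                 arm = meta$arm, iva_surgery_rate = meta$iva_surgery_rate),
            class = "sim_summary")
}

#' @export
print.sim_summary <- function(x, ...) {
  cat(sprintf("Monte Carlo cohort: %s arm, model %s (%s), n = %d%s\n",
              x$arm, x$model_id, x$currency, x$n,
              if (!is.null(x$seed)) sprintf(", seed %d", x$seed) else ""))
  if (!is.na(x$iva_surgery_rate)) {
    cat(sprintf("IVa surgery rate: %.2g\n", x$iva_surgery_rate))
  }
  cat(sprintf("mean %.2f (se %.2f), sd %.2f\n", x$mean, x$se, x$sd))
  cat(sprintf("median %.2f, 95%% interval [%.2f, %.2f]\n",
              x$median, x$q025, x$q975))
  invisible(x)
}

#' Cost reduction of the FNAC-first strategy versus upfront surgery
#'
#' `reduction_from_means()` is the pure arithmetic: absolute saving
#' `upfront - fnac` and percent saving `100 * saving / upfront`, the latter
#' also *truncated toward zero* to whole percent (the package's reporting
#' convention; the full-precision value is always retained alongside).
#' `compare_arms()` applies it to two [simulate_tree()] summaries after
#' checking they share currency and model.
#'
#' @param upfront_mean,fnac_mean Mean per-case costs.
#' @param upfront,fnac `sim_summary` objects for the two arms of one model.
#' @return An object of class `cost_reduction`: `upfront_mean`, `fnac_mean`,
#'   `absolute_saving`, `percent_saving` (full precision),
#'   `percent_saving_truncated` (integer).
#' @name cost_reduction
NULL

#' @rdname cost_reduction
#' @export
reduction_from_means <- function(upfront_mean, fnac_mean) {
  saving <- upfront_mean - fnac_mean
  pct <- 100 * saving / upfront_mean
  structure(list(upfront_mean = upfront_mean, fnac_mean = fnac_mean,
                 absolute_saving = saving,
                 percent_saving = pct,
                 percent_saving_truncated = trunc(pct)),
            class = "cost_reduction")
}

#' @rdname cost_reduction
#' @export
compare_arms <- function(upfront, fnac) {
  stopifnot(inherits(upfront, "sim_summary"), inherits(fnac, "sim_summary"))
  if (!identical(upfront$currency, fnac$currency)) {
    stop("cannot compare arms in different currencies (",
         upfront$currency, " vs ", fnac$currency, ")", call. = FALSE)
  }
  if (!identical(upfront$model_id, fnac$model_id)) {
    stop("cannot compare arms from different models (",
         upfront$model_id, " vs ", fnac$model_id, ")", call. = FALSE)
  }
  out <- reduction_from_means(upfront$mean, fnac$mean)
  out$currency <- upfront$currency
  out$model_id <- upfront$model_id
  out$iva_surgery_rate <- fnac$iva_surgery_rate
  out
}

#' @export
print.cost_reduction <- function(x, ...) {
  unit <- if (!is.null(x$currency)) paste0(" ", x$currency) else ""
  cat(sprintf("upfront %.2f%s vs FNAC-first %.2f%s\n",
              x$upfront_mean, unit, x$fnac_mean, unit))
  cat(sprintf("saving %.2f%s = %d%% (%.2f%% untruncated)\n",
              x$absolute_saving, unit, x$percent_saving_truncated,
              x$percent_saving))
  invisible(x)
}

#' Convergence diagnostic for a Monte Carlo summary
#'
#' Compares the simulated mean with the tree's exact [expected_cost()] and
#' flags the run if the absolute deviation exceeds `z_max` Monte Carlo
#' standard errors (default 3.5, a per-check false-alarm rate below 1/2000
#' under normal approximation).
#'
#' @param tree The [decision_tree()] the summary was produced from.
#' @param summary A `sim_summary`.
#' @param z_max Flagging threshold in standard errors.
#' @return List with `expected`, `mean`, `se`, `z` and logical `pass`.
#' @export
convergence_check <- function(tree, summary, z_max = 3.5) {
  stopifnot(inherits(summary, "sim_summary"))
  expected <- expected_cost(tree)
  se <- summary$se
  z <- if (se == 0) {
    if (summary$mean == expected) 0 else Inf
  } else {
    abs(summary$mean - expected) / se
  }
  list(expected = expected, mean = summary$mean, se = se, z = z,
       pass = z <= z_max)
}

#' Export per-patient trajectories to CSV
#'
#' Requires a summary produced with `keep_trajectories = TRUE`. Columns:
#' `patient_id, events, is_malignant, n_fnac, n_surgeries, cost`; events are
#' the visited node labels joined by `" -> "`.
#'
#' @param summary A `sim_summary` with retained trajectories.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_trajectories <- function(summary, path) {
  stopifnot(inherits(summary, "sim_summary"))
  if (is.null(summary$trajectories)) {
    stop("summary was produced with keep_trajectories = FALSE", call. = FALSE)
  }
  df <- data.frame(
    patient_id = seq_len(summary$n),
    events = vapply(summary$trajectories,
                    function(tr) paste(tr$events, collapse = " -> "),
                    character(1)),
    is_malignant = summary$is_malignant,
    n_fnac = summary$n_fnac,
    n_surgeries = summary$n_surgeries,
    cost = summary$costs)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
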