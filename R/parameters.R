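# Model inputs: Milan categories, tariff tables, category distributions and
# risks of malignancy, plus the three built-in parameter sets.

#' Milan System (MSRSGC) diagnostic categories
#'
#' The seven reporting categories of the Milan System for Reporting Salivary
#' Gland Cytopathology, in conventional order.
#'
#' @return Character vector of category codes:
#'   `I` (non-diagnostic), `II` (non-neoplastic), `III` (atypia of undetermined
#'   significance, AUS), `IVa` (neoplasm: benign), `IVb` (neoplasm of uncertain
#'   malignant potential, SUMP), `V` (suspicious for malignancy),
#'   `VI` (malignant).
#' @export
#' @examples
#' milan_categories()
milan_categories <- function() {
  c("I", "II", "III", "IVa", "IVb", "V", "VI")
}

#' @rdname milan_categories
#' @return `milan_category_labels()`: named character vector of descriptive
#'   labels keyed by category code.
#' @export
milan_category_labels <- function() {
  c(I    = "Non-diagnostic",
    II   = "Non-neoplastic",
    III  = "Atypia of undetermined significance (AUS)",
    IVa  = "Neoplasm: benign",
    IVb  = "Neoplasm: uncertain malignant potential (SUMP)",
    V    = "Suspicious for malignancy",
    VI   = "Malignant")
}

# procedures every cost table must price
cost_procedures <- function() {
  c("partial_parotidectomy", "submandibulectomy",
    "total_parotidectomy_nd", "submandibulectomy_nd", "neck_dissection",
    "fnac", "frozen_section", "repeat_fnac", "follow_up")
}

#' Construct and validate a procedure cost table
#'
#' A cost table maps the procedures of the diagnostic pathway to monetary
#' costs in a single currency. No arithmetic across currencies is ever
#' performed by the package.
#'
#' @param currency `"USD"` or `"EUR"`.
#' @param entries Named numeric vector of non-negative costs. Must contain
#'   every procedure listed by `cost_procedures()`: the gland-conserving
#'   excisions (`partial_parotidectomy`, `submandibulectomy`), the oncologic
#'   procedures (`total_parotidectomy_nd`, `submandibulectomy_nd`,
#'   `neck_dissection`), and the diagnostics (`fnac`, `frozen_section`,
#'   `repeat_fnac`, `follow_up`).
#' @param codes Optional named character vector of billing codes (CPT or
#'   OPS/EBM) for documentation and CSV export.
#' @return An object of class `cost_table`.
#' @seealso [builtin_cost_table()]
#' @export
cost_table <- function(currency, entries, codes = NULL) {
  currency <- match.arg(currency, c("USD", "EUR"))
  problems <- character()
  missing <- setdiff(cost_procedures(), names(entries))
  if (length(missing)) {
    problems <- c(problems,
                  sprintf("entries: missing procedures %s",
                          paste(missing, collapse = ", ")))
  }
  bad <- names(entries)[!is.finite(entries) | entries < 0]
  if (length(bad)) {
    problems <- c(problems,
                  sprintf("entries.%s: cost must be a finite number >= 0", bad))
  }
  if (length(problems)) {
    stop("invalid cost table: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  structure(list(currency = currency,
                 entries = entries[cost_procedures()],
                 codes = codes),
            class = "cost_table")
}

#' Built-in tariff tables (US and German, 2025)
#'
#' Approximated procedure costs: US values from the Medicare Physician Fee
#' Schedule / FAIR Health (CPT codes), German values from a DRG web grouper for
#' OPS codes and the EBM outpatient catalog. The ultrasound-guided FNAC tariff
#' is the only outpatient item; note the two orders of magnitude between the
#' German FNAC fee (15.37 EUR) and any surgical DRG.
#'
#' No tariff is published for intraoperative frozen section (bundled into the
#' surgical fee) or for clinical/radiological follow-up; both default to 0 and
#' can be overridden. A repeat FNAC is priced like the first.
#'
#' @param currency `"USD"` or `"EUR"`.
#' @return A [cost_table()].
#' @export
#' @examples
#' builtin_cost_table("USD")$entries[["partial_parotidectomy"]]  # 13316
#' builtin_cost_table("EUR")$entries[["fnac"]]                   # 15.37
builtin_cost_table <- function(currency) {
  currency <- match.arg(currency, c("USD", "EUR"))
  if (currency == "USD") {
    entries <- c(partial_parotidectomy  = 13316,
                 submandibulectomy      = 8707,
                 total_parotidectomy_nd = 18456,
                 submandibulectomy_nd   = 24103,
                 neck_dissection        = 15396,
                 fnac                   = 141,
                 frozen_section         = 0,
                 repeat_fnac            = 141,
                 follow_up              = 0)
    codes <- c(partial_parotidectomy  = "42420",
               submandibulectomy      = "42440",
               total_parotidectomy_nd = "42426",
               submandibulectomy_nd   = "42440, 38724",
               neck_dissection        = "38724",
               fnac                   = "10022",
               frozen_section         = "",
               repeat_fnac            = "10022",
               follow_up              = "")
  } else {
    entries <- c(partial_parotidectomy  = 5047.34,
                 submandibulectomy      = 3808.19,
                 total_parotidectomy_nd = 11931.02,
                 submandibulectomy_nd   = 11931.02,
                 neck_dissection        = 9864.74,
                 fnac                   = 15.37,
                 frozen_section         = 0,
                 repeat_fnac            = 15.37,
                 follow_up              = 0)
    codes <- c(partial_parotidectomy  = "5-262.0",
               submandibulectomy      = "5-262.4",
               total_parotidectomy_nd = "5-262.1, 5-403.20",
               submandibulectomy_nd   = "5-262.4, 5-403.20",
               neck_dissection        = "5-403.20",
               fnac                   = "02340+33011",
               frozen_section         = "",
               repeat_fnac            = "02340+33011",
               follow_up              = "")
  }
  cost_table(currency, entries, codes)
}

# validate a probability vector over the milan categories; returns messages
check_category_prob <- function(x, field, must_sum = FALSE, tol = 1e-9) {
  problems <- character()
  missing <- setdiff(milan_categories(), names(x))
  if (length(missing)) {
    return(sprintf("%s: missing categories %s", field,
                   paste(missing, collapse = ", ")))
  }
  x <- x[milan_categories()]
  bad <- names(x)[!is.finite(x) | x < 0 | x > 1]
  if (length(bad)) {
    problems <- c(problems,
                  sprintf("%s.%s: probability outside [0, 1]", field, bad))
  }
  if (must_sum && all(is.finite(x)) && abs(sum(x) - 1) > tol) {
    problems <- c(problems,
                  sprintf("%s: probabilities sum to %.10g, not 1", field,
                          sum(x)))
  }
  problems
}

check_unit_interval <- function(x, field) {
  if (length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
    sprintf("%s: must be a single probability in [0, 1]", field)
  } else character()
}

#' Construct and validate a full model parameter set
#'
#' Bundles everything the arm builders need besides the tariff table: the
#' Milan category distribution of the FNAC population, the per-category risk
#' of malignancy (ROM), the anatomic site mix, the management rate for
#' category IVa lesions, the category distribution of a repeat FNAC, and the
#' malignancy prevalence assumed in the upfront-surgery arm.
#'
#' @param model_id Identifier, conventionally `"1a"`, `"1b"` or `"1c"` for the
#'   built-in sets; free text for user-defined sets.
#' @param currency Tariff jurisdiction the parameters belong to
#'   (`"USD"`/`"EUR"`); checked against the cost table when an arm is built.
#' @param category_dist Named probability vector over [milan_categories()],
#'   summing to 1 within `1e-9`.
#' @param rom Named vector of per-category risks of malignancy in `[0, 1]`.
#' @param site_mix Probability that a lesion is parotid (vs submandibular).
#' @param iva_surgery_rate Probability that a category-IVa lesion is resected
#'   rather than followed conservatively (scenario dial: 1, 0.7, 0).
#' @param second_fnac_dist Category distribution of the repeat FNAC performed
#'   for category I/III lesions; defaults to `category_dist`.
#' @param upfront_malignancy_rate Malignancy prevalence used in the
#'   upfront-surgery arm, where no cytology informs the case mix; defaults to
#'   0.25, the midpoint of the 20--30% malignant share reported for salivary
#'   gland tumors. Use [weighted_rom()] for the cytology-implied alternative.
#' @return An object of class `model_parameters`.
#' @seealso [builtin_parameters()], [apply_iva_scenario()]
#' @export
model_parameters <- function(model_id, currency, category_dist, rom,
                             site_mix = 0.8, iva_surgery_rate = 1,
                             second_fnac_dist = NULL,
                             upfront_malignancy_rate = 0.25) {
  currency <- match.arg(currency, c("USD", "EUR"))
  if (is.null(second_fnac_dist)) second_fnac_dist <- category_dist
  problems <- c(
    check_category_prob(category_dist, "category_dist", must_sum = TRUE),
    check_category_prob(rom, "rom"),
    check_category_prob(second_fnac_dist, "second_fnac_dist", must_sum = TRUE),
    check_unit_interval(site_mix, "site_mix"),
    check_unit_interval(iva_surgery_rate, "iva_surgery_rate"),
    check_unit_interval(upfront_malignancy_rate, "upfront_malignancy_rate"))
  if (length(problems)) {
    stop("invalid model parameters: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  structure(list(model_id = as.character(model_id),
                 currency = currency,
                 category_dist = category_dist[milan_categories()],
                 rom = rom[milan_categories()],
                 site_mix = site_mix,
                 iva_surgery_rate = iva_surgery_rate,
                 second_fnac_dist = second_fnac_dist[milan_categories()],
                 upfront_malignancy_rate = upfront_malignancy_rate),
            class = "model_parameters")
}

#' Category-weighted mean risk of malignancy
#'
#' The malignancy prevalence implied by the FNAC-arm inputs,
#' \eqn{\sum_c P(c)\,\mathrm{ROM}(c)}. Available as an alternative value for
#' `upfront_malignancy_rate` when the two arms should share one prevalence.
#'
#' @param params A [model_parameters()] object.
#' @return A single probability.
#' @export
weighted_rom <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  sum(params$category_dist * params$rom)
}

# MSRSGC point estimates: midpoints of the published frequency ranges
# (open bounds "< x" -> x/2, "> x" -> midpoint of (x, 100)), renormalized.
msrsgc_estimate_dist <- function() {
  mid <- c(I = 15, II = 20, III = 5, IVa = 35, IVb = 5, V = 2.5, VI = 12.5)
  mid / sum(mid)
}

msrsgc_estimate_rom <- function() {
  c(I = 0.15, II = 0.11, III = 0.30, IVa = 0.015, IVb = 0.35,
    V = 0.83, VI = 0.99)
}

# real-world single-center cohort, n = 1289 with final histology
rwd_counts <- function() {
  c(I = 314, II = 182, III = 113, IVa = 501, IVb = 72, V = 54, VI = 53)
}

rwd_rom <- function() {
  c(I = 0.239, II = 0.044, III = 0.345, IVa = 0.010, IVb = 0.153,
    V = 0.741, VI = 0.962)
}

#' Built-in parameter sets for the three models
#'
#' * `"1a"`: MSRSGC point estimates, US tariffs. Category frequencies are the
#'   midpoints of the MSRSGC 2nd-edition ranges (an open bound `< x` is taken
#'   as `x/2`, `> x` as the midpoint of `(x, 100)`), renormalized to sum to 1;
#'   ROMs are the MSRSGC point values.
#' * `"1b"`: the same probabilities with German tariffs.
#' * `"1c"`: real-world category counts and ROMs from a single-center cohort
#'   of 1289 FNACs with final histology, German tariffs. Counts are used
#'   directly (314/182/113/501/72/54/53), so the distribution sums to 1
#'   without renormalization.
#'
#' The anatomic site mix defaults to 0.8 parotid in all sets, and the repeat
#' FNAC redistributes over the first-pass category distribution; neither
#' quantity is published, see the methods vignette for the rationale.
#'
#' @param model_id `"1a"`, `"1b"` or `"1c"`.
#' @return A [model_parameters()] object.
#' @export
#' @examples
#' p <- builtin_parameters("1c")
#' p$category_dist[["IVa"]]  # 501/1289
#' p$rom[["V"]]              # 0.741
builtin_parameters <- function(model_id) {
  valid <- c("1a", "1b", "1c")
  if (length(model_id) != 1 || !model_id %in% valid) {
    stop(sprintf("unknown model_id '%s'; valid ids: %s",
                 toString(model_id), paste(valid, collapse = ", ")),
         call. = FALSE)
  }
  if (model_id %in% c("1a", "1b")) {
    model_parameters(model_id,
                     currency = if (model_id == "1a") "USD" else "EUR",
                     category_dist = msrsgc_estimate_dist(),
                     rom = msrsgc_estimate_rom())
  } else {
    counts <- rwd_counts()
    model_parameters("1c", currency = "EUR",
                     category_dist = counts / sum(counts),
                     rom = rwd_rom())
  }
}

#' @export
print.cost_table <- function(x, ...) {
  cat(sprintf("Procedure cost table (%s)\n", x$currency))
  df <- data.frame(procedure = names(x$entries),
                   cost = unname(x$entries))
  if (!is.null(x$codes)) df$code <- unname(x$codes[names(x$entries)])
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat(sprintf("Model parameters '%s' (%s)\n", x$model_id, x$currency))
  df <- data.frame(category = milan_categories(),
                   frequency = round(unname(x$category_dist), 4),
                   rom = unname(x$rom),
                   second_fnac = round(unname(x$second_fnac_dist), 4))
  print(df, row.names = FALSE)
  cat(sprintf("site_mix (parotid): %.3g; IVa surgery rate: %.3g\n",
              x$site_mix, x$iva_surgery_rate))
  cat(sprintf("upfront malignancy rate: %.3g (weighted ROM: %.3g)\n",
              x$upfront_malignancy_rate, weighted_rom(x)))
  invisible(x)
}
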