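# Builders for the two strategy arms: upfront surgery, and FNAC followed by
# surgery if indicated. Pathway rules per category:
#   I, III -> one repeat FNAC; a second I/III result goes straight to
#             gland-conserving surgery (never a third FNAC)
#   II     -> clinical/radiological follow-up, no surgery
#   IVa    -> surgery with probability iva_surgery_rate, else follow-up
#   IVb    -> surgery
#   V, VI  -> surgery with intraoperative frozen section; a malignant frozen
#             section upgrades to the primary oncologic procedure
# Malignant histology after a gland-conserving excision sends the patient to
# the revision arm (completion neck dissection): the gland is already out, so
# only the neck dissection is billed on top.

#' Bind a parameter set to a tariff table
#'
#' Checks that the parameters and the cost table belong to the same
#' jurisdiction (currency) before any arm is built; mixed-currency arithmetic
#' is never performed.
#'
#' @param params A [model_parameters()] object.
#' @param costs A [cost_table()]; defaults to the built-in tariff for the
#'   parameter set's currency.
#' @return An object of class `arm_spec`.
#' @export
arm_spec <- function(params, costs = builtin_cost_table(params$currency)) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(costs, "cost_table"))
  if (!identical(params$currency, costs$currency)) {
    stop(sprintf("currency mismatch: parameters are %s but cost table is %s",
                 params$currency, costs$currency), call. = FALSE)
  }
  structure(list(params = params, costs = costs), class = "arm_spec")
}

# chance node that drops zero-probability branches; a single surviving branch
# is kept as a p = 1 pass-through
mk_chance <- function(label, cost, probs, nodes, tags = character()) {
  keep <- which(probs > 0)
  chance_node(label, cost,
              branches = Map(branch, probs[keep], nodes[keep]),
              tags = tags)
}

partial_label <- function(site) {
  if (site == "parotid") "partial_parotidectomy" else "submandibulectomy"
}

oncologic_label <- function(site) {
  if (site == "parotid") "total_parotidectomy_nd" else "submandibulectomy_nd"
}

# gland-conserving excision, then histology; malignancy triggers the revision
# arm (completion neck dissection appended to the already-performed excision)
surgery_with_revision <- function(site, rom, costs) {
  e <- costs$entries
  mk_chance(partial_label(site), e[[partial_label(site)]],
            probs = c(rom, 1 - rom),
            nodes = list(
              terminal_node("revision_neck_dissection",
                            e[["neck_dissection"]],
                            tags = c("surgery", "revision", "malignant")),
              terminal_node("benign_histology")),
            tags = "surgery")
}

# category V/VI surgery: frozen section arbitrates between the primary
# oncologic procedure and the gland-conserving excision
frozen_section_surgery <- function(site, rom, costs) {
  e <- costs$entries
  mk_chance("frozen_section", e[["frozen_section"]],
            probs = c(rom, 1 - rom),
            nodes = list(
              terminal_node(oncologic_label(site),
                            e[[oncologic_label(site)]],
                            tags = c("surgery", "malignant")),
              terminal_node(partial_label(site), e[[partial_label(site)]],
                            tags = "surgery")),
            tags = "frozen_section")
}

follow_up_node <- function(costs) {
  terminal_node("follow_up", costs$entries[["follow_up"]],
                tags = "follow_up")
}

iva_management <- function(site, params, costs, rate) {
  mk_chance("iva_management", 0,
            probs = c(rate, 1 - rate),
            nodes = list(
              surgery_with_revision(site, params$rom[["IVa"]], costs),
              follow_up_node(costs)))
}

# pathway taken once a (first- or second-pass) category is known;
# I/III only appear here on the first pass, where they trigger the repeat FNAC
category_pathway <- function(cat, site, params, costs, rate, first_pass) {
  if (cat %in% c("I", "III")) {
    if (!first_pass) {
      stop("internal error: I/III reached after the repeat FNAC")
    }
    return(repeat_fnac_pathway(site, params, costs, rate))
  }
  switch(cat,
         "II"  = follow_up_node(costs),
         "IVa" = iva_management(site, params, costs, rate),
         "IVb" = surgery_with_revision(site, params$rom[["IVb"]], costs),
         "V"   = frozen_section_surgery(site, params$rom[["V"]], costs),
         "VI"  = frozen_section_surgery(site, params$rom[["VI"]], costs))
}

repeat_fnac_pathway <- function(site, params, costs, rate) {
  cats <- milan_categories()
  q <- params$second_fnac_dist
  nodes <- lapply(cats, function(cat2) {
    inner <- if (cat2 %in% c("I", "III")) {
      # second inconclusive/atypical result: immediate surgery, risk of
      # malignancy of the second category
      surgery_with_revision(site, params$rom[[cat2]], costs)
    } else {
      category_pathway(cat2, site, params, costs, rate, first_pass = FALSE)
    }
    mk_chance(paste0("second_category_", cat2), 0, probs = 1,
              nodes = list(inner))
  })
  mk_chance("repeat_fnac", costs$entries[["repeat_fnac"]],
            probs = unname(q[cats]), nodes = nodes, tags = "fnac")
}

site_split <- function(params, make_subtree) {
  mk_chance("lesion", 0,
            probs = c(params$site_mix, 1 - params$site_mix),
            nodes = list(make_subtree("parotid"),
                         make_subtree("submandibular")))
}

#' Build the FNAC-first strategy arm
#'
#' Every patient receives an ultrasound-guided FNAC; the Milan category then
#' dictates the pathway (see the per-category rules in the package
#' documentation and methods vignette). Category I/III lesions get exactly one
#' repeat FNAC, whose result redistributes over `second_fnac_dist`; a repeat
#' I/III result goes straight to gland-conserving surgery.
#'
#' @param spec An [arm_spec()].
#' @param iva_surgery_rate Probability that a category IVa (benign neoplasm)
#'   lesion is resected; defaults to the rate stored in the parameters.
#' @return A validated [decision_tree()] with arm `"fnac_first"`.
#' @export
build_fnac_arm <- function(spec, iva_surgery_rate = NULL) {
  stopifnot(inherits(spec, "arm_spec"))
  params <- spec$params
  costs <- spec$costs
  rate <- iva_surgery_rate %||% params$iva_surgery_rate
  if (length(rate) != 1 || !is.finite(rate) || rate < 0 || rate > 1) {
    stop("iva_surgery_rate must be a single probability in [0, 1]",
         call. = FALSE)
  }
  cats <- milan_categories()
  fnac_subtree <- function(site) {
    cat_nodes <- lapply(cats, function(cat) {
      mk_chance(paste0("category_", cat), 0, probs = 1,
                nodes = list(category_pathway(cat, site, params, costs, rate,
                                              first_pass = TRUE)))
    })
    inner <- mk_chance("fnac", costs$entries[["fnac"]],
                       probs = unname(params$category_dist[cats]),
                       nodes = cat_nodes, tags = "fnac")
    mk_chance(site, 0, probs = 1, nodes = list(inner))
  }
  tree <- decision_tree(site_split(params, fnac_subtree),
                        currency = costs$currency,
                        model_id = params$model_id,
                        arm = "fnac_first",
                        iva_surgery_rate = rate)
  stop_if_invalid(tree)
}

#' Build the upfront-surgery strategy arm
#'
#' Every patient undergoes a site-appropriate gland-conserving excision with
#' intraoperative frozen section and no prior cytologic triage. With
#' probability `upfront_malignancy_rate` the histology is malignant and the
#' patient enters the revision arm: by default (`completion = "append"`) the
#' full oncologic procedure is billed on top of the initial excision (total
#' parotidectomy + neck dissection for parotid lesions; completion neck
#' dissection for submandibular lesions, whose gland is already excised).
#' `completion = "replace"` instead bills only the difference between the
#' oncologic bundle and the already-incurred excision, for sensitivity
#' analysis.
#'
#' @param spec An [arm_spec()].
#' @param completion `"append"` (default) or `"replace"`.
#' @return A validated [decision_tree()] with arm `"upfront_surgery"`.
#' @export
build_upfront_arm <- function(spec, completion = c("append", "replace")) {
  stopifnot(inherits(spec, "arm_spec"))
  completion <- match.arg(completion)
  params <- spec$params
  e <- spec$costs$entries
  m <- params$upfront_malignancy_rate
  completion_node <- function(site) {
    if (completion == "append") {
      if (site == "parotid") {
        terminal_node("total_parotidectomy_nd", e[["total_parotidectomy_nd"]],
                      tags = c("surgery", "revision", "malignant"))
      } else {
        terminal_node("revision_neck_dissection", e[["neck_dissection"]],
                      tags = c("surgery", "revision", "malignant"))
      }
    } else {
      top_up <- max(e[[oncologic_label(site)]] - e[[partial_label(site)]], 0)
      terminal_node(paste0("completion_", oncologic_label(site)), top_up,
                    tags = c("surgery", "revision", "malignant"))
    }
  }
  surgery_subtree <- function(site) {
    histology <- mk_chance("frozen_section", e[["frozen_section"]],
                           probs = c(m, 1 - m),
                           nodes = list(completion_node(site),
                                        terminal_node("benign_histology")),
                           tags = "frozen_section")
    excision <- mk_chance(partial_label(site), e[[partial_label(site)]],
                          probs = 1, nodes = list(histology),
                          tags = "surgery")
    mk_chance(site, 0, probs = 1, nodes = list(excision))
  }
  tree <- decision_tree(site_split(params, surgery_subtree),
                        currency = spec$costs$currency,
                        model_id = params$model_id,
                        arm = "upfront_surgery")
  stop_if_invalid(tree)
}

#' Derive a parameter set for a IVa management scenario
#'
#' Returns a copy of `params` identical except for `iva_surgery_rate`. The
#' base scenario resects all category IVa (benign neoplasm) lesions
#' (rate 1); the alternates resect 70% (the share of benign histotypes with a
#' documented propensity for malignant transformation) or none.
#'
#' @param params A [model_parameters()] object.
#' @param rate Probability in `[0, 1]`; conventional scenario values are
#'   1.0, 0.7 and 0.0.
#' @return A [model_parameters()] object.
#' @export
apply_iva_scenario <- function(params, rate) {
  stopifnot(inherits(params, "model_parameters"))
  if (length(rate) != 1 || !is.finite(rate) || rate < 0 || rate > 1) {
    stop("iva_surgery_rate: must be a single probability in [0, 1]",
         call. = FALSE)
  }
  params$iva_surgery_rate <- rate
  params
}

#' Convenience constructor for the built-in arms
#'
#' @param model_id `"1a"`, `"1b"` or `"1c"`.
#' @param arm `"fnac_first"` or `"upfront_surgery"`.
#' @param iva_surgery_rate IVa surgery rate for the FNAC arm.
#' @param ... Passed on to [build_upfront_arm()] (e.g. `completion`).
#' @return A [decision_tree()].
#' @export
#' @examples
#' tree <- builtin_arm("1b", "fnac_first", iva_surgery_rate = 0.7)
#' expected_cost(tree)
builtin_arm <- function(model_id, arm = c("fnac_first", "upfront_surgery"),
                        iva_surgery_rate = 1, ...) {
  arm <- match.arg(arm)
  spec <- arm_spec(builtin_parameters(model_id))
  if (arm == "fnac_first") {
    build_fnac_arm(spec, iva_surgery_rate = iva_surgery_rate)
  } else {
    build_upfront_arm(spec, ...)
  }
}
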