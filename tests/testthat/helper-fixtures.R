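# Shared fixtures: toy trees, degenerate parameter sets, random tree
# generator for oracle-equivalence checks.

toy_terminal <- function(cost = 100) terminal_node("end", cost)

# 50/50 split between a free and a costly outcome
toy_5050 <- function(lo = 0, hi = 100) {
  chance_node("flip", 0, list(branch(0.5, terminal_node("cheap", lo)),
                              branch(0.5, terminal_node("dear", hi))))
}

# partial parotidectomy with a 20% completion-surgery risk (US tariff):
# expectation 13316 + 0.2 * 18456 = 17007.2
toy_tariff <- function() {
  chance_node("partial_parotidectomy", 13316,
              list(branch(0.2, terminal_node("completion", 18456)),
                   branch(0.8, terminal_node("benign", 0))))
}

# parameters concentrated on one Milan category (EUR by default);
# rom values stay at the real-world ones unless overridden
degenerate_params <- function(cat, currency = "EUR", rom = NULL,
                              second_cat = cat, site_mix = 0.8,
                              iva_surgery_rate = 1) {
  dist <- stats::setNames(rep(0, 7), milan_categories())
  dist[cat] <- 1
  second <- stats::setNames(rep(0, 7), milan_categories())
  second[second_cat] <- 1
  if (is.null(rom)) rom <- builtin_parameters("1c")$rom
  model_parameters(paste0("degenerate_", cat), currency,
                   category_dist = dist, rom = rom, site_mix = site_mix,
                   iva_surgery_rate = iva_surgery_rate,
                   second_fnac_dist = second)
}

# random finite chance/terminal tree for property tests; uses current RNG
random_tree <- function(depth = 6, branch_max = 4) {
  if (depth == 0 || stats::runif(1) < 0.3) {
    return(terminal_node("leaf", stats::runif(1, 0, 1000)))
  }
  nb <- sample(2:branch_max, 1)
  w <- stats::runif(nb)
  p <- w / sum(w)
  chance_node("chance", stats::runif(1, 0, 1000),
              lapply(seq_len(nb), function(i) {
                branch(p[i], random_tree(depth - 1, branch_max))
              }))
}

# brute-force expectation via the path table (the enumeration oracle)
path_expectation <- function(tree) {
  pt <- enumerate_paths(tree)
  sum(pt$probability * pt$cost)
}
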