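# Strategy-arm construction: closed forms, pathway structure, monotonicity.

eur <- function() builtin_cost_table("EUR")
usd <- function() builtin_cost_table("USD")

test_that("parameters and tariffs must share a currency", {
  expect_error(arm_spec(builtin_parameters("1a"), eur()),
               "currency mismatch")
  expect_error(arm_spec(builtin_parameters("1b"), usd()),
               "currency mismatch")
})

test_that("upfront arm collapses to closed forms", {
  p <- builtin_parameters("1c")

  # no malignancy: expected cost is exactly the site-mixed excision tariff
  p0 <- model_parameters("t", "EUR", p$category_dist, p$rom,
                         site_mix = 0.8, upfront_malignancy_rate = 0)
  expect_equal(expected_cost(build_upfront_arm(arm_spec(p0))),
               0.8 * 5047.34 + 0.2 * 3808.19)

  # all-parotid: partial parotidectomy + m * completion oncologic procedure
  for (m in c(0.1, 0.25, 0.9)) {
    pp <- model_parameters("t", "USD", p$category_dist, p$rom,
                           site_mix = 1, upfront_malignancy_rate = m)
    expect_equal(expected_cost(build_upfront_arm(arm_spec(pp))),
                 13316 + m * 18456)
    # replacement mode bills only the tariff difference
    expect_equal(expected_cost(build_upfront_arm(arm_spec(pp),
                                                 completion = "replace")),
                 13316 + m * (18456 - 13316))
  }
})

test_that("degenerate category distributions reduce to single pathways", {
  # all category IVa, nobody operated: one FNAC then follow-up
  p_iva <- degenerate_params("IVa", iva_surgery_rate = 0)
  expect_equal(expected_cost(build_fnac_arm(arm_spec(p_iva))), 15.37)

  # all category II: the FNAC is the only cost
  p_ii <- degenerate_params("II")
  tree_ii <- build_fnac_arm(arm_spec(p_ii))
  expect_equal(expected_cost(tree_ii), 15.37)
  pt <- enumerate_paths(tree_ii)
  expect_true(all(grepl("follow_up", pt$path)))
  expect_false(any(grepl("parotidectomy|submandibulectomy", pt$path)))

  # category I whose repeat resolves to II: two FNACs, nothing else
  p_i_ii <- degenerate_params("I", second_cat = "II")
  expect_equal(expected_cost(build_fnac_arm(arm_spec(p_i_ii))), 2 * 15.37)

  # category I repeating as I: immediate surgery with ROM-driven revision
  p_i_i <- degenerate_params("I", second_cat = "I", site_mix = 1)
  expect_equal(expected_cost(build_fnac_arm(arm_spec(p_i_i))),
               2 * 15.37 + 5047.34 + 0.239 * 9864.74)
  pt <- enumerate_paths(build_fnac_arm(arm_spec(p_i_i)))
  expect_true(all(grepl("repeat_fnac", pt$path)))
  # never a third FNAC
  expect_true(all(vapply(strsplit(pt$path, " -> "), function(labels) {
    sum(labels %in% c("fnac", "repeat_fnac")) == 2
  }, logical(1))))

  # category V: every path passes through the frozen section
  p_v <- degenerate_params("V")
  pt <- enumerate_paths(build_fnac_arm(arm_spec(p_v)))
  expect_true(all(grepl("frozen_section", pt$path)))
  expect_true(any(grepl("total_parotidectomy_nd", pt$path)))
})

test_that("every built-in arm is structurally valid and conserves probability", {
  for (id in c("1a", "1b", "1c")) {
    spec <- arm_spec(builtin_parameters(id))
    trees <- c(list(build_upfront_arm(spec)),
               lapply(c(1, 0.7, 0), function(r) {
                 build_fnac_arm(spec, iva_surgery_rate = r)
               }))
    for (tree in trees) {
      expect_length(validate_tree(tree), 0)
      expect_equal(sum(enumerate_paths(tree)$probability), 1,
                   tolerance = 1e-9)
    }
  }
})

test_that("FNAC-first is analytically cheaper than upfront surgery in every built-in scenario", {
  for (id in c("1a", "1b", "1c")) {
    spec <- arm_spec(builtin_parameters(id))
    up <- expected_cost(build_upfront_arm(spec))
    for (rate in c(1, 0.7, 0)) {
      expect_lt(expected_cost(build_fnac_arm(spec, iva_surgery_rate = rate)),
                up)
    }
  }
})

test_that("FNAC-arm expected cost is strictly increasing in the IVa surgery rate", {
  spec <- arm_spec(builtin_parameters("1b"))
  costs <- vapply(seq(0, 1, by = 0.2), function(r) {
    expected_cost(build_fnac_arm(spec, iva_surgery_rate = r))
  }, numeric(1))
  expect_true(all(diff(costs) > 0))
})

test_that("FNAC-arm expected cost responds monotonically to ROM and tariff perturbations", {
  p <- builtin_parameters("1b")
  spec <- arm_spec(p)
  base <- expected_cost(build_fnac_arm(spec))

  up_rom <- p
  up_rom$rom <- pmin(p$rom * 1.2, 1)
  down_rom <- p
  down_rom$rom <- p$rom * 0.8
  expect_gte(expected_cost(build_fnac_arm(arm_spec(up_rom))), base)
  expect_lte(expected_cost(build_fnac_arm(arm_spec(down_rom))), base)

  dear <- cost_table("EUR", eur()$entries * 1.2)
  cheap <- cost_table("EUR", eur()$entries * 0.8)
  expect_gte(expected_cost(build_fnac_arm(arm_spec(p, dear))), base)
  expect_lte(expected_cost(build_fnac_arm(arm_spec(p, cheap))), base)

  # single-entry perturbation: a dearer neck dissection can only raise cost
  entries <- eur()$entries
  entries[["neck_dissection"]] <- entries[["neck_dissection"]] * 1.2
  expect_gte(expected_cost(build_fnac_arm(arm_spec(p, cost_table("EUR",
                                                                 entries)))),
             base)
})

test_that("IVa scenarios change only the surgery rate", {
  p <- builtin_parameters("1c")
  for (rate in c(1, 0.7, 0)) {
    q <- apply_iva_scenario(p, rate)
    expect_equal(q$iva_surgery_rate, rate)
    q$iva_surgery_rate <- p$iva_surgery_rate
    expect_equal(q, p)
  }
  expect_error(apply_iva_scenario(p, 1.3), "iva_surgery_rate")
  expect_error(build_fnac_arm(arm_spec(p), iva_surgery_rate = -0.1),
               "iva_surgery_rate")
})
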