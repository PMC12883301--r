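# Built-in tariff and probability tables, and input validation.

test_that("built-in tariff tables match the published fee schedules cell for cell", {
  usd <- builtin_cost_table("USD")
  expect_identical(usd$currency, "USD")
  expect_equal(usd$entries[c("partial_parotidectomy", "submandibulectomy",
                             "total_parotidectomy_nd", "submandibulectomy_nd",
                             "neck_dissection", "fnac")],
               c(partial_parotidectomy = 13316, submandibulectomy = 8707,
                 total_parotidectomy_nd = 18456, submandibulectomy_nd = 24103,
                 neck_dissection = 15396, fnac = 141))
  eur <- builtin_cost_table("EUR")
  expect_equal(eur$entries[c("partial_parotidectomy", "submandibulectomy",
                             "total_parotidectomy_nd", "submandibulectomy_nd",
                             "neck_dissection", "fnac")],
               c(partial_parotidectomy = 5047.34, submandibulectomy = 3808.19,
                 total_parotidectomy_nd = 11931.02,
                 submandibulectomy_nd = 11931.02,
                 neck_dissection = 9864.74, fnac = 15.37))
  # unpriced supplementary items default to zero / the FNAC tariff
  for (tab in list(usd, eur)) {
    expect_identical(unname(tab$entries[["frozen_section"]]), 0)
    expect_identical(unname(tab$entries[["follow_up"]]), 0)
    expect_identical(tab$entries[["repeat_fnac"]], tab$entries[["fnac"]])
  }
})

test_that("real-world parameter set reproduces the published cohort table", {
  p <- builtin_parameters("1c")
  counts <- c(I = 314, II = 182, III = 113, IVa = 501, IVb = 72,
              V = 54, VI = 53)
  expect_equal(p$category_dist, counts / 1289)
  # published percentages (which sum to 99.5 from rounding) agree after
  # renormalization
  expect_equal(unname(p$category_dist[["IVa"]]), 0.387, tolerance = 0.005)
  expect_equal(p$rom,
               c(I = 0.239, II = 0.044, III = 0.345, IVa = 0.010,
                 IVb = 0.153, V = 0.741, VI = 0.962))
  expect_identical(p$currency, "EUR")
})

test_that("MSRSGC-estimate sets use renormalized range midpoints", {
  # independent mini-oracle: midpoints with open bounds halved / centered
  mid <- c(I = (10 + 20) / 2, II = (15 + 25) / 2, III = 10 / 2,
           IVa = (30 + 40) / 2, IVb = 10 / 2, V = 5 / 2,
           VI = (10 + 15) / 2)
  for (id in c("1a", "1b")) {
    p <- builtin_parameters(id)
    expect_equal(p$category_dist, mid / sum(mid))
    expect_equal(p$rom,
                 c(I = 0.15, II = 0.11, III = 0.30, IVa = 0.015,
                   IVb = 0.35, V = 0.83, VI = 0.99))
  }
  expect_identical(builtin_parameters("1a")$currency, "USD")
  expect_identical(builtin_parameters("1b")$currency, "EUR")
})

test_that("all built-in distributions satisfy the probability invariants", {
  for (id in c("1a", "1b", "1c")) {
    p <- builtin_parameters(id)
    expect_lt(abs(sum(p$category_dist) - 1), 1e-9)
    expect_lt(abs(sum(p$second_fnac_dist) - 1), 1e-9)
    expect_true(all(p$rom >= 0 & p$rom <= 1))
    expect_true(p$site_mix >= 0 && p$site_mix <= 1)
    expect_true(p$upfront_malignancy_rate >= 0 &&
                  p$upfront_malignancy_rate <= 1)
  }
})

test_that("unknown model ids are rejected with the list of valid ids", {
  expect_error(builtin_parameters("2x"), "1a, 1b, 1c")
  expect_error(builtin_cost_table("GBP"))
})

test_that("validation rejects malformed inputs naming the offending field", {
  p <- builtin_parameters("1c")
  bad_dist <- p$category_dist * 0.8
  expect_error(
    model_parameters("x", "EUR", bad_dist, p$rom),
    "category_dist")
  bad_rom <- p$rom
  bad_rom[["VI"]] <- 1.2
  expect_error(
    model_parameters("x", "EUR", p$category_dist, bad_rom),
    "rom\\.VI")
  expect_error(
    model_parameters("x", "EUR", p$category_dist, p$rom, site_mix = 1.5),
    "site_mix")
  expect_error(
    model_parameters("x", "EUR", p$category_dist[-4], p$rom),
    "missing categories IVa")
  expect_error(
    cost_table("EUR", c(builtin_cost_table("EUR")$entries[-6],
                        fnac = -1)),
    "entries\\.fnac")
})

test_that("weighted ROM is the frequency-weighted mean risk of malignancy", {
  p <- degenerate_params("VI")
  expect_equal(weighted_rom(p), unname(p$rom[["VI"]]))
  p3 <- builtin_parameters("1c")
  expect_equal(weighted_rom(p3), sum(p3$category_dist * p3$rom))
})
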