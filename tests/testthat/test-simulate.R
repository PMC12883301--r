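# Monte Carlo simulation: determinism, reproducibility, trajectory
# invariants, arm comparison arithmetic, convergence diagnostics.

test_that("a degenerate tree simulates deterministically", {
  line <- chance_node("a", 10, list(branch(1, terminal_node("b", 32))))
  s <- simulate_tree(line, n = 50, seed = 3)
  expect_equal(s$mean, 42)
  expect_equal(s$sd, 0)
  set.seed(99)
  t1 <- sample_trajectory(line)
  t2 <- sample_trajectory(line)
  expect_identical(t1, t2)
  expect_identical(t1$events, c("a", "b"))
})

test_that("the same seed reproduces the cohort bit for bit", {
  tree <- builtin_arm("1c", "fnac_first", iva_surgery_rate = 0.7)
  s1 <- simulate_tree(tree, n = 500, seed = 123, keep_trajectories = TRUE)
  s2 <- simulate_tree(tree, n = 500, seed = 123, keep_trajectories = TRUE)
  expect_identical(s1$costs, s2$costs)
  expect_identical(s1$trajectories, s2$trajectories)
  s3 <- simulate_tree(tree, n = 500, seed = 124)
  expect_false(identical(s1$costs, s3$costs))
})

test_that("a 50/50 cost split converges to the binomial expectation", {
  s <- simulate_tree(toy_5050(), n = 10000, seed = 7)
  se <- 50 / sqrt(10000)  # closed-form binomial se for costs {0, 100}
  expect_lt(abs(s$mean - 50), 3.5 * se)
  expect_equal(s$se, s$sd / sqrt(s$n))
  expect_true(s$q025 <= s$median && s$median <= s$q975)
})

test_that("trajectory costs and flags are consistent with the path table", {
  tree <- builtin_arm("1b", "fnac_first", iva_surgery_rate = 0.7)
  pt <- enumerate_paths(tree)
  cost_of <- stats::setNames(pt$cost, pt$path)
  s <- simulate_tree(tree, n = 400, seed = 11, keep_trajectories = TRUE)
  for (tr in s$trajectories) {
    path <- paste(tr$events, collapse = " -> ")
    expect_true(path %in% names(cost_of))
    expect_equal(tr$total_cost, unname(cost_of[[path]]))
  }
  expect_true(all(s$costs >= 0))
  # FNAC arm: one or two FNACs, never more (single repeat rule)
  expect_true(all(s$n_fnac %in% c(1L, 2L)))

  up <- simulate_tree(builtin_arm("1b", "upfront_surgery"), n = 400,
                      seed = 11, keep_trajectories = TRUE)
  expect_true(all(up$n_fnac == 0L))
  expect_true(all(up$n_surgeries >= 1L))
})

test_that("malignant-tagged paths set the malignancy flag", {
  tree <- builtin_arm("1c", "fnac_first", iva_surgery_rate = 1)
  s <- simulate_tree(tree, n = 600, seed = 21, keep_trajectories = TRUE)
  revised <- vapply(s$trajectories, function(tr) {
    any(grepl("revision_neck_dissection|total_parotidectomy_nd|submandibulectomy_nd",
              tr$events))
  }, logical(1))
  expect_identical(s$is_malignant, revised)
})

test_that("cost-reduction arithmetic truncates toward zero", {
  r <- reduction_from_means(17472, 11866)
  expect_equal(r$absolute_saving, 5606)
  expect_identical(r$percent_saving_truncated, 32)
  # 39.82% truncates to 39 where rounding would give 40
  r <- reduction_from_means(8018, 4825)
  expect_identical(r$percent_saving_truncated, 39)
  expect_gt(r$percent_saving, 39.5)
  r <- reduction_from_means(5000, 5000)
  expect_identical(r$percent_saving_truncated, 0)
  expect_equal(r$absolute_saving, 0)
})

test_that("arm comparison refuses mismatched currencies or models", {
  up_usd <- simulate_tree(builtin_arm("1a", "upfront_surgery"), n = 50,
                          seed = 1)
  fn_eur <- simulate_tree(builtin_arm("1b", "fnac_first"), n = 50, seed = 1)
  expect_error(compare_arms(up_usd, fn_eur), "currencies")
  up_1b <- simulate_tree(builtin_arm("1b", "upfront_surgery"), n = 50,
                         seed = 1)
  fn_1c <- simulate_tree(builtin_arm("1c", "fnac_first"), n = 50, seed = 1)
  expect_error(compare_arms(up_1b, fn_1c), "models")
  red <- compare_arms(up_1b, simulate_tree(builtin_arm("1b", "fnac_first"),
                                           n = 50, seed = 2))
  expect_equal(red$absolute_saving, red$upfront_mean - red$fnac_mean)
})

test_that("the convergence diagnostic passes honest runs and flags wrong expectations", {
  tree <- builtin_arm("1b", "fnac_first", iva_surgery_rate = 1)
  s <- simulate_tree(tree, n = 10000, seed = 31)
  expect_true(convergence_check(tree, s)$pass)

  # negative control: pretend the cohort came from a tree twice as expensive
  wrong <- map_tree_costs(tree, function(cost) 2 * cost)
  expect_false(convergence_check(wrong, s)$pass)

  line <- chance_node("a", 10, list(branch(1, terminal_node("b", 32))))
  d <- convergence_check(line, simulate_tree(line, n = 20, seed = 1))
  expect_equal(d$z, 0)
  expect_true(d$pass)
})

test_that("cohort size is validated and trajectories export to CSV", {
  tree <- builtin_arm("1b", "fnac_first")
  expect_error(simulate_tree(tree, n = 0, seed = 1), "n must be >= 1")
  s <- simulate_tree(tree, n = 25, seed = 2, keep_trajectories = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  export_trajectories(s, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), 25)
  expect_equal(df$cost, s$costs)
  s2 <- simulate_tree(tree, n = 5, seed = 2)
  expect_error(export_trajectories(s2, path), "keep_trajectories")
})
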