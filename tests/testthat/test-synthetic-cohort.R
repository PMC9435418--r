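test_that("cohort_config validates its inputs", {
  expect_error(cohort_config(n_nurses = 0), "positive")
  expect_error(cohort_config(missing_rate = 1), "\\[0, 1\\)")
  expect_error(cohort_config(target_marginals = list(exposure = c(0.5, 0.4))),
               "exposure")
})

test_that("the default truth network hits the published category marginals", {
  net <- make_truth_network(cohort_config())$network
  marg <- list(
    exposure = c(47, 126, 36) / 209,
    sensitivity = c(59, 93, 57) / 209,
    annoyance = c(61, 104, 44) / 209,
    quality = c(19, 97, 93) / 209
  )
  for (v in names(marg))
    expect_equal(as.numeric(infer_posterior(net, v)), marg[[v]], tolerance = 1e-6)
})

test_that("the published-CPT option exposes the printed quality rows", {
  truth <- make_truth_network(cohort_config(quality_cpt = "table3"))
  arr <- truth$network$cpts$quality
  # (high exposure, high sensitivity, moderate annoyance) -> (0, 0, 1)
  expect_equal(as.numeric(arr[, 3, 3, 2]), c(0, 0, 1))
  # uniform-CPT truth samples each state about equally often
  uni <- bn_network(list(a = c("s1", "s2", "s3")), cpts = list(a = rep(1 / 3, 3)))
  tab <- prop.table(table(sample_cohort(uni, 6000, seed = 8)$a))
  expect_equal(as.numeric(tab), rep(1 / 3, 3), tolerance = 0.03)
})

test_that("ancestral sampling is seeded, exact for n = 1, and matches the CPT", {
  net <- two_node_net(p_parent = 0.5, p_child_given = c(x = 0.7, y = 0.2))
  a <- sample_cohort(net, 200, seed = 9)
  b <- sample_cohort(net, 200, seed = 9)
  expect_identical(a, b)
  one <- sample_cohort(net, 1, seed = 10)
  expect_equal(nrow(one), 1L)
  expect_true(as.character(one$parent) %in% c("x", "y"))
  expect_true(as.character(one$child) %in% c("a", "b"))

  big <- sample_cohort(net, 5000, seed = 11)
  nx <- sum(big$parent == "x")
  emp <- mean(big$child[big$parent == "x"] == "a")
  se <- sqrt(0.7 * 0.3 / nx)          # binomial sampling error
  expect_lt(abs(emp - 0.7), 3 * se)
})

test_that("sampled conditional frequencies converge to the truth CPT", {
  truth <- make_truth_network(cohort_config(seed = 3))
  d <- sample_cohort(truth, 6000, seed = 12)
  arr <- truth$network$cpts$sensitivity
  for (ie in 1:3) {
    sel <- d$exposure == levels(d$exposure)[ie]
    if (sum(sel) < 150) next
    emp <- as.numeric(prop.table(table(d$sensitivity[sel])))
    tv <- 0.5 * sum(abs(emp - arr[, ie]))
    expect_lt(tv, 0.03)
  }
})

test_that("item expansion re-scores to the assigned categories", {
  truth <- make_truth_network(cohort_config(seed = 13))
  coh <- sample_cohort(truth, 500, seed = 13)
  ex <- suppressWarnings(expand_to_items(coh, seed = 14))
  sc <- score_cohort(ex)
  for (v in c("sensitivity", "annoyance", "quality",
              "psychosocial", "communicational", "physical"))
    expect_equal(as.character(sc[[v]]), as.character(ex[[v]]))

  # fixed-cut-off scales honour the assigned band
  des <- which(as.character(ex$quality) == "desirable")
  expect_true(all(sc$qpcs_total[des] >= 196 & sc$qpcs_total[des] <= 260))
  und <- which(as.character(ex$physical) == "undesirable")
  expect_true(all(sc$physical_score[und] < 48))

  # percentile scales sit strictly on the right side of the sample quartiles
  q <- quantile(sc$sensitivity_score, c(0.25, 0.75), type = 7)
  expect_true(all(sc$sensitivity_score[sc$sensitivity == "low"] < q[1]))
  expect_true(all(sc$sensitivity_score[sc$sensitivity == "high"] > q[2]))

  # determinism
  ex2 <- suppressWarnings(expand_to_items(coh, seed = 14))
  expect_identical(ex[, names(ex)], ex2[, names(ex2)])
})

test_that("the simulated noise environment reproduces exposure categories", {
  truth <- make_truth_network(cohort_config(seed = 15))
  coh <- sample_cohort(truth, 120, seed = 15)
  env <- simulate_noise_environment(coh, n_points = 300, seed = 16)
  expect_equal(nrow(env$grid), 300L * 10L)
  nm <- build_noise_map(env$grid)
  expect_equal(nrow(nm), 300L)
  expo <- nurse_exposure(nm, env$assignments)
  m <- match(coh$nurse_id, expo$nurse_id)
  expect_equal(as.character(expo$category[m]), as.character(coh$exposure))

  # zero within-point variance makes all repeats identical
  env0 <- simulate_noise_environment(coh[1:10, ], n_points = 60, seed = 17,
                                     repeat_sd = 0)
  spread <- tapply(env0$grid$leq_db, env0$grid$point_id,
                   function(x) diff(range(x)))
  expect_true(all(spread == 0))
})

test_that("MCAR injection hits the requested rate and is reproducible", {
  truth <- make_truth_network(cohort_config(seed = 18))
  coh <- sample_cohort(truth, 209, seed = 18)
  cols <- study_nodes()
  expect_identical(inject_missing(coh, 0, seed = 19), coh)
  m1 <- inject_missing(coh, 0.1, seed = 19)
  m2 <- inject_missing(coh, 0.1, seed = 19)
  expect_identical(m1, m2)
  frac <- mean(is.na(as.matrix(m1[, cols])))
  expect_equal(frac, 0.1, tolerance = 0.02)
  expect_error(inject_missing(coh, 1), "\\[0, 1\\)")
})
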