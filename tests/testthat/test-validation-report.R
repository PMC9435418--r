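test_that("k-fold assignment is exhaustive, near-equal and seeded", {
  f <- kfold_split(209, 10, seed = 1)
  expect_equal(length(f), 209L)
  sizes <- as.numeric(table(f))
  expect_equal(sort(sizes), c(20, rep(21, 9)))
  expect_identical(kfold_split(209, 10, seed = 1), f)
  expect_false(identical(kfold_split(209, 10, seed = 2), f))

  expect_equal(as.numeric(table(kfold_split(10, 10, seed = 3))), rep(1, 10))
  expect_error(kfold_split(5, 10), "cannot split")
  expect_error(kfold_split(20, 1), ">= 2")

  # stratified folds keep every class in every fold when feasible
  strata <- rep(c("a", "b", "c"), times = c(40, 40, 40))
  fs <- kfold_split(120, 4, seed = 4, strata = strata)
  expect_true(all(table(strata, fs) == 10))
})

test_that("classification metrics follow the macro one-vs-rest definitions", {
  ident <- diag(c(5, 7, 9))
  m <- classification_metrics(ident)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, 1)

  hand <- rbind(c(5, 0, 0), c(0, 0, 5), c(0, 0, 5))
  mh <- classification_metrics(hand)
  expect_equal(mh$accuracy, 10 / 15)
  expect_equal(mh$sensitivity, mean(c(1, 0, 1)))
  # class-permutation invariance of the scalar metrics
  p <- c(3, 1, 2)
  mp <- classification_metrics(hand[p, p])
  expect_equal(mp$accuracy, mh$accuracy)
  expect_equal(mp$sensitivity, mh$sensitivity)
  expect_equal(mp$specificity, mh$specificity)
  expect_error(classification_metrics(matrix(0, 2, 3)), "square")
})

test_that("one-vs-rest AUC has the right limits, null level and negation symmetry", {
  lab <- rep(c("pos", "neg"), each = 50)
  sc <- c(seq(0.6, 1, length.out = 50), seq(0, 0.4, length.out = 50))
  post <- cbind(pos = sc, neg = 1 - sc)
  r <- roc_auc(post, lab)
  expect_equal(unname(r$per_class["pos"]), 1)
  expect_equal(unname(r$per_class["neg"]), 1)

  r_anti <- roc_auc(cbind(pos = 1 - sc, neg = sc), lab)
  expect_equal(unname(r_anti$per_class["pos"]), 0)

  set.seed(23)
  lab2 <- rep(c("pos", "neg"), 1000)
  sc2 <- runif(2000)
  r2 <- roc_auc(cbind(pos = sc2, neg = 1 - sc2), lab2)
  expect_equal(unname(r2$per_class["pos"]), 0.5, tolerance = 0.03)
  # AUC(score) = 1 - AUC(-score) for the same positive class
  a1 <- roc_auc(cbind(pos = sc2, neg = 1 - sc2), lab2)$per_class[["pos"]]
  a2 <- roc_auc(cbind(pos = -sc2, neg = sc2), lab2)$per_class[["pos"]]
  expect_equal(a1, 1 - a2, tolerance = 1e-12)

  expect_warning(roc_auc(cbind(pos = sc2, other = sc2), lab2), "no positives")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(29)
  lab <- sample(c("yes", "no"), 300, replace = TRUE)
  sc <- runif(300) + 0.4 * (lab == "yes")
  ours <- roc_auc(cbind(yes = sc, no = -sc), lab)$per_class[["yes"]]
  ref <- as.numeric(pROC::auc(pROC::roc(response = lab, predictor = sc,
                                        levels = c("no", "yes"), quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("cross-validation is perfect on a deterministic target and chance on noise", {
  # target copies the feature deterministically
  copy <- bn_network(
    list(f = c("s1", "s2", "s3"), t = c("s1", "s2", "s3")),
    parents = list(t = "f"),
    cpts = list(f = rep(1 / 3, 3), t = diag(3))
  )
  d <- sample_cohort(copy, 200, seed = 24)[, c("f", "t")]
  cv <- cross_validate(d, bn_network(copy$variables, copy$parents), "t",
                       k = 5, seed = 25)
  expect_equal(cv$metrics$accuracy, 1)
  expect_equal(sum(cv$confusion), nrow(d))

  # independent target, balanced classes: accuracy near 1/3
  ind <- bn_network(
    list(f = c("s1", "s2", "s3"), t = c("s1", "s2", "s3")),
    cpts = list(f = rep(1 / 3, 3), t = rep(1 / 3, 3))
  )
  d2 <- sample_cohort(ind, 900, seed = 26)[, c("f", "t")]
  cv2 <- cross_validate(d2, bn_network(ind$variables, ind$parents), "t",
                        k = 5, seed = 27)
  expect_lt(abs(cv2$metrics$accuracy - 1 / 3), 0.06)

  # reproducibility: identical seed, identical report
  cv3 <- cross_validate(d2, bn_network(ind$variables, ind$parents), "t",
                        k = 5, seed = 27)
  expect_identical(cv2$confusion, cv3$confusion)
  expect_identical(cv2$posteriors, cv3$posteriors)
})

test_that("accuracy never exceeds the best per-class recall", {
  set.seed(30)
  for (i in 1:10) {
    m <- matrix(rpois(9, 8), 3)
    met <- classification_metrics(m)
    expect_lte(met$accuracy, max(met$recall_per_class, na.rm = TRUE) + 1e-12)
  }
})

test_that("generate_report writes a structurally valid bundle", {
  out <- file.path(tempdir(), "nc_report_test")
  res <- generate_report(out, n = 80, seed = 42, k = 5, n_points = 250)
  files <- c("category_summary.csv", "quality_cpt.csv",
             "sensitivity_scenarios.csv", "sensitivity_scenarios.json",
             "influence_ranking.csv", "validation.csv", "validation.json",
             "report.json", "run_log.txt")
  for (f in files) expect_true(file.exists(file.path(out, f)), info = f)

  summ <- read.csv(file.path(out, "category_summary.csv"))
  # percentages sum to 100 per variable and frequencies to n
  for (v in unique(summ$variable)) {
    expect_equal(sum(summ$percent[summ$variable == v]), 100, tolerance = 0.11)
    expect_equal(sum(summ$frequency[summ$variable == v]), 80)
  }
  scen <- read.csv(file.path(out, "sensitivity_scenarios.csv"))
  expect_equal(length(unique(scen$scenario)), 8L)
  infl <- read.csv(file.path(out, "influence_ranking.csv"))
  expect_equal(nrow(infl), 15L)
  val <- jsonlite::fromJSON(file.path(out, "validation.json"))
  expect_true(val$accuracy >= 0 && val$accuracy <= 1)
  total <- sum(unlist(val$confusion))
  expect_true(total > 0 && total <= 80)  # records with an observed target
  expect_equal(length(res$validation$folds), 80L)
  unlink(out, recursive = TRUE)
})
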