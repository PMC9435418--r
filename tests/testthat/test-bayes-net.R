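test_that("network construction validates states, parents, cycles and CPT rows", {
  expect_error(bn_network(list(a = "only_one_state")), "2 unique")
  expect_error(bn_network(list(a = c("x", "y")), parents = list(a = "b")),
               "undeclared parent")
  expect_error(bn_network(list(a = c("x", "y"), b = c("x", "y")),
                          parents = list(a = "b", b = "a")), "cycle")
  expect_error(
    bn_network(list(a = c("x", "y")), cpts = list(a = c(0.5, 0.6))),
    "'a'.*sum to 1"
  )
})

test_that("the study structure has the 15 published parent-child arcs", {
  net <- build_study_network()
  arcs <- do.call(rbind, lapply(names(net$parents), function(v) {
    if (length(net$parents[[v]]))
      data.frame(parent = net$parents[[v]], child = v)
  }))
  expect_equal(nrow(arcs), 15L)
  published <- rbind(
    c("exposure", "annoyance"), c("physical", "quality"),
    c("communicational", "quality"), c("psychosocial", "quality"),
    c("sensitivity", "annoyance"), c("annoyance", "physical"),
    c("exposure", "psychosocial"), c("annoyance", "psychosocial"),
    c("annoyance", "communicational"), c("exposure", "communicational"),
    c("sensitivity", "communicational"), c("exposure", "physical"),
    c("sensitivity", "physical"), c("exposure", "sensitivity"),
    c("sensitivity", "psychosocial")
  )
  for (i in seq_len(nrow(published)))
    expect_true(any(arcs$parent == published[i, 1] & arcs$child == published[i, 2]),
                info = paste(published[i, ], collapse = " -> "))
  # acyclic by construction (topological order exists over all nodes)
  expect_equal(sort(net$order), sort(names(net$variables)))
})

test_that("joint_probability is the product of selected CPT entries", {
  one <- bn_network(list(a = c("s1", "s2")), cpts = list(a = c(0.2, 0.8)))
  expect_equal(joint_probability(one, c(a = "s1")), 0.2)
  net <- chain_net()
  # hand product: 0.3 * 0.8 * 0.9
  expect_equal(joint_probability(net, c(a = "a1", b = "b1", c = "c1")), 0.216)
  expect_equal(joint_probability(net, c(a = "a2", b = "b1", c = "c2")),
               0.7 * 0.4 * 0.1)
  expect_error(joint_probability(net, c(a = "a1")), "missing")
})

test_that("posteriors from the published-CPT fixture equal the printed rows", {
  net <- read_network(table3_network_path())
  p <- infer_posterior(net, "quality",
                       c(exposure = "low", sensitivity = "moderate", annoyance = "low"))
  expect_equal(as.numeric(p), c(0.167, 0.083, 0.750), tolerance = 1e-12)
  p <- infer_posterior(net, "quality",
                       c(exposure = "moderate", sensitivity = "high", annoyance = "low"))
  expect_equal(as.numeric(p), c(0.500, 0.500, 0.000), tolerance = 1e-12)
})

test_that("variable elimination equals brute-force enumeration on random nets", {
  for (s in 1:40) {
    net <- random_network(n_nodes = 3 + (s %% 5), seed = 1000 + s)
    nodes <- names(net$variables)
    q <- nodes[1 + (s %% length(nodes))]
    ev <- NULL
    if (s %% 3 != 0) {
      evn <- setdiff(nodes, q)[1:min(2, length(nodes) - 1)]
      ev <- vapply(evn, function(v) net$variables[[v]][1 + (s %% 3)], "")
    }
    p_ve <- infer_posterior(net, q, ev)
    p_en <- enum_posterior(net, q, ev)
    expect_equal(as.numeric(p_ve), p_en, tolerance = 1e-9)
    expect_equal(sum(p_ve), 1, tolerance = 1e-9)
  }
})

test_that("no evidence returns the prior and impossible evidence errors", {
  one <- bn_network(list(a = c("s1", "s2")), cpts = list(a = c(0.25, 0.75)))
  expect_equal(as.numeric(infer_posterior(one, "a")), c(0.25, 0.75))
  det <- bn_network(
    list(a = c("x", "y"), b = c("x", "y")), parents = list(b = "a"),
    cpts = list(a = c(1, 0), b = matrix(c(1, 0, 0, 1), 2))
  )
  expect_error(infer_posterior(det, "a", c(b = "y")), "impossible evidence")
  expect_error(infer_posterior(det, "a", c(a = "x")), "part of the evidence")
})

test_that("map_predict takes the argmax with state-order tie-breaking", {
  tri <- bn_network(list(a = c("s1", "s2", "s3")),
                    cpts = list(a = c(0.1, 0.3, 0.6)))
  expect_equal(map_predict(tri, "a"), "s3")
  tie <- bn_network(list(a = c("s1", "s2", "s3")),
                    cpts = list(a = c(0.5, 0.5, 0)))
  expect_equal(map_predict(tie, "a"), "s1")
  copy <- bn_network(
    list(f = c("x", "y"), t = c("x", "y")), parents = list(t = "f"),
    cpts = list(f = c(0.5, 0.5), t = matrix(c(1, 0, 0, 1), 2))
  )
  for (s in c("x", "y")) expect_equal(map_predict(copy, "t", c(f = s)), s)
})

test_that("JSON round-trip preserves the network and rejects invalid rows", {
  net <- build_study_network(fitted = TRUE)
  path <- tempfile(fileext = ".json")
  write_network(net, path)
  net2 <- read_network(path)
  expect_equal(net2$variables, net$variables)
  expect_equal(net2$parents[order(names(net2$parents))],
               net$parents[order(names(net$parents))])
  for (v in names(net$variables))
    expect_equal(as.numeric(net2$cpts[[v]]), as.numeric(net$cpts[[v]]),
                 tolerance = 1e-12)

  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    variables = list(list(name = "a", states = c("x", "y"))),
    cpts = list(list(child = "a", parents = character(0),
                     rows = list(list(config = character(0), p = c(0.5, 0.6)))))
  ), bad, auto_unbox = TRUE)
  expect_error(read_network(bad), "sum to 1")
})

test_that("EM on complete data returns conditional relative frequencies", {
  net <- two_node_net(p_parent = 0.6, p_child_given = c(x = 0.7, y = 0.2))
  d <- sample_cohort(net, 2000, seed = 21)[, c("parent", "child")]
  fit <- em_learn(bn_network(net$variables, net$parents), d, seed = 1)
  # counting oracle
  freq <- prop.table(table(d$child, d$parent), margin = 2)
  expect_equal(as.numeric(fit$cpts$child), as.numeric(freq), tolerance = 1e-12)
  expect_equal(as.numeric(fit$cpts$parent),
               as.numeric(prop.table(table(d$parent))), tolerance = 1e-12)
  expect_true(attr(fit, "em_converged"))
})

test_that("EM gives unseen parent configurations the uniform row", {
  struct <- bn_network(list(p = c("low", "moderate", "high"),
                            c = c("low", "moderate", "high")),
                       parents = list(c = "p"))
  d <- data.frame(p = rep(c("low", "moderate"), each = 10),
                  c = rep(c("low", "high"), 10))
  fit <- em_learn(struct, d, seed = 2)
  expect_equal(as.numeric(fit$cpts$c[, 3]), rep(1 / 3, 3))  # p = "high" never seen
})

test_that("EM log-likelihood is monotone on incomplete data and order invariant", {
  truth <- two_node_net(p_parent = 0.4, p_child_given = c(x = 0.85, y = 0.3))
  d <- sample_cohort(truth, 400, seed = 31)[, c("parent", "child")]
  d <- inject_missing(d, 0.25, seed = 32, columns = c("parent", "child"))
  struct <- bn_network(truth$variables, truth$parents)
  fit <- em_learn(struct, d, seed = 3)
  ll <- attr(fit, "em_loglik")
  expect_gte(length(ll), 2L)
  expect_true(all(diff(ll) >= -1e-8))

  # complete-data fits are invariant to record order
  dc <- sample_cohort(truth, 300, seed = 33)[, c("parent", "child")]
  f1 <- em_learn(struct, dc, seed = 4)
  f2 <- em_learn(struct, dc[rev(seq_len(nrow(dc))), ], seed = 4)
  expect_equal(f1$cpts, f2$cpts, tolerance = 1e-12)
})

test_that("EM recovers known parameters from a complete synthetic cohort", {
  truth <- make_truth_network(cohort_config(seed = 5))
  d <- sample_cohort(truth, 3000, seed = 51)[, study_nodes()]
  fit <- em_learn(build_study_network(), d, seed = 6)
  # well-sampled rows of the annoyance CPT (parents exposure x sensitivity)
  counts <- table(d$exposure, d$sensitivity)
  for (ie in 1:3) for (is in 1:3) {
    if (counts[ie, is] < 100) next
    tv <- 0.5 * sum(abs(fit$cpts$annoyance[, ie, is] -
                          truth$network$cpts$annoyance[, ie, is]))
    expect_lt(tv, 0.1)
  }
})

test_that("posterior with full parent evidence equals the CPT row", {
  net <- read_network(table3_network_path())
  for (e in c("low", "high")) for (s in c("low", "moderate")) {
    p <- infer_posterior(net, "quality",
                         c(exposure = e, sensitivity = s, annoyance = "moderate"))
    row <- net$cpts$quality[, match(e, c("low", "moderate", "high")),
                            match(s, c("low", "moderate", "high")), 2]
    expect_equal(as.numeric(p), as.numeric(row), tolerance = 1e-12)
  }
})
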