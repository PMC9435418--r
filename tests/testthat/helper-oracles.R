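# Brute-force enumeration oracle for posterior inference: sums
# joint_probability() over the full state grid. Independent of the
# variable-elimination path in infer_posterior().
enum_posterior <- function(net, query, evidence = NULL) {
  nodes <- names(net$variables)
  grid <- expand.grid(lapply(nodes, function(v) net$variables[[v]]),
                      stringsAsFactors = FALSE)
  names(grid) <- nodes
  keep <- rep(TRUE, nrow(grid))
  for (v in names(evidence)) keep <- keep & grid[[v]] == evidence[[v]]
  grid <- grid[keep, , drop = FALSE]
  p <- vapply(seq_len(nrow(grid)), function(i) {
    a <- vapply(nodes, function(v) grid[[v]][i], "")
    joint_probability(net, a)
  }, 1)
  agg <- tapply(p, factor(grid[[query]], levels = net$variables[[query]]), sum)
  agg[is.na(agg)] <- 0
  as.numeric(agg / sum(agg))
}

# two-node net: binary parent, binary child with given conditionals
two_node_net <- function(p_parent = 0.5, p_child_given = c(x = 0.7, y = 0.2)) {
  bn_network(
    variables = list(parent = c("x", "y"), child = c("a", "b")),
    parents = list(child = "parent"),
    cpts = list(
      parent = c(p_parent, 1 - p_parent),
      child = matrix(c(p_child_given[["x"]], 1 - p_child_given[["x"]],
                       p_child_given[["y"]], 1 - p_child_given[["y"]]), nrow = 2)
    )
  )
}

# binary chain a -> b -> c with hand-specified conditionals
chain_net <- function() {
  bn_network(
    variables = list(a = c("a1", "a2"), b = c("b1", "b2"), c = c("c1", "c2")),
    parents = list(b = "a", c = "b"),
    cpts = list(
      a = c(0.3, 0.7),
      b = matrix(c(0.8, 0.2, 0.4, 0.6), nrow = 2),
      c = matrix(c(0.9, 0.1, 0.2, 0.8), nrow = 2)
    )
  )
}

study_nodes <- function() c("exposure", "sensitivity", "annoyance",
                            "psychosocial", "communicational", "physical",
                            "quality")
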