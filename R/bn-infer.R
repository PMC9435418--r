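# Exact inference by variable elimination.
#
# Factors are lists (vars, card, states, v) where v is a numeric vector in
# mixed-radix order with the FIRST variable varying fastest (the same order
# as as.vector() on an array whose first dimension is vars[1]).

fac_from_cpt <- function(net, node) {
  arr <- net$cpts[[node]]
  if (is.null(arr)) stop(sprintf("node '%s' has no CPT", node))
  vars <- c(node, net$parents[[node]])
  list(vars = vars,
       card = vapply(vars, function(u) length(net$variables[[u]]), 1L),
       states = lapply(vars, function(u) net$variables[[u]]),
       v = as.vector(arr))
}

radix_weights <- function(card) {
  if (!length(card)) return(numeric(0))
  cumprod(c(1, card[-length(card)]))
}

fac_reduce <- function(f, var, state_idx) {
  k <- match(var, f$vars)
  if (is.na(k)) return(f)
  idx <- arrayInd(seq_along(f$v), f$card)
  keep <- idx[, k] == state_idx
  list(vars = f$vars[-k], card = f$card[-k], states = f$states[-k],
       v = f$v[keep])
}

fac_product <- function(f, g) {
  if (!length(f$vars)) return(list(vars = g$vars, card = g$card,
                                   states = g$states, v = g$v * f$v))
  if (!length(g$vars)) return(list(vars = f$vars, card = f$card,
                                   states = f$states, v = f$v * g$v))
  vars <- union(f$vars, g$vars)
  pos_f <- match(f$vars, vars); pos_g <- match(g$vars, vars)
  card <- integer(length(vars))
  card[pos_f] <- f$card; card[pos_g] <- g$card
  states <- vector("list", length(vars))
  states[pos_f] <- f$states; states[pos_g] <- g$states
  idx <- arrayInd(seq_len(prod(card)), card)
  fi <- as.vector((idx[, pos_f, drop = FALSE] - 1L) %*% radix_weights(f$card)) + 1L
  gi <- as.vector((idx[, pos_g, drop = FALSE] - 1L) %*% radix_weights(g$card)) + 1L
  list(vars = vars, card = card, states = states, v = f$v[fi] * g$v[gi])
}

fac_marginalize <- function(f, var) {
  k <- match(var, f$vars)
  if (is.na(k)) return(f)
  if (length(f$vars) == 1L)
    return(list(vars = character(0), card = integer(0), states = list(),
                v = sum(f$v)))
  idx <- arrayInd(seq_along(f$v), f$card)
  rem <- seq_along(f$vars)[-k]
  lin <- as.vector((idx[, rem, drop = FALSE] - 1L) %*% radix_weights(f$card[rem])) + 1L
  v <- numeric(prod(f$card[rem]))
  agg <- rowsum(f$v, lin)
  v[as.integer(rownames(agg))] <- agg[, 1L]
  list(vars = f$vars[-k], card = f$card[-k], states = f$states[-k], v = v)
}

#' Joint probability of a full assignment
#'
#' Evaluates the factorised joint probability of a complete assignment of
#' every network variable: the product over nodes of the CPT entry selected
#' by the assignment. This is the elementary quantity behind brute-force
#' enumeration and is deliberately independent of the variable-elimination
#' machinery used by [infer_posterior()].
#'
#' @param net A parameterised `bn` object.
#' @param assignment Named character vector/list giving one state for every
#'   variable in the network.
#' @return A single probability.
#' @export
joint_probability <- function(net, assignment) {
  assignment <- check_evidence(net, assignment)
  missing <- setdiff(names(net$variables), names(assignment))
  if (length(missing))
    stop(sprintf("assignment must cover all variables; missing: %s",
                 paste(missing, collapse = ", ")))
  p <- 1
  for (v in names(net$variables)) {
    arr <- net$cpts[[v]]
    if (is.null(arr)) stop(sprintf("node '%s' has no CPT", v))
    fam <- c(v, net$parents[[v]])
    idx <- vapply(fam, function(u) match(assignment[[u]], net$variables[[u]]), 1L)
    p <- p * arr[matrix(idx, nrow = 1L)]
  }
  unname(p)
}

#' Exact posterior of one variable given evidence
#'
#' Computes the exact conditional distribution of `query` given the
#' evidence, by variable elimination over the network's CPT factors with a
#' greedy smallest-intermediate-factor elimination order.
#'
#' @param net A parameterised `bn` object.
#' @param query Name of the query variable (must not be in the evidence).
#' @param evidence Named character vector/list of observed states, or `NULL`.
#' @return Named probability vector over the query variable's states.
#' @examples
#' net <- build_study_network(fitted = TRUE)
#' infer_posterior(net, "quality", c(exposure = "high", sensitivity = "high"))
#' @export
infer_posterior <- function(net, query, evidence = NULL) {
  stopifnot(inherits(net, "bn"))
  if (!query %in% names(net$variables)) stop(sprintf("unknown query node '%s'", query))
  evidence <- check_evidence(net, evidence)
  if (query %in% names(evidence)) stop("query variable is part of the evidence")

  factors <- lapply(names(net$variables), function(v) fac_from_cpt(net, v))
  for (v in names(evidence)) {
    si <- match(evidence[[v]], net$variables[[v]])
    factors <- lapply(factors, fac_reduce, var = v, state_idx = si)
  }
  to_eliminate <- setdiff(names(net$variables), c(query, names(evidence)))
  while (length(to_eliminate)) {
    # greedy: eliminate the variable whose combined factor is smallest
    cost <- vapply(to_eliminate, function(u) {
      inv <- Filter(function(f) u %in% f$vars, factors)
      vars <- unique(unlist(lapply(inv, `[[`, "vars")))
      prod(vapply(vars, function(w) length(net$variables[[w]]), 1L))
    }, 1)
    u <- to_eliminate[which.min(cost)]
    involved <- vapply(factors, function(f) u %in% f$vars, TRUE)
    prodf <- Reduce(fac_product, factors[involved])
    factors <- c(factors[!involved], list(fac_marginalize(prodf, u)))
    to_eliminate <- setdiff(to_eliminate, u)
  }
  res <- Reduce(fac_product, factors)
  if (length(res$vars) != 1L || res$vars != query)
    stop("internal error: elimination did not reduce to the query variable")
  total <- sum(res$v)
  if (!is.finite(total) || total <= 0)
    stop("impossible evidence: the observed configuration has probability 0")
  stats::setNames(res$v / total, net$variables[[query]])
}

#' Most probable state of a variable given evidence
#'
#' Maximum a posteriori prediction: the state of `target` with the largest
#' posterior probability under [infer_posterior()]. Exact ties are broken in
#' favour of the earlier state in the variable's declared state order.
#'
#' @inheritParams infer_posterior
#' @param target Name of the variable to predict.
#' @return A single state label.
#' @export
map_predict <- function(net, target, evidence = NULL) {
  post <- infer_posterior(net, target, evidence)
  names(post)[which.max(post)]
}

#' Generate a random ternary-node network
#'
#' Draws a random directed acyclic graph over `n_nodes` three-state
#' variables and fills every CPT row with a Dirichlet(1,..,1) draw. Intended
#' for property-style verification of the inference engine (for example,
#' comparing variable elimination against full-joint enumeration).
#'
#' @param n_nodes Number of nodes (named `v1`, `v2`, ...).
#' @param max_parents Maximum in-degree.
#' @param seed Integer seed; every call with the same arguments returns the
#'   same network.
#' @return A parameterised `bn` object.
#' @export
random_network <- function(n_nodes, max_parents = 3, seed = 1) {
  with_seed(seed, {
    nodes <- paste0("v", seq_len(n_nodes))
    states <- c("s1", "s2", "s3")
    variables <- stats::setNames(rep(list(states), n_nodes), nodes)
    parents <- stats::setNames(vector("list", n_nodes), nodes)
    for (i in seq_len(n_nodes)) {
      avail <- nodes[seq_len(i - 1L)]
      k <- if (length(avail)) sample(0:min(max_parents, length(avail)), 1L) else 0L
      parents[[nodes[i]]] <- if (k) sample(avail, k) else character(0)
    }
    net <- bn_network(variables, parents)
    for (v in nodes) {
      np <- length(net$parents[[v]])
      nrow_cfg <- 3L^np
      m <- matrix(stats::rgamma(3L * nrow_cfg, shape = 1), nrow = 3L)
      m <- sweep(m, 2L, colSums(m), "/")
      net <- set_cpt(net, v, array(m, dim = rep(3L, np + 1L)))
    }
    net
  })
}
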