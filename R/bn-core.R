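# Discrete Bayesian network data model.
#
# A network is a list with components
#   variables : named list, node name -> character vector of ordered states
#   parents   : named list, node name -> character vector of parent names
#   cpts      : named list, node name -> probability array or NULL (unset)
# A CPT array has dim c(n_child_states, n_states(parent1), ...) with the
# child dimension first, and dimnames carrying state labels; each slice
# along the child dimension for a fixed parent configuration is a
# probability vector.

PROB_TOL <- 1e-9

#' Construct a discrete Bayesian network
#'
#' Builds (and validates) a discrete Bayesian network from a set of named
#' variables with ordered states, a parent map defining an acyclic graph,
#' and optionally one conditional probability table (CPT) per node.
#'
#' @param variables Named list mapping each node name to a character vector
#'   of at least two unique state labels. State order is meaningful: it is
#'   the display order and the tie-break order for [map_predict()].
#' @param parents Named list mapping node names to character vectors of
#'   parent node names. Nodes absent from the list are treated as parentless.
#' @param cpts Named list mapping node names to CPT arrays (child dimension
#'   first, then one dimension per parent in the declared parent order).
#'   May be `NULL` or partial: a network with unset CPTs is a "structure"
#'   that can be passed to [em_learn()].
#'
#' @return An object of class `bn`.
#' @examples
#' net <- bn_network(
#'   variables = list(a = c("no", "yes"), b = c("no", "yes")),
#'   parents = list(b = "a"),
#'   cpts = list(
#'     a = bn_cpt(c(0.4, 0.6), c("no", "yes")),
#'     b = bn_cpt(matrix(c(0.9, 0.1, 0.2, 0.8), nrow = 2),
#'                c("no", "yes"), list(a = c("no", "yes")))
#'   )
#' )
#' @export
bn_network <- function(variables, parents = NULL, cpts = NULL) {
  if (is.null(names(variables)) || any(!nzchar(names(variables))))
    stop("'variables' must be a named list")
  nodes <- names(variables)
  if (anyDuplicated(nodes)) stop("duplicate variable names")
  for (v in nodes) {
    st <- variables[[v]]
    if (!is.character(st) || length(st) < 2L || anyDuplicated(st))
      stop(sprintf("variable '%s' must have >= 2 unique character states", v))
  }
  if (is.null(parents)) parents <- list()
  full_parents <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) {
    pa <- parents[[v]]
    if (is.null(pa)) pa <- character(0)
    bad <- setdiff(pa, nodes)
    if (length(bad))
      stop(sprintf("undeclared parent(s) of '%s': %s", v, paste(bad, collapse = ", ")))
    if (anyDuplicated(pa)) stop(sprintf("duplicated parents of '%s'", v))
    full_parents[[v]] <- as.character(pa)
  }
  extra <- setdiff(names(parents), nodes)
  if (length(extra))
    stop(sprintf("parents declared for unknown node(s): %s", paste(extra, collapse = ", ")))
  ord <- topological_order(nodes, full_parents)  # errors on cycles
  full_cpts <- stats::setNames(vector("list", length(nodes)), nodes)
  if (!is.null(cpts)) {
    extra <- setdiff(names(cpts), nodes)
    if (length(extra))
      stop(sprintf("CPT supplied for unknown node(s): %s", paste(extra, collapse = ", ")))
    for (v in names(cpts)) {
      if (is.null(cpts[[v]])) next
      full_cpts[[v]] <- validate_cpt(v, cpts[[v]], variables, full_parents[[v]])
    }
  }
  structure(
    list(variables = variables, parents = full_parents,
         cpts = full_cpts, order = ord),
    class = "bn"
  )
}

#' Build a CPT array
#'
#' Convenience constructor for the CPT arrays stored in a [bn_network()].
#'
#' @param values Numeric vector, matrix or array of probabilities. The child
#'   dimension comes first; values are recycled into an array of dimension
#'   `c(length(child_states), sapply(parent_states, length))`.
#' @param child_states Character vector of the child's states.
#' @param parent_states Named list of parent state vectors (in parent order),
#'   or `NULL` for a parentless node.
#' @return A probability array with state labels as dimnames.
#' @export
bn_cpt <- function(values, child_states, parent_states = NULL) {
  dims <- c(length(child_states),
            if (length(parent_states)) vapply(parent_states, length, 1L))
  arr <- array(as.numeric(values), dim = dims)
  dimnames(arr) <- c(list(child_states), unname(parent_states))
  arr
}

validate_cpt <- function(node, arr, variables, parents) {
  states <- variables[[node]]
  want_dim <- c(length(states),
                vapply(parents, function(p) length(variables[[p]]), 1L))
  arr <- as.array(arr)
  if (length(dim(arr)) == 1L && length(want_dim) == 1L) dim(arr) <- want_dim
  if (!identical(as.integer(dim(arr)), as.integer(want_dim)))
    stop(sprintf("CPT for '%s' has dim (%s); expected (%s)", node,
                 paste(dim(arr), collapse = ","), paste(want_dim, collapse = ",")))
  if (any(!is.finite(arr)) || any(arr < -PROB_TOL))
    stop(sprintf("CPT for '%s' contains negative or non-finite entries", node))
  arr[arr < 0] <- 0
  sums <- if (length(want_dim) == 1L) sum(arr)
          else apply(arr, seq_along(want_dim)[-1], sum)
  if (any(abs(sums - 1) > 1e-6))
    stop(sprintf("CPT for '%s': a row does not sum to 1 (max |sum-1| = %.3g)",
                 node, max(abs(sums - 1))))
  dimnames(arr) <- c(list(states),
                     lapply(parents, function(p) variables[[p]]))
  names(dimnames(arr)) <- c(node, parents)
  arr
}

# Kahn's algorithm; errors on a cycle.
topological_order <- function(nodes, parents) {
  indeg <- vapply(parents[nodes], length, 1L)
  children <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) for (p in parents[[v]]) children[[p]] <- c(children[[p]], v)
  queue <- nodes[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(nodes)) stop("parent graph contains a cycle")
  out
}

#' Set or replace one node's CPT
#'
#' @param net A `bn` object.
#' @param node Node name.
#' @param values CPT array or vector, as in [bn_cpt()].
#' @return The modified network.
#' @export
set_cpt <- function(net, node, values) {
  stopifnot(inherits(net, "bn"))
  if (!node %in% names(net$variables)) stop(sprintf("unknown node '%s'", node))
  arr <- bn_cpt(values, net$variables[[node]],
                lapply(net$parents[[node]], function(p) net$variables[[p]]))
  net$cpts[[node]] <- validate_cpt(node, arr, net$variables, net$parents[[node]])
  net
}

bn_arcs <- function(net) {
  out <- do.call(rbind, lapply(names(net$parents), function(v) {
    pa <- net$parents[[v]]
    if (!length(pa)) return(NULL)
    data.frame(parent = pa, child = v, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) out <- data.frame(parent = character(0), child = character(0))
  out
}

bn_is_fit <- function(net) !any(vapply(net$cpts, is.null, TRUE))

#' @export
print.bn <- function(x, ...) {
  arcs <- bn_arcs(x)
  cat(sprintf("Discrete Bayesian network: %d nodes, %d arcs (%s)\n",
              length(x$variables), nrow(arcs),
              if (bn_is_fit(x)) "parameterised" else "structure only"))
  for (v in x$order) {
    pa <- x$parents[[v]]
    cat(sprintf("  %s [%s]%s\n", v, paste(x$variables[[v]], collapse = "/"),
                if (length(pa)) paste0(" <- ", paste(pa, collapse = ", ")) else ""))
  }
  invisible(x)
}

check_evidence <- function(net, evidence) {
  if (is.null(evidence) || length(evidence) == 0L) return(character(0))
  evidence <- unlist(evidence)
  if (is.null(names(evidence)) || any(!nzchar(names(evidence))))
    stop("evidence must be a named vector or list: node = state")
  bad <- setdiff(names(evidence), names(net$variables))
  if (length(bad)) stop(sprintf("evidence on unknown node(s): %s", paste(bad, collapse = ", ")))
  for (v in names(evidence)) {
    if (!evidence[[v]] %in% net$variables[[v]])
      stop(sprintf("'%s' is not a state of node '%s'", evidence[[v]], v))
  }
  evidence
}

# Evaluate the RNG-state-preserving expression under an explicit seed.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}
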