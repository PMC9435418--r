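# EM parameter learning from incomplete categorical records.

# Convert a data.frame of states (factor/character, NA = missing) into an
# integer matrix of state indices aligned with the network's variables.
data_to_indices <- function(net, data) {
  nodes <- names(net$variables)
  missing_cols <- setdiff(nodes, names(data))
  if (length(missing_cols))
    stop(sprintf("data is missing column(s): %s", paste(missing_cols, collapse = ", ")))
  idx <- matrix(NA_integer_, nrow = nrow(data), ncol = length(nodes),
                dimnames = list(NULL, nodes))
  for (v in nodes) {
    x <- as.character(data[[v]])
    x[!is.na(x) & x == ""] <- NA
    i <- match(x, net$variables[[v]])
    bad <- which(!is.na(x) & is.na(i))
    if (length(bad))
      stop(sprintf("column '%s': value '%s' is not a declared state", v, x[bad[1L]]))
    idx[, v] <- i
  }
  idx
}

# Probability of each complete assignment (rows of an index matrix) under
# the current parameters; vectorised over rows.
assignment_probs <- function(net, idx_mat) {
  p <- rep(1, nrow(idx_mat))
  for (v in names(net$variables)) {
    fam <- c(v, net$parents[[v]])
    arr <- net$cpts[[v]]
    p <- p * arr[idx_mat[, fam, drop = FALSE]]
  }
  p
}

init_cpts <- function(net, how = c("jitter", "uniform"), concentration = 50) {
  how <- match.arg(how)
  for (v in names(net$variables)) {
    k <- length(net$variables[[v]])
    ncfg <- prod(vapply(net$parents[[v]],
                        function(p) length(net$variables[[p]]), 1L))
    if (how == "uniform") {
      m <- matrix(1 / k, nrow = k, ncol = ncfg)
    } else {
      m <- matrix(stats::rgamma(k * ncfg, shape = concentration), nrow = k)
      m <- sweep(m, 2L, colSums(m), "/")
    }
    pdims <- vapply(net$parents[[v]], function(p) length(net$variables[[p]]), 1L)
    net <- set_cpt(net, v, array(m, dim = c(k, pdims)))
  }
  net
}

#' Learn CPTs by expectation-maximisation
#'
#' Fits the conditional probability tables of a fixed network structure
#' from categorical records that may contain missing values (`NA`). The
#' E-step computes, for every record, the exact posterior over its missing
#' cells by enumerating their completions under the current parameters
#' (records are grouped by unique observation pattern); the M-step sets
#' every CPT row to the normalised expected counts. Parent configurations
#' with zero expected count receive the uniform distribution. Iteration
#' stops when the observed-data log-likelihood improves by less than `tol`
#' or after `max_iter` iterations. A decrease of the observed-data
#' log-likelihood beyond numerical noise is raised as an error, since EM
#' guarantees monotonicity.
#'
#' With complete data the procedure converges immediately to the
#' conditional relative frequencies.
#'
#' @param structure A `bn` object (CPTs may be unset; any set CPTs are
#'   ignored and re-learned).
#' @param data Data frame with one column per network variable; `NA` or
#'   empty string marks a missing cell.
#' @param max_iter Maximum EM iterations.
#' @param tol Absolute log-likelihood improvement below which iteration
#'   stops.
#' @param seed Integer seed for the jittered initialisation (ignored for
#'   `init = "uniform"`).
#' @param init Initialisation: near-uniform rows with a seeded Dirichlet
#'   jitter (concentration 50) to break symmetry, or exactly uniform rows.
#' @param smooth Optional Laplace pseudo-count added to every expected
#'   count in the M-step (default 0: Table-style hard 0/1 rows are
#'   attainable).
#'
#' @return A parameterised `bn` with attributes `em_loglik` (the
#'   per-iteration observed-data log-likelihood trace), `em_iterations` and
#'   `em_converged`.
#' @export
em_learn <- function(structure, data, max_iter = 100, tol = 1e-6,
                     seed = NULL, init = c("jitter", "uniform"), smooth = 0) {
  stopifnot(inherits(structure, "bn"))
  init <- match.arg(init)
  nodes <- names(structure$variables)
  idx <- data_to_indices(structure, data)
  if (nrow(idx) == 0L) stop("no records")
  all_missing <- colSums(!is.na(idx)) == 0L
  if (any(all_missing))
    stop(sprintf("variable(s) entirely missing from data: %s",
                 paste(nodes[all_missing], collapse = ", ")))

  # group records by unique pattern
  key <- apply(idx, 1L, paste, collapse = "|")
  groups <- split(seq_len(nrow(idx)), key)
  pat <- idx[vapply(groups, `[`, 1L, 1L), , drop = FALSE]
  wt <- vapply(groups, length, 1L)

  # pre-compute each pattern's completion index matrix
  completions <- lapply(seq_len(nrow(pat)), function(i) {
    row <- pat[i, ]
    mis <- which(is.na(row))
    if (!length(mis)) return(matrix(row, nrow = 1L, dimnames = list(NULL, nodes)))
    grids <- lapply(mis, function(j) seq_along(structure$variables[[nodes[j]]]))
    g <- as.matrix(expand.grid(grids))
    out <- matrix(rep(row, each = nrow(g)), nrow = nrow(g),
                  dimnames = list(NULL, nodes))
    out[, mis] <- g
    out
  })

  fams <- lapply(nodes, function(v) c(v, structure$parents[[v]]))
  names(fams) <- nodes
  dims <- lapply(nodes, function(v)
    vapply(fams[[v]], function(u) length(structure$variables[[u]]), 1L))
  names(dims) <- nodes

  net <- with_seed(seed, init_cpts(structure, init))
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    counts <- lapply(nodes, function(v) array(0, dim = dims[[v]]))
    names(counts) <- nodes
    ll <- 0
    for (i in seq_along(completions)) {
      comp <- completions[[i]]
      p <- assignment_probs(net, comp)
      tot <- sum(p)
      if (tot <= 0) {
        # a pattern inconsistent with current parameters contributes -Inf;
        # spread its mass uniformly to keep EM moving
        w <- rep(1 / nrow(comp), nrow(comp))
        ll <- -Inf
      } else {
        w <- p / tot
        ll <- ll + wt[i] * log(tot)
      }
      w <- w * wt[i]
      for (v in nodes) {
        lin <- 1L + as.vector((comp[, fams[[v]], drop = FALSE] - 1L) %*%
                                radix_weights(dims[[v]]))
        agg <- rowsum(w, lin)
        counts[[v]][as.integer(rownames(agg))] <-
          counts[[v]][as.integer(rownames(agg))] + agg[, 1L]
      }
    }
    for (v in nodes) {
      cnt <- counts[[v]] + smooth
      k <- dims[[v]][1L]
      m <- matrix(cnt, nrow = k)
      colt <- colSums(m)
      zero <- colt <= 0
      m[, zero] <- 1 / k
      m[, !zero] <- sweep(m[, !zero, drop = FALSE], 2L, colt[!zero], "/")
      net$cpts[[v]] <- validate_cpt(v, array(m, dim = dims[[v]]),
                                    net$variables, net$parents[[v]])
    }
    trace <- c(trace, ll)
    if (iter >= 2L) {
      prev <- trace[iter - 1L]
      if (is.finite(prev) && is.finite(ll)) {
        if (ll < prev - 1e-8 * (abs(prev) + 1))
          stop(sprintf("EM log-likelihood decreased (%.10g -> %.10g); this indicates a bug",
                       prev, ll))
        if (ll - prev < tol) { converged <- TRUE; break }
      }
    }
  }
  attr(net, "em_loglik") <- trace
  attr(net, "em_iterations") <- length(trace)
  attr(net, "em_converged") <- converged
  net
}
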