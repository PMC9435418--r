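# Study network structure and JSON serialisation.

STUDY_NOISE_STATES <- c("low", "moderate", "high")
STUDY_QUALITY_STATES <- c("undesirable", "partly_desirable", "desirable")
STUDY_NOISE_NODES <- c("exposure", "sensitivity", "annoyance")
STUDY_ASPECT_NODES <- c("psychosocial", "communicational", "physical")

#' The study's expert-drawn network structure
#'
#' Seven ternary nodes: noise exposure, noise sensitivity and noise
#' annoyance (states low/moderate/high) and the three quality-of-care
#' aspects plus the overall quality node (states
#' undesirable/partly_desirable/desirable). Arcs: exposure -> sensitivity;
#' exposure and sensitivity -> annoyance; exposure, sensitivity and
#' annoyance -> each aspect; the three aspects -> overall quality
#' (15 arcs in total).
#'
#' @param fitted If `TRUE`, the network is returned with the package's
#'   documented default ground-truth CPTs (see [make_truth_network()]);
#'   otherwise CPTs are unset and the object is a structure suitable for
#'   [em_learn()].
#' @return A `bn` object.
#' @export
build_study_network <- function(fitted = FALSE) {
  variables <- c(
    stats::setNames(rep(list(STUDY_NOISE_STATES), 3L), STUDY_NOISE_NODES),
    stats::setNames(rep(list(STUDY_QUALITY_STATES), 4L),
                    c(STUDY_ASPECT_NODES, "quality"))
  )
  parents <- list(
    sensitivity = "exposure",
    annoyance = c("exposure", "sensitivity"),
    psychosocial = c("exposure", "sensitivity", "annoyance"),
    communicational = c("exposure", "sensitivity", "annoyance"),
    physical = c("exposure", "sensitivity", "annoyance"),
    quality = c("psychosocial", "communicational", "physical")
  )
  net <- bn_network(variables, parents)
  if (fitted) net <- default_truth_cpts(net)
  net
}

#' Read a network from a JSON specification
#'
#' The on-disk format is a JSON object
#' `{"variables": [{"name", "states"}], "cpts": [{"child", "parents",
#' "rows": [{"config", "p"}]}]}` where `config` lists one state per parent
#' (empty for root nodes) and `p` is the probability vector over the
#' child's states. Every parent configuration must appear exactly once and
#' every `p` must sum to 1.
#'
#' The packaged fixture `table3_network.json` (under `extdata`) encodes the
#' published conditional probability table of overall quality of patient
#' care given noise exposure, sensitivity and annoyance, with the three
#' parent priors set to the published category relative frequencies.
#'
#' @param path Path to a JSON network file.
#' @return A `bn` object.
#' @examples
#' fix <- system.file("extdata", "table3_network.json", package = "noisecare")
#' net <- read_network(fix)
#' infer_posterior(net, "quality",
#'                 c(exposure = "low", sensitivity = "moderate", annoyance = "low"))
#' @export
read_network <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(spec$variables)) stop("network spec: missing 'variables'")
  variables <- list()
  for (vs in spec$variables) {
    if (is.null(vs$name) || is.null(vs$states))
      stop("network spec: each variable needs 'name' and 'states'")
    variables[[vs$name]] <- unlist(vs$states)
  }
  parents <- list(); cpts <- list()
  for (cs in spec$cpts) {
    child <- cs$child
    if (is.null(child) || !child %in% names(variables))
      stop(sprintf("network spec: CPT for undeclared child '%s'", as.character(child)))
    pa <- as.character(unlist(cs$parents))
    parents[[child]] <- pa
    kc <- length(variables[[child]])
    dims <- c(kc, vapply(pa, function(p) length(variables[[p]]), 1L))
    arr <- array(NA_real_, dim = dims)
    seen <- array(FALSE, dim = if (length(pa)) dims[-1L] else 1L)
    for (row in cs$rows) {
      cfg <- as.character(unlist(row$config))
      if (length(cfg) != length(pa))
        stop(sprintf("network spec: CPT '%s': config length %d, expected %d",
                     child, length(cfg), length(pa)))
      p <- as.numeric(unlist(row$p))
      if (length(p) != kc)
        stop(sprintf("network spec: CPT '%s': probability vector of length %d, expected %d",
                     child, length(p), kc))
      idx <- mapply(function(s, pnode) {
        i <- match(s, variables[[pnode]])
        if (is.na(i)) stop(sprintf("network spec: CPT '%s': '%s' is not a state of '%s'",
                                   child, s, pnode))
        i
      }, cfg, pa)
      if (length(pa)) {
        if (seen[matrix(idx, nrow = 1L)])
          stop(sprintf("network spec: CPT '%s': duplicate config (%s)",
                       child, paste(cfg, collapse = ", ")))
        seen[matrix(idx, nrow = 1L)] <- TRUE
        arr[matrix(c(rep(seq_len(kc), 1), rep(idx, each = kc)),
                   ncol = length(dims))] <- p
      } else {
        seen[1L] <- TRUE
        arr[] <- p
      }
    }
    if (!all(seen))
      stop(sprintf("network spec: CPT '%s': %d parent configuration(s) missing",
                   child, sum(!seen)))
    cpts[[child]] <- arr
  }
  missing_cpt <- setdiff(names(variables), names(cpts))
  if (length(missing_cpt))
    stop(sprintf("network spec: no CPT for node(s): %s", paste(missing_cpt, collapse = ", ")))
  bn_network(variables, parents, cpts)
}

#' Write a network to a JSON specification
#'
#' Inverse of [read_network()]: `read_network(write_network(net, path))`
#' reproduces the network exactly (up to floating-point serialisation).
#'
#' @param net A parameterised `bn` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "bn"))
  if (!bn_is_fit(net)) stop("cannot write a network with unset CPTs")
  variables <- lapply(names(net$variables), function(v)
    list(name = v, states = net$variables[[v]]))
  cpts <- lapply(names(net$variables), function(v) {
    pa <- net$parents[[v]]
    arr <- net$cpts[[v]]
    if (length(pa)) {
      cfgs <- expand.grid(lapply(pa, function(p) net$variables[[p]]),
                          stringsAsFactors = FALSE)
      rows <- lapply(seq_len(nrow(cfgs)), function(i) {
        cfg <- as.character(cfgs[i, ])
        idx <- mapply(function(s, p) match(s, net$variables[[p]]), cfg, pa)
        sel <- do.call(`[`, c(list(arr), list(TRUE), as.list(idx)))
        list(config = I(cfg), p = as.numeric(sel))
      })
    } else {
      rows <- list(list(config = I(character(0)), p = as.numeric(arr)))
    }
    list(child = v, parents = I(pa), rows = rows)
  })
  jsonlite::write_json(list(variables = variables, cpts = cpts), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Path to the packaged published-CPT fixture network
#'
#' @return Path of `table3_network.json` in the installed package.
#' @export
table3_network_path <- function() {
  system.file("extdata", "table3_network.json", package = "noisecare",
              mustWork = TRUE)
}
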