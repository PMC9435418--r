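# Scoring of the Weinstein noise-sensitivity scale, the annoyance visual
# analogue scale and the 65-item quality-of-patient-care scale (QPCS),
# plus Cronbach's alpha and EM-based item imputation.

QPCS_SUBSCALES <- c(psychosocial = 28L, communicational = 13L, physical = 24L)

# fixed score-band cut-offs; bands are closed at the printed limits
QPCS_CUTOFFS <- list(
  total           = c(lo = 65,  partly = 130, desirable = 196, hi = 260),
  psychosocial    = c(lo = 28,  partly = 56,  desirable = 85,  hi = 112),
  communicational = c(lo = 13,  partly = 26,  desirable = 40,  hi = 52),
  physical        = c(lo = 24,  partly = 48,  desirable = 73,  hi = 96)
)

# Default positional subscale map: items 1-28 psychosocial, 29-41
# communicational, 42-65 physical. The instrument's item order is
# configurable because only the subscale sizes are fixed.
default_qpcs_map <- function() {
  rep(names(QPCS_SUBSCALES), times = QPCS_SUBSCALES)
}

#' Score the Weinstein noise-sensitivity scale
#'
#' Sum of 21 six-point items coded 0-5; reverse-keyed items contribute
#' `5 - raw`. Total range 0-105. Which items (if any) are reverse-keyed is
#' configurable and defaults to none.
#'
#' @param items Numeric vector of 21 integer responses in 0..5.
#' @param reverse_key Integer indices (1..21) of reverse-keyed items.
#' @return Integer total score.
#' @export
score_weinstein <- function(items, reverse_key = integer(0)) {
  if (length(items) != 21L)
    stop(sprintf("expected 21 items, got %d", length(items)))
  bad <- which(!is.finite(items) | items < 0 | items > 5 | items != round(items))
  if (length(bad))
    stop(sprintf("item %d has value '%s'; responses must be integers in 0..5",
                 bad[1L], as.character(items[bad[1L]])))
  if (length(reverse_key)) {
    if (any(!reverse_key %in% 1:21)) stop("'reverse_key' indices must be in 1..21")
    items[reverse_key] <- 5 - items[reverse_key]
  }
  as.integer(sum(items))
}

#' Categorise scores by sample percentiles
#'
#' Scores strictly below the sample's 25th percentile are `low`, strictly
#' above the 75th percentile `high`, and `moderate` otherwise (ties at a
#' percentile therefore fall in the moderate band). Percentiles use linear
#' interpolation between order statistics (`quantile()` type 7).
#'
#' @param scores Numeric vector of at least 4 scores.
#' @return Factor with levels `low`, `moderate`, `high`, same length as
#'   `scores`.
#' @export
percentile_categorize <- function(scores) {
  if (length(scores) < 4L) stop("at least 4 scores are required")
  if (any(!is.finite(scores))) stop("scores must be finite")
  q <- stats::quantile(scores, c(0.25, 0.75), type = 7, names = FALSE)
  factor(ifelse(scores < q[1L], "low", ifelse(scores > q[2L], "high", "moderate")),
         levels = c("low", "moderate", "high"))
}

#' Score the quality-of-patient-care scale
#'
#' Sums 65 four-point items (1-4) into a total (65-260) and three subscale
#' scores (psychosocial 28-112, communicational 13-52, physical 24-96), and
#' categorises each by fixed cut-offs: total < 130 undesirable, 130-195
#' partly desirable, 196-260 desirable; psychosocial < 56 / 56-84 / 85-112;
#' communicational < 26 / 26-39 / 40-52; physical < 48 / 48-72 / 73-96.
#'
#' @param items Numeric vector of 65 integer responses in 1..4.
#' @param subscale_map Character vector of length 65 assigning each item to
#'   `psychosocial`, `communicational` or `physical` (subscale sizes must
#'   be 28/13/24). Defaults to the positional map: items 1-28 psychosocial,
#'   29-41 communicational, 42-65 physical.
#' @return One-row data frame: `qpcs_total`, `psychosocial`,
#'   `communicational`, `physical` and the four corresponding `_cat`
#'   factors (levels `undesirable`, `partly_desirable`, `desirable`).
#' @export
score_qpcs <- function(items, subscale_map = default_qpcs_map()) {
  if (length(items) != 65L)
    stop(sprintf("expected 65 items, got %d", length(items)))
  bad <- which(!is.finite(items) | items < 1 | items > 4 | items != round(items))
  if (length(bad))
    stop(sprintf("item %d has value '%s'; responses must be integers in 1..4",
                 bad[1L], as.character(items[bad[1L]])))
  if (length(subscale_map) != 65L) stop("'subscale_map' must have length 65")
  sizes <- table(factor(subscale_map, levels = names(QPCS_SUBSCALES)))
  if (!identical(as.integer(sizes), as.integer(QPCS_SUBSCALES)))
    stop(sprintf("subscale sizes must be %s; got %s",
                 paste(QPCS_SUBSCALES, collapse = "/"), paste(sizes, collapse = "/")))
  total <- sum(items)
  subs <- vapply(names(QPCS_SUBSCALES), function(s) sum(items[subscale_map == s]), 1)
  out <- data.frame(qpcs_total = total, psychosocial = subs[["psychosocial"]],
                    communicational = subs[["communicational"]],
                    physical = subs[["physical"]])
  out$qpcs_total_cat <- qpcs_band(total, "total")
  out$psychosocial_cat <- qpcs_band(subs[["psychosocial"]], "psychosocial")
  out$communicational_cat <- qpcs_band(subs[["communicational"]], "communicational")
  out$physical_cat <- qpcs_band(subs[["physical"]], "physical")
  out
}

qpcs_band <- function(score, scale) {
  cut <- QPCS_CUTOFFS[[scale]]
  factor(ifelse(score < cut[["partly"]], "undesirable",
                ifelse(score < cut[["desirable"]], "partly_desirable", "desirable")),
         levels = c("undesirable", "partly_desirable", "desirable"))
}

#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(total score))`
#' with sample (n-1) variances.
#'
#' @param item_matrix Numeric matrix or data frame, records in rows and
#'   items in columns; no missing cells.
#' @return Cronbach's alpha.
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (ncol(m) < 2L || nrow(m) < 2L) stop("need at least 2 items and 2 records")
  if (any(is.na(m))) stop("item matrix contains missing cells; impute first")
  vt <- stats::var(rowSums(m))
  if (vt <= 0) stop("total score has zero variance")
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2L, stats::var)) / vt)
}

#' Impute missing item responses by EM under a normal working model
#'
#' Fits a multivariate-normal working model to the item matrix by
#' expectation-maximisation (conditional means and covariances in the
#' E-step, moment updates in the M-step), then replaces each missing cell
#' by its conditional mean given the record's observed items, clipped to
#' the legal response range and optionally rounded to an integer response.
#' Records whose missing fraction exceeds `max_missing` are excluded from
#' the fit, flagged, and returned unimputed.
#'
#' The working model is a pragmatic imputation device for bounded Likert
#' items, not a generative claim; with correlated items it is strictly
#' better than per-column mean imputation.
#'
#' @param item_matrix Numeric matrix with `NA` for missing cells.
#' @param range Length-2 numeric legal response range used for clipping.
#' @param integer_items Round imputed values to integers (default `TRUE`).
#' @param max_missing Per-record missing-fraction ceiling (default 0.2).
#' @param max_iter,tol EM iteration controls (parameter-change criterion).
#' @param ridge Diagonal regularisation added to the covariance update.
#' @return The completed matrix, with attributes `excluded` (row indices
#'   beyond the ceiling, left untouched) and `n_imputed`.
#' @export
impute_items <- function(item_matrix, range = c(1, 4), integer_items = TRUE,
                         max_missing = 0.2, max_iter = 100, tol = 1e-6,
                         ridge = 1e-3) {
  m <- as.matrix(item_matrix)
  storage.mode(m) <- "double"
  if (any(colSums(!is.na(m)) == 0L)) stop("a column is entirely missing")
  frac <- rowMeans(is.na(m))
  excluded <- which(frac > max_missing)
  use <- setdiff(seq_len(nrow(m)), excluded)
  x <- m[use, , drop = FALSE]
  if (!any(is.na(x))) {
    out <- m
    attr(out, "excluded") <- excluded
    attr(out, "n_imputed") <- 0L
    return(out)
  }
  k <- ncol(x)
  mu <- colMeans(x, na.rm = TRUE)
  v <- apply(x, 2L, stats::var, na.rm = TRUE)
  v[!is.finite(v) | v <= 0] <- ridge
  sigma <- diag(v, k)
  pat_key <- apply(is.na(x), 1L, paste, collapse = "")
  pats <- split(seq_len(nrow(x)), pat_key)
  for (iter in seq_len(max_iter)) {
    t1 <- numeric(k); t2 <- matrix(0, k, k)
    for (rows in pats) {
      mis <- which(is.na(x[rows[1L], ]))
      obs <- setdiff(seq_len(k), mis)
      xo <- x[rows, obs, drop = FALSE]
      if (!length(mis)) {
        t1 <- t1 + colSums(xo)
        t2 <- t2 + crossprod(xo)
        next
      }
      so_inv_sm <- solve(sigma[obs, obs, drop = FALSE] + diag(ridge, length(obs)),
                         sigma[obs, mis, drop = FALSE])
      cond_mu <- matrix(mu[mis], nrow = length(rows), ncol = length(mis),
                        byrow = TRUE) +
        (xo - matrix(mu[obs], nrow = length(rows), ncol = length(obs),
                     byrow = TRUE)) %*% so_inv_sm
      cond_cov <- sigma[mis, mis, drop = FALSE] -
        crossprod(so_inv_sm, sigma[obs, mis, drop = FALSE])
      xc <- matrix(NA_real_, length(rows), k)
      xc[, obs] <- xo; xc[, mis] <- cond_mu
      t1 <- t1 + colSums(xc)
      add <- crossprod(xc)
      add[mis, mis] <- add[mis, mis] + length(rows) * cond_cov
      t2 <- t2 + add
    }
    n <- nrow(x)
    mu_new <- t1 / n
    sigma_new <- t2 / n - tcrossprod(mu_new) + diag(ridge, k)
    delta <- max(abs(mu_new - mu), abs(sigma_new - sigma))
    mu <- mu_new; sigma <- sigma_new
    if (delta < tol) break
  }
  # final imputation pass
  n_imp <- 0L
  for (rows in pats) {
    mis <- which(is.na(x[rows[1L], ]))
    if (!length(mis)) next
    obs <- setdiff(seq_len(k), mis)
    so_inv_sm <- solve(sigma[obs, obs, drop = FALSE] + diag(ridge, length(obs)),
                       sigma[obs, mis, drop = FALSE])
    cond_mu <- matrix(mu[mis], nrow = length(rows), ncol = length(mis),
                      byrow = TRUE) +
      (x[rows, obs, drop = FALSE] -
         matrix(mu[obs], nrow = length(rows), ncol = length(obs), byrow = TRUE)) %*%
      so_inv_sm
    filled <- pmin(pmax(cond_mu, range[1L]), range[2L])
    if (integer_items) filled <- round(filled)
    x[rows, mis] <- filled
    n_imp <- n_imp + length(rows) * length(mis)
  }
  out <- m
  out[use, ] <- x
  attr(out, "excluded") <- excluded
  attr(out, "n_imputed") <- n_imp
  out
}

#' Re-score an item-level cohort into totals and categories
#'
#' Applies [score_weinstein()], [percentile_categorize()] and
#' [score_qpcs()] to a cohort table carrying item-level columns
#' (`ns_01`..`ns_21`, `annoyance_vas`, `qpc_01`..`qpc_65`) and writes the
#' derived score and category columns, overwriting any present. Sensitivity
#' and annoyance categories are relative to this cohort's own 25th/75th
#' percentiles; quality categories use the fixed cut-offs.
#'
#' @param cohort Data frame with the item columns above.
#' @param reverse_key Passed to [score_weinstein()].
#' @return The cohort with columns `sensitivity_score`, `annoyance_score`,
#'   `qpcs_total`, `psychosocial_score`, `communicational_score`,
#'   `physical_score` and category columns `sensitivity`, `annoyance`,
#'   `quality`, `psychosocial`, `communicational`, `physical`.
#' @export
score_cohort <- function(cohort, reverse_key = integer(0)) {
  ns_cols <- sprintf("ns_%02d", 1:21)
  qp_cols <- sprintf("qpc_%02d", 1:65)
  miss <- setdiff(c(ns_cols, "annoyance_vas", qp_cols), names(cohort))
  if (length(miss))
    stop(sprintf("cohort is missing item column(s), e.g. %s", miss[1L]))
  ns <- as.matrix(cohort[, ns_cols])
  qp <- as.matrix(cohort[, qp_cols])
  cohort$sensitivity_score <- apply(ns, 1L, score_weinstein, reverse_key = reverse_key)
  cohort$annoyance_score <- cohort$annoyance_vas
  qsc <- do.call(rbind, lapply(seq_len(nrow(qp)), function(i) score_qpcs(qp[i, ])))
  cohort$qpcs_total <- qsc$qpcs_total
  cohort$psychosocial_score <- qsc$psychosocial
  cohort$communicational_score <- qsc$communicational
  cohort$physical_score <- qsc$physical
  cohort$sensitivity <- percentile_categorize(cohort$sensitivity_score)
  cohort$annoyance <- percentile_categorize(cohort$annoyance_score)
  cohort$quality <- qsc$qpcs_total_cat
  cohort$psychosocial <- qsc$psychosocial_cat
  cohort$communicational <- qsc$communicational_cat
  cohort$physical <- qsc$physical_cat
  cohort
}
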