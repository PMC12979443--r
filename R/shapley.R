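# In-house Shapley attribution of individual predictions. The value
# function is the marginal (interventional) expectation: features absent
# from a coalition are replaced, row by row, by a background sample, and
# the predictor's mean output over those hybrids is the coalition's value.
# Exact mode enumerates all 2^d coalitions (d <= 12); sampled mode averages
# marginal contributions over seeded random permutations and reports a
# per-feature Monte-Carlo standard error.

# Resolve the predictor argument into a row-scoring function over a
# data frame of feature columns.
as_score_fun <- function(predictor) {
  if (inherits(predictor, "trained_predictor"))
    return(function(X) predict(predictor, X))
  if (inherits(predictor, "sync_fit"))
    return(function(X) predict(predictor, X))
  if (is.function(predictor)) return(predictor)
  stop("predictor must be a function or a trained model")
}

# Mean prediction over background rows with the coalition S (logical mask)
# taken from `row` and the rest from the background.
coalition_value <- function(score, row, background, mask) {
  X <- background
  for (j in which(mask)) X[[j]] <- rep(row[[j]], nrow(background))
  mean(score(X))
}

#' Shapley attribution of a single prediction
#'
#' Attributes `prediction - base_value` across features by coalition-game
#' Shapley values. `mode = "exact"` enumerates every coalition (feature
#' count at most 12) and satisfies the efficiency identity
#' `base_value + sum(phi) = prediction` to numerical precision;
#' `mode = "sampled"` uses `n_perm` seeded random permutations and reports
#' a Monte-Carlo standard error per feature.
#'
#' @param predictor A scoring function over a feature data frame, or a
#'   [train_learner()] / [sync_fit()] model.
#' @param row One-row data frame: the prediction to explain.
#' @param background Data frame of background rows (the reference
#'   distribution; e.g. 100 training rows).
#' @param mode `"exact"` or `"sampled"`.
#' @param n_perm Number of permutations for sampled mode.
#' @param seed Integer seed (sampled mode).
#' @return Object of class `"attribution"`: `base_value` (mean background
#'   prediction), `contributions` (named phi vector), `prediction`,
#'   `feature_values`, `mode`, and `mc_se` (sampled mode).
#' @examples
#' f <- function(X) X$x1 + X$x2
#' bg <- data.frame(x1 = 0, x2 = 0)
#' shapley_values(f, data.frame(x1 = 2, x2 = 3), bg)$contributions
#' @export
shapley_values <- function(predictor, row, background,
                           mode = c("exact", "sampled"), n_perm = 256L,
                           seed = 1L) {
  mode <- match.arg(mode)
  score <- as_score_fun(predictor)
  stopifnot(is.data.frame(row), nrow(row) == 1L, is.data.frame(background))
  if (nrow(background) == 0) stop("background sample must be non-empty")
  features <- names(row)
  d <- length(features)
  background <- background[, features, drop = FALSE]
  base_value <- mean(score(background))
  prediction <- score(row)

  if (mode == "exact") {
    if (d > 12) stop("exact mode enumerates 2^d coalitions; use mode = ",
                     "'sampled' for more than 12 features")
    nS <- 2^d
    vals <- numeric(nS)
    sizes <- integer(nS)
    for (s in 0:(nS - 1)) {
      mask <- as.logical(bitwAnd(s, 2^(0:(d - 1))))
      sizes[s + 1] <- sum(mask)
      vals[s + 1] <- if (s == 0) base_value else
        coalition_value(score, row, background, mask)
    }
    wt <- function(sz) factorial(sz) * factorial(d - sz - 1) / factorial(d)
    phi <- numeric(d)
    for (j in seq_len(d)) {
      bit <- 2^(j - 1)
      without <- which(bitwAnd(0:(nS - 1), bit) == 0)
      for (s in without) {
        phi[j] <- phi[j] + wt(sizes[s]) * (vals[s + bit] - vals[s])
      }
    }
    mc_se <- rep(0, d)
  } else {
    contrib <- matrix(0, n_perm, d)
    with_seed(derive_seed(seed, "shapley"), {
      for (p in seq_len(n_perm)) {
        perm <- sample.int(d)
        mask <- rep(FALSE, d)
        v_prev <- base_value
        for (j in perm) {
          mask[j] <- TRUE
          v_now <- coalition_value(score, row, background, mask)
          contrib[p, j] <- v_now - v_prev
          v_prev <- v_now
        }
      }
    })
    phi <- colMeans(contrib)
    mc_se <- apply(contrib, 2, sd) / sqrt(n_perm)
  }
  names(phi) <- features; names(mc_se) <- features
  structure(list(base_value = base_value, contributions = phi,
                 prediction = prediction, feature_values = row,
                 mode = mode, mc_se = mc_se,
                 n_perm = if (mode == "sampled") n_perm else NA_integer_),
            class = "attribution")
}

#' @export
print.attribution <- function(x, ...) {
  cat(sprintf("%s Shapley attribution: base %.4f -> prediction %.4f\n",
              x$mode, x$base_value, x$prediction))
  ord <- order(abs(x$contributions), decreasing = TRUE)
  for (j in ord)
    cat(sprintf("  %-24s phi = %+.4f%s\n", names(x$contributions)[j],
                x$contributions[j],
                if (x$mode == "sampled")
                  sprintf("  (se %.4f)", x$mc_se[j]) else ""))
  invisible(x)
}

#' Global feature importance from a set of attributions
#'
#' Mean absolute Shapley value per feature over a cohort of explained rows,
#' ranked descending (ties broken by feature order) — the summary-plot
#' ranking.
#'
#' @param attributions List of [shapley_values()] results over a common
#'   feature set.
#' @return Object of class `"global_importance"`: `importance` (named
#'   mean-|phi| vector, input order) and `ranking` (feature names, most
#'   important first).
#' @export
global_importance <- function(attributions) {
  stopifnot(length(attributions) >= 1)
  feats <- names(attributions[[1]]$contributions)
  phi <- t(vapply(attributions, function(a) {
    if (!identical(names(a$contributions), feats))
      stop("attributions have inconsistent feature sets")
    a$contributions
  }, numeric(length(feats))))
  imp <- colMeans(abs(phi))
  ord <- order(-imp, seq_along(imp))
  structure(list(importance = imp, ranking = feats[ord]),
            class = "global_importance")
}

#' @export
print.global_importance <- function(x, ...) {
  cat("global importance (mean |phi|):\n")
  for (f in x$ranking)
    cat(sprintf("  %-24s %.4f\n", f, x$importance[f]))
  invisible(x)
}

#' Waterfall, force and decision views of an attribution
#'
#' Restructures one attribution into the three standard per-prediction
#' views: the waterfall (features by descending |phi| with the running
#' cumulative sum from base value to prediction), the force partition
#' (risk-increasing phi > 0 vs risk-decreasing phi < 0), and the decision
#' path (cumulative trajectory in importance order).
#'
#' @param attribution A [shapley_values()] result.
#' @return List with `waterfall` (data frame: feature, value, phi,
#'   cumulative), `force` (list: `increasing`, `decreasing`, named phi
#'   vectors), `decision` (data frame: feature, cumulative).
#' @export
explanation_views <- function(attribution) {
  stopifnot(inherits(attribution, "attribution"))
  phi <- attribution$contributions
  ord <- order(abs(phi), decreasing = TRUE)
  cum <- attribution$base_value + cumsum(phi[ord])
  waterfall <- data.frame(
    feature = names(phi)[ord],
    value = unlist(lapply(attribution$feature_values[ord], as.character)),
    phi = unname(phi[ord]),
    cumulative = unname(cum))
  list(
    waterfall = waterfall,
    force = list(increasing = phi[phi > 0], decreasing = phi[phi < 0]),
    decision = data.frame(feature = names(phi)[ord],
                          cumulative = unname(cum)))
}

#' Dependence-scatter data for one feature, colored by another
#'
#' One (feature value, phi, color value) triple per explained row in cohort
#' order — the data behind a dependence plot stratified by a second
#' feature, used to surface interactions.
#'
#' @param attributions List of attributions over a common feature set.
#' @param feature Feature whose value/phi relationship is examined.
#' @param color_feature Stratifying feature (may equal `feature`).
#' @return Data frame with columns `value`, `phi`, `color`.
#' @export
dependence_data <- function(attributions, feature, color_feature = feature) {
  stopifnot(length(attributions) >= 1)
  feats <- names(attributions[[1]]$contributions)
  if (!feature %in% feats) stop("unknown feature '", feature, "'")
  if (!color_feature %in% feats)
    stop("unknown feature '", color_feature, "'")
  data.frame(
    value = vapply(attributions,
                   function(a) as.numeric(a$feature_values[[feature]]),
                   numeric(1)),
    phi = vapply(attributions, function(a) a$contributions[[feature]],
                 numeric(1)),
    color = vapply(attributions,
                   function(a) as.numeric(a$feature_values[[color_feature]]),
                   numeric(1)))
}
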