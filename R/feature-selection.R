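# Feature ranking (F-score, mRMR) and the cross-validated selection
# combination (FSC).
#
# F-score follows the LIBSVM fselect convention:
#   F(i) = [ (mean_pos - mean_all)^2 + (mean_neg - mean_all)^2 ]
#          / [ var_pos + var_neg ]                 (unbiased class variances)
# with the degenerate cases made total: 0/0 -> 0 (a feature constant
# everywhere carries nothing), x/0 with x > 0 -> +Inf (a perfect separator
# with zero within-class spread sorts first).
#
# mRMR is the MID (mutual-information difference) greedy: the first feature
# maximises MI with the label; each next feature maximises
#   MI(f; y) - mean over selected s of MI(f; s).
# Continuous features are discretised to 3 levels at mean +/- one standard
# deviation before MI estimation; features with <= 3 distinct values (one-hot
# bits, confidence codes) pass through unchanged. MI uses empirical joint
# frequencies and natural logs.

prep_xy <- function(x, y) {
  if (is.data.frame(x)) x <- feature_matrix(x)
  if (!is.matrix(x)) abort("`x` must be a matrix or data frame of features.")
  y <- as_binary_label(y)
  if (length(y) != nrow(x)) abort("`y` must have one label per row of `x`.")
  if (length(unique(y)) < 2) abort("`y` must contain both classes.")
  if (min(table(y)) < 2) abort("Need at least 2 samples per class.")
  list(x = x, y = y)
}

as_binary_label <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.logical(y)) y <- ifelse(y, "positive", "negative")
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) abort("Numeric labels must be 0/1.")
    y <- ifelse(y == 1, "positive", "negative")
  }
  if (!all(y %in% c("positive", "negative"))) {
    abort("Labels must be positive/negative (or logical / 0-1).")
  }
  y
}

#' Rank features by F-score
#'
#' Fisher-style per-feature discriminativeness between the positive and
#' negative class; higher is more discriminative. The ranking is invariant
#' to sample order and to swapping the two class labels.
#'
#' @param x Feature matrix, or an encoded window tibble (bookkeeping columns
#'   are dropped automatically).
#' @param y Labels: positive/negative strings, a factor, logical, or 0/1.
#'   May be omitted when `x` is a tibble with a `label` column.
#' @return A ranking tibble: `rank`, `feature_index`, `feature_name`,
#'   `method`, `score`, sorted by score descending (ties by feature index).
#' @export
#' @examples
#' fscore_rank(matrix(c(1, 2, 3, 4), ncol = 1), c(1, 1, 0, 0))
fscore_rank <- function(x, y = NULL) {
  if (is.null(y) && is.data.frame(x) && "label" %in% names(x)) y <- x$label
  d <- prep_xy(x, y)
  pos <- d$y == "positive"
  x <- d$x
  mean_all <- colMeans(x)
  mean_pos <- colMeans(x[pos, , drop = FALSE])
  mean_neg <- colMeans(x[!pos, , drop = FALSE])
  var_pos <- apply(x[pos, , drop = FALSE], 2, var)
  var_neg <- apply(x[!pos, , drop = FALSE], 2, var)
  num <- (mean_pos - mean_all)^2 + (mean_neg - mean_all)^2
  den <- var_pos + var_neg
  score <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  ranking_tibble(score, colnames(x), "fscore",
                 order(score, seq_along(score), decreasing = c(TRUE, FALSE),
                       method = "radix"))
}

ranking_tibble <- function(scores, names, method, ord) {
  if (is.null(names)) names <- paste0("f", seq_along(scores))
  tibble(
    rank = seq_along(ord),
    feature_index = as.integer(ord),
    feature_name = names[ord],
    method = method,
    score = unname(scores[ord])
  )
}

# 3-level discretisation at mean +/- sd; low-cardinality columns pass through
# as integer codes.
discretize_features <- function(x) {
  apply(x, 2, function(col) {
    u <- unique(col)
    if (length(u) <= 3) return(match(col, sort(u)))
    s <- stats::sd(col)
    if (s == 0) return(rep(1L, length(col)))
    m <- mean(col)
    findInterval(col, c(m - s, m + s)) + 1L
  })
}

mutual_information <- function(a, b) {
  joint <- table(a, b) / length(a)
  pa <- rowSums(joint)
  pb <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(pa, pb)[nz]))
}

#' Rank features by mRMR (minimum redundancy, maximum relevance)
#'
#' Greedy MID ordering: relevance is mutual information with the label;
#' redundancy is the mean mutual information with the already-selected
#' features. Ties break towards the lower feature index, so the ordering is
#' deterministic.
#'
#' @inheritParams fscore_rank
#' @param k Number of features to rank (default: all).
#' @return A ranking tibble as in [fscore_rank()]; `score` is the greedy-step
#'   objective (relevance minus mean redundancy) at selection time.
#' @export
mrmr_rank <- function(x, y = NULL, k = NULL) {
  if (is.null(y) && is.data.frame(x) && "label" %in% names(x)) y <- x$label
  d <- prep_xy(x, y)
  p <- ncol(d$x)
  k <- k %||% p
  if (k > p) abort(paste0("`k` (", k, ") exceeds the feature count (", p, ")."))
  if (k < 1) abort("`k` must be at least 1.")
  xd <- discretize_features(d$x)
  y <- d$y
  relevance <- apply(xd, 2, mutual_information, b = y)
  selected <- integer(0)
  red_sum <- numeric(p)
  obj <- numeric(k)
  remaining <- seq_len(p)
  for (step in seq_len(k)) {
    crit <- if (step == 1) {
      relevance[remaining]
    } else {
      relevance[remaining] - red_sum[remaining] / (step - 1)
    }
    pick <- remaining[which.max(crit)]   # which.max: first max -> lowest index
    obj[step] <- max(crit)
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) > 0 && step < k) {
      red_sum[remaining] <- red_sum[remaining] + apply(
        xd[, remaining, drop = FALSE], 2, mutual_information, b = xd[, pick]
      )
    }
  }
  ranking_tibble(
    setNames(numeric(p), NULL), colnames(d$x), "mrmr", selected
  ) |>
    mutate(score = obj)
}

#' Select a feature subset by cross-validated MCC over nested rankings (FSC)
#'
#' For each ranking method (F-score and mRMR) and each subset size `k` in the
#' grid, the top-`k` features are scored by mean cross-validated MCC under
#' the given classifier; the all-features baseline always enters the
#' comparison, so the winner never scores below it. Ties break towards fewer
#' features, then towards the F-score family.
#'
#' @inheritParams fscore_rank
#' @param k_grid Candidate subset sizes (default `c(25, 50, 100, 200, 400,
#'   903)`, truncated to the feature count).
#' @param spec A [classifier_spec()] used for the CV scoring.
#' @param folds,rounds Cross-validation folds (default 5) and rounds
#'   (default 1).
#' @param seed Seed controlling fold assignment and classifier fits.
#' @return An `fsc_selection`: `indices` (the chosen features), `method`,
#'   `k`, `cv_mcc`, and `grid` (the full comparison table). [tidy()] returns
#'   the grid, [glance()] the chosen row.
#' @export
fsc_select <- function(x, y = NULL, k_grid = c(25, 50, 100, 200, 400, 903),
                       spec = classifier_spec(), folds = 5, rounds = 1,
                       seed = NULL) {
  if (is.null(y) && is.data.frame(x) && "label" %in% names(x)) y <- x$label
  d <- prep_xy(x, y)
  p <- ncol(d$x)
  k_grid <- sort(unique(pmin(k_grid, p)))
  data <- bind_cols(
    tibble(label = d$y),
    as_tibble(d$x, .name_repair = "minimal")
  )
  rankings <- list(
    fscore = fscore_rank(d$x, d$y),
    mrmr = mrmr_rank(d$x, d$y, k = max(k_grid))
  )
  cv_for <- function(idx, tag) {
    cv <- cross_validate(data, spec = spec, folds = folds, rounds = rounds,
                         feature_idx = idx, seed = seed)
    tibble(method = tag$method, k = tag$k, cv_mcc = cv$summary$mcc,
           indices = list(idx))
  }
  combos <- tidyr::expand_grid(method = names(rankings), k = k_grid)
  grid <- bind_rows(
    purrr::pmap(combos, function(method, k) {
      idx <- rankings[[method]]$feature_index[seq_len(k)]
      cv_for(idx, list(method = method, k = k))
    }),
    cv_for(seq_len(p), list(method = "all", k = p))
  )
  # winner: max CV MCC; ties -> fewer features -> fscore before mrmr before all
  pref <- match(grid$method, c("fscore", "mrmr", "all"))
  best <- order(-grid$cv_mcc, grid$k, pref)[1]
  structure(
    list(
      indices = sort(grid$indices[[best]]),
      method = grid$method[best],
      k = grid$k[best],
      cv_mcc = grid$cv_mcc[best],
      grid = select(grid, -"indices"),
      rankings = rankings
    ),
    class = "fsc_selection"
  )
}

#' @export
print.fsc_selection <- function(x, ...) {
  cat(sprintf(
    "<fsc_selection> %d features via %s (k = %d), CV MCC = %.3f\n",
    length(x$indices), x$method, x$k, x$cv_mcc
  ))
  invisible(x)
}

#' @describeIn fsc_select The (method, k) comparison grid with CV MCC.
#' @param x An `fsc_selection`.
#' @param ... Unused.
#' @export
tidy.fsc_selection <- function(x, ...) x$grid

#' @describeIn fsc_select One-row tibble describing the chosen subset.
#' @export
glance.fsc_selection <- function(x, ...) {
  tibble(method = x$method, k = x$k, n_features = length(x$indices),
         cv_mcc = x$cv_mcc)
}

#' Write a feature ranking to TSV
#'
#' @param ranking A ranking tibble from [fscore_rank()] or [mrmr_rank()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  write_tsv_with_header(ranking, path)
}
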