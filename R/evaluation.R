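# Threshold metrics, the balanced 20-cycle testing protocol, repeated
# stratified cross-validation, CN+CY confusion recombination, and ROC curves.
#
# All five threshold metrics derive from the confusion counts:
#   Sn  = TP / (TP + FN)                     Sp  = TN / (TN + FP)
#   Precision = TP / (TP + FP)               ACC = (TP + TN) / total
#   MCC = (TP*TN - FN*FP) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))
# MCC with any zero factor in the denominator is defined as 0 (the usual
# convention); an undefined Sn/Sp/Precision (zero denominator) is NA and is
# excluded from protocol means.

#' Threshold classification metrics from confusion counts
#'
#' Computes sensitivity, specificity, precision, accuracy and the Matthews
#' correlation coefficient. Vectorised over counts.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts. Alternatively pass a
#'   data frame with columns `tp`, `fp`, `tn`, `fn` as `tp`.
#' @return A tibble with columns `tp`, `fp`, `tn`, `fn`, `sn`, `sp`,
#'   `precision`, `acc`, `mcc`.
#' @export
#' @examples
#' site_metrics(tp = 2, fp = 1, tn = 3, fn = 1)  # MCC = 5/12
site_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.data.frame(tp)) {
    counts <- tp
    if (!all(c("tp", "fp", "tn", "fn") %in% names(counts))) {
      abort("Count data frame must have columns tp, fp, tn, fn.")
    }
    tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  }
  counts <- cbind(tp, fp, tn, fn)
  if (any(is.na(counts)) || any(counts < 0)) {
    abort("Confusion counts must be non-negative.")
  }
  tp <- as.double(tp); fp <- as.double(fp)
  tn <- as.double(tn); fn <- as.double(fn)
  sn <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  sp <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  total <- tp + fp + tn + fn
  acc <- ifelse(total > 0, (tp + tn) / total, NA_real_)
  denom <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  mcc <- ifelse(denom > 0, (tp * tn - fn * fp) / sqrt(denom), 0)
  tibble(tp = tp, fp = fp, tn = tn, fn = fn,
         sn = sn, sp = sp, precision = precision, acc = acc, mcc = mcc)
}

confusion_from <- function(truth, predicted) {
  tibble(
    tp = sum(truth == "positive" & predicted == "positive"),
    fp = sum(truth == "negative" & predicted == "positive"),
    tn = sum(truth == "negative" & predicted == "negative"),
    fn = sum(truth == "positive" & predicted == "negative")
  )
}

#' Combine CN and CY confusion counts
#'
#' Element-wise sum of the two submodels' confusion counts from the same
#' evaluation split, followed by metric recomputation on the sum — the
#' recombination used to report one figure for the paired-model system.
#'
#' @param cn,cy One-row data frames (or named lists) with `tp`, `fp`, `tn`,
#'   `fn`.
#' @return A one-row metrics tibble for the summed counts.
#' @export
combine_cncy <- function(cn, cy) {
  site_metrics(
    tp = cn$tp + cy$tp, fp = cn$fp + cy$fp,
    tn = cn$tn + cy$tn, fn = cn$fn + cy$fn
  )
}

#' Balanced repeated-subsampling evaluation (the 20-cycle protocol)
#'
#' Scores every supplied window once with the trained model, then runs
#' `cycles` evaluation cycles: each cycle keeps all positives and a fresh
#' seeded draw of `round(n_pos * ratio)` negatives without replacement
#' (independent across cycles), accumulates confusion counts at the score
#' threshold, and computes the five metrics. The headline figure is the mean
#' over cycles; a pooled row (counts summed over cycles, metrics recomputed)
#' is also reported.
#'
#' @param model A trained model from [train_cncy()], any object with a
#'   compatible `predict` method returning a `predicted_label` column, or a
#'   function `f(data, threshold)` returning such a tibble.
#' @param data Encoded window tibble with `label` in {positive, negative}.
#' @param cycles Number of cycles (default 20).
#' @param ratio Negatives drawn per positive (default 1, i.e. a 1:1 balance;
#'   accepts "1:1" strings).
#' @param threshold Score threshold for calling a site positive (default
#'   0.5).
#' @param seed Seed controlling the negative draws.
#' @return An `eval_report`: use [tidy()] for per-cycle rows, [glance()] for
#'   the mean row, [autoplot()] for a per-cycle MCC plot.
#' @export
evaluate_cycles <- function(model, data, cycles = 20, ratio = 1,
                            threshold = 0.5, seed = NULL) {
  ratio <- parse_ratio(ratio)
  if (!all(data$label %in% c("positive", "negative"))) {
    abort("`data` labels must all be positive or negative.")
  }
  preds <- if (is.function(model)) {
    model(data, threshold)
  } else {
    predict(model, data, threshold = threshold)
  }
  pos_idx <- which(data$label == "positive")
  neg_idx <- which(data$label == "negative")
  if (length(pos_idx) == 0) abort("No positive windows to evaluate.")
  n_draw <- round(length(pos_idx) * ratio)
  if (n_draw > length(neg_idx)) {
    warn(paste0(
      "Only ", length(neg_idx), " negatives available; each cycle uses all ",
      "of them instead of the requested ", n_draw, "."
    ))
    n_draw <- length(neg_idx)
  }
  cycle_seeds <- vapply(seq_len(cycles), function(i) {
    s <- derive_seed(seed, i)
    if (is.null(s)) NA_integer_ else s
  }, integer(1))
  rows <- purrr::map(seq_len(cycles), function(i) {
    draw <- with_seed(
      if (is.na(cycle_seeds[i])) NULL else cycle_seeds[i],
      sample(neg_idx, n_draw)
    )
    idx <- c(pos_idx, draw)
    counts <- confusion_from(data$label[idx], preds$predicted_label[idx])
    mutate(site_metrics(counts), cycle = i, .before = 1)
  })
  per_cycle <- bind_rows(rows)
  metric_cols <- c("sn", "sp", "precision", "acc", "mcc")
  mean_row <- summarise(
    per_cycle,
    across(all_of(c("tp", "fp", "tn", "fn")), mean),
    across(all_of(metric_cols), ~ mean(.x, na.rm = TRUE))
  )
  pooled <- site_metrics(
    tp = sum(per_cycle$tp), fp = sum(per_cycle$fp),
    tn = sum(per_cycle$tn), fn = sum(per_cycle$fn)
  )
  structure(
    list(
      per_cycle = per_cycle,
      mean = mean_row,
      pooled = pooled,
      cycle_seeds = cycle_seeds,
      protocol = list(cycles = cycles, ratio = ratio, threshold = threshold,
                      seed = seed, n_pos = length(pos_idx), n_draw = n_draw)
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  p <- x$protocol
  cat(sprintf(
    "<eval_report> %d cycles, 1:%g P/N balance, threshold %g (%d positives/cycle)\n",
    p$cycles, p$ratio, p$threshold, p$n_pos
  ))
  m <- x$mean
  cat(sprintf(
    "  mean: Sn %.3f  Sp %.3f  Precision %.3f  ACC %.3f  MCC %.3f\n",
    m$sn, m$sp, m$precision, m$acc, m$mcc
  ))
  invisible(x)
}

#' @describeIn evaluate_cycles Per-cycle counts and metrics as a tibble.
#' @param x An `eval_report`.
#' @param ... Unused.
#' @export
tidy.eval_report <- function(x, ...) x$per_cycle

#' @describeIn evaluate_cycles One-row summary: mean metrics over cycles plus
#'   the pooled-count MCC.
#' @export
glance.eval_report <- function(x, ...) {
  bind_cols(
    x$mean[, c("sn", "sp", "precision", "acc", "mcc")],
    tibble(mcc_pooled = x$pooled$mcc, cycles = x$protocol$cycles,
           ratio = x$protocol$ratio)
  )
}

#' @describeIn evaluate_cycles Per-cycle MCC plot with the mean as a line.
#' @param object An `eval_report`.
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object$per_cycle, ggplot2::aes(x = .data$cycle, y = .data$mcc)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = object$mean$mcc, colour = "firebrick",
                        linetype = 2) +
    ggplot2::labs(x = "cycle", y = "MCC",
                  title = sprintf("Mean MCC %.3f over %d balanced cycles",
                                  object$mean$mcc, object$protocol$cycles)) +
    ggplot2::theme_minimal()
}

#' Write an evaluation report to TSV (per-cycle rows + mean and pooled rows)
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  out <- bind_rows(
    mutate(report$per_cycle, row = as.character(.data$cycle)),
    mutate(bind_cols(tibble(cycle = NA_integer_), report$mean), row = "mean"),
    mutate(bind_cols(tibble(cycle = NA_integer_), report$pooled), row = "pooled")
  )
  write_tsv_with_header(
    select(out, "row", dplyr::everything(), -"cycle"),
    path, seed = report$protocol$seed, config = report$protocol
  )
}

#' Repeated stratified k-fold cross-validation
#'
#' Fold assignment is stratified by class and re-randomised every round.
#' Within a round, out-of-fold predictions are pooled into one confusion
#' matrix; metrics are computed per round and averaged over rounds.
#'
#' @param data Encoded window tibble with `label` in {positive, negative}
#'   (or any tibble whose non-bookkeeping columns are features).
#' @param spec A [classifier_spec()].
#' @param folds Number of folds (default 5).
#' @param rounds Number of re-randomised rounds (default 1; the full
#'   protocol uses 30).
#' @param feature_idx Optional integer vector restricting to a feature
#'   subset (1-based into the feature columns).
#' @param threshold Score threshold (default 0.5).
#' @param seed Seed for fold assignment and classifier fits.
#' @return A list: `summary` (one-row tibble of mean metrics), `rounds`
#'   (per-round metrics tibble).
#' @export
cross_validate <- function(data, spec = classifier_spec(), folds = 5,
                           rounds = 1, feature_idx = NULL, threshold = 0.5,
                           seed = NULL) {
  X <- feature_matrix(data)
  if (!is.null(feature_idx)) X <- X[, feature_idx, drop = FALSE]
  y <- data$label
  if (!all(y %in% c("positive", "negative"))) {
    abort("`data` labels must all be positive or negative.")
  }
  n_by_class <- table(y)
  if (length(n_by_class) < 2 || any(n_by_class < folds)) {
    abort(paste0("Each class needs at least `folds` = ", folds, " members."))
  }
  round_rows <- purrr::map(seq_len(rounds), function(r) {
    fold_id <- with_seed(derive_seed(seed, r), stratified_folds(y, folds))
    counts <- list(tp = 0, fp = 0, tn = 0, fn = 0)
    for (f in seq_len(folds)) {
      test <- fold_id == f
      fit <- fit_classifier(X[!test, , drop = FALSE], y[!test], spec,
                            seed = derive_seed(seed, r * 1000L + f))
      scores <- predict_scores(fit, X[test, , drop = FALSE])
      pred <- ifelse(scores >= threshold, "positive", "negative")
      cc <- confusion_from(y[test], pred)
      counts <- purrr::map2(counts, cc, `+`)
    }
    mutate(site_metrics(counts$tp, counts$fp, counts$tn, counts$fn),
           round = r, .before = 1)
  })
  per_round <- bind_rows(round_rows)
  metric_cols <- c("sn", "sp", "precision", "acc", "mcc")
  summary <- summarise(per_round,
                       across(all_of(metric_cols), ~ mean(.x, na.rm = TRUE)))
  list(summary = summary, rounds = per_round)
}

stratified_folds <- function(y, folds) {
  fold_id <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

#' ROC curve and area under the curve
#'
#' Standard threshold sweep over the distinct scores; AUC by the trapezoid
#' rule.
#'
#' @param scores Numeric prediction scores.
#' @param labels Labels in {positive, negative} (or a logical/0-1 vector).
#' @return A `roc_result`: `points` (tibble of `threshold`, `fpr`, `tpr`)
#'   and `auc`. [tidy()] returns the points, [glance()] the AUC,
#'   [autoplot()] draws the curve.
#' @export
roc_curve <- function(scores, labels) {
  if (is.logical(labels) || is.numeric(labels)) {
    labels <- ifelse(as.logical(labels), "positive", "negative")
  }
  if (length(unique(labels)) < 2) {
    abort("ROC needs both classes present in `labels`.")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- labels[ord] == "positive"
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  cum_tp <- cumsum(pos)
  cum_fp <- cumsum(!pos)
  last <- c(diff(s) != 0, TRUE)   # one point per distinct score
  points <- tibble(
    threshold = c(Inf, s[last]),
    tpr = c(0, cum_tp[last] / n_pos),
    fpr = c(0, cum_fp[last] / n_neg)
  )
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + points$tpr[-1]) / 2)
  structure(list(points = points, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d points)\n", x$auc, nrow(x$points)))
  invisible(x)
}

#' @describeIn roc_curve ROC points as a tibble.
#' @param x,object A `roc_result`.
#' @param ... Unused.
#' @export
tidy.roc_result <- function(x, ...) x$points

#' @describeIn roc_curve One-row tibble with the AUC.
#' @export
glance.roc_result <- function(x, ...) tibble(auc = x$auc)

#' @describeIn roc_curve ROC plot.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Write ROC points to TSV
#'
#' @param roc A `roc_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roc <- function(roc, path) {
  write_tsv_with_header(roc$points, path)
}
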