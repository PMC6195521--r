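# Ratio-controlled negative sampling, CN/CY submodel training with candidate
# resampling, routing prediction, persistence, and the pooled-model
# comparison harness.
#
# Each submodel sees only its motif partition. All positives of the
# partition are kept; negatives are drawn at the configured P/N ratio. The
# draw is repeated `n_candidates` times; each candidate model is scored by
# stratified CV MCC on its own training draw and the best candidate is
# refitted on that draw in full. Prediction routes every window to the
# submodel matching its motif class.

#' Classifier specification
#'
#' Frozen defaults for the two supported learners: random forest (100 trees,
#' probability by out-of-bag vote fraction) and an RBF support-vector
#' machine (C = 1, gamma = 1/n_features, Platt-scaled probability output).
#'
#' @param method `"random_forest"` (default) or `"svm"`.
#' @param ... Overrides: `ntree` for the forest; `cost`, `gamma` for the
#'   SVM.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(method = c("random_forest", "svm"), ...) {
  method <- match.arg(method)
  defaults <- switch(method,
    random_forest = list(ntree = 100),
    svm = list(cost = 1, gamma = NULL)
  )
  structure(
    c(list(method = method), modifyList(defaults, list(...))),
    class = "classifier_spec"
  )
}

fit_classifier <- function(X, y, spec = classifier_spec(), seed = NULL) {
  y <- factor(as_binary_label(y), levels = c("negative", "positive"))
  if (nlevels(droplevels(y)) < 2) {
    abort("Training data must contain both classes.")
  }
  # constant columns break svm scaling; drop them symmetrically at predict
  keep <- which(apply(X, 2, function(c) any(c != c[1])))
  fit <- with_seed(seed, {
    if (spec$method == "random_forest") {
      randomForest::randomForest(
        x = X[, keep, drop = FALSE], y = y, ntree = spec$ntree
      )
    } else {
      e1071::svm(
        x = X[, keep, drop = FALSE], y = y, kernel = "radial",
        cost = spec$cost, gamma = spec$gamma %||% (1 / max(length(keep), 1)),
        probability = TRUE
      )
    }
  })
  structure(list(fit = fit, spec = spec, keep = keep, p = ncol(X)),
            class = "sumo_classifier")
}

predict_scores <- function(object, X) {
  if (ncol(X) != object$p) {
    abort(paste0("Encoding dimension mismatch: model expects ", object$p,
                 " features, got ", ncol(X), "."))
  }
  X <- X[, object$keep, drop = FALSE]
  if (object$spec$method == "random_forest") {
    unname(predict(object$fit, X, type = "prob")[, "positive"])
  } else {
    pr <- predict(object$fit, X, probability = TRUE)
    unname(attr(pr, "probabilities")[, "positive"])
  }
}

#' Sample negatives at a P/N ratio
#'
#' Uniform draw without replacement of `round(n_pos * ratio)` rows. If fewer
#' negatives are available than requested, all of them are returned with a
#' warning (sampling with replacement would duplicate feature rows and bias
#' cross-validation).
#'
#' @param negatives A tibble (or vector) of negative examples.
#' @param n_pos Number of positives the draw is matched to (> 0).
#' @param ratio Negatives per positive: `2`, `"1:2"`, etc.
#' @param seed Seed for the draw.
#' @return The sampled rows (same type as `negatives`).
#' @export
sample_negatives <- function(negatives, n_pos, ratio = 1, seed = NULL) {
  n_avail <- if (is.data.frame(negatives)) nrow(negatives) else length(negatives)
  if (n_avail == 0) abort("`negatives` is empty.")
  if (n_pos <= 0) abort("`n_pos` must be positive.")
  n <- round(n_pos * parse_ratio(ratio))
  if (n > n_avail) {
    warn(paste0("Requested ", n, " negatives but only ", n_avail,
                " available; returning all of them."))
    n <- n_avail
  }
  idx <- with_seed(seed, sample(n_avail, n))
  if (is.data.frame(negatives)) negatives[idx, ] else negatives[idx]
}

#' Training configuration for the paired CN/CY system
#'
#' @param motif Consensus-motif variant, `"C1"` ... `"C6"` (default `"C1"`).
#' @param ratio_cn P/N ratio for the non-conforming (CN) submodel (default
#'   `"1:2"`).
#' @param ratio_cy P/N ratio for the conforming (CY) submodel (default
#'   `"1:1"`).
#' @param classifier A [classifier_spec()].
#' @param n_candidates Number of seeded negative-resampling candidates per
#'   submodel, each scored by CV MCC (default 500; use a handful for quick
#'   runs).
#' @param cv_folds,cv_rounds Cross-validation folds/rounds used to score
#'   candidates (and FSC subsets).
#' @param fsc `NULL` to train on all 903 features, or a list of arguments
#'   for [fsc_select()] (e.g. `list(k_grid = c(50, 200))`) to run feature
#'   selection per submodel on its first candidate draw.
#' @param threshold Score threshold for predicted labels (default 0.5).
#' @param seed Master seed; all draws and fits derive from it.
#' @return A `training_config` list.
#' @export
training_config <- function(motif = "C1", ratio_cn = "1:2", ratio_cy = "1:1",
                            classifier = classifier_spec(),
                            n_candidates = 500, cv_folds = 5, cv_rounds = 1,
                            fsc = NULL, threshold = 0.5, seed = NULL) {
  if (n_candidates < 1) abort("`n_candidates` must be at least 1.")
  structure(
    list(
      motif = motif_def(motif)$id,
      ratio_cn = parse_ratio(ratio_cn), ratio_cy = parse_ratio(ratio_cy),
      classifier = classifier, n_candidates = n_candidates,
      cv_folds = cv_folds, cv_rounds = cv_rounds, fsc = fsc,
      threshold = threshold, seed = seed
    ),
    class = "training_config"
  )
}

train_submodel <- function(part, ratio, config, seed_base) {
  pos <- filter(part, .data$label == "positive")
  neg <- filter(part, .data$label == "negative")
  sel <- NULL
  feature_idx <- NULL
  if (!is.null(config$fsc)) {
    fsc_draw <- bind_rows(
      pos, sample_negatives(neg, nrow(pos), ratio,
                            seed = derive_seed(seed_base, 0L))
    )
    sel <- rlang::exec(
      fsc_select, fsc_draw, fsc_draw$label,
      !!!config$fsc,
      spec = config$classifier, folds = config$cv_folds,
      rounds = config$cv_rounds, seed = derive_seed(seed_base, 1L)
    )
    feature_idx <- sel$indices
  }
  best <- NULL
  for (i in seq_len(config$n_candidates)) {
    draw <- bind_rows(
      pos, sample_negatives(neg, nrow(pos), ratio,
                            seed = derive_seed(seed_base, 10L + i))
    )
    # candidate scoring needs >= folds members per class; a partition too
    # small to cross-validate falls back to the first draw
    cv_mcc <- if (min(table(draw$label)) >= config$cv_folds) {
      cross_validate(
        draw, spec = config$classifier, folds = config$cv_folds,
        rounds = config$cv_rounds, feature_idx = feature_idx,
        threshold = config$threshold, seed = derive_seed(seed_base, 1000L + i)
      )$summary$mcc
    } else {
      NA_real_
    }
    if (is.null(best) ||
        (!is.na(cv_mcc) && (is.na(best$cv_mcc) || cv_mcc > best$cv_mcc))) {
      best <- list(draw = draw, cv_mcc = cv_mcc, candidate = i)
    }
  }
  X <- feature_matrix(best$draw)
  if (!is.null(feature_idx)) X <- X[, feature_idx, drop = FALSE]
  fit <- fit_classifier(X, best$draw$label, config$classifier,
                        seed = derive_seed(seed_base, 5000L + best$candidate))
  list(
    fit = fit, feature_idx = feature_idx, fsc = sel,
    cv_mcc = best$cv_mcc, candidate = best$candidate,
    n_pos = nrow(pos), n_neg = sum(best$draw$label == "negative")
  )
}

#' Train the paired CN/CY motif-screening model
#'
#' Partitions the encoded windows by motif class, then trains one classifier
#' per partition: the CY submodel on motif-conforming sites at `ratio_cy`
#' (default 1:1), the CN submodel on non-conforming sites at `ratio_cn`
#' (default 1:2). Per submodel, `n_candidates` negative draws are each
#' scored by stratified CV MCC and the best candidate is kept. The two
#' submodels never see each other's partition.
#'
#' @param data Encoded window tibble ([encode_windows()]) with labels in
#'   {positive, negative}.
#' @param config A [training_config()].
#' @return A `cncy_model` with submodels `cn` and `cy`, the config, and
#'   training metadata. Use [predict()][predict.cncy_model], [tidy()],
#'   [glance()], [save_cncy_model()].
#' @export
train_cncy <- function(data, config = training_config()) {
  parts <- partition_windows(data, config$motif)
  model <- list(config = config, layout_version = LAYOUT_VERSION,
                physchem_hash = hash_of(physchem_table()))
  for (cls in c("cn", "cy")) {
    part <- filter(parts, .data$motif_class == toupper(cls))
    if (!all(c("positive", "negative") %in% part$label)) {
      abort(paste0(
        "The ", toupper(cls), " partition needs both positives and negatives ",
        "(has ", sum(part$label == "positive"), " positives, ",
        sum(part$label == "negative"), " negatives)."
      ))
    }
    ratio <- if (cls == "cn") config$ratio_cn else config$ratio_cy
    offset <- if (cls == "cn") 1L else 2L
    model[[cls]] <- train_submodel(
      part, ratio, config,
      seed_base = derive_seed(config$seed %||% 0L, offset * 100003L)
    )
  }
  structure(model, class = "cncy_model")
}

#' @export
print.cncy_model <- function(x, ...) {
  cat(sprintf(
    "<cncy_model> motif %s, %s classifier\n", x$config$motif,
    x$config$classifier$method
  ))
  for (cls in c("cn", "cy")) {
    s <- x[[cls]]
    cat(sprintf(
      "  %s: 1:%g P/N (%d pos / %d neg), %s, candidate CV MCC %.3f\n",
      toupper(cls),
      if (cls == "cn") x$config$ratio_cn else x$config$ratio_cy,
      s$n_pos, s$n_neg,
      if (is.null(s$feature_idx)) "all 903 features"
      else paste0(length(s$feature_idx), " selected features"),
      s$cv_mcc
    ))
  }
  invisible(x)
}

#' @describeIn train_cncy Per-submodel summary rows.
#' @param x A `cncy_model`.
#' @param ... Unused.
#' @export
tidy.cncy_model <- function(x, ...) {
  purrr::map_dfr(c("cn", "cy"), function(cls) {
    s <- x[[cls]]
    tibble(
      submodel = toupper(cls),
      ratio = if (cls == "cn") x$config$ratio_cn else x$config$ratio_cy,
      n_pos = s$n_pos, n_neg = s$n_neg,
      n_features = length(s$feature_idx %||% integer(0)) %0% 903L,
      cv_mcc = s$cv_mcc, best_candidate = s$candidate
    )
  })
}

`%0%` <- function(a, b) if (identical(a, 0L)) b else a

#' @describeIn train_cncy One-row model summary.
#' @export
glance.cncy_model <- function(x, ...) {
  tibble(
    motif = x$config$motif, classifier = x$config$classifier$method,
    ratio_cn = x$config$ratio_cn, ratio_cy = x$config$ratio_cy,
    n_candidates = x$config$n_candidates,
    cv_mcc_cn = x$cn$cv_mcc, cv_mcc_cy = x$cy$cv_mcc
  )
}

#' Predict SUMOylation for encoded windows
#'
#' Each window is classified under the model's motif grammar and scored by
#' the submodel matching its class; a CY window never touches the CN
#' submodel and vice versa.
#'
#' @param object A `cncy_model`.
#' @param data Encoded window tibble with the same 903-column layout the
#'   model was trained on.
#' @param threshold Score threshold for `predicted_label` (default: the
#'   training config's threshold).
#' @param ... Unused.
#' @return A tibble: `protein_id`, `center_pos`, `motif_class`, `score`,
#'   `predicted_label`.
#' @export
predict.cncy_model <- function(object, data, threshold = NULL, ...) {
  threshold <- threshold %||% object$config$threshold
  routed <- classify_sites(data, object$config$motif)
  X <- feature_matrix(data)
  score <- rep(NA_real_, nrow(data))
  for (cls in c("cn", "cy")) {
    rows <- which(routed$motif_class == toupper(cls))
    if (length(rows) == 0) next
    sub <- object[[cls]]
    expected <- if (is.null(sub$feature_idx)) sub$fit$p else max(sub$feature_idx)
    if (ncol(X) < expected) {
      abort(paste0("Encoding dimension mismatch: the ", toupper(cls),
                   " submodel expects at least ", expected,
                   " feature columns, got ", ncol(X), "."))
    }
    Xs <- X[rows, , drop = FALSE]
    if (!is.null(sub$feature_idx)) Xs <- Xs[, sub$feature_idx, drop = FALSE]
    score[rows] <- predict_scores(sub$fit, Xs)
  }
  tibble(
    protein_id = data$protein_id,
    center_pos = data$center_pos,
    motif_class = routed$motif_class,
    score = score,
    predicted_label = ifelse(score >= threshold, "positive", "negative")
  )
}

#' Save / load a trained CN/CY model archive
#'
#' The archive records the encoding layout version and the hash of the
#' physicochemical table alongside the fitted submodels; loading refuses an
#' archive whose layout or table differs from the running package's, so a
#' model can never silently score mis-aligned encodings.
#'
#' @param model A `cncy_model`.
#' @param path Archive path (an `.rds` file).
#' @return `save_cncy_model`: `path`, invisibly. `load_cncy_model`: the
#'   `cncy_model`.
#' @export
save_cncy_model <- function(model, path) {
  saveRDS(
    list(layout_version = model$layout_version,
         physchem_hash = model$physchem_hash, model = model),
    path
  )
  invisible(path)
}

#' @rdname save_cncy_model
#' @export
load_cncy_model <- function(path) {
  arch <- readRDS(path)
  if (!identical(arch$layout_version, LAYOUT_VERSION)) {
    abort(paste0(
      "Model archive uses encoding layout version ", arch$layout_version,
      "; this package uses ", LAYOUT_VERSION, ". Retrain before predicting."
    ))
  }
  if (!identical(arch$physchem_hash, hash_of(physchem_table()))) {
    abort(paste0(
      "Model archive was trained under a different physicochemical table ",
      "(hash mismatch). Point physchem_table() at the matching table or retrain."
    ))
  }
  arch$model
}

#' Write predictions to TSV
#'
#' @param predictions Tibble from [predict.cncy_model()].
#' @param path Output path.
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path, seed = NULL) {
  write_tsv_with_header(predictions, path, seed = seed)
}

#' Compare the paired CN/CY system against a single pooled model
#'
#' Splits the data into a training and held-out part (stratified by label),
#' trains (a) the CN/CY pair and (b) one undivided model on the pooled
#' training windows at `pooled_ratio`, and evaluates both on the identical
#' held-out windows: per-partition confusion counts summed for the paired
#' arm, plain counts for the pooled arm.
#'
#' @param data Encoded window tibble with labels.
#' @param config A [training_config()].
#' @param holdout Fraction of each class held out for testing (default 0.3).
#' @param pooled_ratio P/N ratio of the pooled arm (default `"1:2"`).
#' @param seed Seed for the split (training draws derive from
#'   `config$seed`).
#' @return A list: `comparison` (two-row metrics tibble, arms `cncy` and
#'   `pooled`), `holdout_ids` (the evaluated windows).
#' @export
compare_nocncy <- function(data, config = training_config(), holdout = 0.3,
                           pooled_ratio = "1:2", seed = NULL) {
  y <- data$label
  test_idx <- with_seed(derive_seed(seed %||% config$seed, 77L), {
    unlist(lapply(c("positive", "negative"), function(cls) {
      idx <- which(y == cls)
      sample(idx, max(1L, round(length(idx) * holdout)))
    }))
  })
  train <- data[-test_idx, ]
  test <- data[test_idx, ]

  cncy <- train_cncy(train, config)
  pred_cncy <- predict(cncy, test)
  counts_by_class <- lapply(c("CN", "CY"), function(cls) {
    rows <- pred_cncy$motif_class == cls
    confusion_from(test$label[rows], pred_cncy$predicted_label[rows])
  })
  cncy_metrics <- combine_cncy(counts_by_class[[1]], counts_by_class[[2]])

  pos <- filter(train, .data$label == "positive")
  neg <- filter(train, .data$label == "negative")
  pooled_draw <- bind_rows(
    pos, sample_negatives(neg, nrow(pos), pooled_ratio,
                          seed = derive_seed(config$seed %||% 0L, 88L))
  )
  X <- feature_matrix(pooled_draw)
  pooled_fit <- fit_classifier(X, pooled_draw$label, config$classifier,
                               seed = derive_seed(config$seed %||% 0L, 89L))
  pooled_scores <- predict_scores(pooled_fit, feature_matrix(test))
  pooled_pred <- ifelse(pooled_scores >= config$threshold,
                        "positive", "negative")
  pooled_metrics <- site_metrics(confusion_from(test$label, pooled_pred))

  list(
    comparison = bind_rows(
      mutate(cncy_metrics, arm = "cncy", .before = 1),
      mutate(pooled_metrics, arm = "pooled", .before = 1)
    ),
    holdout_ids = select(test, "protein_id", "center_pos", "label"),
    model = cncy
  )
}
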