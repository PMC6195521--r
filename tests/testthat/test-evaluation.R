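# Independent hand oracle for the five threshold metrics (plain arithmetic,
# no shared code with site_metrics).
metrics_oracle <- function(tp, fp, tn, fn) {
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  pr <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  acc <- if (tp + fp + tn + fn > 0) (tp + tn) / (tp + fp + tn + fn) else NA_real_
  den <- sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tp + fp) * sqrt(tn + fn)
  mcc <- if (den > 0) (tp * tn - fn * fp) / den else 0
  c(sn = sn, sp = sp, precision = pr, acc = acc, mcc = mcc)
}

test_that("metrics hit their boundary and hand-derived values", {
  m <- site_metrics(tp = 1, fp = 0, tn = 1, fn = 0)
  expect_equal(unlist(m[, c("sn", "sp", "precision", "acc", "mcc")]),
               c(sn = 1, sp = 1, precision = 1, acc = 1, mcc = 1))
  m <- site_metrics(tp = 0, fp = 1, tn = 0, fn = 1)
  expect_equal(m$acc, 0)
  expect_equal(m$mcc, -1)
  # hand evaluation: (2*3 - 1*1) / sqrt(3*4*3*4) = 5/12
  m <- site_metrics(tp = 2, fp = 1, tn = 3, fn = 1)
  expect_equal(m$mcc, 5 / 12)
  expect_error(site_metrics(tp = -1, fp = 0, tn = 0, fn = 0), "non-negative")
})

test_that("metrics agree with the oracle and its identities on all small counts", {
  grid <- expand.grid(tp = 0:6, fp = 0:6, tn = 0:6, fn = 0:6)
  got <- site_metrics(grid)
  for (i in seq_len(nrow(grid))) {
    want <- metrics_oracle(grid$tp[i], grid$fp[i], grid$tn[i], grid$fn[i])
    if (!isTRUE(all.equal(
      unlist(got[i, c("sn", "sp", "precision", "acc", "mcc")]),
      want, tolerance = 1e-12
    ))) {
      fail(sprintf("mismatch at TP=%d FP=%d TN=%d FN=%d",
                   grid$tp[i], grid$fp[i], grid$tn[i], grid$fn[i]))
    }
  }
  succeed()
  # ACC identity: ACC = (Sn*P + Sp*N) / (P + N) wherever both are defined
  P <- grid$tp + grid$fn; N <- grid$tn + grid$fp
  ok <- P > 0 & N > 0
  expect_equal(got$acc[ok], (got$sn[ok] * P[ok] + got$sp[ok] * N[ok]) /
                 (P[ok] + N[ok]))
  # MCC is invariant under scaling all four counts
  for (s in c(2L, 5L)) {
    scaled <- site_metrics(grid * s)
    expect_equal(scaled$mcc, got$mcc)
  }
})

test_that("CN + CY counts combine by summation before recomputation", {
  cy <- site_metrics(tp = 3, fp = 2, tn = 5, fn = 1)
  zero <- list(tp = 0, fp = 0, tn = 0, fn = 0)
  expect_equal(combine_cncy(zero, cy)$mcc, cy$mcc)
  # identical arms: counts double, MCC unchanged (scale invariance)
  expect_equal(combine_cncy(cy, cy)$mcc, cy$mcc)
  # hand oracle: (1,1,1,1) + (3,0,3,0) = (4,1,4,1) -> (16-1)/sqrt(5^4) = 0.6
  comb <- combine_cncy(list(tp = 1, fp = 1, tn = 1, fn = 1),
                       list(tp = 3, fp = 0, tn = 3, fn = 0))
  expect_equal(comb$mcc, 0.6)
})

# A deterministic stand-in model: scores equal a fixed column so cycle
# behaviour can be checked without classifier noise.
oracle_model <- function() {
  function(data, threshold) {
    tibble::tibble(
      protein_id = data$protein_id, center_pos = data$center_pos,
      score = data$true_score,
      predicted_label = ifelse(data$true_score >= threshold,
                               "positive", "negative")
    )
  }
}

test_that("the balanced-cycle protocol draws, counts and averages correctly", {
  set.seed(41)
  n_pos <- 12; n_neg <- 40
  data <- tibble::tibble(
    protein_id = sprintf("P%03d", 1:(n_pos + n_neg)),
    center_pos = 11L,
    label = rep(c("positive", "negative"), c(n_pos, n_neg)),
    true_score = c(runif(n_pos, 0.6, 1), runif(n_neg, 0, 0.55))
  )
  rep20 <- evaluate_cycles(oracle_model(), data, cycles = 20, seed = 4)
  expect_equal(nrow(tidy(rep20)), 20)
  # 1:1 balance: each cycle holds equally many positives and negatives
  pc <- tidy(rep20)
  expect_true(all(pc$tp + pc$fn == n_pos))
  expect_true(all(pc$fp + pc$tn == n_pos))
  # mean lies within the per-cycle range
  expect_gte(rep20$mean$mcc, min(pc$mcc))
  expect_lte(rep20$mean$mcc, max(pc$mcc))
  # same seed, identical report; different seed, different draws
  again <- evaluate_cycles(oracle_model(), data, cycles = 20, seed = 4)
  expect_identical(tidy(again), pc)

  # when negatives exactly match the positive count, the draw is everything
  balanced <- data[c(1:n_pos, n_pos + 1:n_pos), ]
  r1 <- evaluate_cycles(oracle_model(), balanced, cycles = 1, seed = 9)
  expect_equal(tidy(r1)$tp + tidy(r1)$fn, n_pos)
  expect_equal(tidy(r1)$fp + tidy(r1)$tn, n_pos)
  # fewer negatives than requested: clamp with a warning
  expect_warning(
    evaluate_cycles(oracle_model(), data, cycles = 1, ratio = 10, seed = 1),
    "negatives available"
  )
})

test_that("stratified CV touches each sample once and is honest on noise", {
  set.seed(11)
  n <- 40
  data <- dplyr::bind_cols(
    tibble::tibble(label = rep(c("positive", "negative"), each = n / 2)),
    tibble::as_tibble(matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8))))
  )
  # leave-one-out at folds = class size: every sample tested exactly once
  cv <- cross_validate(data, spec = fast_spec(), folds = n / 2, seed = 3)
  counts <- cv$rounds
  expect_equal(counts$tp + counts$fp + counts$tn + counts$fn, n)

  # fold sizes differ by at most one within each class
  fold_id <- with_seed(1, stratified_folds(data$label, 3))
  for (cls in c("positive", "negative")) {
    sizes <- table(fold_id[data$label == cls])
    expect_lte(max(sizes) - min(sizes), 1)
  }

  # pure-noise data: mean CV MCC over rounds stays near zero
  cv_noise <- cross_validate(data, spec = fast_spec(), folds = 5, rounds = 8,
                             seed = 13)
  expect_lt(abs(cv_noise$summary$mcc), 0.25)
  expect_error(cross_validate(data[1:6, ], folds = 5), "at least")
})

test_that("ROC sweep matches its symmetries and an external implementation", {
  labels <- rep(c("positive", "negative"), each = 50)
  perfect <- roc_curve(as.numeric(labels == "positive"), labels)
  expect_equal(perfect$auc, 1)

  set.seed(17)
  scores <- runif(100)
  r <- roc_curve(scores, labels)
  expect_equal(roc_curve(-scores, labels)$auc, 1 - r$auc)
  expect_true(all(diff(tidy(r)$fpr) >= 0))
  expect_error(roc_curve(scores, rep("positive", 100)), "both classes")

  big_labels <- rep(c("positive", "negative"), each = 1000)
  set.seed(23)
  noise <- rnorm(2000)
  expect_lt(abs(roc_curve(noise, big_labels)$auc - 0.5), 0.05)

  skip_if_not_installed("pROC")
  ref <- pROC::auc(pROC::roc(
    response = labels, predictor = scores,
    levels = c("negative", "positive"), direction = "<", quiet = TRUE
  ))
  expect_equal(r$auc, as.numeric(ref), tolerance = 1e-12)
})
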