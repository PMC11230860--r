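# Metric panel and the balanced-resampling validation protocol

test_that("confusion counts match per-item tallies", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unclass(cc)[c("tp", "fn", "tn", "fp")],
               list(tp = 1L, fn = 1L, tn = 1L, fp = 1L))
  cc2 <- confusion_counts(c(1, 1, 1, 0, 0), c(1, 1, 0, 1, 0))
  expect_equal(unlist(unclass(cc2)), c(tp = 2L, fn = 1L, tn = 1L, fp = 1L))
  perfect <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$fn + perfect$fp, 0L)
  expect_equal(perfect$tp + perfect$tn, 3L)
  expect_error(confusion_counts(c(1, 0), c(1)), class = "ms_config_error")

  # oracle equivalence: counts from lists equal brute-force per-item tally
  set.seed(11)
  for (i in 1:50) {
    n <- sample(1:40, 1)
    y <- rbinom(n, 1, 0.5); p <- rbinom(n, 1, 0.5)
    cc <- confusion_counts(y, p)
    expect_equal(cc$tp, sum(y & p))
    expect_equal(cc$fn, sum(y & !p))
    expect_equal(cc$tn, sum(!y & !p))
    expect_equal(cc$fp, sum(!y & p))
    expect_equal(cc$tp + cc$fn + cc$tn + cc$fp, n)
  }
})

test_that("the metric panel follows the standard formulas", {
  m <- metrics_from_counts(list(tp = 3, fn = 2, tn = 4, fp = 1))
  expect_equal(m$precision, 0.75)
  expect_equal(m$sensitivity, 0.60)
  expect_equal(m$accuracy, 0.70)
  expect_equal(m$specificity, 0.80)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / (0.75 + 0.6))

  perfect <- metrics_from_counts(list(tp = 10, fn = 0, tn = 10, fp = 0))
  expect_true(all(unlist(perfect) == 1))

  # fractional averaged counts are legal inputs
  frac <- metrics_from_counts(list(tp = 134, fn = 20, tn = 11.6, fp = 8.3))
  expect_equal(frac$sensitivity, 134 / 154)

  # zero denominators yield flagged NA, never 0 and never an exception
  und <- metrics_from_counts(list(tp = 0, fn = 0, tn = 5, fp = 0))
  expect_true(is.na(und$precision))
  expect_true(is.na(und$sensitivity))
  expect_true(all(c("precision", "sensitivity", "f1") %in%
                    attr(und, "undefined")))
  expect_equal(und$accuracy, 1)
})

test_that("AUROC is pairwise concordance with half-credit ties", {
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auroc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  # complement symmetry under label inversion
  s <- c(0.3, 0.7, 0.2, 0.9, 0.5)
  y <- c(0, 1, 0, 1, 1)
  expect_equal(auroc(s, y), 1 - auroc(s, 1 - y))
  # ties count one half
  expect_equal(auroc(c(0.5, 0.5), c(0, 1)), 0.5)
  expect_true(is.na(auroc(c(0.2, 0.3), c(1, 1))))
  # invariance under strictly increasing transforms
  set.seed(8)
  s2 <- runif(30); y2 <- rbinom(30, 1, 0.4)
  expect_equal(auroc(s2, y2), auroc(qlogis(s2 * 0.98 + 0.01), y2))
})

test_that("AUROC equals the brute-force oracle on random instances", {
  set.seed(2025)
  for (i in 1:1000) {
    n <- sample(2:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, runif(1, 0.2, 0.8)))
    s <- round(runif(n), sample(1:3, 1))  # rounding forces ties
    expect_equal(auroc(s, y), auroc_bruteforce(s, y))
  }
})

test_that("AUPRC follows the step-wise convention with prevalence baseline", {
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auprc(c(0.9, 0.1, 0.2), c(1, 0, 0)), 1)  # single positive, top
  expect_true(is.na(auprc(c(0.1, 0.2), c(0, 0))))
  # random scores: AUPRC concentrates near the positive prevalence
  set.seed(31)
  p <- 0.3
  vals <- replicate(60, {
    y <- rbinom(400, 1, p)
    auprc(runif(400), y)
  })
  expect_lt(abs(mean(vals) - p), 0.03)
})

test_that("held-out evaluation combines thresholded and threshold-free metrics", {
  m <- small_sert_model()
  sp <- small_sert_split()
  res <- evaluate_model_on_test(m, sp$test)
  expect_true(all(unlist(res[c("auroc", "auprc")]) >= 0))
  s <- predict(m, sp$test)
  expect_equal(res$auroc, as.numeric(auroc(s, sp$test$records$label)))
  expect_no_error(evaluate_model_on_test(m, sp$test, threshold = 0.5))
})

test_that("degenerate resampling (pool size equals sample) is a fixed evaluation", {
  tab <- data.frame(ensemble = c(0.9, 0.8, 0.3, 0.2, 0.6, 0.1),
                    label = c(1, 1, 0, 0, 0, 0))
  rep1 <- balanced_resampling_validation(tab, thresholds = 0.5, n_reps = 25,
                                         n_sample = 4, seed = 9)
  expect_equal(rep1$counts$tp, 2)
  expect_equal(rep1$counts$fn, 0)
  expect_equal(rep1$counts$fp, 1)   # 0.6 >= 0.5 in every identical rep
  expect_equal(rep1$counts$tn, 3)
  # every rep identical, so both aggregations coincide
  expect_equal(rep1$metrics_of_mean_counts$accuracy,
               rep1$mean_of_metrics$accuracy)
})

test_that("perfectly separated scores give perfect counts at any threshold", {
  tab <- data.frame(ensemble = c(rep(1, 5), rep(0, 40)),
                    label = c(rep(1, 5), rep(0, 40)))
  rep1 <- balanced_resampling_validation(tab, thresholds = c(0.3, 0.5, 1),
                                         n_reps = 50, n_sample = 5, seed = 2)
  expect_equal(rep1$counts$tp, rep(5, 3))
  expect_equal(rep1$counts$tn, rep(5, 3))
  expect_equal(rep1$counts$fp, rep(0, 3))
  expect_equal(rep1$counts$fn, rep(0, 3))
})

test_that("resampling respects structural invariants and determinism", {
  set.seed(5)
  tab <- data.frame(ensemble = c(runif(30, 0.4, 1), runif(200, 0, 0.7)),
                    label = c(rep(1, 30), rep(0, 200)))
  r <- balanced_resampling_validation(tab, n_reps = 40, seed = 77)
  # tp+fn constant = positive count in every threshold row
  expect_equal(r$counts$tp + r$counts$fn, rep(30, length(r$thresholds)))
  # tn+fp = per-rep negative sample size in every row
  expect_equal(r$counts$tn + r$counts$fp, rep(30, length(r$thresholds)))
  # tp anti-monotone in threshold
  expect_true(all(diff(r$counts$tp) <= 0))
  # averaged counts lie inside the per-rep convex hull
  expect_true(all(r$counts$fp >= 0 & r$counts$fp <= 30))
  r2 <- balanced_resampling_validation(tab, n_reps = 40, seed = 77)
  expect_identical(r$counts, r2$counts)
  expect_error(balanced_resampling_validation(tab, n_sample = 1000),
               class = "ms_config_error")
  expect_error(balanced_resampling_validation(
    data.frame(ensemble = runif(5), label = 0), n_reps = 5),
    class = "ms_config_error")
  # report table mirrors the threshold-sweep layout
  df <- as.data.frame(r)
  expect_equal(names(df), c("threshold", "TP", "FN", "TN", "FP", "accuracy",
                            "precision", "sensitivity", "specificity", "F1"))
})
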