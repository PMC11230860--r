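# Splitting, training, prediction, persistence

test_that("split sizes follow floor-with-remainder-to-train", {
  expect_equal(unname(mpnnscreen:::.split_sizes(
    400L, c(train = 0.7, valid = 0.1, test = 0.2))), c(280, 40, 80))
  expect_equal(unname(mpnnscreen:::.split_sizes(
    302L, c(train = 0.7, valid = 0.1, test = 0.2))), c(212, 30, 60))
})

test_that("splitting partitions the data deterministically", {
  ds <- small_sert_dataset()
  sp1 <- split_dataset(ds, split_config(seed = 5))
  sp2 <- split_dataset(ds, split_config(seed = 5))
  expect_identical(lapply(sp1, function(d) d$records$id),
                   lapply(sp2, function(d) d$records$id))
  ids <- unlist(lapply(sp1, function(d) d$records$id))
  expect_setequal(ids, ds$records$id)
  expect_equal(length(ids), nrow(ds$records))   # disjoint cover
  # stratified: class balance preserved in each non-empty split
  for (part in sp1) {
    tab <- table(part$records$label)
    expect_equal(length(tab), 2L)
  }
  sp3 <- split_dataset(ds, split_config(seed = 6))
  expect_false(identical(sp1$test$records$id, sp3$test$records$id))
})

test_that("degenerate stratified splits are refused", {
  ds <- small_sert_dataset()
  tiny <- labeled_dataset(ds$records[c(1:5, 31:35),
                                     c("id", "smiles", "target", "ki_nM",
                                       "label")], "SERT")
  expect_error(split_dataset(tiny, split_config(seed = 1)),
               class = "ms_split_error")
  expect_error(split_dataset(labeled_dataset(ds$records[1:6, c("id", "smiles",
                                                               "target",
                                                               "ki_nM",
                                                               "label")],
                                             "SERT"),
                             split_config(seed = 1)),
               class = "ms_split_error")
})

test_that("analytic gradients match numerical differentiation", {
  fs <- feature_spec()
  feats <- lapply(c("CCO", "c1ccncc1", "CC(=O)OC1=CC=CC=C1C(=O)O", "C"),
                  function(s) featurize(parse_smiles(s)))
  batch <- mpnnscreen:::mpnn_batch(feats)
  params <- mpnnscreen:::mpnn_init_params(fs$d_atom, fs$d_bond, 5L, c(7L, 4L),
                                          seed = 3L)
  # move biases off the ReLU kink so central differences are valid
  set.seed(99)
  for (nm in setdiff(names(params), "n_ffn"))
    params[[nm]] <- params[[nm]] + stats::rnorm(length(params[[nm]]), sd = 0.05)
  y <- c(1, 0, 1, 0)
  depth <- 3L
  fw <- mpnnscreen:::mpnn_forward(params, batch, depth, keep_cache = TRUE)
  gr <- mpnnscreen:::mpnn_backward(params, batch, fw$cache, y, depth)
  lossf <- function(p)
    mean((mpnnscreen:::mpnn_forward(p, batch, depth)$scores - y)^2)
  for (nm in setdiff(names(params), "n_ffn")) {
    ks <- sample(length(params[[nm]]), min(8L, length(params[[nm]])))
    for (k in ks) {
      p1 <- params; p1[[nm]][k] <- p1[[nm]][k] + 1e-6
      p2 <- params; p2[[nm]][k] <- p2[[nm]][k] - 1e-6
      num <- (lossf(p1) - lossf(p2)) / 2e-6
      expect_lt(abs(num - gr[[nm]][k]) /
                  max(1e-7, abs(num) + abs(gr[[nm]][k])), 1e-4)
    }
  }
})

test_that("training descends, separates the synthetic classes, and is deterministic", {
  sp <- small_sert_split()
  m <- small_sert_model()
  h <- m$history
  expect_equal(nrow(h), m$config$epochs)   # exactly cfg$epochs epochs run
  expect_true(all(is.finite(h$train_loss)))
  first5 <- mean(utils::head(h$train_loss, 5))
  last5 <- mean(utils::tail(h$train_loss, 5))
  expect_lt(last5, first5)                 # descent sanity

  s <- predict(m, sp$test)
  labels <- sp$test$records$label
  expect_true(all(s >= 0 & s <= 1))
  expect_gt(median(s[labels == 1]), median(s[labels == 0]))

  m2 <- train_model(sp$train, sp$valid, tiny_model_config())
  expect_equal(m$params, m2$params, tolerance = 1e-12)
})

test_that("training refuses single-class data", {
  ds <- small_sert_dataset()
  rec <- ds$records[ds$records$label == 1L,
                    c("id", "smiles", "target", "ki_nM", "label")]
  one_class <- labeled_dataset(rec, "SERT")
  expect_error(train_model(one_class, NULL, tiny_model_config()),
               class = "ms_training_error")
})

test_that("prediction preserves order, bounds, and batching invariance", {
  m <- small_sert_model()
  sp <- small_sert_split()
  smiles <- sp$test$records$smiles
  s_all <- predict(m, smiles)
  s_one <- vapply(smiles, function(x) predict(m, x)[1], numeric(1),
                  USE.NAMES = FALSE)
  expect_equal(as.numeric(s_all), s_one, tolerance = 1e-6)
  s_small <- predict(m, smiles, batch_size = 3L)
  expect_equal(as.numeric(s_all), as.numeric(s_small), tolerance = 1e-12)
  # unparseable entries score NA and are reported, order preserved
  mixed <- c(smiles[1], "C1CC", smiles[2])
  sm <- predict(m, mixed)
  expect_true(is.na(sm[2]))
  expect_equal(attr(sm, "rejects"), 2L)
  expect_equal(sm[c(1, 3)], as.numeric(s_all[1:2]), tolerance = 1e-12)
})

test_that("model persistence round-trips and rejects corrupt artifacts", {
  m <- small_sert_model()
  sp <- small_sert_split()
  p <- tempfile(fileext = ".rds")
  save_model(m, p)
  m2 <- load_model(p)
  s1 <- predict(m, sp$test$records$smiles[1:10])
  s2 <- predict(m2, sp$test$records$smiles[1:10])
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-6)

  # truncated file: explicit error, not a garbage model
  raw <- readBin(p, "raw", file.info(p)$size)
  pt <- tempfile(fileext = ".rds")
  writeBin(raw[1:floor(length(raw) / 3)], pt)
  expect_error(load_model(pt), class = "ms_io_error")
  # a non-model RDS is refused
  po <- tempfile(fileext = ".rds")
  saveRDS(list(foo = 1), po)
  expect_error(load_model(po), class = "ms_io_error")
  # feature-vocabulary mismatch is an incompatibility error
  obj <- readRDS(p)
  obj$model$feature_spec$version <- "someone-elses-vocabulary"
  pv <- tempfile(fileext = ".rds")
  saveRDS(obj, pv)
  expect_error(load_model(pv), class = "ms_incompat_error")
})
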