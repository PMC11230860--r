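# Shared fixtures, built lazily once per test run. Everything is generated in
# code from fixed seeds; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fx, inherits = FALSE))
    assign(name, builder(), envir = .fx)
  get(name, envir = .fx, inherits = FALSE)
}

# small populations for unit tests (30 actives / 30 decoys per target)
small_spec <- function() fixture("small_spec", function()
  synthetic_spec(scale = 0.15, seed = 7))

tiny_model_config <- function(epochs = 12L, seed = 11L)
  model_config(epochs = epochs, mp_hidden = 16L, hidden_layers = c(32L, 16L),
               seed = seed)

small_sert_dataset <- function() fixture("small_sert_dataset", function() {
  spec <- small_spec()
  assemble_training_set(generate_actives(spec, "SERT"),
                        generate_decoys(spec, "SERT"), "SERT")
})

small_sert_split <- function() fixture("small_sert_split", function()
  split_dataset(small_sert_dataset(), split_config(seed = 5)))

small_sert_model <- function() fixture("small_sert_model", function() {
  sp <- small_sert_split()
  train_model(sp$train, sp$valid, tiny_model_config())
})

# ---- the full synthetic study benchmark (study-sized populations,
# 70/10/20 stratified split, 30 epochs, fixed seeds) ------------------------

bench_spec <- function() fixture("bench_spec", function()
  synthetic_spec(seed = 101))

bench_run <- function() fixture("bench_run", function() {
  spec <- bench_spec()
  targets <- names(spec$motif_per_target)
  out <- list(models = list(), splits = list(), test_metrics = list())
  for (t in targets) {
    ds <- assemble_training_set(generate_actives(spec, t),
                                generate_decoys(spec, t), t)
    sp <- split_dataset(ds, split_config(seed = 2024))
    mdl <- train_model(sp$train, sp$valid,
                       model_config(epochs = 30L, seed = 97L))
    out$models[[t]] <- mdl
    out$splits[[t]] <- sp
    out$test_metrics[[t]] <- evaluate_model_on_test(mdl, sp$test)
  }
  out
})

bench_screen <- function() fixture("bench_screen", function() {
  lib <- generate_screening_library(bench_spec())
  screen_library(bench_run()$models, lib, screening_config(0.5))
})

# brute-force pairwise-concordance AUROC oracle (independent of the
# rank-based implementation)
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
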