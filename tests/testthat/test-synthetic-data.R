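# Synthetic active/decoy populations: ground truth by construction,
# re-checked here with independent substructure matching.

smarts_hits <- function(smiles, pattern) {
  sdf <- ChemmineR::smiles2sdf(stats::setNames(smiles,
                                               paste0("q", seq_along(smiles))))
  unname(ChemmineR::smartsSearchOB(sdf, pattern, uniqueMatches = TRUE)) > 0
}

test_that("zero-count requests yield empty record sets", {
  spec <- synthetic_spec(n_actives = 0L, n_decoys = 0L, n_screen_pos = 0L,
                         n_screen_neg = 0L)
  expect_equal(nrow(generate_actives(spec, "SERT")), 0L)
  expect_equal(nrow(generate_decoys(spec, "SERT")), 0L)
  expect_equal(nrow(generate_screening_library(spec)), 0L)
})

test_that("generation is a pure function of (spec, seed)", {
  spec <- small_spec()
  expect_identical(generate_actives(spec, "D2"), generate_actives(spec, "D2"))
  expect_identical(generate_decoys(spec, "D2"), generate_decoys(spec, "D2"))
  expect_identical(generate_screening_library(spec),
                   generate_screening_library(spec))
  spec2 <- synthetic_spec(scale = 0.15, seed = 8)
  expect_false(identical(generate_actives(spec, "D2")$smiles,
                         generate_actives(spec2, "D2")$smiles))
})

test_that("actives carry their motif and pass the activity filter", {
  spec <- small_spec()
  for (t in names(spec$motif_per_target)) {
    act <- generate_actives(spec, t)
    expect_equal(nrow(act), spec$n_actives[[t]])
    expect_true(all(act$label == 1L))
    # every sampled Ki respects the stated interval, so the full set
    # survives the threshold filter at the interval's upper bound
    expect_true(all(act$ki_nM >= spec$ki_range_active[1]))
    expect_true(all(act$ki_nM <= spec$ki_range_active[2]))
    expect_equal(nrow(filter_actives(act, spec$ki_range_active[2])),
                 nrow(act))
    # independent substructure scan: motif present in 100% of actives
    expect_true(all(smarts_hits(act$smiles, spec$motif_per_target[[t]])))
  }
})

test_that("decoys contain no target motif (exhaustive substructure scan)", {
  spec <- small_spec()
  for (t in names(spec$motif_per_target)) {
    dec <- generate_decoys(spec, t)
    expect_equal(nrow(dec), spec$n_decoys[[t]])
    expect_true(all(dec$label == 0L))
    expect_true(all(dec$ki_nM >= spec$ki_range_inactive[1]))
    for (motif in spec$motif_per_target)
      expect_false(any(smarts_hits(dec$smiles, motif)))
  }
})

test_that("screening library has the requested composition and ground truth", {
  spec <- small_spec()
  lib <- generate_screening_library(spec)
  expect_equal(nrow(lib), spec$n_screen_pos + spec$n_screen_neg)
  expect_equal(sum(lib$label == 1L), spec$n_screen_pos)
  expect_equal(sum(lib$label == 0L), spec$n_screen_neg)
  pos <- lib[lib$label == 1L, ]
  neg <- lib[lib$label == 0L, ]
  any_motif <- Reduce(`|`, lapply(spec$motif_per_target, function(m)
    smarts_hits(pos$smiles, m)))
  expect_true(all(any_motif))
  for (motif in spec$motif_per_target)
    expect_false(any(smarts_hits(neg$smiles, motif)))
})

test_that("screening library is disjoint from every training set", {
  spec <- small_spec()
  lib <- generate_screening_library(spec)
  for (t in names(spec$motif_per_target)) {
    ds <- assemble_training_set(generate_actives(spec, t),
                                generate_decoys(spec, t), t)
    expect_length(assert_disjoint(ds, lib), 0L)
  }
})

test_that("invalid specs are rejected with configuration errors", {
  expect_error(synthetic_spec(n_actives = -1), class = "ms_config_error")
  expect_error(synthetic_spec(ki_range_active = c(1, 2000)),
               class = "ms_config_error")  # actives less potent than decoys
  expect_error(synthetic_spec(motif_per_target = c(SERT = "C1CC")),
               class = "ms_config_error")  # invalid motif SMILES
  expect_error(synthetic_spec(scale = 0), class = "ms_config_error")
})
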