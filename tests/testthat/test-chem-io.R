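# Molecule table IO, Ki filtering, dataset assembly, disjointness

write_fixture_csv <- function(rows, header = "id,smiles,target,ki_nM,label") {
  path <- tempfile(fileext = ".csv")
  writeLines(c(header, rows), path)
  path
}

test_that("CSV rows map to records and Ki units normalize to nM", {
  p <- write_fixture_csv("a1,CC(=O)OC1=CC=CC=C1C(=O)O,SERT,5.0,1")
  rec <- read_molecule_table(p)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$ki_nM, 5.0)
  expect_equal(rec$label, 1L)
  expect_equal(rec$target, "SERT")

  p2 <- write_fixture_csv(c("a,CCO,T,5,1,nM", "b,CCN,T,2,1,uM", "c,CCC,T,1,0,M"),
                          header = "id,smiles,target,ki,label,units")
  rec2 <- read_molecule_table(p2, dialect = list(id = "id", smiles = "smiles",
                                                 target = "target", ki = "ki",
                                                 label = "label",
                                                 units = "units"))
  expect_equal(rec2$ki_nM, c(5, 2e3, 1e9))
})

test_that("unparseable SMILES rows are dropped and reported", {
  p <- write_fixture_csv(c("a,CCO,T,1,1", "b,C1CC,T,2,1", "c,CCC,T,3,0"))
  expect_warning(rec <- read_molecule_table(p), "unparseable")
  expect_equal(nrow(rec), 2L)
  expect_equal(attr(rec, "dropped_rows"), 2L)
  expect_equal(rec$id, c("a", "c"))
})

test_that("empty and malformed tables are handled", {
  p <- write_fixture_csv(character(0))
  expect_warning(rec <- read_molecule_table(p), "empty")
  expect_equal(nrow(rec), 0L)
  p2 <- write_fixture_csv("a,CCO", header = "id,notsmiles")
  expect_error(read_molecule_table(p2), class = "ms_format_error")
  expect_error(read_molecule_table(tempfile()), class = "ms_io_error")
})

test_that("round-trip through CSV preserves records", {
  rec <- generate_actives(small_spec(), "SERT")
  p <- tempfile(fileext = ".csv")
  write_molecule_table(rec, p)
  back <- read_molecule_table(p)
  expect_equal(back$id, rec$id)
  expect_equal(back$smiles, rec$smiles)
  expect_equal(back$ki_nM, rec$ki_nM)
  expect_equal(back$label, rec$label)
  # and the write is byte-reproducible
  p2 <- tempfile(fileext = ".csv")
  write_molecule_table(rec, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("SMILES line format round-trips", {
  rec <- utils::head(generate_decoys(small_spec(), "SERT"), 5L)
  p <- tempfile(fileext = ".smi")
  write_smiles_file(rec, p)
  back <- read_smiles_file(p)
  expect_equal(back$smiles, rec$smiles)
  expect_equal(back$id, rec$id)
})

test_that("Ki filtering is boundary-inclusive and order-preserving", {
  rec <- data.frame(id = c("a", "b", "c"), smiles = c("CCO", "CCN", "CCC"),
                    target = "T", ki_nM = c(5, 10, 15), label = NA_integer_)
  expect_equal(filter_actives(rec, 10)$id, c("a", "b"))   # 10 nM included
  expect_equal(filter_actives(rec, 12)$id, c("a", "b"))
  expect_equal(filter_actives(rec, 5)$id, "a")
  expect_equal(nrow(filter_actives(rec, 4.9)), 0L)
  expect_equal(nrow(filter_actives(rec[0, ], 10)), 0L)
  # records without Ki are excluded and counted
  rec$ki_nM[2] <- NA
  out <- filter_actives(rec, 10)
  expect_equal(out$id, "a")
  expect_equal(attr(out, "n_missing_ki"), 1L)
  expect_error(filter_actives(rec, -1), class = "ms_config_error")
})

test_that("filtering is monotone in the threshold", {
  set.seed(3)
  rec <- data.frame(id = sprintf("m%02d", 1:40),
                    smiles = rep(c("CCO", "CCC", "CCCC", "CCOC"), 10),
                    target = "T", ki_nM = 10^runif(40, -1, 5),
                    label = NA_integer_)
  thresholds <- sort(10^runif(6, -1, 5))
  prev <- character(0)
  for (t in thresholds) {
    cur <- filter_actives(rec, t)$id
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("assembly labels, deduplicates and detects class conflicts", {
  spec <- small_spec()
  act <- generate_actives(spec, "NMDA")
  dec <- generate_decoys(spec, "NMDA")
  ds <- assemble_training_set(act, dec, "NMDA")
  expect_s3_class(ds, "labeled_dataset")
  expect_equal(nrow(ds$records), nrow(act) + nrow(dec))
  expect_equal(sum(ds$records$label), nrow(act))

  # duplicate inside one class is removed, not fatal
  act_dup <- rbind(act, act[1, ])
  ds2 <- assemble_training_set(act_dup, dec, "NMDA")
  expect_equal(nrow(ds2$records), nrow(act) + nrow(dec))
  expect_equal(attr(ds2, "n_duplicates_removed"), 1L)

  # equivalent spellings across classes are a contradiction
  dec_bad <- dec
  dec_bad$smiles[1] <- act$smiles[2]
  err <- expect_error(assemble_training_set(act, dec_bad, "NMDA"),
                      class = "ms_conflict_error")
  expect_match(conditionMessage(err), "both classes")
  expect_error(assemble_training_set(act[0, ], dec, "NMDA"),
               class = "ms_config_error")
})

test_that("disjointness report finds exactly the shared molecules", {
  spec <- small_spec()
  ds <- assemble_training_set(generate_actives(spec, "D2"),
                              generate_decoys(spec, "D2"), "D2")
  external <- generate_screening_library(spec)
  expect_length(assert_disjoint(ds, external), 0L)
  # inject one training molecule (different spelling) into the external set
  external2 <- external
  external2$smiles[1] <- ds$records$smiles[1]
  clash <- assert_disjoint(ds, external2)
  expect_length(clash, 1L)
  expect_equal(clash[1], canonical_smiles(ds$records$smiles[1]))
})
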