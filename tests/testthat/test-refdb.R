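# Reference database loading, round-trip, and the Sec-aware scoring model.

write_ref_fixture <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

test_that("reference FASTA loads with Sec positions derived from the sequence", {
  f <- write_ref_fixture(c(
    ">g1 family=GPX", "MAUGT",
    ">g2 family=GPX motif=UxT", "MAUTTK",
    ">g3 family=PDI", "MCCUGUU"))
  db <- read_reference_db(f)
  expect_s3_class(db, "seleno_refdb")
  expect_equal(nrow(db), 3)
  expect_equal(sort(unique(db$family)), c("GPX", "PDI"))
  expect_equal(db$sec_positions[[1]], 2L)
  expect_equal(db$sec_positions[[3]], c(3L, 5L, 6L))
  # every U is indexed and every index is a U (invariant by construction)
  for (i in seq_len(nrow(db))) {
    ch <- strsplit(db$residues[i], "")[[1]]
    expect_identical(which(ch == "U") - 1L, db$sec_positions[[i]])
  }
  fams <- reference_families(db)
  expect_equal(sum(fams$n_members), 3)
  expect_equal(fams$motif[fams$family == "GPX"], "UxT")
})

test_that("malformed and duplicate records are rejected with the record named", {
  f1 <- write_ref_fixture(c(">g1 nofamily", "MAU"))
  expect_error(read_reference_db(f1), "family")
  f2 <- write_ref_fixture(c(">g1 family=A", "MAU", ">g1 family=A", "MGU"))
  expect_error(read_reference_db(f2), "duplicate.*g1")
  f3 <- write_ref_fixture(c(">g1 family=A", "MAOU"))
  expect_error(read_reference_db(f3), "g1")
  f4 <- write_ref_fixture(c(">g1 family=A motif=ZZZZZ", "MAU"))
  expect_error(read_reference_db(f4), "motif")
})

test_that("write/read round-trip preserves the database exactly", {
  db <- example_reference_db(seed = 5)
  f <- tempfile(fileext = ".fasta")
  write_reference_db(db, f)
  db2 <- read_reference_db(f)
  expect_equal(as.data.frame(db2), as.data.frame(db[, names(db2)]))
})

test_that("scoring matrix extends the base table by the inherit-C rule", {
  m <- seleno_scoring_matrix(sec_bonus = 2)
  expect_equal(m["U", "U"], m["C", "C"] + 2L)
  expect_equal(m["U", "C"], m["C", "C"])
  std <- setdiff(rownames(m), c("U", "C", "X", "*"))
  for (w in std) expect_equal(m["U", w], m["C", w])
  expect_identical(m, t(m), ignore_attr = TRUE)
})

test_that("scoring matrix invariants hold for any positive sec bonus", {
  for (b in 1:10) {
    m <- seleno_scoring_matrix(sec_bonus = b)
    expect_true(m["U", "U"] > m["U", "C"])
    std <- setdiff(rownames(m), c("U", "C", "X", "*"))
    expect_true(m["U", "C"] > max(m["U", std]))
    expect_identical(unclass(m), t(unclass(m)), ignore_attr = TRUE)
  }
  expect_error(seleno_scoring_matrix(sec_bonus = 0), "positive")
  expect_error(seleno_scoring_matrix(sec_bonus = -3), "positive")
})

test_that("parameters validate ranges and read from JSON", {
  expect_error(seleno_params(min_window_positive_frac = 1.2), "\\[0, 1\\]")
  expect_error(seleno_params(min_orf_aa = 0), "positive")
  expect_error(seleno_params(max_readthrough_tga = -1), ">= 0")
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(min_orf_aa = 25, min_hit_score = 80), f,
                       auto_unbox = TRUE)
  p <- read_params_json(f)
  expect_equal(p$min_orf_aa, 25L)
  expect_equal(p$min_hit_score, 80L)
  expect_equal(p$sec_window, 5L)   # untouched default
  jsonlite::write_json(list(not_a_param = 1), f, auto_unbox = TRUE)
  expect_error(read_params_json(f), "not_a_param")
})
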