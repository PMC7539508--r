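# Sec-aware alignment, site classification, frameshift/pseudogene calling,
# fusions, and their invariants.

test_that("self-alignment scores the diagonal sum over the full length", {
  m <- test_matrix()
  q <- "MAUGTCWUK"
  al <- align_sec_aware(q, q, m)
  ch <- strsplit(q, "")[[1]]
  expect_equal(al$score, sum(vapply(ch, function(a) m[a, a], 0L)))
  expect_equal(al$q_span, c(0L, nchar(q)))
  expect_equal(al$r_span, c(0L, nchar(q)))
  expect_error(align_sec_aware("MA#", q, m), "alphabet")
  expect_error(align_sec_aware("", q, m), "non-empty")
})

test_that("alignment scores equal the independent DP oracle on random pairs", {
  set.seed(51)
  m <- test_matrix()
  go <- attr(m, "gap_open"); ge <- attr(m, "gap_extend")
  for (i in 1:80) {
    q <- random_aa_with_u(sample(5:40, 1))
    r <- random_aa_with_u(sample(5:40, 1))
    al <- align_sec_aware(q, r, m)
    expect_identical(al$score, as.integer(oracle_sw_score(q, r, m, go, ge)))
  }
})

test_that("every alignment's score re-derives from its aligned columns", {
  set.seed(52)
  m <- test_matrix()
  for (i in 1:40) {
    q <- random_aa_with_u(sample(10:50, 1))
    r <- random_aa_with_u(sample(10:50, 1))
    al <- align_sec_aware(q, r, m)
    if (al$score == 0) next
    expect_equal(alignment_score_from_columns(al, q, r, m), al$score)
  }
})

test_that("Sec sites classify by the aligned query residue", {
  m <- test_matrix()
  p <- seleno_params()
  ref <- "MKLVAUGTWENDKLY"
  secs <- 5L   # 0-based
  for (case in list(c("U", "Sec"), c("C", "Cys"), c("W", "Other"))) {
    q <- sub("U", case[1], ref)
    al <- align_sec_aware(q, ref, m)
    sc <- classify_sec_sites(al, q, ref, secs, m, p)
    expect_equal(sc$site_class, case[2])
    expect_equal(sc$query_residue, case[1])
    expect_gte(sc$window_positive_frac, 0.9)
  }
})

test_that("a UxxC reference pairs its Sec column with C of a CxxC query", {
  m <- test_matrix()
  ref <- "MKLVAGTWUAECDNKLYHR"   # UxxC at positions 8..11 (0-based)
  qry <- "MKLVAGTWCAECDNKLYHR"   # CxxC homolog
  al <- align_sec_aware(qry, ref, m)
  sc <- classify_sec_sites(al, qry, ref, 8L, m, seleno_params())
  expect_equal(sc$site_class, "Cys")
  expect_equal(sc$query_residue, "C")
})

test_that("weakly conserved Sec windows are demoted to Unaligned", {
  m <- test_matrix()
  ref <- paste0(strrep("A", 10), "U", strrep("A", 10))
  qry <- paste0(strrep("G", 10), "U", strrep("G", 10))
  al <- align_sec_aware(qry, ref, m)
  sc <- classify_sec_sites(al, qry, ref, 10L, m, seleno_params())
  expect_equal(sc$query_residue, "U")
  expect_lt(sc$window_positive_frac, seleno_params()$min_window_positive_frac)
  expect_equal(sc$site_class, "Unaligned")
})

test_that("best family hit applies the threshold and lexicographic tie-break", {
  m <- test_matrix()
  seq <- "MKLVAUGTWENDKLYHRPQS"
  db <- selenoscan:::new_refdb(tibble::tibble(
    id = c("zz1", "aa1"), family = c("ZFAM", "AFAM"),
    residues = c(seq, seq),
    sec_positions = list(5L, 5L), length = nchar(seq),
    motif = NA_character_))
  hit <- best_family_hit(seq, db, m, seleno_params(min_hit_score = 30))
  expect_equal(hit$family, "AFAM")    # equal scores, first family name wins
  expect_null(best_family_hit(seq, db, m, seleno_params(min_hit_score = 1e6)))
})

test_that("raising the hit threshold never adds calls", {
  set.seed(53)
  m <- test_matrix()
  db <- test_refdb()
  peps <- c(db$residues[c(1, 5, 9)],
            replicate(10, random_aa_with_u(60)))
  n_hits <- vapply(c(30, 60, 120, 300), function(th) {
    p <- seleno_params(min_hit_score = th)
    sum(!vapply(peps, function(q) is.null(best_family_hit(q, db, m, p)), TRUE))
  }, 0)
  expect_true(all(diff(n_hits) <= 0))
})

test_that("frameshift detection localizes single planted indels", {
  set.seed(54)
  m <- test_matrix()
  p <- seleno_params()
  db <- test_refdb()
  res <- db$residues[1]
  g <- plant_gene(res, "Cys")
  clean <- paste0(selenoscan:::random_dna(40), g$cds,
                  selenoscan:::random_dna(40))
  expect_equal(nrow(detect_frameshifts(res, clean, m, p)), 0)
  ps <- plant_pseudogene(g$cds, codon = 10, kind = "deletion", len = 1)
  dna <- paste0(selenoscan:::random_dna(40), ps$cds,
                selenoscan:::random_dna(40))
  ev <- detect_frameshifts(res, dna, m, p)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "deletion")
  expect_lte(abs(ev$pos_nt - (40 + 30)), 3)   # within one codon
})

test_that("frameshift DP matches the exhaustive oracle on tiny instances", {
  set.seed(55)
  m <- test_matrix()
  p <- seleno_params()
  for (i in 1:25) {
    prot <- random_peptide_std(sample(8:14, 1))
    g <- plant_gene(prot, "Cys")
    cds <- substr(g$cds, 4, nchar(g$cds) - 3)   # drop ATG/stop: exact match
    dna <- if (i %% 2 == 0) {
      full <- paste0("ATG", cds, "TAA")
      rng <- 5:(nchar(full) / 3 - 5)
      ps <- plant_pseudogene(full, codon = rng[sample.int(length(rng), 1)])
      substr(ps$cds, 4, nchar(ps$cds) - 3)
    } else cds
    got <- detect_frameshifts(prot, dna, m, p)
    want <- oracle_frameshift(prot, dna, m, p$frameshift_penalty,
                              p$fs_gap_penalty)
    expect_equal(attr(got, "score"), want$score)
    expect_equal(nrow(got), nrow(want$events))
    if (nrow(got) > 0) {
      expect_equal(got$kind, want$events$kind)
      expect_true(all(abs(got$pos_nt - want$events$pos_nt) <= 3))
    }
  }
})

test_that("the pseudogene rule follows EST support", {
  set.seed(56)
  m <- test_matrix()
  p <- seleno_params()
  db <- test_refdb()
  res <- db$residues[3]
  g <- plant_gene(res, "Sec")
  ps <- plant_pseudogene(g$cds, codon = 15, kind = "deletion", len = 1)
  dna <- paste0(selenoscan:::random_dna(60), ps$cds,
                selenoscan:::random_dna(60))
  ev <- detect_frameshifts(res, dna, m, p)
  expect_gte(nrow(ev), 1)
  # no ESTs: pseudogene
  no_est <- call_pseudogene(ev, dna, character(0), p)
  expect_true(no_est$pseudogene)
  # an EST carrying the same indel (a genomic substring) rescues the gene
  est <- substr(dna, ev$pos_nt[1] - 80, ev$pos_nt[1] + 80)
  with_est <- call_pseudogene(ev, dna, est, p)
  expect_false(with_est$pseudogene)
  expect_true(all(with_est$events$est_supported))
  # an EST of the intact transcript does NOT support the genomic indel
  intact <- paste0(selenoscan:::random_dna(60), g$cds)
  est2 <- substr(intact, ev$pos_nt[1] - 80, ev$pos_nt[1] + 80)
  wrong <- call_pseudogene(ev, dna, est2, p)
  expect_true(wrong$pseudogene)
  # zero events: never a pseudogene
  none <- call_pseudogene(detect_frameshifts(res, paste0("ATG",
    back_translate(res), "TAA"), m, p), dna, character(0), p)
  expect_false(none$pseudogene)
})

test_that("fusion ORFs report two non-overlapping families once", {
  set.seed(57)
  m <- test_matrix()
  p <- seleno_params()
  db <- test_refdb()
  gst <- db$residues[db$id == "GST_1"]
  msra <- db$residues[db$id == "MSRA_1"]
  fused <- paste0(gst, "GSGS", msra)
  fh <- selenoscan:::per_family_hits(fused, db, m, p)
  fu <- detect_fusions(fh, "fused_orf", p)
  expect_equal(nrow(fu), 1)
  expect_equal(fu$family_a, "GST")
  expect_equal(fu$family_b, "MSRA")
  expect_gte(fu$gap_between, 0)
  # single family: no fusion
  fh1 <- selenoscan:::per_family_hits(gst, db, m, p)
  expect_equal(nrow(detect_fusions(fh1, "x", p)), 0)
  # overlapping spans: no fusion
  overlap <- tibble::tibble(family = c("A", "B"), score = c(100, 100),
                            q_start = c(0L, 10L), q_end = c(50L, 60L))
  expect_equal(nrow(detect_fusions(overlap, "x", p)), 0)
})
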