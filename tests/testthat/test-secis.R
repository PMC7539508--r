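# SECIS grammar scan: detection, soundness, windows, strand handling.

test_that("low-complexity regions contain no SECIS", {
  expect_equal(nrow(detect_secis(strrep("A", 300))), 0)
  expect_equal(nrow(detect_secis(strrep("AC", 150))), 0)
  # region shorter than the minimal span is empty, not an error
  expect_equal(nrow(detect_secis("ATGAAC")), 0)
})

test_that("every detected element re-validates against the grammar", {
  set.seed(41)
  n_checked <- 0
  for (i in 1:40) {
    region <- selenoscan:::random_dna(1500)
    if (i %% 2 == 0) {
      el <- plant_secis()
      substr(region, 501, 500 + nchar(el$seq)) <- el$seq
    }
    hits <- detect_secis(region)
    for (k in seq_len(nrow(hits))) {
      expect_true(secis_revalidate(region, hits[k, ]))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 20)   # the planted elements guarantee coverage
})

test_that("detected elements respect the grammar caps and are ordered", {
  set.seed(42)
  g <- secis_grammar()
  el <- plant_secis(g)
  region <- paste0(selenoscan:::random_dna(200), el$seq,
                   selenoscan:::random_dna(200))
  hits <- detect_secis(region, g)
  expect_true(all(hits$mismatches <= g$helix2_max_mismatch))
  expect_true(all(diff(hits$start) > 0 | diff(hits$start) == 0))
  expect_true(all(hits$core5_start > hits$start))
  expect_true(all(hits$core3_end < hits$end))
})

test_that("downstream windows are strand-resolved and mirrored", {
  set.seed(43)
  el <- plant_secis()
  cds <- paste0("ATG", selenoscan:::random_dna(120), "TAA")
  cassette <- paste0(cds, selenoscan:::random_dna(100), el$seq,
                     selenoscan:::random_dna(60))
  pad_l <- selenoscan:::random_dna(500)
  pad_r <- selenoscan:::random_dna(500)
  fwd_ctg <- paste0(pad_l, cassette, pad_r)
  rev_ctg <- paste0(pad_l, revcomp(cassette), pad_r)
  orf_start <- 500L; orf_end <- 500L + nchar(cds) - 3L
  fwd <- attach_secis(fwd_ctg, orf_start, orf_end, "+")
  # on the minus strand the ORF occupies the mirrored interval
  r_end <- 500L + nchar(cassette)
  r_start <- r_end - (nchar(cds) - 3L)
  rev <- attach_secis(rev_ctg, r_start, r_end, "-")
  expect_equal(nrow(fwd), 1)
  expect_equal(nrow(rev), 1)
  expect_equal(fwd$distance_from_stop, rev$distance_from_stop)
  expect_equal(fwd$core5_off, rev$core5_off)
  expect_equal(fwd$score, rev$score)
  # mirrored forward-strand spans
  n <- nchar(fwd_ctg)
  expect_equal(rev$start, n - fwd$end)
  expect_equal(rev$end, n - fwd$start)
})

test_that("elements beyond the stop-distance window are not reported", {
  set.seed(44)
  el <- plant_secis()
  g <- secis_grammar(max_distance_from_stop = 200L)
  ctg <- paste0(strrep("C", 100), "TAA", strrep("C", 400), el$seq,
                strrep("C", 100))
  hits <- attach_secis(ctg, 40L, 100L, "+", g, window_nt = 2000L)
  expect_equal(nrow(hits), 0)
  g2 <- secis_grammar(max_distance_from_stop = 2000L)
  hits2 <- attach_secis(ctg, 40L, 100L, "+", g2, window_nt = 2000L)
  expect_equal(nrow(hits2), 1)
})

test_that("ORFs at the contig edge yield empty results without error", {
  ctg <- selenoscan:::random_dna(300)
  expect_equal(nrow(attach_secis(ctg, 250L, nchar(ctg) - 3L, "+")), 0)
  expect_equal(nrow(attach_secis(ctg, 3L, 60L, "-")), 0)
  expect_equal(nrow(attach_secis(ctg, 0L, nchar(ctg), "+")), 0)
})

test_that("type-II apical loops are found only when asked for", {
  set.seed(45)
  g2 <- secis_grammar(apical_required = "CC")
  el <- plant_secis(g2)
  region <- paste0(strrep("G", 60), el$seq, strrep("G", 60))
  expect_equal(nrow(detect_secis(region, g2)), 1)
})
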