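# Read-through ORF enumeration: contract examples, equivalence with an
# independent brute-force enumerator, and the strand/K invariants.

test_that("read-through and terminate-at-TGA variants are both emitted", {
  p <- seleno_params(min_orf_aa = 1)
  o <- enumerate_orfs("ATGGCATGAGCATAA", p, strands = "forward")
  peps <- o$peptide
  expect_true("MAUA" %in% peps)
  expect_true("MA" %in% peps)
  full <- o[o$peptide == "MAUA", ]
  expect_equal(full$tga_offsets[[1]], 2L)
  expect_equal(full$terminal_stop, "TAA")
  expect_equal(o$terminal_stop[o$peptide == "MA"], "TGA")
  # K = 0: the TGA may only act as a stop
  o0 <- enumerate_orfs("ATGGCATGAGCATAA",
                       seleno_params(min_orf_aa = 1, max_readthrough_tga = 0),
                       strands = "forward")
  expect_false("MAUA" %in% o0$peptide)
  expect_true("MA" %in% o0$peptide)
})

test_that("enumeration equals the brute-force six-frame oracle on random contigs", {
  set.seed(11)
  for (rep in 1:6) {
    n <- sample(300:900, 1)
    s <- selenoscan:::random_dna(n)
    K <- sample(0:3, 1)
    min_aa <- sample(c(5, 10, 20), 1)
    got <- enumerate_orfs(s, seleno_params(max_readthrough_tga = K,
                                           min_orf_aa = min_aa))
    want <- oracle_orfs(s, K, min_aa)
    got_key <- sort(paste(got$strand, got$start, got$end, got$peptide))
    want_key <- sort(paste(want$strand, want$start, want$end, want$peptide))
    expect_identical(got_key, want_key)
  }
  # and on one larger contig
  s <- selenoscan:::random_dna(10000)
  got <- enumerate_orfs(s, seleno_params(min_orf_aa = 25))
  want <- oracle_orfs(s, 3, 25)
  expect_identical(sort(paste(got$strand, got$start, got$end, got$peptide)),
                   sort(paste(want$strand, want$start, want$end, want$peptide)))
})

test_that("strand symmetry: reverse-complementing the contig flips the calls", {
  set.seed(12)
  s <- selenoscan:::random_dna(1200)
  p <- seleno_params(min_orf_aa = 10)
  a <- enumerate_orfs(s, p)
  b <- enumerate_orfs(revcomp(s), p)
  n <- nchar(s)
  flip <- data.frame(strand = ifelse(b$strand == "+", "-", "+"),
                     start = n - b$end, end = n - b$start,
                     peptide = b$peptide)
  expect_identical(
    sort(paste(a$strand, a$start, a$end, a$peptide)),
    sort(paste(flip$strand, flip$start, flip$end, flip$peptide)))
})

test_that("the ORF set grows monotonically in the read-through budget", {
  set.seed(13)
  s <- selenoscan:::random_dna(3000)
  keys <- lapply(0:3, function(K) {
    o <- enumerate_orfs(s, seleno_params(max_readthrough_tga = K,
                                         min_orf_aa = 10))
    paste(o$strand, o$start, o$end)
  })
  for (k in 1:3) expect_true(all(keys[[k]] %in% keys[[k + 1]]))
})

test_that("no emitted ORF contains an internal hard stop and N becomes X", {
  set.seed(14)
  s <- selenoscan:::random_dna(4000)
  o <- enumerate_orfs(s, seleno_params(min_orf_aa = 10))
  expect_false(any(grepl("\\*", o$peptide)))
  # peptide[i] == U exactly at tga_offsets
  for (i in sample(nrow(o), 50)) {
    ch <- strsplit(o$peptide[i], "")[[1]]
    expect_identical(which(ch == "U") - 1L, o$tga_offsets[[i]])
  }
  on <- enumerate_orfs("ATGAANCCTGGATAA", seleno_params(min_orf_aa = 1),
                       strands = "forward")
  expect_true(any(grepl("X", on$peptide)))
  expect_error(enumerate_orfs("ATGQQ", seleno_params()), "non-ACGTN")
})

test_that("transcript mode honours the strand flags", {
  set.seed(15)
  s <- paste0("ATG", selenoscan:::random_dna(90), "TAA")
  tr <- setNames(c(s, revcomp(s)), c("t_fwd", "t_rev"))
  p <- seleno_params(min_orf_aa = 10)
  fwd <- orfs_from_transcripts(tr, p)
  expect_true(all(fwd$strand == "+"))
  both <- orfs_from_transcripts(tr, p, both_strands = TRUE)
  expect_true(any(both$strand == "-"))
  # equivalence with enumerate_orfs on the same sequence
  a <- orfs_from_transcripts(tr["t_fwd"], p, both_strands = TRUE)
  b <- enumerate_orfs(s, p, contig = "t_fwd", species = a$species[1])
  expect_identical(sort(paste(a$strand, a$start, a$end, a$peptide)),
                   sort(paste(b$strand, b$start, b$end, b$peptide)))
})

test_that("ATG-restricted mode only emits methionine-initiated ORFs", {
  set.seed(16)
  s <- selenoscan:::random_dna(3000)
  o <- enumerate_orfs(s, seleno_params(min_orf_aa = 10, require_atg = TRUE))
  expect_true(all(substr(o$peptide, 1, 1) == "M"))
})
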