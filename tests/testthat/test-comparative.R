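# Comparative analytics: clusters, duplications, presence matrix, double
# clustering, motif census.

fake_calls <- function(starts, ends, species = "sp1", contig = "c1",
                       family = "GPX", class = "Sec") {
  n <- length(starts)
  tibble::tibble(call_id = sprintf("%s_%s_%d", species, contig, seq_len(n)),
                 species = species, contig = contig, strand = "+",
                 start = as.integer(starts), end = as.integer(ends),
                 family = rep_len(family, n),
                 overall_class = rep_len(class, n),
                 pseudogene = FALSE, peptide = NA_character_,
                 motif = NA_character_)
}

test_that("clusters chain adjacent genes and respect the gap cap", {
  p <- seleno_params(cluster_max_gap_nt = 10000)
  calls <- fake_calls(c(1000, 4000, 40000), c(2000, 5000, 41000),
                      family = c("GPX", "PDI_a", "GRX"),
                      class = c("Sec", "Cys", "Sec"))
  cl <- detect_clusters(calls, p)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_members, 2)
  expect_equal(cl$families, "GPX(U),PDI_a(C)")
  # a single gene is never a cluster
  expect_equal(nrow(detect_clusters(fake_calls(100, 500), p)), 0)
})

test_that("cluster detection equals the brute-force chaining oracle", {
  set.seed(61)
  p <- seleno_params(cluster_max_gap_nt = 5000)
  for (rep in 1:100) {
    n <- sample(2:12, 1)
    starts <- sort(sample.int(150000, n))
    ends <- starts + sample(200:1500, n, replace = TRUE)
    ends <- pmin(ends, c(starts[-1], Inf) - 1)   # keep non-overlapping
    calls <- fake_calls(starts, ends)
    got <- detect_clusters(calls, p)
    want <- oracle_clusters(starts, ends, p$cluster_max_gap_nt)
    expect_equal(nrow(got), length(want))
    expect_equal(sort(got$n_members), sort(vapply(want, length, 0L)),
                 ignore_attr = TRUE)
  }
})

test_that("planted gene+flank duplications pass and controls fail the 50/80/20 rule", {
  set.seed(62)
  db <- test_refdb()
  spec <- cohort_spec(n_species = 1, contigs_per_species = 2,
                      contig_length_nt = 150000L, n_sec_genes = 4,
                      n_cys_homologs = 0, n_other_homologs = 0,
                      n_pseudogenes = 0, n_clusters = 0, n_duplications = 1,
                      duplication_flank_nt = 4000L, seed = 63)
  co <- simulate_cohort(spec)
  t <- co$truth
  p <- seleno_params(duplication_flank_nt = 4000L)
  m <- test_matrix()
  # assemble minimal calls straight from truth (peptides re-translated)
  calls <- tibble::tibble(
    call_id = t$gene_id, species = t$species, contig = t$contig,
    strand = t$strand, start = t$start, end = t$end, family = t$family,
    overall_class = "Sec", pseudogene = FALSE,
    peptide = vapply(seq_len(nrow(t)), function(k) {
      cds <- substr(co$genomes[[t$species[k]]][[t$contig[k]]],
                    t$start[k] + 1, t$end[k])
      translate_cds(cds)
    }, ""), motif = NA_character_)
  dup <- detect_duplications(calls, co$genomes, m, p)
  expect_equal(nrow(dup), 1)
  pair <- t$gene_id[!is.na(t$duplication_id)]
  expect_setequal(c(dup$call_a, dup$call_b), pair)
  expect_gt(dup$protein_positive_frac, 0.5)
  expect_gte(dup$flank_coverage_frac, 0.2)
  # same-family pair without copied flanks fails stage 2 even though the
  # proteins are near-identical (stage 1 passes)
  fam_counts <- table(calls$family)
  same_fam <- calls[calls$family %in% names(fam_counts)[fam_counts >= 2], ]
  non_dup <- same_fam[!same_fam$call_id %in% pair, ]
  if (nrow(non_dup) >= 2) {
    d2 <- detect_duplications(non_dup, co$genomes, m, p)
    expect_equal(nrow(d2), 0)
  }
  # cross-family pairs are never tested
  cross <- calls[!duplicated(calls$family), ]
  expect_equal(nrow(detect_duplications(cross, co$genomes, m, p)), 0)
})

test_that("duplication detection is symmetric in the pair", {
  set.seed(64)
  seg <- selenoscan:::random_dna(30000)
  copy <- plant_duplication(seg, 0.01)
  genome <- list(sp = c(c1 = paste0(seg, selenoscan:::random_dna(5000), copy)))
  pep <- random_peptide_std(80)
  calls <- tibble::tibble(call_id = c("a", "b"), species = "sp", contig = "c1",
                          strand = "+",
                          start = c(14000L, 14000L + 35000L),
                          end = c(15000L, 15000L + 35000L),
                          family = "GPX", overall_class = "Sec",
                          pseudogene = FALSE, peptide = pep,
                          motif = NA_character_)
  p <- seleno_params(duplication_flank_nt = 4000L)
  d1 <- detect_duplications(calls, genome, test_matrix(), p)
  d2 <- detect_duplications(calls[2:1, ], genome, test_matrix(), p)
  expect_equal(nrow(d1), 1)
  expect_equal(d1[, c("call_a", "call_b", "flank_coverage_frac")],
               d2[, c("call_a", "call_b", "flank_coverage_frac")])
})

test_that("presence cells are the union of call classes", {
  calls <- dplyr::bind_rows(
    fake_calls(1, 10, species = "spA", family = "GPX", class = "Sec"),
    fake_calls(100, 110, species = "spA", family = "GPX", class = "Cys"),
    fake_calls(1, 10, species = "spA", family = "GRX", class = "Other"),
    fake_calls(1, 10, species = "spB", family = "GPX", class = "Cys"))
  mat <- build_presence_matrix(calls)
  cells <- mat$cells
  cell <- function(sp, f) cells$presence[cells$species == sp &
                                           cells$family == f]
  expect_equal(cell("spA", "GPX"), "Sec&Cys")
  expect_equal(cell("spA", "GRX"), "Other")
  expect_equal(cell("spB", "GPX"), "Cys")
  expect_equal(cell("spB", "GRX"), "absent")
  # empty call set: all-absent matrix over a declared universe
  m0 <- build_presence_matrix(fake_calls(integer(0), integer(0))[0, ],
                              species = c("s1", "s2"), families = "GPX")
  expect_true(all(m0$cells$presence == "absent"))
  # cell classes are invariant to call order; totals recount the calls
  mat2 <- build_presence_matrix(calls[sample(nrow(calls)), ])
  expect_equal(mat$cells, mat2$cells)
  expect_equal(sum(mat$species_totals$n_families), 3)
})

test_that("matrix clustering is deterministic and input-order invariant", {
  set.seed(65)
  calls <- dplyr::bind_rows(
    fake_calls(1, 10, species = "spA", family = "GPX", class = "Sec"),
    fake_calls(1, 10, species = "spA", family = "GRX", class = "Sec"),
    fake_calls(1, 10, species = "spB", family = "GPX", class = "Sec"),
    fake_calls(1, 10, species = "spB", family = "GRX", class = "Sec"),
    fake_calls(1, 10, species = "spC", family = "MSRA", class = "Cys"))
  mat <- build_presence_matrix(calls, species = c("spA", "spB", "spC", "spD"))
  cl1 <- cluster_matrix(mat)
  cl2 <- cluster_matrix(build_presence_matrix(
    calls[rev(seq_len(nrow(calls))), ],
    species = c("spD", "spC", "spB", "spA")))
  expect_identical(cl1$species_order, cl2$species_order)
  expect_identical(cl1$family_order, cl2$family_order)
  # identical profiles sit adjacent (distance zero)
  pa <- match("spA", cl1$species_order)
  pb <- match("spB", cl1$species_order)
  expect_equal(abs(pa - pb), 1)
  # all-absent species is maximally distant from a fully loaded one
  m <- selenoscan:::presence_indicators(mat)
  d <- as.matrix(selenoscan:::jaccard_dist(m))
  expect_equal(d["spA", "spD"], 1)
  expect_equal(d["spA", "spB"], 0)
})

test_that("motif census tabulates per family and class", {
  calls <- dplyr::bind_rows(
    fake_calls(1, 10, family = "PDI_e", class = "Sec"),
    fake_calls(20, 30, family = "PDI_e", class = "Sec"),
    fake_calls(40, 50, family = "AhpC_b", class = "Cys"))
  calls$motif <- c("GUGUU", "GUGUU", "CLFC")
  cen <- motif_census(calls)
  expect_equal(cen$n[cen$family == "PDI_e" & cen$motif == "GUGUU"], 2L)
  expect_equal(cen$motif[cen$family == "AhpC_b"], "CLFC")
  expect_equal(nrow(motif_census(calls[0, ])), 0)
})
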