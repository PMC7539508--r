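# Synthetic cohorts with planted truth: multi-contig genomes carrying
# intronless selenoprotein genes (1-3 in-frame TGAs at family Sec positions,
# canonical SECIS downstream), Cys- and Other-homolog variants, frameshifted
# pseudogene copies, tandem clusters, near-identical gene+flank duplications,
# and ESTs sampled from the planted transcripts.

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

#' Synthetic reference family database
#'
#' Builds a synthetic database of selenoprotein-like families for simulation
#' and testing: random peptides with planted Sec sites and, for three
#' families, the field's diagnostic Sec-flank motifs (the triple-Sec GUGUU
#' pattern of PDI_e, the UxxC pattern of AhpC_b, the CxU pattern of SELENOF).
#' Members of a family differ by ~8% random substitutions outside the motif.
#'
#' @param n_families Number of families (up to 10).
#' @param members_per_family Members per family.
#' @param seed Integer seed.
#' @return A `seleno_refdb` tibble.
#' @export
example_reference_db <- function(n_families = 10, members_per_family = 2,
                                 seed = 42) {
  designs <- list(
    list(name = "GPX", motif = NA, len = 110),
    list(name = "TXNRD", motif = NA, len = 120),
    list(name = "PDI_e", motif = "GUGUU", len = 100),
    list(name = "AhpC_b", motif = "UxxC", len = 100),
    list(name = "SELENOF", motif = "CxU", len = 90),
    list(name = "GST", motif = NA, len = 105),
    list(name = "MSRA", motif = NA, len = 115),
    list(name = "GRX", motif = NA, len = 85),
    list(name = "SELENOU", motif = NA, len = 95),
    list(name = "SELENOW", motif = NA, len = 88)
  )
  if (n_families > length(designs)) {
    abort(paste0("at most ", length(designs), " built-in families"))
  }
  designs <- designs[seq_len(n_families)]
  local_seed(seed, {
    rows <- list()
    for (d in designs) {
      cons <- strsplit(random_peptide(d$len), "")[[1]]
      if (!is.na(d$motif)) {
        mot <- strsplit(d$motif, "")[[1]]
        mot[mot == "x"] <- sample(setdiff(AA_STANDARD, "C"), sum(mot == "x"),
                                  replace = TRUE)
        at <- sample(seq(round(d$len * 0.3), round(d$len * 0.6)), 1)
        cons[at:(at + length(mot) - 1)] <- mot
        protect <- at:(at + length(mot) - 1)
      } else {
        at <- sample(seq(round(d$len * 0.3), round(d$len * 0.7)), 1)
        cons[at] <- "U"
        protect <- at
      }
      for (m in seq_len(members_per_family)) {
        res <- cons
        mut <- setdiff(which(runif(d$len) < 0.08), protect)
        res[mut] <- vapply(res[mut], function(r) {
          sample(setdiff(AA_STANDARD, r), 1)
        }, "")
        rows[[length(rows) + 1]] <- tibble(
          id = paste0(d$name, "_", m), family = d$name,
          residues = paste0(res, collapse = ""),
          motif = if (is.na(d$motif)) NA_character_ else d$motif)
      }
    }
    db <- bind_rows(rows)
    db$sec_positions <- map(db$residues, function(s) {
      which(strsplit(s, "")[[1]] == "U") - 1L
    })
    db$length <- nchar(db$residues)
    new_refdb(db)
  })
}

#' Specification of a synthetic cohort
#'
#' Defaults describe the package's reference study conditions: 5 species of
#' four 500-kb contigs each, carrying per species 30 Sec genes, 20
#' Cys-homologs, 5 Other-homologs and 5 frameshifted pseudogenes drawn from
#' 10 reference families, 2 tandem clusters, 2 gene+flank duplications, every
#' Sec gene followed by a canonical SECIS, and noise-free coding sequence
#' (`mutation_rate = 0`; duplication copies instead diverge by 0.5% in their
#' flanks, emulating the published >98%-positive copy pairs).
#'
#' @param n_species,contigs_per_species,contig_length_nt Cohort geometry.
#' @param families A `seleno_refdb` to plant from.
#' @param n_sec_genes,n_cys_homologs,n_other_homologs,n_pseudogenes Gene
#'   counts per species (cluster members and duplication sources are drawn
#'   from the Sec budget; duplication copies are added on top).
#' @param n_clusters Tandem clusters (of `cluster_size` genes) per species.
#' @param cluster_size Genes per planted cluster.
#' @param n_duplications Gene+flank duplication events per species.
#' @param secis_attach_prob Probability a Sec gene receives a SECIS.
#' @param mutation_rate Per-site substitution rate applied to planted CDS
#'   outside the Sec-flank windows.
#' @param dup_divergence Per-site substitution rate applied to the flanks of
#'   duplication copies.
#' @param duplication_flank_nt Flank copied on each side of a duplicated gene.
#' @param n_ests,est_length_nt,est_error_rate EST sampling parameters per
#'   species.
#' @param plant_reverse Place genes on a random strand instead of always `+`.
#' @param seed Integer seed; cohort and truth are reproducible from
#'   (spec, seed).
#' @return List of class `seleno_cohort_spec`.
#' @export
cohort_spec <- function(n_species = 5, contigs_per_species = 4,
                        contig_length_nt = 500000L, families = NULL,
                        n_sec_genes = 30, n_cys_homologs = 20,
                        n_other_homologs = 5, n_pseudogenes = 5,
                        n_clusters = 2, cluster_size = 2, n_duplications = 2,
                        secis_attach_prob = 1, mutation_rate = 0,
                        dup_divergence = 0.005,
                        duplication_flank_nt = 10000L, n_ests = 120,
                        est_length_nt = 300L, est_error_rate = 0.005,
                        plant_reverse = FALSE, seed = 1L) {
  spec <- list(n_species = n_species, contigs_per_species = contigs_per_species,
               contig_length_nt = as.integer(contig_length_nt),
               families = families %||% example_reference_db(),
               n_sec_genes = n_sec_genes, n_cys_homologs = n_cys_homologs,
               n_other_homologs = n_other_homologs,
               n_pseudogenes = n_pseudogenes, n_clusters = n_clusters,
               cluster_size = cluster_size, n_duplications = n_duplications,
               secis_attach_prob = secis_attach_prob,
               mutation_rate = mutation_rate, dup_divergence = dup_divergence,
               duplication_flank_nt = as.integer(duplication_flank_nt),
               n_ests = n_ests, est_length_nt = as.integer(est_length_nt),
               est_error_rate = est_error_rate,
               plant_reverse = isTRUE(plant_reverse), seed = as.integer(seed))
  counts <- c("n_species", "contigs_per_species", "n_sec_genes",
              "n_cys_homologs", "n_other_homologs", "n_pseudogenes",
              "n_clusters", "n_duplications", "n_ests")
  for (f in counts) if (spec[[f]] < 0) abort(paste0(f, " must be >= 0"))
  if (spec$n_sec_genes < spec$n_clusters * spec$cluster_size +
        spec$n_duplications) {
    abort("n_sec_genes must cover cluster members and duplication sources")
  }
  # rough packing validation: planted material must fit with separation
  need <- (spec$n_sec_genes + spec$n_cys_homologs + spec$n_other_homologs +
             spec$n_pseudogenes) * 4500 +
    spec$n_duplications * 2 * (2 * spec$duplication_flank_nt + 4500)
  avail <- spec$contigs_per_species * spec$contig_length_nt
  if (spec$n_species > 0 && need > 0.8 * avail) {
    abort("planted features do not fit the contigs; enlarge the genome")
  }
  structure(spec, class = "seleno_cohort_spec")
}

#' Back-translate a reference member into a plantable CDS
#'
#' The CDS is `ATG` + the back-translated peptide + `TAA`; Sec positions
#' become TGA for class `Sec`, TGC/TGT for class `Cys`, and a random non-Cys
#' codon one mutation away from TGA (TGG and similar) for class `Other`.
#' Point mutations at `mutation_rate` are applied outside the Sec-flank
#' windows; a mutation that would create an in-frame stop codon is reverted,
#' so the planted class is unambiguous.
#'
#' @param residues Reference member peptide (with `U` at Sec sites).
#' @param planted_class `"Sec"`, `"Cys"` or `"Other"`.
#' @param mutation_rate Per-site substitution probability.
#' @param sec_window Residues on each side of a Sec site protected from
#'   mutation.
#' @return List: `cds`, `sec_codon_offsets` (0-based codon indices of TGA in
#'   the CDS; empty unless class `Sec`), `peptide` (the encoded protein),
#'   `planted_class`.
#' @export
plant_gene <- function(residues, planted_class = c("Sec", "Cys", "Other"),
                       mutation_rate = 0, sec_window = 5L) {
  planted_class <- match.arg(planted_class)
  aa <- strsplit(residues, "")[[1]]
  secs <- which(aa == "U")
  codons <- unname(BACK_CODON[aa])
  if (anyNA(codons)) {
    abort("residues contain letters outside the back-translation table")
  }
  if (planted_class == "Cys") {
    codons[secs] <- sample(c("TGC", "TGT"), length(secs), replace = TRUE)
  } else if (planted_class == "Other") {
    codons[secs] <- sample(c("TGG", "CGT", "TCT", "GGT"), length(secs),
                           replace = TRUE)
  }
  cds <- paste0("ATG", paste0(codons, collapse = ""), "TAA")
  sec_offs <- if (planted_class == "Sec") as.integer(secs) else integer(0)
  if (mutation_rate > 0) {
    protect <- c(1:3, (nchar(cds) - 2):nchar(cds))
    for (s in secs) {
      lo <- max(1L, 3L * (s - sec_window) + 1L)
      hi <- min(nchar(cds), 3L * (s + sec_window) + 3L)
      protect <- c(protect, lo:hi)
    }
    mutated <- mutate_dna(cds, mutation_rate, protect = unique(protect))
    # revert any codon that mutated into a stop (or into TGA for non-Sec)
    n <- nchar(mutated)
    mcod <- substring(mutated, seq(1, n - 2, 3), seq(3, n, 3))
    ocod <- substring(cds, seq(1, n - 2, 3), seq(3, n, 3))
    inner <- seq_len(length(mcod) - 1)[-1]
    bad <- inner[mcod[inner] %in% c("TAA", "TAG", "TGA") &
                   ocod[inner] != mcod[inner]]
    mcod[bad] <- ocod[bad]
    cds <- paste0(mcod, collapse = "")
  }
  peptide <- translate_cds(substr(cds, 1, nchar(cds) - 3))
  list(cds = cds, sec_codon_offsets = sec_offs, peptide = peptide,
       planted_class = planted_class)
}

#' Introduce a single frameshifting indel into a CDS
#'
#' Exactly one 1- or 2-nt insertion or deletion at a codon at least 5 codons
#' from either end of the CDS.
#'
#' @param cds DNA string (length a multiple of 3).
#' @param codon 0-based codon index for the indel; random when `NULL`.
#' @param kind `"insertion"` or `"deletion"`; random when `NULL`.
#' @param len 1 or 2; random when `NULL`.
#' @return List: `cds` (frameshifted), `indel_offset_nt` (0-based nt offset),
#'   `kind`, `length`.
#' @export
plant_pseudogene <- function(cds, codon = NULL, kind = NULL, len = NULL) {
  ncod <- nchar(cds) %/% 3
  lo <- 5L; hi <- ncod - 5L
  if (hi < lo) abort("CDS too short to place an interior indel")
  codon <- codon %||% sample(lo:hi, 1)
  if (codon < lo || codon > hi) {
    abort("indel codon must be >= 5 codons from either end")
  }
  kind <- kind %||% sample(c("insertion", "deletion"), 1)
  len <- len %||% sample(1:2, 1)
  off <- 3L * as.integer(codon)
  if (kind == "deletion") {
    out <- paste0(substr(cds, 1, off), substr(cds, off + len + 1, nchar(cds)))
  } else {
    out <- paste0(substr(cds, 1, off), random_dna(len),
                  substr(cds, off + 1, nchar(cds)))
  }
  list(cds = out, indel_offset_nt = off, kind = kind, length = as.integer(len))
}

#' Mutated copy of a genomic segment
#'
#' Applies independent substitutions at `divergence` to a segment, sparing
#' `protect` (1-based positions); used to emit near-identical gene+flank
#' duplication copies.
#'
#' @param segment DNA string.
#' @param divergence Per-site substitution probability.
#' @param protect Integer vector of protected 1-based positions.
#' @return Mutated DNA string of identical length.
#' @export
plant_duplication <- function(segment, divergence = 0.005,
                              protect = integer(0)) {
  mutate_dna(segment, divergence, protect = protect)
}

#' Sample ESTs from transcript sequences
#'
#' Substrings of planted transcripts with iid sequencing errors.
#'
#' @param transcripts Named character vector of transcript sequences.
#' @param n Number of ESTs.
#' @param est_length_nt Target EST length (clipped to the transcript).
#' @param error_rate Per-site substitution error probability.
#' @return List: `ests` (named character vector) and `truth` (tibble linking
#'   `est_id` to `gene_id` and transcript offsets).
#' @export
sample_ests <- function(transcripts, n = 100, est_length_nt = 300L,
                        error_rate = 0.005) {
  empty <- list(ests = setNames(character(0), character(0)),
                truth = tibble(est_id = character(0), gene_id = character(0),
                               t_start = integer(0), t_end = integer(0)))
  if (length(transcripts) == 0 || n == 0) return(empty)
  ests <- character(n); src <- character(n); st <- integer(n); en <- integer(n)
  for (k in seq_len(n)) {
    gi <- sample(length(transcripts), 1)
    tr <- transcripts[[gi]]
    len <- min(est_length_nt, nchar(tr))
    s <- if (nchar(tr) > len) sample(0:(nchar(tr) - len), 1) else 0L
    ests[k] <- mutate_dna(substr(tr, s + 1, s + len), error_rate)
    src[k] <- names(transcripts)[gi]
    st[k] <- s; en[k] <- s + len
  }
  ids <- sprintf("est%04d", seq_len(n))
  list(ests = setNames(ests, ids),
       truth = tibble(est_id = ids, gene_id = src, t_start = st, t_end = en))
}

truth_empty <- function() {
  tibble(species = character(0), contig = character(0), gene_id = character(0),
         family = character(0), member_id = character(0),
         planted_class = character(0), strand = character(0),
         start = integer(0), end = integer(0), sec_codon_offsets = list(),
         indel_offset_nt = integer(0), indel_kind = character(0),
         secis_present = logical(0), secis_start = integer(0),
         secis_end = integer(0), cluster_id = character(0),
         duplication_id = character(0))
}

#' Generate a synthetic cohort with planted truth
#'
#' Emits, per species, multi-contig genomes carrying planted genes of every
#' class, transcripts and ESTs, and a truth table for every planted feature.
#' On emission every truth record is sliced back out of the genome and
#' re-translated to confirm its intended class. Jointly reproducible from
#' (spec, seed).
#'
#' @param spec A [cohort_spec()].
#' @return List of class `seleno_cohort`: `spec`, `genomes` (list species ->
#'   named contig vector), `transcripts`, `ests`, `truth` (tibble),
#'   `est_truth`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  local_seed(spec$seed, {
    db <- spec$families
    fams <- sort(unique(db$family))
    genomes <- list(); transcripts <- list(); ests <- list()
    truth_rows <- list(); est_truth <- list()
    for (sp in seq_len(spec$n_species)) {
      species <- sprintf("species%02d", sp)
      nc <- spec$contigs_per_species
      clen <- spec$contig_length_nt
      contigs <- setNames(
        vapply(seq_len(nc), function(i) random_dna(clen), ""),
        sprintf("%s_ctg%02d", species, seq_len(nc)))
      occupied <- rep(list(matrix(numeric(0), ncol = 2)), nc)
      min_sep <- 3000L
      place <- function(len) {
        for (try in 1:400) {
          ci <- sample(nc, 1)
          if (clen - len - 1 <= 1) next
          pos <- sample.int(clen - len - 1, 1)
          occ <- occupied[[ci]]
          ok <- nrow(occ) == 0 ||
            all(pos + len + min_sep <= occ[, 1] | pos >= occ[, 2] + min_sep)
          if (ok) {
            occupied[[ci]] <<- rbind(occ, c(pos, pos + len))
            return(list(contig = ci, pos = pos))
          }
        }
        abort("could not pack feature into the cohort (enlarge the contigs)")
      }
      write_cassette <- function(ci, pos, cas_str, strand) {
        s <- if (strand == "-") revcomp(cas_str) else cas_str
        ctg <- contigs[[ci]]
        substr(ctg, pos + 1, pos + nchar(s)) <- s
        contigs[[ci]] <<- ctg
        invisible(NULL)
      }
      pick_strand <- function() {
        if (spec$plant_reverse) sample(c("+", "-"), 1) else "+"
      }
      gene_no <- 0L
      sp_transcripts <- character(0)

      make_cassette <- function(member_row, cls) {
        indel <- NULL
        if (cls == "Pseudogene") {
          base_cls <- sample(c("Sec", "Cys"), 1)
          g <- plant_gene(member_row$residues, base_cls,
                          mutation_rate = spec$mutation_rate)
          indel <- plant_pseudogene(g$cds)
          cds <- indel$cds
          with_secis <- FALSE
        } else {
          g <- plant_gene(member_row$residues, cls,
                          mutation_rate = spec$mutation_rate)
          cds <- g$cds
          with_secis <- cls == "Sec" && runif(1) < spec$secis_attach_prob
        }
        secis <- NULL
        if (with_secis) {
          spacer <- sample(50:400, 1)
          el <- plant_secis()
          cas <- paste0(cds, random_dna(spacer), el$seq, random_dna(50))
          secis <- list(start = nchar(cds) + spacer,
                        end = nchar(cds) + spacer + nchar(el$seq))
        } else {
          cas <- paste0(cds, random_dna(100))
        }
        list(cassette = cas, cds_len = nchar(cds) - 3L, secis = secis,
             sec_offs = g$sec_codon_offsets,
             indel_off = if (is.null(indel)) NA_integer_ else indel$indel_offset_nt,
             indel_kind = if (is.null(indel)) NA_character_ else indel$kind)
      }

      add_truth <- function(ci, pos, cas, member_row, cls, strand,
                            cluster_id = NA_character_,
                            duplication_id = NA_character_) {
        gene_no <<- gene_no + 1L
        gid <- sprintf("%s_g%03d", species, gene_no)
        cas_len <- nchar(cas$cassette)
        if (strand == "+") {
          gstart <- pos; gend <- pos + cas$cds_len
          ss <- if (is.null(cas$secis)) NA_integer_ else pos + cas$secis$start
          se <- if (is.null(cas$secis)) NA_integer_ else pos + cas$secis$end
        } else {
          gstart <- pos + cas_len - cas$cds_len; gend <- pos + cas_len
          ss <- if (is.null(cas$secis)) NA_integer_ else pos + cas_len - cas$secis$end
          se <- if (is.null(cas$secis)) NA_integer_ else pos + cas_len - cas$secis$start
        }
        truth_rows[[length(truth_rows) + 1]] <<- tibble(
          species = species, contig = names(contigs)[ci], gene_id = gid,
          family = member_row$family, member_id = member_row$id,
          planted_class = cls, strand = strand,
          start = as.integer(gstart), end = as.integer(gend),
          sec_codon_offsets = list(cas$sec_offs),
          indel_offset_nt = cas$indel_off, indel_kind = cas$indel_kind,
          secis_present = !is.null(cas$secis),
          secis_start = as.integer(ss), secis_end = as.integer(se),
          cluster_id = cluster_id, duplication_id = duplication_id)
        gid
      }

      plant_one <- function(member_row, cls, cluster_id = NA_character_,
                            at = NULL, strand = NULL) {
        cas <- make_cassette(member_row, cls)
        strand <- strand %||% pick_strand()
        loc <- at %||% place(nchar(cas$cassette))
        write_cassette(loc$contig, loc$pos, cas$cassette, strand)
        gid <- add_truth(loc$contig, loc$pos, cas, member_row, cls, strand,
                         cluster_id = cluster_id)
        if (cls != "Pseudogene") sp_transcripts[[gid]] <<- cas$cassette
        invisible(gid)
      }

      pick_member <- function(fam) {
        sub <- db[db$family == fam, ]
        sub[sample(nrow(sub), 1), ]
      }
      sec_fam_cycle <- rep(fams, length.out = spec$n_sec_genes)
      fam_i <- 0L
      next_sec_fam <- function() {
        fam_i <<- fam_i + 1L
        sec_fam_cycle[fam_i]
      }

      # 1) gene+flank duplications: source reserved with clean flanks, then
      #    the whole segment is copied (flanks diverged) to a distant locus
      flank <- spec$duplication_flank_nt
      for (d in seq_len(spec$n_duplications)) {
        member <- pick_member(next_sec_fam())
        cas <- make_cassette(member, "Sec")
        L <- nchar(cas$cassette)
        seg_len <- L + 2L * flank
        strand <- pick_strand()
        loc <- place(seg_len)
        write_cassette(loc$contig, loc$pos + flank, cas$cassette, strand)
        dup_id <- sprintf("%s_dup%02d", species, d)
        gid <- add_truth(loc$contig, loc$pos + flank, cas, member, "Sec",
                         strand, duplication_id = dup_id)
        sp_transcripts[[gid]] <- cas$cassette
        segment <- substr(contigs[[loc$contig]], loc$pos + 1,
                          loc$pos + seg_len)
        copy <- plant_duplication(segment, spec$dup_divergence,
                                  protect = (flank + 1L):(flank + L))
        loc2 <- place(seg_len)
        ctg2 <- contigs[[loc2$contig]]
        substr(ctg2, loc2$pos + 1, loc2$pos + seg_len) <- copy
        contigs[[loc2$contig]] <- ctg2
        occupied[[loc2$contig]] <- occupied[[loc2$contig]]  # already reserved
        gid2 <- add_truth(loc2$contig, loc2$pos + flank, cas, member, "Sec",
                          strand, duplication_id = dup_id)
        sp_transcripts[[gid2]] <- cas$cassette
      }
      # 2) tandem clusters from the Sec budget
      for (cl in seq_len(spec$n_clusters)) {
        members <- lapply(seq_len(spec$cluster_size),
                          function(i) pick_member(next_sec_fam()))
        cass <- lapply(members, function(m) make_cassette(m, "Sec"))
        gaps <- sample(2000:6000, spec$cluster_size - 1, replace = TRUE)
        total <- sum(vapply(cass, function(x) nchar(x$cassette), 0)) +
          sum(gaps)
        loc <- place(total)
        cid <- sprintf("%s_cl%02d", species, cl)
        pos <- loc$pos
        for (i in seq_along(cass)) {
          strand <- pick_strand()
          write_cassette(loc$contig, pos, cass[[i]]$cassette, strand)
          gid <- add_truth(loc$contig, pos, cass[[i]], members[[i]], "Sec",
                           strand, cluster_id = cid)
          sp_transcripts[[gid]] <- cass[[i]]$cassette
          pos <- pos + nchar(cass[[i]]$cassette) +
            if (i < length(cass)) gaps[i] else 0L
        }
      }
      # 3) remaining singles
      n_single <- spec$n_sec_genes - spec$n_clusters * spec$cluster_size -
        spec$n_duplications
      for (i in seq_len(max(0, n_single))) {
        plant_one(pick_member(next_sec_fam()), "Sec")
      }
      for (i in seq_len(spec$n_cys_homologs)) {
        plant_one(pick_member(sample(fams, 1)), "Cys")
      }
      for (i in seq_len(spec$n_other_homologs)) {
        plant_one(pick_member(sample(fams, 1)), "Other")
      }
      for (i in seq_len(spec$n_pseudogenes)) {
        plant_one(pick_member(sample(fams, 1)), "Pseudogene")
      }
      genomes[[species]] <- contigs
      transcripts[[species]] <- sp_transcripts
      se <- sample_ests(sp_transcripts, spec$n_ests, spec$est_length_nt,
                        spec$est_error_rate)
      ests[[species]] <- se$ests
      if (nrow(se$truth) > 0) {
        est_truth[[length(est_truth) + 1]] <- mutate(se$truth,
                                                     species = species)
      }
    }
    truth <- if (length(truth_rows) > 0) bind_rows(truth_rows) else truth_empty()
    cohort <- structure(
      list(spec = spec, genomes = genomes, transcripts = transcripts,
           ests = ests, truth = truth,
           est_truth = if (length(est_truth) > 0) bind_rows(est_truth) else
             tibble(est_id = character(0), gene_id = character(0),
                    t_start = integer(0), t_end = integer(0),
                    species = character(0))),
      class = "seleno_cohort")
    check_cohort_truth(cohort)
    cohort
  })
}

# self-check: slice every truth record from the emitted genome and confirm
# the intended peptide class
check_cohort_truth <- function(cohort) {
  t <- cohort$truth
  for (k in seq_len(nrow(t))) {
    if (t$planted_class[k] == "Pseudogene") next
    ctg <- cohort$genomes[[t$species[k]]][[t$contig[k]]]
    cds <- substr(ctg, t$start[k] + 1, t$end[k])
    if (t$strand[k] == "-") cds <- revcomp(cds)
    pep <- translate_cds(cds)
    offs <- t$sec_codon_offsets[[k]]
    ch <- strsplit(pep, "")[[1]]
    ok <- switch(t$planted_class[k],
      Sec = length(offs) > 0 && all(ch[offs + 1] == "U"),
      Cys = !any(ch == "U"),
      Other = !any(ch == "U"))
    if (!isTRUE(ok) || any(ch == "*")) {
      abort(paste0("truth self-check failed for ", t$gene_id[k]))
    }
  }
  invisible(TRUE)
}

#' Read a cohort specification from JSON
#'
#' Keys match [cohort_spec()] arguments (the reference family database is not
#' configurable through JSON and keeps its default); unknown keys raise a
#' validation error naming the field.
#'
#' @param path Path to a JSON file.
#' @return A `seleno_cohort_spec`.
#' @export
read_cohort_spec_json <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- setdiff(names(formals(cohort_spec)), "families")
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown cohort spec field(s): ",
                 paste(unknown, collapse = ", ")))
  }
  do.call(cohort_spec, vals[intersect(names(vals), known)])
}
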