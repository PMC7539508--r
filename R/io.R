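# File formats: FASTA in (Biostrings), GFF3 + TSV out (rtracklayer /
# GenomicRanges). Internal coordinates are 0-based half-open; GFF3 writers
# convert to 1-based closed and readers convert back, so conversion is
# localized here.

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector (names are the first header token).
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)),
           vapply(strsplit(names(x), "\\s+"), `[`, "", 1))
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs Named character vector (DNA).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write assembled calls as GFF3
#'
#' Gene features with attributes `family`, `gene_class`, `pseudogene`,
#' `secis_count`, `motif`, `confidence`, `score_raw` and `species`.
#'
#' @param calls Calls tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_gff3 <- function(calls, path) {
  if (nrow(calls) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = calls$contig,
    ranges = IRanges::IRanges(start = calls$start + 1L, end = calls$end),
    strand = calls$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = "gene", ID = calls$call_id, species = calls$species,
    family = calls$family, gene_class = calls$overall_class,
    pseudogene = tolower(as.character(calls$pseudogene)),
    secis_count = calls$secis_count,
    motif = ifelse(is.na(calls$motif), ".", calls$motif),
    confidence = calls$confidence, score_raw = calls$score)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read calls written by [write_calls_gff3()]
#'
#' @param path GFF3 path.
#' @return Tibble with 0-based half-open coordinates and the exported
#'   attributes.
#' @export
read_calls_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) {
    return(tibble(call_id = character(0), species = character(0),
                  contig = character(0), strand = character(0),
                  start = integer(0), end = integer(0), family = character(0),
                  overall_class = character(0), pseudogene = logical(0),
                  secis_count = integer(0), motif = character(0),
                  confidence = character(0), score = integer(0)))
  }
  mc <- S4Vectors::mcols(gr)
  tibble(call_id = as.character(mc$ID),
         species = as.character(mc$species),
         contig = as.character(GenomicRanges::seqnames(gr)),
         strand = as.character(GenomicRanges::strand(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr),
         family = as.character(mc$family),
         overall_class = as.character(mc$gene_class),
         pseudogene = as.character(mc$pseudogene) == "true",
         secis_count = as.integer(as.character(mc$secis_count)),
         motif = ifelse(as.character(mc$motif) == ".", NA_character_,
                        as.character(mc$motif)),
         confidence = as.character(mc$confidence),
         score = as.integer(as.character(mc$score_raw)))
}

#' Write a truth table as GFF3
#'
#' @param truth Truth tibble from [simulate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_gff3 <- function(truth, path) {
  if (nrow(truth) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = truth$contig,
    ranges = IRanges::IRanges(start = truth$start + 1L, end = truth$end),
    strand = truth$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = "gene", ID = truth$gene_id, species = truth$species,
    family = truth$family, gene_class = truth$planted_class,
    secis = tolower(as.character(truth$secis_present)))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a tibble as TSV
#'
#' List columns are collapsed to comma-separated strings.
#'
#' @param x Tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_flat <- function(x, path) {
  for (cn in names(x)) {
    if (is.list(x[[cn]])) {
      x[[cn]] <- vapply(x[[cn]], function(v) {
        if (is.data.frame(v)) return(paste0(nrow(v), " rows"))
        paste(v, collapse = ",")
      }, "")
    }
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a cohort and write it to disk
#'
#' Writes, per species, the genome / transcript / EST FASTA files, plus the
#' truth table as GFF3 and TSV and a manifest recording the seed and a hash
#' of the specification.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory (created).
#' @return The `seleno_cohort`, invisibly.
#' @export
run_simulate <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(spec)
  for (sp in names(cohort$genomes)) {
    write_genome_fasta(cohort$genomes[[sp]],
                       file.path(out_dir, paste0(sp, "_genome.fasta")))
    if (length(cohort$transcripts[[sp]]) > 0) {
      write_genome_fasta(cohort$transcripts[[sp]],
                         file.path(out_dir, paste0(sp, "_transcripts.fasta")))
    }
    if (length(cohort$ests[[sp]]) > 0) {
      write_genome_fasta(cohort$ests[[sp]],
                         file.path(out_dir, paste0(sp, "_ests.fasta")))
    }
  }
  write_truth_gff3(cohort$truth, file.path(out_dir, "truth.gff3"))
  write_tsv_flat(cohort$truth, file.path(out_dir, "truth.tsv"))
  write_tsv_flat(cohort$est_truth, file.path(out_dir, "est_truth.tsv"))
  manifest <- list(seed = cohort$spec$seed,
                   spec_hash = hash(cohort$spec[setdiff(names(cohort$spec),
                                                        "families")]),
                   n_species = cohort$spec$n_species,
                   n_truth_records = nrow(cohort$truth))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(cohort)
}

#' Run prediction over a cohort directory and write reports
#'
#' Runs [seleno_predict()] for every `<species>_genome.fasta` under
#' `cohort_dir` (using `<species>_ests.fasta` when present) and writes
#' combined `calls.gff3`, `calls.tsv`, `secis.tsv` and `fusions.tsv`.
#'
#' @param cohort_dir Directory written by [run_simulate()] (or any directory
#'   following its naming).
#' @param refdb A `seleno_refdb` or FASTA path.
#' @param out_dir Output directory.
#' @param params A [seleno_params()] list.
#' @param verbose Log per-stage counts.
#' @return Combined calls tibble, invisibly.
#' @export
run_predict <- function(cohort_dir, refdb, out_dir,
                        params = seleno_params(), verbose = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(refdb) && length(refdb) == 1) {
    refdb <- read_reference_db(refdb)
  }
  genomes <- list.files(cohort_dir, pattern = "_genome\\.fasta$",
                        full.names = TRUE)
  if (length(genomes) == 0) abort("no *_genome.fasta files found")
  matrix <- seleno_scoring_matrix()
  all_calls <- list(); all_fusions <- list(); all_secis <- list()
  for (g in sort(genomes)) {
    sp <- sub("_genome\\.fasta$", "", basename(g))
    est_path <- file.path(cohort_dir, paste0(sp, "_ests.fasta"))
    ests <- if (file.exists(est_path)) read_genome_fasta(est_path) else
      character(0)
    res <- seleno_predict(read_genome_fasta(g), refdb, params, matrix,
                          ests = ests, species = sp, verbose = verbose)
    all_calls[[sp]] <- res$calls
    all_fusions[[sp]] <- res$fusions
    if (nrow(res$calls) > 0) {
      sec <- bind_rows(lapply(seq_len(nrow(res$calls)), function(i) {
        s <- res$calls$secis[[i]]
        if (nrow(s) == 0) return(NULL)
        mutate(s, call_id = res$calls$call_id[i], species = sp,
               contig = res$calls$contig[i])
      }))
      if (!is.null(sec) && nrow(sec) > 0) all_secis[[sp]] <- sec
    }
  }
  calls <- bind_rows(all_calls)
  write_calls_gff3(calls, file.path(out_dir, "calls.gff3"))
  write_tsv_flat(select(calls, -"site_classes", -"secis"),
                 file.path(out_dir, "calls.tsv"))
  secis <- if (length(all_secis) > 0) bind_rows(all_secis) else
    attach_secis_empty()
  write_tsv_flat(secis, file.path(out_dir, "secis.tsv"))
  write_tsv_flat(bind_rows(all_fusions), file.path(out_dir, "fusions.tsv"))
  invisible(calls)
}

#' Comparative reports over assembled calls
#'
#' Writes the species x family presence matrix, gene clusters, the motif
#' census, deterministic clustering leaf orders, and (when genomes are
#' supplied) flanking-duplication events.
#'
#' @param calls Combined calls tibble (several species allowed).
#' @param out_dir Output directory.
#' @param genomes Optional list species -> named contig vector, enabling
#'   duplication detection.
#' @param params A [seleno_params()] list.
#' @return List with `matrix`, `clustering`, `clusters`, `duplications`,
#'   `motifs`, invisibly.
#' @export
run_compare <- function(calls, out_dir, genomes = NULL,
                        params = seleno_params()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mat <- build_presence_matrix(calls)
  clu <- cluster_matrix(mat)
  clusters <- detect_clusters(calls, params)
  motifs <- motif_census(calls)
  dups <- if (!is.null(genomes)) {
    detect_duplications(calls, genomes, seleno_scoring_matrix(), params)
  } else NULL
  cells <- tidyr::pivot_wider(mat$cells, names_from = "species",
                              values_from = "presence")
  write_tsv_flat(cells, file.path(out_dir, "matrix.tsv"))
  write_tsv_flat(clusters, file.path(out_dir, "clusters.tsv"))
  write_tsv_flat(motifs, file.path(out_dir, "motif_census.tsv"))
  writeLines(clu$species_order, file.path(out_dir, "species_order.txt"))
  writeLines(clu$family_order, file.path(out_dir, "family_order.txt"))
  if (!is.null(dups)) {
    write_tsv_flat(dups, file.path(out_dir, "duplications.tsv"))
  }
  invisible(list(matrix = mat, clustering = clu, clusters = clusters,
                 duplications = dups, motifs = motifs))
}
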