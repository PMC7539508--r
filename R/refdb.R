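# Reference selenoprotein-family database: FASTA with Sec written as `U` and a
# `family=` key in the description line; optional `motif=` gives the family's
# canonical Sec-flank motif (with `x` matching any residue).

REF_ALLOWED <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "U", "X")

#' Read a reference selenoprotein family database
#'
#' Loads a FASTA file whose description lines follow the convention
#' `>id family=NAME [motif=PATTERN]`, with Sec written as `U` in the
#' sequences. Sec positions are derived directly from the sequence, so every
#' `U` is always indexed.
#'
#' @param path Path to the FASTA file.
#' @return A tibble of class `seleno_refdb` with one row per reference
#'   sequence: `id`, `family`, `residues`, `sec_positions` (list of 0-based
#'   indices), `length`, `motif` (family canonical motif or `NA`).
#' @export
read_reference_db <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0) abort("reference database is empty")
  headers <- names(aas)
  seqs <- toupper(as.character(aas))
  parse_one <- function(h) {
    parts <- strsplit(trimws(h), "\\s+")[[1]]
    id <- parts[1]
    kv <- parts[-1]
    fam <- sub("^family=", "", kv[grepl("^family=", kv)])
    motif <- sub("^motif=", "", kv[grepl("^motif=", kv)])
    if (length(fam) != 1 || fam == "") {
      abort(paste0("malformed header (missing family=): record '", h, "'"))
    }
    tibble(id = id, family = fam,
           motif = if (length(motif) == 1) motif else NA_character_)
  }
  meta <- bind_rows(lapply(headers, parse_one))
  if (anyDuplicated(meta$id)) {
    abort(paste0("duplicate reference ids: ",
                 paste(unique(meta$id[duplicated(meta$id)]), collapse = ", ")))
  }
  db <- meta
  db$residues <- unname(seqs)
  bad <- map_lgl(db$residues, function(s) {
    any(!strsplit(s, "")[[1]] %in% REF_ALLOWED)
  })
  if (any(bad)) {
    abort(paste0("record '", db$id[bad][1], "' contains residues outside the ",
                 "20 standard letters plus U/X"))
  }
  if (any(nchar(db$residues) == 0)) {
    abort(paste0("record '", db$id[nchar(db$residues) == 0][1], "' is empty"))
  }
  db$sec_positions <- map(db$residues, function(s) {
    which(strsplit(s, "")[[1]] == "U") - 1L
  })
  db$length <- nchar(db$residues)
  # family motif: first declared motif wins; must occur in >= 1 member
  fam_motif <- db |>
    group_by(.data$family) |>
    summarise(motif = {
      m <- .data$motif[!is.na(.data$motif)]
      if (length(m) > 0) m[1] else NA_character_
    }, .groups = "drop")
  db$motif <- NULL
  db <- left_join(db, fam_motif, by = "family")
  for (f in unique(db$family)) {
    m <- db$motif[db$family == f][1]
    if (!is.na(m)) {
      rx <- gsub("x", ".", m, fixed = TRUE)
      if (!any(grepl(rx, db$residues[db$family == f]))) {
        abort(paste0("family '", f, "' declares motif '", m,
                     "' but no member contains it"))
      }
    }
  }
  new_refdb(db)
}

new_refdb <- function(db) {
  db <- as_tibble(db)[, c("id", "family", "residues", "sec_positions",
                          "length", "motif")]
  class(db) <- c("seleno_refdb", class(db))
  db
}

#' Write a reference database back to FASTA
#'
#' Inverse of [read_reference_db()]; a reload yields an identical database.
#'
#' @param db A `seleno_refdb` tibble.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_db <- function(db, path) {
  hdr <- paste0(db$id, " family=", db$family,
                ifelse(is.na(db$motif), "", paste0(" motif=", db$motif)))
  x <- Biostrings::AAStringSet(db$residues)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Summarise reference families
#'
#' @param db A `seleno_refdb` tibble.
#' @return Tibble with one row per family: name, member count, total Sec
#'   sites, canonical motif.
#' @export
reference_families <- function(db) {
  db |>
    group_by(family = .data$family) |>
    summarise(n_members = n(),
              n_sec_sites = sum(lengths(.data$sec_positions)),
              motif = .data$motif[1],
              .groups = "drop")
}

#' Build the Sec-aware substitution scoring matrix
#'
#' Extends a standard protein substitution table to selenocysteine: the `U`
#' row/column copies the `C` row, except that `U`-`U` scores
#' `score(C,C) + sec_bonus`. This makes Sec-Sec pairings preferred over
#' Sec-Cys, which in turn outscore every other pairing with Sec, without
#' distorting the remainder of the matrix.
#'
#' @param base Name of the base table (`"BLOSUM62"`, as shipped with
#'   Biostrings).
#' @param sec_bonus Positive integer added to `score(C,C)` for the `U`-`U`
#'   pair.
#' @param gap_open Score for the first residue of a gap (negative).
#' @param gap_extend Score for each subsequent gap residue (negative).
#' @return Integer matrix over the 20 standard residues plus `U`, `X` and
#'   `*`, with attributes `gap_open` and `gap_extend`; class
#'   `seleno_scoring_matrix`.
#' @export
seleno_scoring_matrix <- function(base = "BLOSUM62", sec_bonus = 2L,
                                  gap_open = -11L, gap_extend = -1L) {
  if (!is.numeric(sec_bonus) || sec_bonus <= 0) {
    abort("sec_bonus must be a positive integer (U-U must outscore U-C)")
  }
  if (gap_open >= 0 || gap_extend >= 0) abort("gap scores must be negative")
  e <- new.env()
  data(list = base, package = "Biostrings", envir = e)
  bm <- get(base, envir = e)
  keep <- c(AA_STANDARD, "X", "*")
  if (!all(keep %in% rownames(bm))) {
    abort(paste0("base table '", base, "' does not cover the standard residues"))
  }
  m <- bm[keep, keep]
  full <- matrix(0L, nrow(m) + 1, ncol(m) + 1,
                 dimnames = list(c(rownames(m), "U"), c(colnames(m), "U")))
  full[rownames(m), colnames(m)] <- m
  full["U", colnames(m)] <- m["C", ]
  full[rownames(m), "U"] <- m[, "C"]
  full["U", "U"] <- m["C", "C"] + as.integer(sec_bonus)
  storage.mode(full) <- "integer"
  stopifnot(identical(full, t(full)))
  structure(full, gap_open = as.integer(gap_open),
            gap_extend = as.integer(gap_extend),
            class = c("seleno_scoring_matrix", class(full)))
}

#' Pipeline parameters
#'
#' All tunable thresholds of the discovery pipeline in one validated list.
#' Defaults: up to 3 read-through TGAs per ORF (the largest known Sec count
#' per gene among the reference families), 30 aa minimum ORF length, a
#' +/-5-residue window around each Sec column with at least 40% positively
#' scoring columns, raw local-alignment score cut-off 60, 3000 nt SECIS
#' search window, 10 kb cluster gap, and the published duplication rules
#' (protein positive rate > 50%, flank identity >= 80%, covered fraction
#' >= 20% of the compared segment, 10 kb flanks).
#'
#' @param max_readthrough_tga Maximum internal TGA codons read through as Sec.
#' @param min_orf_aa Minimum ORF length in residues.
#' @param sec_window Residues on each side of a Sec column used for the
#'   local-conservation check.
#' @param min_window_positive_frac Minimum fraction of positively scoring
#'   columns in the Sec window; below it the site is called Unaligned.
#' @param min_hit_score Minimum local alignment score for a family hit.
#' @param secis_search_window_nt Search window downstream of the stop codon.
#' @param duplication_positive_frac Protein-level positive-rate threshold.
#' @param duplication_identity_frac Nucleotide block identity threshold.
#' @param duplication_coverage_frac Minimum covered fraction of the compared
#'   gene+flank segment.
#' @param duplication_flank_nt Flank length on each side of a gene.
#' @param cluster_max_gap_nt Maximum inter-gene gap within a cluster.
#' @param est_min_identity_frac Minimum EST identity to support an indel.
#' @param seed Integer seed used by stochastic stages.
#' @param kmer_prefilter_k Peptide k-mer length for the alignment prefilter.
#' @param merge_gap_nt Same-family loci closer than this are merged into one
#'   locus before frameshift scanning (rejoins pseudogene fragments).
#' @param frameshift_penalty Score penalty per frameshift event.
#' @param fs_gap_penalty Per-unit gap penalty in the protein-to-DNA aligner.
#' @param locus_flank_nt Extension of a locus window before frameshift
#'   scanning.
#' @param require_atg Restrict genomic ORFs to ATG-initiated ones.
#' @return A validated list of class `seleno_params`.
#' @export
seleno_params <- function(max_readthrough_tga = 3L, min_orf_aa = 30L,
                          sec_window = 5L, min_window_positive_frac = 0.4,
                          min_hit_score = 60L, secis_search_window_nt = 3000L,
                          duplication_positive_frac = 0.50,
                          duplication_identity_frac = 0.80,
                          duplication_coverage_frac = 0.20,
                          duplication_flank_nt = 10000L,
                          cluster_max_gap_nt = 10000L,
                          est_min_identity_frac = 0.95, seed = 1L,
                          kmer_prefilter_k = 6L, merge_gap_nt = 1000L,
                          frameshift_penalty = 12L, fs_gap_penalty = 8L,
                          locus_flank_nt = 300L, require_atg = FALSE) {
  p <- list(max_readthrough_tga = as.integer(max_readthrough_tga),
            min_orf_aa = as.integer(min_orf_aa),
            sec_window = as.integer(sec_window),
            min_window_positive_frac = min_window_positive_frac,
            min_hit_score = as.integer(min_hit_score),
            secis_search_window_nt = as.integer(secis_search_window_nt),
            duplication_positive_frac = duplication_positive_frac,
            duplication_identity_frac = duplication_identity_frac,
            duplication_coverage_frac = duplication_coverage_frac,
            duplication_flank_nt = as.integer(duplication_flank_nt),
            cluster_max_gap_nt = as.integer(cluster_max_gap_nt),
            est_min_identity_frac = est_min_identity_frac,
            seed = as.integer(seed),
            kmer_prefilter_k = as.integer(kmer_prefilter_k),
            merge_gap_nt = as.integer(merge_gap_nt),
            frameshift_penalty = as.integer(frameshift_penalty),
            fs_gap_penalty = as.integer(fs_gap_penalty),
            locus_flank_nt = as.integer(locus_flank_nt),
            require_atg = isTRUE(require_atg))
  fracs <- c("min_window_positive_frac", "duplication_positive_frac",
             "duplication_identity_frac", "duplication_coverage_frac",
             "est_min_identity_frac")
  for (f in fracs) {
    if (!is.numeric(p[[f]]) || p[[f]] < 0 || p[[f]] > 1) {
      abort(paste0(f, " must lie in [0, 1]"))
    }
  }
  lens <- c("min_orf_aa", "sec_window", "secis_search_window_nt",
            "duplication_flank_nt", "cluster_max_gap_nt", "kmer_prefilter_k")
  for (f in lens) {
    if (p[[f]] <= 0) abort(paste0(f, " must be positive"))
  }
  if (p$max_readthrough_tga < 0) abort("max_readthrough_tga must be >= 0")
  structure(p, class = "seleno_params")
}

#' Read parameters from a JSON config file
#'
#' @param path Path to a JSON file whose keys match [seleno_params()]
#'   arguments; absent keys fall back to the defaults.
#' @return A `seleno_params` list.
#' @export
read_params_json <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(seleno_params))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown parameter(s) in config: ",
                 paste(unknown, collapse = ", ")))
  }
  do.call(seleno_params, vals[intersect(names(vals), known)])
}
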