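# Read-through ORF enumeration. An ORF is a run of codons free of TAA/TAG in
# which up to `max_readthrough_tga` internal TGA codons are provisionally
# translated as Sec (U); for every such locus the terminate-at-TGA prefix
# variants are emitted as well, so that downstream homology - not this stage -
# decides whether a TGA is Sec or stop.

orf_empty <- function() {
  tibble(contig = character(0), species = character(0), strand = character(0),
         start = integer(0), end = integer(0), frame = integer(0),
         peptide = character(0), tga_offsets = list(),
         terminal_stop = character(0), n_tga = integer(0),
         length_aa = integer(0), orf_id = character(0))
}

#' Enumerate read-through ORFs on both strands of a contig
#'
#' For each strand and frame, maximal segments bounded by TAA/TAG or the
#' sequence ends are enumerated once per choice of at most
#' `params$max_readthrough_tga` read-through TGAs: the maximal ORF treating
#' its internal TGAs as Sec, plus every prefix ORF terminating at each
#' internal TGA. ORFs shorter than `params$min_orf_aa` are dropped;
#' N-containing codons translate to `X` and never count as stops.
#'
#' @param contig_seq DNA string over A/C/G/T/N (case-insensitive).
#' @param params A [seleno_params()] list.
#' @param contig Contig identifier recorded in the output.
#' @param species Species label recorded in the output.
#' @param strands `"both"` (default), `"forward"`, or `"reverse"`.
#' @param require_atg Restrict to ATG-initiated ORFs; defaults to
#'   `params$require_atg`.
#' @return Tibble with one row per candidate ORF: `contig`, `species`,
#'   `strand`, `start`/`end` (0-based half-open forward-strand nt
#'   coordinates, excluding the terminal stop), `frame` (0/1/2 on its own
#'   strand), `peptide` (with `U` at read-through positions), `tga_offsets`
#'   (list of 0-based codon indices), `terminal_stop` (codon or `NA`),
#'   `n_tga`, `length_aa`, `orf_id`.
#' @export
enumerate_orfs <- function(contig_seq, params = seleno_params(),
                           contig = "contig", species = "sample",
                           strands = "both", require_atg = NULL) {
  contig_seq <- toupper(contig_seq)
  if (nchar(contig_seq) == 0) abort(paste0("contig '", contig, "' is empty"))
  bad <- regexpr("[^ACGTN]", contig_seq)
  if (bad > 0) {
    abort(paste0("contig '", contig, "': non-ACGTN character at offset ",
                 bad - 1))
  }
  require_atg <- require_atg %||% params$require_atg
  tab <- codon_table()
  one_strand <- function(s, strand) {
    res <- cpp_enumerate_orfs(s, params$max_readthrough_tga, params$min_orf_aa,
                              require_atg, names(tab), unname(tab))
    k <- length(res$start)
    if (k == 0) return(orf_empty())
    n <- nchar(s)
    if (strand == "+") {
      start <- res$start; end <- res$end
    } else {
      start <- n - res$end; end <- n - res$start
    }
    tibble(contig = contig, species = species, strand = strand,
           start = as.integer(start), end = as.integer(end),
           frame = as.integer(res$frame), peptide = res$peptide,
           tga_offsets = lapply(res$tga_offsets, as.integer),
           terminal_stop = ifelse(res$terminal_stop == "", NA_character_,
                                  res$terminal_stop),
           n_tga = lengths(res$tga_offsets),
           length_aa = nchar(res$peptide))
  }
  out <- switch(strands,
    both = bind_rows(one_strand(contig_seq, "+"),
                     one_strand(revcomp(contig_seq), "-")),
    forward = one_strand(contig_seq, "+"),
    reverse = one_strand(revcomp(contig_seq), "-"),
    abort("strands must be 'both', 'forward' or 'reverse'"))
  out <- arrange(out, .data$start, .data$end, .data$strand)
  out$orf_id <- paste0(contig, ":", out$strand, ":", out$start, "-", out$end)
  out
}

#' Enumerate read-through ORFs from transcript (EST) sequences
#'
#' Same contract as [enumerate_orfs()], on the forward strand by default
#' (assembled transcripts are usually oriented); set `both_strands = TRUE`
#' when the orientation is unknown.
#'
#' @param transcripts Named character vector of transcript sequences, or a
#'   path to a FASTA file.
#' @param params A [seleno_params()] list.
#' @param both_strands Also scan the reverse complement.
#' @param species Species label recorded in the output.
#' @return Tibble as for [enumerate_orfs()], with `contig` holding the
#'   transcript id.
#' @export
orfs_from_transcripts <- function(transcripts, params = seleno_params(),
                                  both_strands = FALSE, species = "sample") {
  if (is.character(transcripts) && length(transcripts) == 1 &&
      file.exists(transcripts)) {
    x <- Biostrings::readDNAStringSet(transcripts)
    transcripts <- setNames(as.character(x),
                            vapply(strsplit(names(x), "\\s+"), `[`, "", 1))
  }
  strands <- if (both_strands) "both" else "forward"
  bind_rows(imap(as.list(transcripts), function(s, id) {
    enumerate_orfs(s, params, contig = id, species = species,
                   strands = strands, require_atg = FALSE)
  }))
}

#' Write candidate ORF peptides to FASTA
#'
#' @param orfs Tibble from [enumerate_orfs()].
#' @param path Output FASTA path (`U` retained in peptides).
#' @return `path`, invisibly.
#' @export
write_orf_fasta <- function(orfs, path) {
  x <- Biostrings::AAStringSet(orfs$peptide)
  names(x) <- orfs$orf_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
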