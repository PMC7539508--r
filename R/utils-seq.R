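# Sequence helpers shared across modules. All coordinates in this package are
# 0-based half-open on the forward strand; GFF3 writers convert to 1-based
# closed at the boundary.

AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V")

#' Standard codon translation table
#'
#' Named character vector mapping the 64 DNA codons to one-letter amino
#' acids, with `*` for the three stop codons. Taken from the standard
#' genetic code shipped with Biostrings.
#'
#' @return Named character vector of length 64.
#' @export
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

# Fixed back-translation table (one codon per residue). Sec (U) maps to TGA.
BACK_CODON <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGC", Q = "CAA", E = "GAA",
  G = "GGT", H = "CAT", I = "ATT", L = "CTG", K = "AAA", M = "ATG", F = "TTT",
  P = "CCT", S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT", U = "TGA",
  `*` = "TAA"
)

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Back-translate a peptide to a CDS
#'
#' Uses a fixed one-codon-per-residue table; `U` (Sec) becomes TGA. The
#' returned CDS has no start or stop codon appended.
#'
#' @param peptide Amino-acid string (may contain `U`).
#' @return DNA string of length `3 * nchar(peptide)`.
#' @export
back_translate <- function(peptide) {
  aa <- strsplit(peptide, "")[[1]]
  bad <- setdiff(aa, names(BACK_CODON))
  if (length(bad) > 0) {
    abort(paste0("cannot back-translate residue(s): ", paste(bad, collapse = ", ")))
  }
  paste0(BACK_CODON[aa], collapse = "")
}

#' Translate a CDS codon-by-codon
#'
#' @param dna DNA string whose length is a multiple of 3.
#' @param readthrough_tga If TRUE, internal TGA codons translate to `U`
#'   instead of `*`.
#' @return Amino-acid string; codons containing `N` become `X`.
#' @export
translate_cds <- function(dna, readthrough_tga = TRUE) {
  n <- nchar(dna)
  if (n %% 3 != 0) abort("CDS length is not a multiple of 3")
  if (n == 0) return("")
  codons <- substring(dna, seq(1, n - 2, 3), seq(3, n, 3))
  tab <- codon_table()
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"
  if (readthrough_tga) aa[codons == "TGA"] <- "U"
  paste0(aa, collapse = "")
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_peptide <- function(n, alphabet = AA_STANDARD) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

# mutate a DNA string by iid substitutions at `rate`, sparing `protect`
# (integer vector of 1-based positions)
mutate_dna <- function(seq, rate, protect = integer(0)) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  hit <- which(runif(n) < rate)
  hit <- setdiff(hit, protect)
  if (length(hit) == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  alts <- c("A", "C", "G", "T")
  ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(alts, b), 1), "")
  paste0(ch, collapse = "")
}

# all k-mers of a character scalar
seq_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, 1:(n - k + 1), k:n)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erikson shuffle: returns a random sequence with exactly the same
#' dinucleotide (and hence mononucleotide) composition as the input, via a
#' random Eulerian walk on the dinucleotide multigraph. Used to build
#' realistic null windows for the SECIS false-positive measurement.
#'
#' @param seq DNA string.
#' @return Shuffled DNA string of identical length.
#' @export
shuffle_dinucleotide <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  if (n < 3) return(seq)
  final <- ch[n]
  out_edges <- split(ch[-1], factor(ch[-n], levels = unique(ch)))
  verts <- names(out_edges)
  repeat {
    # choose a random candidate last edge per non-terminal vertex and accept
    # only if the last edges form a tree into the terminal vertex
    le <- setNames(rep(NA_character_, length(verts)), verts)
    for (v in verts) {
      es <- out_edges[[v]]
      if (v != final && length(es) > 0) le[v] <- es[sample.int(length(es), 1)]
    }
    ok <- TRUE
    for (v in verts) {
      if (v == final || length(out_edges[[v]]) == 0) next
      w <- v; seen <- character(0)
      repeat {
        if (w == final) break
        if (w %in% seen || is.na(le[[w]])) { ok <- FALSE; break }
        seen <- c(seen, w)
        w <- le[[w]]
      }
      if (!ok) break
    }
    if (!ok) next
    lists <- list()
    for (v in verts) {
      es <- out_edges[[v]]
      if (!is.na(le[[v]])) {
        es <- es[-match(le[[v]], es)]
        lists[[v]] <- c(es[sample.int(length(es))], le[[v]])
      } else {
        lists[[v]] <- es[sample.int(length(es))]
      }
    }
    res <- character(n)
    res[1] <- ch[1]
    ptr <- setNames(rep(1L, length(verts)), verts)
    cur <- ch[1]
    for (i in 2:n) {
      nxt <- lists[[cur]][ptr[[cur]]]
      ptr[[cur]] <- ptr[[cur]] + 1L
      res[i] <- nxt
      cur <- nxt
    }
    return(paste0(res, collapse = ""))
  }
}
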