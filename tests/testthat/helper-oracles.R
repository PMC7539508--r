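# Independent brute-force oracles. Each is written directly from the
# definition of the operation it checks, not from the package's
# implementation, and is only used at small problem sizes.

# --- local alignment: plain three-matrix affine DP, score only -------------
oracle_sw_score <- function(q, r, mat, gap_open, gap_extend) {
  qs <- strsplit(q, "")[[1]]; rs <- strsplit(r, "")[[1]]
  n <- length(qs); m <- length(rs)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      M[i + 1, j + 1] <- max(0, max(M[i, j], X[i, j], Y[i, j]) +
                                  mat[qs[i], rs[j]])
      X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open, X[i, j + 1] + gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open, Y[i + 1, j] + gap_extend)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# --- read-through ORF set: direct enumeration from the definition ----------
# An ORF is any codon interval (s, e) in a frame such that: s is a segment
# start or immediately follows a TGA; e is a segment end or immediately
# precedes a TGA; no internal TAA/TAG; at most K internal TGA; length >=
# min_aa. Emitted on both strands with forward-strand coordinates.
oracle_orfs <- function(seq, K, min_aa) {
  tab <- selenoscan::codon_table()
  one <- function(s, strand, total_len) {
    out <- list()
    for (f in 0:2) {
      ncod <- (nchar(s) - f) %/% 3
      if (ncod < 1) next
      codons <- substring(s, f + seq(1, 3 * ncod, 3), f + seq(3, 3 * ncod, 3))
      codons[grepl("N", codons)] <- "NNN"
      hard <- codons %in% c("TAA", "TAG")
      tga <- codons == "TGA"
      starts <- c(1, which(hard | tga) + 1)
      ends <- c(which(hard | tga) - 1, ncod)
      for (a in starts) {
        for (b in ends) {
          if (b < a || b - a + 1 < min_aa) next
          if (any(hard[a:b])) next
          if (sum(tga[a:b]) > K) next
          # coordinates on this strand
          st <- f + 3 * (a - 1); en <- f + 3 * b
          if (strand == "+") {
            fs <- st; fe <- en
          } else {
            fs <- total_len - en; fe <- total_len - st
          }
          aa <- unname(tab[codons[a:b]])
          aa[is.na(aa)] <- "X"
          aa[tga[a:b]] <- "U"
          out[[length(out) + 1]] <- data.frame(
            strand = strand, start = fs, end = fe,
            peptide = paste0(aa, collapse = ""))
        }
      }
    }
    do.call(rbind, out)
  }
  res <- rbind(one(seq, "+", nchar(seq)),
               one(selenoscan::revcomp(seq), "-", nchar(seq)))
  if (is.null(res)) return(res)
  res <- unique(res)
  res[order(res$start, res$end, res$strand), , drop = FALSE]
}

# --- frameshift-aware protein-to-DNA alignment: plain R DP -----------------
oracle_frameshift <- function(prot, dna, mat, fs_penalty, gap_penalty) {
  tab <- selenoscan::codon_table()
  tab[names(tab) == "TGA"] <- "U"
  ps <- strsplit(prot, "")[[1]]; ds <- strsplit(dna, "")[[1]]
  n <- length(ps); m <- length(ds)
  tr <- function(j) {
    if (j < 3) return("X")
    cd <- paste0(ds[(j - 2):j], collapse = "")
    a <- unname(tab[cd])
    if (is.na(a)) "X" else a
  }
  bases <- c("A", "C", "G", "T")
  # candidate residues for a broken codon: best completion of the remaining
  # 1 or 2 nt with the missing base(s) anywhere
  broken_aa <- function(j, c) {
    if (c == 2) {
      if (j < 2) return(character(0))
      b <- ds[(j - 1):j]
      cands <- c(paste0(rep(bases, 1), b[1], b[2]),
                 paste0(b[1], bases, b[2]),
                 paste0(b[1], b[2], bases))
    } else {
      b <- ds[j]
      g <- expand.grid(bases, bases, stringsAsFactors = FALSE)
      cands <- c(paste0(b, g[[1]], g[[2]]), paste0(g[[1]], b, g[[2]]),
                 paste0(g[[1]], g[[2]], b))
    }
    a <- unname(tab[cands])
    unique(a[!is.na(a)])
  }
  H <- matrix(0, n + 1, m + 1)
  from <- matrix(0L, n + 1, m + 1)
  for (i in 1:n) {
    for (j in 1:m) {
      v <- 0; tb <- 0L
      aa <- tr(j)
      sc3 <- if (aa %in% rownames(mat)) mat[ps[i], aa] else 0
      for (c in c(3L, 1L, 2L, 4L, 5L)) {
        if (j - c < 0) next
        sc <- if (c %in% c(1L, 2L)) {
          ba <- intersect(broken_aa(j, c), rownames(mat))
          if (length(ba) == 0) 0 else max(mat[ps[i], ba])
        } else sc3
        cand <- H[i, j - c + 1] + sc - if (c != 3) fs_penalty else 0
        if (cand > v) { v <- cand; tb <- c }
      }
      cand <- H[i, j + 1] - gap_penalty
      if (cand > v) { v <- cand; tb <- 6L }
      if (j >= 3) {
        cand <- H[i + 1, j - 2] - gap_penalty
        if (cand > v) { v <- cand; tb <- 7L }
      }
      H[i + 1, j + 1] <- v; from[i + 1, j + 1] <- tb
    }
  }
  best <- which(H == max(H), arr.ind = TRUE)[1, ]
  events <- data.frame(pos_nt = integer(0), kind = character(0),
                       length = integer(0))
  i <- best[1]; j <- best[2]
  while (i > 1 && j > 1 && H[i, j] > 0) {
    tb <- from[i, j]
    if (tb == 0) break
    if (tb %in% 1:5) {
      if (tb != 3) {
        events <- rbind(data.frame(
          pos_nt = j - tb - 1L,   # 0-based start of the shifted step
          kind = if (tb < 3) "deletion" else "insertion",
          length = abs(tb - 3L)), events)
      }
      i <- i - 1; j <- j - tb
    } else if (tb == 6) i <- i - 1 else j <- j - 3
  }
  list(score = max(H), events = events)
}

# --- cluster chaining: brute-force connected components --------------------
oracle_clusters <- function(starts, ends, max_gap) {
  n <- length(starts)
  if (n == 0) return(list())
  ord <- order(starts, ends)
  starts <- starts[ord]; ends <- ends[ord]
  # adjacency between consecutive genes only (chain definition)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      if (starts[i + 1] - ends[i] <= max_gap && comp[i + 1] != comp[i]) {
        comp[comp == comp[i + 1]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  keep <- split(ord, comp)
  keep[vapply(keep, length, 0L) >= 2]
}

# --- shared fixtures -------------------------------------------------------
test_refdb <- function() selenoscan::example_reference_db(seed = 42)
test_matrix <- function() selenoscan::seleno_scoring_matrix()

random_peptide_std <- function(n) {
  paste0(sample(selenoscan:::AA_STANDARD, n, replace = TRUE), collapse = "")
}

random_aa_with_u <- function(n, p_u = 0.08) {
  ab <- c(selenoscan:::AA_STANDARD, "U")
  w <- c(rep((1 - p_u) / 20, 20), p_u)
  paste0(sample(ab, n, replace = TRUE, prob = w), collapse = "")
}
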