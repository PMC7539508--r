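# Sec-aware homology: local alignment of candidate ORFs to reference
# families, classification of the residue standing at each reference Sec
# column, frameshift-aware pseudogene calling, and fusion detection.

#' Sec-aware local alignment
#'
#' Optimal Smith-Waterman local alignment with affine gaps under a
#' [seleno_scoring_matrix()]. Traceback is deterministic: diagonal is
#' preferred over up (gap in reference) over left (gap in query), and among
#' equal-scoring end cells the smallest coordinates win.
#'
#' @param query Peptide string (may contain `U`/`X`).
#' @param ref Reference peptide string.
#' @param matrix A [seleno_scoring_matrix()].
#' @return List of class `seleno_alignment`: `score`, `q_span` and `r_span`
#'   (0-based half-open residue intervals), `q_idx`/`r_idx` (1-based aligned
#'   column indices, `NA` marking a gap).
#' @export
align_sec_aware <- function(query, ref, matrix = seleno_scoring_matrix()) {
  if (nchar(query) == 0 || nchar(ref) == 0) abort("sequences must be non-empty")
  al <- cpp_sw_align(query, ref, paste0(rownames(matrix), collapse = ""),
                     unclass(matrix), attr(matrix, "gap_open"),
                     attr(matrix, "gap_extend"))
  structure(list(score = al$score,
                 q_span = c(al$q_start - 1L, al$q_end),
                 r_span = c(al$r_start - 1L, al$r_end),
                 q_idx = al$q_idx, r_idx = al$r_idx),
            class = "seleno_alignment")
}

#' Recompute an alignment score from its columns
#'
#' Sums matrix scores over substitution columns and affine gap costs over gap
#' runs; used to assert the aligned-columns/score consistency invariant.
#'
#' @param al A `seleno_alignment`.
#' @param query,ref The aligned sequences.
#' @param matrix The scoring matrix used.
#' @return Integer score.
#' @export
alignment_score_from_columns <- function(al, query, ref,
                                         matrix = seleno_scoring_matrix()) {
  qs <- strsplit(query, "")[[1]]
  rs <- strsplit(ref, "")[[1]]
  go <- attr(matrix, "gap_open"); ge <- attr(matrix, "gap_extend")
  total <- 0L
  in_gap <- FALSE
  for (k in seq_along(al$q_idx)) {
    qi <- al$q_idx[k]; ri <- al$r_idx[k]
    if (!is.na(qi) && !is.na(ri)) {
      total <- total + matrix[qs[qi], rs[ri]]
      in_gap <- FALSE
    } else {
      total <- total + if (in_gap) ge else go
      in_gap <- TRUE
    }
  }
  as.integer(total)
}

#' Classify the residue at each reference Sec column
#'
#' For every annotated Sec position of the reference, reports the aligned
#' query residue and its class: `Sec` (U), `Cys` (C), `Other`, or `Unaligned`
#' (gap or outside the aligned span). Sites whose +/-`sec_window` reference
#' columns fall below `min_window_positive_frac` positively scoring aligned
#' columns are demoted to `Unaligned` - the local Sec-flank region must be
#' conserved for a site call to stand.
#'
#' @param al A `seleno_alignment` of `query` against `ref_residues`.
#' @param query Query peptide.
#' @param ref_residues Reference peptide.
#' @param sec_positions Integer vector of 0-based Sec indices in the
#'   reference.
#' @param matrix Scoring matrix (positive = `matrix > 0`).
#' @param params A [seleno_params()] list.
#' @return Tibble: `ref_sec_index`, `query_residue` (letter, `-` for gap, or
#'   `NA`), `site_class`, `window_positive_frac`.
#' @export
classify_sec_sites <- function(al, query, ref_residues, sec_positions,
                               matrix = seleno_scoring_matrix(),
                               params = seleno_params()) {
  qs <- strsplit(query, "")[[1]]
  rs <- strsplit(ref_residues, "")[[1]]
  w <- params$sec_window
  # per reference position (1-based): aligned query residue or "-" or NA
  qres <- rep(NA_character_, length(rs))
  pos_score <- rep(FALSE, length(rs))
  for (k in seq_along(al$r_idx)) {
    ri <- al$r_idx[k]; qi <- al$q_idx[k]
    if (!is.na(ri)) {
      if (!is.na(qi)) {
        qres[ri] <- qs[qi]
        pos_score[ri] <- matrix[qs[qi], rs[ri]] > 0
      } else {
        qres[ri] <- "-"
      }
    }
  }
  if (length(sec_positions) == 0) {
    return(tibble(ref_sec_index = integer(0), query_residue = character(0),
                  site_class = character(0),
                  window_positive_frac = numeric(0)))
  }
  rows <- lapply(sec_positions, function(p0) {
    p <- p0 + 1L
    win <- max(1L, p - w):min(length(rs), p + w)
    frac <- sum(pos_score[win]) / length(win)
    res <- qres[p]
    cls <- if (is.na(res) || res == "-") "Unaligned"
           else if (res == "U") "Sec"
           else if (res == "C") "Cys"
           else "Other"
    if (cls != "Unaligned" && frac < params$min_window_positive_frac) {
      cls <- "Unaligned"
    }
    tibble(ref_sec_index = as.integer(p0), query_residue = res,
           site_class = cls, window_positive_frac = frac)
  })
  bind_rows(rows)
}

#' Best family hit for a candidate ORF peptide
#'
#' Aligns the peptide against every member of every reference family and
#' returns the highest-scoring hit at or above `params$min_hit_score`. Ties
#' are broken by (family name, reference id) lexicographically.
#'
#' @param peptide Query peptide.
#' @param db A `seleno_refdb` tibble.
#' @param matrix Scoring matrix.
#' @param params A [seleno_params()] list.
#' @return List (`alignment`, `family`, `ref_id`, `score`) or `NULL` when no
#'   hit reaches the threshold.
#' @export
best_family_hit <- function(peptide, db, matrix = seleno_scoring_matrix(),
                            params = seleno_params()) {
  ord <- order(db$family, db$id)
  best <- NULL
  for (i in ord) {
    al <- align_sec_aware(peptide, db$residues[i], matrix)
    if (al$score >= params$min_hit_score &&
        (is.null(best) || al$score > best$score)) {
      best <- list(alignment = al, family = db$family[i], ref_id = db$id[i],
                   score = al$score)
    }
  }
  best
}

# best hit per family (for fusion detection); returns tibble
per_family_hits <- function(peptide, db, matrix, params) {
  fams <- sort(unique(db$family))
  rows <- list()
  for (f in fams) {
    sub <- db[db$family == f, ]
    sub <- sub[order(sub$id), ]
    best <- NULL
    for (i in seq_len(nrow(sub))) {
      al <- align_sec_aware(peptide, sub$residues[i], matrix)
      if (al$score >= params$min_hit_score &&
          (is.null(best) || al$score > best$al$score)) {
        best <- list(al = al, id = sub$id[i])
      }
    }
    if (!is.null(best)) {
      rows[[length(rows) + 1]] <- tibble(
        family = f, ref_id = best$id, score = best$al$score,
        q_start = best$al$q_span[1], q_end = best$al$q_span[2],
        alignment = list(best$al))
    }
  }
  bind_rows(rows)
}

#' Detect frameshift events between a reference protein and genomic DNA
#'
#' Local protein-to-DNA alignment with explicit 1- and 2-nt frameshift moves
#' (fixed penalty per event). Each point where the reading frame changes is
#' reported.
#'
#' @param ref_residues Reference peptide.
#' @param locus_dna DNA string of the locus (strand-resolved).
#' @param matrix Scoring matrix.
#' @param params A [seleno_params()] list (`frameshift_penalty`,
#'   `fs_gap_penalty`).
#' @return Tibble: `pos_nt` (0-based nt offset in `locus_dna` of the codon
#'   step containing the event), `kind` (`insertion`/`deletion` relative to
#'   an intact reading frame), `length` (1 or 2), with the alignment score
#'   and spans as attributes `score`, `dna_span`, `prot_span`.
#' @export
detect_frameshifts <- function(ref_residues, locus_dna,
                               matrix = seleno_scoring_matrix(),
                               params = seleno_params()) {
  tab <- codon_table()
  # readthrough: score genomic TGA codons as U so Sec genes do not fragment
  tab[names(tab) == "TGA"] <- "U"
  res <- cpp_frameshift_align(ref_residues, toupper(locus_dna),
                              paste0(rownames(matrix), collapse = ""),
                              unclass(matrix), names(tab), unname(tab),
                              params$frameshift_penalty, params$fs_gap_penalty)
  ev <- tibble(pos_nt = as.integer(res$event_pos) - 1L,
               kind = as.character(res$event_kind),
               length = as.integer(res$event_len))
  attr(ev, "score") <- res$score
  attr(ev, "dna_span") <- c(res$dna_start - 1L, res$dna_end)
  attr(ev, "prot_span") <- c(res$prot_start - 1L, res$prot_end)
  if (nrow(ev) == 1) {
    ev$pos_nt <- refine_event_position(ev, ref_residues, toupper(locus_dna),
                                       tab)
  }
  ev
}

# In repetitive sequence several indel placements are co-optimal under the
# alignment score. Normalize a single event by full reconstruction: repair
# the sequence at each candidate position (deletions try every fill base),
# re-translate in frame, and keep the position whose repaired protein agrees
# best with the reference. Ties resolve to the DP's own placement.
refine_event_position <- function(ev, ref_residues, dna, tab) {
  p <- ev$pos_nt[1]
  L <- ev$length[1]
  d1 <- attr(ev, "dna_span")[1]
  p1 <- attr(ev, "prot_span")[1]
  prot <- strsplit(ref_residues, "")[[1]]
  n <- nchar(dna)
  bases <- c("A", "C", "G", "T")
  fills <- if (ev$kind[1] == "deletion") {
    if (L == 1) bases else as.vector(outer(bases, bases, paste0))
  } else ""
  score_q <- function(q) {
    best <- -1L
    for (b in fills) {
      rep <- if (ev$kind[1] == "deletion") {
        paste0(substr(dna, 1, q), b, substr(dna, q + 1, n))
      } else {
        paste0(substr(dna, 1, q), substr(dna, q + L + 1, n))
      }
      k <- min(length(prot) - p1, (nchar(rep) - d1) %/% 3)
      if (k <= 0) return(0L)
      pep <- translate_cds(substr(rep, d1 + 1, d1 + 3L * k))
      s <- sum(strsplit(pep, "")[[1]] == prot[(p1 + 1):(p1 + k)])
      if (s > best) best <- s
    }
    best
  }
  cand <- seq(max(d1, p - 9L), min(attr(ev, "dna_span")[2] - 1L, p + 9L))
  sc <- vapply(cand, score_q, 0L)
  best <- cand[sc == max(sc)]
  as.integer(best[order(abs(best - p), best)][1])
}

# DNA scoring matrix for EST-to-genome checks
dna_scoring_matrix <- function() {
  ab <- c("A", "C", "G", "T", "N")
  m <- matrix(-3L, 5, 5, dimnames = list(ab, ab))
  diag(m) <- 2L
  m["N", ] <- 0L; m[, "N"] <- 0L
  structure(m, gap_open = -5L, gap_extend = -2L,
            class = c("seleno_scoring_matrix", class(m)))
}

# does any EST align across locus_dna position `pos` (0-based) at
# >= est_min_identity_frac with >= margin nt on each side?
est_supports_position <- function(locus_dna, pos, ests, params,
                                  margin = 10L, window = 40L) {
  if (length(ests) == 0) return(FALSE)
  n <- nchar(locus_dna)
  ws <- max(0L, pos - window)
  we <- min(n, pos + window)
  target <- substr(locus_dna, ws + 1, we)
  center <- pos - ws            # 0-based position of the event in target
  dm <- dna_scoring_matrix()
  for (est in ests) {
    for (s in c(est, revcomp(est))) {
      # cheap prefilter: require a shared 16-mer
      if (!any(cpp_kmer_filter(s, seq_kmers(target, 16L), 16L))) next
      al <- align_sec_aware(s, target, dm)
      if (al$score <= 0) next
      cols <- !is.na(al$q_idx) & !is.na(al$r_idx)
      if (sum(cols) == 0) next
      qs <- strsplit(s, "")[[1]]; rs <- strsplit(target, "")[[1]]
      ident <- sum(qs[al$q_idx[cols]] == rs[al$r_idx[cols]]) / length(al$q_idx)
      spans <- al$r_span[1] <= center - margin && al$r_span[2] >= center + margin
      # the EST must carry the same indel: a gap column inside the bridging
      # region means it does not match the genomic frameshift
      bridged <- TRUE
      for (kk in seq_along(al$r_idx)) {
        ri <- al$r_idx[kk]
        near <- (!is.na(ri) && abs(ri - 1L - center) <= margin) ||
          (is.na(ri) && kk > 1 && kk < length(al$r_idx) &&
             !is.na(al$r_idx[kk - 1]) &&
             abs(al$r_idx[kk - 1] - 1L - center) <= margin)
        if (near && (is.na(al$q_idx[kk]) || is.na(ri))) bridged <- FALSE
      }
      if (ident >= params$est_min_identity_frac && spans && bridged) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Pseudogene call from frameshift events and EST evidence
#'
#' A locus is a pseudogene when it carries at least one frameshift event that
#' no EST alignment supports: an event is EST-supported when a transcript
#' aligns across it at `est_min_identity_frac` or better carrying the same
#' indel, in which case the frameshift is genuinely transcribed and the gene
#' is not pseudogenised.
#'
#' @param events Tibble from [detect_frameshifts()].
#' @param locus_dna The locus DNA the events refer to.
#' @param ests Character vector of EST sequences (may be empty).
#' @param params A [seleno_params()] list.
#' @return List: `pseudogene` flag and the `events` tibble gaining an
#'   `est_supported` column.
#' @export
call_pseudogene <- function(events, locus_dna, ests = character(0),
                            params = seleno_params()) {
  if (nrow(events) == 0) {
    events$est_supported <- logical(0)
    return(list(pseudogene = FALSE, events = events))
  }
  events$est_supported <- vapply(events$pos_nt, function(p) {
    est_supports_position(locus_dna, p, ests, params)
  }, logical(1))
  list(pseudogene = any(!events$est_supported), events = events)
}

#' Detect fusion genes: two families on one ORF
#'
#' Two non-overlapping hits from different families on the same ORF, each at
#' or above `min_hit_score`, constitute a fusion call (query order defines
#' `family_a`/`family_b`).
#'
#' @param fam_hits Tibble from the per-family alignment stage (`family`,
#'   `score`, `q_start`, `q_end`).
#' @param orf_id Identifier recorded in the output.
#' @param params A [seleno_params()] list.
#' @return Tibble: `orf_id`, `family_a`, `family_b`, spans, `gap_between`.
#' @export
detect_fusions <- function(fam_hits, orf_id = "orf", params = seleno_params()) {
  empty <- tibble(orf_id = character(0), family_a = character(0),
                  family_b = character(0), a_start = integer(0),
                  a_end = integer(0), b_start = integer(0), b_end = integer(0),
                  gap_between = integer(0))
  fam_hits <- fam_hits[fam_hits$score >= params$min_hit_score, ]
  if (nrow(fam_hits) < 2) return(empty)
  out <- list()
  for (i in seq_len(nrow(fam_hits) - 1)) {
    for (j in (i + 1):nrow(fam_hits)) {
      a <- fam_hits[i, ]; b <- fam_hits[j, ]
      if (a$family == b$family) next
      if (a$q_start > b$q_start) { tmp <- a; a <- b; b <- tmp }
      if (a$q_end > b$q_start) next       # overlapping spans
      out[[length(out) + 1]] <- tibble(
        orf_id = orf_id, family_a = a$family, family_b = b$family,
        a_start = as.integer(a$q_start), a_end = as.integer(a$q_end),
        b_start = as.integer(b$q_start), b_end = as.integer(b$q_end),
        gap_between = as.integer(b$q_start - a$q_end))
    }
  }
  if (length(out) == 0) return(empty)
  bind_rows(out)
}
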