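# SECIS element detection. Eukaryotic SECIS elements are modelled with an
# explicit stem-loop grammar (5'->3'): a lower helix (helix 1), the core
# quartet 5' AUGA (DNA ATGA), an upper helix (helix 2) of 9-15 pairs with at
# most 2 mismatches (G.U wobble pairs count as paired), an apical loop of
# 3-18 nt containing an unpaired AA, the 3' core GA, and the 3' arm of
# helix 1. Scoring: one point per helix-2 pair, minus a per-mismatch penalty,
# plus a bonus for the apical AA.

#' SECIS grammar
#'
#' @param core5,core3 Core quartet sequences on the DNA strand.
#' @param helix2_pairs_min,helix2_pairs_max Length range of helix 2.
#' @param helix2_max_mismatch Maximum non-pairing positions in helix 2.
#' @param apical_min,apical_max Apical loop length range (nt).
#' @param apical_required Subsequence that must occur in the apical loop; for
#'   type-II elements pass `"CC"`.
#' @param helix1_pairs_min Pairing positions required in helix 1 (checked on
#'   the `helix1_pairs_min` nt flanking the core).
#' @param max_distance_from_stop Maximum distance of the element start from
#'   the stop codon (nt).
#' @param mismatch_penalty,apical_bonus Score terms.
#' @return List of class `secis_grammar`.
#' @export
secis_grammar <- function(core5 = "ATGA", core3 = "GA", helix2_pairs_min = 9L,
                          helix2_pairs_max = 15L, helix2_max_mismatch = 2L,
                          apical_min = 3L, apical_max = 18L,
                          apical_required = "AA", helix1_pairs_min = 4L,
                          max_distance_from_stop = 3000L,
                          mismatch_penalty = 2L, apical_bonus = 2L) {
  g <- list(core5 = core5, core3 = core3,
            helix2_pairs_min = as.integer(helix2_pairs_min),
            helix2_pairs_max = as.integer(helix2_pairs_max),
            helix2_max_mismatch = as.integer(helix2_max_mismatch),
            apical_min = as.integer(apical_min),
            apical_max = as.integer(apical_max),
            apical_required = apical_required,
            helix1_pairs_min = as.integer(helix1_pairs_min),
            max_distance_from_stop = as.integer(max_distance_from_stop),
            mismatch_penalty = as.integer(mismatch_penalty),
            apical_bonus = as.integer(apical_bonus))
  if (g$helix2_pairs_min > g$helix2_pairs_max) abort("helix2 range inverted")
  if (g$apical_min > g$apical_max) abort("apical range inverted")
  structure(g, class = "secis_grammar")
}

# Watson-Crick + G.U wobble pairing on the DNA alphabet
.pairs_with <- function(x, y) {
  (x == "A" & y == "T") | (x == "T" & y == "A") |
    (x == "G" & y == "C") | (x == "C" & y == "G") |
    (x == "G" & y == "T") | (x == "T" & y == "G")
}

secis_empty <- function() {
  tibble(start = integer(0), end = integer(0), core5_start = integer(0),
         apical_start = integer(0), apical_end = integer(0),
         core3_end = integer(0), helix2_pairs = integer(0),
         mismatches = integer(0), score = numeric(0))
}

#' Detect SECIS elements in a 3'-UTR region
#'
#' Scans a strand-resolved DNA region (the sequence downstream of a stop
#' codon) for every coordinate tuple satisfying the grammar, scores each, and
#' reduces overlapping hits to local maxima.
#'
#' @param region DNA string, already strand-resolved (5'->3' of the mRNA).
#' @param grammar A [secis_grammar()].
#' @return Tibble with one row per element: `start`/`end` (whole element,
#'   0-based half-open region offsets), `core5_start`, `apical_start`,
#'   `apical_end`, `core3_end` (region offsets), `helix2_pairs`,
#'   `mismatches`, `score`; ordered by position then score. A region shorter
#'   than the minimal element span yields zero rows.
#' @export
detect_secis <- function(region, grammar = secis_grammar()) {
  g <- grammar
  region <- toupper(region)
  n <- nchar(region)
  h1 <- g$helix1_pairs_min
  min_span <- h1 + nchar(g$core5) + 2 * g$helix2_pairs_min + g$apical_min +
    nchar(g$core3) + h1
  if (n < min_span) return(secis_empty())
  ch <- strsplit(region, "")[[1]]
  c5 <- nchar(g$core5)
  # all occurrences, including self-overlapping ones (ATGATGA hides a core)
  locs <- which(substring(region, 1:(n - c5 + 1), c5:n) == g$core5)
  c3 <- nchar(g$core3)
  out <- list()
  for (i in locs) {                      # 1-based position of core5
    if (i - h1 < 1) next
    before <- ch[(i - h1):(i - 1)]
    for (h in g$helix2_pairs_min:g$helix2_pairs_max) {
      if (i + c5 + h - 1 > n) break
      arm5 <- ch[(i + c5):(i + c5 + h - 1)]
      for (a in g$apical_min:g$apical_max) {
        p_ap <- i + c5 + h                # 1-based apical start
        p_arm3 <- p_ap + a
        p_c3 <- p_arm3 + h
        p_after <- p_c3 + c3
        if (p_after + h1 - 1 > n) next
        if (paste0(ch[p_c3:(p_c3 + c3 - 1)], collapse = "") != g$core3) next
        apical <- ch[p_ap:(p_ap + a - 1)]
        if (!grepl(g$apical_required, paste0(apical, collapse = ""),
                   fixed = TRUE)) next
        arm3 <- ch[p_arm3:(p_arm3 + h - 1)]
        mm <- sum(!.pairs_with(arm5, rev(arm3)))
        if (mm > g$helix2_max_mismatch) next
        after <- ch[p_after:(p_after + h1 - 1)]
        if (sum(.pairs_with(before, rev(after))) < h1) next
        out[[length(out) + 1]] <- c(
          start = i - h1 - 1L, end = p_after + h1 - 1L,
          core5_start = i - 1L, apical_start = p_ap - 1L,
          apical_end = p_ap + a - 1L, core3_end = p_c3 + c3 - 1L,
          helix2_pairs = h - mm, mismatches = mm,
          score = (h - mm) - g$mismatch_penalty * mm + g$apical_bonus)
      }
    }
  }
  if (length(out) == 0) return(secis_empty())
  hits <- as_tibble(do.call(rbind, out))
  # overlapping parses of one core quartet reduce to the local maximum;
  # distinct cores are distinct candidate elements and are all reported
  hits <- hits |>
    arrange(desc(.data$score), .data$start, .data$apical_start) |>
    group_by(.data$core5_start) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$start, desc(.data$score))
  hits |>
    mutate(across(c("start", "end", "core5_start", "apical_start",
                    "apical_end", "core3_end", "helix2_pairs", "mismatches"),
                  as.integer))
}

#' Search SECIS elements downstream of a candidate ORF
#'
#' Extracts the strand-correct window downstream of the ORF's terminal stop
#' codon (reverse-complemented for `-` strand loci), delegates to
#' [detect_secis()], and maps results back to forward-strand contig
#' coordinates.
#'
#' @param contig_seq Forward-strand contig DNA string.
#' @param orf_start,orf_end 0-based half-open forward-strand coordinates of
#'   the ORF (excluding the terminal stop).
#' @param strand `"+"` or `"-"`.
#' @param grammar A [secis_grammar()].
#' @param window_nt Search window length downstream of the stop.
#' @return Tibble: `start`/`end` (forward-strand span of the whole element),
#'   `strand`, `distance_from_stop`, element-local offsets `core5_off`,
#'   `apical_off`, `apical_len`, plus `helix2_pairs`, `mismatches`, `score`.
#' @export
attach_secis <- function(contig_seq, orf_start, orf_end, strand = "+",
                         grammar = secis_grammar(), window_nt = 3000L) {
  n <- nchar(contig_seq)
  if (strand == "+") {
    wstart <- min(orf_end + 3L, n)         # skip the stop codon
    wend <- min(wstart + window_nt, n)
    if (wend <= wstart) return(attach_secis_empty())
    region <- substr(contig_seq, wstart + 1, wend)
  } else {
    wend <- max(orf_start - 3L, 0L)
    wstart <- max(wend - window_nt, 0L)
    if (wend <= wstart) return(attach_secis_empty())
    region <- revcomp(substr(contig_seq, wstart + 1, wend))
  }
  els <- detect_secis(region, grammar)
  els <- filter(els, .data$start <= grammar$max_distance_from_stop)
  if (nrow(els) == 0) return(attach_secis_empty())
  wlen <- nchar(region)
  if (strand == "+") {
    fstart <- wstart + els$start
    fend <- wstart + els$end
  } else {
    fstart <- wstart + (wlen - els$end)
    fend <- wstart + (wlen - els$start)
  }
  tibble(start = as.integer(fstart), end = as.integer(fend), strand = strand,
         distance_from_stop = els$start,
         core5_off = els$core5_start - els$start,
         apical_off = els$apical_start - els$start,
         apical_len = els$apical_end - els$apical_start,
         helix2_pairs = els$helix2_pairs, mismatches = els$mismatches,
         score = els$score)
}

attach_secis_empty <- function() {
  tibble(start = integer(0), end = integer(0), strand = character(0),
         distance_from_stop = integer(0), core5_off = integer(0),
         apical_off = integer(0), apical_len = integer(0),
         helix2_pairs = integer(0), mismatches = integer(0),
         score = numeric(0))
}

#' Emit a canonical SECIS element from the grammar
#'
#' Constructs a random element that satisfies [detect_secis()]'s grammar by
#' construction: complementary helices, the core quartet, and an apical loop
#' containing the required subsequence. Used by the synthetic-data generator
#' and by round-trip tests.
#'
#' @param grammar A [secis_grammar()].
#' @return List: `seq` (DNA string), `core5_off`, `apical_off`, `apical_len`,
#'   `helix2_len` (0-based offsets within `seq`).
#' @export
plant_secis <- function(grammar = secis_grammar()) {
  g <- grammar
  h1len <- g$helix1_pairs_min + 2L
  for (try in 1:100) {
    arm1 <- random_dna(h1len)
    h <- sample(g$helix2_pairs_min:g$helix2_pairs_max, 1)
    arm2 <- random_dna(h)
    a <- sample(max(g$apical_min, nchar(g$apical_required)):g$apical_max, 1)
    apical <- strsplit(random_dna(a), "")[[1]]
    pos <- sample(seq_len(a - nchar(g$apical_required) + 1), 1)
    req <- strsplit(g$apical_required, "")[[1]]
    apical[pos:(pos + length(req) - 1)] <- req
    apical <- paste0(apical, collapse = "")
    s <- paste0(arm1, g$core5, arm2, apical, revcomp(arm2), g$core3,
                revcomp(arm1))
    # canonical elements carry exactly one core quartet; rebuild on the rare
    # draw where an arm or the loop spells out a second one
    if (length(str_locate_all(s, stringr::fixed(g$core5))[[1]][, 1]) == 1) {
      return(list(seq = s, core5_off = h1len,
                  apical_off = h1len + nchar(g$core5) + h,
                  apical_len = a, helix2_len = h))
    }
  }
  abort("could not build a single-core element from this grammar")
}

#' Independent grammar re-validation of a detected element
#'
#' Pair-by-pair complementarity check used as the soundness oracle in tests;
#' written directly from the grammar definition, not from the scanner.
#'
#' @param region The region that was scanned.
#' @param el One row of the [detect_secis()] result.
#' @param grammar A [secis_grammar()].
#' @return TRUE if the element satisfies the grammar.
#' @export
secis_revalidate <- function(region, el, grammar = secis_grammar()) {
  g <- grammar
  ch <- strsplit(toupper(region), "")[[1]]
  c5 <- nchar(g$core5); c3 <- nchar(g$core3)
  i <- el$core5_start + 1L
  if (paste0(ch[i:(i + c5 - 1)], collapse = "") != g$core5) return(FALSE)
  h <- (el$apical_start - (el$core5_start + c5))
  if (h < g$helix2_pairs_min || h > g$helix2_pairs_max) return(FALSE)
  a <- el$apical_end - el$apical_start
  if (a < g$apical_min || a > g$apical_max) return(FALSE)
  apical <- paste0(ch[(el$apical_start + 1):el$apical_end], collapse = "")
  if (!grepl(g$apical_required, apical, fixed = TRUE)) return(FALSE)
  arm5 <- ch[(el$core5_start + c5 + 1):el$apical_start]
  arm3 <- ch[(el$apical_end + 1):(el$apical_end + h)]
  if (sum(!.pairs_with(arm5, rev(arm3))) > g$helix2_max_mismatch) return(FALSE)
  if (paste0(ch[(el$apical_end + h + 1):(el$apical_end + h + c3)],
             collapse = "") != g$core3) return(FALSE)
  h1 <- g$helix1_pairs_min
  before <- ch[(el$core5_start - h1 + 1):el$core5_start]
  after <- ch[(el$core3_end + 1):(el$core3_end + h1)]
  sum(.pairs_with(before, rev(after))) >= h1
}
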