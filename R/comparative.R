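# Cross-genome analytics on assembled calls: tandem gene clusters,
# flanking-duplication detection under the published 50%/80%/20% thresholds,
# the species x family presence matrix, and its double clustering.

#' Detect tandem gene clusters
#'
#' Maximal chains of calls (any class) on one contig whose consecutive
#' inter-gene gaps are at most `cluster_max_gap_nt`.
#'
#' @param calls Calls tibble (needs `species`, `contig`, `start`, `end`,
#'   `family`, `overall_class`, `call_id`).
#' @param params A [seleno_params()] list.
#' @return Tibble: `cluster_id`, `species`, `contig`, `start`, `end`,
#'   `n_members`, `members` (list of call ids), `families` (label such as
#'   `"GPX(U),PDI_a(C)"`), ordered by coordinate.
#' @export
detect_clusters <- function(calls, params = seleno_params()) {
  empty <- tibble(cluster_id = character(0), species = character(0),
                  contig = character(0), start = integer(0), end = integer(0),
                  n_members = integer(0), members = list(),
                  families = character(0))
  if (nrow(calls) == 0) return(empty)
  out <- list()
  cl_no <- 0L
  for (key in split(seq_len(nrow(calls)),
                    paste(calls$species, calls$contig, sep = "\r"))) {
    sub <- calls[key, ]
    sub <- arrange(sub, .data$start, .data$end)
    run <- 1L
    flush <- function(idx) {
      if (length(idx) < 2) return(invisible(NULL))
      cl_no <<- cl_no + 1L
      letter <- c(Sec = "U", Cys = "C", Other = "O")
      out[[length(out) + 1]] <<- tibble(
        cluster_id = sprintf("cluster%03d", cl_no),
        species = sub$species[idx[1]], contig = sub$contig[idx[1]],
        start = min(sub$start[idx]), end = max(sub$end[idx]),
        n_members = length(idx), members = list(sub$call_id[idx]),
        families = paste0(sub$family[idx], "(",
                          letter[sub$overall_class[idx]], ")",
                          collapse = ","))
      invisible(NULL)
    }
    chain <- 1L
    if (nrow(sub) > 1) {
      for (i in 2:nrow(sub)) {
        gap <- sub$start[i] - sub$end[i - 1]
        if (gap <= params$cluster_max_gap_nt) {
          chain <- c(chain, i)
        } else {
          flush(chain)
          chain <- i
        }
      }
    }
    flush(chain)
  }
  if (length(out) == 0) return(empty)
  arrange(bind_rows(out), .data$species, .data$contig, .data$start)
}

# positively scoring aligned columns / aligned columns (incl gaps) of the
# optimal local alignment of two peptides
protein_positive_frac <- function(pep_a, pep_b, matrix) {
  al <- align_sec_aware(pep_a, pep_b, matrix)
  ncol <- length(al$q_idx)
  if (ncol == 0) return(0)
  qs <- strsplit(pep_a, "")[[1]]; rs <- strsplit(pep_b, "")[[1]]
  pos <- 0L
  for (k in seq_len(ncol)) {
    qi <- al$q_idx[k]; ri <- al$r_idx[k]
    if (!is.na(qi) && !is.na(ri) && matrix[qs[qi], rs[ri]] > 0) pos <- pos + 1L
  }
  pos / ncol
}

# high-identity block finding between two DNA segments: exact-match anchors
# on shared diagonals extended/merged while block identity stays above the
# threshold; returns total nt of segment A covered by accepted blocks
identity_block_coverage <- function(seg_a, seg_b, identity_min = 0.8,
                                    anchor_len = 20L, min_anchors = 2L,
                                    mask_a = integer(0)) {
  best <- 0L
  for (b in c(seg_b, revcomp(seg_b))) {
    covered <- logical(nchar(seg_a))
    ka <- seq_kmers(seg_a, anchor_len)
    kb <- seq_kmers(b, anchor_len)
    if (length(ka) == 0 || length(kb) == 0) next
    hit <- match(kb, ka)
    ib <- which(!is.na(hit))
    if (length(ib) == 0) next
    diags <- hit[ib] - ib            # a_pos - b_pos
    tab <- sort(table(diags), decreasing = TRUE)
    cand <- as.integer(names(tab)[tab >= min_anchors])
    cha <- strsplit(seg_a, "")[[1]]
    chb <- strsplit(b, "")[[1]]
    for (d in cand) {
      a_lo <- max(1L, 1L + d); a_hi <- min(nchar(seg_a), nchar(b) + d)
      if (a_hi - a_lo + 1 < anchor_len) next
      eq <- cha[a_lo:a_hi] == chb[(a_lo - d):(a_hi - d)]
      r <- rle(eq)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      runs <- which(r$values & r$lengths >= anchor_len)
      if (length(runs) == 0) next
      # greedy merge of consecutive exact runs while identity >= threshold
      bs <- starts[runs[1]]; be <- ends[runs[1]]; nmatch <- r$lengths[runs[1]]
      blocks <- list()
      if (length(runs) > 1) {
        for (q in runs[-1]) {
          cand_match <- nmatch + r$lengths[q]
          cand_len <- ends[q] - bs + 1L
          if (cand_match / cand_len >= identity_min) {
            be <- ends[q]; nmatch <- cand_match
          } else {
            blocks[[length(blocks) + 1]] <- c(bs, be)
            bs <- starts[q]; be <- ends[q]; nmatch <- r$lengths[q]
          }
        }
      }
      blocks[[length(blocks) + 1]] <- c(bs, be)
      for (bl in blocks) {
        covered[(a_lo + bl[1] - 1L):(a_lo + bl[2] - 1L)] <- TRUE
      }
    }
    if (length(mask_a) > 0) covered[mask_a] <- FALSE
    best <- max(best, sum(covered))
  }
  best
}

#' Detect gene+flank duplication events
#'
#' Same-species, same-family call pairs are screened in two stages following
#' the published rule: (1) the protein-level positive rate of the optimal
#' local alignment must exceed `duplication_positive_frac` (50%); (2) the
#' gene+flank genomic segments (`duplication_flank_nt` on each side) must
#' share identity blocks (>= `duplication_identity_frac`) covering at least
#' `duplication_coverage_frac` of the compared segment.
#'
#' @param calls Calls tibble (needs `species`, `contig`, `start`, `end`,
#'   `family`, `peptide`, `call_id`).
#' @param genomes List: species -> named character vector of contigs.
#' @param matrix A [seleno_scoring_matrix()].
#' @param params A [seleno_params()] list.
#' @return Tibble: `species`, `family`, `call_a`, `call_b`,
#'   `protein_positive_frac`, `flank_coverage_frac`, `segment_nt`.
#' @export
detect_duplications <- function(calls, genomes,
                                matrix = seleno_scoring_matrix(),
                                params = seleno_params()) {
  empty <- tibble(species = character(0), family = character(0),
                  call_a = character(0), call_b = character(0),
                  protein_positive_frac = numeric(0),
                  flank_coverage_frac = numeric(0), segment_nt = integer(0))
  if (nrow(calls) == 0) return(empty)
  out <- list()
  groups <- split(seq_len(nrow(calls)),
                  paste(calls$species, calls$family, sep = "\r"))
  for (idx in groups) {
    if (length(idx) < 2) next
    sub <- calls[idx, ]
    sub <- arrange(sub, .data$call_id)
    for (i in seq_len(nrow(sub) - 1)) {
      for (j in (i + 1):nrow(sub)) {
        ppf <- protein_positive_frac(sub$peptide[i], sub$peptide[j], matrix)
        if (ppf <= params$duplication_positive_frac) next
        seg <- function(k) {
          ctg <- genomes[[sub$species[k]]][[sub$contig[k]]]
          lo <- max(0L, sub$start[k] - params$duplication_flank_nt)
          hi <- min(nchar(ctg), sub$end[k] + params$duplication_flank_nt)
          list(seq = substr(ctg, lo + 1, hi), lo = lo, hi = hi)
        }
        sa <- seg(i); sb <- seg(j)
        seg_a <- sa$seq; seg_b <- sb$seq
        # nearby genes share genomic sequence where their flank windows
        # overlap; that self-identity is not duplication evidence
        mask <- integer(0)
        if (sub$contig[i] == sub$contig[j]) {
          olo <- max(sa$lo, sb$lo); ohi <- min(sa$hi, sb$hi)
          if (ohi > olo) mask <- (olo - sa$lo + 1L):(ohi - sa$lo)
        }
        cov_nt <- identity_block_coverage(
          seg_a, seg_b, identity_min = params$duplication_identity_frac,
          mask_a = mask)
        cov <- cov_nt / nchar(seg_a)
        if (cov >= params$duplication_coverage_frac) {
          out[[length(out) + 1]] <- tibble(
            species = sub$species[i], family = sub$family[i],
            call_a = sub$call_id[i], call_b = sub$call_id[j],
            protein_positive_frac = ppf, flank_coverage_frac = cov,
            segment_nt = nchar(seg_a))
        }
      }
    }
  }
  if (length(out) == 0) return(empty)
  arrange(bind_rows(out), .data$species, .data$family, .data$call_a)
}

PRESENCE_CLASSES <- c("absent", "Sec", "Cys", "Other", "Sec&Cys", "Sec&Other",
                      "Cys&Other", "Sec&Cys&Other")

#' Build the species x family presence matrix
#'
#' Each cell is the set-union of the overall classes of the calls for that
#' (family, species): `absent`, `Sec`, `Cys`, `Other`, or a `&`-joined
#' combination (ordered Sec, Cys, Other). Pseudogene-flagged calls are not
#' functional family members and never fill a cell.
#'
#' @param calls Calls tibble (needs `species`, `family`, `overall_class`).
#' @param species,families Optional fixed row/column universes (defaults to
#'   the values observed in `calls`).
#' @return Object of class `seleno_matrix`: list with `cells` (tibble
#'   `species`, `family`, `presence`), `species`, `families`, and
#'   `species_totals` (families per class per species).
#' @export
build_presence_matrix <- function(calls, species = NULL, families = NULL) {
  species <- sort(unique(c(species, calls$species)))
  families <- sort(unique(c(families, calls$family)))
  # pseudogenes are not functional family members; they never fill a cell
  if ("pseudogene" %in% names(calls)) {
    calls <- calls[!calls$pseudogene, ]
  }
  grid <- tidyr::expand_grid(species = species, family = families)
  agg <- calls |>
    group_by(.data$species, .data$family) |>
    summarise(presence = {
      cl <- unique(.data$overall_class)
      paste(intersect(c("Sec", "Cys", "Other"), cl), collapse = "&")
    }, .groups = "drop")
  cells <- left_join(grid, agg, by = c("species", "family")) |>
    mutate(presence = ifelse(is.na(.data$presence) | .data$presence == "",
                             "absent", .data$presence))
  totals <- cells |>
    filter(.data$presence != "absent") |>
    mutate(has_sec = grepl("Sec", .data$presence)) |>
    group_by(.data$species) |>
    summarise(n_families = n(), n_sec_families = sum(.data$has_sec),
              .groups = "drop")
  structure(list(cells = cells, species = species, families = families,
                 species_totals = totals),
            class = "seleno_matrix")
}

# indicator encoding: for each family three binary columns (Sec, Cys, Other)
presence_indicators <- function(mat) {
  cells <- mat$cells
  enc <- function(cl, what) as.integer(grepl(what, cl))
  wide <- cells |>
    mutate(Sec = enc(.data$presence, "Sec"), Cys = enc(.data$presence, "Cys"),
           Other = enc(.data$presence, "Other")) |>
    select("species", "family", "Sec", "Cys", "Other") |>
    tidyr::pivot_longer(c("Sec", "Cys", "Other"), names_to = "class",
                        values_to = "present") |>
    mutate(key = paste(.data$family, .data$class, sep = ":")) |>
    select("species", "key", "present") |>
    tidyr::pivot_wider(names_from = "key", values_from = "present")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$species
  m[, sort(colnames(m)), drop = FALSE]
}

# binary Jaccard distance with the all-zero convention: two empty profiles
# are identical (0), empty vs non-empty is maximal (1)
jaccard_dist <- function(m) {
  nz <- rowSums(m) > 0
  d <- matrix(0, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
  if (sum(nz) > 1) {
    dd <- as.matrix(vegan::vegdist(m[nz, , drop = FALSE], method = "jaccard",
                                   binary = TRUE))
    d[nz, nz] <- dd
  }
  d[nz, !nz] <- 1; d[!nz, nz] <- 1
  as.dist(d)
}

#' Double clustering of the presence matrix
#'
#' Average-linkage hierarchical clustering of species and of families on
#' Jaccard distances between presence-class indicator profiles (three binary
#' indicators - Sec, Cys, Other - per family). Input rows are sorted by name
#' before clustering, so the leaf order is deterministic and invariant to
#' the order calls were supplied in.
#'
#' @param mat A `seleno_matrix` from [build_presence_matrix()].
#' @return Object of class `seleno_clustering`: `species_order`,
#'   `family_order` (leaf orders), `species_hclust`, `family_hclust`.
#' @export
cluster_matrix <- function(mat) {
  m <- presence_indicators(mat)
  m <- m[sort(rownames(m)), , drop = FALSE]
  sp_order <- rownames(m)
  if (nrow(m) > 1) {
    hc_sp <- hclust(jaccard_dist(m), method = "average")
    sp_order <- rownames(m)[hc_sp$order]
  } else hc_sp <- NULL
  # family profiles: presence indicators across species
  fam_m <- t(m)
  fam <- sub(":(Sec|Cys|Other)$", "", rownames(fam_m))
  fam_prof <- do.call(rbind, lapply(split(seq_len(nrow(fam_m)), fam),
                                    function(ix) as.vector(fam_m[ix, ,
                                                                 drop = FALSE])))
  rownames(fam_prof) <- names(split(seq_len(nrow(fam_m)), fam))
  fam_prof <- fam_prof[sort(rownames(fam_prof)), , drop = FALSE]
  fam_order <- rownames(fam_prof)
  if (nrow(fam_prof) > 1) {
    hc_fam <- hclust(jaccard_dist(fam_prof), method = "average")
    fam_order <- rownames(fam_prof)[hc_fam$order]
  } else hc_fam <- NULL
  structure(list(species_order = sp_order, family_order = fam_order,
                 species_hclust = hc_sp, family_hclust = hc_fam),
            class = "seleno_clustering")
}

#' Census of Sec-flank motifs per family and class
#'
#' Tabulates the extracted Sec-flank motif strings of the calls by family
#' and overall class.
#'
#' @param calls Calls tibble (needs `family`, `overall_class`, `motif`).
#' @return Tibble: `family`, `overall_class`, `motif`, `n`, sorted by
#'   decreasing frequency within family.
#' @export
motif_census <- function(calls) {
  if (nrow(calls) == 0) {
    return(tibble(family = character(0), overall_class = character(0),
                  motif = character(0), n = integer(0)))
  }
  calls |>
    filter(!is.na(.data$motif)) |>
    count(.data$family, .data$overall_class, .data$motif, name = "n") |>
    arrange(.data$family, desc(.data$n))
}
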