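## Six context-dependent substitution-rate estimators from three-way
## (human, chimp, ancestor) alignments.
##
## Counting semantics:
##  * Only alignment columns whose human position falls inside the CGI
##    seed counts; a dinucleotide is attributed to the CGI by its FIRST
##    base (the second column may lie just outside).
##  * An ancestral dinucleotide is two consecutive alignment columns in
##    which the ancestor row has two non-gap, non-N bases; a lineage
##    contributes at most one event per ancestral dinucleotide and only
##    when it is non-gap and non-N in both columns.
##  * Single-base contexts (CpG vs non-CpG) are evaluated on the
##    ungapped sequence of the relevant species: the nearest non-gap
##    neighbour base on each side. A/T -> G/C events require the derived
##    G/C to sit in a non-CpG context of the DERIVED sequence; the
##    G/C -> A/T denominator requires the ancestral G/C to sit in a
##    non-CpG context of the ANCESTRAL sequence.
##  * Columns with N in the relevant species contribute to neither
##    numerator nor denominator.

.GAPN <- c("-", "N")
.TPG_CPA <- c("TG", "CA")
.OTHER_DINUC <- c("GG", "AG", "CC", "CT")

.count_names <- c("anc_cpg", "ev_cpg_to_tpg_cpa", "ev_cpg_to_other",
                  "anc_tpg_cpa", "ev_tpg_cpa_to_cpg",
                  "anc_other", "ev_other_to_cpg",
                  "anc_at", "ev_at_to_gc",
                  "anc_gc_noncpg", "ev_gc_to_at")

.rate_names <- c("cpg_to_tpg_cpa", "cpg_to_other", "tpg_cpa_to_cpg",
                 "other_to_cpg", "at_to_gc", "gc_to_at")

## Columns of a prepped block whose human position lies in [start, end).
## count of sorted x <= v, by binary search (findInterval revalidates
## its whole vector on every call, which dominates at many CGIs/block)
.n_le <- function(x, v) {
  lo <- 0L; hi <- length(x)
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (x[mid] <= v) lo <- mid else hi <- mid - 1L
  }
  lo
}

.cgi_columns <- function(prep, start, end) {
  pos <- prep$ng_pos
  if (length(pos) == 0L) return(integer(0))
  lo <- .n_le(pos, start - 1L) + 1L
  hi <- .n_le(pos, end - 1L)
  if (lo > hi) return(integer(0))
  prep$ng_cols[lo:hi]
}

.count_block <- function(prep, start, end) {
  counts <- stats::setNames(numeric(length(.count_names)), .count_names)
  cols <- .cgi_columns(prep, start, end)
  if (length(cols) == 0L) return(counts)
  a <- prep$a
  lineages <- list(prep$h, prep$c)
  nb <- prep$nb
  lin_nb <- list(nb$human, nb$chimp)

  ## --- dinucleotide classes: first column in CGI, second is the next column
  j <- cols[cols < prep$L]
  if (length(j)) {
    a1 <- a[j]; a2 <- a[j + 1L]
    valid <- !(a1 %in% .GAPN) & !(a2 %in% .GAPN)
    pair <- paste0(a1, a2)
    cls_cpg <- valid & pair == "CG"
    cls_tpg <- valid & pair %in% .TPG_CPA
    cls_oth <- valid & pair %in% .OTHER_DINUC
    counts["anc_cpg"] <- sum(cls_cpg)
    counts["anc_tpg_cpa"] <- sum(cls_tpg)
    counts["anc_other"] <- sum(cls_oth)
    for (x in lineages) {
      x1 <- x[j]; x2 <- x[j + 1L]
      lv <- !(x1 %in% .GAPN) & !(x2 %in% .GAPN)
      dp <- paste0(x1, x2)
      counts["ev_cpg_to_tpg_cpa"] <- counts["ev_cpg_to_tpg_cpa"] +
        sum(cls_cpg & lv & dp %in% .TPG_CPA)
      counts["ev_cpg_to_other"] <- counts["ev_cpg_to_other"] +
        sum(cls_cpg & lv & dp %in% .OTHER_DINUC)
      counts["ev_tpg_cpa_to_cpg"] <- counts["ev_tpg_cpa_to_cpg"] +
        sum(cls_tpg & lv & dp == "CG")
      counts["ev_other_to_cpg"] <- counts["ev_other_to_cpg"] +
        sum(cls_oth & lv & dp == "CG")
    }
  }

  ## --- single-base classes
  k <- cols
  ak <- a[k]
  a_valid <- !(ak %in% .GAPN)
  anc_cpg_ctx <- (ak == "C" & nb$ancestor$nxt[k] %in% "G") |
                 (ak == "G" & nb$ancestor$prev[k] %in% "C")
  is_at <- a_valid & ak %in% c("A", "T")
  is_gc_noncpg <- a_valid & ak %in% c("G", "C") & !anc_cpg_ctx
  counts["anc_at"] <- sum(is_at)
  counts["anc_gc_noncpg"] <- sum(is_gc_noncpg)
  for (li in 1:2) {
    d <- lineages[[li]][k]
    d_valid <- !(d %in% .GAPN)
    d_cpg_ctx <- (d == "C" & lin_nb[[li]]$nxt[k] %in% "G") |
                 (d == "G" & lin_nb[[li]]$prev[k] %in% "C")
    counts["ev_at_to_gc"] <- counts["ev_at_to_gc"] +
      sum(is_at & d_valid & d %in% c("G", "C") & !d_cpg_ctx)
    counts["ev_gc_to_at"] <- counts["ev_gc_to_at"] +
      sum(is_gc_noncpg & d_valid & d %in% c("A", "T"))
  }
  counts
}

#' Count substitution opportunities and events within a CGI
#'
#' Scans every alignment column whose human position falls inside the
#' CGI and tallies, over both the human and chimpanzee lineages,
#' ancestral opportunity counts and derived event counts for the six
#' substitution classes: CpG to TpG/CpA, CpG to GpG/ApG/CpC/CpT,
#' TpG/CpA to CpG, GpG/ApG/CpC/CpT to CpG, A/T to G/C (derived G/C in a
#' non-CpG context of the derived sequence), and G/C to A/T (ancestral
#' G/C in a non-CpG context of the ancestral sequence). A dinucleotide
#' belongs to the CGI when its first base does.
#'
#' @param cgi A single-row data.frame (or list) with `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param aln A `triple_alignment`.
#' @return Named numeric vector of the 11 counts (`anc_cpg`,
#'   `ev_cpg_to_tpg_cpa`, `ev_cpg_to_other`, `anc_tpg_cpa`,
#'   `ev_tpg_cpa_to_cpg`, `anc_other`, `ev_other_to_cpg`, `anc_at`,
#'   `ev_at_to_gc`, `anc_gc_noncpg`, `ev_gc_to_at`).
#' @export
count_substitution_events <- function(cgi, aln) {
  counts <- stats::setNames(numeric(length(.count_names)), .count_names)
  for (b in aln$blocks) {
    if (b$chrom != cgi$chrom) next
    counts <- counts + .count_block(.prep_block(b), cgi$start, cgi$end)
  }
  counts
}

#' Fraction of a CGI covered by the alignment
#'
#' The fraction of CGI bases present as non-gap human positions in any
#' alignment block. Blocks are assumed not to overlap on the human
#' genome (as in whole-genome ancestor alignments); the fraction is
#' capped at 1.
#'
#' @inheritParams count_substitution_events
#' @return Coverage fraction in `[0, 1]`.
#' @export
cgi_alignment_coverage <- function(cgi, aln) {
  len <- cgi$end - cgi$start
  covered <- 0L
  for (b in aln$blocks) {
    if (b$chrom != cgi$chrom) next
    prep <- .prep_block(b)
    covered <- covered + length(.cgi_columns(prep, cgi$start, cgi$end))
  }
  min(covered / len, 1)
}

#' Substitution rates from opportunity/event counts
#'
#' Each rate is the event count divided by twice the corresponding
#' ancestral opportunity count (two lineages); `NA` when the
#' opportunity count is zero.
#'
#' @param counts Named numeric vector from
#'   [count_substitution_events()].
#' @return Named numeric vector of the six rates (`cpg_to_tpg_cpa`,
#'   `cpg_to_other`, `tpg_cpa_to_cpg`, `other_to_cpg`, `at_to_gc`,
#'   `gc_to_at`), each in `[0, 1]` or `NA`.
#' @export
rates_from_counts <- function(counts) {
  rate <- function(ev, anc) if (counts[[anc]] == 0) NA_real_ else counts[[ev]] / (2 * counts[[anc]])
  c(cpg_to_tpg_cpa = rate("ev_cpg_to_tpg_cpa", "anc_cpg"),
    cpg_to_other = rate("ev_cpg_to_other", "anc_cpg"),
    tpg_cpa_to_cpg = rate("ev_tpg_cpa_to_cpg", "anc_tpg_cpa"),
    other_to_cpg = rate("ev_other_to_cpg", "anc_other"),
    at_to_gc = rate("ev_at_to_gc", "anc_at"),
    gc_to_at = rate("ev_gc_to_at", "anc_gc_noncpg"))
}

#' Per-CGI substitution rates with the coverage filter
#'
#' Computes alignment coverage, opportunity/event counts and the six
#' substitution rates for every CGI. CGIs whose human-anchored
#' alignment coverage is below `min_coverage` are excluded: their
#' counts and rates are reported as `NA` and `excluded` is `TRUE`.
#' Coverage of exactly `min_coverage` is retained (only strictly lower
#' coverage is removed).
#'
#' @param cgis CGI interval data.frame (`cgi_id`, `chrom`, `start`, `end`).
#' @param aln A `triple_alignment`.
#' @param min_coverage Exclusion threshold on the covered fraction
#'   (default 0.5).
#' @return data.frame with `cgi_id`, `coverage`, `excluded`, the 11
#'   count columns and the 6 rate columns.
#' @export
cgi_substitution_rates <- function(cgis, aln, min_coverage = 0.5) {
  preps <- lapply(aln$blocks, .prep_block)
  chroms <- vapply(aln$blocks, `[[`, character(1), "chrom")
  n <- nrow(cgis)
  count_mat <- matrix(NA_real_, n, length(.count_names),
                      dimnames = list(NULL, .count_names))
  rate_mat <- matrix(NA_real_, n, length(.rate_names),
                     dimnames = list(NULL, .rate_names))
  coverage <- numeric(n)
  for (i in seq_len(n)) {
    len <- cgis$end[i] - cgis$start[i]
    counts <- stats::setNames(numeric(length(.count_names)), .count_names)
    covered <- 0L
    for (bi in which(chroms == cgis$chrom[i])) {
      cols <- .cgi_columns(preps[[bi]], cgis$start[i], cgis$end[i])
      covered <- covered + length(cols)
      if (length(cols))
        counts <- counts + .count_block(preps[[bi]], cgis$start[i], cgis$end[i])
    }
    coverage[i] <- min(covered / len, 1)
    if (coverage[i] >= min_coverage) {
      count_mat[i, ] <- counts
      rate_mat[i, ] <- rates_from_counts(counts)
    }
  }
  out <- data.frame(cgi_id = cgis$cgi_id, coverage = coverage,
                    excluded = coverage < min_coverage,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(count_mat), as.data.frame(rate_mat))
}
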