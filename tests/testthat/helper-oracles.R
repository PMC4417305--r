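# Fixture builders and independent brute-force oracles used across the
# test files. The oracles deliberately share no code with the package
# internals they check.

# One gene-model row in the read_gene_models() layout.
make_gene <- function(name, chrom, strand, exon_starts, exon_ends,
                      coding = TRUE) {
  tx_start <- min(exon_starts)
  tx_end <- max(exon_ends)
  df <- data.frame(name = name, chrom = chrom, strand = strand,
                   tx_start = tx_start, tx_end = tx_end,
                   cds_start = if (coding) tx_start + 10L else tx_start,
                   cds_end = if (coding) tx_end - 10L else tx_start,
                   coding = coding, stringsAsFactors = FALSE)
  df$exon_starts <- list(as.integer(exon_starts))
  df$exon_ends <- list(as.integer(exon_ends))
  df
}

make_genes <- function(...) do.call(rbind, list(...))

make_cgis <- function(chrom, start, end, id = NULL) {
  data.frame(cgi_id = id %||% paste0("cgi_", seq_along(start)),
             chrom = chrom, start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_sites <- function(pos, strand, meth, unmeth, chrom = "chr1") {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             meth_calls = as.integer(meth), unmeth_calls = as.integer(unmeth),
             stringsAsFactors = FALSE)
}

# --- classification oracle: exhaustive per-base enumeration -----------------
# Marks every base of every window type on a small genome and classifies a
# CGI by the first priority class any of its bases carries.
oracle_classify <- function(cgi, genes, flank = 3000L) {
  base_sets <- list(five_prime = list(), three_prime = list(), intragenic = list())
  for (g in seq_len(nrow(genes))) {
    if (genes$chrom[g] != cgi$chrom) next
    es <- genes$exon_starts[[g]]; ee <- genes$exon_ends[[g]]
    plus <- genes$strand[g] == "+"
    first <- if (plus) 1L else length(es)
    final <- if (plus) length(es) else 1L
    w5 <- if (plus) c(max(0L, es[first] - flank), ee[first])
          else c(es[first], ee[first] + flank)
    w3 <- if (plus) c(es[final], ee[final] + flank)
          else c(max(0L, es[final] - flank), ee[final])
    base_sets$five_prime[[length(base_sets$five_prime) + 1L]] <-
      list(name = genes$name[g], coding = genes$coding[g], bases = seq(w5[1L], w5[2L] - 1L))
    base_sets$three_prime[[length(base_sets$three_prime) + 1L]] <-
      list(name = genes$name[g], coding = genes$coding[g], bases = seq(w3[1L], w3[2L] - 1L))
    if (length(es) >= 2L) {
      wi <- c(min(ee), max(es))
      if (wi[2L] > wi[1L])
        base_sets$intragenic[[length(base_sets$intragenic) + 1L]] <-
          list(name = genes$name[g], coding = genes$coding[g], bases = seq(wi[1L], wi[2L] - 1L))
    }
  }
  cgi_bases <- seq(cgi$start, cgi$end - 1L)
  for (cat in names(base_sets)) {
    triggering <- Filter(function(w) length(intersect(cgi_bases, w$bases)) > 0L,
                         base_sets[[cat]])
    if (length(triggering)) {
      return(list(category = cat,
                  coding = if (any(vapply(triggering, `[[`, logical(1), "coding")))
                    "coding" else "noncoding",
                  genes = sort(unique(vapply(triggering, `[[`, character(1), "name")))))
    }
  }
  list(category = "intergenic", coding = "noncoding", genes = character(0))
}

# --- substitution-count oracle: per-position scan on gapless strings --------
# Enumerates every (position, lineage) pair with substr() arithmetic only.
oracle_count_events <- function(anc, hum, chp, start, end) {
  at <- function(s, i) substr(s, i + 1L, i + 1L)   # 0-based accessor
  L <- nchar(anc)
  counts <- c(anc_cpg = 0, ev_cpg_to_tpg_cpa = 0, ev_cpg_to_other = 0,
              anc_tpg_cpa = 0, ev_tpg_cpa_to_cpg = 0,
              anc_other = 0, ev_other_to_cpg = 0,
              anc_at = 0, ev_at_to_gc = 0, anc_gc_noncpg = 0, ev_gc_to_at = 0)
  tpg <- c("TG", "CA"); oth <- c("GG", "AG", "CC", "CT")
  for (i in seq(start, end - 1L)) {
    a1 <- at(anc, i)
    if (i + 1L < L) {
      a2 <- at(anc, i + 1L)
      ap <- paste0(a1, a2)
      ok <- !a1 %in% c("N", "-") && !a2 %in% c("N", "-")
      if (ok && ap == "CG") counts["anc_cpg"] <- counts["anc_cpg"] + 1
      if (ok && ap %in% tpg) counts["anc_tpg_cpa"] <- counts["anc_tpg_cpa"] + 1
      if (ok && ap %in% oth) counts["anc_other"] <- counts["anc_other"] + 1
      for (s in c(hum, chp)) {
        d1 <- at(s, i); d2 <- at(s, i + 1L)
        if (d1 %in% c("N", "-") || d2 %in% c("N", "-")) next
        dp <- paste0(d1, d2)
        if (ok && ap == "CG" && dp %in% tpg)
          counts["ev_cpg_to_tpg_cpa"] <- counts["ev_cpg_to_tpg_cpa"] + 1
        if (ok && ap == "CG" && dp %in% oth)
          counts["ev_cpg_to_other"] <- counts["ev_cpg_to_other"] + 1
        if (ok && ap %in% tpg && dp == "CG")
          counts["ev_tpg_cpa_to_cpg"] <- counts["ev_tpg_cpa_to_cpg"] + 1
        if (ok && ap %in% oth && dp == "CG")
          counts["ev_other_to_cpg"] <- counts["ev_other_to_cpg"] + 1
      }
    }
    if (a1 %in% c("N", "-")) next
    anc_cpg_ctx <- (a1 == "C" && i + 1L < L && at(anc, i + 1L) == "G") ||
                   (a1 == "G" && i > 0L && at(anc, i - 1L) == "C")
    if (a1 %in% c("A", "T")) counts["anc_at"] <- counts["anc_at"] + 1
    if (a1 %in% c("G", "C") && !anc_cpg_ctx)
      counts["anc_gc_noncpg"] <- counts["anc_gc_noncpg"] + 1
    for (s in c(hum, chp)) {
      d <- at(s, i)
      if (d %in% c("N", "-")) next
      d_cpg_ctx <- (d == "C" && i + 1L < L && at(s, i + 1L) == "G") ||
                   (d == "G" && i > 0L && at(s, i - 1L) == "C")
      if (a1 %in% c("A", "T") && d %in% c("G", "C") && !d_cpg_ctx)
        counts["ev_at_to_gc"] <- counts["ev_at_to_gc"] + 1
      if (a1 %in% c("G", "C") && !anc_cpg_ctx && d %in% c("A", "T"))
        counts["ev_gc_to_at"] <- counts["ev_gc_to_at"] + 1
    }
  }
  counts
}

# Random gapless triple over a short region, with point differences.
random_triple <- function(len = 100L, diverge = 0.1) {
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, len, replace = TRUE)
  mutate <- function(x) {
    hit <- runif(len) < diverge
    x[hit] <- sample(bases, sum(hit), replace = TRUE)
    x
  }
  list(anc = paste(anc, collapse = ""),
       hum = paste(mutate(anc), collapse = ""),
       chp = paste(mutate(anc), collapse = ""))
}

# --- stump oracle: brute force over every candidate threshold ---------------
oracle_stump <- function(rate, label) {
  v <- sort(unique(rate))
  cand <- (v[-length(v)] + v[-1L]) / 2
  lev <- sort(unique(label))
  best <- list(wg = Inf, threshold = NA_real_)
  for (t in cand) {
    lo <- label[rate < t]; hi <- label[rate >= t]
    g <- function(l) {
      if (!length(l)) return(0)
      p <- table(factor(l, levels = lev)) / length(l)
      1 - sum(p^2)
    }
    wg <- (length(lo) * g(lo) + length(hi) * g(hi)) / length(label)
    if (wg < best$wg - 1e-12) best <- list(wg = wg, threshold = t)
  }
  best
}
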