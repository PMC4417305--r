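#' Read CpG island intervals from a BED3+ file
#'
#' Reads a BED-like file of CGI coordinates. Coordinates are 0-based
#' half-open, following the UCSC table convention. An optional fourth
#' column supplies CGI identifiers; otherwise identifiers `cgi_1`,
#' `cgi_2`, ... are assigned in file order.
#'
#' @param path Path to a tab-separated BED3+ file (no header).
#' @return A data.frame with columns `cgi_id`, `chrom`, `start`, `end`.
#' @export
read_cgi_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3L) .stopf("BED file '%s' has fewer than 3 columns", path)
  out <- data.frame(
    cgi_id = if (ncol(df) >= 4L) as.character(df[[4L]]) else paste0("cgi_", seq_len(nrow(df))),
    chrom = as.character(df[[1L]]),
    start = as.integer(df[[2L]]),
    end = as.integer(df[[3L]]),
    stringsAsFactors = FALSE
  )
  validate_intervals(out)
  out
}

#' Validate genomic intervals
#'
#' Checks the interval invariants used throughout the package:
#' non-empty chromosome names, `start >= 0` and `end > start`
#' (0-based half-open coordinates).
#'
#' @param df A data.frame with columns `chrom`, `start`, `end`.
#' @return `df`, invisibly; errors on violation.
#' @export
validate_intervals <- function(df) {
  if (any(is.na(df$start)) || any(is.na(df$end)))
    .stopf("interval coordinates contain NA")
  if (any(df$start < 0)) .stopf("interval start < 0")
  if (any(df$end <= df$start)) .stopf("interval end <= start")
  if (any(!nzchar(df$chrom))) .stopf("empty chromosome name")
  invisible(df)
}

#' Read transcript models from a knownGene-style table
#'
#' Parses a UCSC knownGene-style tab-separated table. The table must
#' carry a header naming at least `name`, `chrom`, `strand`, `txStart`,
#' `txEnd`, `cdsStart`, `cdsEnd`, `exonStarts`, `exonEnds` (set
#' `header = FALSE` for raw UCSC dumps, which use that column order
#' with `exonCount` between `cdsEnd` and `exonStarts`). Exon lists are
#' comma-separated with an optional trailing comma, as in UCSC dumps.
#'
#' A transcript is flagged non-coding when `cdsStart == cdsEnd`, the
#' convention used for non-coding entries in the knownGene table.
#'
#' @param path Path to the TSV file.
#' @param header Logical; does the file carry a header line?
#' @return A data.frame with one row per transcript: `name`, `chrom`,
#'   `strand`, `tx_start`, `tx_end`, `cds_start`, `cds_end`, `coding`
#'   (logical), and list-columns `exon_starts`, `exon_ends` (integer
#'   vectors, 0-based half-open).
#' @export
read_gene_models <- function(path, header = TRUE) {
  if (header) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, comment.char = "")
    need <- c("name", "chrom", "strand", "txStart", "txEnd",
              "cdsStart", "cdsEnd", "exonStarts", "exonEnds")
    miss <- setdiff(need, names(df))
    if (length(miss)) .stopf("gene table missing columns: %s", paste(miss, collapse = ", "))
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, comment.char = "")
    if (ncol(df) < 10L) .stopf("headerless gene table needs >= 10 columns")
    names(df)[1:10] <- c("name", "chrom", "strand", "txStart", "txEnd",
                         "cdsStart", "cdsEnd", "exonCount", "exonStarts", "exonEnds")
  }
  parse_list <- function(x, row, what) {
    v <- suppressWarnings(as.integer(strsplit(sub(",$", "", x), ",", fixed = TRUE)[[1L]]))
    if (length(v) == 0L || anyNA(v))
      .stopf("row %d ('%s'): malformed %s list '%s'", row, df$name[row], what, x)
    v
  }
  n <- nrow(df)
  exon_starts <- vector("list", n)
  exon_ends <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parse_list(df$exonStarts[i], i, "exonStarts")
    e <- parse_list(df$exonEnds[i], i, "exonEnds")
    if (length(s) != length(e))
      .stopf("row %d ('%s'): exonStarts/exonEnds length mismatch (%d vs %d)",
             i, df$name[i], length(s), length(e))
    if (is.unsorted(s, strictly = TRUE) || any(e <= s) || any(utils::head(e, -1) > utils::tail(s, -1)))
      .stopf("row %d ('%s'): exons not sorted/non-overlapping", i, df$name[i])
    exon_starts[[i]] <- s
    exon_ends[[i]] <- e
  }
  if (!all(df$strand %in% c("+", "-"))) .stopf("gene strand must be '+' or '-'")
  out <- data.frame(
    name = as.character(df$name),
    chrom = as.character(df$chrom),
    strand = as.character(df$strand),
    tx_start = as.integer(df$txStart),
    tx_end = as.integer(df$txEnd),
    cds_start = as.integer(df$cdsStart),
    cds_end = as.integer(df$cdsEnd),
    coding = as.integer(df$cdsStart) != as.integer(df$cdsEnd),
    stringsAsFactors = FALSE
  )
  out$exon_starts <- exon_starts
  out$exon_ends <- exon_ends
  out
}

## First exon in transcription orientation: highest-coordinate exon on '-'.
.first_exon <- function(genes) {
  n_ex <- lengths(genes$exon_starts)
  idx <- ifelse(genes$strand == "+", 1L, n_ex)
  data.frame(
    start = mapply(function(s, i) s[i], genes$exon_starts, idx),
    end = mapply(function(e, i) e[i], genes$exon_ends, idx)
  )
}

.final_exon <- function(genes) {
  n_ex <- lengths(genes$exon_starts)
  idx <- ifelse(genes$strand == "+", n_ex, 1L)
  data.frame(
    start = mapply(function(s, i) s[i], genes$exon_starts, idx),
    end = mapply(function(e, i) e[i], genes$exon_ends, idx)
  )
}

#' Promoter-side (5') classification window of a transcript
#'
#' The window runs from `flank` bases upstream of the first exon
#' (in transcription orientation) through the end of the first exon.
#' On the minus strand the first exon is the highest-coordinate exon
#' and "upstream" extends toward higher coordinates. The lower bound is
#' clamped at 0, and the upper bound at the chromosome length when
#' `chrom_lengths` is supplied.
#'
#' @param genes Gene-model data.frame from [read_gene_models()].
#' @param flank Upstream extent in bases (default 3000).
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return data.frame `name`, `chrom`, `start`, `end` (0-based half-open).
#' @export
five_prime_window <- function(genes, flank = 3000L, chrom_lengths = NULL) {
  fe <- .first_exon(genes)
  start <- ifelse(genes$strand == "+", pmax(0L, fe$start - flank), fe$start)
  end <- ifelse(genes$strand == "+", fe$end, fe$end + flank)
  .clamp_windows(genes, start, end, chrom_lengths)
}

#' Downstream (3') classification window of a transcript
#'
#' Spans the final exon (in transcription orientation) through `flank`
#' bases downstream of transcription. The exon body is included,
#' mirroring the 5' window definition. Bounds are clamped as in
#' [five_prime_window()].
#'
#' @inheritParams five_prime_window
#' @return data.frame `name`, `chrom`, `start`, `end`.
#' @export
three_prime_window <- function(genes, flank = 3000L, chrom_lengths = NULL) {
  fe <- .final_exon(genes)
  start <- ifelse(genes$strand == "+", fe$start, pmax(0L, fe$start - flank))
  end <- ifelse(genes$strand == "+", fe$end + flank, fe$end)
  .clamp_windows(genes, start, end, chrom_lengths)
}

#' Intragenic classification window of a transcript
#'
#' The region between the first and final introns: from the
#' transcription-3' end of the first exon to the transcription-5' end of
#' the final exon. In genomic coordinates this is the span between the
#' end of the lowest-coordinate exon and the start of the
#' highest-coordinate exon, for either strand. Single-exon transcripts
#' have no such window and are dropped from the result.
#'
#' @inheritParams five_prime_window
#' @return data.frame `name`, `chrom`, `start`, `end`; zero rows when
#'   no transcript has an intron.
#' @export
intragenic_window <- function(genes) {
  n_ex <- lengths(genes$exon_starts)
  keep <- n_ex >= 2L
  g <- genes[keep, , drop = FALSE]
  start <- vapply(g$exon_ends, function(e) e[1L], integer(1))
  end <- vapply(g$exon_starts, function(s) s[length(s)], integer(1))
  out <- data.frame(name = g$name, chrom = g$chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  out[out$end > out$start, , drop = FALSE]
}

.clamp_windows <- function(genes, start, end, chrom_lengths) {
  start <- pmax(0L, as.integer(start))
  end <- as.integer(end)
  if (!is.null(chrom_lengths)) {
    lim <- unname(chrom_lengths[genes$chrom])
    end <- pmin(end, ifelse(is.na(lim), end, as.integer(lim)))
  }
  data.frame(name = genes$name, chrom = genes$chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Classify CpG islands by position relative to transcripts
#'
#' Assigns each CGI one of four positional categories by a fixed
#' priority: `five_prime` if it shares at least one base with any
#' transcript's 5' window; else `three_prime` against the 3' windows;
#' else `intragenic` against the first-to-final-intron windows; else
#' `intergenic`. A CGI is flagged `coding` when any transcript whose
#' window triggered the assigned category is protein-coding; intergenic
#' CGIs are always `noncoding`.
#'
#' @param cgis data.frame of CGI intervals (`cgi_id`, `chrom`, `start`,
#'   `end`), e.g. from [read_cgi_bed()].
#' @param genes Gene-model data.frame from [read_gene_models()].
#' @param flank Window flank in bases (default 3000).
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   window clamping.
#' @return data.frame with columns `cgi_id`, `chrom`, `start`, `end`,
#'   `category` (one of `five_prime`, `three_prime`, `intragenic`,
#'   `intergenic`), `coding` (`"coding"`/`"noncoding"`), and
#'   `associated_genes` (comma-separated transcript names that triggered
#'   the category; empty for intergenic).
#' @export
classify_cgis <- function(cgis, genes, flank = 3000L, chrom_lengths = NULL) {
  if (is.null(cgis$cgi_id)) cgis$cgi_id <- paste0("cgi_", seq_len(nrow(cgis)))
  validate_intervals(cgis)
  n <- nrow(cgis)
  category <- rep("intergenic", n)
  coding <- rep("noncoding", n)
  assoc <- rep("", n)
  if (nrow(genes) > 0L && n > 0L) {
    gr_cgi <- .as_granges(cgis)
    windows <- list(
      five_prime = five_prime_window(genes, flank, chrom_lengths),
      three_prime = three_prime_window(genes, flank, chrom_lengths),
      intragenic = intragenic_window(genes)
    )
    unassigned <- rep(TRUE, n)
    coding_by_name <- stats::setNames(genes$coding, genes$name)
    for (cat in names(windows)) {
      w <- windows[[cat]]
      if (nrow(w) == 0L) next
      hits <- GenomicRanges::findOverlaps(gr_cgi, .as_granges(w))
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      keep <- unassigned[q]
      q <- q[keep]; s <- s[keep]
      if (length(q) == 0L) next
      by_cgi <- split(w$name[s], q)
      idx <- as.integer(names(by_cgi))
      category[idx] <- cat
      unassigned[idx] <- FALSE
      assoc[idx] <- vapply(by_cgi, function(g) paste(sort(unique(g)), collapse = ","),
                           character(1))
      coding[idx] <- ifelse(
        vapply(by_cgi, function(g) any(coding_by_name[unique(g)]), logical(1)),
        "coding", "noncoding")
    }
  }
  data.frame(
    cgi_id = cgis$cgi_id, chrom = cgis$chrom, start = cgis$start, end = cgis$end,
    category = factor(category, levels = c("five_prime", "three_prime",
                                           "intragenic", "intergenic")),
    coding = factor(coding, levels = c("coding", "noncoding")),
    associated_genes = assoc,
    stringsAsFactors = FALSE
  )
}
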