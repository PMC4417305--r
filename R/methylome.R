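#' Read per-site bisulfite call counts
#'
#' Reads a tab-separated table of per-cytosine call counts with columns
#' `chrom`, `pos` (0-based offset of the cytosine), `strand` (`+`/`-`),
#' `meth_calls`, `unmeth_calls`. This is the shape bedGraph-like and
#' Bismark-CX-like exports reduce to after column mapping. The same
#' reader serves 5hmC call streams (hydroxymethylated vs
#' non-hydroxymethylated calls in the two count columns).
#'
#' @param path Path to the TSV file (with header).
#' @return data.frame of site calls.
#' @export
read_site_calls <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "strand", "meth_calls", "unmeth_calls")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("site-call table missing columns: %s", paste(miss, collapse = ", "))
  if (any(df$meth_calls < 0) || any(df$unmeth_calls < 0)) .stopf("negative call counts")
  if (!all(df$strand %in% c("+", "-"))) .stopf("site strand must be '+' or '-'")
  df[need]
}

## Restrict sites to one CGI: cytosine position in [start, end).
.sites_in_cgi <- function(sites, cgi) {
  sites[sites$chrom == cgi$chrom & sites$pos >= cgi$start & sites$pos < cgi$end, ,
        drop = FALSE]
}

#' Pooled methylation level of a CGI
#'
#' The pooled estimator: 100 * S / (S + C) where S and C are the total
#' methylated and unmethylated calls over all sites of the CGI, both
#' strands together. Returns `NA` when there are no calls.
#'
#' @param sites data.frame of site calls already restricted to the CGI
#'   (columns `meth_calls`, `unmeth_calls`, `strand`).
#' @return Methylation level as a percentage in `[0, 100]`, or `NA`.
#' @export
cgi_level_pooled <- function(sites) {
  s <- sum(sites$meth_calls)
  c_ <- sum(sites$unmeth_calls)
  if (s + c_ == 0) return(NA_real_)
  100 * s / (s + c_)
}

#' Strand-averaged pooled methylation level of a CGI
#'
#' Pools calls within each strand, computes the two per-strand pooled
#' levels, and returns their unweighted mean. A strand with zero calls
#' is ignored (the other strand's level is returned) rather than
#' treated as 0%. Returns `NA` when neither strand has calls.
#'
#' @inheritParams cgi_level_pooled
#' @return Percentage in `[0, 100]`, or `NA`.
#' @export
cgi_level_pooled_strand_averaged <- function(sites) {
  lv <- vapply(c("+", "-"), function(st) {
    cgi_level_pooled(sites[sites$strand == st, , drop = FALSE])
  }, numeric(1))
  lv <- lv[!is.na(lv)]
  if (length(lv) == 0L) return(NA_real_)
  mean(lv)
}

#' Site-mean methylation level of a CGI
#'
#' The unweighted mean of per-site methylation ratios
#' `meth / (meth + unmeth)`, times 100, over sites whose total call
#' count is at least `min_reads_per_site`. Sites with zero calls are
#' always dropped (their ratio is undefined). Use
#' `min_reads_per_site = 4` for RRBS-style data restricted to sites
#' covered by at least 4 reads, and 0 for the unrestricted variant.
#'
#' @inheritParams cgi_level_pooled
#' @param min_reads_per_site Minimum calls per site (default 0).
#' @return Percentage in `[0, 100]`, or `NA` when no site qualifies.
#' @export
cgi_level_site_mean <- function(sites, min_reads_per_site = 0L) {
  tot <- sites$meth_calls + sites$unmeth_calls
  keep <- tot >= max(min_reads_per_site, 1L)
  if (!any(keep)) return(NA_real_)
  100 * mean(sites$meth_calls[keep] / tot[keep])
}

#' Pooled hydroxymethylation level of a CGI
#'
#' 100 * HC / (HC + NHC) over all calls of the CGI, with
#' hydroxymethylated and non-hydroxymethylated counts in the
#' `meth_calls` / `unmeth_calls` columns. Identical arithmetic to
#' [cgi_level_pooled()], kept as its own entry point because it
#' consumes a separate 5hmC call stream.
#'
#' @inheritParams cgi_level_pooled
#' @return Percentage in `[0, 100]`, or `NA`.
#' @export
cgi_hydroxymethylation_level <- function(sites) cgi_level_pooled(sites)

#' Minimum-call exclusion filter
#'
#' A CGI is excluded from methylation analysis when fewer than
#' `min_total_calls` calls (methylated plus unmethylated, all sites,
#' both strands) were mapped to its CpG dinucleotides.
#'
#' @inheritParams cgi_level_pooled
#' @param min_total_calls Exclusion threshold (default 5): totals
#'   strictly below it are excluded.
#' @return `TRUE` if the CGI passes, `FALSE` if it is excluded.
#' @export
minimum_call_filter <- function(sites, min_total_calls = 5L) {
  sum(sites$meth_calls) + sum(sites$unmeth_calls) >= min_total_calls
}

#' Label methylation levels as LM / HM / intermediate
#'
#' Levels at or below `lm_max` are labelled `LM`, at or above `hm_min`
#' `HM` (both bounds inclusive), `intermediate` otherwise, and
#' `excluded` for `NA` levels.
#'
#' @param level Numeric vector of levels in percent (NA = excluded).
#' @param lm_max Upper bound for LM (default 20).
#' @param hm_min Lower bound for HM (default 80).
#' @return Factor with levels `LM`, `HM`, `intermediate`, `excluded`.
#' @export
methylation_label <- function(level, lm_max = 20, hm_min = 80) {
  lab <- ifelse(is.na(level), "excluded",
         ifelse(level <= lm_max, "LM",
         ifelse(level >= hm_min, "HM", "intermediate")))
  factor(lab, levels = c("LM", "HM", "intermediate", "excluded"))
}

#' Per-CGI methylation levels and labels
#'
#' Applies one of the three estimator variants to every CGI, with the
#' minimum-call exclusion filter and LM/HM labelling.
#'
#' @param sites Site-call data.frame from [read_site_calls()].
#' @param cgis CGI interval data.frame (`cgi_id`, `chrom`, `start`, `end`).
#' @param estimator One of `"pooled_strand_averaged"` (pool within each
#'   strand, average the two strands), `"pooled"` (single pooled ratio),
#'   `"site_mean"` (unweighted mean of per-site ratios).
#' @param min_reads_per_site Per-site coverage floor for the
#'   `site_mean` estimator (default 0; ignored otherwise).
#' @param min_total_calls CGI-level exclusion threshold (default 5).
#' @param lm_max,hm_min Label bounds passed to [methylation_label()].
#' @return data.frame `cgi_id`, `level`, `n_calls`, `n_sites`, `label`.
#'   Excluded CGIs carry `level = NA` and `label = "excluded"`.
#' @export
cgi_methylation <- function(sites, cgis,
                            estimator = c("pooled_strand_averaged", "pooled", "site_mean"),
                            min_reads_per_site = 0L, min_total_calls = 5L,
                            lm_max = 20, hm_min = 80) {
  estimator <- match.arg(estimator)
  n <- nrow(cgis)
  level <- rep(NA_real_, n)
  n_calls <- integer(n)
  n_sites <- integer(n)
  for (i in seq_len(n)) {
    ss <- .sites_in_cgi(sites, cgis[i, ])
    n_calls[i] <- sum(ss$meth_calls) + sum(ss$unmeth_calls)
    n_sites[i] <- nrow(ss)
    if (!minimum_call_filter(ss, min_total_calls)) next
    level[i] <- switch(estimator,
      pooled_strand_averaged = cgi_level_pooled_strand_averaged(ss),
      pooled = cgi_level_pooled(ss),
      site_mean = cgi_level_site_mean(ss, min_reads_per_site))
  }
  data.frame(
    cgi_id = cgis$cgi_id, level = level, n_calls = n_calls, n_sites = n_sites,
    label = methylation_label(level, lm_max, hm_min),
    stringsAsFactors = FALSE
  )
}

#' Flag CGIs carrying any hydroxymethylated call
#'
#' Bisulfite chemistry does not separate 5mC from 5hmC, and
#' hydroxymethylated CpGs deaminate less readily, so analyses of
#' methylation-driven CpG loss may remove every CGI showing at least
#' one hydroxymethylated call in a 5hmC call stream.
#'
#' @param hmc_sites 5hmC site calls ([read_site_calls()] layout;
#'   hydroxymethylated counts in `meth_calls`).
#' @param cgis CGI interval data.frame.
#' @return Logical vector along `cgis`: `TRUE` where the CGI has at
#'   least one hydroxymethylated call.
#' @export
has_hydroxymethylation <- function(hmc_sites, cgis) {
  vapply(seq_len(nrow(cgis)), function(i) {
    sum(.sites_in_cgi(hmc_sites, cgis[i, ])$meth_calls) >= 1L
  }, logical(1))
}
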