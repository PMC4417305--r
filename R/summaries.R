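#' Assemble per-CGI profiles
#'
#' Joins the positional classification, per-sample methylation
#' levels/labels and the per-CGI substitution rates into one wide
#' profile table, the substrate of every summary operation.
#'
#' @param classification Output of [classify_cgis()].
#' @param methylation Named list of per-sample outputs of
#'   [cgi_methylation()]; names become sample names.
#' @param rates Optional output of [cgi_substitution_rates()].
#' @return data.frame with the classification columns plus, per sample
#'   `s`, `level_<s>` and `label_<s>`, and the rate/count columns when
#'   `rates` is given.
#' @export
build_cgi_profiles <- function(classification, methylation = list(), rates = NULL) {
  out <- classification
  for (s in names(methylation)) {
    m <- methylation[[s]]
    idx <- match(out$cgi_id, m$cgi_id)
    out[[paste0("level_", s)]] <- m$level[idx]
    lab <- m$label[idx]
    lab[is.na(idx)] <- "excluded"
    out[[paste0("label_", s)]] <- factor(lab, levels = levels(m$label))
  }
  if (!is.null(rates)) {
    idx <- match(out$cgi_id, rates$cgi_id)
    for (col in setdiff(names(rates), "cgi_id")) out[[col]] <- rates[[col]][idx]
  }
  out
}

.label_col <- function(profiles, sample) {
  col <- paste0("label_", sample)
  if (!col %in% names(profiles)) .stopf("no methylation labels for sample '%s'", sample)
  profiles[[col]]
}

#' LM/HM counts per genomic position
#'
#' Tallies, for one sample, the LM- and HM-labelled CGIs in each
#' positional category by coding status, with a totals row.
#' Intermediate and excluded CGIs are omitted.
#'
#' @param profiles Profile table from [build_cgi_profiles()].
#' @param sample Sample name whose labels are counted.
#' @return data.frame `category`, `coding`, `LM`, `HM` with a final
#'   `Total` row.
#' @export
position_label_counts <- function(profiles, sample) {
  lab <- .label_col(profiles, sample)
  cells <- unique(data.frame(category = profiles$category, coding = profiles$coding))
  cells <- cells[order(cells$category, cells$coding), ]
  count <- function(cat, cod, l) {
    sum(profiles$category == cat & profiles$coding == cod & lab == l, na.rm = TRUE)
  }
  out <- data.frame(
    category = as.character(cells$category), coding = as.character(cells$coding),
    LM = mapply(count, cells$category, cells$coding, MoreArgs = list(l = "LM")),
    HM = mapply(count, cells$category, cells$coding, MoreArgs = list(l = "HM")),
    stringsAsFactors = FALSE
  )
  rbind(out, data.frame(category = "Total", coding = "",
                        LM = sum(out$LM), HM = sum(out$HM)))
}

#' Cross-tabulate methylation labels between two samples
#'
#' For each stratum of (category, coding, label in sample A restricted
#' to LM/HM), counts the CGIs labelled LM and HM in sample B. CGIs
#' whose sample-B label is intermediate or excluded fall in neither
#' column, so `LM + HM` need not reach the stratum size `n`.
#'
#' @param profiles Profile table from [build_cgi_profiles()].
#' @param sample_a,sample_b Sample names (strata are formed on A,
#'   counts taken on B).
#' @return data.frame `category`, `coding`, `label_a`, `n`, `LM`, `HM`.
#' @export
methylation_crosstab <- function(profiles, sample_a, sample_b) {
  la <- .label_col(profiles, sample_a)
  lb <- .label_col(profiles, sample_b)
  keep <- la %in% c("LM", "HM")
  p <- profiles[keep, , drop = FALSE]
  la <- la[keep]; lb <- lb[keep]
  key <- data.frame(category = as.character(p$category),
                    coding = as.character(p$coding),
                    label_a = as.character(la), stringsAsFactors = FALSE)
  grp <- unique(key)
  grp <- grp[order(grp$category, grp$coding, grp$label_a), ]
  rows <- lapply(seq_len(nrow(grp)), function(i) {
    in_g <- key$category == grp$category[i] & key$coding == grp$coding[i] &
            key$label_a == grp$label_a[i]
    data.frame(grp[i, ], n = sum(in_g),
               LM = sum(lb[in_g] == "LM"), HM = sum(lb[in_g] == "HM"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Grouped mean and SEM of the six substitution rates
#'
#' For each group defined by `group_vars` and each substitution-rate
#' type: the number of CGIs with that rate defined, their mean rate and
#' the standard error of the mean (sample standard deviation over
#' `sqrt(n)`, `NA` for `n < 2`). Undefined rates (zero ancestral
#' opportunities, or coverage-excluded CGIs) are dropped from that
#' rate's summary rather than imputed.
#'
#' @param profiles Profile table carrying the rate columns.
#' @param group_vars Character vector of profile columns to group by.
#' @return data.frame: the grouping columns, `rate_type`, `n`, `mean`,
#'   `sem`, ordered by group then rate type.
#' @export
group_rate_summary <- function(profiles, group_vars) {
  miss <- setdiff(group_vars, names(profiles))
  if (length(miss)) .stopf("unknown grouping columns: %s", paste(miss, collapse = ", "))
  key <- interaction(lapply(group_vars, function(v) profiles[[v]]), drop = TRUE, sep = "\r")
  rows <- list()
  for (g in levels(key)) {
    in_g <- which(key == g)
    gvals <- profiles[in_g[1L], group_vars, drop = FALSE]
    for (rt in .rate_names) {
      x <- profiles[[rt]][in_g]
      x <- x[!is.na(x)]
      rows[[length(rows) + 1L]] <- data.frame(
        gvals, rate_type = rt, n = length(x),
        mean = if (length(x)) mean(x) else NA_real_,
        sem = .sem(x), row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[do.call(order, out[c(group_vars, "rate_type")]), , drop = FALSE]
}

#' CGIs below a rate threshold, by position and germline status
#'
#' For each stratum of (category, coding, label in the `h1_sample`
#' restricted to LM/HM): the stratum size, the number and fraction of
#' CGIs with a defined CpG-to-TpG/CpA rate strictly below `threshold`,
#' and the number and fraction that are additionally LM in the
#' `sperm_sample`.
#'
#' @param profiles Profile table with rates and both samples' labels.
#' @param threshold Rate threshold (fitted via [fit_stump()] or fixed).
#' @param h1_sample Sample defining the strata (e.g. an embryonic stem
#'   cell line).
#' @param sperm_sample Germline sample whose LM status is counted.
#' @return data.frame `category`, `coding`, `label_h1`, `n`, `n_below`,
#'   `frac_below`, `n_below_sperm_lm`, `frac_below_sperm_lm`.
#' @export
threshold_partition_report <- function(profiles, threshold, h1_sample, sperm_sample) {
  lh <- .label_col(profiles, h1_sample)
  ls_ <- .label_col(profiles, sperm_sample)
  rate <- profiles$cpg_to_tpg_cpa
  keep <- lh %in% c("LM", "HM")
  p <- profiles[keep, , drop = FALSE]
  lh <- lh[keep]; ls_ <- ls_[keep]; rate <- rate[keep]
  key <- data.frame(category = as.character(p$category),
                    coding = as.character(p$coding),
                    label_h1 = as.character(lh), stringsAsFactors = FALSE)
  grp <- unique(key)
  grp <- grp[order(grp$category, grp$coding, grp$label_h1), ]
  rows <- lapply(seq_len(nrow(grp)), function(i) {
    in_g <- key$category == grp$category[i] & key$coding == grp$coding[i] &
            key$label_h1 == grp$label_h1[i]
    n <- sum(in_g)
    below <- in_g & !is.na(rate) & rate < threshold
    below_lm <- below & ls_ == "LM"
    data.frame(grp[i, ], n = n, n_below = sum(below),
               frac_below = sum(below) / n,
               n_below_sperm_lm = sum(below_lm),
               frac_below_sperm_lm = sum(below_lm) / n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
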