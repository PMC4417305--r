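## Seeded synthetic-data generator. Emulates the statistical structure
## the analysis assumes: CpG-enriched islands on a background sequence,
## transcript models populating every positional class, binomial
## bisulfite call counts at Poisson coverage, and two lineages diverged
## independently from the ancestor under context-dependent substitution
## probabilities, with exact event bookkeeping for parameter-recovery
## tests.

#' Simulation configuration
#'
#' Collects and validates the parameters of the synthetic study.
#' Defaults describe the study conditions the package is tested under:
#' island CpG density 0.12 against a 0.01 background, CGI lengths
#' 500-1500 bp (the scale of annotated human CGIs), true methylation
#' 0.9 for highly methylated (HM) and 0.05 for lowly methylated (LM)
#' CGIs, mean bisulfite coverage 30 per site and strand, balanced
#' sperm HM/LM groups, and per-branch substitution probabilities with
#' CpG deamination elevated in the sperm-HM group (0.04 vs 0.005) and
#' TpG/CpA-to-CpG fixation slightly elevated (0.012 vs 0.008), the
#' remaining classes equal across groups.
#'
#' @param seed Integer seed; fixed seed implies byte-identical outputs.
#' @param n_chromosomes Number of chromosomes to lay cassettes on.
#' @param n_cgis_per_class CGIs per positional class combination
#'   (7 combinations: 5'/3'/intragenic each coding and non-coding,
#'   plus intergenic non-coding).
#' @param cgi_length Length range (min, max) in bases.
#' @param island_cpg_density,background_cpg_density Probability that a
#'   2-base slot is a planted CpG inside/outside islands.
#' @param base_freqs Background base frequencies (named A, C, G, T).
#' @param sperm_hm_fraction Probability a CGI is sperm-HM.
#' @param h1_hm_given_sperm Named probabilities (`HM`, `LM`) that a CGI
#'   is H1-HM given its sperm group.
#' @param meth_level_true Named true methylation proportions (`HM`, `LM`).
#' @param branch_probs Named list of per-branch substitution
#'   probability vectors (`HM`, `LM`, `background`), each with entries
#'   `cpg_to_tpg`, `cpg_to_other`, `tpg_to_cpg`, `other_to_cpg`,
#'   `at_to_gc`, `gc_to_at`.
#' @param coverage_mean Mean Poisson coverage per site and strand.
#' @param indel_rate Per-base probability of a short deletion in each
#'   descendant lineage (default 0: gapless alignments, under which the
#'   recorded truth counts match an exact recount).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       n_cgis_per_class = 5L,
                       cgi_length = c(500L, 1500L),
                       island_cpg_density = 0.12,
                       background_cpg_density = 0.01,
                       base_freqs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                       sperm_hm_fraction = 0.5,
                       h1_hm_given_sperm = c(HM = 0.7, LM = 0.1),
                       meth_level_true = c(HM = 0.9, LM = 0.05),
                       branch_probs = list(
                         HM = c(cpg_to_tpg = 0.04, cpg_to_other = 0.004,
                                tpg_to_cpg = 0.012, other_to_cpg = 0.004,
                                at_to_gc = 0.003, gc_to_at = 0.006),
                         LM = c(cpg_to_tpg = 0.005, cpg_to_other = 0.004,
                                tpg_to_cpg = 0.008, other_to_cpg = 0.004,
                                at_to_gc = 0.003, gc_to_at = 0.006),
                         background = c(cpg_to_tpg = 0.08, cpg_to_other = 0.004,
                                        tpg_to_cpg = 0.004, other_to_cpg = 0.004,
                                        at_to_gc = 0.003, gc_to_at = 0.006)),
                       coverage_mean = 30,
                       indel_rate = 0) {
  cfg <- list(seed = seed, n_chromosomes = n_chromosomes,
              n_cgis_per_class = n_cgis_per_class, cgi_length = cgi_length,
              island_cpg_density = island_cpg_density,
              background_cpg_density = background_cpg_density,
              base_freqs = base_freqs, sperm_hm_fraction = sperm_hm_fraction,
              h1_hm_given_sperm = h1_hm_given_sperm,
              meth_level_true = meth_level_true, branch_probs = branch_probs,
              coverage_mean = coverage_mean, indel_rate = indel_rate)
  for (p in unlist(branch_probs)) if (p < 0 || p > 1) .stopf("branch probabilities must be in [0,1]")
  for (g in c("HM", "LM")) {
    s <- branch_probs[[g]][["cpg_to_tpg"]] + branch_probs[[g]][["cpg_to_other"]]
    if (s > 1) .stopf("cpg_to_tpg + cpg_to_other > 1 for group %s", g)
  }
  if (island_cpg_density <= 0 || island_cpg_density >= 1 ||
      background_cpg_density <= 0 || background_cpg_density >= 1)
    .stopf("CpG densities must be in (0,1)")
  if (cgi_length[1L] < 100L || cgi_length[2L] < cgi_length[1L])
    .stopf("invalid cgi_length range")
  if (abs(sum(base_freqs) - 1) > 1e-8) .stopf("base_freqs must sum to 1")
  structure(cfg, class = "sim_config")
}

## Build one chromosome as L/2 two-base slots: a slot is a planted CpG
## with the region's density, otherwise a non-CpG dinucleotide drawn
## from the background base frequencies. Boundary CpGs arising across
## slot joins are patched (G -> A) so the planted slots are exactly the
## CpG dinucleotides of the sequence.
.sim_chromosome <- function(length, islands, island_density, background_density,
                            base_freqs) {
  stopifnot(length %% 2L == 0L)
  n_slots <- length %/% 2L
  dens <- rep(background_density, n_slots)
  if (nrow(islands)) {
    for (i in seq_len(nrow(islands))) {
      s <- islands$start[i]; e <- islands$end[i]
      stopifnot(s %% 2L == 0L, e %% 2L == 0L, e <= length)
      dens[(s %/% 2L + 1L):(e %/% 2L)] <- island_density
    }
  }
  planted <- stats::runif(n_slots) < dens
  bases <- names(base_freqs)
  dinuc <- expand.grid(b1 = bases, b2 = bases, stringsAsFactors = FALSE)
  keep <- !(dinuc$b1 == "C" & dinuc$b2 == "G")
  dinuc <- dinuc[keep, ]
  w <- (base_freqs[dinuc$b1] * base_freqs[dinuc$b2])
  pick <- sample.int(nrow(dinuc), n_slots, replace = TRUE, prob = w / sum(w))
  seq <- character(length)
  odd <- seq(1L, length, by = 2L)
  seq[odd] <- ifelse(planted, "C", dinuc$b1[pick])
  seq[odd + 1L] <- ifelse(planted, "G", dinuc$b2[pick])
  ## patch boundary CpGs (slot-final C followed by slot-initial G of a
  ## non-planted slot; planted slots start with C, so no planted CpG is touched)
  j <- which(seq[odd + 1L][-n_slots] == "C" & seq[odd][-1L] == "G")
  if (length(j)) seq[odd[j + 1L]] <- "A"
  list(seq = paste(seq, collapse = ""),
       cpg_pos0 = 2L * (which(planted) - 1L))
}

.CLASS_COMBOS <- data.frame(
  category = c("five_prime", "five_prime", "three_prime", "three_prime",
               "intragenic", "intragenic", "intergenic"),
  coding = c("coding", "noncoding", "coding", "noncoding",
             "coding", "noncoding", "noncoding"),
  stringsAsFactors = FALSE
)

#' Simulate a genome with planted CGIs and transcript models
#'
#' Lays out independent 12-kb cassettes, each holding one CGI planted in
#' a known positional class relative to a 3-exon transcript (or with no
#' transcript, for intergenic CGIs), builds CpG-enriched island
#' sequence at every CGI over a CpG-poor background, and assigns each
#' CGI its sperm and H1 methylation groups. Cassettes are spaced so
#' window overlaps never cross cassettes, making the planted class the
#' true class by construction.
#'
#' @param config A [sim_config()].
#' @return A list: `genome` (named character vector of chromosome
#'   sequences), `cgis` (interval data.frame), `genes` (gene-model
#'   data.frame as from [read_gene_models()]), `chrom_lengths`, and
#'   `truth` (per-CGI data.frame: planted `category`, `coding`,
#'   `sperm_group`, `h1_group`, true methylation per group, `n_cpg`
#'   planted CpGs).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  W <- 12000L
  combos <- .CLASS_COMBOS[rep(seq_len(nrow(.CLASS_COMBOS)), each = config$n_cgis_per_class), ]
  n_cas <- nrow(combos)
  chrom <- paste0("chr", (seq_len(n_cas) - 1L) %% config$n_chromosomes + 1L)
  base <- (seq_len(n_cas) - 1L) %/% config$n_chromosomes * W
  lens <- sample(seq(config$cgi_length[1L], config$cgi_length[2L], by = 2L),
                 n_cas, replace = TRUE)
  strand <- sample(c("+", "-"), n_cas, replace = TRUE)
  if (max(base) + W > .Machine$integer.max) .stopf("layout exceeds coordinate range")

  cgi_start <- integer(n_cas); cgi_end <- integer(n_cas)
  genes <- list()
  for (k in seq_len(n_cas)) {
    g0 <- base[k] + 4000L
    L <- lens[k]
    cat_k <- combos$category[k]
    if (cat_k != "intergenic") {
      ex_s <- g0 + c(0L, 1000L, 2000L)
      ex_e <- g0 + c(400L, 1400L, 2400L)
      coding_k <- combos$coding[k] == "coding"
      genes[[length(genes) + 1L]] <- list(
        name = sprintf("tx_%04d", k), chrom = chrom[k], strand = strand[k],
        tx_start = g0, tx_end = g0 + 2400L,
        cds_start = if (coding_k) g0 + 100L else g0,
        cds_end = if (coding_k) g0 + 2300L else g0,
        coding = coding_k, exon_starts = ex_s, exon_ends = ex_e)
    }
    s <- switch(cat_k,
      five_prime = if (strand[k] == "+") g0 - L %/% 2L else g0 + 2400L - L %/% 2L,
      three_prime = if (strand[k] == "+") g0 + 2600L else g0 + 200L - L,
      intragenic = g0 + 500L,
      intergenic = base[k] + 5000L)
    if (cat_k == "intragenic") L <- min(L, 1400L)
    s <- s - s %% 2L
    cgi_start[k] <- s
    cgi_end[k] <- s + L
  }
  genes_df <- do.call(rbind, lapply(genes, function(g) {
    data.frame(name = g$name, chrom = g$chrom, strand = g$strand,
               tx_start = g$tx_start, tx_end = g$tx_end,
               cds_start = g$cds_start, cds_end = g$cds_end,
               coding = g$coding, stringsAsFactors = FALSE)
  }))
  genes_df$exon_starts <- lapply(genes, `[[`, "exon_starts")
  genes_df$exon_ends <- lapply(genes, `[[`, "exon_ends")

  cgis <- data.frame(cgi_id = sprintf("cgi_%04d", seq_len(n_cas)),
                     chrom = chrom, start = cgi_start, end = cgi_end,
                     stringsAsFactors = FALSE)
  chrom_names <- paste0("chr", seq_len(config$n_chromosomes))
  chrom_lengths <- stats::setNames(integer(config$n_chromosomes), chrom_names)
  for (cn in chrom_names) {
    chrom_lengths[cn] <- (max(c(0L, base[chrom == cn])) + W)
  }
  genome <- character(0)
  n_cpg <- integer(n_cas)
  for (cn in chrom_names) {
    on_c <- which(chrom == cn)
    sim <- .sim_chromosome(chrom_lengths[[cn]], cgis[on_c, , drop = FALSE],
                           config$island_cpg_density, config$background_cpg_density,
                           config$base_freqs)
    genome[cn] <- sim$seq
    for (k in on_c) {
      n_cpg[k] <- sum(sim$cpg_pos0 >= cgi_start[k] & sim$cpg_pos0 < cgi_end[k])
    }
  }
  sperm_group <- ifelse(stats::runif(n_cas) < config$sperm_hm_fraction, "HM", "LM")
  h1_group <- ifelse(stats::runif(n_cas) < config$h1_hm_given_sperm[sperm_group],
                     "HM", "LM")
  truth <- data.frame(
    cgi_id = cgis$cgi_id, chrom = chrom, start = cgi_start, end = cgi_end,
    category = combos$category, coding = combos$coding,
    sperm_group = sperm_group, h1_group = h1_group,
    true_meth_sperm = unname(config$meth_level_true[sperm_group]),
    true_meth_h1 = unname(config$meth_level_true[h1_group]),
    n_cpg = n_cpg, stringsAsFactors = FALSE
  )
  list(genome = genome, cgis = cgis, genes = genes_df,
       chrom_lengths = chrom_lengths, truth = truth)
}

## Truth-side opportunity counts for one CGI, computed directly on the
## ungapped ancestor string (independent of the alignment-column
## scanner): dinucleotide attributed by its first base.
.anc_opportunities <- function(seq_chars, start, end) {
  L <- length(seq_chars)
  idx <- (start + 1L):end
  a1 <- seq_chars[idx]
  a2 <- if (end < L) seq_chars[idx + 1L] else c(seq_chars[idx[-length(idx)] + 1L], NA)
  pair <- paste0(a1, a2)
  prev <- if (start > 0L) seq_chars[idx - 1L] else c(NA, seq_chars[idx[-1L] - 1L])
  cpg_ctx <- (a1 == "C" & a2 %in% "G") | (a1 == "G" & prev %in% "C")
  c(anc_cpg = sum(pair == "CG", na.rm = TRUE),
    anc_tpg_cpa = sum(pair %in% .TPG_CPA),
    anc_other = sum(pair %in% .OTHER_DINUC),
    anc_at = sum(a1 %in% c("A", "T")),
    anc_gc_noncpg = sum(a1 %in% c("G", "C") & !cpg_ctx))
}

#' Evolve two lineages from an ancestral genome
#'
#' Mutates the ancestor independently along the human and chimpanzee
#' branches under context-dependent substitution probabilities chosen
#' per region (each CGI uses its group's probability set, everything
#' else the `background` set). Each ancestral CpG converts to TpG or
#' CpA (target uniform) with its region's `cpg_to_tpg` probability, or
#' to one of GpG/ApG/CpC/CpT with `cpg_to_other`; ancestral TpG/CpA and
#' GpG/ApG/CpC/CpT dinucleotides convert to CpG with `tpg_to_cpg` /
#' `other_to_cpg`; ancestral A/T bases convert to a G/C that does not
#' create a derived CpG with `at_to_gc` (the event is skipped when both
#' targets would); ancestral G/C bases outside CpGs convert to A or T
#' with `gc_to_at`. At most one event touches a base, and a
#' dinucleotide event locks both its bases, so the committed events are
#' exactly what the alignment-column scanner recounts on the emitted
#' (gapless) alignment. With `indel_rate > 0`, short deletions are
#' additionally punched into each descendant row as a gap-handling
#' stressor; truth event counts are not adjusted for bases lost to
#' deletions.
#'
#' @param genome Named character vector of ancestor chromosome sequences.
#' @param cgis CGI interval data.frame.
#' @param groups Character vector along `cgis` naming each CGI's
#'   probability set in `branch_probs`.
#' @param branch_probs Named list of probability vectors (must include
#'   `background`); see [sim_config()].
#' @param seed Optional seed.
#' @param indel_rate Per-base deletion probability per descendant row.
#' @return A list: `human`, `chimp` (named sequence vectors), `aln`
#'   (a gapless `triple_alignment`, one block per chromosome), and
#'   `truth` (per-CGI data.frame of the 11 opportunity/event counts,
#'   events summed over both lineages).
#' @export
evolve_pair <- function(genome, cgis, groups, branch_probs, seed = NULL,
                        indel_rate = 0) {
  if (!is.null(seed)) set.seed(seed)
  if (!"background" %in% names(branch_probs))
    .stopf("branch_probs must include a 'background' set")
  pm <- do.call(rbind, branch_probs)  # groups x 6 probs
  n_cgi <- nrow(cgis)
  ev <- matrix(0, n_cgi, 6L,
               dimnames = list(cgis$cgi_id,
                               c("ev_cpg_to_tpg_cpa", "ev_cpg_to_other",
                                 "ev_tpg_cpa_to_cpg", "ev_other_to_cpg",
                                 "ev_at_to_gc", "ev_gc_to_at")))
  opp <- matrix(0, n_cgi, 5L)
  colnames(opp) <- c("anc_cpg", "anc_tpg_cpa", "anc_other", "anc_at", "anc_gc_noncpg")
  human <- chimp <- stats::setNames(character(length(genome)), names(genome))

  for (cn in names(genome)) {
    a <- .chars(genome[[cn]])
    L <- length(a)
    on_c <- which(cgis$chrom == cn)
    region <- integer(L)             # 0 = background, else CGI row index
    for (i in on_c) region[(cgis$start[i] + 1L):cgis$end[i]] <- i
    grp <- rep("background", L)
    grp[region > 0L] <- groups[region[region > 0L]]
    for (i in on_c) {
      opp[i, ] <- opp[i, ] + .anc_opportunities(a, cgis$start[i], cgis$end[i])
    }
    a2v <- c(a[-1L], "X")
    pair <- paste0(a, a2v)           # pair starting at each position
    prev <- c("X", a[-L])
    cpg_ctx <- (a == "C" & a2v == "G") | (a == "G" & prev == "C")
    pos_cpg <- which(pair == "CG")
    pos_tpg <- which(pair %in% .TPG_CPA)
    pos_oth <- which(pair %in% .OTHER_DINUC)
    pos_at <- which(a %in% c("A", "T"))
    pos_gcn <- which(a %in% c("G", "C") & !cpg_ctx)

    gi <- match(grp, rownames(pm))        # integer group code per position
    for (lineage in c("human", "chimp")) {
      derived <- a
      locked <- logical(L)
      p_of <- function(pos, what) pm[cbind(gi[pos], match(what, colnames(pm)))]
      ## dinucleotide event draws
      u <- stats::runif(length(pos_cpg))
      p1 <- p_of(pos_cpg, "cpg_to_tpg"); p2 <- p_of(pos_cpg, "cpg_to_other")
      cpg_type <- ifelse(u < p1, 1L, ifelse(u < p1 + p2, 2L, 0L))
      hit_tpg <- pos_tpg[stats::runif(length(pos_tpg)) < p_of(pos_tpg, "tpg_to_cpg")]
      hit_oth <- pos_oth[stats::runif(length(pos_oth)) < p_of(pos_oth, "other_to_cpg")]
      d_pos <- c(pos_cpg[cpg_type > 0L], hit_tpg, hit_oth)
      ## 1 = cpg->tpg/cpa, 2 = cpg->other, 3 = tpg/cpa->cpg, 4 = other->cpg
      d_cls <- c(cpg_type[cpg_type > 0L],
                 rep(3L, length(hit_tpg)), rep(4L, length(hit_oth)))
      ord <- order(d_pos)
      d_pos <- d_pos[ord]; d_cls <- d_cls[ord]
      ## Would writing value v at base m make the overlapping ancestral
      ## dinucleotide at (q, q+1) display a derived state in a target
      ## class its truth ledger never recorded? Skipping such draws
      ## keeps the emitted alignment exactly recountable.
      dinuc_cls <- function(pr) {
        if (pr == "CG") 1L else if (pr %in% .TPG_CPA || pr %in% .OTHER_DINUC) 2L else 0L
      }
      ## p = first base of the event's own dinucleotide, which is
      ## excluded from the check (its new state IS the event)
      neighbour_conflict <- function(p, m, v) {
        q <- if (m == p) p - 1L else p + 1L   # the one dinuc sharing base m
        if (q < 1L || q + 1L > L) return(FALSE)
        anc_pr <- paste0(a[q], a[q + 1L])
        acls <- dinuc_cls(anc_pr)
        if (acls == 0L) return(FALSE)
        d1 <- if (q == m) v else derived[q]
        d2 <- if (q + 1L == m) v else derived[q + 1L]
        der_pr <- paste0(d1, d2)
        if (der_pr == anc_pr) return(FALSE)
        if (acls == 1L && (der_pr %in% .TPG_CPA || der_pr %in% .OTHER_DINUC)) return(TRUE)
        acls == 2L && der_pr == "CG"
      }
      for (t in seq_along(d_pos)) {
        p <- d_pos[t]
        if (p >= L || locked[p] || locked[p + 1L]) next
        cls <- d_cls[t]
        if (cls == 1L) {            # CpG -> TpG or CpA
          if (stats::runif(1) < 0.5) { m <- p; v <- "T" } else { m <- p + 1L; v <- "A" }
          type <- "ev_cpg_to_tpg_cpa"
        } else if (cls == 2L) {     # CpG -> GpG/ApG/CpC/CpT
          tgt <- sample(.OTHER_DINUC, 1L)
          if (tgt %in% c("GG", "AG")) { m <- p; v <- substr(tgt, 1L, 1L) }
          else { m <- p + 1L; v <- substr(tgt, 2L, 2L) }
          type <- "ev_cpg_to_other"
        } else if (cls == 3L) {     # TpG/CpA -> CpG
          if (a[p] == "T") { m <- p; v <- "C" } else { m <- p + 1L; v <- "G" }
          type <- "ev_tpg_cpa_to_cpg"
        } else {                    # GpG/ApG/CpC/CpT -> CpG
          if (a[p] != "C") { m <- p; v <- "C" } else { m <- p + 1L; v <- "G" }
          type <- "ev_other_to_cpg"
        }
        ## the modified base must not be part of an already-mutated or
        ## ambiguity-creating overlapping dinucleotide
        if (neighbour_conflict(p, m, v)) next
        derived[m] <- v
        locked[p] <- locked[p + 1L] <- TRUE
        if (region[p] > 0L) ev[region[p], type] <- ev[region[p], type] + 1L
      }
      ## single-base event draws
      s_pos <- c(pos_at[stats::runif(length(pos_at)) < p_of(pos_at, "at_to_gc")],
                 pos_gcn[stats::runif(length(pos_gcn)) < p_of(pos_gcn, "gc_to_at")])
      s_is_at <- a[s_pos] %in% c("A", "T")
      ord <- order(s_pos)
      s_pos <- s_pos[ord]; s_is_at <- s_is_at[ord]
      for (t in seq_along(s_pos)) {
        p <- s_pos[t]
        if (locked[p]) next
        if (s_is_at[t]) {
          targets <- c("G", "C")
          if (p > 1L && derived[p - 1L] == "C") targets <- setdiff(targets, "G")
          if (p < L && derived[p + 1L] == "G") targets <- setdiff(targets, "C")
          if (!length(targets)) next     # event would create a CpG; skipped
          derived[p] <- if (length(targets) == 1L) targets else sample(targets, 1L)
          type <- "ev_at_to_gc"
        } else {
          derived[p] <- sample(c("A", "T"), 1L)
          type <- "ev_gc_to_at"
        }
        locked[p] <- TRUE
        if (region[p] > 0L) ev[region[p], type] <- ev[region[p], type] + 1L
      }
      if (lineage == "human") human[cn] <- paste(derived, collapse = "")
      else chimp[cn] <- paste(derived, collapse = "")
    }
  }
  blocks <- lapply(names(genome), function(cn) {
    h <- human[[cn]]; c_ <- chimp[[cn]]; anc <- genome[[cn]]
    if (indel_rate > 0) {
      ## deletion stressor in the non-anchoring rows: the human row keeps
      ## every column (it defines the coordinate system), while chimp and
      ## ancestor lose short runs, exercising the gap rules of the counters
      punch <- function(s) {
        ch <- .chars(s)
        hit <- which(stats::runif(length(ch)) < indel_rate)
        run <- hit[stats::runif(length(hit)) < 0.5]
        ch[unique(c(hit, pmin(run + 1L, length(ch))))] <- "-"
        paste(ch, collapse = "")
      }
      c_ <- punch(c_); anc <- punch(anc)
    }
    list(chrom = cn, start = 0L, human = h, chimp = c_, ancestor = anc)
  })
  truth <- data.frame(cgi_id = cgis$cgi_id, opp, ev, stringsAsFactors = FALSE,
                      row.names = NULL)
  list(human = human, chimp = chimp, aln = triple_alignment(blocks), truth = truth)
}

#' Simulate per-site bisulfite call counts
#'
#' For every CpG dinucleotide of each CGI (in the given reference
#' sequence), emits one site per strand — the C on `+`, the G position
#' on `-` — with coverage drawn from a Poisson law and methylated calls
#' from a binomial at the CGI's true methylation level. Zero-coverage
#' sites are omitted, as in real call tables.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param cgis CGI interval data.frame.
#' @param true_level Numeric vector along `cgis` of true methylation
#'   proportions in `[0, 1]`.
#' @param coverage_mean Mean coverage per site and strand.
#' @param seed Optional seed.
#' @return Site-call data.frame (`chrom`, `pos`, `strand`,
#'   `meth_calls`, `unmeth_calls`).
#' @export
simulate_methylome <- function(genome, cgis, true_level, coverage_mean = 30,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(true_level) == nrow(cgis), all(true_level >= 0 & true_level <= 1))
  out <- list()
  for (i in seq_len(nrow(cgis))) {
    seq <- genome[[cgis$chrom[i]]]
    sub <- substr(seq, cgis$start[i] + 1L, cgis$end[i])
    ch <- .chars(sub)
    p <- which(ch == "C" & c(ch[-1L], "X") == "G")    # 1-based within sub
    if (!length(p)) next
    pos0 <- cgis$start[i] + p - 1L                    # 0-based C position
    pos <- c(pos0, pos0 + 1L)
    strand <- rep(c("+", "-"), each = length(p))
    cov <- stats::rpois(length(pos), coverage_mean)
    meth <- stats::rbinom(length(pos), cov, true_level[i])
    keep <- cov > 0L
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = cgis$chrom[i], pos = pos[keep], strand = strand[keep],
      meth_calls = meth[keep], unmeth_calls = (cov - meth)[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), pos = integer(0), strand = character(0),
                      meth_calls = integer(0), unmeth_calls = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$pos, res$strand), , drop = FALSE]
}

#' Simulate labelled rates for stump fitting
#'
#' Draws per-CGI rates from uniform distributions with known supports
#' for two classes. When the supports are disjoint, the midpoint of the
#' gap (a Bayes-optimal threshold) is recorded in the truth.
#'
#' @param n_per_class Named integer vector, e.g. `c(HM = 100, LM = 100)`.
#' @param dist Named list of `c(min, max)` support bounds per class.
#' @param seed Optional seed.
#' @return A list: `data` (`cgi_id`, `rate`, `label`) and `truth`
#'   (`supports`, `bayes_threshold` or `NA` when supports overlap).
#' @export
simulate_stump_dataset <- function(n_per_class, dist, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(names(n_per_class) %in% names(dist)))
  rows <- lapply(names(n_per_class), function(cl) {
    n <- n_per_class[[cl]]
    if (n == 0L) return(NULL)
    data.frame(rate = stats::runif(n, dist[[cl]][1L], dist[[cl]][2L]),
               label = cl, stringsAsFactors = FALSE)
  })
  data <- do.call(rbind, rows)
  if (is.null(data)) data <- data.frame(rate = numeric(0), label = character(0))
  data <- data.frame(cgi_id = sprintf("cgi_%04d", seq_len(nrow(data))), data,
                     stringsAsFactors = FALSE)
  bayes <- NA_real_
  if (length(dist) == 2L) {
    b <- dist[[order(vapply(dist, `[[`, numeric(1), 1L))[1L]]]
    t <- dist[[order(vapply(dist, `[[`, numeric(1), 1L))[2L]]]
    if (b[2L] < t[1L]) bayes <- (b[2L] + t[1L]) / 2
  }
  list(data = data, truth = list(supports = dist, bayes_threshold = bayes))
}

#' Simulate a rate cohort of islands only
#'
#' A lighter path for substitution-rate and threshold studies: builds a
#' single chromosome of CpG-enriched islands separated by short
#' background spacers, assigns each island a group, evolves human and
#' chimpanzee from the ancestor under the group's branch
#' probabilities, and estimates the six rates per island with
#' [cgi_substitution_rates()].
#'
#' @param n_per_group Named integer vector of islands per group (names
#'   must match `branch_probs` entries, e.g. `HM`, `LM`).
#' @param config A [sim_config()]; supplies lengths, densities and
#'   branch probabilities.
#' @param seed Optional seed (defaults to `config$seed`).
#' @return data.frame per island: `cgi_id`, `group`, `coverage`, the 11
#'   estimated counts, the 6 estimated rates, and the 11 truth counts
#'   (prefixed `true_`).
#' @export
simulate_rate_cohort <- function(n_per_group, config = sim_config(), seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- sum(n_per_group)
  group <- sample(rep(names(n_per_group), n_per_group))
  lens <- sample(seq(config$cgi_length[1L], config$cgi_length[2L], by = 2L),
                 n, replace = TRUE)
  spacer <- 200L
  start <- cumsum(c(spacer, utils::head(lens, -1L) + spacer))
  start <- start - start %% 2L
  cgis <- data.frame(cgi_id = sprintf("cgi_%04d", seq_len(n)), chrom = "chr1",
                     start = start, end = start + lens, stringsAsFactors = FALSE)
  L <- max(cgis$end) + spacer
  L <- L + L %% 2L
  sim <- .sim_chromosome(L, cgis, config$island_cpg_density,
                         config$background_cpg_density, config$base_freqs)
  evo <- evolve_pair(c(chr1 = sim$seq), cgis, group, config$branch_probs)
  rates <- cgi_substitution_rates(cgis, evo$aln)
  truth <- evo$truth[, -1L, drop = FALSE]
  names(truth) <- paste0("true_", names(truth))
  cbind(data.frame(cgi_id = cgis$cgi_id, group = group, stringsAsFactors = FALSE),
        rates[, -1L, drop = FALSE], truth)
}

#' Simulate a complete synthetic study
#'
#' Runs the full generator: genome and transcript layout, lineage
#' evolution, and bisulfite call tables for a sperm-like and an
#' H1-like sample (true levels set by each CGI's sperm and H1 group).
#'
#' @param config A [sim_config()].
#' @return A list: `genome`, `cgis`, `genes`, `chrom_lengths`, `truth`
#'   (per-CGI planted classes/groups plus the 11 substitution-truth
#'   counts), `aln` (`triple_alignment`), and `sites` (named list of
#'   site-call tables for samples `sperm` and `h1`).
#' @export
simulate_study <- function(config = sim_config()) {
  gen <- simulate_genome(config)
  evo <- evolve_pair(gen$genome, gen$cgis, gen$truth$sperm_group, config$branch_probs,
                     indel_rate = config$indel_rate)
  sites <- list(
    sperm = simulate_methylome(gen$genome, gen$cgis, gen$truth$true_meth_sperm,
                               config$coverage_mean),
    h1 = simulate_methylome(gen$genome, gen$cgis, gen$truth$true_meth_h1,
                            config$coverage_mean)
  )
  truth <- merge(gen$truth, evo$truth, by = "cgi_id", sort = FALSE)
  list(genome = gen$genome, cgis = gen$cgis, genes = gen$genes,
       chrom_lengths = gen$chrom_lengths, truth = truth,
       aln = evo$aln, sites = sites)
}

#' Write CGI intervals as BED4
#' @param cgis CGI interval data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cgi_bed <- function(cgis, path) {
  utils::write.table(cgis[, c("chrom", "start", "end", "cgi_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write gene models as a knownGene-style TSV (with header)
#' @param genes Gene-model data.frame ([read_gene_models()] layout).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  df <- data.frame(
    name = genes$name, chrom = genes$chrom, strand = genes$strand,
    txStart = genes$tx_start, txEnd = genes$tx_end,
    cdsStart = genes$cds_start, cdsEnd = genes$cds_end,
    exonCount = lengths(genes$exon_starts),
    exonStarts = vapply(genes$exon_starts, function(x) paste0(paste(x, collapse = ","), ","), character(1)),
    exonEnds = vapply(genes$exon_ends, function(x) paste0(paste(x, collapse = ","), ","), character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write site calls as TSV
#' @param sites Site-call data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_calls <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
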