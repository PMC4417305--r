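#' Run the full CGI methylation/substitution analysis pipeline
#'
#' Orchestrates every stage end to end: input acquisition (either a
#' seeded simulation or files on disk), positional classification,
#' per-sample methylation levels and labels, per-CGI substitution
#' rates with the coverage filter, decision-stump threshold fitting,
#' and the summary tables. Every intermediate table is written to
#' `out_dir` as TSV, together with a `manifest.json` recording the
#' package version, seed, per-stage row counts and filter exclusions.
#' Reruns with the same configuration and seed produce byte-identical
#' outputs.
#'
#' The configuration is a named list (or a path to a YAML file with
#' the same structure):
#' \describe{
#'   \item{simulate}{optional named list of [sim_config()] arguments;
#'     when present the pipeline generates its own inputs and writes
#'     them under `out_dir/inputs`.}
#'   \item{inputs}{when not simulating: paths `cgi_bed`, `genes_tsv`,
#'     `maf`, named list `sites` (sample name -> site-call TSV), and
#'     optionally `species` (named human/chimp/ancestor labels for the
#'     MAF).}
#'   \item{samples}{optional per-sample settings: named list with
#'     `estimator` and `min_reads_per_site` entries per sample.}
#'   \item{h1_sample, sperm_sample}{sample names used for the
#'     cross-tab, stump and threshold partition (defaults `h1`,
#'     `sperm`).}
#'   \item{lm_max, hm_min}{label bounds (defaults 20, 80).}
#'   \item{min_total_calls}{CGI-level call filter (default 5).}
#'   \item{min_coverage}{alignment coverage filter (default 0.5).}
#'   \item{flank}{classification window flank (default 3000).}
#'   \item{fixed_threshold}{optional rate threshold that replaces the
#'     fitted one in the summary stage, e.g. to replay a published
#'     split.}
#'   \item{seed}{integer seed for the simulation stage.}
#' }
#'
#' @param config Named list or path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results: `profiles`,
#'   `classification`, `methylation`, `rates`, `stump`, `threshold`,
#'   `summaries`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) config <- yaml::read_yaml(config)
  if (!is.list(config)) .stopf("config must be a list or a YAML file path")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "cgiturnover",
                   version = as.character(utils::packageVersion("cgiturnover")),
                   seed = config$seed %||% NA, stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
    message(sprintf("[%s] %s", stage,
                    paste(names(list(...)), unlist(list(...)), sep = "=", collapse = " ")))
  }
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  h1_sample <- config$h1_sample %||% "h1"
  sperm_sample <- config$sperm_sample %||% "sperm"
  lm_max <- config$lm_max %||% 20
  hm_min <- config$hm_min %||% 80
  min_total_calls <- config$min_total_calls %||% 5L
  min_coverage <- config$min_coverage %||% 0.5
  flank <- config$flank %||% 3000L

  ## --- stage 1: inputs -------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (!is.null(config$seed)) sim_args$seed <- config$seed
    cfg <- do.call(sim_config, sim_args)
    study <- simulate_study(cfg)
    cgis <- study$cgis
    genes <- study$genes
    aln <- study$aln
    sites <- study$sites
    idir <- file.path(out_dir, "inputs")
    dir.create(idir, showWarnings = FALSE)
    write_cgi_bed(cgis, file.path(idir, "cgis.bed"))
    write_gene_models(genes, file.path(idir, "genes.tsv"))
    write_maf(aln, file.path(idir, "alignment.maf"))
    for (s in names(sites)) write_site_calls(sites[[s]], file.path(idir, paste0("sites_", s, ".tsv")))
    tsv(study$truth, "inputs/truth.tsv")
    note("inputs", source = "simulated", n_cgis = nrow(cgis), n_genes = nrow(genes),
         n_samples = length(sites))
  } else {
    inp <- config$inputs
    if (is.null(inp)) .stopf("config needs either 'simulate' or 'inputs'")
    for (p in c(inp$cgi_bed, inp$genes_tsv, inp$maf, unlist(inp$sites)))
      if (!file.exists(p)) .stopf("input file not found: %s", p)
    cgis <- read_cgi_bed(inp$cgi_bed)
    genes <- read_gene_models(inp$genes_tsv)
    species <- unlist(inp$species) %||% c(human = "human", chimp = "chimp", ancestor = "ancestor")
    aln <- read_maf(inp$maf, species = species)
    sites <- lapply(inp$sites, read_site_calls)
    note("inputs", source = "files", n_cgis = nrow(cgis), n_genes = nrow(genes),
         n_samples = length(sites), maf_blocks = length(aln$blocks),
         maf_rejected = aln$n_rejected)
  }

  ## --- stage 2: positional classification ------------------------------
  classification <- classify_cgis(cgis, genes, flank = flank)
  tsv(classification, "classification.tsv")
  note("regions", n = nrow(classification),
       intergenic = sum(classification$category == "intergenic"))

  ## --- stage 3: methylation --------------------------------------------
  methylation <- list()
  meth_long <- list()
  for (s in names(sites)) {
    opts <- config$samples[[s]] %||% list()
    m <- cgi_methylation(sites[[s]], cgis,
                         estimator = opts$estimator %||% "pooled_strand_averaged",
                         min_reads_per_site = opts$min_reads_per_site %||% 0L,
                         min_total_calls = min_total_calls,
                         lm_max = lm_max, hm_min = hm_min)
    methylation[[s]] <- m
    meth_long[[s]] <- data.frame(sample = s, m, stringsAsFactors = FALSE)
  }
  tsv(do.call(rbind, meth_long), "methylation.tsv")
  note("methylome", n = sum(vapply(methylation, nrow, integer(1))),
       excluded = sum(vapply(methylation, function(m) sum(m$label == "excluded"), integer(1))))

  ## --- stage 4: substitution rates -------------------------------------
  rates <- cgi_substitution_rates(cgis, aln, min_coverage = min_coverage)
  tsv(rates, "substitution_rates.tsv")
  note("subrates", n = nrow(rates), excluded_by_coverage = sum(rates$excluded))

  ## --- stage 5: stump --------------------------------------------------
  profiles <- build_cgi_profiles(classification, methylation, rates)
  sperm_label <- profiles[[paste0("label_", sperm_sample)]]
  in_fit <- sperm_label %in% c("HM", "LM") & !is.na(profiles$cpg_to_tpg_cpa)
  stump <- fit_stump(profiles$cpg_to_tpg_cpa[in_fit], droplevels(sperm_label[in_fit]))
  threshold <- config$fixed_threshold %||% stump$threshold
  stump_report <- list(
    fitted_threshold = stump$threshold,
    threshold_used = threshold,
    degenerate = stump$degenerate,
    n = stump$n,
    root = as.list(stump$root),
    counts = if (!stump$degenerate) apply(stump$counts, 1L, as.list, simplify = FALSE),
    weighted_gini = stump$weighted_gini,
    root_gini = stump$root_gini)
  jsonlite::write_json(stump_report, file.path(out_dir, "stump.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  if (!stump$degenerate && !is.na(threshold)) {
    leaf <- predict(stump, profiles$cpg_to_tpg_cpa)
    leaf <- as.character(leaf)
    leaf[is.na(leaf)] <- "excluded"
    profiles$stump_leaf <- leaf
    tsv(profiles[, c("cgi_id", "stump_leaf")], "stump_leaves.tsv")
  }
  note("stump", n = stump$n, degenerate = stump$degenerate,
       threshold = threshold %||% NA)

  ## --- stage 6: summaries ----------------------------------------------
  summaries <- list()
  summaries$position_label_counts <- position_label_counts(profiles, h1_sample)
  tsv(summaries$position_label_counts, "position_label_counts.tsv")
  summaries$crosstab <- methylation_crosstab(profiles, h1_sample, sperm_sample)
  tsv(summaries$crosstab, "crosstab.tsv")
  summaries$group_rate_summary <- group_rate_summary(
    profiles[sperm_label %in% c("HM", "LM"), , drop = FALSE],
    c("category", "coding", paste0("label_", sperm_sample)))
  tsv(.round_cols(summaries$group_rate_summary, c("mean", "sem")), "group_rate_summary.tsv")
  if (!is.na(threshold %||% NA)) {
    summaries$threshold_partition <- threshold_partition_report(
      profiles, threshold, h1_sample, sperm_sample)
    tsv(.round_cols(summaries$threshold_partition,
                    c("frac_below", "frac_below_sperm_lm")), "threshold_partition.tsv")
  }
  note("summaries", tables = length(summaries))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(profiles = profiles, classification = classification,
                 methylation = methylation, rates = rates, stump = stump,
                 threshold = threshold, summaries = summaries, manifest = manifest))
}

## Round reported fractions to 4 decimals for the emitted tables;
## in-memory results keep full precision.
.round_cols <- function(df, cols) {
  for (cl in intersect(cols, names(df))) df[[cl]] <- round(df[[cl]], 4L)
  df
}
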