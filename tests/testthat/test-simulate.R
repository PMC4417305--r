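test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 101, n_cgis_per_class = 2)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$sites, s2$sites)
  expect_identical(s1$aln$blocks, s2$aln$blocks)
  expect_identical(s1$truth, s2$truth)
  d1 <- tempfile(); d2 <- tempfile()
  dir.create(d1); dir.create(d2)
  write_maf(s1$aln, file.path(d1, "a.maf"))
  write_maf(s2$aln, file.path(d2, "a.maf"))
  expect_identical(readLines(file.path(d1, "a.maf")), readLines(file.path(d2, "a.maf")))
})

test_that("planted positional classes are recovered exactly by classification", {
  cfg <- sim_config(seed = 102, n_cgis_per_class = 5)
  gen <- simulate_genome(cfg)
  cl <- classify_cgis(gen$cgis, gen$genes, chrom_lengths = gen$chrom_lengths)
  expect_identical(as.character(cl$category), gen$truth$category)
  expect_identical(as.character(cl$coding), gen$truth$coding)
  # every class combination is populated
  expect_identical(nrow(unique(gen$truth[, c("category", "coding")])), 7L)
})

test_that("island CpG density lands within 3 sigma of the planted density", {
  cfg <- sim_config(seed = 103, n_cgis_per_class = 5)
  gen <- simulate_genome(cfg)
  n_slots <- sum(gen$cgis$end - gen$cgis$start) / 2
  d <- cfg$island_cpg_density
  expect_lt(abs(sum(gen$truth$n_cpg) / n_slots - d), 3 * sqrt(d * (1 - d) / n_slots))
  # planted CpG truth equals a direct scan of the emitted sequence
  i <- 1L
  sub <- substr(gen$genome[[gen$cgis$chrom[i]]], gen$cgis$start[i] + 1L, gen$cgis$end[i])
  expect_identical(lengths(regmatches(sub, gregexpr("CG", sub))), gen$truth$n_cpg[i])
})

test_that("zero branch probabilities leave both lineages identical to the ancestor", {
  cfg <- sim_config(seed = 104, n_cgis_per_class = 2)
  gen <- simulate_genome(cfg)
  zero <- lapply(cfg$branch_probs, function(p) p * 0)
  evo <- evolve_pair(gen$genome, gen$cgis, gen$truth$sperm_group, zero)
  expect_identical(evo$human, gen$genome)
  expect_identical(evo$chimp, gen$genome)
  r <- cgi_substitution_rates(gen$cgis, evo$aln)
  rv <- unlist(r[, c("cpg_to_tpg_cpa", "cpg_to_other", "tpg_cpa_to_cpg",
                     "other_to_cpg", "at_to_gc", "gc_to_at")])
  expect_true(all(rv[!is.na(rv)] == 0))
})

test_that("recorded truth counts equal an exact recount of the emitted alignment", {
  cfg <- sim_config(seed = 105, n_cgis_per_class = 3)
  gen <- simulate_genome(cfg)
  evo <- evolve_pair(gen$genome, gen$cgis, gen$truth$sperm_group, cfg$branch_probs)
  est <- cgi_substitution_rates(gen$cgis, evo$aln)
  for (cn in grep("^(anc|ev)_", names(evo$truth), value = TRUE)) {
    expect_identical(unname(est[[cn]]), unname(as.numeric(evo$truth[[cn]])))
  }
  # and the independent brute-force scanner agrees on a few CGIs
  for (i in 1:3) {
    cn <- gen$cgis$chrom[i]
    want <- oracle_count_events(gen$genome[[cn]], evo$human[[cn]], evo$chimp[[cn]],
                                gen$cgis$start[i], gen$cgis$end[i])
    got <- count_substitution_events(gen$cgis[i, ], evo$aln)
    expect_equal(got[names(want)], want)
  }
})

test_that("methylome simulation respects degenerate and low-coverage regimes", {
  cfg <- sim_config(seed = 106, n_cgis_per_class = 2)
  gen <- simulate_genome(cfg)
  sites <- simulate_methylome(gen$genome, gen$cgis, rep(0, nrow(gen$cgis)), 20)
  expect_true(all(sites$meth_calls == 0))
  expect_true(all(sites$unmeth_calls >= 1))   # zero-coverage rows dropped
  # near-zero coverage: most CGIs fail the five-call filter
  sparse <- simulate_methylome(gen$genome, gen$cgis, rep(0.5, nrow(gen$cgis)), 0.02)
  m <- cgi_methylation(sparse, gen$cgis)
  expect_gt(mean(m$label == "excluded"), 0.5)
})

test_that("methylation estimates recover planted levels and labels", {
  cfg <- sim_config(seed = 107, n_cgis_per_class = 4)
  gen <- simulate_genome(cfg)
  sites <- simulate_methylome(gen$genome, gen$cgis, gen$truth$true_meth_sperm, 30)
  m <- cgi_methylation(sites, gen$cgis)
  expect_true(all(!is.na(m$level)))
  err <- abs(m$level / 100 - gen$truth$true_meth_sperm)
  se <- sqrt(gen$truth$true_meth_sperm * (1 - gen$truth$true_meth_sperm) /
               pmax(m$n_calls, 1))
  expect_true(all(err < 3 * se + 0.01))
  expect_identical(as.character(m$label), gen$truth$sperm_group)
})

test_that("stump datasets carry truth: disjoint supports and degenerate classes", {
  sim <- simulate_stump_dataset(c(HM = 50, LM = 50),
                                list(LM = c(0, 0.02), HM = c(0.06, 0.1)), seed = 108)
  expect_equal(sim$truth$bayes_threshold, 0.04)
  fit <- fit_stump(sim$data$rate, sim$data$label)
  expect_gt(fit$threshold, 0.02)
  expect_lt(fit$threshold, 0.06)
  overlap <- simulate_stump_dataset(c(HM = 50, LM = 50),
                                    list(LM = c(0, 0.05), HM = c(0.02, 0.1)), seed = 109)
  expect_true(is.na(overlap$truth$bayes_threshold))
  onecls <- simulate_stump_dataset(c(HM = 0, LM = 20),
                                   list(LM = c(0, 0.05), HM = c(0.02, 0.1)), seed = 110)
  expect_true(fit_stump(onecls$data$rate, onecls$data$label)$degenerate)
})

test_that("indel stressor produces gapped rows that the counters handle", {
  cfg <- sim_config(seed = 111, n_cgis_per_class = 2, indel_rate = 0.1)
  gen <- simulate_genome(cfg)
  evo <- evolve_pair(gen$genome, gen$cgis, gen$truth$sperm_group, cfg$branch_probs,
                     indel_rate = cfg$indel_rate)
  b <- evo$aln$blocks[[1L]]
  expect_gt(lengths(regmatches(b$chimp, gregexpr("-", b$chimp, fixed = TRUE))), 0L)
  expect_gt(lengths(regmatches(b$ancestor, gregexpr("-", b$ancestor, fixed = TRUE))), 0L)
  # human row stays the ungapped anchor: full coverage, fewer opportunities
  expect_equal(cgi_alignment_coverage(gen$cgis[1, ], evo$aln), 1)
  r <- cgi_substitution_rates(gen$cgis, evo$aln)
  gapless <- cgi_substitution_rates(
    gen$cgis, evolve_pair(gen$genome, gen$cgis, gen$truth$sperm_group,
                          cfg$branch_probs, seed = 111)$aln)
  expect_true(all(r$anc_cpg <= gapless$anc_cpg | is.na(r$anc_cpg)))
  rv <- unlist(r[, c("cpg_to_tpg_cpa", "tpg_cpa_to_cpg", "at_to_gc")])
  expect_true(all(is.na(rv) | (rv >= 0 & rv <= 1)))
})
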