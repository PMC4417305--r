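toy_aln <- function(anc, hum, chp, chrom = "chr1", start = 0L) {
  triple_alignment(list(list(chrom = chrom, start = start,
                             human = hum, chimp = chp, ancestor = anc)))
}

toy_cgi <- function(start, end, chrom = "chr1") {
  list(cgi_id = "cgi_1", chrom = chrom, start = start, end = end)
}

test_that("event counting reproduces hand-enumerated examples", {
  # human TpG from an ancestral CpG; chimp unchanged
  cnt <- count_substitution_events(toy_cgi(0L, 4L), toy_aln("ACGT", "ATGT", "ACGT"))
  expect_equal(cnt[["anc_cpg"]], 1)
  expect_equal(cnt[["ev_cpg_to_tpg_cpa"]], 1)
  # CpA in both lineages: two events on one opportunity
  cnt <- count_substitution_events(toy_cgi(0L, 4L), toy_aln("ACGT", "ACAT", "ACAT"))
  expect_equal(cnt[["anc_cpg"]], 1)
  expect_equal(cnt[["ev_cpg_to_tpg_cpa"]], 2)
  # identity alignment: zero events everywhere, rates all 0
  cnt <- count_substitution_events(toy_cgi(0L, 8L),
                                   toy_aln("ACGTTGCA", "ACGTTGCA", "ACGTTGCA"))
  expect_true(all(cnt[grep("^ev_", names(cnt))] == 0))
  r <- rates_from_counts(cnt)
  expect_true(all(r[!is.na(r)] == 0))
  # TpG -> CpG fixation in one lineage
  cnt <- count_substitution_events(toy_cgi(0L, 3L), toy_aln("ATG", "ACG", "ATG"))
  expect_equal(cnt[["anc_tpg_cpa"]], 1)
  expect_equal(cnt[["ev_tpg_cpa_to_cpg"]], 1)
})

test_that("rates are events over twice the opportunities, NA when empty", {
  cnt <- count_substitution_events(toy_cgi(0L, 4L), toy_aln("ACGT", "ATGT", "ACGT"))
  r <- rates_from_counts(cnt)
  expect_equal(r[["cpg_to_tpg_cpa"]], 0.5)    # 1 / (2 * 1)
  cnt <- count_substitution_events(toy_cgi(0L, 4L), toy_aln("ATTT", "ATTT", "ATTT"))
  expect_true(is.na(rates_from_counts(cnt)[["cpg_to_tpg_cpa"]]))
})

test_that("single-base classes respect CpG context on the right sequence", {
  # ancestral A -> derived G that forms no CpG: counted for A/T -> G/C
  cnt <- count_substitution_events(toy_cgi(0L, 3L), toy_aln("TAT", "TGT", "TAT"))
  expect_equal(cnt[["ev_at_to_gc"]], 1)
  # derived C immediately before G: CpG context on the derived sequence, skipped
  cnt <- count_substitution_events(toy_cgi(0L, 3L), toy_aln("TAG", "TCG", "TAG"))
  expect_equal(cnt[["ev_at_to_gc"]], 0)
  expect_equal(cnt[["anc_at"]], 2)
  # ancestral G inside an ancestral CpG is no G/C -> A/T opportunity
  cnt <- count_substitution_events(toy_cgi(0L, 4L), toy_aln("ACGT", "ACAT", "ACGT"))
  expect_equal(cnt[["anc_gc_noncpg"]], 0)
  expect_equal(cnt[["ev_gc_to_at"]], 0)
  # ancestral G outside CpG context with derived A: counted
  cnt <- count_substitution_events(toy_cgi(0L, 3L), toy_aln("TGT", "TAT", "TGT"))
  expect_equal(cnt[["anc_gc_noncpg"]], 1)
  expect_equal(cnt[["ev_gc_to_at"]], 1)
})

test_that("gaps void lineage events and N voids both sides of the count", {
  # lineage gap in the second column of the dinucleotide: no event possible
  cnt <- count_substitution_events(toy_cgi(0L, 4L), toy_aln("ACGT", "AT-T", "ACGT"))
  expect_equal(cnt[["anc_cpg"]], 1)
  expect_equal(cnt[["ev_cpg_to_tpg_cpa"]], 0)
  # ancestor gap: no ancestral dinucleotide at those columns
  cnt <- count_substitution_events(toy_cgi(0L, 4L), toy_aln("AC-T", "ACGT", "ACGT"))
  expect_equal(cnt[["anc_cpg"]], 0)
  # N in the ancestor removes the opportunity
  cnt <- count_substitution_events(toy_cgi(0L, 4L), toy_aln("ACNT", "ATGT", "ACGT"))
  expect_equal(cnt[["anc_cpg"]], 0)
})

test_that("dinucleotides are attributed to the CGI by their first base", {
  # CpG with first base at the final CGI position: counted; at one past: not
  aln <- toy_aln("TTCGTT", "TTTGTT", "TTCGTT")
  expect_equal(count_substitution_events(toy_cgi(0L, 3L), aln)[["anc_cpg"]], 1)
  expect_equal(count_substitution_events(toy_cgi(0L, 3L), aln)[["ev_cpg_to_tpg_cpa"]], 1)
  expect_equal(count_substitution_events(toy_cgi(0L, 2L), aln)[["anc_cpg"]], 0)
  expect_equal(count_substitution_events(toy_cgi(3L, 6L), aln)[["anc_cpg"]], 0)
})

test_that("coverage filter removes CGIs under 50% and keeps exactly 50%", {
  # 200-base CGI, 80 aligned bases -> 0.4 -> excluded
  aln <- triple_alignment(list(list(chrom = "chr1", start = 0L,
    human = strrep("A", 80), chimp = strrep("A", 80), ancestor = strrep("A", 80))))
  cgis <- make_cgis("chr1", 0L, 200L)
  expect_equal(cgi_alignment_coverage(toy_cgi(0L, 200L), aln), 0.4)
  r <- cgi_substitution_rates(cgis, aln)
  expect_true(r$excluded)
  expect_true(is.na(r$cpg_to_tpg_cpa))
  # exactly 50% is retained
  cgis <- make_cgis("chr1", 0L, 160L)
  r <- cgi_substitution_rates(cgis, aln)
  expect_equal(r$coverage, 0.5)
  expect_false(r$excluded)
  # full coverage
  expect_equal(cgi_alignment_coverage(toy_cgi(0L, 80L), aln), 1)
})

test_that("column counting agrees with the brute-force scanner on random triples", {
  set.seed(501)
  for (rep in 1:200) {
    len <- sample(20:100, 1)
    tr <- random_triple(len, diverge = 0.15)
    start <- sample(0:(len %/% 2), 1)
    end <- sample((start + 5):len, 1)
    got <- count_substitution_events(toy_cgi(start, end),
                                     toy_aln(tr$anc, tr$hum, tr$chp))
    want <- oracle_count_events(tr$anc, tr$hum, tr$chp, start, end)
    expect_equal(got[names(want)], want)
  }
})

test_that("defined rates stay in [0,1] and events never exceed twice the opportunities", {
  set.seed(502)
  for (rep in 1:40) {
    tr <- random_triple(60, diverge = 0.4)
    cnt <- count_substitution_events(toy_cgi(0L, 60L), toy_aln(tr$anc, tr$hum, tr$chp))
    expect_lte(cnt[["ev_cpg_to_tpg_cpa"]] + cnt[["ev_cpg_to_other"]], 2 * cnt[["anc_cpg"]])
    expect_lte(cnt[["ev_tpg_cpa_to_cpg"]], 2 * cnt[["anc_tpg_cpa"]])
    expect_lte(cnt[["ev_other_to_cpg"]], 2 * cnt[["anc_other"]])
    expect_lte(cnt[["ev_at_to_gc"]], 2 * cnt[["anc_at"]])
    expect_lte(cnt[["ev_gc_to_at"]], 2 * cnt[["anc_gc_noncpg"]])
    r <- rates_from_counts(cnt)
    r <- r[!is.na(r)]
    expect_true(all(r >= 0 & r <= 1))
  }
})
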