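test_that("gene model parsing sets coding status and validates exon lists", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "name\tchrom\tstrand\ttxStart\ttxEnd\tcdsStart\tcdsEnd\texonStarts\texonEnds",
    "nc1\tchr1\t+\t100\t900\t500\t500\t100,600,\t200,900,",
    "cod1\tchr1\t+\t100\t900\t100\t900\t100,600,\t200,900,"
  ), tsv)
  genes <- read_gene_models(tsv)
  expect_identical(genes$coding, c(FALSE, TRUE))
  expect_identical(genes$exon_starts[[1L]], c(100L, 600L))

  writeLines(c(
    "name\tchrom\tstrand\ttxStart\ttxEnd\tcdsStart\tcdsEnd\texonStarts\texonEnds",
    "bad1\tchr1\t+\t100\t900\t100\t900\t100,600,\t200,"
  ), tsv)
  expect_error(read_gene_models(tsv), "bad1")

  writeLines("name\tchrom\tstrand\ttxStart\ttxEnd\tcdsStart\tcdsEnd\texonStarts\texonEnds", tsv)
  expect_identical(nrow(read_gene_models(tsv)), 0L)
})

test_that("classification windows follow transcription orientation and clamp at 0", {
  g_plus <- make_gene("gp", "chr1", "+", c(5000L), c(5200L))
  w <- five_prime_window(g_plus)
  expect_identical(c(w$start, w$end), c(2000L, 5200L))

  g_minus <- make_gene("gm", "chr1", "-", c(100L, 300L), c(200L, 400L))
  w <- five_prime_window(g_minus)  # first exon on '-' is (300,400)
  expect_identical(c(w$start, w$end), c(300L, 3400L))

  g_clamp <- make_gene("gc", "chr1", "+", c(1000L), c(1100L))
  w <- five_prime_window(g_clamp)
  expect_identical(c(w$start, w$end), c(0L, 1100L))

  g3 <- make_gene("g3", "chr1", "+", c(8000L, 9000L), c(8100L, 9500L))
  w <- three_prime_window(g3)
  expect_identical(c(w$start, w$end), c(9000L, 12500L))

  w <- three_prime_window(g_minus)  # final exon on '-' is (100,200), clamped
  expect_identical(c(w$start, w$end), c(0L, 200L))

  g_i <- make_gene("gi", "chr1", "+", c(100L, 500L, 900L), c(200L, 600L, 1000L))
  w <- intragenic_window(g_i)
  expect_identical(c(w$start, w$end), c(200L, 900L))
  expect_identical(nrow(intragenic_window(g_plus)), 0L)  # single exon: no introns
  g_2ex <- make_gene("g2", "chr1", "+", c(100L, 900L), c(200L, 1000L))
  w <- intragenic_window(g_2ex)
  expect_identical(c(w$start, w$end), c(200L, 900L))
})

test_that("CGI classification applies the 5' > 3' > intragenic > intergenic priority", {
  gA <- make_gene("A", "chr1", "+", c(10000L, 14000L, 18000L), c(10400L, 14400L, 18400L),
                  coding = FALSE)
  gB <- make_gene("B", "chr1", "+", c(2000L, 30000L), c(2400L, 30400L), coding = TRUE)
  genes <- make_genes(gA, gB)
  cgis <- make_cgis("chr1", c(9500L, 11000L, 31000L, 60000L), c(9900L, 11400L, 31400L, 60400L))
  cl <- classify_cgis(cgis, genes)
  # CGI 1 overlaps A's 5' window; CGI 2 the intragenic windows of both A
  # and B (so any-coding applies); CGI 3 only B's 3' window; CGI 4 nothing.
  expect_identical(as.character(cl$category),
                   c("five_prime", "intragenic", "three_prime", "intergenic"))
  expect_identical(as.character(cl$coding),
                   c("noncoding", "coding", "coding", "noncoding"))
  expect_identical(cl$associated_genes, c("A", "A,B", "B", ""))

  # a CGI overlapping one gene's 5' window and another's intragenic window
  # is five_prime, and coding comes from the triggering transcript set only
  cgis2 <- make_cgis("chr1", 11300L, 11700L)
  gC <- make_gene("C", "chr1", "+", c(11500L, 20000L), c(11600L, 20400L), coding = TRUE)
  cl2 <- classify_cgis(cgis2, make_genes(gA, gC))
  expect_identical(as.character(cl2$category), "five_prime")
  expect_identical(as.character(cl2$coding), "coding")   # C (coding) triggered 5'
  cl3 <- classify_cgis(cgis2, make_genes(gA))
  expect_identical(as.character(cl3$category), "intragenic")
})

test_that("classification agrees with exhaustive per-base enumeration", {
  set.seed(401)
  for (rep in 1:25) {
    n_genes <- sample(1:5, 1)
    genes <- do.call(make_genes, lapply(seq_len(n_genes), function(k) {
      n_ex <- sample(1:3, 1)
      es <- sort(sample(seq(0L, 9000L, by = 50L), n_ex))
      ee <- es + sample(c(50L, 100L), n_ex, replace = TRUE)
      while (any(utils::head(ee, -1) > utils::tail(es, -1))) {
        es <- sort(sample(seq(0L, 9000L, by = 50L), n_ex))
        ee <- es + sample(c(50L, 100L), n_ex, replace = TRUE)
      }
      make_gene(paste0("g", k), "chr1", sample(c("+", "-"), 1), es, ee,
                coding = sample(c(TRUE, FALSE), 1))
    }))
    s <- sample(seq(0L, 9500L, by = 10L), 4L)
    cgis <- make_cgis("chr1", s, s + sample(c(100L, 400L), 4L, replace = TRUE))
    cl <- classify_cgis(cgis, genes, flank = 3000L)
    for (i in seq_len(nrow(cgis))) {
      o <- oracle_classify(cgis[i, ], genes)
      expect_identical(as.character(cl$category[i]), o$category)
      expect_identical(as.character(cl$coding[i]), o$coding)
    }
  }
})

test_that("adding a 5'-window overlap never demotes a CGI from five_prime", {
  gA <- make_gene("A", "chr1", "+", c(10000L, 14000L), c(10400L, 14400L))
  cgis <- make_cgis("chr1", 10050L, 10450L)
  before <- classify_cgis(cgis, make_genes(gA))
  expect_identical(as.character(before$category), "five_prime")
  # pile on overlaps of every other window type
  gB <- make_gene("B", "chr1", "+", c(9000L, 20000L), c(9100L, 20400L))   # intragenic over CGI
  gC <- make_gene("C", "chr1", "+", c(9800L, 10030L), c(9900L, 10060L))   # 3' window over CGI
  after <- classify_cgis(cgis, make_genes(gA, gB, gC))
  expect_identical(as.character(after$category), "five_prime")
})

test_that("classification is invariant under coordinate mirroring with strand flip", {
  set.seed(402)
  G <- 10000L
  for (rep in 1:10) {
    genes <- do.call(make_genes, lapply(1:3, function(k) {
      es <- sort(sample(seq(0L, 9000L, by = 100L), 2L))
      ee <- es + 80L
      make_gene(paste0("g", k), "chr1", sample(c("+", "-"), 1), es, ee,
                coding = sample(c(TRUE, FALSE), 1))
    }))
    s <- sample(seq(0L, 9500L, by = 10L), 3L)
    cgis <- make_cgis("chr1", s, s + 200L)
    fwd <- classify_cgis(cgis, genes)
    mirror_genes <- do.call(make_genes, lapply(seq_len(nrow(genes)), function(k) {
      es <- rev(G - genes$exon_ends[[k]]); ee <- rev(G - genes$exon_starts[[k]])
      make_gene(genes$name[k], "chr1", if (genes$strand[k] == "+") "-" else "+",
                es, ee, coding = genes$coding[k])
    }))
    mirror_cgis <- make_cgis("chr1", G - cgis$end, G - cgis$start, id = cgis$cgi_id)
    rev_ <- classify_cgis(mirror_cgis, mirror_genes)
    expect_identical(as.character(fwd$category), as.character(rev_$category))
    expect_identical(as.character(fwd$coding), as.character(rev_$coding))
  }
})
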