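# direct-summation oracle, independent of pbinom
binom_tail_oracle <- function(n, N, p) {
  if (n == 0) return(1)
  m <- n:N
  sum(exp(lchoose(N, m) + m * log(p) + (N - m) * log1p(-p)))
}

test_that("binomial upper tail matches direct summation on random triples", {
  expect_equal(binom_upper_tail(0, 10, 0.3), 1)
  expect_equal(binom_upper_tail(10, 10, 0.3), 0.3^10)
  expect_equal(binom_upper_tail(5, 10, 0.1), binom_tail_oracle(5, 10, 0.1),
               tolerance = 1e-12)
  expect_equal(signif(binom_upper_tail(5, 10, 0.1), 5), 1.6349e-3)
  set.seed(77)
  for (i in 1:1000) {
    N <- sample.int(1000, 1)
    n <- sample.int(N + 1, 1) - 1L
    p <- runif(1, 0.001, 0.999)
    a <- binom_upper_tail(n, N, p)
    b <- binom_tail_oracle(n, N, p)
    expect_equal(a, b, tolerance = 1e-12 + 1e-12 * abs(b))
  }
  expect_error(binom_upper_tail(-1, 10, 0.5))
  expect_error(binom_upper_tail(5, 10, 0))
})

test_that("gene loci tile chromosomes with midpoint splits", {
  f <- tempfile(fileext = ".gtf")
  a1 <- 'gene_id "gA";'; a2 <- 'gene_id "gB";'
  writeLines(c(
    paste("chr1", "t", "gene", 1, 100, ".", "+", ".", a1, sep = "\t"),
    paste("chr1", "t", "exon", 1, 100, ".", "+", ".", a1, sep = "\t"),
    paste("chr1", "t", "gene", 201, 300, ".", "-", ".", a2, sep = "\t"),
    paste("chr1", "t", "exon", 201, 300, ".", "-", ".", a2, sep = "\t")
  ), f)
  gm <- read_gene_models(f)
  loci <- build_gene_loci(gm, c(chr1 = 400L))
  # gap [101,200] split at midpoint (100+201)/2 = 150
  expect_equal(GenomicRanges::start(loci), c(1L, 151L))
  expect_equal(GenomicRanges::end(loci), c(150L, 400L))
  expect_equal(sum(GenomicRanges::width(loci)), 400L)

  # a single gene owns its whole chromosome
  f2 <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr2", "t", "gene", 5000, 6000, ".", "+", ".", a1, sep = "\t"),
    paste("chr2", "t", "exon", 5000, 6000, ".", "+", ".", a1, sep = "\t")
  ), f2)
  loci2 <- build_gene_loci(read_gene_models(f2), c(chr2 = 20000L))
  expect_equal(GenomicRanges::start(loci2), 1L)
  expect_equal(GenomicRanges::end(loci2), 20000L)

  # larger random layout still tiles exactly and without overlap
  set.seed(12)
  starts <- sort(sample(seq(1000, 900000, by = 1000), 20))
  f3 <- tempfile(fileext = ".gtf")
  rows <- unlist(lapply(seq_along(starts), function(i) {
    at <- sprintf('gene_id "g%02d";', i)
    c(paste("chr3", "t", "gene", starts[i], starts[i] + 500, ".", "+", ".",
            at, sep = "\t"),
      paste("chr3", "t", "exon", starts[i], starts[i] + 500, ".", "+", ".",
            at, sep = "\t"))
  }))
  writeLines(rows, f3)
  loci3 <- build_gene_loci(read_gene_models(f3), c(chr3 = 1000000L))
  expect_equal(sum(GenomicRanges::width(loci3)), 1000000L)
  expect_equal(nrow(overlap_pairs(loci3, loci3)), length(loci3))  # self only
})

test_that("overlapping gene bodies merge into one locus with both ids", {
  f <- tempfile(fileext = ".gtf")
  a1 <- 'gene_id "gA";'; a2 <- 'gene_id "gB";'
  writeLines(c(
    paste("chr1", "t", "gene", 100, 300, ".", "+", ".", a1, sep = "\t"),
    paste("chr1", "t", "exon", 100, 300, ".", "+", ".", a1, sep = "\t"),
    paste("chr1", "t", "gene", 250, 500, ".", "-", ".", a2, sep = "\t"),
    paste("chr1", "t", "exon", 250, 500, ".", "-", ".", a2, sep = "\t")
  ), f)
  loci <- build_gene_loci(read_gene_models(f), c(chr1 = 1000L))
  expect_length(loci, 1)
  expect_true(grepl("gA", S4Vectors::mcols(loci)$gene_ids))
  expect_true(grepl("gB", S4Vectors::mcols(loci)$gene_ids))
})

test_that("susceptibility-locus merging keeps only enriched runs", {
  # toy genome of 2500 bp: chrX carries 4 gene loci of 250 bp; the
  # remaining variants sit outside every locus (rest of the genome)
  loci <- gr("chrX", c(1, 251, 501, 751), c(250, 500, 750, 1000))
  off_locus <- GenomicRanges::GRanges("chrY",
                                      IRanges::IRanges(c(100, 300, 500, 700),
                                                       width = 1))
  # adjacent loci 1+2 both carry variants -> one merged run of 6 variants
  # in 500/2500 = 0.2 of the genome: tail P(X>=6 | 10, 0.2) ~ 0.0064,
  # rejected at 0.003
  snvs <- suppressWarnings(c(GenomicRanges::GRanges(
    "chrX", IRanges::IRanges(c(10, 60, 110, 160, 210, 300), width = 1)),
    off_locus))
  p_run <- binom_tail_oracle(6, 10, 0.2)
  expect_gt(p_run, 0.003)
  expect_length(merge_susceptibility_loci(loci, snvs, 2500, 0.003), 0)

  # 5 variants concentrated in locus 1 alone: 250/2500 = 0.1 of the
  # genome, P ~ 1.63e-3 < 0.003 -> retained as a single-locus region
  snvs2 <- suppressWarnings(c(GenomicRanges::GRanges(
    "chrX", IRanges::IRanges(c(10, 60, 110, 160, 210, 990), width = 1)),
    off_locus))
  expect_equal(binom_tail_oracle(5, 10, 0.1), 1.6349e-3, tolerance = 1e-4)
  sus2 <- merge_susceptibility_loci(loci, snvs2, genome_size = 2500,
                                    p_cut = 0.003)
  expect_length(sus2, 1)
  expect_equal(GenomicRanges::start(sus2), 1L)
  expect_equal(GenomicRanges::end(sus2), 250L)
  expect_equal(S4Vectors::mcols(sus2)$n_adsnv, 5)
  # non-adjacent qualifying loci are never merged together: the variant in
  # locus 4 forms its own (rejected) run rather than extending locus 1's
  expect_false(any(GenomicRanges::end(sus2) > 250))

  # zero adSNVs -> empty result
  expect_length(merge_susceptibility_loci(loci, snvs2[0], 2500), 0)
})

test_that("locus classification follows the exclusive-enrichment rules", {
  locus <- gr("chrX", 1, 1000)
  genome_size <- 100000
  at <- function(n, lo = 1, hi = 1000) {
    GenomicRanges::GRanges("chrX", IRanges::IRanges(
      sample(lo:hi, n, replace = TRUE), width = 1))
  }
  far <- function(n) {
    GenomicRanges::GRanges("chrX", IRanges::IRanges(
      sample(50000:99000, n, replace = TRUE), width = 1))
  }
  set.seed(31)
  # silencer variants concentrated in the locus, enhancers elsewhere
  sl <- classify_locus(locus, c(at(30), far(70)), far(100), genome_size)
  expect_equal(sl$klass, "SL")
  expect_lt(sl$p_s, 0.005)
  expect_gt(sl$p_e, 0.005)
  en <- classify_locus(locus, far(100), c(at(30), far(70)), genome_size)
  expect_equal(en$klass, "EN")
  both <- classify_locus(locus, c(at(30), far(70)), c(at(30), far(70)),
                         genome_size)
  expect_equal(both$klass, "ENSL")
  uc <- classify_locus(locus, far(100), far(100), genome_size)
  expect_equal(uc$klass, "UC")
  # promoter/exon annotation
  ep <- classify_locus(locus, far(100), far(100), genome_size,
                       n_ad_locus = 50, n_ep_locus = 30, gamma0 = 0.1)
  expect_true(ep$ep_enriched)
  expect_equal(ep$p_ep, binom_tail_oracle(30, 50, 0.1), tolerance = 1e-10)
})

test_that("locus classification is invariant to coordinate shifts", {
  set.seed(44)
  genome_size <- 100000
  pos_s <- sample(1:1000, 25, TRUE)
  pos_e <- sample(30000:99000, 200, TRUE)
  mk <- function(p, shift = 0) {
    GenomicRanges::GRanges("chrX", IRanges::IRanges(p + shift, width = 1))
  }
  locus <- gr("chrX", 1, 1000)
  a <- classify_locus(locus, mk(pos_s), mk(pos_e), genome_size)
  shift <- 500
  b <- classify_locus(GenomicRanges::shift(locus, shift),
                      mk(pos_s, shift), mk(pos_e, shift), genome_size)
  expect_equal(a$p_s, b$p_s)
  expect_equal(a$klass, b$klass)
  # and to variant ordering
  cc <- classify_locus(locus, mk(rev(pos_s)), mk(sample(pos_e)), genome_size)
  expect_equal(a$p_s, cc$p_s)
  expect_equal(a$p_e, cc$p_e)
})

test_that("disease overlap and enrichment statistics", {
  ids <- sprintf("v%02d", 1:20)
  dis <- c(ids[1:8], "other1", "other2")
  ov <- disease_overlap(ids, dis, w_d = 0.05)
  expect_equal(ov$Q, 20L)
  expect_equal(ov$q, 8L)
  expect_equal(ov$p, binom_tail_oracle(8, 20, 0.05), tolerance = 1e-10)
  expect_true(ov$significant)
  # q = 0 -> tail is 1; Q = 0 -> undefined, flagged
  expect_equal(disease_overlap(ids, "none", 0.05)$p, 1)
  expect_true(is.na(disease_overlap(character(0), dis, 0.05)$p))
  # q = Q closed form
  expect_equal(disease_overlap(ids[1:3], ids[1:3], 0.05)$p, 0.05^3)
  expect_error(disease_overlap(ids, dis, 1.5), "w_d")

  # two-sided enrichment against a background rate
  ev <- enrichment_vs_background(10, 10, 50, 100)
  expect_equal(ev$fold, 2)
  expect_equal(ev$p, binom.test(10, 10, 0.5)$p.value)
  expect_equal(ev$p, 2 * 0.5^10, tolerance = 1e-12)
  # null case: equal rates give fold 1 and a large p
  ev0 <- enrichment_vs_background(50, 100, 500, 1000)
  expect_equal(ev0$fold, 1)
  expect_gt(ev0$p, 0.9)
  # fold is scale invariant
  expect_equal(enrichment_vs_background(20, 40, 100, 400)$fold,
               enrichment_vs_background(40, 80, 200, 800)$fold)
  expect_true(enrichment_vs_background(5, 10, 0, 100)$pseudocount)
})
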