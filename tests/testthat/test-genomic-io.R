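test_that("BED parsing sorts, converts coordinates and validates rows", {
  f <- write_bed3(c("chr2\t0\t100", "chr1\t500\t700", "chr1\t50\t150"))
  ps <- read_intervals(f, "bed3")
  expect_length(ps, 3)
  expect_equal(as.character(GenomicRanges::seqnames(ps)),
               c("chr1", "chr1", "chr2"))
  expect_equal(GenomicRanges::start(ps), c(51, 501, 1))  # 0-based -> 1-based
  expect_equal(GenomicRanges::end(ps), c(150, 700, 100))

  bad <- write_bed3(c("chr1\t10\t20", "chr1\t500\t400"))
  expect_error(read_intervals(bad, "bed3"), "line 2")
})

test_that("narrowPeak dialect keeps the summit and bed6 fields", {
  f <- write_bed3("chr1\t100\t400\tpeak1\t17\t+\t5.5\t3.2\t2.1\t75")
  np <- read_intervals(f, "narrowpeak")
  expect_equal(S4Vectors::mcols(np)$summit, 75L)
  expect_equal(S4Vectors::mcols(np)$name, "peak1")
  expect_equal(as.character(GenomicRanges::strand(np)), "+")
  expect_error(read_intervals(f, "unknown"))
  # a bed3 file can't satisfy the narrowPeak column count
  f3 <- write_bed3("chr1\t100\t400")
  expect_error(read_intervals(f3, "narrowpeak"), "columns")
})

test_that("write/read round trip reproduces BED coordinates exactly", {
  set.seed(42)
  starts <- sort(sample.int(1e6, 50))
  rows <- sprintf("chr%d\t%d\t%d", sample(1:3, 50, TRUE), starts,
                  starts + sample.int(5000, 50))
  f <- write_bed3(rows)
  ps <- read_intervals(f, "bed3")
  f2 <- tempfile(fileext = ".bed")
  write_intervals(ps, f2, "bed3")
  ps2 <- read_intervals(f2, "bed3")
  expect_identical(GenomicRanges::start(ps), GenomicRanges::start(ps2))
  expect_identical(GenomicRanges::end(ps), GenomicRanges::end(ps2))
  expect_identical(as.character(GenomicRanges::seqnames(ps)),
                   as.character(GenomicRanges::seqnames(ps2)))
})

test_that("gene models collapse transcripts, merge exons and place the TSS", {
  gm <- read_gene_models(tiny_gtf())
  expect_length(gm$genes, 2)
  g1 <- gm$genes[S4Vectors::mcols(gm$genes)$gene_id == "g1"]
  g2 <- gm$genes[S4Vectors::mcols(gm$genes)$gene_id == "g2"]
  # plus strand: TSS at gene start; minus strand: at gene end
  expect_equal(S4Vectors::mcols(g1)$tss, 1001L)
  expect_equal(S4Vectors::mcols(g2)$tss, 6000L)
  # overlapping exons [1001,1100] and [1051,1150] merge
  ex1 <- gm$exons[["g1"]]
  expect_equal(GenomicRanges::start(ex1), c(1001L, 1901L))
  expect_equal(GenomicRanges::end(ex1), c(1150L, 2000L))

  # exon outside the gene body is rejected
  f <- tempfile(fileext = ".gtf")
  a <- 'gene_id "g1";'
  writeLines(c(
    paste("chrT", "t", "gene", 1000, 2000, ".", "+", ".", a, sep = "\t"),
    paste("chrT", "t", "exon", 500, 900, ".", "+", ".", a, sep = "\t")
  ), f)
  expect_error(read_gene_models(f), "outside")
})

test_that("window extraction is exact, uppercased, and edge-checked", {
  genome <- Biostrings::DNAStringSet(c(chrA = paste(rep("acgt", 250),
                                                    collapse = "")))
  # whole-chromosome window: length-1000 chromosome, 0-based centre 500
  s <- extract_window(genome, "chrA", 500, 1000)
  expect_equal(nchar(s), 1000)
  expect_equal(s, toupper(paste(rep("acgt", 250), collapse = "")))
  expect_error(extract_window(genome, "chrA", 100, 1000), "edge")
  expect_error(extract_window(genome, "chrB", 500, 100), "chromosome")

  # a specific centre: the returned window midpoint must be the centre
  genome2 <- Biostrings::DNAStringSet(c(chrB = rand_seq(5000)))
  w <- extract_window(genome2, "chrB", 2500, 10)
  expect_equal(w, toupper(as.character(Biostrings::subseq(genome2[["chrB"]],
                                                          2496, 2505))))
})

test_that("overlap_pairs respects half-open adjacency and min_bp", {
  a <- gr("chr1", c(1, 1), c(100, 1000))
  b <- gr("chr1", c(101, 301), c(200, 900))
  # [0,100) vs [100,200): book-ended, no overlap
  ov <- overlap_pairs(a[1], b[1])
  expect_equal(nrow(ov), 0)
  # overlap of 600 bp: excluded at min_bp = 601, included at 600
  expect_equal(nrow(overlap_pairs(a[2], b[2], min_bp = 601)), 0)
  ov2 <- overlap_pairs(a[2], b[2], min_bp = 600)
  expect_equal(ov2$overlap_bp, 600)
  # self-overlap pairs every interval with itself
  self <- overlap_pairs(a, a)
  expect_true(all(seq_along(a) %in% self$query[self$query == self$subject]))
})

test_that("overlap_pairs agrees with a brute-force scan on random sets", {
  set.seed(11)
  for (rep in 1:3) {
    n <- 150
    mk <- function() {
      st <- sample.int(20000, n, replace = TRUE)
      gr(sample(c("c1", "c2"), n, TRUE), st, st + sample.int(500, n, TRUE))
    }
    a <- mk(); b <- mk()
    ov <- overlap_pairs(a, b, min_bp = 1)
    brute <- 0L
    for (i in seq_along(a)) {
      for (j in seq_along(b)) {
        if (as.character(GenomicRanges::seqnames(a))[i] !=
            as.character(GenomicRanges::seqnames(b))[j]) next
        o <- min(GenomicRanges::end(a)[i], GenomicRanges::end(b)[j]) -
          max(GenomicRanges::start(a)[i], GenomicRanges::start(b)[j]) + 1L
        if (o >= 1L) brute <- brute + 1L
      }
    }
    expect_equal(nrow(ov), brute)
    # symmetry in content
    ov_t <- overlap_pairs(b, a, min_bp = 1)
    expect_setequal(paste(ov$query, ov$subject), paste(ov_t$subject, ov_t$query))
  }
})

test_that("variant TSV round trip and validation", {
  v <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 200), width = 1))
  S4Vectors::mcols(v)$id <- c("v1", "v2")
  S4Vectors::mcols(v)$ref <- c("A", "C")
  S4Vectors::mcols(v)$alt <- c("G", "T")
  S4Vectors::mcols(v)$assoc_p <- c(1e-8, 1e-6)
  f <- tempfile(fileext = ".tsv")
  write_variants(v, f)
  v2 <- read_variants(f, "tsv")
  expect_equal(GenomicRanges::start(v2), c(100, 200))
  expect_equal(S4Vectors::mcols(v2)$alt, c("G", "T"))
  # invalid rows (ref == alt, non-ACGT) are dropped
  writeLines(c("id\tchrom\tpos\tref\talt\tassoc_p",
               "v1\tchr1\t10\tA\tA\t0.001",
               "v2\tchr1\t20\tN\tC\t0.001",
               "v3\tchr1\t30\tG\tT\t0.001"), f)
  expect_length(read_variants(f, "tsv"), 1)
})

test_that("VCF input keeps SNVs only", {
  skip_if_not_installed("VariantAnnotation")
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=10000>",
    '##INFO=<ID=ASSOC_P,Number=1,Type=Float,Description="association p">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\trs1\tA\tG\t.\t.\tASSOC_P=1e-6",
    "chr1\t200\trs2\tAT\tA\t.\t.\tASSOC_P=1e-6",
    "chr1\t300\trs3\tC\tT\t.\t.\tASSOC_P=1e-7"
  ), f)
  v <- read_variants(f, "vcf")
  expect_length(v, 2)
  expect_equal(S4Vectors::mcols(v)$id, c("rs1", "rs3"))
  expect_equal(S4Vectors::mcols(v)$assoc_p, c(1e-6, 1e-7))
})
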