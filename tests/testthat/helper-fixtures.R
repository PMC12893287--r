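# Shared fixture builders: everything is generated in code at test time.

gr <- function(chrom, start, end, ...) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  extra <- list(...)
  for (nm in names(extra)) S4Vectors::mcols(g)[[nm]] <- extra[[nm]]
  g
}

write_bed3 <- function(rows) {
  f <- tempfile(fileext = ".bed")
  writeLines(rows, f)
  f
}

# random sequence of length L over ACGT
rand_seq <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# a tiny two-gene GTF on one chromosome
tiny_gtf <- function() {
  f <- tempfile(fileext = ".gtf")
  a1 <- 'gene_id "g1"; gene_name "GENE1";'
  a2 <- 'gene_id "g2"; gene_name "GENE2";'
  writeLines(c(
    paste("chrT", "test", "gene", 1001, 2000, ".", "+", ".", a1, sep = "\t"),
    paste("chrT", "test", "exon", 1001, 1100, ".", "+", ".", a1, sep = "\t"),
    paste("chrT", "test", "exon", 1051, 1150, ".", "+", ".", a1, sep = "\t"),
    paste("chrT", "test", "exon", 1901, 2000, ".", "+", ".", a1, sep = "\t"),
    paste("chrT", "test", "gene", 5001, 6000, ".", "-", ".", a2, sep = "\t"),
    paste("chrT", "test", "exon", 5001, 5100, ".", "-", ".", a2, sep = "\t"),
    paste("chrT", "test", "exon", 5901, 6000, ".", "-", ".", a2, sep = "\t")
  ), f)
  f
}

# small trained-model cache shared across test files (built lazily)
.silens_test_env <- new.env(parent = emptyenv())
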