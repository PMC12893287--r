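#' Read genomic intervals from BED-family files
#'
#' Parses BED3, BED6 or ENCODE narrowPeak (BED6+4) text into a sorted
#' [GenomicRanges::GRanges]. Coordinates in the files are 0-based half-open
#' (BED convention) and are converted to the 1-based closed convention of
#' `GRanges` on read; [write_intervals()] converts back, so a read/write
#' round trip reproduces the file coordinates exactly.
#'
#' @param path Path to a tab- or space-separated BED-family file.
#' @param dialect One of `"bed3"`, `"bed6"`, `"narrowpeak"`.
#' @param source Optional label (assay/sample) stored as metadata.
#' @return A sorted `GRanges`. BED6 adds `name`, `score`, strand; narrowPeak
#'   additionally `signalValue`, `pValue`, `qValue` and `summit` (the peak
#'   summit offset from the interval start, `-1` when absent).
#' @details Rows with `start >= end` or negative `start` raise an error that
#'   names the offending line.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines(c("chr2\t0\t100", "chr1\t50\t150"), f)
#' read_intervals(f, "bed3")
#' @export
read_intervals <- function(path, dialect = c("bed3", "bed6", "narrowpeak"),
                           source = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  ncol_needed <- switch(dialect, bed3 = 3L, bed6 = 6L, narrowpeak = 10L)
  df <- read.table(path, header = FALSE, sep = "", comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < ncol_needed) {
    stop(sprintf("dialect '%s' needs >= %d columns, file has %d",
                 dialect, ncol_needed, ncol(df)))
  }
  df[[1]] <- as.character(df[[1]])
  df[[2]] <- as.integer(df[[2]])
  df[[3]] <- as.integer(df[[3]])
  bad <- which(df[[2]] >= df[[3]] | df[[2]] < 0)
  if (length(bad)) {
    stop(sprintf("invalid interval (start >= end or start < 0) at line %d: %s %d %d",
                 bad[1], df[[1]][bad[1]], df[[2]][bad[1]], df[[3]][bad[1]]))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = df[[1]],
    ranges = IRanges::IRanges(start = df[[2]] + 1L, end = df[[3]]),
    strand = if (ncol_needed >= 6L) {
      ifelse(df[[6]] %in% c("+", "-"), df[[6]], "*")
    } else "*"
  )
  if (ncol_needed >= 6L) {
    S4Vectors::mcols(gr)$name <- as.character(df[[4]])
    S4Vectors::mcols(gr)$score <- suppressWarnings(as.numeric(df[[5]]))
  }
  if (dialect == "narrowpeak") {
    S4Vectors::mcols(gr)$signalValue <- as.numeric(df[[7]])
    S4Vectors::mcols(gr)$pValue <- as.numeric(df[[8]])
    S4Vectors::mcols(gr)$qValue <- as.numeric(df[[9]])
    S4Vectors::mcols(gr)$summit <- as.integer(df[[10]])
  }
  S4Vectors::metadata(gr)$source <- source
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write intervals to a BED-family file
#'
#' Inverse of [read_intervals()]: converts the 1-based closed `GRanges`
#' coordinates back to 0-based half-open BED coordinates.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param dialect `"bed3"`, `"bed6"` or `"narrowpeak"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(gr, path, dialect = c("bed3", "bed6", "narrowpeak")) {
  dialect <- match.arg(dialect)
  m <- S4Vectors::mcols(gr)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (dialect %in% c("bed6", "narrowpeak")) {
    df$name <- if (!is.null(m$name)) m$name else "."
    df$score <- if (!is.null(m$score) && !all(is.na(m$score))) m$score else 0
    s <- as.character(GenomicRanges::strand(gr))
    df$strand <- ifelse(s == "*", ".", s)
  }
  if (dialect == "narrowpeak") {
    df$signalValue <- if (!is.null(m$signalValue)) m$signalValue else 0
    df$pValue <- if (!is.null(m$pValue)) m$pValue else -1
    df$qValue <- if (!is.null(m$qValue)) m$qValue else -1
    df$summit <- if (!is.null(m$summit)) m$summit else -1L
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Collapses a GTF annotation to one model per `gene_id`: the gene body is
#' the union span over all gene records of that id, exons are merged across
#' transcripts, and the transcription start site (TSS) is strand-aware
#' (the gene-body start on `+`, the gene-body end on `-`; 1-based).
#'
#' @param path Path to a GTF file with `gene` and `exon` features carrying
#'   `gene_id` attributes.
#' @return A `silens_genes` object: list with
#'   * `genes`: `GRanges` of gene bodies with `gene_id`, `symbol`, `tss`;
#'   * `exons`: `GRangesList` of merged exons, one element per gene.
#' @export
read_gene_models <- function(path) {
  gtf <- rtracklayer::import(path, format = "gtf")
  ty <- S4Vectors::mcols(gtf)$type
  genes <- gtf[ty == "gene"]
  exons <- gtf[ty == "exon"]
  if (length(genes) == 0L) stop("GTF contains no 'gene' features")
  if (any(as.character(GenomicRanges::strand(genes)) == "*")) {
    stop("gene feature with missing strand in ", path)
  }
  ids <- unique(S4Vectors::mcols(genes)$gene_id)
  gene_span <- lapply(ids, function(id) {
    g <- genes[S4Vectors::mcols(genes)$gene_id == id]
    GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(g)[1],
      ranges = IRanges::IRanges(min(GenomicRanges::start(g)),
                                max(GenomicRanges::end(g))),
      strand = GenomicRanges::strand(g)[1]
    )
  })
  body <- do.call(c, gene_span)
  symbols <- vapply(ids, function(id) {
    g <- genes[S4Vectors::mcols(genes)$gene_id == id]
    nm <- S4Vectors::mcols(g)$gene_name
    if (is.null(nm) || all(is.na(nm))) id else nm[1]
  }, character(1))
  strand_chr <- as.character(GenomicRanges::strand(body))
  tss <- ifelse(strand_chr == "+", GenomicRanges::start(body),
                GenomicRanges::end(body))
  S4Vectors::mcols(body)$gene_id <- ids
  S4Vectors::mcols(body)$symbol <- unname(symbols)
  S4Vectors::mcols(body)$tss <- as.integer(tss)
  ex_by_gene <- lapply(seq_along(ids), function(i) {
    ex <- exons[S4Vectors::mcols(exons)$gene_id == ids[i]]
    if (length(ex) == 0L) {
      return(GenomicRanges::GRanges())
    }
    if (any(GenomicRanges::start(ex) < GenomicRanges::start(body)[i]) ||
        any(GenomicRanges::end(ex) > GenomicRanges::end(body)[i])) {
      stop("exon outside gene body for gene ", ids[i])
    }
    GenomicRanges::reduce(GenomicRanges::granges(ex))
  })
  exl <- GenomicRanges::GRangesList(ex_by_gene)
  names(exl) <- ids
  structure(list(genes = body, exons = exl), class = "silens_genes")
}

#' @export
print.silens_genes <- function(x, ...) {
  cat(sprintf("<silens_genes> %d genes on %d chromosome(s)\n",
              length(x$genes),
              length(unique(as.character(GenomicRanges::seqnames(x$genes))))))
  invisible(x)
}

#' Promoter windows of a gene set
#'
#' @param genes A `silens_genes` object.
#' @param flank Half-width of the promoter window around the TSS, in bp.
#'   The input files never fix a promoter extent; the conventional
#'   TSS +/- 1 kb default is used and is configurable.
#' @return `GRanges` of promoter windows (clipped at position 1).
#' @export
promoter_regions <- function(genes, flank = 1000L) {
  g <- genes$genes
  tss <- S4Vectors::mcols(g)$tss
  GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(g),
    ranges = IRanges::IRanges(start = pmax(1L, tss - as.integer(flank)),
                              end = tss + as.integer(flank))
  )
}

#' Read single-nucleotide variants
#'
#' Reads either the package's TSV variant dialect (columns `id`, `chrom`,
#' `pos` 1-based, `ref`, `alt`, `assoc_p`) or a VCF. Non-SNV records
#' (indels, multi-allelic sites) are skipped with a logged count. `assoc_p`
#' is the minimum association p-value of the variant across studies.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"vcf"`.
#' @return A width-1 `GRanges` with metadata columns `id`, `ref`, `alt`,
#'   `assoc_p`.
#' @export
read_variants <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, comment.char = "#")
    need <- c("id", "chrom", "pos", "ref", "alt", "assoc_p")
    if (!all(need %in% names(df))) {
      stop("variant TSV must have columns: ", paste(need, collapse = ", "))
    }
  } else {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
      stop("reading VCF requires the VariantAnnotation package")
    }
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(VariantAnnotation::ref(vcf))
    altl <- VariantAnnotation::alt(vcf)
    alt1 <- vapply(seq_along(altl), function(i) {
      a <- as.character(altl[[i]])
      if (length(a) == 1L) a else ""
    }, character(1))
    snv <- nchar(ref) == 1L & nchar(alt1) == 1L &
      ref %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T")
    if (any(!snv)) {
      silens_log(sum(!snv), " non-SNV record(s) skipped while reading ", path)
    }
    info <- VariantAnnotation::info(vcf)
    p <- if ("ASSOC_P" %in% names(info)) as.numeric(info$ASSOC_P) else NA_real_
    df <- data.frame(
      id = names(rr), chrom = as.character(GenomicRanges::seqnames(rr)),
      pos = GenomicRanges::start(rr), ref = ref, alt = alt1,
      assoc_p = p, stringsAsFactors = FALSE
    )[snv, , drop = FALSE]
  }
  ok <- df$ref %in% c("A", "C", "G", "T") & df$alt %in% c("A", "C", "G", "T") &
    df$ref != df$alt
  if (any(!ok)) {
    silens_log(sum(!ok), " invalid variant row(s) dropped from ", path)
    df <- df[ok, , drop = FALSE]
  }
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$pos, width = 1L)
  )
  S4Vectors::mcols(gr)$id <- as.character(df$id)
  S4Vectors::mcols(gr)$ref <- df$ref
  S4Vectors::mcols(gr)$alt <- df$alt
  S4Vectors::mcols(gr)$assoc_p <- as.numeric(df$assoc_p)
  gr
}

#' Write variants in the package TSV dialect
#' @param variants Width-1 `GRanges` with `id`, `ref`, `alt`, `assoc_p`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  m <- S4Vectors::mcols(variants)
  df <- data.frame(
    id = m$id,
    chrom = as.character(GenomicRanges::seqnames(variants)),
    pos = GenomicRanges::start(variants),
    ref = m$ref, alt = m$alt, assoc_p = m$assoc_p,
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract a fixed-length sequence window around a position
#'
#' @param genome A named [Biostrings::DNAStringSet] (one entry per
#'   chromosome) or a path to a FASTA file.
#' @param chrom Chromosome name.
#' @param center Window midpoint as a 0-based position: the window covers
#'   `[center - length/2, center + length/2)` in 0-based half-open
#'   coordinates (so a length-1000 chromosome is returned whole for
#'   `center = 500`). Interval midpoints computed as
#'   `floor((start0 + end0) / 2)` plug in directly.
#' @param length Window length in bp (default 1000).
#' @return Uppercase character string of exactly `length` bases. Soft-masked
#'   (lowercase) input is uppercased; characters outside A/C/G/T are kept
#'   (typically `N`) and handled at one-hot encoding.
#' @details Windows crossing a chromosome edge raise an error; callers drop
#'   such elements with a logged warning rather than padding with fabricated
#'   sequence.
#' @export
extract_window <- function(genome, chrom, center, length = 1000L) {
  genome <- as_genome(genome)
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  half <- as.integer(length) %/% 2L
  start1 <- as.integer(center) - half + 1L   # 1-based inclusive
  end1 <- start1 + as.integer(length) - 1L
  L <- Biostrings::width(genome[chrom])
  if (start1 < 1L || end1 > L) {
    stop(sprintf("window [%d,%d] crosses the edge of %s (length %d)",
                 start1, end1, chrom, L))
  }
  toupper(as.character(Biostrings::subseq(genome[[chrom]], start1, end1)))
}

#' @noRd
as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  genome
}

#' Extract 1-kb window sequences for a set of intervals
#'
#' Windows are recentred at each interval midpoint
#' (`floor((start0 + end0) / 2)` in 0-based coordinates) and extracted with
#' [extract_window()]. Intervals whose window would cross a chromosome edge
#' are dropped with a logged count.
#'
#' @param genome Genome as in [extract_window()].
#' @param gr `GRanges` of intervals.
#' @param length Window length.
#' @return List with `seqs` (character vector) and `keep` (logical index of
#'   retained intervals).
#' @export
window_sequences <- function(genome, gr, length = 1000L) {
  genome <- as_genome(genome)
  mid0 <- midpoint0(gr)
  half <- as.integer(length) %/% 2L
  chroms <- as.character(GenomicRanges::seqnames(gr))
  L <- setNames(Biostrings::width(genome), names(genome))
  keep <- chroms %in% names(genome) &
    (mid0 - half) >= 0L & (mid0 + half) <= L[chroms]
  keep[is.na(keep)] <- FALSE
  if (any(!keep)) {
    silens_log(sum(!keep), " window(s) dropped at chromosome edges",
               level = "WARN")
  }
  seqs <- vapply(which(keep), function(i) {
    extract_window(genome, chroms[i], mid0[i], length)
  }, character(1))
  list(seqs = unname(seqs), keep = keep)
}

# 0-based midpoint of 1-based closed intervals: floor((start0 + end0)/2)
#' @noRd
midpoint0 <- function(gr) {
  (GenomicRanges::start(gr) - 1L + GenomicRanges::end(gr)) %/% 2L
}

#' Recentre intervals as fixed-width windows at their midpoints
#'
#' @param gr `GRanges`.
#' @param width Window width (default 1000).
#' @return `GRanges` of equal-width windows; metadata columns are kept and a
#'   `midpoint` column (0-based) is added.
#' @export
window_at_midpoint <- function(gr, width = 1000L) {
  mid0 <- midpoint0(gr)
  half <- as.integer(width) %/% 2L
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges = IRanges::IRanges(start = mid0 - half + 1L,
                              width = as.integer(width)),
    strand = GenomicRanges::strand(gr)
  )
  S4Vectors::mcols(out) <- S4Vectors::mcols(gr)
  S4Vectors::mcols(out)$midpoint <- mid0
  out
}

#' Overlapping interval pairs between two sets
#'
#' Thin wrapper around [GenomicRanges::findOverlaps()] reporting the number
#' of overlapping bases per pair. Overlap is computed on the half-open/BED
#' interpretation: book-ended intervals (one ending where the next starts)
#' do not overlap.
#'
#' @param a,b `GRanges`.
#' @param min_bp Minimum overlap in bp for a pair to be reported.
#' @return `data.frame` with `query` (index in `a`), `subject` (index in
#'   `b`), `overlap_bp`.
#' @export
overlap_pairs <- function(a, b, min_bp = 1L) {
  hits <- GenomicRanges::findOverlaps(a, b, minoverlap = as.integer(min_bp),
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    GenomicRanges::granges(a)[qi], GenomicRanges::granges(b)[si],
    ignore.strand = TRUE))
  data.frame(query = qi, subject = si, overlap_bp = ov)
}
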