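#' Call candidate enhancer and silencer elements for one sample
#'
#' Applies the peak-overlap rules defining candidate regulatory elements:
#'
#' * **Enhancer**: a DNase peak overlapping any H3K27ac peak (>= 1 bp) with
#'   no H3K27me3 peak intersecting the 400-bp window centred on the DNase
#'   peak midpoint.
#' * **Silencer**: a DNase peak overlapping an H3K27me3 peak (>= 1 bp,
#'   whole-peak) with no H3K27ac peak in the central 400 bp, together with
#'   H3K27me3 peaks overlapping neither DNase nor H3K27ac peaks.
#'
#' Every element is re-windowed to 1 kb about its midpoint. Windows
#' overlapping a promoter (TSS +/- `promoter_flank`) or an exon of any gene
#' in `genes` are removed, as are windows crossing a chromosome edge (when
#' `seqlengths` are available), with logged counts.
#'
#' @param dnase,ac,me3 `GRanges` peak sets (DNase-seq, H3K27ac, H3K27me3)
#'   from the same sample.
#' @param genes A `silens_genes` object, or `NULL` to skip the
#'   promoter/exon exclusion.
#' @param sample_id Label recorded per element.
#' @param promoter_flank Promoter half-width in bp (default 1000).
#' @param seqlengths Optional named vector of chromosome lengths used to
#'   drop edge-crossing windows.
#' @param central_bp Width of the central exclusion window (default 400).
#' @return `GRanges` of 1-kb windows with metadata `klass`
#'   (`"enhancer"`/`"silencer"`), `sample_id`, `midpoint`.
#' @export
call_candidates <- function(dnase, ac, me3, genes = NULL,
                            sample_id = "sample1", promoter_flank = 1000L,
                            seqlengths = NULL, central_bp = 400L) {
  central <- window_at_midpoint(dnase, width = central_bp)
  has_ac_any <- GenomicRanges::countOverlaps(dnase, ac, minoverlap = 1L,
                                             ignore.strand = TRUE) > 0L
  has_me3_any <- GenomicRanges::countOverlaps(dnase, me3, minoverlap = 1L,
                                              ignore.strand = TRUE) > 0L
  me3_central <- GenomicRanges::countOverlaps(central, me3, minoverlap = 1L,
                                              ignore.strand = TRUE) > 0L
  ac_central <- GenomicRanges::countOverlaps(central, ac, minoverlap = 1L,
                                             ignore.strand = TRUE) > 0L

  enh <- dnase[has_ac_any & !me3_central]
  sil_dnase <- dnase[has_me3_any & !ac_central]
  # H3K27me3 peaks untouched by both accessibility and activation marks
  iso <- me3[GenomicRanges::countOverlaps(me3, dnase, ignore.strand = TRUE) == 0L &
               GenomicRanges::countOverlaps(me3, ac, ignore.strand = TRUE) == 0L]

  win <- function(gr, klass) {
    if (length(gr) == 0L) {
      return(GenomicRanges::GRanges())
    }
    w <- window_at_midpoint(GenomicRanges::granges(gr), width = 1000L)
    S4Vectors::mcols(w)$klass <- klass
    w
  }
  out <- c(win(enh, "enhancer"), win(sil_dnase, "silencer"),
           win(iso, "silencer"))
  if (length(out) == 0L) {
    return(out)
  }
  # windows sharing a midpoint through both silencer routes collapse to one
  key <- paste(GenomicRanges::seqnames(out), GenomicRanges::start(out),
               S4Vectors::mcols(out)$klass)
  out <- out[!duplicated(key)]

  if (!is.null(seqlengths)) {
    chroms <- as.character(GenomicRanges::seqnames(out))
    inside <- GenomicRanges::start(out) >= 1L &
      GenomicRanges::end(out) <= unname(seqlengths[chroms])
    inside[is.na(inside)] <- FALSE
    if (any(!inside)) {
      silens_log(sum(!inside), " element window(s) dropped at chromosome edges",
                 level = "WARN")
    }
    out <- out[inside]
  }
  if (!is.null(genes)) {
    excl <- c(promoter_regions(genes, promoter_flank),
              GenomicRanges::granges(unlist(genes$exons)))
    hit <- GenomicRanges::countOverlaps(out, excl, ignore.strand = TRUE) > 0L
    if (any(hit)) {
      silens_log(sum(hit), " element(s) removed for promoter/exon overlap")
    }
    out <- out[!hit]
  }
  S4Vectors::mcols(out)$sample_id <- sample_id
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Remove redundant elements overlapping by more than 600 bp
#'
#' Among any chained group of 1-kb element windows that pairwise overlap by
#' strictly more than 600 bp, a single element is retained at random.
#' Elements are visited in a seeded random order; an element is kept unless
#' it conflicts with an already-kept element. Windows overlapping by exactly
#' 600 bp or less are all kept. Keeping one original window (rather than
#' merging or recentring) preserves the alignment between window midpoints
#' and the underlying peak midpoints.
#'
#' @param elements `GRanges` of 1-kb windows (all samples pooled).
#' @param seed Integer seed controlling the random retention.
#' @param max_overlap Overlap (bp) strictly above which two windows are
#'   redundant (default 600).
#' @return The retained subset, in genomic order.
#' @export
deduplicate_elements <- function(elements, seed = 1L, max_overlap = 600L) {
  n <- length(elements)
  if (n <= 1L) {
    return(elements)
  }
  hits <- GenomicRanges::findOverlaps(elements,
                                      minoverlap = as.integer(max_overlap) + 1L,
                                      drop.self = TRUE, drop.redundant = FALSE,
                                      ignore.strand = TRUE)
  nbr <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  keep <- logical(n)
  dropped <- logical(n)
  order_visit <- with_seed(seed, sample.int(n))
  for (i in order_visit) {
    if (dropped[i]) next
    keep[i] <- TRUE
    js <- nbr[[as.character(i)]]
    if (!is.null(js)) dropped[js] <- TRUE
  }
  elements[keep]
}

#' Assign nine-context labels to elements
#'
#' The tissue context keeps the element class. For each of the eight
#' cell-type contexts, an element keeps its class when its 1-kb window
#' overlaps (>= 1 bp) any accessibility peak of that cell type and is
#' labelled `"control"` otherwise. Control elements are `"control"` in
#' every context. Cell-type membership is binary; accessibility read counts
#' are not used.
#'
#' @param elements `GRanges` with a `klass` column.
#' @param atac_by_celltype Named list of 8 `GRanges` accessibility peak
#'   sets; names must match `silens_contexts()[-1]`.
#' @return `elements` with a `label_<context>` metadata column per context.
#' @export
label_contexts <- function(elements, atac_by_celltype) {
  ctx <- silens_contexts()
  cells <- ctx[-1]
  if (!all(cells %in% names(atac_by_celltype))) {
    stop("atac_by_celltype must be named after: ", paste(cells, collapse = ", "))
  }
  klass <- S4Vectors::mcols(elements)$klass
  lab <- matrix("control", nrow = length(elements), ncol = length(ctx),
                dimnames = list(NULL, ctx))
  lab[, "tissue"] <- klass
  for (cell in cells) {
    hit <- GenomicRanges::countOverlaps(elements, atac_by_celltype[[cell]],
                                        minoverlap = 1L,
                                        ignore.strand = TRUE) > 0L
    lab[hit, cell] <- klass[hit]
  }
  lab[klass == "control", ] <- "control"
  for (cx in ctx) {
    S4Vectors::mcols(elements)[[paste0("label_", cx)]] <- lab[, cx]
  }
  elements
}

#' @noRd
context_label_matrix <- function(elements) {
  ctx <- silens_contexts()
  cols <- paste0("label_", ctx)
  m <- S4Vectors::mcols(elements)
  if (!all(cols %in% names(m))) stop("elements lack context labels")
  out <- do.call(cbind, lapply(cols, function(cl) as.character(m[[cl]])))
  colnames(out) <- ctx
  out
}

#' Sample control elements from a background accessibility pool
#'
#' Controls emulate accessible regions of unrelated (non-target) biosamples:
#' peaks from `pool` are re-windowed to 1 kb at their midpoints, windows
#' overlapping any exclusion set (candidate elements and the epigenomic
#' peaks that defined them) are removed, and `n_controls` of the remainder
#' are sampled uniformly without replacement.
#'
#' @param pool `GRanges` of background accessible regions.
#' @param exclusions List of `GRanges` to exclude (>= 1 bp overlap).
#' @param n_controls Number of controls requested. The model test mixture
#'   uses a 1:9 positive-to-control ratio, so 9-10 controls per positive is
#'   a typical request.
#' @param seed Integer seed.
#' @param seqlengths Optional chromosome lengths to drop edge windows.
#' @return `GRanges` of 1-kb control windows with `klass = "control"`.
#' @export
sample_controls <- function(pool, exclusions = list(), n_controls,
                            seed = 1L, seqlengths = NULL) {
  win <- window_at_midpoint(GenomicRanges::granges(pool), width = 1000L)
  if (!is.null(seqlengths)) {
    chroms <- as.character(GenomicRanges::seqnames(win))
    inside <- GenomicRanges::start(win) >= 1L &
      GenomicRanges::end(win) <= unname(seqlengths[chroms])
    inside[is.na(inside)] <- FALSE
    win <- win[inside]
  }
  for (ex in exclusions) {
    if (length(win) == 0L) break
    win <- win[GenomicRanges::countOverlaps(win, ex, minoverlap = 1L,
                                            ignore.strand = TRUE) == 0L]
  }
  if (length(win) < n_controls) {
    stop(sprintf("control pool exhausted: %d available after exclusions, %d requested",
                 length(win), n_controls))
  }
  idx <- with_seed(seed, sample.int(length(win), n_controls))
  out <- GenomicRanges::sort(win[idx], ignore.strand = TRUE)
  S4Vectors::mcols(out)$klass <- "control"
  S4Vectors::mcols(out)$sample_id <- "background"
  out
}

#' Split elements into training and held-out test sets by chromosome
#'
#' Whole chromosomes are held out so that no test sequence shares local
#' context with training sequences; chromosomes 7 and 8 are the default
#' holdout.
#'
#' @param elements Labelled `GRanges`.
#' @param holdout_chroms Chromosomes reserved for testing.
#' @return List with `train`, `test` (`GRanges`) and `holdout_chroms`.
#' @export
split_holdout <- function(elements, holdout_chroms = c("chr7", "chr8")) {
  chroms <- as.character(GenomicRanges::seqnames(elements))
  is_test <- chroms %in% holdout_chroms
  if (!any(is_test)) {
    warning("holdout split is empty: no elements on ",
            paste(holdout_chroms, collapse = ", "))
  }
  train <- elements[!is_test]
  test <- elements[is_test]
  kl_train <- table(S4Vectors::mcols(train)$klass)
  kl_test <- table(S4Vectors::mcols(test)$klass)
  silens_log("holdout split: train {",
             paste(names(kl_train), as.integer(kl_train), collapse = ", "),
             "}, test {",
             paste(names(kl_test), as.integer(kl_test), collapse = ", "), "}")
  list(train = train, test = test, holdout_chroms = holdout_chroms)
}
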