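#' Exact upper-tail binomial probability
#'
#' `P(X >= n_obs)` for `X ~ Binomial(N_trials, p_success)`, i.e.
#' \eqn{\sum_{m=n}^{N} \binom{N}{m} p^m (1-p)^{N-m}}. Computed with the
#' exact distribution function, so it agrees with direct summation to
#' machine precision.
#'
#' @param n_obs Observed count (0..N).
#' @param N_trials Number of trials.
#' @param p_success Per-trial success probability in (0, 1).
#' @return Upper-tail probability.
#' @export
binom_upper_tail <- function(n_obs, N_trials, p_success) {
  if (any(n_obs < 0) || any(n_obs > N_trials)) {
    stop("n_obs must lie in [0, N_trials]")
  }
  if (any(p_success <= 0) || any(p_success >= 1)) {
    stop("p_success must lie in (0, 1)")
  }
  pbinom(n_obs - 1, size = N_trials, prob = p_success, lower.tail = FALSE)
}

#' Build gene loci tiling each chromosome
#'
#' A gene locus is the gene body plus its flanking intergenic regions;
#' each intergenic gap is split at the midpoint between the two adjacent
#' gene bodies, and chromosome ends are assigned to the terminal genes, so
#' gene loci tile every chromosome exactly. Overlapping gene bodies are
#' merged into a single locus carrying all member gene ids.
#'
#' @param genes A `silens_genes` object.
#' @param seqlengths Named vector of chromosome lengths.
#' @return `GRanges` of loci with metadata `gene_ids` (comma-separated).
#' @export
build_gene_loci <- function(genes, seqlengths) {
  g <- genes$genes
  out <- list()
  for (chrom in names(seqlengths)) {
    gi <- g[as.character(GenomicRanges::seqnames(g)) == chrom]
    if (length(gi) == 0L) next
    merged <- GenomicRanges::reduce(GenomicRanges::granges(gi),
                                    ignore.strand = TRUE)
    ov <- GenomicRanges::findOverlaps(merged, gi, ignore.strand = TRUE)
    ids <- vapply(seq_along(merged), function(k) {
      paste(S4Vectors::mcols(gi)$gene_id[
        S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == k]],
        collapse = ",")
    }, character(1))
    o <- order(GenomicRanges::start(merged))
    merged <- merged[o]; ids <- ids[o]
    nb <- length(merged)
    starts <- integer(nb); ends <- integer(nb)
    starts[1] <- 1L
    ends[nb] <- unname(seqlengths[chrom])
    if (nb > 1L) {
      for (k in seq_len(nb - 1L)) {
        cut <- (GenomicRanges::end(merged)[k] +
                  GenomicRanges::start(merged)[k + 1L]) %/% 2L
        ends[k] <- cut
        starts[k + 1L] <- cut + 1L
      }
    }
    loci <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends))
    S4Vectors::mcols(loci)$gene_ids <- ids
    out[[chrom]] <- loci
  }
  if (length(out) == 0L) stop("no genes on the supplied chromosomes")
  unname(do.call(c, unname(out)))
}

#' Merge adjacent variant-bearing gene loci into susceptibility loci
#'
#' Maximal runs of consecutive gene loci that each contain at least one
#' associated variant are merged into candidate susceptibility loci. A
#' merged region is retained when its variant count is enriched over the
#' genome-wide average: the upper-tail binomial probability of observing at
#' least its count, with per-variant success probability equal to region
#' length / genome size and the total variant count as trials, is below
#' `p_cut`.
#'
#' @param gene_loci `GRanges` from [build_gene_loci()].
#' @param adsnvs Width-1 `GRanges` of disease-associated variants (already
#'   filtered to association p < 1e-5).
#' @param genome_size Total genome length (sum of chromosome lengths).
#' @param p_cut Enrichment cut-off (default 0.003).
#' @return `GRanges` of susceptibility loci with metadata `n_adsnv`,
#'   `p_enrich`, `gene_ids`, `member_loci` (indices into `gene_loci`).
#' @export
merge_susceptibility_loci <- function(gene_loci, adsnvs, genome_size,
                                      p_cut = 0.003) {
  if (length(adsnvs) == 0L) {
    return(GenomicRanges::GRanges())
  }
  cnt <- GenomicRanges::countOverlaps(gene_loci, adsnvs, ignore.strand = TRUE)
  has <- cnt > 0L
  N <- length(adsnvs)
  chroms <- as.character(GenomicRanges::seqnames(gene_loci))
  # runs of consecutive variant-bearing loci on the same chromosome
  new_run <- !has | c(TRUE, chroms[-1] != chroms[-length(chroms)])
  run_id <- cumsum(new_run)
  keep_regions <- list()
  for (rid in unique(run_id[has])) {
    members <- which(run_id == rid & has)
    if (length(members) == 0L) next
    region <- range(GenomicRanges::granges(gene_loci[members]))
    n <- sum(cnt[members])
    p0 <- sum(GenomicRanges::width(region)) / genome_size
    p <- binom_upper_tail(n, N, p0)
    if (p < p_cut) {
      S4Vectors::mcols(region)$n_adsnv <- n
      S4Vectors::mcols(region)$p_enrich <- p
      S4Vectors::mcols(region)$gene_ids <- paste(
        S4Vectors::mcols(gene_loci)$gene_ids[members], collapse = ",")
      S4Vectors::mcols(region)$member_loci <- paste(members, collapse = ",")
      keep_regions[[length(keep_regions) + 1L]] <- region
    }
  }
  if (length(keep_regions) == 0L) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::sort(do.call(c, keep_regions), ignore.strand = TRUE)
}

#' Classify a susceptibility locus by regulatory-variant enrichment
#'
#' With `pi0` = locus length / genome size, the silencer enrichment is
#' `P_S = P(X >= n_sil)` for `X ~ Binomial(total_sil, pi0)`, and `P_E`
#' analogously for enhancer variants. Classes: **SL** iff `P_S < p_cut`
#' only, **EN** iff `P_E < p_cut` only, **ENSL** iff both, **UC**
#' otherwise. When promoter/exon variant counts are supplied, the
#' promoter/exon enrichment `P_ep` uses the genome-wide promoter/exon
#' fraction `gamma0` with trials equal to the locus's associated-variant
#' count and is annotated at `ep_cut` (not used for the class).
#'
#' @param locus `GRanges` of length 1.
#' @param rad_sil,rad_enh Width-1 `GRanges` of silencer / enhancer
#'   regulatory variants (genome-wide sets).
#' @param genome_size Genome length.
#' @param p_cut Class cut-off (default 0.005).
#' @param n_ad_locus,n_ep_locus Optional: associated variants in the locus
#'   and how many of them are promoter/exon variants.
#' @param gamma0 Genome-wide promoter/exon fraction of associated variants.
#' @param ep_cut Promoter/exon annotation cut-off (default 0.05).
#' @return List: `klass` (`"SL"/"EN"/"ENSL"/"UC"`), `p_s`, `p_e`, `n_sil`,
#'   `n_enh`, and optionally `p_ep`, `ep_enriched`.
#' @export
classify_locus <- function(locus, rad_sil, rad_enh, genome_size,
                           p_cut = 0.005, n_ad_locus = NULL,
                           n_ep_locus = NULL, gamma0 = NULL, ep_cut = 0.05) {
  stopifnot(length(locus) == 1L)
  w <- GenomicRanges::width(locus)
  if (w <= 0L) stop("zero-length locus")
  pi0 <- w / genome_size
  n_sil <- GenomicRanges::countOverlaps(locus, rad_sil, ignore.strand = TRUE)
  n_enh <- GenomicRanges::countOverlaps(locus, rad_enh, ignore.strand = TRUE)
  p_s <- if (length(rad_sil)) binom_upper_tail(n_sil, length(rad_sil), pi0) else 1
  p_e <- if (length(rad_enh)) binom_upper_tail(n_enh, length(rad_enh), pi0) else 1
  klass <- if (p_s < p_cut && p_e < p_cut) "ENSL"
    else if (p_s < p_cut) "SL"
    else if (p_e < p_cut) "EN"
    else "UC"
  out <- list(klass = klass, p_s = p_s, p_e = p_e,
              n_sil = as.integer(n_sil), n_enh = as.integer(n_enh))
  if (!is.null(n_ad_locus) && !is.null(n_ep_locus) && !is.null(gamma0)) {
    out$p_ep <- binom_upper_tail(n_ep_locus, n_ad_locus, gamma0)
    out$ep_enriched <- out$p_ep < ep_cut
  }
  out
}

#' Cross-disease overlap of a locus's regulatory variants
#'
#' Tests whether the regulatory variants of a locus are enriched for
#' association with another disease `d`:
#' `P = P(X >= q)`, `X ~ Binomial(Q, w_d)`, where `Q` is the number of
#' regulatory variants in the locus, `q` how many of them are associated
#' with `d`, and `w_d` the genome-wide fraction of common variants
#' associated with `d`.
#'
#' @param locus_rad_ids Ids of the locus's regulatory variants.
#' @param disease_variant_ids Ids of variants associated with disease `d`.
#' @param w_d Genome-wide associated fraction, in (0, 1).
#' @param p_cut Significance cut-off (default 0.005).
#' @return List: `Q`, `q`, `p`, `significant`. `Q = 0` yields `p = NA` with
#'   `significant = NA` (undefined, flagged).
#' @export
disease_overlap <- function(locus_rad_ids, disease_variant_ids, w_d,
                            p_cut = 0.005) {
  if (w_d <= 0 || w_d >= 1) stop("w_d must lie in (0, 1)")
  Q <- length(locus_rad_ids)
  if (Q == 0L) {
    return(list(Q = 0L, q = 0L, p = NA_real_, significant = NA))
  }
  q <- sum(locus_rad_ids %in% disease_variant_ids)
  p <- binom_upper_tail(q, Q, w_d)
  list(Q = Q, q = as.integer(q), p = p, significant = p < p_cut)
}

#' Fold enrichment with an exact two-sided binomial test
#'
#' Compares a query proportion `k_query / n_query` with a background
#' proportion `k_bg / n_bg`: the fold is the ratio of the proportions and
#' the p-value is the exact two-sided binomial test (minimum-likelihood-sum
#' definition, as in [stats::binom.test()]) of `k_query` successes in
#' `n_query` trials at the background rate.
#'
#' @param k_query,n_query Query successes and trials.
#' @param k_bg,n_bg Background successes and trials.
#' @return List: `fold`, `p`, `rate_bg`, `pseudocount` (TRUE when the
#'   background rate needed a pseudocount because `k_bg = 0`).
#' @export
enrichment_vs_background <- function(k_query, n_query, k_bg, n_bg) {
  if (n_query <= 0 || n_bg <= 0) stop("n_query and n_bg must be positive")
  pseudo <- k_bg == 0
  rate <- if (pseudo) (k_bg + 0.5) / (n_bg + 1) else k_bg / n_bg
  fold <- if (pseudo) NA_real_ else (k_query / n_query) / rate
  p <- binom.test(k_query, n_query, p = rate)$p.value
  list(fold = fold, p = p, rate_bg = rate, pseudocount = pseudo)
}

#' Classify every susceptibility locus in a table
#'
#' @param loci `GRanges` from [merge_susceptibility_loci()].
#' @param rad_sil,rad_enh Genome-wide silencer / enhancer regulatory
#'   variant `GRanges`.
#' @param genome_size Genome length.
#' @param p_cut Class cut-off (default 0.005).
#' @return `data.frame`: one row per locus with interval, counts, `p_s`,
#'   `p_e` and class.
#' @export
classify_loci <- function(loci, rad_sil, rad_enh, genome_size,
                          p_cut = 0.005) {
  rows <- lapply(seq_along(loci), function(i) {
    cl <- classify_locus(loci[i], rad_sil, rad_enh, genome_size, p_cut)
    data.frame(
      chrom = as.character(GenomicRanges::seqnames(loci[i])),
      start = GenomicRanges::start(loci[i]),
      end = GenomicRanges::end(loci[i]),
      n_sil = cl$n_sil, n_enh = cl$n_enh,
      p_s = cl$p_s, p_e = cl$p_e, klass = cl$klass,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
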