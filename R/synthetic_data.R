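#' Generate a random genome
#'
#' Chromosomes of i.i.d. bases at a requested GC fraction. One chromosome
#' is conventionally named `chr7` so that the default chromosome holdout
#' has a non-empty test split.
#'
#' @param lengths Named integer vector of chromosome lengths (>= 10 kb
#'   each).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed Integer seed; the same seed reproduces the same genome
#'   byte for byte.
#' @return A named [Biostrings::DNAStringSet].
#' @export
make_genome <- function(lengths = c(chr1 = 8e6, chr2 = 8e6, chr7 = 8e6),
                        gc = 0.41, seed = 1L) {
  if (is.na(gc) || gc < 0 || gc > 1) stop("gc must lie in [0, 1]")
  if (any(lengths < 1e4)) stop("chromosome lengths must be >= 10 kb")
  if (is.null(names(lengths))) {
    names(lengths) <- paste0("chr", seq_along(lengths))
  }
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- with_seed(seed, {
    vapply(lengths, function(L) {
      paste(sample(names(probs), L, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(lengths)
  out
}

#' @noRd
default_activator_motifs <- function() c("TGACTCAGC", "GCCACGTGAC")

#' @noRd
default_repressor_motifs <- function() c("CTGTCCTAAG", "AACCGTTGCA")

#' Plant regulatory elements and emit matching peak sets
#'
#' Chooses non-overlapping 1-kb element slots (centres at least `spacing`
#' bp apart), assigns them enhancer/silencer/control classes, writes 3-6
#' copies of activator motifs into each enhancer window and 3-6 repressor
#' copies into each silencer window (controls receive none), and emits
#' DNase/H3K27ac/H3K27me3 peak sets whose overlap structure makes
#' [call_candidates()] recover exactly the planted classes:
#'
#' * enhancer: DNase + overlapping H3K27ac peak, no H3K27me3;
#' * silencer (half of them): DNase + overlapping H3K27me3, no H3K27ac;
#' * silencer (other half): isolated H3K27me3 peak, no DNase/H3K27ac;
#' * control: a peak in a separate background accessibility pool only.
#'
#' Silencer window background is re-drawn at a slightly lower GC fraction
#' than the genome (mimicking the lower GC content of repressed elements);
#' this is cosmetic and carries no label information beyond the motifs.
#' Each non-control element is also made accessible in a random subset of
#' the eight cell types (inclusion probability `atac_prob`), emitted as
#' per-cell-type accessibility peak sets.
#'
#' @param genome Genome from [make_genome()].
#' @param n_enh,n_sil,n_ctrl Element counts.
#' @param activator_motifs,repressor_motifs Disjoint motif k-mers
#'   (k 6-10).
#' @param seed Integer seed.
#' @param spacing Minimum distance between element centres (bp).
#' @param atac_prob Per-cell-type accessibility probability.
#' @return List: `genome` (with motifs written in), `peaks` (list `dnase`,
#'   `ac`, `me3`, `pool`, `atac` = list of 8 `GRanges`), `elements` (truth
#'   table: id, chrom, center, window, class, cell-type membership),
#'   `motifs` (planted motif instances), `params`.
#' @export
plant_elements <- function(genome, n_enh = 800L, n_sil = 800L,
                           n_ctrl = 8000L,
                           activator_motifs = default_activator_motifs(),
                           repressor_motifs = default_repressor_motifs(),
                           seed = 1L, spacing = 2400L, atac_prob = 0.45) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  if (any(activator_motifs %in% repressor_motifs)) {
    stop("activator and repressor motif sets must be disjoint")
  }
  klen <- nchar(c(activator_motifs, repressor_motifs))
  if (any(klen < 6L | klen > 10L)) stop("motif lengths must be 6-10")
  lens <- setNames(Biostrings::width(genome), names(genome))
  n_total <- n_enh + n_sil + n_ctrl
  slots <- do.call(rbind, lapply(names(lens), function(ch) {
    centers <- seq(1600L, lens[[ch]] - 1600L, by = as.integer(spacing))
    data.frame(chrom = ch, center = centers, stringsAsFactors = FALSE)
  }))
  if (nrow(slots) < n_total) {
    stop(sprintf("genome too small: %d element slots available, %d requested",
                 nrow(slots), n_total))
  }
  cells <- silens_contexts()[-1]
  res <- with_seed(seed, {
    take <- sort(sample.int(nrow(slots), n_total))
    el <- slots[take, , drop = FALSE]
    el$class <- sample(rep(c("enhancer", "silencer", "control"),
                           c(n_enh, n_sil, n_ctrl)))
    el$id <- sprintf("el%05d", seq_len(nrow(el)))
    sil_idx <- which(el$class == "silencer")
    el$sil_type <- NA_character_
    el$sil_type[sil_idx] <- sample(rep(c("dnase_me3", "isolated_me3"),
                                       length.out = length(sil_idx)))
    # cell-type memberships for non-controls
    memb <- matrix(FALSE, nrow(el), length(cells),
                   dimnames = list(el$id, cells))
    nonctrl <- el$class != "control"
    memb[nonctrl, ] <- matrix(runif(sum(nonctrl) * length(cells)) < atac_prob,
                              sum(nonctrl), length(cells))

    raws <- lapply(as.character(genome), charToRaw)
    names(raws) <- names(genome)
    gc <- mean(Biostrings::letterFrequency(genome, "GC") /
                 Biostrings::width(genome))
    bases <- c("A", "C", "G", "T")

    motif_rows <- vector("list", nrow(el))
    for (i in seq_len(nrow(el))) {
      cls <- el$class[i]
      if (cls == "control") next
      ch <- el$chrom[i]; c0 <- el$center[i]
      if (cls == "silencer") {
        # silencer windows trend to lower GC, with enough per-window
        # spread that the class distributions overlap (a compositional
        # tendency, not a separating feature)
        gc_i <- min(0.95, max(0.05, rnorm(1L, gc - 0.03, 0.03)))
        probs_i <- c((1 - gc_i) / 2, gc_i / 2, gc_i / 2, (1 - gc_i) / 2)
        win <- charToRaw(paste(sample(bases, 1000L, TRUE, probs_i),
                               collapse = ""))
        raws[[ch]][(c0 - 500L):(c0 + 499L)] <- win
      }
      motifs <- if (cls == "enhancer") activator_motifs else repressor_motifs
      k <- sample(3:6, 1L)
      placed <- integer(0)
      starts <- integer(0); chosen <- character(0)
      tries <- 0L
      # motifs live inside the accessible peak footprint (the central
      # ~400 bp), as binding sites do in real elements; the rest of the
      # 1-kb window is model context
      while (length(starts) < k && tries < 300L) {
        tries <- tries + 1L
        mo <- sample(motifs, 1L)
        lo <- c0 - 180L
        hi <- c0 + 180L - nchar(mo)
        s <- sample(lo:hi, 1L)
        if (all(abs(s - placed) >= 40L)) {
          placed <- c(placed, s)
          starts <- c(starts, s)
          chosen <- c(chosen, mo)
        }
      }
      for (j in seq_along(starts)) {
        raws[[ch]][starts[j]:(starts[j] + nchar(chosen[j]) - 1L)] <-
          charToRaw(chosen[j])
      }
      motif_rows[[i]] <- data.frame(
        element_id = el$id[i], chrom = ch, start = starts,
        end = starts + nchar(chosen) - 1L, motif = chosen,
        type = if (cls == "enhancer") "activator" else "repressor",
        stringsAsFactors = FALSE)
    }
    list(el = el, memb = memb, raws = raws,
         motifs = do.call(rbind, motif_rows))
  })
  el <- res$el

  genome2 <- Biostrings::DNAStringSet(vapply(res$raws, rawToChar, character(1)))
  names(genome2) <- names(genome)

  peak_at <- function(df, half = 200L, shift_start = 0L, shift_end = 0L) {
    if (nrow(df) == 0L) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(df$center - half + shift_start,
                                            df$center + half - 1L + shift_end))
  }
  is_enh <- el$class == "enhancer"
  is_sil_d <- !is.na(el$sil_type) & el$sil_type == "dnase_me3"
  is_sil_i <- !is.na(el$sil_type) & el$sil_type == "isolated_me3"
  is_ctrl <- el$class == "control"
  dnase <- GenomicRanges::sort(peak_at(el[is_enh | is_sil_d, ]))
  ac <- GenomicRanges::sort(peak_at(el[is_enh, ], half = 150L))
  me3 <- GenomicRanges::sort(c(peak_at(el[is_sil_d, ], half = 180L),
                               peak_at(el[is_sil_i, ])))
  pool <- GenomicRanges::sort(peak_at(el[is_ctrl, ]))
  atac <- lapply(cells, function(cc) {
    GenomicRanges::sort(peak_at(el[res$memb[, cc], , drop = FALSE]))
  })
  names(atac) <- cells

  el$window_start <- el$center - 500L
  el$window_end <- el$center + 499L
  truth <- cbind(el[, c("id", "chrom", "center", "window_start", "window_end",
                        "class", "sil_type")],
                 as.data.frame(res$memb))
  rownames(truth) <- NULL
  list(genome = genome2,
       peaks = list(dnase = dnase, ac = ac, me3 = me3, pool = pool,
                    atac = atac),
       elements = truth, motifs = res$motifs,
       params = list(n_enh = n_enh, n_sil = n_sil, n_ctrl = n_ctrl,
                     spacing = spacing, seed = seed,
                     activator_motifs = activator_motifs,
                     repressor_motifs = repressor_motifs))
}

#' Plant variants with known regulatory direction
#'
#' Disrupting variants substitute the central (most informative) base of a
#' planted motif copy: an activator motif inside a true enhancer yields an
#' `activation_loss` variant, a repressor motif inside a true silencer a
#' `repression_loss` variant. Neutral variants fall inside element windows
#' at least 50 bp away from every planted motif. All variants receive
#' association p-values below 1e-5 (disease-associated grade); reference
#' alleles are read from the genome.
#'
#' @param sim Result of [plant_elements()].
#' @param n_disrupting,n_neutral Variant counts.
#' @param seed Integer seed.
#' @return List: `variants` (width-1 `GRanges` with `id`, `ref`, `alt`,
#'   `assoc_p`) and `truth` (`data.frame` with `id`, `element_id`,
#'   `direction` in `activation_loss`/`repression_loss`/`neutral`, and
#'   `expected_sign` of delta-activity: -1, +1 or 0).
#' @export
make_variants <- function(sim, n_disrupting = 400L, n_neutral = 400L,
                          seed = 1L) {
  mot <- sim$motifs
  el <- sim$elements
  genome_chr <- as.character(sim$genome)
  # complementary transversions preserve window GC exactly, so the planted
  # direction label isolates motif loss from the compositional covariate
  # (silencer windows trend AT-rich; a GC-changing substitution would mix
  # a composition effect of its own into every variant)
  transversion <- c(A = "T", C = "G", G = "C", T = "A")
  res <- with_seed(seed, {
    el_class <- setNames(el$class, el$id)
    usable <- mot[(mot$type == "activator" &
                     el_class[mot$element_id] == "enhancer") |
                  (mot$type == "repressor" &
                     el_class[mot$element_id] == "silencer"), , drop = FALSE]
    if (nrow(usable) < n_disrupting) {
      stop(sprintf("only %d motif instances available for %d disrupting variants",
                   nrow(usable), n_disrupting))
    }
    pick <- usable[sample.int(nrow(usable), n_disrupting), , drop = FALSE]
    pos_d <- (pick$start + pick$end) %/% 2L
    dir_d <- ifelse(pick$type == "activator", "activation_loss",
                    "repression_loss")
    # neutral positions: inside element windows, >= 50 bp from any motif
    elements_nonctrl <- el[el$class != "control", , drop = FALSE]
    neutral <- data.frame()
    guard <- 0L
    while (nrow(neutral) < n_neutral && guard < 50L * n_neutral) {
      guard <- guard + 1L
      i <- sample.int(nrow(elements_nonctrl), 1L)
      e <- elements_nonctrl[i, ]
      p <- sample((e$center - 450L):(e$center + 449L), 1L)
      em <- mot[mot$element_id == e$id, , drop = FALSE]
      if (nrow(em) == 0L ||
          all(p < em$start - 50L | p > em$end + 50L)) {
        neutral <- rbind(neutral, data.frame(element_id = e$id,
                                             chrom = e$chrom, pos = p,
                                             stringsAsFactors = FALSE))
      }
    }
    if (nrow(neutral) < n_neutral) {
      stop("could not place the requested number of neutral variants")
    }
    df <- data.frame(
      element_id = c(pick$element_id, neutral$element_id),
      chrom = c(pick$chrom, neutral$chrom),
      pos = c(pos_d, neutral$pos),
      direction = c(dir_d, rep("neutral", n_neutral)),
      stringsAsFactors = FALSE)
    df$ref <- substring(genome_chr[df$chrom], df$pos, df$pos)
    df$alt <- unname(transversion[df$ref])
    df$assoc_p <- 10^-runif(nrow(df), 5.1, 8)
    df$id <- sprintf("var%05d", seq_len(nrow(df)))
    df
  })
  gr <- GenomicRanges::GRanges(res$chrom, IRanges::IRanges(res$pos, width = 1L))
  S4Vectors::mcols(gr)$id <- res$id
  S4Vectors::mcols(gr)$ref <- res$ref
  S4Vectors::mcols(gr)$alt <- res$alt
  S4Vectors::mcols(gr)$assoc_p <- res$assoc_p
  truth <- data.frame(
    id = res$id, element_id = res$element_id, direction = res$direction,
    expected_sign = c(activation_loss = -1, repression_loss = 1,
                      neutral = 0)[res$direction],
    stringsAsFactors = FALSE)
  list(variants = gr, truth = truth)
}

#' Synthetic susceptibility-locus scenario
#'
#' Lays out equally sized genes along one chromosome, designates isolated
#' single-gene susceptibility loci of each class (SL, EN, ENSL, UC), and
#' places associated variants so that each designated locus passes the
#' associated-variant enrichment cut (p < `merge_cut`) and its
#' silencer/enhancer regulatory-variant counts respect the class
#' definition with at least a 10x design margin: enriched channels get
#' `n_enriched` variants (tail p < `class_cut`/10) and non-enriched
#' channels the expected background count (tail p > 10 x `class_cut`).
#' Background regulatory variants are scattered over isolated buffer loci
#' so designated loci never merge with their neighbours. The gene
#' annotation is written as GTF and read back through [read_gene_models()].
#'
#' @param n_per_class Designated loci per class (>= 1; total >= 4 loci).
#' @param n_enriched Regulatory variants in an enriched channel.
#' @param seed Integer seed.
#' @param gtf_path Where to write the GTF (default: temporary file).
#' @param merge_cut,class_cut The enrichment cut-offs (defaults 0.003,
#'   0.005).
#' @return List: `genes` (`silens_genes`), `seqlengths`, `genome_size`,
#'   `variants` (`GRanges` with `id`, `channel` in
#'   silencer/enhancer/none), `truth` (designated locus intervals and
#'   classes), `gtf_path`.
#' @export
make_locus_scenario <- function(n_per_class = 2L, n_enriched = 50L,
                                seed = 1L, gtf_path = tempfile(fileext = ".gtf"),
                                merge_cut = 0.003, class_cut = 0.005) {
  if (n_per_class < 1L) stop("need at least one locus per class")
  classes <- rep(c("SL", "EN", "ENSL", "UC"), n_per_class)
  n_designated <- length(classes)
  # designated loci at every 4th gene locus; background at offset 2;
  # neighbours of both stay variant-free
  n_genes <- 4L * n_designated + 4L
  locus_size <- 2e6
  chrom_len <- n_genes * locus_size
  chrom <- "chrL"
  gene_start <- as.integer((seq_len(n_genes) - 1L) * locus_size + 9e5 + 1L)
  gene_end <- as.integer(gene_start + 2e5 - 1L)
  strands <- rep(c("+", "-"), length.out = n_genes)
  ids <- sprintf("G%03d", seq_len(n_genes))
  gtf <- character(0)
  for (i in seq_len(n_genes)) {
    attrs <- sprintf('gene_id "%s"; gene_name "%s";', ids[i], ids[i])
    gtf <- c(gtf,
             paste(chrom, "synth", "gene", gene_start[i], gene_end[i], ".",
                   strands[i], ".", attrs, sep = "\t"),
             paste(chrom, "synth", "exon", gene_start[i],
                   gene_start[i] + 999L, ".", strands[i], ".", attrs,
                   sep = "\t"),
             paste(chrom, "synth", "exon", gene_end[i] - 999L, gene_end[i],
                   ".", strands[i], ".", attrs, sep = "\t"))
  }
  writeLines(gtf, gtf_path)
  genes <- read_gene_models(gtf_path)
  seqlengths <- setNames(chrom_len, chrom)
  loci <- build_gene_loci(genes, seqlengths)
  genome_size <- sum(seqlengths)

  designated_idx <- 4L * seq_len(n_designated)       # gene-locus indices
  background_idx <- setdiff(seq(2L, n_genes, by = 4L), designated_idx)
  pi0 <- locus_size / genome_size

  # non-enriched channel count: the genome-average expectation
  counts <- with_seed(seed, {
    place <- function(locus_i, n) {
      if (n == 0L) return(integer(0))
      s <- GenomicRanges::start(loci)[locus_i]
      e <- GenomicRanges::end(loci)[locus_i]
      sample(s:e, n, replace = FALSE)
    }
    rows <- list()
    add <- function(locus_i, n, channel) {
      if (n == 0L) return()
      pos <- place(locus_i, n)
      rows[[length(rows) + 1L]] <<- data.frame(
        pos = pos, channel = channel, locus = locus_i,
        stringsAsFactors = FALSE)
    }
    # provisional totals to derive the expected background count
    n_bg_per_locus <- 12L
    exp_total_S <- n_per_class * (2L * n_enriched) +
      length(background_idx) * n_bg_per_locus
    n_expected <- max(1L, round(exp_total_S * pi0))
    for (k in seq_len(n_designated)) {
      cl <- classes[k]
      li <- designated_idx[k]
      add(li, if (cl %in% c("SL", "ENSL")) n_enriched else n_expected,
          "silencer")
      add(li, if (cl %in% c("EN", "ENSL")) n_enriched else n_expected,
          "enhancer")
      # plain associated variants so every designated locus (UC included)
      # passes the associated-variant enrichment merge cut
      add(li, 60L, "none")
    }
    for (li in background_idx) {
      add(li, n_bg_per_locus, "silencer")
      add(li, n_bg_per_locus, "enhancer")
    }
    do.call(rbind, rows)
  })
  counts <- counts[order(counts$pos), ]
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(counts$pos, width = 1L))
  S4Vectors::mcols(gr)$id <- sprintf("rv%05d", seq_along(gr))
  S4Vectors::mcols(gr)$channel <- counts$channel
  S4Vectors::mcols(gr)$ref <- "A"
  S4Vectors::mcols(gr)$alt <- "C"
  S4Vectors::mcols(gr)$assoc_p <- 1e-8

  truth <- data.frame(
    chrom = chrom,
    start = GenomicRanges::start(loci)[designated_idx],
    end = GenomicRanges::end(loci)[designated_idx],
    klass = classes, stringsAsFactors = FALSE)

  # verify the 10x design margins hold at the realised totals
  total_S <- sum(counts$channel == "silencer")
  total_E <- sum(counts$channel == "enhancer")
  for (k in seq_len(n_designated)) {
    for (ch in c("silencer", "enhancer")) {
      n_here <- sum(counts$channel == ch & counts$locus == designated_idx[k])
      tot <- if (ch == "silencer") total_S else total_E
      p <- binom_upper_tail(n_here, tot, pi0)
      enriched <- (classes[k] == "ENSL") ||
        (classes[k] == "SL" && ch == "silencer") ||
        (classes[k] == "EN" && ch == "enhancer")
      if (enriched && p > class_cut / 10) {
        stop("design margin unattainable for an enriched channel (p = ", p, ")")
      }
      if (!enriched && p < class_cut * 10) {
        stop("design margin unattainable for a background channel (p = ", p, ")")
      }
    }
  }
  list(genes = genes, seqlengths = seqlengths, genome_size = genome_size,
       variants = gr, truth = truth, gtf_path = gtf_path,
       merge_cut = merge_cut, class_cut = class_cut)
}

#' Synthetic cell-type regulatory-impact features
#'
#' Independent standard-normal feature columns scaled to a maximum
#' absolute value of 1 per column, emulating a normalised gene x cell-type
#' regulatory-impact matrix.
#'
#' @param n_genes,n_celltypes Matrix dimensions.
#' @param seed Integer seed.
#' @return `n_genes x n_celltypes` matrix with cell-type column names.
#' @export
make_ri_features <- function(n_genes = 2000L, n_celltypes = 7L, seed = 1L) {
  cells <- silens_contexts()[-1][seq_len(n_celltypes)]
  X <- with_seed(seed, matrix(rnorm(n_genes * n_celltypes), n_genes,
                              n_celltypes, dimnames = list(NULL, cells)))
  normalize_columns(X)
}

#' Synthetic subtype expression from known cell-type weights
#'
#' `y = X w + e`, `e ~ N(0, noise_sd)`, then scaled to a maximum absolute
#' value of 1 (the same rule applied to real expression inputs). The
#' planted weights are returned pre-scaling together with the applied
#' scale factor.
#'
#' @param ri_matrix Normalised feature matrix (genes x cell types).
#' @param planted_weights Weight vector, one per column.
#' @param noise_sd Gaussian noise standard deviation (default 0.05).
#' @param seed Integer seed.
#' @return List: `y` (scaled response), `weights` (planted, pre-scaling),
#'   `scale` (divisor applied to y), `noise_sd`.
#' @export
make_subtype_expression <- function(ri_matrix, planted_weights,
                                    noise_sd = 0.05, seed = 1L) {
  stopifnot(ncol(ri_matrix) == length(planted_weights))
  y_raw <- with_seed(seed, {
    as.numeric(ri_matrix %*% planted_weights) +
      rnorm(nrow(ri_matrix), sd = noise_sd)
  })
  sc <- max(abs(y_raw))
  if (sc == 0) sc <- 1
  list(y = y_raw / sc, weights = planted_weights, scale = sc,
       noise_sd = noise_sd)
}
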