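#' Fit an empirical false-positive-rate curve from control scores
#'
#' Maps a raw model score to the fraction of control-sequence scores at
#' least as high: `FPR(s) = max(#\{controls >= s\} / N, 1/(N+1))`. The
#' add-one floor `1/(N+1)` keeps `log10 FPR` finite for scores above every
#' control. FPR is computed over control samples only; it is invariant to
#' the positive:control mixture ratio of the evaluation set the controls
#' came from.
#'
#' @param control_scores Numeric vector of at least 100 control scores.
#' @param context,channel Optional labels stored on the curve.
#' @return A `silens_fpr` object.
#' @export
fit_fpr <- function(control_scores, context = NA_character_,
                    channel = NA_character_) {
  control_scores <- as.numeric(control_scores)
  if (length(control_scores) < 100L) {
    stop("need >= 100 control scores to calibrate an FPR curve, got ",
         length(control_scores))
  }
  if (anyNA(control_scores)) stop("control scores contain NA")
  structure(list(scores = sort(control_scores), n = length(control_scores),
                 floor = 1 / (length(control_scores) + 1),
                 context = context, channel = channel),
            class = "silens_fpr")
}

#' @export
print.silens_fpr <- function(x, ...) {
  cat(sprintf("<silens_fpr> %s/%s, N = %d controls, floor = %.3g\n",
              x$context, x$channel, x$n, x$floor))
  invisible(x)
}

#' Evaluate an FPR curve
#'
#' @param curve A `silens_fpr` from [fit_fpr()].
#' @param s Scores to evaluate (vectorised).
#' @return `FPR(s)` per score: a non-increasing step function of `s` with
#'   value 1 below the minimum control score and `1/(N+1)` above the
#'   maximum.
#' @export
fpr_at <- function(curve, s) {
  stopifnot(inherits(curve, "silens_fpr"))
  n_lt <- findInterval(s, curve$scores, left.open = TRUE)  # controls < s
  pmax((curve$n - n_lt) / curve$n, curve$floor)
}

#' Score threshold at a target false-positive rate
#'
#' @param curve A `silens_fpr`.
#' @param target Target FPR (default 0.05).
#' @return The smallest observed control score `c` with `FPR(c) <= target`.
#' @export
threshold_at <- function(curve, target = 0.05) {
  stopifnot(inherits(curve, "silens_fpr"))
  if (target < curve$floor) {
    stop(sprintf("target FPR %.4g below achievable floor %.4g", target,
                 curve$floor))
  }
  sc <- curve$scores
  fpr <- (curve$n - seq_along(sc) + 1L) / curve$n  # FPR at each sorted score
  idx <- which(fpr <= target)
  sc[idx[1]]
}

#' Classify a variant as silencer/enhancer variant
#'
#' Implements the three-branch rule on the reference-allele window scores:
#'
#' 1. Variant inside a repressive-mark (H3K27me3) peak: a **silencer
#'    variant** iff its silencer score strictly exceeds the context
#'    threshold `c_s,i` in at least one context.
#' 2. Variant inside an active-mark (H3K27ac) peak: an **enhancer variant**
#'    iff its enhancer score exceeds `c_e,i` in at least one context.
#' 3. Variant inside a DNase peak carrying neither mark: a silencer variant
#'    iff the silencer score exceeds `c_s,i` in some context *and* the
#'    enhancer score is below `c_e,i` in *all* contexts; symmetrically for
#'    enhancer variants; otherwise unclassified.
#'
#' Variants outside all three peak sets are unclassified. Threshold
#' comparisons are strict (`>`).
#'
#' @param variant Width-1 `GRanges` (single variant).
#' @param peaks List with `me3`, `ac`, `dnase` `GRanges`.
#' @param scores `9 x 3` matrix (contexts x enhancer/silencer/control) of
#'   model scores for the 1-kb reference window centred at the variant, or
#'   the `1 x 9 x 3` slice from [predict.silens_model()].
#' @param thresholds List with numeric vectors `c_e` and `c_s` of length 9
#'   (per-context thresholds at the target FPR).
#' @return List: `membership` (`in_me3`/`in_ac`/`in_dnase_only`/`none`),
#'   `call` (`silencer_variant`/`enhancer_variant`/`unclassified`),
#'   `contexts` (names of triggering contexts).
#' @export
classify_variant <- function(variant, peaks, scores, thresholds) {
  if (length(dim(scores)) == 3L) scores <- scores[1, , ]
  ctx <- silens_contexts()
  stopifnot(nrow(scores) == length(ctx))
  p_enh <- scores[, "enhancer"]
  p_sil <- scores[, "silencer"]
  over <- function(set) {
    length(set) > 0L &&
      GenomicRanges::countOverlaps(variant, set, ignore.strand = TRUE) > 0L
  }
  sil_hit <- p_sil > thresholds$c_s
  enh_hit <- p_enh > thresholds$c_e
  membership <- if (over(peaks$me3)) "in_me3"
    else if (over(peaks$ac)) "in_ac"
    else if (over(peaks$dnase)) "in_dnase_only"
    else "none"
  call <- "unclassified"
  triggering <- character(0)
  if (membership == "in_me3") {
    if (any(sil_hit)) {
      call <- "silencer_variant"; triggering <- ctx[sil_hit]
    }
  } else if (membership == "in_ac") {
    if (any(enh_hit)) {
      call <- "enhancer_variant"; triggering <- ctx[enh_hit]
    }
  } else if (membership == "in_dnase_only") {
    if (any(sil_hit) && !any(enh_hit)) {
      call <- "silencer_variant"; triggering <- ctx[sil_hit]
    } else if (any(enh_hit) && !any(sil_hit)) {
      call <- "enhancer_variant"; triggering <- ctx[enh_hit]
    }
  }
  list(membership = membership, call = call, contexts = triggering)
}

#' Allelic delta-activity score
#'
#' Quantifies the regulatory difference between two alleles of a variant on
#' the log10 FPR-calibrated scale, per context:
#'
#' \deqn{\Delta = (\log_{10} FPR_e(ref) - \log_{10} FPR_e(alt)) +
#'               (\log_{10} FPR_s(alt) - \log_{10} FPR_s(ref))}
#'
#' In this orientation a positive value means the alternate allele gains
#' activation and/or loses repression relative to the reference. (Read
#' literally, the conventional formula's enhancer term has the opposite
#' sign to its stated semantics; `literal_sign = TRUE` reproduces the
#' literal form, which is the exact negation.) FPR values are clamped at
#' the curve floor before the logarithm, so the score is always finite, is
#' exactly antisymmetric under allele swap, and is zero for identical
#' windows.
#'
#' @param ref_scores,alt_scores `9 x 3` score matrices (or `1 x 9 x 3`
#'   arrays) for the reference- and alternate-allele windows.
#' @param curves List per context, each a list with `enhancer` and
#'   `silencer` `silens_fpr` curves.
#' @param literal_sign Use the literal (negated) orientation.
#' @return Named numeric vector of per-context delta-activity.
#' @export
delta_activity <- function(ref_scores, alt_scores, curves,
                           literal_sign = FALSE) {
  if (length(dim(ref_scores)) == 3L) ref_scores <- ref_scores[1, , ]
  if (length(dim(alt_scores)) == 3L) alt_scores <- alt_scores[1, , ]
  ctx <- silens_contexts()
  stopifnot(all(ctx %in% names(curves)))
  out <- setNames(numeric(length(ctx)), ctx)
  for (cx in ctx) {
    cur <- curves[[cx]]
    if (!inherits(cur$enhancer, "silens_fpr") ||
        !inherits(cur$silencer, "silens_fpr")) {
      stop("curves for context ", cx, " are not fitted")
    }
    i <- match(cx, ctx)
    fe_ref <- log10(fpr_at(cur$enhancer, ref_scores[i, "enhancer"]))
    fe_alt <- log10(fpr_at(cur$enhancer, alt_scores[i, "enhancer"]))
    fs_ref <- log10(fpr_at(cur$silencer, ref_scores[i, "silencer"]))
    fs_alt <- log10(fpr_at(cur$silencer, alt_scores[i, "silencer"]))
    d <- (fe_ref - fe_alt) + (fs_alt - fs_ref)
    out[cx] <- if (literal_sign) -d else d
  }
  out
}

#' Significance call for a delta-activity score
#'
#' A delta-activity value is significant when it reaches the top 5% (for
#' positive values) or bottom 5% (for negative values) of a background
#' panel of delta-activity scores computed with the same model over a large
#' variant set; the percentiles are taken over the pooled signed
#' distribution.
#'
#' @param delta Numeric vector of delta-activity values to flag.
#' @param background_deltas Background panel (>= 100 values).
#' @param level Tail probability (default 0.05).
#' @return Logical vector.
#' @export
call_significance <- function(delta, background_deltas, level = 0.05) {
  if (length(background_deltas) < 100L) {
    stop("need >= 100 background delta-activity values, got ",
         length(background_deltas))
  }
  qs <- quantile(background_deltas, probs = c(level, 1 - level),
                 names = FALSE, na.rm = TRUE)
  (delta >= qs[2] & delta > 0) | (delta <= qs[1] & delta < 0)
}

#' Directional concordance rate
#'
#' Fraction of paired scores whose signs agree, e.g. delta-activity against
#' an external allelic readout (reporter-assay scores). Pairs where either
#' value is exactly zero are excluded from the denominator and their count
#' reported.
#'
#' @param deltas,external_scores Paired numeric vectors.
#' @param mask Optional logical subset to evaluate.
#' @return List with `dcr`, `n_used`, `n_zero`.
#' @export
directional_concordance <- function(deltas, external_scores, mask = NULL) {
  stopifnot(length(deltas) == length(external_scores))
  if (!is.null(mask)) {
    deltas <- deltas[mask]
    external_scores <- external_scores[mask]
  }
  ok <- is.finite(deltas) & is.finite(external_scores)
  deltas <- deltas[ok]; external_scores <- external_scores[ok]
  nz <- sign(deltas) != 0 & sign(external_scores) != 0
  if (!any(nz)) stop("no nonzero pairs left after exclusions")
  list(dcr = mean(sign(deltas[nz]) == sign(external_scores[nz])),
       n_used = sum(nz), n_zero = sum(!nz))
}

#' Per-context FPR curves and thresholds from control predictions
#'
#' Convenience wrapper: fits enhancer and silencer FPR curves per context
#' from the predictions of control sequences and derives the thresholds at
#' the target FPR.
#'
#' @param control_scores `n x 9 x 3` prediction array for control
#'   sequences.
#' @param target Target FPR (default 0.05).
#' @return List with `curves` (per context: `enhancer`/`silencer`
#'   `silens_fpr`) and `thresholds` (list `c_e`, `c_s`, length-9 vectors).
#' @export
calibrate_contexts <- function(control_scores, target = 0.05) {
  ctx <- silens_contexts()
  curves <- list()
  c_e <- c_s <- setNames(numeric(length(ctx)), ctx)
  for (i in seq_along(ctx)) {
    ce <- fit_fpr(control_scores[, i, "enhancer"], ctx[i], "enhancer")
    cs <- fit_fpr(control_scores[, i, "silencer"], ctx[i], "silencer")
    curves[[ctx[i]]] <- list(enhancer = ce, silencer = cs)
    c_e[i] <- threshold_at(ce, target)
    c_s[i] <- threshold_at(cs, target)
  }
  list(curves = curves, thresholds = list(c_e = c_e, c_s = c_s))
}

#' Score and classify a variant table
#'
#' For each variant: scores the 1-kb reference window and the window with
#' the alternate allele substituted, applies [classify_variant()] and
#' [delta_activity()], and (when a background is supplied) flags
#' significant delta-activity per context.
#'
#' @param variants Width-1 `GRanges` with `id`, `ref`, `alt`.
#' @param genome Genome (`DNAStringSet` or FASTA path).
#' @param model Trained `silens_model`.
#' @param peaks List with `me3`, `ac`, `dnase` `GRanges`.
#' @param calibration Result of [calibrate_contexts()].
#' @param background_deltas Optional background delta panel (tissue
#'   context) for significance calls.
#' @return `data.frame`, one row per variant: id, coordinates, alleles,
#'   membership, call, and tissue-context enhancer/silencer scores,
#'   delta-activity and significance. The full per-context delta matrix is
#'   attached as attribute `"delta_matrix"`.
#' @export
score_variants <- function(variants, genome, model, peaks, calibration,
                           background_deltas = NULL) {
  genome <- as_genome(genome)
  n <- length(variants)
  half <- model$config$seq_length %/% 2L
  chroms <- as.character(GenomicRanges::seqnames(variants))
  pos <- GenomicRanges::start(variants)
  m <- S4Vectors::mcols(variants)
  refs <- character(n); alts <- character(n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      extract_window(genome, chroms[i], pos[i], model$config$seq_length),
      error = function(e) NULL)
    if (is.null(res)) next
    center_idx <- half  # 1-based index of `pos` inside the window
    ref_obs <- substr(res, center_idx, center_idx)
    if (!identical(ref_obs, m$ref[i])) {
      silens_log("variant ", m$id[i], ": reference allele mismatch (",
                 ref_obs, " vs ", m$ref[i], ")", level = "WARN")
    }
    refs[i] <- res
    alt_seq <- res
    substr(alt_seq, center_idx, center_idx) <- m$alt[i]
    alts[i] <- alt_seq
    keep[i] <- TRUE
  }
  idx <- which(keep)
  if (length(idx) == 0L) stop("no variant windows could be extracted")
  ref_scores <- predict(model, refs[idx])
  alt_scores <- predict(model, alts[idx])
  ctxs <- silens_contexts()
  delta <- matrix(NA_real_, nrow = n, ncol = length(ctxs),
                  dimnames = list(m$id, ctxs))
  call <- rep("unclassified", n)
  membership <- rep(NA_character_, n)
  for (j in seq_along(idx)) {
    i <- idx[j]
    cl <- classify_variant(variants[i], peaks, ref_scores[j, , ],
                           calibration$thresholds)
    call[i] <- cl$call
    membership[i] <- cl$membership
    delta[i, ] <- delta_activity(ref_scores[j, , ], alt_scores[j, , ],
                                 calibration$curves)
  }
  sig <- rep(NA, n)
  if (!is.null(background_deltas)) {
    sig[idx] <- call_significance(delta[idx, "tissue"], background_deltas)
  }
  out <- data.frame(
    id = m$id, chrom = chroms, pos = pos, ref = m$ref, alt = m$alt,
    membership = membership, call = call,
    p_enh_tissue = NA_real_, p_sil_tissue = NA_real_,
    delta_tissue = delta[, "tissue"], significant = sig,
    stringsAsFactors = FALSE
  )
  out$p_enh_tissue[idx] <- ref_scores[, "tissue", "enhancer"]
  out$p_sil_tissue[idx] <- ref_scores[, "tissue", "silencer"]
  attr(out, "delta_matrix") <- delta
  out
}
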