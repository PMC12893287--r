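#' Regulatory impact of accessible peaks per cellular context
#'
#' For an accessibility peak re-windowed to 1 kb at its midpoint and scored
#' by the sequence model, the regulatory impact in context `c` is
#'
#' \deqn{RI^c = I_E \cdot (-\log_{10} FPR_E^c) - I_S \cdot
#'   (-\log_{10} FPR_s^c)}
#'
#' where `I_E` / `I_S` indicate overlap with a tissue H3K27ac / H3K27me3
#' peak and the FPRs calibrate the peak's enhancer and silencer scores.
#' Stronger enhancer evidence is positive and stronger silencer evidence
#' negative; FPRs are clamped at the curve floor before the logarithm so RI
#' is finite. (The conventional formula written directly in terms of
#' `log10 FPR` has the opposite sign; `literal_sign = TRUE` reproduces it.)
#'
#' @param peaks `GRanges` of accessibility peaks (1-kb windows).
#' @param scores `n x 9 x 3` prediction array for the peak windows.
#' @param curves Per-context calibration curves
#'   (see [calibrate_contexts()]).
#' @param ac,me3 Tissue H3K27ac and H3K27me3 peak `GRanges`.
#' @param literal_sign Use the literal (negated) orientation.
#' @return `n x 9` matrix of RI values (columns `silens_contexts()`).
#' @export
regulatory_impact <- function(peaks, scores, curves, ac, me3,
                              literal_sign = FALSE) {
  n <- length(peaks)
  stopifnot(dim(scores)[1] == n)
  i_e <- GenomicRanges::countOverlaps(peaks, ac, ignore.strand = TRUE) > 0L
  i_s <- GenomicRanges::countOverlaps(peaks, me3, ignore.strand = TRUE) > 0L
  ctx <- silens_contexts()
  ri <- matrix(0, nrow = n, ncol = length(ctx),
               dimnames = list(NULL, ctx))
  for (i in seq_along(ctx)) {
    cur <- curves[[ctx[i]]]
    fe <- -log10(fpr_at(cur$enhancer, scores[, i, "enhancer"]))
    fs <- -log10(fpr_at(cur$silencer, scores[, i, "silencer"]))
    v <- as.numeric(i_e) * fe - as.numeric(i_s) * fs
    ri[, i] <- if (literal_sign) -v else v
  }
  ri
}

#' Regulatory domain of a gene
#'
#' The union of the 200-kb region around the TSS (`[tss - flank,
#' tss + flank)`, clipped at the chromosome start) and the gene's introns
#' (gene body minus merged exons).
#'
#' @param genes A `silens_genes` object.
#' @param gene_id Gene to query.
#' @param flank TSS flank in bp (default 200000).
#' @return `GRanges` of domain intervals.
#' @export
gene_domains <- function(genes, gene_id, flank = 200000L) {
  i <- match(gene_id, S4Vectors::mcols(genes$genes)$gene_id)
  if (is.na(i)) stop("unknown gene: ", gene_id)
  g <- genes$genes[i]
  tss <- S4Vectors::mcols(g)$tss
  tss_win <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(g),
    IRanges::IRanges(start = max(1L, tss - as.integer(flank)),
                     end = tss + as.integer(flank) - 1L))
  ex <- genes$exons[[gene_id]]
  introns <- GenomicRanges::setdiff(GenomicRanges::granges(g),
                                    GenomicRanges::granges(ex),
                                    ignore.strand = TRUE)
  # gene body minus exons leaves flanks only when exons don't reach the
  # body ends; restrict to internal gaps (true introns)
  if (length(ex) > 0L) {
    introns <- introns[GenomicRanges::start(introns) >
                         min(GenomicRanges::start(ex)) &
                       GenomicRanges::end(introns) <
                         max(GenomicRanges::end(ex))]
  } else {
    introns <- GenomicRanges::GRanges()
  }
  GenomicRanges::reduce(c(tss_win, introns), ignore.strand = TRUE)
}

#' Aggregate peak regulatory impact over gene regulatory domains
#'
#' Per gene and context, sums the RI of every peak whose window overlaps
#' the gene's regulatory domain (a peak inside two genes' domains
#' contributes to both), then normalises each context column.
#'
#' @param genes A `silens_genes` object.
#' @param peaks `GRanges` of scored peak windows.
#' @param ri RI matrix from [regulatory_impact()].
#' @param flank TSS flank (default 200000).
#' @param normalize Apply per-column max-absolute scaling (default TRUE).
#' @return Gene x context matrix; when normalised, the scale divisors are
#'   attached as attribute `"scale"`.
#' @export
aggregate_gene_ri <- function(genes, peaks, ri, flank = 200000L,
                              normalize = TRUE) {
  ids <- S4Vectors::mcols(genes$genes)$gene_id
  ctx <- silens_contexts()
  out <- matrix(0, nrow = length(ids), ncol = length(ctx),
                dimnames = list(ids, ctx))
  for (k in seq_along(ids)) {
    dom <- gene_domains(genes, ids[k], flank)
    hit <- GenomicRanges::countOverlaps(peaks, dom, ignore.strand = TRUE) > 0L
    if (any(hit)) {
      out[k, ] <- colSums(ri[hit, , drop = FALSE])
    }
  }
  zero_rows <- rowSums(out != 0) == 0L
  if (any(zero_rows)) {
    silens_log(sum(zero_rows), " gene(s) with no peak in their regulatory ",
               "domain (zero RI rows)")
  }
  if (normalize) out <- normalize_columns(out) else out
}

#' Scale each column to a maximum absolute value of 1
#'
#' The "scaled to a maximum of 1" rule, implemented as division by the
#' per-column maximum absolute value so that sign is preserved (RI columns
#' can be negative); all-zero columns are left unchanged. Idempotent.
#'
#' @param m Numeric matrix.
#' @return Scaled matrix with attribute `"scale"` (the divisors).
#' @export
normalize_columns <- function(m) {
  sc <- apply(abs(m), 2, max)
  sc[sc == 0] <- 1
  out <- sweep(m, 2, sc, "/")
  attr(out, "scale") <- sc
  out
}

#' @noRd
lasso_fit <- function(X, y, l1) {
  if (sd(y) == 0) {
    # constant response: every coefficient is shrunk to zero
    return(list(w = rep(0, ncol(X)), b = y[1]))
  }
  fit <- glmnet::glmnet(X, y, alpha = 1, lambda = l1, standardize = FALSE,
                        intercept = TRUE, maxit = 1000L)
  list(w = as.numeric(fit$beta), b = as.numeric(fit$a0))
}

#' L1-penalised regression of subtype expression on cell-type profiles
#'
#' Fits `y ~ X` with the lasso (penalty weight `l1` on the coefficient
#' L1 norm under the 1/(2n) squared-error objective). Per trial, genes are
#' partitioned into `folds` folds at random; one model is fitted per
#' training split and its RMSE measured on the held-out fold. The trial
#' RMSE is the mean over folds, the reported RMSE the mean over trials,
#' and the reported weights the average over all fold-models.
#'
#' @param y Response per gene (already scaled to max 1).
#' @param X Gene x feature matrix (columns scaled to max 1).
#' @param l1 Penalty weight (default 1e-4).
#' @param folds,trials Cross-validation folds and independent trials.
#' @param seed Seed; fold assignments are re-drawn each trial.
#' @return A `silens_subtype_model`: list with `weights` (averaged),
#'   `intercept`, `rmse` (mean over trials), `rmse_trials`, `l1`, `folds`,
#'   `trials`.
#' @export
fit_subtype_model <- function(y, X, l1 = 1e-4, folds = 10L, trials = 100L,
                              seed = 1L) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (n < folds) stop("fewer genes (", n, ") than folds (", folds, ")")
  rmse_trials <- numeric(trials)
  wsum <- numeric(ncol(X))
  bsum <- 0
  nmodels <- 0L
  with_seed(seed, {
    for (t in seq_len(trials)) {
      fold_of <- sample(rep_len(seq_len(folds), n))
      fold_rmse <- numeric(folds)
      for (f in seq_len(folds)) {
        test <- fold_of == f
        fit <- lasso_fit(X[!test, , drop = FALSE], y[!test], l1)
        pred <- X[test, , drop = FALSE] %*% fit$w + fit$b
        fold_rmse[f] <- sqrt(mean((y[test] - pred)^2))
        wsum <- wsum + fit$w
        bsum <- bsum + fit$b
        nmodels <- nmodels + 1L
      }
      rmse_trials[t] <- mean(fold_rmse)
    }
  })
  structure(list(
    weights = setNames(wsum / nmodels, colnames(X)),
    intercept = bsum / nmodels,
    rmse = mean(rmse_trials), rmse_trials = rmse_trials,
    l1 = l1, folds = folds, trials = trials
  ), class = "silens_subtype_model")
}

#' @export
print.silens_subtype_model <- function(x, ...) {
  cat(sprintf("<silens_subtype_model> %d features, RMSE %.4f (%d x %d-fold)\n",
              length(x$weights), x$rmse, x$trials, x$folds))
  invisible(x)
}

#' Shuffled-response baseline RMSE
#'
#' Repeats the procedure of [fit_subtype_model()] with the response
#' permuted independently in each trial, giving the chance-level RMSE the
#' model must beat.
#'
#' @inheritParams fit_subtype_model
#' @return List with `rmse` (mean over trials) and `rmse_trials`.
#' @export
shuffled_baseline <- function(y, X, l1 = 1e-4, folds = 10L, trials = 100L,
                              seed = 1L) {
  X <- as.matrix(X)
  n <- length(y)
  if (n < folds) stop("fewer genes (", n, ") than folds (", folds, ")")
  rmse_trials <- numeric(trials)
  with_seed(seed, {
    for (t in seq_len(trials)) {
      ys <- sample(y)
      fold_of <- sample(rep_len(seq_len(folds), n))
      fold_rmse <- numeric(folds)
      for (f in seq_len(folds)) {
        test <- fold_of == f
        fit <- lasso_fit(X[!test, , drop = FALSE], ys[!test], l1)
        pred <- X[test, , drop = FALSE] %*% fit$w + fit$b
        fold_rmse[f] <- sqrt(mean((ys[test] - pred)^2))
      }
      rmse_trials[t] <- mean(fold_rmse)
    }
  })
  list(rmse = mean(rmse_trials), rmse_trials = rmse_trials)
}
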