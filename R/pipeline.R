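#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end run, with the defaults used
#' throughout: FPR target 0.05 for the variant thresholds; locus cut-offs
#' 0.003 (susceptibility-locus merge), 0.005 (class), 0.05 (promoter/exon
#' annotation); L1 penalty 1e-4 with 10-fold cross-validation; chromosome
#' 7/8 holdout.
#'
#' @param outdir Output directory.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param ... Overrides for any default entry.
#' @return Named list (class `silens_run_config`).
#' @export
pipeline_config <- function(outdir = "silens_run", seed = 1L, ...) {
  cfg <- list(
    outdir = outdir,
    seed = as.integer(seed),
    # simulation sizes
    chrom_lengths = c(chr1 = 8e6, chr2 = 8e6, chr7 = 8e6),
    gc = 0.41,
    n_enh = 800L, n_sil = 800L, n_ctrl = 8000L,
    n_disrupting = 400L, n_neutral = 400L,
    # element construction
    promoter_flank = 1000L, dedup_overlap = 600L,
    holdout_chroms = c("chr7", "chr8"),
    # model
    epochs = 10L, batch_size = 64L, learning_rate = 2e-4,
    output_mode = "shared_control_19",
    # fraction of training elements held out for validation-loss model
    # selection; 0 trains on everything for the fixed epoch budget (the
    # weighted cross entropy is a poor ranking selector on these data)
    val_fraction = 0,
    # calibration / variants
    fpr_target = 0.05,
    # loci
    merge_cut = 0.003, class_cut = 0.005, ep_cut = 0.05,
    locus_n_per_class = 2L, locus_n_enriched = 50L,
    # subtype regression
    l1 = 1e-4, folds = 10L, trials = 20L,
    n_genes = 2000L, n_celltypes = 7L, noise_sd = 0.05,
    planted_weights = c(0.8, -0.6, 0.5, -0.4, 0.3, -0.7, 0.2)
  )
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- c("silens_run_config", "list")
  cfg
}

#' @noRd
stage_dir <- function(cfg, ...) {
  d <- file.path(cfg$outdir, ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

#' @noRd
derive_seed <- function(cfg, offset) (cfg$seed * 1000L + offset) %% .Machine$integer.max

# md5 of the resolved configuration, recorded in every output table
#' @noRd
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  yaml::write_yaml(unclass(cfg), f)
  unname(tools::md5sum(f))
}

#' @noRd
stage_table <- function(df, path, cfg) {
  write_tsv_with_header(df, path, comment = sprintf(
    "silens %s  config %s  seed %d",
    as.character(utils::packageVersion("silens")), config_hash(cfg),
    cfg$seed))
}

#' Simulate genome, elements and variants
#'
#' Writes the simulated genome (FASTA), peak files (BED), the variant
#' table (TSV) and all ground-truth tables into `<outdir>/sim/`.
#'
#' @param cfg A [pipeline_config()].
#' @return The simulation objects, invisibly.
#' @export
stage_simulate <- function(cfg) {
  d <- stage_dir(cfg, "sim")
  silens_log("simulate: genome ", sum(cfg$chrom_lengths) / 1e6, " Mb, ",
             cfg$n_enh, "/", cfg$n_sil, "/", cfg$n_ctrl, " elements")
  genome <- make_genome(cfg$chrom_lengths, cfg$gc, derive_seed(cfg, 1L))
  sim <- plant_elements(genome, cfg$n_enh, cfg$n_sil, cfg$n_ctrl,
                        seed = derive_seed(cfg, 2L))
  vars <- make_variants(sim, cfg$n_disrupting, cfg$n_neutral,
                        seed = derive_seed(cfg, 3L))
  fa <- file.path(d, "genome.fa")
  Biostrings::writeXStringSet(sim$genome, fa)
  for (nm in c("dnase", "ac", "me3", "pool")) {
    write_intervals(sim$peaks[[nm]], file.path(d, paste0(nm, ".bed")), "bed3")
  }
  for (cell in names(sim$peaks$atac)) {
    write_intervals(sim$peaks$atac[[cell]],
                    file.path(d, paste0("atac_", cell, ".bed")), "bed3")
  }
  write_variants(vars$variants, file.path(d, "variants.tsv"))
  stage_table(sim$elements, file.path(d, "elements_truth.tsv"), cfg)
  stage_table(sim$motifs, file.path(d, "motifs_truth.tsv"), cfg)
  stage_table(vars$truth, file.path(d, "variants_truth.tsv"), cfg)
  invisible(list(sim = sim, vars = vars))
}

#' Build the labelled training set from the simulated files
#'
#' Reads the peak files back through the package's own IO, applies the
#' element-construction rules, deduplicates, assigns nine-context labels,
#' samples controls at roughly ten per positive from the background pool,
#' and splits by holdout chromosome. Writes `<outdir>/trainset/elements.tsv`.
#'
#' @param cfg A [pipeline_config()].
#' @return List with the labelled `elements` (`GRanges`) and the split.
#' @export
stage_build_trainset <- function(cfg) {
  dsim <- file.path(cfg$outdir, "sim")
  if (!file.exists(file.path(dsim, "genome.fa"))) {
    stop("missing input: ", file.path(dsim, "genome.fa"),
         " (run the simulate stage first)")
  }
  d <- stage_dir(cfg, "trainset")
  genome <- as_genome(file.path(dsim, "genome.fa"))
  seqlen <- setNames(Biostrings::width(genome), names(genome))
  peaks <- lapply(c(dnase = "dnase", ac = "ac", me3 = "me3", pool = "pool"),
                  function(nm) {
                    read_intervals(file.path(dsim, paste0(nm, ".bed")), "bed3")
                  })
  cells <- silens_contexts()[-1]
  atac <- lapply(cells, function(cell) {
    read_intervals(file.path(dsim, paste0("atac_", cell, ".bed")), "bed3")
  })
  names(atac) <- cells

  cand <- call_candidates(peaks$dnase, peaks$ac, peaks$me3, genes = NULL,
                          sample_id = "sim", seqlengths = seqlen)
  cand <- deduplicate_elements(cand, seed = derive_seed(cfg, 4L),
                               max_overlap = cfg$dedup_overlap)
  n_pos <- length(cand)
  ctrl <- sample_controls(peaks$pool,
                          exclusions = list(cand, peaks$dnase, peaks$ac,
                                            peaks$me3),
                          n_controls = min(cfg$n_ctrl, 10L * n_pos),
                          seed = derive_seed(cfg, 5L), seqlengths = seqlen)
  elements <- c(cand, ctrl)
  elements <- label_contexts(elements, atac)
  split <- split_holdout(elements, cfg$holdout_chroms)

  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(elements)),
    start = GenomicRanges::start(elements) - 1L,
    end = GenomicRanges::end(elements),
    klass = S4Vectors::mcols(elements)$klass,
    sample_id = S4Vectors::mcols(elements)$sample_id,
    split = ifelse(as.character(GenomicRanges::seqnames(elements)) %in%
                     cfg$holdout_chroms, "test", "train"),
    stringsAsFactors = FALSE
  )
  for (cx in silens_contexts()) {
    df[[paste0("label_", cx)]] <-
      S4Vectors::mcols(elements)[[paste0("label_", cx)]]
  }
  stage_table(df, file.path(d, "elements.tsv"), cfg)
  invisible(list(elements = elements, split = split))
}

#' @noRd
read_elements_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  for (nm in setdiff(names(df), c("chrom", "start", "end"))) {
    S4Vectors::mcols(gr)[[nm]] <- df[[nm]]
  }
  gr
}

#' Train the sequence model on the built training set
#'
#' Extracts 1-kb window sequences, holds out `val_fraction` of the
#' training elements for early stopping, trains the multitask network and
#' evaluates it on the chromosome-holdout test set. Writes
#' `model.json`, `metrics.tsv` (loss history) and `evaluation.tsv`
#' (per-channel auROC and auPRC at the 1:9 mixture) under
#' `<outdir>/model/`.
#'
#' @param cfg A [pipeline_config()].
#' @return List with the trained `model` and the `evaluation` table.
#' @export
stage_train <- function(cfg) {
  dsim <- file.path(cfg$outdir, "sim")
  dts <- file.path(cfg$outdir, "trainset")
  ep <- file.path(dts, "elements.tsv")
  if (!file.exists(ep)) stop("missing input: ", ep)
  d <- stage_dir(cfg, "model")
  genome <- as_genome(file.path(dsim, "genome.fa"))
  elements <- read_elements_table(ep)
  labs <- context_label_matrix(elements)
  seqs <- window_sequences(genome, elements)
  stopifnot(all(seqs$keep))
  is_test <- S4Vectors::mcols(elements)$split == "test"

  tr_idx <- which(!is_test)
  if (cfg$val_fraction > 0) {
    n_val <- max(1L, round(cfg$val_fraction * length(tr_idx)))
    val_idx <- with_seed(derive_seed(cfg, 6L), sample(tr_idx, n_val))
  } else {
    val_idx <- integer(0)
  }
  fit_idx <- setdiff(tr_idx, val_idx)

  config <- model_config(epochs = cfg$epochs, batch_size = cfg$batch_size,
                         learning_rate = cfg$learning_rate,
                         output_mode = cfg$output_mode,
                         rng_seed = derive_seed(cfg, 7L))
  model <- build_model(config)
  silens_log("train: ", length(fit_idx), " train / ", length(val_idx),
             " val / ",
             sum(is_test), " test; ", format(model$n_params, big.mark = ","),
             " parameters")
  if (length(val_idx)) {
    model <- train_model(model, seqs$seqs[fit_idx],
                         labs[fit_idx, , drop = FALSE],
                         seqs$seqs[val_idx], labs[val_idx, , drop = FALSE])
  } else {
    model <- train_model(model, seqs$seqs[fit_idx],
                         labs[fit_idx, , drop = FALSE])
  }
  save_model(model, file.path(d, "model.json"))
  stage_table(model$history, file.path(d, "metrics.tsv"), cfg)
  evaluation <- evaluate_model(model, seqs$seqs[is_test],
                               labs[is_test, , drop = FALSE],
                               seed = derive_seed(cfg, 8L))
  stage_table(evaluation, file.path(d, "evaluation.tsv"), cfg)
  invisible(list(model = model, evaluation = evaluation))
}

#' Calibrate, score and classify the simulated variants
#'
#' Fits per-context FPR curves on the held-out control elements, derives
#' the thresholds at the target FPR, classifies each variant through the
#' three-branch rule, computes per-context delta-activity for the
#' ref/alt alleles and flags significance against the panel of all scored
#' variants. Writes `<outdir>/variants/variants_scored.tsv` and
#' `thresholds.tsv`.
#'
#' @param cfg A [pipeline_config()].
#' @return The scored variant table, invisibly.
#' @export
stage_score_variants <- function(cfg) {
  dsim <- file.path(cfg$outdir, "sim")
  dmod <- file.path(cfg$outdir, "model")
  mp <- file.path(dmod, "model.json")
  if (!file.exists(mp)) stop("missing input: ", mp, " (train first)")
  d <- stage_dir(cfg, "variants")
  genome <- as_genome(file.path(dsim, "genome.fa"))
  model <- load_model(mp)
  elements <- read_elements_table(file.path(cfg$outdir, "trainset",
                                            "elements.tsv"))
  test_ctrl <- elements[S4Vectors::mcols(elements)$split == "test" &
                          S4Vectors::mcols(elements)$klass == "control"]
  seqs <- window_sequences(genome, test_ctrl)
  ctrl_scores <- predict(model, seqs$seqs)
  calib <- calibrate_contexts(ctrl_scores, target = cfg$fpr_target)
  thr <- data.frame(context = silens_contexts(),
                    c_e = calib$thresholds$c_e, c_s = calib$thresholds$c_s)
  stage_table(thr, file.path(d, "thresholds.tsv"), cfg)

  variants <- read_variants(file.path(dsim, "variants.tsv"), "tsv")
  peaks <- lapply(c(me3 = "me3", ac = "ac", dnase = "dnase"),
                  function(nm) {
                    read_intervals(file.path(dsim, paste0(nm, ".bed")), "bed3")
                  })
  scored <- score_variants(variants, genome, model, peaks, calib)
  # the scored panel itself is the significance background (top/bottom 5%
  # of all scored variants); too small a panel leaves the flag unset
  if (nrow(scored) >= 100L) {
    scored$significant <- call_significance(scored$delta_tissue,
                                            scored$delta_tissue)
  } else {
    silens_log("variant panel too small for significance calls (",
               nrow(scored), " < 100)", level = "WARN")
  }
  delta <- attr(scored, "delta_matrix")
  for (cx in silens_contexts()) {
    scored[[paste0("delta_", cx)]] <- delta[, cx]
  }
  scored$delta_tissue <- delta[, "tissue"]
  stage_table(scored, file.path(d, "variants_scored.tsv"), cfg)
  invisible(scored)
}

#' Run the susceptibility-locus scenario and classify its loci
#'
#' Generates the locus scenario with known classes, builds gene loci from
#' the GTF, merges susceptibility loci, classifies each and compares with
#' the planted truth. Writes `<outdir>/loci/loci.tsv`.
#'
#' @param cfg A [pipeline_config()].
#' @return List with the classified `loci` table, the `truth` and
#'   `accuracy`.
#' @export
stage_classify_loci <- function(cfg) {
  d <- stage_dir(cfg, "loci")
  scen <- make_locus_scenario(cfg$locus_n_per_class, cfg$locus_n_enriched,
                              seed = derive_seed(cfg, 9L),
                              gtf_path = file.path(d, "genes.gtf"),
                              merge_cut = cfg$merge_cut,
                              class_cut = cfg$class_cut)
  gene_loci <- build_gene_loci(scen$genes, scen$seqlengths)
  adsnvs <- scen$variants[S4Vectors::mcols(scen$variants)$assoc_p < 1e-5]
  sus <- merge_susceptibility_loci(gene_loci, adsnvs, scen$genome_size,
                                   p_cut = cfg$merge_cut)
  ch <- S4Vectors::mcols(scen$variants)$channel
  rad_sil <- scen$variants[ch == "silencer"]
  rad_enh <- scen$variants[ch == "enhancer"]
  tab <- classify_loci(sus, rad_sil, rad_enh, scen$genome_size,
                       p_cut = cfg$class_cut)
  truth <- scen$truth
  key <- function(df) paste(df$chrom, df$start, df$end)
  m <- match(key(truth), key(tab))
  truth$predicted <- tab$klass[m]
  accuracy <- mean(truth$predicted == truth$klass, na.rm = FALSE)
  stage_table(tab, file.path(d, "loci.tsv"), cfg)
  stage_table(truth, file.path(d, "loci_truth.tsv"), cfg)
  silens_log("classify-loci: ", nrow(truth), " designated loci, accuracy ",
             signif(accuracy, 3))
  invisible(list(loci = tab, truth = truth, accuracy = accuracy))
}

#' Subtype-expression regression on synthetic features
#'
#' Generates normalised cell-type features and a subtype expression vector
#' from planted mixed-sign weights plus Gaussian noise, fits the
#' L1-penalised regression with cross-validated RMSE, and compares against
#' the shuffled baseline. Writes `<outdir>/subtype/weights.tsv` and
#' `rmse.tsv`.
#'
#' @param cfg A [pipeline_config()].
#' @return List with the fitted model, baseline, weight correlation.
#' @export
stage_subtype_regress <- function(cfg) {
  d <- stage_dir(cfg, "subtype")
  X <- make_ri_features(cfg$n_genes, cfg$n_celltypes,
                        seed = derive_seed(cfg, 10L))
  sim <- make_subtype_expression(X, cfg$planted_weights, cfg$noise_sd,
                                 seed = derive_seed(cfg, 11L))
  fit <- fit_subtype_model(sim$y, X, l1 = cfg$l1, folds = cfg$folds,
                           trials = cfg$trials,
                           seed = derive_seed(cfg, 12L))
  base <- shuffled_baseline(sim$y, X, l1 = cfg$l1, folds = cfg$folds,
                            trials = cfg$trials,
                            seed = derive_seed(cfg, 13L))
  wc <- cor(sim$weights, fit$weights)
  wt <- data.frame(celltype = colnames(X),
                   planted = sim$weights / sim$scale,
                   recovered = fit$weights)
  stage_table(wt, file.path(d, "weights.tsv"), cfg)
  stage_table(
    data.frame(model_rmse = fit$rmse, shuffled_rmse = base$rmse,
               weight_correlation = wc),
    file.path(d, "rmse.tsv"), cfg)
  silens_log("subtype-regress: RMSE ", signif(fit$rmse, 3), " vs shuffled ",
             signif(base$rmse, 3), ", weight cor ", signif(wc, 3))
  invisible(list(fit = fit, baseline = base, weight_correlation = wc))
}

#' Evaluate variant-direction recovery
#'
#' Compares the sign of the tissue-context delta-activity of the planted
#' motif-disrupting variants with their known direction and reports the
#' directional concordance rate.
#'
#' @param cfg A [pipeline_config()].
#' @return List with `dcr`, counts, and the merged table.
#' @export
stage_evaluate <- function(cfg) {
  vs <- file.path(cfg$outdir, "variants", "variants_scored.tsv")
  vt <- file.path(cfg$outdir, "sim", "variants_truth.tsv")
  if (!file.exists(vs)) stop("missing input: ", vs)
  scored <- read.table(vs, header = TRUE, sep = "\t", comment.char = "#",
                       stringsAsFactors = FALSE)
  truth <- read.table(vt, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE)
  m <- merge(scored, truth, by = "id")
  disrupting <- m$expected_sign != 0
  dc <- directional_concordance(m$delta_tissue[disrupting],
                                m$expected_sign[disrupting])
  out <- list(dcr = dc$dcr, n_disrupting = sum(disrupting),
              n_zero_delta = dc$n_zero, table = m)
  silens_log("evaluate: direction concordance ", signif(dc$dcr, 3), " over ",
             dc$n_used, " variants")
  jsonlite::write_json(out[c("dcr", "n_disrupting", "n_zero_delta")],
                       file.path(cfg$outdir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Run the full pipeline
#'
#' simulate, build-trainset, train, score-variants, classify-loci,
#' subtype-regress, evaluate — in order, with all artifacts under
#' `cfg$outdir` and the resolved configuration written beside them.
#'
#' @param cfg A [pipeline_config()] (or arguments forwarded to it).
#' @param ... Overrides forwarded to [pipeline_config()] when `cfg` is a
#'   directory path.
#' @return List of per-stage results (model evaluation, variant DCR, locus
#'   accuracy, regression metrics).
#' @export
run_pipeline <- function(cfg = pipeline_config(), ...) {
  if (is.character(cfg)) cfg <- pipeline_config(outdir = cfg, ...)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(cfg$outdir, "config.yaml"))
  stage_simulate(cfg)
  stage_build_trainset(cfg)
  tr <- stage_train(cfg)
  stage_score_variants(cfg)
  lc <- stage_classify_loci(cfg)
  sr <- stage_subtype_regress(cfg)
  ev <- stage_evaluate(cfg)
  list(evaluation = tr$evaluation,
       history = tr$model$history,
       dcr = ev$dcr,
       locus_accuracy = lc$accuracy,
       locus_truth = lc$truth,
       subtype = list(rmse = sr$fit$rmse, shuffled_rmse = sr$baseline$rmse,
                      weight_correlation = sr$weight_correlation),
       config = cfg)
}

#' Command-line interface
#'
#' Thin shell over the pipeline stages; installed as `exec/silens`.
#' Usage: `silens <subcommand> [--config file.yaml] [--outdir dir]
#' [--seed n] [--log-level LEVEL]` with subcommands `simulate`,
#' `build-trainset`, `train`, `score-variants`, `classify-loci`,
#' `subtype-regress`, `evaluate`, `run-all`.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 success, 1 runtime error, 2 usage or
#'   configuration error).
#' @export
silens_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  stages <- c("simulate", "build-trainset", "train", "score-variants",
              "classify-loci", "subtype-regress", "evaluate", "run-all")
  if (length(args) < 1L || !(args[1] %in% stages)) {
    message("usage: silens <", paste(stages, collapse = "|"), "> ",
            "[--config file.yaml] [--outdir dir] [--seed n] ",
            "[--log-level DEBUG|INFO|WARN]")
    return(2L)
  }
  sub <- args[1]
  opts <- list(outdir = "silens_run", seed = 1L, config = NULL,
               log_level = "INFO")
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    key <- gsub("-", "_", key)
    if (!(key %in% names(opts)) || i == length(args)) {
      message("unknown or incomplete option: ", args[i])
      return(2L)
    }
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  options(silens.log_level = opts$log_level)
  over <- list()
  if (!is.null(opts$config)) {
    if (!file.exists(opts$config)) {
      message("config file not found: ", opts$config)
      return(2L)
    }
    over <- yaml::read_yaml(opts$config)
  }
  over$outdir <- opts$outdir
  over$seed <- as.integer(opts$seed)
  cfg <- tryCatch(do.call(pipeline_config, over),
                  error = function(e) e)
  if (inherits(cfg, "error")) {
    message("invalid configuration: ", conditionMessage(cfg))
    return(2L)
  }
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(cfg$outdir, "config.yaml"))
  run <- switch(sub,
    "simulate" = function() stage_simulate(cfg),
    "build-trainset" = function() stage_build_trainset(cfg),
    "train" = function() stage_train(cfg),
    "score-variants" = function() stage_score_variants(cfg),
    "classify-loci" = function() stage_classify_loci(cfg),
    "subtype-regress" = function() stage_subtype_regress(cfg),
    "evaluate" = function() stage_evaluate(cfg),
    "run-all" = function() run_pipeline(cfg))
  res <- tryCatch({ run(); 0L }, error = function(e) {
    message("error in stage '", sub, "': ", conditionMessage(e))
    if (grepl("missing input", conditionMessage(e))) 2L else 1L
  })
  res
}
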