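#' @keywords internal
#' Evaluate an expression under a temporary RNG state.
#'
#' All stochastic operations in the package take an explicit seed and leave
#' the caller's RNG stream untouched.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(as.integer(seed))
  }
  expr
}

#' @noRd
silens_log <- function(..., level = "INFO") {
  lv <- getOption("silens.log_level", "INFO")
  ranks <- c(DEBUG = 1L, INFO = 2L, WARN = 3L, ERROR = 4L)
  if (ranks[[level]] >= ranks[[lv]]) {
    message(sprintf("[%s] [%s] %s", format(Sys.time(), "%H:%M:%S"), level,
                    paste0(...)))
  }
  invisible(NULL)
}

#' Cellular contexts scored by the model
#'
#' The first context is the bulk tissue; the remaining eight are the major
#' brain cell types resolved by single-cell chromatin accessibility.
#'
#' @return Character vector of nine context names.
#' @export
silens_contexts <- function() {
  c("tissue", "astrocyte", "endothelia", "excitatory_neuron",
    "inhibitory_neuron", "immune", "microglia", "oligodendrocyte",
    "opc")
}

#' @noRd
element_classes <- function() c("enhancer", "silencer", "control")

# Area under the precision-recall curve, computed as average precision
# (precision integrated over recall steps at each positive).
#' @noRd
average_precision <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  o <- order(scores, decreasing = TRUE)
  y <- as.integer(labels[o])
  npos <- sum(y)
  if (npos == 0L) return(NA_real_)
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  sum(prec[y == 1L]) / npos
}

#' @noRd
auroc <- function(scores, labels) {
  as.numeric(pROC::auc(pROC::roc(
    response = as.integer(labels), predictor = as.numeric(scores),
    levels = c(0, 1), direction = "<", quiet = TRUE
  )))
}

#' @noRd
write_tsv_with_header <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) {
    writeLines(paste0("# ", comment), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
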