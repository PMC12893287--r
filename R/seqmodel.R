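#' Model configuration
#'
#' Hyperparameters of the multitask convolutional sequence model. The layer
#' stack is: 1D convolution (64 kernels, width 4, stride 1, ReLU), max
#' pooling (width 3, stride 2), dropout 0.2, 1D convolution (128 kernels,
#' width 3, stride 1, ReLU), dropout 0.2, dense 100 (sigmoid), dense 50
#' (sigmoid), then per-context 3-way softmax outputs over
#' enhancer/silencer/control.
#'
#' @param seq_length Input window length (1000).
#' @param output_mode `"shared_control_19"` (default): 19 output nodes —
#'   per-context enhancer and silencer logits plus one control logit shared
#'   across the nine softmax groups. `"per_context_27"`: an independent
#'   3-node output group per context (27 nodes).
#' @param epochs,batch_size,learning_rate Optimiser settings (adaptive
#'   moment estimation).
#' @param dropout1,dropout2 Dropout proportions after pooling and after the
#'   second convolution.
#' @param class_weights `"balanced"` (per-context weights inversely
#'   proportional to class frequency) or `"none"`.
#' @param weight_decay Decoupled weight decay applied to the dense weight
#'   matrices; regularises the high-dimensional flatten-to-dense layer so
#'   the network generalises from motif content rather than memorising
#'   training windows.
#' @param lr_conv_mult Learning-rate multiplier for the two convolution
#'   layers relative to the base rate.
#' @param lr_w3_mult Learning-rate multiplier for the flatten-to-dense
#'   weight matrix. Its 63k-wide fan-in makes full-rate adaptive steps
#'   saturate the sigmoid units and memorise training windows; throttling
#'   this one matrix lets the rest of the network train at a healthy
#'   rate.
#' @param adam_restart Re-initialise the optimiser moments every this many
#'   epochs (0 = never); a brief enlargement of the normalised steps after
#'   each restart.
#' @param head_init_scale Multiplier on the Glorot scale for the two dense
#'   head matrices (dense-100 to dense-50, and dense-50 to output). At
#'   standard scale the head's random projection of the trunk features is
#'   frequently too weak to couple the class error back into the trunk,
#'   and training sits on the uniform-prediction plateau for many epochs;
#'   a wider head init makes the coupling reliable across initialisation
#'   seeds.
#' @param augment_rc Train on each sequence and its reverse complement
#'   (labels copied), the standard augmentation for strand-symmetric
#'   regulatory signals.
#' @param patience Early-stopping patience on validation loss, in epochs.
#' @param rng_seed Seed for weight initialisation, shuffling and dropout.
#' @return A `silens_config` list.
#' @export
model_config <- function(seq_length = 1000L,
                         output_mode = c("shared_control_19", "per_context_27"),
                         epochs = 10L, batch_size = 64L, learning_rate = 2e-4,
                         dropout1 = 0.2, dropout2 = 0.2,
                         class_weights = c("balanced", "none"),
                         weight_decay = 3, lr_conv_mult = 3,
                         lr_w3_mult = 1, adam_restart = 2L,
                         head_init_scale = 5,
                         augment_rc = FALSE,
                         patience = 5L, rng_seed = 1L) {
  output_mode <- match.arg(output_mode)
  class_weights <- match.arg(class_weights)
  cfg <- list(
    seq_length = as.integer(seq_length),
    conv1 = list(kernels = 64L, width = 4L, stride = 1L),
    pool = list(width = 3L, stride = 2L),
    dropout1 = dropout1,
    conv2 = list(kernels = 128L, width = 3L, stride = 1L),
    dropout2 = dropout2,
    dense1 = 100L, dense2 = 50L,
    n_contexts = 9L,
    output_mode = output_mode,
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    learning_rate = learning_rate,
    class_weights = class_weights,
    weight_decay = weight_decay,
    lr_conv_mult = lr_conv_mult,
    lr_w3_mult = lr_w3_mult,
    adam_restart = as.integer(adam_restart),
    head_init_scale = head_init_scale,
    augment_rc = isTRUE(augment_rc),
    patience = as.integer(patience),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "silens_config"
  cfg
}

#' @noRd
output_nodes <- function(cfg) {
  if (cfg$output_mode == "shared_control_19") 2L * cfg$n_contexts + 1L
  else 3L * cfg$n_contexts
}

#' One-hot encode a DNA sequence
#'
#' @param seq Character string over A/C/G/T/N (case-insensitive).
#' @return `length(seq)` x 4 numeric matrix, columns A, C, G, T; an `N`
#'   yields an all-zero row.
#' @examples
#' one_hot("ACGT")  # 4x4 identity
#' @export
one_hot <- function(seq) {
  codes <- encode_seqs(seq)[, 1]
  L <- length(codes)
  m <- matrix(0, nrow = L, ncol = 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  ok <- codes < 4L
  m[cbind(which(ok), codes[ok] + 1L)] <- 1
  m
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# reverse complement on the integer code matrix: A<->T (0<->3), C<->G
# (1<->2), N (4) unchanged; positions reversed
#' @noRd
revcomp_codes <- function(codes) {
  comp <- c(3L, 2L, 1L, 0L, 4L)
  m <- matrix(comp[codes + 1L], nrow = nrow(codes))
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

# character vector of sequences -> integer code matrix L x n
# (0=A,1=C,2=G,3=T,4=N)
#' @noRd
encode_seqs <- function(seqs) {
  lut <- rep(4L, 256)
  lut[utf8ToInt("A") + 1L] <- 0L; lut[utf8ToInt("a") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L; lut[utf8ToInt("c") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L; lut[utf8ToInt("g") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L; lut[utf8ToInt("t") + 1L] <- 3L
  lut[utf8ToInt("N") + 1L] <- 4L; lut[utf8ToInt("n") + 1L] <- 4L
  allowed <- c(utf8ToInt("A"), utf8ToInt("C"), utf8ToInt("G"), utf8ToInt("T"),
               utf8ToInt("N"), utf8ToInt("a"), utf8ToInt("c"), utf8ToInt("g"),
               utf8ToInt("t"), utf8ToInt("n"))
  Ls <- nchar(seqs)
  if (length(unique(Ls)) != 1L) stop("sequences must all have the same length")
  raw <- lapply(seqs, function(s) utf8ToInt(s))
  bad <- vapply(raw, function(r) any(!(r %in% allowed)), logical(1))
  if (any(bad)) {
    stop("sequence contains characters outside A/C/G/T/N")
  }
  m <- vapply(raw, function(r) lut[r + 1L], integer(Ls[1]))
  matrix(m, nrow = Ls[1])
}

#' Build an untrained sequence model
#'
#' Initialises all layer weights (Glorot-uniform, seeded from
#' `config$rng_seed`) for the architecture described in [model_config()].
#'
#' @param config A `silens_config`.
#' @return A `silens_model` with elements `config`, `weights`, `trained`
#'   (FALSE) and `n_params`.
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "silens_config"))
  L <- config$seq_length
  k1 <- config$conv1$width; n1 <- config$conv1$kernels
  k2 <- config$conv2$width; n2 <- config$conv2$kernels
  L1 <- L - k1 + 1L
  Lp <- (L1 - config$pool$width) %/% config$pool$stride + 1L
  L2 <- Lp - k2 + 1L
  flat <- L2 * n2
  K <- output_nodes(config)
  glorot <- function(nin, nout) {
    lim <- sqrt(6 / (nin + nout))
    matrix(runif(nin * nout, -lim, lim), nin, nout)
  }
  hs <- config$head_init_scale %||% 1
  weights <- with_seed(config$rng_seed, list(
    W1 = glorot(4L * k1, n1), b1 = matrix(0, 1, n1),
    W2 = glorot(k2 * n1, n2), b2 = matrix(0, 1, n2),
    W3 = glorot(flat, config$dense1), b3 = matrix(0, 1, config$dense1),
    W4 = hs * glorot(config$dense1, config$dense2),
    b4 = matrix(0, 1, config$dense2),
    W5 = hs * glorot(config$dense2, K), b5 = matrix(0, 1, K)
  ))
  n_params <- sum(vapply(weights, length, integer(1)))
  structure(list(config = config, weights = weights, trained = FALSE,
                 history = NULL, n_params = n_params),
            class = "silens_model")
}

#' @export
print.silens_model <- function(x, ...) {
  cat(sprintf(
    "<silens_model> %s, %d output nodes, %s parameters, %s\n",
    x$config$output_mode, output_nodes(x$config),
    format(x$n_params, big.mark = ","),
    if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' @noRd
encode_labels <- function(label_matrix) {
  ctx <- silens_contexts()
  stopifnot(ncol(label_matrix) == length(ctx))
  code <- matrix(match(label_matrix, c("enhancer", "silencer", "control")) - 1L,
                 nrow = nrow(label_matrix))
  if (any(is.na(code))) stop("labels must be enhancer/silencer/control")
  storage.mode(code) <- "integer"
  code
}

#' @noRd
balanced_class_weights <- function(codes) {
  w <- matrix(1, nrow = ncol(codes), ncol = 3)
  for (c in seq_len(ncol(codes))) {
    cnt <- tabulate(codes[, c] + 1L, nbins = 3L)
    present <- cnt > 0L
    w[c, present] <- sum(cnt) / (sum(present) * cnt[present])
    w[c, !present] <- 0
  }
  w
}

#' Train the multitask sequence model
#'
#' Minimises the sum over the nine contexts of the 3-class cross entropy,
#' with mini-batch adaptive-moment optimisation. When a validation set is
#' supplied, the weights with the best validation loss are kept
#' (early stopping with `config$patience`).
#'
#' @param model A `silens_model` from [build_model()].
#' @param train_seqs Character vector of training sequences (length
#'   `config$seq_length`).
#' @param train_labels Character matrix `n x 9` over
#'   enhancer/silencer/control (column order `silens_contexts()`).
#' @param val_seqs,val_labels Optional validation set in the same form.
#' @return The model with trained weights and a `history` data frame of
#'   per-epoch training/validation loss.
#' @details Every class must be present in at least one context of the
#'   training labels; an all-control training set is rejected. Training is
#'   deterministic for a fixed seed and fixed BLAS thread settings.
#' @export
train_model <- function(model, train_seqs, train_labels,
                        val_seqs = NULL, val_labels = NULL) {
  stopifnot(inherits(model, "silens_model"))
  cfg <- model$config
  codes <- encode_seqs(train_seqs)
  labs <- encode_labels(train_labels)
  if (nrow(labs) != ncol(codes)) stop("sequence/label count mismatch")
  if (isTRUE(cfg$augment_rc)) {
    codes <- cbind(codes, revcomp_codes(codes))
    labs <- rbind(labs, labs)
  }
  present <- sort(unique(as.vector(labs)))
  for (k in 0:1) {
    if (!(k %in% present)) {
      stop("class '", c("enhancer", "silencer")[k + 1L],
           "' absent from every context of the training labels")
    }
  }
  if (!is.null(val_seqs)) {
    vcodes <- encode_seqs(val_seqs)
    vlabs <- encode_labels(val_labels)
  } else {
    vcodes <- matrix(integer(0), nrow = nrow(codes), ncol = 0)
    vlabs <- matrix(integer(0), nrow = 0, ncol = ncol(labs))
  }
  cw <- if (cfg$class_weights == "balanced") balanced_class_weights(labs)
        else matrix(1, nrow = cfg$n_contexts, ncol = 3)
  hyper <- list(
    epochs = cfg$epochs, batch_size = cfg$batch_size,
    learning_rate = cfg$learning_rate,
    dropout1 = cfg$dropout1, dropout2 = cfg$dropout2,
    mode = if (cfg$output_mode == "shared_control_19") 19L else 27L,
    pool_width = cfg$pool$width, pool_stride = cfg$pool$stride,
    patience = cfg$patience, seed = cfg$rng_seed,
    weight_decay = cfg$weight_decay %||% 0,
    lr_conv_mult = cfg$lr_conv_mult %||% 1,
    lr_w3_mult = cfg$lr_w3_mult %||% 1,
    adam_restart = cfg$adam_restart %||% 0L,
    class_weights = cw
  )
  fit <- .cnn_train(codes, labs, vcodes, vlabs, model$weights, hyper)
  model$weights <- fit$weights
  model$history <- data.frame(
    epoch = fit$history$epoch,
    train_loss = fit$history$train_loss,
    val_loss = if (is.null(fit$history$val_loss)) NA_real_
               else fit$history$val_loss
  )
  model$best_epoch <- fit$best_epoch
  model$trained <- TRUE
  model
}

#' Score sequences with a trained model
#'
#' @param object A `silens_model`.
#' @param seqs Character vector of sequences of length
#'   `config$seq_length`.
#' @param ... Unused.
#' @return Numeric array `n x 9 x 3` of class probabilities
#'   (`dimnames`: sequence, context, `c("enhancer","silencer","control")`).
#'   Each context triple sums to one; inference is deterministic (dropout
#'   disabled).
#' @export
predict.silens_model <- function(object, seqs, ...) {
  cfg <- object$config
  codes <- encode_seqs(seqs)
  if (nrow(codes) != cfg$seq_length) {
    stop("sequences must have length ", cfg$seq_length)
  }
  hyper <- list(
    mode = if (cfg$output_mode == "shared_control_19") 19L else 27L,
    pool_width = cfg$pool$width, pool_stride = cfg$pool$stride
  )
  p <- .cnn_predict(codes, object$weights, hyper)
  arr <- array(NA_real_, dim = c(nrow(p), cfg$n_contexts, 3L),
               dimnames = list(NULL, silens_contexts(),
                               c("enhancer", "silencer", "control")))
  for (c in seq_len(cfg$n_contexts)) {
    arr[, c, ] <- p[, (3L * (c - 1L) + 1L):(3L * c), drop = FALSE]
  }
  arr
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a plain-text JSON archive embedding the configuration
#' and all weight matrices.
#'
#' @param model A `silens_model`.
#' @param path Checkpoint path (`.json`).
#' @return `path` invisibly (save); the restored `silens_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "silens_model"))
  payload <- list(
    config = unclass(model$config),
    weights = lapply(model$weights, function(w) {
      d <- dim(w)
      if (is.null(d)) d <- c(1L, length(w))
      list(dim = d, data = as.numeric(w))
    }),
    trained = model$trained,
    n_params = model$n_params
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- payload$config
  cfg$conv1 <- as.list(cfg$conv1); cfg$conv2 <- as.list(cfg$conv2)
  cfg$pool <- as.list(cfg$pool)
  class(cfg) <- "silens_config"
  weights <- lapply(payload$weights, function(w) {
    matrix(w$data, nrow = w$dim[1], ncol = w$dim[2])
  })
  structure(list(config = cfg, weights = weights,
                 trained = isTRUE(payload$trained), history = NULL,
                 n_params = payload$n_params),
            class = "silens_model")
}

#' Evaluate a model on labelled held-out sequences
#'
#' Computes, per context and channel, the area under the ROC curve of the
#' channel score for true-class versus control sequences, and the average
#' precision (auPRC) on a mixture subsampled to a 1:9 positive-to-control
#' ratio (controls are subsampled, or positives if controls are scarcer).
#'
#' @param model Trained `silens_model`.
#' @param seqs Character vector of sequences.
#' @param labels Character label matrix `n x 9`.
#' @param contexts Contexts to evaluate (default: tissue only).
#' @param ratio Positive:control ratio for auPRC (default 1:9).
#' @param seed Seed for the mixture subsampling.
#' @return `data.frame` with context, channel, n_pos, n_ctrl, auroc, auprc.
#' @export
evaluate_model <- function(model, seqs, labels, contexts = "tissue",
                           ratio = 1 / 9, seed = 1L) {
  scores <- predict(model, seqs)
  out <- list()
  for (cx in contexts) {
    ci <- match(cx, silens_contexts())
    lab <- labels[, ci]
    for (channel in c("enhancer", "silencer")) {
      pos <- which(lab == channel)
      ctrl <- which(lab == "control")
      if (length(pos) == 0L || length(ctrl) == 0L) next
      sc <- scores[, ci, channel]
      roc_auc <- auroc(sc[c(pos, ctrl)],
                       c(rep(1L, length(pos)), rep(0L, length(ctrl))))
      # subsample to the reference 1:9 mixture for average precision
      n_ctrl_target <- round(length(pos) / ratio)
      mix <- with_seed(seed, {
        if (length(ctrl) >= n_ctrl_target) {
          list(pos = pos, ctrl = sample(ctrl, n_ctrl_target))
        } else {
          list(pos = sample(pos, max(1L, round(length(ctrl) * ratio))),
               ctrl = ctrl)
        }
      })
      ap <- average_precision(
        sc[c(mix$pos, mix$ctrl)],
        c(rep(1L, length(mix$pos)), rep(0L, length(mix$ctrl))))
      out[[length(out) + 1L]] <- data.frame(
        context = cx, channel = channel,
        n_pos = length(pos), n_ctrl = length(ctrl),
        auroc = roc_auc, auprc = ap)
    }
  }
  do.call(rbind, out)
}
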