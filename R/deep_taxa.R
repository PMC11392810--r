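# integer encoding of reads: 1..5 = A,C,G,T,N, 0 = right padding
.seqs_to_int <- function(sequences, max_len = 150L) {
  n <- length(sequences)
  lens <- nchar(sequences)
  if (any(lens > max_len)) {
    stop("read ", which(lens > max_len)[1], " longer than ", max_len, " nt")
  }
  out <- matrix(0L, n, max_len)
  alphabet <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)
  for (i in seq_len(n)) {
    if (lens[i] == 0L) next
    ch <- strsplit(sequences[i], "", fixed = TRUE)[[1]]
    v <- alphabet[ch]
    if (anyNA(v)) {
      p <- which(is.na(v))[1]
      stop("read ", i, " position ", p, ": character '", ch[p],
           "' outside A/C/G/T/N")
    }
    out[i, seq_len(lens[i])] <- v
  }
  list(seqs = out, lengths = as.integer(lens))
}

#' One-hot encode reads for the deep classifier
#'
#' Channel order (A, C, G, T, N); reads are right-padded with all-zero
#' vectors up to `max_len` and the mask marks real positions.
#'
#' @param sequences Character vector of reads (<= `max_len` nt over
#'   A/C/G/T/N).
#' @param max_len Padded length (default 150).
#' @return List: `tensor` (n x max_len x 5 array), `mask` (n x max_len
#'   logical), `lengths`.
#' @export
encode_reads <- function(sequences, max_len = 150L) {
  enc <- .seqs_to_int(sequences, max_len)
  n <- length(sequences)
  tensor <- array(0, dim = c(n, max_len, 5L),
                  dimnames = list(NULL, NULL, c("A", "C", "G", "T", "N")))
  for (i in seq_len(n)) {
    for (t in seq_len(enc$lengths[i])) tensor[i, t, enc$seqs[i, t]] <- 1
  }
  mask <- outer(enc$lengths, seq_len(max_len), `>=`)
  list(tensor = tensor, mask = mask, lengths = enc$lengths)
}

#' Deep classifier architecture configuration
#'
#' Layer order: masking of padded positions, four parallel 1-D convolution
#' branches (kernel sizes 15, 17, 19, 23, ReLU, same padding), concatenation,
#' dropout 0.5, two bidirectional LSTM layers, dropout 0.2, dense ReLU,
#' dropout 0.1, dense ReLU, softmax over genera.
#'
#' @param n_classes Number of genera (>= 2).
#' @param kernels Convolution kernel sizes.
#' @param filters Filters per convolution branch.
#' @param recurrent_units Hidden units per LSTM direction per layer.
#' @param dense_units Widths of the two dense layers.
#' @param dropout The three dropout rates.
#' @param max_len Padded read length.
#' @return List of class `deep_taxa_config`.
#' @export
deep_taxa_config <- function(n_classes, kernels = c(15L, 17L, 19L, 23L),
                             filters = 32L, recurrent_units = 48L,
                             dense_units = c(96L, 48L),
                             dropout = c(0.5, 0.2, 0.1), max_len = 150L) {
  if (n_classes < 2) stop("n_classes must be >= 2")
  stopifnot(all(dropout >= 0), all(dropout < 1), all(kernels %% 2 == 1))
  structure(list(n_classes = as.integer(n_classes),
                 kernels = as.integer(kernels), filters = as.integer(filters),
                 recurrent_units = as.integer(recurrent_units),
                 dense_units = as.integer(dense_units), dropout = dropout,
                 max_len = as.integer(max_len)),
            class = "deep_taxa_config")
}

# Glorot-uniform matrix
.glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

.lstm_init <- function(n_in, H) {
  b <- rep(0, 4 * H)
  b[(H + 1):(2 * H)] <- 1       # forget-gate bias at 1
  list(Wx = .glorot(n_in, 4 * H), Wh = .glorot(H, 4 * H), b = b)
}

#' Build an (unfitted) deep genus classifier
#'
#' Initializes Glorot-uniform weights for the architecture in
#' [deep_taxa_config()]; deterministic under the seed.
#'
#' @param classes Character vector of genus labels (the output vocabulary).
#' @param config A [deep_taxa_config()]; defaults to the reference
#'   architecture with `n_classes = length(classes)`.
#' @param seed Integer seed for initialization.
#' @return A `deep_taxa_model` (unfitted).
#' @export
build_deep_model <- function(classes, config = NULL, seed = 1L) {
  classes <- sort(unique(as.character(classes)))
  if (is.null(config)) config <- deep_taxa_config(length(classes))
  if (config$n_classes != length(classes)) {
    stop("config n_classes does not match the class vocabulary")
  }
  F <- config$filters; H <- config$recurrent_units
  C <- F * length(config$kernels)
  D <- config$dense_units
  w <- withr::with_seed(seed, {
    w <- list()
    for (k in config$kernels) {
      w[[paste0("conv_w_", k)]] <- .glorot(5L * k, F)
      w[[paste0("conv_b_", k)]] <- rep(0, F)
    }
    for (dir in c("fwd", "bwd")) {
      l1 <- .lstm_init(C, H)
      w[[paste0("lstm1_", dir, "_Wx")]] <- l1$Wx
      w[[paste0("lstm1_", dir, "_Wh")]] <- l1$Wh
      w[[paste0("lstm1_", dir, "_b")]] <- l1$b
      l2 <- .lstm_init(2L * H, H)
      w[[paste0("lstm2_", dir, "_Wx")]] <- l2$Wx
      w[[paste0("lstm2_", dir, "_Wh")]] <- l2$Wh
      w[[paste0("lstm2_", dir, "_b")]] <- l2$b
    }
    w$dense1_W <- .glorot(2L * H, D[1]); w$dense1_b <- rep(0, D[1])
    w$dense2_W <- .glorot(D[1], D[2]); w$dense2_b <- rep(0, D[2])
    w$out_W <- .glorot(D[2], config$n_classes)
    w$out_b <- rep(0, config$n_classes)
    w
  })
  structure(list(classes = classes, config = config, weights = w,
                 fitted = FALSE, history = NULL, n_params = n_params_deep(config)),
            class = "deep_taxa_model")
}

#' Trainable parameter count of the architecture
#'
#' Closed-form layer-size arithmetic for a [deep_taxa_config()].
#'
#' @param config A [deep_taxa_config()].
#' @return Integer parameter count.
#' @export
n_params_deep <- function(config) {
  F <- config$filters; H <- config$recurrent_units
  C <- F * length(config$kernels); D <- config$dense_units
  conv <- sum(5L * config$kernels * F + F)
  lstm1 <- 2L * (C * 4L * H + H * 4L * H + 4L * H)
  lstm2 <- 2L * (2L * H * 4L * H + H * 4L * H + 4L * H)
  dense <- 2L * H * D[1] + D[1] + D[1] * D[2] + D[2]
  out <- D[2] * config$n_classes + config$n_classes
  conv + lstm1 + lstm2 + dense + out
}

#' @export
print.deep_taxa_model <- function(x, ...) {
  cat("<deep_taxa_model> ", length(x$classes), " genera, ", x$n_params,
      " trainable parameters, ", if (x$fitted) "fitted" else "unfitted",
      "\n", sep = "")
  invisible(x)
}

#' Training configuration
#'
#' @param split Training fraction (default 0.8; the rest is held out for
#'   evaluation; `split = 1` trains on everything).
#' @param max_epochs Maximum epochs (default 15).
#' @param patience Early-stop patience: training stops when the training loss
#'   has not decreased in this many consecutive epochs (default 5).
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param seed Integer seed (shuffling, dropout, split).
#' @return List of class `deep_train_config`.
#' @export
deep_train_config <- function(split = 0.8, max_epochs = 15L, patience = 5L,
                              batch_size = 64L, learning_rate = 1e-3,
                              seed = 1L) {
  stopifnot(split > 0, split <= 1)
  structure(list(split = split, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "deep_train_config")
}

#' Train the deep genus classifier
#'
#' Categorical cross-entropy minimized with Adam; every epoch starts by
#' shuffling the training data; training stops at `max_epochs` or when the
#' training loss has not decreased for `patience` consecutive epochs.
#' Deterministic under a fixed seed and single-threaded execution.
#'
#' @param model A `deep_taxa_model` from [build_deep_model()].
#' @param sequences Reads (<= 150 nt).
#' @param labels Genus label per read; every class in the model vocabulary
#'   must be present in the training split.
#' @param config A [deep_train_config()].
#' @return The fitted model, with `history` (tibble: epoch, loss, accuracy)
#'   and, when `split < 1`, `heldout` metrics from [evaluate_model()].
#' @export
train_deep <- function(model, sequences, labels, config = deep_train_config()) {
  labels <- as.character(labels)
  if (!all(labels %in% model$classes)) {
    stop("label(s) outside the model's class vocabulary: ",
         setdiff(labels, model$classes)[1])
  }
  enc <- .seqs_to_int(sequences, model$config$max_len)
  y <- match(labels, model$classes)
  n <- length(sequences)
  w <- model$weights
  adam_m <- lapply(w, function(x) x * 0)
  adam_v <- lapply(w, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8; t_adam <- 0L
  lr <- config$learning_rate
  history <- list()
  withr::with_seed(config$seed, {
    if (config$split < 1) {
      idx <- sample.int(n)
      n_train <- floor(config$split * n)
      train_idx <- idx[seq_len(n_train)]
      test_idx <- idx[-seq_len(n_train)]
    } else {
      train_idx <- seq_len(n); test_idx <- integer(0)
    }
    missing_cls <- setdiff(model$classes, labels[train_idx])
    if (length(missing_cls)) {
      stop("class absent from training split: ", missing_cls[1])
    }
    best_loss <- Inf; stall <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(train_idx)
      losses <- accs <- numeric(0)
      for (start in seq(1L, length(ord), by = config$batch_size)) {
        bidx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        res <- .dt_grad(w, model$config$kernels,
                        enc$seqs[bidx, , drop = FALSE], enc$lengths[bidx],
                        y[bidx], model$config$dropout, TRUE)
        t_adam <- t_adam + 1L
        corr <- sqrt(1 - b2^t_adam) / (1 - b1^t_adam)
        for (nm in names(w)) {
          gnm <- res$grads[[nm]]
          adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * gnm
          adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * gnm^2
          w[[nm]] <- w[[nm]] - lr * corr * adam_m[[nm]] /
            (sqrt(adam_v[[nm]]) + adam_eps)
        }
        losses <- c(losses, res$loss)
        accs <- c(accs, res$accuracy)
      }
      ep_loss <- mean(losses)
      history[[epoch]] <- tibble(epoch = epoch, loss = ep_loss,
                                 accuracy = mean(accs))
      if (ep_loss < best_loss - 1e-6) {
        best_loss <- ep_loss; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
  })
  model$weights <- w
  model$fitted <- TRUE
  model$history <- dplyr::bind_rows(history)
  model$train_config <- config
  if (length(test_idx)) {
    model$heldout <- evaluate_model(model, sequences[test_idx], labels[test_idx])
  }
  model
}

#' Predict genus per read
#'
#' Argmax over the softmax output; ties break to the lowest class index.
#'
#' @param model A fitted `deep_taxa_model`.
#' @param sequences Reads.
#' @return Tibble: `genus`, `probability`, plus a `probs` attribute with the
#'   full probability matrix (reads x classes).
#' @export
predict_genus <- function(model, sequences) {
  if (!model$fitted) stop("model is not fitted")
  enc <- .seqs_to_int(sequences, model$config$max_len)
  probs <- .dt_forward(model$weights, model$config$kernels, enc$seqs, enc$lengths)
  colnames(probs) <- model$classes
  best <- max.col(probs, ties.method = "first")
  out <- tibble(genus = model$classes[best],
                probability = probs[cbind(seq_len(nrow(probs)), best)])
  attr(out, "probs") <- probs
  out
}

# one-vs-rest AUROC from scores and a binary truth vector (rank formula)
.auc_rank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate the deep classifier on labeled reads
#'
#' Accuracy, macro F1 over classes present in the truth, and mean
#' one-vs-rest AUROC. A single-class test set has no defined AUROC and
#' reports it as NA.
#'
#' @param model A fitted `deep_taxa_model`.
#' @param sequences Reads.
#' @param labels True genus labels.
#' @return One-row tibble: `accuracy`, `macro_f1`, `auroc`.
#' @export
evaluate_model <- function(model, sequences, labels) {
  pred <- predict_genus(model, sequences)
  probs <- attr(pred, "probs")
  labels <- as.character(labels)
  acc <- mean(pred$genus == labels)
  present <- sort(unique(labels))
  f1 <- vapply(present, function(cl) {
    tp <- sum(pred$genus == cl & labels == cl)
    fp <- sum(pred$genus == cl & labels != cl)
    fn <- sum(pred$genus != cl & labels == cl)
    if (tp == 0) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
  auc <- if (length(present) < 2) NA_real_ else {
    mean(vapply(present, function(cl)
      .auc_rank(probs[, cl], labels == cl), numeric(1)))
  }
  tibble(accuracy = acc, macro_f1 = mean(f1), auroc = auc)
}

#' Save / load a deep classifier checkpoint
#'
#' Self-describing JSON: class vocabulary, architecture config and all weight
#' matrices at full precision.
#'
#' @param model A `deep_taxa_model`.
#' @param path Checkpoint path.
#' @return `path` (save) or the model (load).
#' @export
save_deep_model <- function(model, path) {
  jsonlite::write_json(list(
    classes = model$classes,
    config = unclass(model$config),
    fitted = model$fitted,
    weights = model$weights), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_deep_model
#' @export
load_deep_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  config <- do.call(deep_taxa_config, obj$config)
  w <- obj$weights
  # vectors (biases) come back as numeric, matrices as matrices
  structure(list(classes = obj$classes, config = config,
                 weights = w, fitted = obj$fitted, history = NULL,
                 n_params = n_params_deep(config)),
            class = "deep_taxa_model")
}
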