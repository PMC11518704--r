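# Bilinear attention drug-target interaction network.
#
# Architecture: a three-layer graph-convolution block over the molecular
# graph (node-level output retained), an embedding plus three 1D
# convolutions over the protein sequence (each row of the output describes a
# subsequence), a bilinear interaction map with softmax attention over all
# (atom node, protein subsequence) pairs, bilinear pooling to a joint
# representation, and a fully connected classifier with sigmoid output.
# Training minimises binary cross-entropy with Adam. All forward and
# reverse-mode computations are explicit base-R matrix algebra; gradients
# are verified against finite differences in the test suite.

#' Model configuration
#'
#' Layer counts are fixed at three graph convolutions and three sequence
#' convolutions; everything else is overridable. Hidden dimensions, kernel
#' sizes, attention latent size, optimizer settings and batch size follow
#' the configuration family customary for bilinear-attention interaction
#' networks (feature dimension 128, kernels 3/6/9, Adam at 5e-4, batch 64).
#'
#' @param d_drug,d_prot Latent feature dimensions of the drug and protein
#'   encoders.
#' @param att_dim Bilinear attention latent dimension.
#' @param hidden Classifier hidden width.
#' @param kernels Kernel sizes of the three protein convolutions.
#' @param theta_d Maximum heavy-atom count (molecules above it truncate).
#' @param theta_p Maximum protein length (sequences above it truncate).
#' @param epochs,batch_size,lr Training schedule (default 100 epochs,
#'   batch 64, Adam learning rate 5e-4).
#' @param lr_schedule `"cosine"` (decay to zero over the epochs, the
#'   default) or `"constant"`.
#' @param class_weight Loss weight of positive samples: a number, or
#'   `"balanced"` (the default) for the negative/positive count ratio -
#'   activity data is typically strongly imbalanced.
#' @param select_by Validation metric for best-checkpoint selection when a
#'   validation set is supplied to [train_dta()]: `"auprc"` (default) or
#'   `"auroc"`.
#' @param seed Seed controlling initialization and batch shuffling.
#' @return A `dta_config` list.
#' @export
dta_config <- function(d_drug = 128, d_prot = 128, att_dim = 64, hidden = 128,
                       kernels = c(3, 6, 9), theta_d = 290, theta_p = 1200,
                       epochs = 100, batch_size = 64, lr = 5e-4,
                       lr_schedule = c("cosine", "constant"),
                       class_weight = "balanced",
                       select_by = c("auprc", "auroc"), seed = 1) {
  stopifnot(d_drug > 0, d_prot > 0, att_dim > 0, hidden > 0,
            length(kernels) == 3, all(kernels >= 1), epochs >= 0,
            batch_size >= 1, lr >= 0)
  if (!identical(class_weight, "balanced")) {
    stopifnot(is.numeric(class_weight), class_weight > 0)
  }
  structure(list(d_drug = d_drug, d_prot = d_prot, att_dim = att_dim,
                 hidden = hidden, kernels = kernels, gcn_layers = 3L,
                 conv_layers = 3L, theta_d = theta_d, theta_p = theta_p,
                 epochs = epochs, batch_size = batch_size, lr = lr,
                 lr_schedule = match.arg(lr_schedule),
                 class_weight = class_weight,
                 select_by = match.arg(select_by), seed = seed),
            class = "dta_config")
}

.glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

#' Initialize model parameters
#'
#' Glorot-uniform weights, zero biases, N(0, 0.1) protein embeddings; fully
#' determined by `config$seed`.
#'
#' @param config A `dta_config`.
#' @return A `dta_model` (list of parameter matrices plus the config).
#' @export
dta_init <- function(config) {
  set.seed(config$seed)
  Dd <- config$d_drug; Dp <- config$d_prot
  K <- config$att_dim; H <- config$hidden
  # one-hot embedding start: the first convolution sees raw residue
  # identity immediately, which speeds up motif discovery; trainable.
  # (falls back to Gaussian when the latent width is below the alphabet)
  Ep0 <- if (Dp >= 23) {
    E <- matrix(0, 23, Dp)
    E[cbind(1:23, 1:23)] <- 1
    E
  } else {
    matrix(stats::rnorm(23 * Dp, sd = 0.1), 23, Dp)
  }
  params <- list(
    W0 = .glorot(74, Dd),
    Wg = lapply(1:3, function(i) .glorot(Dd, Dd)),
    Ep = Ep0,
    Cw = lapply(config$kernels, function(k) .glorot(k * Dp, Dp)),
    Cb = lapply(config$kernels, function(k) numeric(Dp)),
    U = .glorot(Dd, K),
    V = .glorot(Dp, K),
    q = stats::rnorm(K, sd = 0.1),
    Wc1 = .glorot(K, H),
    bc1 = numeric(H),
    wc2 = .glorot(H, 1),
    bc2 = 0
  )
  structure(list(params = params, config = config, loss_trace = numeric(0)),
            class = "dta_model")
}

# Trimmed (real-node, effective-length) inputs for the compiled core.
.graph_input <- function(graph) {
  n <- graph$n_real
  list(M = graph$features[seq_len(n), , drop = FALSE],
       A = graph$adj_norm[seq_len(n), seq_len(n), drop = FALSE])
}

# Forward pass for one (molecule graph, protein index vector) pair.
# Virtual nodes and sequence padding are excluded by construction: the
# encoders operate on real atoms and the effective length only, so padding
# can never change the output.
.dta_forward <- function(params, graph, prot_idx, config) {
  g <- .graph_input(graph)
  .cpp_dta_forward(g$M, g$A, prot_idx, params, as.integer(config$kernels))
}

# elementwise binary op over the nested parameter structure
.param_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) .param_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else f(a, b)
}

.param_map <- function(f, a) {
  if (is.list(a)) {
    out <- lapply(a, function(x) .param_map(f, x))
    names(out) <- names(a)
    out
  } else f(a)
}

.bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the bilinear attention interaction model
#'
#' Minibatch Adam on (optionally class-weighted) binary cross-entropy, with
#' a cosine learning-rate schedule by default. When a validation set is
#' supplied, the model evaluates it after every epoch and the returned
#' parameters are the checkpoint with the best validation metric
#' (`config$select_by`) - the customary guard against late-training
#' memorization of label noise. Featurization of unique molecules and
#' proteins is done once up front. The run is fully determined by
#' `config$seed` on a single device.
#'
#' @param records Data frame with columns `smiles`, `sequence`, `label`
#'   (both classes must be present).
#' @param config A `dta_config`.
#' @param validation Optional data frame with the same columns, used for
#'   best-checkpoint selection.
#' @param verbose Print per-epoch loss (default `FALSE`).
#' @return A `dta_model` with trained `params`, per-epoch mean training loss
#'   in `loss_trace`, and, when `validation` was given, `val_trace` and
#'   `best_epoch`.
#' @export
train_dta <- function(records, config = dta_config(), validation = NULL,
                      verbose = FALSE) {
  stopifnot(all(c("smiles", "sequence", "label") %in% names(records)))
  if (length(unique(records$label)) < 2) {
    stop("training set must contain both classes")
  }
  model <- dta_init(config)
  all_smiles <- c(records$smiles, validation$smiles)
  all_seq <- c(records$sequence, validation$sequence)
  graphs <- .graph_cache(all_smiles, config$theta_d)
  prots <- .protein_cache(all_seq, config$theta_p)
  graph_in <- lapply(graphs, .graph_input)
  rec_graph <- graph_in[records$smiles]
  rec_prot <- prots[records$sequence]
  if (!is.null(validation)) {
    val_graph <- graph_in[validation$smiles]
    val_prot <- prots[validation$sequence]
    val_metric <- if (config$select_by == "auprc") auprc else auroc
  }
  kernels <- as.integer(config$kernels)
  n <- nrow(records)
  y <- records$label
  w_pos <- if (identical(config$class_weight, "balanced")) {
    sum(y == 0) / sum(y == 1)
  } else config$class_weight
  w <- ifelse(y == 1, w_pos, 1)
  adam <- list(
    m = .param_map(function(x) x * 0, model$params),
    v = .param_map(function(x) x * 0, model$params),
    t = 0
  )
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss_trace <- numeric(config$epochs)
  val_trace <- numeric(config$epochs)
  best <- list(metric = -Inf, params = model$params, epoch = 0L)
  if (config$epochs > 0) for (epoch in seq_len(config$epochs)) {
    lr_epoch <- if (config$lr_schedule == "cosine") {
      config$lr * 0.5 * (1 + cos(pi * (epoch - 1) / config$epochs))
    } else config$lr
    perm <- sample(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1L, n)]
      res <- .cpp_dta_batch_grad(rec_graph[idx], rec_prot[idx], y[idx],
                                 w[idx], model$params, kernels)
      batch_loss <- res$loss
      grad <- .param_map(function(g) g / length(idx), res$grads)
      adam$t <- adam$t + 1
      adam$m <- .param_map2(function(m, g) b1 * m + (1 - b1) * g, adam$m, grad)
      adam$v <- .param_map2(function(v, g) b2 * v + (1 - b2) * g^2, adam$v, grad)
      corr <- lr_epoch * sqrt(1 - b2^adam$t) / (1 - b1^adam$t)
      step <- .param_map2(function(m, v) corr * m / (sqrt(v) + eps),
                          adam$m, adam$v)
      model$params <- .param_map2(`-`, model$params, step)
      losses <- c(losses, batch_loss / length(idx))
    }
    loss_trace[epoch] <- mean(losses)
    if (!is.null(validation)) {
      val_scores <- .cpp_dta_predict(val_graph, val_prot, model$params, kernels)
      val_trace[epoch] <- val_metric(val_scores, validation$label)
      if (val_trace[epoch] > best$metric) {
        best <- list(metric = val_trace[epoch], params = model$params,
                     epoch = epoch)
      }
    }
    if (verbose) message(sprintf("epoch %d loss %.4f", epoch, loss_trace[epoch]))
  }
  model$loss_trace <- loss_trace
  if (!is.null(validation) && best$epoch > 0L) {
    model$params <- best$params
    model$val_trace <- val_trace
    model$best_epoch <- best$epoch
  }
  model
}

.graph_cache <- function(smiles, theta_d) {
  uniq <- unique(smiles)
  stats::setNames(featurize_molecule(uniq, theta_d), uniq)
}

.protein_cache <- function(sequences, theta_p) {
  uniq <- unique(sequences)
  stats::setNames(lapply(uniq, encode_protein, theta_p = theta_p), uniq)
}

#' Predict interaction probabilities
#'
#' @param model A trained `dta_model`.
#' @param records Data frame with `smiles` and `sequence` columns.
#' @param attention Also return the per-pair attention maps (default
#'   `FALSE`).
#' @return Numeric vector of probabilities in \[0, 1\], or, with
#'   `attention = TRUE`, a list with `prob` and `attention`.
#' @export
predict_dta <- function(model, records, attention = FALSE) {
  config <- model$config
  graphs <- .graph_cache(records$smiles, config$theta_d)
  prots <- .protein_cache(records$sequence, config$theta_p)
  graph_in <- lapply(graphs, .graph_input)
  rec_graph <- graph_in[records$smiles]
  rec_prot <- prots[records$sequence]
  kernels <- as.integer(config$kernels)
  if (attention) {
    fwds <- lapply(seq_len(nrow(records)), function(i) {
      .cpp_dta_forward(rec_graph[[i]]$M, rec_graph[[i]]$A, rec_prot[[i]],
                       model$params, kernels)
    })
    list(prob = vapply(fwds, `[[`, numeric(1), "p"),
         attention = lapply(fwds, `[[`, "attention"))
  } else {
    .cpp_dta_predict(rec_graph, rec_prot, model$params, kernels)
  }
}

#' Score and rank all (molecule, target) pairs
#'
#' @param model A trained `dta_model`.
#' @param molecules Data frame with `name` and `smiles`.
#' @param targets Data frame with `target_id` and `sequence`.
#' @param top_k Optionally keep only the first `top_k` rows after sorting.
#' @return Data frame `name`, `target_id`, `score`, sorted by descending
#'   score (ties broken by name then target for determinism).
#' @export
rank_candidates <- function(model, molecules, targets, top_k = NULL) {
  pairs <- expand.grid(mi = seq_len(nrow(molecules)),
                       ti = seq_len(nrow(targets)))
  records <- data.frame(smiles = molecules$smiles[pairs$mi],
                        sequence = targets$sequence[pairs$ti],
                        stringsAsFactors = FALSE)
  score <- predict_dta(model, records)
  out <- data.frame(name = molecules$name[pairs$mi],
                    target_id = targets$target_id[pairs$ti],
                    score = score, stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$name, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out
}
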