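#' Training configuration
#'
#' Multi-task loss weights default to 0.1 (classification) and 0.9
#' (regression), summing to 1.  Optimisation uses adaptive moment estimation
#' with cosine learning-rate decay and early stopping on the combined
#' validation loss.
#'
#' @param w_lc,w_lr weights of the classification and regression losses.
#' @param lr initial learning rate.
#' @param epochs training epochs.
#' @param batch_nodes maximum total nodes per mini-batch (graphs are
#'   concatenated node-wise, no padding).
#' @param batch_graphs maximum graphs per mini-batch; keeps the number of
#'   optimiser steps per epoch useful when graphs are small.
#' @param patience early-stopping patience in epochs (Inf disables).
#' @param use_class_factor include the 1/C factor inside the cross-entropy
#'   (the printed form); FALSE gives the standard cross-entropy.
#' @param seed seed for shuffling and dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(w_lc = 0.1, w_lr = 0.9, lr = 2e-3, epochs = 30,
                         batch_nodes = 2000, batch_graphs = 8,
                         patience = Inf, use_class_factor = TRUE, seed = 1) {
  stopifnot(w_lc >= 0, w_lr >= 0, lr > 0, epochs >= 1)
  structure(list(w_lc = w_lc, w_lr = w_lr, lr = lr,
                 epochs = as.integer(epochs),
                 batch_nodes = as.integer(batch_nodes),
                 batch_graphs = as.integer(batch_graphs),
                 patience = patience,
                 use_class_factor = isTRUE(use_class_factor),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Mean squared error of predicted quality scores
#'
#' @param pred,true equal-length numeric vectors.
#' @return scalar mean squared error.
#' @export
regression_loss <- function(pred, true) {
  stopifnot(length(pred) == length(true))
  if (length(pred) == 0) stop("empty batch", call. = FALSE)
  mean((pred - true)^2)
}

#' Cross-entropy over the four quality classes
#'
#' Computes `-(1/N) sum_i f sum_j y*_ij log y'_ij` where `f = 1/C` when
#' `use_class_factor` is TRUE (the default, matching the printed multi-task
#' loss) and `f = 1` for the standard cross-entropy.  Predicted probabilities
#' are clamped below at 1e-12.
#'
#' @param probs N x C matrix of predicted probabilities (rows sum to 1).
#' @param true_class integer class index (1..C), or a factor.
#' @param use_class_factor include the 1/C factor.
#' @return scalar loss.
#' @export
classification_loss <- function(probs, true_class, use_class_factor = TRUE) {
  probs <- rbind(probs)
  if (is.factor(true_class)) true_class <- as.integer(true_class)
  stopifnot(nrow(probs) == length(true_class))
  if (nrow(probs) == 0) stop("empty batch", call. = FALSE)
  p <- probs[cbind(seq_len(nrow(probs)), true_class)]
  if (any(p < 1e-12)) {
    message("clamping ", sum(p < 1e-12), " zero probabilit(ies) at 1e-12")
    p <- pmax(p, 1e-12)
  }
  f <- if (use_class_factor) 1 / ncol(probs) else 1
  -mean(f * log(p))
}

#' Weighted multi-task loss
#'
#' @param lc classification loss value.
#' @param lr regression loss value.
#' @param config a [train_config()] supplying the weights.
#' @return `w_lc * lc + w_lr * lr`.
#' @export
combined_loss <- function(lc, lr, config = train_config()) {
  config$w_lc * lc + config$w_lr * lr
}

# --- Adam ---------------------------------------------------------------

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_apply_update(params, upd)
  list(params = params, state = state)
}

# subtract updates from every parameter leaf except BN running statistics
tree_apply_update <- function(params, upd) {
  if (is.list(params)) {
    out <- params
    for (nm in names(params)) {
      if (nm %in% bn_stat_names) next
      out[[nm]] <- tree_apply_update(params[[nm]], upd[[nm]])
    }
    return(out)
  }
  params - upd
}

# --- loss + gradient on one batch ---------------------------------------

batch_loss_grads <- function(graphs, dockq, class_idx, params, config,
                             tcfg, training = TRUE, drop_masks = NULL) {
  fw <- ggt_forward(graphs, params, config, training = training,
                    drop_masks = drop_masks)
  G <- length(fw$score)
  lr_loss <- regression_loss(fw$score, dockq)
  lc_loss <- suppressMessages(
    classification_loss(fw$class_probs, class_idx, tcfg$use_class_factor))
  loss <- combined_loss(lc_loss, lr_loss, tcfg)
  if (!training) {
    return(list(loss = loss, lr_loss = lr_loss, lc_loss = lc_loss))
  }
  d_score <- tcfg$w_lr * 2 * (fw$score - dockq) / G
  d_reg_logit <- d_score * fw$score * (1 - fw$score)
  y <- matrix(0, G, 4)
  y[cbind(seq_len(G), class_idx)] <- 1
  f <- if (tcfg$use_class_factor) 1 / 4 else 1
  d_cls_logits <- tcfg$w_lc * f * unname(fw$class_probs - y) / G
  grads <- ggt_backward(fw$params, config, fw$cache, d_reg_logit,
                        d_cls_logits)
  list(loss = loss, lr_loss = lr_loss, lc_loss = lc_loss, grads = grads,
       params = fw$params)
}

make_drop_masks <- function(G, config) {
  if (config$dropout <= 0) return(NULL)
  p <- config$dropout
  r1 <- config$readout_hidden_dims[1]
  r2 <- config$readout_hidden_dims[2]
  mk <- function(d) matrix((runif(G * d) >= p) / (1 - p), G, d)
  list(reg = list(m1 = mk(r1), m2 = mk(r2)),
       cls = list(m1 = mk(r1), m2 = mk(r2)))
}

# --- training loop -------------------------------------------------------

#' Train the gated graph transformer on labelled decoy graphs
#'
#' Desk-scale multi-task training: mini-batches of whole graphs capped at
#' `batch_nodes` total nodes, adaptive moment estimation with cosine decay,
#' per-epoch train/validation logging, and retention of the
#' lowest-validation-loss parameters.  Fully reproducible from the seeds in
#' the two configs.
#'
#' @param graphs named list of featurised `complex_graph`s keyed by decoy id.
#' @param labels tibble with `decoy_id`, `dockq` and `class` (factor or
#'   character over Incorrect/Acceptable/Medium/High); a `target_id` column
#'   is used for splitting.
#' @param splits optional fold table, either target-level (`target_id`,
#'   `fold` in "train"/"val") or decoy-level (`decoy_id`, `fold`); entries
#'   absent from it are ignored.  Without it a random quarter of each
#'   target's decoys (at least one) forms the validation fold, so validation
#'   measures generalisation to unseen decoys while whole-target holdouts
#'   are left to the caller.
#' @param config a [ggt_config()].
#' @param tcfg a [train_config()].
#' @return a `ggt_fit`: `params` (best validation), `final_params`, `config`,
#'   `tcfg`, `history` tibble (epoch, lr, train/val losses), `best_epoch`.
#' @export
train_ggt <- function(graphs, labels, splits = NULL, config = ggt_config(),
                      tcfg = train_config()) {
  stopifnot(all(labels$decoy_id %in% names(graphs)))
  labels$class_idx <- if (is.factor(labels$class)) {
    as.integer(labels$class)
  } else {
    match(as.character(labels$class), QUALITY_CLASSES)
  }
  if (is.null(labels$target_id)) labels$target_id <- "target"
  if (is.null(splits)) {
    set.seed(tcfg$seed)
    splits <- labels |>
      dplyr::group_by(.data$target_id) |>
      dplyr::mutate(fold = ifelse(seq_len(dplyr::n()) %in%
                                    sample(dplyr::n(),
                                           max(1, round(dplyr::n() / 4))),
                                  "val", "train")) |>
      dplyr::ungroup() |>
      dplyr::select("decoy_id", "fold")
  }
  join_key <- if ("decoy_id" %in% names(splits)) "decoy_id" else "target_id"
  lab <- dplyr::inner_join(labels, splits[, c(join_key, "fold")],
                           by = join_key)
  train_lab <- lab[lab$fold == "train", ]
  val_lab <- lab[lab$fold == "val", ]
  if (nrow(train_lab) == 0) stop("empty training fold", call. = FALSE)
  params <- ggt_init_params(config)
  opt <- adam_init(params)
  history <- list()
  best <- list(loss = Inf, params = params, epoch = 0L)
  since_best <- 0L
  for (epoch in seq_len(tcfg$epochs)) {
    set.seed((tcfg$seed * 131 + epoch) %% .Machine$integer.max)
    lr_t <- tcfg$lr * 0.5 * (1 + cos(pi * (epoch - 1) / tcfg$epochs))
    ord <- sample(nrow(train_lab))
    sizes <- vapply(graphs[train_lab$decoy_id[ord]],
                    function(g) g$n_nodes, integer(1))
    batch_id <- assign_batches(sizes, tcfg$batch_nodes, tcfg$batch_graphs)
    ep_loss <- 0
    n_seen <- 0
    for (bi in unique(batch_id)) {
      rows <- ord[batch_id == bi]
      ids <- train_lab$decoy_id[rows]
      masks <- make_drop_masks(length(ids), config)
      bl <- batch_loss_grads(graphs[ids], train_lab$dockq[rows],
                             train_lab$class_idx[rows], params, config,
                             tcfg, training = TRUE, drop_masks = masks)
      if (!is.finite(bl$loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch,
             call. = FALSE)
      }
      params <- bl$params  # running statistics updated by the forward pass
      st <- adam_step(params, bl$grads, opt, lr_t)
      params <- st$params
      opt <- st$state
      ep_loss <- ep_loss + bl$loss * length(ids)
      n_seen <- n_seen + length(ids)
    }
    train_loss <- ep_loss / n_seen
    if (nrow(val_lab) > 0) {
      vl <- batch_loss_grads(graphs[val_lab$decoy_id], val_lab$dockq,
                             val_lab$class_idx, params, config, tcfg,
                             training = FALSE)
      val_loss <- vl$loss
    } else {
      val_loss <- train_loss
    }
    history[[epoch]] <- tibble::tibble(epoch = epoch, lr = lr_t,
                                       train_loss = train_loss,
                                       val_loss = val_loss)
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= tcfg$patience) break
    }
  }
  fit <- list(params = best$params, final_params = params, config = config,
              tcfg = tcfg, history = dplyr::bind_rows(history),
              best_epoch = best$epoch, splits = splits)
  class(fit) <- "ggt_fit"
  fit
}

# greedy batching in the given order, capped by nodes and by graph count
assign_batches <- function(sizes, node_cap, graph_cap = Inf) {
  batch <- integer(length(sizes))
  cur <- 1L
  acc <- 0L
  cnt <- 0L
  for (i in seq_along(sizes)) {
    if (cnt > 0 && (acc + sizes[i] > node_cap || cnt >= graph_cap)) {
      cur <- cur + 1L
      acc <- 0L
      cnt <- 0L
    }
    batch[i] <- cur
    acc <- acc + sizes[i]
    cnt <- cnt + 1L
  }
  batch
}

#' @export
print.ggt_fit <- function(x, ...) {
  cat(sprintf(
    "<ggt_fit> %d layers x %d heads, %d epochs (best %d, val loss %.4f)\n",
    x$config$n_layers, x$config$n_heads, nrow(x$history), x$best_epoch,
    min(x$history$val_loss)))
  invisible(x)
}

#' Tidy the training history of a GGT fit
#'
#' One row per epoch with learning rate and train/validation losses
#' (broom-style `tidy()` method).
#'
#' @param x a `ggt_fit`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy ggt_fit
#' @export
tidy.ggt_fit <- function(x, ...) x$history

#' One-row summary of a GGT fit
#'
#' @param x a `ggt_fit`.
#' @param ... unused.
#' @return a tibble with epochs run, best epoch, best validation loss and
#'   final training loss.
#' @method glance ggt_fit
#' @export
glance.ggt_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
                 best_val_loss = min(x$history$val_loss),
                 final_train_loss = x$history$train_loss[nrow(x$history)])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# --- checkpointing -------------------------------------------------------

flatten_tree <- function(x) {
  if (is.list(x)) return(lapply(x, flatten_tree))
  list(.dim = as.integer(dim(x) %||% length(x)), .data = as.numeric(x))
}

unflatten_tree <- function(x) {
  if (is.list(x) && identical(sort(names(x)), c(".data", ".dim"))) {
    d <- as.integer(x$.dim)
    v <- as.numeric(x$.data)
    if (length(d) == 2) return(matrix(v, d[1], d[2]))
    return(v)
  }
  lapply(x, unflatten_tree)
}

#' Save / load a model checkpoint
#'
#' Plain-JSON container holding a format version, the architecture config
#' and every named parameter array (with shapes).  Loading restores a list
#' usable by [predict_quality()] and [ggt_forward()].
#'
#' @param model a `ggt_fit` or a list with `params` and `config`.
#' @param path file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint` the
#'   model list (class `ggt_checkpoint`).
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(format_version = 1L,
              config = unclass(model$config),
              params = flatten_tree(model$params))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (is.null(obj$format_version) || obj$format_version != 1L) {
    stop("unrecognised checkpoint version", call. = FALSE)
  }
  cfg <- obj$config
  class(cfg) <- "ggt_config"
  model <- list(config = cfg, params = unflatten_tree(obj$params))
  class(model) <- "ggt_checkpoint"
  model
}
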