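# ---- small tree utilities over parameter structures ------------------------

pk_tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) {
      if (!is.null(a[[nm]])) out[[nm]] <- pk_tree_map2(f, a[[nm]], b[[nm]])
    }
    out
  } else {
    f(a, b)
  }
}

pk_tree_sumsq <- function(a) {
  if (is.list(a)) sum(vapply(a, pk_tree_sumsq, numeric(1))) else sum(a^2)
}

pk_tree_zero <- function(a) {
  if (is.list(a)) lapply(a, pk_tree_zero) else a * 0
}

# Trainable leaves of a parameter structure (normalization constants and
# dimension bookkeeping are excluded).
pk_trainable <- function(params) {
  params[c("encoder", "solvent", "ffn")]
}

# ---- metrics ---------------------------------------------------------------

#' Area under the ROC curve (rank statistic)
#'
#' Computed from the Wilcoxon rank-sum identity with midrank tie handling:
#' the probability that a random positive is scored above a random negative.
#'
#' @param scores Numeric predictions.
#' @param labels Binary truths (0/1).
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    abort("AUC is undefined for a single-class truth vector",
          class = "probekit_metric_error")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Coefficient of determination
#' @param pred,truth Numeric vectors.
#' @return R-squared (can be negative; never exceeds 1).
#' @export
r_squared <- function(pred, truth) {
  1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2)
}

#' Mean absolute error
#' @param pred,truth Numeric vectors.
#' @export
mae <- function(pred, truth) mean(abs(pred - truth))

#' Evaluate predictions against truths
#'
#' @param predictions Numeric vector (scores or predicted values).
#' @param truths Numeric vector (binary labels or measured values).
#' @param task `"classification"` (AUC) or `"regression"` (R-squared, MAE).
#' @return A tibble with one row per metric.
#' @export
evaluate_predictions <- function(predictions, truths,
                                 task = c("classification", "regression")) {
  task <- match.arg(task)
  stopifnot(length(predictions) == length(truths), length(truths) >= 2)
  if (task == "classification") {
    if (!all(truths %in% c(0, 1))) {
      abort("classification truths must be binary 0/1")
    }
    tibble(metric = "auc", value = auc_score(predictions, truths))
  } else {
    tibble(
      metric = c("r_squared", "mae"),
      value = c(r_squared(predictions, truths), mae(predictions, truths))
    )
  }
}

# ---- data normalization ----------------------------------------------------

pk_norm_labels <- function(x) {
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) abort("labels must be binary 0/1")
    return(as.numeric(x))
  }
  lab <- tolower(as.character(x))
  if (!all(lab %in% c("fluorescent", "non-fluorescent"))) {
    abort("labels must be 0/1 or 'fluorescent'/'non-fluorescent'")
  }
  as.numeric(lab == "fluorescent")
}

pk_check_training_frame <- function(data, task) {
  if (nrow(data) == 0) abort("empty training set", class = "probekit_data_error")
  need <- if (task == "classification") c("smiles", "label", "abs_query", "em_query")
          else c("smiles", "solvent_smiles", "value")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "probekit_data_error")
  }
  data
}

# Featurize a character vector of SMILES through a cache environment.
pk_featurize_cached <- function(smiles, cache = new.env(parent = emptyenv())) {
  out <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    key <- smiles[[i]]
    g <- cache[[key]]
    if (is.null(g)) {
      g <- featurize_molecule(key)
      cache[[key]] <- g
    }
    out[[i]] <- g
  }
  out
}

# Assemble fixed mini-batches (graph structures, conditions, targets) once;
# the training loop then only performs dense algebra.
pk_make_batches <- function(data, cfg, cache, shuffle = TRUE) {
  n <- nrow(data)
  ord <- if (shuffle) sample.int(n) else seq_len(n)
  starts <- seq(1, n, by = cfg$batch_size)
  graphs <- pk_featurize_cached(data$smiles, cache)
  lapply(starts, function(s) {
    ix <- ord[s:min(s + cfg$batch_size - 1, n)]
    b <- pk_batch_graphs(graphs[ix], cfg$aggregation)
    out <- list(batch = b, idx = ix)
    if (cfg$task == "classification") {
      out$cond <- cbind((data$abs_query[ix] - 300) / 600,
                        (data$em_query[ix] - 400) / 800)
      out$y <- pk_norm_labels(data$label)[ix]
    } else {
      sv <- data$solvent_smiles[ix]
      usv <- unique(sv)
      out$solvent_batch <- pk_batch_graphs(pk_featurize_cached(usv, cache),
                                           cfg$aggregation)
      out$solvent_map <- Matrix::sparseMatrix(
        i = seq_along(ix), j = match(sv, usv), x = 1,
        dims = c(length(ix), length(usv))
      )
      out$smap <- match(sv, usv)
      out$y <- data$value[ix]
    }
    out
  })
}

pk_forward_batch <- function(bt, cfg, params, training = FALSE) {
  fwd <- pk_encoder_forward(bt$batch, params$encoder, cfg$depth, cfg$update_rule)
  if (cfg$task == "classification") {
    U <- cbind(fwd$emb, bt$cond)
    sfwd <- NULL
  } else {
    sfwd <- pk_encoder_forward(bt$solvent_batch, params$solvent,
                               cfg$solvent_depth, cfg$update_rule)
    s_emb <- as.matrix(bt$solvent_map %*% sfwd$emb)
    U <- cbind(fwd$emb, s_emb)
  }
  ffn <- pk_ffn_forward(U, params$ffn, cfg$dropout, training)
  list(fwd = fwd, sfwd = sfwd, ffn = ffn, z = as.numeric(ffn$out))
}

pk_backward_batch <- function(bt, cfg, params, fw, dz) {
  bk <- pk_ffn_backward(fw$ffn, params$ffn, matrix(dz, ncol = 1))
  h <- cfg$hidden
  d_emb <- bk$d_in[, 1:h, drop = FALSE]
  g_enc <- pk_encoder_backward(bt$batch, params$encoder, fw$fwd, d_emb,
                               cfg$depth, cfg$update_rule)
  g_solv <- NULL
  if (cfg$task == "regression") {
    hs <- cfg$solvent_hidden
    d_s_records <- bk$d_in[, (h + 1):(h + hs), drop = FALSE]
    d_s <- as.matrix(Matrix::crossprod(bt$solvent_map, d_s_records))
    g_solv <- pk_encoder_backward(bt$solvent_batch, params$solvent, fw$sfwd,
                                  d_s, cfg$solvent_depth, cfg$update_rule)
  }
  list(encoder = g_enc, solvent = g_solv, ffn = bk$grads)
}

# ---- training --------------------------------------------------------------

#' Train a conditioned message-passing model
#'
#' Minimizes binary cross-entropy (classification, on the logit) or mean
#' squared error on z-scored targets (regression) with Adam at a constant
#' learning rate, mini-batches of `cfg$batch_size`, and global
#' gradient-norm clipping. The parameters of the epoch with the best
#' validation metric (AUC, or R-squared for regression) are returned; with
#' no validation set the final epoch is kept. Fully deterministic for a
#' given `cfg$seed`.
#'
#' Classification frames need columns `smiles`, `label` (0/1 or
#' `"fluorescent"`/`"non-fluorescent"`), `abs_query`, `em_query`;
#' regression frames need `smiles`, `solvent_smiles`, `value`.
#'
#' @param train,val Training and optional validation tibbles.
#' @param cfg An [encoder_config()].
#' @param verbose Print per-epoch progress.
#' @param engine `"cpp"` (default; compiled single-precision core) or
#'   `"r"` (the reference double-precision implementation; identical
#'   contract, slower). Prediction always uses the reference path.
#' @return A `dmpnn_model`: list with `params`, `cfg`, `history` (per-epoch
#'   loss and validation metric), `best_epoch`, and a retrieval `cache` of
#'   the training records keyed by (canonical structure, condition).
#' @export
train_model <- function(train, val = NULL, cfg, verbose = FALSE,
                        engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(cfg, "encoder_config"))
  train <- pk_check_training_frame(train, cfg$task)
  if (!is.null(val)) val <- pk_check_training_frame(val, cfg$task)

  params <- pk_init_params(cfg)
  if (cfg$task == "regression") {
    params$target_mean <- mean(train$value)
    params$target_sd <- stats::sd(train$value)
    if (!is.finite(params$target_sd) || params$target_sd == 0) params$target_sd <- 1
  }

  gcache <- new.env(parent = emptyenv())
  set.seed(cfg$seed)
  batches <- pk_make_batches(train, cfg, gcache, shuffle = TRUE)
  val_batches <- if (!is.null(val)) pk_make_batches(val, cfg, gcache, shuffle = FALSE)

  yz <- function(y) if (cfg$task == "regression") (y - params$target_mean) / params$target_sd else y

  if (engine == "cpp") {
    return(pk_train_cpp(train, val, cfg, params, batches, val_batches, yz,
                        verbose))
  }

  adam_m <- pk_tree_zero(pk_trainable(params))
  adam_v <- pk_tree_zero(pk_trainable(params))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L

  history <- tibble(
    epoch = seq_len(cfg$epochs),
    train_loss = NA_real_,
    val_metric = NA_real_
  )
  best_metric <- -Inf
  best_params <- params
  best_epoch <- NA_integer_

  for (ep in seq_len(cfg$epochs)) {
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      bt <- batches[[bi]]
      fw <- pk_forward_batch(bt, cfg, params, training = TRUE)
      y <- yz(bt$y)
      nb <- length(y)
      if (cfg$task == "classification") {
        z <- fw$z
        losses[bi] <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
        dz <- (stats::plogis(z) - y) / nb
      } else {
        r <- fw$z - y
        losses[bi] <- mean(r^2)
        dz <- 2 * r / nb
      }
      if (!is.finite(losses[bi])) {
        abort(paste0("non-finite training loss at epoch ", ep),
              class = "probekit_divergence_error")
      }
      grads <- pk_backward_batch(bt, cfg, params, fw, dz)
      gn <- sqrt(pk_tree_sumsq(grads))
      if (is.finite(cfg$grad_clip) && gn > cfg$grad_clip) {
        sc <- cfg$grad_clip / gn
        grads <- pk_tree_map2(function(g, .) g * sc, grads, grads)
      }
      step <- step + 1L
      adam_m <- pk_tree_map2(function(m, g) b1 * m + (1 - b1) * g, adam_m, grads)
      adam_v <- pk_tree_map2(function(v, g) b2 * v + (1 - b2) * g^2, adam_v, grads)
      corr1 <- 1 - b1^step
      corr2 <- 1 - b2^step
      upd <- pk_tree_map2(
        function(m, v) cfg$init_lr * (m / corr1) / (sqrt(v / corr2) + eps),
        adam_m, adam_v
      )
      new_tr <- pk_tree_map2(`-`, pk_trainable(params), upd)
      params[c("encoder", "solvent", "ffn")] <- new_tr
    }
    history$train_loss[ep] <- mean(losses)

    if (!is.null(val)) {
      vp <- unlist(lapply(val_batches, function(bt) {
        fw <- pk_forward_batch(bt, cfg, params)
        if (cfg$task == "classification") stats::plogis(fw$z)
        else fw$z * params$target_sd + params$target_mean
      }))
      vy <- unlist(lapply(val_batches, function(bt) bt$y))
      metric <- if (cfg$task == "classification") auc_score(vp, vy)
                else r_squared(vp, vy)
      history$val_metric[ep] <- metric
      if (metric > best_metric) {
        best_metric <- metric
        best_params <- params
        best_epoch <- ep
      }
    }
    if (verbose) {
      cat(sprintf("epoch %3d  loss %.5f  val %.4f\n", ep,
                  history$train_loss[ep], history$val_metric[ep]))
    }
  }
  if (is.null(val)) {
    best_params <- params
    best_epoch <- cfg$epochs
  }

  cache <- pk_build_retrieval_cache(train, cfg)
  structure(
    list(
      cfg = cfg, params = best_params, history = history,
      best_epoch = best_epoch, cache = cache,
      n_train = nrow(train),
      call_counter = local({e <- new.env(); e$n <- 0L; e})
    ),
    class = "dmpnn_model"
  )
}

# ---- compiled training engine ---------------------------------------------

pk_graph_for_cpp <- function(b) {
  list(Xedge = b$X_edge, Xatom = b$X_atom,
       a = b$lists$a, b = b$lists$b, s = b$lists$s)
}

pk_batch_for_cpp <- function(bt, cfg, yz) {
  out <- list(graph = pk_graph_for_cpp(bt$batch), y = yz(bt$y))
  if (cfg$task == "classification") {
    out$cond <- bt$cond
  } else {
    out$solvent <- pk_graph_for_cpp(bt$solvent_batch)
    out$smap <- as.integer(bt$smap - 1L)
  }
  out
}

pk_train_cpp <- function(train, val, cfg, params, batches, val_batches, yz,
                         verbose) {
  sess <- pk_cpp_new_session(
    params[c("encoder", "solvent", "ffn")],
    list(depth = cfg$depth, solvent_depth = cfg$solvent_depth,
         update_rule = cfg$update_rule, task = cfg$task,
         grad_clip = cfg$grad_clip)
  )
  pk_cpp_load_batches(sess, lapply(batches, pk_batch_for_cpp, cfg, yz), FALSE)
  if (!is.null(val)) {
    pk_cpp_load_batches(sess, lapply(val_batches, pk_batch_for_cpp, cfg, yz),
                        TRUE)
  }
  history <- tibble(epoch = seq_len(cfg$epochs), train_loss = NA_real_,
                    val_metric = NA_real_)
  best_metric <- -Inf
  best_raw <- NULL
  best_epoch <- NA_integer_
  for (ep in seq_len(cfg$epochs)) {
    loss <- pk_cpp_train_epoch(sess, cfg$init_lr)
    if (!is.finite(loss)) {
      abort(paste0("non-finite training loss at epoch ", ep),
            class = "probekit_divergence_error")
    }
    history$train_loss[ep] <- loss
    if (!is.null(val)) {
      z <- pk_cpp_predict_loaded(sess, TRUE)
      vp <- if (cfg$task == "classification") stats::plogis(z)
            else z * params$target_sd + params$target_mean
      vy <- unlist(lapply(val_batches, function(bt) bt$y))
      metric <- if (cfg$task == "classification") auc_score(vp, vy)
                else r_squared(vp, vy)
      history$val_metric[ep] <- metric
      if (metric > best_metric) {
        best_metric <- metric
        best_raw <- pk_cpp_get_params(sess)
        best_epoch <- ep
      }
    }
    if (verbose) {
      cat(sprintf("epoch %3d  loss %.5f  val %.4f\n", ep,
                  history$train_loss[ep], history$val_metric[ep]))
    }
  }
  if (is.null(val)) {
    best_raw <- pk_cpp_get_params(sess)
    best_epoch <- cfg$epochs
  }
  params$encoder <- best_raw$encoder
  if (!is.null(best_raw$solvent)) params$solvent <- best_raw$solvent
  params$ffn <- lapply(best_raw$ffn, function(l) {
    list(W = l$W, b = as.numeric(l$b))
  })
  cache <- pk_build_retrieval_cache(train, cfg)
  structure(
    list(cfg = cfg, params = params, history = history,
         best_epoch = best_epoch, cache = cache, n_train = nrow(train),
         call_counter = local({e <- new.env(); e$n <- 0L; e})),
    class = "dmpnn_model"
  )
}

# Retrieval cache: experimental training records keyed by structure and
# condition, consulted by the screening pipeline before any model call.
pk_build_retrieval_cache <- function(train, cfg) {
  if (cfg$task == "classification") {
    tibble(
      smiles = train$smiles,
      key = paste(train$smiles, train$abs_query, train$em_query, sep = "|"),
      stored = pk_norm_labels(train$label)
    )
  } else {
    tibble(
      smiles = train$smiles,
      key = paste(train$smiles, train$solvent_smiles, sep = "|"),
      stored = train$value
    )
  }
}

#' Predict with a trained model
#'
#' @param object A `dmpnn_model`.
#' @param newdata Tibble with `smiles` plus either `abs_query`/`em_query`
#'   (classification) or `solvent_smiles` (regression).
#' @param ... Unused.
#' @return `newdata` with a `.pred` column (activity score in \[0,1\], or
#'   the property value in its units).
#' @export
predict.dmpnn_model <- function(object, newdata, ...) {
  cfg <- object$cfg
  params <- object$params
  df <- newdata
  if (cfg$task == "regression" && !"value" %in% names(df)) df$value <- 0
  if (cfg$task == "classification" && !"label" %in% names(df)) df$label <- 0
  df <- pk_check_training_frame(df, cfg$task)
  gcache <- new.env(parent = emptyenv())
  eval_cfg <- cfg
  eval_cfg$batch_size <- 256L
  batches <- pk_make_batches(df, eval_cfg, gcache, shuffle = FALSE)
  pred <- unlist(lapply(batches, function(bt) {
    fw <- pk_forward_batch(bt, cfg, params)
    if (cfg$task == "classification") stats::plogis(fw$z)
    else fw$z * params$target_sd + params$target_mean
  }))
  object$call_counter$n <- object$call_counter$n + nrow(df)
  dplyr::mutate(newdata, .pred = pred)
}

#' @export
print.dmpnn_model <- function(x, ...) {
  cat("<dmpnn_model> task:", x$cfg$task,
      if (!is.null(x$cfg$target_property)) paste0("(", x$cfg$target_property, ")"),
      "\n  depth", x$cfg$depth, "hidden", x$cfg$hidden,
      "| trained", x$cfg$epochs, "epochs on", x$n_train, "records",
      "| best epoch", x$best_epoch, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a fitted model
#' @param x A `dmpnn_model`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `train_loss`, `val_metric`.
#' @export
tidy.dmpnn_model <- function(x, ...) x$history

#' One-row model summary
#' @param x A `dmpnn_model`.
#' @param ... Unused.
#' @export
glance.dmpnn_model <- function(x, ...) {
  tibble(
    task = x$cfg$task,
    target_property = x$cfg$target_property %||% NA_character_,
    epochs = x$cfg$epochs,
    best_epoch = x$best_epoch,
    best_val_metric = if (all(is.na(x$history$val_metric))) NA_real_
                      else max(x$history$val_metric, na.rm = TRUE),
    final_train_loss = x$history$train_loss[x$cfg$epochs],
    n_train = x$n_train
  )
}

#' @importFrom rlang %||%
NULL
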