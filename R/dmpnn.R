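#' Encoder / model configuration
#'
#' Hyperparameters of the conditioned directed message-passing model. The
#' defaults mirror the reference configuration: message-passing depth 3,
#' solvent-specific depth 3, hidden size 300 for both branches; the
#' classifier trains 30 epochs at initial learning rate 1e-4 and the
#' regressors 200 epochs at 1e-3 (Adam, constant schedule).
#'
#' @param task `"classification"` (wavelength-conditioned activity) or
#'   `"regression"` (solvent-conditioned property).
#' @param target_property For regression, one of
#'   `r paste0('"', pk_properties(), '"', collapse = ", ")`.
#' @param depth,hidden Message-passing iterations and hidden width of the
#'   solute encoder.
#' @param solvent_depth,solvent_hidden Same for the solvent encoder
#'   (regression only).
#' @param activation Nonlinearity; only `"relu"` is implemented.
#' @param aggregation Atom pooling, `"mean"` or `"sum"`.
#' @param ffn_layers,ffn_hidden Feed-forward head depth and width.
#' @param dropout Dropout fraction on FFN hidden layers during training.
#' @param update_rule `"concat"`: h_t = relu(W_h [h_{t-1}, m_t]) (the bond
#'   state is concatenated with the summed neighbor messages);
#'   `"add"`: h_t = relu(h_0 + W_h m_t), the widely used alternative.
#' @param epochs,init_lr,batch_size,seed Training settings. `NULL` epochs /
#'   learning rate resolve to the task defaults (30 / 1e-4 classification,
#'   200 / 1e-3 regression).
#' @param grad_clip Global gradient-norm clip.
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(task = c("classification", "regression"),
                           target_property = NULL,
                           depth = 3L, hidden = 300L,
                           solvent_depth = 3L, solvent_hidden = 300L,
                           activation = "relu",
                           aggregation = c("mean", "sum"),
                           ffn_layers = 2L, ffn_hidden = 300L,
                           dropout = 0,
                           update_rule = c("concat", "add"),
                           epochs = NULL, init_lr = NULL,
                           batch_size = 64L, seed = 0L,
                           grad_clip = 10) {
  task <- match.arg(task)
  aggregation <- match.arg(aggregation)
  update_rule <- match.arg(update_rule)
  if (depth < 0 || hidden <= 0) abort("depth must be >= 0 and hidden > 0")
  if (dropout < 0 || dropout >= 1) abort("dropout must lie in [0, 1)")
  if (activation != "relu") abort("only the relu activation is implemented")
  if (task == "regression") {
    target_property <- match.arg(target_property, pk_properties())
  }
  if (is.null(epochs)) epochs <- if (task == "classification") 30L else 200L
  if (is.null(init_lr)) init_lr <- if (task == "classification") 1e-4 else 1e-3
  structure(
    list(
      task = task, target_property = target_property,
      depth = as.integer(depth), hidden = as.integer(hidden),
      solvent_depth = as.integer(solvent_depth),
      solvent_hidden = as.integer(solvent_hidden),
      activation = activation, aggregation = aggregation,
      ffn_layers = as.integer(ffn_layers), ffn_hidden = as.integer(ffn_hidden),
      dropout = dropout, update_rule = update_rule,
      epochs = as.integer(epochs), init_lr = init_lr,
      batch_size = as.integer(batch_size), seed = as.integer(seed),
      grad_clip = grad_clip
    ),
    class = "encoder_config"
  )
}

pk_glorot <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
}

pk_init_encoder <- function(d_in, d_atom, hidden, update_rule) {
  list(
    W_in = pk_glorot(d_in, hidden),
    W_h = if (update_rule == "concat") pk_glorot(2 * hidden, hidden)
          else pk_glorot(hidden, hidden),
    W_a = pk_glorot(d_atom + hidden, hidden)
  )
}

# Initialize all weights for a model configuration (seeded).
pk_init_params <- function(cfg, d_atom = PK_D_ATOM, d_bond = PK_D_BOND) {
  set.seed(cfg$seed)
  enc <- pk_init_encoder(d_atom + d_bond, d_atom, cfg$hidden, cfg$update_rule)
  solvent <- NULL
  head_in <- if (cfg$task == "classification") cfg$hidden + 2L else NA_integer_
  if (cfg$task == "regression") {
    solvent <- pk_init_encoder(d_atom + d_bond, d_atom, cfg$solvent_hidden,
                               cfg$update_rule)
    head_in <- cfg$hidden + cfg$solvent_hidden
  }
  dims <- c(head_in, rep(cfg$ffn_hidden, cfg$ffn_layers), 1L)
  ffn <- vector("list", length(dims) - 1)
  for (l in seq_along(ffn)) {
    ffn[[l]] <- list(W = pk_glorot(dims[l], dims[l + 1]),
                     b = numeric(dims[l + 1]))
  }
  list(encoder = enc, solvent = solvent, ffn = ffn,
       target_mean = 0, target_sd = 1, d_atom = d_atom, d_bond = d_bond)
}

# ---- batched graph assembly ------------------------------------------------

# Collate a list of mol_graph into one block-diagonal structure with the
# sparse operators the encoder needs:
#   A (E x E)  message aggregation: A[e, e'] = 1 iff tgt(e') == src(e),
#              e' != rev(e)
#   B (N x E)  incoming-edge sum per atom
#   S (M x N)  atom pooling per molecule (mean or sum)
pk_batch_graphs <- function(graphs, aggregation = "mean") {
  n_atoms <- vapply(graphs, function(g) g$n_atoms, integer(1))
  n_edges <- vapply(graphs, function(g) g$n_edges, integer(1))
  atom_off <- c(0L, cumsum(n_atoms))
  edge_off <- c(0L, cumsum(n_edges))
  N <- sum(n_atoms); E <- sum(n_edges); M <- length(graphs)

  X_atom <- do.call(rbind, lapply(graphs, function(g) g$atom_features))
  src <- integer(E); tgt <- integer(E); rev_idx <- integer(E)
  bf <- matrix(0, E, PK_D_BOND)
  for (m in seq_len(M)) {
    g <- graphs[[m]]
    if (g$n_edges == 0) next
    ix <- (edge_off[m] + 1L):(edge_off[m] + g$n_edges)
    src[ix] <- g$edges[, "src"] + atom_off[m]
    tgt[ix] <- g$edges[, "tgt"] + atom_off[m]
    rev_idx[ix] <- g$rev_index + edge_off[m]
    bf[ix, ] <- g$bond_features
  }
  X_edge <- cbind(X_atom[src, , drop = FALSE], bf)

  # A: pair every edge e with the edges incoming to its source atom,
  # excluding its own reverse.
  if (E > 0) {
    by_tgt <- split(seq_len(E), tgt)
    e_list <- vector("list", N); n_in <- integer(N)
    in_of <- function(v) {
      x <- by_tgt[[as.character(v)]]
      if (is.null(x)) integer(0) else x
    }
    rows <- vector("list", E); cols <- vector("list", E)
    for (e in seq_len(E)) {
      inc <- in_of(src[e])
      inc <- inc[inc != rev_idx[e]]
      if (length(inc)) {
        rows[[e]] <- rep.int(e, length(inc))
        cols[[e]] <- inc
      }
    }
    A <- Matrix::sparseMatrix(
      i = unlist(rows), j = unlist(cols), x = 1, dims = c(E, E)
    )
    B <- Matrix::sparseMatrix(i = tgt, j = seq_len(E), x = 1, dims = c(N, E))
  } else {
    A <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(0, 0))
    B <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(N, 0))
  }
  mol_of_atom <- rep(seq_len(M), n_atoms)
  w <- if (aggregation == "mean") 1 / n_atoms[mol_of_atom] else rep(1, N)
  S <- Matrix::sparseMatrix(i = mol_of_atom, j = seq_len(N), x = w,
                            dims = c(M, N))

  # 0-based adjacency lists consumed by the compiled training core.
  if (E > 0) {
    a_len <- vapply(cols, length, integer(1))
    a_lists <- list(ptr = c(0L, cumsum(a_len)),
                    idx = as.integer(unlist(cols) - 1L))
    ord <- order(tgt)
    b_lists <- list(ptr = c(0L, cumsum(tabulate(tgt, N))),
                    idx = as.integer(ord - 1L))
  } else {
    a_lists <- list(ptr = 0L, idx = integer(0))
    b_lists <- list(ptr = c(0L, integer(N)), idx = integer(0))
  }
  s_lists <- list(ptr = as.integer(atom_off), idx = seq_len(N) - 1L,
                  w = w)

  list(X_atom = X_atom, X_edge = X_edge, A = A, B = B, S = S,
       N = N, E = E, M = M,
       lists = list(a = a_lists, b = b_lists, s = s_lists))
}

# ---- encoder forward / backward -------------------------------------------

pk_encoder_forward <- function(batch, enc, depth, update_rule) {
  E <- batch$E
  h <- ncol(enc$W_in)
  if (E > 0) {
    H0p <- batch$X_edge %*% enc$W_in
    H <- list(pmax(H0p, 0))
    masks <- list(H0p > 0)
    cats <- list()
    for (t in seq_len(depth)) {
      Mt <- as.matrix(batch$A %*% H[[t]])
      if (update_rule == "concat") {
        Ct <- cbind(H[[t]], Mt)
        Hp <- Ct %*% enc$W_h
        cats[[t]] <- Ct
      } else {
        Hp <- H[[1]] + Mt %*% enc$W_h
        cats[[t]] <- Mt
      }
      H[[t + 1]] <- pmax(Hp, 0)
      masks[[t + 1]] <- Hp > 0
    }
    Z <- as.matrix(batch$B %*% H[[depth + 1]])
  } else {
    H <- list(); masks <- list(); cats <- list()
    Z <- matrix(0, batch$N, h)
  }
  Ca <- cbind(batch$X_atom, Z)
  Ap <- Ca %*% enc$W_a
  A_atom <- pmax(Ap, 0)
  emb <- as.matrix(batch$S %*% A_atom)
  list(H = H, masks = masks, cats = cats, Z = Z, Ca = Ca,
       mask_a = Ap > 0, A_atom = A_atom, emb = emb)
}

pk_encoder_backward <- function(batch, enc, fwd, d_emb, depth, update_rule) {
  g_a <- as.matrix(Matrix::crossprod(batch$S, d_emb)) * fwd$mask_a
  dW_a <- crossprod(fwd$Ca, g_a)
  dCa <- g_a %*% t(enc$W_a)
  d_atom <- ncol(batch$X_atom)
  h <- ncol(enc$W_in)
  dW_in <- matrix(0, nrow(enc$W_in), ncol(enc$W_in))
  dW_h <- matrix(0, nrow(enc$W_h), ncol(enc$W_h))
  if (batch$E > 0) {
    dH <- as.matrix(Matrix::crossprod(batch$B,
                                      dCa[, (d_atom + 1):(d_atom + h), drop = FALSE]))
    dH0_extra <- 0
    for (t in rev(seq_len(depth))) {
      g <- dH * fwd$masks[[t + 1]]
      if (update_rule == "concat") {
        dW_h <- dW_h + crossprod(fwd$cats[[t]], g)
        dC <- g %*% t(enc$W_h)
        dH <- dC[, 1:h, drop = FALSE] +
          as.matrix(Matrix::crossprod(batch$A, dC[, (h + 1):(2 * h), drop = FALSE]))
      } else {
        dW_h <- dW_h + crossprod(fwd$cats[[t]], g)
        dM <- g %*% t(enc$W_h)
        dH <- as.matrix(Matrix::crossprod(batch$A, dM))
        dH0_extra <- dH0_extra + g
      }
    }
    if (!identical(dH0_extra, 0)) dH <- dH + dH0_extra
    g0 <- dH * fwd$masks[[1]]
    dW_in <- crossprod(batch$X_edge, g0)
  }
  list(W_in = dW_in, W_h = dW_h, W_a = dW_a)
}

# ---- feed-forward head -----------------------------------------------------

pk_ffn_forward <- function(U, ffn, dropout = 0, training = FALSE) {
  acts <- list(U)
  masks <- list()
  L <- length(ffn)
  X <- U
  for (l in seq_len(L)) {
    Z <- sweep(X %*% ffn[[l]]$W, 2, ffn[[l]]$b, "+")
    if (l < L) {
      X <- pmax(Z, 0)
      masks[[l]] <- Z > 0
      if (training && dropout > 0) {
        keep <- matrix(stats::rbinom(length(X), 1, 1 - dropout) / (1 - dropout),
                       nrow(X), ncol(X))
        X <- X * keep
        masks[[l]] <- masks[[l]] * keep
      }
      acts[[l + 1]] <- X
    } else {
      X <- Z
    }
  }
  list(out = X, acts = acts, masks = masks)
}

pk_ffn_backward <- function(fwd, ffn, d_out) {
  L <- length(ffn)
  grads <- vector("list", L)
  d <- d_out
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(fwd$acts[[l]], d), b = colSums(d))
    d <- d %*% t(ffn[[l]]$W)
    if (l > 1) d <- d * fwd$masks[[l - 1]]
  }
  list(grads = grads, d_in = d)
}

# ---- user-facing single-molecule operations --------------------------------

#' Encode a molecular graph into an embedding vector
#'
#' Runs the bond-centric message-passing encoder: each directed edge starts
#' from its source-atom and bond features, then for `depth` iterations
#' aggregates the hidden states of the edges incoming to its source atom
#' (excluding its own reverse edge); atom states are read out from incoming
#' edge states and pooled into a fixed-length molecule embedding.
#'
#' @param graph A `mol_graph` from [featurize_molecule()].
#' @param cfg An [encoder_config()].
#' @param params Model parameters (from `pk_init_params()` or a trained
#'   model's `$params`).
#' @param branch `"encoder"` (solute) or `"solvent"`.
#' @return Numeric vector of length `cfg$hidden`.
#' @export
encode_graph <- function(graph, cfg, params, branch = "encoder") {
  stopifnot(inherits(graph, "mol_graph"))
  enc <- params[[branch]]
  depth <- if (branch == "solvent") cfg$solvent_depth else cfg$depth
  batch <- pk_batch_graphs(list(graph), cfg$aggregation)
  fwd <- pk_encoder_forward(batch, enc, depth, cfg$update_rule)
  as.numeric(fwd$emb)
}

#' Predict fluorescence activity for one molecule
#'
#' Activity score in \[0, 1\] under a wavelength-pair condition:
#' `sigmoid(FFN([embedding, scaled wavelength pair]))`.
#'
#' @inheritParams encode_graph
#' @param wavelength_pair Numeric `c(abs_nm, em_nm)`.
#' @return Scalar score in \[0, 1\].
#' @export
predict_activity <- function(graph, wavelength_pair, cfg, params) {
  if (cfg$task != "classification") {
    abort("predict_activity requires a classification configuration",
          class = "probekit_task_mismatch")
  }
  cond <- encode_condition(wavelength_pair[1], wavelength_pair[2])
  emb <- encode_graph(graph, cfg, params)
  U <- matrix(c(emb, cond), 1)
  stats::plogis(pk_ffn_forward(U, params$ffn)$out[1, 1])
}

#' Predict a photophysical property for one molecule in a solvent
#'
#' `denormalize(FFN([solute embedding, solvent embedding]))`, the solvent
#' embedding coming from the solvent-specific encoder branch.
#'
#' @inheritParams encode_graph
#' @param solvent_smiles Solvent SMILES string.
#' @return Predicted value in the property's units.
#' @export
predict_property <- function(graph, solvent_smiles, cfg, params) {
  if (cfg$task != "regression") {
    abort("predict_property requires a regression configuration",
          class = "probekit_task_mismatch")
  }
  s_graph <- featurize_molecule(solvent_smiles)
  emb <- encode_graph(graph, cfg, params)
  s_emb <- encode_graph(s_graph, cfg, params, branch = "solvent")
  U <- matrix(c(emb, s_emb), 1)
  z <- pk_ffn_forward(U, params$ffn)$out[1, 1]
  z * params$target_sd + params$target_mean
}

#' The seven modeled photophysical properties
#'
#' @return Character vector of property names.
#' @export
pk_properties <- function() {
  c("abs_wavelength", "em_wavelength", "abs_fwhm", "em_fwhm",
    "log10_eps", "plqy", "lifetime")
}
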