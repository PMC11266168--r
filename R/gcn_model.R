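# Affinity transform, graph convolution, and the twin-GCN + MLP regressor
# with manual reverse-mode gradients and Adam optimization.

#' Transform an IC50 concentration to the log50k affinity score
#'
#' `score = 1 - log(IC50 nM) / log(50000)`, clamped to `[0, 1]`; 1 nM or
#' stronger maps to 1, 50000 nM or weaker to 0.
#'
#' @param ic50_nM Positive IC50 value(s) in nanomolar.
#' @return Score(s) in `[0, 1]`.
#' @export
ic50_to_score <- function(ic50_nM) {
  if (any(!is.finite(ic50_nM)) || any(ic50_nM <= 0)) {
    stop("IC50 must be positive and finite", call. = FALSE)
  }
  pmin(1, pmax(0, 1 - log(ic50_nM) / log(50000)))
}

#' Invert the log50k transform
#'
#' @param score Affinity score(s) in `[0, 1]`.
#' @return IC50 in nanomolar, `exp((1 - score) * log(50000))`.
#' @export
score_to_ic50 <- function(score) {
  if (any(score < 0 | score > 1)) {
    stop("score must lie in [0, 1]", call. = FALSE)
  }
  exp((1 - score) * log(50000))
}

#' The binder cutoff on the transformed scale
#'
#' The 500 nM classification threshold expressed as a log50k score,
#' held at full precision (about 0.426).
#'
#' @return A single numeric value.
#' @export
binder_cutoff_score <- function() 1 - log(500) / log(50000)

#' Classify transformed scores into binders and nonbinders
#'
#' Scores strictly greater than the 500 nM cutoff score classify as
#' binders (an IC50 of exactly 500 nM is a nonbinder).
#'
#' @param score Score(s) in `[0, 1]`.
#' @param cutoff Cutoff score; default [binder_cutoff_score()].
#' @return Character vector of `"binder"` / `"nonbinder"`.
#' @export
classify_binder <- function(score, cutoff = binder_cutoff_score()) {
  if (any(score < 0 | score > 1)) {
    stop("score must lie in [0, 1]", call. = FALSE)
  }
  ifelse(score > cutoff, "binder", "nonbinder")
}

#' Symmetrically normalized adjacency with self-loops
#'
#' Builds `Abar = Dhat^(-1/2) (A + I) Dhat^(-1/2)` from an undirected edge
#' list, the propagation operator of the graph convolution. With
#' `edge_weight_mode = "distance_inverse"`, entries of `A` are `1/distance`
#' before augmentation (edges lacking a distance fall back to 1).
#'
#' @param edges Data frame with columns `i`, `j` (1-based node indices) and
#'   optionally `distance`; duplicate pairs (e.g. the same residue pair
#'   under two bond types) collapse to a single adjacency entry keeping the
#'   maximum weight.
#' @param n Number of nodes.
#' @param edge_weight_mode `"binary"` (default) or `"distance_inverse"`.
#' @return Dense symmetric `n x n` matrix.
#' @export
normalize_adjacency <- function(edges, n, edge_weight_mode = "binary") {
  stopifnot(n >= 1L)
  A <- matrix(0, n, n)
  if (!is.null(edges) && nrow(edges)) {
    if (any(edges$i < 1L | edges$i > n | edges$j < 1L | edges$j > n)) {
      stop("edge index out of range", call. = FALSE)
    }
    if (any(edges$i == edges$j)) {
      stop("self-loops are not stored in edge lists", call. = FALSE)
    }
    w <- if (edge_weight_mode == "distance_inverse") {
      d <- edges$distance
      if (is.null(d)) d <- rep(1, nrow(edges))
      ifelse(is.finite(1 / d), 1 / d, 1)
    } else if (edge_weight_mode == "binary") {
      rep(1, nrow(edges))
    } else {
      stop("unknown edge_weight_mode '", edge_weight_mode, "'",
           call. = FALSE)
    }
    for (r in seq_len(nrow(edges))) {
      i <- edges$i[r]; j <- edges$j[r]
      A[i, j] <- max(A[i, j], w[r])
      A[j, i] <- A[i, j]
    }
  }
  Ahat <- A + diag(n)
  dinv <- 1 / sqrt(rowSums(Ahat))
  Ahat * outer(dinv, dinv)
}

#' One graph convolution layer
#'
#' `H' = ReLU(Abar H W)` with `Abar` the normalized self-loop-augmented
#' adjacency from [normalize_adjacency()].
#'
#' @param H Node embedding matrix (N x C_in).
#' @param Abar Normalized adjacency (N x N).
#' @param W Weight matrix (C_in x C_out).
#' @return N x C_out matrix.
#' @export
gcn_layer <- function(H, Abar, W) {
  if (ncol(H) != nrow(W) || nrow(H) != ncol(Abar)) {
    stop("gcn_layer shape mismatch: H is ", nrow(H), "x", ncol(H),
         ", Abar ", nrow(Abar), "x", ncol(Abar),
         ", W ", nrow(W), "x", ncol(W), call. = FALSE)
  }
  pmax(Abar %*% H %*% W, 0)
}

#' Permutation-invariant graph readout
#'
#' Pools node embeddings into one graph-level vector by per-channel mean,
#' sum, or max.
#'
#' @param H Node embedding matrix (N x C), N >= 1.
#' @param mode `"mean"`, `"sum"`, or `"max"`.
#' @return Numeric vector of length C.
#' @export
graph_readout <- function(H, mode = c("mean", "sum", "max")) {
  mode <- match.arg(mode)
  stopifnot(nrow(H) >= 1L)
  switch(mode,
         mean = colMeans(H),
         sum = colSums(H),
         max = apply(H, 2L, max))
}

#' Model configuration
#'
#' Hyperparameters of the twin-GCN affinity regressor. The MLP head has
#' exactly three hidden linear layers, each followed by ReLU and dropout,
#' then a final linear output unit.
#'
#' @param hla_layer_dims Hidden widths of the HLA-branch GCN stack.
#' @param pep_layer_dims Hidden widths of the peptide-branch GCN stack
#'   (depth sets the bond-hop receptive field of each atom embedding).
#' @param readout Pooling mode, see [graph_readout()].
#' @param mlp_dims The three hidden widths of the MLP head.
#' @param dropout Dropout fraction in `[0, 1)` applied after each MLP ReLU
#'   during training.
#' @param learning_rate Adam step size.
#' @param n_epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @param edge_weight_mode Adjacency weighting, see [normalize_adjacency()].
#' @param standardize_features Standardize node features per channel using
#'   training-set statistics (stored in the model, applied at prediction).
#' @param hla_input_dim,pep_input_dim Input feature widths (43 and 22).
#' @return A `gcn_config` list.
#' @export
gcn_config <- function(hla_layer_dims = c(32L, 32L),
                       pep_layer_dims = c(48L, 48L, 48L),
                       readout = "mean",
                       mlp_dims = c(64L, 32L, 16L),
                       dropout = 0.1,
                       learning_rate = 5e-3,
                       n_epochs = 200L,
                       batch_size = 16L,
                       seed = 1L,
                       edge_weight_mode = "binary",
                       standardize_features = TRUE,
                       hla_input_dim = RESIDUE_FEATURE_WIDTH,
                       pep_input_dim = ATOM_FEATURE_WIDTH) {
  stopifnot(length(hla_layer_dims) >= 1L, length(pep_layer_dims) >= 1L,
            length(mlp_dims) == 3L,
            dropout >= 0, dropout < 1,
            learning_rate > 0, n_epochs >= 1L, batch_size >= 1L)
  readout <- match.arg(readout, c("mean", "sum", "max"))
  edge_weight_mode <- match.arg(edge_weight_mode,
                                c("binary", "distance_inverse"))
  structure(list(
    hla_layer_dims = as.integer(hla_layer_dims),
    pep_layer_dims = as.integer(pep_layer_dims),
    readout = readout,
    mlp_dims = as.integer(mlp_dims),
    dropout = dropout,
    learning_rate = learning_rate,
    n_epochs = as.integer(n_epochs),
    batch_size = as.integer(batch_size),
    seed = as.integer(seed),
    edge_weight_mode = edge_weight_mode,
    standardize_features = isTRUE(standardize_features),
    hla_input_dim = as.integer(hla_input_dim),
    pep_input_dim = as.integer(pep_input_dim)
  ), class = "gcn_config")
}

glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

#' Initialize an untrained affinity model
#'
#' Weights drawn from scaled normal initialization under the config seed;
#' feature standardization is the identity until a training set provides
#' statistics.
#'
#' @param config A [gcn_config()].
#' @return An `affinity_model`.
#' @export
init_affinity_model <- function(config) {
  stopifnot(inherits(config, "gcn_config"))
  set.seed(config$seed)
  mk_branch <- function(input_dim, dims) {
    full <- c(input_dim, dims)
    lapply(seq_along(dims), function(l) glorot(full[l], full[l + 1L]))
  }
  hla_W <- mk_branch(config$hla_input_dim, config$hla_layer_dims)
  pep_W <- mk_branch(config$pep_input_dim, config$pep_layer_dims)
  zdim <- config$hla_layer_dims[length(config$hla_layer_dims)] +
    config$pep_layer_dims[length(config$pep_layer_dims)]
  full <- c(zdim, config$mlp_dims, 1L)
  mlp <- lapply(seq_len(4L), function(k) {
    list(W = glorot(full[k], full[k + 1L]), b = rep(0, full[k + 1L]))
  })
  structure(list(
    config = config,
    std = list(
      hla = list(mean = rep(0, config$hla_input_dim),
                 sd = rep(1, config$hla_input_dim)),
      pep = list(mean = rep(0, config$pep_input_dim),
                 sd = rep(1, config$pep_input_dim))
    ),
    hla_W = hla_W, pep_W = pep_W, mlp = mlp,
    training_history = numeric(0)
  ), class = "affinity_model")
}

#' @export
print.affinity_model <- function(x, ...) {
  cfg <- x$config
  cat("<affinity_model>\n",
      "  HLA GCN:  ", cfg$hla_input_dim, " -> ",
      paste(cfg$hla_layer_dims, collapse = " -> "), "\n",
      "  pep GCN:  ", cfg$pep_input_dim, " -> ",
      paste(cfg$pep_layer_dims, collapse = " -> "), "\n",
      "  MLP:      ", paste(cfg$mlp_dims, collapse = " -> "), " -> 1",
      " (dropout ", cfg$dropout, ")\n",
      "  readout:  ", cfg$readout, "\n",
      "  trained:  ", length(x$training_history), " epochs\n", sep = "")
  invisible(x)
}

# standardized feature matrix + propagation tensors for one graph
prepare_graph <- function(model, g, branch = c("hla", "pep")) {
  branch <- match.arg(branch)
  X <- g$X
  want <- if (branch == "hla") model$config$hla_input_dim else
    model$config$pep_input_dim
  if (ncol(X) != want) {
    stop("feature-width mismatch in ", branch, " branch: graph has ",
         ncol(X), " features, model expects ", want, call. = FALSE)
  }
  if (model$config$standardize_features) {
    st <- model$std[[branch]]
    X <- sweep(sweep(X, 2L, st$mean), 2L, st$sd, "/")
  }
  ed <- if (inherits(g, "residue_graph")) g$edges else g$bonds
  Abar <- normalize_adjacency(ed, nrow(X), model$config$edge_weight_mode)
  # the first-layer propagation Abar X is weight-independent; cache it
  list(X = X, Abar = Abar, M1 = Abar %*% X)
}

# forward through one GCN branch; returns readout vector + caches
branch_forward <- function(Ws, tens, readout) {
  H <- tens$X
  L <- length(Ws)
  Ms <- vector("list", L)   # Abar %*% H_{l-1}
  Zpos <- vector("list", L) # ReLU masks
  Hs <- vector("list", L)
  for (l in seq_len(L)) {
    M <- if (l == 1L && !is.null(tens$M1)) tens$M1 else tens$Abar %*% H
    Z <- M %*% Ws[[l]]
    H <- pmax(Z, 0)
    Ms[[l]] <- M; Zpos[[l]] <- Z > 0; Hs[[l]] <- H
  }
  h <- graph_readout(H, readout)
  argmax <- if (readout == "max") max.col(t(H), ties.method = "first") else NULL
  list(h = h, Ms = Ms, Zpos = Zpos, Hs = Hs, T = H, argmax = argmax,
       n = nrow(tens$X))
}

# gradient of readout vector back onto node embeddings
readout_backward <- function(dvec, cache, readout) {
  n <- cache$n; C <- length(dvec)
  if (readout == "mean") {
    matrix(rep(dvec / n, each = n), n, C)
  } else if (readout == "sum") {
    matrix(rep(dvec, each = n), n, C)
  } else {
    dH <- matrix(0, n, C)
    dH[cbind(cache$argmax, seq_len(C))] <- dvec
    dH
  }
}

# backprop through a branch given dL/dreadout; returns weight grads
branch_backward <- function(Ws, tens, cache, dvec, readout) {
  L <- length(Ws)
  dH <- readout_backward(dvec, cache, readout)
  gW <- vector("list", L)
  for (l in rev(seq_len(L))) {
    dZ <- dH * cache$Zpos[[l]]
    gW[[l]] <- crossprod(cache$Ms[[l]], dZ)
    if (l > 1L) {
      dH <- tens$Abar %*% (dZ %*% t(Ws[[l]]))
    }
  }
  gW
}

# forward through the MLP head from the concatenated vector z0
mlp_forward <- function(mlp, z0, dropout = 0, training = FALSE) {
  z <- z0
  zs <- vector("list", 3L)
  relu_mask <- vector("list", 3L)
  drop_mask <- vector("list", 3L)
  for (k in seq_len(3L)) {
    a <- drop(z %*% mlp[[k]]$W) + mlp[[k]]$b
    r <- pmax(a, 0)
    relu_mask[[k]] <- a > 0
    if (training && dropout > 0) {
      m <- (stats::runif(length(r)) >= dropout) / (1 - dropout)
      drop_mask[[k]] <- m
      r <- r * m
    } else {
      drop_mask[[k]] <- rep(1, length(r))
    }
    zs[[k]] <- r
    z <- r
  }
  P <- drop(z %*% mlp[[4L]]$W) + mlp[[4L]]$b
  list(P = as.numeric(P), zs = zs, relu_mask = relu_mask,
       drop_mask = drop_mask, z0 = z0)
}

# backprop dL/dP through the MLP; returns grads and dL/dz0
mlp_backward <- function(mlp, cache, dP) {
  g <- vector("list", 4L)
  dz <- dP * as.numeric(mlp[[4L]]$W)        # dL/dz3
  g[[4L]] <- list(W = matrix(cache$zs[[3L]] * dP, ncol = 1L), b = dP)
  for (k in rev(seq_len(3L))) {
    dr <- dz * cache$drop_mask[[k]]
    da <- dr * cache$relu_mask[[k]]
    zin <- if (k == 1L) cache$z0 else cache$zs[[k - 1L]]
    g[[k]] <- list(W = outer(zin, da), b = da)
    dz <- drop(mlp[[k]]$W %*% da)
  }
  list(grads = g, dz0 = dz)
}

# full forward for one (hla, pep) pair; eval mode unless training
pair_forward <- function(model, hla_t, pep_t, training = FALSE) {
  ch <- branch_forward(model$hla_W, hla_t, model$config$readout)
  cp <- branch_forward(model$pep_W, pep_t, model$config$readout)
  z0 <- c(ch$h, cp$h)
  cm <- mlp_forward(model$mlp, z0, model$config$dropout, training)
  list(P = cm$P, hla = ch, pep = cp, mlp = cm)
}

#' Predict the binding affinity score of one HLA-peptide pair
#'
#' Deterministic evaluation-mode forward pass (dropout off); the raw MLP
#' output is clamped to `[0, 1]`.
#'
#' @param model A trained or initialized `affinity_model`.
#' @param hla A `residue_graph`.
#' @param pep An `atom_graph`.
#' @param clamp Clamp the output into `[0, 1]` (default `TRUE`).
#' @return A single numeric score.
#' @export
predict_affinity <- function(model, hla, pep, clamp = TRUE) {
  stopifnot(inherits(model, "affinity_model"))
  ht <- prepare_graph(model, hla, "hla")
  pt <- prepare_graph(model, pep, "pep")
  P <- pair_forward(model, ht, pt, training = FALSE)$P
  if (clamp) min(1, max(0, P)) else P
}

# --- training -------------------------------------------------------------

# normalize the accepted dataset shapes into (samples, hla keys, graphs)
coerce_training_set <- function(dataset) {
  if (inherits(dataset, "affinity_dataset")) return(dataset)
  if (!is.list(dataset) || !length(dataset)) {
    stop("empty training dataset", call. = FALSE)
  }
  hla_graphs <- list(); hla_key <- character(length(dataset))
  pep_graphs <- vector("list", length(dataset))
  y <- numeric(length(dataset))
  for (s in seq_along(dataset)) {
    smp <- dataset[[s]]
    if (!all(c("hla", "pep", "y") %in% names(smp))) {
      stop("each sample needs fields hla, pep, y", call. = FALSE)
    }
    hit <- NA_integer_
    for (k in seq_along(hla_graphs)) {
      if (identical(hla_graphs[[k]], smp$hla)) { hit <- k; break }
    }
    if (is.na(hit)) {
      hla_graphs[[length(hla_graphs) + 1L]] <- smp$hla
      hit <- length(hla_graphs)
    }
    hla_key[s] <- as.character(hit)
    pep_graphs[[s]] <- smp$pep
    y[s] <- smp$y
  }
  names(hla_graphs) <- as.character(seq_along(hla_graphs))
  structure(list(
    samples = data.frame(hla_id = hla_key,
                         pep_id = seq_along(dataset),
                         y = y, stringsAsFactors = FALSE),
    hla_graphs = hla_graphs,
    pep_graphs = stats::setNames(pep_graphs,
                                 as.character(seq_along(pep_graphs)))
  ), class = "affinity_dataset")
}

adam_new <- function(shapes) {
  lapply(shapes, function(s) list(m = array(0, dim = s),
                                  v = array(0, dim = s)))
}

#' Train the affinity model
#'
#' Minimizes mean squared error between the raw MLP output and the log50k
#' scores with Adam on minibatches. All randomness (initialization,
#' shuffling, dropout) is controlled by `config$seed`; identical seeds give
#' identical training histories. The per-epoch training MSE is recorded in
#' `training_history`.
#'
#' @param dataset Either an `affinity_dataset` (see
#'   [build_training_set()]) or a plain list of samples, each a list with
#'   fields `hla` (`residue_graph`), `pep` (`atom_graph`) and `y` (score in
#'   `[0, 1]`).
#' @param config A [gcn_config()].
#' @return A trained `affinity_model`.
#' @export
train_affinity_model <- function(dataset, config = gcn_config()) {
  ds <- coerce_training_set(dataset)
  n <- nrow(ds$samples)
  if (n < 1L) stop("empty training dataset", call. = FALSE)
  if (any(ds$samples$y < 0 | ds$samples$y > 1)) {
    stop("training scores must lie in [0, 1]", call. = FALSE)
  }
  model <- init_affinity_model(config)

  if (config$standardize_features) {
    hstack <- do.call(rbind, lapply(ds$hla_graphs, `[[`, "X"))
    pstack <- do.call(rbind, lapply(ds$pep_graphs, `[[`, "X"))
    mk <- function(S) {
      mu <- colMeans(S); sd <- apply(S, 2L, stats::sd)
      sd[!is.finite(sd) | sd < 1e-8] <- 1
      list(mean = mu, sd = sd)
    }
    model$std$hla <- mk(hstack)
    model$std$pep <- mk(pstack)
  }

  hla_t <- lapply(ds$hla_graphs, prepare_graph, model = model,
                  branch = "hla")
  pep_t <- lapply(ds$pep_graphs, prepare_graph, model = model,
                  branch = "pep")

  # flatten parameters for Adam bookkeeping
  nh <- length(model$hla_W); np <- length(model$pep_W)
  get_params <- function(m) {
    c(m$hla_W, m$pep_W,
      lapply(m$mlp, `[[`, "W"), lapply(m$mlp, `[[`, "b"))
  }
  set_params <- function(m, pl) {
    m$hla_W <- pl[seq_len(nh)]
    m$pep_W <- pl[nh + seq_len(np)]
    for (k in seq_len(4L)) {
      m$mlp[[k]]$W <- pl[[nh + np + k]]
      m$mlp[[k]]$b <- as.numeric(pl[[nh + np + 4L + k]])
    }
    m
  }
  params <- get_params(model)
  opt <- adam_new(lapply(params, function(p) {
    if (is.matrix(p)) dim(p) else length(p)
  }))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t_step <- 0L
  history <- numeric(config$n_epochs)

  for (epoch in seq_len(config$n_epochs)) {
    ord <- sample.int(n)
    sq_err <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      bidx <- ord[start:min(start + config$batch_size - 1L, n)]
      grads <- lapply(params, function(p) p * 0)
      # forward the HLA branch once per distinct molecule in the batch
      keys <- unique(ds$samples$hla_id[bidx])
      hcache <- lapply(keys, function(k)
        branch_forward(model$hla_W, hla_t[[k]], config$readout))
      names(hcache) <- keys
      dvec_h <- lapply(hcache, function(cc) numeric(length(cc$h)))
      for (s in bidx) {
        key <- ds$samples$hla_id[s]
        ch <- hcache[[key]]
        cp <- branch_forward(model$pep_W,
                             pep_t[[as.character(ds$samples$pep_id[s])]],
                             config$readout)
        z0 <- c(ch$h, cp$h)
        cm <- mlp_forward(model$mlp, z0, config$dropout, training = TRUE)
        err <- cm$P - ds$samples$y[s]
        sq_err <- sq_err + err^2
        dP <- 2 * err / length(bidx)
        mb <- mlp_backward(model$mlp, cm, dP)
        Ch <- length(ch$h)
        dvec_h[[key]] <- dvec_h[[key]] + mb$dz0[seq_len(Ch)]
        dpep <- mb$dz0[(Ch + 1L):length(mb$dz0)]
        gp <- branch_backward(model$pep_W,
                              pep_t[[as.character(ds$samples$pep_id[s])]],
                              cp, dpep, config$readout)
        for (l in seq_len(np)) {
          grads[[nh + l]] <- grads[[nh + l]] + gp[[l]]
        }
        for (k in seq_len(4L)) {
          grads[[nh + np + k]] <- grads[[nh + np + k]] + mb$grads[[k]]$W
          grads[[nh + np + 4L + k]] <-
            grads[[nh + np + 4L + k]] + mb$grads[[k]]$b
        }
      }
      for (key in keys) {
        gh <- branch_backward(model$hla_W, hla_t[[key]], hcache[[key]],
                              dvec_h[[key]], config$readout)
        for (l in seq_len(nh)) grads[[l]] <- grads[[l]] + gh[[l]]
      }
      # Adam step
      t_step <- t_step + 1L
      for (pidx in seq_along(params)) {
        g <- grads[[pidx]]
        opt[[pidx]]$m <- b1 * opt[[pidx]]$m + (1 - b1) * g
        opt[[pidx]]$v <- b2 * opt[[pidx]]$v + (1 - b2) * g^2
        mhat <- opt[[pidx]]$m / (1 - b1^t_step)
        vhat <- opt[[pidx]]$v / (1 - b2^t_step)
        params[[pidx]] <- params[[pidx]] -
          config$learning_rate * mhat / (sqrt(vhat) + eps)
      }
      model <- set_params(model, params)
    }
    history[epoch] <- sq_err / n
  }
  model$training_history <- history
  model
}

#' Assemble a training set from affinity records and graphs
#'
#' Builds peptide graphs once per unique sequence and pairs every record
#' with its HLA residue graph. Records may carry `ic50_nM` (transformed via
#' [ic50_to_score()]) or a precomputed `score`.
#'
#' @param records Data frame with columns `hla_id`, `peptide_seq` and one
#'   of `ic50_nM` / `score`.
#' @param hla_graphs Named list of `residue_graph` objects keyed by
#'   `hla_id`.
#' @return An `affinity_dataset`.
#' @export
build_training_set <- function(records, hla_graphs) {
  stopifnot(is.data.frame(records),
            all(c("hla_id", "peptide_seq") %in% names(records)))
  missing_hla <- setdiff(unique(records$hla_id), names(hla_graphs))
  if (length(missing_hla)) {
    stop("no residue graph supplied for HLA(s): ",
         paste(missing_hla, collapse = ", "), call. = FALSE)
  }
  y <- if ("score" %in% names(records)) {
    records$score
  } else if ("ic50_nM" %in% names(records)) {
    ic50_to_score(records$ic50_nM)
  } else {
    stop("records need an ic50_nM or score column", call. = FALSE)
  }
  seqs <- unique(records$peptide_seq)
  pg <- lapply(seqs, function(s) suppressWarnings(build_peptide_graph(s)))
  names(pg) <- seqs
  structure(list(
    samples = data.frame(hla_id = records$hla_id,
                         pep_id = records$peptide_seq,
                         y = y, stringsAsFactors = FALSE),
    hla_graphs = hla_graphs[unique(records$hla_id)],
    pep_graphs = pg
  ), class = "affinity_dataset")
}

#' Save a model checkpoint
#'
#' Single-file JSON archive holding the full configuration, feature
#' standardization statistics, all weights, and the training history;
#' [load_affinity_model()] restores it losslessly.
#'
#' @param model An `affinity_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_affinity_model <- function(model, path) {
  obj <- list(
    format = "pepGCN-checkpoint-1",
    config = unclass(model$config),
    std = model$std,
    hla_W = model$hla_W,
    pep_W = model$pep_W,
    mlp = model$mlp,
    training_history = model$training_history
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File written by [save_affinity_model()].
#' @return An `affinity_model`.
#' @export
load_affinity_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "pepGCN-checkpoint-1")) {
    stop("not a model checkpoint: ", path, call. = FALSE)
  }
  cfg <- do.call(gcn_config, obj$config[setdiff(names(obj$config), NULL)])
  model <- init_affinity_model(cfg)
  model$std <- obj$std
  model$hla_W <- lapply(obj$hla_W, as.matrix)
  model$pep_W <- lapply(obj$pep_W, as.matrix)
  model$mlp <- lapply(obj$mlp, function(l) {
    list(W = as.matrix(l$W), b = as.numeric(l$b))
  })
  model$training_history <- as.numeric(obj$training_history)
  model
}
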