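#' Model configuration
#'
#' Hyperparameters of the cross-omics graph network: a relational graph
#' convolution encoder over the fixed heterogeneous graph, an attentive
#' per-modality readout, attention-based fusion of the three modality
#' vectors, and a softmax classifier, trained with a graph Laplacian
#' smoothness penalty and weight decay.
#'
#' @param hidden_dim Hidden width of node states (default 12 at desk scale).
#' @param num_layers Number of message-passing layers L (default 2).
#' @param inverse_relations Add learnable reverse relations (CpG->gene /
#'   gene->CpG / miRNA->gene / gene->miRNA each with its own weight matrix)
#'   so gene evidence can reach CpG and miRNA states. When `FALSE` the
#'   gene-CpG relation is undirected with one shared matrix and the
#'   miRNA->gene relation flows only into genes.
#' @param lambda_gr Weight of the graph smoothness penalty (default 1e-5;
#'   the penalty sums over all edges and hidden units, so small weights
#'   already move the optimum).
#' @param lambda_wd Weight decay coefficient (default 3e-3).
#' @param dropout Dropout rate on hidden node states during training
#'   (default 0.1).
#' @param num_classes Number of subtype classes K (default 5).
#' @param seed Seed for parameter initialization.
#' @return A `xonet_config` list.
#' @export
xonet_config <- function(hidden_dim = 12L, num_layers = 2L,
                         inverse_relations = TRUE, lambda_gr = 1e-5,
                         lambda_wd = 3e-3, dropout = 0.1,
                         num_classes = 5L, seed = 1L) {
  stopifnot(hidden_dim >= 1, num_layers >= 1, lambda_gr >= 0, lambda_wd >= 0,
            dropout >= 0, dropout < 1, num_classes >= 2)
  structure(
    list(
      hidden_dim = as.integer(hidden_dim), num_layers = as.integer(num_layers),
      inverse_relations = isTRUE(inverse_relations),
      lambda_gr = lambda_gr, lambda_wd = lambda_wd, dropout = dropout,
      num_classes = as.integer(num_classes), seed = as.integer(seed)
    ),
    class = "xonet_config"
  )
}

# Message-passing structure derived from a hetero_graph: per-relation edge
# index vectors, destination degrees, a global edge-id space (gene-CpG
# edges first, then miRNA->gene) shared by the attribution gates, plus the
# precomputed sparse operators of the d x (n*P) state layout (readout
# summers and regularizer scatter maps).
build_mp <- function(graph, config) {
  d <- config$hidden_dim
  nn <- graph_n_nodes(graph)
  gc <- graph$edges$gc
  mg <- graph$edges$mg
  n_gc <- nrow(gc)
  n_mg <- nrow(mg)
  rel <- function(name, wname, src, dst, src_idx, dst_idx, edge_id) {
    list(
      name = name, wname = wname, src = src, dst = dst,
      src_idx = src_idx, dst_idx = dst_idx, edge_id = edge_id,
      deg = tabulate(dst_idx, nbins = nn[[dst]])
    )
  }
  gc_id <- seq_len(n_gc)
  mg_id <- n_gc + seq_len(n_mg)
  if (config$inverse_relations) {
    rels <- list(
      rel("c2g", "c2g", "c", "g", gc$cpg, gc$gene, gc_id),
      rel("g2c", "g2c", "g", "c", gc$gene, gc$cpg, gc_id),
      rel("m2g", "m2g", "m", "g", mg$mirna, mg$gene, mg_id),
      rel("g2m", "g2m", "g", "m", mg$gene, mg$mirna, mg_id)
    )
  } else {
    rels <- list(
      rel("c2g", "gc", "c", "g", gc$cpg, gc$gene, gc_id),
      rel("g2c", "gc", "g", "c", gc$gene, gc$cpg, gc_id),
      rel("m2g", "m2g", "m", "g", mg$mirna, mg$gene, mg_id)
    )
  }
  Rsum <- purrr::map(nn, function(n) {
    kron_id(Matrix::sparseMatrix(i = rep(1L, n), j = seq_len(n), x = 1,
                                 dims = c(1L, n)), d)
  })
  names(Rsum) <- c("g", "c", "m")
  reg_pair <- function(a, b, ia, ib, w) {
    ne <- length(ia)
    list(
      a = a, b = b, ia = ia, ib = ib, w = w, ne = ne,
      Sa = if (ne) kron_id(Matrix::sparseMatrix(i = seq_len(ne), j = ia, x = 1,
                                                dims = c(ne, nn[[a]])), d),
      Sb = if (ne) kron_id(Matrix::sparseMatrix(i = seq_len(ne), j = ib, x = 1,
                                                dims = c(ne, nn[[b]])), d)
    )
  }
  mp <- list(
    n = nn, d = d, rels = rels, n_edges = n_gc + n_mg, n_gc = n_gc,
    n_mg = n_mg, wnames = unique(purrr::map_chr(rels, "wname")),
    Rsum = Rsum,
    reg = list(
      reg_pair("c", "g", gc$cpg, gc$gene, gc$weight),
      reg_pair("m", "g", mg$mirna, mg$gene, mg$weight)
    )
  )
  # unit-gate aggregation operators (the training hot path) cached once;
  # attribution passes with non-unit gates rebuild them on the fly
  mp$K1 <- build_agg(mp, rep(1, mp$n_edges))
  mp$K1t <- purrr::map(mp$K1, Matrix::t)
  # 0-based index structures for the compiled training core
  t_idx <- c(g = 0L, c = 1L, m = 2L)
  mp$cpp <- list(
    rels = purrr::map(rels, function(r) {
      list(src = t_idx[[r$src]], dst = t_idx[[r$dst]],
           src_idx = r$src_idx - 1L, dst_idx = r$dst_idx - 1L,
           inv_deg = 1 / r$deg[r$dst_idx], wname = r$wname)
    }),
    regs = purrr::map(mp$reg, function(pr) {
      list(a = t_idx[[pr$a]], b = t_idx[[pr$b]],
           ia = pr$ia - 1L, ib = pr$ib - 1L, w = pr$w)
    })
  )
  mp
}

# Fast prediction probabilities through the compiled forward pass.
forward_probs_cpp <- function(params, mp, batch, config) {
  m <- batch$mask
  storage.mode(m) <- "integer"
  pr <- .cpp_forward_probs(params, unname(batch$X), m, mp$cpp$rels,
                           config$num_layers, config$hidden_dim)
  pr
}

# Seeded parameter initialization (Glorot-style scaling).
init_params <- function(mp, config) {
  d <- config$hidden_dim
  K <- config$num_classes
  set.seed(derive_seed(config$seed, "init"))
  glorot <- function(nr, nc) {
    matrix(rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
  }
  p <- list()
  for (t in c("g", "c", "m")) {
    p[[paste0("proj_w_", t)]] <- rnorm(d, sd = sqrt(2 / (1 + d)))
    p[[paste0("proj_b_", t)]] <- numeric(d)
  }
  for (l in seq_len(config$num_layers)) {
    p[[paste0("W0_", l)]] <- glorot(d, d)
    for (w in mp$wnames) p[[paste0("Wr_", w, "_", l)]] <- glorot(d, d)
  }
  # attention score vectors start small so early attention is near-uniform
  # (a spiky softmax at initialization starves most nodes of gradient)
  for (t in c("g", "c", "m")) {
    p[[paste0("Watt_", t)]] <- glorot(d, d)
    p[[paste0("aatt_", t)]] <- rnorm(d, sd = 0.1 * sqrt(2 / (d + 1)))
  }
  p$U <- glorot(d, d)
  p$q <- rnorm(d, sd = 0.1 * sqrt(2 / (d + 1)))
  p$Wo <- glorot(K, d)
  p$bo <- numeric(K)
  p
}

# Per-relation aggregation operators (A %x% I_d) with A[v, u] =
# gate_e / |N_r(v)|.
build_agg <- function(mp, gates) {
  purrr::map(mp$rels, function(r) {
    A <- Matrix::sparseMatrix(
      i = r$dst_idx, j = r$src_idx, x = gates[r$edge_id] / r$deg[r$dst_idx],
      dims = c(mp$n[[r$dst]], mp$n[[r$src]])
    )
    kron_id(A, mp$d)
  })
}

# Patient-major column index of nodes `idx` across all P patients.
colidx <- function(idx, n, P) {
  rep(seq(0L, P - 1L) * n, each = length(idx)) + idx
}

#' Initialize node states from a patient batch
#'
#' Each node carries one scalar molecular measurement per patient; the
#' scalar is lifted to the hidden dimension through the node type's learned
#' affine projection. Nodes of a masked modality carry the projection of
#' zero.
#'
#' @param batch A `patient_batch` (see [prepare_batch()]).
#' @param params Model parameter list.
#' @param d Hidden dimension.
#' @return List of layer-0 state matrices (`d` x nodes*patients) per type.
#' @keywords internal
init_node_states <- function(batch, params, d) {
  purrr::imap(batch$X, function(X, t) {
    X[, !batch$mask[t, ]] <- 0
    outer(params[[paste0("proj_w_", t)]], as.vector(X)) +
      params[[paste0("proj_b_", t)]]
  })
}

# Full forward pass. Returns probabilities plus (optionally) every
# intermediate needed for reverse-mode gradients.
xonet_forward <- function(params, mp, batch, config, gates = NULL,
                          training = FALSE, keep_cache = FALSE) {
  d <- config$hidden_dim
  P <- ncol(batch$X$g)
  mask <- batch$mask
  unit_gates <- is.null(gates)
  gates <- gates %||% rep(1, mp$n_edges)
  K <- if (unit_gates) mp$K1 else build_agg(mp, gates)
  Kt <- if (unit_gates) mp$K1t else purrr::map(K, Matrix::t)

  X <- purrr::imap(batch$X, function(Xt, t) {
    Xt[, !mask[t, ]] <- 0
    Xt
  })
  H <- init_node_states(list(X = X, mask = mask), params, d)
  Hs <- list(H)
  pres <- list()
  drops <- list()
  for (l in seq_len(config$num_layers)) {
    W0 <- params[[paste0("W0_", l)]]
    pre <- lapply(H, function(h) W0 %*% h)
    for (ri in seq_along(mp$rels)) {
      r <- mp$rels[[ri]]
      if (length(r$src_idx) == 0L) next
      Wr <- params[[paste0("Wr_", r$wname, "_", l)]]
      pre[[r$dst]] <- pre[[r$dst]] + agg_apply(K[[ri]], Wr %*% H[[r$src]], d)
    }
    H <- lapply(pre, relu)
    if (training && config$dropout > 0) {
      keep <- 1 - config$dropout
      dm <- lapply(H, function(h) {
        matrix((runif(length(h)) < keep) / keep, nrow(h))
      })
      H <- Map(`*`, H, dm)
      drops[[l]] <- dm
    }
    pres[[l]] <- pre
    Hs[[l + 1L]] <- H
  }

  # attentive readout per node type
  alpha <- list()
  ztyp <- list()
  Ts <- list()
  for (t in c("g", "c", "m")) {
    n <- mp$n[[t]]
    Tt <- tanh(params[[paste0("Watt_", t)]] %*% H[[t]])
    score <- matrix(as.numeric(crossprod(params[[paste0("aatt_", t)]], Tt)),
                    n, P)
    al <- col_softmax(score)
    alpha[[t]] <- al
    Ts[[t]] <- Tt
    Hal <- H[[t]] * rep(as.vector(al), each = d)
    dim(Hal) <- c(d * n, P)
    ztyp[[t]] <- as.matrix(mp$Rsum[[t]] %*% Hal)
  }

  # modality fusion over present modalities only
  u <- purrr::map(ztyp, ~ tanh(params$U %*% .x))
  f <- do.call(rbind, purrr::map(u, ~ as.numeric(crossprod(params$q, .x))))
  rownames(f) <- c("g", "c", "m")
  f[!mask] <- -Inf
  beta <- col_softmax(f)
  z <- matrix(0, d, P)
  for (t in c("g", "c", "m")) {
    z <- z + sweep(ztyp[[t]], 2L, beta[t, ], "*")
  }

  logits <- params$Wo %*% z + params$bo
  probs <- col_softmax(logits)
  out <- list(
    probs = probs, logits = logits, beta = beta, alpha = alpha,
    z = z, ztyp = ztyp, H_final = H
  )
  if (keep_cache) {
    out$cache <- list(
      X = X, Hs = Hs, pres = pres, drops = drops, K = K, Kt = Kt,
      gates = gates, Ts = Ts, u = u, mask = mask, d = d, P = P
    )
  }
  out
}

#' Graph smoothness regularizer on final node embeddings
#'
#' Sum over both relations of (optionally weighted) squared differences
#' between the final-layer embeddings of each edge's endpoints, computed
#' per patient. Zero exactly when endpoint states coincide on every
#' positive-weight edge.
#'
#' @param states Named list of final node-state matrices (`g`, `c`, `m`) in
#'   the model's `hidden x (nodes*patients)` layout, e.g. `$H_final` of a
#'   forward pass.
#' @param graph The `hetero_graph` the states live on.
#' @param d Hidden dimension of the states.
#' @param reduce `"mean"` for the batch mean, `"none"` for the per-patient
#'   vector.
#' @return Non-negative scalar or per-patient vector.
#' @export
graph_regularizer <- function(states, graph, d, reduce = c("mean", "none")) {
  reduce <- match.arg(reduce)
  nn <- graph_n_nodes(graph)
  P <- ncol(states$g) %/% nn[["g"]]
  per <- numeric(P)
  pairs <- list(
    list(a = "c", b = "g", ia = graph$edges$gc$cpg, ib = graph$edges$gc$gene,
         w = graph$edges$gc$weight),
    list(a = "m", b = "g", ia = graph$edges$mg$mirna, ib = graph$edges$mg$gene,
         w = graph$edges$mg$weight)
  )
  for (pr in pairs) {
    ne <- length(pr$ia)
    if (ne == 0L) next
    D <- states[[pr$a]][, colidx(pr$ia, nn[[pr$a]], P), drop = FALSE] -
      states[[pr$b]][, colidx(pr$ib, nn[[pr$b]], P), drop = FALSE]
    per <- per + colSums(matrix(colSums(D * D) * pr$w, ne, P))
  }
  if (reduce == "mean") mean(per) else per
}

#' Training loss
#'
#' Mean cross-entropy over the minibatch, plus `lambda_gr` times the mean
#' per-patient graph smoothness penalty, plus `lambda_wd` times the squared
#' norm of all trainable parameters. Both data terms are minibatch means so
#' the loss weights are batch-size invariant.
#'
#' @param probs K x P probability matrix (columns on the simplex).
#' @param labels Integer class labels in 1..K, length P.
#' @param reg Per-patient regularizer values (length P) or a scalar mean.
#' @param lambda_gr,lambda_wd Loss weights.
#' @param params Model parameter list (for the weight-decay term); `NULL`
#'   drops that term.
#' @return Scalar loss.
#' @export
total_loss <- function(probs, labels, reg = 0, lambda_gr = 0, lambda_wd = 0,
                       params = NULL) {
  P <- ncol(probs)
  ce <- -mean(log(probs[cbind(labels, seq_len(P))]))
  wd <- if (is.null(params)) 0 else sum(vapply(params, function(x) sum(x^2), 0))
  ce + lambda_gr * mean(reg) + lambda_wd * wd
}
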