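# Gradient-based attributions. All scores are taken on the subtype logit
# (pre-softmax) with model parameters frozen; edge gates sit at 1 during
# scoring and only serve as differentiable handles on the message terms.

# Gradient of the summed logit of class k w.r.t. the requested quantities.
# Per-patient structure is preserved: input gradients are naturally
# per-patient, and gate gradients are accumulated per patient explicitly.
logit_grad <- function(fit, batch, k, gates = NULL, want = "inputs") {
  fw <- xonet_forward(fit$params, fit$mp, batch, fit$config, gates = gates,
                      keep_cache = TRUE)
  K <- fit$config$num_classes
  P <- ncol(fw$probs)
  dlogits <- matrix(0, K, P)
  dlogits[k, ] <- 1
  bw <- xonet_backward(fit$params, fit$mp, fit$config, fw, dlogits,
                       want = want)
  list(fw = fw, bw = bw)
}

#' Saliency node attributions for one subtype
#'
#' Per-node, per-patient absolute gradient of the subtype logit with
#' respect to the standardized input feature. Masked modalities receive
#' exactly zero scores.
#'
#' @param fit A `xonet_fit`.
#' @param batch A `patient_batch`.
#' @param k Subtype index (1..K) or class label.
#' @return Tibble with `node_type`, `node`, `sample_id`, `score`
#'   (`score >= 0`).
#' @export
saliency_nodes <- function(fit, batch, k) {
  k <- resolve_class(fit, k)
  gr <- logit_grad(fit, batch, k, want = "inputs")$bw$inputs
  node_score_table(gr, batch, absolute = TRUE)
}

#' Integrated-gradients node attributions for one subtype
#'
#' Riemann-sum integrated gradients along the straight path from the
#' all-zero standardized input (the cohort mean in raw space) to the
#' observed input: `IG_v = x_v * mean_s grad_v(s/steps * x)`. Satisfies the
#' completeness property up to path resolution:
#' `sum_v IG_v ~= s_k(x) - s_k(0)`.
#'
#' @inheritParams saliency_nodes
#' @param steps Path resolution (default 64).
#' @param signed Return signed IG values (needed for completeness checks)
#'   instead of absolute scores.
#' @return Tibble with `node_type`, `node`, `sample_id`, `score`.
#' @export
integrated_gradients_nodes <- function(fit, batch, k, steps = 64L,
                                       signed = FALSE) {
  k <- resolve_class(fit, k)
  acc <- purrr::map(batch$X, ~ .x * 0)
  for (s in seq_len(steps)) {
    b <- batch
    b$X <- purrr::map(batch$X, ~ .x * (s / steps))
    gr <- logit_grad(fit, b, k, want = "inputs")$bw$inputs
    acc <- purrr::map2(acc, gr, `+`)
  }
  ig <- purrr::map2(acc, batch$X, ~ .x / steps * .y)
  node_score_table(ig, batch, absolute = !signed)
}

#' Edge-gate attributions for one subtype
#'
#' Each edge carries a continuous gate multiplying its message contribution
#' in every layer; the attribution is the per-patient gradient magnitude of
#' the subtype logit with respect to the gate, evaluated at gates = 1. An
#' integrated variant averages the gate gradient along the path from fully
#' closed (0) to open (1) gates.
#'
#' @inheritParams saliency_nodes
#' @param method `"gradient"` (at gates = 1) or `"ig"` (path integral).
#' @param steps Path resolution for the integrated variant.
#' @return Tibble with `edge_id`, `relation`, `sample_id`, `score`.
#' @export
edge_gate_attribution <- function(fit, batch, k, method = c("gradient", "ig"),
                                  steps = 16L) {
  method <- match.arg(method)
  k <- resolve_class(fit, k)
  ne <- fit$mp$n_edges
  if (method == "gradient") {
    G <- logit_grad(fit, batch, k, gates = rep(1, ne), want = "gates")$bw$gates
  } else {
    G <- matrix(0, ne, length(batch$sample_ids))
    for (s in seq_len(steps)) {
      G <- G + logit_grad(fit, batch, k, gates = rep(s / steps, ne),
                          want = "gates")$bw$gates
    }
    G <- G / steps
  }
  relation <- rep(c("g-c", "m->g"), c(fit$mp$n_gc, fit$mp$n_mg))
  tibble::tibble(
    edge_id = rep(seq_len(ne), times = ncol(G)),
    relation = rep(relation, times = ncol(G)),
    sample_id = rep(batch$sample_ids, each = ne),
    score = abs(as.vector(G))
  )
}

resolve_class <- function(fit, k) {
  if (is.character(k)) k <- match(k, fit$classes)
  stopifnot(!is.na(k), k >= 1, k <= fit$config$num_classes)
  as.integer(k)
}

node_score_table <- function(score_list, batch, absolute = TRUE) {
  ids <- list(g = rownames(batch$X$g), c = rownames(batch$X$c),
              m = rownames(batch$X$m))
  purrr::imap_dfr(score_list, function(S, t) {
    if (absolute) S <- abs(S)
    tibble::tibble(
      node_type = t,
      node = rep(ids[[t]] %||% as.character(seq_len(nrow(S))), times = ncol(S)),
      sample_id = rep(batch$sample_ids, each = nrow(S)),
      score = as.vector(S)
    )
  })
}

#' Aggregate per-sample attributions over out-of-fold predictions
#'
#' For every (repeat, fold) model of a cross-validation run, attributions
#' are computed on that fold's held-out test samples only, with respect to
#' each sample's predicted-subtype logit (switchable to the true label),
#' and averaged as absolute values within subtype groups.
#'
#' @param cv A `xonet_cv` run with `keep_fits = TRUE`.
#' @param graph The `hetero_graph` used for the run.
#' @param expr,probe_beta,mirna Raw cohort matrices (standardized per fold
#'   with the stored fold standardizers).
#' @param what `"nodes"` or `"edges"`.
#' @param method Attribution method: `"saliency"` or `"ig"` for nodes;
#'   `"gradient"` or `"ig"` for edges.
#' @param group_by `"predicted"` (default) or `"label"`.
#' @param steps Path resolution for IG variants.
#' @return Tibble of aggregated scores per subtype and node (or edge),
#'   with the number of contributing predictions; also per-fold retained
#'   top-edge sets when `what = "edges"` (attribute `"fold_scores"`).
#' @export
aggregate_attributions <- function(cv, graph, expr, probe_beta, mirna,
                                   what = c("nodes", "edges"),
                                   method = NULL,
                                   group_by = c("predicted", "label"),
                                   steps = 32L) {
  what <- match.arg(what)
  group_by <- match.arg(group_by)
  if (is.null(cv$fits)) abort("run xonet_cv() with keep_fits = TRUE first")
  method <- method %||% if (what == "nodes") "saliency" else "gradient"
  cbeta_raw <- summarize_cluster_methylation(probe_beta, graph$nodes$cpg)
  sample_ids <- rownames(expr)
  fold_keys <- dplyr::distinct(cv$oof, .data$repeat_id, .data$fold)
  res <- list()
  for (i in seq_len(nrow(fold_keys))) {
    fit <- cv$fits[[i]]
    sub <- dplyr::semi_join(cv$oof, fold_keys[i, ],
                            by = c("repeat_id", "fold"))
    std <- fit$standardizers
    batch <- prepare_batch(
      graph,
      apply_standardizer(std$g, expr),
      apply_standardizer(std$c, cbeta_raw),
      apply_standardizer(std$m, mirna),
      sample_ids = sample_ids
    )
    test_b <- subset_batch(batch, sub$sample_id)
    grp <- if (group_by == "predicted") sub$.pred_class else sub$label
    for (cl in unique(as.character(grp))) {
      in_cl <- sub$sample_id[as.character(grp) == cl]
      scores <- if (what == "nodes") {
        if (method == "saliency") {
          saliency_nodes(fit, test_b, cl)
        } else {
          integrated_gradients_nodes(fit, test_b, cl, steps = steps)
        }
      } else {
        edge_gate_attribution(fit, test_b, cl, method = method, steps = steps)
      }
      res[[length(res) + 1L]] <- scores |>
        dplyr::filter(.data$sample_id %in% in_cl) |>
        dplyr::mutate(subtype = cl, repeat_id = fold_keys$repeat_id[i],
                      fold = fold_keys$fold[i])
    }
  }
  all_scores <- dplyr::bind_rows(res)
  key <- if (what == "nodes") c("subtype", "node_type", "node") else
    c("subtype", "relation", "edge_id")
  agg <- all_scores |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::summarise(score = mean(.data$score), n_predictions = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$subtype, dplyr::desc(.data$score))
  attr(agg, "fold_scores") <- all_scores
  agg
}

#' Extract a subtype-specific explanatory subnetwork
#'
#' Ranks cross-omics edges by attribution score, keeps the top `budget`
#' fraction (`ceiling(budget * |E|)` edges; ties break by edge id), then
#' prunes connected components smaller than `min_component_size` nodes.
#' Hubs are nodes whose degree inside the pruned subnetwork reaches
#' `hub_threshold`.
#'
#' @param edge_scores Tibble with `edge_id` and `score` (one row per edge;
#'   aggregate first).
#' @param graph The `hetero_graph` defining the edge-id space.
#' @param budget Fraction of all cross-omics edges to retain (default 0.01).
#' @param min_component_size Minimum connected-component node count kept
#'   after retention (default 3).
#' @param hub_threshold Minimum within-subnetwork degree to call a node a
#'   hub (default 5).
#' @return An `explanatory_subnetwork`: retained edge tibble (with node
#'   ids and relation), node tibble, hub counts per type, and counts.
#' @export
extract_subnetwork <- function(edge_scores, graph, budget = 0.01,
                               min_component_size = 3L, hub_threshold = 5L) {
  ne <- nrow(graph$edges$gc) + nrow(graph$edges$mg)
  n_keep <- min(ne, ceiling(budget * ne))
  es <- edge_scores |>
    dplyr::arrange(dplyr::desc(.data$score), .data$edge_id) |>
    dplyr::slice_head(n = n_keep)
  edges <- edge_endpoint_table(graph)[es$edge_id, ]
  edges$score <- es$score
  # connected components on the retained bipartite-ish edge set
  nodes <- unique(c(edges$from, edges$to))
  comp <- connected_components(edges$from, edges$to, nodes)
  sizes <- table(comp)
  keep_nodes <- names(comp)[comp %in% names(sizes)[sizes >= min_component_size]]
  pruned <- edges[edges$from %in% keep_nodes & edges$to %in% keep_nodes, ]
  deg <- table(c(pruned$from, pruned$to))
  node_tbl <- tibble::tibble(
    node = names(deg),
    node_type = sub("@.*$", "", names(deg)),
    degree = as.integer(deg)
  )
  hubs <- node_tbl |>
    dplyr::filter(.data$degree >= hub_threshold) |>
    dplyr::count(.data$node_type, name = "hubs")
  structure(
    list(
      edges = pruned, nodes = node_tbl,
      n_edges_retained = n_keep, n_edges = nrow(pruned),
      n_nodes = nrow(node_tbl),
      hub_counts = hubs, budget = budget,
      min_component_size = min_component_size, hub_threshold = hub_threshold
    ),
    class = "explanatory_subnetwork"
  )
}

# Edge endpoints in the global edge-id order, with type-tagged node keys.
edge_endpoint_table <- function(graph) {
  dplyr::bind_rows(
    tibble::tibble(
      edge_id = seq_len(nrow(graph$edges$gc)), relation = "g-c",
      from = paste0("c@", graph$edges$gc$cluster_id),
      to = paste0("g@", graph$edges$gc$gene_id)
    ),
    tibble::tibble(
      edge_id = nrow(graph$edges$gc) + seq_len(nrow(graph$edges$mg)),
      relation = "m->g",
      from = paste0("m@", graph$edges$mg$mirna_id),
      to = paste0("g@", graph$edges$mg$gene_id)
    )
  )
}

# Union-find connected components on an edge list.
connected_components <- function(from, to, nodes) {
  parent <- setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(from)) {
    a <- find(match(from[e], nodes))
    b <- find(match(to[e], nodes))
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_along(nodes), find, 0L)
  setNames(as.character(roots), nodes)
}

#' @export
print.explanatory_subnetwork <- function(x, ...) {
  cat(sprintf(
    "<explanatory_subnetwork> %d nodes, %d edges after pruning (budget %.2g%% = %d retained)\n",
    x$n_nodes, x$n_edges, 100 * x$budget, x$n_edges_retained
  ))
  invisible(x)
}

#' Stability of retained edge sets across folds
#'
#' Mean pairwise Jaccard index of the per-fold retained edge-id sets:
#' 1 for identical sets, 0 for pairwise-disjoint sets.
#'
#' @param edge_sets List of integer (or character) edge-id vectors, one per
#'   fold or repeat.
#' @return Scalar in \[0, 1\].
#' @export
fold_overlap <- function(edge_sets) {
  m <- length(edge_sets)
  if (m < 2L) return(1)
  pairs <- utils::combn(m, 2L)
  mean(apply(pairs, 2L, function(ij) {
    a <- edge_sets[[ij[1]]]
    b <- edge_sets[[ij[2]]]
    u <- length(union(a, b))
    if (u == 0L) return(1)
    length(intersect(a, b)) / u
  }))
}
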