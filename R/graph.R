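#' Define strand-aware promoter spans around transcription start sites
#'
#' Each annotated TSS of each gene yields one promoter window covering
#' `upstream` bases on the 5' side of the TSS and `downstream` bases on the
#' 3' side, oriented by gene strand. Windows are reported in the 0-based,
#' half-open convention used throughout the package and are clipped at
#' coordinate 0. Genes carry one or more TSS (multi-isoform gene models), so
#' a gene may contribute several spans; the union of its spans defines its
#' promoter for downstream linking.
#'
#' @param genes Tibble of gene records with columns `gene_id`, `symbol`,
#'   `chrom`, `strand` (`"+"` or `"-"`), and `tss` — either a list-column of
#'   integer vectors or a character column of semicolon-separated positions.
#' @param upstream,downstream Window half-sizes in bases (defaults 2000/500).
#' @return Tibble with one row per (gene, TSS): `gene_id`, `chrom`, `strand`,
#'   `source_tss`, `start`, `end` (0-based half-open). Records with an
#'   unknown strand symbol are dropped with a warning.
#' @export
define_promoter_spans <- function(genes, upstream = 2000L, downstream = 500L) {
  stopifnot(upstream >= 0, downstream >= 0)
  genes <- tibble::as_tibble(genes)
  bad <- !genes$strand %in% c("+", "-")
  if (any(bad)) {
    warn(sprintf(
      "dropping %d gene record(s) with unknown strand symbol: %s",
      sum(bad), paste(head(genes$gene_id[bad], 5L), collapse = ", ")
    ))
    genes <- genes[!bad, , drop = FALSE]
  }
  tss_list <- parse_tss(genes$tss)
  spans <- purrr::pmap_dfr(
    list(genes$gene_id, genes$chrom, genes$strand, tss_list),
    function(gene_id, chrom, strand, tss) {
      tibble::tibble(
        gene_id = gene_id, chrom = chrom, strand = strand,
        source_tss = as.integer(tss)
      )
    }
  )
  # inclusive genomic window, then 0-based half-open: [lo, hi+1)
  lo <- ifelse(spans$strand == "+",
    spans$source_tss - upstream, spans$source_tss - downstream
  )
  hi <- ifelse(spans$strand == "+",
    spans$source_tss + downstream, spans$source_tss + upstream
  )
  spans$start <- pmax(0L, as.integer(lo))
  spans$end <- as.integer(hi) + 1L
  stopifnot(all(spans$start < spans$end))
  spans
}

parse_tss <- function(tss) {
  if (is.list(tss)) {
    out <- purrr::map(tss, ~ sort(unique(as.integer(.x))))
  } else {
    out <- purrr::map(
      strsplit(as.character(tss), ";", fixed = TRUE),
      ~ sort(unique(as.integer(.x)))
    )
  }
  if (any(lengths(out) == 0L)) abort("every gene needs at least one TSS")
  if (any(purrr::map_lgl(out, ~ any(.x < 0)))) abort("TSS positions must be non-negative")
  out
}

#' Cluster methylation probes into CpG clusters
#'
#' Probes with more than `max_missing` missing samples are removed first.
#' Remaining probes are sorted within each chromosome and merged by
#' single-linkage chaining: adjacent probes at most `max_gap` bases apart
#' (inclusive) join the same chain. Chains with fewer than `min_probes`
#' members are dropped. Cluster identifiers are derived deterministically
#' from the chromosome and span, and the representative position is the
#' integer midpoint of the member span.
#'
#' @param probes Tibble with columns `probe_id`, `chrom`, `pos`, and
#'   optionally `missing_fraction` (assumed 0 when absent).
#' @param max_gap Maximum distance between adjacent probes in a chain.
#' @param min_probes Minimum chain size to retain (default 2).
#' @param max_missing Missingness threshold; probes strictly above it are
#'   removed before chaining.
#' @return Tibble of clusters: `cluster_id`, `chrom`, `span_start`,
#'   `span_end`, `representative_pos`, `n_probes`, and list-column
#'   `member_probe_ids`.
#' @export
cluster_probes <- function(probes, max_gap = 500L, min_probes = 2L,
                           max_missing = 0.10) {
  probes <- tibble::as_tibble(probes)
  if (nrow(probes) == 0L) {
    return(tibble::tibble(
      cluster_id = character(), chrom = character(),
      span_start = integer(), span_end = integer(),
      representative_pos = integer(), n_probes = integer(),
      member_probe_ids = list()
    ))
  }
  if (!"missing_fraction" %in% names(probes)) probes$missing_fraction <- 0
  stopifnot(all(probes$pos >= 0))
  probes <- dplyr::filter(probes, .data$missing_fraction <= max_missing)
  probes <- dplyr::arrange(probes, .data$chrom, .data$pos, .data$probe_id)
  out <- probes |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(df, key) {
      gap <- diff(df$pos)
      chain <- cumsum(c(1L, as.integer(gap > max_gap)))
      df |>
        dplyr::mutate(.chain = chain) |>
        dplyr::group_by(.data$.chain) |>
        dplyr::summarise(
          span_start = min(.data$pos),
          span_end = max(.data$pos),
          n_probes = dplyr::n(),
          member_probe_ids = list(.data$probe_id),
          .groups = "drop"
        ) |>
        dplyr::select(-".chain")
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$n_probes >= min_probes) |>
    dplyr::mutate(
      representative_pos = as.integer((.data$span_start + .data$span_end) %/% 2),
      cluster_id = sprintf("cpg_%s_%d_%d", .data$chrom, .data$span_start, .data$span_end)
    ) |>
    dplyr::arrange(.data$chrom, .data$span_start) |>
    dplyr::select(
      "cluster_id", "chrom", "span_start", "span_end",
      "representative_pos", "n_probes", "member_probe_ids"
    )
  out
}

#' Summarize probe-level beta values at the CpG-cluster level
#'
#' Cluster methylation is the unweighted arithmetic mean of the member
#' probes' beta values, per sample.
#'
#' @param beta_matrix Numeric samples x probes matrix with probe ids as
#'   column names; values in \[0, 1\].
#' @param clusters Cluster tibble from [cluster_probes()].
#' @return Numeric samples x clusters matrix, columns named by `cluster_id`.
#' @export
summarize_cluster_methylation <- function(beta_matrix, clusters) {
  missing <- setdiff(unlist(clusters$member_probe_ids), colnames(beta_matrix))
  if (length(missing) > 0L) {
    abort(sprintf(
      "probe(s) absent from beta matrix: %s",
      paste(head(missing, 5L), collapse = ", ")
    ))
  }
  out <- vapply(clusters$member_probe_ids, function(ids) {
    rowMeans(beta_matrix[, ids, drop = FALSE])
  }, numeric(nrow(beta_matrix)))
  out <- matrix(out, nrow = nrow(beta_matrix),
                dimnames = list(rownames(beta_matrix), clusters$cluster_id))
  out
}

#' Link CpG clusters to genes through promoter membership
#'
#' A cluster is linked to a gene when the cluster's genomic position (by
#' default its representative midpoint) falls inside any promoter span of
#' the gene on the same chromosome. The relation is many-to-many; duplicate
#' (cluster, gene) pairs arising from multiple TSS spans collapse to one
#' edge.
#'
#' @param clusters Cluster tibble from [cluster_probes()].
#' @param spans Promoter span tibble from [define_promoter_spans()].
#' @param position One of `"midpoint"` (test the representative position) or
#'   `"any_member"` (link if any member span position falls inside).
#' @return Tibble of edges: `cluster_id`, `gene_id`.
#' @export
link_cpg_to_genes <- function(clusters, spans,
                              position = c("midpoint", "any_member")) {
  position <- match.arg(position)
  if (nrow(clusters) == 0L || nrow(spans) == 0L) {
    return(tibble::tibble(cluster_id = character(), gene_id = character()))
  }
  hit <- dplyr::inner_join(
    dplyr::select(clusters, "cluster_id", "chrom", "span_start", "span_end",
                  "representative_pos"),
    dplyr::select(spans, "gene_id", "chrom", "start", "end"),
    by = "chrom", relationship = "many-to-many"
  )
  keep <- if (position == "midpoint") {
    hit$representative_pos >= hit$start & hit$representative_pos < hit$end
  } else {
    # the whole member span may straddle the promoter; any overlap of the
    # probe span with the window counts
    hit$span_end >= hit$start & hit$span_start < hit$end
  }
  hit[keep, c("cluster_id", "gene_id")] |>
    dplyr::distinct() |>
    dplyr::arrange(.data$cluster_id, .data$gene_id)
}

#' Filter a scored miRNA target table
#'
#' Retains interactions whose cumulative weighted context score is at or
#' below `score_threshold` (more negative = stronger predicted repression;
#' the threshold is inclusive), optionally restricts both endpoints to the
#' retained feature space, and collapses repeated mappings to unique edges.
#'
#' @param records Tibble with columns `mirna_id`, `gene_symbol`,
#'   `context_score`.
#' @param score_threshold Inclusive upper bound on the score (default -0.2).
#' @param keep_mirnas,keep_genes Optional character vectors restricting the
#'   retained endpoint identifier space.
#' @return Tibble of edges: `mirna_id`, `gene_symbol`.
#' @export
filter_mirna_targets <- function(records, score_threshold = -0.2,
                                 keep_mirnas = NULL, keep_genes = NULL) {
  out <- tibble::as_tibble(records) |>
    dplyr::filter(.data$context_score <= score_threshold)
  if (!is.null(keep_mirnas)) out <- dplyr::filter(out, .data$mirna_id %in% keep_mirnas)
  if (!is.null(keep_genes)) out <- dplyr::filter(out, .data$gene_symbol %in% keep_genes)
  out |>
    dplyr::distinct(.data$mirna_id, .data$gene_symbol) |>
    dplyr::arrange(.data$mirna_id, .data$gene_symbol)
}

#' Resolve duplicate feature mappings by cross-sample variance
#'
#' When several candidate instances map to the same retained feature
#' identifier, the instance with the largest cross-sample variance wins;
#' ties break to the lexicographically smallest instance id.
#'
#' @param candidates Tibble with columns `feature_id`, `instance`,
#'   `variance`.
#' @return Tibble with one row per `feature_id`: `feature_id`, `instance`.
#' @export
dedup_by_variance <- function(candidates) {
  tibble::as_tibble(candidates) |>
    dplyr::arrange(.data$feature_id, dplyr::desc(.data$variance), .data$instance) |>
    dplyr::distinct(.data$feature_id, .keep_all = TRUE) |>
    dplyr::select("feature_id", "instance")
}

#' Assemble the heterogeneous cross-omics graph
#'
#' Combines the typed node tables and the two relations (gene-CpG promoter
#' links and miRNA-to-gene target links) into a single fixed graph with
#' stable integer node indices and a stage-count ledger. The graph is built
#' once, before any cross-validation, and shared across all patients.
#'
#' @param genes Tibble with at least `gene_id` (and optionally `symbol`).
#' @param clusters Cluster tibble from [cluster_probes()].
#' @param mirnas Tibble with `mirna_id`, or a character vector of ids.
#' @param gc_edges Tibble `cluster_id`, `gene_id` from [link_cpg_to_genes()].
#' @param mg_edges Tibble `mirna_id`, `gene_id` from [filter_mirna_targets()]
#'   after symbol-to-id harmonization.
#' @param stage_counts Optional tibble of upstream ledger rows
#'   (`stage`, `entity`, `count`) to prepend.
#' @return A `hetero_graph` object: node tibbles per type (`gene`, `cpg`,
#'   `mirna`) with integer `.idx`, edge tibbles `gc` (`cpg`, `gene`, indices)
#'   and `mg` (`mirna`, `gene`), unit edge weights, and the `stage_counts`
#'   ledger.
#' @export
assemble_graph <- function(genes, clusters, mirnas, gc_edges, mg_edges,
                           stage_counts = NULL) {
  genes <- tibble::as_tibble(genes)
  if (is.character(mirnas)) mirnas <- tibble::tibble(mirna_id = mirnas)
  nodes <- list(
    gene = dplyr::distinct(genes, .data$gene_id, .keep_all = TRUE) |>
      dplyr::arrange(.data$gene_id) |>
      dplyr::mutate(.idx = dplyr::row_number()),
    cpg = dplyr::distinct(clusters, .data$cluster_id, .keep_all = TRUE) |>
      dplyr::arrange(.data$cluster_id) |>
      dplyr::mutate(.idx = dplyr::row_number()),
    mirna = dplyr::distinct(mirnas, .data$mirna_id, .keep_all = TRUE) |>
      dplyr::arrange(.data$mirna_id) |>
      dplyr::mutate(.idx = dplyr::row_number())
  )
  gidx <- setNames(nodes$gene$.idx, nodes$gene$gene_id)
  cidx <- setNames(nodes$cpg$.idx, nodes$cpg$cluster_id)
  midx <- setNames(nodes$mirna$.idx, nodes$mirna$mirna_id)

  gc_edges <- dplyr::distinct(tibble::as_tibble(gc_edges), .data$cluster_id, .data$gene_id)
  mg_edges <- dplyr::distinct(tibble::as_tibble(mg_edges), .data$mirna_id, .data$gene_id)
  check_endpoints(gc_edges$cluster_id, cidx, "CpG cluster")
  check_endpoints(gc_edges$gene_id, gidx, "gene")
  check_endpoints(mg_edges$mirna_id, midx, "miRNA")
  check_endpoints(mg_edges$gene_id, gidx, "gene")

  gc <- tibble::tibble(
    cluster_id = gc_edges$cluster_id, gene_id = gc_edges$gene_id,
    cpg = unname(cidx[gc_edges$cluster_id]),
    gene = unname(gidx[gc_edges$gene_id]), weight = 1
  ) |> dplyr::arrange(.data$cpg, .data$gene)
  mg <- tibble::tibble(
    mirna_id = mg_edges$mirna_id, gene_id = mg_edges$gene_id,
    mirna = unname(midx[mg_edges$mirna_id]),
    gene = unname(gidx[mg_edges$gene_id]), weight = 1
  ) |> dplyr::arrange(.data$mirna, .data$gene)

  ledger <- dplyr::bind_rows(
    stage_counts,
    tibble::tibble(
      stage = "final",
      entity = c("gene", "cpg", "mirna", "gc_edge", "mg_edge"),
      count = c(nrow(nodes$gene), nrow(nodes$cpg), nrow(nodes$mirna),
                nrow(gc), nrow(mg))
    )
  )
  structure(
    list(nodes = nodes, edges = list(gc = gc, mg = mg), stage_counts = ledger),
    class = "hetero_graph"
  )
}

check_endpoints <- function(ids, index, what) {
  missing <- setdiff(unique(ids), names(index))
  if (length(missing) > 0L) {
    abort(sprintf(
      "edge references %s node(s) absent from the registry: %s",
      what, paste(head(missing, 5L), collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat(sprintf(
    "<hetero_graph> %d genes, %d CpG clusters, %d miRNAs; %d gene-CpG edges, %d miRNA->gene edges\n",
    nrow(x$nodes$gene), nrow(x$nodes$cpg), nrow(x$nodes$mirna),
    nrow(x$edges$gc), nrow(x$edges$mg)
  ))
  invisible(x)
}

graph_n_nodes <- function(graph) {
  c(g = nrow(graph$nodes$gene), c = nrow(graph$nodes$cpg),
    m = nrow(graph$nodes$mirna))
}

#' Fingerprint a heterogeneous graph
#'
#' Stable hash of the node identifier sets and both edge lists; used by
#' model checkpoints to refuse loading against a different graph.
#'
#' @param graph A `hetero_graph`.
#' @return A character hash.
#' @export
graph_fingerprint <- function(graph) {
  rlang::hash(list(
    graph$nodes$gene$gene_id, graph$nodes$cpg$cluster_id,
    graph$nodes$mirna$mirna_id,
    graph$edges$gc[, c("cpg", "gene")], graph$edges$mg[, c("mirna", "gene")]
  ))
}

#' Build the full graph from annotation tables
#'
#' End-to-end convenience wrapper over the individual construction steps:
#' promoter spans, probe clustering, cluster-to-gene linking, target
#' filtering, identifier harmonization against the retained feature space,
#' and assembly with a stage-count ledger.
#'
#' @param genes Gene model tibble (see [define_promoter_spans()]); needs a
#'   `symbol` column when the target table uses symbols.
#' @param probes Probe manifest tibble (see [cluster_probes()]).
#' @param targets Scored target tibble (see [filter_mirna_targets()]).
#' @param mirnas Optional character vector of retained miRNA ids (defaults
#'   to those in the target table).
#' @param upstream,downstream,max_gap,min_probes,max_missing,score_threshold
#'   Assembly parameters, as in the step functions.
#' @param cluster_position Promoter membership rule for clusters
#'   (see [link_cpg_to_genes()]).
#' @return A `hetero_graph`.
#' @export
build_hetero_graph <- function(genes, probes, targets, mirnas = NULL,
                               upstream = 2000L, downstream = 500L,
                               max_gap = 500L, min_probes = 2L,
                               max_missing = 0.10, score_threshold = -0.2,
                               cluster_position = "midpoint") {
  genes <- tibble::as_tibble(genes)
  if (!"symbol" %in% names(genes)) genes$symbol <- genes$gene_id
  spans <- define_promoter_spans(genes, upstream, downstream)
  clusters <- cluster_probes(probes, max_gap, min_probes, max_missing)
  gc_edges <- link_cpg_to_genes(clusters, spans, position = cluster_position)
  mirnas <- mirnas %||% sort(unique(targets$mirna_id))
  mg_sym <- filter_mirna_targets(
    targets, score_threshold,
    keep_mirnas = mirnas, keep_genes = genes$symbol
  )
  sym2id <- setNames(genes$gene_id, genes$symbol)
  mg_edges <- tibble::tibble(
    mirna_id = mg_sym$mirna_id,
    gene_id = unname(sym2id[mg_sym$gene_symbol])
  ) |> dplyr::distinct()
  # keep only clusters that made it into the node registry no matter what;
  # clusters without promoter links stay as isolated CpG nodes
  mf <- probes$missing_fraction %||% rep(0, nrow(probes))
  ledger <- tibble::tibble(
    stage = c("raw", "raw", "raw", "filtered", "filtered", "linked", "linked"),
    entity = c("gene", "probe", "target_row", "probe", "target_row",
               "gc_edge", "mg_edge"),
    count = c(nrow(genes), nrow(probes), nrow(targets),
              sum(mf <= max_missing),
              sum(targets$context_score <= score_threshold),
              nrow(gc_edges), nrow(mg_edges))
  )
  assemble_graph(genes, clusters, mirnas, gc_edges, mg_edges,
                 stage_counts = ledger)
}
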