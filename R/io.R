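# Readers and writers for the plain-text formats the pipeline exchanges.
# Internally all coordinates are 0-based half-open; the GTF reader converts
# from its 1-based inclusive convention at the boundary.

#' Read gene models from TSV or GTF
#'
#' The TSV dialect has columns `gene_id`, `symbol`, `chrom`, `strand`, and
#' `tss` with semicolon-separated positions for multi-TSS genes (0-based).
#' A `.gtf`/`.gff` file is imported through rtracklayer and reduced to one
#' record per gene with the union of its transcript start sites (converted
#' from 1-based to 0-based).
#'
#' @param path File path.
#' @return Gene tibble suitable for [define_promoter_spans()].
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.(gtf|gff[23]?)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("reading GTF requires the rtracklayer package; use the TSV dialect instead")
    }
    gr <- rtracklayer::import(path)
    tx <- gr[gr$type %in% c("transcript", "mRNA")]
    if (length(tx) == 0L) tx <- gr[gr$type == "gene"]
    strand <- as.character(BiocGenerics::strand(tx))
    tss1 <- ifelse(strand == "+", BiocGenerics::start(tx), BiocGenerics::end(tx))
    tibble::tibble(
      gene_id = tx$gene_id,
      symbol = if (!is.null(tx$gene_name)) tx$gene_name else tx$gene_id,
      chrom = as.character(GenomicRanges::seqnames(tx)),
      strand = strand,
      tss = tss1 - 1L
    ) |>
      dplyr::filter(.data$strand %in% c("+", "-")) |>
      dplyr::group_by(.data$gene_id, .data$symbol, .data$chrom, .data$strand) |>
      dplyr::summarise(tss = list(sort(unique(.data$tss))), .groups = "drop")
  } else {
    readr::read_tsv(path, show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  }
}

#' Read a methylation probe manifest TSV
#'
#' Columns: `probe_id`, `chrom`, `pos`, `missing_fraction`.
#' @param path File path.
#' @return Probe tibble.
#' @export
read_probe_manifest <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE) |>
    dplyr::mutate(pos = as.integer(.data$pos))
}

#' Read a scored miRNA target table TSV
#'
#' Columns: `mirna_id`, `gene_symbol`, `context_score`.
#' @param path File path.
#' @return Target tibble.
#' @export
read_target_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read an omics matrix TSV
#'
#' Samples in rows; header row of feature identifiers; first column holds
#' sample ids.
#' @param path File path.
#' @return Numeric matrix with sample ids as row names.
#' @export
read_omics_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write an omics matrix TSV
#' @param m Numeric matrix, samples x features, row names = sample ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(m, path) {
  df <- tibble::as_tibble(m, rownames = "sample_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Write a heterogeneous graph to a directory of text files
#'
#' Emits node tables (`nodes_gene.tsv`, `nodes_cpg.tsv`, `nodes_mirna.tsv`),
#' relation-tagged edge lists (`edges_gc.tsv`, `edges_mg.tsv`) and a
#' `graph_meta.json` carrying the stage-count ledger and fingerprint.
#'
#' @param graph A `hetero_graph`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_hetero_graph <- function(graph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flatten <- function(df) {
    dplyr::mutate(df, dplyr::across(
      dplyr::where(is.list),
      ~ purrr::map_chr(.x, paste, collapse = ";")
    ))
  }
  readr::write_tsv(flatten(graph$nodes$gene), file.path(dir, "nodes_gene.tsv"))
  readr::write_tsv(flatten(graph$nodes$cpg), file.path(dir, "nodes_cpg.tsv"))
  readr::write_tsv(flatten(graph$nodes$mirna), file.path(dir, "nodes_mirna.tsv"))
  readr::write_tsv(
    dplyr::mutate(graph$edges$gc, relation = "g-c"),
    file.path(dir, "edges_gc.tsv")
  )
  readr::write_tsv(
    dplyr::mutate(graph$edges$mg, relation = "m->g"),
    file.path(dir, "edges_mg.tsv")
  )
  jsonlite::write_json(
    list(
      fingerprint = graph_fingerprint(graph),
      stage_counts = graph$stage_counts
    ),
    file.path(dir, "graph_meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a heterogeneous graph written by [write_hetero_graph()]
#' @param dir Directory path.
#' @return A `hetero_graph`.
#' @export
read_hetero_graph <- function(dir) {
  unflatten <- function(df, col) {
    if (col %in% names(df)) {
      df[[col]] <- strsplit(as.character(df[[col]]), ";", fixed = TRUE)
    }
    df
  }
  genes <- readr::read_tsv(file.path(dir, "nodes_gene.tsv"), show_col_types = FALSE)
  cpg <- readr::read_tsv(file.path(dir, "nodes_cpg.tsv"), show_col_types = FALSE) |>
    unflatten("member_probe_ids")
  mirna <- readr::read_tsv(file.path(dir, "nodes_mirna.tsv"), show_col_types = FALSE)
  gc <- readr::read_tsv(file.path(dir, "edges_gc.tsv"), show_col_types = FALSE)
  mg <- readr::read_tsv(file.path(dir, "edges_mg.tsv"), show_col_types = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "graph_meta.json"), simplifyVector = TRUE)
  g <- assemble_graph(
    dplyr::select(genes, -".idx"), dplyr::select(cpg, -".idx"),
    dplyr::select(mirna, -".idx"),
    gc[, c("cluster_id", "gene_id")], mg[, c("mirna_id", "gene_id")],
    stage_counts = NULL
  )
  g$stage_counts <- tibble::as_tibble(meta$stage_counts)
  g
}

#' Write / read a fold plan as TSV
#'
#' Long format: one row per (sample, repeat) with the fold assignment.
#' @param plan A `fold_plan` from [make_fold_plan()].
#' @param path File path.
#' @return `path` (writer) or a `fold_plan` (reader).
#' @export
write_fold_plan <- function(plan, path) {
  readr::write_tsv(plan$assignments, path)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  assignments <- readr::read_tsv(path, show_col_types = FALSE)
  structure(
    list(
      assignments = assignments,
      k = max(assignments$fold), r = max(assignments$repeat_id), seed = NA_integer_
    ),
    class = "fold_plan"
  )
}
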