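#' Synthetic cohort configuration
#'
#' Describes the generated world: annotation scale, subtype structure, and
#' the planted cross-omics signal. Each subtype owns a disjoint set of
#' anchor genes (overexpressed, promoter-hypomethylated, with one
#' upregulated targeting miRNA whose other filtered targets are repressed)
#' plus a broader program of moderately shifted genes with the same
#' promoter coupling. Subtypes are graded along four axes - program
#' strength, program size, methylation coupling, and miRNA participation -
#' emulating how real intrinsic subtypes differ in the strength, extent and
#' epigenetic coupling of their expression programs; the grading is also
#' what renders the subtypes distinguishable to an architecture whose node
#' states carry no identity information. Optional per-site batch shifts
#' emulate source-site structure.
#'
#' @param n_genes,n_mirnas Annotation sizes (desk-scale defaults 100 / 15).
#' @param targets_per_mirna Mean number of genes targeted per miRNA in the
#'   fixture target table (default 20, emulating dense real target maps).
#' @param n_patients Cohort size (default 300).
#' @param n_subtypes Number of subtype classes K (default 5).
#' @param proportions Subtype mixing proportions (default balanced).
#' @param anchors_per_subtype Anchor genes planted per subtype (default 4).
#' @param effect_size Anchor expression / miRNA shift in SD units (default
#'   4; subtype marker genes are selected in practice precisely because
#'   their shifts are large — amplification-driven markers shift by several
#'   SD).
#' @param subtype_strength Per-subtype strength multipliers (default an
#'   even grid 0.7 to 1.3).
#' @param program_frac Fraction of genes in a unit-size breadth program
#'   (default 0.4).
#' @param program_size Per-subtype program size multipliers (default an
#'   even grid 0.6 to 1.4).
#' @param breadth_scale Breadth-gene effect relative to anchors (default 0.8).
#' @param meth_coupling Promoter hypomethylation per unit anchor effect on
#'   the logit scale (default 1).
#' @param meth_coupling_mult Per-subtype coupling multipliers (default
#'   c(1.3, 0.7, 1.0, 1.2, 0.8) recycled to K).
#' @param mirna_strength_mult Per-subtype miRNA participation multipliers
#'   (default c(0.8, 1.2, 0.7, 1.0, 1.3) recycled to K).
#' @param mirna_repression Downshift of the subtype miRNA's other targets
#'   in units of the subtype effect (default 0.5).
#' @param noise_sd Per-modality noise SD (expression, methylation logit,
#'   miRNA), default 1 each.
#' @param probe_noise_sd Probe-level logit noise around the cluster signal.
#' @param n_sites Number of source sites (default 1 = no site structure).
#' @param site_shift SD of per-(site, feature) mean shifts (default 0).
#' @param seed Root seed; the generator is a pure function of this config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 100L, n_mirnas = 15L, targets_per_mirna = 20L,
                       n_patients = 300L, n_subtypes = 5L, proportions = NULL,
                       anchors_per_subtype = 4L, effect_size = 4,
                       subtype_strength = NULL, program_frac = 0.4,
                       program_size = NULL, breadth_scale = 0.8,
                       meth_coupling = 1.0, meth_coupling_mult = NULL,
                       mirna_strength_mult = NULL, mirna_repression = 0.5,
                       noise_sd = c(g = 1, c = 1, m = 1),
                       probe_noise_sd = 0.3,
                       n_sites = 1L, site_shift = 0, seed = 1L) {
  K <- as.integer(n_subtypes)
  proportions <- proportions %||% rep(1 / K, K)
  subtype_strength <- subtype_strength %||% seq(0.7, 1.3, length.out = K)
  program_size <- program_size %||% seq(0.6, 1.4, length.out = K)
  meth_coupling_mult <- meth_coupling_mult %||%
    rep_len(c(1.3, 0.7, 1.0, 1.2, 0.8), K)
  mirna_strength_mult <- mirna_strength_mult %||%
    rep_len(c(0.8, 1.2, 0.7, 1.0, 1.3), K)
  stopifnot(abs(sum(proportions) - 1) < 1e-8, length(proportions) == K,
            effect_size >= 0, meth_coupling >= 0, mirna_repression >= 0,
            length(subtype_strength) == K, length(program_size) == K,
            program_frac >= 0, program_frac <= 1)
  structure(
    list(
      n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
      targets_per_mirna = as.integer(targets_per_mirna),
      n_patients = as.integer(n_patients), n_subtypes = K,
      proportions = proportions,
      anchors_per_subtype = as.integer(anchors_per_subtype),
      effect_size = effect_size, subtype_strength = subtype_strength,
      program_frac = program_frac, program_size = program_size,
      breadth_scale = breadth_scale,
      meth_coupling = meth_coupling,
      meth_coupling_mult = meth_coupling_mult,
      mirna_strength_mult = mirna_strength_mult,
      mirna_repression = mirna_repression, noise_sd = noise_sd,
      probe_noise_sd = probe_noise_sd,
      n_sites = as.integer(n_sites), site_shift = site_shift,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Generate annotation fixtures: gene models, probe manifest, target table
#'
#' Genes sit on two chromosomes on alternating strands with 1-3 TSS each,
#' spaced widely enough that most promoters are disjoint (a few adjacent
#' pairs overlap so the many-to-many cluster-gene case is exercised). Genes
#' carry 0-3 promoter probe clusters of 2-4 probes; the manifest also
#' contains singleton probes (dropped by the minimum-cluster-size rule) and
#' a fraction of high-missingness probes (dropped by the missingness
#' filter). Target scores straddle the -0.2 retention threshold, and
#' targeting is dense enough that gene in-degrees vary widely, mirroring
#' real target maps.
#'
#' @param sim A [sim_config()].
#' @return List of tibbles: `genes`, `probes`, `targets`.
#' @export
make_annotation_fixture <- function(sim) {
  set.seed(derive_seed(sim$seed, "annot"))
  ng <- sim$n_genes
  chrom <- rep(c("chr1", "chr2"), length.out = ng)
  strand <- rep(c("+", "-"), length.out = ng)
  # base TSS spacing 12 kb; every 10th gene is pulled close to its
  # predecessor so promoter windows overlap
  offset <- cumsum(rep(12000L, ng))
  close <- which(seq_len(ng) %% 10L == 0L)
  offset[close] <- offset[close - 1L] + 1500L
  n_tss <- sample(1:3, ng, replace = TRUE)
  genes <- tibble::tibble(
    gene_id = sprintf("G%03d", seq_len(ng)),
    symbol = sprintf("GENE%03d", seq_len(ng)),
    chrom = chrom, strand = strand,
    tss = purrr::map2(offset, n_tss, function(o, k) {
      sort(unique(as.integer(o + c(0, sample(100:900, k - 1L)))))
    })
  )
  spans <- define_promoter_spans(genes)
  first_span <- dplyr::distinct(spans, .data$gene_id, .keep_all = TRUE)
  # 0-3 clusters per gene promoter, 2-4 probes each, gaps well under the
  # 500 bp chaining threshold
  n_clusters <- sample(0:3, ng, replace = TRUE,
                       prob = c(0.10, 0.45, 0.27, 0.18))
  probe_rows <- list()
  pid <- 0L
  for (i in seq_len(ng)) {
    for (cc in seq_len(n_clusters[i])) {
      k <- sample(2:4, 1L)
      start <- first_span$start[i] + 200L + (cc - 1L) * 700L + sample(0:80, 1L)
      pos <- start + cumsum(c(0L, sample(60:180, k - 1L, replace = TRUE)))
      probe_rows[[length(probe_rows) + 1L]] <- tibble::tibble(
        probe_id = sprintf("cg%06d", pid + seq_len(k)),
        chrom = first_span$chrom[i], pos = as.integer(pos),
        missing_fraction = 0
      )
      pid <- pid + k
    }
  }
  # stray singletons far from any promoter (> max_gap apart)
  n_single <- max(3L, ng %/% 10L)
  probe_rows[[length(probe_rows) + 1L]] <- tibble::tibble(
    probe_id = sprintf("cg9%05d", seq_len(n_single)),
    chrom = "chr1",
    pos = as.integer(5e6 + seq_len(n_single) * 5000L),
    missing_fraction = 0
  )
  # high-missingness probes placed inside promoters: would join clusters if
  # the missingness filter did not run first
  hosts <- which(n_clusters > 0)
  hosts <- hosts[seq_len(min(max(2L, ng %/% 15L), length(hosts)))]
  probe_rows[[length(probe_rows) + 1L]] <- tibble::tibble(
    probe_id = sprintf("cg8%05d", seq_along(hosts)),
    chrom = first_span$chrom[hosts],
    pos = as.integer(first_span$start[hosts] + 230L),
    missing_fraction = 0.25
  )
  probes <- dplyr::bind_rows(probe_rows)
  # dense scored target table straddling the -0.2 threshold
  mirnas <- sprintf("mir-%03d", seq_len(sim$n_mirnas))
  targets <- purrr::map_dfr(mirnas, function(m) {
    nhit <- min(ng, max(2L, stats::rpois(1L, sim$targets_per_mirna)))
    tibble::tibble(
      mirna_id = m, gene_symbol = sample(genes$symbol, nhit),
      context_score = round(runif(nhit, -0.6, 0.05), 3)
    )
  })
  list(genes = genes, probes = probes, targets = targets)
}

#' Simulate a multi-omics cohort with planted cross-omics signal
#'
#' Places graded subtype programs on a fixture graph. For subtype s with
#' strength multiplier gamma_s: anchor genes shift by
#' `effect_size * gamma_s`, breadth-program genes by `breadth_scale` times
#' that, promoter clusters of all program genes shift toward low beta on
#' the logit scale (coupling times the gene shift), one targeting miRNA per
#' anchor is upregulated (participation multiplier times the subtype
#' effect), and that miRNA's other filtered targets are repressed. Site
#' shifts, when configured, are added last. Probe-level betas are the
#' cluster logit plus probe noise mapped through the logistic function, so
#' values stay in \[0, 1\].
#'
#' @param graph A `hetero_graph` built from [make_annotation_fixture()]
#'   output.
#' @param sim The same [sim_config()].
#' @return A `xonet_cohort`: matrices `expr`, `probe_beta`, `mirna`
#'   (samples x features), `samples` tibble (`sample_id`, `subtype`,
#'   `site`), and `truth` (anchor table, breadth gene sets, planted edge
#'   ids).
#' @export
make_cohort <- function(graph, sim) {
  set.seed(derive_seed(sim$seed, "cohort"))
  P <- sim$n_patients
  K <- sim$n_subtypes
  genes <- graph$nodes$gene
  clusters <- graph$nodes$cpg
  mirnas <- graph$nodes$mirna
  gc <- graph$edges$gc
  mg <- graph$edges$mg

  # eligible anchors: genes with both a promoter cluster and a targeting miRNA
  eligible <- intersect(unique(gc$gene_id), unique(mg$gene_id))
  need <- K * sim$anchors_per_subtype
  if (length(eligible) < need) {
    abort(sprintf(
      "need %d anchor genes with both a promoter cluster and a targeting miRNA; only %d eligible",
      need, length(eligible)
    ))
  }
  anchors <- sample(eligible, need)
  anchor_tbl <- tibble::tibble(
    subtype = rep(paste0("S", seq_len(K)), each = sim$anchors_per_subtype),
    gene_id = anchors
  )
  # assign each anchor a targeting miRNA, preferring miRNAs not already
  # carrying another subtype's signal: subtype-characteristic miRNAs are
  # distinct in real cohorts, and sharing them across subtypes would
  # confound the miRNA modality
  used <- character(0)
  anchor_tbl$mirna_id <- purrr::map_chr(anchor_tbl$gene_id, function(g) {
    cand <- sort(mg$mirna_id[mg$gene_id == g])
    pick <- c(setdiff(cand, used), cand)[1]
    used <<- union(used, pick)
    pick
  })

  # labels per mixing proportions (deterministic counts, shuffled order)
  counts <- floor(sim$proportions * P)
  rem <- P - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  subtype <- sample(rep(paste0("S", seq_len(K)), counts))
  site <- rep_len(sprintf("site%d", seq_len(sim$n_sites)), P)
  sample_ids <- sprintf("P%04d", seq_len(P))

  expr <- matrix(rnorm(P * nrow(genes), sd = sim$noise_sd[["g"]]),
                 P, nrow(genes), dimnames = list(sample_ids, genes$gene_id))
  mirna <- matrix(rnorm(P * nrow(mirnas), sd = sim$noise_sd[["m"]]),
                  P, nrow(mirnas), dimnames = list(sample_ids, mirnas$mirna_id))
  clogit <- matrix(rnorm(P * nrow(clusters), sd = sim$noise_sd[["c"]]),
                   P, nrow(clusters),
                   dimnames = list(sample_ids, clusters$cluster_id))

  breadth <- list()
  for (s in seq_len(K)) {
    sname <- paste0("S", s)
    rows <- subtype == sname
    at <- anchor_tbl[anchor_tbl$subtype == sname, ]
    e_s <- sim$effect_size * sim$subtype_strength[s]
    nb <- round(nrow(genes) * sim$program_frac * sim$program_size[s])
    pool <- setdiff(genes$gene_id, anchor_tbl$gene_id)
    bg <- sample(pool, min(nb, length(pool)))
    breadth[[sname]] <- bg
    # anchor markers are at full strength in every subtype (defining
    # markers are selected for being strong); the breadth program carries
    # the subtype-strength grading
    for (prog in list(list(g = at$gene_id, e = sim$effect_size),
                      list(g = bg, e = e_s * sim$breadth_scale))) {
      expr[rows, prog$g] <- expr[rows, prog$g] + prog$e
      ancl <- unique(gc$cluster_id[gc$gene_id %in% prog$g])
      if (length(ancl) > 0) {
        clogit[rows, ancl] <- clogit[rows, ancl] -
          sim$meth_coupling * sim$meth_coupling_mult[s] * prog$e
      }
    }
    m_anchor <- sim$mirna_strength_mult[s] * sim$effect_size
    mids <- unique(at$mirna_id)
    mirna[rows, mids] <- mirna[rows, mids] + m_anchor
    reptargets <- setdiff(unique(mg$gene_id[mg$mirna_id %in% mids]),
                          anchor_tbl$gene_id)
    if (length(reptargets) > 0) {
      expr[rows, reptargets] <- expr[rows, reptargets] -
        sim$mirna_repression * m_anchor
    }
  }

  if (sim$n_sites > 1L && sim$site_shift > 0) {
    for (sn in unique(site)) {
      rows <- site == sn
      expr[rows, ] <- sweep(expr[rows, , drop = FALSE], 2L,
                            rnorm(ncol(expr), sd = sim$site_shift), "+")
      mirna[rows, ] <- sweep(mirna[rows, , drop = FALSE], 2L,
                             rnorm(ncol(mirna), sd = sim$site_shift), "+")
      clogit[rows, ] <- sweep(clogit[rows, , drop = FALSE], 2L,
                              rnorm(ncol(clogit), sd = sim$site_shift), "+")
    }
  }

  # probe-level betas: cluster logit + probe noise, through the logistic map
  member <- clusters$member_probe_ids
  probe_ids <- unlist(member)
  probe_beta <- matrix(
    NA_real_, P, length(probe_ids),
    dimnames = list(sample_ids, probe_ids)
  )
  col0 <- 0L
  for (ci in seq_along(member)) {
    kprobes <- length(member[[ci]])
    noise <- matrix(rnorm(P * kprobes, sd = sim$probe_noise_sd), P, kprobes)
    probe_beta[, col0 + seq_len(kprobes)] <- plogis(clogit[, ci] + noise)
    col0 <- col0 + kprobes
  }

  planted_edges <- sort(unique(c(
    which(gc$gene_id %in% anchor_tbl$gene_id),
    nrow(gc) + which(mg$gene_id %in% anchor_tbl$gene_id &
                       mg$mirna_id %in% anchor_tbl$mirna_id)
  )))
  signal_genes <- unique(c(anchor_tbl$gene_id, unlist(breadth)))
  signal_edges <- sort(unique(c(
    which(gc$gene_id %in% signal_genes),
    nrow(gc) + which(mg$gene_id %in% anchor_tbl$gene_id &
                       mg$mirna_id %in% anchor_tbl$mirna_id)
  )))
  structure(
    list(
      expr = expr, probe_beta = probe_beta, mirna = mirna,
      samples = tibble::tibble(sample_id = sample_ids,
                               subtype = factor(subtype),
                               site = site),
      truth = list(anchors = anchor_tbl, breadth = breadth,
                   planted_edges = planted_edges,
                   signal_edges = signal_edges),
      sim = sim
    ),
    class = "xonet_cohort"
  )
}

#' @export
print.xonet_cohort <- function(x, ...) {
  cat(sprintf(
    "<xonet_cohort> %d patients, %d subtypes; %d genes / %d probes / %d miRNAs\n",
    nrow(x$expr), nlevels(x$samples$subtype), ncol(x$expr),
    ncol(x$probe_beta), ncol(x$mirna)
  ))
  invisible(x)
}

#' Ground-truth table of planted signal for attribution checks
#'
#' @param cohort A `xonet_cohort`.
#' @return List with the anchor tibble (`subtype`, `gene_id`, `mirna_id`)
#'   and the planted global edge-id vector.
#' @export
plant_edge_signal_report <- function(cohort) {
  cohort$truth
}

#' Degree-preserving randomization of cross-omics edges
#'
#' Repeated double-edge swaps within each relation (default 10 x |E|
#' attempts): two edges (u1, v1), (u2, v2) become (u1, v2), (u2, v1)
#' whenever the swap creates no duplicate edge. Every node keeps its degree
#' under each relation, so the rewired graph is a topology null that
#' destroys the biological alignment of the edges.
#'
#' @param graph A `hetero_graph`.
#' @param seed Integer seed.
#' @param swaps_per_edge Swap attempts per edge (default 10).
#' @return A rewired `hetero_graph` (stage counts annotated).
#' @export
rewire_edges <- function(graph, seed = 1L, swaps_per_edge = 10L) {
  set.seed(derive_seed(seed, "rewire"))
  swap_rel <- function(a, b) {
    ne <- length(a)
    if (ne < 2L) return(list(a = a, b = b))
    key <- function(x, y) paste0(x, "_", y)
    existing <- new.env(hash = TRUE)
    for (i in seq_len(ne)) assign(key(a[i], b[i]), TRUE, envir = existing)
    for (it in seq_len(swaps_per_edge * ne)) {
      ij <- sample.int(ne, 2L)
      i <- ij[1L]; j <- ij[2L]
      na1 <- key(a[i], b[j]); na2 <- key(a[j], b[i])
      if (exists(na1, envir = existing) || exists(na2, envir = existing)) next
      if (b[i] == b[j]) next
      rm(list = c(key(a[i], b[i]), key(a[j], b[j])), envir = existing)
      tmp <- b[i]; b[i] <- b[j]; b[j] <- tmp
      assign(key(a[i], b[i]), TRUE, envir = existing)
      assign(key(a[j], b[j]), TRUE, envir = existing)
    }
    list(a = a, b = b)
  }
  gc <- graph$edges$gc
  mg <- graph$edges$mg
  sw <- swap_rel(gc$cpg, gc$gene)
  gc$cpg <- sw$a; gc$gene <- sw$b
  gc$cluster_id <- graph$nodes$cpg$cluster_id[gc$cpg]
  gc$gene_id <- graph$nodes$gene$gene_id[gc$gene]
  sw <- swap_rel(mg$mirna, mg$gene)
  mg$mirna <- sw$a; mg$gene <- sw$b
  mg$mirna_id <- graph$nodes$mirna$mirna_id[mg$mirna]
  mg$gene_id <- graph$nodes$gene$gene_id[mg$gene]
  out <- graph
  out$edges$gc <- dplyr::arrange(gc, .data$cpg, .data$gene)
  out$edges$mg <- dplyr::arrange(mg, .data$mirna, .data$gene)
  out$stage_counts <- dplyr::bind_rows(
    graph$stage_counts,
    tibble::tibble(stage = "rewired", entity = c("gc_edge", "mg_edge"),
                   count = c(nrow(gc), nrow(mg)))
  )
  out
}

#' Write a simulated cohort to the pipeline's file formats
#'
#' Emits exactly the files the real pipeline reads: gene models TSV, probe
#' manifest TSV, target table TSV, three omics matrices, labels TSV, and a
#' ground-truth JSON.
#'
#' @param annot Output of [make_annotation_fixture()].
#' @param cohort A `xonet_cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(annot, cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genes <- annot$genes
  genes$tss <- purrr::map_chr(genes$tss, paste, collapse = ";")
  readr::write_tsv(genes, file.path(dir, "genes.tsv"))
  readr::write_tsv(annot$probes, file.path(dir, "probes.tsv"))
  readr::write_tsv(annot$targets, file.path(dir, "targets.tsv"))
  write_omics_matrix(cohort$expr, file.path(dir, "expression.tsv"))
  write_omics_matrix(cohort$probe_beta, file.path(dir, "methylation.tsv"))
  write_omics_matrix(cohort$mirna, file.path(dir, "mirna.tsv"))
  readr::write_tsv(cohort$samples, file.path(dir, "labels.tsv"))
  jsonlite::write_json(
    list(anchors = cohort$truth$anchors,
         planted_edges = cohort$truth$planted_edges,
         sim = unclass(cohort$sim)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
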