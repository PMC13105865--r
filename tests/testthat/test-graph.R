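# Graph construction: promoter windows, probe clustering, promoter
# membership, target filtering, variance dedup, assembly invariants.

test_that("promoter spans follow the strand-aware window and clip at zero", {
  genes <- tibble::tibble(
    gene_id = c("A", "B", "C"), symbol = c("A", "B", "C"),
    chrom = "chr1", strand = c("+", "-", "+"),
    tss = list(10000L, 10000L, 100L)
  )
  spans <- define_promoter_spans(genes)
  # + strand: inclusive genomic positions 8000..10500 -> [8000, 10501)
  expect_equal(spans$start[spans$gene_id == "A"], 8000L)
  expect_equal(spans$end[spans$gene_id == "A"], 10501L)
  # - strand mirror: 9500..12000 inclusive
  expect_equal(spans$start[spans$gene_id == "B"], 9500L)
  expect_equal(spans$end[spans$gene_id == "B"], 12001L)
  # clipping at chromosome start
  expect_equal(spans$start[spans$gene_id == "C"], 0L)
  # span length = upstream + downstream + 1 positions when unclipped
  unclipped <- spans[spans$gene_id != "C", ]
  expect_true(all(unclipped$end - unclipped$start == 2501L))
})

test_that("unknown strand records are rejected with a warning", {
  genes <- tibble::tibble(
    gene_id = c("A", "B"), symbol = c("A", "B"), chrom = "chr1",
    strand = c("+", "*"), tss = list(5000L, 5000L)
  )
  expect_warning(spans <- define_promoter_spans(genes), "strand")
  expect_equal(spans$gene_id, "A")
})

test_that("multi-TSS genes contribute one span per TSS", {
  genes <- tibble::tibble(
    gene_id = "A", symbol = "A", chrom = "chr1", strand = "+",
    tss = "10000;12000;12000"
  )
  spans <- define_promoter_spans(genes)
  expect_equal(nrow(spans), 2L) # duplicate TSS collapse
  expect_setequal(spans$source_tss, c(10000L, 12000L))
})

test_that("probe chaining merges within the gap threshold inclusively", {
  probes <- tibble::tibble(
    probe_id = c("p1", "p2", "p3"), chrom = "chr1",
    pos = c(100L, 550L, 1200L), missing_fraction = 0
  )
  cl <- cluster_probes(probes)
  # 550-100 = 450 <= 500 joins; 1200-550 = 650 > 500 leaves a dropped singleton
  expect_equal(nrow(cl), 1L)
  expect_setequal(cl$member_probe_ids[[1]], c("p1", "p2"))

  boundary <- tibble::tibble(
    probe_id = c("a", "b", "c"), chrom = "chr1",
    pos = c(0L, 500L, 1000L), missing_fraction = 0
  )
  cl2 <- cluster_probes(boundary)
  expect_equal(cl2$n_probes, 3L) # gaps of exactly 500 are inclusive
})

test_that("high-missingness probes are removed before chaining", {
  probes <- tibble::tibble(
    probe_id = c("p1", "p2", "p3"), chrom = "chr1",
    pos = c(100L, 550L, 1000L), missing_fraction = c(0, 0.2, 0)
  )
  cl <- cluster_probes(probes)
  # without p2 the 100 -> 1000 gap exceeds 500: no cluster survives
  expect_equal(nrow(cl), 0L)
  # at the threshold (10%) the probe is kept: filter is strict ">"
  probes$missing_fraction[2] <- 0.10
  expect_equal(cluster_probes(probes)$n_probes, 3L)
})

test_that("cluster_probes is permutation-invariant and idempotent; empty ok", {
  set.seed(42)
  probes <- tibble::tibble(
    probe_id = sprintf("p%02d", 1:40),
    chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
    pos = sample.int(20000L, 40),
    missing_fraction = sample(c(0, 0, 0, 0.3), 40, replace = TRUE)
  )
  cl1 <- cluster_probes(probes)
  cl2 <- cluster_probes(probes[sample.int(40), ])
  expect_equal(cl1, cl2)
  # re-clustering the member probes of each cluster reproduces it
  members <- probes[probes$probe_id %in% unlist(cl1$member_probe_ids), ]
  cl3 <- cluster_probes(members)
  expect_equal(cl3$cluster_id, cl1$cluster_id)
  # retained clusters satisfy their own invariants under re-scan
  for (i in seq_len(nrow(cl1))) {
    pos <- sort(probes$pos[probes$probe_id %in% cl1$member_probe_ids[[i]]])
    expect_gte(length(pos), 2L)
    if (length(pos) > 1) expect_true(all(diff(pos) <= 500L))
    expect_true(cl1$representative_pos[i] >= cl1$span_start[i] &&
                  cl1$representative_pos[i] <= cl1$span_end[i])
  }
  expect_equal(nrow(cluster_probes(probes[0, ])), 0L)
})

test_that("cluster methylation is the arithmetic mean of member probes", {
  clusters <- tibble::tibble(
    cluster_id = c("c1", "c2"), chrom = "chr1",
    span_start = c(0L, 100L), span_end = c(50L, 300L),
    representative_pos = c(25L, 200L), n_probes = c(2L, 3L),
    member_probe_ids = list(c("p1", "p2"), c("p3", "p4", "p5"))
  )
  beta <- matrix(c(0.2, 0.4, 0.1, 0.2, 0.9), 1,
                 dimnames = list("s1", paste0("p", 1:5)))
  out <- summarize_cluster_methylation(beta, clusters)
  expect_equal(out["s1", "c1"], 0.3)
  expect_equal(out["s1", "c2"], 0.4)
  # constant members give the constant back
  beta2 <- matrix(0.77, 2, 5, dimnames = list(c("s1", "s2"), paste0("p", 1:5)))
  expect_true(all(summarize_cluster_methylation(beta2, clusters) == 0.77))
  # missing member probe errors with its name
  expect_error(summarize_cluster_methylation(beta[, 1:4, drop = FALSE], clusters), "p5")
})

test_that("cluster-gene linking matches brute force and collapses duplicates", {
  genes <- tibble::tibble(
    gene_id = c("A", "B"), symbol = c("A", "B"), chrom = "chr1",
    strand = "+", tss = list(c(10000L, 10400L), 10600L)
  )
  spans <- define_promoter_spans(genes)
  clusters <- tibble::tibble(
    cluster_id = c("c1", "c2"), chrom = "chr1",
    span_start = c(8900L, 6900L), span_end = c(9100L, 7100L),
    representative_pos = c(9000L, 7000L), n_probes = 2L,
    member_probe_ids = list(c("x", "y"), c("u", "v"))
  )
  edges <- link_cpg_to_genes(clusters, spans)
  # c1 at 9000 is inside both TSS windows of A (one edge after dedup) and
  # inside B's window [8600, 11101); c2 at 7000 is outside all windows
  expect_equal(edges, tibble::tibble(cluster_id = c("c1", "c1"),
                                     gene_id = c("A", "B")))

  # brute-force double loop on a random instance
  set.seed(7)
  genes2 <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:20), symbol = sprintf("g%02d", 1:20),
    chrom = sample(c("chr1", "chr2"), 20, replace = TRUE),
    strand = sample(c("+", "-"), 20, replace = TRUE),
    tss = purrr::map(1:20, ~ sample.int(60000L, sample(1:2, 1)))
  )
  spans2 <- define_promoter_spans(genes2)
  clusters2 <- tibble::tibble(
    cluster_id = sprintf("c%02d", 1:30),
    chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
    representative_pos = sample.int(60000L, 30)
  ) |>
    dplyr::mutate(span_start = .data$representative_pos - 100L,
                  span_end = .data$representative_pos + 100L,
                  n_probes = 2L,
                  member_probe_ids = purrr::map(.data$cluster_id, ~ c("a", "b")))
  got <- link_cpg_to_genes(clusters2, spans2)
  want <- list()
  for (i in seq_len(nrow(clusters2))) {
    for (j in seq_len(nrow(spans2))) {
      if (clusters2$chrom[i] == spans2$chrom[j] &&
          clusters2$representative_pos[i] >= spans2$start[j] &&
          clusters2$representative_pos[i] < spans2$end[j]) {
        want[[length(want) + 1]] <- tibble::tibble(
          cluster_id = clusters2$cluster_id[i], gene_id = spans2$gene_id[j]
        )
      }
    }
  }
  want <- dplyr::arrange(dplyr::distinct(dplyr::bind_rows(want)),
                         .data$cluster_id, .data$gene_id)
  expect_equal(got, want)
})

test_that("target filtering keeps score <= -0.2 inclusively and dedups", {
  records <- tibble::tibble(
    mirna_id = c("m1", "m1", "m2", "m2", "m2"),
    gene_symbol = c("A", "B", "A", "A", "C"),
    context_score = c(-0.35, -0.1, -0.2, -0.5, -0.199)
  )
  out <- filter_mirna_targets(records)
  expect_equal(out, tibble::tibble(mirna_id = c("m1", "m2"),
                                   gene_symbol = c("A", "A")))
  # feature-space restriction
  out2 <- filter_mirna_targets(records, keep_genes = "B")
  expect_equal(nrow(out2), 0L)
})

test_that("variance dedup keeps the largest-variance instance, ties by id", {
  cand <- tibble::tibble(
    feature_id = c("f1", "f1", "f2", "f3", "f3"),
    instance = c("i2", "i1", "solo", "tb", "ta"),
    variance = c(0.7, 0.1, 0.5, 0.5, 0.5)
  )
  out <- dedup_by_variance(cand)
  expect_equal(out$instance[out$feature_id == "f1"], "i2")
  expect_equal(out$instance[out$feature_id == "f2"], "solo")
  expect_equal(out$instance[out$feature_id == "f3"], "ta")
})

test_that("assembled graph passes invariants and ledger is monotone", {
  w <- tiny_world()
  g <- w$graph
  expect_false(any(duplicated(g$edges$gc[, c("cpg", "gene")])))
  expect_false(any(duplicated(g$edges$mg[, c("mirna", "gene")])))
  expect_true(all(g$edges$gc$cpg %in% g$nodes$cpg$.idx))
  expect_true(all(g$edges$gc$gene %in% g$nodes$gene$.idx))
  expect_true(all(g$edges$mg$mirna %in% g$nodes$mirna$.idx))
  # probe counts never grow across filter stages
  ledger <- g$stage_counts
  praw <- ledger$count[ledger$stage == "raw" & ledger$entity == "probe"]
  pfil <- ledger$count[ledger$stage == "filtered" & ledger$entity == "probe"]
  expect_lte(pfil, praw)
  traw <- ledger$count[ledger$stage == "raw" & ledger$entity == "target_row"]
  tfil <- ledger$count[ledger$stage == "filtered" & ledger$entity == "target_row"]
  expect_lte(tfil, traw)
  # dangling edges are rejected
  expect_error(
    assemble_graph(g$nodes$gene, g$nodes$cpg, g$nodes$mirna,
                   tibble::tibble(cluster_id = "nope", gene_id = g$nodes$gene$gene_id[1]),
                   g$edges$mg[, c("mirna_id", "gene_id")]),
    "absent"
  )
})

test_that("graph fingerprint distinguishes graphs and survives a round trip", {
  w <- tiny_world()
  dir <- withr::local_tempdir()
  write_hetero_graph(w$graph, dir)
  g2 <- read_hetero_graph(dir)
  expect_equal(graph_fingerprint(g2), graph_fingerprint(w$graph))
  rew <- rewire_edges(w$graph, seed = 5)
  expect_false(graph_fingerprint(rew) == graph_fingerprint(w$graph))
})
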