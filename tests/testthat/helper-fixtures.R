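# Shared fixtures. Small worlds are built fresh per call; the medium
# trained model used by several attribution/robustness tests is memoized so
# the suite trains it only once.

tiny_world <- function(seed = 3, n_patients = 8, n_genes = 12, n_mirnas = 5,
                       n_subtypes = 3) {
  sim <- sim_config(
    n_genes = n_genes, n_mirnas = n_mirnas, n_patients = n_patients,
    n_subtypes = n_subtypes, anchors_per_subtype = 1, seed = seed
  )
  annot <- make_annotation_fixture(sim)
  graph <- build_hetero_graph(annot$genes, annot$probes, annot$targets)
  cohort <- make_cohort(graph, sim)
  cb <- summarize_cluster_methylation(cohort$probe_beta, graph$nodes$cpg)
  std <- list(
    g = fit_standardizer(cohort$expr),
    c = fit_standardizer(cb),
    m = fit_standardizer(cohort$mirna)
  )
  batch <- prepare_batch(
    graph,
    apply_standardizer(std$g, cohort$expr),
    apply_standardizer(std$c, cb),
    apply_standardizer(std$m, cohort$mirna),
    labels = cohort$samples$subtype
  )
  list(sim = sim, annot = annot, graph = graph, cohort = cohort,
       cbeta = cb, batch = batch)
}

tiny_model <- function(world, hidden_dim = 5, num_layers = 2, seed = 7,
                       lambda_gr = 1e-2) {
  cfg <- xonet_config(
    hidden_dim = hidden_dim, num_layers = num_layers,
    num_classes = nlevels(world$cohort$samples$subtype),
    lambda_gr = lambda_gr, seed = seed
  )
  mp <- xonet:::build_mp(world$graph, cfg)
  params <- xonet:::init_params(mp, cfg)
  fit <- structure(
    list(params = params, mp = mp, config = cfg,
         classes = levels(world$cohort$samples$subtype),
         graph_fingerprint = graph_fingerprint(world$graph)),
    class = "xonet_fit"
  )
  list(cfg = cfg, mp = mp, params = params, fit = fit)
}

# Memoized trained model on a small planted cohort (used by attribution and
# robustness tests).
.trained_cache <- new.env(parent = emptyenv())

trained_toy <- function() {
  if (!is.null(.trained_cache$fit)) return(as.list(.trained_cache))
  world <- planted_world(seed = 21)
  fit <- xonet_fit(world$graph, world$train_b, world$cfg)
  for (nm in names(world)) .trained_cache[[nm]] <- world[[nm]]
  .trained_cache$fit <- fit
  as.list(.trained_cache)
}

# 120-patient planted cohort split into train/test with fold-safe
# standardization.
planted_world <- function(seed = 21, n_patients = 120) {
  sim <- sim_config(n_patients = n_patients, seed = seed)
  annot <- make_annotation_fixture(sim)
  graph <- build_hetero_graph(annot$genes, annot$probes, annot$targets)
  cohort <- make_cohort(graph, sim)
  cb <- summarize_cluster_methylation(cohort$probe_beta, graph$nodes$cpg)
  set.seed(seed)
  n <- nrow(cohort$expr)
  test_idx <- sort(sample(n, round(0.2 * n)))
  tr <- setdiff(seq_len(n), test_idx)
  std <- list(
    g = fit_standardizer(cohort$expr[tr, , drop = FALSE]),
    c = fit_standardizer(cb[tr, , drop = FALSE]),
    m = fit_standardizer(cohort$mirna[tr, , drop = FALSE])
  )
  batch <- prepare_batch(
    graph,
    apply_standardizer(std$g, cohort$expr),
    apply_standardizer(std$c, cb),
    apply_standardizer(std$m, cohort$mirna),
    labels = cohort$samples$subtype
  )
  cfg <- xonet_config(seed = seed)
  list(
    sim = sim, annot = annot, graph = graph, cohort = cohort, cbeta = cb,
    std = std, batch = batch, cfg = cfg,
    train_ids = batch$sample_ids[tr], test_ids = batch$sample_ids[test_idx],
    train_b = xonet:::subset_batch(batch, batch$sample_ids[tr]),
    test_b = xonet:::subset_batch(batch, batch$sample_ids[test_idx])
  )
}

# Slow per-patient reference forward: dense double loops over neighbours,
# one patient at a time. Oracle for the vectorized implementation.
reference_forward <- function(params, mp, batch, cfg) {
  P <- ncol(batch$X$g)
  d <- cfg$hidden_dim
  vapply(seq_len(P), function(p) {
    H <- list()
    for (t in c("g", "c", "m")) {
      x <- batch$X[[t]][, p]
      if (!batch$mask[t, p]) x <- x * 0
      H[[t]] <- outer(x, params[[paste0("proj_w_", t)]]) +
        matrix(params[[paste0("proj_b_", t)]], length(x), d, byrow = TRUE)
    }
    for (l in seq_len(cfg$num_layers)) {
      W0 <- params[[paste0("W0_", l)]]
      pre <- lapply(H, function(h) h %*% t(W0))
      for (r in mp$rels) {
        Wr <- params[[paste0("Wr_", r$wname, "_", l)]]
        for (v in seq_len(mp$n[[r$dst]])) {
          nb <- r$src_idx[r$dst_idx == v]
          if (length(nb) > 0) {
            pre[[r$dst]][v, ] <- pre[[r$dst]][v, ] +
              colMeans(H[[r$src]][nb, , drop = FALSE] %*% t(Wr))
          }
        }
      }
      H <- lapply(pre, function(m) pmax(m, 0))
    }
    zs <- sapply(c("g", "c", "m"), function(t) {
      sc <- tanh(H[[t]] %*% t(params[[paste0("Watt_", t)]])) %*%
        params[[paste0("aatt_", t)]]
      al <- exp(sc - max(sc))
      al <- al / sum(al)
      colSums(H[[t]] * as.numeric(al))
    })
    f <- apply(zs, 2, function(zt) sum(params$q * tanh(params$U %*% zt)))
    f[!batch$mask[, p]] <- -Inf
    be <- exp(f - max(f))
    be <- be / sum(be)
    as.numeric(params$Wo %*% (zs %*% be) + params$bo)
  }, numeric(cfg$num_classes))
}

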