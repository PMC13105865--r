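# Reverse-mode gradients for the full model, hand-derived layer by layer
# and verified against finite differences in the test suite. One backward
# call can return any combination of parameter gradients (training), input
# gradients (node saliency / integrated gradients), and per-patient edge
# gate gradients (edge attribution). States use the d x (n*P) layout of
# the forward pass, so every step below is a BLAS product, a sparse
# Kronecker product, or an elementwise operation.

zero_like <- function(params) purrr::map(params, function(x) x * 0)

# dlogits: K x P gradient of the objective w.r.t. the logits.
# lambda_gr adds the graph-smoothness gradient (batch mean) at the final
# node states. Returns list(params =, inputs =, gates =) per `want`.
xonet_backward <- function(params, mp, config, fw, dlogits,
                           lambda_gr = 0,
                           want = c("params", "inputs", "gates")) {
  ch <- fw$cache
  d <- ch$d
  P <- ch$P
  L <- config$num_layers
  types <- c("g", "c", "m")
  want_par <- "params" %in% want
  want_inp <- "inputs" %in% want
  want_gat <- "gates" %in% want
  g <- if (want_par) zero_like(params) else list()
  gate_grad <- if (want_gat) matrix(0, mp$n_edges, P) else NULL

  z <- fw$z
  ztyp <- fw$ztyp
  beta <- fw$beta
  u <- ch$u
  mask <- ch$mask

  if (want_par) {
    g$Wo <- g$Wo + tcrossprod(dlogits, z)
    g$bo <- g$bo + rowSums(dlogits)
  }
  dz <- crossprod(params$Wo, dlogits)

  # fusion backward
  dbeta <- do.call(rbind, purrr::map(ztyp, ~ colSums(dz * .x)))
  dztyp <- purrr::imap(ztyp, function(zt, t) sweep(dz, 2L, beta[t, ], "*"))
  ssum <- colSums(beta * dbeta)
  df <- beta * sweep(dbeta, 2L, ssum, "-")
  df[!mask] <- 0
  for (t in types) {
    dpre_u <- outer(params$q, df[t, ]) * (1 - u[[t]]^2)
    if (want_par) {
      g$U <- g$U + tcrossprod(dpre_u, ztyp[[t]])
      g$q <- g$q + as.numeric(u[[t]] %*% df[t, ])
    }
    dztyp[[t]] <- dztyp[[t]] + crossprod(params$U, dpre_u)
  }

  # readout backward per type -> gradient at the final node states
  HL <- ch$Hs[[L + 1L]]
  dHL <- list()
  for (t in types) {
    H <- HL[[t]]
    n <- mp$n[[t]]
    alvec <- as.vector(fw$alpha[[t]])
    Tt <- ch$Ts[[t]]
    aatt <- params[[paste0("aatt_", t)]]
    # z_t = Rsum %*% (H * alpha): split the product rule
    dHal <- as.matrix(Matrix::crossprod(mp$Rsum[[t]], dztyp[[t]]))
    dim(dHal) <- c(d, n * P)
    dH <- dHal * rep(alvec, each = d)
    dalpha <- matrix(colSums(H * dHal), n, P)
    al <- fw$alpha[[t]]
    sa <- colSums(al * dalpha)
    dscore <- al * sweep(dalpha, 2L, sa, "-")
    dsvec <- as.vector(dscore)
    dTt <- outer(aatt, dsvec)
    if (want_par) {
      g[[paste0("aatt_", t)]] <- g[[paste0("aatt_", t)]] +
        as.numeric(Tt %*% dsvec)
    }
    dpreT <- dTt * (1 - Tt^2)
    if (want_par) {
      g[[paste0("Watt_", t)]] <- g[[paste0("Watt_", t)]] + tcrossprod(dpreT, H)
    }
    dHL[[t]] <- dH + crossprod(params[[paste0("Watt_", t)]], dpreT)
  }

  # graph smoothness penalty gradient at the final states (batch mean)
  if (lambda_gr > 0) {
    scl <- 2 * lambda_gr / P
    for (pr in mp$reg) {
      if (pr$ne == 0L) next
      D <- HL[[pr$a]][, colidx(pr$ia, mp$n[[pr$a]], P), drop = FALSE] -
        HL[[pr$b]][, colidx(pr$ib, mp$n[[pr$b]], P), drop = FALSE]
      D <- D * (scl * rep(pr$w, each = d))
      dim(D) <- c(d * pr$ne, P)
      da <- as.matrix(Matrix::crossprod(pr$Sa, D))
      dim(da) <- c(d, mp$n[[pr$a]] * P)
      db <- as.matrix(Matrix::crossprod(pr$Sb, D))
      dim(db) <- c(d, mp$n[[pr$b]] * P)
      dHL[[pr$a]] <- dHL[[pr$a]] + da
      dHL[[pr$b]] <- dHL[[pr$b]] - db
    }
  }

  # message-passing layers, last to first
  dH <- dHL
  for (l in rev(seq_len(L))) {
    Hin <- ch$Hs[[l]]
    pre <- ch$pres[[l]]
    if (length(ch$drops) >= l && !is.null(ch$drops[[l]])) {
      dH <- Map(`*`, dH, ch$drops[[l]])
    }
    dpre <- Map(function(dh, p) dh * (p > 0), dH, pre)
    W0 <- params[[paste0("W0_", l)]]
    dHin <- lapply(dpre, function(x) crossprod(W0, x))
    if (want_par) {
      for (t in types) {
        g[[paste0("W0_", l)]] <- g[[paste0("W0_", l)]] +
          tcrossprod(dpre[[t]], Hin[[t]])
      }
    }
    for (ri in seq_along(mp$rels)) {
      r <- mp$rels[[ri]]
      ne <- length(r$src_idx)
      if (ne == 0L) next
      Wr <- params[[paste0("Wr_", r$wname, "_", l)]]
      dT <- agg_apply(ch$Kt[[ri]], dpre[[r$dst]], d)
      if (want_par) {
        g[[paste0("Wr_", r$wname, "_", l)]] <-
          g[[paste0("Wr_", r$wname, "_", l)]] + tcrossprod(dT, Hin[[r$src]])
      }
      dHin[[r$src]] <- dHin[[r$src]] + crossprod(Wr, dT)
      if (want_gat) {
        Tmsg <- Wr %*% Hin[[r$src]]
        prod <- dpre[[r$dst]][, colidx(r$dst_idx, mp$n[[r$dst]], P),
                              drop = FALSE] *
          Tmsg[, colidx(r$src_idx, mp$n[[r$src]], P), drop = FALSE]
        gg <- matrix(colSums(prod), ne, P) / r$deg[r$dst_idx]
        gate_grad[r$edge_id, ] <- gate_grad[r$edge_id, ] + gg
      }
    }
    dH <- dHin
  }

  # input projection backward
  dinputs <- NULL
  if (want_par || want_inp) {
    dinputs <- list()
    for (t in types) {
      pw <- params[[paste0("proj_w_", t)]]
      dH0 <- dH[[t]]
      if (want_par) {
        g[[paste0("proj_w_", t)]] <- g[[paste0("proj_w_", t)]] +
          as.numeric(dH0 %*% as.vector(ch$X[[t]]))
        g[[paste0("proj_b_", t)]] <- g[[paste0("proj_b_", t)]] + rowSums(dH0)
      }
      if (want_inp) {
        dX <- matrix(as.numeric(crossprod(pw, dH0)), nrow(ch$X[[t]]), P)
        dX[, !mask[t, ]] <- 0 # masked modalities never see their true input
        dimnames(dX) <- dimnames(ch$X[[t]])
        dinputs[[t]] <- dX
      }
    }
  }

  list(params = if (want_par) g else NULL, inputs = dinputs,
       gates = gate_grad)
}

# Loss + gradients in one call (training step). Returns loss components and
# parameter gradients including graph regularizer and weight decay terms.
# The compiled backend is the training default; the pure-R path is retained
# as the reference implementation and numerical oracle.
xonet_loss_grad <- function(params, mp, config, graph, batch, labels,
                            training = FALSE, backend = c("cpp", "r")) {
  backend <- match.arg(backend)
  if (backend == "cpp") {
    m <- batch$mask
    storage.mode(m) <- "integer"
    res <- .cpp_loss_grad(
      params, unname(batch$X), m, as.integer(labels),
      mp$cpp$rels, mp$cpp$regs, config$num_layers, config$hidden_dim,
      config$lambda_gr, config$lambda_wd, config$dropout, training
    )
    return(list(loss = res$loss, grads = res$grads))
  }
  fw <- xonet_forward(params, mp, batch, config,
                      training = training, keep_cache = TRUE)
  P <- ncol(fw$probs)
  reg <- graph_regularizer(fw$H_final, graph, config$hidden_dim, reduce = "none")
  loss <- total_loss(fw$probs, labels, reg, config$lambda_gr,
                     config$lambda_wd, params)
  Y <- matrix(0, nrow(fw$probs), P)
  Y[cbind(labels, seq_len(P))] <- 1
  dlogits <- (fw$probs - Y) / P
  bw <- xonet_backward(params, mp, config, fw, dlogits,
                       lambda_gr = config$lambda_gr, want = "params")
  grads <- purrr::map2(bw$params, params, ~ .x + 2 * config$lambda_wd * .y)
  list(loss = loss, grads = grads, fw = fw)
}

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
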