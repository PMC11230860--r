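# Directed message-passing encoder + feed-forward head, with analytic
# backpropagation. All dense algebra is base matrix code; the three
# graph-structured aggregations (arc -> arc messages, arc -> atom readin,
# atom -> molecule pooling) are sparse matrix products assembled per batch.
#
# Forward pass, for a batch of molecules with atom features X (atoms x d_a)
# and arc features E (arcs x d_b), arc a running src(a) -> dst(a):
#   H0   = relu([X[src,], E] Wi + bi)                (arc states, dim h)
#   H_t  = relu(H0 + (A H_{t-1}) Wh + bh)            t = 1..depth-1
#          where A[a, b] = 1 iff dst(b) = src(a) and b != reverse(a)
#   Hv   = relu([X, B H_{depth-1}] Wo + bo)          B[v, a] = 1 iff dst(a) = v
#   G    = P Hv                                      mean pooling per molecule
#   S    = sigmoid(relu-MLP(G) w_out + b_out)        hidden widths per config
# trained by minibatch MSE against {0, 1} labels.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- batch assembly ---------------------------------------------------------

# Combine per-molecule graph_features (list) into one batch with sparse
# aggregation operators. Molecules with zero bonds contribute atoms only.
mpnn_batch <- function(feats) {
  n_mols <- length(feats)
  na <- vapply(feats, function(f) f$n_atoms, integer(1))
  nr <- vapply(feats, function(f) 2L * f$n_bonds, integer(1))
  atom_off <- cumsum(c(0L, na[-n_mols]))
  arc_off <- cumsum(c(0L, nr[-n_mols]))
  X <- do.call(rbind, lapply(feats, `[[`, "atom_features"))
  E <- do.call(rbind, lapply(feats, `[[`, "bond_features"))
  src <- unlist(lapply(seq_len(n_mols), function(i) feats[[i]]$src + atom_off[i]))
  dst <- unlist(lapply(seq_len(n_mols), function(i) feats[[i]]$dst + atom_off[i]))
  src <- as.integer(src %||% integer(0))
  dst <- as.integer(dst %||% integer(0))

  # arc -> arc: A[a, b] = 1 iff b feeds a's source, b not a's reverse
  ai <- unlist(lapply(seq_len(n_mols), function(i) {
    f <- feats[[i]]
    rep(seq_len(2L * f$n_bonds) + arc_off[i],
        lengths(f$bond_neighbors))
  }))
  aj <- unlist(lapply(seq_len(n_mols), function(i) {
    f <- feats[[i]]
    unlist(f$bond_neighbors) + arc_off[i]
  }))
  n_arcs <- sum(nr)
  n_atoms <- sum(na)
  A <- Matrix::sparseMatrix(i = as.integer(ai %||% integer(0)),
                            j = as.integer(aj %||% integer(0)),
                            x = 1, dims = c(n_arcs, n_arcs))
  B <- Matrix::sparseMatrix(i = dst, j = seq_len(n_arcs), x = 1,
                            dims = c(n_atoms, n_arcs))
  P <- Matrix::sparseMatrix(i = rep(seq_len(n_mols), na),
                            j = seq_len(n_atoms), x = rep(1 / na, na),
                            dims = c(n_mols, n_atoms))
  list(X = X, E = E, src = src, A = A, B = B, P = P,
       n_mols = n_mols, n_arcs = n_arcs, n_atoms = n_atoms)
}

# --- parameters -------------------------------------------------------------

mpnn_init_params <- function(d_atom, d_bond, mp_hidden, hidden_layers, seed) {
  glorot <- function(nin, nout) {
    matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
  }
  with_seed(seed, {
    h <- mp_hidden
    p <- list(
      Wi = glorot(d_atom + d_bond, h), bi = numeric(h),
      Wh = glorot(h, h),               bh = numeric(h),
      Wo = glorot(d_atom + h, h),      bo = numeric(h)
    )
    widths <- c(h, hidden_layers, 1L)
    for (l in seq_len(length(widths) - 1L)) {
      p[[paste0("W", l)]] <- glorot(widths[l], widths[l + 1L])
      p[[paste0("b", l)]] <- numeric(widths[l + 1L])
    }
    p$n_ffn <- length(widths) - 1L
    p
  })
}

# --- forward / backward -----------------------------------------------------

mpnn_forward <- function(params, batch, depth, keep_cache = FALSE) {
  Fin <- cbind(batch$X[batch$src, , drop = FALSE], batch$E)
  H0 <- relu(sweep(Fin %*% params$Wi, 2L, params$bi, `+`))
  H <- H0
  Ms <- vector("list", max(depth - 1L, 0L))
  Hs <- vector("list", max(depth - 1L, 0L))
  if (depth > 1L) for (t in seq_len(depth - 1L)) {
    M <- as.matrix(batch$A %*% H)
    H <- relu(sweep(H0 + M %*% params$Wh, 2L, params$bh, `+`))
    Ms[[t]] <- M
    Hs[[t]] <- H
  }
  Mv <- as.matrix(batch$B %*% H)
  Av <- cbind(batch$X, Mv)
  Hv <- relu(sweep(Av %*% params$Wo, 2L, params$bo, `+`))
  G <- as.matrix(batch$P %*% Hv)
  Z <- vector("list", params$n_ffn)
  cur <- G
  for (l in seq_len(params$n_ffn - 1L)) {
    cur <- relu(sweep(cur %*% params[[paste0("W", l)]], 2L,
                      params[[paste0("b", l)]], `+`))
    Z[[l]] <- cur
  }
  logits <- sweep(cur %*% params[[paste0("W", params$n_ffn)]], 2L,
                  params[[paste0("b", params$n_ffn)]], `+`)
  S <- sigmoid(logits)
  out <- list(scores = as.numeric(S))
  if (keep_cache)
    out$cache <- list(Fin = Fin, H0 = H0, Ms = Ms, Hs = Hs, H = H, Mv = Mv,
                      Av = Av, Hv = Hv, G = G, Z = Z, S = S)
  out
}

# gradients of mean((S - y)^2) w.r.t. every parameter
mpnn_backward <- function(params, batch, cache, y, depth) {
  n <- length(y)
  g <- list()
  dS <- matrix(2 * (cache$S - y) / n, ncol = 1L)
  dL <- dS * cache$S * (1 - cache$S)
  # FFN
  cur_in <- if (params$n_ffn > 1L) cache$Z[[params$n_ffn - 1L]] else cache$G
  g[[paste0("W", params$n_ffn)]] <- crossprod(cur_in, dL)
  g[[paste0("b", params$n_ffn)]] <- colSums(dL)
  dcur <- dL %*% t(params[[paste0("W", params$n_ffn)]])
  for (l in rev(seq_len(params$n_ffn - 1L))) {
    dpre <- dcur * (cache$Z[[l]] > 0)
    prev <- if (l > 1L) cache$Z[[l - 1L]] else cache$G
    g[[paste0("W", l)]] <- crossprod(prev, dpre)
    g[[paste0("b", l)]] <- colSums(dpre)
    dcur <- dpre %*% t(params[[paste0("W", l)]])
  }
  dG <- dcur
  # pooling and atom readout
  dHv <- as.matrix(Matrix::crossprod(batch$P, dG))
  dPo <- dHv * (cache$Hv > 0)
  g$Wo <- crossprod(cache$Av, dPo)
  g$bo <- colSums(dPo)
  dAv <- dPo %*% t(params$Wo)
  d_atom <- ncol(batch$X)
  dMv <- dAv[, (d_atom + 1L):ncol(dAv), drop = FALSE]
  dH <- as.matrix(Matrix::crossprod(batch$B, dMv))
  # message-passing unroll
  g$Wh <- matrix(0, nrow(params$Wh), ncol(params$Wh))
  g$bh <- numeric(length(params$bh))
  dH0 <- matrix(0, nrow(cache$H0), ncol(cache$H0))
  if (depth > 1L) for (t in rev(seq_len(depth - 1L))) {
    dpre <- dH * (cache$Hs[[t]] > 0)
    g$Wh <- g$Wh + crossprod(cache$Ms[[t]], dpre)
    g$bh <- g$bh + colSums(dpre)
    dH0 <- dH0 + dpre
    dH <- as.matrix(Matrix::crossprod(batch$A, dpre %*% t(params$Wh)))
  }
  dH0 <- dH0 + dH   # path of H entering the first aggregation (H_0 = H0)
  dpre0 <- dH0 * (cache$H0 > 0)
  g$Wi <- crossprod(cache$Fin, dpre0)
  g$bi <- colSums(dpre0)
  g
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  nm <- setdiff(names(params), "n_ffn")
  list(m = lapply(params[nm], function(p) p * 0),
       v = lapply(params[nm], function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(params, grads, state, lr) {
  state$t <- state$t + 1L
  b1t <- 1 - state$beta1^state$t
  b2t <- 1 - state$beta2^state$t
  for (nm in names(state$m)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * gr
    state$v[[nm]] <- state$beta2 * state$v[[nm]] + (1 - state$beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + state$eps)
  }
  list(params = params, state = state)
}
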