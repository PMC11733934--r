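# E(3)-equivariant graph network noise predictor.
#
# Node features are invariant scalars (one-hot blocks + time signal), so
# feature updates are trivially rotation-invariant; coordinate updates are
# sums of relative vectors (x_i - x_j) scaled by invariant gates, so they
# rotate covariantly. Only ligand nodes' coordinates are ever updated:
# pocket C-alpha nodes and interaction particles are fixed conditions.

silu <- function(x) x / (1 + exp(-x))
silu_grad <- function(x) {
  s <- 1 / (1 + exp(-x))
  s * (1 + x * (1 - s))
}
sigmoid <- function(x) 1 / (1 + exp(-x))

KIND_LIGAND <- 1L; KIND_POCKET <- 2L; KIND_PARTICLE <- 3L

#' Build the undirected distance-cutoff edge list
#'
#' An edge joins every pair of nodes (any kinds) strictly closer than
#' `cutoff`; no self edges; isolated nodes are allowed.
#' @param positions n x 3 coordinate matrix
#' @param cutoff edge cutoff in Angstrom (default 5.0)
#' @return data.frame(i, j) with i < j
#' @export
build_edges <- function(positions, cutoff = 5.0) {
  stopifnot(cutoff > 0)
  n <- nrow(positions)
  if (n < 2) return(data.frame(i = integer(0), j = integer(0)))
  d <- pairwise_dist(positions, positions)
  hit <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
  data.frame(i = hit[, 1], j = hit[, 2])
}

kind_pair_class <- function(ki, kj) {
  # unordered kind pair -> 1..6: LL, LP, LI, PP, PI, II
  lo <- pmin(ki, kj); hi <- pmax(ki, kj)
  match(lo * 10 + hi, c(11, 12, 13, 22, 23, 33))
}

#' Assemble the conditioned joint graph for one denoising evaluation
#'
#' Node order: ligand, pocket, particles. Features are the concatenation
#' ligand-atom one-hot block (noised values on ligand rows, zero elsewhere)
#' | pocket residue one-hot | particle role one-hot | node-kind flags |
#' t/T. Edges come from [build_edges()] on the current coordinates; edge
#' features are the one-hot of the unordered node-kind pair (6 classes).
#'
#' @param z_x ligand latent coordinates (n_lig x 3)
#' @param z_h ligand latent features (n_lig x vocab)
#' @param pocket CalphaPocket (or NULL)
#' @param particles particle data.frame (may have zero rows)
#' @param t_frac time signal t/T in \[0, 1\]
#' @param cutoff edge cutoff (Angstrom)
#' @return list(x, h, kind, lig_mask, edges (directed), edge_feat, n_lig)
#' @export
conditioned_graph <- function(z_x, z_h, pocket, particles, t_frac,
                              cutoff = 5.0) {
  n_lig <- nrow(z_x)
  if (is.null(n_lig) || n_lig < 1) stop("graph needs at least one ligand node")
  pocket_pos <- if (is.null(pocket)) matrix(0, 0, 3) else pocket$pos
  pocket_oh <- if (is.null(pocket)) matrix(0, 0, 21) else pocket$onehot
  part_pos <- as.matrix(particles[, c("x", "y", "z"), drop = FALSE])
  part_oh <- particle_one_hot(particles$role)
  n_p <- nrow(pocket_pos); n_i <- nrow(part_pos)
  n <- n_lig + n_p + n_i
  kind <- rep(c(KIND_LIGAND, KIND_POCKET, KIND_PARTICLE),
              c(n_lig, n_p, n_i))
  x <- rbind(z_x, pocket_pos, part_pos)
  vocab_dim <- ncol(z_h)
  h <- matrix(0, n, vocab_dim + 21 + 2 + 3 + 1)
  h[seq_len(n_lig), seq_len(vocab_dim)] <- z_h
  if (n_p) h[n_lig + seq_len(n_p), vocab_dim + seq_len(21)] <- pocket_oh
  if (n_i) h[n_lig + n_p + seq_len(n_i), vocab_dim + 21 + seq_len(2)] <- part_oh
  h[cbind(seq_len(n), vocab_dim + 23 + kind)] <- 1
  h[, ncol(h)] <- t_frac
  und <- build_edges(x, cutoff)
  ei <- c(und$i, und$j); ej <- c(und$j, und$i) # directed: ei receives from ej
  ef <- matrix(0, length(ei), 6)
  if (length(ei)) ef[cbind(seq_along(ei), kind_pair_class(kind[ei], kind[ej]))] <- 1
  list(x = x, h = h, kind = kind, lig_mask = kind == KIND_LIGAND,
       edges = cbind(ei, ej), edge_feat = ef, n_lig = n_lig,
       t_frac = t_frac, cutoff = cutoff)
}

glorot <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(1 / nin)), nin, nout)
}

#' Initialize an EGNN noise-prediction model
#'
#' @param n_layers number of equivariant graph convolutional layers
#' @param hidden hidden width of every MLP
#' @param vocab_dim ligand element vocabulary size (feature-noise dimension)
#' @param edge_feat_dim edge-feature dimension (6 kind-pair classes)
#' @param cutoff edge cutoff carried in the config
#' @param seed integer seed for the weight draw
#' @param zero_final zero-initialize the last layer of the coordinate gate
#'   and the feature output head, so the untrained network is the identity
#'   on coordinates (stable start of training)
#' @return model object: list(config, params)
#' @export
egnn_init <- function(n_layers = 6, hidden = 256, vocab_dim = 10,
                      edge_feat_dim = 6, cutoff = 5.0, seed = NULL,
                      zero_final = TRUE) {
  n_feat_in <- vocab_dim + 21 + 2 + 3 + 1
  with_seed(seed, {
    W <- hidden
    params <- list(emb_W = glorot(n_feat_in, W), emb_b = numeric(W))
    for (l in seq_len(n_layers)) {
      p <- list(
        We1 = glorot(2 * W + 1 + edge_feat_dim, W), be1 = numeric(W),
        We2 = glorot(W, W), be2 = numeric(W),
        Wa = glorot(W, 1), ba = numeric(1),
        Wh1 = glorot(2 * W, W), bh1 = numeric(W),
        Wh2 = glorot(W, W), bh2 = numeric(W),
        Wr1 = glorot(W, W), br1 = numeric(W),
        Wr2 = if (zero_final) matrix(0, W, 1) else glorot(W, 1) * 0.1,
        br2 = numeric(1))
      names(p) <- paste0("l", l, "_", names(p))
      params <- c(params, p)
    }
    params$out_W <- if (zero_final) matrix(0, W, vocab_dim) else
      glorot(W, vocab_dim) * 0.1
    params$out_b <- numeric(vocab_dim)
    structure(list(
      config = list(n_layers = n_layers, hidden = hidden,
                    vocab_dim = vocab_dim, edge_feat_dim = edge_feat_dim,
                    n_feat_in = n_feat_in, cutoff = cutoff, version = 1L),
      params = params), class = "egnn_model")
  })
}

layer_forward <- function(x, h, graph, P, lig_idx, keep_cache) {
  ei <- graph$edges[, 1]; ej <- graph$edges[, 2]
  n <- nrow(x); W <- ncol(h)
  if (!length(ei)) {
    cache <- if (keep_cache) list(empty = TRUE, x_in = x, h_in = h) else NULL
    return(list(x = x, h = h, cache = cache))
  }
  v <- x[ei, , drop = FALSE] - x[ej, , drop = FALSE]
  d2 <- rowSums(v^2); d <- sqrt(d2)
  ein <- cbind(h[ei, , drop = FALSE], h[ej, , drop = FALSE], d2,
               graph$edge_feat)
  p1 <- sweep(ein %*% P$We1, 2, P$be1, "+"); q1 <- silu(p1)
  p2 <- sweep(q1 %*% P$We2, 2, P$be2, "+"); m <- silu(p2)
  za <- m %*% P$Wa + P$ba[1]
  att <- sigmoid(za)
  mt <- m * as.numeric(att)
  agg <- matrix(0, n, W)
  rs <- rowsum(mt, ei)
  agg[as.integer(rownames(rs)), ] <- rs
  u <- cbind(h, agg)
  ph1 <- sweep(u %*% P$Wh1, 2, P$bh1, "+"); qh1 <- silu(ph1)
  ph2 <- sweep(qh1 %*% P$Wh2, 2, P$bh2, "+")
  h_out <- h + ph2
  pr1 <- sweep(m %*% P$Wr1, 2, P$br1, "+"); qr1 <- silu(pr1)
  sc <- qr1 %*% P$Wr2 + P$br2[1]
  r <- v / (d + 1)
  upd <- matrix(0, n, 3)
  rs2 <- rowsum(r * as.numeric(sc), ei)
  upd[as.integer(rownames(rs2)), ] <- rs2
  x_out <- x
  x_out[lig_idx, ] <- x[lig_idx, , drop = FALSE] + upd[lig_idx, , drop = FALSE]
  cache <- NULL
  if (keep_cache) {
    cache <- list(x_in = x, h_in = h, v = v, d = d, ein = ein, p1 = p1,
                  q1 = q1, p2 = p2, m = m, za = za, att = att, mt = mt,
                  u = u, ph1 = ph1, qh1 = qh1, pr1 = pr1, qr1 = qr1,
                  sc = sc, r = r)
  }
  list(x = x_out, h = h_out, cache = cache)
}

#' Predict the noise for the ligand nodes of a conditioned graph
#'
#' Runs the stacked equivariant layers. The network's raw outputs are the
#' total ligand coordinate displacement F_x (equivariant) and a linear
#' head F_h on the final ligand embeddings. Without preconditioning the
#' raw outputs are returned as the noise prediction. With `precond =
#' list(alpha, sigma)` (the schedule entries at the current step) the
#' prediction is assembled as eps_hat = sigma_t z - alpha_t F: the
#' signal-to-noise-aware residual parametrization whose optimal network
#' target sigma_t x0 - alpha_t eps is bounded and smooth across the whole
#' time range, so a small network trains stably at both ends of the
#' schedule. Condition nodes' positions are never modified.
#'
#' @param graph a [conditioned_graph()]
#' @param model an [egnn_init()] model
#' @param keep_cache retain intermediates for the backward pass
#' @param precond NULL, or list(alpha, sigma) for the residual
#'   parametrization
#' @return list(eps_x (n_lig x 3), eps_h (n_lig x vocab), cache)
#' @export
predict_noise <- function(graph, model, keep_cache = FALSE, precond = NULL) {
  if (graph$n_lig < 1) stop("no ligand nodes in graph")
  P <- model$params
  if (ncol(graph$h) != model$config$n_feat_in) {
    stop("graph feature width ", ncol(graph$h),
         " does not match model config ", model$config$n_feat_in)
  }
  lig_idx <- which(graph$lig_mask)
  h <- sweep(graph$h %*% P$emb_W, 2, P$emb_b, "+")
  x <- graph$x
  caches <- vector("list", model$config$n_layers)
  for (l in seq_len(model$config$n_layers)) {
    Pl <- P[paste0("l", l, "_",
                   c("We1", "be1", "We2", "be2", "Wa", "ba", "Wh1", "bh1",
                     "Wh2", "bh2", "Wr1", "br1", "Wr2", "br2"))]
    names(Pl) <- sub("^l[0-9]+_", "", names(Pl))
    out <- layer_forward(x, h, graph, Pl, lig_idx, keep_cache)
    x <- out$x; h <- out$h; caches[[l]] <- out$cache
  }
  F_x <- x[lig_idx, , drop = FALSE] - graph$x[lig_idx, , drop = FALSE]
  F_h <- sweep(h[lig_idx, , drop = FALSE] %*% P$out_W, 2, P$out_b, "+")
  if (is.null(precond)) {
    eps_x <- F_x; eps_h <- F_h
  } else {
    z_x <- graph$x[lig_idx, , drop = FALSE]
    z_h <- graph$h[lig_idx, seq_len(model$config$vocab_dim), drop = FALSE]
    eps_x <- precond$sigma * z_x - precond$alpha * F_x
    eps_h <- precond$sigma * z_h - precond$alpha * F_h
  }
  list(eps_x = eps_x, eps_h = eps_h,
       cache = if (keep_cache) list(layers = caches, h_final = h,
                                    lig_idx = lig_idx,
                                    precond = precond) else NULL)
}

#' Single equivariant layer applied to a graph (exposed for testing)
#' @param graph a [conditioned_graph()]
#' @param model model whose layer `l` is applied
#' @param l layer index
#' @return list(x, h) updated positions and embedded features
#' @export
egcl_forward <- function(graph, model, l = 1L) {
  P <- model$params
  h <- sweep(graph$h %*% P$emb_W, 2, P$emb_b, "+")
  Pl <- P[paste0("l", l, "_",
                 c("We1", "be1", "We2", "be2", "Wa", "ba", "Wh1", "bh1",
                   "Wh2", "bh2", "Wr1", "br1", "Wr2", "br2"))]
  names(Pl) <- sub("^l[0-9]+_", "", names(Pl))
  out <- layer_forward(graph$x, h, graph, Pl, which(graph$lig_mask), FALSE)
  list(x = out$x, h = out$h)
}
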