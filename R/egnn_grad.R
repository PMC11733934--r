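# Reverse-mode gradients for the EGNN, written by hand (no autodiff
# framework is available in the target environment). The layout mirrors
# layer_forward(); every intermediate used here is stored in the forward
# cache. Gradients are checked against central finite differences in the
# test suite.

scatter_add <- function(target, idx, vals) {
  rs <- rowsum(vals, idx)
  ii <- as.integer(rownames(rs))
  target[ii, ] <- target[ii, , drop = FALSE] + rs
  target
}

layer_backward <- function(cache, graph, P, lig_idx, dX, dH) {
  if (!is.null(cache$empty)) {
    g <- lapply(P, function(w) w * 0)
    return(list(dX = dX, dH = dH, grads = g))
  }
  ei <- graph$edges[, 1]; ej <- graph$edges[, 2]
  W <- ncol(cache$h_in)
  n <- nrow(cache$x_in)

  # ---- h branch: h_out = h_in + phi_h([h_in, agg]) ----
  dph2 <- dH
  gWh2 <- crossprod(cache$qh1, dph2); gbh2 <- colSums(dph2)
  dqh1 <- dph2 %*% t(P$Wh2)
  dph1 <- dqh1 * silu_grad(cache$ph1)
  gWh1 <- crossprod(cache$u, dph1); gbh1 <- colSums(dph1)
  du <- dph1 %*% t(P$Wh1)
  dH_in <- dH + du[, seq_len(W), drop = FALSE]
  dagg <- du[, W + seq_len(W), drop = FALSE]

  # ---- coordinate branch: x_out = x_in + mask * sum_j r * s ----
  dupd <- matrix(0, n, 3)
  dupd[lig_idx, ] <- dX[lig_idx, , drop = FALSE]
  dupd_e <- dupd[ei, , drop = FALSE]
  ds <- rowSums(dupd_e * cache$r)                       # per-edge scalar
  dr <- dupd_e * as.numeric(cache$sc)
  gWr2 <- crossprod(cache$qr1, cbind(ds)); gbr2 <- sum(ds)
  dqr1 <- cbind(ds) %*% t(P$Wr2)
  dpr1 <- dqr1 * silu_grad(cache$pr1)
  gWr1 <- crossprod(cache$m, dpr1); gbr1 <- colSums(dpr1)
  dm <- dpr1 %*% t(P$Wr1)

  # r = v / (d + 1):  dv = dr/(d+1) - v (v . dr) / (d (d+1)^2)
  d_ <- cache$d
  vdotdr <- rowSums(cache$v * dr)
  dv <- dr / (d_ + 1) - cache$v * (vdotdr / (d_ * (d_ + 1)^2))

  # ---- attention-gated messages ----
  dmt <- dagg[ei, , drop = FALSE]
  dm <- dm + dmt * as.numeric(cache$att)
  datt <- rowSums(dmt * cache$m)
  dza <- datt * as.numeric(cache$att) * (1 - as.numeric(cache$att))
  gWa <- crossprod(cache$m, cbind(dza)); gba <- sum(dza)
  dm <- dm + cbind(dza) %*% t(P$Wa)

  # ---- phi_e ----
  dp2 <- dm * silu_grad(cache$p2)
  gWe2 <- crossprod(cache$q1, dp2); gbe2 <- colSums(dp2)
  dq1 <- dp2 %*% t(P$We2)
  dp1 <- dq1 * silu_grad(cache$p1)
  gWe1 <- crossprod(cache$ein, dp1); gbe1 <- colSums(dp1)
  dein <- dp1 %*% t(P$We1)

  dH_in <- scatter_add(dH_in, ei, dein[, seq_len(W), drop = FALSE])
  dH_in <- scatter_add(dH_in, ej, dein[, W + seq_len(W), drop = FALSE])
  dd2 <- dein[, 2 * W + 1]
  dv <- dv + 2 * cache$v * dd2

  dX_in <- dX
  dX_in <- scatter_add(dX_in, ei, dv)
  dX_in <- scatter_add(dX_in, ej, -dv)

  list(dX = dX_in, dH = dH_in,
       grads = list(We1 = gWe1, be1 = gbe1, We2 = gWe2, be2 = gbe2,
                    Wa = gWa, ba = gba, Wh1 = gWh1, bh1 = gbh1,
                    Wh2 = gWh2, bh2 = gbh2, Wr1 = gWr1, br1 = gbr1,
                    Wr2 = gWr2, br2 = gbr2))
}

#' Gradients of a scalar loss w.r.t. every model parameter
#'
#' @param graph the [conditioned_graph()] used in the forward pass
#' @param model the model
#' @param fwd result of `predict_noise(graph, model, keep_cache = TRUE)`
#' @param d_eps_x gradient of the loss w.r.t. eps_x (n_lig x 3)
#' @param d_eps_h gradient of the loss w.r.t. eps_h (n_lig x vocab)
#' @return named list of gradients matching `model$params`
#' @export
egnn_backward <- function(graph, model, fwd, d_eps_x, d_eps_h) {
  P <- model$params
  if (!is.null(fwd$cache$precond)) {
    # eps_hat = sigma z - alpha F: only the network term F carries
    # parameter gradients
    d_eps_x <- -fwd$cache$precond$alpha * d_eps_x
    d_eps_h <- -fwd$cache$precond$alpha * d_eps_h
  }
  lig_idx <- fwd$cache$lig_idx
  n <- nrow(graph$x)
  grads <- lapply(P, function(w) w * 0)

  # output head
  h_lig <- fwd$cache$h_final[lig_idx, , drop = FALSE]
  grads$out_W <- crossprod(h_lig, d_eps_h)
  grads$out_b <- colSums(d_eps_h)

  dH <- matrix(0, n, model$config$hidden)
  dH[lig_idx, ] <- d_eps_h %*% t(P$out_W)
  dX <- matrix(0, n, 3)
  dX[lig_idx, ] <- d_eps_x   # eps_x = x_final - x_input on ligand rows

  for (l in rev(seq_len(model$config$n_layers))) {
    nm <- c("We1", "be1", "We2", "be2", "Wa", "ba", "Wh1", "bh1",
            "Wh2", "bh2", "Wr1", "br1", "Wr2", "br2")
    Pl <- P[paste0("l", l, "_", nm)]
    names(Pl) <- nm
    bk <- layer_backward(fwd$cache$layers[[l]], graph, Pl, lig_idx, dX, dH)
    dX <- bk$dX; dH <- bk$dH
    for (k in nm) grads[[paste0("l", l, "_", k)]] <- bk$grads[[k]]
  }

  grads$emb_W <- crossprod(graph$h, dH)
  grads$emb_b <- colSums(dH)
  grads
}
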