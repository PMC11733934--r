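# EGNN denoiser: edges, equivariance, permutation, gradients, sensitivity.

toy_graph <- function(seed = 3, t_frac = 0.5, n_hb = 2) {
  prep <- prepared_toy(seed = seed, n_hb = n_hb)
  tns <- complex_tensors(prep)
  conditioned_graph(tns$lig_x, tns$lig_h, tns$pocket, tns$particles, t_frac)
}

test_that("edge building straddles the cutoff and matches brute force", {
  two <- rbind(c(0, 0, 0), c(4.9, 0, 0))
  expect_equal(nrow(build_edges(two, 5)), 1)
  two[2, 1] <- 5.1
  expect_equal(nrow(build_edges(two, 5)), 0)
  # n = 8 nodes all mutually close: complete graph
  set.seed(1)
  cl <- matrix(rnorm(24, sd = 0.5), 8, 3)
  expect_equal(nrow(build_edges(cl, 5)), 28)
  # random 50-node cloud vs O(n^2) oracle
  pts <- matrix(runif(150, 0, 12), 50, 3)
  e <- build_edges(pts, 5)
  n_oracle <- 0
  for (i in 1:49) for (j in (i + 1):50) {
    if (sqrt(sum((pts[i, ] - pts[j, ])^2)) < 5) n_oracle <- n_oracle + 1
  }
  expect_equal(nrow(e), n_oracle)
  # doubling the cutoff can only add edges
  e2 <- build_edges(pts, 10)
  expect_true(all(paste(e$i, e$j) %in% paste(e2$i, e2$j)))
})

test_that("conditioned graph has exactly one active one-hot block per node", {
  g <- toy_graph()
  vocab <- length(default_element_vocab())
  blocks <- cbind(rowSums(abs(g$h[, 1:vocab])) > 0,
                  rowSums(g$h[, vocab + 1:21]) > 0,
                  rowSums(g$h[, vocab + 22:23]) > 0)
  expect_equal(rowSums(blocks), rep(1, nrow(g$h)))
  expect_equal(unname(blocks[cbind(seq_len(nrow(g$h)), g$kind)]),
               rep(TRUE, nrow(g$h)))
  # symmetric directed edges, no self loops
  expect_true(all(g$edges[, 1] != g$edges[, 2]))
  expect_setequal(paste(g$edges[, 1], g$edges[, 2]),
                  paste(g$edges[, 2], g$edges[, 1]))
  expect_equal(g$h[, ncol(g$h)], rep(0.5, nrow(g$h)))
})

test_that("zero coordinate gate leaves positions unchanged", {
  g <- toy_graph()
  model <- egnn_init(n_layers = 2, hidden = 16, seed = 5, zero_final = FALSE)
  for (l in 1:2) {
    model$params[[paste0("l", l, "_Wr2")]][] <- 0
    model$params[[paste0("l", l, "_br2")]][] <- 0
  }
  fwd <- predict_noise(g, model)
  expect_equal(fwd$eps_x, matrix(0, g$n_lig, 3), ignore_attr = TRUE)
})

test_that("single layer and full network are SE(3) equivariant", {
  set.seed(10)
  g <- toy_graph()
  model <- egnn_init(n_layers = 3, hidden = 24, seed = 8, zero_final = FALSE)
  base_layer <- egcl_forward(g, model, l = 1)
  base <- predict_noise(g, model)
  for (k in 1:20) {
    tf <- random_rigid_transform()
    g2 <- g
    g2$x <- apply_rigid(g$x, tf)
    l2 <- egcl_forward(g2, model, l = 1)
    expect_lt(max(abs(l2$x - apply_rigid(base_layer$x, tf))), 1e-8)
    expect_lt(max(abs(l2$h - base_layer$h)), 1e-8)
    f2 <- predict_noise(g2, model)
    expect_lt(max(abs(f2$eps_x - base$eps_x %*% t(tf$R))), 1e-8)
    expect_lt(max(abs(f2$eps_h - base$eps_h)), 1e-8)
  }
})

test_that("node permutation permutes outputs exactly", {
  prep <- prepared_toy(seed = 6, n_hb = 2)
  tns <- complex_tensors(prep)
  model <- egnn_init(n_layers = 2, hidden = 16, seed = 3, zero_final = FALSE)
  g <- conditioned_graph(tns$lig_x, tns$lig_h, tns$pocket, tns$particles, 0.3)
  base <- predict_noise(g, model)
  # permute the ligand nodes (kind blocks keep their internal layout)
  set.seed(2)
  p <- sample(g$n_lig)
  g2 <- conditioned_graph(tns$lig_x[p, ], tns$lig_h[p, ], tns$pocket,
                          tns$particles, 0.3)
  f2 <- predict_noise(g2, model)
  expect_equal(f2$eps_x, base$eps_x[p, ], tolerance = 1e-12)
  expect_equal(f2$eps_h, base$eps_h[p, ], tolerance = 1e-12)
})

test_that("condition nodes are bit-identical through the network", {
  g <- toy_graph()
  model <- egnn_init(n_layers = 2, hidden = 16, seed = 5, zero_final = FALSE)
  fwd <- predict_noise(g, model, keep_cache = TRUE)
  # recompute final positions: conditions must be untouched
  cond <- !g$lig_mask
  x_final <- g$x
  x_final[g$lig_mask, ] <- g$x[g$lig_mask, ] + fwd$eps_x
  expect_identical(g$x[cond, ], x_final[cond, ])
})

test_that("removing interaction particles changes the prediction", {
  prep <- prepared_toy(seed = 12, n_hb = 2)
  tns <- complex_tensors(prep)
  model <- egnn_init(n_layers = 2, hidden = 16, seed = 4, zero_final = FALSE)
  g_with <- conditioned_graph(tns$lig_x, tns$lig_h, tns$pocket,
                              tns$particles, 0.5)
  g_without <- conditioned_graph(tns$lig_x, tns$lig_h, tns$pocket,
                                 tns$particles[0, ], 0.5)
  f1 <- predict_noise(g_with, model)
  f2 <- predict_noise(g_without, model)
  expect_gt(max(abs(f1$eps_x - f2$eps_x)) + max(abs(f1$eps_h - f2$eps_h)),
            1e-6)
})

test_that("hand-written gradients match central finite differences", {
  prep <- prepared_toy(seed = 3, n_hb = 1, n_lig = 5, n_pocket = 4)
  tns <- complex_tensors(prep)
  sch <- build_noise_schedule(50)
  g <- conditioned_graph(tns$lig_x, tns$lig_h, tns$pocket, tns$particles, 0.4)
  model <- egnn_init(n_layers = 2, hidden = 8, seed = 7, zero_final = FALSE)
  for (pc in list(NULL, pocketdiff:::sched_at(sch, 20))) {
    fwd <- predict_noise(g, model, keep_cache = TRUE, precond = pc)
    set.seed(1)
    dex <- matrix(rnorm(length(fwd$eps_x)), nrow(fwd$eps_x))
    deh <- matrix(rnorm(length(fwd$eps_h)), nrow(fwd$eps_h))
    grads <- egnn_backward(g, model, fwd, dex, deh)
    lossfn <- function(m) {
      f <- predict_noise(g, m, precond = pc)
      sum(f$eps_x * dex) + sum(f$eps_h * deh)
    }
    eps <- 1e-6
    for (k in names(model$params)) {
      w <- model$params[[k]]
      idx <- seq_len(min(3, length(w)))
      for (i in idx) {
        mp <- model; mp$params[[k]][i] <- w[i] + eps
        mm <- model; mm$params[[k]][i] <- w[i] - eps
        fd <- (lossfn(mp) - lossfn(mm)) / (2 * eps)
        expect_lt(abs(fd - grads[[k]][i]) /
                    max(1e-6, abs(fd) + abs(grads[[k]][i])), 1e-4)
      }
    }
  }
})

test_that("gradient flows to every layer on a training step", {
  prep <- prepared_toy(seed = 5, n_hb = 1, n_lig = 6, n_pocket = 4)
  tns <- complex_tensors(prep)
  sch <- build_noise_schedule(50)
  model <- egnn_init(n_layers = 2, hidden = 8, seed = 2, zero_final = FALSE)
  set.seed(3)
  t <- 25
  fd_x <- forward_diffuse(tns$lig_x, t, sch)
  fd_h <- forward_diffuse(tns$lig_h, t, sch)
  g <- conditioned_graph(fd_x$z, fd_h$z, tns$pocket, tns$particles, t / 50)
  fwd <- predict_noise(g, model, keep_cache = TRUE,
                       precond = pocketdiff:::sched_at(sch, t))
  N <- length(fwd$eps_x) + length(fwd$eps_h)
  grads <- egnn_backward(g, model, fwd, (fwd$eps_x - fd_x$eps) / N,
                         (fwd$eps_h - fd_h$eps) / N)
  for (k in names(grads)) {
    expect_true(all(is.finite(grads[[k]])), info = k)
    expect_gt(max(abs(grads[[k]])), 0)
  }
})

test_that("checkpoints round-trip and mismatches fail loudly", {
  model <- egnn_init(n_layers = 2, hidden = 8, seed = 2)
  p <- tempfile(fileext = ".json")
  save_checkpoint(model, p)
  back <- load_checkpoint(p)
  expect_equal(back$params, model$params, tolerance = 1e-12)
  expect_equal(back$config$hidden, model$config$hidden)
  ck <- jsonlite::read_json(p, simplifyVector = TRUE)
  ck$params$emb_W$data <- ck$params$emb_W$data[-1]
  p2 <- tempfile(fileext = ".json")
  jsonlite::write_json(ck, p2, digits = NA, auto_unbox = TRUE)
  expect_error(load_checkpoint(p2), "mismatch")
  ck$format <- "other"
  jsonlite::write_json(ck, p2, digits = NA, auto_unbox = TRUE)
  expect_error(load_checkpoint(p2), "unrecognized")
})
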