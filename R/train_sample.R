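# Training loop, ligand-size sampler, reverse-diffusion generation and
# point-cloud -> molecule decoding.

#' Precompute the conditioned tensors of a prepared complex
#'
#' Translates the whole complex into the conditions-anchored frame: the
#' centroid of the fixed condition nodes (pocket C-alpha + interaction
#' particles) is moved to the origin. The ligand is diffused in this frame;
#' the anchor is stored so generated coordinates can be mapped back.
#'
#' @param record a prepared ComplexRecord (see [prepare_complex()])
#' @return list(lig_x, lig_h, pocket, particles, anchor, id)
#' @export
complex_tensors <- function(record) {
  if (is.null(record$pocket)) stop("complex not prepared: pocket missing")
  part_pos <- as.matrix(record$particles[, c("x", "y", "z"), drop = FALSE])
  cond <- rbind(record$pocket$pos, part_pos)
  anchor <- colMeans(cond)
  pocket <- record$pocket
  pocket$pos <- sweep(pocket$pos, 2, anchor, "-")
  particles <- record$particles
  if (nrow(particles)) {
    particles[, c("x", "y", "z")] <-
      sweep(part_pos, 2, anchor, "-")
  }
  list(lig_x = sweep(record$ligand$coords, 2, anchor, "-"),
       lig_h = record$ligand$onehot,
       pocket = pocket, particles = particles,
       anchor = anchor, id = record$id)
}

adam_init <- function(params) {
  list(m = lapply(params, function(w) w * 0),
       v = lapply(params, function(w) w * 0), t = 0L)
}

adam_update <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] - lr * (state$m[[k]] / bc1) /
      (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' One stochastic-gradient training step
#'
#' Per sample: t ~ Uniform\{1..T\}; the ligand coordinates and element
#' one-hots are forward-noised; the EGNN predicts the noise on the
#' conditioned graph; the loss is [simplified_loss()] pooled over
#' coordinates and features; parameters move by one Adam step.
#'
#' @param batch list of [complex_tensors()] objects
#' @param model egnn model
#' @param schedule NoiseSchedule
#' @param opt Adam state (from `adam_init(model$params)`)
#' @param lr learning rate (default 1e-3, the published setting)
#' @return list(model, opt, loss)
#' @export
training_step <- function(batch, model, schedule, opt, lr = 1e-3,
                          t_values = NULL) {
  stopifnot(length(batch) >= 1)
  if (!is.null(t_values)) stopifnot(length(t_values) == length(batch))
  total_grads <- lapply(model$params, function(w) w * 0)
  loss <- 0
  for (bi in seq_along(batch)) {
    tensors <- batch[[bi]]
    t <- if (is.null(t_values)) sample.int(schedule$T, 1) else t_values[bi]
    fd_x <- forward_diffuse(tensors$lig_x, t, schedule)
    fd_h <- forward_diffuse(tensors$lig_h, t, schedule)
    graph <- conditioned_graph(fd_x$z, fd_h$z, tensors$pocket,
                               tensors$particles, t / schedule$T,
                               model$config$cutoff)
    fwd <- predict_noise(graph, model, keep_cache = TRUE,
                         precond = sched_at(schedule, t))
    rx <- fwd$eps_x - fd_x$eps
    rh <- fwd$eps_h - fd_h$eps
    N <- length(rx) + length(rh)
    loss_i <- 0.5 * (sum(rx^2) + sum(rh^2)) / N
    if (!is.finite(loss_i)) {
      stop("non-finite loss at t=", t, " for complex ", tensors$id)
    }
    loss <- loss + loss_i
    g <- egnn_backward(graph, model, fwd, rx / N, rh / N)
    for (k in names(total_grads)) {
      total_grads[[k]] <- total_grads[[k]] + g[[k]]
    }
  }
  nb <- length(batch)
  loss <- loss / nb
  for (k in names(total_grads)) total_grads[[k]] <- total_grads[[k]] / nb
  upd <- adam_update(model$params, total_grads, opt, lr = lr)
  model$params <- upd$params
  list(model = model, opt = upd$state, loss = loss)
}

#' Train a model on a set of prepared complexes
#'
#' @param tensors_list list of [complex_tensors()] objects
#' @param model egnn model
#' @param schedule NoiseSchedule
#' @param steps number of optimizer steps
#' @param batch_size samples per step, drawn with replacement (a batch may
#'   revisit the same complex with independent time/noise draws)
#' @param lr peak learning rate
#' @param lr_schedule "constant", or "cosine" decay to lr/10 over the run
#'   (helps resolve the low-noise end of the diffusion time range)
#' @param seed integer seed fixing the whole trajectory
#' @param stratify_t draw the batch's diffusion steps stratified across
#'   \[1, T\] (variance reduction; the marginal distribution of t stays
#'   uniform)
#' @param verbose print the loss every `verbose` steps (0 = quiet)
#' @return list(model, losses)
#' @export
train_model <- function(tensors_list, model, schedule, steps = 500,
                        batch_size = 64, lr = 1e-3,
                        lr_schedule = c("constant", "cosine"), seed = NULL,
                        stratify_t = FALSE, verbose = 0) {
  lr_schedule <- match.arg(lr_schedule)
  opt <- adam_init(model$params)
  losses <- numeric(steps)
  with_seed(seed, {
    for (s in seq_len(steps)) {
      lr_s <- if (lr_schedule == "cosine") {
        lr / 10 + (lr - lr / 10) * (1 + cos(pi * (s - 1) / steps)) / 2
      } else lr
      idx <- sample.int(length(tensors_list), batch_size, replace = TRUE)
      tv <- if (stratify_t) {
        edges <- round(seq(0, schedule$T, length.out = batch_size + 1))
        pmin(schedule$T, pmax(1, edges[-(batch_size + 1)] +
          vapply(diff(edges), function(w) sample.int(max(w, 1), 1),
                 integer(1))))
      } else NULL
      st <- training_step(tensors_list[idx], model, schedule, opt, lr_s, tv)
      model <- st$model; opt <- st$opt; losses[s] <- st$loss
      if (verbose > 0 && s %% verbose == 0) {
        message(sprintf("step %d  loss %.5f", s, st$loss))
      }
    }
  })
  list(model = model, losses = losses)
}

#' Fit the ligand-size sampler
#'
#' Builds the joint histogram of (pocket node count, ligand atom count)
#' over the training pairs, blurs it with a separable Gaussian filter of
#' standard deviation `sigma` bins, and renormalizes each pocket-size row
#' into a conditional distribution P(n_ligand | n_pocket).
#'
#' @param pairs data.frame or 2-column matrix: n_pocket, n_ligand
#' @param sigma Gaussian smoothing sd in bins (0 = raw histogram)
#' @return SizeSampler: list(table, pocket_sizes, ligand_sizes, sigma)
#' @export
fit_size_distribution <- function(pairs, sigma = 1) {
  pairs <- as.matrix(pairs)
  if (!nrow(pairs)) stop("no (n_pocket, n_ligand) pairs supplied")
  spill <- if (sigma > 0) ceiling(4 * sigma) else 0
  prange <- range(pairs[, 1]); lrange <- range(pairs[, 2])
  psz <- seq(prange[1] - spill, prange[2] + spill)
  lsz <- seq(max(1, lrange[1] - spill), lrange[2] + spill)
  tab <- matrix(0, length(psz), length(lsz))
  for (r in seq_len(nrow(pairs))) {
    i <- match(pairs[r, 1], psz); j <- match(pairs[r, 2], lsz)
    tab[i, j] <- tab[i, j] + 1
  }
  if (sigma > 0) {
    rad <- ceiling(4 * sigma)
    k <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
    k <- k / sum(k)
    blur1d <- function(v) {
      n <- length(v)
      out <- numeric(n)
      for (i in seq_len(n)) {
        lo <- max(1, i - rad); hi <- min(n, i + rad)
        out[i] <- sum(v[lo:hi] * k[(lo - i + rad + 1):(hi - i + rad + 1)])
      }
      out
    }
    tab <- t(apply(tab, 1, blur1d))   # along ligand axis
    tab <- apply(tab, 2, blur1d)      # along pocket axis
    if (length(psz) == 1) tab <- matrix(tab, 1)
  }
  rs <- rowSums(tab)
  nz <- rs > 0
  tab[nz, ] <- tab[nz, , drop = FALSE] / rs[nz]
  structure(list(table = tab, pocket_sizes = psz, ligand_sizes = lsz,
                 sigma = sigma), class = "SizeSampler")
}

#' Draw a ligand size conditioned on the pocket size
#'
#' @param sampler a [fit_size_distribution()] object
#' @param n_pocket pocket node count; out-of-range values fall back to the
#'   nearest tabulated row with a warning
#' @param seed optional integer seed
#' @return integer ligand atom count
#' @export
sample_ligand_size <- function(sampler, n_pocket, seed = NULL) {
  rows_nz <- which(rowSums(sampler$table) > 0)
  i <- match(n_pocket, sampler$pocket_sizes)
  if (is.na(i) || !(i %in% rows_nz)) {
    i <- rows_nz[which.min(abs(sampler$pocket_sizes[rows_nz] - n_pocket))]
    warning("pocket size ", n_pocket, " outside fitted support; using row ",
            sampler$pocket_sizes[i])
  }
  p <- sampler$table[i, ]
  with_seed(seed, sampler$ligand_sizes[sample.int(length(p), 1, prob = p)])
}

#' Decode a generated point cloud into a molecule
#'
#' Element labels are the argmax of each atom's type vector (ties break to
#' the lowest vocabulary index). Bonds are inferred from a covalent-radius
#' distance window: atoms i, j bond (order 1) iff
#' 0.6 (r_i + r_j) <= d_ij <= r_i + r_j + 0.45 A. Atoms whose inferred
#' degree exceeds the element's typical max valence are flagged, never
#' dropped.
#'
#' @param coords n x 3 coordinate matrix (Angstrom)
#' @param type_onehots n x vocab score matrix
#' @param vocab element vocabulary
#' @param pocket_id,seed,T_steps provenance stored on the result
#' @return GeneratedLigand: list(coords, elements, bonds, flags, ...)
#' @export
decode_molecule <- function(coords, type_onehots, vocab = default_element_vocab(),
                            pocket_id = NA_character_, seed = NA_integer_,
                            T_steps = NA_integer_) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) >= 1, all(is.finite(coords)))
  idx <- max.col(as.matrix(type_onehots), ties.method = "first")
  elements <- vocab[idx]
  n <- nrow(coords)
  bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  if (n > 1) {
    d <- pairwise_dist(coords, coords)
    r <- COVALENT_RADII[elements]
    rsum <- outer(r, r, "+")
    hit <- which(upper.tri(d) & d >= 0.6 * rsum & d <= rsum + 0.45,
                 arr.ind = TRUE)
    if (nrow(hit)) {
      bonds <- data.frame(i = hit[, 1], j = hit[, 2], order = 1L)
    }
  }
  deg <- tabulate(c(bonds$i, bonds$j), nbins = n)
  overflow <- which(deg > MAX_VALENCE[elements])
  structure(list(coords = coords, elements = elements, bonds = bonds,
                 valence_overflow = overflow,
                 valid = length(overflow) == 0,
                 pocket_id = pocket_id, seed = seed, T_steps = T_steps),
            class = "GeneratedLigand")
}

#' Generate ligands in a pocket by reverse diffusion
#'
#' For each sample the ligand size is drawn from the size sampler (or
#' fixed via `n_atoms`), the ligand latent is initialized from a standard
#' normal in the conditions-anchored frame, and the reverse chain runs
#' T -> 0 with the pocket and interaction particles held fixed; the final
#' latent is decoded with [decode_molecule()]. The edge graph is rebuilt
#' from the current coordinates at every step. The last step adds no
#' noise. `particles` may be empty (generation without hydrogen-bond
#' guidance) or user-placed.
#'
#' @param pocket CalphaPocket
#' @param particles particle data.frame (zero rows allowed)
#' @param model trained egnn model
#' @param schedule NoiseSchedule
#' @param n_samples number of molecules
#' @param seed integer seed (fixes everything)
#' @param size_sampler optional [fit_size_distribution()] object
#' @param n_atoms fixed ligand size (used when no sampler is given)
#' @param vocab element vocabulary
#' @param noise optional recorded noise stream (list as returned in the
#'   `noise` attribute when `record_noise = TRUE`); replays the chain with
#'   externally transformed noise for the equivariance tests
#' @param record_noise attach every drawn noise matrix to the result
#' @param clamp_margin margin (Angstrom) added to the conditions' bounding
#'   radius to clamp the implied clean-coordinate prediction during the
#'   reverse chain (see [denoise_step()]); NULL disables clamping
#' @return list of GeneratedLigand (attribute "noise" when recording)
#' @export
generate <- function(pocket, particles, model, schedule, n_samples = 1,
                     seed = NULL, size_sampler = NULL, n_atoms = NULL,
                     vocab = default_element_vocab(), noise = NULL,
                     record_noise = FALSE, clamp_margin = 5) {
  if (is.null(size_sampler) && is.null(n_atoms)) {
    stop("supply either a size_sampler or a fixed n_atoms")
  }
  part_pos <- as.matrix(particles[, c("x", "y", "z"), drop = FALSE])
  cond <- rbind(pocket$pos, part_pos)
  anchor <- colMeans(cond)
  pocket_c <- pocket; pocket_c$pos <- sweep(pocket$pos, 2, anchor, "-")
  particles_c <- particles
  if (nrow(particles)) {
    particles_c[, c("x", "y", "z")] <- sweep(part_pos, 2, anchor, "-")
  }
  cond_c <- rbind(pocket_c$pos,
                  as.matrix(particles_c[, c("x", "y", "z"), drop = FALSE]))
  clamp_radius <- if (is.null(clamp_margin)) NULL else
    max(sqrt(rowSums(cond_c^2))) + clamp_margin
  vocab_dim <- model$config$vocab_dim
  recorded <- list()
  draw_ptr <- 0L
  draw <- function(nr, nc) {
    if (!is.null(noise)) {
      draw_ptr <<- draw_ptr + 1L
      return(noise[[draw_ptr]])
    }
    m <- matrix(rnorm(nr * nc), nr, nc)
    if (record_noise) recorded[[length(recorded) + 1L]] <<- m
    m
  }
  out <- with_seed(seed, {
    lapply(seq_len(n_samples), function(k) {
      n_lig <- if (!is.null(n_atoms)) n_atoms else
        sample_ligand_size(size_sampler, nrow(pocket$pos))
      z_x <- draw(n_lig, 3)
      z_h <- draw(n_lig, vocab_dim)
      for (t in seq(schedule$T, 1)) {
        s <- t - 1
        graph <- conditioned_graph(z_x, z_h, pocket_c, particles_c,
                                   t / schedule$T, model$config$cutoff)
        eh <- predict_noise(graph, model, precond = sched_at(schedule, t))
        nx <- if (s > 0) draw(n_lig, 3) else NULL
        nh <- if (s > 0) draw(n_lig, vocab_dim) else NULL
        z_x <- denoise_step(z_x, eh$eps_x, s, t, schedule, noise = nx,
                            clamp_radius = clamp_radius)
        z_h <- denoise_step(z_h, eh$eps_h, s, t, schedule, noise = nh)
      }
      decode_molecule(sweep(z_x, 2, anchor, "+"), z_h, vocab,
                      pocket_id = attr(pocket, "id") %||% NA_character_,
                      seed = if (is.null(seed)) NA_integer_ else seed,
                      T_steps = schedule$T)
    })
  })
  if (record_noise) attr(out, "noise") <- recorded
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a model checkpoint (versioned JSON)
#'
#' The checkpoint stores the model config and flat parameter arrays with
#' their dimensions; loading validates the format version and every
#' parameter shape and fails loudly on any mismatch.
#' @param model egnn model
#' @param path JSON file
#' @export
save_checkpoint <- function(model, path) {
  flat <- lapply(model$params, function(w) {
    list(dim = if (is.matrix(w)) dim(w) else length(w), data = as.numeric(w))
  })
  jsonlite::write_json(list(format = "pocketdiff-egnn", version = 1L,
                            config = model$config, params = flat),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(ck$format) || ck$format != "pocketdiff-egnn" ||
      is.na(ck$version) || ck$version != 1L) {
    stop("unrecognized checkpoint format in ", path)
  }
  cfg <- ck$config
  ref <- egnn_init(cfg$n_layers, cfg$hidden, cfg$vocab_dim,
                   cfg$edge_feat_dim, cfg$cutoff, seed = 1)
  params <- list()
  for (k in names(ref$params)) {
    entry <- ck$params[[k]]
    if (is.null(entry)) stop("checkpoint missing parameter ", k)
    w <- ref$params[[k]]
    if (is.matrix(w)) {
      if (length(entry$dim) != 2 || any(entry$dim != dim(w)) ||
          length(entry$data) != prod(entry$dim)) {
        stop("checkpoint shape mismatch for ", k)
      }
      params[[k]] <- matrix(entry$data, entry$dim[1], entry$dim[2])
    } else {
      if (length(entry$data) != length(w)) {
        stop("checkpoint shape mismatch for ", k)
      }
      params[[k]] <- entry$data
    }
  }
  structure(list(config = ref$config, params = params), class = "egnn_model")
}
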