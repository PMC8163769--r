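## Fitting the potential to time-series snapshots.
##
## The loss simulates a growth-weighted batch forward from each snapshot
## to the next with the model's Euler-Maruyama discretization, compares
## simulated and empirical populations with the Sinkhorn divergence
## (source masses = expected descendants), and adds the entropic
## regularizer tau * sum Psi(x_j) / sigma^2 over the final snapshot.
## Gradients flow through the drift at every simulation step via the
## hand-derived second-order reverse pass in potential.R.

#' Snapshot dataset: states with real-time labels and growth rates
#'
#' @param states n x k matrix of all cells' low-dimensional states.
#' @param time length-n vector of snapshot times (real units).
#' @param g optional length-n per-cell net growth rates (per real-time
#'   unit) used for transport weights and initialization sampling.
#' @return object of class `SnapshotDataset` with sorted unique `times`
#'   and per-snapshot row indices.
#' @export
snapshot_dataset <- function(states, time, g = NULL) {
  states <- as.matrix(states)
  if (length(time) != nrow(states)) stop("time length mismatch")
  if (!is.null(g) && length(g) != nrow(states)) stop("g length mismatch")
  times <- sort(unique(time))
  if (length(times) < 2) stop("need at least two snapshots")
  structure(list(states = states, time = time, g = g, times = times,
                 idx = lapply(times, function(tt) which(time == tt))),
            class = "SnapshotDataset")
}

#' @export
print.SnapshotDataset <- function(x, ...) {
  cat(sprintf("SnapshotDataset: %d cells, k = %d, %d snapshots (%s)\n",
              nrow(x$states), ncol(x$states), length(x$times),
              paste(x$times, collapse = ", ")))
  invisible(x)
}

snapshot_states <- function(ds, i) ds$states[ds$idx[[i]], , drop = FALSE]
snapshot_g <- function(ds, i) {
  if (is.null(ds$g)) rep(0, length(ds$idx[[i]])) else ds$g[ds$idx[[i]]]
}

#' Training configuration
#'
#' Defaults follow the reference optimization recipe: Adam with batches
#' of 1/10 of each snapshot, learning-rate decay 0.9 every 100 steps,
#' gradient clipping at max-norm 0.1, contrastive-divergence pretraining
#' at learning rate 1e-9, process constants sigma = dt = 0.1 and
#' tau = 1e-6, Sinkhorn blur 0.1 with annealing scaling 0.7.
#'
#' @param epochs training epochs.
#' @param batch_fraction fraction of each snapshot drawn per epoch.
#' @param lr initial Adam learning rate.
#' @param lr_decay,lr_decay_every multiplicative decay and its cadence
#'   (optimizer steps).
#' @param clip_norm gradient-clipping max norm.
#' @param pretrain_steps,pretrain_lr contrastive-divergence pretraining.
#' @param tau entropic regularizer strength.
#' @param sigma,dt process noise scale and step size.
#' @param blur,scaling Sinkhorn parameters.
#' @param sinkhorn_max_iter,sinkhorn_tol per-level iteration cap and
#'   marginal tolerance used inside the training loss. The transport
#'   value converges orders of magnitude faster than the marginals, so a
#'   small cap (multiscale-solver style) loses no loss accuracy; strict
#'   defaults remain in [sinkhorn_divergence()] for standalone use.
#' @param seed RNG seed governing batching and simulation noise.
#' @param eval_every checkpoint cadence in epochs.
#' @param square_loss if TRUE (default) the per-pair Sinkhorn divergence
#'   enters the loss squared.
#' @param use_growth_weights if TRUE source transport masses are the
#'   cells' expected descendant counts; FALSE gives uniform masses.
#' @param schedule `"pairwise"` (simulate each snapshot to the next) or
#'   `"chained"` (one simulation from the first snapshot through all).
#' @return list of class `TrainingConfig`.
#' @export
training_config <- function(epochs = 2500, batch_fraction = 0.1, lr = 0.01,
                            lr_decay = 0.9, lr_decay_every = 100,
                            clip_norm = 0.1, pretrain_steps = 100,
                            pretrain_lr = 1e-9, tau = 1e-6, sigma = 0.1,
                            dt = 0.1, blur = 0.1, scaling = 0.7,
                            sinkhorn_max_iter = 10, sinkhorn_tol = 1e-4,
                            seed = 1,
                            eval_every = 500, square_loss = TRUE,
                            use_growth_weights = TRUE,
                            schedule = c("pairwise", "chained")) {
  schedule <- match.arg(schedule)
  cfg <- list(epochs = epochs, batch_fraction = batch_fraction, lr = lr,
              lr_decay = lr_decay, lr_decay_every = lr_decay_every,
              clip_norm = clip_norm, pretrain_steps = pretrain_steps,
              pretrain_lr = pretrain_lr, tau = tau, sigma = sigma, dt = dt,
              blur = blur, scaling = scaling,
              sinkhorn_max_iter = sinkhorn_max_iter,
              sinkhorn_tol = sinkhorn_tol, seed = seed,
              eval_every = eval_every, square_loss = square_loss,
              use_growth_weights = use_growth_weights, schedule = schedule)
  stopifnot(cfg$epochs >= 0, cfg$batch_fraction > 0, cfg$batch_fraction <= 1,
            cfg$lr >= 0, cfg$dt > 0, cfg$sigma >= 0)
  if (cfg$sigma == 0 && cfg$tau > 0)
    stop("the entropic regularizer (tau > 0) requires sigma > 0")
  class(cfg) <- "TrainingConfig"
  cfg
}

# forward simulation storing the whole path (training internal; the
# noise stream is reproducible from `seed`)
sim_path <- function(params, X0, n_steps, dt, noise_sd, seed) {
  path <- vector("list", n_steps + 1)
  path[[1]] <- X0
  n <- nrow(X0); k <- ncol(X0)
  with_seed(seed, {
    for (s in seq_len(n_steps)) {
      X <- path[[s]]
      G <- mlp_input_grad_G(params, X)
      path[[s + 1]] <- X - G * dt + noise_sd * matrix(stats::rnorm(n * k), n, k)
      if (any(!is.finite(path[[s + 1]])))
        stop("non-finite states at training simulation step ", s)
    }
  })
  path
}

mlp_input_grad_G <- function(params, X) mlp_input_grad(params, X)$G

# reverse pass: given dL/dX_T, accumulate dL/dparams through the path
backprop_path <- function(params, path, dt, adj_final, grads) {
  adj <- adj_final
  for (s in rev(seq_len(length(path) - 1))) {
    cache <- mlp_input_grad(params, path[[s]])
    vjp <- mlp_grad_vjp(params, cache, -dt * adj)
    grads <- add_params(grads, vjp$grads)
    adj <- adj + vjp$X
  }
  list(grads = grads, adj0 = adj)
}

#' Training objective (loss and gradient)
#'
#' Assembles the full objective on given (optionally batched) snapshot
#' data: per consecutive snapshot pair, a growth-weighted simulated batch
#' is compared to the empirical next-snapshot batch by (squared) Sinkhorn
#' divergence; the entropic regularizer is evaluated on the final
#' snapshot batch.
#'
#' @param model potential_mlp model.
#' @param snapshots SnapshotDataset.
#' @param config TrainingConfig.
#' @param seed seed for the simulation noise of this evaluation.
#' @param batches optional list of per-snapshot row indices (within each
#'   snapshot) selecting the batch; default uses all cells.
#' @param grad if TRUE also return the parameter gradient.
#' @return list with `loss`, per-pair `pair_losses`, and `grads` when
#'   requested.
#' @export
objective <- function(model, snapshots, config = training_config(),
                      seed = 1, batches = NULL, grad = FALSE) {
  stopifnot(inherits(model, "potential_mlp"),
            inherits(snapshots, "SnapshotDataset"))
  if (length(snapshots$times) < 2) stop("need at least two snapshots")
  p <- model$params
  dt <- config$dt
  noise_sd <- sqrt(2 * config$sigma^2 * dt)
  nt <- length(snapshots$times)
  pick <- function(i) {
    full <- seq_along(snapshots$idx[[i]])
    if (is.null(batches)) full else batches[[i]]
  }
  grads <- if (grad) zero_like_params(p) else NULL
  pair_losses <- numeric(nt - 1)
  loss <- 0
  if (config$schedule == "pairwise") {
    for (i in seq_len(nt - 1)) {
      bi <- pick(i); bj <- pick(i + 1)
      X0 <- snapshot_states(snapshots, i)[bi, , drop = FALSE]
      Y <- snapshot_states(snapshots, i + 1)[bj, , drop = FALSE]
      dt_real <- snapshots$times[i + 1] - snapshots$times[i]
      n_steps <- real_time_to_steps(snapshots$times[i],
                                    snapshots$times[i + 1], dt)
      path <- sim_path(p, X0, n_steps, dt, noise_sd, seed + i)
      masses <- if (config$use_growth_weights)
        weighted_marginals_from_growth(
          descendants_from_growth(snapshot_g(snapshots, i)[bi], dt_real))
      else rep(1 / length(bi), length(bi))
      dv <- sinkhorn_divergence(
        weighted_cloud(path[[n_steps + 1]], masses), weighted_cloud(Y),
        blur = config$blur, scaling = config$scaling,
        tol = config$sinkhorn_tol, max_iter = config$sinkhorn_max_iter,
        grad = grad)
      pair_losses[i] <- if (config$square_loss) dv$value^2 else dv$value
      loss <- loss + pair_losses[i]
      if (grad) {
        scale <- if (config$square_loss) 2 * dv$value else 1
        bp <- backprop_path(p, path, dt, scale * dv$grad_source, grads)
        grads <- bp$grads
      }
    }
  } else {
    # chained: one simulation from the first snapshot through all times
    bi <- pick(1)
    X0 <- snapshot_states(snapshots, 1)[bi, , drop = FALSE]
    g0 <- snapshot_g(snapshots, 1)[bi]
    steps_to <- vapply(2:nt, function(i)
      real_time_to_steps(snapshots$times[1], snapshots$times[i], dt), 0L)
    path <- sim_path(p, X0, steps_to[nt - 1], dt, noise_sd, seed)
    adjoints <- vector("list", steps_to[nt - 1] + 1)
    for (i in 2:nt) {
      bj <- pick(i)
      Y <- snapshot_states(snapshots, i)[bj, , drop = FALSE]
      dt_real <- snapshots$times[i] - snapshots$times[1]
      masses <- if (config$use_growth_weights)
        weighted_marginals_from_growth(descendants_from_growth(g0, dt_real))
      else rep(1 / length(bi), length(bi))
      Xi <- path[[steps_to[i - 1] + 1]]
      dv <- sinkhorn_divergence(weighted_cloud(Xi, masses),
                                weighted_cloud(Y), blur = config$blur,
                                scaling = config$scaling,
                                tol = config$sinkhorn_tol,
                                max_iter = config$sinkhorn_max_iter,
                                grad = grad)
      pair_losses[i - 1] <- if (config$square_loss) dv$value^2 else dv$value
      loss <- loss + pair_losses[i - 1]
      if (grad) {
        scale <- if (config$square_loss) 2 * dv$value else 1
        adjoints[[steps_to[i - 1] + 1]] <- scale * dv$grad_source
      }
    }
    if (grad) {
      adj <- matrix(0, nrow(X0), ncol(X0))
      for (s in rev(seq_len(length(path) - 1))) {
        if (!is.null(adjoints[[s + 1]])) adj <- adj + adjoints[[s + 1]]
        cache <- mlp_input_grad(p, path[[s]])
        vjp <- mlp_grad_vjp(p, cache, -dt * adj)
        grads <- add_params(grads, vjp$grads)
        adj <- adj + vjp$X
      }
    }
  }
  # entropic regularizer on the final snapshot (steady-state assumption)
  bf <- pick(nt)
  Xf <- snapshot_states(snapshots, nt)[bf, , drop = FALSE]
  reg <- if (config$tau > 0)
    config$tau * sum(mlp_forward(p, Xf)$psi) / config$sigma^2 else 0
  loss <- loss + reg
  if (grad && config$tau > 0) {
    grads <- add_params(
      grads,
      mlp_param_grad(p, Xf, rep(config$tau / config$sigma^2, nrow(Xf))))
  }
  if (!is.finite(loss)) stop("non-finite training loss")
  out <- list(loss = loss, pair_losses = pair_losses, regularizer = reg)
  if (grad) out$grads <- grads
  out
}

#' Contrastive-divergence pretraining of the potential
#'
#' Initializes the potential so that `exp(-Psi(x)/sigma^2)` roughly
#' matches the density of the final snapshot before dynamic training:
#' each step lowers Psi at data samples and raises it at negative samples
#' produced by one Euler-Maruyama step from the data (CD-1 with a
#' Langevin-style proposal), by plain SGD.
#'
#' @param model potential_mlp.
#' @param final_snapshot n x k matrix of final-snapshot states.
#' @param steps number of SGD steps.
#' @param lr learning rate (default 1e-9, matching the reference recipe;
#'   small models benefit from larger values).
#' @param seed RNG seed.
#' @return the model with updated parameters.
#' @export
pretrain <- function(model, final_snapshot, steps, lr = 1e-9, seed = 1) {
  stopifnot(inherits(model, "potential_mlp"))
  X <- as_state_matrix(final_snapshot, model$k)
  if (!nrow(X)) stop("final snapshot is empty")
  p <- model$params
  noise_sd <- sqrt(2 * model$sigma^2 * model$dt)
  n <- nrow(X); k <- ncol(X)
  with_seed(seed, {
    for (s in seq_len(steps)) {
      G <- mlp_input_grad(p, X)$G
      Xneg <- X - G * model$dt + noise_sd * matrix(stats::rnorm(n * k), n, k)
      gpos <- mlp_param_grad(p, X, rep(1 / (n * model$sigma^2), n))
      gneg <- mlp_param_grad(p, Xneg, rep(1 / (n * model$sigma^2), n))
      g <- add_params(gpos, gneg, scale = -1)
      if (!is.finite(param_grad_norm(g))) stop("pretraining diverged")
      p <- add_params(p, g, scale = -lr)
    }
  })
  model$params <- p
  model
}

adam_init <- function(p) {
  list(m = zero_like_params(p), v = zero_like_params(p), t = 0)
}

adam_step <- function(p, g, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(p)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(p = p, state = state)
}

#' Train the potential on snapshot data
#'
#' Runs contrastive-divergence pretraining on the final snapshot, then
#' the main Adam loop with per-epoch random batches, learning-rate decay
#' and gradient clipping, checkpointing at the evaluation cadence.
#'
#' @param model potential_mlp (its sigma/dt/tau are overridden by the
#'   config for consistency).
#' @param snapshots SnapshotDataset (with per-cell growth rates when
#'   growth weighting is enabled).
#' @param config TrainingConfig.
#' @param checkpoint_dir optional directory for .rds checkpoints.
#' @param verbose print progress every 50 epochs.
#' @param resume optional TrainingState to continue from: optimizer
#'   state, learning rate and epoch counter are restored, and epochs
#'   `resume_epoch + 1 ... config$epochs` are run with the same per-epoch
#'   seed derivation, reproducing an uninterrupted run exactly.
#' @return object of class `TrainingState`: final `model`, `losses`
#'   (per epoch), `checkpoints` (list of parameter snapshots with epoch
#'   tags), `config`, optimizer state (for resuming).
#' @export
train_potential <- function(model, snapshots, config = training_config(),
                            checkpoint_dir = NULL, verbose = FALSE,
                            resume = NULL) {
  stopifnot(inherits(model, "potential_mlp"))
  model$sigma <- config$sigma; model$dt <- config$dt; model$tau <- config$tau
  if (is.null(resume) && config$pretrain_steps > 0) {
    nt <- length(snapshots$times)
    model <- pretrain(model, snapshot_states(snapshots, nt),
                      steps = config$pretrain_steps,
                      lr = config$pretrain_lr,
                      seed = derive_seed(config$seed, "pretrain"))
  }
  if (is.null(resume)) {
    p <- model$params
    opt <- adam_init(p)
    lr <- config$lr
    epoch_start <- 1L
    losses <- numeric(config$epochs)
    checkpoints <- list()
  } else {
    stopifnot(inherits(resume, "TrainingState"))
    p <- resume$model$params
    opt <- resume$opt
    lr <- resume$lr
    epoch_start <- length(resume$losses) + 1L
    losses <- c(resume$losses, numeric(config$epochs - length(resume$losses)))
    checkpoints <- resume$checkpoints
  }
  sizes <- vapply(snapshots$idx, length, 0L)
  bsizes <- pmax(1L, as.integer(ceiling(sizes * config$batch_fraction)))
  for (epoch in seq(epoch_start,
                    length.out = max(0L, config$epochs - epoch_start + 1L))) {
    batches <- with_seed(derive_seed(config$seed, paste0("batch", epoch)),
                         lapply(seq_along(sizes), function(i)
                           sample.int(sizes[i], bsizes[i])))
    model$params <- p
    ob <- objective(model, snapshots, config,
                    seed = derive_seed(config$seed, paste0("noise", epoch)),
                    batches = batches, grad = TRUE)
    g <- clip_params_norm(ob$grads, config$clip_norm)
    st <- adam_step(p, g, opt, lr)
    p <- st$p; opt <- st$state
    if (opt$t %% config$lr_decay_every == 0) lr <- lr * config$lr_decay
    losses[epoch] <- ob$loss
    if (verbose && epoch %% 50 == 0)
      message(sprintf("epoch %d loss %.5f lr %.2e", epoch, ob$loss, lr))
    if (epoch %% config$eval_every == 0 || epoch == config$epochs) {
      tag <- sprintf("epoch%05d", epoch)
      if (is.null(checkpoints[[tag]])) {
        checkpoints[[tag]] <- list(params = p, epoch = epoch,
                                   loss = ob$loss)
        if (!is.null(checkpoint_dir)) {
          model$params <- p
          save_checkpoint(model, file.path(checkpoint_dir,
                                           paste0(tag, ".rds")),
                          meta = list(epoch = epoch, loss = ob$loss,
                                      seed = config$seed))
        }
      }
    }
  }
  model$params <- p
  structure(list(model = model, losses = losses, checkpoints = checkpoints,
                 config = config, opt = opt, lr = lr),
            class = "TrainingState")
}

#' @export
print.TrainingState <- function(x, ...) {
  cat(sprintf("TrainingState: %d epochs, final loss %.5f, %d checkpoints\n",
              length(x$losses), utils::tail(x$losses, 1),
              length(x$checkpoints)))
  invisible(x)
}

#' Model from a training-state checkpoint
#' @param state TrainingState.
#' @param tag checkpoint name (default: last).
#' @return potential_mlp model with the checkpoint's parameters.
#' @export
checkpoint_model <- function(state, tag = NULL) {
  if (is.null(tag)) tag <- utils::tail(names(state$checkpoints), 1)
  m <- state$model
  m$params <- state$checkpoints[[tag]]$params
  m
}

#' Held-out time-point evaluation
#'
#' For each checkpoint: sample `n_sim` cells from the first snapshot with
#' replacement weighted by expected proliferation, simulate to the final
#' training time (training distance) and to the held-out time (testing
#' distance), and measure Sinkhorn divergences against the empirical
#' populations. The checkpoint with the lowest training distance is
#' selected and its testing distance reported, alongside the
#' transport-midpoint interpolation baseline between the flanking
#' snapshots.
#'
#' @param state TrainingState fit without the held-out snapshot.
#' @param full SnapshotDataset including the held-out snapshot.
#' @param held_out_time a time strictly between two training snapshots.
#' @param n_sim number of simulated cells (default 1000).
#' @param seed RNG seed.
#' @param blur,scaling Sinkhorn evaluation parameters.
#' @return list with `per_checkpoint` (data.frame of training/testing
#'   distances), `selected` (tag), `test_distance`, `baseline_distance`.
#' @export
evaluate_heldout <- function(state, full, held_out_time, n_sim = 1000,
                             seed = 1, blur = 0.1, scaling = 0.7,
                             max_iter = 50) {
  stopifnot(inherits(state, "TrainingState"),
            inherits(full, "SnapshotDataset"))
  times <- full$times
  hi <- match(held_out_time, times)
  if (is.na(hi) || hi == 1 || hi == length(times))
    stop("held_out_time must be an interior snapshot time")
  t0 <- times[1]; t_end <- times[length(times)]
  i0 <- 1
  X0 <- snapshot_states(full, i0)
  g0 <- snapshot_g(full, i0)
  w <- descendants_from_growth(g0, t_end - t0)
  Yh <- snapshot_states(full, hi)
  Ye <- snapshot_states(full, length(times))
  dist_to <- function(sim, Y) sinkhorn_divergence(
    weighted_cloud(sim), weighted_cloud(Y), blur = blur,
    scaling = scaling, max_iter = max_iter)$value
  rows <- lapply(names(state$checkpoints), function(tag) {
    m <- checkpoint_model(state, tag)
    init <- sample_initial(X0, weights = w, n_cells = n_sim,
                           seed = derive_seed(seed, paste0("init", tag)))
    n_h <- real_time_to_steps(t0, held_out_time, m$dt)
    n_e <- real_time_to_steps(t0, t_end, m$dt)
    traj <- simulate_diffusion(m, init$states, n_e, keep_path = TRUE,
                               seed = derive_seed(seed, paste0("sim", tag)))
    sim_h <- traj$states[n_h + 1, , ]
    data.frame(tag = tag,
               train_distance = dist_to(traj$final, Ye),
               test_distance = dist_to(sim_h, Yh))
  })
  per <- do.call(rbind, rows)
  sel <- per$tag[which.min(per$train_distance)]
  # midpoint interpolation baseline between the flanking snapshots
  src <- weighted_cloud(X0, descendants_from_growth(g0, t_end - t0))
  tgt <- weighted_cloud(Ye)
  pl <- sinkhorn_ot(src, tgt, blur = blur, scaling = scaling,
                    max_iter = max_iter)
  interp <- interpolate_midpoint(src, tgt, pl$plan, n_points = n_sim,
                                 seed = derive_seed(seed, "interp"))
  list(per_checkpoint = per, selected = sel,
       test_distance = per$test_distance[per$tag == sel],
       baseline_distance = dist_to(interp, Yh))
}
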