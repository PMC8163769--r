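# zero-drift model: near-zero weights so psi ~ const and drift ~ 0
flat_mlp <- function(k, sigma = 1e-9, tau = 0) {
  m <- potential_mlp(k = k, hidden = c(4, 4), seed = 1,
                     init_scale = 1e-9, sigma = sigma, tau = tau)
  m
}

test_that("objective floors at zero when simulation reproduces the data", {
  set.seed(1)
  X <- matrix(rnorm(40), 20, 2)
  # identical populations at both times, negligible noise and drift
  ds <- snapshot_dataset(rbind(X, X), rep(c(0, 1), each = 20))
  cfg <- training_config(sigma = 1e-9, tau = 0, dt = 0.1,
                         use_growth_weights = FALSE,
                         sinkhorn_tol = 1e-8, sinkhorn_max_iter = 500)
  ob <- objective(flat_mlp(2), ds, cfg, seed = 1)
  expect_lt(ob$loss, 1e-6)
})

test_that("objective matches the point-mass transport law for shifted clouds", {
  v <- c(1.5, -2)
  ds <- snapshot_dataset(rbind(c(0, 0), c(0, 0) + v), c(0, 1))
  cfg <- training_config(sigma = 1e-9, tau = 0, square_loss = FALSE,
                         use_growth_weights = FALSE,
                         sinkhorn_tol = 1e-8, sinkhorn_max_iter = 500)
  ob <- objective(flat_mlp(2), ds, cfg, seed = 1)
  expect_equal(ob$loss, sum(v^2), tolerance = 1e-4)
  # squared-loss flag squares the divergence
  cfg2 <- training_config(sigma = 1e-9, tau = 0, square_loss = TRUE,
                          use_growth_weights = FALSE,
                          sinkhorn_tol = 1e-8, sinkhorn_max_iter = 500)
  expect_equal(objective(flat_mlp(2), ds, cfg2, seed = 1)$loss,
               sum(v^2)^2, tolerance = 1e-3)
})

test_that("the entropic regularizer contributes tau * m * c / sigma^2 for constant psi", {
  set.seed(2)
  X <- matrix(rnorm(24), 12, 2)
  ds <- snapshot_dataset(rbind(X, X), rep(c(0, 1), each = 12))
  cc <- 3.7
  m <- flat_mlp(2)
  m$params$b3 <- cc   # psi identically cc, drift exactly 0
  cfg <- training_config(sigma = 0.5, tau = 0.01,
                         use_growth_weights = FALSE,
                         sinkhorn_tol = 1e-8, sinkhorn_max_iter = 500)
  # drift is ~0 but sigma = 0.5 adds noise; isolate the regularizer
  ob <- objective(m, ds, cfg, seed = 3)
  expect_equal(ob$regularizer, 0.01 * 12 * cc / 0.5^2, tolerance = 1e-9)
  # tau-term grows linearly in tau
  cfg2 <- training_config(sigma = 0.5, tau = 0.02,
                          use_growth_weights = FALSE,
                          sinkhorn_tol = 1e-8, sinkhorn_max_iter = 500)
  expect_equal(objective(m, ds, cfg2, seed = 3)$regularizer,
               2 * ob$regularizer, tolerance = 1e-9)
})

test_that("objective gradient matches finite differences through the simulation", {
  set.seed(4)
  ds <- snapshot_dataset(matrix(rnorm(24), 12, 2),
                         rep(c(0, 0.2), each = 6),
                         g = runif(12, -0.5, 0.5))
  m <- potential_mlp(k = 2, hidden = c(4, 3), seed = 5, init_scale = 0.5)
  cfg <- training_config(sigma = 0.05, tau = 1e-3, dt = 0.1,
                         use_growth_weights = TRUE,
                         sinkhorn_tol = 1e-12, sinkhorn_max_iter = 500)
  ob <- objective(m, ds, cfg, seed = 6, grad = TRUE)
  v0 <- fateflow:::flatten_params(m$params)
  ga <- fateflow:::flatten_params(ob$grads)
  f <- function(v) {
    mm <- m
    mm$params <- fateflow:::unflatten_params(v, m$params)
    objective(mm, ds, cfg, seed = 6)$loss
  }
  h <- 1e-5
  idx <- seq(1, length(v0), length.out = 15)  # spot-check a spread of params
  for (i in round(idx)) {
    vp <- v0; vp[i] <- vp[i] + h
    vm <- v0; vm[i] <- vm[i] - h
    fd <- (f(vp) - f(vm)) / (2 * h)
    # envelope gradients carry a small fixed-point error on tiny
    # components; require 0.5% relative with a 0.01 magnitude floor
    expect_lt(abs(ga[i] - fd), 5e-3 * max(abs(fd), 0.01))
  }
})

test_that("chained schedule agrees with pairwise on a two-snapshot dataset", {
  set.seed(12)
  ds <- snapshot_dataset(matrix(rnorm(32), 16, 2),
                         rep(c(0, 0.3), each = 8))
  m <- potential_mlp(k = 2, hidden = c(4, 4), seed = 2, init_scale = 0.3)
  base <- list(sigma = 0, tau = 0, use_growth_weights = FALSE,
               sinkhorn_tol = 1e-8, sinkhorn_max_iter = 500)
  ob_p <- objective(m, ds, do.call(training_config,
                                   c(base, schedule = "pairwise")), seed = 3)
  ob_c <- objective(m, ds, do.call(training_config,
                                   c(base, schedule = "chained")), seed = 3)
  # with a single pair and no noise the two schedules coincide exactly
  expect_equal(ob_p$pair_losses, ob_c$pair_losses, tolerance = 1e-9)
  expect_equal(ob_p$loss, ob_c$loss, tolerance = 1e-9)
})

test_that("pretraining is a seeded no-op at zero steps and lowers psi on data", {
  m <- potential_mlp(k = 2, hidden = c(16, 16), seed = 3)
  set.seed(7)
  X <- matrix(rnorm(400, sd = 0.5), 200, 2) + 2   # off-center Gaussian
  m0 <- pretrain(m, X, steps = 0, lr = 1e-3, seed = 1)
  expect_identical(m0$params, m$params)
  m1 <- pretrain(m, X, steps = 200, lr = 1e-2, seed = 1)
  m1b <- pretrain(m, X, steps = 200, lr = 1e-2, seed = 1)
  expect_identical(m1$params, m1b$params)
  # after pretraining, data sit lower on the potential than background
  set.seed(8)
  bg <- cbind(runif(400, min(X[, 1]), max(X[, 1])),
              runif(400, min(X[, 2]), max(X[, 2])))
  held <- matrix(rnorm(200, sd = 0.5), 100, 2) + 2
  gap0 <- mean(potential(m, bg)) - mean(potential(m, held))
  gap1 <- mean(potential(m1, bg)) - mean(potential(m1, held))
  expect_gt(gap1, gap0)
  expect_gt(gap1, 0)
})

test_that("training with zero learning rate leaves parameters untouched", {
  set.seed(9)
  X <- matrix(rnorm(60), 30, 2)
  ds <- snapshot_dataset(rbind(X, X + 0.3), rep(c(0, 0.5), each = 30))
  m <- potential_mlp(k = 2, hidden = c(8, 8), seed = 4)
  cfg <- training_config(epochs = 5, lr = 0, pretrain_steps = 0,
                         batch_fraction = 1, sigma = 0, tau = 0,
                         use_growth_weights = FALSE, eval_every = 5,
                         seed = 2)
  st <- train_potential(m, ds, cfg)
  expect_equal(st$model$params, m$params, tolerance = 1e-12)
  # deterministic full-batch sigma = 0 evaluation: losses constant
  expect_equal(diff(range(st$losses)), 0, tolerance = 1e-9)
})

test_that("training loss on linear-drift data halves within 200 epochs", {
  # data generated by the exact discretization of a quadratic potential
  truth <- potential_quadratic(k = 2, sigma = 0.15, dt = 0.1)
  set.seed(10)
  X0 <- matrix(rnorm(400, sd = 1.2), 200, 2)
  X1 <- final_states(simulate_diffusion(truth, X0, 10, seed = 11))
  ds <- snapshot_dataset(rbind(X0, X1), rep(c(0, 1), each = 200))
  m <- potential_mlp(k = 2, hidden = c(32, 32), seed = 5)
  cfg <- training_config(epochs = 200, lr = 0.01, batch_fraction = 0.25,
                         pretrain_steps = 25, pretrain_lr = 1e-3,
                         use_growth_weights = FALSE, eval_every = 100,
                         seed = 3)
  st <- train_potential(m, ds, cfg)
  early <- mean(st$losses[1:10])
  late <- mean(utils::tail(st$losses, 10))
  expect_lt(late, 0.5 * early)
})

test_that("resuming from a checkpoint reproduces uninterrupted training", {
  set.seed(11)
  X <- matrix(rnorm(80), 40, 2)
  ds <- snapshot_dataset(rbind(X, X + 0.2), rep(c(0, 0.3), each = 40))
  m <- potential_mlp(k = 2, hidden = c(6, 6), seed = 6)
  cfg_full <- training_config(epochs = 30, lr = 0.01, eval_every = 10,
                              pretrain_steps = 5, pretrain_lr = 1e-4,
                              use_growth_weights = FALSE, seed = 4)
  full <- train_potential(m, ds, cfg_full)
  cfg_half <- cfg_full; cfg_half$epochs <- 15
  half <- train_potential(m, ds, cfg_half)
  resumed <- train_potential(m, ds, cfg_full, resume = half)
  expect_equal(resumed$losses, full$losses, tolerance = 1e-12)
  expect_equal(resumed$model$params, full$model$params, tolerance = 1e-12)
})

test_that("held-out evaluation selects the argmin training checkpoint", {
  b <- ff_fixture_bundle()
  st <- ff_trained(1, heldout = TRUE)
  keep_ds <- snapshot_dataset(b$states, b$time, b$growth$g)
  ev <- evaluate_heldout(st, keep_ds, held_out_time = 1, n_sim = 300,
                         seed = 2)
  expect_equal(ev$selected,
               ev$per_checkpoint$tag[which.min(ev$per_checkpoint$train_distance)])
  expect_true(all(is.finite(ev$per_checkpoint$test_distance)))
  expect_gt(ev$baseline_distance, 0)
  expect_error(evaluate_heldout(st, keep_ds, held_out_time = 9),
               "interior")
})
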