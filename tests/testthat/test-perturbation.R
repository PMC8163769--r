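# small deterministic dataset for perturbation-machinery tests: gene "gx"
# drives state dimension 1, "gy" dimension 2, "konst" is flat
pert_world <- function(n = 60, seed = 5) {
  set.seed(seed)
  lat <- cbind(rnorm(n), rnorm(n))
  vals <- cbind(gx = 2 * lat[, 1] + rnorm(n, sd = 0.05),
                gy = 2 * lat[, 2] + rnorm(n, sd = 0.05),
                g3 = rnorm(n), konst = rep(4, n))
  rownames(vals) <- paste0("c", seq_len(n))
  expr <- toy_expression(vals, times = rep(0, n))
  prep <- preprocess_fit(expr, k = 2)
  ap <- preprocess_apply(expr, prep)
  list(expr = expr, prep = prep, scaled = ap$scaled, states = ap$states)
}

test_that("perturbation edits scaled values and shifts states linearly", {
  w <- pert_world()
  # no-op: editing a zero-variance gene to its scaled value 0
  noop <- apply_perturbation(w$scaled, "konst", 0, w$prep$pca)
  expect_equal(noop$states, project_states(w$scaled, w$prep$pca),
               tolerance = 1e-12)
  # single-gene edit shifts along the loading row, exactly
  z <- 3
  pert <- apply_perturbation(w$scaled, "gx", z, w$prep$pca)
  shift <- outer(z - w$scaled[, "gx"], w$prep$pca$loadings["gx", ])
  expect_equal(pert$states - project_states(w$scaled, w$prep$pca),
               shift, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(pert$scaled[, "gy"], w$scaled[, "gy"])
  expect_error(apply_perturbation(w$scaled, "nope", 1, w$prep$pca),
               "unknown gene")
})

test_that("the z ladder displaces states monotonically along the loading", {
  w <- pert_world()
  ladder <- c(-2.5, -1, -0.5, 2, 5, 10)
  load_gx <- w$prep$pca$loadings["gx", ]
  base <- project_states(w$scaled, w$prep$pca)
  proj <- sapply(ladder, function(z) {
    st <- apply_perturbation(w$scaled, "gx", z, w$prep$pca)$states
    mean((st - base) %*% load_gx)
  })
  expect_true(all(diff(proj) > 0))
})

test_that("paired simulations with shared seeds isolate the perturbation", {
  w <- pert_world()
  q <- potential_quadratic(k = 2, sigma = 0.1, dt = 0.1)
  set.seed(6)
  ref <- rbind(cbind(rnorm(60, -2, 0.3), rnorm(60, 0, 0.3)),
               cbind(rnorm(60, 2, 0.3), rnorm(60, 0, 0.3)))
  clf <- fit_fate_classifier(ref, rep(c("neg", "pos"), each = 60), k = 10)
  spec <- perturbation_spec("konst", 0, time = 0, n_cells = 30,
                            n_reps = 4, seed = 11)
  res <- run_perturbation(q, spec, w$scaled, w$expr$meta, w$prep$pca,
                          clf, t_final = 1)
  # no-op perturbation: every paired fraction difference is exactly zero
  wide <- reshape(res, idvar = c("rep", "fate"), timevar = "arm",
                  direction = "wide", drop = c("gene", "z"))
  expect_identical(wide$fraction.perturbed, wide$fraction.unperturbed)
  # permuting cells has no effect under shared seeds: rerun is identical
  res2 <- run_perturbation(q, spec, w$scaled, w$expr$meta, w$prep$pca,
                           clf, t_final = 1)
  expect_identical(res$fraction, res2$fraction)
})

test_that("perturbing the basin-axis gene shifts fate monotonically in z", {
  w <- pert_world(n = 80)
  # fine step: explicit Euler needs dt << 1/|psi''| out at the large
  # displacements the z = 10 dose produces on the cubic drift
  well <- potential_analytic(
    psi_fn = function(x) (x[, 1]^2 - 1)^2 / 4 + x[, 2]^2 / 2,
    drift_fn = function(x) cbind(x[, 1] - x[, 1]^3, -x[, 2]),
    k = 2, sigma = 0.1, dt = 0.005)
  set.seed(7)
  ref <- rbind(cbind(rnorm(80, -1, 0.2), rnorm(80, 0, 0.2)),
               cbind(rnorm(80, 1, 0.2), rnorm(80, 0, 0.2)))
  clf <- fit_fate_classifier(ref, rep(c("L", "R"), each = 80), k = 10)
  # axis-aligned projection: gx drives the fate axis (dim 1) exactly,
  # gy only the orthogonal dimension, so control-gene loadings on the
  # fate axis are exactly zero
  L <- matrix(0, 4, 2, dimnames = list(colnames(w$scaled), NULL))
  L["gx", 1] <- 1; L["gy", 2] <- 1
  proj <- structure(list(loadings = L, center = colMeans(w$scaled),
                         sdev = c(1, 1), k = 2,
                         genes = colnames(w$scaled)),
                    class = "PCAProjection")
  frac_R <- sapply(c(-2.5, -1, -0.5, 2, 5, 10), function(z) {
    spec <- perturbation_spec("gx", z, time = 0, n_cells = 60,
                              n_reps = 2, seed = 21)
    res <- run_perturbation(well, spec, w$scaled, w$expr$meta,
                            proj, clf, t_final = 3)
    mean(res$fraction[res$fate == "R" & res$arm == "perturbed"])
  })
  expect_true(all(diff(frac_R) >= 0))
  expect_gt(frac_R[6], frac_R[1])
  # control gene on the orthogonal axis leaves the x1 dynamics alone
  specc <- perturbation_spec("gy", 5, time = 0, n_cells = 60,
                             n_reps = 2, seed = 22)
  resc <- run_perturbation(well, specc, w$scaled, w$expr$meta,
                           proj, clf, t_final = 3)
  stc <- perturbation_stats(resc, "R", n_cells = 60)
  expect_lt(abs(stc$log2fc), 0.1)
})

test_that("perturbation statistics match hand-computed t-tests", {
  u <- c(0.30, 0.32, 0.29, 0.35, 0.31, 0.28, 0.33, 0.30, 0.34, 0.29)
  p <- c(0.41, 0.44, 0.38, 0.47, 0.40, 0.39, 0.45, 0.42, 0.46, 0.41)
  rows <- rbind(
    data.frame(gene = "g", z = 5, rep = 1:10, arm = "unperturbed",
               fate = "R", fraction = u),
    data.frame(gene = "g", z = 5, rep = 1:10, arm = "perturbed",
               fate = "R", fraction = p))
  st_w <- perturbation_stats(rows, "R", mode = "independent",
                             n_cells = 200)
  # Welch statistic by the direct formula
  tw <- (mean(p) - mean(u)) / sqrt(var(p) / 10 + var(u) / 10)
  expect_equal(st_w$t, tw, tolerance = 1e-12)
  dfw <- (var(p) / 10 + var(u) / 10)^2 /
    ((var(p) / 10)^2 / 9 + (var(u) / 10)^2 / 9)
  expect_equal(st_w$p_value, 2 * pt(-abs(tw), dfw), tolerance = 1e-12)
  expect_equal(st_w$log2fc, log2(mean(p) / mean(u)), tolerance = 1e-12)
  # paired mode
  st_p <- perturbation_stats(rows, "R", mode = "paired", n_cells = 200)
  d <- p - u
  tp <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(st_p$t, tp, tolerance = 1e-12)
  # identical arms: exact null
  rows0 <- rows; rows0$fraction <- rep(u, 2)
  st0 <- perturbation_stats(rows0, "R", n_cells = 200)
  expect_equal(st0$p_value, 1)
  expect_equal(st0$log2fc, 0)
  # exact doubling
  rows2 <- rows; rows2$fraction <- c(u, 2 * u)
  expect_equal(perturbation_stats(rows2, "R", n_cells = 200)$log2fc, 1)
})

test_that("hit calling applies BH and the conjunction rule", {
  set.seed(8)
  stats <- data.frame(gene = paste0("g", 1:201),
                      z = 5, mean_unperturbed = 0.3,
                      mean_perturbed = 0.3,
                      log2fc = c(2, rep(0.01, 200)),
                      t = 0,
                      p_value = c(1e-9, runif(200, 0.2, 1)))
  hits <- call_hits(stats)
  expect_equal(hits$q_value, p.adjust(stats$p_value, "BH"))
  expect_true(hits$hit[1])
  expect_equal(sum(hits$hit), 1)
  # tiny p but small effect is not a hit
  stats$log2fc[1] <- 0.2
  expect_equal(sum(call_hits(stats)$hit), 0)
  # global null
  stats$p_value <- rep(1, 201)
  expect_equal(sum(call_hits(stats)$hit), 0)
  stats$p_value[1] <- 2
  expect_error(call_hits(stats), "\\[0, 1\\]")
})

test_that("screens share the unperturbed arm and pair exactly", {
  w <- pert_world()
  q <- potential_quadratic(k = 2, sigma = 0.1, dt = 0.1)
  set.seed(9)
  ref <- rbind(cbind(rnorm(50, -2, 0.3), rnorm(50, 0, 0.3)),
               cbind(rnorm(50, 2, 0.3), rnorm(50, 0, 0.3)))
  clf <- fit_fate_classifier(ref, rep(c("neg", "pos"), each = 50), k = 10)
  res <- run_screen(q, genes = c("konst", "gx"), z_value = 0,
                    scaled = w$scaled, meta = w$expr$meta,
                    pca = w$prep$pca, clf = clf, time = 0, t_final = 1,
                    n_cells = 25, n_reps = 3, seed = 12)
  st <- screen_stats(res, "pos", n_cells = 25)
  # z = 0 on the flat gene is a perfect no-op against the shared arm
  expect_equal(st$p_value[st$gene == "konst"], 1)
  expect_equal(st$log2fc[st$gene == "konst"], 0)
  expect_equal(nrow(st), 2)
})

test_that("temporal perturbations report per-initialization differences", {
  w <- pert_world()
  # cells at two snapshot times
  w$expr$meta$time <- rep(c(0, 1), 30)
  q <- potential_quadratic(k = 2, sigma = 0.1, dt = 0.1)
  set.seed(10)
  ref <- rbind(cbind(rnorm(50, -2, 0.3), rnorm(50, 0, 0.3)),
               cbind(rnorm(50, 2, 0.3), rnorm(50, 0, 0.3)))
  clf <- fit_fate_classifier(ref, rep(c("neg", "pos"), each = 50), k = 10)
  tp <- temporal_perturbation(q, "konst", 0, times = c(0, 1),
                              scaled = w$scaled, meta = w$expr$meta,
                              pca = w$prep$pca, clf = clf, t_final = 2,
                              target_fate = "pos", n_cells = 20,
                              n_reps = 2, seed = 13)
  expect_equal(tp$difference, c(0, 0))
  expect_equal(tp$time, c(0, 1))
  expect_error(temporal_perturbation(q, "konst", 0, times = c(0, 2),
                                     scaled = w$scaled, meta = w$expr$meta,
                                     pca = w$prep$pca, clf = clf,
                                     t_final = 2, target_fate = "pos"),
               "precede")
})
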