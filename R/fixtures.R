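## Synthetic ground-truth benchmarks.
##
## Generates time-series snapshots from a landscape with a known
## potential: cells diffuse under the exact Euler-Maruyama discretization
## of the true SDE at a fine step size, divide with a region-dependent
## probability per step (so clone barcodes carry genuine growth signal),
## and are observed through a linear gene-loading map with Gaussian
## noise. Every downstream module is testable against the closed-form
## drift, the planted growth rates, the clone descendant counts and the
## terminal basin labels.

#' Define a landscape fixture
#'
#' The bistable form is the double-well `Psi(x) = a (x1^2 - 1)^2 / 4 +
#' sum(x_other^2) / 2`: a saddle at the origin and basins at x1 = -1
#' ("left") and x1 = +1 ("right"). The right basin proliferates faster;
#' `descendant_ratio` sets the expected right/left clone descendant ratio
#' over the whole time course. Gene loadings are linear: the first five
#' genes ("cyc*") load positively on the branch axis x1 and act as the
#' toy cell-cycle signature, the next five ("apo*") load negatively
#' (apoptosis signature), genes "ax1".."ax3" load strongly on x1 (planted
#' perturbation targets), and the remainder have random loadings.
#'
#' @param form `"bistable"` or `"quadratic"`.
#' @param n_genes total genes (>= 13; default 30).
#' @param snapshot_times observation times (default c(0, 1, 2)).
#' @param n_initial founding cells (one clone each; default 500).
#' @param n_per_snapshot cells emitted per snapshot (default 500).
#' @param sigma diffusion noise scale (default 0.1).
#' @param dt_fine simulation step (default 0.02).
#' @param a double-well depth parameter (default 1).
#' @param base_rate division rate of the slow (left) region per time unit.
#' @param descendant_ratio expected right/left descendant ratio over the
#'   time course (default 3).
#' @param noise_sd Gaussian observation noise on gene expression.
#' @param init_sd initial spread around the origin (length-2 recycled).
#' @param latent_extra additional isotropic OU latent dimensions beyond
#'   the 2-D landscape (default 0).
#' @param seed RNG seed; regeneration with the same seed is bit-identical.
#' @return list of class `LandscapeFixture`.
#' @export
landscape_fixture <- function(form = c("bistable", "quadratic"),
                              n_genes = 30, snapshot_times = c(0, 1, 2),
                              n_initial = 500, n_per_snapshot = 500,
                              sigma = 0.1, dt_fine = 0.02, a = 1,
                              base_rate = 0.25, descendant_ratio = 3,
                              noise_sd = 0.3, init_sd = c(0.15, 0.3),
                              latent_extra = 0, seed = 1) {
  form <- match.arg(form)
  if (length(snapshot_times) < 2) stop("need at least two snapshot times")
  if (n_genes < 13) stop("need at least 13 genes for the named sets")
  span <- max(snapshot_times) - min(snapshot_times)
  fast_rate <- base_rate + log(descendant_ratio) / span
  structure(list(form = form, n_genes = n_genes,
                 snapshot_times = sort(snapshot_times),
                 n_initial = n_initial, n_per_snapshot = n_per_snapshot,
                 sigma = sigma, dt_fine = dt_fine, a = a,
                 base_rate = base_rate, fast_rate = fast_rate,
                 descendant_ratio = descendant_ratio,
                 noise_sd = noise_sd,
                 init_sd = rep_len(init_sd, 2),
                 latent_extra = latent_extra, seed = seed),
            class = "LandscapeFixture")
}

#' Closed-form drift of a fixture's true potential
#'
#' @param fixture LandscapeFixture.
#' @param states n x d matrix of latent states (d = 2 + latent_extra).
#' @return n x d matrix of `-grad Psi_true`.
#' @export
true_drift <- function(fixture, states) {
  states <- as.matrix(states)
  d <- states
  if (fixture$form == "bistable") {
    d[, 1] <- -fixture$a * (states[, 1]^3 - states[, 1])
    d[, -1] <- -states[, -1, drop = FALSE]
  } else {
    d <- -states
  }
  d
}

#' Closed-form potential of a fixture
#' @param fixture LandscapeFixture.
#' @param states n x d matrix.
#' @return numeric vector of true potential values.
#' @export
true_potential <- function(fixture, states) {
  states <- as.matrix(states)
  if (fixture$form == "bistable") {
    fixture$a * (states[, 1]^2 - 1)^2 / 4 +
      rowSums(states[, -1, drop = FALSE]^2) / 2
  } else {
    rowSums(states^2) / 2
  }
}

# division rate field: fast region is x1 > 0
division_rate <- function(fixture, states) {
  ifelse(states[, 1] > 0, fixture$fast_rate, fixture$base_rate)
}

#' Generate the fixture dataset
#'
#' Simulates the branching diffusion and emits, per snapshot time, up to
#' `n_per_snapshot` cells (uniform subsample of the living population)
#' with expression `states %*% t(loadings) + noise`, clone barcodes and
#' metadata. Terminal-snapshot cells carry their basin as `cell_type`
#' ("left"/"right"); earlier cells are "progenitor".
#'
#' @param fixture LandscapeFixture.
#' @return list with:
#'   * `expr`: ExpressionMatrix (meta: time, clone_id, cell_type)
#'   * `truth`: list with `loadings` (genes x d), `latent` (emitted
#'     cells x d true states), `basin` (per emitted cell), `division_rate`
#'     (per emitted cell), `clone_fates` (per founding clone: terminal
#'     left/right descendant counts in the full population), `gene_sets`
#'     (cycle/apoptosis/axis), and the fixture itself.
#' @export
generate_fixture <- function(fixture) {
  stopifnot(inherits(fixture, "LandscapeFixture"))
  fx <- fixture
  d <- 2 + fx$latent_extra
  with_seed(fx$seed, {
    loadings <- build_loadings(fx, d)
    X <- cbind(stats::rnorm(fx$n_initial, 0, fx$init_sd[1]),
               stats::rnorm(fx$n_initial, 0, fx$init_sd[2]))
    if (fx$latent_extra > 0)
      X <- cbind(X, matrix(stats::rnorm(fx$n_initial * fx$latent_extra,
                                        0, fx$init_sd[2]),
                           fx$n_initial))
    clone <- seq_len(fx$n_initial)
    t_now <- fx$snapshot_times[1]
    noise_sd <- sqrt(2 * fx$sigma^2 * fx$dt_fine)
    emitted <- list()
    emit <- function(X, clone, tt) {
      n <- nrow(X)
      keep <- if (n > fx$n_per_snapshot)
        sort(sample.int(n, fx$n_per_snapshot)) else seq_len(n)
      list(states = X[keep, , drop = FALSE], clone = clone[keep],
           time = tt)
    }
    emitted[[1]] <- emit(X, clone, t_now)
    for (si in 2:length(fx$snapshot_times)) {
      t_target <- fx$snapshot_times[si]
      n_steps <- round((t_target - t_now) / fx$dt_fine)
      for (s in seq_len(n_steps)) {
        n <- nrow(X)
        X <- X + true_drift(fx, X) * fx$dt_fine +
          noise_sd * matrix(stats::rnorm(n * d), n, d)
        p_div <- pmin(division_rate(fx, X) * fx$dt_fine, 1)
        div <- stats::runif(n) < p_div
        if (any(div)) {
          X <- rbind(X, X[div, , drop = FALSE])
          clone <- c(clone, clone[div])
        }
      }
      t_now <- t_target
      emitted[[si]] <- emit(X, clone, t_now)
    }
    # full terminal population fate counts per founding clone
    basin_all <- ifelse(X[, 1] > 0, "right", "left")
    clone_fates <- data.frame(
      clone_id = seq_len(fx$n_initial),
      n_right = as.numeric(table(factor(clone[basin_all == "right"],
                                        levels = seq_len(fx$n_initial)))),
      n_left = as.numeric(table(factor(clone[basin_all == "left"],
                                       levels = seq_len(fx$n_initial)))))
    clone_fates$bias <- with(clone_fates,
                             (n_right + 1) / (n_right + n_left + 2))
    # assemble emitted cells
    states <- do.call(rbind, lapply(emitted, `[[`, "states"))
    times <- unlist(lapply(emitted, function(e) rep(e$time, nrow(e$states))))
    clones <- unlist(lapply(emitted, `[[`, "clone"))
    n_cells <- nrow(states)
    expr_vals <- states %*% t(loadings) +
      matrix(stats::rnorm(n_cells * fx$n_genes, 0, fx$noise_sd),
             n_cells, fx$n_genes)
    basin <- ifelse(states[, 1] > 0, "right", "left")
    terminal <- times == max(fx$snapshot_times)
    cell_type <- ifelse(terminal, basin, "progenitor")
    ids <- sprintf("t%g_c%05d", times, seq_len(n_cells))
    meta <- data.frame(time = times, clone_id = clones,
                       cell_type = cell_type)
    expr <- expression_matrix(expr_vals, rownames(loadings), ids, meta)
    gene_sets <- list(cycle = rownames(loadings)[1:5],
                      apoptosis = rownames(loadings)[6:10],
                      axis = rownames(loadings)[11:13])
    list(expr = expr,
         truth = list(loadings = loadings, latent = states,
                      basin = basin,
                      division_rate = division_rate(fx, states),
                      clone_fates = clone_fates, gene_sets = gene_sets,
                      fixture = fx))
  })
}

build_loadings <- function(fx, d) {
  n <- fx$n_genes
  L <- matrix(stats::rnorm(n * d, 0, 0.4), n, d)
  L[1:5, 1] <- 1 + stats::rnorm(5, 0, 0.1)      # cycle: + branch axis
  L[1:5, 2] <- stats::rnorm(5, 0, 0.1)
  L[6:10, 1] <- -1 + stats::rnorm(5, 0, 0.1)    # apoptosis: - branch axis
  L[6:10, 2] <- stats::rnorm(5, 0, 0.1)
  L[11:13, 1] <- 1.5 + stats::rnorm(3, 0, 0.1)  # planted targets
  L[11:13, 2] <- stats::rnorm(3, 0, 0.1)
  rn <- c(paste0("cyc", 1:5), paste0("apo", 1:5), paste0("ax", 1:3),
          paste0("g", seq_len(n - 13) + 13))
  rownames(L) <- rn
  if (qr(L)$rank < d) stop("degenerate loading matrix")
  L
}

#' Write fixture data in the standard input formats
#'
#' Emits the delimited expression matrix, the metadata table, and the toy
#' cycle/apoptosis/axis gene-set files into a directory, plus the
#' ground-truth clone fate table.
#'
#' @param fx_data result of [generate_fixture()].
#' @param dir output directory.
#' @export
write_fixture <- function(fx_data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_delim(fx_data$expr, file.path(dir, "expression.tsv"),
                         meta_file = file.path(dir, "metadata.tsv"))
  for (nm in names(fx_data$truth$gene_sets))
    writeLines(fx_data$truth$gene_sets[[nm]],
               file.path(dir, paste0("geneset_", nm, ".txt")))
  utils::write.table(fx_data$truth$clone_fates,
                     file.path(dir, "clone_fates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
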