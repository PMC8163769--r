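## In-silico perturbation screens: set target genes' scaled expression to
## a z-score, re-project through the fitted PCA, simulate paired
## perturbed/unperturbed populations with shared noise, and test fate
## fraction shifts.

#' Perturbation specification
#'
#' @param genes character vector of target genes.
#' @param z_value target z-score (negative = knockdown, positive =
#'   overexpression).
#' @param time initialization snapshot time (selector).
#' @param cell_type optional cell-type filter for the initial population.
#' @param n_cells cells sampled per repetition (default 200).
#' @param n_reps independent repetitions (default 10).
#' @param seed base RNG seed.
#' @return list of class `PerturbationSpec`.
#' @export
perturbation_spec <- function(genes, z_value, time, cell_type = NULL,
                              n_cells = 200, n_reps = 10, seed = 1) {
  stopifnot(length(genes) >= 1, n_cells >= 1, n_reps >= 1)
  structure(list(genes = genes, z_value = z_value, time = time,
                 cell_type = cell_type, n_cells = n_cells,
                 n_reps = n_reps, seed = seed),
            class = "PerturbationSpec")
}

#' Apply a perturbation in scaled gene space
#'
#' Sets the target genes' scaled (z-scored) values to `z_value`, leaving
#' all other genes untouched, and projects the edited profiles through
#' the fitted PCA. Because the projection is linear, the state shift is
#' exactly `sum_g (z - v_g) * loadings[g, ]` per cell.
#'
#' @param scaled cells x genes matrix of scaled expression.
#' @param genes target genes (must be present as columns).
#' @param z_value target z-score.
#' @param pca PCAProjection.
#' @return list with `scaled` (edited matrix) and `states` (projected).
#' @export
apply_perturbation <- function(scaled, genes, z_value, pca) {
  scaled <- as.matrix(scaled)
  miss <- setdiff(genes, colnames(scaled))
  if (length(miss)) stop("unknown genes: ", paste(miss, collapse = ", "))
  out <- scaled
  out[, genes] <- z_value
  list(scaled = out, states = project_states(out, pca))
}

select_population <- function(meta, time, cell_type = NULL) {
  sel <- meta$time == time
  if (!is.null(cell_type)) {
    if (!"cell_type" %in% names(meta)) stop("meta lacks cell_type")
    sel <- sel & meta$cell_type %in% cell_type
  }
  idx <- which(sel)
  if (!length(idx)) stop("empty selector population")
  idx
}

fate_fractions <- function(labels, classes) {
  cnt <- table(factor(labels, levels = classes))
  as.numeric(cnt) / length(labels)
}

#' Run a paired perturbed/unperturbed simulation experiment
#'
#' Per repetition: sample `n_cells` from the selector population weighted
#' by expected proliferation, simulate the same cells both unperturbed
#' and perturbed to the final time with a shared noise stream (so
#' fraction differences isolate the perturbation), classify terminal
#' states, and record per-fate fractions.
#'
#' @param model trained potential model.
#' @param spec PerturbationSpec.
#' @param scaled cells x genes scaled expression for the whole dataset.
#' @param meta per-cell metadata (time, optional cell_type).
#' @param pca fitted PCAProjection.
#' @param clf FateClassifier.
#' @param growth_n per-cell expected descendant counts (sampling
#'   weights); default uniform.
#' @param t_final final real time simulated to.
#' @return data.frame of class `ScreenResult`: one row per repetition x
#'   arm x fate with the terminal fraction.
#' @export
run_perturbation <- function(model, spec, scaled, meta, pca, clf,
                             growth_n = NULL, t_final) {
  stopifnot(inherits(spec, "PerturbationSpec"))
  pop <- select_population(meta, spec$time, spec$cell_type)
  if (is.null(growth_n)) growth_n <- rep(1, nrow(scaled))
  pert <- apply_perturbation(scaled, spec$genes, spec$z_value, pca)
  base_states <- project_states(scaled, pca)
  n_steps <- real_time_to_steps(spec$time, t_final, model$dt)
  rows <- list()
  for (r in seq_len(spec$n_reps)) {
    srep <- derive_seed(spec$seed, paste0("rep", r))
    draw <- sample_initial(base_states[pop, , drop = FALSE],
                           weights = growth_n[pop],
                           n_cells = spec$n_cells, seed = srep)
    idx <- pop[draw$index]
    sim_seed <- derive_seed(srep, "noise")
    lab_u <- classify_states(clf, final_states(
      simulate_diffusion(model, base_states[idx, , drop = FALSE],
                         n_steps, seed = sim_seed, keep_path = FALSE)))
    lab_p <- classify_states(clf, final_states(
      simulate_diffusion(model, pert$states[idx, , drop = FALSE],
                         n_steps, seed = sim_seed, keep_path = FALSE)))
    for (arm in c("unperturbed", "perturbed")) {
      fr <- fate_fractions(if (arm == "unperturbed") lab_u else lab_p,
                           clf$classes)
      rows[[length(rows) + 1]] <-
        data.frame(gene = paste(spec$genes, collapse = "+"),
                   z = spec$z_value, rep = r, arm = arm,
                   fate = clf$classes, fraction = fr)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ScreenResult", "data.frame")
  out
}

#' Test fate-fraction shifts between perturbed and unperturbed arms
#'
#' Two-sided t-tests on the target-fate fractions across repetitions:
#' Welch's independent test (`mode = "independent"`) or the paired test
#' used in large screens (`mode = "paired"`). The log2 fold-change is
#' `log2(mean perturbed / mean unperturbed)` with both means floored at
#' `1 / (n_cells * n_reps)` so all-zero fractions stay finite.
#'
#' @param result ScreenResult rows (possibly several genes/z values).
#' @param target_fate fate label tested.
#' @param mode `"independent"` (Welch) or `"paired"`.
#' @param n_cells cells per repetition (for the zero-fraction floor).
#' @return data.frame with one row per gene x z: means, log2FC, t
#'   statistic, p-value.
#' @export
perturbation_stats <- function(result, target_fate,
                               mode = c("independent", "paired"),
                               n_cells = 200) {
  mode <- match.arg(mode)
  d <- result[result$fate == target_fate, , drop = FALSE]
  if (!nrow(d)) stop("target fate not present in result")
  keys <- unique(d[, c("gene", "z")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    di <- d[d$gene == keys$gene[i] & d$z == keys$z[i], ]
    u <- di$fraction[di$arm == "unperturbed"][order(di$rep[di$arm == "unperturbed"])]
    p <- di$fraction[di$arm == "perturbed"][order(di$rep[di$arm == "perturbed"])]
    if (length(u) < 2) stop("need >= 2 repetitions")
    floor_ <- 1 / (n_cells * length(u))
    l2fc <- log2(max(mean(p), floor_) / max(mean(u), floor_))
    if (isTRUE(all.equal(u, p))) {
      tt <- list(statistic = 0, p.value = 1)   # identical arms: exact null
    } else {
      tt <- if (mode == "independent")
        stats::t.test(p, u, var.equal = FALSE)
      else stats::t.test(p - u)
    }
    data.frame(gene = keys$gene[i], z = keys$z[i],
               mean_unperturbed = mean(u), mean_perturbed = mean(p),
               log2fc = l2fc, t = unname(tt$statistic),
               p_value = unname(tt$p.value))
  })
  do.call(rbind, rows)
}

#' Call screen hits with FDR and effect-size thresholds
#'
#' Benjamini-Hochberg adjustment across all screened genes; a hit
#' requires `q < fdr_threshold` and `log2FC > lfc_threshold`.
#'
#' @param stats data.frame from [perturbation_stats()].
#' @param fdr_threshold default 0.01.
#' @param lfc_threshold default 0.5.
#' @return the table with added `q_value` and `hit` columns.
#' @export
call_hits <- function(stats, fdr_threshold = 0.01, lfc_threshold = 0.5) {
  if (any(stats$p_value < 0 | stats$p_value > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats$q_value <- stats::p.adjust(stats$p_value, method = "BH")
  stats$hit <- stats$q_value < fdr_threshold & stats$log2fc > lfc_threshold
  stats
}

#' Screen many genes with a shared unperturbed arm
#'
#' For each repetition the same sampled cells and noise stream are reused
#' across all genes (and for the single unperturbed arm), so per-gene
#' differences are paired and comparable.
#'
#' @param model trained potential model.
#' @param genes character vector of genes to screen.
#' @param z_value perturbation z-score (default 5).
#' @inheritParams run_perturbation
#' @param time initialization snapshot time.
#' @param cell_type optional subpopulation filter.
#' @param n_cells,n_reps,seed experiment size.
#' @return ScreenResult data.frame covering all genes plus an
#'   `"unperturbed"` pseudo-gene row set per repetition.
#' @export
run_screen <- function(model, genes, z_value = 5, scaled, meta, pca, clf,
                       growth_n = NULL, time, cell_type = NULL, t_final,
                       n_cells = 200, n_reps = 10, seed = 1) {
  pop <- select_population(meta, time, cell_type)
  if (is.null(growth_n)) growth_n <- rep(1, nrow(scaled))
  base_states <- project_states(scaled, pca)
  n_steps <- real_time_to_steps(time, t_final, model$dt)
  rows <- list()
  for (r in seq_len(n_reps)) {
    srep <- derive_seed(seed, paste0("rep", r))
    draw <- sample_initial(base_states[pop, , drop = FALSE],
                           weights = growth_n[pop], n_cells = n_cells,
                           seed = srep)
    idx <- pop[draw$index]
    sim_seed <- derive_seed(srep, "noise")
    frac_of <- function(states) fate_fractions(
      classify_states(clf, final_states(
        simulate_diffusion(model, states, n_steps, seed = sim_seed,
                           keep_path = FALSE))), clf$classes)
    fr_u <- frac_of(base_states[idx, , drop = FALSE])
    rows[[length(rows) + 1]] <- data.frame(
      gene = "unperturbed", z = 0, rep = r, arm = "unperturbed",
      fate = clf$classes, fraction = fr_u)
    for (gn in genes) {
      pert <- apply_perturbation(scaled[idx, , drop = FALSE], gn,
                                 z_value, pca)
      rows[[length(rows) + 1]] <- data.frame(
        gene = gn, z = z_value, rep = r, arm = "perturbed",
        fate = clf$classes, fraction = frac_of(pert$states))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ScreenResult", "data.frame")
  out
}

#' Paired screen statistics against the shared unperturbed arm
#'
#' @param screen ScreenResult from [run_screen()].
#' @param target_fate fate label tested.
#' @param n_cells cells per repetition.
#' @return per-gene paired t statistics and log2FC (see
#'   [perturbation_stats()]).
#' @export
screen_stats <- function(screen, target_fate, n_cells = 200) {
  d <- screen[screen$fate == target_fate, , drop = FALSE]
  u <- d[d$gene == "unperturbed", ]
  u <- u$fraction[order(u$rep)]
  genes <- setdiff(unique(d$gene), "unperturbed")
  rows <- lapply(genes, function(gn) {
    di <- d[d$gene == gn, ]
    p <- di$fraction[order(di$rep)]
    floor_ <- 1 / (n_cells * length(u))
    l2fc <- log2(max(mean(p), floor_) / max(mean(u), floor_))
    if (isTRUE(all.equal(u, p))) {
      tt <- list(statistic = 0, p.value = 1)
    } else tt <- stats::t.test(p - u)
    data.frame(gene = gn, z = di$z[1], mean_unperturbed = mean(u),
               mean_perturbed = mean(p), log2fc = l2fc,
               t = unname(tt$statistic), p_value = unname(tt$p.value))
  })
  do.call(rbind, rows)
}

#' Perturbation introduced at successive timepoints
#'
#' Repeats a paired perturbation experiment with initialization at each
#' given snapshot time (all simulated to the same final time) and
#' reports the perturbed-minus-unperturbed difference in the target-fate
#' fraction, the signature of when a fate decision is made.
#'
#' @param model trained potential model.
#' @param genes,z_value perturbation definition.
#' @param times initialization snapshot times (each < t_final).
#' @inheritParams run_perturbation
#' @param target_fate fate whose fraction difference is reported.
#' @param n_cells,n_reps,seed experiment size.
#' @return data.frame with one row per initialization time: mean
#'   fractions per arm and their difference.
#' @export
temporal_perturbation <- function(model, genes, z_value, times, scaled,
                                  meta, pca, clf, growth_n = NULL,
                                  t_final, target_fate, n_cells = 200,
                                  n_reps = 10, seed = 1) {
  if (any(times >= t_final)) stop("initialization times must precede t_final")
  rows <- lapply(times, function(tt) {
    spec <- perturbation_spec(genes, z_value, time = tt,
                              n_cells = n_cells, n_reps = n_reps,
                              seed = derive_seed(seed, paste0("t", tt)))
    res <- run_perturbation(model, spec, scaled, meta, pca, clf,
                            growth_n = growth_n, t_final = t_final)
    d <- res[res$fate == target_fate, ]
    mu_u <- mean(d$fraction[d$arm == "unperturbed"])
    mu_p <- mean(d$fraction[d$arm == "perturbed"])
    data.frame(time = tt, mean_unperturbed = mu_u, mean_perturbed = mu_p,
               difference = mu_p - mu_u)
  })
  do.call(rbind, rows)
}

#' Read / write perturbation specs as key-value text
#'
#' Format: YAML with fields `genes`, `z_value`, `time`, optional
#' `cell_type`, `n_cells`, `n_reps`, `seed`.
#'
#' @param file path.
#' @return PerturbationSpec.
#' @export
read_perturbation_spec <- function(file) {
  y <- yaml::read_yaml(file)
  perturbation_spec(genes = as.character(y$genes), z_value = y$z_value,
                    time = y$time, cell_type = y$cell_type,
                    n_cells = y$n_cells %||% 200,
                    n_reps = y$n_reps %||% 10, seed = y$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_perturbation_spec
#' @param spec PerturbationSpec to write.
#' @export
write_perturbation_spec <- function(spec, file) {
  yaml::write_yaml(unclass(spec), file)
  invisible(file)
}
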