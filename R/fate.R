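## Clonal fate-bias prediction: simulate trajectory ensembles per initial
## cell, classify terminal states with a k-NN cell-type classifier, and
## score predictions against lineage-tracing ground truth.

#' Fit a k-nearest-neighbor terminal-fate classifier
#'
#' Majority vote over the k nearest reference cells by Euclidean distance
#' in PCA space. The default backend is a kd-tree (RANN); `exact = TRUE`
#' uses brute-force search with deterministic index-order tie-breaking
#' and serves as the reference implementation.
#'
#' @param reference n x k matrix of reference states.
#' @param labels character/factor of reference cell-type labels.
#' @param k neighbor count (default 20).
#' @param exact use exact brute-force neighbor search.
#' @return object of class `FateClassifier`.
#' @export
fit_fate_classifier <- function(reference, labels, k = 20, exact = FALSE) {
  reference <- as.matrix(reference)
  if (!nrow(reference)) stop("empty reference")
  if (nrow(reference) < k) stop("need at least k reference points")
  labels <- as.character(labels)
  if (length(labels) != nrow(reference)) stop("labels length mismatch")
  structure(list(reference = reference, labels = labels, k = k,
                 classes = sort(unique(labels)), exact = exact),
            class = "FateClassifier")
}

#' Classify states by k-NN majority vote
#'
#' Vote ties are broken deterministically by label (lexicographic) order.
#'
#' @param clf FateClassifier.
#' @param states m x k matrix of query states.
#' @return character vector of predicted labels.
#' @export
classify_states <- function(clf, states) {
  stopifnot(inherits(clf, "FateClassifier"))
  states <- as.matrix(states)
  if (ncol(states) != ncol(clf$reference)) stop("state dimension mismatch")
  idx <- if (clf$exact) knn_index(clf$reference, states, clf$k)
  else RANN::nn2(clf$reference, states, k = clf$k)$nn.idx
  apply(idx, 1, function(nb) {
    cnt <- table(factor(clf$labels[nb], levels = clf$classes))
    names(cnt)[which.max(cnt)]   # ties -> first label in sorted order
  })
}

#' Clonal fate bias with pseudocount
#'
#' `bias = (counts_A + pseudocount) / (counts_A + counts_B +
#' 2 * pseudocount)`: the fraction of trajectories reaching fate A among
#' those reaching either target fate, regularized so that a clone with no
#' cell classified as either fate gets bias 0.5.
#'
#' @param counts_A,counts_B nonnegative terminal counts of the two target
#'   fates (e.g. neutrophil and monocyte).
#' @param pseudocount added to each fate's count (default 1).
#' @return bias in (0, 1).
#' @export
clonal_fate_bias <- function(counts_A, counts_B, pseudocount = 1) {
  if (any(counts_A < 0) || any(counts_B < 0)) stop("counts must be >= 0")
  (counts_A + pseudocount) / (counts_A + counts_B + 2 * pseudocount)
}

#' Simulate a trajectory ensemble from one initial cell and count fates
#'
#' Runs `n_traj` independent simulations initialized at copies of the
#' given cell until the final time, classifies the terminal states, and
#' computes the clonal fate bias between the two target fates.
#'
#' @param model trained potential model.
#' @param initial_cell length-k state vector (the clone's starting cell).
#' @param clf FateClassifier.
#' @param n_traj number of trajectories (default 2000).
#' @param t_from,t_final real start and end times.
#' @param fate_A,fate_B the two target fate labels (bias = A fraction).
#' @param seed RNG seed.
#' @param pseudocount passed to [clonal_fate_bias()].
#' @return object of class `FateOutcome`: `counts` (per label), `bias`,
#'   `hit_any` (did any trajectory end in either target fate), `n_traj`.
#' @export
predict_fate <- function(model, initial_cell, clf, n_traj = 2000,
                         t_from, t_final, fate_A, fate_B, seed = 1,
                         pseudocount = 1) {
  stopifnot(inherits(clf, "FateClassifier"))
  init <- matrix(rep(as.numeric(initial_cell), each = n_traj),
                 nrow = n_traj)
  n_steps <- real_time_to_steps(t_from, t_final, model$dt)
  traj <- simulate_diffusion(model, init, n_steps, seed = seed,
                             keep_path = FALSE)
  lab <- classify_states(clf, final_states(traj))
  counts <- table(factor(lab, levels = union(clf$classes, c(fate_A, fate_B))))
  structure(list(counts = counts,
                 bias = clonal_fate_bias(as.numeric(counts[fate_A]),
                                         as.numeric(counts[fate_B]),
                                         pseudocount),
                 hit_any = (counts[fate_A] + counts[fate_B]) > 0,
                 n_traj = n_traj, seed = seed),
            class = "FateOutcome")
}

#' Ensemble fate-bias predictions across checkpoints
#'
#' Arithmetic mean of per-checkpoint bias estimates (typically the last
#' 5 evaluated checkpoints).
#'
#' @param per_checkpoint_biases numeric vector (>= 1 value).
#' @return mean bias.
#' @export
ensemble_bias <- function(per_checkpoint_biases) {
  if (!length(per_checkpoint_biases)) stop("no checkpoint biases given")
  mean(per_checkpoint_biases)
}

#' Score fate-bias predictions against ground truth
#'
#' Pearson correlation between predicted and actual bias, and AUROC for
#' classifying clones with actual bias > 0.5 (rank-based, ties give 0.5).
#'
#' @param predicted,actual numeric vectors of equal length (n >= 3).
#' @return list with `pearson_r` and `auroc` (NA when undefined, e.g.
#'   only one outcome class).
#' @export
score_predictions <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("length mismatch")
  if (length(predicted) < 3) stop("need at least 3 predictions")
  if (stats::sd(predicted) == 0 || stats::sd(actual) == 0)
    r <- NA_real_
  else r <- stats::cor(predicted, actual)
  pos <- actual > 0.5
  auroc <- if (length(unique(pos)) < 2) NA_real_ else
    as.numeric(pROC::auc(pROC::roc(
      response = pos, predictor = predicted, quiet = TRUE,
      direction = "<", levels = c(FALSE, TRUE))))
  list(pearson_r = r, auroc = auroc)
}

#' Write fate outcomes as a delimited table
#' @param outcomes named list of FateOutcome objects (names = clone ids).
#' @param file output path.
#' @export
write_fate_outcomes <- function(outcomes, file) {
  labs <- names(outcomes[[1]]$counts)
  rows <- do.call(rbind, lapply(names(outcomes), function(id) {
    o <- outcomes[[id]]
    data.frame(clone_id = id, t(as.numeric(o$counts)), bias = o$bias,
               hit_any = as.logical(o$hit_any))
  }))
  names(rows)[2:(1 + length(labs))] <- labs
  utils::write.table(rows, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
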