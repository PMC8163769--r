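#' Empirical expected descendants from clonal barcodes
#'
#' For a cell carrying clone barcode c observed at `t_from`, the expected
#' number of descendants at `t_to` is the number of cells sharing c at
#' `t_to` divided by the number sharing c at `t_from`, with a pseudocount
#' added to both counts to tolerate barcode dropout. Cells without a clone
#' barcode get n = 1.
#'
#' @param meta data.frame with columns `time` and `clone_id` (NA allowed).
#' @param t_from,t_to the two snapshot times (`t_to > t_from`).
#' @param pseudocount added to numerator and denominator counts (default 1).
#' @return numeric vector of expected descendant counts, one per cell of
#'   the `t_from` snapshot (in `meta` row order).
#' @export
empirical_descendants <- function(meta, t_from, t_to, pseudocount = 1) {
  if (t_to <= t_from) stop("t_to must be greater than t_from")
  if (!all(c("time", "clone_id") %in% names(meta)))
    stop("meta must have time and clone_id columns")
  from_rows <- which(meta$time == t_from)
  if (!length(from_rows)) stop("no cells at t_from")
  cl_from <- meta$clone_id[from_rows]
  cnt_from <- table(meta$clone_id[meta$time == t_from], useNA = "no")
  cnt_to <- table(meta$clone_id[meta$time == t_to], useNA = "no")
  n <- rep(1, length(from_rows))
  has <- !is.na(cl_from) & nzchar(as.character(cl_from))
  cf <- as.numeric(cnt_from[as.character(cl_from[has])])
  ct <- cnt_to[as.character(cl_from[has])]
  ct <- ifelse(is.na(ct), 0, as.numeric(ct))
  n[has] <- (ct + pseudocount) / (cf + pseudocount)
  if (any(n <= 0)) stop("non-positive descendant estimate; increase pseudocount")
  stats::setNames(n, rownames(meta)[from_rows])
}

#' Gene-signature score per cell
#'
#' Mean of the scaled (z-scored) expression over the genes of a signature
#' set present in the matrix; the standard proxy for proliferative or
#' apoptotic activity.
#'
#' @param scaled cells x genes matrix of scaled expression (gene column
#'   names required).
#' @param gene_set character vector of gene symbols.
#' @return numeric vector, one score per cell.
#' @export
signature_score <- function(scaled, gene_set) {
  scaled <- as.matrix(scaled)
  hit <- intersect(gene_set, colnames(scaled))
  if (!length(hit)) stop("no genes of the set are present in the matrix")
  rowMeans(scaled[, hit, drop = FALSE])
}

#' Smooth per-cell scores over the k-NN graph in state space
#'
#' Iteratively replaces each score s_i by
#' `beta * s_i + (1 - beta) * mean(s over the k nearest neighbors of i)`,
#' with neighbors computed once by Euclidean distance in PCA space and the
#' graph held fixed across iterations. The neighbor set excludes the cell
#' itself; ties at equal distance are broken by cell index order.
#'
#' @param scores numeric vector of per-cell scores.
#' @param states cells x k matrix of PCA coordinates.
#' @param k_nn number of neighbors (default 20).
#' @param beta self weight per iteration (default 0.1).
#' @param iters number of smoothing iterations (default 5).
#' @return smoothed numeric vector.
#' @export
smooth_scores <- function(scores, states, k_nn = 20, beta = 0.1, iters = 5) {
  states <- as.matrix(states)
  n <- nrow(states)
  if (length(scores) != n) stop("scores/states length mismatch")
  if (k_nn >= n) stop("need at least k_nn + 1 cells")
  nb <- knn_index(states, states, k = k_nn + 1)
  # drop self from each neighbor row (self is at distance 0 but may tie)
  idx <- t(vapply(seq_len(n), function(i) {
    row <- nb[i, ]
    row <- row[row != i]
    if (length(row) < k_nn) row <- c(row, nb[i, ])[seq_len(k_nn)]
    row[seq_len(k_nn)]
  }, integer(k_nn)))
  s <- scores
  for (it in seq_len(iters)) {
    nbmean <- rowMeans(matrix(s[idx], nrow = n))
    s <- beta * s + (1 - beta) * nbmean
  }
  s
}

# Exact k nearest reference indices per query row; ties at equal distance
# broken by reference index order (deterministic).
knn_index <- function(reference, query, k) {
  reference <- as.matrix(reference); query <- as.matrix(query)
  k <- min(k, nrow(reference))
  rn2 <- rowSums(reference^2)
  idx <- matrix(0L, nrow(query), k)
  step <- max(1L, floor(2e7 / nrow(reference)))
  for (start in seq(1L, nrow(query), by = step)) {
    rows <- start:min(start + step - 1L, nrow(query))
    q <- query[rows, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rn2, "+") - 2 * q %*% t(reference)
    for (i in seq_along(rows)) {
      ord <- order(d2[i, ], seq_len(ncol(d2)))
      idx[rows[i], ] <- ord[seq_len(k)]
    }
  }
  idx
}

#' Logistic calibration of birth/death rates
#'
#' Builds the calibration mapping a signature score s to a rate
#' `L0 + L / (1 + exp(-k * s))`. The steepness k is set so the logistic
#' term at the minimum observed score is 0.001 of its range, i.e.
#' `k = log(1000) / |s_min|`.
#'
#' @param s_min minimum observed score (nonzero).
#' @param L0 baseline rate (default 0.3).
#' @param L rate range (default 1.2).
#' @return object of class `LogisticCalibration`.
#' @export
logistic_calibration <- function(s_min, L0 = 0.3, L = 1.2) {
  if (L0 <= 0 || L <= 0) stop("L0 and L must be positive")
  if (!is.finite(s_min) || s_min == 0)
    stop("s_min must be finite and nonzero")
  k <- log(1000) / abs(s_min)
  structure(list(L0 = L0, L = L, k = k, s_min = s_min),
            class = "LogisticCalibration")
}

#' Map signature scores to rates through a logistic
#'
#' @param scores finite numeric scores.
#' @param calib LogisticCalibration.
#' @return rates in (L0, L0 + L), increasing in the score.
#' @export
logistic_rates <- function(scores, calib) {
  stopifnot(inherits(calib, "LogisticCalibration"))
  if (any(!is.finite(scores))) stop("scores must be finite")
  calib$L0 + calib$L / (1 + exp(-calib$k * scores))
}

#' Expected descendants from a growth rate
#'
#' Birth-death model: a cell with net growth rate g = b - d has
#' `n = exp(dt_real * g)` expected descendants over a real-time interval.
#'
#' @param g net growth rate (per real-time unit).
#' @param dt_real length of the interval (> 0).
#' @return expected descendant count(s).
#' @export
descendants_from_growth <- function(g, dt_real) {
  if (dt_real <= 0) stop("dt_real must be positive")
  exp(dt_real * g)
}

#' Signature-based growth table
#'
#' Full birth-death pipeline: score cells with cell-cycle (birth) and
#' apoptosis (death) signatures on scaled expression, smooth the scores
#' over the k-NN graph in PCA space, calibrate logistic rate maps from the
#' smoothed score minima, and convert g = b - d into expected descendants
#' over `dt_real`.
#'
#' @param scaled cells x genes scaled expression.
#' @param states cells x k PCA coordinates (for smoothing).
#' @param birth_genes,death_genes signature gene sets.
#' @param dt_real real-time interval for the descendant count.
#' @param L0,L logistic baseline and range (defaults 0.3 and 1.2).
#' @param k_nn,beta,iters smoothing parameters (defaults 20, 0.1, 5).
#' @param cell_ids optional ids for the output table.
#' @return data.frame of class `GrowthTable` with columns `cell_id`,
#'   `s_birth`, `s_death`, `birth`, `death`, `g`, `n`, and attribute
#'   `dt_real`.
#' @export
signature_growth <- function(scaled, states, birth_genes, death_genes,
                             dt_real, L0 = 0.3, L = 1.2,
                             k_nn = 20, beta = 0.1, iters = 5,
                             cell_ids = rownames(scaled)) {
  sb <- smooth_scores(signature_score(scaled, birth_genes), states,
                      k_nn = k_nn, beta = beta, iters = iters)
  sd_ <- smooth_scores(signature_score(scaled, death_genes), states,
                       k_nn = k_nn, beta = beta, iters = iters)
  cb <- logistic_calibration(min(sb), L0 = L0, L = L)
  cd <- logistic_calibration(min(sd_), L0 = L0, L = L)
  b <- logistic_rates(sb, cb)
  d <- logistic_rates(sd_, cd)
  g <- b - d
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_along(g))
  out <- data.frame(cell_id = cell_ids, s_birth = sb, s_death = sd_,
                    birth = b, death = d, g = g,
                    n = descendants_from_growth(g, dt_real))
  attr(out, "dt_real") <- dt_real
  class(out) <- c("GrowthTable", "data.frame")
  out
}

#' Write a growth table as delimited text
#' @param growth GrowthTable.
#' @param file output path.
#' @export
write_growth_table <- function(growth, file) {
  utils::write.table(as.data.frame(growth), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}
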