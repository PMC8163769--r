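#' Select highly variable genes by variance ranking
#'
#' Ranks genes by their expression variance across cells and returns the
#' top `n_genes`. Ties are broken by gene-name lexicographic order so the
#' selection is deterministic. An optional exclusion list (e.g. cell-cycle
#' genes) is removed before ranking.
#'
#' @param expr ExpressionMatrix.
#' @param n_genes number of genes to keep.
#' @param exclude optional character vector of gene symbols to drop before
#'   ranking.
#' @return character vector of selected gene symbols, in the original
#'   column order of `expr`.
#' @export
select_variable_genes <- function(expr, n_genes, exclude = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (n_genes < 1) stop("n_genes must be >= 1")
  genes <- expr$gene_names
  keep <- if (is.null(exclude)) genes else setdiff(genes, exclude)
  if (n_genes > length(keep))
    stop("n_genes exceeds number of available genes")
  v <- apply(expr$values[, keep, drop = FALSE], 2, stats::var)
  ord <- order(-v, keep)   # variance desc, then lexicographic
  sel <- keep[ord[seq_len(n_genes)]]
  genes[genes %in% sel]    # restore original column order
}

#' Fit a per-gene standard scaler
#'
#' Computes per-gene mean and standard deviation on a reference cell set.
#' For held-out time-point experiments the reference should be the training
#' snapshots only; otherwise all cells.
#'
#' @param expr ExpressionMatrix (the reference set).
#' @param genes optional gene subset to fit on (default all genes).
#' @return object of class `ScalerParams` with fields `mean`, `sd`,
#'   `genes`, and `zero_var` flagging genes with sd == 0.
#' @export
fit_scaler <- function(expr, genes = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (!is.null(genes)) expr <- subset_cells(expr, genes = genes)
  mu <- colMeans(expr$values)
  sd <- apply(expr$values, 2, stats::sd)
  structure(list(mean = mu, sd = sd, genes = expr$gene_names,
                 zero_var = sd == 0),
            class = "ScalerParams")
}

#' Apply a fitted scaler (z-score per gene)
#'
#' Column j of the output is `(x_j - mean_j) / sd_j`; genes with zero
#' fitted variance map to 0.
#'
#' @param expr ExpressionMatrix or a plain cells x genes matrix with gene
#'   column names.
#' @param params ScalerParams from [fit_scaler()].
#' @return numeric matrix of scaled (z-scored) expression, cells x genes,
#'   restricted to the fitted genes.
#' @export
scale_genes <- function(expr, params) {
  stopifnot(inherits(params, "ScalerParams"))
  m <- if (inherits(expr, "ExpressionMatrix")) expr$values else as.matrix(expr)
  miss <- setdiff(params$genes, colnames(m))
  if (length(miss))
    stop("matrix lacks fitted genes: ", paste(miss, collapse = ", "))
  m <- m[, params$genes, drop = FALSE]
  sd <- ifelse(params$zero_var, 1, params$sd)
  out <- sweep(sweep(m, 2, params$mean, "-"), 2, sd, "/")
  out[, params$zero_var] <- 0
  out
}

#' Fit a PCA projection on scaled expression
#'
#' Wraps [stats::prcomp()] (no re-scaling; input is already z-scored).
#' If `k` exceeds the numerical rank of the data it is reduced with a
#' warning.
#'
#' @param scaled cells x genes matrix of scaled expression.
#' @param k number of components.
#' @return object of class `PCAProjection` with orthonormal `loadings`
#'   (genes x k), `center` (length genes), `sdev`, and `k`.
#' @export
fit_pca <- function(scaled, k) {
  scaled <- as.matrix(scaled)
  if (k < 1) stop("k must be >= 1")
  if (k > min(dim(scaled)))
    stop("k must be <= min(cells, genes)")
  pc <- stats::prcomp(scaled, center = TRUE, scale. = FALSE)
  pos <- sum(pc$sdev > pc$sdev[1] * 1e-8)
  if (k > pos) {
    warning(sprintf("k = %d exceeds numerical rank %d; reduced", k, pos))
    k <- pos
  }
  structure(list(loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 center = pc$center, sdev = pc$sdev[seq_len(k)], k = k,
                 genes = colnames(scaled)),
            class = "PCAProjection")
}

#' Project scaled expression into PCA state space
#' @param scaled cells x genes matrix (same genes as the fit).
#' @param pca PCAProjection.
#' @return cells x k matrix of states.
#' @export
project_states <- function(scaled, pca) {
  stopifnot(inherits(pca, "PCAProjection"))
  scaled <- as.matrix(scaled)
  if (ncol(scaled) != length(pca$center))
    stop("gene dimension mismatch with PCA fit")
  sweep(scaled, 2, pca$center, "-") %*% pca$loadings
}

#' Back-project PCA states to scaled-gene space
#' @param states cells x k matrix.
#' @param pca PCAProjection.
#' @return cells x genes matrix (approximation within the PCA span).
#' @export
back_project <- function(states, pca) {
  stopifnot(inherits(pca, "PCAProjection"))
  states <- as.matrix(states)
  if (ncol(states) != pca$k) stop("state dimension mismatch with PCA fit")
  sweep(states %*% t(pca$loadings), 2, pca$center, "+")
}

#' Fit the full preprocessing bundle
#'
#' Variable-gene selection, scaler and PCA fit on a reference set, in one
#' call. Returns a bundle usable with [preprocess_apply()].
#'
#' @param expr ExpressionMatrix.
#' @param n_genes number of variable genes (default all genes).
#' @param k number of PCs.
#' @param reference_cells optional selector (indices/ids/logical) of cells
#'   the scaler and PCA are fit on; default all cells.
#' @param exclude gene exclusion list passed to [select_variable_genes()].
#' @return object of class `Preprocessing` with `genes`, `scaler`, `pca`.
#' @export
preprocess_fit <- function(expr, n_genes = length(expr$gene_names), k,
                           reference_cells = NULL, exclude = NULL) {
  ref <- if (is.null(reference_cells)) expr else
    subset_cells(expr, cells = reference_cells)
  genes <- select_variable_genes(ref, n_genes, exclude = exclude)
  scaler <- fit_scaler(ref, genes = genes)
  pca <- fit_pca(scale_genes(ref, scaler), k)
  structure(list(genes = genes, scaler = scaler, pca = pca),
            class = "Preprocessing")
}

#' Apply a fitted preprocessing bundle
#' @param expr ExpressionMatrix.
#' @param prep Preprocessing from [preprocess_fit()].
#' @return list with `scaled` (cells x genes) and `states` (cells x k).
#' @export
preprocess_apply <- function(expr, prep) {
  stopifnot(inherits(prep, "Preprocessing"))
  scaled <- scale_genes(expr, prep$scaler)
  list(scaled = scaled, states = project_states(scaled, prep$pca))
}

#' Write / read a preprocessing bundle as plain text
#'
#' Serializes the variable-gene list, scaler and PCA loadings into a
#' directory of delimited text files so runs are reproducible across
#' sessions.
#'
#' @param prep Preprocessing.
#' @param dir output directory (created if missing).
#' @export
write_preprocessing <- function(prep, dir) {
  stopifnot(inherits(prep, "Preprocessing"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(prep$genes, file.path(dir, "genes.txt"))
  utils::write.table(
    data.frame(gene = prep$scaler$genes, mean = prep$scaler$mean,
               sd = prep$scaler$sd),
    file.path(dir, "scaler.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  load <- data.frame(gene = rownames(prep$pca$loadings),
                     center = prep$pca$center, prep$pca$loadings,
                     check.names = FALSE)
  utils::write.table(load, file.path(dir, "pca.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_preprocessing
#' @return `read_preprocessing()` returns the Preprocessing bundle.
#' @export
read_preprocessing <- function(dir) {
  genes <- readLines(file.path(dir, "genes.txt"))
  sc <- utils::read.table(file.path(dir, "scaler.tsv"), header = TRUE,
                          sep = "\t")
  scaler <- structure(list(mean = stats::setNames(sc$mean, sc$gene),
                           sd = stats::setNames(sc$sd, sc$gene),
                           genes = sc$gene, zero_var = sc$sd == 0),
                      class = "ScalerParams")
  pc <- utils::read.table(file.path(dir, "pca.tsv"), header = TRUE,
                          sep = "\t", check.names = FALSE)
  loadings <- as.matrix(pc[, -(1:2), drop = FALSE])
  rownames(loadings) <- pc$gene
  pca <- structure(list(loadings = loadings,
                        center = stats::setNames(pc$center, pc$gene),
                        sdev = rep(NA_real_, ncol(loadings)),
                        k = ncol(loadings), genes = pc$gene),
                   class = "PCAProjection")
  structure(list(genes = genes, scaler = scaler, pca = pca),
            class = "Preprocessing")
}
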