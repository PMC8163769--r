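# Small in-code fixtures shared across test files.

# cells x genes toy ExpressionMatrix with controllable columns
toy_expression <- function(values, times = rep(0, nrow(values)), ...) {
  expression_matrix(values,
                    gene_names = colnames(values),
                    cell_ids = rownames(values),
                    meta = data.frame(time = times, ...))
}

# deterministic matrix with named genes
toy_matrix <- function(..., genes = NULL) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  colnames(m) <- if (is.null(genes)) names(cols) else genes
  rownames(m) <- paste0("c", seq_len(nrow(m)))
  m
}

# exact brute-force k-NN majority vote classifier (oracle for RANN path)
oracle_knn_classify <- function(reference, labels, query, k) {
  classes <- sort(unique(labels))
  apply(as.matrix(query), 1, function(q) {
    d2 <- colSums((t(reference) - q)^2)
    nb <- order(d2, seq_along(d2))[seq_len(k)]
    cnt <- table(factor(labels[nb], levels = classes))
    names(cnt)[which.max(cnt)]
  })
}
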