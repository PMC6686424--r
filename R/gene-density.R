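#' Per-sample, per-gene variant density matrix
#'
#' Density is the number of a sample's variants assigned to a gene divided
#' by the full transcript length (units: variants per nucleotide). The
#' matrix is dense over all requested (sample, gene) pairs, zero where the
#' sample has no calls in the gene.
#'
#' @param calls Annotated call tibble with sample_id and gene_id (rows with
#'   `NA` gene_id are ignored).
#' @param models A `gene_models` object supplying transcript lengths.
#' @param samples Optional sample ids fixing row order (defaults to samples
#'   observed in `calls`).
#' @return Numeric matrix, rows = samples, columns = genes.
#' @export
density_matrix <- function(calls, models, samples = NULL) {
  calls <- calls[!is.na(calls$gene_id), , drop = FALSE]
  unknown <- setdiff(unique(calls$gene_id), models$genes$gene_id)
  if (length(unknown) > 0L)
    stop("calls reference unknown gene ids: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  if (is.null(samples)) samples <- sort(unique(calls$sample_id))
  genes <- models$genes$gene_id
  counts <- table(factor(calls$sample_id, levels = samples),
                  factor(calls$gene_id, levels = genes))
  m <- matrix(as.numeric(counts), nrow = length(samples),
              dimnames = list(samples, genes))
  sweep(m, 2, models$genes$tx_length, "/")
}

#' Sample-by-sample Pearson correlation of density profiles
#'
#' Correlates every pair of samples across genes. Genes with no variants in
#' the whole cohort (all-zero columns) carry no information and are dropped
#' first, with a message. Samples whose remaining density row has zero
#' variance yield `NA` correlations (flagged, not silently zero).
#'
#' @param mat Density matrix from [density_matrix()] (samples x genes).
#' @param drop_empty_genes Drop all-zero gene columns first (default TRUE).
#' @return Symmetric correlation matrix with unit diagonal for well-defined
#'   samples.
#' @export
sample_correlation <- function(mat, drop_empty_genes = TRUE) {
  if (ncol(mat) < 2L) stop("need at least two genes", call. = FALSE)
  if (drop_empty_genes) {
    empty <- colSums(mat) == 0
    if (any(empty)) {
      message(sprintf("dropping %d gene(s) with no variants in the cohort",
                      sum(empty)))
      mat <- mat[, !empty, drop = FALSE]
    }
  }
  if (ncol(mat) < 2L) stop("fewer than two informative genes", call. = FALSE)
  flat <- apply(mat, 1, stats::sd) == 0
  cc <- suppressWarnings(stats::cor(t(mat), method = "pearson"))
  if (any(flat)) cc[flat, ] <- cc[, flat] <- NA_real_
  diag(cc)[!flat] <- 1
  cc
}

#' Order a sample correlation matrix by group blocks and plot it
#'
#' Samples are sorted by group label (groups sorted by center, then name),
#' mirroring cohort-sorted correlation heatmaps. Returns the reordered
#' matrix plus the ordering, and optionally renders an annotated heatmap.
#'
#' @param corr Correlation matrix from [sample_correlation()].
#' @param metadata Metadata tibble covering all samples in `corr`.
#' @param file Optional path: render the heatmap (pheatmap) to this file.
#' @return List: `matrix` (reordered), `order` (sample ids), `annotation`
#'   (data.frame of center/group per sample).
#' @export
ordered_heatmap <- function(corr, metadata, file = NULL) {
  ids <- rownames(corr)
  meta <- metadata[match(ids, metadata$sample_id), ]
  if (anyNA(meta$sample_id))
    stop("metadata does not cover all samples in the matrix", call. = FALSE)
  o <- order(meta$center, meta$group, meta$sample_id)
  ordered <- corr[o, o]
  ann <- data.frame(center = meta$center[o], group = meta$group[o],
                    row.names = ids[o])
  if (!is.null(file)) {
    pheatmap::pheatmap(
      ordered, cluster_rows = FALSE, cluster_cols = FALSE,
      show_rownames = FALSE, show_colnames = FALSE,
      annotation_row = ann, annotation_col = ann,
      main = "Sample-sample Pearson correlation of per-gene variant density",
      filename = file
    )
  }
  list(matrix = ordered, order = ids[o], annotation = ann)
}

#' Mean within-center vs between-center correlation
#'
#' Summary of batch structure in the correlation matrix: the average
#' correlation among sample pairs from the same sequencing center versus
#' pairs from different centers (diagonal excluded).
#'
#' @param corr Correlation matrix.
#' @param metadata Metadata tibble.
#' @return List with `within`, `between`, and their difference `delta`.
#' @export
correlation_contrast <- function(corr, metadata) {
  ids <- rownames(corr)
  ctr <- metadata$center[match(ids, metadata$sample_id)]
  same <- outer(ctr, ctr, "==")
  ut <- upper.tri(corr)
  list(within = mean(corr[ut & same], na.rm = TRUE),
       between = mean(corr[ut & !same], na.rm = TRUE),
       delta = mean(corr[ut & same], na.rm = TRUE) -
         mean(corr[ut & !same], na.rm = TRUE))
}
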