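#' Jaccard distance between two binary vectors
#'
#' `1 - |intersection| / |union|` over the supports of two equal-length 0/1
#' vectors; the metric used on both axes of the membership bi-clustering.
#'
#' @param u,v binary vectors of equal length.
#' @return distance in `[0, 1]`.
#' @export
binary_distance <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  if (!all(u %in% c(0, 1)) || !all(v %in% c(0, 1)))
    stop("vectors must be binary (0/1)")
  uni <- sum(u == 1 | v == 1)
  if (uni == 0) stop("Jaccard distance undefined for two all-zero vectors")
  1 - sum(u == 1 & v == 1) / uni
}

#' Build the binary gene-by-pathway membership matrix
#'
#' Rows are query genes, columns retained pathways, entries 1 when the gene
#' is annotated to the pathway. All-zero rows and columns (genes in no
#' retained pathway, pathways hitting no query gene) are pruned with a
#' message, since the Jaccard distance is undefined for them.
#'
#' @param query_genes character vector of genes.
#' @param pathways gene-set table ([read_gmt()] layout), typically the
#'   retained terms of [enrich()] joined back to their member lists.
#' @return integer 0/1 matrix, genes x pathways.
#' @export
membership_matrix <- function(query_genes, pathways) {
  query_genes <- unique(query_genes)
  m <- vapply(pathways$genes, function(g) as.integer(query_genes %in% g),
              integer(length(query_genes)))
  m <- matrix(m, nrow = length(query_genes),
              dimnames = list(query_genes, pathways$term_id))
  zr <- rowSums(m) == 0; zc <- colSums(m) == 0
  if (any(zr)) message("membership_matrix: pruned ", sum(zr), " all-zero gene row(s)")
  if (any(zc)) message("membership_matrix: pruned ", sum(zc), " all-zero pathway column(s)")
  m[!zr, !zc, drop = FALSE]
}

#' Bi-cluster a binary membership matrix
#'
#' Independent agglomerative clustering of the two axes: Jaccard distance
#' (`stats::dist(method = "binary")`) and the requested linkage on rows
#' (genes) and on columns (pathways), each dendrogram cut into the
#' configured number of flat clusters. Defaults (9 pathway clusters, 8 gene
#' clusters) follow the published analysis of a 20-pathway result set.
#'
#' @param m binary membership matrix from [membership_matrix()].
#' @param k_pathways,k_genes number of flat clusters per axis.
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return an object of class `sv_bicluster`: `$gene_clusters`,
#'   `$pathway_clusters` (named integer vectors) and the two `hclust` trees.
#' @export
bicluster <- function(m, k_pathways = 9, k_genes = 8, linkage = "average") {
  if (k_genes > nrow(m)) stop("k_genes exceeds number of gene rows")
  if (k_pathways > ncol(m)) stop("k_pathways exceeds number of pathway columns")
  hg <- stats::hclust(stats::dist(m, method = "binary"), method = linkage)
  hp <- stats::hclust(stats::dist(t(m), method = "binary"), method = linkage)
  structure(list(
    gene_clusters = stats::cutree(hg, k = k_genes),
    pathway_clusters = stats::cutree(hp, k = k_pathways),
    gene_hclust = hg,
    pathway_hclust = hp,
    matrix = m
  ), class = "sv_bicluster")
}

#' @export
print.sv_bicluster <- function(x, ...) {
  cat("<sv_bicluster> ", nrow(x$matrix), " genes x ", ncol(x$matrix),
      " pathways; ", max(x$gene_clusters), " gene clusters, ",
      max(x$pathway_clusters), " pathway clusters\n", sep = "")
  invisible(x)
}

#' Heatmap of a bi-clustering (visual aid)
#'
#' Draws the membership matrix with the two dendrograms via `pheatmap`,
#' when that package is available.
#'
#' @param x an `sv_bicluster`.
#' @param ... passed to [pheatmap::pheatmap()].
#' @return the pheatmap object, invisibly.
#' @export
plot_bicluster <- function(x, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plot_bicluster needs the 'pheatmap' package")
  ph <- pheatmap::pheatmap(
    x$matrix,
    cluster_rows = stats::as.hclust(x$gene_hclust),
    cluster_cols = stats::as.hclust(x$pathway_hclust),
    cutree_rows = max(x$gene_clusters),
    cutree_cols = max(x$pathway_clusters),
    legend = FALSE, ...)
  invisible(ph)
}

#' Write bi-cluster labels as a TSV
#'
#' @param x an `sv_bicluster`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_bicluster_labels <- function(x, path) {
  out <- rbind(
    data.frame(axis = "gene", item = names(x$gene_clusters),
               cluster = unname(x$gene_clusters)),
    data.frame(axis = "pathway", item = names(x$pathway_clusters),
               cluster = unname(x$pathway_clusters)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
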