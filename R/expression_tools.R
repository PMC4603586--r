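#' Relative expression by the 2^-ddCt method
#'
#' Replicate Ct values are averaged on the Ct scale per (gene, sample);
#' dCt = mean Ct(gene) - mean Ct(reference gene) within each sample;
#' ddCt = dCt(sample) - dCt(calibrator sample); fold = 2^-ddCt. By
#' construction every gene's fold in the calibrator sample is exactly 1.
#'
#' @param ct data.frame with columns `gene_id`, `sample_id`, `replicate`,
#'   `ct`.
#' @param reference_gene id of the internal-standard gene (e.g. an actin),
#'   present in every sample.
#' @param calibrator_sample id of the calibrator (e.g. the untreated
#'   0-hour sample), whose expression is set to 1.
#' @return data.frame with columns `gene_id`, `sample_id`, `delta_ct`,
#'   `ddct`, `fold`, `log2_fold` (reference gene excluded).
#' @examples
#' ct <- data.frame(
#'   gene_id = rep(c("g", "ref"), each = 2),
#'   sample_id = rep(c("treated", "ctrl"), 2),
#'   replicate = 1L, ct = c(25, 24, 20, 20))
#' ddct(ct, "ref", "ctrl")  # fold 0.5 in the treated sample
#' @export
ddct <- function(ct, reference_gene, calibrator_sample) {
  stopifnot(all(c("gene_id", "sample_id", "ct") %in% names(ct)))
  if (!calibrator_sample %in% ct$sample_id) {
    stop("calibrator sample not present: ", calibrator_sample)
  }
  mean_ct <- aggregate(ct ~ gene_id + sample_id, data = ct, FUN = mean)
  ref <- mean_ct[mean_ct$gene_id == reference_gene, ]
  missing_ref <- setdiff(unique(mean_ct$sample_id), ref$sample_id)
  if (length(missing_ref)) {
    stop("reference gene ", reference_gene, " missing in sample(s): ",
         paste(missing_ref, collapse = ", "))
  }
  x <- mean_ct[mean_ct$gene_id != reference_gene, ]
  x$delta_ct <- x$ct - ref$ct[match(x$sample_id, ref$sample_id)]
  cal <- x[x$sample_id == calibrator_sample, ]
  x$ddct <- x$delta_ct - cal$delta_ct[match(x$gene_id, cal$gene_id)]
  x$fold <- 2^(-x$ddct)
  x$log2_fold <- -x$ddct
  x <- x[order(x$gene_id, x$sample_id), ]
  rownames(x) <- NULL
  x[, c("gene_id", "sample_id", "delta_ct", "ddct", "fold", "log2_fold")]
}

#' Cluster genes by expression profile
#'
#' Agglomerative clustering with distance 1 - Pearson correlation between
#' gene profiles and average linkage (UPGMA on the distance matrix), the
#' combination conventionally used for qRT-PCR heatmaps. Rows are sorted
#' by gene id before clustering so ties break deterministically. Genes
#' with zero-variance (constant) profiles have undefined correlation;
#' their distance to every other gene is set to the maximum (2).
#'
#' @param mat numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns; typically log2 fold changes from [ddct()].
#' @return list with `order` (gene ids in dendrogram leaf order),
#'   `merge`, `height` (hclust components) and `hclust` (the full
#'   object, with a cophenetic-ready structure).
#' @export
cluster_genes <- function(mat) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (nrow(mat) < 2L || ncol(mat) < 2L) {
    stop("need at least 2 genes and 2 samples")
  }
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  constant <- apply(mat, 1L, function(r) stats::var(r) == 0)
  if (sum(!constant) < 2L) stop("fewer than 2 non-constant gene profiles")
  d <- pearson_distance(mat)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  list(order = rownames(mat)[hc$order], merge = hc$merge,
       height = hc$height, hclust = hc)
}

# 1 - Pearson correlation; constant rows at maximal distance (2) to all
pearson_distance <- function(mat) {
  constant <- apply(mat, 1L, function(r) stats::var(r) == 0)
  d <- matrix(2, nrow(mat), nrow(mat),
              dimnames = list(rownames(mat), rownames(mat)))
  if (any(!constant)) {
    cc <- stats::cor(t(mat[!constant, , drop = FALSE]))
    d[!constant, !constant] <- 1 - cc
  }
  diag(d) <- 0
  d
}

#' Render a merge tree as a Newick string
#'
#' @param hc an `hclust` object (e.g. from [cluster_genes()]).
#' @param digits branch-length digits.
#' @return a Newick-format character scalar.
#' @export
merge_tree_newick <- function(hc, digits = 6L) {
  lab <- hc$labels
  node <- function(k, parent_h) {
    if (k < 0L) {
      sprintf("%s:%s", lab[-k], format(parent_h, digits = digits))
    } else {
      h <- hc$height[k]
      sprintf("(%s,%s):%s", node(hc$merge[k, 1L], h),
              node(hc$merge[k, 2L], h),
              format(parent_h - h, digits = digits))
    }
  }
  n <- length(hc$height)
  h <- hc$height[n]
  paste0("(", node(hc$merge[n, 1L], h), ",", node(hc$merge[n, 2L], h), ");")
}
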