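#' Construct a gene signature
#'
#' An ordered gene list with its derivation provenance.
#'
#' @param name signature name.
#' @param genes ordered character vector of unique gene ids.
#' @param stat per-gene statistics data frame aligned with `genes`.
#' @param method derivation method ("markers", "correlation", "planted").
#' @param params list of the parameters used to derive the signature.
#' @return a `gene_signature` object.
#' @export
new_gene_signature <- function(name, genes, stat = NULL, method = "manual",
                               params = list()) {
  if (anyDuplicated(genes)) stop("signature genes must be unique")
  structure(list(name = name, genes = as.character(genes), stat = stat,
                 method = method, params = params),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s (%s): %d genes\n", x$name, x$method,
              length(x$genes)))
  cat("  ", paste(utils::head(x$genes, 8), collapse = ", "),
      if (length(x$genes) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Signature derivation parameters
#'
#' @param min_diff_pct minimum difference (strict) in detection fraction
#'   between the cluster and the rest for a marker to pass.
#' @param top_n number of genes kept after ordering (about 100 for marker
#'   signatures; 20-30 for correlation signatures).
#' @param excluded_prefixes gene-id prefixes dropped before selection
#'   (poorly supported transcript models carry the "AP-" prefix).
#' @param excluded_biotypes biotypes dropped when a biotype annotation is
#'   supplied (noncoding classes by default).
#' @return a `signature_params` list.
#' @export
signature_params <- function(min_diff_pct = 0.25, top_n = 100,
                             excluded_prefixes = "AP-",
                             excluded_biotypes = c("lincRNA", "miRNA")) {
  p <- list(min_diff_pct = check_fraction(min_diff_pct, "min_diff_pct"),
            top_n = check_count(top_n, "top_n"),
            excluded_prefixes = excluded_prefixes,
            excluded_biotypes = excluded_biotypes)
  class(p) <- "signature_params"
  p
}

#' Normalize single-cell expression for scoring and correlation
#'
#' Scales each cell's counts so its total equals the cohort median total,
#' then applies log1p. This is the normalized scale used by
#' [score_cells()], [rank_sum_markers()] and [correlation_signature()].
#'
#' @param counts genes x cells nonnegative count matrix.
#' @return normalized matrix of the same shape.
#' @export
normalize_expression <- function(counts) {
  tot <- colSums(counts)
  target <- stats::median(tot[tot > 0])
  scl <- ifelse(tot == 0, 0, target / tot)
  log1p(sweep(counts, 2, scl, "*"))
}

# Two-sided Wilcoxon rank-sum p for one gene: exact enumeration when both
# groups have <= 8 cells and no ties, else normal approximation with tie
# correction (what stats::wilcox.test does in each regime).
rank_sum_p <- function(x, y) {
  exact <- length(x) <= 8L && length(y) <= 8L && !anyDuplicated(c(x, y))
  suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                      correct = !exact)$p.value)
}

#' Cluster marker signature by one-vs-rest Wilcoxon rank-sum test
#'
#' Tests each gene between the cells of `cluster` and all other cells,
#' keeps genes detected in a larger fraction of cluster cells than of the
#' rest by more than `min_diff_pct` (strict) with a positive mean effect,
#' drops excluded prefixes/biotypes, orders by ascending p then descending
#' effect, and truncates to `top_n`.
#'
#' @param expr genes x cells normalized expression matrix
#'   (see [normalize_expression()]).
#' @param cluster_labels per-cell cluster labels.
#' @param cluster the cluster whose markers are derived.
#' @param params a [signature_params()].
#' @param biotypes optional named character vector gene -> biotype.
#' @param effect one of "mean_diff" (difference of mean normalized
#'   expression, default) or "logfc" (log fold change of mean expm1).
#' @return a `gene_signature`; `stat` holds per-gene effect, p and the
#'   detection fractions.
#' @export
rank_sum_markers <- function(expr, cluster_labels, cluster,
                             params = signature_params(), biotypes = NULL,
                             effect = c("mean_diff", "logfc")) {
  effect <- match.arg(effect)
  if (!cluster %in% cluster_labels)
    stop("cluster label not present: ", cluster)
  inside <- cluster_labels == cluster
  if (sum(inside) < 2L || sum(!inside) < 2L)
    stop("need at least 2 cells inside and outside the cluster")
  genes <- rownames(expr)

  keep <- rep(TRUE, length(genes))
  for (pre in params$excluded_prefixes)
    keep <- keep & !startsWith(genes, pre)
  if (!is.null(biotypes))
    keep <- keep & !(biotypes[genes] %in% params$excluded_biotypes)

  pct_in <- rowMeans(expr[, inside, drop = FALSE] > 0)
  pct_out <- rowMeans(expr[, !inside, drop = FALSE] > 0)
  mu_in <- rowMeans(expr[, inside, drop = FALSE])
  mu_out <- rowMeans(expr[, !inside, drop = FALSE])
  eff <- if (effect == "mean_diff") mu_in - mu_out
         else log((rowMeans(expm1(expr[, inside, drop = FALSE])) + 1e-9) /
                  (rowMeans(expm1(expr[, !inside, drop = FALSE])) + 1e-9))
  keep <- keep & (pct_in - pct_out > params$min_diff_pct) & eff > 0

  idx <- which(keep)
  pv <- vapply(idx, function(i)
    rank_sum_p(expr[i, inside], expr[i, !inside]), numeric(1))
  o <- order(pv, -eff[idx], genes[idx])
  sel <- idx[o][seq_len(min(params$top_n, length(idx)))]

  stat <- data.frame(gene = genes[sel], effect = eff[sel],
                     p = pv[o][seq_along(sel)],
                     pct_in = pct_in[sel], pct_out = pct_out[sel])
  new_gene_signature(name = paste0("markers_", cluster), genes = genes[sel],
                     stat = stat, method = "markers",
                     params = c(params, list(cluster = cluster,
                                             effect = effect)))
}

#' Co-expression signature around a reference gene
#'
#' Pearson-correlates each variable gene with the reference gene across the
#' given cells and keeps the top `k` (reference first, ties broken by gene
#' id).
#'
#' @param expr genes x cells normalized expression matrix.
#' @param reference_gene gene id present in `expr` with nonzero variance.
#' @param k signature size, conventionally 20-30.
#' @param variable_genes the gene universe to rank (computed upstream by a
#'   single-cell toolkit's variable-feature selection).
#' @param cells optional barcode subset (e.g. nonstimulated CD8 cells).
#' @return a `gene_signature` with per-gene correlation r in `stat`.
#' @export
correlation_signature <- function(expr, reference_gene, k = 25,
                                  variable_genes, cells = NULL) {
  if (!reference_gene %in% rownames(expr))
    stop("reference gene not found: ", reference_gene)
  if (!is.null(cells)) expr <- expr[, cells, drop = FALSE]
  ref <- expr[reference_gene, ]
  if (stats::sd(ref) == 0) stop("reference gene has zero variance")
  vg <- setdiff(intersect(variable_genes, rownames(expr)), reference_gene)
  r <- suppressWarnings(stats::cor(t(expr[vg, , drop = FALSE]), ref))[, 1]
  o <- order(-r, vg)
  sel <- vg[o][seq_len(min(k - 1L, length(vg)))]
  genes <- c(reference_gene, sel)
  stat <- data.frame(gene = genes, r = c(1, r[sel]))
  new_gene_signature(name = paste0("corr_", reference_gene), genes = genes,
                     stat = stat, method = "correlation",
                     params = list(reference = reference_gene, k = k))
}

#' Score cells by average signature expression
#'
#' @param expr genes x cells normalized expression matrix.
#' @param signature a `gene_signature` or character vector of gene ids.
#' @return named numeric vector of per-cell scores (arithmetic mean over
#'   the signature genes present in `expr`); attribute `n_missing` counts
#'   the signature genes absent from the matrix.
#' @export
score_cells <- function(expr, signature) {
  genes <- if (inherits(signature, "gene_signature")) signature$genes
           else as.character(signature)
  present <- intersect(genes, rownames(expr))
  if (length(present) == 0L)
    stop("no signature gene present in the expression matrix")
  s <- colMeans(expr[present, , drop = FALSE])
  structure(s, n_missing = length(genes) - length(present))
}
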