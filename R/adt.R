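#' Depth-scale an ADT count matrix
#'
#' Rescales each cell's antibody counts so its total equals the mean
#' per-cell total of the input (cells with zero total are left at zero).
#'
#' @param raw antibodies x cells nonnegative count matrix.
#' @return matrix of the same shape; every nonzero cell's column sums to
#'   the input's mean per-cell total.
#' @export
depth_scale_adt <- function(raw) {
  if (!is.matrix(raw)) stop("raw must be an antibodies x cells matrix")
  tot <- colSums(raw)
  if (all(tot == 0)) stop("all-zero ADT matrix")
  target <- mean(tot)
  scl <- ifelse(tot == 0, 0, target / tot)
  sweep(raw, 2, scl, "*")
}

#' Centered log-ratio normalization of ADT signals
#'
#' Per cell, each antibody value x becomes
#' `log((x + 1) / geometric mean over the panel of (x + 1))`, treating a
#' cell's tag counts as a composition. With `scale = TRUE` (the default)
#' each antibody is then centered and unit-scaled across cells.
#'
#' @param x antibodies x cells nonnegative matrix (typically depth-scaled).
#' @param scale standardize each antibody across cells after the CLR.
#' @return normalized matrix; attribute `clr` holds the unscaled CLR values.
#' @export
clr_normalize <- function(x, scale = TRUE) {
  if (any(x < 0)) stop("ADT values must be nonnegative")
  lx <- log(x + 1)
  clr <- sweep(lx, 2, colMeans(lx), "-")
  out <- clr
  if (scale) {
    m <- rowMeans(clr)
    s <- apply(clr, 1, stats::sd)
    s[s == 0] <- 1  # constant antibody: centered only
    out <- (clr - m) / s
  }
  structure(out, clr = clr)
}

#' Average ADT profile per cluster
#'
#' @param adt antibodies x cells normalized matrix.
#' @param cluster_labels per-cell cluster labels (named by cell or in
#'   column order); every cell must be labeled.
#' @return antibodies x clusters matrix of arithmetic means.
#' @export
cluster_profiles <- function(adt, cluster_labels) {
  if (!is.null(names(cluster_labels)) && !is.null(colnames(adt)))
    cluster_labels <- cluster_labels[colnames(adt)]
  if (length(cluster_labels) != ncol(adt) || anyNA(cluster_labels))
    stop("every cell must carry a cluster label")
  cl <- factor(cluster_labels)
  prof <- t(rowsum(t(adt), cl) / as.vector(table(cl)))
  prof[, levels(cl), drop = FALSE]
}

#' Link stimulated to nonstimulated clusters by Pearson correlation
#'
#' Correlates every stimulated cluster's ADT profile with every
#' nonstimulated profile over a shared antibody subset and pairs each
#' stimulated cluster with its best-correlated nonstimulated cluster.
#'
#' @param stim,nonstim antibodies x clusters profile matrices
#'   (from [cluster_profiles()]).
#' @param panel_subset antibodies to correlate over (default: all shared);
#'   at least 3 required. Use this to drop isotype-control-like channels.
#' @return a `linkage_map` list: `correlation` (stim x nonstim Pearson r,
#'   NA where a profile has zero variance) and `pairing` (row-wise argmax,
#'   named by stimulated cluster).
#' @export
link_by_correlation <- function(stim, nonstim, panel_subset = NULL) {
  shared <- intersect(rownames(stim), rownames(nonstim))
  if (!is.null(panel_subset)) shared <- intersect(shared, panel_subset)
  if (length(shared) < 3L)
    stop("need at least 3 shared antibodies to correlate profiles")
  s <- stim[shared, , drop = FALSE]
  ns <- nonstim[shared, , drop = FALSE]
  r <- suppressWarnings(stats::cor(s, ns))  # zero variance -> NA
  pairing <- apply(r, 1, function(v)
    if (all(is.na(v))) NA_character_ else colnames(r)[which.max(v)])
  structure(list(correlation = r, pairing = pairing), class = "linkage_map")
}

#' Link stimulated clusters to nonstimulated marker sets by enrichment
#'
#' For each stimulated cluster, genes are ranked by descending mean
#' expression and each nonstimulated cluster's marker set is scored with
#' the preranked enrichment engine; each stimulated cluster is paired with
#' the marker set of highest normalized enrichment score.
#'
#' @param stim_means genes x stimulated-clusters matrix of mean expression.
#' @param marker_sets named list of nonstimulated marker gene sets (must
#'   intersect the gene universe).
#' @param params an [enrichment_params()]; `n_perm` can be modest here.
#' @return a `linkage_map` list: `nes` (stim x set NES matrix) and
#'   `pairing` (row-wise argmax).
#' @export
link_by_gsea <- function(stim_means, marker_sets,
                         params = enrichment_params(n_perm = 500)) {
  if (length(marker_sets) == 0L || any(lengths(marker_sets) == 0L))
    stop("marker sets must be nonempty")
  universe <- rownames(stim_means)
  bad <- vapply(marker_sets, function(s) length(intersect(s, universe)) == 0L,
                logical(1))
  if (any(bad))
    stop("marker set(s) disjoint from gene universe: ",
         paste(names(marker_sets)[bad], collapse = ", "))
  nes <- matrix(NA_real_, ncol(stim_means), length(marker_sets),
                dimnames = list(colnames(stim_means), names(marker_sets)))
  for (j in seq_len(ncol(stim_means))) {
    v <- stim_means[, j]
    o <- order(-v, universe)
    ranked <- list(genes = universe[o], stat = v[o])
    for (k in seq_along(marker_sets)) {
      r <- gsea_significance(ranked, marker_sets[[k]], params)
      nes[j, k] <- r$nes
    }
  }
  pairing <- apply(nes, 1, function(v) colnames(nes)[which.max(v)])
  structure(list(nes = nes, pairing = pairing), class = "linkage_map")
}
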