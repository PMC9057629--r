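#' Parameters for preranked enrichment
#'
#' @param p_w weight exponent on the rank statistic (0 gives the classic
#'   unweighted Kolmogorov-Smirnov statistic; 1, the default, weights hits
#'   by |z|).
#' @param n_perm number of random same-size gene sets drawn for the
#'   permutation null.
#' @param seed integer seed for the null.
#' @param alpha significance level on the BH-adjusted p for classification.
#' @param bh_family family over which BH adjustment runs:
#'   "patients_per_set" (across patients for each gene set, the default
#'   matching cohort classification per set) or "sets_per_patient".
#' @return an `enrichment_params` list.
#' @export
enrichment_params <- function(p_w = 1, n_perm = 10000, seed = 1L,
                              alpha = 0.05,
                              bh_family = c("patients_per_set",
                                            "sets_per_patient")) {
  if (p_w < 0) stop_config("p_w must be >= 0")
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must be in (0, 1)")
  p <- list(p_w = p_w, n_perm = check_count(n_perm, "n_perm"),
            seed = as.integer(seed), alpha = alpha,
            bh_family = match.arg(bh_family))
  class(p) <- "enrichment_params"
  p
}

#' Per-patient z-score rankings of a bulk cohort
#'
#' Standardizes each gene across patients (sample sd) and, for each
#' patient, orders genes by descending z. Genes constant across the cohort
#' are dropped with a message; ties are broken by gene id.
#'
#' @param expr genes x patients log2 expression matrix (at least 3
#'   patients).
#' @return named list (one element per patient) of `list(genes, stat)` with
#'   genes in rank order and `stat` the patient's z-scores in that order.
#' @export
per_patient_zranks <- function(expr) {
  if (ncol(expr) < 3L) stop("need at least 3 patients to standardize genes")
  sds <- row_sds(expr)
  drop <- sds == 0
  if (any(drop)) {
    message(sum(drop), " zero-variance gene(s) dropped from rankings")
    expr <- expr[!drop, , drop = FALSE]
    sds <- sds[!drop]
  }
  z <- (expr - rowMeans(expr)) / sds
  genes <- rownames(z)
  out <- lapply(seq_len(ncol(z)), function(j) {
    o <- order(-z[, j], genes)
    list(genes = genes[o], stat = unname(z[o, j]))
  })
  names(out) <- colnames(expr)
  out
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list: a gene-set hit at rank i increments the running
#' sum by `|stat_i|^p_w / sum over hits of |stat|^p_w`, a miss decrements
#' by `1 / (N - N_hits)`. The enrichment score is the running-sum value of
#' maximal absolute deviation from zero (signed); the leading edge holds
#' the hits at or before the extremum (at or after it for negative scores).
#'
#' @param ranked `list(genes, stat)` in rank order (as produced by
#'   [per_patient_zranks()]), or a named numeric vector of statistics
#'   sorted in rank order.
#' @param gene_set character vector; must intersect the ranking and not
#'   cover it entirely.
#' @param p_w weight exponent.
#' @return list: `es`, `running` (running sum after each rank) and
#'   `leading_edge` (gene ids).
#' @export
enrichment_score <- function(ranked, gene_set, p_w = 1) {
  if (is.numeric(ranked)) ranked <- list(genes = names(ranked), stat = ranked)
  genes <- ranked$genes
  N <- length(genes)
  hit <- genes %in% gene_set
  k <- sum(hit)
  if (k == 0L) stop("gene set does not intersect the ranked universe")
  if (k == N)
    stop("gene set covers the whole universe; the score is undefined")
  w <- abs(ranked$stat)^p_w
  wh <- sum(w[hit])
  if (wh == 0) w[hit] <- wh <- 1  # all-zero hit stats: fall back to p_w = 0
  inc <- ifelse(hit, w / sum(w[hit]), -1 / (N - k))
  running <- cumsum(inc)
  hi <- max(running)
  lo <- min(running, 0)
  # equal extremum magnitudes (to numerical resolution) resolve positive
  es <- if (hi >= -lo - 1e-12) hi else lo
  i <- if (es >= 0) which.max(running) else which.min(running)
  le <- if (es >= 0) genes[seq_len(i)][hit[seq_len(i)]]
        else genes[i:N][hit[i:N]]
  list(es = es, running = running, leading_edge = le)
}

# Fast ES from sorted hit positions. pos: k x m matrix (each column one
# gene set's sorted rank positions); w: length-N weights |stat|^p_w.
# The running sum attains its maximum just after a hit and its minimum
# just before one, so only those 2k candidates are evaluated.
es_from_positions <- function(pos, w, N) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 1L)
  k <- nrow(pos)
  wp <- matrix(w[pos], nrow = k)
  H <- apply(wp, 2L, cumsum)
  if (k == 1L) H <- matrix(H, nrow = 1L)
  tot <- H[k, ]
  zero <- tot == 0
  if (any(zero)) {  # all-zero hit weights: uniform increments, as p_w = 0
    H[, zero] <- seq_len(k) / k
    tot[zero] <- 1
  }
  H <- sweep(H, 2L, tot, "/")
  Hprev <- rbind(0, H[-k, , drop = FALSE])
  D <- (pos - seq_len(k)) / (N - k)
  after <- H - D      # value just after each hit
  before <- Hprev - D # value just before each hit
  hi <- apply(after, 2L, max)
  lo <- pmin(apply(before, 2L, min), 0)
  ifelse(hi >= -lo - 1e-12, hi, lo)
}

# Shared null machinery: n_perm random sorted position sets of size k.
null_es <- function(k, N, w, n_perm) {
  pos <- vapply(seq_len(n_perm), function(i) sort.int(sample.int(N, k)),
                integer(k))
  es_from_positions(pos, w, N)
}

# Add-one same-sign permutation p and NES for one observed ES against a
# null ES vector.
p_nes_from_null <- function(es, null) {
  same <- if (es >= 0) null[null >= 0] else null[null < 0]
  if (length(same) == 0L)
    return(list(p = 1, nes = 0, degenerate = TRUE))
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  list(p = p, nes = es / mean(abs(same)), degenerate = FALSE)
}

#' Permutation significance of one gene set on one ranking
#'
#' The null is the enrichment score of `n_perm` random gene sets of the
#' same size drawn from the ranked universe. The p-value is the add-one
#' estimate among null scores of the same sign as the observed score; the
#' normalized enrichment score (NES) divides the observed score by the
#' mean |null score| of that sign. If no null draw shares the sign the
#' result is flagged degenerate with p = 1, NES = 0.
#'
#' @inheritParams enrichment_score
#' @param params an [enrichment_params()].
#' @return one-row data frame: es, nes, p, size, degenerate, plus a
#'   `leading_edge` list column.
#' @export
gsea_significance <- function(ranked, gene_set, params = enrichment_params()) {
  if (is.numeric(ranked)) ranked <- list(genes = names(ranked), stat = ranked)
  sc <- enrichment_score(ranked, gene_set, params$p_w)
  N <- length(ranked$genes)
  k <- sum(ranked$genes %in% gene_set)
  w <- abs(ranked$stat)^params$p_w
  null <- with_seed(params$seed, null_es(k, N, w, params$n_perm))
  pn <- p_nes_from_null(sc$es, null)
  out <- data.frame(es = sc$es, nes = pn$nes, p = pn$p, size = k,
                    degenerate = pn$degenerate)
  out$leading_edge <- list(sc$leading_edge)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1.
#'
#' @param pvalues numeric vector of raw p-values, all in (0, 1].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-patient preranked enrichment across a cohort
#'
#' Ranks every patient by z-score ([per_patient_zranks()]), scores each
#' gene set on each patient's ranking, and attaches permutation p-values
#' and NES. For efficiency one permutation null is drawn per patient and
#' distinct gene-set size and shared across the sets of that size (the
#' null depends on the ranking and the set size only). BH adjustment runs
#' over the family given by `params$bh_family`.
#'
#' @param expr genes x patients log2 expression matrix, or a precomputed
#'   ranking list from [per_patient_zranks()].
#' @param gene_sets named list of gene sets.
#' @param params an [enrichment_params()].
#' @return an `enrichment_result` data frame: patient, set, es, nes, p,
#'   padj, size, degenerate.
#' @export
gsea_cohort <- function(expr, gene_sets, params = enrichment_params()) {
  ranks <- if (is.matrix(expr)) per_patient_zranks(expr) else expr
  if (is.null(names(gene_sets)) || length(gene_sets) == 0L)
    stop("gene_sets must be a nonempty named list")
  rows <- vector("list", length(ranks) * length(gene_sets))
  i <- 0L
  for (pid in names(ranks)) {
    ranked <- ranks[[pid]]
    N <- length(ranked$genes)
    w <- abs(ranked$stat)^params$p_w
    sizes <- vapply(gene_sets, function(s)
      sum(ranked$genes %in% s), integer(1))
    if (any(sizes == 0L))
      stop("gene set(s) disjoint from universe: ",
           paste(names(gene_sets)[sizes == 0L], collapse = ", "))
    nulls <- lapply(unique(sizes), function(k)
      with_seed(params$seed + k, null_es(k, N, w, params$n_perm)))
    names(nulls) <- as.character(unique(sizes))
    for (sn in names(gene_sets)) {
      sc <- enrichment_score(ranked, gene_sets[[sn]], params$p_w)
      pn <- p_nes_from_null(sc$es, nulls[[as.character(sizes[[sn]])]])
      i <- i + 1L
      rows[[i]] <- data.frame(patient = pid, set = sn, es = sc$es,
                              nes = pn$nes, p = pn$p, size = sizes[[sn]],
                              degenerate = pn$degenerate)
    }
  }
  res <- do.call(rbind, rows)
  fam <- if (params$bh_family == "patients_per_set") res$set else res$patient
  res$padj <- stats::ave(res$p, fam, FUN = bh_adjust)
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Classify patients as enriched, depleted or neither
#'
#' A patient is "enriched" for a gene set when NES > 0 and the BH-adjusted
#' p falls below `params$alpha`, "depleted" when NES < 0 and adjusted p
#' below `params$alpha`, and "neither" otherwise.
#'
#' @param results an `enrichment_result` from [gsea_cohort()] (must carry
#'   `padj`).
#' @param params an [enrichment_params()].
#' @return `results` with a `class` column added.
#' @export
classify_patients <- function(results, params = enrichment_params()) {
  if (is.null(results$padj)) stop("results must carry BH-adjusted p-values")
  results$class <- ifelse(
    results$padj < params$alpha & results$nes > 0, "enriched",
    ifelse(results$padj < params$alpha & results$nes < 0, "depleted",
           "neither"))
  results
}
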