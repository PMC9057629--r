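#' Build clonotypes from TCR contig annotations
#'
#' Collapses 10x-style contig rows to one row per cell and assigns a
#' clonotype id keyed on the TRB CDR3 nucleotide sequence within each
#' patient (the same sequence in two patients gives two ids). Cells without
#' a productive TRB are recorded with an `NA` clonotype. With
#' `paired_key = TRUE` the key is the TRB+TRA pair instead.
#'
#' @param contigs data frame with columns barcode, patient, chain, cdr3_nt,
#'   productive, and optionally tissue. Rows missing barcode, chain or
#'   cdr3_nt are skipped with a message.
#' @param paired_key key clonotypes on the TRB and TRA pair.
#' @return a `clonotype_table` data frame: barcode, patient, tissue,
#'   trb_cdr3_nt, tra_cdr3_nt, paired, clonotype_id. Attribute `summary`
#'   holds cell counts and assigned/paired percentages (rounded to integer
#'   percent).
#' @export
build_clonotypes <- function(contigs, paired_key = FALSE) {
  need <- c("barcode", "patient", "chain", "cdr3_nt")
  if (!all(need %in% names(contigs)))
    stop("contigs must have columns: ", paste(need, collapse = ", "))
  bad <- !stats::complete.cases(contigs[need]) |
    contigs$barcode == "" | contigs$cdr3_nt == ""
  if (any(bad)) {
    message(sum(bad), " malformed contig row(s) skipped")
    contigs <- contigs[!bad, , drop = FALSE]
  }
  if ("productive" %in% names(contigs))
    contigs <- contigs[as.logical(contigs$productive), , drop = FALSE]

  first_of <- function(chain) {
    sub <- contigs[contigs$chain == chain, , drop = FALSE]
    sub[!duplicated(sub$barcode), , drop = FALSE]
  }
  trb <- first_of("TRB")
  tra <- first_of("TRA")

  cells <- contigs[!duplicated(contigs$barcode),
                   c("barcode", "patient",
                     intersect("tissue", names(contigs))), drop = FALSE]
  cells$trb_cdr3_nt <- trb$cdr3_nt[match(cells$barcode, trb$barcode)]
  cells$tra_cdr3_nt <- tra$cdr3_nt[match(cells$barcode, tra$barcode)]
  cells$paired <- !is.na(cells$trb_cdr3_nt) & !is.na(cells$tra_cdr3_nt)
  if (!"tissue" %in% names(cells)) cells$tissue <- NA_character_

  key <- if (paired_key)
    ifelse(cells$paired,
           paste(cells$patient, cells$trb_cdr3_nt, cells$tra_cdr3_nt,
                 sep = "|"), NA_character_)
  else ifelse(is.na(cells$trb_cdr3_nt), NA_character_,
              paste(cells$patient, cells$trb_cdr3_nt, sep = "|"))
  ids <- match(key, unique(stats::na.omit(key)))
  cells$clonotype_id <- ifelse(is.na(key), NA_character_,
                               paste0(cells$patient, "_ct",
                                      stats::ave(ids, cells$patient,
                                                 FUN = function(v)
                                                   match(v, unique(v)))))
  rownames(cells) <- NULL

  n <- nrow(cells)
  assigned <- sum(!is.na(cells$clonotype_id))
  paired <- sum(cells$paired)
  summary <- list(
    n_cells = n, n_assigned = assigned, n_paired = paired,
    assigned_pct = round(100 * assigned / n),
    paired_pct = round(100 * paired / n),
    n_clonotypes = length(unique(stats::na.omit(cells$clonotype_id))))
  structure(cells, summary = summary,
            class = c("clonotype_table", "data.frame"))
}

#' Summarize clonotype assignment
#'
#' @param table a `clonotype_table` from [build_clonotypes()].
#' @return list with cell counts, distinct clonotypes, and assigned/paired
#'   integer percentages.
#' @export
clonotype_summary <- function(table) attr(table, "summary")

#' Per-cell clone frequency
#'
#' Each cell's frequency is its clone's size divided by the size of its
#' group, where a group is a patient x tissue combination (tumor and normal
#' cells of one patient form separate denominators). Cells without a
#' clonotype are excluded.
#'
#' @param table a `clonotype_table`.
#' @return data frame barcode, patient, tissue, clonotype_id, clone_size,
#'   group_size, frequency in (0, 1].
#' @export
clone_frequencies <- function(table) {
  x <- table[!is.na(table$clonotype_id), , drop = FALSE]
  if (nrow(x) == 0L) return(x[, c("barcode", "clonotype_id")])
  grp <- paste(x$patient, x$tissue, sep = "|")
  group_size <- stats::ave(rep(1L, nrow(x)), grp, FUN = sum)
  clone_size <- stats::ave(rep(1L, nrow(x)), paste(grp, x$clonotype_id),
                           FUN = sum)
  data.frame(barcode = x$barcode, patient = x$patient, tissue = x$tissue,
             clonotype_id = x$clonotype_id, clone_size = clone_size,
             group_size = group_size, frequency = clone_size / group_size)
}

#' Clonal composition of clusters by expansion bin
#'
#' For each cluster, the proportion of clonotype-assigned cells whose clone
#' size (within patient x tissue) falls in each bin.
#'
#' @param table a `clonotype_table`.
#' @param cluster_labels per-cell cluster labels named by barcode.
#' @param bins list of `c(lo, hi)` clone-size ranges; they must not overlap.
#' @return clusters x bins matrix of proportions; each row sums to 1.
#' @export
clonal_composition <- function(table, cluster_labels,
                               bins = list(c(1, 1), c(2, 5), c(6, Inf))) {
  lo <- vapply(bins, `[`, numeric(1), 1)
  hi <- vapply(bins, `[`, numeric(1), 2)
  o <- order(lo)
  if (any(lo > hi) || any(utils::head(hi[o], -1) >= utils::tail(lo[o], -1)))
    stop("bins must be non-overlapping ranges")
  freq <- clone_frequencies(table)
  freq$cluster <- cluster_labels[freq$barcode]
  freq <- freq[!is.na(freq$cluster), , drop = FALSE]
  bin_of <- function(sz) {
    w <- which(sz >= lo & sz <= hi)
    if (length(w)) w[1] else NA_integer_
  }
  freq$bin <- vapply(freq$clone_size, bin_of, integer(1))
  freq <- freq[!is.na(freq$bin), , drop = FALSE]
  bin_names <- vapply(bins, function(b)
    if (b[1] == b[2]) as.character(b[1])
    else if (is.infinite(b[2])) paste0(b[1], "+")
    else paste0(b[1], "-", b[2]), character(1))
  tab <- table(factor(freq$cluster), factor(freq$bin, seq_along(bins),
                                            labels = bin_names))
  prop <- as.matrix(tab / rowSums(tab))
  prop
}

#' Permutation test of TCR clonotype sharing between two clusters
#'
#' The observed statistic is the number of distinct clonotypes (TRB CDR3
#' within patient) present in both clusters. The null permutes cluster
#' labels among the two clusters' cells within each patient; the p-value is
#' the add-one permutation estimate `(1 + #null >= observed) / (1 + n_perm)`.
#'
#' @param table a `clonotype_table`.
#' @param cluster_labels per-cell cluster labels named by barcode.
#' @param cluster_a,cluster_b the two clusters compared.
#' @param n_perm number of label permutations (a value below 100 warns).
#' @param seed integer seed for the permutation null.
#' @return list: shared (observed count), sizes, p, n_perm, method.
#' @export
tcr_sharing_test <- function(table, cluster_labels, cluster_a, cluster_b,
                             n_perm = 1000, seed = 1L) {
  if (n_perm < 100) warning("n_perm < 100 gives a coarse p-value")
  x <- table[!is.na(table$clonotype_id), , drop = FALSE]
  x$cluster <- cluster_labels[x$barcode]
  x <- x[x$cluster %in% c(cluster_a, cluster_b), , drop = FALSE]
  na <- sum(x$cluster == cluster_a)
  nb <- sum(x$cluster == cluster_b)
  if (na == 0L || nb == 0L) stop("both clusters must contain assigned cells")

  shared_count <- function(cl) {
    length(intersect(unique(x$clonotype_id[cl == cluster_a]),
                     unique(x$clonotype_id[cl == cluster_b])))
  }
  observed <- shared_count(x$cluster)

  null <- with_seed(seed, {
    pat <- factor(x$patient)
    vapply(seq_len(n_perm), function(i) {
      perm <- x$cluster
      for (p in levels(pat)) {
        idx <- which(pat == p)
        perm[idx] <- perm[idx][sample.int(length(idx))]
      }
      shared_count(perm)
    }, numeric(1))
  })
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  list(cluster_a = cluster_a, cluster_b = cluster_b, shared = observed,
       sizes = c(a = na, b = nb), p = p, n_perm = n_perm,
       method = "within-patient label permutation")
}
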