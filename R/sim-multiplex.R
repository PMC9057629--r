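#' Configuration for a simulated multiplexed droplet run
#'
#' Defines the ground-truth structure of a hashed CITE-seq-style run:
#' `n_tags` samples pooled into one lane, a fraction of droplets holding two
#' cells, ambient hashtag background, clustered transcriptomes with planted
#' marker genes, an antibody panel with cluster-specific means, and a skewed
#' clonotype distribution per sample.
#'
#' @param n_cells number of cell barcodes (droplets).
#' @param n_tags number of hashtag-labeled samples (treated as patients).
#' @param doublet_rate fraction of droplets co-encapsulating two cells.
#' @param ambient_fraction share of a cell's HTO counts drawn uniformly from
#'   the non-own tags (ambient background).
#' @param n_genes,n_clusters,markers_per_cluster transcriptome structure;
#'   `n_clusters * markers_per_cluster` genes are reserved as markers.
#' @param marker_fold multiplicative mean elevation of a marker gene in its
#'   own cluster (>= 1).
#' @param adt_panel_size number of antibodies in the ADT panel.
#' @param clonotype_concentration concentration of the Chinese-restaurant
#'   clone-assignment process; smaller values give more clonal expansion.
#' @param hto_depth mean total HTO UMIs per cell.
#' @param gene_depth median baseline mean counts per gene per cell.
#' @param gene_sdlog log-scale spread of baseline gene means; the default
#'   keeps marker elevation detectable in both mean and detection fraction.
#' @param nb_dispersion negative-binomial size parameter shared by the count
#'   models (Poisson-gamma mixing).
#' @param trb_rate fraction of cells with an annotated TRB chain.
#' @param tra_rate fraction of TRB-assigned cells that also carry TRA.
#' @param seed integer seed; the seed fully determines the simulated run.
#' @return a validated `multiplex_sim_config` list.
#' @export
multiplex_sim_config <- function(n_cells = 2000, n_tags = 4,
                                 doublet_rate = 0.08, ambient_fraction = 0.05,
                                 n_genes = 500, n_clusters = 5,
                                 markers_per_cluster = 20, marker_fold = 4,
                                 adt_panel_size = 23,
                                 clonotype_concentration = 5,
                                 hto_depth = 200, gene_depth = 0.5,
                                 gene_sdlog = 0.5, nb_dispersion = 10,
                                 trb_rate = 0.9, tra_rate = 0.86,
                                 seed = 1L) {
  cfg <- list(
    n_cells = check_count(n_cells, "n_cells"),
    n_tags = check_count(n_tags, "n_tags"),
    doublet_rate = check_fraction(doublet_rate, "doublet_rate"),
    ambient_fraction = check_fraction(ambient_fraction, "ambient_fraction"),
    n_genes = check_count(n_genes, "n_genes"),
    n_clusters = check_count(n_clusters, "n_clusters"),
    markers_per_cluster = check_count(markers_per_cluster, "markers_per_cluster"),
    marker_fold = check_positive(marker_fold, "marker_fold"),
    adt_panel_size = check_count(adt_panel_size, "adt_panel_size"),
    clonotype_concentration = check_positive(clonotype_concentration,
                                             "clonotype_concentration"),
    hto_depth = check_positive(hto_depth, "hto_depth"),
    gene_depth = check_positive(gene_depth, "gene_depth"),
    gene_sdlog = check_positive(gene_sdlog, "gene_sdlog"),
    nb_dispersion = check_positive(nb_dispersion, "nb_dispersion"),
    trb_rate = check_fraction(trb_rate, "trb_rate"),
    tra_rate = check_fraction(tra_rate, "tra_rate"),
    seed = as.integer(seed))
  if (cfg$marker_fold < 1) stop_config("marker_fold must be >= 1")
  if (cfg$n_tags < 2 && cfg$doublet_rate > 0)
    stop_config("doublets require at least 2 tags")
  if (cfg$n_clusters * cfg$markers_per_cluster > cfg$n_genes)
    stop_config("n_genes too small for the requested marker structure")
  class(cfg) <- "multiplex_sim_config"
  cfg
}

# One singlet's expected HTO composition: own tag gets 1 - ambient_fraction,
# the ambient share is split uniformly over the other tags.
hto_prob <- function(tag, n_tags, ambient) {
  p <- rep(ambient / max(1, n_tags - 1), n_tags)
  p[tag] <- 1 - ambient
  p
}

random_cdr3 <- function(n, len = 30L) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# Chinese-restaurant assignment of n cells to clones; concentration alpha
# controls expansion skew (small alpha -> few large clones).
crp_assign <- function(n, alpha) {
  z <- integer(n)
  if (n == 0L) return(z)
  z[1] <- 1L
  k <- 1L
  sizes <- 1
  for (i in seq_len(n)[-1]) {
    p <- c(sizes, alpha)
    pick <- sample.int(k + 1L, 1L, prob = p)
    if (pick > k) {
      k <- k + 1L
      sizes <- c(sizes, 1)
      z[i] <- k
    } else {
      sizes[pick] <- sizes[pick] + 1
      z[i] <- pick
    }
  }
  z
}

#' Simulate a multiplexed droplet run with ground truth
#'
#' Generates, from one seed, the four linked observables of a hashed
#' CITE-seq lane — HTO counts, ADT counts, gene counts and a clonotype
#' table — plus the ground-truth labels used by downstream tests.
#'
#' Singlet droplets concentrate HTO counts on the true tag with a uniform
#' ambient background; doublets are sums of two independently drawn singlet
#' profiles with distinct tags. Gene and ADT counts are negative binomial
#' (Poisson-gamma) with cluster-specific means; each cluster elevates its
#' own marker genes by `marker_fold`. Clonotypes are drawn per patient from
#' a Chinese-restaurant process so expanded clones exist.
#'
#' @param config a [multiplex_sim_config()].
#' @return list with elements `hto` (tags x barcodes), `adt`
#'   (antibodies x barcodes), `expr` (genes x barcodes counts),
#'   `clonotypes` (10x-style contig rows for singlet cells),
#'   `cell_meta` (barcode, patient, tissue, condition, cluster) and
#'   `truth` (per-barcode tag, doublet flag and second tag, cluster,
#'   clone id; per-cluster marker gene list).
#' @export
simulate_multiplexed_run <- function(config) {
  if (!inherits(config, "multiplex_sim_config"))
    config <- do.call(multiplex_sim_config, config)
  with_seed(config$seed, {
    n <- config$n_cells
    barcodes <- sprintf("cell%05d", seq_len(n))
    tags <- paste0("HTO", seq_len(config$n_tags))

    tag1 <- sample.int(config$n_tags, n, replace = TRUE)
    is_doublet <- stats::rbinom(n, 1L, config$doublet_rate) == 1L
    tag2 <- rep(NA_integer_, n)
    tag2[is_doublet] <- vapply(tag1[is_doublet], function(t)
      sample(setdiff(seq_len(config$n_tags), t), 1L), integer(1))

    # HTO counts: each contributing cell draws its own total and multinomial
    # split; a doublet is the sum of its two cells' profiles.
    draw_hto <- function(tag) {
      tot <- stats::rnbinom(1L, mu = config$hto_depth, size = config$nb_dispersion)
      if (tot == 0L) return(integer(config$n_tags))
      stats::rmultinom(1L, tot, hto_prob(tag, config$n_tags,
                                         config$ambient_fraction))[, 1]
    }
    hto <- vapply(seq_len(n), function(i) {
      x <- draw_hto(tag1[i])
      if (is_doublet[i]) x <- x + draw_hto(tag2[i])
      x
    }, numeric(config$n_tags))
    hto <- matrix(hto, nrow = config$n_tags,
                  dimnames = list(tags, barcodes))

    cluster <- sample.int(config$n_clusters, n, replace = TRUE)
    clusters <- paste0("C", seq_len(config$n_clusters))

    genes <- sprintf("G%04d", seq_len(config$n_genes))
    base_mu <- stats::rlnorm(config$n_genes, meanlog = log(config$gene_depth),
                             sdlog = config$gene_sdlog)
    marker_idx <- split(seq_len(config$n_clusters * config$markers_per_cluster),
                        rep(seq_len(config$n_clusters),
                            each = config$markers_per_cluster))
    mu <- matrix(base_mu, nrow = config$n_genes, ncol = n)
    for (k in seq_len(config$n_clusters))
      mu[marker_idx[[k]], cluster == k] <-
        mu[marker_idx[[k]], cluster == k] * config$marker_fold
    expr <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = config$nb_dispersion),
                   nrow = config$n_genes, dimnames = list(genes, barcodes))

    antibodies <- sprintf("ADT%02d", seq_len(config$adt_panel_size))
    adt_mu <- matrix(stats::rlnorm(config$adt_panel_size * config$n_clusters,
                                   meanlog = log(20), sdlog = 1),
                     nrow = config$adt_panel_size,
                     dimnames = list(antibodies, clusters))
    adt <- matrix(stats::rnbinom(config$adt_panel_size * n,
                                 mu = adt_mu[, cluster],
                                 size = config$nb_dispersion),
                  nrow = config$adt_panel_size,
                  dimnames = list(antibodies, barcodes))

    tissue <- sample(c("tumor", "normal"), n, replace = TRUE)
    condition <- sample(c("nonstimulated", "stimulated"), n, replace = TRUE)

    # Clonotypes for singlet cells only: per-patient CRP clone assignment,
    # unique CDR3nt per clone within a patient.
    singlet <- which(!is_doublet)
    clone_id <- rep(NA_character_, n)
    contigs <- list()
    for (t in seq_len(config$n_tags)) {
      cells_t <- singlet[tag1[singlet] == t]
      has_trb <- cells_t[stats::rbinom(length(cells_t), 1L,
                                       config$trb_rate) == 1L]
      if (length(has_trb) == 0L) next
      z <- crp_assign(length(has_trb), config$clonotype_concentration)
      cdr3 <- random_cdr3(max(z))
      clone_id[has_trb] <- paste0("P", t, "_clone", z)
      has_tra <- stats::rbinom(length(has_trb), 1L, config$tra_rate) == 1L
      trb <- data.frame(barcode = barcodes[has_trb],
                        patient = paste0("P", t),
                        tissue = tissue[has_trb],
                        chain = "TRB",
                        cdr3_nt = cdr3[z],
                        productive = TRUE)
      tra <- data.frame(barcode = barcodes[has_trb][has_tra],
                        patient = paste0("P", t),
                        tissue = tissue[has_trb][has_tra],
                        chain = "TRA",
                        cdr3_nt = random_cdr3(sum(has_tra)),
                        productive = TRUE)
      contigs[[t]] <- rbind(trb, tra)
    }
    clonotypes <- do.call(rbind, contigs)
    rownames(clonotypes) <- NULL

    cell_meta <- data.frame(
      barcode = barcodes,
      patient = paste0("P", tag1),
      tissue = tissue,
      condition = condition,
      cluster = clusters[cluster])

    truth <- list(
      tag = stats::setNames(tags[tag1], barcodes),
      doublet = stats::setNames(is_doublet, barcodes),
      second_tag = stats::setNames(ifelse(is.na(tag2), NA_character_,
                                          tags[tag2]), barcodes),
      cluster = stats::setNames(clusters[cluster], barcodes),
      clone_id = stats::setNames(clone_id, barcodes),
      markers = stats::setNames(lapply(marker_idx, function(i) genes[i]),
                                clusters))

    list(hto = hto, adt = adt, expr = expr, clonotypes = clonotypes,
         cell_meta = cell_meta, truth = truth)
  })
}
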