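contig_row <- function(barcode, patient, chain, cdr3, tissue = "tumor") {
  data.frame(barcode = barcode, patient = patient, tissue = tissue,
             chain = chain, cdr3_nt = cdr3, productive = TRUE)
}

test_that("clonotypes key on TRB CDR3 within patient", {
  contigs <- rbind(
    contig_row("bc1", "P1", "TRB", "AAA"),
    contig_row("bc2", "P1", "TRB", "AAA"),
    contig_row("bc3", "P2", "TRB", "AAA"),   # same CDR3, other patient
    contig_row("bc4", "P1", "TRB", "CCC"),
    contig_row("bc4", "P1", "TRA", "GGG"),   # paired cell
    contig_row("bc5", "P1", "TRA", "TTT"))   # TRA only -> unassigned
  tab <- build_clonotypes(contigs)
  ids <- setNames(tab$clonotype_id, tab$barcode)
  expect_identical(ids[["bc1"]], ids[["bc2"]])
  expect_false(identical(ids[["bc1"]], ids[["bc3"]]))
  expect_false(identical(ids[["bc1"]], ids[["bc4"]]))
  expect_true(is.na(ids[["bc5"]]))
  expect_true(tab$paired[tab$barcode == "bc4"])
  s <- clonotype_summary(tab)
  expect_equal(s$n_cells, 5L)
  expect_equal(s$n_assigned, 4L)
  expect_equal(s$n_paired, 1L)
  # malformed rows are skipped, not fatal
  expect_message(build_clonotypes(rbind(contigs,
    contig_row("", "P1", "TRB", "AAA"))), "malformed")
})

test_that("assigned and paired percentages are integer-rounded ratios", {
  # e.g. 6 of 7 assigned -> 86%
  contigs <- rbind(
    do.call(rbind, lapply(1:6, function(i)
      contig_row(paste0("b", i), "P1", "TRB", paste0("S", i)))),
    contig_row("b7", "P1", "TRA", "X"))
  s <- clonotype_summary(build_clonotypes(contigs))
  expect_equal(s$assigned_pct, round(100 * 6 / 7))
})

test_that("clone frequencies use patient-by-tissue denominators", {
  contigs <- rbind(
    contig_row(paste0("t", 1:3), "P1", "TRB", c("A", "A", "B"), "tumor"),
    contig_row(paste0("n", 1:2), "P1", "TRB", c("A", "C"), "normal"))
  freq <- clone_frequencies(build_clonotypes(contigs))
  f <- setNames(freq$frequency, freq$barcode)
  expect_equal(f[["t1"]], 2 / 3)   # clone of 2 among 3 tumor cells
  expect_equal(f[["t3"]], 1 / 3)
  expect_equal(f[["n1"]], 1 / 2)   # same CDR3, separate normal denominator
  # conservation: sum of 1/clone_size per group = number of distinct clones
  grp <- paste(freq$patient, freq$tissue)
  for (g in unique(grp)) {
    sub <- freq[grp == g, ]
    expect_equal(sum(1 / sub$clone_size),
                 length(unique(sub$clonotype_id)))
  }
})

test_that("clonal composition bins proportions that sum to one", {
  contigs <- rbind(
    contig_row(paste0("s", 1:4), "P1", "TRB", paste0("U", 1:4)),  # singletons
    contig_row(paste0("e", 1:4), "P1", "TRB", rep("EXP", 4)))     # one clone
  tab <- build_clonotypes(contigs)
  labels <- setNames(rep(c("K1", "K2"), each = 4),
                     c(paste0("s", 1:4), paste0("e", 1:4)))
  comp <- clonal_composition(tab, labels, bins = list(c(1, 1), c(2, Inf)))
  expect_equal(unname(comp["K1", ]), c(1, 0))
  expect_equal(unname(comp["K2", ]), c(0, 1))
  expect_equal(unname(rowSums(comp)), c(1, 1))
  expect_error(clonal_composition(tab, labels,
                                  bins = list(c(1, 2), c(2, 5))),
               "overlap")
})

test_that("expansion skew shows up in the composition of a skewed run", {
  skewed <- simulate_multiplexed_run(multiplex_sim_config(
    n_cells = 1500, clonotype_concentration = 1, seed = 71))
  uniform <- simulate_multiplexed_run(multiplex_sim_config(
    n_cells = 1500, clonotype_concentration = 100, seed = 71))
  mass_expanded <- function(run) {
    tab <- build_clonotypes(run$clonotypes)
    labels <- setNames(run$cell_meta$cluster, run$cell_meta$barcode)
    comp <- clonal_composition(tab, labels, bins = list(c(1, 1), c(2, Inf)))
    mean(comp[, 2])
  }
  expect_gt(mass_expanded(skewed), mass_expanded(uniform))
})

test_that("sharing test behaves at its degenerate extremes", {
  contigs <- rbind(
    contig_row(paste0("a", 1:3), "P1", "TRB", paste0("A", 1:3)),
    contig_row(paste0("b", 1:3), "P1", "TRB", paste0("B", 1:3)))
  tab <- build_clonotypes(contigs)
  labels <- setNames(rep(c("K1", "K2"), each = 3),
                     c(paste0("a", 1:3), paste0("b", 1:3)))
  disjoint <- tcr_sharing_test(tab, labels, "K1", "K2", n_perm = 200)
  expect_equal(disjoint$shared, 0L)
  expect_equal(disjoint$p, 1)

  same <- rbind(contig_row(c("x1", "x2"), "P1", "TRB", "SAME"))
  tab2 <- build_clonotypes(same)
  lab2 <- setNames(c("K1", "K2"), c("x1", "x2"))
  ident <- tcr_sharing_test(tab2, lab2, "K1", "K2", n_perm = 200)
  expect_equal(ident$shared, 1L)
  expect_equal(ident$p, 1)
  expect_warning(tcr_sharing_test(tab, labels, "K1", "K2", n_perm = 50),
                 "coarse")
})

test_that("planted sharing is detected and the null is reproducible", {
  set.seed(72)
  # 50 clones per cluster, a fifth of all clones seeded in both clusters
  shared_cl <- paste0("SH", 1:15)
  a_only <- paste0("AO", 1:35)
  b_only <- paste0("BO", 1:35)
  contigs <- rbind(
    contig_row(sprintf("a%02d", 1:50), "P1", "TRB", c(shared_cl, a_only)),
    contig_row(sprintf("b%02d", 1:50), "P1", "TRB", c(shared_cl, b_only)))
  tab <- build_clonotypes(contigs)
  labels <- setNames(rep(c("K1", "K2"), each = 50),
                     c(sprintf("a%02d", 1:50), sprintf("b%02d", 1:50)))
  res <- tcr_sharing_test(tab, labels, "K1", "K2", n_perm = 10000, seed = 3)
  expect_lt(res$p, 0.01)
  res2 <- tcr_sharing_test(tab, labels, "K1", "K2", n_perm = 10000, seed = 3)
  expect_identical(res, res2)
  expect_gt(res$p, 0)
  expect_lte(res$p, 1)
})
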