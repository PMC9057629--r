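ranked_from <- function(stats) {
  o <- order(-stats, names(stats))
  list(genes = names(stats)[o], stat = unname(stats[o]))
}

test_that("per-patient z-ranking standardizes against the cohort", {
  expr <- rbind(gA = c(2, 4, 6), gB = c(10, 10, 10), gC = c(1, 0, 2))
  colnames(expr) <- paste0("p", 1:3)
  expect_message(ranks <- per_patient_zranks(expr), "zero-variance")
  # gene (2,4,6): sample sd 2, z = (-1, 0, 1)
  zA <- vapply(ranks, function(r) r$stat[r$genes == "gA"], numeric(1))
  expect_equal(unname(zA), c(-1, 0, 1))
  # constant gene excluded from every ranking
  expect_false(any(vapply(ranks, function(r) "gB" %in% r$genes, logical(1))))
  # a patient at the cohort mean ranks by the gene-id tie-break
  expr2 <- rbind(g2 = c(1, 2, 3), g1 = c(4, 5, 6))
  colnames(expr2) <- paste0("p", 1:3)
  r2 <- per_patient_zranks(expr2)
  expect_identical(r2$p2$genes, c("g1", "g2"))
  expect_equal(r2$p2$stat, c(0, 0))
  expect_error(per_patient_zranks(expr[, 1:2]), "3 patients")
})

test_that("extreme gene-set placements give unit enrichment scores", {
  stats <- setNames(c(9, 7, 5, 3, 1, 0.5), paste0("g", 1:6))
  for (pw in c(0, 1, 2)) {
    expect_equal(enrichment_score(stats, c("g1", "g2"), pw)$es, 1)
    expect_equal(enrichment_score(stats, c("g5", "g6"), pw)$es, -1)
  }
  expect_error(enrichment_score(stats, "absent"), "intersect")
  expect_error(enrichment_score(stats, paste0("g", 1:6)), "whole universe")
})

test_that("the worked running sum matches the brute-force oracle", {
  stats <- setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5))
  sc <- enrichment_score(stats, c("g1", "g4"), p_w = 1)
  oracle <- weighted_es_oracle(c(5, 4, 3, 2, 1), c(1, 4), p_w = 1)
  expect_equal(sc$es, 5 / 7, tolerance = 1e-12)
  expect_equal(sc$running, oracle$running, tolerance = 1e-12)
  expect_equal(sc$running, c(5 / 7, 5 / 7 - 1 / 3, 5 / 7 - 2 / 3, 1 / 3, 0),
               tolerance = 1e-12)
  expect_identical(sc$leading_edge, "g1")
})

test_that("unweighted scores equal the exhaustive KS statistic", {
  for (N in 2:8) {
    stats <- setNames(sort(rnorm(N), decreasing = TRUE), paste0("g", 1:N))
    subsets <- unlist(lapply(seq_len(N - 1), function(k)
      combn(N, k, simplify = FALSE)), recursive = FALSE)
    for (pos in subsets) {
      es <- enrichment_score(stats, paste0("g", pos), p_w = 0)$es
      expect_equal(es, ks_oracle(N, pos), tolerance = 1e-12)
    }
  }
})

test_that("scores agree with an independent preranked implementation", {
  skip_if_not_installed("fgsea")
  set.seed(81)
  for (i in 1:25) {
    N <- sample(50:200, 1)
    stats <- setNames(sort(rnorm(N), decreasing = TRUE),
                      sprintf("g%03d", 1:N))
    set_genes <- sample(names(stats), sample(3:20, 1))
    es <- enrichment_score(stats, set_genes, p_w = 1)$es
    ref <- fgsea::calcGseaStat(stats,
                               selectedStats = which(names(stats) %in%
                                                       set_genes),
                               gseaParam = 1)
    expect_equal(es, ref, tolerance = 1e-10)
  }
})

test_that("negating and reversing a ranking negates the score", {
  set.seed(82)
  for (i in 1:10) {
    stats <- setNames(sort(rnorm(40), decreasing = TRUE),
                      sprintf("g%02d", 1:40))
    set_genes <- sample(names(stats), 8)
    es <- enrichment_score(stats, set_genes, 1)$es
    flipped <- rev(-stats)
    es_flip <- enrichment_score(flipped, set_genes, 1)$es
    expect_equal(es_flip, -es, tolerance = 1e-12)
    expect_within(es, -1, 1)
  }
})

test_that("permutation significance is seeded, bounded and flags degeneracy", {
  stats <- setNames(sort(rnorm(100), decreasing = TRUE), sprintf("g%03d", 1:100))
  params <- enrichment_params(n_perm = 500, seed = 7)
  a <- gsea_significance(stats, names(stats)[1:10], params)
  b <- gsea_significance(stats, names(stats)[1:10], params)
  expect_identical(a, b)
  expect_gt(a$p, 0)
  expect_lte(a$p, 1)
  expect_equal(sign(a$nes), sign(a$es))
  expect_gt(a$nes, 1)  # top-concentrated set beats the null mean
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(83)
  for (i in 1:200) {
    p <- runif(sample(1:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj[order(p)] == cummax(adj[order(p)])))  # monotone
    expect_true(all(adj >= p - 1e-15))
  }
})

test_that("patient classification follows the NES and adjusted-p rule", {
  res <- data.frame(patient = c("p1", "p2", "p3"), set = "s",
                    nes = c(2.1, -1.8, 1.5), p = c(0.001, 0.01, 0.15),
                    padj = c(0.01, 0.03, 0.20))
  out <- classify_patients(res, enrichment_params(n_perm = 100))
  expect_identical(out$class, c("enriched", "depleted", "neither"))
  expect_error(classify_patients(res[, -5], enrichment_params(n_perm = 100)),
               "adjusted")
})

test_that("cohort-level enrichment recovers the planted classes", {
  sim <- simulate_bulk_cohort(cohort_sim_config(
    n_patients = 150, n_genes = 800, signature_size = 60, seed = 84))
  params <- enrichment_params(n_perm = 500, seed = 3)
  res <- classify_patients(
    gsea_cohort(sim$cohort$expr, list(sig = sim$signature$genes), params),
    params)
  cls <- setNames(res$class, res$patient)
  tr <- sim$truth$class
  expect_gte(mean(cls[tr == "enriched"] == "enriched"), 0.9)
  expect_gte(mean(cls[tr == "depleted"] == "depleted"), 0.9)
  expect_gte(mean(cls[tr == "neither"] == "neither"), 0.9)
  expect_true(all(res$padj >= res$p - 1e-15))
})
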