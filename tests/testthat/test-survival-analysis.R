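test_that("the product-limit estimate matches hand computation", {
  # all events: empirical survival
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # all censored: flat at 1
  km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  # censoring at 2 removes that subject from the risk set: the last event
  # happens in a risk set of one, so the curve steps to zero
  km1 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km1$surv[km1$time == 1], 2 / 3)
  expect_equal(km1$surv[km1$time == 3], 2 / 3 * (1 - 1 / 1))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("uncensored Kaplan-Meier equals the empirical survival function", {
  set.seed(91)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    t <- round(rexp(n, 0.1), 2)
    km <- km_estimate(t, rep(1, n))
    expect_equal(km$surv, empirical_surv(t, sort(unique(t))),
                 tolerance = 1e-12)
  }
})

test_that("the two-group log-rank toy reproduces the O-E statistic", {
  time <- c(1, 2, 3, 4)
  event <- rep(1, 4)
  group <- c("a", "a", "b", "b")
  res <- logrank_test(time, event, group)
  # hand computation: O-E = 2 - (1/2 + 1/3), variance sum = 1/4 + 2/9 + 1/4
  oe <- 2 - (1 / 2 + 1 / 3 + 0 + 0)
  v <- 1 / 4 + 2 / 9 + 0 + 0
  expect_equal(res$chisq, oe^2 / v, tolerance = 1e-9)
  # the observed split maximizes chi-square over all group assignments, so
  # its exact permutation p is the minimum: the ranks agree
  perms <- combn(4, 2, function(ia) {
    g <- rep("b", 4)
    g[ia] <- "a"
    logrank_test(time, event, g)$chisq
  })
  expect_equal(max(perms), res$chisq, tolerance = 1e-9)
  expect_equal(logrank_perm_p(time, event, group), 2 / 6)
  expect_equal(res$chisq, 2.882353, tolerance = 1e-6)
  # symmetric in group order
  expect_equal(logrank_test(time, event, rev(group))$chisq, res$chisq)
  # invariant to time-unit rescaling
  expect_equal(logrank_test(time * 30.4, event, group)$chisq, res$chisq)
})

test_that("chi-square p ranks agree with exact permutation p on small data", {
  set.seed(92)
  cases <- lapply(1:6, function(i) {
    n <- 6
    list(time = round(rexp(n, 0.2) + 0.01, 3),
         group = rep(c("a", "b"), each = 3))
  })
  chisq_p <- vapply(cases, function(cs)
    logrank_test(cs$time, rep(1, 6), cs$group)$p, numeric(1))
  perm_p <- vapply(cases, function(cs)
    logrank_perm_p(cs$time, rep(1, 6), cs$group), numeric(1))
  # rank agreement at the resolution the discrete permutation p supports
  for (i in seq_along(cases)) for (j in seq_along(cases)) {
    if (chisq_p[i] + 0.05 < chisq_p[j] && abs(perm_p[i] - perm_p[j]) > 0.05)
      expect_lt(perm_p[i], perm_p[j])
  }
})

test_that("degenerate log-rank inputs are flagged, not fatal", {
  expect_error(logrank_test(1:4, rep(1, 4), rep("a", 4)), "2 groups")
  same <- logrank_test(c(1, 2, 1, 2), c(1, 1, 1, 1), c("a", "a", "b", "b"))
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-9)
  none <- logrank_test(c(1, 2), c(0, 0), c("a", "b"))
  expect_true(none$degenerate)
  expect_equal(none$p, 1)
})

test_that("log-rank detects a planted hazard ratio with high power", {
  set.seed(93)
  rejections <- vapply(1:60, function(i) {
    t1 <- rexp(100, 0.02)
    t2 <- rexp(100, 0.06)
    logrank_test(c(t1, t2), rep(1, 200),
                 rep(c("e", "d"), each = 100))$p < 0.01
  }, logical(1))
  expect_gte(mean(rejections), 0.95)
})

test_that("stratified comparison restricts stages and drops 'neither'", {
  sim <- simulate_bulk_cohort(cohort_sim_config(
    n_patients = 400, n_genes = 50, signature_size = 10,
    hazard_ratio_depleted_vs_enriched = 4, seed = 94))
  cls <- sim$truth$class  # use truth directly; enrichment tested elsewhere
  all_st <- stratified_survival(sim$cohort$clinical, cls)
  expect_false(all_st$flagged)
  expect_lt(all_st$test$p, 0.01)
  expect_identical(
    all_st$test$chisq,
    stratified_survival(sim$cohort$clinical, cls,
                        stages_subset = c("I", "II", "III", "IV"))$test$chisq)
  sub <- stratified_survival(sim$cohort$clinical, cls,
                             stages_subset = c("II", "III"))
  expect_false(sub$flagged)
  expect_true(all(sub$n[c("enriched", "depleted")] <
                    all_st$n[c("enriched", "depleted")]))
  # restriction that empties a class is flagged, no test
  cl2 <- sim$cohort$clinical
  drop <- cl2$stage == "I" & cls[cl2$patient_id] == "depleted"
  cls2 <- cls
  cls2[cl2$patient_id[!drop & cls == "depleted"]] <- "neither"
  flagged <- stratified_survival(cl2, cls2, stages_subset = c("II", "III"))
  expect_true(flagged$flagged)
  expect_null(flagged$test)
})

test_that("stage parsing and composition summaries are correct", {
  expect_equal(parse_stage(c("Stage IIA", "III", "stage iv", "I", "x")),
               c(2L, 3L, 4L, 1L, NA))
  cls <- setNames(c(rep("enriched", 4), rep("depleted", 4)),
                  paste0("p", 1:8))
  stg <- setNames(c(rep("II", 4), "I", "II", "III", "IV"), paste0("p", 1:8))
  comp <- stage_composition(cls, stg)
  expect_equal(unname(comp$proportions["enriched", ]), c(0, 1, 0, 0))
  expect_equal(unname(comp$mean_stage["enriched"]), 2)
  expect_equal(unname(comp$mean_stage["depleted"]), 2.5)
  expect_message(
    stage_composition(cls, replace(stg, 1, "unknown")), "excluded")
})

test_that("classification overlap reports printed-count percentages", {
  pts <- sprintf("p%03d", 1:100)
  class_a <- setNames(rep("neither", 100), pts)
  class_a[1:33] <- "enriched"
  class_b <- setNames(rep("neither", 100), pts)
  class_b[c(1:25, 40:47)] <- "enriched"
  ov <- classification_overlap(class_a, class_b)
  expect_equal(ov$n_both, 25L)
  expect_equal(ov$n_a, 33L)
  expect_equal(ov$percent, 76)
  expect_equal(classification_overlap(class_a, class_a)$percent, 100)
  expect_equal(
    classification_overlap(class_a,
                           setNames(rep("neither", 100), pts))$n_both, 0L)
  expect_error(classification_overlap(class_a, class_b[1:50]), "universe")
})
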