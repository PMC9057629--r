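#' Configuration for a simulated bulk survival cohort
#'
#' Defines a bulk log2 expression cohort with a planted gene signature:
#' a subset of patients ("enriched") has the signature genes shifted up by
#' `effect_size` standard deviations, another subset ("depleted") shifted
#' down, and overall survival follows an exponential proportional-hazards
#' model whose hazard depends on the enrichment class and tumor stage.
#'
#' @param n_patients,n_genes cohort dimensions.
#' @param signature_size number of planted signature genes.
#' @param enriched_fraction,depleted_fraction fractions of patients in each
#'   class; their sum must not exceed 1.
#' @param effect_size mean shift, in per-gene standard-deviation (z) units,
#'   applied to signature genes of enriched (+) / depleted (-) patients.
#' @param baseline_hazard events per month for the enriched class at the
#'   reference stage (II).
#' @param hazard_ratio_depleted_vs_enriched hazard ratio of the depleted
#'   class relative to enriched; the "neither" class sits at the geometric
#'   midpoint.
#' @param stage_hazard_ratio per-stage multiplicative hazard step (stage II
#'   is the reference).
#' @param censor_rate probability that a patient's follow-up is censored
#'   (uniformly before the event time).
#' @param stage_probs probability vector over stages I-IV.
#' @param seed integer seed.
#' @return a validated `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_patients = 300, n_genes = 2000,
                              signature_size = 100,
                              enriched_fraction = 0.2,
                              depleted_fraction = 0.2,
                              effect_size = 1.5,
                              baseline_hazard = 0.02,
                              hazard_ratio_depleted_vs_enriched = 3,
                              stage_hazard_ratio = 1.3,
                              censor_rate = 0.3,
                              stage_probs = c(0.15, 0.35, 0.35, 0.15),
                              seed = 1L) {
  cfg <- list(
    n_patients = check_count(n_patients, "n_patients"),
    n_genes = check_count(n_genes, "n_genes"),
    signature_size = check_count(signature_size, "signature_size"),
    enriched_fraction = check_fraction(enriched_fraction, "enriched_fraction"),
    depleted_fraction = check_fraction(depleted_fraction, "depleted_fraction"),
    effect_size = effect_size,
    baseline_hazard = check_positive(baseline_hazard, "baseline_hazard"),
    hazard_ratio_depleted_vs_enriched =
      check_positive(hazard_ratio_depleted_vs_enriched,
                     "hazard_ratio_depleted_vs_enriched"),
    stage_hazard_ratio = check_positive(stage_hazard_ratio,
                                        "stage_hazard_ratio"),
    censor_rate = check_fraction(censor_rate, "censor_rate"),
    stage_probs = stage_probs,
    seed = as.integer(seed))
  if (cfg$enriched_fraction + cfg$depleted_fraction > 1)
    stop_config("enriched_fraction + depleted_fraction must not exceed 1")
  if (length(cfg$stage_probs) != 4L || any(cfg$stage_probs < 0) ||
      abs(sum(cfg$stage_probs) - 1) > 1e-8)
    stop_config("stage_probs must be 4 nonnegative probabilities summing to 1")
  if (cfg$signature_size > cfg$n_genes)
    stop_config("signature_size cannot exceed n_genes")
  class(cfg) <- "cohort_sim_config"
  cfg
}

#' Simulate a bulk expression cohort with survival and a planted signature
#'
#' Baseline log2 expression is Gaussian per gene; signature genes are
#' shifted by `effect_size` per-gene standard deviations (up in enriched,
#' down in depleted patients). Overall survival times are exponential with
#' hazard `baseline_hazard * class_multiplier * stage_hazard_ratio^(stage-2)`
#' where the class multiplier is 1 (enriched), the square root of the
#' depleted-vs-enriched hazard ratio ("neither"), or the full ratio
#' (depleted). With probability `censor_rate` a patient is censored at a
#' uniform fraction of the event time, so the expected censoring rate
#' equals the configured one exactly.
#'
#' @param config a [cohort_sim_config()].
#' @return list with `cohort` (list `expr`: genes x patients log2 matrix;
#'   `clinical`: data frame patient_id, os_months, os_event, stage),
#'   `signature` (the planted [gene_signature]) and `truth` (per-patient
#'   class in enriched/depleted/neither; planted signature gene ids).
#' @export
simulate_bulk_cohort <- function(config) {
  if (!inherits(config, "cohort_sim_config"))
    config <- do.call(cohort_sim_config, config)
  with_seed(config$seed, {
    n <- config$n_patients
    patients <- sprintf("PT%04d", seq_len(n))
    genes <- sprintf("G%04d", seq_len(config$n_genes))

    n_enr <- round(n * config$enriched_fraction)
    n_dep <- round(n * config$depleted_fraction)
    class_true <- sample(rep(c("enriched", "depleted", "neither"),
                             c(n_enr, n_dep, n - n_enr - n_dep)))
    names(class_true) <- patients

    gene_mean <- stats::rnorm(config$n_genes, mean = 8, sd = 2)
    gene_sd <- stats::runif(config$n_genes, 0.5, 1.5)
    expr <- matrix(stats::rnorm(config$n_genes * n, mean = gene_mean,
                                sd = gene_sd),
                   nrow = config$n_genes, dimnames = list(genes, patients))

    sig_genes <- sort(sample(genes, config$signature_size))
    si <- match(sig_genes, genes)
    shift <- config$effect_size * gene_sd[si]
    expr[si, class_true == "enriched"] <-
      expr[si, class_true == "enriched"] + shift
    expr[si, class_true == "depleted"] <-
      expr[si, class_true == "depleted"] - shift

    stage <- sample.int(4L, n, replace = TRUE, prob = config$stage_probs)
    hr <- config$hazard_ratio_depleted_vs_enriched
    class_mult <- c(enriched = 1, neither = sqrt(hr), depleted = hr)
    hazard <- config$baseline_hazard * class_mult[class_true] *
      config$stage_hazard_ratio^(stage - 2)
    event_time <- stats::rexp(n, rate = hazard)
    censored <- stats::rbinom(n, 1L, config$censor_rate) == 1L
    os_months <- ifelse(censored, stats::runif(n) * event_time, event_time)

    clinical <- data.frame(
      patient_id = patients,
      os_months = os_months,
      os_event = as.integer(!censored),
      stage = c("I", "II", "III", "IV")[stage])

    signature <- new_gene_signature(
      name = "planted_signature", genes = sig_genes,
      stat = data.frame(gene = sig_genes,
                        effect = rep(config$effect_size, length(sig_genes))),
      method = "planted",
      params = list(effect_size = config$effect_size))

    list(cohort = list(expr = expr, clinical = clinical),
         signature = signature,
         truth = list(class = class_true, signature_genes = sig_genes))
  })
}
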