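#' Kaplan-Meier estimate
#'
#' Product-limit estimate of overall survival, computed with
#' [survival::survfit()]. Ties between events and censorings at the same
#' time follow the standard convention that events precede censorings.
#'
#' @param time follow-up times in months (nonnegative).
#' @param event event indicator (1 = death, 0 = censored).
#' @param group optional group labels; one curve per group.
#' @return data frame: group, time, n_risk, n_event, n_censor, surv — the
#'   step values of the estimator at the observed times (S(0) = 1 is
#'   implicit).
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (any(time < 0)) stop("negative survival time")
  if (is.null(group)) group <- rep("all", length(time))
  fit <- survival::survfit(survival::Surv(time, event) ~ g,
                           data = data.frame(time = time, event = event,
                                             g = group))
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(unique(group)[1], length(s$time))
         else sub("^g=", "", as.character(s$strata))
  data.frame(group = grp, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event,
             n_censor = if (!is.null(s$n.censor)) s$n.censor else 0,
             surv = s$surv)
}

#' Two-group log-rank test
#'
#' Observed-minus-expected statistic with hypergeometric variance summed
#' over event times, referred to chi-square with 1 df, via
#' [survival::survdiff()]. A comparison with no events (or an empty risk
#' set throughout) is degenerate and returns p = 1, flagged.
#'
#' @inheritParams km_estimate
#' @param group two-level group labels.
#' @return list: chisq, df, p, n (per-group sizes), degenerate.
#' @export
logrank_test <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) != 2L) stop("logrank_test compares exactly 2 groups")
  if (any(table(g) == 0L)) stop("both groups must be nonempty")
  if (sum(event) == 0L)
    return(list(chisq = 0, df = 1L, p = 1, n = table(g), degenerate = TRUE))
  sd <- survival::survdiff(survival::Surv(time, event) ~ g,
                           data = data.frame(time = time, event = event,
                                             g = g))
  if (!is.finite(sd$chisq))
    return(list(chisq = 0, df = 1L, p = 1, n = table(g), degenerate = TRUE))
  list(chisq = unname(sd$chisq), df = 1L,
       p = unname(stats::pchisq(sd$chisq, 1, lower.tail = FALSE)),
       n = table(g), degenerate = FALSE)
}

#' Survival comparison of enriched vs depleted patients, optionally
#' restricted to a stage subset
#'
#' Joins a classification to the clinical table, keeps the "enriched" and
#' "depleted" classes (the "neither" class is excluded), restricts to
#' `stages_subset`, and returns the Kaplan-Meier curves and log-rank test.
#' If either class is empty after restriction no test is run and the
#' result is flagged.
#'
#' @param clinical data frame with patient_id, os_months, os_event, stage.
#' @param classification named character vector patient -> class
#'   (enriched/depleted/neither), or a classified `enrichment_result`
#'   restricted to one gene set.
#' @param stages_subset stages to keep (e.g. `c("II", "III")`); default all.
#' @param three_group keep "neither" as a third group (exploratory).
#' @return list: curves (from [km_estimate()]), test (from
#'   [logrank_test()] or NULL), n (class counts), flagged.
#' @export
stratified_survival <- function(clinical, classification,
                                stages_subset = NULL, three_group = FALSE) {
  if (is.data.frame(classification)) {
    if (length(unique(classification$set)) > 1L)
      stop("restrict the enrichment result to a single gene set first")
    classification <- stats::setNames(classification$class,
                                      classification$patient)
  }
  d <- clinical
  d$class <- classification[d$patient_id]
  d$stage_num <- parse_stage(d$stage)
  if (!is.null(stages_subset))
    d <- d[d$stage %in% stages_subset |
             d$stage_num %in% parse_stage(stages_subset), , drop = FALSE]
  keep <- if (three_group) c("enriched", "depleted", "neither")
          else c("enriched", "depleted")
  d <- d[!is.na(d$class) & d$class %in% keep, , drop = FALSE]
  n <- table(factor(d$class, keep))
  if (any(n[c("enriched", "depleted")] == 0L))
    return(list(curves = NULL, test = NULL, n = n, flagged = TRUE))
  curves <- km_estimate(d$os_months, d$os_event, d$class)
  test <- if (three_group) NULL
          else logrank_test(d$os_months, d$os_event, d$class)
  list(curves = curves, test = test, n = n, flagged = FALSE)
}

#' Parse AJCC-like stage strings to numeric stage
#'
#' "Stage IIA" and "II" both map to 2; unparseable values give NA.
#'
#' @param stage character vector of stage labels.
#' @return integer vector in 1..4 (NA where unknown).
#' @export
parse_stage <- function(stage) {
  s <- toupper(trimws(sub("(?i)^stage\\s*", "", as.character(stage),
                          perl = TRUE)))
  s <- sub("^(IV|III|II|I).*$", "\\1", s)
  unname(c(I = 1L, II = 2L, III = 3L, IV = 4L)[s])
}

#' Stage composition per enrichment class
#'
#' @param classification named character vector patient -> class.
#' @param stages named character vector patient -> stage label; patients
#'   with missing/unparseable stage are excluded with a message.
#' @return list: proportions (class x stage matrix, rows sum to 1) and
#'   mean_stage (average numeric stage per class).
#' @export
stage_composition <- function(classification, stages) {
  stages <- stages[names(classification)]
  num <- parse_stage(stages)
  drop <- is.na(num)
  if (any(drop)) {
    message(sum(drop), " patient(s) without a usable stage excluded")
    classification <- classification[!drop]
    num <- num[!drop]
  }
  cl <- factor(classification)
  st <- factor(c("I", "II", "III", "IV")[num], c("I", "II", "III", "IV"))
  tab <- table(cl, st)
  list(proportions = as.matrix(tab / rowSums(tab)),
       mean_stage = tapply(num, cl, mean))
}

#' Overlap between two patient classifications
#'
#' Counts patients enriched under both classifications and reports the
#' overlap as a percentage of the first classification's enriched set
#' (rounded to the nearest integer percent), plus the full
#' enriched/depleted/neither cross-tabulation.
#'
#' @param class_a,class_b named character vectors patient -> class over
#'   the same patient universe.
#' @return list: n_both, n_a, n_b, percent, crosstab.
#' @export
classification_overlap <- function(class_a, class_b) {
  if (!setequal(names(class_a), names(class_b)))
    stop("classifications cover different patient universes")
  class_b <- class_b[names(class_a)]
  a <- names(class_a)[class_a == "enriched"]
  b <- names(class_b)[class_b == "enriched"]
  lv <- c("enriched", "depleted", "neither")
  list(n_both = length(intersect(a, b)), n_a = length(a), n_b = length(b),
       percent = if (length(a)) round(100 * length(intersect(a, b)) /
                                        length(a)) else NA_real_,
       crosstab = table(a = factor(class_a, lv), b = factor(class_b, lv)))
}
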