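#' Demultiplexing parameters
#'
#' Thresholds operate on the normalized per-barcode scale where each
#' barcode's hashtag counts sum to `normalized_total` (100 by default, so
#' thresholds read as percentages of a barcode's HTO content).
#'
#' @param normalized_total target per-barcode total after normalization.
#' @param singlet_min minimum normalized value of the top tag for a singlet
#'   call.
#' @param doublet_second_min normalized value of the second tag at or above
#'   which a barcode is called a doublet.
#' @param min_total_raw minimum raw HTO UMIs per barcode; below it the
#'   barcode is "negative".
#' @return a validated `demux_params` list.
#' @export
demux_params <- function(normalized_total = 100, singlet_min = 60,
                         doublet_second_min = 30, min_total_raw = 10) {
  p <- list(normalized_total = check_positive(normalized_total,
                                              "normalized_total"),
            singlet_min = check_positive(singlet_min, "singlet_min"),
            doublet_second_min = check_positive(doublet_second_min,
                                                "doublet_second_min"),
            min_total_raw = check_positive(min_total_raw, "min_total_raw"))
  if (!(p$doublet_second_min < p$singlet_min &&
        p$singlet_min <= p$normalized_total))
    stop_config("need 0 < doublet_second_min < singlet_min <= normalized_total")
  class(p) <- "demux_params"
  p
}

#' Normalize hashtag counts per barcode
#'
#' Rescales each barcode's tag counts so they sum to
#' `params$normalized_total`. Barcodes with zero total are left at zero and
#' flagged; [assign_barcodes()] labels them "negative".
#'
#' @param raw tags x barcodes nonnegative count matrix.
#' @param params a [demux_params()].
#' @return normalized matrix of the same shape, with attributes `raw_total`
#'   (per-barcode raw totals) and `zero_total` (logical flag).
#' @export
normalize_tags <- function(raw, params = demux_params()) {
  if (!is.matrix(raw) || nrow(raw) < 1L)
    stop("raw must be a tags x barcodes matrix with at least one tag")
  if (any(raw < 0) || any(!is.finite(raw)))
    stop("tag counts must be finite and nonnegative")
  tot <- colSums(raw)
  zero <- tot == 0
  scl <- ifelse(zero, 0, params$normalized_total / tot)
  norm <- sweep(raw, 2, scl, "*")
  structure(norm, raw_total = tot, zero_total = zero)
}

#' Assign each barcode to a tag, "negative" or "doublet"
#'
#' A barcode is assigned to its most highly expressed tag when that tag's
#' normalized value reaches `singlet_min` and the runner-up stays below
#' `doublet_second_min`; a runner-up at or above `doublet_second_min` gives
#' "doublet" (a tie at the top is treated as a doublet); a weak top tag or a
#' raw total below `min_total_raw` gives "negative".
#'
#' @param normalized output of [normalize_tags()].
#' @param params a [demux_params()].
#' @return a `demux_result` data frame: barcode, label, top_tag, top_value,
#'   second_value.
#' @export
assign_barcodes <- function(normalized, params = demux_params()) {
  raw_total <- attr(normalized, "raw_total")
  if (is.null(raw_total))
    stop("normalized must come from normalize_tags()")
  tags <- rownames(normalized)
  if (is.null(tags)) tags <- paste0("tag", seq_len(nrow(normalized)))
  n <- ncol(normalized)
  label <- character(n)
  top_tag <- character(n)
  top_v <- numeric(n)
  second_v <- numeric(n)
  for (j in seq_len(n)) {
    v <- normalized[, j]
    o <- order(v, decreasing = TRUE)
    top_v[j] <- v[o[1]]
    second_v[j] <- if (length(v) > 1L) v[o[2]] else 0
    top_tag[j] <- tags[o[1]]
    tie <- length(v) > 1L && v[o[1]] == v[o[2]] && v[o[1]] > 0
    label[j] <- if (raw_total[j] < params$min_total_raw ||
                    top_v[j] < params$singlet_min) {
      if (tie || second_v[j] >= params$doublet_second_min) "doublet"
      else "negative"
    } else if (tie || second_v[j] >= params$doublet_second_min) {
      "doublet"
    } else tags[o[1]]
  }
  # barcodes failing the raw-UMI floor are negative regardless of shape
  label[raw_total < params$min_total_raw] <- "negative"
  res <- data.frame(barcode = colnames(normalized), label = label,
                    top_tag = top_tag, top_value = top_v,
                    second_value = second_v)
  class(res) <- c("demux_result", "data.frame")
  res
}

#' Demultiplex a hashtag count matrix
#'
#' Convenience wrapper: [normalize_tags()] then [assign_barcodes()].
#'
#' @inheritParams normalize_tags
#' @return a `demux_result` data frame.
#' @export
demux_hto <- function(raw, params = demux_params()) {
  assign_barcodes(normalize_tags(raw, params), params)
}

#' Count demultiplexing labels
#'
#' @param result a `demux_result` from [assign_barcodes()].
#' @return named integer vector of label counts; counts sum to the number
#'   of barcodes.
#' @export
demux_summary <- function(result) {
  if (nrow(result) == 0L) return(integer(0))
  counts <- table(result$label)
  stats::setNames(as.integer(counts), names(counts))
}
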