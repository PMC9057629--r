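#' @keywords internal
"_PACKAGE"

# Internal validation helpers shared across modules.

stop_config <- function(...) {
  stop(structure(
    class = c("tilstrat_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config(name, " must be a fraction in [0, 1]")
  x
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x))
    stop_config(name, " must be a positive integer")
  as.integer(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_config(name, " must be a positive number")
  x
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Sample standard deviation by row of a matrix.
row_sds <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop("need at least 2 columns for a sample sd")
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1L))
}
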