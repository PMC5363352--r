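#' @keywords internal
"_PACKAGE"

#' @importFrom stats dnorm kmeans rnorm runif sd uniroot cor fisher.test
#'   quantile setNames rbinom
#' @importFrom utils read.delim write.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

# Derive a stage seed from a master seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1103L + offset) %% .Machine$integer.max)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}

# Split a sequence string into a character vector of single bases.
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]
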