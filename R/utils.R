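# Internal helpers shared across modules.

# Deterministic named substream seeds: every table draws from its own
# substream of the root seed, so adding a table never perturbs existing ones.
.substreamSeed <- function(seed, name) {
  stopifnot(length(name) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) + h) %% 2147483647)
}

.checkFinite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("invalid value: '", what, "' must be finite numeric", call. = FALSE)
  }
  invisible(x)
}

# Nearest-rank percentile of each x within `values`: 100 * (# strictly
# below) / N. Shared convention for magnitude regions and quartile splits.
.strictPercentile <- function(values, x) {
  if (length(values) == 0L) {
    stop("empty input: percentile of an empty value set is undefined",
         call. = FALSE)
  }
  100 * findInterval(x, sort(values), left.open = TRUE) / length(values)
}

.bh <- function(p) p.adjust(p, method = "BH")

# Extract a plain numeric matrix (features x samples) from a FeatureMatrix,
# SummarizedExperiment or matrix.
.valuesMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) return(assay(x, 1L))
  if (is.matrix(x)) return(x)
  stop("expected a FeatureMatrix, SummarizedExperiment or matrix",
       call. = FALSE)
}
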