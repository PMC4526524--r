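# Internal helpers shared across modules.
#
# All genomic intervals inside the package are 0-based half-open [start, end).
# Conversions to other conventions (VCF 1-based, human-readable 1-based
# inclusive) happen only at I/O boundaries in the formats module.

# IRanges from 0-based half-open coordinates.
.ir <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

# Point positions (0-based) as width-1 IRanges.
.ir_point <- function(pos) IRanges::IRanges(start = pos + 1L, width = 1L)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 && x == round(x)

.is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1

# Open a connection that is transparent to .gz suffixes.
.out_con <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
}

# Deterministic child seed derived from a base seed; kept well below 2^31.
.child_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% 2147483000L
}
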