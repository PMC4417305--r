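#' @keywords internal
"_PACKAGE"

## Split a sequence string into single characters.
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## 0-based half-open interval data.frame -> GRanges (1-based closed).
.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

## Sample standard error of the mean; NA for n < 2.
.sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
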