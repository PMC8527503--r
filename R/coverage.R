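#' Physical coverage of sequencing libraries
#'
#' Fold coverage is the total number of sequenced bases divided by the
#' genome size; summing over libraries gives the total physical coverage of
#' a dataset.  Coverage is additive over disjoint library sets.
#'
#' @param total_bases numeric vector, bases sequenced per library (bp).
#' @param genome_size genome size in bp (shared across libraries).
#' @param digits decimals in the reported fold value (default 1, the
#'   conventional reporting precision).
#' @return fold coverage (x), rounded to `digits`.
#' @examples
#' physical_coverage(27.4e9, 110.6e6)  # 247.7
#' @export
physical_coverage <- function(total_bases, genome_size, digits = 1) {
  if (any(genome_size <= 0)) stop("genome_size must be positive")
  if (any(total_bases < 0)) stop("total_bases must be non-negative")
  if (length(total_bases) == 0L) return(round(0, digits))
  round(sum(total_bases / genome_size), digits)
}
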