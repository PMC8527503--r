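# Nested intronic (NI) genes: genes whose transcripts lie within a single
# intron of another gene, allowing limited end-overlap with the host's
# exons.  The end-overlap allowance is read as a fraction of the nested
# transcript's span, applied independently at each end, and the overhang
# must actually lie within the intron-defining transcript's exons.

#' Extract and filter introns genome-wide
#'
#' Derives per-transcript introns (deduplicated within each gene by
#' coordinates), then removes the longest `ceiling(exclude_top_fraction * N)`
#' introns genome-wide.  Excluding the longest tail avoids counting the
#' giant "introns" induced by trans-spliced leader exons far upstream of
#' gene bodies.
#'
#' @param ann an [annotation].
#' @param exclude_top_fraction fraction of the longest introns to drop
#'   (default 0.005, i.e. the top 0.5%).
#' @return data.frame as [introns], sorted by `seqid`, `start`.
#' @export
filter_introns <- function(ann, exclude_top_fraction = 0.005) {
  stopifnot(exclude_top_fraction >= 0, exclude_top_fraction < 1)
  ir <- introns(ann)
  if (!nrow(ir)) return(ir)
  key <- paste(ir$host_gene_id, ir$seqid, ir$start, ir$end)
  ir <- ir[!duplicated(key), , drop = FALSE]
  k <- ceiling(exclude_top_fraction * nrow(ir))
  if (k > 0) {
    ord <- order(-ir$length, ir$seqid, ir$start)
    ir <- ir[-ord[seq_len(k)], , drop = FALSE]
  }
  ir <- ir[order(ir$seqid, ir$start, ir$end), , drop = FALSE]
  rownames(ir) <- NULL
  ir
}

## does [from, to) lie entirely within the exons of transcript tx?
.covered_by_exons <- function(ann, tx_id, from, to) {
  if (from >= to) return(TRUE)
  e <- ann$exons[ann$exons$tx_id == tx_id, , drop = FALSE]
  if (!nrow(e)) return(FALSE)
  cov <- IRanges::reduce(IRanges::IRanges(e$start + 1L, e$end))
  q <- IRanges::IRanges(from + 1L, to)
  sum(IRanges::width(IRanges::intersect(cov, q))) == (to - from)
}

#' Detect nested intronic genes
#'
#' A gene G is nested in host H (G != H) when at least one transcript of G
#' lies within the span of a single filtered intron of H, extended at each
#' end by at most `end_overlap_tolerance` times the transcript span of
#' overlap with H's exons (the exons of the intron-defining transcript).
#' Each NI gene is reported once, with its minimal-span qualifying host
#' intron; a gene nested inside another NI gene's intron has nesting depth
#' 2 (depth is capped at 2 in reporting).
#'
#' @param ann an [annotation].
#' @param intron_set filtered introns from [filter_introns]; derived from
#'   `ann` with the default exclusion when omitted.
#' @param end_overlap_tolerance allowed end-overlap fraction in `[0, 0.5)`
#'   (default 0.15).
#' @return data.frame with one row per NI gene: `nested_gene_id`,
#'   `host_gene_id`, `host_tx_id`, `intron_start`, `intron_end`,
#'   `five_prime_overlap`, `three_prime_overlap` (bp, in nested-transcript
#'   orientation), `orientation` (`parallel`/`antiparallel`),
#'   `nesting_depth`.
#' @export
detect_nested_genes <- function(ann, intron_set = NULL,
                                end_overlap_tolerance = 0.15) {
  if (end_overlap_tolerance < 0 || end_overlap_tolerance >= 0.5)
    stop("end_overlap_tolerance must lie in [0, 0.5)")
  if (is.null(intron_set)) intron_set <- filter_introns(ann)
  empty <- data.frame(nested_gene_id = character(), host_gene_id = character(),
                      host_tx_id = character(), intron_start = integer(),
                      intron_end = integer(), five_prime_overlap = integer(),
                      three_prime_overlap = integer(),
                      orientation = character(), nesting_depth = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(intron_set) || !nrow(ann$transcripts)) return(empty)

  tx <- ann$transcripts
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(tx$start + 1L, tx$end),
    IRanges::IRanges(intron_set$start + 1L, intron_set$end))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  same_seq <- tx$seqid[qi] == intron_set$seqid[si]
  self <- tx$gene_id[qi] == intron_set$host_gene_id[si]
  qi <- qi[same_seq & !self]; si <- si[same_seq & !self]
  if (!length(qi)) return(empty)

  len <- tx$end[qi] - tx$start[qi]
  allow <- floor(end_overlap_tolerance * len)
  left_ov <- pmax(0L, intron_set$start[si] - tx$start[qi])
  right_ov <- pmax(0L, tx$end[qi] - intron_set$end[si])
  ok <- left_ov <= allow & right_ov <= allow
  qi <- qi[ok]; si <- si[ok]
  left_ov <- left_ov[ok]; right_ov <- right_ov[ok]
  if (!length(qi)) return(empty)

  # overhanging ends must be covered by the host transcript's exons
  cov <- vapply(seq_along(qi), function(j) {
    htx <- intron_set$host_tx_id[si[j]]
    .covered_by_exons(ann, htx, tx$start[qi[j]], intron_set$start[si[j]]) &&
      .covered_by_exons(ann, htx, intron_set$end[si[j]], tx$end[qi[j]])
  }, logical(1))
  qi <- qi[cov]; si <- si[cov]
  left_ov <- left_ov[cov]; right_ov <- right_ov[cov]
  if (!length(qi)) return(empty)

  cand <- data.frame(
    nested_gene_id = tx$gene_id[qi],
    host_gene_id = intron_set$host_gene_id[si],
    host_tx_id = intron_set$host_tx_id[si],
    intron_start = intron_set$start[si],
    intron_end = intron_set$end[si],
    left_ov = left_ov, right_ov = right_ov,
    span = intron_set$end[si] - intron_set$start[si],
    nested_strand = tx$strand[qi],
    stringsAsFactors = FALSE)
  # one record per nested gene: minimal-span qualifying intron, then
  # deterministic position/host tie-breaks
  cand <- cand[order(cand$nested_gene_id, cand$span, cand$intron_start,
                     cand$host_gene_id), , drop = FALSE]
  cand <- cand[!duplicated(cand$nested_gene_id), , drop = FALSE]

  host_strand <- ann$genes$strand[match(cand$host_gene_id,
                                        ann$genes$gene_id)]
  minus <- cand$nested_strand == "-"
  out <- data.frame(
    nested_gene_id = cand$nested_gene_id,
    host_gene_id = cand$host_gene_id,
    host_tx_id = cand$host_tx_id,
    intron_start = cand$intron_start,
    intron_end = cand$intron_end,
    five_prime_overlap = ifelse(minus, cand$right_ov, cand$left_ov),
    three_prime_overlap = ifelse(minus, cand$left_ov, cand$right_ov),
    orientation = ifelse(cand$nested_strand == host_strand |
                           cand$nested_strand == "." | host_strand == ".",
                         "parallel", "antiparallel"),
    stringsAsFactors = FALSE)
  out$nesting_depth <- ifelse(out$host_gene_id %in% out$nested_gene_id,
                              2L, 1L)
  out <- out[order(out$nested_gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a set of nested-gene records
#'
#' Exonic base totals are computed on the strand-collapsed union of exon
#' intervals (so duplicate transcripts never double-count), genome-wide and
#' restricted to NI genes.
#'
#' @param ann an [annotation].
#' @param records output of [detect_nested_genes].
#' @return list with `n_host_genes`, `n_ni_genes`, `n_doubly_nested`,
#'   `exonic_bp_total`, `exonic_bp_ni`, `percent_exonic_in_ni`.
#' @export
summarize_nested <- function(ann, records) {
  union_bp <- function(ex) {
    if (!nrow(ex)) return(0L)
    sum(vapply(split(ex, ex$seqid), function(e)
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(e$start + 1L, e$end)))), numeric(1)))
  }
  ni_tx <- ann$transcripts$tx_id[ann$transcripts$gene_id %in%
                                   records$nested_gene_id]
  total <- union_bp(ann$exons)
  ni <- union_bp(ann$exons[ann$exons$tx_id %in% ni_tx, , drop = FALSE])
  list(n_host_genes = length(unique(records$host_gene_id)),
       n_ni_genes = nrow(records),
       n_doubly_nested = sum(records$nesting_depth == 2L),
       exonic_bp_total = total,
       exonic_bp_ni = ni,
       percent_exonic_in_ni = if (total > 0) 100 * ni / total else 0)
}

#' Flag nested genes flanked by transposable elements
#'
#' For each NI record the 5' flank segment is the interval between the host
#' intron start and the nested gene start, and the 3' flank segment the
#' interval between the nested gene end and the host intron end (genomic
#' orientation).  A side is TE-flanked when at least one TE interval
#' overlaps that segment by >= 1 bp; zero-length segments are not flanked.
#'
#' @param records output of [detect_nested_genes].
#' @param ann the [annotation] the records came from.
#' @param te_intervals data.frame of TE intervals (`seqid`, `start`, `end`;
#'   0-based half-open, e.g. from [read_bed]).
#' @return `records` with logical columns `flank5_te`, `flank3_te` added,
#'   plus attributes `n_te_flanked_one_side` and `n_te_flanked_both_sides`.
#' @export
te_flanking <- function(records, ann, te_intervals) {
  g <- ann$genes[match(records$nested_gene_id, ann$genes$gene_id), ,
                 drop = FALSE]
  seg_hit <- function(seqid, from, to) {
    if (from >= to) return(FALSE)
    te <- te_intervals[te_intervals$seqid == seqid, , drop = FALSE]
    any(te$start < to & te$end > from)
  }
  f5 <- logical(nrow(records)); f3 <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    f5[i] <- seg_hit(g$seqid[i], records$intron_start[i], g$start[i])
    f3[i] <- seg_hit(g$seqid[i], g$end[i], records$intron_end[i])
  }
  records$flank5_te <- f5
  records$flank3_te <- f3
  attr(records, "n_te_flanked_one_side") <- sum(f5 | f3)
  attr(records, "n_te_flanked_both_sides") <- sum(f5 & f3)
  records
}
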