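# Reciprocal-best-hit orthology and collinear gene-block (microsynteny)
# chaining, plus Oxford dot-plot / scaffold-partner (macrosynteny)
# summaries.

#' Read a 12-column blast-style tabular hit file
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore (blast `-outfmt 6`).
#'
#' @param path TSV file, no header.
#' @return data.frame with the 12 standard columns.
#' @export
read_hits <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) != 12L)
    stop("hit table must have 12 columns, found ", ncol(x))
  names(x) <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                "bitscore")
  x
}

## best subject per query: highest bitscore, then lower e-value, then
## lexicographically smallest subject id
.best_per_query <- function(hits) {
  hits <- hits[order(hits$qseqid, -hits$bitscore, hits$evalue,
                     hits$sseqid), , drop = FALSE]
  hits[!duplicated(hits$qseqid), c("qseqid", "sseqid", "bitscore"),
       drop = FALSE]
}

#' Reciprocal best hits between two protein sets
#'
#' Duplicate (query, subject) rows keep the highest-bitscore copy.  A pair
#' (a, b) is retained when b is a's best hit and a is b's best hit.
#'
#' @param hits_ab,hits_ba hit tables (see [read_hits]) in the two query
#'   directions; must be non-empty.
#' @return data.frame with `gene_a`, `gene_b`, `bitscore` (the A->B score),
#'   one row per reciprocal pair; attribute `n_duplicates` counts dropped
#'   duplicate rows.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba) {
  if (!nrow(hits_ab) || !nrow(hits_ba)) stop("hit tables must be non-empty")
  dedup <- function(h) {
    h <- h[order(h$qseqid, h$sseqid, -h$bitscore), , drop = FALSE]
    key <- paste(h$qseqid, h$sseqid)
    list(h = h[!duplicated(key), , drop = FALSE],
         n = sum(duplicated(key)))
  }
  da <- dedup(hits_ab); db <- dedup(hits_ba)
  best_ab <- .best_per_query(da$h)
  best_ba <- .best_per_query(db$h)
  m <- match(best_ab$sseqid, best_ba$qseqid)
  keep <- !is.na(m) & best_ba$sseqid[m] == best_ab$qseqid
  out <- data.frame(gene_a = best_ab$qseqid[keep],
                    gene_b = best_ab$sseqid[keep],
                    bitscore = best_ab$bitscore[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_duplicates") <- da$n + db$n
  out
}

## ordinal index of each gene within its sequence: sorted by start, ties by
## end then gene id; gene position is the start of the gene span
.gene_table <- function(ann) {
  g <- ann$genes[order(ann$genes$seqid, ann$genes$start, ann$genes$end,
                       ann$genes$gene_id), , drop = FALSE]
  g$ordinal <- stats::ave(seq_len(nrow(g)), g$seqid,
                          FUN = seq_along)
  g
}

## adjacency test between consecutive chain members i-1 and i of `p`
.chain_step_ok <- function(p, i, max_intervening, max_gap) {
  a_ok <- p$a_seqid[i] == p$a_seqid[i - 1L] &&
    (p$a_ord[i] - p$a_ord[i - 1L] - 1L) <= max_intervening &&
    abs(p$a_start[i] - p$a_start[i - 1L]) <= max_gap
  b_ok <- p$b_seqid[i] == p$b_seqid[i - 1L] &&
    (abs(p$b_ord[i] - p$b_ord[i - 1L]) - 1L) <= max_intervening &&
    abs(p$b_start[i] - p$b_start[i - 1L]) <= max_gap &&
    p$b_ord[i] != p$b_ord[i - 1L]
  a_ok && b_ok
}

#' Chain reciprocal best hits into collinear microsynteny blocks
#'
#' Genome A is scanned in gene order; a growing chain is extended with the
#' next ortholog pair when, on both genomes, consecutive chain members are
#' separated by at most `max_intervening` annotated genes (matched or not)
#' and by at most `max_gap` bp between gene starts, and the B-side ordinals
#' continue the chain's orientation (strictly increasing or strictly
#' decreasing, fixed by the first two members).  Chains shorter than
#' `min_block` are discarded.  The default 3 / 5 / 30 kb rule requires a
#' minimum of 3 consecutive genes, up to 5 intervening genes, and at most
#' 30 kb to the next gene.
#'
#' @param pairs data.frame from [reciprocal_best_hits] (`gene_a`, `gene_b`).
#' @param ann_a,ann_b the two [annotation]s.
#' @param min_block minimum genes per block (default 3).
#' @param max_intervening maximum intervening genes (default 5).
#' @param max_gap maximum start-to-start distance in bp (default 30000).
#' @return list with `blocks` (data.frame `block_id`, `n_genes`,
#'   `orientation`, `a_seqid`, `b_seqid`, `a_start`, `a_end`, `b_start`,
#'   `b_end`) and `pairs` (the input pairs annotated with coordinates,
#'   ordinals and `block_id`, `NA` for unchained pairs).
#' @export
collinear_blocks <- function(pairs, ann_a, ann_b, min_block = 3,
                             max_intervening = 5, max_gap = 30000) {
  stopifnot(min_block >= 2, max_intervening >= 0, max_gap > 0)
  ga <- .gene_table(ann_a); gb <- .gene_table(ann_b)
  ia <- match(pairs$gene_a, ga$gene_id)
  ib <- match(pairs$gene_b, gb$gene_id)
  if (anyNA(ia) || anyNA(ib))
    stop("pair references a gene absent from the annotations")
  p <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                  a_seqid = ga$seqid[ia], a_start = ga$start[ia],
                  a_ord = ga$ordinal[ia],
                  b_seqid = gb$seqid[ib], b_start = gb$start[ib],
                  b_ord = gb$ordinal[ib], stringsAsFactors = FALSE)
  p <- p[order(p$a_seqid, p$a_ord), , drop = FALSE]
  rownames(p) <- NULL

  n <- nrow(p)
  # validity and direction of each step between consecutive pairs in A order
  step_ok <- rep(FALSE, n)
  step_sign <- rep(0L, n)
  for (i in seq_len(n)[-1L]) {
    step_ok[i] <- .chain_step_ok(p, i, max_intervening, max_gap)
    if (step_ok[i]) step_sign[i] <- sign(p$b_ord[i] - p$b_ord[i - 1L])
  }
  # maximal runs of valid steps with constant direction; a pair at an
  # orientation flip belongs to both flanking candidate runs
  cand <- list()
  i <- 2L
  while (i <= n) {
    if (!step_ok[i]) { i <- i + 1L; next }
    s <- step_sign[i]
    j <- i
    while (j + 1L <= n && step_ok[j + 1L] && step_sign[j + 1L] == s)
      j <- j + 1L
    cand[[length(cand) + 1L]] <- list(from = i - 1L, to = j, sign = s)
    i <- j + 1L
  }
  cand <- Filter(function(cc) cc$to - cc$from + 1L >= min_block, cand)
  # conflict resolution: each pair belongs to at most one block; keep the
  # longer block, then the earlier-starting one
  if (length(cand)) {
    ord <- order(-vapply(cand, function(cc) cc$to - cc$from + 1L, numeric(1)),
                 vapply(cand, function(cc) p$a_seqid[cc$from], character(1)),
                 vapply(cand, function(cc) p$a_start[cc$from], numeric(1)))
    cand <- cand[ord]
    used <- rep(FALSE, n)
    keep <- list()
    for (cc in cand) {
      idx <- cc$from:cc$to
      idx <- idx[!used[idx]]
      if (length(idx) > 1L) {         # longest contiguous free stretch
        grp <- cumsum(c(1L, diff(idx) != 1L))
        pieces <- split(idx, grp)
        idx <- pieces[[which.max(lengths(pieces))]]
      }
      if (length(idx) >= min_block) {
        used[idx] <- TRUE
        keep[[length(keep) + 1L]] <- list(idx = idx, sign = cc$sign)
      }
    }
    cand <- keep
  }
  p$block_id <- NA_integer_
  for (b in seq_along(cand)) p$block_id[cand[[b]]$idx] <- b

  blocks <- lapply(seq_along(cand), function(b) {
    q <- p[cand[[b]]$idx, , drop = FALSE]
    data.frame(block_id = b, n_genes = nrow(q),
               orientation = if (cand[[b]]$sign > 0L) "forward"
                             else "reverse",
               a_seqid = q$a_seqid[1L], b_seqid = q$b_seqid[1L],
               a_start = min(q$a_start), a_end = max(q$a_start),
               b_start = min(q$b_start), b_end = max(q$b_start),
               stringsAsFactors = FALSE)
  })
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(block_id = integer(), n_genes = integer(),
               orientation = character(), a_seqid = character(),
               b_seqid = character(), a_start = numeric(),
               a_end = numeric(), b_start = numeric(), b_end = numeric(),
               stringsAsFactors = FALSE)
  if (nrow(blocks)) {
    blocks <- blocks[order(blocks$a_seqid, blocks$a_start), , drop = FALSE]
    remap <- setNames(seq_len(nrow(blocks)), blocks$block_id)
    blocks$block_id <- as.integer(remap[as.character(blocks$block_id)])
    p$block_id <- as.integer(remap[as.character(p$block_id)])
    rownames(blocks) <- NULL
  }
  list(blocks = blocks, pairs = p)
}

#' Macrosynteny summary: scaffold partners and Oxford dot-plot table
#'
#' For each sequence of genome A, reports the genome-B sequence receiving
#' the plurality of its ortholog pairs (ties resolved to the
#' lexicographically smallest B sequence and flagged ambiguous), and the
#' full dot-plot coordinate table.
#'
#' @inheritParams collinear_blocks
#' @return list with `partners` (data.frame `a_seqid`, `b_seqid`,
#'   `n_pairs`, `n_total`, `fraction`, `ambiguous`) and `dots` (data.frame
#'   `a_seqid`, `a_pos`, `b_seqid`, `b_pos`, one row per pair).
#' @export
macrosynteny_summary <- function(pairs, ann_a, ann_b) {
  if (!nrow(pairs)) stop("no ortholog pairs")
  ia <- match(pairs$gene_a, ann_a$genes$gene_id)
  ib <- match(pairs$gene_b, ann_b$genes$gene_id)
  if (anyNA(ia) || anyNA(ib))
    stop("pair references a gene absent from the annotations")
  dots <- data.frame(a_seqid = ann_a$genes$seqid[ia],
                     a_pos = ann_a$genes$start[ia],
                     b_seqid = ann_b$genes$seqid[ib],
                     b_pos = ann_b$genes$start[ib],
                     stringsAsFactors = FALSE)
  partners <- do.call(rbind, lapply(split(dots, dots$a_seqid), function(d) {
    tab <- table(d$b_seqid)
    top <- max(tab)
    winners <- sort(names(tab)[tab == top])
    data.frame(a_seqid = d$a_seqid[1L], b_seqid = winners[1L],
               n_pairs = as.integer(top), n_total = nrow(d),
               fraction = top / nrow(d),
               ambiguous = length(winners) > 1L,
               stringsAsFactors = FALSE)
  }))
  rownames(partners) <- NULL
  list(partners = partners, dots = dots)
}
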