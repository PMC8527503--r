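#' @importFrom methods as is
#' @importFrom stats median rbinom rpois runif setNames
#' @importFrom utils read.delim write.table head tail
NULL

# Internal coordinate convention: every interval in this package is 0-based,
# half-open [start, end).  GFF3 (1-based, inclusive) and BED (0-based,
# half-open) are converted at the boundary and nowhere else.

#' Construct a genome annotation object
#'
#' An `annotation` holds a gene -> transcript -> exon hierarchy together with
#' the lengths of the underlying sequences.  All coordinates are 0-based,
#' half-open.  The constructor validates the hierarchy: gene identifiers must
#' be unique, every transcript must lie within its gene span and share its
#' strand, and the exons of a transcript must be non-overlapping and lie
#' within the transcript span.
#'
#' @param genes data.frame with columns `gene_id`, `seqid`, `start`, `end`,
#'   `strand` (one of `"+"`, `"-"`, `"."`).
#' @param transcripts data.frame with columns `tx_id`, `gene_id`, `seqid`,
#'   `start`, `end`, `strand`.
#' @param exons data.frame with columns `tx_id`, `seqid`, `start`, `end`,
#'   `strand`.
#' @param seqlens named numeric vector of sequence lengths (bp).
#' @param n_skipped number of input features dropped during parsing (unknown
#'   parents, geneless transcripts, exonless genes).
#' @return An object of class `annotation`.
#' @export
annotation <- function(genes, transcripts, exons, seqlens, n_skipped = 0L) {
  genes       <- as.data.frame(genes, stringsAsFactors = FALSE)
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  exons       <- as.data.frame(exons, stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene identifiers: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (nrow(genes) && any(genes$start < 0 | genes$start >= genes$end))
    stop("invalid gene interval (need 0 <= start < end)")
  if (!all(transcripts$gene_id %in% genes$gene_id))
    stop("transcript references unknown gene")
  if (!all(exons$tx_id %in% transcripts$tx_id))
    stop("exon references unknown transcript")

  # canonical ordering makes write/parse round trips exact
  genes <- genes[order(genes$seqid, genes$start, genes$end, genes$gene_id), ,
                 drop = FALSE]
  transcripts <- transcripts[order(match(transcripts$gene_id, genes$gene_id),
                                   transcripts$start, transcripts$tx_id), ,
                             drop = FALSE]
  exons <- exons[order(match(exons$tx_id, transcripts$tx_id), exons$start), ,
                 drop = FALSE]
  rownames(genes) <- rownames(transcripts) <- rownames(exons) <- NULL

  gidx <- match(transcripts$gene_id, genes$gene_id)
  bad <- which(transcripts$start < genes$start[gidx] |
               transcripts$end   > genes$end[gidx])
  if (length(bad))
    stop("transcript outside gene span: ", transcripts$tx_id[bad[1]])
  bad <- which(transcripts$strand != genes$strand[gidx])
  if (length(bad))
    stop("transcript strand differs from gene strand: ",
         transcripts$tx_id[bad[1]])

  tidx <- match(exons$tx_id, transcripts$tx_id)
  bad <- which(exons$start < transcripts$start[tidx] |
               exons$end   > transcripts$end[tidx])
  if (length(bad))
    stop("exon outside transcript span in transcript: ", exons$tx_id[bad[1]])
  for (tx in unique(exons$tx_id)) {
    e <- exons[exons$tx_id == tx, , drop = FALSE]
    if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)]))
      stop("overlapping exons in transcript: ", tx)
  }
  ntx <- table(factor(transcripts$gene_id, levels = genes$gene_id))
  if (nrow(genes) && any(ntx == 0L))
    stop("gene without transcripts: ", names(ntx)[ntx == 0L][1L])

  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 seqlens = seqlens, n_skipped = as.integer(n_skipped)),
            class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf(
    "annotation: %d genes, %d transcripts, %d exons on %d sequences\n",
    nrow(x$genes), nrow(x$transcripts), nrow(x$exons), length(x$seqlens)))
  if (x$n_skipped > 0L)
    cat(sprintf("  (%d input features skipped during parsing)\n", x$n_skipped))
  invisible(x)
}

## sequence-region directives, e.g. "##sequence-region chr1 1 110600000"
.gff3_directives <- function(lines) {
  d <- grep("^##sequence-region", lines, value = TRUE)
  if (!length(d)) return(NULL)
  parts <- strsplit(trimws(d), "[ \t]+")
  setNames(vapply(parts, function(p) as.numeric(p[4L]), numeric(1)),
           vapply(parts, function(p) p[2L], character(1)))
}

#' Read a GFF3 annotation
#'
#' Parses a GFF3 file carrying `gene`, `mRNA`/`transcript` and `exon` features
#' linked through `Parent` attributes into an [annotation], converting the
#' 1-based inclusive GFF3 coordinates to the package's 0-based half-open
#' convention.  Unknown feature types are ignored; features whose parents
#' cannot be resolved (and genes left without any exon-bearing transcript)
#' are skipped and counted in `n_skipped`.
#'
#' @param path GFF3 file.
#' @param seqlens optional named vector of sequence lengths; if missing,
#'   lengths are taken from a FASTA (`fasta`), then from
#'   `##sequence-region` directives, then from the maximum feature end.
#' @param fasta optional FASTA file supplying sequence lengths.
#' @return An [annotation].
#' @export
read_gff3 <- function(path, seqlens = NULL, fasta = NULL) {
  lines <- readLines(path, warn = FALSE)
  fasta_at <- grep("^##FASTA", lines)
  if (length(fasta_at)) lines <- lines[seq_len(fasta_at[1L] - 1L)]
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L))
    stop("malformed GFF3 (expected 9 tab-separated columns) at line ",
         body[which(nfield != 9L)[1L]])

  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  id <- as.character(gr$ID)
  parent <- gr$Parent  # CharacterList

  is_gene <- type == "gene"
  is_tx   <- type %in% c("mRNA", "transcript")
  is_exon <- type == "exon"

  g <- data.frame(gene_id = id[is_gene],
                  seqid  = as.character(GenomicRanges::seqnames(gr))[is_gene],
                  start  = GenomicRanges::start(gr)[is_gene] - 1L,
                  end    = GenomicRanges::end(gr)[is_gene],
                  strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))[is_gene]),
                  stringsAsFactors = FALSE)
  if (anyNA(g$gene_id)) stop("gene feature without ID attribute")

  n_skipped <- 0L
  tx_par <- vapply(parent[is_tx], function(p) if (length(p)) p[1L] else NA_character_,
                   character(1))
  t <- data.frame(tx_id  = id[is_tx],
                  gene_id = tx_par,
                  seqid  = as.character(GenomicRanges::seqnames(gr))[is_tx],
                  start  = GenomicRanges::start(gr)[is_tx] - 1L,
                  end    = GenomicRanges::end(gr)[is_tx],
                  strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))[is_tx]),
                  stringsAsFactors = FALSE)
  keep <- !is.na(t$gene_id) & t$gene_id %in% g$gene_id
  n_skipped <- n_skipped + sum(!keep)
  t <- t[keep, , drop = FALSE]

  ex_idx <- which(is_exon)
  ex_par <- parent[is_exon]
  reps <- lengths(ex_par)
  n_skipped <- n_skipped + sum(reps == 0L)
  ex_row <- rep(ex_idx, reps)
  e <- data.frame(tx_id = unlist(ex_par, use.names = FALSE),
                  seqid  = as.character(GenomicRanges::seqnames(gr))[ex_row],
                  start  = GenomicRanges::start(gr)[ex_row] - 1L,
                  end    = GenomicRanges::end(gr)[ex_row],
                  strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))[ex_row]),
                  stringsAsFactors = FALSE)
  keep <- e$tx_id %in% t$tx_id
  n_skipped <- n_skipped + sum(!keep)
  e <- e[keep, , drop = FALSE]

  # drop transcripts without exons, then genes without transcripts
  has_exon <- t$tx_id %in% e$tx_id
  n_skipped <- n_skipped + sum(!has_exon)
  t <- t[has_exon, , drop = FALSE]
  has_tx <- g$gene_id %in% t$gene_id
  n_skipped <- n_skipped + sum(!has_tx)
  g <- g[has_tx, , drop = FALSE]

  if (is.null(seqlens)) {
    if (!is.null(fasta)) {
      ss <- Biostrings::readDNAStringSet(fasta)
      seqlens <- setNames(Biostrings::width(ss),
                          sub("\\s.*$", "", names(ss)))
    } else {
      seqlens <- .gff3_directives(lines)
      if (is.null(seqlens)) {
        seqlens <- tapply(g$end, g$seqid, max)
        seqlens <- setNames(as.numeric(seqlens), names(seqlens))
      }
    }
  }
  annotation(g, t, e, seqlens, n_skipped = n_skipped)
}

#' Write an annotation to GFF3
#'
#' Serializes the gene/transcript/exon hierarchy back to GFF3 (1-based,
#' inclusive), with `##sequence-region` directives recording sequence
#' lengths.  `read_gff3(write_gff3(x))` reproduces `x` exactly.
#'
#' @param ann an [annotation].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  stopifnot(is(ann, "annotation"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d",
                     names(ann$seqlens), as.integer(ann$seqlens)), con)
  fmt <- function(seqid, type, start, end, strand, attrs)
    sprintf("%s\tctenotools\t%s\t%d\t%d\t.\t%s\t.\t%s",
            seqid, type, as.integer(start) + 1L, as.integer(end), strand, attrs)
  for (i in seq_len(nrow(ann$genes))) {
    gn <- ann$genes[i, ]
    writeLines(fmt(gn$seqid, "gene", gn$start, gn$end, gn$strand,
                   paste0("ID=", gn$gene_id)), con)
    txs <- ann$transcripts[ann$transcripts$gene_id == gn$gene_id, , drop = FALSE]
    for (j in seq_len(nrow(txs))) {
      tx <- txs[j, ]
      writeLines(fmt(tx$seqid, "mRNA", tx$start, tx$end, tx$strand,
                     paste0("ID=", tx$tx_id, ";Parent=", gn$gene_id)), con)
      exs <- ann$exons[ann$exons$tx_id == tx$tx_id, , drop = FALSE]
      writeLines(fmt(exs$seqid, "exon", exs$start, exs$end, exs$strand,
                     paste0("Parent=", tx$tx_id)), con)
    }
  }
  invisible(path)
}

#' Derive introns from an annotation
#'
#' Introns are the gaps between consecutive exons of each transcript.
#'
#' @param ann an [annotation].
#' @return data.frame with columns `seqid`, `start`, `end`, `strand`,
#'   `host_gene_id`, `host_tx_id`, `length` (0-based half-open), sorted by
#'   `seqid` then `start`.
#' @export
introns <- function(ann) {
  stopifnot(is(ann, "annotation"))
  out <- vector("list", nrow(ann$transcripts))
  for (i in seq_len(nrow(ann$transcripts))) {
    tx <- ann$transcripts[i, ]
    e <- ann$exons[ann$exons$tx_id == tx$tx_id, , drop = FALSE]
    if (nrow(e) < 2L) next
    out[[i]] <- data.frame(seqid = tx$seqid,
                           start = e$end[-nrow(e)],
                           end   = e$start[-1L],
                           strand = tx$strand,
                           host_gene_id = tx$gene_id,
                           host_tx_id = tx$tx_id,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(seqid = character(), start = integer(), end = integer(),
                      strand = character(), host_gene_id = character(),
                      host_tx_id = character(), stringsAsFactors = FALSE)
  out$length <- out$end - out$start
  out <- out[order(out$seqid, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a BED file of intervals
#'
#' BED 3/6; BED is already 0-based half-open so coordinates pass through.
#'
#' @param path BED file.
#' @return data.frame with `seqid`, `start`, `end` and, for BED6+, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  comment.char = "#")
  names(x)[1:3] <- c("seqid", "start", "end")
  if (ncol(x) >= 6L) names(x)[4:6] <- c("name", "score", "strand")
  x
}

#' Write intervals to BED
#'
#' @param x data.frame with `seqid`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("seqid", "start", "end", "name", "score", "strand"),
                    names(x))
  write.table(x[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
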