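# Trans-spliced leader analysis: genomic motif scanning (semi-global
# alignment, identity over alignment columns so gaps count against
# identity), read 5'-prefix detection, shared-first-exon clustering, and a
# transcript start-dinucleotide census.

.as_dnastringset <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is(x, "DNAString")) return(Biostrings::DNAStringSet(x))
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(Biostrings::readDNAStringSet(x))
  Biostrings::DNAStringSet(x)
}

.unit_submat <- function()
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)

## align motif semi-globally inside a window; returns identity, subject
## span (1-based within window) or NULL
.refine_candidate <- function(motif, window) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(motif), window, type = "global-local",
    substitutionMatrix = .unit_submat(), gapOpening = 2, gapExtension = 1)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  list(identity = Biostrings::nmatch(aln) / cols,
       s_start = Biostrings::start(Biostrings::subject(aln)),
       s_end = Biostrings::end(Biostrings::subject(aln)))
}

#' Scan a genome for spliced-leader motif occurrences
#'
#' Finds occurrences of the leader motif by semi-global alignment (the
#' motif aligned end-to-end, free end gaps on the genome side), keeping
#' candidates whose identity (matching columns / alignment columns) is at
#' least `min_identity` and whose aligned genomic span lies within
#' `[min_len, max_len]`.  Overlapping candidates are reduced to the
#' highest-identity non-overlapping set (ties to the leftmost).  Both
#' strands are scanned by default.
#'
#' @param genome FASTA path, [Biostrings::DNAStringSet], or character
#'   vector of sequences.
#' @param motif leader sequence (default [leader_motif]); must be at least
#'   10 bp.
#' @param min_identity minimum identity fraction (default 0.90).
#' @param min_len,max_len admissible aligned span (bp; defaults 35 / 48).
#' @param both_strands scan the reverse strand too (default `TRUE`).
#' @return data.frame with `seqid`, `start`, `end` (0-based half-open,
#'   forward-strand coordinates), `strand`, `identity`, `matched_length`.
#' @export
scan_leader_motif <- function(genome, motif = leader_motif(),
                              min_identity = 0.90, min_len = 35,
                              max_len = 48, both_strands = TRUE) {
  if (nchar(motif) < 10L)
    stop("motif shorter than 10 bp: identity threshold is meaningless")
  if (!(min_identity > 0.5 && min_identity <= 1))
    stop("min_identity must lie in (0.5, 1]")
  gen <- .as_dnastringset(genome)
  if (is.null(names(gen))) names(gen) <- paste0("seq", seq_along(gen))
  m <- nchar(motif)
  max_ed <- ceiling((1 - min_identity) * m)  # superset of admissible hits
  pat <- Biostrings::DNAString(motif)
  pad <- max_ed + 4L

  out <- list()
  strands <- if (both_strands) c("+", "-") else "+"
  for (si in seq_along(gen)) {
    L <- Biostrings::width(gen)[si]
    for (st in strands) {
      subj <- if (st == "+") gen[[si]] else
        Biostrings::reverseComplement(gen[[si]])
      hits <- Biostrings::matchPattern(pat, subj, max.mismatch = max_ed,
                                       with.indels = TRUE)
      if (!length(hits)) next
      hs <- Biostrings::start(hits); he <- Biostrings::end(hits)
      for (k in seq_along(hs)) {
        ws <- max(1L, hs[k] - pad); we <- min(L, he[k] + pad)
        r <- .refine_candidate(motif, subj[ws:we])
        span <- r$s_end - r$s_start + 1L
        if (r$identity < min_identity || span < min_len || span > max_len)
          next
        s1 <- ws + r$s_start - 1L; e1 <- ws + r$s_end  # 0-based half-open
        if (st == "-") { tmp <- L - e1 + 2L; e1 <- L - s1 + 2L; s1 <- tmp }
        out[[length(out) + 1L]] <- data.frame(
          seqid = names(gen)[si], start = s1 - 1L, end = e1 - 1L,
          strand = st, identity = r$identity, matched_length = span,
          stringsAsFactors = FALSE)
      }
    }
  }
  empty <- data.frame(seqid = character(), start = integer(),
                      end = integer(), strand = character(),
                      identity = numeric(), matched_length = integer(),
                      stringsAsFactors = FALSE)
  if (!length(out)) return(empty)
  cand <- unique(do.call(rbind, out))
  # greedy non-overlapping selection: identity desc, then leftmost
  cand <- cand[order(cand$seqid, -cand$identity, cand$start), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (ch in unique(cand$seqid)) {
    idx <- which(cand$seqid == ch)
    taken_s <- integer(0); taken_e <- integer(0)
    for (i in idx) {
      if (!any(cand$start[i] < taken_e & cand$end[i] > taken_s)) {
        keep[i] <- TRUE
        taken_s <- c(taken_s, cand$start[i])
        taken_e <- c(taken_e, cand$end[i])
      }
    }
  }
  res <- cand[keep, , drop = FALSE]
  res <- res[order(res$seqid, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Fraction of reads carrying the leader as a 5' prefix
#'
#' A read carries the leader when some suffix of the motif of length at
#' least `min_suffix` matches the read's 5' end with a mismatch fraction of
#' at most `1 - min_identity` (ungapped).  Reads are also tested in reverse
#' complement.  The suffix rule tolerates 5' shearing of reads that lost
#' part of the leader.
#'
#' @param reads FASTA/FASTQ path, [Biostrings::DNAStringSet], or character
#'   vector.
#' @param motif leader sequence.
#' @param min_identity minimum identity fraction (default 0.90).
#' @param min_suffix shortest motif suffix tested (bp, default 15): long
#'   enough that chance 15-mers are rare, short enough to tolerate 5'
#'   shearing.
#' @return list with `fraction`, `n_carrying`, `n_total`.
#' @export
leader_read_fraction <- function(reads, motif = leader_motif(),
                                 min_identity = 0.90, min_suffix = 15) {
  rd <- if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    if (grepl("\\.f(ast)?q(\\.gz)?$", reads))
      Biostrings::readDNAStringSet(reads, format = "fastq")
    else Biostrings::readDNAStringSet(reads)
  } else .as_dnastringset(reads)
  if (!length(rd)) stop("no reads supplied")
  mot <- strsplit(motif, "")[[1L]]
  m <- length(mot)
  carries_fwd <- function(seq_chars) {
    n <- length(seq_chars)
    for (L in seq(min(m, n), min_suffix)) {
      suf <- mot[(m - L + 1L):m]
      mism <- sum(suf != seq_chars[seq_len(L)])
      if (mism / L <= 1 - min_identity) return(TRUE)
    }
    FALSE
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  carrying <- vapply(as.character(rd), function(s) {
    ch <- strsplit(s, "")[[1L]]
    if (length(ch) < min_suffix) return(FALSE)
    if (carries_fwd(ch)) return(TRUE)
    rc <- rev(unname(comp[ch])); rc[is.na(rc)] <- "N"
    carries_fwd(rc)
  }, logical(1), USE.NAMES = FALSE)
  list(fraction = mean(carrying), n_carrying = sum(carrying),
       n_total = length(rd))
}

#' Cluster genes sharing a leader-like first exon
#'
#' The first exon of each transcript (5'-most in transcript orientation,
#' i.e. the genomic last exon for minus-strand transcripts) is tested
#' against the motif under the scanning rules; genes whose first exon
#' matches are grouped by the matching genomic leader locus.
#'
#' @param ann an [annotation].
#' @param genome genome sequences (FASTA path or
#'   [Biostrings::DNAStringSet]) whose names cover the annotation seqids.
#' @param motif,min_identity,min_len,max_len as in [scan_leader_motif].
#' @return data.frame with `locus` (seqid:start-end key), `seqid`, `start`,
#'   `end`, `gene_id`, one row per matching gene; genes sharing a `locus`
#'   form a cluster.
#' @export
shared_first_exon_clusters <- function(ann, genome, motif = leader_motif(),
                                       min_identity = 0.90, min_len = 35,
                                       max_len = 48) {
  gen <- .as_dnastringset(genome)
  out <- list()
  for (i in seq_len(nrow(ann$transcripts))) {
    tx <- ann$transcripts[i, ]
    e <- ann$exons[ann$exons$tx_id == tx$tx_id, , drop = FALSE]
    first <- if (tx$strand == "-") e[which.max(e$start), ] else
      e[which.min(e$start), ]
    seqi <- match(first$seqid, names(gen))
    if (is.na(seqi)) stop("annotation seqid absent from genome: ",
                          first$seqid)
    exseq <- Biostrings::subseq(gen[[seqi]], first$start + 1L, first$end)
    if (tx$strand == "-") exseq <- Biostrings::reverseComplement(exseq)
    r <- .refine_candidate(motif, exseq)
    span <- r$s_end - r$s_start + 1L
    if (r$identity < min_identity || span < min_len || span > max_len)
      next
    # map aligned span back to forward-strand genome coordinates
    w <- first$end - first$start
    if (tx$strand == "-") {
      gs <- first$start + (w - r$s_end)
      ge <- first$start + (w - r$s_start + 1L)
    } else {
      gs <- first$start + r$s_start - 1L
      ge <- first$start + r$s_end
    }
    out[[length(out) + 1L]] <- data.frame(
      locus = sprintf("%s:%d-%d", first$seqid, gs, ge),
      seqid = first$seqid, start = gs, end = ge, gene_id = tx$gene_id,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(locus = character(), seqid = character(),
                      start = integer(), end = integer(),
                      gene_id = character(), stringsAsFactors = FALSE))
  res <- unique(do.call(rbind, out))
  res <- res[order(res$seqid, res$start, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Census of transcript start dinucleotides
#'
#' Exact tally of the first two bases over transcripts of length >= 2 with
#' unambiguous (ACGT) leading bases; fractions sum to 1 over the valid set.
#'
#' @param tx_seqs character vector or [Biostrings::DNAStringSet] of
#'   transcript sequences (5' to 3').
#' @return data.frame with `dinucleotide`, `n`, `fraction`, sorted by
#'   decreasing count.
#' @export
start_dinucleotide_census <- function(tx_seqs) {
  s <- as.character(.as_dnastringset(tx_seqs))
  if (!length(s)) stop("no transcript sequences supplied")
  di <- toupper(substr(s, 1L, 2L))
  valid <- nchar(s) >= 2L & grepl("^[ACGT]{2}$", di)
  di <- di[valid]
  if (!length(di)) stop("no valid transcripts (length >= 2, unambiguous)")
  tab <- sort(table(di), decreasing = TRUE)
  data.frame(dinucleotide = names(tab), n = as.integer(tab),
             fraction = as.numeric(tab) / sum(tab),
             stringsAsFactors = FALSE)
}
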