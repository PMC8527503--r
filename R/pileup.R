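# Pileup site records: the atom of depth-conditioned heterozygosity
# estimation.  The on-disk contract is a 6-column TSV derivable from standard
# `samtools mpileup` output:
#   seqid  pos(1-based)  depth  ref_count  snp_alt_count  indel_alt_count
# ref/snp/indel counts are reads supporting, respectively, the reference
# allele, a substitution allele, and an insertion/deletion allele.  Each
# count must be <= depth; their sum may fall short of depth (multi-allelic
# remainder), which is why depth is carried explicitly.

#' Read a 6-column pileup site table
#'
#' Converts the 1-based positions of the TSV contract to the package's
#' 0-based convention and validates the per-site count invariants.
#'
#' @param path tab-separated file with columns seqid, position (1-based),
#'   depth, reads matching the reference allele, reads supporting a
#'   substitution allele, reads supporting an indel allele.  No header.
#' @return data.frame of class `pileup` with columns `seqid`, `pos`
#'   (0-based), `depth`, `ref_count`, `snp_alt`, `indel_alt`.
#' @export
read_pileup <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) != 6L)
    stop("pileup TSV must have exactly 6 columns, found ", ncol(x))
  names(x) <- c("seqid", "pos", "depth", "ref_count", "snp_alt", "indel_alt")
  x$pos <- x$pos - 1L
  validate_pileup(x)
}

#' @rdname read_pileup
#' @param sites a `pileup` data.frame (0-based positions).
#' @export
validate_pileup <- function(sites) {
  num <- c("depth", "ref_count", "snp_alt", "indel_alt")
  neg <- which(Reduce(`|`, lapply(sites[num], function(v) v < 0)))
  if (length(neg))
    stop("negative count at ", sites$seqid[neg[1L]], ":",
         sites$pos[neg[1L]] + 1L)
  over <- which(sites$ref_count > sites$depth |
                sites$snp_alt   > sites$depth |
                sites$indel_alt > sites$depth)
  if (length(over))
    stop("allele count exceeds depth at ", sites$seqid[over[1L]], ":",
         sites$pos[over[1L]] + 1L)
  class(sites) <- unique(c("pileup", class(sites)))
  sites
}

#' Write pileup sites to the 6-column TSV contract
#'
#' @param sites `pileup` data.frame (0-based positions).
#' @param path output file; positions are written 1-based.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(sites, path) {
  out <- data.frame(sites$seqid, sites$pos + 1L, sites$depth,
                    sites$ref_count, sites$snp_alt, sites$indel_alt)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
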