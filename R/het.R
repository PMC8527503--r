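# Depth-conditioned heterozygosity estimation.  On a collapsed diploid
# assembly, sites at the modal mapping depth D* carry reads from both
# haplotypes, so heterozygous sites show an allele balance near 1/2 while
# sites near D*/2 (single-haplotype regions) look homozygous.  Restricting
# to D* therefore avoids mis-estimation from assembly collapse, without any
# variant calling.

#' Depth histogram and modal depth of a pileup
#'
#' @param sites `pileup` data.frame.
#' @return list with `counts` (data.frame `depth`, `n`) and `modal_depth`,
#'   the smallest depth >= 1 attaining the maximum site count.
#' @export
depth_histogram <- function(sites) {
  if (nrow(sites) == 0L) stop("empty pileup: cannot build depth histogram")
  tab <- table(sites$depth)
  counts <- data.frame(depth = as.integer(names(tab)), n = as.integer(tab))
  pos <- counts[counts$depth >= 1L, , drop = FALSE]
  if (nrow(pos) == 0L) stop("no sites with depth >= 1")
  modal <- pos$depth[which.max(pos$n)]  # ties -> lowest depth (sorted)
  structure(list(counts = counts, modal_depth = modal),
            class = "depth_histogram")
}

#' @export
print.depth_histogram <- function(x, ...) {
  cat(sprintf("depth histogram: %d sites over %d depth values, mode %dx\n",
              sum(x$counts$n), nrow(x$counts), x$modal_depth))
  invisible(x)
}

#' Classify pileup sites by allele balance
#'
#' With `f = ref_count / depth`: `f >= upper` is `hom_ref`; `f <= 1 - upper`
#' is `hom_alt`; `lower <= f <= upper` is heterozygous, subtype `het_indel`
#' when indel-supporting reads outnumber substitution-supporting reads and
#' `het_snp` otherwise (ties go to SNP); everything else is `other`.
#'
#' @param sites `pileup` data.frame with depth >= 1.
#' @param lower,upper allele-balance band, `0 < lower < 0.5 < upper < 1`
#'   (defaults 0.30 / 0.70).
#' @return factor with levels `hom_ref`, `het_snp`, `het_indel`, `hom_alt`,
#'   `other`.
#' @export
classify_sites <- function(sites, lower = 0.30, upper = 0.70) {
  if (!(lower > 0 && lower < 0.5 && upper > 0.5 && upper < 1))
    stop("band must satisfy 0 < lower < 0.5 < upper < 1")
  if (any(sites$depth < 1L)) stop("sites must have depth >= 1")
  f <- sites$ref_count / sites$depth
  cls <- rep("other", nrow(sites))
  cls[f >= upper] <- "hom_ref"
  cls[f <= 1 - upper] <- "hom_alt"
  het <- f >= lower & f <= upper
  cls[het & sites$indel_alt > sites$snp_alt] <- "het_indel"
  cls[het & sites$indel_alt <= sites$snp_alt] <- "het_snp"
  factor(cls, levels = c("hom_ref", "het_snp", "het_indel", "hom_alt",
                         "other"))
}

.het_row <- function(sites_total, sites_het, variant_class, depth_used,
                     seqid = "all", region = "genome") {
  data.frame(seqid = seqid, region = region, variant_class = variant_class,
             depth_used = depth_used, sites_total = sites_total,
             sites_het = sites_het,
             heterozygosity = if (sites_total > 0) sites_het / sites_total
                              else NA_real_,
             stringsAsFactors = FALSE)
}

#' Estimate heterozygosity at the modal depth
#'
#' The denominator is every site whose depth lies within `depth_window` of
#' `modal_depth` (default: exactly the modal depth); the numerator is the
#' subset classified heterozygous.  Sites in the `other` allele-balance
#' class stay in the denominator: the estimate divides by the total number
#' of sites at that depth.
#'
#' @param sites `pileup` data.frame.
#' @param modal_depth restriction depth D* (x); typically
#'   `depth_histogram(sites)$modal_depth`.
#' @param variant_class one of `"combined"`, `"snp"`, `"indel"` (or several).
#' @param lower,upper allele-balance band (see [classify_sites]).
#' @param depth_window sites with `|depth - modal_depth| <= depth_window`
#'   enter the estimate (default 0).
#' @return data.frame with one row per variant class: `seqid`, `region`,
#'   `variant_class`, `depth_used`, `sites_total`, `sites_het`,
#'   `heterozygosity`.
#' @export
estimate_het <- function(sites, modal_depth,
                         variant_class = c("combined", "snp", "indel"),
                         lower = 0.30, upper = 0.70, depth_window = 0) {
  stopifnot(modal_depth >= 1)
  variant_class <- match.arg(variant_class, several.ok = TRUE)
  at <- sites[abs(sites$depth - modal_depth) <= depth_window, , drop = FALSE]
  if (nrow(at) == 0L)
    stop("no sites at depth ", modal_depth)
  cls <- classify_sites(at, lower, upper)
  n <- nrow(at)
  rows <- lapply(variant_class, function(vc) {
    nhet <- switch(vc,
                   snp = sum(cls == "het_snp"),
                   indel = sum(cls == "het_indel"),
                   combined = sum(cls %in% c("het_snp", "het_indel")))
    .het_row(n, nhet, vc, modal_depth)
  })
  do.call(rbind, rows)
}

## region class per site with precedence exonic > intronic > intergenic;
## a base exonic in any transcript is exonic, intronic = inside a gene span
## but not exonic.
.region_of_sites <- function(sites, ann) {
  miss <- setdiff(unique(sites$seqid), names(ann$seqlens))
  if (length(miss))
    stop("pileup seqid absent from annotation sequence lengths: ", miss[1L])
  region <- rep("intergenic", nrow(sites))
  for (ch in unique(sites$seqid)) {
    i <- which(sites$seqid == ch)
    pos <- sites$pos[i]
    ex <- ann$exons[ann$exons$seqid == ch, , drop = FALSE]
    gn <- ann$genes[ann$genes$seqid == ch, , drop = FALSE]
    inx <- function(df) {
      if (!nrow(df)) return(rep(FALSE, length(pos)))
      r <- IRanges::reduce(IRanges::IRanges(df$start + 1L, df$end))
      IRanges::overlapsAny(IRanges::IRanges(pos + 1L, pos + 1L), r)
    }
    in_exon <- inx(ex)
    in_gene <- inx(gn)
    region[i][in_gene & !in_exon] <- "intronic"
    region[i][in_exon] <- "exonic"
  }
  region
}

#' Heterozygosity stratified by chromosome and region class
#'
#' Assigns each site one region class (exonic > intronic > intergenic,
#' against the strand-collapsed exon/gene unions of the annotation) and
#' emits one [estimate_het] row for every (seqid, region, variant class)
#' stratum with at least one site at the restriction depth.
#'
#' @inheritParams estimate_het
#' @param ann an [annotation] whose sequence set covers the pileup.
#' @return data.frame of heterozygosity estimates.
#' @export
stratified_het <- function(sites, ann, modal_depth, lower = 0.30,
                           upper = 0.70, depth_window = 0) {
  region <- .region_of_sites(sites, ann)
  at <- abs(sites$depth - modal_depth) <= depth_window
  out <- list()
  for (ch in unique(sites$seqid)) for (rg in c("exonic", "intronic",
                                               "intergenic")) {
    sel <- at & sites$seqid == ch & region == rg
    if (!any(sel)) next
    est <- estimate_het(sites[sel, , drop = FALSE], modal_depth,
                        lower = lower, upper = upper,
                        depth_window = depth_window)
    est$seqid <- ch
    est$region <- rg
    out[[length(out) + 1L]] <- est
  }
  do.call(rbind, out)
}

#' Two-dimensional (depth, reference-count) site histogram
#'
#' The exact joint tally underlying the allele-balance picture: bi-allelic
#' sites concentrate near `ref_count = depth / 2` at the modal depth.
#' Marginalizing over `ref_count` reproduces [depth_histogram].
#'
#' @param sites `pileup` data.frame.
#' @return data.frame with columns `depth`, `ref_count`, `n`.
#' @export
allele_balance_2d <- function(sites) {
  if (nrow(sites) == 0L) stop("empty pileup")
  key <- paste(sites$depth, sites$ref_count)
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  out <- data.frame(depth = as.integer(parts[, 1L]),
                    ref_count = as.integer(parts[, 2L]),
                    n = as.integer(tab))
  out <- out[order(out$depth, out$ref_count), , drop = FALSE]
  rownames(out) <- NULL
  out
}
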