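# TAD boundary / gene proximity.  Each TAD contributes two boundary points;
# a boundary inside a gene span scores distance 0, otherwise the distance
# to the nearest gene edge on the same chromosome.  Significance of
# "boundaries sit closer to genes than expected" comes from size-preserving
# random re-placement of the TADs.

.gene_edges_by_chrom <- function(genes) {
  lapply(split(genes, genes$seqid), function(g)
    list(edges = sort(unique(c(g$start, g$end))),
         starts = sort(g$start), ends = g$end[order(g$start)]))
}

## distance of points to nearest gene edge; containment (closed span) -> 0
.point_gene_distance <- function(pos, ginfo) {
  edges <- ginfo$edges
  idx <- findInterval(pos, edges)
  lo <- edges[pmax(idx, 1L)]
  hi <- edges[pmin(idx + 1L, length(edges))]
  d <- pmin(abs(pos - lo), abs(hi - pos))
  # containment: pos within [start, end] of some gene
  si <- findInterval(pos, ginfo$starts)
  inside <- si >= 1L & pos <= ginfo$ends[pmax(si, 1L)]
  # genes may overlap; check the running max of ends up to si
  if (any(!inside & si >= 1L)) {
    cmax <- cummax(ginfo$ends)
    inside <- si >= 1L & pos <= cmax[pmax(si, 1L)]
  }
  d[inside] <- 0
  d
}

.tad_boundaries <- function(tads) {
  b <- rbind(data.frame(seqid = tads$seqid, pos = tads$start),
             data.frame(seqid = tads$seqid, pos = tads$end))
  unique(b)  # adjacent TADs sharing a coordinate contribute it once
}

#' Distances from TAD boundaries to the nearest gene
#'
#' @param tads data.frame of TAD intervals (`seqid`, `start`, `end`;
#'   0-based half-open, e.g. from [read_bed]).
#' @param genes gene spans: an [annotation] or a data.frame with `seqid`,
#'   `start`, `end`.
#' @param chrom_sizes named vector of chromosome lengths; taken from the
#'   annotation when omitted.
#' @return list with `distances` (data.frame `seqid`, `pos`, `distance`,
#'   `no_genes` flag) and `median_distance`.  Boundaries on chromosomes
#'   without genes score the chromosome length and are flagged.
#' @export
boundary_gene_distances <- function(tads, genes, chrom_sizes = NULL) {
  if (is(genes, "annotation")) {
    if (is.null(chrom_sizes)) chrom_sizes <- genes$seqlens
    genes <- genes$genes
  }
  if (is.null(chrom_sizes))
    stop("chrom_sizes required when genes is not an annotation")
  miss <- setdiff(unique(tads$seqid), names(chrom_sizes))
  if (length(miss)) stop("TAD seqid absent from chromosome sizes: ", miss[1L])
  if (any(tads$start < 0 | tads$end > chrom_sizes[tads$seqid]))
    stop("TAD outside chromosome")
  ginfo <- .gene_edges_by_chrom(genes)
  b <- .tad_boundaries(tads)
  b$distance <- NA_real_
  b$no_genes <- FALSE
  for (ch in unique(b$seqid)) {
    i <- b$seqid == ch
    if (is.null(ginfo[[ch]])) {
      b$distance[i] <- chrom_sizes[[ch]]
      b$no_genes[i] <- TRUE
    } else {
      b$distance[i] <- .point_gene_distance(b$pos[i], ginfo[[ch]])
    }
  }
  rownames(b) <- NULL
  list(distances = b, median_distance = median(b$distance))
}

#' Permutation test for TAD-boundary proximity to genes
#'
#' Re-places every TAD `n` times: a chromosome is chosen with probability
#' proportional to its length among chromosomes the TAD fits on, and the
#' start uniformly in `[0, chrom_len - tad_len]`; placed TADs may overlap.
#' Null medians are computed exactly as the observed one, and the one-sided
#' p-value for "boundaries closer to genes than expected" uses the add-one
#' correction `p = (#\{null <= observed\} + 1) / (n + 1)`, so `p` is always
#' in `[1/(n+1), 1]`.
#'
#' @inheritParams boundary_gene_distances
#' @param n number of permutations (default 1000).
#' @param seed integer seed; identical seeds give identical null medians.
#' @return object of class `tad_permutation`: list with `observed_median`,
#'   `null_medians`, `p_value`, `n_permutations`, `seed`.
#' @export
tad_permutation_test <- function(tads, genes, chrom_sizes = NULL, n = 1000,
                                 seed = 1) {
  stopifnot(n >= 1)
  if (is(genes, "annotation")) {
    if (is.null(chrom_sizes)) chrom_sizes <- genes$seqlens
    genes <- genes$genes
  }
  obs <- boundary_gene_distances(tads, genes, chrom_sizes)$median_distance
  ginfo <- .gene_edges_by_chrom(genes)
  lens <- tads$end - tads$start
  if (any(lens > max(chrom_sizes)))
    stop("a TAD is longer than every chromosome")
  chroms <- names(chrom_sizes)
  T_ <- length(lens)
  null_medians <- .with_seed(seed, {
    # vectorized over permutations: draw all chromosomes and starts at once
    ch_mat <- matrix(NA_integer_, nrow = T_, ncol = n)
    for (t in seq_len(T_)) {
      fit <- which(chrom_sizes >= lens[t])
      ch_mat[t, ] <- if (length(fit) == 1L) rep(fit, n) else
        sample(fit, n, replace = TRUE, prob = chrom_sizes[fit])
    }
    start_mat <- matrix(
      floor(runif(T_ * n) *
              (chrom_sizes[as.vector(ch_mat)] - rep(lens, n) + 1)),
      nrow = T_)
    end_mat <- start_mat + lens
    pos <- rbind(start_mat, end_mat)           # 2T x n boundary points
    chn <- rbind(ch_mat, ch_mat)
    dist <- matrix(NA_real_, nrow = 2L * T_, ncol = n)
    for (ci in seq_along(chroms)) {
      sel <- chn == ci
      if (!any(sel)) next
      gi <- ginfo[[chroms[ci]]]
      dist[sel] <- if (is.null(gi)) chrom_sizes[[ci]] else
        .point_gene_distance(pos[sel], gi)
    }
    apply(dist, 2L, median)
  })
  p <- (sum(null_medians <= obs) + 1) / (n + 1)
  structure(list(observed_median = obs, null_medians = null_medians,
                 p_value = p, n_permutations = n, seed = seed),
            class = "tad_permutation")
}

#' @export
print.tad_permutation <- function(x, ...) {
  cat(sprintf(
    "TAD boundary permutation test: observed median %.0f bp, p = %.4g (%d permutations)\n",
    x$observed_median, x$p_value, x$n_permutations))
  invisible(x)
}

#' Order statistics of TAD lengths
#'
#' @param tads data.frame of TAD intervals (`seqid`, `start`, `end`).
#' @return list with `median`, `mean`, `n`.
#' @export
tad_length_stats <- function(tads) {
  if (!nrow(tads)) stop("empty TAD set")
  lens <- tads$end - tads$start
  if (any(lens <= 0)) stop("TAD lengths must be positive")
  list(median = median(lens), mean = mean(lens), n = length(lens))
}
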