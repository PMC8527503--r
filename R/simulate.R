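# Seeded generators producing inputs with the statistical structure each
# analysis assumes, together with recorded ground truth.  Every generator
# draws all randomness from one seeded generator per invocation and restores
# the caller's RNG state on exit, so identical seed + config give identical
# output without disturbing the session.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  expr
}

#' Simulate a diploid read pileup
#'
#' Emulates short-read pileups over a collapsed diploid reference: per-site
#' depth is Poisson around a mean (negative-binomial over-dispersion
#' available via `dispersion`), heterozygous sites draw each read from either
#' haplotype with probability 1/2, and sequencing errors flip a read's
#' support to one of the two wrong allele categories.  Indel heterozygosity
#' is planted directly as pileup signal (reads supporting an indel allele);
#' the consuming estimator reads pileups only, so indels are never realized
#' in sequence space.
#'
#' @param genome_length number of sites (bp).
#' @param mean_depth mean mapping depth (x).
#' @param snp_rate,indel_rate per-bp probabilities of a heterozygous SNP /
#'   indel; their sum must be < 1.
#' @param error_rate per-read probability of miscalled allele support.
#' @param dispersion optional negative-binomial size parameter; `NULL`
#'   (default) keeps the Poisson depth model.
#' @param seqid sequence name used in the emitted sites.
#' @param seed integer seed; identical seed and configuration give
#'   byte-identical output.
#' @return list with `sites` (a `pileup` data.frame), `truth` (data.frame of
#'   planted variants: `pos`, `type`), `true_snp_het`, `true_indel_het`,
#'   `true_combined_het` (realized fractions).
#' @export
simulate_diploid_pileup <- function(genome_length, mean_depth = 178,
                                    snp_rate = 0.02, indel_rate = 0.012,
                                    error_rate = 0, dispersion = NULL,
                                    seqid = "sim1", seed = 1) {
  stopifnot(genome_length > 0, snp_rate >= 0, indel_rate >= 0,
            error_rate >= 0, error_rate <= 1)
  if (snp_rate + indel_rate >= 1)
    stop("snp_rate + indel_rate must be < 1")
  .with_seed(seed, {
    L <- as.integer(genome_length)
    u <- runif(L)
    type <- integer(L)                       # 0 hom, 1 snp, 2 indel
    type[u < snp_rate] <- 1L
    type[u >= snp_rate & u < snp_rate + indel_rate] <- 2L
    depth <- if (is.null(dispersion)) rpois(L, mean_depth)
             else stats::rnbinom(L, size = dispersion, mu = mean_depth)

    ref <- depth
    snp <- integer(L)
    indel <- integer(L)
    het <- type > 0L
    alt <- rbinom(sum(het), depth[het], 0.5)
    ref[het] <- depth[het] - alt
    snp[het][type[het] == 1L] <- alt[type[het] == 1L]
    indel[het][type[het] == 2L] <- alt[type[het] == 2L]

    if (error_rate > 0) {
      # each read flips to one of the two wrong categories with equal odds
      flip <- function(n) { e <- rbinom(length(n), n, error_rate)
                            a <- rbinom(length(e), e, 0.5); cbind(e, a) }
      fr <- flip(ref)   # ref reads -> snp (a) or indel (e - a)
      fs <- flip(snp)   # snp reads -> ref (a) or indel (e - a)
      fi <- flip(indel) # indel reads -> ref (a) or snp (e - a)
      ref2   <- ref - fr[, 1L] + fs[, 2L] + fi[, 2L]
      snp2   <- snp - fs[, 1L] + fr[, 2L] + (fi[, 1L] - fi[, 2L])
      indel2 <- indel - fi[, 1L] + (fr[, 1L] - fr[, 2L]) + (fs[, 1L] - fs[, 2L])
      ref <- ref2; snp <- snp2; indel <- indel2
    }

    sites <- validate_pileup(data.frame(
      seqid = seqid, pos = 0:(L - 1L), depth = depth, ref_count = ref,
      snp_alt = snp, indel_alt = indel, stringsAsFactors = FALSE))
    truth <- data.frame(pos = which(het) - 1L,
                        type = c("snp", "indel")[type[het]],
                        stringsAsFactors = FALSE)
    list(sites = sites, truth = truth,
         true_snp_het = sum(type == 1L) / L,
         true_indel_het = sum(type == 2L) / L,
         true_combined_het = sum(het) / L)
  })
}

#' Simulate an annotation containing nested intronic genes
#'
#' Builds host genes with a large central intron and plants nested genes
#' inside it, optionally overlapping the host's flanking exons by a
#' controlled fraction of the nested transcript length at the 5' and/or 3'
#' end.  Doubly nested genes are planted inside the intron of another
#' planted (two-exon) nested gene.  The returned truth table lists every
#' planted nesting relation with its depth.
#'
#' @param n_hosts number of host genes.
#' @param n_nested total number of nested genes to plant (depth 1 and 2).
#' @param n_doubly how many of `n_nested` are doubly nested (depth 2);
#'   each requires a depth-1 carrier gene with its own intron.
#' @param overlap5,overlap3 numeric vectors (recycled over depth-1 genes) of
#'   end-overlap fractions in `[0, 0.5)`: the planted 5'/3' overlap into the
#'   host exon as a fraction of the nested transcript length.
#' @param host_exon_len,host_intron_len,nested_len geometry (bp).
#' @param seqid sequence name.
#' @param seed integer seed.
#' @return list with `annotation` (an [annotation]) and `truth` (data.frame
#'   `nested_gene_id`, `host_gene_id`, `depth`, `overlap5`, `overlap3`).
#' @export
simulate_nested_annotation <- function(n_hosts = 1, n_nested = 4,
                                       n_doubly = 0, overlap5 = 0,
                                       overlap3 = 0, host_exon_len = 2000,
                                       host_intron_len = 40000,
                                       nested_len = 1000, seqid = "chrS",
                                       seed = 1) {
  stopifnot(n_hosts >= 0, n_nested >= 0, n_doubly >= 0, n_doubly <= n_nested)
  if (any(overlap5 < 0 | overlap5 >= 0.5) || any(overlap3 < 0 | overlap3 >= 0.5))
    stop("overlap fractions must lie in [0, 0.5)")
  .with_seed(seed, {
    genes <- list(); txs <- list(); exons <- list(); truth <- list()
    add_gene <- function(id, start, end, strand, exon_bounds) {
      genes[[length(genes) + 1L]] <<- data.frame(
        gene_id = id, seqid = seqid, start = start, end = end,
        strand = strand, stringsAsFactors = FALSE)
      txid <- paste0(id, ".t1")
      txs[[length(txs) + 1L]] <<- data.frame(
        tx_id = txid, gene_id = id, seqid = seqid, start = start, end = end,
        strand = strand, stringsAsFactors = FALSE)
      exons[[length(exons) + 1L]] <<- data.frame(
        tx_id = txid, seqid = seqid, start = exon_bounds[, 1L],
        end = exon_bounds[, 2L], strand = strand, stringsAsFactors = FALSE)
    }

    n_depth1 <- n_nested - n_doubly
    per_host <- if (n_hosts > 0)
      diff(floor(seq(0, n_depth1, length.out = n_hosts + 1L))) else integer()
    o5 <- rep_len(overlap5, max(n_depth1, 1L))
    o3 <- rep_len(overlap3, max(n_depth1, 1L))

    cursor <- 1000L
    host_span <- 2L * host_exon_len + host_intron_len
    k <- 0L              # depth-1 gene counter
    d2_left <- n_doubly  # inner genes still to plant
    for (h in seq_len(n_hosts)) {
      hs <- cursor
      he <- hs + host_span
      hid <- sprintf("host%d", h)
      istart <- hs + host_exon_len
      iend <- he - host_exon_len
      add_gene(hid, hs, he, "+",
               rbind(c(hs, istart), c(iend, he)))
      slots <- per_host[h]
      if (slots > 0) {
        gap <- (host_intron_len - slots * nested_len) %/% (slots + 1L)
        if (gap < 1L) stop("intron too short for requested nested genes")
        for (s in seq_len(slots)) {
          k <- k + 1L
          ov5 <- floor(o5[k] * nested_len)
          ov3 <- floor(o3[k] * nested_len)
          ns <- istart + s * gap + (s - 1L) * nested_len
          ne <- ns + nested_len
          # first slot takes the 5' overlap, last slot the 3' overlap; with a
          # single slot the 3' request wins (transcript length is fixed)
          if (s == 1L && ov5 > 0) { ns <- istart - ov5; ne <- ns + nested_len }
          if (s == slots && ov3 > 0) { ne <- iend + ov3; ns <- ne - nested_len }
          nid <- sprintf("nested%d", k)
          strand <- sample(c("+", "-"), 1L)
          if (d2_left > 0L) {
            # two-exon carrier whose intron hosts an inner (depth-2) gene
            ex <- max(100L, nested_len %/% 5L)
            inner_len <- max(50L, (nested_len - 2L * ex) %/% 3L)
            add_gene(nid, ns, ne, strand,
                     rbind(c(ns, ns + ex), c(ne - ex, ne)))
            iin <- ns + ex; iout <- ne - ex
            ipad <- ((iout - iin) - inner_len) %/% 2L
            if (ipad < 1L) stop("intron too short for requested nested genes")
            did <- sprintf("inner%d", n_doubly - d2_left + 1L)
            ds <- iin + ipad
            add_gene(did, ds, ds + inner_len, sample(c("+", "-"), 1L),
                     cbind(ds, ds + inner_len))
            truth[[length(truth) + 1L]] <- data.frame(
              nested_gene_id = did, host_gene_id = nid, depth = 2L,
              overlap5 = 0, overlap3 = 0, stringsAsFactors = FALSE)
            d2_left <- d2_left - 1L
          } else {
            add_gene(nid, ns, ne, strand, cbind(ns, ne))
          }
          truth[[length(truth) + 1L]] <- data.frame(
            nested_gene_id = nid, host_gene_id = hid, depth = 1L,
            overlap5 = ov5 / nested_len, overlap3 = ov3 / nested_len,
            stringsAsFactors = FALSE)
        }
      }
      cursor <- he + 5000L
    }
    g <- do.call(rbind, genes); t <- do.call(rbind, txs)
    e <- do.call(rbind, exons)
    tr <- if (length(truth)) do.call(rbind, truth) else
      data.frame(nested_gene_id = character(), host_gene_id = character(),
                 depth = integer(), overlap5 = numeric(),
                 overlap3 = numeric(), stringsAsFactors = FALSE)
    ann <- annotation(g, t, e,
                      seqlens = setNames(cursor + 10000, seqid))
    list(annotation = ann, truth = tr)
  })
}

#' Simulate a pair of genomes with known ortholog gene order
#'
#' Genome A carries `n_genes` single-exon genes in order along one sequence;
#' genome B is the same gene order transformed by a list of rearrangements
#' (inversions reverse a span in place; relocations excise a span to a
#' separate sequence, leaving the donor coordinates unfilled).  Hit tables
#' contain exactly the one-to-one ortholog pairs, plus optional lower-score
#' decoy hits.  The truth blocks are the maximal collinear runs implied by
#' the construction.
#'
#' @param n_genes number of ortholog pairs.
#' @param rearrangements list of `list(type = "inversion"|"relocation",
#'   span = c(from, to))` in A gene indices; spans must not overlap.
#' @param gene_len,spacing gene length and start-to-start spacing (bp).  The
#'   default spacing (12 kb) keeps adjacent genes within the 30 kb chaining
#'   gap while a >=3-gene excision exceeds it.
#' @param n_decoys number of random low-bitscore decoy hits per direction.
#' @param seed integer seed.
#' @return list with annotations `ann_a`, `ann_b`, hit tables `hits_ab`,
#'   `hits_ba` (12-column blast-style data.frames), and `truth_blocks`
#'   (data.frame `block_id`, `a_from`, `a_to`, `orientation`, `b_seqid`,
#'   `n_genes`; one row per maximal collinear run).
#' @export
simulate_ortholog_tables <- function(n_genes = 20, rearrangements = list(),
                                     gene_len = 2000, spacing = 12000,
                                     n_decoys = 0, seed = 1) {
  stopifnot(n_genes >= 1)
  spans <- lapply(rearrangements, `[[`, "span")
  for (sp in spans)
    if (sp[1L] < 1 || sp[2L] > n_genes || sp[1L] > sp[2L])
      stop("rearrangement span outside gene count")
  if (length(spans) > 1L) {
    m <- do.call(rbind, spans)
    m <- m[order(m[, 1L]), , drop = FALSE]
    if (any(m[-1L, 1L] <= m[-nrow(m), 2L]))
      stop("overlapping rearrangement spans")
  }
  .with_seed(seed, {
    mk_ann <- function(ids, seqids, starts, strand = "+") {
      seqids <- rep_len(seqids, length(ids))
      annotation(
        data.frame(gene_id = ids, seqid = seqids, start = starts,
                   end = starts + gene_len, strand = strand,
                   stringsAsFactors = FALSE),
        data.frame(tx_id = paste0(ids, ".t"), gene_id = ids, seqid = seqids,
                   start = starts, end = starts + gene_len, strand = strand,
                   stringsAsFactors = FALSE),
        data.frame(tx_id = paste0(ids, ".t"), seqid = seqids, start = starts,
                   end = starts + gene_len, strand = strand,
                   stringsAsFactors = FALSE),
        seqlens = {
          sl <- tapply(starts + gene_len + spacing, seqids, max)
          setNames(as.numeric(sl), names(sl))
        })
    }
    a_ids <- sprintf("a%d", seq_len(n_genes))
    b_ids <- sprintf("b%d", seq_len(n_genes))
    a_starts <- (seq_len(n_genes) - 1L) * spacing + 1000
    ann_a <- mk_ann(a_ids, "chrA1", a_starts)

    # B layout: A coordinates inherited; inverted spans reversed in place;
    # relocated spans moved to chrB2 (original slots left empty).
    b_seq <- rep("chrB1", n_genes)
    b_start <- a_starts
    boundaries <- c(0L, n_genes)  # segment cut points (after index)
    reloc_cursor <- 1000
    segs <- list()
    for (r in rearrangements) {
      sp <- r$span
      boundaries <- c(boundaries, sp[1L] - 1L, sp[2L])
      idx <- sp[1L]:sp[2L]
      if (r$type == "inversion") {
        b_start[idx] <- rev(b_start[idx])
        segs[[length(segs) + 1L]] <- data.frame(
          a_from = sp[1L], a_to = sp[2L], orientation = "reverse",
          b_seqid = "chrB1", stringsAsFactors = FALSE)
      } else if (r$type == "relocation") {
        b_seq[idx] <- "chrB2"
        b_start[idx] <- reloc_cursor + (seq_along(idx) - 1L) * spacing
        reloc_cursor <- reloc_cursor + length(idx) * spacing + 100000
        segs[[length(segs) + 1L]] <- data.frame(
          a_from = sp[1L], a_to = sp[2L], orientation = "forward",
          b_seqid = "chrB2", stringsAsFactors = FALSE)
      } else stop("unknown rearrangement type: ", r$type)
    }
    boundaries <- sort(unique(boundaries))
    covered <- unlist(lapply(spans, function(sp) sp[1L]:sp[2L]))
    for (i in seq_len(length(boundaries) - 1L)) {
      from <- boundaries[i] + 1L; to <- boundaries[i + 1L]
      if (from > to || any(from:to %in% covered)) next
      segs[[length(segs) + 1L]] <- data.frame(
        a_from = from, a_to = to, orientation = "forward",
        b_seqid = "chrB1", stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, segs)
    truth <- truth[order(truth$a_from), , drop = FALSE]
    truth$block_id <- seq_len(nrow(truth))
    truth$n_genes <- truth$a_to - truth$a_from + 1L
    rownames(truth) <- NULL
    ann_b <- mk_ann(b_ids, b_seq, b_start)

    mk_hits <- function(q, s) data.frame(
      qseqid = q, sseqid = s, pident = 95, length = gene_len %/% 3,
      mismatch = 10, gapopen = 0, qstart = 1, qend = gene_len %/% 3,
      sstart = 1, send = gene_len %/% 3, evalue = 1e-100, bitscore = 500,
      stringsAsFactors = FALSE)
    hits_ab <- mk_hits(a_ids, b_ids)
    hits_ba <- mk_hits(b_ids, a_ids)
    if (n_decoys > 0) {
      dq <- sample(a_ids, n_decoys, replace = TRUE)
      ds <- sample(b_ids, n_decoys, replace = TRUE)
      decoy <- mk_hits(dq, ds); decoy$bitscore <- 100; decoy$evalue <- 1e-10
      hits_ab <- rbind(hits_ab, decoy)
      decoy2 <- mk_hits(ds, dq); decoy2$bitscore <- 100; decoy2$evalue <- 1e-10
      hits_ba <- rbind(hits_ba, decoy2)
    }
    list(ann_a = ann_a, ann_b = ann_b, hits_ab = hits_ab, hits_ba = hits_ba,
         truth_blocks = truth[, c("block_id", "a_from", "a_to", "orientation",
                                  "b_seqid", "n_genes")])
  })
}

#' Simulate a genome with planted spliced-leader motif copies
#'
#' Plants `n_insertions` copies of the leader motif at non-overlapping
#' uniform random loci on random strands in an i.i.d. uniform ACGT
#' background, each copy independently mutated at
#' `ceiling(divergence * nchar(motif))` distinct positions.
#'
#' @param genome_length background length (bp).
#' @param n_insertions number of planted copies.
#' @param divergence fraction of motif positions mutated per copy, in
#'   `[0, 0.3]`.
#' @param motif leader sequence (default: the 44-bp ctenophore spliced
#'   leader).
#' @param seed integer seed.
#' @return list with `genome` (a [Biostrings::DNAStringSet] of one
#'   sequence named `simL`) and `truth` (data.frame `start`, `end` (0-based
#'   half-open), `strand`, `n_mut`, `identity`).
#' @export
simulate_leader_sequences <- function(genome_length, n_insertions,
                                      divergence = 0,
                                      motif = leader_motif(), seed = 1) {
  stopifnot(genome_length > 0, n_insertions >= 0)
  if (divergence < 0 || divergence > 0.3)
    stop("divergence must lie in [0, 0.3]")
  m <- nchar(motif)
  .with_seed(seed, {
    bg <- sample(c("A", "C", "G", "T"), genome_length, replace = TRUE)
    starts <- integer(0)
    tries <- 0L
    while (length(starts) < n_insertions) {
      cand <- sample.int(genome_length - m + 1L, 1L)
      if (!any(abs(cand - starts) < m)) starts <- c(starts, cand)
      tries <- tries + 1L
      if (tries > 1000L * max(n_insertions, 1L))
        stop("cannot place insertions without overlap")
    }
    n_mut <- as.integer(ceiling(divergence * m))
    truth <- data.frame(start = integer(0), end = integer(0),
                        strand = character(0), n_mut = integer(0),
                        identity = numeric(0), stringsAsFactors = FALSE)
    for (s in starts) {
      copy <- strsplit(motif, "")[[1L]]
      if (n_mut > 0) {
        at <- sample.int(m, n_mut)
        for (p in at)
          copy[p] <- sample(setdiff(c("A", "C", "G", "T"), copy[p]), 1L)
      }
      strand <- sample(c("+", "-"), 1L)
      planted <- if (strand == "+") copy else
        rev(chartr("ACGT", "TGCA", copy))
      bg[s:(s + m - 1L)] <- planted
      truth <- rbind(truth, data.frame(
        start = s - 1L, end = s - 1L + m, strand = strand, n_mut = n_mut,
        identity = (m - n_mut) / m, stringsAsFactors = FALSE))
    }
    genome <- Biostrings::DNAStringSet(paste(bg, collapse = ""))
    names(genome) <- "simL"
    list(genome = genome, truth = truth[order(truth$start), , drop = FALSE])
  })
}

#' The 44-bp ctenophore trans-spliced leader motif
#' @return character scalar.
#' @export
leader_motif <- function()
  "GAGTTTCAAACTTTTCAACACTACTTTAAACAAATTAATTTGAG"

#' Simulate a TAD landscape with controlled boundary-to-gene offsets
#'
#' Genes are laid along each chromosome with irregular lengths and
#' intergenic gaps (uniform jitter around `gene_len` and `mean_gap`), so
#' that gene edges carry no periodic structure a random placement could
#' accidentally phase-lock to.  Each TAD boundary is placed at a sampled
#' offset downstream of an actual gene end: the start boundary at
#' `offset` bp past a random anchor gene end, the end boundary at `offset`
#' bp past the gene end nearest to `start + tad_length`.  Offsets are
#' therefore realized exactly (the true median boundary-to-gene distance
#' equals the median of the supplied offsets) while TAD lengths are
#' honored up to the local gene spacing.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param n_tads number of TADs.
#' @param tad_length TAD length(s) in bp, recycled over TADs (default
#'   60 kb, a small-TAD regime).
#' @param offsets numeric vector of boundary offsets (bp), recycled over
#'   the `2 * n_tads` boundaries; each must be smaller than `0.3 *
#'   mean_gap` so the planted offset is guaranteed to be the distance to
#'   the nearest gene edge.
#' @param mean_gap,gene_len mean intergenic gap and gene length (bp); both
#'   are jittered uniformly by +/-40%.
#' @return list with `tads` (data.frame `seqid`, `start`, `end`), `genes`
#'   (data.frame `seqid`, `start`, `end`, `gene_id`), `truth_median_offset`,
#'   and `offsets` (the realized per-boundary offsets).
#' @param seed integer seed.
#' @export
simulate_tad_landscape <- function(chrom_sizes, n_tads, tad_length = 60000,
                                   offsets = 0, mean_gap = 8000,
                                   gene_len = 2000, seed = 1) {
  stopifnot(n_tads >= 1, all(chrom_sizes > 0))
  if (any(offsets < 0) || any(offsets >= 0.3 * mean_gap))
    stop("offset larger than intergenic space")
  lens <- rep_len(tad_length, n_tads)
  offs <- rep_len(offsets, 2L * n_tads)
  .with_seed(seed, {
    genes <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
      size <- chrom_sizes[[ch]]
      starts <- numeric(0); ends <- numeric(0)
      cursor <- 1000
      repeat {
        gl <- round(gene_len * runif(1, 0.6, 1.4))
        if (cursor + gl > size - 1000) break
        starts <- c(starts, cursor); ends <- c(ends, cursor + gl)
        cursor <- cursor + gl + round(mean_gap * runif(1, 0.6, 1.4))
      }
      data.frame(seqid = ch, start = starts, end = ends,
                 gene_id = sprintf("%s.g%d", ch, seq_along(starts)),
                 stringsAsFactors = FALSE)
    }))
    margin <- 2 * (mean_gap + gene_len)
    tads <- vector("list", n_tads)
    for (i in seq_len(n_tads)) {
      fit <- names(chrom_sizes)[chrom_sizes >= lens[i] + 2 * margin]
      if (!length(fit)) stop("TADs do not fit within chromosomes")
      ch <- if (length(fit) == 1L) fit else
        sample(fit, 1L, prob = chrom_sizes[fit])
      ge <- sort(genes$end[genes$seqid == ch])
      anchors <- ge[ge + lens[i] + margin <= chrom_sizes[[ch]] & ge > margin]
      if (!length(anchors)) stop("TADs do not fit within chromosomes")
      a <- if (length(anchors) == 1L) anchors else sample(anchors, 1L)
      s <- a + offs[2L * i - 1L]
      later <- ge[ge > s + gene_len]
      e2 <- later[which.min(abs(later - (s + lens[i])))]
      e <- e2 + offs[2L * i]
      tads[[i]] <- data.frame(seqid = ch, start = s, end = e,
                              stringsAsFactors = FALSE)
    }
    tads <- do.call(rbind, tads)
    list(tads = tads, genes = genes,
         truth_median_offset = median(offs),
         offsets = offs)
  })
}
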