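# Independent oracles and fixture builders shared across the test files.
# These deliberately use plain scalar R and exhaustive enumeration, not the
# package's own code paths.

## ---- affine-gap global alignment oracle (Gotoh, with traceback) ----
## gap of length k costs gap_open + k * gap_extend, as in the implementation
oracle_global_identity <- function(a, b, match = 1, mismatch = -1,
                                   gap_open = 2, gap_extend = 0.5) {
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)  # ends with A char over gap
  Y <- matrix(NEG, n + 1L, m + 1L)  # ends with gap over B char
  M[1L, 1L] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- -(gap_open + gap_extend * i)
  for (j in seq_len(m)) Y[1L, j + 1L] <- -(gap_open + gap_extend * j)
  go <- gap_open + gap_extend; ge <- gap_extend
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (A[i] == B[j]) match else mismatch
    M[i + 1L, j + 1L] <- s + max(M[i, j], X[i, j], Y[i, j])
    X[i + 1L, j + 1L] <- max(M[i, j + 1L] - go, X[i, j + 1L] - ge,
                             Y[i, j + 1L] - go)
    Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - go, X[i + 1L, j] - go,
                             Y[i + 1L, j] - ge)
  }
  state <- which.max(c(M[n + 1L, m + 1L], X[n + 1L, m + 1L],
                       Y[n + 1L, m + 1L]))
  i <- n; j <- m; matches <- 0L; cols <- 0L
  while (i > 0L || j > 0L) {
    cols <- cols + 1L
    if (state == 1L) {
      if (A[i] == B[j]) matches <- matches + 1L
      s <- if (A[i] == B[j]) match else mismatch
      prev <- c(M[i, j], X[i, j], Y[i, j])
      state <- which.max(prev)
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      prev <- c(M[i, j + 1L] - go, X[i, j + 1L] - ge, Y[i, j + 1L] - go)
      state <- which.max(prev)
      i <- i - 1L
    } else {
      prev <- c(M[i + 1L, j] - go, X[i + 1L, j] - go, Y[i + 1L, j] - ge)
      state <- which.max(prev)
      j <- j - 1L
    }
  }
  list(identity = 100 * matches / cols, matches = matches, columns = cols)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

## ---- quadratic brute-force nested-gene oracle ----
## tests every (gene, transcript, intron) triple directly with scalar
## interval arithmetic; same definition, independent route
oracle_nested <- function(ann, intron_set, tol = 0.15) {
  covered <- function(from, to, htx) {
    if (from >= to) return(TRUE)
    e <- ann$exons[ann$exons$tx_id == htx, , drop = FALSE]
    if (!nrow(e)) return(FALSE)
    all(vapply(from:(to - 1L), function(p)
      any(e$start <= p & p < e$end), logical(1)))
  }
  out <- list()
  for (gid in ann$genes$gene_id) {
    best <- NULL
    txs <- ann$transcripts[ann$transcripts$gene_id == gid, , drop = FALSE]
    for (ti in seq_len(nrow(txs))) {
      tx <- txs[ti, ]
      lenT <- tx$end - tx$start
      allow <- floor(tol * lenT)
      for (ii in seq_len(nrow(intron_set))) {
        ir <- intron_set[ii, ]
        if (ir$host_gene_id == gid || ir$seqid != tx$seqid) next
        lov <- max(0L, ir$start - tx$start)
        rov <- max(0L, tx$end - ir$end)
        if (lov > allow || rov > allow) next
        if (!covered(tx$start, ir$start, ir$host_tx_id)) next
        if (!covered(ir$end, tx$end, ir$host_tx_id)) next
        cand <- list(host = ir$host_gene_id, span = ir$end - ir$start,
                     start = ir$start)
        if (is.null(best) ||
            cand$span < best$span ||
            (cand$span == best$span && cand$start < best$start) ||
            (cand$span == best$span && cand$start == best$start &&
             cand$host < best$host))
          best <- cand
      }
    }
    if (!is.null(best))
      out[[length(out) + 1L]] <- data.frame(
        nested_gene_id = gid, host_gene_id = best$host,
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(nested_gene_id = character(),
                      host_gene_id = character(), nesting_depth = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$nesting_depth <- ifelse(res$host_gene_id %in% res$nested_gene_id,
                              2L, 1L)
  res[order(res$nested_gene_id), , drop = FALSE]
}

## random small annotation: a mix of hosts, nested genes, overlapping and
## free-standing genes; valid by construction
rand_annotation <- function(n_genes = 30, seqids = c("c1", "c2")) {
  genes <- list(); txs <- list(); exons <- list()
  cursors <- setNames(rep(1000L, length(seqids)), seqids)
  for (i in seq_len(n_genes)) {
    ch <- sample(seqids, 1L)
    kind <- sample(c("plain", "host", "jump"), 1L,
                   prob = c(0.4, 0.4, 0.2))
    gid <- sprintf("g%03d", i)
    strand <- sample(c("+", "-"), 1L)
    st <- cursors[[ch]] + sample(0:2000, 1L)
    if (kind == "plain") {
      len <- sample(300:2000, 1L)
      ex <- cbind(st, st + len)
    } else if (kind == "host") {
      e1 <- sample(200:1500, 1L); ilen <- sample(1000:20000, 1L)
      e2 <- sample(200:1500, 1L)
      ex <- rbind(c(st, st + e1),
                  c(st + e1 + ilen, st + e1 + ilen + e2))
    } else {
      # gene planted inside the previous gene's footprint (may nest)
      st <- max(1000L, cursors[[ch]] - sample(2000:15000, 1L))
      len <- sample(200:1500, 1L)
      ex <- cbind(st, st + len)
    }
    en <- max(ex[, 2L])
    genes[[i]] <- data.frame(gene_id = gid, seqid = ch, start = min(ex[, 1L]),
                             end = en, strand = strand,
                             stringsAsFactors = FALSE)
    txid <- paste0(gid, ".t1")
    txs[[i]] <- data.frame(tx_id = txid, gene_id = gid, seqid = ch,
                           start = min(ex[, 1L]), end = en, strand = strand,
                           stringsAsFactors = FALSE)
    exons[[i]] <- data.frame(tx_id = txid, seqid = ch, start = ex[, 1L],
                             end = ex[, 2L], strand = strand,
                             stringsAsFactors = FALSE)
    cursors[[ch]] <- max(cursors[[ch]], en) + sample(100:4000, 1L)
  }
  annotation(do.call(rbind, genes), do.call(rbind, txs),
             do.call(rbind, exons),
             seqlens = cursors + 50000)
}

## ---- exhaustive collinear-chain oracle ----
## enumerates every contiguous interval of the A-ordered pair list, keeps
## maximal valid constant-direction intervals, then applies the
## longer-block-wins / earlier-start conflict rule
oracle_blocks <- function(pairs, ann_a, ann_b, min_block = 3,
                          max_intervening = 5, max_gap = 30000) {
  ord_tab <- function(ann) {
    g <- ann$genes
    g <- g[order(g$seqid, g$start, g$end, g$gene_id), , drop = FALSE]
    g$ordinal <- unlist(lapply(split(seq_len(nrow(g)), g$seqid)[
      unique(g$seqid)], seq_along), use.names = FALSE)
    g
  }
  ga <- ord_tab(ann_a); gb <- ord_tab(ann_b)
  ia <- match(pairs$gene_a, ga$gene_id); ib <- match(pairs$gene_b, gb$gene_id)
  p <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                  a_seqid = ga$seqid[ia], a_start = ga$start[ia],
                  a_ord = ga$ordinal[ia], b_seqid = gb$seqid[ib],
                  b_start = gb$start[ib], b_ord = gb$ordinal[ib],
                  stringsAsFactors = FALSE)
  p <- p[order(p$a_seqid, p$a_ord), , drop = FALSE]
  n <- nrow(p)
  valid <- function(i, j) {
    if (j - i < 1L) return(FALSE)
    signs <- integer(0)
    for (k in (i + 1L):j) {
      if (p$a_seqid[k] != p$a_seqid[k - 1L] ||
          p$b_seqid[k] != p$b_seqid[k - 1L]) return(FALSE)
      if (p$a_ord[k] - p$a_ord[k - 1L] - 1L > max_intervening) return(FALSE)
      if (abs(p$b_ord[k] - p$b_ord[k - 1L]) - 1L > max_intervening)
        return(FALSE)
      if (abs(p$a_start[k] - p$a_start[k - 1L]) > max_gap) return(FALSE)
      if (abs(p$b_start[k] - p$b_start[k - 1L]) > max_gap) return(FALSE)
      signs <- c(signs, sign(p$b_ord[k] - p$b_ord[k - 1L]))
    }
    length(unique(signs)) == 1L
  }
  cand <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i || !valid(i, j)) next
    if ((i > 1L && valid(i - 1L, j)) || (j < n && valid(i, j + 1L))) next
    cand[[length(cand) + 1L]] <- c(i, j)
  }
  cand <- Filter(function(cc) cc[2L] - cc[1L] + 1L >= min_block, cand)
  if (length(cand)) {
    ord <- order(-vapply(cand, function(cc) cc[2L] - cc[1L] + 1L, numeric(1)),
                 vapply(cand, function(cc) p$a_seqid[cc[1L]], character(1)),
                 vapply(cand, function(cc) p$a_start[cc[1L]], numeric(1)))
    cand <- cand[ord]
    used <- rep(FALSE, n)
    keep <- list()
    for (cc in cand) {
      idx <- cc[1L]:cc[2L]
      idx <- idx[!used[idx]]
      if (length(idx) > 1L) {
        grp <- cumsum(c(1L, diff(idx) != 1L))
        pieces <- split(idx, grp)
        idx <- pieces[[which.max(lengths(pieces))]]
      }
      if (length(idx) >= min_block) {
        used[idx] <- TRUE
        keep[[length(keep) + 1L]] <- sort(p$gene_a[idx])
      }
    }
    return(keep)
  }
  list()
}

## random synteny instance on <= 20 genes: arbitrary B permutation and
## spacings, so chains break on gaps, intervening genes and direction flips
rand_synteny_instance <- function(n = 12) {
  mk <- function(ids, seqid, starts) {
    annotation(
      data.frame(gene_id = ids, seqid = seqid, start = starts,
                 end = starts + 500, strand = "+", stringsAsFactors = FALSE),
      data.frame(tx_id = paste0(ids, ".t"), gene_id = ids, seqid = seqid,
                 start = starts, end = starts + 500, strand = "+",
                 stringsAsFactors = FALSE),
      data.frame(tx_id = paste0(ids, ".t"), seqid = seqid, start = starts,
                 end = starts + 500, strand = "+", stringsAsFactors = FALSE),
      seqlens = setNames(max(starts) + 10000, seqid[1L]))
  }
  a_ids <- sprintf("a%02d", seq_len(n))
  b_ids <- sprintf("b%02d", seq_len(n))
  a_gaps <- sample(c(2000, 8000, 40000), n, TRUE, prob = c(0.5, 0.35, 0.15))
  b_gaps <- sample(c(2000, 8000, 40000), n, TRUE, prob = c(0.5, 0.35, 0.15))
  ann_a <- mk(a_ids, "cA", cumsum(a_gaps))
  perm <- sample(n)
  ann_b <- mk(b_ids, "cB", cumsum(b_gaps))
  # ortholog pairs: a_i <-> b at permuted position; subset of genes matched
  matched <- sort(sample(n, max(4L, rbinom(1L, n, 0.8))))
  pairs <- data.frame(gene_a = a_ids[matched],
                      gene_b = b_ids[perm[matched]],
                      bitscore = 500, stringsAsFactors = FALSE)
  list(pairs = pairs, ann_a = ann_a, ann_b = ann_b)
}
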