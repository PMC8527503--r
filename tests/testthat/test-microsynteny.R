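# Reciprocal best hits and collinear block chaining.

mk_hit <- function(q, s, bitscore = 500, evalue = 1e-100) {
  data.frame(qseqid = q, sseqid = s, pident = 90, length = 100, mismatch = 5,
             gapopen = 0, qstart = 1, qend = 100, sstart = 1, send = 100,
             evalue = evalue, bitscore = bitscore, stringsAsFactors = FALSE)
}

test_that("reciprocal best hits require mutual best matches", {
  ab <- mk_hit("a1", "b1")
  ba <- mk_hit("b1", "a1")
  expect_equal(nrow(reciprocal_best_hits(ab, ba)), 1L)
  # a1 -> b1 best, but b1 -> a2 best: no pair
  ab2 <- mk_hit("a1", "b1", 500)
  ba2 <- rbind(mk_hit("b1", "a2", 600), mk_hit("b1", "a1", 500))
  expect_equal(nrow(reciprocal_best_hits(ab2, ba2)), 0L)
})

test_that("best-hit tie-breaks use e-value then subject id", {
  ab <- rbind(mk_hit("a1", "b2", 500, evalue = 1e-50),
              mk_hit("a1", "b1", 500, evalue = 1e-80))
  ba <- rbind(mk_hit("b1", "a1"), mk_hit("b2", "a1"))
  rbh <- reciprocal_best_hits(ab, ba)
  expect_equal(rbh$gene_b, "b1")     # lower e-value wins the tie
  ab2 <- rbind(mk_hit("a1", "b2", 500), mk_hit("a1", "b1", 500))
  rbh2 <- reciprocal_best_hits(ab2, ba)
  expect_equal(rbh2$gene_b, "b1")    # then lexicographic subject
})

test_that("duplicate hit rows are collapsed to the highest bitscore", {
  ab <- rbind(mk_hit("a1", "b1", 300), mk_hit("a1", "b1", 500),
              mk_hit("a1", "b2", 400))
  ba <- mk_hit("b1", "a1")
  rbh <- reciprocal_best_hits(ab, ba)
  expect_equal(rbh$gene_b, "b1")
  expect_equal(rbh$bitscore, 500)
  expect_equal(attr(rbh, "n_duplicates"), 1L)
})

test_that("identity order chains into a single forward block", {
  sim <- simulate_ortholog_tables(10, seed = 1)
  rbh <- reciprocal_best_hits(sim$hits_ab, sim$hits_ba)
  expect_equal(nrow(rbh), 10L)
  bl <- collinear_blocks(rbh, sim$ann_a, sim$ann_b)
  expect_equal(nrow(bl$blocks), 1L)
  expect_equal(bl$blocks$n_genes, 10L)
  expect_equal(bl$blocks$orientation, "forward")
})

test_that("relocations split chains and inversions reverse them", {
  rel <- simulate_ortholog_tables(10, list(list(type = "relocation",
                                                span = c(4, 6))), seed = 2)
  bl <- collinear_blocks(reciprocal_best_hits(rel$hits_ab, rel$hits_ba),
                         rel$ann_a, rel$ann_b)
  expect_equal(nrow(bl$blocks), 3L)
  expect_equal(sort(bl$blocks$n_genes), c(3L, 3L, 4L))
  expect_equal(bl$blocks$b_seqid[2L], "chrB2")

  inv <- simulate_ortholog_tables(10, list(list(type = "inversion",
                                                span = c(3, 7))), seed = 2)
  bl2 <- collinear_blocks(reciprocal_best_hits(inv$hits_ab, inv$hits_ba),
                          inv$ann_a, inv$ann_b)
  rb <- bl2$blocks[bl2$blocks$orientation == "reverse", ]
  expect_equal(rb$n_genes, 5L)
})

test_that("runs below the minimum block size yield no block", {
  sim <- simulate_ortholog_tables(2, seed = 3)
  bl <- collinear_blocks(reciprocal_best_hits(sim$hits_ab, sim$hits_ba),
                         sim$ann_a, sim$ann_b, min_block = 3)
  expect_equal(nrow(bl$blocks), 0L)
  expect_true(all(is.na(bl$pairs$block_id)))
})

test_that("chaining matches exhaustive enumeration on random instances", {
  withr::with_seed(23, {
    for (rep in 1:40) {
      inst <- rand_synteny_instance(n = sample(8:20, 1L))
      got <- collinear_blocks(inst$pairs, inst$ann_a, inst$ann_b)
      got_sets <- lapply(split(got$pairs$gene_a[!is.na(got$pairs$block_id)],
                               got$pairs$block_id[!is.na(got$pairs$block_id)]),
                         sort)
      names(got_sets) <- NULL
      want_sets <- oracle_blocks(inst$pairs, inst$ann_a, inst$ann_b)
      key <- function(sets) unname(sort(vapply(sets, paste, character(1),
                                               collapse = ",")))
      expect_equal(key(got_sets), key(want_sets))
    }
  })
})

test_that("swapping the genomes preserves block pair sets", {
  # symmetry holds for segment-structured rearrangements (the chaining
  # scans genome A in order, so adversarially interleaved pair lists can
  # differ between directions; planted inversions/relocations cannot)
  withr::with_seed(29, {
    for (rep in 1:10) {
      ops <- list(list(type = "inversion", span = c(3, 7)),
                  list(type = "relocation", span = c(10, 12)))
      inst <- simulate_ortholog_tables(15, ops[sample(1:2,
                                                      sample(1:2, 1L))],
                                       seed = rep)
      inst$pairs <- reciprocal_best_hits(inst$hits_ab, inst$hits_ba)
      fwd <- collinear_blocks(inst$pairs, inst$ann_a, inst$ann_b)
      swapped <- data.frame(gene_a = inst$pairs$gene_b,
                            gene_b = inst$pairs$gene_a,
                            stringsAsFactors = FALSE)
      rev <- collinear_blocks(swapped, inst$ann_b, inst$ann_a)
      setf <- lapply(split(fwd$pairs$gene_a[!is.na(fwd$pairs$block_id)],
                           fwd$pairs$block_id[!is.na(fwd$pairs$block_id)]),
                     sort)
      setr <- lapply(split(rev$pairs$gene_b[!is.na(rev$pairs$block_id)],
                           rev$pairs$block_id[!is.na(rev$pairs$block_id)]),
                     sort)
      key <- function(sets) unname(sort(vapply(sets, paste, character(1),
                                               collapse = ",")))
      expect_equal(key(setf), key(setr))
    }
  })
})

test_that("relaxing gap or intervening limits never drops chained genes", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      inst <- rand_synteny_instance(n = 16)
      n_in <- function(max_int, max_gap) {
        bl <- collinear_blocks(inst$pairs, inst$ann_a, inst$ann_b,
                               max_intervening = max_int, max_gap = max_gap)
        sum(bl$blocks$n_genes)
      }
      expect_lte(n_in(2, 10000), n_in(5, 10000))
      expect_lte(n_in(5, 10000), n_in(5, 30000))
      expect_lte(n_in(5, 30000), n_in(8, 60000))
    }
  })
})

test_that("macrosynteny partners reproduce a 13-chromosome one-to-one map", {
  withr::with_seed(37, {
    # 13 chromosome pairs, 30 genes each, 95% of pairs intra-partner
    n_chr <- 13L; per <- 30L
    a_seq <- rep(sprintf("cA%02d", 1:n_chr), each = per)
    b_seq <- rep(sprintf("cB%02d", 1:n_chr), each = per)
    n <- n_chr * per
    swap <- runif(n) < 0.05
    b_seq[swap] <- sample(sprintf("cB%02d", 1:n_chr), sum(swap), TRUE)
    mk <- function(ids, seqid) {
      st <- ave(seq_along(ids), seqid, FUN = seq_along) * 10000
      annotation(
        data.frame(gene_id = ids, seqid = seqid, start = st, end = st + 500,
                   strand = "+", stringsAsFactors = FALSE),
        data.frame(tx_id = paste0(ids, ".t"), gene_id = ids, seqid = seqid,
                   start = st, end = st + 500, strand = "+",
                   stringsAsFactors = FALSE),
        data.frame(tx_id = paste0(ids, ".t"), seqid = seqid, start = st,
                   end = st + 500, strand = "+", stringsAsFactors = FALSE),
        seqlens = tapply(st + 20000, seqid, max))
    }
    a_ids <- sprintf("a%03d", 1:n); b_ids <- sprintf("b%03d", 1:n)
    ann_a <- mk(a_ids, a_seq); ann_b <- mk(b_ids, b_seq)
    pairs <- data.frame(gene_a = a_ids, gene_b = b_ids,
                        stringsAsFactors = FALSE)
    mac <- macrosynteny_summary(pairs, ann_a, ann_b)
    expect_equal(nrow(mac$partners), n_chr)
    expect_equal(mac$partners$b_seqid,
                 sub("cA", "cB", mac$partners$a_seqid))
    expect_true(all(mac$partners$fraction > 0.7))
    expect_false(any(mac$partners$ambiguous))
    expect_equal(nrow(mac$dots), n)
  })
})

test_that("plurality ties pick the smallest B sequence and are flagged", {
  sim <- simulate_ortholog_tables(4, seed = 5)
  ann_b <- sim$ann_b
  ann_b$genes$seqid <- c("cB1", "cB1", "cB2", "cB2")
  ann_b$transcripts$seqid <- ann_b$genes$seqid
  ann_b$exons$seqid <- ann_b$genes$seqid
  ann_b$seqlens <- c(cB1 = 1e6, cB2 = 1e6)
  ann_b <- annotation(ann_b$genes, ann_b$transcripts, ann_b$exons,
                      ann_b$seqlens)
  pairs <- data.frame(gene_a = sprintf("a%d", 1:4),
                      gene_b = sprintf("b%d", 1:4))
  mac <- macrosynteny_summary(pairs, sim$ann_a, ann_b)
  expect_equal(mac$partners$b_seqid, "cB1")
  expect_true(mac$partners$ambiguous)
})
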