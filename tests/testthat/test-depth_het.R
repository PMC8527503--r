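# Depth-conditioned heterozygosity estimator.

mk_sites <- function(depth, ref, snp = 0L, indel = 0L, seqid = "c1") {
  n <- max(length(depth), length(ref), length(snp), length(indel))
  validate_pileup(data.frame(
    seqid = rep_len(seqid, n), pos = seq_len(n) - 1L,
    depth = rep_len(depth, n), ref_count = rep_len(ref, n),
    snp_alt = rep_len(snp, n), indel_alt = rep_len(indel, n),
    stringsAsFactors = FALSE))
}

test_that("depth histogram tallies exactly and breaks mode ties low", {
  h <- depth_histogram(mk_sites(c(5L, 5L, 7L), 1L))
  expect_equal(h$counts$depth, c(5L, 7L))
  expect_equal(h$counts$n, c(2L, 1L))
  expect_equal(h$modal_depth, 5L)
  expect_equal(depth_histogram(mk_sites(c(4L, 4L, 6L, 6L), 1L))$modal_depth,
               4L)
  expect_error(depth_histogram(mk_sites(integer(0), integer(0))),
               "empty|no sites")
})

test_that("allele-balance classification follows the band rules", {
  s <- mk_sites(depth = c(178L, 178L, 178L, 178L, 178L),
                ref   = c(178L,  89L,  90L,   0L, 140L),
                snp   = c(  0L,  89L,   3L, 178L,  30L),
                indel = c(  0L,   0L,  85L,   0L,   0L))
  cls <- classify_sites(s)
  expect_equal(as.character(cls),
               c("hom_ref",   # pure reference
                 "het_snp",   # half the reads match the reference
                 "het_indel", # f = 0.506 in band, indel majority
                 "hom_alt",
                 "hom_ref"))  # f = 0.787 >= upper
  # with an asymmetric band, fractions between 1 - upper and lower are
  # neither het nor homozygous
  oth <- mk_sites(100L, 32L, snp = 60L)
  expect_equal(as.character(classify_sites(oth, lower = 0.35)), "other")
  # tie between snp and indel support goes to SNP
  tie <- mk_sites(100L, 50L, snp = 25L, indel = 25L)
  expect_equal(as.character(classify_sites(tie)), "het_snp")
  expect_error(classify_sites(s, lower = 0.6, upper = 0.7), "band")
})

test_that("heterozygosity is counted over all sites at the modal depth", {
  # 10 sites at D* = 50: 2 balanced SNP sites, 1 balanced indel site
  s <- mk_sites(depth = rep(50L, 10L),
                ref = c(25L, 25L, 24L, rep(50L, 7L)),
                snp = c(25L, 25L, 0L, rep(0L, 7L)),
                indel = c(0L, 0L, 26L, rep(0L, 7L)))
  est <- estimate_het(s, 50L)
  cmb <- est[est$variant_class == "combined", ]
  expect_equal(cmb$sites_total, 10L)
  expect_equal(cmb$sites_het, 3L)
  expect_equal(cmb$heterozygosity, 0.3)
  expect_equal(est$sites_het[est$variant_class == "snp"], 2L)
  expect_equal(est$sites_het[est$variant_class == "indel"], 1L)
  # all-homozygous pileup -> 0
  hom <- estimate_het(mk_sites(rep(50L, 5L), 50L), 50L)
  expect_true(all(hom$heterozygosity == 0))
  expect_error(estimate_het(s, 99L), "99")
})

test_that("widening the band never decreases the het count", {
  sim <- simulate_diploid_pileup(20000, 60, 0.03, 0.01, 0.005, seed = 8)
  dh <- depth_histogram(sim$sites)
  bands <- list(c(0.45, 0.55), c(0.40, 0.60), c(0.30, 0.70), c(0.20, 0.80))
  hets <- vapply(bands, function(b)
    estimate_het(sim$sites, dh$modal_depth, "combined",
                 lower = b[1L], upper = b[2L])$sites_het, numeric(1))
  expect_true(all(diff(hets) >= 0))
})

test_that("estimator recovers planted heterozygosity across rates and seeds", {
  for (h in c(0.005, 0.02, 0.032)) {
    ests <- numeric(0); ses <- numeric(0)
    for (s in 1:20) {
      sim <- simulate_diploid_pileup(200000, 60, snp_rate = h * 0.625,
                                     indel_rate = h * 0.375,
                                     error_rate = 0.002, seed = 100 + s)
      dh <- depth_histogram(sim$sites)
      est <- estimate_het(sim$sites, dh$modal_depth, "combined")
      ests <- c(ests, est$heterozygosity)
      ses <- c(ses, sqrt(h * (1 - h) / est$sites_total))
    }
    expect_lt(abs(mean(ests) - h), 3 * mean(ses) / sqrt(20))
  }
})

test_that("heterozygosity at half the modal depth collapses", {
  # sites near D*/2 carry reads from a single haplotype and look homozygous
  sim <- simulate_diploid_pileup(200000, 178, 0.02, 0.012, seed = 12)
  half <- sim$sites
  one_hap <- half$snp_alt > 0 | half$indel_alt > 0
  # emulate single-haplotype mapping: reads from one haplotype only
  half$depth <- ceiling(half$depth / 2)
  half$ref_count <- pmin(half$ref_count, half$depth)
  half$snp_alt <- half$depth - half$ref_count
  half$indel_alt <- 0L
  half$snp_alt[one_hap] <- 0L
  half$ref_count[one_hap] <- half$depth[one_hap]
  dh <- depth_histogram(sim$sites)
  at_mode <- estimate_het(sim$sites, dh$modal_depth,
                          "combined")$heterozygosity
  at_half <- estimate_het(half, ceiling(dh$modal_depth / 2),
                          "combined")$heterozygosity
  expect_lt(at_half, at_mode / 5)
})

test_that("region stratification follows exonic > intronic > intergenic", {
  # gene A exon covers [0,100); gene B spans [50,200) with intron [60,190)
  g <- data.frame(gene_id = c("A", "B"), seqid = "c1",
                  start = c(0L, 50L), end = c(100L, 200L), strand = "+")
  t <- data.frame(tx_id = c("tA", "tB"), gene_id = c("A", "B"), seqid = "c1",
                  start = c(0L, 50L), end = c(100L, 200L), strand = "+")
  e <- data.frame(tx_id = c("tA", "tB", "tB"), seqid = "c1",
                  start = c(0L, 50L, 190L), end = c(100L, 60L, 200L),
                  strand = "+")
  ann <- annotation(g, t, e, c(c1 = 300))
  s <- mk_sites(rep(10L, 3L), c(5L, 5L, 5L), snp = 5L)
  s$pos <- c(70L, 150L, 250L)  # in A-exon & B-intron; B-intron; intergenic
  reg <- ctenotools:::.region_of_sites(s, ann)
  expect_equal(reg, c("exonic", "intronic", "intergenic"))
  st <- stratified_het(s, ann, 10L)
  expect_setequal(unique(st$region), c("exonic", "intronic", "intergenic"))
  expect_true(all(st$sites_total == 1L))
  # single-exon genes covering everything leave no intronic/intergenic strata
  g2 <- data.frame(gene_id = "A", seqid = "c1", start = 0L, end = 300L,
                   strand = "+")
  t2 <- data.frame(tx_id = "tA", gene_id = "A", seqid = "c1", start = 0L,
                   end = 300L, strand = "+")
  e2 <- data.frame(tx_id = "tA", seqid = "c1", start = 0L, end = 300L,
                   strand = "+")
  st2 <- stratified_het(s, annotation(g2, t2, e2, c(c1 = 300)), 10L)
  expect_equal(unique(st2$region), "exonic")
  expect_error(stratified_het(mk_sites(10L, 5L, seqid = "missing"), ann,
                              10L), "absent")
})

test_that("stratified estimates preserve the planted indel excess direction", {
  # higher indel rate planted outside exons than inside
  withr::with_seed(21, {
    L <- 60000L
    g <- data.frame(gene_id = "A", seqid = "s", start = 0L, end = 30000L,
                    strand = "+")
    t <- data.frame(tx_id = "tA", gene_id = "A", seqid = "s", start = 0L,
                    end = 30000L, strand = "+")
    e <- data.frame(tx_id = "tA", seqid = "s", start = 0L, end = 30000L,
                    strand = "+")
    ann <- annotation(g, t, e, c(s = L))
    exonic <- simulate_diploid_pileup(30000, 60, snp_rate = 0.02,
                                      indel_rate = 0.004, seqid = "s",
                                      seed = 31)$sites
    inter <- simulate_diploid_pileup(30000, 60, snp_rate = 0.01,
                                     indel_rate = 0.02, seqid = "s",
                                     seed = 32)$sites
    inter$pos <- inter$pos + 30000L
    sites <- validate_pileup(rbind(exonic, inter))
    dh <- depth_histogram(sites)
    st <- stratified_het(sites, ann, dh$modal_depth, depth_window = 2)
    iex <- st$heterozygosity[st$region == "exonic" &
                               st$variant_class == "indel"]
    iig <- st$heterozygosity[st$region == "intergenic" &
                               st$variant_class == "indel"]
    expect_gt(iig, iex)
  })
})

test_that("2D allele-balance histogram conserves the depth marginal", {
  sim <- simulate_diploid_pileup(20000, 40, 0.02, 0.01, seed = 13)
  h2 <- allele_balance_2d(sim$sites)
  expect_equal(sum(h2$n), nrow(sim$sites))
  marg <- tapply(h2$n, h2$depth, sum)
  dh <- depth_histogram(sim$sites)
  expect_equal(as.integer(marg[as.character(dh$counts$depth)]),
               dh$counts$n)
  one <- allele_balance_2d(mk_sites(10L, 5L))
  expect_equal(one, data.frame(depth = 10L, ref_count = 5L, n = 1L))
  # het sites concentrate near half the modal depth
  sim2 <- simulate_diploid_pileup(50000, 178, 0.05, 0, seed = 14)
  h22 <- allele_balance_2d(sim2$sites)
  at_mode <- h22[h22$depth == 178L & h22$ref_count < 120L &
                   h22$ref_count > 60L, ]
  expect_gt(sum(at_mode$n), 0)
  peak <- at_mode$ref_count[which.max(at_mode$n)]
  expect_lt(abs(peak - 89L), 8L)
})

test_that("region counts at the modal depth partition the depth histogram", {
  sim <- simulate_diploid_pileup(30000, 50, 0.02, 0.01, seed = 15)
  ann <- simulate_nested_annotation(n_hosts = 2, n_nested = 2, seed = 15)
  a <- ann$annotation
  a$genes$seqid <- "sim1"; a$transcripts$seqid <- "sim1"
  a$exons$seqid <- "sim1"
  names(a$seqlens) <- "sim1"
  a$seqlens[] <- 1e6
  dh <- depth_histogram(sim$sites)
  st <- stratified_het(sim$sites, a, dh$modal_depth)
  by_region <- st[st$variant_class == "combined", ]
  expect_equal(sum(by_region$sites_total),
               dh$counts$n[dh$counts$depth == dh$modal_depth])
})
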