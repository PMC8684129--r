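test_that("group_log2fc matches hand arithmetic with pseudo-count 1", {
  m <- rbind(r1 = c(9, 9, 4, 4, 4), r2 = c(3, 3, 3, 3, 3),
             r3 = c(0, 0, 0, 0, 0))
  colnames(m) <- paste0("s", 1:5)
  g <- setNames(c(1, 1, 2, 2, 2), colnames(m))
  lfc <- group_log2fc(m, g, 1)
  expect_equal(unname(lfc["r1"]), log2(10 / 5), tolerance = 1e-12)  # = 1
  expect_equal(unname(lfc["r2"]), 0)
  expect_equal(unname(lfc["r3"]), 0)  # pseudo-count guards zeros
  # configurable pseudo-count
  expect_equal(unname(group_log2fc(m, g, 1, pseudo_count = 2)["r1"]),
               log2(11 / 6), tolerance = 1e-12)
  expect_error(group_log2fc(m, g, 3), "no members")
  expect_error(group_log2fc(m, setNames(rep(1, 5), colnames(m)), 1),
               "every sample")
})

test_that("log2fc is invariant to column permutation and antisymmetric under complement", {
  co <- small_cohort()
  m <- co$accessibility
  g <- truth_groups(co)
  lfc <- group_log2fc(m, g, 2)
  set.seed(8)
  perm <- sample(ncol(m))
  expect_equal(group_log2fc(m[, perm], g[perm], 2), lfc)
  # complementing membership on a two-group split flips the sign
  g2 <- ifelse(g == 2, 1L, 2L)
  names(g2) <- names(g)
  expect_equal(group_log2fc(m, g2, 1), lfc, tolerance = 1e-12)
  expect_equal(group_log2fc(m, g2, 2), -lfc, tolerance = 1e-12)
})

test_that("define_signature applies a strict threshold", {
  # craft a region sitting exactly at log2FC = 2.5: mean_in+1 = 2^2.5*(mean_out+1)
  mo <- 1
  mi <- 2^2.5 * (mo + 1) - 1
  m <- rbind(exact = c(mi, mi, mo, mo), above = c(60, 60, 1, 1))
  colnames(m) <- paste0("s", 1:4)
  g <- setNames(c(1, 1, 2, 2), colnames(m))
  sig <- define_signature(m, g, 1, lfc_threshold = 2.5)
  expect_identical(sig$region_id, "above")
  # all-equal matrix yields an empty signature
  m0 <- matrix(5, 3, 4, dimnames = list(paste0("r", 1:3), paste0("s", 1:4)))
  expect_equal(nrow(define_signature(m0, g, 1)), 0L)
})

test_that("noise-free signatures recover the planted sets exactly", {
  co <- noisefree_cohort()
  g <- truth_groups(co)
  for (grp in 1:3) {
    sig <- define_signature(co$accessibility, g, grp)
    expect_setequal(sig$region_id,
                    co$truth$signature_regions[[as.character(grp)]])
  }
})

test_that("distance_to_tss measures midpoint-to-nearest-TSS and flags empty chromosomes", {
  r <- region_set(c("chr1", "chr1", "chr2"), c(400, 300, 0), c(600, 500, 100))
  tss <- data.frame(chrom = "chr1", position = c(100, 500, 900))
  expect_warning(d <- distance_to_tss(r, tss), "without a TSS")
  df <- region_df(r)
  expect_equal(unname(d[df$region_id[df$start == 400]]), 0)   # midpoint 500
  expect_equal(unname(d[df$region_id[df$start == 300]]), 100) # midpoint 400 -> 500
  expect_true(is.na(d[df$region_id[df$chrom == "chr2"]]))
  # min over TSS oracle
  expect_equal(unname(distance_to_tss(region_set("chr1", 300, 500),
                                      data.frame(chrom = "chr1", position = c(100, 900)))),
               300)
})

test_that("cpg_density counts CG dinucleotides per base pair", {
  genome <- c(chr1 = "CGCGCGAAAAAAACGNCG")
  r <- region_set(rep("chr1", 3), c(0, 6, 12), c(6, 12, 18),
                  name = c("a", "b", "c"))
  d <- cpg_density(r, genome)
  expect_equal(unname(d["a"]), 0.5)   # CGCGCG
  expect_equal(unname(d["b"]), 0)     # AAAAAA
  expect_equal(unname(d["c"]), 2 / 6) # ACGNCG: N never matches
  expect_error(cpg_density(region_set("chr1", 10, 30), genome), "exceeds")
  # substring-count oracle on random sequence
  set.seed(19)
  s <- random_dna(500)
  want <- length(gregexpr("(?=CG)", s, perl = TRUE)[[1]])
  if (gregexpr("(?=CG)", s, perl = TRUE)[[1]][1] == -1) want <- 0
  got <- cpg_density(region_set("chrX", 0, 500), setNames(s, "chrX"))
  expect_equal(unname(got) * 500, want)
})

test_that("nearby_genes applies the 1 Mb midpoint window inclusively", {
  r <- region_set("chr1", 1999000, 2001000)  # midpoint 2,000,000
  genes <- data.frame(
    gene_id = c("in_edge", "out_edge", "near", "mid", "other_chrom"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    position = c(2e6 - 999999, 2e6 + 1000001, 2e6 + 10000, 2e6 + 500000, 2e6))
  hit <- nearby_genes(r, genes, window = 1e6)[[1]]
  expect_setequal(hit, c("in_edge", "near", "mid"))
  # exact boundary is included
  genes2 <- data.frame(gene_id = "at_bound", chrom = "chr1", position = 2e6 + 1e6)
  expect_equal(nearby_genes(r, genes2)[[1]], "at_bound")
  genes3 <- data.frame(gene_id = "g", chrom = "chr9", position = 5)
  expect_equal(length(nearby_genes(r, genes3)[[1]]), 0L)
})

test_that("sample_background is size-matched, deterministic and bounded", {
  co <- small_cohort()
  peaks <- co$regions
  targets <- peaks[sample(length(peaks), 60)]
  bg1 <- sample_background(peaks, targets, n = 100, seed = 3)
  bg2 <- sample_background(peaks, targets, n = 100, seed = 3)
  expect_identical(region_df(bg1), region_df(bg2))
  expect_equal(length(bg1), 100)
  expect_error(sample_background(peaks, targets, n = length(peaks) + 1),
               "background regions")
  # n equal to the peak count returns every peak
  expect_equal(length(sample_background(peaks, targets, n = length(peaks))),
               length(peaks))
  # constant-length targets restrict draws to the peak length-decile
  # stratum containing that length
  starts <- seq(0, 29000, 1000)
  tl <- region_set(rep("chr1", 30), starts, starts + 200)
  bg <- sample_background(peaks, tl, n = 20, seed = 9)
  pq <- unique(quantile(GenomicRanges::width(peaks), seq(0, 1, 0.1), type = 7))
  cuts <- c(-Inf, pq[-c(1, length(pq))], Inf)
  stratum_of <- function(w) findInterval(w, cuts, left.open = TRUE)
  expect_true(all(stratum_of(GenomicRanges::width(bg)) == stratum_of(200)))
})
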