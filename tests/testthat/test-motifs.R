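# brute-force oracle: score every window explicitly, on the forward sequence
# and on the reverse complement of each window
oracle_scan <- function(model, seq_, background = rep(0.25, 4)) {
  lo <- log2(model$prob / background)
  L <- ncol(lo)
  bases <- c("A", "C", "G", "T")
  score1 <- function(w) {
    ch <- strsplit(w, "")[[1]]
    if (any(!ch %in% bases)) return(NA_real_)
    sum(vapply(seq_len(L), function(j) lo[match(ch[j], bases), j], 0))
  }
  n <- nchar(seq_) - L + 1
  if (n < 1) return(data.frame(start = integer(), strand = character(),
                               score = numeric()))
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    w <- substr(seq_, i, i + L - 1)
    data.frame(start = i - 1L, strand = c("+", "-"),
               score = c(score1(w), score1(revcomp(w))))
  }))
  thr <- model$score_fraction * sum(apply(lo, 2, max))
  out[!is.na(out$score) & out$score >= thr - 1e-9, , drop = FALSE]
}

test_that("a planted consensus yields exactly one forward hit at fraction 1.0", {
  genome <- c(chr1 = paste0("TTTTT", "ACCT", paste(rep("T", 20), collapse = "")))
  model <- motif_model("m", consensus = "ACCT", score_fraction = 1.0)
  occ <- scan_motif(model, region_set("chr1", 0, nchar(genome), name = "r1"),
                    genome)
  expect_equal(nrow(occ), 1L)
  expect_equal(occ$start, 5L)
  expect_equal(occ$strand, "+")
})

test_that("reverse-complement sites are reported on the minus strand at the same interval", {
  site <- "AACCGGTA"
  genome <- c(chr1 = paste0("TTTTTTTTTT", revcomp(site), "TTTTTTTTTT"))
  model <- motif_model("m", consensus = site, score_fraction = 1.0)
  occ <- scan_motif(model, region_set("chr1", 0, nchar(genome)), genome)
  expect_equal(nrow(occ), 1L)
  expect_equal(occ$strand, "-")
  expect_equal(occ$start, 10L)
  expect_equal(occ$end, 18L)
})

test_that("a palindromic consensus hits both strands over the same interval", {
  site <- "AACCGGTT"  # its own reverse complement
  genome <- c(chr1 = paste0("TTTTTTTTTT", site, "TTTTTTTTTT"))
  model <- motif_model("m", consensus = site, score_fraction = 1.0)
  occ <- scan_motif(model, region_set("chr1", 0, nchar(genome)), genome)
  expect_equal(nrow(occ), 2L)
  expect_setequal(occ$strand, c("+", "-"))
  expect_equal(unique(occ$start), 10L)
})

test_that("a motif never hits in an incompatible or N-containing sequence", {
  model <- motif_model("m", consensus = "ACGT", score_fraction = 1.0)
  genome <- c(chr1 = strrep("T", 50))
  expect_equal(nrow(scan_motif(model, region_set("chr1", 0, 50), genome)), 0L)
  genomeN <- c(chr1 = paste0("TTTTT", "ACNT", "TTTTT"))
  expect_equal(nrow(scan_motif(motif_model("m", consensus = "ACGT",
                                           score_fraction = 0.5),
                               region_set("chr1", 0, 14), genomeN)), 0L)
  # regions shorter than the motif yield no hits and no error
  expect_equal(nrow(scan_motif(model, region_set("chr1", 0, 3),
                               c(chr1 = "ACG"))), 0L)
})

test_that("scan_motif agrees with the brute-force all-window scorer on random sequences", {
  set.seed(701)
  model_pwm <- motif_model("pwm", matrix = {
    m <- matrix(runif(4 * 6), 4)
    sweep(m, 2, colSums(m), "/")
  }, score_fraction = 0.8)
  for (trial in 1:100) {
    len <- 2000
    s <- random_dna(len)
    # sprinkle some Ns
    if (trial %% 3 == 0) {
      at <- sample(len - 1, 5)
      for (a in at) substr(s, a, a) <- "N"
    }
    model <- if (trial %% 2) model_pwm else
      motif_model("c", consensus = "TGTTTACA", score_fraction = 0.9)
    occ <- scan_motif(model, region_set("chrZ", 0, len), c(chrZ = s))
    want <- oracle_scan(model, s)
    got_key <- paste(occ$start, occ$strand)
    want_key <- paste(want$start, want$strand)
    expect_setequal(got_key, want_key)
    if (nrow(occ)) {
      ord <- match(got_key, want_key)
      expect_equal(occ$score, want$score[ord], tolerance = 1e-9)
    }
  }
})

test_that("motif_enrichment computes the binomial tail against the background rate", {
  tg <- region_set("chr1", seq(0, 990, 10), seq(0, 990, 10) + 5,
                   name = sprintf("t%03d", 1:100))  # 100 regions
  bg <- region_set("chr2", seq(0, 990, 10), seq(0, 990, 10) + 5,
                   name = sprintf("b%03d", 1:100))
  occ <- data.frame(region_id = c(names(tg)[1:30], names(bg)[1:10]))
  e <- motif_enrichment(tg, bg, occ)
  expect_equal(e$fold, 3.0)
  # exact binomial summation oracle: P(X >= 30 | n = 100, p = 0.1)
  want_p <- sum(vapply(30:100, function(k) choose(100, k) * 0.1^k * 0.9^(100 - k), 0))
  expect_equal(e$p, want_p, tolerance = 1e-9)
  # identical rates: fold 1, p not small
  e0 <- motif_enrichment(tg, bg, data.frame(region_id = c(names(tg)[1:10], names(bg)[1:10])))
  expect_equal(e0$fold, 1.0)
  expect_gt(e0$p, 0.4)
  # zero background hits: rate floor 1 / (2 * n_background)
  ez <- motif_enrichment(tg, bg, data.frame(region_id = names(tg)[1:5]))
  expect_true(is.infinite(ez$fold))
  expect_equal(ez$p, pbinom(4, 100, 1 / 200, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(motif_enrichment(GenomicRanges::GRanges(), bg, occ), "empty target")
})

test_that("enrichment p-values are calibrated under label shuffling", {
  co <- small_cohort()
  occ <- scan_motif(co$motifs$FOX, co$regions, co$genome)
  set.seed(31)
  n <- length(co$regions)
  hits <- 0
  for (i in 1:200) {
    pick <- sample(n)
    tg <- co$regions[pick[1:60]]
    bg <- co$regions[pick[61:260]]
    e <- motif_enrichment(tg, bg, occ)
    if (e$p < 0.05) hits <- hits + 1
  }
  expect_lte(hits, 0.10 * 200)
})

test_that("motif_accessibility averages distinct motif-bearing regions per sample", {
  m <- rbind(r1 = c(s1 = 2, s2 = 10), r2 = c(4, 20), r3 = c(100, 100))
  colnames(m) <- c("s1", "s2")
  occ <- data.frame(region_id = c("r1", "r2", "r2"))  # duplicate counts once
  v <- motif_accessibility(m, occ)
  expect_equal(unname(v), c(3, 15))
  expect_equal(unname(motif_accessibility(m, data.frame(region_id = "r1"))),
               c(2, 10))
  expect_error(motif_accessibility(m, data.frame(region_id = character())),
               "no motif occurrences")
  expect_error(motif_accessibility(m, data.frame(region_id = "absent")),
               "no occurrence region")
})

test_that("profile_matrix bins signal around anchors and ignores no-signal anchors", {
  tr <- coverage_track("chr1", c(0, 100), c(100, 200), c(0, 3))
  anchors <- data.frame(chrom = "chr1", center = 100)
  pr <- profile_matrix(tr, anchors, half_window = 50, n_bins = 10)
  expect_equal(unname(pr$profile[1, ]), c(rep(0, 5), rep(3, 5)))
  # uniform signal fills all bins
  tru <- coverage_track("chr1", 0, 200, 2)
  pru <- profile_matrix(tru, anchors, half_window = 50, n_bins = 4)
  expect_equal(unname(pru$profile[1, ]), rep(2, 4))
  # all-zero anchor excluded from column means
  anchors2 <- data.frame(chrom = "chr1", center = c(100, 1000))
  pr2 <- suppressWarnings(profile_matrix(tr, anchors2, 50, 10))
  expect_equal(pr2$n_used, 1L)
  expect_equal(pr2$column_means, pr$profile[1, ])
  # minus-strand anchors are reversed to read 5' -> 3'
  anchors3 <- data.frame(chrom = "chr1", center = 100, strand = "-")
  pr3 <- profile_matrix(tr, anchors3, 50, 10)
  expect_equal(unname(pr3$profile[1, ]), c(rep(3, 5), rep(0, 5)))
  expect_error(profile_matrix(tr, anchors, 50, 7), "n_bins")
})

test_that("read_motifs parses name/consensus TSVs", {
  f <- withr::local_tempfile(lines = c("name\tconsensus", "FOX\tTGTTTACA",
                                       "SOX\tAACAATGG\t0.95"))
  ms <- read_motifs(f)
  expect_equal(names(ms), c("FOX", "SOX"))
  expect_equal(ms$SOX$score_fraction, 0.95)
  expect_equal(ms$FOX$consensus, "TGTTTACA")
  expect_equal(colSums(ms$FOX$prob), rep(1, 8), tolerance = 1e-9,
               ignore_attr = TRUE)
})
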