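test_that("one_tailed_t matches the Welch formula and its complementarity", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  # textbook Welch computation on these six numbers
  sx2 <- var(x) / 3; sy2 <- var(y) / 3
  t_stat <- (mean(x) - mean(y)) / sqrt(sx2 + sy2)
  df <- (sx2 + sy2)^2 / (sx2^2 / 2 + sy2^2 / 2)
  want <- pt(t_stat, df)  # P(T <= t): x less than y
  p_less <- one_tailed_t(x, y, "less")
  expect_equal(as.numeric(p_less), want, tolerance = 1e-9)
  expect_equal(as.numeric(one_tailed_t(x, y, "greater")), 1 - want,
               tolerance = 1e-9)
  # no effect: identical samples give p = 0.5 either way
  expect_equal(as.numeric(one_tailed_t(x, x, "greater")), 0.5)
  # degenerate zero-variance equal means
  expect_equal(as.numeric(one_tailed_t(c(2, 2), c(2, 2), "greater")), 0.5)
  expect_error(one_tailed_t(1, y), ">= 2 values")
})

test_that("pearson_cor matches the direct covariance formula to 1e-12", {
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  got <- pearson_cor(x, y)
  expect_equal(got$r, 0.8, tolerance = 1e-12)
  t_stat <- 0.8 * sqrt(2 / (1 - 0.8^2))
  expect_equal(got$p, 2 * pt(-abs(t_stat), df = 2), tolerance = 1e-12)
  expect_equal(pearson_cor(x, x)$r, 1)
  expect_equal(pearson_cor(x, -2 * x + 5)$r, -1)
  # high-precision direct computation on random vectors
  set.seed(61)
  for (i in 1:25) {
    a <- rnorm(50); b <- rnorm(50)
    direct <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(pearson_cor(a, b)$r, direct, tolerance = 1e-12)
  }
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_cor(1:2, 1:2), "n >= 3")
})

test_that("significance stars follow the 0.01 / 0.001 / 0.0001 bands", {
  expect_equal(p_stars(c(0.5, 0.009, 0.0009, 0.00009)),
               c("", "*", "**", "***"))
  expect_equal(p_stars(0.01), "")  # strict <
})

test_that("basal_filter removes bottom-quartile-of-both samples under the type-7 rule", {
  mk <- function(foxa1, gata3) {
    m <- rbind(FOXA1 = foxa1, GATA3 = gata3)
    colnames(m) <- sprintf("s%02d", seq_along(foxa1))
    m
  }
  # disjoint bottom quartiles: nothing removed
  f1 <- basal_filter(mk(1:8, 8:1))
  expect_equal(length(f1$removed), 0L)
  # identical ordering: type-7 quartile of 1..8 is 2.75, so samples 1 and 2 go
  f2 <- basal_filter(mk(1:8, 1:8))
  expect_equal(f2$removed, c("s01", "s02"))
  expect_equal(unname(f2$cuts), c(2.75, 2.75))
  # constant expression: cut equals the value, <= removes everyone, with a warning
  expect_warning(f3 <- basal_filter(mk(rep(4, 8), rep(4, 8))), "degenerate")
  expect_equal(length(f3$removed), 8L)
  # strict boundary rule keeps ties
  f4 <- basal_filter(mk(rep(4, 8), rep(4, 8)), boundary = "lt") |>
    suppressWarnings()
  expect_equal(length(f4$removed), 0L)
  expect_error(basal_filter(mk(1:8, 1:8)[1, , drop = FALSE]), "missing")
})

test_that("basal_filter is invariant to sample order and monotone marker transforms", {
  co <- small_cohort()
  expr <- co$expression
  base <- basal_filter(expr)
  set.seed(17)
  perm <- sample(ncol(expr))
  expect_setequal(basal_filter(expr[, perm])$removed, base$removed)
  tr <- expr
  tr["FOXA1", ] <- log1p(tr["FOXA1", ])
  tr["GATA3", ] <- tr["GATA3", ]^2
  expect_setequal(basal_filter(tr)$removed, base$removed)
})

test_that("divergent_genes classifies by log2FC with pseudo-count 1", {
  m <- rbind(up = c(15, 15, 3, 3), flat = c(5, 5, 5, 5), dn = c(3, 3, 15, 15))
  colnames(m) <- paste0("s", 1:4)
  dv <- divergent_genes(m, c("s1", "s2"), c("s3", "s4"), lfc_threshold = 1)
  expect_equal(dv$higher_in_a$gene_id, "up")
  expect_equal(dv$higher_in_a$log2fc, log2(16 / 4), tolerance = 1e-12)
  expect_equal(dv$lower_in_a$gene_id, "dn")
  # equal means appear in neither list even at threshold 0
  dv0 <- divergent_genes(m, c("s1", "s2"), c("s3", "s4"), lfc_threshold = 0)
  expect_false("flat" %in% c(dv0$higher_in_a$gene_id, dv0$lower_in_a$gene_id))
  expect_setequal(c(dv0$higher_in_a$gene_id, dv0$lower_in_a$gene_id),
                  c("up", "dn"))
  expect_error(divergent_genes(m, c("s1", "s2"), c("s2", "s3")), "overlap")
})

test_that("decile_tables selects floor(n*decile) samples deterministically", {
  set.seed(71)
  m <- matrix(rlnorm(3 * 20), nrow = 3,
              dimnames = list(c("ANP32E", "g1", "g2"), sprintf("s%02d", 1:20)))
  dt <- decile_tables(m, "ANP32E", decile = 0.1)
  expect_equal(dt$n_selected, 2L)
  expect_equal(length(dt$top$samples), 2L)
  ord <- order(m["ANP32E", ], colnames(m))
  expect_equal(dt$bottom$samples, colnames(m)[ord[1:2]])
  expect_equal(dt$top$means, rowMeans(m[, dt$top$samples]), tolerance = 1e-12)
  expect_equal(dt$bottom$means, rowMeans(m[, dt$bottom$samples]),
               tolerance = 1e-12)
  expect_error(decile_tables(m[, 1:5], "ANP32E", decile = 0.1), "decile < 1")
  expect_error(decile_tables(m, "nope"), "not in expression")
})

test_that("stage_trend tests adjacent and extreme stage pairs with stars", {
  set.seed(81)
  vals <- list(I = rnorm(10, 10), II = rnorm(10, 13), III = rnorm(10, 16),
               IV = rnorm(10, 19))
  st <- stage_trend(vals, direction = "increasing")
  expect_equal(st$stage_a, c("I", "II", "III", "I"))
  expect_equal(st$stage_b, c("II", "III", "IV", "IV"))
  expect_true(all(st$p < 0.01))
  expect_true(all(nchar(st$stars) >= 1))
  # the comparison agrees with a direct Welch computation
  expect_equal(st$p[1], as.numeric(one_tailed_t(vals$II, vals$I, "greater")),
               tolerance = 1e-12)
  expect_error(stage_trend(vals["I"]), "two stages")
  expect_error(stage_trend(list(I = 1, II = c(1, 2))), ">= 2 values")
})

test_that("shuffled stage labels rarely reach significance", {
  co <- small_cohort()
  v <- motif_accessibility(co$accessibility,
                           data.frame(region_id = co$truth$motif_carriers$FOX))
  md <- co$metadata
  set.seed(99)
  n_sig <- 0L; n_cmp <- 0L
  for (i in 1:100) {
    md$stage <- sample(md$stage)
    st <- stage_trend(split_by_stage(v, md), direction = "increasing")
    n_sig <- n_sig + sum(st$p < 0.01)
    n_cmp <- n_cmp + nrow(st)
  }
  expect_lte(n_sig / n_cmp, 0.10)
})
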