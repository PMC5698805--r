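make_vs <- function(gt, dp = NULL, gq = NULL, qual = 10, map35 = 1,
                    map20 = 1) {
  n <- nrow(gt)
  sites <- data.frame(chrom = "1", pos = seq_len(n) * 100L,
                      ref = "A", alt = "G", qual = qual,
                      stringsAsFactors = FALSE)
  vs <- variant_set(sites, gt, dp, gq)
  ann <- data.frame(chrom = "1", pos = sites$pos, ref = "A", alt = "G",
                    gene = "G1", consequence = "missense",
                    maf = 0.001, cadd = 20, dbsnp = NA_character_,
                    map35 = map35, map20 = map20, aa_change = "p.A1V",
                    stringsAsFactors = FALSE)
  ann$key <- paste(ann$chrom, ann$pos, ann$ref, ann$alt, sep = ":")
  class(ann) <- c("variant_annotations", "data.frame")
  list(vs = vs, ann = ann)
}

test_that("genotype filter masks low-depth/low-GQ calls at inclusive bounds", {
  gt <- matrix(c(1L, 1L, 1L, 1L), 1, 4,
               dimnames = list(NULL, paste0("s", 1:4)))
  dp <- matrix(c(4L, 5L, 50L, 50L), 1, 4, dimnames = dimnames(gt))
  gq <- matrix(c(99L, 20L, 19L, 99L), 1, 4, dimnames = dimnames(gt))
  vs <- make_vs(gt, dp, gq)$vs
  out <- filter_genotypes(vs)
  expect_equal(unname(out$gt[1, ]), c(NA, 1L, NA, 1L))
  expect_equal(attr(out, "n_masked"), 2L)
  # all passing -> unchanged
  ok <- make_vs(gt, dp + 10L, gq + 10L)$vs
  expect_equal(filter_genotypes(ok)$gt, ok$gt)
})

test_that("site filter applies mappability and strict VQSLOD rules", {
  gt <- matrix(1L, 3, 2, dimnames = list(NULL, c("s1", "s2")))
  x <- make_vs(gt, qual = c(5, 0, 5), map35 = c(1, 1, 0.5),
               map20 = c(0.5, 1, 1))
  out <- filter_sites(x$vs, x$ann)
  # site 1: map20 exactly 0.5 kept; site 2: vqslod 0 removed (strict >);
  # site 3: map35 != 1 removed
  expect_equal(out$sites$pos, 100L)
  expect_equal(attr(out, "n_removed"), 2L)
})

test_that("genotype and site filters commute", {
  set.seed(3)
  gt <- matrix(sample(c(0:2, NA), 40, TRUE), 10, 4,
               dimnames = list(NULL, paste0("s", 1:4)))
  dp <- matrix(sample(2:60, 40, TRUE), 10, 4, dimnames = dimnames(gt))
  gq <- matrix(sample(5:99, 40, TRUE), 10, 4, dimnames = dimnames(gt))
  x <- make_vs(gt, dp, gq, qual = runif(10, -1, 5),
               map35 = sample(c(1, 0.5), 10, TRUE),
               map20 = runif(10, 0.3, 1))
  a <- filter_sites(filter_genotypes(x$vs), x$ann)
  b <- filter_genotypes(filter_sites(x$vs, x$ann))
  expect_equal(a$gt, b$gt)
  expect_equal(a$sites, b$sites)
})

test_that("call rates use the non-missing fraction with >= comparisons", {
  gt <- matrix(1L, 50, 2, dimnames = list(NULL, c("s1", "s2")))
  gt[1, 1] <- NA
  vs <- make_vs(gt)$vs
  cr <- sample_call_rates(vs)
  expect_equal(unname(cr["s1"]), 0.98)
  expect_true(cr["s1"] >= qc_config()$sample_call_rate_min)
  expect_equal(unname(cr["s2"]), 1)
  gt2 <- matrix(c(rep(1L, 94), rep(NA, 6)), 1, 100,
                dimnames = list(NULL, paste0("s", 1:100)))
  vs2 <- make_vs(gt2)$vs
  expect_lt(snp_call_rate(vs2), qc_config()$snp_call_rate_min)
  empty <- make_vs(matrix(1L, 1, 1, dimnames = list(NULL, "s1")))$vs
  empty$gt <- empty$gt[0, , drop = FALSE]
  expect_error(sample_call_rates(empty), ">= 1 variant")
})

test_that("concordance counts identical unordered genotypes", {
  g1 <- matrix(c(0L, 1L, 2L, 1L, 0L, NA, 1L, 2L, 0L, 1L), 5, 2)
  expect_equal(concordance(g1, g1), 1)
  g2 <- g1
  g2[1, 1] <- 1L
  expect_equal(concordance(g1, g2), 1 - 1 / sum(!is.na(g1)))
  expect_error(concordance(matrix(NA_integer_, 2, 2),
                           matrix(NA_integer_, 2, 2)), "no overlapping")
  # simulated 1% error overlay
  set.seed(9)
  n <- 20000
  a <- matrix(sample(0:2, n, TRUE), 200, 100,
              dimnames = list(NULL, paste0("s", 1:100)))
  b <- a
  flip <- runif(n) < 0.01
  b[flip] <- (a[flip] + 1L) %% 3L
  expect_equal(concordance(a, b), 0.99,
               tolerance = 3 * sqrt(0.99 * 0.01 / n) / 0.99)
})

test_that("LD pruning removes correlated markers and keeps independent ones", {
  set.seed(21)
  base <- matrix(sample(0:2, 300, TRUE), 3, 100,
                 dimnames = list(NULL, paste0("s", 1:100)))
  dup <- rbind(base[1, , drop = FALSE], base)  # marker 1 == marker 2
  kept <- ld_prune(dup)
  expect_length(intersect(kept, 1:2), 1L)
  # mutually independent markers all kept
  indep <- matrix(rbinom(500, 2, 0.5), 5, 100,
                  dimnames = list(NULL, paste0("s", 1:100)))
  while (TRUE) {
    cc <- cor(t(indep))^2
    diag(cc) <- 0
    if (max(cc) <= 0.5) break
    indep <- matrix(rbinom(500, 2, 0.5), 5, 100)
  }
  expect_equal(ld_prune(indep), 1:5)
  # deterministic given input
  expect_equal(ld_prune(dup), kept)
})

test_that("pruned block panels satisfy the pairwise r2 bound within windows", {
  set.seed(33)
  n_samp <- 80
  blocks <- lapply(1:40, function(b) {
    anchor <- rbinom(n_samp, 2, runif(1, 0.2, 0.8))
    t(vapply(1:5, function(k) {
      noisy <- anchor
      sw <- runif(n_samp) < 0.1
      noisy[sw] <- sample(0:2, sum(sw), TRUE)
      noisy
    }, numeric(n_samp)))
  })
  panel <- do.call(rbind, blocks)
  colnames(panel) <- paste0("s", 1:n_samp)
  cfg <- qc_config()
  kept <- ld_prune(panel, cfg)
  expect_lt(length(kept), nrow(panel))
  starts <- seq(1L, nrow(panel) - 1L, by = cfg$ld_step)
  for (s in starts) {
    win <- intersect(s:(s + cfg$ld_window - 1L), kept)
    if (length(win) < 2L) next
    prs <- utils::combn(win, 2L)
    for (p in seq_len(ncol(prs))) {
      r <- cor(panel[prs[1, p], ], panel[prs[2, p], ])^2
      expect_lte(r, cfg$ld_r2_max + 1e-12)
    }
  }
})
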