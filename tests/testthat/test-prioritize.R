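test_that("segregation requires every non-missing sequenced affected to carry", {
  ped <- pedigree("f", id = c("a1", "a2", "a3", "u1"),
                  father = NA, mother = NA, sex = "unknown",
                  affection = c(rep("affected", 3), "unaffected"),
                  sequenced = TRUE)
  expect_true(is_segregating(c(a1 = 1, a2 = 1, a3 = 2, u1 = 0), ped))
  expect_false(is_segregating(c(a1 = 1, a2 = 0, a3 = 1, u1 = 0), ped))
  # missing calls drop out of the denominator
  expect_true(is_segregating(c(a1 = 1, a2 = 1, a3 = NA, u1 = 0), ped))
  expect_true(is.na(is_segregating(c(a1 = NA, a2 = NA, a3 = NA), ped)))
  solo <- pedigree("s", id = "a", father = NA, mother = NA,
                   affection = "affected")
  expect_true(is_segregating(c(a = 1), solo))
  none <- pedigree("n", id = "u", father = NA, mother = NA,
                   affection = "unaffected")
  expect_error(is_segregating(c(u = 1), none), "no sequenced affecteds")
})

test_that("known-gene tier reproduces the example tables and its boundaries", {
  ex <- example_study()
  t1 <- strategy_known_genes(ex$variants, ex$annotations, ex$gene_list,
                             ex$peds)
  expect_equal(nrow(t1), 15L)                      # one row per (variant, family)
  expect_equal(length(unique(t1$key)), 14L)
  expect_equal(length(unique(t1$gene)), 10L)
  expect_false(all(t1$segregating))                # segregation not required
  # MAF boundary: a 2.1% variant is excluded, the 1.808% one retained
  ann2 <- ex$annotations
  unc5c <- ann2$gene == "UNC5C" & ann2$maf == 0.01808
  expect_true(any(t1$maf == 0.01808))
  ann2$maf[unc5c] <- 0.021
  t1b <- strategy_known_genes(ex$variants, ann2, ex$gene_list, ex$peds)
  expect_false(any(t1b$maf == 0.021))
  # a variant absent from the population database passes rarity, flagged
  ann3 <- ex$annotations
  ann3$maf[ann3$gene == "CD33"] <- NA
  t1c <- strategy_known_genes(ex$variants, ann3, ex$gene_list, ex$peds)
  expect_equal(t1c$maf_flag[t1c$gene == "CD33"], "maf_missing")
  expect_true("CD33" %in% t1c$gene)
})

test_that("linkage tier keeps segregating rare variants inside family regions", {
  ex <- example_study()
  t2 <- strategy_linkage(ex$variants, ex$annotations, ex$regions, ex$peds)
  expect_equal(nrow(t2), 5L)
  expect_setequal(unique(t2$gene),
                  c("CD163L1", "CLECL1", "CTNNA1", "GALR3", "MIEF1"))
  expect_setequal(unique(t2$family), c("757", "911", "1201"))
  expect_true(all(t2$segregating))
  # CADD is a flag, not a filter: CLECL1 (0.03) stays with flag FALSE
  expect_false(t2$cadd_flag[t2$gene == "CLECL1"])
  expect_true(t2$cadd_flag[t2$gene == "MIEF1"])
  # a variant outside every region is dropped even if rare and segregating
  far <- ex$regions
  far$start <- far$start + 1e9
  far$end <- far$end + 1e9
  expect_equal(nrow(strategy_linkage(ex$variants, ex$annotations, far,
                                     ex$peds)), 0L)
})

test_that("cross-family tier clusters genes hit in two or more families", {
  ex <- example_study()
  t3 <- strategy_cross_family(ex$variants, ex$annotations, ex$peds,
                              exclude_genes = ex$gene_list)
  expect_equal(nrow(t3), 4L)
  expect_setequal(t3$gene, c("DAAM2", "MKL2", "PLEKHG5", "THBS2"))
  expect_equal(sum(t3$identical_variant_shared), 3L)
  expect_false(t3$identical_variant_shared[t3$gene == "DAAM2"])
  # without the known-gene exclusion the INPP5D pair also clusters
  t3all <- strategy_cross_family(ex$variants, ex$annotations, ex$peds)
  expect_true("INPP5D" %in% t3all$gene)
  expect_error(strategy_cross_family(ex$variants, ex$annotations,
                                     ex$peds[1]), ">= 2 families")
})

test_that("retained sets grow monotonically with the MAF ceiling", {
  ex <- example_study()
  k1 <- strategy_known_genes(ex$variants, ex$annotations, ex$gene_list,
                             ex$peds, maf_max = 0.005)$key
  k2 <- strategy_known_genes(ex$variants, ex$annotations, ex$gene_list,
                             ex$peds, maf_max = 0.02)$key
  expect_true(all(k1 %in% k2))
  l1 <- strategy_linkage(ex$variants, ex$annotations, ex$regions, ex$peds,
                         maf_max = 0.002)$key
  l2 <- strategy_linkage(ex$variants, ex$annotations, ex$regions, ex$peds,
                         maf_max = 0.01)$key
  expect_true(all(l1 %in% l2))
})

test_that("prioritized flags re-derive from the raw annotations", {
  ex <- example_study()
  t1 <- strategy_known_genes(ex$variants, ex$annotations, ex$gene_list,
                             ex$peds)
  a <- annotation_for(ex$annotations, t1$key)
  expect_equal(t1$cadd_flag, !is.na(a$cadd) & a$cadd >= 15)
  expect_equal(t1$maf, a$maf)
  expect_equal(t1$gene, a$gene)
})
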