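test_that("gene drop transmits unbroken founder haplotypes at theta 0", {
  set.seed(55)
  ped <- template_ped <- pedexome:::template_pedigree("t", 3L, 2L)
  labs <- gene_drop(ped, n_markers = 20L, theta = 0)
  founders <- ped$id[is_founder(ped)]
  founder_labels <- c(paste0(founders, ".1"), paste0(founders, ".2"))
  for (id in ped$id) {
    for (row in 1:2) {
      lab <- unique(labs[[id]][row, ])
      expect_length(lab, 1L)  # no switches at theta 0
      expect_true(lab %in% founder_labels)
    }
  }
})

test_that("child labels are always drawn from the parents' labels", {
  set.seed(56)
  ped <- pedexome:::template_pedigree("t", 2L, 2L)
  labs <- gene_drop(ped, n_markers = 15L, theta = 0.3)
  for (i in which(!is_founder(ped))) {
    id <- ped$id[i]
    expect_true(all(labs[[id]][1, ] %in% labs[[ped$father[i]]]))
    expect_true(all(labs[[id]][2, ] %in% labs[[ped$mother[i]]]))
  }
})

test_that("full penetrance makes carrier status and affection coincide", {
  set.seed(57)
  ped <- pedexome:::template_pedigree("t", 4L, 3L)
  labs <- gene_drop(ped, n_markers = 9L, theta = 0.05)
  planted <- plant_causal(ped, labs, marker = 5L,
                          penetrances = c(0, 1, 1))
  expect_equal(planted$ped$affection == "affected",
               unname(planted$dosage >= 1))
  # by construction the causal variant segregates in every such family
  geno <- stats::setNames(as.integer(planted$dosage), ped$id)
  planted$ped$sequenced <- TRUE
  expect_true(is_segregating(geno, planted$ped))
})

test_that("incomplete penetrance affects carriers at the configured rate", {
  set.seed(58)
  ped <- pedexome:::template_pedigree("t", 6L, 4L)
  labs <- gene_drop(ped, n_markers = 3L, theta = 0.5)
  n_aff <- 0L
  n_carrier <- 0L
  for (rep in 1:120) {
    pl <- plant_causal(ped, labs, marker = 2L, penetrances = c(0, 0.8, 0.8))
    carriers <- pl$dosage >= 1
    n_carrier <- n_carrier + sum(carriers)
    n_aff <- n_aff + sum(pl$ped$affection == "affected" & carriers)
  }
  p_hat <- n_aff / n_carrier
  expect_lt(abs(p_hat - 0.8), 3 * sqrt(0.8 * 0.2 / n_carrier))
})

test_that("identical seeds give identical studies and emitted files", {
  cfg <- sim_config(seed = 99, gen2_children = 3, gen3_children = 2,
                    n_background = 20L, n_markers = 10L)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$marker_gt, s2$marker_gt)
  expect_identical(s1$variants$gt, s2$variants$gt)
  d1 <- file.path(tempdir(), "emitA")
  d2 <- file.path(tempdir(), "emitB")
  p1 <- emit_study(s1, d1)
  p2 <- emit_study(s2, d2)
  for (nm in names(p1))
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     label = paste("file", nm))
})

test_that("emitted studies re-read consistently with the truth table", {
  cfg <- sim_config(seed = 123, gen2_children = 3, gen3_children = 2,
                    n_background = 10L, n_markers = 8L)
  st <- simulate_study(cfg)
  dir <- file.path(tempdir(), "emitC")
  paths <- emit_study(st, dir)
  vs <- read_variants(paths$vcf)
  peds <- read_pedigree(paths$ped)
  ann <- read_annotations(paths$annotations)
  expect_equal(length(vs$samples), sum(vapply(peds, nrow, 1L)))
  expect_equal(unname(vs$gt), unname(st$variants$gt))
  truth <- utils::read.delim(paths$truth, colClasses = "character")
  ci <- match(truth$key, variant_key(vs))
  expect_false(is.na(ci))
  # carrier counts re-derived from the VCF match the in-memory study
  expect_equal(sum(vs$gt[ci, ] >= 1, na.rm = TRUE),
               sum(st$variants$gt[ci, ] >= 1, na.rm = TRUE))
  # annotations round trip with the causal gene present
  expect_true(truth$gene %in% ann$gene)
  # zero background rate leaves only the causal record
  cfg0 <- sim_config(seed = 7, gen2_children = 2, gen3_children = 2,
                     n_background = 0L, n_markers = 5L)
  st0 <- simulate_study(cfg0)
  expect_equal(nrow(st0$variants$sites), 1L)
})

test_that("adjacent-marker switch fraction tracks theta", {
  set.seed(61)
  n_kids <- 2500L
  ped <- pedigree("big",
    id = c("f", "m", paste0("k", seq_len(n_kids))),
    father = c(NA, NA, rep("f", n_kids)),
    mother = c(NA, NA, rep("m", n_kids)),
    sex = c("male", "female", rep("female", n_kids)))
  for (theta in c(0.1, 0.5)) {
    labs <- gene_drop(ped, n_markers = 2L, theta = theta)
    switches <- vapply(paste0("k", seq_len(n_kids)), function(id)
      sum(labs[[id]][, 1] != labs[[id]][, 2]), numeric(1))
    frac <- sum(switches) / (2 * n_kids)
    expect_lt(abs(frac - theta),
              3 * sqrt(theta * (1 - theta) / (2 * n_kids)))
  }
})
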