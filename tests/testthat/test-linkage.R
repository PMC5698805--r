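test_that("single-founder likelihood equals hand enumeration", {
  ped <- pedigree("solo", id = "a", father = NA, mother = NA,
                  sex = "male", affection = "affected")
  dm <- disease_model(q = 0.01, penetrances = c(0, 1, 1))
  mm <- marker_model(c(0.3, 0.7), theta = 0.1)
  # phenotype and genotype factors are independent within one founder:
  # P(affected) * P(marker genotype ref/ref)
  q <- 0.01
  want <- (2 * q * (1 - q) + q^2) * 0.3^2
  expect_equal(pedigree_likelihood(ped, c(a = 0), mm, dm), want,
               tolerance = 1e-12)
})

test_that("peeling equals exhaustive enumeration on random small pedigrees", {
  set.seed(71)
  for (rep in 1:20) {
    ped <- random_pedigree(8L)
    dm <- disease_model(q = runif(1, 0.001, 0.2),
                        penetrances = sort(runif(3)),
                        affecteds_only = sample(c(TRUE, FALSE), 1))
    f2 <- runif(1, 0.1, 0.9)
    mm <- marker_model(c(1 - f2, f2), theta = runif(1, 0, 0.5))
    g <- random_genotypes(ped)
    lp <- pedigree_likelihood(ped, g, mm, dm)
    lb <- brute_pedigree_likelihood(ped, g, mm, dm)
    if (lb == 0) expect_equal(lp, 0)
    else expect_lt(abs(lp - lb) / lb, 1e-10)
  }
})

test_that("likelihood factorizes into disease and marker parts at theta 0.5", {
  set.seed(73)
  ped <- random_pedigree(7L)
  g <- random_genotypes(ped, missing_rate = 0)
  dm <- disease_model(q = 0.05, penetrances = c(0.1, 0.8, 0.9),
                      affecteds_only = FALSE)
  mm <- marker_model(c(0.4, 0.6), theta = 0.5)
  joint <- pedigree_likelihood(ped, g, mm, dm)
  marker_only <- local({
    p2 <- ped
    p2$affection <- "unknown"
    pedigree_likelihood(p2, g, mm, dm)
  })
  disease_only <- pedigree_likelihood(ped, setNames(rep(NA_integer_,
    nrow(ped)), ped$id), mm, dm)
  expect_equal(joint, marker_only * disease_only, tolerance = 1e-10)
})

test_that("phase-known informative meioses give the closed-form LOD", {
  ids <- c("gf", "gm", "fa", "mo", paste0("k", 1:10))
  ped <- pedigree("cf", id = ids,
    father = c(NA, NA, "gf", NA, rep("fa", 10)),
    mother = c(NA, NA, "gm", NA, rep("mo", 10)),
    sex = c("male", "female", "male", "female", rep("female", 10)),
    affection = c("affected", "unaffected", "affected", "unaffected",
                  rep("affected", 10)))
  g <- setNames(c(0, 2, 1, 2, rep(1, 10)), ids)
  dm <- disease_model(q = 1e-4, penetrances = c(0, 1, 1),
                      affecteds_only = FALSE)
  res <- two_point_lod(ped, g, marker_model(), dm,
                       theta_grid = c(0, 0.1, 0.2, 0.5))
  expect_equal(unname(res$lod[res$theta == 0]), 10 * log10(2),
               tolerance = 1e-6)
  expect_equal(unname(res$lod[res$theta == 0.5]), 0, tolerance = 1e-9)
  expect_equal(unname(res$lod[res$theta == 0.1]),
               10 * log10((1 - 0.1) / 0.5), tolerance = 1e-6)
  # one recombinant child (paternal marker allele 2) kills theta = 0
  g2 <- g
  g2["k1"] <- 2
  res2 <- two_point_lod(ped, g2, marker_model(), dm,
                        theta_grid = c(0, 0.1, 0.5))
  expect_equal(unname(res2$lod[res2$theta == 0]), -99)
  expect_equal(unname(res2$lod[res2$theta == 0.1]),
               log10(0.1 * 0.9^9 / 0.5^10), tolerance = 1e-6)
})

test_that("uninformative or untyped families score zero LOD", {
  ped <- trio_ped(affection = c("affected", "unaffected", "affected"))
  dm <- disease_model()
  # all founders homozygous for the same marker allele
  res <- two_point_lod(ped, c(fa = 0, mo = 0, ch = 0), marker_model(), dm,
                       theta_grid = c(0, 0.1, 0.5))
  expect_equal(unname(res$lod), rep(0, 3), tolerance = 1e-9)
  # all genotypes missing
  res2 <- two_point_lod(ped, c(fa = NA, mo = NA, ch = NA),
                        marker_model(), dm, theta_grid = c(0, 0.5))
  expect_equal(unname(res2$lod), rep(0, 2), tolerance = 1e-9)
})

test_that("LOD is additive over families and invariant to member order", {
  set.seed(79)
  peds <- list(random_pedigree(6L), random_pedigree(7L))
  peds[[2]]$famid <- "rf2"
  genos <- lapply(peds, random_genotypes, missing_rate = 0.1)
  names(genos[[2]]) <- peds[[2]]$id
  dm <- disease_model()
  mm <- marker_model(c(0.5, 0.5))
  joint <- two_point_lod(peds, genos, mm, dm)
  solo <- lapply(seq_along(peds), function(i)
    two_point_lod(peds[[i]], genos[[i]], mm, dm))
  expect_equal(unname(joint$lod),
               unname(solo[[1]]$lod + solo[[2]]$lod), tolerance = 1e-9)
  # member order
  shuf <- peds[[1]][sample(nrow(peds[[1]])), ]
  expect_equal(pedigree_likelihood(shuf, genos[[1]], mm, dm),
               pedigree_likelihood(peds[[1]], genos[[1]], mm, dm),
               tolerance = 1e-12)
})

test_that("affecteds-only likelihood ignores unaffected phenotypes", {
  set.seed(83)
  ped <- random_pedigree(8L)
  g <- random_genotypes(ped)
  dm <- disease_model(affecteds_only = TRUE)
  mm <- marker_model(c(0.5, 0.5), theta = 0.05)
  base <- pedigree_likelihood(ped, g, mm, dm)
  flip <- ped
  flip$affection[flip$affection == "unaffected"] <- "unknown"
  expect_equal(pedigree_likelihood(flip, g, mm, dm), base,
               tolerance = 1e-12)
})

test_that("lod_regions extracts maximal runs above threshold", {
  tab <- data.frame(chrom = "1", pos = (1:6) * 1e6,
                    max_lod = c(0.5, 1.9, 2.95, 1.2, 2.1, 2.4),
                    family = "757")
  reg <- lod_regions(tab)
  expect_equal(nrow(reg), 2L)
  # bounds extend to the flanking (first excluded) markers
  expect_equal(reg$start, c(2e6, 4e6))
  expect_equal(reg$end, c(4e6, 6e6))
  expect_equal(reg$max_lod[1], 2.95)
  none <- lod_regions(data.frame(chrom = "1", pos = 1:3,
                                 max_lod = c(0, 1, 2), family = "x"))
  expect_equal(nrow(none), 0L)  # threshold is exclusive
})
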