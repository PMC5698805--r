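#' Exhaustive pedigree likelihood (cross-check engine)
#'
#' Computes the same joint disease-marker likelihood as
#' [pedigree_likelihood()] by brute-force enumeration over every ordered
#' two-locus diplotype assignment consistent with the observed marker
#' genotypes, with no clique elimination. Exponential in pedigree size;
#' intended as an independent correctness oracle for small pedigrees,
#' never for analysis.
#'
#' @inheritParams pedigree_likelihood
#' @return The likelihood.
#' @export
brute_pedigree_likelihood <- function(ped, geno, mm, dm) {
  depth <- ped_depth(ped)
  if (is.null(depth)) stop("pedigree contains a parental cycle")
  ord <- order(depth[ped$id])
  ped <- ped[ord, ]
  fa <- match(ped$father, ped$id) - 1L
  mo <- match(ped$mother, ped$id) - 1L
  fa[is.na(fa)] <- -1L
  mo[is.na(mo)] <- -1L
  aff <- c(unknown = 0L, unaffected = 1L, affected = 2L)[ped$affection]
  k <- length(mm$freqs)
  pairs <- lapply(ped$id, function(id) {
    g <- if (id %in% names(geno)) geno[[id]] else NA
    p <- geno_pair(g, k)
    if (is.null(p)) c(-1L, -1L) else as.integer(p) - 1L
  })
  ga <- vapply(pairs, `[`, 1L, 1)
  gb <- vapply(pairs, `[`, 1L, 2)
  brute_likelihood_cpp(fa, mo, unname(aff), ga, gb,
                       dm$q, dm$penetrances, dm$affecteds_only,
                       mm$theta, mm$freqs)
}
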