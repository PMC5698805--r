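damaging_consequences <- c("missense", "frameshift", "stop_gain", "splice")

#' Does a variant segregate in a family's sequenced affecteds?
#'
#' Segregation means every sequenced affected individual with a
#' non-missing call carries at least one alternate allele. A single
#' sequenced affected carrier segregates trivially (flag the small n
#' downstream).
#'
#' @param geno named dosage vector (0/1/2/NA) by member id.
#' @param ped a [pedigree()].
#' @return `TRUE`/`FALSE`, or `NA` when every sequenced affected's call
#'   is missing. Errors when the family has no sequenced affecteds.
#' @export
is_segregating <- function(geno, ped) {
  ids <- ped$id[ped$affection == "affected" & ped$sequenced]
  if (!length(ids)) stop("family ", ped$famid[1], " has no sequenced affecteds")
  g <- geno[intersect(ids, names(geno))]
  g <- g[!is.na(g)]
  if (!length(g)) return(NA)
  all(g >= 1)
}

# carrier bookkeeping per (variant, family); geno indexed by member id
family_carrier_stats <- function(geno, ped) {
  ids <- ped$id[ped$affection == "affected" & ped$sequenced]
  g <- geno[intersect(ids, names(geno))]
  carriers <- names(g)[!is.na(g) & g >= 1]
  list(carriers = carriers, n_carriers = length(carriers),
       n_affected_sequenced = length(ids),
       segregating = if (all(is.na(g))) NA else all(g[!is.na(g)] >= 1))
}

prioritized_row <- function(key, ann_row, fam, strategy, st, maf_max) {
  maf <- ann_row$maf
  data.frame(
    key = key, gene = ann_row$gene, chrom = ann_row$chrom,
    pos = ann_row$pos, ref = ann_row$ref, alt = ann_row$alt,
    aa_change = ann_row$aa_change, dbsnp = ann_row$dbsnp,
    maf = maf, cadd = ann_row$cadd, family = fam, strategy = strategy,
    carriers = paste(st$carriers, collapse = ","),
    n_carriers = st$n_carriers,
    n_affected_sequenced = st$n_affected_sequenced,
    segregating = st$segregating,
    cadd_flag = !is.na(ann_row$cadd) & ann_row$cadd >= 15,
    maf_flag = if (is.na(maf)) "maf_missing" else
      sprintf("maf_le_%g", maf_max),
    stringsAsFactors = FALSE)
}

empty_prioritized <- function() {
  prioritized_row("k", data.frame(gene = "", chrom = "", pos = 0L,
                                  ref = "A", alt = "C", aa_change = "",
                                  dbsnp = "", maf = 0, cadd = 0),
                  "f", "s", list(carriers = character(), n_carriers = 0L,
                                 n_affected_sequenced = 0L,
                                 segregating = NA), 1)[0, ]
}

#' Tier 1: rare damaging variants in known risk genes
#'
#' Retains nonsynonymous/loss-of-function variants in listed genes with
#' population MAF at most `maf_max` (2% default) or unobserved, and
#' reports one row per (variant, family) with at least one sequenced
#' affected carrier. Segregation is reported but not required: partially
#' shared variants in established genes can still be contributing
#' alleles.
#'
#' @param vs a [variant_set()].
#' @param ann a `variant_annotations` table.
#' @param gene_list character vector of known risk genes.
#' @param peds list of [pedigree()] objects.
#' @param maf_max inclusive MAF ceiling (default 0.02).
#' @return Data frame of prioritized (variant, family) rows.
#' @export
strategy_known_genes <- function(vs, ann, gene_list, peds, maf_max = 0.02) {
  if (!length(gene_list)) stop("gene list is empty")
  keys <- variant_key(vs)
  a <- annotation_for(ann, keys)
  keep <- !is.na(a$gene) & a$gene %in% gene_list &
    a$consequence %in% damaging_consequences &
    (is.na(a$maf) | a$maf <= maf_max)
  rows <- list()
  for (i in which(keep)) {
    geno <- vs$gt[i, ]
    for (ped in peds) {
      st <- family_carrier_stats(geno, ped)
      if (st$n_carriers >= 1L)
        rows[[length(rows) + 1L]] <- prioritized_row(
          keys[i], a[i, ], ped$famid[1], "known_gene", st, maf_max)
    }
  }
  if (!length(rows)) return(empty_prioritized())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tier 2: segregating rare variants under family linkage peaks
#'
#' Within each family that has a LOD-supported region, retains
#' nonsynonymous/LOF variants located inside that family's region,
#' segregating in all sequenced affecteds, with MAF at most `maf_max`
#' (1% default) or unobserved. A CADD >= 15 deleteriousness flag is
#' annotated but is not a hard filter: linkage plus segregation is the
#' primary evidence and low-scored candidates remain visible for review.
#'
#' @param vs a [variant_set()].
#' @param ann a `variant_annotations` table.
#' @param regions data frame with `chrom`, `start`, `end`, `family`
#'   (1-based inclusive), e.g. from [lod_regions()].
#' @param peds list of [pedigree()] objects.
#' @param maf_max inclusive MAF ceiling (default 0.01).
#' @return Data frame of prioritized (variant, family) rows.
#' @export
strategy_linkage <- function(vs, ann, regions, peds, maf_max = 0.01) {
  keys <- variant_key(vs)
  a <- annotation_for(ann, keys)
  base_keep <- a$consequence %in% damaging_consequences &
    (is.na(a$maf) | a$maf <= maf_max)
  base_keep[is.na(base_keep)] <- FALSE
  rows <- list()
  for (ped in peds) {
    fam <- ped$famid[1]
    fam_regions <- regions[regions$family == fam, , drop = FALSE]
    if (!nrow(fam_regions)) next
    inside <- in_regions(fam_regions, vs$sites$chrom, vs$sites$pos)
    for (i in which(base_keep & inside)) {
      st <- family_carrier_stats(vs$gt[i, ], ped)
      if (isTRUE(st$segregating) && st$n_carriers >= 1L)
        rows[[length(rows) + 1L]] <- prioritized_row(
          keys[i], a[i, ], fam, "linkage_region", st, maf_max)
    }
  }
  if (!length(rows)) return(empty_prioritized())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tier 3: genes hit in multiple families
#'
#' Collects, per gene, the nonsynonymous/LOF variants that segregate in a
#' family's sequenced affecteds with MAF at most `maf_max` (1% default,
#' or unobserved) and CADD at least `cadd_min` (15; variants without a
#' CADD score cannot demonstrate deleteriousness and are not selected),
#' then reports genes hit in at least two distinct families. Genes
#' already covered by the known-gene tier may be excluded so this tier
#' surfaces novel candidates.
#'
#' @param vs a [variant_set()].
#' @param ann a `variant_annotations` table.
#' @param peds list of at least two [pedigree()] objects.
#' @param maf_max inclusive MAF ceiling (default 0.01).
#' @param cadd_min inclusive CADD floor (default 15).
#' @param exclude_genes genes to omit (e.g. the known-gene list).
#' @return Data frame of class `gene_clusters`: `gene`, `n_families`,
#'   `families`, `n_variants`, `variants`, `identical_variant_shared`
#'   (some identical variant occurs in >= 2 families).
#' @export
strategy_cross_family <- function(vs, ann, peds, maf_max = 0.01,
                                  cadd_min = 15, exclude_genes = character()) {
  if (length(peds) < 2L) stop("cross-family clustering needs >= 2 families")
  keys <- variant_key(vs)
  a <- annotation_for(ann, keys)
  keep <- a$consequence %in% damaging_consequences &
    (is.na(a$maf) | a$maf <= maf_max) &
    !is.na(a$cadd) & a$cadd >= cadd_min &
    !is.na(a$gene) & !(a$gene %in% exclude_genes)
  keep[is.na(keep)] <- FALSE
  hits <- list()  # per gene: data.frame(key, family)
  for (i in which(keep)) {
    geno <- vs$gt[i, ]
    for (ped in peds) {
      st <- family_carrier_stats(geno, ped)
      if (isTRUE(st$segregating) && st$n_carriers >= 1L) {
        g <- a$gene[i]
        hits[[g]] <- rbind(hits[[g]], data.frame(
          key = keys[i], family = ped$famid[1], stringsAsFactors = FALSE))
      }
    }
  }
  out <- data.frame(gene = character(), n_families = integer(),
                    families = character(), n_variants = integer(),
                    variants = character(),
                    identical_variant_shared = logical(),
                    stringsAsFactors = FALSE)
  for (g in sort(names(hits))) {
    h <- hits[[g]]
    fams <- unique(h$family)
    if (length(fams) < 2L) next
    shared <- any(vapply(unique(h$key), function(k)
      length(unique(h$family[h$key == k])) >= 2L, logical(1)))
    out[nrow(out) + 1L, ] <- list(
      g, length(fams), paste(sort(fams), collapse = ","),
      length(unique(h$key)), paste(sort(unique(h$key)), collapse = ","),
      shared)
  }
  class(out) <- c("gene_clusters", "data.frame")
  out
}
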