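#' Load the bundled example candidate tables
#'
#' Three tab-separated tables of prioritized exome variants from a
#' 23-family late-onset Alzheimer disease study design: tier 1 (rare
#' variants in known risk genes), tier 2 (segregating variants under
#' family linkage peaks, with the family LOD score) and tier 3 (genes
#' hit in more than one family).
#'
#' @return List of data frames `tier1`, `tier2`, `tier3`.
#' @export
load_example_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "pedexome",
                                  mustWork = TRUE)
  rd <- function(f) utils::read.delim(path(f), stringsAsFactors = FALSE,
                                      na.strings = c("", "NA"))
  list(tier1 = rd("ad_tier1_known_genes.tsv"),
       tier2 = rd("ad_tier2_linkage.tsv"),
       tier3 = rd("ad_tier3_shared.tsv"))
}

#' Reconstruct an analyzable study from the example tables
#'
#' Expands the printed candidate tables into the pipeline's input model:
#' one minimal pedigree per family (its sequenced affecteds), a
#' [variant_set()] whose calls reproduce each row's carriers-of-total
#' count, an annotation table, the known-gene list, and the tier-2
#' families' LOD regions (a window around their reported variants, with
#' the printed LOD). Tier-3 rows with fewer carriers than sequenced
#' affecteds are published as segregating, so the non-carrier calls are
#' encoded missing (not called) rather than reference; tier-1 rows make
#' no segregation claim and their non-carriers are homozygous reference.
#'
#' @param region_halfwidth half-width (bp) of the reconstructed LOD
#'   regions around tier-2 variants.
#' @return List: `variants`, `annotations`, `peds`, `gene_list`,
#'   `regions`, `tables`.
#' @export
example_study <- function(region_halfwidth = 1e6) {
  tb <- load_example_tables()
  parse_carriers <- function(x) {
    parts <- strsplit(x, "/", fixed = TRUE)
    list(k = vapply(parts, function(p) as.integer(p[1]), 1L),
         n = vapply(parts, function(p) as.integer(p[2]), 1L))
  }
  c1 <- parse_carriers(tb$tier1$carriers)
  c3 <- parse_carriers(tb$tier3$carriers)
  rows <- rbind(
    data.frame(tb$tier1[c("gene", "chrom", "pos", "nucleotide",
                          "aa_change", "dbsnp", "maf", "cadd", "family")],
               k = c1$k, n = c1$n, tier = 1L, lod = NA_real_),
    data.frame(tb$tier2[c("gene", "chrom", "pos", "nucleotide",
                          "aa_change", "dbsnp", "maf", "cadd", "family")],
               k = tb$tier2$n_carriers, n = tb$tier2$n_carriers, tier = 2L,
               lod = tb$tier2$lod),
    data.frame(tb$tier3[c("gene", "chrom", "pos", "nucleotide",
                          "aa_change", "dbsnp", "maf", "cadd", "family")],
               k = c3$k, n = c3$n, tier = 3L, lod = NA_real_))
  rows$family <- as.character(rows$family)
  rows$chrom <- as.character(rows$chrom)
  nuc <- strsplit(rows$nucleotide, ">", fixed = TRUE)
  rows$ref <- vapply(nuc, `[`, "", 1)
  rows$alt <- vapply(nuc, `[`, "", 2)
  rows$key <- paste(rows$chrom, rows$pos, rows$ref, rows$alt, sep = ":")

  # one pedigree per family: its sequenced affecteds as members
  fam_n <- tapply(rows$n, rows$family, max)
  peds <- lapply(names(fam_n), function(fam)
    pedigree(fam, id = paste0(fam, "_A", seq_len(fam_n[[fam]])),
             father = NA, mother = NA, sex = "unknown",
             affection = "affected", sequenced = TRUE, genotyped = TRUE))
  names(peds) <- names(fam_n)
  samples <- unlist(lapply(peds, `[[`, "id"), use.names = FALSE)

  keys <- unique(rows$key)
  sites <- rows[match(keys, rows$key), c("chrom", "pos", "ref", "alt")]
  sites$qual <- 10
  sites$id <- rows$dbsnp[match(keys, rows$key)]
  gt <- matrix(0L, length(keys), length(samples),
               dimnames = list(NULL, samples))
  for (r in seq_len(nrow(rows))) {
    i <- match(rows$key[r], keys)
    members <- peds[[rows$family[r]]]$id
    carriers <- members[seq_len(rows$k[r])]
    gt[i, carriers] <- 1L
    rest <- setdiff(members, carriers)
    if (length(rest))
      gt[i, rest] <- if (rows$tier[r] == 3L) NA_integer_ else 0L
  }
  vs <- variant_set(sites, gt)

  ann <- rows[match(keys, rows$key),
              c("chrom", "pos", "ref", "alt", "gene", "maf", "cadd",
                "dbsnp", "aa_change", "key")]
  ann$consequence <- ifelse(grepl("fs", ann$aa_change), "frameshift",
                            "missense")
  ann$map35 <- 1
  ann$map20 <- 1
  rownames(ann) <- NULL
  class(ann) <- c("variant_annotations", "data.frame")

  t2 <- rows[rows$tier == 2L, ]
  regions <- do.call(rbind, lapply(split(t2, paste(t2$family, t2$chrom)),
    function(s) data.frame(
      chrom = s$chrom[1], start = min(s$pos) - region_halfwidth,
      end = max(s$pos) + region_halfwidth, max_lod = max(s$lod),
      family = s$family[1], stringsAsFactors = FALSE)))
  rownames(regions) <- NULL

  list(variants = vs, annotations = ann, peds = peds,
       gene_list = read_gene_list(system.file("extdata",
                                              "known_ad_genes.txt",
                                              package = "pedexome")),
       regions = regions, tables = tb)
}
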