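#' Run the full prioritization pipeline
#'
#' Orchestrates QC, linkage (or precomputed LOD regions), IBD sharing and
#' the three prioritization strategies over one set of in-memory inputs,
#' returning every report plus a line-oriented log of per-stage in/out
#' counts. When real marker genotypes for a study's families are not
#' available, precomputed LOD regions can be supplied to bypass the
#' linkage stage; the log records which route was taken.
#'
#' @param variants a [variant_set()] of exome calls.
#' @param annotations a `variant_annotations` table.
#' @param peds list of [pedigree()] objects.
#' @param gene_list character vector of known risk genes.
#' @param regions optional precomputed LOD regions (`chrom`, `start`,
#'   `end`, `max_lod`, `family`).
#' @param marker_gt,markers optional marker dosage matrix and map
#'   (`chrom`, `pos`, `freq2`) for the two-point linkage scan (used when
#'   `regions` is absent).
#' @param labels optional founder-haplotype labels
#'   (family > chrom > individual) for IBD segment calling.
#' @param qc a [qc_config()].
#' @param dm a [disease_model()].
#' @param lod_threshold LOD bound for region extraction (exclusive).
#' @param theta_grid recombination fractions for the scan.
#' @return List of class `pedexome_run`: filtered variants, `lod_table`,
#'   `regions`, `ibd`, `tier1`, `tier2`, `tier3`, `summary`, `log`.
#' @export
run_pipeline <- function(variants, annotations, peds, gene_list,
                         regions = NULL, marker_gt = NULL, markers = NULL,
                         labels = NULL, qc = qc_config(),
                         dm = disease_model(), lod_threshold = 2,
                         theta_grid = c(0, 0.01, 0.05, 0.1, 0.2, 0.5)) {
  log <- character()
  say <- function(stage, msg)
    log <<- c(log, paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), "\t",
                          stage, "\t", msg))
  n0 <- nrow(variants$sites)
  say("input", paste0("variants=", n0, " samples=",
                      length(variants$samples), " families=", length(peds)))
  vs <- filter_genotypes(variants, qc)
  say("qc_genotypes", paste0("in=", n0, " out=", nrow(vs$sites),
                             " calls_masked=", attr(vs, "n_masked")))
  vs <- filter_sites(vs, annotations, qc)
  say("qc_sites", paste0("in=", n0, " removed=", attr(vs, "n_removed"),
                         " out=", nrow(vs$sites)))
  lod_table <- NULL
  if (is.null(regions)) {
    if (!is.null(marker_gt) && !is.null(markers)) {
      lod_table <- two_point_scan(peds, marker_gt, markers, dm,
                                  theta_grid = theta_grid)
      regions <- lod_regions(lod_table, threshold = lod_threshold)
      say("linkage", paste0("markers=", nrow(markers), " regions=",
                            nrow(regions), " route=scan"))
    } else {
      regions <- data.frame(chrom = character(), start = numeric(),
                            end = numeric(), max_lod = numeric(),
                            family = character(), stringsAsFactors = FALSE)
      say("linkage", "route=none (no markers, no precomputed regions)")
    }
  } else {
    say("linkage", paste0("regions=", nrow(regions),
                          " route=precomputed"))
  }
  ibd <- NULL
  if (!is.null(labels) && !is.null(markers)) {
    segs <- list()
    for (fam in intersect(names(labels), names(peds)))
      for (ch in names(labels[[fam]])) {
        mk <- markers[markers$chrom == ch, ]
        sp <- sharing_profile(peds[[fam]], labels[[fam]][[ch]],
                              mk$pos, chrom = ch)
        segs[[paste(fam, ch)]] <- call_ibd_segments(sp)
      }
    ibd <- do.call(rbind, segs)
    rownames(ibd) <- NULL
    say("ibd", paste0("segments=", if (is.null(ibd)) 0 else nrow(ibd)))
  }
  tier1 <- strategy_known_genes(vs, annotations, gene_list, peds)
  say("tier1", paste0("rows=", nrow(tier1)))
  tier2 <- strategy_linkage(vs, annotations, regions, peds)
  say("tier2", paste0("rows=", nrow(tier2)))
  tier3 <- if (length(peds) >= 2L)
    strategy_cross_family(vs, annotations, peds,
                          exclude_genes = gene_list)
  else strategy_cross_family_empty()
  say("tier3", paste0("clusters=", nrow(tier3)))
  run <- structure(list(variants = vs, lod_table = lod_table,
                        regions = regions, ibd = ibd, tier1 = tier1,
                        tier2 = tier2, tier3 = tier3, log = log),
                   class = "pedexome_run")
  run$summary <- summarize_run(run)
  run
}

strategy_cross_family_empty <- function() {
  out <- data.frame(gene = character(), n_families = integer(),
                    families = character(), n_variants = integer(),
                    variants = character(),
                    identical_variant_shared = logical(),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_clusters", "data.frame")
  out
}

#' Summary counts of a pipeline run
#'
#' Machine-readable counts per tier; empty tiers give zeros, never absent
#' keys.
#'
#' @param run a `pedexome_run`.
#' @return Named list of counts.
#' @export
summarize_run <- function(run) {
  t1 <- run$tier1; t2 <- run$tier2; t3 <- run$tier3
  max_or_zero <- function(x) if (length(x) && any(!is.na(x)))
    max(x, na.rm = TRUE) else 0
  genes_multi <- if (nrow(t1)) {
    per_gene <- tapply(t1$key, t1$gene, function(k) length(unique(k)))
    sum(per_gene >= 2)
  } else 0L
  multicarrier <- if (nrow(t1))
    length(unique(t1$key[t1$n_carriers >= 2])) else 0L
  list(
    tier1_rows = nrow(t1),
    tier1_variants = length(unique(t1$key)),
    tier1_genes = length(unique(t1$gene)),
    tier1_families = length(unique(t1$family)),
    tier1_multicarrier_variants = multicarrier,
    tier1_genes_multiple_variants = as.integer(genes_multi),
    tier1_max_cadd = max_or_zero(t1$cadd),
    tier2_rows = nrow(t2),
    tier2_variants = length(unique(t2$key)),
    tier2_genes = length(unique(t2$gene)),
    tier2_families = length(unique(t2$family)),
    tier2_max_cadd = max_or_zero(t2$cadd),
    tier3_clusters = nrow(t3),
    tier3_genes = length(unique(t3$gene)),
    tier3_identical_variant_clusters =
      if (nrow(t3)) sum(t3$identical_variant_shared) else 0L,
    tier3_families = if (nrow(t3))
      length(unique(unlist(strsplit(t3$families, ",")))) else 0L)
}

#' Write a pipeline run to report files
#'
#' Emits the three tier tables, the LOD table and regions, IBD segments,
#' a key-value summary and the run log. Report tables carry no
#' timestamps, so reruns on identical inputs are byte-identical; only
#' the log is timestamped.
#'
#' @param run a `pedexome_run`.
#' @param dir output directory.
#' @return Named list of written paths.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  wt <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.table(x, p, quote = FALSE, sep = "\t", row.names = FALSE)
    paths[[sub("\\.tsv$", "", name)]] <<- p
    p
  }
  wt(run$tier1, "tier1_known_genes.tsv")
  wt(run$tier2, "tier2_linkage.tsv")
  wt(run$tier3, "tier3_cross_family.tsv")
  if (!is.null(run$lod_table)) wt(run$lod_table, "lod_table.tsv")
  wt(run$regions, "lod_regions.tsv")
  if (!is.null(run$ibd)) wt(run$ibd, "ibd_segments.tsv")
  s <- run$summary
  wt(data.frame(key = names(s), value = unlist(s, use.names = FALSE)),
     "summary.tsv")
  writeLines(run$log, file.path(dir, "run.log"))
  paths$log <- file.path(dir, "run.log")
  paths
}

#' @exportS3Method base::print
print.pedexome_run <- function(x, ...) {
  s <- x$summary
  cat("pedexome run:",
      s$tier1_variants, "tier-1 variants in", s$tier1_genes, "genes;",
      s$tier2_variants, "tier-2 variants;",
      s$tier3_clusters, "tier-3 gene clusters\n")
  invisible(x)
}
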