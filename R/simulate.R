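#' Simulation configuration
#'
#' Study-condition defaults emulate the multiplex late-onset design the
#' pipeline targets: three-generation families whose affected counts fall
#' in the 4-16 range typical of heavily loaded dominant pedigrees, a rare
#' (q = 0.0001) fully penetrant dominant causal allele planted on one
#' founder haplotype, biallelic markers at 50% frequency with adjacent
#' recombination fraction 0.05, and a background of exome variants whose
#' population MAFs are drawn from a mixture straddling the 1%/2% rarity
#' thresholds so that filters are exercised on both sides.
#'
#' @param seed integer RNG seed; identical seeds give identical studies.
#' @param n_families number of families to simulate.
#' @param gen2_children,gen3_children sibship sizes of the 3-generation
#'   template (each second-generation child marries in a founder spouse).
#' @param chroms chromosome labels.
#' @param n_markers markers per chromosome.
#' @param marker_freq frequency of marker allele 2 (used when
#'   `n_marker_alleles` is 2).
#' @param n_marker_alleles alleles per linkage marker (default 8,
#'   equifrequent): the microsatellite-style highly informative panel of
#'   classical parametric linkage, standing in for the information
#'   content that multipoint analysis extracts from dense SNP arrays.
#'   Set to 2 for a SNP-style panel.
#' @param theta recombination fraction between adjacent markers.
#' @param marker_spacing physical spacing between markers (bp).
#' @param causal list: `chrom`, `marker` (index of the marker the causal
#'   site sits at; `NULL` places it mid-panel), `q`, `penetrances`,
#'   `gene`, `maf`, `cadd`.
#' @param n_background background exome variants across the genome.
#' @param bg_rare_frac,bg_mid_frac fractions of background MAFs drawn
#'   rare (<1%) and intermediate (1-2%); the rest are common.
#' @param bg_synonymous_frac fraction of background variants annotated
#'   synonymous.
#' @param geno_error per-call genotype error rate on emitted exome calls.
#' @param missing_rate per-call missingness rate on emitted exome calls.
#' @param min_affected rejection-sample families until at least this many
#'   affected members (0 disables; template redrawn, transmission never
#'   conditioned).
#' @param unaffected_sequenced_frac fraction of unaffecteds flagged
#'   sequenced.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_families = 1L,
                       gen2_children = 6L, gen3_children = 4L,
                       chroms = c("1", "2"), n_markers = 30L,
                       marker_freq = 0.5, n_marker_alleles = 8L,
                       theta = 0.05,
                       marker_spacing = 1e6,
                       causal = list(chrom = "1", marker = NULL, q = 1e-4,
                                     penetrances = c(0, 1, 1),
                                     gene = "CAUSAL1", maf = 1e-4,
                                     cadd = 35),
                       n_background = 60L, bg_rare_frac = 0.4,
                       bg_mid_frac = 0.2, bg_synonymous_frac = 0.2,
                       geno_error = 0, missing_rate = 0,
                       min_affected = 4L,
                       unaffected_sequenced_frac = 0.15) {
  rates <- c(marker_freq, theta * 2, bg_rare_frac, bg_mid_frac,
             bg_synonymous_frac, geno_error, missing_rate,
             unaffected_sequenced_frac)
  if (any(rates < 0 | rates > 1)) stop("rates/frequencies must lie in [0,1]")
  if (is.null(causal$marker))
    causal$marker <- max(1L, as.integer(ceiling(n_markers / 2)))
  if (causal$marker > n_markers)
    stop("causal marker index exceeds the marker panel")
  structure(as.list(environment()), class = "sim_config")
}

# three-generation template: founder couple, gen-2 sibship with married-in
# founder spouses, gen-3 sibships
template_pedigree <- function(famid, gen2_children, gen3_children) {
  id <- c("gp1", "gp2")
  father <- c(NA, NA)
  mother <- c(NA, NA)
  sex <- c("male", "female")
  for (i in seq_len(gen2_children)) {
    cid <- paste0("c", i)
    sid <- paste0("s", i)
    csex <- if (i %% 2 == 1) "male" else "female"
    id <- c(id, cid, sid)
    father <- c(father, "gp1", NA)
    mother <- c(mother, "gp2", NA)
    sex <- c(sex, csex, if (csex == "male") "female" else "male")
    for (j in seq_len(gen3_children)) {
      gid <- paste0("g", i, "_", j)
      id <- c(id, gid)
      father <- c(father, if (csex == "male") cid else sid)
      mother <- c(mother, if (csex == "male") sid else cid)
      sex <- c(sex, if (j %% 2 == 1) "female" else "male")
    }
  }
  pedigree(famid, id = id, father = father, mother = mother, sex = sex,
           affection = "unknown")
}

#' Gene-drop founder haplotypes through a pedigree
#'
#' Founders receive uniquely labelled haplotype pairs (`<id>.1`,
#' `<id>.2`); every meiosis transmits a recombinant mosaic of the
#' parent's two haplotypes with switch probability `theta` between
#' adjacent markers. Child haplotype labels are therefore always a subset
#' of founder labels, and at `theta = 0` every transmitted haplotype is
#' an unbroken founder haplotype.
#'
#' @param ped a [pedigree()].
#' @param n_markers number of markers on the chromosome.
#' @param theta adjacent-marker recombination fraction.
#' @return List by member id of 2 x n_markers character label matrices
#'   (row 1 paternal, row 2 maternal).
#' @export
gene_drop <- function(ped, n_markers, theta) {
  depth <- ped_depth(ped)
  labels <- list()
  transmit <- function(parent_labels) {
    hap <- sample.int(2L, 1L)
    out <- character(n_markers)
    for (m in seq_len(n_markers)) {
      if (m > 1L && stats::runif(1) < theta) hap <- 3L - hap
      out[m] <- parent_labels[hap, m]
    }
    out
  }
  for (i in order(depth[ped$id])) {
    id <- ped$id[i]
    if (is.na(ped$father[i])) {
      labels[[id]] <- rbind(rep(paste0(id, ".1"), n_markers),
                            rep(paste0(id, ".2"), n_markers))
    } else {
      labels[[id]] <- rbind(transmit(labels[[ped$father[i]]]),
                            transmit(labels[[ped$mother[i]]]))
    }
  }
  labels
}

#' Plant a causal allele and sample affection
#'
#' Places the risk allele on one founder haplotype at the causal marker
#' and samples each member's affection from the penetrance vector given
#' their count of that haplotype there. Carrier affecteds therefore share
#' the founder haplotype around the locus.
#'
#' @param ped a [pedigree()].
#' @param labels gene-drop labels for the causal chromosome.
#' @param marker causal marker index.
#' @param founder_hap label of the haplotype carrying the risk allele
#'   (default: first founder's first haplotype).
#' @param penetrances numeric length 3.
#' @return List: `ped` (affection filled in), `dosage` (named causal
#'   dosage per member), `founder_hap`.
#' @export
plant_causal <- function(ped, labels, marker,
                         founder_hap = paste0(ped$id[which(is_founder(ped))[1]], ".1"),
                         penetrances = c(0, 1, 1)) {
  dosage <- vapply(ped$id, function(id)
    sum(labels[[id]][, marker] == founder_hap), integer(1))
  aff <- ifelse(stats::runif(nrow(ped)) < penetrances[dosage + 1L],
                "affected", "unaffected")
  ped$affection <- aff
  list(ped = ped, dosage = dosage, founder_hap = founder_hap)
}

#' Simulate a complete multi-family study
#'
#' Drives [gene_drop()] and [plant_causal()] per family (redrawing until
#' `min_affected` is met), derives marker genotypes from per-haplotype
#' founder alleles, overlays background exome variants with
#' mixture-drawn MAFs, and assembles the pieces every pipeline stage
#' consumes.
#'
#' @param cfg a [sim_config()].
#' @return List of class `sim_study`: `peds`, `labels`
#'   (family > chrom > id label matrices), `markers` (chrom, pos, freq2),
#'   `marker_gt` (markers x samples dosage), `variants`
#'   ([variant_set()] of exome sites), `annotations`, `truth` (causal
#'   keys and carriers).
#' @export
simulate_study <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  n_mk <- cfg$n_markers
  k_mk <- cfg$n_marker_alleles
  markers <- do.call(rbind, lapply(cfg$chroms, function(ch)
    data.frame(chrom = ch, pos = as.integer(seq_len(n_mk) * cfg$marker_spacing),
               freq2 = cfg$marker_freq, n_alleles = k_mk,
               stringsAsFactors = FALSE)))
  peds <- list()
  labels <- list()
  causal_dosage <- list()
  for (f in seq_len(cfg$n_families)) {
    famid <- paste0("fam", f)
    for (try in seq_len(1000L)) {
      ped <- template_pedigree(famid, cfg$gen2_children, cfg$gen3_children)
      drop <- lapply(cfg$chroms, function(ch) gene_drop(ped, n_mk, cfg$theta))
      names(drop) <- cfg$chroms
      planted <- plant_causal(ped, drop[[cfg$causal$chrom]],
                              cfg$causal$marker,
                              penetrances = cfg$causal$penetrances)
      if (sum(planted$ped$affection == "affected") >= cfg$min_affected) break
    }
    ped <- planted$ped
    ped$sequenced <- ped$affection == "affected" |
      stats::runif(nrow(ped)) < cfg$unaffected_sequenced_frac
    # unique ids across families
    ped$id <- paste0(famid, ".", ped$id)
    ped$father <- ifelse(is.na(ped$father), NA, paste0(famid, ".", ped$father))
    ped$mother <- ifelse(is.na(ped$mother), NA, paste0(famid, ".", ped$mother))
    for (ch in cfg$chroms) {
      names(drop[[ch]]) <- paste0(famid, ".", names(drop[[ch]]))
      drop[[ch]] <- lapply(drop[[ch]], function(m) {
        m[] <- paste0(famid, ".", m)
        m
      })
    }
    peds[[famid]] <- ped
    labels[[famid]] <- drop
    causal_dosage[[famid]] <- stats::setNames(planted$dosage, ped$id)
  }
  samples <- unlist(lapply(peds, `[[`, "id"), use.names = FALSE)

  # marker alleles: one allele (1..k) per founder haplotype per marker
  founder_alleles <- new.env(parent = emptyenv())
  allele_of <- function(lab, m) {
    key <- paste0(lab, "@", m)
    got <- founder_alleles[[key]]
    if (is.null(got)) {
      got <- if (k_mk == 2L) 1L + stats::rbinom(1L, 1L, cfg$marker_freq)
             else sample.int(k_mk, 1L)
      founder_alleles[[key]] <- got
    }
    got
  }
  # biallelic panels are emitted as alt dosage, multi-allelic ones as
  # "a/b" unordered pairs (the linkage engine accepts both)
  marker_gt <- matrix(if (k_mk == 2L) NA_integer_ else NA_character_,
                      nrow(markers), length(samples),
                      dimnames = list(NULL, samples))
  row0 <- 0L
  for (ch in cfg$chroms) {
    for (m in seq_len(n_mk)) {
      for (fam in names(peds)) {
        for (id in peds[[fam]]$id) {
          labs <- labels[[fam]][[ch]][[id]][, m]
          a <- allele_of(paste0(ch, ":", labs[1]), m)
          b <- allele_of(paste0(ch, ":", labs[2]), m)
          marker_gt[row0 + m, id] <- if (k_mk == 2L) (a - 1L) + (b - 1L)
            else paste(min(a, b), max(a, b), sep = "/")
        }
      }
    }
    row0 <- row0 + n_mk
  }

  # exome variants: one causal site + background sites
  causal_pos <- as.integer(cfg$causal$marker * cfg$marker_spacing)
  sites <- data.frame(chrom = cfg$causal$chrom, pos = causal_pos,
                      ref = "A", alt = "T", qual = 10,
                      id = NA_character_, stringsAsFactors = FALSE)
  gt <- matrix(unlist(lapply(names(peds), function(fam)
    causal_dosage[[fam]][peds[[fam]]$id])), nrow = 1)
  colnames(gt) <- samples
  ann <- data.frame(chrom = cfg$causal$chrom, pos = causal_pos, ref = "A",
                    alt = "T", gene = cfg$causal$gene,
                    consequence = "missense", maf = cfg$causal$maf,
                    cadd = cfg$causal$cadd, dbsnp = NA_character_,
                    map35 = 1, map20 = 1, aa_change = "p.Arg100Trp",
                    stringsAsFactors = FALSE)
  if (cfg$n_background > 0L) {
    for (b in seq_len(cfg$n_background)) {
      ch <- sample(cfg$chroms, 1L)
      mk <- sample.int(n_mk, 1L)
      pos <- as.integer(mk * cfg$marker_spacing + b)  # distinct from marker positions
      u <- stats::runif(1)
      maf <- if (u < cfg$bg_rare_frac) stats::runif(1, 1e-5, 0.009)
             else if (u < cfg$bg_rare_frac + cfg$bg_mid_frac)
               stats::runif(1, 0.011, 0.019)
             else stats::runif(1, 0.021, 0.4)
      dos <- integer(0)
      for (fam in names(peds)) {
        hap_carrier <- new.env(parent = emptyenv())
        carries <- function(lab) {
          got <- hap_carrier[[lab]]
          if (is.null(got)) {
            got <- stats::runif(1) < maf
            hap_carrier[[lab]] <- got
          }
          got
        }
        dos <- c(dos, vapply(peds[[fam]]$id, function(id) {
          labs <- labels[[fam]][[ch]][[id]][, mk]
          sum(vapply(labs, carries, logical(1)))
        }, integer(1)))
      }
      sites[nrow(sites) + 1L, ] <- list(ch, pos, "A", "G", 10,
                                        NA_character_)
      gt <- rbind(gt, dos)
      cons <- if (stats::runif(1) < cfg$bg_synonymous_frac) "synonymous"
              else "missense"
      cadd <- if (stats::runif(1) < 0.5) stats::runif(1, 0, 14)
              else stats::runif(1, 15, 40)
      ann[nrow(ann) + 1L, ] <- list(ch, pos, "A", "G",
                                    sprintf("BG%04d", b), cons, maf, cadd,
                                    sprintf("rs%07d", b), 1, 1,
                                    "p.Ala1Val")
    }
  }
  rownames(gt) <- NULL
  # genotype error / missingness overlays
  if (cfg$geno_error > 0) {
    flip <- stats::runif(length(gt)) < cfg$geno_error & !is.na(gt)
    gt[flip] <- (gt[flip] + sample(1:2, sum(flip), replace = TRUE)) %% 3L
  }
  if (cfg$missing_rate > 0)
    gt[stats::runif(length(gt)) < cfg$missing_rate] <- NA_integer_
  dp <- matrix(stats::rpois(length(gt), 40) + 1L, nrow(gt), ncol(gt),
               dimnames = dimnames(gt))
  gq <- matrix(sample(60:99, length(gt), replace = TRUE), nrow(gt),
               ncol(gt), dimnames = dimnames(gt))
  vs <- variant_set(sites, gt, dp, gq)
  ann$key <- paste(ann$chrom, ann$pos, ann$ref, ann$alt, sep = ":")
  class(ann) <- c("variant_annotations", "data.frame")
  truth <- data.frame(
    key = variant_key(vs)[1], gene = cfg$causal$gene,
    chrom = cfg$causal$chrom, pos = causal_pos,
    stringsAsFactors = FALSE)
  structure(list(cfg = cfg, peds = peds, labels = labels,
                 markers = markers, marker_gt = marker_gt, variants = vs,
                 annotations = ann, truth = truth),
            class = "sim_study")
}

#' Write a simulated study to files
#'
#' Emits the standard external representations: exome VCF, PED,
#' annotation TSV, founder-haplotype label TSV, marker map and marker
#' genotype TSVs, and a truth table of planted causal keys for recovery
#' scoring. Files re-read cleanly through the package readers.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return Named list of file paths.
#' @export
emit_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(dir, "study.vcf"),
    ped = file.path(dir, "study.ped"),
    annotations = file.path(dir, "annotations.tsv"),
    labels = file.path(dir, "haplotype_labels.tsv"),
    marker_map = file.path(dir, "marker_map.tsv"),
    marker_gt = file.path(dir, "marker_genotypes.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_variants(study$variants, paths$vcf)
  write_pedigree(study$peds, paths$ped)
  ann <- study$annotations
  utils::write.table(ann[, setdiff(names(ann), "key")], paths$annotations,
                     quote = FALSE, sep = "\t", row.names = FALSE)
  flat <- list()
  for (fam in names(study$labels))
    for (ch in names(study$labels[[fam]]))
      flat[[fam]][[ch]] <- study$labels[[fam]][[ch]]
  write_haplotype_labels(flat, paths$labels)
  utils::write.table(study$markers, paths$marker_map, quote = FALSE,
                     sep = "\t", row.names = FALSE)
  utils::write.table(
    data.frame(study$markers[, c("chrom", "pos")], study$marker_gt,
               check.names = FALSE),
    paths$marker_gt, quote = FALSE, sep = "\t", row.names = FALSE)
  utils::write.table(study$truth, paths$truth, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  paths
}
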