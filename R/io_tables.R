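#' Read pedigrees from a PED file
#'
#' Whitespace-delimited, one row per individual with columns family, id,
#' father, mother, sex (1=male, 2=female, 0=unknown), phenotype
#' (2=affected, 1=unaffected, 0/-9=unknown) and an optional seventh column
#' flagging sequenced individuals (1/0). Unknown parents are coded 0 and
#' become founders.
#'
#' @param path PED file.
#' @param mci_as one of `"unknown"` (default) or `"affected"`: how to map
#'   an optional phenotype code 3 used for intermediate diagnoses such as
#'   mild cognitive impairment.
#' @return Named list of [pedigree()] objects, one per family id.
#' @export
read_pedigree <- function(path, mci_as = c("unknown", "affected")) {
  mci_as <- match.arg(mci_as)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(tab) < 6)
    stop("PED file needs >= 6 columns, got ", ncol(tab), ": ", path)
  names(tab)[1:6] <- c("famid", "id", "father", "mother", "sex", "phen")
  phen <- tab$phen
  phen[phen == "3"] <- if (mci_as == "affected") "2" else "0"
  sequenced <- if (ncol(tab) >= 7) tab[[7]] == "1" else TRUE
  out <- lapply(split(seq_len(nrow(tab)), tab$famid), function(ix) {
    pedigree(tab$famid[ix[1]], id = tab$id[ix],
             father = tab$father[ix], mother = tab$mother[ix],
             sex = tab$sex[ix], affection = phen[ix],
             sequenced = sequenced[ix], genotyped = TRUE)
  })
  out[unique(tab$famid)]
}

#' Write pedigrees to a PED file
#' @param peds a [pedigree()] or list of pedigrees.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(peds, path) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  rows <- lapply(peds, function(p) {
    data.frame(
      famid = p$famid, id = p$id,
      father = ifelse(is.na(p$father), "0", p$father),
      mother = ifelse(is.na(p$mother), "0", p$mother),
      sex = c(male = "1", female = "2", unknown = "0")[p$sex],
      phen = c(affected = "2", unaffected = "1", unknown = "0")[p$affection],
      seq = ifelse(p$sequenced, "1", "0"),
      stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, quote = FALSE,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a variant annotation table
#'
#' Tab-separated with a header naming at least `chrom`, `pos`, `ref`,
#' `alt`, `gene`, `consequence`; optional columns `maf`, `cadd`, `dbsnp`,
#' `map35`, `map20`, `aa_change`. Empty cells in `maf`/`cadd`/`dbsnp` are
#' stored as missing (`NA`), never as 0: absence from a population
#' database is evidence of rarity and is flagged as such downstream, not
#' conflated with frequency zero.
#'
#' @param path annotation TSV.
#' @return Data frame of class `variant_annotations` keyed by
#'   `chrom:pos:ref:alt` (column `key`); one row per unique key.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           na.strings = c("", "NA", "."))
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("annotation table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  for (opt in c("maf", "cadd", "dbsnp", "map35", "map20", "aa_change"))
    if (is.null(tab[[opt]]))
      tab[[opt]] <- if (opt %in% c("dbsnp", "aa_change")) NA_character_ else NA_real_
  tab$chrom <- as.character(tab$chrom)
  ok_cons <- c("missense", "frameshift", "stop_gain", "splice",
               "synonymous", "other")
  bad <- !tab$consequence %in% ok_cons
  if (any(bad))
    stop("unknown consequence values: ",
         paste(unique(tab$consequence[bad]), collapse = ", "))
  for (col in c("maf", "map35", "map20")) {
    v <- tab[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop(col, " values must lie in [0,1]")
  }
  tab$key <- paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = ":")
  if (anyDuplicated(tab$key)) {
    cols <- c("gene", "consequence", "maf", "cadd", "dbsnp",
              "map35", "map20", "aa_change")
    for (k in unique(tab$key[duplicated(tab$key)])) {
      rows <- tab[tab$key == k, cols]
      if (nrow(unique(rows)) > 1L)
        stop("duplicate annotation key with conflicting values: ", k)
    }
    tab <- tab[!duplicated(tab$key), ]
    rownames(tab) <- NULL
  }
  class(tab) <- c("variant_annotations", "data.frame")
  tab
}

#' Look up annotations for variant keys
#' @param ann a `variant_annotations` table.
#' @param keys character keys (`chrom:pos:ref:alt`).
#' @return Data frame of annotation rows aligned to `keys` (NA rows where
#'   unannotated).
#' @export
annotation_for <- function(ann, keys) {
  ann[match(keys, ann$key), , drop = FALSE]
}

#' Read genomic regions from a BED-like file
#'
#' Columns chrom, start, end (0-based half-open) and an optional label.
#' Intervals are converted on read to the package's 1-based inclusive
#' convention (`[100, 200)` in BED covers 1-based positions 101..200) and
#' sorted within chromosome.
#'
#' @param path BED3+label file (no header, tab- or space-delimited).
#' @return Data frame `chrom`, `start`, `end` (1-based inclusive),
#'   `label`.
#' @export
read_regions <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 3) stop("region file needs >= 3 columns: ", path)
  names(tab)[1:3] <- c("chrom", "start0", "end0")
  tab$label <- if (ncol(tab) >= 4) as.character(tab[[4]]) else NA_character_
  if (any(tab$start0 >= tab$end0))
    stop("region with start >= end at line(s): ",
         paste(which(tab$start0 >= tab$end0), collapse = ", "))
  out <- data.frame(chrom = as.character(tab$chrom),
                    start = tab$start0 + 1L, end = tab$end0,
                    label = tab$label, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end), ]
  rownames(out) <- NULL
  out
}

#' Test whether positions fall inside regions
#' @param regions data frame as from [read_regions()] (1-based inclusive).
#' @param chrom,pos vectors of positions to test (recycled together).
#' @return Logical vector: position covered by at least one region.
#' @export
in_regions <- function(regions, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(pos, n)
  vapply(seq_len(n), function(i)
    any(regions$chrom == chrom[i] &
          regions$start <= pos[i] & regions$end >= pos[i]),
    logical(1))
}

#' Read a gene list
#'
#' Plain text, one symbol per line; blank lines and `#` comments ignored.
#' @param path file path.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read founder-haplotype labels
#'
#' Tab-separated columns family, individual, chrom, marker index (1-based
#' along the chromosome), label1, label2: the two founder-haplotype labels
#' carried by the individual at that marker, as produced by an external
#' phasing step or by [gene_drop()].
#'
#' @param path label TSV (with header).
#' @return Nested list `labels[[family]][[chrom]][[individual]]`: a
#'   2 x n_markers character matrix.
#' @export
read_haplotype_labels <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("family", "individual", "chrom", "marker", "label1", "label2")
  if (!all(need %in% names(tab)))
    stop("haplotype label file needs columns: ", paste(need, collapse = ", "))
  tab$marker <- as.integer(tab$marker)
  out <- list()
  for (fam in unique(tab$family)) {
    tf <- tab[tab$family == fam, ]
    out[[fam]] <- list()
    for (ch in unique(tf$chrom)) {
      tc <- tf[tf$chrom == ch, ]
      nm <- max(tc$marker)
      out[[fam]][[ch]] <- lapply(split(tc, tc$individual), function(ti) {
        m <- matrix(NA_character_, 2, nm)
        m[1, ti$marker] <- ti$label1
        m[2, ti$marker] <- ti$label2
        m
      })
    }
  }
  out
}

#' Write founder-haplotype labels
#' @param labels nested list as returned by [read_haplotype_labels()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_haplotype_labels <- function(labels, path) {
  rows <- list()
  for (fam in names(labels))
    for (ch in names(labels[[fam]]))
      for (ind in names(labels[[fam]][[ch]])) {
        m <- labels[[fam]][[ch]][[ind]]
        rows[[length(rows) + 1L]] <- data.frame(
          family = fam, individual = ind, chrom = ch,
          marker = seq_len(ncol(m)), label1 = m[1, ], label2 = m[2, ],
          stringsAsFactors = FALSE)
      }
  utils::write.table(do.call(rbind, rows), path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}
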