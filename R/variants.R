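#' Construct a variant set
#'
#' Container for biallelic variant sites with per-sample calls. Each site
#' carries exactly one alternate allele (multi-allelic VCF records are
#' split on read). Genotypes are stored as alt-allele dosage (0/1/2,
#' `NA` missing) with matching read-depth and genotype-quality matrices.
#'
#' @param sites data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, and optionally `qual` (VQSLOD-like site quality, `NA` allowed)
#'   and `id`.
#' @param gt integer matrix, sites x samples, of alt dosages.
#' @param dp,gq optional matrices of per-call depth and genotype quality
#'   (same shape as `gt`).
#' @return Object of class `variant_set`.
#' @export
variant_set <- function(sites, gt, dp = NULL, gq = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  if (is.null(sites$qual)) sites$qual <- NA_real_
  if (is.null(sites$id)) sites$id <- NA_character_
  sites$pos <- as.integer(sites$pos)
  gt <- as.matrix(gt)
  if (nrow(gt) != nrow(sites))
    stop("gt has ", nrow(gt), " rows but sites has ", nrow(sites))
  if (is.null(colnames(gt))) stop("gt must have sample names as colnames")
  ok <- is.na(gt) | gt %in% 0:2
  if (!all(ok)) stop("gt entries must be 0/1/2 or NA")
  bad_allele <- !grepl("^[ACGT]+$", sites$ref) | !grepl("^[ACGT]+$", sites$alt)
  if (any(bad_allele))
    stop("ref/alt must be non-empty strings over {A,C,G,T}; offending rows: ",
         paste(which(bad_allele), collapse = ", "))
  if (any(sites$pos < 1)) stop("positions must be >= 1")
  check_shape <- function(m, what) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (!identical(dim(m), dim(gt))) stop(what, " shape differs from gt")
    m
  }
  structure(list(sites = sites, gt = gt,
                 dp = check_shape(dp, "dp"), gq = check_shape(gq, "gq"),
                 samples = colnames(gt)),
            class = "variant_set")
}

#' @exportS3Method base::print
print.variant_set <- function(x, ...) {
  cat("variant_set: ", nrow(x$sites), " sites x ", length(x$samples),
      " samples\n", sep = "")
  invisible(x)
}

#' Variant keys
#'
#' Canonical `chrom:pos:ref:alt` identifier per site.
#' @param x a `variant_set` or a sites data frame.
#' @return Character vector of keys.
#' @export
variant_key <- function(x) {
  s <- if (inherits(x, "variant_set")) x$sites else x
  paste(s$chrom, s$pos, s$ref, s$alt, sep = ":")
}

#' Indel length per site
#'
#' `|nchar(ref) - nchar(alt)|`; 0 for substitutions. The bundled example
#' frameshift (`CCCGG>C`) has length 4.
#' @param x a `variant_set` or sites data frame.
#' @export
indel_length <- function(x) {
  s <- if (inherits(x, "variant_set")) x$sites else x
  abs(nchar(s$ref) - nchar(s$alt))
}

#' Normalize one ref/alt pair
#'
#' Parsimony normalization: strip the longest shared suffix, then the
#' longest shared prefix (advancing `pos`), always keeping at least one
#' base on each allele. Idempotent. Left-alignment against a reference
#' genome is out of scope: no pipeline input carries reference sequence,
#' and trimmed representations are already unique keys for exome sites.
#'
#' @param pos 1-based position.
#' @param ref,alt allele strings.
#' @return `list(pos, ref, alt)`.
#' @examples
#' normalize_allele(100, "ATT", "AT")   # -> pos 100, AT > A
#' normalize_allele(100, "CCCGG", "C")  # unchanged, deletion length 4
#' @export
normalize_allele <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  # suffix
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  # prefix
  while (length(r) > 1L && length(a) > 1L && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

#' Normalize all sites of a variant set
#' @param vs a [variant_set()].
#' @return The variant set with parsimony-trimmed alleles and adjusted
#'   positions.
#' @export
normalize_variants <- function(vs) {
  for (i in seq_len(nrow(vs$sites))) {
    n <- normalize_allele(vs$sites$pos[i], vs$sites$ref[i], vs$sites$alt[i])
    vs$sites$pos[i] <- n$pos
    vs$sites$ref[i] <- n$ref
    vs$sites$alt[i] <- n$alt
  }
  vs
}

#' Read a multi-sample VCF into a variant set
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}), splits multi-allelic sites into
#' one biallelic record per alternate allele, applies parsimony
#' normalization, and extracts per-call dosage, depth (DP) and genotype
#' quality (GQ). Half-calls (one allele missing) are conservatively set to
#' missing. The QUAL column is carried as the VQSLOD-like site quality.
#'
#' @param path VCF file (plain or gzipped).
#' @return A [variant_set()].
#' @export
read_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt_raw <- v@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2)
    stop("VCF carries no sample genotype columns: ", path)
  fmt <- gt_raw[, 1]
  samples <- colnames(gt_raw)[-1]
  n_rec <- nrow(fix)

  parse_field <- function(row, field) {
    keys <- strsplit(fmt[row], ":", fixed = TRUE)[[1]]
    k <- match(field, keys)
    vals <- gt_raw[row, -1]
    if (is.na(k)) return(rep(NA_character_, length(vals)))
    vapply(strsplit(vals, ":", fixed = TRUE), function(p)
      if (length(p) >= k) p[k] else NA_character_, "")
  }

  sites_list <- list()
  gt_rows <- list()
  dp_rows <- list()
  gq_rows <- list()
  for (r in seq_len(n_rec)) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    gts <- parse_field(r, "GT")
    dps <- suppressWarnings(as.integer(parse_field(r, "DP")))
    gqs <- suppressWarnings(as.integer(parse_field(r, "GQ")))
    allele_mat <- t(vapply(gts, function(g) {
      if (is.na(g)) return(c(NA_integer_, NA_integer_))
      a <- strsplit(g, "[/|]")[[1]]
      if (length(a) != 2L) return(c(NA_integer_, NA_integer_))
      suppressWarnings(as.integer(sub("\\.", NA, a)))
    }, integer(2)))
    # half-calls -> missing
    half <- xor(is.na(allele_mat[, 1]), is.na(allele_mat[, 2]))
    allele_mat[half, ] <- NA_integer_
    qual <- suppressWarnings(as.numeric(fix[r, "QUAL"]))
    for (k in seq_along(alts)) {
      dos <- rowSums(allele_mat == k)
      dos[is.na(allele_mat[, 1])] <- NA_integer_
      norm <- normalize_allele(as.integer(fix[r, "POS"]),
                               fix[r, "REF"], alts[k])
      sites_list[[length(sites_list) + 1L]] <- data.frame(
        chrom = fix[r, "CHROM"], pos = norm$pos, ref = norm$ref,
        alt = norm$alt, qual = qual,
        id = if (is.na(fix[r, "ID"]) || fix[r, "ID"] == ".")
          NA_character_ else fix[r, "ID"],
        stringsAsFactors = FALSE)
      gt_rows[[length(gt_rows) + 1L]] <- dos
      dp_rows[[length(dp_rows) + 1L]] <- dps
      gq_rows[[length(gq_rows) + 1L]] <- gqs
    }
  }
  sites <- do.call(rbind, sites_list)
  rownames(sites) <- NULL
  as_mat <- function(rows) {
    m <- do.call(rbind, rows)
    colnames(m) <- samples
    m
  }
  variant_set(sites, as_mat(gt_rows), as_mat(dp_rows), as_mat(gq_rows))
}

#' Write a variant set as VCF 4.2
#'
#' Emits GT/DP/GQ per call. Dosage 1 is written as `0/1`, 2 as `1/1`,
#' missing as `./.`.
#'
#' @param vs a [variant_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variants <- function(vs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", vs$samples), collapse = "\t")), con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[vs$gt + 1L], nrow = nrow(vs$gt))
  gt_str[is.na(vs$gt)] <- "./."
  fmt_int <- function(m, i, j) {
    if (is.null(m) || is.na(m[i, j])) "." else as.character(m[i, j])
  }
  for (i in seq_len(nrow(vs$sites))) {
    calls <- vapply(seq_along(vs$samples), function(j)
      paste(gt_str[i, j], fmt_int(vs$dp, i, j), fmt_int(vs$gq, i, j),
            sep = ":"), "")
    writeLines(paste(c(
      vs$sites$chrom[i], vs$sites$pos[i],
      if (is.na(vs$sites$id[i])) "." else vs$sites$id[i],
      vs$sites$ref[i], vs$sites$alt[i],
      if (is.na(vs$sites$qual[i])) "." else
        format(vs$sites$qual[i], trim = TRUE),
      "PASS", ".", "GT:DP:GQ", calls), collapse = "\t"), con)
  }
  invisible(path)
}
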