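#' Quality-control configuration
#'
#' Bundles every QC threshold with the study's defaults: per-call minimum
#' depth 5 and GQ 20 (both inclusive), site VQSLOD strictly > 0,
#' 35-bp-track mappability exactly 1 and 20-bp-track mappability >= 0.5,
#' per-sample call rate >= 0.98, per-SNP call rate >= 0.95, cross-batch
#' presence >= 0.60, and LD pruning with a 50-marker window, step 5 and
#' r-squared cap 0.5.
#'
#' @param min_depth,min_gq per-call thresholds (inclusive).
#' @param min_vqslod site quality bound (exclusive).
#' @param map35_required required 35-bp mappability (equality).
#' @param map20_min minimum 20-bp mappability (inclusive).
#' @param sample_call_rate_min,snp_call_rate_min call-rate floors.
#' @param cross_platform_presence_min minimum fraction of samples, pooled
#'   across genotyping batches, with a non-missing call.
#' @param ld_window,ld_step,ld_r2_max windowed LD-pruning parameters.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_depth = 5L, min_gq = 20L, min_vqslod = 0,
                      map35_required = 1, map20_min = 0.5,
                      sample_call_rate_min = 0.98,
                      snp_call_rate_min = 0.95,
                      cross_platform_presence_min = 0.60,
                      ld_window = 50L, ld_step = 5L, ld_r2_max = 0.5) {
  rates <- c(sample_call_rate_min, snp_call_rate_min,
             cross_platform_presence_min, map35_required, map20_min,
             ld_r2_max)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0,1]")
  if (ld_step < 1 || ld_window < ld_step)
    stop("need ld_window >= ld_step >= 1")
  structure(as.list(environment()), class = "qc_config")
}

#' Genotype-level filtering
#'
#' Sets individual calls failing depth or genotype-quality thresholds to
#' missing; sites are always retained (downstream segregation logic
#' handles missingness). Calls without depth/GQ metadata are kept.
#'
#' @param vs a [variant_set()].
#' @param cfg a [qc_config()].
#' @return The filtered variant set, with an attribute `n_masked` giving
#'   the number of calls set to missing.
#' @export
filter_genotypes <- function(vs, cfg = qc_config()) {
  fail <- matrix(FALSE, nrow(vs$gt), ncol(vs$gt))
  if (!is.null(vs$dp)) fail <- fail | (!is.na(vs$dp) & vs$dp < cfg$min_depth)
  if (!is.null(vs$gq)) fail <- fail | (!is.na(vs$gq) & vs$gq < cfg$min_gq)
  n_masked <- sum(fail & !is.na(vs$gt))
  vs$gt[fail] <- NA_integer_
  attr(vs, "n_masked") <- n_masked
  vs
}

#' Site-level filtering
#'
#' Keeps a site iff its VQSLOD-like quality is strictly positive (sites
#' without a quality value pass, flagged), its 35-bp mappability equals 1
#' and its 20-bp mappability is >= 0.5. Sites whose mappability is not
#' annotated pass (not-observed is not evidence of poor mappability); the
#' kept set records which sites lacked a quality value.
#'
#' @param vs a [variant_set()].
#' @param ann a `variant_annotations` table supplying map35/map20.
#' @param cfg a [qc_config()].
#' @return Filtered variant set; attributes `n_removed` and
#'   `qual_missing` (logical per kept site).
#' @export
filter_sites <- function(vs, ann, cfg = qc_config()) {
  a <- annotation_for(ann, variant_key(vs))
  qual_ok <- is.na(vs$sites$qual) | vs$sites$qual > cfg$min_vqslod
  map35_ok <- is.na(a$map35) | a$map35 == cfg$map35_required
  map20_ok <- is.na(a$map20) | a$map20 >= cfg$map20_min
  keep <- qual_ok & map35_ok & map20_ok
  out <- subset_sites(vs, keep)
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "qual_missing") <- is.na(vs$sites$qual)[keep]
  out
}

subset_sites <- function(vs, keep) {
  variant_set(vs$sites[keep, , drop = FALSE],
              vs$gt[keep, , drop = FALSE],
              if (!is.null(vs$dp)) vs$dp[keep, , drop = FALSE],
              if (!is.null(vs$gq)) vs$gq[keep, , drop = FALSE])
}

#' Per-sample call rates
#' @param vs a [variant_set()] with at least one site and sample.
#' @return Named numeric vector: fraction of non-missing calls per
#'   sample.
#' @export
sample_call_rates <- function(vs) {
  if (nrow(vs$gt) == 0L || ncol(vs$gt) == 0L)
    stop("call rates need >= 1 variant and >= 1 sample")
  colMeans(!is.na(vs$gt))
}

#' Per-site call rates
#' @param vs a [variant_set()] with at least one site and sample.
#' @return Numeric vector: fraction of non-missing calls per site.
#' @export
snp_call_rate <- function(vs) {
  if (nrow(vs$gt) == 0L || ncol(vs$gt) == 0L)
    stop("call rates need >= 1 variant and >= 1 sample")
  rowMeans(!is.na(vs$gt))
}

#' Cross-batch presence
#'
#' Fraction of samples, pooled across labeled genotyping batches, with a
#' non-missing call per marker; markers below the configured floor would
#' be excluded from multi-platform analyses.
#'
#' @param vs a [variant_set()].
#' @param batches character vector of batch labels per sample (unused in
#'   the pooled fraction but validated for length).
#' @return Numeric vector per site.
#' @export
batch_presence <- function(vs, batches) {
  if (length(batches) != length(vs$samples))
    stop("one batch label per sample required")
  rowMeans(!is.na(vs$gt))
}

#' Genotype concordance between two platforms
#'
#' Fraction of overlapping (sample, site) calls, non-missing on both
#' platforms, with identical unordered genotypes (equal alt dosage).
#'
#' @param g1,g2 dosage matrices with matching dimnames (sites x samples).
#' @return Concordance in [0,1].
#' @export
concordance <- function(g1, g2) {
  if (!identical(dim(g1), dim(g2)))
    stop("genotype matrices must have identical shape")
  both <- !is.na(g1) & !is.na(g2)
  if (!any(both)) stop("no overlapping non-missing calls")
  mean(g1[both] == g2[both])
}

#' Windowed LD pruning
#'
#' Greedy pruning in the style of array-QC toolchains: within each
#' `ld_window`-marker window (advancing by `ld_step`), repeatedly drop one
#' marker of any pair whose squared Pearson correlation of alt dosage
#' (over complete pairs) exceeds `ld_r2_max`. Of a violating pair, the
#' marker with the lower call rate is dropped; ties drop the later
#' position. Deterministic given marker order.
#'
#' @param gt dosage matrix, markers (rows, position-ordered) x samples.
#' @param cfg a [qc_config()].
#' @return Integer vector of kept marker row indices.
#' @export
ld_prune <- function(gt, cfg = qc_config()) {
  n <- nrow(gt)
  if (n == 0L) return(integer())
  keep <- rep(TRUE, n)
  call_rate <- rowMeans(!is.na(gt))
  r2 <- function(i, j) {
    ok <- !is.na(gt[i, ]) & !is.na(gt[j, ])
    if (sum(ok) < 2L) return(0)
    v <- suppressWarnings(stats::cor(gt[i, ok], gt[j, ok]))
    if (is.na(v)) 0 else v^2
  }
  starts <- seq(1L, max(1L, n - 1L), by = cfg$ld_step)
  for (s in starts) {
    win <- s:min(n, s + cfg$ld_window - 1L)
    repeat {
      active <- win[keep[win]]
      if (length(active) < 2L) break
      dropped <- FALSE
      pairs <- utils::combn(active, 2L)
      for (p in seq_len(ncol(pairs))) {
        i <- pairs[1, p]; j <- pairs[2, p]
        if (!keep[i] || !keep[j]) next
        if (r2(i, j) > cfg$ld_r2_max) {
          drop <- if (call_rate[i] < call_rate[j]) i
                  else if (call_rate[j] < call_rate[i]) j
                  else max(i, j)
          keep[drop] <- FALSE
          dropped <- TRUE
        }
      }
      if (!dropped) break
    }
    if (s + cfg$ld_window - 1L >= n) break
  }
  which(keep)
}
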