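#' Per-marker IBD sharing profile of a family's affecteds
#'
#' A marker is shared when some founder haplotype label is carried by
#' every genotyped affected individual at that marker, i.e. all affecteds
#' have inherited at least one haplotype from a common founder there.
#'
#' @param ped a [pedigree()].
#' @param labels list keyed by individual id of 2 x n_markers character
#'   matrices of founder-haplotype labels (one chromosome), as from
#'   [gene_drop()] or [read_haplotype_labels()].
#' @param positions numeric vector of strictly increasing marker
#'   positions.
#' @param chrom chromosome label.
#' @return Object of class `sharing_profile`: list with `family_id`,
#'   `chrom`, `markers` (positions) and `shared` (logical per marker).
#' @export
sharing_profile <- function(ped, labels, positions, chrom = "1") {
  ids <- ped$id[ped$affection == "affected" & ped$genotyped]
  ids <- intersect(ids, names(labels))
  if (!length(ids)) stop("no genotyped affected individuals with labels")
  if (is.unsorted(positions, strictly = TRUE))
    stop("marker positions must be strictly increasing")
  nm <- length(positions)
  shared <- vapply(seq_len(nm), function(i) {
    common <- unique(c(labels[[ids[1]]][, i]))
    for (id in ids[-1]) {
      common <- intersect(common, labels[[id]][, i])
      if (!length(common)) return(FALSE)
    }
    length(common) > 0L
  }, logical(1))
  structure(list(family_id = ped$famid[1], chrom = chrom,
                 markers = positions, shared = shared),
            class = "sharing_profile")
}

#' Call IBD segments from a sharing profile
#'
#' Sliding-window rule: a marker is IBD-positive iff the shared fraction
#' in any window of `window` consecutive markers covering it is strictly
#' greater than `threshold` (with the 10-marker default: at least 6 of
#' 10 shared). Maximal runs of positive markers become segments whose
#' bounds are the first and last positive marker positions. Chromosomes
#' with fewer markers than `window` fall back to a single
#' whole-chromosome window and the result is flagged.
#'
#' @param sp a [sharing_profile()].
#' @param window window length in markers (default 10).
#' @param threshold shared-fraction bound, exclusive (default 0.5).
#' @return Data frame of class `ibd_segments`: `family_id`, `chrom`,
#'   `start_pos`, `end_pos`, `n_markers`, `mean_sharing`, `fallback`.
#' @export
call_ibd_segments <- function(sp, window = 10L, threshold = 0.5) {
  nm <- length(sp$markers)
  fallback <- nm < window
  positive <- ibd_positive(sp$shared, if (fallback) nm else window, threshold)
  runs <- rle(positive)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  seg_ix <- which(runs$values)
  out <- data.frame(
    family_id = character(), chrom = character(), start_pos = numeric(),
    end_pos = numeric(), n_markers = integer(), mean_sharing = numeric(),
    fallback = logical(), stringsAsFactors = FALSE)
  for (k in seg_ix) {
    i <- starts[k]; j <- ends[k]
    out[nrow(out) + 1L, ] <- list(
      sp$family_id, sp$chrom, sp$markers[i], sp$markers[j],
      j - i + 1L, mean(sp$shared[i:j]), fallback)
  }
  class(out) <- c("ibd_segments", "data.frame")
  out
}

# max-over-covering-windows positivity: positive[i] iff any length-w
# window containing marker i has shared fraction > threshold
ibd_positive <- function(shared, w, threshold) {
  n <- length(shared)
  if (w > n) w <- n
  nwin <- n - w + 1L
  win_pass <- vapply(seq_len(nwin), function(s)
    mean(shared[s:(s + w - 1L)]) > threshold, logical(1))
  positive <- logical(n)
  for (s in which(win_pass)) positive[s:(s + w - 1L)] <- TRUE
  positive
}
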