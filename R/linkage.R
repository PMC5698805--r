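#' Parametric disease model
#'
#' Single-locus diallelic disease model for parametric linkage: risk
#' allele frequency `q` and penetrances (f0, f1, f2) for 0/1/2 copies.
#' The default is the rare fully penetrant dominant, affecteds-only model
#' (q = 0.0001, penetrances 0/1/1) in which unaffected and unknown
#' phenotypes contribute a likelihood factor of 1, guarding against
#' incomplete penetrance.
#'
#' @param q risk allele frequency in (0,1).
#' @param penetrances numeric length 3, each in [0,1].
#' @param affecteds_only logical; if `TRUE` unaffecteds are treated as
#'   phenotype-unknown.
#' @return List of class `disease_model`.
#' @export
disease_model <- function(q = 1e-4, penetrances = c(0, 1, 1),
                          affecteds_only = TRUE) {
  if (q <= 0 || q >= 1) stop("q must lie in (0,1)")
  if (length(penetrances) != 3 || any(penetrances < 0 | penetrances > 1))
    stop("penetrances must be 3 probabilities")
  structure(list(q = q, penetrances = penetrances,
                 affecteds_only = affecteds_only),
            class = "disease_model")
}

#' Marker model
#'
#' Codominant marker with two or more alleles (SNP or microsatellite
#' style) and a recombination fraction to the disease locus.
#'
#' @param freqs positive allele frequencies summing to 1 (tolerance
#'   1e-9); length >= 2.
#' @param theta recombination fraction in [0, 0.5].
#' @return List of class `marker_model`.
#' @export
marker_model <- function(freqs = c(0.5, 0.5), theta = 0) {
  if (length(freqs) < 2 || any(freqs <= 0))
    stop("marker needs >= 2 positive allele frequencies")
  if (abs(sum(freqs) - 1) > 1e-9) stop("allele frequencies must sum to 1")
  if (theta < 0 || theta > 0.5) stop("theta must lie in [0, 0.5]")
  structure(list(freqs = freqs, theta = theta), class = "marker_model")
}

# ---- two-locus state machinery -----------------------------------------
# A haplotype h in 1:(2k) is (disease allele d in {1 wild, 2 risk},
# marker allele m in 1:k): h = (d-1)*k + m. An ordered diplotype state
# s in 1:(2k)^2 is (paternal h, maternal h): s = (hp-1)*2k + hm.

locus_cache <- new.env(parent = emptyenv())

locus_space <- function(k) {
  key <- as.character(k)
  got <- locus_cache[[key]]
  if (!is.null(got)) return(got)
  nh <- 2L * k
  hap_d <- rep(1:2, each = k)
  hap_m <- rep(seq_len(k), times = 2)
  state_hp <- rep(seq_len(nh), each = nh)
  state_hm <- rep(seq_len(nh), times = nh)
  m1 <- hap_m[state_hp]
  m2 <- hap_m[state_hm]
  ls <- list(k = k, nh = nh, ns = nh * nh,
             hap_d = hap_d, hap_m = hap_m,
             state_hp = state_hp, state_hm = state_hm,
             state_ndisease = (hap_d[state_hp] == 2) + (hap_d[state_hm] == 2),
             state_ma = pmin(m1, m2), state_mb = pmax(m1, m2))
  locus_cache[[key]] <- ls
  ls
}

# P(transmitted haplotype h | parent ordered diplotype s), ns x nh
transmission_matrix <- function(theta, k = 2L) {
  ls <- locus_space(k)
  tm <- matrix(0, ls$ns, ls$nh)
  hap_idx <- function(d, m) (d - 1L) * ls$k + m
  for (s in seq_len(ls$ns)) {
    hA <- ls$state_hp[s]; hB <- ls$state_hm[s]
    add <- function(h, p) tm[s, h] <<- tm[s, h] + p
    add(hA, 0.5 * (1 - theta))
    add(hap_idx(ls$hap_d[hA], ls$hap_m[hB]), 0.5 * theta)
    add(hB, 0.5 * (1 - theta))
    add(hap_idx(ls$hap_d[hB], ls$hap_m[hA]), 0.5 * theta)
  }
  tm
}

founder_prior <- function(dm, marker_freqs) {
  ls <- locus_space(length(marker_freqs))
  fh <- c(1 - dm$q, dm$q)[ls$hap_d] * marker_freqs[ls$hap_m]
  fh[ls$state_hp] * fh[ls$state_hm]
}

# genotype -> unordered allele pair c(a, b) or NULL when missing.
# Biallelic markers accept alt dosage 0/1/2; the general encoding is
# "a/b" with 1-based allele numbers.
geno_pair <- function(g, k) {
  if (length(g) == 0L || is.na(g)) return(NULL)
  if (is.character(g)) {
    ab <- suppressWarnings(as.integer(strsplit(g, "/", fixed = TRUE)[[1]]))
    if (length(ab) != 2L || anyNA(ab)) return(NULL)
    return(sort(ab))
  }
  if (k != 2L)
    stop("dosage genotypes are only defined for biallelic markers")
  switch(as.character(g), `0` = c(1L, 1L), `1` = c(1L, 2L),
         `2` = c(2L, 2L), stop("invalid dosage: ", g))
}

state_unary <- function(affection, g, dm, ls) {
  f <- dm$penetrances
  pen <- switch(affection,
    affected = f[ls$state_ndisease + 1L],
    unaffected = if (dm$affecteds_only) rep(1, ls$ns)
                 else 1 - f[ls$state_ndisease + 1L],
    rep(1, ls$ns))
  pair <- geno_pair(g, ls$k)
  if (!is.null(pair))
    pen <- pen * (ls$state_ma == pair[1] & ls$state_mb == pair[2])
  pen
}

#' Pedigree likelihood at one marker
#'
#' Exact joint disease-marker likelihood of a pedigree's phenotypes and
#' marker genotypes: the sum over all two-locus diplotype assignments of
#' founder haplotype priors (linkage equilibrium), Mendelian
#' transmissions with recombination `mm$theta`, penetrance factors, and
#' marker-genotype compatibility. Evaluated exactly by Elston-Stewart
#' peeling along [peeling_order()]; genotype configurations impossible
#' under the pedigree give likelihood 0 (not an error).
#'
#' @param ped a [pedigree()] (loop-free).
#' @param geno named genotype vector by member id: alt dosage (0/1/2/NA)
#'   for biallelic markers, or `"a/b"` allele pairs for multi-allelic
#'   ones; members absent from `geno` are treated as untyped.
#' @param mm a [marker_model()].
#' @param dm a [disease_model()].
#' @return The likelihood (a probability).
#' @export
pedigree_likelihood <- function(ped, geno, mm, dm) {
  10^ped_loglik10(ped, geno, mm, dm, mm$theta)
}

# log10 likelihood; -Inf when impossible
ped_loglik10 <- function(ped, geno, mm, dm, theta,
                         tm = transmission_matrix(theta,
                                                  length(mm$freqs))) {
  ls <- locus_space(length(mm$freqs))
  prior <- founder_prior(dm, mm$freqs)
  founder <- is_founder(ped)
  unary <- lapply(seq_len(nrow(ped)), function(i) {
    g <- if (ped$id[i] %in% names(geno)) geno[[ped$id[i]]] else NA
    state_unary(ped$affection[i], g, dm, ls)
  })
  names(unary) <- ped$id
  founder_by_id <- stats::setNames(founder, ped$id)
  cliques <- peeling_order(ped)
  in_fam <- unique(unlist(lapply(cliques, function(f)
    c(f$father, f$mother, f$children))))
  log_acc <- 0
  for (cl in cliques) {
    uf <- unary[[cl$father]]
    um <- unary[[cl$mother]]
    wf <- if (founder_by_id[[cl$father]]) uf * prior else uf
    wm <- if (founder_by_id[[cl$mother]]) um * prior else um
    pivot <- cl$pivot
    elim_children <- setdiff(cl$children, pivot)
    A <- matrix(1, ls$ns, ls$ns)
    for (ch in elim_children) {
      uc <- matrix(unary[[ch]], ls$nh, ls$nh)
      A <- A * (tm %*% uc %*% t(tm))
    }
    if (is.null(pivot)) {
      contrib <- as.numeric(wf %*% A %*% wm)
      if (contrib <= 0) return(-Inf)
      log_acc <- log_acc + log10(contrib)
    } else if (identical(pivot, cl$father)) {
      r <- as.numeric(A %*% wm)
      mx <- max(r)
      if (mx <= 0) return(-Inf)
      log_acc <- log_acc + log10(mx)
      unary[[cl$father]] <- uf * (r / mx)
    } else if (identical(pivot, cl$mother)) {
      r <- as.numeric(crossprod(A, wf))
      mx <- max(r)
      if (mx <= 0) return(-Inf)
      log_acc <- log_acc + log10(mx)
      unary[[cl$mother]] <- um * (r / mx)
    } else {
      # pivot is a child of this clique
      B <- outer(wf, wm) * A
      r4 <- crossprod(tm, B) %*% tm   # [paternal hap, maternal hap]
      r <- as.numeric(t(r4))          # state order: hp slow, hm fast
      mx <- max(r)
      if (mx <= 0) return(-Inf)
      log_acc <- log_acc + log10(mx)
      unary[[pivot]] <- unary[[pivot]] * (r / mx)
    }
  }
  # individuals outside every nuclear family contribute independently
  for (id in setdiff(ped$id, in_fam)) {
    contrib <- sum(prior * unary[[id]])
    if (contrib <= 0) return(-Inf)
    log_acc <- log_acc + log10(contrib)
  }
  log_acc
}

#' Two-point parametric LOD scores
#'
#' For each recombination fraction in `theta_grid`, computes
#' lod(theta) = log10 L(theta) - log10 L(0.5), summed over families.
#' Genotype configurations impossible at a given theta (but possible at
#' 0.5) are reported with the finite sentinel -99 so tabular output stays
#' well-formed; families with no marker information score 0 everywhere.
#'
#' @param peds a [pedigree()] or list of pedigrees (independent
#'   families; LOD is additive).
#' @param genos named genotype vector covering all members, or a list of
#'   such vectors parallel to `peds`.
#' @param mm a [marker_model()] (its `theta` is ignored; the grid rules).
#' @param dm a [disease_model()].
#' @param theta_grid recombination fractions; 0.5 is appended if absent.
#' @return Object of class `linkage_result`: list with `theta`, `lod`
#'   (total per theta), `per_family` (families x theta matrix),
#'   `max_lod`, `families`.
#' @export
two_point_lod <- function(peds, genos, mm, dm,
                          theta_grid = c(0, 0.01, 0.05, 0.1, 0.2,
                                         0.3, 0.4, 0.5)) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  if (!is.list(genos)) genos <- list(genos)
  if (length(genos) == 1L && length(peds) > 1L)
    genos <- rep(genos, length(peds))
  theta_grid <- sort(unique(c(theta_grid, 0.5)))
  k <- length(mm$freqs)
  tms <- lapply(theta_grid, transmission_matrix, k = k)
  fam_ids <- vapply(peds, function(p) p$famid[1], "")
  per_family <- matrix(0, length(peds), length(theta_grid),
                       dimnames = list(fam_ids, format(theta_grid)))
  for (i in seq_along(peds)) {
    g <- genos[[i]]
    ll <- vapply(seq_along(theta_grid), function(j)
      ped_loglik10(peds[[i]], g, mm, dm, theta_grid[j], tms[[j]]),
      numeric(1))
    ll_half <- ll[theta_grid == 0.5]
    lods <- ll - ll_half
    lods[is.infinite(lods) & lods < 0] <- -99
    per_family[i, ] <- lods
  }
  total <- colSums(per_family)
  structure(list(theta = theta_grid, lod = total,
                 per_family = per_family,
                 max_lod = max(total), families = fam_ids),
            class = "linkage_result")
}

#' @exportS3Method base::print
print.linkage_result <- function(x, ...) {
  cat("Two-point LOD over", length(x$families), "family(ies); max LOD",
      format(x$max_lod, digits = 4), "\n")
  print(rbind(theta = x$theta, lod = round(x$lod, 4)))
  invisible(x)
}

#' Extract LOD-supported regions along a chromosome
#'
#' Maximal runs of consecutive, position-ordered markers whose maximum
#' LOD exceeds the threshold become regions. Bounds extend to the
#' flanking markers just outside the run (or the run's end markers at a
#' chromosome edge): between the last passing marker and the first
#' failing one the data cannot place the recombination breakpoint, so
#' the region of support conservatively reaches the excluded marker.
#'
#' @param marker_lods data frame with columns `chrom`, `pos`, `max_lod`
#'   and optionally `family` (rows = markers, ordered within chromosome).
#' @param threshold LOD bound, exclusive (default 2).
#' @return Data frame `chrom`, `start`, `end`, `max_lod`, `family`.
#' @export
lod_regions <- function(marker_lods, threshold = 2) {
  if (is.null(marker_lods$family)) marker_lods$family <- "combined"
  out <- data.frame(chrom = character(), start = numeric(),
                    end = numeric(), max_lod = numeric(),
                    family = character(), stringsAsFactors = FALSE)
  for (fam in unique(marker_lods$family)) {
    for (ch in unique(marker_lods$chrom[marker_lods$family == fam])) {
      sub <- marker_lods[marker_lods$family == fam &
                           marker_lods$chrom == ch, ]
      sub <- sub[order(sub$pos), ]
      pass <- sub$max_lod > threshold
      runs <- rle(pass)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (r in which(runs$values)) {
        i <- max(1L, starts[r] - 1L)        # flanking marker below
        j <- min(nrow(sub), ends[r] + 1L)   # flanking marker above
        out[nrow(out) + 1L, ] <- list(ch, sub$pos[i], sub$pos[j],
                                      max(sub$max_lod[starts[r]:ends[r]]),
                                      fam)
      }
    }
  }
  out
}

#' Genome-wide two-point scan
#'
#' Runs the two-point LOD computation at every marker of a panel for
#' each family and reports the per-marker maximum LOD over the theta
#' grid.
#'
#' @param peds list of [pedigree()] objects.
#' @param marker_gt genotype matrix, markers x samples (sample names are
#'   member ids): alt dosage for biallelic markers or `"a/b"` pairs for
#'   multi-allelic ones.
#' @param markers data frame with `chrom`, `pos`, and either `freq2`
#'   (frequency of the dosage-counted allele, biallelic) or `n_alleles`
#'   (equifrequent multi-allelic marker), rows parallel to `marker_gt`.
#' @param dm a [disease_model()].
#' @param theta_grid recombination fractions to profile.
#' @return Data frame `marker`, `chrom`, `pos`, `family`, `max_lod`.
#' @export
two_point_scan <- function(peds, marker_gt, markers, dm,
                           theta_grid = c(0, 0.01, 0.05, 0.1, 0.2, 0.5)) {
  theta_grid <- sort(unique(c(theta_grid, 0.5)))
  half_ix <- which(theta_grid == 0.5)
  tm_cache <- list()
  rows <- vector("list", nrow(marker_gt) * length(peds))
  n <- 0L
  for (r in seq_len(nrow(marker_gt))) {
    if (!is.null(markers$n_alleles) && !is.na(markers$n_alleles[r]) &&
        markers$n_alleles[r] > 2) {
      k <- as.integer(markers$n_alleles[r])
      freqs <- rep(1 / k, k)
    } else {
      f2 <- min(max(markers$freq2[r], 1e-6), 1 - 1e-6)
      k <- 2L
      freqs <- c(1 - f2, f2)
    }
    kk <- as.character(k)
    if (is.null(tm_cache[[kk]]))
      tm_cache[[kk]] <- lapply(theta_grid, transmission_matrix, k = k)
    mm <- marker_model(freqs, theta = 0)
    g <- marker_gt[r, ]
    for (i in seq_along(peds)) {
      gi <- g[intersect(names(g), peds[[i]]$id)]
      ll <- vapply(seq_along(theta_grid), function(j)
        ped_loglik10(peds[[i]], gi, mm, dm, theta_grid[j],
                     tm_cache[[kk]][[j]]),
        numeric(1))
      lods <- ll - ll[half_ix]
      lods[is.infinite(lods) & lods < 0] <- -99
      n <- n + 1L
      rows[[n]] <- data.frame(
        marker = r, chrom = markers$chrom[r], pos = markers$pos[r],
        family = peds[[i]]$famid[1], max_lod = max(lods),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows[seq_len(n)])
}

#' Estimate biallelic marker allele frequencies from founders
#'
#' Mean alt dosage over genotyped founders, divided by 2; flagged as
#' founder-estimated. Small-sample estimates are biased, so supplying
#' frequencies explicitly is preferred.
#'
#' @param peds list of pedigrees.
#' @param marker_gt dosage matrix, markers x samples.
#' @return Numeric vector of allele-2 frequencies with attribute
#'   `method = "founder_estimate"`.
#' @export
estimate_founder_freqs <- function(peds, marker_gt) {
  founder_ids <- unlist(lapply(peds, function(p) p$id[is_founder(p)]))
  cols <- intersect(colnames(marker_gt), founder_ids)
  if (!length(cols)) stop("no genotyped founders")
  est <- rowMeans(marker_gt[, cols, drop = FALSE], na.rm = TRUE) / 2
  est[is.nan(est)] <- 0.5
  attr(est, "method") <- "founder_estimate"
  est
}
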