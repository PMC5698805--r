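# shared fixtures and independent oracles for the test suite

# random loop-free pedigree with <= n_max members: grow by marrying a
# new founder spouse into the family and adding children, which can
# never create a marriage loop
random_pedigree <- function(n_max = 8L) {
  id <- c("p1", "p2", "p3")
  father <- c(NA, NA, "p1")
  mother <- c(NA, NA, "p2")
  sex <- c("male", "female", sample(c("male", "female"), 1))
  while (length(id) + 2L <= n_max && stats::runif(1) < 0.8) {
    # marry a new founder to a random member, give the couple children
    mate <- sample(id, 1)
    mate_sex <- sex[id == mate]
    if (mate_sex == "unknown") next
    spouse <- paste0("p", length(id) + 1L)
    id <- c(id, spouse)
    father <- c(father, NA)
    mother <- c(mother, NA)
    sex <- c(sex, if (mate_sex == "male") "female" else "male")
    n_kids <- min(sample(1:2, 1), n_max - length(id))
    for (k in seq_len(n_kids)) {
      kid <- paste0("p", length(id) + 1L)
      id <- c(id, kid)
      father <- c(father, if (mate_sex == "male") mate else spouse)
      mother <- c(mother, if (mate_sex == "male") spouse else mate)
      sex <- c(sex, sample(c("male", "female"), 1))
    }
  }
  pedigree("rf", id = id, father = father, mother = mother, sex = sex,
           affection = sample(c("affected", "unaffected", "unknown"),
                              length(id), replace = TRUE,
                              prob = c(0.4, 0.4, 0.2)))
}

random_genotypes <- function(ped, missing_rate = 0.15) {
  g <- sample(0:2, nrow(ped), replace = TRUE, prob = c(0.35, 0.4, 0.25))
  g[stats::runif(nrow(ped)) < missing_rate] <- NA
  stats::setNames(g, ped$id)
}

# Wright's path-counting kinship: sum over common ancestors C and pairs
# of ancestor paths meeting only at C of (1/2)^(n1+n2+1) * (1 + f_C)
path_kinship <- function(ped, a, b) {
  fa <- stats::setNames(ped$father, ped$id)
  mo <- stats::setNames(ped$mother, ped$id)
  paths_up <- function(x) {
    # all node paths from x up to each ancestor (including the trivial path)
    out <- list(c(x))
    if (!is.na(fa[[x]]))
      for (p in c(paths_up(fa[[x]]), paths_up(mo[[x]])))
        out[[length(out) + 1L]] <- c(x, p)
    out
  }
  inbreeding <- function(x) {
    if (is.na(fa[[x]])) return(0)
    path_kinship(ped, fa[[x]], mo[[x]])
  }
  if (a == b) return(0.5 * (1 + inbreeding(a)))
  pa <- paths_up(a)
  pb <- paths_up(b)
  total <- 0
  for (p1 in pa) for (p2 in pb) {
    C <- p1[length(p1)]
    if (C != p2[length(p2)]) next
    if (length(intersect(p1[-length(p1)], p2[-length(p2)]))) next
    total <- total +
      0.5^(length(p1) - 1 + length(p2) - 1 + 1) * (1 + inbreeding(C))
  }
  total
}

# brute-force sliding-window IBD positivity (independent of the package's
# vectorized implementation)
brute_ibd_positive <- function(shared, w, threshold) {
  n <- length(shared)
  if (w > n) w <- n
  pos <- logical(n)
  for (i in seq_len(n)) {
    for (s in max(1L, i - w + 1L):min(i, n - w + 1L)) {
      if (mean(shared[s:(s + w - 1L)]) > threshold) {
        pos[i] <- TRUE
        break
      }
    }
  }
  pos
}

brute_ibd_segments <- function(positions, shared, w = 10L, threshold = 0.5) {
  pos <- brute_ibd_positive(shared, w, threshold)
  runs <- rle(pos)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  data.frame(start_pos = positions[starts[runs$values]],
             end_pos = positions[ends[runs$values]])
}

# independent re-implementation of parsimony allele trimming for the
# normalization cross-check
trim_oracle <- function(pos, ref, alt) {
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) ==
           substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

random_indel <- function() {
  bases <- c("A", "C", "G", "T")
  core <- paste(sample(bases, sample(1:4, 1), TRUE), collapse = "")
  ins <- paste(sample(bases, sample(1:4, 1), TRUE), collapse = "")
  pre <- paste(sample(bases, sample(0:3, 1), TRUE), collapse = "")
  post <- paste(sample(bases, sample(0:3, 1), TRUE), collapse = "")
  if (stats::runif(1) < 0.5)
    list(ref = paste0(pre, core, ins, post), alt = paste0(pre, core, post))
  else
    list(ref = paste0(pre, core, post), alt = paste0(pre, core, ins, post))
}

trio_ped <- function(affection = c("affected", "unaffected", "affected")) {
  pedigree("trio", id = c("fa", "mo", "ch"),
           father = c(NA, NA, "fa"), mother = c(NA, NA, "mo"),
           sex = c("male", "female", "female"), affection = affection)
}
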