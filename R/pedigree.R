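#' Construct a pedigree
#'
#' A pedigree holds one family's members with parental links, sex,
#' affection status and sequencing/genotyping flags. Founders have both
#' parent ids absent; non-founders must have both present.
#'
#' @param famid family identifier (length-1 character).
#' @param id character vector of unique member ids.
#' @param father,mother character vectors of parent ids; `NA` or `"0"`
#'   marks an unknown parent. Either both parents are known or both
#'   unknown.
#' @param sex one of `"male"`, `"female"`, `"unknown"` per member (also
#'   accepts PLINK codes 1/2/0).
#' @param affection one of `"affected"`, `"unaffected"`, `"unknown"` per
#'   member (also accepts PLINK codes 2/1/0/-9).
#' @param sequenced,genotyped logical flags per member.
#' @return An object of class `pedigree`: a data frame with one row per
#'   member.
#' @examples
#' trio <- pedigree("fam1",
#'   id = c("dad", "mom", "kid"),
#'   father = c(NA, NA, "dad"), mother = c(NA, NA, "mom"),
#'   sex = c("male", "female", "female"),
#'   affection = c("affected", "unaffected", "affected"))
#' n_founders(trio)
#' @export
pedigree <- function(famid, id, father, mother,
                     sex = "unknown", affection = "unknown",
                     sequenced = TRUE, genotyped = TRUE) {
  n <- length(id)
  id <- as.character(id)
  if (anyDuplicated(id))
    stop("duplicated individual id within family '", famid, "': ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  father <- norm_parent(father, n)
  mother <- norm_parent(mother, n)
  sex <- norm_sex(rep_len(sex, n))
  affection <- norm_affection(rep_len(affection, n))
  ped <- data.frame(
    famid = as.character(famid), id = id,
    father = father, mother = mother,
    sex = sex, affection = affection,
    sequenced = rep_len(as.logical(sequenced), n),
    genotyped = rep_len(as.logical(genotyped), n),
    stringsAsFactors = FALSE
  )
  class(ped) <- c("pedigree", "data.frame")
  bad <- xor(is.na(ped$father), is.na(ped$mother))
  if (any(bad))
    stop("individuals with exactly one known parent: ",
         paste(ped$id[bad], collapse = ", "))
  for (p in c("father", "mother")) {
    ref <- ped[[p]][!is.na(ped[[p]])]
    missing_ref <- setdiff(ref, ped$id)
    if (length(missing_ref))
      stop(p, " id referenced but absent: ",
           paste(missing_ref, collapse = ", "))
  }
  self <- !is.na(ped$father) & (ped$father == ped$id | ped$mother == ped$id)
  if (any(self))
    stop("individual listed as its own parent: ",
         paste(ped$id[self], collapse = ", "))
  if (is.null(ped_depth(ped)))
    stop("pedigree contains a parental cycle in family '", famid, "'")
  ped
}

norm_parent <- function(x, n) {
  x <- as.character(rep_len(x, n))
  x[!is.na(x) & (x == "0" | x == "")] <- NA_character_
  x
}

norm_sex <- function(x) {
  x <- as.character(x)
  map <- c("1" = "male", "2" = "female", "0" = "unknown",
           male = "male", female = "female", unknown = "unknown")
  out <- unname(map[x])
  if (anyNA(out)) stop("invalid sex code: ", paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

norm_affection <- function(x) {
  x <- as.character(x)
  map <- c("2" = "affected", "1" = "unaffected", "0" = "unknown",
           "-9" = "unknown", affected = "affected",
           unaffected = "unaffected", unknown = "unknown")
  out <- unname(map[x])
  if (anyNA(out)) stop("invalid affection code: ", paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' @exportS3Method base::print
print.pedigree <- function(x, ...) {
  cat("Pedigree '", x$famid[1], "': ", nrow(x), " members (",
      sum(is_founder(x)), " founders, ",
      sum(x$affection == "affected"), " affected)\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Founder indicator
#' @param ped a [pedigree()].
#' @return Logical vector, `TRUE` where both parents are unknown.
#' @export
is_founder <- function(ped) is.na(ped$father) & is.na(ped$mother)

#' Number of founders
#' @param ped a [pedigree()].
#' @export
n_founders <- function(ped) sum(is_founder(ped))

# Generation depth per member (founders 0); NULL if the parent graph is
# cyclic. Used both for cycle detection and to orient the kinship
# recursion.
ped_depth <- function(ped) {
  n <- nrow(ped)
  depth <- ifelse(is_founder(ped), 0L, NA_integer_)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  for (iter in seq_len(n + 1L)) {
    todo <- which(is.na(depth))
    if (!length(todo)) return(stats::setNames(depth, ped$id))
    progressed <- FALSE
    for (i in todo) {
      df <- depth[fi[i]]; dm <- depth[mi[i]]
      if (!is.na(df) && !is.na(dm)) {
        depth[i] <- max(df, dm) + 1L
        progressed <- TRUE
      }
    }
    if (!progressed) return(NULL)
  }
  NULL
}

#' Validate a pedigree
#'
#' Checks the structural rules that the stricter [pedigree()] constructor
#' enforces, but returns violations as data rather than raising errors,
#' mirroring array-QC practice where inconsistencies are reported and
#' reviewed. Rules: parent references resolve; no parental cycles; each
#' referenced father is male or unknown sex and each mother female or
#' unknown; one-known-parent individuals.
#'
#' @param ped a `pedigree` (or pedigree-shaped data frame).
#' @return Data frame with columns `id` and `rule` (empty when valid).
#' @export
validate_pedigree <- function(ped) {
  v <- list()
  add <- function(id, rule) v[[length(v) + 1L]] <<- data.frame(
    id = id, rule = rule, stringsAsFactors = FALSE)
  half <- xor(is.na(ped$father), is.na(ped$mother))
  for (i in which(half)) add(ped$id[i], "single_known_parent")
  for (p in c("father", "mother")) {
    ref <- ped[[p]]
    bad <- !is.na(ref) & !(ref %in% ped$id)
    for (i in which(bad)) add(ped$id[i], paste0("unresolved_", p))
    self <- !is.na(ref) & ref == ped$id
    for (i in which(self)) add(ped$id[i], "own_parent")
  }
  fathers <- unique(stats::na.omit(ped$father[ped$father %in% ped$id]))
  for (f in fathers)
    if (ped$sex[ped$id == f] == "female") add(f, "father_coded_female")
  mothers <- unique(stats::na.omit(ped$mother[ped$mother %in% ped$id]))
  for (m in mothers)
    if (ped$sex[ped$id == m] == "male") add(m, "mother_coded_male")
  # cycle check only meaningful once references resolve
  if (!length(v) || !any(grepl("unresolved|own_parent", vapply(v, `[[`, "", "rule")))) {
    if (is.null(ped_depth(ped))) {
      cyc <- ped$id[cycle_members(ped)]
      for (i in cyc) add(i, "ancestor_cycle")
    }
  }
  if (!length(v))
    return(data.frame(id = character(), rule = character(), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

cycle_members <- function(ped) {
  # members whose depth cannot be resolved participate in (or descend
  # from) a cycle; report the minimal unresolved set
  n <- nrow(ped)
  depth <- ifelse(is_founder(ped), 0L, NA_integer_)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  repeat {
    progressed <- FALSE
    for (i in which(is.na(depth))) {
      if (!is.na(depth[fi[i]]) && !is.na(depth[mi[i]])) {
        depth[i] <- max(depth[fi[i]], depth[mi[i]]) + 1L
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  is.na(depth)
}

#' Kinship coefficient
#'
#' Probability that one allele sampled at random from `a` and one from `b`
#' are identical by descent, by the standard recursion over parents
#' (founders unrelated and non-inbred).
#'
#' @param ped a [pedigree()].
#' @param a,b member ids.
#' @return Numeric kinship coefficient; e.g. 0.25 for parent-offspring or
#'   full sibs, 0.0625 for first cousins, 0.5 for a non-inbred individual
#'   with itself.
#' @export
kinship <- function(ped, a, b) {
  if (!a %in% ped$id) stop("unknown id: ", a)
  if (!b %in% ped$id) stop("unknown id: ", b)
  depth <- ped_depth(ped)
  if (is.null(depth)) stop("pedigree contains a parental cycle")
  fa <- stats::setNames(ped$father, ped$id)
  mo <- stats::setNames(ped$mother, ped$id)
  memo <- new.env(parent = emptyenv())
  phi <- function(x, y) {
    if (x > y) { tmp <- x; x <- y; y <- tmp }
    key <- paste(x, y, sep = "\r")
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (x == y) {
      if (is.na(fa[[x]])) 0.5 else 0.5 * (1 + phi(fa[[x]], mo[[x]]))
    } else {
      # recurse on the deeper member so we never step past a common
      # ancestor; ties broken arbitrarily (result is symmetric)
      deep <- if (depth[[x]] >= depth[[y]]) x else y
      other <- if (identical(deep, x)) y else x
      if (is.na(fa[[deep]])) 0
      else 0.5 * (phi(fa[[deep]], other) + phi(mo[[deep]], other))
    }
    memo[[key]] <- val
    val
  }
  phi(as.character(a), as.character(b))
}

#' Pairwise kinship matrix
#' @param ped a [pedigree()].
#' @return Symmetric matrix of kinship coefficients over all members.
#' @export
kinship_matrix <- function(ped) {
  ids <- ped$id
  k <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids))
    for (j in i:length(ids))
      k[i, j] <- k[j, i] <- kinship(ped, ids[i], ids[j])
  k
}

#' Mendelian inconsistencies at a biallelic autosomal site
#'
#' A child is flagged when its non-missing genotype is impossible given
#' both parents' non-missing genotypes, i.e. no choice of one transmitted
#' allele per parent reproduces the child's allele count.
#'
#' @param ped a [pedigree()].
#' @param geno named integer vector of alt-allele dosages (0/1/2, `NA`
#'   missing) indexed by member id.
#' @return Character vector of inconsistent child ids (possibly empty).
#' @export
mendelian_inconsistencies <- function(ped, geno) {
  transmissible <- list(`0` = 0L, `1` = 0:1, `2` = 1L)
  out <- character()
  for (i in which(!is_founder(ped))) {
    gc <- geno[[ped$id[i]]]
    gf <- geno[[ped$father[i]]]
    gm <- geno[[ped$mother[i]]]
    if (is.na(gc) || is.na(gf) || is.na(gm)) next
    possible <- outer(transmissible[[as.character(gf)]],
                      transmissible[[as.character(gm)]], `+`)
    if (!(gc %in% possible)) out <- c(out, ped$id[i])
  }
  out
}

# ---- nuclear families and peeling order --------------------------------

#' Nuclear families of a pedigree
#' @param ped a [pedigree()].
#' @return List of `list(father, mother, children)`, one per parental
#'   couple.
#' @keywords internal
nuclear_families <- function(ped) {
  kids <- which(!is_founder(ped))
  if (!length(kids)) return(list())
  couple <- paste(ped$father[kids], ped$mother[kids], sep = "\r")
  lapply(split(kids, couple), function(ix) {
    list(father = ped$father[ix[1]], mother = ped$mother[ix[1]],
         children = ped$id[ix])
  })
}

#' Peeling order over nuclear-family cliques
#'
#' Orders the nuclear families so that each, when processed, shares at
#' most one member (the pivot) with the still-unprocessed remainder of the
#' pedigree. Eliminating each clique's non-pivot members in this order is
#' the Elston-Stewart strategy used by [pedigree_likelihood()]. Pedigrees
#' whose nuclear families interlock through more than one member (marriage
#' loops) are rejected.
#'
#' @param ped a [pedigree()].
#' @return List of cliques `list(father, mother, children, pivot)` in
#'   elimination order; the final clique has `pivot = NULL`. An empty list
#'   for a pedigree with no parent-child links.
#' @export
peeling_order <- function(ped) {
  fams <- nuclear_families(ped)
  if (!length(fams)) return(list())
  members <- lapply(fams, function(f) c(f$father, f$mother, f$children))
  remaining <- rep(TRUE, length(fams))
  order_out <- list()
  while (any(remaining)) {
    open <- which(remaining)
    if (length(open) == 1L) {
      f <- fams[[open]]
      f$pivot <- NULL
      order_out[[length(order_out) + 1L]] <- f
      remaining[open] <- FALSE
      break
    }
    placed <- FALSE
    for (k in open) {
      others <- unique(unlist(members[setdiff(open, k)]))
      connectors <- intersect(members[[k]], others)
      if (length(connectors) <= 1L) {
        f <- fams[[k]]
        f$pivot <- if (length(connectors)) connectors else NULL
        order_out[[length(order_out) + 1L]] <- f
        remaining[k] <- FALSE
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("pedigree contains a marriage loop; peeling unsupported")
  }
  order_out
}
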