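# Classical pedigree statistics: kinship/inbreeding by the tabular method
# (dense, computed on the ancestor closure of the animals of interest),
# average additive relationship, and the five-generation pedigree
# completeness index.

# Kinship matrix for a set of ids, computed on their ancestor closure.
closure_kinship <- function(ped, ids) {
  closure <- ancestors_of(ped, ids, include_self = TRUE)
  idx <- ped_index(ped, closure)
  # restrict to closure, keep topological order
  sub <- idx[order(match(idx, ped$topo))]
  pos <- integer(n_animals(ped))
  pos[sub] <- seq_along(sub)
  par0 <- function(p) {
    p <- p[sub]
    ifelse(is.na(p), 0L, pos[p])
  }
  K <- kinship_dense_cpp(par0(ped$sire_idx), par0(ped$dam_idx))
  dimnames(K) <- list(ped$records$animal[sub], ped$records$animal[sub])
  K
}

#' Kinship (coancestry) matrix
#'
#' Pairwise kinship coefficients f(i, j): the probability that one allele
#' sampled from i and one from j are identical by descent. Computed by the
#' tabular relationship method on the ancestor closure of `ids`; unknown
#' ancestors are treated as unrelated founders. The additive relationship is
#' `2 * kinship`.
#'
#' @param ped A `Pedigree`.
#' @param ids Animal ids (default: all animals).
#' @return A symmetric numeric matrix with `ids` as dimnames;
#'   `diag = 0.5 * (1 + F)`.
#' @export
kinship_matrix <- function(ped, ids = NULL) {
  if (is.null(ids)) ids <- ped_ids(ped)
  K <- closure_kinship(ped, ids)
  K[ids, ids, drop = FALSE]
}

#' Inbreeding coefficients
#'
#' F(x) is the kinship of x's parents: the probability that x's two alleles at
#' a locus are identical by descent. Founders, and any animal with an unknown
#' parent, have F = 0 (unknown ancestors are assumed unrelated).
#'
#' @param ped A `Pedigree`.
#' @return Named numeric vector of F in record order.
#' @export
inbreeding <- function(ped) {
  K <- closure_kinship(ped, ped_ids(ped))
  f <- 2 * diag(K) - 1
  setNames(f[ped_ids(ped)], ped_ids(ped))
}

#' Average additive relationship within a group
#'
#' Mean of the additive relationship a_ij = 2 * kinship(i, j) over all
#' unordered pairs i != j of `members` (self-pairs excluded).
#'
#' @param ped A `Pedigree`.
#' @param members At least two animal ids.
#' @return A single numeric value.
#' @export
average_relationship <- function(ped, members) {
  members <- unique(members)
  if (length(members) < 2) {
    stop("average_relationship needs at least 2 distinct members")
  }
  K <- kinship_matrix(ped, members)
  A <- 2 * K
  mean(A[upper.tri(A)])
}

# Per-generation proportions of known ancestors along one parent line.
line_completeness <- function(ped, parent_idx, depth) {
  g <- numeric(depth)
  frontier <- parent_idx
  for (i in seq_len(depth)) {
    g[i] <- sum(!is.na(frontier)) / 2^(i - 1)
    if (i < depth) {
      nxt <- rbind(ped$sire_idx[frontier], ped$dam_idx[frontier])
      frontier <- as.integer(nxt)
    }
  }
  mean(g)
}

#' Pedigree completeness index
#'
#' MacCluer-type index over `depth` generations: for each parental line,
#' C_line is the mean over generations i = 1..depth of the proportion of the
#' 2^(i-1) ancestor slots of that line that are filled; the index is the
#' harmonic mean of the paternal and maternal line values,
#' `PCI = 2 * C_pat * C_mat / (C_pat + C_mat)`. It is 1 when all ancestors up
#' to `depth` generations are known and 0 when either parent is unknown.
#'
#' @param ped A `Pedigree`.
#' @param animals Animal ids (default: all).
#' @param depth Number of generations (default 5).
#' @return Named numeric vector of indices in `[0, 1]`.
#' @export
pci <- function(ped, animals = NULL, depth = 5L) {
  if (depth < 1) stop("depth must be >= 1")
  if (is.null(animals)) animals <- ped_ids(ped)
  idx <- ped_index(ped, animals)
  out <- vapply(idx, function(i) {
    cp <- if (is.na(ped$sire_idx[i])) 0 else
      line_completeness(ped, ped$sire_idx[i], depth)
    cm <- if (is.na(ped$dam_idx[i])) 0 else
      line_completeness(ped, ped$dam_idx[i], depth)
    if (cp + cm == 0) 0 else 2 * cp * cm / (cp + cm)
  }, numeric(1))
  setNames(out, animals)
}
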