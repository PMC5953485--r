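# Probabilities of gene origin: raw genetic contributions of individuals to a
# reference cohort and the iterative marginal decomposition with
# pseudo-founder pruning.
#
# The raw contribution q_k of ancestor k to a cohort is the expected
# proportion of the cohort's gene pool inherited from k: the mean over cohort
# members j of c(k -> j), where c halves along each parent link and
# terminates at k. The marginal contribution p_k is the part of q_k not
# already explained by previously selected ancestors: at each round the
# candidate raw contributions are computed in the pruned pedigree, adjusted by
# p_k = q_k * (1 - sum(a_i)) for the contributions a_i of the already selected
# ancestors to candidate k, and the largest-p candidate is selected and made a
# pseudo-founder. The resulting marginals are orthogonal (no double counting)
# and sum to 1 when all founders are known.

#' Raw genetic contribution of an ancestor to a cohort
#'
#' Expected proportion of the cohort members' genomes inherited from
#' `ancestor`: the mean over members j of c(ancestor -> j), with
#' c(k -> k) = 1, c(k -> j) = 0.5 c(k -> sire(j)) + 0.5 c(k -> dam(j)), and 0
#' through unknown parents.
#'
#' @param ped A `Pedigree`.
#' @param ancestor A single animal id.
#' @param cohort Non-empty vector of member ids.
#' @return Numeric in `[0, 1]`.
#' @export
raw_contribution <- function(ped, ancestor, cohort) {
  if (!length(cohort)) stop("cohort is empty")
  arr <- ped_topo_arrays(ped)
  src <- match(ancestor, arr$ids)
  if (is.na(src)) stop("unknown ancestor id: ", ancestor)
  memb <- match(cohort, arr$ids)
  if (anyNA(memb)) {
    stop("unknown cohort member id(s): ",
         paste(cohort[is.na(memb)], collapse = ", "))
  }
  M <- contrib_forward_cpp(arr$sire, arr$dam, src)
  mean(M[1, memb])
}

#' Stopping rule for the marginal decomposition
#'
#' @param cumulative Stop once the cumulative explained proportion of the gene
#'   pool reaches this value (in `(0, 1]`; default 0.99, mirroring reporting
#'   of the ancestors that explain 99% of a cohort's genetic variability).
#' @param max_ancestors Stop after this many ancestors (default unlimited).
#' @return A list with class `decomposition_stop`.
#' @export
decomposition_stop <- function(cumulative = 0.99, max_ancestors = Inf) {
  if (!is.numeric(cumulative) || length(cumulative) != 1 ||
      cumulative <= 0 || cumulative > 1) {
    stop("cumulative stop threshold must be in (0, 1]")
  }
  if (!is.numeric(max_ancestors) || length(max_ancestors) != 1 ||
      max_ancestors < 1) {
    stop("max_ancestors must be >= 1")
  }
  structure(list(cumulative = cumulative, max_ancestors = max_ancestors),
            class = "decomposition_stop")
}

#' Marginal decomposition of a cohort's gene pool
#'
#' Iterative selection of the highest-contributing ancestors ("probabilities
#' of gene origin"). At each round, every individual that is an ancestor of at
#' least one cohort member in the current (pruned) pedigree -- excluding
#' cohort members themselves and previously selected ancestors -- is a
#' candidate; its raw contribution q_k is computed in the current pedigree,
#' adjusted for already-selected ancestors via `p_k = q_k * (1 - sum(a_i))`
#' (a_i = raw contribution of selected ancestor i to candidate k, in the
#' current pedigree state), and the candidate with the largest marginal p_k is
#' selected and turned into a pseudo-founder. Ties are broken by earlier
#' birth year, then lexicographic id, making runs reproducible. Selection
#' stops at the `stop` rule, at candidate exhaustion, or when no remaining
#' candidate has a positive marginal.
#'
#' @param ped A `Pedigree`.
#' @param cohort Non-empty vector of member ids (the reference population).
#' @param stop A [decomposition_stop()] rule.
#' @param label Optional cohort label carried into the result.
#' @return An object of class `MarginalDecomposition`: list with `entries`
#'   (data frame `ancestor`, `q`, `p`, `cumulative`, ordered by selection
#'   round), `explained` (sum of marginals) and `label`.
#' @export
marginal_decomposition <- function(ped, cohort,
                                   stop = decomposition_stop(),
                                   label = NULL) {
  if (!inherits(stop, "decomposition_stop")) {
    stop <- do.call(decomposition_stop, as.list(stop))
  }
  if (!length(cohort)) base::stop("cohort is empty")
  arr <- ped_topo_arrays(ped)
  memb <- match(unique(cohort), arr$ids)
  if (anyNA(memb)) {
    base::stop("unknown cohort member id(s): ",
               paste(unique(cohort)[is.na(memb)], collapse = ", "))
  }
  n <- length(arr$ids)
  w <- numeric(n)
  w[memb] <- 1 / length(memb)
  sire <- arr$sire
  dam <- arr$dam
  is_member <- logical(n)
  is_member[memb] <- TRUE
  selected <- integer(0)

  anc <- character(0)
  qs <- numeric(0)
  ps <- numeric(0)
  cum <- 0
  repeat {
    q <- contrib_backward_cpp(sire, dam, w)
    cand <- which(q > .eps_zero & !is_member)
    cand <- setdiff(cand, selected)
    if (!length(cand)) break
    if (length(selected)) {
      M <- contrib_forward_cpp(sire, dam, selected)
      a_sum <- colSums(M)[cand]
    } else {
      a_sum <- numeric(length(cand))
    }
    p <- q[cand] * pmax(0, 1 - a_sum)
    pmax_val <- max(p)
    if (pmax_val <= .eps_zero) break
    tied <- cand[p >= pmax_val - .eps_tie]
    by <- arr$birth_year[tied]
    by[is.na(by)] <- .Machine$integer.max
    best <- tied[order(by, arr$ids[tied])][1]
    p_best <- p[match(best, cand)]
    q_best <- q[best]

    anc <- c(anc, arr$ids[best])
    qs <- c(qs, q_best)
    ps <- c(ps, p_best)
    cum <- cum + p_best
    selected <- c(selected, best)
    sire[best] <- 0L
    dam[best] <- 0L
    if (length(anc) >= stop$max_ancestors) break
    if (cum >= stop$cumulative - .eps_tie) break
  }

  entries <- data.frame(ancestor = anc, q = qs, p = ps,
                        cumulative = cumsum(ps), stringsAsFactors = FALSE)
  structure(list(entries = entries, explained = cum, label = label,
                 stop = stop, n_cohort = length(memb)),
            class = "MarginalDecomposition")
}

#' @export
print.MarginalDecomposition <- function(x, ...) {
  cat(sprintf("Marginal decomposition%s: %d ancestors explain %.1f%% of the gene pool\n",
              if (is.null(x$label)) "" else paste0(" of ", x$label),
              nrow(x$entries), 100 * x$explained))
  print(utils::head(x$entries, 10L))
  if (nrow(x$entries) > 10L) cat("...\n")
  invisible(x)
}

#' Gene-pool coverage counts
#'
#' For each threshold, the minimal number of top marginal contributors whose
#' cumulative contribution reaches that share of the cohort's gene pool.
#' Thresholds that the decomposition does not reach (e.g. because unknown
#' ancestors prevent explaining 100% of the pool) are flagged unreachable.
#'
#' @param dec A `MarginalDecomposition`.
#' @param thresholds Proportions in `(0, 1]` (default 0.50, 0.75, 0.99).
#' @return Data frame with columns `threshold`, `n_ancestors` (NA when
#'   unreachable) and `reached`; the largest single marginal contribution is
#'   attached as attribute `largest_marginal`.
#' @export
pool_coverage <- function(dec, thresholds = c(0.50, 0.75, 0.99)) {
  stopifnot(inherits(dec, "MarginalDecomposition"))
  if (!nrow(dec$entries)) stop("empty decomposition")
  if (any(thresholds <= 0 | thresholds > 1)) {
    stop("thresholds must lie in (0, 1]")
  }
  cum <- dec$entries$cumulative
  n_anc <- vapply(thresholds, function(tau) {
    k <- match(TRUE, cum >= tau - .eps_tie)
    if (is.na(k)) NA_integer_ else as.integer(k)
  }, integer(1))
  out <- data.frame(threshold = thresholds, n_ancestors = n_anc,
                    reached = !is.na(n_anc))
  attr(out, "largest_marginal") <- max(dec$entries$p)
  out
}

#' Ancestor-by-cohort matrix of marginal contributions
#'
#' Runs [marginal_decomposition()] for each cohort and assembles the results
#' into an ancestor x cohort matrix. Cells of ancestors not selected for a
#' cohort are missing (`NA`), which is distinct from a selected ancestor with
#' a zero marginal; per-ancestor row averages are taken over non-missing cells
#' only. An empty cohort yields an all-missing column.
#'
#' @param ped A `Pedigree`.
#' @param cohorts List of `Cohort` objects (one group) sharing a window axis.
#' @param stop A [decomposition_stop()] rule applied to every cohort.
#' @param keep_decompositions Attach the per-cohort `MarginalDecomposition`
#'   objects (needed for [pool_coverage()] summaries).
#' @return Object of class `ContributionMatrix`: list with `values` (numeric
#'   matrix, rows = ancestors sorted by row average descending, columns =
#'   cohort window labels), `windows` (data frame `label`, `year_start`,
#'   `year_end`) and `group`.
#' @export
contribution_matrix <- function(ped, cohorts, stop = decomposition_stop(),
                                keep_decompositions = FALSE) {
  stopifnot(length(cohorts) > 0)
  groups <- unique(vapply(cohorts, function(co) co$group, character(1)))
  if (length(groups) != 1) {
    stop("cohorts must all belong to one group (affected or control)")
  }
  windows <- data.frame(
    label = vapply(cohorts, function(co) co$label, character(1)),
    year_start = vapply(cohorts, function(co) co$year_start, numeric(1)),
    year_end = vapply(cohorts, function(co) co$year_end, numeric(1)),
    stringsAsFactors = FALSE)
  decs <- lapply(cohorts, function(co) {
    if (!length(co$members)) return(NULL)
    marginal_decomposition(ped, co$members, stop = stop, label = co$label)
  })
  anc <- unique(unlist(lapply(decs, function(d) {
    if (is.null(d)) character(0) else d$entries$ancestor
  })))
  values <- matrix(NA_real_, nrow = length(anc), ncol = length(cohorts),
                   dimnames = list(anc, windows$label))
  for (j in seq_along(decs)) {
    d <- decs[[j]]
    if (is.null(d)) next
    values[d$entries$ancestor, j] <- d$entries$p
  }
  if (length(anc) > 1) {
    ord <- order(-rowMeans(values, na.rm = TRUE), rownames(values))
    values <- values[ord, , drop = FALSE]
  }
  out <- structure(list(values = values, windows = windows,
                        group = tolower(groups)),
                   class = "ContributionMatrix")
  if (keep_decompositions) out$decompositions <- decs
  out
}

#' Assemble a ContributionMatrix from a value matrix
#'
#' Constructor used for externally supplied contribution tables (e.g. the
#' packaged published tables) and for tests.
#'
#' @param values Numeric matrix, rows = ancestors, columns = windows; `NA`
#'   marks an ancestor not selected for that cohort.
#' @param windows Data frame with `label`, `year_start`, `year_end` matching
#'   the columns of `values`.
#' @param group `"affected"` or `"control"`.
#' @return A `ContributionMatrix`.
#' @export
contribution_matrix_values <- function(values, windows, group) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            nrow(windows) == ncol(values),
            all(c("label", "year_start", "year_end") %in% names(windows)))
  colnames(values) <- windows$label
  structure(list(values = values, windows = windows, group = tolower(group)),
            class = "ContributionMatrix")
}

#' Per-ancestor row averages of a contribution matrix
#'
#' Mean marginal contribution over the cohorts in which the ancestor was
#' selected (non-missing cells only), as in the published tables' "Ave."
#' column.
#'
#' @param m A `ContributionMatrix`.
#' @return Named numeric vector.
#' @export
row_averages <- function(m) {
  stopifnot(inherits(m, "ContributionMatrix"))
  rowMeans(m$values, na.rm = TRUE)
}

#' @export
print.ContributionMatrix <- function(x, ...) {
  cat(sprintf("ContributionMatrix (%s): %d ancestors x %d cohorts [%s .. %s]\n",
              x$group, nrow(x$values), ncol(x$values),
              x$windows$label[1], x$windows$label[nrow(x$windows)]))
  invisible(x)
}
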