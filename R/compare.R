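# Case-control comparison of marginal ancestral contributions: selection of
# high-contributing ancestors, paired two-tailed t-tests across the cohort
# windows, and Benjamini-Hochberg false-discovery-rate control.

#' Ancestor selection rule
#'
#' An ancestor is tested when, in either the affected or the control
#' contribution matrix, its average non-missing marginal contribution is at
#' least `min_avg_contribution` and it was selected in at least
#' `min_nonoverlapping_cohorts` cohorts whose birth-year windows are pairwise
#' disjoint (e.g. 93/95 and 96/98 are disjoint; 93/95 and 94/96 are not).
#'
#' @param min_avg_contribution Minimal average contribution (default 0.005,
#'   i.e. 0.5%).
#' @param min_nonoverlapping_cohorts Minimal number of pairwise disjoint
#'   cohort windows (default 2).
#' @return A list of class `selection_rule`.
#' @export
selection_rule <- function(min_avg_contribution = 0.005,
                           min_nonoverlapping_cohorts = 2L) {
  stopifnot(min_avg_contribution > 0, min_avg_contribution < 1,
            min_nonoverlapping_cohorts >= 1)
  structure(list(min_avg_contribution = min_avg_contribution,
                 min_nonoverlapping_cohorts = as.integer(min_nonoverlapping_cohorts)),
            class = "selection_rule")
}

# Size of a maximal set of pairwise disjoint windows among `which_cells`
# (interval scheduling: greedy by earliest end year).
max_disjoint_windows <- function(windows, which_cells) {
  w <- windows[which_cells, , drop = FALSE]
  if (!nrow(w)) return(0L)
  w <- w[order(w$year_end, w$year_start), , drop = FALSE]
  count <- 0L
  last_end <- -Inf
  for (i in seq_len(nrow(w))) {
    if (w$year_start[i] > last_end) {
      count <- count + 1L
      last_end <- w$year_end[i]
    }
  }
  count
}

check_same_windows <- function(mA, mC) {
  stopifnot(inherits(mA, "ContributionMatrix"),
            inherits(mC, "ContributionMatrix"))
  # labels carry the group initial (A93/95 vs C93/95): compare years only
  if (!identical(as.numeric(mA$windows$year_start),
                 as.numeric(mC$windows$year_start)) ||
      !identical(as.numeric(mA$windows$year_end),
                 as.numeric(mC$windows$year_end))) {
    stop("contribution matrices do not share the same cohort-window axis")
  }
}

#' Select ancestors for case-control testing
#'
#' Applies the [selection_rule()] to a pair of affected/control contribution
#' matrices sharing the same window axis.
#'
#' @param mA,mC Affected and control `ContributionMatrix` objects.
#' @param rule A [selection_rule()].
#' @return Character vector of ancestor ids, in the order of the union of the
#'   matrix rows.
#' @export
select_candidate_ancestors <- function(mA, mC, rule = selection_rule()) {
  check_same_windows(mA, mC)
  all_anc <- union(rownames(mA$values), rownames(mC$values))
  windows <- mA$windows
  passes <- function(cells) {
    filled <- which(!is.na(cells))
    length(filled) > 0 &&
      mean(cells, na.rm = TRUE) >= rule$min_avg_contribution &&
      max_disjoint_windows(windows, filled) >= rule$min_nonoverlapping_cohorts
  }
  sel <- vapply(all_anc, function(a) {
    rA <- if (a %in% rownames(mA$values)) mA$values[a, ] else
      rep(NA_real_, nrow(windows))
    rC <- if (a %in% rownames(mC$values)) mC$values[a, ] else
      rep(NA_real_, nrow(windows))
    passes(rA) || passes(rC)
  }, logical(1))
  all_anc[sel]
}

#' Paired two-tailed t-test of one ancestor's contributions
#'
#' Pairs the per-window contributions of one ancestor to the affected and
#' control cohorts. A window contributes a pair when either side is
#' non-missing; a missing side is treated as a zero contribution (the ancestor
#' was not selected for that cohort, so it explains none of its gene pool).
#' The statistic is `t = mean(d) / (sd(d) / sqrt(n))` on the differences
#' `d = affected - control`, with `df = n - 1`; positive `t` means a larger
#' contribution to the affected cohorts.
#'
#' @param rowA,rowC Numeric vectors of per-window contributions (`NA` =
#'   missing), in the same window order.
#' @return List with `n_pairs`, `df`, `t`, `p` (two-sided).
#' @section Errors: fewer than 2 usable pairs is an error; identical rows
#'   (zero variance of the differences) raise a condition of class
#'   `pedcontrib_degenerate_test`.
#' @export
paired_t <- function(rowA, rowC) {
  if (length(rowA) != length(rowC)) {
    stop("rows must cover the same window axis")
  }
  use <- !is.na(rowA) | !is.na(rowC)
  n <- sum(use)
  if (n < 2) stop("fewer than 2 usable pairs")
  a <- ifelse(is.na(rowA), 0, rowA)[use]
  c_ <- ifelse(is.na(rowC), 0, rowC)[use]
  d <- a - c_
  s <- sd(d)
  # guard against floating-point dust when all differences are equal
  if (s <= 1e-12 * max(abs(mean(d)), .Machine$double.eps)) {
    stop(errorCondition(
      "degenerate paired t-test: all differences are identical (sd = 0)",
      class = c("pedcontrib_degenerate_test", "error", "condition")))
  }
  tt <- mean(d) / (s / sqrt(n))
  list(n_pairs = n, df = n - 1L, t = tt,
       p = 2 * pt(-abs(tt), df = n - 1L))
}

#' Benjamini-Hochberg step-up flags
#'
#' Flags the p-values rejected by the Benjamini-Hochberg step-up procedure at
#' false discovery rate `q`: all `p <= p_(k*)` where
#' `k* = max{k : p_(k) <= k q / m}`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q Target false discovery rate in `(0, 1)`.
#' @return Logical vector of the same length (empty input gives empty flags).
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  stopifnot(q > 0, q < 1)
  if (!length(p_values)) return(logical(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH") <= q
}

#' Case-control comparison of ancestral contributions
#'
#' The full testing stage: selects ancestors by `rule`, runs the paired
#' two-tailed t-test per ancestor across the cohort windows (missing side
#' zero-filled, union pairing), classifies each ancestor as contributing more
#' to affected (`t > 0`) or control (`t < 0`) cohorts at `p <= alpha`, and
#' attaches Benjamini-Hochberg flags at 5% and 10% FDR over the tested set.
#' Degenerate tests (all differences identical) are reported with `NA`
#' statistics and left unclassified.
#'
#' @param mA,mC Affected and control `ContributionMatrix` objects on the same
#'   window axis.
#' @param rule A [selection_rule()].
#' @param alpha Significance level (default 0.05).
#' @return Data frame, one row per tested ancestor, sorted by direction
#'   (affected, control, ns) then |t| descending: `ancestor`, `n_pairs`, `df`,
#'   `t`, `p`, `significant`, `fdr05`, `fdr10`, `direction`, `degenerate`.
#'   The significance level is attached as attribute `alpha`.
#' @export
run_comparison <- function(mA, mC, rule = selection_rule(), alpha = 0.05) {
  check_same_windows(mA, mC)
  sel <- select_candidate_ancestors(mA, mC, rule)
  empty <- data.frame(ancestor = character(0), n_pairs = integer(0),
                      df = integer(0), t = numeric(0), p = numeric(0),
                      significant = logical(0), fdr05 = logical(0),
                      fdr10 = logical(0), direction = character(0),
                      degenerate = logical(0), stringsAsFactors = FALSE)
  if (!length(sel)) return(structure(empty, alpha = alpha))
  nwin <- nrow(mA$windows)
  get_row <- function(m, a) {
    if (a %in% rownames(m$values)) m$values[a, ] else rep(NA_real_, nwin)
  }
  rows <- lapply(sel, function(a) {
    res <- tryCatch(paired_t(get_row(mA, a), get_row(mC, a)),
                    pedcontrib_degenerate_test = function(e) NULL)
    if (is.null(res)) {
      data.frame(ancestor = a, n_pairs = NA_integer_, df = NA_integer_,
                 t = NA_real_, p = NA_real_, degenerate = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(ancestor = a, n_pairs = res$n_pairs, df = res$df,
                 t = res$t, p = res$p, degenerate = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p) & out$p <= alpha
  out$fdr05 <- FALSE
  out$fdr10 <- FALSE
  testable <- !out$degenerate
  out$fdr05[testable] <- bh_fdr(out$p[testable], 0.05)
  out$fdr10[testable] <- bh_fdr(out$p[testable], 0.10)
  out$direction <- ifelse(!out$significant, "ns",
                          ifelse(out$t > 0, "affected", "control"))
  dir_rank <- match(out$direction, c("affected", "control", "ns"))
  ord <- order(dir_rank, -abs(out$t), out$ancestor, na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out <- out[, c("ancestor", "n_pairs", "df", "t", "p", "significant",
                 "fdr05", "fdr10", "direction", "degenerate")]
  structure(out, alpha = alpha)
}

# "< 0.001" style bound for a p-value, as used in published t-test tables.
p_bound_label <- function(p, alpha = 0.05) {
  if (is.na(p)) return("degenerate")
  if (p > alpha) return("N.S.")
  for (b in c(0.001, 0.002, 0.01, 0.02, 0.05)) {
    if (p < b) return(sprintf("< %g", b))
  }
  sprintf("<= %g", alpha)
}

#' Write comparison results as a delimited table
#'
#' One row per tested ancestor: DF, t (4 decimals), exact p, a `< bound` /
#' `N.S.` label, FDR marks (`*` = 5%, `#` = 10%) and direction group.
#'
#' @param results Data frame from [run_comparison()].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_ttest_table <- function(results, path, sep = "\t") {
  alpha <- attr(results, "alpha")
  if (is.null(alpha)) alpha <- 0.05
  out <- data.frame(
    ancestor = results$ancestor,
    DF = results$df,
    t = ifelse(is.na(results$t), "", sprintf("%.4f", results$t)),
    p = ifelse(is.na(results$p), "", format(results$p, digits = 4)),
    P = vapply(results$p, p_bound_label, character(1), alpha = alpha),
    FDR = ifelse(results$significant & results$fdr05, "*",
                 ifelse(results$significant & results$fdr10, "#", "")),
    group = ifelse(results$direction == "affected", "Affected",
                   ifelse(results$direction == "control", "Control", "-")),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
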