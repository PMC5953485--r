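# Overlapping birth-year cohorts of case and control animals, contemporary
# control sampling, and per-cohort descriptive pedigree statistics.

#' Construct a cohort
#'
#' A labeled birth-window subset of case or control animals. The label encodes
#' the group initial and the two-digit start/end years, e.g. `A93/95` for
#' affected animals born 1993-1995.
#'
#' @param group `"affected"` or `"control"`.
#' @param year_start,year_end First and last birth year (inclusive).
#' @param members Animal ids.
#' @return An object of class `Cohort`.
#' @export
cohort <- function(group, year_start, year_end, members) {
  group <- match.arg(tolower(group), c("affected", "control"))
  stopifnot(year_end >= year_start)
  label <- sprintf("%s%02d/%02d", toupper(substr(group, 1, 1)),
                   year_start %% 100, year_end %% 100)
  structure(list(label = label, group = group,
                 year_start = as.integer(year_start),
                 year_end = as.integer(year_end),
                 members = as.character(members)),
            class = "Cohort")
}

#' @export
print.Cohort <- function(x, ...) {
  cat(sprintf("Cohort %s (%s, born %d-%d): %d members\n", x$label, x$group,
              x$year_start, x$year_end, length(x$members)))
  invisible(x)
}

#' Build overlapping case and control birth cohorts
#'
#' Creates three-year (by default) birth-window cohorts sliding by one year:
#' `[first_year, first_year + window - 1]`, `[first_year + 1, ...]`, ..., up
#' to `last_year`. One affected and one control cohort is produced per window;
#' an animal belongs to every window covering its birth year.
#'
#' @param cases,controls Ids of case and control animals. Every member must
#'   have a birth year in the pedigree.
#' @param ped A `Pedigree`.
#' @param first_year,last_year Birth-year span covered by the windows
#'   (defaults 1993 and 2007).
#' @param window Window width in years (default 3).
#' @return List of `Cohort` objects (for each window: affected then control),
#'   with the window table attached as attribute `windows`.
#' @export
build_cohorts <- function(cases, controls, ped, first_year = 1993L,
                          last_year = 2007L, window = 3L) {
  stopifnot(last_year >= first_year, window >= 1,
            last_year - first_year + 1 >= window)
  members <- unique(c(cases, controls))
  by <- ped$records$birth_year[ped_index(ped, members)]
  if (anyNA(by)) {
    stop("cohort member(s) without birth year: ",
         paste(members[is.na(by)], collapse = ", "))
  }
  year_of <- setNames(by, members)
  starts <- first_year:(last_year - window + 1L)
  out <- list()
  for (s in starts) {
    e <- s + window - 1L
    in_win <- function(ids) ids[year_of[ids] >= s & year_of[ids] <= e]
    a <- cohort("affected", s, e, in_win(cases))
    c_ <- cohort("control", s, e, in_win(controls))
    out[[a$label]] <- a
    out[[c_$label]] <- c_
  }
  attr(out, "windows") <- data.frame(year_start = starts,
                                     year_end = starts + window - 1L)
  out
}

#' Subset cohorts by group
#'
#' @param cohorts List of `Cohort` objects (as from [build_cohorts()]).
#' @param group `"affected"` or `"control"`.
#' @return List of the cohorts of that group, in window order.
#' @export
cohort_group <- function(cohorts, group) {
  group <- match.arg(tolower(group), c("affected", "control"))
  Filter(function(co) co$group == group, cohorts)
}

#' Sample birth-year-matched contemporary controls
#'
#' For each case, draws `ratio` controls without replacement among pool
#' animals born in the same year; a control is never reused across cases.
#' Sampling is deterministic given `seed` (cases are processed in
#' (birth year, id) order).
#'
#' @param cases Case animal ids.
#' @param pool Candidate control ids, disjoint from `cases`.
#' @param ped A `Pedigree` providing birth years.
#' @param ratio Controls per case (default 5).
#' @param seed Integer seed; required.
#' @return Character vector of `ratio * length(cases)` control ids.
#' @export
sample_controls <- function(cases, pool, ped, ratio = 5L, seed) {
  if (missing(seed)) stop("sample_controls requires an explicit seed")
  stopifnot(ratio >= 1)
  if (length(intersect(cases, pool))) {
    stop("pool must be disjoint from cases")
  }
  yr <- function(ids) ped$records$birth_year[ped_index(ped, ids)]
  case_year <- yr(cases)
  if (anyNA(case_year)) {
    stop("case(s) without birth year: ",
         paste(cases[is.na(case_year)], collapse = ", "))
  }
  pool_year <- yr(pool)
  ord <- order(case_year, cases)
  with_seed(seed, {
    used <- character(0)
    picks <- vector("list", length(cases))
    for (i in ord) {
      cand <- sort(pool[!is.na(pool_year) & pool_year == case_year[i]])
      cand <- setdiff(cand, used)
      if (length(cand) < ratio) {
        stop("insufficient matching control candidates for case ", cases[i],
             " (birth year ", case_year[i], "): need ", ratio, ", have ",
             length(cand))
      }
      sel <- cand[sample.int(length(cand), ratio)]
      used <- c(used, sel)
      picks[[i]] <- sel
    }
    unlist(picks)
  })
}

#' Descriptive pedigree statistics of a cohort
#'
#' Aggregates the classical statistics for one cohort: average/maximum/minimum
#' inbreeding, numbers of distinct sires and dams of the members, average
#' additive relationship among members, average pedigree completeness index at
#' `depth` generations, cohort size, and total pedigree size (members plus all
#' traced ancestors).
#'
#' @param cohort A `Cohort`.
#' @param ped A `Pedigree`.
#' @param F Optional precomputed named inbreeding vector (from
#'   [inbreeding()]); computed if `NULL`.
#' @param depth Generations for the completeness index (default 5).
#' @return A one-row data frame.
#' @export
cohort_descriptives <- function(cohort, ped, F = NULL, depth = 5L) {
  stopifnot(inherits(cohort, "Cohort"))
  m <- cohort$members
  n <- length(m)
  if (!n) {
    return(data.frame(cohort = cohort$label, group = cohort$group, n = 0L,
                      pedigree_size = 0L, f_avg = NA_real_, f_max = NA_real_,
                      f_min = NA_real_, n_sires = 0L, n_dams = 0L,
                      avg_relationship = NA_real_, pci_avg = NA_real_,
                      stringsAsFactors = FALSE))
  }
  if (is.null(F)) F <- inbreeding(ped)
  idx <- ped_index(ped, m)
  fm <- F[m]
  data.frame(
    cohort = cohort$label, group = cohort$group, n = n,
    pedigree_size = length(ancestors_of(ped, m, include_self = TRUE)),
    f_avg = mean(fm), f_max = max(fm), f_min = min(fm),
    n_sires = length(unique(ped$records$sire[idx][!is.na(ped$records$sire[idx])])),
    n_dams = length(unique(ped$records$dam[idx][!is.na(ped$records$dam[idx])])),
    avg_relationship = if (n >= 2) average_relationship(ped, m) else NA_real_,
    pci_avg = mean(pci(ped, m, depth = depth)),
    stringsAsFactors = FALSE)
}

#' Descriptive statistics for a list of cohorts
#'
#' @param cohorts List of `Cohort` objects.
#' @param ped A `Pedigree`.
#' @param depth Generations for the completeness index.
#' @return Data frame with one row per cohort. Inbreeding is computed once
#'   for the whole pedigree and reused.
#' @export
cohort_descriptives_table <- function(cohorts, ped, depth = 5L) {
  Fv <- inbreeding(ped)
  out <- do.call(rbind, lapply(cohorts, function(co) {
    cohort_descriptives(co, ped, F = Fv, depth = depth)
  }))
  rownames(out) <- NULL
  out
}
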