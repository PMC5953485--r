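# Appearance of designated ancestors in the five-generation pedigrees of case
# animals, split by the transmission path: through the case's sire or through
# its dam.

# Occurrences of `ancestor_idx` among the ancestor slots reachable from one
# parent of a case, within `depth` generations (the parent itself is
# generation 1). Slots are path-distinct: an ancestor filling three slots
# counts three times.
count_side_slots <- function(ped, parent_idx, ancestor_idx, depth) {
  count <- 0L
  frontier <- parent_idx
  for (g in seq_len(depth)) {
    count <- count + sum(frontier == ancestor_idx, na.rm = TRUE)
    if (g < depth) {
      frontier <- as.integer(rbind(ped$sire_idx[frontier],
                                   ped$dam_idx[frontier]))
    }
  }
  count
}

#' Count an ancestor's appearances in a case's pedigree, by parental path
#'
#' Counts the distinct ancestor slots occupied by `ancestor` within `depth`
#' generations of `case_id`'s pedigree. An occurrence is "via sire" when the
#' first step of its path from the case is the sire link, "via dam" when it is
#' the dam link; the case itself is never an occurrence.
#'
#' @param ped A `Pedigree`.
#' @param case_id A single animal id.
#' @param ancestor A single animal id.
#' @param depth Number of generations (default 5).
#' @return Named integer vector `c(via_sire =, via_dam =)`.
#' @export
appearance_counts <- function(ped, case_id, ancestor, depth = 5L) {
  if (depth < 1) stop("depth must be >= 1")
  i <- ped_index(ped, case_id)
  a <- ped_index(ped, ancestor, what = "ancestor")
  c(via_sire = count_side_slots(ped, ped$sire_idx[i], a, depth),
    via_dam = count_side_slots(ped, ped$dam_idx[i], a, depth))
}

#' Appearance profile of an ancestor over a set of cases
#'
#' Aggregates [appearance_counts()] over case animals: how many cases carry
#' the ancestor once vs multiple times, through the sire only, the dam only,
#' or both, and the percentage of cases with at least one appearance in their
#' `depth`-generation pedigree.
#'
#' @param ped A `Pedigree`.
#' @param cases Non-empty vector of case ids.
#' @param ancestor A single animal id.
#' @param depth Number of generations (default 5).
#' @return An object of class `AppearanceProfile`: list with `ancestor`,
#'   `depth`, `per_case` (data frame `case`, `via_sire`, `via_dam`) and the
#'   aggregate fields `n_cases_once`, `n_cases_multiple`,
#'   `n_cases_via_sire_only`, `n_cases_via_dam_only`, `n_cases_via_both`,
#'   `pct_cases_with_ancestor`.
#' @export
build_profile <- function(ped, cases, ancestor, depth = 5L) {
  if (!length(cases)) stop("cases is empty")
  counts <- vapply(cases, function(cs)
    appearance_counts(ped, cs, ancestor, depth), integer(2))
  vs <- counts["via_sire", ]
  vd <- counts["via_dam", ]
  tot <- vs + vd
  structure(list(
    ancestor = ancestor, depth = as.integer(depth),
    per_case = data.frame(case = cases, via_sire = vs, via_dam = vd,
                          row.names = NULL, stringsAsFactors = FALSE),
    n_cases_once = sum(tot == 1L),
    n_cases_multiple = sum(tot > 1L),
    n_cases_via_sire_only = sum(vs > 0L & vd == 0L),
    n_cases_via_dam_only = sum(vd > 0L & vs == 0L),
    n_cases_via_both = sum(vs > 0L & vd > 0L),
    pct_cases_with_ancestor = 100 * sum(tot > 0L) / length(cases)),
    class = "AppearanceProfile")
}

#' @export
print.AppearanceProfile <- function(x, ...) {
  cat(sprintf(
    "AppearanceProfile of %s (depth %d): present in %.1f%% of %d cases (%d once, %d multiple; sire only %d, dam only %d, both %d)\n",
    x$ancestor, x$depth, x$pct_cases_with_ancestor, nrow(x$per_case),
    x$n_cases_once, x$n_cases_multiple, x$n_cases_via_sire_only,
    x$n_cases_via_dam_only, x$n_cases_via_both))
  invisible(x)
}

#' Appearance profiles for several ancestors
#'
#' @param ped A `Pedigree`.
#' @param cases Case ids.
#' @param ancestors Ancestor ids to profile.
#' @param depth Number of generations (default 5).
#' @return Data frame with one row per ancestor (percentages to 1 decimal in
#'   [write_appearance_table()]).
#' @export
appearance_table <- function(ped, cases, ancestors, depth = 5L) {
  do.call(rbind, lapply(ancestors, function(a) {
    p <- build_profile(ped, cases, a, depth)
    data.frame(ancestor = a, n_cases = length(cases),
               n_cases_once = p$n_cases_once,
               n_cases_multiple = p$n_cases_multiple,
               via_sire_only = p$n_cases_via_sire_only,
               via_dam_only = p$n_cases_via_dam_only,
               via_both = p$n_cases_via_both,
               pct_cases_with_ancestor = p$pct_cases_with_ancestor,
               stringsAsFactors = FALSE)
  }))
}

#' Write appearance profiles to a delimited file
#'
#' @param tab Data frame from [appearance_table()].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_appearance_table <- function(tab, path, sep = "\t") {
  tab$pct_cases_with_ancestor <- sprintf("%.1f", tab$pct_cases_with_ancestor)
  write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
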