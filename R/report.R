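# End-to-end orchestration: run the whole analysis from input files (or
# in-memory objects) and write a report bundle of delimited tables shaped
# like the published ones.

#' Configuration of a full analysis run
#'
#' @param pedigree_path Delimited pedigree file (see [read_pedigree()]).
#' @param cases_path,controls_path Membership files: delimited text with a
#'   header containing an `animal` column (a single unnamed column is also
#'   accepted).
#' @param out_dir Output directory for the report bundle (created if absent).
#' @param first_year,last_year,window Cohort window parameters (defaults
#'   1993, 2007, 3).
#' @param stop A [decomposition_stop()] rule for the contribution matrices.
#' @param rule A [selection_rule()] for ancestor testing.
#' @param alpha Significance level (default 0.05).
#' @param appearance_depth Generations for appearance profiles (default 5).
#' @param seed Integer seed echoed into the run log (the analysis itself is
#'   deterministic; the seed matters when the inputs were simulated).
#' @return A list of class `RunConfig`.
#' @export
run_config <- function(pedigree_path, cases_path, controls_path, out_dir,
                       first_year = 1993L, last_year = 2007L, window = 3L,
                       stop = decomposition_stop(), rule = selection_rule(),
                       alpha = 0.05, appearance_depth = 5L, seed = 1L) {
  for (p in c(pedigree_path, cases_path, controls_path)) {
    if (!file.exists(p)) base::stop("input file not found: ", p)
  }
  stopifnot(alpha > 0, alpha < 1, window >= 1, last_year >= first_year)
  structure(list(pedigree_path = pedigree_path, cases_path = cases_path,
                 controls_path = controls_path, out_dir = out_dir,
                 first_year = as.integer(first_year),
                 last_year = as.integer(last_year), window = as.integer(window),
                 stop = stop, rule = rule, alpha = alpha,
                 appearance_depth = as.integer(appearance_depth),
                 seed = as.integer(seed)),
            class = "RunConfig")
}

read_member_file <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  x <- read.delim(path, sep = sep, colClasses = "character",
                  check.names = FALSE, stringsAsFactors = FALSE,
                  header = grepl("animal|id", tolower(first)))
  col <- intersect(c("animal", "animal_id", "id"), tolower(names(x)))
  ids <- if (length(col)) x[[match(col[1], tolower(names(x)))]] else x[[1]]
  unique(trimws(ids[nzchar(trimws(ids))]))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    base::stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               call. = FALSE)
  })
}

#' Write a contribution matrix to delimited text
#'
#' @param m A `ContributionMatrix`.
#' @param path Output path.
#' @param digits Decimal places (default 3, as in the published tables).
#' @param format `"wide"` (ancestor rows, window columns, `-` for missing, an
#'   `ave` column of non-missing row averages) or `"tidy"`
#'   (ancestor, cohort, marginal; missing cells omitted).
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_contribution_matrix <- function(m, path, digits = 3,
                                      format = c("wide", "tidy"),
                                      sep = "\t") {
  stopifnot(inherits(m, "ContributionMatrix"))
  format <- match.arg(format)
  v <- m$values
  if (format == "wide") {
    fmt <- function(x) ifelse(is.na(x), "-", sprintf(paste0("%.", digits, "f"), x))
    out <- data.frame(ancestor = rownames(v),
                      apply(v, 2, fmt),
                      ave = fmt(rowMeans(v, na.rm = TRUE)),
                      check.names = FALSE, stringsAsFactors = FALSE)
    write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  } else {
    idx <- which(!is.na(v), arr.ind = TRUE)
    out <- data.frame(ancestor = rownames(v)[idx[, 1]],
                      cohort = colnames(v)[idx[, 2]],
                      marginal = sprintf(paste0("%.", digits, "f"),
                                         v[idx]),
                      stringsAsFactors = FALSE)
    out <- out[order(out$ancestor, out$cohort), ]
    write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a wide contribution matrix
#'
#' Round-trip parser for the `"wide"` format of
#' [write_contribution_matrix()] (also the layout of the packaged published
#' tables).
#'
#' @param path File path.
#' @param group `"affected"` or `"control"`.
#' @return A `ContributionMatrix`.
#' @export
read_contribution_matrix <- function(path, group) {
  parse_contribution_fixture(path, group)
}

#' Run the full analysis and write the report bundle
#'
#' Executes the whole pipeline: read inputs, build overlapping case/control
#' cohorts, per-cohort descriptive statistics, per-cohort marginal
#' decompositions assembled into contribution matrices, the paired t-test
#' comparison with FDR flags, gene-pool coverage counts, and appearance
#' profiles of the affected-significant ancestors in the case pedigrees.
#' Writes cohort sizes, descriptives, both contribution matrices (wide and
#' tidy), the t-test table, the coverage table, the appearance table and a
#' run log (package version, seed, parameter echo) into `cfg$out_dir`. Any
#' stage error aborts with the stage name and cause.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with all computed objects.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  ped <- run_stage("load", read_pedigree(cfg$pedigree_path))
  cases <- run_stage("load", read_member_file(cfg$cases_path))
  controls <- run_stage("load", read_member_file(cfg$controls_path))
  if (!length(cases)) base::stop("stage 'load' failed: empty case list",
                                 call. = FALSE)
  if (!length(controls)) base::stop("stage 'load' failed: empty control list",
                                    call. = FALSE)

  cohorts <- run_stage("cohorts", build_cohorts(
    cases, controls, ped, first_year = cfg$first_year,
    last_year = cfg$last_year, window = cfg$window))
  descriptives <- run_stage("descriptives",
                            cohort_descriptives_table(cohorts, ped))
  aff <- run_stage("contributions", contribution_matrix(
    ped, cohort_group(cohorts, "affected"), stop = cfg$stop,
    keep_decompositions = TRUE))
  ctl <- run_stage("contributions", contribution_matrix(
    ped, cohort_group(cohorts, "control"), stop = cfg$stop,
    keep_decompositions = TRUE))
  tests <- run_stage("compare", run_comparison(aff, ctl, rule = cfg$rule,
                                               alpha = cfg$alpha))
  coverage <- run_stage("coverage", do.call(rbind, lapply(
    c(aff$decompositions, ctl$decompositions), function(d) {
      if (is.null(d)) return(NULL)
      pc <- pool_coverage(d)
      data.frame(cohort = d$label,
                 n50 = pc$n_ancestors[pc$threshold == 0.50],
                 n75 = pc$n_ancestors[pc$threshold == 0.75],
                 n99 = pc$n_ancestors[pc$threshold == 0.99],
                 largest_marginal = attr(pc, "largest_marginal"),
                 stringsAsFactors = FALSE)
    })))
  aff_sig <- tests$ancestor[tests$direction == "affected"]
  appearance <- run_stage("appearance", if (length(aff_sig)) {
    appearance_table(ped, cases, aff_sig, depth = cfg$appearance_depth)
  } else {
    NULL
  })

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  run_stage("write", {
    sizes <- data.frame(cohort = descriptives$cohort, group = descriptives$group,
                        size = descriptives$n,
                        pedigree_size = descriptives$pedigree_size)
    write.table(sizes, out("cohort_sizes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    d4 <- descriptives
    for (cc in c("f_avg", "f_max", "f_min", "avg_relationship", "pci_avg")) {
      d4[[cc]] <- sprintf("%.4f", d4[[cc]])
    }
    write.table(d4, out("cohort_descriptives.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_contribution_matrix(aff, out("contributions_affected.tsv"))
    write_contribution_matrix(ctl, out("contributions_control.tsv"))
    write_contribution_matrix(aff, out("contributions_affected_tidy.tsv"),
                              format = "tidy")
    write_contribution_matrix(ctl, out("contributions_control_tidy.tsv"),
                              format = "tidy")
    write_ttest_table(tests, out("ancestor_tests.tsv"))
    write.table(coverage, out("pool_coverage.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (!is.null(appearance)) {
      write_appearance_table(appearance, out("appearance_profiles.tsv"))
    }
    writeLines(c(
      sprintf("pedcontrib %s (R %s.%s)", as.character(packageVersion("pedcontrib")),
              R.version$major, R.version$minor),
      sprintf("seed: %d", cfg$seed),
      sprintf("pedigree: %s (%d animals)", cfg$pedigree_path, n_animals(ped)),
      sprintf("cases: %s (n = %d)", cfg$cases_path, length(cases)),
      sprintf("controls: %s (n = %d)", cfg$controls_path, length(controls)),
      sprintf("windows: %d-%d, width %d", cfg$first_year, cfg$last_year,
              cfg$window),
      sprintf("stop rule: cumulative >= %g, max_ancestors %s",
              cfg$stop$cumulative, format(cfg$stop$max_ancestors)),
      sprintf("selection rule: avg >= %g over >= %d non-overlapping cohorts",
              cfg$rule$min_avg_contribution,
              cfg$rule$min_nonoverlapping_cohorts),
      sprintf("alpha: %g", cfg$alpha)),
      out("run_log.txt"))
  })
  invisible(list(pedigree = ped, cases = cases, controls = controls,
                 cohorts = cohorts, descriptives = descriptives,
                 affected = aff, control = ctl, tests = tests,
                 coverage = coverage, appearance = appearance))
}
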