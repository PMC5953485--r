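# Machine-readable copies of the published contribution and t-test tables
# (41 high-contributing ancestors x 13 three-year cohort windows, 1993-2007),
# shipped as read-only fixtures with checksums. They let the statistical
# stage of the pipeline run and be tested without access to the registry
# pedigree data, which was never deposited.

.fixture_files <- c(control = "published_control_contributions.tsv",
                    affected = "published_affected_contributions.tsv",
                    ttests = "published_ancestor_ttests.tsv")

fixture_dir <- function() {
  system.file("extdata", package = "pedcontrib", mustWork = TRUE)
}

parse_contribution_fixture <- function(path, group) {
  x <- read.delim(path, check.names = FALSE, colClasses = "character",
                  stringsAsFactors = FALSE)
  labels <- setdiff(names(x), c("ancestor", "ave"))
  m <- as.matrix(x[, labels])
  m[m == "-"] <- NA
  values <- matrix(as.numeric(m), nrow = nrow(x),
                   dimnames = list(x$ancestor, labels))
  # labels are "[group initial]YY/YY"; pivot two-digit years at 1950
  expand_year <- function(yy) ifelse(yy >= 50L, 1900L + yy, 2000L + yy)
  starts <- expand_year(as.integer(sub("/.*", "",
                                       sub("^[^0-9]*", "", labels))))
  ends <- expand_year(as.integer(sub(".*/", "", labels)))
  windows <- data.frame(label = labels, year_start = starts,
                        year_end = ends, stringsAsFactors = FALSE)
  out <- contribution_matrix_values(values, windows, group)
  attr(out, "ave_printed") <- setNames(
    suppressWarnings(as.numeric(ifelse(x$ave == "-", NA, x$ave))), x$ancestor)
  out
}

#' Load the packaged published tables
#'
#' Returns the published marginal-contribution tables for the 13 control and
#' 13 affected three-year cohorts (41 ancestors; `-` preserved as missing)
#' and the published paired t-test table (DF, t, printed p bound, FDR mark,
#' direction group, broodmare flag). File checksums are verified against the
#' packaged manifest.
#'
#' @param dir Directory holding the fixture files (default: the package's
#'   `extdata`).
#' @param verify Verify MD5 checksums (default `TRUE`).
#' @return Object of class `FixtureSet`: list with `control` and `affected`
#'   (`ContributionMatrix`) and `ttests` (data frame).
#' @export
load_fixtures <- function(dir = NULL, verify = TRUE) {
  if (is.null(dir)) dir <- fixture_dir()
  paths <- file.path(dir, .fixture_files)
  names(paths) <- names(.fixture_files)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("fixture file(s) not found: ",
         paste(.fixture_files[missing], collapse = ", "))
  }
  if (verify) {
    manifest_path <- file.path(dir, "MANIFEST.md5")
    if (!file.exists(manifest_path)) stop("fixture manifest not found")
    manifest <- read.table(manifest_path, header = FALSE,
                           col.names = c("md5", "file"),
                           stringsAsFactors = FALSE)
    sums <- tools::md5sum(paths)
    expected <- setNames(manifest$md5, manifest$file)[.fixture_files]
    bad <- which(unname(sums) != unname(expected) | is.na(expected))
    if (length(bad)) {
      stop("fixture checksum mismatch: ",
           paste(.fixture_files[bad], collapse = ", "),
           " (fixtures are read-only data)")
    }
  }
  control <- parse_contribution_fixture(paths["control"], "control")
  affected <- parse_contribution_fixture(paths["affected"], "affected")
  tt <- read.delim(paths["ttests"], stringsAsFactors = FALSE)
  tt$df <- as.integer(tt$df)
  tt$t <- as.numeric(tt$t)
  tt$broodmare <- tt$broodmare == "yes"
  anc_union <- union(rownames(control$values), rownames(affected$values))
  if (length(anc_union) != 41L || nrow(tt) != 41L ||
      ncol(control$values) != 13L || ncol(affected$values) != 13L) {
    stop("fixture tables are inconsistent with the published layout ",
         "(41 ancestors x 13 windows)")
  }
  structure(list(control = control, affected = affected, ttests = tt),
            class = "FixtureSet")
}

#' @export
print.FixtureSet <- function(x, ...) {
  cat(sprintf(
    "FixtureSet: published contribution tables (%d ancestors x %d windows) and t-test table\n",
    nrow(x$ttests), ncol(x$control$values)))
  invisible(x)
}

#' Run the case-control comparison on the published tables
#'
#' "Fixtures-only" mode: feeds the packaged published contribution tables
#' directly into ancestor selection and the paired t-tests, decoupling the
#' statistical stage from the gene-origin decomposition (whose raw inputs are
#' not publicly available).
#'
#' @param rule A [selection_rule()].
#' @param alpha Significance level (default 0.05).
#' @param dir Optional fixture directory (see [load_fixtures()]).
#' @return Data frame from [run_comparison()].
#' @export
fixtures_only_comparison <- function(rule = selection_rule(), alpha = 0.05,
                                     dir = NULL) {
  fx <- load_fixtures(dir = dir)
  run_comparison(fx$affected, fx$control, rule = rule, alpha = alpha)
}
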