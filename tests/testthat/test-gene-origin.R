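test_that("raw contributions: closed forms and path sums", {
  ped <- pedigree(fullsib_mating_df())
  expect_equal(raw_contribution(ped, "Z", "Z"), 1)
  expect_equal(raw_contribution(ped, "X", "Z"), 0.5)
  expect_equal(raw_contribution(ped, "GS", "X"), 0.5)
  # grandsire via one path
  expect_equal(raw_contribution(ped, "GS", c("Z")), 0.5)  # two paths of 0.25
  # ancestor appearing as both paternal and maternal grandsire
  df <- data.frame(
    animal = c("G", "GD1", "GD2", "S", "D", "X"),
    sire = c(NA, NA, NA, "G", "G", "S"),
    dam = c(NA, NA, NA, "GD1", "GD2", "D"),
    sex = c("male", "female", "female", "male", "female", "male"),
    stringsAsFactors = FALSE)
  ped2 <- pedigree(df)
  expect_equal(raw_contribution(ped2, "G", "X"), 0.5)
  expect_equal(raw_contribution(ped2, "S", "X"), 0.5)
  # contribution through an unknown parent is 0; cohort averaging
  expect_equal(raw_contribution(ped2, "G", c("X", "GD1")), 0.25)
  expect_error(raw_contribution(ped2, "G", character(0)), "empty")
})

test_that("raw contributions equal the recursive path-expectation oracle", {
  df <- random_ped_df(300, seed = 31, single_parent_rate = 0.1)
  ped <- pedigree(df)
  oracle <- oracle_contribution_fun(df)
  set.seed(32)
  cohort <- df$animal[sample(200:300, 20)]
  for (anc in df$animal[c(1, 5, 20, 77, 150)]) {
    expect_equal(raw_contribution(ped, anc, cohort), oracle(anc, cohort),
                 tolerance = 1e-12)
  }
})

test_that("full-sib family decomposes into the two parents, summing to 1", {
  ped <- pedigree(fullsib_mating_df())
  dec <- marginal_decomposition(ped, c("X", "Y"),
                                stop = decomposition_stop(cumulative = 1))
  # GS and GD each contribute 0.5; GS is selected first (earlier birth year)
  expect_equal(dec$entries$ancestor, c("GS", "GD"))
  expect_equal(dec$entries$q, c(0.5, 0.5))
  expect_equal(dec$entries$p, c(0.5, 0.5))
  expect_equal(dec$explained, 1)
})

test_that("after a sire is selected, its own ancestors explain nothing new", {
  # G is the sire of S and has no other path to the cohort
  df <- data.frame(
    animal = c("G", "GD", "S", "D", "X1", "X2"),
    sire = c(NA, NA, "G", NA, "S", "S"),
    dam = c(NA, NA, "GD", NA, "D", "D"),
    birth_year = c(1970, 1971, 1980, 1981, 1990, 1991),
    sex = c("male", "female", "male", "female", "male", "female"),
    stringsAsFactors = FALSE)
  ped <- pedigree(df)
  dec <- marginal_decomposition(ped, c("X1", "X2"),
                                stop = decomposition_stop(cumulative = 1))
  expect_false("G" %in% dec$entries$ancestor)
  expect_false("GD" %in% dec$entries$ancestor)
  expect_equal(sort(dec$entries$ancestor), c("D", "S"))
  expect_equal(dec$explained, 1)
})

test_that("an ancestor reachable through a selected ancestor and an
           independent path keeps only the unexplained share", {
  # G is the sire of both of X's parents (their dams unknown):
  # G -> S -> X and G -> D -> X. G is oldest and selected first (q = p = 0.5);
  # S and D then keep only the share not routed through G:
  # p = q * (1 - a_G) = 0.5 * (1 - 0.5) = 0.25 each.
  df <- data.frame(
    animal = c("G", "S", "D", "X"),
    sire = c(NA, "G", "G", "S"),
    dam = c(NA, NA, NA, "D"),
    birth_year = c(1960, 1980, 1981, 2000),
    sex = c("male", "male", "female", "male"),
    stringsAsFactors = FALSE)
  ped <- pedigree(df)
  dec <- marginal_decomposition(ped, "X",
                                stop = decomposition_stop(cumulative = 1))
  e <- dec$entries
  expect_equal(e$ancestor, c("G", "S", "D"))
  expect_equal(e$q, c(0.5, 0.5, 0.5))
  expect_equal(e$p, c(0.5, 0.25, 0.25))
  expect_equal(dec$explained, 1)
})

test_that("marginals sum to 1 with all founders known, stay <= 1 otherwise,
           and never exceed the raw contribution", {
  for (seed in c(41, 42)) {
    df <- random_ped_df(150, seed = seed)
    ped <- pedigree(df)
    # a founder inside the cohort is excluded from candidacy, so its own
    # share of the pool is unexplainable by construction: use non-founders
    cohort <- utils::tail(df$animal[!is.na(df$sire) & !is.na(df$dam)], 20)
    dec <- marginal_decomposition(ped, cohort,
                                  stop = decomposition_stop(cumulative = 1))
    expect_equal(dec$explained, 1, tolerance = 1e-9)
    expect_true(all(dec$entries$p <= dec$entries$q + 1e-12))
    expect_true(all(dec$entries$p >= 0))
    # with unknown single parents part of the pool is unexplainable
    df2 <- random_ped_df(150, seed = seed + 100, single_parent_rate = 0.3)
    coh2 <- utils::tail(df2$animal[!is.na(df2$sire) & !is.na(df2$dam)], 20)
    dec2 <- marginal_decomposition(pedigree(df2), coh2,
                                   stop = decomposition_stop(cumulative = 1))
    expect_lte(dec2$explained, 1 + 1e-9)
    expect_true(all(dec2$entries$p <= dec2$entries$q + 1e-12))
  }
})

test_that("the decomposition is invariant to input record order", {
  df <- random_ped_df(200, seed = 51)
  cohort <- df$animal[180:200]
  dec1 <- marginal_decomposition(pedigree(df), cohort)
  dec2 <- marginal_decomposition(pedigree(shuffle_rows(df, 52)), cohort)
  # same selection sequence; values agree up to summation-order rounding
  expect_identical(dec1$entries$ancestor, dec2$entries$ancestor)
  expect_equal(dec1$entries$q, dec2$entries$q, tolerance = 1e-12)
  expect_equal(dec1$entries$p, dec2$entries$p, tolerance = 1e-12)
})

test_that("stop rules bound the decomposition", {
  df <- random_ped_df(150, seed = 61)
  ped <- pedigree(df)
  cohort <- df$animal[130:150]
  d3 <- marginal_decomposition(ped, cohort,
                               stop = decomposition_stop(max_ancestors = 3))
  expect_equal(nrow(d3$entries), 3L)
  d50 <- marginal_decomposition(ped, cohort,
                                stop = decomposition_stop(cumulative = 0.5))
  expect_gte(d50$explained, 0.5)
  expect_lt(d50$explained - d50$entries$p[nrow(d50$entries)], 0.5)
  expect_error(decomposition_stop(cumulative = 0), "\\(0, 1\\]")
  expect_error(decomposition_stop(cumulative = 1.2), "\\(0, 1\\]")
})

test_that("pool coverage counts come from cumulative sums", {
  fake <- structure(list(entries = data.frame(
    ancestor = paste0("A", 1:4), q = c(0.6, 0.3, 0.09, 0.01),
    p = c(0.6, 0.3, 0.09, 0.01), cumulative = cumsum(c(0.6, 0.3, 0.09, 0.01))),
    explained = 1), class = "MarginalDecomposition")
  pc <- pool_coverage(fake, thresholds = c(0.5, 0.75, 0.99))
  expect_equal(pc$n_ancestors, c(1L, 2L, 3L))
  expect_true(all(pc$reached))
  expect_equal(attr(pc, "largest_marginal"), 0.6)
  # counts are non-decreasing in the threshold
  expect_true(!is.unsorted(pc$n_ancestors))

  short <- fake
  short$entries$p <- c(0.6, 0.3, 0.04, 0.01)
  short$entries$cumulative <- cumsum(short$entries$p)
  pc2 <- pool_coverage(short, thresholds = c(0.99))
  expect_false(pc2$reached)
  expect_true(is.na(pc2$n_ancestors))

  # on a real decomposition the counts equal a direct re-scan
  df <- random_ped_df(150, seed = 71)
  dec <- marginal_decomposition(pedigree(df), df$animal[130:150])
  pc3 <- pool_coverage(dec)
  cum <- cumsum(dec$entries$p)
  for (k in seq_len(nrow(pc3))) {
    if (pc3$reached[k]) {
      expect_equal(pc3$n_ancestors[k], min(which(cum >= pc3$threshold[k] - 1e-12)))
    }
  }
})

test_that("contribution matrices assemble decompositions with missing cells", {
  df <- random_ped_df(250, seed = 81)
  ped <- pedigree(df)
  rec <- as.data.frame(ped)
  mk <- function(lab, s, e, members) cohort("affected", s, e, members)
  members <- function(a, b) rec$animal[rec$birth_year >= a & rec$birth_year <= b]
  cohorts <- list(mk("A", 1980, 1985, members(1980, 1985)),
                  mk("B", 1986, 1991, members(1986, 1991)),
                  mk("C", 1992, 1997, members(1992, 1997)))
  m <- contribution_matrix(ped, cohorts, stop = decomposition_stop(0.9))
  expect_s3_class(m, "ContributionMatrix")
  expect_equal(ncol(m$values), 3L)
  # single-cohort matrix equals that cohort's decomposition
  m1 <- contribution_matrix(ped, cohorts[1])
  d1 <- marginal_decomposition(ped, cohorts[[1]]$members)
  expect_setequal(rownames(m1$values), d1$entries$ancestor)
  expect_equal(unname(m1$values[d1$entries$ancestor, 1]), d1$entries$p)
  # row averages are over non-missing cells only
  avg <- row_averages(m)
  for (a in rownames(m$values)) {
    expect_equal(unname(avg[a]), mean(m$values[a, ], na.rm = TRUE))
  }
  # an ancestor selected for a single cohort averages to that single cell
  single <- rownames(m$values)[rowSums(!is.na(m$values)) == 1]
  if (length(single)) {
    a <- single[1]
    expect_equal(unname(avg[a]), m$values[a, which(!is.na(m$values[a, ]))])
  }
  # an empty cohort yields an all-missing column
  m2 <- contribution_matrix(ped, list(cohorts[[1]],
                                      mk("D", 1875, 1876, character(0))))
  expect_true(all(is.na(m2$values[, 2])))
})
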