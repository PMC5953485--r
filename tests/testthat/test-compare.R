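# Thirteen 3-year windows starting 1993..2005, as in the study design.
test_windows <- function(n = 13) {
  starts <- 1993:(1992 + n)
  data.frame(label = sprintf("%02d/%02d", starts %% 100, (starts + 2) %% 100),
             year_start = starts, year_end = starts + 2,
             stringsAsFactors = FALSE)
}

cm <- function(values, group, windows = test_windows(ncol(values))) {
  contribution_matrix_values(values, windows, group)
}

test_that("the selection rule needs both the average and disjoint windows", {
  w <- test_windows()
  v <- function(cells) {
    m <- matrix(NA_real_, 1, 13, dimnames = list("A", w$label))
    m[1, names(cells)] <- cells
    m
  }
  none <- matrix(NA_real_, 1, 13, dimnames = list("ZZ", w$label))
  # overlapping windows only (93/95 and 94/96): excluded however large
  mA <- cm(v(c("93/95" = 0.2, "94/96" = 0.2)), "affected")
  mC <- cm(none, "control")
  expect_length(select_candidate_ancestors(mA, mC), 0L)
  # two disjoint windows below the average threshold: excluded
  mA2 <- cm(v(c("93/95" = 0.004, "96/98" = 0.004)), "affected")
  expect_length(select_candidate_ancestors(mA2, mC), 0L)
  # the same pattern at 0.006: included
  mA3 <- cm(v(c("93/95" = 0.006, "96/98" = 0.006)), "affected")
  expect_equal(select_candidate_ancestors(mA3, mC), "A")
  # qualifying in the control matrix alone is enough
  mC4 <- cm(`rownames<-`(v(c("93/95" = 0.02, "99/01" = 0.02)), "B"), "control")
  expect_equal(select_candidate_ancestors(cm(none, "affected"), mC4), "B")
  # mismatched window axes are rejected
  w12 <- test_windows(12)
  none12 <- matrix(NA_real_, 1, 12, dimnames = list("ZZ", w12$label))
  expect_error(select_candidate_ancestors(mA3, cm(none12, "control", w12)),
               "window axis")
})

test_that("paired t uses union pairing with zero-filled missing sides", {
  # textbook closed form on three full pairs
  rowA <- c(0.02, 0.04, 0.06)
  rowC <- c(0.01, 0.02, 0.03)
  res <- paired_t(rowA, rowC)
  d <- rowA - rowC
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(3)))
  expect_equal(res$df, 2L)
  # cross-check against the independent routine
  tt <- t.test(rowA, rowC, paired = TRUE)
  expect_equal(res$t, unname(tt$statistic))
  expect_equal(res$p, tt$p.value)

  # six affected-only values: the control side is zero-filled, df = 5
  rowA2 <- c(NA, NA, 0.010, 0.174, NA, 0.200, 0.205, 0.148, 0.158)
  rowC2 <- rep(NA_real_, 9)
  res2 <- paired_t(rowA2, rowC2)
  expect_equal(res2$n_pairs, 6L)
  expect_equal(res2$df, 5L)
  vals <- rowA2[!is.na(rowA2)]
  expect_equal(res2$t, mean(vals) / (sd(vals) / sqrt(6)))

  # a window with only a control value still contributes a (negative) pair
  rowA3 <- c(0.02, NA, 0.03)
  rowC3 <- c(NA, 0.05, 0.01)
  res3 <- paired_t(rowA3, rowC3)
  expect_equal(res3$n_pairs, 3L)
  expect_equal(res3$t, mean(c(0.02, -0.05, 0.02)) /
                 (sd(c(0.02, -0.05, 0.02)) / sqrt(3)))
})

test_that("degenerate and underdetermined tests raise errors", {
  expect_error(paired_t(c(0.1, NA, NA), c(NA, NA, NA)), "fewer than 2")
  expect_error(paired_t(rep(0.05, 13), rep(0.05, 13)),
               class = "pedcontrib_degenerate_test")
  expect_error(paired_t(c(0.1, 0.2), c(0.05, 0.15)),
               class = "pedcontrib_degenerate_test")  # constant difference
  expect_error(paired_t(c(0.1, 0.2), c(0.05)), "same window")
})

test_that("Benjamini-Hochberg flags match the hand step-up and a brute-force
           oracle", {
  expect_identical(bh_fdr(0.01, 0.05), TRUE)
  expect_identical(bh_fdr(c(0.001, 0.02, 0.03, 0.9), 0.05),
                   c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(bh_fdr(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_identical(bh_fdr(numeric(0), 0.05), logical(0))
  set.seed(101)
  for (rep in 1:25) {
    m <- sample(1:100, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    expect_identical(bh_fdr(p, q), oracle_bh(p, q))
  }
})

test_that("planted mean shifts are recovered with the right direction and
           nothing else", {
  w <- test_windows()
  # symmetric differences around zero: mean exactly 0 for null ancestors
  sym <- c(-0.006, -0.005, -0.004, -0.003, -0.002, -0.001, 0,
           0.001, 0.002, 0.003, 0.004, 0.005, 0.006)
  base <- 0.03
  n_null <- 12
  null_names <- sprintf("N%02d", seq_len(n_null))
  up_names <- sprintf("UP%d", 1:5)
  dn_names <- sprintf("DN%d", 1:3)
  rn <- c(null_names, up_names, dn_names)
  C <- matrix(base, nrow = length(rn), ncol = 13, dimnames = list(rn, w$label))
  A <- C
  for (i in seq_len(n_null)) {
    A[null_names[i], ] <- base + sym[(seq_len(13) + i) %% 13 + 1]
  }
  for (a in up_names) A[a, ] <- base + 0.05 + sym
  for (a in dn_names) A[a, ] <- base - 0.05 + sym
  res <- run_comparison(cm(A, "affected"), cm(C, "control"))
  expect_equal(nrow(res), length(rn))
  expect_setequal(res$ancestor[res$direction == "affected"], up_names)
  expect_setequal(res$ancestor[res$direction == "control"], dn_names)
  expect_setequal(res$ancestor[res$direction == "ns"], null_names)
  # classification invariants
  expect_true(all(res$t[res$direction == "affected"] > 0))
  expect_true(all(res$t[res$direction == "control"] < 0))
  expect_true(all(res$significant == (res$p <= 0.05), na.rm = TRUE))
  expect_true(all(res$fdr10[res$fdr05]))  # 5% FDR implies 10% FDR
  # output is sorted by direction group then |t| descending
  rank <- match(res$direction, c("affected", "control", "ns"))
  expect_true(!is.unsorted(rank))
  for (g in unique(rank)) {
    expect_true(!is.unsorted(-abs(res$t[rank == g])))
  }
})

test_that("degenerate ancestors are reported but unclassified, and an
           all-failing rule gives an empty result", {
  w <- test_windows()
  rn <- c("CONST", "VAR")
  C <- matrix(0.03, 2, 13, dimnames = list(rn, w$label))
  A <- C
  A["CONST", ] <- 0.05  # constant difference: sd = 0
  A["VAR", ] <- 0.03 + seq(-0.006, 0.006, length.out = 13) + 0.02
  res <- run_comparison(cm(A, "affected"), cm(C, "control"))
  expect_true(res$degenerate[res$ancestor == "CONST"])
  expect_equal(res$direction[res$ancestor == "CONST"], "ns")
  expect_true(is.na(res$t[res$ancestor == "CONST"]))
  expect_false(res$fdr05[res$ancestor == "CONST"])

  # single shared ancestor failing the rule: empty result
  tiny <- matrix(0.001, 1, 13, dimnames = list("X", w$label))
  res2 <- run_comparison(cm(tiny, "affected"), cm(tiny, "control"))
  expect_equal(nrow(res2), 0L)
})

test_that("the t-test table writer emits the published layout", {
  w <- test_windows()
  A <- matrix(rep(0.05, 13) + seq(-0.012, 0.012, length.out = 13), 1, 13,
              dimnames = list("A1", w$label))
  C <- matrix(0.02, 1, 13, dimnames = list("A1", w$label))
  res <- run_comparison(cm(A, "affected"), cm(C, "control"))
  f <- withr_local_tempfile()
  write_ttest_table(res, f)
  tab <- read.delim(f, stringsAsFactors = FALSE)
  expect_equal(names(tab), c("ancestor", "DF", "t", "p", "P", "FDR", "group"))
  expect_equal(tab$DF, 12L)
  expect_equal(tab$group, "Affected")
  expect_match(tab$P, "^< ")
})
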