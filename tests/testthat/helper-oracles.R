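# Independent oracles: deliberately different algorithms (and pure R) from the
# package implementation, used to cross-check its results.

# Memoized recursive kinship on a pedigree data frame. Returns phi(a, b) for
# animal ids: phi(a, a) = 0.5 * (1 + phi(sire_a, dam_a));
# phi(a, b) = 0.5 * (phi(a, sire_b) + phi(a, dam_b)) with b the younger (by
# generation number); kinship to an unknown parent is 0.
oracle_kinship_fun <- function(df) {
  idx <- setNames(seq_len(nrow(df)), df$animal)
  sire <- unname(idx[df$sire])
  dam <- unname(idx[df$dam])
  gen <- rep(0L, nrow(df))
  repeat {
    g2 <- pmax(ifelse(is.na(sire), 0L, gen[sire] + 1L),
               ifelse(is.na(dam), 0L, gen[dam] + 1L))
    if (identical(g2, gen)) break
    gen <- g2
  }
  memo <- new.env(hash = TRUE, parent = emptyenv())
  phi <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    if (gen[a] > gen[b] || (gen[a] == gen[b] && a > b)) {
      tmp <- a; a <- b; b <- tmp
    }
    key <- paste(a, b)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- if (a == b) {
      0.5 * (1 + phi(sire[a], dam[a]))
    } else {
      0.5 * (phi(a, sire[b]) + phi(a, dam[b]))
    }
    memo[[key]] <- v
    v
  }
  function(a, b) phi(idx[[a]], idx[[b]])
}

# Memoized recursive genetic contribution c(k -> j) by direct path expansion.
oracle_contribution_fun <- function(df) {
  idx <- setNames(seq_len(nrow(df)), df$animal)
  sire <- unname(idx[df$sire])
  dam <- unname(idx[df$dam])
  memo <- new.env(hash = TRUE, parent = emptyenv())
  cc <- function(k, j) {
    if (is.na(j)) return(0)
    if (j == k) return(1)
    key <- paste(k, j)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- 0.5 * cc(k, sire[j]) + 0.5 * cc(k, dam[j])
    memo[[key]] <- v
    v
  }
  function(ancestor, members) {
    mean(vapply(idx[members], function(j) cc(idx[[ancestor]], j), numeric(1)))
  }
}

# Gene-dropping Monte Carlo estimate of the raw contribution of `ancestor` to
# `cohort`: both alleles of the ancestor are labelled 1 (all other origins 0),
# alleles segregate randomly down the pedigree, and the contribution is the
# expected allele-label proportion averaged over the cohort. Returns the
# estimate and its Monte Carlo standard error.
oracle_gene_drop <- function(df, ancestor, cohort, n_drops = 1e5, seed = 1,
                             chunk = 1e4) {
  set.seed(seed)
  idx <- setNames(seq_len(nrow(df)), df$animal)
  sire <- unname(idx[df$sire])
  dam <- unname(idx[df$dam])
  gen <- rep(0L, nrow(df))
  repeat {
    g2 <- pmax(ifelse(is.na(sire), 0L, gen[sire] + 1L),
               ifelse(is.na(dam), 0L, gen[dam] + 1L))
    if (identical(g2, gen)) break
    gen <- g2
  }
  ord <- order(gen)
  anc <- idx[[ancestor]]
  memb <- unname(idx[cohort])
  n <- nrow(df)
  total <- 0
  total_sq <- 0
  done <- 0
  while (done < n_drops) {
    m <- min(chunk, n_drops - done)
    A1 <- matrix(0, n, m)
    A2 <- matrix(0, n, m)
    for (i in ord) {
      if (i == anc) {
        A1[i, ] <- 1
        A2[i, ] <- 1
        next
      }
      s <- sire[i]
      if (!is.na(s)) {
        pick <- runif(m) < 0.5
        A1[i, ] <- ifelse(pick, A1[s, ], A2[s, ])
      }
      d <- dam[i]
      if (!is.na(d)) {
        pick <- runif(m) < 0.5
        A2[i, ] <- ifelse(pick, A1[d, ], A2[d, ])
      }
    }
    contrib <- colMeans((A1[memb, , drop = FALSE] +
                           A2[memb, , drop = FALSE]) / 2)
    total <- total + sum(contrib)
    total_sq <- total_sq + sum(contrib^2)
    done <- done + m
  }
  est <- total / n_drops
  se <- sqrt(pmax(total_sq / n_drops - est^2, 0) / n_drops)
  list(estimate = est, se = se)
}

# Brute-force Benjamini-Hochberg step-up: flag all p <= p_(k*) with
# k* = max{k : p_(k) <= k q / m}.
oracle_bh <- function(p, q) {
  m <- length(p)
  if (!m) return(logical(0))
  ord <- order(p)
  ps <- p[ord]
  ok <- which(ps <= seq_len(m) * q / m)
  if (!length(ok)) return(rep(FALSE, m))
  p <= ps[max(ok)]
}

# Exhaustive slot enumeration of an ancestor in the depth-generation pedigree
# of a case, split by first step (sire vs dam side).
oracle_slot_count <- function(df, case_id, ancestor, depth) {
  idx <- setNames(seq_len(nrow(df)), df$animal)
  sire <- unname(idx[df$sire])
  dam <- unname(idx[df$dam])
  a <- idx[[ancestor]]
  walk <- function(j, d) {
    if (is.na(j) || d < 1) return(0L)
    (j == a) + walk(sire[j], d - 1L) + walk(dam[j], d - 1L)
  }
  i <- idx[[case_id]]
  c(via_sire = walk(sire[i], depth), via_dam = walk(dam[i], depth))
}
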