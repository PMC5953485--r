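# Synthetic pedigree and liability-threshold disease generator.
#
# Emulates the structure the analysis assumes about a closed racehorse
# registry: a multi-generation pedigree with heavily skewed sire usage (a few
# popular stallions sire a large share of each foal crop), case status arising
# from a liability-threshold model with moderate heritability, optionally a
# planted high-risk sire family, and birth-year-matched contemporary controls.

#' Configuration of the synthetic pedigree and disease generator
#'
#' @param n_founders Number of founder animals (balanced sexes); founders are
#'   given staggered birth years over the 12 years up to `years[1]`.
#' @param years Integer `c(first, last)`: founders carry birth years up to
#'   `first`; one foal crop is born in each year `first + 1` to `last`.
#' @param matings_per_year Matings per foal crop (each dam at most once per
#'   year).
#' @param sire_skew Parameter in (0, 1) of the truncated geometric
#'   distribution over popularity-ranked eligible sires: the rank-r sire is
#'   drawn with probability proportional to `sire_skew * (1 - sire_skew)^(r-1)`.
#'   Larger values concentrate matings on the top-ranked stallions.
#' @param offspring_per_mating Foals per mating (default 1).
#' @param h2_liability Narrow-sense heritability of the disease liability
#'   (default 0.15).
#' @param sire_family_effect Liability-scale shift added to every descendant
#'   of the planted risk sire (default 0 = no planted family).
#' @param risk_sire Id of the planted risk sire, or `NULL` to auto-select the
#'   sire with the most offspring.
#' @param prevalence Target marginal disease prevalence in (0, 1); the
#'   liability threshold is `qnorm(1 - prevalence)` on the base N(0, 1)
#'   liability scale (default 0.04).
#' @param control_ratio Contemporary controls sampled per case (default 5).
#' @param first_case_year Cases are drawn among animals born from this year to
#'   `years[2]` (default 1993).
#' @param seed Integer seed; all stochastic operations are reproducible from
#'   the configuration.
#' @return A validated list of class `SimulationConfig`.
#' @export
sim_config <- function(n_founders = 200L, years = c(1978L, 2007L),
                       matings_per_year = 150L, sire_skew = 0.15,
                       offspring_per_mating = 1L, h2_liability = 0.15,
                       sire_family_effect = 0, risk_sire = NULL,
                       prevalence = 0.04, control_ratio = 5L,
                       first_case_year = 1993L, seed = 1L) {
  stopifnot(n_founders >= 2, length(years) == 2, years[2] >= years[1],
            matings_per_year >= 1, offspring_per_mating >= 1,
            sire_skew > 0, sire_skew < 1,
            h2_liability >= 0, h2_liability <= 1,
            prevalence > 0, prevalence < 1,
            control_ratio >= 1, is.numeric(seed), length(seed) == 1)
  if (first_case_year > years[2]) {
    stop("first_case_year lies after the last birth year")
  }
  structure(list(n_founders = as.integer(n_founders),
                 years = as.integer(years),
                 matings_per_year = as.integer(matings_per_year),
                 sire_skew = sire_skew,
                 offspring_per_mating = as.integer(offspring_per_mating),
                 h2_liability = h2_liability,
                 sire_family_effect = sire_family_effect,
                 risk_sire = risk_sire,
                 prevalence = prevalence,
                 control_ratio = as.integer(control_ratio),
                 first_case_year = as.integer(first_case_year),
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

.founder_year_span <- 12L
.sire_age <- c(3L, 22L)
.dam_age <- c(3L, 20L)

#' Simulate a pedigree with popular-sire structure
#'
#' Founders receive staggered birth years over the 12 years up to
#' `cfg$years[1]`. For each subsequent year, dams are drawn uniformly without
#' replacement among breeding-age females (ages 3-20), and the sire of each
#' mating is drawn from the popularity-ranked breeding-age stallions (ages
#' 3-22) with truncated-geometric probabilities controlled by
#' `cfg$sire_skew` (each stallion keeps a fixed latent popularity for life).
#' Offspring sexes are balanced Bernoulli; gait is inherited from the sire.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A validated `Pedigree`.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  with_seed(cfg$seed, {
    nf <- cfg$n_founders
    cap <- nf + (cfg$years[2] - cfg$years[1]) * cfg$matings_per_year *
      cfg$offspring_per_mating + 1L
    animal <- character(cap)
    sire <- rep(NA_character_, cap)
    dam <- rep(NA_character_, cap)
    birth_year <- integer(cap)
    sex <- character(cap)
    gait <- character(cap)
    popularity <- numeric(cap)

    k <- nf
    animal[1:nf] <- sprintf("F%04d", seq_len(nf))
    birth_year[1:nf] <- cfg$years[1] - (seq_len(nf) - 1L) %% .founder_year_span
    sex[1:nf] <- rep_len(c("male", "female"), nf)
    gait[1:nf] <- sample(c("pacer", "trotter"), nf, replace = TRUE,
                         prob = c(0.7, 0.3))
    popularity[1:nf] <- runif(nf)

    breeding_years <- if (cfg$years[2] > cfg$years[1]) {
      (cfg$years[1] + 1L):cfg$years[2]
    } else {
      integer(0)
    }
    for (y in breeding_years) {
      age <- y - birth_year[1:k]
      sires_el <- which(sex[1:k] == "male" &
                          age >= .sire_age[1] & age <= .sire_age[2])
      dams_el <- which(sex[1:k] == "female" &
                         age >= .dam_age[1] & age <= .dam_age[2])
      if (!length(dams_el)) {
        stop("infeasible configuration: no breeding-age females in year ", y)
      }
      if (!length(sires_el)) {
        stop("infeasible configuration: no breeding-age males in year ", y)
      }
      nm <- min(cfg$matings_per_year, length(dams_el))
      dams_y <- dams_el[sample.int(length(dams_el), nm)]
      ranked <- sires_el[order(-popularity[sires_el], sires_el)]
      pr <- cfg$sire_skew * (1 - cfg$sire_skew)^(seq_along(ranked) - 1)
      sires_y <- ranked[sample.int(length(ranked), nm, replace = TRUE,
                                   prob = pr / sum(pr))]
      for (m in seq_len(nm)) {
        for (o in seq_len(cfg$offspring_per_mating)) {
          k <- k + 1L
          animal[k] <- sprintf("X%06d", k - nf)
          sire[k] <- animal[sires_y[m]]
          dam[k] <- animal[dams_y[m]]
          birth_year[k] <- y
          sex[k] <- if (runif(1) < 0.5) "male" else "female"
          gait[k] <- gait[sires_y[m]]
          popularity[k] <- runif(1)
        }
      }
    }
    pedigree(data.frame(animal = animal[1:k], sire = sire[1:k],
                        dam = dam[1:k], birth_year = birth_year[1:k],
                        sex = sex[1:k], gait = gait[1:k],
                        stringsAsFactors = FALSE))
  })
}

# Sire with the most recorded offspring (ties: earlier birth year, then id).
top_progeny_sire <- function(ped) {
  sires <- ped$records$sire[!is.na(ped$records$sire)]
  if (!length(sires)) stop("pedigree has no sire links")
  counts <- table(sires)
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1) {
    by <- ped$records$birth_year[ped_index(ped, top)]
    by[is.na(by)] <- .Machine$integer.max
    top <- top[order(by, top)]
  }
  top[1]
}

#' Assign liability-threshold case status
#'
#' Disease liability is `l = u + e` on a base N(0, 1) scale: breeding values
#' `u` follow the pedigree (`u = 0.5 u_sire + 0.5 u_dam +` Mendelian sampling
#' term with variance `0.5 h2 (1 - (F_s + F_d) / 2)`; founder variance `h2`),
#' environmental noise has variance `1 - h2`. If `cfg$sire_family_effect` is
#' non-zero, that shift is added to the liability of every descendant of the
#' planted risk sire (`cfg$risk_sire`, or the sire with the most offspring).
#' Animals born between `cfg$first_case_year` and `cfg$years[2]` whose
#' liability exceeds `qnorm(1 - cfg$prevalence)` are cases.
#'
#' @param ped A `Pedigree` (typically from [simulate_pedigree()]).
#' @param cfg The [sim_config()] used to generate it.
#' @return Character vector of case ids, with attributes `liability` (named
#'   vector), `threshold` and `risk_sire`.
#' @export
assign_phenotypes <- function(ped, cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  with_seed(cfg$seed + 1000003L, {
    arr <- ped_topo_arrays(ped)
    n <- length(arr$ids)
    h2 <- cfg$h2_liability
    u <- numeric(n)
    if (h2 > 0) {
      Fv <- inbreeding(ped)[arr$ids]
      z <- rnorm(n)
      for (i in seq_len(n)) {
        s <- arr$sire[i]
        d <- arr$dam[i]
        if (s > 0L && d > 0L) {
          vm <- 0.5 * h2 * (1 - 0.5 * (Fv[s] + Fv[d]))
          u[i] <- 0.5 * (u[s] + u[d]) + sqrt(vm) * z[i]
        } else if (s > 0L || d > 0L) {
          u[i] <- 0.5 * u[max(s, d)] + sqrt(0.75 * h2) * z[i]
        } else {
          u[i] <- sqrt(h2) * z[i]
        }
      }
    }
    liab <- u + rnorm(n, sd = sqrt(1 - h2))
    risk_sire <- cfg$risk_sire
    if (is.null(risk_sire)) risk_sire <- top_progeny_sire(ped)
    if (cfg$sire_family_effect != 0) {
      desc <- descendants_of(ped, risk_sire)
      liab[match(desc, arr$ids)] <- liab[match(desc, arr$ids)] +
        cfg$sire_family_effect
    }
    threshold <- qnorm(1 - cfg$prevalence)
    eligible <- !is.na(arr$birth_year) &
      arr$birth_year >= cfg$first_case_year &
      arr$birth_year <= cfg$years[2]
    cases <- arr$ids[eligible & liab > threshold]
    structure(cases, liability = setNames(liab, arr$ids),
              threshold = threshold, risk_sire = risk_sire)
  })
}

#' Simulate a full case-control study
#'
#' Convenience wrapper: simulates the pedigree, assigns liability-threshold
#' case status, and samples `cfg$control_ratio` birth-year-matched contemporary
#' controls per case from the unaffected animals born in the case window.
#' Roles are recorded in the returned pedigree.
#'
#' @param cfg A [sim_config()].
#' @return List with `pedigree`, `cases`, `controls` and `risk_sire`.
#' @export
simulate_study <- function(cfg) {
  ped <- simulate_pedigree(cfg)
  cases <- assign_phenotypes(ped, cfg)
  risk_sire <- attr(cases, "risk_sire")
  cases <- as.character(cases)
  by <- ped$records$birth_year
  pool <- ped$records$animal[!is.na(by) & by >= cfg$first_case_year &
                               by <= cfg$years[2]]
  pool <- setdiff(pool, cases)
  controls <- sample_controls(cases, pool, ped, ratio = cfg$control_ratio,
                              seed = cfg$seed + 2000003L)
  ped$records$role[ped_index(ped, cases)] <- "case"
  ped$records$role[ped_index(ped, controls)] <- "control"
  list(pedigree = ped, cases = cases, controls = controls,
       risk_sire = risk_sire)
}
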