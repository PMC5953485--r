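# Shared designs for the null-calibration and power simulation studies.
# Problem sizes are chosen desk-scale (documented in the methods vignette):
# 60 founders, one 60-80 foal crop per year 1980-2003, case window 1993-2003
# (9 overlapping 3-year windows), 5 contemporary controls per case.

null_study_cfg <- function(seed, sire_family_effect = 0, prevalence = 0.04,
                           matings_per_year = 60L, risk_sire = NULL) {
  sim_config(n_founders = 60L, years = c(1979L, 2003L),
             matings_per_year = matings_per_year, sire_skew = 0.2,
             h2_liability = 0, sire_family_effect = sire_family_effect,
             risk_sire = risk_sire, prevalence = prevalence,
             first_case_year = 1993L, seed = seed)
}

# Simulate one study and run the full comparison pipeline on its cohorts.
run_study_pipeline <- function(cfg, window = 3L) {
  study <- simulate_study(cfg)
  cohorts <- build_cohorts(study$cases, study$controls, study$pedigree,
                           first_year = cfg$first_case_year,
                           last_year = cfg$years[2], window = window)
  aff <- contribution_matrix(study$pedigree, cohort_group(cohorts, "affected"))
  ctl <- contribution_matrix(study$pedigree, cohort_group(cohorts, "control"))
  list(results = run_comparison(aff, ctl), study = study, cohorts = cohorts)
}

# One replicate of the power design: a liability shift of 2 (in liability SD)
# is planted on the family of a moderately used stallion born 1984-1988 (the
# male whose descendant count inside the case window is closest to 60, i.e. a
# family large enough to be detectable but small enough that unaffected
# contemporaries still outnumber cases 5:1 in every birth year). Returns
# whether any member of the planted sire family (the sire, an ancestor, or a
# descendant) is classified affected-significant.
power_replicate <- function(seed) {
  cfg0 <- null_study_cfg(seed, matings_per_year = 80L)
  ped <- simulate_pedigree(cfg0)
  rec <- as.data.frame(ped)
  sired <- unique(rec$sire[!is.na(rec$sire)])
  mid <- rec$animal[rec$sex == "male" & !is.na(rec$birth_year) &
                      rec$birth_year >= 1984L & rec$birth_year <= 1988L]
  mid <- intersect(mid, sired)
  yr <- setNames(rec$birth_year, rec$animal)
  dwin <- vapply(mid, function(m) {
    d <- descendants_of(ped, m)
    sum(yr[d] >= 1993L & yr[d] <= 2003L, na.rm = TRUE)
  }, numeric(1))
  rs <- mid[order(abs(dwin - 60), mid)][1]
  cfg <- null_study_cfg(seed, sire_family_effect = 2.0, prevalence = 0.02,
                        matings_per_year = 80L, risk_sire = rs)
  out <- tryCatch(run_study_pipeline(cfg), error = function(e) NULL)
  if (is.null(out)) return(FALSE)  # an infeasible replicate counts as a miss
  aff_sig <- out$results$ancestor[out$results$direction == "affected"]
  family <- c(rs, ancestors_of(ped, rs), descendants_of(ped, rs))
  any(aff_sig %in% family)
}
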