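# Small pedigree builders used across the tests. All return plain data frames
# (so tests can shuffle or perturb rows) unless noted.

withr_local_tempfile <- function(fileext = ".tsv") {
  tempfile(fileext = fileext)
}

trio_df <- function() {
  data.frame(animal = c("S", "D", "X"), sire = c(NA, NA, "S"),
             dam = c(NA, NA, "D"), birth_year = c(1990L, 1991L, 2000L),
             sex = c("male", "female", "male"), stringsAsFactors = FALSE)
}

# Z is the offspring of a full-sib mating (grandparents GS x GD twice).
fullsib_mating_df <- function() {
  data.frame(
    animal = c("GS", "GD", "X", "Y", "Z"),
    sire = c(NA, NA, "GS", "GS", "X"),
    dam = c(NA, NA, "GD", "GD", "Y"),
    birth_year = c(1980L, 1981L, 1990L, 1991L, 2000L),
    sex = c("male", "female", "male", "female", "male"),
    stringsAsFactors = FALSE)
}

# Z is the offspring of a half-sib mating (common sire GS, unrelated dams).
halfsib_mating_df <- function() {
  data.frame(
    animal = c("GS", "GD1", "GD2", "X", "Y", "Z"),
    sire = c(NA, NA, NA, "GS", "GS", "X"),
    dam = c(NA, NA, NA, "GD1", "GD2", "Y"),
    birth_year = c(1980L, 1981L, 1982L, 1990L, 1991L, 2000L),
    sex = c("male", "female", "female", "male", "female", "male"),
    stringsAsFactors = FALSE)
}

# Proband "P" with a complete `depth`-generation ancestry (2^depth + ... + 2
# ancestors, all distinct). Ancestor ids encode the path, e.g. "Asd" is the
# dam of the sire of P.
complete_tree_df <- function(depth = 5L) {
  rows <- list(data.frame(animal = "P", sire = "As", dam = "Ad",
                          stringsAsFactors = FALSE))
  paths <- c("s", "d")
  for (g in seq_len(depth)) {
    for (p in paths) {
      id <- paste0("A", p)
      if (g < depth) {
        rows[[length(rows) + 1L]] <- data.frame(
          animal = id, sire = paste0("A", p, "s"), dam = paste0("A", p, "d"),
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          animal = id, sire = NA_character_, dam = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
    paths <- c(paste0(rep(paths, each = 2), c("s", "d")))
  }
  df <- do.call(rbind, rows)
  df$sex <- ifelse(df$animal == "P", "male",
                   ifelse(substr(df$animal, nchar(df$animal),
                                 nchar(df$animal)) == "s", "male", "female"))
  df$birth_year <- 2000L - nchar(sub("^A", "", sub("P", "", df$animal)))
  df
}

# Random multi-generation pedigree: each animal is a founder with probability
# p_founder (or when no parents of both sexes exist yet), otherwise it gets a
# random earlier sire and dam. With single_parent_rate > 0 some animals get
# exactly one known parent.
random_ped_df <- function(n, seed, p_founder = 0.15,
                          single_parent_rate = 0) {
  set.seed(seed)
  animal <- sprintf("R%04d", seq_len(n))
  sex <- sample(c("male", "female"), n, replace = TRUE)
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  birth_year <- 1900L + floor(seq(0, 99.999, length.out = n))
  for (i in seq_len(n)) {
    males <- which(sex[seq_len(i - 1)] == "male")
    females <- which(sex[seq_len(i - 1)] == "female")
    if (!length(males) || !length(females) || runif(1) < p_founder) next
    sire[i] <- animal[males[sample.int(length(males), 1)]]
    dam[i] <- animal[females[sample.int(length(females), 1)]]
    if (single_parent_rate > 0 && runif(1) < single_parent_rate) {
      if (runif(1) < 0.5) sire[i] <- NA_character_ else dam[i] <- NA_character_
    }
  }
  data.frame(animal = animal, sire = sire, dam = dam,
             birth_year = birth_year, sex = sex, stringsAsFactors = FALSE)
}

shuffle_rows <- function(df, seed) {
  set.seed(seed)
  df[sample.int(nrow(df)), , drop = FALSE]
}
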