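# Pedigree data model, validation and I/O.
#
# A Pedigree is the directed acyclic parent graph of a population: one record
# per animal with sire, dam, birth year, sex, and two annotation fields (gait,
# role). Unknown parents are represented as NA; on input the encodings "",
# "0" and "NA" are accepted.

.unknown_codes <- c("", "0", "NA")
.sexes <- c("male", "female", "unknown")

normalize_id <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x) | x %in% .unknown_codes] <- NA_character_
  x
}

normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("m", "male", "1", "s", "stallion")] <- "male"
  x[x %in% c("f", "female", "2", "mare")] <- "female"
  x[is.na(x) | !(x %in% .sexes)] <- "unknown"
  x
}

#' Construct a validated pedigree
#'
#' Builds a `Pedigree` object from a data frame with one row per animal.
#' The parent graph is checked for duplicate ids, self-parenting, dangling
#' parent ids, parent/sex consistency and cycles; a topological order
#' (every parent before its offspring) is computed and cached.
#'
#' @param records Data frame with columns `animal`, `sire`, `dam` and
#'   optionally `birth_year`, `sex` (`male`/`female`/`unknown`), `gait`
#'   (`pacer`/`trotter`/`unknown`) and `role` (`case`/`control`/
#'   `ancestor_only`). Unknown parents may be coded `NA`, `""`, `"0"` or
#'   `"NA"`.
#' @param permissive If `TRUE`, parent ids without a record are auto-created
#'   as founder records (sex inferred from the role in which they appear)
#'   instead of raising an error.
#' @return An object of class `Pedigree`.
#' @examples
#' ped <- pedigree(data.frame(
#'   animal = c("S", "D", "X"), sire = c(NA, NA, "S"), dam = c(NA, NA, "D"),
#'   birth_year = c(1990, 1991, 2000), sex = c("male", "female", "male")))
#' topological_order(ped)
#' @export
pedigree <- function(records, permissive = FALSE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  required <- c("animal", "sire", "dam")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("pedigree records lack required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  animal <- normalize_id(records$animal)
  if (anyNA(animal)) stop("missing/unknown-coded animal id in records")
  sire <- normalize_id(records$sire)
  dam <- normalize_id(records$dam)
  birth_year <- if ("birth_year" %in% names(records)) {
    suppressWarnings(as.integer(records$birth_year))
  } else {
    rep(NA_integer_, length(animal))
  }
  sex <- if ("sex" %in% names(records)) normalize_sex(records$sex) else "unknown"
  gait <- if ("gait" %in% names(records)) {
    g <- tolower(trimws(as.character(records$gait)))
    g[is.na(g) | !(g %in% c("pacer", "trotter"))] <- "unknown"
    g
  } else {
    "unknown"
  }
  role <- if ("role" %in% names(records)) {
    r <- tolower(trimws(as.character(records$role)))
    r[is.na(r) | !(r %in% c("case", "control"))] <- "ancestor_only"
    r
  } else {
    "ancestor_only"
  }

  dup <- unique(animal[duplicated(animal)])
  if (length(dup)) {
    stop("duplicate animal id(s): ", paste(dup, collapse = ", "))
  }
  self <- animal == sire | animal == dam
  self[is.na(self)] <- FALSE
  if (any(self)) {
    stop("self-parenting: animal(s) listed as their own parent: ",
         paste(animal[self], collapse = ", "))
  }

  df <- data.frame(animal = animal, sire = sire, dam = dam,
                   birth_year = birth_year,
                   sex = rep_len(sex, length(animal)),
                   gait = rep_len(gait, length(animal)),
                   role = rep_len(role, length(animal)),
                   stringsAsFactors = FALSE)

  dangling_sires <- setdiff(unique(df$sire[!is.na(df$sire)]), df$animal)
  dangling_dams <- setdiff(unique(df$dam[!is.na(df$dam)]), df$animal)
  dangling <- union(dangling_sires, dangling_dams)
  if (length(dangling)) {
    if (!permissive) {
      stop("parent id(s) without a pedigree record: ",
           paste(dangling, collapse = ", "),
           " (use permissive = TRUE to auto-create founder records)")
    }
    add <- data.frame(animal = dangling, sire = NA_character_,
                      dam = NA_character_, birth_year = NA_integer_,
                      sex = ifelse(dangling %in% dangling_sires &
                                     !(dangling %in% dangling_dams), "male",
                                   ifelse(dangling %in% dangling_dams &
                                            !(dangling %in% dangling_sires),
                                          "female", "unknown")),
                      gait = "unknown", role = "ancestor_only",
                      stringsAsFactors = FALSE)
    df <- rbind(df, add)
  }

  idx <- seq_len(nrow(df))
  names(idx) <- df$animal
  sire_idx <- unname(idx[df$sire])
  dam_idx <- unname(idx[df$dam])

  bad_sire <- which(!is.na(sire_idx) & df$sex[sire_idx] == "female")
  if (length(bad_sire)) {
    stop("sex inconsistency: sire(s) recorded as female: ",
         paste(unique(df$animal[sire_idx[bad_sire]]), collapse = ", "))
  }
  bad_dam <- which(!is.na(dam_idx) & df$sex[dam_idx] == "male")
  if (length(bad_dam)) {
    stop("sex inconsistency: dam(s) recorded as male: ",
         paste(unique(df$animal[dam_idx[bad_dam]]), collapse = ", "))
  }

  topo <- topo_sort_idx(sire_idx, dam_idx, df$animal)

  structure(list(records = df, sire_idx = sire_idx, dam_idx = dam_idx,
                 topo = topo),
            class = "Pedigree")
}

# Kahn's algorithm; errors with one explicit cycle if none exists.
topo_sort_idx <- function(sire_idx, dam_idx, ids) {
  n <- length(sire_idx)
  npar <- (!is.na(sire_idx)) + (!is.na(dam_idx))
  parent <- c(sire_idx, dam_idx)
  child <- rep.int(seq_len(n), 2L)
  keep <- !is.na(parent)
  children <- split(child[keep], factor(parent[keep], levels = seq_len(n)))
  queue <- integer(n)
  tail <- 0L
  for (v in which(npar == 0L)) {
    tail <- tail + 1L
    queue[tail] <- v
  }
  out <- integer(n)
  head <- 0L
  while (head < tail) {
    head <- head + 1L
    v <- queue[head]
    out[head] <- v
    for (ch in children[[v]]) {
      npar[ch] <- npar[ch] - 1L
      if (npar[ch] == 0L) {
        tail <- tail + 1L
        queue[tail] <- ch
      }
    }
  }
  if (head < n) {
    start <- which(npar > 0L)[1]
    path <- integer(0)
    v <- start
    repeat {
      if (v %in% path) {
        cyc <- path[which(path == v)[1]:length(path)]
        stop("cycle detected in parent graph: ",
             paste(ids[c(cyc, v)], collapse = " -> "))
      }
      path <- c(path, v)
      p <- c(sire_idx[v], dam_idx[v])
      p <- p[!is.na(p) & npar[p] >= 0L]
      # at least one parent is itself stuck in the cycle
      p_stuck <- p[p %in% which(npar > 0L)]
      v <- if (length(p_stuck)) p_stuck[1] else p[1]
    }
  }
  out
}

#' @export
print.Pedigree <- function(x, ...) {
  n <- nrow(x$records)
  nf <- sum(is.na(x$sire_idx) & is.na(x$dam_idx))
  yr <- range(x$records$birth_year, na.rm = TRUE)
  cat(sprintf("Pedigree: %d animals (%d founders)", n, nf))
  if (all(is.finite(yr))) cat(sprintf(", birth years %d-%d", yr[1], yr[2]))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.Pedigree <- function(x, ...) x$records

#' Number of animals in a pedigree
#' @param ped A `Pedigree`.
#' @return Integer count of records.
#' @export
n_animals <- function(ped) nrow(ped$records)

#' Animal identifiers of a pedigree
#' @param ped A `Pedigree`.
#' @return Character vector of ids in record order.
#' @export
ped_ids <- function(ped) ped$records$animal

ped_index <- function(ped, ids, what = "animal") {
  i <- match(ids, ped$records$animal)
  if (anyNA(i)) {
    stop("unknown ", what, " id(s): ", paste(ids[is.na(i)], collapse = ", "))
  }
  i
}

#' Topological order of a pedigree
#'
#' @param ped A `Pedigree`.
#' @return Character vector of animal ids in which every parent precedes all
#'   of its offspring.
#' @export
topological_order <- function(ped) {
  ped$records$animal[ped$topo]
}

#' All ancestors of a set of animals
#'
#' @param ped A `Pedigree`.
#' @param ids Animal ids whose ancestry is traced (to the earliest known
#'   ancestors).
#' @param include_self Include `ids` themselves in the result.
#' @return Character vector of ancestor ids.
#' @export
ancestors_of <- function(ped, ids, include_self = FALSE) {
  idx <- ped_index(ped, ids)
  seen <- logical(n_animals(ped))
  frontier <- idx
  anc <- logical(n_animals(ped))
  while (length(frontier)) {
    seen[frontier] <- TRUE
    par <- c(ped$sire_idx[frontier], ped$dam_idx[frontier])
    par <- unique(par[!is.na(par)])
    frontier <- par[!seen[par]]
    anc[par] <- TRUE
  }
  out <- anc
  if (include_self) out[idx] <- TRUE
  ped$records$animal[out]
}

#' All descendants of an animal
#'
#' @param ped A `Pedigree`.
#' @param id A single animal id.
#' @param include_self Include `id` itself.
#' @return Character vector of descendant ids.
#' @export
descendants_of <- function(ped, id, include_self = FALSE) {
  idx <- ped_index(ped, id)
  n <- n_animals(ped)
  child_of <- c(ped$sire_idx, ped$dam_idx)
  child <- rep.int(seq_len(n), 2L)
  keep <- !is.na(child_of)
  kids <- split(child[keep], factor(child_of[keep], levels = seq_len(n)))
  desc <- logical(n)
  frontier <- idx
  while (length(frontier)) {
    ch <- unique(unlist(kids[frontier], use.names = FALSE))
    ch <- ch[!desc[ch]]
    desc[ch] <- TRUE
    frontier <- ch
  }
  if (include_self) desc[idx] <- TRUE
  ped$records$animal[desc]
}

#' Turn animals into pseudo-founders
#'
#' Deletes the sire and dam links of the given animals, so their own ancestry
#' can no longer be traced through them. This is the pruning primitive of the
#' iterative marginal-contribution decomposition: once an ancestor's
#' contribution has been accounted for, its parents' contributions must not be
#' double counted through it. The input pedigree is not modified.
#'
#' @param ped A `Pedigree`.
#' @param animals Ids of animals to convert.
#' @return A new `Pedigree` with identical records except that `animals` have
#'   unknown parents.
#' @export
make_pseudo_founder <- function(ped, animals) {
  idx <- ped_index(ped, animals)
  ped$records$sire[idx] <- NA_character_
  ped$records$dam[idx] <- NA_character_
  ped$sire_idx[idx] <- NA_integer_
  ped$dam_idx[idx] <- NA_integer_
  # removing edges cannot invalidate the cached topological order
  ped
}

# Internal: pedigree as 0/1-based parent arrays in topological order.
# Returns ids (topo order), sire/dam as positions into the topo order (0 =
# unknown), and pos mapping record index -> topo position.
ped_topo_arrays <- function(ped) {
  n <- n_animals(ped)
  pos <- integer(n)
  pos[ped$topo] <- seq_len(n)
  to0 <- function(parent_idx) {
    p <- parent_idx[ped$topo]
    ifelse(is.na(p), 0L, pos[p])
  }
  list(ids = ped$records$animal[ped$topo],
       birth_year = ped$records$birth_year[ped$topo],
       sire = to0(ped$sire_idx), dam = to0(ped$dam_idx), pos = pos)
}

.col_synonyms <- list(
  animal = c("animal", "animal_id", "id"),
  sire = c("sire", "sire_id", "father"),
  dam = c("dam", "dam_id", "mother"),
  birth_year = c("birth_year", "birthyear", "year", "yob"),
  sex = "sex", gait = "gait", role = "role")

#' Read a pedigree from a delimited text file
#'
#' The file must have a header row naming at least the animal, sire and dam
#' columns (synonyms such as `id`, `sire_id`, `year` are recognised). The
#' field separator is auto-detected (tab or comma) unless given. Unknown
#' parents may be encoded as an empty field, `"0"` or `"NA"`.
#'
#' @param path Path to the file.
#' @param sep Field separator; `NULL` (default) auto-detects.
#' @param permissive Passed to [pedigree()]: auto-create founder records for
#'   parent ids that have no row of their own.
#' @return A validated `Pedigree`.
#' @export
read_pedigree <- function(path, sep = NULL, permissive = FALSE) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- read.delim(path, sep = sep, colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(raw) <- tolower(trimws(names(raw)))
  out <- list()
  for (canon in names(.col_synonyms)) {
    hit <- intersect(.col_synonyms[[canon]], names(raw))
    if (length(hit)) out[[canon]] <- raw[[hit[1]]]
  }
  missing_cols <- setdiff(c("animal", "sire", "dam"), names(out))
  if (length(missing_cols)) {
    stop("pedigree file header lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  pedigree(as.data.frame(out, stringsAsFactors = FALSE),
           permissive = permissive)
}

#' Write a pedigree to a delimited text file
#'
#' Rows are emitted deterministically: sorted by generation number (founders
#' first, then each animal after both parents) and id within generation.
#' Unknown parents are written as empty fields.
#'
#' @param ped A `Pedigree`.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path, sep = "\t") {
  df <- ped$records
  gen <- integer(nrow(df))
  for (i in ped$topo) {
    pg <- c(ped$sire_idx[i], ped$dam_idx[i])
    pg <- pg[!is.na(pg)]
    gen[i] <- if (length(pg)) max(gen[pg]) + 1L else 0L
  }
  ord <- order(gen, df$animal)
  df <- df[ord, , drop = FALSE]
  df$sire[is.na(df$sire)] <- ""
  df$dam[is.na(df$dam)] <- ""
  df$birth_year <- ifelse(is.na(df$birth_year), "", df$birth_year)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
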