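## Umami/sweet functional prediction from Tas1r heterodimer logic: the
## Tas1r1-Tas1r3 heterodimer senses umami and the Tas1r2-Tas1r3 heterodimer
## senses sweet, so a modality is predicted functional only when both
## partners have at least one intact gene. Tas1r3 loss therefore knocks out
## both modalities.

# parse repertoire entries like "2", "2(1PS)", "2 (1PS)" into intact/pseudo
.parse_count_entry <- function(x) {
  x <- gsub("\\s+", "", x)
  m <- regmatches(x, regexec("^([0-9]+)(?:\\(([0-9]+)PS\\))?$", x))[[1L]]
  if (!length(m)) .stopf("unparseable count entry: %s", x)
  total <- as.integer(m[2L])
  pseudo <- if (nzchar(m[3L])) as.integer(m[3L]) else 0L
  c(intact = total - pseudo, pseudo = pseudo, total = total)
}

#' Read a Tas1r repertoire table
#'
#' Reads a TSV with per-species `tas1r1`, `tas1r2`, `tas1r3` columns whose
#' entries may carry pseudogene annotations (`"2(1PS)"` means 2 loci, 1 of
#' them a pseudogene, so 1 intact), and resolves them into intact and pseudo
#' counts. The packaged amphibian repertoire table is the default.
#'
#' @param path TSV path; defaults to the packaged fixture.
#' @return data frame with `name`, `species`, intact/pseudo counts per
#'   family, and any `umami`/`sweet` columns present in the file.
#' @export
read_taste_counts <- function(path = system.file("extdata", "tas1r_table1.tsv",
                                                 package = "tastemine")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (fam in c("tas1r1", "tas1r2", "tas1r3")) {
    parsed <- t(vapply(as.character(df[[fam]]), .parse_count_entry, numeric(3)))
    df[[paste0(fam, "_intact")]] <- as.integer(parsed[, "intact"])
    df[[paste0(fam, "_pseudo")]] <- as.integer(parsed[, "pseudo"])
  }
  df
}

#' Predict umami and sweet function from intact Tas1r counts
#'
#' @param tas1r1,tas1r2,tas1r3 intact gene counts (vectors recycle).
#' @param species optional species labels.
#' @param tas1r1_pseudo,tas1r2_pseudo,tas1r3_pseudo pseudogene counts,
#'   carried through for cohort summaries.
#' @return data frame of class `taste_profile` with logical `umami`
#'   (`tas1r1 >= 1` and `tas1r3 >= 1`) and `sweet` (`tas1r2 >= 1` and
#'   `tas1r3 >= 1`).
#' @export
predict_taste <- function(tas1r1, tas1r2, tas1r3, species = NULL,
                          tas1r1_pseudo = 0L, tas1r2_pseudo = 0L,
                          tas1r3_pseudo = 0L) {
  n <- max(length(tas1r1), length(tas1r2), length(tas1r3))
  cnt <- data.frame(
    tas1r1 = rep_len(as.integer(tas1r1), n),
    tas1r2 = rep_len(as.integer(tas1r2), n),
    tas1r3 = rep_len(as.integer(tas1r3), n),
    tas1r1_pseudo = rep_len(as.integer(tas1r1_pseudo), n),
    tas1r2_pseudo = rep_len(as.integer(tas1r2_pseudo), n),
    tas1r3_pseudo = rep_len(as.integer(tas1r3_pseudo), n))
  if (any(as.matrix(cnt) < 0L)) .stopf("gene counts must be non-negative")
  out <- cbind(
    data.frame(species = species %||% sprintf("species%d", seq_len(n)),
               stringsAsFactors = FALSE),
    cnt,
    umami = cnt$tas1r1 >= 1L & cnt$tas1r3 >= 1L,
    sweet = cnt$tas1r2 >= 1L & cnt$tas1r3 >= 1L)
  class(out) <- c("taste_profile", "data.frame")
  out
}

#' Summarise a cohort of taste profiles
#'
#' Tallies how many species lack sweet sensation only, how many lack both
#' umami and sweet, the per-family intact totals, and the total number of
#' pseudogenised or absent Tas1r loci (pseudogene annotations plus
#' family-species cells with no locus at all).
#'
#' @param profiles a `taste_profile` data frame (see [predict_taste()]).
#' @return list with `n_species`, `lost_both`, `lost_sweet_only`,
#'   `lost_umami_only`, `intact_totals`, `pseudo_or_absent`.
#' @export
summarize_cohort <- function(profiles) {
  if (nrow(profiles) == 0L)
    return(list(n_species = 0L, lost_both = 0L, lost_sweet_only = 0L,
                lost_umami_only = 0L,
                intact_totals = c(tas1r1 = 0L, tas1r2 = 0L, tas1r3 = 0L),
                pseudo_or_absent = 0L))
  intact <- as.matrix(profiles[, c("tas1r1", "tas1r2", "tas1r3")])
  pseudo <- as.matrix(profiles[, c("tas1r1_pseudo", "tas1r2_pseudo",
                                   "tas1r3_pseudo")])
  absent <- (intact + pseudo) == 0L
  list(
    n_species = nrow(profiles),
    lost_both = sum(!profiles$umami & !profiles$sweet),
    lost_sweet_only = sum(profiles$umami & !profiles$sweet),
    lost_umami_only = sum(!profiles$umami & profiles$sweet),
    intact_totals = c(tas1r1 = sum(intact[, 1L]), tas1r2 = sum(intact[, 2L]),
                      tas1r3 = sum(intact[, 3L])),
    pseudo_or_absent = sum(pseudo) + sum(absent)
  )
}
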