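## Pipeline orchestration and reporting: repertoire summary tables,
## recovery scoring against simulation truth, simple standard-format writers
## and the end-to-end `run_pipeline()` driver.

#' Summarise a receptor repertoire
#'
#' Per species: intact, partial and pseudogene counts, total, and the
#' pseudogene percentage (1 decimal place). Accepts either classified
#' `gene_models` (with an optional `species` column) or a named count
#' vector `c(intact =, partial =, pseudo =)`.
#'
#' @param x `gene_models` data frame or named counts.
#' @param species species label(s) used when `x` has no species column.
#' @return data frame of class `repertoire_summary` with the identity
#'   `total = intact + partial + pseudo` asserted.
#' @export
summarize_repertoire <- function(x, species = "species1") {
  if (is.numeric(x)) {
    df <- data.frame(species = species,
                     intact = as.integer(x[["intact"]] %||% 0),
                     partial = as.integer(x[["partial"]] %||% 0),
                     pseudo = as.integer(x[["pseudo"]] %||% 0),
                     stringsAsFactors = FALSE)
  } else {
    sp <- if ("species" %in% names(x)) x$species else
      rep_len(species, nrow(x))
    tab <- table(factor(sp),
                 factor(x$category, levels = c("INTACT", "PARTIAL", "PSEUDO",
                                               "SHORT")))
    df <- data.frame(species = rownames(tab),
                     intact = as.integer(tab[, "INTACT"]),
                     partial = as.integer(tab[, "PARTIAL"]),
                     pseudo = as.integer(tab[, "PSEUDO"]),
                     short = as.integer(tab[, "SHORT"]),
                     stringsAsFactors = FALSE)
  }
  df$total <- df$intact + df$partial + df$pseudo
  stopifnot(df$total == df$intact + df$partial + df$pseudo)
  df$pseudo_pct <- round(100 * df$pseudo / pmax(df$total, 1L), 1)
  class(df) <- c("repertoire_summary", "data.frame")
  df
}

#' Score annotated models against simulation truth
#'
#' Matches each truth record to models on the same contig overlapping at
#' least half of the planted interval, and reports presence precision and
#' recall plus category accuracy over recovered plants.
#'
#' @param models `gene_models` from [annotate_loci()].
#' @param truth truth table from [simulate_genome()].
#' @return list with `recall`, `precision`, `category_accuracy`,
#'   `n_truth`, `n_models`, and the per-plant match table.
#' @export
evaluate_recovery <- function(models, truth) {
  n_truth <- nrow(truth); n_models <- nrow(models)
  if (n_truth == 0L)
    return(list(recall = NA_real_, precision = if (n_models) 0 else NA_real_,
                category_accuracy = NA_real_, n_truth = 0L,
                n_models = n_models, matches = NULL))
  match_row <- function(i) {
    tr <- truth[i, ]
    cand <- which(models$contig == tr$contig &
                    pmin(models$end, tr$end) - pmax(models$start, tr$start) >=
                    0.5 * (tr$end - tr$start))
    if (!length(cand)) return(c(NA_integer_, 0L))
    j <- cand[which.max(pmin(models$end[cand], tr$end) -
                          pmax(models$start[cand], tr$start))]
    c(j, as.integer(models$category[j] == tr$category))
  }
  mm <- t(vapply(seq_len(n_truth), match_row, integer(2)))
  found <- !is.na(mm[, 1L])
  used <- unique(mm[found, 1L])
  list(
    recall = mean(found),
    precision = if (n_models) length(used) / n_models else NA_real_,
    category_accuracy = if (any(found)) mean(mm[found, 2L]) else NA_real_,
    n_truth = n_truth, n_models = n_models,
    matches = data.frame(gene_id = truth$gene_id, model_row = mm[, 1L],
                         category_ok = mm[, 2L] == 1L,
                         stringsAsFactors = FALSE)
  )
}

#' Write gene models as GFF3
#'
#' Converts the package's 0-based half-open coordinates to GFF3's 1-based
#' inclusive convention; category, TM count and disruptions are emitted as
#' attributes.
#'
#' @param models `gene_models`.
#' @param file output path.
#' @export
write_gff3 <- function(models, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    attrs <- sprintf("ID=%s;category=%s;tm_count=%d;disruptions=%s",
                     m$gene_name %||% m$locus_id, m$category, m$tm_count,
                     if (nzchar(m$disruptions)) m$disruptions else ".")
    writeLines(sprintf("%s\ttastemine\tgene\t%d\t%d\t%.1f\t%s\t.\t%s",
                       m$contig, m$start + 1L, m$end, m$score, m$strand,
                       attrs), con)
  }
  invisible(file)
}

#' Write sequences as FASTA
#' @param seqs named character vector of sequences.
#' @param file output path.
#' @param type `"AA"` or `"DNA"`.
#' @export
write_fasta <- function(seqs, file, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(unlist(seqs))
  else Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(set, file)
  invisible(file)
}

#' Read flanking-marker annotations
#'
#' Accepts a TSV with columns `marker`, `contig`, `start`, `end`
#' (0-based half-open) or a GFF3 file (converted from 1-based inclusive;
#' the marker symbol is taken from the `ID` or `Name` attribute).
#'
#' @param path input path.
#' @return data frame with `marker`, `contig`, `start`, `end`.
#' @export
read_marker_annotations <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
    f <- strsplit(ln, "\t", fixed = TRUE)
    bad <- vapply(f, length, integer(1)) != 9L
    if (any(bad)) .stopf("malformed GFF3 line: %s", ln[bad][1L])
    attrs <- vapply(f, `[[`, character(1), 9L)
    id <- sub(".*(?:^|;)(?:ID|Name)=([^;]+).*", "\\1", attrs)
    return(data.frame(marker = id,
                      contig = vapply(f, `[[`, character(1), 1L),
                      start = as.integer(vapply(f, `[[`, character(1), 4L)) - 1L,
                      end = as.integer(vapply(f, `[[`, character(1), 5L)),
                      stringsAsFactors = FALSE))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker", "contig", "start", "end")
  if (!all(need %in% names(df)))
    .stopf("marker TSV needs columns: %s", paste(need, collapse = ", "))
  df
}

#' Run the mining pipeline end to end
#'
#' Executes the configured stages in order: `simulate` (synthetic genome) or
#' input loading, `search` (translated search, filter, merge, extend),
#' `annotate` (gene models + classification), `synteny` (marker-based status
#' calls when markers are available), and `report` (repertoire summary and,
#' for synthetic input, recovery metrics). Outputs are written as
#' TSV/FASTA/GFF3 under `out_dir`. Re-running with an identical
#' configuration and seed reproduces the outputs exactly.
#'
#' @param config a list, or path to a YAML file, with elements `seed`,
#'   `species`, either `sim` (a list of [sim_spec()] arguments) or `genome` +
#'   `queries` (FASTA paths), and optional `search` ([search_params()]
#'   overrides) and `stages` (character subset of
#'   `c("simulate","search","annotate","synteny","report")`).
#' @param out_dir output directory (created if needed); `NULL` disables
#'   file output.
#' @return list with the produced objects (`sim`, `hits`, `loci`, `models`,
#'   `summary`, `status`, `recovery` as applicable).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages %||% c("simulate", "search", "annotate", "synteny",
                                 "report")
  seed <- config$seed %||% 1L
  species <- config$species %||% "Synthetica exemplaris"
  res <- list()
  log <- function(stage, msg) message(sprintf("[%s] %s", stage, msg))

  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(obj, fname, writer) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, fname))
  }
  write_tsv <- function(df, path)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

  if ("simulate" %in% stages) {
    sim_args <- config$sim %||% list()
    sim_args$seed <- sim_args$seed %||% seed
    sim <- simulate_genome(do.call(sim_spec, sim_args))
    res$sim <- sim
    genome <- sim$genome
    queries <- vapply(as.list(sim$queries), as.character, character(1))
    log("simulate", sprintf("%d contigs, %d planted genes",
                            length(genome), nrow(sim$truth)))
    emit(sim$truth, "truth.tsv", write_tsv)
    if (!is.null(out_dir))
      Biostrings::writeXStringSet(genome, file.path(out_dir, "genome.fa"))
  } else {
    if (is.null(config$genome)) .stopf("pipeline config missing field: genome")
    if (is.null(config$queries)) .stopf("pipeline config missing field: queries")
    genome <- Biostrings::readDNAStringSet(config$genome)
    queries <- vapply(as.list(Biostrings::readAAStringSet(config$queries)),
                      as.character, character(1))
  }

  params <- do.call(search_params, config$search %||% list())
  if ("search" %in% stages) {
    hits <- search_genome(queries, genome, params)
    hits <- filter_hits(hits, params)
    loci <- merge_hits(hits, params)
    loci <- extend_locus(loci, params, contig_lengths(genome))
    res$hits <- hits; res$loci <- loci
    log("search", sprintf("%d hits -> %d loci", nrow(hits), nrow(loci)))
    emit(hits, "hits.tsv", write_tsv)
    emit(loci, "loci.tsv", write_tsv)
  }

  if ("annotate" %in% stages) {
    if (is.null(res$loci)) .stopf("annotate stage requires the search stage")
    models <- annotate_loci(res$loci, genome, queries)
    models <- assign_gene_names(models, species, config$family %||% "Tas2r")
    res$models <- models
    log("annotate", sprintf("%d models (%s)", nrow(models),
                            paste(sprintf("%s=%d", names(table(models$category)),
                                          table(models$category)),
                                  collapse = ", ")))
    emit(models[setdiff(names(models), "protein")], "models.tsv", write_tsv)
    if (!is.null(out_dir)) {
      write_gff3(models, file.path(out_dir, "models.gff3"))
      write_fasta(stats::setNames(models$protein, models$gene_name),
                  file.path(out_dir, "proteins.fa"), "AA")
    }
  }

  if ("synteny" %in% stages && !is.null(res$models)) {
    markers <- if (!is.null(config$markers))
      read_marker_annotations(config$markers)
    else if (!is.null(res$sim) && nrow(res$sim$markers)) res$sim$markers
    if (!is.null(markers) && nrow(markers)) {
      res$marker_annotations <- markers
      log("synteny", sprintf("%d marker annotations loaded", nrow(markers)))
    }
  }

  if ("report" %in% stages && !is.null(res$models)) {
    res$summary <- summarize_repertoire(res$models, species)
    emit(res$summary, "summary.tsv", write_tsv)
    if (!is.null(res$sim)) {
      res$recovery <- evaluate_recovery(res$models, res$sim$truth)
      log("report", sprintf(
        "recovery: recall %.3f, precision %.3f, category accuracy %.3f",
        res$recovery$recall, res$recovery$precision,
        res$recovery$category_accuracy))
    }
  }
  res
}
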