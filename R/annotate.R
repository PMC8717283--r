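## Gene-model building: guided ORF extraction from candidate loci, detection
## of coding disruptions (premature stops, frameshifts), Kyte-Doolittle
## seven-transmembrane screening, and the intact / partial / pseudogene
## classification with its precedence rules. Pseudogene evidence (a positive
## disruption) outranks truncation evidence (which is only missing data).

#' Count transmembrane segments by Kyte-Doolittle hydropathy
#'
#' Sliding-window mean hydropathy; maximal runs of above-threshold windows,
#' separated from the next run by at least `min_gap` window positions, count
#' as one transmembrane segment each.
#'
#' @param protein amino-acid string.
#' @param window window length (residues).
#' @param threshold hydropathy threshold for a window to count as membrane.
#' @param min_gap runs closer than this many windows are merged.
#' @return integer segment count (0 for proteins shorter than `window`).
#' @export
count_tm_segments <- function(protein, window = 19L, threshold = 1.6,
                              min_gap = 3L) {
  aa <- .chars(protein)
  n <- length(aa)
  if (n < window) return(0L)
  h <- .KD[aa]
  h[is.na(h)] <- 0
  cs <- c(0, cumsum(h))
  means <- (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
  above <- means >= threshold
  if (!any(above)) return(0L)
  r <- rle(above)
  # merge above-runs separated by short below-runs
  segs <- 0L; gap_since <- Inf
  for (i in seq_along(r$lengths)) {
    if (r$values[i]) {
      if (gap_since >= min_gap) segs <- segs + 1L
      gap_since <- 0
    } else gap_since <- gap_since + r$lengths[i]
  }
  segs
}

## ---- guided extraction ----------------------------------------------------

# All ORF-like candidates in the 3 frames of an oriented locus sequence:
# complete ORFs (ATG..stop), an open-ended tail (ATG.. locus end, no stop)
# and an open-ended head (locus start .. first stop, start possibly missing).
.orf_candidates <- function(locus_seq) {
  out <- list()
  L <- nchar(locus_seq)
  for (f in 0:2) {
    aa <- translate_nt(substr(locus_seq, f + 1L, L))
    n <- nchar(aa)
    if (n < 20L) next
    ch <- .chars(aa)
    stops <- which(ch == "*")
    ms <- which(ch == "M")
    bounds <- c(0L, stops)
    add <- function(p_from, p_to, has_start, has_stop) {
      prot <- substr(aa, p_from, p_to)
      if (nchar(prot) < 30L) return()
      # nt interval in locus coords, incl. stop codon when present
      nt_from <- f + 3L * (p_from - 1L)
      nt_to <- f + 3L * (p_to + as.integer(has_stop))
      out[[length(out) + 1L]] <<- list(
        frame = f, protein = prot, start = nt_from, end = min(nt_to, L),
        has_start = has_start, has_stop = has_stop)
    }
    # complete ORFs: first M after the previous stop, up to each stop
    for (s in stops) {
      prev <- max(bounds[bounds < s])
      m <- ms[ms > prev & ms < s]
      if (length(m)) add(m[1L], s - 1L, TRUE, TRUE)
    }
    # head: locus start to first stop (start codon may be missing)
    if (length(stops)) {
      add(1L, stops[1L] - 1L, ch[1L] == "M", TRUE)
    }
    # tail: first M after the last stop, to the locus end (stop missing)
    last <- if (length(stops)) stops[length(stops)] else 0L
    m <- ms[ms > last]
    if (length(m)) add(m[1L], n, ch[1L] == "M" && last == 0L, FALSE)
    if (!length(stops)) add(1L, n, ch[1L] == "M", FALSE)
  }
  out
}

#' Extract the gene model of a candidate locus guided by its best query
#'
#' Enumerates ORF-like candidates in the three reading frames of the oriented
#' locus sequence and returns the one maximising local alignment score to the
#' guide protein: the maximal complete ORF when present, otherwise the
#' open-ended translation to the locus boundary.
#'
#' @param locus_seq locus nucleotide string, already oriented (5'->3' on the
#'   gene's strand).
#' @param guide guide protein (best-scoring query).
#' @param floor_score loci whose best candidate scores below this are
#'   dropped (`NULL` is returned).
#' @return `NULL`, or a list with `start`, `end` (0-based half-open, locus
#'   coords), `frame`, `protein`, `has_start`, `has_stop`, `score`.
#' @export
extract_gene_model <- function(locus_seq, guide, floor_score = 60) {
  cands <- .orf_candidates(locus_seq)
  if (!length(cands)) return(NULL)
  scores <- vapply(cands, function(cc)
    .protein_local_align(guide, cc$protein)$score, numeric(1))
  lens <- vapply(cands, function(cc) nchar(cc$protein), numeric(1))
  ord <- order(-scores, -lens, vapply(cands, `[[`, numeric(1), "start"))
  best <- cands[[ord[1L]]]
  if (scores[ord[1L]] < floor_score) return(NULL)
  best$score <- scores[ord[1L]]
  # the maximal ORF may begin at a chance upstream in-frame ATG in the
  # flank; trim the start to the methionine the guide alignment points at
  if (best$has_start) {
    al <- .protein_local_align(guide, best$protein)
    est <- al$s_start - (al$p_start - 1L)
    if (est > 1L && substr(best$protein, est, est) == "M") {
      best$protein <- substr(best$protein, est, nchar(best$protein))
      best$start <- best$start + 3L * (est - 1L)
    }
  }
  best
}

## ---- disruption detection -------------------------------------------------

# iterative masked local alignments of guide against one frame translation
.frame_segments <- function(guide, aa, frame, seg_floor, max_iter = 4L) {
  segs <- list()
  subj <- aa
  for (i in seq_len(max_iter)) {
    if (nchar(gsub("[*]", "", subj)) < 10L) break
    al <- .protein_local_align(guide, subj)
    if (al$score < seg_floor) break
    segs[[length(segs) + 1L]] <- data.frame(
      frame = frame, q_start = al$p_start, q_end = al$p_end,
      s_start = al$s_start, s_end = al$s_end, score = al$score)
    # mask the found region so the next-best segment can surface
    masked <- strrep("*", al$s_end - al$s_start + 1L)
    subj <- paste0(substr(subj, 1L, al$s_start - 1L), masked,
                   substr(subj, al$s_end + 1L, nchar(subj)))
  }
  segs
}

#' Detect coding disruptions in a candidate locus
#'
#' Aligns the guide protein against the three frame translations of the
#' oriented locus (iteratively, so several segments per frame can be found),
#' chains the segments along the guide, and reports every in-frame stop codon
#' before the expected C-terminus as a premature stop and every frame
#' transition between chained segments as a frameshift (with the implied
#' indel length modulo 3).
#'
#' @param locus_seq oriented locus nucleotide string.
#' @param guide guide protein.
#' @param seg_floor minimum alignment score for a chained segment.
#' @return data frame with columns `kind` (`PREMATURE_STOP`/`FRAMESHIFT`),
#'   `position` (1-based codon index from the inferred coding start for
#'   stops; nt offset for frameshifts) and `len_mod3` (frameshifts only).
#'   The chained gene span (locus nt coords) is attached as attribute
#'   `span`.
#' @export
detect_disruptions <- function(locus_seq, guide, seg_floor = 35) {
  L <- nchar(locus_seq)
  gl <- nchar(guide)
  segs <- list()
  frame_aa <- character(3)
  for (f in 0:2) {
    frame_aa[f + 1L] <- translate_nt(substr(locus_seq, f + 1L, L))
    segs <- c(segs, .frame_segments(guide, frame_aa[f + 1L], f, seg_floor))
  }
  empty <- data.frame(kind = character(0), position = integer(0),
                      len_mod3 = integer(0), stringsAsFactors = FALSE)
  if (!length(segs)) return(structure(empty, span = c(NA_integer_, NA_integer_)))
  segs <- do.call(rbind, segs)
  # nt coordinates of segments in locus space
  segs$nt_start <- segs$frame + 3L * (segs$s_start - 1L)
  segs$nt_end <- segs$frame + 3L * segs$s_end
  # chain along the guide: greedy by score, keep mutually consistent segments
  segs <- segs[order(-segs$score), , drop = FALSE]
  chain <- segs[1L, , drop = FALSE]
  rejected <- list()
  for (i in seq_len(nrow(segs))[-1L]) {
    s <- segs[i, , drop = FALSE]
    ok <- TRUE
    for (j in seq_len(nrow(chain))) {
      c_ <- chain[j, , drop = FALSE]
      q_olap <- min(s$q_end, c_$q_end) - max(s$q_start, c_$q_start) + 1L
      nt_olap <- min(s$nt_end, c_$nt_end) - max(s$nt_start, c_$nt_start)
      nt_allow <- min(60, 0.3 * min(s$nt_end - s$nt_start, c_$nt_end - c_$nt_start))
      # must extend coverage and be collinear in guide and locus; small
      # boundary overlaps (alignment slop at breakpoints) are tolerated
      if (q_olap > 0.3 * (s$q_end - s$q_start + 1L) || nt_olap > nt_allow ||
          xor(s$q_start < c_$q_start, s$nt_start < c_$nt_start)) { ok <- FALSE; break }
    }
    if (ok) chain <- rbind(chain, s) else rejected[[length(rejected) + 1L]] <- s
  }
  chain <- chain[order(chain$q_start), , drop = FALSE]

  # a strong different-frame segment nested inside a chained segment means
  # the aligner bridged a double frameshift (net in-frame indels): the gene
  # enters the nested frame and returns, i.e. two frameshifts
  nested <- list()
  for (s in rejected) {
    if (s$score < 60) next
    for (j in seq_len(nrow(chain))) {
      c_ <- chain[j, , drop = FALSE]
      if (s$frame != c_$frame &&
          s$nt_start > c_$nt_start + 15L && s$nt_end < c_$nt_end - 15L &&
          s$q_start >= c_$q_start && s$q_end <= c_$q_end) {
        nested[[length(nested) + 1L]] <- list(host_frame = c_$frame, seg = s)
        break
      }
    }
  }

  # inferred coding start (codon 1 of the guide) in locus nt coords
  coding_start <- chain$nt_start[1L] - 3L * (chain$q_start[1L] - 1L)
  disr <- empty
  add_stops <- function(frame, nt_from, nt_to) {
    # report '*' codons in [nt_from, nt_to) read in `frame`
    if (nt_to <= nt_from) return()
    p_from <- (nt_from - frame) %/% 3L + 1L
    p_to <- (nt_to - frame) %/% 3L
    if (p_to < p_from) return()
    aa <- .chars(substr(frame_aa[frame + 1L], p_from, p_to))
    for (w in which(aa == "*")) {
      nt <- frame + 3L * (p_from + w - 2L)
      codon <- (nt - coding_start) %/% 3L + 1L
      if (codon < gl - 5L && codon >= 1L)
        disr <<- rbind(disr, data.frame(kind = "PREMATURE_STOP",
                                        position = codon, len_mod3 = 0L,
                                        stringsAsFactors = FALSE))
    }
  }
  for (j in seq_len(nrow(chain))) {
    c_ <- chain[j, , drop = FALSE]
    # stops inside the aligned segment itself
    add_stops(c_$frame, c_$nt_start, c_$nt_end)
    if (j == nrow(chain)) break
    nxt <- chain[j + 1L, , drop = FALSE]
    if (nxt$frame == c_$frame) {
      add_stops(c_$frame, c_$nt_end, nxt$nt_start)
    } else {
      shift <- (c_$frame - nxt$frame) %% 3L
      disr <- rbind(disr, data.frame(kind = "FRAMESHIFT",
                                     position = c_$nt_end - coding_start,
                                     len_mod3 = shift,
                                     stringsAsFactors = FALSE))
    }
  }
  for (ns in nested) {
    s <- ns$seg
    disr <- rbind(disr,
                  data.frame(kind = "FRAMESHIFT",
                             position = s$nt_start - coding_start,
                             len_mod3 = (ns$host_frame - s$frame) %% 3L,
                             stringsAsFactors = FALSE),
                  data.frame(kind = "FRAMESHIFT",
                             position = s$nt_end - coding_start,
                             len_mod3 = (s$frame - ns$host_frame) %% 3L,
                             stringsAsFactors = FALSE))
    # stops inside the nested (true-frame) region
    add_stops(s$frame, s$nt_start, s$nt_end)
  }
  # a stop immediately after the last segment, before the expected C-terminus
  lastc <- chain[nrow(chain), , drop = FALSE]
  if (lastc$q_end < gl - 5L)
    add_stops(lastc$frame, lastc$nt_end, min(L, lastc$nt_end + 9L))
  disr <- disr[order(disr$position), , drop = FALSE]
  disr <- disr[!duplicated(disr[c("kind", "position")]), , drop = FALSE]
  rownames(disr) <- NULL
  structure(disr, span = c(min(chain$nt_start), max(chain$nt_end)))
}

## ---- classification -------------------------------------------------------

#' Classify a gene model as intact, partial, pseudogene or short
#'
#' Applies the repertoire-mining rules: a gene is `INTACT` when its protein
#' exceeds 270 aa with both start and stop codons, no disruptions, and at
#' least 7 transmembrane segments; `PSEUDO` when any disruption is present or
#' a complete ORF fails the transmembrane screen (disruption evidence
#' outranks truncation evidence); `PARTIAL` when the start or stop is missing
#' and the truncation coincides with a contig edge; `SHORT` for clean
#' complete ORFs of 270 aa or less (reported, not counted intact).
#'
#' @param protein model protein string.
#' @param has_start,has_stop does the ORF have a start / stop codon?
#' @param disruptions data frame from [detect_disruptions()] (or `NULL`).
#' @param tm_count transmembrane segment count from [count_tm_segments()].
#' @param truncated_at_edge is the missing end at a contig edge or gap?
#' @return one of `"INTACT"`, `"PARTIAL"`, `"PSEUDO"`, `"SHORT"`.
#' @export
classify_gene <- function(protein, has_start, has_stop, disruptions = NULL,
                          tm_count = NA_integer_, truncated_at_edge = FALSE) {
  if (!is.null(disruptions) && nrow(disruptions) > 0L) return("PSEUDO")
  if (!has_start || !has_stop)
    return(if (truncated_at_edge) "PARTIAL" else "PSEUDO")
  if (nchar(protein) > 270L) {
    if (!is.na(tm_count) && tm_count < 7L) return("PSEUDO")
    return("INTACT")
  }
  "SHORT"
}

#' Annotate candidate loci into classified gene models
#'
#' Driver over [extract_gene_model()], [detect_disruptions()],
#' [count_tm_segments()] and [classify_gene()]: extracts each locus sequence
#' (oriented by the locus strand), builds the model guided by the locus's
#' best query, and classifies it. Loci with no candidate above the alignment
#' floor are dropped.
#'
#' @param loci `candidate_loci` (typically flank-extended).
#' @param genome the genome searched (same accepted forms as
#'   [search_genome()]).
#' @param queries the query proteins used in the search.
#' @param floor_score see [extract_gene_model()].
#' @return data frame of class `gene_models`: one row per retained locus with
#'   contig, forward-strand coordinates, strand, category, protein, tm_count
#'   and disruption summary.
#' @export
annotate_loci <- function(loci, genome, queries, floor_score = 60) {
  if (inherits(genome, "genome_sim")) genome <- genome$genome
  genome <- vapply(as.list(genome), as.character, character(1))
  queries <- vapply(as.list(queries), as.character, character(1))
  out <- list()
  for (i in seq_len(nrow(loci))) {
    lc <- loci[i, , drop = FALSE]
    contig <- genome[[lc$contig]]
    clen <- nchar(contig)
    seq <- substr(contig, lc$start + 1L, lc$end)
    if (lc$strand == "-") seq <- revcomp(seq)
    guide <- queries[[lc$best_query]]
    model <- extract_gene_model(seq, guide, floor_score)
    if (is.null(model)) next
    disr <- detect_disruptions(seq, guide)
    span <- attr(disr, "span")
    # coding interval in locus coords: disruption-chain span for disrupted
    # loci, the selected ORF otherwise
    if (nrow(disr) > 0L && !anyNA(span)) {
      c_from <- min(model$start, span[1L]); c_to <- max(model$end, span[2L])
    } else { c_from <- model$start; c_to <- model$end }
    # locus coords -> forward contig coords
    if (lc$strand == "+") {
      g_start <- lc$start + c_from; g_end <- lc$start + c_to
      miss_start_at_edge <- lc$start == 0L && c_from <= 2L
      miss_stop_at_edge <- lc$end == clen && c_to >= nchar(seq) - 2L
    } else {
      g_start <- lc$end - c_to; g_end <- lc$end - c_from
      miss_start_at_edge <- lc$end == clen && c_from <= 2L
      miss_stop_at_edge <- lc$start == 0L && c_to >= nchar(seq) - 2L
    }
    truncated_at_edge <- (!model$has_start && miss_start_at_edge) ||
      (!model$has_stop && miss_stop_at_edge)
    tm <- count_tm_segments(model$protein)
    category <- classify_gene(model$protein, model$has_start, model$has_stop,
                              disr, tm, truncated_at_edge)
    out[[length(out) + 1L]] <- data.frame(
      locus_id = lc$locus_id, contig = lc$contig, strand = lc$strand,
      start = g_start, end = g_end, category = category,
      protein = model$protein, aa_len = nchar(model$protein),
      has_start = model$has_start, has_stop = model$has_stop,
      tm_count = tm, n_disruptions = nrow(disr),
      disruptions = paste(sprintf("%s@%d", disr$kind, disr$position),
                          collapse = ";"),
      best_query = lc$best_query, score = model$score,
      stringsAsFactors = FALSE)
  }
  models <- if (length(out)) do.call(rbind, out) else
    data.frame(locus_id = character(0), contig = character(0),
               strand = character(0), start = integer(0), end = integer(0),
               category = character(0), protein = character(0),
               aa_len = integer(0), has_start = logical(0),
               has_stop = logical(0), tm_count = integer(0),
               n_disruptions = integer(0), disruptions = character(0),
               best_query = character(0), score = numeric(0),
               stringsAsFactors = FALSE)
  rownames(models) <- NULL
  class(models) <- c("gene_models", "data.frame")
  models
}

## ---- partial-locus disambiguation, reciprocal check, nomenclature ---------

#' Group partial gene fragments into inferred loci
#'
#' Aligns each partial-model protein to the guide: fragments whose aligned
#' guide regions overlap must come from different gene loci and are kept
#' separate; fragments covering disjoint, complementary guide regions are
#' fused into one inferred locus.
#'
#' @param proteins character vector of partial-fragment proteins.
#' @param guide guide protein.
#' @return integer vector of locus group ids, one per fragment.
#' @export
deduplicate_partials <- function(proteins, guide) {
  n <- length(proteins)
  if (n == 0L) return(integer(0))
  iv <- t(vapply(proteins, function(p) {
    al <- .protein_local_align(guide, p)
    c(al$p_start, al$p_end)
  }, numeric(2)))
  ord <- order(iv[, 1L])
  group <- integer(n)
  open <- list() # per group: covered guide intervals
  for (i in ord) {
    placed <- FALSE
    for (g in seq_along(open)) {
      olap <- vapply(open[[g]], function(ab)
        min(ab[2L], iv[i, 2L]) - max(ab[1L], iv[i, 1L]) + 1L, numeric(1))
      if (all(olap <= 0)) {
        open[[g]] <- c(open[[g]], list(iv[i, ]))
        group[i] <- g; placed <- TRUE; break
      }
    }
    if (!placed) {
      open[[length(open) + 1L]] <- list(iv[i, ])
      group[i] <- length(open)
    }
  }
  group
}

#' Verify family assignment by reciprocal best hit against a reference panel
#'
#' Scores the protein against every panel member; the best-scoring member's
#' family is returned, or `"REJECTED"` when the best hit belongs to a decoy
#' family (e.g. vomeronasal receptors, the nearest GPCR relatives of the
#' taste receptors).
#'
#' @param protein query protein string.
#' @param panel named character vector of reference proteins.
#' @param families character vector of family labels, one per panel member.
#' @param decoys family labels treated as decoys.
#' @return a family label or `"REJECTED"`.
#' @export
reciprocal_verify <- function(protein, panel, families,
                              decoys = c("V1R", "V2R")) {
  if (!length(panel)) .stopf("reference panel is empty")
  stopifnot(length(panel) == length(families))
  scores <- vapply(panel, function(ref)
    .protein_local_align(protein, ref)$score, numeric(1))
  fam <- families[which.max(scores)]
  if (fam %in% decoys) "REJECTED" else fam
}

#' Assign gene names in genomic order
#'
#' Builds the four-letter species prefix (first two letters of the genus +
#' first two of the epithet, capitalised `Xxxx`) and numbers genes
#' consecutively in genomic order, e.g. `Lele_Tas2r1`.
#'
#' @param models `gene_models` for one species.
#' @param species binomial species name, e.g. `"Leptobrachium leishanense"`.
#' @param family gene family label, e.g. `"Tas2r"`.
#' @param existing_prefixes named character vector (prefix -> species) of
#'   prefixes already in use; a collision with a different species errors.
#' @return `models` with a `gene_name` column; the prefix as attribute
#'   `prefix`.
#' @export
assign_gene_names <- function(models, species, family = "Tas2r",
                              existing_prefixes = character(0)) {
  parts <- strsplit(trimws(species), "\\s+")[[1L]]
  if (length(parts) < 2L) .stopf("species must be a binomial name: %s", species)
  prefix <- paste0(toupper(substr(parts[1L], 1L, 1L)),
                   tolower(substr(parts[1L], 2L, 2L)),
                   tolower(substr(parts[2L], 1L, 2L)))
  clash <- names(existing_prefixes) == prefix &
    existing_prefixes != species
  if (any(clash))
    .stopf("gene-name prefix collision: %s already used by %s", prefix,
           existing_prefixes[clash][1L])
  if (nrow(models) == 0L) {
    models$gene_name <- character(0)
    return(structure(models, prefix = prefix))
  }
  ord <- order(models$contig, models$start)
  models$gene_name <- NA_character_
  models$gene_name[ord] <- sprintf("%s_%s%d", prefix, family,
                                   seq_len(nrow(models)))
  structure(models, prefix = prefix)
}
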