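## Translated homology search: protein queries against six-frame genome
## translations (seeded word matching + ungapped X-drop extension, BLOSUM62
## scored), then the repertoire-mining filter/merge/extend rules: hits under
## 100 nt discarded, overlapping hits merged into loci, loci extended 500 nt
## both ways. All genomic coordinates are 0-based half-open, forward strand.

#' Search parameters
#'
#' @param min_hit_len minimum genomic span of a hit in nt (hits strictly
#'   shorter are discarded; the default keeps 100 nt hits).
#' @param flank nt added to both ends of a merged locus.
#' @param word_size seed word length (amino acids).
#' @param min_score minimum raw alignment score for a hit.
#' @param min_score_per_res minimum score per aligned residue; together with
#'   `min_score` this is the deterministic stand-in for an e-value cutoff
#'   (`evalue_meta` is carried as configuration metadata only).
#' @param x_drop ungapped extension stops when the running score falls this
#'   far below the running maximum.
#' @param frameshift_gap hits on the same contig and strand in different
#'   frames separated by at most this many nt are merged into one locus, so
#'   frameshifted pseudogenes present as a single candidate locus.
#' @param evalue_meta nominal e-value threshold, metadata only.
#' @return an object of class `search_params`.
#' @export
search_params <- function(min_hit_len = 100L, flank = 500L, word_size = 4L,
                          min_score = 60, min_score_per_res = 1.5,
                          x_drop = 40, frameshift_gap = 50L,
                          evalue_meta = 1e-10) {
  stopifnot(min_hit_len > 0, flank >= 0, word_size >= 2, x_drop > 0)
  structure(list(min_hit_len = as.integer(min_hit_len),
                 flank = as.integer(flank), word_size = as.integer(word_size),
                 min_score = min_score, min_score_per_res = min_score_per_res,
                 x_drop = x_drop, frameshift_gap = as.integer(frameshift_gap),
                 evalue_meta = evalue_meta),
            class = "search_params")
}

#' Six-frame translation with coordinate maps
#'
#' Translates a contig in the three forward and three reverse-complement
#' frames. Stop codons are rendered as `*`. Use [frame_to_nt()] to convert a
#' protein position in any frame back to its forward-strand nt interval.
#'
#' @param contig nucleotide string (or `DNAString`) over `A,C,G,T,N`.
#' @return a list of six records, each with `strand` (`+`/`-`), `frame`
#'   (0-2) and `aa` (protein string); the contig length is attached as
#'   attribute `contig_len`.
#' @export
sixframe_translate <- function(contig) {
  contig <- toupper(as.character(contig))
  L <- nchar(contig)
  rc <- if (L) revcomp(contig) else ""
  frames <- list()
  for (f in 0:2) {
    frames[[length(frames) + 1L]] <-
      list(strand = "+", frame = f,
           aa = if (L > f) translate_nt(substr(contig, f + 1L, L)) else "")
    frames[[length(frames) + 1L]] <-
      list(strand = "-", frame = f,
           aa = if (L > f) translate_nt(substr(rc, f + 1L, L)) else "")
  }
  attr(frames, "contig_len") <- L
  frames
}

#' Map a protein-frame position range to a forward-strand nt interval
#'
#' @param strand `"+"` or `"-"`.
#' @param frame frame offset 0-2.
#' @param p_start,p_end 1-based protein positions (inclusive range).
#' @param contig_len contig length in nt.
#' @return integer `c(start, end)`, 0-based half-open forward-strand.
#' @export
frame_to_nt <- function(strand, frame, p_start, p_end, contig_len) {
  s <- frame + 3L * (p_start - 1L)
  e <- frame + 3L * p_end
  if (strand == "+") c(s, e) else c(contig_len - e, contig_len - s)
}

.empty_hits <- function() {
  structure(data.frame(query = character(0), contig = character(0),
                       strand = character(0), frame = integer(0),
                       start = integer(0), end = integer(0),
                       length_nt = integer(0), score = numeric(0),
                       q_start = integer(0), q_end = integer(0),
                       stringsAsFactors = FALSE),
            class = c("search_hits", "data.frame"))
}

# ungapped X-drop extension of one seed along a diagonal score vector v
# (v[i] = score of aligning query residue qlo+i-1 with its diagonal partner);
# returns c(lo, hi, score) in v-index space or NULL
.xdrop_extend <- function(v, seed_lo, seed_hi, x_drop) {
  n <- length(v)
  # right extension
  hi <- seed_hi; run <- 0; best <- 0
  j <- seed_hi
  while (j < n) {
    j <- j + 1L
    run <- run + v[j]
    if (run > best) { best <- run; hi <- j }
    if (run < best - x_drop) break
  }
  # left extension
  lo <- seed_lo; run <- 0; best <- 0
  j <- seed_lo
  while (j > 1L) {
    j <- j - 1L
    run <- run + v[j]
    if (run > best) { best <- run; lo <- j }
    if (run < best - x_drop) break
  }
  c(lo, hi, sum(v[lo:hi]))
}

.kmer_positions <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(list())
  kmers <- substring(s, 1:(n - k + 1L), k:n)
  split(seq_len(n - k + 1L), kmers)
}

#' Translated search of protein queries against a genome
#'
#' Seeds exact amino-acid word matches between each query and each of the six
#' frame translations of each contig, extends them without gaps under an
#' X-drop rule with BLOSUM62 scoring, and reports hits passing the score
#' thresholds. Deterministic: hits are ordered by (contig, start, query).
#' Contigs that are more than 50% `N` are skipped with a warning.
#'
#' @param queries protein sequences (named character vector or
#'   `AAStringSet`).
#' @param genome contig sequences (named character vector, `DNAStringSet`, or
#'   a `genome_sim` object).
#' @param params a [search_params()].
#' @return data frame of class `search_hits`.
#' @export
search_genome <- function(queries, genome, params = search_params()) {
  if (inherits(genome, "genome_sim")) genome <- genome$genome
  genome <- vapply(as.list(genome), as.character, character(1))
  queries <- vapply(as.list(queries), as.character, character(1))
  if (!length(queries) || !length(genome)) .stopf("queries and genome must be non-empty")
  if (is.null(names(genome))) names(genome) <- sprintf("contig%d", seq_along(genome))
  if (is.null(names(queries))) names(queries) <- sprintf("query%d", seq_along(queries))
  M <- .blosum62()
  k <- params$word_size
  qk_idx <- lapply(queries, .kmer_positions, k = k)
  qchars <- lapply(queries, .chars)
  out <- list()

  for (cn in names(genome)) {
    contig <- genome[[cn]]
    L <- nchar(contig)
    if (L == 0L) next
    n_frac <- sum(.chars(contig) == "N") / L
    if (n_frac > 0.5) {
      warning(sprintf("contig %s skipped: %.0f%% N", cn, 100 * n_frac))
      next
    }
    frames <- sixframe_translate(contig)
    for (fr in frames) {
      faa <- fr$aa
      if (nchar(faa) < k) next
      sk <- .kmer_positions(faa, k)
      schars <- .chars(faa)
      for (qn in names(queries)) {
        qk <- qk_idx[[qn]]
        shared <- intersect(names(qk), names(sk))
        if (!length(shared)) next
        seeds <- do.call(rbind, lapply(shared, function(w)
          expand.grid(q = qk[[w]], s = sk[[w]])))
        seeds$diag <- seeds$s - seeds$q
        qc <- qchars[[qn]]
        nq <- length(qc); ns <- length(schars)
        covered_hi <- new.env() # per diagonal, rightmost covered v-index
        for (d in sort(unique(seeds$diag))) {
          # overlap of the diagonal: query index range
          qlo <- max(1L, 1L - d); qhi <- min(nq, ns - d)
          if (qhi - qlo + 1L < k) next
          v <- M[cbind(qc[qlo:qhi], schars[(qlo + d):(qhi + d)])]
          dseeds <- sort(seeds$q[seeds$diag == d])
          key <- as.character(d)
          for (sq in dseeds) {
            i <- sq - qlo + 1L
            prev <- get0(key, envir = covered_hi, inherits = FALSE,
                         ifnotfound = -1L)
            if (i <= prev) next
            ext <- .xdrop_extend(v, i, i + k - 1L, params$x_drop)
            assign(key, ext[2L], envir = covered_hi)
            len_aa <- ext[2L] - ext[1L] + 1L
            sc <- ext[3L]
            if (sc < params$min_score || sc / len_aa < params$min_score_per_res) next
            p1 <- qlo + ext[1L] - 1L; p2 <- qlo + ext[2L] - 1L
            nt <- frame_to_nt(fr$strand, fr$frame, p1 + d, p2 + d, L)
            out[[length(out) + 1L]] <- data.frame(
              query = qn, contig = cn, strand = fr$strand, frame = fr$frame,
              start = nt[1L], end = nt[2L], length_nt = nt[2L] - nt[1L],
              score = sc, q_start = p1, q_end = p2, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(out)) return(.empty_hits())
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$contig, hits$start, hits$query), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("search_hits", "data.frame")
  hits
}

#' Discard short hits
#'
#' Removes hits whose genomic span is strictly shorter than
#' `params$min_hit_len` nt (default 100 nt; a 100 nt hit is retained).
#' Order is otherwise preserved.
#'
#' @param hits a `search_hits` data frame.
#' @param params a [search_params()].
#' @return filtered `search_hits`.
#' @export
filter_hits <- function(hits, params = search_params()) {
  keep <- hits$length_nt >= params$min_hit_len
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("search_hits", "data.frame")
  out
}

.empty_loci <- function() {
  structure(data.frame(locus_id = character(0), contig = character(0),
                       strand = character(0), start = integer(0),
                       end = integer(0), n_hits = integer(0),
                       best_query = character(0), n_frames = integer(0),
                       score = numeric(0), stringsAsFactors = FALSE),
            class = c("candidate_loci", "data.frame"))
}

#' Merge hits into candidate loci
#'
#' Hits on the same contig and strand whose genomic intervals overlap are
#' transitively unioned into maximal, mutually disjoint loci (half-open
#' semantics: abutting hits are not merged). Additionally, adjacent loci in
#' different reading frames separated by at most `params$frameshift_gap` nt
#' are fused, so a frameshifted pseudogene presents as one locus.
#'
#' @param hits filtered `search_hits`.
#' @param params a [search_params()].
#' @return data frame of class `candidate_loci`.
#' @export
merge_hits <- function(hits, params = search_params()) {
  if (!nrow(hits)) return(.empty_loci())
  groups <- split(seq_len(nrow(hits)),
                  paste(hits$contig, hits$strand, sep = "\r"))
  out <- list()
  for (g in groups) {
    h <- hits[g, , drop = FALSE]
    ir <- IRanges::IRanges(start = h$start + 1L, end = h$end)
    red <- IRanges::reduce(ir, min.gapwidth = 0L, with.revmap = TRUE)
    loci <- data.frame(start = IRanges::start(red) - 1L,
                       end = IRanges::end(red))
    revmap <- as.list(S4Vectors::mcols(red)$revmap)
    # fuse adjacent loci in different frames across small gaps (frameshifts)
    i <- 1L
    while (i < nrow(loci)) {
      gap <- loci$start[i + 1L] - loci$end[i]
      fr_a <- unique(h$frame[revmap[[i]]])
      fr_b <- unique(h$frame[revmap[[i + 1L]]])
      if (gap >= 0L && gap <= params$frameshift_gap && !setequal(fr_a, fr_b)) {
        loci$end[i] <- loci$end[i + 1L]
        revmap[[i]] <- c(revmap[[i]], revmap[[i + 1L]])
        loci <- loci[-(i + 1L), , drop = FALSE]
        revmap <- revmap[-(i + 1L)]
      } else i <- i + 1L
    }
    for (j in seq_len(nrow(loci))) {
      hh <- h[revmap[[j]], , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        contig = hh$contig[1L], strand = hh$strand[1L],
        start = loci$start[j], end = loci$end[j],
        n_hits = nrow(hh),
        best_query = hh$query[which.max(hh$score)],
        n_frames = length(unique(hh$frame)),
        score = max(hh$score), stringsAsFactors = FALSE)
    }
  }
  loci <- do.call(rbind, out)
  loci <- loci[order(loci$contig, loci$start, loci$strand), , drop = FALSE]
  loci <- cbind(locus_id = sprintf("locus%03d", seq_len(nrow(loci))), loci,
                stringsAsFactors = FALSE)
  rownames(loci) <- NULL
  class(loci) <- c("candidate_loci", "data.frame")
  loci
}

#' Extend candidate loci by flanking sequence
#'
#' Prolongs each locus by `params$flank` nt (default 500) in both the 5' and
#' 3' directions, clipped to the contig bounds.
#'
#' @param loci `candidate_loci`.
#' @param params a [search_params()].
#' @param contig_lengths named integer vector of contig lengths.
#' @return `candidate_loci` with extended intervals.
#' @export
extend_locus <- function(loci, params = search_params(), contig_lengths) {
  if (!nrow(loci)) return(loci)
  lens <- contig_lengths[loci$contig]
  if (anyNA(lens)) .stopf("missing contig length for %s",
                          paste(unique(loci$contig[is.na(lens)]), collapse = ", "))
  loci$start <- pmax(0L, loci$start - params$flank)
  loci$end <- pmin(as.integer(lens), loci$end + params$flank)
  loci
}

#' Contig lengths of a genome
#' @param genome named character vector, `DNAStringSet`, or `genome_sim`.
#' @return named integer vector.
#' @export
contig_lengths <- function(genome) {
  if (inherits(genome, "genome_sim")) genome <- genome$genome
  if (inherits(genome, "XStringSet"))
    return(stats::setNames(Biostrings::width(genome), names(genome)))
  stats::setNames(nchar(genome), names(genome))
}
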