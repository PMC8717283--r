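## Counting-based selective-pressure estimation: Nei-Gojobori (NG86)
## synonymous/nonsynonymous site and difference counting with Jukes-Cantor
## correction, family mean omega, and a binomial site-wise selection scan
## giving positive/negative/neutral calls with a posterior-like score.

# per-codon (S, N) site counts, memoised over the 61 sense codons
.site_counts <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    nts <- c("A", "C", "G", "T")
    m <- matrix(0, nrow = length(.SENSE_CODONS), ncol = 2,
                dimnames = list(.SENSE_CODONS, c("S", "N")))
    for (cod in .SENSE_CODONS) {
      ch <- .chars(cod)
      s_tot <- 0
      for (p in 1:3) {
        syn <- 0L; valid <- 0L
        for (nt in setdiff(nts, ch[p])) {
          to <- ch; to[p] <- nt; to <- paste0(to, collapse = "")
          if (.AA_OF[to] == "*") next
          valid <- valid + 1L
          if (.AA_OF[to] == .AA_OF[cod]) syn <- syn + 1L
        }
        if (valid > 0L) s_tot <- s_tot + syn / valid
      }
      m[cod, ] <- c(s_tot, 3 - s_tot)
    }
    cache <<- m
    m
  }
})

#' Synonymous and nonsynonymous site counts of a codon
#'
#' For each codon position, the fraction of the single-nucleotide changes
#' that are synonymous (changes to stop codons are excluded from the
#' denominator), summed over the three positions; synonymous + nonsynonymous
#' sites always total 3.
#'
#' @param codon a sense codon string, e.g. `"TTT"`.
#' @return named numeric `c(S = ..., N = ...)`.
#' @export
count_sites <- function(codon) {
  codon <- toupper(codon)
  m <- .site_counts()
  if (!codon %in% rownames(m)) .stopf("not a sense codon: %s", codon)
  c(S = m[codon, "S"], N = m[codon, "N"])
}

# pathway-averaged (syn, nonsyn) difference counts between two sense codons;
# pathways traversing stop codons are excluded (all-stop pathway sets fall
# back to including them, per the usual convention for rare codon pairs)
.path_diffs <- local({
  cache <- new.env()
  function(c1, c2) {
    if (c1 == c2) return(c(0, 0))
    key <- paste0(c1, c2)
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    pos <- which(.chars(c1) != .chars(c2))
    perms <- if (length(pos) == 1L) list(pos) else {
      if (length(pos) == 2L) list(pos, rev(pos)) else {
        do.call(c, lapply(seq_len(6L), function(i) {
          p <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))[[i]]
          list(pos[p])
        }))
      }
    }
    eval_path <- function(ord) {
      cur <- .chars(c1); tgt <- .chars(c2)
      sd <- 0; nd <- 0
      for (p in ord) {
        nxt <- cur; nxt[p] <- tgt[p]
        from <- paste0(cur, collapse = ""); to <- paste0(nxt, collapse = "")
        if (.AA_OF[to] == "*") return(NULL)
        if (.AA_OF[from] == .AA_OF[to]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    }
    res <- Filter(Negate(is.null), lapply(perms, eval_path))
    if (!length(res)) {
      eval_any <- function(ord) {
        cur <- .chars(c1); tgt <- .chars(c2); sd <- 0; nd <- 0
        for (p in ord) {
          nxt <- cur; nxt[p] <- tgt[p]
          from <- paste0(cur, collapse = ""); to <- paste0(nxt, collapse = "")
          if (.AA_OF[from] == .AA_OF[to] && .AA_OF[to] != "*") sd <- sd + 1
          else nd <- nd + 1
          cur <- nxt
        }
        c(sd, nd)
      }
      res <- lapply(perms, eval_any)
    }
    out <- Reduce(`+`, res) / length(res)
    assign(key, out, envir = cache)
    out
  }
})

.jc_correct <- function(p) {
  if (is.na(p) || p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise Nei-Gojobori dN/dS
#'
#' Counts synonymous/nonsynonymous sites averaged over the two sequences and
#' observed differences averaged over all shortest mutational pathways
#' (stop-traversing pathways excluded), applies the Jukes-Cantor correction
#' `d = -3/4 log(1 - 4p/3)`, and reports `omega = dN/dS`. Codons with a gap
#' or ambiguity in either sequence are dropped (pairwise deletion).
#'
#' @param seq1,seq2 equal-length codon-aligned nucleotide strings.
#' @return object of class `dnds`: list with `N`, `S`, `Nd`, `Sd`, `pN`,
#'   `pS`, `dN`, `dS`, `omega`, `omega_defined`, `n_codons`.
#' @export
pairwise_dnds <- function(seq1, seq2) {
  if (nchar(seq1) != nchar(seq2)) .stopf("sequences must be equal length")
  c1 <- .codons_of(toupper(seq1)); c2 <- .codons_of(toupper(seq2))
  keep <- c1 %in% .SENSE_CODONS & c2 %in% .SENSE_CODONS
  c1 <- c1[keep]; c2 <- c2[keep]
  if (!length(c1)) .stopf("no comparable codons")
  m <- .site_counts()
  S <- (sum(m[c1, "S"]) + sum(m[c2, "S"])) / 2
  N <- (sum(m[c1, "N"]) + sum(m[c2, "N"])) / 2
  diffs <- vapply(seq_along(c1), function(i) .path_diffs(c1[i], c2[i]),
                  numeric(2))
  Sd <- sum(diffs[1L, ]); Nd <- sum(diffs[2L, ])
  pS <- Sd / S; pN <- Nd / N
  dS <- .jc_correct(pS); dN <- .jc_correct(pN)
  omega_defined <- !is.na(dS) && !is.na(dN) && dS > 0
  structure(list(N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
                 dN = dN, dS = dS,
                 omega = if (omega_defined) dN / dS else NA_real_,
                 omega_defined = omega_defined, n_codons = length(c1)),
            class = "dnds")
}

#' @export
print.dnds <- function(x, ...) {
  cat(sprintf("NG86: N=%.2f S=%.2f Nd=%.2f Sd=%.2f dN=%.4f dS=%.4f omega=%s\n",
              x$N, x$S, x$Nd, x$Sd, x$dN %||% NA, x$dS %||% NA,
              if (x$omega_defined) sprintf("%.3f", x$omega) else "undefined"))
  invisible(x)
}

.aln_seqs <- function(alignment) {
  if (inherits(alignment, "codon_alignment")) return(alignment$seqs)
  if (inherits(alignment, "XStringSet"))
    return(vapply(as.list(alignment), as.character, character(1)))
  unlist(alignment)
}

#' Mean pairwise omega of a family alignment
#'
#' @param alignment a `codon_alignment`, named character vector, or
#'   `DNAStringSet` of codon-aligned sequences.
#' @return list with `mean_omega`, `n_pairs`, `n_undefined` (pairs whose
#'   omega is undefined, e.g. identical sequences with `dS = 0`).
#' @export
mean_family_omega <- function(alignment) {
  seqs <- .aln_seqs(alignment)
  n <- length(seqs)
  if (n < 2L) .stopf("need at least 2 sequences")
  omegas <- c(); undef <- 0L
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    r <- pairwise_dnds(seqs[[i]], seqs[[j]])
    if (r$omega_defined) omegas <- c(omegas, r$omega) else undef <- undef + 1L
  }
  list(mean_omega = if (length(omegas)) mean(omegas) else NA_real_,
       n_pairs = n * (n - 1L) / 2L, n_undefined = undef)
}

## ---- site-wise selection scan ---------------------------------------------

# Fitch parsimony substitution events per codon column along a tree;
# returns pathway-decomposed c(syn, nonsyn) counts
.parsimony_site_counts <- function(codons_by_taxon, tree) {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  kids <- vector("list", n)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1L]]] <- c(kids[[tree$edge[e, 1L]]], tree$edge[e, 2L])
  root <- ntip + 1L
  sets <- vector("list", n)
  for (i in seq_len(ntip)) sets[[i]] <- codons_by_taxon[[tree$tip.label[i]]]
  postorder <- function(v) {
    for (k in kids[[v]]) postorder(k)
    if (length(kids[[v]])) {
      s <- Reduce(intersect, lapply(kids[[v]], function(k) sets[[k]]))
      if (!length(s)) s <- Reduce(union, lapply(kids[[v]], function(k) sets[[k]]))
      sets[[v]] <<- s
    }
  }
  postorder(root)
  state <- character(n)
  assign_down <- function(v, parent_state) {
    state[v] <<- if (!is.null(parent_state) && parent_state %in% sets[[v]])
      parent_state else sets[[v]][1L]
    for (k in kids[[v]]) assign_down(k, state[v])
  }
  assign_down(root, NULL)
  out <- c(0, 0)
  for (e in seq_len(nrow(tree$edge))) {
    a <- state[tree$edge[e, 1L]]; b <- state[tree$edge[e, 2L]]
    if (a != b) out <- out + .path_diffs(a, b)
  }
  out
}

#' Site-wise selection scan
#'
#' For every codon column, compares observed nonsynonymous vs synonymous
#' change counts (Fitch parsimony along the guide tree when one is given,
#' pooled pairwise pathway counts otherwise) against the neutral expectation
#' from the column's site composition, using a mid-P binomial tail score in
#' `[0, 1]`. Sites scoring at least `threshold` toward excess nonsynonymous
#' change are `POSITIVE`; toward deficit, `NEGATIVE`; otherwise `NEUTRAL`.
#'
#' @param alignment as in [mean_family_omega()].
#' @param tree optional ape `phylo` (or Newick) relating the taxa.
#' @param threshold posterior-like score threshold (default 0.9).
#' @return data frame of class `site_scan`: per site `n_changes`, `nonsyn`,
#'   `syn`, `expected_nonsyn_frac`, `score`, `class`.
#' @export
site_selection_scan <- function(alignment, tree = NULL, threshold = 0.9) {
  seqs <- .aln_seqs(alignment)
  if (is.character(tree)) tree <- read_newick(tree)
  codons <- lapply(seqs, .codons_of)
  L <- unique(vapply(codons, length, integer(1)))
  if (length(L) != 1L) .stopf("sequences must be aligned to equal length")
  m <- .site_counts()
  out <- data.frame(site = seq_len(L), n_changes = 0, nonsyn = 0, syn = 0,
                    expected_nonsyn_frac = NA_real_, score = 0.5,
                    class = "NEUTRAL", stringsAsFactors = FALSE)
  nseq <- length(codons)
  for (s in seq_len(L)) {
    col <- vapply(codons, `[[`, character(1), s)
    ok <- col %in% .SENSE_CODONS
    if (sum(ok) < 2L) next
    colv <- col[ok]
    p0 <- mean(m[colv, "N"]) / 3
    if (!is.null(tree)) {
      taxa <- names(seqs)[ok]
      keep_tree <- if (length(taxa) < length(tree$tip.label))
        ape::keep.tip(tree, taxa) else tree
      cnt <- .parsimony_site_counts(
        stats::setNames(as.list(colv), taxa), keep_tree)
    } else {
      cnt <- c(0, 0)
      idx <- which(ok)
      for (i in seq_along(idx)[-length(idx)])
        for (j in seq.int(i + 1L, length(idx)))
          cnt <- cnt + .path_diffs(col[idx[i]], col[idx[j]])
    }
    syn <- cnt[1L]; ns <- cnt[2L]
    n <- round(syn + ns); x <- round(ns)
    out$n_changes[s] <- syn + ns; out$syn[s] <- syn; out$nonsyn[s] <- ns
    out$expected_nonsyn_frac[s] <- p0
    if (n < 1L) next
    x <- min(x, n)
    score <- stats::pbinom(x - 1L, n, p0) + 0.5 * stats::dbinom(x, n, p0)
    out$score[s] <- score
    out$class[s] <- if (score >= threshold) "POSITIVE"
    else if (1 - score >= threshold) "NEGATIVE" else "NEUTRAL"
  }
  attr(out, "threshold") <- threshold
  class(out) <- c("site_scan", "data.frame")
  out
}
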