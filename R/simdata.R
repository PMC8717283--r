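## Synthetic-data generators: genomes with planted receptor genes, engineered
## pseudogenes, birth-death gene-family histories, and codon alignments
## evolved under site-wise selection. Every generator records ground truth so
## downstream stages can be scored against known answers.

.HYDROPHOBIC <- c("I", "L", "V", "F", "A", "M")
.HYDROPHILIC <- c("D", "E", "K", "R", "N", "Q", "S", "T", "G", "P", "H", "Y")

# inverse codon table: amino acid -> sense codons
.codons_for_aa <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      ct <- Biostrings::GENETIC_CODE
      tab <<- split(names(ct), as.character(ct))
    }
    tab
  }
})

#' Specify a synthetic genome simulation
#'
#' Bundles and validates the parameters of [simulate_genome()]: how many
#' contigs of what length, how many intact / partial (contig-edge truncated) /
#' pseudogenised receptor genes to plant, the protein-level divergence of the
#' plants from the query templates, base composition and the random seed.
#'
#' @param n_contigs number of contigs.
#' @param contig_len length of each contig in nucleotides.
#' @param n_intact,n_partial,n_pseudo numbers of planted genes per category.
#' @param divergence expected protein distance of plants from their query
#'   templates, as a fraction of residues substituted, in `[0, 1)`.
#' @param gc background GC content in `(0, 1)`.
#' @param seed integer random seed; identical seeds give byte-identical output.
#' @param n_templates number of distinct receptor query templates.
#' @param marker_pairs number of intact plants that additionally receive a
#'   pair of flanking marker-gene annotations (for synteny tests).
#' @return an object of class `sim_spec`.
#' @export
sim_spec <- function(n_contigs = 30L, contig_len = 6000L,
                     n_intact = 20L, n_partial = 5L, n_pseudo = 5L,
                     divergence = 0.1, gc = 0.42, seed = 1L,
                     n_templates = 4L, marker_pairs = 0L) {
  stopifnot(
    n_contigs >= 1, contig_len >= 1200,
    n_intact >= 0, n_partial >= 0, n_pseudo >= 0,
    divergence >= 0, divergence < 1, gc > 0, gc < 1,
    n_templates >= 1, marker_pairs >= 0, marker_pairs <= n_intact
  )
  structure(list(
    n_contigs = as.integer(n_contigs), contig_len = as.integer(contig_len),
    n_intact = as.integer(n_intact), n_partial = as.integer(n_partial),
    n_pseudo = as.integer(n_pseudo), divergence = divergence, gc = gc,
    seed = as.integer(seed), n_templates = as.integer(n_templates),
    marker_pairs = as.integer(marker_pairs)
  ), class = "sim_spec")
}

# A 7-TM receptor-shaped protein: hydrophobic 21-aa blocks alternating with
# hydrophilic loops, so a Kyte-Doolittle transmembrane screen passes by
# construction. Returns the protein and the logical TM mask.
.receptor_template <- function(aa_len) {
  stopifnot(aa_len >= 275)
  tm_len <- 21L; loop_len <- 15L; nterm <- 20L
  core <- 7L * tm_len + 6L * loop_len
  tail <- aa_len - nterm - core
  stopifnot(tail >= 1L)
  segs <- character(0); mask <- logical(0)
  add <- function(pool, n, is_tm) {
    segs <<- c(segs, sample(pool, n, replace = TRUE))
    mask <<- c(mask, rep(is_tm, n))
  }
  add(.HYDROPHILIC, nterm, FALSE)
  for (k in seq_len(7L)) {
    add(.HYDROPHOBIC, tm_len, TRUE)
    if (k < 7L) add(.HYDROPHILIC, loop_len, FALSE)
  }
  add(.HYDROPHILIC, tail, FALSE)
  segs[1L] <- "M"
  list(protein = paste0(segs, collapse = ""), tm_mask = mask)
}

# Substitute a fraction of residues. Positions inside TM blocks are replaced
# from the hydrophobic alphabet so the transmembrane architecture (a property
# conserved in real GPCRs) survives divergence; the initial Met is never
# touched.
.diverge_protein <- function(template, divergence) {
  aa <- .chars(template$protein)
  n <- length(aa)
  k <- round(divergence * (n - 1L))
  if (k == 0L) return(paste0(aa, collapse = ""))
  pos <- sample(2:n, k)
  for (p in pos) {
    pool <- if (template$tm_mask[p]) .HYDROPHOBIC else names(.KD)
    pool <- setdiff(pool, aa[p])
    aa[p] <- sample(pool, 1L)
  }
  paste0(aa, collapse = "")
}

# back-translate with uniform codon choice; append a random stop codon
.backtranslate_orf <- function(protein) {
  tab <- .codons_for_aa()
  codons <- vapply(.chars(protein), function(a) {
    cs <- tab[[a]]
    if (length(cs) == 1L) cs else sample(cs, 1L)
  }, character(1))
  paste0(c(codons, sample(tab[["*"]], 1L)), collapse = "")
}

.random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste0(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Engineer pseudogenising disruptions into an intact ORF
#'
#' Introduces exactly `n_disruptions` coding disruptions — premature stop
#' codons or 1-2 nt frameshifting indels — at recorded positions. The start
#' codon and the terminal stop are never touched.
#'
#' @param orf complete ORF nucleotide string (start codon, stop codon,
#'   length divisible by 3).
#' @param n_disruptions number of disruptions, at least 1.
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @param kinds disruption kinds to sample from, a subset of
#'   `"PREMATURE_STOP"`, `"FRAMESHIFT"`.
#' @return a list with `seq` (the disrupted sequence) and `disruptions`
#'   (a data frame: kind, codon index in the original ORF, nt offset, and for
#'   frameshifts the indel length modulo 3).
#' @export
mutate_to_pseudogene <- function(orf, n_disruptions, seed = NULL,
                                 kinds = c("PREMATURE_STOP", "FRAMESHIFT")) {
  if (n_disruptions < 1) .stopf("n_disruptions must be >= 1")
  n <- nchar(orf)
  if (n %% 3L != 0L) .stopf("ORF length must be divisible by 3")
  codons <- .codons_of(orf)
  L <- length(codons)
  if (substr(orf, 1L, 3L) != "ATG") .stopf("ORF must begin with ATG")
  if (.AA_OF[codons[L]] != "*") .stopf("ORF must end with a stop codon")
  if (any(.AA_OF[codons[-L]] == "*")) .stopf("ORF already contains a premature stop")
  lo <- 10L; hi <- L - 10L
  if (hi - lo + 1L < n_disruptions) .stopf("ORF too short for %d disruptions", n_disruptions)
  run <- function() {
    pos <- sort(sample(lo:hi, n_disruptions))
    kind <- sample(kinds, n_disruptions, replace = TRUE)
    rec <- data.frame(kind = kind, codon = pos,
                      nt_offset = (pos - 1L) * 3L,
                      len_mod3 = 0L, stringsAsFactors = FALSE)
    # apply right-to-left so earlier coordinates stay valid
    seq <- orf
    for (i in rev(seq_len(n_disruptions))) {
      off <- rec$nt_offset[i]
      if (rec$kind[i] == "PREMATURE_STOP") {
        stopc <- sample(c("TAA", "TAG", "TGA"), 1L)
        seq <- paste0(substr(seq, 1L, off), stopc, substr(seq, off + 4L, nchar(seq)))
      } else {
        del <- sample(1:2, 1L)
        rec$len_mod3[i] <- del
        seq <- paste0(substr(seq, 1L, off), substr(seq, off + del + 1L, nchar(seq)))
      }
    }
    list(seq = seq, disruptions = rec)
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

#' Simulate a genome assembly with planted taste-receptor genes
#'
#' Generates random-background contigs carrying planted receptor ORFs with a
#' seven-transmembrane hydropathy profile: intact plants are complete ORFs of
#' 816-1272 nt; pseudogene plants carry engineered premature stops and/or
#' frameshifts; partial plants are truncated by a contig edge. Plants diverge
#' from the returned query templates by the requested protein distance. The
#' returned truth table records every plant (0-based half-open forward-strand
#' coordinates, strand flag, category, disruptions) and any flanking marker
#' placements.
#'
#' @param spec a [sim_spec()].
#' @return an object of class `genome_sim`: a list with `genome`
#'   (a [Biostrings::DNAStringSet]), `truth` (data frame), `markers`
#'   (data frame), `queries` (an [Biostrings::AAStringSet] of undiverged
#'   templates) and `spec`.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  .with_seed(spec$seed, {
    templates <- lapply(seq_len(spec$n_templates), function(i) {
      # ORF nt length (incl. stop) = 3*(aa+1) in [828, 1263] nt
      .receptor_template(sample(275:420, 1L))
    })
    names(templates) <- sprintf("queryTas2r%d", seq_along(templates))

    n_genes <- spec$n_intact + spec$n_partial + spec$n_pseudo
    contigs <- vapply(seq_len(spec$n_contigs),
                      function(i) .random_dna(spec$contig_len, spec$gc),
                      character(1))
    names(contigs) <- sprintf("contig%02d", seq_len(spec$n_contigs))

    truth <- list(); markers <- list()
    margin <- 600L
    cursor <- rep(margin, spec$n_contigs)       # next free position, interior plants
    edge_free <- rep(TRUE, spec$n_contigs)      # contig start edge free for partials

    plant_interior <- function(orf_len) {
      for (ci in seq_len(spec$n_contigs)) {
        start <- cursor[ci]
        if (start + orf_len + margin <= spec$contig_len) {
          cursor[ci] <<- start + orf_len + margin
          return(c(ci, start))
        }
      }
      .stopf("simulation spec infeasible: planted genes cannot fit in %d contigs of %d nt",
             spec$n_contigs, spec$contig_len)
    }

    make_plant <- function() {
      ti <- sample(seq_along(templates), 1L)
      prot <- .diverge_protein(templates[[ti]], spec$divergence)
      list(template = names(templates)[ti], orf = .backtranslate_orf(prot))
    }

    insert <- function(ci, start, block) {
      # replace contig substring [start, start+len) (0-based half-open)
      s <- contigs[[ci]]
      contigs[[ci]] <<- paste0(substr(s, 1L, start),
                               block,
                               substr(s, start + nchar(block) + 1L, nchar(s)))
    }

    gid <- 0L
    add_truth <- function(ci, start, len, strand, category, template, disr) {
      gid <<- gid + 1L
      truth[[gid]] <<- data.frame(
        gene_id = sprintf("plant%03d", gid),
        contig = names(contigs)[ci], strand = strand,
        start = start, end = start + len,
        category = category, family = "Tas2r", template = template,
        n_disruptions = if (is.null(disr)) 0L else nrow(disr),
        disruptions = if (is.null(disr)) "" else
          paste(sprintf("%s@%d", disr$kind, disr$codon), collapse = ";"),
        stringsAsFactors = FALSE
      )
      gid
    }

    # intact plants
    for (i in seq_len(spec$n_intact)) {
      pl <- make_plant()
      len <- nchar(pl$orf)
      at <- plant_interior(len)
      strand <- sample(c("+", "-"), 1L)
      insert(at[1L], at[2L], if (strand == "+") pl$orf else revcomp(pl$orf))
      id <- add_truth(at[1L], at[2L], len, strand, "INTACT", pl$template, NULL)
      if (length(markers) < spec$marker_pairs) {
        k <- length(markers) + 1L
        markers[[k]] <- data.frame(
          marker = c(sprintf("MKUP%d", k), sprintf("MKDN%d", k)),
          contig = names(contigs)[at[1L]],
          start = c(at[2L] - 550L, at[2L] + len + 450L),
          end = c(at[2L] - 450L, at[2L] + len + 550L),
          target = sprintf("plant%03d", id),
          stringsAsFactors = FALSE
        )
      }
    }

    # pseudogene plants
    for (i in seq_len(spec$n_pseudo)) {
      pl <- make_plant()
      mut <- mutate_to_pseudogene(pl$orf, sample(1:2, 1L))
      len <- nchar(mut$seq)
      at <- plant_interior(len)
      strand <- sample(c("+", "-"), 1L)
      insert(at[1L], at[2L], if (strand == "+") mut$seq else revcomp(mut$seq))
      add_truth(at[1L], at[2L], len, strand, "PSEUDO", pl$template, mut$disruptions)
    }

    # partial plants: truncated by the start edge of a fresh contig (5' cut,
    # start codon lost) or placed flush against the end (stop codon lost)
    for (i in seq_len(spec$n_partial)) {
      ci <- which(edge_free & cursor == margin)
      if (!length(ci)) .stopf("simulation spec infeasible: no free contig edge for partial plants")
      ci <- ci[length(ci)]   # fill from the last untouched contig backwards
      pl <- make_plant()
      len <- nchar(pl$orf)
      keep <- 3L * sample(120:170, 1L)    # in-frame kept portion, >= 360 nt
      if (i %% 2L == 1L) {
        frag <- substr(pl$orf, len - keep + 1L, len)   # 3' piece: no start
        insert(ci, 0L, frag)
        add_truth(ci, 0L, keep, "+", "PARTIAL", pl$template, NULL)
      } else {
        frag <- substr(pl$orf, 1L, keep)               # 5' piece: no stop
        insert(ci, spec$contig_len - keep, frag)
        add_truth(ci, spec$contig_len - keep, keep, "+", "PARTIAL", pl$template, NULL)
      }
      cursor[ci] <- spec$contig_len   # contig consumed
      edge_free[ci] <- FALSE
    }

    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(gene_id = character(0), contig = character(0),
                 strand = character(0), start = integer(0), end = integer(0),
                 category = character(0), family = character(0),
                 template = character(0), n_disruptions = integer(0),
                 disruptions = character(0), stringsAsFactors = FALSE)
    markers <- if (length(markers)) do.call(rbind, markers) else
      data.frame(marker = character(0), contig = character(0),
                 start = integer(0), end = integer(0), target = character(0),
                 stringsAsFactors = FALSE)

    structure(list(
      genome = Biostrings::DNAStringSet(unlist(contigs)),
      truth = truth, markers = markers,
      queries = Biostrings::AAStringSet(
        vapply(templates, `[[`, character(1), "protein")),
      spec = spec
    ), class = "genome_sim")
  })
}

#' @export
print.genome_sim <- function(x, ...) {
  cat(sprintf("Synthetic genome: %d contigs (%d nt each), %d planted genes\n",
              length(x$genome), x$spec$contig_len, nrow(x$truth)))
  if (nrow(x$truth)) print(table(x$truth$category))
  invisible(x)
}

## ---- gene-family birth-death histories ------------------------------------

# species tree input: ape phylo or newick string; returns phylo with node labels
.as_species_tree <- function(tree) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) .stopf("species tree must be rooted")
  if (!ape::is.binary(tree)) .stopf("species tree must be binary")
  ntip <- length(tree$tip.label)
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label)))
    tree$node.label <- sprintf("n%d", (ntip + 1L):(ntip + tree$Nnode))
  tree
}

.node_label <- function(tree, node) {
  ntip <- length(tree$tip.label)
  ifelse(node <= ntip, tree$tip.label[node], tree$node.label[node - ntip])
}

#' Simulate gene-family evolution by a birth-death process on a species tree
#'
#' Gene copies duplicate and are lost along each species-tree branch under a
#' continuous-time birth-death process with per-branch expected rates. Returns
#' the gene tree(s) of surviving lineages together with the full truth event
#' log (duplications that left no pair of surviving descendant lineages are
#' flagged unobservable: no reconciliation method can recover them).
#'
#' @param species_tree rooted binary tree (ape `phylo` or Newick string).
#' @param birth_rate,death_rate expected events per gene copy per branch.
#' @param root_count number of gene copies at the species-tree root.
#' @param seed random seed.
#' @return an object of class `family_history`: list with `species_tree`,
#'   `gene_trees` (list of ape `phylo`, one per surviving root copy; leaf
#'   labels are `Species_gN`), `events` (data frame: branch, event,
#'   observable), `branch_counts` (per-branch n_in/dup/loss/n_out) and
#'   `tip_counts` (named per-species surviving gene counts). If every lineage
#'   goes extinct the history is returned with `extinct = TRUE`.
#' @export
simulate_family_evolution <- function(species_tree, birth_rate, death_rate,
                                      root_count = 1L, seed = 1L) {
  stopifnot(birth_rate >= 0, death_rate >= 0, root_count >= 1)
  sp <- .as_species_tree(species_tree)
  ntip <- length(sp$tip.label)
  root <- ntip + 1L
  kids <- function(v) sp$edge[sp$edge[, 1L] == v, 2L]

  .with_seed(seed, {
    events <- list(); ev_i <- 0L
    bc <- new.env()
    bump <- function(branch, what, by = 1L) {
      cur <- get0(branch, envir = bc, inherits = FALSE,
                  ifnotfound = c(n_in = 0L, dup = 0L, loss = 0L))
      cur[what] <- cur[what] + by
      assign(branch, cur, envir = bc)
    }
    log_event <- function(branch, event, observable) {
      ev_i <<- ev_i + 1L
      events[[ev_i]] <<- data.frame(branch = branch, event = event,
                                    observable = observable,
                                    stringsAsFactors = FALSE)
      ev_i
    }
    gcount <- stats::setNames(rep(0L, ntip), sp$tip.label)

    # simulate one gene lineage down the branch above species node v;
    # returns newick fragment of the surviving subtree, or NULL if extinct
    sim_into <- function(v) {
      branch <- .node_label(sp, v)
      bump(branch, "n_in")
      sim_within(v, 1.0, branch)
    }
    sim_within <- function(v, t_left, branch) {
      rate <- birth_rate + death_rate
      repeat {
        if (rate <= 0) break
        dt <- stats::rexp(1L, rate)
        if (dt > t_left) break
        t_left <- t_left - dt
        if (stats::runif(1L) < birth_rate / rate) {
          bump(branch, "dup")
          ei <- log_event(branch, "DUPLICATION", NA)
          a <- sim_within(v, t_left, branch)
          b <- sim_within(v, t_left, branch)
          obs <- !is.null(a) && !is.null(b)
          events[[ei]]$observable <<- obs
          if (obs) return(sprintf("(%s,%s)", a, b))
          return(if (is.null(a)) b else a)
        } else {
          bump(branch, "loss")
          log_event(branch, "LOSS", FALSE)
          return(NULL)
        }
      }
      # survived to the bottom of the branch
      if (v <= ntip) {
        gcount[v] <<- gcount[v] + 1L
        return(sprintf("%s_g%d", sp$tip.label[v], gcount[v]))
      }
      ch <- kids(v)
      a <- sim_into(ch[1L]); b <- sim_into(ch[2L])
      if (!is.null(a) && !is.null(b)) return(sprintf("(%s,%s)", a, b))
      if (is.null(a)) b else a
    }

    newicks <- lapply(seq_len(root_count), function(i) {
      ch <- kids(root)
      a <- sim_into(ch[1L]); b <- sim_into(ch[2L])
      if (!is.null(a) && !is.null(b)) sprintf("(%s,%s);", a, b)
      else if (!is.null(a)) sprintf("%s;", a)
      else if (!is.null(b)) sprintf("%s;", b)
      else NULL
    })
    newicks <- Filter(Negate(is.null), newicks)
    gene_trees <- lapply(newicks, function(s) ape::read.tree(text = s))
    # single-leaf "trees" stay as newick strings in ape; keep only valid phylo
    events <- if (ev_i) do.call(rbind, events) else
      data.frame(branch = character(0), event = character(0),
                 observable = logical(0), stringsAsFactors = FALSE)
    bcdf <- do.call(rbind, lapply(ls(bc), function(b) {
      v <- get(b, envir = bc)
      data.frame(branch = b, n_in = v[["n_in"]], dup = v[["dup"]],
                 loss = v[["loss"]], stringsAsFactors = FALSE)
    }))
    if (is.null(bcdf))
      bcdf <- data.frame(branch = character(0), n_in = integer(0),
                         dup = integer(0), loss = integer(0),
                         stringsAsFactors = FALSE)
    structure(list(
      species_tree = sp, gene_trees = gene_trees, gene_newicks = newicks,
      events = events, branch_counts = bcdf, tip_counts = gcount,
      root_count = as.integer(root_count),
      extinct = length(newicks) == 0L
    ), class = "family_history")
  })
}

#' @export
print.family_history <- function(x, ...) {
  cat(sprintf("Gene-family history: %d surviving root lineage(s), %d events (%d dup, %d loss)%s\n",
              length(x$gene_newicks), nrow(x$events),
              sum(x$events$event == "DUPLICATION"),
              sum(x$events$event == "LOSS"),
              if (x$extinct) " [all lineages extinct]" else ""))
  print(x$tip_counts)
  invisible(x)
}

## ---- codon alignments under site-wise selection ---------------------------

# neighbor structure for the 61 sense codons: single-nt neighbors with
# transition / synonymy flags (stop neighbors excluded)
.codon_neighbors <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    nts <- c("A", "C", "G", "T")
    is_ts <- function(a, b) paste0(a, b) %in% c("AG", "GA", "CT", "TC")
    out <- list()
    for (cod in .SENSE_CODONS) {
      ch <- .chars(cod)
      tos <- character(0); ts <- logical(0); syn <- logical(0)
      for (p in 1:3) for (nt in setdiff(nts, ch[p])) {
        to <- ch; to[p] <- nt; to <- paste0(to, collapse = "")
        if (.AA_OF[to] == "*") next
        tos <- c(tos, to)
        ts <- c(ts, is_ts(ch[p], nt))
        syn <- c(syn, .AA_OF[to] == .AA_OF[cod])
      }
      out[[cod]] <- list(to = tos, ts = ts, syn = syn)
    }
    cache <<- out
    out
  }
})

#' Simulate a codon alignment under site-wise dN/dS
#'
#' Evolves gap-free codon sequences along a tree with branch lengths by a
#' continuous-time codon substitution process: single-nucleotide exchanges,
#' transition/transversion ratio `kappa`, nonsynonymous rates scaled by the
#' site's `omega`, stop codons never introduced. Branch lengths are in
#' expected substitutions per codon under neutrality (`omega = 1`).
#'
#' @param tree ape `phylo` (or Newick string) with branch lengths.
#' @param omega dN/dS value(s), a scalar or one per codon site (recycled).
#' @param kappa transition/transversion rate ratio. The default 1 matches the
#'   assumption of counting-based dN/dS estimation.
#' @param n_codons number of codon sites.
#' @param seed random seed.
#' @return object of class `codon_alignment`: list with `seqs` (named
#'   character vector of aligned nucleotide strings), `omega`, `n_codons`.
#' @export
simulate_codon_alignment <- function(tree, omega, kappa = 1, n_codons = 300L,
                                     seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), n_codons >= 1, all(omega >= 0), kappa > 0)
  if (is.null(tree$edge.length)) .stopf("tree must have branch lengths")
  omega <- rep_len(omega, n_codons)
  nb <- .codon_neighbors()
  # normaliser: mean total rate per codon at omega = 1
  q0 <- mean(vapply(nb, function(x) sum(ifelse(x$ts, kappa, 1)), numeric(1)))

  evolve_site <- function(codon, w, t) {
    repeat {
      x <- nb[[codon]]
      rates <- ifelse(x$ts, kappa, 1) * ifelse(x$syn, 1, w)
      R <- sum(rates) / q0
      if (R <= 0) return(codon)
      dt <- stats::rexp(1L, R)
      if (dt > t) return(codon)
      t <- t - dt
      codon <- sample(x$to, 1L, prob = rates)
    }
  }

  .with_seed(seed, {
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    n_nodes <- ntip + tree$Nnode
    seqs <- vector("list", n_nodes)
    seqs[[root]] <- sample(.SENSE_CODONS, n_codons, replace = TRUE)
    # cladewise edge order guarantees parents are simulated before children
    tree <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
      t <- tree$edge.length[e]
      s <- seqs[[par]]
      if (t > 0) s <- vapply(seq_len(n_codons),
                             function(i) evolve_site(s[i], omega[i], t),
                             character(1))
      seqs[[child]] <- s
    }
    out <- vapply(seq_len(ntip), function(i) paste0(seqs[[i]], collapse = ""),
                  character(1))
    names(out) <- tree$tip.label
    structure(list(seqs = out, omega = omega, n_codons = as.integer(n_codons),
                   kappa = kappa),
              class = "codon_alignment")
  })
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("Codon alignment: %d sequences x %d codons (mean omega %.3g)\n",
              length(x$seqs), x$n_codons, mean(x$omega)))
  invisible(x)
}

#' Extract a planted gene's sequence from a synthetic genome
#'
#' Returns the forward-strand-corrected nucleotide sequence of a truth-table
#' record, i.e. the sequence as the gene reads 5' to 3'.
#'
#' @param sim a `genome_sim`.
#' @param gene_id a `gene_id` from `sim$truth`.
#' @return nucleotide string.
#' @export
extract_planted <- function(sim, gene_id) {
  rec <- sim$truth[sim$truth$gene_id == gene_id, ]
  if (nrow(rec) != 1L) .stopf("unknown gene_id: %s", gene_id)
  s <- substr(as.character(sim$genome[[rec$contig]]), rec$start + 1L, rec$end)
  if (rec$strand == "-") revcomp(s) else s
}
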