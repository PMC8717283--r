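# Synthetic-data generators: determinism, planted-gene ground truth, and
# birth-death / codon-substitution histories.

test_that("simulate_genome is deterministic and honours planted counts", {
  spec <- sim_spec(n_intact = 4, n_partial = 1, n_pseudo = 1, n_contigs = 8,
                   divergence = 0.1, seed = 7)
  a <- simulate_genome(spec)
  b <- simulate_genome(spec)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth, b$truth)
  c_ <- simulate_genome(sim_spec(n_intact = 4, n_partial = 1, n_pseudo = 1,
                                 n_contigs = 8, divergence = 0.1, seed = 8))
  expect_false(identical(as.character(a$genome), as.character(c_$genome)))

  sim <- shared_sim()
  expect_equal(nrow(sim$truth), 30)
  expect_equal(unname(table(sim$truth$category)[c("INTACT", "PARTIAL", "PSEUDO")]),
               c(20L, 5L, 5L), ignore_attr = TRUE)
})

test_that("an empty spec plants nothing and the miner finds nothing", {
  sim <- simulate_genome(sim_spec(n_intact = 0, n_partial = 0, n_pseudo = 0,
                                  n_contigs = 3, contig_len = 3000, seed = 1))
  expect_equal(nrow(sim$truth), 0)
  hits <- filter_hits(search_genome(sim$queries, sim))
  models <- annotate_loci(merge_hits(hits), sim, sim$queries)
  expect_equal(nrow(models), 0)
})

test_that("intact plant lengths fall in the observed receptor gene range", {
  sim <- shared_sim()
  len <- with(sim$truth[sim$truth$category == "INTACT", ], end - start)
  expect_true(all(len >= 816 & len <= 1272))
})

test_that("re-extracting planted loci translates consistently with the category", {
  sim <- shared_sim()
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    aa <- oracle_translate(extract_planted(sim, tr$gene_id))
    body <- sub("\\*$", "", aa)
    internal_stop <- grepl("\\*", body)
    if (tr$category == "INTACT") {
      expect_true(startsWith(aa, "M"), info = tr$gene_id)
      expect_true(endsWith(aa, "*"), info = tr$gene_id)
      expect_false(internal_stop, info = tr$gene_id)
      expect_gt(nchar(body), 270)
    } else if (tr$category == "PSEUDO") {
      # a premature stop shows up in frame; a frameshift breaks the frame
      frameshift <- (tr$end - tr$start) %% 3L != 0L ||
        grepl("FRAMESHIFT", tr$disruptions)
      expect_true(internal_stop || frameshift, info = tr$gene_id)
    } else {
      expect_false(startsWith(aa, "M") && endsWith(aa, "*"), info = tr$gene_id)
    }
  }
})

test_that("an infeasible spec errors instead of silently dropping genes", {
  expect_error(simulate_genome(sim_spec(n_intact = 50, n_contigs = 2,
                                        contig_len = 3000, seed = 1)),
               "infeasible")
})

test_that("mutate_to_pseudogene engineers the requested disruptions", {
  orf <- fixture_orf()
  expect_error(mutate_to_pseudogene(orf, 0), "n_disruptions")

  # premature stop at a known codon truncates the protein there
  mut <- mutate_to_pseudogene(orf, 1, seed = 3, kinds = "PREMATURE_STOP")
  pos <- mut$disruptions$codon[1]
  aa <- oracle_translate(mut$seq)
  expect_equal(regexpr("\\*", aa)[[1]], pos)
  expect_equal(nchar(sub("\\*.*$", "", aa)), pos - 1L)
  expect_identical(substr(mut$seq, 1, 3), "ATG")

  # a 1-2 nt deletion is recovered as exactly one frameshift downstream
  mutf <- mutate_to_pseudogene(orf, 1, seed = 5, kinds = "FRAMESHIFT")
  tmpl <- fixture_template()
  disr <- detect_disruptions(mutf$seq, tmpl$protein)
  expect_equal(nrow(disr), 1)
  expect_equal(disr$kind, "FRAMESHIFT")
  expect_equal(disr$len_mod3, mutf$disruptions$len_mod3[1])
})

test_that("family evolution with zero rates reproduces the species tree", {
  sp <- "((A,B),(C,D));"
  fh <- simulate_family_evolution(sp, 0, 0, 1, seed = 1)
  expect_equal(unname(fh$tip_counts), rep(1L, 4))
  expect_equal(nrow(fh$events), 0)
  rec <- lca_reconcile(fh$gene_trees[[1]], sp)
  expect_equal(rec$D, 0)
  expect_equal(unname(rec$L), 0)
})

test_that("death-only histories go extinct with only LOSS events logged", {
  fh <- simulate_family_evolution("((A,B),(C,D));", 0, 8, 1, seed = 2)
  expect_true(fh$extinct)
  expect_true(all(fh$events$event == "LOSS"))
  expect_true(all(fh$tip_counts == 0))
})

test_that("per-branch event counts replay from root to tip counts", {
  sp <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  for (seed in c(5, 9, 13)) {
    fh <- simulate_family_evolution(sp, 0.4, 0.3, 2, seed = seed)
    bc <- fh$branch_counts
    n_out <- with(bc, n_in + dup - loss)
    names(n_out) <- bc$branch
    # a tip's outflow is its gene count; an internal branch's outflow enters
    # both child branches
    sp2 <- tastemine:::.as_species_tree(sp)
    for (i in seq_len(nrow(bc))) {
      b <- bc$branch[i]
      tip <- match(b, sp2$tip.label)
      if (!is.na(tip)) {
        expect_equal(unname(n_out[b]), unname(fh$tip_counts[b]))
      } else {
        node <- match(b, sp2$node.label) + length(sp2$tip.label)
        kids <- sp2$edge[sp2$edge[, 1] == node, 2]
        for (k in kids) {
          kl <- tastemine:::.node_label(sp2, k)
          kin <- bc$n_in[bc$branch == kl]
          if (length(kin)) expect_equal(unname(n_out[b]), kin)
          else expect_equal(unname(n_out[b]), 0L)
        }
      }
    }
    # surviving leaves in gene trees match tip counts
    leaves <- unlist(lapply(fh$gene_trees, function(g) g$tip.label))
    cnt <- table(sub("_[^_]+$", "", leaves))
    for (s in names(fh$tip_counts))
      expect_equal(unname(fh$tip_counts[s]),
                   if (s %in% names(cnt)) unname(c(cnt[s])) else 0L)
  }
})

test_that("codon alignments degenerate correctly and are deterministic", {
  tre <- "((a:0,b:0):0,c:0);"
  aln <- simulate_codon_alignment(tre, omega = 1, n_codons = 40, seed = 1)
  expect_equal(length(unique(aln$seqs)), 1) # zero tree length: identical rows

  tre2 <- omega_recovery_tree()
  a <- simulate_codon_alignment(tre2, omega = 0.5, n_codons = 60, seed = 4)
  b <- simulate_codon_alignment(tre2, omega = 0.5, n_codons = 60, seed = 4)
  expect_identical(a$seqs, b$seqs)
  # no stop codons ever introduced; gap-free
  for (s in a$seqs) {
    expect_false(grepl("\\*", oracle_translate(s)))
    expect_equal(nchar(s), 180)
  }

  # omega 0: no nonsynonymous differences in any pair
  a0 <- simulate_codon_alignment(tre2, omega = 0, n_codons = 60, seed = 6)
  nm <- names(a0$seqs)
  for (i in 1:3) for (j in (i + 1):4) {
    r <- pairwise_dnds(a0$seqs[[nm[i]]], a0$seqs[[nm[j]]])
    expect_equal(r$Nd, 0)
  }
})
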