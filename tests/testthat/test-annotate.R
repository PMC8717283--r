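# Gene-model building and classification: TM screening, guided extraction,
# disruption round-trips, partial disambiguation, reciprocal verification
# and nomenclature.

test_that("hydropathy TM counting matches an independent hydropathy plot", {
  expect_equal(count_tm_segments(strrep("D", 300)), 0)

  blocks <- paste0(rep(c(strrep("L", 21), strrep("D", 15)), 7)[1:13],
                   collapse = "")
  expect_equal(count_tm_segments(blocks), 7)
  expect_equal(oracle_tm_segments(blocks), 7)

  # simulator templates pass the screen by construction, and agree with the
  # oracle on every template
  sim <- shared_sim()
  for (q in as.character(sim$queries)) {
    expect_gte(count_tm_segments(q), 7)
    expect_equal(count_tm_segments(q), oracle_tm_segments(q))
  }

  # random proteins: implementation equals oracle
  set.seed(8)
  for (k in 1:20) {
    p <- paste0(sample(names(tastemine:::.KD), 150, replace = TRUE),
                collapse = "")
    expect_equal(count_tm_segments(p), oracle_tm_segments(p))
  }
  expect_equal(count_tm_segments("MKV"), 0) # shorter than the window
})

test_that("classification follows the intact/partial/pseudo/short rules", {
  none <- data.frame(kind = character(0), position = integer(0),
                     len_mod3 = integer(0))
  one <- data.frame(kind = "PREMATURE_STOP", position = 10L, len_mod3 = 0L)
  p300 <- strrep("A", 300); p270 <- strrep("A", 270)
  expect_equal(classify_gene(p300, TRUE, TRUE, none, 7L), "INTACT")
  expect_equal(classify_gene(p300, TRUE, FALSE, none, 7L, TRUE), "PARTIAL")
  expect_equal(classify_gene(p300, TRUE, TRUE, none, 5L), "PSEUDO")
  expect_equal(classify_gene(p270, TRUE, TRUE, none, 7L), "SHORT")
  # disruption evidence outranks truncation evidence
  expect_equal(classify_gene(p300, TRUE, FALSE, one, 7L, TRUE), "PSEUDO")
  # truncation away from any contig edge is not excusable as partial
  expect_equal(classify_gene(p300, FALSE, TRUE, none, 7L, FALSE), "PSEUDO")
})

test_that("planted intact genes are recovered at their exact truth intervals", {
  mining <- shared_mining()
  sim <- mining$sim
  models <- mining$models
  intact <- sim$truth[sim$truth$category == "INTACT", ]
  for (i in seq_len(nrow(intact))) {
    tr <- intact[i, ]
    m <- models[models$contig == tr$contig & models$start < tr$end &
                  models$end > tr$start, ]
    expect_equal(nrow(m), 1, info = tr$gene_id)
    expect_equal(m$start, tr$start, info = tr$gene_id)
    expect_equal(m$end, tr$end, info = tr$gene_id)
    expect_equal(m$strand, tr$strand, info = tr$gene_id)
  }
})

test_that("strand symmetry: a reverse-strand plant yields the forward protein", {
  tmpl <- fixture_template()
  orf <- fixture_orf()
  set.seed(10)
  bg1 <- paste0(sample(c("A", "C", "G", "T"), 800, replace = TRUE), collapse = "")
  bg2 <- paste0(sample(c("A", "C", "G", "T"), 800, replace = TRUE), collapse = "")
  genome <- c(fwd = paste0(bg1, orf, bg2),
              rev = paste0(bg1, tastemine:::revcomp(orf), bg2))
  queries <- c(q = tmpl$protein)
  params <- search_params()
  hits <- filter_hits(search_genome(queries, genome, params), params)
  loci <- extend_locus(merge_hits(hits, params), params,
                       contig_lengths(genome))
  models <- annotate_loci(loci, genome, queries)
  expect_equal(models$strand[models$contig == "fwd"], "+")
  expect_equal(models$strand[models$contig == "rev"], "-")
  expect_equal(models$protein[models$contig == "rev"],
               models$protein[models$contig == "fwd"])
  expect_equal(models$protein[models$contig == "fwd"], tmpl$protein)

  # random sequence alone is dropped
  expect_null(extract_gene_model(bg1, tmpl$protein))
})

test_that("disruption detection round-trips engineered pseudogenes", {
  tmpl <- fixture_template()
  orf <- fixture_orf()
  # clean gene: no disruptions
  expect_equal(nrow(detect_disruptions(orf, tmpl$protein)), 0)

  # premature stop at an exact codon
  n_codons <- nchar(orf) / 3
  stop_codon <- 150L
  mut <- paste0(substr(orf, 1, (stop_codon - 1) * 3), "TAA",
                substr(orf, stop_codon * 3 + 1, nchar(orf)))
  disr <- detect_disruptions(mut, tmpl$protein)
  expect_equal(nrow(disr), 1)
  expect_equal(disr$kind, "PREMATURE_STOP")
  expect_equal(disr$position, stop_codon)

  # every engineered pseudogene classifies as PSEUDO
  for (seed in 1:8) {
    m <- mutate_to_pseudogene(orf, sample(1:2, 1), seed = seed)
    d <- detect_disruptions(m$seq, tmpl$protein)
    expect_gt(nrow(d), 0, label = sprintf("seed %d disruptions", seed))
    gm <- extract_gene_model(m$seq, tmpl$protein)
    expect_equal(classify_gene(gm$protein, gm$has_start, gm$has_stop, d,
                               count_tm_segments(gm$protein)), "PSEUDO")
  }
})

test_that("truncating a contig through an intact gene flips INTACT to PARTIAL", {
  sim <- simulate_genome(sim_spec(n_intact = 2, n_partial = 0, n_pseudo = 0,
                                  n_contigs = 4, divergence = 0.1, seed = 31))
  tr <- sim$truth[1, ]
  cut <- tr$start + 450L # mid-gene truncation
  genome <- vapply(as.list(sim$genome), as.character, character(1))
  genome[[tr$contig]] <- substr(genome[[tr$contig]], 1, cut)
  params <- search_params()
  hits <- filter_hits(search_genome(sim$queries, genome, params), params)
  loci <- extend_locus(merge_hits(hits, params), params,
                       contig_lengths(genome))
  models <- annotate_loci(loci, genome, sim$queries)
  m <- models[models$contig == tr$contig & models$start < tr$end &
                models$end > tr$start, ]
  expect_equal(m$category, "PARTIAL")
})

test_that("partial fragments group by guide coverage overlap", {
  tmpl <- fixture_template()
  g <- tmpl$protein
  frag <- function(a, b) substr(g, a, b)
  # overlapping fragments: different loci
  expect_equal(length(unique(deduplicate_partials(c(frag(1, 120), frag(80, 290)), g))), 2)
  # disjoint complementary fragments: one fused locus
  expect_equal(length(unique(deduplicate_partials(c(frag(1, 120), frag(150, 290)), g))), 1)
  expect_equal(deduplicate_partials(frag(1, 150), g), 1L)
})

test_that("reciprocal verification accepts family members and rejects decoys", {
  set.seed(12)
  t1 <- tastemine:::.receptor_template(280)$protein
  t2 <- tastemine:::.receptor_template(300)$protein
  decoy <- paste0(sample(names(tastemine:::.KD), 300, replace = TRUE),
                  collapse = "")
  panel <- c(a = t1, b = t2, v = decoy)
  fams <- c("Tas2r", "Tas2r", "V2R")
  expect_equal(reciprocal_verify(t1, panel, fams), "Tas2r")
  # a diverged family member still verifies
  tm <- list(protein = t1, tm_mask = rep(TRUE, nchar(t1)))
  div <- tastemine:::.diverge_protein(list(protein = t1,
                                           tm_mask = rep(FALSE, nchar(t1))), 0.1)
  expect_equal(reciprocal_verify(div, panel, fams), "Tas2r")
  # a decoy-derived protein is rejected
  expect_equal(reciprocal_verify(decoy, panel, fams), "REJECTED")
  expect_error(reciprocal_verify(t1, character(0), character(0)), "empty")
})

test_that("gene names follow the four-letter prefix and genomic order", {
  models <- data.frame(contig = c("c2", "c1", "c1"), start = c(5L, 900L, 10L),
                       end = c(100L, 1000L, 200L), category = "INTACT")
  named <- assign_gene_names(models, "Leptobrachium leishanense", "Tas2r")
  expect_equal(attr(named, "prefix"), "Lele")
  ord <- named$gene_name[order(named$contig, named$start)]
  expect_equal(ord, c("Lele_Tas2r1", "Lele_Tas2r2", "Lele_Tas2r3"))

  b <- assign_gene_names(models, "Bufo gargarizans", "Tas2r")
  expect_equal(sort(b$gene_name)[3], "Buga_Tas2r3")

  empty <- assign_gene_names(models[0, ], "Bufo gargarizans")
  expect_equal(nrow(empty), 0)

  expect_error(
    assign_gene_names(models, "Bufo gargarizans",
                      existing_prefixes = c(Buga = "Bufo gargantuan")),
    "collision")
})
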