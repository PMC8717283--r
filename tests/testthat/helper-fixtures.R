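# Shared fixtures, memoised so expensive simulations run once per session.

.fixture_env <- new.env()

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# the reference planted-gene recovery condition
shared_sim <- function() memo("sim7",
  simulate_genome(sim_spec(n_intact = 20, n_partial = 5, n_pseudo = 5,
                           divergence = 0.1, seed = 7)))

shared_mining <- function() memo("mining7", {
  sim <- shared_sim()
  params <- search_params()
  hits <- filter_hits(search_genome(sim$queries, sim, params), params)
  loci <- extend_locus(merge_hits(hits, params), params, contig_lengths(sim))
  models <- annotate_loci(loci, sim, sim$queries)
  list(sim = sim, hits = hits, loci = loci, models = models,
       recovery = evaluate_recovery(models, sim$truth))
})

# balanced tree with uniform branch lengths, Newick string
balanced_tree <- function(n_tips, b, prefix = "t") {
  build <- function(v) {
    if (length(v) == 1) return(sprintf("%s:%g", v, b))
    h <- length(v) %/% 2
    sprintf("(%s,%s):%g", build(v[1:h]), build(v[(h + 1):length(v)]), b)
  }
  core <- build(sprintf("%s%d", prefix, seq_len(n_tips)))
  paste0(sub(":[0-9eE.+-]+$", "", core), ";")
}

# the 9-taxon tree used for omega parameter-recovery runs
omega_recovery_tree <- function(b = 0.15) {
  inner <- function(x, y) sprintf("(%s:%g,%s:%g):%g", x, b, y, b, b)
  sprintf("(((%s,%s):%g,(%s,%s):%g):%g,t9:%g);",
          inner("t1", "t2"), inner("t3", "t4"), b,
          inner("t5", "t6"), inner("t7", "t8"), b, b, 3 * b)
}

# a clean complete ORF for mutation round-trips: receptor-shaped, 299 aa
fixture_orf <- function(seed = 42) {
  set.seed(seed)
  tmpl <- tastemine:::.receptor_template(299)
  tastemine:::.backtranslate_orf(tmpl$protein)
}

fixture_template <- function(seed = 42) {
  set.seed(seed)
  tastemine:::.receptor_template(299)
}
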