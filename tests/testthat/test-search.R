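# Translated search: six-frame translation with coordinate maps, hit
# filtering/merging/extension rules, and planted-gene recall.

test_that("six-frame translation and coordinate maps are exact", {
  fr <- sixframe_translate("ATGAAA")
  fwd0 <- Filter(function(x) x$strand == "+" && x$frame == 0, fr)[[1]]
  expect_equal(fwd0$aa, "MK")

  # reverse-complement symmetry: forward frames of the reverse complement
  # equal the reverse frames of the original
  set.seed(1)
  s <- paste0(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  fr_s <- sixframe_translate(s)
  fr_rc <- sixframe_translate(tastemine:::revcomp(s))
  for (f in 0:2) {
    a <- Filter(function(x) x$strand == "-" && x$frame == f, fr_s)[[1]]$aa
    b <- Filter(function(x) x$strand == "+" && x$frame == f, fr_rc)[[1]]$aa
    expect_equal(a, b)
  }

  # round trip: frame position -> nt interval -> re-translation gives the
  # same residue, checked with independent index arithmetic
  set.seed(2)
  L <- 3000
  s <- paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  frames <- sixframe_translate(s)
  for (k in 1:1000) {
    fr <- frames[[sample(6, 1)]]
    n_aa <- nchar(fr$aa)
    p <- sample(n_aa, 1)
    nt <- frame_to_nt(fr$strand, fr$frame, p, p, L)
    sub <- substr(s, nt[1] + 1, nt[2])
    if (fr$strand == "-") sub <- tastemine:::revcomp(sub)
    expect_identical(oracle_translate(sub), substr(fr$aa, p, p))
  }
})

test_that("hits shorter than the minimum genomic span are discarded", {
  h <- structure(data.frame(query = "q", contig = "c", strand = "+",
                            frame = 0L, start = c(0L, 0L, 0L),
                            end = c(99L, 100L, 300L),
                            length_nt = c(99L, 100L, 300L),
                            score = c(50, 50, 50),
                            q_start = 1L, q_end = 10L),
                 class = c("search_hits", "data.frame"))
  out <- filter_hits(h, search_params())
  expect_equal(out$length_nt, c(100L, 300L))
  empty <- filter_hits(h[0, ], search_params())
  expect_equal(nrow(empty), 0)
})

test_that("merge_hits unions overlaps, keeps abutting loci apart, and matches a brute-force oracle", {
  mk <- function(start, end, frame = 0L, strand = "+") {
    data.frame(query = "q", contig = "c", strand = strand, frame = frame,
               start = start, end = end, length_nt = end - start, score = 10,
               q_start = 1L, q_end = 10L)
  }
  h <- structure(rbind(mk(100, 400), mk(350, 700)),
                 class = c("search_hits", "data.frame"))
  loci <- merge_hits(h, search_params(frameshift_gap = 0))
  expect_equal(nrow(loci), 1)
  expect_equal(c(loci$start, loci$end), c(100, 700))

  h2 <- structure(rbind(mk(100, 400), mk(400, 700)),
                  class = c("search_hits", "data.frame"))
  loci2 <- merge_hits(h2, search_params(frameshift_gap = 0))
  expect_equal(nrow(loci2), 2)

  # 500 random intervals against the coverage-vector union oracle
  set.seed(3)
  starts <- sample(0:5000, 500, replace = TRUE)
  ends <- starts + sample(30:400, 500, replace = TRUE)
  h3 <- structure(do.call(rbind, Map(mk, starts, ends)),
                  class = c("search_hits", "data.frame"))
  loci3 <- merge_hits(h3, search_params(frameshift_gap = 0))
  oracle <- oracle_interval_union(starts, ends)
  expect_equal(loci3$start, oracle$start)
  expect_equal(loci3$end, oracle$end)

  # idempotence: merging the merged loci changes nothing
  h4 <- structure(do.call(rbind, Map(mk, loci3$start, loci3$end)),
                  class = c("search_hits", "data.frame"))
  again <- merge_hits(h4, search_params(frameshift_gap = 0))
  expect_equal(again$start, loci3$start)
  expect_equal(again$end, loci3$end)

  # every input hit lies inside exactly one locus
  inside <- vapply(seq_len(nrow(h3)), function(i)
    sum(loci3$start <= h3$start[i] & loci3$end >= h3$end[i]), integer(1))
  expect_true(all(inside == 1))
  expect_lte(nrow(loci3), nrow(h3))

  # frameshift rule: nearby different-frame hits fuse into one locus
  h5 <- structure(rbind(mk(100, 400, frame = 0L), mk(430, 700, frame = 1L)),
                  class = c("search_hits", "data.frame"))
  expect_equal(nrow(merge_hits(h5, search_params(frameshift_gap = 50))), 1)
  expect_equal(nrow(merge_hits(h5, search_params(frameshift_gap = 10))), 2)
})

test_that("locus extension adds the flank and clips at contig bounds", {
  loci <- structure(data.frame(locus_id = c("l1", "l2", "l3"), contig = "c",
                               strand = "+", start = c(600L, 200L, 0L),
                               end = c(1500L, 900L, 10000L), n_hits = 1L,
                               best_query = "q", n_frames = 1L, score = 10),
                    class = c("candidate_loci", "data.frame"))
  out <- extend_locus(loci, search_params(), c(c = 10000L))
  expect_equal(out$start, c(100L, 0L, 0L))
  expect_equal(out$end, c(2000L, 1400L, 10000L))
})

test_that("planted genes are recovered and random queries are not", {
  sim <- shared_sim()
  mining <- shared_mining()
  hits <- mining$hits

  # identity query: a hit covers >= 95% of each planted intact interval
  sim_id <- simulate_genome(sim_spec(n_intact = 3, n_partial = 0,
                                     n_pseudo = 0, n_contigs = 4,
                                     divergence = 0, seed = 21))
  h_id <- search_genome(sim_id$queries, sim_id)
  for (i in seq_len(nrow(sim_id$truth))) {
    tr <- sim_id$truth[i, ]
    cover <- h_id[h_id$contig == tr$contig, ]
    olap <- sum(pmax(0, pmin(cover$end, tr$end) - pmax(cover$start, tr$start)))
    expect_gte(olap, 0.95 * (tr$end - tr$start))
  }

  # every planted gene (divergence 0.1) is overlapped by at least one hit
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    expect_true(any(hits$contig == tr$contig & hits$end > tr$start &
                      hits$start < tr$end), info = tr$gene_id)
  }

  # scrambled query against random genome: all hits (typically none) score
  # above threshold
  set.seed(4)
  scramble <- paste0(sample(names(tastemine:::.KD), 300, replace = TRUE),
                     collapse = "")
  h_rand <- search_genome(c(scr = scramble), sim$genome[1:5])
  expect_true(all(h_rand$score >= search_params()$min_score))

  # determinism with sorted tie-break order
  h_a <- search_genome(sim$queries, sim$genome[1:3])
  h_b <- search_genome(sim$queries, sim$genome[1:3])
  expect_identical(h_a, h_b)
  expect_true(!is.unsorted(order(h_a$contig, h_a$start)))
})
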