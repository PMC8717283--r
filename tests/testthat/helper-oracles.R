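# Independent oracles used to validate package computations. These share no
# code with the implementation paths they check.

# brute-force interval union via a coverage vector (0-based half-open input)
oracle_interval_union <- function(starts, ends) {
  if (!length(starts)) return(data.frame(start = integer(0), end = integer(0)))
  hi <- max(ends)
  cov <- logical(hi)
  for (i in seq_along(starts))
    if (ends[i] > starts[i]) cov[(starts[i] + 1L):ends[i]] <- TRUE
  r <- rle(cov)
  stop_at <- cumsum(r$lengths)
  start_at <- stop_at - r$lengths
  data.frame(start = start_at[r$values], end = stop_at[r$values])
}

# independent translation through Biostrings
oracle_translate <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3L
  as.character(Biostrings::translate(Biostrings::DNAString(substr(nt, 1, n)),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

# independent hydropathy-plot segment counter (direct per-position means)
oracle_tm_segments <- function(protein, window = 19, threshold = 1.6,
                               min_gap = 3) {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  if (n < window) return(0L)
  above <- vapply(seq_len(n - window + 1), function(i)
    mean(kd[aa[i:(i + window - 1)]], na.rm = TRUE) >= threshold, logical(1))
  tw <- which(above)
  if (!length(tw)) return(0L)
  # a below-threshold gap of at least min_gap windows separates segments
  1L + sum(diff(tw) >= min_gap + 1L)
}

# exhaustive dynamic-programming minimal reconciliation: minimises total
# duplications + losses over every embedding of the gene tree in the species
# tree (ties broken by fewest duplications)
oracle_reconcile_dp <- function(gene_tree, species_tree) {
  if (is.character(gene_tree)) gene_tree <- ape::read.tree(text = gene_tree)
  if (is.character(species_tree)) species_tree <- ape::read.tree(text = species_tree)
  sp_kids <- function(tr) {
    n <- length(tr$tip.label) + tr$Nnode
    k <- vector("list", n)
    for (e in seq_len(nrow(tr$edge)))
      k[[tr$edge[e, 1]]] <- c(k[[tr$edge[e, 1]]], tr$edge[e, 2])
    k
  }
  skids <- sp_kids(species_tree)
  gkids <- sp_kids(gene_tree)
  s_ntip <- length(species_tree$tip.label)
  s_n <- s_ntip + species_tree$Nnode
  # descendants (incl self) and pairwise edge distances on the species tree
  desc <- vector("list", s_n)
  fill_desc <- function(v) {
    d <- v
    for (k in skids[[v]]) d <- c(d, fill_desc(k))
    desc[[v]] <<- d
    d
  }
  fill_desc(s_ntip + 1L)
  depth <- integer(s_n); depth[s_ntip + 1L] <- 0L
  q <- s_ntip + 1L
  while (length(q)) {
    v <- q[1]; q <- q[-1]
    for (k in skids[[v]]) { depth[k] <- depth[v] + 1L; q <- c(q, k) }
  }
  g_ntip <- length(gene_tree$tip.label)
  g_n <- g_ntip + gene_tree$Nnode
  sp_of_leaf <- match(sub("_[^_]+$", "", gene_tree$tip.label),
                      species_tree$tip.label)
  INF <- 1e9
  # cost[g, s, ] = c(total, D)
  cost <- array(INF, dim = c(g_n, s_n, 2))
  solve_node <- function(g) {
    if (g <= g_ntip) {
      cost[g, sp_of_leaf[g], ] <<- c(0, 0)
      return()
    }
    for (k in gkids[[g]]) solve_node(k)
    u <- gkids[[g]][1]; v <- gkids[[g]][2]
    for (s in seq_len(s_n)) {
      best <- c(INF, INF)
      for (su in desc[[s]]) for (sv in desc[[s]]) {
        cu <- cost[u, su, ]; cv <- cost[v, sv, ]
        if (cu[1] >= INF || cv[1] >= INF) next
        ch <- skids[[s]]
        sep <- length(ch) == 2 &&
          ((su %in% desc[[ch[1]]] && sv %in% desc[[ch[2]]]) ||
             (su %in% desc[[ch[2]]] && sv %in% desc[[ch[1]]]))
        du <- depth[su] - depth[s]; dv <- depth[sv] - depth[s]
        if (sep) {
          tot <- cu[1] + cv[1] + (du - 1) + (dv - 1)
          D <- cu[2] + cv[2]
        } else {
          tot <- cu[1] + cv[1] + 1 + du + dv
          D <- cu[2] + cv[2] + 1
        }
        if (tot < best[1] || (tot == best[1] && D < best[2])) best <- c(tot, D)
      }
      cost[g, s, ] <<- best
    }
  }
  root <- g_ntip + 1L
  if (g_ntip == 1L) return(c(D = 0, L = 0))
  solve_node(root)
  tots <- cost[root, , 1]; Ds <- cost[root, , 2]
  best <- which(tots == min(tots))
  best <- best[which.min(Ds[best])]
  c(D = Ds[best], L = tots[best] - Ds[best])
}

# random gene/species tree pair with leaves labelled Species_gene
random_reconcile_case <- function(seed) {
  set.seed(seed)
  n_sp <- sample(2:4, 1)
  sp <- ape::rtree(n_sp, tip.label = LETTERS[1:n_sp], br = NULL)
  n_g <- sample(2:6, 1)
  gt <- ape::rtree(n_g, br = NULL)
  gt$tip.label <- sprintf("%s_g%d", sample(LETTERS[1:n_sp], n_g, replace = TRUE),
                          seq_len(n_g))
  list(gene = gt, species = sp)
}
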