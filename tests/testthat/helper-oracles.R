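# Independent oracles and fixture builders used across the suite.
# Each oracle is a brute-force or closed-form computation kept deliberately
# separate from the package's own code paths.

hamming <- function(a, b) sum(a != b)

# pairwise Hamming distance matrix for a character state matrix
hamming_matrix <- function(X) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- hamming(X[i, ], X[j, ])
  D
}

# total MST weight by Prim (independent re-implementation for oracles)
oracle_mst_weight <- function(D) {
  n <- nrow(D)
  if (n < 2) return(0)
  used <- c(TRUE, rep(FALSE, n - 1))
  best <- D[1, ]
  tot <- 0
  for (k in seq_len(n - 1)) {
    j <- which(!used)[which.min(best[!used])]
    tot <- tot + best[j]
    used[j] <- TRUE
    best <- pmin(best, D[j, ])
  }
  tot
}

# brute-force minimal Steiner configuration: minimum spanning weight over
# the observed haplotypes plus up to `max_extra` internal nodes drawn from
# the per-column observed state products
steiner_min_weight <- function(X, max_extra = 3) {
  cand <- as.matrix(expand.grid(lapply(seq_len(ncol(X)), function(j)
    unique(X[, j])), stringsAsFactors = FALSE))
  obs_key <- apply(X, 1, paste, collapse = "")
  cand <- cand[!apply(cand, 1, paste, collapse = "") %in% obs_key, ,
               drop = FALSE]
  best <- oracle_mst_weight(hamming_matrix(X))
  for (k in seq_len(min(max_extra, nrow(cand)))) {
    subsets <- utils::combn(nrow(cand), k)
    for (s in seq_len(ncol(subsets))) {
      full <- rbind(X, cand[subsets[, s], , drop = FALSE])
      w <- oracle_mst_weight(hamming_matrix(full))
      if (w < best) best <- w
    }
  }
  best
}

# exhaustive minimum spanning tree weight via Pruefer enumeration (n <= 7)
exhaustive_mst_weight <- function(D) {
  n <- nrow(D)
  stopifnot(n >= 2, n <= 7)
  if (n == 2) return(D[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    pr <- seqs[r, ]
    degree <- rep(1L, n)
    for (v in pr) degree[v] <- degree[v] + 1L
    w <- 0
    prf <- pr
    deg <- degree
    for (i in seq_along(prf)) {
      leaf <- which(deg == 1L)[1L]
      w <- w + D[leaf, prf[i]]
      deg[leaf] <- 0L
      deg[prf[i]] <- deg[prf[i]] - 1L
    }
    last <- which(deg == 1L)
    w <- w + D[last[1L], last[2L]]
    if (w < best) best <- w
  }
  best
}

# greedy Ward oracle: explicit SSE bookkeeping over point coordinates;
# returns the set of clusters (label vectors) formed across all merges
ward_oracle_clades <- function(P) {
  sse <- function(rows) {
    if (length(rows) < 2) return(0)
    ctr <- colMeans(P[rows, , drop = FALSE])
    sum(sweep(P[rows, , drop = FALSE], 2, ctr)^2)
  }
  clusters <- as.list(seq_len(nrow(P)))
  clades <- list()
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(length(clusters) - 1))
      for (j in (i + 1):length(clusters)) {
        un <- c(clusters[[i]], clusters[[j]])
        inc <- sse(un) - sse(clusters[[i]]) - sse(clusters[[j]])
        if (inc < best - 1e-12) { best <- inc; bi <- i; bj <- j }
      }
    merged <- sort(c(clusters[[bi]], clusters[[bj]]))
    clades[[length(clades) + 1]] <- rownames(P)[merged]
    clusters[[bi]] <- merged
    clusters[[bj]] <- NULL
  }
  lapply(clades, sort)
}

# rooted clade label sets of a phylo tree (excluding trivial singletons)
clade_set <- function(tr) {
  pp <- ape::prop.part(tr)
  lapply(pp, function(idx) sort(attr(pp, "labels")[idx]))
}

setequal_clades <- function(a, b) {
  ka <- sort(vapply(a, paste, "", collapse = "|"))
  kb <- sort(vapply(b, paste, "", collapse = "|"))
  identical(ka, kb)
}

# random additive distance matrix from a random tree with its generating tree
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- round(stats::runif(nrow(tr$edge), 0.5, 3), 2)
  D <- ape::cophenetic.phylo(tr)
  D <- D[order(rownames(D)), order(colnames(D))]
  list(tree = tr, D = D)
}

# small genotype table builder
toy_genotypes <- function() {
  msat_genotypes(data.frame(
    individual = c("i1", "i1", "i2", "i2", "i3", "i3"),
    group = c("A", "A", "A", "A", "B", "B"),
    locus = rep(c("L1", "L2"), 3),
    allele1 = c(10L, 20L, 10L, 22L, 14L, 20L),
    allele2 = c(12L, 20L, 10L, 22L, 14L, 24L),
    stringsAsFactors = FALSE))
}

tmpfile <- function(ext) tempfile(fileext = ext)
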