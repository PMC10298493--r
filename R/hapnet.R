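#' Collapse an alignment into distinct haplotypes
#'
#' Keeps the columns at which at least two distinct determined bases are
#' observed (the variable columns), then merges identical restricted
#' sequences, summing their sample multiplicities.
#'
#' @param a a \code{felid_alignment}.
#' @return an object of class \code{"haplotype_set"}: \code{haplotypes}
#'   (character matrix, rows = distinct haplotypes over variable columns),
#'   \code{labels} (representative = first member label), \code{members}
#'   (list of input labels per haplotype), \code{multiplicity},
#'   \code{column_map} (variable column -> original 1-based alignment
#'   column) and \code{n_input}.
#' @export
collapse_haplotypes <- function(a) {
  m <- aln_matrix(a)
  states <- apply(m, 2L, function(col) length(unique(col[is_base(col)])))
  var_cols <- which(states >= 2L)
  hm <- m[, var_cols, drop = FALSE]
  key <- apply(hm, 1L, paste, collapse = "")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  members <- split(a$labels, idx)
  structure(list(
    haplotypes = hm[first, , drop = FALSE],
    labels = a$labels[first],
    members = unname(members[order(as.integer(names(members)))]),
    multiplicity = as.integer(table(idx)),
    column_map = var_cols,
    n_input = n_seq(a)), class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("Haplotype set:", nrow(x$haplotypes), "haplotypes over",
      length(x$column_map), "variable columns (", x$n_input, "sequences )\n")
  invisible(x)
}

# pairwise mismatch counts over columns determined in both rows
hap_dist_matrix <- function(X) {
  bases <- c("A", "C", "G", "T")
  nm <- matrix(0, nrow(X), ncol(X))
  match_ct <- matrix(0, nrow(X), nrow(X))
  NM <- matrix(as.numeric(is_base(X)), nrow(X), ncol(X))
  for (s in bases) {
    I <- matrix(as.numeric(X == s), nrow(X), ncol(X))
    match_ct <- match_ct + tcrossprod(I)
  }
  both <- tcrossprod(NM)
  d <- both - match_ct
  diag(d) <- 0
  d
}

# connectivity thresholds: thr[i,j] = smallest w such that i and j are
# connected using only links of weight <= w; also the total MST weight.
conn_thresholds <- function(D) {
  n <- nrow(D)
  comp <- seq_len(n)
  thr <- matrix(0, n, n)
  mst_w <- 0
  for (w in sort(unique(D[upper.tri(D)]))) {
    repeat {
      idx <- which(D == w & outer(comp, comp, "!="), arr.ind = TRUE)
      if (nrow(idx) == 0L) break
      i <- idx[1L, 1L]; j <- idx[1L, 2L]
      a <- comp[i]; b <- comp[j]
      pa <- which(comp == a); pb <- which(comp == b)
      thr[pa, pb] <- w; thr[pb, pa] <- w
      comp[comp == b] <- a
      mst_w <- mst_w + w
    }
    if (all(comp == comp[1L])) break
  }
  list(thr = thr, mst_weight = mst_w, connected = all(comp == comp[1L]))
}

# minimum spanning network adjacency: link (i,j) present iff the direct
# distance is within epsilon of the connectivity threshold
msn_adjacency <- function(D, epsilon = 0) {
  ct <- conn_thresholds(D)
  A <- D <= ct$thr + epsilon & upper.tri(D)
  A <- A | t(A)
  diag(A) <- FALSE
  list(adj = A, mst_weight = ct$mst_weight)
}

# total MST weight of a node set given its distance matrix (Prim)
mst_weight <- function(D) {
  n <- nrow(D)
  if (n < 2L) return(0)
  intree <- c(TRUE, rep(FALSE, n - 1L))
  best <- D[1L, ]
  tot <- 0
  for (k in seq_len(n - 1L)) {
    cand <- which(!intree)
    j <- cand[which.min(best[cand])]
    tot <- tot + best[j]
    intree[j] <- TRUE
    best <- pmin(best, D[j, ])
  }
  tot
}

# per-column majority of three rows; ties resolved toward the earliest row
# (used by build_mjn for triplet median vectors)
# (rows must be passed in ascending node order); missing ignored
triplet_median <- function(a, b, c) {
  miss <- function(z) !is_base(z)
  med <- a
  ma <- miss(med); med[ma] <- b[ma]
  ma <- miss(med); med[ma] <- c[ma]
  bc <- (b == c) & !miss(b)
  med[bc] <- b[bc]
  ab <- (a == b | a == c) & !miss(a)
  med[ab] <- a[ab]
  med
}

#' Build a median-joining haplotype network
#'
#' Iterates the median-joining construction: (i) compute the minimum
#' spanning network keeping every link whose weight is within
#' \code{epsilon} of the smallest weight that connects its endpoints;
#' (ii) for each connected triplet (two links sharing a node) form the
#' per-column majority median vector; (iii) add median vectors whose
#' inclusion reduces the total minimum-spanning weight of the node set,
#' and repeat until no median helps. Median vectors left with fewer than
#' two links are deleted. Ties in the majority vote go to the state of the
#' first triplet member in node order. The maximum-parsimony pruning step
#' of the original software is not applied (see the package vignette).
#'
#' @param h a \code{\link{collapse_haplotypes}} result.
#' @param epsilon tolerance parameter \code{>= 0}; 0 (default) is the most
#'   parsimonious setting.
#' @param max_iter safety cap on median-addition sweeps.
#' @return an object of class \code{"hap_network"}: \code{nodes} (character
#'   matrix over variable columns; observed haplotypes then medians),
#'   \code{labels}, \code{is_median}, \code{multiplicity}, \code{edges}
#'   (data.frame \code{from}, \code{to}, \code{weight} with a list column
#'   \code{columns} of differing original alignment columns),
#'   \code{epsilon}, \code{column_map}.
#' @export
build_mjn <- function(h, epsilon = 0, max_iter = 25L) {
  stopifnot(inherits(h, "haplotype_set"), epsilon >= 0)
  X <- h$haplotypes
  labels <- h$labels
  is_median <- rep(FALSE, nrow(X))
  mult <- h$multiplicity
  n_med <- 0L
  for (iter in seq_len(max_iter)) {
    D <- hap_dist_matrix(X)
    msn <- msn_adjacency(D, epsilon)
    adj <- msn$adj
    cur_w <- msn$mst_weight
    keys <- apply(X, 1L, paste, collapse = "")
    added <- FALSE
    n <- nrow(X)
    for (v in seq_len(n)) {
      nb <- which(adj[v, ])
      if (length(nb) < 2L) next
      for (ii in seq_along(nb)[-length(nb)]) for (jj in (ii + 1L):length(nb)) {
        tri <- sort(c(v, nb[ii], nb[jj]))
        med <- triplet_median(X[tri[1L], ], X[tri[2L], ], X[tri[3L], ])
        key <- paste(med, collapse = "")
        if (key %in% keys) next
        dm <- colSums((t(X) != med) & is_base(t(X)) &
                        matrix(is_base(med), ncol(X), nrow(X)))
        D2 <- rbind(cbind(D, dm), c(dm, 0))
        w2 <- mst_weight(D2)
        if (w2 < cur_w) {
          X <- rbind(X, med)
          D <- D2
          keys <- c(keys, key)
          n_med <- n_med + 1L
          labels <- c(labels, paste0("mv", n_med))
          is_median <- c(is_median, TRUE)
          mult <- c(mult, 0L)
          cur_w <- w2
          added <- TRUE
        }
      }
    }
    if (!added) break
  }
  # delete obsolete median vectors (degree <= 1 in the final MSN)
  repeat {
    D <- hap_dist_matrix(X)
    adj <- msn_adjacency(D, epsilon)$adj
    deg <- rowSums(adj)
    drop <- which(is_median & deg <= 1L)
    if (length(drop) == 0L) break
    X <- X[-drop, , drop = FALSE]
    labels <- labels[-drop]
    is_median <- is_median[-drop]
    mult <- mult[-drop]
  }
  rownames(X) <- labels
  ed <- which(adj & upper.tri(adj), arr.ind = TRUE)
  cols <- lapply(seq_len(nrow(ed)), function(k) {
    i <- ed[k, 1L]; j <- ed[k, 2L]
    h$column_map[which(X[i, ] != X[j, ] & is_base(X[i, ]) & is_base(X[j, ]))]
  })
  edges <- data.frame(from = labels[ed[, 1L]], to = labels[ed[, 2L]],
                      weight = D[ed], stringsAsFactors = FALSE)
  edges$columns <- cols
  structure(list(nodes = X, labels = labels, is_median = is_median,
                 multiplicity = mult, edges = edges, epsilon = epsilon,
                 column_map = h$column_map),
            class = "hap_network")
}

#' Build a minimum spanning haplotype network (no inferred medians)
#'
#' The first phase of the median-joining construction on its own: every
#' link whose weight is within \code{epsilon} of the smallest weight
#' connecting its endpoints. Useful at mitogenome-scale divergences, where
#' inferred median vectors subdivide links without changing any
#' shortest-path distance from an ancestral node (the quantity rho uses);
#' see the vignette.
#'
#' @inheritParams build_mjn
#' @return a \code{hap_network} with no median vectors.
#' @export
build_msn <- function(h, epsilon = 0) {
  build_mjn(h, epsilon = epsilon, max_iter = 0L)
}

#' @export
print.hap_network <- function(x, ...) {
  cat("Median-joining network:", sum(!x$is_median), "haplotypes,",
      sum(x$is_median), "median vectors,", nrow(x$edges), "links",
      sprintf("(epsilon = %g)\n", x$epsilon))
  invisible(x)
}

#' Convert a haplotype network to an igraph object
#' @param net a \code{hap_network}.
#' @return an igraph undirected graph; vertex attributes \code{label},
#'   \code{multiplicity}, \code{is_median}; edge attribute \code{weight}.
#' @export
as_igraph <- function(net) {
  vs <- data.frame(name = net$labels, multiplicity = net$multiplicity,
                   is_median = net$is_median, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(net$edges[, c("from", "to", "weight")],
                                directed = FALSE, vertices = vs)
}

#' Export a haplotype network as GraphML
#' @param net a \code{hap_network}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Years-per-mutation calendar from a per-position rate
#'
#' Converts a substitution rate in percent per million years per position
#' and a sequence length into the expected waiting time between mutations
#' on that sequence: \code{round(1 / (length * rate/100/1e6))} years. For
#' the 315-bp ND5 fragment at 1.22\%/My this is 260,213 years.
#'
#' @param length sequence length in bp (\code{>= 1}).
#' @param rate substitution rate, percent per My per position (\code{> 0}).
#' @return integer years per mutation.
#' @export
years_per_mutation <- function(length, rate) {
  if (length < 1 || rate <= 0) stop("domain error: need length >= 1, rate > 0")
  round(1 / (length * rate / 100 / 1e6))
}

#' Mutation-rate calendar specification
#' @param rate percent per My per position.
#' @param length sequence length in bp.
#' @param years_per_mutation override for the derived calendar (used when a
#'   published calendar does not match its stated length and rate).
#' @return list with \code{rate}, \code{length}, \code{years_per_mutation}.
#' @export
mutation_rate_spec <- function(rate, length,
                               years_per_mutation = NULL) {
  ypm <- if (is.null(years_per_mutation))
    years_per_mutation(length, rate) else years_per_mutation
  structure(list(rate = rate, length = length, years_per_mutation = ypm),
            class = "rate_spec")
}

# deterministic Dijkstra parent tree from the ancestor node
shortest_path_tree <- function(net, ancestor) {
  n <- length(net$labels)
  W <- matrix(Inf, n, n)
  ei <- match(net$edges$from, net$labels)
  ej <- match(net$edges$to, net$labels)
  W[cbind(ei, ej)] <- net$edges$weight
  W[cbind(ej, ei)] <- net$edges$weight
  src <- match(ancestor, net$labels)
  dist <- rep(Inf, n); dist[src] <- 0
  parent <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  for (k in seq_len(n)) {
    open <- which(!done & is.finite(dist))
    if (length(open) == 0L) break
    u <- open[which.min(dist[open])]
    done[u] <- TRUE
    relax <- which(is.finite(W[u, ]))
    for (v in relax) {
      nd <- dist[u] + W[u, v]
      if (nd < dist[v] || (nd == dist[v] && !is.na(parent[v]) && u < parent[v])) {
        dist[v] <- nd
        parent[v] <- u
      }
    }
  }
  list(dist = dist, parent = parent)
}

#' The rho statistic: mean mutational distance from an ancestral node
#'
#' \code{rho} is the multiplicity-weighted mean number of mutations along
#' network shortest paths from a designated ancestral node to the sampled
#' haplotypes. Its standard error uses the genealogy implied by the
#' shortest-path tree: every mutation on a tree edge subtends the sampled
#' fraction below that edge, and \code{sigma^2} is the sum of those squared
#' fractions.
#'
#' @param net a \code{hap_network}.
#' @param ancestor label of the designated ancestral node (must be chosen by
#'   the analyst; the method does not root itself).
#' @param tips labels of the sampled haplotypes to average over; defaults to
#'   every observed (non-median) haplotype except the ancestor.
#' @param calendar optional \code{\link{mutation_rate_spec}}; when supplied,
#'   \code{time} and \code{time_error} in years are filled in.
#' @return object of class \code{"rho_estimate"}: \code{rho}, \code{sigma},
#'   \code{n_tips} (total multiplicity averaged over), and \code{time},
#'   \code{time_error} in years when a calendar is given.
#' @export
rho <- function(net, ancestor, tips = NULL, calendar = NULL) {
  if (!ancestor %in% net$labels)
    stop("lookup error: unknown ancestor '", ancestor, "'")
  if (is.null(tips))
    tips <- setdiff(net$labels[!net$is_median], ancestor)
  spt <- shortest_path_tree(net, ancestor)
  ti <- match(tips, net$labels)
  if (anyNA(ti)) stop("lookup error: unknown tip label")
  if (any(!is.finite(spt$dist[ti])))
    stop("connectivity error: tip not reachable from ancestor")
  m <- net$multiplicity[ti]
  m[m == 0L] <- 1L  # user-designated median tips count once
  M <- sum(m)
  r <- sum(m * spt$dist[ti]) / M
  # multiplicity below each parent edge, summed over the tips set
  below <- rep(0, length(net$labels))
  for (k in seq_along(ti)) {
    v <- ti[k]
    while (!is.na(spt$parent[v])) {
      below[v] <- below[v] + m[k]
      v <- spt$parent[v]
    }
  }
  edge_w <- spt$dist - spt$dist[spt$parent]
  has_par <- !is.na(spt$parent)
  s2 <- sum(edge_w[has_par] * (below[has_par] / M)^2)
  out <- list(rho = r, sigma = sqrt(s2), n_tips = M,
              time = NA_real_, time_error = NA_real_)
  if (!is.null(calendar)) {
    out$time <- r * calendar$years_per_mutation
    out$time_error <- out$sigma * calendar$years_per_mutation
  }
  structure(out, class = "rho_estimate")
}

#' @export
print.rho_estimate <- function(x, ...) {
  cat(sprintf("rho = %.3f +/- %.3f over %d sampled haplotypes\n",
              x$rho, x$sigma, x$n_tips))
  if (!is.na(x$time))
    cat(sprintf("  dated: %.2f +/- %.2f My\n", x$time / 1e6,
                x$time_error / 1e6))
  invisible(x)
}

#' Date a split from a rho estimate and a calendar
#' @param r a \code{\link{rho}} estimate.
#' @param cal a \code{\link{mutation_rate_spec}}.
#' @return list with \code{time_my} and \code{error_my} (million years);
#'   the print method displays two decimals.
#' @export
date_split <- function(r, cal) {
  structure(list(time_my = r$rho * cal$years_per_mutation / 1e6,
                 error_my = r$sigma * cal$years_per_mutation / 1e6),
            class = "split_date")
}

#' @export
print.split_date <- function(x, ...) {
  cat(sprintf("split: %.2f +/- %.2f My\n", x$time_my, x$error_my))
  invisible(x)
}

#' Average independent split estimates
#'
#' Utility for combining dating results obtained by different procedures on
#' the same split (e.g. a dated-tree estimate and a network rho estimate).
#'
#' @param estimates numeric vector of split times in My.
#' @param digits decimals to round the mean to (default 1).
#' @return rounded mean in My.
#' @export
combine_split_estimates <- function(estimates, digits = 1L) {
  round(mean(estimates), digits)
}
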