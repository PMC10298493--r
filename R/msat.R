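#' Construct a microsatellite genotype table
#'
#' Diploid genotypes at a set of loci: every call is an unordered pair of
#' allele sizes in repeat units (positive integers), or missing (both
#' \code{NA}). Stored long, one row per individual x locus.
#'
#' @param df data.frame with columns \code{individual}, \code{group},
#'   \code{locus}, \code{allele1}, \code{allele2}.
#' @return object of class \code{"msat_genotypes"}: the validated long
#'   data.frame plus \code{individuals}, \code{groups} (named by
#'   individual), \code{loci}.
#' @export
msat_genotypes <- function(df) {
  need <- c("individual", "group", "locus", "allele1", "allele2")
  if (!all(need %in% names(df)))
    stop("genotype table needs columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df$individual <- as.character(df$individual)
  df$group <- as.character(df$group)
  df$locus <- as.character(df$locus)
  one_na <- xor(is.na(df$allele1), is.na(df$allele2))
  if (any(one_na))
    stop("half-missing call (exactly one allele) for individual ",
         df$individual[one_na][1L])
  sizes <- c(df$allele1, df$allele2)
  if (any(!is.na(sizes) & (sizes < 1 | sizes != round(sizes))))
    stop("allele sizes must be positive integers (repeat units)")
  grp <- unique(df[, c("individual", "group")])
  if (anyDuplicated(grp$individual))
    stop("individual assigned to more than one group")
  groups <- stats::setNames(grp$group, grp$individual)
  structure(list(calls = df, individuals = grp$individual,
                 groups = groups, loci = unique(df$locus)),
            class = "msat_genotypes")
}

#' @export
print.msat_genotypes <- function(x, ...) {
  cat("Microsatellite genotypes:", length(x$individuals), "individuals,",
      length(x$loci), "loci,", length(unique(x$groups)), "groups\n")
  invisible(x)
}

#' Read a genotype CSV
#' @param path CSV with columns
#'   \code{individual,group,locus,allele1,allele2}.
#' @return a \code{msat_genotypes}.
#' @export
read_genotypes <- function(path) {
  msat_genotypes(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a genotype CSV
#' @param g a \code{msat_genotypes}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_genotypes <- function(g, path) {
  utils::write.csv(g$calls, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Group-level allele frequencies and mean allele sizes
#'
#' Each called genotype contributes two allele observations to its group;
#' missing calls contribute none. The per-group, per-locus mean allele size
#' \code{mu} is the frequency-weighted mean size in repeat units.
#'
#' @param g a \code{msat_genotypes}.
#' @param grouping optional named vector individual -> group overriding the
#'   table's group column.
#' @return object of class \code{"allele_freq_table"}: \code{groups},
#'   \code{loci}, \code{freq[[locus]][[group]]} (named relative-frequency
#'   vectors), \code{mean_size} and \code{sample_size} (group x locus
#'   matrices; sample sizes count alleles).
#' @export
allele_freqs <- function(g, grouping = NULL) {
  calls <- g$calls
  if (!is.null(grouping)) calls$group <- grouping[calls$individual]
  groups <- unique(calls$group)
  loci <- g$loci
  long <- rbind(calls[, c("group", "locus", "allele1")] |>
                  stats::setNames(c("group", "locus", "allele")),
                calls[, c("group", "locus", "allele2")] |>
                  stats::setNames(c("group", "locus", "allele")))
  long <- long[!is.na(long$allele), ]
  freq <- list()
  mean_size <- matrix(NA_real_, length(groups), length(loci),
                      dimnames = list(groups, loci))
  sample_size <- matrix(0L, length(groups), length(loci),
                        dimnames = list(groups, loci))
  for (l in loci) {
    freq[[l]] <- list()
    for (gr in groups) {
      al <- long$allele[long$locus == l & long$group == gr]
      if (length(al) == 0L) {
        freq[[l]][[gr]] <- numeric(0)
        next
      }
      tab <- table(al) / length(al)
      fv <- as.numeric(tab)
      names(fv) <- names(tab)
      freq[[l]][[gr]] <- fv
      mean_size[gr, l] <- sum(as.numeric(names(fv)) * fv)
      sample_size[gr, l] <- length(al)
    }
  }
  empty <- rowSums(sample_size) == 0L
  if (any(empty))
    stop("empty-group error: no called genotype in group ",
         groups[empty][1L], call. = FALSE)
  structure(list(groups = groups, loci = loci, freq = freq,
                 mean_size = mean_size, sample_size = sample_size),
            class = "allele_freq_table")
}

#' Delta-mu-squared distance between two groups
#'
#' The squared difference of mean allele sizes, averaged over the loci with
#' data in both groups. Under the stepwise mutation model its expectation
#' after \code{tau} generations of divergence at mutation rate \code{beta}
#' is \code{2 * beta * tau}. Averaging (rather than summing) over loci keeps
#' values comparable across locus subsets during bootstrap.
#'
#' @param f an \code{\link{allele_freqs}} table.
#' @param a,b group labels.
#' @return numeric distance (squared repeat units).
#' @export
delta_mu2 <- function(f, a, b) {
  stopifnot(a %in% f$groups, b %in% f$groups)
  ok <- f$sample_size[a, ] > 0L & f$sample_size[b, ] > 0L
  if (!any(ok)) stop("no-overlap error: no locus shared by ", a, " and ", b)
  mean((f$mean_size[a, ok] - f$mean_size[b, ok])^2)
}

#' All-pairs group distance matrix from microsatellite frequencies
#'
#' \code{"deltamu2"} applies \code{\link{delta_mu2}}; \code{"euclidean"} is
#' the Euclidean distance between group allele-frequency vectors over the
#' union of (locus, allele) keys (loci missing in a group contribute their
#' zero vector).
#'
#' @param f an \code{\link{allele_freqs}} table.
#' @param method \code{"deltamu2"} or \code{"euclidean"}.
#' @return a \code{felid_dist} over groups.
#' @export
group_distance_matrix <- function(f, method = c("deltamu2", "euclidean")) {
  method <- match.arg(method)
  n <- length(f$groups)
  d <- matrix(0, n, n, dimnames = list(f$groups, f$groups))
  if (method == "deltamu2") {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- delta_mu2(f, f$groups[i], f$groups[j])
  } else {
    V <- freq_vectors(f)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- sqrt(sum((V[i, ] - V[j, ])^2))
  }
  dist_matrix(d, f$groups)
}

# group x (locus, allele) frequency matrix
freq_vectors <- function(f) {
  keys <- unlist(lapply(f$loci, function(l)
    paste(l, sort(unique(unlist(lapply(f$freq[[l]], names)))), sep = ":")))
  V <- matrix(0, length(f$groups), length(keys),
              dimnames = list(f$groups, keys))
  for (l in f$loci) for (gr in f$groups) {
    fv <- f$freq[[l]][[gr]]
    if (length(fv)) V[gr, paste(l, names(fv), sep = ":")] <- fv
  }
  V
}

# individuals x (locus, allele) 0/1/2 allele-count encoding with group-mean
# imputation of missing calls; loci restricted via `loci`
allele_count_encoding <- function(g, loci = g$loci) {
  calls <- g$calls[g$calls$locus %in% loci, ]
  keys <- character(0)
  for (l in loci) {
    sizes <- sort(unique(stats::na.omit(
      c(calls$allele1[calls$locus == l], calls$allele2[calls$locus == l]))))
    keys <- c(keys, paste(l, sizes, sep = ":"))
  }
  M <- matrix(0, length(g$individuals), length(keys),
              dimnames = list(g$individuals, keys))
  called <- matrix(FALSE, length(g$individuals), length(loci),
                   dimnames = list(g$individuals, loci))
  for (r in seq_len(nrow(calls))) {
    if (is.na(calls$allele1[r])) next
    id <- calls$individual[r]; l <- calls$locus[r]
    called[id, l] <- TRUE
    for (al in c(calls$allele1[r], calls$allele2[r])) {
      k <- paste(l, al, sep = ":")
      M[id, k] <- M[id, k] + 1
    }
  }
  # impute missing calls with the individual's group mean allele counts
  for (l in loci) {
    cols <- grep(paste0("^", l, ":"), colnames(M))
    for (id in g$individuals[!called[, l]]) {
      same <- g$individuals[g$groups == g$groups[id] & called[, l]]
      donor <- if (length(same)) same else g$individuals[called[, l]]
      if (length(donor) == 0L) next
      M[id, cols] <- colMeans(M[donor, cols, drop = FALSE])
    }
  }
  M
}

#' Squared-Euclidean distance matrix among individuals
#'
#' Each individual is encoded as a vector of allele counts (0/1/2) over the
#' union of (locus, allele) keys; the distance is the squared Euclidean
#' distance between these vectors. A missing call is imputed with the
#' individual's group mean allele counts at that locus so the vectors stay
#' complete (a requirement of Ward clustering).
#'
#' @param g a \code{msat_genotypes} with at least 2 individuals.
#' @param loci optional locus subset (used by the locus bootstrap).
#' @return a \code{felid_dist} over individuals (squared repeat-unit^2
#'   scale).
#' @export
individual_distance_matrix <- function(g, loci = g$loci) {
  stopifnot(length(g$individuals) >= 2L)
  M <- allele_count_encoding(g, loci)
  d <- as.matrix(stats::dist(M))^2
  dist_matrix(d, g$individuals)
}

#' Ward minimum-variance tree with locus bootstrap
#'
#' Agglomerates individuals by Ward's minimum-variance criterion
#' (Lance-Williams \code{ward.D} update on the squared Euclidean distances
#' from \code{\link{individual_distance_matrix}}). When genotypes are
#' supplied, bootstrap support is the percentage of \code{B} locus-resampled
#' trees containing each internal bipartition (clade, since a Ward tree is
#' rooted).
#'
#' @param x a \code{msat_genotypes} (enables the bootstrap) or a
#'   \code{felid_dist} of squared Euclidean distances.
#' @param B bootstrap replicates (0 disables; default 500).
#' @param seed integer seed for the locus resampling.
#' @return an \code{ape} \code{phylo} tree (rooted), node labels carrying
#'   bootstrap support in percent when computed.
#' @export
ward_tree <- function(x, B = 500L, seed = 20230615L) {
  if (inherits(x, "msat_genotypes")) {
    m <- individual_distance_matrix(x)
  } else {
    m <- x
    B <- 0L
  }
  hc <- stats::hclust(stats::as.dist(m$d), method = "ward.D")
  tr <- ape::as.phylo(hc)
  if (B > 0L) {
    set.seed(seed)
    boots <- vector("list", B)
    for (b in seq_len(B)) {
      loci <- sample(x$loci, length(x$loci), replace = TRUE)
      db <- individual_distance_matrix(x, loci = loci)
      boots[[b]] <- ape::as.phylo(stats::hclust(stats::as.dist(db$d),
                                                method = "ward.D"))
    }
    cnt <- ape::prop.clades(tr, boots, rooted = TRUE)
    cnt[is.na(cnt)] <- 0L
    tr$node.label <- round(100 * cnt / B)
  }
  tr
}

#' Unrooted neighbour-joining tree
#'
#' Canonical neighbour-joining on a distance matrix; negative branch
#' lengths are clamped to zero with the deficit transferred to the sister
#' branch so path lengths are preserved as far as possible.
#'
#' @param m a \code{felid_dist} with at least 3 labels.
#' @return an unrooted \code{phylo} tree.
#' @export
nj_tree <- function(m) {
  stopifnot(length(m$labels) >= 3L)
  tr <- ape::nj(stats::as.dist(m$d))
  for (pass in 1:10) {
    neg <- which(tr$edge.length < -1e-12)
    if (length(neg) == 0L) break
    k <- neg[1L]
    p <- tr$edge[k, 1L]
    sib <- setdiff(which(tr$edge[, 1L] == p), k)
    if (length(sib)) tr$edge.length[sib[1L]] <-
        tr$edge.length[sib[1L]] + tr$edge.length[k]
    tr$edge.length[k] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  ape::unroot(tr)
}

#' Principal coordinate analysis (Gower)
#'
#' Double-centers \code{-d^2/2} and eigendecomposes it; coordinates are the
#' eigenvectors scaled by the square roots of the positive eigenvalues.
#' Negative eigenvalues (possible for non-Euclidean inputs such as
#' delta-mu-squared) are reported and their axes dropped.
#'
#' @param m a \code{felid_dist} with at least 3 labels.
#' @return object of class \code{"pcoa_ordination"}: \code{coordinates}
#'   (points x axes), \code{eigenvalues} (all, descending),
#'   \code{negative_eigenvalue_mass}, \code{percent_variance} (per retained
#'   axis, of the positive eigenvalue total).
#' @export
pcoa <- function(m) {
  stopifnot(length(m$labels) >= 3L)
  n <- length(m$labels)
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(m$d), k = n - 1L, eig = TRUE))
  eig <- fit$eig
  tol <- 1e-9 * max(abs(eig), 1)
  pos <- which(eig > tol)
  pts <- fit$points[, seq_along(pos), drop = FALSE]
  rownames(pts) <- m$labels
  colnames(pts) <- paste0("Axis", seq_along(pos))
  structure(list(
    coordinates = pts,
    eigenvalues = eig,
    negative_eigenvalue_mass = abs(sum(eig[eig < 0])) / sum(abs(eig)),
    percent_variance = 100 * eig[pos] / sum(eig[pos])),
    class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat("PCoA:", nrow(x$coordinates), "points,", ncol(x$coordinates),
      "positive axes; axis 1-2 variance:",
      paste0(round(x$percent_variance[seq_len(min(2, ncol(x$coordinates)))],
                   1), "%", collapse = ", "), "\n")
  invisible(x)
}

#' Minimum spanning tree of a distance matrix
#'
#' Prim's algorithm started from the first label, with deterministic
#' tie-breaks by label order, so repeated runs give identical edge lists.
#'
#' @param m a \code{felid_dist} with at least 2 labels.
#' @return data.frame \code{from}, \code{to}, \code{weight} with
#'   \code{n - 1} rows.
#' @export
mst <- function(m) {
  n <- length(m$labels)
  stopifnot(n >= 2L)
  D <- m$d
  intree <- c(TRUE, rep(FALSE, n - 1L))
  best <- D[1L, ]; bestfrom <- rep(1L, n)
  out <- NULL
  for (k in seq_len(n - 1L)) {
    cand <- which(!intree)
    j <- cand[which.min(best[cand])]  # which.min is first-index on ties
    out <- rbind(out, data.frame(from = m$labels[min(bestfrom[j], j)],
                                 to = m$labels[max(bestfrom[j], j)],
                                 weight = best[j],
                                 stringsAsFactors = FALSE))
    intree[j] <- TRUE
    upd <- which(!intree & D[j, ] < best)
    best[upd] <- D[j, upd]
    bestfrom[upd] <- j
  }
  out
}

#' Overlay a minimum spanning tree on a PCoA ordination
#'
#' Pairs the first two ordination axes with MST edges drawn between the
#' corresponding points; the result can be plotted, or written as a
#' combined coordinates+edges CSV and as an SVG figure.
#'
#' @param o a \code{\link{pcoa}} ordination.
#' @param edges an \code{\link{mst}} edge list over the same labels.
#' @return object of class \code{"pcoa_mst_overlay"} with \code{points}
#'   (label, x, y), \code{edges}, and axis labels carrying the percent
#'   variance of the displayed axes.
#' @export
pcoa_mst_overlay <- function(o, edges) {
  stopifnot(inherits(o, "pcoa_ordination"), ncol(o$coordinates) >= 2L)
  pts <- data.frame(label = rownames(o$coordinates),
                    x = o$coordinates[, 1L], y = o$coordinates[, 2L],
                    stringsAsFactors = FALSE, row.names = NULL)
  stopifnot(all(edges$from %in% pts$label), all(edges$to %in% pts$label))
  structure(list(
    points = pts, edges = edges,
    xlab = sprintf("PCoA axis 1 (%.1f%%)", o$percent_variance[1L]),
    ylab = sprintf("PCoA axis 2 (%.1f%%)", o$percent_variance[2L])),
    class = "pcoa_mst_overlay")
}

#' @export
plot.pcoa_mst_overlay <- function(x, ...) {
  graphics::plot(x$points$x, x$points$y, xlab = x$xlab, ylab = x$ylab,
                 pch = 19, ...)
  i <- match(x$edges$from, x$points$label)
  j <- match(x$edges$to, x$points$label)
  graphics::segments(x$points$x[i], x$points$y[i],
                     x$points$x[j], x$points$y[j], col = "grey40")
  graphics::text(x$points$x, x$points$y, x$points$label, pos = 3, cex = 0.7)
  invisible(x)
}

#' Write a PCoA+MST overlay to disk
#'
#' The CSV holds one \code{record} column distinguishing point rows
#' (label, x, y) from edge rows (from, to, weight). The SVG is drawn with
#' the base \code{svg} device when the build of R supports it.
#'
#' @param ov a \code{\link{pcoa_mst_overlay}}.
#' @param csv path for the combined CSV (always written).
#' @param svg optional path for an SVG figure.
#' @return \code{csv}, invisibly.
#' @export
write_overlay <- function(ov, csv, svg = NULL) {
  pts <- data.frame(record = "point", label = ov$points$label,
                    from = NA, to = NA,
                    x = ov$points$x, y = ov$points$y, weight = NA)
  eds <- data.frame(record = "edge", label = NA,
                    from = ov$edges$from, to = ov$edges$to,
                    x = NA, y = NA, weight = ov$edges$weight)
  utils::write.csv(rbind(pts, eds), csv, row.names = FALSE)
  if (!is.null(svg)) {
    if (!capabilities("cairo"))
      stop("SVG output needs cairo support in this R build")
    grDevices::svg(svg, width = 7, height = 6)
    on.exit(grDevices::dev.off())
    plot(ov, main = "PCoA with MST overlay")
  }
  invisible(csv)
}
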