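test_that("allele frequencies and mean sizes aggregate diploid calls", {
  g <- msat_genotypes(data.frame(
    individual = c("i1", "i2", "i3"), group = "A",
    locus = "L1", allele1 = c(10L, 10L, NA), allele2 = c(12L, 10L, NA)))
  f <- allele_freqs(g)
  expect_equal(f$freq$L1$A, c("10" = 0.75, "12" = 0.25))
  expect_equal(f$mean_size["A", "L1"], 10.5)
  expect_equal(f$sample_size["A", "L1"], 4L)  # the missing call adds nothing

  # a group with no called genotype anywhere is an error
  gb <- msat_genotypes(data.frame(
    individual = c("i1", "i2"), group = c("A", "B"), locus = "L1",
    allele1 = c(10L, NA), allele2 = c(12L, NA)))
  expect_error(allele_freqs(gb), "empty-group")

  g1 <- msat_genotypes(data.frame(individual = "i1", group = "A",
                                  locus = "L1", allele1 = 10L,
                                  allele2 = 12L))
  f1 <- allele_freqs(g1)
  expect_equal(f1$freq$L1$A, c("10" = 0.5, "12" = 0.5))
  expect_equal(f1$mean_size["A", "L1"], 11)

  expect_error(msat_genotypes(data.frame(
    individual = "i1", group = "A", locus = "L1",
    allele1 = 10L, allele2 = NA)), "half-missing")
})

test_that("genotype tables round-trip through CSV", {
  g <- toy_genotypes()
  f <- tmpfile(".csv")
  write_genotypes(g, f)
  g2 <- read_genotypes(f)
  expect_equal(g2$calls$allele1, g$calls$allele1)
  expect_equal(g2$groups, g$groups)
})

test_that("delta-mu-squared is the mean squared difference of mean sizes", {
  g <- toy_genotypes()
  f <- allele_freqs(g)
  expect_equal(delta_mu2(f, "A", "A"), 0)
  # A means: L1 (10+12+10+10)/4 = 10.5, L2 (20+20+22+22)/4 = 21
  # B means: L1 14, L2 22
  expect_equal(delta_mu2(f, "A", "B"), ((10.5 - 14)^2 + (21 - 22)^2) / 2)
  dm <- group_distance_matrix(f, "deltamu2")
  expect_equal(dm$d["A", "B"], dm$d["B", "A"])
  # exact-shift construction: mu differs by 2 at every locus
  gs <- msat_genotypes(data.frame(
    individual = rep(c("a1", "b1"), each = 6),
    group = rep(c("A", "B"), each = 6),
    locus = rep(paste0("L", 1:6), 2),
    allele1 = c(rep(10L, 6), rep(12L, 6)),
    allele2 = c(rep(10L, 6), rep(12L, 6))))
  expect_equal(delta_mu2(allele_freqs(gs), "A", "B"), 4)
})

test_that("individual allele-count encoding gives the documented squared
          Euclidean distances", {
  g <- msat_genotypes(data.frame(
    individual = c("i1", "i2", "i3"), group = "A", locus = "L1",
    allele1 = c(10L, 12L, 10L), allele2 = c(10L, 12L, 12L)))
  m <- individual_distance_matrix(g)
  expect_equal(m$d["i1", "i2"], 8)  # (2,0) vs (0,2)
  expect_equal(m$d["i1", "i3"], 2)  # (2,0) vs (1,1)
  expect_equal(m$d["i1", "i1"], 0)
})

test_that("missing calls are imputed with group mean allele counts", {
  g <- msat_genotypes(data.frame(
    individual = c("i1", "i2", "i3"), group = "A",
    locus = "L1", allele1 = c(10L, 10L, NA), allele2 = c(10L, 12L, NA)))
  M <- felidelim:::allele_count_encoding(g)
  expect_equal(unname(M["i3", ]), c(1.5, 0.5))  # mean of (2,0) and (1,1)
})

test_that("Ward trees merge by minimum SSE increase (brute-force oracle)", {
  for (s in 1:6) {
    set.seed(800 + s)
    n <- sample(5:7, 1)
    P <- matrix(stats::rnorm(n * 3), n, 3,
                dimnames = list(paste0("p", 1:n), NULL))
    D2 <- as.matrix(stats::dist(P))^2
    wt <- ward_tree(dist_matrix(D2))
    expect_true(setequal_clades(clade_set(wt), ward_oracle_clades(P)))
  }
  # merging two singletons at squared distance d costs d/2 in SSE
  P <- rbind(a = c(0, 0), b = c(2, 0))
  d <- sum((P[1, ] - P[2, ])^2)
  ctr <- colMeans(P)
  expect_equal(sum(sweep(P, 2, ctr)^2), d / 2)
})

test_that("locus bootstrap supports planted group structure", {
  g <- simulate_msat(n_pops = 3, tau = 3000, beta = 0.01, n_loci = 12,
                     n_ind = 5, seed = 77)
  wt <- ward_tree(g, B = 120, seed = 78)
  expect_true(all(wt$node.label >= 0 & wt$node.label <= 100))
  grp_clades <- Filter(function(cl)
    length(unique(sub("_.*", "", cl))) == 1L && length(cl) == 5L,
    clade_set(wt))
  expect_equal(length(grp_clades), 3L)  # each population is a clade
  sup <- wt$node.label[match(
    vapply(grp_clades, paste, "", collapse = "|"),
    vapply(clade_set(wt), paste, "", collapse = "|"))]
  expect_true(all(sup >= 90))
})

test_that("neighbour-joining recovers additive matrices exactly", {
  for (s in 1:8) {
    ra <- random_additive(sample(4:8, 1), 820 + s)
    tr <- nj_tree(dist_matrix(ra$D))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(ra$tree), tr)), 0)
    co <- ape::cophenetic.phylo(tr)[rownames(ra$D), colnames(ra$D)]
    expect_equal(co, ra$D, tolerance = 1e-8)
  }
  # 3 taxa: unique unrooted topology, three-point branch lengths
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(dist_matrix(D))
  co <- ape::cophenetic.phylo(t3)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(co, D)
})

test_that("on ultrametric input NJ matches UPGMA topology", {
  for (s in 1:4) {
    set.seed(840 + s)
    tr <- ape::rcoal(6)
    D <- ape::cophenetic.phylo(tr)
    njt <- nj_tree(dist_matrix(D))
    up <- phangorn::upgma(stats::as.dist(D))
    expect_equal(as.numeric(ape::dist.topo(njt, ape::unroot(up))), 0)
  }
})

test_that("PCoA reproduces Euclidean geometry and reports negative mass", {
  # collinear points at distances 1, 1, 2
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(c("p", "q", "r"), c("p", "q", "r")))
  o <- pcoa(dist_matrix(D))
  expect_equal(sort(unname(o$coordinates[, 1])), c(-1, 0, 1))
  expect_equal(unname(colMeans(o$coordinates)), 0, tolerance = 1e-9)
  # full reconstruction of a 3-D Gaussian cloud
  set.seed(9)
  P <- matrix(stats::rnorm(30), 10, 3)
  D3 <- as.matrix(stats::dist(P))
  rownames(D3) <- colnames(D3) <- paste0("g", 1:10)
  o3 <- pcoa(dist_matrix(D3))
  rec <- as.matrix(stats::dist(o3$coordinates))
  expect_equal(unname(rec), unname(D3), tolerance = 1e-6)
  expect_equal(ncol(o3$coordinates), 3L)
  expect_lt(o3$negative_eigenvalue_mass, 1e-9)
  expect_true(all(diff(o3$eigenvalues) <= 1e-9))
})

test_that("the MST matches exhaustive enumeration and handles structure", {
  # triangle with weights 1, 2, 3 keeps the 1 and 2 edges
  D <- matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  e <- mst(dist_matrix(D))
  expect_setequal(e$weight, c(1, 2))
  for (s in 1:6) {
    set.seed(860 + s)
    n <- sample(4:7, 1)
    M <- matrix(0, n, n)
    M[upper.tri(M)] <- stats::runif(n * (n - 1) / 2, 1, 10)
    M <- M + t(M)
    m <- dist_matrix(M, paste0("x", 1:n))
    expect_equal(sum(mst(m)$weight), exhaustive_mst_weight(M))
  }
  # chain-structured distances give a path graph
  x <- c(0, 1, 2.1, 3.3, 4.6)
  Dc <- as.matrix(stats::dist(x))
  rownames(Dc) <- colnames(Dc) <- paste0("c", 1:5)
  ec <- mst(dist_matrix(Dc))
  deg <- table(c(ec$from, ec$to))
  expect_equal(sort(as.integer(deg)), c(1L, 1L, 2L, 2L, 2L))
})

test_that("the PCoA+MST overlay is structurally complete", {
  g <- simulate_msat(n_pops = 3, tau = 800, n_loci = 15, n_ind = 4,
                     seed = 91)
  dm <- group_distance_matrix(allele_freqs(g), "deltamu2")
  o <- pcoa(dm)
  ov <- pcoa_mst_overlay(o, mst(dm))
  expect_setequal(ov$points$label, dm$labels)       # all points plotted
  expect_equal(nrow(ov$edges), length(dm$labels) - 1L)
  expect_match(ov$xlab, "%\\)")                      # axis carries variance
  f <- tmpfile(".csv")
  write_overlay(ov, f)
  rec <- utils::read.csv(f)
  expect_equal(sum(rec$record == "point"), 3L)
  expect_equal(sum(rec$record == "edge"), 2L)
})
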