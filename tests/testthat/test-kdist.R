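test_that("site-pattern counting classifies changes and deletes pairwise", {
  expect_equal(unclass(count_site_patterns("ACGT", "ACGT"))[c("n", "ts", "tv")],
               list(n = 4L, ts = 0L, tv = 0L))
  expect_equal(unclass(count_site_patterns("AAAA", "GAAC"))[c("n", "ts", "tv")],
               list(n = 4L, ts = 1L, tv = 1L))
  expect_equal(unclass(count_site_patterns("AN-T", "AAGT"))[c("n", "ts", "tv")],
               list(n = 2L, ts = 0L, tv = 0L))
  expect_error(count_site_patterns("NN", "AA"), "no-overlap")
})

test_that("K2P distance matches its closed form and the delta-method SE is
          calibrated", {
  expect_equal(k2p(list(P = 0, Q = 0, n = 100)),
               list(distance = 0, se = 0))
  r <- k2p(list(P = 0.1, Q = 0.05, n = 100))
  expect_equal(r$distance, -0.5 * log(0.75) - 0.25 * log(0.9))
  # domain boundary: 1 - 2P - Q = 0
  expect_true(is.na(k2p(list(P = 0.5, Q = 0, n = 100))$distance))
  # SE against a multinomial site-bootstrap oracle
  set.seed(1)
  cnt <- stats::rmultinom(5e4, 100, c(0.85, 0.1, 0.05))
  db <- -0.5 * log(1 - 2 * cnt[2, ] / 100 - cnt[3, ] / 100) -
    0.25 * log(1 - 2 * cnt[3, ] / 100)
  expect_equal(r$se, stats::sd(db, na.rm = TRUE), tolerance = 0.05)
})

test_that("K2P distances and variances agree with an independent
          implementation", {
  a <- simulate_sequences(ape::read.tree(text = "(a:2e6,b:2e6,c:5e6);"),
                         4000, 1.15, kappa = 2, seed = 42)
  ours <- k2p_matrix(a)
  dna <- ape::as.DNAbin(strsplit(tolower(a$seqs), ""))
  names(dna) <- a$labels
  ref <- ape::dist.dna(dna, model = "K80", variance = TRUE,
                       pairwise.deletion = TRUE)
  expect_equal(ours$d[lower.tri(ours$d)], as.numeric(ref),
               tolerance = 1e-12)
  expect_equal(ours$se[lower.tri(ours$se)]^2,
               as.numeric(attr(ref, "variance")), tolerance = 1e-12)
})

test_that("the K2P matrix is symmetric, dominates the p-distance, and flags
          saturated pairs", {
  for (rep in 1:3) {
    set.seed(30 + rep)
    tr <- ape::rtree(5)
    tr$edge.length <- tr$edge.length * 5e6
    a <- simulate_sequences(tr, 300, 1.15, seed = 30 + rep)
    m <- k2p_matrix(a)
    expect_equal(m$d, t(m$d))
    expect_equal(diag(m$d), stats::setNames(rep(0, 5), a$labels))
    mm <- do.call(rbind, strsplit(a$seqs, ""))
    for (i in 1:4) for (j in (i + 1):5) {
      if (is.na(m$d[i, j])) next
      p <- mean(mm[i, ] != mm[j, ])
      expect_gte(m$d[i, j] + 1e-12, p)
    }
  }
  # force saturation: high divergence, short sequences
  sat <- alignment(c(x = "ACACACACAC", y = "GTGTGTGTGT"))
  ms <- k2p_matrix(sat)
  expect_true(is.na(ms$d[1, 2]))
  expect_equal(nrow(ms$undefined_pairs), 1L)
})

test_that("the K2P estimator recovers a known divergence", {
  st <- k2p_recovery_study(n_rep = 40, true_d = 0.05, length = 10000,
                           seed = 101)
  expect_lt(abs(st$mean - st$true_d), 2 * st$se_mean)
  # se shrinks with n at fixed P, Q
  ses <- vapply(c(1e2, 1e4, 1e6),
                function(n) k2p(list(P = 0.1, Q = 0.05, n = n))$se, 0)
  expect_true(all(diff(ses) < 0))
  expect_equal(ses[2] / ses[1], 0.1, tolerance = 1e-9)
})

test_that("nearest-taxon ranking orders by distance with undefined last", {
  m <- table1_fixture()
  nt <- nearest_taxa(m, "Narino_cat",
                     exclude = c("F_catus", "H_yagouaroundi"))
  expect_equal(nt$label[1:2], c("CA_transAndean_tigrina", "L_geoffroyi"))
  expect_equal(nt$percent[1:2], c(5.6, 5.8))
  nt2 <- nearest_taxa(m, "L_guigna")
  expect_equal(nt2$label[1], "L_geoffroyi")
  expect_equal(nt2$percent[1], 2.0)
  expect_error(nearest_taxa(m, "nope"), "lookup error")
  # 2-taxon matrix gives a single-entry list; NA-distance pairs sort last
  d <- matrix(c(0, NA, NA, 0), 2, 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  m2 <- dist_matrix(d)
  expect_equal(nrow(nearest_taxa(m2, "a")), 1L)
})

test_that("threshold flagging classifies against species bands", {
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 0.10    # 10%
  d["a", "c"] <- d["c", "a"] <- 0.056   # 5.6%
  d["a", "d"] <- d["d", "a"] <- 0.028   # 2.8%
  d["b", "c"] <- d["c", "b"] <- 0.01
  d["b", "d"] <- d["d", "b"] <- 0.01
  d["c", "d"] <- d["d", "c"] <- 0.01
  m <- dist_matrix(d)
  tr <- threshold_report(m, "a", threshold_band(6, 11, "mitogenome"))
  fl <- stats::setNames(tr$flags$flag, tr$flags$label)
  expect_equal(fl[["b"]], "within")
  expect_equal(fl[["c"]], "below")
  # a degenerate band models a single cut-off (2.5% Cyt-b rule)
  tr2 <- threshold_report(m, "a", threshold_band(2.5))
  fl2 <- stats::setNames(tr2$flags$flag, tr2$flags$label)
  expect_equal(fl2[["d"]], "above")
  expect_equal(sum(tr$counts), 3L)
})
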