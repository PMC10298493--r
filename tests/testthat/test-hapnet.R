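test_that("haplotype collapsing keeps variable columns and multiplicities", {
  a <- alignment(c(s1 = "ACGT", s2 = "ACGT", s3 = "ACGT", s4 = "ACGT"))
  h <- collapse_haplotypes(a)
  expect_equal(nrow(h$haplotypes), 1L)
  expect_equal(h$multiplicity, 4L)
  expect_length(h$column_map, 0L)

  b <- alignment(c(x = "ACGT", y = "ACGA", z = "ACGA"))
  hb <- collapse_haplotypes(b)
  expect_equal(nrow(hb$haplotypes), 2L)
  expect_equal(hb$column_map, 4L)
  expect_equal(hb$multiplicity, c(1L, 2L))
  expect_equal(sum(hb$multiplicity), n_seq(b))

  # a column whose variation is only missing data is not variable
  c3 <- alignment(c(x = "ANT", y = "A-T", z = "ANT"))
  expect_length(collapse_haplotypes(c3)$column_map, 0L)
})

test_that("median-joining networks add useful median vectors only", {
  # two haplotypes: a single link, no medians
  a <- alignment(c(x = "AAAA", y = "AAGG"))
  net <- build_mjn(collapse_haplotypes(a))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$weight, 2)
  expect_false(any(net$is_median))

  # the classic triplet 100/010/001 needs the 000 Steiner point
  b <- alignment(c(x = "GAA", y = "AGA", z = "AAG"))
  nb <- build_mjn(collapse_haplotypes(b))
  expect_equal(sum(nb$is_median), 1L)
  expect_equal(sort(nb$edges$weight), c(1, 1, 1))
  med <- nb$nodes[nb$is_median, ]
  expect_equal(unname(med), c("A", "A", "A"))

  # link column labels refer to original alignment coordinates
  expect_setequal(unlist(nb$edges$columns), 1:3)
})

test_that("median-joining cost matches brute-force Steiner minima on random
          small instances", {
  for (s in 1:12) {
    set.seed(700 + s)
    nh <- sample(3:5, 1); nc <- sample(3:4, 1)
    repeat {
      X <- matrix(sample(c("A", "G"), nh * nc, TRUE), nh, nc)
      if (!anyDuplicated(apply(X, 1, paste, collapse = ""))) break
    }
    a <- alignment(apply(X, 1, paste, collapse = ""), paste0("h", 1:nh))
    net <- build_mjn(collapse_haplotypes(a))
    w_net <- felidelim:::mst_weight(felidelim:::hap_dist_matrix(net$nodes))
    expect_equal(w_net, steiner_min_weight(X))
  }
})

test_that("on homoplasy-free data the network is the generating tree", {
  set.seed(7)
  tr <- ape::rtree(6)
  tr$edge.length <- tr$edge.length * 2e4
  a <- simulate_sequences(tr, 50000, 1.15, seed = 9)
  expect_equal(sum(duplicated(attr(a, "mutation_log")$site)), 0L)
  net <- build_mjn(collapse_haplotypes(a))
  expect_equal(nrow(net$edges), length(net$labels) - 1L)  # a tree
})

test_that("the epsilon-0 network always contains a minimum spanning tree", {
  for (s in 1:5) {
    a <- simulate_star(6, 3e5, 1000, 1.15, seed = 720 + s)
    net <- build_msn(collapse_haplotypes(a))
    D <- felidelim:::hap_dist_matrix(net$nodes)
    Dr <- matrix(Inf, nrow(D), ncol(D)); diag(Dr) <- 0
    for (k in seq_len(nrow(net$edges))) {
      i <- match(net$edges$from[k], net$labels)
      j <- match(net$edges$to[k], net$labels)
      Dr[i, j] <- Dr[j, i] <- D[i, j]
    }
    expect_equal(felidelim:::mst_weight(Dr), felidelim:::mst_weight(D))
  }
})

test_that("mutation-rate calendars convert rates to years per mutation", {
  expect_equal(years_per_mutation(315, 1.22), 260213)
  expect_equal(years_per_mutation(1, 1.0), 1e8)
  # computed from first principles; published round figures may differ
  expect_equal(years_per_mutation(16756, 1.15),
               round(1 / (16756 * 1.15e-8)))
  expect_error(years_per_mutation(0, 1), "domain")
  expect_error(years_per_mutation(315, 0), "domain")
  # an override carries a published calendar verbatim
  cal <- mutation_rate_spec(1.15, 16756, years_per_mutation = 5500)
  expect_equal(cal$years_per_mutation, 5500)
})

test_that("rho averages root-to-tip mutations and dates linearly", {
  # star: four tips at exactly two mutations from the ancestor
  a <- alignment(c(anc = "AAAAAAAA", t1 = "GGAAAAAA", t2 = "AAGGAAAA",
                   t3 = "AAAAGGAA", t4 = "AAAAAAGG"))
  net <- build_msn(collapse_haplotypes(a))
  r <- rho(net, "anc", tips = paste0("t", 1:4))
  expect_equal(r$rho, 2)
  # tips at 0,1,2,3 mutations: plain mean 1.5
  b <- alignment(c(anc = "AAA", u = "GAA", v = "GGA", w = "GGG"))
  nb <- build_msn(collapse_haplotypes(b))
  rb <- rho(nb, "anc", tips = c("anc", "u", "v", "w"))
  expect_equal(rb$rho, 1.5)
  # sigma on a star: sqrt(sum d_i m_i^2) / M
  expect_equal(r$sigma, sqrt(4 * 2) / 4)
  # dating is linear in the calendar
  cal1 <- mutation_rate_spec(1.22, 315)
  cal2 <- mutation_rate_spec(1.22, 315,
                             years_per_mutation = 2 * 260213)
  d1 <- date_split(r, cal1); d2 <- date_split(r, cal2)
  expect_equal(d2$time_my, 2 * d1$time_my)
  expect_equal(date_split(rho(net, "anc", tips = "anc"), cal1)$time_my, 0)
  # direct product: rho = 1 at the ND5 calendar is 0.26 My (2 dp)
  rb1 <- rho(nb, "anc", tips = "u")
  expect_equal(round(date_split(rb1, cal1)$time_my, 2), 0.26)
  expect_error(rho(net, "missing_node"), "lookup")
})

test_that("rho is invariant to relabeling and tip duplication", {
  a <- simulate_star(8, 2e5, 1500, 1.15, seed = 33)
  h <- collapse_haplotypes(a)
  net <- build_msn(h)
  anc <- h$labels[vapply(h$members, function(m) "root" %in% m, TRUE)]
  tips <- setdiff(net$labels[!net$is_median], anc)
  r1 <- rho(net, anc, tips)

  # relabel: permute sequence order
  set.seed(1)
  perm <- sample(n_seq(a))
  b <- alignment(a$seqs[perm], a$labels[perm])
  hb <- collapse_haplotypes(b)
  nb <- build_msn(hb)
  ancb <- hb$labels[vapply(hb$members, function(m) "root" %in% m, TRUE)]
  r2 <- rho(nb, ancb, setdiff(nb$labels[!nb$is_median], ancb))
  expect_equal(r2$rho, r1$rho)
  expect_equal(r2$sigma, r1$sigma)

  # duplicate every tip: multiplicities double, rho unchanged
  dup <- alignment(c(a$seqs, a$seqs[a$labels != "root"]),
                   c(a$labels, paste0("d_", a$labels[a$labels != "root"])))
  hd <- collapse_haplotypes(dup)
  nd <- build_msn(hd)
  ancd <- hd$labels[vapply(hd$members, function(m) "root" %in% m, TRUE)]
  r3 <- rho(nd, ancd, setdiff(nd$labels[!nd$is_median], ancd))
  expect_equal(r3$rho, r1$rho)
})

test_that("median vectors do not change root-to-tip shortest paths", {
  # at modest divergence the full MJN and the MSN agree on every
  # root-to-tip distance, so rho can be computed on either
  a <- simulate_star(10, 1.2e6, 2000, 1.15, seed = 55)
  h <- collapse_haplotypes(a)
  anc <- h$labels[vapply(h$members, function(m) "root" %in% m, TRUE)]
  tips <- setdiff(h$labels, anc)
  r_msn <- rho(build_msn(h), anc, tips)
  r_mjn <- rho(build_mjn(h), anc, tips)
  expect_equal(r_mjn$rho, r_msn$rho)
})

test_that("network exports carry labels, multiplicities and median flags", {
  b <- alignment(c(x = "GAA", y = "AGA", z = "AAG", z2 = "AAG"))
  net <- build_mjn(collapse_haplotypes(b))
  g <- as_igraph(net)
  expect_setequal(igraph::V(g)$name, net$labels)
  expect_equal(sum(igraph::V(g)$is_median), sum(net$is_median))
  expect_equal(sum(igraph::V(g)$multiplicity), 4L)
  f <- tmpfile(".graphml")
  write_graphml(net, f)
  expect_true(file.size(f) > 0)
})

test_that("independent split estimates average onto the printed scale", {
  expect_equal(combine_split_estimates(c(1.09, 1.33)), 1.2)
})
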