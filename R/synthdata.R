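#' Simulate sequences on a tree under a two-class substitution process
#'
#' Evolves a uniform-random root sequence along a tree whose branch lengths
#' are in years. Substitution events arrive per site at
#' \code{rate/100/1e6} per year; each event is a transition
#' (\code{A<->G}, \code{C<->T}) with probability \code{kappa/(kappa+2)},
#' otherwise a uniformly chosen transversion. This is exactly the two-class
#' process the Kimura 2-parameter estimator inverts, which makes estimator
#' recovery a clean oracle; richer models are deliberately excluded.
#'
#' @param tree an \code{ape} \code{phylo} with branch lengths in years.
#' @param length sequence length in bp.
#' @param rate substitution rate, percent per My per position.
#' @param kappa transition/transversion rate ratio (\code{kappa = 2} gives
#'   equal total transition and transversion probabilities).
#' @param seed integer seed; the simulation is a pure function of its
#'   arguments.
#' @param include_root also return the root sequence, labelled
#'   \code{"root"}.
#' @return a \code{felid_alignment} of the tip sequences, with attributes
#'   \code{mutation_log} (data.frame \code{node}, \code{site}, \code{from},
#'   \code{to}, \code{class}) and \code{root_seq}.
#' @export
simulate_sequences <- function(tree, length, rate, kappa = 2,
                               seed = 20230615L, include_root = FALSE) {
  stopifnot(inherits(tree, "phylo"), length >= 1, rate > 0, kappa > 0)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  partner <- c(A = "G", G = "A", C = "T", T = "C")
  tvs <- list(A = c("C", "T"), G = c("C", "T"),
              C = c("A", "G"), T = c("A", "G"))
  r <- rate / 100 / 1e6
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- sample(bases, length, replace = TRUE)
  tr <- stats::reorder(tree)  # cladewise: parents before children
  logs <- vector("list", nrow(tr$edge))
  p_ts <- kappa / (kappa + 2)
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    s <- seqs[[par]]
    t_yr <- tr$edge.length[e]
    n_ev <- stats::rpois(1L, length * r * t_yr)
    if (n_ev > 0L) {
      sites <- sample.int(length, n_ev, replace = TRUE)
      is_ts <- stats::runif(n_ev) < p_ts
      froms <- character(n_ev); tos <- character(n_ev)
      for (k in seq_len(n_ev)) {
        from <- s[sites[k]]
        to <- if (is_ts[k]) partner[[from]] else sample(tvs[[from]], 1L)
        s[sites[k]] <- to
        froms[k] <- from; tos[k] <- to
      }
      logs[[e]] <- data.frame(node = child, site = sites, from = froms,
                              to = tos,
                              class = ifelse(is_ts, "ts", "tv"),
                              stringsAsFactors = FALSE)
    }
    seqs[[child]] <- s
  }
  log <- if (all(vapply(logs, is.null, TRUE))) NULL else
    do.call(rbind, logs)
  labels <- tree$tip.label
  out_seqs <- vapply(seqs[seq_len(ntip)], paste, "", collapse = "")
  if (include_root) {
    labels <- c(labels, "root")
    out_seqs <- c(out_seqs, paste(seqs[[root]], collapse = ""))
  }
  a <- alignment(out_seqs, labels)
  attr(a, "mutation_log") <- if (is.null(log))
    data.frame(node = integer(), site = integer(), from = character(),
               to = character(), class = character()) else log
  attr(a, "root_seq") <- paste(seqs[[root]], collapse = "")
  a
}

#' Simulate sequences on a star tree
#'
#' Convenience wrapper: \code{n_tips} pendant branches of equal duration
#' radiating from the ancestor, evolved as in
#' \code{\link{simulate_sequences}}. The ancestor is included as an extra
#' record labelled \code{"root"} so it can anchor rho dating.
#'
#' @param n_tips number of pendant lineages.
#' @param age_years branch duration in years.
#' @inheritParams simulate_sequences
#' @return a \code{felid_alignment} (tips + \code{"root"}).
#' @export
simulate_star <- function(n_tips, age_years, length, rate, kappa = 2,
                          seed = 20230615L) {
  stopifnot(n_tips >= 1, age_years >= 0)
  tree <- ape::stree(max(n_tips, 2L), type = "star")
  tree$edge.length <- rep(age_years, nrow(tree$edge))
  a <- simulate_sequences(tree, length, rate, kappa, seed,
                          include_root = TRUE)
  if (n_tips == 1L) {  # drop the padding tip used to build a valid tree
    keep <- c(1L, n_seq(a))
    a2 <- alignment(a$seqs[keep], a$labels[keep])
    attr(a2, "root_seq") <- attr(a, "root_seq")
    return(a2)
  }
  a
}

#' Simulate diploid microsatellite genotypes under stepwise mutation
#'
#' Wright-Fisher populations of \code{n_ind} diploids evolve under the
#' stepwise mutation model: each allele copies a uniformly chosen parental
#' allele of the previous generation and mutates with probability
#' \code{beta} per generation by +/-1 repeat unit (reflecting at size 1).
#' An ancestral population is first run for \code{burn_in} generations to
#' reach mutation-drift equilibrium, then each descendant population starts
#' from a copy of the ancestral pool and evolves independently for
#' \code{tau} generations. With shared within-population drift the expected
#' delta-mu-squared between two populations is \code{2 * beta * tau}.
#'
#' @param n_pops number of descendant populations.
#' @param tau generations since the split.
#' @param beta mutation probability per allele per generation.
#' @param n_loci number of independent loci.
#' @param n_ind diploid individuals per population (also the population
#'   size).
#' @param ancestral_size starting allele size in repeat units; keep
#'   \code{>= 30} so the reflecting boundary at 1 stays negligible.
#' @param seed integer seed.
#' @param burn_in ancestral generations before the split; default
#'   \code{10 * n_ind}.
#' @return a \code{msat_genotypes} with groups \code{pop1..popK}.
#' @export
simulate_msat <- function(n_pops = 2L, tau = 500L, beta = 5e-3,
                          n_loci = 500L, n_ind = 30L, ancestral_size = 40L,
                          seed = 20230615L, burn_in = 10L * n_ind) {
  stopifnot(n_pops >= 1, tau >= 0, beta >= 0, n_loci >= 1, n_ind >= 1,
            ancestral_size >= 1)
  set.seed(seed)
  n_al <- 2L * n_ind
  step_pop <- function(A, gens) {
    for (g in seq_len(gens)) {
      idx <- sample.int(n_al, n_al * n_loci, replace = TRUE)
      A <- matrix(A[idx + rep((seq_len(n_loci) - 1L) * n_al, each = n_al)],
                  n_al, n_loci)
      mut <- stats::runif(n_al * n_loci) < beta
      if (any(mut)) {
        stp <- ifelse(stats::runif(sum(mut)) < 0.5, -1L, 1L)
        A[mut] <- A[mut] + stp
        A[A < 1L] <- 2L - A[A < 1L]  # reflect at size 1
      }
    }
    A
  }
  anc <- matrix(ancestral_size, n_al, n_loci)
  anc <- step_pop(anc, burn_in)
  calls <- NULL
  for (p in seq_len(n_pops)) {
    A <- step_pop(anc, tau)
    loci <- paste0("L", seq_len(n_loci))
    ids <- sprintf("pop%d_i%02d", p, seq_len(n_ind))
    calls <- rbind(calls, data.frame(
      individual = rep(ids, times = n_loci),
      group = paste0("pop", p),
      locus = rep(loci, each = n_ind),
      allele1 = as.vector(A[seq(1L, n_al, by = 2L), ]),
      allele2 = as.vector(A[seq(2L, n_al, by = 2L), ]),
      stringsAsFactors = FALSE))
  }
  msat_genotypes(calls)
}

#' Packaged mitogenome K2P distance matrix
#'
#' The 14-taxon whole-mitogenome Kimura 2P matrix for the Leopardus taxa,
#' the Narino cat, the domestic cat and the jaguarundi, shipped as a
#' lower-triangle-percent fixture (distances below the diagonal, standard
#' errors above, both in percent) and parsed into substitutions/site.
#'
#' @return a \code{felid_dist} with 14 taxa and standard errors.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "mitogenome_k2p_table.csv",
                      package = "felidelim", mustWork = TRUE)
  read_distance_matrix(path, dialect = "lower-triangle-percent")
}
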