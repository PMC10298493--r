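#' K2P estimator recovery study
#'
#' Simulates sequence pairs at a known true divergence under the two-class
#' substitution process and re-estimates the distance, returning the
#' per-replicate estimates together with the recovery summary (mean
#' estimate, its standard error over replicates, and the mean delta-method
#' SE).
#'
#' @param n_rep replicates.
#' @param true_d true divergence between the two sequences,
#'   substitutions/site.
#' @param length sequence length in bp.
#' @param kappa transition/transversion rate ratio.
#' @param seed base seed; replicate \code{i} uses \code{seed + i}.
#' @return list with \code{estimates}, \code{mean}, \code{se_mean},
#'   \code{mean_model_se}, \code{true_d}.
#' @export
k2p_recovery_study <- function(n_rep = 100L, true_d = 0.05, length = 1e4,
                               kappa = 2, seed = 20230615L) {
  rate <- 1.15                       # %/My/position; arbitrary calendar
  age <- true_d / 2 / (rate / 100 / 1e6)  # per-branch years giving true_d
  tree <- ape::read.tree(text = sprintf("(a:%.0f,b:%.0f);", age, age))
  est <- se <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    a <- simulate_sequences(tree, length, rate, kappa, seed = seed + i)
    res <- k2p(count_site_patterns(a$seqs[1L], a$seqs[2L]))
    est[i] <- res$distance
    se[i] <- res$se
  }
  list(estimates = est, mean = mean(est),
       se_mean = stats::sd(est) / sqrt(n_rep),
       mean_model_se = mean(se), true_d = true_d)
}

#' Rho-dating recovery study on star genealogies
#'
#' Simulates star genealogies of known age, builds the minimum spanning
#' haplotype network with the simulated ancestor designated as the root,
#' and dates each replicate with rho under the calendar implied by the
#' simulation's own length and rate. Returns per-replicate dated ages plus
#' the summary used to judge bias: the mean dated age and the mean
#' rho-based time error ("sigma bar").
#'
#' @param n_rep replicates (each with its own seed offset).
#' @param n_tips sampled lineages per star.
#' @param length sequence length in bp.
#' @param rate substitution rate, percent per My per position.
#' @param age_years true age of the star radiation.
#' @param kappa transition/transversion ratio.
#' @param seed base seed.
#' @return list with \code{ages_my}, \code{mean_age_my},
#'   \code{mean_sigma_my} (mean per-replicate time error, My),
#'   \code{true_age_my}, \code{years_per_mutation}.
#' @export
rho_recovery_study <- function(n_rep = 200L, n_tips = 50L, length = 16000L,
                               rate = 1.15, age_years = 1.2e6, kappa = 2,
                               seed = 20230615L) {
  cal <- mutation_rate_spec(rate = rate, length = length)
  ages <- sig <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    a <- simulate_star(n_tips, age_years, length, rate, kappa,
                       seed = seed + i)
    h <- collapse_haplotypes(a)
    net <- build_msn(h)
    anc <- h$labels[vapply(h$members, function(mm) "root" %in% mm, TRUE)]
    tips <- setdiff(net$labels[!net$is_median], anc)
    r <- rho(net, anc, tips = tips, calendar = cal)
    ages[i] <- r$time / 1e6
    sig[i] <- r$time_error / 1e6
  }
  list(ages_my = ages, mean_age_my = mean(ages),
       mean_sigma_my = mean(sig), true_age_my = age_years / 1e6,
       years_per_mutation = cal$years_per_mutation)
}

#' Delta-mu-squared calibration study under stepwise mutation
#'
#' Simulates pairs of populations diverged for a grid of times tau under
#' the stepwise mutation model and regresses the observed
#' delta-mu-squared on tau. Under the model the slope estimates
#' \code{2 * beta}.
#'
#' @param taus grid of divergence times (generations).
#' @param beta per-generation mutation probability.
#' @param n_loci loci per simulation.
#' @param n_ind diploid individuals per population.
#' @param seed base seed.
#' @return list with \code{taus}, \code{dmu2} (observed distances),
#'   \code{slope}, \code{expected_slope} (\code{2 beta}), \code{ratio}.
#' @export
deltamu2_slope_study <- function(taus = c(200L, 400L, 600L, 800L),
                                 beta = 5e-3, n_loci = 500L, n_ind = 30L,
                                 seed = 20230615L) {
  d <- numeric(length(taus))
  for (k in seq_along(taus)) {
    g <- simulate_msat(n_pops = 2L, tau = taus[k], beta = beta,
                       n_loci = n_loci, n_ind = n_ind,
                       seed = seed + k)
    f <- allele_freqs(g)
    d[k] <- delta_mu2(f, "pop1", "pop2")
  }
  slope <- unname(stats::coef(stats::lm(d ~ taus))[2L])
  list(taus = taus, dmu2 = d, slope = slope, expected_slope = 2 * beta,
       ratio = slope / (2 * beta))
}

#' Planted-synapomorphy diagnosis study
#'
#' Generates random alignments with a known set of private fixed
#' differences planted on one focal sequence, runs
#' \code{\link{diagnostic_sites}}, and counts false positives and false
#' negatives against the planted truth.
#'
#' @param n_fixtures random constructions.
#' @param n_background background sequences per fixture.
#' @param n_sites alignment length in bp.
#' @param n_planted planted diagnostic sites per fixture.
#' @param seed base seed.
#' @return list with \code{false_positives}, \code{false_negatives}
#'   (totals over all fixtures), \code{n_fixtures}.
#' @export
diagnosis_planted_study <- function(n_fixtures = 100L, n_background = 6L,
                                    n_sites = 400L, n_planted = 7L,
                                    seed = 20230615L) {
  fp <- fn <- 0L
  for (i in seq_len(n_fixtures)) {
    set.seed(seed + i)
    fx <- plant_synapomorphies(n_background, n_sites, n_planted)
    dg <- diagnostic_sites(fx$alignment, focal = "focal",
                            reference = "focal")
    got <- dg$sites$position
    fp <- fp + length(setdiff(got, fx$planted))
    fn <- fn + length(setdiff(fx$planted, got))
  }
  list(false_positives = fp, false_negatives = fn,
       n_fixtures = n_fixtures)
}

# build one planted-synapomorphy fixture: background sequences share a
# random base at every column (with small shared variation that is never
# private to the focal), the focal copies a background sequence and gets
# unique states at `n_planted` random columns. Caller sets the RNG seed.
plant_synapomorphies <- function(n_background, n_sites, n_planted) {
  bases <- c("A", "C", "G", "T")
  cons <- sample(bases, n_sites, replace = TRUE)
  bg <- matrix(rep(cons, each = n_background), n_background, n_sites)
  # background-only variation at some columns (not diagnostic for focal)
  var_cols <- sample.int(n_sites, max(1L, n_sites %/% 20L))
  for (j in var_cols) {
    who <- sample.int(n_background, max(1L, n_background %/% 2L))
    bg[who, j] <- sample(setdiff(bases, cons[j]), 1L)
  }
  focal <- cons
  planted <- sort(sample(setdiff(seq_len(n_sites), var_cols), n_planted))
  for (j in planted) {
    present <- unique(bg[, j])
    focal[j] <- sample(setdiff(bases, present), 1L)
  }
  rownames(bg) <- paste0("bg", seq_len(n_background))
  seqs <- c(apply(bg, 1L, paste, collapse = ""),
            focal = paste(focal, collapse = ""))
  list(alignment = alignment(seqs, c(rownames(bg), "focal")),
       planted = planted)
}
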