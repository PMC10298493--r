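#' Count transition/transversion site patterns between two sequences
#'
#' Sites where either sequence carries a non-\code{ACGT} character are
#' excluded (pairwise deletion). Transitions are the purine-purine and
#' pyrimidine-pyrimidine changes \code{A<->G} and \code{C<->T}; every other
#' mismatch is a transversion.
#'
#' @param a,b nucleotide strings (or character vectors of single bases) of
#'   equal length.
#' @return a list of class \code{"site_counts"} with \code{n} (compared
#'   sites), \code{ts}, \code{tv}, and the proportions \code{P = ts/n},
#'   \code{Q = tv/n}.
#' @export
count_site_patterns <- function(a, b) {
  av <- if (length(a) == 1L) strsplit(toupper(a), "")[[1L]] else toupper(a)
  bv <- if (length(b) == 1L) strsplit(toupper(b), "")[[1L]] else toupper(b)
  if (length(av) != length(bv))
    stop("count_site_patterns(): sequences differ in length")
  ok <- is_base(av) & is_base(bv)
  n <- sum(ok)
  if (n == 0L) stop("no-overlap error: no site compared in both sequences",
                    call. = FALSE)
  x <- av[ok]; y <- bv[ok]
  diff <- x != y
  purine <- function(z) z %in% c("A", "G")
  ts <- sum(diff & (purine(x) == purine(y)))
  tv <- sum(diff) - ts
  structure(list(n = n, ts = ts, tv = tv, P = ts / n, Q = tv / n),
            class = "site_counts")
}

#' Kimura 2-parameter distance with delta-method standard error
#'
#' \code{d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)} with \code{P}, \code{Q}
#' the transition and transversion proportions. The variance follows the
#' delta method: with \code{c1 = 1/(1-2P-Q)} and
#' \code{c3 = (c1 + 1/(1-2Q))/2},
#' \code{var = (c1^2 P + c3^2 Q - (c1 P + c3 Q)^2)/n}.
#' When a log argument is non-positive the distance is saturated and both
#' values are returned as \code{NA}.
#'
#' @param counts a \code{site_counts} object from
#'   \code{\link{count_site_patterns}}.
#' @return list with \code{distance} and \code{se} in substitutions/site
#'   (\code{NA} when undefined).
#' @export
k2p <- function(counts) {
  P <- counts$P; Q <- counts$Q; n <- counts$n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    return(list(distance = NA_real_, se = NA_real_))
  d <- -0.5 * log(w1) - 0.25 * log(w2)
  c1 <- 1 / w1
  c3 <- 0.5 * (1 / w1 + 1 / w2)
  v <- (c1^2 * P + c3^2 * Q - (c1 * P + c3 * Q)^2) / n
  list(distance = d, se = sqrt(max(v, 0)))
}

#' All-pairs K2P distance matrix
#'
#' Applies \code{\link{count_site_patterns}} and \code{\link{k2p}} to every
#' sequence pair under pairwise deletion. Saturated pairs are recorded in
#' \code{undefined_pairs} rather than dropped: mitogenome-scale outgroup
#' divergences (~33\%) sit near the estimator's domain edge and must stay
#' visible.
#'
#' @param a a \code{felid_alignment} with at least 2 sequences.
#' @return a \code{felid_dist} with the \code{se} slot filled.
#' @export
k2p_matrix <- function(a) {
  stopifnot(n_seq(a) >= 2L)
  m <- aln_matrix(a)
  n <- nrow(m)
  d <- matrix(0, n, n)
  se <- matrix(0, n, n)
  undef <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    res <- tryCatch(k2p(count_site_patterns(m[i, ], m[j, ])),
                    error = function(e) list(distance = NA_real_,
                                             se = NA_real_))
    d[i, j] <- d[j, i] <- res$distance
    se[i, j] <- se[j, i] <- res$se
    if (is.na(res$distance))
      undef <- rbind(undef, c(a$labels[i], a$labels[j]))
  }
  dist_matrix(d, a$labels, se = se,
              undefined_pairs = if (is.null(undef))
                matrix(character(), ncol = 2L) else undef)
}

#' Rank taxa by distance from a focal taxon
#'
#' @param m a \code{felid_dist}.
#' @param focal focal taxon label.
#' @param exclude labels to leave out of the ranking (e.g. outgroups).
#' @return data.frame with columns \code{label}, \code{distance}
#'   (substitutions/site), \code{percent}, ascending by distance; undefined
#'   pairs last; ties broken by label order in \code{m$labels}.
#' @export
nearest_taxa <- function(m, focal, exclude = character()) {
  if (!focal %in% m$labels) stop("lookup error: unknown focal taxon '",
                                 focal, "'", call. = FALSE)
  others <- setdiff(m$labels, c(focal, exclude))
  dv <- m$d[focal, others]
  ord <- order(is.na(dv), dv, match(others, m$labels))
  data.frame(label = others[ord], distance = unname(dv[ord]),
             percent = unname(100 * dv[ord]), stringsAsFactors = FALSE)
}

#' Species-threshold band
#'
#' Divergence bands used to flag candidate species: e.g. mitogenome
#' distances above 6-11\% are typical between distinct felid species, and
#' 2.5\% at Cyt-b is a conventional mammal species cut-off (a degenerate
#' band with \code{lower == upper}).
#'
#' @param lower,upper band bounds in percent, \code{0 < lower <= upper}.
#' @param context free-text marker name.
#' @return a \code{threshold_band} object.
#' @export
threshold_band <- function(lower, upper = lower, context = "") {
  stopifnot(lower > 0, lower <= upper)
  structure(list(lower = lower, upper = upper, context = context),
            class = "threshold_band")
}

#' Flag focal-taxon distances against a species-threshold band
#'
#' Each comparison taxon's distance from the focal taxon (in percent) is
#' classified as \code{below}, \code{within} or \code{above} the band;
#' undefined distances are flagged \code{undefined}.
#'
#' @param m a \code{felid_dist}.
#' @param focal focal taxon label.
#' @param band a \code{\link{threshold_band}}.
#' @param exclude labels to leave out.
#' @return list of class \code{"threshold_report"} with a per-taxon
#'   data.frame \code{flags} and a named count vector \code{counts}.
#' @export
threshold_report <- function(m, focal, band, exclude = character()) {
  stopifnot(inherits(band, "threshold_band"))
  nt <- nearest_taxa(m, focal, exclude)
  pct <- nt$percent
  flag <- ifelse(is.na(pct), "undefined",
          ifelse(pct < band$lower, "below",
          ifelse(pct > band$upper, "above", "within")))
  nt$flag <- flag
  counts <- vapply(c("below", "within", "above", "undefined"),
                   function(f) sum(flag == f), 0L)
  structure(list(focal = focal, band = band, flags = nt, counts = counts),
            class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat("Threshold report for", x$focal, sprintf("(band %s-%s%% %s)\n",
      x$band$lower, x$band$upper, x$band$context))
  print(x$counts)
  invisible(x)
}
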