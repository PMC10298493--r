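#' Construct a labelled distance matrix
#'
#' Distances are stored internally in substitutions/site (dimensionless);
#' report helpers render them as percent with one decimal. Pairs where an
#' estimator diverged (saturated distances) are carried explicitly in
#' \code{undefined_pairs} and hold \code{NA} in \code{d}.
#'
#' @param d square numeric matrix, symmetric, zero diagonal.
#' @param labels taxon names; default \code{rownames(d)}.
#' @param se optional matching matrix of standard errors.
#' @param undefined_pairs optional 2-column character matrix of label pairs
#'   whose distance is undefined.
#' @return an object of class \code{"felid_dist"}.
#' @export
dist_matrix <- function(d, labels = rownames(d), se = NULL,
                        undefined_pairs = NULL) {
  d <- as.matrix(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  labels <- as.character(labels)
  stopifnot(nrow(d) == ncol(d), length(labels) == nrow(d))
  if (anyDuplicated(labels)) stop("duplicate taxon labels")
  diag(d) <- 0
  asym <- max(abs(d - t(d)), na.rm = TRUE)
  if (asym > 1e-9)
    stop("format error: matrix asymmetric beyond tolerance (", asym, ")",
         call. = FALSE)
  d <- (d + t(d)) / 2
  if (any(d < 0, na.rm = TRUE)) stop("negative distances")
  dimnames(d) <- list(labels, labels)
  if (!is.null(se)) {
    se <- as.matrix(se)
    stopifnot(all(dim(se) == dim(d)))
    if (any(se < 0, na.rm = TRUE)) stop("negative standard errors")
    dimnames(se) <- dimnames(d)
  }
  if (is.null(undefined_pairs))
    undefined_pairs <- matrix(character(), ncol = 2L)
  structure(list(labels = labels, d = d, se = se,
                 undefined_pairs = undefined_pairs),
            class = "felid_dist")
}

#' @export
print.felid_dist <- function(x, ...) {
  cat("Distance matrix:", length(x$labels), "taxa",
      if (!is.null(x$se)) "(with SE)" else "", "\n")
  if (nrow(x$undefined_pairs))
    cat("  undefined pairs:", nrow(x$undefined_pairs), "\n")
  invisible(x)
}

#' Look up one pairwise distance
#' @param m a \code{felid_dist}.
#' @param a,b taxon labels.
#' @param percent return percent instead of substitutions/site.
#' @return numeric distance (NA if undefined).
#' @export
dist_between <- function(m, a, b, percent = FALSE) {
  stopifnot(a %in% m$labels, b %in% m$labels)
  v <- m$d[a, b]
  if (percent) 100 * v else v
}

#' Read a distance matrix file
#'
#' Two dialects are supported. \code{"square-csv"}: labelled square matrix of
#' distances already in substitutions/site; asymmetry beyond 1e-9 is a format
#' error. \code{"lower-triangle-percent"}: the layout used in mitogenome
#' distance tables - distances as percentages below the main diagonal and,
#' when numeric, standard errors as percentages above it; both are divided by
#' 100 on input. The first row and first column carry labels; the diagonal
#' may hold \code{-}, blanks or zeros.
#'
#' @param path CSV file (comma separated, \code{.} decimal, UTF-8).
#' @param dialect \code{"square-csv"} or \code{"lower-triangle-percent"}.
#' @return a \code{felid_dist}.
#' @export
read_distance_matrix <- function(path,
                                 dialect = c("square-csv",
                                             "lower-triangle-percent")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(raw[[1L]])
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  if (!identical(colnames(cells), labels))
    stop("format error: row labels do not match column labels", call. = FALSE)
  n <- length(labels)
  num <- matrix(suppressWarnings(as.numeric(cells)), n, n)
  if (dialect == "square-csv") {
    dg <- diag(num)
    dg[is.na(dg)] <- 0
    diag(num) <- dg
    if (anyNA(num)) stop("format error: non-numeric cell in square matrix")
    return(dist_matrix(num, labels))
  }
  d <- matrix(NA_real_, n, n)
  se <- matrix(NA_real_, n, n)
  low <- lower.tri(d)
  d[low] <- num[low] / 100
  se[upper.tri(se)] <- num[upper.tri(num)] / 100
  if (anyNA(d[low]))
    stop("format error: non-numeric distance below the diagonal")
  d[upper.tri(d)] <- t(d)[upper.tri(d)]
  se[lower.tri(se)] <- t(se)[lower.tri(se)]
  diag(d) <- 0
  diag(se) <- 0
  if (anyNA(se)) se_out <- NULL else se_out <- se
  dist_matrix(d, labels, se = se_out)
}

#' Write a distance matrix
#'
#' Inverse of \code{\link{read_distance_matrix}} for both dialects; values
#' are formatted at 6 significant digits so read-write round-trips are exact
#' at that precision.
#'
#' @param m a \code{felid_dist}.
#' @param path output CSV file.
#' @param dialect see \code{\link{read_distance_matrix}}.
#' @return \code{path}, invisibly.
#' @export
write_distance_matrix <- function(m, path,
                                  dialect = c("square-csv",
                                              "lower-triangle-percent")) {
  dialect <- match.arg(dialect)
  n <- length(m$labels)
  fmt <- function(x) ifelse(is.na(x), "", signif(x, 6L))
  if (dialect == "square-csv") {
    out <- matrix(fmt(m$d), n, n)
  } else {
    out <- matrix("-", n, n)
    out[lower.tri(out)] <- fmt(100 * m$d)[lower.tri(m$d)]
    up <- if (is.null(m$se)) matrix(NA_real_, n, n) else 100 * m$se
    out[upper.tri(out)] <- fmt(up)[upper.tri(up)]
  }
  df <- data.frame(taxon = m$labels, out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("taxon", m$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render a distance in percent, one decimal
#' @param x distance in substitutions/site.
#' @return character, e.g. \code{"5.6"}.
#' @export
format_percent <- function(x) formatC(100 * x, format = "f", digits = 1L)
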