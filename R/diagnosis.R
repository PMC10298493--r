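#' Map alignment columns to reference coordinates
#'
#' Columns where the reference sequence carries a base get successive
#' 1-based positions in the reference's own coordinate system; columns where
#' the reference is gapped (or ambiguous) map to \code{NA}.
#'
#' @param a a \code{felid_alignment}.
#' @param reference label of the reference sequence.
#' @return integer vector, one entry per alignment column.
#' @export
map_reference_coords <- function(a, reference) {
  if (!reference %in% a$labels)
    stop("lookup error: unknown reference '", reference, "'", call. = FALSE)
  ref <- aln_matrix(a)[reference, ]
  pos <- rep(NA_integer_, length(ref))
  hit <- is_base(ref)
  pos[hit] <- seq_len(sum(hit))
  pos
}

#' Read a gene interval table
#'
#' A BED-like plain-text table with columns \code{gene}, \code{start},
#' \code{end}: 1-based inclusive intervals in reference coordinates.
#'
#' @param path TSV or CSV file.
#' @return data.frame with \code{gene}, \code{start}, \code{end}.
#' @export
read_gene_intervals <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  g <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "start", "end") %in% names(g)),
            all(g$start >= 1), all(g$end >= g$start))
  g[, c("gene", "start", "end")]
}

#' Fixed diagnostic sites (synapomorphies) of a focal taxon
#'
#' A column is diagnostic when every focal sequence shares one determined
#' base there and no comparison (background) sequence carries that base.
#' Background missing data are ignored - a site can be diagnostic even if
#' some background sequences show \code{N} - but a single background match
#' of the focal state rejects the site. Positions are reported in the
#' coordinates of a designated reference sequence and, when gene intervals
#' are supplied, restricted and annotated to them.
#'
#' @param a a \code{felid_alignment}.
#' @param focal labels of the focal taxon's sequences.
#' @param background labels of the comparison sequences (disjoint from
#'   \code{focal}); defaults to all non-focal sequences.
#' @param reference label used for coordinates; defaults to the first focal
#'   sequence.
#' @param genes optional data.frame of gene intervals
#'   (\code{gene,start,end}, 1-based inclusive, reference coordinates).
#' @return object of class \code{"diagnostic_report"}: data.frame
#'   \code{sites} with \code{position} (reference bp), \code{column}
#'   (alignment column), \code{gene}, \code{focal_state},
#'   \code{background_states}; plus the input sets.
#' @export
diagnostic_sites <- function(a, focal, background = NULL,
                             reference = focal[1L], genes = NULL) {
  stopifnot(all(focal %in% a$labels))
  if (is.null(background)) background <- setdiff(a$labels, focal)
  stopifnot(all(background %in% a$labels), length(background) >= 1L)
  if (length(intersect(focal, background)))
    stop("argument error: focal and background sets overlap", call. = FALSE)
  m <- aln_matrix(a)
  fm <- m[focal, , drop = FALSE]
  bm <- m[background, , drop = FALSE]
  pos <- map_reference_coords(a, reference)
  hits <- NULL
  for (j in seq_len(ncol(m))) {
    fs <- unique(fm[, j])
    if (length(fs) != 1L || !is_base(fs)) next  # focal must be fixed, no N
    bs <- bm[, j][is_base(bm[, j])]
    if (fs %in% bs) next
    if (is.na(pos[j])) next  # unreported: reference is gapped here
    hits <- rbind(hits, data.frame(
      position = pos[j], column = j, gene = NA_character_,
      focal_state = fs,
      background_states = paste(sort(unique(bs)), collapse = ","),
      stringsAsFactors = FALSE))
  }
  if (is.null(hits))
    hits <- data.frame(position = integer(), column = integer(),
                       gene = character(), focal_state = character(),
                       background_states = character(),
                       stringsAsFactors = FALSE)
  if (!is.null(genes) && nrow(hits)) {
    idx <- rep(NA_integer_, nrow(hits))
    for (k in seq_len(nrow(genes)))
      idx[hits$position >= genes$start[k] &
            hits$position <= genes$end[k]] <- k
    hits$gene <- genes$gene[idx]
    hits <- hits[!is.na(hits$gene), , drop = FALSE]
    rownames(hits) <- NULL
  }
  structure(list(sites = hits, focal = focal, background = background,
                 reference = reference),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat("Diagnostic sites for {", paste(x$focal, collapse = ", "), "}: ",
      nrow(x$sites), " site(s)\n", sep = "")
  if (nrow(x$sites)) print(x$sites, row.names = FALSE)
  invisible(x)
}

#' Write a diagnostic report as TSV
#' @param rep a \code{diagnostic_report}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_diagnostic_report <- function(rep, path) {
  utils::write.table(rep$sites, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
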