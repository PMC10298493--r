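#' Construct a nucleotide alignment
#'
#' An alignment is the substrate for distance estimation, haplotype networks
#' and diagnostic-site scans: a set of equal-length nucleotide sequences with
#' unique labels. Characters outside \code{A,C,G,T} (gaps, \code{N}, IUPAC
#' ambiguity codes) are kept verbatim but treated as missing by every
#' downstream counting operation (pairwise deletion).
#'
#' @param seqs character vector of nucleotide strings, all the same length.
#' @param labels character vector of unique sequence identifiers; defaults to
#'   \code{names(seqs)}.
#' @return An object of class \code{"felid_alignment"}: a list with elements
#'   \code{labels}, \code{seqs} (uppercase strings) and \code{length} (bp).
#' @export
alignment <- function(seqs, labels = names(seqs)) {
  if (is.null(labels)) stop("alignment(): sequence labels are required")
  labels <- as.character(labels)
  seqs <- toupper(as.character(seqs))
  if (length(seqs) != length(labels))
    stop("alignment(): labels and seqs differ in length")
  if (anyDuplicated(labels))
    stop("duplicate sequence label: ", labels[duplicated(labels)][1L],
         call. = FALSE)
  lens <- nchar(seqs)
  if (length(seqs) == 0L || lens[1L] < 1L)
    stop("alignment(): need at least one non-empty sequence")
  if (any(lens != lens[1L])) {
    bad <- labels[which(lens != lens[1L])[1L]]
    stop("alignment error: sequence '", bad, "' has length ",
         lens[lens != lens[1L]][1L], ", expected ", lens[1L], call. = FALSE)
  }
  structure(list(labels = labels, seqs = unname(seqs), length = lens[1L]),
            class = "felid_alignment")
}

#' @export
print.felid_alignment <- function(x, ...) {
  cat("Alignment:", length(x$labels), "sequences x", x$length, "bp\n")
  invisible(x)
}

#' Number of sequences in an alignment
#' @param a a \code{felid_alignment}.
#' @return integer count.
#' @export
n_seq <- function(a) length(a$labels)

# character matrix view (rows = sequences, named by label)
aln_matrix <- function(a) {
  m <- do.call(rbind, strsplit(a$seqs, "", fixed = TRUE))
  rownames(m) <- a$labels
  m
}

matrix_aln <- function(m) {
  alignment(apply(m, 1L, paste, collapse = ""), labels = rownames(m))
}

# TRUE where a character is a determined base
is_base <- function(x) x %in% c("A", "C", "G", "T")

#' Read a multi-FASTA alignment
#'
#' Parses via \code{ape::read.FASTA}, normalises case to upper, and enforces
#' the alignment invariants (equal lengths, unique labels).
#'
#' @param path path to a FASTA file.
#' @return a \code{felid_alignment}.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("empty FASTA: ", path)
  seqs <- vapply(as.character(dna), paste, "", collapse = "")
  alignment(toupper(seqs), labels = names(dna))
}

#' Write an alignment as FASTA
#' @param a a \code{felid_alignment}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(a, path) {
  dna <- ape::as.DNAbin(strsplit(tolower(a$seqs), "", fixed = TRUE))
  names(dna) <- a$labels
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Write a tree in Newick format
#'
#' Thin wrapper over \code{ape::write.tree} (branch lengths at default
#' precision, integer node support carried in \code{node.label}); reading
#' the file back reproduces topology, lengths and support.
#'
#' @param t an \code{ape} \code{phylo}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_newick <- function(t, path) {
  stopifnot(inherits(t, "phylo"))
  ape::write.tree(t, file = path)
  invisible(path)
}

#' Drop gappy alignment columns
#'
#' Retains exactly the columns whose fraction of missing characters (gap,
#' \code{N}, ambiguity) is at most \code{max_gap_fraction}; column order is
#' preserved. This simple per-column filter stands in for block-selection
#' heuristics applied to concatenated mitochondrial alignments.
#'
#' @param a a \code{felid_alignment}.
#' @param max_gap_fraction maximum tolerated missing fraction in \[0, 1\].
#' @return filtered \code{felid_alignment} (may have zero columns retained
#'   only if all columns fail, in which case an error is raised).
#' @export
filter_columns <- function(a, max_gap_fraction) {
  stopifnot(max_gap_fraction >= 0, max_gap_fraction <= 1)
  m <- aln_matrix(a)
  frac <- colMeans(!apply(m, 2L, is_base))
  keep <- frac <= max_gap_fraction
  if (!any(keep)) stop("filter_columns(): no columns retained")
  out <- matrix_aln(m[, keep, drop = FALSE])
  attr(out, "kept_columns") <- which(keep)
  out
}
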