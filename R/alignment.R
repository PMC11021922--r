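#' Aligned haploid sequences
#'
#' A `seq_alignment` holds equal-length aligned haploid sequences (one row per
#' sample) over the alphabet `A, C, G, T, N, -`. IUPAC ambiguity codes are
#' accepted on input and converted to `N`; `N` and `-` are treated as missing
#' throughout. This is the unit of all mitochondrial control-region
#' computation (here a 723-bp alignment in the motivating study design).
#'
#' @param sequences character vector of equal-length sequences, or a character
#'   matrix with one row per sample and one column per site.
#' @param sample_ids unique sample identifiers; defaults to names of
#'   `sequences` or `seq_1 ... seq_n`.
#' @return an object of class `seq_alignment`: a list with elements
#'   `ids` (character), `seqs` (n x L character matrix, uppercase) and
#'   `L` (number of sites).
#' @export
#' @examples
#' aln <- seq_alignment(c(a = "ACGT", b = "ACGA"))
#' n_samples(aln)
seq_alignment <- function(sequences, sample_ids = NULL) {
  if (is.matrix(sequences)) {
    m <- toupper(sequences)
    if (is.null(sample_ids)) sample_ids <- rownames(sequences)
  } else {
    if (is.null(sample_ids)) sample_ids <- names(sequences)
    sequences <- as.character(sequences)
    if (length(sequences) == 0L) stop("empty alignment")
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L)
      stop("sequences differ in length (", paste(unique(lens), collapse = ", "), ")")
    m <- do.call(rbind, strsplit(toupper(sequences), ""))
  }
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty alignment")
  if (is.null(sample_ids)) sample_ids <- paste0("seq_", seq_len(nrow(m)))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (length(sample_ids) != nrow(m)) stop("sample_ids length must match number of sequences")
  # IUPAC ambiguity and anything unexpected becomes missing
  m[!(m %in% c("A", "C", "G", "T", "-"))] <- "N"
  rownames(m) <- sample_ids
  structure(list(ids = sample_ids, seqs = m, L = ncol(m)),
            class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat("seq_alignment:", nrow(x$seqs), "sequences x", x$L, "sites\n")
  miss <- mean(x$seqs %in% c("N", "-"))
  cat(sprintf("  missing/masked cells: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
#' @rdname seq_alignment
n_samples <- function(alignment) nrow(alignment$seqs)

#' Sites usable across the whole alignment
#'
#' Returns the logical index of sites at which no sequence carries a missing
#' state (`N` or `-`). Global statistics (segregating sites, nucleotide
#' diversity, haplotype collapsing) are computed on these sites only
#' (complete deletion); pairwise distances instead drop sites per pair.
#'
#' @param alignment a [seq_alignment()].
#' @return logical vector of length L.
#' @export
unmasked_sites <- function(alignment) {
  colSums(alignment$seqs == "N" | alignment$seqs == "-") == 0L
}

# trusted constructor for simulator output: uppercase ACGT matrix, valid ids
.seq_alignment_fast <- function(m, sample_ids) {
  rownames(m) <- sample_ids
  structure(list(ids = sample_ids, seqs = m, L = ncol(m)),
            class = "seq_alignment")
}

# integer encoding A=1 C=2 G=3 T=4, NA for missing; used by the fast paths
.aln_int <- function(alignment) {
  m <- match(alignment$seqs, c("A", "C", "G", "T"))
  dim(m) <- dim(alignment$seqs)
  rownames(m) <- alignment$ids
  m
}

#' Read an aligned FASTA file
#'
#' Thin wrapper around [ape::read.FASTA()]; sequences must be pre-aligned
#' (equal length). IUPAC ambiguity codes are read but treated as missing.
#'
#' @param path FASTA file.
#' @return a [seq_alignment()].
#' @export
read_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  ch <- toupper(vapply(as.character(dna), paste, "", collapse = ""))
  seq_alignment(ch, sample_ids = names(dna))
}

#' Write an alignment as wrapped FASTA
#'
#' @param alignment a [seq_alignment()].
#' @param path output file.
#' @param width line-wrap column (default 80).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path, width = 80L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(alignment$seqs))) {
    s <- paste(alignment$seqs[i, ], collapse = "")
    chunks <- substring(s, seq(1L, nchar(s), width),
                        pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s)))
    writeLines(c(paste0(">", alignment$ids[i]), chunks), con)
  }
  invisible(path)
}

#' Subset an alignment by sample
#'
#' @param alignment a [seq_alignment()].
#' @param which sample ids or indices to keep, in the order given.
#' @return a [seq_alignment()].
#' @export
subset_alignment <- function(alignment, which) {
  if (is.character(which)) which <- match(which, alignment$ids)
  if (anyNA(which)) stop("unknown sample ids")
  seq_alignment(alignment$seqs[which, , drop = FALSE],
                sample_ids = alignment$ids[which])
}
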