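#' Multiple sequence alignment container
#'
#' A light container for a gapped amino-acid alignment: a character matrix
#' with one row per species and one column per alignment position.  Row
#' names are the species labels and must be unique; all rows have equal
#' length by construction.
#'
#' @param x either a named character vector of aligned sequence strings
#'   (equal lengths) or a character matrix of single residues with row names.
#' @param id optional alignment identifier.
#' @return An object of class `msa`: a character matrix with attributes
#'   `id`.
#' @export
msa <- function(x, id = NULL) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x)) || anyDuplicated(names(x))) {
      stop("sequences must carry unique species names")
    }
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) stop("aligned sequences must have equal length")
    m <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
    rownames(m) <- names(x)
  } else if (is.matrix(x) && is.character(x)) {
    if (is.null(rownames(x)) || anyDuplicated(rownames(x))) {
      stop("alignment matrix must carry unique species row names")
    }
    m <- x
    m[] <- toupper(m)
  } else {
    stop("x must be a named character vector or character matrix")
  }
  if (ncol(m) < 1L) stop("alignment must have at least one column")
  structure(m, id = id, class = c("msa", "matrix", "array"))
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa %s: %d sequences x %d columns>\n",
              if (is.null(attr(x, "id"))) "" else attr(x, "id"),
              nrow(x), ncol(x)))
  invisible(x)
}

#' @rdname msa
#' @param aln an `msa` object.
#' @export
msa_species <- function(aln) rownames(aln)

#' @rdname msa
#' @export
msa_id <- function(aln) attr(aln, "id")

#' Restrict an alignment to a set of species, preserving the given order
#'
#' @param aln an [msa()] object.
#' @param species character vector, subset of `msa_species(aln)`.
#' @export
msa_subset <- function(aln, species) {
  missing <- setdiff(species, rownames(aln))
  if (length(missing)) {
    stop("species not present in alignment: ", paste(missing, collapse = ", "))
  }
  msa(unclass(aln)[species, , drop = FALSE], id = attr(aln, "id"))
}

# Encode residues as integer state indices in AA_STATES order; gaps and
# ambiguity codes become NA (treated as missing data downstream).
msa_encode <- function(aln) {
  enc <- match(unclass(aln), AA_STATES)
  dim(enc) <- dim(aln)
  rownames(enc) <- rownames(aln)
  enc
}

#' Remove alignment columns exceeding a gap-fraction threshold
#'
#' Keeps the columns whose fraction of gap characters (`-` or `.`) is at
#' most `max_gap_fraction`; column order is preserved and the row set is
#' unchanged.  With the default threshold of 0.20 this reproduces the
#' "maximum of 20% gaps per column" filtering used to strip poorly aligned
#' variable regions before tree inference.
#'
#' @param aln an [msa()] object.
#' @param max_gap_fraction maximum allowed per-column gap fraction in
#'   \[0, 1\].
#' @return The filtered [msa()]; errors if no column survives.
#' @export
filter_gap_columns <- function(aln, max_gap_fraction = 0.20) {
  stopifnot(inherits(aln, "msa"))
  if (!is.numeric(max_gap_fraction) || max_gap_fraction < 0 || max_gap_fraction > 1) {
    stop("max_gap_fraction must be in [0, 1]")
  }
  gap_frac <- colMeans(unclass(aln) == "-" | unclass(aln) == ".")
  keep <- gap_frac <= max_gap_fraction
  if (!any(keep)) stop("gap filter removed every alignment column")
  msa(unclass(aln)[, keep, drop = FALSE], id = attr(aln, "id"))
}

#' Read / write aligned FASTA
#'
#' Thin wrappers over \pkg{Biostrings} FASTA I/O returning/accepting the
#' package's [msa()] container.  Sequence identifiers are used as species
#' labels.
#'
#' @param path file path.
#' @param id optional alignment identifier (defaults to the file name).
#' @return `read_msa_fasta()` returns an [msa()].
#' @export
read_msa_fasta <- function(path, id = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required for FASTA I/O")
  }
  ss <- Biostrings::readAAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  msa(seqs, id = if (is.null(id)) basename(path) else id)
}

#' @rdname read_msa_fasta
#' @param aln an [msa()] object.
#' @export
write_msa_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "msa"))
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required for FASTA I/O")
  }
  seqs <- apply(unclass(aln), 1, paste, collapse = "")
  ss <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}
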