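#' Protein sequence
#'
#' A single protein sequence over the 22-letter alphabet (20 standard amino
#' acids, U for selenocysteine, X for unknown). Residues are case-normalized
#' to upper case and a terminal stop (`*`) is stripped.
#'
#' @param id accession-like identifier.
#' @param residues residue string.
#' @param description optional free-text description.
#' @return an object of class `protein_sequence` with fields `id`,
#'   `description` and `residues`.
#' @examples
#' protein_sequence("toy", "MKVLY")
#' @export
protein_sequence <- function(id, residues, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nchar(id) > 0L,
            is.character(residues), length(residues) == 1L)
  residues <- normalize_residues(residues, id)
  if (nchar(residues) < 1L)
    stop(sprintf("record '%s': empty sequence", id), call. = FALSE)
  structure(list(id = id, description = description, residues = residues),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s (%d aa)\n", x$id, nchar(x$residues)))
  invisible(x)
}

#' @export
length.protein_sequence <- function(x) nchar(x$residues)

seq_letters <- function(x) strsplit(x$residues, "", fixed = TRUE)[[1]]

#' Multiple sequence alignment
#'
#' Ordered rows of equal-length gapped residue strings. De-gapping a row
#' reproduces the underlying sequence. `.` gap characters are normalized
#' to `-`.
#'
#' @param ids character vector of row identifiers.
#' @param gapped character vector of gapped strings (same length as `ids`).
#' @return an object of class `alignment` with fields `ids`, `gapped`,
#'   `ncol`.
#' @export
alignment <- function(ids, gapped) {
  stopifnot(is.character(ids), is.character(gapped),
            length(ids) == length(gapped), length(ids) >= 1L)
  ids <- unname(ids)
  gapped <- unname(toupper(gsub(".", "-", gapped, fixed = TRUE)))
  widths <- nchar(gapped)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment: rows have unequal lengths", call. = FALSE)
  for (i in seq_along(gapped)) {
    degapped <- gsub("-", "", gapped[i], fixed = TRUE)
    if (nchar(degapped) > 0L) {
      norm <- normalize_residues(degapped, ids[i])
      ## re-insert the normalized letters under the original gap pattern
      if (!identical(norm, degapped)) {
        chars <- strsplit(gapped[i], "", fixed = TRUE)[[1]]
        chars[chars != "-"] <- strsplit(norm, "", fixed = TRUE)[[1]]
        gapped[i] <- paste(chars, collapse = "")
      }
    }
  }
  structure(list(ids = ids, gapped = gapped, ncol = widths[1]),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d rows x %d columns\n", length(x$ids), x$ncol))
  invisible(x)
}

#' Extract one de-gapped row of an alignment as a protein_sequence
#' @param aln an `alignment`.
#' @param id row identifier.
#' @return a `protein_sequence`.
#' @export
alignment_row <- function(aln, id) {
  i <- match(id, aln$ids)
  if (is.na(i)) stop(sprintf("no row '%s' in alignment", id), call. = FALSE)
  protein_sequence(id, gsub("-", "", aln$gapped[i], fixed = TRUE))
}

alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$gapped, "", fixed = TRUE))
}

#' C-alpha structure
#'
#' An ordered set of residue-numbered C-alpha coordinates (Angstrom).
#' Residue numbers must be strictly increasing and coordinates finite.
#'
#' @param id structure identifier.
#' @param chain chain identifier.
#' @param resno integer vector of 1-based residue numbers.
#' @param resletter character vector of 1-letter residue codes.
#' @param xyz numeric matrix with one row per residue and columns x, y, z.
#' @return an object of class `calpha_structure`.
#' @export
calpha_structure <- function(id, chain, resno, resletter, xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(length(resno) == length(resletter), nrow(xyz) == length(resno),
            ncol(xyz) == 3L)
  if (length(resno) < 1L)
    stop(sprintf("structure '%s': no CA atoms", id), call. = FALSE)
  resno <- as.integer(resno)
  if (any(diff(resno) <= 0L))
    stop(sprintf("structure '%s': residue numbers not strictly increasing", id),
         call. = FALSE)
  if (!all(is.finite(xyz)))
    stop(sprintf("structure '%s': non-finite coordinates", id), call. = FALSE)
  resletter <- toupper(resletter)
  bad <- !(resletter %in% AA_ALPHABET)
  resletter[bad] <- "X"
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(id = id, chain = chain, resno = resno,
                 resletter = resletter, xyz = xyz),
            class = "calpha_structure")
}

#' @export
print.calpha_structure <- function(x, ...) {
  cat(sprintf("<calpha_structure> %s chain %s: %d residues\n",
              x$id, x$chain, length(x$resno)))
  invisible(x)
}

#' @export
length.calpha_structure <- function(x) length(x$resno)

#' Domain architecture
#'
#' Ordered list of (domain id, start, end) intervals in 1-based inclusive
#' residue coordinates.
#'
#' @param domain_id character vector of domain identifiers.
#' @param start,end integer vectors of interval bounds.
#' @return an object of class `domain_architecture`.
#' @export
domain_architecture <- function(domain_id, start, end) {
  stopifnot(length(domain_id) == length(start), length(start) == length(end))
  start <- as.integer(start); end <- as.integer(end)
  if (length(domain_id)) {
    if (any(start > end)) stop("domain interval with start > end", call. = FALSE)
    if (any(start < 1L)) stop("domain interval before position 1", call. = FALSE)
    if (is.unsorted(start)) stop("domain intervals must be ordered by start",
                                 call. = FALSE)
  }
  structure(list(domain_id = as.character(domain_id), start = start, end = end),
            class = "domain_architecture")
}

#' Functional residue set
#'
#' The annotated catalytic/functional positions of a reference sequence:
#' 1-based position, expected residue letter and a free-text role tag.
#' The expected letter must match the reference residue at that position.
#'
#' @param reference a `protein_sequence` the positions refer to.
#' @param position integer vector of 1-based positions.
#' @param residue character vector of expected 1-letter codes.
#' @param role character vector of role tags (recycled if scalar).
#' @return an object of class `functional_residue_set`.
#' @export
functional_residue_set <- function(reference, position, residue,
                                   role = "catalytic") {
  stopifnot(inherits(reference, "protein_sequence"),
            length(position) == length(residue))
  position <- as.integer(position)
  residue <- toupper(residue)
  role <- rep_len(as.character(role), length(position))
  L <- nchar(reference$residues)
  if (any(position < 1L | position > L))
    stop("functional residue position outside reference length", call. = FALSE)
  actual <- substring(reference$residues, position, position)
  if (any(actual != residue))
    stop(sprintf("expected residue mismatch at position %d: reference has %s, annotation says %s",
                 position[which(actual != residue)[1]],
                 actual[which(actual != residue)[1]],
                 residue[which(actual != residue)[1]]), call. = FALSE)
  structure(list(reference_id = reference$id, position = position,
                 residue = residue, role = role),
            class = "functional_residue_set")
}

#' @export
print.functional_residue_set <- function(x, ...) {
  cat(sprintf("<functional_residue_set> %s: %s\n", x$reference_id,
              paste0(x$residue, x$position, collapse = ", ")))
  invisible(x)
}
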