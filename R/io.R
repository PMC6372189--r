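#' Read protein sequences from a FASTA file
#'
#' Parses with [Biostrings::readBStringSet()] and normalizes each record to
#' the package alphabet (upper case, terminal `*` stripped, B/Z/J mapped to
#' X with a warning). Illegal characters raise an error naming the record
#' and offset.
#'
#' @param path path to a FASTA file (plain or `.gz`).
#' @return a list of [protein_sequence] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop(sprintf("FASTA format error in %s: %s",
                                 path, conditionMessage(e)), call. = FALSE))
  if (length(set) == 0L)
    stop(sprintf("FASTA format error in %s: no records", path), call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- protein_sequence(ids[i], as.character(set[[i]]), desc[i])
  }
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs a list of [protein_sequence] objects.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (inherits(seqs, "protein_sequence")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    header <- if (nzchar(s$description)) paste(s$id, s$description) else s$id
    writeLines(paste0(">", header), con)
    n <- nchar(s$residues)
    starts <- seq(1L, n, by = width)
    writeLines(substring(s$residues, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read a multiple sequence alignment
#'
#' Supports aligned-FASTA and Stockholm. `.` gaps are normalized to `-`;
#' ragged rows raise a format error.
#'
#' @param path path to the alignment file.
#' @param dialect `"aligned-fasta"` or `"stockholm"`.
#' @return an [alignment].
#' @export
read_msa <- function(path, dialect = c("aligned-fasta", "stockholm")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (dialect == "aligned-fasta") {
    set <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e)
                      stop(sprintf("MSA format error in %s: %s",
                                   path, conditionMessage(e)), call. = FALSE))
    if (length(set) == 0L)
      stop(sprintf("MSA format error in %s: no records", path), call. = FALSE)
    ids <- sub("\\s.*$", "", names(set))
    alignment(ids, as.character(set))
  } else {
    msa <- tryCatch(
      Biostrings::readAAMultipleAlignment(path, format = "stockholm"),
      error = function(e)
        stop(sprintf("Stockholm format error in %s: %s",
                     path, conditionMessage(e)), call. = FALSE))
    rows <- as.character(msa)
    alignment(names(rows), unname(rows))
  }
}

#' Write an alignment as aligned-FASTA
#'
#' @param aln an [alignment].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$ids)) {
    writeLines(c(paste0(">", aln$ids[i]), aln$gapped[i]), con)
  }
  invisible(path)
}

#' Read a C-alpha structure from PDB ATOM records
#'
#' Parses with [bio3d::read.pdb()] and keeps only `ATOM` records with atom
#' name `CA`, from the first MODEL, with blank or `'A'` altloc, for the
#' requested chain (default: the first chain encountered). 3-letter residue
#' codes are mapped to 1-letter (`MSE -> M`, `SEC -> U`, unknown -> `X`).
#' Insertion-coded duplicates of a residue number keep the first occurrence.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier, or `NULL` for the first chain.
#' @param id structure identifier (defaults to the file name).
#' @return a [calpha_structure].
#' @export
read_calpha_pdb <- function(path, chain = NULL, id = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (is.null(id)) id <- sub("\\.pdb$", "", basename(path))
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, multi = FALSE)),
                  error = function(e)
                    stop(sprintf("PDB parse error in %s: %s",
                                 path, conditionMessage(e)), call. = FALSE))
  at <- pdb$atom
  keep <- at$type == "ATOM" & at$elety == "CA" &
    (is.na(at$alt) | at$alt %in% c("", "A"))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L)
    stop(sprintf("structure '%s': no CA atoms", id), call. = FALSE)
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L)
    stop(sprintf("structure '%s': no CA atoms for chain %s", id, chain),
         call. = FALSE)
  at <- at[!duplicated(at$resno), , drop = FALSE]
  calpha_structure(id, chain, at$resno, three_to_one(at$resid),
                   cbind(at$x, at$y, at$z))
}

AA_ONE_TO_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL", U = "SEC", X = "UNK")

#' Write a C-alpha structure as PDB ATOM records
#'
#' @param s a [calpha_structure].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calpha_pdb <- function(s, path) {
  stopifnot(inherits(s, "calpha_structure"))
  con <- file(path, "w")
  on.exit(close(con))
  ch <- substr(ifelse(is.na(s$chain) | !nzchar(s$chain), "A", s$chain), 1, 1)
  for (i in seq_along(s$resno)) {
    writeLines(sprintf(
      "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      i, AA_ONE_TO_THREE[[s$resletter[i]]], ch, s$resno[i],
      s$xyz[i, 1], s$xyz[i, 2], s$xyz[i, 3]), con)
  }
  writeLines(c("TER", "END"), con)
  invisible(path)
}

#' Write a candidate report table as TSV
#'
#' Tab-delimited, `.` decimal separator, UTF-8. Character fields containing
#' a tab or newline are rejected.
#'
#' @param records a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(records, path) {
  stopifnot(is.data.frame(records))
  for (cn in names(records)) {
    v <- records[[cn]]
    if (is.character(v) && any(grepl("[\t\n]", v)))
      stop(sprintf("field '%s' contains a tab or newline", cn), call. = FALSE)
  }
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV report written by [write_report_tsv()]
#'
#' @param path input path.
#' @return a data.frame.
#' @export
read_report_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Read a functional-residue annotation table
#'
#' TSV with columns `position`, `residue`, `role`.
#'
#' @param path input path.
#' @param reference the [protein_sequence] the positions refer to.
#' @return a [functional_residue_set].
#' @export
read_frs_tsv <- function(path, reference) {
  tab <- read_report_tsv(path)
  functional_residue_set(reference, tab$position, tab$residue,
                         if ("role" %in% names(tab)) tab$role else "catalytic")
}
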