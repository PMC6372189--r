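#' Iterative profile search against a sequence database
#'
#' Round 1 scores every database sequence against a profile built from the
#' query alone (or from `seed_alignment` when given — the
#' alignment-seeded analog of a domain-profile search). After each round,
#' hits with `E <= inclusion_E` are stitched into the profile alignment via
#' their traceback to profile columns (insertions relative to the profile
#' are dropped; profile columns are never changed) and the profile is
#' rebuilt, so later rounds can pull in progressively more remote family
#' members. E-values come from a per-round Gumbel calibration on shuffled
#' database sequences.
#'
#' Reported statistics follow the usual search-report semantics: percent
#' identity and similarity are measured against the query residues for a
#' single-sequence profile, and against the profile consensus when the
#' profile was seeded from an alignment (`stats_source` records which);
#' coverage is the percent of query columns inside the aligned span. Hits
#' are flagged full-length when coverage reaches `coverage_full`.
#'
#' @param query a [protein_sequence].
#' @param database list of [protein_sequence] objects.
#' @param seed_alignment optional [alignment] used to seed the round-1
#'   profile (the query must be its first row).
#' @param n_iter number of search rounds (>= 1).
#' @param inclusion_E inclusion threshold for profile updates.
#' @param matrix a [substitution_matrix].
#' @param gap_open,gap_extend affine gap penalties.
#' @param beta PSSM pseudocount weight.
#' @param coverage_full full-length coverage threshold (percent).
#' @param report_E hits with E-value above this are not reported.
#' @param n_shuffles shuffles per round for E-value calibration.
#' @param seed integer seed (shuffling only; the search is deterministic).
#' @return data.frame of hits with columns `target`, `round`, `raw`,
#'   `bits`, `evalue`, `qstart`, `qend`, `tstart`, `tend`, `pident`,
#'   `psim`, `qcov`, `full_length`, `stats_source`, plus attributes
#'   `profile_alignment` (the final profile alignment) and `calibrations`.
#' @export
iterative_search <- function(query, database, seed_alignment = NULL,
                             n_iter = 3, inclusion_E = 0.005,
                             matrix = substitution_matrix(),
                             gap_open = 11, gap_extend = 1, beta = 10,
                             coverage_full = 65, report_E = 10,
                             n_shuffles = 60, seed = 1) {
  stopifnot(inherits(query, "protein_sequence"), length(database) >= 1L)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  profile_seeded <- !is.null(seed_alignment)
  aln <- if (profile_seeded) {
    stopifnot(inherits(seed_alignment, "alignment"))
    seed_alignment
  } else {
    alignment(query$id, query$residues)
  }
  stats_source <- if (profile_seeded) "profile-match" else "sequence-match"
  db_ids <- vapply(database, function(s) s$id, character(1))
  included <- character(0)
  rows <- list()
  calibs <- list()

  for (r in seq_len(n_iter)) {
    profile <- build_pssm(aln, matrix, beta = beta)
    calib <- calibrate_evalue(profile, database, n_shuffles = n_shuffles,
                              seed = child_seed(seed, r),
                              gap_open = gap_open, gap_extend = gap_extend)
    calibs[[r]] <- calib
    alis <- lapply(database, local_align_profile, profile = profile,
                   gap_open = gap_open, gap_extend = gap_extend)
    raw <- vapply(alis, `[[`, numeric(1), "score")
    E <- evalue(calib, raw)
    for (k in seq_along(database)) {
      if (E[k] > report_E) next
      st <- profile_hit_stats(profile, database[[k]], alis[[k]])
      rows[[length(rows) + 1L]] <- data.frame(
        target = db_ids[k], round = r, raw = raw[k],
        bits = bit_score(calib, raw[k]), evalue = E[k],
        qstart = alis[[k]]$qstart, qend = alis[[k]]$qend,
        tstart = alis[[k]]$tstart, tend = alis[[k]]$tend,
        pident = st$pident, psim = st$psim, qcov = st$qcov,
        full_length = st$qcov >= coverage_full,
        stats_source = stats_source, stringsAsFactors = FALSE)
    }
    ## profile update for the next round
    if (r < n_iter) {
      newly <- which(E <= inclusion_E & !(db_ids %in% c(included, aln$ids)))
      for (k in newly) {
        aln <- stitch_into_profile(aln, profile, database[[k]], alis[[k]])
        included <- c(included, db_ids[k])
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target = character(0), round = integer(0), raw = numeric(0),
               bits = numeric(0), evalue = numeric(0), qstart = integer(0),
               qend = integer(0), tstart = integer(0), tend = integer(0),
               pident = numeric(0), psim = numeric(0), qcov = numeric(0),
               full_length = logical(0), stats_source = character(0),
               stringsAsFactors = FALSE)
  attr(out, "profile_alignment") <- aln
  attr(out, "calibrations") <- calibs
  out
}

## Add a hit as a new alignment row using its traceback to profile columns.
## Profile columns map to alignment columns (gappy columns that were
## dropped from the profile stay gaps in the new row); target insertions
## are discarded.
stitch_into_profile <- function(aln, profile, target, ali) {
  row <- rep("-", aln$ncol)
  pr <- ali$pairs
  if (nrow(pr)) {
    letters <- seq_letters(target)
    row[profile$aln_columns[pr[, "profile_col"]]] <- letters[pr[, "target_pos"]]
  }
  alignment(c(aln$ids, target$id), c(aln$gapped, paste(row, collapse = "")))
}
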