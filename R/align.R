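## Alignment engines. All DP goes through the compiled Gotoh kernel
## (.dp_align); profile scores (bits) are doubled to the half-bit scale so
## that the conventional gap penalties (open 11, extend 1) keep their
## BLAST meaning relative to BLOSUM62.

#' Locally align a profile to a target sequence
#'
#' Smith-Waterman with affine gaps over the profile's per-column scores.
#' The empty alignment (score 0) is allowed. Traceback is deterministic:
#' substitution is preferred over a gap in the target, which is preferred
#' over a gap in the profile; score ties resolve to the leftmost-highest
#' cell.
#'
#' @param profile a [pssm].
#' @param target a [protein_sequence].
#' @param gap_open,gap_extend affine gap penalties (half-bit scale); a gap
#'   of length k costs `gap_open + k * gap_extend`.
#' @param mode `"local"` or `"global"`.
#' @return list with `score` (raw, half-bit scale), `qstart`/`qend`
#'   (profile columns), `tstart`/`tend` (target positions), `pairs`
#'   (two-column matrix of matched profile column / target position), and
#'   `row_index`/`col_index` (full gapped path; 0 marks a gap).
#' @export
local_align_profile <- function(profile, target, gap_open = 11,
                                gap_extend = 1, mode = c("local", "global")) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "pssm"), inherits(target, "protein_sequence"),
            gap_open >= gap_extend, gap_extend >= 0)
  letters <- seq_letters(target)
  S <- 2 * profile$scores[, letters, drop = FALSE]
  res <- .dp_align(S, gap_open, gap_extend, if (mode == "local") 0L else 1L)
  ri <- res$row_index; ci <- res$col_index
  matched <- ri > 0L & ci > 0L
  pairs <- cbind(profile_col = ri[matched], target_pos = ci[matched])
  list(score = res$score,
       qstart = if (any(matched)) min(pairs[, 1]) else NA_integer_,
       qend = if (any(matched)) max(pairs[, 1]) else NA_integer_,
       tstart = if (any(matched)) min(pairs[, 2]) else NA_integer_,
       tend = if (any(matched)) max(pairs[, 2]) else NA_integer_,
       pairs = pairs, row_index = ri, col_index = ci)
}

## identity / similarity / coverage statistics from a profile-target path
profile_hit_stats <- function(profile, target, ali) {
  ri <- ali$row_index; ci <- ali$col_index
  ncols <- length(ri)
  if (ncols == 0L)
    return(list(pident = 0, psim = 0, qcov = 0))
  letters <- seq_letters(target)
  matched <- ri > 0L & ci > 0L
  tl <- letters[ci[matched]]
  rl <- profile$ref_letters[ri[matched]]
  ident <- sum(tl == rl)
  colscore <- profile$scores[cbind(ri[matched], match(tl, AA_ALPHABET))]
  sim <- sum(tl == rl | colscore > 0)
  qpos <- profile$query_positions[ri[ri > 0L]]
  qpos <- qpos[!is.na(qpos)]
  span <- if (length(qpos)) max(qpos) - min(qpos) + 1L else 0L
  list(pident = 100 * ident / ncols,
       psim = 100 * sim / ncols,
       qcov = 100 * span / profile$query_length)
}

#' Pairwise alignment statistics between two sequences
#'
#' Aligns `a` (query) and `b` (target) with affine gaps and reports percent
#' identity (identical columns / aligned columns; gap columns count in the
#' denominator only), percent similarity (identities plus positive-scoring
#' substitutions) and query coverage (aligned query residues / query
#' length).
#'
#' @param a,b [protein_sequence] objects (query, target).
#' @param matrix a [substitution_matrix].
#' @param gap_open,gap_extend affine gap penalties.
#' @param mode `"local"` (Smith-Waterman) or `"global"` (Needleman-Wunsch).
#' @return list with `identity`, `similarity`, `coverage` (percent),
#'   `score`, and `alignment` (an [alignment] of the two gapped rows).
#' @export
pairwise_stats <- function(a, b, matrix = substitution_matrix(),
                           gap_open = 11, gap_extend = 1,
                           mode = c("local", "global")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "protein_sequence"), inherits(b, "protein_sequence"))
  la <- seq_letters(a); lb <- seq_letters(b)
  S <- matrix(matrix[la, lb], nrow = length(la))
  res <- .dp_align(S, gap_open, gap_extend, if (mode == "local") 0L else 1L)
  ri <- res$row_index; ci <- res$col_index
  ncols <- length(ri)
  ga <- ifelse(ri > 0L, la[pmax(ri, 1L)], "-")
  gb <- ifelse(ci > 0L, lb[pmax(ci, 1L)], "-")
  matched <- ri > 0L & ci > 0L
  ident <- sum(ga[matched] == gb[matched])
  sim <- sum(ga[matched] == gb[matched] |
               matrix[cbind(ga[matched], gb[matched])] > 0)
  n_aligned_query <- sum(ri > 0L)
  aln <- if (ncols) alignment(c(a$id, b$id),
                              c(paste(ga, collapse = ""),
                                paste(gb, collapse = "")))
         else NULL
  list(identity = if (ncols) 100 * ident / ncols else 0,
       similarity = if (ncols) 100 * sim / ncols else 0,
       coverage = 100 * n_aligned_query / length(la),
       score = res$score, alignment = aln)
}
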