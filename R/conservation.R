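#' Residue-equivalence rules for functional-residue mapping
#'
#' Unordered residue pairs treated as functionally equivalent when mapping
#' catalytic residues onto a candidate. Three pairs reflect substitutions
#' with direct experimental or chemical support (tyrosine/phenylalanine,
#' aspartate/asparagine, cysteine/selenocysteine) and are always on; the
#' generic conservative groups (D/E, K/R, S/T, I/L/V) are on by default
#' but can be switched off.
#'
#' @param conservative_groups include the generic conservative groups.
#' @param extra_pairs optional list of additional character vectors, each a
#'   group of mutually equivalent letters.
#' @param proximity_cutoff C-alpha distance cutoff (A) for structural
#'   proximity rescue.
#' @return an object of class `equivalence_rules`.
#' @export
equivalence_rules <- function(conservative_groups = TRUE,
                              extra_pairs = list(),
                              proximity_cutoff = 5.0) {
  if (proximity_cutoff <= 0) stop("proximity cutoff must be > 0",
                                  call. = FALSE)
  groups <- list(c("Y", "F"), c("D", "N"), c("C", "U"))
  if (conservative_groups)
    groups <- c(groups, list(c("D", "E"), c("K", "R"), c("S", "T"),
                             c("I", "L", "V")))
  groups <- c(groups, lapply(extra_pairs, toupper))
  structure(list(groups = groups, proximity_cutoff = proximity_cutoff),
            class = "equivalence_rules")
}

is_equivalent <- function(a, b, rules) {
  if (a == b) return(TRUE)
  for (g in rules$groups) if (a %in% g && b %in% g) return(TRUE)
  FALSE
}

#' Align a candidate sequence to a reference alignment
#'
#' Global profile-to-sequence alignment of the candidate against the MSA's
#' column profile. The original MSA columns are unchanged; candidate
#' residues that fall between profile columns become new insertion columns
#' (all-gap in the original rows), flagged in the `insertion_columns`
#' attribute.
#'
#' @param candidate a [protein_sequence].
#' @param reference_msa an [alignment].
#' @param matrix a [substitution_matrix].
#' @param gap_open,gap_extend affine gap penalties.
#' @param beta PSSM pseudocount weight.
#' @return an [alignment] of the MSA rows plus the candidate row, with
#'   attribute `insertion_columns` (integer positions of inserted columns
#'   in the augmented alignment).
#' @export
align_candidate_to_msa <- function(candidate, reference_msa,
                                   matrix = substitution_matrix(),
                                   gap_open = 11, gap_extend = 1,
                                   beta = 10) {
  stopifnot(inherits(candidate, "protein_sequence"),
            inherits(reference_msa, "alignment"))
  profile <- build_pssm(reference_msa, matrix, beta = beta,
                        max_gap_frac = 1) # keep every MSA column
  ali <- local_align_profile(profile, candidate, gap_open, gap_extend,
                             mode = "global")
  ri <- ali$row_index; ci <- ali$col_index
  C <- reference_msa$ncol
  letters <- seq_letters(candidate)
  ## build the augmented column list: each path element is either an MSA
  ## column (ri > 0) or a candidate insertion column (ri == 0)
  old_rows <- strsplit(reference_msa$gapped, "", fixed = TRUE)
  n_old <- length(old_rows)
  new_rows <- lapply(seq_len(n_old), function(i) character(0))
  cand_row <- character(0)
  insertion_cols <- integer(0)
  for (k in seq_along(ri)) {
    if (ri[k] > 0L) {
      for (i in seq_len(n_old))
        new_rows[[i]] <- c(new_rows[[i]], old_rows[[i]][ri[k]])
      cand_row <- c(cand_row, if (ci[k] > 0L) letters[ci[k]] else "-")
    } else {
      for (i in seq_len(n_old)) new_rows[[i]] <- c(new_rows[[i]], "-")
      cand_row <- c(cand_row, letters[ci[k]])
      insertion_cols <- c(insertion_cols, k)
    }
  }
  out <- alignment(c(reference_msa$ids, candidate$id),
                   c(vapply(new_rows, paste, character(1), collapse = ""),
                     paste(cand_row, collapse = "")))
  attr(out, "insertion_columns") <- insertion_cols
  out
}

#' Map functional residues of a reference onto a candidate
#'
#' For each annotated functional residue, reads the candidate letter in the
#' same alignment column and classifies it: `identical` (same letter),
#' `equivalent` (allowed equivalence pair), or `missing` (gap or
#' non-equivalent letter). Candidate positions are 1-based de-gapped
#' positions; a hard internal assertion checks each reported position
#' indexes the reported letter.
#'
#' @param aug_msa an [alignment] containing both the reference and the
#'   candidate row.
#' @param frs a [functional_residue_set] on the reference.
#' @param rules an [equivalence_rules].
#' @param candidate_id row id of the candidate (default: last row).
#' @return an object of class `residue_mapping`: a data.frame with columns
#'   `ref_position`, `ref_residue`, `role`, `cand_position`,
#'   `cand_residue`, `status`, plus attributes `conserved_fraction`,
#'   `reference_id`, `candidate_id`.
#' @export
map_functional_residues <- function(aug_msa, frs, rules = equivalence_rules(),
                                    candidate_id = NULL) {
  stopifnot(inherits(aug_msa, "alignment"),
            inherits(frs, "functional_residue_set"))
  if (is.null(candidate_id)) candidate_id <- aug_msa$ids[length(aug_msa$ids)]
  iref <- match(frs$reference_id, aug_msa$ids)
  icand <- match(candidate_id, aug_msa$ids)
  if (is.na(iref)) stop(sprintf("reference row '%s' not in alignment",
                                frs$reference_id), call. = FALSE)
  if (is.na(icand)) stop(sprintf("candidate row '%s' not in alignment",
                                 candidate_id), call. = FALSE)
  A <- alignment_matrix(aug_msa)
  ref_degap <- cumsum(A[iref, ] != "-")
  cand_degap <- cumsum(A[icand, ] != "-")
  cand_seq <- A[icand, ][A[icand, ] != "-"]

  n <- length(frs$position)
  cand_pos <- rep(NA_integer_, n)
  cand_res <- rep(NA_character_, n)
  status <- character(n)
  for (i in seq_len(n)) {
    col <- match(frs$position[i], ref_degap)
    if (is.na(col) || A[iref, col] == "-")
      stop("reference letter mismatch: functional residue position not in alignment",
           call. = FALSE)
    if (A[iref, col] != frs$residue[i])
      stop(sprintf("reference letter mismatch at position %d: alignment has %s, annotation %s",
                   frs$position[i], A[iref, col], frs$residue[i]),
           call. = FALSE)
    cl <- A[icand, col]
    if (cl == "-") {
      status[i] <- "missing"
    } else {
      cand_pos[i] <- cand_degap[col]
      cand_res[i] <- cl
      stopifnot(cand_seq[cand_pos[i]] == cl) # bookkeeping hard assertion
      status[i] <- if (cl == frs$residue[i]) "identical"
                   else if (is_equivalent(frs$residue[i], cl, rules)) "equivalent"
                   else "missing"
      if (status[i] == "missing") { cand_pos[i] <- NA; cand_res[i] <- NA }
    }
  }
  out <- data.frame(ref_position = frs$position, ref_residue = frs$residue,
                    role = frs$role, cand_position = cand_pos,
                    cand_residue = cand_res, status = status,
                    stringsAsFactors = FALSE)
  class(out) <- c("residue_mapping", "data.frame")
  attr(out, "conserved_fraction") <- mean(status != "missing")
  attr(out, "reference_id") <- frs$reference_id
  attr(out, "candidate_id") <- candidate_id
  out
}

#' Conserved fraction of a residue mapping
#' @param mapping a `residue_mapping`.
#' @return fraction of functional residues with status other than missing.
#' @export
conserved_fraction <- function(mapping) attr(mapping, "conserved_fraction")

#' Rescue missing functional residues by structural proximity
#'
#' A residue with status `missing` is upgraded to `proximal` if the
#' candidate structure contains a residue of identical or equivalent
#' letter whose superposed C-alpha lies within the cutoff of the reference
#' residue's C-alpha. Residue numbers in the structures are assumed to be
#' sequence positions. No other statuses change; the operation is
#' idempotent.
#'
#' @param mapping a `residue_mapping`.
#' @param ref_structure [calpha_structure] of the reference.
#' @param cand_structure [calpha_structure] of the candidate.
#' @param superposition a `superposition_result` mapping the candidate
#'   structure onto the reference frame (see [kabsch_superpose()], with
#'   the reference as `A` and the candidate as `B`).
#' @param rules an [equivalence_rules] (supplies the cutoff).
#' @return the updated `residue_mapping`.
#' @export
proximity_rescue <- function(mapping, ref_structure, cand_structure,
                             superposition, rules = equivalence_rules()) {
  stopifnot(inherits(mapping, "residue_mapping"),
            inherits(ref_structure, "calpha_structure"),
            inherits(cand_structure, "calpha_structure"),
            inherits(superposition, "superposition_result"))
  cand_xyz <- transform_coords(cand_structure$xyz, superposition)
  cutoff <- rules$proximity_cutoff
  for (i in seq_len(nrow(mapping))) {
    if (mapping$status[i] != "missing") next
    iref <- match(mapping$ref_position[i], ref_structure$resno)
    if (is.na(iref)) {
      warning(sprintf("reference structure lacks residue %d; status unchanged",
                      mapping$ref_position[i]), call. = FALSE)
      next
    }
    ok <- vapply(seq_along(cand_structure$resno), function(j)
      is_equivalent(mapping$ref_residue[i], cand_structure$resletter[j],
                    rules), logical(1))
    if (!any(ok)) next
    d <- sqrt(rowSums((cand_xyz[ok, , drop = FALSE] -
                         matrix(ref_structure$xyz[iref, ], sum(ok), 3,
                                byrow = TRUE))^2))
    if (min(d) <= cutoff) {
      j <- which(ok)[which.min(d)]
      mapping$status[i] <- "proximal"
      mapping$cand_position[i] <- cand_structure$resno[j]
      mapping$cand_residue[i] <- cand_structure$resletter[j]
    }
  }
  attr(mapping, "conserved_fraction") <- mean(mapping$status != "missing")
  mapping
}

#' Compare two domain architectures
#'
#' The match flag is true iff the ordered domain-id sequences are
#' identical. The score is the mean, over matched domains, of the Jaccard
#' overlap of the intervals after linear rescaling of positions to
#' `[0, 1]` by each protein's length — so a uniform boundary drift of a few
#' residues (well under 10% of the protein) keeps the score near 1.
#'
#' @param a,b [domain_architecture] objects.
#' @param len_a,len_b the protein lengths.
#' @return list with `match` (logical) and `score` in `[0, 1]`.
#' @export
compare_domain_architecture <- function(a, b, len_a, len_b) {
  stopifnot(inherits(a, "domain_architecture"),
            inherits(b, "domain_architecture"))
  if (!identical(a$domain_id, b$domain_id))
    return(list(match = FALSE, score = 0))
  if (!length(a$domain_id)) return(list(match = TRUE, score = 1))
  sc <- vapply(seq_along(a$domain_id), function(i) {
    ia <- c((a$start[i] - 1) / len_a, a$end[i] / len_a)
    ib <- c((b$start[i] - 1) / len_b, b$end[i] / len_b)
    inter <- max(0, min(ia[2], ib[2]) - max(ia[1], ib[1]))
    un <- max(ia[2], ib[2]) - min(ia[1], ib[1])
    if (un <= 0) 0 else inter / un
  }, numeric(1))
  list(match = TRUE, score = mean(sc))
}

#' Secondary-structure string
#'
#' A 3-state (H/E/C) secondary-structure annotation of a sequence.
#'
#' @param id sequence identifier.
#' @param states character scalar over `{H, E, C}`.
#' @return an object of class `ss_string`.
#' @export
ss_string <- function(id, states) {
  states <- toupper(states)
  if (grepl("[^HEC]", states))
    stop("secondary-structure states must be H, E or C", call. = FALSE)
  structure(list(id = id, states = states), class = "ss_string")
}

#' Consensus of secondary-structure predictions
#'
#' Per-position majority vote over equal-length 3-state strings; ties
#' resolve to coil (C).
#'
#' @param ss_list list of [ss_string] objects of equal length.
#' @return an [ss_string] with id `"consensus"`.
#' @export
ss_consensus <- function(ss_list) {
  stopifnot(length(ss_list) >= 1L)
  mats <- lapply(ss_list, function(s) strsplit(s$states, "", fixed = TRUE)[[1]])
  lens <- lengths(mats)
  if (length(unique(lens)) != 1L)
    stop("secondary-structure strings have unequal lengths", call. = FALSE)
  M <- do.call(rbind, mats)
  cons <- apply(M, 2, function(col) {
    tab <- table(factor(col, levels = c("H", "E", "C")))
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) "C" else top
  })
  ss_string("consensus", paste(cons, collapse = ""))
}

#' Percent secondary-structure agreement over an alignment
#'
#' Maps each sequence's 3-state string through the gap structure of a
#' pairwise alignment and reports the percentage of non-gap aligned
#' columns with equal labels.
#'
#' @param ss_a,ss_b [ss_string] objects matching the two sequences'
#'   lengths.
#' @param aln a two-row [alignment] of the sequences (a first).
#' @return percent agreement in `[0, 100]`.
#' @export
ss_agreement <- function(ss_a, ss_b, aln) {
  stopifnot(inherits(aln, "alignment"), length(aln$ids) == 2L)
  A <- alignment_matrix(aln)
  sa <- strsplit(ss_a$states, "", fixed = TRUE)[[1]]
  sb <- strsplit(ss_b$states, "", fixed = TRUE)[[1]]
  if (length(sa) != sum(A[1, ] != "-") || length(sb) != sum(A[2, ] != "-"))
    stop("secondary-structure string length does not match its sequence",
         call. = FALSE)
  pa <- cumsum(A[1, ] != "-")
  pb <- cumsum(A[2, ] != "-")
  both <- A[1, ] != "-" & A[2, ] != "-"
  if (!any(both)) return(0)
  100 * mean(sa[pa[both]] == sb[pb[both]])
}
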