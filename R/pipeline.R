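#' Screen a database for remote-ortholog candidates of one query
#'
#' Runs the full sequence arm of the triage pipeline: an iterative profile
#' search of `query` against `database`, then, for every target with a
#' statistically significant hit (E at or below the inclusion threshold in
#' any round), alignment into the reference alignment, functional-residue
#' mapping and tier assignment. Targets that never reach significance are
#' reported as rejected ("no significant hit"); significant targets whose
#' mapped residue set is empty are rejected by the conservation screen.
#'
#' The detection route is `"pairwise"` when the target was already
#' significant in round 1 of a single-sequence-seeded search (the plain
#' pairwise-search analog) and `"profile-iterative"` otherwise.
#'
#' @param query a [protein_sequence].
#' @param database list of [protein_sequence] objects.
#' @param frs a [functional_residue_set] on the query.
#' @param reference_msa optional [alignment] (query first row) used as the
#'   conservation reference; defaults to the query alone.
#' @param thresholds a [triage_thresholds].
#' @param rules an [equivalence_rules].
#' @param matrix a [substitution_matrix].
#' @param n_iter,seed,... passed to [iterative_search()].
#' @return list with `hits` (the search report), `summary` (data.frame:
#'   `target`, `best_evalue`, `identity`, `coverage`, `group`,
#'   `rationale`), `records` and `tiers` for the significant candidates.
#' @export
screen_candidates <- function(query, database, frs, reference_msa = NULL,
                              thresholds = triage_thresholds(),
                              rules = equivalence_rules(),
                              matrix = substitution_matrix(),
                              n_iter = 3, seed = 1, ...) {
  if (is.null(reference_msa))
    reference_msa <- alignment(query$id, query$residues)
  hits <- iterative_search(query, database, n_iter = n_iter,
                           inclusion_E = thresholds$inclusion_e,
                           matrix = matrix,
                           coverage_full = thresholds$coverage_fulllength,
                           seed = seed, ...)
  db_ids <- vapply(database, function(s) s$id, character(1))
  records <- list(); tiers <- list()
  rows <- list()
  for (k in seq_along(database)) {
    target <- database[[k]]
    th <- hits[hits$target == db_ids[k], , drop = FALSE]
    best_e <- if (nrow(th)) min(th$evalue) else Inf
    if (!nrow(th) || best_e > thresholds$inclusion_e) {
      rows[[k]] <- data.frame(target = db_ids[k], best_evalue = best_e,
                              identity = NA_real_, coverage = NA_real_,
                              group = "rejected",
                              rationale = "no statistically significant hit",
                              stringsAsFactors = FALSE)
      next
    }
    best <- th[which.min(th$evalue), , drop = FALSE]
    route <- if (any(th$round == 1 & th$evalue <= thresholds$inclusion_e) &&
                 best$stats_source == "sequence-match") "pairwise"
             else "profile-iterative"
    aug <- align_candidate_to_msa(target, reference_msa, matrix)
    mapping <- map_functional_residues(aug, frs, rules,
                                       candidate_id = target$id)
    rec <- assemble_candidate_record(query$id, target$id, best, mapping,
                                     detection_route = route)
    tier <- assign_tier(rec, thresholds)
    records[[db_ids[k]]] <- rec
    tiers[[db_ids[k]]] <- tier
    rows[[k]] <- data.frame(target = db_ids[k], best_evalue = best_e,
                            identity = best$pident, coverage = best$qcov,
                            group = tier$group, rationale = tier$rationale,
                            stringsAsFactors = FALSE)
  }
  list(hits = hits, summary = do.call(rbind, rows), records = records,
       tiers = tiers)
}
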