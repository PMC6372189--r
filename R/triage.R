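#' Threshold configuration for tier assignment
#'
#' All tunable screening thresholds in one place so a classification run is
#' an explicit, re-runnable experiment.
#'
#' @param identity_g1 minimum percent identity for the high-confidence
#'   tier.
#' @param identity_g2 minimum percent identity for the mid-range tier.
#' @param coverage_fulllength minimum query coverage (percent) for a hit
#'   to count as a full-length, pairwise-detectable match.
#' @param inclusion_e profile-inclusion E-value threshold.
#' @param proximity_cutoff C-alpha proximity rescue cutoff (A).
#' @param ss_agreement_min minimum secondary-structure agreement (percent)
#'   to pass screening.
#' @return a named list of class `triage_thresholds`.
#' @export
triage_thresholds <- function(identity_g1 = 30, identity_g2 = 20,
                              coverage_fulllength = 65,
                              inclusion_e = 0.005, proximity_cutoff = 5.0,
                              ss_agreement_min = 60) {
  structure(list(identity_g1 = identity_g1, identity_g2 = identity_g2,
                 coverage_fulllength = coverage_fulllength,
                 inclusion_e = inclusion_e,
                 proximity_cutoff = proximity_cutoff,
                 ss_agreement_min = ss_agreement_min),
            class = "triage_thresholds")
}

#' Assemble one candidate's evidence into a record
#'
#' Binds the outputs of the search, conservation and structure stages into
#' one record shaped like a row of the summary report.
#'
#' @param human_gene reference (human) gene identifier.
#' @param candidate_id candidate identifier.
#' @param hit one-row data.frame from [iterative_search()] (or a list with
#'   the same fields) carrying `pident`, `psim`, `evalue`, `qcov`,
#'   `stats_source`.
#' @param mapping a `residue_mapping` for the candidate (its
#'   `candidate_id` attribute must agree with `candidate_id`).
#' @param detection_route `"pairwise"`, `"profile-iterative"` or
#'   `"structure-only"`.
#' @param architecture optional result of [compare_domain_architecture()].
#' @param ss_agreement optional percent secondary-structure agreement.
#' @param superposition optional `superposition_result` (fold evidence).
#' @param residue_summary optional list with `conserved_fraction` and
#'   `full_set`, used instead of `mapping` when the per-residue mapping is
#'   not available (e.g. records transcribed from a published table).
#' @return an object of class `candidate_record`.
#' @export
assemble_candidate_record <- function(human_gene, candidate_id, hit, mapping,
                                      detection_route = c("pairwise",
                                                          "profile-iterative",
                                                          "structure-only"),
                                      architecture = NULL,
                                      ss_agreement = NA_real_,
                                      superposition = NULL,
                                      residue_summary = NULL) {
  detection_route <- match.arg(detection_route)
  if (!is.null(mapping)) {
    mid <- attr(mapping, "candidate_id")
    if (!is.null(mid) && !identical(mid, candidate_id))
      stop(sprintf("candidate id mismatch: record says '%s', mapping says '%s'",
                   candidate_id, mid), call. = FALSE)
  }
  stats_source <- if (!is.null(hit$stats_source)) hit$stats_source[1]
                  else "sequence-match"
  if (stats_source == "profile-match" && detection_route == "pairwise")
    stop("profile-match statistics are inconsistent with a pairwise detection route",
         call. = FALSE)
  pct <- c(hit$pident[1], hit$psim[1], hit$qcov[1])
  if (any(pct < 0 | pct > 100, na.rm = TRUE))
    stop("percentages must be in [0, 100]", call. = FALSE)
  if (hit$evalue[1] < 0) stop("E-value must be >= 0", call. = FALSE)
  structure(list(
    human_gene = human_gene, candidate_id = candidate_id,
    identity = hit$pident[1], similarity = hit$psim[1],
    evalue = hit$evalue[1], coverage = hit$qcov[1],
    stats_source = stats_source, detection_route = detection_route,
    arch_match = if (is.null(architecture)) NA else architecture$match,
    arch_score = if (is.null(architecture)) NA_real_ else architecture$score,
    ss_agreement = ss_agreement,
    conserved_fraction = if (!is.null(mapping)) conserved_fraction(mapping)
                         else if (!is.null(residue_summary))
                           residue_summary$conserved_fraction
                         else NA_real_,
    full_residue_set = if (!is.null(mapping))
                         all(mapping$status %in% c("identical", "equivalent"))
                       else if (!is.null(residue_summary))
                         residue_summary$full_set
                       else NA,
    mapping = mapping,
    fold = if (is.null(superposition)) NULL
           else list(rmsd = superposition$rmsd,
                     n_pairs = superposition$n_pairs,
                     tm_score = superposition$tm_score)),
    class = "candidate_record")
}

#' @export
print.candidate_record <- function(x, ...) {
  cat(sprintf("<candidate_record> %s -> %s: id %.0f%%, cov %.0f%%, E=%.2g (%s)\n",
              x$human_gene, x$candidate_id, x$identity, x$coverage,
              x$evalue, x$stats_source))
  invisible(x)
}

## fold match: TM-score above the conventional same-fold threshold when
## fold evidence exists; otherwise fall back to architecture agreement
record_fold_match <- function(record) {
  if (!is.null(record$fold)) return(record$fold$tm_score > 0.5)
  if (!is.na(record$arch_match)) return(isTRUE(record$arch_match))
  NA
}

#' Assign a confidence tier to a candidate record
#'
#' Evaluation order: (i) rejected when the fold does not match or no
#' functional residue is conserved; (ii) distant tier (group 3) when the
#' candidate is not pairwise-detectable — detection route other than
#' pairwise, profile-match statistics, or coverage below the full-length
#' threshold; (iii) high-confidence (group 1) when identity meets the
#' group-1 threshold and the full functional residue set is conserved
#' (identical or equivalent); (iv) mid-range (group 2) when identity meets
#' the group-2 threshold and at least one residue is conserved;
#' (v) otherwise group 3. The detection-route test deliberately precedes
#' the identity tests: distant candidates can show high profile identities
#' while mid-range ones sit above the group-1 cutoff, so identity alone
#' cannot separate the tiers.
#'
#' @param record a `candidate_record`.
#' @param thresholds a [triage_thresholds].
#' @return an object of class `tier_assignment`: `group` (`"1"`, `"2"`,
#'   `"3"` or `"rejected"`), `criteria` (named logicals), `rationale`.
#' @export
assign_tier <- function(record, thresholds = triage_thresholds()) {
  stopifnot(inherits(record, "candidate_record"))
  th <- thresholds
  fold_ok <- record_fold_match(record)
  cons <- record$conserved_fraction
  crit <- c(
    identity_ge_g1 = !is.na(record$identity) &&
      record$identity >= th$identity_g1,
    identity_ge_g2 = !is.na(record$identity) &&
      record$identity >= th$identity_g2,
    fold_match = isTRUE(fold_ok),
    full_residue_set = isTRUE(record$full_residue_set),
    partial_residue_set = !is.na(cons) && cons > 0 &&
      !isTRUE(record$full_residue_set),
    pairwise_detectable = record$detection_route == "pairwise" &&
      record$stats_source == "sequence-match",
    coverage_ok = !is.na(record$coverage) &&
      record$coverage >= th$coverage_fulllength)

  group <- NULL; why <- NULL
  if ((!is.na(fold_ok) && !fold_ok) || (!is.na(cons) && cons == 0)) {
    group <- "rejected"
    why <- if (!is.na(fold_ok) && !fold_ok) "dissimilar fold/architecture"
           else "no conserved functional residue"
  } else if (!crit[["pairwise_detectable"]] || !crit[["coverage_ok"]]) {
    group <- "3"
    why <- "not detectable as a full-length pairwise match"
  } else if (crit[["identity_ge_g1"]] && crit[["full_residue_set"]]) {
    group <- "1"
    why <- sprintf("identity %.0f%% >= %g%% with the full functional residue set",
                   record$identity, th$identity_g1)
  } else if (crit[["identity_ge_g2"]] && (!is.na(cons) && cons > 0)) {
    group <- "2"
    why <- sprintf("identity %.0f%% >= %g%% with a partial residue set",
                   record$identity, th$identity_g2)
  } else {
    group <- "3"
    why <- "low identity despite pairwise detection"
  }
  structure(list(group = group, criteria = as.list(crit), rationale = why),
            class = "tier_assignment")
}

#' @export
print.tier_assignment <- function(x, ...) {
  cat(sprintf("<tier_assignment> group %s (%s)\n", x$group, x$rationale))
  invisible(x)
}

#' Render tiered candidate records as a report table
#'
#' One row per candidate in the published summary-table layout, with the
#' tier and rationale appended. Profile-match statistics carry a `*`
#' suffix. Rows are ordered by human gene, then ascending E-value.
#'
#' @param records list of `candidate_record` objects.
#' @param tiers list of matching `tier_assignment` objects.
#' @param path optional output path; when given the table is written as
#'   TSV via [write_report_tsv()].
#' @return the report data.frame (invisibly when `path` is given).
#' @export
render_table <- function(records, tiers, path = NULL) {
  stopifnot(length(records) == length(tiers))
  if (!length(records)) {
    tab <- data.frame(human_gene = character(0), candidate = character(0),
                      identity = character(0), similarity = character(0),
                      evalue = character(0), coverage = character(0),
                      group = character(0), rationale = character(0),
                      stringsAsFactors = FALSE)
    if (!is.null(path)) { write_report_tsv(tab, path); return(invisible(tab)) }
    return(tab)
  }
  fmt <- function(x, starred) {
    ifelse(is.na(x), "", paste0(format(x, trim = TRUE),
                                ifelse(starred, "*", "")))
  }
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]; a <- tiers[[i]]
    starred <- r$stats_source == "profile-match"
    data.frame(
      human_gene = r$human_gene, candidate = r$candidate_id,
      identity = fmt(r$identity, starred),
      similarity = fmt(r$similarity, starred),
      evalue = fmt(r$evalue, starred),
      coverage = fmt(r$coverage, starred),
      group = a$group, rationale = a$rationale,
      evalue_num = r$evalue, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$human_gene, tab$evalue_num), ]
  tab$evalue_num <- NULL
  rownames(tab) <- NULL
  if (!is.null(path)) {
    write_report_tsv(tab, path)
    return(invisible(tab))
  }
  tab
}
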