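#' Specification for a synthetic ortholog family
#'
#' Describes a family of orthologs evolved from a common root sequence at a
#' controlled mean pairwise identity, carrying a planted set of functional
#' (motif) residues that are conserved identically or replaced by an
#' allowed equivalent with a stated probability. Indels follow a geometric
#' length distribution and are never placed on motif positions.
#'
#' @param root_length length of the root sequence (residues).
#' @param n_orthologs number of orthologs to generate (root excluded).
#' @param target_identity target mean pairwise identity to the root, in
#'   percent (0, 100].
#' @param motif_positions 1-based motif positions on the root.
#' @param motif_residues residue letters planted at the motif positions
#'   (recycled; default drawn at generation time).
#' @param equivalent_sets named list mapping a motif letter to its allowed
#'   equivalent letters (e.g. `list(Y = "F")`).
#' @param equivalence_prob probability that a motif site carries an allowed
#'   equivalent instead of the identical letter.
#' @param indel_rate per-site indel event rate in [0, 0.2].
#' @param seed integer seed; all randomness derives from it.
#' @return an object of class `family_spec`.
#' @export
family_spec <- function(root_length = 200L, n_orthologs = 5L,
                        target_identity = 30, motif_positions = integer(0),
                        motif_residues = NULL,
                        equivalent_sets = list(Y = "F", D = "N", C = "U"),
                        equivalence_prob = 0, indel_rate = 0.02, seed = 1L) {
  if (target_identity <= 0 || target_identity > 100)
    stop("target identity must be in (0, 100]", call. = FALSE)
  if (indel_rate < 0 || indel_rate > 0.2)
    stop("indel rate must be in [0, 0.2]", call. = FALSE)
  if (length(motif_positions) &&
      any(motif_positions < 1L | motif_positions > root_length))
    stop("motif positions outside root length", call. = FALSE)
  if (target_identity == 100 && indel_rate > 0)
    stop("target identity 100 is unreachable with a nonzero indel rate",
         call. = FALSE)
  if (!is.null(motif_residues))
    motif_residues <- rep_len(toupper(motif_residues),
                              length(motif_positions))
  structure(list(root_length = as.integer(root_length),
                 n_orthologs = as.integer(n_orthologs),
                 target_identity = target_identity,
                 motif_positions = as.integer(motif_positions),
                 motif_residues = motif_residues,
                 equivalent_sets = equivalent_sets,
                 equivalence_prob = equivalence_prob,
                 indel_rate = indel_rate, seed = as.integer(seed)),
            class = "family_spec")
}

#' Generate a synthetic ortholog family with known ground truth
#'
#' The root is drawn from the background composition with the motif
#' residues planted. Each ortholog substitutes a fixed number of non-motif
#' sites (chosen so the expected identity to the root equals the target),
#' each substituted site drawing a *different* residue from the
#' BLOSUM62-conditional distribution; motif sites stay identical or, with
#' `equivalence_prob`, switch to an allowed equivalent. Indel events
#' (insertion or deletion, geometric length, p = 0.5) are placed uniformly
#' outside motif positions, and the emitted true alignment records the
#' resulting gap structure with the root as coordinate master.
#'
#' @param spec a [family_spec].
#' @return list with `sequences` (root first, then orthologs),
#'   `true_alignment` (an [alignment]), `motif` (the root's
#'   [functional_residue_set]), and `motif_positions` (list per sequence of
#'   the motif's 1-based de-gapped positions, NA where deleted).
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(spec$seed, {
    L <- spec$root_length
    root_letters <- sample(AA_STANDARD, L, replace = TRUE,
                           prob = AA_BACKGROUND)
    mp <- spec$motif_positions
    if (length(mp)) {
      mres <- spec$motif_residues
      if (is.null(mres)) mres <- root_letters[mp]
      root_letters[mp] <- mres
    }
    root <- protein_sequence("root", paste(root_letters, collapse = ""))

    cond <- substitution_conditionals()
    ## per-site probability of an identical residue after one substitution
    ## event is 0 (substituted sites always change), so the number of
    ## substituted sites directly sets the identity to the root
    mutable <- setdiff(seq_len(L), mp)
    n_sub <- round((1 - spec$target_identity / 100) * L)
    n_sub <- min(n_sub, length(mutable))

    seqs <- list(root)
    rows <- list(root = list(letters = root_letters,
                             insert_after = vector("list", L + 1L)))
    motif_truth <- list(root = mp)

    for (o in seq_len(spec$n_orthologs)) {
      letters <- root_letters
      sub_sites <- sample(mutable, n_sub)
      for (s in sub_sites) {
        a <- letters[s]
        p <- cond[a, ]; p[a] <- 0
        letters[s] <- sample(AA_STANDARD, 1L, prob = p)
      }
      if (length(mp) && spec$equivalence_prob > 0) {
        for (i in seq_along(mp)) {
          a <- root_letters[mp[i]]
          equi <- spec$equivalent_sets[[a]]
          if (!is.null(equi) && stats::runif(1) < spec$equivalence_prob)
            letters[mp[i]] <- sample(c(equi), 1L)
        }
      }
      ## indel events: deletion removes root-aligned sites, insertion adds
      ## residues after a root position
      present <- rep(TRUE, L)
      insert_after <- vector("list", L + 1L)
      n_events <- stats::rbinom(1L, L, spec$indel_rate)
      if (n_events > 0) {
        for (e in seq_len(n_events)) {
          len <- stats::rgeom(1L, 0.5) + 1L
          if (stats::runif(1) < 0.5) { # deletion
            anchors <- setdiff(which(present), mp)
            if (!length(anchors)) next
            at <- sample(anchors, 1L)
            ## motif sites are never deleted
            rng <- at:min(L, at + len - 1L)
            present[setdiff(rng, mp)] <- FALSE
          } else { # insertion
            at <- sample(0:L, 1L)
            ins <- sample(AA_STANDARD, len, replace = TRUE,
                          prob = AA_BACKGROUND)
            insert_after[[at + 1L]] <- c(insert_after[[at + 1L]], ins)
          }
        }
      }
      letters[!present] <- NA
      rows[[sprintf("orth%02d", o)]] <-
        list(letters = ifelse(is.na(letters), "-", letters),
             insert_after = insert_after)
    }

    ## assemble the true alignment on the root coordinate system
    ids <- names(rows)
    gapped <- stats::setNames(vector("list", length(ids)), ids)
    for (id in ids) gapped[[id]] <- character(0)
    emit <- function(col_letters) {
      for (id in ids) gapped[[id]] <<- c(gapped[[id]], col_letters[[id]])
    }
    for (pos in 0:L) {
      if (pos > 0) {
        emit(lapply(rows, function(r) r$letters[pos]))
      }
      for (id in ids) {
        ins <- rows[[id]]$insert_after[[pos + 1L]]
        if (length(ins)) {
          for (ch in ins) {
            col <- stats::setNames(as.list(rep("-", length(ids))), ids)
            col[[id]] <- ch
            emit(col)
          }
        }
      }
    }
    truth <- alignment(ids, vapply(gapped, paste, character(1), collapse = ""))
    seqs <- lapply(ids, alignment_row, aln = truth)
    names(seqs) <- ids

    ## per-sequence motif positions from the true alignment
    A <- alignment_matrix(truth)
    root_cols <- which(A[1, ] != "-")
    motif_cols <- root_cols[mp]
    motif_pos <- lapply(seq_along(ids), function(i) {
      degap <- cumsum(A[i, ] != "-")
      p <- ifelse(A[i, motif_cols] == "-", NA_integer_, degap[motif_cols])
      as.integer(p)
    })
    names(motif_pos) <- ids

    motif <- if (length(mp))
      functional_residue_set(seqs$root, mp, root_letters[mp], "planted")
    else NULL
    list(sequences = seqs, true_alignment = truth, motif = motif,
         motif_positions = motif_pos)
  })
}

#' Shuffle a sequence into a composition-preserving decoy
#'
#' Seeded Fisher-Yates permutation of the residues; the residue multiset is
#' exactly preserved.
#'
#' @param seq a [protein_sequence] of length >= 2.
#' @param seed integer seed.
#' @return a [protein_sequence] with id suffixed `_shuf`.
#' @export
shuffle_decoy <- function(seq, seed = 1L) {
  stopifnot(inherits(seq, "protein_sequence"), nchar(seq$residues) >= 2L)
  with_seed(seed, {
    letters <- seq_letters(seq)
    protein_sequence(paste0(seq$id, "_shuf"),
                     paste(sample(letters), collapse = ""),
                     seq$description)
  })
}

#' Generate an ideal alpha-helix bundle C-alpha structure
#'
#' Helices use ideal C-alpha geometry (rise 1.5 A per residue, radius
#' 2.3 A, 100 degrees per residue); successive helices run antiparallel and
#' are offset laterally by `spacing`. Consecutive C-alpha distances within
#' a helix are 3.8 +/- 0.1 A.
#'
#' @param n_helices number of helices (>= 1).
#' @param residues_per_helix residues in each helix.
#' @param spacing lateral offset between adjacent helix axes (A).
#' @param id structure identifier.
#' @param seed seed for the (arbitrary) residue letters.
#' @return a [calpha_structure] of `n_helices * residues_per_helix`
#'   residues numbered consecutively.
#' @export
generate_helix_bundle <- function(n_helices = 4L, residues_per_helix = 15L,
                                  spacing = 10, id = "bundle", seed = 1L) {
  stopifnot(n_helices >= 1L, residues_per_helix >= 1L)
  rise <- 1.5; radius <- 2.3; turn <- 100 * pi / 180
  xyz <- NULL
  for (h in seq_len(n_helices)) {
    t <- seq_len(residues_per_helix) - 1L
    z <- t * rise
    if (h %% 2L == 0L) z <- max(z) - z # antiparallel
    helix <- cbind(x = (h - 1L) * spacing + radius * cos(t * turn),
                   y = radius * sin(t * turn),
                   z = z)
    xyz <- rbind(xyz, helix)
  }
  n <- nrow(xyz)
  letters <- with_seed(seed,
                       sample(AA_STANDARD, n, replace = TRUE,
                              prob = AA_BACKGROUND))
  calpha_structure(id, "A", seq_len(n), letters, xyz)
}

#' Specification for a structure perturbation
#'
#' @param sigma per-coordinate Gaussian noise standard deviation (A, >= 0).
#' @param loops list of `c(after_residue, length)` pairs describing loop
#'   insertions (random-walk coordinates, 3.8 A steps).
#' @param seed integer seed controlling the rigid transform, the noise and
#'   the loop geometry.
#' @return an object of class `structure_perturb_spec`.
#' @export
structure_perturb_spec <- function(sigma = 0.5, loops = list(), seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  for (l in loops)
    if (length(l) != 2L || l[2] < 0)
      stop("each loop must be c(after_residue, length) with length >= 0",
           call. = FALSE)
  structure(list(sigma = sigma, loops = loops, seed = as.integer(seed)),
            class = "structure_perturb_spec")
}

#' Perturb a C-alpha structure with known ground truth
#'
#' Applies a seeded random rigid rotation and translation, adds iid
#' Gaussian noise (`sigma` per coordinate) to every C-alpha, and inserts
#' loop residues as 3.8 A random walks. The returned correspondence lists
#' original/perturbed residue-number pairs, excluding inserted loops.
#'
#' @param s a [calpha_structure].
#' @param spec a [structure_perturb_spec].
#' @return list with `structure` (the perturbed [calpha_structure],
#'   renumbered 1..N+loops), `correspondence` (two-column matrix
#'   `resno_a`, `resno_b`), `rotation`, `translation`.
#' @export
perturb_structure <- function(s, spec) {
  stopifnot(inherits(s, "calpha_structure"),
            inherits(spec, "structure_perturb_spec"))
  with_seed(spec$seed, {
    R <- random_rotation()
    t <- stats::runif(3, -20, 20)
    xyz <- s$xyz %*% t(R) + matrix(t, nrow(s$xyz), 3, byrow = TRUE)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, spec$sigma),
                        nrow(xyz), 3)
    letters <- s$resletter
    orig_no <- s$resno
    is_loop <- rep(FALSE, nrow(xyz))
    ## insert loops (walk from the preceding residue, or the first)
    for (l in spec$loops) {
      after <- l[1]; len <- l[2]
      if (len == 0) next
      anchor_idx <- which(orig_no == after & !is_loop)
      if (!length(anchor_idx)) next
      anchor_idx <- anchor_idx[1]
      walk <- matrix(0, len, 3)
      prev <- xyz[anchor_idx, ]
      for (k in seq_len(len)) {
        step <- stats::rnorm(3)
        step <- 3.8 * step / sqrt(sum(step^2))
        prev <- prev + step
        walk[k, ] <- prev
      }
      ins_at <- anchor_idx
      xyz <- rbind(xyz[seq_len(ins_at), , drop = FALSE], walk,
                   xyz[-seq_len(ins_at), , drop = FALSE])
      letters <- c(letters[seq_len(ins_at)],
                   sample(AA_STANDARD, len, replace = TRUE,
                          prob = AA_BACKGROUND),
                   letters[-seq_len(ins_at)])
      orig_no <- c(orig_no[seq_len(ins_at)], rep(NA_integer_, len),
                   orig_no[-seq_len(ins_at)])
      is_loop <- c(is_loop[seq_len(ins_at)], rep(TRUE, len),
                   is_loop[-seq_len(ins_at)])
    }
    new_no <- seq_len(nrow(xyz))
    out <- calpha_structure(paste0(s$id, "_pert"), s$chain, new_no, letters,
                            xyz)
    corr <- cbind(resno_a = orig_no[!is_loop], resno_b = new_no[!is_loop])
    list(structure = out, correspondence = corr, rotation = R,
         translation = t)
  })
}

## Uniform random rotation matrix (quaternion method)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
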