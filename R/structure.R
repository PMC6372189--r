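#' Optimal rigid superposition of paired C-alpha atoms (Kabsch)
#'
#' Closed-form least-squares fit via singular value decomposition with the
#' determinant correction that excludes reflections. The returned transform
#' maps structure `B` onto structure `A`:
#' `B_fit = B %*% t(rotation) + translation`. RMSD and TM-score are
#' computed on the transformed pairs; the TM-score is normalized by
#' `l_target` (default: the length of `A`, the reference).
#'
#' @param A,B [calpha_structure] objects.
#' @param pairs two-column matrix of paired residue numbers
#'   (`resno` in A, `resno` in B); at least 3 non-collinear pairs.
#' @param l_target normalization length for the TM-score.
#' @return an object of class `superposition_result`: `rotation` (3x3,
#'   det +1), `translation`, `rmsd` (A), `n_pairs`, `tm_score`,
#'   `correspondence`.
#' @export
kabsch_superpose <- function(A, B, pairs, l_target = length(A)) {
  stopifnot(inherits(A, "calpha_structure"), inherits(B, "calpha_structure"))
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 3L)
    stop("at least 3 residue pairs are required", call. = FALSE)
  ia <- match(pairs[, 1], A$resno)
  ib <- match(pairs[, 2], B$resno)
  if (anyNA(ia) || anyNA(ib))
    stop("pair refers to a residue number absent from a structure",
         call. = FALSE)
  Pa <- A$xyz[ia, , drop = FALSE]
  Pb <- B$xyz[ib, , drop = FALSE]
  ca <- colMeans(Pa); cb <- colMeans(Pb)
  Ac <- sweep(Pa, 2, ca); Bc <- sweep(Pb, 2, cb)
  if (svd(Ac)$d[2] < 1e-8 || svd(Bc)$d[2] < 1e-8)
    stop("degenerate (collinear) point configuration", call. = FALSE)
  H <- t(Bc) %*% Ac
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  tr <- ca - as.vector(R %*% cb)
  Bfit <- Pb %*% t(R) + matrix(tr, nrow(Pb), 3, byrow = TRUE)
  dists <- sqrt(rowSums((Bfit - Pa)^2))
  structure(list(rotation = R, translation = tr,
                 rmsd = sqrt(mean(dists^2)), n_pairs = nrow(pairs),
                 tm_score = tm_score(dists, l_target),
                 correspondence = pairs, distances = dists),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition> RMSD %.3f A over %d residues, TM-score %.3f\n",
              x$rmsd, x$n_pairs, x$tm_score))
  invisible(x)
}

## apply a superposition's rigid transform to an n x 3 coordinate matrix
transform_coords <- function(xyz, sup) {
  xyz %*% t(sup$rotation) + matrix(sup$translation, nrow(xyz), 3,
                                   byrow = TRUE)
}

#' TM-score from post-superposition pair distances
#'
#' `TM = (1/L) * sum_i 1 / (1 + (d_i/d0)^2)` with
#' `d0 = 1.24 * (L - 15)^(1/3) - 1.8`, clamped below at 0.5, where `L` is
#' the normalization (target) length.
#'
#' @param distances numeric vector of paired C-alpha distances (A).
#' @param l_target normalization length (>= 1).
#' @return TM-score in `(0, 1]`.
#' @export
tm_score <- function(distances, l_target) {
  stopifnot(l_target >= 1)
  d0 <- max(0.5, 1.24 * max(l_target - 15, 0)^(1 / 3) - 1.8)
  sum(1 / (1 + (distances / d0)^2)) / l_target
}

#' Structure-based alignment of two C-alpha structures
#'
#' Iterative superposition refinement: the correspondence is initialized
#' either from a global sequence alignment of the residue strings
#' (`seed = "sequence"`) or from the best gapless 20-residue fragment
#' superposition (`seed = "fragments"`), then alternates between Kabsch
#' superposition on the current pairs and rebuilding the pairs as the
#' order-preserving matching of residues within 8 A, found by dynamic
#' programming on the superposed distance matrix with per-cell score
#' `1 / (1 + (d/d0)^2)`. Stops when the RMSD changes by less than 0.01 A
#' or after 50 iterations.
#'
#' @param A,B [calpha_structure] objects with at least 10 residues.
#' @param seed `"sequence"` or `"fragments"`.
#' @param matrix substitution matrix for the sequence seed.
#' @param max_iter,tol iteration cap and RMSD convergence tolerance.
#' @return list with `correspondence` (residue-number pairs) and
#'   `superposition` (a `superposition_result`).
#' @export
structure_align <- function(A, B, seed = c("sequence", "fragments"),
                            matrix = substitution_matrix(),
                            max_iter = 50L, tol = 0.01) {
  seed <- match.arg(seed)
  stopifnot(length(A) >= 10L, length(B) >= 10L)
  d0 <- max(0.5, 1.24 * max(length(A) - 15, 0)^(1 / 3) - 1.8)

  pairs <- if (seed == "sequence") seed_pairs_sequence(A, B, matrix)
           else seed_pairs_fragments(A, B)
  if (is.null(pairs) || nrow(pairs) < 3L)
    stop("structure alignment failed: no initial correspondence with >= 3 pairs",
         call. = FALSE)
  last_rmsd <- Inf
  sup <- NULL
  for (it in seq_len(max_iter)) {
    sup <- kabsch_superpose(A, B, pairs)
    Bt <- transform_coords(B$xyz, sup)
    D <- outer(rowSums(A$xyz^2), rep(1, nrow(Bt))) +
      outer(rep(1, nrow(A$xyz)), rowSums(Bt^2)) - 2 * A$xyz %*% t(Bt)
    D <- sqrt(pmax(D, 0))
    S <- 1 / (1 + (D / d0)^2)
    S[D > 8] <- 0
    res <- .dp_align(S, 0, 0, 1L) # order-preserving, free gaps
    m <- res$row_index > 0L & res$col_index > 0L
    keep <- m & D[cbind(pmax(res$row_index, 1L), pmax(res$col_index, 1L))] <= 8
    new_pairs <- cbind(A$resno[res$row_index[keep]],
                       B$resno[res$col_index[keep]])
    if (nrow(new_pairs) < 3L)
      stop("structure alignment failed: correspondence collapsed below 3 pairs",
           call. = FALSE)
    pairs <- new_pairs
    if (abs(last_rmsd - sup$rmsd) < tol) break
    last_rmsd <- sup$rmsd
  }
  sup <- kabsch_superpose(A, B, pairs)
  colnames(pairs) <- c("resno_a", "resno_b")
  list(correspondence = pairs, superposition = sup)
}

seed_pairs_sequence <- function(A, B, matrix) {
  sa <- protein_sequence("a", paste(A$resletter, collapse = ""))
  sb <- protein_sequence("b", paste(B$resletter, collapse = ""))
  ps <- pairwise_stats(sa, sb, matrix, mode = "global")
  M <- alignment_matrix(ps$alignment)
  ia <- cumsum(M[1, ] != "-"); ib <- cumsum(M[2, ] != "-")
  both <- M[1, ] != "-" & M[2, ] != "-"
  cbind(A$resno[ia[both]], B$resno[ib[both]])
}

seed_pairs_fragments <- function(A, B, window = 20L, stride = 4L) {
  na <- length(A); nb <- length(B)
  w <- min(window, na, nb)
  best <- NULL; best_rmsd <- Inf
  for (i in seq(1L, na - w + 1L, by = stride)) {
    for (j in seq(1L, nb - w + 1L, by = stride)) {
      pr <- cbind(A$resno[i:(i + w - 1L)], B$resno[j:(j + w - 1L)])
      sup <- try(kabsch_superpose(A, B, pr), silent = TRUE)
      if (inherits(sup, "try-error")) next
      if (sup$rmsd < best_rmsd) { best_rmsd <- sup$rmsd; best <- pr }
    }
  }
  best
}

#' Sequence identity and similarity over a structural correspondence
#'
#' @param A,B [calpha_structure] objects.
#' @param correspondence two-column matrix of paired residue numbers.
#' @param matrix a [substitution_matrix] for the positive-substitution
#'   similarity criterion.
#' @return list with `identity` and `similarity` (percent of pairs).
#' @export
structure_based_identity <- function(A, B, correspondence,
                                     matrix = substitution_matrix()) {
  correspondence <- as.matrix(correspondence)
  stopifnot(nrow(correspondence) >= 1L)
  la <- A$resletter[match(correspondence[, 1], A$resno)]
  lb <- B$resletter[match(correspondence[, 2], B$resno)]
  ident <- la == lb
  pos <- ident | matrix[cbind(la, lb)] > 0
  list(identity = 100 * mean(ident), similarity = 100 * mean(pos))
}
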