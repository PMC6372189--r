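#' Build a position-specific scoring matrix from an alignment
#'
#' Observed per-column residue frequencies are computed with Henikoff
#' position-based sequence weights, mixed with substitution-matrix-derived
#' pseudocount frequencies at weight `beta / (Neff + beta)` (`Neff` = mean
#' number of distinct residues per kept column), and converted to log-odds:
#' `score(col, a) = log2(f_mixed(col, a) / background(a))` in bits.
#' Columns with more than `max_gap_frac` gaps are dropped from the profile
#' (reported via a message). Zero mixed frequencies are floored at 1e-9 so
#' scores stay finite.
#'
#' Selenocysteine (U) is pooled with cysteine for counting and scoring; a
#' target X scores a flat -1 at every column.
#'
#' @param aln an [alignment]; the first row is taken as the query row for
#'   coverage bookkeeping.
#' @param matrix a [substitution_matrix] supplying the pseudocount model.
#' @param beta pseudocount weight (>= 0).
#' @param background named numeric vector of background frequencies over
#'   the 20 standard letters (default: Robinson-Robinson).
#' @param max_gap_frac columns whose gap fraction exceeds this are dropped.
#' @return an object of class `pssm`: fields `scores` (L x 22, bits),
#'   `background`, `beta`, `neff`, `aln_columns` (profile column ->
#'   alignment column), `query_positions` (profile column -> 1-based query
#'   residue position or NA), `query_length`, `ref_letters` (query letter,
#'   or column consensus where the query is gapped), `consensus`,
#'   `source_id`.
#' @export
build_pssm <- function(aln, matrix = substitution_matrix(), beta = 10,
                       background = AA_BACKGROUND, max_gap_frac = 0.5) {
  stopifnot(inherits(aln, "alignment"), beta >= 0)
  background <- background[AA_STANDARD] / sum(background[AA_STANDARD])
  if (abs(sum(background) - 1) > 1e-9)
    stop("background frequencies must sum to 1", call. = FALSE)
  A <- alignment_matrix(aln)
  A[A == "U"] <- "C" # selenocysteine pooled with cysteine
  n <- nrow(A); C <- ncol(A)
  gap_frac <- colMeans(A == "-")
  if (all(gap_frac == 1)) stop("all-gap alignment", call. = FALSE)
  keep <- which(gap_frac <= max_gap_frac)
  if (length(keep) < C)
    message(sprintf("build_pssm: dropped %d column(s) with > %d%% gaps",
                    C - length(keep), round(100 * max_gap_frac)))

  ## Henikoff position-based weights over the full alignment
  w <- rep(0, n)
  for (cc in seq_len(C)) {
    col <- A[, cc]
    obs <- col[col != "-" & col != "X"]
    if (!length(obs)) next
    counts <- table(obs)
    r <- length(counts)
    contrib <- 1 / (r * as.numeric(counts[col]))
    contrib[is.na(contrib)] <- 0
    w <- w + contrib
  }
  if (sum(w) == 0) w <- rep(1, n)
  w <- w / sum(w)

  cond <- substitution_conditionals(matrix) # P(b | a), 20 x 20
  L <- length(keep)
  fobs <- matrix(0, L, 20L, dimnames = list(NULL, AA_STANDARD))
  ndistinct <- numeric(L)
  for (k in seq_len(L)) {
    col <- A[, keep[k]]
    sel <- col != "-" & col != "X"
    if (any(sel)) {
      ws <- w[sel]
      f <- tapply(ws, factor(col[sel], levels = AA_STANDARD), sum)
      f[is.na(f)] <- 0
      fobs[k, ] <- f / sum(f)
      ndistinct[k] <- length(unique(col[sel]))
    } else {
      fobs[k, ] <- background
      ndistinct[k] <- 1
    }
  }
  neff <- mean(ndistinct)
  g <- fobs %*% cond # pseudocount frequencies
  fmix <- (neff * fobs + beta * g) / (neff + beta)
  fmix <- pmax(fmix, 1e-9)
  scores <- log2(sweep(fmix, 2, background, "/"))

  full <- matrix(-1, L, 22L, dimnames = list(NULL, AA_ALPHABET))
  full[, AA_STANDARD] <- scores
  full[, "U"] <- scores[, "C"]

  ## query-row bookkeeping (first alignment row)
  qrow <- strsplit(aln$gapped[1], "", fixed = TRUE)[[1]]
  qpos_all <- cumsum(qrow != "-")
  qpos_all[qrow == "-"] <- NA
  consensus <- AA_STANDARD[apply(fobs, 1, which.max)]
  ref_letters <- qrow[keep]
  ref_letters[ref_letters == "-"] <- consensus[ref_letters == "-"]

  structure(list(scores = full, background = background, beta = beta,
                 neff = neff, aln_columns = keep,
                 query_positions = qpos_all[keep],
                 query_length = sum(qrow != "-"),
                 ref_letters = ref_letters, consensus = consensus,
                 source_id = aln$ids[1], n_rows = n),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm> %d columns from '%s' (%d rows, beta=%.3g, Neff=%.2f)\n",
              nrow(x$scores), x$source_id, x$n_rows, x$beta, x$neff))
  invisible(x)
}

#' Number of columns of a PSSM
#' @param x a `pssm`.
#' @export
length.pssm <- function(x) nrow(x$scores)
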