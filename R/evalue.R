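#' Calibrate an empirical E-value model for a profile
#'
#' Scores the profile against shuffled database sequences and fits a Gumbel
#' (extreme-value) distribution to the raw local-alignment scores by
#' maximum likelihood. With location `mu` and scale `b`, the
#' Karlin-Altschul parameters are `lambda = 1/b` and
#' `K = exp(mu/b) / (m * nbar)` (`m` = profile length, `nbar` = mean
#' shuffled sequence length), giving `E(S) = K * m * n * exp(-lambda * S)`
#' for a database of `n` residues.
#'
#' @param profile a [pssm].
#' @param database list of [protein_sequence] objects used as the shuffle
#'   pool.
#' @param n_shuffles number of shuffled sequences scored (>= 50).
#' @param seed integer seed for the shuffles.
#' @param gap_open,gap_extend affine gap penalties passed to the aligner.
#' @return an object of class `evalue_calibration` with fields `lambda`,
#'   `K`, `n_shuffles`, `n` (database letter count), `m` (profile length),
#'   and `scores` (the null score sample).
#' @export
calibrate_evalue <- function(profile, database, n_shuffles = 200, seed = 1,
                             gap_open = 11, gap_extend = 1) {
  stopifnot(inherits(profile, "pssm"), length(database) >= 1L,
            n_shuffles >= 50L)
  idx <- rep_len(seq_along(database), n_shuffles)
  scores <- numeric(n_shuffles)
  lens <- numeric(n_shuffles)
  for (k in seq_len(n_shuffles)) {
    dec <- shuffle_decoy(database[[idx[k]]], seed = child_seed(seed, k))
    lens[k] <- nchar(dec$residues)
    scores[k] <- local_align_profile(profile, dec, gap_open, gap_extend)$score
  }
  if (stats::sd(scores) < 1e-9)
    stop("degenerate null score sample (zero variance); cannot calibrate",
         call. = FALSE)
  fit <- fit_gumbel(scores)
  m <- nrow(profile$scores)
  nbar <- mean(lens)
  K <- exp(fit$mu / fit$b) / (m * nbar)
  n_db <- sum(vapply(database, function(s) nchar(s$residues), numeric(1)))
  structure(list(lambda = 1 / fit$b, K = K, n_shuffles = n_shuffles,
                 n = n_db, m = m, scores = scores),
            class = "evalue_calibration")
}

#' @export
print.evalue_calibration <- function(x, ...) {
  cat(sprintf("<evalue_calibration> lambda=%.4f K=%.4g (m=%d, n=%d, %d shuffles)\n",
              x$lambda, x$K, x$m, x$n, x$n_shuffles))
  invisible(x)
}

## Maximum-likelihood Gumbel fit (location mu, scale b) via Nelder-Mead
## from moment starting values.
fit_gumbel <- function(x) {
  b0 <- stats::sd(x) * sqrt(6) / pi
  mu0 <- mean(x) - 0.5772156649 * b0
  nll <- function(par) {
    b <- exp(par[2])
    z <- (x - par[1]) / b
    length(x) * log(b) + sum(z) + sum(exp(-z))
  }
  opt <- stats::optim(c(mu0, log(b0)), nll, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  list(mu = opt$par[1], b = exp(opt$par[2]))
}

#' E-value of a raw score under a calibration
#'
#' @param calibration an `evalue_calibration`.
#' @param score raw alignment score(s).
#' @param n database letter count (defaults to the calibrated database).
#' @return numeric E-value(s).
#' @export
evalue <- function(calibration, score, n = calibration$n) {
  stopifnot(inherits(calibration, "evalue_calibration"))
  calibration$K * calibration$m * n * exp(-calibration$lambda * score)
}

#' Bit score of a raw score under a calibration
#'
#' `bits = (lambda * S - ln K) / ln 2`, the conventional normalized score.
#'
#' @inheritParams evalue
#' @return numeric bit score(s).
#' @export
bit_score <- function(calibration, score) {
  (calibration$lambda * score - log(calibration$K)) / log(2)
}
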