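#' Substitution matrix over the package alphabet
#'
#' Returns the named scoring matrix (half-bit integer scores) extended to
#' the 22-letter alphabet: selenocysteine (U) scores as cysteine, and X
#' takes the matrix's own X column. The base 20x20 scores come from the
#' matrices shipped with Biostrings.
#'
#' @param name matrix name; currently `"BLOSUM62"`.
#' @return an object of class `substitution_matrix`: a symmetric integer
#'   matrix with a `name` attribute.
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  name <- match.arg(name, c("BLOSUM62"))
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  base <- env[[name]]
  m <- matrix(0L, 22L, 22L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  std <- AA_STANDARD
  m[std, std] <- base[std, std]
  m["U", std] <- base["C", std]; m[std, "U"] <- base[std, "C"]
  m["U", "U"] <- base["C", "C"]
  m["X", std] <- base["X", std]; m[std, "X"] <- base[std, "X"]
  m["X", "X"] <- base["X", "X"]
  m["X", "U"] <- base["X", "C"]; m["U", "X"] <- base["C", "X"]
  structure(m, name = name, class = c("substitution_matrix", class(m)))
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat(sprintf("<substitution_matrix> %s (%dx%d, half-bit integers)\n",
              attr(x, "name"), nrow(x), ncol(x)))
  invisible(x)
}

## Conditional substitution probabilities P(b | a) implied by a half-bit
## log-odds matrix under the standard background: P(b|a) ~ p_b * 2^(s_ab/2).
## Used for pseudocounts in PSSM construction and for the mutation model of
## the family generator.
substitution_conditionals <- function(matrix = substitution_matrix()) {
  std <- AA_STANDARD
  s <- matrix[std, std]
  p <- AA_BACKGROUND[std]
  cond <- sweep(2^(s / 2), 2, p, "*")
  cond / rowSums(cond)
}

## Evaluate RNG-dependent code under a seed without disturbing the caller's
## RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

## Deterministic child seed derivation (single global seed per run; every
## sub-generator derives its own stream).
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 1103 * k) %% 2147483647)
}
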