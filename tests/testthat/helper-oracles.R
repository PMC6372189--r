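## Independent oracles and fixture builders used across the suite.

## Exhaustive best local alignment score by enumeration of matched-pair
## chains. Any local alignment with affine gaps is determined by its
## strictly increasing chain of matched cells; the gap between consecutive
## matches of sizes (di, dj) costs open + d*ext per non-empty run. This
## enumerates every chain (sum_k C(L,k) * C(M,k) of them), so it is
## tractable only for dimensions <= 8 - which is the point: it shares no
## code or recurrence with the DP under test.
oracle_local_score <- function(S, gap_open, gap_extend) {
  L <- nrow(S); M <- ncol(S)
  gapcost <- function(d) sum(ifelse(d > 0, gap_open + d * gap_extend, 0))
  best <- 0
  for (k in seq_len(min(L, M))) {
    rows <- utils::combn(L, k)
    cols <- utils::combn(M, k)
    for (a in seq_len(ncol(rows))) {
      r <- rows[, a]
      gr <- gapcost(diff(r) - 1L)
      for (b in seq_len(ncol(cols))) {
        cc <- cols[, b]
        sc <- sum(S[cbind(r, cc)]) - gr - gapcost(diff(cc) - 1L)
        if (sc > best) best <- sc
      }
    }
  }
  best
}

## score a traceback path independently (validates path consistency)
path_score <- function(S, ri, ci, gap_open, gap_extend, local = TRUE) {
  if (!length(ri)) return(0)
  sc <- 0
  in_x <- FALSE; in_y <- FALSE
  for (k in seq_along(ri)) {
    if (ri[k] > 0L && ci[k] > 0L) {
      sc <- sc + S[ri[k], ci[k]]
      in_x <- in_y <- FALSE
    } else if (ri[k] > 0L) {
      sc <- sc - (if (in_x) gap_extend else gap_open + gap_extend)
      in_x <- TRUE; in_y <- FALSE
    } else {
      sc <- sc - (if (in_y) gap_extend else gap_open + gap_extend)
      in_y <- TRUE; in_x <- FALSE
    }
  }
  sc
}

## 10-degree Euler-angle rotation grid, rows = flattened (column-major)
## rotation matrices. Built once per test run.
euler_grid <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    step <- 10 * pi / 180
    alpha <- seq(0, 2 * pi - step, by = step)
    beta <- seq(0, pi, by = step)
    gamma <- alpha
    rots <- matrix(0, length(alpha) * length(beta) * length(gamma), 9L)
    r <- 1L
    for (a in alpha) for (b in beta) for (g in gamma) {
      Rz1 <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
      Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
      Rz2 <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3)
      rots[r, ] <- as.vector(Rz1 %*% Ry %*% Rz2)
      r <- r + 1L
    }
    cache <<- rots
    rots
  }
})

## min RMSD over the rotation grid after centroid matching:
## rmsd^2(R) = (ss_a + ss_b - 2 tr(R M)) / n with M = t(Bc) %*% Ac
grid_min_rmsd <- function(Pa, Pb) {
  n <- nrow(Pa)
  Ac <- sweep(Pa, 2, colMeans(Pa))
  Bc <- sweep(Pb, 2, colMeans(Pb))
  M <- t(Bc) %*% Ac
  tr <- euler_grid() %*% as.vector(t(M))
  sq <- (sum(Ac^2) + sum(Bc^2) - 2 * tr) / n
  sqrt(max(0, min(sq)))
}

## self-avoiding-ish random walk C-alpha chain, 3.8 A steps
random_structure <- function(n, seed, id = "rand") {
  set.seed(seed)
  xyz <- matrix(0, n, 3)
  for (i in 2:n) {
    step <- rnorm(3)
    xyz[i, ] <- xyz[i - 1, ] + 3.8 * step / sqrt(sum(step^2))
  }
  letters <- sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                      "K", "M", "F", "P", "S", "T", "W", "Y", "V"), n, TRUE)
  calpha_structure(id, "A", seq_len(n), letters, xyz)
}

## standard planted-family fixture used by several tests
make_test_family <- function(seed = 11, n_orthologs = 5,
                             target_identity = 30, root_length = 200,
                             motif = c(20, 55, 90, 120, 150, 170, 190),
                             indel_rate = 0.02, equivalence_prob = 0) {
  generate_family(family_spec(
    root_length = root_length, n_orthologs = n_orthologs,
    target_identity = target_identity, motif_positions = motif,
    indel_rate = indel_rate, equivalence_prob = equivalence_prob,
    seed = seed))
}

make_decoys <- function(template, n = 50, seed0 = 1000) {
  lapply(seq_len(n), function(i) {
    d <- shuffle_decoy(template, seed = seed0 + i)
    d$id <- sprintf("decoy%02d", i)
    d
  })
}

## identity of each non-root row to the root, computed from a true
## alignment (columns where both rows are residues)
alignment_identities_to_root <- function(truth) {
  A <- do.call(rbind, strsplit(truth$gapped, "", fixed = TRUE))
  vapply(2:nrow(A), function(i) {
    both <- A[1, ] != "-" & A[i, ] != "-"
    100 * mean(A[1, both] == A[i, both])
  }, numeric(1))
}

## for each residue of the cand_row, the root-row position it aligns to
## (NA where the candidate sits in an insertion column)
residue_to_root_map <- function(M, root_row, cand_row) {
  rootpos <- cumsum(M[root_row, ] != "-")
  cand_cols <- which(M[cand_row, ] != "-")
  ifelse(M[root_row, cand_cols] == "-", NA_integer_, rootpos[cand_cols])
}

## two-residue-per-line toy PDB writer for io tests
write_toy_pdb_lines <- function(path, lines) {
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, resname, chain, resno, x, y, z,
                          atom = " CA ", alt = " ") {
  sprintf("ATOM  %5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, atom, alt, resname, chain, resno, x, y, z)
}
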