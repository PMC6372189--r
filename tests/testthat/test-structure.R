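test_that("Kabsch superposition is exact on rigid copies", {
  s <- random_structure(30, seed = 1)
  self <- kabsch_superpose(s, s, cbind(s$resno, s$resno))
  expect_lt(self$rmsd, 1e-9)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)
  expect_equal(self$tm_score, 1.0, tolerance = 1e-9)

  pert <- perturb_structure(s, structure_perturb_spec(sigma = 0, seed = 3))
  sup <- kabsch_superpose(s, pert$structure, pert$correspondence)
  expect_lt(sup$rmsd, 1e-6)
  ## orthonormal, det +1
  expect_lt(max(abs(t(sup$rotation) %*% sup$rotation - diag(3))), 1e-8)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
})

test_that("Kabsch rejects degenerate inputs", {
  s <- random_structure(10, seed = 2)
  expect_error(kabsch_superpose(s, s, cbind(1:2, 1:2)), "3")
  line <- calpha_structure("line", "A", 1:5, rep("A", 5),
                           cbind(seq(0, 15.2, 3.8), 0, 0))
  expect_error(kabsch_superpose(line, line, cbind(1:5, 1:5)), "collinear")
})

test_that("Kabsch beats a 10-degree rotation grid on random instances", {
  set.seed(7)
  for (k in 1:100) {
    n <- sample(6:12, 1)
    A <- random_structure(n, seed = 1000 + k, id = "a")
    B <- random_structure(n, seed = 2000 + k, id = "b")
    sup <- kabsch_superpose(A, B, cbind(A$resno, B$resno))
    grid <- grid_min_rmsd(A$xyz, B$xyz)
    expect_lte(sup$rmsd, grid + 1e-3,
               label = sprintf("instance %d", k))
  }
})

test_that("Kabsch agrees with the bio3d fitting routine", {
  for (k in 1:5) {
    A <- random_structure(25, seed = 300 + k, id = "a")
    B <- random_structure(25, seed = 400 + k, id = "b")
    sup <- kabsch_superpose(A, B, cbind(A$resno, B$resno))
    fit <- suppressWarnings(
      bio3d::fit.xyz(as.vector(t(A$xyz)), as.vector(t(B$xyz))))
    ref_rmsd <- sqrt(mean(rowSums(
      (matrix(fit, ncol = 3, byrow = TRUE) - A$xyz)^2)))
    expect_equal(sup$rmsd, ref_rmsd, tolerance = 1e-6)
  }
})

test_that("RMSD is invariant to pre-rotating either input", {
  A <- random_structure(20, seed = 5, id = "a")
  B <- random_structure(20, seed = 6, id = "b")
  base <- kabsch_superpose(A, B, cbind(A$resno, B$resno))$rmsd
  R <- eicotriage:::random_rotation()
  A2 <- calpha_structure("a2", "A", A$resno, A$resletter, A$xyz %*% t(R))
  B2 <- calpha_structure("b2", "A", B$resno, B$resletter, B$xyz %*% t(R))
  expect_equal(kabsch_superpose(A2, B, cbind(A$resno, B$resno))$rmsd, base,
               tolerance = 1e-9)
  expect_equal(kabsch_superpose(A, B2, cbind(A$resno, B$resno))$rmsd, base,
               tolerance = 1e-9)
})

test_that("TM-score follows its formula and is monotone in distance", {
  expect_equal(tm_score(rep(0, 40), 40), 1.0)
  ## L = 4 clamps d0 to 0.5; four pairs at d = 0.5 give exactly 1/2
  expect_equal(tm_score(rep(0.5, 4), 4), 0.5)
  ## independent recomputation at mixed distances
  set.seed(12)
  d <- runif(80, 0, 12); L <- 100
  d0 <- 1.24 * (L - 15)^(1 / 3) - 1.8
  expect_equal(tm_score(d, L), sum(1 / (1 + (d / d0)^2)) / L,
               tolerance = 1e-12)
  ## monotone non-increasing in each distance
  base <- tm_score(d, L)
  d2 <- d; d2[13] <- d2[13] + 1
  expect_lt(tm_score(d2, L), base)
})

test_that("structure alignment recovers the identity mapping on rigid copies", {
  s <- random_structure(60, seed = 21)
  pert <- perturb_structure(s, structure_perturb_spec(sigma = 0, seed = 2))
  res <- structure_align(s, pert$structure, seed = "sequence")
  expect_lt(res$superposition$rmsd, 1e-6)
  expect_equal(res$correspondence[, "resno_a"],
               res$correspondence[, "resno_b"], ignore_attr = TRUE)
  expect_equal(nrow(res$correspondence), 60L)
})

test_that("structure alignment recovers ground truth on perturbed pairs", {
  ok <- vapply(1:20, function(k) {
    s <- random_structure(80, seed = 500 + k)
    pert <- perturb_structure(s, structure_perturb_spec(
      sigma = 0.5, loops = list(c(40, 5)), seed = 600 + k))
    res <- structure_align(s, pert$structure, seed = "sequence")
    truth <- pert$correspondence
    found <- res$correspondence
    key_t <- paste(truth[, 1], truth[, 2])
    key_f <- paste(found[, 1], found[, 2])
    mean(key_f %in% key_t)
  }, numeric(1))
  expect_gte(mean(ok), 0.90)
})

test_that("swapping the structure order preserves the final fit quality", {
  s <- random_structure(50, seed = 31)
  pert <- perturb_structure(s, structure_perturb_spec(sigma = 0.4,
                                                      seed = 32))
  ab <- structure_align(s, pert$structure, seed = "sequence")
  ba <- structure_align(pert$structure, s, seed = "sequence")
  expect_equal(ab$superposition$rmsd, ba$superposition$rmsd,
               tolerance = 1e-6)
})

test_that("unrelated equal-size folds score below the same-fold threshold", {
  tms <- vapply(1:20, function(k) {
    a <- random_structure(60, seed = 700 + k, id = "a")
    b <- random_structure(60, seed = 800 + k, id = "b")
    res <- try(structure_align(a, b, seed = "fragments"), silent = TRUE)
    if (inherits(res, "try-error")) return(0)
    res$superposition$tm_score
  }, numeric(1))
  expect_lt(mean(tms), 0.5)
})

test_that("structure-based identity counts paired letters", {
  s <- random_structure(30, seed = 41)
  self <- structure_based_identity(s, s, cbind(s$resno, s$resno))
  expect_equal(self$identity, 100)
  expect_equal(self$similarity, 100)

  a <- calpha_structure("a", "A", 1:4, c("A", "C", "K", "W"),
                        rbind(c(0, 0, 0), c(3.8, 0, 1), c(7.6, 1, 0),
                              c(11.4, 0, 1)))
  b <- calpha_structure("b", "A", 1:4, c("A", "D", "R", "G"),
                        rbind(c(0, 0, 0), c(3.8, 0, 1), c(7.6, 1, 0),
                              c(11.4, 0, 1)))
  res <- structure_based_identity(a, b, cbind(1:4, 1:4))
  expect_equal(res$identity, 25) # only A/A matches
  expect_gte(res$similarity, res$identity) # K/R scores positive
})

test_that("proximity rescue finds the true partner on perturbed structures", {
  ## a motif residue shifted by one sequence position maps as missing but
  ## is rescued at its spatial ground-truth partner
  hits <- vapply(1:20, function(k) {
    s <- random_structure(60, seed = 900 + k)
    s$resletter[30] <- "W"
    pert <- perturb_structure(s, structure_perturb_spec(sigma = 0.5,
                                                        seed = 950 + k))
    cand <- pert$structure
    ## mapping that calls reference position 30 (W) missing
    ref_seq <- protein_sequence("ref", paste(s$resletter, collapse = ""))
    cand_letters <- cand$resletter
    msa <- alignment(c("ref", "cand"),
                     c(paste(s$resletter, collapse = ""),
                       paste(ifelse(seq_along(cand_letters) == 30, "G",
                                    cand_letters)[seq_len(60)],
                             collapse = "")))
    frs <- functional_residue_set(ref_seq, 30, "W")
    m <- map_functional_residues(msa, frs)
    if (m$status != "missing") return(NA_real_)
    sup <- kabsch_superpose(s, cand, pert$correspondence)
    m2 <- proximity_rescue(m, s, cand, sup)
    truth_partner <- pert$correspondence[pert$correspondence[, 1] == 30, 2]
    as.numeric(m2$status == "proximal" &&
                 m2$cand_position == truth_partner)
  }, numeric(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.95)
})
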