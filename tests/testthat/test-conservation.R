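toy_msa <- alignment(c("ref", "orth"), c("MKY-LCD", "MKF-LCD"))

test_that("a candidate identical to an MSA row adopts that row's gap pattern", {
  cand <- protein_sequence("cand", "MKYLCD")
  aug <- align_candidate_to_msa(cand, toy_msa)
  expect_equal(aug$ids, c("ref", "orth", "cand"))
  expect_equal(aug$gapped[3], aug$gapped[1])
  expect_length(attr(aug, "insertion_columns"), 0L)
})

test_that("candidate insertions become flagged all-gap columns", {
  cand <- protein_sequence("cand", "MKYWWLCD")
  aug <- align_candidate_to_msa(cand, toy_msa)
  ins <- attr(aug, "insertion_columns")
  expect_gt(length(ins), 0L)
  A <- do.call(rbind, strsplit(aug$gapped, "", fixed = TRUE))
  expect_true(all(A[1:2, ins] == "-"))
  ## removing insertion columns restores the original MSA rows
  expect_equal(paste(A[1, -ins], collapse = ""), toy_msa$gapped[1])
})

test_that("an all-X candidate aligns without crashing", {
  cand <- protein_sequence("cand", strrep("X", 6))
  aug <- align_candidate_to_msa(cand, toy_msa)
  expect_equal(alignment_row(aug, "cand")$residues, strrep("X", 6))
})

test_that("re-aligning the root to its family recovers the true gap pattern", {
  fam <- make_test_family(seed = 31)
  truth <- fam$true_alignment
  ## reference: the ortholog rows only; candidate: the root itself
  M <- do.call(rbind, strsplit(truth$gapped[-1], "", fixed = TRUE))
  not_empty <- colSums(M != "-") > 0
  ref <- alignment(truth$ids[-1],
                   apply(M[, not_empty, drop = FALSE], 1, paste,
                         collapse = ""))
  aug <- suppressMessages(align_candidate_to_msa(fam$sequences$root, ref))
  ## each root residue should re-align to its true partner in orth01
  truthM <- do.call(rbind, strsplit(truth$gapped, "", fixed = TRUE))
  augM <- do.call(rbind, strsplit(aug$gapped, "", fixed = TRUE))
  map_truth <- residue_to_root_map(truthM, root_row = 2L, cand_row = 1L)
  map_aug <- residue_to_root_map(augM, root_row = 1L,
                                 cand_row = nrow(augM))
  agree <- mean(map_truth == map_aug, na.rm = TRUE)
  expect_gte(agree, 0.95)
})

test_that("functional residues map with identity, equivalence and gaps", {
  ref <- alignment_row(toy_msa, "ref")
  frs <- functional_residue_set(ref, c(3, 4), c("Y", "L"))
  aug <- align_candidate_to_msa(protein_sequence("cand", "MKYLCD"), toy_msa)
  m <- map_functional_residues(aug, frs, candidate_id = "cand")
  expect_equal(m$status, c("identical", "identical"))
  expect_equal(m$cand_position, c(3L, 4L))
  expect_equal(conserved_fraction(m), 1)

  ## Y aligned to F: equivalent under the default rules
  m2 <- map_functional_residues(toy_msa, frs, candidate_id = "orth")
  expect_equal(m2$status[1], "equivalent")
  expect_equal(m2$cand_residue[1], "F")

  ## C aligned to U: equivalent (selenocysteine)
  msa3 <- alignment(c("ref", "cand"), c("MKCLD", "MKULD"))
  frs3 <- functional_residue_set(alignment_row(msa3, "ref"), 3, "C")
  m3 <- map_functional_residues(msa3, frs3)
  expect_equal(m3$status, "equivalent")

  ## gap -> missing
  msa4 <- alignment(c("ref", "cand"), c("MKYLD", "MK-LD"))
  frs4 <- functional_residue_set(alignment_row(msa4, "ref"), 3, "Y")
  m4 <- map_functional_residues(msa4, frs4)
  expect_equal(m4$status, "missing")
  expect_equal(conserved_fraction(m4), 0)

  ## non-equivalent substitution -> missing
  msa5 <- alignment(c("ref", "cand"), c("MKYLD", "MKGLD"))
  m5 <- map_functional_residues(msa5, frs4)
  expect_equal(m5$status, "missing")
})

test_that("equivalence groups can be restricted to the attested pairs", {
  strict <- equivalence_rules(conservative_groups = FALSE)
  msa <- alignment(c("ref", "cand"), c("MKDLD", "MKELD"))
  frs <- functional_residue_set(alignment_row(msa, "ref"), 3, "D")
  expect_equal(map_functional_residues(msa, frs, rules = strict)$status,
               "missing") # D/E is a conservative pair, not an attested one
  expect_equal(map_functional_residues(msa, frs)$status, "equivalent")
})

test_that("proximity rescue upgrades missing residues within the cutoff only", {
  ## reference: 12 residues on a gentle zig-zag; candidate equals the
  ## reference except the functional Q at position 6 sits elsewhere
  xyz <- cbind(seq(0, by = 3.8, length.out = 12),
               rep(c(0, 1.5), 6), rep(c(0, 0, 1.5), 4))
  ref_letters <- strsplit("MKVLYQAHDEIW", "")[[1]]
  ref_s <- calpha_structure("ref", "A", 1:12, ref_letters, xyz)
  cand_letters <- strsplit("MKVLYGAHDQIW", "")[[1]] # Q moved 6 -> 10
  cand_s <- calpha_structure("cand", "A", 1:12, cand_letters, xyz)

  msa <- alignment(c("ref", "cand"),
                   c(paste(ref_letters, collapse = ""),
                     paste(cand_letters, collapse = "")))
  frs <- functional_residue_set(
    protein_sequence("ref", paste(ref_letters, collapse = "")), 6, "Q")
  m <- map_functional_residues(msa, frs)
  expect_equal(m$status, "missing")

  sup <- kabsch_superpose(ref_s, cand_s, cbind(1:12, 1:12))
  ## candidate Q10 is 4 * 3.8 A away from reference position 6: no rescue
  m_far <- proximity_rescue(m, ref_s, cand_s, sup)
  expect_equal(m_far$status, "missing")

  ## move the candidate's Q to 3 A from the reference Q position
  xyz2 <- xyz; xyz2[10, ] <- xyz[6, ] + c(0, 3, 0)
  cand_near <- calpha_structure("cand", "A", 1:12, cand_letters, xyz2)
  sup2 <- kabsch_superpose(ref_s, cand_near,
                           cbind(c(1:5, 7:9, 11:12), c(1:5, 7:9, 11:12)))
  m_near <- proximity_rescue(m, ref_s, cand_near, sup2)
  expect_equal(m_near$status, "proximal")
  expect_equal(m_near$cand_position, 10L)
  expect_equal(conserved_fraction(m_near), 1)

  ## idempotence and monotone conserved fraction
  m_again <- proximity_rescue(m_near, ref_s, cand_near, sup2)
  expect_equal(m_again, m_near)
  expect_gte(conserved_fraction(m_near), conserved_fraction(m))

  ## at 6 A with a 5 A cutoff the residue stays missing
  xyz3 <- xyz; xyz3[10, ] <- xyz[6, ] + c(0, 6, 0)
  cand6 <- calpha_structure("cand", "A", 1:12, cand_letters, xyz3)
  m6 <- proximity_rescue(m, ref_s, cand6, sup2)
  expect_equal(m6$status, "missing")
})

test_that("planted motifs are recovered as identical across seeds", {
  hits <- 0; total <- 0
  for (s in 1:20) {
    fam <- make_test_family(seed = 400 + s, n_orthologs = 2,
                            root_length = 150,
                            motif = c(15, 50, 85, 120), indel_rate = 0.02)
    truth <- fam$true_alignment
    frs <- fam$motif
    for (cand_id in truth$ids[-1]) {
      m <- map_functional_residues(truth, frs, candidate_id = cand_id)
      hits <- hits + sum(m$status == "identical")
      total <- total + nrow(m)
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("domain architecture comparison scores interval drift", {
  a <- domain_architecture("MAPEG", 16, 146)
  b <- domain_architecture("MAPEG", 18, 148)
  same <- compare_domain_architecture(a, a, 153, 153)
  expect_true(same$match)
  expect_equal(same$score, 1.0)

  drift <- compare_domain_architecture(a, b, 153, 152)
  expect_true(drift$match)
  expect_gt(drift$score, 0.9)
  ## independent recomputation of the rescaled Jaccard overlap
  ia <- c(15 / 153, 146 / 153); ib <- c(17 / 152, 148 / 152)
  jac <- (min(ia[2], ib[2]) - max(ia[1], ib[1])) /
    (max(ia[2], ib[2]) - min(ia[1], ib[1]))
  expect_equal(drift$score, jac, tolerance = 1e-12)

  swapped <- compare_domain_architecture(
    domain_architecture(c("A", "B"), c(1, 60), c(50, 110)),
    domain_architecture(c("B", "A"), c(1, 60), c(50, 110)), 110, 110)
  expect_false(swapped$match)
  expect_equal(swapped$score, 0)
})

test_that("secondary-structure consensus takes majorities with ties to coil", {
  one <- ss_string("a", "HHEC")
  expect_equal(ss_consensus(list(one))$states, "HHEC")
  three <- list(ss_string("a", "HHH"), ss_string("b", "HEE"),
                ss_string("c", "ECC"))
  ## columns: {H,H,E}->H, {H,E,C}->C, {H,E,C}->C
  expect_equal(ss_consensus(three)$states, "HCC")
  expect_error(ss_consensus(list(ss_string("a", "HH"),
                                 ss_string("b", "H"))), "unequal")
  expect_error(ss_string("a", "HQ"), "H, E or C")
})

test_that("secondary-structure agreement behaves at both extremes and on nulls", {
  seqs <- alignment(c("a", "b"), c("MKVL", "MKVL"))
  expect_equal(ss_agreement(ss_string("a", "HHEC"),
                            ss_string("b", "HHEC"), seqs), 100)
  expect_equal(ss_agreement(ss_string("a", "HHHH"),
                            ss_string("b", "EEEE"), seqs), 0)
  set.seed(99)
  vals <- vapply(1:100, function(k) {
    sa <- paste(sample(c("H", "E", "C"), 100, TRUE), collapse = "")
    sb <- paste(sample(c("H", "E", "C"), 100, TRUE), collapse = "")
    aln <- alignment(c("a", "b"), c(strrep("A", 100), strrep("A", 100)))
    ss_agreement(ss_string("a", sa), ss_string("b", sb), aln)
  }, numeric(1))
  expect_lt(abs(mean(vals) - 100 / 3), 10)
})
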