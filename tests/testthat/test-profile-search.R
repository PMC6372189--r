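uniform_bg <- setNames(rep(1 / 20, 20),
                       c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"))

test_that("PSSM log-odds follow the stated formula", {
  ## single row, no pseudocounts, uniform background
  p <- build_pssm(alignment("q", "ACD"), beta = 0, background = uniform_bg)
  expect_equal(unname(p$scores[1, "A"]), log2(20), tolerance = 1e-9)
  expect_equal(unname(p$scores[2, "C"]), log2(20), tolerance = 1e-9)

  ## duplicated rows change nothing (weights normalize)
  p2 <- build_pssm(alignment(c("q", "q2"), c("ACD", "ACD")), beta = 0,
                   background = uniform_bg)
  expect_equal(p2$scores, p$scores)

  ## half/half column
  p3 <- build_pssm(alignment(c("a", "b"), c("A", "V")), beta = 0,
                   background = uniform_bg)
  expect_equal(unname(p3$scores[1, "A"]), log2(0.5 / (1 / 20)), tolerance = 1e-9)
  expect_equal(unname(p3$scores[1, "V"]), log2(0.5 / (1 / 20)), tolerance = 1e-9)

  ## selenocysteine scores as cysteine
  expect_equal(unname(p$scores[2, "U"]), unname(p$scores[2, "C"]))

  ## finite scores, background normalized
  expect_true(all(is.finite(p$scores)))
  expect_equal(sum(p$background), 1, tolerance = 1e-9)
})

test_that("mostly-gapped columns are dropped with a message", {
  aln <- alignment(c("a", "b", "c"), c("MKV", "M-V", "M-V"))
  expect_message(p <- build_pssm(aln), "dropped 1 column")
  expect_equal(nrow(p$scores), 2L)
  expect_equal(p$aln_columns, c(1L, 3L))
  expect_error(build_pssm(alignment("a", "-")), "all-gap")
})

test_that("local profile alignment matches forced optima and the SW floor", {
  pA <- build_pssm(alignment("q", "AAAA"), beta = 0,
                   background = uniform_bg)
  hit <- local_align_profile(pA, protein_sequence("t", "AAAA"))
  expect_equal(hit$score, 4 * 2 * log2(20), tolerance = 1e-9)
  expect_equal(hit$pairs[, "profile_col"], 1:4, ignore_attr = TRUE)
  expect_equal(hit$pairs[, "target_pos"], 1:4, ignore_attr = TRUE)

  ## all-negative scores: empty alignment at score 0
  hit2 <- local_align_profile(pA, protein_sequence("t", "WWWW"))
  expect_equal(hit2$score, 0)
  expect_equal(nrow(hit2$pairs), 0L)
})

test_that("the DP engine equals exhaustive chain enumeration (local, <=8)", {
  set.seed(202)
  n_cases <- 200
  for (case in seq_len(n_cases)) {
    L <- sample(2:8, 1); M <- sample(2:8, 1)
    S <- matrix(sample(seq(-4, 6, by = 0.5), L * M, replace = TRUE), L, M)
    go <- sample(c(2, 4, 6), 1); ge <- sample(c(0.5, 1, 2), 1)
    ge <- min(ge, go)
    res <- eicotriage:::.dp_align(S, go, ge, 0L)
    expect_equal(res$score, oracle_local_score(S, go, ge),
                 tolerance = 1e-9,
                 label = sprintf("case %d (%dx%d)", case, L, M))
    ## the reported traceback reproduces the reported score
    expect_equal(path_score(S, res$row_index, res$col_index, go, ge),
                 res$score, tolerance = 1e-9)
  }
})

test_that("global alignment paths cover both inputs and score consistently", {
  set.seed(303)
  for (case in 1:50) {
    L <- sample(2:10, 1); M <- sample(2:10, 1)
    S <- matrix(rnorm(L * M, 0, 3), L, M)
    res <- eicotriage:::.dp_align(S, 4, 1, 1L)
    expect_equal(sort(res$row_index[res$row_index > 0]), 1:L)
    expect_equal(sort(res$col_index[res$col_index > 0]), 1:M)
    expect_equal(path_score(S, res$row_index, res$col_index, 4, 1),
                 res$score, tolerance = 1e-9)
  }
})

test_that("pairwise statistics match hand-checked examples and are symmetric", {
  a <- protein_sequence("a", "MKVLYAHD")
  expect_equal(pairwise_stats(a, a, mode = "global")[c("identity",
                                                       "similarity",
                                                       "coverage")],
               list(identity = 100, similarity = 100, coverage = 100))
  x <- protein_sequence("x", "AAAA"); y <- protein_sequence("y", "AAGG")
  ps <- pairwise_stats(x, y, mode = "global")
  expect_equal(ps$identity, 50)
  expect_gte(ps$similarity, ps$identity)

  ## score symmetry under the symmetric matrix
  set.seed(17)
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  for (k in 1:20) {
    s1 <- protein_sequence("s1", paste(sample(aas, 30, TRUE), collapse = ""))
    s2 <- protein_sequence("s2", paste(sample(aas, 25, TRUE), collapse = ""))
    expect_equal(pairwise_stats(s1, s2)$score, pairwise_stats(s2, s1)$score)
  }
})

test_that("Gumbel fitting recovers known parameters within 15%", {
  set.seed(44)
  mu <- 30; b <- 4
  x <- mu - b * log(-log(runif(400)))
  fit <- eicotriage:::fit_gumbel(x)
  expect_lt(abs(fit$mu - mu) / mu, 0.15)
  expect_lt(abs(fit$b - b) / b, 0.15)
})

test_that("E-values scale linearly with database size and reject degenerate nulls", {
  set.seed(55)
  db <- lapply(1:20, function(i) protein_sequence(
    sprintf("s%02d", i),
    paste(sample(names(uniform_bg), 120, TRUE,
                 prob = eicotriage:::AA_BACKGROUND), collapse = "")))
  prof <- build_pssm(alignment(db[[1]]$id, db[[1]]$residues))
  calib <- calibrate_evalue(prof, db, n_shuffles = 60, seed = 6)
  expect_gt(calib$lambda, 0)
  expect_gt(calib$K, 0)
  expect_equal(evalue(calib, 50, n = 2 * calib$n),
               2 * evalue(calib, 50, n = calib$n))
  ## zero-variance null
  mono <- list(protein_sequence("m", strrep("A", 60)))
  pm <- build_pssm(alignment("m", strrep("A", 60)))
  expect_error(calibrate_evalue(pm, mono, n_shuffles = 50, seed = 1),
               "degenerate")
})

test_that("a database containing only the query yields a perfect round-1 hit", {
  set.seed(66)
  q <- protein_sequence("q", paste(sample(names(uniform_bg), 150, TRUE),
                                   collapse = ""))
  hits <- iterative_search(q, list(q), n_iter = 1, seed = 2)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$pident, 100)
  expect_equal(hits$qcov, 100)
  expect_true(hits$full_length)
  expect_lt(hits$evalue, 1e-10)
})

test_that("inclusion_E = 0 freezes the profile across rounds", {
  fam <- make_test_family(seed = 21, n_orthologs = 3, root_length = 120, motif = c(20, 60, 100))
  q <- fam$sequences$root
  db <- fam$sequences[-1]
  hits <- iterative_search(q, db, n_iter = 2, inclusion_E = 0, seed = 4)
  r1 <- hits[hits$round == 1, c("target", "raw", "qstart", "qend")]
  r2 <- hits[hits$round == 2, c("target", "raw", "qstart", "qend")]
  rownames(r1) <- rownames(r2) <- NULL
  expect_equal(r1, r2)
})

test_that("profile updates never lose a true family member", {
  ## including one homolog reshapes the profile (raw scores may shift),
  ## but every other family member must remain overwhelmingly significant
  for (s in 1:8) {
    fam <- generate_family(family_spec(
      root_length = 150, n_orthologs = 3, target_identity = 30,
      motif_positions = c(20, 70, 120), indel_rate = 0.02, seed = s))
    q <- fam$sequences$root
    db <- fam$sequences[-1]
    aln1 <- alignment(q$id, q$residues)
    p1 <- build_pssm(aln1)
    ali_b <- local_align_profile(p1, db[[2]])
    aln2 <- eicotriage:::stitch_into_profile(aln1, p1, db[[2]], ali_b)
    p2 <- suppressMessages(build_pssm(aln2))
    c2 <- calibrate_evalue(p2, db, n_shuffles = 60, seed = 77)
    e_after <- evalue(c2, local_align_profile(p2, db[[1]])$score)
    expect_lt(e_after, 1e-3, label = sprintf("seed %d", s))
  }
})

test_that("iterative search separates a planted family from decoys", {
  fam <- make_test_family(seed = 11, n_orthologs = 5)
  q <- fam$sequences$root
  db <- c(fam$sequences[-1], make_decoys(q, n = 50))
  hits <- suppressMessages(iterative_search(q, db, n_iter = 3, seed = 3))
  best <- aggregate(evalue ~ target, hits, min)
  planted <- best$evalue[grepl("^orth", best$target)]
  expect_length(planted, 5L)
  expect_true(all(planted < 0.005))
  reported_decoys <- best$evalue[grepl("^decoy", best$target)]
  expect_true(all(reported_decoys > 0.005))
})
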