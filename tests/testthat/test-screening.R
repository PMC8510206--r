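test_that("consensus thresholds are strict and per-predictor", {
  t1 <- call_predictors(table1_scores())
  # every printed score row clears every cutoff
  expect_true(all(t1$anticp_pos))
  expect_true(all(t1$iacp_pos))
  expect_true(all(t1$mlacp_pos))
  expect_equal(sum(t1$consensus_acp), 4L)

  zero <- call_predictors(data.frame(
    peptide = "AAAA", anticp_svm = 0, iacp_prob = 0, mlacp_rf = 0,
    mlacp_svm = 0))
  expect_false(any(zero$anticp_pos, zero$iacp_pos, zero$mlacp_pos,
                   zero$consensus_acp))

  # boundary: exactly at the cutoff is negative ("over" is strict)
  edge <- call_predictors(data.frame(
    peptide = "AAAA", anticp_svm = 1.00, iacp_prob = 0.6, mlacp_rf = 0.6,
    mlacp_svm = 0.6))
  expect_false(edge$anticp_pos)
  expect_true(edge$iacp_pos && edge$mlacp_pos)
  expect_false(edge$consensus_acp)

  # MLACP needs both probabilities over 0.5
  half <- call_predictors(data.frame(
    peptide = "AAAA", anticp_svm = 2, iacp_prob = 0.9, mlacp_rf = 0.9,
    mlacp_svm = 0.4))
  expect_false(half$mlacp_pos)

  expect_error(call_predictors(data.frame(peptide = "A", anticp_svm = 1)),
               "missing column")
  expect_error(call_predictors(data.frame(
    peptide = "A", anticp_svm = 1, iacp_prob = 1.4, mlacp_rf = 0.5,
    mlacp_svm = 0.5)), "outside")
})

test_that("raising any score never flips a positive verdict negative", {
  set.seed(21)
  for (rep in 1:30) {
    sc <- data.frame(peptide = "PEPTIDE", anticp_svm = rnorm(1, 1, 0.5),
                     iacp_prob = runif(1), mlacp_rf = runif(1),
                     mlacp_svm = runif(1))
    v0 <- call_predictors(sc)$consensus_acp
    col <- sample(c("anticp_svm", "iacp_prob", "mlacp_rf", "mlacp_svm"), 1)
    sc[[col]] <- min(sc[[col]] + runif(1, 0, 0.5),
                     if (col == "anticp_svm") Inf else 1)
    v1 <- call_predictors(sc)$consensus_acp
    expect_true(v1 >= v0)
  }
})

test_that("Venn regions match explicit set algebra", {
  all_pos <- call_predictors(data.frame(
    peptide = c("AAA", "CCC", "DDD"), anticp_svm = 2, iacp_prob = 0.9,
    mlacp_rf = 0.9, mlacp_svm = 0.9))
  v <- venn_counts(all_pos)
  expect_equal(v$count[v$region == "all_three"], 3L)
  expect_equal(sum(v$count), 3L)

  # constructed 8-peptide table covering every region once (one all-negative)
  tbl <- expand.grid(a = c(FALSE, TRUE), b = c(FALSE, TRUE),
                     c = c(FALSE, TRUE))
  sc8 <- data.frame(
    peptide = sprintf("pep%d", 1:8),
    anticp_svm = ifelse(tbl$a, 2, 0), iacp_prob = ifelse(tbl$b, 0.9, 0.1),
    mlacp_rf = ifelse(tbl$c, 0.9, 0.1), mlacp_svm = ifelse(tbl$c, 0.9, 0.1))
  v8 <- venn_counts(call_predictors(sc8))
  expect_true(all(v8$count == 1L))
  expect_equal(attr(v8, "union"), 7L)

  expect_error(venn_counts(call_predictors(rbind(sc8, sc8))), "duplicate")

  # randomized tables vs the set-operations oracle + inclusion-exclusion
  set.seed(22)
  for (rep in 1:10) {
    n <- 60
    sc <- data.frame(
      peptide = sprintf("r%03d", 1:n), anticp_svm = rnorm(n, 1, 0.6),
      iacp_prob = runif(n), mlacp_rf = runif(n), mlacp_svm = runif(n))
    verd <- call_predictors(sc)
    v <- venn_counts(verd)
    ora <- oracle_venn(verd$peptide[verd$anticp_pos],
                       verd$peptide[verd$iacp_pos],
                       verd$peptide[verd$mlacp_pos])
    expect_equal(setNames(v$count, v$region), ora)
    t <- attr(v, "totals")
    pairwise <- sum(verd$anticp_pos & verd$iacp_pos) +
      sum(verd$anticp_pos & verd$mlacp_pos) +
      sum(verd$iacp_pos & verd$mlacp_pos)
    expect_equal(t[["anticp"]] + t[["iacp"]] + t[["mlacp"]] - pairwise +
                   v$count[v$region == "all_three"], attr(v, "union"))
  }
})

test_that("mode-of-action stratification partitions the consensus set", {
  sc <- call_predictors(data.frame(
    peptide = sprintf("p%02d", 1:10), anticp_svm = 2, iacp_prob = 0.9,
    mlacp_rf = 0.9, mlacp_svm = 0.9,
    toxic = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
              FALSE),
    cpp = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE,
            TRUE)))
  moa <- classify_moa(sc)
  # hand tally: both {p01,p08}; toxic_only {p02}; cpp_only {p03,p04,p05,p10};
  # none {p06,p07,p09}
  expect_equal(moa$category_counts,
               c(toxic_only = 1L, cpp_only = 4L, both = 2L, none = 3L))
  expect_equal(sum(moa$category_counts), 10L)
  expect_equal(moa$overlapping_totals, c(toxic = 3L, cpp = 6L))
  # overlap identity: toxic + cpp - both + none == consensus size
  expect_equal(moa$overlapping_totals[["toxic"]] +
                 moa$overlapping_totals[["cpp"]] -
                 moa$category_counts[["both"]] +
                 moa$category_counts[["none"]], 10L)
  expect_equal(moa$assignments$moa_category[moa$assignments$peptide == "p01"],
               "both")
  expect_equal(moa$assignments$moa_category[moa$assignments$peptide == "p06"],
               "none")
  # flags must be present for consensus peptides
  expect_error(classify_moa(call_predictors(table1_scores())), "flags")
})

test_that("candidate ranking is the documented total order", {
  two <- data.frame(peptide = c("AAA", "CCC"), anticp_svm = c(1.2, 1.5),
                    iacp_prob = 0.9, mlacp_rf = 0.9, mlacp_svm = 0.9)
  expect_equal(rank_candidates(two)$peptide, c("CCC", "AAA"))

  tie <- data.frame(peptide = c("AAA", "CCC"), anticp_svm = 1.5,
                    iacp_prob = c(0.6, 0.9), mlacp_rf = 0.5, mlacp_svm = 0.5)
  expect_equal(rank_candidates(tie)$peptide, c("CCC", "AAA"))

  # full tie falls back to lexicographic sequence
  fulltie <- data.frame(peptide = c("CCC", "AAA"), anticp_svm = 1,
                        iacp_prob = 0.5, mlacp_rf = 0.5, mlacp_svm = 0.5)
  expect_equal(rank_candidates(fulltie)$peptide, c("AAA", "CCC"))

  # printed score table: the redesigned peptide outranks the original
  t1 <- table1_scores()
  cgroup <- rank_candidates(t1[t1$peptide %in% c("VTFVLIAAK", "FTFVLLAAK"), ])
  expect_equal(cgroup$peptide[1], "FTFVLLAAK")

  # permuting input never changes the output order
  set.seed(23)
  sc <- data.frame(peptide = sprintf("p%02d", 1:15),
                   anticp_svm = sample(c(1.1, 1.5, 2.0), 15, replace = TRUE),
                   iacp_prob = runif(15), mlacp_rf = runif(15),
                   mlacp_svm = runif(15))
  ranked <- rank_candidates(sc)
  for (rep in 1:5)
    expect_equal(rank_candidates(sc[sample(15), ]), ranked)
  expect_error(rank_candidates(sc[0, ]), "empty")
})

test_that("property summary panels sum to 100 with 1-decimal rounding", {
  props <- peptide_properties(c("KKKKK", "DDDDD"))
  s <- property_summary(props)
  expect_equal(unname(s$charge[c("cationic", "anionic")]), c(50, 50))
  expect_equal(sum(s$length), 100)
  expect_equal(sum(s$hydrophobicity), 100)

  one <- property_summary(peptide_properties("VTFVLIAAK"))
  expect_equal(one$charge[["cationic"]], 100)
  expect_equal(one$hydrophobicity[["hydrophobic"]], 100)
  expect_equal(one$length[["5-20"]], 100)

  expect_true(attr(property_summary(peptide_properties(character())),
                   "empty"))

  # hand tally on a mixed set
  set.seed(24)
  seqs <- replicate(40, random_peptide(sample(5:50, 1)))
  props <- peptide_properties(seqs)
  s <- property_summary(props)
  expect_equal(s$charge[["cationic"]],
               round(100 * mean(props$net_charge > 0), 1))
  expect_equal(s$length[["21-35"]],
               round(100 * mean(props$length >= 21 & props$length <= 35), 1))
})

test_that("score tables round-trip through TSV with column mapping", {
  sc <- table1_scores()
  sc$toxic <- c(1L, 1L, 0L, 0L)
  sc$cpp <- c(1L, 1L, 0L, 1L)
  f <- tempfile(fileext = ".tsv")
  names(sc)[2] <- "SVM Score"
  write.table(sc, f, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_scores(f, column_map = c(anticp_svm = "SVM Score"))
  expect_equal(got$anticp_svm, table1_scores()$anticp_svm)
  expect_identical(got$toxic, c(TRUE, TRUE, FALSE, FALSE))
  expect_error(read_scores(f), "missing column")
})
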