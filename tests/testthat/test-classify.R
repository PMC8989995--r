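test_that("classifier gives full confidence for a unique exact reference", {
  set.seed(73)
  refs <- random_dna(4, 300)
  names(refs) <- sprintf("R%d", 1:4)
  tax <- toy_taxonomy(names(refs), genus = c("GenusA", "GenusB"))
  idx <- build_kmer_index(refs, tax)
  out <- classify(c(q = refs[[2]]), idx, seed = 5)
  expect_equal(unname(unlist(out$taxonomy[1, tax_ranks()])),
               unname(unlist(tax[2, tax_ranks()])))
  expect_true(all(out$confidence[1, ] == 1))
  expect_error(classify(c(q = "ACGT"), idx), "shorter")
})

test_that("two identical references split species confidence near one half", {
  set.seed(79)
  s <- random_dna(1, 300)
  refs <- c(R1 = s, R2 = s)
  tax <- toy_taxonomy(c("R1", "R2"), species = c("spA", "spB"))
  idx <- build_kmer_index(refs, tax)
  params <- classifier_params(bootstraps = 1000)
  out <- classify(c(q = s), idx, params, seed = 11)
  spc <- out$confidence[1, "species"]
  # analytic expectation 0.5; binomial(1000, .5)99.9% band
  expect_gt(spc, 0.45)
  expect_lt(spc, 0.55)
  # species truncated at the 0.8 cutoff, genus retained
  expect_true(is.na(out$taxonomy$species[1]))
  expect_equal(out$taxonomy$genus[1], "GenusA")
  expect_equal(out$confidence[1, "genus"], 1)
})

test_that("the confidence cutoff is inclusive and truncation is downward", {
  conf <- c(1, 1, 1, 1, 1, 0.8, 0.79)
  # emulate the truncation rule on a synthetic confidence profile
  keep <- conf >= 0.8
  keep[seq_along(keep) >= which(!keep)[1]] <- FALSE
  expect_equal(sum(keep), 6)  # rank at exactly 0.8 retained, 0.79 dropped

  # end to end: references engineered so genus confidence ~0.5 < 0.8
  set.seed(83)
  s <- random_dna(1, 300)
  refs <- c(R1 = s, R2 = s)
  tax <- toy_taxonomy(c("R1", "R2"), genus = c("GenusA", "GenusB"),
                      species = c("spA", "spB"))
  idx <- build_kmer_index(refs, tax)
  out <- classify(c(q = s), idx, classifier_params(bootstraps = 500), seed = 7)
  expect_true(is.na(out$taxonomy$genus[1]))
  expect_true(is.na(out$taxonomy$species[1]))
  expect_equal(out$taxonomy$family[1], "FamilyA")
})

test_that("classification is reproducible under a seed", {
  set.seed(89)
  refs <- random_dna(6, 250)
  names(refs) <- sprintf("R%d", 1:6)
  tax <- toy_taxonomy(names(refs), genus = c("GenusA", "GenusB", "GenusC"))
  idx <- build_kmer_index(refs, tax)
  qs <- vapply(refs[1:3], mutate_positions, "", k = 5)
  names(qs) <- c("a", "b", "c")
  r1 <- classify(qs, idx, seed = 42)
  r2 <- classify(qs, idx, seed = 42)
  expect_identical(r1, r2)
})

test_that("coverage is the filtered fraction of high-identity ASVs", {
  set.seed(97)
  asv <- random_dna(4, 120)
  names(asv) <- sprintf("A%d", 1:4)
  counts <- matrix(100L, 4, 2, dimnames = list(names(asv), c("s1", "s2")))

  # database contains everything verbatim: 100% everywhere
  cov <- coverage_eval(counts, asv, stats::setNames(asv, sprintf("D%d", 1:4)))
  expect_true(all(cov$per_sample$coverage == 100))

  # 1 of 4 kept ASVs at ~98% best identity: 75%
  db <- asv
  db[4] <- mutate_positions(asv[4], 3)  # 117/120 = 97.5%
  names(db) <- sprintf("D%d", 1:4)
  cov <- coverage_eval(counts, asv, db)
  expect_true(all(cov$per_sample$coverage == 75))

  # deterministic construction: db omitting taxa with known kept fraction
  counts2 <- matrix(c(5000L, 3000L, 1500L, 500L), 4, 1,
                    dimnames = list(names(asv), "s1"))
  db2 <- stats::setNames(asv[1:2], c("D1", "D2"))
  cov2 <- coverage_eval(counts2, asv, db2)
  expect_equal(cov2$per_sample$coverage, 50)  # 2 of 4 kept ASVs covered
})

test_that("abundance filter and empty samples behave as specified", {
  asv <- c(A1 = "ACGTACGTACGTACGTACGT", A2 = "TTGCATTGCATTGCATTGCA")
  counts <- matrix(c(9999L, 1L), 2, 1, dimnames = list(names(asv), "s1"))
  cov <- coverage_eval(counts, asv, stats::setNames(asv[1], "D1"))
  # A2 at 1e-4 relative abundance is exactly at the >= 0.01% filter: kept
  expect_equal(cov$per_sample$coverage, 50)
})

test_that("classification rates count named ranks among kept ASVs", {
  asv <- c(A1 = "ACGTACGTACGTACGTACGT", A2 = "TTGCATTGCATTGCATTGCA")
  counts <- matrix(c(100L, 100L), 2, 1, dimnames = list(names(asv), "s1"))
  cls <- data.frame(id = c("A1", "A2"), domain = "Bacteria",
                    phylum = "P", class = "C", order = "O", family = "F",
                    genus = c("G", NA), species = c(NA, NA),
                    stringsAsFactors = FALSE)
  gen <- classification_rate_eval(counts, cls, "genus")
  spc <- classification_rate_eval(counts, cls, "species")
  expect_equal(gen$per_sample$rate, 50)
  expect_equal(spc$per_sample$rate, 0)

  cls$genus <- c("G1", "G2"); cls$species <- c("S1", "S2")
  expect_equal(classification_rate_eval(counts, cls, "species")$per_sample$rate,
               100)
})

test_that("database comparison is monotone in database content", {
  set.seed(101)
  asv <- random_dna(10, 150)
  names(asv) <- sprintf("A%02d", 1:10)
  counts <- matrix(rpois(30, 200) + 1L, 10, 3,
                   dimnames = list(names(asv), c("s1", "s2", "s3")))
  db1 <- stats::setNames(asv, sprintf("D%02d", 1:10))
  db2 <- db1[1:7]  # drop 30% of references
  c1 <- coverage_eval(counts, asv, db1)$per_sample$coverage
  c2 <- coverage_eval(counts, asv, db2)$per_sample$coverage
  expect_true(all(c2 <= c1))
  expect_true(all(c1 >= 0 & c1 <= 100))

  tax1 <- toy_taxonomy(names(db1))
  res <- compare_databases(counts, asv,
                           list(full = list(seqs = db1, taxonomy = tax1),
                                same = list(seqs = db1, taxonomy = tax1)),
                           seed = 3)
  full <- res[res$database == "full", -1]
  same <- res[res$database == "same", -1]
  rownames(full) <- rownames(same) <- NULL
  expect_equal(full, same)
})

test_that("box statistics follow the 1.5 IQR whisker rule", {
  x <- c(1, 2, 3, 4, 5, 100)
  b <- box_stats(x)
  expect_equal(b$median, 3.5)
  expect_equal(b$whisker_low, 1)
  expect_true(b$whisker_high < 100)  # the outlier is outside the fence
  expect_gte(b$whisker_low, min(x))
  expect_lte(b$whisker_high, max(x))
})
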