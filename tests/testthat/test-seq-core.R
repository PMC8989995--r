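test_that("FASTA round-trip normalizes and is byte-stable", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b desc", "acgu"), f)
  seqs <- read_fasta(f)
  expect_equal(unname(seqs), c("ACGT", "ACGT"))
  expect_equal(names(seqs)[1], "a")

  f2 <- withr::local_tempfile(fileext = ".fasta")
  f3 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f2)
  write_fasta(read_fasta(f2), f3)
  expect_identical(readLines(f2), readLines(f3))

  # seed comment lines are ignored on read
  f4 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f4, seed = 42)
  expect_equal(readLines(f4)[1], "; seed=42")
  expect_equal(read_fasta(f4), seqs)

  fbad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "ACGZ"), fbad)
  expect_error(read_fasta(fbad), "x")
})

test_that("size annotations are parsed and honoured", {
  expect_equal(parse_size(c("a;size=10", "b", "c;size=3")), c(10L, 1L, 3L))
})

test_that("IUPAC degenerate matching counts true mismatches", {
  expect_equal(iupac_match("GTGYCAGCMGCCGCGGTAA", "GTGCCAGCAGCCGCGGTAA"), 0)
  p <- "GGACTACNVGGGTWTCTAAT"
  for (b in c("A", "C", "G", "T")) {
    w <- sub("N", b, sub("V", "A", sub("W", "A", p)))
    expect_equal(iupac_match(p, w), 0)
  }
  expect_equal(iupac_match("AAAA", "AAAT"), 1)
  expect_error(iupac_match("AAA", "AAAA"), "length")
})

test_that("primer sites are found leftmost within the mismatch bound", {
  seq <- paste0("AAAATTTT", "GGGG", paste(rep("C", 50), collapse = ""))
  hit <- find_primer_site(seq, "AAAATTTT", max_mismatch = 0)
  expect_equal(hit$pos, 1)
  expect_equal(hit$mismatches, 0)
  expect_true(is.na(find_primer_site(seq, "GGGGGGGG", 0)$pos))

  # one-mismatch site upstream of an exact site: brute-force over all
  # windows confirms the leftmost window satisfying each bound
  set.seed(7)
  for (rep in 1:20) {
    s <- random_dna(1, 80)
    primer <- "ACGTACGTAC"
    near <- mutate_positions(primer, 1)
    s <- paste0(substr(s, 1, 10), near, substr(s, 21, 50), primer,
                substr(s, 61, 80))
    for (mm in 0:1) {
      got <- find_primer_site(s, primer, mm, search_window = Inf)
      wins <- vapply(1:(nchar(s) - 9), function(p)
        iupac_match(primer, substr(s, p, p + 9)), 0)
      expect_equal(got$pos, which(wins <= mm)[1])
    }
  }
})

test_that("orientation flips reverse-complemented reads and keeps ties", {
  set.seed(3)
  refs <- random_dna(3, 200)
  out <- orient(c(a = refs[1]), refs)
  expect_equal(unname(out[1]), refs[1])
  expect_false(attr(out, "flipped")[1])

  out <- orient(c(a = revcomp(refs[2])), refs)
  expect_equal(unname(out[1]), refs[2])
  expect_true(attr(out, "flipped")[1])

  # unrelated short sequence: tie on shared 8-mers keeps input orientation
  stray <- "ACACACACACAC"
  out <- orient(c(a = stray), refs)
  expect_equal(unname(out[1]), stray)
})

test_that("trimming between primers excises exactly the insert", {
  fwd <- primer_set("V1V3")$forward
  rev_ <- primer_set("FL")$reverse
  set.seed(5)
  insert <- random_dna(1, 60)
  seq <- paste0(fwd, insert, revcomp(rev_))
  tr <- trim_between_primers(seq, fwd, rev_)
  expect_equal(tr$seq, insert)
  # trimmed output never retains the primers at its ends
  expect_false(startsWith(tr$seq, fwd))

  expect_null(trim_between_primers(paste0(fwd, insert), fwd, rev_))
  expect_null(trim_between_primers(paste0(fwd, revcomp(rev_)), fwd, rev_))
})

test_that("identity matches hand-checked examples and is symmetric", {
  expect_equal(global_identity("ACGT", "ACGT"), 1.0)
  expect_equal(global_identity("ACGTACGT", "ACGAACGT"), 7 / 8)
  set.seed(11)
  for (i in 1:25) {
    a <- random_dna(1, sample(10:50, 1))
    b <- random_dna(1, sample(10:50, 1))
    ia <- global_identity(a, b)
    expect_equal(ia, global_identity(b, a))
    expect_gte(ia, 0); expect_lte(ia, 1)
  }
})

test_that("alignment identity equals the brute-force DP oracle", {
  set.seed(23)
  for (i in 1:200) {
    len_a <- sample(8:60, 1)
    a <- random_dna(1, len_a)
    b <- if (runif(1) < 0.5) {
      mutate_positions(a, sample(0:min(8, len_a), 1))
    } else {
      random_dna(1, sample(8:60, 1))
    }
    got <- asvref:::cpp_align_identity(a, b)
    want <- oracle_align(a, b)
    expect_equal(got$score, want$score)
    expect_equal(got$identity, want$identity)
  }
})

test_that("top hit equals exhaustive argmax with smallest-id ties", {
  refs <- c(r2 = "ACGTACGTAA", r1 = "ACGTACGTAA", r3 = "TTTTTTTTTT")
  hit <- top_hit(c(q = "ACGTACGTAA"), refs)
  expect_equal(hit$ref, "r1")
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$tie_count, 2L)
  expect_error(top_hit(c(q = "ACGT"), character(0)), "empty")

  set.seed(31)
  queries <- random_dna(50, 30)
  names(queries) <- sprintf("q%02d", 1:50)
  refs <- c(random_dna(25, 30), vapply(queries[1:25], mutate_positions, "", k = 2))
  names(refs) <- sprintf("r%02d", 1:50)
  got <- top_hit(queries, refs)
  for (i in seq_along(queries)) {
    want <- oracle_top_hit(queries[[i]], refs)
    expect_equal(got$ref[i], want$ref)
    expect_equal(got$identity[i], want$identity)
    expect_equal(got$tie_count[i], want$tie_count)
  }
})

test_that("greedy OTU clustering recovers planted clusters", {
  expect_equal(nrow(unique(cluster_otus(c(a = "ACGTACGTACGT",
                                          b = "ACGTACGTACGT"))["centroid"])), 1)

  set.seed(41)
  # two sequences at < 97%: distinct OTUs
  a <- random_dna(1, 100)
  b <- mutate_positions(a, 10)
  cl <- cluster_otus(c(s1 = a, s2 = b))
  expect_equal(length(unique(cl$centroid)), 2)

  # planted clusters: 99% within, ~90% between
  centroids <- random_dna(3, 200)
  seqs <- character(0)
  truth <- integer(0)
  for (k in 1:3) {
    for (j in 1:4) {
      seqs <- c(seqs, mutate_positions(centroids[k], 2))
      truth <- c(truth, k)
    }
  }
  names(seqs) <- sprintf("m%02d", seq_along(seqs))
  cl <- cluster_otus(seqs, threshold = 0.97)
  expect_equal(length(unique(cl$centroid)), 3)
  expect_true(all(table(truth, cl$centroid) %in% c(0, 4)))
  # every member is >= threshold identical to its centroid
  expect_true(all(cl$identity >= 0.97))
})
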