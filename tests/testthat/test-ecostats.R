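test_that("rarefaction drops shallow samples and hits exact depth", {
  set.seed(109)
  m <- matrix(rpois(40, 60), 10, 4,
              dimnames = list(paste0("t", 1:10), paste0("s", 1:4)))
  m[, 1] <- c(9999L, rep(0L, 9))       # 9,999 reads: dropped at depth 10,000
  m[, 2] <- c(5000L, 5000L, rep(0L, 8))  # exactly 10,000: kept unchanged
  m[, 3] <- rpois(10, 2000)
  m[, 4] <- rpois(10, 1500)
  out <- rarefy(m, depth = 10000, seed = 1)
  expect_false("s1" %in% colnames(out))
  expect_true(all(colSums(out) == 10000))
  expect_equal(out[, "s2"], m[, "s2"])
  # never more reads per feature than before rarefaction
  expect_true(all(out <= m[, colnames(out)]))
  expect_error(rarefy(m, depth = 0), "positive")
})

test_that("alpha diversity matches closed forms", {
  m <- matrix(c(rep(10L, 5), 50L, rep(0L, 4)), 5, 2,
              dimnames = list(paste0("t", 1:5), c("uniform", "single")))
  a <- alpha_diversity(m)
  expect_equal(a$richness, c(5, 1))
  expect_equal(a$invsimpson, c(5, 1))
  set.seed(113)
  m2 <- matrix(rpois(50, 20) + 1L, 10, 5,
               dimnames = list(paste0("t", 1:10), paste0("s", 1:5)))
  a2 <- alpha_diversity(m2)
  expect_true(all(a2$invsimpson <= a2$richness))
})

test_that("beta diversity matches the textbook formulas", {
  rel <- matrix(c(0.5, 0.5, 0, 0,
                  0.5, 0.5, 0, 0,
                  0, 0, 0.5, 0.5), 4, 3,
                dimnames = list(paste0("t", 1:4), c("a", "b", "c")))
  bc <- as.matrix(bray_curtis(rel))
  expect_equal(bc["a", "b"], 0)
  expect_equal(bc["a", "c"], 1)

  set.seed(127)
  rel2 <- matrix(stats::runif(60), 12, 5)
  rel2 <- sweep(rel2, 2, colSums(rel2), "/")
  dimnames(rel2) <- list(paste0("t", 1:12), paste0("s", 1:5))
  bc2 <- as.matrix(bray_curtis(rel2))
  so2 <- as.matrix(soerensen(rel2, presence = 0.02))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(bc2[i, j], oracle_bray(rel2[, i], rel2[, j]))
    expect_equal(so2[i, j], oracle_soerensen(rel2[, i], rel2[, j], 0.02))
  }
  # distance matrix invariants
  expect_true(all(bc2 == t(bc2)))
  expect_true(all(diag(bc2) == 0))
  expect_true(all(bc2 >= 0 & bc2 <= 1))
})

test_that("Haversine distances use the 6378.137 km radius", {
  expect_equal(as.vector(haversine_km(c(10, 10), c(20, 20))), 0)
  pole <- as.vector(haversine_km(c(90, -90), c(0, 0)))
  expect_equal(pole, pi * 6378.137, tolerance = 1e-6)
  expect_equal(as.vector(haversine_km(c(10, 20), c(30, 40))),
               as.vector(haversine_km(c(20, 10), c(40, 30))))
  expect_error(haversine_km(c(91, 0), c(0, 0)), "range")
})

test_that("Mantel statistic and p-value behave at the extremes", {
  set.seed(131)
  m <- matrix(stats::runif(100), 10, 10)
  d1 <- stats::as.dist(m + t(m))
  r <- mantel_test(d1, d1, n_perm = 999, seed = 2)
  expect_equal(r$statistic, 1)
  expect_gte(r$p_value, 1 / 1000)
  expect_error(mantel_test(stats::dist(1:2), stats::dist(1:2)), "3")
})

test_that("distance decay fits slopes per stratum", {
  set.seed(137)
  n <- 20
  km <- matrix(stats::runif(n * n, 0, 5000), n, n)
  km <- (km + t(km)) / 2; diag(km) <- 0
  # plant a linear decay only below the breakpoint
  sim <- 0.8 - 1e-4 * pmin(as.vector(stats::as.dist(km)), 2500)
  comm <- stats::as.dist(matrix(0, n, n))
  cm <- matrix(0, n, n); cm[lower.tri(cm)] <- 1 - sim
  comm <- stats::as.dist(cm + t(cm))
  out <- ddr(comm, stats::as.dist(km), breakpoint = 2500)
  expect_equal(out$slope[out$stratum == "within"], -1e-4, tolerance = 1e-6)
  expect_equal(out$slope[out$stratum == "beyond"], 0, tolerance = 1e-6)
  # degenerate: co-located plants leave the beyond stratum empty
  km0 <- stats::as.dist(matrix(0, 5, 5))
  expect_error(ddr(stats::as.dist(matrix(0.5, 5, 5) - diag(0.5, 5)), km0),
               "beyond")
})

test_that("PERMANOVA matches the direct sum-of-squares oracle", {
  set.seed(139)
  for (rep in 1:5) {
    n <- sample(8:12, 1)
    x <- matrix(stats::rnorm(n * 3), n, 3)
    d <- stats::dist(x)
    groups <- sample(rep(c("a", "b"), length.out = n))
    got <- permanova(d, groups, n_perm = 99, seed = rep)
    expect_equal(got$R2, oracle_permanova_r2(d, groups), tolerance = 1e-10)
  }
  # two fully separated clusters: tiny p, R2 near its planted share
  x <- rbind(matrix(stats::rnorm(12, 0, 0.05), 6, 2),
             matrix(stats::rnorm(12, 10, 0.05), 6, 2))
  d <- stats::dist(x)
  g <- rep(c("a", "b"), each = 6)
  got <- permanova(d, g, n_perm = 999, seed = 1)
  expect_equal(got$p_value, 1 / 1000)
  expect_gt(got$R2, 0.95)
  # single group: no partition
  expect_equal(permanova(d, rep("a", 12))$R2, 0)
  expect_error(permanova(d, c("a", rep("b", 11))), "singleton")
})

test_that("PCoA reproduces Euclidean configurations", {
  # three equidistant points: two equal positive eigenvalues
  d <- stats::as.dist(matrix(1, 3, 3) - diag(1, 3))
  p <- pcoa(d)
  pos <- p$eigenvalues[p$eigenvalues > 1e-9]
  expect_equal(length(pos), 2)
  expect_equal(pos[1], pos[2])

  set.seed(149)
  x <- matrix(stats::rnorm(40), 20, 2)
  d <- stats::dist(x)
  p <- pcoa(d)
  rec <- stats::dist(p$coordinates)
  expect_lt(max(abs(as.vector(rec) - as.vector(d))), 1e-8)
  # eigenvalue sum equals total centred sum of squares
  dm <- as.matrix(d)
  expect_equal(sum(p$eigenvalues), sum(dm[lower.tri(dm)]^2) / 20)
})

test_that("Kruskal-Wallis with Dunn handles ties and extreme separation", {
  # all values tied: H = 0, p = 1
  out <- kruskal_dunn(rep(5, 12), rep(c("a", "b", "c"), each = 4))
  expect_equal(out$H, 0)
  expect_equal(out$p_value, 1)
  expect_false(any(out$pairwise$significant))

  # complete separation of two groups achieves the maximal H for that n
  v <- c(1:6, 101:106)
  g <- rep(c("a", "b"), each = 6)
  out <- kruskal_dunn(v, g, alpha = 0.01)
  n <- 12
  h_max <- (12 / (n * (n + 1))) * (6 * (mean(1:6) - (n + 1) / 2)^2 +
                                     6 * (mean(7:12) - (n + 1) / 2)^2)
  expect_equal(out$H, h_max)
  expect_true(out$pairwise$significant[1])

  # matches the base R statistic on random data with ties
  set.seed(151)
  v <- sample(1:5, 30, replace = TRUE)
  g <- rep(c("a", "b", "c"), each = 10)
  out <- kruskal_dunn(v, g)
  ref <- stats::kruskal.test(v, factor(g))
  expect_equal(out$H, unname(ref$statistic))
  expect_equal(out$p_value, ref$p.value)
})

test_that("distance matrices round-trip through TSV", {
  set.seed(157)
  d <- stats::dist(matrix(stats::rnorm(20), 10, 2))
  attr(d, "Labels") <- paste0("s", 1:10)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dist_tsv(d, f)
  back <- read_dist_tsv(f)
  expect_equal(as.matrix(back), as.matrix(d), tolerance = 1e-12)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_dist_tsv(d, f2, format = "long")
  long <- utils::read.table(f2, header = TRUE, sep = "\t")
  expect_equal(nrow(long), 45)
})
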