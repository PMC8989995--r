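#' Rarefy samples to a common depth
#'
#' Samples with fewer than `depth` reads are dropped; the rest are subsampled
#' without replacement to exactly `depth` reads.
#'
#' @param counts Matrix, features x samples.
#' @param depth Target depth, default 10000.
#' @param seed Integer seed.
#' @return Rarefied matrix (possibly with fewer columns); the `plants`
#'   attribute, when present, is subset accordingly.
#' @export
rarefy <- function(counts, depth = 10000, seed = 1) {
  if (depth <= 0) stop("depth must be positive")
  tot <- colSums(counts)
  keep <- tot >= depth
  out <- unclass(counts)[, keep, drop = FALSE]
  set.seed(seed)
  # vegan warns when the smallest nonzero count exceeds 1, suspecting scaled
  # data; rank-aggregated counts legitimately look like that
  sub <- withCallingHandlers(
    t(vegan::rrarefy(t(out), depth)),
    warning = function(w) {
      if (grepl("smallest count", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  plants <- attr(counts, "plants")
  if (!is.null(plants)) attr(sub, "plants") <- plants[colnames(sub)]
  sub
}

#' Alpha diversity: observed richness and inverse Simpson
#'
#' @param counts Matrix, features x samples (rarefied input recommended).
#' @return Data frame with `sample`, `richness`, `invsimpson`.
#' @export
alpha_diversity <- function(counts) {
  tot <- colSums(counts)
  if (any(tot == 0)) stop("zero-sum sample")
  data.frame(
    sample = colnames(counts),
    richness = colSums(counts > 0),
    invsimpson = vegan::diversity(t(unclass(counts)), index = "invsimpson"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Bray-Curtis dissimilarity between samples
#'
#' @param rel Matrix, features x samples, of relative abundances.
#' @return A `dist` object over samples with entries in `[0, 1]`.
#' @export
bray_curtis <- function(rel) {
  vegan::vegdist(t(unclass(rel)), method = "bray")
}

#' Soerensen dissimilarity on thresholded presence/absence
#'
#' Relative abundances are binarized at `presence` (strictly greater) before
#' computing the Soerensen dissimilarity `1 - 2|A and B| / (|A| + |B|)`.
#' Pairs where both samples are empty after thresholding get distance 1 with
#' a warning.
#'
#' @param rel Matrix, features x samples, of relative abundances.
#' @param presence Presence threshold as a fraction, default 1e-4 (0.01%).
#' @return A `dist` object over samples.
#' @export
soerensen <- function(rel, presence = 1e-4) {
  pa <- (unclass(rel) > presence) * 1
  empty <- colSums(pa) == 0
  d <- vegan::vegdist(t(pa), method = "bray", binary = TRUE)
  if (any(empty)) {
    warning("samples empty after presence thresholding: ",
            paste(colnames(rel)[empty], collapse = ", "))
    m <- as.matrix(d)
    m[empty, ] <- 1
    m[, empty] <- 1
    diag(m) <- 0
    d <- stats::as.dist(m)
  }
  d
}

#' Great-circle distance in kilometres (Haversine)
#'
#' Uses the Haversine formula with earth radius 6378.137 km.
#'
#' @param lat,lon Numeric vectors of coordinates in degrees.
#' @param radius_km Earth radius, default 6378.137.
#' @return A `dist` object of pairwise distances in km.
#' @export
haversine_km <- function(lat, lon, radius_km = 6378.137) {
  if (any(abs(lat) > 90) || any(abs(lon) > 180)) {
    stop("coordinates out of range")
  }
  hav <- function(p1, p2) geosphere::distHaversine(p1, p2, r = radius_km * 1000)
  m <- geosphere::distm(cbind(lon, lat), fun = hav)
  stats::as.dist(m / 1000)
}

#' Mantel test (Spearman, permutation p-value)
#'
#' Correlates the lower triangles of two distance matrices with Spearman's
#' rank correlation; significance by permuting one matrix's labels, with the
#' add-one estimator `p = (1 + #{perm r >= observed}) / (n_perm + 1)`.
#'
#' @param d1,d2 `dist` objects over the same labels.
#' @param n_perm Number of permutations, default 999.
#' @param seed Integer seed.
#' @return List (`mantel_result`) with `statistic`, `p_value`,
#'   `permutations`, `seed`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1) {
  n <- attr(d1, "Size")
  if (n < 3) stop("need at least 3 samples")
  if (n != attr(d2, "Size")) stop("distance matrices differ in size")
  set.seed(seed)
  m <- vegan::mantel(d1, d2, method = "spearman", permutations = n_perm)
  list(statistic = unname(m$statistic), p_value = m$signif,
       permutations = n_perm, seed = seed)
}

#' Distance-decay relationship with a distance breakpoint
#'
#' Community similarity (1 - dissimilarity) is regressed by least squares on
#' untransformed geographic distance, separately for pairs closer than the
#' breakpoint and pairs at or beyond it.
#'
#' @param comm `dist` of community dissimilarities.
#' @param geo `dist` of geographic distances in km (same labels).
#' @param breakpoint Breakpoint in km, default 2500.
#' @return Data frame with one row per stratum (`within`, `beyond`):
#'   `slope` (per km), `intercept`, `mean_similarity`, `n_pairs`.
#' @export
ddr <- function(comm, geo, breakpoint = 2500) {
  sim <- 1 - as.vector(comm)
  km <- as.vector(geo)
  if (length(sim) != length(km)) stop("distance matrices differ in size")
  strata <- list(within = km < breakpoint, beyond = km >= breakpoint)
  rows <- lapply(names(strata), function(s) {
    sel <- strata[[s]]
    if (sum(sel) < 2) stop("stratum '", s, "' has fewer than 2 pairs")
    fit <- stats::lm(sim[sel] ~ km[sel])
    data.frame(stratum = s, slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               mean_similarity = mean(sim[sel]), n_pairs = sum(sel),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Single-factor PERMANOVA
#'
#' Partitions the total sum of squares of a distance matrix by one grouping
#' factor (Gower-centred decomposition); reports pseudo-F, R-squared =
#' SS_between / SS_total, and an add-one permutation p-value.
#'
#' @param d `dist` object.
#' @param groups Factor (or coercible) of group labels, one per sample.
#' @param n_perm Permutations, default 999.
#' @param seed Integer seed.
#' @return List with `F`, `R2`, `p_value`, `permutations`, `seed`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1) {
  groups <- factor(groups)
  if (any(table(groups) < 2)) stop("singleton group")
  if (nlevels(groups) < 2) {
    return(list(F = NA_real_, R2 = 0, p_value = 1,
                permutations = n_perm, seed = seed))
  }
  set.seed(seed)
  fit <- vegan::adonis2(d ~ groups, permutations = n_perm)
  list(F = fit$F[1], R2 = fit$R2[1], p_value = fit$`Pr(>F)`[1],
       permutations = n_perm, seed = seed)
}

#' Principal coordinate analysis (classical scaling)
#'
#' Classical scaling of the double-centred squared-distance matrix. All
#' eigenvalues (including negative ones for non-Euclidean input) are
#' reported; coordinates span the axes with positive eigenvalues, ordered by
#' decreasing eigenvalue.
#'
#' @param d `dist` object.
#' @return List with `coordinates` (samples x axes) and `eigenvalues`.
#' @export
pcoa <- function(d) {
  n <- attr(d, "Size")
  # cmdscale warns that non-Euclidean input has fewer positive axes than
  # requested; that is expected for Bray-Curtis matrices
  fit <- withCallingHandlers(
    stats::cmdscale(d, k = n - 1, eig = TRUE),
    warning = function(w) {
      if (grepl("eigenvalues", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  npos <- sum(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig)))
  coords <- fit$points[, seq_len(min(npos, ncol(fit$points))), drop = FALSE]
  list(coordinates = coords, eigenvalues = fit$eig)
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Kruskal-Wallis H (tie-corrected, chi-square p-value) followed by Dunn's
#' pairwise z-tests with tie correction, Bonferroni-adjusted. Pairs are
#' significant when the adjusted p-value is below `alpha`.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @param alpha Significance level applied to adjusted p-values, default
#'   0.01.
#' @param correction Multiple-testing correction, default "bonferroni".
#' @return List with `H`, `p_value`, `df`, and `pairwise` (data frame:
#'   group pair, z, p, p_adj, significant).
#' @export
kruskal_dunn <- function(values, groups, alpha = 0.01,
                         correction = "bonferroni") {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (length(unique(values)) == 1) {
    lev <- levels(groups)
    pairs <- utils::combn(lev, 2)
    pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     z = 0, p = 1, p_adj = 1, significant = FALSE,
                     stringsAsFactors = FALSE)
    return(list(H = 0, p_value = 1, df = nlevels(groups) - 1, pairwise = pw))
  }
  kw <- stats::kruskal.test(values, groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ns <- table(groups)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(p) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[[p[1]]] + 1 / ns[[p[2]]]))
    (rbar[[p[1]]] - rbar[[p[2]]]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p, method = correction)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   z = unname(z), p = unname(p), p_adj = unname(p_adj),
                   significant = unname(p_adj < alpha),
                   stringsAsFactors = FALSE)
  list(H = unname(kw$statistic), p_value = kw$p.value,
       df = unname(kw$parameter), pairwise = pw)
}

#' Write / read a distance matrix as TSV
#'
#' Square form has labels as the first column and as the header; long form
#' has columns `from`, `to`, `distance` over the lower triangle.
#'
#' @param d A `dist` object.
#' @param path Output path.
#' @param format "square" or "long".
#' @return `path` invisibly (write); a `dist` (read, square form only).
#' @export
write_dist_tsv <- function(d, path, format = c("square", "long")) {
  format <- match.arg(format)
  m <- as.matrix(d)
  if (format == "square") {
    df <- data.frame(label = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    idx <- which(lower.tri(m), arr.ind = TRUE)
    df <- data.frame(from = rownames(m)[idx[, 1]], to = colnames(m)[idx[, 2]],
                     distance = m[idx])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_dist_tsv
#' @export
read_dist_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  stats::as.dist(m)
}
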