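#' Construct a count table
#'
#' Features (ASVs, OTUs, genera or species) are rows; samples are columns.
#' Each sample maps to a plant (wastewater treatment plant); replicate
#' samples of one plant share the plant id.
#'
#' @param counts Non-negative integer matrix with row and column names.
#' @param kind Feature kind: "ASV", "OTU", "genus" or "species".
#' @param plants Named character vector mapping sample name to plant id.
#' @return A `count_table` (matrix with attributes `kind` and `plants`).
#' @export
count_table <- function(counts, kind = c("ASV", "OTU", "genus", "species"),
                        plants = NULL) {
  kind <- match.arg(kind)
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate feature ids")
  if (is.null(plants)) {
    plants <- stats::setNames(colnames(counts), colnames(counts))
  }
  if (!all(colnames(counts) %in% names(plants))) {
    stop("every sample must map to a plant")
  }
  structure(counts, kind = kind, plants = plants[colnames(counts)],
            class = c("count_table", class(counts)))
}

#' Per-sample relative abundances
#'
#' @param counts Matrix, features x samples.
#' @return Matrix of proportions; each column (sample) sums to 1.
#' @export
relative_abundance <- function(counts) {
  tot <- colSums(counts)
  if (any(tot == 0)) {
    stop("zero-sum sample: ", paste(colnames(counts)[tot == 0], collapse = ", "))
  }
  out <- sweep(unclass(counts), 2, tot, "/")
  attributes(out)$plants <- attr(counts, "plants")
  out
}

#' Aggregate an ASV table to a taxonomic rank
#'
#' Counts are summed per rank name. ASVs without a name at the rank are
#' pooled into an explicit `"unclassified"` feature, which is excluded from
#' core/CRAT candidacy downstream but kept in all denominators. Column sums
#' are conserved.
#'
#' @param counts Matrix, ASVs x samples.
#' @param classifications Data frame with `id` and rank columns.
#' @param rank Target rank.
#' @return Matrix at the rank (rownames are taxon names), `plants`
#'   attribute carried over.
#' @export
aggregate_by_rank <- function(counts, classifications, rank = "genus") {
  if (!rank %in% tax_ranks()) stop("unknown rank: ", rank)
  lab <- classifications[[rank]][match(rownames(counts), classifications$id)]
  lab[is.na(lab) | !nzchar(lab)] <- "unclassified"
  out <- rowsum(unclass(counts), lab)
  attr(out, "plants") <- attr(counts, "plants")
  out
}

#' Collapse replicate samples to plant-level profiles
#'
#' Plant profiles are the mean of their replicate samples' relative
#' abundances (plants, not samples, are the denominator for core
#' assignments).
#'
#' @param rel Matrix of per-sample relative abundances, features x samples.
#' @param plants Named character vector sample -> plant; defaults to the
#'   `plants` attribute of `rel`.
#' @return Matrix, features x plants.
#' @export
plant_collapse <- function(rel, plants = attr(rel, "plants")) {
  if (is.null(plants)) stop("no sample-to-plant map available")
  plants <- plants[colnames(rel)]
  sums <- rowsum(t(rel), plants)  # plants x features, rows sorted by plant id
  t(sums / as.vector(table(plants)))
}

#' Classify taxa as core, CRAT or other
#'
#' Occupancy is the fraction of plants where the taxon exceeds `abund`
#' (strictly) in relative abundance. Tiers: strict core (occupancy > 0.8),
#' general core (> 0.5), loose core (> 0.2). Taxa not in any core tier whose
#' maximum plant abundance strictly exceeds `crat` (1%) are conditionally
#' rare or abundant taxa (CRAT); everything else is "other". The
#' "unclassified" pooled feature is never a candidate and is labelled
#' `"unclassified"`.
#'
#' @param plant_rel Matrix, taxa x plants, of plant-level relative
#'   abundances.
#' @param abund Abundance cut defining presence, default 0.001 (0.1%).
#' @param crat CRAT abundance cut, default 0.01 (1%).
#' @param occupancy Occupancy cuts `c(loose, general, strict)`, default
#'   `c(0.2, 0.5, 0.8)`.
#' @return Data frame with `taxon`, `tier`, `occupancy`, `max_abund`.
#' @export
core_crat_assign <- function(plant_rel, abund = 0.001, crat = 0.01,
                             occupancy = c(0.2, 0.5, 0.8)) {
  if (nrow(plant_rel) == 0) stop("empty table")
  occ <- rowMeans(plant_rel > abund)
  mx <- apply(plant_rel, 1, max)
  tier <- rep("other", nrow(plant_rel))
  tier[mx > crat] <- "CRAT"
  tier[occ > occupancy[1]] <- "loose"
  tier[occ > occupancy[2]] <- "general"
  tier[occ > occupancy[3]] <- "strict"
  tier[rownames(plant_rel) == "unclassified"] <- "unclassified"
  data.frame(taxon = rownames(plant_rel), tier = tier,
             occupancy = unname(occ), max_abund = unname(mx),
             stringsAsFactors = FALSE)
}

#' Cumulative abundance of core/CRAT groups per plant group
#'
#' For each group of plants (e.g. process type), sums the mean relative
#' abundance of taxa per tier (strict, general, loose, CRAT, other,
#' unclassified). Tiers are disjoint, so shares sum to 100%.
#'
#' @param assignments Output of [core_crat_assign()].
#' @param plant_rel Matrix, taxa x plants, plant-level relative abundances.
#' @param groups Named character vector plant -> group; a single group is
#'   used when NULL.
#' @return Data frame: `group`, `tier`, `n_taxa`, `share_pct`.
#' @export
cumulative_group_abundance <- function(assignments, plant_rel, groups = NULL) {
  if (is.null(groups)) {
    groups <- stats::setNames(rep("all", ncol(plant_rel)), colnames(plant_rel))
  }
  groups <- groups[colnames(plant_rel)]
  tiers <- c("strict", "general", "loose", "CRAT", "other", "unclassified")
  tier <- stats::setNames(assignments$tier, assignments$taxon)[rownames(plant_rel)]
  rows <- list()
  for (g in unique(groups)) {
    sub <- plant_rel[, groups == g, drop = FALSE]
    mean_ab <- rowMeans(sub)
    for (tr in tiers) {
      sel <- tier == tr
      rows[[length(rows) + 1]] <- data.frame(
        group = g, tier = tr, n_taxa = sum(sel),
        share_pct = 100 * sum(mean_ab[sel]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Compare genus abundances between two primer sets
#'
#' Genera at or above `min_abund` mean relative abundance in either primer
#' set are kept. The fold ratio is `mean_v13 / mean_v4` with zero means
#' replaced by the pseudo-abundance `eps`; genera with ratio >= 2 are
#' V1-V3-preferential, <= 0.5 V4-preferential, otherwise neutral.
#'
#' @param mean_v13,mean_v4 Named numeric vectors of mean relative abundances
#'   (fractions) per genus.
#' @param min_abund Keep filter, default 1e-5 (0.001%).
#' @param fold Fold-change boundary, default 2.
#' @param eps Pseudo-abundance for zeros, default 1e-6.
#' @return Data frame: `genus`, `mean_v13`, `mean_v4`, `ratio`, `category`.
#' @export
primer_bias_compare <- function(mean_v13, mean_v4, min_abund = 1e-5,
                                fold = 2, eps = 1e-6) {
  genera <- union(names(mean_v13), names(mean_v4))
  a <- stats::setNames(rep(0, length(genera)), genera)
  b <- a
  a[names(mean_v13)] <- mean_v13
  b[names(mean_v4)] <- mean_v4
  keep <- a >= min_abund | b >= min_abund
  a <- a[keep]; b <- b[keep]
  ratio <- pmax(a, eps) / pmax(b, eps)
  category <- ifelse(ratio >= fold, "V1V3",
                     ifelse(ratio <= 1 / fold, "V4", "neutral"))
  data.frame(genus = names(a), mean_v13 = unname(a), mean_v4 = unname(b),
             ratio = unname(ratio), category = unname(category),
             stringsAsFactors = FALSE)
}

#' Discretize plant metadata into the standard bins
#'
#' Temperature (deg C): very low (1.8-10.0], low (10.0-15.0], moderate
#' (15.0-20.0], high (20.0-25.0], very high (25.0-30.0], extremely high
#' (30.0-38.0]; values outside 1.8-38.0 become "unbinned". Industrial load
#' (% of influent COD): none (0), very low (0-10], low (10-30), medium
#' [30-50], high (50-100), all (100); negative or >100 become "unbinned".
#'
#' @param meta Data frame with numeric columns `temperature` and
#'   `industrial_cod`.
#' @return `meta` with added factor columns `temperature_bin` and
#'   `industrial_bin`.
#' @export
bin_metadata <- function(meta) {
  tlev <- c("very low", "low", "moderate", "high", "very high",
            "extremely high", "unbinned")
  tbin <- as.character(cut(meta$temperature,
                           breaks = c(1.8, 10, 15, 20, 25, 30, 38),
                           labels = tlev[1:6], include.lowest = TRUE))
  tbin[is.na(tbin)] <- "unbinned"
  x <- meta$industrial_cod
  ibin <- rep("unbinned", length(x))
  ibin[x == 0] <- "none"
  ibin[x > 0 & x <= 10] <- "very low"
  ibin[x > 10 & x < 30] <- "low"
  ibin[x >= 30 & x <= 50] <- "medium"
  ibin[x > 50 & x < 100] <- "high"
  ibin[x == 100] <- "all"
  meta$temperature_bin <- factor(tbin, levels = tlev)
  meta$industrial_bin <- factor(ibin, levels = c("none", "very low", "low",
                                                 "medium", "high", "all",
                                                 "unbinned"))
  meta
}
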