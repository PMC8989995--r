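#' Parameters for the bootstrap k-mer classifier
#'
#' @param kmer_size K-mer length, default 8.
#' @param subsample K-mers drawn (without replacement) per bootstrap from the
#'   query's distinct k-mer set, default 32 (capped at the number of distinct
#'   k-mers).
#' @param bootstraps Number of bootstrap draws, default 100.
#' @param confidence_cutoff Minimum per-rank confidence for a rank name to be
#'   reported (inclusive), default 0.8.
#' @param strand `"plus"` assumes pre-oriented queries; `"both"` also scores
#'   the reverse complement and keeps the better orientation.
#' @return List of classifier parameters.
#' @export
classifier_params <- function(kmer_size = 8, subsample = 32, bootstraps = 100,
                              confidence_cutoff = 0.8,
                              strand = c("plus", "both")) {
  strand <- match.arg(strand)
  stopifnot(confidence_cutoff > 0, confidence_cutoff <= 1,
            kmer_size >= 1, subsample >= 1, bootstraps >= 1)
  list(kmer_size = kmer_size, subsample = subsample, bootstraps = bootstraps,
       confidence_cutoff = confidence_cutoff, strand = strand)
}

#' Build a k-mer index over a reference database
#'
#' @param refs Named character vector of reference sequences.
#' @param taxonomy Data frame with `id` and the seven rank columns.
#' @param kmer_size K-mer length, default 8.
#' @return A `kmer_index` object (sparse k-mer-by-reference membership
#'   matrix plus taxonomy), for use with [classify()].
#' @export
build_kmer_index <- function(refs, taxonomy, kmer_size = 8) {
  stopifnot(length(refs) > 0, !is.null(names(refs)))
  ranks <- tax_ranks()
  stopifnot(all(c("id", ranks) %in% names(taxonomy)))
  ids <- sort(names(refs))
  refs <- refs[ids]
  km <- lapply(refs, kmer_codes, k = kmer_size)
  i <- unlist(km) + 1L
  j <- rep(seq_along(km), lengths(km))
  mat <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                              dims = c(4^kmer_size, length(refs)))
  tax <- taxonomy[match(ids, taxonomy$id), ranks, drop = FALSE]
  structure(list(mat = mat, ids = ids, tax = tax, kmer_size = kmer_size),
            class = "kmer_index")
}

classify_one <- function(seq, index, params) {
  k <- index$kmer_size
  if (nchar(seq) < k) stop("query shorter than k-mer size")
  kms <- kmer_codes(seq, k) + 1L
  nboot <- params$bootstraps
  sub <- min(params$subsample, length(kms))
  nref <- length(index$ids)
  votes <- integer(nboot)
  for (b in seq_len(nboot)) {
    pick <- if (length(kms) == 1) kms else sample(kms, sub)
    counts <- Matrix::colSums(index$mat[pick, , drop = FALSE])
    best <- which(counts == max(counts))
    votes[b] <- if (length(best) == 1) best else sample(best, 1)
  }
  ranks <- tax_ranks()
  conf <- numeric(7)
  name <- character(7)
  for (ri in seq_along(ranks)) {
    nm <- index$tax[[ranks[ri]]][votes]
    tabs <- table(nm)
    top <- names(tabs)[which.max(tabs)]
    name[ri] <- top
    conf[ri] <- max(tabs) / nboot
  }
  keep <- conf >= params$confidence_cutoff
  # truncate at the first rank failing the cutoff
  if (any(!keep)) keep[seq(7) >= which(!keep)[1]] <- FALSE
  name[!keep] <- NA_character_
  list(name = name, confidence = conf)
}

#' Bootstrap k-mer taxonomic classification
#'
#' SINTAX-style classifier: per bootstrap, `subsample` k-mers are drawn
#' uniformly without replacement from the query's distinct k-mer set and the
#' reference sharing most of them wins (ties broken uniformly at random).
#' Per-rank confidence is the fraction of bootstraps voting for that rank
#' name; the reported label is truncated at the first rank whose confidence
#' falls below the cutoff (the cutoff itself is retained, strictly lower
#' confidence is not). Seeded and reproducible.
#'
#' @param queries Named character vector of query sequences (pre-oriented
#'   unless `strand = "both"`).
#' @param index A [build_kmer_index()] object.
#' @param params A [classifier_params()] list.
#' @param seed Integer seed.
#' @return List with `taxonomy` (data frame: `id` + rank columns, NA where
#'   truncated) and `confidence` (matrix, queries x ranks).
#' @export
classify <- function(queries, index, params = classifier_params(), seed = 1) {
  stopifnot(inherits(index, "kmer_index"))
  if (is.null(names(queries))) names(queries) <- paste0("Q", seq_along(queries))
  ranks <- tax_ranks()
  set.seed(seed)
  res_names <- matrix(NA_character_, length(queries), 7,
                      dimnames = list(names(queries), ranks))
  res_conf <- matrix(NA_real_, length(queries), 7,
                     dimnames = list(names(queries), ranks))
  for (i in seq_along(queries)) {
    q <- queries[[i]]
    r <- classify_one(q, index, params)
    if (params$strand == "both") {
      r2 <- classify_one(revcomp(q), index, params)
      if (sum(r2$confidence) > sum(r$confidence)) r <- r2
    }
    res_names[i, ] <- r$name
    res_conf[i, ] <- r$confidence
  }
  tax <- data.frame(id = names(queries), res_names,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(taxonomy = tax, confidence = res_conf)
}

#' Box-plot summary statistics for per-sample percentages
#'
#' Mean, SD, median, quartiles, and whisker bounds at 1.5x the interquartile
#' range (whiskers are the min and max of the values inside the fences).
#'
#' @param x Numeric vector of per-sample percentages.
#' @return One-row data frame of summary statistics.
#' @export
box_stats <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- x[x >= lo & x <= hi]
  data.frame(mean = mean(x), sd = stats::sd(x), median = q[2],
             q25 = q[1], q75 = q[3],
             whisker_low = min(inside), whisker_high = max(inside),
             n = length(x))
}

filter_by_abundance <- function(counts, min_abund) {
  rel <- sweep(counts, 2, colSums(counts), "/")
  rel >= min_abund
}

#' Database coverage evaluation (high-identity hits)
#'
#' Per sample, ASVs are filtered to those with relative abundance at or
#' above `min_abund` (relative to all reads in the sample); coverage is the
#' percentage of kept ASVs whose exhaustive top-hit identity against the
#' database is at or above `min_ident`. Samples with no kept ASVs are
#' excluded with a warning.
#'
#' @param counts Integer matrix, ASVs x samples (rownames = ASV ids).
#' @param asv_seqs Named character vector of ASV sequences.
#' @param db_seqs Named character vector of database sequences.
#' @param min_abund Relative-abundance filter, default 1e-4 (0.01%).
#' @param min_ident Identity cutoff, default 0.99.
#' @return List with `per_sample` (data frame: sample, coverage) and
#'   `summary` ([box_stats()] row).
#' @export
coverage_eval <- function(counts, asv_seqs, db_seqs,
                          min_abund = 1e-4, min_ident = 0.99) {
  stopifnot(all(rownames(counts) %in% names(asv_seqs)))
  keep <- filter_by_abundance(counts, min_abund)
  used <- rownames(counts)[rowSums(keep) > 0]
  hits <- top_hit(asv_seqs[used], db_seqs)
  good <- stats::setNames(hits$identity >= min_ident, hits$query)
  cov <- vapply(seq_len(ncol(counts)), function(s) {
    ids <- rownames(counts)[keep[, s]]
    if (length(ids) == 0) return(NA_real_)
    100 * mean(good[ids])
  }, 0)
  names(cov) <- colnames(counts)
  if (anyNA(cov)) {
    warning("samples with no ASVs above the abundance filter were excluded: ",
            paste(names(cov)[is.na(cov)], collapse = ", "))
    cov <- cov[!is.na(cov)]
  }
  list(per_sample = data.frame(sample = names(cov), coverage = unname(cov),
                               stringsAsFactors = FALSE),
       summary = box_stats(unname(cov)))
}

#' Classification-rate evaluation
#'
#' Per sample (after the same abundance filter as [coverage_eval()]), the
#' percentage of kept ASVs carrying a name at the given rank in the
#' (confidence-truncated) classifications. De novo placeholder names count
#' as classified.
#'
#' @param counts Integer matrix, ASVs x samples.
#' @param classifications Data frame with `id` and rank columns (NA where
#'   truncated), e.g. `classify()$taxonomy`.
#' @param rank Rank to evaluate ("genus" or "species", any rank accepted).
#' @param min_abund Relative-abundance filter, default 1e-4.
#' @return List with `per_sample` and `summary` as in [coverage_eval()].
#' @export
classification_rate_eval <- function(counts, classifications, rank = "genus",
                                     min_abund = 1e-4) {
  stopifnot(rank %in% tax_ranks())
  keep <- filter_by_abundance(counts, min_abund)
  lab <- stats::setNames(classifications[[rank]], classifications$id)
  rate <- vapply(seq_len(ncol(counts)), function(s) {
    ids <- rownames(counts)[keep[, s]]
    if (length(ids) == 0) return(NA_real_)
    has <- !is.na(lab[ids]) & nzchar(lab[ids])
    has[is.na(has)] <- FALSE
    100 * mean(has)
  }, 0)
  names(rate) <- colnames(counts)
  if (anyNA(rate)) {
    warning("samples with no ASVs above the abundance filter were excluded: ",
            paste(names(rate)[is.na(rate)], collapse = ", "))
    rate <- rate[!is.na(rate)]
  }
  list(per_sample = data.frame(sample = names(rate), rate = unname(rate),
                               stringsAsFactors = FALSE),
       summary = box_stats(unname(rate)))
}

#' Compare reference databases on the same amplicon dataset
#'
#' Runs [coverage_eval()] and [classification_rate_eval()] (genus and
#' species) for each database and returns a long-format summary.
#'
#' @param counts Integer matrix, ASVs x samples.
#' @param asv_seqs Named character vector of ASV sequences.
#' @param databases Named list; each element a list with `seqs` (named
#'   character vector) and `taxonomy` (data frame with `id` + ranks).
#' @param params Classifier parameters.
#' @param min_abund,min_ident Filters as in [coverage_eval()].
#' @param seed Seed for the classifier.
#' @return Data frame with one row per database x metric, including mean,
#'   sd and box statistics across samples.
#' @export
compare_databases <- function(counts, asv_seqs, databases,
                              params = classifier_params(),
                              min_abund = 1e-4, min_ident = 0.99, seed = 1) {
  stopifnot(length(databases) >= 1, !is.null(names(databases)))
  rows <- list()
  for (nm in names(databases)) {
    dbx <- databases[[nm]]
    cov <- coverage_eval(counts, asv_seqs, dbx$seqs, min_abund, min_ident)
    idx <- build_kmer_index(dbx$seqs, dbx$taxonomy, params$kmer_size)
    cls <- classify(asv_seqs, idx, params, seed = seed)
    gen <- classification_rate_eval(counts, cls$taxonomy, "genus", min_abund)
    spc <- classification_rate_eval(counts, cls$taxonomy, "species", min_abund)
    for (met in c("coverage", "genus_rate", "species_rate")) {
      s <- switch(met, coverage = cov, genus_rate = gen, species_rate = spc)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(database = nm, metric = met, stringsAsFactors = FALSE),
        s$summary)
    }
  }
  do.call(rbind, rows)
}
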