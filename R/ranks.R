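#' Taxonomic ranks used throughout the package
#'
#' Seven ranks from domain to species, in order.
#' @return Character vector of rank names.
#' @export
tax_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus", "species")
}

#' Rank-specific 16S rRNA identity thresholds
#'
#' Identity thresholds (percent) below which a sequence is considered novel at
#' a given rank, and at-or-above which a rank name may be inherited from the
#' closest typed relative: phylum 75.0, class 78.5, order 82.0, family 86.5,
#' genus 94.5, species 98.7. The domain rank carries no threshold and is
#' always inherited.
#'
#' @return Named numeric vector (percent identity), one entry per rank below
#'   domain, strictly increasing from phylum to species.
#' @export
rank_thresholds <- function() {
  c(phylum = 75.0, class = 78.5, order = 82.0, family = 86.5,
    genus = 94.5, species = 98.7)
}

#' Single-letter rank codes used in de novo placeholder names
#' @return Named character vector mapping rank name to its code.
#' @export
rank_codes <- function() {
  c(phylum = "p", class = "c", order = "o", family = "f",
    genus = "g", species = "s")
}

#' Mint a de novo placeholder name
#'
#' Placeholder taxa follow the `<prefix>_<r>_<n>` grammar with `r` the
#' single-letter rank code and `n` a positive integer, e.g. `midas_g_123`.
#'
#' @param rank Rank name (phylum..species).
#' @param n Positive integer.
#' @param prefix Placeholder prefix, default `"midas"`.
#' @return Placeholder name string.
#' @export
denovo_name <- function(rank, n, prefix = "midas") {
  code <- rank_codes()[[rank]]
  sprintf("%s_%s_%d", prefix, code, as.integer(n))
}

#' Test whether names are de novo placeholders at a given rank
#' @param x Character vector of taxon names.
#' @param rank Rank name, or NULL to match any rank code.
#' @param prefix Placeholder prefix.
#' @return Logical vector.
#' @export
is_denovo_name <- function(x, rank = NULL, prefix = "midas") {
  code <- if (is.null(rank)) "[pcofgs]" else rank_codes()[[rank]]
  grepl(sprintf("^%s_%s_[0-9]+$", prefix, code), x)
}

#' Rounded percentage as reported in novelty tables
#'
#' Percentages are reported as 100 * count / total rounded to two decimals.
#'
#' @param count Numerator count(s).
#' @param total Denominator.
#' @return Numeric percentage(s), rounded to 2 decimals.
#' @export
novelty_percent <- function(count, total) {
  stopifnot(total > 0)
  round(100 * count / total, 2)
}
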