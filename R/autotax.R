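#' Inherit taxonomy from the closest typed relative by identity thresholds
#'
#' Each query is mapped against the typed reference set with [top_hit()]
#' (exhaustive, maximum identity, smallest-id ties). Rank names are inherited
#' from the best hit from domain downward while `100 * identity` is at or
#' above the rank threshold; ranks strictly below their threshold are left
#' unassigned (`NA`). Domain is always inherited.
#'
#' @param queries Named character vector of query sequences.
#' @param refs Named character vector of typed reference sequences.
#' @param ref_taxonomy Data frame with `id` and the seven rank columns for
#'   the references.
#' @param thresholds Named percent thresholds, see [rank_thresholds()].
#' @return Data frame with `id`, the seven rank columns (NA where
#'   unassigned), `best_hit`, `identity` (fraction) and `tie_count`.
#' @export
assign_inherited <- function(queries, refs, ref_taxonomy,
                             thresholds = rank_thresholds()) {
  if (length(refs) == 0) stop("empty typed reference set")
  ranks <- tax_ranks()
  stopifnot(all(c("id", ranks) %in% names(ref_taxonomy)))
  hits <- top_hit(queries, refs)
  m <- ref_taxonomy[match(hits$ref, ref_taxonomy$id), ranks, drop = FALSE]
  pct <- 100 * hits$identity
  for (r in names(thresholds)) {
    m[[r]][pct < thresholds[[r]]] <- NA_character_
  }
  out <- data.frame(id = hits$query, m,
                    best_hit = hits$ref, identity = hits$identity,
                    tie_count = hits$tie_count,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Mint de novo placeholder names for unassigned ranks
#'
#' Works top-down from phylum to species. At each rank, sequences that are
#' unassigned at that rank are greedily clustered at the rank's identity
#' threshold (first-come centroid, database order), scoped within their
#' parent taxon so that, for example, a de novo genus can never appear under
#' two different families. Each new cluster receives the next
#' `<prefix>_<r>_<n>` name (a per-rank counter shared across parents), and
#' members inherit the centroid's name. Deterministic for a given input
#' order.
#'
#' @param seqs Named character vector of database sequences, in database
#'   (id) order.
#' @param partial Data frame as returned by [assign_inherited()] for `seqs`,
#'   in the same order.
#' @param thresholds Named percent thresholds.
#' @param prefix Placeholder prefix, default "midas".
#' @return Data frame with `id`, the seven (complete) rank columns and
#'   logical `denovo_<rank>` flag columns.
#' @export
mint_denovo <- function(seqs, partial, thresholds = rank_thresholds(),
                        prefix = "midas") {
  ranks <- tax_ranks()
  stopifnot(identical(partial$id, names(seqs)))
  tax <- partial[ranks]
  n <- nrow(tax)
  flags <- as.data.frame(matrix(FALSE, n, 7, dimnames = list(NULL, paste0("denovo_", ranks))))
  for (r in names(thresholds)) {
    counter <- 0L
    thr <- thresholds[[r]] / 100
    parent_rank <- ranks[match(r, ranks) - 1]
    todo <- which(is.na(tax[[r]]))
    if (length(todo) == 0) next
    # centroids per parent lineage, in creation order
    cent_idx <- list()
    for (i in todo) {
      parent <- tax[[parent_rank]][i]
      key <- parent
      hit <- NA_integer_
      for (ci in cent_idx[[key]]) {
        if (global_identity(seqs[[i]], seqs[[ci]]) >= thr) {
          hit <- ci
          break
        }
      }
      if (is.na(hit)) {
        counter <- counter + 1L
        tax[[r]][i] <- denovo_name(r, counter, prefix)
        cent_idx[[key]] <- c(cent_idx[[key]], i)
      } else {
        tax[[r]][i] <- tax[[r]][hit]
      }
      flags[[paste0("denovo_", r)]][i] <- TRUE
    }
  }
  data.frame(id = partial$id, tax, flags, stringsAsFactors = FALSE)
}

#' Assign complete seven-rank taxonomy to a database
#'
#' Convenience wrapper: [assign_inherited()] followed by [mint_denovo()].
#'
#' @inheritParams assign_inherited
#' @inheritParams mint_denovo
#' @return Data frame with `id`, complete rank columns, `denovo_*` flags,
#'   `best_hit` and `identity`.
#' @export
assign_taxonomy <- function(queries, refs, ref_taxonomy,
                            thresholds = rank_thresholds(), prefix = "midas") {
  part <- assign_inherited(queries, refs, ref_taxonomy, thresholds)
  full <- mint_denovo(queries, part, thresholds, prefix)
  full$best_hit <- part$best_hit
  full$identity <- part$identity
  full
}

#' Sequence- and taxonomy-novelty table
#'
#' For each rank below domain: the number (and percentage of the database) of
#' sequences whose best identity to the typed set is strictly below the rank
#' threshold, and the number (and percentage of observed taxa at that rank)
#' of distinct de novo placeholder taxa. Percentages are rounded to two
#' decimals.
#'
#' @param taxonomy Complete taxonomy as from [assign_taxonomy()] (needs the
#'   rank columns and `identity`).
#' @param thresholds Named percent thresholds.
#' @param prefix Placeholder prefix used for de novo names.
#' @return Data frame with one row per rank: `rank`, `threshold`,
#'   `novel_sequences`, `novel_sequences_pct`, `denovo_taxa`,
#'   `denovo_taxa_pct`.
#' @export
novelty_table <- function(taxonomy, thresholds = rank_thresholds(),
                          prefix = "midas") {
  n <- nrow(taxonomy)
  pct <- 100 * taxonomy$identity
  rows <- lapply(names(thresholds), function(r) {
    novel <- sum(pct < thresholds[[r]])
    taxa <- unique(taxonomy[[r]])
    dn <- sum(is_denovo_name(taxa, r, prefix))
    data.frame(
      rank = r, threshold = thresholds[[r]],
      novel_sequences = novel,
      novel_sequences_pct = novelty_percent(novel, n),
      denovo_taxa = dn,
      denovo_taxa_pct = novelty_percent(dn, length(taxa)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
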