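#' Resolve full-length ASVs from reads by exact dereplication
#'
#' Exact (string-identical) dereplication of oriented, primer-trimmed
#' full-length reads. Variants supported by at least `min_copies` identical
#' reads are retained (singletons are discarded at the default of 2), sorted
#' by decreasing count and then by sequence.
#'
#' @param reads Character vector of read sequences.
#' @param min_copies Minimum identical copies required, default 2.
#' @return Data frame with columns `seq` and `count`.
#' @export
resolve_flasvs <- function(reads, min_copies = 2) {
  if (length(reads) == 0) {
    return(data.frame(seq = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  reads <- normalize_seq(reads)
  tab <- table(reads)
  keep <- tab[tab >= min_copies]
  out <- data.frame(seq = names(keep), count = as.integer(keep),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

db_hash <- function(seqs) {
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeLines(seqs, tmp)
  unname(tools::md5sum(tmp))
}

#' Create an empty reference database
#'
#' A reference database is an append-only, ordered collection of unique
#' full-length ASV sequences with stable `FLASV<k>` ids, a content-hashed
#' version string and a provenance log of every merge.
#'
#' @return A `refdb` object.
#' @export
new_refdb <- function() {
  db <- list(
    flasv = data.frame(id = character(0), seq = character(0),
                       source_version = character(0), stringsAsFactors = FALSE),
    next_k = 1L,
    version = db_hash(character(0)),
    provenance = character(0)
  )
  class(db) <- "refdb"
  db
}

#' @export
print.refdb <- function(x, ...) {
  cat(sprintf("<refdb> %d FL-ASVs, version %s\n", nrow(x$flasv), x$version))
  invisible(x)
}

#' Number of FL-ASVs in a database
#' @param x A `refdb`.
#' @return Integer count.
#' @export
db_size <- function(x) nrow(x$flasv)

#' Merge dereplicated sequences into a reference database
#'
#' Sequences already present verbatim are skipped; novel sequences are
#' appended with the next sequential `FLASV<k>` ids. Existing entries and
#' their ids are never touched, so ids are stable across any merge history.
#' The input must be pre-dereplicated (duplicates within `new` are an error).
#'
#' @param db A `refdb`.
#' @param new Character vector of dereplicated sequences.
#' @param label Provenance label recorded for this merge.
#' @return Updated `refdb`.
#' @export
merge_into_database <- function(db, new, label = "merge") {
  stopifnot(inherits(db, "refdb"))
  new <- normalize_seq(new)
  if (anyDuplicated(new)) stop("duplicate sequences in input; dereplicate first")
  novel <- setdiff(new, db$flasv$seq)
  novel <- new[new %in% novel]  # keep input order
  if (length(novel) > 0) {
    ks <- seq(db$next_k, length.out = length(novel))
    add <- data.frame(id = sprintf("FLASV%d", ks), seq = novel,
                      source_version = label, stringsAsFactors = FALSE)
    db$flasv <- rbind(db$flasv, add)
    db$next_k <- db$next_k + length(novel)
  }
  db$version <- db_hash(db$flasv$seq)
  db$provenance <- c(db$provenance,
                     sprintf("%s: +%d new, %d skipped, %d total", label,
                             length(novel), length(new) - length(novel),
                             nrow(db$flasv)))
  db
}

check_tax_names <- function(tax) {
  bad <- vapply(tax, function(col) any(grepl("[,;\t]", col)), NA)
  if (any(bad)) {
    stop("taxon names may not contain ',', ';' or tabs (rank: ",
         names(tax)[bad][1], ")")
  }
}

tax_matrix <- function(db, taxonomy) {
  ranks <- tax_ranks()
  stopifnot(all(c("id", ranks) %in% names(taxonomy)))
  m <- taxonomy[match(db$flasv$id, taxonomy$id), ranks, drop = FALSE]
  if (any(is.na(m)) || any(m == "")) {
    miss <- db$flasv$id[apply(is.na(m) | m == "", 1, any)]
    stop("incomplete taxonomy for record: ", miss[1])
  }
  check_tax_names(m)
  m
}

#' Export a reference database with taxonomy
#'
#' Three dialects are supported:
#' * `sintax`: one FASTA, headers
#'   `>FLASVk;tax=d:...,p:...,c:...,o:...,f:...,g:...,s:...;`
#' * `qiime`: a FASTA plus a two-column TSV with
#'   `d__...; p__...; c__...; o__...; f__...; g__...; s__...`
#' * `dada2`: a FASTA whose header is the semicolon-joined lineage.
#'
#' Every record needs a complete seven-rank taxonomy; names containing the
#' dialect delimiters are rejected. Re-importing each dialect with
#' [import_database()] reproduces the database.
#'
#' @param db A `refdb`.
#' @param taxonomy Data frame with columns `id` and the seven ranks.
#' @param dialect One of "sintax", "qiime", "dada2".
#' @param path Output path; for qiime the taxonomy TSV is written next to it
#'   with extension `.tax.tsv`.
#' @return Character vector of files written, invisibly.
#' @export
export_database <- function(db, taxonomy, dialect = c("sintax", "qiime", "dada2"),
                            path) {
  dialect <- match.arg(dialect)
  m <- tax_matrix(db, taxonomy)
  ids <- db$flasv$id
  seqs <- db$flasv$seq
  files <- path
  if (dialect == "sintax") {
    codes <- c("d", "p", "c", "o", "f", "g", "s")
    tax <- apply(m, 1, function(r) paste0(codes, ":", r, collapse = ","))
    hdr <- sprintf("%s;tax=%s;", ids, tax)
    write_fasta(stats::setNames(seqs, hdr), path)
  } else if (dialect == "qiime") {
    write_fasta(stats::setNames(seqs, ids), path)
    codes <- c("d", "p", "c", "o", "f", "g", "s")
    tax <- apply(m, 1, function(r) paste0(codes, "__", r, collapse = "; "))
    taxfile <- paste0(sub("\\.fa(sta)?$", "", path), ".tax.tsv")
    utils::write.table(data.frame(ids, tax), taxfile, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    files <- c(path, taxfile)
  } else {
    hdr <- apply(m, 1, paste, collapse = ";")
    write_fasta(stats::setNames(seqs, hdr), path)
  }
  invisible(files)
}

#' Import a reference database exported with [export_database()]
#'
#' @param path FASTA path (for qiime, the `.tax.tsv` file is expected next to
#'   it as written by the export).
#' @param dialect One of "sintax", "qiime", "dada2". The dada2 dialect does
#'   not carry record ids, so ids are regenerated sequentially in file order.
#' @return List with `db` (a `refdb`) and `taxonomy` (data frame).
#' @export
import_database <- function(path, dialect = c("sintax", "qiime", "dada2")) {
  dialect <- match.arg(dialect)
  seqs <- read_fasta(path)
  ranks <- tax_ranks()
  if (dialect == "sintax") {
    ids <- sub(";tax=.*$", "", names(seqs))
    tax <- sub("^.*;tax=", "", sub(";$", "", names(seqs)))
    parts <- strsplit(tax, ",")
    m <- t(vapply(parts, function(p) sub("^[a-z]:", "", p), character(7)))
  } else if (dialect == "qiime") {
    ids <- names(seqs)
    taxfile <- paste0(sub("\\.fa(sta)?$", "", path), ".tax.tsv")
    tt <- utils::read.table(taxfile, sep = "\t", stringsAsFactors = FALSE)
    tt <- tt[match(ids, tt[[1]]), ]
    parts <- strsplit(tt[[2]], "; ")
    m <- t(vapply(parts, function(p) sub("^[a-z]__", "", p), character(7)))
  } else {
    ids <- sprintf("FLASV%d", seq_along(seqs))
    parts <- strsplit(names(seqs), ";")
    m <- t(vapply(parts, function(p) p[seq_len(7)], character(7)))
  }
  colnames(m) <- ranks
  taxonomy <- data.frame(id = ids, m, stringsAsFactors = FALSE)
  db <- new_refdb()
  db$flasv <- data.frame(id = ids, seq = unname(seqs),
                         source_version = "import", stringsAsFactors = FALSE)
  ks <- suppressWarnings(as.integer(sub("^FLASV", "", ids)))
  db$next_k <- if (all(!is.na(ks))) max(ks) + 1L else length(ids) + 1L
  db$version <- db_hash(db$flasv$seq)
  db$provenance <- sprintf("import (%s): %d records", dialect, length(ids))
  list(db = db, taxonomy = taxonomy)
}

#' Effective sequencing concentration for read-tag library size normalisation
#'
#' Empirical formula converting a library fraction's peak molarity and peak
#' fragment size into the effective sequencing concentration used for
#' equimolar pooling:
#' `C_seq = peak_molarity * 0.0124 * (215 - peak_size) + 10.332`.
#'
#' @param peak_molarity Peak molarity in pmol/l (non-negative).
#' @param peak_size Peak fragment size in bp, in (0, 1500].
#' @return Effective concentration in pmol/l.
#' @export
effective_seq_concentration <- function(peak_molarity, peak_size) {
  if (any(peak_molarity < 0)) stop("peak_molarity must be non-negative")
  if (any(peak_size <= 0 | peak_size > 1500)) {
    stop("peak_size must be in (0, 1500] bp")
  }
  peak_molarity * 0.0124 * (215 - peak_size) + 10.332
}
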