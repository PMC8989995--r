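#' @useDynLib asvref, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

normalize_seq <- function(x) {
  x <- toupper(x)
  chartr("U", "T", x)
}

#' Read a FASTA file
#'
#' Sequences are normalized to uppercase and U is converted to T. Leading
#' comment lines starting with `;` (used to carry seeds in files emitted by
#' the synthetic generator) are ignored. `;size=N` abundance annotations are
#' kept as part of the record id and can be parsed with [parse_size()].
#'
#' @param path Path to a FASTA file.
#' @param alphabet Allowed residue alphabet after normalization; records with
#'   other characters raise an error naming the record.
#' @return Named character vector of sequences (names are record ids).
#' @export
read_fasta <- function(path, alphabet = c("strict", "iupac")) {
  alphabet <- match.arg(alphabet)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, ";")]
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  set <- Biostrings::readBStringSet(tmp)
  seqs <- normalize_seq(as.character(set))
  names(seqs) <- names(set)
  if (any(!nzchar(seqs))) {
    stop("empty FASTA record: ", names(seqs)[!nzchar(seqs)][1])
  }
  pat <- if (alphabet == "strict") "^[ACGT]+$" else
    sprintf("^[%s]+$", paste(names(IUPAC_SETS), collapse = ""))
  bad <- !grepl(pat, seqs)
  if (any(bad)) {
    stop("non-IUPAC residues in record: ", names(seqs)[bad][1])
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param seed Optional integer; when given, a `; seed=<seed>` comment line
#'   is written at the top of the file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, seed = NULL) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("; seed=%d", as.integer(seed)), con)
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), con)
  invisible(path)
}

#' Parse `;size=N` abundance annotations
#' @param ids Character vector of record ids.
#' @return Integer vector of sizes (1 where no annotation is present).
#' @export
parse_size <- function(ids) {
  m <- regmatches(ids, regexpr(";size=[0-9]+", ids))
  out <- rep(1L, length(ids))
  has <- grepl(";size=[0-9]+", ids)
  out[has] <- as.integer(sub(";size=", "", m))
  out
}

#' Reverse complement
#' @param x Character vector of IUPAC DNA strings.
#' @return Reverse-complemented strings.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

#' Standard primer sets
#'
#' Returns the default degenerate primer pairs: V1V3 27F/534R, V4 515F/806R,
#' and FL (full length) 27F/1391R. `max_mismatch` defaults to 2 for
#' full-length trimming and 0 for in-silico extraction of amplicon regions.
#'
#' @param name One of "V1V3", "V4", "FL".
#' @return List with `name`, `forward`, `reverse`, `max_mismatch`.
#' @export
primer_set <- function(name = c("V1V3", "V4", "FL")) {
  name <- match.arg(name)
  switch(name,
    V1V3 = list(name = "V1V3", forward = "AGAGTTTGATCCTGGCTCAG",
                reverse = "ATTACCGCGGCTGCTGG", max_mismatch = 0L),
    V4   = list(name = "V4", forward = "GTGYCAGCMGCCGCGGTAA",
                reverse = "GGACTACNVGGGTWTCTAAT", max_mismatch = 0L),
    FL   = list(name = "FL", forward = "AGAGTTTGATCCTGGCTCAG",
                reverse = "GACGGGCGGTGTGTRCA", max_mismatch = 2L)
  )
}

#' Count mismatches of a window against an IUPAC primer
#'
#' A position counts as a mismatch when the window base is not in the base
#' set of the primer's IUPAC code at that position.
#'
#' @param primer IUPAC DNA string.
#' @param window Plain DNA string of the same length.
#' @return Integer mismatch count.
#' @export
iupac_match <- function(primer, window) {
  p <- strsplit(toupper(primer), "")[[1]]
  w <- strsplit(toupper(window), "")[[1]]
  if (length(p) != length(w)) stop("primer and window lengths differ")
  bad <- !vapply(seq_along(p), function(i) w[i] %in% IUPAC_SETS[[p[i]]], NA)
  sum(bad)
}

#' Locate a primer binding site in a sequence
#'
#' Scans windows of primer length and returns the leftmost start position
#' whose mismatch count is within `max_mismatch`, or `NA` when no such
#' window exists. The scan is restricted to `search_window` positions from
#' the chosen end (primer sites are terminal in amplicons).
#'
#' @param seq DNA string.
#' @param primer IUPAC DNA string.
#' @param max_mismatch Maximum allowed mismatches.
#' @param search_window Number of candidate start positions scanned, counted
#'   from the start (`from = "start"`) or such that the site ends within the
#'   last `search_window` bases (`from = "end"`). `Inf` scans everywhere.
#' @param from Which end the window is anchored at.
#' @return List with `pos` (start, 1-based, or NA) and `mismatches`.
#' @export
find_primer_site <- function(seq, primer, max_mismatch = 0,
                             search_window = 100, from = c("start", "end")) {
  from <- match.arg(from)
  L <- nchar(seq); k <- nchar(primer)
  if (k > L) return(list(pos = NA_integer_, mismatches = NA_integer_))
  search_window <- min(search_window, L)
  if (from == "start") {
    lo <- 1L
    hi <- min(search_window, L - k + 1)
  } else {
    lo <- max(1, L - k + 1 - (search_window - 1))
    hi <- L - k + 1
  }
  hit <- cpp_scan_primer(seq, toupper(primer), as.integer(max_mismatch),
                         as.integer(lo), as.integer(hi))
  list(pos = hit[1], mismatches = hit[2])
}

kmer_codes <- function(seq, k = 8) {
  v <- utf8ToInt(seq)
  map <- integer(128)
  map[utf8ToInt("A")] <- 0L; map[utf8ToInt("C")] <- 1L
  map[utf8ToInt("G")] <- 2L; map[utf8ToInt("T")] <- 3L
  v <- map[v]
  n <- length(v)
  if (n < k) return(integer(0))
  code <- 0L
  out <- Reduce(`+`, lapply(0:(k - 1), function(j) {
    v[(1 + j):(n - k + 1 + j)] * 4L^(k - 1 - j)
  }))
  unique(out)
}

#' Orient sequences against a typed reference set
#'
#' Orientation is decided by counting shared 8-mers with the reference set in
#' both orientations; the orientation sharing more 8-mers wins, and ties keep
#' the input orientation.
#'
#' @param seqs Named character vector of sequences to orient.
#' @param refs Character vector of reference sequences.
#' @param k K-mer size used for screening, default 8.
#' @return Named character vector with sequences flipped where needed; the
#'   attribute `"flipped"` is a logical vector marking reverse-complemented
#'   records.
#' @export
orient <- function(seqs, refs, k = 8) {
  ref_kmers <- unique(unlist(lapply(refs, kmer_codes, k = k)))
  flipped <- logical(length(seqs))
  out <- seqs
  for (i in seq_along(seqs)) {
    fwd <- sum(kmer_codes(seqs[[i]], k) %in% ref_kmers)
    rc <- revcomp(seqs[[i]])
    rev_ <- sum(kmer_codes(rc, k) %in% ref_kmers)
    if (rev_ > fwd) {
      out[[i]] <- rc
      flipped[i] <- TRUE
    }
  }
  attr(out, "flipped") <- flipped
  out
}

#' Trim a sequence between forward and reverse primer binding sites
#'
#' Returns the region between the 3' end of the forward primer site and the
#' 5' start of the reverse primer site (located as the reverse complement of
#' the reverse primer near the 3' end), with both primers excluded. Records
#' missing either site, with the reverse site upstream of the forward site,
#' or with an empty insert are rejected (`NULL`).
#'
#' @param seq Oriented DNA string.
#' @param forward,reverse IUPAC primer strings (reverse given 5'->3' on the
#'   opposite strand, as usual).
#' @param max_mismatch Maximum mismatches allowed per site.
#' @param search_window Scan window passed to [find_primer_site()].
#' @return List with `seq` (trimmed string), `mm_fwd`, `mm_rev`; or `NULL`
#'   when rejected.
#' @export
trim_between_primers <- function(seq, forward, reverse, max_mismatch = 2,
                                 search_window = 100) {
  f <- find_primer_site(seq, forward, max_mismatch, search_window, "start")
  if (is.na(f$pos)) return(NULL)
  r <- find_primer_site(seq, revcomp(reverse), max_mismatch, search_window, "end")
  if (is.na(r$pos)) return(NULL)
  lo <- f$pos + nchar(forward)
  hi <- r$pos - 1
  if (hi < lo) return(NULL)
  list(seq = substr(seq, lo, hi), mm_fwd = f$mismatches, mm_rev = r$mismatches)
}

#' Pairwise identity from semi-global alignment
#'
#' Needleman-Wunsch alignment with free terminal gaps (semi-global), scored
#' match +1, mismatch -1, gap open -2, gap extend -1. Identity is the number
#' of matching columns divided by alignment columns, excluding terminal gap
#' columns; internal gap columns count as non-matching. This convention
#' differs from "BLAST-like" identities and is configurable via the scoring
#' arguments.
#'
#' @param a,b DNA strings.
#' @param gap_open,gap_ext Positive gap penalties (a gap of length k costs
#'   `gap_open + (k-1)*gap_ext`).
#' @return Identity fraction in `[0, 1]`.
#' @export
global_identity <- function(a, b, gap_open = 2, gap_ext = 1) {
  stopifnot(nzchar(a), nzchar(b))
  if (identical(a, b)) return(1.0)
  cpp_align_identity(a, b, gap_open = gap_open, gap_ext = gap_ext)$identity
}

#' Exhaustive top-hit mapping
#'
#' Every query is aligned against every reference (no heuristic termination);
#' the hit with maximum identity is reported. Ties are broken by the smallest
#' reference id; `tie_count` reports how many references achieve the maximum.
#'
#' @param queries Named character vector of query sequences.
#' @param refs Named character vector of reference sequences (ids as names).
#' @return Data frame with columns `query`, `ref`, `identity`, `tie_count`.
#' @export
top_hit <- function(queries, refs) {
  if (length(refs) == 0) stop("empty reference set")
  if (is.null(names(refs))) names(refs) <- as.character(seq_along(refs))
  if (is.null(names(queries))) names(queries) <- as.character(seq_along(queries))
  ord <- order(names(refs))
  refs <- refs[ord]
  hits <- cpp_top_hits(unname(queries), unname(refs))
  data.frame(
    query = names(queries),
    ref = names(refs)[hits$index],
    identity = hits$identity,
    tie_count = hits$tie_count,
    stringsAsFactors = FALSE
  )
}

#' Greedy centroid OTU clustering
#'
#' Sequences must be given in decreasing abundance order (honouring `;size=`
#' annotations if present in the names; the function re-sorts when sizes are
#' annotated). Each sequence joins the first centroid with identity at or
#' above the threshold, otherwise it founds a new centroid. No chimera
#' filtering is performed.
#'
#' @param seqs Named character vector of sequences.
#' @param threshold Identity threshold, default 0.97.
#' @return Data frame with `id`, `centroid` (centroid id), `identity`;
#'   centroids map to themselves with identity 1.
#' @export
cluster_otus <- function(seqs, threshold = 0.97) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  sizes <- parse_size(names(seqs))
  if (any(sizes != 1L)) seqs <- seqs[order(-sizes)]
  res <- cpp_greedy_cluster(unname(seqs), threshold)
  data.frame(
    id = names(seqs),
    centroid = names(seqs)[res$centroid],
    identity = res$identity,
    stringsAsFactors = FALSE
  )
}
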