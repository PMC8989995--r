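# Independent brute-force oracles used by the test suite. These implement
# the documented conventions directly and slowly, without sharing code with
# the package internals.

# Global affine alignment oracle: match +1 / mismatch -1, gap open 2 /
# extend 1; terminal gap runs are penalized in the score but excluded from
# the identity columns. Among equal-scoring alignments the canonical one
# maximizes matches and then minimizes columns (value-based, so the
# identity is symmetric).
oracle_align <- function(a, b, match_s = 1, mismatch_s = -1,
                         gap_open = 2, gap_ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e8
  grun <- function(k) if (k <= 0) 0 else gap_open + (k - 1) * gap_ext
  better <- function(x, y) {
    if (x[1] != y[1]) return(x[1] > y[1])
    if (x[2] != y[2]) return(x[2] > y[2])
    x[3] < y[3]
  }
  best_of <- function(cands) {
    out <- cands[[1]]
    for (k in seq_along(cands)[-1]) if (better(cands[[k]], out)) out <- cands[[k]]
    out
  }
  # cells hold c(score, matches, columns) per state: M, X (gap in b), Y
  M <- X <- Y <- array(NEG, c(n + 1, m + 1, 3))
  M[, , 2:3] <- 0
  X[, , 2:3] <- 0
  Y[, , 2:3] <- 0
  M[1, 1, 1] <- X[1, 1, 1] <- Y[1, 1, 1] <- 0
  for (j in seq_len(m)) Y[1, j + 1, ] <- c(-grun(j), 0, 0)
  for (i in seq_len(n)) X[i + 1, 1, ] <- c(-grun(i), 0, 0)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      eq <- av[i] == bv[j]
      s <- if (eq) match_s else mismatch_s
      p <- best_of(list(M[i, j, ], X[i, j, ], Y[i, j, ]))
      M[i + 1, j + 1, ] <- if (p[1] <= NEG / 2) c(NEG, 0, 0) else
        c(p[1] + s, p[2] + as.integer(eq), p[3] + 1)
      q <- best_of(list(M[i, j + 1, ] - c(gap_open, 0, 0),
                        X[i, j + 1, ] - c(gap_ext, 0, 0),
                        Y[i, j + 1, ] - c(gap_open, 0, 0)))
      X[i + 1, j + 1, ] <- if (q[1] <= NEG / 2) c(NEG, 0, 0) else
        q + c(0, 0, 1)
      r <- best_of(list(M[i + 1, j, ] - c(gap_open, 0, 0),
                        X[i + 1, j, ] - c(gap_open, 0, 0),
                        Y[i + 1, j, ] - c(gap_ext, 0, 0)))
      Y[i + 1, j + 1, ] <- if (r[1] <= NEG / 2) c(NEG, 0, 0) else
        r + c(0, 0, 1)
    }
  }
  cands <- list()
  add <- function(cell, pen) {
    if (cell[1] > NEG / 2) cands[[length(cands) + 1]] <<- cell - c(pen, 0, 0)
  }
  for (i in 0:n) {   # ends at (i, m): a's tail is a trailing gap in b
    k <- n - i
    add(M[i + 1, m + 1, ], grun(k))
    add(X[i + 1, m + 1, ], if (k > 0) k * gap_ext else 0)
    add(Y[i + 1, m + 1, ], grun(k))
  }
  for (j in 0:(m - 1)) {  # ends at (n, j): b's tail is a trailing gap in a
    k <- m - j
    add(M[n + 1, j + 1, ], grun(k))
    add(X[n + 1, j + 1, ], grun(k))
    add(Y[n + 1, j + 1, ], k * gap_ext)
  }
  best <- best_of(cands)
  ident <- if (best[3] > 0) best[2] / best[3] else 0
  list(identity = ident, score = best[1],
       matches = best[2], columns = best[3])
}

oracle_top_hit <- function(query, refs) {
  ids <- sort(names(refs))
  best <- -1; best_ref <- NA_character_; ties <- 0L
  for (id in ids) {
    ident <- oracle_align(query, refs[[id]])$identity
    if (ident > best) {
      best <- ident; best_ref <- id; ties <- 1L
    } else if (ident == best) {
      ties <- ties + 1L
    }
  }
  list(ref = best_ref, identity = best, tie_count = ties)
}

oracle_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

oracle_soerensen <- function(x, y, thr = 1e-4) {
  a <- x > thr; b <- y > thr
  1 - 2 * sum(a & b) / (sum(a) + sum(b))
}

# PERMANOVA R^2 by direct sum-of-squares partition of a distance matrix:
# SS_total = sum_{i<j} d_ij^2 / n; SS_within = per-group pair sums / n_g.
oracle_permanova_r2 <- function(d, groups) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  sst <- sum(dm[lower.tri(dm)]^2) / n
  ssw <- 0
  for (g in unique(groups)) {
    sel <- which(groups == g)
    sub <- dm[sel, sel, drop = FALSE]
    ssw <- ssw + sum(sub[lower.tri(sub)]^2) / length(sel)
  }
  (sst - ssw) / sst
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""), "")
}

mutate_positions <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# Minimal complete taxonomy table for constructed reference sets
toy_taxonomy <- function(ids, genus = "GenusA", species = NULL) {
  n <- length(ids)
  data.frame(
    id = ids, domain = "Bacteria", phylum = "PhylumA", class = "ClassA",
    order = "OrderA", family = "FamilyA",
    genus = rep_len(genus, n),
    species = if (is.null(species)) paste0("sp", seq_len(n))
              else rep_len(species, n),
    stringsAsFactors = FALSE
  )
}
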