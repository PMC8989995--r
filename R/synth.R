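#' Configuration for the synthetic 16S world generator
#'
#' Defines the taxonomy tree, sequence model, plant panel and community
#' model used by [make_reference_world()], [make_plants()],
#' [sample_communities()] and [simulate_reads()]. Defaults are desk-scale
#' study conditions; see the methods vignette for the reasoning behind each
#' value.
#'
#' @param seed Master seed; every generator operation derives from it.
#' @param n_phyla,n_classes_per_phylum,n_orders_per_class,n_families_per_order,n_genera_per_family,n_species_per_genus
#'   Taxonomy tree shape.
#' @param seq_length Full-length sequence size in bp, default 1300.
#' @param per_rank_divergence Named per-rank substitution fractions applied
#'   to the parent centroid when descending the tree; strictly decreasing
#'   from phylum to species.
#' @param typed_fraction Fraction of species whose representative enters the
#'   typed (taxonomy-bearing) reference set.
#' @param n_extra_per_species Environmental sequence variants generated per
#'   species.
#' @param extra_divergence_max Max substitution fraction for variants
#'   (uniform in `[0, max]`).
#' @param indel_rate Optional per-variant indel rate (default 0: pure
#'   substitutions so ground-truth identities are exact Hamming fractions).
#' @param n_plants Number of treatment plants.
#' @param spatial_pools Number of regional species pools (distance decay).
#' @param read_depth Reads per amplicon sample.
#' @param low_depth_frac,low_depth Fraction of samples sequenced at
#'   `low_depth` (exercises the <10,000-read discard path).
#' @param community_depth Cells counted per biological replicate when
#'   resampling plant truth into replicate samples.
#' @param lognormal_mu,lognormal_sigma Log-normal abundance variation.
#' @param core_fractions Fractions of genera planted as strict/general/loose
#'   core and CRAT (the rest are "other").
#' @param occupancy_probs Per-tier occupancy probabilities (plus "other").
#' @param pool_occupancy_boost,pool_occupancy_damp Occupancy multipliers for
#'   loose-core/other genera inside vs outside their home pool.
#' @param pool_abundance_boost Abundance multiplier inside the home pool.
#' @param process_affinity_prob,process_affinity_boost Probability that a
#'   core genus prefers one process type, and its abundance multiplier
#'   there.
#' @param crat_spike_prob,crat_spike_level CRAT burst probability per plant
#'   and burst weight.
#' @param crat_baseline,other_weight Baseline weights (relative to the core
#'   genus weight of 1).
#' @param primer_mismatch_rates Named list (`V1V3`, `V4`) of planted primer
#'   mismatch counts, one per biased genus; biased genera are taken from the
#'   strict core so they are observable everywhere.
#' @param singleton_noise Number of noise singleton reads in full-length
#'   read simulation.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(seed = 1,
                         n_phyla = 3, n_classes_per_phylum = 2,
                         n_orders_per_class = 2, n_families_per_order = 2,
                         n_genera_per_family = 2, n_species_per_genus = 2,
                         seq_length = 1300,
                         per_rank_divergence = c(phylum = 0.10, class = 0.05,
                                                 order = 0.04, family = 0.03,
                                                 genus = 0.025, species = 0.014),
                         typed_fraction = 0.5,
                         n_extra_per_species = 5,
                         extra_divergence_max = 0.05,
                         indel_rate = 0,
                         n_plants = 60, spatial_pools = 4,
                         read_depth = 12000,
                         low_depth_frac = 0.05, low_depth = 6000,
                         community_depth = 1e5,
                         lognormal_mu = 0, lognormal_sigma = 0.2,
                         core_fractions = c(strict = 0.125, general = 0.17,
                                            loose = 0.21, crat = 0.21),
                         occupancy_probs = c(strict = 0.95, general = 0.68,
                                             loose = 0.35, other = 0.08),
                         pool_occupancy_boost = 1.6,
                         pool_occupancy_damp = 0.85,
                         pool_abundance_boost = 1.5,
                         process_affinity_prob = 0.3,
                         process_affinity_boost = 2,
                         crat_spike_prob = 0.08, crat_spike_level = 0.6,
                         crat_baseline = 0.005, other_weight = 0.05,
                         primer_mismatch_rates = list(V1V3 = c(1, 1, 1, 2),
                                                      V4 = c(1)),
                         singleton_noise = 5) {
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  validate_config(cfg)
  cfg
}

#' Validate a synthetic-world configuration
#'
#' Checks the generator invariants: strictly decreasing per-rank divergence,
#' probabilities in `[0, 1]`, read depth allowing the 10,000-read
#' rarefaction path, and a divergence schedule that keeps taxonomic ranks
#' separated (the expected identity between sister taxa at each rank must
#' fall below that rank's threshold; otherwise the identity bands overlap
#' and taxa could not be told apart).
#'
#' @param cfg A `synth_config`.
#' @return `cfg`, invisibly; errors on an invalid configuration.
#' @export
validate_config <- function(cfg) {
  d <- cfg$per_rank_divergence
  ranks <- c("phylum", "class", "order", "family", "genus", "species")
  if (!identical(names(d), ranks)) {
    stop("config error: per_rank_divergence must be named phylum..species")
  }
  if (any(diff(d) >= 0)) {
    stop("config error: per_rank_divergence must be strictly decreasing")
  }
  probs <- c(cfg$typed_fraction, cfg$occupancy_probs, cfg$crat_spike_prob,
             cfg$core_fractions, cfg$low_depth_frac, cfg$indel_rate)
  if (any(probs < 0 | probs > 1)) stop("config error: probabilities must be in [0,1]")
  if (sum(cfg$core_fractions) > 1) stop("config error: core fractions exceed 1")
  if (cfg$read_depth < 10000) {
    stop("config error: read_depth must be >= 10,000 so rarefaction is exercised")
  }
  if (cfg$n_plants < 2) stop("config error: need at least 2 plants")
  thr <- rank_thresholds()
  cum <- rev(cumsum(rev(d)))  # divergence accumulated from each rank down
  sister_identity <- 100 * (1 - 2 * cum)
  bad <- sister_identity >= thr[names(d)]
  if (any(bad)) {
    stop("config error: overlapping identity bands; ranks not separated at: ",
         paste(names(d)[bad], collapse = ", "))
  }
  invisible(cfg)
}

## --- sequence layout -------------------------------------------------------

instantiate_iupac <- function(primer) {
  p <- strsplit(primer, "")[[1]]
  paste(vapply(p, function(cc) IUPAC_SETS[[cc]][1], ""), collapse = "")
}

# Fixed primer-site layout within a full-length sequence. Sites are kept
# free of random mutations so primer bias is planted, not accidental.
#
# The real 515F and 534R primers target overlapping positions of the 16S
# gene, so a 534R site instance contains a near-match of the 515F core. To
# keep the two planted sites independently addressable here, the 515F site
# instantiates its degenerate positions as Y->T and M->C (both valid 515F
# bindings) so that it mismatches the 534R core twice, and a fixed guard
# triplet before the 534 site blocks the reciprocal off-by-three 515F
# match. Both would otherwise create spurious primer hits within the
# tolerance used for in-silico extraction.
seq_layout <- function(L) {
  p13 <- primer_set("V1V3"); p4 <- primer_set("V4"); pfl <- primer_set("FL")
  f27 <- p13$forward
  s534 <- revcomp(instantiate_iupac(p13$reverse))
  s515 <- "GTGTCAGCCGCCGCGGTAA"
  stopifnot(iupac_match(p4$forward, s515) == 0)
  s806 <- revcomp(instantiate_iupac(p4$reverse))
  s1391 <- revcomp(instantiate_iupac(pfl$reverse))
  if (L < 900) stop("seq_length must be at least 900 bp for the primer layout")
  start534 <- floor(0.37 * L)
  start515 <- start534 + nchar(s534) + 4
  start806 <- floor(0.60 * L)
  start1391 <- L - nchar(s1391) + 1
  sites <- data.frame(
    name = c("f27", "guard534", "s534", "s515", "s806", "s1391"),
    seq = c(f27, "AAA", s534, s515, s806, s1391),
    start = c(1L, start534 - 3L, start534, start515, start806, start1391),
    stringsAsFactors = FALSE
  )
  sites$end <- sites$start + nchar(sites$seq) - 1L
  stopifnot(all(diff(as.vector(rbind(sites$start, sites$end))) > 0))
  sites
}

layout_protected <- function(sites, L) {
  prot <- logical(L)
  for (i in seq_len(nrow(sites))) prot[sites$start[i]:sites$end[i]] <- TRUE
  which(prot)
}

mutate_seq <- function(chars, n_mut, mutable) {
  if (n_mut <= 0) return(chars)
  pos <- sample(mutable, min(n_mut, length(mutable)))
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    chars[p] <- sample(setdiff(bases, chars[p]), 1)
  }
  chars
}

# Pick a base for `site_pos` in a primer site that is a true IUPAC mismatch.
plant_site_mismatches <- function(chars, site, m, primer, site_is_revcomp) {
  pat <- strsplit(toupper(primer), "")[[1]]
  len <- length(pat)
  allowed <- lapply(pat, function(cc) IUPAC_SETS[[cc]])
  if (site_is_revcomp) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    allowed <- rev(lapply(allowed, function(s) unname(comp[s])))
  }
  candidates <- which(lengths(allowed) == 1)  # non-degenerate positions
  pos <- candidates[seq_len(m)]
  for (k in pos) {
    abs_pos <- site$start + k - 1L
    chars[abs_pos] <- setdiff(c("A", "C", "G", "T"), allowed[[k]])[1]
  }
  chars
}

## --- world -----------------------------------------------------------------

#' Generate a synthetic reference world with known ground truth
#'
#' Descends the taxonomy tree from a random root centroid, substituting a
#' binomially sampled number of positions per rank (primer sites are
#' protected). Every species gets a representative full-length sequence plus
#' `n_extra_per_species` environmental variants; a `typed_fraction` of
#' species representatives forms the typed reference set with full
#' seven-rank taxonomy. Ground truth records, per pool sequence, its true
#' taxonomy and its realized identity to the closest typed reference
#' (recomputed from the emitted sequences). Genus-level community roles
#' (core tier, primer mismatches, pool and process affinities) are also
#' planted here.
#'
#' @param cfg A [synth_config()].
#' @param identity_method How the realized closest-relative identity is
#'   recorded in the ground truth: `"alignment"` (exhaustive semi-global
#'   mapping, the definition used by the taxonomy pipeline; costly),
#'   `"hamming"` (substitution-only fraction, exact for the default
#'   indel-free model and cheap; equals the alignment identity at
#'   within-species divergences but can fall below it for distant
#'   relatives, where gapped alignments recover extra matching columns),
#'   or `"none"`. The `hamming_identity` column is always recorded for
#'   equal-length worlds.
#' @return A `synth_world` list: `sequences`, `taxonomy`, `typed_seqs`,
#'   `typed_taxonomy`, `ground_truth`, `genus_info`, `species_info`,
#'   `layout`, `config`.
#' @export
make_reference_world <- function(cfg = synth_config(),
                                 identity_method = c("hamming", "alignment",
                                                     "none")) {
  identity_method <- match.arg(identity_method)
  validate_config(cfg)
  set.seed(cfg$seed)
  L <- cfg$seq_length
  sites <- seq_layout(L)
  protected <- layout_protected(sites, L)
  mutable <- setdiff(seq_len(L), protected)
  d <- cfg$per_rank_divergence

  root <- character(L)
  root[mutable] <- sample(c("A", "C", "G", "T"), length(mutable), replace = TRUE)
  for (i in seq_len(nrow(sites))) {
    root[sites$start[i]:sites$end[i]] <- strsplit(sites$seq[i], "")[[1]]
  }

  counts <- c(cfg$n_phyla, cfg$n_classes_per_phylum, cfg$n_orders_per_class,
              cfg$n_families_per_order, cfg$n_genera_per_family,
              cfg$n_species_per_genus)
  rk <- c("phylum", "class", "order", "family", "genus", "species")

  nodes <- list(list(chars = root, lineage = c(domain = "Bacteria")))
  for (level in seq_along(rk)) {
    nxt <- list()
    idx <- 0
    for (node in nodes) {
      for (child in seq_len(counts[level])) {
        idx <- idx + 1
        n_mut <- stats::rbinom(1, L, d[[rk[level]]])
        chars <- mutate_seq(node$chars, n_mut, mutable)
        lin <- c(node$lineage,
                 stats::setNames(sprintf("%s_%03d", toupper(substr(rk[level], 1, 1)),
                                         idx), rk[level]))
        nxt[[length(nxt) + 1]] <- list(chars = chars, lineage = lin)
      }
    }
    nodes <- nxt
  }

  n_species <- length(nodes)
  species_tax <- do.call(rbind, lapply(nodes, function(n)
    as.data.frame(as.list(n$lineage), stringsAsFactors = FALSE)))
  genera <- unique(species_tax$genus)
  n_genera <- length(genera)

  ## genus roles: tiers, primer mismatches, pools, process affinity
  nf <- cfg$core_fractions
  n_strict <- max(1, round(nf[["strict"]] * n_genera))
  n_general <- round(nf[["general"]] * n_genera)
  n_loose <- round(nf[["loose"]] * n_genera)
  n_crat <- round(nf[["crat"]] * n_genera)
  n_bias <- sum(lengths(cfg$primer_mismatch_rates))
  if (n_strict < n_bias) {
    stop("config error: need at least ", n_bias, " strict-core genera to ",
         "carry the planted primer mismatches")
  }
  perm <- sample(genera)
  tiers <- rep("other", n_genera)
  tiers[seq_len(n_strict)] <- "strict"
  if (n_general > 0) tiers[n_strict + seq_len(n_general)] <- "general"
  if (n_loose > 0) tiers[n_strict + n_general + seq_len(n_loose)] <- "loose"
  if (n_crat > 0) tiers[n_strict + n_general + n_loose + seq_len(n_crat)] <- "crat"
  genus_info <- data.frame(genus = perm, tier = tiers,
                           mm_v13 = 0L, mm_v4 = 0L,
                           pool = sample(seq_len(cfg$spatial_pools), n_genera,
                                         replace = TRUE),
                           process_affinity = NA_character_,
                           stringsAsFactors = FALSE)
  bias_slots <- seq_len(n_bias)
  slot <- 1
  for (m in cfg$primer_mismatch_rates$V4) {
    genus_info$mm_v4[slot] <- as.integer(m); slot <- slot + 1
  }
  for (m in cfg$primer_mismatch_rates$V1V3) {
    genus_info$mm_v13[slot] <- as.integer(m); slot <- slot + 1
  }
  proc_types <- c("C", "C,N", "C,N,DN", "C,N,DN,P")
  core_rows <- genus_info$tier %in% c("strict", "general", "loose")
  has_aff <- core_rows & stats::runif(n_genera) < cfg$process_affinity_prob
  genus_info$process_affinity[has_aff] <-
    sample(proc_types, sum(has_aff), replace = TRUE)
  genus_info <- genus_info[order(match(genus_info$genus, genera)), ]
  rownames(genus_info) <- NULL

  ## plant primer mismatches into all species of the biased genera
  s534 <- sites[sites$name == "s534", ]
  s515 <- sites[sites$name == "s515", ]
  p13 <- primer_set("V1V3"); p4 <- primer_set("V4")
  for (i in seq_len(n_species)) {
    g <- species_tax$genus[i]
    gi <- genus_info[genus_info$genus == g, ]
    if (gi$mm_v4 > 0) {
      nodes[[i]]$chars <- plant_site_mismatches(nodes[[i]]$chars, s515,
                                                gi$mm_v4, p4$forward, FALSE)
    }
    if (gi$mm_v13 > 0) {
      nodes[[i]]$chars <- plant_site_mismatches(nodes[[i]]$chars, s534,
                                                gi$mm_v13, p13$reverse, TRUE)
    }
  }

  ## assemble pool sequences: species representatives + variants
  sp_ids <- sprintf("SP%03d", seq_len(n_species))
  seqs <- character(0)
  tax_rows <- list()
  for (i in seq_len(n_species)) {
    rep_seq <- paste(nodes[[i]]$chars, collapse = "")
    ids <- sp_ids[i]
    these <- rep_seq
    if (cfg$n_extra_per_species > 0) {
      for (v in seq_len(cfg$n_extra_per_species)) {
        u <- stats::runif(1, 0, cfg$extra_divergence_max)
        n_mut <- stats::rbinom(1, L, u)
        ch <- mutate_seq(nodes[[i]]$chars, n_mut, mutable)
        if (cfg$indel_rate > 0 && stats::runif(1) < cfg$indel_rate) {
          cut <- sample(mutable, 1)
          ch <- ch[-cut]
        }
        these <- c(these, paste(ch, collapse = ""))
        ids <- c(ids, sprintf("%s_V%d", sp_ids[i], v))
      }
    }
    names(these) <- ids
    seqs <- c(seqs, these)
    tr <- species_tax[rep(i, length(these)), , drop = FALSE]
    tr$id <- ids
    tax_rows[[i]] <- tr
  }
  taxonomy <- do.call(rbind, tax_rows)
  taxonomy <- taxonomy[c("id", tax_ranks())]
  rownames(taxonomy) <- NULL

  typed_species <- sort(sample(n_species, max(1, round(cfg$typed_fraction * n_species))))
  typed_ids <- sp_ids[typed_species]
  typed_seqs <- stats::setNames(seqs[typed_ids], paste0("REF_", typed_ids))
  typed_taxonomy <- taxonomy[match(typed_ids, taxonomy$id), ]
  typed_taxonomy$id <- names(typed_seqs)
  rownames(typed_taxonomy) <- NULL

  ham <- if (identity_method == "none") {
    list(ref = NA_character_, identity = NA_real_)
  } else {
    nearest_typed_identity(seqs, typed_seqs)
  }
  ground_truth <- data.frame(id = names(seqs),
                             taxonomy[match(names(seqs), taxonomy$id),
                                      tax_ranks()],
                             nearest_typed = ham$ref,
                             hamming_identity = ham$identity,
                             identity = NA_real_,
                             stringsAsFactors = FALSE)
  rownames(ground_truth) <- NULL
  if (identity_method == "alignment") {
    hits <- top_hit(seqs, typed_seqs)
    ground_truth$nearest_typed <- hits$ref
    ground_truth$identity <- hits$identity
  }

  species_info <- data.frame(species_id = sp_ids,
                             species = species_tax$species,
                             genus = species_tax$genus,
                             stringsAsFactors = FALSE)

  structure(list(sequences = seqs, taxonomy = taxonomy,
                 typed_seqs = typed_seqs, typed_taxonomy = typed_taxonomy,
                 ground_truth = ground_truth, genus_info = genus_info,
                 species_info = species_info, layout = sites, config = cfg),
            class = "synth_world")
}

# Realized identity of every sequence to its closest typed reference.
# For equal-length (substitution-only) worlds this is an exact Hamming
# fraction; with indels it falls back to exhaustive alignment.
nearest_typed_identity <- function(seqs, typed) {
  L <- unique(nchar(c(seqs, typed)))
  if (length(L) == 1) {
    M <- vapply(seqs, function(s) utf8ToInt(s), integer(L))
    best_id <- rep(-1, length(seqs))
    best_ref <- character(length(seqs))
    for (j in seq_along(typed)) {
      r <- utf8ToInt(typed[[j]])
      ident <- 1 - colSums(M != r) / L
      upd <- ident > best_id
      best_id[upd] <- ident[upd]
      best_ref[upd] <- names(typed)[j]
    }
    list(ref = best_ref, identity = best_id)
  } else {
    hits <- top_hit(seqs, typed)
    list(ref = hits$ref, identity = hits$identity)
  }
}

#' @export
print.synth_world <- function(x, ...) {
  cat(sprintf("<synth_world> %d sequences (%d species, %d typed refs), seed %d\n",
              length(x$sequences), nrow(x$species_info),
              length(x$typed_seqs), x$config$seed))
  invisible(x)
}

#' Generate a synthetic plant (WWTP) metadata panel
#'
#' Plants are assigned to regional pools laid out along a latitude band
#' (neighbouring pool centres roughly 1,900 km apart so the distance-decay
#' breakpoint is informative), with jittered coordinates, process types
#' drawn with realistic frequencies, plant types, temperatures, industrial
#' COD fractions and climate groups.
#'
#' @param cfg A [synth_config()].
#' @return Data frame with one row per plant: `plant_id`, `process_type`,
#'   `plant_type`, `continent`, `country`, `latitude`, `longitude`,
#'   `temperature`, `industrial_cod`, `climate_group`, `pool`.
#' @export
make_plants <- function(cfg = synth_config()) {
  validate_config(cfg)
  set.seed(cfg$seed + 1L)
  n <- cfg$n_plants
  k <- cfg$spatial_pools
  continents <- rep(c("Europe", "Asia", "North America", "Africa",
                      "South America", "Oceania"), length.out = k)
  centre_lon <- seq(0, by = 20, length.out = k)
  centre_lat <- rep(30, k)
  pool <- sample(seq_len(k), n, replace = TRUE)
  lat <- pmin(89, pmax(-89, centre_lat[pool] + stats::runif(n, -6, 6)))
  lon <- centre_lon[pool] + stats::runif(n, -6, 6)
  proc_types <- c("C", "C,N", "C,N,DN", "C,N,DN,P")
  process <- sample(proc_types, n, replace = TRUE,
                    prob = c(0.235, 0.101, 0.434, 0.230))
  plant_type <- sample(c("activated sludge", "biofilter", "MBBR", "MBR",
                         "granular sludge"), n, replace = TRUE,
                       prob = c(0.70, 0.08, 0.10, 0.07, 0.05))
  temperature <- round(pmin(38, pmax(2, stats::rnorm(n, 18, 6))), 1)
  industrial <- sample(c(0, 5, 20, 40, 75, 100), n, replace = TRUE,
                       prob = c(0.30, 0.25, 0.20, 0.15, 0.07, 0.03))
  climate <- as.character(cut(abs(lat), c(0, 23.5, 35, 50, 66.5, 90),
                              labels = c("A", "B", "C", "D", "E"),
                              include.lowest = TRUE))
  data.frame(
    plant_id = sprintf("Plant_%03d", seq_len(n)),
    process_type = process, plant_type = plant_type,
    continent = continents[pool],
    country = sprintf("%s_%d", continents[pool], 1 + (seq_len(n) %% 3)),
    latitude = lat, longitude = lon,
    temperature = temperature, industrial_cod = industrial,
    climate_group = climate, pool = pool,
    stringsAsFactors = FALSE
  )
}

#' Sample truth-level communities for a plant panel
#'
#' Per plant, genus weights are the product of a tier-specific occupancy
#' Bernoulli, a log-normal abundance draw, a process-type multiplier and a
#' regional-pool weighting; CRAT genera carry a low baseline everywhere with
#' occasional spikes. Genus weights are split into species by a per-genus
#' Dirichlet split, renormalized into plant truth proportions, and two
#' replicate samples per plant are emitted by multinomial resampling at
#' `community_depth`. Ground-truth core/CRAT tiers are the core definitions
#' applied to the noiseless plant truth.
#'
#' @param world A [make_reference_world()] object.
#' @param plants A [make_plants()] data frame.
#' @param cfg The shared [synth_config()] (defaults to the world's).
#' @return List: `plant_truth` (species x plants proportions), `samples`
#'   (species x samples counts with a `plants` attribute), `genus_truth`
#'   (data frame with planted and realized tiers), `plants`.
#' @export
sample_communities <- function(world, plants, cfg = world$config) {
  set.seed(cfg$seed + 2L)
  gi <- world$genus_info
  si <- world$species_info
  n_g <- nrow(gi)
  n_p <- nrow(plants)
  occ <- cfg$occupancy_probs

  split <- lapply(seq_len(n_g), function(g) {
    k <- sum(si$genus == gi$genus[g])
    w <- stats::rgamma(k, shape = 5)
    w / sum(w)
  })

  gw <- matrix(0, n_g, n_p, dimnames = list(gi$genus, plants$plant_id))
  for (p in seq_len(n_p)) {
    same_pool <- gi$pool == plants$pool[p]
    for (g in seq_len(n_g)) {
      tier <- gi$tier[g]
      logn <- stats::rlnorm(1, cfg$lognormal_mu, cfg$lognormal_sigma)
      proc_mult <- if (!is.na(gi$process_affinity[g]) &&
                       gi$process_affinity[g] == plants$process_type[p])
        cfg$process_affinity_boost else 1
      if (tier == "crat") {
        w <- cfg$crat_baseline
        if (stats::runif(1) < cfg$crat_spike_prob) {
          w <- cfg$crat_spike_level * logn
        }
      } else {
        p_on <- if (tier == "other") occ[["other"]] else occ[[tier]]
        if (tier %in% c("loose", "other")) {
          p_on <- if (same_pool[g]) min(1, p_on * cfg$pool_occupancy_boost)
                  else p_on * cfg$pool_occupancy_damp
        }
        on <- stats::runif(1) < p_on
        base <- if (tier == "other") cfg$other_weight else 1
        pool_mult <- if (same_pool[g] && tier != "other")
          cfg$pool_abundance_boost else 1
        w <- if (on) base * logn * proc_mult * pool_mult else 0
      }
      gw[g, p] <- w
    }
  }
  zero <- colSums(gw) == 0
  if (any(zero)) {
    message("regenerating all-zero plants: ",
            paste(plants$plant_id[zero], collapse = ", "))
    for (p in which(zero)) gw[gi$tier == "strict", p] <- 1
  }

  sw <- matrix(0, nrow(si), n_p, dimnames = list(si$species_id, plants$plant_id))
  for (g in seq_len(n_g)) {
    rows <- which(si$genus == gi$genus[g])
    sw[rows, ] <- outer(split[[g]], gw[g, ])
  }
  plant_truth <- sweep(sw, 2, colSums(sw), "/")

  sample_ids <- as.vector(t(outer(plants$plant_id, c("_R1", "_R2"), paste0)))
  plant_of <- stats::setNames(rep(plants$plant_id, each = 2), sample_ids)
  samples <- matrix(0L, nrow(si), length(sample_ids),
                    dimnames = list(si$species_id, sample_ids))
  for (s in seq_along(sample_ids)) {
    pr <- plant_truth[, plant_of[s]]
    samples[, s] <- stats::rmultinom(1, cfg$community_depth, pr)[, 1]
  }
  attr(samples, "plants") <- plant_of

  genus_rel <- rowsum(plant_truth, si$genus)
  realized <- core_crat_assign(genus_rel)
  genus_truth <- data.frame(
    genus = gi$genus,
    planted_tier = ifelse(gi$tier == "crat", "CRAT", gi$tier),
    realized_tier = realized$tier[match(gi$genus, realized$taxon)],
    occupancy = realized$occupancy[match(gi$genus, realized$taxon)],
    max_abund = realized$max_abund[match(gi$genus, realized$taxon)],
    stringsAsFactors = FALSE
  )
  list(plant_truth = plant_truth, samples = samples,
       genus_truth = genus_truth, plants = plants)
}

# Extract an amplicon and its planted primer mismatch count for one species.
extract_amplicon <- function(seq, pset, max_mismatch = 2) {
  trim_between_primers(seq, pset$forward, pset$reverse,
                       max_mismatch = max_mismatch, search_window = 1500)
}

#' Simulate amplicon reads from truth-level communities
#'
#' For `V1V3` and `V4`, the amplicon region between the primer sites is
#' extracted per species (allowing up to `max_mismatch` planted mismatches
#' per site); species with a missing site are silently dropped and reported.
#' Per-species detection weight is multiplied by `2^(-m)` where `m` is the
#' total planted mismatch count, and `depth` reads are drawn per sample by
#' multinomial sampling. Identical amplicons are collapsed into ASVs.
#'
#' For `FL`, a pooled full-length read set is emitted: dereplicable
#' (>= 2 copy) reads for detected species plus `singleton_noise` one-off
#' noise reads.
#'
#' @param comm Output of [sample_communities()].
#' @param world The matching [make_reference_world()].
#' @param primer One of "V1V3", "V4", "FL".
#' @param depth Reads per sample (scalar); samples chosen as low-depth get
#'   `cfg$low_depth`.
#' @param seed Seed (defaults to the config seed).
#' @param max_mismatch Mismatch tolerance when locating primer sites.
#' @return For V1V3/V4: list with `counts` (ASV x samples), `asv_seqs`,
#'   `asv_taxonomy` (truth classification of each ASV), `asv_species`
#'   (ASV -> species ids), `dropped` (species without the primer sites),
#'   `factors` (per-species detection factors). For FL: list with `reads`
#'   and `read_species`.
#' @export
simulate_reads <- function(comm, world, primer = c("V1V3", "V4", "FL"),
                           depth = world$config$read_depth, seed = NULL,
                           max_mismatch = 2) {
  primer <- match.arg(primer)
  cfg <- world$config
  if (is.null(seed)) seed <- cfg$seed + 3L
  set.seed(seed + match(primer, c("V1V3", "V4", "FL")))
  pset <- primer_set(primer)
  si <- world$species_info
  reps <- world$sequences[si$species_id]

  amp <- lapply(reps, extract_amplicon, pset = pset, max_mismatch = max_mismatch)
  ok <- !vapply(amp, is.null, NA)
  mm <- ifelse(ok, vapply(amp, function(a) if (is.null(a)) NA_integer_
                          else a$mm_fwd + a$mm_rev, 0L), NA_integer_)
  factors <- ifelse(ok, 2^(-as.numeric(mm)), 0)
  names(factors) <- si$species_id
  dropped <- si$species_id[!ok]

  if (primer == "FL") {
    pr <- rowMeans(comm$plant_truth) * factors
    pr <- pr / sum(pr)
    counts <- stats::rmultinom(1, depth, pr)[, 1]
    counts[counts == 1] <- 2L  # real taxa always yield resolvable duplicates
    keep <- counts > 0
    reads <- rep(vapply(amp[keep], `[[`, "", "seq"), counts[keep])
    read_species <- rep(si$species_id[keep], counts[keep])
    noise <- character(0)
    if (cfg$singleton_noise > 0) {
      L <- nchar(reads[1])
      for (i in seq_len(cfg$singleton_noise)) {
        ch <- strsplit(reads[sample(length(reads), 1)], "")[[1]]
        ch <- mutate_seq(ch, 25, seq_along(ch))
        noise <- c(noise, paste(ch, collapse = ""))
      }
    }
    return(list(reads = c(reads, noise),
                read_species = c(read_species,
                                 rep("noise", length(noise))),
                factors = factors, dropped = dropped))
  }

  amp_seq <- vapply(amp[ok], `[[`, "", "seq")
  sp_ok <- si$species_id[ok]
  uniq <- unique(amp_seq)
  asv_of_species <- match(amp_seq, uniq)

  det <- comm$plant_truth[sp_ok, , drop = FALSE] * factors[sp_ok]
  total_w <- rowSums(rowsum(det, asv_of_species))
  ord <- order(-total_w)
  asv_ids <- character(length(uniq))
  asv_ids[ord] <- sprintf("ASV%03d", seq_along(uniq))
  asv_seqs <- stats::setNames(uniq, asv_ids)
  asv_species <- split(sp_ok, asv_ids[asv_of_species])

  n_samp <- ncol(comm$samples)
  depths <- rep(depth, n_samp)
  low <- stats::runif(n_samp) < cfg$low_depth_frac
  depths[low] <- cfg$low_depth
  counts <- matrix(0L, length(uniq), n_samp,
                   dimnames = list(asv_ids, colnames(comm$samples)))
  for (s in seq_len(n_samp)) {
    w <- comm$samples[sp_ok, s] * factors[sp_ok]
    w_asv <- rowsum(w, asv_of_species)[, 1]
    w_asv <- w_asv[order(as.integer(names(w_asv)))]
    pr <- w_asv / sum(w_asv)
    counts[asv_ids[as.integer(names(w_asv))], s] <-
      stats::rmultinom(1, depths[s], pr)[, 1]
  }
  attr(counts, "plants") <- attr(comm$samples, "plants")

  first_sp <- vapply(asv_species[asv_ids], `[`, "", 1)
  asv_taxonomy <- data.frame(
    id = asv_ids,
    world$taxonomy[match(first_sp, world$taxonomy$id), tax_ranks()],
    stringsAsFactors = FALSE
  )
  rownames(asv_taxonomy) <- NULL

  list(counts = counts, asv_seqs = asv_seqs, asv_taxonomy = asv_taxonomy,
       asv_species = asv_species, dropped = dropped, factors = factors,
       depths = stats::setNames(depths, colnames(comm$samples)))
}

#' Write a synthetic world and metadata to files
#'
#' Emits the pool FASTA, typed reference FASTA, taxonomy TSV, ground-truth
#' TSV and plant metadata TSV; every file carries the seed in a header
#' comment line.
#'
#' @param world A `synth_world`.
#' @param plants Optional plant metadata to write alongside.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_world <- function(world, plants = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- world$config$seed
  files <- c(
    pool = file.path(dir, "pool.fasta"),
    typed = file.path(dir, "typed_refs.fasta"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    ground_truth = file.path(dir, "ground_truth.tsv")
  )
  write_fasta(world$sequences, files[["pool"]], seed = seed)
  write_fasta(world$typed_seqs, files[["typed"]], seed = seed)
  write_tsv_seeded(world$taxonomy, files[["taxonomy"]], seed)
  write_tsv_seeded(world$ground_truth, files[["ground_truth"]], seed)
  if (!is.null(plants)) {
    f <- file.path(dir, "plants.tsv")
    write_tsv_seeded(plants, f, seed)
    files <- c(files, plants = f)
  }
  invisible(files)
}

write_tsv_seeded <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d", as.integer(seed)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_seeded()]-style writers
#' @param path File path.
#' @return Data frame (seed comment line skipped).
#' @export
read_tsv_seeded <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write / read a synthetic configuration as YAML
#' @param cfg A `synth_config`.
#' @param path File path.
#' @return `path` invisibly (write); a `synth_config` (read).
#' @export
write_synth_config <- function(cfg, path) {
  lst <- unclass(cfg)
  lst$per_rank_divergence <- as.list(lst$per_rank_divergence)
  lst$core_fractions <- as.list(lst$core_fractions)
  lst$occupancy_probs <- as.list(lst$occupancy_probs)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  lst <- yaml::read_yaml(path)
  for (f in c("per_rank_divergence", "core_fractions", "occupancy_probs")) {
    lst[[f]] <- unlist(lst[[f]])
  }
  do.call(synth_config, lst)
}
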