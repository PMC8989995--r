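# small, fast world configuration used throughout these tests
small_cfg <- function(seed = 1, ...) {
  synth_config(seed = seed, n_phyla = 2, n_classes_per_phylum = 1,
               n_orders_per_class = 2, n_families_per_order = 1,
               n_genera_per_family = 2, n_species_per_genus = 2,
               n_extra_per_species = 1, n_plants = 12, spatial_pools = 2,
               core_fractions = c(strict = 0.25, general = 0.25,
                                  loose = 0.25, crat = 0.125),
               primer_mismatch_rates = list(V1V3 = c(1), V4 = c(1)),
               ...)
}

test_that("configuration invariants are enforced", {
  expect_s3_class(synth_config(), "synth_config")
  expect_error(synth_config(per_rank_divergence = c(
    phylum = 0.05, class = 0.06, order = 0.04, family = 0.03,
    genus = 0.02, species = 0.01)), "decreasing")
  expect_error(synth_config(read_depth = 5000), "10,000")
  expect_error(synth_config(typed_fraction = 1.5), "probabilities")
  # a schedule too shallow to separate species from each other
  expect_error(synth_config(per_rank_divergence = c(
    phylum = 0.10, class = 0.05, order = 0.04, family = 0.03,
    genus = 0.025, species = 0.001)), "overlapping identity bands")
})

test_that("world generation is deterministic and annotated", {
  cfg <- small_cfg(seed = 5)
  w1 <- make_reference_world(cfg)
  w2 <- make_reference_world(cfg)
  expect_identical(w1$sequences, w2$sequences)
  expect_identical(w1$ground_truth, w2$ground_truth)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_world(w1, dir = d1)
  write_world(w2, dir = d2)
  expect_identical(readLines(file.path(d1, "pool.fasta")),
                   readLines(file.path(d2, "pool.fasta")))
  expect_equal(readLines(file.path(d1, "pool.fasta"))[1], "; seed=5")

  # every sequence carries a complete seven-rank label
  expect_false(any(is.na(w1$taxonomy[tax_ranks()])))
  expect_false(any(w1$taxonomy[tax_ranks()] == ""))
})

test_that("realized identities reflect the mutation model", {
  # zero divergence in the variant layer: variants identical to the species
  cfg <- small_cfg(seed = 9, extra_divergence_max = 0,
                   typed_fraction = 1)
  w <- make_reference_world(cfg)
  expect_true(all(w$ground_truth$hamming_identity == 1))

  # ten substitutions over 1300 bp: identity 1290/1300, above the species
  # threshold
  set.seed(11)
  parent <- random_dna(1, 1300)
  child <- mutate_positions(parent, 10)
  ham <- sum(strsplit(parent, "")[[1]] == strsplit(child, "")[[1]]) / 1300
  expect_equal(ham, 1290 / 1300)
  expect_gte(100 * ham, rank_thresholds()[["species"]])

  # stored alignment identity equals recomputed top-hit identity
  w2 <- make_reference_world(small_cfg(seed = 13), identity_method = "alignment")
  hits <- top_hit(w2$sequences, w2$typed_seqs)
  expect_equal(hits$identity, w2$ground_truth$identity)
})

test_that("plant metadata stays in range with all process types", {
  cfg <- synth_config(seed = 3, n_plants = 200)
  p <- make_plants(cfg)
  expect_equal(nrow(p), 200)
  expect_true(all(abs(p$latitude) <= 90))
  expect_true(all(abs(p$longitude) <= 180))
  expect_true(all(p$process_type %in% c("C", "C,N", "C,N,DN", "C,N,DN,P")))
  expect_equal(length(unique(p$process_type)), 4)
  expect_true(all(p$climate_group %in% c("A", "B", "C", "D", "E")))
  expect_true(all(p$temperature >= 1.8 & p$temperature <= 38))
})

test_that("communities carry planted structure and replicate correlation", {
  cfg <- small_cfg(seed = 21)
  w <- make_reference_world(cfg, identity_method = "none")
  p <- make_plants(cfg)
  comm <- sample_communities(w, p, cfg)
  expect_equal(colnames(comm$plant_truth), p$plant_id)
  expect_true(all(abs(colSums(comm$plant_truth) - 1) < 1e-9))
  expect_equal(ncol(comm$samples), 2 * nrow(p))

  # replicates of one plant correlate more than cross-plant pairs
  rel <- relative_abundance(comm$samples)
  within <- cor(rel[, "Plant_001_R1"], rel[, "Plant_001_R2"],
                method = "spearman")
  cross <- apply(rel[, paste0(p$plant_id[-1], "_R1"), drop = FALSE], 2,
                 cor, y = rel[, "Plant_001_R1"], method = "spearman")
  expect_gt(within, stats::median(cross))

  # crat_spike_prob = 0: no planted CRAT exceeds 1% anywhere
  cfg0 <- small_cfg(seed = 22, crat_spike_prob = 0)
  w0 <- make_reference_world(cfg0, identity_method = "none")
  comm0 <- sample_communities(w0, make_plants(cfg0), cfg0)
  crat_genera <- w0$genus_info$genus[w0$genus_info$tier == "crat"]
  genus_rel <- rowsum(comm0$plant_truth, w0$species_info$genus)
  expect_true(all(genus_rel[crat_genera, ] < 0.01))
})

test_that("read simulation hits exact depth and collapses ASVs", {
  cfg <- small_cfg(seed = 31, low_depth_frac = 0)
  w <- make_reference_world(cfg, identity_method = "none")
  comm <- sample_communities(w, make_plants(cfg), cfg)
  rd <- simulate_reads(comm, w, "V1V3", depth = 10000)
  expect_true(all(colSums(rd$counts) == 10000))
  expect_true(all(rd$depths == 10000))
  # ASV sequences are the region between the primers, primer-free
  p13 <- primer_set("V1V3")
  expect_false(any(startsWith(rd$asv_seqs, p13$forward)))
  # every ASV maps back to >= 1 species with matching genus
  expect_true(all(lengths(rd$asv_species) >= 1))

  # planted V4 mismatch halves the detection factor
  focal <- w$genus_info$genus[w$genus_info$mm_v4 == 1][1]
  sp <- w$species_info$species_id[w$species_info$genus == focal]
  rd4 <- simulate_reads(comm, w, "V4", depth = 10000)
  expect_true(all(rd4$factors[sp] == 0.5))
  expect_true(all(rd4$factors[setdiff(names(rd4$factors), sp)] == 1))
  # and the V1-V3 factors are unaffected for that genus
  expect_true(all(rd$factors[sp] == 1))
})

test_that("full-length mode emits duplicates plus removable singletons", {
  cfg <- small_cfg(seed = 37, singleton_noise = 5)
  w <- make_reference_world(cfg, identity_method = "none")
  comm <- sample_communities(w, make_plants(cfg), cfg)
  fl <- simulate_reads(comm, w, "FL", depth = 2000)
  tab <- table(fl$reads)
  expect_equal(sum(tab == 1), 5)
  flasv <- resolve_flasvs(fl$reads)
  # exactly the >= 2-copy (real) variants survive dereplication
  expect_equal(sort(flasv$seq), sort(names(tab)[tab >= 2]))
  expect_false(any(flasv$seq %in% names(tab)[tab == 1]))
})

test_that("config YAML round-trips", {
  cfg <- small_cfg(seed = 41)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_synth_config(cfg, f)
  back <- read_synth_config(f)
  expect_equal(unclass(back), unclass(cfg))
})

test_that("regional pools induce distance decay below the breakpoint", {
  cfg <- synth_config(seed = 7, n_extra_per_species = 0, low_depth_frac = 0)
  w <- make_reference_world(cfg, identity_method = "none")
  p <- make_plants(cfg)
  comm <- sample_communities(w, p, cfg)
  rd <- simulate_reads(comm, w, "V1V3")
  genus <- aggregate_by_rank(rd$counts, rd$asv_taxonomy, "genus")
  rel <- relative_abundance(rarefy(genus, 10000, seed = 7))
  plant_rel <- plant_collapse(rel)
  bc <- bray_curtis(plant_rel)
  keep <- colnames(plant_rel)
  pm <- p[match(keep, p$plant_id), ]
  geo <- haversine_km(pm$latitude, pm$longitude)
  out <- ddr(bc, geo, breakpoint = 2500)
  s_within <- out$slope[out$stratum == "within"]
  s_beyond <- out$slope[out$stratum == "beyond"]
  expect_lt(s_within, 0)
  expect_lt(s_within, s_beyond)
})
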