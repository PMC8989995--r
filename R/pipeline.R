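#' Run configuration for the end-to-end pipeline
#'
#' Bundles the stage parameters (all defaulting to the standard analysis
#' values: 0.99 identity for coverage, 0.01% abundance filter, 0.8
#' classifier cutoff, 10,000-read rarefaction, 0.1%/1% core-CRAT abundance
#' cuts, 0.2/0.5/0.8 occupancy cuts, 999 permutations, 2,500 km distance
#' breakpoint) with a synthetic-world configuration.
#'
#' @param synth A [synth_config()].
#' @param min_ident High-identity coverage cutoff (fraction).
#' @param min_abund Relative-abundance filter for database evaluation.
#' @param cutoff Classifier confidence cutoff.
#' @param rarefy_depth Rarefaction depth.
#' @param core_abund,crat_abund Core presence and CRAT abundance cuts.
#' @param occupancy Loose/general/strict occupancy cuts.
#' @param n_perm Permutations for Mantel/PERMANOVA.
#' @param breakpoint_km Distance-decay breakpoint.
#' @param otu_threshold OTU clustering identity.
#' @param min_copies Copies required to resolve an FL-ASV.
#' @return A `run_config` list.
#' @export
run_config <- function(synth = synth_config(),
                       min_ident = 0.99, min_abund = 1e-4, cutoff = 0.8,
                       rarefy_depth = 10000, core_abund = 0.001,
                       crat_abund = 0.01, occupancy = c(0.2, 0.5, 0.8),
                       n_perm = 999, breakpoint_km = 2500,
                       otu_threshold = 0.97, min_copies = 2) {
  cfg <- as.list(environment())
  stopifnot(min_ident > 0, min_ident <= 1, min_abund >= 0, min_abund < 1,
            cutoff > 0, cutoff <= 1, rarefy_depth > 0,
            core_abund > 0, crat_abund > core_abund,
            length(occupancy) == 3, all(diff(occupancy) > 0),
            all(occupancy > 0), all(occupancy < 1),
            n_perm >= 1, breakpoint_km > 0,
            otu_threshold > 0, otu_threshold <= 1, min_copies >= 1)
  validate_config(cfg$synth)
  class(cfg) <- "run_config"
  cfg
}

manifest_entry <- function(files) {
  lapply(files, function(f) {
    list(file = basename(f), md5 = unname(tools::md5sum(f)))
  })
}

#' Run the synthetic end-to-end pipeline
#'
#' Chains the stages on synthetic data: world simulation, full-length read
#' simulation and FL-ASV database building, taxonomy assignment, database
#' evaluation, community profiling (core/CRAT, primer bias) and ecological
#' statistics. Writes stage outputs as TSV/FASTA plus a JSON manifest with
#' parameters, seed and file hashes.
#'
#' @param config A [run_config()].
#' @param outdir Output directory.
#' @param stages Character vector of stages to run, or "all".
#' @return List of in-memory stage results (invisibly written to `outdir`).
#' @export
run_pipeline <- function(config = run_config(), outdir = tempfile("asvref_run"),
                         stages = "all") {
  all_stages <- c("simulate", "build-db", "assign-tax", "evaluate",
                  "profile", "ecostats")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  scfg <- config$synth
  res <- list()
  files <- character(0)

  world <- make_reference_world(scfg)
  plants <- make_plants(scfg)
  comm <- sample_communities(world, plants, scfg)
  reads13 <- simulate_reads(comm, world, "V1V3")
  if ("simulate" %in% stages) {
    files <- c(files, write_world(world, plants, outdir))
    res$world <- world
    res$plants <- plants
  }
  res$comm <- comm

  if ("build-db" %in% stages) {
    fl <- simulate_reads(comm, world, "FL")
    flasv <- resolve_flasvs(fl$reads, min_copies = config$min_copies)
    db <- merge_into_database(new_refdb(), flasv$seq, label = "synthetic run")
    res$db <- db
    res$fl <- fl
  }

  if ("assign-tax" %in% stages) {
    stopifnot(!is.null(res$db))
    seqs <- stats::setNames(res$db$flasv$seq, res$db$flasv$id)
    tax <- assign_taxonomy(seqs, world$typed_seqs, world$typed_taxonomy)
    res$taxonomy <- tax
    res$novelty <- novelty_table(tax)
    f <- file.path(outdir, "novelty.tsv")
    write_tsv_seeded(res$novelty, f, scfg$seed)
    ft <- file.path(outdir, "taxonomy.tsv")
    write_tsv_seeded(tax, ft, scfg$seed)
    f2 <- file.path(outdir, "db_sintax.fasta")
    export_database(res$db, tax, "sintax", f2)
    files <- c(files, f, ft, f2)
  }

  if ("evaluate" %in% stages) {
    stopifnot(!is.null(res$db), !is.null(res$taxonomy))
    dbs <- list(synthetic = list(
      seqs = stats::setNames(res$db$flasv$seq, res$db$flasv$id),
      taxonomy = res$taxonomy))
    ev <- compare_databases(reads13$counts, reads13$asv_seqs, dbs,
                            min_abund = config$min_abund,
                            min_ident = config$min_ident, seed = scfg$seed)
    res$evaluation <- ev
    f <- file.path(outdir, "evaluation.tsv")
    write_tsv_seeded(ev, f, scfg$seed)
    files <- c(files, f)
  }

  if ("profile" %in% stages) {
    genus_counts <- aggregate_by_rank(reads13$counts, reads13$asv_taxonomy,
                                      "genus")
    rar <- rarefy(genus_counts, config$rarefy_depth, seed = scfg$seed)
    rel <- relative_abundance(rar)
    plant_rel <- plant_collapse(rel)
    assign <- core_crat_assign(plant_rel, config$core_abund,
                               config$crat_abund, config$occupancy)
    groups <- stats::setNames(plants$process_type, plants$plant_id)
    cum <- cumulative_group_abundance(assign, plant_rel,
                                      groups[colnames(plant_rel)])
    reads4 <- simulate_reads(comm, world, "V4")
    g13 <- rowMeans(relative_abundance(
      aggregate_by_rank(reads13$counts, reads13$asv_taxonomy, "genus")))
    g4 <- rowMeans(relative_abundance(
      aggregate_by_rank(reads4$counts, reads4$asv_taxonomy, "genus")))
    bias <- primer_bias_compare(g13, g4)
    res$core <- assign
    res$cumulative <- cum
    res$bias <- bias
    res$plant_rel <- plant_rel
    for (nm in c("core", "cumulative", "bias")) {
      f <- file.path(outdir, paste0(nm, ".tsv"))
      write_tsv_seeded(res[[nm]], f, scfg$seed)
      files <- c(files, f)
    }
  }

  if ("ecostats" %in% stages) {
    genus_counts <- aggregate_by_rank(reads13$counts, reads13$asv_taxonomy,
                                      "genus")
    rar <- rarefy(genus_counts, config$rarefy_depth, seed = scfg$seed)
    alpha <- alpha_diversity(rar)
    rel <- relative_abundance(rar)
    plant_rel <- plant_collapse(rel)
    bc <- bray_curtis(plant_rel)
    keep <- colnames(plant_rel)
    pmeta <- plants[match(keep, plants$plant_id), ]
    geo <- haversine_km(pmeta$latitude, pmeta$longitude)
    res$alpha <- alpha
    res$mantel <- mantel_test(bc, geo, config$n_perm, seed = scfg$seed)
    res$ddr <- ddr(bc, geo, config$breakpoint_km)
    res$permanova <- permanova(bc, pmeta$process_type, config$n_perm,
                               seed = scfg$seed)
    res$pcoa <- pcoa(bc)
    f <- file.path(outdir, "alpha.tsv")
    write_tsv_seeded(alpha, f, scfg$seed)
    files <- c(files, f)
  }

  manifest <- list(
    package = "asvref",
    version = as.character(utils::packageVersion("asvref")),
    seed = scfg$seed,
    stages = stages,
    parameters = lapply(unclass(config)[setdiff(names(config), "synth")],
                        unclass),
    synth = lapply(unclass(scfg), function(x)
      if (is.numeric(x) && !is.null(names(x))) as.list(x) else x),
    files = manifest_entry(files),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  res$outdir <- outdir
  invisible(res)
}
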