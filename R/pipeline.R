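# End-to-end orchestration: simulate -> diversity -> structure ->
# chronology -> geography -> networks from a single config, with a
# manifest recording seeds, parameters and output checksums.  Each stage
# derives its own seed deterministically from the run seed, so stages are
# independently reproducible.

#' Demo pipeline configuration
#'
#' A small, fully synthetic configuration exercising every stage: a
#' two-region set of populations with one planted southern lineage, a
#' dated genealogy for sequence statistics and chronology, and a planted
#' frequency hotspot.
#'
#' @param seed mandatory integer run seed.
#' @param out_dir output directory.
#' @return a config list for [run_pipeline()].
#' @export
demo_pipeline_config <- function(seed, out_dir = tempfile("ypg_run_")) {
  pops <- data.frame(
    name = c("North1", "North2", "North3", "South1", "South2", "South3"),
    region = rep(c("north", "south"), each = 3),
    latitude = c(40, 38, 36, 24, 22, 20),
    longitude = c(110, 114, 118, 105, 108, 111),
    n = 60)
  list(
    seed = seed, out_dir = out_dir,
    populations = pops,
    haplogroups = c("O2a2b1a1a", "O2a1b1a2a", "O1b1a1a1a1", "O1a1a1",
                    "C2b1a", "N1b2", "D1a1a1a1", "Q1a1a"),
    base_concentration = 8,
    planted_lineages = data.frame(haplogroup = "O1b1a1a1a1",
                                  slope = -0.012, baseline = 0.25),
    level = 4,
    hdh_freq = 0.05, hdh_alpha = 0.05, fs_alpha = 0.02,
    min_descendants = 30, min_freq = 0.01, bin_width = 500,
    permutations = 199,
    coalescent = list(N0 = 2000, growth_rate = 0.02, growth_onset = 200,
                      generation_time = 29, mu = 7.6e-10, n_sites = 60000),
    hotspot = list(center = c(22, 106), radius_km = 400, peak = 0.45,
                   background = 0.05, n_per_point = 200))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in dependency order, writes one TSV per result
#' (each with a parameter-echo header) plus a JSON manifest with the seed,
#' parameters and md5 checksums of all outputs.  Reruns with the same
#' config produce byte-identical tables.  A failing stage stops the run
#' with the stage named; outputs of completed stages are left in place
#' alongside an `error_report.txt`.
#'
#' @param config a config list (see [demo_pipeline_config()]).
#' @return the output directory, invisibly; the manifest is
#'   `manifest.json` inside it.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$seed)) stop_ypg("config must carry a seed")
  out <- config$out_dir %||% stop_ypg("config must carry out_dir")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      writeLines(c(paste("stage:", name), conditionMessage(e)),
                 file.path(out, "error_report.txt"))
      stop_ypg("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  par0 <- list(seed = config$seed, level = config$level,
               hdh_freq = config$hdh_freq, hdh_alpha = config$hdh_alpha,
               fs_alpha = config$fs_alpha,
               min_descendants = config$min_descendants,
               min_freq = config$min_freq, bin_width = config$bin_width,
               permutations = config$permutations)
  emit <- function(df, file, extra = list()) {
    p <- file.path(out, file)
    write_table(df, p, params = c(par0, extra))
    written <<- c(written, p)
    p
  }

  # -- simulate ------------------------------------------------------------
  samples <- NULL; aln <- NULL; tree <- NULL; field <- NULL
  stage("simulate", {
    samples <- simulate_haplogroup_dataset(
      config$populations, config$haplogroups,
      base_concentration = config$base_concentration,
      planted_lineages = config$planted_lineages,
      seed = derive_seed(config$seed, "simulate"))
    co <- config$coalescent
    tree <- simulate_coalescent_tree(
      nrow(samples), N0 = co$N0, growth_rate = co$growth_rate,
      growth_onset = co$growth_onset, generation_time = co$generation_time,
      seed = derive_seed(config$seed, "tree"))
    tree$tip.label <- samples$sample_id
    attr(tree, "tip_regions") <- setNames(samples$region, samples$sample_id)
    aln <- drop_mutations(tree, mu = co$mu, n_sites = co$n_sites,
                          seed = derive_seed(config$seed, "mutations"),
                          segregating_only = TRUE)
    grid <- expand.grid(latitude = seq(18, 42, length.out = 7),
                        longitude = seq(98, 122, length.out = 7))
    h <- config$hotspot
    field <- simulate_hotspot_field(grid, h$center, h$radius_km, h$peak,
                                    h$background, h$n_per_point,
                                    seed = derive_seed(config$seed, "field"))
    write_sample_table(samples, file.path(out, "samples.tsv"))
    write_dated_tree(tree, file.path(out, "tree.nwk"))
    write_alignment(aln, file.path(out, "alignment.fa"))
    written <- c(written, file.path(out, c("samples.tsv", "tree.nwk",
                                           "alignment.fa")))
  })

  # -- diversity -----------------------------------------------------------
  stage("diversity", {
    prof <- population_diversity_profile(samples, aln)
    emit(prof, "diversity.tsv")
  })

  # -- structure -----------------------------------------------------------
  ft <- NULL
  stage("structure", {
    ft <- frequency_table(samples, level = config$level)
    emit(data.frame(population = rownames(ft$freq), ft$freq,
                    check.names = FALSE), "frequencies.tsv")
    pca <- pca_haplogroups(ft)
    emit(data.frame(population = rownames(pca$scores), pca$scores,
                    check.names = FALSE), "pca_scores.tsv",
         list(explained = paste(round(pca$explained, 2), collapse = "/")))
    d2 <- dist_squared_labels(
      hg_truncate_name(samples$haplogroup, config$level))
    ph <- pairwise_phist(d2, samples$population, B = config$permutations,
                         seed = derive_seed(config$seed, "phist"))
    emit(data.frame(population = rownames(ph$phist), ph$phist,
                    check.names = FALSE), "phist.tsv")
    up <- upgma_tree(pmax(ph$phist, 0)) # negative estimates floored for tree
    write_dated_tree(up, file.path(out, "upgma.nwk"))
    written <- c(written, file.path(out, "upgma.nwk"))
    am <- amova(d2, samples$population, samples$region,
                B = config$permutations,
                seed = derive_seed(config$seed, "amova"))
    emit(am$table, "amova.tsv",
         list(phi = paste(names(am$phi), round(am$phi, 4), sep = "=",
                          collapse = ";")))
    north <- colSums(ft$counts[config$populations$region == "north", ,
                               drop = FALSE])
    south <- colSums(ft$counts[config$populations$region == "south", ,
                               drop = FALSE])
    hdh <- identify_hdh(north, south, freq_threshold = config$hdh_freq,
                        alpha = config$hdh_alpha)
    emit(hdh, "hdh.tsv")
  })

  # -- chronology ----------------------------------------------------------
  stage("chronology", {
    hist <- branching_histogram(tree, bin_width = config$bin_width)
    emit(hist, "branching_histogram.tsv")
    sh <- shared_lineages(tree, region_a = "north", region_b = "south",
                          min_descendants = config$min_descendants,
                          min_freq = config$min_freq)
    emit(sh, "shared_lineages.tsv")
  })

  # -- geography -----------------------------------------------------------
  stage("geography", {
    hs <- getis_ord_hotspots(field$freq, field$latitude, field$longitude)
    emit(hs, "hotspots.tsv",
         list(distance_band_km = attr(hs, "distance_band_km")))
    planted <- config$planted_lineages$haplogroup[1]
    pf <- vapply(rownames(ft$freq), function(p) {
      col <- hg_truncate_name(planted, config$level)
      if (col %in% colnames(ft$freq)) ft$freq[p, col] else 0
    }, numeric(1))
    gc <- geo_frequency_correlation(pf, config$populations$latitude,
                                    config$populations$longitude)
    emit(gc, "geo_correlation.tsv")
    sub <- subsistence_profile(samples)
    emit(sub, "subsistence.tsv")
  })

  # -- network -------------------------------------------------------------
  stage("network", {
    big <- names(which.max(table(samples$population)))
    ids <- samples$sample_id[samples$population == big]
    sub <- subset_alignment(aln, ids)
    net <- build_mj_network(sub)
    write_network(net, file.path(out, "network_nodes.tsv"),
                  file.path(out, "network_edges.tsv"),
                  file.path(out, "network.graphml"))
    written <- c(written, file.path(out, c("network_nodes.tsv",
                                           "network_edges.tsv",
                                           "network.graphml")))
  })

  # -- manifest ------------------------------------------------------------
  manifest <- list(
    package = as.character(utils::packageVersion("ypopgen")),
    seed = config$seed,
    parameters = par0,
    outputs = as.list(setNames(unname(tools::md5sum(written)),
                               basename(written))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}
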