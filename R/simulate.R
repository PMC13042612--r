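# Generators for haplogroup sample tables, planted spatial hotspot fields,
# and noisy low-coverage query genotypes.  Together with the coalescent
# simulator these produce every input the analysis stages consume.

#' Simulate a haplogroup sample table
#'
#' Per-population haplogroup frequency vectors are drawn from a Dirichlet
#' distribution with concentration vector `base_concentration` (one entry
#' per haplogroup; larger total concentration pulls every population toward
#' the shared mean vector).  Planted lineages then overwrite their entries
#' with a deterministic latitudinal cline
#' `baseline + slope * (latitude - mean latitude)`, clamped to `[0, 1]`;
#' the full vector is renormalised to sum to 1 and sample haplogroups are
#' drawn multinomially.
#'
#' @param populations data.frame with columns `name`, `region`, `latitude`,
#'   `longitude`, `n` (>= 1) and optionally `language`.
#' @param haplogroups character vector of haplogroup names (the multinomial
#'   categories).
#' @param base_concentration Dirichlet concentration per haplogroup
#'   (recycled if scalar).
#' @param planted_lineages optional data.frame with columns `haplogroup`,
#'   `slope` (frequency change per degree latitude) and `baseline`
#'   (frequency at the mean sampled latitude, in `[0, 1]`).
#' @param seed integer seed.
#' @return a sample-record data.frame (columns `sample_id`, `population`,
#'   `region`, `language`, `latitude`, `longitude`, `haplogroup`).
#' @export
simulate_haplogroup_dataset <- function(populations, haplogroups,
                                        base_concentration = 5,
                                        planted_lineages = NULL,
                                        seed = NULL) {
  if (!nrow(populations)) stop_ypg("empty population list")
  need <- c("name", "region", "latitude", "longitude", "n")
  if (!all(need %in% names(populations)))
    stop_ypg("populations needs columns: ", paste(need, collapse = ", "))
  if (any(populations$n < 1)) stop_ypg("population sample sizes must be >= 1")
  K <- length(haplogroups)
  alpha <- rep_len(base_concentration, K)
  if (!is.null(planted_lineages)) {
    if (!all(planted_lineages$haplogroup %in% haplogroups))
      stop_ypg("planted lineage not in haplogroup list")
    if (any(planted_lineages$baseline < 0 | planted_lineages$baseline > 1))
      stop_ypg("planted baseline frequencies must be in [0, 1]")
  }
  with_seed_(seed, {
    lat0 <- mean(populations$latitude)
    recs <- vector("list", nrow(populations))
    for (i in seq_len(nrow(populations))) {
      p <- populations[i, ]
      # Dirichlet draw via normalised gammas
      f <- rgamma(K, shape = alpha, rate = 1)
      f <- f / sum(f)
      if (!is.null(planted_lineages)) {
        for (j in seq_len(nrow(planted_lineages))) {
          pl <- planted_lineages[j, ]
          idx <- match(pl$haplogroup, haplogroups)
          f[idx] <- min(1, max(0, pl$baseline + pl$slope *
                                    (p$latitude - lat0)))
        }
      }
      f <- f / sum(f)
      counts <- as.vector(rmultinom(1, size = p$n, prob = f))
      hg <- rep(haplogroups, counts)
      recs[[i]] <- data.frame(
        sample_id = sprintf("%s_%04d", p$name, seq_len(p$n)),
        population = p$name, region = p$region,
        language = if ("language" %in% names(p)) p$language else "unknown",
        latitude = p$latitude, longitude = p$longitude,
        haplogroup = sample(hg), # shuffle within population
        stringsAsFactors = FALSE)
    }
    do.call(rbind, recs)
  })
}

#' Simulate a planted spatial frequency hotspot
#'
#' Binomial counts at each grid point with success probability
#' `background + (peak - background) * exp(-d^2 / (2 r^2))`, where `d` is
#' the great-circle distance (km) to the planted centre and `r` the hotspot
#' radius.  This is the ground truth for hotspot-recovery experiments.
#'
#' @param grid data.frame with columns `latitude`, `longitude` (one row per
#'   sampling location).
#' @param center length-2 numeric `(latitude, longitude)` of the planted
#'   centre.
#' @param radius_km Gaussian kernel radius in km (> 0).
#' @param peak_freq,background_freq frequencies in `[0, 1]` with
#'   `peak_freq >= background_freq`.
#' @param n_per_point binomial sample size per location.
#' @param seed integer seed.
#' @return data.frame `latitude`, `longitude`, `count`, `n`, `freq`,
#'   `true_p`.
#' @export
simulate_hotspot_field <- function(grid, center, radius_km, peak_freq,
                                   background_freq, n_per_point,
                                   seed = NULL) {
  if (radius_km <= 0) stop_ypg("radius_km must be > 0")
  if (peak_freq < background_freq)
    stop_ypg("peak_freq must be >= background_freq")
  if (any(c(peak_freq, background_freq) < 0) ||
      any(c(peak_freq, background_freq) > 1))
    stop_ypg("frequencies must be in [0, 1]")
  with_seed_(seed, {
    d <- haversine_km(grid$latitude, grid$longitude, center[1], center[2])
    p <- background_freq + (peak_freq - background_freq) *
      exp(-d^2 / (2 * radius_km^2))
    count <- rbinom(nrow(grid), size = n_per_point, prob = p)
    data.frame(latitude = grid$latitude, longitude = grid$longitude,
               count = count, n = n_per_point, freq = count / n_per_point,
               true_p = p)
  })
}

#' Annotate every branch of a tree with diagnostic SNPs
#'
#' Assigns `snps_per_branch` synthetic SNP identifiers to every branch
#' (identified by the label of its child node).  Used to build reference
#' trees for placement experiments; real trees carry such annotations from
#' variant calling.
#'
#' @param tree an [ape::phylo].
#' @param snps_per_branch SNPs per branch (>= 1).
#' @return data.frame `branch_id`, `snp_id`.
#' @export
annotate_branch_snps <- function(tree, snps_per_branch = 20) {
  if (snps_per_branch < 1) stop_ypg("snps_per_branch must be >= 1")
  ids <- node_label(tree, tree$edge[, 2])
  data.frame(
    branch_id = rep(ids, each = snps_per_branch),
    snp_id = paste0(rep(ids, each = snps_per_branch), "_snp",
                    seq_len(snps_per_branch)),
    stringsAsFactors = FALSE)
}

#' Simulate a noisy low-coverage query genotype table
#'
#' For every annotated SNP the true state is `derived` if its branch lies
#' on the root-to-`true_branch` path (inclusive) and `ancestral` otherwise.
#' Each call is then dropped with probability `missing_rate` (the row is
#' absent) and flipped with probability `error_rate`, emulating a
#' low-coverage sample with few informative positions.
#'
#' @param tree an [ape::phylo] whose branches are annotated.
#' @param branch_snps data.frame `branch_id`, `snp_id` (e.g. from
#'   [annotate_branch_snps()]).
#' @param true_branch label of the child node of the branch the query truly
#'   belongs to.
#' @param missing_rate,error_rate probabilities in `[0, 1]`.
#' @param seed integer seed.
#' @return data.frame `snp_id`, `branch_id`, `allele_state` with one row
#'   per observed (non-missing) call.
#' @export
simulate_query_genotypes <- function(tree, branch_snps, true_branch,
                                     missing_rate = 0, error_rate = 0,
                                     seed = NULL) {
  if (is.null(branch_snps) || !nrow(branch_snps))
    stop_ypg("tree has no branch-SNP annotation")
  if (missing_rate < 0 || missing_rate > 1 || error_rate < 0 ||
      error_rate > 1)
    stop_ypg("rates must be in [0, 1]")
  path <- root_path_labels(tree, true_branch)
  with_seed_(seed, {
    truth <- ifelse(branch_snps$branch_id %in% path, "derived", "ancestral")
    keep <- runif(length(truth)) >= missing_rate
    flip <- runif(length(truth)) < error_rate
    state <- ifelse(flip, ifelse(truth == "derived", "ancestral", "derived"),
                    truth)
    out <- data.frame(snp_id = branch_snps$snp_id,
                      branch_id = branch_snps$branch_id,
                      allele_state = state, stringsAsFactors = FALSE)
    out[keep, , drop = FALSE]
  })
}

# Labels of the child nodes of every branch on the root -> `label` path,
# including the branch above `label` itself.
root_path_labels <- function(tree, label) {
  num <- node_number(tree, label)
  root <- ape::Ntip(tree) + 1L
  path <- character(0)
  cur <- num
  while (cur != root) {
    path <- c(path, node_label(tree, cur))
    cur <- tree$edge[tree$edge[, 2] == cur, 1]
    if (!length(cur)) stop_ypg("node ", label, " not connected to root")
  }
  path
}
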