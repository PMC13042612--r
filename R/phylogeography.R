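# Geographic analyses: frequency-vs-coordinate Pearson correlations,
# Getis-Ord Gi* hotspot detection with FDR control, and subsistence-
# strategy lineage profiles.

#' Pearson correlation of frequencies with geographic coordinates
#'
#' Pearson r and the two-sided p-value from the t-distribution with n - 2
#' degrees of freedom, separately for latitude and longitude.  A
#' zero-variance frequency or coordinate vector yields an undefined r with
#' a flag rather than an error.
#'
#' @param freq frequency per location.
#' @param latitude,longitude coordinates per location (>= 3 finite
#'   locations).
#' @return data.frame with rows `latitude`, `longitude`: `r`, `p`, `n`,
#'   `flag`.
#' @export
geo_frequency_correlation <- function(freq, latitude, longitude) {
  stopifnot(length(freq) == length(latitude),
            length(freq) == length(longitude))
  ok <- is.finite(freq) & is.finite(latitude) & is.finite(longitude)
  if (sum(ok) < 3) stop_ypg("need at least 3 locations")
  one <- function(x, axis) {
    if (sd(freq[ok]) == 0 || sd(x[ok]) == 0)
      return(data.frame(axis = axis, r = NA_real_, p = NA_real_,
                        n = sum(ok), flag = "zero-variance",
                        stringsAsFactors = FALSE))
    ct <- cor.test(freq[ok], x[ok], method = "pearson")
    data.frame(axis = axis, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), flag = NA_character_, stringsAsFactors = FALSE)
  }
  rbind(one(latitude, "latitude"), one(longitude, "longitude"))
}

#' Getis-Ord Gi* hotspot analysis
#'
#' Local Gi* statistic with binary distance-band weights (self-inclusive,
#' the "star" convention): for location i,
#' \deqn{z_i = \frac{\sum_j w_{ij} x_j - \bar{x} W_i}
#'   {s \sqrt{(n \sum_j w_{ij}^2 - W_i^2) / (n - 1)}}}
#' with \eqn{\bar{x}, s} the global mean and standard deviation and
#' \eqn{W_i = \sum_j w_{ij}}.  Two-sided normal p-values are
#' Benjamini-Hochberg adjusted across locations and classified at adjusted
#' p < 0.01 / 0.05 / 0.10 (hot when z > 0, cold when z < 0).
#'
#' When `distance_band` is `NULL`, the band is chosen as the median over
#' points of the distance to the k-th nearest neighbour (k = 8 by default),
#' a data-driven analogue of an "optimized" band choice; the band used is
#' always reported.
#'
#' @param values numeric values per location (e.g. haplogroup frequencies).
#' @param latitude,longitude coordinates in decimal degrees.
#' @param distance_band neighbourhood radius in km, or `NULL` for the
#'   k-nearest-neighbour heuristic.
#' @param k neighbour rank for the automatic band (default 8).
#' @param alpha base significance level (default 0.05; the 99/95/90 classes
#'   use 0.01/0.05/0.10 on the adjusted p).
#' @return data.frame per location: `latitude`, `longitude`, `value`, `z`,
#'   `p`, `p_adj`, `class` in
#'   `{hot-99, hot-95, hot-90, cold-99, cold-95, cold-90, none}`, plus
#'   attributes `distance_band_km` and `low_power` (fewer than 8
#'   locations).
#' @export
getis_ord_hotspots <- function(values, latitude, longitude,
                               distance_band = NULL, k = 8, alpha = 0.05) {
  n <- length(values)
  stopifnot(length(latitude) == n, length(longitude) == n)
  if (!is.null(distance_band) && distance_band <= 0)
    stop_ypg("distance_band must be > 0")
  low_power <- n < 8
  # pairwise haversine distances
  dmat <- matrix(0, n, n)
  for (i in seq_len(n))
    dmat[i, ] <- haversine_km(latitude[i], longitude[i], latitude, longitude)
  if (is.null(distance_band)) {
    kth <- apply(dmat, 1, function(r) sort(r[-which.min(r)])[min(k, n - 1)])
    distance_band <- stats::median(kth)
  }
  W <- (dmat <= distance_band) * 1 # self-inclusive: diagonal is 0 <= band
  xbar <- mean(values)
  s <- sqrt(mean(values^2) - xbar^2) # population sd, the Gi* convention
  z <- numeric(n)
  if (s > 0) {
    for (i in seq_len(n)) {
      wi <- W[i, ]
      sw <- sum(wi)
      denom <- s * sqrt((n * sum(wi^2) - sw^2) / (n - 1))
      z[i] <- if (denom > 0) (sum(wi * values) - xbar * sw) / denom else 0
    }
  }
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- p.adjust(p, method = "BH")
  cls <- rep("none", n)
  cls[p_adj < 0.10] <- ifelse(z[p_adj < 0.10] > 0, "hot-90", "cold-90")
  cls[p_adj < 0.05] <- ifelse(z[p_adj < 0.05] > 0, "hot-95", "cold-95")
  cls[p_adj < 0.01] <- ifelse(z[p_adj < 0.01] > 0, "hot-99", "cold-99")
  isolated <- rowSums(W) <= 1
  out <- data.frame(latitude = latitude, longitude = longitude,
                    value = values, z = z, p = p, p_adj = p_adj,
                    class = cls, isolated = isolated,
                    stringsAsFactors = FALSE)
  attr(out, "distance_band_km") <- distance_band
  attr(out, "low_power") <- low_power
  out
}

#' Default subsistence-strategy haplogroup map
#'
#' Lineages associated with millet-farming and rice-farming archaeological
#' contexts in the East and Southeast Asian paternal record.  Foraging and
#' pastoralism lists are deliberately empty: they must be supplied by the
#' user, so no speculative biology ships as a default.
#'
#' @return named list of character vectors (category -> haplogroup
#'   prefixes).
#' @export
default_subsistence_map <- function() {
  list(
    millet = c("C2b1a", "C2b1b1", "D1a1a1a1", "D1a1b1a", "N1b2", "O1a1a2",
               "O1b1a2", "O2a1b1a1a1a1", "O2a2b1a1a", "O2a2b2", "Q1a1a"),
    rice = c("O1a1a1", "O1b1a1a1a1", "O1b1a1a1b", "O2a1b1a2a",
             "O2a2a1a2a1", "O2a2b1a2a"),
    foraging = character(0),
    pastoralism = character(0))
}

#' Per-population subsistence-strategy lineage profile
#'
#' Each sample is assigned to the category of its deepest matching mapped
#' haplogroup: a mapped name matches when it is the sample's haplogroup or
#' an ancestor of it (via the hierarchy when supplied, otherwise by
#' nomenclature-prefix segments).  Samples matching no category fall into
#' `other`.  A haplogroup matching two categories at the same depth is a
#' configuration error.
#'
#' @param samples sample-record data.frame.
#' @param category_map named list of haplogroup vectors per category
#'   (default [default_subsistence_map()]).
#' @param hier optional [haplogroup_hierarchy()] used for ancestry matching.
#' @return data.frame: one row per population, one column per category
#'   (plus `other`); frequencies sum to 1 per population.
#' @export
subsistence_profile <- function(samples, category_map =
                                  default_subsistence_map(), hier = NULL) {
  cats <- names(category_map)
  assign_one <- function(hg) {
    best_cat <- "other"; best_depth <- -1L
    for (cat in cats) {
      for (anc in category_map[[cat]]) {
        if (hg_is_ancestor(anc, hg, hier)) {
          d <- hg_name_depth(anc)
          if (d > best_depth) {
            best_depth <- d; best_cat <- cat
          } else if (d == best_depth && best_cat != cat) {
            stop_ypg("ambiguous category map: ", hg, " matches both ",
                     best_cat, " and ", cat, " at depth ", d)
          }
        }
      }
    }
    best_cat
  }
  assigned <- vapply(samples$haplogroup, assign_one, character(1),
                     USE.NAMES = FALSE)
  pops <- unique(samples$population)
  tab <- table(factor(samples$population, levels = pops),
               factor(assigned, levels = c(cats, "other")))
  freq <- as.matrix(tab / rowSums(tab))
  out <- data.frame(population = pops, stringsAsFactors = FALSE)
  for (cn in colnames(freq)) out[[cn]] <- unname(freq[, cn])
  out
}

# Is `anc` equal to or an ancestor of `hg`?  With a hierarchy: walk parent
# links; otherwise nomenclature segments: every segment of `anc` must
# prefix-match `hg`'s segments.
hg_is_ancestor <- function(anc, hg, hier = NULL) {
  if (anc == hg) return(TRUE)
  if (!is.null(hier) && hg %in% hier$nodes && anc %in% hier$nodes) {
    cur <- hg
    while (cur != hier$root) {
      cur <- hg_parent(hier, cur)
      if (cur == anc) return(TRUE)
    }
    return(FALSE)
  }
  d <- hg_name_depth(anc)
  hg_truncate_name(hg, d) == anc && hg_name_depth(hg) >= d
}

hg_name_depth <- function(name) {
  length(regmatches(name, gregexpr("[A-Za-z]+|[0-9]+", name))[[1]])
}
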