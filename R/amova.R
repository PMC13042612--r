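# Hierarchical analysis of molecular variance (AMOVA) from pairwise squared
# molecular distances, with the three standard permutation schemes, and
# pairwise Phi-st as its two-population restriction.
#
# Two distance conventions mirror the two ways Y-chromosome data are scored:
# "sequence" mode uses the number of pairwise differences between haploid
# sequences as the squared distance; "frequency" mode uses the 0/1 mismatch
# of haplogroup labels (at a stated nomenclature level).

# Sum of squared deviations for an index set, from the squared-distance
# matrix: SSD = sum_{i<j in set} d2_ij / n_set.
ssd_ <- function(d2, idx) {
  if (length(idx) < 2) return(0)
  sum(d2[idx, idx]) / (2 * length(idx))
}

# Core variance-component decomposition for a fixed assignment.
amova_components <- function(d2, pop, grp) {
  N <- length(pop)
  pops <- unique(pop)
  P <- length(pops)
  groups <- unique(grp)
  G <- length(groups)
  pop_idx <- split(seq_len(N), pop)
  n_p <- lengths(pop_idx)
  ssd_t <- ssd_(d2, seq_len(N))
  ssd_wp <- sum(vapply(pop_idx, function(ix) ssd_(d2, ix), numeric(1)))
  if (G > 1) {
    grp_of_pop <- tapply(grp, pop, function(g) g[1])
    grp_idx <- split(seq_len(N), grp)
    N_g <- lengths(grp_idx)
    ssd_wg <- sum(vapply(grp_idx, function(ix) ssd_(d2, ix), numeric(1)))
    ssd_ag <- ssd_t - ssd_wg
    ssd_ap <- ssd_wg - ssd_wp
    df <- c(ag = G - 1, ap = P - G, wp = N - P)
    ms <- c(ssd_ag, ssd_ap, ssd_wp) / df
    # n-coefficients for unequal sizes
    sum_np2_by_g <- tapply(n_p[as.character(names(grp_of_pop))]^2,
                           grp_of_pop, sum)
    Ng_of_g <- vapply(names(sum_np2_by_g),
                      function(g) sum(n_p[names(grp_of_pop)[grp_of_pop == g]]),
                      numeric(1))
    n1 <- (N - sum(sum_np2_by_g / Ng_of_g)) / (P - G)
    n2 <- (sum(sum_np2_by_g / Ng_of_g) - sum(n_p^2) / N) / (G - 1)
    n3 <- (N - sum(Ng_of_g^2) / N) / (G - 1)
    sc <- unname(ms[3])
    sb <- unname((ms[2] - sc) / n1)
    sa <- unname((ms[1] - sc - n2 * sb) / n3)
    sig <- c(sa, sb, sc)
    tot <- sum(sig)
    list(ssd = c(ssd_ag, ssd_ap, ssd_wp), df = df, ms = ms,
         sigma2 = sig, percent = 100 * sig / tot,
         phi = c(phi_ct = sa / tot, phi_sc = sb / (sb + sc),
                 phi_st = (sa + sb) / tot))
  } else {
    df <- c(ap = P - 1, wp = N - P)
    ssd_ap <- ssd_t - ssd_wp
    ms <- c(ssd_ap, ssd_wp) / df
    nprime <- (N - sum(n_p^2) / N) / (P - 1)
    sc <- unname(ms[2])
    sa <- unname((ms[1] - sc) / nprime)
    sig <- c(sa, sc)
    tot <- sum(sig)
    list(ssd = c(ssd_ap, ssd_wp), df = df, ms = ms, sigma2 = sig,
         percent = 100 * sig / tot,
         phi = c(phi_st = sa / tot))
  }
}

#' Hierarchical AMOVA with permutation tests
#'
#' Partitions squared molecular distances into among-group, among-population
#' (within groups) and within-population components using the standard sums
#' of squared deviations and n-coefficients for unequal sample sizes.
#' Negative components are reported as computed, never clipped; the three
#' percentages always sum to 100.  Significance is assessed by three
#' permutation schemes: whole populations among groups (for Phi_CT),
#' individuals among populations within their group (Phi_SC), and
#' individuals among all populations (Phi_ST); p-values are
#' `(b + 1)/(B + 1)`.
#'
#' With a single group the among-group level is reported absent (`NA`) and
#' the decomposition reduces to among/within populations with
#' `phi_st = sigma_a^2 / total`.
#'
#' @param d2 symmetric matrix of squared molecular distances between
#'   individuals (see [dist_squared_sequences()] / [dist_squared_labels()]).
#' @param populations population assignment per individual.
#' @param groups optional group assignment per individual (must be constant
#'   within each population); `NULL` for a single group.
#' @param B number of permutations per scheme (default 1000).
#' @param seed integer seed for the permutations.
#' @return an object of class `amova_result`: a list with `table`
#'   (component, df, SSD, MS, sigma2, percent, p), `phi`, `B` and `seed`.
#' @export
amova <- function(d2, populations, groups = NULL, B = 1000, seed = NULL) {
  populations <- as.character(populations)
  N <- length(populations)
  stopifnot(nrow(d2) == N, ncol(d2) == N)
  if (length(unique(populations)) < 2)
    stop_ypg("need at least 2 populations")
  if (is.null(groups)) groups <- rep("all", N)
  groups <- as.character(groups)
  chk <- tapply(groups, populations, function(g) length(unique(g)))
  if (any(chk > 1))
    stop_ypg("populations assigned to more than one group: ",
             paste(names(chk)[chk > 1], collapse = ", "))
  if (length(unique(groups)) > 1 &&
      length(unique(populations)) == length(unique(groups)))
    stop_ypg("each group holds a single population; the among-populations-",
             "within-groups stratum has zero degrees of freedom. Run with ",
             "groups = NULL (populations as the only stratum) instead.")
  obs <- amova_components(d2, populations, groups)
  G <- length(unique(groups))
  p <- with_seed_(seed, amova_permute(d2, populations, groups, obs, B))
  comp_names <- if (G > 1)
    c("among_groups", "among_populations_within_groups",
      "within_populations")
  else c("among_populations", "within_populations")
  tab <- data.frame(component = comp_names, df = unname(obs$df),
                    SSD = unname(obs$ssd), MS = unname(obs$ms),
                    sigma2 = unname(obs$sigma2),
                    percent = unname(obs$percent),
                    p = unname(p), stringsAsFactors = FALSE)
  structure(list(table = tab, phi = obs$phi, B = B, seed = seed,
                 n_groups = G),
            class = "amova_result")
}

amova_permute <- function(d2, pop, grp, obs, B) {
  N <- length(pop)
  G <- length(unique(grp))
  grp_of_pop <- tapply(grp, pop, function(g) g[1])
  if (G > 1) {
    b_ct <- b_sc <- b_st <- 0
    for (r in seq_len(B)) {
      # scheme 1: whole populations among groups
      perm_gop <- setNames(sample(unname(grp_of_pop)), names(grp_of_pop))
      g1 <- unname(perm_gop[pop])
      c1 <- amova_components(d2, pop, g1)
      if (c1$phi["phi_ct"] >= obs$phi["phi_ct"]) b_ct <- b_ct + 1
      # scheme 2: individuals among populations within groups
      p2 <- pop
      for (g in unique(grp)) {
        ix <- which(grp == g)
        p2[ix] <- pop[ix][sample.int(length(ix))]
      }
      c2 <- amova_components(d2, p2, grp)
      if (c2$phi["phi_sc"] >= obs$phi["phi_sc"]) b_sc <- b_sc + 1
      # scheme 3: individuals among all populations
      p3 <- pop[sample.int(N)]
      g3 <- unname(grp_of_pop[p3])
      c3 <- amova_components(d2, p3, g3)
      if (c3$phi["phi_st"] >= obs$phi["phi_st"]) b_st <- b_st + 1
    }
    c(ag = (b_ct + 1) / (B + 1), ap = (b_sc + 1) / (B + 1),
      wp = (b_st + 1) / (B + 1))
  } else {
    b_st <- 0
    for (r in seq_len(B)) {
      p3 <- pop[sample.int(N)]
      c3 <- amova_components(d2, p3, grp)
      if (c3$phi["phi_st"] >= obs$phi["phi_st"]) b_st <- b_st + 1
    }
    c(ap = (b_st + 1) / (B + 1), wp = NA_real_)
  }
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (", x$n_groups, "group(s),", x$B, "permutations )\n")
  print(x$table, row.names = FALSE)
  cat("Phi:", paste(names(x$phi), round(x$phi, 4), sep = " = ",
                    collapse = ", "), "\n")
  invisible(x)
}

#' Squared molecular distances between individuals
#'
#' `dist_squared_sequences` uses the number of pairwise sequence differences
#' (pairwise deletion for `N`, scaled as in
#' [mean_pairwise_differences()]); `dist_squared_labels` uses the 0/1 label
#' mismatch indicator.  Both serve directly as the squared distances of the
#' AMOVA decomposition.
#'
#' @param aln a [hap_alignment()].
#' @return symmetric numeric matrix with zero diagonal.
#' @export
dist_squared_sequences <- function(aln) {
  m <- aln$mat
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  L <- ncol(m)
  has_missing <- any(m == "N")
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (has_missing) {
      ok <- m[i, ] != "N" & m[j, ] != "N"
      lc <- sum(ok)
      v <- if (lc == 0) 0 else sum(m[i, ok] != m[j, ok]) * L / lc
    } else v <- sum(m[i, ] != m[j, ])
    d[i, j] <- d[j, i] <- v
  }
  d
}

#' @rdname dist_squared_sequences
#' @param labels haplogroup (or haplotype) label per individual.
#' @export
dist_squared_labels <- function(labels) {
  labels <- as.character(labels)
  outer(labels, labels, FUN = `!=`) * 1
}

#' Pairwise Phi-st matrix with permutation p-values
#'
#' For every population pair, Phi-st from the two-population AMOVA
#' decomposition of squared distances; the p-value permutes individuals
#' between the two populations.  Negative estimates are reported as
#' computed.  Pairs involving a population with fewer than 2 individuals
#' are flagged `NA`.
#'
#' @param d2 squared-distance matrix between individuals (see
#'   [dist_squared_sequences()] / [dist_squared_labels()]).
#' @param populations population assignment per individual.
#' @param B permutations per pair (default 1000).
#' @param seed integer seed.
#' @return list with symmetric matrices `phist` and `p` (populations in
#'   first-appearance order).
#' @export
pairwise_phist <- function(d2, populations, B = 1000, seed = NULL) {
  populations <- as.character(populations)
  pops <- unique(populations)
  if (length(pops) < 2) stop_ypg("need at least 2 populations")
  K <- length(pops)
  phist <- matrix(0, K, K, dimnames = list(pops, pops))
  pmat <- matrix(NA_real_, K, K, dimnames = list(pops, pops))
  with_seed_(seed, {
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
      ia <- which(populations == pops[i])
      ib <- which(populations == pops[j])
      if (length(ia) < 2 || length(ib) < 2) {
        phist[i, j] <- phist[j, i] <- NA_real_
        next
      }
      idx <- c(ia, ib)
      sub <- d2[idx, idx]
      lab <- rep(c("A", "B"), c(length(ia), length(ib)))
      obs <- amova_components(sub, lab, rep("all", length(lab)))
      st <- obs$phi["phi_st"]
      b <- 0
      for (r in seq_len(B)) {
        pl <- lab[sample.int(length(lab))]
        cp <- amova_components(sub, pl, rep("all", length(lab)))
        if (cp$phi["phi_st"] >= st) b <- b + 1
      }
      phist[i, j] <- phist[j, i] <- unname(st)
      pmat[i, j] <- pmat[j, i] <- (b + 1) / (B + 1)
    }
    list(phist = phist, p = pmat)
  })
}
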