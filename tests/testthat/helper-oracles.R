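# Independent oracles used to cross-check the package implementations.
# Each is written from the defining formula or by brute-force enumeration,
# deliberately avoiding the code paths it checks.

# brute-force mean pairwise differences (no missing data)
oracle_pi <- function(mat) {
  n <- nrow(mat)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(mat[i, ] != mat[j, ])
  tot / choose(n, 2)
}

# random test alignment over ACGT
random_alignment <- function(n, L) {
  hap_alignment(matrix(sample(c("A", "C", "G", "T"), n * L, TRUE), n, L,
                       dimnames = list(paste0("q", seq_len(n)), NULL)))
}

# Tajima's D from an independent re-derivation of the 1989 constants
oracle_tajima_d <- function(pi, S, n) {
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# exact unsigned Stirling numbers of the first kind (integer arithmetic,
# exact in doubles for n <= 8)
oracle_stirling_row <- function(n) {
  row <- 1
  if (n == 1) return(row)
  for (m in 2:n) row <- c(0, row) + (m - 1) * c(row, 0)
  row # |s(n, k)| for k = 1..n
}

# exact Ewens P(K >= k) and Fu's FS
oracle_fs <- function(n, k_obs, theta) {
  s <- oracle_stirling_row(n)
  pk <- s * theta^seq_len(n) / prod(theta + 0:(n - 1))
  sp <- sum(pk[k_obs:n])
  log(sp / (1 - sp))
}

# direct double-loop Gi* z-scores from the defining formula
oracle_gi <- function(x, lat, lon, band) {
  n <- length(x)
  xbar <- mean(x)
  s <- sqrt(sum(x^2) / n - xbar^2)
  z <- numeric(n)
  for (i in seq_len(n)) {
    sw <- 0; sw2 <- 0; swx <- 0
    for (j in seq_len(n)) {
      d <- geosphere::distHaversine(c(lon[i], lat[i]), c(lon[j], lat[j]),
                                    r = 6371)
      if (d <= band) { sw <- sw + 1; sw2 <- sw2 + 1; swx <- swx + x[j] }
    }
    den <- s * sqrt((n * sw2 - sw^2) / (n - 1))
    z[i] <- if (den > 0) (swx - xbar * sw) / den else 0
  }
  z
}

# closed-form Pearson r and two-sided p from summary sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

# exact Mann-Whitney two-sided p by full enumeration of label assignments
# (no ties), replicating the standard exact two-sided convention
oracle_mw_exact <- function(x, y) {
  m <- length(x); n <- length(y)
  pool <- c(x, y)
  combs <- utils::combn(m + n, m)
  wdist <- apply(combs, 2, function(ix) {
    r <- rank(pool)
    sum(r[ix]) - m * (m + 1) / 2
  })
  w_obs <- sum(rank(pool)[seq_len(m)]) - m * (m + 1) / 2
  lo <- mean(wdist <= w_obs); hi <- mean(wdist >= w_obs)
  if (w_obs > m * n / 2) min(1, 2 * hi) else min(1, 2 * lo)
}

# literal double-loop AMOVA oracle: sums of squared deviations and
# n-coefficients computed directly from the definitions
oracle_amova <- function(d2, pop, grp) {
  N <- length(pop)
  ssd_set <- function(idx) {
    if (length(idx) < 2) return(0)
    tot <- 0
    for (a in seq_along(idx)) for (b in seq_along(idx))
      tot <- tot + d2[idx[a], idx[b]]
    tot / (2 * length(idx))
  }
  pops <- sort(unique(pop)); P <- length(pops)
  grps <- sort(unique(grp)); G <- length(grps)
  ssd_t <- ssd_set(seq_len(N))
  ssd_wp <- sum(sapply(pops, function(p) ssd_set(which(pop == p))))
  n_p <- sapply(pops, function(p) sum(pop == p))
  if (G > 1) {
    ssd_wg <- sum(sapply(grps, function(g) ssd_set(which(grp == g))))
    ssd_ag <- ssd_t - ssd_wg
    ssd_ap <- ssd_wg - ssd_wp
    grp_of <- sapply(pops, function(p) grp[pop == p][1])
    N_g <- sapply(grps, function(g) sum(grp == g))
    sum_np2_g <- sapply(grps, function(g) sum(n_p[grp_of == g]^2))
    n1 <- (N - sum(sum_np2_g / N_g)) / (P - G)
    n2 <- (sum(sum_np2_g / N_g) - sum(n_p^2) / N) / (G - 1)
    n3 <- (N - sum(N_g^2) / N) / (G - 1)
    msc <- ssd_wp / (N - P)
    msb <- ssd_ap / (P - G)
    msa <- ssd_ag / (G - 1)
    sc <- msc
    sb <- (msb - sc) / n1
    sa <- (msa - sc - n2 * sb) / n3
    c(sa, sb, sc)
  } else {
    ssd_ap <- ssd_t - ssd_wp
    nprime <- (N - sum(n_p^2) / N) / (P - 1)
    sc <- ssd_wp / (N - P)
    sa <- (ssd_ap / (P - 1) - sc) / nprime
    c(sa, sc)
  }
}

hamming_str <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# MST cost over a set of node indices given a full distance matrix (Prim)
oracle_mst_cost <- function(d, idx) {
  k <- length(idx)
  if (k < 2) return(0)
  sub <- d[idx, idx, drop = FALSE]
  intree <- c(TRUE, rep(FALSE, k - 1))
  mind <- sub[1, ]
  cost <- 0
  for (s in seq_len(k - 1)) {
    j <- which(!intree)[which.min(mind[!intree])]
    cost <- cost + mind[j]
    intree[j] <- TRUE
    mind <- pmin(mind, sub[j, ])
  }
  cost
}

# exhaustive Steiner-like minimum: least MST cost over observed haplotypes
# plus any subset of at most (k - 2) candidate median strings
oracle_steiner_cost <- function(obs) {
  L <- nchar(obs[1])
  k <- length(obs)
  all_str <- apply(expand.grid(rep(list(c("0", "1")), L)), 1, paste,
                   collapse = "")
  cand <- setdiff(all_str, obs)
  universe <- c(obs, cand)
  M <- length(universe)
  d <- matrix(0, M, M)
  for (i in seq_len(M - 1)) for (j in (i + 1):M)
    d[i, j] <- d[j, i] <- hamming_str(universe[i], universe[j])
  best <- oracle_mst_cost(d, seq_len(k))
  max_med <- k - 2
  for (sz in seq_len(max_med)) {
    subs <- utils::combn(length(cand), sz)
    for (cidx in seq_len(ncol(subs))) {
      idx <- c(seq_len(k), k + subs[, cidx])
      cost <- oracle_mst_cost(d, idx)
      if (cost < best) best <- cost
    }
  }
  best
}

# union of edge sets of all minimum spanning trees, by Pruefer enumeration
oracle_all_mst_edges <- function(d) {
  n <- nrow(d)
  stopifnot(n >= 3, n <= 7)
  pruefer_to_edges <- function(code) {
    degree <- rep(1L, n)
    for (v in code) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, n - 1, 2)
    for (i in seq_along(code)) {
      leaf <- min(which(degree == 1L))
      edges[i, ] <- c(leaf, code[i])
      degree[leaf] <- degree[leaf] - 1L
      degree[code[i]] <- degree[code[i]] - 1L
    }
    last <- which(degree == 1L)
    edges[n - 1, ] <- last
    edges
  }
  codes <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf; keep <- list()
  for (r in seq_len(nrow(codes))) {
    e <- pruefer_to_edges(codes[r, ])
    cost <- sum(d[e])
    if (cost < best - 1e-9) { best <- cost; keep <- list(e) }
    else if (abs(cost - best) <= 1e-9) keep <- c(keep, list(e))
  }
  edges <- unique(do.call(rbind, lapply(keep, function(e)
    t(apply(e, 1, sort)))))
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

# deterministic lineage-count ODE: expected coalescent events per age bin
# under N(t) = N0 exp(-g t) up to onset, constant after (t in generations)
oracle_rate_integral_mode <- function(n, N0, g, onset_gen, generation_time,
                                      bin_width, t_max) {
  dt <- 0.25 # generations
  steps <- ceiling(t_max / generation_time / dt)
  k <- n
  nbins <- ceiling(t_max / bin_width)
  events <- numeric(nbins)
  t <- 0
  for (s in seq_len(steps)) {
    Nt <- if (t < onset_gen) N0 * exp(-g * t) else N0 * exp(-g * onset_gen)
    dk <- k * (k - 1) / (2 * Nt) * dt
    dk <- min(dk, k - 1)
    b <- min(floor(t * generation_time / bin_width), nbins - 1) + 1
    events[b] <- events[b] + dk
    k <- k - dk
    t <- t + dt
  }
  which.max(events) # bin index, youngest first
}

# small planted-region tree helpers used across chronology tests
toy_dated_tree <- function(text) {
  tf <- tempfile(fileext = ".nwk")
  writeLines(text, tf)
  read_dated_tree(tf)
}
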