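# Within-population diversity and neutrality statistics: mean pairwise
# differences (pi), Watterson's theta, Tajima's D, Fu's FS, and the Nei
# gene-diversity estimator used for both haplotype diversity (HD) and
# haplogroup diversity (HGD).

#' Mean pairwise differences (pi)
#'
#' Average number of differing sites over all unordered sequence pairs.
#' Missing symbols (`N`) are handled by pairwise deletion: each pair is
#' compared over its mutually non-missing sites and the raw difference
#' count is scaled by `L / L_compared` so pairs with different amounts of
#' missingness remain comparable.
#'
#' @param aln a [hap_alignment()] with at least two sequences.
#' @return pi, a non-negative number.
#' @export
mean_pairwise_differences <- function(aln) {
  m <- aln$mat
  n <- nrow(m)
  if (n < 2) stop_ypg("need at least 2 sequences")
  if (ncol(m) == 0) return(0)
  L <- ncol(m)
  has_missing <- any(m == "N")
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (has_missing) {
        ok <- m[i, ] != "N" & m[j, ] != "N"
        lc <- sum(ok)
        d <- if (lc == 0) 0 else sum(m[i, ok] != m[j, ok]) * L / lc
      } else {
        d <- sum(m[i, ] != m[j, ])
      }
      tot <- tot + d
    }
  }
  tot / (n * (n - 1) / 2)
}

#' Number of segregating sites
#'
#' A site is segregating when it shows more than one state among its
#' non-missing entries.
#'
#' @param aln a [hap_alignment()].
#' @return integer count.
#' @export
segregating_sites <- function(aln) {
  m <- aln$mat
  if (ncol(m) == 0) return(0L)
  sum(apply(m, 2, function(col) {
    s <- unique(col[col != "N"])
    length(s) > 1
  }))
}

#' Watterson's theta
#'
#' \eqn{\theta_W = S / a_1} with \eqn{a_1 = \sum_{i=1}^{n-1} 1/i}, the
#' segregating-sites estimator of the scaled mutation rate (per locus).
#'
#' @param S number of segregating sites.
#' @param n number of sequences (>= 2).
#' @return theta_W.
#' @export
watterson_theta <- function(S, n) {
  if (n < 2) stop_ypg("need at least 2 sequences")
  S / sum(1 / seq_len(n - 1))
}

# Tajima (1989) normalising constants for sample size n.
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' \eqn{D = (\pi - \theta_W) / \sqrt{e_1 S + e_2 S (S-1)}} with the 1989
#' normalising constants.  Undefined (returned as `NA` with a flag, never
#' an error) when `S = 0` or the variance term vanishes, so batch profiles
#' always complete.
#'
#' @param aln a [hap_alignment()] (n >= 4 recommended for a stable value).
#' @return a list with `d` (`NA` when undefined) and `flag`
#'   (`NA`, `"no-segregating-sites"` or `"zero-variance"`).
#' @export
tajimas_d <- function(aln) {
  n <- nrow(aln$mat)
  if (n < 2) stop_ypg("need at least 2 sequences")
  S <- segregating_sites(aln)
  if (S == 0)
    return(list(d = NA_real_, flag = "no-segregating-sites"))
  tajima_d_from_summary(mean_pairwise_differences(aln), S, n)
}

#' @rdname tajimas_d
#' @param pi mean pairwise differences.
#' @param S segregating sites.
#' @param n number of sequences.
#' @export
tajima_d_from_summary <- function(pi, S, n) {
  if (n < 2) stop_ypg("need at least 2 sequences")
  if (S == 0)
    return(list(d = NA_real_, flag = "no-segregating-sites"))
  k <- tajima_constants(n)
  v <- k$e1 * S + k$e2 * S * (S - 1)
  if (v <= 0)
    return(list(d = NA_real_, flag = "zero-variance"))
  list(d = (pi - S / k$a1) / sqrt(v), flag = NA_character_)
}

#' Unsigned Stirling numbers of the first kind, in log space
#'
#' Row `n` of \eqn{|s(n, k)|} computed by the recurrence
#' \eqn{|s(n,k)| = |s(n-1,k-1)| + (n-1)|s(n-1,k)|} with log-sum-exp, so
#' values remain finite for n in the thousands.
#'
#' @param n row index (>= 1).
#' @return numeric vector of length `n`: `log |s(n, k)|` for `k = 1..n`.
#' @export
log_stirling1 <- function(n) {
  ls <- 0 # row 1: |s(1,1)| = 1
  if (n == 1) return(ls)
  for (m in 2:n) {
    prev <- c(-Inf, ls, -Inf) # pad k = 0 and k = m
    new <- numeric(m)
    for (k in seq_len(m)) {
      a <- prev[k]                  # |s(m-1, k-1)|
      b <- log(m - 1) + prev[k + 1] # (m-1) |s(m-1, k)|
      mx <- max(a, b)
      new[k] <- if (is.finite(mx)) mx + log(exp(a - mx) + exp(b - mx)) else -Inf
    }
    ls <- new
  }
  ls
}

# log P(K = k) for k = 1..n under the Ewens sampling formula at theta.
ewens_log_pk <- function(n, theta, ls = log_stirling1(n)) {
  denom <- sum(log(theta + 0:(n - 1)))
  ls + seq_len(n) * log(theta) - denom
}

#' Fu's FS
#'
#' \eqn{F_S = \ln(S' / (1 - S'))} where \eqn{S' = P(K \ge k_{obs})} under
#' the Ewens sampling formula with \eqn{\theta = \pi} (the observed mean
#' pairwise differences) and \eqn{k_{obs}} the observed number of distinct
#' haplotypes.  Strongly negative values indicate an excess of haplotypes,
#' the footprint of recent expansion.  Undefined when \eqn{\pi = 0}.
#'
#' @param aln a [hap_alignment()].
#' @return list with `fs` (`NA` when undefined), `k_obs`, `pi`, `s_prime`
#'   and `flag`.
#' @export
fus_fs <- function(aln) {
  n <- nrow(aln$mat)
  if (n < 2) stop_ypg("need at least 2 sequences")
  pi <- mean_pairwise_differences(aln)
  if (pi <= 0)
    return(list(fs = NA_real_, k_obs = 1L, pi = pi, s_prime = NA_real_,
                flag = "zero-pi"))
  k_obs <- n_haplotypes(aln)
  logp <- ewens_log_pk(n, pi)
  log_sp <- log_sum_exp(logp[k_obs:n])
  sp <- exp(log_sp)
  fs <- if (sp >= 1) Inf else log_sp - log1p(-sp)
  list(fs = fs, k_obs = k_obs, pi = pi, s_prime = sp, flag = NA_character_)
}

#' Number of distinct haplotypes in an alignment
#' @param aln a [hap_alignment()].
#' @return integer count of distinct sequences.
#' @export
n_haplotypes <- function(aln) {
  length(unique(apply(aln$mat, 1, paste, collapse = "")))
}

#' Simulated p-value for Fu's FS
#'
#' There is no closed-form null for FS; the null distribution is obtained
#' by coalescent simulation under a constant-size neutral model with
#' \eqn{\theta = \pi_{obs}}, computing FS for each simulated sample, and
#' reporting \eqn{p = \Pr(F_S^{sim} \le F_S^{obs})} as `(b + 1)/(B + 1)`.
#' The conventional reporting threshold is p < 0.02, which corresponds to
#' the 5% significance level for this statistic.
#'
#' @param aln a [hap_alignment()].
#' @param B number of simulated null samples (default 1000).
#' @param seed integer seed.
#' @return list with `fs`, `p` (`NA` when FS is undefined) and `B`.
#' @export
fs_pvalue <- function(aln, B = 1000, seed = NULL) {
  obs <- fus_fs(aln)
  if (is.na(obs$fs)) return(list(fs = NA_real_, p = NA_real_, B = B))
  n <- nrow(aln$mat)
  with_seed_(seed, {
    sim <- coal_pi_k_cpp(n, obs$pi, B)
    fs_sim <- fs_from_pi_k(n, sim[, 1], sim[, 2])
    b <- sum(fs_sim <= obs$fs)
    list(fs = obs$fs, p = (b + 1) / (B + 1), B = B)
  })
}

# Vectorised FS from (pi, k) pairs at fixed n; pi = 0 maps to +Inf
# (P(K >= 1) = 1).
fs_from_pi_k <- function(n, pi, k, ls = log_stirling1(n)) {
  out <- numeric(length(pi))
  for (i in seq_along(pi)) {
    if (pi[i] <= 0) { out[i] <- Inf; next }
    logp <- ewens_log_pk(n, pi[i], ls)
    log_sp <- log_sum_exp(logp[k[i]:n])
    sp <- exp(log_sp)
    out[i] <- if (sp >= 1) Inf else log_sp - log1p(-sp)
  }
  out
}

#' Nei gene diversity
#'
#' Unbiased estimator \eqn{(n/(n-1)) (1 - \sum_i p_i^2)} of the probability
#' that two randomly chosen sequences carry different labels.  With
#' haplotype labels this is haplotype diversity (HD); with haplogroup
#' labels, haplogroup diversity (HGD).
#'
#' @param labels vector of labels (length >= 2).
#' @return diversity in `[0, 1]`.
#' @export
gene_diversity <- function(labels) {
  n <- length(labels)
  if (n < 2) stop_ypg("need at least 2 labels")
  p <- table(labels) / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Per-population diversity profile
#'
#' One row per population with all six statistics: n, S, pi, theta_W,
#' Tajima's D, Fu's FS, HD and HGD.  Populations below `min_n` are marked
#' excluded (flag `small-sample`) but still reported, never silently
#' dropped; undefined statistics carry their own flags.
#'
#' @param samples a sample-record data.frame (see [read_sample_table()]).
#' @param aln a [hap_alignment()] whose ids match `samples$sample_id`.
#' @param min_n minimum population size for inclusion (default 20, the
#'   conventional cut-off for frequency-based population comparisons).
#' @return data.frame, one row per population.
#' @export
population_diversity_profile <- function(samples, aln, min_n = 20) {
  missing <- setdiff(samples$sample_id, aln$ids)
  if (length(missing))
    stop_ypg("samples absent from alignment: ",
             paste(head(missing, 5), collapse = ", "))
  pops <- unique(samples$population)
  rows <- lapply(pops, function(p) {
    ids <- samples$sample_id[samples$population == p]
    n <- length(ids)
    flags <- character(0)
    if (n < min_n) flags <- "small-sample"
    if (n < 2) {
      return(data.frame(population = p, n = n, S = NA_integer_,
                        pi = NA_real_, theta_w = NA_real_,
                        tajima_d = NA_real_, fu_fs = NA_real_,
                        hd = NA_real_, hgd = NA_real_,
                        excluded = n < min_n,
                        flags = paste(c(flags, "insufficient-sample"),
                                      collapse = ";"),
                        stringsAsFactors = FALSE))
    }
    sub <- subset_alignment(aln, ids)
    S <- segregating_sites(sub)
    d <- tajimas_d(sub)
    fs <- fus_fs(sub)
    flags <- c(flags, d$flag[!is.na(d$flag)], fs$flag[!is.na(fs$flag)])
    hd <- gene_diversity(apply(sub$mat, 1, paste, collapse = ""))
    hgd <- gene_diversity(samples$haplogroup[samples$population == p])
    data.frame(population = p, n = n, S = S,
               pi = mean_pairwise_differences(sub),
               theta_w = watterson_theta(S, n),
               tajima_d = d$d, fu_fs = fs$fs, hd = hd, hgd = hgd,
               excluded = n < min_n,
               flags = paste(flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
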