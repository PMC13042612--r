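# Frequency-table construction, PCA of haplogroup frequencies, highly
# differentiated haplogroup (HDH) identification, and regional frequency
# comparisons.

#' Population-by-haplogroup frequency table at a nomenclature level
#'
#' Haplogroup calls are truncated to their ancestor at `level` (depth in a
#' supplied hierarchy, or the character-segment fallback otherwise; see
#' [hg_ancestor_at_level()]).  Names that cannot be resolved are collected
#' into an `unresolved` column and reported, never dropped.
#'
#' @param samples sample-record data.frame.
#' @param level nomenclature level (e.g. 4 for fourth-level haplogroups).
#' @param hier optional [haplogroup_hierarchy()].
#' @return object of class `freq_table`: list with `counts` and `freq`
#'   matrices (populations x haplogroups, columns sorted), `n` per
#'   population, and `level`.
#' @export
frequency_table <- function(samples, level = 4, hier = NULL) {
  trunc <- vapply(samples$haplogroup,
                  function(h) hg_ancestor_at_level(h, level, hier),
                  character(1), USE.NAMES = FALSE)
  trunc[is.na(trunc) | !nzchar(trunc)] <- "unresolved"
  pops <- unique(samples$population)
  tab <- table(factor(samples$population, levels = pops), trunc)
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = dimnames(tab))
  counts <- counts[, order(colnames(counts)), drop = FALSE]
  n <- rowSums(counts)
  freq <- counts / n
  structure(list(counts = counts, freq = freq, n = n, level = level),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat("freq_table: ", nrow(x$counts), " populations x ", ncol(x$counts),
      " haplogroups (level ", x$level, ")\n", sep = "")
  invisible(x)
}

#' PCA of a haplogroup frequency table
#'
#' Column-centred (unscaled) singular value decomposition of the frequency
#' matrix, the standard treatment for frequency-matrix PCA.  Explained
#' variance percentages are non-negative, non-increasing, and computed
#' against the total variance, so retained components sum to at most 100.
#' The sign of each component is fixed so its largest-magnitude loading is
#' positive, making outputs reproducible.
#'
#' @param ft a [frequency_table()] or a plain populations x haplogroups
#'   frequency matrix.
#' @param n_components components to retain (default 2).
#' @param scale. also divide columns by their standard deviation (off by
#'   default).
#' @return list with `scores`, `loadings`, `explained` (percentages) and
#'   `flag` (`"zero-variance"` when all populations are identical).
#' @export
pca_haplogroups <- function(ft, n_components = 2, scale. = FALSE) {
  X <- if (inherits(ft, "freq_table")) ft$freq else as.matrix(ft)
  if (nrow(X) < 2 || ncol(X) < 2)
    stop_ypg("need at least 2 populations and 2 haplogroup columns")
  Xc <- scale(X, center = TRUE, scale = scale.)
  Xc[is.nan(Xc)] <- 0
  total_var <- sum(Xc^2) / (nrow(X) - 1)
  k <- min(n_components, nrow(X) - 1, ncol(X))
  if (total_var <= .Machine$double.eps) {
    return(list(scores = matrix(0, nrow(X), k,
                                dimnames = list(rownames(X),
                                                paste0("PC", seq_len(k)))),
                loadings = matrix(0, ncol(X), k,
                                  dimnames = list(colnames(X),
                                                  paste0("PC", seq_len(k)))),
                explained = rep(0, k), flag = "zero-variance"))
  }
  sv <- svd(Xc)
  expl <- 100 * sv$d^2 / sum(sv$d^2)
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  loadings <- sv$v
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(k)) {
    s <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (s < 0) { loadings[, j] <- -loadings[, j]; scores[, j] <- -scores[, j] }
  }
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_along(sv$d)))
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_along(sv$d)))
  list(scores = scores[, seq_len(k), drop = FALSE],
       loadings = loadings[, seq_len(k), drop = FALSE],
       explained = expl[seq_len(k)], flag = NA_character_)
}

#' Identify highly differentiated haplogroups (HDH)
#'
#' Candidates are haplogroups whose frequency differs by at least
#' `freq_threshold` between the two groups; each candidate is then tested
#' with a 2x2 chi-square (haplogroup vs rest, no continuity correction by
#' default) and a two-sided Fisher exact test, and is confirmed only when
#' both are significant at `alpha`.  No multiple-testing correction is
#' applied by default; `adjust = "BH"` switches on Benjamini-Hochberg
#' adjustment of both test families.
#'
#' @param counts_a,counts_b named integer vectors of haplogroup counts over
#'   a shared haplogroup set.
#' @param freq_threshold minimum absolute frequency difference (default
#'   0.05).
#' @param alpha significance level for both tests (default 0.05).
#' @param correct apply Yates continuity correction to the chi-square
#'   (default `FALSE`).
#' @param adjust p-value adjustment method (`"none"` or any
#'   [stats::p.adjust] method) applied across candidates.
#' @return data.frame with one row per haplogroup: frequencies, absolute
#'   difference, both p-values and `verdict` in
#'   `{rejected, candidate, confirmed}`.
#' @export
identify_hdh <- function(counts_a, counts_b, freq_threshold = 0.05,
                         alpha = 0.05, correct = FALSE, adjust = "none") {
  hgs <- union(names(counts_a), names(counts_b))
  if (!length(hgs)) stop_ypg("count vectors must be named by haplogroup")
  a <- setNames(rep(0L, length(hgs)), hgs); a[names(counts_a)] <- counts_a
  b <- setNames(rep(0L, length(hgs)), hgs); b[names(counts_b)] <- counts_b
  nA <- sum(a); nB <- sum(b)
  if (nA == 0 || nB == 0) stop_ypg("zero total count in a group")
  fa <- a / nA; fb <- b / nB
  delta <- abs(fa - fb)
  cand <- delta >= freq_threshold
  chi_p <- fis_p <- rep(NA_real_, length(hgs))
  for (i in which(cand)) {
    m <- matrix(c(a[i], nA - a[i], b[i], nB - b[i]), nrow = 2)
    chi_p[i] <- suppressWarnings(chisq.test(m, correct = correct)$p.value)
    fis_p[i] <- fisher.test(m)$p.value
  }
  if (adjust != "none") {
    chi_p[cand] <- p.adjust(chi_p[cand], method = adjust)
    fis_p[cand] <- p.adjust(fis_p[cand], method = adjust)
  }
  verdict <- ifelse(!cand, "rejected",
                    ifelse(!is.na(chi_p) & chi_p < alpha &
                             !is.na(fis_p) & fis_p < alpha,
                           "confirmed", "candidate"))
  data.frame(haplogroup = hgs, count_a = unname(a), count_b = unname(b),
             freq_a = unname(fa), freq_b = unname(fb),
             abs_diff = unname(delta), chi_p = chi_p, fisher_p = fis_p,
             verdict = verdict, stringsAsFactors = FALSE)
}

#' Regional haplogroup-frequency comparisons
#'
#' For each haplogroup, a Mann-Whitney U test (exact for small samples
#' without ties, normal approximation otherwise) and a Welch's t-test on
#' the population-level frequencies of two region sets, with the usual
#' star convention (* 0.01 <= p < 0.05, ** 0.001 <= p < 0.01,
#' *** p < 0.001).
#'
#' @param freq_a,freq_b populations x haplogroups frequency matrices for
#'   the two sides (at least 2 populations each); columns are matched by
#'   name, absent columns count as frequency 0.
#' @return data.frame with one row per haplogroup: means, U and t
#'   p-values, and stars.
#' @export
group_frequency_tests <- function(freq_a, freq_b) {
  freq_a <- as.matrix(freq_a); freq_b <- as.matrix(freq_b)
  if (nrow(freq_a) < 2 || nrow(freq_b) < 2)
    stop_ypg("need at least 2 populations per side")
  hgs <- sort(union(colnames(freq_a), colnames(freq_b)))
  rows <- lapply(hgs, function(h) {
    xa <- if (h %in% colnames(freq_a)) freq_a[, h] else rep(0, nrow(freq_a))
    xb <- if (h %in% colnames(freq_b)) freq_b[, h] else rep(0, nrow(freq_b))
    u_p <- if (length(unique(c(xa, xb))) == 1) 1
      else suppressWarnings(wilcox.test(xa, xb)$p.value)
    t_p <- if (sd(xa) == 0 && sd(xb) == 0) {
      if (mean(xa) == mean(xb)) 1 else NA_real_
    } else t.test(xa, xb)$p.value
    data.frame(haplogroup = h, mean_a = mean(xa), mean_b = mean(xb),
               mw_p = u_p, mw_stars = p_stars(u_p),
               welch_p = t_p, welch_stars = p_stars(t_p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
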