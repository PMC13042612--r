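# UPGMA (average-linkage) clustering of a genetic distance matrix into a
# rooted ultrametric tree.  Written out explicitly (rather than through a
# generic clustering routine) so the merge tie-break is documented and the
# Newick output is byte-reproducible: ties between candidate merges are
# broken by lexicographic pair order, comparing the lexicographically
# smallest original member of each cluster.

#' UPGMA tree from a distance matrix
#'
#' Standard unweighted pair-group average agglomeration: the closest pair
#' of clusters is merged at height d/2 and distances to the merged cluster
#' are size-weighted averages.  The result is rooted and ultrametric
#' (equal root-to-tip path lengths), and its cophenetic distances equal the
#' average of the original distances within each merged pair of clusters.
#'
#' @param D symmetric numeric matrix with zero diagonal and row/column
#'   names; `NA`/`NaN` entries are rejected naming the offending pair.
#' @return a rooted ultrametric [ape::phylo].
#' @export
upgma_tree <- function(D) {
  D <- as.matrix(D)
  labels <- rownames(D) %||% paste0("t", seq_len(nrow(D)))
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-12, na.rm = TRUE))
    stop_ypg("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop_ypg("distance matrix diagonal must be zero")
  bad <- which(is.na(D) | is.nan(D), arr.ind = TRUE)
  bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
  if (nrow(bad))
    stop_ypg("NA/NaN distance between ", labels[bad[1, 1]], " and ",
             labels[bad[1, 2]])
  k <- nrow(D)
  if (k < 2) stop_ypg("need at least 2 taxa")
  newick <- labels            # Newick fragment per active cluster
  height <- rep(0, k)         # current height of each cluster
  size <- rep(1L, k)
  first <- labels             # lexicographically smallest member
  d <- D
  while (k > 1) {
    # find minimum off-diagonal distance with lexicographic tie-break
    best <- NULL; best_d <- Inf
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      key <- sort(c(first[i], first[j]))
      if (d[i, j] < best_d - 1e-12 ||
          (abs(d[i, j] - best_d) <= 1e-12 && !is.null(best) &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best_d <- d[i, j]
        best <- list(i = i, j = j, key = key)
      }
    }
    i <- best$i; j <- best$j
    h <- best_d / 2
    frag <- sprintf("(%s:%.12g,%s:%.12g)", newick[i], h - height[i],
                    newick[j], h - height[j])
    # merged distances: size-weighted average
    keep <- setdiff(seq_len(k), c(i, j))
    newd <- (size[i] * d[i, keep] + size[j] * d[j, keep]) /
      (size[i] + size[j])
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd),
               c(newd, 0))
    newick <- c(newick[keep], frag)
    height <- c(height[keep], h)
    size <- c(size[keep], size[i] + size[j])
    first <- c(first[keep], min(best$key))
    k <- k - 1L
  }
  ape::read.tree(text = paste0(newick, ";"))
}
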