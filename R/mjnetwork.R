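# Median-joining haplotype networks (Bandelt's algorithm) and the
# Excoffier-Smouse minimum spanning network it iterates over.  Outputs are
# deterministic: haplotypes are ordered lexicographically by sequence, all
# minimum-spanning ties are retained, and median vectors are generated in a
# fixed order.

hamming_mat <- function(seqmat) {
  n <- nrow(seqmat)
  d <- matrix(0L, n, n)
  if (n >= 2)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- sum(seqmat[i, ] != seqmat[j, ])
  d
}

# Edge set of the minimum spanning network: edge (i, j) is included iff i
# and j lie in different connected components of the graph containing all
# strictly shorter edges (shorter than d_ij - epsilon).  At epsilon = 0
# this is exactly the union of all minimum spanning trees, so every tie is
# retained.
msn_edges <- function(d, epsilon = 0) {
  n <- nrow(d)
  if (n < 2) return(data.frame(from = integer(0), to = integer(0),
                               weight = numeric(0)))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[pairs]
  comp_below <- function(thresh) {
    # connected components using edges with weight < thresh
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    sel <- which(w < thresh)
    for (e in sel) {
      a <- find(pairs[e, 1]); b <- find(pairs[e, 2])
      if (a != b) parent[a] <- b
    }
    vapply(seq_len(n), find, integer(1))
  }
  keep <- logical(nrow(pairs))
  for (lev in sort(unique(w))) {
    comp <- comp_below(lev - epsilon - 1e-9)
    at <- which(abs(w - lev) < 1e-9)
    keep[at] <- comp[pairs[at, 1]] != comp[pairs[at, 2]]
  }
  data.frame(from = pairs[keep, 1], to = pairs[keep, 2], weight = w[keep])
}

prepare_haplotypes <- function(haplotypes, counts = NULL,
                               max_haplotypes = 2000) {
  if (inherits(haplotypes, "hap_alignment")) {
    seqs <- apply(haplotypes$mat, 1, paste, collapse = "")
    tab <- table(seqs)
    counts <- as.integer(tab)
    seqs <- names(tab)
  } else {
    seqs <- toupper(as.character(haplotypes))
    if (anyDuplicated(seqs)) stop_ypg("haplotypes must be distinct")
    counts <- counts %||% rep(1L, length(seqs))
  }
  if (length(unique(nchar(seqs))) > 1) stop_ypg("ragged haplotypes")
  if (length(seqs) > max_haplotypes)
    stop_ypg(length(seqs), " haplotypes exceed the limit of ",
             max_haplotypes, "; subsample the input")
  ord <- order(seqs) # canonical internal ordering
  list(seqs = seqs[ord], counts = counts[ord])
}

#' Minimum spanning network of haplotypes
#'
#' All edges belonging to any minimum spanning tree of the Hamming-distance
#' graph, plus (for `epsilon > 0`) alternative edges within `epsilon` of
#' the merge threshold.  Ties are always retained, so three equidistant
#' haplotypes form a triangle.
#'
#' @param haplotypes distinct equal-length haplotype strings over
#'   `{A,C,G,T,0,1}`, or a [hap_alignment()] (whose duplicate sequences are
#'   collapsed into counts).
#' @param counts optional multiplicities (annotation only).
#' @param epsilon weight tolerance (default 0, the parsimonious setting).
#' @param max_haplotypes size guard (default 2000).
#' @return object of class `haplotype_network` (see [build_mj_network()])
#'   without median vectors.
#' @export
minimum_spanning_network <- function(haplotypes, counts = NULL, epsilon = 0,
                                     max_haplotypes = 2000) {
  h <- prepare_haplotypes(haplotypes, counts, max_haplotypes)
  if (length(h$seqs) < 2) stop_ypg("need at least 2 distinct haplotypes")
  seqmat <- do.call(rbind, strsplit(h$seqs, ""))
  d <- hamming_mat(seqmat)
  edges <- msn_edges(d, epsilon)
  make_network(h$seqs, h$counts, inferred = rep(FALSE, length(h$seqs)),
               edges = edges, epsilon = epsilon)
}

make_network <- function(seqs, counts, inferred, edges, epsilon) {
  ids <- ifelse(inferred, paste0("mv", cumsum(inferred)),
                paste0("H", cumsum(!inferred)))
  nodes <- data.frame(id = ids, sequence = seqs, count = counts,
                      inferred = inferred, stringsAsFactors = FALSE)
  edges <- data.frame(from = ids[edges$from], to = ids[edges$to],
                      weight = edges$weight, stringsAsFactors = FALSE)
  cost <- steiner_network_cost(seqs, inferred)
  structure(list(nodes = nodes, edges = edges, epsilon = epsilon,
                 total_cost = cost),
            class = "haplotype_network")
}

# Cost of the cheapest tree contained in the network that connects every
# observed haplotype: minimum MST cost over the observed nodes plus any
# subset of the retained median vectors.  A median-joining network is a
# union of optimal trees, so it may retain medians that no single cheapest
# tree uses; those must not be charged to the network cost.  Exact subset
# enumeration up to 12 medians, greedy median elimination beyond that.
steiner_network_cost <- function(seqs, inferred) {
  seqmat <- do.call(rbind, strsplit(seqs, ""))
  d <- hamming_mat(seqmat)
  obs <- which(!inferred)
  med <- which(inferred)
  if (!length(med)) return(mst_cost_d(d, obs))
  if (length(med) <= 12) {
    best <- Inf
    for (mask in 0:(2^length(med) - 1)) {
      pick <- med[bitwAnd(mask, 2^(seq_along(med) - 1)) > 0]
      best <- min(best, mst_cost_d(d, c(obs, pick)))
    }
    best
  } else {
    keep <- med
    cur <- mst_cost_d(d, c(obs, keep))
    repeat {
      improved <- FALSE
      for (i in seq_along(keep)) {
        trial <- mst_cost_d(d, c(obs, keep[-i]))
        if (trial <= cur) {
          cur <- trial; keep <- keep[-i]; improved <- TRUE; break
        }
      }
      if (!improved || !length(keep)) break
    }
    cur
  }
}

mst_cost_d <- function(d, idx) {
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

# Minimum-spanning-tree cost over a haplotype set (Prim).
mst_cost <- function(seqs) {
  n <- length(seqs)
  if (n < 2) return(0)
  seqmat <- do.call(rbind, strsplit(seqs, ""))
  d <- hamming_mat(seqmat)
  intree <- c(TRUE, rep(FALSE, n - 1))
  mind <- d[1, ]
  cost <- 0
  for (step in seq_len(n - 1)) {
    j <- which(!intree)[which.min(mind[!intree])]
    cost <- cost + mind[j]
    intree[j] <- TRUE
    mind <- pmin(mind, d[j, ])
  }
  cost
}

#' Median-joining haplotype network
#'
#' Bandelt's median-joining algorithm: iteratively build the minimum
#' spanning network at tolerance `epsilon`, enumerate connected triplets
#' (u, v, w with u-v and v-w network edges), form their majority-state
#' median vectors, and add the medians whose connection cost
#' \eqn{d(u,m) + d(v,m) + d(w,m)} is within `epsilon` of the round's
#' minimum, until no new median reduces the network.  Obsolete median
#' vectors (degree < 3 in the final network) are pruned.  Multiplicities
#' are carried as node annotations and never affect topology.  At a site
#' where all three triplet states differ the state of the central node `v`
#' is kept (only possible for non-binary alphabets).
#'
#' @inheritParams minimum_spanning_network
#' @return object of class `haplotype_network`: list with `nodes`
#'   (id, sequence, count, inferred), `edges` (from, to, weight),
#'   `epsilon` and `total_cost` -- the cost of the cheapest tree contained
#'   in the network that connects every observed haplotype (the network is
#'   a union of optimal trees, so unused alternative medians are not
#'   charged); never more than the MST cost over observed haplotypes
#'   alone.
#' @export
build_mj_network <- function(haplotypes, counts = NULL, epsilon = 0,
                             max_haplotypes = 2000) {
  h <- prepare_haplotypes(haplotypes, counts, max_haplotypes)
  if (length(h$seqs) < 2) stop_ypg("need at least 2 distinct haplotypes")
  obs <- h$seqs
  seqs <- obs
  max_iter <- 25L
  for (iter in seq_len(max_iter)) {
    seqmat <- do.call(rbind, strsplit(seqs, ""))
    d <- hamming_mat(seqmat)
    edges <- msn_edges(d, epsilon)
    adj <- vector("list", length(seqs))
    for (e in seq_len(nrow(edges))) {
      adj[[edges$from[e]]] <- c(adj[[edges$from[e]]], edges$to[e])
      adj[[edges$to[e]]] <- c(adj[[edges$to[e]]], edges$from[e])
    }
    cand <- character(0); lambda <- numeric(0)
    for (v in seq_along(seqs)) {
      nb <- sort(unique(adj[[v]]))
      if (length(nb) < 2) next
      for (a in seq_len(length(nb) - 1)) for (b in (a + 1):length(nb)) {
        u <- nb[a]; w <- nb[b]
        m <- median_vector(seqmat[u, ], seqmat[v, ], seqmat[w, ])
        ms <- paste(m, collapse = "")
        if (ms %in% seqs) next
        lam <- sum(m != seqmat[u, ]) + sum(m != seqmat[v, ]) +
          sum(m != seqmat[w, ])
        hit <- match(ms, cand)
        if (is.na(hit)) {
          cand <- c(cand, ms); lambda <- c(lambda, lam)
        } else lambda[hit] <- min(lambda[hit], lam)
      }
    }
    if (!length(cand)) break
    add <- sort(unique(cand[lambda <= min(lambda) + epsilon]))
    seqs <- sort(c(seqs, add))
  }
  # prune obsolete medians: inferred nodes need degree >= 3
  repeat {
    seqmat <- do.call(rbind, strsplit(seqs, ""))
    d <- hamming_mat(seqmat)
    edges <- msn_edges(d, epsilon)
    deg <- tabulate(c(edges$from, edges$to), length(seqs))
    drop <- which(!(seqs %in% obs) & deg < 3)
    if (!length(drop)) break
    seqs <- seqs[-drop]
  }
  inferred <- !(seqs %in% obs)
  counts <- integer(length(seqs))
  counts[!inferred] <- h$counts[match(seqs[!inferred], obs)]
  make_network(seqs, counts, inferred, edges, epsilon)
}

# Site-wise majority of three aligned haplotypes; central state v breaks
# three-way disagreements.
median_vector <- function(u, v, w) {
  m <- v
  uw <- u == w
  m[uw] <- u[uw]
  m
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("haplotype_network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$inferred), "inferred ),", nrow(x$edges),
      "edges, cost", x$total_cost, "\n")
  invisible(x)
}

#' Write a haplotype network as node/edge TSVs and GraphML
#'
#' @param net a `haplotype_network`.
#' @param nodes_path,edges_path TSV outputs.
#' @param graphml_path optional GraphML XML export.
#' @return invisibly, the paths written.
#' @export
write_network <- function(net, nodes_path, edges_path,
                          graphml_path = NULL) {
  write_table(net$nodes, nodes_path, params = list(epsilon = net$epsilon,
                                                   cost = net$total_cost))
  write_table(net$edges, edges_path, params = list(epsilon = net$epsilon))
  if (!is.null(graphml_path)) {
    con <- file(graphml_path, "wt")
    on.exit(close(con))
    writeLines(c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '<key id="seq" for="node" attr.name="sequence" attr.type="string"/>',
      '<key id="count" for="node" attr.name="count" attr.type="int"/>',
      '<key id="w" for="edge" attr.name="weight" attr.type="double"/>',
      '<graph edgedefault="undirected">'), con)
    for (i in seq_len(nrow(net$nodes)))
      writeLines(sprintf(
        '<node id="%s"><data key="seq">%s</data><data key="count">%d</data></node>',
        net$nodes$id[i], net$nodes$sequence[i], net$nodes$count[i]), con)
    for (i in seq_len(nrow(net$edges)))
      writeLines(sprintf(
        '<edge source="%s" target="%s"><data key="w">%g</data></edge>',
        net$edges$from[i], net$edges$to[i], net$edges$weight[i]), con)
    writeLines(c("</graph>", "</graphml>"), con)
  }
  invisible(c(nodes_path, edges_path, graphml_path))
}
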