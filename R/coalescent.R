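# Coalescent genealogy simulator (constant size or exponential growth) and
# infinite-sites mutation dropper.  These are the synthetic stand-ins for
# the demographic processes a dated Y-chromosome phylogeny records: a
# constant-size null, and recent exponential growth such as a
# Neolithic-expansion signal.

#' Simulate a dated coalescent genealogy
#'
#' Standard Kingman coalescent with pairwise coalescence rate
#' \eqn{{k \choose 2} / (2 N(t))} per generation, so for a sample of two the
#' expected coalescence time is \eqn{2 N_0} generations.  Under exponential
#' growth at rate `g` per generation starting `growth_onset` generations
#' before present, the backward-time population size is
#' \eqn{N(t) = N_0 e^{-g t}} for \eqn{t \le} `growth_onset` and constant
#' \eqn{N_0 e^{-g\,\mathrm{onset}}} earlier; waiting times are drawn by
#' exact deterministic time rescaling of unit exponentials, not by
#' discrete-generation simulation.
#'
#' @param n_samples number of tips (>= 2).
#' @param N0 present-day effective size (> 0), in individuals.
#' @param growth_rate exponential growth rate per generation (>= 0; 0 =
#'   constant size).
#' @param growth_onset generations before present at which growth began
#'   (`Inf` = growth throughout).
#' @param generation_time years per generation (default 29, the value
#'   conventionally used for human paternal genealogies).
#' @param seed integer seed; all randomness in the call flows through it.
#' @return a rooted binary [ape::phylo] with `n_samples` tips at age 0,
#'   branch lengths in years, internal node labels `n1..`, and a
#'   `node_ages` attribute (years, indexed by ape node number).
#' @export
simulate_coalescent_tree <- function(n_samples, N0, growth_rate = 0,
                                     growth_onset = Inf,
                                     generation_time = 29, seed = NULL) {
  if (n_samples < 2) stop_ypg("n_samples must be >= 2")
  if (N0 <= 0) stop_ypg("N0 must be > 0")
  if (growth_rate < 0) stop_ypg("growth_rate must be >= 0")
  if (generation_time <= 0) stop_ypg("generation_time must be > 0")
  with_seed_(seed, {
    n <- as.integer(n_samples)
    g <- growth_rate
    onset <- growth_onset
    # node numbering: tips 1..n; internal node for coalescent event j
    # (j = 1..n-1) is 2n - j, so the root (last event) is n + 1 as ape
    # requires.
    ages_gen <- numeric(2 * n - 1)
    edge <- matrix(0L, nrow = 2 * (n - 1), ncol = 2)
    active <- seq_len(n)
    t <- 0
    erow <- 0L
    for (j in seq_len(n - 1)) {
      k <- length(active)
      lam <- k * (k - 1) / 2
      E <- rexp(1)
      if (g > 0 && t < onset) {
        # growth phase: intensity integral lam * (e^{g u} - e^{g t})/(2 N0 g)
        rhs <- exp(g * t) + 2 * N0 * g * E / lam
        u <- log(rhs) / g
        if (u > onset) {
          E1 <- lam * (exp(g * onset) - exp(g * t)) / (2 * N0 * g)
          N_anc <- N0 * exp(-g * onset)
          u <- onset + 2 * N_anc * (E - E1) / lam
        }
      } else {
        Ncur <- if (g > 0) N0 * exp(-g * onset) else N0
        u <- t + 2 * Ncur * E / lam
      }
      t <- u
      pair <- sample.int(k, 2)
      p <- 2L * n - j
      ages_gen[p] <- t
      for (c in active[pair]) {
        erow <- erow + 1L
        edge[erow, ] <- c(p, c)
      }
      active <- c(active[-pair], p)
    }
    ages <- ages_gen * generation_time
    edge_len <- ages[edge[, 1]] - ages[edge[, 2]]
    tr <- structure(list(edge = edge, edge.length = edge_len,
                         tip.label = paste0("s", seq_len(n)),
                         node.label = paste0("n", seq_len(n - 1)),
                         Nnode = n - 1L),
                    class = "phylo", order = "cladewise")
    tr <- ape::reorder.phylo(tr, "cladewise")
    attr(tr, "node_ages") <- ages
    tr
  })
}

#' Drop infinite-sites mutations on a dated tree
#'
#' Each branch receives a Poisson number of mutations with mean
#' `mu * branch length (years) * n_sites`; every mutation is assigned to a
#' distinct site of a finite grid (infinite-sites emulation).  If the total
#' number of mutations exceeds `n_sites`, the site grid is saturated and an
#' error advises increasing `n_sites` (collisions are never silently
#' reused).  Sequences are binary: `0` ancestral, `1` derived.
#'
#' @param tree dated [ape::phylo] with branch lengths in years (e.g. from
#'   [simulate_coalescent_tree()]).
#' @param mu mutation rate per site per year (default 7.6e-10, the
#'   substitution rate conventionally used for Y-chromosome dating).
#' @param n_sites size of the site grid (>= 1).
#' @param seed integer seed.
#' @param segregating_only if `TRUE`, return only the mutated (segregating)
#'   columns; the full grid size remains available as the `n_sites`
#'   attribute.  Invariant columns carry no information for any statistic
#'   in the package, so this is purely a memory choice.
#' @return a [hap_alignment()] over the tips, with attributes `site_map`
#'   (data.frame `site`, `branch_id` = label of the child node of the
#'   mutated branch) and `n_sites`.
#' @export
drop_mutations <- function(tree, mu = 7.6e-10, n_sites, seed = NULL,
                           segregating_only = FALSE) {
  if (n_sites < 1) stop_ypg("n_sites must be >= 1")
  if (mu < 0) stop_ypg("mu must be >= 0")
  with_seed_(seed, {
    n <- ape::Ntip(tree)
    nmut <- rpois(nrow(tree$edge), mu * tree$edge.length * n_sites)
    total <- sum(nmut)
    if (total > n_sites)
      stop_ypg("site grid saturated: ", total, " mutations on ", n_sites,
               " sites; increase n_sites")
    sites <- sample.int(n_sites, total)
    tip_sets <- edge_tip_sets(tree)
    keep_cols <- if (segregating_only) sites else seq_len(n_sites)
    mat <- matrix("0", nrow = n, ncol = length(keep_cols))
    col_of <- setNames(seq_along(keep_cols), keep_cols)
    branch_ids <- node_label(tree, tree$edge[, 2])
    site_map <- data.frame(site = integer(0), branch_id = character(0),
                           stringsAsFactors = FALSE)
    idx <- 0L
    rows <- vector("list", sum(nmut > 0))
    ri <- 0L
    for (e in which(nmut > 0)) {
      s <- sites[idx + seq_len(nmut[e])]
      idx <- idx + nmut[e]
      mat[tip_sets[[e]], col_of[as.character(s)]] <- "1"
      ri <- ri + 1L
      rows[[ri]] <- data.frame(site = s, branch_id = branch_ids[e],
                               stringsAsFactors = FALSE)
    }
    if (ri > 0) site_map <- do.call(rbind, rows[seq_len(ri)])
    site_map <- site_map[order(site_map$site), , drop = FALSE]
    rownames(site_map) <- NULL
    aln <- hap_alignment(mat, ids = tree$tip.label)
    attr(aln, "site_map") <- site_map
    attr(aln, "n_sites") <- n_sites
    aln
  })
}

# Label of a node by ape number: tip label for tips, node.label otherwise.
node_label <- function(tree, num) {
  n <- ape::Ntip(tree)
  lab <- character(length(num))
  is_tip <- num <= n
  lab[is_tip] <- tree$tip.label[num[is_tip]]
  if (is.null(tree$node.label))
    tree$node.label <- paste0("n", seq_len(tree$Nnode))
  lab[!is_tip] <- tree$node.label[num[!is_tip] - n]
  lab
}

# ape number of a node by label.
node_number <- function(tree, lab) {
  n <- ape::Ntip(tree)
  labels <- c(tree$tip.label,
              tree$node.label %||% paste0("n", seq_len(tree$Nnode)))
  i <- match(lab, labels)
  if (anyNA(i)) stop_ypg("unknown node label(s): ",
                         paste(lab[is.na(i)], collapse = ", "))
  i
}

# For each edge, the tip numbers below its child node (postorder sweep).
edge_tip_sets <- function(tree) {
  n <- ape::Ntip(tree)
  below <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) below[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; c <- po$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  lapply(seq_len(nrow(tree$edge)), function(e) below[[tree$edge[e, 2]]])
}
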