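# Dated-tree chronology: clade TMRCA extraction, branching-events-through-
# time histograms, the shared-lineage criterion between two regions, and
# SNP-based placement of low-coverage query samples onto an annotated
# reference tree.

#' TMRCA of a set of tips
#'
#' Age (in the tree's branch-length units, here years) of the most recent
#' common ancestor of the tip set.
#'
#' @param tree dated [ape::phylo].
#' @param tips character vector of tip labels (non-empty).
#' @return age in years; a single tip returns 0 with a warning flag
#'   attribute.
#' @export
clade_tmrca <- function(tree, tips) {
  if (!length(tips)) stop_ypg("empty tip set")
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing))
    stop_ypg("tips absent from tree: ", paste(missing, collapse = ", "))
  ages <- attr(tree, "node_ages") %||% node_ages(tree)
  if (length(tips) == 1) {
    out <- ages[match(tips, tree$tip.label)]
    attr(out, "flag") <- "single-tip"
    return(out)
  }
  mrca <- ape::getMRCA(tree, tips)
  unname(ages[mrca])
}

#' Branching-events-through-time histogram
#'
#' Each internal node (one coalescent/branching event in a dated genealogy)
#' is assigned by its age to the half-open bin `[k*w, (k+1)*w)` -- a node
#' exactly on a boundary goes to the younger bin.  New counts are per bin;
#' cumulative counts accumulate from the oldest bin in range toward the
#' present, so they are non-decreasing toward age 0.
#'
#' @param tree dated [ape::phylo] (branch lengths in years).
#' @param bin_width bin width in years (default 500).
#' @param t_max optional upper age limit; nodes older than `t_max` are
#'   outside the range and uncounted.
#' @return data.frame ordered oldest to youngest: `bin_start`, `bin_end`
#'   (ages in years, `bin_start < bin_end`), `new`, `cumulative`.
#' @export
branching_histogram <- function(tree, bin_width = 500, t_max = NULL) {
  if (bin_width <= 0) stop_ypg("bin_width must be > 0")
  ages <- (attr(tree, "node_ages") %||% node_ages(tree))
  ages <- ages[(ape::Ntip(tree) + 1):(ape::Ntip(tree) + tree$Nnode)]
  if (!is.null(t_max)) ages <- ages[ages < t_max]
  if (!length(ages))
    return(data.frame(bin_start = numeric(0), bin_end = numeric(0),
                      new = integer(0), cumulative = integer(0)))
  top <- if (!is.null(t_max)) t_max else max(ages) + bin_width
  nbins <- ceiling(top / bin_width)
  bin <- pmin(floor(ages / bin_width), nbins - 1)
  counts <- tabulate(bin + 1, nbins)
  df <- data.frame(bin_start = (seq_len(nbins) - 1) * bin_width,
                   bin_end = seq_len(nbins) * bin_width,
                   new = counts)
  df <- df[order(-df$bin_start), ]
  df$cumulative <- cumsum(df$new)
  rownames(df) <- NULL
  df
}

#' Shared-lineage detection between two regions
#'
#' Every internal clade is evaluated against the shared-lineage rule: a
#' clade is shared between regions A and B when it contains strictly more
#' than `min_descendants` tips ("more than" is a strict inequality, so a
#' clade of exactly `min_descendants` tips does not qualify) and the
#' clade's tips reach frequency at least `min_freq` among each region's
#' total tips.  By default only maximal qualifying clades are reported
#' (a qualifying clade nested in another qualifying clade is suppressed);
#' `report_nested = TRUE` reports all.
#'
#' @param tree dated [ape::phylo].
#' @param regions named character vector (names = tip labels) with region
#'   labels; tips not in `region_a`/`region_b` count as "other".  Defaults
#'   to the tree's `tip_regions` attribute.
#' @param region_a,region_b the two region labels of interest.
#' @param min_descendants strict lower bound on clade size (default 30).
#' @param min_freq minimum within-region frequency in both regions
#'   (default 0.01; the defining frequency is a tunable threshold and is
#'   echoed in the output).
#' @param report_nested report nested qualifying clades too.
#' @return data.frame, one row per reported clade: `clade` (internal node
#'   label), `n_tips`, per-region counts and frequencies, `tmrca`, and
#'   `shared` verdict; thresholds echoed as attributes `min_descendants`
#'   and `min_freq`.
#' @export
shared_lineages <- function(tree, regions = NULL, region_a, region_b,
                            min_descendants = 30, min_freq = 0.01,
                            report_nested = FALSE) {
  regions <- regions %||% attr(tree, "tip_regions")
  if (is.null(regions)) stop_ypg("no region labels supplied")
  missing <- setdiff(tree$tip.label, names(regions))
  if (length(missing))
    stop_ypg("tips without region label: ", paste(missing, collapse = ", "))
  reg <- unname(regions[tree$tip.label])
  n <- ape::Ntip(tree)
  tot_a <- sum(reg == region_a)
  tot_b <- sum(reg == region_b)
  ages <- attr(tree, "node_ages") %||% node_ages(tree)
  tip_sets <- clade_tip_sets(tree)
  nodes <- (n + 1):(n + tree$Nnode)
  qual <- logical(length(nodes))
  info <- vector("list", length(nodes))
  for (k in seq_along(nodes)) {
    tips <- tip_sets[[nodes[k]]]
    ca <- sum(reg[tips] == region_a)
    cb <- sum(reg[tips] == region_b)
    fa <- if (tot_a > 0) ca / tot_a else 0
    fb <- if (tot_b > 0) cb / tot_b else 0
    ok <- length(tips) > min_descendants && fa >= min_freq && fb >= min_freq
    qual[k] <- ok
    info[[k]] <- data.frame(clade = node_label(tree, nodes[k]),
                            n_tips = length(tips), count_a = ca,
                            count_b = cb, freq_a = fa, freq_b = fb,
                            tmrca = unname(ages[nodes[k]]), shared = ok,
                            stringsAsFactors = FALSE)
  }
  keep <- qual
  if (!report_nested && any(qual)) {
    # suppress qualifying clades nested inside another qualifying clade
    parent_of <- function(num) {
      p <- tree$edge[tree$edge[, 2] == num, 1]
      if (length(p)) p else NA_integer_
    }
    for (k in which(qual)) {
      p <- parent_of(nodes[k])
      while (!is.na(p)) {
        if (qual[match(p, nodes)]) { keep[k] <- FALSE; break }
        p <- parent_of(p)
      }
    }
  }
  out <- do.call(rbind, info[keep])
  if (is.null(out))
    out <- data.frame(clade = character(0), n_tips = integer(0),
                      count_a = integer(0), count_b = integer(0),
                      freq_a = numeric(0), freq_b = numeric(0),
                      tmrca = numeric(0), shared = logical(0))
  rownames(out) <- NULL
  attr(out, "min_descendants") <- min_descendants
  attr(out, "min_freq") <- min_freq
  out
}

# Tip numbers below every node (tips map to themselves).
clade_tip_sets <- function(tree) {
  n <- ape::Ntip(tree)
  below <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) below[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; c <- po$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  below
}

#' Place a low-coverage query onto a branch-annotated tree
#'
#' Root-to-terminal walk: at each node every child branch is scored over
#' its annotated SNPs observed in the query as (derived matches) minus
#' (ancestral conflicts); the walk descends only when exactly one child
#' branch scores at least `min_support`, and otherwise stops with reason
#' `"no-support"` or `"tie"`.  Stopping on a tie deliberately places
#' ambiguous low-coverage queries upstream (toward the root) rather than
#' guessing a subclade.
#'
#' @param tree [ape::phylo] whose branches are annotated.
#' @param branch_snps data.frame `branch_id`, `snp_id`.
#' @param genotypes query genotype data.frame `snp_id`, `allele_state` in
#'   `{ancestral, derived}` (missing calls simply absent).
#' @param min_support minimum net derived support to descend (default 1).
#' @return list of class `placement_result`: `branch` (label of the child
#'   node of the final branch, `NA` if the query never left the root),
#'   `path` (labels root-ward to final branch), `stop_reason` in
#'   `{no-support, tie, tip-reached, unplaceable}`, and `tallies`
#'   (per-visited-branch support/conflict counts).
#' @export
place_query <- function(tree, branch_snps, genotypes, min_support = 1) {
  if (is.null(branch_snps) || !nrow(branch_snps))
    stop_ypg("tree has no branch-SNP annotation")
  geno <- genotypes[genotypes$snp_id %in% branch_snps$snp_id, , drop = FALSE]
  if (!nrow(geno))
    return(structure(list(branch = NA_character_, path = character(0),
                          stop_reason = "unplaceable",
                          tallies = data.frame()),
                     class = "placement_result"))
  state <- setNames(geno$allele_state, geno$snp_id)
  snp_by_branch <- split(branch_snps$snp_id, branch_snps$branch_id)
  n <- ape::Ntip(tree)
  cur <- n + 1L # root
  path <- character(0)
  tallies <- list()
  reason <- NULL
  repeat {
    children <- tree$edge[tree$edge[, 1] == cur, 2]
    if (!length(children)) { reason <- "tip-reached"; break }
    score <- support <- conflict <- numeric(length(children))
    for (ci in seq_along(children)) {
      lab <- node_label(tree, children[ci])
      snps <- snp_by_branch[[lab]] %||% character(0)
      obs <- state[snps[snps %in% names(state)]]
      support[ci] <- sum(obs == "derived")
      conflict[ci] <- sum(obs == "ancestral")
      score[ci] <- support[ci] - conflict[ci]
    }
    qual <- which(score >= min_support)
    if (length(qual) == 0) { reason <- "no-support"; break }
    if (length(qual) > 1) { reason <- "tie"; break }
    ch <- children[qual]
    lab <- node_label(tree, ch)
    path <- c(path, lab)
    tallies[[lab]] <- data.frame(branch = lab, support = support[qual],
                                 conflict = conflict[qual],
                                 stringsAsFactors = FALSE)
    cur <- ch
  }
  structure(list(branch = if (length(path)) tail(path, 1) else NA_character_,
                 path = path, stop_reason = reason,
                 tallies = if (length(tallies))
                   do.call(rbind, unname(tallies)) else data.frame()),
            class = "placement_result")
}

#' @export
print.placement_result <- function(x, ...) {
  cat("placement:", x$branch %||% "NA", "(", x$stop_reason, ")\n")
  invisible(x)
}
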