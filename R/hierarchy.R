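# Haplogroup nomenclature hierarchy and level-truncation conventions.

#' Build a haplogroup hierarchy from parent-child edges
#'
#' The hierarchy is a single-rooted, acyclic name tree (as implied by a
#' haplogroup classifier's nomenclature).  Multi-root and cyclic edge lists
#' are rejected.
#'
#' @param parent,child character vectors of equal length; each pair is one
#'   edge of the name tree.
#' @return an object of class `haplogroup_hierarchy` with the parent lookup.
#' @export
haplogroup_hierarchy <- function(parent, child) {
  parent <- as.character(parent); child <- as.character(child)
  stopifnot(length(parent) == length(child))
  if (anyDuplicated(child))
    stop_ypg("haplogroup listed with more than one parent: ",
             paste(unique(child[duplicated(child)]), collapse = ", "))
  nodes <- union(parent, child)
  roots <- setdiff(parent, child)
  if (length(roots) != 1L)
    stop_ypg("hierarchy must have exactly one root, found: ",
             paste(sort(roots), collapse = ", ") %||% "none")
  pmap <- setNames(parent, child)
  # cycle / orphan check: every node must reach the root
  for (n in nodes) {
    seen <- character(0); cur <- n
    while (cur %in% names(pmap)) {
      if (cur %in% seen) stop_ypg("cycle in hierarchy at ", cur)
      seen <- c(seen, cur)
      cur <- pmap[[cur]]
    }
    if (cur != roots) stop_ypg("node ", n, " does not descend from the root")
  }
  structure(list(parent = pmap, root = roots, nodes = nodes),
            class = "haplogroup_hierarchy")
}

#' Read a haplogroup hierarchy from a two-column parent-child TSV
#' @param path TSV with columns `parent` and `child` (header required).
#' @return a [haplogroup_hierarchy()].
#' @export
read_haplogroup_hierarchy <- function(path) {
  df <- read_tsv_(path)
  need <- c("parent", "child")
  if (!all(need %in% names(df)))
    stop_ypg("hierarchy file must have columns: ", paste(need, collapse = ", "))
  haplogroup_hierarchy(df$parent, df$child)
}

#' @export
print.haplogroup_hierarchy <- function(x, ...) {
  cat("haplogroup_hierarchy:", length(x$nodes), "names, root", x$root, "\n")
  invisible(x)
}

#' Parent, children and depth within a haplogroup hierarchy
#'
#' Depth is counted from the root, with `depth(root) = 1`.
#'
#' @param hier a [haplogroup_hierarchy()].
#' @param name haplogroup name.
#' @return `hg_parent`: parent name or `NA` at the root; `hg_children`:
#'   character vector; `hg_depth`: integer depth.
#' @export
hg_parent <- function(hier, name) {
  if (name == hier$root) return(NA_character_)
  if (!name %in% names(hier$parent)) stop_ypg("unknown haplogroup: ", name)
  unname(hier$parent[[name]])
}

#' @rdname hg_parent
#' @export
hg_children <- function(hier, name) {
  unname(names(hier$parent)[hier$parent == name])
}

#' @rdname hg_parent
#' @export
hg_depth <- function(hier, name) {
  if (!name %in% hier$nodes) stop_ypg("unknown haplogroup: ", name)
  d <- 1L; cur <- name
  while (cur != hier$root) { cur <- hg_parent(hier, cur); d <- d + 1L }
  d
}

#' Ancestor of a haplogroup at a given nomenclature level
#'
#' Two conventions are supported.  With a hierarchy, "level" is depth in the
#' supplied name tree (root = level 1) and the ancestor is found by walking
#' parent links.  Without one, the character-segment fallback splits the
#' name into alternating letter/digit runs and keeps the first `level` runs
#' (`O` = 1, `O2` = 2, `O2a` = 3, `O2a2` = 4), the usual shorthand for
#' Y-haplogroup nomenclature strings.
#'
#' @param name haplogroup name.
#' @param level target level (>= 1).
#' @param hier optional [haplogroup_hierarchy()]; `NULL` selects the
#'   segment fallback.
#' @return ancestor name; the name itself if already at or above the level.
#'   Unknown names under a hierarchy return `NA` (callers bucket these as
#'   "unresolved").
#' @export
hg_ancestor_at_level <- function(name, level, hier = NULL) {
  stopifnot(level >= 1)
  if (is.null(hier)) return(hg_truncate_name(name, level))
  if (!name %in% hier$nodes) return(NA_character_)
  d <- hg_depth(hier, name)
  while (d > level) { name <- hg_parent(hier, name); d <- d - 1L }
  name
}

# Character-segment fallback: first `level` alternating alphanumeric runs.
hg_truncate_name <- function(name, level) {
  vapply(as.character(name), function(nm) {
    segs <- regmatches(nm, gregexpr("[A-Za-z]+|[0-9]+", nm))[[1]]
    paste(segs[seq_len(min(level, length(segs)))], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
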