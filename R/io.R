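# Readers and writers for the plain-text interchange formats: sample TSVs,
# dated Newick trees, result tables.  Readers validate and reject malformed
# input; they never silently repair it.

# Internal TSV reader; lines starting with '#' are parameter-echo headers.
read_tsv_ <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

SAMPLE_COLUMNS <- c("sample_id", "population", "region", "language",
                    "latitude", "longitude", "haplogroup")

#' Read a sample table
#'
#' One row per sequenced individual: identifier, population, geographic
#' region label, language family, WGS84 coordinates in decimal degrees and
#' the haplogroup call.  Duplicate ids, out-of-range coordinates and empty
#' haplogroup calls are rejected with their row numbers.
#'
#' @param path TSV with header columns `sample_id`, `population`, `region`,
#'   `language`, `latitude`, `longitude`, `haplogroup`.
#' @return a `data.frame` of validated sample records.
#' @export
read_sample_table <- function(path) {
  df <- read_tsv_(path)
  missing <- setdiff(SAMPLE_COLUMNS, names(df))
  if (length(missing))
    stop_ypg("sample table is missing columns: ",
             paste(missing, collapse = ", "))
  df <- df[SAMPLE_COLUMNS]
  validate_sample_table(df)
  df
}

validate_sample_table <- function(df) {
  df$latitude <- as.numeric(df$latitude)
  df$longitude <- as.numeric(df$longitude)
  bad_lat <- which(is.na(df$latitude) | df$latitude < -90 | df$latitude > 90)
  if (length(bad_lat))
    stop_ypg("invalid latitude at row(s): ", paste(bad_lat, collapse = ", "))
  bad_lon <- which(is.na(df$longitude) | df$longitude < -180 |
                     df$longitude > 180)
  if (length(bad_lon))
    stop_ypg("invalid longitude at row(s): ", paste(bad_lon, collapse = ", "))
  dup <- which(duplicated(df$sample_id))
  if (length(dup))
    stop_ypg("duplicate sample_id at row(s): ", paste(dup, collapse = ", "))
  empty <- which(is.na(df$haplogroup) | !nzchar(df$haplogroup))
  if (length(empty))
    stop_ypg("empty haplogroup at row(s): ", paste(empty, collapse = ", "))
  invisible(df)
}

#' Write a result table as TSV with a parameter-echo header
#'
#' Numeric columns are formatted to `digits` significant digits.  The
#' `params` list is echoed as `# key=value` comment lines so every output
#' records the parameters and seed that produced it.
#'
#' @param df a data.frame.
#' @param path output file.
#' @param params named list echoed into the header.
#' @param digits significant digits for numeric columns (default 6).
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, params = list(), digits = 6) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(params)) {
    for (k in names(params))
      writeLines(sprintf("# %s=%s", k,
                         paste(format(params[[k]], digits = 15),
                               collapse = ",")), con)
  }
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- signif(out[[j]], digits)
  }
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_sample_table
#' @param df a sample-record data.frame (validated before writing).
#' @export
write_sample_table <- function(df, path) {
  validate_sample_table(df)
  write.table(df[SAMPLE_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a dated rooted tree from Newick
#'
#' Branch lengths are in years.  Node ages are computed as (maximum
#' root-to-tip path length) minus (distance from root), so an ultrametric
#' tree has all tips at age 0.  BEAST-style bracketed comments are stripped,
#' not parsed.  Tip annotations of the form `name|region` are split into a
#' `region` attribute.
#'
#' @param path Newick file.
#' @return an [ape::phylo] tree with a `node_ages` attribute (vector indexed
#'   by ape node number) and, when tip labels carry `|region` suffixes, a
#'   `tip_regions` attribute named by the bare tip labels.
#' @export
read_dated_tree <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  txt <- gsub("\\[[^]]*\\]", "", txt) # strip bracketed comments
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop_ypg("unparseable Newick: ",
                                              conditionMessage(e)))
  if (is.null(tr)) stop_ypg("unparseable Newick in ", path)
  if (is.null(tr$edge.length)) stop_ypg("Newick has no branch lengths")
  if (any(tr$edge.length < 0)) stop_ypg("negative branch length in tree")
  regions <- NULL
  if (any(grepl("|", tr$tip.label, fixed = TRUE))) {
    parts <- strsplit(tr$tip.label, "|", fixed = TRUE)
    tr$tip.label <- vapply(parts, `[`, character(1), 1)
    regions <- setNames(vapply(parts, function(p) p[2] %||% NA_character_,
                               character(1)), tr$tip.label)
  }
  attr(tr, "node_ages") <- node_ages(tr)
  if (!is.null(regions)) attr(tr, "tip_regions") <- regions
  tr
}

#' Node ages of a dated tree
#'
#' Ages in the units of the branch lengths, measured back from the youngest
#' tip: age(node) = max root-to-tip distance - distance(root, node).
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @return numeric vector of length `Ntip + Nnode`, indexed by ape node
#'   number.
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_len(ape::Ntip(tree))]) - depth
}

#' Write a dated tree as Newick
#' @param tree an [ape::phylo].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dated_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read / write branch-SNP annotation and query genotype tables
#'
#' Branch-SNP tables have columns `branch_id` (label of the child node of
#' the annotated branch) and `snp_id`.  Query genotype tables additionally
#' carry `allele_state` in `{ancestral, derived}` (missing calls are simply
#' absent rows).
#'
#' @param path TSV file.
#' @return a data.frame.
#' @export
read_branch_snps <- function(path) {
  df <- read_tsv_(path)
  need <- c("branch_id", "snp_id")
  if (!all(need %in% names(df)))
    stop_ypg("branch-SNP table needs columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname read_branch_snps
#' @export
read_query_genotypes <- function(path) {
  df <- read_tsv_(path)
  need <- c("snp_id", "branch_id", "allele_state")
  if (!all(need %in% names(df)))
    stop_ypg("genotype table needs columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$allele_state), c("ancestral", "derived"))
  if (length(bad))
    stop_ypg("invalid allele_state values: ", paste(bad, collapse = ", "))
  df
}
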