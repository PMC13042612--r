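# Dated-tree chronology: TMRCA, branching histograms, shared lineages,
# query placement.

test_that("clade TMRCA reads node ages off the dated tree", {
  tr <- toy_dated_tree("((A:100,B:100):400,C:500);")
  expect_equal(clade_tmrca(tr, c("A", "B")), 100)
  expect_equal(clade_tmrca(tr, c("A", "B", "C")), 500)
  single <- clade_tmrca(tr, "A")
  expect_equal(as.numeric(single), 0)
  expect_equal(attr(single, "flag"), "single-tip")
  expect_error(clade_tmrca(tr, character(0)), "empty")
  expect_error(clade_tmrca(tr, "Z"), "absent")
  # simulated trees: TMRCA of all tips is the recorded root age
  sim <- simulate_coalescent_tree(12, 700, seed = 4)
  expect_equal(clade_tmrca(sim, sim$tip.label),
               max(attr(sim, "node_ages")))
  # monotone under supersets
  expect_lte(clade_tmrca(sim, sim$tip.label[1:3]),
             clade_tmrca(sim, sim$tip.label[1:6]))
})

test_that("branching histograms bin node ages half-open and accumulate", {
  # internal node ages 100, 600, 1100
  tr <- toy_dated_tree("((A:100,B:100):1000,(C:600,D:600):500);")
  h <- branching_histogram(tr, bin_width = 500)
  expect_equal(h$new[h$bin_start == 0], 1)
  expect_equal(h$new[h$bin_start == 500], 1)
  expect_equal(h$new[h$bin_start == 1000], 1)
  # cumulative accumulates oldest -> youngest
  expect_equal(h$cumulative, cumsum(h$new))
  expect_equal(h$bin_start, sort(h$bin_start, decreasing = TRUE))
  # totals equal internal node count on any tree
  sim <- simulate_coalescent_tree(40, 900, seed = 8)
  hs <- branching_histogram(sim, 500)
  expect_equal(sum(hs$new), 39)
  expect_error(branching_histogram(sim, 0), "bin_width")
  # boundary node goes to the younger bin
  tb <- toy_dated_tree("((A:500,B:500):100,C:600);")
  hb <- branching_histogram(tb, 500)
  expect_equal(hb$new[hb$bin_start == 500], 2) # ages 500 and 600
})

region_tree <- function() {
  # 34-tip clade (17 EA + 17 MSEA) as sister to 30 outside tips, plus a
  # 30-tip clade that misses the strict ">30" rule
  inner <- paste0("(", paste0(
    c(sprintf("i%d|EA:100", 1:17), sprintf("j%d|MSEA:100", 1:17)),
    collapse = ","), "):400")
  small <- paste0("(", paste0(
    c(sprintf("k%d|EA:50", 1:15), sprintf("l%d|MSEA:50", 1:15)),
    collapse = ","), "):450")
  rest <- paste0(sprintf("o%d|other:600", 1:30), collapse = ",")
  toy_dated_tree(paste0("((", inner, ",", small, "):100,(", rest, "):0);"))
}

test_that("shared-lineage rule is strict on descendant counts", {
  tr <- region_tree()
  rep <- shared_lineages(tr, region_a = "EA", region_b = "MSEA",
                         min_descendants = 30, min_freq = 0.01,
                         report_nested = TRUE)
  expect_true(all(rep$shared))
  expect_true(34 %in% rep$n_tips)   # qualifying clade reported
  expect_false(30 %in% rep$n_tips)  # exactly 30 tips: "more than 30" strict
  expect_equal(attr(rep, "min_descendants"), 30)
  # lowering the bound admits the 30-tip clade
  rep2 <- shared_lineages(tr, region_a = "EA", region_b = "MSEA",
                          min_descendants = 29, min_freq = 0.01,
                          report_nested = TRUE)
  expect_true(30 %in% rep2$n_tips)
  # maximal-only suppresses qualifying clades nested in qualifying parents
  rep3 <- shared_lineages(tr, region_a = "EA", region_b = "MSEA",
                          min_descendants = 29, min_freq = 0.01)
  expect_lt(nrow(rep3), nrow(rep2))
  expect_error(shared_lineages(tr, regions = c(x = "EA"), region_a = "EA",
                               region_b = "MSEA"), "without region")
})

test_that("shared-lineage verdicts are invariant to tip order", {
  tr <- region_tree()
  rot <- ape::rotateConstr(tr, rev(tr$tip.label))
  attr(rot, "tip_regions") <- attr(tr, "tip_regions")
  a <- shared_lineages(tr, region_a = "EA", region_b = "MSEA",
                       report_nested = TRUE)
  b <- shared_lineages(rot, region_a = "EA", region_b = "MSEA",
                       report_nested = TRUE)
  expect_setequal(a$n_tips, b$n_tips)
  expect_equal(sort(a$tmrca), sort(b$tmrca))
})

test_that("noiseless queries place on their true branch", {
  tr <- simulate_coalescent_tree(20, 600, seed = 14)
  bs <- annotate_branch_snps(tr, 6)
  for (tip in tr$tip.label[c(1, 7, 13, 20)]) {
    g <- simulate_query_genotypes(tr, bs, tip, seed = 1)
    res <- place_query(tr, bs, g)
    expect_equal(res$branch, tip)
    expect_equal(res$stop_reason, "tip-reached")
    expect_true(all(res$tallies$conflict == 0))
  }
})

test_that("ties stop the walk upstream and empty queries are unplaceable", {
  tr <- toy_dated_tree("((A:100,B:100):400,C:500);")
  bs <- annotate_branch_snps(tr, 3)
  # derived support for both children of the cherry: tie at their parent
  cherry <- setdiff(unique(bs$branch_id), c("A", "B", "C"))
  tie_geno <- data.frame(
    snp_id = bs$snp_id[bs$branch_id %in% c("A", "B", cherry)],
    branch_id = bs$branch_id[bs$branch_id %in% c("A", "B", cherry)],
    allele_state = "derived")
  res <- place_query(tr, bs, tie_geno)
  expect_equal(res$stop_reason, "tie")
  expect_equal(res$branch, cherry) # stopped on the branch above the tie
  # zero observed annotated SNPs
  none <- data.frame(snp_id = "zz", branch_id = "A",
                     allele_state = "derived")
  expect_equal(place_query(tr, bs, none)$stop_reason, "unplaceable")
})

test_that("placement support and conflict tallies are consistent", {
  tr <- simulate_coalescent_tree(15, 600, seed = 21)
  bs <- annotate_branch_snps(tr, 8)
  g <- simulate_query_genotypes(tr, bs, "s9", missing_rate = 0.4,
                                error_rate = 0, seed = 5)
  res <- place_query(tr, bs, g)
  # with zero error, every visited branch only accumulates derived support
  expect_true(all(res$tallies$conflict == 0))
  path <- ypopgen:::root_path_labels(tr, "s9")
  expect_true(res$branch %in% c(path, NA))
})
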