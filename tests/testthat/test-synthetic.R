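# Synthetic-data generators: coalescent trees, infinite-sites mutations,
# haplogroup sample tables, hotspot fields, query genotypes.

test_that("coalescent trees are valid rooted binary genealogies", {
  tr <- simulate_coalescent_tree(10, N0 = 1000, seed = 11)
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 10)
  expect_equal(tr$Nnode, 9) # exactly n - 1 internal nodes
  ages <- attr(tr, "node_ages")
  expect_true(all(abs(ages[1:10]) < 1e-9)) # tips at age 0
  expect_true(all(ages[11:19] > 0))
  # child age <= parent age on every edge
  expect_true(all(ages[tr$edge[, 1]] >= ages[tr$edge[, 2]] - 1e-9))
  expect_error(simulate_coalescent_tree(1, 100), "n_samples")
  expect_error(simulate_coalescent_tree(5, -3), "N0")
})

test_that("identical seeds give byte-identical Newick output", {
  a <- simulate_coalescent_tree(15, 500, growth_rate = 0.05,
                                growth_onset = 100, seed = 7)
  b <- simulate_coalescent_tree(15, 500, growth_rate = 0.05,
                                growth_onset = 100, seed = 7)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
  c <- simulate_coalescent_tree(15, 500, seed = 8)
  expect_false(identical(ape::write.tree(a), ape::write.tree(c)))
})

test_that("pairwise coalescence time matches the analytic expectation", {
  # E[T2] = 2 N0 generations for the standard coalescent
  N0 <- 400
  ages <- withr::with_seed(21, replicate(4000, {
    max(attr(simulate_coalescent_tree(2, N0, generation_time = 1),
             "node_ages"))
  }))
  expect_lt(abs(mean(ages) / (2 * N0) - 1), 0.05)
})

test_that("mutation dropper respects rate, site map and saturation", {
  tr <- simulate_coalescent_tree(6, 800, seed = 3)
  # zero rate: all sequences identical
  a0 <- drop_mutations(tr, mu = 0, n_sites = 50, seed = 1)
  expect_equal(segregating_sites(a0), 0)
  # site map covers exactly the segregating sites
  a1 <- drop_mutations(tr, mu = 5e-7, n_sites = 500, seed = 2)
  seg <- which(apply(a1$mat, 2, function(col) length(unique(col)) > 1))
  expect_setequal(attr(a1, "site_map")$site, seg)
  # saturation is an error, not silent reuse
  expect_error(drop_mutations(tr, mu = 1, n_sites = 3, seed = 4),
               "saturated")
})

test_that("expected segregating sites on a two-tip tree match Poisson mean", {
  # two branches of length L years each: E[S] = 2 L mu n_sites
  L <- 1000; mu <- 1e-5; ns <- 300
  tr <- toy_dated_tree("(A:1000,B:1000);")
  S <- withr::with_seed(5, replicate(2000, {
    segregating_sites(drop_mutations(tr, mu = mu, n_sites = ns))
  }))
  expected <- 2 * L * mu * ns
  expect_lt(abs(mean(S) / expected - 1), 0.05)
})

test_that("haplogroup dataset converges to the base vector at high concentration", {
  pops <- data.frame(name = "P1", region = "r", latitude = 30,
                     longitude = 100, n = 1e5)
  f0 <- c(0.4, 0.3, 0.2, 0.1)
  smp <- simulate_haplogroup_dataset(pops, c("A1", "B1", "C1", "D1"),
                                     base_concentration = 1e7 * f0,
                                     seed = 13)
  emp <- table(factor(smp$haplogroup, c("A1", "B1", "C1", "D1"))) / nrow(smp)
  expect_true(all(abs(as.numeric(emp) - f0) < 0.01))
})

test_that("planted negative cline is recovered with the right sign", {
  pops <- data.frame(name = paste0("P", 1:20), region = "r",
                     latitude = seq(18, 45, length.out = 20),
                     longitude = 105, n = 200)
  hit <- vapply(1:3, function(s) {
    smp <- simulate_haplogroup_dataset(
      pops, c("O1", "O2", "C2", "N1"),
      planted_lineages = data.frame(haplogroup = "O1", slope = -0.02,
                                    baseline = 0.3),
      seed = s)
    ft <- frequency_table(smp, level = 2)
    ct <- cor.test(ft$freq[, "O1"], pops$latitude)
    ct$estimate < 0 && ct$p.value < 0.05
  }, logical(1))
  expect_true(all(hit))
})

test_that("invalid haplogroup-dataset configs are rejected", {
  expect_error(simulate_haplogroup_dataset(
    data.frame(name = character(0), region = character(0),
               latitude = numeric(0), longitude = numeric(0),
               n = integer(0)), "A"), "empty")
  expect_error(simulate_haplogroup_dataset(
    data.frame(name = "P", region = "r", latitude = 0, longitude = 0,
               n = 0), "A"), "sizes")
})

test_that("hotspot field follows the Gaussian kernel ground truth", {
  grid <- expand.grid(latitude = seq(20, 38, 2), longitude = seq(100, 118, 2))
  f <- simulate_hotspot_field(grid, center = c(30, 110), radius_km = 200,
                              peak_freq = 0.6, background_freq = 0.05,
                              n_per_point = 500, seed = 3)
  # maximum expected frequency at the grid point nearest the centre
  d <- geosphere::distHaversine(cbind(grid$longitude, grid$latitude),
                                c(110, 30), r = 6371)
  expect_equal(which.max(f$true_p), which.min(d))
  # degenerate case: peak = background is spatially exchangeable
  g <- simulate_hotspot_field(grid, c(30, 110), 200, 0.1, 0.1, 100, seed = 4)
  expect_true(all(abs(g$true_p - 0.1) < 1e-12))
  expect_error(simulate_hotspot_field(grid, c(30, 110), 200, 0.05, 0.2,
                                      100), "peak_freq")
})

test_that("query genotypes reflect the root path, missingness and errors", {
  tr <- simulate_coalescent_tree(12, 500, seed = 9)
  bs <- annotate_branch_snps(tr, 4)
  g0 <- simulate_query_genotypes(tr, bs, "s5", missing_rate = 0,
                                 error_rate = 0, seed = 1)
  path <- ypopgen:::root_path_labels(tr, "s5")
  expect_equal(nrow(g0), nrow(bs)) # nothing missing
  expect_true(all((g0$branch_id %in% path) ==
                    (g0$allele_state == "derived")))
  g1 <- simulate_query_genotypes(tr, bs, "s5", missing_rate = 1, seed = 2)
  expect_equal(nrow(g1), 0)
  expect_error(simulate_query_genotypes(tr, bs[0, ], "s5"), "annotation")
})

test_that("growth shifts Tajima's D negative relative to the constant-size null", {
  stats_at <- function(g, seed) {
    withr::with_seed(seed, mean(replicate(120, {
      tr <- simulate_coalescent_tree(20, 1000, growth_rate = g,
                                     growth_onset = 50,
                                     generation_time = 1)
      a <- drop_mutations(tr, mu = 2.5e-6, n_sites = 1000,
                          segregating_only = TRUE)
      d <- tajimas_d(a)$d
      if (is.na(d)) 0 else d
    })))
  }
  d_null <- stats_at(0, 31)
  d_grow <- stats_at(0.1, 32)
  expect_gt(d_null, -0.3)
  expect_lt(d_grow, -0.5)
  expect_lt(d_grow, d_null)
})
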