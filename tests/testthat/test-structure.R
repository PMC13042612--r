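# Frequency tables, PCA, HDH identification, regional frequency tests,
# AMOVA / pairwise Phi-st, and UPGMA.

test_that("frequency tables truncate haplogroups at the requested level", {
  smp <- data.frame(sample_id = paste0("s", 1:3), population = "P1",
                    region = "r", language = "l", latitude = 0,
                    longitude = 0,
                    haplogroup = c("O2a2b1a1a", "O2a1b", "O2a2"))
  ft <- frequency_table(smp, level = 4)
  expect_equal(unname(ft$counts[1, "O2a2"]), 2)
  expect_equal(unname(ft$counts[1, "O2a1"]), 1)
  expect_equal(sum(ft$freq), 1)
  # single population, single haplogroup
  one <- smp[1, ]
  expect_equal(unname(frequency_table(one, 4)$freq[1, 1]), 1)
  # invariant to sample order
  ft2 <- frequency_table(smp[c(3, 1, 2), ], level = 4)
  expect_equal(ft$counts, ft2$counts)
})

test_that("PCA handles degenerate and full-rank frequency matrices", {
  X <- matrix(0.25, nrow = 4, ncol = 4,
              dimnames = list(paste0("P", 1:4), paste0("h", 1:4)))
  p0 <- pca_haplogroups(X)
  expect_equal(p0$flag, "zero-variance")
  expect_true(all(p0$explained == 0))
  # collinear rows: PC1 explains 100%
  Y <- cbind(c(0.2, 0.4, 0.6), 1 - c(0.2, 0.4, 0.6))
  rownames(Y) <- paste0("P", 1:3); colnames(Y) <- c("a", "b")
  p1 <- pca_haplogroups(Y)
  expect_equal(p1$explained[1], 100, tolerance = 1e-9)
  # eigendecomposition oracle on random matrices, up to sign
  withr::with_seed(3, {
    for (r in 1:5) {
      Z <- matrix(runif(160), 20, 8)
      Z <- Z / rowSums(Z)
      rownames(Z) <- paste0("P", 1:20); colnames(Z) <- paste0("h", 1:8)
      pc <- pca_haplogroups(Z, n_components = 4)
      Zc <- scale(Z, center = TRUE, scale = FALSE)
      eg <- eigen(crossprod(Zc))
      ev <- 100 * eg$values / sum(eg$values)
      expect_equal(pc$explained, ev[1:4], tolerance = 1e-8)
      sc_oracle <- Zc %*% eg$vectors[, 1:4]
      for (j in 1:4)
        expect_equal(abs(unname(pc$scores[, j])),
                     abs(unname(sc_oracle[, j])), tolerance = 1e-8)
      expect_true(all(diff(pc$explained) <= 1e-12))
    }
  })
})

test_that("HDH rule confirms the worked 2x2 example and applies the threshold", {
  res <- identify_hdh(c(X = 30, rest = 70), c(X = 10, rest = 90))
  row <- res[res$haplogroup == "X", ]
  expect_equal(row$abs_diff, 0.2)
  # hand chi-square: n(ad-bc)^2/((a+b)(c+d)(a+c)(b+d)) = 12.5
  chi_stat <- 200 * (30 * 90 - 70 * 10)^2 / (100 * 100 * 40 * 160)
  expect_equal(chi_stat, 12.5)
  expect_equal(row$chi_p, stats::pchisq(12.5, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # Fisher oracle by hypergeometric enumeration
  pobs <- stats::dhyper(30, 100, 100, 40)
  fisher_oracle <- sum(stats::dhyper(0:40, 100, 100, 40)[
    stats::dhyper(0:40, 100, 100, 40) <= pobs + 1e-12])
  expect_equal(row$fisher_p, fisher_oracle, tolerance = 1e-9)
  expect_equal(row$verdict, "confirmed")
  # below-threshold difference is not even a candidate
  res2 <- identify_hdh(c(X = 7, rest = 93), c(X = 3, rest = 97))
  expect_equal(res2$verdict[res2$haplogroup == "X"], "rejected")
  # identical vectors: no candidates at all
  res3 <- identify_hdh(c(A = 5, B = 5), c(A = 5, B = 5))
  expect_true(all(res3$verdict == "rejected"))
})

test_that("regional frequency tests use exact Mann-Whitney and Welch", {
  fa <- matrix(c(0.5, 0.5, 0.5, 0.5), 4, 1, dimnames = list(NULL, "O2"))
  same <- group_frequency_tests(fa, fa)
  expect_equal(same$mw_p, 1)
  expect_true(is.na(same$mw_stars) || same$mw_stars == "")
  # disjoint support, n = 6 vs 6: exact enumeration oracle
  withr::with_seed(2, {
    xa <- sort(runif(6, 0.6, 0.9)); xb <- sort(runif(6, 0.1, 0.4))
  })
  fa2 <- matrix(xa, 6, 1, dimnames = list(NULL, "O2"))
  fb2 <- matrix(xb, 6, 1, dimnames = list(NULL, "O2"))
  out <- group_frequency_tests(fa2, fb2)
  expect_equal(out$mw_p, oracle_mw_exact(xa, xb), tolerance = 1e-12)
  expect_equal(out$mw_p, 2 / choose(12, 6), tolerance = 1e-12)
  # star mapping on synthetic p-values
  expect_equal(ypopgen:::p_stars(c(0.2, 0.03, 0.005, 5e-4)),
               c("", "*", "**", "***"))
  expect_error(group_frequency_tests(fa2[1, , drop = FALSE], fb2), "2 pop")
})

test_that("AMOVA components match the direct SSD oracle on random designs", {
  withr::with_seed(17, {
    for (r in 1:8) {
      G <- sample(2:4, 1); P <- sample((G + 1):8, 1)
      pops <- paste0("P", 1:P)
      grp_of <- setNames(paste0("G", c(seq_len(G),
                                       sample(G, P - G, TRUE))), pops)
      pop <- unlist(lapply(pops, function(p)
        rep(p, sample(3:10, 1))))
      grp <- unname(grp_of[pop])
      lab <- sample(letters[1:5], length(pop), TRUE)
      d2 <- dist_squared_labels(lab)
      fit <- amova(d2, pop, grp, B = 5, seed = r)
      expect_equal(fit$table$sigma2, oracle_amova(d2, pop, grp),
                   tolerance = 1e-8)
      expect_equal(sum(fit$table$percent), 100, tolerance = 1e-6)
    }
  })
})

test_that("AMOVA on identical populations puts ~100% within populations", {
  withr::with_seed(5, {
    lab <- c(sample(letters[1:4], 50, TRUE, prob = c(.4, .3, .2, .1)),
             sample(letters[1:4], 50, TRUE, prob = c(.4, .3, .2, .1)))
  })
  pop <- rep(c("A", "B"), each = 50)
  fit <- amova(dist_squared_labels(lab), pop, B = 99, seed = 1)
  expect_lt(abs(fit$table$percent[2] - 100), 7)
  expect_equal(sum(fit$table$percent), 100, tolerance = 1e-6)
  # negative among-group components on exchangeable data are retained and
  # non-significant; try a few seeds to find one with a negative estimate
  pop4 <- rep(paste0("P", 1:4), each = 25)
  grp4 <- rep(c("g1", "g2"), each = 50)
  fits <- lapply(1:6, function(s) {
    l <- withr::with_seed(100 + s, sample(letters[1:4], 100, TRUE))
    amova(dist_squared_labels(l), pop4, grp4, B = 99, seed = s)
  })
  for (f in fits) expect_equal(sum(f$table$percent), 100, tolerance = 1e-6)
  negs <- vapply(fits, function(f) f$table$sigma2[1] < 0, logical(1))
  expect_true(any(negs)) # negative estimates occur and are not clipped
  f_neg <- fits[[which(negs)[1]]]
  expect_lt(f_neg$table$percent[1], 0)
  expect_gt(f_neg$table$p[1], 0.05)
})

test_that("pairwise Phi-st equals the two-population AMOVA restriction", {
  withr::with_seed(23, {
    for (r in 1:10) {
      n1 <- sample(5:15, 1); n2 <- sample(5:15, 1)
      lab <- c(sample(letters[1:3], n1, TRUE),
               sample(letters[2:5], n2, TRUE))
      pop <- rep(c("A", "B"), c(n1, n2))
      d2 <- dist_squared_labels(lab)
      ph <- pairwise_phist(d2, pop, B = 5, seed = r)
      fit <- amova(d2, pop, B = 5, seed = r)
      expect_identical(ph$phist["A", "B"], unname(fit$phi["phi_st"]))
    }
  })
})

test_that("Phi-st hits its boundary cases", {
  # identical composition: near zero
  withr::with_seed(9, {
    lab <- sample(letters[1:4], 200, TRUE)
  })
  pop <- rep(c("A", "B"), each = 100)
  ph <- pairwise_phist(dist_squared_labels(lab), pop, B = 99, seed = 3)
  expect_lt(abs(ph$phist["A", "B"]), 0.02)
  # fixed for different haplotypes: exactly 1
  lab2 <- rep(c("x", "y"), each = 20)
  ph2 <- pairwise_phist(dist_squared_labels(lab2),
                        rep(c("A", "B"), each = 20), B = 99, seed = 4)
  expect_equal(unname(ph2$phist["A", "B"]), 1)
  # undefined pair when a population has n < 2
  lab3 <- c("x", "x", "y")
  ph3 <- pairwise_phist(dist_squared_labels(lab3), c("A", "A", "B"),
                        B = 9, seed = 5)
  expect_true(is.na(ph3$phist["A", "B"]))
  # column-order invariance of the underlying label distance
  expect_equal(dist_squared_labels(c("b", "a", "c")),
               dist_squared_labels(c("b", "a", "c"))[, ])
})

test_that("UPGMA reproduces the textbook example and cophenetic averages", {
  D <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_tree(D)
  ages <- node_ages(tr)
  expect_equal(unname(ages[ape::getMRCA(tr, c("A", "B"))]), 1)
  expect_equal(unname(ages[ape::Ntip(tr) + 1]), 3)
  expect_error(upgma_tree(matrix(c(0, NA, NA, 0), 2, 2,
                                 dimnames = list(c("A", "B"),
                                                 c("A", "B")))), "NA")
  # lexicographic tie-break: with all distances equal the first merge is A-B
  E <- matrix(2, 3, 3, dimnames = list(c("C", "A", "B"), c("C", "A", "B")))
  diag(E) <- 0
  nw <- ape::write.tree(upgma_tree(E))
  expect_match(nw, "\\(A:1,B:1\\)")
  # cophenetic oracle (average-linkage heights via hclust) on random data
  withr::with_seed(31, {
    for (r in 1:10) {
      n <- sample(4:8, 1)
      M <- matrix(runif(n * n, 1, 10), n, n)
      M <- M + t(M); diag(M) <- 0
      dimnames(M) <- list(paste0("t", 1:n), paste0("t", 1:n))
      tr <- upgma_tree(M)
      hc <- stats::hclust(stats::as.dist(M), method = "average")
      co_h <- as.matrix(stats::cophenetic(hc))
      co_t <- as.matrix(ape::cophenetic.phylo(tr))
      expect_equal(co_t[rownames(co_h), colnames(co_h)], co_h,
                   tolerance = 1e-9)
      # ultrametric: equal root-to-tip distances
      depths <- ape::node.depth.edgelength(tr)[seq_len(n)]
      expect_lt(diff(range(depths)), 1e-9)
    }
  })
})
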