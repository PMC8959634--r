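test_that("SNP filters apply the MAF, HWE and call-rate rules", {
  set.seed(1)
  n <- 1000
  dos <- cbind(
    common  = rbinom(n, 2, 0.3),
    rare    = rbinom(n, 2, 0.005),           # MAF ~0.005 < 0.01
    mono    = rep(0L, n),                    # monomorphic
    hwe_bad = rep(c(0L, 2L), n / 2)          # no hets: extreme HWE failure
  )
  g <- genotype_matrix(dos)
  qc <- filter_snps(g)
  expect_identical(colnames(qc$genotypes$dosages), "common")
  expect_gte(qc$report[["maf"]], 2)          # rare + monomorphic
  expect_gte(qc$report[["hwe"]], 1)

  # HWE oracle: counts AA=50, Aa=0, aa=50 -> 1-df chi2 = n, p << 1e-4
  counts <- c(50, 0, 50); N <- 100
  p <- (2 * counts[3] + counts[2]) / (2 * N)
  expected <- N * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi2 <- sum((counts - expected)^2 / expected)
  p_oracle <- pchisq(chi2, 1, lower.tail = FALSE)
  expect_lt(p_oracle, 1e-4)
  dosage_vec <- rep(c(0, 2), times = counts[c(1, 3)])
  expect_equal(rnmkit:::hwe_pvalue(dosage_vec), p_oracle)

  # duplicated SNP ids removed
  g2 <- genotype_matrix(dos[, c(1, 1)], snp_ids = c("a", "a"))
  expect_equal(filter_snps(g2)$report[["duplicate"]], 1)

  # low call rate excluded
  dos3 <- cbind(ok = rbinom(200, 2, 0.4), sparse = rbinom(200, 2, 0.4))
  dos3[1:20, 2] <- NA  # call rate 0.9 < 0.95
  qc3 <- filter_snps(genotype_matrix(dos3))
  expect_equal(qc3$report[["call_rate"]], 1)

  expect_error(filter_snps(genotype_matrix(matrix(0, 10, 2))), "no SNPs")
})

test_that("GRM matches the standardized-dosage definition", {
  # printed toy: one SNP, dosages (0, 2), phat = 0.5
  K <- compute_grm(genotype_matrix(matrix(c(0, 2), 2, 1)))$K
  expect_equal(unname(K), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)

  # identical genotype rows give identical relationships
  dos <- rbind(a = c(0, 1, 2, 1), b = c(0, 1, 2, 1), c = c(2, 0, 1, 1))
  K2 <- compute_grm(genotype_matrix(dos))$K
  expect_equal(K2[1, 2], K2[1, 1])
  expect_equal(K2[1, 1], K2[2, 2])

  # mean diagonal ~ 1 at scale
  g <- simulate_genotypes(500, 5000, maf_range = c(0.05, 0.5), seed = 3)
  expect_lt(abs(mean(diag(compute_grm(g)$K)) - 1), 0.05)

  expect_error(compute_grm(genotype_matrix(matrix(c(0, 0, 1, 1), 2))),
               "monomorphic")
})

test_that("GRM respects permutation conjugation and SNP-block averaging", {
  g <- simulate_genotypes(40, 120, maf_range = c(0.25, 0.5), seed = 13)
  K <- compute_grm(g)$K
  perm <- sample(40)
  gp <- genotype_matrix(g$dosages[perm, ], sample_ids = g$sample_ids[perm])
  expect_equal(unname(compute_grm(gp)$K), unname(K[perm, perm]),
               tolerance = 1e-12)

  # disjoint SNP halves average (weighted by SNP count) to the full GRM
  h1 <- genotype_matrix(g$dosages[, 1:50])
  h2 <- genotype_matrix(g$dosages[, 51:120])
  Kavg <- (50 * compute_grm(h1)$K + 70 * compute_grm(h2)$K) / 120
  expect_equal(unname(Kavg), unname(K), tolerance = 1e-12)
})

test_that("relatedness pruning removes one member per flagged pair", {
  ids <- paste0("s", 1:5)
  K <- diag(5); dimnames(K) <- list(ids, ids)
  expect_identical(prune_related(grm(K)), ids)  # nothing to prune

  K2 <- K; K2[1, 2] <- K2[2, 1] <- 0.06
  kept <- prune_related(grm(K2), seed = 1)
  expect_length(kept, 4)
  expect_length(setdiff(c("s1", "s2"), kept), 1)
  expect_identical(prune_related(grm(K2), seed = 1),
                   prune_related(grm(K2), seed = 1))

  # 3-clique: greedy removal matches the brute-force minimal vertex cover
  K3 <- diag(5)
  K3[1:3, 1:3] <- 0.2; diag(K3) <- 1
  dimnames(K3) <- list(ids, ids)
  kept3 <- prune_related(grm(K3), seed = 2)
  # brute force: smallest removal set leaving no pair > 0.05
  best <- 5
  for (r in 0:3) {
    for (drop in if (r) combn(5, r, simplify = FALSE) else list(integer(0))) {
      sub <- K3[setdiff(1:5, drop), setdiff(1:5, drop), drop = FALSE]
      off <- sub[lower.tri(sub)]
      if (!length(off) || max(off) <= 0.05) { best <- min(best, r); break }
    }
  }
  expect_equal(best, 2)
  expect_length(kept3, 5 - best)
})

test_that("PC outlier screen keeps homogeneous samples, drops planted outlier", {
  removed_any <- vapply(1:100, function(s) {
    K <- toy_grm(60, seed = 600 + s, m = 120)
    length(pc_outlier_removal(K, n_sd = 6)) < 60
  }, TRUE)
  expect_gte(mean(!removed_any), 0.95)

  # planted sample with shifted allele frequencies at differentiated SNPs
  set.seed(99)
  n <- 80; m <- 200
  dos <- matrix(rbinom(n * m, 2, 0.2), n, m)
  dos[n, ] <- rbinom(m, 2, 0.8)
  K <- compute_grm(genotype_matrix(dos))
  kept <- pc_outlier_removal(K, n_sd = 6)
  expect_false(paste0("id", n) %in% kept)

  expect_length(pc_outlier_removal(K, n_sd = Inf), n)
  expect_error(pc_outlier_removal(grm(diag(2))), "at least 3")
})

test_that("sample splitting is balanced, disjoint and deterministic", {
  s <- split_samples(paste0("i", 1:10), 2, seed = 4)
  expect_equal(unname(table(s)), c(5L, 5L), ignore_attr = TRUE)

  s2 <- split_samples(paste0("i", 1:7), 3, seed = 4)
  expect_setequal(as.integer(table(s2)), c(3L, 2L))
  expect_length(s2, 7)

  expect_identical(split_samples(letters, 4, seed = 9),
                   split_samples(letters, 4, seed = 9))
  expect_error(split_samples(letters[1:3], 5), "more groups")
})
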