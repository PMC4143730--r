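test_that("feature matrix collapses singletons into one SUPER column", {
  # 8 variants, 3 singletons: 5 dosage features + SUPER
  d <- matrix(0L, 6, 8)
  d[1, 1] <- 1L; d[2, 2] <- 1L; d[3, 3] <- 1L          # singletons
  d[1:2, 4] <- 1L; d[3:4, 5] <- 1L; d[5:6, 6] <- 1L
  d[c(1, 4), 7] <- 1L; d[c(2, 5), 8] <- 1L
  geno <- toy_geno(d)
  gs <- toy_geneset(geno)
  fm <- build_feature_matrix(gs, geno, collapse_singletons = TRUE)
  expect_equal(ncol(fm$F), 6)
  expect_true("SUPER" %in% fm$labels)
  expect_equal(unname(fm$F[, "SUPER"]), c(1, 1, 1, 0, 0, 0))

  # no singletons: flag on and off agree
  d2 <- d[, 4:8]
  geno2 <- toy_geno(d2)
  gs2 <- toy_geneset(geno2)
  f_on <- build_feature_matrix(gs2, geno2, collapse_singletons = TRUE)
  f_off <- build_feature_matrix(gs2, geno2, collapse_singletons = FALSE)
  expect_equal(unname(f_on$F), unname(f_off$F))

  # all variants singleton: a single SUPER feature
  d3 <- rbind(diag(1L, 4), 0L, 0L)
  geno3 <- toy_geno(d3)
  f3 <- build_feature_matrix(toy_geneset(geno3), geno3)
  expect_equal(f3$labels, "SUPER")
  expect_equal(unname(f3$F[, 1]), c(1, 1, 1, 1, 0, 0))

  # constant features are dropped with a message
  d4 <- cbind(c(1L, 1L, 0L, 0L), c(0L, 0L, 0L, 0L))
  geno4 <- toy_geno(d4)
  expect_message(f4 <- build_feature_matrix(toy_geneset(geno4), geno4,
                                            collapse_singletons = FALSE),
                 "constant")
  expect_equal(ncol(f4$F), 1)
})

test_that("C-alpha matches a term-by-term computation", {
  # balanced singleton contributes zero
  expect_equal(calpha_statistic(1, 1, 0.5), 0)

  # five-feature toy, term-by-term oracle
  n <- c(1, 1, 2, 3, 4); yv <- c(1, 0, 2, 1, 3); p0 <- 64 / 103
  oracle <- sum(vapply(1:5, function(i)
    (yv[i] - n[i] * p0)^2 - n[i] * p0 * (1 - p0), 0))
  expect_equal(calpha_statistic(yv, n, p0), oracle)

  # exact binomial expectation attains the statistic's minimum
  expect_equal(calpha_statistic(c(1, 2) * 0.5, c(1, 2), 0.5),
               -sum(c(1, 2) * 0.25))

  expect_error(calpha_statistic(2, 1, 0.5), "y_case")
})

test_that("C-alpha on features equals the statistic on case copy counts", {
  d <- cbind(c(1L, 0L, 0L, 0L, 0L, 0L), c(1L, 1L, 0L, 2L, 0L, 0L))
  y <- c(1, 1, 1, 0, 0, 0)
  geno <- toy_geno(d)
  fm <- build_feature_matrix(toy_geneset(geno), geno,
                             collapse_singletons = FALSE)
  expect_equal(calpha_from_features(fm, y),
               calpha_statistic(c(1, 2), c(1, 4), 0.5))
})

test_that("SSU equals the squared norm of the score vector", {
  F <- cbind(c(1, 0, 2, 0), c(0, 1, 1, 0))
  y <- c(1, 1, 0, 0)
  U <- t(F) %*% (y - mean(y))            # hand linear algebra
  expect_equal(ssu_statistic(F, y), sum(U^2))

  # features orthogonal to the centered phenotype give zero
  Fo <- cbind(c(1, 1, 1, 1), c(2, 2, 2, 2))
  expect_equal(ssu_statistic(Fo, y), 0)

  expect_error(ssu_statistic(F, c(1, 1, 1, 1)), "constant")
})

test_that("Hotelling T2 matches direct matrix algebra and survives rank loss", {
  G <- cbind(c(1L, 1L, 0L, 1L, 0L, 0L), c(0L, 1L, 1L, 0L, 0L, 1L))
  y <- c(1, 1, 1, 0, 0, 0)
  n1 <- 3; n2 <- 3
  m1 <- colMeans(G[y == 1, ]); m2 <- colMeans(G[y == 0, ])
  S <- (cov(G[y == 1, ]) * (n1 - 1) + cov(G[y == 0, ]) * (n2 - 1)) /
    (n1 + n2 - 2)
  oracle <- n1 * n2 / (n1 + n2) *
    drop(t(m1 - m2) %*% solve(S) %*% (m1 - m2))
  expect_equal(cmc_hotelling(G, y), oracle)

  # identical group means give zero
  Gz <- cbind(c(1L, 0L, 1L, 0L), c(0L, 1L, 0L, 1L))
  expect_equal(cmc_hotelling(Gz, c(1, 1, 0, 0)), 0)

  # duplicated bin: pseudo-inverse equals the deduplicated statistic
  Gd <- cbind(G, G[, 2])
  expect_equal(cmc_hotelling(Gd, y), cmc_hotelling(G, y))
})

test_that("CMC bins group features by minor-allele count", {
  d <- matrix(0L, 6, 4)
  d[1, 1] <- 1L                          # singleton
  d[1:2, 2] <- 1L; d[3:4, 3] <- 1L       # count-2 bin
  d[1:5, 4] <- 1L                        # count 5
  geno <- toy_geno(d)
  fm <- build_feature_matrix(toy_geneset(geno), geno,
                             collapse_singletons = FALSE)
  G <- cmc_indicators(fm, breaks = c(1, 2, Inf))
  expect_equal(ncol(G), 2)
  expect_equal(unname(G[, 1]), c(1L, 0L, 0L, 0L, 0L, 0L))
  expect_equal(unname(G[, 2]), c(1L, 1L, 1L, 1L, 1L, 0L))

  # the collapsed SUPER column lives in the singleton bin
  fmc <- build_feature_matrix(toy_geneset(geno), geno)
  Gc <- cmc_indicators(fmc)
  expect_equal(unname(Gc[, 1]), unname(fmc$F[, "SUPER"]))
})

test_that("permutation p-values follow the b/B convention with < 1/B display", {
  F <- cbind(c(1, 0, 1, 0, 0, 0))
  y <- c(1, 1, 1, 0, 0, 0)
  # constant statistic: every permutation ties, p = 1
  tr <- permutation_pvalue(function(f, yy) 1, F, y, B = 50, seed = 1)
  expect_equal(tr$b, 50L)
  expect_equal(tr$p, 1)

  # b = 0 is displayed as a bound (statistic exceeded on the observed
  # labels only, via a call counter so chance label recurrence cannot tie)
  calls <- 0L
  first_call_wins <- function(f, yy) {
    calls <<- calls + 1L
    if (calls == 1L) 1 else 0
  }
  tr0 <- permutation_pvalue(first_call_wins, F, y, B = 10000, seed = 1)
  expect_equal(tr0$b, 0L)
  expect_equal(tr0$p_display, "<1.0e-04")
  expect_equal(format_p(0, 1e6), "<1.0e-06")

  # conservative option
  trc <- permutation_pvalue(function(f, yy) 1, F, y, B = 9, seed = 1,
                            convention = "plus_one")
  expect_equal(trc$p, 1)
})

test_that("Monte-Carlo permutation p agrees with exhaustive enumeration", {
  set.seed(5)
  F <- cbind(c(1, 0, 1, 0, 0, 1, 0), c(0, 1, 1, 0, 1, 0, 0))
  y <- c(1, 1, 1, 0, 0, 0, 0)
  B <- 10000
  for (fn in list(ssu_statistic, calpha_from_features)) {
    exact <- enum_perm_p(fn, F, y)
    mc <- permutation_pvalue(fn, F, y, B = B, seed = 3)$p
    expect_lt(abs(mc - exact), 3 * sqrt(exact * (1 - exact) / B))
  }
  G <- (F >= 1) * 1L
  exact <- enum_perm_p(cmc_hotelling, G, y)
  mc <- permutation_pvalue(cmc_hotelling, G, y, B = B, seed = 3)$p
  expect_lt(abs(mc - exact), 3 * sqrt(exact * (1 - exact) / B))
})

test_that("statistics are invariant under joint relabeling of samples", {
  set.seed(8)
  d <- matrix(rbinom(10 * 6, 1, 0.2), 10, 6)
  y <- c(rep(1, 4), rep(0, 6))
  perm <- sample(10)
  expect_equal(ssu_statistic(d, y), ssu_statistic(d[perm, ], y[perm]))
  expect_equal(calpha_from_features(d, y),
               calpha_from_features(d[perm, ], y[perm]))
  G <- (d >= 1) * 1L
  expect_equal(cmc_hotelling(G, y), cmc_hotelling(G[perm, ], y[perm]))
})

test_that("C-alpha and SSU give identical permutation p on shared streams", {
  # on binary features the two statistics differ by a label-invariant
  # constant, so their exceedance counts coincide permutation by permutation
  X <- cbind(c(1, 1, 0, 1, 0, 0, 0, 0))
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  a <- permutation_pvalue(ssu_statistic, X, y, B = 500, seed = 11)
  b <- permutation_pvalue(calpha_from_features, X, y, B = 500, seed = 11)
  expect_equal(a$b, b$b)
})

test_that("the vectorized scan engine matches the generic permutation path", {
  cfg <- sim_config(small_gene("G", signal = TRUE), seed = 31)
  coh <- simulate_cohort(cfg)
  gs <- assign_to_genes(coh$geno, coh$models)$G
  fm <- build_feature_matrix(gs, coh$geno)
  G <- cmc_indicators(fm)
  y <- coh$phenotype$y
  B <- 400
  sc <- supervar:::perm_scan_gene(fm, G, y, B, seed = 77,
                                  methods = c("ssu", "calpha", "cmc"))
  gen_ssu <- permutation_pvalue(ssu_statistic, fm$F, y, B, seed = 77)
  gen_cmc <- permutation_pvalue(cmc_hotelling, G, y, B, seed = 77)
  expect_equal(sc$b[["ssu"]], gen_ssu$b)
  expect_equal(sc$b[["cmc"]], gen_cmc$b)
  expect_equal(sc$b[["ssu"]], sc$b[["calpha"]])
})

test_that("two-step scan promotes candidates and degenerates cleanly", {
  cfg <- sim_config(list(small_gene("SIG", signal = TRUE),
                         small_gene("N1"), small_gene("N2")), seed = 17)
  coh <- simulate_cohort(cfg)
  gs <- assign_to_genes(coh$geno, coh$models)

  # B1 = B2 collapses to single-stage testing
  res <- two_step_scan(gs, coh$geno, coh$phenotype,
                       plan = permutation_plan(B1 = 300, B2 = 300, seed = 3))
  expect_true(all(res$stage == 1))
  expect_true(all(res$final))

  # two-stage: the signal gene is promoted and re-tested at B2
  res2 <- two_step_scan(gs, coh$geno, coh$phenotype,
                        plan = permutation_plan(B1 = 500, B2 = 2000,
                                                alpha_promote = 0.01,
                                                seed = 3))
  expect_true(all(res2$stage[res2$gene == "SIG" & res2$final] == 2))
  expect_true(all(res2$B[res2$final & res2$gene == "SIG"] == 2000))
  # columns carry the reporting contract
  expect_true(all(c("gene", "method", "stage", "statistic", "b", "B", "p",
                    "p_display", "significant") %in% names(res2)))
})

test_that("stage-1 promotions on null genes match the binomial expectation", {
  specs <- lapply(1:150, function(i) small_gene(paste0("G", i), 20, 8))
  cfg <- sim_config(specs, carrier_or = 1, seed = 23)
  coh <- simulate_cohort(cfg)
  gs <- assign_to_genes(coh$geno, coh$models)
  res <- two_step_scan(gs, coh$geno, coh$phenotype,
                       plan = permutation_plan(B1 = 1000, B2 = 2000,
                                               alpha_promote = 0.001,
                                               seed = 9))
  n_promoted <- length(unique(res$gene[res$promoted]))
  # union over three correlated methods of P(promote) = 0.001 each:
  # expectation is below 150 * 3 * 0.001; allow the exact upper binomial tail
  expect_lte(n_promoted, qbinom(0.999, 150 * 3, 0.001) + 1)
})

test_that("a strong signal gene is promoted in most replicate cohorts", {
  hits <- 0
  for (r in 1:10) {
    cfg <- sim_config(list(gene_spec("SIG", 150, 135, is_signal = TRUE),
                           small_gene("N1")), seed = 400 + r)
    coh <- simulate_cohort(cfg)
    gs <- assign_to_genes(coh$geno, coh$models)
    res <- two_step_scan(gs, coh$geno, coh$phenotype,
                         plan = permutation_plan(B1 = 1000, B2 = 1000,
                                                 seed = r),
                         methods = "ssu")
    if (res$p[res$gene == "SIG"] < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("Bonferroni threshold divides alpha by the gene count", {
  expect_equal(bonferroni_threshold(0.05, 10000), 5.0e-6)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 10148), 0.05 / 10148)
  expect_equal(signif(bonferroni_threshold(0.05, 10148), 4), 4.927e-6)
})

test_that("supervariant tables tally carriers by case status", {
  X <- c(1, 0, 1, 1, 0, 0)
  phen <- data.frame(sample_id = letters[1:6], y = c(1, 1, 1, 0, 0, 0))
  tb <- supervariant_table(X, phen)
  expect_equal(unname(unclass(tb)[1:4]), c(2, 1, 1, 2))

  # perfect separation: X = y
  tb2 <- supervariant_table(c(1, 1, 1, 0, 0, 0), phen)
  expect_equal(tb2[["b"]], 0)
  expect_equal(tb2[["c"]], 0)

  # all-zero supervariant
  tb3 <- supervariant_table(rep(0, 6), phen)
  expect_equal(tb3[["a"]], 0)
  expect_equal(tb3[["c"]], 0)
})

test_that("per-variant tests agree with the supervariant on identical input", {
  d <- cbind(c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L))
  geno <- toy_geno(d)
  phen <- data.frame(sample_id = geno$sample_ids,
                     y = c(1, 1, 1, 1, 0, 0, 0, 0))
  gs <- toy_geneset(geno)
  pv <- per_variant_fisher(gs, geno, phen)
  ft <- fisher_exact_2x2(supervariant_table(d[, 1], phen))
  expect_equal(pv$min_p, ft$p)

  empty <- toy_geneset(geno, idx = integer())
  pv0 <- per_variant_fisher(empty, geno, phen)
  expect_equal(nrow(pv0$results), 0)
  expect_true(is.na(pv0$min_p))
})
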