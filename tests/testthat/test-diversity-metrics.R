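test_that("nuc_div matches its definition on simple samples", {
  expect_equal(nuc_div(c(0, 0, 1, 1)), 2 / 3)      # 2p(1-p) * n/(n-1)
  expect_equal(nuc_div(rep(1, 10)), 0)
  expect_true(is.na(nuc_div(1)))
  # three states at frequencies 0.5/0.3/0.2 on an explicit 10-sequence sample
  x <- rep(c("a", "b", "c"), c(5, 3, 2))
  expect_equal(nuc_div(x), (1 - (0.25 + 0.09 + 0.04)) * 10 / 9)
  expect_equal(nuc_div(x), oracle_pi(x))
})

test_that("nuc_div equals the exhaustive pairwise oracle on random samples", {
  withr::local_seed(101)
  for (k in 1:1000) {
    n <- sample(2:10, 1)
    x <- sample(seq_len(sample(2:4, 1)), n, replace = TRUE)
    expect_equal(nuc_div(x), oracle_pi(x), tolerance = 1e-12)
    expect_equal(nuc_div(x), nuc_div(sample(x)), tolerance = 1e-14)  # permutation-invariant
  }
})

test_that("dxy matches formula and enumeration", {
  expect_equal(dxy(rep(1, 5), rep(0, 5)), 1)                 # fixed difference
  p <- 0.3
  x <- rep(c(1, 0), c(3, 7)); y <- rep(c(1, 0), c(3, 7))
  expect_equal(dxy(x, y), 2 * p * (1 - p))                   # equal freqs
  x <- rep(c(1, 0), c(9, 1)); y <- rep(c(1, 0), c(1, 9))
  expect_equal(dxy(x, y), 0.82)
  expect_equal(dxy(x, y), oracle_dxy(x, y))
  withr::local_seed(202)
  for (k in 1:200) {
    x <- sample(1:3, sample(2:8, 1), replace = TRUE)
    y <- sample(1:3, sample(2:8, 1), replace = TRUE)
    expect_equal(dxy(x, y), oracle_dxy(x, y), tolerance = 1e-12)
  }
})

test_that("fst_wc reproduces the component-wise Weir-Cockerham oracle", {
  # two demes, 100 haplotypes each, p = 0.8 vs 0.2
  cts <- rbind(c(80, 20), c(20, 80))
  expect_equal(fst_wc(cts), oracle_fst_wc(cts), tolerance = 1e-12)
  expect_equal(fst_wc(cts), 0.5246588, tolerance = 1e-6)
  # fixation
  expect_equal(fst_wc(rbind(c(1000, 0), c(0, 1000))), 1, tolerance = 1e-6)
  # identical counts: near zero, slightly negative allowed
  same <- rbind(c(50, 50), c(50, 50))
  expect_lte(fst_wc(same), 0)
  # monomorphic pooled sample is undefined
  expect_true(is.na(fst_wc(rbind(c(10, 0), c(10, 0)))))
  expect_error(fst_wc(matrix(c(5, 5), 1)), "two populations")
})

test_that("fst_wc equals the oracle on 1000 random count tables", {
  withr::local_seed(303)
  for (k in 1:1000) {
    r <- sample(2:5, 1)
    al <- sample(2:4, 1)
    cts <- matrix(rpois(r * al, lambda = sample(3:30, 1)) + 1L, r, al)
    expect_equal(fst_wc(cts), oracle_fst_wc(cts), tolerance = 1e-12)
  }
})

test_that("multi-locus fst pools variance components as a ratio of sums", {
  withr::local_seed(304)
  tables <- replicate(20, matrix(rpois(4, 20) + 1L, 2, 2), simplify = FALSE)
  num <- 0; den <- 0
  for (ct in tables) {
    # recompute from the oracle's own components
    r <- 2; ni <- rowSums(ct); ntot <- sum(ni)
    nc <- (ntot - sum(ni^2) / ntot) / (r - 1)
    for (al in 1:2) {
      p <- ct[, al] / ni; pbar <- sum(ct[, al]) / ntot
      msp <- sum(ni * (p - pbar)^2) / (r - 1)
      msg <- sum(ni * p * (1 - p)) / (ntot - r)
      num <- num + (msp - msg) / nc
      den <- den + (msp - msg) / nc + msg
    }
  }
  expect_equal(fst_wc_global(tables), num / den, tolerance = 1e-12)
})

test_that("ld_r2 matches the D^2 identity and handles degenerate loci", {
  # four-gamete table (40, 10, 10, 40)
  x <- rep(c(0, 0, 1, 1), c(40, 10, 10, 40))
  y <- rep(c(0, 1, 0, 1), c(40, 10, 10, 40))
  expect_equal(ld_r2(x, y), 0.36)
  expect_equal(ld_r2(x, y), oracle_r2(x, y), tolerance = 1e-12)
  expect_equal(ld_r2(x, x), 1)                     # perfect coupling
  expect_true(is.na(ld_r2(rep(0, 10), rep(c(0, 1), 5))))
  withr::local_seed(404)
  for (k in 1:200) {
    x <- rbinom(50, 1, 0.5); y <- rbinom(50, 1, 0.5)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(ld_r2(x, y), oracle_r2(x, y), tolerance = 1e-12)
    expect_gte(ld_r2(x, y), 0)
    expect_lte(ld_r2(x, y), 1)
  }
})

test_that("pooled diversity decomposes into within and between components", {
  # for two demes of equal size n: pi_total(pooled, no correction)
  #   = 0.5 * mean(pi_w uncorrected) + 0.5 * dxy
  withr::local_seed(505)
  for (k in 1:100) {
    n <- 30
    x <- rbinom(n, 1, runif(1, 0.05, 0.95))
    y <- rbinom(n, 1, runif(1, 0.05, 0.95))
    pooled <- c(x, y)
    pi_tot_raw <- nuc_div(pooled) * (2 * n - 1) / (2 * n)   # remove correction
    pi_w_raw <- (nuc_div(x) * (n - 1) / n + nuc_div(y) * (n - 1) / n) / 2
    expect_equal(pi_tot_raw, 0.5 * pi_w_raw * 2 / 2 + 0.5 * dxy(x, y),
                 tolerance = 1e-12)
    expect_gte(pi_tot_raw + 1e-12, pi_w_raw)        # pooled >= mean within
  }
})

test_that("locus_metrics agrees with the scalar estimators on a small state", {
  map <- build_flanking_map(n_flank_per_side = 3, min_cM = 0.1, max_cM = 10)
  params <- sim_params(N = 10, d = 2, m = 0.1, V_S = 5, seed = 11,
                       continuum_init = "monomorphic",
                       generations = 10, sample_every = 5)
  state <- initialize_metapop(params, map)
  mt <- locus_metrics(state, map, generation = 0L)

  l <- 2L  # an arbitrary neutral locus
  got_pi <- mt$value[mt$metric == "pi_w" & mt$patch == "1" & mt$locus_id == l]
  expect_equal(got_pi, nuc_div(state[[1]][, l]))
  got_dxy <- mt$value[mt$metric == "dxy" & mt$locus_id == l]
  expect_equal(got_dxy, dxy(state[[1]][, l], state[[2]][, l]))
  got_fst <- mt$value[mt$metric == "fst" & mt$locus_id == l]
  cts <- rbind(table(factor(state[[1]][, l], levels = 0:1)),
               table(factor(state[[2]][, l], levels = 0:1)))
  expect_equal(got_fst, oracle_fst_wc(cts), tolerance = 1e-12)
  got_tot <- mt$value[mt$metric == "pi_total" & mt$locus_id == l]
  expect_equal(got_tot, nuc_div(c(state[[1]][, l], state[[2]][, l])))
  # r2 of a neutral locus with the (monomorphic) selected locus is undefined
  expect_true(all(is.na(mt$value[mt$metric == "r2"])))
  # phenotype rows: continuum start is monomorphic at 0
  expect_equal(mt$value[mt$metric == "mean_phenotype"], c(0, 0))
})

test_that("snapshot VCF export round-trips through vcfR", {
  skip_if_not_installed("vcfR")
  map <- build_flanking_map(n_flank_per_side = 4, min_cM = 0.5, max_cM = 10)
  params <- sim_params(N = 8, d = 2, m = 0.1, seed = 3,
                       effect_model = "nonredundant_diallelic",
                       generations = 4, sample_every = 2)
  state <- initialize_metapop(params, map)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_snapshot_vcf(state, map, path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  expect_equal(nrow(v@gt), nrow(map))              # all loci diallelic here
  expect_equal(ncol(v@gt) - 1L, 2L * 8L)           # one column per individual
  # allele frequencies survive the round trip at locus 1
  gt <- vcfR::extract.gt(v)[1, ]
  alt_freq <- mean(unlist(strsplit(gt, "|", fixed = TRUE)) == "1")
  raw <- c(state[[1]][, 1], state[[2]][, 1])
  expect_equal(alt_freq, mean(raw != min(raw)))
})
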