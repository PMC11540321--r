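tiny_map <- function(flanks = 2, min_cM = 0.1) {
  build_flanking_map(n_flank_per_side = flanks, min_cM = min_cM, max_cM = 10)
}

test_that("Gaussian fitness follows the stabilizing-selection formula", {
  expect_equal(fitness_gaussian(1, 1, 5), 1)
  expect_equal(fitness_gaussian(3, 1, 5), exp(-0.4))
  expect_equal(fitness_gaussian(-1, 1, 1e9), 1, tolerance = 1e-8)
  # relative fitness averages to 1 within a patch
  z <- c(-1, 0, 0.5, 1)
  expect_equal(mean(fitness_gaussian(z, 1, 5, relative = TRUE)), 1)
  expect_error(fitness_gaussian(0, 0, -1), "positive")
})

test_that("phenotypes are additive over selected loci", {
  # nonredundant: optimal homozygote at all l loci gives z = 1
  l <- 4
  map <- build_flanking_map(n_selected = l, n_flank_per_side = 1,
                            min_cM = 10, max_cM = 10)
  a <- 1 / (2 * l)
  haps <- matrix(0, 2, nrow(map))
  haps[, map$kind == "selected"] <- a
  expect_equal(phenotypes(haps, map), 1)
  # redundant: +0.25 homozygote at exactly 2 of many loci gives z = 1
  map2 <- build_flanking_map(n_selected = 10, n_flank_per_side = 1,
                             min_cM = 10, max_cM = 10)
  haps2 <- matrix(0, 2, nrow(map2))
  sel <- which(map2$kind == "selected")
  haps2[, sel[c(3, 8)]] <- 0.25
  expect_equal(phenotypes(haps2, map2), 1)
  expect_equal(phenotypes(matrix(0, 4, nrow(map2)), map2), c(0, 0))
})

test_that("migration matrices implement two-patch exchange and stepping stones", {
  expect_equal(migration_matrix(0.1, 2), rbind(c(0.9, 0.1), c(0.1, 0.9)))
  M <- migration_matrix(0.1, 10)
  expect_equal(rowSums(M), rep(1, 10))
  expect_equal(M[5, 4:6], c(0.05, 0.90, 0.05))
  expect_equal(M[1, 1:2], c(0.95, 0.05))           # terminal: m/2 from one side
  expect_equal(M[10, 9:10], c(0.05, 0.95))
  # interior patches receive twice the immigrant fraction of terminal ones
  influx <- 1 - diag(M)
  expect_equal(influx[5] / influx[1], 2)
  expect_error(migration_matrix(-0.1, 2), "m must")
  expect_error(migration_matrix(0.1, 1), "d must")
})

test_that("initialization matches the standing-variation design", {
  map <- build_flanking_map()
  p <- sim_params(N = 400, d = 2, m = 0.1, seed = 99)
  st <- initialize_metapop(p, map)
  expect_length(st, 2)
  expect_equal(dim(st[[1]]), c(800L, 75L))
  neu <- which(map$kind == "neutral")
  freqs <- colMeans(st[[1]][, neu])
  expect_equal(mean(freqs), 0.5, tolerance = 0.02)
  expect_true(all(st[[1]][, neu] %in% c(0, 1)))
  # continuum standing start: initial allele copies drawn from N(0, 1)
  sel_init <- st[[1]][, map$kind == "selected"]
  expect_gt(stats::sd(sel_init), 0.8)
  expect_lt(abs(mean(sel_init)), 0.2)
  # monomorphic option starts all copies at effect 0
  pm <- sim_params(N = 400, d = 2, m = 0.1, seed = 99,
                   continuum_init = "monomorphic")
  stm <- initialize_metapop(pm, map)
  expect_true(all(stm[[1]][, map$kind == "selected"] == 0))
  # diallelic models start Bernoulli(0.5) over the two effect states
  pr <- sim_params(N = 400, d = 2, m = 0.1, n_adaptive = 1, seed = 99,
                   effect_model = "redundant_diallelic")
  str <- initialize_metapop(pr, map)
  sel_vals <- str[[1]][, map$kind == "selected"]
  expect_true(all(sel_vals %in% c(-0.25, 0.25)))
  expect_equal(mean(sel_vals > 0), 0.5, tolerance = 0.06)
  # determinism
  expect_identical(st, initialize_metapop(p, map))
  # map/params mismatch is caught
  expect_error(initialize_metapop(sim_params(n_adaptive = 2), map),
               "selected loci")
})

test_that("recombination respects complete linkage and free recombination", {
  parent <- rbind(rep(0, 5), rep(1, 5))
  # all rec fractions 0: gametes are intact parental haplotypes
  g0 <- sim_gametes(parent, rep(0, 4), 200, seed = 1)
  expect_true(all(rowSums(g0) %in% c(0, 5)))
  expect_equal(mean(rowSums(g0) == 5), 0.5, tolerance = 0.12)
  # a 0.5 interval decouples the two sides
  g5 <- sim_gametes(parent, c(0, 0.5, 0, 0), 4000, seed = 2)
  left <- g5[, 2]; right <- g5[, 3]
  expect_lt(abs(cor(left, right)), 0.05)
  # single 0.1 interval: switch frequency within binomial error
  n <- 1e5
  g1 <- sim_gametes(rbind(c(0, 0), c(1, 1)), 0.1, n, seed = 3)
  sw <- mean(g1[, 1] != g1[, 2])
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(sw - 0.1), 3.5 * se)
  # intermediate fraction via the map convention: 25 cM -> 0.25
  g2 <- sim_gametes(rbind(c(0, 0), c(1, 1)), cm_to_recfrac(25), n, seed = 4)
  expect_lt(abs(mean(g2[, 1] != g2[, 2]) - 0.25), 3.5 * sqrt(0.25 * 0.75 / n))
})

test_that("mutation rates produce the expected flip frequencies", {
  map <- tiny_map()
  # monomorphic-0 neutral start, one generation at high mu: freq ~= mu
  p <- sim_params(N = 500, d = 2, m = 0, V_S = 1e9, mu_neutral = 0.01,
                  mu_adaptive = 0, generations = 1, sample_every = 1, seed = 5)
  st <- initialize_metapop(p, map)
  for (k in 1:2) st[[k]][, map$kind == "neutral"] <- 0
  eng <- ladsim:::engine_create(st, rec_fractions(map), which(map$kind == "selected"),
                       list(theta = p$theta, V_S = p$V_S,
                            mu_neutral = p$mu_neutral, mu_adaptive = p$mu_adaptive,
                            adaptive_model = 0L,
                            migration = migration_matrix(p$m, p$d)),
                       1)
  ladsim:::engine_run(eng, 1L)
  out <- ladsim:::engine_state(eng)
  copies <- 2 * 1000 * sum(tiny_map()$kind == "neutral")
  flips <- sum(out[[1]][, map$kind == "neutral"]) +
    sum(out[[2]][, map$kind == "neutral"])
  expect_lt(abs(flips - copies * 0.01), 4 * sqrt(copies * 0.01))
  # mu = 0 leaves a monomorphic system monomorphic
  p0 <- sim_params(N = 50, d = 2, m = 0.1, V_S = 1e9, mu_neutral = 0,
                   mu_adaptive = 0, generations = 30, sample_every = 30, seed = 6)
  st0 <- initialize_metapop(p0, map)
  for (k in 1:2) st0[[k]][] <- 0
  eng0 <- ladsim:::engine_create(st0, rec_fractions(map), which(map$kind == "selected"),
                        list(theta = p0$theta, V_S = p0$V_S, mu_neutral = 0,
                             mu_adaptive = 0, adaptive_model = 0L,
                             migration = migration_matrix(0.1, 2)), 2)
  ladsim:::engine_run(eng0, 30L)
  expect_true(all(unlist(ladsim:::engine_state(eng0)) == 0))
})

test_that("allele domains are closed and census size is conserved", {
  map <- tiny_map()
  p <- sim_params(N = 30, d = 2, m = 0.2, V_S = 5, mu_neutral = 1e-3,
                  mu_adaptive = 1e-3, n_adaptive = 1,
                  effect_model = "redundant_diallelic",
                  generations = 200, sample_every = 100, seed = 7)
  sim <- simulate_metapop(p, map)
  for (st in list(sim$final_state)) {
    expect_length(st, 2)
    for (h in st) {
      expect_equal(dim(h), c(60L, nrow(map)))
      expect_true(all(h[, map$kind == "neutral"] %in% c(0, 1)))
      expect_true(all(h[, map$kind == "selected"] %in% c(-0.25, 0.25)))
    }
  }
})

test_that("identical seeds give identical metric streams", {
  map <- tiny_map()
  p <- sim_params(N = 40, d = 2, m = 0.05, V_S = 5, generations = 100,
                  sample_every = 50, seed = 123)
  s1 <- simulate_metapop(p, map)
  s2 <- simulate_metapop(p, map)
  expect_identical(s1$metrics, s2$metrics)
  expect_identical(s1$final_state, s2$final_state)
  p2 <- sim_params(N = 40, d = 2, m = 0.05, V_S = 5, generations = 100,
                   sample_every = 50, seed = 124)
  s3 <- simulate_metapop(p2, map)
  expect_false(identical(s1$metrics, s3$metrics))
})

test_that("maximal mixing makes two patches behave as one population", {
  # m = 0.5, neutral: allele-frequency difference between patches stays at
  # binomial sampling noise, and pooled diversity matches a panmictic run
  map <- tiny_map()
  p <- sim_params(N = 100, d = 2, m = 0.5, V_S = 1e9, mu_neutral = 1e-4,
                  generations = 300, sample_every = 300, seed = 8)
  sim <- simulate_metapop(p, map)
  st <- sim$final_state
  neu <- which(map$kind == "neutral")
  dp <- abs(colMeans(st[[1]][, neu]) - colMeans(st[[2]][, neu]))
  polym <- (colMeans(st[[1]][, neu]) + colMeans(st[[2]][, neu])) / 2
  keep <- polym > 0.1 & polym < 0.9
  skip_if(sum(keep) < 2)
  # SD of the between-patch difference of two binomial(2N) samples
  expect_lt(mean(dp[keep]), 4 * sqrt(2 * 0.5 * 0.5 / 200))
})

test_that("neutral drift without migration follows the classical decay law", {
  # E[H_t] = H_0 (1 - 1/(2N))^t; loci and replicates give the mean
  withr::local_seed(909)
  map <- tiny_map()
  N <- 20; gens <- 60
  pw <- replicate(12, {
    p <- sim_params(N = N, d = 2, m = 0, V_S = 1e9, mu_neutral = 0,
                    generations = gens, sample_every = gens,
                    seed = sample.int(1e6, 1))
    sim <- simulate_metapop(p, map)
    st <- sim$final_state
    neu <- which(map$kind == "neutral")
    # raw (uncorrected) expected heterozygosity
    mean(vapply(1:2, function(k) {
      f <- colMeans(st[[k]][, neu]); mean(2 * f * (1 - f))
    }, numeric(1)))
  })
  h0 <- 0.5
  expected <- h0 * (1 - 1 / (2 * N))^gens
  se <- stats::sd(pw) / sqrt(length(pw))
  expect_lt(abs(mean(pw) - expected), 4 * max(se, 0.005))
})

test_that("neutral island diversity matches a single-locus Markov-chain oracle", {
  # Engine (V_S = 1e9) vs an independent allele-frequency WF chain with the
  # same N, d = 2, m, and symmetric diallelic mutation.
  N <- 50; m <- 0.1; mu <- 1e-3; gens <- 1500
  map <- tiny_map(flanks = 10, min_cM = 1e-3)
  p <- sim_params(N = N, d = 2, m = m, V_S = 1e9, mu_neutral = mu,
                  generations = gens, sample_every = gens, seed = 77)
  sim <- simulate_metapop(p, map)
  neu <- which(map$kind == "neutral")
  f1 <- colMeans(sim$final_state[[1]][, neu])
  pi_engine <- mean(2 * f1 * (1 - f1) * (2 * N) / (2 * N - 1))

  # oracle: binomial-sampling chain over allele frequencies only
  oracle_chain <- function(nloci, seed) {
    set.seed(seed)
    p1 <- rep(0.5, nloci); p2 <- rep(0.5, nloci)
    for (t in seq_len(gens)) {
      q1 <- (1 - m) * p1 + m * p2
      q2 <- (1 - m) * p2 + m * p1
      q1 <- q1 * (1 - mu) + (1 - q1) * mu
      q2 <- q2 * (1 - mu) + (1 - q2) * mu
      p1 <- rbinom(nloci, 2 * N, q1) / (2 * N)
      p2 <- rbinom(nloci, 2 * N, q2) / (2 * N)
    }
    mean(2 * p1 * (1 - p1) * (2 * N) / (2 * N - 1))
  }
  pi_oracle <- oracle_chain(5000, 31)
  # engine has 20 (linked) loci -> generous Monte-Carlo band
  expect_lt(abs(pi_engine - pi_oracle), 0.35 * pi_oracle + 0.02)
  # and both sit in the diallelic-equilibrium ballpark below 4 d N mu
  expect_lt(pi_oracle, 4 * 2 * N * mu)
  expect_gt(pi_oracle, 4 * N * mu / 2)
})

test_that("patch labels are exchangeable in symmetric two-patch runs", {
  # mirrored optima with paired seeds: patch 1 under theta = (-1, 1) should
  # be distributed like patch 2 under theta = (1, -1)
  map <- tiny_map()
  seeds <- 1:15
  stat <- function(theta, patch, s) {
    p <- sim_params(N = 30, d = 2, m = 0.01, V_S = 5, theta = theta,
                    generations = 300, sample_every = 300, seed = s)
    sim <- simulate_metapop(p, map)
    neu <- which(map$kind == "neutral")
    f <- colMeans(sim$final_state[[patch]][, neu])
    mean(2 * f * (1 - f))
  }
  a <- vapply(seeds, function(s) stat(c(-1, 1), 1, s), numeric(1))
  b <- vapply(seeds, function(s) stat(c(1, -1), 2, s + 500), numeric(1))
  expect_gt(stats::t.test(a, b)$p.value, 0.01)
})
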