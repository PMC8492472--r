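test_that("pi and theta match the brute-force haplotype oracle", {
  set.seed(41)
  for (trial in 1:5) {
    n_hap <- sample(c(6, 8, 10), 1)
    n_sites <- sample(4:12, 1)
    haps <- matrix(rbinom(n_hap * n_sites, 1, runif(1, 0.2, 0.6)),
                   n_hap, n_sites)
    pos <- sort(sample.int(900, n_sites))
    gm <- haps_to_gm(haps, pos, pop = "p1")
    w <- window_diversity_stats(gm, "p1", window_size = 1000, step = 1000,
                                chrom_lengths = c(chr1 = 1000))
    want <- oracle_pi_theta(haps, 1000)
    expect_equal(w$pi, want$pi, tolerance = 1e-12)
    expect_equal(w$theta_w, want$theta_w, tolerance = 1e-12)
    expect_equal(w$n_sites, want$S)
  }
})

test_that("hand-listed 6-haplotype window matches pairwise counting and a_5", {
  haps <- rbind(c(1, 0, 0, 0), c(1, 1, 0, 0), c(0, 1, 1, 0),
                c(0, 0, 1, 0), c(0, 0, 0, 1), c(0, 0, 0, 0))
  gm <- haps_to_gm(haps, c(10, 250, 500, 750), pop = "p1")
  w <- window_diversity_stats(gm, "p1", window_size = 1000, step = 1000,
                              chrom_lengths = c(chr1 = 1000))
  want <- oracle_pi_theta(haps, 1000)
  expect_equal(w$pi, want$pi)
  expect_equal(w$theta_w, want$theta_w)
  expect_equal(sum(1 / 1:5), 137 / 60)
})

test_that("a single diploid pair with 3 differences in 1 kb gives pi = 0.003", {
  haps <- rbind(c(1, 1, 1), c(0, 0, 0))      # one diploid, 3 het sites
  gm <- haps_to_gm(haps, c(100, 400, 800), pop = "p1")
  w <- window_diversity_stats(gm, "p1", window_size = 1000, step = 1000,
                              chrom_lengths = c(chr1 = 1000))
  expect_equal(w$pi, 0.003)
})

test_that("monomorphic windows report zero diversity and missing D", {
  haps <- matrix(0L, 8, 1)
  haps[1, 1] <- 1L   # one singleton far away in a second window
  gm <- haps_to_gm(haps, 1500, pop = "p1")
  w <- window_diversity_stats(gm, "p1", window_size = 1000, step = 1000,
                              chrom_lengths = c(chr1 = 2000))
  expect_equal(w$pi[1], 0)
  expect_equal(w$theta_w[1], 0)
  expect_true(is.na(w$tajima_d[1]))
  expect_gt(w$pi[2], 0)
})

test_that("Tajima's D and Fu & Li D*/F* are centred near zero on neutral data", {
  sim <- simulate_two_population_genotypes(20, 2e7, 0, seed = 13)
  w <- window_diversity_stats(sim$gm, "pop1", step = 1e5,
                              chrom_lengths = c(chr1 = 2e7))
  expect_equal(nrow(w), 200)
  expect_lt(abs(mean(w$tajima_d, na.rm = TRUE)), 0.3)
  expect_lt(abs(mean(w$fuli_d_star, na.rm = TRUE)), 0.5)
  expect_lt(abs(mean(w$fuli_f_star, na.rm = TRUE)), 0.5)
  # neutral simulated diversity matches the target within sampling error
  expect_lt(abs(mean(w$pi) - 2e-3) / 2e-3, 0.15)
  expect_lt(abs(mean(w$theta_w) - 2e-3) / 2e-3, 0.15)
})

test_that("Weir-Cockerham Fst matches a hand-computed single site", {
  # two pops of 10 diploids; alt counts 12/20 and 4/20
  # genotypes chosen with explicit heterozygote counts (6 and 4 hets)
  d1 <- c(2, 2, 2, 1, 1, 1, 1, 1, 1, 0)       # alt = 12, het = 6
  d2 <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)       # alt = 4, het = 4
  gm <- genotype_matrix(
    sprintf("s%02d", 1:20),
    data.frame(chromosome = "chr1", position = 500, ref = "A", alt = "G"),
    matrix(c(d1, d2), 1, 20,
           dimnames = list(NULL, sprintf("s%02d", 1:20))),
    population_of = setNames(rep(c("p1", "p2"), each = 10),
                             sprintf("s%02d", 1:20)))
  w <- weir_cockerham_fst(gm, "p1", "p2", window_size = 1000, step = 1000,
                          chrom_lengths = c(chr1 = 1000))
  # WC84 by hand: r=2, nbar=10, nc=10, pbar=0.4, s2=(10*.04+10*.04)/10=0.08
  n1 <- 10; n2 <- 10; r <- 2
  p1 <- 0.6; p2 <- 0.2; h1 <- 0.6; h2 <- 0.4
  nbar <- 10; nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                            hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  expect_equal(w$fst, a / (a + b + cc))
})

test_that("Fst limits: identical pops near zero, fixed difference near one", {
  set.seed(5)
  n <- 40
  haps <- matrix(rbinom(2 * n * 30, 1, 0.4), 2 * n, 30)
  haps2 <- rbind(haps, haps)   # both pops identical haplotype pools
  gm <- haps_to_gm(haps2, sort(sample.int(900, 30)))
  gm$population_of <- setNames(rep(c("p1", "p2"), each = n),
                               gm$sample_ids)
  w <- weir_cockerham_fst(gm, "p1", "p2", window_size = 1000, step = 1000,
                          chrom_lengths = c(chr1 = 1000))
  expect_lt(abs(w$fst_raw), 0.05)

  fixed <- rbind(matrix(1L, 2 * n, 30), matrix(0L, 2 * n, 30))
  gmf <- haps_to_gm(fixed, sort(sample.int(900, 30)))
  gmf$population_of <- gm$population_of
  wf <- weir_cockerham_fst(gmf, "p1", "p2", window_size = 1000,
                           step = 1000, chrom_lengths = c(chr1 = 1000))
  expect_gt(wf$fst, 0.95)

  # label swap symmetry for equal sample sizes
  wswap <- weir_cockerham_fst(gm, "p2", "p1", window_size = 1000,
                              step = 1000, chrom_lengths = c(chr1 = 1000))
  expect_lt(abs(w$fst_raw - wswap$fst_raw), 1e-12)
})

test_that("ZFst standardises to mean 0 and sample sd 1", {
  expect_equal(zfst_transform(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(2)
  z <- zfst_transform(runif(500))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(zfst_transform(rep(0.5, 10)), "zero variance")
  expect_error(zfst_transform(0.5), "at least 2")
})

test_that("neutral-genome ZFst is approximately standard normal", {
  sim <- simulate_two_population_genotypes(20, 2e7, 0, seed = 23)
  fst <- weir_cockerham_fst(sim$gm, "pop1", "pop2", step = 1e5,
                            chrom_lengths = c(chr1 = 2e7))
  z <- zfst_transform(fst$fst_raw)
  ks <- suppressWarnings(ks.test(z, "pnorm"))
  expect_gt(ks$p.value, 0.01)
})

test_that("sweep calling recovers planted windows with at most one false call", {
  sim <- simulate_two_population_genotypes(20, 1e7, 5,
                                           pi_background = 2e-3,
                                           pi_sweep = 5e-4, seed = 9)
  w1 <- window_diversity_stats(sim$gm, "pop1", step = 1e5,
                               chrom_lengths = c(chr1 = 1e7))
  w2 <- window_diversity_stats(sim$gm, "pop2", step = 1e5,
                               chrom_lengths = c(chr1 = 1e7))
  fst <- weir_cockerham_fst(sim$gm, "pop1", "pop2", step = 1e5,
                            chrom_lengths = c(chr1 = 1e7))
  wdf <- data.frame(w1[, c("chromosome", "start", "end")],
                    pi_ratio = w2$pi / w1$pi,
                    zfst = zfst_transform(fst$fst))
  sw <- call_selective_sweeps(wdf, 0.05)
  called <- sw$calls$start[sw$calls$direction == "selected_in_pop1"]
  planted <- sim$truth$sweep_window_starts
  expect_gte(sum(planted %in% called), 4)
  expect_lte(sum(!(called %in% planted)), 1)
  # directions disjoint, calls a subset of windows
  expect_lte(nrow(sw$calls), nrow(wdf))
})

test_that("sweep calling degenerates safely and respects the counting bound", {
  flat <- data.frame(chromosome = "c", start = 0:99 * 100,
                     end = 0:99 * 100 + 100,
                     pi_ratio = rep(1, 100), zfst = rep(0, 100))
  flat$zfst <- zfst_transform(c(rep(0, 99), 1e-9))[1:100] # avoid zero var
  flat$pi_ratio <- rep(1, 100)
  sw <- suppressWarnings(call_selective_sweeps(flat, 0.05))
  expect_true(sw$degenerate || nrow(sw$calls) <= 10)

  set.seed(1)
  big <- data.frame(chromosome = "c", start = seq_len(1000),
                    end = seq_len(1000) + 1,
                    pi_ratio = rlnorm(1000), zfst = rnorm(1000))
  swb <- call_selective_sweeps(big, 0.05)
  for (dir in c("selected_in_pop1", "selected_in_pop2"))
    expect_lte(sum(swb$calls$direction == dir), 50)
  expect_error(call_selective_sweeps(big[1:10, ], 0.05), "fewer than")
})

test_that("null simulation produces no more than chance-level sweep calls", {
  sim <- simulate_two_population_genotypes(20, 1e7, 0, seed = 31)
  w1 <- window_diversity_stats(sim$gm, "pop1", step = 1e5,
                               chrom_lengths = c(chr1 = 1e7))
  w2 <- window_diversity_stats(sim$gm, "pop2", step = 1e5,
                               chrom_lengths = c(chr1 = 1e7))
  fst <- weir_cockerham_fst(sim$gm, "pop1", "pop2", step = 1e5,
                            chrom_lengths = c(chr1 = 1e7))
  wdf <- data.frame(w1[, c("chromosome", "start", "end")],
                    pi_ratio = w2$pi / w1$pi,
                    zfst = zfst_transform(fst$fst))
  sw <- call_selective_sweeps(wdf, 0.05)
  # joint top-5% under independence ~ 0.25% of 100 windows
  expect_lte(nrow(sw$calls), 3)
})

test_that("LD decay: perfect LD for duplicated sites, 1/n for unlinked", {
  set.seed(6)
  n <- 100
  site <- rbinom(2 * n, 1, 0.5)
  haps <- cbind(site, site)      # identical site duplicated at distance d
  gm <- haps_to_gm(haps, c(100, 2100), pop = "p1")
  ld <- ld_decay_curve(gm, "p1", max_distance = 5000, bin_size = 1000)
  expect_equal(ld$curve$mean_r2[2], 1)

  unlinked <- matrix(rbinom(2 * n * 60, 1, 0.5), 2 * n, 60)
  gmu <- haps_to_gm(unlinked, sort(sample.int(5000, 60)), pop = "p1")
  ldu <- ld_decay_curve(gmu, "p1", max_distance = 5000, bin_size = 5000)
  expect_equal(ldu$curve$mean_r2[1], 1 / n, tolerance = 0.5)
})

test_that("half-decay distance recovers a planted exponential decay", {
  set.seed(44)
  n <- 120
  n_sites <- 150
  pos <- sort(sample.int(2e5, n_sites))
  half_target <- 3e4
  anchor <- rbinom(2 * n, 1, 0.5)
  haps <- matrix(0L, 2 * n, n_sites)
  # correlation decaying exponentially with distance from site 1
  for (j in seq_len(n_sites)) {
    rho <- exp(-log(2) * (pos[j] - pos[1]) / half_target)
    keep <- runif(2 * n) < sqrt(rho)
    haps[, j] <- ifelse(keep, anchor, rbinom(2 * n, 1, 0.5))
  }
  gm <- haps_to_gm(haps, pos, pop = "p1")
  ld <- ld_decay_curve(gm, "p1", max_distance = 1.5e5, bin_size = 1e4)
  expect_false(is.na(ld$half_decay_distance))
  # within one bin of the planted half distance (loose: composite decay)
  expect_lt(abs(ld$half_decay_distance - half_target), 2e4)
})

test_that("simulated genotypes are deterministic and VCF bytes identical per seed", {
  a <- simulate_two_population_genotypes(6, 3e5, 1, window_size = 1e5,
                                         seed = 99)
  b <- simulate_two_population_genotypes(6, 3e5, 1, window_size = 1e5,
                                         seed = 99)
  expect_identical(a$gm$genotypes, b$gm$genotypes)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_vcf_minimal(a$gm, f1); write_vcf_minimal(b$gm, f2)
  expect_identical(readLines(f1), readLines(f2))
})
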