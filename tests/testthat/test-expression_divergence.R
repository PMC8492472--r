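# small hand-built panel helper
tiny_panel <- function(tpm, n_ctx = ncol(tpm) %||% 9) {
  n <- nrow(tpm) / 3
  pair_id <- sprintf("p%d", seq_len(n))
  structure(list(
    tpm = tpm,
    pairs = data.frame(pair_id = pair_id,
                       subA = rownames(tpm)[seq_len(n)],
                       subB = rownames(tpm)[n + seq_len(n)],
                       outgroup = rownames(tpm)[2 * n + seq_len(n)],
                       stringsAsFactors = FALSE),
    contexts = colnames(tpm)), class = "expression_panel")
}

mk_tpm <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- sprintf("ctx%d", seq_len(ncol(m)))
  m
}

test_that("dominance counts strict winners, ties and floor exclusions", {
  tpm <- mk_tpm(A1 = c(5, 2, 0.2, 3), A2 = c(1, 1, 1, 1),
                B1 = c(10, 2, 0.5, 1), B2 = c(2, 1, 1, 1),
                O1 = c(1, 1, 1, 1), O2 = c(1, 1, 1, 1))
  p <- tiny_panel(tpm)
  dom <- dominance_analysis(p, floor = 1)
  # ctx1: B1 > A1 and B2 > A2 -> two subB wins
  expect_equal(dom$subB_dominant[1], 2)
  # ctx2: 2 == 2 and 1 == 1 -> ties
  expect_equal(dom$ties[2], 2)
  # ctx3: pair 1 has both copies below floor -> excluded
  expect_equal(dom$excluded[3], 1)
  # accounting invariant
  expect_true(all(dom$subA_dominant + dom$subB_dominant + dom$ties +
                    dom$excluded == 2))
})

test_that("chi-square on dominance counts matches the closed form", {
  # counts (600, 400): X2 = 2 * (100^2 / 500) = 40
  ct <- suppressWarnings(chisq.test(c(600, 400), p = c(0.5, 0.5)))
  expect_equal(unname(ct$statistic), 40)
  expect_equal(ct$p.value, pchisq(40, 1, lower.tail = FALSE))
})

test_that("dominance-bias recovery and null calibration on simulated panels", {
  p <- simulate_expression_panel(2000, dominance_bias = 0.6, seed = 4)
  pd <- pair_dominance(p)
  expect_lt(abs(mean(pd$dominant == "subB") - 0.6), 0.03)

  # at bias 0.5 the per-context chi-square should rarely reject
  ps <- unlist(lapply(1:6, function(s) {
    dominance_analysis(simulate_expression_panel(1000, dominance_bias = 0.5,
                                                 seed = s))$p_value
  }))
  expect_gte(mean(ps > 0.05), 0.95)
})

test_that("conservation and divergence follow the r/distance rules", {
  base <- c(2, 4, 8, 16, 32, 16, 8, 4, 2)
  tpm <- mk_tpm(A1 = base, A2 = base,
                B1 = base, B2 = rev(base) * 5,
                O1 = base, O2 = base)
  p <- tiny_panel(tpm)
  cd <- conservation_and_divergence(p)
  # copy identical to outgroup -> conserved, r = 1
  expect_true(cd$subA_conserved[1])
  expect_equal(cd$subA_outgroup_r[1], 1)
  # identical homoeologs -> distance 0, r = 1, nondivergent
  expect_equal(cd$euclidean_distance[1], 0)
  expect_false(cd$divergent[1])
  # anti-correlated pair -> divergent by correlation
  expect_true(cd$divergent[2])
})

test_that("constant profiles give undefined correlation, classified divergent", {
  tpm <- mk_tpm(A1 = rep(5, 9), B1 = 1:9, O1 = 1:9)
  p <- tiny_panel(tpm)
  cd <- conservation_and_divergence(p)
  expect_true(cd$r_undefined[1])
  expect_true(cd$divergent[1])
})

test_that("planted high-distance pairs are exactly the ones over the 90th percentile", {
  set.seed(31)
  n <- 100
  base <- matrix(2^rnorm(n * 9, 3, 0.2), n, 9)
  a <- base
  b <- base * matrix(2^rnorm(n * 9, 0, 0.05), n, 9)
  planted <- sample(n, 10)
  b[planted, ] <- b[planted, ] * matrix(2^rnorm(10 * 9, 6, 0.3), 10, 9)
  tpm <- rbind(a, b, base)
  rownames(tpm) <- c(sprintf("a%d", 1:n), sprintf("b%d", 1:n),
                     sprintf("o%d", 1:n))
  colnames(tpm) <- sprintf("ctx%d", 1:9)
  p <- tiny_panel(tpm)
  cd <- conservation_and_divergence(p)
  top10 <- order(cd$euclidean_distance, decreasing = TRUE)[1:10]
  expect_setequal(top10, planted)
  expect_true(all(cd$euclidean_distance[planted] >=
                    attr(cd, "dist_threshold")))
})

test_that("average-linkage clustering splits blobs and groups duplicates", {
  set.seed(8)
  blob1 <- matrix(rnorm(50 * 5, 0, 0.2), 50, 5)
  blob2 <- matrix(rnorm(50 * 5, 8, 0.2), 50, 5)
  m <- 2^rbind(blob1, blob2) - 1
  m[m < 0] <- 0
  rownames(m) <- sprintf("g%d", 1:100)
  cl <- cluster_profiles(m, 2)
  expect_equal(length(unique(cl[1:50])), 1)
  expect_equal(length(unique(cl[51:100])), 1)
  expect_false(cl[1] == cl[51])

  dup <- m[c(1, 1, 60, 60), ]
  rownames(dup) <- sprintf("d%d", 1:4)
  cld <- cluster_profiles(dup, 2)
  expect_equal(cld[1], cld[2], ignore_attr = TRUE)
  expect_equal(cld[3], cld[4], ignore_attr = TRUE)
  expect_error(cluster_profiles(dup, 9), "exceeds")
})

test_that("functionalization classes follow the precedence rules", {
  base <- c(2, 4, 8, 16, 32, 16, 8, 4, 2)
  tpm <- mk_tpm(
    A1 = base, A2 = rep(0, 9), A3 = base,
    B1 = base * 1.1, B2 = base, B3 = rev(base) * 30,
    O1 = base, O2 = base, O3 = base)
  p <- tiny_panel(tpm)
  genes <- c(p$pairs$subA, p$pairs$subB)
  clusters <- cluster_profiles(p$tpm[genes, ], 2)
  cd <- conservation_and_divergence(p)
  fc <- classify_functionalization(p, clusters, cd)
  # pair 2: subA silent everywhere -> non-F
  expect_equal(fc$class[2], "non-F")
  # pair 1: both copies track the outgroup, same cluster -> coexpressed
  expect_equal(fc$class[1], "coexpressed")
  # pair 3: subA conserved, subB reversed/divergent, clusters differ -> neo-F
  expect_equal(fc$class[3], "neo-F")
  # classes partition classifiable pairs
  expect_true(all(fc$class %in%
                    c("non-F", "neo-F", "sub-F", "coexpressed")))
})

test_that("sub-F requires the summed profile to restore outgroup correlation", {
  # complementary expression: subA covers one half of the (non-constant)
  # outgroup profile, subB the other; only their sum tracks it
  outp <- c(4, 8, 16, 32, 64, 32, 16, 8, 4)
  a <- c(8, 16, 32, 64, 0, 0, 0, 0, 0)
  b <- outp * 2 - a
  tpm <- mk_tpm(A1 = a, B1 = b, O1 = outp)
  p <- tiny_panel(tpm)
  genes <- c(p$pairs$subA, p$pairs$subB)
  clusters <- setNames(c(1L, 2L), genes)
  cd <- conservation_and_divergence(p)
  expect_false(isTRUE(cd$subA_conserved[1]))
  expect_false(isTRUE(cd$subB_conserved[1]))
  fc <- classify_functionalization(p, clusters, cd)
  expect_equal(fc$class[1], "sub-F")
})

test_that("cotranscription percentages at the floor and degenerate floors", {
  p <- simulate_expression_panel(500, seed = 6)
  ct <- cotranscription_summary(p)
  expect_gte(ct$pct_ge3_contexts, ct$pct_all_contexts)
  expect_equal(ct$pct_all_contexts,
               round_half_up(100 * ct$n_all_contexts / 500, 1))

  everything <- cotranscription_summary(p, floor = 0)
  expect_equal(everything$pct_all_contexts, 100)
  nothing <- cotranscription_summary(p, floor = max(p$tpm) + 1)
  expect_equal(nothing$pct_all_contexts, 0)
  expect_equal(nothing$pct_ge3_contexts, 0)
})

test_that("pseudo-ancestral dosage sums homoeologs against the ortholog", {
  tpm <- mk_tpm(A1 = c(3, 3, 3), B1 = c(4, 4, 4), O1 = c(7, 7, 7))
  p <- tiny_panel(tpm)
  d <- pseudo_ancestral_dosage(p)
  expect_equal(d$median_difference, c(0, 0, 0))
  expect_true(all(d$p_value > 0.05))

  # halved copies match the ortholog distribution
  set.seed(12)
  o <- matrix(2^rnorm(200 * 9, 4, 1), 200, 9)
  a <- o / 2
  b <- o / 2
  tpm2 <- rbind(a, b, o)
  rownames(tpm2) <- c(sprintf("a%d", 1:200), sprintf("b%d", 1:200),
                      sprintf("o%d", 1:200))
  colnames(tpm2) <- sprintf("ctx%d", 1:9)
  d2 <- pseudo_ancestral_dosage(tiny_panel(tpm2))
  expect_true(all(d2$p_value > 0.05))
})

test_that("divergence fraction rises across Ka/Ks bins when planted", {
  set.seed(14)
  n <- 1000
  kaks <- rexp(n, 10)
  p_div <- plogis(-2 + 30 * kaks)
  divergent <- runif(n) < p_div
  tr <- kaks_divergence_trend(kaks, divergent)
  expect_equal(tr$rho, 1)
  expect_lt(tr$trend_p, 1e-6)

  # independent divergence: trend statistic near zero across seeds
  rhos <- vapply(1:10, function(s) {
    set.seed(s)
    kaks_divergence_trend(rexp(n, 10), runif(n) < 0.3)$rho
  }, 0)
  expect_lt(abs(mean(rhos)), 0.35)

  all_div <- kaks_divergence_trend(rexp(100, 10), rep(TRUE, 100), n_bins = 2)
  expect_true(all(all_div$bins$fraction == 1))
})

test_that("DEG balance test counts single-DE pairs and calibrates", {
  flags <- c(rep(TRUE, 30), rep(FALSE, 70))
  same <- deg_balance_test(flags, flags)
  expect_equal(same$chisq_p, 1)
  expect_equal(same$n_one_de, 0)

  allA <- deg_balance_test(rep(TRUE, 50), rep(FALSE, 50))
  expect_equal(allA$pct_one_de, 100)

  set.seed(3)
  ps <- vapply(1:20, function(i)
    deg_balance_test(runif(2000) < 0.3, runif(2000) < 0.3)$chisq_p, 0)
  expect_gte(mean(ps > 0.05), 0.95)
})

test_that("trans-splicing calls classify by partner subgenomes", {
  locations <- data.frame(
    gene_id = c("gA1", "gA2", "gB1", "gB2", "gS"),
    chromosome = c("chrA1", "chrA2", "chrB1", "chrB2", "scaffold:3"),
    stringsAsFactors = FALSE)
  assignments <- data.frame(
    chromosome = c("chrA1", "chrA2", "chrB1", "chrB2"),
    subgenome = c("A", "A", "B", "B"),
    stringsAsFactors = FALSE)
  calls <- data.frame(
    gene5prime = c("gA1", "gA1", "gB1", "gA2", "gS"),
    gene3prime = c("gB1", "gA2", "gB2", "unknown", "gB1"),
    stringsAsFactors = FALSE)
  res <- classify_trans_splicing(calls, locations, assignments)
  expect_equal(res$calls$class[1:3],
               c("inter-subgenome", "intra-A", "intra-B"))
  expect_equal(res$n_excluded, 2)
  expect_equal(unname(res$counts["inter-subgenome"]), 1L)
})

test_that("planted trans-splicing mix is recovered exactly", {
  set.seed(17)
  locations <- data.frame(
    gene_id = sprintf("g%03d", 1:200),
    chromosome = sample(c(sprintf("cA%d", 1:5), sprintf("cB%d", 1:5)),
                        200, replace = TRUE),
    stringsAsFactors = FALSE)
  assignments <- data.frame(
    chromosome = c(sprintf("cA%d", 1:5), sprintf("cB%d", 1:5)),
    subgenome = rep(c("A", "B"), each = 5),
    stringsAsFactors = FALSE)
  sub_of <- assignments$subgenome[
    match(locations$chromosome, assignments$chromosome)]
  a_genes <- locations$gene_id[sub_of == "A"]
  b_genes <- locations$gene_id[sub_of == "B"]
  calls <- rbind(
    data.frame(gene5prime = sample(a_genes, 50, TRUE),
               gene3prime = sample(b_genes, 50, TRUE)),
    data.frame(gene5prime = sample(a_genes, 25, TRUE),
               gene3prime = sample(a_genes, 25, TRUE)),
    data.frame(gene5prime = sample(b_genes, 25, TRUE),
               gene3prime = sample(b_genes, 25, TRUE)))
  res <- classify_trans_splicing(calls, locations, assignments)
  expect_equal(unname(res$counts),
               c(`intra-A` = 25L, `intra-B` = 25L,
                 `inter-subgenome` = 50L),
               ignore_attr = TRUE)
})
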