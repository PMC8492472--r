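canonical_newick <- paste0(
  "(zebrafish|z,(pguichenoti|p,((ptetrazona|t,(carp|c1,goldfish|g1)),",
  "(carp|c2,goldfish|g2))));")

test_that("the canonical heptad topology is classified with subB in the Pt clade", {
  cl <- classify_heptad_topology(read_newick(canonical_newick))
  expect_equal(cl$status, "canonical")
  expect_equal(cl$carp_subB_gene, "c1")
  expect_equal(cl$goldfish_subB_gene, "g1")
  expect_equal(cl$carp_subA_gene, "c2")
  expect_equal(cl$goldfish_subA_gene, "g2")
})

test_that("a tree with both carp copies inside the Pt clade is complex", {
  nwk <- paste0(
    "(zebrafish|z,(pguichenoti|p,((ptetrazona|t,((carp|c1,carp|c2),",
    "goldfish|g1)),goldfish|g2)));")
  cl <- classify_heptad_topology(read_newick(nwk))
  expect_equal(cl$status, "complex")
  expect_true(is.na(cl$carp_subA_gene))
})

test_that("classification is invariant to leaf order and node rotation", {
  rotated <- paste0(
    "((((goldfish|g2,carp|c2),((carp|c1,goldfish|g1),ptetrazona|t)),",
    "pguichenoti|p),zebrafish|z);")
  cl <- classify_heptad_topology(read_newick(rotated))
  expect_equal(cl$status, "canonical")
  expect_equal(cl$carp_subB_gene, "c1")
  expect_equal(cl$carp_subA_gene, "c2")
})

test_that("leaf census violations raise errors", {
  expect_error(classify_heptad_topology(read_newick("((a,b),c);")),
               "7 leaves")
  bad <- paste0(
    "(zebrafish|z,(zebrafish|z2,((ptetrazona|t,(carp|c1,goldfish|g1)),",
    "(carp|c2,goldfish|g2))));")
  expect_error(classify_heptad_topology(read_newick(bad)), "census")
})

test_that("min_support gates the two defining clades", {
  supported <- paste0(
    "(zebrafish|z,(pguichenoti|p,((ptetrazona|t,(carp|c1,goldfish|g1))80,",
    "(carp|c2,goldfish|g2)75)90));")
  cl <- classify_heptad_topology(read_newick(supported), min_support = 50)
  expect_equal(cl$status, "canonical")
  expect_true(cl$min_support_ok)
  cl2 <- classify_heptad_topology(read_newick(supported), min_support = 85)
  expect_equal(cl2$status, "canonical")
  expect_false(cl2$min_support_ok)
})

test_that("canonical count over all 10,395 rooted shapes matches the clade oracle", {
  labels <- c("zebrafish|z", "pguichenoti|p", "ptetrazona|t",
              "carp|c1", "carp|c2", "goldfish|g1", "goldfish|g2")
  newicks <- enumerate_rooted_trees(labels)
  expect_length(newicks, 10395)
  got <- 0L; want <- 0L
  for (nwk in newicks) {
    tr <- read_newick(nwk)
    if (classify_heptad_topology(tr)$status == "canonical")
      got <- got + 1L
    if (oracle_is_canonical(tr)) want <- want + 1L
  }
  expect_gt(got, 0)
  expect_equal(got, want)
})

test_that("chromosome assignment follows the majority and flips under label swap", {
  labels <- data.frame(
    gene_id = sprintf("g%02d", 1:35),
    label = c(rep("subB", 30), rep("subA", 5)),
    stringsAsFactors = FALSE)
  locations <- data.frame(gene_id = labels$gene_id, chromosome = "chr1",
                          stringsAsFactors = FALSE)
  asn <- assign_chromosome_subgenomes(labels, locations)
  expect_equal(asn$subgenome, "B")
  expect_equal(asn$subB_count, 30)

  swapped <- labels
  swapped$label <- ifelse(labels$label == "subA", "subB", "subA")
  expect_equal(assign_chromosome_subgenomes(swapped, locations)$subgenome,
               "A")
})

test_that("tied chromosomes are resolved through the homoeologous pairing", {
  labels <- data.frame(
    gene_id = sprintf("g%d", 1:6),
    label = c("subA", "subB", "subB", "subB", "subA", "subA"),
    stringsAsFactors = FALSE)
  locations <- data.frame(
    gene_id = labels$gene_id,
    chromosome = c("c1", "c1", "c2", "c2", "c2", "c2"),
    stringsAsFactors = FALSE)
  pairs <- data.frame(chrom1 = "c1", chrom2 = "c2",
                      stringsAsFactors = FALSE)
  asn <- assign_chromosome_subgenomes(labels, locations, pairs)
  # c1 is tied 1:1, c2 is tied 2:2 -> pairing fallback assigns one A one B
  expect_setequal(asn$subgenome, c("A", "B"))
  expect_true(all(asn$tie_broken))
})

test_that("noiseless simulation recovers every label, assignment and no HE", {
  sim <- simulate_heptad_families(50, he_rate = 0, topology_noise = 0,
                                  seed = 1)
  cls <- lapply(sim$families, function(f) classify_heptad_topology(f$tree))
  expect_true(all(vapply(cls, `[[`, "", "status") == "canonical"))
  for (sp in c("carp", "goldfish")) {
    lab <- subgenome_gene_labels(cls, sp)
    truth <- sim$truth$labels[sim$truth$labels$species == sp, ]
    m <- merge(lab, truth, by = "gene_id")
    expect_equal(nrow(m), 100)
    expect_true(all(m$label.x == m$label.y))
    asn <- assign_chromosome_subgenomes(lab, sim$locations,
                                        sim$homoeolog_pairs[[sp]])
    expect_equal(nrow(asn), 50)
    expect_true(all(grepl("_A", asn$chromosome) == (asn$subgenome == "A")))
    he <- detect_homoeologous_exchanges(lab, sim$locations, asn)
    expect_equal(nrow(he$events), 0)
  }
})

test_that("planted HE genes are detected exactly; scaffold genes excluded", {
  sim <- simulate_heptad_families(200, he_rate = 0.03, seed = 2)
  detected <- character(0)
  for (sp in c("carp", "goldfish")) {
    cls <- lapply(sim$families, function(f) classify_heptad_topology(f$tree))
    lab <- subgenome_gene_labels(cls, sp)
    asn <- assign_chromosome_subgenomes(lab, sim$locations,
                                        sim$homoeolog_pairs[[sp]])
    he <- detect_homoeologous_exchanges(lab, sim$locations, asn)
    detected <- c(detected, he$events$gene_id)
  }
  expect_identical(sort(detected), sim$truth$he_genes)

  # genes on scaffolds never become events
  loc2 <- sim$locations
  moved <- sim$truth$he_genes[1]
  loc2$chromosome[loc2$gene_id == moved] <- "scaffold:17"
  cls <- lapply(sim$families, function(f) classify_heptad_topology(f$tree))
  sp <- if (startsWith(moved, "cc_")) "carp" else "goldfish"
  lab <- subgenome_gene_labels(cls, sp)
  asn <- assign_chromosome_subgenomes(lab, loc2, sim$homoeolog_pairs[[sp]])
  he2 <- detect_homoeologous_exchanges(lab, loc2, asn)
  expect_false(moved %in% he2$events$gene_id)
  expect_equal(he2$n_scaffold_excluded, 1)
})

test_that("HE read-bias validation: direction, ties and empty groups", {
  res <- validate_he_read_bias(c(100, 120, 95, 110), c(50, 55, 48, 60),
                               "exchanged_higher")
  expect_equal(res$p_value, 1 / 70)
  expect_true(res$validated)

  flip <- validate_he_read_bias(c(100, 120, 95, 110), c(50, 55, 48, 60),
                                "exchanged_lower")
  expect_false(flip$validated)

  same <- validate_he_read_bias(1:20, 1:20)
  expect_gt(same$p_value, 0.4)
  expect_false(same$validated)

  empty <- validate_he_read_bias(numeric(0), 1:5)
  expect_equal(empty$status, "untested")
  expect_true(is.na(empty$validated))
})

test_that("windowed depth ratios flag two-fold sign inversions as HE", {
  # chromosome-wide bias toward A (median log2 ratio ~ +1), one window
  # inverted beyond two-fold
  depth_a <- c(20, 22, 18, 21, 4, 19)
  depth_b <- c(10, 11, 10, 10, 16, 9)
  calls <- detect_he_regions(depth_a, depth_b)
  expect_equal(which(calls$he_call), 5L)
})
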