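## Synthetic heptad gene families: codon sequences evolved along the
## fixed species topology
##   (zebrafish,(Pg,((Pt,(ccB,gfB)),(ccA,gfA))));
## with per-branch synonymous divergence targeting the Ks scales of the
## carp/goldfish system, planted homoeologous exchanges and a controlled
## fraction of non-canonical ("complex") gene trees.

#' Default per-comparison Ks targets for the heptad simulator
#'
#' Named synonymous divergences (substitutions per synonymous site)
#' between lineage pairs: A-lineage vs B-lineage 0.19, P. tetrazona vs
#' the B-subgenome ancestor 0.18, carp-B vs goldfish-B 0.10 and carp-A vs
#' goldfish-A 0.095.
#' @export
default_ks_spec <- function() {
  c(A_vs_B = 0.19, Pt_vs_Banc = 0.18, ccB_gfB = 0.10, ccA_gfA = 0.095)
}

# Branch lengths (in Ks units) realising a clock-like tree whose pairwise
# path lengths hit the ks_spec targets, plus outgroup depths for
# P. guichenoti (~0.26, Gobionidae split) and zebrafish (~0.42).
.heptad_branch_lengths <- function(ks_spec) {
  half_ab <- ks_spec[["A_vs_B"]] / 2      # depth of the A/B split
  b_tip <- ks_spec[["ccB_gfB"]] / 2       # ccB and gfB tip branches
  a_tip <- ks_spec[["ccA_gfA"]] / 2       # ccA and gfA tip branches
  pt_tip <- ks_spec[["Pt_vs_Banc"]] / 2   # Pt branch from the Pt/B node
  list(
    zeb_tip   = 0.42 / 2,
    pg_tip    = 0.26 / 2,
    root_in   = 0.42 / 2 - 0.26 / 2,      # root -> (Pg, ingroup) node
    pg_in     = 0.26 / 2 - half_ab,       # Pg node -> A/B split
    ab_to_ptb = half_ab - pt_tip,         # A/B split -> (Pt,B) node
    ab_to_a   = half_ab - a_tip,          # A/B split -> A-pair node
    pt_tip    = pt_tip,
    ptb_to_b  = pt_tip - b_tip,           # (Pt,B) node -> B-pair node
    b_tip     = b_tip,
    a_tip     = a_tip)
}

# Evolve one codon sequence (vector of codon strings) along a branch of
# synonymous length t (expected synonymous substitutions per synonymous
# site) with nonsynonymous substitutions at omega * t per nonsynonymous
# site.  Substitutions are applied one at a time among the codon's
# currently allowed single-nucleotide neighbours.
.evolve_codons <- function(codons, t, omega = 0.2) {
  if (t <= 0) return(codons)
  syn_sites <- ng86_syn_sites()
  nbr <- codon_neighbour_lists()
  s <- syn_sites[codons]
  lambda <- t * s + omega * t * (3 - s)
  n_events <- stats::rpois(length(codons), lambda)
  for (i in which(n_events > 0L)) {
    cd <- codons[i]
    for (k in seq_len(n_events[i])) {
      s_i <- syn_sites[[cd]]
      p_syn <- (t * s_i) / (t * s_i + omega * t * (3 - s_i))
      pool <- if (stats::runif(1) < p_syn) nbr[[cd]]$syn else nbr[[cd]]$nonsyn
      if (!length(pool)) pool <- c(nbr[[cd]]$syn, nbr[[cd]]$nonsyn)
      if (!length(pool)) break
      cd <- sample(pool, 1L)
    }
    codons[i] <- cd
  }
  codons
}

.random_root_codons <- function(n_codons) {
  codons <- all_codons()
  ok <- codons[codon_aa(codons) != "*"]
  sample(ok, n_codons, replace = TRUE)
}

#' Simulate heptad gene families with planted truth
#'
#' Each family evolves a root codon sequence along the fixed species tree
#' with branch lengths realising `ks_spec`; the seven tip sequences, the
#' (true or perturbed) gene tree, gene locations on 50 tetraploid
#' chromosomes per tetraploid, and a truth record are returned.  A
#' fraction `he_rate` of carp and goldfish genes is relocated to the
#' homoeologous partner chromosome (planted HE); a fraction
#' `topology_noise` of families is emitted with a non-canonical gene tree
#' (both carp copies sister to each other inside the P. tetrazona clade).
#'
#' @param n_families number of families.
#' @param ks_spec named Ks targets, see [default_ks_spec()].
#' @param he_rate fraction of tetraploid genes relocated (planted HE).
#' @param topology_noise fraction of families emitted with a
#'   non-canonical topology.
#' @param n_codons codons per root sequence (default 300, a typical
#'   teleost coding-sequence length; with ~0.75 synonymous sites per
#'   codon this gives a per-pair Ks granularity of ~1/225, fine enough
#'   to resolve Ks modes at the 0.01 scale).
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `families` (per family: `family_id`, `sequences`
#'   named codon-string vector, `tree` (`phylo`), `newick`), `locations`
#'   (data.frame: `gene_id`, `species`, `chromosome`, `start`, `end`,
#'   `strand`), `homoeolog_pairs` per species, and `truth`
#'   (per-gene labels, planted HE gene ids, planted complex family ids,
#'   branch Ks targets, seed).
#' @export
simulate_heptad_families <- function(n_families,
                                     ks_spec = default_ks_spec(),
                                     he_rate = 0,
                                     topology_noise = 0,
                                     n_codons = 300,
                                     seed = 1) {
  stopifnot(he_rate >= 0, he_rate <= 1,
            topology_noise >= 0, topology_noise <= 1,
            all(ks_spec >= 0))
  bl <- .heptad_branch_lengths(ks_spec)
  if (any(unlist(bl) < 0))
    stopf("ks_spec implies a negative branch length; targets must be nested")

  with_seed(seed, {
    tips <- c("zebrafish", "pguichenoti", "ptetrazona",
              "carpB", "goldfishB", "carpA", "goldfishA")

    families <- vector("list", n_families)
    labels_rows <- list()
    complex_ids <- character(0)

    for (f in seq_len(n_families)) {
      fid <- sprintf("fam%04d", f)
      gene <- c(zebrafish = sprintf("zeb_%s", fid),
                pguichenoti = sprintf("pg_%s", fid),
                ptetrazona = sprintf("pt_%s", fid),
                carpB = sprintf("cc_%s_1", fid),
                goldfishB = sprintf("gf_%s_1", fid),
                carpA = sprintf("cc_%s_2", fid),
                goldfishA = sprintf("gf_%s_2", fid))

      root <- .random_root_codons(n_codons)
      n_root <- .evolve_codons(root, bl$root_in)      # ancestor of Pg+ingroup
      seq_zeb <- .evolve_codons(root, bl$zeb_tip)
      seq_pg <- .evolve_codons(n_root, bl$pg_tip)
      n_ab <- .evolve_codons(n_root, bl$pg_in)        # A/B split
      n_ptb <- .evolve_codons(n_ab, bl$ab_to_ptb)     # (Pt, B-pair) node
      n_a <- .evolve_codons(n_ab, bl$ab_to_a)         # A-pair node
      seq_pt <- .evolve_codons(n_ptb, bl$pt_tip)
      n_b <- .evolve_codons(n_ptb, bl$ptb_to_b)       # B-pair node
      seq_ccb <- .evolve_codons(n_b, bl$b_tip)
      seq_gfb <- .evolve_codons(n_b, bl$b_tip)
      seq_cca <- .evolve_codons(n_a, bl$a_tip)
      seq_gfa <- .evolve_codons(n_a, bl$a_tip)

      seqs <- list(seq_zeb, seq_pg, seq_pt, seq_ccb, seq_gfb,
                   seq_cca, seq_gfa)
      names(seqs) <- unname(gene[tips])
      seqs <- vapply(seqs, paste0, "", collapse = "")

      leaf <- c(zebrafish = sprintf("zebrafish|%s", gene[["zebrafish"]]),
                pguichenoti = sprintf("pguichenoti|%s", gene[["pguichenoti"]]),
                ptetrazona = sprintf("ptetrazona|%s", gene[["ptetrazona"]]),
                carpB = sprintf("carp|%s", gene[["carpB"]]),
                goldfishB = sprintf("goldfish|%s", gene[["goldfishB"]]),
                carpA = sprintf("carp|%s", gene[["carpA"]]),
                goldfishA = sprintf("goldfish|%s", gene[["goldfishA"]]))

      is_complex <- stats::runif(1) < topology_noise
      if (!is_complex) {
        nwk <- sprintf("(%s:%g,(%s:%g,((%s:%g,(%s:%g,%s:%g)95:%g)90:%g,(%s:%g,%s:%g)92:%g)88:%g)85:%g);",
                       leaf[["zebrafish"]], bl$zeb_tip,
                       leaf[["pguichenoti"]], bl$pg_tip,
                       leaf[["ptetrazona"]], bl$pt_tip,
                       leaf[["carpB"]], bl$b_tip,
                       leaf[["goldfishB"]], bl$b_tip, bl$ptb_to_b,
                       bl$ab_to_ptb,
                       leaf[["carpA"]], bl$a_tip,
                       leaf[["goldfishA"]], bl$a_tip, bl$ab_to_a,
                       bl$pg_in, bl$root_in)
      } else {
        # both carp copies sister to each other inside the Pt clade:
        # violates the one-copy-per-tetraploid rule -> complex
        nwk <- sprintf("(%s:%g,(%s:%g,((%s:%g,((%s:%g,%s:%g)70:%g,%s:%g)60:%g)55:%g,%s:%g)50:%g)85:%g);",
                       leaf[["zebrafish"]], bl$zeb_tip,
                       leaf[["pguichenoti"]], bl$pg_tip,
                       leaf[["ptetrazona"]], bl$pt_tip,
                       leaf[["carpB"]], bl$b_tip,
                       leaf[["carpA"]], bl$b_tip, bl$ptb_to_b / 2,
                       leaf[["goldfishB"]], bl$b_tip, bl$ptb_to_b / 2,
                       bl$ab_to_ptb,
                       leaf[["goldfishA"]], ks_spec[["ccA_gfA"]] / 2,
                       bl$pg_in, bl$root_in)
        complex_ids <- c(complex_ids, fid)
      }

      families[[f]] <- list(family_id = fid, sequences = seqs,
                            tree = read_newick(nwk), newick = nwk)
      labels_rows[[f]] <- data.frame(
        family_id = fid,
        gene_id = unname(gene[c("carpB", "carpA", "goldfishB", "goldfishA")]),
        species = c("carp", "carp", "goldfish", "goldfish"),
        label = c("subB", "subA", "subB", "subA"),
        stringsAsFactors = FALSE)
    }

    labels <- do.call(rbind, labels_rows)

    # gene locations: 25 homoeologous chromosome pairs per tetraploid;
    # subA genes live on A chromosomes, subB genes on B chromosomes,
    # except planted HE genes, which sit on the partner chromosome.
    loc_rows <- list()
    pairs_by_species <- list()
    he_genes <- character(0)
    for (sp in c("carp", "goldfish")) {
      pre <- if (sp == "carp") "cc" else "gf"
      pairs <- data.frame(
        chrom1 = sprintf("%s_A%02d", pre, 1:25),
        chrom2 = sprintf("%s_B%02d", pre, 1:25),
        stringsAsFactors = FALSE)
      pairs_by_species[[sp]] <- pairs
      sub <- labels[labels$species == sp, , drop = FALSE]
      pair_idx <- sample(rep_len(1:25, nrow(sub) / 2))
      # one pair index per family, shared by the two homoeologs
      fam_pair <- setNames(pair_idx, unique(sub$family_id))
      chrom <- ifelse(sub$label == "subA",
                      sprintf("%s_A%02d", pre, fam_pair[sub$family_id]),
                      sprintf("%s_B%02d", pre, fam_pair[sub$family_id]))
      is_he <- stats::runif(nrow(sub)) < he_rate
      partner <- ifelse(sub$label == "subA",
                        sprintf("%s_B%02d", pre, fam_pair[sub$family_id]),
                        sprintf("%s_A%02d", pre, fam_pair[sub$family_id]))
      chrom[is_he] <- partner[is_he]
      he_genes <- c(he_genes, sub$gene_id[is_he])
      start <- sample.int(3e7, nrow(sub))
      loc_rows[[sp]] <- data.frame(
        gene_id = sub$gene_id, species = sp, chromosome = chrom,
        start = start, end = start + 3L * n_codons,
        strand = sample(c("+", "-"), nrow(sub), replace = TRUE),
        stringsAsFactors = FALSE)
    }
    locations <- do.call(rbind, loc_rows)
    rownames(locations) <- NULL

    list(families = families,
         locations = locations,
         homoeolog_pairs = pairs_by_species,
         truth = list(labels = labels,
                      he_genes = sort(he_genes),
                      complex_families = complex_ids,
                      ks_spec = ks_spec,
                      he_rate = he_rate,
                      topology_noise = topology_noise,
                      seed = seed))
  })
}

#' Write heptad simulation outputs to disk
#'
#' Emits one FASTA codon alignment and one newick per family, a gene
#' location TSV and the truth record as JSON.
#'
#' @param sim output of [simulate_heptad_families()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_heptad_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (fam in sim$families) {
    fa <- file.path(dir, paste0(fam$family_id, ".fasta"))
    con <- file(fa, "w")
    for (g in names(fam$sequences)) {
      writeLines(c(paste0(">", g), fam$sequences[[g]]), con)
    }
    close(con)
    writeLines(fam$newick, file.path(dir, paste0(fam$family_id, ".nwk")))
  }
  utils::write.table(sim$locations, file.path(dir, "locations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
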