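## Subgenome assignment of tetraploid gene copies from gene-tree
## topologies, chromosome-level assignment by majority vote, and
## homoeologous-exchange (HE) detection/validation.

#' Classify a heptad gene tree as canonical or complex
#'
#' A heptad family carries one gene from each diploid (zebrafish,
#' P. guichenoti, P. tetrazona) and two genes from each tetraploid (carp,
#' goldfish).  After rooting on zebrafish, the family is canonical when
#' some clade contains exactly the P. tetrazona gene, one carp gene and
#' one goldfish gene, and its sister clade contains exactly the other
#' carp and goldfish genes.  Members of the P. tetrazona clade are the
#' subB copies (phylogenetically closer to the progenitor-like diploid);
#' the sister pair are the subA copies.
#'
#' @param tree a `phylo` with 7 leaves labelled `"species|gene"`.
#' @param min_support optional integer; when given, the supports (integer
#'   node labels) of the two clades defining the split must both be at
#'   least `min_support` for `min_support_ok` to be TRUE.
#' @return an object of class `heptad_classification`: list with
#'   `status` ("canonical"/"complex"), `carp_subA_gene`, `carp_subB_gene`,
#'   `goldfish_subA_gene`, `goldfish_subB_gene` (NA when complex) and
#'   `min_support_ok`.
#' @export
classify_heptad_topology <- function(tree, min_support = NULL) {
  if (!inherits(tree, "phylo")) stopf("tree must be a 'phylo' object")
  if (length(tree$tip.label) != 7L)
    stopf("heptad tree must have exactly 7 leaves, got %d",
          length(tree$tip.label))
  info <- split_leaf_labels(tree$tip.label)
  census <- table(factor(info$species, levels = allokit_species_tags))
  expected <- c(zebrafish = 1L, pguichenoti = 1L, ptetrazona = 1L,
                carp = 2L, goldfish = 2L)
  if (!all(census[names(expected)] == expected))
    stopf("leaf census is not 1:1:1:2:2 (zebrafish, pguichenoti, ptetrazona, carp x2, goldfish x2)")

  zeb <- info$label[info$species == "zebrafish"]

  # supports keyed by bipartition (ape::root() does not keep node labels
  # attached to their clades, so look them up on the original tree)
  support_map <- new.env(parent = emptyenv())
  if (!is.null(tree$node.label)) {
    nt0 <- length(tree$tip.label)
    desc0 <- vector("list", nt0 + tree$Nnode)
    for (i in seq_len(nt0)) desc0[[i]] <- i
    for (e in ape::postorder(tree)) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      desc0[[p]] <- c(desc0[[p]], desc0[[ch]])
    }
    for (nd in (nt0 + 1L):(nt0 + tree$Nnode)) {
      lab <- suppressWarnings(as.numeric(tree$node.label[nd - nt0]))
      if (is.na(lab)) next
      tips <- sort(tree$tip.label[desc0[[nd]]])
      support_map[[paste(tips, collapse = ";")]] <- lab
      support_map[[paste(sort(setdiff(tree$tip.label, tips)),
                         collapse = ";")]] <- lab
    }
  }

  tr <- ape::root(tree, outgroup = zeb, resolve.root = TRUE)

  n_tip <- length(tr$tip.label)
  tip_species <- split_leaf_labels(tr$tip.label)$species
  # tip sets per internal node
  desc <- vector("list", n_tip + tr$Nnode)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  for (e in ape::postorder(tr)) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }

  support_of <- function(node) {
    key <- paste(sort(tr$tip.label[desc[[node]]]), collapse = ";")
    val <- support_map[[key]]
    if (is.null(val)) NA_real_ else val
  }

  result <- NULL
  internal <- (n_tip + 1L):(n_tip + tr$Nnode)
  for (node in internal) {
    tips <- desc[[node]]
    sp <- tip_species[tips]
    if (length(tips) != 3L) next
    if (sum(sp == "ptetrazona") != 1L || sum(sp == "carp") != 1L ||
        sum(sp == "goldfish") != 1L) next
    # sister clade of this node
    parent <- tr$edge[tr$edge[, 2] == node, 1]
    if (!length(parent)) next
    sibs <- setdiff(tr$edge[tr$edge[, 1] == parent, 2], node)
    for (sib in sibs) {
      stips <- desc[[sib]]
      ssp <- tip_species[stips]
      if (length(stips) == 2L && sum(ssp == "carp") == 1L &&
          sum(ssp == "goldfish") == 1L) {
        result <- list(b_node = node, a_node = sib,
                       b_tips = tips, a_tips = stips)
        break
      }
    }
    if (!is.null(result)) break
  }

  gene_of <- function(tips, species) {
    lab <- tr$tip.label[tips][tip_species[tips] == species]
    split_leaf_labels(lab)$gene_id
  }

  if (is.null(result)) {
    out <- list(status = "complex",
                carp_subA_gene = NA_character_,
                carp_subB_gene = NA_character_,
                goldfish_subA_gene = NA_character_,
                goldfish_subB_gene = NA_character_,
                min_support_ok = NA)
  } else {
    ok <- NA
    if (!is.null(min_support)) {
      s_b <- support_of(result$b_node)
      # the subA pair is a clade only if it is internal; a 2-tip sister is
      # always an internal node here
      s_a <- if (result$a_node > n_tip) support_of(result$a_node) else NA
      ok <- isTRUE(s_b >= min_support) && isTRUE(s_a >= min_support)
    }
    out <- list(status = "canonical",
                carp_subA_gene = gene_of(result$a_tips, "carp"),
                carp_subB_gene = gene_of(result$b_tips, "carp"),
                goldfish_subA_gene = gene_of(result$a_tips, "goldfish"),
                goldfish_subB_gene = gene_of(result$b_tips, "goldfish"),
                min_support_ok = ok)
  }
  class(out) <- "heptad_classification"
  out
}

#' Per-gene subgenome labels from a set of heptad classifications
#'
#' @param classifications list of `heptad_classification` objects (or a
#'   list as returned by [simulate_heptad_families()]' classification step).
#' @param species `"carp"` or `"goldfish"`.
#' @return data.frame with `gene_id`, `label` ("subA"/"subB") for genes
#'   in canonical families.
#' @export
subgenome_gene_labels <- function(classifications,
                                  species = c("carp", "goldfish")) {
  species <- match.arg(species)
  rows <- lapply(classifications, function(cl) {
    if (cl$status != "canonical") return(NULL)
    if (species == "carp") {
      data.frame(gene_id = c(cl$carp_subA_gene, cl$carp_subB_gene),
                 label = c("subA", "subB"), stringsAsFactors = FALSE)
    } else {
      data.frame(gene_id = c(cl$goldfish_subA_gene, cl$goldfish_subB_gene),
                 label = c("subA", "subB"), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), label = character(),
                      stringsAsFactors = FALSE)
  out
}

#' Assign tetraploid chromosomes to subgenomes by majority vote
#'
#' A chromosome encoding more subB than subA labelled genes belongs to the
#' B subgenome, and vice versa.  When `homoeolog_pairs` is supplied, the
#' 25-pair structure is enforced: a tied chromosome takes the complement
#' of its partner, and if both members of a pair get the same majority
#' label the member with the smaller margin is flipped (flagged
#' `tie_broken`).
#'
#' @param labels data.frame with `gene_id`, `label` (from
#'   [subgenome_gene_labels()]).
#' @param locations data.frame with `gene_id`, `chromosome` (genes on
#'   `"scaffold:*"` chromosomes are ignored here).
#' @param homoeolog_pairs optional data.frame with `chrom1`, `chrom2`.
#' @return data.frame with `chromosome`, `subgenome` ("A"/"B"/NA),
#'   `subA_count`, `subB_count`, `tie_broken`.
#' @export
assign_chromosome_subgenomes <- function(labels, locations,
                                         homoeolog_pairs = NULL) {
  loc <- locations[!startsWith(locations$chromosome, "scaffold:"), ,
                   drop = FALSE]
  m <- merge(labels, loc[, c("gene_id", "chromosome")], by = "gene_id")
  if (nrow(m) == 0L) stopf("no labelled genes on anchored chromosomes")
  tab <- table(m$chromosome, factor(m$label, levels = c("subA", "subB")))
  out <- data.frame(chromosome = rownames(tab),
                    subA_count = as.integer(tab[, "subA"]),
                    subB_count = as.integer(tab[, "subB"]),
                    stringsAsFactors = FALSE)
  out$margin <- out$subB_count - out$subA_count
  out$subgenome <- ifelse(out$margin > 0, "B",
                          ifelse(out$margin < 0, "A", NA))
  out$tie_broken <- FALSE

  if (!is.null(homoeolog_pairs)) {
    for (i in seq_len(nrow(homoeolog_pairs))) {
      c1 <- homoeolog_pairs$chrom1[i]
      c2 <- homoeolog_pairs$chrom2[i]
      i1 <- match(c1, out$chromosome)
      i2 <- match(c2, out$chromosome)
      if (is.na(i1) || is.na(i2)) next
      s1 <- out$subgenome[i1]; s2 <- out$subgenome[i2]
      flip <- function(s) if (identical(s, "A")) "B" else "A"
      if (is.na(s1) && is.na(s2)) {
        out$subgenome[c(i1, i2)] <- c("A", "B")
        out$tie_broken[c(i1, i2)] <- TRUE
      } else if (is.na(s1)) {
        out$subgenome[i1] <- flip(s2); out$tie_broken[i1] <- TRUE
      } else if (is.na(s2)) {
        out$subgenome[i2] <- flip(s1); out$tie_broken[i2] <- TRUE
      } else if (s1 == s2) {
        weak <- if (abs(out$margin[i1]) <= abs(out$margin[i2])) i1 else i2
        out$subgenome[weak] <- flip(s1)
        out$tie_broken[weak] <- TRUE
      }
    }
  }
  if (anyNA(out$subgenome))
    warning(sum(is.na(out$subgenome)),
            " chromosome(s) tied with no pairing information; left unassigned")
  out$margin <- NULL
  out[, c("chromosome", "subgenome", "subA_count", "subB_count",
          "tie_broken")]
}

#' Detect homoeologous exchanges from label/host disagreement
#'
#' A labelled gene hosted on a chromosome assigned to the other subgenome
#' is an HE event (subA gene on a B chromosome or subB gene on an A
#' chromosome).  Scaffold-hosted genes and genes with no location are
#' excluded and counted.
#'
#' @param labels data.frame with `gene_id`, `label`.
#' @param locations data.frame with `gene_id`, `chromosome`.
#' @param assignments data.frame from [assign_chromosome_subgenomes()].
#' @return list with `events` (data.frame: `gene_id`, `label`,
#'   `host_chromosome`, `host_subgenome`), `n_scaffold_excluded`,
#'   `n_missing_location`, `n_tested`.
#' @export
detect_homoeologous_exchanges <- function(labels, locations, assignments) {
  loc <- locations[, c("gene_id", "chromosome")]
  m <- merge(labels, loc, by = "gene_id", all.x = TRUE)
  n_missing <- sum(is.na(m$chromosome))
  m <- m[!is.na(m$chromosome), , drop = FALSE]
  scaff <- startsWith(m$chromosome, "scaffold:")
  n_scaffold <- sum(scaff)
  m <- m[!scaff, , drop = FALSE]
  m$host_subgenome <- assignments$subgenome[
    match(m$chromosome, assignments$chromosome)]
  m <- m[!is.na(m$host_subgenome), , drop = FALSE]
  label_sub <- ifelse(m$label == "subA", "A", "B")
  ev <- m[label_sub != m$host_subgenome, , drop = FALSE]
  events <- data.frame(gene_id = ev$gene_id, label = ev$label,
                       host_chromosome = ev$chromosome,
                       host_subgenome = ev$host_subgenome,
                       stringsAsFactors = FALSE)
  rownames(events) <- NULL
  list(events = events, n_scaffold_excluded = n_scaffold,
       n_missing_location = n_missing, n_tested = nrow(m))
}

#' Validate HE events by progenitor read-coverage bias
#'
#' Exchanged subB genes on A chromosomes should attract more
#' progenitor-like (P. tetrazona) genomic reads than the hosted subA
#' genes around them, and conversely for exchanged subA genes.  Counts
#' should be normalised (e.g. per kb of gene length) before testing.
#'
#' @param exchanged_counts,hosted_counts numeric vectors of normalised
#'   read counts.
#' @param direction `"exchanged_higher"` or `"exchanged_lower"`.
#' @param alpha significance level (default 0.05).
#' @return list with `p_value`, `validated`, `status` ("tested" or
#'   "untested" when a group is empty).
#' @export
validate_he_read_bias <- function(exchanged_counts, hosted_counts,
                                  direction = c("exchanged_higher",
                                                "exchanged_lower"),
                                  alpha = 0.05) {
  direction <- match.arg(direction)
  if (!length(exchanged_counts) || !length(hosted_counts))
    return(list(p_value = NA_real_, validated = NA, status = "untested"))
  alt <- if (direction == "exchanged_higher") "greater" else "less"
  wt <- suppressWarnings(
    stats::wilcox.test(exchanged_counts, hosted_counts,
                       alternative = alt))
  list(p_value = wt$p.value, validated = wt$p.value <= alpha,
       status = "tested")
}

#' Region-level HE calls from windowed homoeologous depth ratios
#'
#' Given per-window read depths over paired homoeologous regions, computes
#' `log2(depth_A / depth_B)` and calls an HE window when the log-ratio is
#' inverted relative to the chromosome-wide median by more than 1 (i.e. a
#' two-fold swing across the median).
#'
#' @param depth_a,depth_b positive per-window depths of the A and B copies.
#' @return data.frame with `log2_ratio`, `median_log2_ratio`, `he_call`.
#' @export
detect_he_regions <- function(depth_a, depth_b) {
  stopifnot(length(depth_a) == length(depth_b))
  lr <- log2(depth_a / depth_b)
  med <- stats::median(lr, na.rm = TRUE)
  he <- sign(lr) == -sign(med) & abs(lr - med) > 1
  he[is.na(he)] <- FALSE
  data.frame(log2_ratio = lr, median_log2_ratio = med, he_call = he)
}
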