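## Ancestral-region (AR) calling from multi-genome alignment blocks,
## rearrangement and retention/loss accounting, and Dollo parsimony of
## gene-family losses on a species tree.

#' Call ancestral regions from alignment blocks
#'
#' A block becomes an AR when it is longer than 1 kb and at least
#' `min_support` rows map (through the homoeolog map) to one ancestral
#' chromosome.  The AR orientation is the strand with more sequence
#' support among the agreeing rows; an exact tie goes to "+" with
#' `orientation_tie = TRUE`.
#'
#' @param blocks list of alignment blocks ([read_maf_blocks()]).
#' @param homoeolog_map data.frame with `genome_id`, `chromosome`,
#'   `ancestral_chromosome`.
#' @param min_length minimum block length in bp (default 1000,
#'   exclusive).
#' @param min_support minimum number of agreeing genome rows (default 4).
#' @return data.frame of ARs: `ar_id`, `block_id`,
#'   `ancestral_chromosome`, `orientation`, `n_support`, `length`,
#'   `orientation_tie`, with the supporting rows in the list column
#'   `rows`.
#' @export
call_ancestral_regions <- function(blocks, homoeolog_map,
                                   min_length = 1000, min_support = 4) {
  map_key <- paste0(homoeolog_map$genome_id, ".", homoeolog_map$chromosome)
  ars <- list()
  for (b in blocks) {
    key <- paste0(b$rows$genome_id, ".", b$rows$chromosome)
    anc <- homoeolog_map$ancestral_chromosome[match(key, map_key)]
    if (anyNA(anc)) {
      warning("block ", b$block_id,
              ": unmapped chromosome, block skipped")
      next
    }
    if (b$length <= min_length) next
    tab <- sort(table(anc), decreasing = TRUE)
    if (tab[1] < min_support) next
    anc_chr <- names(tab)[1]
    support <- b$rows[anc == anc_chr, , drop = FALSE]
    n_plus <- sum(support$strand == "+")
    n_minus <- sum(support$strand == "-")
    ars[[length(ars) + 1L]] <- data.frame(
      ar_id = sprintf("AR_%s", b$block_id),
      block_id = b$block_id,
      ancestral_chromosome = anc_chr,
      orientation = if (n_plus >= n_minus) "+" else "-",
      n_support = as.integer(tab[1]),
      length = b$length,
      orientation_tie = n_plus == n_minus,
      rows = I(list(b$rows)),
      stringsAsFactors = FALSE)
  }
  if (!length(ars))
    return(data.frame(ar_id = character(), block_id = character(),
                      ancestral_chromosome = character(),
                      orientation = character(), n_support = integer(),
                      length = numeric(), orientation_tie = logical()))
  out <- do.call(rbind, ars)
  rownames(out) <- NULL
  out
}

#' Translocation and inversion fractions for one genome
#'
#' Over ARs containing a row for `genome_id`: the translocated fraction
#' is the share whose row maps to an ancestral chromosome different from
#' the AR's; the inverted fraction is computed over the non-translocated
#' ARs as the share whose row strand opposes the AR orientation.
#'
#' @param ars AR data.frame from [call_ancestral_regions()].
#' @param genome_id genome to summarise.
#' @param homoeolog_map as in [call_ancestral_regions()].
#' @return list with `genome_id`, `n_ars`, `n_translocated`,
#'   `translocated_fraction`, `n_inverted`, `inverted_fraction`.
#' @export
rearrangement_fractions <- function(ars, genome_id, homoeolog_map) {
  map_key <- paste0(homoeolog_map$genome_id, ".", homoeolog_map$chromosome)
  n <- 0L; n_tl <- 0L; n_iv <- 0L; n_not_tl <- 0L
  for (i in seq_len(nrow(ars))) {
    rows <- ars$rows[[i]]
    r <- rows[rows$genome_id == genome_id, , drop = FALSE]
    if (!nrow(r)) next
    r <- r[1, ]
    n <- n + 1L
    anc <- homoeolog_map$ancestral_chromosome[
      match(paste0(r$genome_id, ".", r$chromosome), map_key)]
    if (!identical(anc, ars$ancestral_chromosome[i])) {
      n_tl <- n_tl + 1L
    } else {
      n_not_tl <- n_not_tl + 1L
      if (r$strand != ars$orientation[i]) n_iv <- n_iv + 1L
    }
  }
  if (n == 0L) stopf("genome '%s' absent from all ARs", genome_id)
  list(genome_id = genome_id, n_ars = n,
       n_translocated = n_tl, translocated_fraction = n_tl / n,
       n_inverted = n_iv,
       inverted_fraction = if (n_not_tl > 0) n_iv / n_not_tl else NA_real_)
}

#' Per-Mb AR retention and loss for one genome
#'
#' Retained loci are the universe members present among the genome's
#' ARs; lost loci are the universe members absent.  Both are divided by
#' the subgenome size in Mb.
#'
#' @param ars AR data.frame (or a character vector of retained locus
#'   ids).
#' @param genome_id genome to summarise (ignored when `ars` is already a
#'   vector of locus ids).
#' @param subgenome_size size in Mb (> 0).
#' @param universe character vector of all ancestral AR locus ids.
#' @return list with `retained`, `lost`, `retained_per_mb`,
#'   `lost_per_mb`.
#' @export
retention_loss_per_mb <- function(ars, genome_id, subgenome_size,
                                  universe) {
  if (subgenome_size <= 0) stopf("subgenome size must be positive")
  present <- if (is.character(ars)) ars else {
    has_row <- vapply(ars$rows, function(r) genome_id %in% r$genome_id,
                      TRUE)
    ars$ar_id[has_row]
  }
  retained <- sum(universe %in% present)
  lost <- length(universe) - retained
  list(retained = retained, lost = lost,
       retained_per_mb = retained / subgenome_size,
       lost_per_mb = lost / subgenome_size)
}

#' Chi-square comparison of two genomes' retained/lost contingency
#'
#' 2x2 chi-square with continuity correction.
#'
#' @param retained1,lost1,retained2,lost2 counts.
#' @return list with `chisq`, `p_value`.
#' @export
retention_loss_chisq <- function(retained1, lost1, retained2, lost2) {
  tab <- rbind(c(retained1, lost1), c(retained2, lost2))
  if (identical(tab[1, ], tab[2, ]))
    return(list(chisq = 0, p_value = 1))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(chisq = unname(ct$statistic), p_value = ct$p.value)
}

# named branches of a rooted tree: one branch per non-root node, named by
# the tip label for terminal branches and by "node_<k>" (or the node
# label) for internal ones
.branch_names <- function(tree) {
  n_tip <- length(tree$tip.label)
  nm <- character(n_tip + tree$Nnode)
  nm[seq_len(n_tip)] <- tree$tip.label
  for (k in seq_len(tree$Nnode)) {
    lab <- if (!is.null(tree$node.label) && nzchar(tree$node.label[k]))
      tree$node.label[k] else sprintf("node_%d", n_tip + k)
    nm[n_tip + k] <- lab
  }
  nm
}

#' Dollo-parsimony gene-family losses on a species tree
#'
#' Each family originates once, at the most recent common ancestor of
#' the taxa containing it; losses are the minimal set of branches below
#' that origin whose removal explains all absences (the maximal
#' all-absent subtrees).  Returns loss counts per branch (named by the
#' child node) and retained family counts per taxon.
#'
#' @param presence logical matrix, families x taxa (every family present
#'   in at least one taxon).
#' @param tree rooted `phylo` whose tip labels are the taxa (columns).
#' @return list with `branch_losses` (named integer vector over
#'   branches), `retained_per_taxon`, `origin_node` per family.
#' @export
dollo_branch_losses <- function(presence, tree) {
  if (is.data.frame(presence)) presence <- as.matrix(presence)
  storage.mode(presence) <- "logical"
  if (any(rowSums(presence) == 0L))
    stopf("family absent from every taxon violates the presence invariant")
  taxa <- colnames(presence)
  if (!setequal(taxa, tree$tip.label))
    stopf("presence columns and tree tips differ")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  # descendant-tip sets per node (tip indices in tree numbering)
  desc <- vector("list", n_node)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  parent <- integer(n_node)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  tip_index <- match(tree$tip.label, taxa)
  inside <- function(nd, org) all(desc[[nd]] %in% desc[[org]])

  losses <- setNames(integer(n_node), .branch_names(tree))
  origin <- integer(nrow(presence))

  for (f in seq_len(nrow(presence))) {
    pres_tips <- which(presence[f, tip_index])  # tree tip numbering
    covers <- vapply(desc, function(d) all(pres_tips %in% d), TRUE)
    org <- which(covers)[which.min(lengths(desc)[covers])]
    origin[f] <- org
    absent <- !vapply(desc, function(d) any(d %in% pres_tips), TRUE)
    # loss edges: all-absent nodes inside the origin subtree whose
    # parent subtree still contains a presence
    for (nd in which(absent)) {
      if (nd == org || parent[nd] == 0L || !inside(nd, org)) next
      if (!absent[parent[nd]]) losses[nd] <- losses[nd] + 1L
    }
  }
  retained <- colSums(presence[, taxa[tip_index], drop = FALSE])
  names(retained) <- tree$tip.label
  list(branch_losses = losses,
       retained_per_taxon = retained,
       origin_node = origin)
}
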