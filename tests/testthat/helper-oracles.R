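# Independent brute-force oracles used to check the package's
# implementations on small inputs.  These deliberately re-derive every
# quantity from first principles rather than calling the code under test.

GC_TABLE <- Biostrings::GENETIC_CODE
NTS <- c("A", "C", "G", "T")

translate1 <- function(codon) unname(GC_TABLE[codon])

# --- NG86 oracle -----------------------------------------------------

# synonymous site count of one codon: per position, the synonymous share
# of its non-stop single-nucleotide mutations
oracle_syn_sites <- function(codon) {
  total <- 0
  for (pos in 1:3) {
    syn <- 0; nonstop <- 0
    for (nt in setdiff(NTS, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (translate1(mut) == "*") next
      nonstop <- nonstop + 1
      if (translate1(mut) == translate1(codon)) syn <- syn + 1
    }
    if (nonstop > 0) total <- total + syn / nonstop
  }
  total
}

# all minimal mutational pathways between two codons, as a recursive
# depth-first search over the remaining differing positions
oracle_pair_diffs <- function(c1, c2) {
  paths <- list()
  walk <- function(cur, remaining, sd, nd, through_stop) {
    if (!length(remaining)) {
      paths[[length(paths) + 1L]] <<- c(sd, nd, through_stop)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      syn <- translate1(nxt) == translate1(cur)
      walk(nxt, setdiff(remaining, p),
           sd + syn, nd + !syn,
           through_stop || translate1(nxt) == "*")
    }
  }
  diffpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(diffpos)) return(c(sd = 0, nd = 0))
  walk(c1, diffpos, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  ok <- m[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(m))
  c(sd = mean(m[ok, 1]), nd = mean(m[ok, 2]))
}

# full NG86 counts for a gap-free codon alignment
oracle_ng86_counts <- function(seq1, seq2) {
  n <- nchar(seq1) / 3
  starts <- 3 * seq_len(n) - 2
  c1 <- substring(seq1, starts, starts + 2)
  c2 <- substring(seq2, starts, starts + 2)
  S <- (sum(vapply(c1, oracle_syn_sites, 0)) +
          sum(vapply(c2, oracle_syn_sites, 0))) / 2
  d <- mapply(function(a, b) oracle_pair_diffs(a, b), c1, c2)
  list(S = S, N = 3 * n - S, Sd = sum(d["sd", ]), Nd = sum(d["nd", ]))
}

# random stop-free codon sequence and a mutated partner
random_codon_seq <- function(n_codons) {
  ok <- names(GC_TABLE)[GC_TABLE != "*"]
  paste0(sample(ok, n_codons, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, n_mut) {
  v <- strsplit(s, "")[[1]]
  for (k in seq_len(n_mut)) {
    repeat {
      i <- sample.int(length(v), 1)
      nt <- sample(setdiff(NTS, v[i]), 1)
      w <- v
      w[i] <- nt
      cod <- ceiling(i / 3)
      codon <- paste0(w[(3 * cod - 2):(3 * cod)], collapse = "")
      if (translate1(codon) != "*") { v <- w; break }
    }
  }
  paste0(v, collapse = "")
}

# --- rooted-binary tree enumeration ---------------------------------

# all rooted binary labelled trees on the given labels, as newick strings
# (built by inserting each next leaf above every node of every partial
# tree; counts follow the double factorial (2n-3)!!)
enumerate_rooted_trees <- function(labels) {
  insert_above <- function(tree, leaf) {
    if (is.character(tree)) {
      return(list(list(tree, leaf)))
    }
    out <- list(list(tree, leaf))                 # above the root
    for (side in 1:2) {
      for (sub in insert_above(tree[[side]], leaf)) {
        t2 <- tree
        t2[[side]] <- sub
        out[[length(out) + 1L]] <- t2
      }
    }
    out
  }
  trees <- list(labels[[1]])
  for (lab in labels[-1]) {
    trees <- unlist(lapply(trees, insert_above, leaf = lab),
                    recursive = FALSE)
  }
  to_newick <- function(tree) {
    if (is.character(tree)) return(tree)
    paste0("(", to_newick(tree[[1]]), ",", to_newick(tree[[2]]), ")")
  }
  vapply(trees, function(t) paste0(to_newick(t), ";"), "")
}

# clade-membership brute force: canonical iff some clade holds exactly
# {Pt, one carp, one goldfish}, the remaining carp+goldfish pair is a
# clade, and their union is a clade (sisterhood)
oracle_is_canonical <- function(tree) {
  zeb <- grep("^zebrafish", tree$tip.label, value = TRUE)
  tr <- ape::root(tree, outgroup = zeb, resolve.root = TRUE)
  pp <- ape::prop.part(tr)
  clades <- lapply(pp, function(i) sort(tr$tip.label[i]))
  clades <- c(clades, as.list(tr$tip.label))
  has_clade <- function(x) any(vapply(clades, identical, TRUE,
                                      y = sort(x)))
  pt <- grep("^ptetrazona", tr$tip.label, value = TRUE)
  cc <- grep("^carp", tr$tip.label, value = TRUE)
  gf <- grep("^goldfish", tr$tip.label, value = TRUE)
  for (ci in 1:2) for (gi in 1:2) {
    b_set <- c(pt, cc[ci], gf[gi])
    a_set <- c(cc[-ci], gf[-gi])
    if (has_clade(b_set) && has_clade(a_set) &&
        has_clade(c(b_set, a_set))) return(TRUE)
  }
  FALSE
}

# --- Dollo exhaustive minimal-loss search ---------------------------

# minimal number of loss branches (subtree deletions below the origin)
# explaining a presence pattern, by scanning all branch subsets
oracle_dollo_losses <- function(presence_row, tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  desc <- vector("list", n_node)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  pres <- which(presence_row[tree$tip.label])
  covers <- vapply(desc, function(d) all(pres %in% d), TRUE)
  org <- which(covers)[which.min(lengths(desc)[covers])]
  in_org <- desc[[org]]
  absent_tips <- setdiff(in_org, pres)
  if (!length(absent_tips)) return(0L)
  # candidate loss branches: nodes strictly inside the origin subtree
  cand <- setdiff(which(vapply(desc, function(d) all(d %in% in_org),
                               TRUE)), org)
  masks <- vapply(cand, function(nd)
    sum(bitwShiftL(1L, desc[[nd]] - 1L)), 0)
  target <- sum(bitwShiftL(1L, absent_tips - 1L))
  best <- Inf
  for (sz in seq_along(cand)) {
    combs <- utils::combn(seq_along(cand), sz)
    for (k in seq_len(ncol(combs))) {
      u <- Reduce(bitwOr, masks[combs[, k]], 0L)
      if (u == target) { best <- sz; break }
    }
    if (is.finite(best)) break
  }
  as.integer(best)
}

# --- diversity oracle -----------------------------------------------

# pi and theta_w by explicit averaging over haplotype pairs
oracle_pi_theta <- function(haplotypes, length_bp) {
  n <- nrow(haplotypes)
  pairs <- utils::combn(n, 2)
  diffs <- apply(pairs, 2, function(ij)
    sum(haplotypes[ij[1], ] != haplotypes[ij[2], ]))
  seg <- sum(apply(haplotypes, 2, function(col) length(unique(col)) > 1))
  a_n <- sum(1 / seq_len(n - 1))
  list(pi = mean(diffs) / length_bp,
       theta_w = seg / a_n / length_bp,
       S = seg)
}

# haplotypes -> genotype_matrix (consecutive rows paired into diploids)
haps_to_gm <- function(haplotypes, positions, chromosome = "chr1",
                       pop = NULL) {
  n_dip <- nrow(haplotypes) / 2
  dos <- haplotypes[seq(1, nrow(haplotypes), 2), , drop = FALSE] +
    haplotypes[seq(2, nrow(haplotypes), 2), , drop = FALSE]
  dos <- t(dos)
  samples <- sprintf("s%02d", seq_len(n_dip))
  colnames(dos) <- samples
  genotype_matrix(samples,
                  data.frame(chromosome = chromosome,
                             position = positions, ref = "A", alt = "G",
                             stringsAsFactors = FALSE),
                  dos,
                  population_of = if (is.null(pop)) NULL else
                    setNames(rep(pop, n_dip), samples))
}
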