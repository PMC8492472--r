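## Codon bookkeeping shared by the NG86 estimator and the heptad sequence
## simulator.  Tables are built once per session and cached.

.codon_env <- new.env(parent = emptyenv())

NUCS <- c("T", "C", "A", "G")

#' All 64 codons in TCAG order
#' @keywords internal
all_codons <- function() {
  if (!is.null(.codon_env$codons)) return(.codon_env$codons)
  g <- expand.grid(p3 = NUCS, p2 = NUCS, p1 = NUCS,
                   stringsAsFactors = FALSE)
  .codon_env$codons <- paste0(g$p1, g$p2, g$p3)
  .codon_env$codons
}

#' Amino acid translation of a codon vector (stops as "*")
#' @keywords internal
codon_aa <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Single-nucleotide neighbours of one codon
#' @keywords internal
codon_neighbours <- function(codon) {
  out <- character(0)
  for (pos in 1:3) {
    for (n in setdiff(NUCS, substr(codon, pos, pos))) {
      nb <- codon
      substr(nb, pos, pos) <- n
      out <- c(out, nb)
    }
  }
  out
}

#' NG86 synonymous site count per codon
#'
#' Each codon position contributes one site, split between synonymous and
#' nonsynonymous in proportion to the synonymous fraction of its non-stop
#' single-nucleotide changes (mutations to stop codons are disregarded).
#' Stop codons themselves get NA.
#' @return named numeric vector over the 64 codons (synonymous sites,
#'   0..3; nonsynonymous sites are `3 - s`).
#' @keywords internal
ng86_syn_sites <- function() {
  if (!is.null(.codon_env$syn_sites)) return(.codon_env$syn_sites)
  codons <- all_codons()
  aa <- codon_aa(codons)
  s <- setNames(rep(NA_real_, 64), codons)
  for (cd in codons[aa != "*"]) {
    total <- 0
    for (pos in 1:3) {
      syn <- 0L
      nonstop <- 0L
      for (n in setdiff(NUCS, substr(cd, pos, pos))) {
        nb <- cd
        substr(nb, pos, pos) <- n
        if (codon_aa(nb) == "*") next
        nonstop <- nonstop + 1L
        if (codon_aa(nb) == codon_aa(cd)) syn <- syn + 1L
      }
      total <- total + if (nonstop > 0L) syn / nonstop else 0
    }
    s[cd] <- total
  }
  .codon_env$syn_sites <- s
  s
}

#' Synonymous/nonsynonymous differences between two codons
#'
#' Averages over all minimal mutational pathways (orderings of the
#' differing positions), skipping pathways passing through a stop codon;
#' if every pathway is blocked by a stop, all pathways are used.
#' @return c(sd, nd)
#' @keywords internal
ng86_pair_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- if (k == 1L) list(pos) else {
    pm <- list()
    gen <- function(rest, acc) {
      if (!length(rest)) { pm[[length(pm) + 1L]] <<- acc; return() }
      for (i in seq_along(rest)) gen(rest[-i], c(acc, rest[i]))
    }
    gen(pos, integer(0))
    pm
  }
  path_counts <- function(order, allow_stop) {
    cur <- c1
    sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allow_stop && codon_aa(nxt) == "*") return(NULL)
      if (codon_aa(nxt) == codon_aa(cur)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null),
                lapply(perms, path_counts, allow_stop = FALSE))
  if (!length(res))
    res <- lapply(perms, path_counts, allow_stop = TRUE)
  m <- do.call(rbind, res)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

#' Cached 64x64 codon-pair difference tables
#' @return list of matrices `sd`, `nd` indexed by codon strings.
#' @keywords internal
ng86_pair_tables <- function() {
  if (!is.null(.codon_env$pair_sd)) {
    return(list(sd = .codon_env$pair_sd, nd = .codon_env$pair_nd))
  }
  codons <- all_codons()
  sd <- matrix(0, 64, 64, dimnames = list(codons, codons))
  nd <- matrix(0, 64, 64, dimnames = list(codons, codons))
  for (i in 1:64) {
    for (j in 1:64) {
      if (i == j) next
      d <- ng86_pair_diffs(codons[i], codons[j])
      sd[i, j] <- d[["sd"]]
      nd[i, j] <- d[["nd"]]
    }
  }
  .codon_env$pair_sd <- sd
  .codon_env$pair_nd <- nd
  list(sd = sd, nd = nd)
}

#' Synonymous / nonsynonymous neighbour lists per codon
#'
#' Used by the codon-evolution simulator: for each non-stop codon, the
#' single-nucleotide neighbours that are synonymous (same amino acid,
#' non-stop) and nonsynonymous (different amino acid, non-stop).
#' @keywords internal
codon_neighbour_lists <- function() {
  if (!is.null(.codon_env$nbr)) return(.codon_env$nbr)
  codons <- all_codons()
  aa <- codon_aa(codons)
  nbr <- list()
  for (cd in codons) {
    if (codon_aa(cd) == "*") { nbr[[cd]] <- NULL; next }
    nbs <- codon_neighbours(cd)
    nb_aa <- codon_aa(nbs)
    nbr[[cd]] <- list(syn = nbs[nb_aa == codon_aa(cd)],
                      nonsyn = nbs[nb_aa != codon_aa(cd) & nb_aa != "*"])
  }
  .codon_env$nbr <- nbr
  nbr
}
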