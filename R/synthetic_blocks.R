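## Synthetic multi-genome alignment blocks over seven genome rows
## (zebrafish, P. guichenoti, P. tetrazona, carp A/B, goldfish A/B) with
## planted translocations and inversions against a known ancestral
## chromosome map.

.block_genomes <- c("zebrafish", "pguichenoti", "ptetrazona",
                    "carpA", "carpB", "goldfishA", "goldfishB")

#' Simulate alignment blocks with planted rearrangements
#'
#' Each block sits on one ancestral chromosome; every genome row is
#' placed on its homoeologous modern chromosome unless a planted
#' translocation moves it to a different ancestral chromosome's
#' counterpart, and a planted inversion flips its strand.  Block lengths
#' are uniform on 0.5-5 kb, so a subset falls below the 1-kb ancestral
#' region (AR) length filter by construction.
#'
#' @param n_ancestral_chromosomes number of ancestral chromosomes
#'   (default 25).
#' @param n_blocks number of blocks.
#' @param transloc_rate per-row translocation probability.
#' @param inversion_rate per-row inversion probability.
#' @param seed integer seed.
#' @return list with `blocks` (as [read_maf_blocks()]), `homoeolog_map`
#'   (data.frame: `genome_id`, `chromosome`, `ancestral_chromosome`),
#'   `src_sizes`, and `truth` (per block: ancestral chromosome; planted
#'   translocated and inverted (block, genome) pairs; rates; seed).
#' @export
simulate_alignment_blocks <- function(n_ancestral_chromosomes = 25,
                                      n_blocks = 200,
                                      transloc_rate = 0,
                                      inversion_rate = 0,
                                      seed = 1) {
  stopifnot(transloc_rate >= 0, transloc_rate <= 1,
            inversion_rate >= 0, inversion_rate <= 1)
  with_seed(seed, {
    n_anc <- n_ancestral_chromosomes
    map <- do.call(rbind, lapply(.block_genomes, function(g) {
      data.frame(genome_id = g,
                 chromosome = sprintf("%s_chr%02d", g, seq_len(n_anc)),
                 ancestral_chromosome = sprintf("anc%02d", seq_len(n_anc)),
                 stringsAsFactors = FALSE)
    }))
    chrom_size <- 3e7
    src_sizes <- setNames(rep(chrom_size, nrow(map)),
                          paste0(map$genome_id, ".", map$chromosome))

    blocks <- vector("list", n_blocks)
    transloc <- list(); invert <- list()
    anc_planted <- character(n_blocks)
    offsets <- new.env(parent = emptyenv())
    for (b in seq_len(n_blocks)) {
      anc <- sample.int(n_anc, 1L)
      anc_planted[b] <- sprintf("anc%02d", anc)
      len <- round(stats::runif(1, 500, 5000))
      rows <- lapply(.block_genomes, function(g) {
        target_anc <- anc
        tl <- stats::runif(1) < transloc_rate
        if (tl && n_anc > 1L)
          target_anc <- sample(setdiff(seq_len(n_anc), anc), 1L)
        iv <- stats::runif(1) < inversion_rate
        chrom <- sprintf("%s_chr%02d", g, target_anc)
        key <- paste0(g, ".", chrom)
        off <- if (is.null(offsets[[key]])) 0 else offsets[[key]]
        offsets[[key]] <- off + len + 100
        if (tl) transloc[[length(transloc) + 1L]] <<-
            data.frame(block_id = sprintf("block_%d", b), genome_id = g,
                       stringsAsFactors = FALSE)
        if (iv) invert[[length(invert) + 1L]] <<-
            data.frame(block_id = sprintf("block_%d", b), genome_id = g,
                       stringsAsFactors = FALSE)
        data.frame(genome_id = g, chromosome = chrom,
                   start = off, end = off + len,
                   strand = if (iv) "-" else "+",
                   stringsAsFactors = FALSE)
      })
      blocks[[b]] <- list(block_id = sprintf("block_%d", b),
                          rows = do.call(rbind, rows),
                          length = len)
    }
    truth <- list(
      ancestral = setNames(anc_planted,
                           vapply(blocks, `[[`, "", "block_id")),
      translocated = if (length(transloc)) do.call(rbind, transloc) else
        data.frame(block_id = character(), genome_id = character()),
      inverted = if (length(invert)) do.call(rbind, invert) else
        data.frame(block_id = character(), genome_id = character()),
      transloc_rate = transloc_rate, inversion_rate = inversion_rate,
      seed = seed)
    list(blocks = blocks, homoeolog_map = map, src_sizes = src_sizes,
         truth = truth)
  })
}
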