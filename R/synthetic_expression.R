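## Synthetic homoeolog expression panels: TPM matrices over shared
## contexts for subA/subB homoeolog pairs and a diploid outgroup
## ortholog, with planted conservation and subgenome-dominance structure.

#' Simulate an expression panel for homoeolog pairs
#'
#' Each pair gets an outgroup log-expression profile; conserved
#' homoeologs track that profile with small noise (Pearson r with the
#' outgroup > 0.66 in expectation), diverged homoeologs get independent
#' profiles.  Per pair, with probability `dominance_bias` the subB copy
#' receives a positive log2 shift (subB dominant), otherwise the subA
#' copy does.
#'
#' @param n_pairs number of homoeolog pairs.
#' @param n_tissues number of contexts (tissues/conditions; >= 3).
#' @param dominance_bias probability that subB is the dominant copy.
#' @param conserved_fraction fraction of homoeolog copies that track the
#'   outgroup profile.
#' @param noise_sd log2 noise around the tracked profile for conserved
#'   copies.
#' @param dominance_shift log2 shift given to the dominant copy (large
#'   enough that the designated copy wins the per-pair majority of
#'   contexts almost surely).
#' @param seed integer seed.
#' @return an `expression_panel`: list with `tpm` (genes x contexts
#'   matrix), `pairs` (data.frame: `pair_id`, `subA`, `subB`,
#'   `outgroup`), `contexts`, and `truth` (per-pair dominant copy,
#'   per-copy conserved flag, parameters, seed).
#' @export
simulate_expression_panel <- function(n_pairs,
                                      n_tissues = 9,
                                      dominance_bias = 0.5,
                                      conserved_fraction = 0.7,
                                      noise_sd = 0.35,
                                      dominance_shift = 3,
                                      seed = 1) {
  stopifnot(dominance_bias >= 0, dominance_bias <= 1,
            conserved_fraction >= 0, conserved_fraction <= 1)
  if (n_tissues < 3L)
    stopf("need at least 3 contexts for correlation-based classification")
  with_seed(seed, {
    contexts <- sprintf("ctx%02d", seq_len(n_tissues))
    pair_id <- sprintf("pair%04d", seq_len(n_pairs))
    pairs <- data.frame(pair_id = pair_id,
                        subA = paste0(pair_id, "_A"),
                        subB = paste0(pair_id, "_B"),
                        outgroup = paste0(pair_id, "_out"),
                        stringsAsFactors = FALSE)
    # outgroup log2 profiles: gene-level mean + tissue effects, kept
    # high enough that profiles sit above the TPM floor region
    out_log <- matrix(stats::rnorm(n_pairs * n_tissues, 0, 1.5),
                      n_pairs, n_tissues) +
      stats::rnorm(n_pairs, 6, 1)
    conservedA <- stats::runif(n_pairs) < conserved_fraction
    conservedB <- stats::runif(n_pairs) < conserved_fraction
    b_dominant <- stats::runif(n_pairs) < dominance_bias

    copy_log <- function(conserved) {
      m <- matrix(NA_real_, n_pairs, n_tissues)
      nc <- sum(conserved)
      if (nc)
        m[conserved, ] <- out_log[conserved, , drop = FALSE] +
          stats::rnorm(nc * n_tissues, 0, noise_sd)
      nd <- sum(!conserved)
      if (nd)
        m[!conserved, ] <- matrix(stats::rnorm(nd * n_tissues, 0, 1.5),
                                  nd, n_tissues) +
          stats::rnorm(nd, 6, 1)
      m
    }
    a_log <- copy_log(conservedA)
    b_log <- copy_log(conservedB)
    a_log[!b_dominant, ] <- a_log[!b_dominant, , drop = FALSE] +
      dominance_shift
    b_log[b_dominant, ] <- b_log[b_dominant, , drop = FALSE] +
      dominance_shift

    tpm <- rbind(2^a_log - 1, 2^b_log - 1, 2^out_log - 1)
    tpm[tpm < 0] <- 0
    rownames(tpm) <- c(pairs$subA, pairs$subB, pairs$outgroup)
    colnames(tpm) <- contexts

    structure(list(tpm = tpm, pairs = pairs, contexts = contexts,
                   truth = list(b_dominant = setNames(b_dominant, pair_id),
                                conservedA = setNames(conservedA, pair_id),
                                conservedB = setNames(conservedB, pair_id),
                                dominance_bias = dominance_bias,
                                conserved_fraction = conserved_fraction,
                                seed = seed)),
              class = "expression_panel")
  })
}

#' Write an expression panel as TSV files
#'
#' @param panel an `expression_panel`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_expression_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- data.frame(gene_id = rownames(panel$tpm), panel$tpm,
                    check.names = FALSE)
  utils::write.table(tab, file.path(dir, "tpm.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(panel$pairs, file.path(dir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(panel$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
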