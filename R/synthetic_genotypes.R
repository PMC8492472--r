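## Two-population genotype simulator with planted sweep windows.
## Sites are drawn per window from a neutral 1/i site-frequency spectrum
## (no full coalescent); planted quantities hold in expectation.

#' Simulate two-population genotypes with planted sweep windows
#'
#' Neutral windows draw sites from a shared 1/i frequency spectrum over
#' the pooled haplotypes of both populations, giving diversity near
#' `pi_background` in each and Fst near 0.  In sweep windows pop1
#' diversity is collapsed to `pi_sweep` (the selected haplotype is near
#' fixation) while pop2 keeps background diversity, which also elevates
#' differentiation.  Sweep windows are non-overlapping `window_size`
#' tiles chosen uniformly.
#'
#' @param n_samples_per_pop diploid samples per population.
#' @param chrom_length chromosome length in bp.
#' @param n_sweep_windows number of planted sweep windows.
#' @param pi_background,pi_sweep per-site diversity targets
#'   (`pi_sweep < pi_background`).
#' @param window_size planting resolution in bp (default 1e5).
#' @param chromosome chromosome name in the output.
#' @param seed integer seed.
#' @return list with `gm` (a `genotype_matrix` with `population_of` set
#'   to pop1/pop2) and `truth` (0-based sweep window starts, parameters,
#'   seed).
#' @export
simulate_two_population_genotypes <- function(n_samples_per_pop,
                                              chrom_length,
                                              n_sweep_windows,
                                              pi_background = 2e-3,
                                              pi_sweep = 5e-4,
                                              window_size = 1e5,
                                              chromosome = "chr1",
                                              seed = 1) {
  if (chrom_length < window_size)
    stopf("chromosome shorter than one window")
  if (pi_sweep >= pi_background)
    stopf("pi_sweep must be below pi_background")
  n_windows <- floor(chrom_length / window_size)
  if (n_sweep_windows > n_windows)
    stopf("more sweep windows than windows")
  with_seed(seed, {
    n_dip <- n_samples_per_pop
    n_hap <- 2L * n_dip                     # haplotypes per population
    n_hap_tot <- 2L * n_hap
    samples <- c(sprintf("pop1_s%02d", seq_len(n_dip)),
                 sprintf("pop2_s%02d", seq_len(n_dip)))
    pops <- setNames(rep(c("pop1", "pop2"), each = n_dip), samples)

    sweep_idx <- if (n_sweep_windows > 0)
      sort(sample.int(n_windows, n_sweep_windows)) else integer(0)

    # for the 1/i SFS over n haplotypes E[pi per site] = theta_w, so the
    # site intensity theta * a_n * L yields the target diversity
    a_tot <- sum(1 / seq_len(n_hap_tot - 1))
    a_pop <- sum(1 / seq_len(n_hap - 1))
    sfs_tot <- 1 / seq_len(n_hap_tot - 1)
    sfs_pop <- 1 / seq_len(n_hap - 1)

    site_pos <- list(); site_hap <- list()
    for (w in seq_len(n_windows)) {
      w0 <- (w - 1) * window_size
      if (!(w %in% sweep_idx)) {
        S <- stats::rpois(1, pi_background * a_tot * window_size)
        if (S == 0) next
        pos <- sort(sample.int(window_size, min(S, window_size)))
        hap <- matrix(0L, length(pos), n_hap_tot)
        cnt <- sample.int(n_hap_tot - 1, length(pos), replace = TRUE,
                          prob = sfs_tot)
        for (k in seq_along(pos))
          hap[k, sample.int(n_hap_tot, cnt[k])] <- 1L
      } else {
        # pop2 keeps background polymorphism; the swept pop1 is
        # monomorphic at these sites, fixed for the derived allele at a
        # coin-flip of them (strong differentiation)
        S <- stats::rpois(1, pi_background * a_pop * window_size)
        if (S == 0) next
        pos <- sort(sample.int(window_size, min(S, window_size)))
        hap <- matrix(0L, length(pos), n_hap_tot)
        cnt2 <- sample.int(n_hap - 1, length(pos), replace = TRUE,
                           prob = sfs_pop)
        for (k in seq_along(pos)) {
          hap[k, n_hap + sample.int(n_hap, cnt2[k])] <- 1L
          if (stats::runif(1) < 0.5) hap[k, seq_len(n_hap)] <- 1L
        }
        # residual pop1 diversity at the pi_sweep level
        S1 <- stats::rpois(1, pi_sweep * a_pop * window_size)
        if (S1 > 0) {
          free <- setdiff(seq_len(window_size), pos)
          pos1 <- sort(sample(free, min(S1, length(free))))
          hap1 <- matrix(0L, length(pos1), n_hap_tot)
          cnt1 <- sample.int(n_hap - 1, length(pos1), replace = TRUE,
                             prob = sfs_pop)
          for (k in seq_along(pos1))
            hap1[k, sample.int(n_hap, cnt1[k])] <- 1L
          pos <- c(pos, pos1)
          hap <- rbind(hap, hap1)
          ord <- order(pos)
          pos <- pos[ord]; hap <- hap[ord, , drop = FALSE]
        }
      }
      site_pos[[length(site_pos) + 1L]] <- w0 + pos
      site_hap[[length(site_hap) + 1L]] <- hap
    }
    pos_all <- unlist(site_pos)
    hap_all <- do.call(rbind, site_hap)
    # haplotypes 1..n_hap are pop1; pairing (1,2),(3,4),... makes the
    # first n_dip diploids pop1 and the rest pop2
    dos <- hap_all[, seq(1, n_hap_tot, 2), drop = FALSE] +
      hap_all[, seq(2, n_hap_tot, 2), drop = FALSE]
    colnames(dos) <- samples
    sites <- data.frame(chromosome = chromosome, position = pos_all,
                        ref = "A", alt = "G",
                        stringsAsFactors = FALSE)
    gm <- genotype_matrix(samples, sites, dos, population_of = pops)
    truth <- list(sweep_window_starts = (sweep_idx - 1L) * window_size,
                  window_size = window_size,
                  chrom_length = chrom_length,
                  pi_background = pi_background, pi_sweep = pi_sweep,
                  n_samples_per_pop = n_samples_per_pop,
                  seed = seed)
    list(gm = gm, truth = truth)
  })
}

#' Write a genotype matrix as a VCF 4.2 text file
#'
#' @param gm a `genotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf_minimal <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", gm$sample_ids),
                     collapse = "\t")), con)
  gt_str <- matrix("./.", nrow(gm$genotypes), ncol(gm$genotypes))
  gt_str[gm$genotypes == 0] <- "0/0"
  gt_str[gm$genotypes == 1] <- "0/1"
  gt_str[gm$genotypes == 2] <- "1/1"
  lines <- paste(gm$sites$chromosome, gm$sites$position, ".",
                 gm$sites$ref, gm$sites$alt, ".", "PASS", ".", "GT",
                 apply(gt_str, 1, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, con)
  invisible(path)
}
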