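## Pairwise Ka/Ks (NG86), Ks-mode estimation, molecular-clock dating,
## sequence identity and subgenome selection-symmetry tests.

#' NG86 pairwise Ka/Ks for a two-sequence codon alignment
#'
#' Nei-Gojobori (1986) counting: each codon position contributes one site,
#' split by the synonymous fraction of its non-stop single-nucleotide
#' changes; observed differences are averaged over all minimal mutational
#' pathways between codons, skipping pathways through stop codons.
#' Proportions are corrected with Jukes-Cantor,
#' `d = -(3/4) log(1 - (4/3) p)`; a saturated proportion (`p >= 3/4`)
#' yields an undefined (NA) rate.  Codons containing a gap or ambiguity in
#' either sequence are dropped pairwise.
#'
#' @param seq1,seq2 coding sequences (character strings, equal length,
#'   multiple of 3, no internal stop codons).
#' @return an object of class `kaks_result`: list with `Ka`, `Ks`,
#'   `ratio` (NA when `Ks` is 0 or undefined), and counts `S`, `N`,
#'   `Sd`, `Nd`, `n_codons_used`.
#' @export
compute_kaks <- function(seq1, seq2) {
  seq1 <- toupper(gsub("U", "T", seq1))
  seq2 <- toupper(gsub("U", "T", seq2))
  if (nchar(seq1) != nchar(seq2))
    stopf("sequences differ in length (%d vs %d)", nchar(seq1), nchar(seq2))
  if (nchar(seq1) %% 3 != 0)
    stopf("alignment length %d is not a multiple of 3", nchar(seq1))
  n_codon <- nchar(seq1) %/% 3
  starts <- 3 * seq_len(n_codon) - 2
  cods1 <- substring(seq1, starts, starts + 2)
  cods2 <- substring(seq2, starts, starts + 2)
  clean <- grepl("^[ACGT]{3}$", cods1) & grepl("^[ACGT]{3}$", cods2)
  cods1 <- cods1[clean]
  cods2 <- cods2[clean]
  aa1 <- codon_aa(cods1)
  aa2 <- codon_aa(cods2)
  internal_stop <- c(which(aa1 == "*"), which(aa2 == "*"))
  internal_stop <- internal_stop[internal_stop < length(cods1)]
  if (length(internal_stop))
    stopf("internal stop codon at codon %d", min(internal_stop))
  # terminal stop codons, if present in both, are dropped
  drop <- aa1 == "*" | aa2 == "*"
  cods1 <- cods1[!drop]
  cods2 <- cods2[!drop]
  if (!length(cods1)) stopf("no usable codons in alignment")

  syn <- ng86_syn_sites()
  tabs <- ng86_pair_tables()
  S <- (sum(syn[cods1]) + sum(syn[cods2])) / 2
  N <- 3 * length(cods1) - S
  idx <- cbind(match(cods1, all_codons()), match(cods2, all_codons()))
  Sd <- sum(tabs$sd[idx])
  Nd <- sum(tabs$nd[idx])

  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  Ks <- jc(ps)
  Ka <- jc(pn)
  ratio <- if (is.na(Ka) || is.na(Ks) || Ks == 0) NA_real_ else Ka / Ks
  structure(list(Ka = Ka, Ks = Ks, ratio = ratio,
                 S = S, N = N, Sd = Sd, Nd = Nd,
                 n_codons_used = length(cods1)),
            class = "kaks_result")
}

#' Mode of a Ks distribution by Gaussian kernel density
#'
#' Density on a 512-point grid over `[0, max(values)]`, bandwidth by
#' Silverman's rule of thumb unless supplied.  Local density maxima are
#' reported as diagnostics for multimodal distributions.
#'
#' @param values numeric vector of Ks values (at least 30 finite values).
#' @param bandwidth optional kernel bandwidth.
#' @return an object of class `ks_distribution`: list with `values`,
#'   `mode`, `bandwidth`, and `peaks` (data.frame of all local maxima,
#'   tallest first).
#' @export
estimate_ks_mode <- function(values, bandwidth = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 30L)
    stopf("need at least 30 finite Ks values (got %d): mode unstable",
          length(values))
  bw <- bandwidth %||% stats::bw.nrd0(values)
  d <- stats::density(values, bw = bw, n = 512,
                      from = 0, to = max(values))
  y <- d$y
  is_peak <- c(FALSE, diff(sign(diff(y))) < 0, FALSE)
  is_peak[which.max(y)] <- TRUE
  peaks <- data.frame(ks = d$x[is_peak], density = y[is_peak])
  peaks <- peaks[order(-peaks$density), , drop = FALSE]
  structure(list(values = values,
                 mode = d$x[which.max(y)],
                 bandwidth = bw,
                 peaks = peaks),
            class = "ks_distribution")
}

#' Convert a Ks mode to a divergence time under a molecular clock
#'
#' Two diverging lineages each accumulate synonymous substitutions, so
#' `time = Ks / (2 * rate)`; reported in million years.
#'
#' @param ks_mode mode of the Ks distribution (substitutions per
#'   synonymous site).
#' @param rate clock rate in substitutions per synonymous site per year
#'   (default 3.51e-9, a teleost synonymous-site clock).
#' @return list with `ks_mode`, `rate`, `time_ma` and `time_ma_printed`
#'   (half-up at 1 decimal).
#' @export
ks_to_divergence_time <- function(ks_mode, rate = 3.51e-9) {
  if (rate <= 0) stopf("clock rate must be positive")
  if (ks_mode < 0) stopf("ks_mode must be non-negative")
  t_ma <- ks_mode / (2 * rate) / 1e6
  list(ks_mode = ks_mode, rate = rate, time_ma = t_ma,
       time_ma_printed = round_half_up(t_ma, 1))
}

#' Percent identity from a global pairwise alignment
#'
#' Needleman-Wunsch global alignment via Biostrings; identity is the
#' number of matching columns over all alignment columns (gaps included).
#'
#' @param seq1,seq2 sequences (character strings).
#' @param mode `"nucleotide"` or `"protein"`.
#' @return percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(seq1, seq2,
                              mode = c("nucleotide", "protein")) {
  mode <- match.arg(mode)
  if (!nchar(seq1) || !nchar(seq2)) stopf("empty sequence")
  if (mode == "nucleotide") {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                    mismatch = -1)
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seq1), Biostrings::DNAString(seq2),
      type = "global", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2)
  } else {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seq1), Biostrings::AAString(seq2),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
  }
  Biostrings::pid(al, type = "PID1")
}

#' Two-sided rank-sum comparison of Ka/Ks distributions
#'
#' Mann-Whitney U-test between two groups of Ka/Ks ratios (undefined
#' ratios removed first, as genes with no ratio are excluded).  The exact
#' null distribution is used when both groups have at most 8 values and
#' there are no ties.
#'
#' @param kaks_group_a,kaks_group_b numeric vectors of Ka/Ks ratios
#'   (at least 5 finite values each).
#' @return list with `U`, `p_value`, `n_a`, `n_b`.
#' @export
compare_selection_symmetry <- function(kaks_group_a, kaks_group_b) {
  a <- kaks_group_a[is.finite(kaks_group_a)]
  b <- kaks_group_b[is.finite(kaks_group_b)]
  if (length(a) < 5L || length(b) < 5L)
    stopf("each group needs at least 5 defined Ka/Ks values")
  exact <- length(a) <= 8L && length(b) <= 8L
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(a), n_b = length(b))
}
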