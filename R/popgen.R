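## Windowed diversity statistics, Weir-Cockerham Fst with
## Z-transformation, joint top-quantile sweep calling, and LD decay.
## Windows are 0-based half-open [start, end).

.pop_dosage <- function(gm, population) {
  if (!is.null(names(population))) population <- unname(population)
  if (is.character(population) && length(population) == 1L &&
      !is.null(gm$population_of)) {
    samples <- names(gm$population_of)[gm$population_of == population]
  } else {
    samples <- population
  }
  missing <- setdiff(samples, gm$sample_ids)
  if (length(missing)) stopf("unknown sample '%s'", missing[1])
  gm$genotypes[, samples, drop = FALSE]
}

.harmonic <- function(n) if (n < 2) 0 else sum(1 / seq_len(n - 1))

.make_windows <- function(chrom_length, window_size, step) {
  starts <- seq(0, max(0, chrom_length - 1), by = step)
  ends <- pmin(starts + window_size, chrom_length)
  keep <- (ends - starts) >= window_size / 2
  data.frame(start = starts[keep], end = ends[keep],
             partial = (ends - starts)[keep] < window_size)
}

# per-site allele summaries within one population dosage matrix
.site_freqs <- function(dos) {
  n_called <- rowSums(!is.na(dos)) * 2          # haplotypes observed
  alt <- rowSums(dos, na.rm = TRUE)
  list(n = n_called, p = ifelse(n_called > 0, alt / n_called, NA_real_),
       alt = alt)
}

#' Windowed nucleotide diversity and frequency-spectrum statistics
#'
#' Per window: pi (per site) from allele frequencies,
#' `sum 2 p (1-p) n/(n-1) / L`; Watterson's theta from segregating
#' sites with the harmonic-number correction at the per-site observed
#' sample size; Tajima's D and the Fu & Li D* and F* star variants
#' (no outgroup) by their published variance formulas.  Windows with no
#' segregating site report 0 diversity and missing D statistics.
#'
#' @param gm a `genotype_matrix`.
#' @param population population name (looked up in `population_of`) or a
#'   character vector of sample ids.
#' @param window_size window length in bp (default 1e5).
#' @param step step in bp (default 5e4).
#' @param chrom_lengths optional named vector of chromosome lengths;
#'   defaults to the last site position per chromosome rounded up to a
#'   window.  Terminal partial windows are kept when at least half a
#'   window long (`partial` flag).
#' @return data.frame per window: `chromosome`, `start`, `end`, `n_sites`
#'   (segregating), `pi`, `theta_w`, `tajima_d`, `fuli_d_star`,
#'   `fuli_f_star`, `partial`.
#' @export
window_diversity_stats <- function(gm, population, window_size = 1e5,
                                   step = 5e4, chrom_lengths = NULL) {
  dos <- .pop_dosage(gm, population)
  # one diploid (two haplotypes) is the lower bound for pairwise diversity
  if (ncol(dos) < 1L) stopf("population has no samples")
  out <- list()
  for (chrom in unique(gm$sites$chromosome)) {
    in_chr <- gm$sites$chromosome == chrom
    pos0 <- gm$sites$position[in_chr] - 1   # to 0-based
    d <- dos[in_chr, , drop = FALSE]
    L <- chrom_lengths[[chrom]] %||%
      (ceiling(max(pos0 + 1) / window_size) * window_size)
    w <- .make_windows(L, window_size, step)
    f <- .site_freqs(d)
    # per-pair singleton status needs alt and ref minor counts
    for (i in seq_len(nrow(w))) {
      sel <- pos0 >= w$start[i] & pos0 < w$end[i]
      len <- w$end[i] - w$start[i]
      n <- f$n[sel]; p <- f$p[sel]
      seg <- !is.na(p) & p > 0 & p < 1 & n > 1
      S <- sum(seg)
      if (S == 0) {
        out[[length(out) + 1L]] <- data.frame(
          chromosome = chrom, start = w$start[i], end = w$end[i],
          n_sites = 0L, pi = 0, theta_w = 0,
          tajima_d = NA_real_, fuli_d_star = NA_real_,
          fuli_f_star = NA_real_, partial = w$partial[i])
        next
      }
      ns <- n[seg]; ps <- p[seg]
      pi_abs <- sum(2 * ps * (1 - ps) * ns / (ns - 1))
      theta_abs <- sum(1 / vapply(ns, .harmonic, 0))
      nn <- round(stats::median(ns))           # sample size for variances
      alt_cnt <- ps * ns
      eta_s <- sum(alt_cnt == 1 | alt_cnt == ns - 1)
      out[[length(out) + 1L]] <- data.frame(
        chromosome = chrom, start = w$start[i], end = w$end[i],
        n_sites = S, pi = pi_abs / len, theta_w = theta_abs / len,
        tajima_d = .tajima_d(S, pi_abs, nn),
        fuli_d_star = .fuli_d_star(S, eta_s, nn),
        fuli_f_star = .fuli_f_star(S, pi_abs, eta_s, nn),
        partial = w$partial[i])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Tajima (1989)
.tajima_d <- function(S, pi_abs, n) {
  if (S == 0 || n < 2) return(NA_real_)
  a1 <- .harmonic(n)
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_abs - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Fu & Li (1993) star variants with the Simonsen et al. (1995)
# corrections (the DnaSP convention); eta_s is the singleton count.
.fuli_d_star <- function(S, eta_s, n) {
  if (S == 0 || n < 3) return(NA_real_)
  a_n <- .harmonic(n)
  a_n1 <- .harmonic(n + 1)
  b_n <- sum(1 / seq_len(n - 1)^2)
  c_n <- if (n == 2) 1 else 2 * (n * a_n - 2 * (n - 1)) /
    ((n - 1) * (n - 2))
  d_n <- c_n + (n - 2) / (n - 1)^2 +
    2 / (n - 1) * (3 / 2 - (2 * a_n1 - 3) / (n - 2) - 1 / n)
  v <- ((n / (n - 1))^2 * b_n + a_n^2 * d_n -
          2 * (n * a_n * (a_n + 1)) / (n - 1)^2) / (a_n^2 + b_n)
  u <- (n / (n - 1)) * (a_n - n / (n - 1)) - v
  (n / (n - 1) * S - a_n * eta_s) / sqrt(u * S + v * S^2)
}

.fuli_f_star <- function(S, pi_abs, eta_s, n) {
  if (S == 0 || n < 3) return(NA_real_)
  a_n <- .harmonic(n)
  a_n1 <- .harmonic(n + 1)
  b_n <- sum(1 / seq_len(n - 1)^2)
  v <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
          2 * (n - 1) * a_n / n^2 - 8 * b_n / n) / (a_n^2 + b_n)
  u <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * a_n1) /
          (3 * n * (n - 1))) / a_n - v
  (pi_abs - (n - 1) / n * eta_s) / sqrt(u * S + v * S^2)
}

#' Per-window Weir-Cockerham Fst between two populations
#'
#' Per-site Weir & Cockerham (1984) variance components a (among
#' populations), b (among individuals within populations) and c (within
#' individuals), combined per window as the weighted estimator
#' `sum(a) / sum(a+b+c)`.  Negative window estimates are truncated to 0
#' with a flag.
#'
#' @param gm a `genotype_matrix`.
#' @param pop1,pop2 population names or sample-id vectors.
#' @param window_size,step,chrom_lengths as in
#'   [window_diversity_stats()].
#' @return data.frame per window: `chromosome`, `start`, `end`,
#'   `n_sites`, `fst`, `fst_raw`, `truncated`.
#' @export
weir_cockerham_fst <- function(gm, pop1, pop2, window_size = 1e5,
                               step = 5e4, chrom_lengths = NULL) {
  d1 <- .pop_dosage(gm, pop1)
  d2 <- .pop_dosage(gm, pop2)
  comp <- .wc_site_components(d1, d2)
  out <- list()
  for (chrom in unique(gm$sites$chromosome)) {
    in_chr <- gm$sites$chromosome == chrom
    pos0 <- gm$sites$position[in_chr] - 1
    a <- comp$a[in_chr]; bc <- comp$abc[in_chr]
    L <- chrom_lengths[[chrom]] %||%
      (ceiling(max(pos0 + 1) / window_size) * window_size)
    w <- .make_windows(L, window_size, step)
    for (i in seq_len(nrow(w))) {
      sel <- pos0 >= w$start[i] & pos0 < w$end[i] & !is.na(a)
      num <- sum(a[sel]); den <- sum(bc[sel])
      fst_raw <- if (den > 0) num / den else NA_real_
      fst <- if (!is.na(fst_raw) && fst_raw < 0) 0 else fst_raw
      out[[length(out) + 1L]] <- data.frame(
        chromosome = chrom, start = w$start[i], end = w$end[i],
        n_sites = sum(sel), fst = fst, fst_raw = fst_raw,
        truncated = !is.na(fst_raw) && fst_raw < 0)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# WC84 components per site for two populations of diploids
.wc_site_components <- function(d1, d2) {
  r <- 2
  stats_of <- function(d) {
    n <- rowSums(!is.na(d))                 # diploid individuals
    p <- ifelse(n > 0, rowSums(d, na.rm = TRUE) / (2 * n), NA_real_)
    h <- ifelse(n > 0, rowSums(d == 1, na.rm = TRUE) / n, NA_real_)
    list(n = n, p = p, h = h)
  }
  s1 <- stats_of(d1); s2 <- stats_of(d2)
  n1 <- s1$n; n2 <- s2$n
  nbar <- (n1 + n2) / r
  usable <- n1 >= 2 & n2 >= 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * s1$p + n2 * s2$p) / (r * nbar)
  s2v <- (n1 * (s1$p - pbar)^2 + n2 * (s2$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * s1$h + n2 * s2$h) / (r * nbar)
  a <- (nbar / nc) * (s2v - (pbar * (1 - pbar) - (r - 1) / r * s2v -
                               hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2v -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  mono <- !is.na(pbar) & (pbar == 0 | pbar == 1)
  a[mono | !usable] <- NA
  abc <- a + b + cc
  list(a = a, abc = abc)
}

#' Z-transform Fst values
#'
#' `(x - mean) / sd` with the sample standard deviation (denominator
#' n - 1); any input therefore has mean 0 and sd 1.
#'
#' @param fst_values numeric vector (at least 2 finite values, non-zero
#'   variance).
#' @return numeric vector of ZFst scores (NA where the input was NA).
#' @export
zfst_transform <- function(fst_values) {
  x <- fst_values[is.finite(fst_values)]
  if (length(x) < 2L) stopf("need at least 2 finite Fst values")
  s <- stats::sd(x)
  if (s == 0) stopf("zero variance: Z-transformation undefined")
  (fst_values - mean(x)) / s
}

#' Call selective sweeps from joint pi-ratio and ZFst quantiles
#'
#' Windows in the top `quantile` of both the diversity ratio
#' (pi_pop2 / pi_pop1, so reduced diversity in the focal pop1 gives a
#' large ratio) and ZFst are called selected in pop1; windows in the
#' bottom `quantile` of both are called selected in pop2.  The empirical
#' thresholds are reported alongside the calls.
#'
#' @param windows data.frame with at least `pi_ratio` and `zfst` columns
#'   (one row per window; `chromosome`, `start`, `end` carried through).
#' @param quantile tail mass per criterion (default 0.05).
#' @return list with `calls` (windows plus `direction`), `thresholds`
#'   and `degenerate` flag (no calls when the thresholds collapse).
#' @export
call_selective_sweeps <- function(windows, quantile = 0.05) {
  if (nrow(windows) < 1 / quantile)
    stopf("fewer than %d windows: quantile thresholds unstable",
          ceiling(1 / quantile))
  pr <- windows$pi_ratio
  z <- windows$zfst
  ok <- is.finite(z) & !is.na(pr)
  hi_pr <- stats::quantile(pr[ok & is.finite(pr)], 1 - quantile,
                           names = FALSE)
  hi_z <- stats::quantile(z[ok], 1 - quantile, names = FALSE)
  lo_pr <- stats::quantile(pr[ok & is.finite(pr)], quantile,
                           names = FALSE)
  lo_z <- stats::quantile(z[ok], quantile, names = FALSE)
  degenerate <- hi_pr == lo_pr || hi_z == lo_z
  direction <- rep(NA_character_, nrow(windows))
  if (!degenerate) {
    sel1 <- ok & (pr >= hi_pr | is.infinite(pr)) & z >= hi_z
    sel2 <- ok & is.finite(pr) & pr <= lo_pr & z <= lo_z
    direction[sel1] <- "selected_in_pop1"
    direction[sel2] <- "selected_in_pop2"
  }
  calls <- windows[!is.na(direction), , drop = FALSE]
  calls$direction <- direction[!is.na(direction)]
  list(calls = calls,
       thresholds = c(pi_ratio_high = hi_pr, zfst_high = hi_z,
                      pi_ratio_low = lo_pr, zfst_low = lo_z),
       degenerate = degenerate)
}

#' LD decay curve and half-decay distance
#'
#' r-squared between site pairs from the squared correlation of unphased
#' genotype dosages (composite LD), within chromosomes only, averaged in
#' distance bins; the half-decay distance is the first bin midpoint
#' where the mean r-squared falls to half the curve maximum.
#'
#' @param gm a `genotype_matrix`.
#' @param population population name or sample ids.
#' @param max_distance maximum pair distance in bp.
#' @param bin_size distance bin width in bp.
#' @param max_sites_per_chrom dense chromosomes are thinned to this many
#'   evenly spaced polymorphic sites before pairing (default 2000), the
#'   usual practice of LD-decay tools; thinning is deterministic.
#' @return list with `curve` (data.frame: `distance`, `mean_r2`,
#'   `n_pairs`) and `half_decay_distance` (bp; NA when the curve never
#'   falls to half its maximum).
#' @export
ld_decay_curve <- function(gm, population, max_distance, bin_size,
                           max_sites_per_chrom = 2000) {
  dos <- .pop_dosage(gm, population)
  n_bins <- ceiling(max_distance / bin_size)
  sum_r2 <- numeric(n_bins)
  n_pair <- integer(n_bins)
  for (chrom in unique(gm$sites$chromosome)) {
    in_chr <- which(gm$sites$chromosome == chrom)
    pos <- gm$sites$position[in_chr]
    d <- dos[in_chr, , drop = FALSE]
    sds <- apply(d, 1, stats::sd, na.rm = TRUE)
    poly <- !is.na(sds) & sds > 0
    pos <- pos[poly]; d <- d[poly, , drop = FALSE]
    if (length(pos) > max_sites_per_chrom) {
      keep <- unique(round(seq(1, length(pos),
                               length.out = max_sites_per_chrom)))
      pos <- pos[keep]; d <- d[keep, , drop = FALSE]
    }
    if (length(pos) < 2L) next
    cm <- suppressWarnings(stats::cor(t(d),
                                      use = "pairwise.complete.obs"))^2
    for (i in seq_len(length(pos) - 1L)) {
      j <- which(pos > pos[i] & pos - pos[i] <= max_distance)
      if (!length(j)) next
      bins <- pmin(n_bins, ceiling((pos[j] - pos[i]) / bin_size))
      r2 <- cm[i, j]
      keep <- !is.na(r2)
      for (bi in unique(bins[keep])) {
        sel <- keep & bins == bi
        sum_r2[bi] <- sum_r2[bi] + sum(r2[sel])
        n_pair[bi] <- n_pair[bi] + sum(sel)
      }
    }
  }
  mids <- (seq_len(n_bins) - 0.5) * bin_size
  mean_r2 <- ifelse(n_pair > 0, sum_r2 / n_pair, NA_real_)
  curve <- data.frame(distance = mids, mean_r2 = mean_r2,
                      n_pairs = n_pair)
  valid <- !is.na(mean_r2)
  half <- NA_real_
  if (any(valid)) {
    mx <- max(mean_r2[valid])
    below <- valid & mean_r2 <= mx / 2
    if (any(below)) half <- mids[which(below)[1]]
  }
  list(curve = curve, half_decay_distance = half)
}
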