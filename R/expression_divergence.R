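## Homoeolog expression divergence: dominance, conservation/divergence,
## profile clustering, functionalization, cotranscription, dosage,
## Ka/Ks-divergence trend, DEG balance and trans-splicing classification.
##
## All profile distances and correlations are computed on log2(TPM + 1);
## the expression floor (default TPM >= 1) defines "expressed".

.pair_mats <- function(panel) {
  list(a = panel$tpm[panel$pairs$subA, , drop = FALSE],
       b = panel$tpm[panel$pairs$subB, , drop = FALSE],
       o = if (all(panel$pairs$outgroup %in% rownames(panel$tpm)))
         panel$tpm[panel$pairs$outgroup, , drop = FALSE] else NULL)
}

#' Per-context homoeolog dominance counts
#'
#' In each context, a pair with a strictly higher subA TPM counts as
#' subA-dominant and vice versa; equal values are ties, and pairs with
#' both copies below the floor are excluded.  A two-sided chi-square
#' goodness-of-fit test against 50:50 is run per context on the dominant
#' counts.
#'
#' @param panel an `expression_panel`.
#' @param floor expression floor on TPM (default 1).
#' @return data.frame per context: `context`, `subA_dominant`,
#'   `subB_dominant`, `ties`, `excluded`, `chisq`, `p_value`.
#' @export
dominance_analysis <- function(panel, floor = 1) {
  m <- .pair_mats(panel)
  out <- lapply(seq_along(panel$contexts), function(j) {
    a <- m$a[, j]; b <- m$b[, j]
    excluded <- a < floor & b < floor
    subA <- sum(a > b & !excluded)
    subB <- sum(b > a & !excluded)
    ties <- sum(a == b & !excluded)
    if (subA + subB > 0) {
      ct <- suppressWarnings(stats::chisq.test(c(subA, subB),
                                               p = c(0.5, 0.5)))
      chisq <- unname(ct$statistic); p <- ct$p.value
    } else {
      chisq <- NA_real_; p <- NA_real_
    }
    data.frame(context = panel$contexts[j], subA_dominant = subA,
               subB_dominant = subB, ties = ties,
               excluded = sum(excluded), chisq = chisq, p_value = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pair-level dominant copy by majority of contexts
#'
#' The dominant copy of a pair is the one with the strictly higher TPM
#' in the majority of contexts where either copy clears the floor; an
#' equal split is a tie.
#'
#' @param panel an `expression_panel`.
#' @param floor expression floor.
#' @return data.frame per pair: `pair_id`, `dominant`
#'   ("subA"/"subB"/"tie"), `n_subA_wins`, `n_subB_wins`.
#' @export
pair_dominance <- function(panel, floor = 1) {
  m <- .pair_mats(panel)
  use <- (m$a >= floor) | (m$b >= floor)
  winsA <- rowSums((m$a > m$b) & use)
  winsB <- rowSums((m$b > m$a) & use)
  data.frame(pair_id = panel$pairs$pair_id,
             dominant = ifelse(winsA > winsB, "subA",
                               ifelse(winsB > winsA, "subB", "tie")),
             n_subA_wins = winsA, n_subB_wins = winsB,
             stringsAsFactors = FALSE)
}

.cor_with_p <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(r = NA_real_, p = NA_real_))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "pearson"))
  c(r = unname(ct$estimate), p = ct$p.value)
}

#' Conservation with the outgroup and homoeolog-pair divergence
#'
#' A homoeolog is conserved when its Pearson correlation with the
#' outgroup ortholog across contexts exceeds `r_threshold` with
#' `p <= 0.05` (at 9 contexts r = 0.666 is itself the two-sided 5%
#' critical value, so the two thresholds are mutually consistent).  A
#' pair is divergent when the Euclidean distance between its two
#' log2(TPM+1) profiles reaches the `dist_quantile` quantile across all
#' pairs, or the homoeolog-homoeolog correlation is below `r_threshold`.
#' Zero-variance profiles give an undefined correlation and are classed
#' divergent with `r_undefined = TRUE`.
#'
#' @param panel an `expression_panel`.
#' @param r_threshold correlation threshold (default 0.66).
#' @param dist_quantile upper distance quantile marking divergence
#'   (default 0.9).
#' @return data.frame per pair: conservation flags and correlations for
#'   both copies, `euclidean_distance`, `pair_r`, `divergent`,
#'   `r_undefined`, plus the distance threshold as an attribute
#'   `dist_threshold`.
#' @export
conservation_and_divergence <- function(panel, r_threshold = 0.66,
                                        dist_quantile = 0.9) {
  m <- .pair_mats(panel)
  la <- log2(m$a + 1); lb <- log2(m$b + 1)
  lo <- if (!is.null(m$o)) log2(m$o + 1) else NULL
  n <- nrow(panel$pairs)
  consA <- consB <- rep(NA, n)
  rA <- rB <- rep(NA_real_, n)
  if (!is.null(lo)) {
    for (i in seq_len(n)) {
      ca <- .cor_with_p(la[i, ], lo[i, ])
      cb <- .cor_with_p(lb[i, ], lo[i, ])
      rA[i] <- ca[["r"]]; rB[i] <- cb[["r"]]
      consA[i] <- isTRUE(ca[["r"]] > r_threshold && ca[["p"]] <= 0.05)
      consB[i] <- isTRUE(cb[["r"]] > r_threshold && cb[["p"]] <= 0.05)
    }
  }
  d <- sqrt(rowSums((la - lb)^2))
  pr <- numeric(n); undef <- logical(n)
  for (i in seq_len(n)) {
    cc <- .cor_with_p(la[i, ], lb[i, ])
    pr[i] <- cc[["r"]]
    undef[i] <- is.na(cc[["r"]])
  }
  thr <- stats::quantile(d, dist_quantile, names = FALSE)
  divergent <- d >= thr | undef | (!is.na(pr) & pr < r_threshold)
  out <- data.frame(pair_id = panel$pairs$pair_id,
                    subA_conserved = consA, subB_conserved = consB,
                    subA_outgroup_r = rA, subB_outgroup_r = rB,
                    euclidean_distance = d, pair_r = pr,
                    divergent = divergent, r_undefined = undef,
                    stringsAsFactors = FALSE)
  attr(out, "dist_threshold") <- thr
  out
}

#' Agglomerative average-linkage clustering of expression profiles
#'
#' Euclidean distance on log2(TPM+1) (or raw values), average linkage,
#' tree cut to exactly `k` clusters; deterministic.
#'
#' @param mat genes x contexts matrix.
#' @param k number of clusters.
#' @param log_transform cluster on log2(x+1) (default TRUE; use FALSE for
#'   raw counts such as splicing-event counts).
#' @return named integer vector of cluster labels.
#' @export
cluster_profiles <- function(mat, k, log_transform = TRUE) {
  if (k > nrow(mat)) stopf("k = %d exceeds number of rows (%d)",
                           k, nrow(mat))
  x <- if (log_transform) log2(mat + 1) else mat
  hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                      method = "average")
  stats::cutree(hc, k = k)
}

#' Classify homoeolog pairs into functionalization classes
#'
#' Precedence: (1) nonfunctionalized when at least one copy is below the
#' floor in every context; (2) neofunctionalized when exactly one copy is
#' conserved with the outgroup and the copies sit in different clusters;
#' (3) subfunctionalized when neither copy is conserved but the summed
#' (pseudo-ancestral) profile is conserved with the outgroup; (4)
#' coexpressed when both copies share a cluster; (5) otherwise
#' neofunctionalized.  Pairs lacking an outgroup are unclassifiable for
#' rules (2)/(3).
#'
#' @param panel an `expression_panel`.
#' @param clusters named cluster vector over homoeolog genes (from
#'   [cluster_profiles()] on the 2n homoeolog profiles).
#' @param conservation data.frame from [conservation_and_divergence()].
#' @param floor expression floor (default 1).
#' @param r_threshold correlation threshold for the summed profile.
#' @return data.frame per pair: `pair_id`, `class` in
#'   {"non-F","neo-F","sub-F","coexpressed","unclassifiable"}.
#' @export
classify_functionalization <- function(panel, clusters, conservation,
                                       floor = 1, r_threshold = 0.66) {
  m <- .pair_mats(panel)
  lo <- if (!is.null(m$o)) log2(m$o + 1) else NULL
  n <- nrow(panel$pairs)
  cls <- character(n)
  for (i in seq_len(n)) {
    a <- m$a[i, ]; b <- m$b[i, ]
    silentA <- all(a < floor); silentB <- all(b < floor)
    if (silentA || silentB) { cls[i] <- "non-F"; next }
    same_cluster <- clusters[[panel$pairs$subA[i]]] ==
      clusters[[panel$pairs$subB[i]]]
    if (is.null(lo)) {
      cls[i] <- if (same_cluster) "coexpressed" else "unclassifiable"
      next
    }
    cA <- isTRUE(conservation$subA_conserved[i])
    cB <- isTRUE(conservation$subB_conserved[i])
    if (xor(cA, cB) && !same_cluster) { cls[i] <- "neo-F"; next }
    if (!cA && !cB) {
      cs <- .cor_with_p(log2(a + b + 1), lo[i, ])
      if (isTRUE(cs[["r"]] > r_threshold && cs[["p"]] <= 0.05)) {
        cls[i] <- "sub-F"; next
      }
    }
    cls[i] <- if (same_cluster) "coexpressed" else "neo-F"
  }
  data.frame(pair_id = panel$pairs$pair_id, class = cls,
             stringsAsFactors = FALSE)
}

#' Cotranscription of homoeolog pairs
#'
#' A pair is cotranscribed in a context when both copies are at or above
#' the floor.
#'
#' @param panel an `expression_panel`.
#' @param floor expression floor.
#' @return list with `n_pairs`, `n_all_contexts`, `pct_all_contexts`,
#'   `n_ge3_contexts`, `pct_ge3_contexts` (percentages half-up, 1
#'   decimal) and per-pair context counts.
#' @export
cotranscription_summary <- function(panel, floor = 1) {
  m <- .pair_mats(panel)
  both <- (m$a >= floor) & (m$b >= floor)
  k <- rowSums(both)
  n <- nrow(panel$pairs)
  n_all <- sum(k == ncol(both))
  n_ge3 <- sum(k >= 3L)
  list(n_pairs = n,
       n_all_contexts = n_all,
       pct_all_contexts = round_half_up(100 * n_all / n, 1),
       n_ge3_contexts = n_ge3,
       pct_ge3_contexts = round_half_up(100 * n_ge3 / n, 1),
       contexts_cotranscribed = setNames(k, panel$pairs$pair_id))
}

#' Pseudo-ancestral dosage versus the diploid ortholog
#'
#' The pseudo-ancestral expression of a pair is the sum of the two
#' homoeolog TPMs; per context the summed values are compared with the
#' outgroup ortholog by a paired Wilcoxon test.
#'
#' @param panel an `expression_panel` (outgroup required).
#' @return data.frame per context: `context`, `median_sum`,
#'   `median_ortholog`, `median_difference`, `p_value`.
#' @export
pseudo_ancestral_dosage <- function(panel) {
  m <- .pair_mats(panel)
  if (is.null(m$o)) stopf("outgroup orthologs missing from panel")
  s <- m$a + m$b
  out <- lapply(seq_along(panel$contexts), function(j) {
    diff <- s[, j] - m$o[, j]
    p <- if (all(diff == 0)) 1 else
      suppressWarnings(stats::wilcox.test(s[, j], m$o[, j],
                                          paired = TRUE))$p.value
    data.frame(context = panel$contexts[j],
               median_sum = stats::median(s[, j]),
               median_ortholog = stats::median(m$o[, j]),
               median_difference = stats::median(diff),
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Divergent fraction across Ka/Ks bins with a trend test
#'
#' Pairs are split into `n_bins` quantile bins on Ka/Ks; the divergent
#' fraction per bin is reported with the Spearman rank correlation of bin
#' index versus fraction and a Cochran-Armitage-style proportion trend
#' test across bins.
#'
#' @param kaks numeric Ka/Ks ratios (undefined values excluded, counted).
#' @param divergent logical divergence flags, same length.
#' @param n_bins number of quantile bins (default 5).
#' @return list with `bins` (data.frame: bin, n, n_divergent, fraction),
#'   `rho`, `trend_p`, `n_excluded`.
#' @export
kaks_divergence_trend <- function(kaks, divergent, n_bins = 5) {
  stopifnot(length(kaks) == length(divergent))
  ok <- is.finite(kaks) & !is.na(divergent)
  n_excluded <- sum(!ok)
  kaks <- kaks[ok]; divergent <- divergent[ok]
  if (length(kaks) < n_bins * 10L)
    stopf("need at least %d pairs with defined Ka/Ks", n_bins * 10L)
  q <- stats::quantile(kaks, probs = seq(0, 1, length.out = n_bins + 1))
  q[1] <- -Inf; q[length(q)] <- Inf
  bin <- cut(kaks, breaks = unique(q), labels = FALSE)
  tab <- data.frame(bin = sort(unique(bin)))
  tab$n <- as.integer(table(bin))
  tab$n_divergent <- as.integer(tapply(divergent, bin, sum))
  tab$fraction <- tab$n_divergent / tab$n
  rho <- suppressWarnings(stats::cor(tab$bin, tab$fraction,
                                     method = "spearman"))
  # a pooled fraction of exactly 0 or 1 leaves no trend to test
  trend_p <- if (sum(tab$n_divergent) %in% c(0L, sum(tab$n)))
    NA_real_ else stats::prop.trend.test(tab$n_divergent, tab$n)$p.value
  list(bins = tab, rho = rho, trend_p = trend_p,
       n_excluded = n_excluded)
}

#' Balance of differential expression between subgenomes
#'
#' 2x2 chi-square of DE/not-DE by subgenome, plus the percentage of
#' pairs with exactly one differentially expressed copy.
#'
#' @param deg_flags_subA,deg_flags_subB logical vectors, one element per
#'   pair.
#' @return list with `chisq_p`, `n_one_de`, `pct_one_de`, `n_subA_de`,
#'   `n_subB_de`.
#' @export
deg_balance_test <- function(deg_flags_subA, deg_flags_subB) {
  stopifnot(length(deg_flags_subA) == length(deg_flags_subB))
  n <- length(deg_flags_subA)
  tab <- rbind(c(sum(deg_flags_subA), n - sum(deg_flags_subA)),
               c(sum(deg_flags_subB), n - sum(deg_flags_subB)))
  p <- if (identical(tab[1, ], tab[2, ])) 1 else
    suppressWarnings(stats::chisq.test(tab, correct = TRUE))$p.value
  one <- xor(deg_flags_subA, deg_flags_subB)
  list(chisq_p = p, n_one_de = sum(one),
       pct_one_de = round_half_up(100 * sum(one) / n, 1),
       n_subA_de = sum(deg_flags_subA), n_subB_de = sum(deg_flags_subB))
}

#' Classify trans-splicing events by partner subgenomes
#'
#' A fusion transcript joining two genes is intra-A, intra-B or
#' inter-subgenome according to the subgenome of each partner's host
#' chromosome; scaffold-located or unlocated partners are excluded and
#' counted.
#'
#' @param fusion_calls data.frame with `gene5prime`, `gene3prime`.
#' @param locations data.frame with `gene_id`, `chromosome`.
#' @param assignments data.frame from [assign_chromosome_subgenomes()].
#' @return list with `calls` (input rows plus `class`), `counts` (named
#'   vector over intra-A/intra-B/inter-subgenome), `n_excluded`.
#' @export
classify_trans_splicing <- function(fusion_calls, locations, assignments) {
  sub_of <- function(genes) {
    chrom <- locations$chromosome[match(genes, locations$gene_id)]
    sub <- assignments$subgenome[match(chrom, assignments$chromosome)]
    sub[!is.na(chrom) & startsWith(chrom, "scaffold:")] <- NA
    sub
  }
  s5 <- sub_of(fusion_calls$gene5prime)
  s3 <- sub_of(fusion_calls$gene3prime)
  cls <- ifelse(is.na(s5) | is.na(s3), NA,
                ifelse(s5 == "A" & s3 == "A", "intra-A",
                       ifelse(s5 == "B" & s3 == "B", "intra-B",
                              "inter-subgenome")))
  out <- fusion_calls
  out$class <- cls
  counts <- table(factor(cls, levels = c("intra-A", "intra-B",
                                         "inter-subgenome")))
  list(calls = out, counts = c(counts), n_excluded = sum(is.na(cls)))
}
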