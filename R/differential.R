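# Differential abundance between exosome and whole-milk libraries.
#
# Counts are normalized by total mapped reads (CPM). Each miRNA is
# tested with a conditional exact test for overdispersed counts: the two
# per-condition count sums (after scaling to a common effective library
# size) are split-tested conditional on their total. Under the null the
# conditional distribution of the split is a Dirichlet-multinomial-type
# law that depends only on the negative-binomial shape parameters
# r = n_reps / phi of each side, not on the unknown mean; with phi = 0
# it reduces to a binomial split with probability nA / (nA + nB). The
# two-sided p-value sums the probabilities of all splits no more likely
# than the observed one.
#
# Fold changes are classified on two tiers: ratio > 2 ("different") and
# ratio > 10 ("significantly different"), each requiring p < alpha, with
# symmetric DOWN marks below 1/2 and 1/10.

#' Counts per million mapped reads
#'
#' @param counts a `mir_counts` object, or a numeric matrix (rows
#'   features, columns samples) with `lib_sizes` supplied.
#' @param lib_sizes per-sample library sizes (total mapped reads); taken
#'   from the `mir_counts` object if omitted.
#' @return numeric matrix of CPM values.
#' @export
cpm <- function(counts, lib_sizes = NULL) {
  if (inherits(counts, "mir_counts")) {
    lib_sizes <- counts$lib_sizes
    counts <- counts$counts
  }
  if (is.null(lib_sizes)) stop("lib_sizes required", call. = FALSE)
  lib_sizes <- lib_sizes[colnames(counts)]
  if (any(is.na(lib_sizes)) || any(lib_sizes <= 0)) {
    stop("library sizes must be positive for every sample", call. = FALSE)
  }
  sweep(counts, 2, lib_sizes, "/") * 1e6
}

#' Pooled method-of-moments common dispersion
#'
#' Estimates a single negative-binomial dispersion phi (variance =
#' mu + phi * mu^2) pooled over all miRNAs, from library-size-scaled
#' counts (each sample scaled to the geometric mean library size).
#' Within each condition, per-miRNA sample means m and variances v give
#' the moment relation v - m = phi * m^2; pooling sums numerator
#' (v - m) and denominator (m^2 - v/n, the unbiased estimate of mu^2)
#' over all miRNA-condition pairs. The estimate is floored at 0.
#'
#' @param counts `mir_counts` or numeric matrix.
#' @param groups factor/character of condition labels, one per column.
#' @param lib_sizes library sizes when `counts` is a bare matrix.
#' @return list of class `mir_dispersion`: `phi` (common dispersion) and
#'   `n_used` (miRNA-condition pairs contributing).
#' @export
estimate_common_dispersion <- function(counts, groups, lib_sizes = NULL) {
  if (inherits(counts, "mir_counts")) {
    lib_sizes <- counts$lib_sizes
    counts <- counts$counts
  }
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(counts))
  if (max(table(groups)) < 2) {
    warning("no condition has replicates; returning phi = 0")
    return(structure(list(phi = 0, n_used = 0L), class = "mir_dispersion"))
  }
  ref <- exp(mean(log(lib_sizes)))
  scaled <- sweep(counts, 2, ref / lib_sizes, "*")
  num <- 0; den <- 0; n_used <- 0L
  for (g in levels(groups)) {
    sub <- scaled[, groups == g, drop = FALSE]
    n <- ncol(sub)
    if (n < 2) next
    m <- rowMeans(sub)
    v <- apply(sub, 1, var)
    keep <- m > 0
    num <- num + sum(v[keep] - m[keep])
    den <- den + sum(pmax(m[keep]^2 - v[keep] / n, 0))
    n_used <- n_used + sum(keep)
  }
  phi <- if (den > 0) max(num / den, 0) else 0
  structure(list(phi = phi, n_used = n_used), class = "mir_dispersion")
}

#' Conditional exact test for a two-group count split
#'
#' Tests whether `sumB` differs from `sumA` beyond sampling noise, where
#' each sum aggregates `nA` / `nB` replicate negative-binomial counts of
#' common dispersion `phi` (counts must be scaled to a common effective
#' library size before summation). Conditional on s = sumA + sumB, the
#' split follows P(a) proportional to C(a + rA - 1, a) *
#' C(s - a + rB - 1, s - a) with rA = nA/phi, rB = nB/phi (independent
#' of the unknown mean because both sides share the NB probability
#' parameter); for phi = 0 it is Binomial(s, nA/(nA+nB)). The two-sided
#' p-value is the total probability of all splits with probability <=
#' that of the observed split.
#'
#' @param sumA,sumB non-negative integer count sums.
#' @param nA,nB replicate counts per condition.
#' @param phi common NB dispersion (>= 0).
#' @return p-value in (0, 1].
#' @export
exact_count_test <- function(sumA, sumB, nA, nB, phi = 0) {
  if (any(c(sumA, sumB) < 0) || any(c(nA, nB) < 1) || phi < 0) {
    stop("counts must be non-negative, replicate numbers >= 1, phi >= 0",
         call. = FALSE)
  }
  sumA <- round(sumA); sumB <- round(sumB)
  s <- sumA + sumB
  if (s == 0) return(1)
  a <- 0:s
  logp <- if (phi == 0) {
    dbinom(a, s, nA / (nA + nB), log = TRUE)
  } else {
    rA <- nA / phi; rB <- nB / phi
    lgamma(a + rA) - lgamma(a + 1) + lgamma(s - a + rB) - lgamma(s - a + 1)
  }
  logp <- logp - max(logp)
  p <- exp(logp); p <- p / sum(p)
  p_obs <- p[sumA + 1L]
  keep <- p <= p_obs * (1 + 1e-10)
  if (all(keep)) return(1)  # observed split is the mode
  min(1, sum(p[keep]))
}

#' Linear and log2 fold ratio with pseudocount
#'
#' ratio = (meanCpmB + pseudo) / (meanCpmA + pseudo); the pseudocount
#' keeps ratios finite when one condition has zero counts (as for a
#' detected-in-exosome-only miRNA).
#'
#' @param mean_cpm_a,mean_cpm_b per-condition mean CPM (vectorized).
#' @param pseudo positive pseudocount on the CPM scale.
#' @return list with `ratio` and `log2_ratio`.
#' @export
fold_ratio <- function(mean_cpm_a, mean_cpm_b, pseudo) {
  stopifnot(pseudo > 0)
  ratio <- (mean_cpm_b + pseudo) / (mean_cpm_a + pseudo)
  list(ratio = ratio, log2_ratio = log2(ratio))
}

#' Two-tier fold-change classification
#'
#' `mark2` is UP iff p < alpha and ratio > fc2 (DOWN iff p < alpha and
#' ratio < 1/fc2); `mark10` likewise with fc10. Otherwise NS. A mark10
#' call always implies the same-direction mark2 call when fc10 >= fc2.
#'
#' @param ratio linear fold ratios (vectorized).
#' @param p_value p-values.
#' @param alpha significance level (default 0.05).
#' @param fc2,fc10 the two fold thresholds (defaults 2 and 10).
#' @return data frame with columns `mark2`, `mark10` (UP/DOWN/NS).
#' @export
classify <- function(ratio, p_value, alpha = 0.05, fc2 = 2, fc10 = 10) {
  sig <- p_value < alpha
  tier <- function(fc) {
    ifelse(sig & ratio > fc, "UP", ifelse(sig & ratio < 1 / fc, "DOWN", "NS"))
  }
  data.frame(mark2 = tier(fc2), mark10 = tier(fc10), stringsAsFactors = FALSE)
}

#' Differential abundance analysis
#'
#' Runs the full differential stage: CPM normalization, pooled common
#' dispersion, per-miRNA conditional exact test on count sums scaled to
#' the geometric-mean library size, pseudocounted fold ratios
#' (condition B vs condition A), and two-tier classification. miRNAs
#' with all-zero counts are excluded (with a message).
#'
#' @param counts `mir_counts` or count matrix.
#' @param groups condition labels per column; `ref_group` is condition
#'   A (the denominator, e.g. whole milk).
#' @param ref_group reference condition; default first level.
#' @param lib_sizes library sizes when `counts` is a bare matrix.
#' @param alpha significance level (default 0.05).
#' @param fc2,fc10 fold-change tiers (defaults 2, 10).
#' @param pseudo CPM pseudocount; default is the CPM equivalent of 0.5
#'   reads at the smallest library.
#' @param phi override for the common dispersion (default: estimated).
#' @return list of class `mir_differential`: `table` (miRNA, per-group
#'   mean counts and CPM, ratio, log2_ratio, p_value, mark2, mark10),
#'   `volcano` (miRNA, log2_ratio, neg_log10_p), `phi`, and the
#'   thresholds used.
#' @export
run_differential <- function(counts, groups, ref_group = NULL,
                             lib_sizes = NULL, alpha = 0.05, fc2 = 2,
                             fc10 = 10, pseudo = NULL, phi = NULL) {
  if (inherits(counts, "mir_counts")) {
    lib_sizes <- counts$lib_sizes
    counts <- counts$counts
  }
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) {
    stop("exactly two condition labels are required", call. = FALSE)
  }
  if (!is.null(ref_group)) groups <- stats::relevel(groups, ref = ref_group)
  gA <- levels(groups)[1]; gB <- levels(groups)[2]

  nz <- rowSums(counts) > 0
  if (any(!nz)) {
    message(sum(!nz), " miRNA(s) with all-zero counts excluded")
  }
  mat <- counts[nz, , drop = FALSE]
  cpm_mat <- cpm(mat, lib_sizes)
  if (is.null(phi)) {
    phi <- estimate_common_dispersion(mat, groups, lib_sizes)$phi
  }
  if (is.null(pseudo)) pseudo <- 0.5 / min(lib_sizes) * 1e6

  ref <- exp(mean(log(lib_sizes)))
  scaled <- sweep(mat, 2, ref / lib_sizes, "*")
  sumA <- round(rowSums(scaled[, groups == gA, drop = FALSE]))
  sumB <- round(rowSums(scaled[, groups == gB, drop = FALSE]))
  nA <- sum(groups == gA); nB <- sum(groups == gB)
  pv <- vapply(seq_len(nrow(mat)), function(i)
    exact_count_test(sumA[i], sumB[i], nA, nB, phi), 0)

  mean_cpm_a <- rowMeans(cpm_mat[, groups == gA, drop = FALSE])
  mean_cpm_b <- rowMeans(cpm_mat[, groups == gB, drop = FALSE])
  fr <- fold_ratio(mean_cpm_a, mean_cpm_b, pseudo)
  marks <- classify(fr$ratio, pv, alpha, fc2, fc10)

  tab <- data.frame(
    miRNA = rownames(mat),
    mean_count_A = rowMeans(mat[, groups == gA, drop = FALSE]),
    mean_count_B = rowMeans(mat[, groups == gB, drop = FALSE]),
    mean_cpm_A = mean_cpm_a,
    mean_cpm_B = mean_cpm_b,
    p_value = pv,
    ratio = fr$ratio,
    log2_ratio = fr$log2_ratio,
    mark2 = marks$mark2,
    mark10 = marks$mark10,
    row.names = NULL,
    stringsAsFactors = FALSE)
  volcano <- data.frame(miRNA = tab$miRNA, log2_ratio = tab$log2_ratio,
                        neg_log10_p = -log10(pmax(tab$p_value, 1e-300)),
                        stringsAsFactors = FALSE)
  structure(list(table = tab, volcano = volcano, phi = phi,
                 groups = c(A = gA, B = gB),
                 alpha = alpha, fc2 = fc2, fc10 = fc10, pseudo = pseudo),
            class = "mir_differential")
}

#' @export
print.mir_differential <- function(x, ...) {
  cat(sprintf(
    "mir_differential: %d miRNAs tested (%s vs %s), phi = %.4g\n",
    nrow(x$table), x$groups[["B"]], x$groups[["A"]], x$phi))
  cat(sprintf("mark2 UP/DOWN: %d/%d; mark10 UP/DOWN: %d/%d\n",
              sum(x$table$mark2 == "UP"), sum(x$table$mark2 == "DOWN"),
              sum(x$table$mark10 == "UP"), sum(x$table$mark10 == "DOWN")))
  invisible(x)
}
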