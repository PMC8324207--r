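# SNP panel construction and genotype simulation.

#' Define a panel of candidate SNPs for a polygenic risk score
#'
#' A panel row describes one biallelic variant by its identifier, risk
#' allele, population risk-allele frequency, per-allele log odds ratio
#' (the PRS weight), and an optional inbreeding coefficient `f` used to
#' force a departure from Hardy-Weinberg equilibrium when genotypes are
#' simulated. Under `f = 0` the genotype frequencies are the HWE
#' proportions `(1-p)^2, 2p(1-p), p^2`; positive `f` removes
#' heterozygote mass, `f = 1` removes it entirely.
#'
#' @param snp_id character vector of unique variant identifiers.
#' @param risk_allele nucleotide symbol of the risk allele per SNP.
#' @param raf risk-allele frequency per SNP, strictly inside (0, 1).
#' @param weight per-allele log odds ratio per SNP (finite).
#' @param inbreeding_f HWE-departure coefficient per SNP in (-1, 1].
#'   Must satisfy `f >= -p/(1-p)` and `f >= -(1-p)/p` so all three
#'   genotype frequencies stay non-negative.
#'
#' @return A `data.frame` of class `snp_panel` with one row per SNP.
#' @export
#' @examples
#' snp_panel("rs1", "A", raf = 0.3, weight = log(1.2))
snp_panel <- function(snp_id, risk_allele, raf, weight, inbreeding_f = 0) {
  n <- length(snp_id)
  risk_allele <- rep_len(risk_allele, n)
  raf <- rep_len(raf, n)
  weight <- rep_len(weight, n)
  inbreeding_f <- rep_len(inbreeding_f, n)
  if (anyDuplicated(snp_id)) {
    stop("snp_id values must be unique", call. = FALSE)
  }
  if (any(raf <= 0 | raf >= 1)) {
    stop("invalid SNP spec: raf must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  if (any(!is.finite(weight))) {
    stop("invalid SNP spec: weights must be finite", call. = FALSE)
  }
  if (any(inbreeding_f <= -1 | inbreeding_f > 1)) {
    stop("invalid SNP spec: inbreeding_f must lie in (-1, 1]", call. = FALSE)
  }
  gf <- genotype_freqs(raf, inbreeding_f)
  if (any(gf < -1e-12)) {
    stop("invalid SNP spec: inbreeding_f too negative for raf, ",
         "genotype frequencies would be negative", call. = FALSE)
  }
  structure(
    data.frame(snp_id = as.character(snp_id),
               risk_allele = toupper(as.character(risk_allele)),
               raf = raf, weight = weight, inbreeding_f = inbreeding_f,
               stringsAsFactors = FALSE),
    class = c("snp_panel", "data.frame")
  )
}

# Genotype frequencies (n x 3: dosage 0, 1, 2) under allele frequency p
# and inbreeding coefficient f.
genotype_freqs <- function(p, f) {
  cbind(`0` = (1 - p)^2 + f * p * (1 - p),
        `1` = 2 * p * (1 - p) * (1 - f),
        `2` = p^2 + f * p * (1 - p))
}

#' Default 24-SNP candidate panel with a forced HWE failure pattern
#'
#' Builds a candidate panel of the size used for targeted colorectal
#' neoplasm genotyping: 24 SNPs of which a configurable number carry a
#' strong inbreeding coefficient so that their simulated genotypes
#' depart from Hardy-Weinberg equilibrium and are removed by the
#' quality filter, leaving the remainder for PRS construction.
#'
#' Risk-allele frequencies and per-allele log odds ratios are drawn once
#' from ranges typical of common colorectal cancer susceptibility
#' variants (RAF 0.1-0.9, OR 1.05-1.35) under the given seed, so the
#' panel is reproducible.
#'
#' @param n_snps total number of candidate SNPs.
#' @param n_hwe_fail number of SNPs given inbreeding coefficient
#'   `hwe_fail_f`.
#' @param hwe_fail_f inbreeding coefficient assigned to the failing SNPs.
#' @param seed integer seed controlling the drawn frequencies/weights.
#'
#' @return A [snp_panel()].
#' @export
default_snp_panel <- function(n_snps = 24, n_hwe_fail = 5,
                              hwe_fail_f = 0.5, seed = 20210716) {
  stopifnot(n_hwe_fail >= 0, n_hwe_fail <= n_snps)
  rs <- local_rng(seed)
  raf <- round(stats::runif(n_snps, 0.10, 0.90), 3)
  weight <- round(log(stats::runif(n_snps, 1.05, 1.35)), 4)
  f <- rep(0, n_snps)
  if (n_hwe_fail > 0) {
    # spread the failing SNPs through the panel rather than blocking them
    f[round(seq(1, n_snps, length.out = n_hwe_fail))] <- hwe_fail_f
  }
  snp_panel(sprintf("rs%05d", seq_len(n_snps) * 101 + 11),
            sample(c("A", "C", "G", "T"), n_snps, replace = TRUE),
            raf = raf, weight = weight, inbreeding_f = f)
}

#' Simulate unphased genotype dosages for a SNP panel
#'
#' Draws, for each SNP independently, genotypes coded as 0/1/2 copies of
#' the risk allele from the frequencies implied by the panel's
#' risk-allele frequency and inbreeding coefficient:
#' `((1-p)^2 + f p (1-p), 2 p (1-p) (1-f), p^2 + f p (1-p))`.
#' Missingness is applied entrywise at rate `missing_rate` (`NA`).
#'
#' @param panel a [snp_panel()].
#' @param n number of subjects (rows), at least 1.
#' @param seed integer seed; a fixed seed yields an identical matrix.
#' @param missing_rate per-entry probability of a missing genotype.
#'
#' @return Integer matrix `n x nrow(panel)`, dimnames
#'   `(subject id, snp_id)`, values 0/1/2 or `NA`.
#' @export
simulate_genotypes <- function(panel, n, seed, missing_rate = 0) {
  stopifnot(inherits(panel, "snp_panel"), nrow(panel) >= 1)
  if (length(n) != 1 || is.na(n) || n < 1) {
    stop("invalid argument: n must be a positive count", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate > 1) {
    stop("invalid argument: missing_rate must lie in [0, 1]", call. = FALSE)
  }
  rs <- local_rng(seed)
  freqs <- genotype_freqs(panel$raf, panel$inbreeding_f)
  freqs[freqs < 0] <- 0
  g <- matrix(NA_integer_, nrow = n, ncol = nrow(panel),
              dimnames = list(sprintf("S%05d", seq_len(n)), panel$snp_id))
  for (j in seq_len(nrow(panel))) {
    g[, j] <- sample(0:2, n, replace = TRUE, prob = freqs[j, ])
  }
  if (missing_rate > 0) {
    g[stats::runif(length(g)) < missing_rate] <- NA_integer_
  }
  g
}

#' Deterministic genotype fixture matching expected HWE pass/fail pattern
#'
#' Builds a genotype matrix in which each SNP's genotype counts equal the
#' rounded expected counts under its risk-allele frequency and
#' inbreeding coefficient. SNPs with `inbreeding_f = 0` therefore sit
#' essentially exactly on their Hardy-Weinberg proportions (chi-square
#' near 0), while SNPs with a large coefficient fail the HWE test
#' decisively, so the filter's pass/fail pattern reflects the panel's
#' design rather than sampling noise. Useful as a reference fixture when
#' an exact retained-SNP count is required.
#'
#' @param panel a [snp_panel()].
#' @param n subjects per SNP.
#' @return Integer matrix `n x nrow(panel)` of dosages 0/1/2.
#' @export
hwe_pattern_genotypes <- function(panel, n = 2000) {
  stopifnot(inherits(panel, "snp_panel"), n >= 10)
  freqs <- genotype_freqs(panel$raf, panel$inbreeding_f)
  freqs[freqs < 0] <- 0
  g <- matrix(NA_integer_, nrow = n, ncol = nrow(panel),
              dimnames = list(sprintf("S%05d", seq_len(n)), panel$snp_id))
  for (j in seq_len(nrow(panel))) {
    counts <- round(freqs[j, ] * n)
    # rounding can leave the total off by one either way
    counts[which.max(counts)] <- counts[which.max(counts)] + (n - sum(counts))
    g[, j] <- rep(0:2, times = counts)
  }
  g
}

# Validate and apply a seed. All exported simulators take an explicit
# seed so that a fixed seed yields byte-identical output.
local_rng <- function(seed) {
  if (length(seed) != 1 || is.na(seed) || !is.finite(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  set.seed(as.integer(seed))
  invisible(seed)
}
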