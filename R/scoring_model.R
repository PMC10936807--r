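#' Convert a Phred quality score to a per-base error probability
#'
#' Inverts the Phred transform: an error probability of `10^(-q/10)`,
#' so q = 20 corresponds to a 1% chance that the called base is wrong.
#' Quality 0 yields probability 1 (a completely uninformative base).
#'
#' @param q Integer vector of Phred-scaled base quality scores (>= 0).
#' @return Numeric vector of error probabilities in (0, 1].
#' @examples
#' per_base_error(c(0, 20, 30))
#' @export
per_base_error <- function(q) {
  if (any(q < 0)) stop("Phred quality scores must be >= 0")
  pmin(10^(-0.1 * q), 1)
}

#' Multinomial probability of a read's match/mismatch counts under one haplotype
#'
#' Probability that a read carrying `k_m` matches and `k_nm` mismatches to a
#' candidate haplotype arose from that haplotype, under a global mean
#' sequencing error rate `epsilon`. A mismatch requires a sequencing error to
#' one specific wrong base out of three, hence the `epsilon/3` term:
#'
#' \deqn{P = \frac{n!}{k_{nm}!\,k_m!} (\epsilon/3)^{k_{nm}} (1-\epsilon)^{k_m}}
#'
#' The multinomial coefficient can be dropped (`use_coefficient = FALSE`);
#' it cancels in likelihood ratios whenever the per-haplotype counts are
#' complementary, but not in general, so it is kept by default.
#'
#' @param k_m Number of variant positions whose read base matches the haplotype.
#' @param k_nm Number of variant positions whose read base mismatches.
#' @param epsilon Global mean per-base sequencing error rate, in (0, 1).
#' @param use_coefficient Include the multinomial coefficient term?
#' @return Probability on the linear scale.
#' @examples
#' multinomial_prob_global(2, 0, 0.03)  # 0.97^2
#' @export
multinomial_prob_global <- function(k_m, k_nm, epsilon, use_coefficient = TRUE) {
  stopifnot(k_m >= 0, k_nm >= 0)
  if (epsilon <= 0 || epsilon >= 1) {
    stop("epsilon must lie strictly inside (0, 1)")
  }
  n <- k_m + k_nm
  lcoef <- if (use_coefficient) lgamma(n + 1) - lgamma(k_nm + 1) - lgamma(k_m + 1) else 0
  exp(lcoef + k_nm * log(epsilon / 3) + k_m * log(1 - epsilon))
}

#' Assemble per-variant read observations for scoring
#'
#' One row per phased heterozygous variant covered by an aligned read: the
#' read base observed there, its per-base error probability (from the Phred
#' quality via [per_base_error()], or a global fallback), and the allele each
#' haplotype carries at that site.
#'
#' @param observed_base Character vector of read bases at the variant sites.
#' @param base_error Numeric vector of per-base error probabilities in (0, 1].
#' @param hap_alleles Character matrix, one row per site, one column per
#'   haplotype, giving the phased allele of each haplotype at that site.
#' @param pos Optional variant positions (1-based), for bookkeeping.
#' @param phase_set Optional phase-set identifier(s).
#' @return A data frame of class `read_observations` with columns
#'   `observed_base`, `base_error` and `allele_h1`, `allele_h2`, ...
#' @export
read_observations <- function(observed_base, base_error, hap_alleles,
                              pos = NULL, phase_set = NULL) {
  hap_alleles <- as.matrix(hap_alleles)
  n <- length(observed_base)
  stopifnot(length(base_error) == n, nrow(hap_alleles) == n || n == 0L)
  if (any(base_error <= 0 | base_error > 1)) {
    stop("base_error must lie in (0, 1]")
  }
  obs <- data.frame(observed_base = as.character(observed_base),
                    base_error = as.numeric(base_error),
                    stringsAsFactors = FALSE)
  l <- if (n == 0L) ncol(hap_alleles) %||% 2L else ncol(hap_alleles)
  for (i in seq_len(l)) obs[[paste0("allele_h", i)]] <- if (n) hap_alleles[, i] else character(0)
  if (!is.null(pos)) obs$pos <- pos
  if (!is.null(phase_set)) obs$phase_set <- phase_set
  class(obs) <- c("read_observations", "data.frame")
  obs
}

obs_ploidy <- function(observations) {
  sum(grepl("^allele_h", names(observations)))
}

obs_allele_matrix <- function(observations) {
  cols <- grep("^allele_h", names(observations), value = TRUE)
  as.matrix(observations[cols])
}

#' Log10 multinomial probability with per-base error rates
#'
#' Generalizes [multinomial_prob_global()] by using each covered site's own
#' per-base error probability instead of one global rate. For haplotype i,
#' with match/mismatch indicators x_a, y_a at site a:
#'
#' \deqn{\log_{10} P_{h_i} = \sum_a \left[x_a \log_{10}(1 - e_a) +
#'   y_a \log_{10}(e_a/3)\right] + \log_{10}\frac{n!}{k_{nm}!\,k_m!}}
#'
#' Computed entirely in log space (factorials via `lgamma`). Error
#' probabilities are clamped to `[1e-12, 1 - 1e-12]` so quality-0 bases
#' remain uninformative rather than producing `log(0)`.
#'
#' @param observations A [read_observations()] data frame.
#' @param haplotype_index Which haplotype column to score against.
#' @param use_coefficient Include the multinomial coefficient term?
#' @return A single log10 probability (0 for an empty observation set).
#' @export
log10_multinomial_prob <- function(observations, haplotype_index,
                                   use_coefficient = TRUE) {
  n <- nrow(observations)
  if (n == 0L) return(0)
  alleles <- obs_allele_matrix(observations)
  if (haplotype_index < 1L || haplotype_index > ncol(alleles)) {
    stop("haplotype_index out of range")
  }
  x <- observations$observed_base == alleles[, haplotype_index]
  e <- clamp_error(observations$base_error)
  k_m <- sum(x)
  k_nm <- n - k_m
  lcoef <- if (use_coefficient) {
    (lgamma(n + 1) - lgamma(k_nm + 1) - lgamma(k_m + 1)) / log(10)
  } else 0
  sum(ifelse(x, log10(1 - e), log10(e / 3))) + lcoef
}

#' Uniform prior over haplotypes
#'
#' Equal a-priori probability of a read originating from any haplotype in a
#' phase set of ploidy `l`.
#'
#' @param l Ploidy (number of haplotypes), >= 1.
#' @return `1 / l`.
#' @export
uniform_prior <- function(l) {
  stopifnot(l >= 1)
  1 / l
}

#' Posterior match probability for each haplotype (log10)
#'
#' Odds-style posterior for haplotype i: the prior-weighted likelihood of i
#' divided by the summed prior-weighted likelihoods of all *other*
#' haplotypes,
#' \deqn{P(r)_{h_i} = \frac{P_{h_i}\beta_{h_i}}
#'   {\sum_j P_{h_j}\beta_{h_j} - P_{h_i}\beta_{h_i}}}
#' evaluated in log space via log-sum-exp over the excluded terms. For a
#' diploid this is simply the likelihood ratio of the two haplotypes.
#'
#' @param log10_probs Per-haplotype log10 likelihoods.
#' @param priors Per-haplotype prior probabilities (default uniform).
#' @return Per-haplotype log10 posterior odds.
#' @export
posterior_log10 <- function(log10_probs, priors = NULL) {
  l <- length(log10_probs)
  if (l < 2L) stop("posterior requires at least 2 haplotypes (denominator vanishes)")
  priors <- priors %||% rep(uniform_prior(l), l)
  stopifnot(length(priors) == l)
  lp <- log10_probs + log10(priors)
  vapply(seq_len(l), function(i) lp[i] - log10_sum(lp[-i]), numeric(1))
}

#' Likelihood ratio of each haplotype versus all others (log10)
#'
#' Same exclusion structure as [posterior_log10()], applied to the
#' posteriors: haplotype i's posterior against the sum of the rest. The
#' maximum over haplotypes is the read's log-likelihood ratio (LLR) score.
#'
#' @param log10_posteriors Per-haplotype log10 posteriors.
#' @return Per-haplotype log10 likelihood ratios.
#' @export
likelihood_ratio_log10 <- function(log10_posteriors) {
  l <- length(log10_posteriors)
  if (l < 2L) stop("likelihood ratio requires at least 2 haplotypes")
  vapply(seq_len(l),
         function(i) log10_posteriors[i] - log10_sum(log10_posteriors[-i]),
         numeric(1))
}

#' Score a read against every haplotype of a phase set
#'
#' Runs the full scoring chain for one read: per-haplotype multinomial
#' likelihoods (per-base error rates by default, or the global-epsilon model
#' when `per_base_mode = FALSE`), uniform priors, posterior odds and
#' likelihood ratios. The best haplotype is the LLR argmax; two or more
#' haplotypes within `tie_tol` of the maximum constitute a tie, which
#' downstream callers translate into an "untagged" label.
#'
#' @param observations A non-empty [read_observations()] data frame.
#' @param ploidy Number of haplotypes (defaults to the observation columns).
#' @param epsilon_global Global mean error rate; required when
#'   `per_base_mode = FALSE`.
#' @param use_coefficient Include the multinomial coefficient?
#' @param per_base_mode Use each base's own quality-derived error rate?
#' @param tie_tol Absolute tolerance on log10 LLR for declaring ties.
#' @return A `haplotag_score` list: `log10_prob_by_haplotype`,
#'   `posterior_by_haplotype`, `lr_by_haplotype`, `best_haplotype`, `llr`,
#'   `tie`, `n_variants`, `n_matches_best`, `n_mismatches_best`,
#'   `mean_epsilon_used`.
#' @export
score_read <- function(observations, ploidy = NULL, epsilon_global = NULL,
                       use_coefficient = TRUE, per_base_mode = TRUE,
                       tie_tol = 1e-9) {
  n <- nrow(observations)
  if (n == 0L) stop("score_read requires at least one observation; reads overlapping no variants are untaggable")
  l <- ploidy %||% obs_ploidy(observations)
  if (!per_base_mode) {
    if (is.null(epsilon_global)) {
      stop("epsilon_global is required when per_base_mode = FALSE")
    }
    observations$base_error <- rep(epsilon_global, n)
  }
  alleles <- obs_allele_matrix(observations)[, seq_len(l), drop = FALSE]
  match_mat <- observations$observed_base == alleles  # n x l indicator x_a
  log10_probs <- vapply(seq_len(l), function(i) {
    log10_multinomial_prob(observations, i, use_coefficient = use_coefficient)
  }, numeric(1))
  post <- posterior_log10(log10_probs)
  lr <- likelihood_ratio_log10(post)
  best <- which.max(lr)
  llr <- lr[best]
  tie <- sum(lr >= llr - tie_tol) >= 2L
  structure(list(
    log10_prob_by_haplotype = log10_probs,
    posterior_by_haplotype = post,
    lr_by_haplotype = lr,
    best_haplotype = best,
    llr = llr,
    tie = tie,
    n_variants = n,
    n_matches_best = sum(match_mat[, best]),
    n_mismatches_best = n - sum(match_mat[, best]),
    mean_epsilon_used = mean(observations$base_error)
  ), class = "haplotag_score")
}

#' @export
print.haplotag_score <- function(x, ...) {
  cat(sprintf("haplotag score: best haplotype h%d, LLR = %.4f%s (%d variants: %d match / %d mismatch)\n",
              x$best_haplotype, x$llr, if (x$tie) " [tie]" else "",
              x$n_variants, x$n_matches_best, x$n_mismatches_best))
  invisible(x)
}
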