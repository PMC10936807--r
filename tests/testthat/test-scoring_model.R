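test_that("Phred conversion inverts the quality transform", {
  expect_equal(per_base_error(20), 0.01)
  expect_equal(per_base_error(0), 1.0)
  expect_equal(per_base_error(30), 0.001)
  expect_error(per_base_error(-1), "must be >= 0")
})

test_that("global multinomial probability matches direct evaluation", {
  expect_equal(multinomial_prob_global(2, 0, 0.03), 0.97^2, tolerance = 1e-12)
  # independent arithmetic: coefficient via choose()
  expect_equal(multinomial_prob_global(1, 1, 0.03),
               choose(2, 1) * 0.01 * 0.97, tolerance = 1e-12)
  expect_equal(multinomial_prob_global(1, 1, 0.03), 0.0194, tolerance = 1e-12)
  expect_equal(multinomial_prob_global(0, 0, 0.5), 1.0)
  expect_equal(multinomial_prob_global(3, 2, 0.1, use_coefficient = FALSE),
               (0.1 / 3)^2 * 0.9^3, tolerance = 1e-12)
  expect_error(multinomial_prob_global(1, 1, 0), "epsilon")
  expect_error(multinomial_prob_global(1, 1, 1), "epsilon")
})

test_that("per-base log-space likelihood reduces to the global model when errors are constant", {
  # exhaustive over all (k_m, k_nm) with n <= 10
  eps <- 0.03
  for (n in 0:10) {
    for (k_m in 0:n) {
      k_nm <- n - k_m
      bases <- c(rep("A", k_m), rep("T", k_nm))
      obs <- make_obs(bases, rep(eps, n), h1 = rep("A", n), h2 = rep("C", n))
      lhs <- 10^log10_multinomial_prob(obs, 1)
      rhs <- multinomial_prob_global(k_m, k_nm, eps)
      expect_equal(lhs, rhs, tolerance = 1e-12)
    }
  }
})

test_that("log-space likelihood handles edge observations", {
  expect_equal(log10_multinomial_prob(make_obs(character(0), numeric(0),
                                               character(0), character(0)), 1), 0)
  obs <- make_obs("A", 0.01, "A", "G")
  expect_equal(log10_multinomial_prob(obs, 1), log10(0.99), tolerance = 1e-12)
  expect_equal(log10_multinomial_prob(obs, 2), log10(0.01 / 3), tolerance = 1e-12)
  # quality-0 base (error prob 1) must stay finite through clamping
  obs0 <- make_obs("A", 1, "A", "G")
  expect_true(is.finite(log10_multinomial_prob(obs0, 1)))
})

test_that("uniform prior is 1/ploidy", {
  expect_equal(uniform_prior(2), 0.5)
  expect_equal(uniform_prior(4), 0.25)
  expect_equal(uniform_prior(1), 1.0)
})

test_that("posterior odds follow the excluded-focal-term form", {
  # P = [0.9, 0.1], uniform priors: 0.45/(0.50-0.45) = 9 and its inverse
  post <- posterior_log10(log10(c(0.9, 0.1)))
  expect_equal(10^post, c(9, 1 / 9), tolerance = 1e-12)
  # equal likelihoods: all posteriors 1/(l-1); for l = 2 both are 1
  expect_equal(10^posterior_log10(log10(c(0.3, 0.3))), c(1, 1), tolerance = 1e-12)
  expect_equal(10^posterior_log10(log10(c(0.2, 0.2, 0.2))), rep(0.5, 3),
               tolerance = 1e-12)
  expect_error(posterior_log10(log10(0.5)), "at least 2")
})

test_that("likelihood ratios square the diploid posterior odds", {
  post <- posterior_log10(log10(c(0.9, 0.1)))
  lr <- likelihood_ratio_log10(post)
  expect_equal(10^lr, c(81, 1 / 81), tolerance = 1e-12)
  expect_equal(max(lr), log10(81), tolerance = 1e-12)
  expect_equal(max(lr), 1.9085, tolerance = 1e-4)
  # tie: all ratios 1, LLR 0
  expect_equal(likelihood_ratio_log10(posterior_log10(log10(c(0.4, 0.4)))),
               c(0, 0), tolerance = 1e-12)
  # extreme separation stays finite in log space
  lr2 <- likelihood_ratio_log10(posterior_log10(c(0, -300)))
  expect_true(all(is.finite(lr2)))
  expect_equal(lr2[1], 600, tolerance = 1e-6)
})

test_that("score_read picks the haplotype supported by the observations", {
  obs <- make_obs(c("A", "C", "G"), rep(0.01, 3),
                  h1 = c("A", "C", "G"), h2 = c("T", "T", "T"))
  sc <- score_read(obs)
  expect_equal(sc$best_haplotype, 1L)
  expect_equal(sc$n_matches_best, 3L)
  expect_equal(sc$n_mismatches_best, 0L)
  expect_gt(sc$llr, 0)
  expect_false(sc$tie)

  # a base matching neither haplotype is uninformative: tie, LLR 0
  sc2 <- score_read(make_obs("T", 0.01, "A", "G"))
  expect_true(sc2$tie)
  expect_equal(sc2$llr, 0, tolerance = 1e-9)

  expect_error(score_read(make_obs(character(0), numeric(0),
                                   character(0), character(0))),
               "at least one observation")
})

test_that("all symmetric two-site configurations tie and asymmetric ones do not", {
  # brute force over every assignment of 2 observed bases to {h1, h2, neither}
  states <- expand.grid(s1 = 1:3, s2 = 1:3)
  base_for <- function(state) c("A", "G", "T")[state]  # h1=A, h2=G, neither=T
  for (r in seq_len(nrow(states))) {
    bases <- base_for(unlist(states[r, ]))
    obs <- make_obs(bases, c(0.01, 0.01), h1 = c("A", "A"), h2 = c("G", "G"))
    sc <- score_read(obs)
    m1 <- sum(bases == "A"); m2 <- sum(bases == "G")
    if (m1 == m2) {
      expect_true(sc$tie, info = paste(bases, collapse = ","))
    } else {
      expect_false(sc$tie, info = paste(bases, collapse = ","))
      expect_equal(sc$best_haplotype, if (m1 > m2) 1L else 2L)
    }
  }
})

test_that("diploid LLR equals twice the log probability difference", {
  withr::with_seed(7, {
    for (i in 1:1000) {
      lp <- log10(sort(runif(2, 1e-12, 1), decreasing = TRUE))
      lr <- likelihood_ratio_log10(posterior_log10(lp))
      expect_equal(max(lr), 2 * (lp[1] - lp[2]), tolerance = 1e-9)
    }
  })
})

test_that("scores are equivariant under haplotype relabeling", {
  withr::with_seed(13, {
    for (i in 1:25) {
      n <- sample(1:6, 1)
      h1 <- sample(c("A", "C"), n, replace = TRUE)
      h2 <- sample(c("G", "T"), n, replace = TRUE)
      bases <- ifelse(runif(n) < 0.5, h1, h2)
      e <- runif(n, 0.001, 0.2)
      sc12 <- score_read(make_obs(bases, e, h1, h2))
      sc21 <- score_read(make_obs(bases, e, h2, h1))
      expect_equal(sc12$lr_by_haplotype, rev(sc21$lr_by_haplotype),
                   tolerance = 1e-9)
      expect_equal(sc12$llr, sc21$llr, tolerance = 1e-9)
    }
  })
})

test_that("an extra matching observation never lowers the best haplotype's LLR", {
  withr::with_seed(21, {
    for (i in 1:25) {
      n <- sample(1:6, 1)
      bases <- sample(c("A", "G"), n, replace = TRUE, prob = c(0.8, 0.2))
      obs <- make_obs(bases, rep(0.02, n), rep("A", n), rep("G", n))
      sc <- score_read(obs)
      best_allele <- c("A", "G")[sc$best_haplotype]
      obs2 <- make_obs(c(bases, best_allele), rep(0.02, n + 1),
                       rep("A", n + 1), rep("G", n + 1))
      sc2 <- score_read(obs2)
      expect_gte(sc2$lr_by_haplotype[sc$best_haplotype] + 1e-9, sc$llr)
    }
  })
})

test_that("linear-space evaluation of the whole chain agrees with the log-space path", {
  # independent oracle: direct probability arithmetic, small n only
  naive_chain <- function(bases, e, h1, h2) {
    p <- vapply(list(h1, h2), function(h) {
      x <- bases == h
      k_m <- sum(x); k_nm <- sum(!x)
      coef <- factorial(k_m + k_nm) / (factorial(k_nm) * factorial(k_m))
      coef * prod(ifelse(x, 1 - e, e / 3))
    }, numeric(1))
    pb <- p * 0.5
    post <- c(pb[1] / pb[2], pb[2] / pb[1])
    lr <- c(post[1] / post[2], post[2] / post[1])
    log10(max(lr))
  }
  withr::with_seed(31, {
    for (i in 1:50) {
      n <- sample(1:8, 1)
      h1 <- rep("A", n); h2 <- rep("G", n)
      bases <- sample(c("A", "G", "T"), n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
      e <- runif(n, 0.005, 0.3)
      sc <- score_read(make_obs(bases, e, h1, h2))
      expect_equal(sc$llr, naive_chain(bases, e, h1, h2), tolerance = 1e-9)
    }
  })
})
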