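test_that("coverage and empirical probability count the top set correctly", {
  phi <- seq(0.1, 1, by = 0.1)  # ten states, distinct likelihoods
  # exactly the top half sampled, all shots inside it
  top_half <- which(phi >= likelihood_quantile(phi, 0.5))
  ens <- make_ens(top_half - 1, rep(10, length(top_half)), 4)
  cov <- coverage_and_empirical_probability(ens, phi, 0.5)
  expect_equal(cov$coverage, 1)
  expect_equal(cov$empirical_probability, 1)

  # sample disjoint from the top set
  bottom <- which(phi < likelihood_quantile(phi, 0.5))
  cov0 <- coverage_and_empirical_probability(make_ens(bottom - 1, rep(1, 5), 4),
                                             phi, 0.5)
  expect_equal(cov0$coverage, 0)
  expect_equal(cov0$empirical_probability, 0)

  # half the top set, every shot inside it (8 states -> top set of 4)
  phi8 <- (1:8) / 8
  top8 <- which(phi8 >= likelihood_quantile(phi8, 0.5))
  half <- top8[1:2]
  covh <- coverage_and_empirical_probability(make_ens(half - 1, c(4, 4), 3),
                                             phi8, 0.5)
  expect_equal(covh$coverage, 0.5)
  expect_equal(covh$empirical_probability, 1)
})

test_that("coverage and empirical probability are non-increasing in q", {
  set.seed(19)
  u <- enumerate_universe(4)
  pc <- sample_target(u, 1)$contact_map
  gtd <- ground_truth_distribution(u, pc)
  ens <- sample_measurements(rep(1 / u$n_states, u$n_states), 4096, seed = 2)
  qs <- c(0, 0.25, 0.5, 0.75, 0.9)
  cov <- t(vapply(qs, function(q) {
    unlist(coverage_and_empirical_probability(ens, gtd$phi, q))
  }, numeric(2)))
  expect_true(all(diff(cov[, 1]) <= 1e-12))
  expect_true(all(diff(cov[, 2]) <= 1e-12))
})

test_that("empirical entropy has the closed-form reference values", {
  expect_equal(empirical_entropy(make_ens(3, 100, 4)), 0)
  expect_equal(empirical_entropy(make_ens(0:4095, rep(1, 4096), 12)), 12)
  expect_equal(empirical_entropy(make_ens(c(0, 1), c(1, 1), 3)), 1)
})

test_that("likelihood ratios by energy level conserve mass", {
  phi <- seq(1, 100) / 100  # 100 states, distinct
  # uniform ensemble: every ratio is 1
  uens <- make_ens(0:99, rep(5, 100), 7)
  lr <- likelihood_ratio_by_level(uens, phi, bins = 10)
  expect_equal(lr$ratio, rep(1, 10))
  expect_equal(sum(lr$uniform_mass), 1)

  # all shots on the lowest-energy (highest phi) bin
  top_bin_states <- order(phi, decreasing = TRUE)[1:10]
  tens <- make_ens(top_bin_states - 1, rep(2, 10), 7)
  lrt <- likelihood_ratio_by_level(tens, phi, bins = 10)
  expect_equal(lrt$ratio[1], 10)
  expect_equal(lrt$ratio[-1], rep(0, 9))
  expect_true(all(lrt$ratio >= 0))
  # shot-mass-weighted... uniform-weighted average of ratios is 1
  expect_equal(sum(lrt$ratio * lrt$uniform_mass), 1)
})

test_that("contact recovery scores match hand-enumerated rank statistics", {
  # perfectly separating scores
  pc <- contact_map_from_pairs(rbind(c(1, 3), c(2, 4)), 4)
  inf_good <- matrix(0, 4, 4)
  inf_good[1, 3] <- inf_good[3, 1] <- 0.9
  inf_good[2, 4] <- inf_good[4, 2] <- 0.8
  inf_good[1, 4] <- inf_good[4, 1] <- 0.2
  s <- contact_recovery_scores(pc, inf_good)
  expect_equal(s$auc, 1)
  expect_equal(s$ap, 1)
  expect_equal(s$mean_pos, 0.85)
  expect_equal(s$max_pos, 0.9)

  # constant scores: tie-averaged AUC is 1/2
  s_const <- contact_recovery_scores(pc, matrix(0.5, 4, 4))
  expect_equal(s_const$auc, 0.5)

  # hand-enumerated mixed case: positives 0.9/0.4 among negatives 0.5/0.1/0/0
  pc5 <- contact_map_from_pairs(rbind(c(1, 3), c(1, 4)), 5)
  m <- matrix(0, 5, 5)
  m[1, 3] <- m[3, 1] <- 0.9
  m[1, 4] <- m[4, 1] <- 0.4
  m[1, 5] <- m[5, 1] <- 0.5
  m[2, 4] <- m[4, 2] <- 0.1
  s5 <- contact_recovery_scores(pc5, m)
  expect_equal(s5$auc, 7 / 8)       # 7 of 8 positive-negative pairs concordant
  expect_equal(s5$ap, 1 / 2 + (2 / 3) / 2)  # precision 1 at R=.5, 2/3 at R=1

  # independent check of the AUC on a random instance
  skip_if_not_installed("pROC")
  set.seed(23)
  n <- 7
  pcr_pairs <- rbind(c(1, 4), c(2, 6), c(3, 7))
  pcr <- contact_map_from_pairs(pcr_pairs, n)
  mr <- matrix(0, n, n)
  mr[upper.tri(mr)] <- runif(sum(upper.tri(mr)))
  mr <- mr + t(mr)
  sr <- contact_recovery_scores(pcr, mr)
  labs <- scores <- c()
  for (i in 1:(n - 2)) for (j in (i + 2):n) {
    labs <- c(labs, unclass(pcr)[i, j]); scores <- c(scores, mr[i, j])
  }
  expect_equal(sr$auc,
               as.numeric(suppressMessages(pROC::auc(labs, scores,
                                                     direction = "<"))),
               tolerance = 1e-12)

  expect_warning(
    s1 <- contact_recovery_scores(contact_map_from_pairs(rbind(c(1, 3), c(1, 4),
                                                               c(2, 4)), 4),
                                  inf_good), "single-class")
  expect_true(is.na(s1$auc))
  expect_false(is.na(s1$ap))
})

test_that("Dice-Sorensen indices cover weighted and max-threshold variants", {
  pc <- contact_map_from_pairs(rbind(c(1, 3)), 4)
  # exact binary recovery
  exact <- unclass(pc) * 1
  r <- dsi(pc, exact)
  expect_equal(r$dsi_w, 1)
  expect_equal(r$dsi_m, 1)

  # all-zero inference with positives present
  r0 <- dsi(pc, matrix(0, 4, 4))
  expect_equal(r0$dsi_w, 0)
  expect_equal(r0$dsi_m, 0)

  # one positive and one negative both scored 0.5
  half <- matrix(0, 4, 4)
  half[1, 3] <- half[3, 1] <- 0.5
  half[2, 4] <- half[4, 2] <- 0.5
  rh <- dsi(pc, half)
  expect_equal(rh$dsi_w, 0.5)
  expect_equal(rh$dsi_m, 2 / 3)  # attained at threshold 0

  # degenerate all-zero case is 1 by convention
  expect_message(rz <- dsi(contact_map(matrix(0, 4, 4)), matrix(0, 4, 4)),
                 "convention")
  expect_equal(rz$dsi_w, 1)
})

test_that("consensus scores are scale-invariant with the closed-form optimum", {
  d2 <- matrix(0, 3, 3)
  d2[1, 2] <- d2[2, 1] <- 1
  d2[1, 3] <- d2[3, 1] <- 1
  d2[2, 3] <- d2[3, 2] <- 4
  Dt_same <- sqrt(d2)
  cs <- consensus_scores(d2, Dt_same)
  expect_equal(cs$rmsd, 0, tolerance = 1e-12)
  expect_equal(cs$spearman, 1)
  expect_equal(consensus_scores(d2, 2 * sqrt(d2))$rmsd, 0, tolerance = 1e-12)

  # three-bead toy: scale 14/6, residuals 1/9 each
  Dt <- matrix(0, 3, 3)
  Dt[1, 2] <- Dt[2, 1] <- 2
  Dt[1, 3] <- Dt[3, 1] <- 2
  Dt[2, 3] <- Dt[3, 2] <- 5
  cs2 <- consensus_scores(d2, Dt)
  expect_equal(cs2$scale, 14 / 6, tolerance = 1e-12)
  expect_equal(cs2$rmsd, 1 / 3, tolerance = 1e-12)
  # numeric minimisation oracle agrees with the closed form
  D <- sqrt(d2[upper.tri(d2)])
  t <- Dt[upper.tri(Dt)]
  opt <- optimize(function(s) sqrt(mean((s * D - t)^2)), c(0.01, 100))
  expect_equal(cs2$rmsd, opt$objective, tolerance = 1e-6)
})

test_that("Jensen-Shannon divergence spans [0, 1] with the closed-form middle", {
  e1 <- make_ens(c(0, 1), c(1, 1), 3)
  expect_equal(ensemble_js_divergence(e1, e1, level = "states"), 0)
  e_disjoint <- make_ens(c(4, 5), c(1, 1), 3)
  expect_equal(ensemble_js_divergence(e1, e_disjoint, level = "states"), 1)
  e_deg <- make_ens(0, 2, 3)
  closed_form <- 0.5 * (0.5 * log2(0.5 / 0.75) + 0.5 * log2(0.5 / 0.25)) +
    0.5 * log2(1 / 0.75)
  expect_equal(ensemble_js_divergence(e1, e_deg, level = "states"),
               closed_form, tolerance = 1e-12)
  expect_equal(closed_form, 0.3113, tolerance = 1e-4)

  # contact-level comparison merges states with identical contact sets:
  # the straight line and a kinked open chain both have no contacts
  line <- spins_to_index(rep(1, 6))
  kink <- spins_to_index(c(1, 1, 1, 1, 1, -1))
  ja <- make_ens(line, 5, 6)
  jb <- make_ens(kink, 5, 6)
  expect_equal(ensemble_js_divergence(ja, jb, level = "contacts"), 0)
  expect_gt(ensemble_js_divergence(ja, jb, level = "states"), 0.99)

  # the embedding hook overrides the distribution construction
  hook <- function(a, b) list(p = c(0.5, 0.5), q = c(0.5, 0.5))
  expect_equal(ensemble_js_divergence(ja, jb, embed = hook), 0)
  expect_error(ensemble_js_divergence(ja, make_ens(0, 1, 3)), "bead counts")
})

test_that("paired F1 matching solves the assignment problem", {
  m_a <- contact_map_from_pairs(rbind(c(1, 3)), 5)
  m_b <- contact_map_from_pairs(rbind(c(2, 5)), 5)
  # identical singletons
  r_same <- paired_f1(list(m_a), list(m_a))
  expect_equal(r_same$scores, 1)
  # contact-disjoint singletons
  r_disj <- paired_f1(list(m_a), list(m_b))
  expect_equal(r_disj$scores, 0)

  # duplicates in the first set are removed before matching
  r_dup <- paired_f1(list(m_a, m_a), list(m_a, m_b))
  expect_equal(length(r_dup$scores), 1L)

  # matching agrees with the exhaustive assignment oracle
  set.seed(29)
  for (rep in 1:10) {
    na <- sample(2:4, 1)
    nb <- sample(na:5, 1)
    mats_a <- lapply(seq_len(na), function(i) {
      contact_map_from_pairs(rbind(c(1, sample(3:6, 1)),
                                   c(2, sample(4:6, 1))), 6)
    })
    mats_b <- lapply(seq_len(nb), function(i) {
      contact_map_from_pairs(rbind(c(1, sample(3:6, 1)),
                                   c(sample(1:2, 1), sample(4:6, 1))), 6)
    })
    vecs_a <- unique(lapply(mats_a, function(m) as.numeric(unclass(m)[upper.tri(m)])))
    f1 <- matrix(0, length(vecs_a), nb)
    for (i in seq_along(vecs_a)) for (j in seq_len(nb)) {
      x <- vecs_a[[i]]
      y <- as.numeric(unclass(mats_b[[j]])[upper.tri(mats_b[[j]])])
      tp <- sum(x & y)
      f1[i, j] <- if (tp + sum(x) + sum(y) == 0) 1 else 2 * tp / (sum(x) + sum(y))
    }
    got <- paired_f1(mats_a, mats_b)
    expect_equal(sum(got$scores), oracle_assignment(f1)$total,
                 tolerance = 1e-9)
  }

  # threshold-fraction summary
  r_thr <- paired_f1(list(m_a, m_b), list(m_a, m_b))
  expect_equal(unname(r_thr$fraction_above[1]), 1)   # everything >= 0
  expect_equal(unname(r_thr$fraction_above[length(r_thr$fraction_above)]), 1)
})

test_that("landscape information content detects flat and rugged objectives", {
  # constant objective: no information
  flat <- landscape_mic(function(theta) 1, p = 2, seed = 1,
                        n_samples = 16, n_walks = 4, walk_length = 20)
  expect_equal(flat$H_M, 0)

  # strictly alternating costs: H_M equals log6(2)
  counter <- local({
    k <- 0
    function(theta) {
      k <<- k + 1
      (-1)^k
    }
  })
  alt <- landscape_mic(counter, p = 2, seed = 2,
                       n_samples = 16, n_walks = 4, walk_length = 40)
  expect_equal(alt$H_M, log(2, base = 6), tolerance = 1e-12)

  # a smooth low-frequency objective is less rugged than a high-frequency one
  smooth <- landscape_mic(function(th) sum(sin(th)), p = 3, seed = 3,
                          n_samples = 32, n_walks = 8, walk_length = 60)
  expect_true(flat$H_M <= smooth$H_M)
  expect_true(smooth$H_M >= 0 && smooth$H_M <= 1)
  expect_error(landscape_mic(function(th) 1, p = 0), "p must")
})
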