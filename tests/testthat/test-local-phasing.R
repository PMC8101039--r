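test_that("energy evaluates couplings directly", {
  pairs <- estimate_error_rates(
    tibble::tibble(i = 1L, j = 2L, n_plus = 4L, n_minus = 1L),
    epsilon0 = 0.02)
  # a single satisfied coupling of weight w contributes -w/2
  pairs$weight <- 3
  expect_equal(phase_energy(c(1L, 1L), pairs), -1.5)
  expect_equal(phase_energy(c(1L, -1L), pairs), 1.5)
  # flipping one spin of the pair costs the full coupling weight
  expect_equal(flip_penalty(c(1L, 1L), pairs, 1), 3)
  expect_equal(switch_penalty(c(1L, 1L), pairs, 1), 3)
  expect_error(phase_energy(c(1L), pairs), "shorter")
})

test_that("flip and switch penalties equal direct energy recomputation", {
  for (seed in 1:10) {
    inst <- random_instance(n = 10, n_pairs = 25, seed = seed)
    s <- sample(c(-1L, 1L), 10, replace = TRUE)
    fp <- flip_penalty(s, inst$pairs)
    sp <- switch_penalty(s, inst$pairs)
    e0 <- phase_energy(s, inst$pairs)
    for (i in 1:10) {
      s2 <- s; s2[i] <- -s2[i]
      expect_equal(fp[i], phase_energy(s2, inst$pairs) - e0)
    }
    for (k in 1:9) {
      s2 <- s; s2[(k + 1):10] <- -s2[(k + 1):10]
      expect_equal(sp[k], phase_energy(s2, inst$pairs) - e0)
    }
  }
})

test_that("flip penalty decomposes into genotype-to-haplotype linkage", {
  # delta E_i = s_i * (eta_R<->S - eta_A<->S) with chi-weighted counts
  inst <- random_instance(n = 6, n_pairs = 12, seed = 3)
  s <- sample(c(-1L, 1L), 6, replace = TRUE)
  p <- inst$pairs
  for (i in 1:6) {
    touching <- p[p$i == i | p$j == i, ]
    other <- ifelse(touching$i == i, touching$j, touching$i)
    sj <- s[other]
    eta_r <- sum(touching$chi * ifelse(sj == 1, touching$n_plus,
                                       touching$n_minus))
    eta_a <- sum(touching$chi * ifelse(sj == 1, touching$n_minus,
                                       touching$n_plus))
    expect_equal(flip_penalty(s, p, i), s[i] * (eta_r - eta_a))
  }
})

test_that("a satisfied adjacent chain has uniform boundary penalties", {
  n <- 6
  pairs <- tibble::tibble(i = 1:(n - 1), j = 2:n,
                          n_plus = 5L, n_minus = 0L)
  pairs$weight <- 2.5
  s <- rep(1L, n)
  expect_equal(switch_penalty(s, pairs), rep(2.5, n - 1))
  # boundary with no crossing linkage has zero penalty
  gap <- pairs[-3, ]
  expect_equal(switch_penalty(s, gap)[3], 0)
})

test_that("error probability is the logistic transform of the penalty", {
  expect_equal(error_probability(0), 0.5)
  expect_equal(error_probability(Inf), 0)
  de <- c(-3, -0.5, 0.2, 7)
  expect_equal(error_probability(-de), 1 - error_probability(de))
})

test_that("minimizer reaches the enumerated optimum on small instances", {
  n_hit <- 0
  n_inst <- 60
  for (seed in seq_len(n_inst)) {
    n <- sample(4:10, 1)
    inst <- random_instance(n = n, n_pairs = min(3 * n, choose(n, 2)),
                            seed = seed)
    fit <- minimize_energy(inst$pairs, n_sites = n)
    best <- brute_energy_min(inst$pairs, n)
    expect_gte(min(fit$spins$flip_penalty), -1e-8)
    expect_gte(min(fit$boundaries$switch_penalty), -1e-8)
    if (isTRUE(all.equal(fit$energy, best$energy)) ||
        fit$energy < best$energy + 1e-9) {
      n_hit <- n_hit + 1
    }
  }
  expect_gte(n_hit / n_inst, 0.95)
})

test_that("two sites reduce to the pairwise phase sign", {
  for (np in 0:5) {
    for (nm in 0:5) {
      if (np + nm == 0 || np == nm) next
      pairs <- estimate_error_rates(
        tibble::tibble(i = 1L, j = 2L, n_plus = np, n_minus = nm),
        epsilon0 = 0.05)
      fit <- minimize_energy(pairs, n_sites = 2)
      expect_identical(fit$spins$spin[1] * fit$spins$spin[2],
                       pair_phase_sign(np, nm))
    }
  }
})

test_that("noiseless chains are recovered exactly up to a global flip", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 40
    truth <- sample(c(-1L, 1L), n, replace = TRUE)
    pairs <- tibble::tibble(
      i = 1:(n - 1), j = 2:n,
      n_plus = ifelse(truth[1:(n - 1)] == truth[2:n], 10L, 0L),
      n_minus = ifelse(truth[1:(n - 1)] == truth[2:n], 0L, 10L))
    fit <- minimize_energy(estimate_error_rates(pairs, epsilon0 = 0.01),
                           n_sites = n)
    agree <- mean(fit$spins$spin == truth)
    expect_true(agree == 1 || agree == 0)
    expect_true(fit$converged)
  }
})

test_that("dense noisy instances converge within ten rounds", {
  g <- simulate_genome(5, chrom_length_bp = 2e6, centromere_gap_bp = 2e5)
  lr <- simulate_linked_reads(g, seed = 6, molecules_per_barcode = 1)
  pairs <- estimate_error_rates(count_linkage(lr, g$sites))
  fit <- minimize_energy(pairs, n_sites = nrow(g$sites))
  expect_true(fit$converged)
  expect_lte(nrow(fit$log), 10)
})

test_that("false variants receive near-zero flip penalties", {
  g <- simulate_genome(9, chrom_length_bp = 2e6, centromere_gap_bp = 2e5,
                       false_variant_rate = 0.03)
  lr <- simulate_linked_reads(g, seed = 10, molecules_per_barcode = 1)
  pairs <- estimate_error_rates(count_linkage(lr, g$sites))
  fit <- minimize_energy(pairs, n_sites = nrow(g$sites))
  ok <- tibble::tibble(site = fit$spins$site,
                       fp = fit$spins$flip_penalty,
                       is_false = g$sites$is_false)
  # flip penalties of false variants are tiny relative to true ones
  expect_lt(median(ok$fp[ok$is_false]), 0.05 * median(ok$fp[!ok$is_false]))
})

test_that("block segmentation cuts below the penalty cutoff", {
  fit <- structure(list(
    spins = tibble::tibble(site = 1:5, spin = c(1L, 1L, -1L, 1L, -1L),
                           flip_penalty = rep(10, 5), flip_error = 0),
    boundaries = tibble::tibble(boundary = 1:4,
                                switch_penalty = c(10, 10, 0.5, 10),
                                switch_error = 0),
    energy = 0, log = tibble::tibble(), converged = TRUE,
    n_sites = 5L, epsilon0 = 0.01), class = "hap_fit")
  one <- segment_blocks(fit, cutoff = 0.25)
  expect_identical(unique(one$block_id), 1L)  # all boundaries above cutoff
  two <- segment_blocks(fit, cutoff = 1, min_report_size = 3)
  expect_identical(two$block_id, c(1L, 1L, 1L, 2L, 2L))
  expect_identical(two$short, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_error(segment_blocks(fit, cutoff = 0), "positive")
})

test_that("raising the cutoff only refines the block partition", {
  set.seed(13)
  for (rep in 1:5) {
    fit <- structure(list(
      spins = tibble::tibble(site = 1:30,
                             spin = sample(c(-1L, 1L), 30, TRUE),
                             flip_penalty = runif(30),
                             flip_error = 0.5),
      boundaries = tibble::tibble(boundary = 1:29,
                                  switch_penalty = rexp(29, 0.1),
                                  switch_error = 0.5),
      energy = 0, log = tibble::tibble(), converged = TRUE,
      n_sites = 30L, epsilon0 = 0.01), class = "hap_fit")
    lo <- segment_blocks(fit, cutoff = 2)$block_id
    hi <- segment_blocks(fit, cutoff = 10)$block_id
    # every cut made at the low cutoff is still a cut at the higher one
    expect_true(all(which(diff(lo) == 1L) %in% which(diff(hi) == 1L)))
    expect_gte(max(hi), max(lo))
  }
})

test_that("cutoff suggestion finds the histogram valley or falls back", {
  set.seed(4)
  bimodal <- c(rexp(300, 1 / 50), rnorm(700, 2000, 300))
  cut <- suggest_cutoff(bimodal)
  expect_gt(cut, 100)
  expect_lt(cut, 1800)
  monotone <- rexp(500, 1 / 100)
  fb <- suggest_cutoff(monotone, median_link_coverage = 60)
  expect_true(fb == 6 || (fb > 0 && fb < max(monotone)))
  expect_error(suggest_cutoff(rep(1, 5)), "median_link_coverage")
})

test_that("fit tidiers expose per-site scores and a one-row summary", {
  inst <- random_instance(n = 8, n_pairs = 14, seed = 8)
  fit <- minimize_energy(inst$pairs, n_sites = 8)
  td <- tidy(fit)
  expect_identical(nrow(td), 8L)
  expect_true(all(c("spin", "flip_penalty", "switch_penalty") %in% names(td)))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$converged)
})
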