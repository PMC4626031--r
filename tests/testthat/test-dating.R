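test_that("rho and sigma on worked small trees", {
  # single tip with k mutations: rho = k, sigma = sqrt(k)
  t1 <- mutation_tree(parent = c(NA, 1), label = c("anc", "a"),
                      mutations = list(character(), as.character(1:7)))
  r1 <- compute_rho(t1)
  expect_equal(r1$rho, 7)
  expect_equal(r1$sigma, sqrt(7))

  # star of 4 tips, 3 mutations each: rho = 3, sigma = sqrt(12)/4
  t2 <- mutation_tree(parent = c(NA, 1, 1, 1, 1),
                      label = c("anc", letters[1:4]),
                      mutations = c(list(character()),
                                    lapply(0:3, function(i) {
                                      as.character(10 * i + 1:3)
                                    })))
  r2 <- compute_rho(t2)
  expect_equal(r2$rho, 3)
  expect_equal(r2$sigma, sqrt(12) / 4)

  # shared branch of 2 over both tips, privates 1 and 3:
  # rho = (2*2 + 1 + 3)/2, sigma = sqrt(2*4 + 1 + 3)/2
  t3 <- mutation_tree(parent = c(NA, 1, 2, 2), label = c("anc", "i", "a", "b"),
                      mutations = list(character(), c("1", "2"), "3",
                                       c("4", "5", "6")))
  r3 <- compute_rho(t3)
  expect_equal(r3$rho, 4)
  expect_equal(r3$sigma, sqrt(12) / 2)

  expect_error(compute_rho(t3, node = "zz"), "no node")
})

test_that("rho/sigma equal brute-force path sums on random trees", {
  set.seed(77)
  for (i in 1:100) {
    t <- random_mutation_tree(sample(2:12, 1L))
    r <- compute_rho(t)
    expect_equal(r$rho, brute_rho(t), tolerance = 1e-12)
    expect_equal(r$sigma, brute_sigma(t), tolerance = 1e-12)
    expect_identical(r$n, sum(t$is_tip))
  }
})

test_that("clade subsetting dates the subtree only", {
  t <- mutation_tree(parent = c(NA, 1, 2, 2, 1),
                     label = c("anc", "H", "a", "b", "c"),
                     mutations = list(character(), c("f1", "f2"),
                                      c("1", "2"), c("3"), c("9")))
  r <- compute_rho(t, node = "H")
  expect_equal(r$rho, 1.5)
  expect_identical(r$n, 2L)
})

test_that("clock conversion is linear and validated", {
  a <- to_age(5.56, 1.22)
  expect_equal(a$T_ky, 5.56 * 3.172)
  expect_equal(a$dT_ky, 1.22 * 3.172)
  a2 <- to_age(2 * 5.56, 2 * 1.22)
  expect_equal(a2$T_ky, 2 * a$T_ky)
  expect_equal(to_age(0, 0)$T_ky, 0)
  expect_error(to_age(-1, 0), "non-negative")
  custom <- clock_model(1000)
  expect_equal(to_age(3, 0, custom)$T_ky, 3)
  expect_error(clock_model(-5), "positive")
})

test_that("HKY85 transition matrices behave like a reversible generator", {
  m <- hky85_model(kappa = 3.7, base_freqs = c(.35, .25, .12, .28))
  expect_equal(unname(hky85_transition_matrix(m, 0)), diag(4),
               tolerance = 1e-12)
  P <- hky85_transition_matrix(m, 0.17)
  expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
  # detailed balance pi_i P_ij = pi_j P_ji: the flux matrix is symmetric
  pi <- m$base_freqs
  flux <- pi * P
  expect_equal(flux, t(flux), tolerance = 1e-12)
  # long branches converge to the stationary frequencies
  Pinf <- hky85_transition_matrix(m, 500)
  for (i in 1:4) expect_equal(unname(Pinf[i, ]), unname(pi), tolerance = 1e-9)
  # kappa = 1, equal frequencies reduces to Jukes-Cantor
  jc <- hky85_model(kappa = 1, base_freqs = rep(.25, 4))
  for (t in c(0.05, 0.3, 1.2)) {
    Pjc <- hky85_transition_matrix(jc, t)
    expect_equal(unname(diag(Pjc)), rep(1 / 4 + 3 / 4 * exp(-4 * t / 3), 4),
                 tolerance = 1e-12)
  }
  # and against an independent matrix exponential
  Q <- oracle_hky_Q(3.7, c(.35, .25, .12, .28))
  expect_equal(unname(P), unname(oracle_expm(Q * 0.17)), tolerance = 1e-9)
})

test_that("discrete gamma rates have mean one and match quadrature", {
  expect_identical(discretize_gamma(0.7, 1), 1)
  for (alpha in c(0.2, 0.5, 1, 4)) {
    r <- discretize_gamma(alpha, 32)
    expect_length(r, 32L)
    expect_equal(mean(r), 1, tolerance = 1e-12)
    expect_true(all(diff(r) > 0))
  }
  # vanishing heterogeneity: all rates approach 1
  expect_equal(discretize_gamma(1e7, 8), rep(1, 8), tolerance = 1e-3)
  # category means by numeric integration of the Gamma(alpha, alpha) density
  alpha <- 0.5; k <- 4
  q <- qgamma(seq(0, 1, length.out = k + 1), alpha, alpha)
  oracle <- vapply(seq_len(k), function(i) {
    k * integrate(function(x) x * dgamma(x, alpha, alpha),
                  q[i], q[i + 1], rel.tol = 1e-12)$value
  }, 0)
  expect_equal(discretize_gamma(alpha, k), oracle, tolerance = 1e-8)
  expect_error(discretize_gamma(-1), "positive")
})

test_that("pruning log-likelihood equals exhaustive state enumeration", {
  set.seed(13)
  pi <- c(.31, .24, .17, .28)
  for (case in 1:3) {
    n <- c(3, 4, 4)[case]
    topo_nested <- list(list("s1", "s2"), if (n == 3) "s3" else
                        list("s3", "s4"))
    seqs <- setNames(vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
    }, ""), paste0("s", seq_len(n)))
    # package topology matching the nested one: root(1) -> i1(2), i2(3)
    if (n == 3) {
      parent <- c(NA, 1, 1, 2, 2)
      label <- c("r", "i1", "s3", "s1", "s2")
      lengths <- c(0, .12, .30, .07, .21)
      node_lengths_oracle <- c(0, .12, .07, .21, .30)
    } else {
      parent <- c(NA, 1, 1, 2, 2, 3, 3)
      label <- c("r", "i1", "i2", "s1", "s2", "s3", "s4")
      lengths <- c(0, .12, .09, .07, .21, .30, .02)
      node_lengths_oracle <- c(0, .12, .07, .21, .09, .30, .02)
    }
    m <- hky85_model(kappa = 4, base_freqs = pi, alpha = 0.6,
                     n_categories = 4)
    got <- pruning_loglik(seqs, list(parent = parent, label = label),
                          lengths, m)
    want <- oracle_enum_loglik(seqs, topo_nested, node_lengths_oracle,
                               kappa = 4, pi = pi, alpha = 0.6, k = 4)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("two-taxon clock ML matches the Jukes-Cantor closed form", {
  set.seed(19)
  L <- 4000L
  s1 <- sample(c("A", "C", "G", "T"), L, TRUE)
  s2 <- s1
  flip <- sample.int(L, 220L)
  s2[flip] <- vapply(s1[flip], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }, "")
  seqs <- c(a = paste(s1, collapse = ""), b = paste(s2, collapse = ""))
  p_mm <- mean(s1 != s2)
  d_jc <- -3 / 4 * log(1 - 4 * p_mm / 3)
  fit <- ml_divergence(seqs,
                       model = hky85_model(kappa = 1, alpha = 1,
                                           n_categories = 1),
                       base_freqs = rep(.25, 4),
                       optimize_kappa = FALSE, optimize_alpha = FALSE)
  # tip-to-tip distance is twice the clock root height
  expect_equal(2 * fit$height, d_jc, tolerance = 1e-4)
  expect_identical(fit$convergence, 0L)
  expect_true(fit$se > 0)
})

test_that("identical sequences give zero divergence and degenerate input errors", {
  seqs <- c(a = strrep("ACGT", 100), b = strrep("ACGT", 100))
  fit <- ml_divergence(seqs)
  expect_identical(fit$divergence, 0)
  expect_identical(fit$se, 0)
  expect_error(ml_divergence(seqs[1]), "two sequences")
  expect_error(ml_divergence(c(a = "ACGT", b = "ACG")), "equal length")
  expect_error(ml_divergence(c(a = "NNNN", b = "NNNN")), "usable")
  expect_error(ml_divergence(seqs, clock = FALSE), "clock")
})

test_that("ML divergence recovers the simulated clade height", {
  set.seed(61)
  age <- 12; n <- 8
  cfg <- sim_config(seed = 301, haplogroup_mix = c(T2 = n),
                    clade_age_ky = c(T2 = age))
  truth_div <- age * 1000 / cfg$clock$years_per_mutation
  divs <- vapply(1:4, function(i) {
    cfg_i <- sim_config(seed = 301 + i, haplogroup_mix = c(T2 = n),
                        clade_age_ky = c(T2 = age))
    ds <- generate_dataset(cfg_i)
    fit <- ml_divergence(ds$sequences,
                         model = hky85_model(kappa = 20, alpha = 0.5),
                         optimize_kappa = FALSE, optimize_alpha = FALSE)
    fit$divergence
  }, 0)
  expect_equal(mean(divs), truth_div, tolerance = 0.30)
})

test_that("age table mirrors the published report layout", {
  tab <- age_table(list(
    Q = list(n = 18, ml = c(5.60, 1.96), rho = c(5.56, 1.22))))
  expect_identical(names(tab),
                   c("haplogroup", "N", "ML", "SE", "T_ml", "dT_ml",
                     "rho", "sigma", "T_rho", "dT_rho"))
  expect_equal(tab$T_rho, 17.64)
  expect_equal(tab$dT_rho, 3.87)
  expect_equal(tab$T_ml, 17.76)
  expect_equal(tab$dT_ml, 6.22)

  empty <- age_table(list())
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty), names(tab))

  zero <- age_table(list(X = list(n = 2, rho = c(0, 0))))
  expect_equal(zero$T_rho, 0)
  expect_equal(zero$dT_rho, 0)
  expect_true(is.na(zero$T_ml))
})
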