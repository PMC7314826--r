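test_that("init_state assigns uniformly, tallies exactly, and is seeded", {
  corp <- tiny_corpus()
  st1 <- init_state(corp, hyperparameters(K = 1, 0.1, 0.1), seed = 1)
  expect_true(all(st1$z == 1L))
  expect_equal(st1$c_dk[, 1], c(3L, 2L))

  st <- init_state(corp, hyperparameters(K = 3, 0.1, 0.1), seed = 42)
  rec <- endotype:::recount_tables(st$tokens, st$z, 3L)
  expect_identical(st$c_dk, rec$c_dk)
  expect_identical(st$c_kq, rec$c_kq)
  expect_identical(st$c_kqv, rec$c_kqv)

  st2 <- init_state(corp, hyperparameters(K = 3, 0.1, 0.1), seed = 42)
  expect_identical(st$z, st2$z)

  empty <- endo_corpus(corp$schema, corp$answers[0, ],
                       tibble::tibble(participant_id = "p1",
                                      days_tracked = 0L))
  expect_error(init_state(empty, hyperparameters(K = 2)), "no tokens")
})

test_that("the collapsed conditional matches brute-force enumeration", {
  corp <- two_token_corpus()
  hyper <- hyperparameters(K = 2, alpha = 1, beta = 1)
  st <- init_state(corp, hyper, seed = 1)
  post <- enum_assignment_posterior(st$tokens, 2, 1, 1)

  # condition on every possible assignment of token 2, check token 1
  for (z2 in 1:2) {
    st$z <- c(1L, z2)
    counts <- endotype:::recount_tables(st$tokens, st$z, 2L)
    st[names(counts)] <- counts
    cond <- gibbs_conditional(st, 1L)
    keep <- post$states[, 2] == z2
    exact <- post$prob[keep][order(post$states[keep, 1])]
    exact <- exact / sum(exact)
    expect_equal(cond, exact, tolerance = 1e-12)
  }

  # K = 1 is forced
  st1 <- init_state(corp, hyperparameters(K = 1), seed = 1)
  expect_equal(gibbs_conditional(st1, 1L), 1)

  # counts symmetric across phenotypes after removing the token -> uniform:
  # one participant with tokens (a, a, a, b, b); excluding token 1, each
  # phenotype holds exactly one a and one b
  schema <- question_schema("q1", vocabulary = list(c("a", "b")))
  ans <- tibble::tibble(participant_id = "p1", question_id = "q1",
                        token = c("a", "b"), count = c(3L, 2L))
  sts <- init_state(endo_corpus(schema, ans), hyper, seed = 1)
  sts$z <- c(1L, 1L, 2L, 1L, 2L)
  counts <- endotype:::recount_tables(sts$tokens, sts$z, 2L)
  sts[names(counts)] <- counts
  expect_equal(gibbs_conditional(sts, 1L), c(0.5, 0.5))
})

test_that("sweeps conserve counts, fix K = 1, and replay under a seed", {
  corp <- tiny_corpus()
  st <- init_state(corp, hyperparameters(K = 3, 0.5, 0.5), seed = 7)
  set.seed(11)
  sw <- gibbs_sweep(st, n_sweeps = 10)
  rec <- endotype:::recount_tables(sw$tokens, sw$z, 3L)
  expect_identical(sw$c_dk, rec$c_dk)
  expect_identical(sw$c_kqv, rec$c_kqv)
  expect_equal(rowSums(sw$c_dk), c(3, 2), ignore_attr = TRUE)

  set.seed(11)
  sw2 <- gibbs_sweep(st, n_sweeps = 10)
  expect_identical(sw$z, sw2$z)

  st1 <- init_state(corp, hyperparameters(K = 1), seed = 7)
  sw1 <- gibbs_sweep(st1)
  expect_identical(sw1$z, st1$z)
})

test_that("fit closed forms hold at K = 1 (including unanswered questions)", {
  schema <- question_schema(c("q1", "q2"),
                            vocabulary = list(c("a", "b"), c("x", "y", "z")))
  answers <- tibble::tibble(participant_id = c("p1", "p1", "p2"),
                            question_id = "q1",
                            token = c("a", "b", "a"), count = c(2L, 1L, 3L))
  corp <- endo_corpus(schema, answers)
  beta <- 0.2
  f <- fit_phenotypes(corp, hyperparameters(K = 1, alpha = 0.3, beta = beta),
                      n_iter = 10, burn_in = 5, thin = 1, seed = 1)
  expect_equal(unname(f$theta[, 1]), c(1, 1))
  # smoothed empirical frequencies for the answered question
  expect_equal(unname(f$phi$q1[1, ]),
               c((5 + beta) / (6 + 2 * beta), (1 + beta) / (6 + 2 * beta)))
  # untouched question: the symmetric prior mean, uniform over V_q
  expect_equal(unname(f$phi$q2[1, ]), rep(1 / 3, 3))
})

test_that("fit recovers well-separated phenotypes at desk scale", {
  sim <- sample_corpus(generator_config(K_true = 2, alpha_true = 0.05,
                                        beta_true = 0.01, D = 60, seed = 21,
                                        volume = volume_model(mean = 6)))
  f <- fit_phenotypes(sim$corpus, hyperparameters(K = 2, 0.1, 0.1),
                      n_iter = 150, burn_in = 75, thin = 5, seed = 3)
  al <- match_phenotypes(f$phi, sim$truth$phi_true)
  expect_lt(al$mean_tv, 0.1)
  asg <- hard_assign(f)
  relab <- order(al$perm)[asg$phenotype]  # map fitted labels onto true ones
  agree <- mean(relab != sim$truth$dominant_phenotype[asg$participant_id])
  expect_lt(agree, 0.05)
})

test_that("fit and baseline coincide on one-question corpora", {
  schema <- question_schema("q1",
                            vocabulary = list(sprintf("t%d", 1:6)))
  sim <- sample_corpus(generator_config(K_true = 2, D = 20, seed = 13,
                                        volume = volume_model(mean = 10)),
                       schema)
  hyper <- hyperparameters(K = 2, 0.1, 0.1)
  f <- fit_phenotypes(sim$corpus, hyper, 60, 30, 2, seed = 5)
  b <- fit_baseline(sim$corpus, hyper, 60, 30, 2, seed = 5)
  expect_equal(unname(b$theta), unname(f$theta))
  expect_equal(unname(b$phi[[1]]), unname(f$phi[[1]]), ignore_attr = TRUE)
  # the baseline smooths over the pooled vocabulary size
  expect_equal(ncol(fit_baseline(
    sample_corpus(generator_config(K_true = 2, D = 5, seed = 1,
                                   volume = volume_model(mean = 2)))$corpus,
    hyper, 10, 5, 1, seed = 1)$phi[[1]]), 202L)
})

test_that("guards: n_iter/burn_in ordering and zero-observation exclusion", {
  corp <- tiny_corpus()
  expect_error(fit_phenotypes(corp, hyperparameters(K = 2),
                              n_iter = 5, burn_in = 5),
               "n_iter > burn_in")
  with_empty <- endo_corpus(
    corp$schema, corp$answers,
    dplyr::bind_rows(corp$participants[c("participant_id", "days_tracked")],
                     tibble::tibble(participant_id = "ghost",
                                    days_tracked = 4L))
  )
  expect_message(
    f <- fit_phenotypes(with_empty, hyperparameters(K = 2, 0.1, 0.1),
                        n_iter = 10, burn_in = 5, thin = 1, seed = 1),
    "zero observations"
  )
  expect_false("ghost" %in% rownames(f$theta))
})

test_that("tidy and glance expose the posteriors in long form", {
  sim <- sample_corpus(generator_config(K_true = 2, D = 8, seed = 31,
                                        volume = volume_model(mean = 3)))
  f <- fit_phenotypes(sim$corpus, hyperparameters(K = 2, 0.1, 0.1),
                      20, 10, 2, seed = 1)
  phi_long <- tidy(f, "phi")
  expect_setequal(names(phi_long),
                  c("phenotype", "question_id", "token", "probability"))
  sums <- dplyr::summarise(
    dplyr::group_by(phi_long, .data$phenotype, .data$question_id),
    s = sum(.data$probability), .groups = "drop"
  )
  expect_true(all(abs(sums$s - 1) < 1e-9))
  th_long <- tidy(f, "theta")
  expect_equal(nrow(th_long), nrow(f$theta) * 2)
  g <- glance(f)
  expect_equal(g$K, 2L)
  expect_equal(g$n_questions, 13L)
})
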