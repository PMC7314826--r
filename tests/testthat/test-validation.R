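expert_fixture <- function(name) {
  read_confusion_csv(system.file("extdata", name, package = "endotype"))
}

test_that("purity reproduces the published expert-agreement values", {
  expect_equal(purity(expert_fixture("confusion_expert1_4x4.csv")), 0.6)
  expect_equal(purity(expert_fixture("confusion_expert2_4x4.csv")), 0.55)
  expect_equal(purity(expert_fixture("confusion_expert1_severe.csv")), 0.9)
  expect_equal(purity(expert_fixture("confusion_expert2_severe.csv")), 0.8)
  expect_equal(purity(expert_fixture("confusion_expert1_mild.csv")), 0.775)
  expect_equal(purity(expert_fixture("confusion_expert2_mild.csv")), 0.7)
})

test_that("purity is permutation-invariant and majority-bounded", {
  set.seed(7)
  for (i in 1:20) {
    m <- matrix(rpois(12, 4), 3, 4)
    if (sum(m) == 0) next
    p <- purity(m)
    expect_equal(purity(m[sample(3), sample(4)]), p)
    expect_gte(p, max(colSums(m)) / sum(m) - 1e-12)
    expect_lte(p, 1)
  }
  expect_equal(purity(diag(c(3, 9, 1))), 1)
  expect_error(purity(matrix(0, 2, 2)), "empty")
})

test_that("confusion matrices tabulate labels and transpose on swap", {
  ids <- sprintf("p%02d", 1:10)
  model <- stats::setNames(rep(c("A", "B"), each = 5), ids)
  expect_equal(unclass(confusion(model, model)),
               matrix(c(5L, 0L, 0L, 5L), 2,
                      dimnames = list(model = c("A", "B"),
                                      reference = c("A", "B"))),
               ignore_attr = FALSE)

  # a worked 40-participant labeling that encodes the Expert-1 table
  m6 <- expert_fixture("confusion_expert1_4x4.csv")
  model_l <- character(0); expert_l <- character(0)
  for (i in rownames(m6)) for (j in colnames(m6)) {
    model_l <- c(model_l, rep(i, m6[i, j]))
    expert_l <- c(expert_l, rep(j, m6[i, j]))
  }
  names(model_l) <- names(expert_l) <- sprintf("p%02d", seq_along(model_l))
  built <- confusion(model_l, expert_l)
  expect_equal(unclass(built), unclass(m6), ignore_attr = TRUE)
  expect_equal(purity(built), 0.6)
  swapped <- confusion(expert_l, model_l)
  expect_equal(unclass(swapped), t(unclass(built)), ignore_attr = TRUE)

  expect_error(confusion(model, stats::setNames(model, rev(toupper(ids)))),
               "different participants")
})

test_that("binary collapse reproduces the severe table and conserves counts", {
  m6 <- expert_fixture("confusion_expert1_4x4.csv")
  sev <- collapse_to_binary(m6, "model_A", "expert_A",
                            labels = c("severe", "non_severe"))
  expect_equal(unclass(sev),
               unclass(expert_fixture("confusion_expert1_severe.csv")),
               ignore_attr = TRUE)
  expect_equal(sum(sev), sum(m6))
  expect_equal(purity(sev), 0.9)

  d <- as_diag <- diag(c(4L, 6L))
  dimnames(d) <- list(c("a", "b"), c("x", "y"))
  dc <- collapse_to_binary(d, "a", "x")
  expect_equal(unname(unclass(dc)), matrix(c(4L, 0L, 0L, 6L), 2, byrow = TRUE))
  expect_error(collapse_to_binary(m6, "model_Z", "expert_A"), "unknown model")
})

test_that("chi-square matches the formula oracle and its invariances", {
  flat <- matrix(10, 2, 2)
  r <- chi_square_independence(flat)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$df, 1)

  m <- matrix(c(7, 2, 2, 29), 2, byrow = TRUE)
  r2 <- chi_square_independence(m)
  expect_equal(r2$statistic, chisq_oracle(m), tolerance = 1e-10)
  expect_equal(r2$p_value,
               stats::pchisq(chisq_oracle(m), 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_true(r2$low_expected)  # expected severe/severe cell is 40*9*9/40^2 ~ 2

  r4 <- chi_square_independence(2 * m)
  expect_equal(r4$statistic, 2 * r2$statistic, tolerance = 1e-10)

  expect_error(chi_square_independence(matrix(c(0, 0, 3, 4), 2)),
               "zero marginal")
})

test_that("Kruskal-Wallis matches the rank-formula oracle", {
  g <- list(c(1, 2, 3), c(4, 5, 6))
  r <- kruskal_wallis(g)
  expect_equal(r$statistic, kw_oracle(g), tolerance = 1e-10)
  expect_equal(r$df, 1)

  # identical multisets in both groups: H = 0 exactly
  same <- list(c(1, 2, 3), c(1, 2, 3))
  expect_equal(kruskal_wallis(same)$statistic, 0, tolerance = 1e-12)

  # tie correction agrees with the oracle on tied data
  tied <- list(c(1, 1, 2, 3), c(2, 2, 3, 4), c(1, 4, 4))
  expect_equal(kruskal_wallis(tied)$statistic, kw_oracle(tied),
               tolerance = 1e-10)

  expect_error(kruskal_wallis(list(c(2, 2), c(2, 2))), "identical")
  expect_error(kruskal_wallis(list(1:3)), "length")
})

test_that("association screening tests the right covariates the right way", {
  sim <- sample_corpus(generator_config(K_true = 4, D = 400, seed = 29,
                                        volume = volume_model(mean = 2)))
  spec <- dplyr::bind_rows(
    survey_covariate("strong_cat", "categorical", levels = c("no", "yes"),
                     effect_size = 0.8),
    survey_covariate("strong_num", "continuous", mean = 10, sd = 2,
                     effect_size = 1),
    survey_covariate("null_cat", "categorical", levels = c("l1", "l2", "l3")),
    survey_covariate("mono", "categorical", levels = c("only", "never"),
                     base_probs = c(1, 0))
  )
  sv <- sample_survey(sim$truth, spec, seed = 29)
  a <- theta_assignments(sim$truth$theta_true, rownames(sim$truth$theta_true))
  expect_warning(res <- association_screen(a, sv), "single observed level")
  expect_setequal(res$covariate, c("strong_cat", "strong_num", "null_cat"))
  expect_equal(res$test[res$covariate == "strong_num"], "kruskal-wallis")
  expect_true(res$significant[res$covariate == "strong_cat"])
  expect_true(res$significant[res$covariate == "strong_num"])

  # BH adjustment adds a column and can only lose discoveries
  expect_warning(resbh <- association_screen(a, sv, adjust = "BH"))
  expect_true(all(resbh$p_adjusted >= resbh$p_value - 1e-15))

  expect_error(association_screen(a, sv[0, ]), "no shared participant")
})

test_that("review-panel strata follow the posterior and activity rules", {
  # 4 phenotypes x 10 certain each + 10 uncertain + boundary cases
  K <- 4
  theta <- rbind(
    do.call(rbind, lapply(1:K, function(k) {
      m <- matrix((1 - 0.97) / (K - 1), 10, K); m[, k] <- 0.97; m
    })),
    matrix(rep(c(0.5, 0.4, 0.05, 0.05), 10), 10, K, byrow = TRUE),
    matrix(0.25, 5, K)  # top-2 mass 0.5: neither certain nor uncertain
  )
  ids <- sprintf("P%03d", seq_len(nrow(theta)))
  a <- theta_assignments(theta, ids)
  corp <- flat_corpus(ids, days = 40, obs = 150)
  panel <- select_review_panel(a, corp, seed = 3)
  expect_equal(nrow(panel), 40L)
  expect_equal(sum(panel$stratum == "certain"), 32L)
  expect_equal(sum(panel$stratum == "uncertain"), 8L)
  expect_false(anyDuplicated(panel$participant_id) > 0)
  # uncertain picks come from the mixed block only
  expect_true(all(panel$participant_id[panel$stratum == "uncertain"]
                  %in% ids[41:50]))

  # activity filter: 29 days is ineligible no matter the volume
  corp29 <- flat_corpus(ids, days = c(rep(29, 10), rep(40, 45)),
                        obs = 500)
  expect_error(select_review_panel(a, corp29, seed = 3),
               "certain, phenotype 1")

  # insufficient uncertain stratum is named
  a2 <- theta_assignments(theta[1:40, ], ids[1:40])
  expect_error(select_review_panel(a2, flat_corpus(ids[1:40], 40, 150),
                                   seed = 1),
               "uncertain")
})
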