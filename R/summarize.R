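#' Hard phenotype assignments
#'
#' Collapses membership posteriors to a hard label per participant (argmax,
#' ties to the lowest index) plus a "clear" flag when the maximum membership
#' probability exceeds `threshold` (0.9 by default: in the endometriosis
#' cohort most participants sat above this line).
#'
#' @param fit An `endo_fit`, or a row-stochastic `D x K` matrix with
#'   participant ids as rownames.
#' @param threshold Clear-assignment probability threshold.
#' @return A tibble of class `endo_assignments` with columns
#'   `participant_id`, `p_1` ... `p_K`, `phenotype`, `max_probability`,
#'   `clear`.
#' @export
hard_assign <- function(fit, threshold = 0.9) {
  theta <- if (inherits(fit, "endo_fit")) fit$theta else fit
  stopifnot(is.matrix(theta), !is.null(rownames(theta)))
  K <- ncol(theta)
  out <- tibble::as_tibble(theta, .name_repair = "minimal")
  names(out) <- paste0("p_", seq_len(K))
  out <- dplyr::bind_cols(
    tibble::tibble(participant_id = rownames(theta)), out
  )
  out$phenotype <- unname(apply(theta, 1L, which.max))
  out$max_probability <- unname(apply(theta, 1L, max))
  out$clear <- out$max_probability > threshold
  class(out) <- c("endo_assignments", class(out))
  out
}

assignment_probs <- function(assignments) {
  as.matrix(assignments[grepl("^p_[0-9]+$", names(assignments))])
}

#' Top answers of a phenotype for one question
#'
#' The `n` highest-probability vocabulary items of the phenotype's posterior
#' answer distribution, in descending order (ties resolved in vocabulary
#' order); fewer if the vocabulary is smaller than `n`.
#'
#' @param fit An `endo_fit`.
#' @param question_id Question key.
#' @param phenotype Phenotype index in `1..K`.
#' @param n Number of items (default 10, the heatmap display depth).
#' @return A tibble with `rank`, `token`, `probability`.
#' @export
top_answers <- function(fit, question_id, phenotype, n = 10L) {
  stopifnot(inherits(fit, "endo_fit"), n >= 1)
  if (!question_id %in% names(fit$phi)) {
    stop("unknown question: ", question_id, call. = FALSE)
  }
  if (phenotype < 1 || phenotype > fit$hyper$K) {
    stop("phenotype must be in 1..", fit$hyper$K, call. = FALSE)
  }
  row <- fit$phi[[question_id]][phenotype, ]
  ord <- order(-row)  # stable: ties in vocabulary order
  take <- ord[seq_len(min(n, length(row)))]
  tibble::tibble(
    rank = seq_along(take),
    token = names(row)[take],
    probability = unname(row[take])
  )
}

#' Answer-cloud weights for one phenotype and question
#'
#' The minimal prefix of the descending-sorted posterior whose cumulative
#' probability reaches `mass` (>= at the boundary), renormalised to sum
#' to 1. Comparing raw posteriors across questions with very different
#' vocabulary sizes is misleading; conditioning on the items covering a
#' fixed 80% of the per-question posterior mass makes relative weights
#' comparable, and font sizes in a rendered answer-cloud are proportional
#' to these weights.
#'
#' @param fit An `endo_fit`.
#' @param question_id Question key.
#' @param phenotype Phenotype index.
#' @param mass Posterior mass to cover, in (0, 1].
#' @return A tibble with `token`, `posterior` (original probability) and
#'   `weight` (renormalised; sums to 1).
#' @export
cloud_weights <- function(fit, question_id, phenotype, mass = 0.8) {
  stopifnot(mass > 0, mass <= 1)
  full <- top_answers(fit, question_id, phenotype,
                      n = ncol(fit$phi[[question_id]]))
  m <- min(which(cumsum(full$probability) >= mass - 1e-12))
  pre <- full[seq_len(m), ]
  tibble::tibble(
    token = pre$token,
    posterior = pre$probability,
    weight = pre$probability / sum(pre$probability)
  )
}

spearman_perm <- function(x, y, n_perm) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(c(rho = 0, p = 1))  # degenerate variance: no association
  }
  rho <- stats::cor(x, y, method = "spearman")
  perm <- vapply(seq_len(n_perm), function(i) {
    stats::cor(x, sample(y), method = "spearman")
  }, numeric(1))
  c(rho = rho, p = (1 + sum(abs(perm) >= abs(rho))) / (1 + n_perm))
}

#' Assignment-vs-tracking-volume diagnostic
#'
#' A fit that tracked engagement rather than disease would show phenotype
#' memberships correlated with how much participants tracked. Reports, per
#' phenotype and volume measure (`days_tracked`, `n_observations`, their
#' ratio), two Spearman correlations with permutation p-values:
#'
#' * `rho_membership` — hard membership in the phenotype (0/1 indicator)
#'   against the measure. This is the statistic that answers whether the
#'   *assignments* track engagement, and the one to read first.
#' * `rho_probability` — the posterior membership probability against the
#'   measure. Read with care: under Dirichlet smoothing a participant whose
#'   tokens never visit phenotype k has probability exactly
#'   `alpha / (N_d + K alpha)`, a deterministically decreasing function of
#'   their observation count, so this correlation is pulled negative by
#'   arithmetic alone even when assignments are perfectly independent of
#'   volume.
#'
#' A per-measure Kruskal-Wallis test of the measure across hard labels is
#' attached as attribute `"hard_label_tests"`. Participants with zero
#' tracked days are excluded from the observations-per-day measure.
#'
#' @param assignments An `endo_assignments` from [hard_assign()].
#' @param corpus The corpus the model was fitted on.
#' @param n_perm Permutations for the p-value.
#' @param seed Integer seed for the permutations.
#' @return A tibble with columns `measure`, `phenotype`, `rho_membership`,
#'   `p_membership`, `rho_probability`, `p_probability`.
#' @export
volume_correlation <- function(assignments, corpus, n_perm = 999L,
                               seed = 1L) {
  stopifnot(inherits(assignments, "endo_assignments"),
            inherits(corpus, "endo_corpus"))
  parts <- corpus$participants
  if (!all(assignments$participant_id %in% parts$participant_id)) {
    stop("assignments contain participants absent from the corpus",
         call. = FALSE)
  }
  dat <- dplyr::left_join(
    assignments, parts, by = "participant_id"
  )
  dat$ratio <- ifelse(dat$days_tracked > 0,
                      dat$n_observations / dat$days_tracked, NA_real_)
  n_zero_days <- sum(dat$days_tracked == 0)
  if (n_zero_days > 0) {
    message(n_zero_days,
            " participant(s) with zero tracked days excluded from the ",
            "observations-per-day measure")
  }
  probs <- assignment_probs(dat)
  measures <- list(days_tracked = dat$days_tracked,
                   n_observations = dat$n_observations,
                   obs_per_day = dat$ratio)
  set.seed(seed)
  rows <- purrr::imap_dfr(measures, function(m, mname) {
    ok <- !is.na(m)
    purrr::map_dfr(seq_len(ncol(probs)), function(k) {
      ind <- spearman_perm(as.numeric(dat$phenotype[ok] == k), m[ok], n_perm)
      pr <- spearman_perm(probs[ok, k], m[ok], n_perm)
      tibble::tibble(measure = mname, phenotype = k,
                     rho_membership = unname(ind["rho"]),
                     p_membership = unname(ind["p"]),
                     rho_probability = unname(pr["rho"]),
                     p_probability = unname(pr["p"]))
    })
  })
  hard <- purrr::imap_dfr(measures, function(m, mname) {
    ok <- !is.na(m)
    if (length(unique(dat$phenotype[ok])) < 2L ||
        length(unique(m[ok])) < 2L) {
      return(tibble::tibble(measure = mname, statistic = NA_real_,
                            p_value = NA_real_))
    }
    kt <- stats::kruskal.test(m[ok], factor(dat$phenotype[ok]))
    tibble::tibble(measure = mname,
                   statistic = unname(kt$statistic),
                   p_value = kt$p.value)
  })
  attr(rows, "hard_label_tests") <- hard
  rows
}
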