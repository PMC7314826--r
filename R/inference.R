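#' Model hyperparameters
#'
#' Symmetric Dirichlet hyperparameters of the multi-modal mixed-membership
#' model: `K` phenotypes, concentration `alpha` over per-participant
#' phenotype proportions and `beta` over per-question answer distributions.
#' The sparse setting `K = 4, alpha = beta = 0.001` is the configuration
#' selected for the endometriosis cohort analysis.
#'
#' @param K Integer >= 1.
#' @param alpha,beta Positive concentrations.
#' @return A list of class `endo_hyper`.
#' @export
hyperparameters <- function(K = 4L, alpha = 0.001, beta = 0.001) {
  if (!is.numeric(K) || K < 1 || K != round(K)) {
    stop("K must be an integer >= 1", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (!is.numeric(beta) || beta <= 0) stop("beta must be > 0", call. = FALSE)
  structure(list(K = as.integer(K), alpha = alpha, beta = beta),
            class = "endo_hyper")
}

recount_tables <- function(tokens, z, K) {
  Q <- tokens$Q
  c_dk <- matrix(0L, tokens$D, K)
  c_kq <- matrix(0L, K, Q)
  c_kqv <- purrr::map(seq_len(Q), function(q) matrix(0L, K, tokens$Vq[q]))
  for (i in seq_along(z)) {
    k <- z[i]; d <- tokens$d[i]; q <- tokens$q[i]; v <- tokens$v[i]
    c_dk[d, k] <- c_dk[d, k] + 1L
    c_kq[k, q] <- c_kq[k, q] + 1L
    c_kqv[[q]][k, v] <- c_kqv[[q]][k, v] + 1L
  }
  list(c_dk = c_dk, c_kq = c_kq, c_kqv = c_kqv)
}

#' Initialise a collapsed Gibbs state
#'
#' Assigns every token a phenotype uniformly at random and tallies the
#' sufficient-count tables. Token visit order is fixed (participant order,
#' then schema question order, then vocabulary order) so runs are
#' reproducible from the seed alone.
#'
#' @param corpus An `endo_corpus` with at least one token.
#' @param hyper [hyperparameters()].
#' @param seed Integer seed.
#' @return A list of class `endo_gibbs_state` with fields `z`, `c_dk`,
#'   `c_kqv`, `c_kq`, `hyper`, `tokens`.
#' @export
init_state <- function(corpus, hyper, seed = 1L) {
  stopifnot(inherits(corpus, "endo_corpus"), inherits(hyper, "endo_hyper"))
  tokens <- corpus_tokens(corpus)
  set.seed(seed)
  z <- sample.int(hyper$K, length(tokens$d), replace = TRUE)
  counts <- recount_tables(tokens, z, hyper$K)
  structure(
    c(list(z = z, hyper = hyper, tokens = tokens), counts),
    class = "endo_gibbs_state"
  )
}

#' Collapsed full conditional for one token
#'
#' The probability vector `P(z = k | z_-token, data)` proportional to
#' `(c_dk + alpha) * (c_kqv + beta) / (c_kq + V_q * beta)`, with the token's
#' own current assignment excluded from all counts. The denominator uses the
#' vocabulary size of the token's own question — the multi-modal extension
#' over vanilla LDA.
#'
#' @param state An `endo_gibbs_state`.
#' @param i Token index (in the state's canonical order).
#' @return A normalised numeric vector of length `K`.
#' @export
gibbs_conditional <- function(state, i) {
  stopifnot(inherits(state, "endo_gibbs_state"))
  tk <- state$tokens
  d <- tk$d[i]; q <- tk$q[i]; v <- tk$v[i]; k0 <- state$z[i]
  K <- state$hyper$K
  a <- state$hyper$alpha; b <- state$hyper$beta
  cdk <- state$c_dk[d, ]; cdk[k0] <- cdk[k0] - 1L
  ckv <- state$c_kqv[[q]][, v]; ckv[k0] <- ckv[k0] - 1L
  ckq <- state$c_kq[, q]; ckq[k0] <- ckq[k0] - 1L
  w <- (cdk + a) * (ckv + b) / (ckq + tk$Vq[q] * b)
  w / sum(w)
}

#' One systematic-scan Gibbs sweep
#'
#' Resamples every token once, in the canonical visit order. Count-table
#' invariants are preserved exactly (tallying `z` reproduces all tables).
#'
#' @param state An `endo_gibbs_state`.
#' @param n_sweeps Number of consecutive sweeps to run (default 1).
#' @return The updated `endo_gibbs_state`.
#' @export
gibbs_sweep <- function(state, n_sweeps = 1L) {
  stopifnot(inherits(state, "endo_gibbs_state"))
  tk <- state$tokens
  res <- cpp_gibbs_run(state$z, tk$d, tk$q, tk$v, tk$D, state$hyper$K,
                       tk$Vq, state$hyper$alpha, state$hyper$beta,
                       as.integer(n_sweeps), as.integer(n_sweeps), 1L, FALSE)
  state$z <- res$z
  state$c_dk <- res$c_dk
  state$c_kqv <- res$c_kqv
  state$c_kq <- res$c_kq
  state
}

#' Fit the multi-modal mixed-membership phenotype model
#'
#' Collapsed Gibbs sampling over token-level phenotype assignments, with
#' posterior-mean estimates averaged over retained post-burn-in sweeps:
#' `phi_kqv = mean (c_kqv + beta) / (c_kq + V_q beta)` and
#' `theta_dk = mean (c_dk + alpha) / (N_d + K alpha)`.
#'
#' Participants with zero observations carry no likelihood and are excluded
#' from the fit (a message reports how many).
#'
#' @param corpus An `endo_corpus`.
#' @param hyper [hyperparameters()].
#' @param n_iter Total sweeps (> `burn_in`).
#' @param burn_in Discarded initial sweeps (>= 0).
#' @param thin Keep every `thin`-th post-burn-in sweep.
#' @param seed Integer seed.
#' @return An object of class `endo_fit`: list with `phi` (per-question
#'   `K x V_q` matrices, columns named by vocabulary), `theta` (`D x K`,
#'   rows named by participant id), `hyper`, `state` (final
#'   `endo_gibbs_state`), `schema`, `n_iter`, `burn_in`, `thin`, `seed`.
#' @export
#' @examples
#' sim <- sample_corpus(generator_config(D = 30, seed = 7))
#' fit <- fit_phenotypes(sim$corpus, hyperparameters(K = 2, 0.1, 0.1),
#'                       n_iter = 50, burn_in = 25, seed = 7)
#' head(tidy(fit, "theta"))
fit_phenotypes <- function(corpus, hyper = hyperparameters(),
                           n_iter = 2000L, burn_in = 1000L, thin = 10L,
                           seed = 1L) {
  stopifnot(inherits(corpus, "endo_corpus"), inherits(hyper, "endo_hyper"))
  if (!(n_iter > burn_in && burn_in >= 0)) {
    stop("need n_iter > burn_in >= 0", call. = FALSE)
  }
  tokens <- corpus_tokens(corpus)
  if (tokens$n_dropped > 0L) {
    message(tokens$n_dropped,
            " participant(s) with zero observations excluded from the fit")
  }
  set.seed(seed)
  z0 <- sample.int(hyper$K, length(tokens$d), replace = TRUE)
  res <- cpp_gibbs_run(z0, tokens$d, tokens$q, tokens$v, tokens$D, hyper$K,
                       tokens$Vq, hyper$alpha, hyper$beta,
                       as.integer(n_iter), as.integer(burn_in),
                       as.integer(thin), FALSE)
  schema <- corpus$schema
  phi <- purrr::map2(res$phi, schema$vocabulary, function(m, voc) {
    dimnames(m) <- list(NULL, voc)
    m
  })
  names(phi) <- schema$question_id
  theta <- res$theta
  rownames(theta) <- tokens$participant_ids
  state <- structure(
    list(z = res$z, c_dk = res$c_dk, c_kqv = res$c_kqv, c_kq = res$c_kq,
         hyper = hyper, tokens = tokens),
    class = "endo_gibbs_state"
  )
  structure(
    list(phi = phi, theta = theta, hyper = hyper, state = state,
         schema = schema, n_iter = n_iter, burn_in = burn_in, thin = thin,
         seed = seed),
    class = "endo_fit"
  )
}

#' Fit the concatenated-vocabulary vanilla LDA baseline
#'
#' Identical sampler run on [concatenate_view()] of the corpus: a single
#' question whose vocabulary is all per-question vocabularies concatenated,
#' so Dirichlet smoothing uses the pooled size `sum(V_q)` everywhere. On a
#' one-question corpus this coincides with [fit_phenotypes()] exactly.
#'
#' @inheritParams fit_phenotypes
#' @return An `endo_fit` on the concatenated corpus.
#' @export
fit_baseline <- function(corpus, hyper = hyperparameters(),
                         n_iter = 2000L, burn_in = 1000L, thin = 10L,
                         seed = 1L) {
  fit_phenotypes(concatenate_view(corpus), hyper, n_iter, burn_in, thin, seed)
}

#' @export
print.endo_fit <- function(x, ...) {
  cat("<endo_fit> K = ", x$hyper$K,
      ", alpha = ", x$hyper$alpha, ", beta = ", x$hyper$beta,
      "; ", nrow(x$theta), " participants, ",
      length(x$phi), " questions; ", x$n_iter, " sweeps (burn-in ",
      x$burn_in, ", thin ", x$thin, ")\n", sep = "")
  invisible(x)
}

#' Tidy a fitted phenotype model
#'
#' `matrix = "phi"` returns the per-question answer posteriors in long form
#' (`phenotype`, `question_id`, `token`, `probability`); `matrix = "theta"`
#' the per-participant membership posteriors (`participant_id`, `phenotype`,
#' `probability`).
#'
#' @param x An `endo_fit`.
#' @param matrix `"phi"` or `"theta"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.endo_fit <- function(x, matrix = c("phi", "theta"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "phi") {
    purrr::imap_dfr(x$phi, function(m, q) {
      tibble::tibble(
        phenotype = rep(seq_len(nrow(m)), ncol(m)),
        question_id = q,
        token = rep(colnames(m), each = nrow(m)),
        probability = as.vector(m)
      )
    })
  } else {
    tibble::tibble(
      participant_id = rep(rownames(x$theta), ncol(x$theta)),
      phenotype = rep(seq_len(ncol(x$theta)), each = nrow(x$theta)),
      probability = as.vector(x$theta)
    )
  }
}

#' One-row summary of a fitted phenotype model
#'
#' @param x An `endo_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the hyperparameters, cohort size, token
#'   count and sampler settings.
#' @export
glance.endo_fit <- function(x, ...) {
  tibble::tibble(
    K = x$hyper$K, alpha = x$hyper$alpha, beta = x$hyper$beta,
    n_participants = nrow(x$theta),
    n_questions = length(x$phi),
    n_tokens = length(x$state$z),
    n_iter = x$n_iter, burn_in = x$burn_in, thin = x$thin, seed = x$seed
  )
}

#' Align phenotype labels between two models
#'
#' The model is identified only up to a permutation of phenotype labels.
#' Finds the permutation of `phi_hat`'s rows minimising the mean total
#' variation distance to `phi_ref` across all questions (exact search over
#' the `K!` permutations).
#'
#' @param phi_hat,phi_ref Lists of `K x V_q` matrices, same shapes.
#' @return A list with `perm` (index such that `phi_hat[[q]][perm, ]` lines
#'   up with `phi_ref`), `tv` (per phenotype x question matrix of aligned
#'   total-variation distances) and `mean_tv`.
#' @export
match_phenotypes <- function(phi_hat, phi_ref) {
  K <- nrow(phi_ref[[1]])
  perms <- permutations(K)
  # cost[i, j]: mean TV over questions between phi_hat row i and phi_ref row j
  cost <- matrix(0, K, K)
  for (q in seq_along(phi_ref)) {
    for (i in seq_len(K)) for (j in seq_len(K)) {
      cost[i, j] <- cost[i, j] +
        0.5 * sum(abs(phi_hat[[q]][i, ] - phi_ref[[q]][j, ]))
    }
  }
  cost <- cost / length(phi_ref)
  scores <- vapply(seq_len(nrow(perms)), function(p) {
    sum(cost[cbind(perms[p, ], seq_len(K))])
  }, numeric(1))
  best <- perms[which.min(scores), ]
  tv <- t(vapply(seq_along(phi_ref), function(q) {
    vapply(seq_len(K), function(j) {
      0.5 * sum(abs(phi_hat[[q]][best[j], ] - phi_ref[[q]][j, ]))
    }, numeric(1))
  }, numeric(K)))
  list(perm = best, tv = tv, mean_tv = mean(tv))
}

permutations <- function(K) {
  if (K == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(K - 1L)
  do.call(rbind, lapply(seq_len(K), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
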