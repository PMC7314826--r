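#' Configure the synthetic-cohort generator
#'
#' The generator draws corpora from the model's own generative process:
#' per-participant phenotype proportions `theta_d ~ Dirichlet(alpha_true)`,
#' per-question observation counts from a right-skewed volume model, and each
#' token's phenotype then answer from `theta_d` and the phenotype's
#' per-question answer distribution.
#'
#' The default `alpha_true = 0.01` emulates a cohort in which most
#' participants belong dominantly to a single phenotype (about 94% of
#' Dirichlet(0.01) draws at `K = 4` put over 0.9 of their mass on one
#' component), matching the strongly separated membership profile the model
#' is meant to recover; raise it to generate more mixed cohorts.
#'
#' @param K_true Number of latent phenotypes (>= 1).
#' @param alpha_true Symmetric Dirichlet concentration for proportions.
#' @param beta_true Symmetric Dirichlet concentration used to draw the
#'   per-phenotype answer distributions, or a list (one matrix per question,
#'   `K_true` x `V_q`, rows summing to 1) of explicit distributions. The
#'   `"well-separated"` preset corresponds to `beta_true = 0.01`.
#' @param D Number of participants (>= 1).
#' @param volume Output of [volume_model()]: the per-question negative
#'   binomial observation-count model.
#' @param volume_phenotype_coupling If `TRUE`, participants whose dominant
#'   phenotype is 1 get doubled volume means (a positive control for the
#'   assignment-vs-volume diagnostic). Default `FALSE`: counts are sampled
#'   independently of `theta_d`.
#' @param seed Integer seed; the same seed reproduces the corpus exactly.
#' @return A list of class `endo_generator_config`.
#' @export
generator_config <- function(K_true = 4L, alpha_true = 0.01, beta_true = 0.1,
                             D = 500L, volume = volume_model(),
                             volume_phenotype_coupling = FALSE,
                             seed = 1L) {
  if (!is.numeric(D) || D < 1) {
    stop("D must be a positive participant count", call. = FALSE)
  }
  if (!is.numeric(alpha_true) || alpha_true <= 0) {
    stop("alpha_true must be > 0", call. = FALSE)
  }
  if (is.numeric(beta_true) && beta_true <= 0) {
    stop("beta_true must be > 0 (or an explicit phi list)", call. = FALSE)
  }
  if (!is.numeric(K_true) || K_true < 1) {
    stop("K_true must be >= 1", call. = FALSE)
  }
  structure(
    list(K_true = as.integer(K_true), alpha_true = alpha_true,
         beta_true = beta_true, D = as.integer(D), volume = volume,
         volume_phenotype_coupling = isTRUE(volume_phenotype_coupling),
         seed = as.integer(seed)),
    class = "endo_generator_config"
  )
}

#' Per-question observation-volume model
#'
#' Negative binomial counts per participant and question. The default means
#' follow the published per-question tracking averages of the Phendo cohort
#' (e.g. 31 for pain location, 42 for difficult activities, 15 for
#' medications) and a small dispersion size produces the heavy right skew
#' seen there (max/mean ratios near 100). `days_mean`/`days_size` govern the
#' per-participant count of distinct tracking days, drawn independently of
#' the answer process.
#'
#' @param mean Scalar or per-question vector of negative binomial means.
#' @param size Negative binomial dispersion (smaller = heavier tail).
#' @param days_mean,days_size Negative binomial parameters for days tracked.
#' @return A list of class `endo_volume_model`.
#' @export
volume_model <- function(mean = NULL, size = 0.25,
                         days_mean = 35, days_size = 1.2) {
  structure(
    list(mean = mean, size = size, days_mean = days_mean,
         days_size = days_size),
    class = "endo_volume_model"
  )
}

# Published per-question mean observation counts, in default schema order.
phendo_question_means <- function() {
  c(pain_location = 31, pain_description = 29, pain_severity = 10,
    symptoms = 9, symptom_severity = 5, period_flow = 3, bleeding_kind = 2,
    gigu = 7, gigu_severity = 6, sex = 1, hard_activities = 42,
    medications = 15, day_quality = 13)
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  s <- rowSums(x)
  # tiny concentrations underflow all gammas to 0; in the alpha -> 0 limit a
  # symmetric Dirichlet draw is a one-hot vector at a category drawn ~ alpha
  bad <- which(!is.finite(s) | s <= 0)
  for (i in bad) {
    x[i, ] <- 0
    x[i, sample.int(k, 1L, prob = alpha)] <- 1
    s[i] <- 1
  }
  x / s
}

#' Sample a synthetic self-tracking corpus with ground truth
#'
#' @param config An [generator_config()].
#' @param schema Question schema; defaults to the 13-question tracking
#'   schema of [default_phendo_schema()].
#' @return A list with elements `corpus` (an `endo_corpus`) and `truth`
#'   (class `endo_ground_truth`: `phi_true` — per-question `K x V_q`
#'   matrices, `theta_true` — `D x K`, `z_true` — per-token labels in
#'   canonical token order, `dominant_phenotype` — `argmax theta`, ties to
#'   the lowest index).
#' @export
#' @examples
#' sim <- sample_corpus(generator_config(D = 20, seed = 42))
#' sim$corpus
sample_corpus <- function(config, schema = default_phendo_schema()) {
  stopifnot(inherits(config, "endo_generator_config"),
            inherits(schema, "endo_schema"))
  set.seed(config$seed)
  K <- config$K_true
  D <- config$D
  Q <- nrow(schema)
  Vq <- schema_sizes(schema)

  mu <- config$volume$mean
  if (is.null(mu)) {
    mu <- if (identical(schema$question_id,
                        names(phendo_question_means()))) {
      unname(phendo_question_means())
    } else {
      rep(10, Q)
    }
  }
  mu <- rep_len(mu, Q)

  phi <- if (is.list(config$beta_true)) {
    stopifnot(length(config$beta_true) == Q)
    config$beta_true
  } else {
    purrr::map(seq_len(Q), function(q) {
      rdirichlet(K, rep(config$beta_true, Vq[q]))
    })
  }
  names(phi) <- schema$question_id

  theta <- rdirichlet(D, rep(config$alpha_true, K))
  dominant <- apply(theta, 1L, which.max)  # which.max ties -> lowest index

  days <- stats::rnbinom(D, mu = config$volume$days_mean,
                         size = config$volume$days_size) + 1L
  pids <- sprintf("P%04d", seq_len(D))

  rows <- vector("list", D)
  z_all <- vector("list", D)
  for (d in seq_len(D)) {
    scale_d <- if (config$volume_phenotype_coupling && dominant[d] == 1L) 2 else 1
    n_dq <- stats::rnbinom(Q, mu = mu * scale_d, size = config$volume$size)
    dz <- integer(0)
    drows <- vector("list", Q)
    for (q in seq_len(Q)) {
      n <- n_dq[q]
      if (n == 0L) next
      z <- sample.int(K, n, replace = TRUE, prob = theta[d, ])
      v <- vapply(z, function(k) {
        sample.int(Vq[q], 1L, prob = phi[[q]][k, ])
      }, integer(1))
      # canonical order within (d, q): ascending vocabulary index
      o <- order(v)
      v <- v[o]; z <- z[o]
      cnt <- table(factor(v, levels = seq_len(Vq[q])))
      keep <- cnt > 0
      drows[[q]] <- tibble::tibble(
        participant_id = pids[d],
        question_id = schema$question_id[q],
        token = schema$vocabulary[[q]][which(keep)],
        count = as.integer(cnt[keep])
      )
      dz <- c(dz, z)
    }
    rows[[d]] <- dplyr::bind_rows(drows)
    z_all[[d]] <- dz
  }
  answers <- dplyr::bind_rows(rows)
  participants <- tibble::tibble(participant_id = pids, days_tracked = days)
  corpus <- endo_corpus(schema, answers, participants)
  truth <- structure(
    list(phi_true = phi,
         theta_true = `rownames<-`(theta, pids),
         z_true = unlist(z_all),
         dominant_phenotype = stats::setNames(dominant, pids)),
    class = "endo_ground_truth"
  )
  list(corpus = corpus, truth = truth)
}

#' Declare survey covariates with phenotype effects
#'
#' Builds the covariate specification consumed by [sample_survey()]. Each
#' covariate is either categorical (per-phenotype level distributions) or
#' continuous (per-phenotype location shifts on a Gaussian base).
#'
#' @param name Covariate name.
#' @param type `"categorical"` or `"continuous"`.
#' @param levels Character vector of levels (categorical).
#' @param base_probs Base level distribution (categorical; defaults uniform).
#' @param effect_size In `[0, 1]` for categorical: 0 leaves every phenotype
#'   at `base_probs`, 1 concentrates phenotype k's distribution on level
#'   `1 + (k-1) mod L`. For continuous: the per-phenotype location step, in
#'   units of `sd`.
#' @param mean,sd Base Gaussian parameters (continuous).
#' @param missingness Probability in `[0, 1)` that a cell is missing.
#' @return A one-row tibble; rows from repeated calls can be bound together
#'   into a full specification.
#' @export
survey_covariate <- function(name, type = c("categorical", "continuous"),
                             levels = c("no", "yes"), base_probs = NULL,
                             effect_size = 0, mean = 0, sd = 1,
                             missingness = 0) {
  type <- match.arg(type)
  if (missingness < 0 || missingness >= 1) {
    stop("missingness must be in [0, 1)", call. = FALSE)
  }
  if (type == "categorical") {
    if (is.null(base_probs)) base_probs <- rep(1 / length(levels), length(levels))
    if (length(base_probs) != length(levels) ||
        abs(sum(base_probs) - 1) > 1e-8 || any(base_probs < 0)) {
      stop("base_probs must be a simplex over `levels`", call. = FALSE)
    }
    if (effect_size < 0 || effect_size > 1) {
      stop("categorical effect_size must be in [0, 1]", call. = FALSE)
    }
  }
  tibble::tibble(
    name = name, type = type,
    levels = list(levels), base_probs = list(base_probs),
    effect_size = effect_size, mean = mean, sd = sd,
    missingness = missingness
  )
}

# per-phenotype level distribution implied by a categorical covariate row
covariate_level_probs <- function(row, K) {
  L <- length(row$levels[[1]])
  base <- row$base_probs[[1]]
  t(vapply(seq_len(K), function(k) {
    point <- numeric(L)
    point[1L + (k - 1L) %% L] <- 1
    (1 - row$effect_size) * base + row$effect_size * point
  }, numeric(L)))
}

#' Sample a survey covariate table from ground truth
#'
#' Categorical covariates are drawn from the level distribution of each
#' participant's dominant phenotype; continuous covariates from a Gaussian
#' base shifted by `effect_size * sd * (k - 1)` for dominant phenotype `k`.
#' Missing cells are `NA`.
#'
#' @param truth `endo_ground_truth` from [sample_corpus()].
#' @param spec Tibble of covariate rows from [survey_covariate()].
#' @param seed Integer seed.
#' @return A tibble keyed by `participant_id`.
#' @export
sample_survey <- function(truth, spec, seed = 1L) {
  stopifnot(inherits(truth, "endo_ground_truth"))
  set.seed(seed)
  dom <- truth$dominant_phenotype
  D <- length(dom)
  K <- ncol(truth$theta_true)
  out <- tibble::tibble(participant_id = names(dom))
  for (i in seq_len(nrow(spec))) {
    row <- spec[i, ]
    if (row$type == "categorical") {
      probs <- covariate_level_probs(row, K)
      lv <- row$levels[[1]]
      val <- vapply(dom, function(k) sample(lv, 1L, prob = probs[k, ]),
                    character(1))
    } else if (row$type == "continuous") {
      shift <- row$effect_size * row$sd * (dom - 1)
      val <- stats::rnorm(D, mean = row$mean + shift, sd = row$sd)
    } else {
      stop("unknown covariate type: ", row$type, call. = FALSE)
    }
    if (row$missingness > 0) {
      val[stats::runif(D) < row$missingness] <- NA
    }
    out[[row$name]] <- unname(val)
  }
  out
}
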