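# Independent oracles and small fixture builders shared across tests.
# Everything here is brute force / closed form on purpose: none of it reuses
# the package's sampler or estimator code paths.

# Exact collapsed posterior over all K^N assignment vectors, by enumerating
# the joint p(z, w) with Dirichlet-multinomial weights per participant and
# per (phenotype, question) block.
enum_assignment_posterior <- function(tokens, K, alpha, beta) {
  N <- length(tokens$d)
  Q <- tokens$Q
  states <- as.matrix(expand.grid(rep(list(seq_len(K)), N)))
  logp <- apply(states, 1L, function(z) {
    lp <- 0
    for (d in seq_len(tokens$D)) {
      nd <- sum(tokens$d == d)
      cdk <- tabulate(z[tokens$d == d], K)
      lp <- lp + lgamma(K * alpha) - lgamma(nd + K * alpha) +
        sum(lgamma(cdk + alpha)) - K * lgamma(alpha)
    }
    for (k in seq_len(K)) {
      for (q in seq_len(Q)) {
        ckqv <- tabulate(tokens$v[tokens$q == q & z == k], tokens$Vq[q])
        lp <- lp + lgamma(tokens$Vq[q] * beta) -
          lgamma(sum(ckqv) + tokens$Vq[q] * beta) +
          sum(lgamma(ckqv + beta)) - tokens$Vq[q] * lgamma(beta)
      }
    }
    lp
  })
  p <- exp(logp - max(logp))
  list(states = states, prob = p / sum(p))
}

# Pearson chi-square statistic from the definition, no library call.
chisq_oracle <- function(m) {
  m <- as.matrix(m)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# Kruskal-Wallis H from the rank formula with tie correction.
kw_oracle <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  n <- length(x)
  rbar <- tapply(r, g, mean)
  ng <- lengths(groups)
  h <- 12 / (n * (n + 1)) * sum(ng * (rbar - (n + 1) / 2)^2)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# A 2-question, 2-participant, 5-token corpus small enough for exact
# enumeration of the assignment posterior.
tiny_corpus <- function() {
  schema <- question_schema(c("q1", "q2"),
                            vocabulary = list(c("a", "b"), c("x", "y", "z")))
  answers <- tibble::tribble(
    ~participant_id, ~question_id, ~token, ~count,
    "p1", "q1", "a", 2L,
    "p1", "q2", "x", 1L,
    "p2", "q1", "b", 1L,
    "p2", "q2", "z", 1L
  )
  endo_corpus(schema, answers,
              tibble::tibble(participant_id = c("p1", "p2"),
                             days_tracked = c(3L, 2L)))
}

# One participant, one binary question, two tokens (a then b): the worked
# instance for checking the collapsed Gibbs conditional by enumeration.
two_token_corpus <- function() {
  schema <- question_schema("q1", vocabulary = list(c("a", "b")))
  answers <- tibble::tibble(participant_id = "p1", question_id = "q1",
                            token = c("a", "b"), count = c(1L, 1L))
  endo_corpus(schema, answers)
}

# Assignments object built directly from a theta matrix.
theta_assignments <- function(theta, ids = sprintf("P%03d", seq_len(nrow(theta)))) {
  rownames(theta) <- ids
  hard_assign(theta)
}

# Corpus whose participants all have the given days/observation counts on a
# trivial one-question schema (for panel-eligibility tests).
flat_corpus <- function(ids, days, obs) {
  schema <- question_schema("q1", vocabulary = list(c("a", "b")))
  answers <- tibble::tibble(participant_id = ids, question_id = "q1",
                            token = "a", count = as.integer(obs))
  endo_corpus(schema, answers,
              tibble::tibble(participant_id = ids,
                             days_tracked = as.integer(days)))
}
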