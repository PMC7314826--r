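#' Select the expert review panel
#'
#' Reproduces the review-panel design: participants with at least
#' `min_days` days of activity and more than `min_obs` tracked
#' observations are eligible; from them, `n_certain` participants per
#' phenotype with maximum membership probability above
#' `certain_threshold`, plus `n_uncertain` participants for which at least
#' `uncertain_mass` of the membership mass is shared by more than one
#' phenotype (top-two mass at or above `uncertain_mass` and maximum at or
#' below `certain_threshold`), sampled uniformly without replacement within
#' each stratum. With the defaults and `K = 4` the panel has
#' `8 * 4 + 8 = 40` members.
#'
#' @param assignments An `endo_assignments`.
#' @param corpus The corpus (supplies days and observation counts).
#' @param seed Integer seed for the stratified sampling.
#' @param n_certain,n_uncertain Panel sizes per stratum.
#' @param certain_threshold,uncertain_mass Posterior cut-offs.
#' @param min_days,min_obs Activity filter (`days >= min_days`,
#'   `observations > min_obs`).
#' @return A tibble of class `endo_panel`: `participant_id`, `stratum`
#'   (`"certain"`/`"uncertain"`), `phenotype` (`NA` for the uncertain
#'   stratum), `max_probability`.
#' @export
select_review_panel <- function(assignments, corpus, seed = 1L,
                                n_certain = 8L, n_uncertain = 8L,
                                certain_threshold = 0.95,
                                uncertain_mass = 0.80,
                                min_days = 30L, min_obs = 100L) {
  stopifnot(inherits(assignments, "endo_assignments"),
            inherits(corpus, "endo_corpus"))
  dat <- dplyr::inner_join(assignments, corpus$participants,
                           by = "participant_id")
  eligible <- dat[dat$days_tracked >= min_days & dat$n_observations > min_obs, ]
  probs <- assignment_probs(eligible)
  K <- ncol(probs)
  top2 <- apply(probs, 1L, function(p) sum(sort(p, decreasing = TRUE)[1:2]))
  certain <- eligible$max_probability > certain_threshold
  uncertain <- !certain & top2 >= uncertain_mass &
    eligible$max_probability <= certain_threshold

  set.seed(seed)
  picks <- purrr::map_dfr(seq_len(K), function(k) {
    pool <- eligible$participant_id[certain & eligible$phenotype == k]
    if (length(pool) < n_certain) {
      stop("stratum 'certain, phenotype ", k, "' has only ", length(pool),
           " eligible participants (need ", n_certain, ")", call. = FALSE)
    }
    tibble::tibble(participant_id = sample(pool, n_certain),
                   stratum = "certain", phenotype = k)
  })
  pool_u <- eligible$participant_id[uncertain]
  if (length(pool_u) < n_uncertain) {
    stop("stratum 'uncertain' has only ", length(pool_u),
         " eligible participants (need ", n_uncertain, ")", call. = FALSE)
  }
  picks <- dplyr::bind_rows(
    picks,
    tibble::tibble(participant_id = sample(pool_u, n_uncertain),
                   stratum = "uncertain", phenotype = NA_integer_)
  )
  picks$max_probability <-
    eligible$max_probability[match(picks$participant_id,
                                   eligible$participant_id)]
  class(picks) <- c("endo_panel", class(picks))
  picks
}

#' Confusion matrix between two labelings
#'
#' Cell `(i, j)` counts participants with model label `i` and reference
#' (expert) label `j`. Label spaces need not coincide.
#'
#' @param model_labels,reference_labels Named vectors (names = participant
#'   ids) or two columns of equal length over the same participants.
#' @return An integer matrix of class `endo_confusion` with model labels as
#'   rows and reference labels as columns.
#' @export
confusion <- function(model_labels, reference_labels) {
  if (!is.null(names(model_labels)) && !is.null(names(reference_labels))) {
    if (!setequal(names(model_labels), names(reference_labels))) {
      stop("model and reference labels cover different participants",
           call. = FALSE)
    }
    reference_labels <- reference_labels[names(model_labels)]
  } else if (length(model_labels) != length(reference_labels)) {
    stop("label vectors differ in length and carry no ids", call. = FALSE)
  }
  if (anyNA(model_labels) || anyNA(reference_labels)) {
    stop("labels must be non-missing", call. = FALSE)
  }
  m <- table(model = as.character(model_labels),
             reference = as.character(reference_labels))
  m <- unclass(m)
  storage.mode(m) <- "integer"
  class(m) <- c("endo_confusion", class(m))
  m
}

as_confusion <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  if (any(m < 0)) stop("confusion cells must be nonnegative", call. = FALSE)
  class(m) <- c("endo_confusion", class(m))
  m
}

#' Read a confusion matrix from CSV
#'
#' First column = model cluster labels, remaining columns = reference
#' cluster counts. The package ships the published expert-agreement
#' matrices under `inst/extdata/`: `confusion_expert{1,2}_4x4.csv` (full
#' four-phenotype comparisons) and `confusion_expert{1,2}_{severe,mild}.csv`
#' (the binary severe/mild collapses).
#'
#' @param path CSV path.
#' @return An `endo_confusion` matrix.
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  as_confusion(m)
}

#' Cluster purity of a confusion matrix
#'
#' The fraction of participants lying in their model cluster's majority
#' reference class: the sum over model rows of each row's maximum cell,
#' divided by the total count. Invariant under row/column permutations and
#' independent of any alignment between the two label spaces.
#'
#' @param m An `endo_confusion` (or plain count matrix).
#' @return A fraction in `[0, 1]`.
#' @export
#' @examples
#' purity(matrix(c(7, 2, 2, 29), 2, byrow = TRUE))  # 0.9
purity <- function(m) {
  m <- as.matrix(m)
  n <- sum(m)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  sum(apply(m, 1L, max)) / n
}

#' Collapse a confusion matrix to a 2x2 one-vs-rest table
#'
#' Sums the selected model row(s) against the rest, and the selected
#' reference column(s) against the rest — e.g. the severe/non-severe view
#' of a full four-phenotype comparison.
#'
#' @param m An `endo_confusion`.
#' @param positive_rows Model labels forming the positive row.
#' @param positive_cols Reference labels forming the positive column.
#' @param labels Length-2 names for the collapsed categories.
#' @return A 2x2 `endo_confusion`; the total count is preserved.
#' @export
collapse_to_binary <- function(m, positive_rows, positive_cols,
                               labels = c("positive", "rest")) {
  m <- as.matrix(m)
  if (!all(positive_rows %in% rownames(m))) {
    stop("unknown model label(s): ",
         paste(setdiff(positive_rows, rownames(m)), collapse = ", "),
         call. = FALSE)
  }
  if (!all(positive_cols %in% colnames(m))) {
    stop("unknown reference label(s): ",
         paste(setdiff(positive_cols, colnames(m)), collapse = ", "),
         call. = FALSE)
  }
  ri <- rownames(m) %in% positive_rows
  ci <- colnames(m) %in% positive_cols
  out <- matrix(c(sum(m[ri, ci]), sum(m[ri, !ci]),
                  sum(m[!ri, ci]), sum(m[!ri, !ci])),
                2, 2, byrow = TRUE,
                dimnames = list(model = labels, reference = labels))
  as_confusion(out)
}

#' Pearson chi-square test of independence
#'
#' Uncorrected Pearson statistic on an r x c contingency table, with
#' degrees of freedom `(r-1)(c-1)` and the upper-tail chi-square p-value.
#' A warning flag is raised when any expected count falls below 5 (the
#' usual adequacy rule); no continuity correction is applied.
#'
#' @param table An r x c matrix of counts with all row and column sums
#'   positive.
#' @param alpha Significance level for the `significant` flag.
#' @param name Covariate name carried into the result.
#' @return A one-row tibble: `covariate`, `test`, `statistic`, `df`,
#'   `p_value`, `significant`, `low_expected`.
#' @export
chi_square_independence <- function(table, alpha = 0.05, name = NA_character_) {
  m <- as.matrix(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("contingency table has a zero marginal", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble::tibble(
    covariate = name, test = "chi-square",
    statistic = unname(ct$statistic), df = unname(ct$parameter),
    p_value = ct$p.value, significant = ct$p.value < alpha,
    low_expected = any(ct$expected < 5)
  )
}

#' Kruskal-Wallis H-test across groups
#'
#' Rank-based K-sample test of equal location (the nonparametric ANOVA
#' analogue), with tie correction and the chi-square approximation on
#' `K - 1` degrees of freedom.
#'
#' @param groups A list of >= 2 numeric vectors.
#' @param alpha Significance level for the flag.
#' @param name Covariate name carried into the result.
#' @return A one-row tibble as in [chi_square_independence()] with
#'   `test = "kruskal-wallis"`.
#' @export
kruskal_wallis <- function(groups, alpha = 0.05, name = NA_character_) {
  stopifnot(is.list(groups), length(groups) >= 2)
  x <- unlist(groups)
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  if (length(unique(x)) == 1L) {
    stop("all values identical: Kruskal-Wallis is undefined", call. = FALSE)
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  tibble::tibble(
    covariate = name, test = "kruskal-wallis",
    statistic = unname(kt$statistic), df = unname(kt$parameter),
    p_value = kt$p.value, significant = kt$p.value < alpha,
    low_expected = NA
  )
}

#' Screen survey covariates for phenotype associations
#'
#' Participants enter with their maximum-posterior phenotype. Categorical
#' covariates are tested with the chi-square test of independence on the
#' phenotype x level contingency table; continuous covariates with the
#' Kruskal-Wallis H-test across phenotype groups. Missing cells are dropped
#' per covariate; covariates left with a single observed level (or constant
#' values) are skipped with a warning. No multiple-testing correction is
#' applied by default (associations are reported at the plain `alpha`
#' level); set `adjust = "BH"` for Benjamini-Hochberg.
#'
#' @param assignments An `endo_assignments`.
#' @param survey Tibble with `participant_id` and covariate columns.
#'   Character/factor/logical columns are treated as categorical, numeric
#'   columns as continuous.
#' @param alpha Significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble with one row per tested covariate.
#' @export
association_screen <- function(assignments, survey, alpha = 0.05,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(assignments, "endo_assignments"))
  survey <- tibble::as_tibble(survey)
  if (!"participant_id" %in% names(survey)) {
    stop("survey needs a participant_id column", call. = FALSE)
  }
  dat <- dplyr::inner_join(
    assignments[c("participant_id", "phenotype")], survey,
    by = "participant_id"
  )
  if (nrow(dat) == 0L) {
    stop("no shared participant ids between assignments and survey",
         call. = FALSE)
  }
  covs <- setdiff(names(survey), "participant_id")
  rows <- purrr::map(covs, function(cv) {
    x <- dat[[cv]]
    ok <- !is.na(x)
    x <- x[ok]; ph <- dat$phenotype[ok]
    if (is.numeric(x)) {
      if (length(unique(x)) < 2L || length(unique(ph)) < 2L) {
        warning("covariate '", cv, "' is degenerate; skipped", call. = FALSE)
        return(NULL)
      }
      kruskal_wallis(split(x, ph), alpha = alpha, name = cv)
    } else if (is.character(x) || is.factor(x) || is.logical(x)) {
      tab <- table(ph, as.character(x))
      tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      if (ncol(tab) < 2L || nrow(tab) < 2L) {
        warning("covariate '", cv, "' has a single observed level; skipped",
                call. = FALSE)
        return(NULL)
      }
      chi_square_independence(tab, alpha = alpha, name = cv)
    } else {
      stop("covariate '", cv, "' has unsupported type ", class(x)[1],
           call. = FALSE)
    }
  })
  out <- dplyr::bind_rows(rows)
  if (adjust == "BH" && nrow(out)) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adjusted < alpha
  }
  out
}
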