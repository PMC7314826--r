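#' Construct a self-tracking corpus
#'
#' A corpus bundles a [question_schema()] with per-participant answer
#' multisets. Answers are bags, not sequences: the mixed-membership model is
#' exchangeable over tokens, so only (token, count) pairs are kept.
#'
#' @param schema An `endo_schema`.
#' @param answers Tibble with columns `participant_id`, `question_id`,
#'   `token`, `count` (positive integers). Every token must belong to its
#'   question's vocabulary.
#' @param participants Optional tibble with columns `participant_id` and
#'   `days_tracked`; participants present in `answers` but absent here get
#'   `days_tracked = 0`. Participants with zero answers may be declared here
#'   so they are retained (modelling operations exclude them).
#'
#' @return An object of class `endo_corpus`: a list with tibbles `schema`,
#'   `participants` (with derived `n_observations`) and `answers`.
#' @export
endo_corpus <- function(schema, answers, participants = NULL) {
  stopifnot(inherits(schema, "endo_schema"))
  answers <- tibble::as_tibble(answers)
  needed <- c("participant_id", "question_id", "token", "count")
  if (!all(needed %in% names(answers))) {
    stop("`answers` needs columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  answers$count <- as.integer(answers$count)
  if (any(answers$count < 1L)) {
    stop("answer counts must be >= 1", call. = FALSE)
  }
  bad_q <- setdiff(unique(answers$question_id), schema$question_id)
  if (length(bad_q)) {
    stop("unknown question_id(s): ", paste(bad_q, collapse = ", "),
         call. = FALSE)
  }
  idx <- schema_token_index(schema)
  for (q in unique(answers$question_id)) {
    toks <- answers$token[answers$question_id == q]
    bad <- setdiff(unique(toks), names(idx[[q]]))
    if (length(bad)) {
      who <- answers$participant_id[answers$question_id == q &
                                      answers$token == bad[1]][1]
      stop("token '", bad[1], "' of participant '", who,
           "' is not in the vocabulary of question '", q, "'", call. = FALSE)
    }
  }

  obs <- dplyr::summarise(
    dplyr::group_by(answers, .data$participant_id),
    n_observations = sum(.data$count), .groups = "drop"
  )
  if (is.null(participants)) {
    participants <- tibble::tibble(
      participant_id = obs$participant_id, days_tracked = 0L
    )
  }
  participants <- tibble::as_tibble(participants)
  if (anyDuplicated(participants$participant_id)) {
    stop("participant_ids must be unique", call. = FALSE)
  }
  extra <- setdiff(obs$participant_id, participants$participant_id)
  if (length(extra)) {
    participants <- dplyr::bind_rows(
      participants,
      tibble::tibble(participant_id = extra, days_tracked = 0L)
    )
  }
  participants$days_tracked <- as.integer(participants$days_tracked)
  if (any(participants$days_tracked < 0L)) {
    stop("days_tracked must be nonnegative", call. = FALSE)
  }
  participants <- dplyr::left_join(participants, obs, by = "participant_id")
  participants$n_observations <-
    as.integer(dplyr::coalesce(participants$n_observations, 0L))
  if (nrow(participants) < 1L) {
    stop("a corpus needs at least one participant", call. = FALSE)
  }

  structure(
    list(schema = schema, participants = participants, answers = answers),
    class = "endo_corpus"
  )
}

#' @export
print.endo_corpus <- function(x, ...) {
  cat("<endo_corpus> ", nrow(x$participants), " participants, ",
      nrow(x$schema), " questions, ",
      sum(x$participants$n_observations), " observations\n", sep = "")
  invisible(x)
}

#' Read a corpus from its JSON interchange format
#'
#' The format is a UTF-8 JSON object with a `schema` array
#' (`question_id`, `prompt`, `vocabulary`) and a `participants` array
#' (`participant_id`, `days_tracked`, `answers` mapping question_id to a
#' token -> count object).
#'
#' @param path File path.
#' @return An `endo_corpus`.
#' @seealso [write_corpus()]
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop("failed to parse '", path, "' as corpus JSON: ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (!is.list(raw) || is.null(raw$schema) || is.null(raw$participants)) {
    stop("corpus file '", path, "' lacks top-level schema/participants",
         call. = FALSE)
  }
  schema <- question_schema(
    question_id = purrr::map_chr(raw$schema, "question_id"),
    prompt = purrr::map_chr(raw$schema, function(s) s$prompt %||% s$question_id),
    vocabulary = purrr::map(raw$schema, function(s) {
      as.character(unlist(s$vocabulary))
    })
  )
  parts <- purrr::map(raw$participants, function(p) {
    if (is.null(p$participant_id)) {
      stop("participant record without participant_id in '", path, "'",
           call. = FALSE)
    }
    p
  })
  participants <- tibble::tibble(
    participant_id = purrr::map_chr(parts, "participant_id"),
    days_tracked = purrr::map_int(parts, function(p) {
      as.integer(p$days_tracked %||% 0L)
    })
  )
  answers <- purrr::map_dfr(parts, function(p) {
    if (is.null(p$answers) || !length(p$answers)) return(NULL)
    purrr::imap_dfr(p$answers, function(tok_counts, q) {
      tibble::tibble(
        participant_id = p$participant_id,
        question_id = q,
        token = names(tok_counts),
        count = as.integer(unlist(tok_counts))
      )
    })
  })
  if (nrow(answers) == 0L) {
    answers <- tibble::tibble(
      participant_id = character(), question_id = character(),
      token = character(), count = integer()
    )
  }
  endo_corpus(schema, answers, participants)
}

#' Write a corpus to the JSON interchange format
#'
#' @param corpus An `endo_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "endo_corpus"))
  schema <- purrr::pmap(corpus$schema, function(question_id, prompt, vocabulary) {
    list(question_id = question_id, prompt = prompt, vocabulary = vocabulary)
  })
  ans_split <- split(corpus$answers, corpus$answers$participant_id)
  participants <- purrr::pmap(corpus$participants,
    function(participant_id, days_tracked, n_observations) {
      rows <- ans_split[[participant_id]]
      answers <- stats::setNames(list(), character())
      if (!is.null(rows)) {
        answers <- purrr::map(
          split(rows, factor(rows$question_id, unique(rows$question_id))),
          function(r) as.list(stats::setNames(r$count, r$token))
        )
      }
      list(participant_id = participant_id,
           days_tracked = days_tracked,
           answers = answers)
    })
  jsonlite::write_json(
    list(schema = schema, participants = participants),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Per-question tracking summary
#'
#' One row per question plus a `"Total"` row, reporting mean and max
#' observation counts and tracking-day counts over all participants
#' (zero-count participants included in the means). The corpus stores a
#' single `days_tracked` per participant, so the per-question day statistic
#' attributes that value to every question the participant answered at least
#' once (0 otherwise); the `"Total"` row sums the per-question rows.
#'
#' @param corpus An `endo_corpus`.
#' @return A tibble with columns `question_id`, `n_obs_mean`, `n_obs_max`,
#'   `n_days_mean`, `n_days_max`.
#' @export
corpus_summary <- function(corpus) {
  stopifnot(inherits(corpus, "endo_corpus"))
  parts <- corpus$participants
  grid <- tidyr::expand_grid(
    question_id = corpus$schema$question_id,
    participant_id = parts$participant_id
  )
  per <- dplyr::summarise(
    dplyr::group_by(corpus$answers, .data$question_id, .data$participant_id),
    n_obs = sum(.data$count), .groups = "drop"
  )
  full <- dplyr::left_join(grid, per, by = c("question_id", "participant_id"))
  full$n_obs <- dplyr::coalesce(full$n_obs, 0L)
  full <- dplyr::left_join(
    full, parts[c("participant_id", "days_tracked")], by = "participant_id"
  )
  full$n_days <- ifelse(full$n_obs > 0L, full$days_tracked, 0L)
  by_q <- dplyr::summarise(
    dplyr::group_by(full, .data$question_id),
    n_obs_mean = mean(.data$n_obs), n_obs_max = max(.data$n_obs),
    n_days_mean = mean(.data$n_days), n_days_max = max(.data$n_days),
    .groups = "drop"
  )
  by_q <- by_q[match(corpus$schema$question_id, by_q$question_id), ]
  total <- tibble::tibble(
    question_id = "Total",
    n_obs_mean = sum(by_q$n_obs_mean), n_obs_max = sum(by_q$n_obs_max),
    n_days_mean = sum(by_q$n_days_mean), n_days_max = sum(by_q$n_days_max)
  )
  dplyr::bind_rows(by_q, total)
}

#' Collapse a corpus to the single-question baseline view
#'
#' Concatenates all per-question vocabularies into one vocabulary of size
#' `sum(V_q)` (202 for the default schema). Tokens are namespaced
#' `"<question_id>.<token>"` because different questions may share answer
#' strings. This is the input representation of the vanilla LDA baseline.
#'
#' @param corpus An `endo_corpus`.
#' @return An `endo_corpus` with a single question `"all"`; every
#'   participant's total observation count is unchanged.
#' @export
concatenate_view <- function(corpus) {
  stopifnot(inherits(corpus, "endo_corpus"))
  vocab <- unlist(purrr::map2(
    corpus$schema$question_id, corpus$schema$vocabulary,
    function(q, v) paste(q, v, sep = ".")
  ))
  schema <- question_schema("all", "All questions, concatenated", list(vocab))
  answers <- corpus$answers
  if (nrow(answers)) {
    answers <- tibble::tibble(
      participant_id = answers$participant_id,
      question_id = "all",
      token = paste(answers$question_id, answers$token, sep = "."),
      count = answers$count
    )
  } else {
    answers <- tibble::tibble(
      participant_id = character(), question_id = character(),
      token = character(), count = integer()
    )
  }
  endo_corpus(schema, answers,
              corpus$participants[c("participant_id", "days_tracked")])
}

# Flatten a corpus into parallel integer token vectors for the sampler.
# Participants with zero observations are dropped here (they carry no
# likelihood); callers needing ids use $participant_ids (modelled subset).
corpus_tokens <- function(corpus) {
  schema <- corpus$schema
  idx <- schema_token_index(schema)
  qid <- stats::setNames(seq_len(nrow(schema)), schema$question_id)
  parts <- corpus$participants
  modelled <- parts$participant_id[parts$n_observations > 0L]
  if (!length(modelled)) stop("corpus has no tokens", call. = FALSE)
  ans <- corpus$answers
  ans <- ans[ans$participant_id %in% modelled, ]
  # canonical token order: participant order, schema question order, vocab order
  ans$d <- match(ans$participant_id, modelled)
  ans$q <- qid[ans$question_id]
  ans$v <- purrr::map2_int(ans$question_id, ans$token,
                           function(q, t) idx[[q]][[t]])
  ans <- ans[order(ans$d, ans$q, ans$v), ]
  rep_i <- rep(seq_len(nrow(ans)), ans$count)
  list(
    d = ans$d[rep_i], q = ans$q[rep_i], v = ans$v[rep_i],
    D = length(modelled), Q = nrow(schema), Vq = schema_sizes(schema),
    participant_ids = modelled,
    n_dropped = sum(parts$n_observations == 0L)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
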