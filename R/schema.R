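#' Build a question schema
#'
#' A schema declares the closed vocabulary of every tracked question. The
#' vocabulary order declared here is the canonical order used everywhere
#' downstream (posterior matrices, serialised files), which keeps outputs
#' bit-reproducible.
#'
#' @param question_id Character vector of unique question keys.
#' @param prompt Character vector of free-text prompts (recycled if length 1).
#' @param vocabulary List of character vectors, one per question; each must
#'   contain at least two distinct answer strings.
#'
#' @return A tibble of class `endo_schema` with columns `question_id`,
#'   `prompt` and a list-column `vocabulary`.
#' @export
#' @examples
#' question_schema("pain", "Where is the pain?", list(c("pelvis", "back")))
question_schema <- function(question_id, prompt = question_id, vocabulary) {
  stopifnot(is.character(question_id), is.list(vocabulary))
  if (length(prompt) == 1L) prompt <- rep(prompt, length(question_id))
  if (length(question_id) < 1L) {
    stop("a schema needs at least one question", call. = FALSE)
  }
  if (anyDuplicated(question_id)) {
    stop("question_ids must be unique within a schema", call. = FALSE)
  }
  if (length(vocabulary) != length(question_id)) {
    stop("`vocabulary` must have one entry per question", call. = FALSE)
  }
  for (i in seq_along(vocabulary)) {
    v <- vocabulary[[i]]
    if (!is.character(v) || length(v) < 2L) {
      stop("vocabulary of question '", question_id[i],
           "' must hold at least 2 answer strings", call. = FALSE)
    }
    if (anyDuplicated(v)) {
      stop("vocabulary of question '", question_id[i],
           "' contains duplicate entries", call. = FALSE)
    }
  }
  out <- tibble::tibble(
    question_id = question_id,
    prompt = prompt,
    vocabulary = vocabulary
  )
  class(out) <- c("endo_schema", class(out))
  out
}

#' Default self-tracking schema
#'
#' The 13 tracked questions of the Phendo endometriosis self-tracking app,
#' with the published per-question vocabulary sizes
#' (39, 15, 3, 14, 3, 21, 3, 3, 3, 6, 23, 64, 5). The full answer strings are
#' not public, so vocabularies hold placeholder tokens (`"pain_location_01"`,
#' ...) of the correct sizes.
#'
#' @return An `endo_schema` tibble with 13 rows and 202 total vocabulary
#'   entries.
#' @export
#' @examples
#' sum(lengths(default_phendo_schema()$vocabulary))  # 202
default_phendo_schema <- function() {
  ids <- c(
    "pain_location", "pain_description", "pain_severity", "symptoms",
    "symptom_severity", "period_flow", "bleeding_kind", "gigu",
    "gigu_severity", "sex", "hard_activities", "medications", "day_quality"
  )
  prompts <- c(
    "Where is the pain?", "Describe the pain.", "How severe is the pain?",
    "What are you experiencing?", "How severe is the symptom?",
    "Describe your period flow.", "What kind of bleeding.",
    "Describe GI/GU system.", "How severe is it?", "Describe sex.",
    "Activities difficult to perform.", "Medications/hormones taken.",
    "How was your day?"
  )
  sizes <- c(39L, 15L, 3L, 14L, 3L, 21L, 3L, 3L, 3L, 6L, 23L, 64L, 5L)
  vocab <- purrr::map2(ids, sizes, function(id, n) {
    sprintf("%s_%02d", id, seq_len(n))
  })
  question_schema(ids, prompts, vocab)
}

# integer lookup helpers -------------------------------------------------

schema_sizes <- function(schema) lengths(schema$vocabulary)

schema_token_index <- function(schema) {
  stats::setNames(
    purrr::map(schema$vocabulary, function(v) {
      stats::setNames(seq_along(v), v)
    }),
    schema$question_id
  )
}
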