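#' Phrase inventory for the three-slot sentence corpus
#'
#' The corpus is built from three sentence slots, each offering two Japanese
#' phrases (romaji encoding).  The six phrases carry token IDs 0--5; token 6 is
#' the start-of-sentence marker and token 7 the end-of-sentence marker, so the
#' decoder vocabulary has exactly eight tokens.
#'
#' @return An object of class `phrase_inventory`: a list with `slots` (a list of
#'   three slots, each a data.frame with columns `romaji`, `gloss`, `token_id`),
#'   `start_token` (6) and `end_token` (7).
#' @examples
#' inv <- phrase_inventory()
#' inv$slots[[1]]
#' @export
phrase_inventory <- function() {
  slots <- list(
    data.frame(romaji = c("watashiwa", "kimito"),
               gloss = c("I", "with you"),
               token_id = c(0L, 1L), stringsAsFactors = FALSE),
    data.frame(romaji = c("gakko:e", "shokubani"),
               gloss = c("to school", "to the office"),
               token_id = c(2L, 3L), stringsAsFactors = FALSE),
    data.frame(romaji = c("itta", "mukau"),
               gloss = c("went", "head"),
               token_id = c(4L, 5L), stringsAsFactors = FALSE)
  )
  structure(list(slots = slots, start_token = 6L, end_token = 7L),
            class = "phrase_inventory")
}

validate_inventory <- function(inventory) {
  if (!inherits(inventory, "phrase_inventory"))
    stop("`inventory` must be a phrase_inventory object", call. = FALSE)
  if (length(inventory$slots) != 3L)
    stop("inventory must have exactly 3 slots, got ", length(inventory$slots),
         call. = FALSE)
  for (s in seq_along(inventory$slots)) {
    slot <- inventory$slots[[s]]
    if (nrow(slot) != 2L)
      stop("slot ", s, " must have exactly 2 phrase options", call. = FALSE)
  }
  ids <- sort(unlist(lapply(inventory$slots, `[[`, "token_id")))
  if (!identical(as.integer(ids), 0:5))
    stop("phrase token_ids must be exactly {0,...,5}", call. = FALSE)
  if (inventory$start_token != 6L || inventory$end_token != 7L)
    stop("start/end tokens must be 6 and 7", call. = FALSE)
  invisible(inventory)
}

#' Enumerate the eight sentences of the corpus
#'
#' Takes the Cartesian product of the two options in each of the three slots
#' (2 x 2 x 2 = 8 sentences), slot-1 major, so sentence 1 is choices (0,0,0)
#' and sentence 8 is (1,1,1).
#'
#' @param inventory A [phrase_inventory()].
#' @return A list of 8 `sentence_spec` objects, each with fields `choices`
#'   (integer vector of 3 zero-based option choices), `romaji` (the space-joined
#'   sentence) and `tokens` (length-5 integer vector `c(6, t1, t2, t3, 7)`).
#' @examples
#' sents <- build_sentences()
#' sents[[1]]$romaji   # "watashiwa gakko:e itta"
#' sents[[1]]$tokens   # 6 0 2 4 7
#' @export
build_sentences <- function(inventory = phrase_inventory()) {
  validate_inventory(inventory)
  grid <- expand.grid(c3 = 0:1, c2 = 0:1, c1 = 0:1)[, 3:1]  # slot-1 major
  lapply(seq_len(nrow(grid)), function(i) {
    choices <- as.integer(grid[i, ])
    phrases <- vapply(1:3, function(s)
      inventory$slots[[s]]$romaji[choices[s] + 1L], character(1))
    ids <- vapply(1:3, function(s)
      inventory$slots[[s]]$token_id[choices[s] + 1L], integer(1))
    structure(list(choices = choices,
                   romaji = paste(phrases, collapse = " "),
                   tokens = c(inventory$start_token, ids, inventory$end_token)),
              class = "sentence_spec")
  })
}

#' Tokenize a romaji sentence
#'
#' Maps a three-phrase romaji sentence to its token ID sequence
#' `c(6, t1, t2, t3, 7)` using the printed phrase-to-ID mapping
#' (watashiwa 0, kimito 1, gakko:e 2, shokubani 3, itta 4, mukau 5).
#'
#' @param sentence A single string of three space-separated phrases, or a
#'   character vector of the three phrases.
#' @param inventory A [phrase_inventory()].
#' @return Integer vector of length 5: start token, the three phrase tokens,
#'   end token.
#' @examples
#' tokenize("kimito shokubani mukau")  # 6 1 3 5 7
#' @export
tokenize <- function(sentence, inventory = phrase_inventory()) {
  validate_inventory(inventory)
  phrases <- if (length(sentence) == 1L)
    strsplit(trimws(sentence), "\\s+")[[1]] else as.character(sentence)
  if (length(phrases) == 0L || all(!nzchar(phrases)))
    stop("empty sentence cannot be tokenized", call. = FALSE)
  if (length(phrases) != 3L)
    stop("a sentence must consist of exactly 3 phrases, got ",
         length(phrases), call. = FALSE)
  ids <- vapply(seq_len(3L), function(s) {
    slot <- inventory$slots[[s]]
    hit <- match(phrases[s], slot$romaji)
    if (is.na(hit))
      stop("phrase '", phrases[s], "' is not an option for slot ", s,
           call. = FALSE)
    slot$token_id[hit]
  }, integer(1))
  c(inventory$start_token, ids, inventory$end_token)
}

#' Render a token sequence back to romaji
#'
#' Inverse of [tokenize()]: drops the start/end markers and maps the three
#' phrase tokens back to their romaji strings.
#'
#' @param tokens Integer token sequence (with or without the 6/7 markers).
#' @param inventory A [phrase_inventory()].
#' @return A single romaji string.
#' @export
detokenize <- function(tokens, inventory = phrase_inventory()) {
  validate_inventory(inventory)
  body <- tokens[!(tokens %in% c(inventory$start_token, inventory$end_token))]
  lut <- do.call(rbind, inventory$slots)
  idx <- match(body, lut$token_id)
  if (anyNA(idx))
    stop("unknown token id(s): ", paste(body[is.na(idx)], collapse = ", "),
         call. = FALSE)
  paste(lut$romaji[idx], collapse = " ")
}

#' Balanced randomized trial schedule
#'
#' Builds a schedule in which each of the 8 sentences occurs exactly
#' `n_trials / 8` times, in an order permuted by a seeded RNG.  With the
#' default 80 trials every sentence appears ten times, matching the recording
#' protocol of one participant session.
#'
#' @param n_trials Number of trials; must be divisible by 8.
#' @param seed Integer RNG seed; the schedule is reproducible given the seed.
#' @return An object of class `trial_schedule`: a list with `sentence`
#'   (integer vector of 1-based sentence indices, length `n_trials`),
#'   `n_trials` and `seed`.
#' @examples
#' sch <- make_schedule(80, seed = 1)
#' table(sch$sentence)  # each of 8 sentences: 10
#' @export
make_schedule <- function(n_trials = 80L, seed = 1L) {
  n_trials <- as.integer(n_trials)
  if (n_trials <= 0L || n_trials %% 8L != 0L)
    stop("n_trials must be a positive multiple of 8, got ", n_trials,
         call. = FALSE)
  balanced <- rep(seq_len(8L), each = n_trials %/% 8L)
  order <- local_rng(seed, sample.int(n_trials))
  structure(list(sentence = balanced[order], n_trials = n_trials,
                 seed = as.integer(seed)),
            class = "trial_schedule")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never disturbs user-level randomness.
local_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write / read the corpus and schedules as plain-text interchange files
#'
#' The corpus is serialized as JSON (`slots`, `start_token`, `end_token`) and a
#' schedule as CSV with columns `trial_index`, `sentence_index` and the seed in
#' a `# seed:` header comment.
#'
#' @param inventory A [phrase_inventory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus_json <- function(inventory, path) {
  validate_inventory(inventory)
  obj <- list(
    slots = lapply(inventory$slots, function(s) list(options = s)),
    start_token = inventory$start_token,
    end_token = inventory$end_token
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_corpus_json
#' @param schedule A [make_schedule()] object.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "trial_schedule"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %d", schedule$seed), con)
  utils::write.csv(data.frame(trial_index = seq_len(schedule$n_trials),
                              sentence_index = schedule$sentence),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_corpus_json
#' @export
read_schedule_csv <- function(path) {
  lines <- readLines(path)
  seed <- as.integer(sub("# seed: ", "", lines[1]))
  df <- utils::read.csv(text = lines[-1])
  structure(list(sentence = as.integer(df$sentence_index),
                 n_trials = nrow(df), seed = seed),
            class = "trial_schedule")
}
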