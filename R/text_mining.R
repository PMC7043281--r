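# Keyword/synonym search over free-text clinical documents with
# negation and family-history filtering. The same machinery is reused for
# steatosis evidence, cirrhosis, death mentions and MELD extraction.

#' Build a synonym lexicon
#'
#' A lexicon is the list of case-insensitive surface forms for one clinical
#' concept (e.g. "steatosis", "fatty liver", "NASH" for hepatic steatosis).
#'
#' @param concept concept name.
#' @param terms character vector of surface forms; duplicates after
#'   case-folding are dropped.
#' @return An object of class `synonym_lexicon`: a data.frame with columns
#'   `concept` and `term`.
#' @examples
#' lexicon("steatosis", c("steatosis", "fatty liver"))
#' @export
lexicon <- function(concept, terms) {
  terms <- as.character(terms)
  terms <- terms[nzchar(terms)]
  terms <- terms[!duplicated(tolower(terms))]
  if (length(terms) == 0L) stop_config("lexicon needs at least one term")
  structure(data.frame(concept = concept, term = terms,
                       stringsAsFactors = FALSE),
            class = c("synonym_lexicon", "data.frame"))
}

#' Default lexicons shipped with the package
#'
#' @param concept one of `"steatosis"`, `"death"`, `"cirrhosis"`.
#' @return a `synonym_lexicon`.
#' @export
default_lexicon <- function(concept = c("steatosis", "death", "cirrhosis")) {
  concept <- match.arg(concept)
  all <- read_csv_strict(pkg_extdata("default_lexicons.csv"))
  lexicon(concept, all$term[all$concept == concept])
}

# Cue inventories. Negation cues act within a token window before the term;
# kinship cues act anywhere in the same sentence.
negation_cues <- function() {
  c("no", "not", "absence of", "without", "negative for", "denies",
    "denied", "free of", "ruled out", "rule out")
}

family_cues <- function() {
  c("mother", "father", "brother", "sister", "aunt", "uncle",
    "grandmother", "grandfather", "family history", "family")
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# sentence spans: [start, end] character offsets, boundaries at . and newline
sentence_spans <- function(text) {
  if (!nzchar(text)) return(data.frame(start = integer(), end = integer()))
  breaks <- gregexpr("[.\n]", text)[[1L]]
  ends <- if (breaks[1L] == -1L) integer() else as.integer(breaks)
  starts <- c(1L, ends + 1L)
  ends <- c(ends, nchar(text))
  keep <- starts <= ends
  data.frame(start = starts[keep], end = ends[keep])
}

tokenize <- function(x) {
  toks <- strsplit(gsub("[^[:alnum:]']+", " ", tolower(x)), " +")[[1L]]
  toks[nzchar(toks)]
}

# Is there a negation cue within `window` tokens immediately before the
# match, inside the same sentence?
has_negation_before <- function(pre_text, window = 6L) {
  toks <- tokenize(pre_text)
  if (length(toks) == 0L) return(FALSE)
  tail_toks <- toks[max(1L, length(toks) - window + 1L):length(toks)]
  tail_str <- paste(tail_toks, collapse = " ")
  cues <- negation_cues()
  any(vapply(cues, function(cue) {
    grepl(paste0("\\b", escape_regex(cue), "\\b"), tail_str, perl = TRUE)
  }, logical(1L)))
}

has_family_cue <- function(sentence_text) {
  s <- tolower(sentence_text)
  any(vapply(family_cues(), function(cue) {
    grepl(paste0("\\b", escape_regex(cue), "\\b"), s, perl = TRUE)
  }, logical(1L)))
}

#' Find concept mentions in a text
#'
#' Scans a document for every case-insensitive, word-bounded occurrence of
#' any lexicon term and classifies each occurrence as `positive`, `negated`
#' (a negation cue such as "no", "absence of", "denies" within a 6-token
#' window before the term, in the same sentence), or
#' `family_or_false_positive` (a kinship cue in the same sentence).
#' Negation takes precedence over the family cue.
#'
#' @param text a single document string (may be empty).
#' @param lex a `synonym_lexicon`.
#' @param negation_window token window for negation scope (default 6).
#' @return data.frame with columns `concept`, `term`, `start`, `end`
#'   (1-based character span) and `polarity`.
#' @export
find_mentions <- function(text, lex, negation_window = 6L) {
  if (!inherits(lex, "synonym_lexicon") || nrow(lex) == 0L)
    stop_config("find_mentions requires a non-empty synonym_lexicon")
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(concept = character(), term = character(),
                      start = integer(), end = integer(),
                      polarity = character(), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  sents <- sentence_spans(text)
  res <- list()
  for (i in seq_len(nrow(lex))) {
    term <- lex$term[i]
    pat <- paste0("\\b", escape_regex(term), "\\b")
    m <- gregexpr(pat, text, ignore.case = TRUE, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    for (j in seq_along(starts)) {
      s <- starts[j]; e <- s + lens[j] - 1L
      sent_i <- which(sents$start <= s & sents$end >= s)[1L]
      sent_start <- sents$start[sent_i]
      sent_end <- sents$end[sent_i]
      pre <- substr(text, sent_start, s - 1L)
      pol <- if (has_negation_before(pre, negation_window)) {
        "negated"
      } else if (has_family_cue(substr(text, sent_start, sent_end))) {
        "family_or_false_positive"
      } else "positive"
      res[[length(res) + 1L]] <- data.frame(
        concept = lex$concept[i], term = term, start = s, end = e,
        polarity = pol, stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  out[order(out$start, out$end, out$term), , drop = FALSE]
}

#' Does a patient's document set support a concept?
#'
#' @param documents data.frame with at least `date` and `text` columns
#'   (one row per document for a single patient).
#' @param lex a `synonym_lexicon`.
#' @return list with `present` (logical: at least one positive mention) and
#'   `date` (earliest positive-mention document date, or `NA`).
#' @export
patient_has_concept <- function(documents, lex) {
  if (is.null(documents) || nrow(documents) == 0L)
    return(list(present = FALSE, date = as.Date(NA)))
  dates <- as_date_strict(documents$date, "document date")
  pos_dates <- as.Date(character())
  for (i in seq_len(nrow(documents))) {
    men <- find_mentions(documents$text[i], lex)
    if (any(men$polarity == "positive"))
      pos_dates <- c(pos_dates, dates[i])
  }
  if (length(pos_dates) == 0L) return(list(present = FALSE, date = as.Date(NA)))
  list(present = TRUE, date = min(pos_dates))
}

#' Extract a MELD score from free text
#'
#' Returns the first integer in 6--40 following the token "MELD"
#' (case-insensitive, optional short filler such as "score:"); integers
#' outside the plausible MELD range are ignored.
#'
#' @param text document string.
#' @return integer score or `NA_integer_`.
#' @examples
#' extract_meld("MELD score: 23")  # 23
#' @export
extract_meld <- function(text) {
  if (is.na(text) || !nzchar(text)) return(NA_integer_)
  m <- gregexpr("(?i)\\bmeld\\b[^0-9.\\n]{0,20}?([0-9]{1,3})", text,
                perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(NA_integer_)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  for (j in seq_along(starts)) {
    frag <- substr(text, starts[j], starts[j] + lens[j] - 1L)
    val <- as.integer(sub(".*?([0-9]{1,3})$", "\\1", frag))
    if (!is.na(val) && val >= 6L && val <= 40L) return(val)
  }
  NA_integer_
}

#' Detect mentions of patient death in clinical documents
#'
#' Same scan as [patient_has_concept()] with the death lexicon
#' (deceased, expired, passed away, death); negated or family-scoped
#' mentions do not count.
#'
#' @inheritParams patient_has_concept
#' @param lex death lexicon; defaults to the shipped one.
#' @export
detect_death_mention <- function(documents, lex = default_lexicon("death")) {
  patient_has_concept(documents, lex)
}
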