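#' Rule set for coding placebo disclosure in PIL text
#'
#' A disclosure rule set has three ordered tiers of keyword tokens:
#' \describe{
#'   \item{fd}{words that name the placebo control outright ("sham",
#'     "placebo", "fake", "dummy") -- full disclosure.}
#'   \item{dd}{neutral or deceitful group labels ("control", "different",
#'     "group one", ...) that avoid naming the placebo -- deceptive
#'     disclosure.}
#'   \item{fd_escalation}{phrases describing a sham procedure
#'     ("non-acupoint", "non-penetrating", ...). A DD-labelled text that also
#'     carries one of these is escalated to FD: the participant was given
#'     enough to perceive the existence of a placebo.}
#' }
#' Tokens are matched whole-word and case-insensitively on text normalized by
#' lower-casing, replacing punctuation with spaces and collapsing whitespace;
#' multi-word tokens are therefore written with single spaces.
#'
#' @param path path to a JSON file with fields `fd`, `dd`, `fd_escalation`
#'   (each an array of strings). The default is the lexicon shipped with the
#'   package, seeded from the published category descriptions.
#' @return an object of class `disclosure_rules`: a named list of character
#'   vectors `fd`, `dd`, `fd_escalation`.
#' @examples
#' rules <- disclosure_rules()
#' rules$fd
#' @export
disclosure_rules <- function(path = system.file("extdata", "disclosure_rules.json",
                                                package = "pilblind")) {
  .check(file.exists(path), "rules file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_disclosure_rules(raw)
}

#' @rdname disclosure_rules
#' @param x a named list of character vectors to validate as a rule set.
#' @export
as_disclosure_rules <- function(x) {
  tiers <- c("fd", "dd", "fd_escalation")
  extra <- setdiff(names(x), tiers)
  .check(length(extra) == 0L,
         "unknown rule tier name(s): %s", paste(extra, collapse = ", "))
  .check(all(tiers %in% names(x)), "rule set must contain tiers: %s",
         paste(tiers, collapse = ", "))
  out <- lapply(x[tiers], function(v) .normalize_text(as.character(v)))
  structure(out, class = "disclosure_rules")
}

# lower-case, strip punctuation to spaces, collapse runs of whitespace
.normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[^[:alnum:]]+", " ", x)
  trimws(gsub("[[:space:]]+", " ", x))
}

# which tokens occur as whole words/phrases in normalized text?
.match_tokens <- function(norm, tokens) {
  if (!nzchar(norm) || length(tokens) == 0L) return(character(0))
  padded <- paste0(" ", norm, " ")
  hits <- vapply(tokens, function(tok) {
    grepl(paste0(" ", tok, " "), padded, fixed = TRUE)
  }, logical(1))
  tokens[hits]
}

#' Code one PIL snippet into a disclosure category
#'
#' Classifies free text describing a trial's control condition into one of
#' three categories: `FD` (full disclosure: a placebo/sham word is used, or a
#' neutral label is accompanied by a sham-procedure description), `DD`
#' (deceptive disclosure: only a neutral/deceitful group label), or `MI`
#' (missing information: empty text or no recognizable description of a
#' control group).
#'
#' @param text character scalar; the control-condition description (may be
#'   `""`).
#' @param rules a [disclosure_rules()] object.
#' @param pil_id,placebo_group_id optional identifiers carried through to the
#'   record.
#' @return a list of class `disclosure_record` with elements
#'   `placebo_group_id`, `pil_id`, `category` (`"FD"|"DD"|"MI"`),
#'   `matched_keywords` (character vector, empty for MI) and `escalated`
#'   (`TRUE` only when a DD label was promoted to FD by a sham-procedure
#'   phrase with no direct FD token present).
#' @examples
#' r <- disclosure_rules()
#' classify_disclosure("you will receive real or sham (placebo) acupuncture", r)$category
#' classify_disclosure("you will be assigned to group one or group two", r)$category
#' @export
classify_disclosure <- function(text, rules = disclosure_rules(),
                                pil_id = NA_character_,
                                placebo_group_id = NA_character_) {
  .check(inherits(rules, "disclosure_rules"),
         "rules must be a disclosure_rules object (see as_disclosure_rules)")
  .check(is.character(text) && length(text) == 1L && !is.na(text),
         "text must be a single character string")
  norm <- .normalize_text(text)
  fd_hits  <- .match_tokens(norm, rules$fd)
  dd_hits  <- .match_tokens(norm, rules$dd)
  esc_hits <- .match_tokens(norm, rules$fd_escalation)

  if (length(fd_hits) > 0L) {
    category <- "FD"; escalated <- FALSE
    matched <- unique(c(fd_hits, dd_hits, esc_hits))
  } else if (length(dd_hits) > 0L && length(esc_hits) > 0L) {
    category <- "FD"; escalated <- TRUE
    matched <- unique(c(dd_hits, esc_hits))
  } else if (length(dd_hits) > 0L) {
    category <- "DD"; escalated <- FALSE
    matched <- dd_hits
  } else {
    category <- "MI"; escalated <- FALSE
    matched <- character(0)
  }
  structure(list(placebo_group_id = placebo_group_id, pil_id = pil_id,
                 category = category, matched_keywords = matched,
                 escalated = escalated),
            class = "disclosure_record")
}

#' Code a whole corpus of PIL snippets
#'
#' @param pils data frame with columns `pil_id`, `placebo_group_id`, `text`
#'   (and optionally `region`); one row per placebo group.
#' @param rules a [disclosure_rules()] object.
#' @return data frame with one row per placebo group: `pil_id`,
#'   `placebo_group_id`, `category`, `matched_keywords` (semicolon-joined),
#'   `escalated`, plus `region` if present in the input.
#' @export
code_corpus <- function(pils, rules = disclosure_rules()) {
  .check(is.data.frame(pils) && nrow(pils) > 0L, "pils must be a non-empty data frame")
  .check(all(c("pil_id", "placebo_group_id", "text") %in% names(pils)),
         "pils needs columns pil_id, placebo_group_id, text")
  .check(all(nzchar(pils$pil_id)) && all(nzchar(pils$placebo_group_id)),
         "pil_id and placebo_group_id must be non-empty")
  key <- paste(pils$pil_id, pils$placebo_group_id, sep = "\r")
  .check(!anyDuplicated(key), "(pil_id, placebo_group_id) pairs must be unique")

  recs <- lapply(seq_len(nrow(pils)), function(i) {
    classify_disclosure(pils$text[i], rules,
                        pil_id = pils$pil_id[i],
                        placebo_group_id = pils$placebo_group_id[i])
  })
  out <- data.frame(
    pil_id = pils$pil_id,
    placebo_group_id = pils$placebo_group_id,
    category = vapply(recs, `[[`, character(1), "category"),
    matched_keywords = vapply(recs, function(r)
      paste(r$matched_keywords, collapse = ";"), character(1)),
    escalated = vapply(recs, `[[`, logical(1), "escalated"),
    stringsAsFactors = FALSE
  )
  if ("region" %in% names(pils)) out$region <- pils$region
  out
}

#' Summarize disclosure-category composition
#'
#' Counts and percentages per category, computed on placebo groups (not
#' PILs). Percentages are rounded half-up to one decimal.
#'
#' @param categories character vector of `"FD"|"DD"|"MI"` codes (e.g. the
#'   `category` column from [code_corpus()]), one element per placebo group.
#' @return data frame with columns `category`, `n`, `pct`, ordered FD, DD,
#'   MI; counts sum to `length(categories)`.
#' @examples
#' summarize_categories(rep(c("FD", "DD", "MI"), c(40, 25, 5)))
#' @export
summarize_categories <- function(categories) {
  .check(length(categories) > 0L, "no disclosure records to summarize")
  .check(all(categories %in% c("FD", "DD", "MI")),
         "categories must be FD, DD or MI")
  lev <- c("FD", "DD", "MI")
  n <- as.integer(table(factor(categories, levels = lev)))
  data.frame(category = lev, n = n,
             pct = round_half_up(100 * n / length(categories), 1),
             stringsAsFactors = FALSE)
}

#' Pearson chi-square test on a 2x2 table
#'
#' The classic test of independence for a 2x2 contingency table, computed
#' from the closed form `N (ad - bc)^2 / (r1 r2 c1 c2)`; optionally with the
#' Yates continuity correction. Used here to compare category composition
#' (e.g. FD vs non-FD) across regions.
#'
#' @param table a 2x2 numeric matrix of non-negative counts with all four
#'   margins positive.
#' @param yates logical; apply the Yates continuity correction (default
#'   `FALSE`).
#' @return list with `statistic`, `df` (always 1) and `p`.
#' @examples
#' chi_square_2x2(matrix(c(30, 10, 10, 20), 2, byrow = TRUE))
#' @export
chi_square_2x2 <- function(table, yates = FALSE) {
  tab <- as.matrix(table)
  .check(all(dim(tab) == c(2L, 2L)), "table must be 2x2")
  .check(all(is.finite(tab)) && all(tab >= 0), "all cells must be non-negative")
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0)) stop(sprintf("degenerate margin: row %d sums to zero",
                                 which(rs == 0)[1]), call. = FALSE)
  if (any(cs == 0)) stop(sprintf("degenerate margin: column %d sums to zero",
                                 which(cs == 0)[1]), call. = FALSE)
  d <- tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1]
  num <- if (yates) max(0, abs(d) - n / 2)^2 else d^2
  stat <- n * num / prod(rs, cs)
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}
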