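#' RNA identifier with cross-reference aliases
#'
#' An RNA is named by one primary identifier (ideally species-specific, e.g.
#' `"hsa-mir-21"`) plus any aliases under which the same molecule appears in
#' the literature. Aliases contribute sentences under the primary id; the
#' extracted record keeps track of which surface form matched.
#'
#' @param primary_id Non-empty string without newlines.
#' @param aliases Character vector of alternative names (duplicates of the
#'   primary id are dropped).
#' @return An object of class `rna_identifier`.
#' @export
rna_identifier <- function(primary_id, aliases = character()) {
  if (!is.character(primary_id) || length(primary_id) != 1 ||
      !nzchar(primary_id)) {
    stop("invalid-identifier: primary_id must be a non-empty string",
         call. = FALSE)
  }
  if (grepl("\n", primary_id, fixed = TRUE)) {
    stop("invalid-identifier: primary_id must not contain newlines",
         call. = FALSE)
  }
  aliases <- unique(as.character(aliases))
  aliases <- aliases[nzchar(aliases) & aliases != primary_id]
  structure(list(primary_id = primary_id, aliases = aliases),
            class = "rna_identifier")
}

as_rna_identifier <- function(id) {
  if (inherits(id, "rna_identifier")) id else rna_identifier(id)
}

#' One article's full text
#'
#' @param pmcid PubMed Central identifier, `PMC` followed by digits.
#' @param body Full text (may be empty).
#' @return An object of class `article_text`.
#' @export
article_text <- function(pmcid, body = "") {
  stopifnot(is.character(pmcid), length(pmcid) == 1)
  if (!grepl("^PMC[0-9]+$", pmcid)) {
    stop("article_text: pmcid must match PMC<digits>, got: ", pmcid,
         call. = FALSE)
  }
  structure(list(pmcid = pmcid, body = as.character(body)),
            class = "article_text")
}

#' Build the literature search query for an RNA identifier
#'
#' Produces the query template used against the open-access literature index:
#' the quoted identifier AND one of six RNA-type terms, restricted to
#' full-text-available, open-access, non-preprint records.
#'
#' @param id An [rna_identifier()] or a plain string.
#' @return The query string.
#' @examples
#' build_query("hsa-mir-21")
#' @export
build_query <- function(id) {
  id <- as_rna_identifier(id)
  if (grepl('"', id$primary_id, fixed = TRUE)) {
    stop("invalid-identifier: identifier contains a double quote and cannot ",
         "be safely quoted", call. = FALSE)
  }
  paste0(
    '("', id$primary_id, '" AND ',
    '("rna" OR "mrna" OR "ncrna" OR "lncrna" OR "rrna" OR "sncrna") AND ',
    'IN_EPMC:Y AND OPEN_ACCESS:Y AND NOT SRC:PPR)'
  )
}

# Regex matching one surface form under the package's mention convention:
# case-insensitive, word boundaries defined as any character that is not
# alphanumeric and not a hyphen (or the string edge), so "hsa-mir-21" does
# not match inside "hsa-mir-210".
mention_regex <- function(surface) {
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", surface)
  paste0("(?<![[:alnum:]-])", esc, "(?![[:alnum:]-])")
}

# First surface form (primary id, then aliases in order) mentioned in text,
# or NA_character_.
matched_surface <- function(text, id) {
  id <- as_rna_identifier(id)
  for (surface in c(id$primary_id, id$aliases)) {
    if (grepl(mention_regex(surface), text, perl = TRUE, ignore.case = TRUE)) {
      return(surface)
    }
  }
  NA_character_
}

#' Does an article mention an RNA identifier?
#'
#' True iff the primary id or any alias occurs in the body under the package's
#' matching convention (case-insensitive, hyphen-aware word boundaries).
#'
#' @param article An [article_text()].
#' @param id An [rna_identifier()] or string.
#' @return Logical scalar.
#' @export
validate_mention <- function(article, id) {
  !is.na(matched_surface(article$body, id))
}

#' Extract identifier-mentioning sentences from an article
#'
#' Segments the article body with [segment_sentences()] and keeps every
#' sentence mentioning the identifier (or an alias), in document order. Each
#' record carries the article's PMCID and the surface form that matched.
#'
#' @inheritParams validate_mention
#' @return A data.frame with columns `rna_id`, `pmcid`, `sentence`,
#'   `matched_alias` (one row per matching sentence; zero rows if none).
#' @export
extract_sentences <- function(article, id) {
  id <- as_rna_identifier(id)
  sentences <- segment_sentences(article$body)
  hits <- vapply(sentences, matched_surface, character(1), id = id,
                 USE.NAMES = FALSE)
  keep <- !is.na(hits)
  data.frame(
    rna_id = rep(id$primary_id, sum(keep)),
    pmcid = rep(article$pmcid, sum(keep)),
    sentence = sentences[keep],
    matched_alias = hits[keep],
    stringsAsFactors = FALSE
  )
}

#' Harvest a sentence corpus from local article files
#'
#' The network retrieval layer sits behind a transport interface; this
#' function is the bundled local transport, serving article bodies from a
#' directory of `<PMCID>.txt` files or a JSONL file of `{pmcid, body}`
#' records.
#'
#' @param source Directory of `<PMCID>.txt` plain-text files, or a path to a
#'   `.jsonl` file.
#' @param id An [rna_identifier()] or string.
#' @return A data.frame of sentence records (see [extract_sentences()]).
#' @export
harvest_corpus <- function(source, id) {
  id <- as_rna_identifier(id)
  articles <- read_articles(source)
  parts <- lapply(articles, extract_sentences, id = id)
  if (length(parts) == 0) {
    return(extract_sentences(article_text("PMC0", ""), id))
  }
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}

#' @rdname harvest_corpus
#' @export
read_articles <- function(source) {
  if (dir.exists(source)) {
    files <- sort(list.files(source, pattern = "^PMC[0-9]+\\.txt$",
                             full.names = TRUE))
    return(lapply(files, function(f) {
      article_text(tools::file_path_sans_ext(basename(f)),
                   paste(readLines(f, warn = FALSE, encoding = "UTF-8"),
                         collapse = "\n"))
    }))
  }
  if (file.exists(source)) {
    recs <- read_jsonl(source)
    pmcids <- vapply(recs, function(r) r$pmcid, character(1))
    if (anyDuplicated(pmcids)) {
      stop("read_articles: duplicate pmcid in one harvest run", call. = FALSE)
    }
    return(lapply(recs, function(r) article_text(r$pmcid, r$body %||% "")))
  }
  stop("read_articles: no such file or directory: ", source, call. = FALSE)
}

#' Read and write sentence-record corpora
#'
#' Serialization of sentence records as JSONL `{rna_id, pmcid, sentence}`
#' objects, the interchange format between harvesting and context building.
#'
#' @param corpus Data.frame with at least `rna_id`, `pmcid`, `sentence`.
#' @param path File path.
#' @return `read_sentences()` returns a data.frame; `write_sentences()` the
#'   path, invisibly.
#' @export
write_sentences <- function(corpus, path) {
  write_jsonl(corpus[, intersect(c("rna_id", "pmcid", "sentence"),
                                 names(corpus)), drop = FALSE], path)
}

#' @rdname write_sentences
#' @export
read_sentences <- function(path) {
  recs <- read_jsonl(path)
  data.frame(
    rna_id = vapply(recs, function(r) r$rna_id, character(1)),
    pmcid = vapply(recs, function(r) r$pmcid, character(1)),
    sentence = vapply(recs, function(r) r$sentence, character(1)),
    stringsAsFactors = FALSE
  )
}
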