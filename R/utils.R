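#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG to a known state, runs `code`, and restores whatever state the
#' session had before, so library internals never disturb user-level
#' reproducibility.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Deterministic 31-bit string hash (polynomial rolling hash over UTF-8 bytes).
# Stays exact in doubles: intermediate values < 2^36.
hash31 <- function(s, mult = 31) {
  h <- 17
  for (b in utf8ToInt(enc2utf8(s))) {
    h <- (h * mult + b) %% 2147483647
  }
  h
}

#' Read and write JSON Lines files
#'
#' One JSON object per line; used for sentence corpora, contexts, and pipeline
#' results.
#'
#' @param x For `write_jsonl()`, a data.frame (rows become objects) or an
#'   unnamed list of named lists.
#' @param path File path.
#' @return `read_jsonl()` returns a list of named lists; `write_jsonl()`
#'   returns `path` invisibly.
#' @export
write_jsonl <- function(x, path) {
  if (is.data.frame(x)) {
    x <- lapply(seq_len(nrow(x)), function(i) as.list(x[i, , drop = FALSE]))
    x <- lapply(x, function(row) lapply(row, function(v) v[[1]]))
  }
  lines <- vapply(
    x,
    function(obj) as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")),
    character(1)
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_jsonl
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
}

#' Read a TOML configuration file
#'
#' Supports the subset used by the pipeline configuration: `[section]`
#' headers, `key = value` pairs with string, integer, float, boolean, and
#' flat-array values, and `#` comments.
#'
#' @param path Path to a TOML file.
#' @return A nested named list (sections become sub-lists).
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  out <- list()
  section <- NULL
  parse_scalar <- function(tok) {
    tok <- trimws(tok)
    if (grepl('^".*"$', tok)) return(gsub('^"|"$', "", tok))
    if (grepl("^'.*'$", tok)) return(gsub("^'|'$", "", tok))
    if (tolower(tok) %in% c("true", "false")) return(tolower(tok) == "true")
    if (grepl("^[+-]?[0-9]+$", tok)) return(as.integer(tok))
    if (grepl("^[+-]?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?$", tok)) return(as.numeric(tok))
    tok
  }
  for (raw in lines) {
    line <- sub("#.*$", "", raw)
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[.+\\]$", line)) {
      section <- gsub("^\\[|\\]$", "", line)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0) stop("read_config: cannot parse line: ", raw, call. = FALSE)
    key <- trimws(substr(line, 1, eq - 1))
    val <- trimws(substr(line, eq + 1, nchar(line)))
    parsed <- if (grepl("^\\[.*\\]$", val)) {
      inner <- trimws(gsub("^\\[|\\]$", "", val))
      if (!nzchar(inner)) list() else {
        toks <- strsplit(inner, ",")[[1]]
        vals <- lapply(toks, parse_scalar)
        tryCatch(unlist(vals), error = function(e) vals)
      }
    } else {
      parse_scalar(val)
    }
    if (is.null(section)) out[[key]] <- parsed else out[[section]][[key]] <- parsed
  }
  out
}

# Stable short hash of an R object (for run-metadata config hashes).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  sprintf("%08x", hash31(s))
}
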