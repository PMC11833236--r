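#' Sampling parameters for generation calls
#'
#' Defaults match the initial summary-generation call: low temperature (0.1)
#' for near-deterministic output, a presence penalty of -2 so the model
#' restates tokens from the context in the summary, and a frequency penalty
#' of 1 to avoid repetition. Rescue, consistency, and revision calls use the
#' conservative variant ([conservative_params()]): same temperature, neutral
#' penalties.
#'
#' @param temperature Sampling temperature, `>= 0`.
#' @param presence_penalty,frequency_penalty Penalties in `[-2, 2]`.
#' @param max_output_tokens Completion-length cap.
#' @return An object of class `generation_params`.
#' @export
generation_params <- function(temperature = 0.1, presence_penalty = -2,
                              frequency_penalty = 1,
                              max_output_tokens = 255L) {
  stopifnot(temperature >= 0,
            presence_penalty >= -2, presence_penalty <= 2,
            frequency_penalty >= -2, frequency_penalty <= 2)
  structure(
    list(temperature = temperature,
         presence_penalty = presence_penalty,
         frequency_penalty = frequency_penalty,
         max_output_tokens = as.integer(max_output_tokens)),
    class = "generation_params"
  )
}

#' @rdname generation_params
#' @export
conservative_params <- function(max_output_tokens = 255L) {
  generation_params(temperature = 0.1, presence_penalty = 0,
                    frequency_penalty = 0,
                    max_output_tokens = max_output_tokens)
}

#' Prompt templates
#'
#' Templates live as editable text files under `inst/templates/`, each with a
#' one-line front matter naming its placeholders, a `---` separator, and the
#' body. Placeholders are `{name}` tokens replaced literally at render time.
#' Seven templates drive the pipeline: `initial`, four rescue templates
#' (`rescue_adequacy`, `rescue_identifier` — shared by the formatting and
#' realness checks, `rescue_placement`, `rescue_concentration`),
#' `consistency_check`, and `consistency_revise`.
#'
#' @param name Template name.
#' @param dir Directory of template files; defaults to the installed set.
#' @return `load_template()` returns an object of class `prompt_template`
#'   with fields `name`, `placeholders`, `text`; `template_names()` the
#'   available names.
#' @export
load_template <- function(name, dir = NULL) {
  dir <- dir %||% system.file("templates", package = "rnasumm")
  path <- file.path(dir, paste0(name, ".txt"))
  if (!file.exists(path)) {
    stop("load_template: no template named '", name, "' in ", dir,
         call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  sep <- which(lines == "---")[1]
  if (is.na(sep)) stop("load_template: missing '---' separator in ", path,
                       call. = FALSE)
  header <- paste(lines[seq_len(sep - 1)], collapse = "\n")
  ph <- trimws(strsplit(sub("^placeholders:", "", header), ",")[[1]])
  structure(
    list(name = name, placeholders = ph[nzchar(ph)],
         text = paste(lines[(sep + 1):length(lines)], collapse = "\n")),
    class = "prompt_template"
  )
}

#' @rdname load_template
#' @export
template_names <- function() {
  c("initial", "rescue_adequacy", "rescue_identifier", "rescue_placement",
    "rescue_concentration", "consistency_check", "consistency_revise")
}

# Rescue template used when a given reference check fails.
rescue_for_check <- function(check) {
  switch(check,
         adequacy = "rescue_adequacy",
         formatting = "rescue_identifier",
         realness = "rescue_identifier",
         placement = "rescue_placement",
         concentration = "rescue_concentration",
         stop("rescue_for_check: unknown check: ", check, call. = FALSE))
}

#' Render a prompt template
#'
#' Literal substitution of `{placeholder}` tokens; the bound text (e.g. a
#' whole literature context) is inserted verbatim, never escaped or
#' re-scanned, so braces inside bound values cannot trigger further
#' substitution.
#'
#' @param template A `prompt_template` (or a name passed to
#'   [load_template()]).
#' @param bindings Named list or character vector of placeholder values.
#' @return The rendered prompt string, with attribute `n_substitutions`.
#' @export
render_prompt <- function(template, bindings) {
  if (is.character(template)) template <- load_template(template)
  bindings <- as.list(bindings)
  m <- gregexpr("\\{([a-z_]+)\\}", template$text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    out <- template$text
    attr(out, "n_substitutions") <- 0L
    return(out)
  }
  lens <- attr(m, "match.length")
  names_found <- substring(template$text, m + 1L, m + lens - 2L)
  missing <- setdiff(unique(names_found), names(bindings))
  if (length(missing) > 0) {
    stop("render_prompt: missing bindings: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pieces <- character(0)
  prev_end <- 0L
  for (i in seq_along(m)) {
    pieces <- c(pieces, substring(template$text, prev_end + 1L, m[i] - 1L),
                as.character(bindings[[names_found[i]]]))
    prev_end <- m[i] + lens[i] - 1L
  }
  pieces <- c(pieces, substring(template$text, prev_end + 1L,
                                nchar(template$text)))
  out <- paste(pieces, collapse = "")
  attr(out, "n_substitutions") <- length(m)
  out
}

#' LLM backends
#'
#' Every model call goes through the generic [llm_complete()], which
#' enforces the token-window guard, performs the call, and appends one
#' exchange record (template name, rendered prompt, parameters, response,
#' token usage) to the backend's log.
#'
#' `scripted_backend()` is the bundled deterministic backend: responses are
#' drawn, in order, from a queue keyed by template name — identical queues
#' and calls always yield identical transcripts, which is what the test
#' suite and offline runs rely on.
#'
#' `http_backend()` talks to an OpenAI-style chat-completion endpoint; the
#' request payload is built by [build_chat_request()] (exposed so parameter
#' serialization is testable without network) and transport failures are
#' retried a bounded number of times.
#'
#' @param queue Named list: template name -> character vector of responses,
#'   consumed front-first.
#' @return A backend object.
#' @export
scripted_backend <- function(queue) {
  stopifnot(is.list(queue))
  env <- new.env(parent = emptyenv())
  env$queue <- queue
  env$log <- list()
  structure(list(state = env), class = c("scripted_backend", "llm_backend"))
}

#' @rdname scripted_backend
#' @param url Endpoint URL.
#' @param model Model name sent in the payload.
#' @param api_key_env Name of the environment variable holding the API key.
#' @param max_retries Bounded retry count for transport failures.
#' @export
http_backend <- function(url, model, api_key_env = "LLM_API_KEY",
                         max_retries = 3L) {
  env <- new.env(parent = emptyenv())
  env$log <- list()
  structure(list(state = env, url = url, model = model,
                 api_key_env = api_key_env,
                 max_retries = as.integer(max_retries)),
            class = c("http_backend", "llm_backend"))
}

#' @rdname scripted_backend
#' @param backend A backend object.
#' @param template_name Which template produced the prompt (keys the
#'   scripted queue and the exchange log).
#' @param prompt Rendered prompt text.
#' @param params A [generation_params()].
#' @param budget A [token_budget()] for the window guard.
#' @param counter Token-counter backend.
#' @export
llm_complete <- function(backend, template_name, prompt, params,
                         budget = token_budget(), counter = "words") {
  prompt_tokens <- count_tokens(prompt, backend = counter)
  if (prompt_tokens + params$max_output_tokens > budget$model_window) {
    stop("budget error: prompt (", prompt_tokens, " tokens) plus output ",
         "reservation exceeds the ", budget$model_window, "-token window",
         call. = FALSE)
  }
  response <- backend_call(backend, template_name, prompt, params)
  exch <- list(template_name = template_name,
               rendered_prompt = prompt,
               params = unclass(params),
               response_text = response,
               token_usage = list(
                 prompt = prompt_tokens,
                 completion = count_tokens(response, backend = counter)))
  backend$state$log <- c(backend$state$log, list(exch))
  response
}

backend_call <- function(backend, template_name, prompt, params) {
  UseMethod("backend_call")
}

#' @export
backend_call.scripted_backend <- function(backend, template_name, prompt,
                                          params) {
  q <- backend$state$queue[[template_name]]
  if (is.null(q) || length(q) == 0) {
    stop(structure(
      class = c("transport_error", "error", "condition"),
      list(message = paste0("transport error: scripted queue exhausted for '",
                            template_name, "'"),
           call = NULL)))
  }
  backend$state$queue[[template_name]] <- q[-1]
  q[[1]]
}

#' @export
backend_call.http_backend <- function(backend, template_name, prompt,
                                      params) {
  if (!requireNamespace("curl", quietly = TRUE)) {
    stop("http_backend requires the 'curl' package", call. = FALSE)
  }
  payload <- build_chat_request(backend$model, prompt, params)
  body <- as.character(jsonlite::toJSON(payload, auto_unbox = TRUE))
  key <- Sys.getenv(backend$api_key_env, "")
  last_err <- NULL
  for (attempt in seq_len(backend$max_retries)) {
    res <- tryCatch({
      h <- curl::new_handle()
      curl::handle_setheaders(h, "Content-Type" = "application/json",
                              Authorization = paste("Bearer", key))
      curl::handle_setopt(h, postfields = body)
      resp <- curl::curl_fetch_memory(backend$url, handle = h)
      if (resp$status_code >= 400) {
        stop("HTTP ", resp$status_code, call. = FALSE)
      }
      parsed <- jsonlite::fromJSON(rawToChar(resp$content),
                                   simplifyVector = FALSE)
      parsed$choices[[1]]$message$content
    }, error = function(e) e)
    if (!inherits(res, "error")) return(res)
    last_err <- res
  }
  stop(structure(
    class = c("transport_error", "error", "condition"),
    list(message = paste0("transport error after ", backend$max_retries,
                          " attempts: ", conditionMessage(last_err)),
         call = NULL)))
}

#' @rdname scripted_backend
#' @export
build_chat_request <- function(model, prompt, params) {
  list(model = model,
       messages = list(list(role = "user", content = prompt)),
       temperature = params$temperature,
       presence_penalty = params$presence_penalty,
       frequency_penalty = params$frequency_penalty,
       max_tokens = params$max_output_tokens)
}

#' @rdname scripted_backend
#' @export
backend_log <- function(backend) backend$state$log
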