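# Classed conditions shared across the package. Exit-code mapping for the
# command line lives in cli.R (usage -> 1, data/parse -> 2, network -> 3).

abort_parse <- function(msg, ...) {
  rlang::abort(msg, class = c("keggcomp_parse_error", "keggcomp_error"), ...)
}

abort_data <- function(msg, ...) {
  rlang::abort(msg, class = c("keggcomp_data_error", "keggcomp_error"), ...)
}

abort_network <- function(msg, ...) {
  rlang::abort(msg, class = c("keggcomp_network_error", "keggcomp_error"), ...)
}

abort_empty_response <- function(msg, ...) {
  # distinct from a transport failure: KEGG answers 200 with an empty body
  # for unknown arguments
  rlang::abort(msg,
    class = c("keggcomp_empty_response", "keggcomp_network_error", "keggcomp_error"),
    ...
  )
}

abort_usage <- function(msg, ...) {
  rlang::abort(msg, class = c("keggcomp_usage_error", "keggcomp_error"), ...)
}

# C-locale (radix) sort so EC lists and file output are stable across platforms
sort_c <- function(x) sort(x, method = "radix")

`%||%` <- rlang::`%||%`
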