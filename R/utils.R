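# internal helpers

clip01 <- function(x) pmin(pmax(x, 0), 1)

stop_validation <- function(msg) abort(msg, class = "frogclock_validation_error")
stop_format <- function(msg) abort(msg, class = "frogclock_format_error")
stop_config <- function(msg) abort(msg, class = "frogclock_config_error")
stop_domain <- function(msg) abort(msg, class = "frogclock_domain_error")

# delimiter from file extension unless given explicitly
guess_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation(sprintf("`%s` must be a single finite number", name))
  }
}
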