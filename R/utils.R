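# Internal helpers shared across modules.

# Deterministic, locale-free rounding: halves always go up.
round_half_up <- function(x) floor(x + 0.5)

# Does a trimmed string look like a plain decimal number?  Accepts integer,
# decimal and scientific notation with "." as the decimal mark; rejects "NA",
# "Inf", hex, locale commas and empty strings.
is_number_like <- function(s) {
  grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", trimws(s))
}

parse_number <- function(s) as.numeric(trimws(s))

# Shortest decimal representation that survives a text round-trip exactly.
format_full_precision <- function(x) {
  vapply(x, function(v) {
    if (v == trunc(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_heatcraft <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "heatcraft_error")))
}
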