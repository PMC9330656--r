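# Internal helpers shared across modules.

# Round half away from zero (printed tables use conventional rounding,
# not banker's rounding as base round() does).
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

quic_abort <- function(message, class) {
  rlang::abort(message, class = c(class, "rtquic_error"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Specimen / diagnosis vocabularies. Parsing is case-insensitive and
# tolerant of '-' vs '_' separators.
SPECIMEN_LEVELS <- c("NS_AN", "NS_MT", "CSF")
DIAGNOSIS_LEVELS <- c("PD", "NON_PD", "CONTROL")

parse_enum <- function(x, levels, what) {
  canon <- toupper(gsub("[-. ]", "_", trimws(as.character(x))))
  bad <- !is.na(canon) & !(canon %in% levels)
  if (any(bad)) {
    quic_abort(
      sprintf(
        "unknown %s value(s): %s (allowed: %s)",
        what, paste(unique(canon[bad]), collapse = ", "),
        paste(levels, collapse = ", ")
      ),
      "rtquic_parse_error"
    )
  }
  factor(canon, levels = levels)
}
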