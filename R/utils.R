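# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# ';'-separated set cells used by the tabular dialects
split_set <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || s == "" || s == "-") character(0)
    else unlist(strsplit(s, ";", fixed = TRUE))
  })
}

join_set <- function(x) {
  vapply(x, function(s) paste(s, collapse = ";"), character(1))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# deterministic TSV writer used for all pipeline outputs (byte-stable reruns)
write_tsv <- function(df, path) {
  is_log <- vapply(df, is.logical, logical(1))
  df[is_log] <- lapply(df[is_log], function(x) ifelse(is.na(x), NA, ifelse(x, "TRUE", "FALSE")))
  is_num <- vapply(df, is.double, logical(1))
  df[is_num] <- lapply(df[is_num], function(x) {
    vapply(x, function(v) if (is.na(v)) NA_character_ else format(v, digits = 15), character(1))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

# 32-bit FNV-1a over a string, in double arithmetic (R has no 32-bit unsigned)
fnv1a_hex <- function(x) {
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- ((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619
    h <- h %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
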