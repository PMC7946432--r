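# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

es_version <- function() {
  tryCatch(as.character(utils::packageVersion("editscope")),
           error = function(e) "dev")
}

# Polynomial rolling hash of a deparsed R object, as 8 hex digits.  Used
# only to stamp output files with a fingerprint of the configuration that
# produced them.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = " ")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

output_header <- function(seed = NULL, config = NULL) {
  paste0("# editscope ", es_version(),
         if (!is.null(seed)) paste0("; seed=", seed),
         if (!is.null(config)) paste0("; config=", config_hash(config)))
}

# Write a data.frame as TSV with a provenance header comment.
write_tsv_header <- function(df, path, seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed = seed, config = config), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_header <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
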