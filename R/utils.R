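# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ks <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

assert_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop_ks("%s is missing required column(s): %s", what,
            paste(miss, collapse = ", "))
  }
  invisible(df)
}

read_tsv_file <- function(path, what = "file") {
  if (!file.exists(path)) stop_ks("%s not found: %s", what, path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards so simulation functions do not perturb
# the session RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}
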