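# internal helpers shared across modules

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the current RNG stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic fan-out of a master seed to a per-label seed, so that adding
# a condition never perturbs the random stream of the others.  Plain
# polynomial string hash folded with the master seed, kept below 2^31.
fanout_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- 0
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer((h + round(master) %% 2147483629 * 2) %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tab-separated writer used for every report (plain text, header row, units
# encoded in the column names); doubles at full precision so numeric tables
# round-trip exactly
write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
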