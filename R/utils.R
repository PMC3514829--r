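## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a stream-specific child seed; kept below 2^31.
child_seed <- function(seed, stream) {
  (as.integer(seed) * 7919L + as.integer(stream) * 104729L) %% 2147483647L
}

random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Round the way the reports do: percents to one decimal, densities to
## the nearest integer.
round_pct <- function(x) round(x, 1)

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

write_tsv <- function(df, file) {
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

read_tsv <- function(file, ...) {
  read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE, ...)
}
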