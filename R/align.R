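#' Alignment parameters
#'
#' Scoring and significance parameters for the seed-and-extend local
#' aligner.  Defaults: match +1, mismatch -3, gap open 5, gap extend 2
#' (a gap of length L costs `gap_open + gap_extend * L`), seed word
#' length 11, and a hard cap of 26 bases on any single alignment gap:
#' extension is terminated at a longer gap and the alignment is split
#' into separate hits rather than silently clipped.  `lambda` and
#' `kappa` are the Karlin-Altschul parameters used for E-values and bit
#' scores under this scoring scheme.
#'
#' @param k seed word length (>= 8).
#' @param match match score (positive).
#' @param mismatch mismatch penalty (positive).
#' @param gap_open,gap_extend affine gap penalties (positive).
#' @param max_gap_len maximum allowed single-gap length in an alignment.
#' @param lambda,kappa Karlin-Altschul scale and constant.
#' @param min_score minimum raw score for a hit to be reported.
#' @param max_windows cap on candidate extension windows per query strand.
#' @param min_seeds minimum seed matches supporting a candidate window
#'   (a two-hit style noise guard; default 2).
#' @return an object of class `align_params`.
#' @export
align_params <- function(k = 11L, match = 1L, mismatch = 3L,
                         gap_open = 5L, gap_extend = 2L,
                         max_gap_len = 26L,
                         lambda = 1.28, kappa = 0.46,
                         min_score = 30L, max_windows = 40L,
                         min_seeds = 2L) {
  assert_that(k >= 8, "seed word length k must be >= 8")
  assert_that(lambda > 0 && kappa > 0, "lambda and kappa must be positive")
  assert_that(max_gap_len >= 1, "max_gap_len must be >= 1")
  structure(list(k = as.integer(k), match = as.integer(match),
                 mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 max_gap_len = as.integer(max_gap_len),
                 lambda = lambda, kappa = kappa,
                 min_score = as.integer(min_score),
                 max_windows = as.integer(max_windows),
                 min_seeds = as.integer(min_seeds)),
            class = "align_params")
}

#' Filter reads by mean Phred quality
#'
#' A read is removed iff its mean per-base Phred score is below
#' `qv_threshold`; kept and removed subsets partition the input.  Reads
#' without quality information (a plain `DNAStringSet`) pass unfiltered
#' and are flagged with a warning.
#'
#' @param reads a `QualityScaledDNAStringSet` (or `DNAStringSet`).
#' @param qv_threshold minimum mean Phred score (default 20).
#' @return list with elements `kept`, `removed` (same class as input) and
#'   `mean_qv` (named numeric).
#' @export
quality_filter <- function(reads, qv_threshold = 20) {
  assert_that(qv_threshold >= 0, "qv_threshold must be non-negative")
  if (!methods::is(reads, "QualityScaledXStringSet")) {
    warning("reads carry no quality information; all pass unfiltered")
    return(list(kept = reads, removed = reads[0],
                mean_qv = setNames(rep(NA_real_, length(reads)),
                                   names(reads))))
  }
  qm <- as(Biostrings::quality(reads), "IntegerList")
  mq <- vapply(qm, function(q) mean(q), numeric(1))
  names(mq) <- names(reads)
  keep <- mq >= qv_threshold
  list(kept = reads[keep], removed = reads[!keep], mean_qv = mq)
}

#' Karlin-Altschul E-value
#'
#' `E = kappa * m * n * exp(-lambda * S)` for raw score `S`, query length
#' `m` and database length `n`.  Strictly decreasing in `S` and linear in
#' `m * n`.
#'
#' @param raw_score raw alignment score(s).
#' @param query_length query length in bases.
#' @param database_length total database length in bases.
#' @param params an [align_params()].
#' @return numeric E-value(s).
#' @export
evalue <- function(raw_score, query_length, database_length,
                   params = align_params()) {
  assert_that(all(query_length > 0) && all(database_length > 0),
              "lengths must be positive")
  exp(log(params$kappa) + log(query_length) + log(database_length) -
        params$lambda * raw_score)
}

bit_score <- function(raw_score, params) {
  (params$lambda * raw_score - log(params$kappa)) / log(2)
}

## identity / mismatch / gap-run statistics recomputed from aligned strings
aln_stats <- function(qaln, saln) {
  n <- length(qaln)
  out <- matrix(0L, n, 4,
                dimnames = list(NULL, c("matches", "mismatch", "gapopen",
                                        "gapbases")))
  gap <- utf8ToInt("-")
  for (i in seq_len(n)) {
    q <- utf8ToInt(qaln[i]); s <- utf8ToInt(saln[i])
    qg <- q == gap; sg <- s == gap
    anygap <- qg | sg
    out[i, "matches"] <- sum(q == s & !anygap)
    out[i, "mismatch"] <- sum(q != s & !anygap)
    r <- rle(ifelse(qg, 1L, ifelse(sg, 2L, 0L)))
    out[i, "gapopen"] <- sum(r$values != 0L)
    out[i, "gapbases"] <- sum(anygap)
  }
  out
}

#' Local alignment of reads against a reference
#'
#' Seed-and-extend local alignment (the computational stand-in for a
#' BLASTN search): exact k-mer seeds against a hash index of the
#' reference, windowed affine-gap Smith-Waterman extension with full
#' traceback, both strands searched.  Hits are reported with identity,
#' mismatch/gap counts recomputed from the aligned strings, query
#' coverage (aligned query length over full read length),
#' Karlin-Altschul E-value and bit score, sorted per query by
#' descending bit score.
#'
#' @param reads query reads (`DNAStringSet`,
#'   `QualityScaledDNAStringSet`, or named character).
#' @param reference reference sequences (`DNAStringSet` or `ref_bundle`).
#' @param params an [align_params()].
#' @return a data frame of hit records: `qseqid`, `sseqid`, `strand`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`,
#'   `sstart`, `send` (1-based closed, `sstart <= send`), `score`,
#'   `bitscore`, `evalue`, `qlen`, `qcovg`, `qaln`, `saln`.
#' @export
local_align <- function(reads, reference, params = align_params()) {
  if (inherits(reference, "ref_bundle")) reference <- reference$genome
  if (methods::is(reads, "XStringSet")) reads <- as.character(reads)
  stopifnot(is.character(reads), !is.null(names(reads)))
  refs <- as.character(reference)
  stopifnot(!is.null(names(refs)))

  short <- nchar(reads) < params$k
  if (any(short)) {
    warning(sum(short), " read(s) shorter than the seed length were skipped")
    reads <- reads[!short]
  }
  db_len <- sum(nchar(refs))
  if (!length(reads)) return(empty_hits())

  raw <- .align_batch_cpp(names(refs), unname(refs),
                          names(reads), unname(reads),
                          params$k, params$match, params$mismatch,
                          params$gap_open, params$gap_extend,
                          params$max_gap_len, params$min_score,
                          params$max_windows, params$min_seeds)
  if (!nrow(raw)) return(empty_hits())
  st <- aln_stats(raw$qaln, raw$saln)
  qlen <- nchar(reads)[raw$qseqid]
  cols <- nchar(raw$qaln)
  hits <- data.frame(
    qseqid = raw$qseqid, sseqid = raw$sseqid, strand = raw$strand,
    pident = 100 * st[, "matches"] / cols,
    length = cols,
    mismatch = st[, "mismatch"], gapopen = st[, "gapopen"],
    qstart = raw$qstart, qend = raw$qend,
    sstart = raw$sstart, send = raw$send,
    score = raw$score,
    bitscore = bit_score(raw$score, params),
    evalue = evalue(raw$score, qlen, db_len, params),
    qlen = unname(qlen),
    qcovg = (raw$qend - raw$qstart + 1) / qlen,
    qaln = raw$qaln, saln = raw$saln,
    stringsAsFactors = FALSE)
  hits <- hits[order(hits$qseqid, -hits$bitscore), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(qseqid = character(), sseqid = character(), strand = character(),
             pident = numeric(), length = integer(), mismatch = integer(),
             gapopen = integer(), qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(), score = integer(),
             bitscore = numeric(), evalue = numeric(), qlen = integer(),
             qcovg = numeric(), qaln = character(), saln = character(),
             stringsAsFactors = FALSE)
}

#' Screen reads against a repeat library
#'
#' A read is classified as repeat-derived iff its best hit against the
#' repeat library has `E < evalue_cutoff` (strict); the two subsets
#' partition the input.
#'
#' @param reads query reads.
#' @param repeat_library repeat consensus sequences (`DNAStringSet`).
#' @param evalue_cutoff strict E-value cutoff (default `1e-50`).
#' @param params an [align_params()].
#' @return list with `repeat`, `nonrepeat` (subsets of `reads`) and
#'   `repeat_ids` (character).
#' @export
screen_repeats <- function(reads, repeat_library, evalue_cutoff = 1e-50,
                           params = align_params()) {
  assert_that(length(repeat_library) > 0, "repeat library is empty")
  if (length(reads) == 0)
    return(list(`repeat` = reads, nonrepeat = reads,
                repeat_ids = character(0)))
  hits <- local_align(reads, repeat_library, params)
  best <- tapply(hits$evalue, hits$qseqid, min)
  rep_ids <- names(best)[best < evalue_cutoff]
  keep <- !(names(reads) %in% rep_ids)
  list(`repeat` = reads[!keep], nonrepeat = reads[keep],
       repeat_ids = rep_ids)
}

#' Write / read hits in BLAST-style tabular format
#'
#' The on-disk dialect is the 12-column BLAST `outfmt 6` layout
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore`) optionally extended with two columns for the
#' aligned query and subject strings.  Coordinates in the file are
#' 1-based inclusive; minus-strand hits carry `sstart > send`.  On
#' read, strand is inferred and subject coordinates normalised to
#' `sstart <= send`.  When aligned strings are absent from a file,
#' variant calling is disabled for those hits (a warning is logged at
#' call time); query coverage is recomputed when read lengths are
#' supplied.
#'
#' @param hits a hit data frame from [local_align()].
#' @param file path to a TSV file.
#' @param aligned_strings write the two extra aligned-string columns
#'   (default TRUE).
#' @param qlen optional named vector of read lengths used to recompute
#'   query coverage on read.
#' @return `file` ([write_hits()]) or a hit data frame ([read_hits()]).
#' @export
write_hits <- function(hits, file, aligned_strings = TRUE) {
  out <- hits[, c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")]
  minus <- hits$strand == "-"
  out$sstart[minus] <- hits$send[minus]
  out$send[minus] <- hits$sstart[minus]
  out$pident <- sprintf("%.2f", out$pident)
  out$bitscore <- sprintf("%.1f", out$bitscore)
  if (aligned_strings) { out$qaln <- hits$qaln; out$saln <- hits$saln }
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

#' @rdname write_hits
#' @export
read_hits <- function(file, qlen = NULL) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- read.table(file, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) == 14) names(df) <- c(cols, "qaln", "saln")
  else if (ncol(df) == 12) { names(df) <- cols; df$qaln <- NA_character_
                             df$saln <- NA_character_ }
  else stop("expected 12 or 14 tab-separated columns", call. = FALSE)
  minus <- df$sstart > df$send
  df$strand <- ifelse(minus, "-", "+")
  tmp <- df$sstart[minus]
  df$sstart[minus] <- df$send[minus]
  df$send[minus] <- tmp
  if (!is.null(qlen)) {
    df$qlen <- unname(qlen[df$qseqid])
    df$qcovg <- (df$qend - df$qstart + 1) / df$qlen
  } else {
    df$qlen <- NA_integer_
    df$qcovg <- NA_real_
  }
  df$score <- NA_integer_
  df[, c(cols[1:2], "strand", cols[3:10], "score", "bitscore", "evalue",
         "qlen", "qcovg", "qaln", "saln")]
}
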