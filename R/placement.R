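#' Placement rules for BES extraction
#'
#' The six extraction criteria applied to per-end hit lists: a hit is
#' significant iff identity > `min_identity`, query coverage >
#' `min_coverage` and `E < evalue_cap` (all strict); an end is unique
#' iff exactly one significant hit survives (no best-hit rescue when
#' several do); a unique pair is concordant iff both ends lie on the
#' same chromosome, on opposite strands facing inward, less than
#' `max_pair_distance` apart.
#'
#' @param min_identity percent identity threshold (strict >, default 90).
#' @param min_coverage query-coverage threshold (strict >, default 0.5).
#' @param max_pair_distance maximum outermost extent of a concordant
#'   pair in bases (strict <, default 200000).
#' @param evalue_cap E-value threshold (strict <, default 1e-100).
#' @param require_unique if TRUE (default) an end with two or more
#'   significant hits is classified REDUNDANT.
#' @param pair_suffixes the two read-id suffixes naming the ends of a
#'   clone, in end-1/end-2 order; the clone id is the read id with
#'   `.suffix` stripped.
#' @return an object of class `placement_rules`.
#' @export
placement_rules <- function(min_identity = 90, min_coverage = 0.5,
                            max_pair_distance = 200000,
                            evalue_cap = 1e-100,
                            require_unique = TRUE,
                            pair_suffixes = c("T7", "SP6")) {
  assert_that(min_identity > 0 && min_coverage > 0 &&
                max_pair_distance > 0 && evalue_cap > 0,
              "placement thresholds must be positive")
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 max_pair_distance = max_pair_distance,
                 evalue_cap = evalue_cap,
                 require_unique = isTRUE(require_unique),
                 pair_suffixes = pair_suffixes),
            class = "placement_rules")
}

pair_regex <- function(rules)
  paste0("\\.(", paste(rules$pair_suffixes, collapse = "|"), ")$")

#' Keep significant hits
#'
#' Applies the identity / coverage / E-value thresholds, all strict:
#' a hit with identity exactly at the threshold is removed.
#'
#' @param hits hit data frame from [local_align()] or [read_hits()].
#' @param rules a [placement_rules()].
#' @return the significant subset of `hits`.
#' @export
filter_hits <- function(hits, rules = placement_rules()) {
  if (!nrow(hits)) return(hits)
  keep <- hits$pident > rules$min_identity &
    hits$qcovg > rules$min_coverage &
    hits$evalue < rules$evalue_cap
  keep[is.na(keep)] <- FALSE
  hits[keep, , drop = FALSE]
}

#' Classify read ends by hit uniqueness
#'
#' Each read is assigned one of REPEAT (flagged by the repeat screen),
#' NO_HIT (no alignment at all), WEAK (alignments but none significant),
#' REDUNDANT (two or more significant hits) or UNIQUE (exactly one);
#' the five statuses partition the input reads.
#'
#' @param hits raw (unfiltered) hit data frame.
#' @param read_ids ids of all reads entering classification (reads
#'   without hits are NO_HIT).
#' @param rules a [placement_rules()].
#' @param repeat_ids read ids removed by the repeat screen.
#' @return data frame with `read_id`, `status`, `n_hits`, `n_significant`
#'   plus the accepted hit columns (`chrom`, `start`, `end`, `strand`,
#'   `qaln`, `saln`, ...) for UNIQUE reads.
#' @export
classify_ends <- function(hits, read_ids, rules = placement_rules(),
                          repeat_ids = character(0)) {
  sig <- filter_hits(hits, rules)
  n_hits <- table(factor(hits$qseqid, levels = read_ids))
  n_sig <- table(factor(sig$qseqid, levels = read_ids))
  status <- ifelse(read_ids %in% repeat_ids, "REPEAT",
            ifelse(n_hits == 0, "NO_HIT",
            ifelse(n_sig == 0, "WEAK",
            ifelse(n_sig >= 2 & rules$require_unique, "REDUNDANT",
                   "UNIQUE"))))
  out <- data.frame(read_id = read_ids, status = status,
                    n_hits = as.integer(n_hits),
                    n_significant = as.integer(n_sig),
                    stringsAsFactors = FALSE)
  acc <- sig[sig$qseqid %in% out$read_id[out$status == "UNIQUE"], ,
             drop = FALSE]
  ## exactly one row per unique read by construction
  idx <- match(out$read_id, acc$qseqid)
  out$chrom <- acc$sseqid[idx]
  out$start <- acc$sstart[idx]
  out$end <- acc$send[idx]
  out$strand <- acc$strand[idx]
  out$evalue <- acc$evalue[idx]
  out$pident <- acc$pident[idx]
  out$qaln <- acc$qaln[idx]
  out$saln <- acc$saln[idx]
  out
}

#' Classify clones from per-end placements
#'
#' Pairs reads into clones via the read-id suffix convention and applies
#' the pair-level criteria: UNIQUE_PAIR iff both ends are UNIQUE,
#' UNIQUE_END iff exactly one is, EXCLUDED otherwise.  A unique pair is
#' CONCORDANT iff both ends map to the same chromosome, on opposite
#' strands facing inward (the forward end leftmost), with outermost
#' extent strictly below the distance cap; otherwise DISCORDANT.
#' Discordant unique pairs are retained (they feed rearrangement
#' detection) but are excluded from contig building.
#'
#' @param ends data frame from [classify_ends()].
#' @param rules a [placement_rules()].
#' @return data frame with one row per clone: end read ids and statuses,
#'   `class`, `concordance`, per-end chrom/start/end/strand, and for
#'   concordant pairs the clone interval (`chrom`, `start`, `end`) and
#'   deduced insert `span`.
#' @export
classify_clones <- function(ends, rules = placement_rules()) {
  rx <- pair_regex(rules)
  has_suffix <- grepl(rx, ends$read_id)
  if (!all(has_suffix))
    warning(sum(!has_suffix), " read id(s) without a recognised end ",
            "suffix were dropped from clone pairing")
  e <- ends[has_suffix, , drop = FALSE]
  clone <- sub(rx, "", e$read_id)
  suffix <- sub(paste0("^.*\\.(", paste(rules$pair_suffixes, collapse = "|"),
                       ")$"), "\\1", e$read_id)
  ord <- match(suffix, rules$pair_suffixes)
  clones <- unique(clone)

  pick <- function(cl, which_end) {
    i <- which(clone == cl & ord == which_end)
    if (length(i) == 0) NULL else e[i[1], ]
  }
  rows <- lapply(clones, function(cl) {
    e1 <- pick(cl, 1L); e2 <- pick(cl, 2L)
    stat <- function(x) if (is.null(x)) "NO_HIT" else x$status
    s1 <- stat(e1); s2 <- stat(e2)
    n_unique <- (s1 == "UNIQUE") + (s2 == "UNIQUE")
    cls <- if (n_unique == 2) "UNIQUE_PAIR"
           else if (n_unique == 1) "UNIQUE_END" else "EXCLUDED"
    conc <- "NOT_APPLICABLE"
    chrom <- NA_character_; cstart <- NA_integer_; cend <- NA_integer_
    span <- NA_integer_
    if (cls == "UNIQUE_PAIR") {
      same_chr <- e1$chrom == e2$chrom
      if (same_chr) {
        cstart <- min(e1$start, e2$start)
        cend <- max(e1$end, e2$end)
        span <- cend - cstart + 1L
        chrom <- e1$chrom
      }
      left <- if (isTRUE(same_chr) && e2$start < e1$start) e2 else e1
      right <- if (isTRUE(same_chr) && e2$start < e1$start) e1 else e2
      inward <- isTRUE(same_chr) && left$strand == "+" &&
        right$strand == "-"
      conc <- if (isTRUE(same_chr) && inward &&
                  span < rules$max_pair_distance) "CONCORDANT"
              else "DISCORDANT"
      if (conc == "DISCORDANT" && !isTRUE(same_chr)) {
        chrom <- NA_character_; cstart <- NA_integer_; cend <- NA_integer_
        span <- NA_integer_
      }
    }
    g <- function(x, f, cast) if (is.null(x)) cast else x[[f]]
    data.frame(
      clone_id = cl, class = cls, concordance = conc,
      chrom = chrom, start = cstart, end = cend, span = span,
      end1_read = if (is.null(e1)) NA_character_ else e1$read_id,
      end2_read = if (is.null(e2)) NA_character_ else e2$read_id,
      end1_status = s1, end2_status = s2,
      end1_chrom = g(e1, "chrom", NA_character_),
      end1_start = g(e1, "start", NA_integer_),
      end1_end = g(e1, "end", NA_integer_),
      end1_strand = g(e1, "strand", NA_character_),
      end2_chrom = g(e2, "chrom", NA_character_),
      end2_start = g(e2, "start", NA_integer_),
      end2_end = g(e2, "end", NA_integer_),
      end2_strand = g(e2, "strand", NA_character_),
      end1_n_significant = g(e1, "n_significant", NA_integer_),
      end2_n_significant = g(e2, "n_significant", NA_integer_),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read counts along the extraction flow
#'
#' Tallies reads into the repeat / no-hit / weak / redundant /
#' unique-pair-end / unique-end bins; the six bins partition the input.
#'
#' @param ends data frame from [classify_ends()].
#' @param clones data frame from [classify_clones()].
#' @return named list of counts, including `total` and
#'   `selection_fraction` (percent, one decimal).
#' @export
flow_counts <- function(ends, clones) {
  upe_clones <- clones$clone_id[clones$class == "UNIQUE_PAIR"]
  upe_reads <- 2L * length(upe_clones)
  ue_reads <- sum(clones$class == "UNIQUE_END")
  n <- function(s) sum(ends$status == s)
  total <- nrow(ends)
  counts <- list(
    total = total,
    `repeat` = n("REPEAT"),
    no_hit = n("NO_HIT"),
    weak = n("WEAK"),
    redundant = n("REDUNDANT"),
    unique_pair_ends = upe_reads,
    unique_ends = ue_reads)
  counts$selection_fraction <-
    selection_fraction(upe_reads, ue_reads, total)
  counts
}

#' Deduced insert-size statistics of concordant clones
#'
#' The insert span of a concordant pair is the distance from the
#' leftmost to the rightmost aligned base across both ends.  Spans are
#' binned at `bin_width` (default 20 kb); the fraction of clones in the
#' modal bin is reported alongside mean and median.
#'
#' @param clones data frame from [classify_clones()].
#' @param bin_width histogram bin width in bases.
#' @return list with `n`, `mean`, `median`, `histogram` (data frame
#'   `bin_start`, `bin_end`, `count`, `fraction`) and
#'   `modal_bin_fraction` (percent, one decimal).
#' @export
insert_size_stats <- function(clones, bin_width = 20000) {
  spans <- clones$span[clones$class == "UNIQUE_PAIR" &
                         clones$concordance == "CONCORDANT"]
  spans <- spans[!is.na(spans)]
  if (!length(spans)) {
    warning("no concordant placements; empty insert-size statistics")
    return(list(n = 0L, mean = NA_real_, median = NA_real_,
                histogram = data.frame(bin_start = integer(),
                                       bin_end = integer(),
                                       count = integer(),
                                       fraction = numeric()),
                modal_bin_fraction = NA_real_))
  }
  b <- floor((spans - 1) / bin_width)
  tab <- table(b)
  hist <- data.frame(
    bin_start = as.integer(names(tab)) * bin_width + 1L,
    bin_end = (as.integer(names(tab)) + 1L) * bin_width,
    count = as.integer(tab))
  hist$fraction <- hist$count / length(spans)
  list(n = length(spans), mean = mean(spans), median = median(spans),
       histogram = hist,
       modal_bin_fraction = round_pct(100 * max(hist$count) / length(spans)))
}
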