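#' Discordance signatures of uniquely placed clone pairs
#'
#' Reduces each discordant unique pair to the geometric anomaly that
#' suggests a rearrangement.  Ends are ordered by genomic position
#' (end A leftmost).  Categories: `ORIENTATION` (same chromosome,
#' within the distance cap, strands violating the inward-facing rule),
#' `ORIENTATION_AND_DISTANCE` (strands violate and the pair is at or
#' beyond the cap), `DISTANCE` (strands correct, too far apart) and
#' `INTERCHROM` (ends on different chromosomes).  Concordant pairs
#' yield no signature; rows that are not unique pairs are rejected.
#'
#' @param clones data frame of UNIQUE_PAIR rows from
#'   [classify_clones()] (concordant rows allowed, they produce no
#'   signature).
#' @param rules a [placement_rules()].
#' @return data frame with one row per discordant pair: `clone_id`,
#'   `category`, ordered end coordinates/strands, `distance`
#'   (outermost extent, same-chromosome only) and the inner gap between
#'   the two end alignments.
#' @export
discordance_signatures <- function(clones, rules = placement_rules()) {
  if (any(clones$class != "UNIQUE_PAIR"))
    stop("discordance signatures are defined for UNIQUE_PAIR placements",
         call. = FALSE)
  d <- clones[clones$concordance == "DISCORDANT", , drop = FALSE]
  empty <- data.frame(clone_id = character(), category = character(),
                      chromA = character(), startA = integer(),
                      endA = integer(), strandA = character(),
                      readA = character(),
                      chromB = character(), startB = integer(),
                      endB = integer(), strandB = character(),
                      readB = character(),
                      distance = integer(), gap_start = integer(),
                      gap_end = integer(), stringsAsFactors = FALSE)
  if (!nrow(d)) return(empty)
  rows <- lapply(seq_len(nrow(d)), function(i) {
    x <- d[i, ]
    e1 <- list(chrom = x$end1_chrom, start = x$end1_start,
               end = x$end1_end, strand = x$end1_strand,
               read = x$end1_read)
    e2 <- list(chrom = x$end2_chrom, start = x$end2_start,
               end = x$end2_end, strand = x$end2_strand,
               read = x$end2_read)
    swap <- (e2$chrom < e1$chrom) ||
      (e2$chrom == e1$chrom && e2$start < e1$start)
    a <- if (swap) e2 else e1
    b <- if (swap) e1 else e2
    same_chr <- a$chrom == b$chrom
    if (same_chr) {
      dist <- max(a$end, b$end) - min(a$start, b$start) + 1L
      inward <- a$strand == "+" && b$strand == "-"
      too_far <- dist >= rules$max_pair_distance
      cat <- if (!inward && !too_far) "ORIENTATION"
             else if (!inward) "ORIENTATION_AND_DISTANCE"
             else "DISTANCE"
      gs <- a$end + 1L; ge <- b$start - 1L
    } else {
      cat <- "INTERCHROM"; dist <- NA_integer_
      gs <- NA_integer_; ge <- NA_integer_
    }
    data.frame(clone_id = x$clone_id, category = cat,
               chromA = a$chrom, startA = a$start, endA = a$end,
               strandA = a$strand, readA = a$read,
               chromB = b$chrom, startB = b$start, endB = b$end,
               strandB = b$strand, readB = b$read,
               distance = dist, gap_start = gs, gap_end = ge,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cluster discordance signatures into candidate rearrangement events
#'
#' Signatures of the same category on the same chromosome (pair) are
#' clustered by single linkage over their clone spans (outermost extent
#' of the two ends): spans closer than `window` fall into one event.
#' Spans are used rather than individual end clusters so that the two
#' orientation sub-families flanking an inversion (both-plus pairs
#' entering from the left, both-minus pairs from the right) merge into
#' the single event they jointly support.  Clusters supported by fewer
#' than `min_support` clones are discarded.
#'
#' Event typing: `ORIENTATION` signatures give `INVERSION`,
#' `ORIENTATION_AND_DISTANCE` give `TRANSLOCATION_INVERSION`,
#' `INTERCHROM` give `TRANSLOCATION` and `DISTANCE` give
#' `DISTANCE_ANOMALY`.  Reported breakpoint regions are the union spans
#' of the two end clusters extended by `breakpoint_pad` on both sides:
#' a junction must lie within one clone length of every supporting end,
#' so the pad should be an upper bound on the insert size (the default
#' reuses the concordance distance cap).  For inversions the size range
#' implied by which end of each clone is inverted is reported as
#' `size_min`/`size_max`.
#'
#' @param signatures data frame from [discordance_signatures()].
#' @param window clustering window in bases (default 50 kb).
#' @param min_support minimum supporting clones per event (default 2;
#'   a single clone is never evidence, it may be chimeric).
#' @param breakpoint_pad pad added to each breakpoint region (default
#'   200 kb).
#' @return data frame with one row per event: `event_id`, `type`,
#'   `category`, `n_support`, `clones`, per-side chromosome, cluster
#'   span (`bpA_start` ...) and padded breakpoint region
#'   (`regionA_start` ...), plus `size_min`/`size_max` for inversions.
#' @export
cluster_events <- function(signatures, window = 50000, min_support = 2,
                           breakpoint_pad = 200000) {
  assert_that(window > 0, "window must be positive")
  assert_that(min_support >= 1, "min_support must be >= 1")
  empty <- data.frame(event_id = character(), type = character(),
                      category = character(), n_support = integer(),
                      clones = character(),
                      chromA = character(), bpA_start = integer(),
                      bpA_end = integer(), regionA_start = integer(),
                      regionA_end = integer(),
                      chromB = character(), bpB_start = integer(),
                      bpB_end = integer(), regionB_start = integer(),
                      regionB_end = integer(),
                      size_min = integer(), size_max = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(signatures)) return(empty)
  type_of <- c(ORIENTATION = "INVERSION",
               ORIENTATION_AND_DISTANCE = "TRANSLOCATION_INVERSION",
               INTERCHROM = "TRANSLOCATION",
               DISTANCE = "DISTANCE_ANOMALY")
  sig <- signatures
  sig$span_start <- pmin(sig$startA, sig$startB)
  sig$span_end <- pmax(sig$endA, sig$endB)
  ## deterministic under input reordering
  sig <- sig[order(sig$category, sig$chromA, sig$chromB, sig$span_start,
                   sig$clone_id), , drop = FALSE]
  key <- paste(sig$category, sig$chromA, sig$chromB, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    s <- sig[key == k, , drop = FALSE]
    ## single-linkage sweep over clone spans
    grp <- integer(nrow(s)); g <- 0L; reach <- -Inf
    for (i in seq_len(nrow(s))) {
      if (s$span_start[i] > reach + window) { g <- g + 1L; reach <- -Inf }
      grp[i] <- g
      reach <- max(reach, s$span_end[i])
    }
    for (gg in unique(grp)) {
      m <- s[grp == gg, , drop = FALSE]
      if (nrow(m) < min_support) next
      bpA <- c(min(m$startA), max(m$endA))
      bpB <- c(min(m$startB), max(m$endB))
      ## inversion size range: the two orientation sub-families bracket
      ## the breakpoints (plus-plus pairs straddle the left junction,
      ## minus-minus pairs the right one); with only one sub-family fall
      ## back to the span of member geometries
      smin <- NA_integer_; smax <- NA_integer_
      if (m$category[1] == "ORIENTATION") {
        pp <- m[m$strandA == "+", , drop = FALSE]
        mm <- m[m$strandA == "-", , drop = FALSE]
        if (nrow(pp) && nrow(mm)) {
          smin <- max(0L, max(mm$endA) - min(pp$startB))
          smax <- max(0L, min(mm$startB) - max(pp$endA))
        } else {
          smin <- max(0L, min(m$startB - m$endA))
          smax <- max(m$endB - m$startA)
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        event_id = NA_character_, type = unname(type_of[m$category[1]]),
        category = m$category[1], n_support = nrow(m),
        clones = paste(sort(m$clone_id), collapse = ","),
        chromA = m$chromA[1], bpA_start = bpA[1], bpA_end = bpA[2],
        regionA_start = max(1L, bpA[1] - breakpoint_pad),
        regionA_end = bpA[2] + breakpoint_pad,
        chromB = m$chromB[1], bpB_start = bpB[1], bpB_end = bpB[2],
        regionB_start = max(1L, bpB[1] - breakpoint_pad),
        regionB_end = bpB[2] + breakpoint_pad,
        size_min = smin, size_max = smax,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$chromA, ev$bpA_start), , drop = FALSE]
  ev$event_id <- sprintf("event%02d", seq_len(nrow(ev)))
  rownames(ev) <- NULL
  ev
}

#' Flag candidate events near repeats or with multicopy support
#'
#' Automates the manual screening of candidate rearrangements: an event
#' is flagged (never silently dropped) when annotated repeats fall
#' within `flank` of any supporting end alignment (the end alignments
#' delimit the junctions), or when any supporting end shows more than
#' one similarity to the genome below `multicopy_evalue` in the raw
#' (pre-filtering) hit list.  Unflagged events are the final
#' candidates.  Only near-full-length extra hits (query coverage above
#' 0.5, where coverage is known) count toward the multicopy flag, so the
#' split alignments of junction-spanning reads do not mark their own
#' event as repetitive.
#'
#' @param events data frame from [cluster_events()].
#' @param signatures the signatures the events were built from (used to
#'   recover supporting read ids).
#' @param repeat_annotation `GRanges` of annotated repeats (may be
#'   empty).
#' @param hits raw hit data frame used for the multicopy check, or
#'   NULL to skip it.
#' @param flank flank width around each supporting end alignment
#'   (default 5 kb).
#' @param multicopy_evalue E-value below which an extra hit marks an
#'   end as multicopy (default 1e-50).
#' @return `events` with added logical columns `flag_repeat`,
#'   `flag_multicopy` and `pass` (neither flag set).
#' @export
filter_events <- function(events, signatures,
                          repeat_annotation = GenomicRanges::GRanges(),
                          hits = NULL, flank = 5000,
                          multicopy_evalue = 1e-50) {
  if (!nrow(events)) {
    events$flag_repeat <- logical(0)
    events$flag_multicopy <- logical(0)
    events$pass <- logical(0)
    return(events)
  }
  flag_rep <- logical(nrow(events))
  if (length(repeat_annotation)) {
    for (i in seq_len(nrow(events))) {
      cl <- strsplit(events$clones[i], ",")[[1]]
      m <- signatures[signatures$clone_id %in% cl, , drop = FALSE]
      ## the supporting end alignments delimit the junctions; a repeat
      ## within `flank` of any of them questions the event
      fl <- GenomicRanges::GRanges(
        c(m$chromA, m$chromB),
        IRanges::IRanges(pmax(1L, c(m$startA, m$startB) - flank),
                         c(m$endA, m$endB) + flank))
      flag_rep[i] <- any(IRanges::overlapsAny(fl, repeat_annotation))
    }
  }
  flag_multi <- logical(nrow(events))
  if (!is.null(hits) && nrow(hits)) {
    ## only alternative near-full-length placements count as multicopy
    ## evidence: a junction-spanning read legitimately split-aligns at two
    ## loci over complementary parts of the read, and those partial hits
    ## are evidence of the rearrangement, not of repetitive sequence
    strong <- hits[hits$evalue < multicopy_evalue &
                     (is.na(hits$qcovg) | hits$qcovg > 0.5), , drop = FALSE]
    n_strong <- table(strong$qseqid)
    for (i in seq_len(nrow(events))) {
      cl <- strsplit(events$clones[i], ",")[[1]]
      m <- signatures[signatures$clone_id %in% cl, , drop = FALSE]
      reads <- c(m$readA, m$readB)
      flag_multi[i] <- any(n_strong[reads] > 1, na.rm = TRUE)
    }
  }
  events$flag_repeat <- flag_rep
  events$flag_multicopy <- flag_multi
  events$pass <- !flag_rep & !flag_multi
  events
}

#' Write events in a per-end tabular report
#'
#' One row per supporting end (clone, end read, chromosome, strand,
#' from, to, event id, possible event), 1-based inclusive coordinates.
#'
#' @param events data frame from [filter_events()] or
#'   [cluster_events()].
#' @param signatures matching signature data frame.
#' @param file path.
#' @return `file`, invisibly.
#' @export
write_events_tsv <- function(events, signatures, file) {
  rows <- list()
  for (i in seq_len(nrow(events))) {
    cl <- strsplit(events$clones[i], ",")[[1]]
    m <- signatures[signatures$clone_id %in% cl, , drop = FALSE]
    for (j in seq_len(nrow(m))) {
      rows[[length(rows) + 1L]] <- data.frame(
        event = events$event_id[i],
        possible_event = events$type[i],
        clone = m$clone_id[j],
        end_read = c(m$readA[j], m$readB[j]),
        chrom = c(m$chromA[j], m$chromB[j]),
        strand = c(m$strandA[j], m$strandB[j]),
        from = c(m$startA[j], m$startB[j]),
        to = c(m$endA[j], m$endB[j]),
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows)
  else data.frame(event = character(), possible_event = character(),
                  clone = character(), end_read = character(),
                  chrom = character(), strand = character(),
                  from = integer(), to = integer())
  write_tsv(df, file)
}
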