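#' Build hypothetical BAC contigs from concordant clone intervals
#'
#' Contigs are the connected components of interval overlap among
#' concordant clone intervals (touching intervals merge); every
#' concordant clone belongs to exactly one contig and contigs on a
#' chromosome are pairwise non-overlapping.
#'
#' @param clones data frame from [classify_clones()].
#' @return data frame with `contig_id`, `chrom`, `start`, `end`,
#'   `n_clones` and `members` (comma-separated clone ids), 1-based
#'   closed coordinates.
#' @export
build_contigs <- function(clones) {
  cc <- clones[clones$class == "UNIQUE_PAIR" &
                 clones$concordance == "CONCORDANT" &
                 !is.na(clones$chrom), , drop = FALSE]
  if (!nrow(cc))
    return(data.frame(contig_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_clones = integer(), members = character(),
                      stringsAsFactors = FALSE))
  gr <- GenomicRanges::GRanges(cc$chrom, IRanges::IRanges(cc$start, cc$end))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
  ov <- GenomicRanges::findOverlaps(gr, merged)
  grp <- S4Vectors::subjectHits(ov)
  members <- split(cc$clone_id, grp)
  md <- as.data.frame(merged)
  out <- data.frame(
    contig_id = sprintf("contig%04d", seq_along(merged)),
    chrom = as.character(md$seqnames),
    start = md$start, end = md$end,
    n_clones = as.integer(lengths(members)[as.character(seq_along(merged))]),
    members = vapply(as.character(seq_along(merged)), function(i)
      paste(members[[i]], collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Chromatin-partitioned genome coverage of BAC contigs
#'
#' Intersects the contig union with the euchromatin/heterochromatin
#' partition: covered bases are split exactly at partition boundaries,
#' while contig and clone counts are assigned to the partition holding
#' the contig midpoint.  Per-chromosome euchromatin, heterochromatin and
#' total rows are emitted, plus grand-total rows over all chromosomes
#' (whose percent coverage is the covered fraction of the summed
#' partition lengths).
#'
#' @param contigs data frame from [build_contigs()].
#' @param partition partition `GRanges` with a `label` column
#'   (see [chromatin_partition()]).
#' @param chrom_lengths named vector of chromosome lengths.
#' @return data frame with `chromosome`, `partition` (`E`, `H` or
#'   `total`), `length`, `n_contigs`, `n_clones`, `covered`,
#'   `uncovered`, `pct_coverage`; grand totals use chromosome
#'   `"Total"`.
#' @export
coverage_stats <- function(contigs, partition, chrom_lengths) {
  chroms <- names(chrom_lengths)
  if (nrow(contigs)) {
    bad <- !(contigs$chrom %in% chroms) |
      contigs$start < 1 | contigs$end > chrom_lengths[contigs$chrom]
    if (any(bad))
      stop("contig outside chromosome bounds: ",
           paste(contigs$contig_id[bad], collapse = ", "), call. = FALSE)
  }
  cgr <- if (nrow(contigs))
    GenomicRanges::GRanges(contigs$chrom,
                           IRanges::IRanges(contigs$start, contigs$end))
  else GenomicRanges::GRanges()
  mid <- if (nrow(contigs))
    floor((contigs$start + contigs$end) / 2) else integer(0)

  part_len <- function(ch, lab) {
    p <- partition[as.character(GenomicRanges::seqnames(partition)) == ch &
                     partition$label == lab]
    sum(GenomicRanges::width(p))
  }
  covered_in <- function(ch, lab) {
    p <- partition[as.character(GenomicRanges::seqnames(partition)) == ch &
                     partition$label == lab]
    if (!length(p) || !length(cgr)) return(0L)
    sum(GenomicRanges::width(GenomicRanges::intersect(
      GenomicRanges::reduce(cgr), p)))
  }
  counts_in <- function(ch, lab) {
    if (!nrow(contigs)) return(c(0L, 0L))
    p <- partition[as.character(GenomicRanges::seqnames(partition)) == ch &
                     partition$label == lab]
    sel <- contigs$chrom == ch &
      IRanges::overlapsAny(GenomicRanges::GRanges(contigs$chrom,
                                                  IRanges::IRanges(mid, mid)),
                           p)
    c(sum(sel), sum(contigs$n_clones[sel]))
  }

  rows <- list()
  for (ch in chroms) {
    for (lab in c("E", "H")) {
      len <- part_len(ch, lab)
      cov <- covered_in(ch, lab)
      cnt <- counts_in(ch, lab)
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = ch, partition = lab, length = len,
        n_contigs = cnt[1], n_clones = cnt[2],
        covered = cov, uncovered = len - cov,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  tot_chr <- do.call(rbind, lapply(chroms, function(ch) {
    s <- df[df$chromosome == ch, ]
    data.frame(chromosome = ch, partition = "total",
               length = sum(s$length), n_contigs = sum(s$n_contigs),
               n_clones = sum(s$n_clones), covered = sum(s$covered),
               uncovered = sum(s$uncovered), stringsAsFactors = FALSE)
  }))
  gtot <- do.call(rbind, lapply(c("E", "H", "total"), function(lab) {
    s <- if (lab == "total") tot_chr else df[df$partition == lab, ]
    data.frame(chromosome = "Total", partition = lab,
               length = sum(s$length), n_contigs = sum(s$n_contigs),
               n_clones = sum(s$n_clones), covered = sum(s$covered),
               uncovered = sum(s$uncovered), stringsAsFactors = FALSE)
  }))
  out <- rbind(df, tot_chr, gtot)
  out$pct_coverage <- round_pct(100 * out$covered / out$length)
  rownames(out) <- NULL
  out
}

#' Summarise a chromosome-coverage table
#'
#' Runs the coverage-row arithmetic over a per-chromosome table of
#' partition lengths and covered bases (for example one read from disk):
#' partition-wide percent coverage is total covered bases over total
#' partition length, reported to one decimal.
#'
#' @param tab data frame with columns `chromosome`, `partition`
#'   (`E`/`H`), `length`, `covered` (per-chromosome rows only).
#' @return list with `euchromatin_pct`, `heterochromatin_pct`,
#'   `total_pct`, and the underlying totals.
#' @export
summarize_coverage_table <- function(tab) {
  stopifnot(all(c("chromosome", "partition", "length", "covered") %in%
                  names(tab)))
  tot <- function(lab) {
    s <- if (lab == "total") tab else tab[tab$partition == lab, ]
    c(length = sum(as.numeric(s$length)), covered = sum(as.numeric(s$covered)))
  }
  e <- tot("E"); h <- tot("H"); t <- tot("total")
  list(euchromatin_pct = round_pct(100 * e["covered"] / e["length"]),
       heterochromatin_pct = round_pct(100 * h["covered"] / h["length"]),
       total_pct = round_pct(100 * t["covered"] / t["length"]),
       euchromatin_covered = unname(e["covered"]),
       heterochromatin_covered = unname(h["covered"]),
       total_covered = unname(t["covered"]),
       total_length = unname(t["length"]))
}

#' Write contigs as BED
#'
#' BED uses 0-based half-open coordinates; columns are chrom, start,
#' end, contig id, member-clone count.
#'
#' @param contigs data frame from [build_contigs()].
#' @param file path.
#' @return `file`, invisibly.
#' @export
write_contigs_bed <- function(contigs, file) {
  bed <- data.frame(chrom = contigs$chrom, start = contigs$start - 1L,
                    end = contigs$end, name = contigs$contig_id,
                    score = contigs$n_clones)
  write.table(bed, file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}
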