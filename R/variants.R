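#' Call SNPs and short indels from the aligned strings of accepted hits
#'
#' Column-wise walk over each hit's aligned query/subject strings:
#' a mismatch column yields a SNP at the subject coordinate; a run of
#' gaps in the query string yields an `INS` (the reference carries
#' bases the read lacks); a run of gaps in the subject string yields a
#' `DEL` (the read carries bases the reference lacks).  A gap run is
#' one polymorphism of its run length.  Indels are anchored VCF-style
#' at the reference base immediately left of the gap, with allele
#' strings in reference-forward orientation (minus-strand hits are
#' already reported subject-forward by the aligner).  Columns
#' containing an ambiguous base produce no call.
#'
#' @param hits data frame of accepted hits carrying `qseqid`, `sseqid`,
#'   `sstart` and aligned strings `qaln`/`saln` — e.g. the UNIQUE rows
#'   of [classify_ends()] renamed via [accepted_hits()], or a filtered
#'   hit frame.
#' @param max_gap_len gap runs longer than this reject the hit (an
#'   upstream contract violation, default 26).
#' @return data frame with `chrom`, `pos` (1-based), `type`
#'   (`SNP`/`INS`/`DEL`), `ref_allele`, `alt_allele`, `indel_length`,
#'   `snp_class` (`TRANSITION`/`TRANSVERSION`/NA) and `read_id`.
#' @export
call_polymorphisms <- function(hits, max_gap_len = 26L) {
  need <- c("qseqid", "sseqid", "sstart", "qaln", "saln")
  stopifnot(all(need %in% names(hits)))
  no_aln <- is.na(hits$qaln) | is.na(hits$saln)
  if (any(no_aln)) {
    warning(sum(no_aln), " hit(s) lack aligned strings; ",
            "variant calling disabled for them")
    hits <- hits[!no_aln, , drop = FALSE]
  }
  out <- list()
  for (i in seq_len(nrow(hits))) {
    q <- strsplit(hits$qaln[i], "")[[1]]
    s <- strsplit(hits$saln[i], "")[[1]]
    if (length(q) != length(s))
      stop("aligned strings of unequal length for ", hits$qseqid[i],
           call. = FALSE)
    qg <- q == "-"; sg <- s == "-"
    ## subject coordinate carried through gaps
    spos <- hits$sstart[i] - 1L + cumsum(!sg)
    ## SNPs
    mm <- which(!qg & !sg & q != s & q %in% c("A", "C", "G", "T") &
                  s %in% c("A", "C", "G", "T"))
    if (length(mm))
      out[[length(out) + 1L]] <- data.frame(
        chrom = hits$sseqid[i], pos = spos[mm], type = "SNP",
        ref_allele = s[mm], alt_allele = q[mm],
        indel_length = NA_integer_,
        read_id = hits$qseqid[i], stringsAsFactors = FALSE)
    ## indel runs
    for (gap_in in c("q", "s")) {
      g <- if (gap_in == "q") qg else sg
      if (!any(g)) next
      r <- rle(g)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      for (j in runs) {
        a <- starts[j]; b <- ends[j]; len <- b - a + 1L
        if (len > max_gap_len)
          stop("gap run of ", len, " bases exceeds the allowed maximum; ",
               "upstream alignment contract violated", call. = FALSE)
        if (a == 1L) next  # cannot anchor a gap at the alignment start
        anchor_pos <- spos[a - 1L]
        anchor <- s[a - 1L]
        if (anchor == "-") next  # adjacent opposite gaps; unanchorable
        if (gap_in == "q") {
          bases <- s[a:b]
          if (any(!bases %in% c("A", "C", "G", "T")) ||
              !anchor %in% c("A", "C", "G", "T")) next
          out[[length(out) + 1L]] <- data.frame(
            chrom = hits$sseqid[i], pos = anchor_pos, type = "INS",
            ref_allele = paste(c(anchor, bases), collapse = ""),
            alt_allele = anchor, indel_length = len,
            read_id = hits$qseqid[i], stringsAsFactors = FALSE)
        } else {
          bases <- q[a:b]
          if (any(!bases %in% c("A", "C", "G", "T")) ||
              !anchor %in% c("A", "C", "G", "T")) next
          out[[length(out) + 1L]] <- data.frame(
            chrom = hits$sseqid[i], pos = anchor_pos, type = "DEL",
            ref_allele = anchor,
            alt_allele = paste(c(anchor, bases), collapse = ""),
            indel_length = len,
            read_id = hits$qseqid[i], stringsAsFactors = FALSE)
        }
      }
    }
  }
  calls <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = integer(), type = character(),
               ref_allele = character(), alt_allele = character(),
               indel_length = integer(), read_id = character(),
               stringsAsFactors = FALSE)
  calls$snp_class <- ifelse(calls$type == "SNP",
                            classify_snp(calls$ref_allele,
                                         calls$alt_allele,
                                         strict = FALSE),
                            NA_character_)
  calls <- calls[order(calls$chrom, calls$pos, calls$type), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Accepted unique hits of classified ends
#'
#' Convenience accessor returning the UNIQUE rows of [classify_ends()]
#' output in the column layout [call_polymorphisms()] expects.
#'
#' @param ends data frame from [classify_ends()].
#' @return data frame with `qseqid`, `sseqid`, `sstart`, `send`,
#'   `strand`, `qaln`, `saln`.
#' @export
accepted_hits <- function(ends) {
  u <- ends[ends$status == "UNIQUE", , drop = FALSE]
  data.frame(qseqid = u$read_id, sseqid = u$chrom, sstart = u$start,
             send = u$end, strand = u$strand, qaln = u$qaln,
             saln = u$saln, stringsAsFactors = FALSE)
}

#' Transition/transversion classification of a SNP
#'
#' Purine-purine (A/G) and pyrimidine-pyrimidine (C/T) substitutions
#' are transitions; all other base pairs are transversions.
#'
#' @param ref,alt single distinct unambiguous bases (vectorised).
#' @param strict reject invalid pairs (default TRUE); with
#'   `strict = FALSE` invalid pairs return NA.
#' @return character vector, `"TRANSITION"` or `"TRANSVERSION"`.
#' @export
classify_snp <- function(ref, alt, strict = TRUE) {
  ref <- toupper(ref); alt <- toupper(alt)
  valid <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  if (strict && !all(valid))
    stop("SNP alleles must be two distinct unambiguous bases",
         call. = FALSE)
  pur <- c("A", "G")
  ti <- (ref %in% pur) == (alt %in% pur)
  ifelse(valid, ifelse(ti, "TRANSITION", "TRANSVERSION"), NA_character_)
}

#' Collapse repeated observations of the same polymorphism
#'
#' Overlapping BESs re-observe the same site; calls identical in
#' (chromosome, position, type, alleles) collapse to one record with
#' merged source read ids.  Distinct alternate alleles at one position
#' are all retained and flagged as conflicting.
#'
#' @param calls data frame from [call_polymorphisms()].
#' @return deduplicated calls with `support` (number of source reads),
#'   `read_id` (comma-merged) and logical `conflict`.
#' @export
dedupe_polymorphisms <- function(calls) {
  if (!nrow(calls)) {
    calls$support <- integer(0); calls$conflict <- logical(0)
    return(calls)
  }
  key <- paste(calls$chrom, calls$pos, calls$type, calls$ref_allele,
               calls$alt_allele, sep = "\r")
  sp <- split(seq_len(nrow(calls)), key)
  first <- vapply(sp, `[`, integer(1), 1L)
  out <- calls[first, , drop = FALSE]
  out$support <- vapply(sp, length, integer(1))
  out$read_id <- vapply(sp, function(i)
    paste(sort(unique(calls$read_id[i])), collapse = ","), character(1))
  site <- paste(out$chrom, out$pos, out$type, sep = "\r")
  out$conflict <- site %in% site[duplicated(site)]
  out <- out[order(out$chrom, out$pos, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Left-normalise indel calls against the reference
#'
#' Shifts an indel's anchor left while the base preceding the gap
#' equals the last base of the gap (the standard VCF normalisation),
#' so that calls and planted truth records in repetitive context
#' compare at identical coordinates.
#'
#' @param calls data frame with `chrom`, `pos`, `type`, `ref_allele`,
#'   `alt_allele` (indel rows are normalised, others pass through).
#' @param genome reference `DNAStringSet`.
#' @return `calls` with normalised `pos`/alleles.
#' @export
normalize_indels <- function(calls, genome) {
  if (!nrow(calls)) return(calls)
  seqs <- as.character(genome)
  for (i in which(calls$type %in% c("INS", "DEL"))) {
    ch <- calls$chrom[i]
    pos <- calls$pos[i]
    gap <- if (calls$type[i] == "INS")
      substring(calls$ref_allele[i], 2) else
      substring(calls$alt_allele[i], 2)
    while (pos > 1) {
      prev <- substr(seqs[[ch]], pos, pos)
      last <- substr(gap, nchar(gap), nchar(gap))
      if (prev != last) break
      gap <- paste0(prev, substr(gap, 1, nchar(gap) - 1))
      pos <- pos - 1L
    }
    anchor <- substr(seqs[[ch]], pos, pos)
    calls$pos[i] <- pos
    if (calls$type[i] == "INS") {
      calls$ref_allele[i] <- paste0(anchor, gap)
      calls$alt_allele[i] <- anchor
    } else {
      calls$ref_allele[i] <- anchor
      calls$alt_allele[i] <- paste0(anchor, gap)
    }
  }
  calls
}

#' Genic annotation of polymorphisms
#'
#' Assigns each call the highest-priority feature class overlapping its
#' position, with priority CDS > 5'/3' UTR > splice junction > intron >
#' intergenic; a splice junction is the first or last two bases of an
#' intron.  Overlapping transcripts are resolved by the same priority
#' across all of them.
#'
#' @param calls data frame with `chrom` and `pos`.
#' @param genes gene-model `GRanges` with a `type` column holding
#'   GFF3-style feature types (`exon`, `CDS`, `five_prime_UTR`,
#'   `three_prime_UTR`, `mRNA`).
#' @return `calls` with an `annotation` column (`CDS`, `UTR5`, `UTR3`,
#'   `SPLICE_JUNCTION`, `INTRON`, `INTERGENIC`).
#' @export
annotate_polymorphisms <- function(calls, genes) {
  if (!nrow(calls)) { calls$annotation <- character(0); return(calls) }
  pos <- GenomicRanges::GRanges(calls$chrom,
                                IRanges::IRanges(calls$pos, calls$pos))
  ann <- rep("INTERGENIC", nrow(calls))
  if (length(genes)) {
    ftype <- S4Vectors::mcols(genes)$type
    sel <- function(t) genes[ftype == t]
    introns <- intron_ranges(genes)
    if (any(GenomicRanges::width(introns) < 1))
      stop("malformed gene model: intron of non-positive length",
           call. = FALSE)
    splice <- c(GenomicRanges::resize(introns, 2L, fix = "start"),
                GenomicRanges::resize(introns, 2L, fix = "end"))
    hit <- function(gr) if (length(gr))
      IRanges::overlapsAny(pos, gr, ignore.strand = TRUE)
    else rep(FALSE, nrow(calls))
    ann[hit(introns)] <- "INTRON"
    ann[hit(splice)] <- "SPLICE_JUNCTION"
    ann[hit(sel("three_prime_UTR"))] <- "UTR3"
    ann[hit(sel("five_prime_UTR"))] <- "UTR5"
    ann[hit(sel("CDS"))] <- "CDS"
  }
  calls$annotation <- ann
  calls
}

## introns = per-transcript gaps between exons
intron_ranges <- function(genes) {
  ftype <- S4Vectors::mcols(genes)$type
  ex <- genes[ftype == "exon"]
  if (!length(ex)) return(GenomicRanges::GRanges())
  parent <- as.character(S4Vectors::mcols(ex)$Parent)
  spl <- GenomicRanges::split(ex, parent)
  tx <- unlist(range(spl))
  unlist(GenomicRanges::psetdiff(tx, spl))
}

#' Polymorphism density by chromosome and chromatin partition
#'
#' Per chromosome and partition (euchromatin, heterochromatin, total):
#' polymorphism count, covered bases (taken from the physical-map
#' coverage rows) and bases per polymorphism (covered / count, nearest
#' integer; empty where the count is zero).  A grand-total row block is
#' appended.
#'
#' @param calls deduplicated calls with `chrom` and `pos`.
#' @param coverage data frame from [coverage_stats()].
#' @param partition partition `GRanges` with `label`.
#' @return data frame with `chromosome`, `partition`, `n_polymorphisms`,
#'   `covered`, `bp_per_polymorphism`.
#' @export
density_stats <- function(calls, coverage, partition) {
  lab <- assign_partition(calls, partition)
  chroms <- unique(coverage$chromosome[coverage$chromosome != "Total"])
  rows <- list()
  for (ch in chroms) {
    for (p in c("E", "H", "total")) {
      n <- if (p == "total") sum(calls$chrom == ch)
           else sum(calls$chrom == ch & lab == p)
      cov <- coverage$covered[coverage$chromosome == ch &
                                coverage$partition == p]
      if (!length(cov)) cov <- NA_real_
      if (!is.na(cov) && cov == 0 && n > 0)
        stop("calls in a partition with zero covered bases: ",
             ch, "/", p, call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = ch, partition = p, n_polymorphisms = n,
        covered = cov,
        bp_per_polymorphism = if (n > 0) round(cov / n) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  tot <- do.call(rbind, lapply(c("E", "H", "total"), function(p) {
    s <- df[df$partition == p, ]
    n <- sum(s$n_polymorphisms); cov <- sum(s$covered)
    data.frame(chromosome = "Total", partition = p, n_polymorphisms = n,
               covered = cov,
               bp_per_polymorphism = if (n > 0) round(cov / n) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out <- rbind(df, tot)
  rownames(out) <- NULL
  out
}

#' Chromatin partition label of each call
#'
#' @param calls data frame with `chrom`, `pos`.
#' @param partition partition `GRanges` with `label`.
#' @return character vector of labels (`E`/`H`, NA outside the
#'   partition).
#' @export
assign_partition <- function(calls, partition) {
  if (!nrow(calls)) return(character(0))
  pos <- GenomicRanges::GRanges(calls$chrom,
                                IRanges::IRanges(calls$pos, calls$pos))
  ov <- GenomicRanges::findOverlaps(pos, partition, select = "first")
  ifelse(is.na(ov), NA_character_, partition$label[ov])
}

#' Summarise a polymorphism density table
#'
#' Runs the density arithmetic over a per-chromosome table of counts
#' and covered bases: bases per polymorphism for the euchromatin,
#' heterochromatin and genome-wide totals, nearest integer.
#'
#' @param tab data frame with columns `chromosome`, `partition`
#'   (`E`/`H`), `n_polymorphisms`, `covered` (per-chromosome rows).
#' @return list with `bp_per_polymorphism_euchromatin`,
#'   `bp_per_polymorphism_heterochromatin`, `bp_per_polymorphism_total`
#'   and the underlying totals.
#' @export
summarize_density_table <- function(tab) {
  stopifnot(all(c("chromosome", "partition", "n_polymorphisms",
                  "covered") %in% names(tab)))
  tot <- function(lab) {
    s <- if (lab == "total") tab else tab[tab$partition == lab, ]
    c(n = sum(as.numeric(s$n_polymorphisms)),
      cov = sum(as.numeric(s$covered)))
  }
  e <- tot("E"); h <- tot("H"); t <- tot("total")
  list(bp_per_polymorphism_euchromatin = round(unname(e["cov"] / e["n"])),
       bp_per_polymorphism_heterochromatin = round(unname(h["cov"] / h["n"])),
       bp_per_polymorphism_total = round(unname(t["cov"] / t["n"])),
       n_total = unname(t["n"]), covered_total = unname(t["cov"]))
}

#' Write polymorphisms as VCF
#'
#' SNPs and indels with INFO tags: TYPE (SNP/INS/DEL, reference-relative
#' indel orientation), SNPCLASS, ANN (genic class), PART (chromatin
#' partition), SUPPORT (number of observing reads) and CONFLICT.
#'
#' @param calls deduplicated, annotated calls.
#' @param file output path (`.vcf`).
#' @param chrom_lengths optional named vector for contig header lines.
#' @return the path written, invisibly.
#' @export
write_variants_vcf <- function(calls, file, chrom_lengths = NULL) {
  gr <- GenomicRanges::GRanges(calls$chrom,
                               IRanges::IRanges(calls$pos,
                                                calls$pos +
                                                  nchar(calls$ref_allele) - 1L))
  if (!is.null(chrom_lengths))
    GenomeInfoDb::seqlengths(gr) <-
      chrom_lengths[GenomeInfoDb::seqlevels(gr)]
  fixed <- S4Vectors::DataFrame(
    REF = Biostrings::DNAStringSet(calls$ref_allele),
    ALT = Biostrings::DNAStringSetList(as.list(calls$alt_allele)),
    QUAL = rep(NA_real_, nrow(calls)),
    FILTER = rep("PASS", nrow(calls)))
  info <- S4Vectors::DataFrame(
    TYPE = calls$type,
    SNPCLASS = ifelse(is.na(calls$snp_class), ".", calls$snp_class),
    ANN = calls$annotation %||% rep(".", nrow(calls)),
    PART = calls$partition %||% rep(".", nrow(calls)),
    SUPPORT = calls$support %||% rep(1L, nrow(calls)),
    CONFLICT = calls$conflict %||% rep(FALSE, nrow(calls)))
  hdr_info <- S4Vectors::DataFrame(
    Number = c("1", "1", "1", "1", "1", "0"),
    Type = c("String", "String", "String", "String", "Integer", "Flag"),
    Description = c("Polymorphism type (reference-relative indels)",
                    "Transition or transversion",
                    "Genic annotation class",
                    "Chromatin partition (E or H)",
                    "Number of reads observing the site",
                    "Conflicting alternate alleles at this site"),
    row.names = c("TYPE", "SNPCLASS", "ANN", "PART", "SUPPORT", "CONFLICT"))
  hdr <- VariantAnnotation::VCFHeader(
    samples = character(0),
    header = IRanges::DataFrameList(
      fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
                                        row.names = "fileformat"),
      INFO = hdr_info))
  vcf <- VariantAnnotation::VCF(rowRanges = gr, fixed = fixed, info = info,
                                collapsed = TRUE)
  VariantAnnotation::header(vcf) <- hdr
  names(vcf) <- rep(".", nrow(calls))
  VariantAnnotation::writeVcf(vcf, file)
  invisible(file)
}
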