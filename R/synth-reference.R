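#' Generate a synthetic reference genome bundle
#'
#' Builds a random multi-chromosome genome with planted repeat-family
#' copies (mutated away from their consensus by the stated divergence),
#' a euchromatin/heterochromatin partition that tiles each chromosome
#' (two distal euchromatin blocks around one central heterochromatin
#' block), and simple multi-exon gene models with CDS/UTR/intron
#' structure.  Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [genome_spec()].
#' @return a list of class `ref_bundle` with elements `genome`
#'   (`DNAStringSet`), `repeat_library` (`DNAStringSet` of family
#'   consensus units), `repeat_annotation` (`GRanges` of planted copies),
#'   `partition` (`GRanges` with a `label` column, `"E"` or `"H"`),
#'   `genes` (`GRanges` of GFF3-style features) and `spec`.
#' @export
generate_reference <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    chroms <- sprintf("chr%02d", seq_len(spec$n_chromosomes))
    lens <- setNames(spec$chrom_length, chroms)

    seqs <- vapply(lens, random_dna, character(1), gc = spec$gc_fraction)

    ## repeat consensus units
    fams <- spec$repeat_families
    lib <- character(0)
    if (nrow(fams) > 0) {
      lib <- vapply(fams$unit_length, random_dna, character(1),
                    gc = spec$gc_fraction)
      names(lib) <- sprintf("repfam%02d", seq_len(nrow(fams)))
    }

    ## place repeat copies, non-overlapping, anywhere on the genome
    rep_ann <- data.frame(chrom = character(), start = integer(),
                          end = integer(), family = character())
    if (nrow(fams) > 0) {
      occ <- lapply(lens, function(L)
        data.frame(start = integer(), end = integer()))
      for (f in seq_len(nrow(fams))) {
        unit <- lib[[f]]
        ul <- fams$unit_length[f]
        for (cp in seq_len(fams$copies[f])) {
          for (try in 1:50) {
            ch <- sample(chroms, 1, prob = lens)
            if (lens[[ch]] <= ul + 2) next
            s <- sample.int(lens[[ch]] - ul, 1)
            o <- occ[[ch]]
            if (!any(s <= o$end & s + ul - 1 >= o$start)) {
              occ[[ch]] <- rbind(o, data.frame(start = s, end = s + ul - 1))
              copy <- mutate_sequence(unit, fams$divergence[f])
              substr(seqs[[ch]], s, s + nchar(copy) - 1) <- copy
              rep_ann <- rbind(rep_ann, data.frame(
                chrom = ch, start = s, end = s + ul - 1,
                family = names(lib)[f]))
              break
            }
          }
        }
      }
    }

    partition <- chromatin_partition(lens, spec$euchromatin_fraction)
    genes <- make_gene_models(lens, spec$gene_density)

    structure(list(
      genome = Biostrings::DNAStringSet(seqs),
      repeat_library = Biostrings::DNAStringSet(lib),
      repeat_annotation = if (nrow(rep_ann))
        GenomicRanges::makeGRangesFromDataFrame(rep_ann,
                                                keep.extra.columns = TRUE)
      else GenomicRanges::GRanges(),
      partition = partition,
      genes = genes,
      spec = spec
    ), class = "ref_bundle")
  })
}

## substitute bases at the given per-base rate (no indels: repeat-family
## divergence is modelled as point divergence from the consensus)
mutate_sequence <- function(x, rate) {
  if (rate <= 0) return(x)
  n <- nchar(x)
  hit <- which(runif(n) < rate)
  if (!length(hit)) return(x)
  v <- strsplit(x, "")[[1]]
  v[hit] <- vapply(v[hit], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  paste(v, collapse = "")
}

#' Euchromatin/heterochromatin partition for a set of chromosomes
#'
#' Two distal euchromatin blocks of equal size flank one central
#' heterochromatin block; the three blocks tile each chromosome exactly.
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param euchromatin_fraction per-chromosome euchromatin fraction
#'   (recycled).
#' @return `GRanges` with a `label` metadata column (`"E"`/`"H"`).
#' @export
chromatin_partition <- function(chrom_lengths, euchromatin_fraction) {
  fr <- rep_len(euchromatin_fraction, length(chrom_lengths))
  out <- lapply(seq_along(chrom_lengths), function(i) {
    L <- chrom_lengths[[i]]
    eu <- round(L * fr[i] / 2)
    blocks <- data.frame(
      chrom = names(chrom_lengths)[i],
      start = c(1, eu + 1, L - eu + 1),
      end = c(eu, L - eu, L),
      label = c("E", "H", "E"))
    blocks[blocks$end >= blocks$start, , drop = FALSE]
  })
  df <- do.call(rbind, out)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               label = df$label)
  GenomeInfoDb::seqlengths(gr) <- chrom_lengths[GenomeInfoDb::seqlevels(gr)]
  gr
}

## Simple multi-exon gene models: 2-6 exons, 5'/3' UTRs inside the
## terminal exons, random strand, non-overlapping genes.
make_gene_models <- function(chrom_lengths, gene_density) {
  feats <- list()
  gid <- 0L
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    n_genes <- max(0L, round(gene_density * L / 1e6))
    if (n_genes == 0) next
    occ <- IRanges::IRanges()
    for (g in seq_len(n_genes)) {
      n_ex <- sample(2:6, 1)
      ex_len <- sample(150:400, n_ex, replace = TRUE)
      in_len <- if (n_ex > 1) sample(100:800, n_ex - 1, replace = TRUE)
                else integer(0)
      span <- sum(ex_len) + sum(in_len)
      placed <- FALSE
      for (try in 1:30) {
        s <- sample.int(max(1L, L - span), 1)
        cand <- IRanges::IRanges(s, s + span - 1)
        if (!any(IRanges::overlapsAny(cand, occ))) {
          occ <- c(occ, cand); placed <- TRUE; break
        }
      }
      if (!placed) next
      gid <- gid + 1L
      strand <- sample(c("+", "-"), 1)
      ex_start <- s + c(0L, cumsum(ex_len[-n_ex] + in_len))
      ex_end <- ex_start + ex_len - 1L
      utr5_len <- min(100L, ex_len[1] - 10L)
      utr3_len <- min(200L, ex_len[n_ex] - 10L)
      if (strand == "-") { tmp <- utr5_len; utr5_len <- utr3_len; utr3_len <- tmp }
      ## on + strand: 5' UTR at the left end of the first exon, 3' UTR at
      ## the right end of the last; swapped lengths already handle '-'
      utr5 <- c(ex_start[1], ex_start[1] + utr5_len - 1L)
      utr3 <- c(ex_end[n_ex] - utr3_len + 1L, ex_end[n_ex])
      cds_start <- utr5[2] + 1L
      cds_end <- utr3[1] - 1L
      gene_id <- sprintf("gene%04d", gid)
      mrna_id <- paste0(gene_id, ".1")
      add <- function(type, starts, ends, id = NA, parent = NA,
                      phase = NA_integer_) {
        data.frame(chrom = ch, start = starts, end = ends, strand = strand,
                   type = type, ID = id, Parent = parent, phase = phase,
                   stringsAsFactors = FALSE)
      }
      cds <- data.frame(start = pmax(ex_start, cds_start),
                        end = pmin(ex_end, cds_end))
      cds <- cds[cds$end >= cds$start, , drop = FALSE]
      ## GFF3 phase: bases to skip to reach the next codon start, walking
      ## the CDS pieces in transcript orientation
      cdslen <- cds$end - cds$start + 1L
      if (strand == "-") cdslen <- rev(cdslen)
      ph <- (3L - (cumsum(c(0L, cdslen[-length(cdslen)])) %% 3L)) %% 3L
      if (strand == "-") ph <- rev(ph)
      feats[[length(feats) + 1L]] <- rbind(
        add("gene", s, s + span - 1L, id = gene_id),
        add("mRNA", s, s + span - 1L, id = mrna_id, parent = gene_id),
        add("exon", ex_start, ex_end,
            id = sprintf("%s.exon%d", mrna_id, seq_len(n_ex)),
            parent = mrna_id),
        add("CDS", cds$start, cds$end,
            id = sprintf("%s.cds%d", mrna_id, seq_len(nrow(cds))),
            parent = mrna_id, phase = ph),
        add(if (strand == "+") "five_prime_UTR" else "three_prime_UTR",
            utr5[1], utr5[2], id = paste0(mrna_id, ".utrL"),
            parent = mrna_id),
        add(if (strand == "+") "three_prime_UTR" else "five_prime_UTR",
            utr3[1], utr3[2], id = paste0(mrna_id, ".utrR"),
            parent = mrna_id))
    }
  }
  if (!length(feats)) return(GenomicRanges::GRanges())
  df <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- df$Parent
  S4Vectors::mcols(gr)$phase <- df$phase
  GenomeInfoDb::seqlengths(gr) <-
    chrom_lengths[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Write a reference bundle to disk
#'
#' Writes `genome.fa`, `repeats.fa`, `genes.gff3`, `partition.tsv`
#' (BED-like, 0-based half-open: chrom, start, end, label) and
#' `repeat_annotation.tsv`.
#'
#' @param bundle a `ref_bundle` from [generate_reference()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ref_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(bundle$genome, file.path(dir, "genome.fa"))
  if (length(bundle$repeat_library))
    Biostrings::writeXStringSet(bundle$repeat_library,
                                file.path(dir, "repeats.fa"))
  if (length(bundle$genes))
    rtracklayer::export(bundle$genes, file.path(dir, "genes.gff3"),
                        format = "gff3")
  write_partition(bundle$partition, file.path(dir, "partition.tsv"))
  if (length(bundle$repeat_annotation)) {
    ra <- as.data.frame(bundle$repeat_annotation)
    write_tsv(data.frame(chrom = ra$seqnames, start = ra$start - 1L,
                         end = ra$end, family = ra$family),
              file.path(dir, "repeat_annotation.tsv"))
  }
  invisible(dir)
}

#' Write / read a chromatin partition table
#'
#' The on-disk format is a BED-like TSV with 0-based half-open
#' coordinates and columns `chrom`, `start`, `end`, `label` (E or H);
#' in memory the partition is a 1-based closed `GRanges`.
#'
#' @param partition `GRanges` with a `label` column.
#' @param file path.
#' @return the file path ([write_partition()]) or a `GRanges`
#'   ([read_partition()]).
#' @export
write_partition <- function(partition, file) {
  df <- as.data.frame(partition)
  write_tsv(data.frame(chrom = df$seqnames, start = df$start - 1L,
                       end = df$end, label = df$label), file)
}

#' @rdname write_partition
#' @export
read_partition <- function(file) {
  df <- read_tsv(file)
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end),
                         label = df$label)
}
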