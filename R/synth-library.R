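#' Simulate a BAC clone library with paired end reads
#'
#' Draws clone inserts from the cultivar genome (insert sizes
#' normal-distributed, resampled if an insert does not fit its
#' chromosome), sequences both insert ends as single-pass reads facing
#' inward on opposite strands, applies substitution errors at the
#' specified per-base rate, and assigns per-base Phred qualities from a
#' read-level mean that declines along the read.  A clone ledger records
#' the true cultivar coordinates of every insert and read.
#'
#' Read identifiers follow the `<clone>.T7` / `<clone>.SP6` convention:
#' the T7 end is the forward (left) end of the insert, the SP6 end the
#' reverse (right) end.
#'
#' @param genome cultivar genome as a `DNAStringSet`, or a
#'   `cultivar_bundle`.
#' @param lspec a [library_spec()].
#' @return a list of class `bac_library` with elements `reads`
#'   (`QualityScaledDNAStringSet`) and `ledger` (data frame with clone
#'   id, cultivar chromosome, insert interval, and per-end read
#'   coordinates and strands; 1-based closed coordinates).
#' @export
simulate_bac_library <- function(genome, lspec) {
  if (inherits(genome, "cultivar_bundle")) genome <- genome$genome
  stopifnot(inherits(genome, "DNAStringSet"), inherits(lspec, "library_spec"))
  lens <- setNames(Biostrings::width(genome), names(genome))
  assert_that(lspec$n_clones > 0, "n_clones must be positive")
  rl <- lspec$read_length_range

  with_seed(lspec$seed, {
    n <- lspec$n_clones
    chrom <- sample(names(lens), n, replace = TRUE, prob = lens)
    insert <- integer(n)
    for (i in seq_len(n)) {
      for (try in 1:100) {
        I <- round(rnorm(1, lspec$insert_mean, lspec$insert_sd))
        if (I > 2 * rl[2] && I < lens[[chrom[i]]]) { insert[i] <- I; break }
      }
      if (insert[i] == 0)
        stop("could not draw an insert fitting chromosome ", chrom[i],
             call. = FALSE)
    }
    start <- vapply(seq_len(n), function(i)
      sample.int(lens[[chrom[i]]] - insert[i] + 1L, 1), integer(1))
    r1len <- sample(rl[1]:rl[2], n, replace = TRUE)
    r2len <- sample(rl[1]:rl[2], n, replace = TRUE)

    clone_id <- sprintf("MTSIM%05d", seq_len(n))
    end <- start + insert - 1L
    r1s <- start; r1e <- start + r1len - 1L
    r2s <- end - r2len + 1L; r2e <- end

    seq1 <- as.character(Biostrings::subseq(genome[chrom],
                                            start = r1s, end = r1e))
    seq2 <- as.character(Biostrings::reverseComplement(
      Biostrings::subseq(genome[chrom], start = r2s, end = r2e)))

    apply_errors <- function(s, rate) {
      if (rate <= 0) return(s)
      vapply(s, function(x) mutate_sequence(x, rate), character(1),
             USE.NAMES = FALSE)
    }
    seq1 <- apply_errors(seq1, lspec$per_base_error)
    seq2 <- apply_errors(seq2, lspec$per_base_error)

    qm <- lspec$quality_model
    qual_for <- function(len) {
      m <- rnorm(1, qm$mean, qm$sd)
      q <- m + qm$decay * (0.5 - (seq_len(len) - 1) / max(1, len - 1)) +
        rnorm(len, 0, qm$noise)
      as.integer(pmin(60, pmax(2, round(q))))
    }
    quals <- lapply(c(r1len, r2len), qual_for)

    ids <- c(paste0(clone_id, ".T7"), paste0(clone_id, ".SP6"))
    dna <- Biostrings::DNAStringSet(setNames(c(seq1, seq2), ids))
    qstr <- vapply(quals, function(q)
      rawToChar(as.raw(q + 33L)), character(1))
    reads <- Biostrings::QualityScaledDNAStringSet(
      dna, Biostrings::PhredQuality(qstr))

    ledger <- data.frame(
      clone_id = clone_id, chrom = chrom,
      insert_start = start, insert_end = end, insert_length = insert,
      read1_id = paste0(clone_id, ".T7"),
      read1_start = r1s, read1_end = r1e, read1_strand = "+",
      read2_id = paste0(clone_id, ".SP6"),
      read2_start = r2s, read2_end = r2e, read2_strand = "-",
      stringsAsFactors = FALSE)

    structure(list(reads = reads, ledger = ledger, lspec = lspec),
              class = "bac_library")
  })
}

#' Write simulated BES reads and their clone ledger
#'
#' Writes `reads.fasta`, `reads.fastq` (Sanger Phred+33) and
#' `clone_ledger.tsv` under `dir`.
#'
#' @param lib a `bac_library` from [simulate_bac_library()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_bac_library <- function(lib, dir) {
  stopifnot(inherits(lib, "bac_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(as(lib$reads, "DNAStringSet"),
                              file.path(dir, "reads.fasta"))
  Biostrings::writeQualityScaledXStringSet(lib$reads,
                                           file.path(dir, "reads.fastq"))
  write_tsv(lib$ledger, file.path(dir, "clone_ledger.tsv"))
  invisible(dir)
}

#' Read FASTQ reads with qualities
#'
#' @param file FASTQ path (Sanger Phred+33).
#' @return a `QualityScaledDNAStringSet`.
#' @export
read_bes_fastq <- function(file) {
  Biostrings::readQualityScaledDNAStringSet(file)
}
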