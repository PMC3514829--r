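#' Specification of a synthetic reference genome
#'
#' Describes a multi-chromosome reference with interleaved repeat families,
#' distal euchromatin blocks flanking a central (pericentromeric)
#' heterochromatin block, and simple multi-exon gene models.  The partition
#' is consumed downstream as a generic interval table, so externally
#' derived euchromatin/heterochromatin boundaries can be substituted.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of each chromosome in bases (recycled).
#' @param gc_fraction GC content in `[0, 1]`.
#' @param repeat_families data frame with columns `unit_length`, `copies`,
#'   `divergence` (mean per-base divergence of planted copies from the
#'   family consensus), one row per family.  May have zero rows.
#' @param euchromatin_fraction fraction of each chromosome assigned to the
#'   two distal euchromatin blocks (half each side); the remainder is one
#'   central heterochromatin block.
#' @param gene_density genes per megabase.
#' @param seed integer seed; all generation is reproducible given the seed.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(n_chromosomes = 2L,
                        chrom_length = 1e6,
                        gc_fraction = 0.36,
                        repeat_families = default_repeat_families(),
                        euchromatin_fraction = 0.4,
                        gene_density = 30,
                        seed = 1L) {
  assert_that(n_chromosomes >= 1, "n_chromosomes must be >= 1")
  assert_that(all(chrom_length > 0), "chrom_length must be positive")
  assert_that(gc_fraction >= 0 && gc_fraction <= 1,
              "gc_fraction must be in [0, 1]")
  assert_that(all(euchromatin_fraction >= 0 & euchromatin_fraction <= 1),
              "euchromatin_fraction must be in [0, 1]")
  if (is.null(repeat_families))
    repeat_families <- data.frame(unit_length = integer(), copies = integer(),
                                  divergence = numeric())
  assert_that(all(c("unit_length", "copies", "divergence") %in%
                    names(repeat_families)),
              "repeat_families needs columns unit_length, copies, divergence")
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = rep_len(as.integer(round(chrom_length)), n_chromosomes),
    gc_fraction = gc_fraction,
    repeat_families = repeat_families,
    euchromatin_fraction = rep_len(euchromatin_fraction, n_chromosomes),
    gene_density = gene_density,
    seed = as.integer(seed)
  ), class = "genome_spec")
}

#' Default repeat families for synthetic genomes
#'
#' Two families loosely shaped like an LTR-retrotransposon fragment and a
#' shorter tandem-prone element: one long low-copy family and one short
#' higher-copy, more diverged family.
#'
#' @return data frame with columns `unit_length`, `copies`, `divergence`.
#' @export
default_repeat_families <- function() {
  data.frame(unit_length = c(400L, 150L),
             copies = c(40L, 80L),
             divergence = c(0.05, 0.10))
}

#' Specification of planted differences between reference and cultivar
#'
#' SNPs and short indels are planted at the given rates (or at enumerated
#' positions), and larger events (inversions, translocations) at explicit
#' coordinates.  Planted features never overlap one another and are kept
#' away from inversion/translocation segments so that every truth record
#' has an unambiguous reference coordinate.
#'
#' Indel type follows the reference-relative convention used throughout
#' the package: `INS` means the reference carries bases the cultivar
#' lacks; `DEL` means the cultivar carries bases the reference lacks.
#'
#' @param snp_rate expected SNPs per base (default one per 3 kb).
#' @param indel_rate expected indels per base.
#' @param indel_geom_p success probability of the truncated-geometric indel
#'   length distribution (lengths capped at `max_indel_len`); the default
#'   makes single-base events dominate.
#' @param max_indel_len hard cap on indel length (default 26).
#' @param ins_fraction fraction of indels that are reference-relative
#'   insertions (`INS`, cultivar lacks bases).
#' @param snp_positions optional data frame `chrom`, `pos` (1-based) of
#'   enumerated SNP positions used instead of `snp_rate` draws.
#' @param inversions data frame `chrom`, `start`, `length` (1-based start).
#' @param translocations data frame `chrom`, `start`, `length`,
#'   `dest_chrom`, `dest_pos`, `inverted`.
#' @param seed integer seed.
#' @return an object of class `mutation_spec`.
#' @export
mutation_spec <- function(snp_rate = 1 / 3000,
                          indel_rate = 1 / 17000,
                          indel_geom_p = 0.9,
                          max_indel_len = 26L,
                          ins_fraction = 0.4,
                          snp_positions = NULL,
                          inversions = NULL,
                          translocations = NULL,
                          seed = 1L) {
  assert_that(snp_rate >= 0 && indel_rate >= 0, "rates must be non-negative")
  assert_that(max_indel_len >= 1 && max_indel_len <= 26,
              "max_indel_len must be in [1, 26]")
  empty_inv <- data.frame(chrom = character(), start = integer(),
                          length = integer())
  empty_tr <- data.frame(chrom = character(), start = integer(),
                         length = integer(), dest_chrom = character(),
                         dest_pos = integer(), inverted = logical())
  structure(list(
    snp_rate = snp_rate, indel_rate = indel_rate,
    indel_geom_p = indel_geom_p,
    max_indel_len = as.integer(max_indel_len),
    ins_fraction = ins_fraction,
    snp_positions = snp_positions,
    inversions = inversions %||% empty_inv,
    translocations = translocations %||% empty_tr,
    seed = as.integer(seed)
  ), class = "mutation_spec")
}

#' Specification of a simulated BAC clone library
#'
#' Inserts are drawn from a normal distribution (default mean 101.3 kb,
#' the average deduced for the emulated library) and sequenced from both
#' ends with Sanger-like single-pass reads facing inward on opposite
#' strands.  The read-length range is a configurable assumption (single
#' pass Sanger reads; no published distribution is emulated).
#'
#' @param n_clones number of clones.
#' @param insert_mean,insert_sd insert size distribution in bases.
#' @param read_length_range integer `c(min, max)` read length in bases.
#' @param per_base_error substitution error probability per base.
#' @param quality_model list with `mean` and `sd` of the read-level mean
#'   Phred score, `decay` (total Phred decline from read start to end) and
#'   `noise` (per-base Phred jitter sd); qualities are clamped to [2, 60].
#' @param seed integer seed.
#' @return an object of class `library_spec`.
#' @export
library_spec <- function(n_clones = 400L,
                         insert_mean = 101300,
                         insert_sd = 10000,
                         read_length_range = c(500L, 900L),
                         per_base_error = 0,
                         quality_model = list(mean = 40, sd = 8,
                                              decay = 15, noise = 3),
                         seed = 1L) {
  assert_that(n_clones > 0, "n_clones must be positive")
  assert_that(per_base_error >= 0 && per_base_error < 1,
              "per_base_error must be in [0, 1)")
  assert_that(insert_mean > max(read_length_range),
              "insert_mean must exceed the maximum read length")
  structure(list(
    n_clones = as.integer(n_clones),
    insert_mean = insert_mean, insert_sd = insert_sd,
    read_length_range = as.integer(read_length_range),
    per_base_error = per_base_error,
    quality_model = quality_model,
    seed = as.integer(seed)
  ), class = "library_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("genome_spec:", x$n_chromosomes, "chromosome(s) of",
      paste(unique(x$chrom_length), collapse = "/"), "bp; GC",
      x$gc_fraction, "\n  euchromatin fraction",
      paste(unique(x$euchromatin_fraction), collapse = "/"),
      "; ", nrow(x$repeat_families), "repeat families;",
      x$gene_density, "genes/Mb; seed", x$seed, "\n")
  invisible(x)
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat("mutation_spec: snp_rate", x$snp_rate, "indel_rate", x$indel_rate,
      "(max len", x$max_indel_len, ")\n ",
      nrow(x$inversions), "inversion(s),",
      nrow(x$translocations), "translocation(s); seed", x$seed, "\n")
  invisible(x)
}

#' @export
print.library_spec <- function(x, ...) {
  cat("library_spec:", x$n_clones, "clones, insert",
      x$insert_mean, "+/-", x$insert_sd, "bp, reads",
      paste(x$read_length_range, collapse = "-"), "bp, error",
      x$per_base_error, "; seed", x$seed, "\n")
  invisible(x)
}
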