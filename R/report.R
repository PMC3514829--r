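#' Library fold coverage of the genome
#'
#' `n_clones * mean_insert / genome_size`, reported to one decimal.
#'
#' @param n_clones number of clones in the library.
#' @param mean_insert_bases mean insert size in bases.
#' @param genome_size_bases genome size in bases.
#' @return fold coverage, one decimal.
#' @export
library_fold_coverage <- function(n_clones, mean_insert_bases,
                                  genome_size_bases) {
  assert_that(genome_size_bases > 0, "genome size must be positive")
  assert_that(n_clones >= 0 && mean_insert_bases > 0,
              "clone count and insert size must be non-negative/positive")
  round(as.numeric(n_clones) * as.numeric(mean_insert_bases) /
          as.numeric(genome_size_bases), 1)
}

#' Selected fraction of reads
#'
#' Percentage of input reads ending up uniquely placed (unique pair
#' ends plus unique ends), one decimal.
#'
#' @param unique_pairs number of unique-pair-end reads.
#' @param unique_ends number of unique-end reads.
#' @param total_reads total reads entering the flow.
#' @return percent, one decimal.
#' @export
selection_fraction <- function(unique_pairs, unique_ends, total_reads) {
  assert_that(total_reads > 0, "total_reads must be positive")
  assert_that(unique_pairs >= 0 && unique_ends >= 0,
              "counts must be non-negative")
  round_pct(100 * (unique_pairs + unique_ends) / total_reads)
}

#' Bundled chromosome coverage summary (SL2.40)
#'
#' Per-chromosome euchromatin/heterochromatin lengths, contig and clone
#' counts and covered bases for the Micro-Tom BES physical map on the
#' SL2.40 tomato pseudomolecules, shipped as a machine-readable table
#' for the summary-arithmetic operations and the worked examples.
#'
#' @return data frame with `chromosome`, `partition`, `length`,
#'   `n_contigs`, `n_clones`, `covered`.
#' @export
published_coverage_table <- function() {
  read_tsv(system.file("extdata", "sl2.40_chromosome_coverage.tsv",
                       package = "besmap", mustWork = TRUE))
}

#' Bundled polymorphism density table (SL2.40)
#'
#' Per-chromosome polymorphism counts and covered bases by chromatin
#' partition for the Micro-Tom vs Heinz 1706 comparison.
#'
#' @return data frame with `chromosome`, `partition`,
#'   `n_polymorphisms`, `covered`.
#' @export
published_density_table <- function() {
  read_tsv(system.file("extdata", "sl2.40_polymorphism_density.tsv",
                       package = "besmap", mustWork = TRUE))
}

#' Bundled mapping summary counts (SL2.40)
#'
#' Headline counts of the Micro-Tom BES mapping (total reads, flow-bin
#' counts, library size, insert statistics, genome size) as a
#' key/value table.
#'
#' @return named numeric vector.
#' @export
published_mapping_summary <- function() {
  df <- read_tsv(system.file("extdata", "sl2.40_mapping_summary.tsv",
                             package = "besmap", mustWork = TRUE))
  setNames(df$value, df$key)
}

#' Configuration for an end-to-end synthetic pipeline run
#'
#' Bundles the three generator specifications with the alignment and
#' placement parameters; every threshold of the extraction flow has a
#' named default.  A single `seed` drives all three generators through
#' derived child seeds.
#'
#' @param gspec,mspec,lspec generator specifications (see
#'   [genome_spec()], [mutation_spec()], [library_spec()]).
#' @param params an [align_params()].
#' @param rules a [placement_rules()].
#' @param qv_threshold mean-Phred read filter threshold.
#' @param repeat_evalue strict E-value cutoff of the repeat screen.
#' @param window,min_support,breakpoint_pad event clustering parameters
#'   (see [cluster_events()]).
#' @param seed master seed; overrides the seeds in the three specs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(gspec = genome_spec(),
                            mspec = mutation_spec(),
                            lspec = library_spec(),
                            params = align_params(),
                            rules = placement_rules(),
                            qv_threshold = 20,
                            repeat_evalue = 1e-50,
                            window = 50000, min_support = 2,
                            breakpoint_pad = 200000,
                            seed = 1L) {
  gspec$seed <- child_seed(seed, 1L)
  mspec$seed <- child_seed(seed, 2L)
  lspec$seed <- child_seed(seed, 3L)
  structure(list(gspec = gspec, mspec = mspec, lspec = lspec,
                 params = params, rules = rules,
                 qv_threshold = qv_threshold,
                 repeat_evalue = repeat_evalue,
                 window = window, min_support = min_support,
                 breakpoint_pad = breakpoint_pad,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full BES analysis on a synthetic genome pair
#'
#' Generates reference and cultivar genomes and a clone library from
#' the config, then runs quality filtering, repeat screening, local
#' alignment, clone placement, contig building and coverage, event
#' detection and polymorphism calling.  When `outdir` is given, all
#' tabular artifacts (hits, placements, contigs, coverage, events,
#' variants VCF, density tables, summary JSON and a parameter log) are
#' written there; re-running with the same config reproduces identical
#' tabular outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory.
#' @return list of class `bes_pipeline` with all intermediate and final
#'   objects (`reference`, `cultivar`, `library`, `ends`, `clones`,
#'   `flow`, `insert_stats`, `contigs`, `coverage`, `signatures`,
#'   `events`, `calls`, `density`, `summary`, `recovery`).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  ref <- generate_reference(config$gspec)
  cult <- derive_cultivar(ref, config$mspec)
  lib <- simulate_bac_library(cult, config$lspec)

  qf <- quality_filter(lib$reads, config$qv_threshold)
  reads <- qf$kept

  if (length(ref$repeat_library)) {
    scr <- screen_repeats(reads, ref$repeat_library,
                          config$repeat_evalue, config$params)
    repeat_ids <- scr$repeat_ids
    query <- scr$nonrepeat
  } else {
    repeat_ids <- character(0)
    query <- reads
  }

  hits <- local_align(query, ref$genome, config$params)
  ends <- classify_ends(hits, names(reads), config$rules, repeat_ids)
  clones <- classify_clones(ends, config$rules)
  flow <- flow_counts(ends, clones)
  ins <- insert_size_stats(clones)

  contigs <- build_contigs(clones)
  lens <- setNames(Biostrings::width(ref$genome), names(ref$genome))
  coverage <- coverage_stats(contigs, ref$partition, lens)

  up <- clones[clones$class == "UNIQUE_PAIR", , drop = FALSE]
  sigs <- discordance_signatures(up, config$rules)
  events <- cluster_events(sigs, config$window, config$min_support,
                           config$breakpoint_pad)
  events <- filter_events(events, sigs, ref$repeat_annotation, hits)

  acc <- accepted_hits(ends)
  calls <- call_polymorphisms(acc, config$params$max_gap_len)
  calls <- dedupe_polymorphisms(calls)
  calls <- normalize_indels(calls, ref$genome)
  calls <- dedupe_after_normalization(calls)
  calls <- annotate_polymorphisms(calls, ref$genes)
  calls$partition <- assign_partition(calls, ref$partition)
  density <- density_stats(calls, coverage, ref$partition)

  recovery <- recovery_metrics(ends, calls, events, cult$truth, ref$genome)

  covT <- function(p) coverage$pct_coverage[coverage$chromosome == "Total" &
                                              coverage$partition == p]
  summary <- list(
    seed = config$seed,
    flow = flow,
    insert = list(n = ins$n, mean = ins$mean, median = ins$median,
                  modal_bin_fraction = ins$modal_bin_fraction),
    library_fold_coverage = library_fold_coverage(
      config$lspec$n_clones, config$lspec$insert_mean, sum(lens)),
    n_contigs = nrow(contigs),
    coverage_pct = list(euchromatin = covT("E"), heterochromatin = covT("H"),
                        total = covT("total")),
    polymorphisms = list(
      total = nrow(calls),
      snps = sum(calls$type == "SNP"),
      transitions = sum(calls$snp_class == "TRANSITION", na.rm = TRUE),
      transversions = sum(calls$snp_class == "TRANSVERSION", na.rm = TRUE),
      indels = sum(calls$type %in% c("INS", "DEL"))),
    bp_per_polymorphism = list(
      euchromatin = density$bp_per_polymorphism[
        density$chromosome == "Total" & density$partition == "E"],
      heterochromatin = density$bp_per_polymorphism[
        density$chromosome == "Total" & density$partition == "H"],
      total = density$bp_per_polymorphism[
        density$chromosome == "Total" & density$partition == "total"]),
    events = list(candidates = nrow(events), pass = sum(events$pass)),
    recovery = recovery)

  out <- structure(list(
    config = config, reference = ref, cultivar = cult, library = lib,
    quality = qf, repeat_ids = repeat_ids, hits = hits, ends = ends,
    clones = clones, flow = flow, insert_stats = ins, contigs = contigs,
    coverage = coverage, signatures = sigs, events = events,
    calls = calls, density = density, summary = summary,
    recovery = recovery), class = "bes_pipeline")
  if (!is.null(outdir)) write_pipeline_artifacts(out, outdir)
  out
}

## a second exact-duplicate collapse; left-normalisation can make two
## differently-anchored observations of one indel identical
dedupe_after_normalization <- function(calls) {
  if (!nrow(calls)) return(calls)
  key <- paste(calls$chrom, calls$pos, calls$type, calls$ref_allele,
               calls$alt_allele, sep = "\r")
  sp <- split(seq_len(nrow(calls)), key)
  first <- vapply(sp, `[`, integer(1), 1L)
  out <- calls[first, , drop = FALSE]
  out$support <- vapply(sp, function(i) sum(calls$support[i]), integer(1))
  out$read_id <- vapply(sp, function(i)
    paste(sort(unique(unlist(strsplit(calls$read_id[i], ",")))),
          collapse = ","), character(1))
  site <- paste(out$chrom, out$pos, out$type, sep = "\r")
  out$conflict <- site %in% site[duplicated(site)]
  out <- out[order(out$chrom, out$pos, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Recovery metrics against a planted truth set
#'
#' Compares pipeline calls with the generator's truth: SNP and indel
#' precision, recall, and the fraction of planted sites covered by
#' accepted unique alignments (a planted site counts as covered when
#' its site interval — the variant plus one flanking base on each side
#' for indels — lies within a single accepted alignment footprint).
#' Planted events are matched to passing events of the corresponding
#' type whose breakpoint regions contain the true junction coordinates.
#'
#' @param ends data frame from [classify_ends()].
#' @param calls deduplicated normalised calls.
#' @param events data frame from [filter_events()].
#' @param truth truth list from [derive_cultivar()].
#' @param genome reference `DNAStringSet` (for truth normalisation).
#' @return list of metrics.
#' @export
recovery_metrics <- function(ends, calls, events, truth, genome) {
  u <- ends[ends$status == "UNIQUE", , drop = FALSE]
  fp <- if (nrow(u))
    GenomicRanges::GRanges(u$chrom, IRanges::IRanges(u$start, u$end))
  else GenomicRanges::GRanges()
  within_fp <- function(chrom, start, end) {
    if (!length(chrom)) return(logical(0))
    g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
    GenomicRanges::countOverlaps(g, fp, type = "within") > 0
  }

  ## SNPs
  ts <- truth$snps
  snp_cov <- within_fp(ts$chrom, ts$pos, ts$pos)
  called_snp <- calls[calls$type == "SNP", , drop = FALSE]
  key <- function(df, alleles = TRUE)
    paste(df$chrom, df$pos, if (alleles) paste(df$ref, df$alt) else "",
          sep = "\r")
  tkey <- paste(ts$chrom, ts$pos, paste(ts$ref, ts$alt), sep = "\r")
  ckey <- paste(called_snp$chrom, called_snp$pos,
                paste(called_snp$ref_allele, called_snp$alt_allele),
                sep = "\r")
  snp_tp <- sum(ckey %in% tkey)
  snp_precision <- if (nrow(called_snp)) snp_tp / nrow(called_snp) else NA
  snp_recall <- if (nrow(ts)) sum(tkey %in% ckey) / nrow(ts) else NA
  snp_covered_fraction <- if (nrow(ts)) mean(snp_cov) else NA

  ## indels: compare left-normalised representations
  ti <- truth$indels
  ti_n <- if (nrow(ti))
    normalize_indels(data.frame(chrom = ti$chrom, pos = ti$pos,
                                type = ti$type,
                                ref_allele = ti$ref_allele,
                                alt_allele = ti$alt_allele,
                                stringsAsFactors = FALSE), genome)
  else ti
  ind_cov <- if (nrow(ti))
    within_fp(ti_n$chrom, ti_n$pos,
              ti_n$pos + ifelse(ti$type == "INS", ti$length, 0L) + 1L)
  else logical(0)
  called_ind <- calls[calls$type %in% c("INS", "DEL"), , drop = FALSE]
  tik <- if (nrow(ti)) paste(ti_n$chrom, ti_n$pos, ti_n$type,
                             ti_n$ref_allele, ti_n$alt_allele, sep = "\r")
         else character(0)
  cik <- paste(called_ind$chrom, called_ind$pos, called_ind$type,
               called_ind$ref_allele, called_ind$alt_allele, sep = "\r")
  ind_tp <- sum(cik %in% tik)
  indel_precision <- if (nrow(called_ind)) ind_tp / nrow(called_ind) else NA
  indel_recall <- if (nrow(ti)) sum(tik %in% cik) / nrow(ti) else NA
  indel_covered_fraction <- if (nrow(ti)) mean(ind_cov) else NA

  ## events
  te <- truth$events
  ev_pass <- events[events$pass, , drop = FALSE]
  match_event <- function(i) {
    t <- te[i, ]
    want <- if (t$type == "inversion") "INVERSION"
      else if (isTRUE(t$inverted) && t$chrom == t$dest_chrom)
        "TRANSLOCATION_INVERSION"
      else if (t$chrom != t$dest_chrom) "TRANSLOCATION"
      else "DISTANCE_ANOMALY"
    bps <- if (t$type == "inversion")
      data.frame(chrom = t$chrom, pos = c(t$start, t$end))
    else data.frame(chrom = c(t$chrom, t$chrom, t$dest_chrom),
                    pos = c(t$start, t$end, t$dest_pos))
    cand <- ev_pass[ev_pass$type == want, , drop = FALSE]
    hit <- vapply(seq_len(nrow(cand)), function(j) {
      e <- cand[j, ]
      all(vapply(seq_len(nrow(bps)), function(b)
        (bps$chrom[b] == e$chromA && bps$pos[b] >= e$regionA_start &&
           bps$pos[b] <= e$regionA_end) ||
        (bps$chrom[b] == e$chromB && bps$pos[b] >= e$regionB_start &&
           bps$pos[b] <= e$regionB_end), logical(1)))
    }, logical(1))
    cand$event_id[hit]
  }
  matched <- lapply(seq_len(nrow(te)), match_event)
  list(snp_precision = snp_precision, snp_recall = snp_recall,
       snp_covered_fraction = snp_covered_fraction,
       n_truth_snps = nrow(ts), n_called_snps = nrow(called_snp),
       indel_precision = indel_precision, indel_recall = indel_recall,
       indel_covered_fraction = indel_covered_fraction,
       n_truth_indels = nrow(ti), n_called_indels = nrow(called_ind),
       n_truth_events = nrow(te),
       events_recovered = sum(lengths(matched) >= 1),
       event_matches = matched,
       n_pass_events = nrow(ev_pass))
}

#' Write all pipeline artifacts
#'
#' @param pipe a `bes_pipeline` from [run_pipeline()].
#' @param outdir output directory (created).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_artifacts <- function(pipe, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_hits(pipe$hits, file.path(outdir, "hits.tsv"))
  write_tsv(pipe$clones, file.path(outdir, "placements.tsv"))
  write_contigs_bed(pipe$contigs, file.path(outdir, "contigs.bed"))
  write_tsv(pipe$coverage, file.path(outdir, "coverage.tsv"))
  write_events_tsv(pipe$events, pipe$signatures,
                   file.path(outdir, "events.tsv"))
  if (nrow(pipe$calls))
    write_variants_vcf(pipe$calls, file.path(outdir, "variants.vcf"),
                       setNames(Biostrings::width(pipe$reference$genome),
                                names(pipe$reference$genome)))
  write_tsv(pipe$density, file.path(outdir, "density.tsv"))
  s <- pipe$summary
  s$recovery$event_matches <- NULL
  jsonlite::write_json(s, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log <- c(
    sprintf("seed\t%d", pipe$config$seed),
    sprintf("qv_threshold\t%g", pipe$config$qv_threshold),
    sprintf("repeat_evalue\t%g", pipe$config$repeat_evalue),
    sprintf("min_identity\t%g", pipe$config$rules$min_identity),
    sprintf("min_coverage\t%g", pipe$config$rules$min_coverage),
    sprintf("evalue_cap\t%g", pipe$config$rules$evalue_cap),
    sprintf("max_pair_distance\t%g", pipe$config$rules$max_pair_distance),
    sprintf("max_gap_len\t%d", pipe$config$params$max_gap_len),
    sprintf("window\t%g", pipe$config$window),
    sprintf("min_support\t%g", pipe$config$min_support))
  writeLines(log, file.path(outdir, "run_parameters.log"))
  invisible(outdir)
}

#' @export
print.bes_pipeline <- function(x, ...) {
  f <- x$flow
  cat("BES pipeline run (seed ", x$config$seed, ")\n",
      "  reads: ", f$total, " (repeat ", f$`repeat`, ", redundant ",
      f$redundant, ", weak ", f$weak, ", no-hit ", f$no_hit,
      ", unique pair ends ", f$unique_pair_ends, ", unique ends ",
      f$unique_ends, ")\n",
      "  selection fraction: ", f$selection_fraction, "%\n",
      "  contigs: ", nrow(x$contigs), "; total coverage ",
      x$summary$coverage_pct$total, "%\n",
      "  polymorphisms: ", x$summary$polymorphisms$total,
      " (SNPs ", x$summary$polymorphisms$snps, ", indels ",
      x$summary$polymorphisms$indels, ")\n",
      "  candidate events passing filters: ", x$summary$events$pass,
      "\n", sep = "")
  invisible(x)
}
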