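#' Derive a cultivar genome from a reference bundle
#'
#' Plants SNPs, short indels (lengths capped at 26 bp), inversions and
#' translocations into the reference and returns the edited genome
#' together with a machine-readable truth set.  Small variants are kept
#' apart from one another and away from inversion/translocation segments
#' so every truth record has an unambiguous reference coordinate; an
#' inverted interval in the cultivar is exactly the reverse complement of
#' the corresponding reference interval.
#'
#' Indel types are reference-relative: `INS` means the reference carries
#' bases the cultivar (and hence any read from it) lacks; `DEL` means the
#' cultivar carries bases the reference lacks.  Indel records are
#' anchored VCF-style at the reference base immediately left of the
#' gap, with `ref_allele`/`alt_allele` giving the anchored allele
#' strings.
#'
#' @param bundle a `ref_bundle` from [generate_reference()].
#' @param mspec a [mutation_spec()].
#' @return a list of class `cultivar_bundle` with elements `genome`
#'   (`DNAStringSet`), `truth` (list of data frames `snps`, `indels`,
#'   `events`) and `mspec`.
#' @export
derive_cultivar <- function(bundle, mspec) {
  stopifnot(inherits(bundle, "ref_bundle"), inherits(mspec, "mutation_spec"))
  seqs <- as.character(bundle$genome)
  lens <- vapply(seqs, nchar, integer(1))
  chroms <- names(seqs)
  guard <- 200L  # keep small variants clear of rearrangement breakpoints

  inv <- mspec$inversions
  tra <- mspec$translocations
  if (nrow(inv)) {
    inv$end <- inv$start + inv$length - 1L
    assert_that(all(inv$chrom %in% chroms) && all(inv$start >= 1) &&
                  all(inv$end <= lens[inv$chrom]),
                "inversion outside chromosome bounds")
  }
  if (nrow(tra)) {
    tra$end <- tra$start + tra$length - 1L
    assert_that(all(tra$chrom %in% chroms) && all(tra$start >= 1) &&
                  all(tra$end <= lens[tra$chrom]),
                "translocation source outside chromosome bounds")
    assert_that(all(tra$dest_chrom %in% chroms) &&
                  all(tra$dest_pos >= 1) &&
                  all(tra$dest_pos <= lens[tra$dest_chrom]),
                "translocation destination outside chromosome bounds")
  }

  ## reference intervals claimed by rearrangements (source segments plus
  ## destination points), used both for overlap validation and to mask
  ## small-variant placement
  sv_df <- rbind(
    if (nrow(inv)) data.frame(chrom = inv$chrom, start = inv$start,
                              end = inv$end),
    if (nrow(tra)) data.frame(chrom = tra$chrom, start = tra$start,
                              end = tra$end),
    if (nrow(tra)) data.frame(chrom = tra$dest_chrom, start = tra$dest_pos,
                              end = tra$dest_pos))
  sv <- if (is.null(sv_df)) GenomicRanges::GRanges()
  else GenomicRanges::GRanges(sv_df$chrom,
                              IRanges::IRanges(sv_df$start, sv_df$end))
  if (length(sv) > 1 &&
      any(GenomicRanges::countOverlaps(sv, sv) > 1))
    stop("planted rearrangement events overlap one another", call. = FALSE)
  sv_mask <- if (length(sv))
    GenomicRanges::resize(sv, GenomicRanges::width(sv) + 2L * guard,
                          fix = "center")
  else GenomicRanges::GRanges()

  with_seed(mspec$seed, {
    ## ---- small variants -------------------------------------------------
    ## blocked-position masks keep sites separated and clear of
    ## rearrangement segments
    blocked <- lapply(chroms, function(ch) logical(lens[[ch]]))
    names(blocked) <- chroms
    if (length(sv_mask)) {
      mdf <- as.data.frame(sv_mask)
      for (i in seq_len(nrow(mdf))) {
        ch <- as.character(mdf$seqnames[i])
        blocked[[ch]][max(1L, mdf$start[i]):min(lens[[ch]], mdf$end[i])] <-
          TRUE
      }
    }
    pick_positions <- function(n_want, min_sep = 30L) {
      out <- data.frame(chrom = character(), pos = integer())
      if (n_want <= 0) return(out)
      pos <- integer(0); chn <- character(0)
      n_try <- 0
      while (length(pos) < n_want && n_try < 20) {
        n_try <- n_try + 1
        need <- n_want - length(pos)
        ch <- sample(chroms, need, replace = TRUE, prob = lens)
        p <- vapply(ch, function(cc)
          sample.int(lens[[cc]] - 60L, 1) + 30L, integer(1))
        for (i in seq_len(need)) {
          lo <- p[i] - min_sep; hi <- p[i] + min_sep
          if (!any(blocked[[ch[i]]][lo:hi])) {
            blocked[[ch[i]]][lo:hi] <<- TRUE
            pos <- c(pos, p[i]); chn <- c(chn, ch[i])
          }
        }
      }
      data.frame(chrom = chn, pos = pos)
    }

    if (!is.null(mspec$snp_positions)) {
      snp_sites <- mspec$snp_positions[, c("chrom", "pos")]
    } else {
      n_snp <- rbinom(1, sum(lens), mspec$snp_rate)
      snp_sites <- pick_positions(n_snp)
    }
    n_indel <- rbinom(1, sum(lens), mspec$indel_rate)
    indel_sites <- pick_positions(n_indel)

    base_at <- function(ch, p) substr(seqs[[ch]], p, p)
    snps <- NULL
    if (nrow(snp_sites)) {
      refb <- mapply(base_at, snp_sites$chrom, snp_sites$pos)
      altb <- vapply(refb, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      snps <- data.frame(chrom = snp_sites$chrom, pos = snp_sites$pos,
                         ref = unname(refb), alt = unname(altb),
                         stringsAsFactors = FALSE)
    } else {
      snps <- data.frame(chrom = character(), pos = integer(),
                         ref = character(), alt = character())
    }

    indels <- data.frame(chrom = character(), pos = integer(),
                         type = character(), length = integer(),
                         ref_allele = character(), alt_allele = character())
    if (nrow(indel_sites)) {
      ln <- 1L + rgeom(nrow(indel_sites), mspec$indel_geom_p)
      while (any(ln > mspec$max_indel_len))
        ln[ln > mspec$max_indel_len] <-
          1L + rgeom(sum(ln > mspec$max_indel_len), mspec$indel_geom_p)
      kind <- ifelse(runif(nrow(indel_sites)) < mspec$ins_fraction,
                     "INS", "DEL")
      anchor <- mapply(base_at, indel_sites$chrom, indel_sites$pos)
      ref_a <- character(nrow(indel_sites))
      alt_a <- character(nrow(indel_sites))
      for (i in seq_len(nrow(indel_sites))) {
        ch <- indel_sites$chrom[i]; p <- indel_sites$pos[i]
        if (kind[i] == "INS") {
          ref_a[i] <- substr(seqs[[ch]], p, p + ln[i])
          alt_a[i] <- anchor[[i]]
        } else {
          ref_a[i] <- anchor[[i]]
          alt_a[i] <- paste0(anchor[[i]], random_dna(ln[i]))
        }
      }
      indels <- data.frame(chrom = indel_sites$chrom, pos = indel_sites$pos,
                           type = kind, length = ln,
                           ref_allele = ref_a, alt_allele = alt_a,
                           stringsAsFactors = FALSE)
    }

    ## ---- assemble edit tables per chromosome ---------------------------
    ## each edit replaces reference interval [start, end] (possibly empty,
    ## end = start - 1) with `repl`
    edits <- lapply(chroms, function(ch)
      data.frame(start = integer(), end = integer(), repl = character()))
    names(edits) <- chroms
    add_edit <- function(ch, start, end, repl) {
      edits[[ch]] <<- rbind(edits[[ch]],
                            data.frame(start = start, end = end, repl = repl,
                                       stringsAsFactors = FALSE))
    }
    if (nrow(snps))
      for (i in seq_len(nrow(snps)))
        add_edit(snps$chrom[i], snps$pos[i], snps$pos[i], snps$alt[i])
    if (nrow(indels))
      for (i in seq_len(nrow(indels))) {
        p <- indels$pos[i]; ln <- indels$length[i]
        if (indels$type[i] == "INS")
          add_edit(indels$chrom[i], p + 1L, p + ln, "")
        else
          add_edit(indels$chrom[i], p + 1L, p,
                   substring(indels$alt_allele[i], 2))
      }

    events <- data.frame(event_id = character(), type = character(),
                         chrom = character(), start = integer(),
                         end = integer(), dest_chrom = character(),
                         dest_pos = integer(), inverted = logical(),
                         stringsAsFactors = FALSE)
    eid <- 0L
    if (nrow(inv))
      for (i in seq_len(nrow(inv))) {
        seg <- substr(seqs[[inv$chrom[i]]], inv$start[i], inv$end[i])
        add_edit(inv$chrom[i], inv$start[i], inv$end[i], revcomp_chr(seg))
        eid <- eid + 1L
        events <- rbind(events, data.frame(
          event_id = sprintf("truth%02d", eid), type = "inversion",
          chrom = inv$chrom[i], start = inv$start[i], end = inv$end[i],
          dest_chrom = NA_character_, dest_pos = NA_integer_,
          inverted = TRUE))
      }
    if (nrow(tra))
      for (i in seq_len(nrow(tra))) {
        seg <- substr(seqs[[tra$chrom[i]]], tra$start[i], tra$end[i])
        if (isTRUE(tra$inverted[i])) seg <- revcomp_chr(seg)
        add_edit(tra$chrom[i], tra$start[i], tra$end[i], "")
        add_edit(tra$dest_chrom[i], tra$dest_pos[i] + 1L, tra$dest_pos[i],
                 seg)
        eid <- eid + 1L
        events <- rbind(events, data.frame(
          event_id = sprintf("truth%02d", eid), type = "translocation",
          chrom = tra$chrom[i], start = tra$start[i], end = tra$end[i],
          dest_chrom = tra$dest_chrom[i], dest_pos = tra$dest_pos[i],
          inverted = isTRUE(tra$inverted[i])))
      }

    ## ---- apply edits ----------------------------------------------------
    cult <- vapply(chroms, function(ch) {
      ed <- edits[[ch]]
      if (!nrow(ed)) return(seqs[[ch]])
      ed <- ed[order(ed$start, ed$end), , drop = FALSE]
      pieces <- character(2 * nrow(ed) + 1)
      cur <- 1L
      for (i in seq_len(nrow(ed))) {
        pieces[2 * i - 1] <- if (ed$start[i] > cur)
          substr(seqs[[ch]], cur, ed$start[i] - 1L) else ""
        pieces[2 * i] <- ed$repl[i]
        cur <- ed$end[i] + 1L
      }
      pieces[2 * nrow(ed) + 1] <- if (cur <= lens[[ch]])
        substr(seqs[[ch]], cur, lens[[ch]]) else ""
      paste(pieces, collapse = "")
    }, character(1))

    structure(list(
      genome = Biostrings::DNAStringSet(setNames(cult, chroms)),
      truth = list(snps = snps, indels = indels, events = events),
      mspec = mspec
    ), class = "cultivar_bundle")
  })
}

#' Write a cultivar truth set to disk
#'
#' Writes `truth_snps.tsv`, `truth_indels.tsv`, `truth_events.tsv` and
#' `cultivar.fa` under `dir`.
#'
#' @param cultivar a `cultivar_bundle` from [derive_cultivar()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cultivar_bundle <- function(cultivar, dir) {
  stopifnot(inherits(cultivar, "cultivar_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(cultivar$genome, file.path(dir, "cultivar.fa"))
  write_tsv(cultivar$truth$snps, file.path(dir, "truth_snps.tsv"))
  write_tsv(cultivar$truth$indels, file.path(dir, "truth_indels.tsv"))
  write_tsv(cultivar$truth$events, file.path(dir, "truth_events.tsv"))
  invisible(dir)
}
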