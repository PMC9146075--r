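## seqio: aligned-FASTA and metadata input, validation, heterozygous-site
## scanning, and random-fill recoding of short deletions.

LOCUS_ALPHABET <- c(BASES, names(IUPAC_HET), "N", "-")

#' Construct a locus alignment
#'
#' A `locus_alignment` holds all specimens' aligned sequences at one
#' locus.  Diploid loci may contain the six two-base IUPAC ambiguity
#' codes (`R Y S W K M`) marking heterozygous sites; haploid loci (e.g.
#' mitochondrial *cytb*) must not.  `-` marks alignment gaps and `N`
#' unknown bases.
#'
#' @param locus Locus name.
#' @param specimen_id Character vector of specimen identifiers.
#' @param seq Character vector of aligned sequences, same length as
#'   `specimen_id`.
#' @param ploidy `"diploid"` or `"haploid"`.
#' @param codon_framed If `TRUE` the aligned length must be divisible
#'   by 3 (protein-coding loci trimmed to whole codons).
#' @return An object of class `locus_alignment`.
#' @export
locus_alignment <- function(locus, specimen_id, seq,
                            ploidy = c("diploid", "haploid"),
                            codon_framed = FALSE) {
  ploidy <- match.arg(ploidy)
  specimen_id <- as.character(specimen_id)
  seq <- toupper(as.character(seq))
  if (length(specimen_id) != length(seq))
    stop("specimen_id and seq lengths differ", call. = FALSE)
  if (anyDuplicated(specimen_id))
    stop("duplicated specimen ids: ",
         paste(unique(specimen_id[duplicated(specimen_id)]), collapse = ", "),
         call. = FALSE)
  lens <- nchar(seq)
  if (length(seq) > 0L && length(unique(lens)) != 1L) {
    bad <- specimen_id[lens != stats::median(lens)][1L]
    stop("ragged alignment at locus ", locus, ": record '", bad,
         "' has length ", nchar(seq[match(bad, specimen_id)]),
         call. = FALSE)
  }
  allowed <- if (ploidy == "haploid") c(BASES, "N", "-") else LOCUS_ALPHABET
  for (i in seq_along(seq)) {
    chars <- strsplit(seq[i], "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% allowed)
    if (length(bad) > 0L)
      stop("disallowed symbol '", chars[bad[1L]], "' in record '",
           specimen_id[i], "' at position ", bad[1L],
           if (ploidy == "haploid" && is_het_code(chars[bad[1L]]))
             " (ambiguity code in haploid locus)" else "",
           call. = FALSE)
  }
  if (codon_framed && length(seq) > 0L && lens[1L] %% 3L != 0L)
    stop("locus ", locus, " marked codon-framed but aligned length ",
         lens[1L], " is not divisible by 3", call. = FALSE)
  structure(
    list(locus = locus, ploidy = ploidy, codon_framed = codon_framed,
         specimen_id = specimen_id, seq = seq),
    class = "locus_alignment"
  )
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("locus_alignment '", x$locus, "': ", length(x$seq), " sequences x ",
      if (length(x$seq)) nchar(x$seq[1L]) else 0L, " bp (", x$ploidy,
      if (x$codon_framed) ", codon-framed" else "", ")\n", sep = "")
  invisible(x)
}

#' @export
length.locus_alignment <- function(x) length(x$seq)

#' Read one locus from an aligned multi-FASTA file
#'
#' Headers (up to the first whitespace) are taken as specimen ids.  All
#' records must have equal aligned length; the alphabet is restricted to
#' `A C G T`, the six two-base IUPAC codes (diploid loci only), `N`
#' and `-`.
#'
#' @inheritParams locus_alignment
#' @param path Path to an aligned multi-FASTA file.
#' @return A [locus_alignment()].
#' @export
read_locus_fasta <- function(path, locus,
                             ploidy = c("diploid", "haploid"),
                             codon_framed = FALSE) {
  ploidy <- match.arg(ploidy)
  if (!file.exists(path))
    stop("locus file not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  locus_alignment(locus, ids, as.character(ss),
                  ploidy = ploidy, codon_framed = codon_framed)
}

#' Write a locus alignment to FASTA
#'
#' @param aln A [locus_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_locus_fasta <- function(aln, path) {
  ss <- Biostrings::BStringSet(aln$seq)
  names(ss) <- aln$specimen_id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Positions of heterozygous sites in a diploid genotype sequence
#'
#' Scans one specimen's sequence for two-base IUPAC ambiguity codes,
#' which record sites where two overlapping peaks were registered in
#' the chromatograms.
#'
#' @param seq A single genotype sequence (character scalar).
#' @param ploidy Ploidy of the locus the sequence comes from; calling
#'   this on a haploid sequence is an error because ambiguity codes are
#'   invalid there.
#' @return A data.frame with columns `pos` (1-based position) and
#'   `code`, in ascending position order; zero rows when the genotype
#'   is fully homozygous.
#' @export
heterozygous_sites <- function(seq, ploidy = "diploid") {
  if (!identical(ploidy, "diploid"))
    stop("heterozygous_sites() is defined for diploid sequences only",
         call. = FALSE)
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  pos <- which(chars %in% names(IUPAC_HET))
  data.frame(pos = pos, code = chars[pos], stringsAsFactors = FALSE)
}

#' Recode short deletions as random absent bases
#'
#' Short ("non-extended") alignment gaps are replaced, column by
#' column, with one nucleotide drawn from the set of bases *not*
#' observed at that column in any ungapped sequence, so the deletion
#' becomes a shared derived state that downstream distance and phasing
#' steps can count like a substitution.  The same fill base is used in
#' every gapped sequence at a column, and the draw is seeded so runs
#' are reproducible.
#'
#' @param aln A [locus_alignment()].
#' @param seed Integer seed controlling the per-column draw.
#' @param max_fill_len Longest gap run (per sequence) that may be
#'   filled; longer runs are an error, as the recoding is only
#'   defensible for short indels.
#' @return A list with elements `alignment` (the filled
#'   [locus_alignment()]; the input is not modified) and `fills`
#'   (data.frame `pos`, `fill`, `observed` recording the provenance of
#'   every filled column).
#' @export
fill_deletion_columns <- function(aln, seed = 1L, max_fill_len = 5L) {
  stopifnot(inherits(aln, "locus_alignment"))
  if (length(aln) == 0L)
    return(list(alignment = aln,
                fills = data.frame(pos = integer(), fill = character(),
                                   observed = character())))
  m <- seq_to_mat(aln$seq)

  # enforce max run length per sequence
  for (i in seq_len(nrow(m))) {
    r <- rle(m[i, ] == "-")
    runs <- r$lengths[r$values]
    if (length(runs) > 0L && max(runs) > max_fill_len)
      stop("gap run of length ", max(runs), " in record '",
           aln$specimen_id[i], "' exceeds max_fill_len = ", max_fill_len,
           call. = FALSE)
  }

  gap_cols <- which(apply(m == "-", 2L, any))
  if (length(gap_cols) == 0L)
    return(list(alignment = aln,
                fills = data.frame(pos = integer(), fill = character(),
                                   observed = character())))

  fills <- with_seed(seed, {
    out <- data.frame(pos = gap_cols, fill = NA_character_,
                      observed = NA_character_)
    for (k in seq_along(gap_cols)) {
      cc <- gap_cols[k]
      col <- m[, cc]
      obs <- character()
      for (sym in unique(col[col != "-"])) {
        if (sym %in% BASES) obs <- c(obs, sym)
        else if (is_het_code(sym)) obs <- c(obs, iupac_decode(sym))
        # 'N' observed contributes nothing: unknown is not evidence
      }
      obs <- sort(unique(obs))
      absent <- setdiff(BASES, obs)
      if (length(absent) == 0L)
        stop("column ", cc, ": all four bases already observed; ",
             "no absent fill base exists", call. = FALSE)
      fill <- if (length(absent) == 1L) absent else sample(absent, 1L)
      m[col == "-", cc] <- fill
      out$fill[k] <- fill
      out$observed[k] <- paste(obs, collapse = "")
    }
    attr(out, "matrix") <- m
    out
  })
  m <- attr(fills, "matrix")
  attr(fills, "matrix") <- NULL
  filled <- locus_alignment(aln$locus, aln$specimen_id, mat_to_seq(m),
                            ploidy = aln$ploidy,
                            codon_framed = aln$codon_framed)
  list(alignment = filled, fills = fills)
}

#' Read the specimen metadata table
#'
#' A tab-separated table with header columns `specimen_id`, `species`,
#' `locality`, and optionally `karyotype` (a Robertsonian formula such
#' as `"2Rb(2.11),1Rb(3.10)"`, empty when not karyotyped) and
#' `karyotype_2n` (the stated diploid number, supporting mosaic ranges
#' such as `"50-51"`).
#'
#' @param path Path to the TSV file.
#' @return A data.frame, one row per specimen.
#' @export
read_specimen_metadata <- function(path) {
  if (!file.exists(path))
    stop("metadata file not found: ", path, call. = FALSE)
  md <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("specimen_id", "species", "locality")
  miss <- setdiff(need, names(md))
  if (length(miss) > 0L)
    stop("metadata is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(md$specimen_id))
    stop("duplicated specimen ids in metadata", call. = FALSE)
  md$locality <- as.integer(md$locality)
  if (!"karyotype" %in% names(md)) md$karyotype <- NA_character_
  md$karyotype[!nzchar(md$karyotype) | is.na(md$karyotype)] <- NA_character_
  md
}
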