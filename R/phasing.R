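## phasing: resolve diploid genotypes into haplotype pairs by
## "subtracting" a reference haplotype drawn from the pool of observed
## homozygotes.  No statistical phasing is attempted: either the
## homozygote pool forces a unique decomposition or the genotype is
## reported unresolved.

#' Pool of haplotypes observed as homozygotes
#'
#' Every genotype with zero heterozygous sites exposes one haplotype
#' directly.  The pool is the set of unique such sequences, with the
#' number and identity of carriers; it is the reference set against
#' which heterozygous genotypes are phased.
#'
#' @param aln A diploid [locus_alignment()] (indels already filled).
#' @return A data.frame with columns `seq`, `freq` (number of
#'   homozygous carriers) and `carriers` (comma-separated specimen
#'   ids), ordered by decreasing frequency then sequence.
#' @export
homozygote_pool <- function(aln) {
  stopifnot(inherits(aln, "locus_alignment"))
  if (aln$ploidy != "diploid")
    stop("homozygote_pool() expects a diploid alignment", call. = FALSE)
  is_hom <- vapply(aln$seq,
                   function(s) nrow(heterozygous_sites(s)) == 0L,
                   logical(1L), USE.NAMES = FALSE)
  seqs <- aln$seq[is_hom]
  ids <- aln$specimen_id[is_hom]
  if (length(seqs) == 0L)
    return(data.frame(seq = character(), freq = integer(),
                      carriers = character(), stringsAsFactors = FALSE))
  tab <- split(ids, seqs)
  pool <- data.frame(
    seq = names(tab),
    freq = lengths(tab),
    carriers = vapply(tab, paste, character(1L), collapse = ","),
    stringsAsFactors = FALSE, row.names = NULL
  )
  pool[order(-pool$freq, pool$seq), , drop = FALSE]
}

#' Subtract a reference haplotype from a heterozygous genotype
#'
#' At every heterozygous (two-base IUPAC) site the complement carries
#' the member of the base pair *not* carried by the reference; at
#' homozygous sites the reference must agree with the genotype and the
#' complement equals it.  `N` in either sequence yields `N` in the
#' complement at that site (unknown stays unknown).
#'
#' @param genotype A genotype sequence (may contain ambiguity codes).
#' @param ref A candidate component haplotype (no ambiguity codes).
#' @return A list with `ok` (logical); on success `seq` holds the
#'   complementary haplotype, on failure `reason` names the first
#'   incompatibility.
#' @export
subtract_haplotype <- function(genotype, ref) {
  g <- strsplit(toupper(genotype), "", fixed = TRUE)[[1L]]
  r <- strsplit(toupper(ref), "", fixed = TRUE)[[1L]]
  if (length(g) != length(r))
    return(list(ok = FALSE, reason = "length mismatch"))
  if (any(r %in% names(IUPAC_HET)))
    return(list(ok = FALSE, reason = "reference contains ambiguity codes"))
  comp <- g
  for (i in seq_along(g)) {
    gi <- g[i]; ri <- r[i]
    if (gi == "N" || ri == "N") { comp[i] <- "N"; next }
    if (is_het_code(gi)) {
      pair <- iupac_decode(gi)
      if (!ri %in% pair)
        return(list(ok = FALSE,
                    reason = paste0("position ", i, ": reference base ", ri,
                                    " not in ambiguity pair ", gi)))
      comp[i] <- setdiff(pair, ri)
    } else {
      if (gi != ri)
        return(list(ok = FALSE,
                    reason = paste0("position ", i, ": reference ", ri,
                                    " conflicts with homozygous ", gi)))
      comp[i] <- gi
    }
  }
  list(ok = TRUE, seq = paste(comp, collapse = ""))
}

#' Phase all genotypes of a locus against the homozygote pool
#'
#' Homozygous genotypes phase trivially (`hap_a == hap_b`).  For each
#' heterozygote every pool haplotype is tried as a reference; among the
#' compatible references, preference is given first to references
#' observed as homozygotes in the focal specimen's own locality, then
#' to references with higher global carrier frequency.  If the
#' preferred references force a single unordered (reference,
#' complement) pair the genotype is phased and any complement absent
#' from the pool is added as a deduced haplotype; otherwise it is
#' reported `unresolved` — ambiguity is never resolved by an arbitrary
#' choice.
#'
#' @param aln A diploid [locus_alignment()] with indels already filled.
#' @param metadata Optional specimen metadata (see
#'   [read_specimen_metadata()]); enables the locality preference.
#' @return An object of class `phased_locus`: a list with `locus`,
#'   `haplotypes` (data.frame `hap_id`, `seq`, `provenance`, `freq`,
#'   `carriers`; deduced haplotypes carry a `*` suffix in their id) and
#'   `phased` (data.frame `specimen_id`, `locus`, `hap_a`, `hap_b`,
#'   `status`, `reference_used`, `note`).  `hap_a`/`hap_b` are reported
#'   in lexicographic order of sequence.
#' @export
phase_all <- function(aln, metadata = NULL) {
  stopifnot(inherits(aln, "locus_alignment"))
  if (aln$ploidy != "diploid")
    stop("phase_all() expects a diploid alignment", call. = FALSE)
  pool <- homozygote_pool(aln)

  locs <- NULL
  if (!is.null(metadata)) {
    locs <- metadata$locality
    names(locs) <- metadata$specimen_id
  }
  carrier_loc <- function(seq) {
    if (is.null(locs)) return(integer())
    ids <- strsplit(pool$carriers[match(seq, pool$seq)], ",")[[1L]]
    unname(locs[ids])
  }

  n <- length(aln)
  out <- data.frame(
    specimen_id = aln$specimen_id, locus = aln$locus,
    hap_a = NA_character_, hap_b = NA_character_,
    status = NA_character_, reference_used = NA_character_,
    note = "", stringsAsFactors = FALSE
  )
  # allele sequences per specimen, filled as we go; NA when unresolved
  allele_a <- rep(NA_character_, n)
  allele_b <- rep(NA_character_, n)
  ref_seq_used <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    g <- aln$seq[i]
    hs <- heterozygous_sites(g)
    if (nrow(hs) == 0L) {
      out$status[i] <- "homozygous"
      allele_a[i] <- allele_b[i] <- g
      next
    }
    if (nrow(pool) == 0L) { out$status[i] <- "unresolved"; next }

    comp_of <- vapply(pool$seq, function(r) {
      s <- subtract_haplotype(g, r)
      if (s$ok) s$seq else NA_character_
    }, character(1L), USE.NAMES = FALSE)
    ok <- which(!is.na(comp_of))
    if (length(ok) == 0L) { out$status[i] <- "unresolved"; next }

    pair_key <- function(idx)
      vapply(idx, function(j)
        paste(sort(c(pool$seq[j], comp_of[j])), collapse = "|"),
        character(1L))

    resolve <- function(idx) {
      # frequency preference within the candidate reference set
      keep <- idx[pool$freq[idx] == max(pool$freq[idx])]
      unique(pair_key(keep))
    }

    # locality preference first, when metadata is available
    cand <- ok
    used_locality <- FALSE
    if (!is.null(locs) && !is.na(locs[aln$specimen_id[i]])) {
      my_loc <- locs[[aln$specimen_id[i]]]
      local <- ok[vapply(ok, function(j)
        my_loc %in% carrier_loc(pool$seq[j]), logical(1L))]
      if (length(local) > 0L) { cand <- local; used_locality <- TRUE }
    }

    pairs <- resolve(cand)
    pairs_freq_only <- resolve(ok)
    if (used_locality && length(pairs) == 1L &&
        length(pairs_freq_only) == 1L && pairs != pairs_freq_only)
      out$note[i] <- "locality_frequency_conflict"

    if (length(pairs) != 1L) { out$status[i] <- "unresolved"; next }

    halves <- strsplit(pairs, "|", fixed = TRUE)[[1L]]
    out$status[i] <- "phased_by_reference"
    allele_a[i] <- halves[1L]
    allele_b[i] <- halves[2L]
    # report the preferred reference actually used (highest frequency
    # among the surviving candidates, ties broken by sequence)
    surv <- cand[pair_key(cand) == pairs]
    surv <- surv[order(-pool$freq[surv], pool$seq[surv])]
    ref_seq_used[i] <- pool$seq[surv[1L]]
  }

  # haplotype table: pool haplotypes first (frequency order), then
  # deduced complements in first-appearance order
  hap_seqs <- pool$seq
  prov <- rep("observed_homozygote", length(hap_seqs))
  for (s in stats::na.omit(c(rbind(allele_a, allele_b)))) {
    if (!s %in% hap_seqs) { hap_seqs <- c(hap_seqs, s); prov <- c(prov, "deduced") }
  }
  width <- max(2L, nchar(length(hap_seqs)))
  hap_id <- sprintf(paste0("%s_H%0", width, "d"), aln$locus,
                    seq_along(hap_seqs))
  hap_id[prov == "deduced"] <- paste0(hap_id[prov == "deduced"], "*")

  id_of <- function(s) hap_id[match(s, hap_seqs)]
  for (i in seq_len(n)) {
    if (is.na(allele_a[i])) next
    ord <- order(c(allele_a[i], allele_b[i]))
    out$hap_a[i] <- id_of(c(allele_a[i], allele_b[i])[ord][1L])
    out$hap_b[i] <- id_of(c(allele_a[i], allele_b[i])[ord][2L])
    if (!is.na(ref_seq_used[i])) out$reference_used[i] <- id_of(ref_seq_used[i])
  }

  # allele-copy frequency and carriers per haplotype
  freq <- integer(length(hap_seqs))
  carriers <- vector("list", length(hap_seqs))
  for (i in seq_len(n)) {
    if (is.na(allele_a[i])) next
    for (s in c(allele_a[i], allele_b[i])) {
      j <- match(s, hap_seqs)
      freq[j] <- freq[j] + 1L
      carriers[[j]] <- union(carriers[[j]], aln$specimen_id[i])
    }
  }

  haplotypes <- data.frame(
    hap_id = hap_id, seq = hap_seqs, provenance = prov, freq = freq,
    carriers = vapply(carriers, function(x)
      paste(x %||% character(), collapse = ","), character(1L)),
    stringsAsFactors = FALSE
  )
  structure(list(locus = aln$locus, haplotypes = haplotypes, phased = out),
            class = "phased_locus")
}

#' @export
print.phased_locus <- function(x, ...) {
  st <- table(x$phased$status)
  cat("phased_locus '", x$locus, "': ", nrow(x$phased), " genotypes (",
      paste(names(st), st, sep = "=", collapse = ", "), "); ",
      nrow(x$haplotypes), " haplotypes (",
      sum(x$haplotypes$provenance == "deduced"), " deduced)\n", sep = "")
  invisible(x)
}

#' Recombine a phased pair back into a genotype sequence
#'
#' Site-wise recombination of the two haplotypes of a phased genotype:
#' equal bases stay, differing bases become the IUPAC code.  Used by
#' the conservation checks; `recombine(hap_a, hap_b)` must reproduce
#' the input genotype of every phased specimen exactly.
#'
#' @param seq_a,seq_b Two haplotype sequences of equal length.
#' @return The genotype sequence.
#' @export
recombine_haplotypes <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1L]]
  stopifnot(length(a) == length(b))
  paste(iupac_encode_vec(a, b), collapse = "")
}
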