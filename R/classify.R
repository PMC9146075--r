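## classify: per-specimen, per-locus genetic calls against
## species-labelled FFRs, fixed-difference diagnosis, and the
## mito-nuclear discordance report.

#' Assign species labels to FFRs by member majority
#'
#' Labels come from the a-priori species column of the metadata
#' (karyotype/morphology), never from the sequences themselves, so the
#' genetic calls stay non-circular.  Ties leave the FFR unlabelled.
#'
#' @param fs An `ffr_set` (see [find_ffrs()], [mt_clades()]).
#' @param metadata Specimen metadata with `specimen_id` and `species`.
#' @return Named character vector: FFR id -> species label (`NA` for
#'   ties or FFRs without labelled members).
#' @export
label_ffrs <- function(fs, metadata) {
  sp <- metadata$species
  names(sp) <- metadata$specimen_id
  out <- stats::setNames(rep(NA_character_, nrow(fs$ffrs)), fs$ffrs$ffr_id)
  for (k in seq_len(nrow(fs$ffrs))) {
    ids <- strsplit(fs$ffrs$members[k], ",")[[1L]]
    labs <- sp[ids[nzchar(ids)]]
    labs <- labs[!is.na(labs) & !labs %in% c("hybrid?", "unknown")]
    if (length(labs) == 0L) next
    tab <- sort(table(labs), decreasing = TRUE)
    if (length(tab) > 1L && tab[1L] == tab[2L]) next # tie -> unlabelled
    out[k] <- names(tab)[1L]
  }
  out
}

#' Genetic call for one phased genotype
#'
#' The two alleles of the genotype are located in the (labelled) FFR
#' partition and compared with the specimen's a-priori species label:
#' both alleles in one FFR of the specimen's own species gives a pure
#' call; one allele in each species' FFR, a heterospecific
#' heterozygote (hybrid pattern); both alleles in the other species'
#' FFR, a heterospecific homozygote (introgression / ancestral
#' polymorphism pattern); alleles in two different FFRs of the same
#' species, an intraspecific lineage heterozygote.
#'
#' @param phased_row One row of the `phased` data.frame of a
#'   `phased_locus`.
#' @param fs The corresponding `ffr_set`.
#' @param ffr_labels Output of [label_ffrs()].
#' @param a_priori_species The specimen's metadata species label.
#' @return A one-row data.frame `specimen_id`, `locus`, `call`,
#'   `ffr_a`, `ffr_b`.
#' @export
call_locus <- function(phased_row, fs, ffr_labels, a_priori_species) {
  res <- data.frame(specimen_id = phased_row$specimen_id,
                    locus = phased_row$locus, call = "unresolved",
                    ffr_a = NA_character_, ffr_b = NA_character_,
                    stringsAsFactors = FALSE)
  if (is.na(phased_row$hap_a) ||
      identical(phased_row$status, "unresolved")) return(res)
  fa <- fs$membership[[phased_row$hap_a]]
  fb <- fs$membership[[phased_row$hap_b]]
  res$ffr_a <- fs$ffrs$ffr_id[min(fa, fb)]
  res$ffr_b <- fs$ffrs$ffr_id[max(fa, fb)]
  la <- unname(ffr_labels[res$ffr_a])
  lb <- unname(ffr_labels[res$ffr_b])
  if (is.na(la) || is.na(lb)) return(res) # unlabelled pool: no call
  res$call <-
    if (la != lb) "heterospecific_heterozygote"
    else if (fa != fb) {
      if (identical(la, a_priori_species))
        "intraspecific_lineage_heterozygote"
      else "heterospecific_homozygote" # both pools of the other species
    }
    else if (identical(la, a_priori_species)) paste0("pure_", la)
    else "heterospecific_homozygote"
  res
}

#' Genetic calls for all specimens at one locus
#'
#' @param phased A `phased_locus`.
#' @param fs Its `ffr_set`.
#' @param metadata Specimen metadata.
#' @return A data.frame of [call_locus()] rows.
#' @export
call_all <- function(phased, fs, metadata) {
  labels <- label_ffrs(fs, metadata)
  sp <- stats::setNames(metadata$species, metadata$specimen_id)
  do.call(rbind, lapply(seq_len(nrow(phased$phased)), function(i) {
    row <- phased$phased[i, , drop = FALSE]
    call_locus(row, fs, labels, unname(sp[row$specimen_id]))
  }))
}

#' Mito-nuclear discordance report
#'
#' Applies a total rule table per specimen:
#' \enumerate{
#'   \item any nuclear locus called `heterospecific_heterozygote` ->
#'     `"interspecific hybrid candidate"`;
#'   \item else any `heterospecific_homozygote` ->
#'     `"introgression/ancestral-polymorphism candidate"` (the two
#'     hypotheses are deliberately not separated);
#'   \item else mitochondrial clade label disagreeing with the majority
#'     nuclear FFR label -> `"mito-nuclear discordant"`;
#'   \item else `"concordant"`.
#' }
#'
#' @param nuclear_calls data.frame of [call_all()] rows over the
#'   nuclear loci.
#' @param mt_fs `ffr_set` from [mt_clades()], or `NULL` when no
#'   mitochondrial locus was scored.
#' @param metadata Specimen metadata (provides a-priori labels and
#'   karyotype formulas for the consistency column).
#' @return A data.frame, one row per specimen: `specimen_id`,
#'   `a_priori_species`, `mt_clade_label`, per-rule evidence counts,
#'   `karyotype_consistent`, `flag`.
#' @export
discordance_report <- function(nuclear_calls, mt_fs, metadata) {
  sp <- stats::setNames(metadata$species, metadata$specimen_id)
  mt_label <- rep(NA_character_, nrow(metadata))
  names(mt_label) <- metadata$specimen_id
  if (!is.null(mt_fs)) {
    labels <- label_ffrs(mt_fs, metadata)
    mem <- ffr_membership_by_specimen(mt_fs)
    for (s in names(mem)) mt_label[s] <- unname(labels[mem[[s]][1L]])
  }
  kc <- if ("karyotype_2n" %in% names(metadata))
    karyotype_consistency(metadata) else NULL

  out <- do.call(rbind, lapply(metadata$specimen_id, function(s) {
    calls <- nuclear_calls$call[nuclear_calls$specimen_id == s]
    n_het <- sum(calls == "heterospecific_heterozygote")
    n_hom <- sum(calls == "heterospecific_homozygote")
    # majority nuclear species label over informative calls
    nuc_sp <- character()
    rows <- nuclear_calls[nuclear_calls$specimen_id == s, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      cl <- rows$call[i]
      if (startsWith(cl, "pure_")) nuc_sp <- c(nuc_sp, sub("^pure_", "", cl))
      else if (cl == "heterospecific_homozygote")
        nuc_sp <- c(nuc_sp, setdiff(unique(sp), sp[s])[1L])
      else if (cl == "intraspecific_lineage_heterozygote")
        nuc_sp <- c(nuc_sp, unname(sp[s]))
    }
    nuc_major <- if (length(nuc_sp) == 0L) NA_character_ else {
      tab <- sort(table(nuc_sp), decreasing = TRUE)
      if (length(tab) > 1L && tab[1L] == tab[2L]) NA_character_
      else names(tab)[1L]
    }
    flag <-
      if (n_het > 0L) "interspecific hybrid candidate"
      else if (n_hom > 0L) "introgression/ancestral-polymorphism candidate"
      else if (!is.na(mt_label[s]) && !is.na(nuc_major) &&
               mt_label[s] != nuc_major) "mito-nuclear discordant"
      else "concordant"
    data.frame(specimen_id = s, a_priori_species = unname(sp[s]),
               mt_clade_label = unname(mt_label[s]),
               n_heterospecific_het = n_het,
               n_heterospecific_hom = n_hom,
               nuclear_majority = nuc_major,
               karyotype_consistent =
                 if (is.null(kc)) NA
                 else kc$consistent[match(s, kc$specimen_id)],
               flag = flag, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fixed nucleotide differences between two allele groups
#'
#' Aligned positions at which every allele of group A carries one base
#' and every allele of group B another; alleles carrying `N` (or a
#' gap) at a site are excluded from that site's tally.
#'
#' @param seqs_a,seqs_b Character vectors of aligned haplotype
#'   sequences (both non-empty).
#' @return Integer vector of 1-based diagnostic positions.
#' @export
fixed_differences <- function(seqs_a, seqs_b) {
  stopifnot(length(seqs_a) > 0L, length(seqs_b) > 0L)
  ma <- seq_to_mat(seqs_a)
  mb <- seq_to_mat(seqs_b)
  if (ncol(ma) != ncol(mb))
    stop("alignments have different lengths", call. = FALSE)
  out <- integer()
  for (p in seq_len(ncol(ma))) {
    ua <- unique(ma[, p]); ua <- ua[ua %in% BASES]
    ub <- unique(mb[, p]); ub <- ub[ub %in% BASES]
    if (length(ua) == 1L && length(ub) == 1L && ua != ub)
      out <- c(out, p)
  }
  out
}
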