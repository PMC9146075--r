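## simdata: synthetic multilocus diploid cohorts with truth tables.
## The generator emulates the regime the delimitation procedure
## presumes: two species-level allele pools per locus separated by a
## handful of fixed substitutions, shallow star-shaped polymorphism
## within pools (sampled allele copies are the pool centre plus a
## Poisson number of private singleton mutations, infinite-sites
## style), a second conspecific lineage distinguished by a short
## deletion, and a haploid mitochondrial locus whose clade can
## disagree with the nuclear pools.

#' Simulation configuration
#'
#' Defaults mirror the empirical study system: three loci of lengths
#' 1143 (haploid mitochondrial), 1404 and 970 bp; nuclear pools
#' separated by a Poisson(3) number of fixed differences with a floor
#' of 3 (the delimitation regime presumes pools separated by at least
#' three diagnosable substitutions, so a smaller divergence is never
#' realised); a second
#' conspecific lineage "E" carrying a 3-nt deletion near the start of
#' the 970-bp locus; shallow within-pool polymorphism (singleton
#' variants, ~0.1 private mutations per sampled allele copy — the
#' near-monomorphic pools typical of these markers); and a
#' mitochondrial divergence of an expected 20 substitutions
#' (sibling-species scale, ~2%).
#'
#' @param seed Integer master seed; all randomness derives from it.
#' @param loci Named list of per-locus settings: `length`, `ploidy`,
#'   `fixed_diffs` (expected interspecies fixed differences),
#'   `intra_fixed_diffs` (expected W-vs-E fixed differences, diploid
#'   loci only) and `deletion` (`NULL` or `list(length, start)` for a
#'   deletion carried by the E lineage).
#' @param n_pure_a,n_pure_b Pure specimens of species A (two W alleles)
#'   and B (two T alleles).
#' @param n_pure_a_e Pure species-A specimens of the E conspecific
#'   lineage (two E alleles), anchoring the E pool with homozygotes.
#' @param n_f1 F1 hybrids: one W and one T allele, species-A label.
#' @param n_introgressed Species-A specimens whose two alleles both
#'   come from the B pool at every nuclear locus.
#' @param n_intra_het Species-A specimens heterozygous between the W
#'   and E conspecific lineages.
#' @param n_mt_discordant Pure species-A specimens carrying a B-clade
#'   mitochondrial haplotype.
#' @param species Length-2 named character vector: labels for species
#'   A and B.
#' @param mut_per_allele Expected number of private mutations on each
#'   sampled allele copy (star genealogy, one tip per copy).  Must be
#'   smaller than every locus' expected divergence.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       loci = list(
                         cytb = list(length = 1143L, ploidy = "haploid",
                                     fixed_diffs = 20, deletion = NULL),
                         IRBP = list(length = 1404L, ploidy = "diploid",
                                     fixed_diffs = 3,
                                     intra_fixed_diffs = 3,
                                     deletion = NULL),
                         XIST = list(length = 970L, ploidy = "diploid",
                                     fixed_diffs = 3,
                                     intra_fixed_diffs = 3,
                                     deletion = list(length = 3L,
                                                     start = 8L))
                       ),
                       n_pure_a = 10L, n_pure_b = 10L, n_pure_a_e = 0L,
                       n_f1 = 0L, n_introgressed = 0L, n_intra_het = 0L,
                       n_mt_discordant = 0L,
                       species = c(a = "alaicus", b = "tancrei"),
                       mut_per_allele = 0.1) {
  counts <- c(n_pure_a, n_pure_b, n_pure_a_e, n_f1, n_introgressed,
              n_intra_het, n_mt_discordant)
  if (any(counts < 0L)) stop("composition counts must be >= 0",
                             call. = FALSE)
  if (n_mt_discordant > n_pure_a)
    stop("n_mt_discordant cannot exceed n_pure_a", call. = FALSE)
  div <- vapply(loci, function(lc) lc$fixed_diffs, numeric(1L))
  if (any(div < mut_per_allele) ||
      (mut_per_allele > 0 && any(div <= mut_per_allele)))
    stop("expected divergence must exceed within-pool diversity ",
         "(fixed_diffs > mut_per_allele at every locus)", call. = FALSE)
  structure(list(seed = as.integer(seed), loci = loci,
                 n_pure_a = n_pure_a, n_pure_b = n_pure_b,
                 n_pure_a_e = n_pure_a_e, n_f1 = n_f1,
                 n_introgressed = n_introgressed,
                 n_intra_het = n_intra_het,
                 n_mt_discordant = n_mt_discordant,
                 species = species, mut_per_allele = mut_per_allele),
            class = "sim_config")
}

# Number of fixed differences between two pools: Poisson(lambda) with
# a guaranteed floor.  The delimitation regime presumes pools separated
# by at least `min_fixed` (default 3) diagnosable substitutions, so the
# generator never realises a divergence below the floor.
rdivergence <- function(lambda, min_fixed = 3L) {
  if (lambda == 0) return(0L)
  max(min_fixed, stats::rpois(1L, lambda))
}

# mutate character-vector sequence at `pos` to different random bases
mutate_at <- function(chars, pos) {
  for (p in pos) chars[p] <- sample(setdiff(BASES, chars[p]), 1L)
  chars
}

#' Simulate the pool centre haplotypes of one locus
#'
#' Draws a random ancestral sequence and derives the central haplotype
#' of each allele pool: for diploid loci, `W` (species A, identical to
#' the ancestor), `E` (a second species-A lineage, separated from W by
#' a conditioned-Poisson number of fixed substitutions and optionally
#' carrying a deletion written as a gap run) and `T` (species B,
#' separated from the ancestor by the configured fixed differences);
#' for haploid loci, clade centres `A` and `B`.  Within-pool singleton
#' variants are added per sampled allele copy by [make_cohort()].
#'
#' Randomness is taken from the current RNG stream; seed it with
#' [with_seed()] or via [make_cohort()].
#'
#' @param cfg A [sim_config()].
#' @param locus Locus name (must be a name of `cfg$loci`).
#' @return A list with `pools` (named character vector of pool centre
#'   sequences), `truth` (`fixed_at` positions of A-vs-B fixed
#'   differences, `intra_fixed_at` for W-vs-E, `deletion_cols`) and
#'   `avoid` (positions private mutations must not hit, preserving the
#'   infinite-sites regime at diagnostic columns).
#' @export
simulate_locus <- function(cfg, locus) {
  lc <- cfg$loci[[locus]]
  if (is.null(lc)) stop("unknown locus: ", locus, call. = FALSE)
  L <- lc$length
  anc <- sample(BASES, L, replace = TRUE)

  k_fixed <- rdivergence(lc$fixed_diffs, lc$min_fixed %||% 3L)
  fixed_at <- if (k_fixed > 0L) sort(sample(L, k_fixed)) else integer()
  b_center <- mutate_at(anc, fixed_at)

  if (lc$ploidy == "haploid") {
    return(list(pools = c(A = paste(anc, collapse = ""),
                          B = paste(b_center, collapse = "")),
                truth = list(fixed_at = fixed_at,
                             intra_fixed_at = integer(),
                             deletion_cols = integer()),
                avoid = fixed_at))
  }

  intra <- lc$intra_fixed_diffs %||% 0
  del <- lc$deletion
  del_cols <- if (!is.null(del)) del$start + seq_len(del$length) - 1L
              else integer()
  k_intra <- rdivergence(intra, lc$min_fixed %||% 3L)
  intra_at <- if (k_intra > 0L)
    sort(sample(setdiff(seq_len(L), c(fixed_at, del_cols)), k_intra))
  else integer()
  e_center <- mutate_at(anc, intra_at)
  if (length(del_cols) > 0L) e_center[del_cols] <- "-"

  list(pools = c(W = paste(anc, collapse = ""),
                 E = paste(e_center, collapse = ""),
                 T = paste(b_center, collapse = "")),
       truth = list(fixed_at = fixed_at, intra_fixed_at = intra_at,
                    deletion_cols = del_cols),
       avoid = c(fixed_at, intra_at, del_cols))
}

# sample one allele copy: pool centre plus Poisson(lambda) private
# mutations at non-diagnostic positions
draw_copy <- function(center_chars, lambda, avoid) {
  k <- stats::rpois(1L, lambda)
  if (k == 0L) return(center_chars)
  free <- setdiff(seq_along(center_chars), avoid)
  mutate_at(center_chars, sample(free, min(k, length(free))))
}

#' Generate a synthetic cohort with truth tables
#'
#' Assembles diploid genotypes per specimen class — pure (two
#' same-pool alleles), F1 (one W + one T), introgressed (two T alleles
#' under a species-A label), intraspecific W/E heterozygote — encodes
#' heterozygous sites as IUPAC codes, and assigns the haploid
#' mitochondrial locus by species with optional discordant exceptions.
#' Deletion gap runs in E alleles are recoded to a random absent base
#' (the same convention [fill_deletion_columns()] applies to real
#' alignments) *before* genotype encoding, because a heterozygous
#' indel cannot be represented in a single IUPAC-coded Sanger
#' consensus; emitted alignments are therefore gap-free and the raw
#' gapped centre haplotype is kept in the truth table.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_cohort`: `alignments` (named list of
#'   [locus_alignment()]), `metadata` (data.frame with karyotype
#'   formulas matching each class), `truth` (per-specimen class, mt
#'   assignment, and per-locus pool centres, fills and true allele
#'   sequences).
#' @export
make_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_pure_a + cfg$n_pure_b + (cfg$n_pure_a_e %||% 0L) +
      cfg$n_f1 + cfg$n_introgressed + cfg$n_intra_het
    if (n == 0L) stop("empty cohort", call. = FALSE)
    cls <- c(rep("pure_a", cfg$n_pure_a), rep("pure_b", cfg$n_pure_b),
             rep("pure_a_e", cfg$n_pure_a_e %||% 0L),
             rep("f1", cfg$n_f1), rep("introgressed", cfg$n_introgressed),
             rep("intra_het", cfg$n_intra_het))
    ids <- sprintf("S%03d", seq_len(n))
    sp_a <- cfg$species[["a"]]; sp_b <- cfg$species[["b"]]
    species <- ifelse(cls == "pure_b", sp_b, sp_a)
    # localities: species A in 1-3, species B in 4-6, mixed-ancestry
    # classes at the contact locality 3
    locality <- integer(n)
    locality[cls == "pure_a"] <- rep_len(1:3, sum(cls == "pure_a"))
    locality[cls == "pure_b"] <- rep_len(4:6, sum(cls == "pure_b"))
    locality[cls == "pure_a_e"] <- rep_len(2:3, sum(cls == "pure_a_e"))
    locality[cls %in% c("f1", "introgressed", "intra_het")] <- 3L

    karyo <- ifelse(cls == "pure_b", "",
             ifelse(cls == "f1", "1Rb(2.11)", "2Rb(2.11)"))
    karyo_2n <- ifelse(cls == "pure_b", "54",
                ifelse(cls == "f1", "53", "52"))
    metadata <- data.frame(specimen_id = ids, species = species,
                           locality = locality, karyotype = karyo,
                           karyotype_2n = karyo_2n,
                           stringsAsFactors = FALSE)

    mt_discordant <- which(cls == "pure_a")[seq_len(cfg$n_mt_discordant)]

    alignments <- list()
    truth <- list(class = stats::setNames(cls, ids),
                  mt_discordant = ids[mt_discordant], loci = list())

    for (locus in names(cfg$loci)) {
      lc <- cfg$loci[[locus]]
      sim <- simulate_locus(cfg, locus)
      centers <- lapply(sim$pools, function(s)
        strsplit(s, "", fixed = TRUE)[[1L]])

      if (lc$ploidy == "haploid") {
        seqs <- character(n)
        for (i in seq_len(n)) {
          pool <- if (species[i] == sp_b) "B" else "A"
          if (i %in% mt_discordant) pool <- "B"
          seqs[i] <- paste(draw_copy(centers[[pool]], cfg$mut_per_allele,
                                     sim$avoid), collapse = "")
        }
        alignments[[locus]] <- locus_alignment(locus, ids, seqs,
                                               ploidy = "haploid")
        truth$loci[[locus]] <- list(pools = sim$pools, truth = sim$truth,
                                    alleles = NULL, fills = NULL)
        next
      }

      # recode the E-lineage deletion exactly as the analysis
      # convention does, so heterozygous genotypes can be IUPAC-encoded
      raw_pools <- sim$pools
      fills <- NULL
      if (length(sim$truth$deletion_cols) > 0L) {
        tmp <- locus_alignment(locus, names(sim$pools),
                               unname(sim$pools), ploidy = "diploid")
        fl <- fill_deletion_columns(tmp, seed = sample.int(2^31 - 1, 1L))
        fills <- fl$fills
        for (p in names(sim$pools))
          centers[[p]] <- strsplit(
            fl$alignment$seq[match(p, fl$alignment$specimen_id)],
            "", fixed = TRUE)[[1L]]
      }

      pool_of <- list(
        pure_a = c("W", "W"), pure_b = c("T", "T"),
        pure_a_e = c("E", "E"), f1 = c("W", "T"),
        introgressed = c("T", "T"), intra_het = c("W", "E"))
      al_a <- character(n); al_b <- character(n)
      for (i in seq_len(n)) {
        pp <- pool_of[[cls[i]]]
        al_a[i] <- paste(draw_copy(centers[[pp[1L]]], cfg$mut_per_allele,
                                   sim$avoid), collapse = "")
        al_b[i] <- paste(draw_copy(centers[[pp[2L]]], cfg$mut_per_allele,
                                   sim$avoid), collapse = "")
      }
      geno <- vapply(seq_len(n), function(i)
        recombine_haplotypes(al_a[i], al_b[i]), character(1L))
      alignments[[locus]] <- locus_alignment(
        locus, ids, geno, ploidy = "diploid",
        codon_framed = isTRUE(lc$codon_framed))
      filled_pools <- vapply(centers, paste, character(1L), collapse = "")
      truth$loci[[locus]] <- list(
        pools = filled_pools, raw_pools = raw_pools, truth = sim$truth,
        fills = fills,
        alleles = data.frame(specimen_id = ids, allele_a = al_a,
                             allele_b = al_b, stringsAsFactors = FALSE))
    }
    structure(list(alignments = alignments, metadata = metadata,
                   truth = truth, config = cfg),
              class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort: ", nrow(x$metadata), " specimens x ",
      length(x$alignments), " loci (classes: ",
      paste(names(table(x$truth$class)), table(x$truth$class),
            sep = "=", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits `locus_<name>.fasta` per locus, `metadata.tsv`, and
#' `truth.json` (pool centres, class labels, true allele sequences,
#' fill provenance and the master seed).
#'
#' @param cohort A [make_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of files written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (locus in names(cohort$alignments)) {
    f <- file.path(dir, paste0("locus_", locus, ".fasta"))
    write_locus_fasta(cohort$alignments[[locus]], f)
    files[paste0("fasta_", locus)] <- f
  }
  mf <- file.path(dir, "metadata.tsv")
  utils::write.table(cohort$metadata, mf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files["metadata"] <- mf
  tf <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(seed = cohort$config$seed, class = as.list(cohort$truth$class),
         mt_discordant = cohort$truth$mt_discordant,
         loci = cohort$truth$loci),
    tf, auto_unbox = TRUE, digits = NA, null = "null")
  files["truth"] <- tf
  invisible(files)
}
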