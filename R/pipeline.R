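## cli_report: end-to-end orchestration.  run_pipeline() chains
## seqio -> phasing -> network -> classify and writes every artifact
## plus a checksummed manifest; a thin optparse front-end lives in
## inst/cli/haploweb.R.

#' Pipeline run configuration
#'
#' @param loci Named list; each element `list(path =, ploidy =,
#'   codon_framed = FALSE)` describing one aligned multi-FASTA.
#' @param metadata Path to the specimen metadata TSV.
#' @param out_dir Output directory.
#' @param fill_seed Seed for [fill_deletion_columns()].
#' @param max_arc_steps Arc span limit for [find_ffrs()].
#' @param mt_step_threshold Edge cut for [mt_clades()].
#' @param consensus_threshold Function of L (loci scored) giving the
#'   consensus linkage threshold; default majority.
#' @return A list of class `run_config`.
#' @export
run_config <- function(loci, metadata, out_dir,
                       fill_seed = 1L, max_arc_steps = 2L,
                       mt_step_threshold = 5L,
                       consensus_threshold = function(L) ceiling(L / 2)) {
  for (nm in names(loci)) {
    if (!file.exists(loci[[nm]]$path))
      stop("locus file for '", nm, "' not found: ", loci[[nm]]$path,
           call. = FALSE)
  }
  if (!file.exists(metadata))
    stop("metadata file not found: ", metadata, call. = FALSE)
  if (max_arc_steps < 0L || mt_step_threshold <= 0L)
    stop("thresholds must be positive", call. = FALSE)
  structure(list(loci = loci, metadata = metadata, out_dir = out_dir,
                 fill_seed = as.integer(fill_seed),
                 max_arc_steps = as.integer(max_arc_steps),
                 mt_step_threshold = as.integer(mt_step_threshold),
                 consensus_threshold = consensus_threshold),
            class = "run_config")
}

#' Run the full multilocus delimitation pipeline
#'
#' For every diploid locus: read and validate, fill short deletions,
#' phase against the homozygote pool, build the haploweb, delimit
#' FFRs, and call each specimen.  Haploid loci contribute their clade
#' partition instead.  Loci are then combined into the conspecificity
#' matrix and the per-specimen discordance report.  All artifacts are
#' written under `cfg$out_dir` and listed, with MD5 checksums, in
#' `manifest.json`; two runs with the same config and seed produce
#' byte-identical text artifacts.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the in-memory results (`phased`,
#'   `webs`, `ffrs`, `calls`, `consp`, `report`) and the `manifest`
#'   data.frame.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  md <- read_specimen_metadata(cfg$metadata)
  artifacts <- character()
  add <- function(path) { artifacts <<- c(artifacts, path); path }

  phased <- list(); webs <- list(); ffrs <- list()
  calls <- NULL; fills <- list()
  for (nm in names(cfg$loci)) {
    lc <- cfg$loci[[nm]]
    message("[", nm, "] reading ", lc$path)
    aln <- read_locus_fasta(lc$path, nm, ploidy = lc$ploidy,
                            codon_framed = isTRUE(lc$codon_framed))
    fl <- fill_deletion_columns(aln, seed = cfg$fill_seed)
    aln <- fl$alignment
    if (nrow(fl$fills) > 0L) fills[[nm]] <- fl$fills

    if (lc$ploidy == "haploid") {
      ffrs[[nm]] <- mt_clades(aln, max_steps = cfg$mt_step_threshold)
      next
    }

    ph <- phase_all(aln, md)
    phased[[nm]] <- ph
    utils::write.table(ph$phased,
                       add(file.path(cfg$out_dir,
                                     paste0("phased_", nm, ".tsv"))),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    hap <- ph$haplotypes
    ss <- Biostrings::BStringSet(hap$seq)
    names(ss) <- hap$hap_id # deduced ids already carry the '*' suffix
    Biostrings::writeXStringSet(
      ss, add(file.path(cfg$out_dir, paste0("haplotypes_", nm, ".fasta"))))

    web <- build_haploweb(ph)
    webs[[nm]] <- web
    write_haploweb(
      web,
      graphml = add(file.path(cfg$out_dir,
                              paste0("haploweb_", nm, ".graphml"))),
      dot = add(file.path(cfg$out_dir, paste0("haploweb_", nm, ".dot"))))

    fs <- find_ffrs(web, ph, max_arc_steps = cfg$max_arc_steps)
    ffrs[[nm]] <- fs
    utils::write.table(fs$ffrs,
                       add(file.path(cfg$out_dir,
                                     paste0("ffr_", nm, ".tsv"))),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    calls <- rbind(calls, call_all(ph, fs, md))
  }

  consp <- conspecificity(ffrs, md$specimen_id,
                          threshold = cfg$consensus_threshold)
  cm <- as.data.frame(consp$matrix)
  cm <- cbind(specimen_id = rownames(consp$matrix), cm)
  utils::write.table(cm, add(file.path(cfg$out_dir, "conspecificity.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(consp$clusters,
                     add(file.path(cfg$out_dir, "consensus_clusters.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  mt <- Filter(function(f) grepl("_CL", f$ffrs$ffr_id[1L]), ffrs)
  report <- discordance_report(
    calls, if (length(mt) > 0L) mt[[1L]] else NULL, md)
  utils::write.table(report, add(file.path(cfg$out_dir, "report.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(calls))
    utils::write.table(calls, add(file.path(cfg$out_dir,
                                            "locus_calls.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  prov <- list(fill_seed = cfg$fill_seed,
               max_arc_steps = cfg$max_arc_steps,
               mt_step_threshold = cfg$mt_step_threshold,
               fills = fills)
  pf <- add(file.path(cfg$out_dir, "provenance.json"))
  jsonlite::write_json(prov, pf, auto_unbox = TRUE, digits = NA)

  manifest <- data.frame(
    path = basename(artifacts),
    md5 = unname(tools::md5sum(artifacts)),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(phased = phased, webs = webs, ffrs = ffrs,
                 calls = calls, consp = consp, report = report,
                 manifest = manifest))
}
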