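# Programmatic fixtures: tiny alignments and files built at test time.

make_aln <- function(seqs, locus = "toy", ploidy = "diploid",
                     ids = sprintf("sp%02d", seq_along(seqs)), ...) {
  locus_alignment(locus, ids, seqs, ploidy = ploidy, ...)
}

write_fasta_text <- function(ids, seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

toy_metadata <- function(ids, species, locality,
                         karyotype = NA_character_) {
  data.frame(specimen_id = ids, species = species,
             locality = as.integer(locality),
             karyotype = karyotype, stringsAsFactors = FALSE)
}

# two diverged 12-bp pools with one heterozygote linking W-variant and
# W-centre, used across network/classify tests
toy_two_pool_phased <- function() {
  w <- "AAAACCCCGGGG"
  w2 <- "AAAACCCCGGGT"          # one step from w
  t1 <- "TTTACCCCGGGG"          # three steps from w
  geno_het <- recombine_haplotypes(w, w2)
  aln <- make_aln(c(w, w, t1, t1, geno_het), locus = "L1",
                  ids = c("a1", "a2", "b1", "b2", "a3"))
  md <- toy_metadata(c("a1", "a2", "b1", "b2", "a3"),
                     c("spA", "spA", "spB", "spB", "spA"),
                     c(1, 1, 2, 2, 1))
  list(phased = phase_all(aln, md), metadata = md)
}
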