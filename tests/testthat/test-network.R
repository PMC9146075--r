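test_that("pairwise_diffs and p_distance count comparable sites", {
  expect_equal(pairwise_diffs("ACGT", "ACGT"), 0L)
  expect_equal(pairwise_diffs("AAAA", "AATT"), 2L)
  expect_error(pairwise_diffs("AAA", "AAAA"), "mismatch")
  # N-sites are skipped (pairwise deletion)
  expect_equal(pairwise_diffs("ANAT", "ATAA"), 1L)
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_true(is.na(p_distance("NNNN", "ACGT")))

  # 3 differences over 970 comparable sites round to 0.003
  a <- strrep("A", 970)
  b <- paste0(strrep("A", 967), "CCC")
  expect_equal(round(p_distance(a, b), 3), 0.003)

  set.seed(21)
  for (i in 1:20) {
    x <- random_seq(50, c("A", "C", "G", "T", "N"))
    y <- random_seq(50, c("A", "C", "G", "T", "N"))
    expect_equal(pairwise_diffs(x, y), oracle_pairwise_diffs(x, y))
    expect_equal(p_distance(x, y), p_distance(y, x))
  }
})

test_that("build_msn retains all tied minimum-spanning-tree edges", {
  expect_equal(nrow(build_msn("ACGT")), 0L)

  # mutual distances 1,1,2: only the two weight-1 edges survive
  ed <- build_msn(c("AAAA", "AAAT", "AATT"))
  expect_equal(nrow(ed), 2L)
  expect_equal(sort(ed$steps), c(1L, 1L))

  # tie retention: three sequences pairwise distance 2 -> all 3 edges
  ed2 <- build_msn(c("AAT", "ATA", "TAA"))
  expect_equal(nrow(ed2), 3L)

  set.seed(99)
  for (i in 1:25) {
    n <- sample(2:7, 1)
    seqs <- unique(replicate(n, random_seq(8)))
    ed <- build_msn(seqs)
    d <- outer(seq_along(seqs), seq_along(seqs),
               Vectorize(function(a, b) pairwise_diffs(seqs[a], seqs[b])))
    want <- oracle_msn(d)
    got <- ed[order(ed$from, ed$to), c("from", "to")]
    want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
    expect_equal(unname(as.matrix(got)), unname(want))
    # connected, and total weight equals MST weight
    g <- igraph::graph_from_edgelist(as.matrix(ed[, 1:2]), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(seqs) - igraph::vcount(g)))
    expect_true(igraph::is_connected(g))
  }
})

test_that("haploweb arcs mirror heterozygous phased genotypes", {
  # all homozygous -> zero arcs
  aln <- make_aln(c("AAAA", "TTAA", "AATT"))
  ph <- phase_all(aln)
  web <- build_haploweb(ph)
  expect_equal(nrow(web$arcs), 0L)

  # two specimens heterozygous for the same pair -> one arc, weight 2
  g <- recombine_haplotypes("AAAA", "AATA")
  aln2 <- make_aln(c("AAAA", "AATA", g, g), ids = c("h1","h2","x1","x2"))
  ph2 <- phase_all(aln2)
  web2 <- build_haploweb(ph2)
  expect_equal(nrow(web2$arcs), 1L)
  expect_equal(web2$arcs$weight, 2L)
  expect_setequal(strsplit(web2$arcs$carriers, ",")[[1]], c("x1", "x2"))

  # arc weights sum to the number of heterozygous phased genotypes
  co <- make_cohort(sim_config(seed = 55, n_f1 = 2))
  ph3 <- phase_all(co$alignments$IRBP, co$metadata)
  web3 <- build_haploweb(ph3)
  n_het <- sum(ph3$phased$status == "phased_by_reference" &
                 ph3$phased$hap_a != ph3$phased$hap_b)
  expect_equal(sum(web3$arcs$weight), n_het)
  # edge steps equal the recomputed pairwise distance
  for (i in seq_len(nrow(web3$edges))) {
    a <- web3$haplotypes$seq[match(web3$edges$hap_i[i],
                                   web3$haplotypes$hap_id)]
    b <- web3$haplotypes$seq[match(web3$edges$hap_j[i],
                                   web3$haplotypes$hap_id)]
    expect_equal(pairwise_diffs(a, b), web3$edges$steps[i])
  }
})

test_that("find_ffrs delimits arc components, not mutational edges", {
  # no heterozygotes: every carried haplotype is its own FFR
  aln <- make_aln(c("AAAA", "AATA", "TTTT"))
  ph <- phase_all(aln)
  fs <- find_ffrs(build_haploweb(ph), ph)
  expect_equal(nrow(fs$ffrs), 3L)
  expect_equal(nrow(fs$bridging), 0L)

  # chain A-het-B, B-het-C merges into one FFR
  a <- "AAAA"; b <- "AATA"; c2 <- "AATT"
  aln2 <- make_aln(c(a, b, c2, recombine_haplotypes(a, b),
                     recombine_haplotypes(b, c2)),
                   ids = c("pa", "pb", "pc", "x1", "x2"))
  ph2 <- phase_all(aln2)
  fs2 <- find_ffrs(build_haploweb(ph2), ph2)
  expect_equal(nrow(fs2$ffrs), 1L)
  expect_equal(fs2$ffrs$n_haplotypes, 3L)
  expect_equal(nrow(fs2$bridging), 0L)
})

test_that("FFRs partition carried haplotypes on random cohorts", {
  for (s in 1:5) {
    co <- make_cohort(sim_config(seed = 600 + s, n_f1 = 2,
                                 n_pure_a_e = 3, n_intra_het = 2))
    for (locus in c("IRBP", "XIST")) {
      ph <- phase_all(co$alignments[[locus]], co$metadata)
      web <- build_haploweb(ph)
      fs <- find_ffrs(web, ph)
      hap_lists <- strsplit(fs$ffrs$hap_ids, ",")
      all_haps <- unlist(hap_lists)
      expect_equal(sort(all_haps), sort(web$haplotypes$hap_id))
      expect_equal(anyDuplicated(all_haps), 0L)
    }
  }
})

test_that("two-species cohorts give two FFRs; F1s bridge them", {
  co <- make_cohort(sim_config(seed = 77))
  for (locus in c("IRBP", "XIST")) {
    ph <- phase_all(co$alignments[[locus]], co$metadata)
    fs <- find_ffrs(build_haploweb(ph), ph)
    expect_equal(nrow(fs$ffrs), 2L)
    expect_equal(nrow(fs$bridging), 0L)
  }
  coh <- make_cohort(sim_config(seed = 78, n_f1 = 2))
  f1_ids <- names(coh$truth$class)[coh$truth$class == "f1"]
  for (locus in c("IRBP", "XIST")) {
    ph <- phase_all(coh$alignments[[locus]], coh$metadata)
    fs <- find_ffrs(build_haploweb(ph), ph)
    expect_equal(nrow(fs$ffrs), 2L)
    expect_setequal(fs$bridging$specimen_id, f1_ids)
  }
})

test_that("mt_clades cuts long edges into clade partitions", {
  near <- c("AAAAAAAAAA", "AAAAAAAAAT")
  far <- c("TTTTTTTTAA", "TTTTTTTTAC")  # 8+ steps from the first pair
  aln <- locus_alignment("mt", sprintf("m%d", 1:4), c(near, far),
                         ploidy = "haploid")
  fs <- mt_clades(aln, max_steps = 5)
  expect_equal(nrow(fs$ffrs), 2L)
  expect_equal(sort(fs$ffrs$n_members), c(2L, 2L))
  # with a generous threshold everything is one clade
  fs2 <- mt_clades(aln, max_steps = 10)
  expect_equal(nrow(fs2$ffrs), 1L)
})

test_that("conspecificity counts shared-FFR loci and clusters", {
  # toy: 4 specimens, 2 loci; s3 is tancrei-like at L2 but alaicus at L1
  mk_fs <- function(locus, groups) {
    # groups: named list ffr label -> specimen ids
    ffrs <- data.frame(
      ffr_id = paste0(locus, "_FFR", seq_along(groups)),
      hap_ids = paste0(locus, "_H", seq_along(groups)),
      members = vapply(groups, paste, character(1), collapse = ","),
      n_haplotypes = 1L, n_members = lengths(groups),
      stringsAsFactors = FALSE)
    structure(list(locus = locus, ffrs = ffrs,
                   bridging = data.frame(), membership = NULL),
              class = "ffr_set")
  }
  ids <- c("s1", "s2", "s3", "s4")
  f1 <- mk_fs("L1", list(c("s1", "s2", "s3"), "s4"))
  f2 <- mk_fs("L2", list(c("s1", "s2"), c("s3", "s4")))
  cs <- conspecificity(list(L1 = f1, L2 = f2), ids)
  expect_true(isSymmetric(cs$matrix))
  expect_equal(unname(diag(cs$matrix)), rep(2L, 4))
  expect_equal(cs$matrix["s1", "s2"], 2L)
  expect_equal(cs$matrix["s1", "s3"], 1L)  # conspecific at L1 only
  expect_equal(cs$matrix["s3", "s4"], 1L)
  expect_equal(cs$matrix["s1", "s4"], 0L)
  # majority threshold (ceil(2/2) = 1) links s3 to both groups:
  # single linkage collapses everything into one cluster
  expect_equal(max(cs$clusters$cluster), 1L)
  # strict threshold separates the two species cleanly
  cs2 <- conspecificity(list(L1 = f1, L2 = f2), ids,
                        threshold = function(L) L)
  cl <- cs2$clusters
  expect_equal(cl$cluster[cl$specimen_id == "s1"],
               cl$cluster[cl$specimen_id == "s2"])
  expect_false(cl$cluster[cl$specimen_id == "s1"] ==
                 cl$cluster[cl$specimen_id == "s4"])

  # three loci including a haploid clade partition, hand-computed
  f3 <- mk_fs("mt", list(c("s1", "s2", "s3"), "s4"))
  cs3 <- conspecificity(list(L1 = f1, L2 = f2, mt = f3), ids)
  expect_equal(cs3$matrix["s1", "s3"], 2L)
  expect_equal(cs3$matrix["s1", "s4"], 0L)
  expect_equal(unname(diag(cs3$matrix)), rep(3L, 4))
  # counts never exceed loci scored
  expect_true(all(cs3$matrix <= cs3$loci_scored))
})

test_that("specimens absent at a locus leave it unscored", {
  mk <- function(locus, groups) {
    ffrs <- data.frame(
      ffr_id = paste0(locus, "_FFR", seq_along(groups)),
      hap_ids = "h", members = vapply(groups, paste, character(1),
                                      collapse = ","),
      n_haplotypes = 1L, n_members = lengths(groups),
      stringsAsFactors = FALSE)
    structure(list(locus = locus, ffrs = ffrs, bridging = data.frame(),
                   membership = NULL), class = "ffr_set")
  }
  ids <- c("s1", "s2", "s3")
  f1 <- mk("L1", list(c("s1", "s2", "s3")))
  f2 <- mk("L2", list(c("s1", "s2")))  # s3 missing at L2
  cs <- conspecificity(list(L1 = f1, L2 = f2), ids)
  expect_equal(cs$loci_scored["s1", "s3"], 1L)
  expect_equal(cs$matrix["s1", "s3"], 1L)
  expect_equal(cs$loci_scored["s1", "s2"], 2L)
})

test_that("haploweb exports GraphML and DOT", {
  x <- toy_two_pool_phased()
  web <- build_haploweb(x$phased)
  g <- haploweb_to_igraph(web)
  expect_equal(igraph::vcount(g), nrow(web$haplotypes))
  expect_setequal(unique(igraph::E(g)$type), c("mutation", "arc"))
  gml <- tempfile(fileext = ".graphml"); dot <- tempfile(fileext = ".dot")
  write_haploweb(web, graphml = gml, dot = dot)
  expect_true(file.exists(gml) && file.size(gml) > 0)
  expect_true(file.exists(dot) && file.size(dot) > 0)
})
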