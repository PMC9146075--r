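## network: pairwise distances, minimum-spanning haplotype networks,
## heterozygote arcs ("haploweb"), fields for recombination (FFRs) and
## the multilocus conspecificity matrix.

#' Count nucleotide differences between two aligned haplotypes
#'
#' Sites where either sequence carries anything other than `A C G T`
#' (i.e. `N`, gaps) are skipped — pairwise deletion.
#'
#' @param h1,h2 Two aligned sequences of equal length.
#' @return Integer count of differing comparable sites.
#' @export
pairwise_diffs <- function(h1, h2) {
  a <- strsplit(toupper(h1), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(h2), "", fixed = TRUE)[[1L]]
  if (length(a) != length(b))
    stop("sequence length mismatch (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  comp <- a %in% BASES & b %in% BASES
  sum(a[comp] != b[comp])
}

#' Uncorrected p-distance between two aligned haplotypes
#'
#' Proportion of differing sites among sites where both sequences carry
#' an unambiguous base (pairwise deletion), uncorrected for multiple
#' hits.  Summaries conventionally round to three decimals.
#'
#' @inheritParams pairwise_diffs
#' @return A fraction in `[0, 1]`, or `NA` when no site is comparable.
#' @export
p_distance <- function(h1, h2) {
  a <- strsplit(toupper(h1), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(h2), "", fixed = TRUE)[[1L]]
  if (length(a) != length(b))
    stop("sequence length mismatch", call. = FALSE)
  comp <- a %in% BASES & b %in% BASES
  if (!any(comp)) return(NA_real_)
  sum(a[comp] != b[comp]) / sum(comp)
}

# distance matrix over a character vector of sequences
diff_matrix <- function(seqs) {
  n <- length(seqs)
  d <- matrix(0L, n, n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- pairwise_diffs(seqs[i], seqs[j])
    }
  }
  d
}

#' Minimum-spanning network over haplotypes
#'
#' The epsilon-0 minimum-spanning network: the union of the edge sets
#' of *all* minimum spanning trees under the mutational-step distance.
#' An edge (u, v) with weight w belongs to some MST exactly when u and
#' v are disconnected in the graph restricted to edges of weight < w,
#' so ties are retained and no inferred median vectors are added.
#'
#' @param seqs Character vector of distinct haplotype sequences.
#' @param d Optional precomputed distance matrix.
#' @return A data.frame with columns `from`, `to` (indices into
#'   `seqs`), `steps`; zero rows for a single haplotype.
#' @export
build_msn <- function(seqs, d = NULL) {
  n <- length(seqs)
  if (n == 0L) stop("build_msn() needs at least one haplotype", call. = FALSE)
  if (is.null(d)) d <- diff_matrix(seqs)
  edges <- data.frame(from = integer(), to = integer(), steps = integer())
  if (n == 1L) return(edges)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[pairs]
  ord <- order(w)
  pairs <- pairs[ord, , drop = FALSE]
  w <- w[ord]
  # union-find over components built from strictly lighter edges
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (lev in unique(w)) {
    at <- which(w == lev)
    keep <- vapply(at, function(k)
      find(pairs[k, 1L]) != find(pairs[k, 2L]), logical(1L))
    edges <- rbind(edges, data.frame(from = pairs[at[keep], 1L],
                                     to = pairs[at[keep], 2L],
                                     steps = rep(lev, sum(keep))))
    for (k in at) { # now merge this weight level
      ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
      if (ra != rb) parent[ra] <- rb
    }
  }
  rownames(edges) <- NULL
  edges
}

#' Build a haploweb from a phased locus
#'
#' Nodes are the haplotypes carried by at least one specimen, edges are
#' minimum-spanning-network mutational steps, and arcs connect the two
#' haplotypes of every heterozygous phased genotype, weighted by the
#' number of carriers.
#'
#' @param phased A `phased_locus` from [phase_all()].
#' @return An object of class `haploweb`: list with `locus`,
#'   `haplotypes` (carried haplotypes only), `edges` (`hap_i`, `hap_j`,
#'   `steps`) and `arcs` (`hap_i`, `hap_j`, `weight`, `carriers`).
#' @export
build_haploweb <- function(phased) {
  stopifnot(inherits(phased, "phased_locus"))
  haps <- phased$haplotypes
  haps <- haps[haps$freq > 0L, , drop = FALSE]
  rownames(haps) <- NULL
  ed <- if (nrow(haps) > 0L) build_msn(haps$seq)
        else data.frame(from = integer(), to = integer(),
                        steps = integer())
  edges <- data.frame(hap_i = haps$hap_id[ed$from],
                      hap_j = haps$hap_id[ed$to],
                      steps = ed$steps, stringsAsFactors = FALSE)

  ph <- phased$phased
  het <- ph[!is.na(ph$hap_a) & ph$hap_a != ph$hap_b, , drop = FALSE]
  if (nrow(het) > 0L) {
    key <- paste(het$hap_a, het$hap_b, sep = "|")
    tab <- split(het$specimen_id, key)
    parts <- strsplit(names(tab), "|", fixed = TRUE)
    arcs <- data.frame(
      hap_i = vapply(parts, `[`, character(1L), 1L),
      hap_j = vapply(parts, `[`, character(1L), 2L),
      weight = lengths(tab),
      carriers = vapply(tab, paste, character(1L), collapse = ","),
      stringsAsFactors = FALSE, row.names = NULL
    )
    bad <- setdiff(c(arcs$hap_i, arcs$hap_j), haps$hap_id)
    if (length(bad) > 0L)
      stop("arc references unknown haplotype: ",
           paste(bad, collapse = ", "), call. = FALSE)
  } else {
    arcs <- data.frame(hap_i = character(), hap_j = character(),
                       weight = integer(), carriers = character())
  }
  structure(list(locus = phased$locus, haplotypes = haps,
                 edges = edges, arcs = arcs),
            class = "haploweb")
}

#' @export
print.haploweb <- function(x, ...) {
  cat("haploweb '", x$locus, "': ", nrow(x$haplotypes), " haplotypes, ",
      nrow(x$edges), " mutational edges, ", nrow(x$arcs),
      " heterozygote arcs\n", sep = "")
  invisible(x)
}

#' Delimit fields for recombination (FFRs)
#'
#' A field for recombination is a pool of alleles linked together by
#' heterozygous individuals: connected components of the arc graph
#' (mutational edges never merge FFRs).  Two refinements keep distinct
#' pools separate in the presence of hybrids:
#' \itemize{
#'   \item An arc spanning more than `max_arc_steps` mutational steps
#'     connects alleles from different pools.  If both sides are
#'     *anchored* — contain a haplotype observed in a homozygote — the
#'     pools stay separate and the arc's carriers are flagged as
#'     FFR-bridging heterozygotes (putative hybrids), listed as members
#'     of both fields.
#'   \item If one side of a long arc is unanchored (only deduced
#'     alleles, e.g. a complement carrying private mutations), it
#'     cannot constitute a field of its own and is absorbed into the
#'     anchored pool its carrier links it to.
#' }
#'
#' @param web A [build_haploweb()] object.
#' @param phased The `phased_locus` the web was built from (provides
#'   specimen membership and haplotype provenance).
#' @param max_arc_steps Largest mutational span an arc may have and
#'   still merge two anchored pools.  The default 2 matches the
#'   within-pool regime (star-shaped shallow polymorphism) the
#'   delimitation procedure presumes; pools separated by three or more
#'   fixed differences stay distinct.
#' @return An object of class `ffr_set`: list with `ffrs` (data.frame
#'   `ffr_id`, `hap_ids`, `members`, `n_haplotypes`, `n_members`) and
#'   `bridging` (data.frame `specimen_id`, `hap_a`, `hap_b`, `ffr_a`,
#'   `ffr_b`).
#' @export
find_ffrs <- function(web, phased, max_arc_steps = 2L) {
  stopifnot(inherits(web, "haploweb"), inherits(phased, "phased_locus"))
  haps <- web$haplotypes$hap_id
  if (length(haps) == 0L)
    return(structure(list(locus = web$locus,
                          ffrs = data.frame(ffr_id = character(),
                                            hap_ids = character(),
                                            members = character(),
                                            n_haplotypes = integer(),
                                            n_members = integer()),
                          bridging = data.frame(specimen_id = character(),
                                                hap_a = character(),
                                                hap_b = character(),
                                                ffr_a = character(),
                                                ffr_b = character()),
                          membership = integer()),
                     class = "ffr_set"))
  steps_of <- function(a, b)
    pairwise_diffs(web$haplotypes$seq[match(a, haps)],
                   web$haplotypes$seq[match(b, haps)])
  span <- if (nrow(web$arcs) > 0L)
    mapply(steps_of, web$arcs$hap_i, web$arcs$hap_j) else numeric()
  short <- web$arcs[span <= max_arc_steps, , drop = FALSE]

  g <- igraph::make_empty_graph(n = length(haps), directed = FALSE)
  igraph::V(g)$name <- haps
  if (nrow(short) > 0L)
    g <- igraph::add_edges(g, rbind(short$hap_i, short$hap_j))
  comp <- igraph::components(g)$membership
  names(comp) <- haps

  # anchored pools contain at least one observed homozygote haplotype;
  # an unanchored component (deduced alleles only) cannot constitute a
  # field of its own and is assigned to the mutationally nearest
  # anchored pool
  is_anch_hap <- web$haplotypes$provenance == "observed_homozygote"
  anchored_comp <- unique(comp[is_anch_hap])
  if (length(anchored_comp) > 0L) {
    anch_haps <- haps[comp %in% anchored_comp]
    for (kc in setdiff(unique(comp), anchored_comp)) {
      mine <- haps[comp == kc]
      d <- outer(mine, anch_haps, Vectorize(steps_of))
      hit <- which(d == min(d), arr.ind = TRUE)
      # deterministic tie-break: first anchored hap in id order
      nearest <- anch_haps[min(hit[, "col"])]
      comp[comp == kc] <- comp[[nearest]]
    }
  }
  # stable ffr ids: order components by their lexicographically first hap
  first_hap <- vapply(split(haps, comp), min, character(1L))
  ord <- order(first_hap)
  relabel <- integer(length(first_hap))
  relabel[ord] <- seq_along(ord)
  comp <- relabel[match(comp, sort(unique(comp)))]
  names(comp) <- haps
  width <- max(1L, nchar(max(comp)))
  ffr_id_of <- function(k) sprintf(paste0("%s_FFR%0", width, "d"),
                                   web$locus, k)

  ph <- phased$phased
  ph <- ph[!is.na(ph$hap_a), , drop = FALSE]
  members <- vector("list", max(comp))
  bridging <- data.frame(specimen_id = character(), hap_a = character(),
                         hap_b = character(), ffr_a = character(),
                         ffr_b = character(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ph))) {
    ka <- comp[[ph$hap_a[i]]]; kb <- comp[[ph$hap_b[i]]]
    members[[ka]] <- union(members[[ka]], ph$specimen_id[i])
    if (kb != ka) {
      members[[kb]] <- union(members[[kb]], ph$specimen_id[i])
      bridging <- rbind(bridging, data.frame(
        specimen_id = ph$specimen_id[i], hap_a = ph$hap_a[i],
        hap_b = ph$hap_b[i],
        ffr_a = ffr_id_of(min(ka, kb)), ffr_b = ffr_id_of(max(ka, kb)),
        stringsAsFactors = FALSE))
    }
  }
  ffrs <- data.frame(
    ffr_id = ffr_id_of(seq_len(max(comp))),
    hap_ids = vapply(seq_len(max(comp)), function(k)
      paste(sort(haps[comp == k]), collapse = ","), character(1L)),
    members = vapply(members, function(x)
      paste(sort(x %||% character()), collapse = ","), character(1L)),
    n_haplotypes = as.integer(table(factor(comp, seq_len(max(comp))))),
    n_members = vapply(members, length, integer(1L)),
    stringsAsFactors = FALSE
  )
  structure(list(locus = web$locus, ffrs = ffrs, bridging = bridging,
                 membership = comp),
            class = "ffr_set")
}

#' @export
print.ffr_set <- function(x, ...) {
  cat("ffr_set '", x$locus, "': ", nrow(x$ffrs), " FFRs, ",
      nrow(x$bridging), " bridging heterozygotes\n", sep = "")
  invisible(x)
}

#' Mitochondrial clades from a haploid alignment
#'
#' A haploid locus has no heterozygotes and hence no arcs; its
#' "pools" are taken as minimum-spanning-network components after
#' cutting edges longer than `max_steps` mutational steps.  The result
#' plays the role of an FFR partition when the locus enters the
#' multilocus conspecificity matrix.
#'
#' @param aln A haploid [locus_alignment()].
#' @param max_steps Edges spanning more than this many steps are cut
#'   before components are read off (default 5).
#' @return An `ffr_set` whose fields are the clades.
#' @export
mt_clades <- function(aln, max_steps = 5L) {
  stopifnot(inherits(aln, "locus_alignment"))
  if (aln$ploidy != "haploid")
    stop("mt_clades() expects a haploid alignment", call. = FALSE)
  tab <- split(aln$specimen_id, aln$seq)
  seqs <- names(tab)
  ed <- build_msn(seqs)
  keep <- ed[ed$steps <= max_steps, , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(seqs), directed = FALSE)
  if (nrow(keep) > 0L)
    g <- igraph::add_edges(g, rbind(keep$from, keep$to))
  comp <- igraph::components(g)$membership
  first_seq <- vapply(split(seq_along(seqs), comp),
                      function(ix) min(seqs[ix]), character(1L))
  ord <- order(first_seq)
  relabel <- integer(length(first_seq)); relabel[ord] <- seq_along(ord)
  comp <- relabel[comp]
  width <- max(1L, nchar(max(comp)))
  hap_id <- sprintf(paste0("%s_H%02d"), aln$locus, seq_along(seqs))
  ffr_id_of <- function(k) sprintf(paste0("%s_CL%0", width, "d"),
                                   aln$locus, k)
  members <- lapply(seq_len(max(comp)), function(k)
    sort(unique(unlist(tab[comp == k], use.names = FALSE))))
  ffrs <- data.frame(
    ffr_id = ffr_id_of(seq_len(max(comp))),
    hap_ids = vapply(seq_len(max(comp)), function(k)
      paste(sort(hap_id[comp == k]), collapse = ","), character(1L)),
    members = vapply(members, paste, character(1L), collapse = ","),
    n_haplotypes = as.integer(table(factor(comp, seq_len(max(comp))))),
    n_members = lengths(members),
    stringsAsFactors = FALSE
  )
  names(comp) <- hap_id
  structure(list(locus = aln$locus, ffrs = ffrs,
                 bridging = data.frame(specimen_id = character(),
                                       hap_a = character(),
                                       hap_b = character(),
                                       ffr_a = character(),
                                       ffr_b = character()),
                 membership = comp),
            class = "ffr_set")
}

# specimen -> character vector of ffr ids (bridging specimens map to two)
ffr_membership_by_specimen <- function(fs) {
  out <- list()
  for (k in seq_len(nrow(fs$ffrs))) {
    ids <- strsplit(fs$ffrs$members[k], ",")[[1L]]
    ids <- ids[nzchar(ids)]
    for (s in ids) out[[s]] <- c(out[[s]], fs$ffrs$ffr_id[k])
  }
  out
}

#' Multilocus conspecificity matrix and consensus clusters
#'
#' Entry (i, j) counts the loci at which specimens i and j fall in the
#' same FFR (sharing at least one field when one of them bridges two).
#' Pairs conspecific at a majority of their mutually scored loci are
#' linked, and consensus clusters are the single-linkage components of
#' that graph.
#'
#' @param ffrs_by_locus Named list of `ffr_set` objects (one per locus;
#'   haploid loci contribute their [mt_clades()] partition).
#' @param specimens Character vector of specimen ids to score.
#' @param threshold Function of the number of mutually scored loci L
#'   returning the minimum shared-FFR count for consensus linkage;
#'   default majority, `ceiling(L / 2)`.
#' @return An object of class `conspecificity`: list with `specimens`,
#'   `matrix` (shared-locus counts; diagonal = loci scored),
#'   `loci_scored` (pairwise matrix), and `clusters` (data.frame
#'   `specimen_id`, `cluster`).
#' @export
conspecificity <- function(ffrs_by_locus, specimens,
                           threshold = function(L) ceiling(L / 2)) {
  stopifnot(length(ffrs_by_locus) >= 1L)
  n <- length(specimens)
  mship <- lapply(ffrs_by_locus, ffr_membership_by_specimen)
  cnt <- matrix(0L, n, n, dimnames = list(specimens, specimens))
  scored <- matrix(0L, n, n, dimnames = list(specimens, specimens))
  for (m in mship) {
    present <- specimens %in% names(m)
    for (i in seq_len(n)) for (j in i:n) {
      if (!present[i] || !present[j]) next
      scored[i, j] <- scored[j, i] <- scored[i, j] + 1L
      if (length(intersect(m[[specimens[i]]], m[[specimens[j]]])) > 0L) {
        cnt[i, j] <- cnt[j, i] <- cnt[i, j] + 1L
      }
    }
  }
  # consensus: link pairs conspecific at >= threshold(L) of L scored loci
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- specimens
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      L <- scored[i, j]
      if (L > 0L && cnt[i, j] >= threshold(L))
        g <- igraph::add_edges(g, c(specimens[i], specimens[j]))
    }
  }
  comp <- igraph::components(g)$membership
  # deterministic cluster numbering by sorted first member
  first <- vapply(split(specimens, comp), min, character(1L))
  ord <- order(first)
  relabel <- integer(length(first)); relabel[ord] <- seq_along(ord)
  clusters <- data.frame(specimen_id = specimens,
                         cluster = relabel[comp],
                         stringsAsFactors = FALSE)
  structure(list(specimens = specimens, matrix = cnt,
                 loci_scored = scored, clusters = clusters),
            class = "conspecificity")
}

#' @export
print.conspecificity <- function(x, ...) {
  cat("conspecificity: ", length(x$specimens), " specimens, ",
      max(x$clusters$cluster), " consensus clusters\n", sep = "")
  invisible(x)
}

#' Convert a haploweb to an igraph object
#'
#' Mutational edges get `type = "mutation"` and `weight = steps`; arcs
#' get `type = "arc"` and `weight =` carrier count.  Nodes carry
#' `freq` (allele copies) for size scaling.
#'
#' @param web A [build_haploweb()] object.
#' @return An undirected igraph graph.
#' @export
haploweb_to_igraph <- function(web) {
  g <- igraph::make_empty_graph(n = nrow(web$haplotypes), directed = FALSE)
  igraph::V(g)$name <- web$haplotypes$hap_id
  igraph::V(g)$freq <- web$haplotypes$freq
  if (nrow(web$edges) > 0L) {
    g <- igraph::add_edges(g, rbind(web$edges$hap_i, web$edges$hap_j),
                           attr = list(type = "mutation",
                                       weight = web$edges$steps,
                                       style = "solid"))
  }
  if (nrow(web$arcs) > 0L) {
    g <- igraph::add_edges(g, rbind(web$arcs$hap_i, web$arcs$hap_j),
                           attr = list(type = "arc",
                                       weight = web$arcs$weight,
                                       style = "dashed"))
  }
  g
}

#' Write a haploweb to GraphML and DOT
#'
#' @param web A [build_haploweb()] object.
#' @param graphml,dot Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_haploweb <- function(web, graphml = NULL, dot = NULL) {
  g <- haploweb_to_igraph(web)
  written <- character()
  if (!is.null(graphml)) {
    igraph::write_graph(g, graphml, format = "graphml")
    written <- c(written, graphml)
  }
  if (!is.null(dot)) {
    igraph::write_graph(g, dot, format = "dot")
    written <- c(written, dot)
  }
  invisible(written)
}
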