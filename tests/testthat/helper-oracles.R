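# Independent oracles: brute-force implementations kept deliberately
# separate from the package's algorithms.

IUPAC_PAIRS <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

oracle_het_sites <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  out <- data.frame(pos = integer(), code = character())
  for (i in seq_along(chars)) {
    if (chars[i] %in% names(IUPAC_PAIRS))
      out <- rbind(out, data.frame(pos = i, code = chars[i]))
  }
  out
}

oracle_pairwise_diffs <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- 0L
  for (i in seq_along(x)) {
    if (x[i] %in% c("A", "C", "G", "T") && y[i] %in% c("A", "C", "G", "T") &&
        x[i] != y[i]) n <- n + 1L
  }
  n
}

# All 2^k decompositions of a genotype into an unordered haplotype pair.
# Returns a list of length-2 character vectors (sorted), de-duplicated.
oracle_decompositions <- function(genotype) {
  chars <- strsplit(genotype, "")[[1]]
  het <- which(chars %in% names(IUPAC_PAIRS))
  k <- length(het)
  base_a <- chars; base_b <- chars
  pairs <- lapply(het, function(i) strsplit(IUPAC_PAIRS[[chars[i]]], "")[[1]])
  out <- list()
  for (mask in 0:(2^k - 1)) {
    a <- base_a; b <- base_b
    for (j in seq_len(k)) {
      bit <- bitwAnd(bitwShiftR(mask, j - 1L), 1L)
      a[het[j]] <- pairs[[j]][bit + 1L]
      b[het[j]] <- pairs[[j]][2L - bit]
    }
    key <- sort(c(paste(a, collapse = ""), paste(b, collapse = "")))
    out[[paste(key, collapse = "|")]] <- key
  }
  unname(out)
}

# Phasing oracle: applies the stated preference rules (locality of
# homozygote carriers first, then global carrier frequency) to the
# exhaustively enumerated decompositions.  pool: data.frame seq/freq/
# carriers as produced by homozygote_pool(); loc_of: named locality
# vector; my_loc: focal specimen's locality (NA to disable).
oracle_phase <- function(genotype, pool, loc_of = NULL, my_loc = NA) {
  decomps <- oracle_decompositions(genotype)
  # candidate references: pool haplotypes appearing in a decomposition
  cand <- list()
  for (d in decomps) {
    for (r in unique(d)) {
      j <- match(r, pool$seq)
      if (!is.na(j)) cand[[length(cand) + 1L]] <- list(ref = j, pair = d)
    }
  }
  if (length(cand) == 0L) return(NULL)
  refs <- vapply(cand, function(x) x$ref, integer(1))
  if (!is.na(my_loc) && !is.null(loc_of)) {
    local <- vapply(cand, function(x) {
      ids <- strsplit(pool$carriers[x$ref], ",")[[1]]
      my_loc %in% loc_of[ids]
    }, logical(1))
    if (any(local)) { cand <- cand[local]; refs <- refs[local] }
  }
  top <- pool$freq[refs] == max(pool$freq[refs])
  cand <- cand[top]
  keys <- unique(vapply(cand, function(x)
    paste(x$pair, collapse = "|"), character(1)))
  if (length(keys) != 1L) return(NULL)  # unresolved
  strsplit(keys, "|", fixed = TRUE)[[1]]
}

# Union of the edge sets of all minimum spanning trees, by exhaustive
# enumeration of spanning trees over <= 7 nodes.
oracle_msn <- function(d) {
  n <- nrow(d)
  if (n == 1L) return(matrix(integer(), 0, 2))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  m <- nrow(pairs)
  best <- Inf; in_any <- rep(FALSE, m)
  for (sel in utils::combn(m, n - 1L, simplify = FALSE)) {
    # spanning check via repeated relaxation
    comp <- seq_len(n)
    for (e in sel) for (dummy in 1:n) {
      i <- pairs[e, 1]; j <- pairs[e, 2]
      lo <- min(comp[i], comp[j]); comp[comp == comp[i] | comp == comp[j]] <- lo
    }
    if (length(unique(comp)) != 1L) next
    w <- sum(d[pairs[sel, , drop = FALSE]])
    if (w < best - 1e-9) { best <- w; in_any <- rep(FALSE, m); in_any[sel] <- TRUE }
    else if (abs(w - best) < 1e-9) in_any[sel] <- TRUE
  }
  pairs[in_any, , drop = FALSE]
}

# random haplotype-like sequence
random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# random diploid genotype with exactly k heterozygous sites
random_genotype <- function(len, k) {
  chars <- strsplit(random_seq(len), "")[[1]]
  pos <- sample(len, k)
  for (p in pos) chars[p] <- sample(names(IUPAC_PAIRS), 1)
  paste(chars, collapse = "")
}
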