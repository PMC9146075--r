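## Internal helpers shared across modules: IUPAC tables, seeded RNG,
## sequence <-> character-matrix conversion.

# Two-base IUPAC ambiguity codes used to record heterozygous sites in
# direct Sanger reads.  Three- and four-base codes are deliberately
# absent: a reproducible three-peak site is invalid input.
IUPAC_HET <- c(
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC"
)

BASES <- c("A", "C", "G", "T")

# code -> c(base1, base2), bases in alphabetical order
iupac_decode <- function(code) {
  pair <- IUPAC_HET[[code]]
  c(substr(pair, 1L, 1L), substr(pair, 2L, 2L))
}

# unordered base pair -> single-letter code (or the base itself when equal)
iupac_encode <- function(b1, b2) {
  if (b1 == b2) return(b1)
  if (b1 == "N" || b2 == "N") return("N")
  pair <- paste(sort(c(b1, b2)), collapse = "")
  hit <- names(IUPAC_HET)[match(pair, IUPAC_HET)]
  if (is.na(hit)) stop("cannot encode base pair ", pair, call. = FALSE)
  hit
}

# Vectorised encode over two equal-length base vectors.
iupac_encode_vec <- function(v1, v2) {
  stopifnot(length(v1) == length(v2))
  out <- v1
  diff <- which(v1 != v2)
  for (i in diff) out[i] <- iupac_encode(v1[i], v2[i])
  out
}

# Does this symbol expand to the given base?
symbol_contains <- function(sym, base) {
  if (sym == base) return(TRUE)
  if (sym %in% names(IUPAC_HET)) return(base %in% iupac_decode(sym))
  FALSE
}

is_het_code <- function(x) x %in% names(IUPAC_HET)

# sequences (character vector of strings) -> n x L character matrix
seq_to_mat <- function(seqs) {
  if (length(seqs) == 0L) return(matrix(character(), 0L, 0L))
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences have unequal lengths", call. = FALSE)
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), ncol = L, byrow = TRUE)
}

mat_to_seq <- function(m) {
  if (nrow(m) == 0L) return(character())
  apply(m, 1L, paste, collapse = "")
}

# Run `expr` under a temporary RNG state seeded with `seed`; the global
# RNG stream is restored afterwards so library code never perturbs a
# user's simulation.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
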