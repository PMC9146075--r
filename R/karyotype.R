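## karyotype: Robertsonian (Rb) fusion arithmetic.  A Rb fusion joins
## two acrocentric autosomes into one metacentric: each fused copy
## lowers the diploid number 2n by one while the fundamental number NF
## (arm count) is unchanged.

#' Construct a Robertsonian karyotype
#'
#' @param rbs A data.frame with columns `arm1`, `arm2` (chromosome-arm
#'   ids, unordered within a fusion) and `zygosity` (1 heterozygous,
#'   2 homozygous); zero rows for the all-acrocentric complement.
#' @param base_2n Diploid number of the fusion-free ancestral
#'   complement (default 54, the all-acrocentric complement of the
#'   mole-vole subgenus under study).
#' @param NF Fundamental number, stored but never computed from the
#'   fusions (default 56).
#' @param sex_system Sex chromosome system label (default `"XX"`, the
#'   X0/XX-derived system of these voles).
#' @return An object of class `karyotype`.
#' @export
karyotype <- function(rbs = NULL, base_2n = 54L, NF = 56L,
                      sex_system = "XX") {
  if (is.null(rbs) || nrow(rbs) == 0L) {
    rbs <- data.frame(arm1 = character(), arm2 = character(),
                      zygosity = integer(), stringsAsFactors = FALSE)
  } else {
    rbs <- data.frame(arm1 = as.character(rbs$arm1),
                      arm2 = as.character(rbs$arm2),
                      zygosity = as.integer(rbs$zygosity),
                      stringsAsFactors = FALSE)
    # canonical arm order within a fusion, fusions sorted numerically
    swap <- suppressWarnings(as.numeric(rbs$arm1) > as.numeric(rbs$arm2))
    swap[is.na(swap)] <- rbs$arm1[is.na(swap)] > rbs$arm2[is.na(swap)]
    tmp <- rbs$arm1[swap]; rbs$arm1[swap] <- rbs$arm2[swap]
    rbs$arm2[swap] <- tmp
    ord <- order(suppressWarnings(as.numeric(rbs$arm1)), rbs$arm1,
                 suppressWarnings(as.numeric(rbs$arm2)), rbs$arm2)
    rbs <- rbs[ord, , drop = FALSE]
    rownames(rbs) <- NULL
    if (any(rbs$arm1 == rbs$arm2))
      stop("a Robertsonian fusion needs two distinct arms", call. = FALSE)
    if (!all(rbs$zygosity %in% c(1L, 2L)))
      stop("zygosity must be 1 or 2", call. = FALSE)
    arms <- c(rbs$arm1, rbs$arm2)
    if (anyDuplicated(arms))
      stop("chromosome arm used by more than one fusion: ",
           paste(unique(arms[duplicated(arms)]), collapse = ", "),
           call. = FALSE)
  }
  structure(list(base_2n = as.integer(base_2n), NF = as.integer(NF),
                 rbs = rbs, sex_system = sex_system),
            class = "karyotype")
}

#' Diploid chromosome number of a karyotype
#'
#' `2n = base_2n - sum(zygosity)`: every fused chromosome copy removes
#' one element from the complement.
#'
#' @param k A [karyotype()].
#' @return Integer diploid number.
#' @export
diploid_number <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  k$base_2n - sum(k$rbs$zygosity)
}

#' Parse a Robertsonian karyotype formula
#'
#' Canonical form `"<z>Rb(<a>.<b>)[,...]"`, e.g.
#' `"2Rb(2.11),1Rb(3.10)"`; the empty string denotes the fusion-free
#' complement.  Whitespace is tolerated; mosaic zygosity ranges such as
#' `"1-2Rb(3.10)"` are parsed with `zygosity_range = c(1, 2)` kept as
#' an attribute on the row (see [karyotype_consistency()]).
#'
#' @param formula Formula string.
#' @param ... Passed to [karyotype()] (`base_2n`, `NF`, ...).
#' @return A [karyotype()].
#' @export
parse_karyotype <- function(formula, ...) {
  formula <- gsub("\\s+", "", formula %||% "")
  if (!nzchar(formula)) return(karyotype(NULL, ...))
  toks <- strsplit(formula, ",", fixed = TRUE)[[1L]]
  pat <- "^([12])(?:-([12]))?Rb\\(([^.()]+)\\.([^.()]+)\\)$"
  m <- regmatches(toks, regexec(pat, toks))
  bad <- toks[vapply(m, length, integer(1L)) == 0L]
  if (length(bad) > 0L)
    stop("malformed karyotype token: '", bad[1L], "'", call. = FALSE)
  lo <- vapply(m, function(x) as.integer(x[2L]), integer(1L))
  hi <- vapply(m, function(x)
    if (nzchar(x[3L])) as.integer(x[3L]) else as.integer(x[2L]), integer(1L))
  if (any(hi < lo))
    stop("mosaic zygosity range must be increasing", call. = FALSE)
  rbs <- data.frame(arm1 = vapply(m, `[`, character(1L), 4L),
                    arm2 = vapply(m, `[`, character(1L), 5L),
                    zygosity = hi, stringsAsFactors = FALSE)
  k <- karyotype(rbs, ...)
  # carry mosaic lower bounds through canonicalisation by re-matching
  lo_of <- stats::setNames(lo, paste(pmin(rbs$arm1, rbs$arm2),
                                     pmax(rbs$arm1, rbs$arm2)))
  key <- paste(pmin(k$rbs$arm1, k$rbs$arm2), pmax(k$rbs$arm1, k$rbs$arm2))
  k$rbs$zygosity_min <- unname(lo_of[key])
  k
}

#' Format a karyotype as its canonical formula string
#'
#' @param x A [karyotype()].
#' @param ... Unused.
#' @return The canonical formula, `""` for the fusion-free complement.
#' @export
format.karyotype <- function(x, ...) {
  if (nrow(x$rbs) == 0L) return("")
  z <- x$rbs$zygosity
  zmin <- x$rbs$zygosity_min %||% z
  zmin[is.na(zmin)] <- z[is.na(zmin)]
  ztxt <- ifelse(zmin < z, paste0(zmin, "-", z), as.character(z))
  paste0(ztxt, "Rb(", x$rbs$arm1, ".", x$rbs$arm2, ")", collapse = ",")
}

#' @export
print.karyotype <- function(x, ...) {
  zmin <- x$rbs$zygosity_min %||% x$rbs$zygosity
  zmin[is.na(zmin)] <- x$rbs$zygosity[is.na(zmin)]
  lo <- x$base_2n - sum(x$rbs$zygosity)
  hi <- x$base_2n - sum(zmin)
  twoN <- if (lo == hi) lo else paste0(lo, "-", hi)
  cat("karyotype: 2n = ", twoN, ", NF = ", x$NF,
      if (nrow(x$rbs) > 0L) paste0(", ", format(x)) else " (no Rb fusions)",
      ", ", x$sex_system, "\n", sep = "")
  invisible(x)
}

#' Predict the F1 hybrid karyotype of two Rb-homozygous parents
#'
#' Each parent, being homozygous for all its fusions, transmits exactly
#' one copy of every fusion it carries, so the F1 carries each parental
#' fusion with zygosity equal to the number of parents carrying it.
#' Parents heterozygous for any fusion are rejected: their gametes are
#' not deterministic.
#'
#' @param p1,p2 Parental [karyotype()]s with all fusions at zygosity 2
#'   and equal `base_2n`.
#' @return The F1 [karyotype()].
#' @export
predict_f1 <- function(p1, p2) {
  stopifnot(inherits(p1, "karyotype"), inherits(p2, "karyotype"))
  if (p1$base_2n != p2$base_2n)
    stop("parents must share base_2n", call. = FALSE)
  if (any(p1$rbs$zygosity != 2L) || any(p2$rbs$zygosity != 2L))
    stop("predict_f1() requires parents homozygous for all fusions",
         call. = FALSE)
  key <- function(k) paste(k$rbs$arm1, k$rbs$arm2, sep = ".")
  all_keys <- union(key(p1), key(p2))
  if (length(all_keys) == 0L) return(karyotype(NULL, base_2n = p1$base_2n,
                                               NF = p1$NF))
  parts <- strsplit(all_keys, ".", fixed = TRUE)
  rbs <- data.frame(
    arm1 = vapply(parts, `[`, character(1L), 1L),
    arm2 = vapply(parts, `[`, character(1L), 2L),
    zygosity = (all_keys %in% key(p1)) + (all_keys %in% key(p2)),
    stringsAsFactors = FALSE
  )
  karyotype(rbs, base_2n = p1$base_2n, NF = p1$NF)
}

#' Check stated against computed diploid numbers
#'
#' For every specimen with both a karyotype formula and a stated 2n
#' (possibly a mosaic range `"50-51"`), recomputes 2n from the formula
#' and flags disagreements.  Mosaic formulas (`"1-2Rb(...)"`) yield a
#' computed range which must cover the stated range.
#'
#' @param metadata Specimen metadata with columns `specimen_id`,
#'   `karyotype` and `karyotype_2n`.
#' @return A data.frame `specimen_id`, `stated_2n`, `computed_2n`,
#'   `consistent` (NA when either side is missing).
#' @export
karyotype_consistency <- function(metadata) {
  parse_range <- function(x) {
    if (is.na(x) || !nzchar(x)) return(c(NA_integer_, NA_integer_))
    p <- as.integer(strsplit(x, "-", fixed = TRUE)[[1L]])
    if (length(p) == 1L) c(p, p) else range(p)
  }
  out <- data.frame(specimen_id = metadata$specimen_id,
                    stated_2n = metadata$karyotype_2n %||% NA_character_,
                    computed_2n = NA_character_, consistent = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(metadata))) {
    f <- metadata$karyotype[i]
    if (is.na(f) || !nzchar(f)) next
    k <- parse_karyotype(f)
    zmin <- k$rbs$zygosity_min
    zmin[is.na(zmin)] <- k$rbs$zygosity[is.na(zmin)]
    lo <- k$base_2n - sum(k$rbs$zygosity)
    hi <- k$base_2n - sum(zmin)
    out$computed_2n[i] <- if (lo == hi) as.character(lo)
                          else paste0(lo, "-", hi)
    st <- parse_range(out$stated_2n[i])
    if (!is.na(st[1L]))
      out$consistent[i] <- st[1L] >= lo && st[2L] <= hi
  }
  out
}
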