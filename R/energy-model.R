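#' Classify an mRNA/piRNA base pair
#'
#' Total, symmetric classification of unordered base pairs over
#' \{A,C,G,U\}: G-C and A-U are canonical, G-U is the wobble pair, A-C is
#' the noncanonical pair recognised by the hybridization model, and every
#' other combination (including identical bases) is a mismatch.
#'
#' @param mrnaBase,pirnaBase character vectors of single bases (recycled
#'   to a common length); `T` is accepted and treated as `U`.
#' @return character vector with values in `"canonical_GC"`,
#'   `"canonical_AU"`, `"wobble_GU"`, `"noncanonical_AC"`, `"mismatch"`.
#' @examples
#' classifyPair("G", "C")   # canonical_GC
#' classifyPair("A", "C")   # noncanonical_AC
#' classifyPair("G", "G")   # mismatch
#' @export
classifyPair <- function(mrnaBase, pirnaBase) {
  a <- .normalizeRna(mrnaBase)
  b <- .normalizeRna(pirnaBase)
  if (any(!a %in% .RNA_BASES) || any(!b %in% .RNA_BASES))
    stop("bases must be single characters in {A, C, G, U}", call. = FALSE)
  key <- paste0(pmin(a, b), pmax(a, b))
  out <- rep("mismatch", length(key))
  out[key == "CG"] <- "canonical_GC"
  out[key == "AU"] <- "canonical_AU"
  out[key == "GU"] <- "wobble_GU"
  out[key == "AC"] <- "noncanonical_AC"
  out
}

# map a classifyPair label to the PairEnergyModel class key
.classKey <- c(canonical_GC = "GC", canonical_AU = "AU",
               wobble_GU = "GU", noncanonical_AC = "AC",
               mismatch = "mismatch")

#' DuplexScore: the score of one ungapped piRNA/mRNA duplex
#'
#' Returned by [scoreDuplex()].  `dG` is the additive hybridization
#' free-energy magnitude of the duplex and `dGm` the magnitude for the
#' fully complementary canonical duplex of the same piRNA, both in
#' kJ/mol (report them with a minus sign); `ratioPct` is `100 * dG/dGm`.
#' The pairing string has one symbol per duplex position in mRNA 5'->3'
#' order: `|` canonical, `:` wobble or noncanonical, `.` mismatch.
#'
#' @slot dG numeric(1), duplex energy magnitude, kJ/mol.
#' @slot dGm numeric(1), maximal (fully canonical) energy magnitude, kJ/mol.
#' @slot ratio numeric(1), percent, `100 * dG / dGm`.
#' @slot pairCounts named integer, pairs per class (`GC`, `AU`, `GU`,
#'   `AC`, `mismatch`); sums to the duplex length.
#' @slot pairing character(1) pairing string.
#' @aliases DuplexScore
#' @exportClass DuplexScore
setClass("DuplexScore",
  representation(dG = "numeric", dGm = "numeric", ratio = "numeric",
                 pairCounts = "integer", pairing = "character"))

setValidity("DuplexScore", function(object) {
  tol <- 1e-9
  if (object@dG < -tol || object@dG > object@dGm + tol)
    return("dG must satisfy 0 <= dG <= dGm")
  if (object@ratio < -tol || object@ratio > 100 + tol)
    return("ratio must lie in [0, 100]")
  if (!identical(names(object@pairCounts), .PAIR_CLASSES))
    return("pairCounts must be named GC, AU, GU, AC, mismatch")
  if (sum(object@pairCounts) != nchar(object@pairing))
    return("pairCounts must sum to the duplex length")
  TRUE
})

#' @describeIn DuplexScore-class duplex free-energy magnitude (kJ/mol).
#' @param x,object a `DuplexScore`.
#' @export
setGeneric("dG", function(x) standardGeneric("dG"))
#' @rdname DuplexScore-class
#' @export
setMethod("dG", "DuplexScore", function(x) x@dG)

#' @describeIn DuplexScore-class maximal canonical energy magnitude (kJ/mol).
#' @export
setGeneric("dGm", function(x) standardGeneric("dGm"))
#' @rdname DuplexScore-class
#' @export
setMethod("dGm", "DuplexScore", function(x) x@dGm)

#' @describeIn DuplexScore-class the dG/dGm percentage.
#' @export
setGeneric("ratioPct", function(x) standardGeneric("ratioPct"))
#' @rdname DuplexScore-class
#' @export
setMethod("ratioPct", "DuplexScore", function(x) x@ratio)

#' @describeIn DuplexScore-class per-class pair counts.
#' @export
setGeneric("pairCounts", function(x) standardGeneric("pairCounts"))
#' @rdname DuplexScore-class
#' @export
setMethod("pairCounts", "DuplexScore", function(x) x@pairCounts)

#' @describeIn DuplexScore-class the pairing string.
#' @export
setGeneric("pairingString", function(x) standardGeneric("pairingString"))
#' @rdname DuplexScore-class
#' @export
setMethod("pairingString", "DuplexScore", function(x) x@pairing)

setMethod("show", "DuplexScore", function(object) {
  cat(sprintf("DuplexScore: dG = -%.1f kJ/mol, dG/dGm = %.1f%%\n",
              object@dG, object@ratio))
  cat("  pairing: ", object@pairing, "\n", sep = "")
})

#' Score one ungapped piRNA/mRNA duplex
#'
#' Pairs an mRNA window with a piRNA of the same length in antiparallel
#' orientation: window position `i` (5'->3') pairs with piRNA position
#' `L - i + 1`, i.e. the piRNA runs 3'->5' beneath the window.  The duplex
#' energy is the sum of the per-pair increments of `model`; no gaps,
#' bulges or stacking terms.
#'
#' @param mrnaWindow mRNA window, 5'->3'; character scalar or
#'   [Biostrings::RNAString]; DNA alphabet is normalized to RNA.
#' @param pirna piRNA sequence, 5'->3'; same length as `mrnaWindow`.
#' @param model a [PairEnergyModel].
#' @return a [DuplexScore-class] object.
#' @examples
#' sc <- scoreDuplex("CCCCC", "GGGGG")
#' dG(sc)        # 5 * 6.37 = 31.85
#' ratioPct(sc)  # 100: fully canonical
#' @export
scoreDuplex <- function(mrnaWindow, pirna, model = PairEnergyModel()) {
  w <- .seqChars(mrnaWindow)
  p <- .seqChars(pirna)
  if (length(w) == 0L)
    stop("empty duplex", call. = FALSE)
  if (length(w) != length(p))
    stop("mRNA window and piRNA must have equal length (ungapped model); got ",
         length(w), " vs ", length(p), call. = FALSE)
  names(w) <- NULL
  .checkAlphabet(paste(w, collapse = ""), "mRNA window")
  .checkAlphabet(paste(p, collapse = ""), "piRNA")
  q <- rev(p)                       # piRNA aligned 3'->5' under the window
  cls <- classifyPair(w, q)
  key <- .classKey[cls]
  e <- pairEnergies(model)
  dg <- sum(e[key])
  dgm <- deltaGmax(paste(p, collapse = ""), model)
  counts <- integer(length(.PAIR_CLASSES))
  names(counts) <- .PAIR_CLASSES
  tab <- table(key)
  counts[names(tab)] <- as.integer(tab)
  sym <- c(canonical_GC = "|", canonical_AU = "|",
           wobble_GU = ":", noncanonical_AC = ":", mismatch = ".")
  new("DuplexScore", dG = dg, dGm = dgm,
      ratio = 100 * dg / dgm, pairCounts = counts,
      pairing = paste(sym[cls], collapse = ""))
}

#' Maximal hybridization energy of a piRNA
#'
#' The energy magnitude `dGm` of a piRNA bound to its fully complementary
#' canonical sequence: each G or C contributes the G-C increment, each A
#' or U the A-U increment.  `dGm` normalizes duplex energies into the
#' dG/dGm selection ratio.
#'
#' @param pirna piRNA sequence (character scalar, [Biostrings::RNAString],
#'   or a set of sequences as a character vector / `RNAStringSet`, in
#'   which case a named numeric vector is returned).
#' @param model a [PairEnergyModel].
#' @return numeric, kJ/mol magnitude(s).
#' @examples
#' deltaGmax("GGCC")  # 4 * 6.37 = 25.48
#' deltaGmax("AUAU")  # 4 * 4.25 = 17.00
#' @export
deltaGmax <- function(pirna, model = PairEnergyModel()) {
  seqs <- vapply(as.character(pirna), .normalizeRna, character(1L))
  .checkAlphabet(seqs, "piRNA")
  e <- pairEnergies(model)
  out <- vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    sum(ifelse(ch %in% c("G", "C"), e[["GC"]], e[["AU"]]))
  }, numeric(1L))
  if (length(out) == 1L && is.null(names(pirna))) out <- unname(out)
  out
}
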