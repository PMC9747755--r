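#' PairEnergyModel: per-pair hybridization energies and hydrogen bonds
#'
#' The additive hybridization model assigns every mRNA/piRNA base pair to
#' one of five classes and gives each class a free-energy increment
#' (stored as a positive magnitude in kJ/mol; reported duplex energies
#' carry a minus sign) and a hydrogen-bond count:
#'
#' \tabular{lll}{
#'   class \tab energy (kJ/mol) \tab H bonds \cr
#'   canonical G-C \tab 6.37 \tab 3 \cr
#'   canonical A-U \tab 4.25 \tab 2 \cr
#'   wobble G-U \tab 2.12 \tab 1 \cr
#'   noncanonical A-C \tab 2.12 \tab 1 \cr
#'   mismatch \tab 0 \tab 0 \cr
#' }
#'
#' The duplex energy is strictly additive over pairs: no stacking, loop or
#' terminal corrections, and mismatches contribute nothing (the dG/dGm
#' selection ratio already bounds mismatch content).  The defaults are the
#' published constants of the model; they can be overridden, but the
#' ordering G-C > A-U > wobble/noncanonical > 0 is enforced so that the
#' fully canonical duplex always attains the maximal energy dGm.
#'
#' @slot energies named numeric, magnitudes in kJ/mol for classes
#'   `GC`, `AU`, `GU`, `AC`, `mismatch`.
#' @slot hbonds named integer, hydrogen-bond counts for the same classes.
#'
#' @examples
#' mod <- PairEnergyModel()
#' pairEnergies(mod)["GC"]   # 6.37 kJ/mol
#' pairHbonds(mod)["AU"]     # 2 hydrogen bonds
#'
#' @seealso [classifyPair()], [scoreDuplex()], [deltaGmax()]
#' @aliases PairEnergyModel
#' @exportClass PairEnergyModel
setClass("PairEnergyModel",
  representation(energies = "numeric", hbonds = "integer"))

.PAIR_CLASSES <- c("GC", "AU", "GU", "AC", "mismatch")

setValidity("PairEnergyModel", function(object) {
  e <- object@energies
  h <- object@hbonds
  if (!identical(names(e), .PAIR_CLASSES))
    return("energies must be named GC, AU, GU, AC, mismatch")
  if (!identical(names(h), .PAIR_CLASSES))
    return("hbonds must be named GC, AU, GU, AC, mismatch")
  if (any(e < 0) || any(h < 0))
    return("energies and hbond counts are magnitudes and must be >= 0")
  if (!(e[["GC"]] > e[["AU"]] && e[["AU"]] > e[["GU"]] &&
        e[["AU"]] > e[["AC"]] && e[["GU"]] > 0 && e[["AC"]] > 0))
    return("required ordering: GC > AU > {GU, AC} > 0")
  if (e[["mismatch"]] != 0 || h[["mismatch"]] != 0L)
    return("mismatches contribute no energy and no hydrogen bonds")
  TRUE
})

#' @describeIn PairEnergyModel-class Constructor; arguments are the
#'   per-class energy magnitudes in kJ/mol and hydrogen-bond counts.
#' @param energyGC,energyAU,energyGU,energyAC per-pair free-energy
#'   magnitudes, kJ/mol.
#' @param hbondsGC,hbondsAU,hbondsGU,hbondsAC hydrogen-bond counts.
#' @return a `PairEnergyModel` object.
#' @export
PairEnergyModel <- function(energyGC = 6.37, energyAU = 4.25,
                            energyGU = 2.12, energyAC = 2.12,
                            hbondsGC = 3L, hbondsAU = 2L,
                            hbondsGU = 1L, hbondsAC = 1L) {
  new("PairEnergyModel",
      energies = c(GC = energyGC, AU = energyAU, GU = energyGU,
                   AC = energyAC, mismatch = 0),
      hbonds = c(GC = as.integer(hbondsGC), AU = as.integer(hbondsAU),
                 GU = as.integer(hbondsGU), AC = as.integer(hbondsAC),
                 mismatch = 0L))
}

#' @describeIn PairEnergyModel-class Named energy magnitudes (kJ/mol).
#' @param object,x a `PairEnergyModel`.
#' @export
setGeneric("pairEnergies", function(x) standardGeneric("pairEnergies"))

#' @rdname PairEnergyModel-class
#' @export
setMethod("pairEnergies", "PairEnergyModel", function(x) x@energies)

#' @describeIn PairEnergyModel-class Named hydrogen-bond counts.
#' @export
setGeneric("pairHbonds", function(x) standardGeneric("pairHbonds"))

#' @rdname PairEnergyModel-class
#' @export
setMethod("pairHbonds", "PairEnergyModel", function(x) x@hbonds)

setMethod("show", "PairEnergyModel", function(object) {
  e <- object@energies
  h <- object@hbonds
  cat("PairEnergyModel (additive hybridization increments)\n")
  for (cl in .PAIR_CLASSES) {
    cat(sprintf("  %-9s %5.2f kJ/mol  %d H bond%s\n",
                cl, e[[cl]], h[[cl]], if (h[[cl]] == 1L) "" else "s"))
  }
})

# 4x4 lookup matrices indexed by encoded bases (A,C,G,U = 1..4).
# Used by the vectorized scanner; scoreDuplex goes through classifyPair.
.energyMatrix <- function(model) {
  .classMatrix(pairEnergies(model))
}

.hbondMatrix <- function(model) {
  .classMatrix(as.numeric(pairHbonds(model)))
}

.classMatrix <- function(values) {
  M <- matrix(values[["mismatch"]], 4L, 4L,
              dimnames = list(.RNA_BASES, .RNA_BASES))
  M["G", "C"] <- M["C", "G"] <- values[["GC"]]
  M["A", "U"] <- M["U", "A"] <- values[["AU"]]
  M["G", "U"] <- M["U", "G"] <- values[["GU"]]
  M["A", "C"] <- M["C", "A"] <- values[["AC"]]
  M
}
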