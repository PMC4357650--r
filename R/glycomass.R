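## Monoisotopic constants (Da). Residue masses are the dehydrated
## monosaccharide increments; a free glycan carries one extra water.
.residueMass <- c(hex = 162.052824, hexnac = 203.079373, dhex = 146.057909,
                  neuac = 291.095417, neugc = 307.090331)
.massWater    <- 18.010565
.massProton   <- 1.0072765
.massSodium   <- 22.989770
.massElectron <- 0.0005486
## [M+Na]+ adds a sodium and loses an electron.
.sodiatedIncrement      <- .massSodium - .massElectron
## glycosylamine reducing end: OH -> NH2 relative to the free form.
.glycosylamineIncrement <- -0.984016
## open-ring reduced alditol: +2H.
.alditolIncrement       <- 2.015650

#' Monoisotopic mass constants
#'
#' Residue and adduct constants used throughout the mass arithmetic:
#' dehydrated residue masses for Hex, HexNAc, deoxyhexose, NeuAc and NeuGc,
#' water, proton, sodium and electron masses, and the derived sodiated
#' (+22.989218), glycosylamine (-0.984016) and alditol (+2.015650)
#' increments.
#'
#' @return named list of constants in Da.
#' @export
massConstants <- function() {
  list(residues = .residueMass, water = .massWater, proton = .massProton,
       sodium = .massSodium, electron = .massElectron,
       sodiated_increment = .sodiatedIncrement,
       glycosylamine_increment = .glycosylamineIncrement,
       alditol_increment = .alditolIncrement)
}

#' Construct a glycan composition
#'
#' @param hex,hexnac,dhex,neuac,neugc non-negative integer residue counts.
#' @return a \linkS4class{GlycanComposition}.
#' @examples
#' man5 <- GlycanComposition(hex = 5, hexnac = 2)
#' compositionMass(man5)   # 1234.4334
#' @export
GlycanComposition <- function(hex = 0, hexnac = 0, dhex = 0, neuac = 0, neugc = 0) {
  n <- c(hex, hexnac, dhex, neuac, neugc)
  if (anyNA(n) || any(n < 0) || any(n != round(n)))
    stop("invalid composition: residue counts must be non-negative integers")
  new("GlycanComposition", hex = as.integer(hex), hexnac = as.integer(hexnac),
      dhex = as.integer(dhex), neuac = as.integer(neuac), neugc = as.integer(neugc))
}

.compositionCounts <- function(c) {
  c(hex = c@hex, hexnac = c@hexnac, dhex = c@dhex, neuac = c@neuac, neugc = c@neugc)
}

setMethod("show", "GlycanComposition", function(object) {
  n <- .compositionCounts(object)
  lab <- c("Hex", "HexNAc", "dHex", "NeuAc", "NeuGc")
  s <- paste0("(", lab[n > 0], ")", n[n > 0], collapse = "")
  if (!nzchar(s)) s <- "(empty)"
  cat("GlycanComposition ", s, "  [M] = ", sprintf("%.4f", compositionMass(object)),
      "\n", sep = "")
})

#' Neutral monoisotopic mass of a glycan composition
#'
#' Sum of the dehydrated residue masses plus one water.
#'
#' @param composition a \linkS4class{GlycanComposition}.
#' @return neutral monoisotopic mass in Da.
#' @export
compositionMass <- function(composition) {
  stopifnot(is(composition, "GlycanComposition"))
  validObject(composition)
  sum(.compositionCounts(composition) * .residueMass) + .massWater
}

#' Sodiated ion m/z
#'
#' \eqn{[M+Na]^+} = neutral mass + sodium - one electron.
#'
#' @inheritParams compositionMass
#' @return m/z in Da.
#' @export
sodiatedMz <- function(composition) {
  compositionMass(composition) + .sodiatedIncrement
}

#' Sodiated glycosylamine m/z
#'
#' The glycosylamine form retains an amine at the reducing-end HexNAc C1
#' and sits 0.984016 Da below the free-reducing-end sodiated ion. Requires
#' at least one HexNAc to carry the reducing end.
#'
#' @inheritParams compositionMass
#' @return m/z in Da.
#' @export
glycosylamineSodiatedMz <- function(composition) {
  stopifnot(is(composition, "GlycanComposition"))
  if (composition@hexnac < 1)
    stop("glycosylamine form requires a reducing-end HexNAc (hexnac >= 1)")
  sodiatedMz(composition) + .glycosylamineIncrement
}

#' Reduced-alditol negative ion m/z
#'
#' The borohydride-reduced (open-ring alditol) glycan gains 2.015650 Da;
#' deprotonated negative ions are \eqn{[M_{red}-H]^-} (charge 1) and
#' \eqn{[M_{red}-2H]^{2-}} (charge 2).
#'
#' @inheritParams compositionMass
#' @param charge 1 or 2 (negative polarity).
#' @return m/z in Da.
#' @export
alditolIonMz <- function(composition, charge = 2) {
  if (!charge %in% c(1, 2)) stop("unsupported charge: must be 1 or 2")
  mred <- compositionMass(composition) + .alditolIncrement
  (mred - charge * .massProton) / charge
}

#' Signed parts-per-million mass error
#'
#' @param observed,calculated m/z in Da; \code{calculated} must be positive.
#' @return 1e6 * (observed - calculated) / calculated.
#' @export
ppmError <- function(observed, calculated) {
  if (any(calculated <= 0)) stop("calculated mass must be positive")
  1e6 * (observed - calculated) / calculated
}

.ionFormMz <- function(composition, form) {
  switch(form,
    "M"                = compositionMass(composition),
    "M+Na"             = sodiatedMz(composition),
    "M-H"              = alditolIonMz(composition, 1),
    "M-2H(2-)"         = alditolIonMz(composition, 2),
    "glycosylamine+Na" = glycosylamineSodiatedMz(composition),
    stop("unknown ion form: ", form))
}

#' Annotate an observed mass against a glycan library
#'
#' Scans every (library record, ion form) pair and returns the matches whose
#' signed ppm error is within tolerance, sorted by |ppm|. Forms that a
#' record cannot take (glycosylamine without HexNAc) are skipped.
#'
#' @param observed observed m/z (Da).
#' @param library a glycan library data.frame as returned by
#'   \code{\link{readGlycanLibrary}} (columns name, hex, hexnac, dhex,
#'   neuac, neugc).
#' @param forms character vector of ion forms among
#'   \code{c("M", "M+Na", "M-H", "M-2H(2-)", "glycosylamine+Na")}.
#' @param tolerancePpm match tolerance (> 0).
#' @return data.frame with columns name, form, calculated_mz, ppm; zero rows
#'   when nothing matches.
#' @examples
#' lib <- readGlycanLibrary(system.file("extdata", "kidney_glycans.csv",
#'                                      package = "glycoMSI"))
#' annotateMass(1257.473, lib, forms = "M+Na", tolerancePpm = 100)
#' @export
annotateMass <- function(observed, library, forms = "M+Na", tolerancePpm = 100) {
  if (tolerancePpm <= 0) stop("tolerancePpm must be > 0")
  out <- list()
  for (i in seq_len(nrow(library))) {
    comp <- GlycanComposition(library$hex[i], library$hexnac[i], library$dhex[i],
                              library$neuac[i], library$neugc[i])
    for (f in forms) {
      if (f == "glycosylamine+Na" && comp@hexnac < 1) next
      calc <- .ionFormMz(comp, f)
      ppm <- ppmError(observed, calc)
      if (abs(ppm) <= tolerancePpm)
        out[[length(out) + 1L]] <- data.frame(
          name = library$name[i], form = f, calculated_mz = calc, ppm = ppm,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(name = character(), form = character(),
                      calculated_mz = numeric(), ppm = numeric()))
  res <- do.call(rbind, out)
  res[order(abs(res$ppm)), , drop = FALSE]
}
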