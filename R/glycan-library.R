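#' Parse a glycan composition string
#'
#' Accepts both total-count notation (\code{"Man5GlcNAc2"},
#' \code{"Hex5HexNAc4dHex1"}, \code{"Man_5_GlcNAc_2_"}) and the
#' delta-plus-core notation \code{"(Hex)2(HexNAc)2 + (Man)3(GlcNAc)2"},
#' folding the chitobiose core into the totals (Man/Gal/Glc count as Hex,
#' GlcNAc/GalNAc as HexNAc, Fuc/Deoxyhexose as dHex).
#'
#' @param x a single composition string.
#' @return a \linkS4class{GlycanComposition}.
#' @export
parseComposition <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  s <- gsub("[[:space:]+]", "", x)
  classOf <- c(Hexose = "hex", HexNAc = "hexnac", GlcNAc = "hexnac",
               GalNAc = "hexnac", Man = "hex", Gal = "hex", Glc = "hex",
               Hex = "hex", Deoxyhexose = "dhex", dHex = "dhex", Fuc = "dhex",
               NeuAc = "neuac", NeuGc = "neugc")
  ## longest names first so Hex never shadows HexNAc
  alt <- paste(names(classOf)[order(-nchar(names(classOf)))], collapse = "|")
  pat <- sprintf("\\(?(%s)\\)?_?([0-9]+)_?", alt)
  mm <- gregexpr(pat, s, perl = TRUE)
  if (mm[[1]][1] == -1) stop("cannot parse composition: ", x)
  if (sum(attr(mm[[1]], "match.length")) != nchar(s))
    stop("unrecognised tokens in composition: ", x)
  counts <- c(hex = 0L, hexnac = 0L, dhex = 0L, neuac = 0L, neugc = 0L)
  for (tok in regmatches(s, mm)[[1]]) {
    parts <- regmatches(tok, regexec(pat, tok, perl = TRUE))[[1]]
    counts[classOf[[parts[2]]]] <- counts[classOf[[parts[2]]]] + as.integer(parts[3])
  }
  GlycanComposition(counts["hex"], counts["hexnac"], counts["dhex"],
                    counts["neuac"], counts["neugc"])
}

#' Read a glycan composition library
#'
#' CSV with columns \code{name, hex, hexnac, dhex, neuac, neugc} and an
#' optional \code{reference_sodiated_mz}. When a reference mass is present
#' it must agree with the computed sodiated mass to 0.002 Da; disagreement
#' is an error (it almost always means a transcription mistake).
#'
#' Two libraries ship with the package under \code{inst/extdata}:
#' \code{gly3_standards.csv}, the three-component calibration standard, and
#' \code{kidney_glycans.csv}, the murine-kidney N-glycan compositions.
#'
#' @param path CSV file path.
#' @return data.frame with the library plus a computed \code{sodiated_mz}.
#' @export
readGlycanLibrary <- function(path) {
  if (!file.exists(path)) stop("glycan library not found: ", path)
  lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "hex", "hexnac", "dhex", "neuac", "neugc")
  if (!all(need %in% names(lib)))
    stop("glycan library ", path, " must have columns: ", paste(need, collapse = ", "))
  lib$sodiated_mz <- vapply(seq_len(nrow(lib)), function(i)
    sodiatedMz(GlycanComposition(lib$hex[i], lib$hexnac[i], lib$dhex[i],
                                 lib$neuac[i], lib$neugc[i])), numeric(1))
  if ("reference_sodiated_mz" %in% names(lib)) {
    ok <- is.na(lib$reference_sodiated_mz) |
      abs(lib$reference_sodiated_mz - lib$sodiated_mz) <= 0.002
    if (!all(ok))
      stop("library ", path, ": reference sodiated mass disagrees with the ",
           "computed mass by > 0.002 Da for: ",
           paste(lib$name[!ok], collapse = ", "))
  }
  lib
}
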