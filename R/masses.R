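# Element inference and atomic masses. Standard atomic weights (amu) for the
# elements that occur in protein/nucleic-acid PDB files; unknowns fall back
# to carbon with a warning.

ELEMENT_MASSES <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
  S = 32.06, SE = 78.971, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  NA. = 22.990, MG = 24.305, K = 39.098, CA = 40.078, MN = 54.938,
  FE = 55.845, CO = 58.933, NI = 58.693, CU = 63.546, ZN = 65.38
)

#' Infer element symbols from PDB atom names
#'
#' Strips digits and primes, then matches two-letter then one-letter
#' symbols; leading digits (as in "1H5'") are handled.
#'
#' @param name character vector of atom names.
#' @return character vector of element symbols.
#' @export
guess_element <- function(name) {
  nm <- toupper(gsub("['*\"]", "", trimws(name)))
  nm <- sub("^[0-9]+", "", nm)
  vapply(nm, function(x) {
    two <- substr(x, 1, 2)
    two <- sub("[0-9]+$", "", two)
    # note: "CA"/"NA" are deliberately absent (C-alpha vs calcium clash);
    # ions normally carry an explicit element column
    if (nchar(two) == 2 && two %in% c("SE", "CL", "BR", "MG", "MN", "FE",
                                      "ZN", "CU", "NI", "CO"))
      return(two)
    substr(x, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

#' Atomic masses for element symbols
#'
#' @param element character vector of element symbols.
#' @return numeric masses in amu; unknown elements get the carbon mass with
#'   a warning.
#' @export
element_mass <- function(element) {
  key <- toupper(trimws(element))
  key[key == "NA"] <- "NA."
  m <- ELEMENT_MASSES[key]
  bad <- is.na(m)
  if (any(bad)) {
    warning("unknown element(s) ", paste(unique(key[bad]), collapse = ","),
            "; assigning carbon mass")
    m[bad] <- ELEMENT_MASSES[["C"]]
  }
  unname(m)
}
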