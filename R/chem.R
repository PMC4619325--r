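# Elemental formulas, monoisotopic masses, adduct m/z and carbon
# isotopolog ratios. All masses in Da; the mass scale is fixed by 12C = 12.

# Most-abundant-isotope masses. Static so that calculated masses are
# reproducible independent of any external mass table.
.ISOTOPE_MASS <- c(
  H  = 1.0078250319,
  C  = 12.0,
  N  = 14.0030740052,
  O  = 15.9949146221,
  F  = 18.9984031627,
  Na = 22.9897692820,
  P  = 30.9737615120,
  S  = 31.9720706912,
  Cl = 34.9688527100,
  K  = 38.9637064864
)

# CODATA proton mass; electron-mass correct for protonated/deprotonated ions.
.PROTON_MASS <- 1.00727646
.ELECTRON_MASS <- 0.000548579909

# IUPAC isotopic abundances of carbon.
.C13_ABUNDANCE <- 0.0107
.C12_ABUNDANCE <- 0.9893

# 13C - 12C mass difference, used for the M+1 isotopolog trace.
.C13_C12_DELTA <- 1.00335484

#' Parse a molecular formula
#'
#' Parses a Hill-notation molecular formula string (e.g. `"C12H18O3"`)
#' into per-element atom counts. Element symbols are a capital letter
#' optionally followed by a lowercase letter; a missing count means 1.
#'
#' @param text Formula string, e.g. `"C12H18O3"`.
#' @return An object of class `formula_counts`: a named integer vector of
#'   atom counts.
#' @examples
#' parse_formula("C12H18O3")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("formula must be a single non-empty string", call. = FALSE)
  text <- trimws(text)
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  parts <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (length(parts) == 0L || paste(parts, collapse = "") != text)
    stop(sprintf("cannot parse formula '%s'", text), call. = FALSE)
  sym <- sub("[0-9]+$", "", parts)
  cnt <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", parts)))
  cnt[is.na(cnt)] <- 1L
  unknown <- setdiff(sym, names(.ISOTOPE_MASS))
  if (length(unknown) > 0L)
    stop(sprintf("unknown element symbol(s) in '%s': %s", text,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  counts <- tapply(cnt, factor(sym, levels = unique(sym)), sum)
  counts <- as.integer(counts)
  names(counts) <- unique(sym)
  if (sum(counts) < 1L)
    stop("formula contains no atoms", call. = FALSE)
  structure(counts, class = "formula_counts")
}

#' Canonical Hill-order formula string
#'
#' Carbon first, then hydrogen, then remaining elements alphabetically
#' (alphabetical throughout if there is no carbon).
#'
#' @param f A `formula_counts` object from [parse_formula()].
#' @return A single string.
#' @export
formula_to_string <- function(f) {
  sym <- names(f)
  if ("C" %in% sym) {
    rest <- sort(setdiff(sym, c("C", "H")))
    ord <- c("C", intersect("H", sym), rest)
  } else {
    ord <- sort(sym)
  }
  n <- unclass(f)[ord]
  paste0(ord, ifelse(n == 1L, "", n), collapse = "")
}

#' Monoisotopic mass of a formula
#'
#' Sum of count times most-abundant-isotope mass over all elements,
#' with 12C = 12 exactly.
#'
#' @param f A `formula_counts` object or formula string.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C12H18O3")  # 210.1256
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  sum(unclass(f) * .ISOTOPE_MASS[names(f)])
}

# Built-in ion species: mass delta (Da) relative to the neutral
# monoisotopic mass and signed charge. Deltas are electron-mass correct.
.ION_SPECIES <- list(
  "[M+H]+"   = list(mass_delta =  1.00727646,  charge =  1L),
  "[M+Na]+"  = list(mass_delta = 22.98922070,  charge =  1L),
  "[M+NH4]+" = list(mass_delta = 18.03382555,  charge =  1L),
  "[M+K]+"   = list(mass_delta = 38.96315791,  charge =  1L),
  "[M-H]-"   = list(mass_delta = -1.00727646,  charge = -1L),
  "[M+Cl]-"  = list(mass_delta = 34.96940129,  charge = -1L)
)

#' Ion species definition
#'
#' Returns a built-in ion species by label, or constructs a user-defined
#' one from an explicit mass delta and charge.
#'
#' @param label Ion species label, e.g. `"[M+H]+"`.
#' @param mass_delta Mass added to the neutral monoisotopic mass (Da);
#'   required for labels that are not built in.
#' @param charge Signed integer charge; `abs(charge) >= 1`.
#' @return A list with elements `label`, `mass_delta`, `charge`.
#' @export
ion_species <- function(label, mass_delta = NULL, charge = NULL) {
  stopifnot(is.character(label), length(label) == 1L)
  if (is.null(mass_delta) || is.null(charge)) {
    hit <- .ION_SPECIES[[label]]
    if (is.null(hit))
      stop(sprintf(
        "unknown ion species '%s'; supply mass_delta and charge, or one of: %s",
        label, paste(names(.ION_SPECIES), collapse = ", ")), call. = FALSE)
    mass_delta <- hit$mass_delta
    charge <- hit$charge
  }
  charge <- as.integer(charge)
  if (abs(charge) < 1L) stop("charge must satisfy |charge| >= 1", call. = FALSE)
  list(label = label, mass_delta = as.numeric(mass_delta), charge = charge)
}

#' List built-in ion species labels
#' @return Character vector of labels.
#' @export
list_ion_species <- function() names(.ION_SPECIES)

#' m/z of an ion species
#'
#' `(neutral_mass + mass_delta) / |charge|`. For `[M+H]+` the delta is
#' the proton mass (1.00727646 Da), i.e. the electron mass is accounted
#' for.
#'
#' @param neutral_mass Neutral monoisotopic mass (Da), positive.
#' @param ion Ion species label or an [ion_species()] list.
#' @return m/z value.
#' @examples
#' adduct_mz(monoisotopic_mass("C12H18O3"), "[M+H]+")  # 211.1329
#' @export
adduct_mz <- function(neutral_mass, ion) {
  stopifnot(is.numeric(neutral_mass), neutral_mass > 0)
  if (is.character(ion)) ion <- ion_species(ion)
  mz <- (neutral_mass + ion$mass_delta) / abs(ion$charge)
  if (!is.finite(mz) || mz <= 0)
    stop("computed m/z is not finite and positive", call. = FALSE)
  mz
}

#' Theoretical carbon isotopolog ratio (RIA)
#'
#' Relative isotopolog abundance of the first carbon isotopic peak:
#' intensity(M+1) / intensity(M), approximated from carbon alone as
#' `nC * a13 / a12` with IUPAC abundances. The carbon-only approximation
#' is biased for formulas rich in N, O or S, whose minor isotopes also
#' contribute to M+1; it is intended for carbon-number estimation, not
#' full isotope-pattern prediction.
#'
#' @param f A `formula_counts` object or formula string with at least one
#'   carbon atom.
#' @return Expected M+1/M intensity ratio.
#' @examples
#' theoretical_ria("C12H18O3")  # about 0.1298
#' @export
theoretical_ria <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  nc <- if ("C" %in% names(f)) unclass(f)[["C"]] else 0L
  if (is.na(nc) || nc < 1L)
    stop("RIA requires at least one carbon atom", call. = FALSE)
  nc * .C13_ABUNDANCE / .C12_ABUNDANCE
}

`%||%` <- function(a, b) if (is.null(a)) b else a
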