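# Elemental-composition arithmetic and exact-mass bookkeeping shared by all
# other modules. Only the elements that occur in sebum lipids and their
# sodium/potassium adducts are supported (C, 13C, H, O, Na, K).

# Monoisotopic atomic masses in Da (CODATA/IUPAC), pinned in code so that
# published ion m/z values reproduce to <= 0.0005 Da.
.ATOMIC_MASS <- c(
  C   = 12.0,
  C13 = 13.0033548378,
  H   = 1.00782503207,
  O   = 15.9949146196,
  Na  = 22.9897692809,
  K   = 38.9637064864
)
.ELECTRON_MASS <- 0.00054857990907
.ELEMENTS <- names(.ATOMIC_MASS)

#' Monoisotopic atomic mass table
#'
#' Returns the fixed table of monoisotopic masses (Da) used throughout the
#' package: \eqn{^{12}}C, \eqn{^{13}}C, \eqn{^{1}}H, \eqn{^{16}}O,
#' \eqn{^{23}}Na, \eqn{^{39}}K, plus the electron mass under the name
#' \code{electron}.
#'
#' @return Named numeric vector of masses in Da.
#' @examples
#' atomic_masses()[["Na"]]
#' @export
atomic_masses <- function() {
  c(.ATOMIC_MASS, electron = .ELECTRON_MASS)
}

#' Create an elemental composition
#'
#' The unit of all mass arithmetic in the package: integer atom counts for
#' \eqn{^{12}}C, \eqn{^{13}}C, H, O, Na and K. Compositions can be added and
#' subtracted with \code{+} and \code{-}; subtraction that would drive any
#' count negative is an error.
#'
#' @param C,H,O,Na,K,C13 Non-negative integer atom counts. \code{C} counts
#'   \eqn{^{12}}C only; isotopologues set \code{C13}.
#' @return An object of class \code{elemcomp} (named integer vector).
#' @examples
#' tg48 <- elemental_composition(C = 51, H = 98, O = 6)
#' monoisotopic_mass(tg48)
#' @seealso [parse_formula()], [format_formula()], [monoisotopic_mass()]
#' @export
elemental_composition <- function(C = 0, H = 0, O = 0, Na = 0, K = 0, C13 = 0) {
  counts <- c(C = C, C13 = C13, H = H, O = O, Na = Na, K = K)
  .validate_counts(counts)
  structure(as.integer(round(counts[.ELEMENTS])), names = .ELEMENTS,
            class = "elemcomp")
}

.validate_counts <- function(counts) {
  if (length(counts) != length(.ELEMENTS) || anyNA(counts))
    stop("invalid composition: six finite atom counts required", call. = FALSE)
  if (any(counts < 0))
    stop("invalid composition: negative atom count", call. = FALSE)
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("invalid composition: atom counts must be integers", call. = FALSE)
  invisible(counts)
}

#' @export
Ops.elemcomp <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "=="))
    stop("operation '", .Generic, "' not defined for compositions", call. = FALSE)
  if (.Generic == "==")
    return(all(unclass(e1) == unclass(e2)))
  res <- unclass(e1) + if (.Generic == "+") unclass(e2) else -unclass(e2)
  if (any(res < 0))
    stop("invalid composition: subtraction gives a negative atom count",
         call. = FALSE)
  structure(as.integer(res), names = .ELEMENTS, class = "elemcomp")
}

#' @export
print.elemcomp <- function(x, ...) {
  cat("<composition>", format_formula(x), "\n")
  invisible(x)
}

#' Write a composition as a formula string
#'
#' Canonical Hill-like text form with element order C, \eqn{^{13}}C
#' (written \code{[13C]n}), H, O, Na, K; unit counts omit the number.
#' Round-trips bit-exactly through [parse_formula()].
#'
#' @param comp An \code{elemcomp}.
#' @return A single string, e.g. \code{"C51H98O6Na"}.
#' @export
format_formula <- function(comp) {
  stopifnot(inherits(comp, "elemcomp"))
  sym <- c(C = "C", C13 = "[13C]", H = "H", O = "O", Na = "Na", K = "K")
  parts <- vapply(.ELEMENTS, function(el) {
    n <- comp[[el]]
    if (n == 0L) "" else if (n == 1L) sym[[el]] else paste0(sym[[el]], n)
  }, character(1))
  out <- paste0(parts, collapse = "")
  if (!nzchar(out)) "" else out
}

#' Parse a formula string into a composition
#'
#' Inverse of [format_formula()]. Accepts element tokens C, H, O, Na, K and
#' the isotope token \code{[13C]}, each followed by an optional count.
#'
#' @param x A single formula string, e.g. \code{"C10H19O2Na2"}.
#' @return An \code{elemcomp}.
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  counts <- c(C = 0L, C13 = 0L, H = 0L, O = 0L, Na = 0L, K = 0L)
  rest <- x
  pat <- "^(\\[13C\\]|Na|K|C|H|O)([0-9]*)"
  while (nzchar(rest)) {
    m <- regmatches(rest, regexec(pat, rest))[[1]]
    if (length(m) == 0L || !nzchar(m[1]))
      stop("cannot parse formula '", x, "' near '", rest, "'", call. = FALSE)
    el <- switch(m[2], "[13C]" = "C13", m[2])
    n <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    counts[[el]] <- counts[[el]] + n
    rest <- substring(rest, nchar(m[1]) + 1L)
  }
  elemental_composition(C = counts[["C"]], H = counts[["H"]], O = counts[["O"]],
                        Na = counts[["Na"]], K = counts[["K"]],
                        C13 = counts[["C13"]])
}

#' Monoisotopic mass of a composition
#'
#' @param comp An \code{elemcomp}.
#' @return Mass in Da (0 for the all-zero composition).
#' @examples
#' monoisotopic_mass(parse_formula("C30H50")) # squalene
#' @export
monoisotopic_mass <- function(comp) {
  stopifnot(inherits(comp, "elemcomp"))
  .validate_counts(unclass(comp))
  sum(unclass(comp) * .ATOMIC_MASS[.ELEMENTS])
}

#' m/z of an intact cation
#'
#' The composition must be that of the whole cation, including any adducted
#' Na/K. The electron mass is subtracted: at m/z 800 it amounts to 0.7 ppm,
#' which is not negligible against the 2 ppm annotation tolerance.
#'
#' @param comp Cation composition (\code{elemcomp}).
#' @param charge Positive integer charge (default 1).
#' @return m/z value: \code{(mass - charge * m_e) / charge}.
#' @examples
#' ion_mz(parse_formula("C30H50Na"))      # sodiated squalene, 433.3805
#' ion_mz(parse_formula("C10H19O2Na2"))   # disodiated decanoic acid, 217.117
#' @export
ion_mz <- function(comp, charge = 1L) {
  if (length(charge) != 1L || is.na(charge) || charge < 1 ||
      abs(charge - round(charge)) > 1e-9)
    stop("charge must be a positive integer", call. = FALSE)
  charge <- as.integer(round(charge))
  (monoisotopic_mass(comp) - charge * .ELECTRON_MASS) / charge
}

#' Double bond equivalents of a neutral parent
#'
#' Neutral-parent convention: the composition must be that of the neutral
#' parent molecule, i.e. with any cationizing Na/K removed (see
#' [neutralize_ion()]). A salt-forming Na/K (e.g. the sodium of a sodium
#' carboxylate) counts as one H, so that disodiated fatty-acid ions come out
#' at DBE 1 and sodiated monounsaturated TG ions at DBE 4, matching the
#' class bookkeeping of saturated TGs at DBE 3 (three ester groups).
#'
#' @param comp Neutral-parent composition.
#' @return Integer DBE; a non-integer result raises a convention-violation
#'   error (the caller most likely passed an intact ion).
#' @examples
#' dbe(parse_formula("C51H98O6"))  # saturated TG -> 3
#' @export
dbe <- function(comp) {
  stopifnot(inherits(comp, "elemcomp"))
  h_eff <- comp[["H"]] + comp[["Na"]] + comp[["K"]]
  val <- comp[["C"]] + comp[["C13"]] + 1 - h_eff / 2
  if (abs(val - round(val)) > 1e-9)
    stop("non-integer DBE: composition violates the neutral-parent ",
         "convention (did you pass an intact cation?)", call. = FALSE)
  as.integer(round(val))
}

#' Z value (hydrogen deficiency) of a neutral parent
#'
#' The Z of the heteroatom-class general form C_cH_{2c-Z}O_wNa_xK_y;
#' \code{Z = 2 * (DBE - 1)} and is always even.
#'
#' @inheritParams dbe
#' @return Even integer Z.
#' @export
z_value <- function(comp) {
  2L * (dbe(comp) - 1L)
}

#' Strip the cationizing adduct from an ion composition
#'
#' Removes one K (preferred, as the heavier substitution) or one Na from an
#' adducted cation, giving the neutral parent used by [dbe()] and
#' [z_value()]. Salt-forming Na (e.g. of a sodium carboxylate) is left in
#' place, where it counts as one H for unsaturation bookkeeping.
#'
#' @param comp Cation composition carrying at least one Na or K.
#' @return Neutral-parent \code{elemcomp}.
#' @export
neutralize_ion <- function(comp) {
  stopifnot(inherits(comp, "elemcomp"))
  if (comp[["K"]] > 0L)
    comp - elemental_composition(K = 1)
  else if (comp[["Na"]] > 0L)
    comp - elemental_composition(Na = 1)
  else
    stop("composition carries no Na/K adduct to remove", call. = FALSE)
}
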