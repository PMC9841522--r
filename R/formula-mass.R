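# Molecular-formula parsing and exact / average mass computation.
#
# The mass table pins monoisotopic masses (mass of the most abundant isotope,
# AME2020/NIST) and IUPAC standard atomic weights (2021 abridged values;
# interval elements use the conventional single value). Carbon-12 is exactly
# 12 u by definition of the unified scale. Only elements that occur in small-
# molecule screening chemistry are tabulated; parsing validates any official
# IUPAC symbol and the mass functions error if a parsed element has no entry.

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og")

# monoisotopic mass of the most abundant isotope / standard atomic weight, u
.mass_table <- local({
  m <- rbind(
    H  = c(1.00782503207,  1.008),
    D  = c(2.01410177785,  2.014),  # deuterium, for labelled formulas
    B  = c(11.0093053645, 10.81),
    C  = c(12.0,          12.011),
    N  = c(14.0030740048, 14.007),
    O  = c(15.9949146196, 15.999),
    F  = c(18.9984031627, 18.998403163),
    Na = c(22.9897692820, 22.98976928),
    Mg = c(23.985041697,  24.305),
    Si = c(27.9769265347, 28.085),
    P  = c(30.9737619984, 30.973761998),
    S  = c(31.9720711744, 32.06),
    Cl = c(34.968852682,  35.45),
    K  = c(38.9637064864, 39.0983),
    Ca = c(39.962590863,  40.078),
    Fe = c(55.934936326,  55.845),
    Zn = c(63.929142220,  65.38),
    Se = c(79.916521800,  78.971),
    Br = c(78.9183376,    79.904),
    I  = c(126.9044719,  126.90447))
  colnames(m) <- c("monoisotopic", "average")
  m
})

.electron_mass_u <- 0.000548579909

#' Masses known to the formula mass calculator
#'
#' @return data.frame with columns `element`, `monoisotopic` (mass in u of the
#'   most abundant isotope) and `average` (standard atomic weight in u)
#' @export
mass_table <- function() {
  data.frame(element = rownames(.mass_table),
             monoisotopic = .mass_table[, "monoisotopic"],
             average = .mass_table[, "average"],
             row.names = NULL)
}

#' Parse a molecular formula in Hill notation
#'
#' Accepts formulas as printed in mass-spectrometry experimental sections,
#' e.g. `"C16H15N4OS+"` for an \[M+H\]+ ion: element symbols with optional
#' integer subscripts and an optional trailing charge suffix. Digits before
#' a trailing sign are element subscripts (as printed in HRMS formulas);
#' multiple charges are written sign-first (`"Fe+2"`) or as repeated signs
#' (`"Ca++"`); the typographic minus `−` is accepted.
#'
#' @param text a single non-empty formula string
#' @return an object of class `mol_formula`: list with `counts` (named
#'   integer vector, element -> count, in order of first appearance) and
#'   `charge` (integer, elementary charges)
#' @examples
#' f <- parse_formula("C16H15N4OS+")
#' f$counts
#' f$charge
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty formula string")

  # Digits before a trailing sign are element subscripts ("...O2S2+" is two
  # sulfurs, charge +1); multi-charges are written sign-first ("Fe+2") or as
  # repeated signs ("Ca++").
  charge <- 0L
  cm <- regmatches(text, regexpr("([+]|-|−)([0-9]+)$", text))[1]
  if (!is.na(cm) && nzchar(cm)) {
    sgn <- if (startsWith(cm, "+")) 1L else -1L
    charge <- sgn * as.integer(gsub("[^0-9]", "", cm))
    text <- substr(text, 1, nchar(text) - nchar(cm))
  } else {
    cm <- regmatches(text, regexpr("([+]+|[-−]+)$", text))[1]
    if (!is.na(cm) && nzchar(cm)) {
      sgn <- if (startsWith(cm, "+")) 1L else -1L
      charge <- sgn * nchar(cm)
      text <- substr(text, 1, nchar(text) - nchar(cm))
    }
  }
  if (abs(charge) > 10) stop("charge magnitude > 10 in formula: ", charge)

  counts <- integer(0)
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    m <- regmatches(rest, regexpr("^([A-Z][a-z]?)([0-9]*)", rest))[1]
    if (is.na(m) || !nzchar(m))
      stop("malformed formula at position ", pos, ": '", rest, "'")
    sym <- gsub("[0-9]", "", m)
    # two-letter greedy match can swallow a following one-letter element's
    # lowercase? no: lowercase letters never start a symbol, so greedy is safe
    if (!(sym %in% c(.element_symbols, "D")))
      stop("unknown element symbol '", sym, "' at position ", pos)
    cnt <- gsub("[^0-9]", "", m)
    cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
    if (cnt < 1) stop("non-positive count for ", sym, " at position ", pos)
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + cnt
    pos <- pos + nchar(m)
  }
  if (!length(counts)) stop("formula contains no element tokens: '", text, "'")
  structure(list(counts = counts, charge = charge), class = "mol_formula")
}

#' Render a formula back to Hill notation
#'
#' Carbon first, then hydrogen, then remaining elements alphabetically;
#' charge appended as `+`/`-` with a trailing multiplicity when
#' |charge| > 1 (`"+2"`). `parse_formula(render_formula(f))` round-trips.
#'
#' @param f a `mol_formula`
#' @return character scalar
#' @export
render_formula <- function(f) {
  stopifnot(inherits(f, "mol_formula"))
  cnt <- f$counts
  ord <- if ("C" %in% names(cnt)) {
    c(intersect(c("C", "H"), names(cnt)),
      sort(setdiff(names(cnt), c("C", "H"))))
  } else sort(names(cnt))
  body <- paste0(vapply(ord, function(s)
    paste0(s, if (cnt[[s]] > 1) cnt[[s]] else ""), character(1)),
    collapse = "")
  ch <- f$charge
  suffix <- if (ch == 0) "" else
    paste0(if (ch > 0) "+" else "-", if (abs(ch) > 1) abs(ch) else "")
  paste0(body, suffix)
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<mol_formula> ", render_formula(x), "\n", sep = "")
  invisible(x)
}

#' Merge two formulas (counts add, charges add)
#'
#' @param f1,f2 `mol_formula` objects
#' @return a `mol_formula`
#' @export
formula_add <- function(f1, f2) {
  stopifnot(inherits(f1, "mol_formula"), inherits(f2, "mol_formula"))
  counts <- f1$counts
  for (s in names(f2$counts))
    counts[s] <- (if (s %in% names(counts)) counts[[s]] else 0L) + f2$counts[[s]]
  structure(list(counts = counts, charge = f1$charge + f2$charge),
            class = "mol_formula")
}

.formula_mass <- function(f, column, electron_correct) {
  stopifnot(inherits(f, "mol_formula"))
  missing <- setdiff(names(f$counts), rownames(.mass_table))
  if (length(missing))
    stop("no mass tabulated for element(s): ", paste(missing, collapse = ", "))
  m <- sum(.mass_table[names(f$counts), column] * f$counts)
  if (electron_correct) m <- m - f$charge * .electron_mass_u
  m
}

#' Monoisotopic mass of a formula
#'
#' Sum of per-element monoisotopic masses. By default no electron-mass
#' correction is applied for charged species, which matches the convention of
#' most printed HRMS calcd m/z values for \[M+H\]+ ions; set
#' `electron_correct = TRUE` to subtract `charge` electron masses
#' (0.00054858 u each) for the strict ion mass.
#'
#' @param f a `mol_formula` (or a formula string, parsed on the fly)
#' @param digits decimals for half-up rounding (default 4, HRMS convention);
#'   `NA` for the unrounded value
#' @param electron_correct logical, subtract charge x electron mass
#' @return mass in u
#' @examples
#' monoisotopic_mass("C16H15N4OS+")   # 311.0967
#' monoisotopic_mass(parse_formula("H2O"))
#' @export
monoisotopic_mass <- function(f, digits = 4, electron_correct = FALSE) {
  if (is.character(f)) f <- parse_formula(f)
  m <- .formula_mass(f, "monoisotopic", electron_correct)
  if (is.na(digits)) m else round_half_up(m, digits)
}

#' Average (standard atomic weight) mass of a formula
#'
#' @inheritParams monoisotopic_mass
#' @param digits decimals for half-up rounding (default 1, low-resolution MS
#'   convention); `NA` for unrounded
#' @return mass in u
#' @examples
#' average_mass("C13H12N3O2S2+")   # 306.4
#' @export
average_mass <- function(f, digits = 1, electron_correct = FALSE) {
  if (is.character(f)) f <- parse_formula(f)
  m <- .formula_mass(f, "average", electron_correct)
  if (is.na(digits)) m else round_half_up(m, digits)
}

#' Batch mass computation over a table of formulas
#'
#' @param formulas character vector of Hill-notation formulas
#' @param mode `"mono"` or `"avg"`
#' @param electron_correct logical
#' @param digits decimals (default: 4 for mono, 1 for avg)
#' @return data.frame with columns `formula`, `charge`, `mass`
#' @export
mass_table_batch <- function(formulas, mode = c("mono", "avg"),
                             electron_correct = FALSE, digits = NULL) {
  mode <- match.arg(mode)
  digits <- digits %||% if (mode == "mono") 4 else 1
  fn <- if (mode == "mono") monoisotopic_mass else average_mass
  parsed <- lapply(formulas, parse_formula)
  data.frame(
    formula = formulas,
    charge = vapply(parsed, function(p) p$charge, integer(1)),
    mass = vapply(parsed, fn, numeric(1), digits = digits,
                  electron_correct = electron_correct))
}
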