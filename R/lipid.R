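# Lipid shorthand parsing and formatting, molecular formula construction,
# monoisotopic mass and adduct m/z calculation.
#
# Names follow the sum-composition shorthand
# "[class]([total carbons]:[total double bonds])", e.g. PC(34:1), with
# optional ether prefixes (O- alkyl, P- alkenyl/plasmalogen), sphingoid
# prefixes (d = dihydroxy, t = trihydroxy), explicit chain splits such as
# ST(d18:1/24:1), hydroxyl modifiers such as (2-OH), and ambiguous
# alternatives joined by "|" where accurate mass alone cannot discriminate,
# e.g. PE(O-36:5)|PE(P-36:4).

LIPID_CLASSES <- c("FA", "CAR", "WE", "PA", "CDP-DG", "PC", "PE", "PG",
                   "PI", "PS", "LPA", "LPC", "SM", "PE-Cer", "ST",
                   "HexCer", "FMC")

# classes whose formulas are built algebraically from (carbons, double bonds)
ALGEBRAIC_CLASSES <- c("FA", "CAR", "LPA", "LPC", "PA", "PC", "PE", "PG",
                       "PI", "PS", "SM")
LOOKUP_CLASSES <- c("CDP-DG", "ST", "HexCer", "FMC", "PE-Cer", "WE")

.parse_one <- function(s, offset = 0) {
  perr <- function(pos, what)
    stop(sprintf("lipid name parse error at position %d: %s",
                 pos + offset, what), call. = FALSE)
  # class code: everything before the first "(" (allows FMC-6, PE-Cer, CDP-DG)
  op <- regexpr("(", s, fixed = TRUE)
  if (op < 0) perr(nchar(s) + 1, "expected '('")
  cls_raw <- substr(s, 1, op - 1)
  cls <- sub("^(FMC)-\\d+$", "\\1", cls_raw)  # FMC-6 -> class FMC
  if (!cls %in% LIPID_CLASSES)
    perr(1, paste0("unknown lipid class '", cls_raw, "'"))
  if (substr(s, nchar(s), nchar(s)) != ")")
    perr(nchar(s), "expected ')'")
  body <- substr(s, op + 1, nchar(s) - 1)
  if (!nzchar(body)) perr(op + 1, "empty composition")

  ether <- NA_character_
  if (grepl("^[OP]-", body)) {
    ether <- substr(body, 1, 1)
    body <- substr(body, 3, nchar(body))
  }
  sphingoid <- NA_character_
  if (grepl("^[dt]\\d", body)) {
    sphingoid <- substr(body, 1, 1)
    body <- substr(body, 2, nchar(body))
  }
  chain_strs <- strsplit(body, "/", fixed = TRUE)[[1]]
  chains <- lapply(chain_strs, function(ch) {
    oh <- 0L
    while (grepl("\\(\\d+-OH\\)$", ch)) {
      oh <- oh + 1L
      pos <- regexpr("\\(\\d+-OH\\)$", ch)
      ch <- substr(ch, 1, pos - 1)
    }
    m <- regmatches(ch, regexec("^(\\d+):(\\d+)$", ch))[[1]]
    if (!length(m))
      perr(op + 1, paste0("malformed chain '", ch,
                          "' (expected carbons:double_bonds)"))
    list(carbons = as.integer(m[2]), double_bonds = as.integer(m[3]),
         hydroxyls = oh)
  })
  carbons <- sum(vapply(chains, `[[`, integer(1), "carbons"))
  dbs <- sum(vapply(chains, `[[`, integer(1), "double_bonds"))
  ohs <- sum(vapply(chains, `[[`, integer(1), "hydroxyls"))
  if (carbons <= 0) perr(op + 1, "carbon count must be positive")
  list(class = cls, class_label = cls_raw, ether = ether,
       sphingoid = sphingoid, chains = chains,
       carbons = carbons, double_bonds = dbs, hydroxyls = ohs)
}

#' Parse a lipid shorthand name
#'
#' @param s a name such as \code{"PC(34:1)"}, \code{"PE(O-36:5)|PE(P-36:4)"},
#'   \code{"ST(d18:1/24:1)"} or \code{"FMC-6(d18:1/22:0(2-OH))"}.
#' @return an object of class \code{lipid_name} with an \code{alternatives}
#'   list (one element per "|" alternative); the first alternative's fields
#'   (\code{class}, \code{ether}, \code{sphingoid}, \code{carbons},
#'   \code{double_bonds}) are mirrored at the top level for convenience.
#'   Malformed input raises a parse error with the offending position.
#' @examples
#' x <- parse_lipid_name("PE(O-36:5)|PE(P-36:4)")
#' length(x$alternatives)  # 2
#' format(x)
#' @export
parse_lipid_name <- function(s) {
  stopifnot(is.character(s), length(s) == 1)
  parts <- strsplit(s, "|", fixed = TRUE)[[1]]
  if (!length(parts)) stop("lipid name parse error at position 1: empty name",
                           call. = FALSE)
  offs <- c(0, cumsum(nchar(parts) + 1))[seq_along(parts)]
  alts <- Map(.parse_one, parts, offs)
  first <- alts[[1]]
  structure(list(alternatives = unname(alts),
                 class = first$class, ether = first$ether,
                 sphingoid = first$sphingoid, carbons = first$carbons,
                 double_bonds = first$double_bonds),
            class = "lipid_name")
}

.format_one <- function(a) {
  chain_str <- vapply(a$chains, function(ch)
    paste0(ch$carbons, ":", ch$double_bonds,
           if (ch$hydroxyls > 0) strrep("(2-OH)", ch$hydroxyls) else ""),
    character(1))
  paste0(a$class_label, "(",
         if (!is.na(a$ether)) paste0(a$ether, "-") else "",
         if (!is.na(a$sphingoid)) a$sphingoid else "",
         paste(chain_str, collapse = "/"), ")")
}

#' @export
format.lipid_name <- function(x, ...) {
  paste(vapply(x$alternatives, .format_one, character(1)), collapse = "|")
}

#' @export
print.lipid_name <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# ---- molecular formulas ----------------------------------------------------

ELEMENTS <- c("C", "H", "N", "O", "P", "S")

#' Construct / manipulate element-count formulas
#'
#' A formula is a named integer vector over C, H, N, O, P, S.
#'
#' @param C,H,N,O,P,S element counts.
#' @return named integer vector of class \code{lipid_formula}.
#' @export
make_formula <- function(C = 0, H = 0, N = 0, O = 0, P = 0, S = 0) {
  f <- c(C = C, H = H, N = N, O = O, P = P, S = S)
  if (any(f < 0)) stop("element counts must be nonnegative")
  structure(as.integer(f), names = ELEMENTS, class = "lipid_formula")
}

#' @rdname make_formula
#' @param s a Hill-style formula string like \code{"C42H82NO8P"}.
#' @export
parse_formula <- function(s) {
  f <- make_formula()
  for (m in regmatches(s, gregexpr("([A-Z][a-z]?)(\\d*)", s))[[1]]) {
    el <- sub("\\d*$", "", m)
    n <- sub("^[A-Za-z]+", "", m)
    if (!el %in% ELEMENTS) stop("unsupported element: ", el)
    f[el] <- f[el] + if (nzchar(n)) as.integer(n) else 1L
  }
  f
}

#' @rdname make_formula
#' @param f a \code{lipid_formula}.
#' @export
format_formula <- function(f) {
  paste0(vapply(ELEMENTS[f > 0], function(el)
    paste0(el, if (f[el] > 1) f[el] else ""), character(1)), collapse = "")
}

# bundled formula lookup for the classes without a closed-form rule
.lookup_env <- new.env(parent = emptyenv())

lipid_lookup_table <- function() {
  if (is.null(.lookup_env$tab)) {
    path <- system.file("extdata", "lipid_lookup.tsv", package = "lipidmsi")
    .lookup_env$tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  .lookup_env$tab
}

#' Molecular formula of a lipid
#'
#' For the algebraically supported classes (FA, CAR, LPA, LPC, PA, PC, PE,
#' PG, PI, PS, SM, plus their O-/P- ether variants) the formula is computed
#' from closed-form per-class rules in total carbons C and double bonds D,
#' e.g. PC(C:D) = C(C+8) H(2C-2D+16) N O8 P; the O- variant is the diacyl
#' formula minus O plus H2 and the P- variant minus O. The remaining classes
#' (CDP-DG, ST, HexCer, FMC, PE-Cer, WE) are resolved against the bundled
#' lookup table. Hydroxyl modifiers add one O each.
#'
#' For an ambiguous "A|B" name the alternatives must agree on the formula
#' (they do for O-/P- pairs, which are isomeric); disagreement is an error.
#'
#' @param name a \code{lipid_name} or a string to parse.
#' @return a \code{lipid_formula}.
#' @export
lipid_formula <- function(name) {
  if (is.character(name)) name <- parse_lipid_name(name)
  forms <- lapply(name$alternatives, .formula_one)
  if (length(forms) > 1) {
    same <- vapply(forms[-1], identical, logical(1), y = forms[[1]])
    if (!all(same))
      stop("ambiguous name alternatives have different formulas")
  }
  forms[[1]]
}

.formula_one <- function(a) {
  C <- a$carbons; D <- a$double_bonds
  f <- switch(a$class,
    FA  = make_formula(C = C,     H = 2 * C - 2 * D,      O = 2),
    CAR = make_formula(C = C + 7, H = 2 * C - 2 * D + 13, N = 1, O = 4),
    LPA = make_formula(C = C + 3, H = 2 * C - 2 * D + 7,  O = 7, P = 1),
    LPC = make_formula(C = C + 8, H = 2 * C - 2 * D + 18, N = 1, O = 7,
                       P = 1),
    PA  = make_formula(C = C + 3, H = 2 * C - 2 * D + 5,  O = 8, P = 1),
    PC  = make_formula(C = C + 8, H = 2 * C - 2 * D + 16, N = 1, O = 8,
                       P = 1),
    PE  = make_formula(C = C + 5, H = 2 * C - 2 * D + 10, N = 1, O = 8,
                       P = 1),
    PG  = make_formula(C = C + 6, H = 2 * C - 2 * D + 11, O = 10, P = 1),
    PI  = make_formula(C = C + 9, H = 2 * C - 2 * D + 15, O = 13, P = 1),
    PS  = make_formula(C = C + 6, H = 2 * C - 2 * D + 10, N = 1, O = 10,
                       P = 1),
    SM  = make_formula(C = C + 5, H = 2 * C - 2 * D + 13, N = 2, O = 6,
                       P = 1),
    NULL)
  if (is.null(f)) {
    if (!a$class %in% LOOKUP_CLASSES)
      stop("no formula rule for class ", a$class,
           "; algebraic classes: ", paste(ALGEBRAIC_CLASSES, collapse = ", "),
           "; lookup classes: ", paste(LOOKUP_CLASSES, collapse = ", "))
    key <- .format_one(a)
    tab <- lipid_lookup_table()
    hit <- match(key, tab$name)
    if (is.na(hit))
      stop("lipid ", key, " is not in the bundled lookup table ",
           "(class ", a$class, " has no closed-form formula rule)")
    return(parse_formula(tab$formula[hit]))
  }
  if (!is.na(a$ether)) {
    if (a$class %in% c("FA", "CAR", "SM"))
      stop("ether prefix not supported for class ", a$class)
    f["O"] <- f["O"] - 1L
    if (a$ether == "O") f["H"] <- f["H"] + 2L
  }
  if (a$hydroxyls > 0) f["O"] <- f["O"] + a$hydroxyls
  if (any(f < 0)) stop("implausible composition: negative element count")
  f
}

# ---- masses and adducts ----------------------------------------------------

# monoisotopic masses of the principal isotopes
ISOTOPE_MASS <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                  O = 15.9949146221, P = 30.97376151, S = 31.97207069)
ELECTRON_MASS <- 0.00054857990924
PROTON_MASS <- ISOTOPE_MASS[["H"]] - ELECTRON_MASS

# adduct rules: mass shift (includes the electron), charge sign, mode
ADDUCT_TABLE <- data.frame(
  adduct = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M-H]-", "[M+Cl]-"),
  shift = c(PROTON_MASS,
            22.98976928 - ELECTRON_MASS,
            38.9637064864 - ELECTRON_MASS,
            -PROTON_MASS,
            34.96885268 + ELECTRON_MASS),
  mode = c("pos", "pos", "pos", "neg", "neg"),
  stringsAsFactors = FALSE
)

#' Monoisotopic mass of a formula
#'
#' Sum of principal-isotope masses (12C exactly 12, 1H 1.0078250319, ...).
#'
#' @param f a \code{lipid_formula} or formula string.
#' @return mass in Da.
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  sum(as.numeric(f) * ISOTOPE_MASS[names(f)])
}

#' m/z of an adduct ion
#'
#' Adds or subtracts the adduct mass including the electron mass; supported
#' adducts are [M+H]+, [M+Na]+, [M+K]+, [M-H]-, [M+Cl]- (singly charged).
#'
#' @param mass neutral monoisotopic mass in Da.
#' @param adduct adduct label.
#' @return m/z in Th.
#' @export
adduct_mz <- function(mass, adduct) {
  i <- match(adduct, ADDUCT_TABLE$adduct)
  if (is.na(i)) stop("unknown adduct '", adduct, "'; supported: ",
                     paste(ADDUCT_TABLE$adduct, collapse = ", "))
  mass + ADDUCT_TABLE$shift[i]
}

#' Mode of an adduct
#' @param adduct adduct label.
#' @return "pos" or "neg".
#' @export
adduct_mode <- function(adduct) {
  i <- match(adduct, ADDUCT_TABLE$adduct)
  if (is.na(i)) stop("unknown adduct '", adduct, "'")
  ADDUCT_TABLE$mode[i]
}
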