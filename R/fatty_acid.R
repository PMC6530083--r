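# Atomic masses (5 significant figures); masses reported to 2 decimals.
.ATOMIC_MASS <- c(C = 12.011, H = 1.008, O = 15.999)
.CH2_MASS <- 14.027

#' Parse fatty-acid shorthand notation
#'
#' Parses the field-standard `"C<carbons>:<double_bonds>"` notation (e.g.
#' `"C18:1"` for oleic acid) into a validated `fatty_acid` object. Parsing is
#' case-insensitive and tolerates surrounding whitespace; the stored label is
#' always the canonical upper-case form, so labels round-trip through the
#' parser.
#'
#' @param notation Character vector of labels such as `"C16:0"`, `"C22:6"`.
#' @return A `fatty_acid` object: a data frame with columns `label`,
#'   `carbons` and `double_bonds`, one row per acid.
#' @examples
#' fatty_acid(c("C16:0", "C18:1", "c22:6 "))
#' @export
fatty_acid <- function(notation) {
  if (inherits(notation, "fatty_acid")) return(notation)
  if (is.data.frame(notation) &&
      all(c("carbons", "double_bonds") %in% names(notation)))
    return(new_fatty_acid(notation$carbons, notation$double_bonds))
  if (!is.character(notation) || length(notation) == 0)
    stop("'notation' must be a non-empty character vector")
  clean <- toupper(gsub("[[:space:]]", "", notation))
  m <- regmatches(clean, regexec("^C([0-9]+):([0-9]+)$", clean))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("malformed fatty-acid notation (expected 'C<carbons>:<double_bonds>'): ",
         paste(sQuote(notation[bad]), collapse = ", "))
  carbons <- vapply(m, function(g) as.integer(g[2]), 1L)
  db <- vapply(m, function(g) as.integer(g[3]), 1L)
  new_fatty_acid(carbons, db)
}

#' @rdname fatty_acid
#' @param carbons Integer chain length(s), at least 4.
#' @param double_bonds Integer double-bond count(s), non-negative and
#'   chemically possible for the chain length.
#' @export
new_fatty_acid <- function(carbons, double_bonds) {
  carbons <- as.integer(carbons)
  double_bonds <- as.integer(double_bonds)
  stopifnot(length(carbons) == length(double_bonds))
  if (any(carbons < 4L))
    stop("chain length below C4 is not a fatty acid: C", paste(carbons[carbons < 4L], collapse = ", C"))
  if (any(double_bonds < 0L))
    stop("negative double-bond count")
  impossible <- double_bonds > (carbons - 1L) %/% 2L
  if (any(impossible))
    stop("impossible double-bond count for chain length: ",
         paste0("C", carbons[impossible], ":", double_bonds[impossible], collapse = ", "))
  out <- data.frame(label = paste0("C", carbons, ":", double_bonds),
                    carbons = carbons, double_bonds = double_bonds,
                    stringsAsFactors = FALSE)
  class(out) <- c("fatty_acid", "data.frame")
  out
}

#' Molecular mass of a fatty acid
#'
#' Mass of the free acid CnH(2n-2d)O2 from atomic masses (C 12.011, H 1.008,
#' O 15.999), or of the corresponding methyl ester (one CH2, 14.027 g/mol,
#' heavier).
#'
#' @param acid A `fatty_acid` object or character notation accepted by
#'   [fatty_acid()].
#' @param basis `"free_acid"` (default) or `"methyl_ester"`.
#' @return Numeric vector of masses in g/mol.
#' @examples
#' molecular_mass(fatty_acid("C18:1"))            # 282.47
#' molecular_mass("C16:0", basis = "methyl_ester") # 270.46
#' @export
molecular_mass <- function(acid, basis = c("free_acid", "methyl_ester")) {
  basis <- match.arg(basis)
  fa <- fatty_acid(acid)
  n <- fa$carbons
  h <- 2L * n - 2L * fa$double_bonds
  mass <- n * .ATOMIC_MASS[["C"]] + h * .ATOMIC_MASS[["H"]] + 2 * .ATOMIC_MASS[["O"]]
  if (basis == "methyl_ester") mass <- mass + .CH2_MASS
  unname(mass)
}

#' @export
print.fatty_acid <- function(x, ...) {
  cat("Fatty acid(s):", paste(x$label, collapse = ", "), "\n")
  invisible(x)
}
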