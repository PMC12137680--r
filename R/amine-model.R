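#' Residue table with two-amine flags
#'
#' The ninhydrin reaction detects free amine groups. Every residue carries the
#' backbone alpha-amine; roughly 30% of the proteinogenic amino acids carry a
#' second ninhydrin-reactive amine on the side chain (glutamine and arginine
#' being the canonical examples). The exact membership of that 30% class is a
#' convention, so it is configurable.
#'
#' @param two_amine character vector of one-letter codes flagged as carrying a
#'   second reactive amine group. The default set of six codes reproduces the
#'   30% fraction (6/20).
#' @return An object of class `residue_table`: a list with elements `residues`
#'   (the 20 standard one-letter codes) and `two_amine`.
#' @examples
#' tab <- residue_table()
#' two_amine_fraction(tab)  # 0.3
#' @export
residue_table <- function(two_amine = c("Q", "R", "K", "N", "H", "W")) {
  residues <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  two_amine <- toupper(as.character(two_amine))
  bad <- setdiff(two_amine, residues)
  if (length(bad))
    stop("unknown residue code(s) in two_amine: ", paste(bad, collapse = ", "))
  structure(list(residues = residues, two_amine = sort(unique(two_amine))),
            class = "residue_table")
}

#' @rdname residue_table
#' @param table a `residue_table`
#' @export
two_amine_fraction <- function(table = residue_table()) {
  length(table$two_amine) / length(table$residues)
}

#' @export
print.residue_table <- function(x, ...) {
  cat("Residue table:", length(x$residues), "residues;",
      length(x$two_amine), "two-amine (",
      paste(x$two_amine, collapse = ""), "), fraction",
      format(two_amine_fraction(x)), "\n")
  invisible(x)
}

#' Count free amine groups on a short peptide
#'
#' Each peptide, whatever its length, exposes exactly one backbone alpha-amine;
#' every residue flagged as two-amine contributes one additional reactive
#' group. A tripeptide of three glutamines therefore counts 4 amine groups, a
#' glutamine-arginine dipeptide counts 3, and a single free glutamine is read
#' by the assay as 2 amino-acid equivalents.
#'
#' @param sequence character string of 1-3 one-letter residue codes.
#' @param table a [residue_table()].
#' @return integer amine-group count (always >= 1).
#' @examples
#' count_amine_groups("QQQ")  # 4
#' count_amine_groups("GG")   # 1
#' @export
count_amine_groups <- function(sequence, table = residue_table()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- toupper(strsplit(sequence, "", fixed = TRUE)[[1]])
  if (length(chars) < 1L || length(chars) > 3L)
    stop("sequence must have 1-3 residues, got ", length(chars))
  bad <- setdiff(chars, table$residues)
  if (length(bad))
    stop("unknown residue code: ", paste(unique(bad), collapse = ", "))
  1L + sum(chars %in% table$two_amine)
}

#' Classify a peptide into the model's species classes
#'
#' Free amino acids form class `A`; dipeptides fall into classes `x1`-`x3` and
#' tripeptides into `y1`-`y4`, the index being the number of intact free amine
#' groups the molecule presents to the assay before hydrolysis.
#'
#' @inheritParams count_amine_groups
#' @return one of `"A"`, `"x1"`, `"x2"`, `"x3"`, `"y1"`, `"y2"`, `"y3"`, `"y4"`.
#' @examples
#' classify_peptide("QQ")   # "x3"
#' classify_peptide("QGG")  # "y2"
#' @export
classify_peptide <- function(sequence, table = residue_table()) {
  n <- count_amine_groups(sequence, table)
  len <- nchar(sequence)
  if (len == 1L) "A" else if (len == 2L) paste0("x", n) else paste0("y", n)
}

#' Number of distinct peptide sequences of a given length
#'
#' @param length peptide length, 2 or 3.
#' @param alphabet_size number of residue types (default 20).
#' @return `alphabet_size ^ length` (400 dipeptides, 8000 tripeptides for the
#'   standard alphabet).
#' @export
enumerate_peptide_count <- function(length, alphabet_size = 20L) {
  if (!length %in% c(2L, 3L)) stop("length must be 2 or 3")
  n <- as.numeric(alphabet_size)^as.integer(length)
  if (n <= .Machine$integer.max) as.integer(n) else n
}

#' Species composition in amine-group-equivalent units
#'
#' Abundances are non-negative reals (concentration equivalents): `A` free
#' amino acids (assumed to carry exactly one amine group each inside the
#' model), dipeptide classes `x1`-`x3` and tripeptide classes `y1`-`y4`
#' indexed by intact amine-group count.
#'
#' @param A,x1,x2,x3,y1,y2,y3,y4 non-negative class abundances.
#' @return object of class `composition` (a named numeric vector).
#' @export
composition <- function(A = 0, x1 = 0, x2 = 0, x3 = 0,
                        y1 = 0, y2 = 0, y3 = 0, y4 = 0) {
  v <- vapply(list(A = A, x1 = x1, x2 = x2, x3 = x3,
                   y1 = y1, y2 = y2, y3 = y3, y4 = y4),
              function(z) as.numeric(z)[1], numeric(1))
  if (any(!is.finite(v)) || any(v < 0))
    stop("composition fields must be finite and non-negative")
  structure(v, class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat("Composition (amine-group-equivalent units):\n")
  print(unclass(x))
  cat("dipeptides x =", format(sum(x[c("x1", "x2", "x3")])),
      " tripeptides y =", format(sum(x[c("y1", "y2", "y3", "y4")])), "\n")
  invisible(x)
}

#' Forward model: composition to (F, T) readings
#'
#' Before hydrolysis the assay reads F = A + x1 + 2 x2 + 3 x3 + y1 + 2 y2 +
#' 3 y3 + 4 y4. Hydrolysis breaks every peptide bond, so each dipeptide
#' releases one further amine group and each tripeptide two: a class-`i`
#' dipeptide yields i + 1 groups and a class-`i` tripeptide i + 2, giving
#' T = F + x + 2 y.
#'
#' @param c a [composition()].
#' @return named numeric `c(F = , T = )`, class `amine_readings`.
#' @examples
#' forward_readings(composition(y1 = 1))  # F = 1, T = 3 (the W = 3 ceiling)
#' @export
forward_readings <- function(c) {
  if (!inherits(c, "composition")) c <- do.call(composition, as.list(c))
  f <- c[["A"]] + c[["x1"]] + 2 * c[["x2"]] + 3 * c[["x3"]] +
    c[["y1"]] + 2 * c[["y2"]] + 3 * c[["y3"]] + 4 * c[["y4"]]
  x <- c[["x1"]] + c[["x2"]] + c[["x3"]]
  y <- c[["y1"]] + c[["y2"]] + c[["y3"]] + c[["y4"]]
  structure(c(F = f, T = f + x + 2 * y), class = "amine_readings")
}
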