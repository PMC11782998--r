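#' @keywords internal
"_PACKAGE"

# Monoisotopic residue masses (Da), standard 20 amino acids, 5+ decimals.
AA_MONO <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

MASS_WATER  <- 18.01056   # Da, monoisotopic H2O
MASS_PROTON <- 1.00728    # Da
MASS_CAM    <- 57.02146   # Da, carbamidomethyl (iodoacetamide on Cys)
MASS_13C    <- 1.0033548  # Da, 13C - 12C
MASS_15N    <- 0.9970349  # Da, 15N - 14N

#' Construct a peptide
#'
#' A peptide is an ordered string of one-letter amino-acid codes with
#' optional modifications and an isotope-label state. The heavy state
#' models a stable-isotope-labelled standard (SILS) carrying a
#' 13C6,15N4 substitution on every arginine (+10.0083 Da each).
#' Carbamidomethylation (+57.02146 Da) is applied to every cysteine by
#' default, matching iodoacetamide alkylation chemistry.
#'
#' @param sequence One-letter amino-acid string (20 standard codes).
#' @param label `"light"` or `"heavy"`.
#' @param modifications List of modifications, each
#'   `list(pos = <1-based position>, delta = <Da>)` or
#'   `list(residue = <one-letter code>, delta = <Da>)` (applied to every
#'   matching residue; matching zero positions is allowed).
#' @param carbamidomethyl Apply the fixed +57.02146 Da cysteine
#'   modification (default `TRUE`).
#' @return An object of class `"peptide"`.
#' @examples
#' peptide("GAFQQAAQILR", label = "heavy")
#' @export
peptide <- function(sequence, label = c("light", "heavy"),
                    modifications = list(), carbamidomethyl = TRUE) {
  label <- match.arg(label)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  residues <- strsplit(sequence, "")[[1]]
  if (length(residues) == 0L) stop("peptide sequence must be non-empty")
  bad <- setdiff(residues, names(AA_MONO))
  if (length(bad)) {
    stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
  }
  n <- length(residues)
  deltas <- numeric(n)
  if (carbamidomethyl) deltas[residues == "C"] <- MASS_CAM
  for (m in modifications) {
    if (!is.list(m) || is.null(m$delta)) {
      stop("each modification must be a list with a 'delta' mass")
    }
    if (!is.null(m$pos)) {
      if (m$pos < 1 || m$pos > n) {
        stop("modification position ", m$pos, " outside sequence bounds")
      }
      deltas[m$pos] <- deltas[m$pos] + m$delta
    } else if (!is.null(m$residue)) {
      deltas[residues == m$residue] <- deltas[residues == m$residue] + m$delta
    } else {
      stop("modification needs a 'pos' or 'residue' rule")
    }
  }
  if (label == "heavy") {
    deltas[residues == "R"] <- deltas[residues == "R"] +
      label_delta(n13C = 6, n15N = 4)
  }
  structure(
    list(sequence = sequence, residues = residues, label = label,
         residue_deltas = deltas),
    class = "peptide"
  )
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf("<peptide> %s [%s], neutral mass %.4f Da\n",
              x$sequence, x$label, peptide_neutral_mass(x)))
  invisible(x)
}

#' Mass shift of an isotope substitution
#'
#' Delta mass of replacing `n13C` 12C atoms with 13C and `n15N` 14N
#' atoms with 15N. The 13C6,15N4 arginine label used for SILS peptides
#' gives 10.0083 Da.
#'
#' @param n13C,n15N Non-negative substitution counts.
#' @return Delta mass in Da.
#' @examples
#' label_delta(6, 4)  # 10.0083
#' @export
label_delta <- function(n13C = 0, n15N = 0) {
  if (n13C < 0 || n15N < 0) stop("substitution counts must be non-negative")
  n13C * MASS_13C + n15N * MASS_15N
}

#' Monoisotopic neutral mass of a peptide
#'
#' Sum of monoisotopic residue masses plus water (18.01056 Da) plus all
#' modification deltas and, for heavy peptides, the label delta on every
#' arginine.
#'
#' @param pep A [peptide()].
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_neutral_mass(peptide("GAFQQAAQILR"))  # 1201.657
#' @export
peptide_neutral_mass <- function(pep) {
  stopifnot(inherits(pep, "peptide"))
  sum(AA_MONO[pep$residues]) + sum(pep$residue_deltas) + MASS_WATER
}

#' Precursor m/z
#'
#' `(neutral mass + charge * 1.00728) / charge`.
#'
#' @param pep A [peptide()].
#' @param charge Positive integer charge state.
#' @return m/z.
#' @examples
#' precursor_mz(peptide("GAFQQAAQILR"), 2)  # 601.8 at 1 d.p.
#' @export
precursor_mz <- function(pep, charge) {
  if (charge < 1) stop("charge must be >= 1")
  (peptide_neutral_mass(pep) + charge * MASS_PROTON) / charge
}

#' Fragment-ion m/z
#'
#' y-ions are C-terminal fragments (`index` residues plus water); b-ions
#' are N-terminal fragments (`index` residues, no water). Modification
#' and label deltas travel with their residues. The y-ion covering the
#' whole chain equals the singly protonated precursor.
#'
#' @param pep A [peptide()].
#' @param type `"y"` or `"b"`.
#' @param index Fragment length, `1 <= index < nchar(sequence)` (the
#'   full-length y-ion `index == nchar(sequence)` is permitted as the
#'   precursor identity).
#' @param charge Positive integer fragment charge.
#' @return m/z.
#' @examples
#' fragment_mz(peptide("GAFQQAAQILR"), "y", 3, 1)  # 401.3 at 1 d.p.
#' @export
fragment_mz <- function(pep, type = c("y", "b"), index, charge = 1) {
  type <- match.arg(type)
  stopifnot(inherits(pep, "peptide"))
  n <- length(pep$residues)
  if (index < 1 || index > n) stop("fragment index out of range")
  if (charge < 1) stop("charge must be >= 1")
  idx <- if (type == "y") seq(n - index + 1L, n) else seq_len(index)
  neutral <- sum(AA_MONO[pep$residues[idx]]) + sum(pep$residue_deltas[idx]) +
    if (type == "y") MASS_WATER else 0
  (neutral + charge * MASS_PROTON) / charge
}

# round half away from zero, as printed transition lists do
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Build an MRM transition table
#'
#' One row per (peptide, fragment) with light and heavy precursor and
#' product m/z. Internal computation is full precision; `*_mz_*` display
#' columns are rounded half-up to one decimal as printed transition
#' lists are. Collision energy and retention time are carried through.
#'
#' @param peptides List of [peptide()] objects (their `label` is
#'   ignored: light and heavy variants are derived per row).
#' @param fragments List, parallel to `peptides`, of data frames with
#'   columns `type` ("y"/"b"), `index`, `charge`, and optionally
#'   `ce` (collision energy, eV) and `rt` (retention time, min).
#' @param precursor_charge Integer vector, parallel to `peptides`.
#' @return A data frame with full-precision and 1-d.p. m/z columns.
#' @examples
#' tt <- build_transition_table(
#'   list(peptide("GAFQQAAQILR")),
#'   list(data.frame(type = "y", index = c(7, 6, 3), charge = 1)),
#'   precursor_charge = 2)
#' tt$product_mz_light
#' @export
build_transition_table <- function(peptides, fragments, precursor_charge) {
  stopifnot(length(peptides) == length(fragments),
            length(peptides) == length(precursor_charge))
  rows <- list()
  for (i in seq_along(peptides)) {
    pl <- peptides[[i]]
    light <- peptide(pl$sequence, label = "light",
                     carbamidomethyl = FALSE)
    # carry the original deltas minus the label so explicit mods survive
    light$residue_deltas <- pl$residue_deltas -
      ifelse(pl$residues == "R" & pl$label == "heavy",
             label_delta(6, 4), 0)
    heavy <- light
    heavy$label <- "heavy"
    heavy$residue_deltas <- light$residue_deltas +
      ifelse(light$residues == "R", label_delta(6, 4), 0)
    fr <- fragments[[i]]
    if (is.null(fr$charge)) fr$charge <- 1L
    z <- precursor_charge[i]
    for (j in seq_len(nrow(fr))) {
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = pl$sequence,
        precursor_charge = z,
        precursor_mz_light = round_half_up(precursor_mz(light, z), 1),
        precursor_mz_heavy = round_half_up(precursor_mz(heavy, z), 1),
        fragment = paste0(fr$type[j], fr$index[j]),
        fragment_charge = fr$charge[j],
        product_mz_light = round_half_up(
          fragment_mz(light, fr$type[j], fr$index[j], fr$charge[j]), 1),
        product_mz_heavy = round_half_up(
          fragment_mz(heavy, fr$type[j], fr$index[j], fr$charge[j]), 1),
        collision_energy = if (!is.null(fr$ce)) fr$ce[j] else NA_real_,
        retention_time = if (!is.null(fr$rt)) fr$rt[j] else NA_real_
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(
      sequence = character(), precursor_charge = integer(),
      precursor_mz_light = numeric(), precursor_mz_heavy = numeric(),
      fragment = character(), fragment_charge = integer(),
      product_mz_light = numeric(), product_mz_heavy = numeric(),
      collision_energy = numeric(), retention_time = numeric()
    ))
  }
  do.call(rbind, rows)
}

#' Write / read a transition table
#'
#' Plain CSV, column layout interoperable with common targeted-proteomics
#' transition lists.
#'
#' @param x Transition table from [build_transition_table()].
#' @param path File path.
#' @return `read_transition_table` returns the data frame.
#' @export
write_transition_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transition_table
#' @export
read_transition_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
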