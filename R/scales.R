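# pKa sets and the pH-dependent lipophilicity scale.

AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Ionizable side chains and their charge sign when ionized.
ACIDIC_GROUPS <- c("D", "E", "C", "Y", "Cterm")
BASIC_GROUPS  <- c("K", "R", "H", "Nterm")
IONIZABLE_AA  <- c("D", "E", "C", "Y", "K", "R", "H")
ALL_GROUPS    <- c(IONIZABLE_AA, "Nterm", "Cterm")

# Built-in pKa sets. "expasy" is the Bjellqvist-style set used by common
# isoelectric-point servers; "calculator" follows the values popularized by
# the Scripps protein calculator. Both cover the 7 ionizable side chains
# plus the free alpha-amino and alpha-carboxyl termini.
.pka_builtin <- list(
  expasy = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0,
             K = 10.0, R = 12.0, H = 5.98, Nterm = 7.5, Cterm = 3.55),
  calculator = c(D = 4.4, E = 4.4, C = 8.5, Y = 10.0,
                 K = 10.0, R = 12.0, H = 6.5, Nterm = 8.0, Cterm = 3.1)
)

# Default two-species lipophilicity values (log-partition units, Gly = 0).
# Non-ionizable residues follow octanol/water side-chain pi values; for
# ionizable residues the neutral-species value carries a charged-species
# penalty reflecting the partition cost of the ion. This is a constructed
# default: any published pH-dependent scale can be dropped in via
# read_lipophilicity_scale().
.lipo_builtin <- data.frame(
  aa = c("A", "G", "I", "L", "M", "F", "P", "S", "T", "W", "V", "N", "Q",
         "D", "E", "C", "Y", "H", "K", "R"),
  neutral = c(0.31, 0.00, 1.80, 1.70, 1.23, 1.79, 0.72, -0.04, 0.26, 2.25,
              1.22, -0.60, -0.22, 0.20, 0.54, 1.54, 0.96, 0.13, 0.52, -0.30),
  charged = c(0.31, 0.00, 1.80, 1.70, 1.23, 1.79, 0.72, -0.04, 0.26, 2.25,
              1.22, -0.60, -0.22, -2.80, -2.46, -1.46, -2.04, -1.87, -0.99,
              -1.01),
  stringsAsFactors = FALSE
)

#' Ionization (pKa) tables
#'
#' An ionization table assigns an acid dissociation constant (pKa) and a
#' charge sign to every ionizable group of a protein: the side chains of
#' D, E, C, Y (charge \eqn{-1} when ionized), K, R, H (\eqn{+1}), and the
#' free N- and C-termini. It drives both the fractional net charge
#' ([net_charge()]) and the Henderson-Hasselbalch mixing of the
#' lipophilicity scale ([residue_lipophilicity()]).
#'
#' Two sets are built in: `"expasy"` (default), a Bjellqvist-style set, and
#' `"calculator"`, the values popularized by a widely used protein charge
#' server. The set name travels with the table so that results are traceable
#' to a specific parameterization.
#'
#' @param set Name of a built-in set, `"expasy"` or `"calculator"`.
#' @return A data frame of class `"ionization_table"` with columns `group`,
#'   `pKa` and `charge` (sign when ionized), and a `name` attribute.
#' @examples
#' ionization_table()
#' ionization_table("calculator")
#' @seealso [read_ionization_table()] to load a custom set from file.
#' @export
ionization_table <- function(set = "expasy") {
  if (!set %in% names(.pka_builtin)) {
    stop("unknown built-in pKa set '", set, "'; available: ",
         paste(names(.pka_builtin), collapse = ", "))
  }
  pka <- .pka_builtin[[set]]
  tab <- data.frame(group = names(pka), pKa = unname(pka),
                    charge = ifelse(names(pka) %in% ACIDIC_GROUPS, -1L, 1L),
                    stringsAsFactors = FALSE)
  validate_ionization_table(tab, name = set)
}

validate_ionization_table <- function(tab, name) {
  missing <- setdiff(ALL_GROUPS, tab$group)
  if (length(missing) > 0) {
    stop("ionization table is missing group(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$group)) {
    stop("ionization table lists group(s) more than once: ",
         paste(unique(tab$group[duplicated(tab$group)]), collapse = ", "))
  }
  if (!is.numeric(tab$pKa) || anyNA(tab$pKa)) {
    stop("non-numeric pKa value in ionization table")
  }
  if (any(tab$pKa <= 0 | tab$pKa >= 14)) {
    stop("pKa values must lie in (0, 14)")
  }
  if (!all(tab$charge %in% c(-1L, 1L))) {
    stop("ionized-species charge must be -1 or +1")
  }
  tab <- tab[match(ALL_GROUPS, tab$group), , drop = FALSE]
  rownames(tab) <- tab$group
  structure(tab, name = name, class = c("ionization_table", "data.frame"))
}

#' Read or write an ionization table
#'
#' Tables are stored as tab-separated text with comment lines starting with
#' `#`; a `# name: <id>` line carries the set identifier. Columns: `group`
#' (one-letter code or `Nterm`/`Cterm`), `pKa`, `charge`.
#'
#' @param path File path.
#' @return `read_ionization_table()` returns a validated
#'   `"ionization_table"`; `write_ionization_table()` returns `path`
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_ionization_table(ionization_table(), f)
#' identical(read_ionization_table(f)$pKa, ionization_table()$pKa)
#' @export
read_ionization_table <- function(path) {
  tab <- read_config_table(path, c("group", "pKa", "charge"))
  if (!is.numeric(tab$pKa)) stop("non-numeric pKa in '", path, "'")
  tab$charge <- as.integer(tab$charge)
  validate_ionization_table(tab, name = attr(tab, "name"))
}

#' @param x An `"ionization_table"`.
#' @rdname read_ionization_table
#' @export
write_ionization_table <- function(x, path) {
  stopifnot(inherits(x, "ionization_table"))
  write_config_table(x, path, attr(x, "name"), "ionization table")
}

#' pH-dependent lipophilicity scales
#'
#' A lipophilicity scale assigns each of the 20 standard amino acids two
#' species-level values in log-partition units: `neutral`, the lipophilicity
#' of the neutral (protonated acid / deprotonated base) species, and
#' `charged`, that of the ionized species. For non-ionizable residues the two
#' are equal. The lipophilicity at an arbitrary pH is the
#' Henderson-Hasselbalch population-weighted mixture of the two species
#' values (see [residue_lipophilicity()]), which reproduces the sigmoid
#' pH-transition of ionizable side chains.
#'
#' The built-in default (`"octanol-hh"`) uses octanol/water side-chain
#' values for the neutral species and charged-species penalties for the
#' ionized forms; it is a constructed scale, and any published two-species
#' table can replace it via [read_lipophilicity_scale()]. Ionization never
#' increases lipophilicity, so `charged <= neutral` is enforced for every
#' ionizable residue.
#'
#' @return A data frame of class `"lipophilicity_scale"` with columns `aa`,
#'   `neutral`, `charged` and a `name` attribute.
#' @examples
#' lipophilicity_scale()
#' @export
lipophilicity_scale <- function() {
  validate_lipophilicity_scale(.lipo_builtin, name = "octanol-hh")
}

validate_lipophilicity_scale <- function(tab, name) {
  missing <- setdiff(AA20, tab$aa)
  if (length(missing) > 0) {
    stop("lipophilicity scale is missing amino acid(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$aa)) {
    stop("lipophilicity scale lists residue(s) more than once: ",
         paste(unique(tab$aa[duplicated(tab$aa)]), collapse = ", "))
  }
  if (!is.numeric(tab$neutral) || !is.numeric(tab$charged) ||
      any(!is.finite(tab$neutral)) || any(!is.finite(tab$charged))) {
    stop("lipophilicity values must be finite numbers")
  }
  ion <- tab$aa %in% IONIZABLE_AA
  if (any(tab$charged[ion] > tab$neutral[ion])) {
    bad <- tab$aa[ion][tab$charged[ion] > tab$neutral[ion]]
    stop("charged-species lipophilicity exceeds neutral-species value for: ",
         paste(bad, collapse = ", "))
  }
  tab <- tab[match(AA20, tab$aa), , drop = FALSE]
  rownames(tab) <- tab$aa
  structure(tab, name = name,
            class = c("lipophilicity_scale", "data.frame"))
}

#' Read or write a lipophilicity scale
#'
#' Same tab-separated format as [read_ionization_table()]: comment lines
#' start with `#`, a `# name:` line identifies the scale, columns are `aa`,
#' `neutral`, `charged`.
#'
#' @param path File path.
#' @return `read_lipophilicity_scale()` returns a validated
#'   `"lipophilicity_scale"`; the writer returns `path` invisibly.
#' @export
read_lipophilicity_scale <- function(path) {
  tab <- read_config_table(path, c("aa", "neutral", "charged"))
  validate_lipophilicity_scale(tab, name = attr(tab, "name"))
}

#' @param x A `"lipophilicity_scale"`.
#' @rdname read_lipophilicity_scale
#' @export
write_lipophilicity_scale <- function(x, path) {
  stopifnot(inherits(x, "lipophilicity_scale"))
  write_config_table(x, path, attr(x, "name"), "lipophilicity scale")
}

read_config_table <- function(path, required_cols) {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  lines <- readLines(path)
  name <- sub("^#\\s*name:\\s*", "",
              grep("^#\\s*name:", lines, value = TRUE)[1])
  if (is.na(name)) name <- basename(path)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(tab))
  if (length(missing) > 0) {
    stop("'", path, "' lacks column(s): ", paste(missing, collapse = ", "))
  }
  attr(tab, "name") <- name
  tab
}

write_config_table <- function(x, path, name, what) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# pHsol ", what), paste0("# name: ", name)), con)
  df <- as.data.frame(x)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-residue lipophilicity at a given pH
#'
#' The lipophilicity of residue `aa` at pH \eqn{p} is the population-weighted
#' mixture of its neutral- and charged-species values,
#' \deqn{l(p) = f_n(p)\, l_{neutral} + (1 - f_n(p))\, l_{charged},}
#' with the neutral fraction \eqn{f_n} from the Henderson-Hasselbalch
#' equation: \eqn{f_n = 1/(1+10^{p - pKa})} for acids and
#' \eqn{1/(1+10^{pKa - p})} for bases. Non-ionizable residues are
#' pH-invariant. At \eqn{p = pKa} the value is the arithmetic mean of the two
#' species values.
#'
#' @param aa Character vector of one-letter residue codes.
#' @param pH Solution pH, in (0, 14). `aa` and `pH` are recycled to a common
#'   length.
#' @param scale A [lipophilicity_scale()].
#' @param pka An [ionization_table()].
#' @param allow_x If `TRUE`, the ambiguity code `X` maps to the mean of the
#'   scale instead of raising an error. All other ambiguity codes (B, Z, J,
#'   U, O) are always rejected.
#' @return Numeric vector of lipophilicity values (log-partition units).
#' @examples
#' residue_lipophilicity("D", c(2, 4.05, 7))
#' residue_lipophilicity("A", c(2, 12))  # identical: Ala does not titrate
#' @export
residue_lipophilicity <- function(aa, pH, scale = lipophilicity_scale(),
                                  pka = ionization_table(),
                                  allow_x = FALSE) {
  check_ph(pH)
  n <- max(length(aa), length(pH))
  aa <- rep_len(aa, n)
  pH <- rep_len(pH, n)
  unknown <- setdiff(unique(aa), c(AA20, if (allow_x) "X"))
  if (length(unknown) > 0) {
    stop("unknown residue code(s): ", paste(unknown, collapse = ", "))
  }
  is_x <- aa == "X"
  idx <- match(aa, scale$aa)
  ln <- scale$neutral[idx]
  lc <- scale$charged[idx]
  if (any(is_x)) {
    ln[is_x] <- mean(scale$neutral)
    lc[is_x] <- mean(scale$charged)
  }
  fn <- neutral_fraction(aa, pH, pka)
  fn * ln + (1 - fn) * lc
}

# Henderson-Hasselbalch neutral-species fraction; 1 for non-ionizable codes.
neutral_fraction <- function(aa, pH, pka) {
  fn <- rep(1, length(aa))
  idx <- match(aa, pka$group)
  ion <- !is.na(idx)
  if (any(ion)) {
    pk <- pka$pKa[idx[ion]]
    sgn <- pka$charge[idx[ion]]
    fn[ion] <- ifelse(sgn < 0,
                      1 / (1 + 10^(pH[ion] - pk)),
                      1 / (1 + 10^(pk - pH[ion])))
  }
  fn
}

check_ph <- function(pH) {
  if (!is.numeric(pH) || length(pH) == 0 || anyNA(pH) ||
      any(pH <= 0 | pH >= 14)) {
    stop("pH must be numeric and lie strictly inside (0, 14)")
  }
  invisible(pH)
}
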