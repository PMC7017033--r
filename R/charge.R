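# Fractional net charge and isoelectric point.

# Count ionizable groups of a protein, honoring blocked termini and the
# optional exclusion of cysteines (e.g. disulfide-bonded constructs).
ionizable_counts <- function(p, exclude_cys = FALSE) {
  aa <- residue_vector(p)
  counts <- table(factor(aa, levels = IONIZABLE_AA))
  counts <- setNames(as.numeric(counts), IONIZABLE_AA)
  if (exclude_cys) counts["C"] <- 0
  c(counts,
    Nterm = as.numeric(!p$nterm_blocked),
    Cterm = as.numeric(!p$cterm_blocked))
}

#' Fractional net charge at a given pH
#'
#' The net charge is the sum of fractional Henderson-Hasselbalch charges of
#' all ionizable groups (acidic and basic side chains plus free termini):
#' \deqn{Q(p) = \sum_{bases} \frac{1}{1+10^{p-pKa}}
#'             - \sum_{acids} \frac{1}{1+10^{pKa-p}}.}
#' \eqn{Q} is continuous and strictly decreasing in pH whenever at least one
#' ionizable group is present. The absolute value `abs_net_charge` is the
#' charge input of the solubility model ([predict_solubility()]).
#'
#' @param seq A [protein()] or a plain sequence string.
#' @param pH Numeric vector of pH values in (0, 14).
#' @param pka An [ionization_table()].
#' @param exclude_cys If `TRUE`, cysteines do not titrate (disulfide-paired
#'   construct). By default free cysteines contribute as weak acids.
#' @return Data frame with one row per pH: `pH`, `net_charge`,
#'   `abs_net_charge`.
#' @examples
#' net_charge("KCNTATCATQRLANFLVHSSNNFGAILSSTNVGSNTY", c(5, 7.4))
#' @export
net_charge <- function(seq, pH, pka = ionization_table(),
                       exclude_cys = FALSE) {
  p <- as_protein(seq)
  check_ph(pH)
  counts <- ionizable_counts(p, exclude_cys = exclude_cys)
  q <- vapply(pH, function(ph) {
    idx <- match(names(counts), pka$group)
    pk <- pka$pKa[idx]
    sgn <- pka$charge[idx]
    frac <- ifelse(sgn > 0,
                   1 / (1 + 10^(ph - pk)),
                   1 / (1 + 10^(pk - ph)))
    sum(counts * sgn * frac)
  }, numeric(1))
  data.frame(pH = pH, net_charge = q, abs_net_charge = abs(q))
}

#' Isoelectric point
#'
#' The pH at which the fractional net charge crosses zero, located by
#' bisection on \eqn{[0.1, 13.9]}. Because \eqn{Q(pH)} is strictly
#' decreasing, the root is unique; bisection is run until
#' \eqn{|Q| \le tol} (at most 60 halvings, which exceeds the resolution of
#' double precision on this interval).
#'
#' The full-precision root is returned; round to 2 decimals for display if
#' comparing against conventionally reported pI values.
#'
#' @inheritParams net_charge
#' @param tol Absolute charge tolerance at the root (default `1e-4`).
#' @return The isoelectric point (numeric scalar).
#' @examples
#' asyn <- read_fasta(system.file("extdata", "reference_idps.fasta",
#'                                package = "pHsol"))[["alpha_synuclein"]]
#' round(isoelectric_point(asyn), 2)
#' @export
isoelectric_point <- function(seq, pka = ionization_table(), tol = 1e-4,
                              exclude_cys = FALSE) {
  p <- as_protein(seq)
  counts <- ionizable_counts(p, exclude_cys = exclude_cys)
  idx <- match(names(counts), pka$group)
  n_acid <- sum(counts[pka$charge[idx] < 0])
  n_base <- sum(counts[pka$charge[idx] > 0])
  if (n_acid == 0 || n_base == 0) {
    stop("no isoelectric point: sequence '", p$id, "' has ",
         if (n_acid == 0) "no acidic" else "no basic",
         " ionizable groups, so the net charge never crosses zero")
  }
  qfun <- function(ph) net_charge(p, ph, pka = pka,
                                  exclude_cys = exclude_cys)$net_charge
  lo <- 0.1
  hi <- 13.9
  qlo <- qfun(lo)
  qhi <- qfun(hi)
  if (qlo < 0 || qhi > 0) {
    stop("net charge does not change sign on [0.1, 13.9] for '", p$id, "'")
  }
  for (i in seq_len(60)) {
    mid <- (lo + hi) / 2
    qm <- qfun(mid)
    if (abs(qm) <= tol) return(mid)
    if (qm > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
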