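# Sliding-window lipophilicity profiles.

#' Sliding-window size rule
#'
#' The window grows with protein length: 5 residues for proteins shorter
#' than 75 amino acids, 7 up to 174, 9 up to 299, and 11 from 300 on
#' (boundaries resolved as half-open intervals: 75 already gets 7, 175 gets
#' 9, 300 gets 11). Windows are always odd so a center residue exists.
#'
#' @param length Sequence length in residues (>= 5, so the smallest window
#'   fits).
#' @return Odd integer window size: 5, 7, 9 or 11.
#' @examples
#' window_size(50)   # 5
#' window_size(200)  # 9
#' window_size(400)  # 11
#' @export
window_size <- function(length) {
  stopifnot(is.numeric(length), length(length) == 1)
  if (length < 5) {
    stop("sequence length ", length, " is too short for the minimum ",
         "window of 5 residues")
  }
  if (length <= 74) 5L else if (length <= 174) 7L else if (length <= 299) 9L
  else 11L
}

#' Lipophilicity profile of a sequence at a given pH
#'
#' Computes the per-residue pH-dependent lipophilicity
#' ([residue_lipophilicity()]), averages it over a sliding window, and
#' assigns each window mean to the residue at the window center. Only full
#' windows are scored, so a length-\eqn{L} sequence with window \eqn{w}
#' yields exactly \eqn{L - w + 1} profile points; terminal residues that
#' cannot center a full window receive no value. The global lipophilicity --
#' the "Lipophilicity" input of the solubility model -- is the unweighted
#' mean of the assigned window values.
#'
#' @param seq A [protein()] or sequence string.
#' @param pH Scalar pH in (0, 14).
#' @param scale A [lipophilicity_scale()].
#' @param pka An [ionization_table()].
#' @param window Odd window size >= 3; default `NULL` applies
#'   [window_size()] to the sequence length.
#' @param allow_x Passed to [residue_lipophilicity()].
#' @return A data frame of class `"lipo_profile"` with columns `position`
#'   (1-based window center), `residue` and `lipophilicity`, and attributes
#'   `id`, `pH`, `window` and `global` (the profile mean).
#' @examples
#' pr <- lipophilicity_profile(strrep("L", 20), pH = 7)
#' nrow(pr)                  # 20 - 5 + 1
#' attr(pr, "global")
#' @export
lipophilicity_profile <- function(seq, pH, scale = lipophilicity_scale(),
                                  pka = ionization_table(), window = NULL,
                                  allow_x = FALSE) {
  p <- as_protein(seq)
  stopifnot(length(pH) == 1)
  check_ph(pH)
  aa <- residue_vector(p)
  L <- length(aa)
  if (is.null(window)) window <- window_size(L)
  if (window %% 2 == 0 || window < 3) {
    stop("window size must be an odd integer >= 3")
  }
  if (L < window) {
    stop("sequence '", p$id, "' (", L, " aa) is shorter than the window (",
         window, ")")
  }
  l <- residue_lipophilicity(aa, pH, scale = scale, pka = pka,
                             allow_x = allow_x)
  cums <- cumsum(c(0, l))
  win_mean <- (cums[(window + 1):(L + 1)] - cums[1:(L - window + 1)]) / window
  half <- (window - 1L) / 2L
  centers <- (half + 1L):(L - half)
  out <- data.frame(position = centers, residue = aa[centers],
                    lipophilicity = win_mean)
  structure(out, id = p$id, pH = pH, window = as.integer(window),
            global = mean(win_mean),
            class = c("lipo_profile", "data.frame"))
}

#' Global (average) lipophilicity at a given pH
#'
#' The mean of the sliding-window lipophilicity profile; this scalar is the
#' lipophilicity input of [predict_solubility()].
#'
#' @inheritParams lipophilicity_profile
#' @return Numeric scalar.
#' @export
global_lipophilicity <- function(seq, pH, scale = lipophilicity_scale(),
                                 pka = ionization_table(), window = NULL,
                                 allow_x = FALSE) {
  attr(lipophilicity_profile(seq, pH, scale = scale, pka = pka,
                             window = window, allow_x = allow_x), "global")
}
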