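# Synthetic charge-variant experiments: an IDP-like wild type, charge-sign
# flipped acidic/basic variants, and noisy solubility measurements drawn
# from the solubility model. This is first-class, seeded, testable code: it
# provides the statistical structure the model assumes without requiring
# any experimental dataset.

# Run code with a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Background composition for disordered sequences: enriched in small polar
# and structure-breaking residues, depleted in aromatics, branched
# hydrophobics and cysteine.
.idp_pool <- c(S = 0.14, P = 0.10, G = 0.14, Q = 0.10, N = 0.08, A = 0.12,
               T = 0.08, M = 0.04, L = 0.06, V = 0.04, I = 0.02, F = 0.02,
               Y = 0.03, H = 0.03)

#' Design of a synthetic charge-variant experiment
#'
#' Collects the generator settings for a synthetic experiment modelled on a
#' charge-engineered IDP: a disordered wild-type sequence, acidic and basic
#' charge-sign-flipped variants, and noisy solubility measurements over a
#' pH grid. Defaults follow the published experiment's magnitudes: a 230
#' residue chain carrying about 60 charged residues with a modest acidic
#' excess, measured over 10 pH points spanning a wide range.
#'
#' @param length Wild-type sequence length (>= the sliding window size).
#' @param charged_fraction Fraction of positions carrying D/E/K/R.
#' @param acidic_fraction Fraction of the charged positions that are acidic
#'   in the wild type.
#' @param ph_grid pH values at which solubility is "measured".
#' @param noise_sd Standard deviation of the additive Gaussian measurement
#'   noise, in solubility-score units. `NULL` (default) uses 2% of the
#'   noiseless score range across the design.
#' @param params True coefficients \eqn{\theta_0} used to generate the
#'   data; defaults to the shipped [solubility_params()].
#' @param seed Integer seed fixing all randomness (sequence and noise).
#' @return A list of class `"synthetic_design"`.
#' @export
synthetic_design <- function(length = 230, charged_fraction = 0.26,
                             acidic_fraction = 0.6,
                             ph_grid = seq(2, 12, length.out = 10),
                             noise_sd = NULL,
                             params = solubility_params(), seed = 1) {
  stopifnot(length >= 5, charged_fraction >= 0, charged_fraction <= 1,
            acidic_fraction >= 0, acidic_fraction <= 1)
  check_ph(ph_grid)
  if (!is.null(noise_sd)) stopifnot(noise_sd >= 0)
  structure(list(length = length, charged_fraction = charged_fraction,
                 acidic_fraction = acidic_fraction, ph_grid = ph_grid,
                 noise_sd = noise_sd, params = params, seed = seed),
            class = "synthetic_design")
}

#' Generate an IDP-like wild-type sequence
#'
#' Draws a sequence with disorder-promoting composition (enriched in
#' S/P/G/Q/N/A, depleted in W/F/I/V/C) and plants the designed number of
#' charged residues (D/E/K/R) at random positions, with the designed acidic
#' excess. Reproducible under the design seed.
#'
#' @param design A [synthetic_design()].
#' @param id Identifier for the generated sequence.
#' @return A [protein()].
#' @examples
#' wt <- make_idp_sequence(synthetic_design(seed = 7))
#' wt
#' @export
make_idp_sequence <- function(design, id = "wt") {
  stopifnot(inherits(design, "synthetic_design"))
  with_seed(design$seed, {
    len <- design$length
    n_charged <- round(len * design$charged_fraction)
    n_acid <- round(n_charged * design$acidic_fraction)
    aa <- sample(names(.idp_pool), len, replace = TRUE, prob = .idp_pool)
    if (n_charged > 0) {
      pos <- sample(len, n_charged)
      if (n_acid > 0) {
        aa[pos[seq_len(n_acid)]] <- sample(c("D", "E"), n_acid,
                                           replace = TRUE)
      }
      if (n_charged > n_acid) {
        aa[pos[(n_acid + 1):n_charged]] <- sample(c("K", "R"),
                                                  n_charged - n_acid,
                                                  replace = TRUE)
      }
    }
    protein(paste(aa, collapse = ""), id = id)
  })
}

#' Flip the sign of charged residues
#'
#' Builds a charge-sign-flipped variant without touching any non-ionizable
#' position: the acidic variant replaces every K/R by E, the basic variant
#' replaces every D/E by K. Histidine, being only weakly basic, is left
#' unchanged by default; `flip_his = TRUE` additionally replaces H by Q in
#' the acidic variant.
#'
#' @param seq A [protein()] or sequence string.
#' @param target `"acidic"` or `"basic"`.
#' @param flip_his Also neutralize histidines in the acidic variant.
#' @return A [protein()] with `"_acidic"` / `"_basic"` appended to the id.
#'   If the sequence contains no residue to flip, it is returned unchanged
#'   with a warning.
#' @examples
#' flip_charges("GSKARDEST", "acidic")$residues  # "GSEAEDEST"
#' @export
flip_charges <- function(seq, target = c("acidic", "basic"),
                         flip_his = FALSE) {
  target <- match.arg(target)
  p <- as_protein(seq)
  aa <- residue_vector(p)
  if (!any(aa %in% c("D", "E", "K", "R"))) {
    warning("sequence '", p$id, "' has no charged residues to flip")
    return(p)
  }
  if (target == "acidic") {
    aa[aa %in% c("K", "R")] <- "E"
    if (flip_his) aa[aa == "H"] <- "Q"
  } else {
    aa[aa %in% c("D", "E")] <- "K"
  }
  protein(paste(aa, collapse = ""), id = paste0(p$id, "_", target),
          nterm_blocked = p$nterm_blocked, cterm_blocked = p$cterm_blocked)
}

#' Generate noisy solubility observations
#'
#' For every variant and every pH grid point, computes the global
#' lipophilicity and absolute net charge with the package pipeline,
#' evaluates the solubility polynomial under the design's true coefficients
#' \eqn{\theta_0}, and adds seeded homoscedastic Gaussian noise. The result
#' has the statistical structure the fitting module assumes and is the
#' training input of [fit_solubility()].
#'
#' @param variants A list of [protein()] objects (e.g. wild type plus
#'   [flip_charges()] variants).
#' @param design A [synthetic_design()]; `design$seed` fixes the noise.
#' @param scale,pka Scale and pKa set used to compute the predictors.
#' @return Data frame with columns `id`, `ph`, `lipophilicity`,
#'   `abs_net_charge`, `solubility`, and attributes `noise_sd` and `params`.
#' @export
generate_solubility_data <- function(variants, design,
                                     scale = lipophilicity_scale(),
                                     pka = ionization_table()) {
  stopifnot(inherits(design, "synthetic_design"))
  if (inherits(variants, "protein")) variants <- list(variants)
  rows <- lapply(variants, function(v) {
    s <- solubility_at_ph(v, design$ph_grid, params = design$params,
                          scale = scale, pka = pka)
    data.frame(id = v$id, ph = s$pH, lipophilicity = s$lipophilicity,
               abs_net_charge = s$abs_net_charge, solubility = s$solubility)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  sd0 <- if (is.null(design$noise_sd)) {
    0.02 * diff(range(out$solubility))
  } else {
    design$noise_sd
  }
  if (sd0 > 0) {
    out$solubility <- out$solubility +
      with_seed(design$seed, rnorm(nrow(out), 0, sd0))
  }
  structure(out, noise_sd = sd0, params = design$params)
}

#' Run a complete synthetic charge-variant experiment
#'
#' Convenience wrapper: generates the wild type, its acidic and basic
#' charge-flip variants, and the noisy solubility dataset, all under the
#' design seed.
#'
#' @param design A [synthetic_design()].
#' @return List with elements `variants` (named list: `wt`, `acidic`,
#'   `basic`), `data` (from [generate_solubility_data()]) and `design`.
#' @examples
#' xp <- simulate_charge_variant_experiment(synthetic_design(seed = 3))
#' head(xp$data)
#' @export
simulate_charge_variant_experiment <- function(design = synthetic_design()) {
  wt <- make_idp_sequence(design)
  variants <- list(wt = wt,
                   acidic = flip_charges(wt, "acidic"),
                   basic = flip_charges(wt, "basic"))
  data <- generate_solubility_data(variants, design)
  list(variants = variants, data = data, design = design)
}
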