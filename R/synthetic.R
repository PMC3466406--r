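#' Random logical models
#'
#' Seeded generator of validated logical models, the substrate for the
#' oracle test suites (steady-state propagation vs exhaustive fixed-point
#' enumeration, intervention sets vs brute-force clamp search). Species are
#' named `S01`, `S02`, ...; a fraction of them can be multivalued (levels up
#' to 3), hyperarc conditions draw distinct species with random thresholds
#' and negations, and arcs become time-scale 2 with probability `p_scale2`.
#'
#' @param n_species number of species.
#' @param n_hyperarcs number of hyperarcs.
#' @param max_condition largest condition size (literals per arc).
#' @param p_negate probability a literal is negated.
#' @param multivalued_fraction fraction of species with max level > 1.
#' @param p_scale2 probability an arc is time-scale 2.
#' @param seed RNG seed; identical seeds give identical models.
#' @return a validated [lih_model()].
#' @export
random_model <- function(n_species = 8L, n_hyperarcs = 10L,
                         max_condition = 3L, p_negate = 0.25,
                         multivalued_fraction = 0, p_scale2 = 0,
                         seed = 1L) {
  stopifnot(n_species >= 1L, n_hyperarcs >= 0L, max_condition >= 1L,
            p_negate >= 0, p_negate <= 1,
            multivalued_fraction >= 0, multivalued_fraction <= 1,
            p_scale2 >= 0, p_scale2 <= 1)
  if (n_hyperarcs > 0L && max_condition > n_species) {
    stop("max_condition cannot exceed n_species", call. = FALSE)
  }
  with_seed(seed, {
    names_ <- sprintf("S%02d", seq_len(n_species))
    n_multi <- round(multivalued_fraction * n_species)
    multi <- if (n_multi > 0L) sample(names_, n_multi) else character(0)
    ml <- stats::setNames(rep(1L, n_species), names_)
    if (length(multi) > 0L) {
      ml[multi] <- sample(2:3, length(multi), replace = TRUE)
    }
    species <- lapply(names_, function(s) lih_species(s, max_level = ml[[s]]))
    arcs <- lapply(seq_len(n_hyperarcs), function(i) {
      target <- sample(names_, 1L)
      k <- sample.int(max_condition, 1L)
      cond_sp <- sample(names_, k)
      lits <- lapply(cond_sp, function(s) {
        lih_literal(s, threshold = sample.int(ml[[s]], 1L),
                    negated = stats::runif(1) < p_negate)
      })
      lih_hyperarc(sprintf("R%03d", i), lits, target,
                   target_level = sample.int(ml[[target]], 1L),
                   time_scale = if (stats::runif(1) < p_scale2) 2L else 1L)
    })
    lih_model(species, arcs)
  })
}

#' Simulate a replicate fluorescence assay
#'
#' Emulates the statistical structure of a plate-based DNA-content assay:
#' `intensity = baseline * 2^(effect + b_experiment + e_technical)` with
#' experiment intercepts `b ~ N(0, sd_experiment^2)` shared by all wells of
#' an experiment (biological variability between animals) and technical
#' noise `e ~ N(0, sd_technical^2)` per well. Effects are true log2 fold
#' changes versus the control, whose effect is 0.
#'
#' @param effects named numeric vector of true log2 effects per treatment
#'   (the control is added automatically).
#' @param control control label.
#' @param n_experiments number of independent experiments.
#' @param n_technical technical replicates per treatment and experiment.
#' @param sd_experiment between-experiment (biological) sd, log2 scale.
#' @param sd_technical within-experiment (technical) sd, log2 scale.
#' @param baseline control-level fluorescence intensity, arbitrary units.
#' @param seed RNG seed.
#' @return a [lih_assay()].
#' @export
simulate_assay <- function(effects, control = "control",
                           n_experiments = 4L, n_technical = 3L,
                           sd_experiment = 0.2, sd_technical = 0.1,
                           baseline = 1000, seed = 1L) {
  stopifnot(sd_experiment >= 0, sd_technical >= 0, baseline > 0,
            n_experiments >= 1L, n_technical >= 1L)
  if (control %in% names(effects)) {
    stop("control must not appear in effects", call. = FALSE)
  }
  all_effects <- c(stats::setNames(0, control), effects)
  with_seed(seed, {
    b <- stats::rnorm(n_experiments, 0, sd_experiment)
    rows <- list()
    for (e in seq_len(n_experiments)) {
      for (tr in names(all_effects)) {
        noise <- stats::rnorm(n_technical, 0, sd_technical)
        rows[[length(rows) + 1L]] <- data.frame(
          experiment = sprintf("exp%d", e), treatment = tr,
          replicate = seq_len(n_technical),
          intensity = baseline * 2^(all_effects[[tr]] + b[e] + noise),
          stringsAsFactors = FALSE)
      }
    }
    lih_assay(do.call(rbind, rows), control = control)
  })
}
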