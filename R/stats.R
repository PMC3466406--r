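#' Replicate fluorescence assay datasets
#'
#' Long-format DNA-content assay data: independent experiments (one animal's
#' hepatocytes each), treatments applied in technical replicates, and a
#' fluorescence intensity per well in arbitrary units. One treatment label
#' is the control (unstimulated or solvent).
#'
#' @param data data frame with columns `experiment`, `treatment`,
#'   `replicate`, `intensity`.
#' @param control control treatment label.
#' @return a `lih_assay`.
#' @export
lih_assay <- function(data, control = "control") {
  need <- c("experiment", "treatment", "replicate", "intensity")
  if (!all(need %in% names(data))) {
    stop("assay data needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  data <- data.frame(experiment = as.character(data$experiment),
                     treatment = as.character(data$treatment),
                     replicate = as.integer(data$replicate),
                     intensity = as.numeric(data$intensity),
                     stringsAsFactors = FALSE)
  if (any(!is.finite(data$intensity)) || any(data$intensity <= 0)) {
    stop("intensities must be positive and finite", call. = FALSE)
  }
  if (!control %in% data$treatment) {
    stop("control treatment '", control, "' absent from data", call. = FALSE)
  }
  structure(list(data = data, control = control), class = "lih_assay")
}

#' @exportS3Method base::print
print.lih_assay <- function(x, ...) {
  d <- x$data
  cat(sprintf("<lih_assay> %d experiments x %d treatments (%d wells), control '%s'\n",
              length(unique(d$experiment)), length(unique(d$treatment)),
              nrow(d), x$control))
  invisible(x)
}

#' Preprocess assay intensities
#'
#' Each intensity is scaled to the average fluorescence intensity of its
#' experiment and log2-transformed, removing multiplicative per-experiment
#' offsets (plate and staining effects) before model fitting. Adds a `value`
#' column.
#'
#' @param assay a [lih_assay()].
#' @return the assay with a `value` column in its data.
#' @export
preprocess_assay <- function(assay) {
  d <- assay$data
  mu <- tapply(d$intensity, d$experiment, mean)
  d$value <- as.numeric(log2(d$intensity / mu[d$experiment]))
  assay$data <- d
  assay
}

# containment denominator df for the treatment contrasts: residual
# observations after the experiment blocks and treatment effects
containment_df <- function(d) {
  nrow(d) - length(unique(d$experiment)) - length(unique(d$treatment)) + 1L
}

#' Discretize assay treatments into binary activity calls
#'
#' Fits the two-level model `value ~ treatment + (1 | experiment)` by REML
#' (fixed treatment effects, random experiment intercept capturing
#' biological variability, residual technical error), forms
#' treatment-vs-control contrasts, and assigns the binary call 1 to
#' treatments with a positive and significant log2 fold change, 0 otherwise.
#'
#' P-values are one-sided (upper tail: induction) per comparison with
#' containment degrees of freedom by default, so the call rate under a null
#' effect equals `alpha`; `adjust = "dunnett"` applies single-step Dunnett
#' (multivariate-t) adjustment over the contrast family via
#' \pkg{multcomp}, and `tail = "two.sided"` is available for two-sided
#' reporting. Confidence intervals are two-sided 95%.
#'
#' If the random-intercept fit is singular or fails, the discretizer falls
#' back to a fixed-effects model with experiment as a blocking factor and
#' flags it in the metadata.
#'
#' Note that scaling to the experiment average deliberately removes most of
#' the between-experiment variation before fitting, so the random-intercept
#' variance is often estimated at the zero boundary and the flagged fallback
#' engages; the contrasts are unaffected in balanced designs. Set
#' `scale = FALSE` to fit the mixed model on raw log2 intensities (e.g. for
#' variance-component estimation).
#'
#' @param assay a [lih_assay()] (raw; preprocessing is applied internally).
#' @param alpha significance threshold for the call.
#' @param adjust `"none"` (per-comparison) or `"dunnett"`.
#' @param tail `"greater"` or `"two.sided"`.
#' @param scale scale intensities to the experiment average before the log2
#'   transform (the default pipeline).
#' @return a `lih_discretization`: `results` data frame (`treatment`,
#'   `estimate`, `ci_low`, `ci_high`, `df`, `p`, `call`) and `metadata`.
#' @export
discretize_assay <- function(assay, alpha = 0.05,
                             adjust = c("none", "dunnett"),
                             tail = c("greater", "two.sided"),
                             scale = TRUE) {
  adjust <- match.arg(adjust)
  tail <- match.arg(tail)
  if (scale) {
    assay <- preprocess_assay(assay)
  } else {
    assay$data$value <- log2(assay$data$intensity)
  }
  d <- assay$data
  n_exp <- length(unique(d$experiment))
  if (n_exp < 2L) {
    stop("mixed-model fitting needs >= 2 experiments", call. = FALSE)
  }
  with_ctl <- tapply(d$treatment, d$experiment,
                     function(tr) assay$control %in% tr)
  if (!all(with_ctl)) {
    stop("every experiment must contain the control treatment",
         call. = FALSE)
  }
  d$treatment <- stats::relevel(factor(d$treatment), ref = assay$control)
  d$experiment <- factor(d$experiment)
  treatments <- setdiff(levels(d$treatment), assay$control)

  singular <- FALSE
  fit <- tryCatch({
    f <- lme4::lmer(value ~ treatment + (1 | experiment), data = d,
                    REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
    if (lme4::isSingular(f, tol = 1e-5)) singular <- TRUE
    f
  }, error = function(e) NULL)
  coef_names <- paste0("treatment", treatments)
  extract <- function(fit) {
    cf <- if (inherits(fit, "lmerMod")) lme4::fixef(fit) else stats::coef(fit)
    vc <- as.matrix(stats::vcov(fit))
    list(est = unname(cf[coef_names]),
         se = sqrt(diag(vc)[coef_names]))
  }
  ext <- if (is.null(fit) || singular) NULL else {
    tryCatch({
      e <- extract(fit)
      if (anyNA(e$est) || anyNA(e$se)) NULL else e
    }, error = function(e) NULL)
  }
  if (is.null(ext)) {
    singular <- TRUE
    fit <- stats::lm(value ~ experiment + treatment, data = d)
    ext <- extract(fit)
  }
  est <- ext$est
  se <- ext$se
  df <- containment_df(d)

  if (adjust == "dunnett" && length(treatments) >= 1L && !singular) {
    glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(treatment = "Dunnett"),
                               alternative = if (tail == "greater") "greater" else "two.sided")
    sm <- summary(glht_fit)
    p <- as.numeric(sm$test$pvalues)
    ci <- stats::confint(glht_fit, level = 0.95)$confint
    ci_low <- ci[, "lwr"]
    ci_high <- ci[, "upr"]
  } else {
    tval <- est / se
    p <- if (tail == "greater") {
      stats::pt(tval, df, lower.tail = FALSE)
    } else {
      2 * stats::pt(abs(tval), df, lower.tail = FALSE)
    }
    if (adjust == "dunnett") {
      # fixed-effects fallback: Bonferroni over the family, flagged below
      p <- pmin(1, p * length(treatments))
    }
    q <- stats::qt(0.975, df)
    ci_low <- est - q * se
    ci_high <- est + q * se
  }

  results <- data.frame(treatment = treatments, estimate = est,
                        ci_low = unname(ci_low), ci_high = unname(ci_high),
                        df = df, p = unname(p),
                        call = as.integer(est > 0 & p < alpha),
                        stringsAsFactors = FALSE)
  rownames(results) <- NULL
  meta <- list(model = if (singular) "fixed-effects (experiment block)" else
                 "lmer: value ~ treatment + (1|experiment), REML",
               singular_fallback = singular,
               adjust = adjust, tail = tail, alpha = alpha,
               df_method = "containment", family_size = length(treatments),
               n_experiments = n_exp)
  if (inherits(fit, "lmerMod")) {
    vcs <- as.data.frame(lme4::VarCorr(fit))
    meta$sd_experiment <- vcs$sdcor[vcs$grp == "experiment"]
    meta$sd_technical <- vcs$sdcor[vcs$grp == "Residual"]
  }
  structure(list(results = results, metadata = meta),
            class = "lih_discretization")
}

#' @exportS3Method base::print
print.lih_discretization <- function(x, ...) {
  cat(sprintf("<lih_discretization> %s; adjust=%s, tail=%s%s\n",
              x$metadata$model, x$metadata$adjust, x$metadata$tail,
              if (x$metadata$singular_fallback) " [singular fallback]" else ""))
  print(x$results, digits = 3)
  invisible(x)
}

#' One-tailed Fisher exact test for intervention-target enrichment
#'
#' Tests enrichment of mutated species among intervention-set members: the
#' exact upper-tail hypergeometric probability, with all margins fixed, of
#' an overlap (the mutated-and-in-MIS cell) at least as large as observed.
#'
#' @param table 2x2 matrix of counts with the overlap in cell `[1, 1]`
#'   (e.g. from [annotate_mis_overlap()]), or a numeric vector
#'   `c(a, b, c, d)` filled by row.
#' @return the one-tailed p-value.
#' @export
fisher_one_tailed <- function(table) {
  if (!is.matrix(table)) table <- matrix(as.numeric(table), 2L, byrow = TRUE)
  if (!all(dim(table) == 2L)) stop("need a 2x2 table", call. = FALSE)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(table) == 0) stop("all-zero table", call. = FALSE)
  stats::fisher.test(table, alternative = "greater")$p.value
}

#' Write discretization results as TSV
#'
#' @param discretization a `lih_discretization`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_discretization_tsv <- function(discretization, path) {
  utils::write.table(discretization$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read assay data from delimited text
#'
#' @param path TSV/CSV file with columns `experiment`, `treatment`,
#'   `replicate`, `intensity`.
#' @param control control treatment label.
#' @param sep field separator (default tab; use `","` for CSV).
#' @return a [lih_assay()].
#' @export
read_assay <- function(path, control = "control", sep = "\t") {
  lih_assay(utils::read.table(path, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE), control = control)
}
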