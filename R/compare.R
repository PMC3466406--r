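#' Observations
#'
#' An observation pairs a scenario with expected species values, e.g. a
#' discretized DNA-synthesis call under a ligand combination, or a
#' literature statement that a kinase is active under a stimulus.
#'
#' @param scenario a [lih_scenario()].
#' @param expected named integer vector of expected values.
#' @param label short scenario label.
#' @param source free-text provenance.
#' @return a `lih_observation`.
#' @export
lih_observation <- function(scenario, expected, label = "", source = "") {
  if (is.null(names(expected)) || any(!nzchar(names(expected)))) {
    stop("expected must be a named vector", call. = FALSE)
  }
  structure(list(scenario = scenario,
                 expected = stats::setNames(as.integer(expected),
                                            names(expected)),
                 label = as.character(label), source = as.character(source)),
            class = "lih_observation")
}

#' Score model predictions against observations
#'
#' Computes the logical steady state for each observation's scenario and
#' compares the predicted value of every observed species with the expected
#' one. A prediction matches when it is determined and equal to the
#' expectation; with `boolean_calls = TRUE` (default) an expected call of 1
#' on a multivalued species is matched by any level >= 1, since
#' active/inactive calls carry no level information. An undetermined
#' prediction is counted as indeterminate, anything else as a mismatch.
#'
#' The unit of counting is a single (scenario, species) observation;
#' `unit = "scenario"` aggregates per scenario instead (a scenario is a
#' mismatch if any of its observations mismatches, else indeterminate if any
#' is indeterminate, else a match).
#'
#' @param model validated [lih_model()].
#' @param observations list of [lih_observation()].
#' @param time_scale_mode overrides every observation scenario's mode
#'   (default `"initial"`, the mode used for input-output predictions);
#'   `NULL` keeps each scenario's own mode.
#' @param unit `"observation"` or `"scenario"`.
#' @param boolean_calls treat expected value 1 as an activity call matched
#'   by any positive level.
#' @return a `lih_comparison`: `details` data frame (label, species,
#'   expected, predicted, status) and `summary` list with counts and
#'   percentages (match + mismatch + indeterminate = 100).
#' @export
compare_observations <- function(model, observations,
                                 time_scale_mode = "initial",
                                 unit = c("observation", "scenario"),
                                 boolean_calls = TRUE) {
  unit <- match.arg(unit)
  if (length(observations) == 0L) {
    stop("observation list is empty", call. = FALSE)
  }
  nm <- species_names(model)
  rows <- list()
  for (obs in observations) {
    miss <- setdiff(names(obs$expected), nm)
    if (length(miss) > 0L) {
      stop("observed species absent from model: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    sc <- obs$scenario
    if (!is.null(time_scale_mode)) {
      sc <- lih_scenario(sc$inputs, sc$perturbations, sc$frozen,
                         time_scale_mode = time_scale_mode)
    }
    st <- compute_lss(model, sc)
    for (s in names(obs$expected)) {
      exp_v <- obs$expected[[s]]
      pred <- st$values[[s]]
      status <- if (is.na(pred)) {
        "indeterminate"
      } else if (pred == exp_v ||
                 (boolean_calls && exp_v == 1L && pred >= 1L)) {
        "match"
      } else {
        "mismatch"
      }
      rows[[length(rows) + 1L]] <-
        data.frame(label = obs$label, species = s, expected = exp_v,
                   predicted = pred, status = status,
                   stringsAsFactors = FALSE)
    }
  }
  details <- do.call(rbind, rows)

  if (unit == "scenario") {
    agg <- vapply(split(details$status, details$label), function(st) {
      if (any(st == "mismatch")) "mismatch"
      else if (any(st == "indeterminate")) "indeterminate"
      else "match"
    }, "")
    status_vec <- unname(agg)
  } else {
    status_vec <- details$status
  }
  n <- length(status_vec)
  counts <- c(match = sum(status_vec == "match"),
              mismatch = sum(status_vec == "mismatch"),
              indeterminate = sum(status_vec == "indeterminate"))
  per_species <- do.call(rbind, lapply(split(details, details$species),
                                       function(d) {
    data.frame(species = d$species[1],
               match = sum(d$status == "match"),
               mismatch = sum(d$status == "mismatch"),
               indeterminate = sum(d$status == "indeterminate"),
               stringsAsFactors = FALSE)
  }))
  rownames(per_species) <- NULL
  structure(list(details = details,
                 per_species = per_species,
                 summary = list(unit = unit, n = n, counts = counts,
                                percent = 100 * counts / n)),
            class = "lih_comparison")
}

#' @exportS3Method base::print
print.lih_comparison <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<lih_comparison> %d %s(s): %.1f%% match, %.1f%% mismatch, %.1f%% indeterminate\n",
              s$n, s$unit, s$percent[["match"]], s$percent[["mismatch"]],
              s$percent[["indeterminate"]]))
  mm <- x$details[x$details$status != "match", , drop = FALSE]
  if (nrow(mm) > 0L) {
    cat(paste(sprintf("  %s: %s expected %d, predicted %s (%s)", mm$label,
                      mm$species, mm$expected,
                      ifelse(is.na(mm$predicted), "?", mm$predicted),
                      mm$status),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Read / write observation tables
#'
#' Observation files are TSV with columns `label`, `clamps` (comma-separated
#' `species=value` input clamps), `species`, `value`, and optionally
#' `source`. Rows sharing a label share one scenario.
#'
#' @param path file path.
#' @param time_scale_mode scenario mode given to every observation.
#' @return list of [lih_observation()].
#' @export
read_observations <- function(path, time_scale_mode = "initial") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("label", "clamps", "species", "value")
  if (!all(need %in% names(df))) {
    stop("observation file must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("observation file is empty", call. = FALSE)
  out <- lapply(split(df, factor(df$label, levels = unique(df$label))),
                function(d) {
    lih_observation(
      lih_scenario(inputs = parse_clamps(d$clamps[1]),
                   time_scale_mode = time_scale_mode),
      expected = stats::setNames(as.integer(d$value), d$species),
      label = d$label[1],
      source = if ("source" %in% names(d)) d$source[1] else "")
  })
  unname(out)
}

#' @rdname read_observations
#' @param observations list of observations.
#' @export
write_observations <- function(observations, path) {
  rows <- do.call(rbind, lapply(observations, function(o) {
    data.frame(label = o$label,
               clamps = format_clamps(o$scenario$inputs),
               species = names(o$expected), value = unname(o$expected),
               source = o$source, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a comparison report as TSV
#'
#' @param comparison a `lih_comparison`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_comparison_tsv <- function(comparison, path) {
  utils::write.table(comparison$details, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
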