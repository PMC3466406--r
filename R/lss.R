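#' Simulation scenarios
#'
#' A scenario fixes species values before propagation. Input clamps represent
#' ligand presence/absence, perturbation clamps represent constitutive
#' activation or inhibition (e.g. knockouts, small-molecule inhibition), and
#' frozen species are held at a reference value (typically their unstimulated
#' steady state) unless they are themselves perturbed. The three maps must be
#' disjoint; when an analysis overlays new perturbations (see
#' [scenario_perturb()]) the perturbation replaces any previous clamp.
#'
#' @param inputs named integer vector of input clamps.
#' @param perturbations named integer vector of constitutive clamps.
#' @param frozen named integer vector of frozen reference values.
#' @param time_scale_mode `"full"` (all hyperarcs active) or `"initial"`
#'   (time-scale-2 arcs removed before propagation, opening feedback loops).
#' @return a `lih_scenario`.
#' @export
lih_scenario <- function(inputs = integer(0), perturbations = integer(0),
                         frozen = integer(0),
                         time_scale_mode = c("full", "initial")) {
  as_clamp <- function(x, what) {
    if (length(x) == 0L) return(stats::setNames(integer(0), character(0)))
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      stop(what, " clamps must be a named vector", call. = FALSE)
    }
    stats::setNames(as.integer(x), names(x))
  }
  sc <- structure(list(inputs = as_clamp(inputs, "input"),
                       perturbations = as_clamp(perturbations, "perturbation"),
                       frozen = as_clamp(frozen, "frozen"),
                       time_scale_mode = match.arg(time_scale_mode)),
                  class = "lih_scenario")
  all_names <- c(names(sc$inputs), names(sc$perturbations), names(sc$frozen))
  if (anyDuplicated(all_names)) {
    stop("species may appear in at most one of inputs/perturbations/frozen: ",
         paste(unique(all_names[duplicated(all_names)]), collapse = ", "),
         call. = FALSE)
  }
  sc
}

#' Overlay perturbation clamps on a scenario
#'
#' New perturbations take precedence: the species are removed from the
#' input and frozen maps first. This is how intervention candidates are
#' applied on top of a context.
#'
#' @param scenario a `lih_scenario`.
#' @param clamps named integer vector.
#' @return modified scenario.
#' @export
scenario_perturb <- function(scenario, clamps) {
  clamps <- stats::setNames(as.integer(clamps), names(clamps))
  keep_in <- setdiff(names(scenario$inputs), names(clamps))
  keep_fr <- setdiff(names(scenario$frozen), names(clamps))
  pert <- scenario$perturbations
  pert <- pert[setdiff(names(pert), names(clamps))]
  lih_scenario(inputs = scenario$inputs[keep_in],
               perturbations = c(pert, clamps),
               frozen = scenario$frozen[keep_fr],
               time_scale_mode = scenario$time_scale_mode)
}

effective_clamps <- function(scenario) {
  c(scenario$perturbations, scenario$inputs, scenario$frozen)
}

check_scenario <- function(model, scenario) {
  ml <- max_levels(model)
  cl <- effective_clamps(scenario)
  unknown <- setdiff(names(cl), names(ml))
  if (length(unknown) > 0L) {
    stop("unknown species in scenario: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  bad <- cl < 0L | cl > ml[names(cl)]
  if (any(bad)) {
    stop("clamp level out of range for: ",
         paste(sprintf("%s=%d", names(cl)[bad], cl[bad]), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

# three-valued literal evaluation: TRUE / FALSE / NA (undetermined)
eval_literal <- function(lit, values) {
  v <- values[[lit$species]]
  if (is.na(v)) return(NA)
  if (lit$negated) v < lit$threshold else v >= lit$threshold
}

# arc condition status under Kleene semantics
eval_condition <- function(lits, values) {
  out <- TRUE
  for (lit in lits) {
    s <- eval_literal(lit, values)
    if (isFALSE(s)) return(FALSE)
    if (is.na(s)) out <- NA
  }
  out
}

#' Compute the partial logical steady state
#'
#' Propagates clamps through the hypergraph under three-valued (Kleene)
#' semantics to the least fixed point of the information order: every species
#' starts undetermined; an arc condition is false as soon as one literal is
#' determined-false, true once all literals are determined-true, and
#' undetermined otherwise. A species with incoming arcs becomes 0 when all
#' arcs are false; it becomes level `L` when some arc with target level `L`
#' is true and no not-false arc carries a higher target level (OR across arcs
#' resolves to the maximum satisfied level). ITT gates force their target
#' level when all inputs are true, 0 when all are false, and leave the target
#' undetermined otherwise. A species with no active incoming arcs takes its
#' clamp, else its default level, else stays undetermined. Because the update
#' is monotone in the information order the fixed point is unique and
#' independent of evaluation order; determined values agree with every
#' synchronous fixed point consistent with the clamps.
#'
#' Clamped species always carry their clamped value: a clamp models
#' constitutive override. If propagation would have assigned a different
#' determined value, the conflict is recorded in the state's `conflicts`
#' table rather than raised.
#'
#' @param model validated [lih_model()].
#' @param scenario [lih_scenario()]; its `time_scale_mode` selects whether
#'   time-scale-2 arcs participate.
#' @return a `lih_state`: named `values` vector (`NA` = undetermined),
#'   `determined_fraction`, and a `conflicts` data frame.
#' @export
compute_lss <- function(model, scenario = lih_scenario()) {
  check_scenario(model, scenario)
  nm <- species_names(model)
  ml <- max_levels(model)
  dl <- default_levels(model)
  clamps <- effective_clamps(scenario)
  initial <- scenario$time_scale_mode == "initial"

  arcs_by_target <- split(
    model$hyperarcs,
    factor(vapply(model$hyperarcs, `[[`, "", "target"), levels = nm))
  if (initial) {
    arcs_by_target <- lapply(arcs_by_target, function(arcs) {
      Filter(function(h) h$time_scale == 1L, arcs)
    })
  }
  gate_by_target <- stats::setNames(vector("list", length(nm)), nm)
  for (g in model$itt_gates) gate_by_target[[g$target]] <- g

  values <- stats::setNames(rep(NA_integer_, length(nm)), nm)
  clamped <- nm %in% names(clamps)
  values[names(clamps)] <- clamps

  eval_species <- function(s) {
    gate <- gate_by_target[[s]]
    if (!is.null(gate)) {
      st <- eval_condition(gate$inputs, values)
      if (isTRUE(st)) return(gate$target_level)
      if (isFALSE(st)) {
        # all-false corner only: every input individually false
        each <- vapply(gate$inputs, function(l) {
          isFALSE(eval_literal(l, values))
        }, TRUE)
        if (all(each)) return(0L)
        return(NA_integer_)
      }
      return(NA_integer_)
    }
    arcs <- arcs_by_target[[s]]
    if (length(arcs) == 0L) return(dl[[s]])
    best_true <- -1L
    any_open <- FALSE
    max_open <- -1L
    for (h in arcs) {
      st <- eval_condition(h$condition, values)
      if (isTRUE(st)) {
        if (h$target_level > best_true) best_true <- h$target_level
      } else if (is.na(st)) {
        any_open <- TRUE
        if (h$target_level > max_open) max_open <- h$target_level
      }
    }
    if (best_true < 0L && !any_open) return(0L)
    if (best_true >= 0L && (!any_open || max_open <= best_true)) {
      return(best_true)
    }
    NA_integer_
  }

  free <- nm[!clamped]
  cap <- length(nm) * (max(ml) + 1L) + 2L
  for (iter in seq_len(cap)) {
    changed <- FALSE
    for (s in free) {
      if (!is.na(values[[s]])) next
      v <- eval_species(s)
      if (!is.na(v)) {
        values[[s]] <- v
        changed <- TRUE
      }
    }
    if (!changed) break
    if (iter == cap) {
      stop("propagation failed to reach a fixed point within the iteration cap",
           call. = FALSE) # nocov
    }
  }

  conflicts <- data.frame(species = character(0), clamped = integer(0),
                          implied = integer(0), stringsAsFactors = FALSE)
  for (s in nm[clamped]) {
    has_logic <- !is.null(gate_by_target[[s]]) ||
      length(arcs_by_target[[s]]) > 0L
    if (!has_logic) next
    implied <- eval_species(s)
    if (!is.na(implied) && implied != values[[s]]) {
      conflicts <- rbind(conflicts,
                         data.frame(species = s, clamped = values[[s]],
                                    implied = implied,
                                    stringsAsFactors = FALSE))
    }
  }

  structure(list(values = values,
                 determined_fraction = mean(!is.na(values)),
                 conflicts = conflicts,
                 scenario = scenario),
            class = "lih_state")
}

#' @exportS3Method base::print
print.lih_state <- function(x, ...) {
  cat(sprintf("<lih_state> %d/%d species determined (%.1f%%)\n",
              sum(!is.na(x$values)), length(x$values),
              100 * x$determined_fraction))
  v <- x$values
  cat(paste(sprintf("  %s = %s", names(v), ifelse(is.na(v), "?", v)),
            collapse = "\n"), "\n")
  if (nrow(x$conflicts) > 0L) {
    cat(sprintf("  %d clamp/propagation conflict(s)\n", nrow(x$conflicts)))
  }
  invisible(x)
}

#' Explain why species remained undetermined
#'
#' Classifies every undetermined species of a partial logical steady state
#' into one or more causes: `undefined-input` (an unclamped source species
#' with no default), `ITT` (an ITT gate with mixed input determinacy), or
#' `feedback-loop` (membership in a cycle of the subnetwork induced by the
#' undetermined species). Causes are propagated downstream: a species also
#' inherits the causes of its undetermined regulators.
#'
#' @param model validated model.
#' @param scenario the scenario used for `state`.
#' @param state result of [compute_lss()] on `(model, scenario)`.
#' @return data frame with columns `species`, `cause`; zero rows for fully
#'   determined states.
#' @export
explain_indeterminacy <- function(model, scenario, state) {
  if (!identical(sort(names(state$values)), sort(species_names(model)))) {
    stop("state does not match model", call. = FALSE)
  }
  und <- names(state$values)[is.na(state$values)]
  if (length(und) == 0L) {
    return(data.frame(species = character(0), cause = character(0),
                      stringsAsFactors = FALSE))
  }
  initial <- scenario$time_scale_mode == "initial"
  active_arcs <- Filter(function(h) !initial || h$time_scale == 1L,
                        model$hyperarcs)
  preds <- stats::setNames(vector("list", length(und)), und)
  causes <- stats::setNames(vector("list", length(und)), und)
  itt_targets <- vapply(model$itt_gates, `[[`, "", "target")
  dl <- default_levels(model)
  for (s in und) {
    arcs_in <- Filter(function(h) h$target == s, active_arcs)
    gate <- if (s %in% itt_targets) {
      model$itt_gates[[match(s, itt_targets)]]
    } else NULL
    lits <- c(unlist(lapply(arcs_in, `[[`, "condition"), recursive = FALSE),
              if (!is.null(gate)) gate$inputs)
    preds[[s]] <- intersect(unique(vapply(lits, `[[`, "", "species")), und)
    base <- character(0)
    if (length(arcs_in) == 0L && is.null(gate) && is.na(dl[[s]])) {
      base <- c(base, "undefined-input")
    }
    if (!is.null(gate)) base <- c(base, "ITT")
    causes[[s]] <- base
  }
  # feedback attribution: cycles within the undetermined subnetwork
  in_cycle <- vapply(und, function(s) {
    # BFS from successors of s back to s inside `und`
    succ <- function(x) und[vapply(und, function(t) x %in% preds[[t]], TRUE)]
    frontier <- succ(s)
    seen <- character(0)
    while (length(frontier) > 0L) {
      if (s %in% frontier) return(TRUE)
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(lapply(frontier, succ))), seen)
    }
    FALSE
  }, TRUE)
  for (s in und[in_cycle]) causes[[s]] <- c(causes[[s]], "feedback-loop")
  # inherit causes from undetermined regulators to a fixed point
  repeat {
    changed <- FALSE
    for (s in und) {
      inherited <- unique(unlist(causes[preds[[s]]]))
      merged <- union(causes[[s]], inherited)
      if (length(merged) > length(causes[[s]])) {
        causes[[s]] <- merged
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(und, function(s) {
    if (length(causes[[s]]) == 0L) {
      return(NULL) # nocov -- every undetermined species has a cause
    }
    data.frame(species = s, cause = sort(causes[[s]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$species, out$cause), , drop = FALSE]
}

#' Write a network state as TSV
#'
#' Two columns (`species`, `value`); undetermined species are written `NA`.
#'
#' @param state a `lih_state`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_state_tsv <- function(state, path) {
  df <- data.frame(species = names(state$values),
                   value = unname(state$values), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a scenario from tabular text
#'
#' One clamp per line: `species value kind` with kind in
#' `input`/`perturb`/`frozen` (tab- or whitespace-separated, `#` comments).
#'
#' @param path input file.
#' @param time_scale_mode passed to [lih_scenario()].
#' @return a `lih_scenario`.
#' @export
read_scenario <- function(path, time_scale_mode = "full") {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  inputs <- integer(0); pert <- integer(0); frozen <- integer(0)
  for (ln in lines) {
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(f) != 3L) stop("malformed scenario line: ", ln, call. = FALSE)
    v <- stats::setNames(as.integer(f[2]), f[1])
    switch(match.arg(f[3], c("input", "perturb", "frozen")),
           input = inputs <- c(inputs, v),
           perturb = pert <- c(pert, v),
           frozen = frozen <- c(frozen, v))
  }
  lih_scenario(inputs, pert, frozen, time_scale_mode = time_scale_mode)
}
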