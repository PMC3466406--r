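#' Logical interaction hypergraph models
#'
#' A logical interaction hypergraph (LIH) represents a signaling network as a
#' set of discrete-valued species connected by hyperarcs. Each hyperarc is an
#' AND conjunction of literals that, when satisfied, drives its target species
#' to a given level; several hyperarcs into the same target combine by OR
#' (sum-of-products form). Multivalued species carry levels `0..max_level`.
#' Hyperarcs are tagged with a time scale (1 or 2); scale-2 arcs are the
#' cycle-closing reactions that are removed when computing the initial
#' response of the network. Incomplete-truth-table (ITT) gates encode
#' multi-input activation where only the all-active and all-inactive corners
#' of the truth table are known.
#'
#' @section Species roles:
#' `normal` species are biomolecular entities; `dummy` species are
#' bookkeeping nodes that compress sum-of-product logic; `reservoir` species
#' model shared protein pools — they never have incoming hyperarcs, and
#' setting a reservoir to 0 disables every complex whose condition contains
#' it (a consequence of plain AND semantics, no special engine support).
#'
#' @name lih_model
NULL

#' Species definition
#'
#' @param name identifier (`[A-Za-z0-9_]+`, case sensitive).
#' @param max_level maximum discrete level (1 = Boolean).
#' @param role one of `"normal"`, `"dummy"`, `"reservoir"`.
#' @param default_level level adopted when the species has no incoming
#'   hyperarc and is not clamped; `NA` means undetermined in that case.
#' @return a `lih_species` list.
#' @export
lih_species <- function(name, max_level = 1L, role = "normal",
                        default_level = NA_integer_) {
  structure(list(name = as.character(name),
                 max_level = as.integer(max_level),
                 role = match.arg(role, c("normal", "dummy", "reservoir")),
                 default_level = as.integer(default_level)),
            class = "lih_species")
}

#' Literal: a threshold test on one species
#'
#' A positive literal with threshold `t` is true iff the species value is
#' `>= t`; a negated literal is true iff the value is `< t`. With Boolean
#' species and `t = 1` this reduces to the usual `A` / `!A`.
#'
#' @param species species identifier.
#' @param threshold integer `>= 1`.
#' @param negated logical flag.
#' @return a `lih_literal` list.
#' @export
lih_literal <- function(species, threshold = 1L, negated = FALSE) {
  structure(list(species = as.character(species),
                 threshold = as.integer(threshold),
                 negated = isTRUE(negated)),
            class = "lih_literal")
}

#' Hyperarc: an AND conjunction driving a target level
#'
#' @param id unique identifier.
#' @param condition list of [lih_literal()] (implicit AND; at most one
#'   literal per species).
#' @param target target species identifier (never a reservoir).
#' @param target_level level the target adopts when the condition holds.
#' @param time_scale 1 (immediate) or 2 (cycle-closing, removed in
#'   initial-response analyses).
#' @return a `lih_hyperarc` list.
#' @export
lih_hyperarc <- function(id, condition, target, target_level = 1L,
                         time_scale = 1L) {
  if (inherits(condition, "lih_literal")) condition <- list(condition)
  structure(list(id = as.character(id),
                 condition = condition,
                 target = as.character(target),
                 target_level = as.integer(target_level),
                 time_scale = as.integer(time_scale)),
            class = "lih_hyperarc")
}

#' Incomplete-truth-table gate
#'
#' All inputs true drives the target to `target_level`; all inputs false
#' drives it to 0; any mixed input combination leaves the target undetermined.
#'
#' @param target target species identifier.
#' @param inputs list of at least two [lih_literal()].
#' @param target_level output level for the all-true corner.
#' @return a `lih_itt_gate` list.
#' @export
lih_itt_gate <- function(target, inputs, target_level = 1L) {
  structure(list(target = as.character(target),
                 inputs = inputs,
                 target_level = as.integer(target_level)),
            class = "lih_itt_gate")
}

#' Assemble a logical model
#'
#' @param species list of [lih_species()].
#' @param hyperarcs list of [lih_hyperarc()].
#' @param itt_gates list of [lih_itt_gate()].
#' @param metadata free-form named list.
#' @param validate if `TRUE` (default), stop on any invariant violation.
#' @return a validated `lih_model`.
#' @seealso [validate_model()], [parse_model()], [serialize_model()]
#' @export
lih_model <- function(species = list(), hyperarcs = list(),
                      itt_gates = list(), metadata = list(),
                      validate = TRUE) {
  m <- structure(list(species = species,
                      hyperarcs = hyperarcs,
                      itt_gates = itt_gates,
                      metadata = metadata),
                 class = "lih_model")
  if (validate) {
    v <- validate_model(m)
    if (nrow(v) > 0L) {
      stop("invalid model:\n", paste0("  - ", v$message, collapse = "\n"),
           call. = FALSE)
    }
  }
  m
}

species_names <- function(model) {
  vapply(model$species, `[[`, "", "name")
}

max_levels <- function(model) {
  stats::setNames(vapply(model$species, `[[`, 1L, "max_level"),
                  species_names(model))
}

default_levels <- function(model) {
  stats::setNames(vapply(model$species, `[[`, 1L, "default_level"),
                  species_names(model))
}

species_roles <- function(model) {
  stats::setNames(vapply(model$species, `[[`, "", "role"),
                  species_names(model))
}

hyperarc_ids <- function(model) {
  vapply(model$hyperarcs, `[[`, "", "id")
}

#' Validate a logical model
#'
#' Checks every structural invariant and returns the violations as a data
#' frame instead of raising conditions, so a model editor can display all
#' problems at once.
#'
#' @param model a `lih_model` (possibly built with `validate = FALSE`).
#' @return data frame with columns `element`, `rule`, `message`; zero rows
#'   iff the model is valid.
#' @export
validate_model <- function(model) {
  bad <- list()
  note <- function(element, rule, message) {
    bad[[length(bad) + 1L]] <<- data.frame(element = element, rule = rule,
                                           message = message,
                                           stringsAsFactors = FALSE)
  }
  nm <- species_names(model)
  ok_id <- is_identifier(nm)
  for (s in nm[!ok_id]) {
    note(s, "identifier", sprintf("species name '%s' is not a valid identifier", s))
  }
  if (anyDuplicated(nm)) {
    for (s in unique(nm[duplicated(nm)])) {
      note(s, "unique-name", sprintf("species '%s' declared more than once", s))
    }
  }
  ml <- max_levels(model)
  dl <- default_levels(model)
  roles <- species_roles(model)
  for (i in seq_along(model$species)) {
    sp <- model$species[[i]]
    if (sp$max_level < 1L) {
      note(sp$name, "max-level", sprintf("species '%s' has max_level < 1", sp$name))
    }
    if (!is.na(sp$default_level) &&
        (sp$default_level < 0L || sp$default_level > sp$max_level)) {
      note(sp$name, "default-level",
           sprintf("species '%s' default level %d outside [0, %d]",
                   sp$name, sp$default_level, sp$max_level))
    }
  }

  check_literals <- function(lits, where) {
    used <- character(0)
    for (lit in lits) {
      if (!lit$species %in% nm) {
        note(where, "undeclared-species",
             sprintf("%s references undeclared species '%s'", where, lit$species))
        next
      }
      if (lit$threshold < 1L || lit$threshold > ml[[lit$species]]) {
        note(where, "threshold",
             sprintf("%s: threshold %d on '%s' outside [1, %d]",
                     where, lit$threshold, lit$species, ml[[lit$species]]))
      }
      if (lit$species %in% used) {
        note(where, "duplicate-literal",
             sprintf("%s has more than one literal on species '%s'",
                     where, lit$species))
      }
      used <- c(used, lit$species)
    }
  }

  ids <- hyperarc_ids(model)
  if (anyDuplicated(ids)) {
    for (id in unique(ids[duplicated(ids)])) {
      note(id, "unique-rule-id", sprintf("duplicate hyperarc id '%s'", id))
    }
  }
  for (h in model$hyperarcs) {
    where <- sprintf("hyperarc '%s'", h$id)
    if (length(h$condition) == 0L) {
      note(h$id, "empty-condition", sprintf("%s has an empty condition", where))
    }
    check_literals(h$condition, where)
    if (!h$target %in% nm) {
      note(h$id, "undeclared-species",
           sprintf("%s targets undeclared species '%s'", where, h$target))
    } else {
      if (roles[[h$target]] == "reservoir") {
        note(h$id, "reservoir-target",
             sprintf("%s targets reservoir species '%s'", where, h$target))
      }
      if (h$target_level < 1L || h$target_level > ml[[h$target]]) {
        note(h$id, "target-level",
             sprintf("%s: target level %d outside [1, %d]",
                     where, h$target_level, ml[[h$target]]))
      }
    }
    if (!h$time_scale %in% c(1L, 2L)) {
      note(h$id, "time-scale", sprintf("%s: time scale must be 1 or 2", where))
    }
  }

  itt_targets <- vapply(model$itt_gates, `[[`, "", "target")
  if (anyDuplicated(itt_targets)) {
    for (t in unique(itt_targets[duplicated(itt_targets)])) {
      note(t, "itt-exclusive", sprintf("species '%s' has more than one ITT gate", t))
    }
  }
  arc_targets <- vapply(model$hyperarcs, `[[`, "", "target")
  for (g in model$itt_gates) {
    where <- sprintf("ITT gate on '%s'", g$target)
    if (length(g$inputs) < 2L) {
      note(g$target, "itt-arity", sprintf("%s has fewer than two inputs", where))
    }
    check_literals(g$inputs, where)
    if (!g$target %in% nm) {
      note(g$target, "undeclared-species",
           sprintf("%s targets undeclared species '%s'", where, g$target))
    } else {
      if (roles[[g$target]] == "reservoir") {
        note(g$target, "reservoir-target",
             sprintf("%s targets reservoir species '%s'", where, g$target))
      }
      if (g$target_level < 1L || g$target_level > ml[[g$target]]) {
        note(g$target, "target-level",
             sprintf("%s: target level %d outside [1, %d]",
                     where, g$target_level, ml[[g$target]]))
      }
      if (g$target %in% arc_targets) {
        note(g$target, "itt-exclusive",
             sprintf("species '%s' regulated by both an ITT gate and hyperarcs",
                     g$target))
      }
    }
  }

  if (length(bad) == 0L) {
    data.frame(element = character(0), rule = character(0),
               message = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, bad)
  }
}

#' @exportS3Method base::print
print.lih_model <- function(x, ...) {
  cat(sprintf("<lih_model> %d species, %d hyperarcs, %d ITT gates\n",
              length(x$species), length(x$hyperarcs), length(x$itt_gates)))
  ml <- max_levels(x)
  if (any(ml > 1L)) {
    cat("  multivalued:",
        paste(sprintf("%s(0..%d)", names(ml)[ml > 1L], ml[ml > 1L]),
              collapse = ", "), "\n")
  }
  ts2 <- sum(vapply(x$hyperarcs, `[[`, 1L, "time_scale") == 2L)
  if (ts2 > 0L) cat(sprintf("  %d hyperarc(s) at time scale 2\n", ts2))
  invisible(x)
}
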