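#' Intervention goals
#'
#' A goal is a conjunction of constraints on the logical steady state, e.g.
#' "DNA synthesis = 1" or "p53 >= 2". A goal is satisfied only by determined
#' values: an undetermined goal species counts as failure, because a state
#' that cannot be computed is not an enforced response.
#'
#' @param species character vector of goal species.
#' @param comparator vector of `"="`, `">="`, `"<="` (recycled).
#' @param level integer vector of goal levels (recycled).
#' @return a `lih_goal`.
#' @export
lih_goal <- function(species, comparator = "=", level = 1L) {
  df <- data.frame(species = as.character(species),
                   comparator = rep_len(as.character(comparator),
                                        length(species)),
                   level = rep_len(as.integer(level), length(species)),
                   stringsAsFactors = FALSE)
  if (!all(df$comparator %in% c("=", ">=", "<="))) {
    stop("comparator must be one of =, >=, <=", call. = FALSE)
  }
  structure(list(constraints = df), class = "lih_goal")
}

goal_satisfied <- function(goal, state) {
  for (i in seq_len(nrow(goal$constraints))) {
    g <- goal$constraints[i, ]
    v <- state$values[[g$species]]
    if (is.na(v)) return(FALSE)
    ok <- switch(g$comparator,
                 "=" = v == g$level,
                 ">=" = v >= g$level,
                 "<=" = v <= g$level)
    if (!ok) return(FALSE)
  }
  TRUE
}

check_goal <- function(model, goal) {
  ml <- max_levels(model)
  miss <- setdiff(goal$constraints$species, names(ml))
  if (length(miss) > 0L) {
    stop("goal references unknown species: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- goal$constraints$level < 0L |
    goal$constraints$level > ml[goal$constraints$species]
  if (any(bad)) {
    stop("goal level out of range for: ",
         paste(goal$constraints$species[bad], collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

new_intervention_set <- function(clamps) {
  clamps <- clamps[order(names(clamps))]
  structure(list(clamps = clamps, size = length(clamps)),
            class = "lih_intervention_set")
}

#' @exportS3Method base::print
print.lih_intervention_set <- function(x, ...) {
  cat(sprintf("<MIS size %d> %s\n", x$size,
              if (x$size == 0L) "(empty)" else format_clamps(x$clamps)))
  invisible(x)
}

#' Enumerate minimal intervention sets
#'
#' A minimal intervention set (MIS) is a support-minimal set of constitutive
#' clamps (activations to a positive level, inhibitions to 0) whose
#' application on top of a context scenario yields a logical steady state
#' satisfying every goal constraint. Support-minimal means that no proper
#' subset of the clamped species — under any clamp values — suffices;
#' enumeration is size-ascending with superset pruning, so the returned sets
#' are exactly the irreducible solutions up to `max_size`.
#'
#' Candidates default to all species except the goal species, species
#' already clamped as context perturbations, and the `excluded` set. Input
#' and frozen context species remain candidates: a perturbation overrides
#' them. Under the default `candidate_levels = "extremes"` policy each
#' candidate may be clamped to 0 or to its maximum level only; `"all"`
#' admits every level.
#'
#' @param model validated [lih_model()].
#' @param context [lih_scenario()] describing inputs/perturbations/frozen
#'   species; its time-scale mode is used for every evaluation.
#' @param goal a [lih_goal()].
#' @param max_size largest support size to enumerate (>= 1).
#' @param candidate_levels `"extremes"` or `"all"`.
#' @param excluded species never clamped.
#' @param candidates optional explicit candidate species set, overriding the
#'   default construction.
#' @param include_goal_species admit goal species as candidates (default
#'   `FALSE`; clamping the goal species trivially enforces it).
#' @param max_space guard on the number of (support, values) combinations
#'   evaluated.
#' @return list of `lih_intervention_set`, ordered by (size, support,
#'   values). If the context alone satisfies the goal, the single empty set
#'   is returned.
#' @export
compute_mis <- function(model, context, goal, max_size = 1L,
                        candidate_levels = c("extremes", "all"),
                        excluded = character(0), candidates = NULL,
                        include_goal_species = FALSE, max_space = 1e6) {
  candidate_levels <- match.arg(candidate_levels)
  check_scenario(model, context)
  check_goal(model, goal)
  if (max_size < 1L) stop("max_size must be >= 1", call. = FALSE)
  ml <- max_levels(model)

  if (is.null(candidates)) {
    candidates <- setdiff(species_names(model),
                          c(excluded, names(context$perturbations),
                            if (!include_goal_species) goal$constraints$species))
  } else {
    miss <- setdiff(candidates, species_names(model))
    if (length(miss) > 0L) {
      stop("unknown candidate species: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    candidates <- setdiff(candidates, excluded)
    if (!include_goal_species) {
      candidates <- setdiff(candidates, goal$constraints$species)
    }
  }
  candidates <- sort(candidates)

  levels_for <- function(s) {
    if (candidate_levels == "extremes") {
      unique(c(0L, ml[[s]]))
    } else {
      0L:ml[[s]]
    }
  }

  # empty intervention: context already enforces the goal
  if (goal_satisfied(goal, compute_lss(model, context))) {
    return(list(new_intervention_set(stats::setNames(integer(0),
                                                     character(0)))))
  }
  if (length(candidates) == 0L) return(list())

  sizes <- seq_len(min(max_size, length(candidates)))
  space <- sum(vapply(sizes, function(k) {
    choose(length(candidates), k) * mean(lengths(lapply(candidates,
                                                        levels_for)))^k
  }, 1))
  if (space > max_space) {
    stop(sprintf("candidate space (~%.3g combinations) exceeds max_space (%g)",
                 space, max_space), call. = FALSE)
  }

  results <- list()
  accepted_supports <- list()
  for (k in sizes) {
    supports <- utils::combn(candidates, k, simplify = FALSE)
    for (sup in supports) {
      if (any(vapply(accepted_supports, function(a) all(a %in% sup), TRUE))) {
        next
      }
      value_grid <- expand.grid(rev(lapply(sup, levels_for)),
                                KEEP.OUT.ATTRS = FALSE)
      value_grid <- value_grid[, rev(seq_len(k)), drop = FALSE]
      names(value_grid) <- sup
      hit <- FALSE
      for (r in seq_len(nrow(value_grid))) {
        clamps <- stats::setNames(as.integer(value_grid[r, ]), sup)
        st <- compute_lss(model, scenario_perturb(context, clamps))
        if (goal_satisfied(goal, st)) {
          results[[length(results) + 1L]] <- new_intervention_set(clamps)
          hit <- TRUE
        }
      }
      if (hit) accepted_supports[[length(accepted_supports) + 1L]] <- sup
    }
  }
  results
}

#' MIS restricted to direct mediators of a module
#'
#' Finds the species within a module that directly mediate a response, by
#' removing indirect candidates: every module species is frozen at its value
#' in the unstimulated reference steady state (computed from the context
#' without perturbations), and interventions are allowed on module species
#' only. In a chain A -> B -> C with goal C = 1, freezing A and B at their
#' unstimulated value 0 removes A = 1 (which acts only through B) and leaves
#' B = 1 as the only size-1 set.
#'
#' @param model validated model.
#' @param context context scenario (typically unstimulated inputs).
#' @param goal a [lih_goal()].
#' @param module_species species subset to freeze and to intervene on.
#' @param max_size largest support size (defaults to the module size).
#' @param ... passed to [compute_mis()].
#' @return list of `lih_intervention_set`.
#' @export
mis_direct_mediators <- function(model, context, goal, module_species,
                                 max_size = length(module_species), ...) {
  miss <- setdiff(module_species, species_names(model))
  if (length(miss) > 0L) {
    stop("module species not in model: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (length(module_species) == 0L) return(list())
  ref <- compute_lss(model, context)
  vals <- ref$values[module_species]
  if (anyNA(vals)) {
    stop("unstimulated reference state undetermined for: ",
         paste(module_species[is.na(vals)], collapse = ", "), call. = FALSE)
  }
  keep_in <- setdiff(names(context$inputs), module_species)
  keep_fr <- setdiff(names(context$frozen), module_species)
  frozen_ctx <- lih_scenario(
    inputs = context$inputs[keep_in],
    perturbations = context$perturbations,
    frozen = c(context$frozen[keep_fr], vals),
    time_scale_mode = context$time_scale_mode)
  compute_mis(model, frozen_ctx, goal, max_size = max_size,
              candidates = module_species, ...)
}

#' Cross-tabulate intervention targets against a mutation list
#'
#' Builds the 2x2 contingency table comparing MIS membership with presence
#' in a mutation database over a species universe, optionally after removing
#' an exclusion list (e.g. cell-cycle inhibitors whose basal activity the
#' model does not represent).
#'
#' @param mis_species species occurring in any MIS.
#' @param mutated species with recorded mutations.
#' @param universe species universe for the comparison.
#' @param excluded species removed from the universe before counting.
#' @return 2x2 integer matrix with rows `mutated`/`not_mutated` and columns
#'   `in_mis`/`not_in_mis` (class `lih_contingency`).
#' @export
annotate_mis_overlap <- function(mis_species, mutated, universe,
                                 excluded = character(0)) {
  if (!all(mis_species %in% universe) || !all(mutated %in% universe)) {
    stop("mis_species and mutated must be subsets of the universe",
         call. = FALSE)
  }
  dropped_mis <- intersect(excluded, mis_species)
  if (length(dropped_mis) > 0L) {
    warning("excluded species are MIS members: ",
            paste(dropped_mis, collapse = ", "), call. = FALSE)
  }
  u <- setdiff(universe, excluded)
  in_mis <- u %in% mis_species
  mut <- u %in% mutated
  tab <- matrix(c(sum(mut & in_mis), sum(mut & !in_mis),
                  sum(!mut & in_mis), sum(!mut & !in_mis)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("mutated", "not_mutated"),
                                c("in_mis", "not_in_mis")))
  structure(tab, class = c("lih_contingency", class(tab)))
}

#' Write an MIS report as TSV
#'
#' Columns: `size`, `clamps` (comma-separated `species=value`), `goal`.
#'
#' @param mis list of `lih_intervention_set`.
#' @param goal the goal that was enforced (labels the rows).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_mis_tsv <- function(mis, goal, path) {
  goal_id <- paste(sprintf("%s%s%d", goal$constraints$species,
                           goal$constraints$comparator,
                           goal$constraints$level), collapse = ",")
  df <- data.frame(size = vapply(mis, `[[`, 1L, "size"),
                   clamps = vapply(mis, function(m) format_clamps(m$clamps), ""),
                   goal = goal_id, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
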