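#' Structural edits
#'
#' Structural sensitivity analysis perturbs the wiring, not the parameters:
#' a time-scale-1 hyperarc can be removed, or an AND conjunction with at
#' least two literals can be weakened to parallel OR arcs or replaced by an
#' ITT gate. Time-scale-2 arcs are never edited — they encode the
#' cycle-opening bookkeeping, not biochemical hypotheses.
#'
#' @param kind `"remove_reaction"`, `"and_to_or"`, or `"and_to_itt"`.
#' @param arc_ids hyperarc id(s) the edit applies to.
#' @return a `lih_edit`.
#' @export
lih_edit <- function(kind = c("remove_reaction", "and_to_or", "and_to_itt"),
                     arc_ids) {
  structure(list(kind = match.arg(kind), arc_ids = as.character(arc_ids)),
            class = "lih_edit")
}

#' Apply structural edits to a model
#'
#' `remove_reaction` deletes the hyperarc; `and_to_or` replaces one AND
#' hyperarc by parallel single-literal hyperarcs (ids `<id>.or1`, ...) to
#' the same target and level; `and_to_itt` replaces it by an ITT gate with
#' the same inputs and target level, which is only possible when the target
#' has no other incoming hyperarc (ITT gates are exclusive regulators).
#'
#' @param model validated [lih_model()].
#' @param edits list of [lih_edit()] (a single edit is accepted).
#' @return the edited, validated model.
#' @export
apply_edits <- function(model, edits) {
  if (inherits(edits, "lih_edit")) edits <- list(edits)
  ids <- hyperarc_ids(model)
  for (e in edits) {
    for (aid in e$arc_ids) {
      k <- match(aid, hyperarc_ids(model))
      if (is.na(k)) stop("no hyperarc with id '", aid, "'", call. = FALSE)
      h <- model$hyperarcs[[k]]
      if (h$time_scale != 1L) {
        stop("edit on time-scale-2 hyperarc '", aid, "'", call. = FALSE)
      }
      if (e$kind != "remove_reaction" && length(h$condition) < 2L) {
        stop(e$kind, " requires a condition with >= 2 literals ('", aid, "')",
             call. = FALSE)
      }
      model$hyperarcs[[k]] <- NULL
      if (e$kind == "and_to_or") {
        for (i in seq_along(h$condition)) {
          model$hyperarcs[[length(model$hyperarcs) + 1L]] <-
            lih_hyperarc(sprintf("%s.or%d", h$id, i),
                         list(h$condition[[i]]), h$target,
                         h$target_level, h$time_scale)
        }
      } else if (e$kind == "and_to_itt") {
        other <- vapply(model$hyperarcs, `[[`, "", "target") == h$target
        if (any(other)) {
          stop("and_to_itt on '", aid, "': target '", h$target,
               "' has other incoming hyperarcs", call. = FALSE)
        }
        model$itt_gates[[length(model$itt_gates) + 1L]] <-
          lih_itt_gate(h$target, h$condition, h$target_level)
      }
    }
  }
  v <- validate_model(model)
  if (nrow(v) > 0L) {
    stop("edited model is invalid:\n",
         paste0("  - ", v$message, collapse = "\n"), call. = FALSE)
  }
  model
}

score_correct <- function(model, observations, time_scale_mode) {
  cmp <- compare_observations(model, observations,
                              time_scale_mode = time_scale_mode)
  unname(cmp$summary$counts[["match"]])
}

eligible_arcs <- function(model, kind) {
  ok <- vapply(model$hyperarcs, function(h) {
    h$time_scale == 1L && (kind == "remove_reaction" || length(h$condition) >= 2L)
  }, TRUE)
  # and_to_itt additionally needs an exclusively-regulated target
  if (kind == "and_to_itt") {
    targets <- vapply(model$hyperarcs, `[[`, "", "target")
    ok <- ok & vapply(seq_along(model$hyperarcs), function(i) {
      sum(targets == targets[i]) == 1L
    }, TRUE)
  }
  hyperarc_ids(model)[ok]
}

#' Structural sensitivity scan
#'
#' Generates a pool of edited models (all combinations, or a seeded sample,
#' of `n_edits` eligible arcs per edit kind — kinds are not mixed within one
#' pool), scores each against the observations, and reports agreement
#' relative to the unedited reference model: `relative = 100 * correct /
#' reference_correct`. A variant whose edit combination is inapplicable
#' (e.g. an ITT conversion colliding with another edit's output) is reported
#' with `NA` scores.
#'
#' @param model validated reference model.
#' @param observations list of [lih_observation()]; multiple datasets should
#'   be concatenated beforehand (see [dedup_observations()]).
#' @param n_edits edits per variant (1-3).
#' @param kinds edit kinds to scan (each gets its own pool).
#' @param mode `"exhaustive"` or `"sampled"`.
#' @param sample_n number of variants per kind when sampling.
#' @param seed RNG seed for sampling.
#' @param time_scale_mode scoring mode, see [compare_observations()].
#' @return a `lih_sensitivity`: `variants` data frame (kind, edits, correct,
#'   relative) and per-kind `summary` (mean, min, fraction >= 90%).
#' @export
sensitivity_scan <- function(model, observations, n_edits = 1L,
                             kinds = c("remove_reaction", "and_to_or",
                                       "and_to_itt"),
                             mode = c("exhaustive", "sampled"),
                             sample_n = 100L, seed = 1L,
                             time_scale_mode = "initial") {
  mode <- match.arg(mode)
  if (length(observations) == 0L) stop("empty observation list", call. = FALSE)
  if (!n_edits %in% 1:3) stop("n_edits must be 1, 2 or 3", call. = FALSE)
  kinds <- match.arg(kinds, several.ok = TRUE)
  ref <- score_correct(model, observations, time_scale_mode)
  if (ref == 0L) {
    stop("reference model scores 0 correct predictions; relative agreement undefined",
         call. = FALSE)
  }
  rows <- list()
  for (kind in kinds) {
    elig <- eligible_arcs(model, kind)
    if (length(elig) < n_edits) next
    combos <- utils::combn(elig, n_edits, simplify = FALSE)
    if (mode == "sampled" && length(combos) > sample_n) {
      combos <- with_seed(seed, sample(combos, sample_n))
    }
    for (arcs in combos) {
      res <- tryCatch({
        edited <- apply_edits(model, lih_edit(kind, arcs))
        correct <- score_correct(edited, observations, time_scale_mode)
        c(correct = correct, relative = 100 * correct / ref)
      }, error = function(e) c(correct = NA_real_, relative = NA_real_))
      rows[[length(rows) + 1L]] <-
        data.frame(kind = kind, edits = paste(arcs, collapse = ","),
                   correct = res[["correct"]], relative = res[["relative"]],
                   stringsAsFactors = FALSE)
    }
  }
  variants <- do.call(rbind, rows)
  summaries <- lapply(split(variants, variants$kind), function(d) {
    rel <- d$relative[!is.na(d$relative)]
    list(n = nrow(d), mean = mean(rel), min = min(rel),
         frac_ge_90 = mean(rel >= 90))
  })
  structure(list(reference_correct = ref, n_edits = n_edits,
                 variants = variants, summary = summaries),
            class = "lih_sensitivity")
}

#' @exportS3Method base::print
print.lih_sensitivity <- function(x, ...) {
  cat(sprintf("<lih_sensitivity> %d edit(s) per variant, reference correct = %d\n",
              x$n_edits, x$reference_correct))
  for (kind in names(x$summary)) {
    s <- x$summary[[kind]]
    cat(sprintf("  %s: n=%d mean=%.1f%% min=%.1f%% >=90%%: %.1f%%\n",
                kind, s$n, s$mean, s$min, 100 * s$frac_ge_90))
  }
  invisible(x)
}

#' Deduplicate observations by label
#'
#' When literature and experimental datasets are concatenated, scenarios
#' present in both can be deduplicated by label, keeping the LAST occurrence
#' (so appending one's own data resolves conflicts in its favor).
#'
#' @param observations list of observations.
#' @return filtered list.
#' @export
dedup_observations <- function(observations) {
  labels <- vapply(observations, `[[`, "", "label")
  keep <- !duplicated(labels, fromLast = TRUE)
  observations[keep]
}

#' Enumerate model variants that fully explain a dataset
#'
#' Applies every subset of an optional-edit space to the base model, keeps
#' the variants whose predictions reproduce every observation (no mismatch,
#' no indeterminate), and groups them into versions. A version is an
#' equivalence class of variants with identical input-output behavior; by
#' default behavior is compared on the dataset's scenarios
#' (`group_by = "dataset"`), while `group_by = "full_io"` compares full
#' truth tables over the dataset's input species (see the methods vignette
#' for the rationale).
#'
#' @param base_model validated model.
#' @param edit_space list of [lih_edit()], each independently applied or not.
#' @param observations list of observations.
#' @param group_by `"dataset"` or `"full_io"`.
#' @param time_scale_mode scoring mode.
#' @param max_space guard on `2^length(edit_space)`.
#' @return a `lih_variants`: `variants` data frame (edits, correct,
#'   explains, class), `n_explaining`, `n_classes`.
#' @export
enumerate_variants <- function(base_model, edit_space, observations,
                               group_by = c("dataset", "full_io"),
                               time_scale_mode = "initial",
                               max_space = 4096) {
  group_by <- match.arg(group_by)
  if (length(observations) == 0L) stop("empty observation list", call. = FALSE)
  m <- length(edit_space)
  if (2^m > max_space) {
    stop("edit space of ", m, " optional edits exceeds max_space",
         call. = FALSE)
  }
  n_obs <- sum(vapply(observations, function(o) length(o$expected), 1L))
  subsets <- if (m == 0L) list(integer(0)) else {
    unlist(lapply(0:m, function(k) {
      utils::combn(seq_len(m), k, simplify = FALSE)
    }), recursive = FALSE)
  }
  io_key <- function(model) {
    if (group_by == "dataset") {
      cmp <- compare_observations(model, observations,
                                  time_scale_mode = time_scale_mode)
      paste(ifelse(is.na(cmp$details$predicted), "?", cmp$details$predicted),
            collapse = "")
    } else {
      inputs <- sort(unique(unlist(lapply(observations, function(o) {
        names(o$scenario$inputs)
      }))))
      outputs <- sort(unique(unlist(lapply(observations, function(o) {
        names(o$expected)
      }))))
      keys <- vapply(outputs, function(out) {
        tt <- io_truth_table(model, inputs, out,
                             time_scale_mode = time_scale_mode)
        paste(ifelse(is.na(tt$rows$output), "?", tt$rows$output),
              collapse = "")
      }, "")
      paste(keys, collapse = ";")
    }
  }
  rows <- list()
  keys <- character(0)
  for (sub in subsets) {
    label <- if (length(sub) == 0L) "(none)" else {
      paste(vapply(edit_space[sub], function(e) {
        paste0(e$kind, ":", paste(e$arc_ids, collapse = "+"))
      }, ""), collapse = ",")
    }
    res <- tryCatch({
      variant <- apply_edits(base_model, edit_space[sub])
      cmp <- compare_observations(variant, observations,
                                  time_scale_mode = time_scale_mode)
      correct <- unname(cmp$summary$counts[["match"]])
      explains <- correct == n_obs
      key <- if (explains) io_key(variant) else NA_character_
      list(correct = correct, explains = explains, key = key)
    }, error = function(e) list(correct = NA_integer_, explains = FALSE,
                                key = NA_character_))
    keys <- c(keys, res$key)
    rows[[length(rows) + 1L]] <-
      data.frame(edits = label, correct = res$correct,
                 explains = res$explains, stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, rows)
  class_ids <- rep(NA_integer_, nrow(variants))
  uk <- unique(keys[!is.na(keys)])
  class_ids[!is.na(keys)] <- match(keys[!is.na(keys)], uk)
  variants$class <- class_ids
  structure(list(variants = variants,
                 n_explaining = sum(variants$explains, na.rm = TRUE),
                 n_classes = length(uk)),
            class = "lih_variants")
}

#' @exportS3Method base::print
print.lih_variants <- function(x, ...) {
  cat(sprintf("<lih_variants> %d variant(s), %d explain the data in %d version class(es)\n",
              nrow(x$variants), x$n_explaining, x$n_classes))
  invisible(x)
}

#' Write a sensitivity pool report as TSV
#'
#' @param scan a `lih_sensitivity`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_sensitivity_tsv <- function(scan, path) {
  utils::write.table(scan$variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
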