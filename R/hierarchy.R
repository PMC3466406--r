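#' Input-output truth table
#'
#' Evaluates the logical steady state for every assignment of the Boolean
#' input species and records the output value. Row order is lexicographic
#' with the first input as the most significant bit (row 1 = all zero).
#'
#' @param model validated [lih_model()].
#' @param inputs Boolean source species (no incoming hyperarcs or gates).
#' @param output output species.
#' @param time_scale_mode propagation mode (default `"initial"`, the mode
#'   used for input-output predictions).
#' @param base_scenario optional scenario supplying additional clamps
#'   (perturbations/frozen) applied in every row.
#' @return a `lih_io_table`: `inputs`, `output`, and a `rows` data frame
#'   with one column per input plus `output` (`NA` = undetermined).
#' @export
io_truth_table <- function(model, inputs, output,
                           time_scale_mode = "initial",
                           base_scenario = NULL) {
  nm <- species_names(model)
  miss <- setdiff(c(inputs, output), nm)
  if (length(miss) > 0L) {
    stop("unknown species: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (length(inputs) > 20L) {
    stop("refusing truth table over more than 20 inputs", call. = FALSE)
  }
  ml <- max_levels(model)
  if (any(ml[inputs] != 1L)) {
    stop("truth-table inputs must be Boolean", call. = FALSE)
  }
  targets <- c(vapply(model$hyperarcs, `[[`, "", "target"),
               vapply(model$itt_gates, `[[`, "", "target"))
  regulated <- inputs %in% targets
  if (any(regulated)) {
    stop("inputs must be source species; regulated: ",
         paste(inputs[regulated], collapse = ", "), call. = FALSE)
  }
  n <- length(inputs)
  grid <- expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_len(n)), drop = FALSE] # first input = MSB
  names(grid) <- inputs
  grid <- grid[do.call(order, grid), , drop = FALSE]
  rownames(grid) <- NULL
  out_vals <- integer(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    clamps <- stats::setNames(as.integer(grid[r, ]), inputs)
    sc <- if (is.null(base_scenario)) {
      lih_scenario(inputs = clamps, time_scale_mode = time_scale_mode)
    } else {
      lih_scenario(inputs = c(clamps,
                              base_scenario$inputs[setdiff(names(base_scenario$inputs),
                                                           inputs)]),
                   perturbations = base_scenario$perturbations,
                   frozen = base_scenario$frozen,
                   time_scale_mode = time_scale_mode)
    }
    out_vals[r] <- compute_lss(model, sc)$values[[output]]
  }
  rows <- cbind(grid, output = out_vals)
  structure(list(inputs = inputs, output = output, rows = rows),
            class = "lih_io_table")
}

#' @exportS3Method base::print
print.lih_io_table <- function(x, ...) {
  cat(sprintf("<lih_io_table> %s = f(%s): %d rows, %d active, %d undetermined\n",
              x$output, paste(x$inputs, collapse = ", "), nrow(x$rows),
              sum(x$rows$output >= 1L, na.rm = TRUE),
              sum(is.na(x$rows$output))))
  invisible(x)
}

# build an io table directly from a 0/1 output vector (row order as in
# io_truth_table); used by tests and by the hierarchy recursion
io_table_from_values <- function(inputs, values, output = "out") {
  n <- length(inputs)
  stopifnot(length(values) == 2^n)
  grid <- expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_len(n)), drop = FALSE]
  names(grid) <- inputs
  grid <- grid[do.call(order, grid), , drop = FALSE]
  rownames(grid) <- NULL
  structure(list(inputs = inputs, output = output,
                 rows = cbind(grid, output = as.integer(values))),
            class = "lih_io_table")
}

check_binary_table <- function(table) {
  out <- table$rows$output
  if (anyNA(out)) {
    stop("truth table contains undetermined rows; indeterminacy is ",
         "information and is not coerced", call. = FALSE)
  }
  if (!all(out %in% c(0L, 1L))) {
    stop("binary output required", call. = FALSE)
  }
  invisible(TRUE)
}

# ---- Quine-McCluskey ------------------------------------------------------
# implicants are strings over {0,1,-}, one character per input

qm_covers <- function(implicant, minterm_bits) {
  cs <- strsplit(implicant, "")[[1]]
  all(cs == "-" | cs == minterm_bits)
}

qm_merge <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  diff <- ca != cb
  if (sum(diff) != 1L) return(NULL)
  if (ca[diff] == "-" || cb[diff] == "-") return(NULL)
  ca[diff] <- "-"
  paste(ca, collapse = "")
}

prime_implicants <- function(minterms, n) {
  if (length(minterms) == 0L) return(character(0))
  bits <- function(m) {
    paste(rev(as.integer(intToBits(m))[seq_len(n)]), collapse = "")
  }
  current <- unique(vapply(minterms, bits, ""))
  primes <- character(0)
  while (length(current) > 0L) {
    merged_flag <- stats::setNames(rep(FALSE, length(current)), current)
    nxt <- character(0)
    if (length(current) > 1L) {
      for (i in seq_len(length(current) - 1L)) {
        for (j in (i + 1L):length(current)) {
          m <- qm_merge(current[i], current[j])
          if (!is.null(m)) {
            merged_flag[i] <- TRUE
            merged_flag[j] <- TRUE
            nxt <- c(nxt, m)
          }
        }
      }
    }
    primes <- c(primes, current[!merged_flag])
    current <- unique(nxt)
  }
  sort(unique(primes))
}

n_literals <- function(implicant) {
  sum(strsplit(implicant, "")[[1]] != "-")
}

# exact minimal cover over prime implicants: essential primes first, then
# exhaustive search over the rest, smallest cover first; ties broken by
# fewest total literals, then lexicographically
minimal_cover <- function(primes, minterms, n) {
  if (length(minterms) == 0L) return(character(0))
  mt_bits <- lapply(minterms, function(m) {
    as.character(rev(as.integer(intToBits(m))[seq_len(n)]))
  })
  cover_mat <- vapply(seq_along(minterms), function(j) {
    vapply(primes, qm_covers, TRUE, minterm_bits = mt_bits[[j]])
  }, logical(length(primes)))
  cover_mat <- matrix(cover_mat, nrow = length(primes))

  essential <- vapply(seq_along(minterms), function(j) {
    hits <- which(cover_mat[, j])
    if (length(hits) == 1L) hits else NA_integer_
  }, 1L)
  chosen <- sort(unique(essential[!is.na(essential)]))
  uncovered <- which(!apply(cover_mat[chosen, , drop = FALSE], 2, any))
  if (length(chosen) == 0L) uncovered <- seq_along(minterms)
  if (length(uncovered) == 0L) return(sort(primes[chosen]))

  rest <- setdiff(seq_along(primes), chosen)
  best <- NULL
  best_score <- NULL
  for (k in seq_len(length(rest))) {
    for (extra in utils::combn(rest, k, simplify = FALSE)) {
      sel <- c(chosen, extra)
      if (all(apply(cover_mat[sel, uncovered, drop = FALSE], 2, any))) {
        cand <- sort(primes[sel])
        score <- list(length(cand), sum(vapply(cand, n_literals, 1L)),
                      paste(cand, collapse = " "))
        better <- is.null(best) ||
          score[[1]] < best_score[[1]] ||
          (score[[1]] == best_score[[1]] && score[[2]] < best_score[[2]]) ||
          (score[[1]] == best_score[[1]] && score[[2]] == best_score[[2]] &&
             score[[3]] < best_score[[3]])
        if (better) {
          best <- cand
          best_score <- score
        }
      }
    }
    if (!is.null(best)) break # smallest cardinality found at this k
  }
  best
}

implicant_to_clause <- function(implicant, inputs) {
  cs <- strsplit(implicant, "")[[1]]
  keep <- cs != "-"
  stats::setNames(as.integer(cs[keep]), inputs[keep])
}

clause_text <- function(clause) {
  if (length(clause) == 0L) return("1")
  clause <- clause[order(names(clause))] # canonical literal order
  paste(ifelse(clause == 0L, paste0("!", names(clause)), names(clause)),
        collapse = " · ")
}

#' Minimal disjunctive normal form of a truth table
#'
#' Computes all prime implicants (Quine-McCluskey merging) of the rows with
#' output 1, then an exact minimum set cover over them; ties are broken by
#' fewest total literals, then lexicographically. The result evaluates
#' identically to the table on every row.
#'
#' @param table fully determined binary `lih_io_table`.
#' @return a `lih_dnf`: list of clauses (named 0/1 vectors, empty clause =
#'   tautology), the prime implicant set, and a printable formula using the
#'   `·`, `+`, `!` operator notation.
#' @export
minimal_dnf <- function(table) {
  check_binary_table(table)
  n <- length(table$inputs)
  out <- table$rows$output
  # row r corresponds to minterm number with first input as MSB
  weights <- 2^((n - 1):0)
  minterms <- vapply(which(out == 1L), function(r) {
    sum(as.integer(table$rows[r, table$inputs]) * weights)
  }, 1)
  primes <- prime_implicants(minterms, n)
  cover <- minimal_cover(primes, minterms, n)
  clauses <- lapply(cover, implicant_to_clause, inputs = table$inputs)
  formula <- if (length(clauses) == 0L) {
    "0"
  } else {
    paste(vapply(clauses, clause_text, ""), collapse = " + ")
  }
  structure(list(inputs = table$inputs, output = table$output,
                 clauses = clauses, primes = primes, formula = formula),
            class = "lih_dnf")
}

#' @exportS3Method base::print
print.lih_dnf <- function(x, ...) {
  cat(sprintf("<lih_dnf> %s = %s\n", x$output, x$formula))
  invisible(x)
}

#' Evaluate a DNF on an input assignment
#'
#' @param dnf a `lih_dnf`.
#' @param assignment named 0/1 vector covering the DNF inputs.
#' @return 0 or 1.
#' @export
eval_dnf <- function(dnf, assignment) {
  for (clause in dnf$clauses) {
    if (length(clause) == 0L ||
        all(assignment[names(clause)] == clause)) {
      return(1L)
    }
  }
  0L
}

#' Canalizing-input hierarchy
#'
#' A canalizing input determines the output regardless of all other inputs:
#' tier 1 collects every (input, value) pair whose fixation makes the output
#' constant. The analysis then recurses on the subtable with all tier-1
#' inputs fixed to their non-canalizing values; if the residual function is
#' not constant, tier 2 is read off as the implicants of its minimal DNF
#' over the remaining inputs — second-order (weak) canalizing inputs and
#' canalizing combinations (multi-literal implicants) that force the output
#' only while the tier-1 inputs are at non-canalizing values. Functions
#' without any canalizing input (e.g. XOR) yield an empty hierarchy with the
#' residual flagged.
#'
#' @param table fully determined binary `lih_io_table`.
#' @return a `lih_hierarchy`: `tier1` data frame (`input`, `value`,
#'   `output`), `tier2` list of clauses forcing output 1, `residual_dnf`,
#'   `residual_constant`/`residual_value`, `canalizer_found`.
#' @export
canalizing_hierarchy <- function(table) {
  check_binary_table(table)
  inputs <- table$inputs
  rows <- table$rows
  tier1 <- data.frame(input = character(0), value = integer(0),
                      output = integer(0), stringsAsFactors = FALSE)
  for (inp in inputs) {
    for (v in 0:1) {
      sub <- rows$output[rows[[inp]] == v]
      if (length(unique(sub)) == 1L) {
        tier1 <- rbind(tier1,
                       data.frame(input = inp, value = v,
                                  output = sub[1], stringsAsFactors = FALSE))
      }
    }
  }
  h <- list(inputs = inputs, output = table$output, tier1 = tier1,
            tier2 = list(), residual_dnf = NULL,
            residual_constant = FALSE, residual_value = NA_integer_,
            canalizer_found = nrow(tier1) > 0L)
  if (nrow(tier1) == 0L) {
    return(structure(h, class = "lih_hierarchy"))
  }
  both <- names(which(table(tier1$input) == 2L))
  if (length(both) > 0L) {
    # an input canalizing at both values determines the output alone;
    # there is no non-canalizing value to recurse on
    h$residual_constant <- TRUE
    return(structure(h, class = "lih_hierarchy"))
  }
  keep <- rep(TRUE, nrow(rows))
  for (i in seq_len(nrow(tier1))) {
    keep <- keep & rows[[tier1$input[i]]] == (1L - tier1$value[i])
  }
  residual_inputs <- setdiff(inputs, tier1$input)
  sub <- rows[keep, , drop = FALSE]
  if (length(unique(sub$output)) == 1L) {
    h$residual_constant <- TRUE
    h$residual_value <- sub$output[1]
    return(structure(h, class = "lih_hierarchy"))
  }
  sub <- sub[do.call(order, sub[residual_inputs]), , drop = FALSE]
  res_table <- io_table_from_values(residual_inputs, sub$output,
                                    output = table$output)
  dnf <- minimal_dnf(res_table)
  h$residual_dnf <- dnf
  h$tier2 <- dnf$clauses
  structure(h, class = "lih_hierarchy")
}

#' @exportS3Method base::print
print.lih_hierarchy <- function(x, ...) {
  cat(sprintf("<lih_hierarchy> output %s\n", x$output))
  if (!x$canalizer_found) {
    cat("  no canalizing input (residual function left unfactored)\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x$tier1))) {
    cat(sprintf("  tier 1: %s = %d -> %s = %d\n", x$tier1$input[i],
                x$tier1$value[i], x$output, x$tier1$output[i]))
  }
  if (length(x$tier2) > 0L) {
    cat("  tier 2 (given tier-1 inputs non-canalizing):\n")
    for (cl in x$tier2) {
      cat(sprintf("    %s -> %s = 1\n", clause_text(cl), x$output))
    }
  } else if (x$residual_constant && !is.na(x$residual_value)) {
    cat(sprintf("  residual constant: %s = %d\n", x$output, x$residual_value))
  }
  invisible(x)
}

#' Evaluate a canalizing hierarchy on an input assignment
#'
#' Tier-1 entries apply first (any canalizing input at its canalizing value
#' forces the output); otherwise the tier-2 clauses apply; otherwise the
#' output is 0 (or the residual constant).
#'
#' @param hierarchy a `lih_hierarchy`.
#' @param assignment named 0/1 vector over the table inputs.
#' @return 0 or 1.
#' @export
eval_hierarchy <- function(hierarchy, assignment) {
  for (i in seq_len(nrow(hierarchy$tier1))) {
    if (assignment[[hierarchy$tier1$input[i]]] == hierarchy$tier1$value[i]) {
      return(hierarchy$tier1$output[i])
    }
  }
  if (hierarchy$residual_constant && !is.na(hierarchy$residual_value)) {
    return(hierarchy$residual_value)
  }
  for (cl in hierarchy$tier2) {
    if (length(cl) == 0L || all(assignment[names(cl)] == cl)) return(1L)
  }
  0L
}

#' Write an input-output table as TSV
#'
#' @param table a `lih_io_table`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_io_table_tsv <- function(table, path) {
  utils::write.table(table$rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
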