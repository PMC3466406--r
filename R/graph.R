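#' Signed interaction graphs
#'
#' The interaction graph underlying a logical model has one signed edge per
#' distinct (regulator, target, sign) triple obtained by splitting every AND
#' gate (and every ITT gate) into its literals; duplicated identical edges
#' are removed, but a pair of edges of opposite sign between the same two
#' species is retained.
#'
#' @param edges data frame with columns `source`, `target`, `sign`
#'   (`"+"`/`"-"`).
#' @param nodes character vector of node names (defaults to those present in
#'   `edges`).
#' @return a `lih_signed_graph`.
#' @export
lih_signed_graph <- function(edges, nodes = NULL) {
  edges <- data.frame(source = as.character(edges$source),
                      target = as.character(edges$target),
                      sign = as.character(edges$sign),
                      stringsAsFactors = FALSE)
  if (!all(edges$sign %in% c("+", "-"))) {
    stop("edge signs must be '+' or '-'", call. = FALSE)
  }
  edges <- unique(edges)
  if (is.null(nodes)) nodes <- sort(unique(c(edges$source, edges$target)))
  miss <- setdiff(c(edges$source, edges$target), nodes)
  if (length(miss) > 0L) {
    stop("edges reference undeclared nodes: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  edges <- edges[order(edges$source, edges$target, edges$sign), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(nodes), edges = edges),
            class = "lih_signed_graph")
}

#' @exportS3Method base::print
print.lih_signed_graph <- function(x, ...) {
  cat(sprintf("<lih_signed_graph> %d nodes, %d signed edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Derive the signed interaction graph of a model
#'
#' Splits all AND conjunctions (hyperarcs and ITT gates alike): each literal
#' contributes one edge from its species to the target, negative iff the
#' literal is negated. Identical duplicated edges are removed.
#'
#' @param model validated [lih_model()].
#' @return a [lih_signed_graph()] over all model species.
#' @export
to_interaction_graph <- function(model) {
  rows <- list()
  add <- function(lits, target) {
    for (lit in lits) {
      rows[[length(rows) + 1L]] <<-
        data.frame(source = lit$species, target = target,
                   sign = if (lit$negated) "-" else "+",
                   stringsAsFactors = FALSE)
    }
  }
  for (h in model$hyperarcs) add(h$condition, h$target)
  for (g in model$itt_gates) add(g$inputs, g$target)
  edges <- if (length(rows) == 0L) {
    data.frame(source = character(0), target = character(0),
               sign = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  lih_signed_graph(edges, nodes = species_names(model))
}

# canonical rotation of a cycle: start at the lexicographically smallest node
canonical_rotation <- function(seq) {
  k <- match(min(seq), seq)
  if (k > 1L) seq <- c(seq[k:length(seq)], seq[seq_len(k - 1L)])
  seq
}

#' Enumerate elementary cycles of a signed graph
#'
#' Feedback loops are elementary cycles: closed paths visiting no node twice
#' except the starting node. Node sequences are found with Johnson's blocked
#' backtracking over the simple digraph; when the two nodes of a step are
#' connected by parallel edges of opposite sign, each sign choice yields a
#' distinct signed cycle. A cycle's sign is the product of its edge signs
#' (negative iff it contains an odd number of inhibiting edges). Self-loops
#' count as cycles of length 1.
#'
#' @param graph a [lih_signed_graph()].
#' @param restrict_to optional node subset; the induced subgraph is taken
#'   before enumeration.
#' @param max_cycles resource guard; enumeration stops with an error beyond
#'   this many signed cycles.
#' @return data frame with columns `sequence` (nodes joined by `|`,
#'   canonical rotation starting at the smallest node), `length`, `sign`;
#'   ordered by (length, sequence, sign).
#' @export
enumerate_cycles <- function(graph, restrict_to = NULL, max_cycles = 1e6) {
  nodes <- graph$nodes
  edges <- graph$edges
  if (!is.null(restrict_to)) {
    miss <- setdiff(restrict_to, nodes)
    if (length(miss) > 0L) {
      stop("restrict_to contains unknown nodes: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    nodes <- sort(unique(restrict_to))
    edges <- edges[edges$source %in% nodes & edges$target %in% nodes, ,
                   drop = FALSE]
  }
  empty <- data.frame(sequence = character(0), length = integer(0),
                      sign = character(0), stringsAsFactors = FALSE)
  if (length(nodes) == 0L || nrow(edges) == 0L) return(empty)

  nodes <- sort(nodes)
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  # simple digraph adjacency + per-pair sign multiplicity
  key <- paste(edges$source, edges$target, sep = "\r")
  pair_signs <- split(edges$sign, key)
  simple <- unique(edges[c("source", "target")])
  adj <- lapply(seq_len(n), function(i) {
    sort(idx[simple$target[simple$source == nodes[i]]])
  })

  cycles <- list()
  n_signed <- 0L

  # Johnson's algorithm: for each start s (ascending), search the subgraph
  # of nodes >= s with blocking to find cycles whose smallest node is s.
  for (s in seq_len(n)) {
    blocked <- rep(FALSE, n)
    blist <- lapply(seq_len(n), function(i) integer(0))
    stack <- integer(0)

    unblock <- function(v) {
      blocked[v] <<- FALSE
      for (w in blist[[v]]) {
        if (blocked[w]) unblock(w)
      }
      blist[[v]] <<- integer(0)
    }

    circuit <- function(v) {
      found <- FALSE
      stack <<- c(stack, v)
      blocked[v] <<- TRUE
      for (w in adj[[v]]) {
        if (w < s) next
        if (w == s) {
          seq_nodes <- nodes[stack]
          n_choices <- prod(vapply(seq_along(stack), function(k) {
            src <- nodes[stack[k]]
            dst <- nodes[stack[if (k == length(stack)) 1L else k + 1L]]
            length(pair_signs[[paste(src, dst, sep = "\r")]])
          }, 1))
          n_signed <<- n_signed + as.integer(n_choices)
          if (n_signed > max_cycles) {
            stop("cycle count exceeds max_cycles guard (", max_cycles, ")",
                 call. = FALSE)
          }
          cycles[[length(cycles) + 1L]] <<- seq_nodes
          found <- TRUE
        } else if (!blocked[w]) {
          if (circuit(w)) found <- TRUE
        }
      }
      if (found) {
        unblock(v)
      } else {
        for (w in adj[[v]]) {
          if (w < s) next
          if (!(v %in% blist[[w]])) blist[[w]] <<- c(blist[[w]], v)
        }
      }
      stack <<- stack[-length(stack)]
      found
    }
    circuit(s)
  }

  if (length(cycles) == 0L) return(empty)

  # expand parallel opposite-sign edges into distinct signed cycles
  out <- list()
  for (seq_nodes in cycles) {
    L <- length(seq_nodes)
    step_signs <- lapply(seq_len(L), function(k) {
      src <- seq_nodes[k]
      dst <- seq_nodes[if (k == L) 1L else k + 1L]
      sort(pair_signs[[paste(src, dst, sep = "\r")]])
    })
    combos <- expand.grid(rev(step_signs), stringsAsFactors = FALSE)
    combos <- combos[, rev(seq_len(L)), drop = FALSE]
    for (r in seq_len(nrow(combos))) {
      sgn <- if (sum(combos[r, ] == "-") %% 2L == 0L) "+" else "-"
      out[[length(out) + 1L]] <-
        data.frame(sequence = paste(seq_nodes, collapse = "|"),
                   length = L, sign = sgn, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$length, out$sequence, out$sign), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Species participation in feedback loops
#'
#' Counts, for every node, the number of (optionally sign-filtered) cycles
#' that contain it. The ranking is by descending count with alphabetical
#' tie-breaking.
#'
#' @param cycles cycle table from [enumerate_cycles()].
#' @param sign_filter optional `"+"` or `"-"`.
#' @param nodes optional node universe; defaults to the nodes appearing in
#'   `cycles` (species in no cycle then get count 0 only if listed here).
#' @return data frame `species`, `count`, `rank`.
#' @export
loop_participation <- function(cycles, sign_filter = NULL, nodes = NULL) {
  if (!is.null(sign_filter)) {
    sign_filter <- match.arg(sign_filter, c("+", "-"))
    cycles <- cycles[cycles$sign == sign_filter, , drop = FALSE]
  }
  members <- strsplit(cycles$sequence, "|", fixed = TRUE)
  counts <- table(unlist(members))
  if (is.null(nodes)) nodes <- sort(names(counts))
  cnt <- stats::setNames(rep(0L, length(nodes)), sort(nodes))
  present <- intersect(names(counts), names(cnt))
  cnt[present] <- as.integer(counts[present])
  df <- data.frame(species = names(cnt), count = unname(cnt),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$species), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Export a signed graph
#'
#' `write_sif` writes a SIF-style edge list (`source sign target`, where
#' sign is `+`/`-`); `write_dot` writes Graphviz DOT with inhibiting edges
#' drawn as tee arrows.
#'
#' @param graph a [lih_signed_graph()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_sif <- function(graph, path) {
  utils::write.table(graph$edges[c("source", "sign", "target")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_sif
#' @export
write_dot <- function(graph, path) {
  lines <- c("digraph lih {",
             sprintf("  \"%s\";", graph$nodes),
             sprintf("  \"%s\" -> \"%s\"%s;", graph$edges$source,
                     graph$edges$target,
                     ifelse(graph$edges$sign == "-",
                            " [arrowhead=tee, color=red]", "")),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' Write a cycle report as TSV
#'
#' @param cycles cycle table from [enumerate_cycles()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_cycles_tsv <- function(cycles, path) {
  utils::write.table(cycles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
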