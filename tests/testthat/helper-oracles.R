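# Independent oracles used to check the analysis engines on small random
# instances. These deliberately use different algorithms from the package:
# exhaustive state enumeration instead of three-valued propagation,
# plain DFS instead of Johnson's blocked search, brute-force implicant
# search instead of Quine-McCluskey merging.

# ---- synchronous fixed points (Boolean models, no ITT gates) -------------
# A state T is a fixed point consistent with the clamps iff for every
# species: clamped -> T[s] = clamp; no incoming arcs -> T[s] = default if
# set (free otherwise); else T[s] = max target level over satisfied arcs
# (0 if none).
oracle_fixed_points <- function(model, clamps = integer(0)) {
  nm <- vapply(model$species, `[[`, "", "name")
  n <- length(nm)
  stopifnot(n <= 14)
  states <- as.matrix(expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE))
  colnames(states) <- nm
  dl <- vapply(model$species, `[[`, 1L, "default_level")
  names(dl) <- nm

  sat <- function(h) {
    ok <- rep(TRUE, nrow(states))
    for (lit in h$condition) {
      v <- states[, lit$species]
      ok <- ok & if (lit$negated) v < lit$threshold else v >= lit$threshold
    }
    ok
  }
  keep <- rep(TRUE, nrow(states))
  targets <- vapply(model$hyperarcs, `[[`, "", "target")
  for (s in nm) {
    expected <- if (s %in% names(clamps)) {
      rep(clamps[[s]], nrow(states))
    } else if (!s %in% targets) {
      if (is.na(dl[[s]])) next else rep(dl[[s]], nrow(states))
    } else {
      val <- rep(0L, nrow(states))
      for (h in model$hyperarcs[targets == s]) {
        val <- pmax(val, ifelse(sat(h), h$target_level, 0L))
      }
      val
    }
    keep <- keep & states[, s] == expected
  }
  states[keep, , drop = FALSE]
}

# ---- simple-cycle enumeration by naive DFS -------------------------------
# edges: data.frame(source, target, sign); returns the same canonical
# representation as enumerate_cycles().
oracle_cycles <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$source, edges$target)))
  simple <- unique(edges[c("source", "target")])
  out <- list()
  walk <- function(path) {
    here <- path[length(path)]
    succ <- simple$target[simple$source == here]
    for (nxt in succ) {
      if (nxt == path[1]) {
        out[[length(out) + 1L]] <<- path
      } else if (!nxt %in% path && nxt > path[1]) {
        # only explore nodes larger than the anchor: each cycle found once,
        # anchored at its smallest node
        walk(c(path, nxt))
      }
    }
  }
  for (s in nodes) walk(s)
  if (length(out) == 0L) {
    return(data.frame(sequence = character(0), length = integer(0),
                      sign = character(0), stringsAsFactors = FALSE))
  }
  rows <- list()
  for (cyc in out) {
    L <- length(cyc)
    step_signs <- lapply(seq_len(L), function(k) {
      src <- cyc[k]
      dst <- cyc[if (k == L) 1L else k + 1L]
      sort(edges$sign[edges$source == src & edges$target == dst])
    })
    combos <- expand.grid(rev(step_signs), stringsAsFactors = FALSE)
    combos <- combos[, rev(seq_len(L)), drop = FALSE]
    for (r in seq_len(nrow(combos))) {
      sgn <- if (sum(combos[r, ] == "-") %% 2L == 0L) "+" else "-"
      rows[[length(rows) + 1L]] <-
        data.frame(sequence = paste(cyc, collapse = "|"), length = L,
                   sign = sgn, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$length, res$sequence, res$sign), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# seeded random signed digraph for cycle tests
random_signed_digraph <- function(n_nodes, p_edge = 0.25, p_neg = 0.4,
                                  seed = 1L) {
  lihnet:::with_seed(seed, {
    nodes <- sprintf("N%d", seq_len(n_nodes))
    pairs <- expand.grid(source = nodes, target = nodes,
                         stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(pairs)) < p_edge
    edges <- pairs[keep, , drop = FALSE]
    edges$sign <- ifelse(stats::runif(nrow(edges)) < p_neg, "-", "+")
    # occasionally duplicate an edge with the opposite sign
    if (nrow(edges) > 0L) {
      dup <- edges[stats::runif(nrow(edges)) < 0.1, , drop = FALSE]
      dup$sign <- ifelse(dup$sign == "+", "-", "+")
      edges <- rbind(edges, dup)
    }
    list(nodes = nodes, edges = edges)
  })
}

# ---- brute-force minimal intervention sets -------------------------------
# every clamp combination up to max_size, goal checked via compute_lss,
# then filtered to support-minimal sets
oracle_mis <- function(model, context, goal, max_size, candidates,
                       levels_for) {
  hits <- list()
  for (k in seq_len(max_size)) {
    for (sup in utils::combn(candidates, k, simplify = FALSE)) {
      grids <- expand.grid(lapply(sup, levels_for), KEEP.OUT.ATTRS = FALSE)
      for (r in seq_len(nrow(grids))) {
        clamps <- stats::setNames(as.integer(grids[r, ]), sup)
        st <- compute_lss(model, scenario_perturb(context, clamps))
        if (lihnet:::goal_satisfied(goal, st)) {
          hits[[length(hits) + 1L]] <- clamps
        }
      }
    }
  }
  # support-minimal filter
  supports <- lapply(hits, names)
  minimal <- vapply(seq_along(hits), function(i) {
    !any(vapply(seq_along(hits), function(j) {
      length(supports[[j]]) < length(supports[[i]]) &&
        all(supports[[j]] %in% supports[[i]])
    }, TRUE))
  }, TRUE)
  hits <- hits[minimal]
  keys <- vapply(hits, lihnet:::format_clamps, "")
  sort(unique(keys))
}

# ---- brute-force prime implicants over n Boolean inputs ------------------
# implicants encoded like the package's QM strings ("0", "1", "-")
oracle_primes <- function(values, n) {
  grid <- expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE)
  grid <- as.matrix(grid[, rev(seq_len(n)), drop = FALSE])
  grid <- grid[do.call(order, as.data.frame(grid)), , drop = FALSE]
  terms <- expand.grid(rep(list(c("0", "1", "-")), n),
                       stringsAsFactors = FALSE)
  covers <- function(term, row) {
    all(term == "-" | term == as.character(row))
  }
  implies_one <- vapply(seq_len(nrow(terms)), function(i) {
    term <- as.character(terms[i, ])
    rows <- which(vapply(seq_len(nrow(grid)), function(r) {
      covers(term, grid[r, ])
    }, TRUE))
    length(rows) > 0L && all(values[rows] == 1L)
  }, TRUE)
  term_strings <- apply(terms, 1, paste, collapse = "")
  implicants <- term_strings[implies_one]
  # prime = no literal can be generalized to '-'
  prime <- vapply(implicants, function(t) {
    cs <- strsplit(t, "")[[1]]
    for (pos in which(cs != "-")) {
      gen <- cs
      gen[pos] <- "-"
      if (paste(gen, collapse = "") %in% implicants) return(FALSE)
    }
    TRUE
  }, TRUE)
  sort(implicants[prime])
}

# convenience: Boolean random model suited to the fixed-point oracle
random_boolean_model <- function(n_species, n_hyperarcs, seed) {
  random_model(n_species = n_species, n_hyperarcs = n_hyperarcs,
               max_condition = min(3L, n_species), p_negate = 0.3,
               multivalued_fraction = 0, p_scale2 = 0, seed = seed)
}

# random clamps for a model (some species clamped 0/1)
random_clamps <- function(model, p_clamp = 0.3, seed = 1L) {
  lihnet:::with_seed(seed, {
    nm <- vapply(model$species, `[[`, "", "name")
    sel <- nm[stats::runif(length(nm)) < p_clamp]
    stats::setNames(sample(0:1, length(sel), replace = TRUE), sel)
  })
}
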