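#' Model text format
#'
#' The native text format has two sections. A `species:` block declares one
#' species per line as `name max_level role default` (default `-` for none).
#' A `rules:` block declares one or more rules per line (separated by `;`),
#' each `[id:] [level]TARGET = lit (. lit)* [@ts]` where literals are
#' `[!][level]NAME`, the level prefix defaults to 1 and the time scale tag
#' `@ts` defaults to 1. The AND operator may be written as the middle dot
#' `·`, `*` or `&`. ITT gates use `?=` instead of `=`. Lines starting
#' with `#` are comments. Rule ids default to `R1`, `R2`, ... by position.
#'
#' A Boolean one-rule-per-line dialect (`format = "boolean"`) has no species
#' header: species are inferred from the rules, all Boolean. The JSON dialect
#' mirrors the in-memory structure.
#'
#' @name model_format
NULL

AND_SPLIT <- "·|\\*|&"

format_literal <- function(lit) {
  paste0(if (lit$negated) "!" else "",
         if (lit$threshold != 1L) lit$threshold else "",
         lit$species)
}

parse_literal <- function(tok, line = NA_integer_) {
  m <- regmatches(tok, regexec("^(!?)([0-9]*)([A-Za-z0-9_]+)$", tok))[[1]]
  if (length(m) == 0L) {
    stop(sprintf("line %s: malformed literal '%s'", line, tok), call. = FALSE)
  }
  lih_literal(m[4],
              threshold = if (nzchar(m[3])) as.integer(m[3]) else 1L,
              negated = m[2] == "!")
}

#' Parse a logical model
#'
#' @param text character vector of lines, or a single string with embedded
#'   newlines, in one of the package's model formats.
#' @param format `"native"` (sectioned text), `"json"`, or `"boolean"`
#'   (headerless one-rule-per-line Boolean dialect).
#' @return a validated [lih_model()].
#' @export
parse_model <- function(text, format = c("native", "json", "boolean")) {
  format <- match.arg(format)
  if (format == "json") return(model_from_json(text))
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  raw <- sub("#.*$", "", lines)
  species <- list()
  rules <- character(0)
  rule_lines <- integer(0)
  if (format == "boolean") {
    keep <- nzchar(trimws(raw))
    rules <- trimws(raw[keep])
    rule_lines <- which(keep)
  } else {
    section <- ""
    for (i in seq_along(raw)) {
      ln <- trimws(raw[i])
      if (!nzchar(ln)) next
      if (ln == "species:") { section <- "species"; next }
      if (ln == "rules:") { section <- "rules"; next }
      if (section == "species") {
        f <- strsplit(ln, "[[:space:]]+")[[1]]
        if (!length(f) %in% c(1L, 2L, 3L, 4L)) {
          stop(sprintf("line %d: malformed species declaration '%s'", i, ln),
               call. = FALSE)
        }
        maxl <- if (length(f) >= 2L) suppressWarnings(as.integer(f[2])) else 1L
        if (is.na(maxl)) {
          stop(sprintf("line %d: bad max_level in '%s'", i, ln), call. = FALSE)
        }
        dflt <- if (length(f) >= 4L && f[4] != "-") {
          suppressWarnings(as.integer(f[4]))
        } else NA_integer_
        species[[length(species) + 1L]] <-
          lih_species(f[1], max_level = maxl,
                      role = if (length(f) >= 3L) f[3] else "normal",
                      default_level = dflt)
      } else if (section == "rules") {
        rules <- c(rules, ln)
        rule_lines <- c(rule_lines, i)
      } else if (grepl("=", ln, fixed = TRUE)) {
        # headerless rule line (species are then inferred from usage)
        rules <- c(rules, ln)
        rule_lines <- c(rule_lines, i)
      } else {
        stop(sprintf("line %d: content outside species:/rules: sections", i),
             call. = FALSE)
      }
    }
  }

  hyperarcs <- list()
  itt_gates <- list()
  auto <- 0L
  for (k in seq_along(rules)) {
    for (one in trimws(strsplit(rules[k], ";", fixed = TRUE)[[1]])) {
      if (!nzchar(one)) next
      ln <- rule_lines[k]
      id <- NULL
      m <- regmatches(one, regexec("^([A-Za-z0-9_]+)[[:space:]]*:[[:space:]]*(.*)$", one))[[1]]
      if (length(m) > 0L) { id <- m[2]; one <- m[3] }
      itt <- grepl("?=", one, fixed = TRUE)
      sides <- strsplit(one, if (itt) "\\?=" else "=", perl = TRUE)[[1]]
      if (length(sides) != 2L) {
        stop(sprintf("line %s: expected one '%s' in rule '%s'",
                     ln, if (itt) "?=" else "=", one), call. = FALSE)
      }
      lhs <- trimws(sides[1])
      mh <- regmatches(lhs, regexec("^([0-9]*)([A-Za-z0-9_]+)$", lhs))[[1]]
      if (length(mh) == 0L) {
        stop(sprintf("line %s: malformed rule head '%s'", ln, lhs), call. = FALSE)
      }
      level <- if (nzchar(mh[2])) as.integer(mh[2]) else 1L
      target <- mh[3]
      rhs <- trimws(sides[2])
      ts <- 1L
      mt <- regmatches(rhs, regexec("^(.*)@[[:space:]]*([0-9]+)[[:space:]]*$", rhs))[[1]]
      if (length(mt) > 0L) { rhs <- trimws(mt[2]); ts <- as.integer(mt[3]) }
      toks <- trimws(strsplit(rhs, AND_SPLIT)[[1]])
      toks <- toks[nzchar(toks)]
      if (length(toks) == 0L) {
        stop(sprintf("line %s: empty condition in rule for '%s'", ln, target),
             call. = FALSE)
      }
      lits <- lapply(toks, parse_literal, line = ln)
      if (itt) {
        itt_gates[[length(itt_gates) + 1L]] <-
          lih_itt_gate(target, lits, target_level = level)
      } else {
        if (is.null(id)) { auto <- auto + 1L; id <- sprintf("R%d", auto) }
        hyperarcs[[length(hyperarcs) + 1L]] <-
          lih_hyperarc(id, lits, target, target_level = level, time_scale = ts)
      }
    }
  }

  if (length(species) == 0L && (length(hyperarcs) + length(itt_gates)) > 0L) {
    # headerless document: infer species, with max levels from usage
    lev <- integer(0)
    bump <- function(lev, s, l) {
      lev[[s]] <- max(if (s %in% names(lev)) lev[[s]] else 0L, l)
      lev
    }
    for (h in hyperarcs) {
      lev <- bump(lev, h$target, h$target_level)
      for (l in h$condition) lev <- bump(lev, l$species, l$threshold)
    }
    for (g in itt_gates) {
      lev <- bump(lev, g$target, g$target_level)
      for (l in g$inputs) lev <- bump(lev, l$species, l$threshold)
    }
    lev <- pmax(lev, 1L)
    if (format == "boolean" && any(lev > 1L)) {
      stop("boolean dialect admits Boolean levels only; multivalued: ",
           paste(names(lev)[lev > 1L], collapse = ", "), call. = FALSE)
    }
    species <- lapply(sort(names(lev)), function(s) {
      lih_species(s, max_level = lev[[s]])
    })
  }

  m <- lih_model(species, hyperarcs, itt_gates, validate = FALSE)
  v <- validate_model(m)
  if (nrow(v) > 0L) {
    stop("parsed model is invalid:\n",
         paste0("  - ", v$message, collapse = "\n"), call. = FALSE)
  }
  m
}

rule_text <- function(cond, target, target_level, time_scale = 1L,
                      id = NULL, itt = FALSE) {
  paste0(if (!is.null(id)) paste0(id, ": ") else "",
         if (target_level != 1L) target_level else "", target,
         if (itt) " ?= " else " = ",
         paste(vapply(cond, format_literal, ""), collapse = " · "),
         if (time_scale != 1L) paste0(" @", time_scale) else "")
}

#' Serialize a logical model
#'
#' Output is deterministic: species sorted by name, hyperarcs by id, ITT
#' gates by target, so two serializations of equal models are byte-identical.
#'
#' @param model validated [lih_model()].
#' @param dialect `"native-text"`, `"native-json"`, or `"boolean-text"`
#'   (refused unless every species is Boolean with no roles/defaults).
#' @return a single string.
#' @export
serialize_model <- function(model,
                            dialect = c("native-text", "native-json",
                                        "boolean-text")) {
  dialect <- match.arg(dialect)
  if (dialect == "native-json") return(model_to_json(model))
  sp <- model$species[order(species_names(model))]
  arcs <- model$hyperarcs[order(hyperarc_ids(model))]
  gates <- model$itt_gates[order(vapply(model$itt_gates, `[[`, "", "target"))]
  if (dialect == "boolean-text") {
    nonb <- vapply(sp, function(s) {
      s$max_level != 1L || s$role != "normal" || !is.na(s$default_level)
    }, TRUE)
    if (any(nonb)) {
      stop("boolean-text dialect requires Boolean species with role 'normal' ",
           "and no default level", call. = FALSE)
    }
    lines <- c(
      vapply(arcs, function(h) {
        rule_text(h$condition, h$target, h$target_level, h$time_scale, h$id)
      }, ""),
      vapply(gates, function(g) {
        rule_text(g$inputs, g$target, g$target_level, itt = TRUE)
      }, ""))
    return(paste0(paste(lines, collapse = "\n"), "\n"))
  }
  sp_lines <- vapply(sp, function(s) {
    paste(s$name, s$max_level, s$role,
          if (is.na(s$default_level)) "-" else s$default_level)
  }, "")
  rule_lines <- c(
    vapply(arcs, function(h) {
      rule_text(h$condition, h$target, h$target_level, h$time_scale, h$id)
    }, ""),
    vapply(gates, function(g) {
      rule_text(g$inputs, g$target, g$target_level, itt = TRUE)
    }, ""))
  paste0(paste(c("# lihnet model", "species:", sp_lines, "rules:", rule_lines),
               collapse = "\n"), "\n")
}

model_to_json <- function(model) {
  obj <- list(
    format = "lihnet-model",
    version = 1L,
    species = lapply(model$species[order(species_names(model))], function(s) {
      list(name = s$name, max_level = s$max_level, role = s$role,
           default_level = if (is.na(s$default_level)) NULL else s$default_level)
    }),
    hyperarcs = lapply(model$hyperarcs[order(hyperarc_ids(model))], function(h) {
      list(id = h$id,
           condition = lapply(h$condition, function(l) {
             list(species = l$species, threshold = l$threshold,
                  negated = l$negated)
           }),
           target = h$target, target_level = h$target_level,
           time_scale = h$time_scale)
    }),
    itt_gates = lapply(model$itt_gates[order(vapply(model$itt_gates, `[[`, "",
                                                    "target"))], function(g) {
      list(target = g$target,
           inputs = lapply(g$inputs, function(l) {
             list(species = l$species, threshold = l$threshold,
                  negated = l$negated)
           }),
           target_level = g$target_level)
    }),
    metadata = model$metadata)
  jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, null = "null")
}

model_from_json <- function(text) {
  obj <- jsonlite::fromJSON(paste(text, collapse = "\n"), simplifyVector = FALSE)
  if (!identical(obj$format, "lihnet-model")) {
    stop("not a lihnet-model JSON document", call. = FALSE)
  }
  as_lit <- function(l) lih_literal(l$species, l$threshold %||% 1L,
                                    isTRUE(l$negated))
  lih_model(
    species = lapply(obj$species, function(s) {
      lih_species(s$name, s$max_level %||% 1L, s$role %||% "normal",
                  s$default_level %||% NA_integer_)
    }),
    hyperarcs = lapply(obj$hyperarcs, function(h) {
      lih_hyperarc(h$id, lapply(h$condition, as_lit), h$target,
                   h$target_level %||% 1L, h$time_scale %||% 1L)
    }),
    itt_gates = lapply(obj$itt_gates, function(g) {
      lih_itt_gate(g$target, lapply(g$inputs, as_lit), g$target_level %||% 1L)
    }),
    metadata = obj$metadata %||% list())
}

#' Read / write model files
#'
#' @param path file path; format inferred from the extension (`.json` for
#'   JSON, anything else native text) unless given.
#' @inheritParams parse_model
#' @return `read_model` returns a validated model; `write_model` returns the
#'   path invisibly.
#' @export
read_model <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "native"
  }
  parse_model(readLines(path, encoding = "UTF-8", warn = FALSE), format = format)
}

#' @rdname read_model
#' @param model validated model.
#' @param dialect serialization dialect, see [serialize_model()].
#' @export
write_model <- function(model, path, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      "native-json"
    } else "native-text"
  }
  writeLines(serialize_model(model, dialect), path, useBytes = TRUE)
  invisible(path)
}

#' Export a Boolean model to SBML-qual
#'
#' Writes a minimal SBML Level 3 qualitative-models document. Only Boolean
#' models are supported; multivalued models are refused because the mapping
#' of threshold literals to SBML-qual default terms is not one-to-one.
#'
#' @param model validated Boolean [lih_model()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_sbml_qual <- function(model, path) {
  ml <- max_levels(model)
  if (any(ml > 1L)) {
    stop("SBML-qual export supports Boolean models only; species ",
         paste(names(ml)[ml > 1L], collapse = ", "), " are multivalued",
         call. = FALSE)
  }
  if (length(model$itt_gates) > 0L) {
    stop("SBML-qual export does not support ITT gates", call. = FALSE)
  }
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  sp <- sort(species_names(model))
  qs <- sprintf(
    '      <qual:qualitativeSpecies qual:id="%s" qual:compartment="default" qual:constant="false" qual:maxLevel="1"/>',
    esc(sp))
  trans <- character(0)
  targets <- unique(vapply(model$hyperarcs, `[[`, "", "target"))
  for (tg in sort(targets)) {
    arcs <- Filter(function(h) h$target == tg, model$hyperarcs)
    srcs <- sort(unique(unlist(lapply(arcs, function(h) {
      vapply(h$condition, `[[`, "", "species")
    }))))
    inputs <- sprintf(
      '          <qual:input qual:qualitativeSpecies="%s" qual:transitionEffect="none"/>',
      esc(srcs))
    terms <- vapply(arcs, function(h) {
      lits <- vapply(h$condition, function(l) {
        sprintf('<apply><%s/><ci>%s</ci><cn type="integer">1</cn></apply>',
                if (l$negated) "lt" else "geq", esc(l$species))
      }, "")
      if (length(lits) > 1L) {
        paste0("<apply><and/>", paste(lits, collapse = ""), "</apply>")
      } else lits
    }, "")
    body <- if (length(terms) > 1L) {
      paste0("<apply><or/>", paste(terms, collapse = ""), "</apply>")
    } else terms
    trans <- c(trans, sprintf(
      paste0('      <qual:transition qual:id="tr_%s">\n',
             '        <qual:listOfInputs>\n%s\n        </qual:listOfInputs>\n',
             '        <qual:listOfOutputs>\n',
             '          <qual:output qual:qualitativeSpecies="%s" qual:transitionEffect="assignmentLevel"/>\n',
             '        </qual:listOfOutputs>\n',
             '        <qual:listOfFunctionTerms>\n',
             '          <qual:defaultTerm qual:resultLevel="0"/>\n',
             '          <qual:functionTerm qual:resultLevel="1">\n',
             '            <math xmlns="http://www.w3.org/1998/Math/MathML">%s</math>\n',
             '          </qual:functionTerm>\n',
             '        </qual:listOfFunctionTerms>\n',
             '      </qual:transition>'),
      esc(tg), paste(inputs, collapse = "\n"), esc(tg), body))
  }
  doc <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1"',
    '      xmlns:qual="http://www.sbml.org/sbml/level3/version1/qual/version1" qual:required="true">',
    '  <model id="lihnet_export">',
    '    <listOfCompartments>',
    '      <compartment id="default" constant="true"/>',
    '    </listOfCompartments>',
    '    <qual:listOfQualitativeSpecies>',
    qs,
    '    </qual:listOfQualitativeSpecies>',
    '    <qual:listOfTransitions>',
    trans,
    '    </qual:listOfTransitions>',
    '  </model>',
    '</sbml>')
  writeLines(doc, path, useBytes = TRUE)
  invisible(path)
}
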