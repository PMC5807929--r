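#' PatternTable class
#'
#' The predicted fragment pattern of every group under every assay
#' (assay = amplicon x enzyme). This is the complete in-silico "gel
#' atlas" from which identification keys are built and against which
#' observed band patterns are scored.
#'
#' @slot groups group (species) labels.
#' @slot assays `data.frame` with columns `amplicon`, `enzyme`, `label`
#'   (label = `"amplicon:enzyme"`).
#' @slot patterns named list: `patterns[[label]][[group]]` is a
#'   decreasing integer vector of fragment lengths.
#' @slot enzymes named list of [RestrictionEnzyme-class] objects covering
#'   every assay enzyme.
#' @export
setClass("PatternTable",
  representation(groups = "character", assays = "data.frame",
                 patterns = "list", enzymes = "list"))

setValidity("PatternTable", function(object) {
  msg <- character()
  if (!all(object@assays$label %in% names(object@patterns)))
    msg <- c(msg, "patterns missing for some assays")
  for (lab in object@assays$label) {
    if (!all(object@groups %in% names(object@patterns[[lab]])))
      msg <- c(msg, sprintf("assay %s lacks patterns for some groups", lab))
  }
  if (!all(object@assays$enzyme %in% names(object@enzymes)))
    msg <- c(msg, "enzyme definitions missing for some assays")
  if (length(msg)) msg else TRUE
})

#' Construct a PatternTable
#'
#' @param patterns named list: `patterns[["amplicon:enzyme"]][[group]]`
#'   giving fragment lengths.
#' @param enzymes named list of [RestrictionEnzyme-class] covering the
#'   assay enzymes.
#' @return a [PatternTable-class].
#' @export
patternTable <- function(patterns, enzymes) {
  labels <- names(patterns)
  parts <- strsplit(labels, ":", fixed = TRUE)
  assays <- data.frame(
    amplicon = vapply(parts, `[`, character(1), 1L),
    enzyme = vapply(parts, `[`, character(1), 2L),
    label = labels, stringsAsFactors = FALSE)
  groups <- sort(unique(unlist(lapply(patterns, names))))
  patterns <- lapply(patterns, function(p) {
    lapply(p, function(x) sort(as.integer(x), decreasing = TRUE))
  })
  new("PatternTable", groups = groups, assays = assays,
      patterns = patterns, enzymes = enzymes)
}

#' @describeIn PatternTable-class look up one group's pattern under one
#'   assay.
#' @param x,object a `PatternTable`.
#' @param assay assay label (`"amplicon:enzyme"`).
#' @param group group label.
#' @export
tablePattern <- function(x, assay, group) x@patterns[[assay]][[group]]

#' @describeIn PatternTable-class group labels.
#' @export
tableGroups <- function(x) x@groups

#' @describeIn PatternTable-class assay definitions (`data.frame`).
#' @export
tableAssays <- function(x) x@assays

setMethod("show", "PatternTable", function(object) {
  cat(sprintf("PatternTable: %d group(s) x %d assay(s)\n",
              length(object@groups), nrow(object@assays)))
  for (lab in object@assays$label) {
    cat(" ", lab, "\n")
    for (g in object@groups) {
      cat(sprintf("    %-16s %s\n", g,
                  paste(object@patterns[[lab]][[g]], collapse = ", ")))
    }
  }
})

#' IdentificationKey class
#'
#' An ordered decision tree of digestion assays. Each internal node holds
#' one assay; its branches are labelled by the distinguishable fragment
#' pattern classes that assay produces among the remaining candidate
#' groups, and leaves hold the group set the path resolves to.
#'
#' @slot root nested-list tree (see [buildKey()]).
#' @slot table the [PatternTable-class] the key was built from.
#' @slot params list with `minDetect`, `tolBp`, `tolFrac`.
#' @export
setClass("IdentificationKey",
  representation(root = "list", table = "PatternTable", params = "list"))

.leaf <- function(groups) list(kind = "leaf", species = as.character(groups))

.leafSpecies <- function(node) {
  if (identical(node$kind, "leaf")) return(node$species)
  unlist(lapply(node$branches, function(b) .leafSpecies(b$child)))
}

.keyDepth <- function(node) {
  if (identical(node$kind, "leaf")) return(0L)
  1L + max(vapply(node$branches, function(b) .keyDepth(b$child), integer(1)))
}

#' @describeIn IdentificationKey-class all group labels reachable from
#'   the root.
#' @param x,object an `IdentificationKey`.
#' @export
keySpecies <- function(x) sort(unique(.leafSpecies(x@root)))

#' @describeIn IdentificationKey-class species sets at the leaves (list
#'   of character vectors).
#' @export
keyLeaves <- function(x) {
  collect <- function(node) {
    if (identical(node$kind, "leaf")) return(list(node$species))
    do.call(c, lapply(node$branches, function(b) collect(b$child)))
  }
  collect(x@root)
}

#' @describeIn IdentificationKey-class maximum number of assays on any
#'   root-to-leaf path.
#' @export
keyDepth <- function(x) .keyDepth(x@root)

# Greedy assay choice: most partition blocks, then smallest sum of
# squared block sizes (fewest expected follow-up assays), then
# lexicographic enzyme name, then assay label.
.chooseAssay <- function(table, groups, minDetect, tolBp, tolFrac) {
  best <- NULL
  for (i in seq_len(nrow(table@assays))) {
    lab <- table@assays$label[i]
    pats <- table@patterns[[lab]][groups]
    blocks <- .partitionPatterns(pats, minDetect, tolBp, tolFrac)
    score <- list(
      nblocks = length(blocks),
      ssq = sum(vapply(blocks, length, integer(1))^2),
      enzyme = table@assays$enzyme[i],
      label = lab, blocks = blocks)
    if (is.null(best) ||
        score$nblocks > best$nblocks ||
        (score$nblocks == best$nblocks && score$ssq < best$ssq) ||
        (score$nblocks == best$nblocks && score$ssq == best$ssq &&
         score$enzyme < best$enzyme)) {
      best <- score
    }
  }
  best
}

.buildNode <- function(table, groups, minDetect, tolBp, tolFrac) {
  groups <- sort(groups)
  if (length(groups) == 1L) return(.leaf(groups))
  best <- .chooseAssay(table, groups, minDetect, tolBp, tolFrac)
  if (is.null(best) || best$nblocks == 1L) {
    .rflpWarn(sprintf("groups indistinguishable by every assay: %s",
                      paste(groups, collapse = ", ")),
              "rflp_ambiguous_key")
    return(.leaf(groups))
  }
  branches <- lapply(best$blocks, function(block) {
    pats <- unique(table@patterns[[best$label]][block])
    list(patterns = unname(pats),
         child = .buildNode(table, block, minDetect, tolBp, tolFrac))
  })
  parts <- strsplit(best$label, ":", fixed = TRUE)[[1]]
  list(kind = "assay", assay = best$label,
       amplicon = parts[1L], enzyme = parts[2L], branches = branches)
}

#' Build a stepwise identification key
#'
#' Greedy decision-tree construction: at each node the assay that splits
#' the remaining candidate groups into the most pattern-distinguishable
#' blocks is chosen (ties broken by fewest expected follow-up assays,
#' then lexicographic enzyme name), and the algorithm recurses into each
#' block. Recursion stops at singleton blocks or when no assay splits
#' further; in the latter case the leaf holds the ambiguous group set and
#' a warning is emitted.
#'
#' @param table a [PatternTable-class], complete over groups x assays.
#' @param minDetect,tolBp,tolFrac gel-realism parameters used to decide
#'   when two patterns are distinguishable (defaults: exact comparison).
#' @return an [IdentificationKey-class].
#' @examples
#' fx <- generateFixtureSet(seed = 1)
#' key <- buildKey(fixturePatternTable(fx))
#' keyLeaves(key)
#' @export
buildKey <- function(table, minDetect = 0, tolBp = 0, tolFrac = 0) {
  stopifnot(is(table, "PatternTable"))
  if (length(table@groups) < 1L) {
    stop(rflpError("pattern table has no groups", "rflp_invalid_input"))
  }
  root <- .buildNode(table, table@groups, minDetect, tolBp, tolFrac)
  new("IdentificationKey", root = root, table = table,
      params = list(minDetect = minDetect, tolBp = tolBp, tolFrac = tolFrac))
}

# Build a node from a declared cascade: spec is list(assay=, branches=
# list(list(groups=, child= spec or NULL))). NULL child -> leaf.
.cascadeNode <- function(table, spec) {
  branches <- lapply(spec$branches, function(b) {
    pats <- unique(table@patterns[[spec$assay]][b$groups])
    child <- if (is.null(b$child)) .leaf(sort(b$groups))
             else .cascadeNode(table, b$child)
    list(patterns = unname(pats), child = child)
  })
  parts <- strsplit(spec$assay, ":", fixed = TRUE)[[1]]
  list(kind = "assay", assay = spec$assay,
       amplicon = parts[1L], enzyme = parts[2L], branches = branches)
}

#' The published sequential assay cascade
#'
#' Hard-codes the field workflow for the six Hawaiian Pocillopora
#' species: digest the mtORF amplicon with SacI first (separating mtORF
#' type 1); type 1 samples are resolved to P. eydouxi vs P. meandrina by
#' XhoI digestion of the PocHistone amplicon; the remainder are screened
#' with AlwNI (P. ligulata), then AciI (P. verrucosa), then NlaIV
#' (confirming the P. acuta / P. damicornis pair) followed by Tsp45I
#' (separating the two). Use this profile for faithful replication of
#' the published workflow; [buildKey()] gives the algorithmic key.
#'
#' @param table a [PatternTable-class] over the six species and the six
#'   panel assays.
#' @return an [IdentificationKey-class].
#' @export
publishedKey <- function(table) {
  stopifnot(is(table, "PatternTable"))
  sp <- pocSpecies()
  need <- c("mtORF:SacI", "PocHistone:XhoI", "mtORF:AlwNI", "mtORF:AciI",
            "mtORF:NlaIV", "mtORF:Tsp45I")
  missing <- setdiff(need, table@assays$label)
  if (length(missing)) {
    stop(rflpError(sprintf("pattern table lacks assay(s): %s",
                           paste(missing, collapse = ", ")),
                   "rflp_invalid_input"))
  }
  type1 <- c("P. eydouxi", "P. meandrina")
  rest1 <- setdiff(sp, type1)
  finePair <- c("P. acuta", "P. damicornis")
  tsp45I <- list(assay = "mtORF:Tsp45I", branches = list(
    list(groups = "P. damicornis", child = NULL),
    list(groups = "P. acuta", child = NULL)))
  nlaIV <- list(assay = "mtORF:NlaIV", branches = list(
    list(groups = finePair, child = tsp45I)))
  aciI <- list(assay = "mtORF:AciI", branches = list(
    list(groups = "P. verrucosa", child = NULL),
    list(groups = finePair, child = nlaIV)))
  alwNI <- list(assay = "mtORF:AlwNI", branches = list(
    list(groups = "P. ligulata", child = NULL),
    list(groups = setdiff(rest1, "P. ligulata"), child = aciI)))
  xhoI <- list(assay = "PocHistone:XhoI", branches = list(
    list(groups = "P. eydouxi", child = NULL),
    list(groups = "P. meandrina", child = NULL)))
  spec <- list(assay = "mtORF:SacI", branches = list(
    list(groups = type1, child = xhoI),
    list(groups = rest1, child = alwNI)))
  new("IdentificationKey", root = .cascadeNode(table, spec), table = table,
      params = list(minDetect = 0, tolBp = 0, tolFrac = 0))
}

#' Render a key as an indented dichotomous key
#'
#' @param key an [IdentificationKey-class].
#' @return character vector of lines (also printed by `show`).
#' @export
renderKey <- function(key) {
  lines <- character()
  walk <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (identical(node$kind, "leaf")) {
      lines <<- c(lines, sprintf("%s=> %s", pad,
                                 paste(node$species, collapse = " | ")))
      return(invisible())
    }
    lines <<- c(lines, sprintf("%sdigest %s with %s:", pad,
                               node$amplicon, node$enzyme))
    for (b in node$branches) {
      labels <- vapply(b$patterns, paste, character(1), collapse = ", ")
      lines <<- c(lines, sprintf("%s  bands (%s):", pad,
                                 paste(unique(labels), collapse = " / ")))
      walk(b$child, indent + 2L)
    }
  }
  walk(key@root, 0L)
  lines
}

setMethod("show", "IdentificationKey", function(object) {
  cat(sprintf("IdentificationKey: %d species, depth %d\n",
              length(keySpecies(object)), keyDepth(object)))
  cat(paste(renderKey(object), collapse = "\n"), "\n")
})

#' SpeciesCall class
#'
#' The outcome of classifying a sample: a single species, an ambiguous
#' candidate set, or no match, together with the assay path taken.
#'
#' @slot outcome one of `"species"`, `"ambiguous"`, `"no_match"`.
#' @slot species candidate group labels (length 1 for `"species"`).
#' @slot path `data.frame` of `assay` and observed/predicted `pattern`
#'   strings, in traversal order.
#' @export
setClass("SpeciesCall",
  representation(outcome = "character", species = "character",
                 path = "data.frame"))

#' @describeIn SpeciesCall-class outcome string.
#' @param x,object a `SpeciesCall`.
#' @export
callOutcome <- function(x) x@outcome

#' @describeIn SpeciesCall-class candidate species labels.
#' @export
callSpecies <- function(x) x@species

#' @describeIn SpeciesCall-class assay path taken (`data.frame`).
#' @export
callPath <- function(x) x@path

setMethod("show", "SpeciesCall", function(object) {
  lab <- switch(object@outcome,
    species = object@species,
    ambiguous = sprintf("ambiguous {%s}", paste(object@species, collapse = ", ")),
    no_match = "no match")
  cat("SpeciesCall:", lab, "\n")
  if (nrow(object@path)) {
    cat(paste(sprintf("  %s -> %s", object@path$assay, object@path$pattern),
              collapse = "\n"), "\n")
  }
})

.speciesCall <- function(species, path) {
  outcome <- if (length(species) == 0L) "no_match"
             else if (length(species) == 1L) "species" else "ambiguous"
  new("SpeciesCall", outcome = outcome, species = as.character(species),
      path = path)
}

.emptyPath <- function() {
  data.frame(assay = character(), pattern = character(),
             stringsAsFactors = FALSE)
}

#' Classify a sample from its amplicon sequences
#'
#' Traverses the key, digesting the supplied amplicon sequence in silico
#' at each node and following the branch whose predicted pattern exactly
#' matches. If the traversal needs an amplicon that was not supplied, a
#' `rflp_needs_more_data` warning names it and the call returns the
#' ambiguous set of species still in play. A pattern matching no branch
#' yields a `no_match` outcome (the assay panel is regional; unknown
#' haplotypes are expected elsewhere).
#'
#' @param seqs named list/vector of nucleotide strings, names being
#'   amplicon labels (e.g. `"mtORF"`, `"PocHistone"`).
#' @param key an [IdentificationKey-class].
#' @return a [SpeciesCall-class].
#' @export
classifySequence <- function(seqs, key) {
  stopifnot(is(key, "IdentificationKey"))
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  seqs <- as.list(seqs)
  enzymes <- key@table@enzymes
  path <- .emptyPath()
  node <- key@root
  repeat {
    if (identical(node$kind, "leaf")) {
      return(.speciesCall(node$species, path))
    }
    if (!node$amplicon %in% names(seqs)) {
      .rflpWarn(sprintf("amplicon '%s' needed to resolve {%s} but not supplied",
                        node$amplicon,
                        paste(.leafSpecies(node), collapse = ", ")),
                "rflp_needs_more_data")
      return(.speciesCall(sort(unique(.leafSpecies(node))), path))
    }
    obs <- fragmentLengths(digestDNA(seqs[[node$amplicon]],
                                     enzymes[[node$enzyme]]))
    path <- rbind(path, data.frame(
      assay = node$assay, pattern = paste(obs, collapse = ", "),
      stringsAsFactors = FALSE))
    hit <- NULL
    for (b in node$branches) {
      if (any(vapply(b$patterns, function(p) identical(as.integer(p), obs),
                     logical(1)))) {
        hit <- b
        break
      }
    }
    if (is.null(hit)) return(.speciesCall(character(), path))
    node <- hit$child
  }
}

#' Classify a sample from observed gel bands
#'
#' Scores observed band lengths against every group's predicted patterns
#' in the table: a group remains a candidate when each observation is
#' compatible with its predicted pattern under the detection limit and
#' sizing tolerance (bands below `minDetect` are dropped from both sides
#' before matching). Defaults reflect a 2% agarose gel.
#'
#' @param bands named list: assay label (`"amplicon:enzyme"`) -> numeric
#'   vector of observed band lengths in bp.
#' @param table a [PatternTable-class] (or an [IdentificationKey-class],
#'   whose table is used).
#' @param minDetect,tolBp,tolFrac gel-realism parameters, see
#'   [patternsDistinguishable()].
#' @return a [SpeciesCall-class].
#' @examples
#' fx <- generateFixtureSet(seed = 1)
#' tab <- fixturePatternTable(fx)
#' classifyObserved(list("mtORF:NlaIV" = c(460, 320, 170)), tab)
#' @export
classifyObserved <- function(bands, table, minDetect = 50, tolBp = 10,
                             tolFrac = 0.05) {
  if (is(table, "IdentificationKey")) table <- table@table
  stopifnot(is(table, "PatternTable"))
  if (length(bands) == 0L) {
    stop(rflpError("at least one assay observation required",
                   "rflp_invalid_input"))
  }
  if (is.null(names(bands)) || any(!nzchar(names(bands)))) {
    stop(rflpError("bands must be a named list (assay label -> lengths)",
                   "rflp_invalid_input"))
  }
  unknown <- setdiff(names(bands), table@assays$label)
  if (length(unknown)) {
    stop(rflpError(sprintf("unknown assay(s): %s; available: %s",
                           paste(unknown, collapse = ", "),
                           paste(table@assays$label, collapse = ", ")),
                   "rflp_invalid_input"))
  }
  for (lab in names(bands)) {
    if (length(bands[[lab]]) == 0L) {
      stop(rflpError(sprintf("empty band list for assay %s", lab),
                     "rflp_invalid_input"))
    }
  }
  candidates <- Filter(function(g) {
    all(vapply(names(bands), function(lab) {
      obs <- .visibleBands(bands[[lab]], minDetect)
      pred <- .visibleBands(table@patterns[[lab]][[g]], minDetect)
      .bandsMatch(obs, pred, tolBp, tolFrac)
    }, logical(1)))
  }, table@groups)
  path <- data.frame(
    assay = names(bands),
    pattern = vapply(bands, function(x)
      paste(sort(x, decreasing = TRUE), collapse = ", "), character(1)),
    stringsAsFactors = FALSE)
  .speciesCall(sort(unlist(candidates)), path)
}

# ---- key / table serialization -------------------------------------------

.serializeNode <- function(node) {
  if (identical(node$kind, "leaf")) {
    return(list(kind = "leaf", species = as.list(node$species)))
  }
  list(kind = "assay", assay = node$assay, amplicon = node$amplicon,
       enzyme = node$enzyme,
       branches = lapply(node$branches, function(b) {
         list(patterns = lapply(b$patterns, as.integer),
              child = .serializeNode(b$child))
       }))
}

.deserializeNode <- function(x) {
  if (identical(x$kind, "leaf")) {
    return(.leaf(unlist(x$species)))
  }
  list(kind = "assay", assay = x$assay, amplicon = x$amplicon,
       enzyme = x$enzyme,
       branches = lapply(x$branches, function(b) {
         list(patterns = lapply(b$patterns, function(p) as.integer(unlist(p))),
              child = .deserializeNode(b$child))
       }))
}

.serializeTable <- function(table) {
  list(
    groups = as.list(table@groups),
    enzymes = lapply(table@enzymes, function(e) {
      list(name = e@name, recognition = e@recognition,
           cut_top = e@cutTop, cut_bottom = e@cutBottom)
    }),
    patterns = lapply(table@patterns, function(p) lapply(p, as.integer))
  )
}

.deserializeTable <- function(x) {
  enzymes <- lapply(x$enzymes, function(e) {
    restrictionEnzyme(e$name, e$recognition, e$cut_top, e$cut_bottom)
  })
  patterns <- lapply(x$patterns, function(p) {
    lapply(p, function(v) as.integer(unlist(v)))
  })
  patternTable(patterns, enzymes)
}

#' Write / read an identification key as JSON
#'
#' The JSON document carries the decision tree, the full pattern table
#' (so band-based classification needs no extra file), the enzyme
#' definitions and the gel parameters the key was built with.
#'
#' @param key an [IdentificationKey-class].
#' @param path file path.
#' @return `readKey` returns an [IdentificationKey-class]; `writeKey`
#'   returns `path` invisibly.
#' @export
writeKey <- function(key, path) {
  stopifnot(is(key, "IdentificationKey"))
  doc <- list(format = "rflpTyper-key", version = 1L,
              params = key@params,
              table = .serializeTable(key@table),
              root = .serializeNode(key@root))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeKey
#' @export
readKey <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "rflpTyper-key")) {
    stop(rflpError(sprintf("%s is not an rflpTyper key file", path),
                   "rflp_data_error"))
  }
  new("IdentificationKey",
      root = .deserializeNode(doc$root),
      table = .deserializeTable(doc$table),
      params = lapply(doc$params, function(x) as.numeric(x)))
}
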