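#' Read and write edge-list layers
#'
#' Edge lists are tab-separated files with two columns (`gene_a`, `gene_b`)
#' or three (`gene_a`, `gene_b`, `weight`); lines starting with `#` are
#' comments. Self-loop lines are dropped with a warning. Rows may not mix
#' column counts, and two rows for the same unordered pair must not carry
#' conflicting weights.
#'
#' @param path File path.
#' @param name,scale Passed to [layer()]; `name` defaults to the file name.
#' @param header Skip a single header line (default `FALSE`).
#' @return `read_edge_list()` returns an `mxp_layer`.
#' @export
read_edge_list <- function(path, name = NULL, scale = "other",
                           header = FALSE) {
  lines <- readLines(path)
  if (header && length(lines) > 0L) lines <- lines[-1L]
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep) + as.integer(header)
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  if (length(lines) == 0L) {
    return(layer(name, matrix(character(0), ncol = 2), scale = scale))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L | nf > 3L)) {
    bad <- lineno[which(nf < 2L | nf > 3L)[1]]
    stop(sprintf("%s: malformed line %d (expected 2 or 3 tab-separated fields)",
                 path, bad), call. = FALSE)
  }
  if (length(unique(nf)) > 1L) {
    stop(path, ": mixed 2- and 3-column rows", call. = FALSE)
  }
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  w <- NULL
  if (nf[1] == 3L) {
    w <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
    if (anyNA(w)) {
      bad <- lineno[which(is.na(w))[1]]
      stop(sprintf("%s: non-numeric weight on line %d", path, bad),
           call. = FALSE)
    }
  }
  # conflicting duplicate weights are an input error, not a silent pick
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  if (!is.null(w)) {
    agg <- tapply(w, key, function(v) length(unique(v)))
    if (any(agg > 1L)) {
      stop(path, ": conflicting weights for duplicated edge(s): ",
           gsub("\r", "-", names(agg)[agg > 1L][1]), call. = FALSE)
    }
  }
  layer(name, cbind(a, b), weights = w, scale = scale)
}

#' @rdname read_edge_list
#' @param l An `mxp_layer`.
#' @param digits Significant digits for serialized weights (default 10, so
#'   round-trips are deterministic across platforms).
#' @export
write_edge_list <- function(l, path, digits = 10) {
  stopifnot(inherits(l, "mxp_layer"))
  if (is.null(l$weights)) {
    lines <- paste(l$edges[, 1], l$edges[, 2], sep = "\t")
  } else {
    lines <- paste(l$edges[, 1], l$edges[, 2],
                   signif(l$weights, digits), sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and write GMT gene-set collections
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Duplicate members within a line are collapsed.
#'
#' @param path File path.
#' @return `read_gene_sets()` returns a named list of character vectors with
#'   a `descriptions` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    stop(sprintf("%s: line %d has fewer than 3 fields", path, bad[1]),
         call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  attr(sets, "descriptions") <- vapply(fields, `[[`, character(1), 2L)
  sets
}

#' @rdname read_gene_sets
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an OBO-subset ontology
#'
#' Parses only `[Term]` stanzas and their `id:`, `name:` and `is_a:` tags;
#' stanzas marked `is_obsolete: true` are skipped, all other tags are
#' ignored. Exactly one parsed term must be parentless (the root), and every
#' `is_a` target must itself be a parsed term.
#'
#' @param path File path.
#' @return An `mxp_ontology`.
#' @export
read_obo_lite <- function(path) {
  lines <- readLines(path)
  stanza_starts <- which(trimws(lines) == "[Term]")
  if (length(stanza_starts) == 0L) stop(path, ": no [Term] stanzas", call. = FALSE)
  bounds <- c(stanza_starts, length(lines) + 1L)
  parents <- list()
  ids <- character(0)
  n_obsolete <- 0L
  for (s in seq_along(stanza_starts)) {
    chunk <- lines[(bounds[s] + 1L):(bounds[s + 1L] - 1L)]
    chunk <- chunk[!grepl("^\\[", trimws(chunk))]
    get_tag <- function(tag) {
      hits <- grep(paste0("^", tag, ":"), chunk, value = TRUE)
      trimws(sub(paste0("^", tag, ":"), "", hits))
    }
    if (any(grepl("^is_obsolete:\\s*true", chunk))) {
      n_obsolete <- n_obsolete + 1L
      next
    }
    id <- get_tag("id")
    if (length(id) != 1L) stop(path, ": [Term] stanza without a single id",
                               call. = FALSE)
    isa <- sub("\\s*!.*$", "", get_tag("is_a"))
    ids <- c(ids, id)
    if (length(isa) > 0L) parents[[id]] <- isa
  }
  unknown <- setdiff(unlist(parents, use.names = FALSE), ids)
  if (length(unknown) > 0L) {
    stop(path, ": is_a references to unknown term(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  roots <- setdiff(ids, names(parents))
  if (length(roots) != 1L) {
    stop(path, ": expected exactly one root term, found ",
         length(roots), call. = FALSE)
  }
  message(sprintf("read_obo_lite: %d terms read, %d obsolete skipped",
                  length(ids), n_obsolete))
  ontology(parents, root = roots)
}

#' @rdname read_obo_lite
#' @param o An `mxp_ontology`.
#' @export
write_obo_lite <- function(o, path) {
  stopifnot(inherits(o, "mxp_ontology"))
  out <- character(0)
  for (t in o$terms) {
    out <- c(out, "[Term]", paste0("id: ", t), paste0("name: ", t))
    for (p in o$parents[[t]]) out <- c(out, paste0("is_a: ", p))
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read and write gene-term annotation tables
#'
#' Two tab-separated columns: gene, term. No header.
#'
#' @param path File path.
#' @param o Optional ontology to validate the terms against.
#' @return `read_annotations()` returns an `mxp_annotations`.
#' @export
read_annotations <- function(path, o = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("gene", "term"),
                           colClasses = "character", quote = "")
  annotations(split(tab$term, tab$gene), o = o)
}

#' @rdname read_annotations
#' @param a An `mxp_annotations`.
#' @export
write_annotations <- function(a, path) {
  stopifnot(inherits(a, "mxp_annotations"))
  lines <- unlist(lapply(names(a), function(g) paste(g, a[[g]], sep = "\t")),
                  use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Read and write expression matrices
#'
#' Tab-separated, header row of sample identifiers, first column gene
#' identifiers. Duplicate gene rows are an error.
#'
#' @param path File path.
#' @return `read_expression()` returns a numeric genes x samples matrix.
#' @export
read_expression <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = NULL,
                           check.names = FALSE, quote = "")
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes)) {
    stop(path, ": duplicated gene row(s): ",
         genes[duplicated(genes)][1], call. = FALSE)
  }
  x <- as.matrix(tab[, -1, drop = FALSE])
  mode(x) <- "numeric"
  rownames(x) <- genes
  if (ncol(x) < 2L) stop(path, ": need at least 2 samples", call. = FALSE)
  x
}

#' @rdname read_expression
#' @param x Numeric matrix with gene rownames and sample colnames.
#' @param digits Significant digits for serialized values.
#' @export
write_expression <- function(x, path, digits = 10) {
  lines <- c(paste(c("gene", colnames(x)), collapse = "\t"),
             vapply(seq_len(nrow(x)), function(i) {
               paste(c(rownames(x)[i], signif(x[i, ], digits)), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write multiplex manifests
#'
#' A manifest is a JSON array of `{name, scale, path}` records pointing at
#' edge-list files (paths relative to the manifest's directory).
#'
#' @param path Manifest path.
#' @return `read_multiplex()` returns an `mxp_multiplex`.
#' @export
read_multiplex <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  dir <- dirname(path)
  layers <- lapply(seq_len(nrow(man)), function(i) {
    read_edge_list(file.path(dir, man$path[i]), name = man$name[i],
                   scale = man$scale[i])
  })
  multiplex(layers)
}

#' @rdname read_multiplex
#' @param m An `mxp_multiplex`.
#' @param dir Output directory (created if needed); one edge-list file per
#'   layer plus `manifest.json`.
#' @export
write_multiplex <- function(m, dir) {
  stopifnot(inherits(m, "mxp_multiplex"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  records <- lapply(m$layers, function(l) {
    fn <- paste0(l$name, ".tsv")
    write_edge_list(l, file.path(dir, fn))
    list(name = l$name, scale = l$scale, path = fn)
  })
  jsonlite::write_json(
    data.frame(name = vapply(records, `[[`, character(1), "name"),
               scale = vapply(records, `[[`, character(1), "scale"),
               path = vapply(records, `[[`, character(1), "path"),
               stringsAsFactors = FALSE),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(file.path(dir, "manifest.json"))
}

#' Read and write patient cases
#'
#' JSON with fields `id`, `hpo_terms`, `candidates`, optional `causal` and
#' `disease_group`.
#'
#' @param path File path.
#' @return `read_patient_case()` returns an `mxp_patient_case`.
#' @export
read_patient_case <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  patient_case(id = j$id, phenotype_terms = j$hpo_terms,
               candidates = j$candidates, causal = j$causal %||% NULL,
               disease_group = j$disease_group %||% NULL)
}

#' @rdname read_patient_case
#' @param case An `mxp_patient_case`.
#' @export
write_patient_case <- function(case, path) {
  stopifnot(inherits(case, "mxp_patient_case"))
  jsonlite::write_json(
    list(id = case$id, hpo_terms = case$phenotype_terms,
         candidates = case$candidates, causal = case$causal,
         disease_group = case$disease_group),
    path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a relevance table as TSV
#'
#' One row per (group, layer) with LCC statistics, adjusted p-values and
#' significance stars (thresholds 0.05, 0.01, 0.001, 1e-4).
#'
#' @param tab Data frame from [relevance_table()].
#' @param path File path.
#' @export
write_relevance_table <- function(tab, path) {
  utils::write.table(format(tab, digits = 10, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
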