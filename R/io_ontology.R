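#' Construct an ontology DAG
#'
#' A minimal is_a ontology: term IDs, display names, and child -> parent
#' edges. Acyclicity is verified at construction; parents must be known
#' terms; every non-root term has at least one parent by construction.
#'
#' @param terms character vector of term IDs.
#' @param names character vector of term names (same length, optional).
#' @param parents named list: term ID -> character vector of parent IDs.
#' @return an object of class `ontology` with elements `terms`, `name`,
#'   `parents`, `children`, `roots`.
#' @export
ontology <- function(terms, names = terms, parents = list()) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop("duplicate term IDs")
  name <- stats::setNames(as.character(names), terms)
  par <- stats::setNames(vector("list", length(terms)), terms)
  for (t in base::names(parents)) {
    if (!t %in% terms) stop("parent list for unknown term: ", t)
    p <- unique(as.character(parents[[t]]))
    unknown <- setdiff(p, terms)
    if (length(unknown)) {
      stop("term ", t, " has unknown parent(s): ", paste(unknown, collapse = ", "))
    }
    par[[t]] <- p
  }
  # Kahn topological check for cycles
  indeg <- stats::setNames(lengths(par), terms)
  queue <- terms[indeg == 0L]
  children <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) for (p in par[[t]]) children[[p]] <- c(children[[p]], t)
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children[[t]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(terms)) {
    stop("cyclic is_a relationships involving: ",
         paste(terms[indeg > 0L], collapse = ", "))
  }
  structure(list(terms = terms, name = name, parents = par,
                 children = children, roots = terms[lengths(par) == 0L]),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology: %d terms, %d root(s)>\n",
              length(x$terms), length(x$roots)))
  invisible(x)
}

#' Read an OBO 1.2 subset
#'
#' Parses `[Term]` stanzas, honouring `id:`, `name:`, `is_a:` (text after
#' `!` stripped) and `is_obsolete: true` (stanza skipped). Everything else
#' is ignored.
#'
#' @param path OBO file path.
#' @return an `ontology`.
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(trimws(lines) == "[Term]")
  bounds <- c(which(grepl("^\\[", trimws(lines))), length(lines) + 1L)
  ids <- character(); nms <- character(); parents <- list()
  for (s in starts) {
    e <- min(bounds[bounds > s]) - 1L
    stanza <- trimws(lines[seq(s + 1L, max(s + 1L, e))])
    field <- function(key) {
      v <- stanza[startsWith(stanza, paste0(key, ":"))]
      trimws(sub("!.*$", "", sub(paste0("^", key, ":"), "", v)))
    }
    if (any(tolower(field("is_obsolete")) == "true")) next
    id <- field("id")
    if (length(id) != 1L || !nzchar(id)) stop("OBO [Term] stanza without id")
    nm <- field("name")
    ids <- c(ids, id)
    nms <- c(nms, if (length(nm)) nm[[1L]] else id)
    isa <- field("is_a")
    if (length(isa)) parents[[id]] <- isa
  }
  ontology(ids, nms, parents)
}

#' Write an ontology as OBO
#' @param ont an `ontology`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_obo <- function(ont, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in ont$terms) {
    writeLines(c("", "[Term]", paste0("id: ", t),
                 paste0("name: ", ont$name[[t]]),
                 if (length(ont$parents[[t]]))
                   paste0("is_a: ", ont$parents[[t]])), con)
  }
  invisible(path)
}

#' Ancestors of a term (is_a closure)
#' @param ont an `ontology`.
#' @param term term ID.
#' @param include_self include the term itself (default `TRUE`).
#' @return character vector of term IDs.
#' @export
term_ancestors <- function(ont, term, include_self = TRUE) {
  if (!term %in% ont$terms) stop("unknown term: ", term)
  out <- character()
  frontier <- term
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- setdiff(unique(unlist(ont$parents[frontier], use.names = FALSE)), out)
  }
  if (!include_self) out <- setdiff(out, term)
  sort(unique(out))
}

# memoized ancestor table for a whole ontology (list term -> ancestors+self)
.ancestor_table <- function(ont) {
  stats::setNames(lapply(ont$terms, term_ancestors, ont = ont), ont$terms)
}

#' Read a GAF-like annotation table
#'
#' First column gene symbol, second column term ID; further columns ignored;
#' `#`/`!` comment lines skipped. Annotations to terms absent from the
#' ontology are dropped with a warning count.
#'
#' @param path TSV file path.
#' @param ont an `ontology` used to validate term IDs.
#' @return a named list gene symbol -> character vector of directly annotated
#'   term IDs, with attribute `n_skipped`.
#' @export
read_gaf <- function(path, ont) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^[#!]", trimws(lines))]
  if (!length(lines)) {
    return(structure(stats::setNames(list(), character()), n_skipped = 0L))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 2L
  if (any(bad)) stop("annotation rows must have at least two columns")
  gene <- canonical_symbols(vapply(parts, `[[`, "", 1L))
  term <- trimws(vapply(parts, `[[`, "", 2L))
  known <- term %in% ont$terms
  n_skipped <- sum(!known)
  if (n_skipped) {
    warning(n_skipped, " annotation(s) to unknown terms skipped")
  }
  gene <- gene[known]; term <- term[known]
  ann <- lapply(split(term, gene), function(x) sort(unique(x)))
  structure(ann[order(names(ann))], n_skipped = n_skipped)
}

#' Write annotations in the GAF-like two-column dialect
#' @param annotations named list gene -> term IDs.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_gaf <- function(annotations, path) {
  gene <- rep(names(annotations), lengths(annotations))
  term <- unlist(annotations, use.names = FALSE)
  utils::write.table(data.frame(gene, term), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read ontology and annotations together
#' @param obo_path OBO file path.
#' @param gaf_path annotation TSV path.
#' @return list with `ontology`, `annotations`, `n_skipped`.
#' @export
read_ontology_annotations <- function(obo_path, gaf_path) {
  ont <- read_obo(obo_path)
  ann <- read_gaf(gaf_path, ont)
  list(ontology = ont, annotations = ann,
       n_skipped = attr(ann, "n_skipped"))
}

#' is_a closure of a gene's annotations
#'
#' Direct annotations propagated up the ontology; idempotent.
#'
#' @param ont an `ontology`.
#' @param terms character vector of (direct or closed) term IDs.
#' @return sorted character vector of term IDs closed under is_a.
#' @export
annotation_closure <- function(ont, terms) {
  if (!length(terms)) return(character())
  sort(unique(unlist(lapply(terms, term_ancestors, ont = ont),
                     use.names = FALSE)))
}
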