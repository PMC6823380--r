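#' Canonicalize gene symbols
#'
#' Uppercases and trims whitespace. Synonym resolution, when requested, is
#' applied *before* this canonicalization so that alias lookup is
#' case-insensitive (worm gene names are printed both as `nhr-6` and `NHR-6`).
#'
#' @param x character vector of gene symbols.
#' @return character vector of canonical symbols.
#' @export
canonical_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Construct a gene set
#'
#' A named set of canonical gene symbols: duplicates and empty symbols are
#' dropped, members are stored sorted for deterministic output.
#'
#' @param members character vector of gene symbols (canonicalized on entry).
#' @param name optional label for the set.
#' @return an object of class `gene_set` with elements `name` and `members`.
#' @export
gene_set <- function(members = character(), name = "") {
  m <- canonical_symbols(members)
  m <- sort(unique(m[nzchar(m)]))
  structure(list(name = name, members = m), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set '%s': %d genes>\n", x$name, length(x$members)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

#' Coerce to a plain character vector of members
#' @param x a `gene_set` or character vector.
#' @return character vector of canonical symbols.
#' @export
as_members <- function(x) {
  if (inherits(x, "gene_set")) x$members else gene_set(x)$members
}

#' Read a plain-text gene list
#'
#' One symbol per line; blank lines and lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param name label for the resulting set (defaults to the file name).
#' @return a `gene_set`.
#' @export
read_gene_list <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gene_set(lines, name = name)
}

#' Write a gene set to a plain-text file
#' @param x a `gene_set` or character vector.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_gene_list <- function(x, path) {
  writeLines(as_members(x), path)
  invisible(path)
}

#' Build a synonym map
#'
#' Maps alias symbols to canonical symbols. Alias chains (an alias whose
#' canonical symbol is itself an alias) are resolved to their fixed point at
#' construction; cyclic chains and aliases claimed by two different canonical
#' symbols are errors. Canonical symbols map to themselves.
#'
#' @param alias character vector of alias symbols.
#' @param canonical character vector of canonical symbols, same length.
#' @return an object of class `synonym_map` (a named character vector
#'   alias -> canonical, both uppercased).
#' @export
synonym_map <- function(alias = character(), canonical = character()) {
  stopifnot(length(alias) == length(canonical))
  a <- canonical_symbols(alias)
  b <- canonical_symbols(canonical)
  keep <- nzchar(a) & nzchar(b)
  a <- a[keep]; b <- b[keep]
  # drop exact duplicate rows, then check for contradictory ones
  pair <- !duplicated(paste(a, b, sep = "\r"))
  a <- a[pair]; b <- b[pair]
  dup <- a[duplicated(a)]
  if (length(dup)) {
    stop("alias mapped to two different canonical symbols: ",
         paste(unique(dup), collapse = ", "))
  }
  map <- stats::setNames(b, a)
  # resolve chains alias -> x -> y to their fixed point; detect cycles
  for (i in seq_along(map)) {
    seen <- names(map)[i]
    val <- map[[i]]
    while (val %in% names(map) && map[[val]] != val) {
      if (val %in% seen) {
        stop("cyclic synonym chain involving: ", paste(seen, collapse = " -> "))
      }
      seen <- c(seen, val)
      val <- map[[val]]
    }
    map[[i]] <- val
  }
  # canonical symbols map to themselves
  self <- setdiff(unname(map), names(map))
  map <- c(map, stats::setNames(self, self))
  structure(map, class = "synonym_map")
}

#' Read a two-column alias/canonical TSV into a synonym map
#'
#' Column 1 is the alias, column 2 the canonical symbol; header optional
#' (detected as a first line containing "alias"); `#` comment lines ignored.
#'
#' @param path file path.
#' @return a `synonym_map`.
#' @export
read_synonym_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) && grepl("alias", tolower(lines[1]), fixed = TRUE)) {
    lines <- lines[-1]
  }
  if (!length(lines)) return(synonym_map())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 2L
  if (any(bad)) stop("synonym table rows must have two tab-separated columns")
  synonym_map(vapply(parts, `[[`, "", 1L), vapply(parts, `[[`, "", 2L))
}

#' Resolve gene symbols through a synonym map
#'
#' Each input symbol is replaced by its canonical symbol when it is a known
#' alias, and passed through (canonicalized) otherwise. Two inputs that
#' resolve to the same canonical symbol collapse to one entry and are counted
#' as a collision.
#'
#' @param symbols character vector (or `gene_set`) of symbols to resolve.
#' @param syn a `synonym_map`.
#' @return a list with `symbols` (unique canonical symbols, first-occurrence
#'   order), `unresolved` (inputs found nowhere in the map), `n_unresolved`,
#'   and `n_collisions`.
#' @export
resolve_synonyms <- function(symbols, syn) {
  if (inherits(symbols, "gene_set")) symbols <- symbols$members
  up <- canonical_symbols(symbols)
  up <- up[nzchar(up)]
  known_alias <- up %in% names(syn)
  resolved <- ifelse(known_alias, unname(unclass(syn)[up]), up)
  unresolved <- unique(up[!known_alias & !(up %in% unname(unclass(syn)))])
  n_coll <- sum(duplicated(resolved))
  list(
    symbols      = resolved[!duplicated(resolved)],
    unresolved   = unresolved,
    n_unresolved = length(unresolved),
    n_collisions = n_coll
  )
}
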