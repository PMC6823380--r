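# Column names follow the BioGRID tab-delimited dialect so that real exports
# load unchanged; unknown extra columns are ignored.
.biogrid_cols <- c(
  a      = "Official Symbol Interactor A",
  b      = "Official Symbol Interactor B",
  class  = "Experimental System Type"
)

#' Read a curated gene-gene interaction table
#'
#' Parses a tab-separated interaction table with (at least) the columns
#' `Official Symbol Interactor A`, `Official Symbol Interactor B` and
#' `Experimental System Type` (values `physical` or `genetic`). Symbols are
#' canonicalized (optionally through a synonym map first); self-interactions
#' are dropped with a warning because the downstream graph model is simple.
#'
#' @param path TSV file path; lines starting with `#` are ignored.
#' @param class_filter optional character vector; keep only rows whose
#'   interaction class is in this set (e.g. `"physical"`).
#' @param synonyms optional `synonym_map` applied to both interactor columns.
#' @return a data.frame with columns `gene_a`, `gene_b`, `interaction_class`,
#'   `source_id`.
#' @export
read_interaction_table <- function(path, class_filter = NULL, synonyms = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  # real BioGRID exports comment their header line ('#BioGRID Interaction
  # ID\t...'); keep it, drop every other '#' line
  is_comment <- startsWith(lines, "#")
  keep <- !is_comment
  header_like <- is_comment & grepl(.biogrid_cols[["a"]], lines, fixed = TRUE)
  if (any(header_like)) keep[which(header_like)[1L]] <- TRUE
  lines <- lines[keep]
  if (!length(lines)) {
    warning("empty interaction table: ", path)
    return(.empty_interactions())
  }
  df <- utils::read.delim(text = lines, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  for (col in .biogrid_cols) {
    if (!col %in% names(df)) {
      stop("interaction table is missing required column '", col, "'")
    }
  }
  if (nrow(df) == 0L) {
    warning("empty interaction table: ", path)
    return(.empty_interactions())
  }
  src <- if ("#BioGRID Interaction ID" %in% names(df)) {
    as.character(df[["#BioGRID Interaction ID"]])
  } else if ("BioGRID Interaction ID" %in% names(df)) {
    as.character(df[["BioGRID Interaction ID"]])
  } else {
    sprintf("row%d", seq_len(nrow(df)))
  }
  out <- data.frame(
    gene_a = as.character(df[[.biogrid_cols[["a"]]]]),
    gene_b = as.character(df[[.biogrid_cols[["b"]]]]),
    interaction_class = tolower(trimws(as.character(df[[.biogrid_cols[["class"]]]]))),
    source_id = src,
    stringsAsFactors = FALSE
  )
  bad_class <- !out$interaction_class %in% c("physical", "genetic")
  if (any(bad_class)) {
    warning(sum(bad_class), " row(s) with interaction class outside ",
            "{physical, genetic} dropped")
    out <- out[!bad_class, , drop = FALSE]
  }
  if (!is.null(class_filter)) {
    out <- out[out$interaction_class %in% tolower(class_filter), , drop = FALSE]
  }
  if (!is.null(synonyms)) {
    out$gene_a <- .resolve_vector(out$gene_a, synonyms)
    out$gene_b <- .resolve_vector(out$gene_b, synonyms)
  }
  out$gene_a <- canonical_symbols(out$gene_a)
  out$gene_b <- canonical_symbols(out$gene_b)
  out <- out[nzchar(out$gene_a) & nzchar(out$gene_b), , drop = FALSE]
  loops <- out$gene_a == out$gene_b
  if (any(loops)) {
    warning(sum(loops), " self-interaction(s) dropped")
    out <- out[!loops, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# elementwise synonym resolution without the dedup/report machinery
.resolve_vector <- function(x, syn) {
  up <- canonical_symbols(x)
  m <- unclass(syn)
  hit <- up %in% names(m)
  up[hit] <- unname(m[up[hit]])
  up
}

.empty_interactions <- function() {
  data.frame(gene_a = character(), gene_b = character(),
             interaction_class = character(), source_id = character(),
             stringsAsFactors = FALSE)
}

#' Write an interaction table in the BioGRID-like TSV dialect
#'
#' Inverse of [read_interaction_table()] on canonicalized records.
#'
#' @param records data.frame as returned by [read_interaction_table()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_interaction_table <- function(records, path) {
  out <- data.frame(
    a = records$gene_a, b = records$gene_b,
    cls = records$interaction_class, id = records$source_id,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  names(out) <- c(.biogrid_cols[["a"]], .biogrid_cols[["b"]],
                  .biogrid_cols[["class"]], "BioGRID Interaction ID")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BLAST-tabular similarity table
#'
#' Expects a headered TSV with at least `qseqid`, `sseqid`, `evalue`,
#' `bitscore`. Species labels come either from `qspecies`/`sspecies` columns
#' or from a named `species_map` (symbol -> species label).
#'
#' @param path TSV file path; `#` comment lines ignored.
#' @param species_map optional named character vector mapping symbols to
#'   species labels, used when the table has no species columns.
#' @return data.frame with columns `query`, `subject`, `query_species`,
#'   `subject_species`, `evalue`, `bitscore`.
#' @export
read_similarity_table <- function(path, species_map = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("qseqid", "sseqid", "evalue", "bitscore")
  for (col in need) {
    if (!col %in% names(df)) {
      stop("similarity table is missing required column '", col, "'")
    }
  }
  if (all(c("qspecies", "sspecies") %in% names(df))) {
    qs <- as.character(df$qspecies)
    ss <- as.character(df$sspecies)
  } else if (!is.null(species_map)) {
    qs <- unname(species_map[as.character(df$qseqid)])
    ss <- unname(species_map[as.character(df$sseqid)])
  } else {
    stop("no qspecies/sspecies columns and no species_map given")
  }
  out <- data.frame(
    query = canonical_symbols(df$qseqid),
    subject = canonical_symbols(df$sseqid),
    query_species = toupper(trimws(qs)),
    subject_species = toupper(trimws(ss)),
    evalue = as.numeric(df$evalue),
    bitscore = as.numeric(df$bitscore),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$evalue)) || any(out$evalue < 0)) {
    stop("e-values must be non-negative numbers")
  }
  if (any(is.na(out$query_species)) || any(!nzchar(out$query_species)) ||
      any(is.na(out$subject_species)) || any(!nzchar(out$subject_species))) {
    stop("species labels must be non-empty for every row")
  }
  out
}

#' Write a similarity table in the BLAST-tabular dialect
#' @param records data.frame as returned by [read_similarity_table()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_similarity_table <- function(records, path) {
  out <- data.frame(
    qseqid = records$query, sseqid = records$subject,
    qspecies = records$query_species, sspecies = records$subject_species,
    evalue = format(records$evalue, scientific = TRUE, trim = TRUE),
    bitscore = records$bitscore,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
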