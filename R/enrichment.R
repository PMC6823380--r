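#' One-sided hypergeometric over-representation p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of seeing
#' at least `k` annotated genes in a study set of size `n` drawn from a
#' population of `N` genes of which `K` carry the annotation. This is the
#' one-sided Fisher's exact test for over-representation.
#'
#' @param k study genes carrying the annotation.
#' @param K population genes carrying the annotation.
#' @param n study size.
#' @param N population size.
#' @return p-value in \[0, 1\].
#' @export
fisher_over <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > n || n > N || K > N || k > K ||
      (n - k) > (N - K)) {
    stop("inconsistent contingency counts: k=", k, " K=", K,
         " n=", n, " N=", N)
  }
  if (k == 0) return(1)
  # exact tail sum; phyper works in log space internally
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order, capped at 1.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric())
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Map terms to their nearest slim ancestors
#'
#' Each term maps to the slim term(s) at minimal is_a distance among its
#' ancestors (including itself); ties map to all tied slim terms; terms with
#' no slim ancestor map to nothing.
#'
#' @param ont an `ontology`.
#' @param terms character vector of term IDs.
#' @param slim_terms character vector of slim term IDs.
#' @return named list term -> character vector of slim term IDs.
#' @export
map_to_slim <- function(ont, terms, slim_terms) {
  slim_terms <- intersect(slim_terms, ont$terms)
  out <- stats::setNames(vector("list", length(terms)), terms)
  for (t in unique(terms)) {
    # BFS up the is_a DAG recording the first depth at which slims appear
    depth <- 0L
    frontier <- t
    seen <- character()
    hit <- character()
    while (length(frontier) && !length(hit)) {
      hit <- intersect(frontier, slim_terms)
      if (length(hit)) break
      seen <- c(seen, frontier)
      frontier <- setdiff(
        unique(unlist(ont$parents[frontier], use.names = FALSE)), seen)
      depth <- depth + 1L
    }
    out[[t]] <- sort(hit)
  }
  out[terms]
}

#' GO over-representation of a study set
#'
#' Per-term one-sided Fisher's exact test of a study gene set against a
#' population, on is_a-closed annotations, with Benjamini-Hochberg
#' correction across the tested terms. Genes without annotations are
#' dropped from both sets (and counted); terms annotating no population
#' gene are not tested.
#'
#' @param study `gene_set` (or character vector), must be contained in
#'   `population`.
#' @param population `gene_set` (or character vector) of background genes.
#' @param ont an `ontology`.
#' @param annotations named list gene -> direct term IDs.
#' @param fdr_cutoff significance threshold on the q-value (default 0.5).
#' @param slim_terms optional character vector of slim term IDs; when given,
#'   each gene's closed annotations are mapped to nearest slim ancestors and
#'   only slim terms are tested.
#' @return data.frame of class `enrichment_table` with columns `term`,
#'   `name`, `study_count`, `study_size`, `population_count`,
#'   `population_size`, `fold`, `p`, `q`, `significant`, ordered by `p`
#'   then term; attributes `n_unannotated_study`, `n_unannotated_population`.
#' @export
enrich <- function(study, population, ont, annotations, fdr_cutoff = 0.5,
                   slim_terms = NULL) {
  stopifnot(fdr_cutoff > 0, fdr_cutoff <= 1)
  study <- as_members(study)
  population <- as_members(population)
  if (!all(study %in% population)) {
    stop("study set is not contained in the population: ",
         paste(setdiff(study, population), collapse = ", "))
  }
  annotated <- names(annotations)[lengths(annotations) > 0L]
  n_un_pop <- sum(!population %in% annotated)
  n_un_study <- sum(!study %in% annotated)
  population <- intersect(population, annotated)
  study <- intersect(study, annotated)
  anc <- .ancestor_table(ont)
  gene_terms <- lapply(annotations[population], function(tt) {
    closed <- unique(unlist(anc[tt], use.names = FALSE))
    if (is.null(slim_terms)) closed else
      unique(unlist(map_to_slim(ont, closed, slim_terms), use.names = FALSE))
  })
  N <- length(population)
  n <- length(study)
  pop_tab <- table(unlist(gene_terms, use.names = FALSE))
  study_tab <- table(unlist(gene_terms[study], use.names = FALSE))
  terms <- sort(names(pop_tab))  # K = 0 terms never appear here
  K <- as.numeric(pop_tab[terms])
  k <- as.numeric(study_tab[terms])
  k[is.na(k)] <- 0
  p <- vapply(seq_along(terms),
              function(i) fisher_over(k[i], K[i], n, N), numeric(1))
  q <- bh_fdr(p)
  fold <- if (n > 0) (k / n) / (K / N) else rep(NA_real_, length(terms))
  out <- data.frame(
    term = terms,
    name = unname(ont$name[terms]),
    study_count = as.integer(k),
    study_size = as.integer(n),
    population_count = as.integer(K),
    population_size = as.integer(N),
    fold = fold,
    p = p,
    q = q,
    significant = q < fdr_cutoff,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_table", "data.frame"),
            n_unannotated_study = n_un_study,
            n_unannotated_population = n_un_pop)
}

#' Write an enrichment table as TSV
#' @param tab an `enrichment_table`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_enrichment_tsv <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
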