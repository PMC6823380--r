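#' Wang-style semantic contribution values of a term
#'
#' S-values over the term's ancestor closure: the term itself contributes 1
#' and each is_a step decays the contribution by the factor `w`, taking the
#' maximum over paths.
#'
#' @param ont an `ontology`.
#' @param term a term ID.
#' @param w decay factor per is_a edge (default 0.8).
#' @return named numeric vector ancestor -> S-value (includes the term).
#' @export
term_svalues <- function(ont, term, w = 0.8) {
  if (!term %in% ont$terms) stop("unknown term: ", term)
  anc <- term_ancestors(ont, term)
  S <- stats::setNames(numeric(length(anc)), anc)
  S[term] <- 1
  # relax child -> parent edges inside the closure until stable (DAG)
  repeat {
    changed <- FALSE
    for (t in anc) {
      if (S[[t]] == 0) next
      for (p in intersect(ont$parents[[t]], anc)) {
        cand <- w * S[[t]]
        if (cand > S[[p]] + 1e-15) {
          S[[p]] <- cand
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  S
}

#' Semantic similarity of two terms
#'
#' Wang's topology-based measure: with S-values `S1`, `S2` over the two
#' ancestor closures, `sim = sum over common ancestors of (S1 + S2) /
#' (SV1 + SV2)` where `SV` is the sum of all S-values of a term. Identical
#' terms score 1; terms with disjoint ancestries score 0.
#'
#' @param ont an `ontology`.
#' @param t1,t2 term IDs.
#' @param w decay factor per is_a edge (default 0.8).
#' @return similarity in \[0, 1\].
#' @export
term_similarity <- function(ont, t1, t2, w = 0.8) {
  S1 <- term_svalues(ont, t1, w)
  S2 <- term_svalues(ont, t2, w)
  common <- intersect(names(S1), names(S2))
  if (!length(common)) return(0)
  sum(S1[common] + S2[common]) / (sum(S1) + sum(S2))
}

#' Semantic similarity of two annotation sets (best-match average)
#'
#' Best-match average over the pairwise term similarity matrix: every term
#' of each set is matched to its best counterpart in the other set and the
#' matches are averaged.
#'
#' @param ont an `ontology`.
#' @param termsA,termsB nonempty character vectors of term IDs.
#' @param w decay factor per is_a edge.
#' @param svalue_cache optional environment used to memoize S-values across
#'   calls.
#' @return similarity in \[0, 1\]; symmetric; 1 on identical sets.
#' @export
gene_similarity <- function(ont, termsA, termsB, w = 0.8,
                            svalue_cache = NULL) {
  stopifnot(length(termsA) > 0, length(termsB) > 0)
  termsA <- unique(termsA)
  termsB <- unique(termsB)
  sval <- function(t) {
    if (is.null(svalue_cache)) return(term_svalues(ont, t, w))
    if (is.null(svalue_cache[[t]])) svalue_cache[[t]] <- term_svalues(ont, t, w)
    svalue_cache[[t]]
  }
  SA <- lapply(termsA, sval)
  SB <- lapply(termsB, sval)
  sim <- matrix(0, length(termsA), length(termsB))
  for (i in seq_along(termsA)) {
    for (j in seq_along(termsB)) {
      common <- intersect(names(SA[[i]]), names(SB[[j]]))
      if (length(common)) {
        sim[i, j] <- sum(SA[[i]][common] + SB[[j]][common]) /
          (sum(SA[[i]]) + sum(SB[[j]]))
      }
    }
  }
  (sum(apply(sim, 1L, max)) + sum(apply(sim, 2L, max))) /
    (length(termsA) + length(termsB))
}

#' Filter candidate genes by semantic similarity to a reference set
#'
#' A candidate is kept when its best gene-level similarity to any reference
#' gene exceeds the threshold (strictly; the default keeps scores beyond
#' 0.9). Unannotated candidates are excluded with a warning; an annotated
#' reference gene is required.
#'
#' @param candidates,reference `gene_set`s (or character vectors).
#' @param ont an `ontology`.
#' @param annotations named list gene -> direct term IDs.
#' @param threshold keep candidates with score > threshold (default 0.9).
#' @param w Wang decay factor.
#' @return list with `kept` (`gene_set`), `scores` (data.frame `candidate`,
#'   `best_reference`, `score`, `kept`), `n_unannotated`.
#' @export
filter_by_semsim <- function(candidates, reference, ont, annotations,
                             threshold = 0.9, w = 0.8) {
  stopifnot(threshold >= 0, threshold <= 1)
  cand <- as_members(candidates)
  ref <- as_members(reference)
  annotated <- names(annotations)[lengths(annotations) > 0L]
  ref <- intersect(ref, annotated)
  if (!length(ref)) stop("reference set has no annotated genes")
  drop <- setdiff(cand, annotated)
  if (length(drop)) {
    warning(length(drop), " unannotated candidate(s) excluded: ",
            paste(drop, collapse = ", "))
  }
  cand <- intersect(cand, annotated)
  cache <- new.env(parent = emptyenv())
  rows <- lapply(cand, function(g) {
    scores <- vapply(ref, function(r) {
      gene_similarity(ont, annotations[[g]], annotations[[r]], w,
                      svalue_cache = cache)
    }, numeric(1))
    best <- which.max(scores)
    data.frame(candidate = g, best_reference = ref[best],
               score = unname(scores[best]),
               kept = unname(scores[best]) > threshold,
               stringsAsFactors = FALSE)
  })
  scores <- if (length(rows)) do.call(rbind, rows) else
    data.frame(candidate = character(), best_reference = character(),
               score = numeric(), kept = logical(), stringsAsFactors = FALSE)
  scores <- scores[order(-scores$score, scores$candidate), , drop = FALSE]
  rownames(scores) <- NULL
  list(kept = gene_set(scores$candidate[scores$kept], name = "semsim_pass"),
       scores = scores, n_unannotated = length(drop))
}
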