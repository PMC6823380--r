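#' Fraction of lifespan-reduction genes in a universe
#'
#' @param universe `gene_set` (or character vector) of all genes considered.
#' @param lrg `gene_set` of lifespan-reduction genes; must be contained in
#'   the universe.
#' @return fraction `|lrg| / |universe|`.
#' @export
lrg_fraction <- function(universe, lrg) {
  u <- as_members(universe)
  l <- as_members(lrg)
  if (!length(u)) stop("universe is empty")
  outside <- setdiff(l, u)
  if (length(outside)) {
    stop("LRG set not contained in universe: ", paste(outside, collapse = ", "))
  }
  length(l) / length(u)
}

#' Probability that k independent picks are all hits
#'
#' With-replacement (independent-marginal) probability `f^k` of picking `k`
#' genes in a row that all belong to a class of frequency `f`.
#'
#' @param f class frequency in \[0, 1\].
#' @param k number of picks (>= 1).
#' @return `f^k`.
#' @export
prob_all_k <- function(f, k) {
  stopifnot(f >= 0, f <= 1, k >= 1)
  f ^ k
}

#' Exact without-replacement companion of [prob_all_k()]
#'
#' Probability that `k` draws without replacement from a universe of `N`
#' genes containing `K` hits are all hits:
#' `prod_{j=0}^{k-1} (K - j) / (N - j)`. Converges to `(K/N)^k` as the
#' universe grows at fixed frequency.
#'
#' @param N universe size.
#' @param K number of hits in the universe (<= N).
#' @param k number of draws (0 allowed; `k > K` gives 0).
#' @return probability in \[0, 1\].
#' @export
hypergeom_all_k <- function(N, K, k) {
  stopifnot(N >= 0, K >= 0, K <= N, k >= 0)
  if (k == 0) return(1)
  if (k > K) return(0)
  j <- seq_len(k) - 1
  prod((K - j) / (N - j))
}

#' Fraction of lifespan-reduction genes among hub nodes
#'
#' @param net a `ppi_network`.
#' @param lrg `gene_set` of lifespan-reduction genes.
#' @param top_fraction hub degree-quantile fraction passed to [hubs()].
#' @return `|hubs ∩ lrg| / |hubs|`.
#' @export
hub_lrg_fraction <- function(net, lrg, top_fraction = 0.1) {
  h <- hubs(net, top_fraction)$members
  if (!length(h)) stop("hub set is empty")
  length(intersect(h, as_members(lrg))) / length(h)
}

#' A-priori probability report
#'
#' Bundles the chance estimates of hitting lifespan-reduction genes by
#' random picks: the genome-wide LRG frequency, the with-replacement
#' probability `f^k` of `k` hits in a row (the headline figure), its exact
#' without-replacement counterpart for the finite universe, and -- when a
#' network is supplied -- the LRG frequency among hub nodes with its own
#' `k`-picks probability.
#'
#' @param universe `gene_set` of all genes.
#' @param lrg `gene_set` of lifespan-reduction genes (subset of universe).
#' @param net optional `ppi_network` for the hub-restricted estimates.
#' @param top_fraction hub fraction for [hubs()].
#' @param k number of picks (default 3).
#' @return list of class `prior_report` with `universe_size`, `lrg_count`,
#'   `f`, `k`, `p_with_replacement`, `p_hypergeometric`, and (with a
#'   network) `hub_count`, `hub_lrg_fraction`, `p_hub_with_replacement`.
#' @export
prior_report <- function(universe, lrg, net = NULL, top_fraction = 0.1,
                         k = 3L) {
  u <- as_members(universe)
  l <- as_members(lrg)
  f <- lrg_fraction(u, l)
  out <- list(
    universe_size = length(u),
    lrg_count = length(l),
    f = f,
    k = as.integer(k),
    p_with_replacement = prob_all_k(f, k),
    p_hypergeometric = hypergeom_all_k(length(u), length(l), k)
  )
  if (!is.null(net)) {
    h <- hubs(net, top_fraction)$members
    fh <- hub_lrg_fraction(net, l, top_fraction)
    out$hub_count <- length(h)
    out$hub_top_fraction <- top_fraction
    out$hub_lrg_fraction <- fh
    out$p_hub_with_replacement <- prob_all_k(fh, k)
  }
  structure(out, class = "prior_report")
}

#' @export
print.prior_report <- function(x, ...) {
  cat(sprintf("<prior_report: f = %.6g (%d/%d), f^%d = %.6g, exact = %.6g>\n",
              x$f, x$lrg_count, x$universe_size, x$k,
              x$p_with_replacement, x$p_hypergeometric))
  if (!is.null(x$hub_lrg_fraction)) {
    cat(sprintf("  hub LRG fraction = %.4g over %d hubs; f_hub^%d = %.6g\n",
                x$hub_lrg_fraction, x$hub_count, x$k,
                x$p_hub_with_replacement))
  }
  invisible(x)
}
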