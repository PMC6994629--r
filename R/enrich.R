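#' One-sided Fisher (hypergeometric upper tail) for a gene-set term
#'
#' Overrepresentation semantics: the p-value is the probability of drawing
#' at least the observed overlap when `|query|` genes are sampled without
#' replacement from the background. The effective term is the term's
#' intersection with the background.
#'
#' @param query_genes query gene list (must be a subset of the background)
#' @param term_genes genes annotated to the term
#' @param background_genes the comparison universe
#' @return list: `overlap`, `term_size` (effective), `p`
#' @export
term_fisher <- function(query_genes, term_genes, background_genes) {
  if (length(background_genes) == 0L) stop2("background is empty")
  background_genes <- unique(background_genes)
  query_genes <- unique(query_genes)
  if (!all(query_genes %in% background_genes))
    stop2("query genes absent from background: ",
          paste(utils::head(setdiff(query_genes, background_genes), 3),
                collapse = ", "))
  term <- intersect(unique(term_genes), background_genes)
  k <- sum(query_genes %in% term)
  p <- stats::phyper(k - 1, m = length(term),
                     n = length(background_genes) - length(term),
                     k = length(query_genes), lower.tail = FALSE)
  list(overlap = k, term_size = length(term), p = p)
}

#' Rank-deviation combined score
#'
#' The product of the log p-value and the z-score of the deviation of the
#' term's rank from its expected rank under random queries:
#' `score = ln(p) * z_rank`. Terms that are both individually significant
#' and better-ranked than expected get large positive scores (ln p < 0 and
#' z < 0).
#'
#' @param p Fisher p-value in (0, 1]
#' @param z_rank rank-deviation z-score
#' @return the combined score
#' @export
combined_score <- function(p, z_rank) {
  if (any(p <= 0 | p > 1)) stop2("p must lie in (0, 1]")
  log(p) * z_rank
}

#' Rank-deviation z-scores for a set of terms
#'
#' Terms are ranked by Fisher p-value for the real query and for
#' `n_random_lists` random queries of the same size drawn without
#' replacement from the background. Each term's z is
#' `(observed_rank - mean(random ranks)) / sd(random ranks)`; a term whose
#' random ranks are constant gets z = 0. Negative z means the term ranks
#' better than expected.
#'
#' @param sets named list of term gene vectors
#' @param query_genes query gene list
#' @param background_genes comparison universe
#' @param n_random_lists number of random queries (>= 10), default 100
#' @param seed RNG seed (the estimate is a deterministic function of it)
#' @return named numeric vector of z-scores (one per term)
#' @export
rank_deviation_z <- function(sets, query_genes, background_genes,
                             n_random_lists = 100, seed = 1) {
  if (n_random_lists < 10) stop2("n_random_lists must be >= 10")
  set.seed(as.integer(seed %% .Machine$integer.max))
  term_p <- function(query) vapply(sets, function(tg)
    term_fisher(query, tg, background_genes)$p, numeric(1))
  obs_rank <- rank(term_p(query_genes), ties.method = "average")
  rand_ranks <- matrix(NA_real_, nrow = n_random_lists, ncol = length(sets))
  k <- length(unique(query_genes))
  for (r in seq_len(n_random_lists)) {
    rq <- sample(unique(background_genes), k)
    rand_ranks[r, ] <- rank(term_p(rq), ties.method = "average")
  }
  mu <- colMeans(rand_ranks)
  sdv <- apply(rand_ranks, 2L, stats::sd)
  z <- ifelse(sdv == 0, 0, (obs_rank - mu) / sdv)
  stats::setNames(z, names(sets))
}

#' Gene-set overrepresentation analysis
#'
#' For each term: hypergeometric upper-tail Fisher p, BH-adjusted p across
#' all terms (shared [bh_fdr()] implementation), rank-deviation z and the
#' combined score `ln(p) * z`.
#'
#' @param query_genes query gene list
#' @param sets named list of term gene vectors (see [read_gmt()])
#' @param background_genes comparison universe; defaults to the union of all
#'   term genes and the query
#' @param n_random_lists random queries for the rank null, default 100
#' @param seed RNG seed for the rank null
#' @return data.frame (`term`, `overlap_count`, `term_size`, `query_size`,
#'   `background_size`, `p`, `adjusted_p`, `z_rank`, `combined_score`)
#'   sorted by decreasing combined score
#' @export
run_enrichment <- function(query_genes, sets, background_genes = NULL,
                           n_random_lists = 100, seed = 1) {
  if (is.null(background_genes))
    background_genes <- unique(c(unlist(sets), query_genes))
  fish <- lapply(sets, term_fisher, query_genes = query_genes,
                 background_genes = background_genes)
  p <- vapply(fish, `[[`, numeric(1), "p")
  z <- rank_deviation_z(sets, query_genes, background_genes,
                        n_random_lists, seed)
  out <- data.frame(term = names(sets),
                    overlap_count = vapply(fish, `[[`, numeric(1), "overlap"),
                    term_size = vapply(fish, `[[`, numeric(1), "term_size"),
                    query_size = length(unique(query_genes)),
                    background_size = length(unique(background_genes)),
                    p = p,
                    adjusted_p = bh_fdr(p),
                    z_rank = z,
                    combined_score = combined_score(p, z),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$combined_score, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
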