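options(twaspleio.quiet = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- tiny object builders -------------------------------------------------

make_panel <- function(dosages, chrom = NULL, pos = NULL, ref = "A",
                       alt = "G") {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  variants <- data.frame(
    chrom = chrom %||% rep("chr1", m),
    pos = pos %||% (1000L * seq_len(m)),
    id = sprintf("v%03d", seq_len(m)),
    ref = rep_len(ref, m), alt = rep_len(alt, m),
    stringsAsFactors = FALSE)
  dosage_panel(variants, sprintf("s%03d", seq_len(nrow(dosages))), dosages)
}

make_weights <- function(gene, variant_id, weight, tissue = "tissueA",
                         effect_allele = "G", non_effect_allele = "A") {
  df <- data.frame(tissue = tissue, gene = gene, variant_id = variant_id,
                   effect_allele = rep_len(effect_allele, length(variant_id)),
                   non_effect_allele = rep_len(non_effect_allele,
                                               length(variant_id)),
                   weight = weight, stringsAsFactors = FALSE)
  class(df) <- c("weight_table", "data.frame")
  df
}

random_panel_and_weights <- function(n_samples, n_variants, n_genes,
                                     max_entries = 5) {
  D <- matrix(round(runif(n_samples * n_variants, 0, 2), 3),
              nrow = n_samples)
  panel <- make_panel(D)
  rows <- lapply(seq_len(n_genes), function(g) {
    k <- sample(min(max_entries, n_variants), 1)
    vi <- sample(n_variants, k)
    flip <- runif(k) < 0.3
    data.frame(tissue = "tissueA", gene = sprintf("g%03d", g),
               variant_id = panel$variants$id[vi],
               effect_allele = ifelse(flip, "A", "G"),
               non_effect_allele = ifelse(flip, "G", "A"),
               weight = rnorm(k), stringsAsFactors = FALSE)
  })
  w <- do.call(rbind, rows)
  class(w) <- c("weight_table", "data.frame")
  list(panel = panel, weights = w)
}

# ---- independent oracles --------------------------------------------------

# naive per-sample, per-entry imputation loop (independent of the matrix path)
naive_impute <- function(panel, weights, tissue) {
  w <- as.data.frame(weights)
  w <- w[w$tissue == tissue, , drop = FALSE]
  genes <- sort(unique(w$gene))
  out <- matrix(0, nrow = length(panel$samples), ncol = length(genes),
                dimnames = list(panel$samples, genes))
  keep_gene <- logical(length(genes))
  for (gi in seq_along(genes)) {
    entries <- w[w$gene == genes[gi], , drop = FALSE]
    for (e in seq_len(nrow(entries))) {
      vi <- match(entries$variant_id[e], panel$variants$id)
      if (is.na(vi)) next
      ref <- panel$variants$ref[vi]; alt <- panel$variants$alt[vi]
      d <- panel$dosages[, vi]
      if (entries$effect_allele[e] == alt && entries$non_effect_allele[e] == ref) {
        out[, gi] <- out[, gi] + entries$weight[e] * d
        keep_gene[gi] <- TRUE
      } else if (entries$effect_allele[e] == ref &&
                 entries$non_effect_allele[e] == alt) {
        out[, gi] <- out[, gi] + entries$weight[e] * (2 - d)
        keep_gene[gi] <- TRUE
      }
    }
  }
  out[, keep_gene, drop = FALSE]
}

# quadratic-time direct step-up definition of BH
bh_direct <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) p[ord[j]] * m / j, numeric(1))
    q_sorted[i] <- min(1, min(cand))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# exhaustive two-sided Fisher: sum point probabilities <= observed
fisher_two_sided_enum <- function(a, b, c_, d) {
  row1 <- a + b; col1 <- a + c_; n <- a + b + c_ + d
  if (n == 0) return(1)
  xs <- max(0, col1 - (n - row1)):min(row1, col1)
  probs <- dhyper(xs, col1, n - col1, row1)
  p_obs <- dhyper(a, col1, n - col1, row1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exhaustive one-sided (upper tail) hypergeometric
hyper_upper_enum <- function(overlap, term_size, bg_size, query_size) {
  xs <- overlap:min(term_size, query_size)
  sum(dhyper(xs, term_size, bg_size - term_size, query_size))
}

# exact two-sided Mann-Whitney by enumeration of all group assignments
mw_exact_enum <- function(x, y) {
  vals <- c(x, y)
  stopifnot(!any(duplicated(vals)))
  nx <- length(x); mn <- nx * length(y)
  u_of <- function(xi) sum(outer(xi, setdiff(vals, xi), ">"))
  u_obs <- sum(outer(x, y, ">"))
  splits <- utils::combn(length(vals), nx)
  us <- apply(splits, 2, function(ii) u_of(vals[ii]))
  u_low <- min(u_obs, mn - u_obs)
  min(1, mean(us <= u_low) + mean(us >= mn - u_low))
}

# brute-force interval union via per-unit coverage. Positions are doubled so
# that intervals sharing a bp ([100,200] & [200,300]) stay connected while
# merely adjacent ones ([100,200] & [201,300]) stay apart.
merge_bruteforce <- function(loci) {
  out <- list()
  for (cc in sort(unique(loci$chrom))) {
    sub <- loci[loci$chrom == cc, , drop = FALSE]
    covered <- logical(2L * max(sub$end))
    for (i in seq_len(nrow(sub)))
      covered[(2L * sub$start[i]):(2L * sub$end[i])] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    out[[cc]] <- data.frame(chrom = cc, start = starts[keep] %/% 2L,
                            end = ends[keep] %/% 2L, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# closed-form OLS via normal equations (independent of the qr/FWL path)
ols_oracle <- function(y, G_col, X) {
  Z <- cbind(X, g = G_col)
  XtX <- crossprod(Z)
  beta_all <- solve(XtX, crossprod(Z, y))
  resid <- y - Z %*% beta_all
  df <- length(y) - ncol(Z)
  sigma2 <- sum(resid^2) / df
  covb <- sigma2 * solve(XtX)
  j <- ncol(Z)
  beta <- beta_all[j]; se <- sqrt(covb[j, j])
  list(beta = beta, se = se, p = 2 * pt(-abs(beta / se), df))
}
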