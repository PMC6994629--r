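test_that("LD r2 is squared Pearson correlation of dosage vectors", {
  panel <- make_panel(matrix(c(0, 1, 2,   2, 1, 0,   1, 1, 1), nrow = 3))
  expect_equal(ld_r2(panel, "v001", "v001"), 1.0)
  expect_equal(ld_r2(panel, "v001", "v002"), 1.0)  # perfect anti-correlation
  expect_equal(ld_r2(panel, "v001", "v003"), 0)    # constant -> 0
  p4 <- make_panel(matrix(c(0, 0, 1, 1,  0, 1, 0, 1), nrow = 4))
  expect_equal(ld_r2(p4, "v001", "v002"), 0)       # orthogonal
  expect_error(ld_r2(panel, "v001", "nope"), "absent")
})

test_that("R2 loci span the min/max of linked variants, strictly above 0.5", {
  # construct dosages with known correlations to the lead (column 2)
  lead <- c(0, 0, 1, 1, 2, 2)
  linked <- lead                      # r2 = 1
  partial <- c(0, 0, 1, 2, 1, 2)     # r2 < 1 but > 0.5
  unlinked <- c(2, 0, 1, 2, 0, 1)
  stopifnot(cor(lead, partial)^2 > 0.5, cor(lead, unlinked)^2 <= 0.5)
  panel <- make_panel(cbind(linked, lead, unlinked, partial),
                      pos = c(8000L, 10000L, 12000L, 15000L))
  loc <- build_r2_locus(panel, "v002")
  expect_equal(c(loc$start, loc$end), c(8000L, 15000L))

  # nothing linked: single-position locus at the lead
  p1 <- make_panel(cbind(lead, unlinked), pos = c(100L, 200L))
  loc1 <- build_r2_locus(p1, "v001")
  expect_equal(c(loc1$start, loc1$end), c(100L, 100L))

  # r2 exactly 0.5 is NOT included (strict >)
  a <- c(0, 0, 1, 1)
  b <- c(0, 1, 1, 2)
  expect_equal(cor(a, b)^2, 0.5)
  p_half <- make_panel(cbind(a, b), pos = c(100L, 900L))
  loc_half <- build_r2_locus(p_half, "v001")
  expect_equal(c(loc_half$start, loc_half$end), c(100L, 100L))

  # a lead absent from the panel falls back to its own coordinate
  fallback <- build_r2_locus(p1, "ghost", lead_chrom = "chr9",
                             lead_pos = 777L)
  expect_equal(c(fallback$chrom, fallback$start, fallback$end),
               c("chr9", 777L, 777L))
  expect_error(build_r2_locus(p1, "ghost"), "absent")
})

test_that("locus merging takes the transitive union with trait labels", {
  loci <- locus_table(rep("chr1", 3), c(100, 150, 400), c(200, 300, 500),
                      traits = c("AMD", "migraine", "AMD"))
  m <- merge_loci(loci)
  expect_equal(m$start, c(100L, 400L))
  expect_equal(m$end, c(300L, 500L))
  expect_equal(m$traits[1], "AMD;migraine")

  # inclusive coordinates: [100,200] and [200,300] share bp 200
  touching <- locus_table(c("chr1", "chr1"), c(100, 200), c(200, 300))
  expect_equal(nrow(merge_loci(touching)), 1L)
  # but [100,200] and [201,300] do not
  apart <- locus_table(c("chr1", "chr1"), c(100, 201), c(200, 300))
  expect_equal(nrow(merge_loci(apart)), 2L)
})

test_that("locus merging equals a per-bp brute-force union on random instances", {
  set.seed(303)
  for (rep in 1:60) {
    n <- sample(1:12, 1)
    start <- sample(1:9000, n, replace = TRUE)
    loci <- locus_table(sample(c("chr1", "chr2"), n, replace = TRUE),
                        start, start + sample(0:800, n, replace = TRUE))
    got <- merge_loci(loci)
    want <- merge_bruteforce(loci)
    expect_equal(got$chrom, want$chrom)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("total merged length is invariant to order and interval splitting", {
  set.seed(99)
  start <- sample(1:5000, 8)
  loci <- locus_table(rep("chr1", 8), start, start + sample(50:500, 8))
  total <- function(l) sum(l$end - l$start + 1)
  base <- total(merge_loci(loci))
  shuffled <- loci[sample(nrow(loci)), ]
  expect_equal(total(merge_loci(locus_table(shuffled$chrom, shuffled$start,
                                            shuffled$end))), base)
  # split the first interval into two covering pieces
  l1 <- loci[1, ]
  mid <- l1$start + (l1$end - l1$start) %/% 2
  rest <- loci[-1, ]
  split_loci <- locus_table(c(rest$chrom, "chr1", "chr1"),
                            c(rest$start, l1$start, mid),
                            c(rest$end, mid, l1$end))
  expect_equal(total(merge_loci(split_loci)), base)
})

test_that("locus extension pads by the window, clamps at 1 and re-merges", {
  loci <- locus_table("chr1", 2000000, 2100000)
  e <- extend_loci(loci, 1e6)
  expect_equal(c(e$start, e$end), c(1000000L, 3100000L))

  near_origin <- locus_table("chr1", 500000, 600000)
  expect_equal(extend_loci(near_origin, 1e6)$start, 1L)

  # two loci 1.5 Mb apart merge after 1 Mb extension
  pair <- locus_table(c("chr1", "chr1"), c(1000000, 2600000),
                      c(1100000, 2700000))
  expect_equal(nrow(extend_loci(pair, 1e6)), 1L)
})

test_that("genes are assigned to categories by positional overlap", {
  loci <- locus_table(c("chr1", "chr1"), c(100, 320), c(300, 380),
                      categories = c("AMD", "neuro"))
  ann <- data.frame(gene = c("gA", "gB", "gC"),
                    chrom = "chr1",
                    start = c(250L, 301L, 290L), end = c(350L, 310L, 400L))
  ot <- overlap_genes(loci, ann)
  expect_true(ot$pleiotropic[ot$gene == "gA"])   # hits both loci
  expect_false(ot$in_any_locus[ot$gene == "gB"]) # falls in the gap
  expect_true(ot$pleiotropic[ot$gene == "gC"])
  # boundary: gene starting 1 bp after a locus end is not assigned
  ann2 <- data.frame(gene = "gD", chrom = "chr1", start = 301L, end = 310L)
  expect_false(overlap_genes(loci[1, ], ann2)$in_any_locus)
  # pleiotropic implies in_any_locus
  expect_true(all(!ot$pleiotropic | ot$in_any_locus))
})

test_that("category enrichment builds the 2x2 table and two-sided Fisher p", {
  mk_overlap <- function(genes, with_cat) {
    data.frame(gene = genes,
               categories = ifelse(with_cat, "catX", "."),
               n_categories = as.integer(with_cat),
               in_any_locus = with_cat, pleiotropic = FALSE)
  }
  # [[0,10],[0,90]]: no gene overlaps -> p = 1
  genes <- sprintf("g%03d", 1:100)
  e0 <- category_enrichment(genes[1:10], genes,
                            mk_overlap(genes, rep(FALSE, 100)), "catX")
  expect_equal(e0$p, 1.0)
  expect_equal(unname(e0$table), c(0, 10, 0, 90))
  # [[1,1],[1,1]] -> p = 1 (all tables equally probable)
  g4 <- genes[1:4]
  e1 <- category_enrichment(g4[1:2], g4,
                            mk_overlap(g4, c(TRUE, FALSE, TRUE, FALSE)),
                            "catX")
  expect_equal(e1$p, 1.0)
  # [[2,0],[0,2]] -> p = 1/3 by exhaustive enumeration
  e2 <- category_enrichment(g4[1:2], g4,
                            mk_overlap(g4, c(TRUE, TRUE, FALSE, FALSE)),
                            "catX")
  expect_equal(e2$p, 1 / 3, tolerance = 1e-12)
  expect_error(category_enrichment(c("zz"), genes,
                                   mk_overlap(genes, rep(FALSE, 100)),
                                   "catX"), "subset")
})

test_that("two-sided Fisher matches exhaustive enumeration for small tables", {
  set.seed(404)
  for (rep in 1:40) {
    tot <- sample(4:60, 1)
    a <- sample(0:tot, 1); rest <- tot - a
    b <- sample(0:rest, 1); rest <- rest - b
    c_ <- sample(0:rest, 1); d <- rest - c_
    got <- fisher.test(matrix(c(a, c_, b, d), 2))$p.value
    want <- fisher_two_sided_enum(a, b, c_, d)
    expect_equal(got, want, tolerance = 1e-7)
  }
})

test_that("tissue-count comparison uses the exact Mann-Whitney null", {
  gs <- data.frame(gene = sprintf("g%d", 1:6),
                   n_significant_tissues = c(1L, 2L, 3L, 4L, 5L, 6L))
  ot <- data.frame(gene = gs$gene,
                   in_any_locus = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  res <- tissue_count_comparison(gs, ot)
  expect_equal(res$p, 0.1)                    # C(6,3)=20 arrangements, U=0
  expect_equal(res$p, mw_exact_enum(c(1, 2, 3), c(4, 5, 6)))

  # swapping the group labels leaves p unchanged
  ot_swap <- ot; ot_swap$in_any_locus <- !ot$in_any_locus
  expect_equal(tissue_count_comparison(gs, ot_swap)$p, res$p)

  # identical multisets give p = 1
  gs2 <- data.frame(gene = sprintf("g%d", 1:4),
                    n_significant_tissues = c(1L, 2L, 1L, 2L))
  ot2 <- data.frame(gene = gs2$gene,
                    in_any_locus = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(tissue_count_comparison(gs2, ot2)$p, 1.0)

  # an empty group is an error
  ot3 <- data.frame(gene = gs$gene, in_any_locus = rep(TRUE, 6))
  expect_error(tissue_count_comparison(gs, ot3), "non-empty")
})

test_that("exact Mann-Whitney agrees with enumeration on random tie-free data", {
  set.seed(505)
  for (rep in 1:15) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    vals <- sample(1:100, nx + ny)
    x <- vals[1:nx]; y <- vals[-(1:nx)]
    got <- suppressWarnings(wilcox.test(x, y, exact = TRUE))$p.value
    expect_equal(got, mw_exact_enum(x, y), tolerance = 1e-12)
  }
})
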