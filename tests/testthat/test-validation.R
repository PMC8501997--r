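toy_genes <- function() {
  data.frame(gene_id = c("gA", "gB"), chrom = c("chr1", "chr1"),
             start = c(100000, 300000), end = c(110000, 320000),
             strand = c("+", "-"),
             tss = c(100000, 320000), tts = c(110000, 300000),
             stringsAsFactors = FALSE)
}

toy_rems <- function() {
  data.frame(chrom = "chr1",
             start = c(95000, 112000, 330000),
             end = c(95500, 112800, 330400),
             gene_id = c("gA", "gA", "gB"),
             stringsAsFactors = FALSE)
}

test_that("background sets match counts and lengths per gene", {
  sets <- generate_background(toy_rems(), toy_genes(), rate = 7,
                              n_sets = 10, seed = 5)
  expect_length(sets, 10)
  for (bg in sets) {
    expect_equal(nrow(bg), 3L)
    expect_equal(sort(bg$end - bg$start),
                 sort(toy_rems()$end - toy_rems()$start))
    expect_equal(table(bg$gene_id), table(toy_rems()$gene_id))
    expect_true(all(bg$start >= 0))
  }
  # distinct sets differ; the whole collection reproduces under one seed
  expect_false(identical(sets[[1]]$start, sets[[2]]$start))
  again <- generate_background(toy_rems(), toy_genes(), rate = 7,
                               n_sets = 10, seed = 5)
  expect_identical(sets, again)
})

test_that("background distances follow the exponential placement model", {
  genes <- toy_genes()[1, ]
  genes$strand <- "+"
  rems <- data.frame(chrom = "chr1", start = rep(112000, 500),
                     end = rep(112100, 500), gene_id = "gA",
                     stringsAsFactors = FALSE)
  sets <- generate_background(rems, genes, rate = 7, n_sets = 20, seed = 2)
  span <- (genes$end - genes$start) + 50000
  d <- unlist(lapply(sets, function(bg) (bg$start - genes$tss) / span))
  # all originals sit downstream of the TSS (rounding can give exactly 0)
  expect_true(all(d >= 0))
  expect_equal(mean(d), 1 / 7, tolerance = 0.05)
})

test_that("gene-matched overlap counting honours gene identity and uniqueness", {
  rems <- data.frame(chrom = "chr1", start = 100, end = 200, gene_id = "gA")
  ann_same <- data.frame(chrom = "chr1", start = 150, end = 160, gene_id = "gA")
  ann_other <- data.frame(chrom = "chr1", start = 150, end = 160, gene_id = "gB")
  expect_equal(count_gene_matched_overlaps(rems, ann_same), 1L)
  expect_equal(count_gene_matched_overlaps(rems, ann_other), 0L)
  # two same-gene annotations on one element still count once
  two <- rbind(ann_same, data.frame(chrom = "chr1", start = 190, end = 195,
                                    gene_id = "gA"))
  expect_equal(count_gene_matched_overlaps(rems, two), 1L)
  # half-open arithmetic: touching intervals do not overlap
  touch <- data.frame(chrom = "chr1", start = 200, end = 210, gene_id = "gA")
  expect_equal(count_gene_matched_overlaps(rems, touch), 0L)
  # self-consistency: the elements support themselves
  r3 <- toy_rems()
  expect_equal(count_gene_matched_overlaps(r3, r3), nrow(r3))
})

test_that("interaction support requires one anchor on the element, one on the gene body", {
  genes <- toy_genes()
  rems <- data.frame(chrom = "chr1", start = 95000, end = 95500,
                     gene_id = "gA", stringsAsFactors = FALSE)
  hit <- data.frame(chrom1 = "chr1", start1 = 95100, end1 = 95200,
                    chrom2 = "chr1", start2 = 105000, end2 = 105800)
  expect_equal(count_interaction_support(rems, hit, genes), 1L)
  # swapped anchor orientation counts too
  swapped <- hit[, c(4:6, 1:3)]
  names(swapped) <- names(hit)
  expect_equal(count_interaction_support(rems, swapped, genes), 1L)
  # both anchors inside the gene body: no element anchor, no support
  inside <- data.frame(chrom1 = "chr1", start1 = 101000, end1 = 101500,
                       chrom2 = "chr1", start2 = 105000, end2 = 105800)
  expect_equal(count_interaction_support(rems, inside, genes), 0L)
  # an intragenic element may use the surrounding gene body as second anchor
  intra <- data.frame(chrom = "chr1", start = 102000, end = 102300,
                      gene_id = "gA", stringsAsFactors = FALSE)
  span <- data.frame(chrom1 = "chr1", start1 = 102100, end1 = 102200,
                     chrom2 = "chr1", start2 = 108000, end2 = 108500)
  expect_equal(count_interaction_support(intra, span, genes), 1L)
  # duplicated interaction records do not inflate the unique-element count
  expect_equal(count_interaction_support(rems, rbind(hit, hit), genes), 1L)
})

test_that("the OE ratio is the observed count over the mean expectation", {
  expect_equal(oe_ratio(5, rep(5, 10)), 1)
  expect_equal(oe_ratio(10, c(4, 6, 5, 5, 5, 5, 5, 5, 5, 5)), 2)
  expect_warning(na <- oe_ratio(3, rep(0, 10)), "not computable")
  expect_true(is.na(na))
})

test_that("activity scores combine coefficient and abundance linearly", {
  rems <- data.frame(chrom = "chr1", start = c(0, 100), end = c(50, 150),
                     rem_id = c("r1", "r2"), score = 0, strand = ".",
                     gene_id = "g", ols_coefficient = c(0.5, -2),
                     ols_pvalue = 0.01, correlation = 0.5,
                     correlation_pvalue = 0.01, stringsAsFactors = FALSE)
  track <- data.frame(position = 0:149, value = c(rep(0.08, 50), rep(0, 50),
                                                  rep(0.1, 50)))
  ranked <- rem_activity_score(rems, track)
  expect_equal(ranked$rem_id, c("r2", "r1"))
  expect_equal(ranked$score[ranked$rem_id == "r1"], 0.5 * 4, tolerance = 1e-9)
  expect_equal(ranked$score[ranked$rem_id == "r2"], -2 * 5, tolerance = 1e-9)
  # doubling the track doubles scores without reordering
  track2 <- transform(track, value = 2 * value)
  ranked2 <- rem_activity_score(rems, track2)
  expect_equal(ranked2$rem_id, ranked$rem_id)
  expect_equal(ranked2$score, 2 * ranked$score, tolerance = 1e-9)
  # zero signal nullifies any coefficient
  zero <- rem_activity_score(rems, transform(track, value = 0))
  expect_equal(zero$score, c(0, 0))
})
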