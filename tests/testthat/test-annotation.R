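## one forward gene on chr1: body [10000,20000), TSS at 10000,
## exon [10000,10200); promoter window = TSS - 2 kb .. TSS + 1 kb
toyGenes <- function() {
  genes <- gr0("chr1", 10000, 20000, gene_id = "g1")
  strand(genes) <- "+"
  exons <- gr0("chr1", 10000, 10200, gene_id = "g1")
  list(genes = genes, exons = exons)
}

test_that("context classification follows the exonic > promoter > intronic precedence", {
  gm <- toyGenes()
  pm <- gr0("chr1", c(
    10195,   # 5 bp of exon overlap -> exonic
    9000,    # 1 kb inside the promoter window, no exon -> promoter
    15000,   # gene body only -> intronic
    500000   # nowhere near the gene -> intergenic
  ), c(10495, 9300, 15300, 500300))
  ctx <- classifyContext(pm, gm$genes, gm$exons)
  expect_equal(as.character(ctx),
               c("exonic", "promoter", "intronic", "intergenic"))
})

test_that("exon and promoter overlaps below their minima fall through", {
  gm <- toyGenes()
  # 4 bp exon overlap is not exonic; the same span overlaps the promoter
  ctx4 <- classifyContext(gr0("chr1", 10196, 10496), gm$genes, gm$exons)
  expect_equal(as.character(ctx4), "promoter")
  # 49 bp promoter overlap is not promoter: falls to intronic here
  # (promoter window ends at TSS + 1 kb, 0-based 11000)
  ctx49 <- classifyContext(gr0("chr1", 10951, 11300), gm$genes, gm$exons)
  expect_equal(as.character(ctx49), "intronic")
  # 50 bp is enough
  ctx50 <- classifyContext(gr0("chr1", 10950, 11300), gm$genes, gm$exons)
  expect_equal(as.character(ctx50), "promoter")
})

test_that("a chromosome without genes is intergenic and contexts partition", {
  gm <- toyGenes()
  lonely <- suppressWarnings(
    classifyContext(gr0("chr7", 100, 400), gm$genes, gm$exons))
  expect_equal(as.character(lonely), "intergenic")
  set.seed(8)
  s <- sample(0:6e4, 200)
  pm <- gr0("chr1", s, s + 300)
  ctx <- classifyContext(pm, gm$genes, gm$exons)
  expect_false(anyNA(ctx))
  expect_equal(sum(table(ctx)), 200)  # exactly one label each
})

test_that("promoter windows are strand-aware", {
  genes <- gr0("chr1", 10000, 20000, gene_id = "gm")
  strand(genes) <- "-"
  exons <- GRanges()
  # minus-strand TSS is at the right edge; upstream extends rightwards
  up <- classifyContext(gr0("chr1", 20100, 20400), genes, exons)
  expect_equal(as.character(up), "promoter")
  down <- classifyContext(gr0("chr1", 8050, 8350), genes, exons)
  expect_equal(as.character(down), "intergenic")
})

test_that("cCRE assignment honours the 50 bp slop and 1 bp overlap rule", {
  ccre <- gr0("chr1", 1000, 1300, label = "distal-enhancer-like")
  # pMEI ending 50 bp before the cCRE: slop makes them abut -> no overlap
  expect_length(assignCcre(gr0("chr1", 600, 950), ccre)[[1]], 0)
  # 49 bp gap: 1 bp of overlap with the slopped cCRE -> labelled
  expect_equal(assignCcre(gr0("chr1", 600, 951), ccre)[[1]],
               "distal-enhancer-like")
  inside <- gr0("chr1", 1100, 1200)
  prom <- gr0("chr1", 1100, 1250, label = "promoter-like")
  both <- suppressWarnings(c(ccre, prom))
  expect_setequal(assignCcre(inside, both)[[1]],
                  c("distal-enhancer-like", "promoter-like"))
  expect_length(assignCcre(inside, GRanges())[[1]], 0)
})

test_that("enlarging the slop never removes a cCRE label", {
  set.seed(21)
  s <- sample(0:5e4, 80)
  pm <- gr0("chr1", s, s + 300)
  cs <- sample(0:5e4, 20)
  ccre <- gr0("chr1", cs, cs + 200,
              label = sample(c("promoter-like", "distal-enhancer-like"),
                             20, replace = TRUE))
  prev <- assignCcre(pm, ccre, slop = 0)
  for (slop in c(10, 50, 200)) {
    cur <- assignCcre(pm, ccre, slop = slop)
    for (i in seq_along(pm))
      expect_true(all(prev[[i]] %in% cur[[i]]))
    prev <- cur
  }
})

test_that("annotatePmeis combines context, nearest gene and cCRE labels", {
  gm <- toyGenes()
  pm <- teGr("chr1", c(9000, 30000), c(9300, 30300), "AluYa5")
  ccre <- gr0("chr1", 30100, 30400, label = "proximal-enhancer-like")
  ann <- annotatePmeis(pm, gm$genes, gm$exons, ccre)
  expect_equal(as.character(ann$context), c("promoter", "intergenic"))
  expect_equal(ann$nearest_gene, c("g1", "g1"))
  expect_equal(ann$distance[1], 700)  # pMEI end 9300 to TSS at 0-based 10000
  expect_equal(ann$ccre_labels[[2]], "proximal-enhancer-like")
})
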