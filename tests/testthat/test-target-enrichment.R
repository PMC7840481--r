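test_that("gene scores follow the signed -log10 p convention", {
  de <- data.frame(mirna_id = "m1", log2FC = 1, p_adj = 0.01)
  tg <- data.frame(mirna_id = "m1", gene_id = "G1")
  gs <- gene_scores(de, tg)
  expect_equal(gs$score, -2)  # up-regulated miRNA represses the target
  # two miRNAs with equal and opposite weights cancel
  de2 <- data.frame(mirna_id = c("m1", "m2"), log2FC = c(1, -1),
                    p_adj = c(0.01, 0.01))
  tg2 <- data.frame(mirna_id = c("m1", "m2"), gene_id = "G1")
  expect_equal(gene_scores(de2, tg2)$score, 0)
  expect_equal(gene_scores(de2, tg2)$n_supporting_mirnas, 2L)
})

test_that("aggregation matches a brute-force per-gene summation oracle", {
  set.seed(3)
  mirnas <- paste0("m", 1:8)
  de <- data.frame(mirna_id = mirnas,
                   log2FC = rnorm(8), p_adj = runif(8, 1e-4, 0.9))
  tg <- data.frame(
    mirna_id = sample(mirnas, 30, replace = TRUE),
    gene_id = sample(paste0("G", 1:10), 30, replace = TRUE)
  )
  tg <- rbind(tg, tg[1:5, ])  # duplicated evidence must merge
  gs <- gene_scores(de, tg)
  utg <- unique(tg)
  for (g in gs$gene_id) {
    mids <- utg$mirna_id[utg$gene_id == g]
    w <- sapply(mids, function(m) {
      row <- de[de$mirna_id == m, ]
      -sign(row$log2FC) * (-log10(row$p_adj))
    })
    expect_equal(gs$score[gs$gene_id == g], sum(w))
    expect_equal(gs$n_supporting_mirnas[gs$gene_id == g], length(mids))
  }
  # genes with no targeting miRNA are absent
  expect_true(all(gs$gene_id %in% tg$gene_id))
  # zero p-values are capped, not infinite
  expect_warning(
    capped <- gene_scores(
      data.frame(mirna_id = "m1", log2FC = -1, p_adj = 0),
      data.frame(mirna_id = "m1", gene_id = "G1")),
    "capped")
  expect_true(is.finite(capped$score))
})

test_that("logistic enrichment matches the IRLS oracle on a small instance", {
  set.seed(5)
  scores <- data.frame(gene_id = paste0("G", 1:20),
                       score = c(rnorm(5, 2), rnorm(15, 0)),
                       n_supporting_mirnas = 1L)
  sets <- list(s1 = paste0("G", 1:5))
  got <- logistic_gsa(scores, sets)
  orc <- oracle_logistic(as.numeric(scores$gene_id %in% sets$s1),
                         scores$score)
  expect_false(got$penalized)
  expect_equal(got$coefficient, orc$coefficient, tolerance = 1e-6)
  expect_equal(got$p, orc$p, tolerance = 1e-6)
})

test_that("null scores are not retained; planted enrichment is", {
  set.seed(7)
  genes <- paste0("G", 1:200)
  # null: scores independent of membership
  null_scores <- data.frame(gene_id = genes, score = rnorm(200),
                            n_supporting_mirnas = 1L)
  sets <- c(lapply(1:5, function(i) sample(genes, 20)),
            list(planted = paste0("G", 1:20)))
  names(sets)[1:5] <- paste0("null", 1:5)
  planted_scores <- null_scores
  planted_scores$score[1:20] <- planted_scores$score[1:20] + 3
  null_res <- logistic_gsa(null_scores, sets["null1"])
  expect_false(null_res$retained)
  res <- logistic_gsa(planted_scores, sets)
  pl <- res[res$set_id == "planted", ]
  expect_gt(pl$coefficient, 0.5)
  expect_lt(pl$p_adj, 0.05)
  expect_true(pl$retained)
  # retention is a pure function of the reported columns
  expect_identical(res$retained,
                   !is.na(res$p) & res$p_adj < 0.05 &
                     abs(res$coefficient) > 0.5 &
                     res$n_target_genes_in_set >= 2)
})

test_that("sets below two scored members are untested", {
  scores <- data.frame(gene_id = paste0("G", 1:10), score = rnorm(10),
                       n_supporting_mirnas = 1L)
  res <- logistic_gsa(scores, list(tiny = "G1", off = c("X1", "X2")))
  expect_true(all(is.na(res$p)))
  expect_true(all(!res$retained))
})

test_that("doubling scores halves the slope and roughly keeps the p-value", {
  set.seed(9)
  scores <- data.frame(gene_id = paste0("G", 1:60),
                       score = c(rnorm(15, 1.5), rnorm(45)),
                       n_supporting_mirnas = 1L)
  sets <- list(s = paste0("G", 1:15))
  a <- logistic_gsa(scores, sets)
  scores2 <- scores; scores2$score <- scores2$score * 2
  b <- logistic_gsa(scores2, sets)
  expect_equal(b$coefficient, a$coefficient / 2, tolerance = 1e-6)
  expect_equal(b$p, a$p, tolerance = 1e-6)
})

test_that("direction-split enrichment selects miRNAs by fold-change sign", {
  set.seed(11)
  de <- data.frame(mirna_id = paste0("m", 1:6),
                   log2FC = c(1, 2, 0.5, -1, -2, -0.5),
                   p_adj = rep(0.01, 6))
  tg <- expand.grid(mirna_id = paste0("m", 1:6),
                    gene_id = paste0("G", 1:8),
                    stringsAsFactors = FALSE)
  tg <- tg[runif(nrow(tg)) < 0.5, ]
  sets <- list(s = paste0("G", 1:4))
  pos <- enrich_targets(de, tg, sets, direction = "positive")
  neg <- enrich_targets(de, tg, sets, direction = "negative")
  expect_s3_class(pos, "data.frame")
  expect_false(identical(pos$coefficient, neg$coefficient))
  expect_error(enrich_targets(de[de$log2FC > 0, ], tg, sets,
                              direction = "negative"), "direction")
})

test_that("the GMT reader round-trips and matches fgsea's parser", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tG1\tG2\tG3",
               "setB\tanother\tG2\tG4"), gmt)
  sets <- read_gmt(gmt)
  expect_equal(sets, list(setA = c("G1", "G2", "G3"),
                          setB = c("G2", "G4")))
  ref <- fgsea::gmtPathways(gmt)
  expect_equal(sets[names(ref)], lapply(ref, unname))
})
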