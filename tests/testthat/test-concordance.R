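test_that("orient takes reciprocals, swaps directions, and is an involution", {
  de <- fake_de(gene = c("pos", "neg", "flat"),
                fc = c(0.5, 2, 1), fdr = c(0.01, 0.02, 0.9),
                numerator = "Cyc", denominator = "Veh")
  fl <- orient(de, flip = TRUE)
  expect_equal(fl$fc, c(2, 0.5, 1))
  expect_equal(fl$direction, c("up", "down", "flat"))
  expect_equal(fl$p, de$p)     # p and fdr untouched
  expect_equal(fl$fdr, de$fdr)
  expect_equal(attr(fl, "numerator"), "Veh")
  expect_equal(attr(fl, "denominator"), "Cyc")
  twice <- orient(fl, flip = TRUE)
  expect_equal(tibble::as_tibble(twice), tibble::as_tibble(de), tolerance = 1e-15)
  expect_identical(orient(de, flip = FALSE), de)
})

test_that("a positively regulated gene measured as Cyc/Veh < 1 flips to Veh/Cyc > 1", {
  de <- fake_de("Gli1", fc = 1 / 1.61, fdr = 0.1,
                numerator = "Cyc", denominator = "Veh")
  fl <- orient(de, flip = TRUE)
  expect_equal(fl$fc, 1.61, tolerance = 1e-12)
  expect_equal(fl$direction, "up")
})

test_that("intersect_common is direction-blind set intersection, sorted", {
  sig_a <- tibble::tibble(gene = c("a", "b", "c"),
                          direction = c("up", "up", "down"))
  sig_b <- tibble::tibble(gene = c("b", "c", "d"),
                          direction = c("down", "down", "up"))
  expect_equal(intersect_common(sig_a, sig_b), c("b", "c"))
  expect_equal(intersect_common(sig_a, tibble::tibble(gene = character(0),
                                                      direction = character(0))),
               character(0))
  expect_equal(intersect_common(sig_a, sig_a), c("a", "b", "c"))
})

test_that("concordance classification follows the sign rule on published examples", {
  vit <- fake_de(gene = c("Gli1", "Gas1", "Disc"),
                 fc = c(25.62, 0.2610966, 2.0),
                 fdr = c(0.000009, 0.000085, 0.001))
  viv <- fake_de(gene = c("Gli1", "Gas1", "Disc"),
                 fc = c(1.61, 0.8547009, 0.8),
                 fdr = c(0.104969, 0.749637, 0.5))
  cls <- classify_concordance(c("Gli1", "Gas1", "Disc"), vit, viv)
  expect_equal(cls$klass[cls$gene == "Gli1"], "concordant_positive")
  expect_equal(cls$klass[cls$gene == "Gas1"], "concordant_negative")
  expect_equal(cls$klass[cls$gene == "Disc"], "discordant")
  # discordant genes are retained, never dropped
  expect_equal(nrow(cls), 3L)
  # input order of the common list does not matter
  cls2 <- classify_concordance(c("Disc", "Gas1", "Gli1"), vit, viv)
  expect_equal(cls, cls2)
  expect_error(classify_concordance(c("Gli1", "Missing"), vit, viv), "missing")
})

test_that("classification partitions the common genes on every simulated run", {
  for (seed in 1:5) {
    res <- run_pipeline(pipeline_config(
      sim = sim_config(n_genes = 800, frac_positive = 0.05,
                       frac_negative = 0.05, seed = seed)))
    g <- glance(res$concordance)
    expect_equal(g$n_concordant_up + g$n_concordant_down + g$n_discordant,
                 g$n_common)
    expect_equal(g$n_common, length(res$common))
  }
})

test_that("rank sums follow fold-change ranks with fdr and name tie-breaks", {
  genes <- classify_concordance(
    c("A", "B", "C"),
    fake_de(c("A", "B", "C"), fc = c(10, 5, 2), fdr = c(1e-5, 1e-3, 1e-2)),
    fake_de(c("A", "B", "C"), fc = c(1.5, 1.8, 1.2), fdr = c(0.3, 0.3, 0.3)))
  rk <- rank_concordant(genes)
  expect_equal(rk$gene, c("A", "B", "C"))    # A before B: equal rank sum, smaller fdr
  expect_equal(rk$rank_sum, c(3, 3, 6))
  expect_equal(rk$rank, 1:3)

  # single gene: both ranks are 1
  one <- classify_concordance("solo",
    fake_de("solo", 2, 0.01), fake_de("solo", 1.3, 0.2))
  expect_equal(rank_concordant(one)$rank_sum, 2)

  # identical fold changes in both arms share average ranks: 1.5 + 1.5
  tie <- classify_concordance(c("t1", "t2"),
    fake_de(c("t1", "t2"), fc = c(3, 3), fdr = c(0.01, 0.01)),
    fake_de(c("t1", "t2"), fc = c(1.4, 1.4), fdr = c(0.2, 0.2)))
  expect_equal(rank_concordant(tie)$rank_sum, c(3, 3))

  # negative class: rank 1 = smallest fold change (strongest repression)
  neg <- classify_concordance(c("Edn1", "Mild"),
    fake_de(c("Edn1", "Mild"), fc = c(0.26, 0.7), fdr = c(1e-4, 1e-3)),
    fake_de(c("Edn1", "Mild"), fc = c(0.68, 0.9), fdr = c(0.2, 0.3)))
  rkn <- rank_concordant(neg)
  expect_equal(rkn$gene[1], "Edn1")
  expect_equal(rkn$rank_sum, c(2, 4))

  # mixed sign classes are rejected; top_k truncates
  mixed <- dplyr::bind_rows(genes, neg)
  expect_error(rank_concordant(mixed), "one concordant sign class")
  expect_equal(nrow(rank_concordant(genes, top_k = 2)), 2L)
})

test_that("rank-sum ordering is invariant under strictly monotone fold-change transforms", {
  set.seed(31)
  fc_v <- 2^runif(12, 0.1, 4)
  fc_w <- 2^runif(12, 0.1, 2)
  genes <- classify_concordance(
    sprintf("g%02d", 1:12),
    fake_de(sprintf("g%02d", 1:12), fc = fc_v, fdr = runif(12, 0, 0.01)),
    fake_de(sprintf("g%02d", 1:12), fc = fc_w, fdr = runif(12, 0, 0.7)))
  rk1 <- rank_concordant(genes)
  # strictly increasing transform of both fold-change columns
  genes2 <- genes
  genes2$fc_vitro <- genes$fc_vitro^1.7
  genes2$fc_vivo <- 1 + log(genes$fc_vivo)
  rk2 <- rank_concordant(genes2)
  expect_equal(rk2$gene, rk1$gene)
  expect_equal(rk2$rank_sum, rk1$rank_sum)
})
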