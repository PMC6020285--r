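test_that("identical seeds give bit-identical simulations, different seeds differ", {
  cfg <- sim_config(n_genes = 200, seed = 42)
  s1 <- simulate_pair(cfg)
  s2 <- simulate_pair(cfg)
  expect_identical(s1$vitro, s2$vitro)
  expect_identical(s1$vivo, s2$vivo)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_pair(sim_config(n_genes = 200, seed = 43))
  expect_false(identical(s1$vitro, s3$vitro))
})

test_that("null model with zero noise realizes fold change exactly 1", {
  cfg <- sim_config(n_genes = 50, frac_positive = 0, frac_negative = 0,
                    sigma_vitro = 0, sigma_vivo = 0, baseline_log2_sd = 0.5,
                    seed = 5)
  sim <- simulate_pair(cfg)
  fc_vit <- fold_change(sim$vitro, numerator = "SHH", denominator = "Veh")
  fc_viv <- fold_change(sim$vivo, numerator = "Veh", denominator = "Cyc")
  expect_equal(fc_vit$fc, rep(1, 50))
  expect_equal(fc_viv$fc, rep(1, 50))
  expect_true(all(sim$truth$status == "null"))
})

test_that("zero-noise realized fold changes equal 2^(true log2 effect) exactly", {
  cfg <- sim_config(n_genes = 100, frac_positive = 0.1, frac_negative = 0.1,
                    sigma_vitro = 0, sigma_vivo = 0, attenuation = 0.25, seed = 9)
  sim <- simulate_pair(cfg)
  fc_vit <- fold_change(sim$vitro, numerator = "SHH", denominator = "Veh")
  fc_viv <- fold_change(sim$vivo, numerator = "Veh", denominator = "Cyc")
  expect_equal(fc_vit$fc, 2^sim$truth$true_log2fc_vitro, tolerance = 1e-12)
  expect_equal(fc_viv$fc, 2^sim$truth$true_log2fc_vivo, tolerance = 1e-12)
})

test_that("simulated effects match their closed-form expectations (Monte Carlo)", {
  cfg <- sim_config(n_genes = 10000, frac_positive = 0.02, frac_negative = 0.02,
                    effect_log2_mean = 2, attenuation = 0.25,
                    sigma_vitro = 0.25, sigma_vivo = 0.5, seed = 100)
  sim <- simulate_pair(cfg)
  pos <- sim$truth$status == "positive"
  # true |log2FC| ~ N(2, 0.5) truncated at 0: truncation mass is negligible,
  # so the mean of the in vitro log2 effect is 2 (geometric-mean linear FC 4)
  expect_equal(mean(sim$truth$true_log2fc_vitro[pos]), 2,
               tolerance = 0.05)
  expect_equal(mean(sim$truth$true_log2fc_vivo[pos]), 0.5,
               tolerance = 0.05)
  # realized log2 fold changes track the truth up to noise that averages out
  fc_vit <- fold_change(sim$vitro, numerator = "SHH", denominator = "Veh")
  fc_viv <- fold_change(sim$vivo, numerator = "Veh", denominator = "Cyc")
  expect_equal(mean(log2(fc_vit$fc[pos])), 2, tolerance = 0.1)
  expect_equal(2^mean(log2(fc_viv$fc[pos])), 2^0.5, tolerance = 0.1)
})

test_that("truth satisfies the null and sign-concordance invariants", {
  for (seed in 1:5) {
    sim <- simulate_pair(sim_config(n_genes = 300, frac_positive = 0.1,
                                    frac_negative = 0.2, seed = seed))
    tr <- sim$truth
    expect_true(all(tr$true_log2fc_vitro[tr$status == "null"] == 0))
    expect_true(all(tr$true_log2fc_vivo[tr$status == "null"] == 0))
    reg <- tr[tr$status != "null", ]
    expect_true(all(sign(reg$true_log2fc_vivo) == sign(reg$true_log2fc_vitro)))
    expect_true(all(reg$true_log2fc_vitro[reg$status == "positive"] > 0))
    expect_true(all(reg$true_log2fc_vitro[reg$status == "negative"] < 0))
  }
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(reps_vitro = 1), "replicate")
  expect_error(sim_config(frac_positive = 0.7, frac_negative = 0.5), "frac")
  expect_error(sim_config(attenuation = 0), "attenuation")
  expect_error(sim_config(attenuation = 1.2), "attenuation")
})

test_that("recovery scoring follows the direction-matched confusion rules", {
  truth <- tibble::tibble(
    gene = paste0("g", 1:10),
    status = c("positive", "positive", "negative", "negative", rep("null", 6)),
    true_log2fc_vitro = c(2, 2, -2, -2, rep(0, 6)),
    true_log2fc_vivo = c(0.5, 0.5, -0.5, -0.5, rep(0, 6)))

  # exactly the regulated genes with correct signs
  perfect <- tibble::tibble(gene = paste0("g", 1:4),
                            direction = c("positive", "positive",
                                          "negative", "negative"))
  sc <- score_recovery(perfect, truth)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1)
  expect_equal(sc$true_negative, 6L)
  expect_equal(sum(sc$true_positive, sc$false_positive,
                   sc$false_negative, sc$true_negative), 10)

  # nothing detected
  none <- tibble::tibble(gene = character(0), direction = character(0))
  sc0 <- score_recovery(none, truth)
  expect_equal(sc0$true_positive, 0L)
  expect_equal(sc0$false_positive, 0L)
  expect_equal(sc0$recall, 0)
  expect_true(is.na(sc0$precision))

  # 2 correct + 1 wrong-sign detection on 4 regulated genes
  mixed <- tibble::tibble(gene = c("g1", "g3", "g2"),
                          direction = c("positive", "negative", "negative"))
  scm <- score_recovery(mixed, truth)
  expect_equal(scm$true_positive, 2L)
  expect_equal(scm$false_positive, 1L)
  expect_equal(scm$false_negative, 2L)
  expect_equal(scm$recall, 0.5)
  expect_equal(scm$precision, 2 / 3)

  # up/down synonyms accepted; unknown genes rejected
  updown <- tibble::tibble(gene = c("g1", "g3"), direction = c("up", "down"))
  expect_equal(score_recovery(updown, truth)$true_positive, 2L)
  expect_error(score_recovery(tibble::tibble(gene = "nope", direction = "up"),
                              truth), "absent from truth")
})

test_that("write_sim emits a readable, consistent set of files", {
  dir <- tempfile()
  sim <- simulate_pair(sim_config(n_genes = 25, seed = 2))
  write_sim(sim, dir)
  expect_true(all(file.exists(file.path(
    dir, c("vitro.tsv", "vivo.tsv", "design_vitro.tsv",
           "design_vivo.tsv", "truth.tsv")))))
  back <- read_expression_matrix(file.path(dir, "vitro.tsv"),
                                 file.path(dir, "design_vitro.tsv"))
  expect_identical(back$shh_1, sim$vitro$shh_1)
})
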