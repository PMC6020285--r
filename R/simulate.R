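#' Configuration for a paired synthetic experiment
#'
#' Describes two linked two-condition experiments over one shared gene
#' universe: an "in vitro" pathway-activation arm (treated vs vehicle, robust
#' effects) and an "in vivo" pathway-inhibition arm (vehicle vs inhibitor,
#' attenuated effects oriented so that the vehicle/inhibitor ratio shares the
#' sign of the in vitro effect). Signals are log-normal: per-sample log2
#' intensity = gene baseline + treatment effect + Gaussian noise.
#'
#' @param n_genes Number of genes.
#' @param frac_positive,frac_negative Fractions of genes positively /
#'   negatively regulated by the pathway (`frac_positive + frac_negative <= 1`).
#' @param effect_log2_mean,effect_log2_sd Mean and SD of the true in vitro
#'   |log2 fold change| of regulated genes, drawn from a normal truncated at 0.
#' @param attenuation Multiplier in (0, 1] mapping the in vitro log2 effect to
#'   the in vivo log2 effect; emulates the weaker transcriptional response of
#'   a complex tissue under transient pathway inhibition.
#' @param sigma_vitro,sigma_vivo Per-sample log2 noise SD in each arm.
#' @param reps_vitro,reps_vivo Replicates per condition in each arm.
#' @param baseline_log2_mean,baseline_log2_sd Distribution of per-gene
#'   baseline log2 intensity.
#' @param seed Integer seed; a single global seed governs all draws.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10000L,
                       frac_positive = 0.02,
                       frac_negative = 0.02,
                       effect_log2_mean = 2,
                       effect_log2_sd = 0.5,
                       attenuation = 0.25,
                       sigma_vitro = 0.25,
                       sigma_vivo = 0.5,
                       reps_vitro = 4L,
                       reps_vivo = 6L,
                       baseline_log2_mean = 8,
                       baseline_log2_sd = 1.5,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              frac_positive = frac_positive, frac_negative = frac_negative,
              effect_log2_mean = effect_log2_mean,
              effect_log2_sd = effect_log2_sd,
              attenuation = attenuation,
              sigma_vitro = sigma_vitro, sigma_vivo = sigma_vivo,
              reps_vitro = as.integer(reps_vitro),
              reps_vivo = as.integer(reps_vivo),
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              seed = as.integer(seed))
  if (cfg$n_genes < 1L) abort("n_genes must be >= 1")
  if (cfg$frac_positive < 0 || cfg$frac_negative < 0 ||
      cfg$frac_positive + cfg$frac_negative > 1) {
    abort("frac_positive + frac_negative must lie in [0, 1]")
  }
  if (cfg$attenuation <= 0 || cfg$attenuation > 1) abort("attenuation must be in (0, 1]")
  if (cfg$sigma_vitro < 0 || cfg$sigma_vivo < 0 || cfg$effect_log2_sd < 0 ||
      cfg$baseline_log2_sd < 0) {
    abort("standard deviations must be >= 0")
  }
  if (cfg$reps_vitro < 2L || cfg$reps_vivo < 2L) abort("replicate counts must be >= 2")
  structure(cfg, class = "sim_config")
}

#' Simulate a paired in vitro / in vivo experiment with known truth
#'
#' Draw order under the single seed: (1) per-gene baselines, (2) regulation
#' status assignment, (3) effect magnitudes, (4) in vitro noise, (5) in vivo
#' noise. Identical config and seed give bit-identical output.
#'
#' In vitro samples: treated log2 signal = baseline + effect, vehicle =
#' baseline. In vivo samples: vehicle = baseline, inhibitor-exposed =
#' baseline - attenuation * effect, so the vehicle/inhibitor (Veh/Cyc) log2
#' ratio equals `attenuation * effect` and is sign-concordant with the in
#' vitro effect for every regulated gene. Intensities are emitted on the
#' linear scale (`2^log2`).
#'
#' @param config A [sim_config()].
#' @return A list of class `shh_sim` with elements `vitro`, `vivo`
#'   (expression tibbles, `gene` + sample columns), `design_vitro`,
#'   `design_vivo` (sample/condition tibbles; conditions `SHH`/`Veh` and
#'   `Veh`/`Cyc`), `truth` (tibble: `gene`, `status` in
#'   positive/negative/null, `true_log2fc_vitro`, `true_log2fc_vivo`), and
#'   `config`.
#' @examples
#' sim <- simulate_pair(sim_config(n_genes = 100, seed = 7))
#' dplyr::count(sim$truth, status)
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  genes <- sprintf("g%05d", seq_len(n))
  set.seed(config$seed)

  baseline <- rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)

  n_pos <- round(config$frac_positive * n)
  n_neg <- round(config$frac_negative * n)
  status <- rep("null", n)
  regulated <- if (n_pos + n_neg > 0L) sample.int(n, n_pos + n_neg) else integer(0)
  status[regulated[seq_len(n_pos)]] <- "positive"
  if (n_neg > 0L) status[regulated[n_pos + seq_len(n_neg)]] <- "negative"

  effect <- numeric(n)
  if (length(regulated) > 0L) {
    mag <- rtruncnorm0(length(regulated), config$effect_log2_mean,
                       config$effect_log2_sd)
    effect[regulated] <- mag * ifelse(status[regulated] == "positive", 1, -1)
  }

  rv <- config$reps_vitro
  vit_treated <- matrix(baseline + effect, n, rv) +
    matrix(rnorm(n * rv, 0, config$sigma_vitro), n, rv)
  vit_vehicle <- matrix(baseline, n, rv) +
    matrix(rnorm(n * rv, 0, config$sigma_vitro), n, rv)

  rw <- config$reps_vivo
  viv_vehicle <- matrix(baseline, n, rw) +
    matrix(rnorm(n * rw, 0, config$sigma_vivo), n, rw)
  viv_cyc <- matrix(baseline - config$attenuation * effect, n, rw) +
    matrix(rnorm(n * rw, 0, config$sigma_vivo), n, rw)

  vitro_samples <- c(paste0("shh_", seq_len(rv)), paste0("veh_", seq_len(rv)))
  vivo_samples <- c(paste0("veh_", seq_len(rw)), paste0("cyc_", seq_len(rw)))

  vitro <- tibble::as_tibble(
    cbind(2^vit_treated, 2^vit_vehicle) |> `colnames<-`(vitro_samples))
  vitro <- dplyr::bind_cols(tibble::tibble(gene = genes), vitro)
  vivo <- tibble::as_tibble(
    cbind(2^viv_vehicle, 2^viv_cyc) |> `colnames<-`(vivo_samples))
  vivo <- dplyr::bind_cols(tibble::tibble(gene = genes), vivo)

  design_vitro <- tibble::tibble(sample = vitro_samples,
                                 condition = rep(c("SHH", "Veh"), each = rv))
  design_vivo <- tibble::tibble(sample = vivo_samples,
                                condition = rep(c("Veh", "Cyc"), each = rw))
  attr(vitro, "design") <- design_vitro
  attr(vivo, "design") <- design_vivo

  truth <- tibble::tibble(gene = genes, status = status,
                          true_log2fc_vitro = effect,
                          true_log2fc_vivo = config$attenuation * effect)

  structure(list(vitro = vitro, vivo = vivo,
                 design_vitro = design_vitro, design_vivo = design_vivo,
                 truth = truth, config = config),
            class = "shh_sim")
}

# normal truncated at zero (magnitudes); rejection sampling is exact and the
# acceptance rate is ~1 for mean/sd ratios used here
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < 0)
  while (length(bad) > 0L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0]
  }
  out
}

#' Score detected genes against simulation truth
#'
#' A detection counts as a true positive only when the gene is truly
#' regulated and the detected direction matches its status. A regulated gene
#' detected with the wrong sign is both a false positive (the call is wrong)
#' and a missed gene (it contributes to FN); with such wrong-sign calls the
#' four counts sum to `n_genes + n_wrong_sign`, otherwise exactly to
#' `n_genes`.
#'
#' @param detected Tibble with columns `gene` and `direction`
#'   (`"positive"`/`"negative"`, or the equivalent `"up"`/`"down"`).
#' @param truth Truth tibble from [simulate_pair()].
#' @return One-row tibble: `true_positive`, `false_positive`,
#'   `false_negative`, `true_negative`, `recall`, `precision` (`precision` is
#'   `NA` when there are no detections).
#' @export
score_recovery <- function(detected, truth) {
  if (nrow(detected) > 0L) {
    unknown <- setdiff(detected$gene, truth$gene)
    if (length(unknown) > 0L) {
      abort(paste0("detected genes absent from truth: ",
                   paste(head(unknown, 5L), collapse = ", ")))
    }
    dir <- c(up = "positive", down = "negative",
             positive = "positive", negative = "negative")[detected$direction]
    if (anyNA(dir)) abort("detected directions must be positive/negative (or up/down)")
    detected <- tibble::tibble(gene = detected$gene, direction = unname(dir))
  }
  truth_reg <- truth[truth$status != "null", ]
  hit <- merge(detected, truth_reg, by = "gene")
  tp <- sum(hit$direction == hit$status)
  fp <- nrow(detected) - tp
  fn <- nrow(truth_reg) - tp
  null_genes <- truth$gene[truth$status == "null"]
  tn <- length(null_genes) - sum(detected$gene %in% null_genes)
  tibble::tibble(true_positive = tp, false_positive = fp,
                 false_negative = fn, true_negative = tn,
                 recall = if (nrow(truth_reg) > 0L) tp / nrow(truth_reg) else NA_real_,
                 precision = if (nrow(detected) > 0L) tp / nrow(detected) else NA_real_)
}

#' Write a simulated pair to an output directory
#'
#' Emits `vitro.tsv`, `vivo.tsv`, `design_vitro.tsv`, `design_vivo.tsv`, and
#' `truth.tsv`.
#'
#' @param sim A `shh_sim` from [simulate_pair()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "shh_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_matrix(sim$vitro, file.path(dir, "vitro.tsv"))
  write_expression_matrix(sim$vivo, file.path(dir, "vivo.tsv"))
  readr::write_tsv(sim$design_vitro, file.path(dir, "design_vitro.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$design_vivo, file.path(dir, "design_vivo.tsv"),
                   progress = FALSE)
  write_tsv_full(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
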