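# End-to-end orchestration: simulate -> cytometry -> variability -> twin
# variance components -> QTL mapping -> MR, with per-stage seeds, output
# manifests and a reproducibility contract (same config => same results).

#' Default pipeline configuration
#'
#' All thresholds carry the analysis defaults: minimum 1000 events per
#' sample, minimum 100 cells per population, MAF < 1% and HWE p <= 1e-50
#' variant exclusion, 1 Mb cis window, clump index p <= 1e-4 (trans) / FDR
#' <= 0.05 (cis) with 250 kb / r2 > 0.5 membership, MR instrument window
#' 200 kb with p <= 1e-5, and 10% FDR on the MR screen.
#'
#' @param seed master integer seed; per-stage seeds are derived from it.
#' @param out_dir run directory (created if missing).
#' @param sim a \code{\link{sim_config}} for the simulate stage.
#' @param stages character vector of stages to run, in order.
#' @return named list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("vprotqtl_run_"),
                            sim = NULL,
                            stages = c("simulate", "cytometry", "variability",
                                       "twinvc", "qtlmap")) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir, stages = stages,
              sim = sim,
              min_events = 1000L, min_cells = 100L,
              doublet_band = c(0.8, 1.3),
              maf_min = 0.01, hwe_p_max = 1e-50,
              cis_half_width = 5e5,
              clump_p_trans = 1e-4, clump_fdr_cis = 0.05,
              clump_dist = 250000, clump_r2 = 0.5,
              mr_window = 2e5, mr_p_max = 1e-5, mr_fdr = 0.10,
              genome_wide_p = 5e-8)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in fixed order on a simulated twin cohort,
#' writing each stage's outputs and a JSON manifest (config, seed, stage
#' log) to the run directory. Rerunning with the same configuration
#' produces identical results for the deterministic stages.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return invisibly, a list with the in-memory stage outputs and the run
#'   directory path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$sim
  if (is.null(sim))
    sim <- sim_config(seed = config$seed, n_mz_pairs = 30L, n_dz_pairs = 30L,
                      n_individuals = 60L, n_snps = 60L, n_chromosomes = 2L,
                      n_cells_per_individual = 1500L, doublet_rate = 0.05)
  if ("twinvc" %in% config$stages &&
      sim$n_mz_pairs + sim$n_dz_pairs == 0L)
    stop("configuration error: twinvc stage enabled but no twin pairs simulated")
  out <- list(run_dir = config$out_dir)
  log <- list()

  # simulate
  cohort <- simulate_twin_cohort(sim)
  traits <- simulate_latent_traits(cohort$genotypes, cohort$pedigree, sim)
  utils::write.table(cohort$pedigree, file.path(config$out_dir, "pedigree.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_dosage_tsv(cohort$genotypes, file.path(config$out_dir, "dosages.tsv"))
  out$cohort <- cohort; out$truth <- traits
  log$simulate <- list(n_individuals = nrow(cohort$pedigree),
                       n_snps = ncol(cohort$genotypes$dosages))

  # cytometry
  samples <- stats::setNames(lapply(seq_len(nrow(traits)), function(i)
    simulate_cells(traits[i, ], sim)), traits$id)
  cyt <- process_cytometry(samples, channel = "FL1-A",
                           cell_type = "synthetic", protein = "P1",
                           min_events = config$min_events,
                           min_cells = config$min_cells,
                           doublet_band = config$doublet_band)
  if (is.null(cyt$summaries)) stop("stage cytometry: all samples rejected")
  utils::write.table(cyt$summaries,
                     file.path(config$out_dir, "trait_summaries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out$summaries <- cyt$summaries
  log$cytometry <- list(n_pass = nrow(cyt$summaries),
                        n_reject = sum(vapply(cyt$qc, function(x)
                          x$stage != "pass", logical(1))))

  # variability
  if ("variability" %in% config$stages) {
    eta <- eta_res_matrix(out$summaries)
    utils::write.table(data.frame(individual = rownames(eta), eta,
                                  check.names = FALSE),
                       file.path(config$out_dir, "eta_res.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$eta <- eta
    log$variability <- list(n_traits = ncol(eta))
  }

  # twin variance components
  if ("twinvc" %in% config$stages) {
    inds <- rownames(out$eta)
    ped <- cohort$pedigree[match(inds, cohort$pedigree$id), ]
    ace <- lapply(colnames(out$eta), function(tr)
      ace_fit(out$eta[, tr], ped, min_pairs = 2L)$fractions)
    ace_tab <- data.frame(trait = colnames(out$eta),
                          do.call(rbind, ace))
    utils::write.table(ace_tab, file.path(config$out_dir, "ace.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$ace <- ace_tab
    log$twinvc <- list(n_traits = nrow(ace_tab))
  }

  # QTL mapping on eta_res
  if ("qtlmap" %in% config$stages) {
    qc <- qc_variants(cohort$genotypes, config$maf_min, config$hwe_p_max)
    gs <- qc$genotypes
    inds <- rownames(out$eta)
    gi <- match(inds, gs$individuals)
    grms <- loco_grms(gs)
    scans <- list()
    for (tr in colnames(out$eta)) {
      y <- out$eta[, tr]
      keep <- !is.na(y)
      per_chrom <- lapply(names(grms$complement), function(cn) {
        g <- grms$complement[[cn]]
        g_sub <- structure(list(matrix = g$matrix[gi[keep], gi[keep]],
                                m = g$m), class = "grm")
        on_c <- gs$variants$chrom == as.integer(cn)
        sc <- lmm_scan(y[keep], NULL,
                       gs$dosages[gi[keep], on_c, drop = FALSE], g_sub)
        sc$chrom <- as.integer(cn)
        sc
      })
      sc <- do.call(rbind, per_chrom)
      sc$trait <- tr
      scans[[tr]] <- sc
    }
    assoc <- do.call(rbind, scans)
    utils::write.table(assoc, file.path(config$out_dir, "assoc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    clumps <- ld_clump(assoc, gs, p_index = config$clump_p_trans,
                       r2 = config$clump_r2, dist = config$clump_dist)
    utils::write.table(clumps, file.path(config$out_dir, "clumps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$assoc <- assoc; out$clumps <- clumps
    log$qtlmap <- list(n_tests = nrow(assoc), n_clumps = nrow(clumps))
  }

  manifest <- list(config = unclass(config)[setdiff(names(config), "sim")],
                   sim = if (!is.null(config$sim)) unclass(config$sim),
                   stages_completed = names(log), log = log,
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       force = TRUE)
  invisible(out)
}
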