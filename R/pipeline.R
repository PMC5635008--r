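#' Default configuration for a full satellitome run
#'
#' The defaults mirror the protocol of a full-scale study scaled to desk
#' size: iterative mining starting from a sample of read pairs that doubles
#' each round, variant/family/superfamily identity thresholds of 95/80/50%,
#' masking of up to ten million read pairs per genome, and diploid-equivalent
#' read simulation of the 1B individual (one B added to a diploid A
#' complement).
#'
#' @param families list of [family_spec()]; `NULL` uses a small demonstration
#'   satellitome (three shared families and one B-restricted satellite).
#' @param background_length haploid A-complement length, bp.
#' @param f B-segment length fraction of the A complement (0.08 emulates a
#'   metacentric B of about 8% of the haploid set).
#' @param n_pairs read pairs simulated per library.
#' @param start_pairs first-iteration mining sample.
#' @param seed master seed; every stage derives its randomness from it.
#' @param prefix species prefix used in family names.
#' @param ... further overrides stored in the config.
#' @return a named list of class `run_config`.
#' @export
default_run_config <- function(families = NULL, background_length = 50000,
                               f = 0.08, n_pairs = 200000,
                               start_pairs = 1000, seed = 1,
                               prefix = "Sim", ...) {
  if (is.null(families))
    families <- list(
      family_spec("satA", rul = 51, at_frac = 0.55, copies_0B = 120,
                  copies_B = 25, intra_divergence = 0.05),
      family_spec("satB", rul = 21, at_frac = 0.45, copies_0B = 180,
                  copies_B = 0, intra_divergence = 0.02),
      family_spec("satC", rul = 86, at_frac = 0.60, copies_0B = 40,
                  copies_B = 8, intra_divergence = 0.08),
      family_spec("satBsp", rul = 24, copies_0B = 0, copies_B = 60,
                  b_restricted = TRUE, dispersed_0B = 3))
  cfg <- list(families = families, background_length = background_length,
              f = f, n_pairs = n_pairs, start_pairs = start_pairs,
              seed = seed, prefix = prefix,
              read_len = 101, insert_mean = 300, insert_sd = 30,
              error_rate = 0.01, diploid_equivalent = TRUE,
              variant_divergence = 0.10, jitter_sdlog = 0,
              thresholds = c(variant = 95, family = 80, superfamily = 50),
              mask_identity = 0.70, mask_min_len = 30,
              mask_max_pairs = 1e7,
              subtract_identity = 0.80, subtract_cov = 0.50,
              recluster_pairs = 2500,
              denominator = "total")
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' @noRd
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (any(cfg$thresholds <= 0 | cfg$thresholds > 100))
    stop("identity thresholds must be in (0, 100]", call. = FALSE)
  if (cfg$start_pairs < 1)
    stop("start_pairs must be positive", call. = FALSE)
  if (cfg$f < 0 || cfg$f >= 1) stop("f must be in [0, 1)", call. = FALSE)
  invisible(cfg)
}

#' Run the full satellitome pipeline on a synthetic genome pair
#'
#' Executes simulate -> mine -> group/name -> quantify (both genomes) ->
#' B-comparison -> B-specificity verification, and (optionally) writes the
#' satellitome table, the B-comparison table, per-stage logs and a manifest
#' to `out_dir`. All randomness flows from `config$seed`, so a rerun with
#' the same config reproduces the outputs byte-identically.
#'
#' @param config a [default_run_config()] list.
#' @param out_dir optional output directory (created if needed).
#' @return list with `pair`, `libraries`, `mining`, `families` (named),
#'   `satellitome` (Table-1-style data frame), `b_comparison`, and
#'   `b_verification` (tandem presence per library for families whose log2
#'   ratio is undefined or positive).
#' @export
run_satellitome_pipeline <- function(config = default_run_config(),
                                     out_dir = NULL) {
  validate_config(config)
  cfg <- config
  stage <- function(name, expr) {
    if (isTRUE(getOption("satellitome.verbose")))
      message("[", format(Sys.time(), "%H:%M:%S"), "] stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  pair <- stage("simulate-genomes",
    plant_families(cfg$families, cfg$background_length, cfg$f,
                   seed = child_seed(cfg$seed, 11),
                   variant_divergence = cfg$variant_divergence,
                   jitter_sdlog = cfg$jitter_sdlog))
  libs <- stage("simulate-reads",
    simulate_pair_libraries(pair, cfg$n_pairs, cfg$read_len, cfg$insert_mean,
                            cfg$insert_sd, cfg$error_rate,
                            seed = child_seed(cfg$seed, 12),
                            diploid_equivalent = cfg$diploid_equivalent))
  mining <- stage("mine",
    mine_satellitome(libs$lib_1B, start_pairs = cfg$start_pairs,
                     subtract_identity = cfg$subtract_identity,
                     subtract_cov = cfg$subtract_cov,
                     family_threshold = cfg$thresholds[["family"]] / 100,
                     seed = child_seed(cfg$seed, 13)))
  grp <- stage("catalogue", group_monomers(mining$monomers,
                                           thresholds = cfg$thresholds))
  ab0 <- stage("quantify-0B",
    quantify_library(libs$lib_0B, grp$families,
                     max_pairs = cfg$mask_max_pairs,
                     seed = child_seed(cfg$seed, 14),
                     min_identity = cfg$mask_identity,
                     min_len = cfg$mask_min_len, genome = "0B",
                     denominator = cfg$denominator))
  fams <- stage("name",
    name_families(grp$families,
                  setNames(ab0$abundance_percent, ab0$family),
                  prefix = cfg$prefix))
  ## re-key the abundance tables by catalogue name
  key <- setNames(vapply(fams, `[[`, character(1), "name"),
                  vapply(fams, `[[`, character(1), "consensus"))
  ab0$family <- unname(key[ab0$family])
  ab1 <- stage("quantify-1B",
    quantify_library(libs$lib_1B, fams, max_pairs = cfg$mask_max_pairs,
                     seed = child_seed(cfg$seed, 15),
                     min_identity = cfg$mask_identity,
                     min_len = cfg$mask_min_len, genome = "1B",
                     denominator = cfg$denominator))
  bc <- stage("b-comparison", b_comparison(ab0, ab1, cfg$f))

  ## B-specificity verification for families that cannot be assessed (or
  ## look enriched) via log2: multimer scan + targeted reclustering
  verify <- NULL
  check <- bc$family[bc$classification %in%
                       c("undefined", "B-enriched candidate")]
  for (fn in check) {
    cons <- names(key)[key == fn][1]
    tr <- stage("b-verification",
      targeted_recluster(libs$lib_0B, libs$lib_1B, cons,
                         n = cfg$recluster_pairs,
                         min_identity = cfg$subtract_identity,
                         min_cov = cfg$subtract_cov))
    tr$family <- fn
    verify <- rbind(verify, tr)
  }

  sat <- merge(catalog_table(fams),
               merge(ab0[, c("family", "abundance_percent",
                             "divergence_percent")],
                     ab1[, c("family", "abundance_percent",
                             "divergence_percent")],
                     by = "family", suffixes = c("_0B", "_1B")),
               by.x = "name", by.y = "family")
  sat <- sat[order(match(sat$name,
                         vapply(fams, `[[`, character(1), "name"))), ]
  sat$log2_1B_0B <- ifelse(sat$abundance_percent_0B > 0 &
                             sat$abundance_percent_1B > 0,
                           log2(sat$abundance_percent_1B /
                                  sat$abundance_percent_0B), NA_real_)
  rownames(sat) <- NULL

  res <- list(pair = pair, libraries = libs, mining = mining,
              families = fams, satellitome = sat, b_comparison = bc,
              b_verification = verify, config = cfg)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' @noRd
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(res$satellitome, "satellitome.tsv")
  tsv(res$b_comparison, "b_comparison.tsv")
  if (!is.null(res$b_verification))
    tsv(res$b_verification, "b_verification.tsv")
  tsv(res$mining$log, "mining_log.tsv")
  write_truth_tsv(res$pair, file.path(out_dir, "truth.tsv"))
  write_catalog_fasta(res$families, file.path(out_dir, "catalog.fasta"))
  cfg <- res$config
  manifest <- c(
    sprintf("package_version: %s",
            as.character(utils::packageVersion("satellitome"))),
    sprintf("seed: %s", cfg$seed),
    sprintf("config_hash: %s",
            paste(format(unlist(cfg[setdiff(names(cfg), "families")])),
                  collapse = "|")))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}
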