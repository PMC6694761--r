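#' Read and validate a run configuration
#'
#' A run configuration is a YAML (or plain list) with blocks `guide`
#' (required: `name`, `spacer`; optional `pam`, `cut_offset`), `simulate`,
#' `process`, `quant`, `pcut`, `model` and `scan`. Unknown or malformed
#' keys raise a schema error naming every offending key.
#'
#' @param config path to a YAML file or a list.
#' @return the validated config list (class `blt_config`) with defaults
#'   filled in.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    guide = list(pam = "TTGAAT", cut_offset = 3L),
    simulate = list(n_templates = 300L, per_base_mismatch_rate = 0.10,
                    umi_t_length = 12L, copies = 30, copies_dist = "poisson",
                    replicates = 2L, spikein_copies = 3,
                    on_target_prob = 0.9, w_seed = 0.05, w_distal = 0.95,
                    mean_pcr_duplicates = 2, error_rate = 0.001,
                    read_length = 150L),
    process = list(q_threshold = 20, min_uncut = 3L),
    quant = list(j = 1L, k = 4L, gimp_mode = "literal", min_reads = 0L),
    pcut = list(enabled = FALSE, binding_on = 0.95, pcut_on = 0.9,
                binding_w_seed = 0.3, binding_w_distal = 0.98,
                pcut_w_seed = 0.1, pcut_w_distal = 0.95),
    model = list(enabled = TRUE, hidden = 10L,
                 split = c(0.70, 0.15, 0.15), min_rows = 50L),
    scan = list(genome = NULL, max_mismatches = 6L,
                pam_pattern = "NNGRRT", top_percent = 5))
  bad <- character(0)
  bad <- c(bad, setdiff(names(config), c(names(defaults))))
  for (blk in names(defaults)) {
    if (!is.null(config[[blk]]) && !is.list(config[[blk]])) {
      bad <- c(bad, blk)
      next
    }
    known <- union(names(defaults[[blk]]), c("name", "spacer"))
    unknown <- setdiff(names(config[[blk]]), known)
    if (length(unknown)) bad <- c(bad, paste0(blk, ".", unknown))
  }
  if (length(bad))
    stop("invalid config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(config$guide$name) || is.null(config$guide$spacer))
    stop("config$guide must define name and spacer", call. = FALSE)
  merged <- defaults
  for (blk in names(defaults))
    merged[[blk]] <- utils::modifyList(defaults[[blk]],
                                       config[[blk]] %||% list())
  merged$model$split <- as.numeric(merged$model$split)
  structure(merged, class = c("blt_config", "list"))
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Run the full BLT analysis pipeline
#'
#' Executes simulate -> process -> quantify -> [pcut] -> model -> [scan]
#' against a configuration, persisting every intermediate as TSV/JSON in
#' `out_dir` so that stages can be re-run individually. All randomness
#' derives from `seed`; a fixed seed gives byte-identical outputs. A
#' `provenance.json` (package version, seed, config hash) is written next
#' to the outputs and its hash is embedded in each JSON artifact.
#'
#' @param config a config list / YAML path (see [read_run_config()]).
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed.
#' @param stages character vector of stages to run; `"all"` (default) runs
#'   every enabled stage. Later stages read the persisted outputs of
#'   earlier ones and fail with an actionable error if those are missing.
#' @return (invisibly) a list of the key result objects.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L, stages = "all") {
  cfg <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  all_stages <- c("simulate", "process", "quantify", "pcut", "model", "scan")
  if (identical(stages, "all")) {
    stages <- c("simulate", "process", "quantify",
                if (isTRUE(cfg$pcut$enabled)) "pcut",
                if (isTRUE(cfg$model$enabled)) "model",
                if (!is.null(cfg$scan$genome)) "scan")
  }
  stopifnot(all(stages %in% all_stages))
  sim <- cfg$simulate
  guide <- guide_spec(cfg$guide$name, cfg$guide$spacer, cfg$guide$pam,
                      cfg$guide$cut_offset)
  layout <- construct_layout(pam = guide$pam,
                             umi_t_length = sim$umi_t_length)
  seqp <- sequencing_params(read_length = sim$read_length,
                            mean_pcr_duplicates = sim$mean_pcr_duplicates,
                            error_rate = sim$error_rate)
  provenance <- list(package = "bltseq",
                     version = as.character(utils::packageVersion("bltseq")),
                     seed = seed, config_hash = rlang::hash(unclass(cfg)))
  .write_json(provenance, file.path(out_dir, "provenance.json"))
  fq <- function(r) file.path(out_dir, sprintf("reads_rep%d.fastq", r))
  fq_spike <- file.path(out_dir, "reads_spikein.fastq")
  rec_path <- function(r) file.path(out_dir, sprintf("records_rep%d.tsv", r))
  reps <- seq_len(sim$replicates)
  if (sim$replicates + 1L > length(seqp$barcode_set))
    stop("not enough barcodes for ", sim$replicates, " replicates + spike-in",
         call. = FALSE)
  results <- list(guide = guide, provenance = provenance)

  if ("simulate" %in% stages) {
    truth <- cleavage_truth(
      guide, on_target_prob = sim$on_target_prob,
      position_weights = seed_gradient_weights(guide$length, sim$w_seed,
                                               sim$w_distal))
    set.seed(seed)
    templates <- generate_template_library(
      guide, library_params(sim$per_base_mismatch_rate, sim$n_templates,
                            sim$umi_t_length))
    truth_tab <- copy(templates)
    truth_tab[, p_true := truth_cut_prob(truth, target)]
    write_truth_table(truth_tab, file.path(out_dir, "truth.tsv"))
    for (r in reps) {
      mol <- simulate_cut_reaction(templates, truth, copies = sim$copies,
                                   copies_dist = sim$copies_dist,
                                   seed = seed + r)
      simulate_ligation_sequencing(mol, guide, layout, seqp,
                                   barcode = seqp$barcode_set[r],
                                   path = fq(r), seed = seed + 100L + r)
    }
    if (sim$spikein_copies > 0) {
      naive <- simulate_cut_reaction(
        templates, cleavage_truth(guide, on_target_prob = 0,
                                  position_weights = rep(1, guide$length)),
        copies = sim$spikein_copies, copies_dist = "poisson",
        seed = seed + 200L)
      simulate_ligation_sequencing(naive, guide, layout, seqp,
                                   barcode = seqp$barcode_set[length(reps) + 1L],
                                   path = fq_spike, seed = seed + 300L)
    }
  }

  if ("process" %in% stages) {
    if (!file.exists(fq(1L)))
      stop("process: no simulated reads in ", out_dir,
           " - run the simulate stage first", call. = FALSE)
    spike_obs <- NULL
    if (file.exists(fq_spike)) {
      sp <- quality_filter(parse_and_demultiplex(fq_spike, guide, layout, seqp),
                           cfg$process$q_threshold)
      spike_obs <- collapse_observations(sp)
    }
    drops <- list()
    for (r in reps) {
      parsed <- parse_and_demultiplex(fq(r), guide, layout, seqp)
      drops[[sprintf("rep%d", r)]] <- drop_report(parsed)
      parsed <- quality_filter(parsed, cfg$process$q_threshold)
      obs <- collapse_observations(parsed)
      fwrite(obs, file.path(out_dir, sprintf("observations_rep%d.tsv", r)),
             sep = "\t")
      rec <- validate_targets(obs, min_uncut = cfg$process$min_uncut,
                              spikein = spike_obs, guide = guide)
      fwrite(rec, rec_path(r), sep = "\t")
    }
    .write_json(c(provenance["config_hash"], drops),
                file.path(out_dir, "drop_report.json"))
  }

  if ("quantify" %in% stages) {
    if (!file.exists(rec_path(1L)))
      stop("quantify: no target records in ", out_dir,
           " - run the process stage first", call. = FALSE)
    recs <- lapply(reps, function(r) fread(rec_path(r)))
    names(recs) <- sprintf("rep%d", reps)
    info <- data.table(sample = names(recs), guide = guide$name,
                       pam = guide$pam, replicate = names(recs))
    grouped <- group_by_guide_pam(recs, info)
    eta_rep <- compute_eta(grouped, guide)
    eta_avg <- replicate_average(eta_rep)
    fwrite(eta_rep, file.path(out_dir, "eta_per_replicate.tsv"), sep = "\t")
    fwrite(eta_avg, file.path(out_dir, "eta_averaged.tsv"), sep = "\t")
    agg <- aggregate_by_mismatch(eta_avg, guide)
    fwrite(agg$by_count, file.path(out_dir, "eta_by_mismatch_count.tsv"),
           sep = "\t")
    fwrite(agg$single_mm_table, file.path(out_dir, "eta_single_mismatch.tsv"),
           sep = "\t")
    fwrite(agg$epistasis, file.path(out_dir, "eta_epistasis.tsv"), sep = "\t")
    gres <- tryCatch(
      gimp_score(eta_avg, j = cfg$quant$j, k = cfg$quant$k,
                 mode = cfg$quant$gimp_mode),
      error = function(e) NULL)
    if (!is.null(gres))
      .write_json(c(provenance["config_hash"],
                    list(guide = guide$name, gimp = gres$gimp,
                         j = gres$j, k = gres$k, mode = gres$mode,
                         by_count = gres$by_count)),
                  file.path(out_dir, "gimp.json"))
    results$eta <- eta_avg
    results$gimp <- gres
  }

  if ("pcut" %in% stages) {
    pc <- cfg$pcut
    truth2 <- cleavage_truth(
      guide,
      binding = list(on = pc$binding_on,
                     position_weights = seed_gradient_weights(
                       guide$length, pc$binding_w_seed, pc$binding_w_distal)),
      pcut = list(on = pc$pcut_on,
                  position_weights = seed_gradient_weights(
                    guide$length, pc$pcut_w_seed, pc$pcut_w_distal)))
    set.seed(seed + 400L)
    templates <- generate_template_library(
      guide, library_params(sim$per_base_mismatch_rate, sim$n_templates,
                            sim$umi_t_length))
    pd <- simulate_pulldown(templates, truth2, copies = sim$copies,
                            copies_dist = sim$copies_dist)
    proc_side <- function(mol, barcode, tag, sseed) {
      p <- file.path(out_dir, sprintf("reads_%s.fastq", tag))
      simulate_ligation_sequencing(mol, guide, layout, seqp, barcode, p,
                                   seed = sseed)
      parsed <- quality_filter(
        parse_and_demultiplex(p, guide, layout, seqp),
        cfg$process$q_threshold)
      validate_targets(collapse_observations(parsed),
                       min_uncut = cfg$process$min_uncut, guide = guide)
    }
    whole_rec <- proc_side(pd$whole, seqp$barcode_set[1], "whole",
                           seed + 401L)
    bound_rec <- proc_side(pd$bound, seqp$barcode_set[2], "bound",
                           seed + 402L)
    ptab <- compute_pcut(bound_rec, whole_rec, guide, by = "mismatch_count")
    fwrite(ptab, file.path(out_dir, "pcut.tsv"), sep = "\t")
    on_row <- ptab[!is.na(class) & class == "on_target"]
    .write_json(c(provenance["config_hash"],
                  list(guide = guide$name,
                       p_cut_on_target = on_row$p_cut,
                       whole_fraction_on_target = on_row$whole_fraction)),
                file.path(out_dir, "pcut.json"))
    results$pcut <- ptab
  }

  if ("model" %in% stages) {
    avg_path <- file.path(out_dir, "eta_averaged.tsv")
    if (!file.exists(avg_path))
      stop("model: no averaged efficiencies in ", out_dir,
           " - run the quantify stage first", call. = FALSE)
    eta_avg <- fread(avg_path)
    fit <- train_guide_model(eta_avg$target, eta_avg$eta, guide,
                             split = cfg$model$split,
                             hidden = cfg$model$hidden, seed = seed,
                             min_rows = cfg$model$min_rows)
    model_to_json(fit, file.path(out_dir, "model.json"))
    results$model <- fit
  }

  if ("scan" %in% stages) {
    if (is.null(cfg$scan$genome))
      stop("scan: config$scan$genome is not set", call. = FALSE)
    model_path <- file.path(out_dir, "model.json")
    if (!file.exists(model_path))
      stop("scan: no trained model in ", out_dir,
           " - run the model stage first", call. = FALSE)
    fit <- model_from_json(model_path)
    sites <- enumerate_sites(cfg$scan$genome, guide,
                             max_mismatches = cfg$scan$max_mismatches,
                             pam_pattern = cfg$scan$pam_pattern)
    ranked <- score_and_rank(sites, fit, guide)
    fwrite(ranked, file.path(out_dir, "sites_ranked.tsv"), sep = "\t")
    results$sites <- ranked
  }

  invisible(results)
}
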