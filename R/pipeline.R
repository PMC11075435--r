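#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (or a JSON file holding one)
#' describing a full simulate -> gate -> demultiplex -> quantify ->
#' background-subtract -> summarise run.  Validation is strict: unknown
#' keys anywhere are rejected, and a run that enables background
#' subtraction without a `background` block fails here, before any stage
#' executes.
#'
#' @param cfg Named list or path to a JSON config.
#' @return The validated config (with defaults filled in), invisibly
#'   classed `run_config`.
#' @export
validate_run_config <- function(cfg) {
  if (is.character(cfg)) cfg <- jsonlite::read_json(cfg, simplifyVector = TRUE)
  top <- c("name", "seed", "n_events", "strains", "proportions", "noise",
           "gating", "samples", "background", "subtract_background",
           "out_dir", "log_level")
  unknown <- setdiff(names(cfg), top)
  if (length(unknown))
    stop_dfm("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg$name <- cfg$name %||% "run"
  cfg$seed <- as.integer(cfg$seed %||% 3841)
  cfg$n_events <- as.integer(cfg$n_events %||% 10000)
  cfg$strains <- cfg$strains %||% c("R", "Y", "B", "RY", "RB", "YB")
  cfg$proportions <- cfg$proportions %||%
    rep(1 / length(cfg$strains), length(cfg$strains))
  if (length(cfg$strains) != length(cfg$proportions))
    stop_dfm("strains and proportions differ in length")
  nk <- c("expr_gsd", "doublet_rate", "debris_rate")
  if (!is.null(cfg$noise)) {
    unknown <- setdiff(names(cfg$noise), nk)
    if (length(unknown))
      stop_dfm("unknown noise key(s): ", paste(unknown, collapse = ", "))
  }
  gk <- c("density_fraction", "singlet_fsc_min", "singlet_ar_min",
          "grid_bins")
  if (!is.null(cfg$gating)) {
    unknown <- setdiff(names(cfg$gating), gk)
    if (length(unknown))
      stop_dfm("unknown gating key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(cfg$samples) || NROW(cfg$samples) == 0)
    stop_dfm("config must define at least one sample")
  sk <- c("sample_id", "timepoint", "analysed_volume_mL",
          "flow_rate_uL_min", "acquisition_time_min", "harvest_volume_mL",
          "root_mass_g", "dilution_factor", "plant", "replicate")
  samples <- if (is.data.frame(cfg$samples))
    split(cfg$samples, seq_len(nrow(cfg$samples))) else cfg$samples
  for (s in samples) {
    unknown <- setdiff(names(s), sk)
    if (length(unknown))
      stop_dfm("unknown sample key(s): ", paste(unknown, collapse = ", "))
  }
  cfg$subtract_background <- isTRUE(cfg$subtract_background)
  if (cfg$subtract_background && is.null(cfg$background))
    stop_dfm("subtract_background is enabled but no background block given")
  if (!is.null(cfg$background)) {
    bk <- c("n_events", "n_replicates", "plant")
    unknown <- setdiff(names(cfg$background), bk)
    if (length(unknown))
      stop_dfm("unknown background key(s): ", paste(unknown, collapse = ", "))
    cfg$background$n_events <- as.integer(cfg$background$n_events %||% 10000)
    cfg$background$n_replicates <-
      as.integer(cfg$background$n_replicates %||% 3)
    cfg$background$plant <- cfg$background$plant %||% "pea"
  }
  invisible(structure(cfg, class = c("run_config", "list")))
}

.meta_from_row <- function(s) {
  sample_meta(
    sample_id = s$sample_id,
    timepoint = s$timepoint %||% NA,
    analysed_volume_mL = s$analysed_volume_mL,
    flow_rate_uL_min = s$flow_rate_uL_min %||% 3.66,
    acquisition_time_min = s$acquisition_time_min,
    harvest_volume_mL = s$harvest_volume_mL %||% 25,
    root_mass_g = s$root_mass_g,
    dilution_factor = s$dilution_factor %||% 1,
    plant = s$plant %||% "pea",
    replicate = s$replicate %||% 1L)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> gate -> demultiplex -> quantify (-> subtract
#' background) -> summarise for every sample in the config and writes a
#' tidy abundance CSV, a relative-abundance CSV, a confusion-summary CSV
#' and a JSON run report (seeds, config hash, package version).  Fully
#' reproducible: the same config yields byte-identical CSV outputs.
#'
#' @param cfg Run configuration (list or JSON path); see
#'   [validate_run_config()].
#' @param out_dir Output directory (created if needed); overrides
#'   `cfg$out_dir`.
#' @return List with `abundance`, `relative`, `confusion`, `report`
#'   (paths in `report$files`), invisibly writing the files.
#' @export
#' @examples
#' cfg_path <- system.file("extdata", "oxcom6.json", package = "dfmcyto")
#' res <- run_pipeline(cfg_path, out_dir = tempfile("dfmrun"))
#' head(res$abundance)
run_pipeline <- function(cfg, out_dir = NULL) {
  cfg_path <- if (is.character(cfg)) cfg else NULL
  cfg <- validate_run_config(cfg)
  out_dir <- out_dir %||% cfg$out_dir %||% stop_dfm("no output directory")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  all_strains <- dfm_strains(include_unlabelled = TRUE)
  specs <- all_strains[cfg$strains]
  if (anyNA(names(specs)))
    stop_dfm("[simulate] unknown strain id in config")
  noise_args <- cfg$noise %||% list()
  gating_args <- cfg$gating %||% list()
  gcfg <- do.call(gating_config, gating_args)

  samples <- if (is.data.frame(cfg$samples))
    split(cfg$samples, seq_len(nrow(cfg$samples))) else cfg$samples

  abundance <- list(); confusion <- list()
  for (i in seq_along(samples)) {
    s <- as.list(samples[[i]])
    meta <- tryCatch(.meta_from_row(s),
                     error = function(e) stop_dfm("[quantify] ",
                                                  conditionMessage(e)))
    seed_i <- (cfg$seed + 1009L * i) %% 2147483647L
    noise <- do.call(noise_model, c(noise_args, list(seed = seed_i)))
    ev <- simulate_mixture(specs, cfg$proportions, cfg$n_events,
                           noise = noise)
    lab <- gate_chain(ev, gcfg)
    abundance[[i]] <- abundance_table(lab, meta)
    sc <- score_assignments(lab, ev$truth)
    confusion[[i]] <- data.frame(
      sample_id = meta$sample_id, strain = rownames(sc$matrix),
      as.data.frame.matrix(sc$matrix),
      accuracy = sc$per_class_accuracy[rownames(sc$matrix)],
      stringsAsFactors = FALSE)
  }
  ab <- do.call(rbind, abundance)

  if (!is.null(cfg$background)) {
    bg <- cfg$background
    bgt <- do.call(rbind, lapply(seq_len(bg$n_replicates), function(j) {
      seed_j <- (cfg$seed + 7717L * j) %% 2147483647L
      bev <- simulate_root_background(
        bg$n_events, noise = root_noise_model(bg$plant, seed = seed_j),
        plant = bg$plant)
      blab <- gate_chain(bev, gcfg)
      bmeta <- sample_meta(paste0("bg", j), analysed_volume_mL = 0.1,
                           root_mass_g = 0.5, plant = bg$plant,
                           replicate = j)
      abundance_table(blab, bmeta)
    }))
    if (cfg$subtract_background) ab <- subtract_background(ab, bgt)
    utils::write.csv(bgt, file.path(out_dir, "background.csv"),
                     row.names = FALSE)
  }
  rel <- to_relative(ab)
  conf <- do.call(rbind, confusion)

  f_ab <- file.path(out_dir, "abundance.csv")
  f_rel <- file.path(out_dir, "relative.csv")
  f_conf <- file.path(out_dir, "confusion.csv")
  utils::write.csv(ab, f_ab, row.names = FALSE)
  utils::write.csv(rel, f_rel, row.names = FALSE)
  utils::write.csv(conf, f_conf, row.names = FALSE)

  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_file, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  report <- list(
    name = cfg$name, seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    config_source = cfg_path,
    package_version = as.character(utils::packageVersion("dfmcyto")),
    r_version = R.version.string,
    files = list(abundance = f_ab, relative = f_rel, confusion = f_conf))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(abundance = ab, relative = rel, confusion = conf,
                 report = report))
}

#' Command-line entry point
#'
#' Thin CLI over the package: `Rscript -e 'dfmcyto::dfm_cli()' run
#' --config cfg.json --out outdir [--seed 3841]`.  Subcommands: `run`
#' (full pipeline), `simulate` (write a simulated mixture as CSV),
#' `growth` (MGT per well from a plate-reader CSV), `attmap` (offset
#' calls from junction FASTA plus reference FASTA).
#'
#' @param args Character vector of CLI arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status 0 on success, invisibly.
#' @export
dfm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: dfm_cli <run|simulate|growth|attmap> [--config F] [--out F]",
    "[--seed N] [--n N] [--glms F] [--tn7r F]")
  if (length(args) == 0) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- list(seed = 3841L, n = 10000L)
  a <- args[-1]
  while (length(a) >= 2) {
    key <- sub("^--", "", a[1]); opt[[key]] <- a[2]; a <- a[-(1:2)]
  }
  opt$seed <- as.integer(opt$seed); opt$n <- as.integer(opt$n)
  switch(cmd,
    run = {
      cfg <- validate_run_config(opt$config)
      cfg$seed <- opt$seed
      run_pipeline(cfg, out_dir = opt$out)
    },
    simulate = {
      mix <- simulate_mixture(dfm_strains(), rep(1 / 6, 6), opt$n,
                              noise = noise_model(seed = opt$seed))
      write_event_csv(mix, opt$out)
    },
    growth = {
      curves <- read_growth_csv(opt$config)
      res <- do.call(rbind, lapply(names(curves), function(w) {
        e <- estimate_mgt(curves[[w]])
        data.frame(well = w, mgt_h = e$mgt, mu = e$mu, r2 = e$r2,
                   valid = e$valid)
      }))
      utils::write.csv(res, opt$out, row.names = FALSE)
    },
    attmap = {
      reads <- read_fasta(opt$config)
      glms <- read_fasta(opt$glms)[[1]]
      tn7r <- read_fasta(opt$tn7r)[[1]]
      res <- do.call(rbind, lapply(names(reads), function(nm) {
        cl <- call_att(list(read_seq = reads[[nm]], glms_ref = glms,
                            tn7r_seq = tn7r))
        data.frame(strain = nm, offset_bp = cl$offset_bp,
                   dup_seq = cl$dup_seq, valid = cl$valid)
      }))
      utils::write.csv(res, opt$out, row.names = FALSE)
    },
    { message(usage); return(invisible(1L)) })
  invisible(0L)
}
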