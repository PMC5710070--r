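# Command-line entry points binding the pipeline together. The exported
# rrfi_cli() is wrapped by the thin Rscript in inst/scripts/rrfi.R; it is an
# ordinary R function so the argument handling and every subcommand are
# testable without a shell. Exit codes: 0 success, 1 usage, 2 data error,
# 3 numerical failure.

#' Read raw phenotype input tables
#'
#' @param path delimited text file (tab or whitespace), header required.
#' @return data.frame.
#' @export
read_table_file <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
}

# internal: parse "--flag value" pairs after the subcommand
parse_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop("unexpected argument: ", args[i])
    key <- sub("^--", "", args[i])
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stop("flag --", key, " needs a value")
    out[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  out
}

flag_or <- function(flags, name, default) {
  if (!is.null(flags[[name]])) flags[[name]] else default
}

# internal: write the run manifest next to the outputs
write_manifest <- function(outdir, subcommand, flags) {
  manifest <- list(
    subcommand = subcommand,
    flags = flags,
    seed = flag_or(flags, "seed", NA),
    package = "rrfi",
    version = as.character(utils::packageVersion("rrfi")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

cli_usage <- function() {
  cat("usage: rrfi <subcommand> [--flag value ...]\n",
      "subcommands:\n",
      "  fixture  --out DIR [--seed N] [--missing-frac F]\n",
      "  prep     --daily F --events F --assignments F --out DIR\n",
      "  fit      --records F --pedigree F --model 1..8 --out DIR\n",
      "           [--iters N] [--burnin N] [--thin N] [--chains N] [--seed N]\n",
      "  compare  --records F --pedigree F --models 1,8 --out DIR [...]\n",
      "  params   --records F --pedigree F --model M --out DIR [...]\n",
      "  simulate --scenario RFI --out DIR [--replicates N]\n",
      "           [--generations N] [--seed N]\n",
      sep = "")
}

cli_fit_one <- function(flags, code) {
  records <- read_table_file(flags$records)
  ped <- read_pedigree(flags$pedigree)
  system <- build_design_system(records, model_spec(code), pedigree = ped)
  config <- chain_config(
    n_iter = as.integer(flag_or(flags, "iters", 50000L)),
    burn_in = as.integer(flag_or(flags, "burnin", 10000L)),
    thin = as.integer(flag_or(flags, "thin", 10L)),
    n_chains = as.integer(flag_or(flags, "chains", 2L)),
    seed = as.integer(flag_or(flags, "seed", 1L)))
  gibbs_sample(system, config)
}

# internal: samples as a long (chain, iteration, parameter, value) table
samples_long <- function(fit) {
  do.call(rbind, lapply(seq_along(fit$chains), function(ch) {
    m <- fit$chains[[ch]]
    data.frame(chain = ch, iteration = rep(seq_len(nrow(m)), ncol(m)),
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  }))
}

#' Command-line interface to the pipeline
#'
#' Subcommands: `fixture` (write a synthetic raw dataset), `prep` (raw tables
#' to weekly records), `fit` (Gibbs sampling of one model), `compare` (DIC
#' table across model codes), `params` (genetic-parameter posterior table),
#' `simulate` (selection-scenario simulation). Every run writes its outputs
#' plus a `manifest.json` recording the subcommand, flags, seed and package
#' version; inputs are never mutated.
#'
#' @param argv character vector of arguments (as from `commandArgs(TRUE)`).
#' @return integer exit status (invisibly): 0 success, 1 usage error, 2 data
#'   error, 3 numerical failure.
#' @export
rrfi_cli <- function(argv) {
  if (!length(argv) || argv[1L] %in% c("-h", "--help", "help")) {
    cli_usage()
    return(invisible(if (length(argv)) 0L else 1L))
  }
  sub <- argv[1L]
  status <- tryCatch({
    flags <- parse_flags(argv[-1L])
    outdir <- flags$out
    if (is.null(outdir)) stop("--out is required")
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    switch(sub,
      fixture = {
        cfg <- fixture_config(
          seed = as.integer(flag_or(flags, "seed", 1L)),
          missing_frac = as.numeric(flag_or(flags, "missing-frac", 0.05)))
        ds <- generate_observational_dataset(cfg)
        write_fixture_files(ds, outdir)
      },
      prep = {
        daily <- read_table_file(flags$daily)
        events <- read_table_file(flags$events)
        assignments <- read_table_file(flags$assignments)
        weekly <- prep_weekly(daily, events, assignments)
        utils::write.table(weekly, file.path(outdir, "weekly_records.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      },
      fit = {
        fit <- cli_fit_one(flags, as.integer(flags$model))
        utils::write.table(samples_long(fit),
                           file.path(outdir, "samples.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(
          data.frame(parameter = fit$param_names[-length(fit$param_names)],
                     mean = colMeans(merged_draws(fit))[-length(fit$param_names)]),
          file.path(outdir, "posterior_means.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
        d <- dic(fit)
        utils::write.table(
          data.frame(dic = d$dic, mean_deviance = d$mean_deviance,
                     p_d = d$p_d),
          file.path(outdir, "dic.tsv"), sep = "\t", quote = FALSE,
          row.names = FALSE)
      },
      compare = {
        codes <- as.integer(strsplit(flags$models, ",")[[1L]])
        rows <- lapply(codes, function(code) {
          fit <- cli_fit_one(flags, code)
          d <- dic(fit)
          data.frame(model = code, dic = d$dic,
                     mean_deviance = d$mean_deviance, p_d = d$p_d)
        })
        utils::write.table(do.call(rbind, rows),
                           file.path(outdir, "dic_table.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      },
      params = {
        fit <- cli_fit_one(flags, as.integer(flags$model))
        utils::write.table(genetic_parameter_table(fit),
                           file.path(outdir, "genetic_parameters.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      },
      simulate = {
        cfg <- sim_config(
          scenario = flag_or(flags, "scenario", "RFI"),
          n_replicates = as.integer(flag_or(flags, "replicates", 50L)),
          n_generations = as.integer(flag_or(flags, "generations", 3L)),
          seed = as.integer(flag_or(flags, "seed", 1L)))
        res <- run_scenario(cfg)
        utils::write.table(
          data.frame(quantity = names(res$response), mean = res$response,
                     sd = res$response_sd),
          file.path(outdir, "responses.tsv"), sep = "\t", quote = FALSE,
          row.names = FALSE)
        utils::write.table(
          data.frame(metric = names(res$metrics), mean = res$metrics,
                     sd = res$metrics_sd),
          file.path(outdir, "selection_metrics.tsv"), sep = "\t",
          quote = FALSE, row.names = FALSE)
      },
      {
        cli_usage()
        stop("unknown subcommand: ", sub)
      })
    write_manifest(outdir, sub, flags)
    0L
  }, error = function(e) {
    message("rrfi ", sub, ": ", conditionMessage(e))
    if (grepl("usage|unknown subcommand|required|needs a value|unexpected",
              conditionMessage(e))) 1L
    else if (grepl("not found|lack|column|unknown|empty|fewer", conditionMessage(e))) 2L
    else 3L
  })
  invisible(status)
}
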