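# End-to-end orchestration: config validation, provenance, file I/O.

# FNV-1a hash of a string, reported as 8 hex digits. All arithmetic is done
# on 16-bit limbs in doubles: R has no unsigned 32-bit integers and a direct
# 32x24-bit product would exceed double precision.
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 65536
    hi <- h %/% 65536
    lo <- bitwXor(as.integer(lo), b)      # b < 256: only the low byte changes
    # (hi*2^16 + lo) * 16777619 mod 2^32
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(config) {
  fnv1a(as.character(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)))
}

#' Write a CSV with a provenance comment line
#'
#' All pipeline CSVs carry a leading `# provenance:` comment recording the
#' config hash and seed that produced them; read them back with
#' `read.csv(..., comment.char = "#")`.
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param provenance Character provenance string.
#' @export
write_csv_prov <- function(df, path, provenance = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# provenance:", provenance), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read / write multi-page TIFF stacks
#'
#' Thin wrappers around the tiff package: one page per frame, 32-bit float.
#' Intensities are stored as-is (no rescaling).
#'
#' @param frames List of numeric matrices.
#' @param path File path.
#' @return `read_tiff_stack` returns a list of matrices.
#' @export
write_tiff_stack <- function(frames, path) {
  mx <- max(unlist(lapply(frames, max)), 1)
  tiff::writeTIFF(lapply(frames, function(f) f / mx), path,
                  bits.per.sample = 32L)
  # store the scale so intensities can be restored exactly
  writeLines(as.character(mx), paste0(path, ".scale"))
  invisible(path)
}

#' @rdname write_tiff_stack
#' @export
read_tiff_stack <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  scale_file <- paste0(path, ".scale")
  if (file.exists(scale_file)) {
    mx <- as.numeric(readLines(scale_file))
    frames <- lapply(frames, function(f) f * mx)
  }
  frames
}

pipeline_schema <- list(
  seed = c("integer"),
  motif = list(kind = "character", family = "character"),
  protocol = list(mode = "character", duration = "numeric", t_on = "numeric",
                  t_off = "numeric"),
  input = list(grid_dt = "numeric"),
  cohort = list(n_nuclei = "numeric", onset_jitter_sd = "numeric",
                noise_sd = "numeric", intensity_scale = "numeric"),
  fit = list(n_starts = "numeric", n_hops = "numeric", maxit = "numeric"),
  perturbations = c("character"),
  summary = list(window = "numeric", min_points = "numeric",
                 ci_level = "numeric", rate_window = "numeric")
)

validate_config <- function(config, schema = pipeline_schema, path = "") {
  for (key in names(config)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(schema))
      stop("unknown configuration key: '", full, "'", call. = FALSE)
    if (is.list(schema[[key]]) && is.list(config[[key]]))
      validate_config(config[[key]], schema[[key]], full)
  }
  invisible(TRUE)
}

#' Demonstration pipeline configuration
#'
#' A small, fast configuration exercising the whole chain on synthetic data.
#'
#' @param seed Integer seed.
#' @return Named list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 1) {
  list(
    seed = seed,
    motif = list(kind = "state_dependent_inactivation", family = "elementary"),
    protocol = list(mode = "continuous", duration = 40),
    input = list(grid_dt = 0.1),
    cohort = list(n_nuclei = 60, onset_jitter_sd = 0.5, noise_sd = 3,
                  intensity_scale = 300),
    fit = list(n_starts = 3, n_hops = 1, maxit = 60),
    perturbations = c("attenuator_ko", "stabilize_active"),
    summary = list(window = 1, min_points = 9, ci_level = 0.95,
                   rate_window = 7)
  )
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the configured chain: build the activation protocol and the
#' nuclear-input profile from the published import-export parameters,
#' simulate a ground-truth expression cohort from the published fitted motif
#' parameters, refit the motif to the pooled total intensity, simulate the
#' applicable in-silico perturbations with the fitted parameters, and
#' summarise the cohort (running mean, confidence intervals, activation
#' rate). All intermediates are written to `out_dir` with provenance (config
#' hash + seed); reruns with the same config are byte-identical.
#'
#' @param config Named list (see [demo_config()]) or path to a YAML file.
#' @param out_dir Output directory, created if missing.
#' @return Invisibly, a list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config = demo_config(), out_dir = tempfile("pipeline")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  config <- modifyList(demo_config(), config)
  hash <- config_hash(config)
  prov <- sprintf("optomotif config %s seed %d", hash, config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  res <- tryCatch({
    stage <- "input"
    proto <- if (config$protocol$mode == "continuous")
      protocol_continuous(config$protocol$duration)
    else protocol_pulsatile(config$protocol$duration,
                            config$protocol$t_on %||% 5,
                            config$protocol$t_off %||% 10)
    ref <- ie_reference_params()
    input <- build_input_profile(
      proto, ref$light, ref$dark, ref$initial_light,
      t_grid = seq(0, config$protocol$duration, by = config$input$grid_dt))
    write_csv_prov(input, file.path(out_dir, "input_profile.csv"), prov)

    stage <- "cohort"
    true_params <- motif_reference_params(config$motif$kind,
                                          config$motif$family)
    coh <- simulate_expression_cohort(
      true_params, input, n_nuclei = config$cohort$n_nuclei,
      onset_jitter_sd = config$cohort$onset_jitter_sd,
      noise_sd = config$cohort$noise_sd,
      t_grid = seq(0.5, config$protocol$duration, by = 0.5),
      intensity_scale = config$cohort$intensity_scale, seed = config$seed)
    write_csv_prov(coh$total_intensity,
                   file.path(out_dir, "total_intensity.csv"), prov)
    write_csv_prov(coh$counts, file.path(out_dir, "counts.csv"), prov)

    stage <- "fit"
    cfg <- fit_config(n_starts = config$fit$n_starts,
                      n_hops = config$fit$n_hops, maxit = config$fit$maxit,
                      seed = config$seed)
    fit <- fit_motif(config$motif$kind, config$motif$family,
                     data = coh$total_intensity, input = input, config = cfg)
    jsonlite::write_json(
      list(kind = fit$kind, family = fit$family, k = as.list(fit$params$k),
           h = as.list(fit$params$h), loss = fit$loss, seed = fit$seed,
           bound_hits = fit$bound_hits, provenance = prov),
      file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA,
      na = "null")

    stage <- "perturb"
    pert_rows <- lapply(config$perturbations, function(p) {
      pp <- apply_perturbation(fit$params, p)
      sim <- simulate_motif(pp, input)
      m <- adaptation_metrics(sim)
      data.frame(perturbation = p, peak = m$peak, final = m$final,
                 adaptation_index = m$adaptation_index)
    })
    base_m <- adaptation_metrics(simulate_motif(fit$params, input))
    pert <- rbind(data.frame(perturbation = "none", peak = base_m$peak,
                             final = base_m$final,
                             adaptation_index = base_m$adaptation_index),
                  do.call(rbind, pert_rows))
    write_csv_prov(pert, file.path(out_dir, "perturbations.csv"), prov)

    stage <- "summarise"
    rm_ <- running_mean(coh$traces$time, coh$traces$value,
                        window = config$summary$window,
                        min_points = config$summary$min_points)
    cis <- do.call(rbind, lapply(split(coh$traces$value, coh$traces$time),
                                 function(v) {
      ci <- normal_ci(v, level = config$summary$ci_level)
      if (is.null(ci)) c(NA_real_, NA_real_) else ci
    }))
    summ <- data.frame(time = as.numeric(rownames(cis)),
                       ci_lower = cis[, 1], ci_upper = cis[, 2])
    summ <- merge(rm_, summ, by = "time", all = TRUE)
    names(summ)[names(summ) == "value"] <- "running_mean"
    write_csv_prov(summ, file.path(out_dir, "summary.csv"), prov)
    rate <- activation_rate(coh$counts$time, coh$counts$value,
                            window = c(0, config$summary$rate_window))

    jsonlite::write_json(
      list(config = config, config_hash = hash, seed = config$seed,
           package_version = as.character(utils::packageVersion("optomotif")),
           activation_rate = rate),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
    list(input = input, cohort = coh, fit = fit, perturbations = pert,
         summary = summ, activation_rate = rate, out_dir = out_dir,
         config_hash = hash)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         " (partial outputs in ", out_dir, ")", call. = FALSE)
  })
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
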