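# Run configuration is TOML; no TOML parser ships with the installed R
# stack, so a small subset reader is implemented here: [section] and
# [section.sub] headers, and key = value lines where value is a number, a
# boolean, a double-quoted string, or a flat array of those.

#' Read a TOML-subset configuration file
#'
#' @param path TOML file.
#' @return Nested named list.
#' @export
read_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  config <- list()
  section <- character(0)
  for (i in seq_along(lines)) {
    line <- sub("(^|[^\"])#.*$", "\\1", lines[[i]])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[[^]]+\\]$", line)) {
      section <- strsplit(gsub("^\\[|\\]$", "", line), ".", fixed = TRUE)[[1L]]
      next
    }
    m <- regmatches(line, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", line))[[1L]]
    if (length(m) != 3L) {
      stop_erfrag(sprintf("cannot parse TOML line %d: %s", i, lines[[i]]),
                  "erfrag_parse_error")
    }
    config <- assign_nested(config, c(section, m[[2L]]),
                            parse_toml_value(m[[3L]], i))
  }
  config
}

assign_nested <- function(x, path, value) {
  if (length(path) == 1L) {
    x[[path]] <- value
    return(x)
  }
  head <- path[[1L]]
  if (is.null(x[[head]])) x[[head]] <- list()
  x[[head]] <- assign_nested(x[[head]], path[-1L], value)
  x
}

parse_toml_value <- function(txt, line_no) {
  txt <- trimws(txt)
  if (grepl("^\\[.*\\]$", txt)) {
    inner <- trimws(gsub("^\\[|\\]$", "", txt))
    if (!nzchar(inner)) return(list())
    parts <- trimws(strsplit(inner, ",", fixed = TRUE)[[1L]])
    return(unlist(lapply(parts, parse_toml_value, line_no = line_no)))
  }
  if (txt %in% c("true", "false")) return(txt == "true")
  if (grepl("^\".*\"$", txt)) return(gsub("^\"|\"$", "", txt))
  num <- suppressWarnings(as.numeric(txt))
  if (!is.na(num)) return(num)
  stop_erfrag(sprintf("unsupported TOML value on line %d: %s", line_no, txt),
              "erfrag_parse_error")
}

#' Default demonstration run configuration
#'
#' A small end-to-end configuration exercising every stage at desk scale.
#'
#' @param seed Master seed.
#' @return Nested configuration list (the [run_pipeline()] input).
#' @export
demo_config <- function(seed = 20260918) {
  list(
    seed = seed,
    stages = list(photobleach = TRUE, morphometry = TRUE, omics = TRUE,
                  kinetics = TRUE),
    photobleach = list(
      lattice_rows = 24, lattice_cols = 24, particles_per_site = 10,
      total_time = 80, frame_interval = 0.5,
      immobile_fraction_connected = 0.10, immobile_fraction_fragmented = 0.65,
      noise_sd = 0.02, n_replicates = 3,
      deplete_below = 0.25, preserve_above = 0.75
    ),
    morphometry = list(n_cells = 60, inclusion_prevalence = 0.40,
                       image_size = 128),
    omics = list(n_genes = 800, n_up = 40, n_down = 40, n_replicates = 5,
                 n_a_exclusive = 14, n_b_exclusive = 3),
    kinetics = list(k_deg = 0.70, k_sec = 0.15, k_ret = 0.15, noise_sd = 0.02)
  )
}

#' Validate a run configuration against every stage's preconditions
#'
#' Checks each configured stage block without executing anything.
#'
#' @param config Configuration list or path to a TOML file.
#' @return Tibble with `field` (module/field path) and `message`; zero rows
#'   means the configuration is valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_toml(config)
  problems <- list()
  flag <- function(field, message) {
    problems[[length(problems) + 1L]] <<- tibble(field = field, message = message)
  }
  num_in <- function(block, name, field, lower, upper) {
    v <- config[[block]][[name]]
    if (!is.null(v) && (!is.numeric(v) || v < lower || v > upper)) {
      flag(field, sprintf("must lie in [%s, %s], got %s", lower, upper, v))
    }
  }
  num_in("morphometry", "inclusion_prevalence",
         "generate_cell_population.inclusion_prevalence", 0, 1)
  num_in("morphometry", "n_cells", "generate_cell_population.n_cells", 1, Inf)
  num_in("photobleach", "immobile_fraction_connected",
         "simulate_photobleach.immobile_fraction", 0, 1)
  num_in("photobleach", "immobile_fraction_fragmented",
         "simulate_photobleach.immobile_fraction", 0, 1)
  num_in("photobleach", "noise_sd", "simulate_photobleach.noise_sd", 0, Inf)
  pb <- config$photobleach
  if (!is.null(pb$deplete_below) && !is.null(pb$preserve_above) &&
      pb$deplete_below >= pb$preserve_above) {
    flag("classify_connectivity.thresholds",
         "deplete_below must be smaller than preserve_above")
  }
  om <- config$omics
  if (!is.null(om$n_up) && !is.null(om$n_down) && !is.null(om$n_genes) &&
      om$n_up + om$n_down > om$n_genes) {
    flag("generate_omics.n_up", "n_up + n_down must not exceed n_genes")
  }
  kin <- config$kinetics
  if (!is.null(kin)) {
    rates <- c(kin$k_deg, kin$k_sec, kin$k_ret)
    if (any(rates < 0) || sum(rates) <= 0) {
      flag("generate_pulse_chase.rates", "rates must be >= 0 with a positive sum")
    }
  }
  if (length(problems) == 0L) {
    tibble(field = character(0), message = character(0))
  } else {
    dplyr::bind_rows(problems)
  }
}

#' Run the full simulate-quantify-report pipeline
#'
#' Executes the enabled stages in dependency order — photobleach simulation
#' and quantification, image morphometry, omics integration, pulse-chase
#' kinetics — writing per-stage TSV outputs and a combined JSON summary.
#' One master seed deterministically spawns per-stage substreams, so
#' toggling a stage leaves the other stages' draws unchanged and re-running
#' with the recorded seed reproduces every output exactly.
#'
#' @param config Configuration list (see [demo_config()]) or TOML path.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of `config$seed`.
#' @return The summary list, invisibly; written to `out_dir/summary.json`.
#' @export
run_pipeline <- function(config = demo_config(), out_dir = tempfile("erfrag_run_"),
                         seed = NULL) {
  if (is.character(config)) config <- read_toml(config)
  problems <- validate_config(config)
  if (nrow(problems) > 0L) {
    stop_erfrag(paste0("invalid configuration:\n",
                       paste0("  ", problems$field, ": ", problems$message,
                              collapse = "\n")),
                "erfrag_config_error")
  }
  if (!is.null(seed)) config$seed <- seed
  if (is.null(config$seed)) config$seed <- 1
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||% list()
  on_stage <- function(s) isTRUE(stages[[s]])
  summary <- list(seed = config$seed, config_hash = rlang::hash(config),
                  stages_run = names(Filter(isTRUE, stages)))

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop_erfrag(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                  "erfrag_stage_error")
    })
  }

  if (on_stage("photobleach")) {
    summary$photobleach <- run_stage("photobleach", function()
      pipeline_photobleach(config$photobleach, derive_seed(config$seed, "photobleach"),
                           out_dir))
  }
  if (on_stage("morphometry")) {
    summary$morphometry <- run_stage("morphometry", function()
      pipeline_morphometry(config$morphometry, derive_seed(config$seed, "morphometry"),
                           out_dir))
  }
  if (on_stage("omics")) {
    summary$omics <- run_stage("omics", function()
      pipeline_omics(config$omics, derive_seed(config$seed, "omics"), out_dir))
  }
  if (on_stage("kinetics")) {
    summary$kinetics <- run_stage("kinetics", function()
      pipeline_kinetics(config$kinetics, derive_seed(config$seed, "kinetics"),
                        out_dir))
  }
  write_report_json(summary, file.path(out_dir, "summary.json"))
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_photobleach <- function(p, seed, out_dir) {
  p <- utils::modifyList(demo_config()$photobleach, p %||% list())
  connected <- make_reticular_geometry(p$lattice_rows, p$lattice_cols)
  frag <- make_fragmented_geometry(1, 10, include_residual_reticulum = TRUE)
  frap_proto <- function(roi) bleach_protocol(roi, "FRAP", pulse_times = 5,
                                              frame_interval = p$frame_interval)
  arms <- list(
    connected = list(geometry = connected, roi = roi_rect(2, 6, 2, 6),
                     immobile = p$immobile_fraction_connected),
    fragmented = list(geometry = frag, roi = roi_rect(0, 5, 0, 5),
                      immobile = p$immobile_fraction_fragmented)
  )
  fits <- purrr::imap_dfr(arms, function(arm, arm_name) {
    purrr::map_dfr(seq_len(p$n_replicates), function(r) {
      tr <- simulate_photobleach(
        arm$geometry, frap_proto(arm$roi), total_time = p$total_time,
        particles_per_site = p$particles_per_site,
        immobile_fraction = arm$immobile, noise_sd = p$noise_sd,
        seed = seed + 97L * r + ifelse(arm_name == "connected", 0L, 1000L)
      )
      fit <- fit_frap(normalize_prebleach(tr))
      dplyr::mutate(tidy(fit), arm = arm_name, replicate = r)
    })
  })
  readr::write_tsv(fits, file.path(out_dir, "frap_fits.tsv"))
  slopes <- split(fits$initial_slope, fits$arm)
  slope_test <- if (all(lengths(slopes) >= 2)) {
    compare_groups(slopes$connected, slopes$fragmented)
  } else NULL

  # FLIP on a connected reticulum vs. two isolated inclusions
  flip_geo <- make_fragmented_geometry(2, c(5, 5))
  flip_proto <- bleach_protocol(roi_rect(0, 5, 0, 5), "FLIP",
                                pulse_times = seq(5, 65, by = 5),
                                frame_interval = 0.5)
  flip_tr <- simulate_photobleach(
    flip_geo, flip_proto,
    rois = list(other_inclusion = roi_rect(6, 11, 0, 5)),
    total_time = 75, particles_per_site = p$particles_per_site,
    immobile_fraction = 0, noise_sd = p$noise_sd, seed = seed + 7L
  )
  calls <- classify_connectivity(flip_depletion(normalize_prebleach(flip_tr)),
                                 deplete_below = p$deplete_below,
                                 preserve_above = p$preserve_above)
  readr::write_tsv(calls, file.path(out_dir, "flip_calls.tsv"))
  list(
    mean_mobile_fraction = purrr::map(split(fits$mobile_fraction, fits$arm), mean),
    slope_p = if (!is.null(slope_test)) slope_test$p else NA,
    connectivity_calls = stats::setNames(as.character(calls$connectivity_call),
                                         calls$roi_id),
    provenance = list(stage = "photobleach", seed = seed, params = p)
  )
}

pipeline_morphometry <- function(p, seed, out_dir) {
  p <- utils::modifyList(demo_config()$morphometry, p %||% list())
  pop <- generate_cell_population(p$n_cells, p$inclusion_prevalence,
                                  image_size = p$image_size, seed = seed)
  morph <- classify_population(pop$images)
  readr::write_tsv(morph, file.path(out_dir, "cell_morphology.tsv"))
  s <- population_summary(morph)
  list(
    prevalence_percent = 100 * s$prevalence,
    prevalence_ci_percent = as.list(100 * s$prevalence_ci),
    class_percent = stats::setNames(as.list(s$class_summary$percent),
                                    s$class_summary$size_class),
    n_cells = s$n_cells,
    provenance = list(stage = "morphometry", seed = seed, params = p)
  )
}

pipeline_omics <- function(p, seed, out_dir) {
  p <- utils::modifyList(demo_config()$omics, p %||% list())
  sim <- generate_omics(n_genes = p$n_genes, n_up = p$n_up, n_down = p$n_down,
                        n_replicates = p$n_replicates,
                        n_a_exclusive = p$n_a_exclusive,
                        n_b_exclusive = p$n_b_exclusive, seed = seed)
  de <- differential_expression(sim$counts, sim$groups, condition_a = "A")
  readr::write_tsv(de, file.path(out_dir, "de_table.tsv"))
  excl <- exclusive_sets(sim$presence_a, sim$presence_b)
  integ <- integrate_gene_protein(de, sim$protein_fc)
  up_genes <- de$gene_id[de$direction == "up"]
  enr <- if (length(up_genes) > 0) ora(up_genes, sim$annotation, sim$universe) else NULL
  if (!is.null(enr)) readr::write_tsv(enr, file.path(out_dir, "ora.tsv"))
  ds <- de_summary(de)
  list(
    de = as.list(ds),
    exclusivity = list(a_exclusive = length(excl$a_exclusive),
                       b_exclusive = length(excl$b_exclusive),
                       union = length(excl$union)),
    integration = as.list(integ$counts),
    top_term = if (!is.null(enr) && nrow(enr) > 0) enr$term_id[[1L]] else NA,
    provenance = list(stage = "omics", seed = seed, params = p)
  )
}

pipeline_kinetics <- function(p, seed, out_dir) {
  p <- utils::modifyList(demo_config()$kinetics, p %||% list())
  chase <- generate_pulse_chase(p$k_deg, p$k_sec, p$k_ret,
                                noise_sd = p$noise_sd, seed = seed)
  readr::write_tsv(chase, file.path(out_dir, "pulse_chase.tsv"))
  fit <- fit_pulse_chase(chase)
  list(
    fractions_percent = list(degraded = 100 * fit$f_deg,
                             secreted = 100 * fit$f_sec,
                             retained = 100 * fit$f_ret),
    rates = list(k_deg = fit$k_deg, k_sec = fit$k_sec, k_ret = fit$k_ret),
    provenance = list(stage = "kinetics", seed = seed, params = p)
  )
}
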