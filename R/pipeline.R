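# End-to-end orchestration: simulate (or ingest) -> score -> analyze, with a
# single top-level seed fanned out to per-stage child seeds, plus the tiny
# synthetic fixtures used by the test suite.

# Deterministic seed splitting: child k of seed s. Linear congruential step
# keeps children below 2^31 and distinct across stages.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 9973) %% 2147483647)
}

#' Default pipeline configuration
#'
#' @param seed top-level seed; every stage derives its own child seed from it.
#' @param n_sessions experiment sessions (default 6).
#' @param correction extreme-rate correction for scoring.
#' @param alpha significance threshold for the analysis report.
#' @param target_r2 population r-squared of the severity link.
#' @param sd_d,sd_c between-observer heterogeneity of the simulated groups
#'   (applied to every group; defaults 0).
#' @param severity_covariates covariate columns for the severity regression.
#' @return A list of class `"pipeline_config"`.
#' @export
default_config <- function(seed = 1L, n_sessions = 6L,
                           correction = "half_count", alpha = 0.05,
                           target_r2 = 0.62, sd_d = 0, sd_c = 0,
                           severity_covariates = character(0)) {
  structure(list(seed = as.integer(seed), n_sessions = as.integer(n_sessions),
                 correction = correction, alpha = alpha,
                 target_r2 = target_r2, sd_d = sd_d, sd_c = sd_c,
                 severity_covariates = severity_covariates),
            class = "pipeline_config")
}

# Synthetic stimulus manifest large enough for an n-session experiment.
synthetic_manifest <- function(n_sessions) {
  n <- 5L * n_sessions
  data.frame(
    stimulus_id = c(sprintf("test_%02d", seq_len(n)),
                    sprintf("ctrl_%02d", seq_len(n))),
    template_id = c(sprintf("tpl_test_%02d", seq_len(n)),
                    sprintf("tpl_ctrl_%02d", seq_len(n))),
    is_test = rep(c(TRUE, FALSE), each = n),
    stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' Builds (or accepts) an experiment plan, simulates a calibrated cohort (or
#' ingests provided trial logs), scores every participant, runs the group
#' analysis, and optionally writes all intermediate tables plus the report
#' and a provenance record to `out_dir`. Deterministic given the config.
#'
#' @param config a [default_config()] list.
#' @param logs optional named list of real trial logs; when supplied the
#'   simulation stage is skipped and `metadata` must be given too.
#' @param metadata metadata table matching `logs` (ignored when simulating).
#' @param specs group specifications for simulation
#'   (default [default_cohort_spec()], heterogeneity from the config).
#' @param out_dir optional directory for CSV/JSON outputs.
#' @return List of class `"pipeline_result"`: `plan`, `cohort`, `scores`,
#'   `report`, `config`.
#' @export
run_pipeline <- function(config = default_config(), logs = NULL,
                         metadata = NULL, specs = NULL, out_dir = NULL) {
  if (is.null(config$seed)) stop("config is missing key 'seed'", call. = FALSE)
  manifest <- synthetic_manifest(config$n_sessions)
  plan <- build_experiment(manifest, n_sessions = config$n_sessions,
                           seed = child_seed(config$seed, 1L))
  cohort <- NULL
  if (is.null(logs)) {
    if (is.null(specs)) {
      specs <- default_cohort_spec()
      if (config$sd_d > 0 || config$sd_c > 0)
        specs <- lapply(specs, function(s) { s$sd_d <- config$sd_d; s$sd_c <- config$sd_c; s })
    }
    cohort <- simulate_cohort(specs, plan, seed = child_seed(config$seed, 2L))
    if (any(cohort$metadata$group == "lbd_vh")) {
      sev_feasible <- stats::sd(with(cohort$metadata[cohort$metadata$group == "lbd_vh", ],
                                     true_d_after - true_d_before)) > 0
      if (sev_feasible)
        cohort <- attach_severity(cohort, target_r2 = config$target_r2,
                                  seed = child_seed(config$seed, 3L))
    }
    logs <- cohort$logs
    metadata <- cohort$metadata
  } else if (is.null(metadata)) {
    stop("config/inputs incomplete: trial logs supplied without metadata",
         call. = FALSE)
  }
  scores <- score_cohort(logs, correction = config$correction)
  report <- run_full_analysis(scores, metadata, alpha = config$alpha,
                              severity_covariates = config$severity_covariates)
  result <- structure(list(plan = plan, cohort = cohort, scores = scores,
                           report = report, config = config),
                      class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(scores, file.path(out_dir, "scores.csv"), row.names = FALSE)
    utils::write.csv(metadata, file.path(out_dir, "metadata.csv"), row.names = FALSE)
    report_to_json(report, file.path(out_dir, "report.json"))
    prov <- list(seed = config$seed,
                 config = unclass(config),
                 r_version = as.character(getRversion()),
                 package_version = as.character(utils::packageVersion("mooneysdt")))
    writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE),
               file.path(out_dir, "provenance.json"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result (seed", x$config$seed, ")\n\n")
  print(x$report)
  invisible(x)
}

#' Synthetic portrait template for tests and examples
#'
#' A bright ellipse ("head and shoulders") over a textured dark background —
#' a stand-in for a person photograph with a known foreground mask.
#'
#' @param size side length in pixels.
#' @param seed seed for the background texture.
#' @return List with `image` (intensity matrix) and `mask` (logical
#'   foreground matrix).
#' @export
synthetic_portrait <- function(size = 100L, seed = 1L) {
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  xs <- matrix(rep(seq_len(size), each = size), size)
  ys <- matrix(rep(seq_len(size), times = size), size)
  cx <- size / 2; cy <- size * 0.4
  mask <- ((xs - cx) / (size * 0.22))^2 + ((ys - cy) / (size * 0.3))^2 <= 1
  img <- matrix(stats::runif(size^2, 20, 90), size)
  img[mask] <- stats::runif(sum(mask), 180, 240)
  list(image = round(img), mask = mask)
}

#' Build the miniature fixture bundle used by the test suite
#'
#' Generates tiny synthetic template images (geometric "person"/"animal"
#' scenes), a 2-session mini experiment plan, and a 6-observer mini cohort;
#' everything is computed in memory from the seed.
#'
#' @param seed integer seed.
#' @return List with `templates` (named list of intensity matrices),
#'   `stimuli` (two-tone objects), `manifest`, `plan`, `cohort` and `scores`.
#' @export
make_fixtures <- function(seed = 42L) {
  templates <- list()
  stimuli <- list()
  params <- stimulus_params(target_size = 64L)
  for (i in 1:20) {
    is_test <- i <= 10
    sp <- synthetic_portrait(48L, seed = child_seed(seed, 10L + i))
    img <- sp$image
    if (!is_test) img <- t(img)[, rev(seq_len(ncol(img)))]  # rotate: "animal"
    id <- sprintf("%s_%02d", if (is_test) "fixt" else "fixc", i)
    templates[[id]] <- img
    stimuli[[id]] <- make_two_tone(img, params, id = id,
                                   template_id = paste0("tpl_", id),
                                   is_test = is_test)
  }
  manifest <- data.frame(
    stimulus_id = names(stimuli),
    template_id = vapply(stimuli, function(s) s$template_id, ""),
    is_test = vapply(stimuli, function(s) s$is_test, TRUE),
    stringsAsFactors = FALSE)
  plan <- build_experiment(manifest, n_sessions = 2L,
                           seed = child_seed(seed, 1L))
  specs <- list(
    lbd_vh = group_spec("lbd_vh", 2, 1.41, 0.23, 1.95, 0.16),
    lbd_nonvh = group_spec("lbd_nonvh", 2, 1.96, 0.14, 2.15, 0.13),
    control = group_spec("control", 2, 1.92, 0.16, 2.32, 0.12))
  cohort <- simulate_cohort(specs, plan, seed = child_seed(seed, 2L))
  scores <- score_cohort(cohort$logs)
  list(templates = templates, stimuli = stimuli, manifest = manifest,
       plan = plan, cohort = cohort, scores = scores)
}
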