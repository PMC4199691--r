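#' Run a pipeline stage
#'
#' Thin orchestration layer tying the stages together behind one entry
#' point, suitable for scripting (see `inst/cli/sazd.R` for the shell
#' wrapper). Configuration is a named list, or a path to a YAML/JSON file
#' holding one. Common fields: `seed`, `alpha`, `tau`. Every JSON artifact
#' embeds the seed and the full configuration, so re-running a deterministic
#' mode with the same configuration reproduces the artifact byte for byte.
#'
#' Modes:
#' \describe{
#'   \item{simulate}{fields `params` (mechanism parameter list for the focal
#'     line), optional `params_even`, optional `design` (arguments to
#'     [screen_design()]), `out_table` (brood TSV), optional `out_params`
#'     (YAML of the generating parameters).}
#'   \item{screen}{fields `input` (brood TSV), optional `out_json` (verdict
#'     record with the full trail), optional `out_report` (plain-text
#'     report).}
#'   \item{estimate}{fields `E` and `F` (literal percent-female values);
#'     prints and returns the two survival estimates and their ratio.}
#'   \item{linkage}{either `input` (linkage TSV) or `simulate` (arguments to
#'     [simulate_recombination_assay()]); optional `out_json`.}
#'   \item{report}{field `input` (a verdict JSON written by screen mode);
#'     renders the trail as text.}
#' }
#'
#' @param config named list or path to a YAML/JSON configuration file.
#' @param mode one of `"simulate"`, `"screen"`, `"estimate"`, `"linkage"`,
#'   `"report"`.
#' @return the mode's result object, invisibly, with attribute `artifacts`
#'   listing the files written.
#' @export
run_pipeline <- function(config,
                         mode = c("simulate", "screen", "estimate",
                                  "linkage", "report")) {
  mode <- match.arg(mode)
  config <- load_config(config)
  seed <- config$seed
  alpha <- config$alpha %||% 0.05
  artifacts <- character()
  emit_json <- function(path, result) {
    payload <- list(seed = seed, config = config, result = result)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    artifacts <<- c(artifacts, path)
  }

  out <- switch(mode,
    simulate = {
      if (is.null(config$params)) stop("simulate mode needs 'params'",
                                       call. = FALSE)
      params_sr <- params_from_list(config$params)
      params_even <- if (!is.null(config$params_even))
        params_from_list(config$params_even) else mechanism_params()
      design <- do.call(screen_design,
                        c(config$design %||% list(), list(alpha = alpha)))
      ds <- simulate_screen_dataset(params_sr, params_even, design,
                                    seed = seed)
      if (!is.null(config$out_table)) {
        write_brood_table(ds$broods, config$out_table)
        artifacts <- c(artifacts, config$out_table)
      }
      if (!is.null(config$out_params)) {
        write_mechanism_params(params_sr, config$out_params)
        artifacts <- c(artifacts, config$out_params)
      }
      ds
    },
    screen = {
      if (is.null(config$input)) stop("screen mode needs 'input'",
                                      call. = FALSE)
      broods <- read_brood_table(config$input)
      inputs <- screen_inputs_from_broods(broods, alpha = alpha)
      cfg <- screen_config(tau = config$tau %||% 0.5, alpha = alpha,
                           sexing = config$sexing %||% "phenotype")
      res <- run_screen(inputs, cfg)
      message("screen verdict: ", res$verdict)
      for (i in seq_len(nrow(res$trail))) {
        message(sprintf("  step %s: %s -> %s", res$trail$step[i],
                        res$trail$comparison[i], res$trail$outcome[i]))
      }
      if (!is.null(config$out_json)) {
        emit_json(config$out_json,
                  list(verdict = res$verdict,
                       has_SD_component = res$has_SD_component,
                       derived = res$derived, trail = res$trail))
      }
      if (!is.null(config$out_report)) {
        writeLines(utils::capture.output(print(res)), config$out_report)
        artifacts <- c(artifacts, config$out_report)
      }
      res
    },
    estimate = {
      if (is.null(config$E) || is.null(config$F)) {
        stop("estimate mode needs literal 'E' and 'F'", call. = FALSE)
      }
      s_mf <- survival_m_rel_f(config$E, config$F)
      s_yx <- survival_Y_rel_X(config$E)
      res <- list(E = config$E, F = config$F,
                  survival_m_rel_f = as.numeric(s_mf),
                  extra_male_mortality_pct = 100 * (1 - as.numeric(s_mf)),
                  survival_Y_rel_X = s_yx,
                  extra_Y_sperm_loss_pct = 100 * (1 - s_yx),
                  mortality_to_sd_ratio =
                    (1 - as.numeric(s_mf)) / (1 - s_yx),
                  predicted_pf = predicted_pf(as.numeric(s_mf)))
      message(sprintf(
        "survival ♂ rel ♀ = %.3f (extra mortality %.1f%%); survival Y rel X = %.3f (extra loss %.1f%%); ratio %.2f",
        res$survival_m_rel_f, res$extra_male_mortality_pct,
        res$survival_Y_rel_X, res$extra_Y_sperm_loss_pct,
        res$mortality_to_sd_ratio))
      if (!is.null(config$out_json)) emit_json(config$out_json, res)
      res
    },
    linkage = {
      data <- if (!is.null(config$input)) {
        read_linkage_table(config$input)
      } else if (!is.null(config$simulate)) {
        do.call(simulate_recombination_assay,
                c(config$simulate, list(seed = seed)))
      } else stop("linkage mode needs 'input' or 'simulate'", call. = FALSE)
      res <- classify_families(data, alpha = alpha,
                               detect_fraction =
                                 config$detect_fraction %||% 0.5)
      message(sprintf(
        "linkage: %d informative sires, %d null-class; upper bound %.2f cM",
        res$n_informative, res$n_null_class, res$bound$upper_cM))
      if (!is.null(config$out_json)) {
        emit_json(config$out_json,
                  list(n_informative = res$n_informative,
                       n_null_class = res$n_null_class,
                       rescued_sires = res$rescued_sires,
                       bound = res$bound))
      }
      res
    },
    report = {
      if (is.null(config$input)) stop("report mode needs 'input'",
                                      call. = FALSE)
      rec <- jsonlite::read_json(config$input, simplifyVector = TRUE)
      cat("Screen verdict:", rec$result$verdict, "\n")
      cat("SD component:  ",
          if (isTRUE(rec$result$has_SD_component)) "yes" else "no", "\n")
      tr <- rec$result$trail
      for (i in seq_len(NROW(tr))) {
        cat(sprintf("  step %-3s %-34s -> %s\n", tr$step[i],
                    tr$comparison[i], tr$outcome[i]))
      }
      rec
    }
  )
  attr(out, "artifacts") <- artifacts
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop("'config' must be a list or a file path",
                             call. = FALSE)
  config
}
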