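# End-to-end orchestration: motion summaries -> exclusions -> covariate
# screen -> univariate heritability -> bivariate correlation grid, driven by
# a YAML configuration, with structured report output and seed capture.

default_pipeline_config <- function() list(
  phenotypes = NULL,          # path to the phenotype table (required)
  motion_dir = NULL,          # optional directory of realignment files
  motion = list(dialect = "spm", radius = 80, trans_thresh = 3,
                rot_thresh = 2),
  traits = NULL,              # SWAN traits to analyse (default: all present)
  hm_trait = "hm_log",
  covariates = c("sex_male", "age_scan"),
  alpha = 0.05,
  ci = FALSE,                 # profile CIs in the bivariate grid
  seed = 1L,
  out_dir = "twinmotion_results")

#' Run the full analysis pipeline
#'
#' Executes, in order: motion summarisation (when a realignment directory is
#' configured), gross-motion exclusion with bookkeeping, the covariate and
#' homogeneity screen for head motion, univariate heritability per trait,
#' and the bivariate head-motion-by-trait correlation grid. Writes a
#' structured JSON report, delimited tables and a markdown summary to the
#' configured output directory.
#'
#' @param config path to a YAML configuration file, or an equivalent named
#'   list. Keys: `phenotypes` (path, required), `motion_dir`, `motion`
#'   (`dialect`, `radius`, `trans_thresh`, `rot_thresh`), `traits`,
#'   `hm_trait`, `covariates`, `alpha`, `ci`, `seed`, `out_dir`.
#' @return the results list, invisibly; files are written to `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- modifyList(default_pipeline_config(), config)
  if (is.null(cfg$phenotypes)) stop("config must name a 'phenotypes' table")
  log_lines <- c(
    sprintf("twinmotion pipeline %s", format(Sys.time())),
    sprintf("seed: %d", cfg$seed),
    "conventions: natural log of mean consecutive-frame displacement; ",
    "profile-likelihood CIs; LRT df without boundary mixture correction")

  dataset <- read_phenotypes(cfg$phenotypes)
  n_input <- nrow(dataset$data)

  motion_tab <- NULL
  excluded <- character(0)
  if (!is.null(cfg$motion_dir)) {
    paths <- list.files(cfg$motion_dir, full.names = TRUE)
    if (!length(paths)) stop("no realignment files in ", cfg$motion_dir)
    motion_tab <- motion_summary_table(
      paths, dialect = cfg$motion$dialect, radius = cfg$motion$radius,
      trans_thresh = cfg$motion$trans_thresh,
      rot_thresh = cfg$motion$rot_thresh)
    excluded <- motion_tab$subject_id[motion_tab$gross_motion]
    d <- dataset$data
    d[[cfg$hm_trait]] <- motion_tab$log_displacement[
      match(d$individual_id, motion_tab$subject_id)]
    d <- d[!d$individual_id %in% excluded, , drop = FALSE]
    dataset <- twin_dataset(d, traits = dataset$traits)
    log_lines <- c(log_lines,
                   sprintf("motion: %d subjects, %d gross-motion exclusions",
                           nrow(motion_tab), length(excluded)))
  }
  n_analyzed <- nrow(dataset$data)
  stopifnot(n_input == n_analyzed + length(excluded))

  bad <- setdiff(cfg$traits, dataset$traits)
  if (length(bad))
    stop("config requests unknown trait(s): ", paste(bad, collapse = ", "))
  traits <- cfg$traits
  if (is.null(traits))
    traits <- setdiff(dataset$traits, cfg$hm_trait)
  traits <- intersect(traits, dataset$traits)
  observed <- vapply(traits, function(tr) any(!is.na(dataset$data[[tr]])),
                     logical(1))
  traits <- traits[observed]

  screen <- homogeneity_battery(dataset, cfg$hm_trait,
                                covariates = cfg$covariates,
                                seed = cfg$seed)
  uni <- lapply(setNames(c(cfg$hm_trait, traits), c(cfg$hm_trait, traits)),
                function(tr)
    heritability_analysis(dataset, tr, covariates = cfg$covariates,
                          alpha = cfg$alpha, ci = FALSE, seed = cfg$seed))
  biv <- lapply(setNames(traits, traits), function(tr)
    cross_trait_analysis(dataset, c(cfg$hm_trait, tr),
                         covariates = cfg$covariates, ci = cfg$ci,
                         seed = cfg$seed))

  results <- list(
    meta = list(seed = cfg$seed, n_input = n_input,
                n_analyzed = n_analyzed,
                n_gross_motion_excluded = length(excluded),
                excluded_subjects = as.list(excluded),
                package_version = as.character(utils::packageVersion("twinmotion"))),
    motion = motion_tab,
    covariate_screen = screen,
    univariate = lapply(uni, function(u) list(
      selected = u$selected, h2 = u$h2,
      tests = u$tests,
      shares = u$fits[[u$selected]]$standardized$shares)),
    bivariate = lapply(biv, function(b) list(
      rp = b$rp, rg = b$rg, re = b$re,
      p_rp = b$tests$rp$p, p_rg = b$tests$rg$p, p_re = b$tests$re$p,
      ci = if (!is.null(b$ci)) lapply(b$ci, function(x)
        list(lower = x[1L], upper = x[2L],
             at_bound = as.logical(attr(x, "at_bound")))) else NULL,
      converged = b$fit$converged)))
  write_report(results, cfg$out_dir, log_lines = log_lines)
  invisible(results)
}

#' Write a report bundle
#'
#' Serialises pipeline results as structured JSON (lossless round trip via
#' [read_report()]), delimited tables for the covariate screen and the
#' correlation grid, and a human-readable markdown summary.
#'
#' @param results results list (as produced by [run_pipeline()]).
#' @param out_dir output directory (created if needed).
#' @param log_lines optional character vector appended to `run.log`.
#' @return paths of the written files, invisibly.
#' @export
write_report <- function(results, out_dir, log_lines = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(out_dir, "results.json")
  jsonlite::write_json(results, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns", pretty = TRUE)
  paths <- json_path
  if (!is.null(results$covariate_screen)) {
    pth <- file.path(out_dir, "covariate_screen.tsv")
    write.table(results$covariate_screen, pth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, pth)
  }
  if (length(results$bivariate)) {
    grid <- do.call(rbind, lapply(names(results$bivariate), function(tr) {
      b <- results$bivariate[[tr]]
      data.frame(trait = tr, rp = b$rp, rg = b$rg, re = b$re,
                 p_rp = b$p_rp, p_rg = b$p_rg, p_re = b$p_re)
    }))
    pth <- file.path(out_dir, "correlation_grid.tsv")
    write.table(grid, pth, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, pth)
  }
  md <- c("# twinmotion pipeline summary", "",
          sprintf("- individuals analysed: %s (input %s, gross-motion excluded %s)",
                  results$meta$n_analyzed, results$meta$n_input,
                  results$meta$n_gross_motion_excluded))
  for (tr in names(results$univariate)) {
    u <- results$univariate[[tr]]
    md <- c(md, sprintf("- %s: selected %s model, h2 = %.3f", tr,
                        u$selected, u$h2))
  }
  for (tr in names(results$bivariate)) {
    b <- results$bivariate[[tr]]
    md <- c(md, sprintf(
      "- hm x %s: rp = %.3f (p = %.2g), rg = %.3f (p = %.2g), re = %.3f",
      tr, b$rp, b$p_rp, b$rg, b$p_rg, b$re))
  }
  md_path <- file.path(out_dir, "summary.md")
  writeLines(md, md_path)
  if (!is.null(log_lines))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(c(paths, md_path))
}

#' @param path a `results.json` written by [write_report()].
#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}
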