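# Pair-structured phenotype container and its delimited-text interface.

ZYGOSITY_GROUPS <- c("MZF", "MZM", "DZF", "DZM", "DZOS", "SIB")
TRAIT_COLUMNS <- c("hm_log", "swan_mi", "swan_mh", "swan_si", "swan_sh")

PHENO_COLUMNS <- c(
  "family_id", "individual_id", "zygosity", "sex", "birth_order",
  "age_scan", "age_mother_report", "age_self_report",
  "hm_log", "swan_mi", "swan_mh", "swan_si", "swan_sh",
  "wave_mother", "wave_self", "design_mother", "design_self", "n_siblings")

#' Construct a twin dataset
#'
#' Wraps an individual-level phenotype table into a validated container used
#' by the model-fitting functions. One row per individual; twins/siblings
#' share a `family_id` (at most two analysed members per family), zygosity is
#' one of `MZF, MZM, DZF, DZM, DZOS, SIB` (sibling pairs are analysed with
#' dizygotic relatedness), and phenotype columns may contain `NA` — the FIML
#' objective marginalises over missing entries rather than dropping families.
#'
#' Derived covariate columns `sex_male` (0/1), `interval_mother` and
#' `interval_self` (rating age minus scan age, years) are added when the
#' source columns are present.
#'
#' @param data data.frame of individuals.
#' @param traits character vector of phenotype column names (defaults to the
#'   trait columns present among `hm_log, swan_mi, swan_mh, swan_si,
#'   swan_sh`).
#' @return An object of class `twin_dataset`.
#' @export
twin_dataset <- function(data, traits = NULL) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  needed <- c("family_id", "individual_id", "zygosity", "sex")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("phenotype table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(traits)) traits <- intersect(TRAIT_COLUMNS, names(data))
  if (!length(traits)) stop("no trait columns found")
  if (!all(traits %in% names(data)))
    stop("trait columns absent from data: ",
         paste(setdiff(traits, names(data)), collapse = ", "))
  bad <- setdiff(unique(data$zygosity), ZYGOSITY_GROUPS)
  if (length(bad)) stop("unknown zygosity values: ", paste(bad, collapse = ", "))
  if (!all(data$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  if (is.null(data$birth_order)) data$birth_order <- 1L
  if (anyDuplicated(data$individual_id))
    stop("individual_id values must be unique")
  sizes <- table(data$family_id)
  if (any(sizes > 2L))
    stop("families with more than 2 analysed members are not supported: ",
         paste(names(sizes)[sizes > 2L], collapse = ", "))
  # same-sex MZ, opposite-sex DZOS (vectorized over ordered pairs)
  ord <- order(data$family_id, data$birth_order)
  fid_o <- data$family_id[ord]
  pair_first <- which(fid_o[-length(fid_o)] == fid_o[-1L])
  if (length(pair_first)) {
    i1 <- ord[pair_first]; i2 <- ord[pair_first + 1L]
    bad_z <- data$zygosity[i1] != data$zygosity[i2]
    if (any(bad_z))
      stop("family ", data$family_id[i1][bad_z][1L],
           " has inconsistent zygosity labels")
    zg <- data$zygosity[i1]
    same_sex <- data$sex[i1] == data$sex[i2]
    bad_ss <- zg %in% c("MZF", "MZM", "DZF", "DZM") & !same_sex
    if (any(bad_ss))
      stop("family ", data$family_id[i1][bad_ss][1L], " labelled ",
           zg[bad_ss][1L], " but members differ in sex")
    bad_os <- zg == "DZOS" & same_sex
    if (any(bad_os))
      stop("family ", data$family_id[i1][bad_os][1L],
           " labelled DZOS but members share sex")
  }
  data$sex_male <- as.numeric(data$sex == "M")
  if (all(c("age_mother_report", "age_scan") %in% names(data)))
    data$interval_mother <- data$age_mother_report - data$age_scan
  if (all(c("age_self_report", "age_scan") %in% names(data)))
    data$interval_self <- data$age_self_report - data$age_scan
  for (dcol in c("design_mother", "design_self"))
    if (dcol %in% names(data) && is.character(data[[dcol]]))
      data[[paste0(dcol, "_retro")]] <-
        as.numeric(data[[dcol]] == "retrospective")
  structure(list(data = data, traits = traits), class = "twin_dataset")
}

#' @export
print.twin_dataset <- function(x, ...) {
  d <- x$data
  sizes <- table(d$family_id)
  n_pairs <- sum(sizes == 2L)
  cat(sprintf("<twin_dataset> %d individuals, %d complete pairs, %d singletons\n",
              nrow(d), n_pairs, sum(sizes == 1L)))
  pair_fams <- names(sizes)[sizes == 2L]
  zg <- d$zygosity[match(pair_fams, d$family_id)]
  if (length(zg)) {
    tab <- table(factor(zg, ZYGOSITY_GROUPS))
    cat("  pairs by group:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  cat("  traits:", paste(x$traits, collapse = ", "), "\n")
  invisible(x)
}

#' Read / write the delimited phenotype table
#'
#' Tab-separated text with a header row; missing values are empty fields.
#'
#' @param path file path.
#' @return `read_phenotypes()` returns a [twin_dataset()].
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.table(path, header = TRUE, sep = "\t", na.strings = "",
                  stringsAsFactors = FALSE)
  twin_dataset(d)
}

#' @param dataset a [twin_dataset()].
#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(dataset, path) {
  d <- dataset$data
  keep <- intersect(PHENO_COLUMNS, names(d))
  write.table(d[, keep], path, sep = "\t", quote = FALSE, na = "",
              row.names = FALSE)
  invisible(path)
}

# Internal: split a dataset into family blocks ordered by birth order.
split_families <- function(dataset) {
  d <- dataset$data
  ord <- order(d$family_id, d$birth_order, d$individual_id)
  d <- d[ord, ]
  split(d, factor(d$family_id, levels = unique(d$family_id)))
}

#' Restrict a dataset to some zygosity groups
#'
#' @param dataset a [twin_dataset()].
#' @param groups character vector of zygosity labels to keep.
#' @return a [twin_dataset()].
#' @export
subset_groups <- function(dataset, groups) {
  d <- dataset$data[dataset$data$zygosity %in% groups, , drop = FALSE]
  if (!nrow(d)) stop("no individuals left after group subset")
  twin_dataset(d, traits = dataset$traits)
}
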