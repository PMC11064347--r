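# On-disk cohort layout: one TSV per omic block (first column sample_id,
# header = feature ids), covariates.tsv, targets.tsv, split.tsv and a JSON
# sidecar carrying the simulation config and planted ground truth. Numbers
# are written with 17 significant digits so the round trip is exact.

.fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  out
}

.write_matrix_tsv <- function(M, path) {
  df <- data.frame(sample_id = rownames(M),
                   apply(M, 2L, .fmt_num),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_matrix_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  M <- apply(as.matrix(df[, -1, drop = FALSE]), 2L, as.numeric)
  if (!is.matrix(M)) M <- matrix(M, nrow = nrow(df),
                                 dimnames = list(NULL, colnames(df)[-1]))
  rownames(M) <- df$sample_id
  M
}

#' Write a cohort to a directory of delimited files
#'
#' @param cohort A `"multiomics_cohort"`.
#' @param directory Target directory (created if absent).
#' @return The directory path, invisibly.
#' @seealso [read_cohort()] for the exact-round-trip reader.
#' @export
write_cohort <- function(cohort, directory) {
  validate_cohort(cohort)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  for (b in names(cohort$blocks))
    .write_matrix_tsv(cohort$blocks[[b]],
                      file.path(directory, paste0("block_", b, ".tsv")))
  .write_matrix_tsv(as.matrix(cohort$covariates),
                    file.path(directory, "covariates.tsv"))
  .write_matrix_tsv(cohort$targets, file.path(directory, "targets.tsv"))
  write.table(data.frame(sample_id = cohort$sample_ids,
                         split = as.character(cohort$split)),
              file.path(directory, "split.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(blocks = names(cohort$blocks),
                  config = if (!is.null(cohort$config))
                    unclass(cohort$config),
                  ground_truth = cohort$ground_truth)
  jsonlite::write_json(sidecar, file.path(directory, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       matrix = "rowmajor")
  invisible(directory)
}

#' Read a cohort written by [write_cohort()]
#'
#' Verifies that every component is present and that sample ids agree, in
#' order, across all files; a permuted or truncated file is an error, not a
#' silent realignment.
#'
#' @param directory Directory produced by [write_cohort()].
#' @return A `"multiomics_cohort"`.
#' @export
read_cohort <- function(directory) {
  sidecar_path <- file.path(directory, "cohort.json")
  if (!file.exists(sidecar_path))
    stop("missing cohort component: cohort.json")
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  needed <- c(paste0("block_", sidecar$blocks, ".tsv"),
              "covariates.tsv", "targets.tsv", "split.tsv")
  missing <- needed[!file.exists(file.path(directory, needed))]
  if (length(missing))
    stop("missing cohort component: ", paste(missing, collapse = ", "))
  blocks <- lapply(sidecar$blocks, function(b)
    .read_matrix_tsv(file.path(directory, paste0("block_", b, ".tsv"))))
  names(blocks) <- sidecar$blocks
  covariates <- .read_matrix_tsv(file.path(directory, "covariates.tsv"))
  targets <- .read_matrix_tsv(file.path(directory, "targets.tsv"))
  split_df <- read.table(file.path(directory, "split.tsv"), sep = "\t",
                         header = TRUE, colClasses = "character")
  ids <- split_df$sample_id
  for (nm in names(blocks))
    if (!identical(rownames(blocks[[nm]]), ids))
      stop("sample ids in block '", nm, "' do not match split.tsv")
  if (!identical(rownames(covariates), ids) ||
      !identical(rownames(targets), ids))
    stop("sample ids misaligned across cohort files")
  config <- sidecar$config
  if (!is.null(config))
    config <- tryCatch(do.call(sim_config, config), error = function(e) NULL)
  gt <- sidecar$ground_truth
  .new_cohort(ids, blocks,
              list(age = covariates[, "age"], sex = covariates[, "sex"],
                   bmi = covariates[, "bmi"]),
              targets,
              factor(split_df$split,
                     levels = c("train", "validation", "test")),
              gt, config)
}
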