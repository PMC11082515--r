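# Reading and writing the frozen CSV schemas.
#
# A dataset on disk is five CSVs plus the generator truth:
#   trees.csv, discs.csv, vessels.csv (long, one row per vessel),
#   leaves.csv, stomata.csv, truth.json
# Radii are 8 numbered columns (stem_r1..stem_r8, hw_r1..hw_r8); decimal
# point, UTF-8, header row.

.dataset_files <- c(trees = "trees.csv", discs = "discs.csv",
                    vessels = "vessels.csv", leaves = "leaves.csv",
                    stomata = "stomata.csv")

#' Write a generated dataset to a directory
#'
#' @param dataset an \code{hw_dataset} from [generate_cohort()] or
#'   [generate_study()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "hw_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (tab in names(.dataset_files)) {
    p <- file.path(dir, .dataset_files[[tab]])
    utils::write.csv(dataset[[tab]], p, row.names = FALSE,
                     fileEncoding = "UTF-8")
    paths <- c(paths, p)
  }
  tp <- file.path(dir, "truth.json")
  jsonlite::write_json(dataset$truth, tp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, tp))
}

#' Read a dataset directory back into an \code{hw_dataset}
#'
#' Accepts either a generated directory or user data in the same schema;
#' \code{truth.json} is optional for user data.
#'
#' @param dir directory holding the five CSVs.
#' @return an \code{hw_dataset}.
#' @export
read_dataset <- function(dir) {
  out <- lapply(.dataset_files, function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing file: ", p)
    utils::read.csv(p, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  })
  names(out) <- names(.dataset_files)
  tp <- file.path(dir, "truth.json")
  out$truth <- if (file.exists(tp)) jsonlite::read_json(tp,
                                                        simplifyVector = TRUE)
               else NULL
  structure(out, class = "hw_dataset")
}
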