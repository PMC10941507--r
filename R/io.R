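#' @name connectograd-io
#' @title Plain-text readers and writers for pipeline artifacts
#' @description
#' All pipeline artifacts are plain TSV/JSON: a time series is a T x R TSV
#' whose header holds the ROI identifiers; a connectivity matrix is an
#' R x R TSV with a leading \code{roi_id} column; vertex areas are a long
#' TSV (\code{roi_id}, \code{vertex_index}, \code{area_mm2}); subject
#' metadata and parcellation partitions are simple keyed TSVs. Writers and
#' readers round-trip losslessly to 1e-12 (values are written with 17
#' significant digits).
NULL

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

check_rectangular <- function(path) {
  counts <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(counts)) > 1L) {
    bad <- which(counts != counts[1L])[1L]
    stop("ragged TSV: line ", bad, " of ", path, " has ", counts[bad],
         " fields, expected ", counts[1L])
  }
  invisible(TRUE)
}

check_numeric_cols <- function(df, path, skip = character(0)) {
  for (nm in setdiff(names(df), skip)) {
    v <- df[[nm]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop("non-numeric cell in column '", nm, "' of ", path,
           " at line ", bad + 1L)
    }
  }
  invisible(TRUE)
}

#' Write / read a parcellated time series as TSV
#'
#' @param ts T x R numeric matrix with ROI identifiers as column names.
#' @param path file path.
#' @return \code{read_timeseries_tsv} returns the T x R matrix.
#' @export
write_timeseries_tsv <- function(ts, path) {
  x <- as_ts_matrix(ts)
  out <- apply(x, c(1, 2), fmt_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = colnames(x))
  invisible(path)
}

#' @rdname write_timeseries_tsv
#' @export
read_timeseries_tsv <- function(path) {
  check_rectangular(path)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = NA)
  if (anyDuplicated(names(df))) {
    stop("duplicate ROI identifiers in header of ", path, ": ",
         paste(names(df)[duplicated(names(df))], collapse = ", "))
  }
  check_numeric_cols(df, path)
  as.matrix(df)
}

#' Write / read a connectivity matrix as TSV
#'
#' The file has a leading \code{roi_id} column and the ROI identifiers as
#' header, so row and column order are explicit.
#'
#' @param m \code{connectivity_matrix} (or square matrix with dimnames).
#' @param path file path.
#' @param kind connectome kind attached on read
#'   (\code{"functional"}/\code{"structural_kl"}; default taken from the
#'   file's sidecar-free context as \code{"functional"}).
#' @return \code{read_connectivity_tsv} returns a
#'   \code{connectivity_matrix}.
#' @export
write_connectivity_tsv <- function(m, path) {
  x <- unclass(as.matrix(m))
  df <- data.frame(roi_id = rownames(x),
                   apply(x, c(1, 2), fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectivity_tsv
#' @export
read_connectivity_tsv <- function(path, kind = "functional") {
  check_rectangular(path)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = NA)
  if (names(df)[1L] != "roi_id") stop("expected leading roi_id column in ", path)
  ids <- as.character(df$roi_id)
  if (anyDuplicated(ids)) stop("duplicate ROI identifiers in ", path)
  check_numeric_cols(df, path, skip = "roi_id")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!identical(colnames(m), ids)) {
    if (!setequal(colnames(m), ids)) stop("row/column ROI sets differ in ", path)
    m <- m[, ids, drop = FALSE]
  }
  rownames(m) <- ids
  new_connectivity(m, kind = kind, roi_ids = ids)
}

#' Write / read vertex surface areas as long TSV
#'
#' Columns: \code{roi_id}, \code{vertex_index}, \code{area_mm2}.
#'
#' @param areas named list of numeric vectors (one per ROI).
#' @param path file path.
#' @return \code{read_vertex_areas_tsv} returns the named list, ROI order
#'   preserved.
#' @export
write_vertex_areas_tsv <- function(areas, path) {
  areas <- as_area_list(areas)
  df <- data.frame(
    roi_id = rep(names(areas), lengths(areas)),
    vertex_index = unlist(lapply(lengths(areas), seq_len), use.names = FALSE),
    area_mm2 = fmt_num(unlist(areas, use.names = FALSE)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vertex_areas_tsv
#' @export
read_vertex_areas_tsv <- function(path) {
  check_rectangular(path)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = NA)
  need <- c("roi_id", "vertex_index", "area_mm2")
  if (!all(need %in% names(df))) {
    stop("expected columns ", paste(need, collapse = ", "), " in ", path)
  }
  check_numeric_cols(df[, c("vertex_index", "area_mm2")], path)
  split(df$area_mm2, factor(df$roi_id, levels = unique(df$roi_id)))
}

#' Write / read the subject metadata table
#'
#' Columns: subject_id, group, age, sex, updrs3_pre, updrs3_post.
#'
#' @param subjects data.frame of subject records.
#' @param path file path.
#' @return \code{read_metadata_tsv} returns the data.frame.
#' @export
write_metadata_tsv <- function(subjects, path) {
  utils::write.table(subjects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_tsv
#' @export
read_metadata_tsv <- function(path) {
  check_rectangular(path)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = NA)
  need <- c("subject_id", "group", "age", "sex")
  if (!all(need %in% names(df))) {
    stop("metadata table ", path, " must contain columns: ",
         paste(need, collapse = ", "))
  }
  df
}

#' Write / read the ROI-to-network partition table
#'
#' Columns: roi_id, network.
#'
#' @param partition data.frame with \code{roi_id} and \code{network}.
#' @param path file path.
#' @return \code{read_partition_tsv} returns the data.frame.
#' @export
write_partition_tsv <- function(partition, path) {
  utils::write.table(partition, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition_tsv
#' @export
read_partition_tsv <- function(path) {
  check_rectangular(path)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = NA)
  if (!all(c("roi_id", "network") %in% names(df))) {
    stop("partition table ", path, " must contain roi_id and network")
  }
  if (anyDuplicated(df$roi_id)) stop("duplicate roi_id in ", path)
  df
}

#' Write / read a gradient set (TSV scores + JSON sidecar)
#'
#' Scores go to \code{<prefix>.tsv} (roi_id, g1..gk); eigenvalues,
#' explained ratios, alpha, diffusion time and alignment flag go to
#' \code{<prefix>.json}.
#'
#' @param gs a \code{gradient_set}.
#' @param prefix path prefix (without extension).
#' @return \code{read_gradients} returns the \code{gradient_set}.
#' @export
write_gradients <- function(gs, prefix) {
  gs <- as_gradient_set(gs)
  sc <- gs$scores
  df <- data.frame(roi_id = rownames(sc),
                   apply(sc, c(1, 2), fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("roi_id", paste0("g", seq_len(ncol(sc))))
  utils::write.table(df, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(eigenvalues = gs$eigenvalues,
               explained_ratio = gs$explained_ratio,
               variance_ratio = gs$variance_ratio,
               alpha = gs$alpha, diffusion_time = gs$diffusion_time,
               aligned = gs$aligned)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_gradients
#' @export
read_gradients <- function(prefix) {
  df <- utils::read.delim(paste0(prefix, ".tsv"), check.names = FALSE)
  sc <- as.matrix(df[, -1L, drop = FALSE])
  rownames(sc) <- df$roi_id
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  new_gradient_set(scores = sc, eigenvalues = meta$eigenvalues,
                   explained_ratio = meta$explained_ratio,
                   variance_ratio = meta$variance_ratio,
                   alpha = meta$alpha, diffusion_time = meta$diffusion_time,
                   aligned = isTRUE(meta$aligned))
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Produces the exact file layout [run_pipeline()] reads: per-session time
#' series and vertex-area TSVs under \code{timeseries/} and \code{areas/},
#' plus \code{subjects.tsv}, \code{partition.tsv} and \code{truth.json}
#' (the planted parameters, kept for parameter-recovery tests).
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "timeseries"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "areas"), recursive = TRUE, showWarnings = FALSE)
  for (key in names(cohort$timeseries)) {
    write_timeseries_tsv(cohort$timeseries[[key]],
                         file.path(dir, "timeseries", paste0(key, ".tsv")))
    write_vertex_areas_tsv(cohort$vertex_areas[[key]],
                           file.path(dir, "areas", paste0(key, ".tsv")))
  }
  write_metadata_tsv(cohort$subjects, file.path(dir, "subjects.tsv"))
  write_partition_tsv(cohort$partition, file.path(dir, "partition.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return list with \code{subjects}, \code{partition}, \code{timeseries},
#'   \code{vertex_areas} and (if present) \code{truth}.
#' @export
read_cohort <- function(dir) {
  subjects <- read_metadata_tsv(file.path(dir, "subjects.tsv"))
  partition <- read_partition_tsv(file.path(dir, "partition.tsv"))
  ts_files <- list.files(file.path(dir, "timeseries"), pattern = "\\.tsv$",
                         full.names = TRUE)
  keys <- sub("\\.tsv$", "", basename(ts_files))
  timeseries <- stats::setNames(lapply(ts_files, read_timeseries_tsv), keys)
  area_files <- file.path(dir, "areas", paste0(keys, ".tsv"))
  vertex_areas <- stats::setNames(lapply(area_files, read_vertex_areas_tsv),
                                  keys)
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  }
  list(subjects = subjects, partition = partition, timeseries = timeseries,
       vertex_areas = vertex_areas, truth = truth)
}
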