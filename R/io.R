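#' Read a gel lane-intensity table
#'
#' Expects a CSV/TSV with header \code{sample_id,time_s,band,intensity};
#' \code{band} must be \code{duplex} or \code{single_strand}.
#'
#' @param path File path; the delimiter is taken from the extension
#'   (\code{.tsv}/\code{.txt} = tab, otherwise comma).
#' @return data.frame suitable for \code{\link{build_progress_curve}}.
#' @export
read_lane_table <- function(path) {
  d <- .read_delim(path)
  need <- c("sample_id", "time_s", "band", "intensity")
  if (!all(need %in% names(d)))
    stop("lane table ", path, " must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!all(d$band %in% c("duplex", "single_strand")))
    stop("lane table ", path, ": band must be duplex or single_strand",
         call. = FALSE)
  if (anyDuplicated(d[c("sample_id", "time_s", "band")]))
    stop("lane table ", path, ": duplicate (sample_id, time_s, band) rows",
         call. = FALSE)
  d
}

#' Read an initial-velocity table
#'
#' CSV with header \code{S_nM,v0_nM_per_min[,replicate]} (substrate series)
#' or \code{I_nM,v0_nM_per_min} (inhibitor dose series).
#'
#' @param path File path.
#' @export
read_velocity_table <- function(path) {
  d <- .read_delim(path)
  if (!("v0_nM_per_min" %in% names(d)) ||
      !any(c("S_nM", "I_nM") %in% names(d)))
    stop("velocity table ", path,
         " must have v0_nM_per_min and S_nM or I_nM", call. = FALSE)
  d
}

#' Read sensorgram traces from a stacked CSV
#'
#' Header \code{time_s,response_RU,conc_nM,phase} with
#' \code{phase} in \code{assoc}/\code{diss}; one trace per concentration.
#'
#' @param path File path.
#' @return List of \code{"sensorgram"} objects.
#' @export
read_sensorgram_csv <- function(path) {
  d <- .read_delim(path)
  need <- c("time_s", "response_RU", "conc_nM", "phase")
  if (!all(need %in% names(d)))
    stop("sensorgram file ", path, " must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  lapply(split(d, d$conc_nM), function(s) {
    s <- s[order(s$time_s), ]
    structure(list(times = s$time_s, response = s$response_RU,
                   analyte_conc = s$conc_nM[1L] * 1e-9,
                   t_assoc_end = max(s$time_s[s$phase == "assoc"])),
              class = "sensorgram")
  })
}

#' Write sensorgrams to a stacked CSV
#'
#' @param sensorgrams List of \code{"sensorgram"} objects.
#' @param path Output path.
#' @export
write_sensorgram_csv <- function(sensorgrams, path) {
  if (inherits(sensorgrams, "sensorgram")) sensorgrams <- list(sensorgrams)
  d <- do.call(rbind, lapply(sensorgrams, as.data.frame))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an isotherm or competition table
#'
#' CSV with header \code{conc_nM,fraction_bound[,series]}.
#'
#' @param path File path.
#' @export
read_isotherm_table <- function(path) {
  d <- .read_delim(path)
  if (!all(c("conc_nM", "fraction_bound") %in% names(d)))
    stop("isotherm table ", path,
         " must have columns conc_nM, fraction_bound", call. = FALSE)
  d
}

#' Read an AFM particle-dimension table
#'
#' CSV with header \code{particle_id,h_nm,a_nm,b_nm[,on_rna]}.
#'
#' @param path File path.
#' @export
read_particle_table <- function(path) {
  d <- .read_delim(path)
  if (!all(c("h_nm", "a_nm", "b_nm") %in% names(d)))
    stop("particle table ", path,
         " must have columns h_nm, a_nm, b_nm", call. = FALSE)
  d
}

#' Write a progress curve to CSV with a JSON sidecar
#'
#' The CSV holds \code{time_s,fraction}; \code{<path>.json} records the
#' mode and substrate concentration.
#'
#' @param curve A \code{"progress_curve"}.
#' @param path Output CSV path.
#' @export
write_progress_curve <- function(curve, path) {
  stopifnot(inherits(curve, "progress_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(
    list(mode = curve$mode, substrate_conc_nM = curve$substrate_conc),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a progress curve written by \code{write_progress_curve}
#'
#' @param path CSV path (the \code{.json} sidecar must sit next to it).
#' @export
read_progress_curve <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  structure(list(times = d$time_s, fraction = d$fraction,
                 substrate_conc = meta$substrate_conc_nM,
                 mode = meta$mode),
            class = "progress_curve")
}

#' Read an FPKM matrix with its library manifest
#'
#' The matrix is a TSV with a \code{transcript_id} column and one column
#' per library; the manifest is a TSV with columns \code{library_id},
#' \code{condition}, \code{antibody}.
#'
#' @param matrix_path,manifest_path File paths.
#' @return Named list of \code{"rip_library"} objects (names =
#'   library ids).
#' @export
read_fpkm_matrix <- function(matrix_path, manifest_path) {
  m <- utils::read.delim(matrix_path, check.names = FALSE)
  if (!("transcript_id" %in% names(m)))
    stop("FPKM matrix must have a transcript_id column", call. = FALSE)
  manifest <- utils::read.delim(manifest_path)
  need <- c("library_id", "condition", "antibody")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$library_id[i]
    if (!(id %in% names(m)))
      stop("library ", id, " missing from the FPKM matrix", call. = FALSE)
    rip_library(id, manifest$condition[i], manifest$antibody[i],
                stats::setNames(m[[id]], m$transcript_id))
  })
  stats::setNames(out, manifest$library_id)
}

#' Write a transcript set as newline-delimited ids
#'
#' @param ids Character vector of transcript ids.
#' @param path Output path.
#' @export
write_gene_set <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' Write a treatment-partition report as JSON and TSV
#'
#' @param partition A \code{"partition_result"}.
#' @param path Output stem; writes \code{<path>.json} and \code{<path>.tsv}.
#' @export
write_partition_report <- function(partition, path) {
  stopifnot(inherits(partition, "partition_result"))
  d <- as.data.frame(partition)
  utils::write.table(d, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(total = partition$total,
         counts = as.list(partition$counts),
         percents = as.list(stats::setNames(partition$percents,
                                            names(partition$counts)))),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

.read_delim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.(tsv|txt)$", path)) utils::read.delim(path)
  else utils::read.csv(path)
}
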