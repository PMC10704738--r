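#' Base-10 logarithm of raw ROS chemiluminescence
#'
#' Chemiluminescence readouts span several orders of magnitude
#' (roughly 9.5 to 540,000 relative light units in a typical elicitor
#' assay), so all modelling is done on the log10 scale.
#'
#' @param ros_raw numeric vector of strictly positive luminescence values.
#' @return numeric vector `log10(ros_raw)`.
#' @export
log_transform <- function(ros_raw) {
  if (!is.numeric(ros_raw)) stop("ros_raw must be numeric")
  bad <- which(!is.finite(ros_raw) | ros_raw <= 0)
  if (length(bad) > 0) {
    stop(sprintf("non-positive or non-finite ROS value at position %d (%.4g): log10 undefined",
                 bad[1], ros_raw[bad[1]]))
  }
  log10(ros_raw)
}

#' Construct a compound library
#'
#' A compound library bundles a descriptor matrix with raw and
#' log-transformed ROS readouts and the derived modulator labels. A
#' compound is labelled a ROS modulator when its log10 ROS production is
#' at or above `threshold` (inclusive); compounds without a ROS
#' measurement carry `NA` labels and are excluded from model fitting.
#'
#' @param descriptors numeric matrix (compounds x features) with unique
#'   rownames (compound ids) and colnames (feature names).
#' @param ros_raw numeric vector of positive luminescence values, `NA`
#'   where unmeasured.
#' @param threshold modulator threshold in log10 units. Default 4.67.
#' @return an object of class `compound_library` with elements
#'   `descriptors`, `feature_names`, `compound_ids`, `ros_raw`,
#'   `log_ros`, `labels`, `threshold`.
#' @export
compound_library <- function(descriptors, ros_raw = NULL, threshold = 4.67) {
  descriptors <- as.matrix(descriptors)
  if (!is.numeric(descriptors)) stop("descriptors must be a numeric matrix")
  if (is.null(rownames(descriptors)) || any(rownames(descriptors) == ""))
    stop("descriptors must have non-empty compound ids as rownames")
  ids <- rownames(descriptors)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop(sprintf("duplicate compound_id: '%s'", dup[1]))
  if (is.null(colnames(descriptors)))
    stop("descriptors must have feature names as colnames")
  if (anyDuplicated(colnames(descriptors)))
    stop("duplicate feature names in descriptor table")
  if (any(!is.finite(descriptors)))
    stop("descriptors contain non-finite values")
  n <- nrow(descriptors)
  if (is.null(ros_raw)) ros_raw <- rep(NA_real_, n)
  if (length(ros_raw) != n) stop("ros_raw length must match number of compounds")
  measured <- !is.na(ros_raw)
  log_ros <- rep(NA_real_, n)
  if (any(measured)) log_ros[measured] <- log_transform(ros_raw[measured])
  labels <- ifelse(is.na(log_ros), NA, log_ros >= threshold)
  names(ros_raw) <- names(log_ros) <- names(labels) <- ids
  structure(
    list(descriptors = descriptors,
         feature_names = colnames(descriptors),
         compound_ids = ids,
         ros_raw = ros_raw,
         log_ros = log_ros,
         labels = labels,
         threshold = threshold),
    class = "compound_library")
}

#' @export
print.compound_library <- function(x, ...) {
  n_meas <- sum(!is.na(x$ros_raw))
  cat(sprintf("compound_library: %d compounds, %d descriptors\n",
              length(x$compound_ids), length(x$feature_names)))
  cat(sprintf("  ROS measured for %d; modulators (log10 ROS >= %.3g): %d\n",
              n_meas, x$threshold, sum(x$labels, na.rm = TRUE)))
  invisible(x)
}

#' Label ROS modulators at a threshold
#'
#' @param library a `compound_library`.
#' @param threshold log10-ROS cutoff; positives satisfy
#'   `log_ros >= threshold`.
#' @return list with `labels` (logical vector, `NA` where ROS is
#'   unmeasured) and `n_positive`.
#' @export
label_modulators <- function(library, threshold = library$threshold) {
  stopifnot(inherits(library, "compound_library"))
  labels <- ifelse(is.na(library$log_ros), NA, library$log_ros >= threshold)
  list(labels = labels, n_positive = sum(labels, na.rm = TRUE))
}

# ---- delimited-file readers/writers -----------------------------------------

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a compound library from descriptor and ROS tables
#'
#' The descriptor table is delimited text (comma or tab, autodetected
#' from the header) with a header row `compound_id,<feat_1>,...`; the
#' optional ROS table has header `compound_id,ros` with raw (positive)
#' luminescence. Compounds present in the descriptor table but absent
#' from the ROS table get `NA` ROS and an undefined label.
#'
#' @param descriptor_path path to the descriptor table.
#' @param ros_path optional path to the ROS table.
#' @param threshold modulator threshold in log10 units.
#' @return a [compound_library()].
#' @export
read_library <- function(descriptor_path, ros_path = NULL, threshold = 4.67) {
  sep <- detect_sep(descriptor_path)
  tab <- read.table(descriptor_path, header = TRUE, sep = sep,
                    colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 2) stop("descriptor table needs compound_id plus at least one feature column")
  ids <- tab[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) stop(sprintf("duplicate compound_id: '%s'", dup[1]))
  feat_names <- colnames(tab)[-1]
  desc <- matrix(NA_real_, nrow = nrow(tab), ncol = length(feat_names),
                 dimnames = list(ids, feat_names))
  for (j in seq_along(feat_names)) {
    v <- suppressWarnings(as.numeric(tab[[j + 1]]))
    bad <- which(is.na(v) & !is.na(tab[[j + 1]]) & tab[[j + 1]] != "NA")
    if (length(bad) > 0)
      stop(sprintf("non-numeric descriptor value at row %d, column '%s': '%s'",
                   bad[1], feat_names[j], tab[[j + 1]][bad[1]]))
    desc[, j] <- v
  }
  ros_raw <- NULL
  if (!is.null(ros_path)) {
    rsep <- detect_sep(ros_path)
    rtab <- read.table(ros_path, header = TRUE, sep = rsep, check.names = FALSE)
    if (!all(c("compound_id", "ros") %in% colnames(rtab)[1:2]))
      stop("ROS table must have header compound_id,ros")
    if (anyDuplicated(rtab$compound_id))
      stop("duplicate compound_id in ROS table")
    ros_raw <- rtab$ros[match(ids, rtab$compound_id)]
    measured <- !is.na(ros_raw)
    if (any(ros_raw[measured] <= 0))
      stop("non-positive ROS value: log10 undefined")
    n_missing <- sum(!measured)
    if (n_missing > 0)
      message(sprintf("%d compounds have no ROS measurement; excluded from training", n_missing))
  }
  compound_library(desc, ros_raw, threshold = threshold)
}

#' Write a compound library to a delimited file
#'
#' Emits the descriptor schema plus `ros`, `log_ros` and `label`
#' columns, readable back with [read_library()].
#'
#' @param library a `compound_library`.
#' @param path output file path.
#' @param sep field separator (`","` or `"\t"`).
#' @export
write_library <- function(library, path, sep = ",") {
  stopifnot(inherits(library, "compound_library"))
  out <- data.frame(compound_id = library$compound_ids,
                    library$descriptors,
                    ros = library$ros_raw,
                    log_ros = library$log_ros,
                    label = as.integer(library$labels),
                    check.names = FALSE)
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract compound ids from an SDF file
#'
#' Reads only the title line of each molecule block (the line before
#' each `$$$$` delimiter starts a new block); used to join structure
#' files against precomputed descriptor tables. No structure parsing.
#'
#' @param path path to an SDF file.
#' @return character vector of molecule titles.
#' @export
sdf_ids <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) return(character(0))
  ends <- which(lines == "$$$$")
  starts <- c(1L, head(ends, -1) + 1L)
  trimws(lines[starts[starts <= length(lines)]])
}
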