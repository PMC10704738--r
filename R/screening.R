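#' First-pass threshold screen over a large descriptor table
#'
#' Streams a descriptor table in chunks, predicts log10 ROS for each
#' compound with the trained model, and retains compounds whose
#' prediction is at or above the modulator threshold. Results are
#' independent of the chunk size; memory use is bounded by one chunk.
#'
#' @param table a descriptor source: either a path to a delimited file
#'   (header `compound_id,<features...>`) or an in-memory numeric
#'   matrix/data.frame with compound ids as rownames.
#' @param model a `ros_model`.
#' @param threshold log10-ROS cutoff. Default the model's threshold.
#' @param chunk_size rows per chunk. Default 5000.
#' @param verbose log a running candidate tally per chunk.
#' @return object of class `screening_funnel` with stage-1 results:
#'   `n_input`, `n_first_pass`, `stage1` (data frame `compound_id`,
#'   `prediction`), and the configuration used.
#' @export
screen_first_pass <- function(table, model, threshold = model$threshold,
                              chunk_size = 5000L, verbose = FALSE) {
  stopifnot(inherits(model, "ros_model"), chunk_size >= 1)
  ids <- character(0); preds <- numeric(0)
  n_input <- 0L
  consume <- function(chunk_ids, chunk_X) {
    p <- predict(model, chunk_X)
    keep <- p >= threshold
    n_input <<- n_input + length(p)
    ids <<- c(ids, chunk_ids[keep])
    preds <<- c(preds, p[keep])
    if (verbose)
      message(sprintf("  %d screened, %d candidates", n_input, length(ids)))
  }
  if (is.character(table) && length(table) == 1) {
    sep <- detect_sep(table)
    con <- file(table, open = "r")
    on.exit(close(con))
    header <- strsplit(readLines(con, n = 1L), sep, fixed = TRUE)[[1]]
    feat_names <- header[-1]
    repeat {
      chunk <- tryCatch(
        read.table(con, sep = sep, nrows = chunk_size, header = FALSE,
                   col.names = header, check.names = FALSE,
                   colClasses = c("character", rep("numeric",
                                                   length(feat_names)))),
        error = function(e) {
          if (grepl("no lines available", conditionMessage(e))) NULL
          else stop(sprintf("malformed row near line %d: %s",
                            n_input + 2L, conditionMessage(e)))
        })
      if (is.null(chunk) || nrow(chunk) == 0) break
      X <- as.matrix(chunk[, -1, drop = FALSE])
      rownames(X) <- chunk[[1]]
      consume(chunk[[1]], X)
      if (nrow(chunk) < chunk_size) break
    }
  } else {
    X <- as.matrix(table)
    if (is.null(rownames(X))) stop("in-memory table needs compound ids as rownames")
    starts <- seq(1, nrow(X), by = chunk_size)
    for (s in starts) {
      e <- min(nrow(X), s + chunk_size - 1)
      consume(rownames(X)[s:e], X[s:e, , drop = FALSE])
    }
  }
  structure(list(n_input = n_input,
                 n_first_pass = length(ids),
                 n_second_pass = NULL,
                 stage1 = data.frame(compound_id = ids, prediction = preds,
                                     stringsAsFactors = FALSE),
                 stage2 = NULL,
                 threshold = threshold, chunk_size = chunk_size),
            class = "screening_funnel")
}

#' The 8x8 compartment grid on the GTM map
#'
#' Partition of \[-1,1\]^2 into `n_rows * n_cols` cells. Cells are
#' half-open `[lo, hi)` except that the top/right boundary (coordinate
#' exactly 1) belongs to the last cell; ids are row-major from the
#' bottom-left corner: `id = row * n_cols + col`, zero-based.
#'
#' @param n_rows,n_cols grid dimensions. Default 8 x 8 (64 cells).
#' @export
compartment_grid <- function(n_rows = 8L, n_cols = 8L) {
  stopifnot(n_rows >= 1, n_cols >= 1)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 bounds = c(-1, 1)),
            class = "compartment_grid")
}

#' Assign map coordinates to compartments
#'
#' @param coords N x 2 matrix of coordinates in \[-1,1\]^2.
#' @param grid a [compartment_grid()].
#' @return integer vector of zero-based compartment ids in
#'   `[0, n_rows * n_cols - 1]`.
#' @export
assign_compartment <- function(coords, grid = compartment_grid()) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2)
  if (any(coords < -1 | coords > 1))
    stop("coordinates outside [-1,1]^2")
  col <- pmin(floor((coords[, 1] + 1) / (2 / grid$n_cols)), grid$n_cols - 1)
  row <- pmin(floor((coords[, 2] + 1) / (2 / grid$n_rows)), grid$n_rows - 1)
  as.integer(row * grid$n_cols + col)
}

#' Compartment-based secondary selection near known modulators
#'
#' Within every compartment that contains at least one reference
#' modulator projection, candidates are ranked twice: `rank_d` by
#' ascending map distance to their nearest reference, and `rank_p` by
#' descending predicted log10 ROS. The combined score is
#' `rank_d + rank_p` (lower is better); the top `quota` candidates per
#' compartment are selected. Ties are broken by higher prediction, then
#' lexicographic compound id. Excluded ids are removed up front;
#' compartments without a reference contribute nothing.
#'
#' @param funnel a `screening_funnel` with stage-1 results.
#' @param candidate_coords N x 2 map coordinates of the stage-1
#'   candidates (rows aligned with `funnel$stage1`).
#' @param reference_coords map coordinates of the known modulators,
#'   projected by the same GTM model.
#' @param grid a [compartment_grid()].
#' @param quota candidates kept per compartment (>= 0). Default 10.
#' @param exclude character vector of deleterious compound ids.
#' @param max_total optional global cap: keep only the best
#'   `max_total` selections overall (by combined score, same
#'   tie-breaks).
#' @return the funnel with `stage2` (data frame `compound_id`,
#'   `prediction`, `compartment`, `rank_d`, `rank_p`, `score`) and
#'   `n_second_pass` filled in.
#' @export
secondary_select <- function(funnel, candidate_coords, reference_coords,
                             grid = compartment_grid(), quota = 10L,
                             exclude = character(0), max_total = NULL) {
  stopifnot(inherits(funnel, "screening_funnel"), quota >= 0)
  reference_coords <- as.matrix(reference_coords)
  if (nrow(reference_coords) == 0) stop("empty reference set")
  cand <- funnel$stage1
  candidate_coords <- as.matrix(candidate_coords)
  stopifnot(nrow(candidate_coords) == nrow(cand))
  keep <- !(cand$compound_id %in% exclude)
  cand <- cand[keep, , drop = FALSE]
  candidate_coords <- candidate_coords[keep, , drop = FALSE]

  if (nrow(cand) == 0 || quota == 0) {
    funnel$stage2 <- cand[0, ]
    funnel$n_second_pass <- 0L
    return(funnel)
  }

  cand_comp <- assign_compartment(candidate_coords, grid)
  ref_comp <- assign_compartment(reference_coords, grid)

  # distance to nearest reference (map space)
  d2 <- outer(rowSums(candidate_coords^2), rep(1, nrow(reference_coords))) +
    outer(rep(1, nrow(cand)), rowSums(reference_coords^2)) -
    2 * candidate_coords %*% t(reference_coords)
  nearest <- sqrt(pmax(apply(d2, 1, min), 0))

  picks <- list()
  for (comp in sort(unique(ref_comp))) {
    in_comp <- which(cand_comp == comp)
    if (length(in_comp) == 0) next
    sub <- cand[in_comp, , drop = FALSE]
    sub$compartment <- comp
    sub$nearest_ref <- nearest[in_comp]
    sub$rank_d <- rank(sub$nearest_ref, ties.method = "min")
    sub$rank_p <- rank(-sub$prediction, ties.method = "min")
    sub$score <- sub$rank_d + sub$rank_p
    ord <- order(sub$score, -sub$prediction, sub$compound_id)
    picks[[as.character(comp)]] <- sub[ord[seq_len(min(quota, nrow(sub)))], ,
                                       drop = FALSE]
  }
  stage2 <- do.call(rbind, picks)
  if (is.null(stage2)) {
    stage2 <- cbind(cand[0, ], compartment = integer(0),
                    nearest_ref = numeric(0), rank_d = integer(0),
                    rank_p = integer(0), score = integer(0))
  }
  rownames(stage2) <- NULL
  if (!is.null(max_total) && nrow(stage2) > max_total) {
    ord <- order(stage2$score, -stage2$prediction, stage2$compound_id)
    stage2 <- stage2[sort(ord[seq_len(max_total)]), , drop = FALSE]
  }
  funnel$stage2 <- stage2
  funnel$n_second_pass <- nrow(stage2)
  funnel$quota <- quota
  funnel
}

#' Screening-funnel report
#'
#' Per-stage candidate counts (input, first screen, second screen) plus
#' the configuration used, as a list convertible to JSON and a
#' human-readable print.
#'
#' @param funnel a `screening_funnel`.
#' @param json_path optional path to also write the report as JSON.
#' @return the report list, invisibly when printed.
#' @export
funnel_report <- function(funnel, json_path = NULL) {
  stopifnot(inherits(funnel, "screening_funnel"))
  rep <- list(
    total_screened = funnel$n_input,
    first_pass_candidates = funnel$n_first_pass,
    second_pass_candidates = funnel$n_second_pass,  # NULL = stage not run
    threshold = funnel$threshold,
    chunk_size = funnel$chunk_size,
    quota = funnel$quota %||% NULL)
  if (!is.null(json_path))
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, null = "null",
                         digits = NA)
  class(rep) <- "funnel_report"
  rep
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("screening funnel\n")
  cat(sprintf("  total screened:        %d\n", x$total_screened))
  cat(sprintf("  1st-pass candidates:   %d\n", x$first_pass_candidates))
  if (is.null(x$second_pass_candidates)) {
    cat("  2nd-pass candidates:   (stage not run)\n")
  } else {
    cat(sprintf("  2nd-pass candidates:   %d\n", x$second_pass_candidates))
  }
  invisible(x)
}

#' @export
print.screening_funnel <- function(x, ...) {
  print(funnel_report(x))
  invisible(x)
}
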