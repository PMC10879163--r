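#' Projection count matrices
#'
#' The projection matrix tabulates, for a cohort of neurons, the number of
#' axonal tracing points falling in each brain parcel (optionally split by
#' hemisphere relative to each neuron's soma). Rows are neurons, columns are
#' (parcel, hemisphere) pairs; entries are non-negative integers whose row
#' sums equal each neuron's in-scope axonal point count. These count vectors
#' are the neurons' projection signatures that all downstream statistics
#' consume.
#'
#' @name projection_matrix
NULL

new_projection_matrix <- function(counts, columns, source_parcel = NA_character_,
                                  dropped = NULL, zero_rows = character(0)) {
  storage.mode(counts) <- "integer"
  obj <- list(counts = counts,
              neuron_ids = rownames(counts),
              columns = columns,
              source_parcel = source_parcel,
              dropped = dropped,
              zero_rows = zero_rows)
  class(obj) <- "projection_matrix"
  obj
}

#' @export
print.projection_matrix <- function(x, ...) {
  cat("<projection_matrix> ", nrow(x$counts), " neurons x ", ncol(x$counts),
      " columns, total ", sum(x$counts), " axonal points\n", sep = "")
  if (length(x$zero_rows)) {
    cat("  zero-count neurons (excluded from distances): ",
        paste(x$zero_rows, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
as.matrix.projection_matrix <- function(x, ...) x$counts

# accept either a projection_matrix or a plain counts matrix
counts_of <- function(M) {
  if (inherits(M, "projection_matrix")) M$counts else as.matrix(M)
}

#' Tabulate axonal points into a neuron-by-parcel count matrix
#'
#' Counts the axon-structure tracing points of each neuron per parcel (or
#' parcel group). With `hemisphere_split = TRUE` each parcel contributes an
#' ipsilateral and a contralateral column; a point's hemisphere is decided by
#' the sign of its mediolateral coordinate relative to the midline, compared
#' with the soma's side. Points in parcels outside `parcel_set` are dropped
#' and summarized in the `dropped` field.
#'
#' @param neurons list of [neuron_reconstruction()].
#' @param parcel_set character vector of parcels (or groups, when `grouping`
#'   is given) to keep; default all observed.
#' @param include_source keep collaterals in each neuron's soma parcel
#'   (default `FALSE`: classification is on target regions).
#' @param hemisphere_split make (parcel, hemisphere) columns (default `TRUE`).
#' @param grouping optional named character vector mapping parcel id to
#'   aggregated column group (see [read_parcel_dictionary()]).
#' @param midline coordinate of the brain midline on `midline_axis`,
#'   micrometers (default 5695, the mediolateral midline of the common
#'   coordinate framework).
#' @param midline_axis which coordinate is mediolateral: `"x"`, `"y"`, `"z"`.
#' @return A `projection_matrix`. Neurons with no in-scope axonal points are
#'   retained as zero rows and listed in `zero_rows`.
#' @export
build_projection_matrix <- function(neurons, parcel_set = NULL,
                                    include_source = FALSE,
                                    hemisphere_split = TRUE,
                                    grouping = NULL,
                                    midline = 5695, midline_axis = "z") {
  stopifnot(length(neurons) >= 1L)
  per_neuron <- lapply(neurons, function(nr) {
    p <- nr$points
    ax <- p[p$structure == "axon" & !is.na(p$parcel), , drop = FALSE]
    parcel <- ax$parcel
    if (!is.null(grouping)) {
      mapped <- unname(grouping[parcel])
      parcel <- ifelse(is.na(mapped), parcel, mapped)
    }
    soma_side <- sign(nr$soma_xyz[[midline_axis]] - midline)
    if (soma_side == 0) soma_side <- 1
    side <- sign(ax[[midline_axis]] - midline)
    side[side == 0] <- soma_side
    hemi <- ifelse(side == soma_side, "ipsi", "contra")
    src <- nr$soma_parcel
    if (!is.null(grouping) && !is.na(src) && src %in% names(grouping)) {
      src <- unname(grouping[src])
    }
    data.frame(parcel = parcel, hemisphere = hemi, source = src,
               stringsAsFactors = FALSE)
  })
  ids <- vapply(neurons, `[[`, character(1L), "neuron_id")
  if (anyDuplicated(ids)) stop("duplicated neuron ids")
  names(per_neuron) <- ids

  all_pts <- do.call(rbind, per_neuron)
  observed <- sort(unique(all_pts$parcel))
  if (is.null(parcel_set)) {
    parcel_set <- observed
    if (!include_source) {
      parcel_set <- setdiff(parcel_set, unique(all_pts$source))
    }
  }
  if (!length(parcel_set)) stop("parcel_set is empty")

  if (hemisphere_split) {
    columns <- data.frame(parcel = rep(parcel_set, each = 2L),
                          hemisphere = rep(c("ipsi", "contra"),
                                           length(parcel_set)),
                          stringsAsFactors = FALSE)
  } else {
    columns <- data.frame(parcel = parcel_set,
                          hemisphere = "both", stringsAsFactors = FALSE)
  }
  col_key <- if (hemisphere_split) {
    paste(columns$parcel, columns$hemisphere, sep = ":")
  } else columns$parcel

  counts <- matrix(0L, nrow = length(neurons), ncol = nrow(columns),
                   dimnames = list(ids, col_key))
  dropped <- list()
  for (id in ids) {
    pts <- per_neuron[[id]]
    if (!include_source) {
      is_src <- !is.na(pts$source) & pts$parcel == pts$source
      pts <- pts[!is_src, , drop = FALSE]
    }
    in_scope <- pts$parcel %in% parcel_set
    if (any(!in_scope)) {
      dropped[[id]] <- table(pts$parcel[!in_scope])
    }
    pts <- pts[in_scope, , drop = FALSE]
    if (!nrow(pts)) next
    key <- if (hemisphere_split) {
      paste(pts$parcel, pts$hemisphere, sep = ":")
    } else pts$parcel
    tab <- table(key)
    counts[id, names(tab)] <- as.integer(tab)
  }
  zero_rows <- ids[rowSums(counts) == 0L]
  if (length(zero_rows)) {
    message("neurons with zero in-scope axonal points (kept as zero rows): ",
            paste(zero_rows, collapse = ", "))
  }
  if (length(dropped)) {
    message(sum(unlist(dropped)), " axonal points in ",
            length(unique(unlist(lapply(dropped, names)))),
            " out-of-scope parcels were dropped")
  }
  new_projection_matrix(counts, columns,
                        source_parcel = paste(unique(all_pts$source),
                                              collapse = ","),
                        dropped = dropped, zero_rows = zero_rows)
}

#' Write / read a projection matrix as CSV with a JSON sidecar
#'
#' @param M a `projection_matrix`.
#' @param file CSV path; the sidecar is written to `paste0(file, ".json")`.
#' @return `write_projection_matrix` returns `file` invisibly;
#'   `read_projection_matrix` returns a `projection_matrix`.
#' @export
write_projection_matrix <- function(M, file) {
  stopifnot(inherits(M, "projection_matrix"))
  df <- data.frame(neuron_id = M$neuron_ids, M$counts, check.names = FALSE)
  write.csv(df, file, row.names = FALSE)
  sidecar <- list(columns = M$columns, source_parcel = M$source_parcel,
                  zero_rows = M$zero_rows,
                  written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(sidecar, paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_projection_matrix
#' @export
read_projection_matrix <- function(file) {
  df <- read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1L, drop = FALSE])
  rownames(counts) <- df$neuron_id
  sidecar_path <- paste0(file, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::fromJSON(sidecar_path)
    columns <- as.data.frame(sc$columns, stringsAsFactors = FALSE)
    new_projection_matrix(counts, columns,
                          source_parcel = sc$source_parcel %||% NA_character_,
                          zero_rows = as.character(sc$zero_rows %||% character(0)))
  } else {
    key <- colnames(counts)
    has_hemi <- grepl(":", key, fixed = TRUE)
    columns <- data.frame(
      parcel = sub(":.*$", "", key),
      hemisphere = ifelse(has_hemi, sub("^.*:", "", key), "both"),
      stringsAsFactors = FALSE
    )
    new_projection_matrix(counts, columns,
                          zero_rows = rownames(counts)[rowSums(counts) == 0])
  }
}
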