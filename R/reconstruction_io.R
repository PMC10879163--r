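#' Neuron reconstruction objects
#'
#' A `neuron_reconstruction` is a rooted tree of tracing points for one
#' neuron: a data frame of points (id, structure, coordinates in micrometers,
#' radius, parent id, optional brain-parcel label) plus soma metadata. The
#' soma is the root of the tree.
#'
#' @param neuron_id character scalar identifier.
#' @param points data frame with columns `point_id`, `structure` (one of
#'   `"soma"`, `"axon"`, `"dendrite"`, `"other"`), `x`, `y`, `z`, `radius`,
#'   `parent_id` (`NA` for the root), and optionally `parcel`.
#' @param soma_layer optional layer label for the soma (e.g. `"L2"`).
#' @return An object of class `neuron_reconstruction`.
#' @export
neuron_reconstruction <- function(neuron_id, points, soma_layer = NULL) {
  stopifnot(is.character(neuron_id), length(neuron_id) == 1L)
  required <- c("point_id", "structure", "x", "y", "z", "radius", "parent_id")
  missing_cols <- setdiff(required, names(points))
  if (length(missing_cols)) {
    stop("points is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"parcel" %in% names(points)) points$parcel <- NA_character_
  points$parcel <- as.character(points$parcel)
  validate_tree(points, neuron_id)
  root <- points[is.na(points$parent_id), , drop = FALSE]
  obj <- list(
    neuron_id = neuron_id,
    points = points,
    soma_xyz = c(x = root$x, y = root$y, z = root$z),
    soma_parcel = root$parcel,
    soma_layer = soma_layer
  )
  class(obj) <- "neuron_reconstruction"
  obj
}

# Tree validation: unique ids, exactly one root, existing parents, no cycles,
# finite coordinates. Errors name the offending point.
validate_tree <- function(points, neuron_id = "?") {
  ids <- points$point_id
  if (anyDuplicated(ids)) {
    stop("neuron ", neuron_id, ": duplicated point id ",
         ids[duplicated(ids)][1L])
  }
  if (!all(is.finite(points$x) & is.finite(points$y) & is.finite(points$z))) {
    stop("neuron ", neuron_id, ": non-finite coordinates")
  }
  is_root <- is.na(points$parent_id)
  if (sum(is_root) != 1L) {
    stop("neuron ", neuron_id, ": expected exactly one root, found ",
         sum(is_root))
  }
  parent <- points$parent_id[!is_root]
  dangling <- setdiff(parent, ids)
  if (length(dangling)) {
    stop("neuron ", neuron_id, ": dangling parent id ", dangling[1L])
  }
  # cycle / connectivity check: walk up from every point; with unique ids,
  # one root and valid parents, reaching the root from all points implies an
  # acyclic connected tree
  idx <- match(points$parent_id, ids)
  n <- nrow(points)
  reached <- is_root
  for (i in seq_len(n)) {
    if (reached[i]) next
    chain <- i
    j <- idx[i]
    while (!reached[j]) {
      if (j %in% chain) {
        stop("neuron ", neuron_id, ": cycle involving point id ", ids[j])
      }
      chain <- c(chain, j)
      j <- idx[j]
    }
    reached[chain] <- TRUE
  }
  invisible(TRUE)
}

#' @export
print.neuron_reconstruction <- function(x, ...) {
  n_axon <- sum(x$points$structure == "axon")
  cat("<neuron_reconstruction> ", x$neuron_id, ": ", nrow(x$points),
      " points (", n_axon, " axonal), soma parcel ",
      ifelse(is.na(x$soma_parcel), "<none>", x$soma_parcel), "\n", sep = "")
  invisible(x)
}

swc_structure <- function(type_code) {
  out <- rep("other", length(type_code))
  out[type_code == 1L] <- "soma"
  out[type_code == 2L] <- "axon"
  out[type_code %in% c(3L, 4L)] <- "dendrite"
  out
}

swc_type_code <- function(structure) {
  unname(c(soma = 1L, axon = 2L, dendrite = 3L, other = 6L)[structure])
}

#' Parse an SWC reconstruction
#'
#' Reads the standard 7-column whitespace-separated SWC dialect
#' (`id type x y z radius parent`, `#` comments). An optional eighth column
#' is interpreted as a per-point brain-parcel label, which the standard
#' format does not carry.
#'
#' @param file path to an SWC file, or a character vector of lines via
#'   `text`.
#' @param text optional character vector of SWC lines (overrides `file`).
#' @param neuron_id identifier; defaults to the file name without extension.
#' @param soma_layer optional soma layer label.
#' @return A [neuron_reconstruction()].
#' @export
parse_swc <- function(file = NULL, text = NULL, neuron_id = NULL,
                      soma_layer = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("either file or text must be given")
    text <- readLines(file, warn = FALSE)
    if (is.null(neuron_id)) {
      neuron_id <- sub("\\.[sS][wW][cC]$", "", basename(file))
    }
  }
  if (is.null(neuron_id)) neuron_id <- "swc"
  keep <- !grepl("^\\s*(#|$)", text)
  data_lines <- text[keep]
  lineno <- which(keep)
  if (!length(data_lines)) stop("SWC contains no data lines")
  fields <- strsplit(trimws(data_lines), "\\s+")
  nfield <- lengths(fields)
  if (any(nfield < 7L)) {
    bad <- which(nfield < 7L)[1L]
    stop("SWC line ", lineno[bad], ": expected 7 columns, found ",
         nfield[bad])
  }
  m <- t(vapply(fields, function(f) f[1:7], character(7L)))
  num <- suppressWarnings(apply(m, 2L, as.numeric))
  num <- matrix(num, ncol = 7L)
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0L)[1L]
    stop("SWC line ", lineno[bad], ": non-numeric field")
  }
  parcel <- vapply(fields, function(f) if (length(f) >= 8L) f[8L]
                   else NA_character_, character(1L))
  parcel[parcel == "NA"] <- NA_character_
  points <- data.frame(
    point_id = as.integer(num[, 1L]),
    structure = swc_structure(as.integer(num[, 2L])),
    x = num[, 3L], y = num[, 4L], z = num[, 5L],
    radius = num[, 6L],
    parent_id = ifelse(num[, 7L] < 0, NA_integer_, as.integer(num[, 7L])),
    parcel = parcel,
    stringsAsFactors = FALSE
  )
  neuron_reconstruction(neuron_id, points, soma_layer = soma_layer)
}

#' Write a reconstruction as SWC
#'
#' Canonical 7-column dialect; a parcel column is appended only when any
#' point carries a parcel label. `parse_swc(write_swc(x))` round-trips
#' topology and coordinates exactly.
#'
#' @param neuron a [neuron_reconstruction()].
#' @param file output path; if `NULL` the lines are returned invisibly.
#' @return Character vector of SWC lines, invisibly.
#' @export
write_swc <- function(neuron, file = NULL) {
  p <- neuron$points
  cols <- list(
    format(p$point_id), format(swc_type_code(p$structure)),
    format(p$x, digits = 17, trim = TRUE),
    format(p$y, digits = 17, trim = TRUE),
    format(p$z, digits = 17, trim = TRUE),
    format(p$radius, digits = 17, trim = TRUE),
    format(ifelse(is.na(p$parent_id), -1L, p$parent_id))
  )
  if (any(!is.na(p$parcel))) {
    cols <- c(cols, list(ifelse(is.na(p$parcel), "NA", p$parcel)))
  }
  lines <- c(paste0("# ", neuron$neuron_id),
             do.call(paste, cols))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Parse a MouseLight-style JSON reconstruction
#'
#' Reads the nested single-neuron JSON layout used by whole-brain tracing
#' repositories: a `neuron` record (or a `neurons` array) holding a `soma`
#' object and `axon`/`dendrite` point arrays with per-point coordinates,
#' parent pointers (`parentNumber`, -1 for the tree root) and brain-parcel
#' annotation (`allenId`).
#'
#' @param file path to a JSON file.
#' @param text optional JSON string (overrides `file`).
#' @return A list of [neuron_reconstruction()] (one element per neuron).
#' @export
parse_projection_json <- function(file = NULL, text = NULL) {
  src <- if (!is.null(text)) text else file
  if (is.null(src)) stop("either file or text must be given")
  doc <- jsonlite::fromJSON(src, simplifyVector = FALSE)
  recs <- if (!is.null(doc$neurons)) doc$neurons
          else if (!is.null(doc$neuron)) list(doc$neuron)
          else stop("JSON parse error: no 'neuron' or 'neurons' record")
  lapply(recs, parse_one_json_neuron)
}

parse_one_json_neuron <- function(rec) {
  id <- rec$idString %||% rec$id %||% "json-neuron"
  id <- as.character(id)
  if (is.null(rec$soma)) stop("JSON parse error: neuron ", id,
                              " lacks a soma record")
  soma <- rec$soma
  need <- c("x", "y", "z")
  if (!all(need %in% names(soma))) {
    stop("JSON parse error: soma of ", id, " missing coordinate field")
  }
  block <- function(pts, structure, offset) {
    if (!length(pts)) return(NULL)
    one <- function(p) {
      if (!all(c("x", "y", "z") %in% names(p))) {
        stop("JSON parse error: point in ", id, " missing coordinate field")
      }
      if (is.null(p$allenId)) {
        stop("JSON parse error: point in ", id, " missing parcel field")
      }
      c(sample = as.numeric(p$sampleNumber %||% NA),
        x = as.numeric(p$x), y = as.numeric(p$y), z = as.numeric(p$z),
        radius = as.numeric(p$radius %||% NA),
        parent = as.numeric(p$parentNumber %||% -1),
        allen = as.numeric(p$allenId))
    }
    m <- t(vapply(pts, one, numeric(7L)))
    data.frame(
      point_id = as.integer(m[, "sample"]) + offset,
      structure = structure,
      x = m[, "x"], y = m[, "y"], z = m[, "z"],
      radius = m[, "radius"],
      parent_id = ifelse(m[, "parent"] < 0, NA_integer_,
                         as.integer(m[, "parent"]) + offset),
      parcel = as.character(as.integer(m[, "allen"])),
      stringsAsFactors = FALSE
    )
  }
  soma_row <- data.frame(
    point_id = 1L, structure = "soma",
    x = as.numeric(soma$x), y = as.numeric(soma$y), z = as.numeric(soma$z),
    radius = as.numeric(soma$radius %||% NA),
    parent_id = NA_integer_,
    parcel = as.character(soma$allenId %||% NA),
    stringsAsFactors = FALSE
  )
  # axon and dendrite arbors use independent sample numberings rooted at the
  # soma; offsets keep point ids unique, and each arbor root (parentNumber -1
  # or pointing at its own sample 1) is re-parented to the soma
  axon <- block(rec$axon, "axon", offset = 1L)
  dend <- block(rec$dendrite, "dendrite",
                offset = 1L + (if (is.null(axon)) 0L else max(axon$point_id)))
  reroot <- function(b) {
    if (is.null(b)) return(NULL)
    b$parent_id[is.na(b$parent_id) | !(b$parent_id %in% b$point_id)] <- 1L
    b
  }
  points <- rbind(soma_row, reroot(axon), reroot(dend))
  neuron_reconstruction(id, points, soma_layer = rec$somaLayer %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a parcel dictionary
#'
#' @param file CSV with columns `parcel_id`, `name`, and optionally `group`
#'   (parcel aggregation used for matrix columns and target definitions).
#' @return Data frame with character columns.
#' @export
read_parcel_dictionary <- function(file) {
  d <- read.csv(file, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("parcel_id", "name") %in% names(d))) {
    stop("parcel dictionary needs columns parcel_id,name")
  }
  if (!"group" %in% names(d)) d$group <- d$name
  d$group[d$group == ""] <- d$name[d$group == ""]
  d
}
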