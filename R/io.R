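#' Read / write pattern sets as CSV
#'
#' Plain-text exchange format: one row per condition, first column `label`,
#' remaining columns the channels. Round trips are lossless (values written
#' at full precision).
#'
#' @param patterns a [pattern_set()].
#' @param path CSV file path.
#' @return `read_patterns`: a [pattern_set()]; `write_patterns`: `path`,
#'   invisibly.
#' @export
write_patterns <- function(patterns, path) {
  stopifnot(inherits(patterns, "pattern_set"))
  df <- data.frame(label = patterns$labels,
                   patterns$data, check.names = FALSE)
  colnames(df) <- c("label", paste0("ch", seq_len(ncol(patterns$data))))
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% colnames(df))
    stop("malformed pattern file ", path, ": no 'label' column")
  mat <- as.matrix(df[, setdiff(colnames(df), "label"), drop = FALSE])
  storage.mode(mat) <- "double"
  dimnames(mat) <- NULL
  pattern_set(mat, labels = df$label)
}

#' Read / write RDMs as CSV
#'
#' Two dialects are supported and load to identical objects:
#' `form = "square"` writes the full symmetric matrix with condition labels
#' as header row and first column; `form = "vector"` writes the canonical
#' upper-triangle vector as a one-column CSV plus a JSON sidecar
#' (`<path>.json`) recording labels, pair order and measure. `read_rdm`
#' detects the dialect by the presence of the sidecar.
#'
#' @param x an [rdm()].
#' @param path CSV file path.
#' @param form `"square"` or `"vector"`.
#' @param measure measure tag to assume for square files without sidecar.
#' @return `read_rdm`: an [rdm()].
#' @export
write_rdm <- function(x, path, form = c("square", "vector")) {
  stopifnot(inherits(x, "rdm"))
  form <- match.arg(form)
  if (form == "square") {
    m <- rdm_square(x$d, labels = x$labels)
    df <- data.frame(label = rownames(m), m, check.names = FALSE)
    utils::write.csv(format(df, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    utils::write.csv(
      data.frame(dissimilarity = format(x$d, digits = 17, trim = TRUE,
                                        scientific = FALSE)),
      path, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(labels = x$labels, order = "utv-rowmajor",
                              measure = x$measure),
                         paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path, measure = "other") {
  if (!file.exists(path)) stop("file not found: ", path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!identical(meta$order, "utv-rowmajor"))
      stop("unsupported pair order '", meta$order, "' in ", sidecar)
    v <- utils::read.csv(path)$dissimilarity
    return(rdm(as.numeric(v), labels = meta$labels, measure = meta$measure))
  }
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% colnames(df))
    stop("malformed RDM file ", path, ": no 'label' column and no sidecar")
  labels <- as.character(df$label)
  m <- as.matrix(df[, setdiff(colnames(df), "label"), drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m))
    stop("RDM file ", path, ": matrix is ", nrow(m), "x", ncol(m),
         ", not square")
  rdm(rdm_vectorize(m), labels = labels, measure = measure)
}

#' Read / write RDM collections
#'
#' Text container for aligned RDM stacks: a CSV of dissimilarity vectors
#' (one row per RDM) plus a JSON sidecar (`<path>.json`) holding condition
#' labels, RDM names, roles and measures.
#'
#' @param collection an [rdm_collection()].
#' @param path CSV file path.
#' @return `read_rdm_collection`: an [rdm_collection()].
#' @export
write_rdm_collection <- function(collection, path) {
  stopifnot(inherits(collection, "rdm_collection"))
  m <- collection_matrix(collection)
  utils::write.table(format(m, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE, sep = ",")
  jsonlite::write_json(
    list(labels = collection$labels,
         names = names(collection$rdms),
         roles = collection$roles,
         measures = vapply(collection$rdms, `[[`, "", "measure"),
         order = "utv-rowmajor"),
    paste0(path, ".json"), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_rdm_collection
#' @export
read_rdm_collection <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  storage.mode(m) <- "double"
  if (nrow(m) != length(meta$names))
    stop("collection file ", path, ": ", nrow(m), " rows but ",
         length(meta$names), " names in sidecar")
  rdms <- lapply(seq_len(nrow(m)), function(i)
    rdm(m[i, ], labels = meta$labels, measure = meta$measures[i]))
  rdm_collection(rdms, roles = meta$roles, names = meta$names)
}

#' Read / write volumes as JSON text
#'
#' Serializes a [volume()] (data, mask, voxel size, labels) as a single
#' JSON document. A plain-text stand-in for binary neuroimaging containers,
#' sufficient for the simulated volumes this package produces.
#'
#' @param vol a [volume()].
#' @param path JSON file path.
#' @return `read_volume`: a [volume()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume"))
  jsonlite::write_json(
    list(dim = dim(vol$data), voxel_size_mm = vol$voxel_size_mm,
         labels = vol$labels, mask = as.integer(vol$mask),
         data = as.numeric(vol$data)),
    path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dm <- as.integer(obj$dim)
  if (length(obj$data) != prod(dm))
    stop("volume file ", path, ": data length ", length(obj$data),
         " does not match dim ", paste(dm, collapse = "x"))
  if (length(obj$mask) != prod(dm[1:3]))
    stop("volume file ", path, ": mask length ", length(obj$mask),
         " does not match spatial dim ", paste(dm[1:3], collapse = "x"))
  volume(array(as.numeric(obj$data), dm),
         array(as.logical(obj$mask), dm[1:3]),
         voxel_size_mm = as.numeric(obj$voxel_size_mm),
         labels = obj$labels)
}
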