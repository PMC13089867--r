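#' Representational dissimilarity matrices
#'
#' An `rdm` is a symmetric 4x4 matrix of pairwise dissimilarities between the
#' four task states, with zero diagonal. Model RDMs hold nonnegative counts
#' or distances; neural RDMs hold cross-validated distance estimates, which
#' are unbiased and may be negative. All downstream correlations operate on
#' the canonical upper-triangle flattening, in the fixed pair order
#' 1-2, 1-3, 1-4, 2-3, 2-4, 3-4.
#'
#' @param values 4x4 symmetric numeric matrix (zero diagonal) or a length-6
#'   vector in canonical pair order.
#' @param type Character tag stored in the object (e.g. `"model"`,
#'   `"crossnobis"`).
#' @param meta Optional named list of metadata.
#' @return An object of class `rdm` (a 4x4 matrix with attributes).
#' @export
rdm <- function(values, type = "model", meta = list()) {
  if (is.matrix(values)) {
    stopifnot(nrow(values) == 4, ncol(values) == 4)
    if (max(abs(values - t(values))) > 1e-8) stop("rdm must be symmetric", call. = FALSE)
    if (max(abs(diag(values))) > 1e-8) stop("rdm must have zero diagonal", call. = FALSE)
    m <- (values + t(values)) / 2
    diag(m) <- 0
  } else {
    stopifnot(length(values) == 6)
    m <- matrix(0, 4, 4)
    m[upper.tri(m)] <- canonical_to_uppertri(values)
    m <- m + t(m)
  }
  dimnames(m) <- list(paste0("S", 1:4), paste0("S", 1:4))
  structure(m, class = c("rdm", "matrix", "array"), type = type, meta = meta)
}

# Canonical order is row-major over the upper triangle: (1,2) (1,3) (1,4)
# (2,3) (2,4) (3,4). R's upper.tri() is column-major: (1,2) (1,3) (2,3)
# (1,4) (2,4) (3,4). These helpers convert.
canonical_pairs <- function() {
  cbind(i = c(1L, 1L, 1L, 2L, 2L, 3L), j = c(2L, 3L, 4L, 3L, 4L, 4L))
}

canonical_to_uppertri <- function(v) v[c(1L, 2L, 4L, 3L, 5L, 6L)]

#' Canonical vector form of an RDM
#'
#' @param x An [rdm()] or plain 4x4 symmetric matrix.
#' @return Numeric length-6 vector, pairs ordered 1-2, 1-3, 1-4, 2-3, 2-4,
#'   3-4.
#' @export
rdm_vec <- function(x) {
  p <- canonical_pairs()
  v <- as.numeric(x[cbind(p[, "i"], p[, "j"])])
  names(v) <- paste0("S", p[, "i"], "-S", p[, "j"])
  v
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm type=%s>\n", attr(x, "type") %||% "?"))
  m <- round(unclass(x), 4)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  print(m)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy an RDM into a pair-per-row tibble
#'
#' @param x An [rdm()] object.
#' @param ... Unused.
#' @return Tibble with columns `state_a`, `state_b`, `dissimilarity` in the
#'   canonical pair order.
#' @export
tidy.rdm <- function(x, ...) {
  p <- canonical_pairs()
  tibble::tibble(
    state_a = p[, "i"], state_b = p[, "j"],
    dissimilarity = as.numeric(rdm_vec(x))
  )
}

#' Write / read an RDM as CSV (4x4 with state labels)
#'
#' @param x An [rdm()] object.
#' @param path File path.
#' @param type,meta Passed to [rdm()] on read.
#' @return `write_rdm_csv` returns `path` invisibly; `read_rdm_csv` an
#'   [rdm()].
#' @export
write_rdm_csv <- function(x, path) {
  df <- as.data.frame(unclass(x))
  df <- cbind(state = rownames(df), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rdm_csv
#' @export
read_rdm_csv <- function(path, type = "model", meta = list()) {
  df <- utils::read.csv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rdm(unname(m), type = type, meta = meta)
}

#' Write an RDM as JSON (labels + canonical vector form)
#'
#' @inheritParams write_rdm_csv
#' @export
write_rdm_json <- function(x, path) {
  jsonlite::write_json(
    list(labels = paste0("S", 1:4), type = attr(x, "type") %||% "model",
         vector_form = as.numeric(rdm_vec(x))),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_rdm_json
#' @export
read_rdm_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rdm(as.numeric(x$vector_form), type = x$type %||% "model")
}
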