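#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pq <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop_pq(fmt, ...)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Deterministic child seed derived from a parent seed and a label so that
# independent generators fed from one CLI/acceptance seed do not share streams.
# Kept below 2^31 - 1.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

#' Read and write tab-separated tables
#'
#' All tabular inputs and outputs of the pipeline are TSV (UTF-8, `.` decimal,
#' header row), matching typical plate-reader and tracking-software exports.
#'
#' @param path file path.
#' @param x data frame to write.
#' @return `read_tsv_table()` returns a data frame; `write_tsv_table()`
#'   invisibly returns `path`.
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write 16-bit grey-scale TIFF images
#'
#' Images are plain numeric matrices in R (row, column indexing, 0-based pixel
#' coordinates in downstream records). On disk they are stored as 16-bit
#' grey-scale TIFF, multi-page for stacks. Intensities are rounded to integers
#' in `[0, 65535]` on write.
#'
#' @param img numeric matrix, or list of matrices for a multi-page stack.
#' @param path file path.
#' @param pages `"all"` to return a list of matrices, or a page index.
#' @return `read_image_tiff()` returns a numeric matrix (single page) or a
#'   list of matrices; values are on the original integer scale.
#' @export
write_image_tiff <- function(img, path) {
  pages <- if (is.list(img)) img else list(img)
  pages <- lapply(pages, function(m) {
    m <- round(m)
    assert_that(all(m >= 0) && all(m <= 65535),
                "image intensities must lie in [0, 65535] for 16-bit TIFF")
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path, pages = "all") {
  out <- tiff::readTIFF(path, all = TRUE)
  out <- lapply(out, function(m) round(m * 65535))
  if (identical(pages, "all")) {
    if (length(out) == 1L) out[[1L]] else out
  } else {
    out[[pages]]
  }
}

# 4-connected components over a set of (row, col) pixel coordinates given as a
# two-column matrix. Returns an integer component label per pixel. The sets
# handled here are tiny (pole regions of single cells), so a plain union-find
# over a coordinate hash is adequate.
label_components4 <- function(px) {
  n <- nrow(px)
  if (n == 0L) return(integer(0))
  key <- paste(px[, 1L], px[, 2L])
  idx <- seq_len(n)
  names(idx) <- key
  parent <- idx
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  for (i in seq_len(n)) {
    for (d in list(c(1, 0), c(0, 1))) {
      nb <- paste(px[i, 1L] + d[1L], px[i, 2L] + d[2L])
      j <- idx[nb]
      if (!is.na(j)) union(i, j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
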