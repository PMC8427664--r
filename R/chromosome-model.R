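#' Chromosome model
#'
#' A minimal description of the chromosome a rearrangement lives on: a name,
#' its length in base pairs and (optionally) the centromere interval. All
#' coordinates in this package are 1-based and inclusive; BED files are
#' converted at the I/O boundary.
#'
#' @param name Character label, e.g. `"chr6"`.
#' @param length Chromosome length in bp (positive integer).
#' @param centromere Optional numeric vector `c(start, end)` in bp,
#'   `1 <= start <= end <= length`. Required only when pericentric versus
#'   paracentric classification is requested.
#'
#' @return An object of class `chromosome_model`.
#' @examples
#' chromosome_model("chr6", 171115067, centromere = c(58780166, 61880166))
#' @export
chromosome_model <- function(name, length, centromere = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  length <- as.numeric(length)
  if (length(length) != 1L || is.na(length) || length <= 0 || length != floor(length))
    stop("`length` must be a single positive integer (bp)", call. = FALSE)
  if (!is.null(centromere)) {
    centromere <- as.numeric(centromere)
    if (length(centromere) != 2L || any(is.na(centromere)))
      stop("`centromere` must be c(start, end)", call. = FALSE)
    if (centromere[1] < 1 || centromere[2] > length || centromere[1] > centromere[2])
      stop("centromere interval must satisfy 1 <= start <= end <= length", call. = FALSE)
  }
  structure(
    list(name = name, length = length, centromere = centromere),
    class = "chromosome_model"
  )
}

#' @export
print.chromosome_model <- function(x, ...) {
  cat(sprintf("<chromosome_model> %s: 1-%s bp", x$name, format(x$length, big.mark = ",")))
  if (!is.null(x$centromere))
    cat(sprintf("; centromere %s-%s",
                format(x$centromere[1], big.mark = ","),
                format(x$centromere[2], big.mark = ",")))
  cat("\n")
  invisible(x)
}

centromere_midpoint <- function(model) {
  if (is.null(model$centromere)) return(NULL)
  floor((model$centromere[1] + model$centromere[2]) / 2)
}

#' Gene annotation table
#'
#' Constructs and validates a gene annotation: one row per gene with a
#' 1-based closed interval and a biotype. Intervals must lie within the
#' chromosome when a model is supplied, and gene ids must be unique.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param start,end Integer vectors, 1-based inclusive, `start <= end`.
#' @param biotype Character vector (recycled), default `"protein_coding"`.
#' @param model Optional [chromosome_model()] used to bounds-check intervals.
#'
#' @return A `data.frame` of class `gene_annotation` with columns
#'   `gene_id`, `start`, `end`, `biotype`, sorted by `start`.
#' @export
gene_annotation <- function(gene_id = character(), start = numeric(),
                            end = numeric(), biotype = "protein_coding",
                            model = NULL) {
  n <- length(gene_id)
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != n || length(end) != n)
    stop("gene_id, start and end must have equal length", call. = FALSE)
  if (anyDuplicated(gene_id))
    stop("gene ids must be unique", call. = FALSE)
  if (n > 0) {
    if (any(is.na(start)) || any(is.na(end)) || any(start > end) || any(start < 1))
      stop("gene intervals must satisfy 1 <= start <= end", call. = FALSE)
    if (!is.null(model) && any(end > model$length))
      stop("gene intervals exceed chromosome length", call. = FALSE)
  }
  biotype <- rep_len(as.character(biotype), n)
  ann <- data.frame(gene_id = as.character(gene_id), start = start, end = end,
                    biotype = biotype, stringsAsFactors = FALSE)
  ann <- ann[order(ann$start, ann$end), , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

# Fast point-in-gene lookup against an annotation sorted by start.
# Returns the row index of a containing gene (the latest-starting one when
# genes overlap) or NA. Used in the simulation hot loop.
gene_index_at <- function(pos, ann) {
  if (nrow(ann) == 0L) return(rep(NA_integer_, length(pos)))
  idx <- findInterval(pos, ann$start)
  out <- rep(NA_integer_, length(pos))
  ok <- idx >= 1L
  hit <- ok & pos <= ann$end[pmax(idx, 1L)]
  out[hit] <- idx[hit]
  # With overlapping genes the containing gene may start earlier than the
  # one findInterval lands on; cummax of ends tells us whether to scan back.
  cm <- cummax(ann$end)
  deep <- which(ok & !hit & cm[pmax(idx, 1L)] >= pos)
  for (i in deep) {
    for (j in seq(idx[i], 1L)) {
      if (ann$end[j] >= pos[i]) { out[i] <- j; break }
    }
  }
  out
}
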