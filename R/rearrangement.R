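#' @importFrom stats setNames
NULL

.SIDES <- c("left_of_cut", "right_of_cut")

#' Build a junction table
#'
#' A junction is the novel adjacency joining two breakends. Each breakend is a
#' 1-based reference position plus a side stating which flank of the cut the
#' retained sequence lies on: `left_of_cut` means the retained sequence ends at
#' `pos` (the cut sits between `pos` and `pos + 1`); `right_of_cut` means the
#' retained sequence starts at `pos` (the cut sits between `pos - 1` and
#' `pos`). `inserted_seq` holds any non-templated or templated bases observed
#' at the join (may be empty).
#'
#' @param junction_id Character vector of unique ids.
#' @param chrom_a,chrom_b Chromosome names (single chromosome supported).
#' @param pos_a,pos_b Breakend positions (bp, 1-based).
#' @param side_a,side_b `"left_of_cut"` or `"right_of_cut"`.
#' @param inserted_seq Inserted bases at the join (default empty).
#'
#' @return A `data.frame` of class `junction_table`.
#' @export
junction_table <- function(junction_id, chrom_a, pos_a, side_a,
                           chrom_b, pos_b, side_b, inserted_seq = "") {
  n <- length(junction_id)
  tab <- data.frame(
    junction_id = as.character(junction_id),
    chrom_a = rep_len(as.character(chrom_a), n),
    pos_a = as.numeric(pos_a),
    side_a = rep_len(as.character(side_a), n),
    chrom_b = rep_len(as.character(chrom_b), n),
    pos_b = as.numeric(pos_b),
    side_b = rep_len(as.character(side_b), n),
    inserted_seq = toupper(rep_len(as.character(inserted_seq), n)),
    stringsAsFactors = FALSE
  )
  validate_junction_table(tab)
}

validate_junction_table <- function(tab) {
  req <- c("junction_id", "chrom_a", "pos_a", "side_a",
           "chrom_b", "pos_b", "side_b", "inserted_seq")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("junction table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tab$junction_id))
    stop("duplicate junction_id: ",
         paste(unique(tab$junction_id[duplicated(tab$junction_id)]), collapse = ", "),
         call. = FALSE)
  if (any(is.na(tab$pos_a)) || any(is.na(tab$pos_b)))
    stop("junction positions must be numeric", call. = FALSE)
  if (any(tab$pos_a < 1) || any(tab$pos_b < 1))
    stop("breakend positions must be >= 1", call. = FALSE)
  if (!all(tab$side_a %in% .SIDES) || !all(tab$side_b %in% .SIDES))
    stop("breakend sides must be 'left_of_cut' or 'right_of_cut'", call. = FALSE)
  same <- tab$chrom_a == tab$chrom_b & tab$pos_a == tab$pos_b & tab$side_a == tab$side_b
  if (any(same))
    stop("junction(s) with two identical breakends: ",
         paste(tab$junction_id[same], collapse = ", "), call. = FALSE)
  class(tab) <- unique(c("junction_table", class(tab)))
  tab
}

# cut implied by a breakend: left_of_cut at pos -> cut pos; right_of_cut -> pos - 1
implied_cut <- function(pos, side) ifelse(side == "left_of_cut", pos, pos - 1)

#' Partition a chromosome into segments at cut sites
#'
#' Cut site `x` means "cut between positions `x` and `x + 1`", so `k` cuts
#' produce `k + 1` segments partitioning `[1, length]`. Segments are labelled
#' `A`, `B`, ... in reference order and returned in direct orientation.
#'
#' @param cuts Strictly increasing cut positions, each in `[1, length - 1]`.
#' @param model A [chromosome_model()].
#'
#' @return A `data.frame` of class `derivative_path` (the identity path) with
#'   columns `segment_id`, `start`, `end`, `orientation`.
#' @examples
#' m <- chromosome_model("chr1", 100)
#' segments_from_cuts(c(40), m)  # [1,40] and [41,100]
#' @export
segments_from_cuts <- function(cuts, model) {
  cuts <- as.numeric(cuts)
  if (anyNA(cuts)) stop("cut sites must be numeric", call. = FALSE)
  if (is.unsorted(cuts, strictly = TRUE))
    stop("cut sites must be strictly increasing (duplicates not allowed)", call. = FALSE)
  if (length(cuts) && (min(cuts) < 1 || max(cuts) > model$length - 1))
    stop("cut sites must lie in [1, length - 1]", call. = FALSE)
  bounds <- c(0, cuts, model$length)
  n <- length(bounds) - 1L
  path <- data.frame(
    segment_id = segment_labels(n),
    start = bounds[-length(bounds)] + 1,
    end = bounds[-1],
    orientation = "direct",
    stringsAsFactors = FALSE
  )
  new_derivative_path(path, model)
}

segment_labels <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  sprintf("S%03d", seq_len(n))
}

new_derivative_path <- function(path, model) {
  rownames(path) <- NULL
  attr(path, "model") <- model
  class(path) <- unique(c("derivative_path", class(path)))
  path
}

#' Validate a derivative path
#'
#' Checks that the segment reference intervals are pairwise disjoint, that
#' their union is `[1, model$length]` (copy-number neutrality), and that
#' orientations are valid.
#'
#' @param path A `derivative_path` data frame.
#' @param model Optional [chromosome_model()]; defaults to the one attached
#'   to `path`.
#' @return `path`, invisibly, or an error.
#' @export
validate_path <- function(path, model = attr(path, "model")) {
  stopifnot(is.data.frame(path))
  if (is.null(model)) stop("derivative path has no chromosome model", call. = FALSE)
  if (!all(c("segment_id", "start", "end", "orientation") %in% names(path)))
    stop("path must have columns segment_id, start, end, orientation", call. = FALSE)
  if (!all(path$orientation %in% c("direct", "inverted")))
    stop("orientations must be 'direct' or 'inverted'", call. = FALSE)
  if (any(path$start > path$end))
    stop("segment intervals must satisfy start <= end", call. = FALSE)
  ref <- path[order(path$start), , drop = FALSE]
  if (ref$start[1] != 1 || ref$end[nrow(ref)] != model$length ||
      (nrow(ref) > 1 && any(ref$start[-1] != ref$end[-nrow(ref)] + 1)))
    stop("segments do not partition [1, length]: path is not copy-number neutral",
         call. = FALSE)
  invisible(path)
}

#' Assemble a derivative chromosome from breakpoint junctions
#'
#' Given the breakpoint junctions of a single-chromosome, copy-number-neutral
#' rearrangement, reconstructs the unique linear derivative path. Breakends
#' whose implied cut positions lie within `merge_tolerance` of each other are
#' unified into a single cut site (real junction pairs differ by small
#' resections), with the merged cut placed at the midpoint (rounded down).
#' The walk starts at the segment containing reference position 1, which must
#' be entered in direct orientation, and must end at the segment containing
#' the last reference base.
#'
#' @param junctions A [junction_table()] (or data frame with its columns).
#' @param model A [chromosome_model()].
#' @param merge_tolerance Breakends within this many bp share a cut
#'   (default 100).
#'
#' @return A `derivative_path`: segments in derivative order with
#'   orientations, the chromosome model attached as an attribute.
#' @export
assemble_path <- function(junctions, model, merge_tolerance = 100) {
  junctions <- validate_junction_table(as.data.frame(junctions))
  if (nrow(junctions) == 0L)
    return(segments_from_cuts(numeric(), model))
  chroms <- unique(c(junctions$chrom_a, junctions$chrom_b))
  if (length(chroms) > 1L)
    stop("multi-chromosome junction sets are not supported (got: ",
         paste(chroms, collapse = ", "), ")", call. = FALSE)

  # one row per breakend
  be <- data.frame(
    junction_id = rep(junctions$junction_id, 2L),
    pos = c(junctions$pos_a, junctions$pos_b),
    side = c(junctions$side_a, junctions$side_b),
    stringsAsFactors = FALSE
  )
  be$cut_raw <- implied_cut(be$pos, be$side)
  if (any(be$cut_raw < 1 | be$cut_raw > model$length - 1))
    stop("breakend(s) imply cut sites outside [1, length - 1]", call. = FALSE)

  # single-linkage clustering of implied cuts within merge_tolerance
  ord <- order(be$cut_raw)
  sorted <- be$cut_raw[ord]
  grp_sorted <- cumsum(c(1, diff(sorted) > merge_tolerance))
  grp <- integer(nrow(be)); grp[ord] <- grp_sorted
  cuts <- vapply(split(be$cut_raw, grp), function(x) floor((min(x) + max(x)) / 2),
                 numeric(1))
  be$cut <- cuts[as.character(grp)]

  # each cut must be used by exactly one left-side and one right-side breakend
  for (cid in unique(names(cuts))) {
    sides <- be$side[grp == as.integer(cid)]
    jids <- be$junction_id[grp == as.integer(cid)]
    if (sum(sides == "left_of_cut") > 1 || sum(sides == "right_of_cut") > 1)
      stop("non-linear architecture: breakend used twice at cut ",
           cuts[cid], " (junctions ", paste(unique(jids), collapse = ", "), ")",
           call. = FALSE)
    if (length(sides) != 2L)
      stop("non-linear architecture: dangling segment end at cut ",
           cuts[cid], " (junction ", paste(unique(jids), collapse = ", "), ")",
           call. = FALSE)
  }

  cut_sites <- sort(unique(be$cut))
  ref <- segments_from_cuts(cut_sites, model)
  nseg <- nrow(ref)

  # map breakends to segment ends; segment i: left end at cut i-1, right end at cut i
  seg_of_cut_left <- match(be$cut, cut_sites)         # segment ending at the cut
  be$segment <- ifelse(be$side == "left_of_cut", seg_of_cut_left, seg_of_cut_left + 1L)
  be$end_used <- ifelse(be$side == "left_of_cut", "right", "left")

  # pairing: junction id -> its two (segment, end) tokens
  token <- paste(be$segment, be$end_used, sep = ":")
  partner <- setNames(vector("list", length(unique(be$junction_id))),
                      unique(be$junction_id))
  link <- split(seq_len(nrow(be)), be$junction_id)
  pair_of <- new.env(parent = emptyenv())
  for (jid in names(link)) {
    idx <- link[[jid]]
    assign(token[idx[1]], list(to = token[idx[2]], jid = jid), envir = pair_of)
    assign(token[idx[2]], list(to = token[idx[1]], jid = jid), envir = pair_of)
  }

  # walk from the p-terminal segment
  order_idx <- integer(nseg)
  orient <- character(nseg)
  seen <- logical(nseg)
  terminated <- FALSE
  cur_seg <- 1L; cur_entry <- "left"
  for (step in seq_len(nseg)) {
    if (seen[cur_seg])
      stop("non-linear architecture: cyclic structure revisits segment ",
           ref$segment_id[cur_seg], call. = FALSE)
    seen[cur_seg] <- TRUE
    order_idx[step] <- cur_seg
    orient[step] <- if (cur_entry == "left") "direct" else "inverted"
    exit_end <- if (cur_entry == "left") "right" else "left"
    exit_token <- paste(cur_seg, exit_end, sep = ":")
    if (cur_seg == nseg && exit_end == "right") {
      if (step != nseg)
        stop("non-linear architecture: q-terminal segment reached before all ",
             "segments were placed", call. = FALSE)
      terminated <- TRUE
      break
    }
    if (!exists(exit_token, envir = pair_of))
      stop("non-linear architecture: dangling end of segment ",
           ref$segment_id[cur_seg], call. = FALSE)
    nxt <- get(exit_token, envir = pair_of)
    cur_entry <- sub(".*:", "", nxt$to)
    cur_seg <- as.integer(sub(":.*", "", nxt$to))
  }
  if (!terminated || !all(seen))
    stop("non-linear architecture: walk did not terminate at the q-terminal ",
         "segment after visiting every segment", call. = FALSE)

  path <- ref[order_idx, , drop = FALSE]
  path$orientation <- orient
  path <- new_derivative_path(path, model)
  validate_path(path)
  path
}

# is the adjacency between consecutive oriented segments a reference join?
is_reference_adjacency <- function(s, t) {
  (s$orientation == "direct" && t$orientation == "direct" && t$start == s$end + 1) ||
    (s$orientation == "inverted" && t$orientation == "inverted" && s$start == t$end + 1)
}

#' Derive breakpoint junctions from a derivative path
#'
#' The inverse of [assemble_path()]: walks the path and emits one junction per
#' adjacency between consecutive segments. By default only non-reference
#' adjacencies (true breakpoint junctions) are emitted; with
#' `include_reference = TRUE` every adjacency is emitted, which makes the
#' round trip through [assemble_path()] exact even for paths that re-create
#' reference joins.
#'
#' @param path A `derivative_path`.
#' @param include_reference Emit junctions for reference-preserving
#'   adjacencies too (default `FALSE`).
#'
#' @return A [junction_table()] with ids `J1`, `J2`, ... in path order.
#' @export
junctions_from_path <- function(path, include_reference = FALSE) {
  model <- attr(path, "model")
  validate_path(path, model)
  n <- nrow(path)
  rows <- list()
  for (i in seq_len(max(0L, n - 1L))) {
    s <- path[i, ]; t <- path[i + 1L, ]
    if (!include_reference && is_reference_adjacency(s, t)) next
    a <- if (s$orientation == "direct")
      list(pos = s$end, side = "left_of_cut")
    else list(pos = s$start, side = "right_of_cut")
    b <- if (t$orientation == "direct")
      list(pos = t$start, side = "right_of_cut")
    else list(pos = t$end, side = "left_of_cut")
    rows[[length(rows) + 1L]] <- data.frame(
      junction_id = NA_character_, chrom_a = model$name, pos_a = a$pos,
      side_a = a$side, chrom_b = model$name, pos_b = b$pos, side_b = b$side,
      inserted_seq = "", stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    tab <- junction_table(character(), character(), numeric(), character(),
                          character(), numeric(), character())
    return(tab)
  }
  tab <- do.call(rbind, rows)
  tab$junction_id <- paste0("J", seq_len(nrow(tab)))
  validate_junction_table(tab)
}

#' Count inversions on a derivative path
#'
#' Every segment carried in inverted orientation counts as one inversion
#' event. An inversion is pericentric when the segment's reference interval
#' contains the centromere midpoint, paracentric otherwise. `n_junctions` is
#' the number of adjacencies in the path that differ from the reference.
#'
#' @param path A `derivative_path` whose model carries a centromere whenever
#'   any inversion is present.
#'
#' @return A list of class `inversion_summary`: `n_inversions`,
#'   `n_pericentric`, `n_paracentric`, `n_junctions`, and `per_segment`
#'   (data frame of inverted segments and their class).
#' @export
classify_inversions <- function(path) {
  model <- attr(path, "model")
  validate_path(path, model)
  inv <- path[path$orientation == "inverted", , drop = FALSE]
  mid <- centromere_midpoint(model)
  if (nrow(inv) > 0 && is.null(mid))
    stop("centromere undefined on the chromosome model: cannot classify ",
         "inversions as pericentric or paracentric", call. = FALSE)
  peri <- if (nrow(inv)) inv$start <= mid & mid <= inv$end else logical()
  n <- nrow(path)
  n_junc <- 0L
  for (i in seq_len(max(0L, n - 1L)))
    if (!is_reference_adjacency(path[i, ], path[i + 1L, ])) n_junc <- n_junc + 1L
  per_segment <- data.frame(
    segment_id = inv$segment_id,
    class = ifelse(peri, "pericentric", "paracentric"),
    stringsAsFactors = FALSE
  )
  structure(
    list(n_inversions = nrow(inv),
         n_pericentric = sum(peri),
         n_paracentric = sum(!peri),
         n_junctions = n_junc,
         per_segment = per_segment),
    class = "inversion_summary"
  )
}

#' @export
print.inversion_summary <- function(x, ...) {
  cat(sprintf("<inversion_summary> %d inversion(s): %d pericentric, %d paracentric; %d breakpoint junction(s)\n",
              x$n_inversions, x$n_pericentric, x$n_paracentric, x$n_junctions))
  if (nrow(x$per_segment)) {
    for (i in seq_len(nrow(x$per_segment)))
      cat(sprintf("  segment %s: %s\n", x$per_segment$segment_id[i], x$per_segment$class[i]))
  }
  invisible(x)
}

# merge runs of reference-adjacent direct/inverted segments; used to state the
# round-trip property of junctions_from_path on paths that re-create
# reference joins.
normalize_path <- function(path) {
  model <- attr(path, "model")
  validate_path(path, model)
  n <- nrow(path)
  if (n <= 1L) return(path)
  keep <- list(path[1L, ])
  for (i in seq(2L, n)) {
    last <- keep[[length(keep)]]
    cur <- path[i, ]
    if (is_reference_adjacency(last, cur)) {
      last$start <- min(last$start, cur$start)
      last$end <- max(last$end, cur$end)
      keep[[length(keep)]] <- last
    } else {
      keep[[length(keep) + 1L]] <- cur
    }
  }
  out <- do.call(rbind, keep)
  # relabel by reference order
  ref_rank <- rank(out$start)
  out$segment_id <- segment_labels(nrow(out))[ref_rank]
  new_derivative_path(out, model)
}
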