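#' Generate a synthetic protein-coding gene annotation
#'
#' Draws `n_genes` non-overlapping gene intervals on the chromosome, with
#' lengths sampled from an exponential distribution of mean `mean_len`
#' (rounded, at least 1 bp) and starts uniform. Overlapping placements are
#' rejection-sampled gene by gene; exceeding the retry budget raises rather
#' than silently relaxing the disjointness constraint. Deterministic given
#' `seed`.
#'
#' @param model A [chromosome_model()].
#' @param n_genes Number of genes (>= 0).
#' @param mean_len Mean gene length in bp (>= 1).
#' @param seed Integer seed.
#' @param max_retries Placement retries per gene (default 1000).
#'
#' @return A [gene_annotation()] with biotype `"protein_coding"`, sorted by
#'   start.
#' @export
generate_genes <- function(model, n_genes, mean_len, seed, max_retries = 1000) {
  stopifnot(n_genes >= 0, mean_len >= 1)
  if (n_genes * mean_len >= model$length)
    stop("impossible packing: requested total gene footprint (", n_genes, " x ",
         mean_len, " bp) is not below the chromosome length", call. = FALSE)
  if (n_genes == 0)
    return(gene_annotation(model = model))
  withr::with_seed(seed, {
    lens <- pmax(1, round(stats::rexp(n_genes, rate = 1 / mean_len)))
    lens <- pmin(lens, model$length)
    starts_acc <- numeric(0); ends_acc <- numeric(0)
    for (i in seq_len(n_genes)) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        s <- floor(stats::runif(1, min = 1, max = model$length - lens[i] + 1))
        e <- s + lens[i] - 1
        j <- findInterval(e, starts_acc)
        if (j >= 1 && ends_acc[j] >= s) next  # overlap
        pos <- findInterval(s, starts_acc)
        starts_acc <- append(starts_acc, s, after = pos)
        ends_acc <- append(ends_acc, e, after = pos)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place gene ", i, " without overlap after ",
             max_retries, " retries", call. = FALSE)
    }
    gene_annotation(gene_id = sprintf("SYNG%04d", seq_len(n_genes)),
                    start = starts_acc, end = ends_acc,
                    biotype = "protein_coding", model = model)
  })
}

#' Generate a ground-truthed rearrangement case
#'
#' Draws a copy-number-neutral shuffle of the chromosome mirroring the null
#' model: `n_segments - 1` distinct cut sites uniform on `[1, length - 1]`,
#' first and last segments positionally static and direct, middle segments
#' uniformly permuted and each independently inverted with probability
#' `inversion_prob`. The emitted junction list covers every derivative
#' adjacency (including any that re-create a reference join), so
#' [assemble_path()] on it reproduces `truth_path` exactly.
#'
#' @param model A [chromosome_model()].
#' @param n_segments Number of segments (>= 3).
#' @param inversion_prob Per-segment inversion probability in `[0, 1]`.
#' @param seed Integer seed.
#'
#' @return An object of class `rearrangement_case`: `model`, `truth_path`,
#'   `junctions`, `cut_sites`.
#' @export
generate_case <- function(model, n_segments, inversion_prob = 0.5, seed) {
  stopifnot(n_segments >= 3, inversion_prob >= 0, inversion_prob <= 1)
  if (n_segments - 1 > model$length - 1)
    stop("more segments requested than the chromosome can hold", call. = FALSE)
  withr::with_seed(seed, {
    draw <- draw_shuffle(model$length, n_segments, inversion_prob)
    truth <- shuffle_to_path(draw, model)
    junctions <- junctions_from_path(truth, include_reference = TRUE)
    structure(
      list(model = model, truth_path = truth, junctions = junctions,
           cut_sites = draw$cuts),
      class = "rearrangement_case"
    )
  })
}

# one random shuffle; consumes the current RNG stream (no seeding here)
draw_shuffle <- function(length, n_segments, inversion_prob) {
  k <- n_segments - 1L
  cuts <- sort(sample.int(length - 1L, k))
  mid <- seq(2L, n_segments - 1L)
  perm <- mid[sample.int(length(mid))]
  inverted <- stats::runif(length(mid)) < inversion_prob
  list(cuts = cuts, perm = perm, inverted = inverted)
}

shuffle_to_path <- function(draw, model) {
  ref <- segments_from_cuts(draw$cuts, model)
  n <- nrow(ref)
  order_idx <- c(1L, draw$perm, n)
  path <- ref[order_idx, , drop = FALSE]
  path$orientation <- c("direct",
                        ifelse(draw$inverted, "inverted", "direct"),
                        "direct")
  new_derivative_path(path, model)
}

.BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

set_substr <- function(x, at, value) {
  substr(x, at, at + nchar(value) - 1L) <- value
  x
}

pick_base_not <- function(exclude) sample(setdiff(.BASES, exclude), 1L)

#' Generate a junction sequence bundle with a planted signature
#'
#' Builds random reference flanks and an observed junction sequence such that
#' the planted signature is the unique maximal call: a planted microhomology
#' of length `k` is shared by the proximal end and the distal flank with the
#' `k + 1`-th base breaking the extension on both sides; a planted insertion
#' is absent from both flanks within the template search window unless a
#' templated origin is specified, in which case the insertion occurs exactly
#' there. Construction is verified by re-calling the bundle; failures draw
#' fresh randomness up to `max_retries` times and then raise.
#'
#' @param truth A [signature_call()] to plant.
#' @param flank_len Flank radius F (default 60 bp); must be at least
#'   `mh_len + nchar(ins_seq) + window`.
#' @param seed Integer seed.
#' @param window Template search window the bundle must support (default 50).
#' @param max_retries Bounded retry count (default 1000).
#'
#' @return A [junction_bundle()] with `truth` attached.
#' @export
generate_junction_bundle <- function(truth, flank_len = 60, seed,
                                     window = 50, max_retries = 1000) {
  stopifnot(inherits(truth, "signature_call"))
  ins_len <- nchar(truth$ins_seq)
  if (flank_len < truth$mh_len + ins_len + window)
    stop("flank_len must be >= mh_len + insertion length + search window",
         call. = FALSE)
  withr::with_seed(seed, {
    for (try in seq_len(max_retries)) {
      bundle <- try_plant_bundle(truth, flank_len, window)
      if (is.null(bundle)) next
      got <- tryCatch(classify_junction(bundle, window = window),
                      error = function(e) NULL)
      if (is.null(got)) next
      if (signature_matches(got, truth)) {
        bundle$truth <- truth
        return(bundle)
      }
    }
    stop("generation error: could not satisfy the planted-signature ",
         "constraints after ", max_retries, " retries", call. = FALSE)
  })
}

signature_matches <- function(got, truth) {
  if (got$klass != truth$klass || got$mh_len != truth$mh_len ||
      got$mh_seq != truth$mh_seq || got$ins_seq != truth$ins_seq)
    return(FALSE)
  if (is.null(truth$template_hit) != is.null(got$template_hit)) return(FALSE)
  if (!is.null(truth$template_hit)) {
    th <- truth$template_hit; gh <- got$template_hit
    if (th$source != gh$source || th$offset != gh$offset ||
        th$strand != gh$strand) return(FALSE)
  }
  TRUE
}

# Mutate one unprotected base inside every occurrence of pat (on the given
# flank) whose start lies within the window, except the occurrence starting
# at `keep`. Returns the edited flank or NULL when an occurrence cannot be
# broken without touching a protected position.
break_occurrences <- function(flank, pat, c0, window, keep = NA_integer_,
                              protect = integer()) {
  for (iter in 1:100) {
    starts <- find_all(pat, flank)
    starts <- starts[abs(starts - c0) <= window &
                     (is.na(keep) | starts != keep)]
    if (!length(starts)) return(flank)
    p <- starts[1]
    cand <- setdiff(seq(p, p + nchar(pat) - 1L), protect)
    if (!length(cand)) return(NULL)
    at <- sample(cand, 1L)
    cur <- substr(flank, at, at)
    flank <- set_substr(flank, at, pick_base_not(cur))
  }
  NULL
}

# one construction attempt; returns NULL on an internal constraint clash
try_plant_bundle <- function(truth, flank_len, window) {
  F <- as.integer(flank_len)
  c0 <- F + 1L
  X <- random_dna(2L * F + 1L)
  Y <- random_dna(2L * F + 1L)
  k <- truth$mh_len
  ins <- truth$ins_seq

  if (k > 0L) {
    # share mh_seq between the proximal end and the distal flank just
    # upstream of the start of the retained distal sequence
    X <- set_substr(X, c0 - k + 1L, truth$mh_seq)
    Y <- set_substr(Y, c0, truth$mh_seq)
    X <- set_substr(X, c0 - k, pick_base_not(substr(Y, c0 - 1L, c0 - 1L)))
    X <- set_substr(X, c0 + 1L, pick_base_not(substr(Y, c0 + k, c0 + k)))
    obs <- paste0(substr(X, 2L, c0), substr(Y, c0 + k, c0 + F - 1L))
  } else if (nzchar(ins)) {
    if (!is.null(truth$template_hit)) {
      th <- truth$template_hit
      pat <- if (th$strand == "forward") ins else revcomp(ins)
      at <- c0 + th$offset
      if (at < 1L || at + nchar(pat) - 1L > 2L * F + 1L) return(NULL)
      if (th$source == "proximal") X <- set_substr(X, at, pat)
      else Y <- set_substr(Y, at, pat)
    }
    first <- substr(ins, 1L, 1L)
    last <- substr(ins, ins_len_ <- nchar(ins), ins_len_)
    # block extension into the insertion from either side
    if (substr(X, c0 + 1L, c0 + 1L) == first)
      X <- set_substr(X, c0 + 1L, pick_base_not(first))
    if (substr(Y, c0 - 1L, c0 - 1L) == last)
      Y <- set_substr(Y, c0 - 1L, pick_base_not(last))
    # destroy chance template occurrences so the planted origin (if any) is
    # the unique minimal hit, and a non-templated insertion has none at all
    if (nchar(ins) >= 3L) {
      th <- truth$template_hit
      prot_X <- c0 + 1L; prot_Y <- c0 - 1L
      keep_X_f <- keep_X_r <- keep_Y_f <- keep_Y_r <- NA_integer_
      if (!is.null(th)) {
        at <- c0 + th$offset
        prot_range <- seq(at, at + nchar(ins) - 1L)
        palindromic <- revcomp(ins) == ins
        if (th$source == "proximal") {
          prot_X <- c(prot_X, prot_range)
          if (th$strand == "forward" || palindromic) keep_X_f <- at
          if (th$strand == "reverse_complement" || palindromic) keep_X_r <- at
        } else {
          prot_Y <- c(prot_Y, prot_range)
          if (th$strand == "forward" || palindromic) keep_Y_f <- at
          if (th$strand == "reverse_complement" || palindromic) keep_Y_r <- at
        }
      }
      rc <- revcomp(ins)
      X <- break_occurrences(X, ins, c0, window, keep_X_f, prot_X)
      if (is.null(X)) return(NULL)
      X <- break_occurrences(X, rc, c0, window, keep_X_r, prot_X)
      if (is.null(X)) return(NULL)
      Y <- break_occurrences(Y, ins, c0, window, keep_Y_f, prot_Y)
      if (is.null(Y)) return(NULL)
      Y <- break_occurrences(Y, rc, c0, window, keep_Y_r, prot_Y)
      if (is.null(Y)) return(NULL)
    }
    obs <- paste0(substr(X, 2L, c0), ins, substr(Y, c0, c0 + F - 1L))
  } else {
    # blunt: break the extension on both sides of the join
    X <- set_substr(X, c0 + 1L, pick_base_not(substr(Y, c0, c0)))
    Y <- set_substr(Y, c0 - 1L, pick_base_not(substr(X, c0, c0)))
    obs <- paste0(substr(X, 2L, c0), substr(Y, c0, c0 + F - 1L))
  }
  junction_bundle(X, Y, obs, flank_len = F, junction_id = truth$junction_id)
}
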