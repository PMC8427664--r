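#' Junction sequence bundle
#'
#' Holds the three sequences needed to call a junction signature at
#' nucleotide resolution: the proximal reference flank (centred on breakend A,
#' spanning `[pos_A - flank_len, pos_A + flank_len]`, retained sequence ending
#' at the centre base), the distal reference flank (centred on breakend B,
#' retained sequence starting at the centre base), and the observed sequence
#' read across the join. All sequences are over `{A, C, G, T}`.
#'
#' @param proximal_ref,distal_ref,junction_obs Character strings.
#' @param flank_len Flank radius F in bp; the breakend base sits at index
#'   `F + 1` of each reference flank.
#' @param junction_id Optional id carried through to calls.
#' @param truth Optional planted [signature_call()] (synthetic bundles).
#'
#' @return An object of class `junction_bundle`.
#' @export
junction_bundle <- function(proximal_ref, distal_ref, junction_obs,
                            flank_len, junction_id = NA_character_,
                            truth = NULL) {
  seqs <- c(proximal_ref, distal_ref, junction_obs)
  if (any(grepl("[^ACGT]", seqs)))
    stop("bundle sequences must be over {A,C,G,T}", call. = FALSE)
  if (nchar(junction_obs) < 2)
    stop("junction_obs must have length >= 2", call. = FALSE)
  flank_len <- as.integer(flank_len)
  if (nchar(proximal_ref) != 2L * flank_len + 1L ||
      nchar(distal_ref) != 2L * flank_len + 1L)
    stop("reference flanks must have length 2 * flank_len + 1", call. = FALSE)
  structure(
    list(proximal_ref = proximal_ref, distal_ref = distal_ref,
         junction_obs = junction_obs, flank_len = flank_len,
         junction_id = junction_id, truth = truth),
    class = "junction_bundle"
  )
}

#' Signature call for one junction
#'
#' @param junction_id Junction id.
#' @param klass `"blunt"`, `"microhomology"` or `"insertion"`.
#' @param mh_len Microhomology length (bp, >= 0).
#' @param mh_seq Microhomology sequence (`nchar(mh_seq) == mh_len`).
#' @param ins_seq Inserted sequence (non-empty iff `klass == "insertion"`).
#' @param template_hit `NULL` or a [template_hit()].
#' @param ambiguous Logical; `TRUE` when a 1-bp feature admits the competing
#'   interpretation (insertion versus microhomology) as well.
#'
#' @return An object of class `signature_call`.
#' @export
signature_call <- function(junction_id, klass, mh_len = 0L, mh_seq = "",
                           ins_seq = "", template_hit = NULL,
                           ambiguous = FALSE) {
  klass <- match.arg(klass, c("blunt", "microhomology", "insertion"))
  mh_len <- as.integer(mh_len)
  ok <- switch(klass,
    blunt = mh_len == 0L && !nzchar(ins_seq),
    microhomology = mh_len >= 1L && !nzchar(ins_seq),
    insertion = nzchar(ins_seq)
  )
  if (!ok || nchar(mh_seq) != mh_len)
    stop("inconsistent signature call: class ", klass, " with mh_len ", mh_len,
         ", mh_seq '", mh_seq, "', ins_seq '", ins_seq, "'", call. = FALSE)
  structure(
    list(junction_id = junction_id, klass = klass, mh_len = mh_len,
         mh_seq = mh_seq, ins_seq = toupper(ins_seq),
         template_hit = template_hit, ambiguous = isTRUE(ambiguous)),
    class = "signature_call"
  )
}

#' Templated-insertion origin
#'
#' @param source `"proximal"` or `"distal"` flank.
#' @param offset Signed start offset of the template occurrence relative to
#'   the breakend base (negative = upstream of the breakend).
#' @param strand `"forward"` or `"reverse_complement"`.
#' @return An object of class `template_hit`.
#' @export
template_hit <- function(source, offset, strand = "forward") {
  structure(
    list(source = match.arg(source, c("proximal", "distal")),
         offset = as.integer(offset),
         strand = match.arg(strand, c("forward", "reverse_complement"))),
    class = "template_hit"
  )
}

#' @export
print.signature_call <- function(x, ...) {
  extra <- switch(x$klass,
    blunt = "",
    microhomology = sprintf(" mh=%d (%s)", x$mh_len, x$mh_seq),
    insertion = sprintf(" ins=%s (%d nt)", x$ins_seq, nchar(x$ins_seq))
  )
  th <- if (!is.null(x$template_hit))
    sprintf(" templated: %s %+d %s", x$template_hit$source,
            x$template_hit$offset, x$template_hit$strand) else ""
  cat(sprintf("<signature_call> %s: %s%s%s%s\n", x$junction_id, x$klass, extra, th,
              if (x$ambiguous) " [ambiguous]" else ""))
  invisible(x)
}

# longest common extension between a and b starting at given offsets
lce <- function(a, b, ia = 1L, ib = 1L) {
  n <- min(nchar(a) - ia, nchar(b) - ib) + 1L
  if (n <= 0L) return(0L)
  av <- substring(a, ia + seq_len(n) - 1L, ia + seq_len(n) - 1L)
  bv <- substring(b, ib + seq_len(n) - 1L, ib + seq_len(n) - 1L)
  neq <- which(av != bv)
  if (!length(neq)) n else neq[1L] - 1L
}

rev_string <- function(s)
  vapply(s, function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""),
         character(1), USE.NAMES = FALSE)

revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# all start positions of fixed pattern in subject (exact, overlapping)
find_all <- function(pattern, subject) {
  if (!nzchar(pattern) || nchar(pattern) > nchar(subject)) return(integer())
  Biostrings::start(Biostrings::matchPattern(pattern, subject))
}

# Core alignment scan. Anchors the observed junction sequence on each flank
# with a short seed, extends exactly, and reads the signature off the overlap
# arithmetic: with a = longest proximal match from the left and b = longest
# distal match from the right, a + b - n > 0 is the total ambiguous overlap
# (microhomology), == 0 a blunt join, < 0 an insertion of the unmatched
# middle. Returns list(a, b, overlap).
scan_junction <- function(bundle, seed_len = 12L) {
  anchor_extend <- function(query, subject, side) {
    n <- nchar(query)
    for (s in seq(min(seed_len, n), 1L)) {
      starts <- find_all(substr(query, 1L, s), subject)
      if (length(starts))
        return(max(vapply(starts, function(q) lce(query, subject, 1L, q),
                          integer(1))))
    }
    stop("alignment error: junction_obs ", side,
         " end not found in its reference flank", call. = FALSE)
  }
  obs <- bundle$junction_obs
  a <- anchor_extend(obs, bundle$proximal_ref, "5'")
  b <- anchor_extend(rev_string(obs), rev_string(bundle$distal_ref), "3'")
  # a junction read must match each flank over a non-trivial stretch;
  # single-base "alignments" mean the read is inconsistent with the flanks
  min_anchor <- max(1L, min(8L, nchar(obs) %/% 3L))
  if (a < min_anchor || b < min_anchor)
    stop("alignment error: junction_obs is inconsistent with the reference ",
         "flanks (matched only ", a, " bp proximal / ", b, " bp distal)",
         call. = FALSE)
  list(a = a, b = b, overlap = a + b - nchar(obs))
}

#' Call microhomology at a junction
#'
#' Microhomology is sequence shared by both reference flanks at the join,
#' which makes the exact break position ambiguous. The scan extends the
#' observed sequence against the proximal flank from the 5' end and against
#' the distal flank from the 3' end; the excess of the two match lengths over
#' the observed length is the total ambiguous overlap, reported as `mh_len`
#' with its sequence.
#'
#' @param bundle A [junction_bundle()].
#' @return A list with `mh_len` (bp) and `mh_seq`.
#' @export
call_microhomology <- function(bundle) {
  sc <- scan_junction(bundle)
  n <- nchar(bundle$junction_obs)
  if (sc$overlap > 0)
    list(mh_len = sc$overlap,
         mh_seq = substr(bundle$junction_obs, n - sc$b + 1L, sc$a))
  else
    list(mh_len = 0L, mh_seq = "")
}

#' Call inserted sequence at a junction
#'
#' Returns the bases of the observed junction sequence matched by neither
#' reference flank (empty when the flanks abut or overlap). Mutually
#' exclusive with a positive microhomology length.
#'
#' @param bundle A [junction_bundle()].
#' @return The inserted sequence (possibly `""`).
#' @export
call_insertion <- function(bundle) {
  sc <- scan_junction(bundle)
  n <- nchar(bundle$junction_obs)
  if (sc$overlap < 0)
    substr(bundle$junction_obs, sc$a + 1L, n - sc$b)
  else ""
}

#' Search for a templated origin of an inserted sequence
#'
#' Scans both reference flanks, forward and reverse-complement, for an exact
#' occurrence of the inserted sequence starting within `window` bp of the
#' breakend. The hit with the smallest absolute offset wins; ties break
#' proximal before distal, then forward before reverse-complement. Inserted
#' sequences shorter than `min_template_len` are not searched (a 1-nt
#' "template" is uninformative).
#'
#' @param ins_seq Inserted sequence (non-empty).
#' @param bundle A [junction_bundle()].
#' @param window Search radius around each breakend, bp (default 50).
#' @param min_template_len Minimum reportable template length (default 3).
#' @return A [template_hit()] or `NULL`.
#' @export
search_template <- function(ins_seq, bundle, window = 50,
                            min_template_len = 3) {
  stopifnot(nzchar(ins_seq))
  if (nchar(ins_seq) < min_template_len) return(NULL)
  if (window > bundle$flank_len)
    stop("window must not exceed flank_len", call. = FALSE)
  centre <- bundle$flank_len + 1L
  hits <- list()
  flanks <- list(proximal = bundle$proximal_ref, distal = bundle$distal_ref)
  for (src in names(flanks)) {
    for (strand in c("forward", "reverse_complement")) {
      pat <- if (strand == "forward") ins_seq else revcomp(ins_seq)
      for (p in find_all(pat, flanks[[src]])) {
        off <- p - centre
        if (abs(off) <= window)
          hits[[length(hits) + 1L]] <- template_hit(src, off, strand)
      }
    }
  }
  if (!length(hits)) return(NULL)
  key <- vapply(hits, function(h) {
    abs(h$offset) * 4 + (h$source == "distal") * 2 + (h$strand == "reverse_complement")
  }, numeric(1))
  hits[[which.min(key)]]
}

#' Classify a junction's nucleotide-level signature
#'
#' Composes the microhomology and insertion callers and the templated-origin
#' search into a single [signature_call()]. One-base-pair features are
#' formally ambiguous between the insertion and microhomology readings; when
#' the competing interpretation also fits the flanks the call is flagged
#' `ambiguous` rather than silently resolved.
#'
#' @param bundle A [junction_bundle()].
#' @param window,min_template_len Passed to [search_template()].
#' @return A [signature_call()].
#' @export
classify_junction <- function(bundle, window = 50, min_template_len = 3) {
  sc <- scan_junction(bundle)
  n <- nchar(bundle$junction_obs)
  centre <- bundle$flank_len + 1L
  if (sc$overlap > 0) {
    mh_seq <- substr(bundle$junction_obs, n - sc$b + 1L, sc$a)
    return(signature_call(bundle$junction_id, "microhomology",
                          mh_len = sc$overlap, mh_seq = mh_seq))
  }
  if (sc$overlap == 0)
    return(signature_call(bundle$junction_id, "blunt"))
  ins <- substr(bundle$junction_obs, sc$a + 1L, n - sc$b)
  th <- if (nchar(ins) >= min_template_len)
    search_template(ins, bundle, window = min(window, bundle$flank_len),
                    min_template_len = min_template_len) else NULL
  # a 1-nt insertion equal to the base just beyond either breakend could as
  # well be read as a 1-bp microhomology under a shifted break assignment
  amb <- nchar(ins) == 1L &&
    (ins == substr(bundle$proximal_ref, centre + 1L, centre + 1L) ||
     ins == substr(bundle$distal_ref, centre - 1L, centre - 1L))
  signature_call(bundle$junction_id, "insertion", ins_seq = ins,
                 template_hit = th, ambiguous = amb)
}

#' Infer a plausible formation mechanism from junction signatures
#'
#' Applies literature-conventional rules to the full set of junction calls of
#' one rearrangement. In precedence order: a rearrangement that is not
#' copy-number neutral, or that carries a templated insertion of at least
#' `template_suspect_len` bp, is `replicative_suspect` (MMBIR-like); a
#' copy-number-neutral event whose junctions all show at most `mh_max` bp of
#' microhomology and insertions of at most `ins_max` nt is `NHEJ_compatible`;
#' one with microhomology in `mmej_band` and no long insertions is
#' `MMEJ_compatible`; anything else is `indeterminate`.
#'
#' @param calls List of [signature_call()] objects (non-empty).
#' @param copy_number_neutral Logical flag for the whole rearrangement.
#' @param mh_max Maximum microhomology for NHEJ (default 1 bp).
#' @param ins_max Maximum insertion length for NHEJ/MMEJ (default 10 nt).
#' @param mmej_band Microhomology range `c(lo, hi)` for MMEJ (default 2-25).
#' @param template_suspect_len Templated-insertion length that triggers the
#'   replicative label (default 10 nt).
#' @return A list of class `mechanism_call`: `label`, `rationale`,
#'   `thresholds`.
#' @export
infer_mechanism <- function(calls, copy_number_neutral = TRUE,
                            mh_max = 1, ins_max = 10, mmej_band = c(2, 25),
                            template_suspect_len = 10) {
  if (!length(calls))
    stop("empty signature call list", call. = FALSE)
  if (inherits(calls, "signature_call")) calls <- list(calls)
  mh <- vapply(calls, function(x) x$mh_len, integer(1))
  ins_len <- vapply(calls, function(x) nchar(x$ins_seq), integer(1))
  templ_len <- vapply(calls, function(x)
    if (!is.null(x$template_hit)) nchar(x$ins_seq) else 0L, integer(1))
  thresholds <- list(mh_max = mh_max, ins_max = ins_max, mmej_band = mmej_band,
                     template_suspect_len = template_suspect_len)
  if (!copy_number_neutral || any(templ_len >= template_suspect_len)) {
    label <- "replicative_suspect"
    rationale <- if (!copy_number_neutral)
      "rearrangement is not copy-number neutral"
    else sprintf("templated insertion of %d nt >= %d",
                 max(templ_len), template_suspect_len)
  } else if (all(mh <= mh_max) && all(ins_len <= ins_max)) {
    label <- "NHEJ_compatible"
    rationale <- sprintf(
      "copy-number neutral; all microhomology <= %d bp and all insertions <= %d nt",
      mh_max, ins_max)
  } else if (any(mh >= mmej_band[1] & mh <= mmej_band[2]) &&
             all(ins_len <= ins_max)) {
    label <- "MMEJ_compatible"
    rationale <- sprintf(
      "copy-number neutral; microhomology of %d bp in the %d-%d bp band",
      max(mh), mmej_band[1], mmej_band[2])
  } else {
    label <- "indeterminate"
    rationale <- "no rule fired"
  }
  structure(list(label = label, rationale = rationale, thresholds = thresholds),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("<mechanism_call> %s (%s)\n", x$label, x$rationale))
  invisible(x)
}
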