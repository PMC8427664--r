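#' Configuration for the chromoanagenesis null model
#'
#' The null model mirrors the observed class of rearrangement: the chromosome
#' is broken into `n_segments` segments at uniformly drawn cut sites, the
#' first and last segments stay positionally static, and the middle segments
#' are uniformly reshuffled, each independently inverted with probability
#' `inversion_prob`. Replicates are drawn `reps` times to build empirical
#' null distributions for two statistics: breakpoint clustering
#' (chromothripsis-like signal) and protein-coding-gene fusion enrichment
#' (chromoplexy-like signal).
#'
#' @param model A [chromosome_model()].
#' @param n_segments Number of segments (default 7).
#' @param inversion_prob Per-segment inversion probability (default 0.5).
#' @param reps Number of Monte Carlo replicates (default 10000).
#' @param seed Integer seed.
#' @param fusion_mode `"junction_fusion"` (junctions whose two breakends fall
#'   in two distinct protein-coding genes) or `"breakpoint_in_gene"`
#'   (cut sites inside any protein-coding gene).
#' @param clustering_mode `"pairwise"` (mean over all unordered pairs of cut
#'   sites, the standard dispersion reading) or `"consecutive_gap"` (mean gap
#'   between consecutive cut sites, i.e. range/(n-1)). Both are always
#'   computed and reported by [run_simulation()]; this selects which one
#'   populates `p_clustering`.
#' @param pvalue_correction Use the (k+1)/(R+1) small-sample correction
#'   instead of the plain proportion k/R (default `FALSE`).
#' @param merge_tolerance Breakend merge tolerance (bp) used when deriving
#'   observed cut sites (default 100).
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(model, n_segments = 7, inversion_prob = 0.5,
                              reps = 10000, seed = 1,
                              fusion_mode = c("junction_fusion",
                                              "breakpoint_in_gene"),
                              clustering_mode = c("pairwise",
                                                  "consecutive_gap"),
                              pvalue_correction = FALSE,
                              merge_tolerance = 100) {
  stopifnot(inherits(model, "chromosome_model"))
  if (n_segments < 3) stop("n_segments must be >= 3", call. = FALSE)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  if (inversion_prob < 0 || inversion_prob > 1)
    stop("inversion_prob must be in [0, 1]", call. = FALSE)
  structure(
    list(model = model, n_segments = as.integer(n_segments),
         inversion_prob = inversion_prob, reps = as.integer(reps),
         seed = as.integer(seed), fusion_mode = match.arg(fusion_mode),
         clustering_mode = match.arg(clustering_mode),
         pvalue_correction = isTRUE(pvalue_correction),
         merge_tolerance = merge_tolerance),
    class = "simulation_config"
  )
}

#' Breakpoint clustering statistic
#'
#' `"pairwise"` (default) is the mean of `|x_i - x_j|` over all unordered
#' pairs of cut sites; `"consecutive_gap"` is the mean distance between
#' consecutive sorted cut sites, which equals `(max - min) / (n - 1)`. Both
#' are translation invariant; smaller values mean denser clustering.
#'
#' @param cut_sites Numeric vector of at least 2 cut positions (bp).
#' @param mode `"pairwise"` or `"consecutive_gap"`.
#' @return The statistic in bp.
#' @examples
#' clustering_stat(c(10, 20, 30))                    # 40/3
#' clustering_stat(c(10, 20, 30), "consecutive_gap") # 10
#' @export
clustering_stat <- function(cut_sites, mode = c("pairwise", "consecutive_gap")) {
  mode <- match.arg(mode)
  x <- sort(as.numeric(cut_sites))
  n <- length(x)
  if (n < 2) stop("clustering_stat needs at least 2 cut sites", call. = FALSE)
  if (mode == "pairwise")
    sum((2 * seq_len(n) - n - 1) * x) / choose(n, 2)
  else
    (x[n] - x[1]) / (n - 1)
}

#' Count protein-coding-gene fusions at breakpoint junctions
#'
#' In `"junction_fusion"` mode, counts junctions whose two breakend positions
#' both fall inside protein-coding gene bodies of two *distinct* genes. In
#' `"breakpoint_in_gene"` mode, counts distinct cut sites lying inside any
#' protein-coding gene body.
#'
#' @param junction_breakend_pairs Two-column matrix or data frame of breakend
#'   positions (`pos_a`, `pos_b`), one row per junction.
#' @param genes A [gene_annotation()]; non-protein-coding rows are ignored.
#' @param mode `"junction_fusion"` or `"breakpoint_in_gene"`.
#' @param cut_sites Cut positions used by `"breakpoint_in_gene"`; defaults to
#'   the distinct breakend positions in `junction_breakend_pairs`.
#' @return An integer count.
#' @export
fusion_count <- function(junction_breakend_pairs, genes,
                         mode = c("junction_fusion", "breakpoint_in_gene"),
                         cut_sites = NULL) {
  mode <- match.arg(mode)
  genes <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  pairs <- as.matrix(as.data.frame(junction_breakend_pairs))
  if (mode == "breakpoint_in_gene") {
    if (is.null(cut_sites)) cut_sites <- unique(as.vector(pairs))
    if (!length(cut_sites)) return(0L)
    return(sum(!is.na(gene_index_at(unique(cut_sites), genes))))
  }
  if (!nrow(pairs)) return(0L)
  ga <- gene_index_at(pairs[, 1], genes)
  gb <- gene_index_at(pairs[, 2], genes)
  sum(!is.na(ga) & !is.na(gb) & ga != gb)
}

#' Observed case for the null model
#'
#' Derives from a junction table the quantities the null model compares
#' against: the merged cut sites (breakends within `merge_tolerance` share a
#' cut), the per-junction breakend position pairs, both clustering statistics
#' and, when an annotation is supplied, both fusion counts.
#'
#' @param junctions A [junction_table()].
#' @param model A [chromosome_model()].
#' @param genes Optional [gene_annotation()].
#' @param merge_tolerance Breakend merge tolerance in bp (default 100).
#' @return An object of class `observed_case`.
#' @export
observed_case <- function(junctions, model, genes = NULL,
                          merge_tolerance = 100) {
  junctions <- validate_junction_table(as.data.frame(junctions))
  cuts_raw <- implied_cut(c(junctions$pos_a, junctions$pos_b),
                          c(junctions$side_a, junctions$side_b))
  sorted <- sort(cuts_raw)
  grp <- cumsum(c(1, diff(sorted) > merge_tolerance))
  cut_sites <- as.numeric(vapply(split(sorted, grp),
                                 function(x) floor((min(x) + max(x)) / 2),
                                 numeric(1)))
  pairs <- cbind(pos_a = junctions$pos_a, pos_b = junctions$pos_b)
  obs <- list(
    cut_sites = cut_sites,
    junction_breakend_pairs = pairs,
    clustering_pairwise = clustering_stat(cut_sites, "pairwise"),
    clustering_gap = clustering_stat(cut_sites, "consecutive_gap"),
    fusion_junction = if (!is.null(genes))
      fusion_count(pairs, genes, "junction_fusion") else NA_integer_,
    fusion_breakpoint = if (!is.null(genes))
      fusion_count(pairs, genes, "breakpoint_in_gene", cut_sites = cut_sites)
      else NA_integer_
  )
  structure(obs, class = "observed_case")
}

# breakend position pairs of the non-reference adjacencies of one shuffle
adjacency_pairs <- function(cuts, order_idx, inverted_mid, L) {
  n <- length(cuts) + 1L
  ori <- c(FALSE, inverted_mid, FALSE)  # TRUE = inverted, in path order
  seg_start <- function(s) if (s == 1L) 1 else cuts[s - 1L] + 1
  seg_end <- function(s) if (s == n) L else cuts[s]
  out <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(n - 1L)) {
    s <- order_idx[i]; t <- order_idx[i + 1L]
    os <- ori[i]; ot <- ori[i + 1L]
    if ((!os && !ot && t == s + 1L) || (os && ot && s == t + 1L)) next
    pos_a <- if (!os) seg_end(s) else seg_start(s)
    pos_b <- if (!ot) seg_start(t) else seg_end(t)
    out <- rbind(out, c(pos_a, pos_b))
  }
  out
}

#' Draw one replicate from the null model
#'
#' @param config A [simulation_config()]; its seed is used unless `seed` is
#'   given.
#' @param seed Optional integer seed overriding `config$seed`.
#' @return A list: `cut_sites` (sorted), `permutation` (derivative order of
#'   all segments), `orientations` (`"direct"`/`"inverted"`, path order) and
#'   `junction_breakend_pairs` (matrix, non-reference adjacencies only).
#' @export
draw_rearrangement <- function(config, seed = config$seed) {
  withr::with_seed(seed, {
    d <- draw_shuffle(config$model$length, config$n_segments,
                      config$inversion_prob)
    order_idx <- c(1L, d$perm, config$n_segments)
    pairs <- adjacency_pairs(d$cuts, order_idx, d$inverted,
                             config$model$length)
    list(cut_sites = d$cuts,
         permutation = order_idx,
         orientations = c("direct",
                          ifelse(d$inverted, "inverted", "direct"),
                          "direct"),
         junction_breakend_pairs = pairs)
  })
}

#' Run the Monte Carlo null model
#'
#' Draws `config$reps` random copy-number-neutral shuffles and compares the
#' observed case against the resulting null distributions. The clustering
#' p-value is the fraction of replicates with a *strictly smaller* clustering
#' statistic than observed (a replicate is "more clustered" only if its
#' average breakpoint distance is smaller); the fusion p-value is the
#' fraction of replicates with a fusion count greater than or equal to the
#' observed count (conventional upper tail). Both clustering variants are
#' computed and reported; `p_clustering` follows `config$clustering_mode`.
#' Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param observed An [observed_case()] with `config$n_segments - 1` cut
#'   sites.
#' @param genes Optional [gene_annotation()]; when `NULL`, fusion counting is
#'   skipped and `p_fusion` compares against an observed count of 0 (so it is
#'   1 by construction).
#' @return An object of class `simulation_result` with the statistic vectors,
#'   p-values, per-replicate cut sites and a config echo.
#' @export
run_simulation <- function(config, observed, genes = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(observed, "observed_case"))
  k <- config$n_segments - 1L
  if (length(observed$cut_sites) != k)
    stop("observed case has ", length(observed$cut_sites),
         " cut sites after merging but the configuration expects ", k,
         call. = FALSE)
  L <- config$model$length
  reps <- config$reps
  use_genes <- !is.null(genes) && nrow(genes) > 0
  if (use_genes)
    genes_pc <- genes[genes$biotype == "protein_coding", , drop = FALSE]

  obs_fusion <- if (use_genes) {
    if (config$fusion_mode == "junction_fusion") {
      if (is.na(observed$fusion_junction))
        fusion_count(observed$junction_breakend_pairs, genes, "junction_fusion")
      else observed$fusion_junction
    } else {
      if (is.na(observed$fusion_breakpoint))
        fusion_count(observed$junction_breakend_pairs, genes,
                     "breakpoint_in_gene", cut_sites = observed$cut_sites)
      else observed$fusion_breakpoint
    }
  } else 0L

  stat_pw <- numeric(reps)
  stat_gap <- numeric(reps)
  fus <- integer(reps)
  cuts_mat <- matrix(0, nrow = reps, ncol = k)
  idx <- seq_len(config$n_segments)
  withr::with_seed(config$seed, {
    for (r in seq_len(reps)) {
      d <- draw_shuffle(L, config$n_segments, config$inversion_prob)
      cuts <- d$cuts
      cuts_mat[r, ] <- cuts
      stat_pw[r] <- sum((2 * idx[-length(idx)] - k - 1) * cuts) / choose(k, 2)
      stat_gap[r] <- (cuts[k] - cuts[1]) / (k - 1)
      if (use_genes) {
        pairs <- adjacency_pairs(cuts, c(1L, d$perm, config$n_segments),
                                 d$inverted, L)
        fus[r] <- if (config$fusion_mode == "junction_fusion")
          fusion_count(pairs, genes_pc, "junction_fusion")
        else
          fusion_count(pairs, genes_pc, "breakpoint_in_gene",
                       cut_sites = cuts)
      }
    }
  })

  pval <- function(kk, RR) if (config$pvalue_correction) (kk + 1) / (RR + 1) else kk / RR
  p_pw <- pval(sum(stat_pw < observed$clustering_pairwise), reps)
  p_gap <- pval(sum(stat_gap < observed$clustering_gap), reps)
  p_fus <- pval(sum(fus >= obs_fusion), reps)

  structure(
    list(
      clustering_stats = if (config$clustering_mode == "pairwise") stat_pw else stat_gap,
      clustering_stats_pairwise = stat_pw,
      clustering_stats_gap = stat_gap,
      fusion_counts = fus,
      p_clustering = if (config$clustering_mode == "pairwise") p_pw else p_gap,
      p_clustering_pairwise = p_pw,
      p_clustering_gap = p_gap,
      p_fusion = p_fus,
      observed_fusion_count = obs_fusion,
      observed = observed,
      cut_sites = cuts_mat,
      config = config,
      seed = config$seed
    ),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> %d replicates on %s (%d segments)\n",
    x$config$reps, x$config$model$name, x$config$n_segments))
  cat(sprintf("  p_clustering (%s): %.4g  [pairwise %.4g, consecutive gap %.4g]\n",
              x$config$clustering_mode, x$p_clustering,
              x$p_clustering_pairwise, x$p_clustering_gap))
  cat(sprintf("  p_fusion (%s, observed count %d): %.4g\n",
              x$config$fusion_mode, x$observed_fusion_count, x$p_fusion))
  invisible(x)
}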