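# Independent brute-force oracles used to check the signature caller and the
# template search. Deliberately written with plain character loops and full
# enumeration, sharing no code with the package internals.

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# longest match of obs against subject starting at every subject offset
# (full enumeration over all offsets; no seeding or anchoring)
oracle_prefix_match <- function(obs, subject) {
  o <- chars(obs); s <- chars(subject)
  best <- 0L
  for (q in seq_along(s)) {
    n <- min(length(o), length(s) - q + 1L)
    if (n <= best) next
    mism <- which(o[seq_len(n)] != s[q + seq_len(n) - 1L])[1]
    k <- if (is.na(mism)) n else mism - 1L
    if (k > best) best <- k
  }
  best
}

oracle_scan <- function(bundle) {
  obs <- bundle$junction_obs
  rev1 <- function(x) paste(rev(chars(x)), collapse = "")
  a <- oracle_prefix_match(obs, bundle$proximal_ref)
  b <- oracle_prefix_match(rev1(obs), rev1(bundle$distal_ref))
  list(a = a, b = b, overlap = a + b - nchar(obs))
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(unname(map[chars(s)])), collapse = "")
}

oracle_template <- function(ins, bundle, window = 50, min_len = 3) {
  if (nchar(ins) < min_len) return(NULL)
  centre <- bundle$flank_len + 1L
  best <- NULL; best_key <- Inf
  sources <- list(proximal = bundle$proximal_ref, distal = bundle$distal_ref)
  for (src_i in 1:2) {
    subject <- sources[[src_i]]
    for (strand_i in 1:2) {
      pat <- if (strand_i == 1L) ins else oracle_revcomp(ins)
      pl <- nchar(pat)
      for (p in seq_len(nchar(subject) - pl + 1L)) {
        if (substr(subject, p, p + pl - 1L) != pat) next
        off <- p - centre
        if (abs(off) > window) next
        key <- abs(off) * 4 + (src_i - 1L) * 2 + (strand_i - 1L)
        if (key < best_key) {
          best_key <- key
          best <- list(source = names(sources)[src_i], offset = off,
                       strand = c("forward", "reverse_complement")[strand_i])
        }
      }
    }
  }
  best
}

oracle_call <- function(bundle, window = 50, min_len = 3) {
  sc <- oracle_scan(bundle)
  n <- nchar(bundle$junction_obs)
  if (sc$overlap > 0) {
    list(klass = "microhomology", mh_len = sc$overlap,
         mh_seq = substr(bundle$junction_obs, n - sc$b + 1L, sc$a),
         ins_seq = "", template = NULL)
  } else if (sc$overlap == 0) {
    list(klass = "blunt", mh_len = 0L, mh_seq = "", ins_seq = "",
         template = NULL)
  } else {
    ins <- substr(bundle$junction_obs, sc$a + 1L, n - sc$b)
    list(klass = "insertion", mh_len = 0L, mh_seq = "", ins_seq = ins,
         template = oracle_template(ins, bundle, window, min_len))
  }
}

# random planted signature spec for property tests
random_signature_spec <- function(id, seed) {
  withr::with_seed(seed, {
    klass <- sample(c("blunt", "microhomology", "insertion"), 1,
                    prob = c(0.3, 0.35, 0.35))
    if (klass == "blunt") return(signature_call(id, "blunt"))
    if (klass == "microhomology") {
      k <- sample(1:6, 1)
      return(signature_call(id, "microhomology", mh_len = k,
                            mh_seq = paste(sample(c("A", "C", "G", "T"), k,
                                                  replace = TRUE),
                                           collapse = "")))
    }
    len <- sample(1:10, 1)
    ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    th <- NULL
    if (len >= 3 && stats::runif(1) < 0.5) {
      strand <- sample(c("forward", "reverse_complement"), 1)
      if (ins == oracle_revcomp(ins)) strand <- "forward"
      th <- template_hit(sample(c("proximal", "distal"), 1),
                         sample(c(-40:-(len + 1), 2:30), 1),
                         strand)
    }
    signature_call(id, "insertion", ins_seq = ins, template_hit = th)
  })
}

tiny_model <- function(len = 1e6, centromere = NULL)
  chromosome_model("chrT", len, centromere = centromere)
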