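# hand-built bundle: explicit flanks with known retained arms
manual_bundle <- function(prox_retained, prox_cont, dist_upstream,
                          dist_retained, obs) {
  F <- max(nchar(prox_retained) - 1L + nchar(prox_cont),
           nchar(dist_upstream) + nchar(dist_retained) - 1L)
  # pad with a fixed neutral base outside the informative region
  padc <- function(n) paste(rep("C", n), collapse = "")
  X <- paste0(padc(F + 1L - nchar(prox_retained)), prox_retained, prox_cont,
              padc(F - nchar(prox_cont)))
  Y <- paste0(padc(F - nchar(dist_upstream)), dist_upstream, dist_retained,
              padc(F + 1L - nchar(dist_retained)))
  junction_bundle(X, Y, obs, flank_len = F, junction_id = "manual")
}

test_that("a blunt junction reports zero microhomology and no insertion", {
  # proximal ...AAAC| continues T...; distal |GTTT...
  b <- manual_bundle("AAAC", "TAGG", "GGCA", "GTTT", "AAACGTTT")
  expect_equal(call_microhomology(b), list(mh_len = 0L, mh_seq = ""))
  expect_equal(call_insertion(b), "")
  expect_equal(classify_junction(b)$klass, "blunt")
})

test_that("the total ambiguous overlap is reported as microhomology", {
  # proximal ...AAAATG| continues CACA; distal |TGGGGG: overlap TG
  b <- manual_bundle("AAAATG", "CACA", "ATTC", "TGGGGG", "AAAATGGGGG")
  expect_equal(call_microhomology(b), list(mh_len = 2L, mh_seq = "TG"))
  expect_equal(call_insertion(b), "")
  call <- classify_junction(b)
  expect_equal(call$klass, "microhomology")
  expect_equal(call$mh_len, 2L)
})

test_that("inserted bases between the flanks are called as an insertion", {
  b <- manual_bundle("AAAC", "TAGG", "GGCC", "GTTT", "AAACGAGTTT")
  expect_equal(call_insertion(b), "GA")
  expect_equal(call_microhomology(b)$mh_len, 0L)
  expect_equal(classify_junction(b)$klass, "insertion")
})

test_that("junction sequences inconsistent with the flanks raise alignment errors", {
  b <- manual_bundle("AAAC", "TAGG", "GGCA", "GTTT", "AAACGTTT")
  bad <- junction_bundle(b$proximal_ref, b$distal_ref,
                         gsub("[ACG]", "T", b$junction_obs),
                         flank_len = b$flank_len)
  expect_error(classify_junction(bad), "alignment error")
})

test_that("template search honours the minimum length and tie-breaking rules", {
  tmpl <- generate_junction_bundle(
    signature_call("t", "insertion", ins_seq = "TTTGAAG",
                   template_hit = template_hit("proximal", -9, "forward")),
    seed = 21)
  expect_null(search_template("G", tmpl))  # below min_template_len
  hit <- search_template("TTTGAAG", tmpl)
  expect_equal(hit$source, "proximal")
  expect_equal(hit$offset, -9L)
  expect_equal(hit$strand, "forward")
  expect_error(search_template("TTTGAAG", tmpl, window = 1000), "window")

  # non-templated insertion: absent from both flanks by construction
  plain <- generate_junction_bundle(
    signature_call("p", "insertion", ins_seq = "ACGTACG"), seed = 22)
  expect_null(search_template("ACGTACG", plain))
  expect_null(oracle_template("ACGTACG", plain))
})

test_that("caller equals the brute-force oracle on random planted fixtures", {
  for (i in 1:300) {
    spec <- random_signature_spec(paste0("f", i), seed = 5000 + i)
    b <- generate_junction_bundle(spec, seed = 9000 + i)
    got <- classify_junction(b)
    exp <- oracle_call(b)
    expect_equal(got$klass, exp$klass, info = paste("fixture", i))
    expect_equal(got$mh_len, exp$mh_len, info = paste("fixture", i))
    expect_equal(got$mh_seq, exp$mh_seq, info = paste("fixture", i))
    expect_equal(got$ins_seq, exp$ins_seq, info = paste("fixture", i))
    if (is.null(exp$template)) expect_null(got$template_hit)
    else {
      expect_equal(got$template_hit$source, exp$template$source)
      expect_equal(got$template_hit$offset, exp$template$offset)
      expect_equal(got$template_hit$strand, exp$template$strand)
    }
    # exclusivity: never both microhomology and insertion
    expect_false(got$mh_len > 0 && nzchar(got$ins_seq))
  }
})

test_that("calls are invariant under strand flip of the whole bundle", {
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  for (i in 1:40) {
    spec <- random_signature_spec(paste0("s", i), seed = 300 + i)
    b <- generate_junction_bundle(spec, seed = 700 + i)
    flipped <- junction_bundle(rc(b$distal_ref), rc(b$proximal_ref),
                               rc(b$junction_obs), flank_len = b$flank_len,
                               junction_id = b$junction_id)
    a <- classify_junction(b); z <- classify_junction(flipped)
    expect_equal(z$mh_len, a$mh_len, info = paste("fixture", i))
    expect_equal(nchar(z$ins_seq), nchar(a$ins_seq), info = paste("fixture", i))
  }
})

test_that("mechanism inference applies the rules in precedence order", {
  six <- lapply(seq_along(index_case_signature_specs()), function(i)
    classify_junction(generate_junction_bundle(
      index_case_signature_specs()[[i]], seed = 40 + i)))
  mech <- infer_mechanism(six, copy_number_neutral = TRUE)
  expect_equal(mech$label, "NHEJ_compatible")

  mmej <- infer_mechanism(list(
    signature_call("x", "microhomology", mh_len = 8,
                   mh_seq = "ACGTACGT")), copy_number_neutral = TRUE)
  expect_equal(mmej$label, "MMEJ_compatible")

  repl <- infer_mechanism(six, copy_number_neutral = FALSE)
  expect_equal(repl$label, "replicative_suspect")

  long_tmpl <- infer_mechanism(list(
    signature_call("y", "insertion", ins_seq = "ACGTACGTACGT",
                   template_hit = template_hit("distal", 5, "forward"))),
    copy_number_neutral = TRUE)
  expect_equal(long_tmpl$label, "replicative_suspect")

  expect_error(infer_mechanism(list()), "empty")

  # order invariance
  expect_equal(infer_mechanism(rev(six))$label, mech$label)
})
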