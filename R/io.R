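#' Read a junction TSV
#'
#' The junction dialect is a tab-separated table with a required header:
#' `junction_id`, `chrom_a`, `pos_a`, `side_a`, `chrom_b`, `pos_b`, `side_b`,
#' `inserted_seq`. Positions are 1-based, sides are `left_of_cut` /
#' `right_of_cut`, inserted sequences are uppercased and blanks read as
#' empty. Lines starting with `#` (provenance comments) are skipped.
#'
#' @param path File path.
#' @return A [junction_table()].
#' @export
read_junction_table <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character", comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("junction_id", "chrom_a", "pos_a", "side_a",
           "chrom_b", "pos_b", "side_b", "inserted_seq")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("parse error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in c("pos_a", "pos_b")) {
    val <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(val) & nzchar(tab[[col]]))
    if (length(bad))
      stop("parse error in ", path, ": non-numeric ", col, " at line ",
           bad[1] + 1L, " ('", tab[[col]][bad[1]], "')", call. = FALSE)
    tab[[col]] <- val
  }
  dup <- which(duplicated(tab$junction_id))
  if (length(dup))
    stop("parse error in ", path, ": duplicate junction_id '",
         tab$junction_id[dup[1]], "' at line ", dup[1] + 1L, call. = FALSE)
  tab$inserted_seq[is.na(tab$inserted_seq)] <- ""
  tab$inserted_seq <- toupper(tab$inserted_seq)
  validate_junction_table(tab[req])
}

#' Write a junction TSV
#'
#' @param junctions A [junction_table()].
#' @param path Output path.
#' @param provenance Optional provenance list written as `#`-prefixed header
#'   comments (see [provenance_block()]).
#' @return `path`, invisibly.
#' @export
write_junction_table <- function(junctions, path, provenance = NULL) {
  junctions <- validate_junction_table(as.data.frame(junctions))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", provenance_lines(provenance)), con)
  utils::write.table(junctions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation BED
#'
#' Accepts BED3+ (0-based half-open on disk, converted to 1-based closed
#' intervals in memory). A fifth column, when present, is read as the gene
#' biotype and records are filtered to `protein_coding`; without it all
#' records are kept (with a message). An empty file yields an empty
#' annotation with a warning.
#'
#' @param path File path.
#' @param model Optional [chromosome_model()] for bounds checking.
#' @return A [gene_annotation()].
#' @export
read_genes_bed <- function(path, model = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines)) {
    warning("empty BED file: ", path, call. = FALSE)
    return(gene_annotation(model = model))
  }
  nfields <- length(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
  extra <- if (nfields >= 5L) c(biotype = "character") else NULL
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed", extraCols = extra),
    error = function(e)
      stop("parse error in ", path, ": ", conditionMessage(e), call. = FALSE)
  )
  start <- GenomicRanges::start(gr)  # rtracklayer converts to 1-based closed
  end <- GenomicRanges::end(gr)
  ids <- if (!is.null(gr$name) && !anyNA(gr$name)) as.character(gr$name)
         else sprintf("G%04d", seq_along(gr))
  if (nfields >= 5L) {
    biotype <- as.character(gr$biotype)
    keep <- biotype == "protein_coding"
    message(sum(keep), "/", length(keep),
            " BED records retained as protein_coding")
    start <- start[keep]; end <- end[keep]; ids <- ids[keep]
    biotype <- biotype[keep]
  } else {
    message("no biotype column in ", basename(path),
            ": keeping all ", length(gr), " records as protein_coding")
    biotype <- "protein_coding"
  }
  gene_annotation(gene_id = ids, start = start, end = end, biotype = biotype,
                  model = model)
}

#' Write a gene annotation as BED
#'
#' Written as BED4+1 (`chrom`, 0-based `start`, `end`, `name`, `biotype`).
#'
#' @param genes A [gene_annotation()].
#' @param path Output path.
#' @param chrom Chromosome name for the first column.
#' @return `path`, invisibly.
#' @export
write_genes_bed <- function(genes, path, chrom = "chr1") {
  df <- data.frame(chrom = chrom, start = genes$start - 1L, end = genes$end,
                   name = genes$gene_id, biotype = genes$biotype)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write junction bundles as FASTA
#'
#' Three records per junction, named `<id>__proximal`, `<id>__distal`,
#' `<id>__observed`.
#'
#' @param bundles A [junction_bundle()] or list thereof.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bundle_fasta <- function(bundles, path) {
  if (inherits(bundles, "junction_bundle")) bundles <- list(bundles)
  seqs <- character(0)
  for (b in bundles) {
    id <- if (is.na(b$junction_id)) paste0("junction", length(seqs) %/% 3 + 1)
          else b$junction_id
    add <- c(b$proximal_ref, b$distal_ref, b$junction_obs)
    names(add) <- paste0(id, c("__proximal", "__distal", "__observed"))
    seqs <- c(seqs, add)
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read junction bundles from FASTA
#'
#' Expects triples of records named `<id>__proximal`, `<id>__distal`,
#' `<id>__observed`. The flank radius is inferred from the proximal record
#' length (`2 * flank_len + 1`).
#'
#' @param path FASTA path.
#' @return A named list of [junction_bundle()] objects.
#' @export
read_bundle_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- names(seqs)
  ids <- unique(sub("__(proximal|distal|observed)$", "", nm))
  out <- list()
  for (id in ids) {
    need <- paste0(id, c("__proximal", "__distal", "__observed"))
    if (!all(need %in% nm))
      stop("parse error in ", path, ": incomplete bundle for '", id,
           "' (need __proximal/__distal/__observed)", call. = FALSE)
    prox <- as.character(seqs[[need[1]]])
    flank <- (nchar(prox) - 1L) %/% 2L
    out[[id]] <- junction_bundle(prox, as.character(seqs[[need[2]]]),
                                 as.character(seqs[[need[3]]]),
                                 flank_len = flank, junction_id = id)
  }
  out
}

#' Read breakend (BND) records from a VCF into a junction table
#'
#' Parses standard bracket-notation breakend ALT alleles, resolves `MATEID`
#' pairs into one junction per pair, and converts symbolic `<INV>` records
#' into the two breakend pairs of a simple inversion. Non-BND, non-`<INV>`
#' records are ignored with a warning.
#'
#' @param path VCF path.
#' @return A [junction_table()].
#' @export
read_breakends_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- as.character(unlist(rr$ALT))
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ids <- names(rr)
  info <- VariantAnnotation::info(vcf)
  mate <- if ("MATEID" %in% names(info)) as.character(unlist(info$MATEID))
          else rep(NA_character_, length(alt))

  is_bnd <- grepl("\\[|\\]", alt)
  is_inv <- alt == "<INV>"
  skipped <- sum(!is_bnd & !is_inv)
  if (skipped > 0)
    warning(skipped, " non-breakend record(s) ignored in ", basename(path),
            call. = FALSE)

  rows <- list()
  seen <- character(0)
  for (i in which(is_bnd)) {
    if (ids[i] %in% seen) next
    m <- regmatches(alt[i], regexec("(\\[|\\])([^:]+):([0-9]+)(\\[|\\])", alt[i]))[[1]]
    if (length(m) != 5L) {
      warning("unparseable BND ALT '", alt[i], "' for record ", ids[i],
              call. = FALSE)
      next
    }
    bracket <- m[2]
    mate_chrom <- m[3]
    mate_pos <- as.numeric(m[4])
    t_first <- !startsWith(alt[i], "[") && !startsWith(alt[i], "]")
    side_a <- if (t_first) "left_of_cut" else "right_of_cut"
    side_b <- if (bracket == "[") "right_of_cut" else "left_of_cut"
    ins <- gsub("\\[[^]]*\\[|\\][^]]*\\]", "", alt[i])
    # the REF anchor base sits junction-side: first char when t leads,
    # last char when the bracket leads
    ins <- if (t_first) sub("^[ACGTNacgtn]", "", ins)
           else sub("[ACGTNacgtn]$", "", ins)
    if (!is.na(mate[i])) seen <- c(seen, mate[i])
    rows[[length(rows) + 1L]] <- data.frame(
      junction_id = ids[i], chrom_a = chrom[i], pos_a = pos[i],
      side_a = side_a, chrom_b = mate_chrom, pos_b = mate_pos,
      side_b = side_b, inserted_seq = toupper(ins),
      stringsAsFactors = FALSE)
  }
  for (i in which(is_inv)) {
    endpos <- info$END[i]
    if (is.null(endpos) || is.na(endpos)) {
      warning("<INV> record ", ids[i], " lacks INFO/END; skipped", call. = FALSE)
      next
    }
    endpos <- as.numeric(endpos)
    # a simple inversion of [pos+1, END] creates two junctions
    rows[[length(rows) + 1L]] <- data.frame(
      junction_id = paste0(ids[i], "_5p"), chrom_a = chrom[i], pos_a = pos[i],
      side_a = "left_of_cut", chrom_b = chrom[i], pos_b = endpos,
      side_b = "left_of_cut", inserted_seq = "", stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      junction_id = paste0(ids[i], "_3p"), chrom_a = chrom[i],
      pos_a = pos[i] + 1, side_a = "right_of_cut", chrom_b = chrom[i],
      pos_b = endpos + 1, side_b = "right_of_cut", inserted_seq = "",
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(junction_table(character(), character(), numeric(), character(),
                          character(), numeric(), character()))
  validate_junction_table(do.call(rbind, rows))
}

#' Provenance block for analysis outputs
#'
#' @param parameters Named list echoing the full parameter set of the run.
#' @return A list with the tool name/version, a timestamp and the parameters.
#' @export
provenance_block <- function(parameters = list()) {
  list(tool = "cgrtools",
       version = as.character(utils::packageVersion("cgrtools")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       parameters = parameters)
}

provenance_lines <- function(prov) {
  par <- paste(names(prov$parameters),
               vapply(prov$parameters, function(x) paste(x, collapse = ","),
                      character(1)),
               sep = "=", collapse = " ")
  c(paste0("provenance: ", prov$tool, " ", prov$version, " ", prov$timestamp),
    paste0("parameters: ", par))
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key=value`; blank lines and `#` comments are ignored.
#' Unknown keys are rejected when `allowed` is supplied.
#'
#' @param path File path.
#' @param allowed Optional character vector of permitted keys.
#' @return A named list of character values.
#' @export
read_run_config <- function(path, allowed = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- which(vapply(kv, length, integer(1)) != 3L)
  if (length(bad))
    stop("parse error in ", path, ": line '", lines[bad[1]],
         "' is not key=value", call. = FALSE)
  keys <- trimws(vapply(kv, `[`, character(1), 2L))
  vals <- trimws(vapply(kv, `[`, character(1), 3L))
  if (!is.null(allowed)) {
    unknown <- setdiff(keys, allowed)
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  stats::setNames(as.list(vals), keys)
}

#' Read a transcript exon table
#'
#' Tab-separated with header columns `exon`, `start`, `end` (1-based closed,
#' plus-strand order). Used for intron/exon lookups such as locating a
#' breakpoint within a disrupted gene.
#'
#' @param path File path.
#' @return A data frame with columns `exon`, `start`, `end`.
#' @export
read_exon_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("exon", "start", "end") %in% names(tab)))
    stop("exon table must have columns exon, start, end", call. = FALSE)
  if (any(tab$start > tab$end) || is.unsorted(tab$start, strictly = TRUE))
    stop("exon table must be sorted with start <= end", call. = FALSE)
  tab
}

#' Locate a position within a transcript model
#'
#' Maps a genomic position onto a plus-strand exon table: inside exon `i`,
#' inside intron `i` (between exons `i` and `i + 1`), or upstream/downstream
#' of the transcript.
#'
#' @param pos Genomic position (bp, 1-based).
#' @param exons A data frame from [read_exon_table()].
#' @return A list with `region` (`"exon"`, `"intron"`, `"upstream"`,
#'   `"downstream"`) and `index` (exon or intron number, `NA` outside the
#'   transcript).
#' @export
locate_intron <- function(pos, exons) {
  if (pos < exons$start[1]) return(list(region = "upstream", index = NA_integer_))
  n <- nrow(exons)
  if (pos > exons$end[n]) return(list(region = "downstream", index = NA_integer_))
  i <- findInterval(pos, exons$start)
  if (pos <= exons$end[i]) list(region = "exon", index = as.integer(exons$exon[i]))
  else list(region = "intron", index = as.integer(exons$exon[i]))
}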