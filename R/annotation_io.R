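# Reading/writing genome annotations and pair tables, and normalization into
# the internal coordinate format: every gene is (start, stop, strand) with
# start < stop always. On the forward strand, `start` is the first base of
# the start codon and `stop` the last base of the stop codon; on the reverse
# strand, `start` is the last base of the stop codon and `stop` the first
# base of the start codon.

GENE_TABLE_COLS <- c(
  "replicon_id", "start", "stop", "strand", "locus_tag", "gene_name",
  "cog_id", "is_protein_coding", "truncated_start", "truncated_stop",
  "transposase_internal"
)

#' Construct a validated gene table
#'
#' Normalizes a data frame of gene records into the internal coordinate
#' format and checks its invariants: `start < stop` for every record, strand
#' is `"+"` or `"-"`, and locus tags are non-missing. Missing optional
#' columns (`gene_name`, `cog_id`, flags) are filled with their defaults.
#'
#' @param df data frame with at least `replicon_id`, `start`, `stop`,
#'   `strand`, `locus_tag`.
#' @return a tibble with the full set of gene-table columns.
#' @export
gene_table <- function(df) {
  df <- tibble::as_tibble(df)
  required <- c("replicon_id", "start", "stop", "strand", "locus_tag")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("gene table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"gene_name" %in% names(df)) df$gene_name <- NA_character_
  if (!"cog_id" %in% names(df)) df$cog_id <- NA_character_
  if (!"is_protein_coding" %in% names(df)) df$is_protein_coding <- TRUE
  for (fl in c("truncated_start", "truncated_stop", "transposase_internal")) {
    if (!fl %in% names(df)) df[[fl]] <- FALSE
    df[[fl]][is.na(df[[fl]])] <- FALSE
  }
  df$start <- as.integer(df$start)
  df$stop <- as.integer(df$stop)
  bad_strand <- !df$strand %in% c("+", "-")
  if (any(bad_strand)) {
    stop("invalid strand (must be '+' or '-') for locus: ",
         paste(utils::head(df$locus_tag[bad_strand], 5), collapse = ", "),
         call. = FALSE)
  }
  bad_coord <- !(df$start < df$stop) | is.na(df$start) | is.na(df$stop)
  if (any(bad_coord)) {
    stop("record-level validation error: start >= stop (or missing) for locus: ",
         paste(utils::head(df$locus_tag[bad_coord], 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(df$locus_tag) | df$locus_tag == "")) {
    stop("record-level validation error: missing locus_tag", call. = FALSE)
  }
  df[, GENE_TABLE_COLS]
}

parse_flag_tokens <- function(flags) {
  # free-form attributes column: semicolon-separated key=value tokens;
  # absent keys default to false (curation flags are caller-supplied)
  out <- tibble::tibble(
    truncated_start = rep(FALSE, length(flags)),
    truncated_stop = FALSE,
    transposase_internal = FALSE,
    is_protein_coding = TRUE
  )
  has <- !is.na(flags) & flags != "." & flags != ""
  for (i in which(has)) {
    toks <- strsplit(flags[i], ";", fixed = TRUE)[[1]]
    for (tok in toks) {
      kv <- strsplit(trimws(tok), "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) next
      key <- kv[1]
      val <- tolower(kv[2]) %in% c("true", "1", "yes")
      if (key %in% names(out)) out[[key]][i] <- val
    }
  }
  out
}

format_flag_tokens <- function(df) {
  toks <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    t <- character(0)
    if (df$truncated_start[i]) t <- c(t, "truncated_start=true")
    if (df$truncated_stop[i]) t <- c(t, "truncated_stop=true")
    if (df$transposase_internal[i]) t <- c(t, "transposase_internal=true")
    if (!df$is_protein_coding[i]) t <- c(t, "is_protein_coding=false")
    toks[i] <- if (length(t)) paste(t, collapse = ";") else "."
  }
  toks
}

#' Read a genome annotation into a gene table
#'
#' Supports GFF3 (via [rtracklayer::import()]; CDS features are marked
#' protein-coding, all other feature types are retained with
#' `is_protein_coding = FALSE`) and the package's TSV gene-table dialect
#' (tab-separated, header row, `.` for missing optional fields, strand
#' `+`/`-`, free-form `flags` column of `key=value` tokens).
#'
#' GFF3 coordinates are 1-based inclusive and are preserved unchanged.
#' Multi-exon (joined) CDS are unsupported and raise an error; prokaryotic
#' annotations are single-span.
#'
#' @param path file path.
#' @param format `"gff3"` or `"tsv"`.
#' @return a gene table (see [gene_table()]).
#' @export
read_gene_table <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "gff3") read_gene_table_gff3(path) else read_gene_table_tsv(path)
}

read_gene_table_gff3 <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("GFF3 parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  strand <- as.character(GenomicRanges::strand(gr))
  keep <- strand %in% c("+", "-")
  if (any(!keep)) {
    warning(sum(!keep), " feature(s) without strand dropped", call. = FALSE)
  }
  gr <- gr[keep]
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  strand <- strand[keep]

  get_attr <- function(nm) {
    if (nm %in% names(mc)) as.character(mc[[nm]]) else rep(NA_character_, length(gr))
  }
  id <- get_attr("ID")
  is_cds <- type == "CDS"
  dup_id <- id[is_cds][!is.na(id[is_cds])]
  if (anyDuplicated(dup_id) > 0) {
    stop("unsupported feature: multi-span (joined) CDS with ID ",
         paste(unique(dup_id[duplicated(dup_id)]), collapse = ", "),
         call. = FALSE)
  }
  locus <- get_attr("locus_tag")
  locus[is.na(locus)] <- id[is.na(locus)]
  gene_name <- get_attr("gene")
  alt_name <- get_attr("Name")
  gene_name[is.na(gene_name)] <- alt_name[is.na(gene_name)]
  flag_attr <- function(nm) {
    v <- get_attr(nm)
    !is.na(v) & tolower(v) %in% c("true", "1", "yes")
  }
  gene_table(tibble::tibble(
    replicon_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    stop = GenomicRanges::end(gr),
    strand = strand,
    locus_tag = locus,
    gene_name = gene_name,
    cog_id = get_attr("cog_id"),
    is_protein_coding = is_cds,
    truncated_start = flag_attr("truncated_start"),
    truncated_stop = flag_attr("truncated_stop"),
    transposase_internal = flag_attr("transposase_internal")
  ))
}

read_gene_table_tsv <- function(path) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      replicon = readr::col_character(),
      start = readr::col_integer(),
      stop = readr::col_integer(),
      strand = readr::col_character(),
      locus_tag = readr::col_character(),
      .default = readr::col_character()
    ),
    na = ".",
    progress = FALSE,
    show_col_types = FALSE
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop("malformed gene table ", path, ": parse error at line(s) ",
         paste(utils::head(unique(probs$row), 5), collapse = ", "),
         call. = FALSE)
  }
  required <- c("replicon", "start", "stop", "strand", "locus_tag")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("TSV gene table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  flags <- if ("flags" %in% names(df)) df$flags else rep(NA_character_, nrow(df))
  fl <- parse_flag_tokens(flags)
  gene_table(tibble::tibble(
    replicon_id = df$replicon,
    start = df$start,
    stop = df$stop,
    strand = df$strand,
    locus_tag = df$locus_tag,
    gene_name = if ("gene_name" %in% names(df)) df$gene_name else NA_character_,
    cog_id = if ("cog_id" %in% names(df)) df$cog_id else NA_character_,
    is_protein_coding = fl$is_protein_coding,
    truncated_start = fl$truncated_start,
    truncated_stop = fl$truncated_stop,
    transposase_internal = fl$transposase_internal
  ))
}

#' Write a gene table as TSV
#'
#' Inverse of [read_gene_table()] with `format = "tsv"`; the
#' read-write-read round trip is the identity on all gene-table fields.
#'
#' @param genes gene table.
#' @param path output path.
#' @export
write_gene_table <- function(genes, path) {
  genes <- gene_table(genes)
  out <- tibble::tibble(
    replicon = genes$replicon_id,
    start = genes$start,
    stop = genes$stop,
    strand = genes$strand,
    locus_tag = genes$locus_tag,
    gene_name = ifelse(is.na(genes$gene_name), ".", genes$gene_name),
    cog_id = ifelse(is.na(genes$cog_id), ".", genes$cog_id),
    flags = format_flag_tokens(genes)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a gene-pair table as TSV
#'
#' One row per pair: replicon, upstream and downstream locus (transcription
#' order; `.` for non-serial pairs), orientation, distance and phase (`.`
#' for non-serial pairs). Rows are written in replicon-then-coordinate
#' order.
#'
#' @param pairs pair table as produced by [classify_orientation()], with
#'   `distance`/`phase` columns for serial pairs (see [intergenic_distance()]).
#' @param path output path.
#' @export
write_pairs_table <- function(pairs, path) {
  pairs <- tibble::as_tibble(pairs)
  if (!"distance" %in% names(pairs)) pairs$distance <- NA_integer_
  if (!"phase" %in% names(pairs)) pairs$phase <- NA_integer_
  pairs <- dplyr::arrange(pairs, .data$replicon_id, .data$first_start)
  fmt <- function(x) ifelse(is.na(x), ".", as.character(x))
  out <- tibble::tibble(
    replicon = pairs$replicon_id,
    upstream_locus = fmt(pairs$upstream_locus),
    downstream_locus = fmt(pairs$downstream_locus),
    orientation = pairs$orientation,
    distance = fmt(pairs$distance),
    phase = fmt(pairs$phase)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a gene-pair table written by [write_pairs_table()]
#'
#' @param path file path.
#' @return tibble with columns `replicon_id`, `upstream_locus`,
#'   `downstream_locus`, `orientation`, `distance`, `phase` (`NA` where the
#'   file holds `.`).
#' @export
read_pairs_table <- function(path) {
  df <- readr::read_tsv(path, col_types = "cccccc", na = ".",
                        progress = FALSE, show_col_types = FALSE)
  tibble::tibble(
    replicon_id = df$replicon,
    upstream_locus = df$upstream_locus,
    downstream_locus = df$downstream_locus,
    orientation = df$orientation,
    distance = as.integer(df$distance),
    phase = as.integer(df$phase)
  )
}

#' Read replicon sequences from a FASTA file
#'
#' Sequence ids must match `replicon_id` values of the annotation they
#' accompany; used for boundary-motif validation of overlapping gene pairs.
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_replicon_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write replicon sequences to a FASTA file
#'
#' @param sequences named character vector (names are replicon ids).
#' @param path output path.
#' @export
write_replicon_fasta <- function(sequences, path) {
  ss <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
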