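# File formats consumed and produced by the pipeline.
# All coordinates are 1-based inclusive (BLAST convention): a hit spanning
# positions a..b covers b - a + 1 bases.

SEQ_ALPHABET <- c("A", "C", "G", "T", "N")

ALIGNMENT_COLS <- c(
  "query_id", "subject_id", "percent_identity", "align_length",
  "mismatches", "gap_open", "q_start", "q_end", "s_start", "s_end",
  "e_value", "bit_score", "subject_taxon", "subject_annotation"
)

DOMAIN_COLS <- c(
  "query_id", "model_id", "bit_score", "e_value", "q_start", "q_end", "source"
)

TAXONOMY_RANKS <- c(
  "root", "kingdom", "phylum", "class", "order", "family", "genus", "species"
)

#' Read a DNA FASTA file with strict validation
#'
#' Reads a nucleotide FASTA file into a [Biostrings::DNAStringSet]. Record
#' ids (the first whitespace-delimited token of each header) must be unique,
#' sequences must be non-empty and restricted to the alphabet A/C/G/T/N
#' (case-insensitive; sequences are normalised to upper case).
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet` named by record id, with a `description`
#'   attribute-like metadata column accessible via `names()` convention:
#'   names hold the id only; full headers are kept in `mcols(x)$description`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  bad <- .locate_fasta_problem(path)
  if (!is.null(bad)) stop(bad, call. = FALSE)
  x <- tryCatch(
    suppressWarnings(Biostrings::readDNAStringSet(path)),
    error = function(e) {
      stop("failed to parse FASTA file ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  if (any(ids == "")) {
    stop("FASTA record with empty id in ", path, call. = FALSE)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate FASTA id '", dup[1], "' in ", path, call. = FALSE)
  }
  if (any(Biostrings::width(x) == 0)) {
    empty_id <- ids[Biostrings::width(x) == 0][1]
    stop("empty sequence for FASTA record '", empty_id, "' in ", path,
         call. = FALSE)
  }
  out <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(out) <- ids
  S4Vectors::mcols(out)$description <- desc
  out
}

# Scan a FASTA file line by line to report the first offending line number.
.locate_fasta_problem <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ok <- paste0("^[", paste(SEQ_ALPHABET, collapse = ""), "]*$")
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">") || ln == "") next
    if (!grepl(ok, toupper(ln))) {
      return(paste0("invalid sequence character at line ", i, " of ", path))
    }
  }
  NULL
}

#' Write sequences to FASTA
#'
#' @param x A named `DNAStringSet` or a named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) {
    x <- Biostrings::DNAStringSet(x)
  }
  if (is.null(names(x)) || any(names(x) == "")) {
    stop("all sequences must be named before writing FASTA", call. = FALSE)
  }
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

# Shared TSV writer: optional '# config=<hash>' style header comments, then a
# header row and tab-separated body. Deterministic byte-for-byte output.
write_tsv <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments) > 0) {
    writeLines(paste0("# ", comments), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, col_names = NULL, colClasses = NA) {
  df <- utils::read.delim(path, header = is.null(col_names),
                          comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE, colClasses = colClasses,
                          na.strings = character())
  if (!is.null(col_names)) {
    if (ncol(df) != length(col_names)) {
      stop("expected ", length(col_names), " columns in ", path,
           ", found ", ncol(df), call. = FALSE)
    }
    names(df) <- col_names
  }
  df
}

#' Read a similarity or domain hit table
#'
#' Alignment tables follow the 12-column BLAST tabular layout
#' (qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart,
#' send, evalue, bitscore) with two optional trailing columns carrying the
#' subject taxon id and subject annotation. Domain tables carry 7 columns:
#' query, model, score, evalue, qstart, qend, source. Lines starting with
#' `#` are ignored.
#'
#' @param path Path to a tab-separated hit table.
#' @param kind Either `"alignment"` or `"domain"`.
#' @return A data frame of typed hits (`alignment_hits` or `domain_hits`).
#' @export
read_hit_table <- function(path, kind = c("alignment", "domain")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("hit table not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!startsWith(raw, "#") & nzchar(raw)]
  if (length(raw) == 0) {
    return(empty_hits(kind))
  }
  fields <- strsplit(raw, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (kind == "alignment") {
    # strsplit drops trailing empty fields, so an empty taxon/annotation
    # column can legitimately surface as 12 or 13 fields
    ok <- n_fields %in% 12:14
    if (!all(ok)) {
      stop("alignment hit table row ", which(!ok)[1],
           " has ", n_fields[!ok][1], " columns (expected 12 or 14)",
           call. = FALSE)
    }
    get <- function(i) vapply(fields, function(f) f[i], character(1))
    df <- data.frame(
      query_id = get(1), subject_id = get(2),
      percent_identity = .parse_num(get(3), path, "percent_identity"),
      align_length = .parse_num(get(4), path, "align_length"),
      mismatches = .parse_num(get(5), path, "mismatches"),
      gap_open = .parse_num(get(6), path, "gap_open"),
      q_start = .parse_num(get(7), path, "q_start"),
      q_end = .parse_num(get(8), path, "q_end"),
      s_start = .parse_num(get(9), path, "s_start"),
      s_end = .parse_num(get(10), path, "s_end"),
      e_value = .parse_num(get(11), path, "e_value"),
      bit_score = .parse_num(get(12), path, "bit_score"),
      subject_taxon = ifelse(n_fields >= 13,
                             vapply(fields, function(f)
                               if (length(f) >= 13) f[13] else "", character(1)),
                             ""),
      subject_annotation = ifelse(n_fields >= 14,
                                  vapply(fields, function(f)
                                    if (length(f) >= 14) f[14] else "", character(1)),
                                  ""),
      stringsAsFactors = FALSE
    )
    validate_alignment_hits(df)
  } else {
    ok <- n_fields == 7L
    if (!all(ok)) {
      stop("domain hit table row ", which(!ok)[1], " has ",
           n_fields[!ok][1], " columns (expected 7)", call. = FALSE)
    }
    get <- function(i) vapply(fields, function(f) f[i], character(1))
    df <- data.frame(
      query_id = get(1), model_id = get(2),
      bit_score = .parse_num(get(3), path, "bit_score"),
      e_value = .parse_num(get(4), path, "e_value"),
      q_start = .parse_num(get(5), path, "q_start"),
      q_end = .parse_num(get(6), path, "q_end"),
      source = get(7),
      stringsAsFactors = FALSE
    )
    validate_domain_hits(df)
  }
}

.parse_num <- function(x, path, col) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out)) {
    row <- which(is.na(out))[1]
    stop("unparsable numeric value '", x[row], "' in column ", col,
         ", row ", row, " of ", path, call. = FALSE)
  }
  out
}

empty_hits <- function(kind) {
  if (kind == "alignment") {
    df <- stats::setNames(
      data.frame(character(), character(), numeric(), numeric(), numeric(),
                 numeric(), numeric(), numeric(), numeric(), numeric(),
                 numeric(), numeric(), character(), character(),
                 stringsAsFactors = FALSE),
      ALIGNMENT_COLS)
    class(df) <- c("alignment_hits", "data.frame")
  } else {
    df <- stats::setNames(
      data.frame(character(), character(), numeric(), numeric(), numeric(),
                 numeric(), character(), stringsAsFactors = FALSE),
      DOMAIN_COLS)
    class(df) <- c("domain_hits", "data.frame")
  }
  df
}

validate_alignment_hits <- function(df) {
  stopifnot(all(ALIGNMENT_COLS %in% names(df)))
  if (any(df$q_start > df$q_end)) {
    row <- which(df$q_start > df$q_end)[1]
    stop("alignment hit row ", row, ": q_start > q_end", call. = FALSE)
  }
  if (any(df$e_value < 0)) {
    stop("alignment hit with negative e_value", call. = FALSE)
  }
  if (any(df$percent_identity < 0 | df$percent_identity > 100)) {
    stop("alignment hit with percent_identity outside [0, 100]",
         call. = FALSE)
  }
  class(df) <- c("alignment_hits", "data.frame")
  df
}

validate_domain_hits <- function(df) {
  stopifnot(all(DOMAIN_COLS %in% names(df)))
  if (any(df$q_start > df$q_end)) {
    row <- which(df$q_start > df$q_end)[1]
    stop("domain hit row ", row, ": q_start > q_end", call. = FALSE)
  }
  if (any(df$e_value < 0)) {
    stop("domain hit with negative e_value", call. = FALSE)
  }
  if (!all(df$source %in% c("hmm", "blast"))) {
    stop("domain hit source must be 'hmm' or 'blast'", call. = FALSE)
  }
  class(df) <- c("domain_hits", "data.frame")
  df
}

#' Write a hit table
#'
#' Inverse of [read_hit_table()]: writes the 12+2-column alignment layout or
#' the 7-column domain layout without a header row, so the file re-reads
#' identically.
#'
#' @param hits A data frame of alignment or domain hits.
#' @param path Output path.
#' @param comments Optional character vector written as leading `#` lines.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path, comments = character()) {
  kind <- if (all(ALIGNMENT_COLS %in% names(hits))) "alignment" else "domain"
  cols <- if (kind == "alignment") ALIGNMENT_COLS else DOMAIN_COLS
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments) > 0) writeLines(paste0("# ", comments), con)
  if (nrow(hits) > 0) {
    body <- do.call(paste, c(lapply(cols, function(cn) {
      v <- hits[[cn]]
      if (is.numeric(v)) format(v, scientific = NA, trim = TRUE, digits = 15)
      else as.character(v)
    }), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

#' Construct and validate a taxonomy tree
#'
#' @param nodes A data frame with columns `taxon_id`, `parent_id`, `rank`,
#'   `name`. Exactly one root (parent empty or self-referential) is required;
#'   parent links must form a tree.
#' @return A `taxonomy` object (validated node table plus id index).
#' @export
taxonomy <- function(nodes) {
  req <- c("taxon_id", "parent_id", "rank", "name")
  if (!all(req %in% names(nodes))) {
    stop("taxonomy table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  nodes$taxon_id <- as.character(nodes$taxon_id)
  nodes$parent_id <- as.character(nodes$parent_id)
  if (anyDuplicated(nodes$taxon_id)) {
    stop("duplicate taxon_id in taxonomy: ",
         nodes$taxon_id[duplicated(nodes$taxon_id)][1], call. = FALSE)
  }
  if (!all(nodes$rank %in% TAXONOMY_RANKS)) {
    stop("invalid rank in taxonomy: ",
         setdiff(nodes$rank, TAXONOMY_RANKS)[1], call. = FALSE)
  }
  is_root <- nodes$parent_id == "" | nodes$parent_id == nodes$taxon_id
  if (sum(is_root) != 1) {
    stop("taxonomy must have exactly one root, found ", sum(is_root),
         call. = FALSE)
  }
  dangling <- setdiff(nodes$parent_id[!is_root], nodes$taxon_id)
  if (length(dangling) > 0) {
    stop("taxonomy parent id not present as a node: ", dangling[1],
         call. = FALSE)
  }
  # cycle/connectivity check: every node must reach the root
  idx <- stats::setNames(seq_len(nrow(nodes)), nodes$taxon_id)
  root_id <- nodes$taxon_id[is_root]
  for (i in seq_len(nrow(nodes))) {
    seen <- character()
    cur <- nodes$taxon_id[i]
    while (cur != root_id) {
      if (cur %in% seen) {
        stop("cycle in taxonomy involving taxon ", cur, call. = FALSE)
      }
      seen <- c(seen, cur)
      cur <- nodes$parent_id[idx[[cur]]]
    }
  }
  structure(list(nodes = nodes, index = idx, root = root_id),
            class = "taxonomy")
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("taxonomy with", nrow(x$nodes), "nodes; root =", x$root, "\n")
  cat("ranks:", paste(sort(unique(x$nodes$rank)), collapse = ", "), "\n")
  invisible(x)
}

#' Read a taxonomy from TSV
#'
#' Expects columns taxon_id, parent_id, rank, name (header optional if the
#' first line matches those names; otherwise the 4 columns are taken in that
#' order).
#'
#' @param path Path to a tab-separated taxonomy dump.
#' @return A `taxonomy` object.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, n = 50L)
  first <- lines[!startsWith(lines, "#")][1]
  has_header <- !is.na(first) && grepl("^taxon_id\t", first)
  df <- utils::read.delim(path, header = has_header, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = "character",
                          na.strings = character())
  if (!has_header) names(df) <- c("taxon_id", "parent_id", "rank", "name")
  taxonomy(df)
}

#' Write a taxonomy to TSV
#' @param tax A `taxonomy` object.
#' @param path Output path.
#' @param comments Optional `#` header comments.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path, comments = character()) {
  write_tsv(tax$nodes, path, comments)
}

# Lineage from root to taxon_id, as a character vector of ids.
tax_lineage <- function(tax, taxon_id) {
  if (!taxon_id %in% names(tax$index)) {
    stop("taxon not present in taxonomy: ", taxon_id, call. = FALSE)
  }
  out <- character()
  cur <- taxon_id
  while (TRUE) {
    out <- c(cur, out)
    if (cur == tax$root) break
    cur <- tax$nodes$parent_id[tax$index[[cur]]]
  }
  out
}

# Ancestor of taxon_id at the requested rank, or NA if its lineage lacks it.
tax_ancestor_at_rank <- function(tax, taxon_id, rank) {
  lin <- tax_lineage(tax, taxon_id)
  ranks <- tax$nodes$rank[tax$index[lin]]
  hit <- lin[ranks == rank]
  if (length(hit) == 0) NA_character_ else hit[1]
}

#' Lowest common ancestor of a set of taxa
#'
#' @param tax A `taxonomy` object.
#' @param taxon_ids Character vector of taxon ids present in `tax`.
#' @return The taxon id of the deepest node ancestral to all inputs.
#' @export
tax_lca <- function(tax, taxon_ids) {
  taxon_ids <- unique(taxon_ids)
  if (length(taxon_ids) == 0) stop("tax_lca needs at least one taxon",
                                   call. = FALSE)
  lin <- tax_lineage(tax, taxon_ids[1])
  for (id in taxon_ids[-1]) {
    other <- tax_lineage(tax, id)
    n <- min(length(lin), length(other))
    same <- lin[seq_len(n)] == other[seq_len(n)]
    if (!all(same)) n <- which(!same)[1] - 1L
    lin <- lin[seq_len(n)]
  }
  lin[length(lin)]
}
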