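# ---- coordinate conventions -------------------------------------------------
# Internally every genomic interval is 0-based half-open [start, end) with
# strand "+" or "-". Display output is 1-based inclusive with a strand arrow
# ("a -> b" on the plus strand, "a <- b" on the minus strand), the style used
# in published tables of novel sRNA coordinates.

#' Construct a genomic interval
#'
#' Intervals are 0-based half-open internally; see [format_position()] for the
#' 1-based inclusive display convention.
#'
#' @param replicon Replicon (chromosome/plasmid) identifier.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must exceed `start`.
#' @param strand `"+"` or `"-"`.
#' @return A one-row data frame with columns `replicon`, `start`, `end`,
#'   `strand`.
#' @export
genomic_interval <- function(replicon, start, end, strand) {
  stopifnot(length(replicon) == length(start), length(start) == length(end),
            length(end) == length(strand))
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval end must exceed start")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  data.frame(replicon = as.character(replicon), start = as.integer(start),
             end = as.integer(end), strand = as.character(strand),
             stringsAsFactors = FALSE)
}

#' Format an interval as a 1-based display position with a strand arrow
#'
#' @param start,end Internal 0-based half-open coordinates.
#' @param strand `"+"` or `"-"`.
#' @param big_mark Thousands separator used in the display (default comma).
#' @return Character vector like `"1,140,986 -> 1,141,063"` (the arrow is the
#'   Unicode right/left arrow).
#' @export
format_position <- function(start, end, strand, big_mark = ",") {
  arrow <- ifelse(strand == "+", "→", "←")
  paste(formatC(start + 1L, big.mark = big_mark, format = "d"), arrow,
        formatC(end, big.mark = big_mark, format = "d"))
}

#' Parse a 1-based arrow-display position back to an internal interval
#'
#' Inverse of [format_position()].
#'
#' @param x Character vector of display positions.
#' @return Data frame with `start`, `end` (0-based half-open) and `strand`.
#' @export
parse_position <- function(x) {
  x <- gsub(",", "", x)
  m <- regmatches(x, regexec("^\\s*(\\d+)\\s*(→|←|->|<-)\\s*(\\d+)\\s*$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("unparseable display position: ", x[bad][1])
  a <- as.integer(vapply(m, `[`, "", 2L))
  b <- as.integer(vapply(m, `[`, "", 4L))
  strand <- ifelse(vapply(m, `[`, "", 3L) %in% c("→", "->"), "+", "-")
  data.frame(start = a - 1L, end = b, strand = strand, stringsAsFactors = FALSE)
}

# ---- S-chimera tables -------------------------------------------------------

#' Column dialect for S-chimera tables
#'
#' Maps the logical fields of an S-chimera record to the column names used in
#' a particular deposited table. The shipped default matches the tables this
#' package writes. Unknown extra columns in a file are ignored.
#'
#' @param first_rna,first_replicon,first_start,first_end,first_strand Column
#'   names for the first RNA of the chimera.
#' @param second_rna,second_replicon,second_start,second_end,second_strand
#'   Column names for the second RNA.
#' @param n_fragments Column holding the supporting chimeric-fragment count.
#' @param coords Either `"1-based"` (inclusive, the on-disk default) or
#'   `"0-based"` (half-open).
#' @return Named list of class `"schimera_dialect"`.
#' @export
schimera_dialect <- function(first_rna = "first_rna",
                             first_replicon = "first_replicon",
                             first_start = "first_start",
                             first_end = "first_end",
                             first_strand = "first_strand",
                             second_rna = "second_rna",
                             second_replicon = "second_replicon",
                             second_start = "second_start",
                             second_end = "second_end",
                             second_strand = "second_strand",
                             n_fragments = "n_fragments",
                             coords = c("1-based", "0-based")) {
  d <- list(first_rna = first_rna, first_replicon = first_replicon,
            first_start = first_start, first_end = first_end,
            first_strand = first_strand, second_rna = second_rna,
            second_replicon = second_replicon, second_start = second_start,
            second_end = second_end, second_strand = second_strand,
            n_fragments = n_fragments, coords = match.arg(coords))
  class(d) <- "schimera_dialect"
  d
}

#' Read an S-chimera table
#'
#' Reads a tab-delimited table of statistically significant chimeric RNA
#' pairs (S-chimeras). Each row records an ordered pair: the first and the
#' second RNA of the chimera, their genomic coordinates and strands, and the
#' number of chimeric fragments supporting the pair. The first/second
#' orientation is semantically meaningful (the Second-In-Chimera score depends
#' on it) and is never swapped.
#'
#' Rows whose two ends map to the same RNA name are retained and flagged as
#' self-chimeras (`is_self`); downstream aggregation counts their fragments
#' once and excludes them from partner counting.
#'
#' @param path Path to the tab-delimited table (with header).
#' @param condition_id Label for the growth condition/data set this table
#'   represents; analyses are run separately per condition.
#' @param dialect A [schimera_dialect()] declaring the column names.
#' @return A data frame of class `"chimera_records"` with internal 0-based
#'   half-open coordinates, columns `condition`, `first_rna`,
#'   `first_replicon`, `first_start`, `first_end`, `first_strand`,
#'   `second_rna`, ..., `n_fragments`, `is_self`.
#' @export
read_schimera_table <- function(path, condition_id = "condition1",
                                dialect = schimera_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "", comment.char = "")
  needed <- unlist(dialect[setdiff(names(dialect), "coords")])
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0)
    stop("S-chimera table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(raw) == 0) {
    warning("S-chimera table '", path, "' has a header but no rows")
    return(chimera_records(data.frame()))
  }
  g <- function(field) raw[[dialect[[field]]]]
  rec <- data.frame(
    condition = condition_id,
    first_rna = as.character(g("first_rna")),
    first_replicon = as.character(g("first_replicon")),
    first_start = as.integer(g("first_start")),
    first_end = as.integer(g("first_end")),
    first_strand = as.character(g("first_strand")),
    second_rna = as.character(g("second_rna")),
    second_replicon = as.character(g("second_replicon")),
    second_start = as.integer(g("second_start")),
    second_end = as.integer(g("second_end")),
    second_strand = as.character(g("second_strand")),
    n_fragments = as.integer(g("n_fragments")),
    stringsAsFactors = FALSE)
  if (dialect$coords == "1-based") {
    rec$first_start <- rec$first_start - 1L
    rec$second_start <- rec$second_start - 1L
  }
  bad <- which(is.na(rec$n_fragments) | rec$n_fragments < 1L)
  if (length(bad) > 0)
    stop("non-positive or missing fragment count at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(rec$first_rna == "" | rec$second_rna == "" |
                 is.na(rec$first_rna) | is.na(rec$second_rna))
  if (length(bad) > 0)
    stop("empty RNA name at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(rec$first_start < 0 | rec$first_end <= rec$first_start |
                 rec$second_start < 0 | rec$second_end <= rec$second_start)
  if (length(bad) > 0)
    stop("malformed coordinates at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!(rec$first_strand %in% c("+", "-")) |
                 !(rec$second_strand %in% c("+", "-")))
  if (length(bad) > 0)
    stop("invalid strand at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  chimera_records(rec)
}

#' Build a chimera-record table from a data frame
#'
#' Validates an in-memory data frame of ordered RNA pairs (internal 0-based
#' half-open coordinates) and stamps the `"chimera_records"` class, adding the
#' `is_self` self-chimera flag.
#'
#' @param df Data frame with the columns produced by [read_schimera_table()]
#'   (minus `is_self`); an empty data frame yields an empty record table.
#' @return Data frame of class `"chimera_records"`.
#' @export
chimera_records <- function(df) {
  if (nrow(df) == 0) {
    df <- data.frame(condition = character(), first_rna = character(),
                     first_replicon = character(), first_start = integer(),
                     first_end = integer(), first_strand = character(),
                     second_rna = character(), second_replicon = character(),
                     second_start = integer(), second_end = integer(),
                     second_strand = character(), n_fragments = integer(),
                     is_self = logical(), stringsAsFactors = FALSE)
    class(df) <- c("chimera_records", "data.frame")
    return(df)
  }
  df$is_self <- df$first_rna == df$second_rna
  class(df) <- c("chimera_records", "data.frame")
  df
}

#' Write an S-chimera table
#'
#' Writes records in the shipped default dialect (1-based inclusive
#' coordinates on disk). `read_schimera_table()` on the result round-trips to
#' an identical record table.
#'
#' @param records A `"chimera_records"` data frame.
#' @param path Output path.
#' @export
write_schimera_table <- function(records, path) {
  out <- as.data.frame(records)[, c("first_rna", "first_replicon",
                                    "first_start", "first_end", "first_strand",
                                    "second_rna", "second_replicon",
                                    "second_start", "second_end",
                                    "second_strand", "n_fragments")]
  out$first_start <- out$first_start + 1L
  out$second_start <- out$second_start + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- labels -----------------------------------------------------------------

.label_levels <- c("known_sRNA", "other_RNA")

#' Read a two-column RNA label list
#'
#' Each RNA in the data is annotated as either `known_sRNA` or `other_RNA`.
#' RNAs absent from the list default to `other_RNA` (with a warning) when
#' labels are resolved against a data set.
#'
#' @param path Two-column tab-delimited file (`rna`, `label`), no header
#'   required (a header line reading `rna<TAB>label` is tolerated).
#' @return Named character vector of class `"label_set"`; values are
#'   `"known_sRNA"` or `"other_RNA"`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "", col.names = c("rna", "label"),
                           colClasses = "character")
  if (nrow(raw) > 0 && raw$rna[1] == "rna" && raw$label[1] == "label")
    raw <- raw[-1, , drop = FALSE]
  if (nrow(raw) == 0) return(label_set(character(0)))
  bad <- !(raw$label %in% .label_levels)
  if (any(bad))
    stop("unknown label token(s): ", paste(unique(raw$label[bad]), collapse = ", "),
         " (expected known_sRNA / other_RNA)")
  # duplicates: consistent ones deduplicate silently, conflicts are an error
  conf <- tapply(raw$label, raw$rna, function(l) length(unique(l)) > 1)
  if (any(conf))
    stop("conflicting labels for: ", paste(names(conf)[conf], collapse = ", "))
  raw <- raw[!duplicated(raw$rna), , drop = FALSE]
  label_set(stats::setNames(raw$label, raw$rna))
}

#' Construct a label set
#'
#' @param x Named character vector mapping RNA name to `"known_sRNA"` or
#'   `"other_RNA"`.
#' @return The vector with class `"label_set"`.
#' @export
label_set <- function(x) {
  if (length(x) > 0) {
    stopifnot(!is.null(names(x)), all(x %in% .label_levels))
  }
  structure(as.character(x), names = names(x), class = "label_set")
}

#' Resolve labels for a set of RNA names
#'
#' @param labels A `"label_set"`.
#' @param rna_names RNA names appearing in the data.
#' @param quiet Suppress the default-label warning.
#' @return Character vector parallel to `rna_names`; unlabeled names default
#'   to `"other_RNA"` with a warning.
#' @export
resolve_labels <- function(labels, rna_names, quiet = FALSE) {
  out <- unclass(labels)[rna_names]
  miss <- is.na(out)
  if (any(miss) && !quiet)
    warning(sum(miss), " RNA name(s) without a label default to other_RNA")
  out[miss] <- "other_RNA"
  stats::setNames(out, rna_names)
}

#' Write a label set
#'
#' @param labels A `"label_set"`.
#' @param path Output path (two-column TSV).
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(rna = names(labels), label = unclass(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# ---- genome -----------------------------------------------------------------

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] keyed by replicon id (first whitespace
#'   token of each FASTA header).
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Fetch the sense-strand sequence of an interval
#'
#' Returns the transcript-sense DNA sequence: the plus-strand slice for `+`
#' intervals, its reverse complement for `-` intervals.
#'
#' @param genome A `DNAStringSet` from [read_genome()].
#' @param replicon,start,end,strand Interval fields (0-based half-open).
#' @return Character scalar (DNA alphabet; read T as U for RNA).
#' @export
fetch_sequence <- function(genome, replicon, start, end, strand) {
  if (!replicon %in% names(genome))
    stop("unknown replicon: ", replicon)
  len <- length(genome[[replicon]])
  if (start < 0 || end > len || end <= start)
    stop("interval [", start, ",", end, ") out of bounds for replicon '",
         replicon, "' (length ", len, ")")
  s <- Biostrings::subseq(genome[[replicon]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

# ---- site tables ------------------------------------------------------------

.site_kinds <- c("TSS", "RNaseE_cleavage", "CLASH_segment")

#' Read a BED-like site table
#'
#' Reads evidence sites: transcription start sites (TSS), RNase E cleavage
#' sites, or CLASH chimera segments. Expected columns (tab-delimited, no
#' header): replicon, start, end, strand — BED convention, 0-based half-open.
#' Point sites (TSS, cleavage) may omit the end column, in which case
#' `end = start + 1`.
#'
#' @param path Input path.
#' @param site_kind One of `"TSS"`, `"RNaseE_cleavage"`, `"CLASH_segment"`;
#'   fixed per file.
#' @return Data frame of class `"site_table"` with columns `replicon`,
#'   `start`, `end`, `strand` and attribute `site_kind`.
#' @export
read_site_table <- function(path, site_kind) {
  site_kind <- match.arg(site_kind, .site_kinds)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  if (ncol(raw) == 3) {
    raw <- data.frame(replicon = raw[[1]], start = raw[[2]],
                      end = raw[[2]] + 1L, strand = raw[[3]],
                      stringsAsFactors = FALSE)
  } else if (ncol(raw) >= 4) {
    raw <- data.frame(replicon = raw[[1]], start = raw[[2]], end = raw[[3]],
                      strand = raw[[4]], stringsAsFactors = FALSE)
  } else {
    stop("site table needs columns: replicon, start[, end], strand")
  }
  raw$start <- suppressWarnings(as.integer(raw$start))
  raw$end <- suppressWarnings(as.integer(raw$end))
  if (any(is.na(raw$start)) || any(is.na(raw$end)) || any(raw$start < 0) ||
      any(raw$end <= raw$start))
    stop("malformed coordinates in site table: ", path)
  if (!all(raw$strand %in% c("+", "-")))
    stop("invalid strand in site table: ", path)
  site_table(raw, site_kind)
}

#' Construct a site table from a data frame
#'
#' @param df Data frame with `replicon`, `start`, `end`, `strand`.
#' @param site_kind One of `"TSS"`, `"RNaseE_cleavage"`, `"CLASH_segment"`.
#' @return Data frame of class `"site_table"`.
#' @export
site_table <- function(df, site_kind) {
  site_kind <- match.arg(site_kind, .site_kinds)
  stopifnot(all(c("replicon", "start", "end", "strand") %in% names(df)))
  attr(df, "site_kind") <- site_kind
  class(df) <- c("site_table", "data.frame")
  df
}

# ---- generic TSV output -----------------------------------------------------

#' Write a pipeline table as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
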