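#' Read a FASTA file
#'
#' Sequences are uppercased and returned as a named character vector keyed
#' by the first whitespace-delimited token of each header. Parsing is
#' line-wrapping-agnostic (Biostrings does the reading).
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (possibly empty, with a
#'   warning, for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  stats::setNames(toupper(as.character(set)), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene/CDS annotations from GFF3
#'
#' A light GFF3 reader for the fields the scanner needs. GFF3 1-based
#' inclusive coordinates are converted to the package-internal 0-based
#' half-open convention; features are sorted by sequence and start. The
#' gene id is taken from the first of the `ID`, `locus_tag` or `gene`
#' attributes.
#'
#' @param path GFF3 file.
#' @param types feature types to keep (default CDS and gene).
#' @return Data frame: `seqid`, `start`, `end` (0-based half-open),
#'   `strand`, `type`, `gene_id`.
#' @export
read_annotations <- function(path, types = c("CDS", "gene")) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  rows <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) {
      stop("malformed GFF3 record at line ", i, ": expected 9 columns")
    }
    if (!f[3] %in% types) next
    s <- suppressWarnings(as.numeric(f[4]))
    e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e)) {
      stop("malformed GFF3 record at line ", i, ": non-numeric coordinates")
    }
    if (e < s) {
      stop("malformed GFF3 record at line ", i, ": end (", e,
           ") < start (", s, ")")
    }
    attrs <- strsplit(f[9], ";", fixed = TRUE)[[1]]
    kv <- strsplit(attrs, "=", fixed = TRUE)
    keys <- vapply(kv, `[`, character(1), 1)
    vals <- vapply(kv, function(x) if (length(x) > 1) x[2] else NA_character_,
                   character(1))
    gid <- NA_character_
    for (key in c("ID", "locus_tag", "gene")) {
      hit <- which(keys == key)
      if (length(hit)) { gid <- vals[hit[1]] ; break }
    }
    rows[[length(rows) + 1]] <- data.frame(
      seqid = f[1], start = s - 1, end = e, strand = f[7], type = f[3],
      gene_id = gid, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seqid = character(), start = numeric(), end = numeric(),
               strand = character(), type = character(),
               gene_id = character(), stringsAsFactors = FALSE)
  out[order(out$seqid, out$start, out$end), , drop = FALSE]
}

#' Write annotations to GFF3
#'
#' Converts internal 0-based half-open features back to GFF3 1-based
#' inclusive coordinates. Round-trips with [read_annotations()] losslessly
#' for the fields the pipeline uses.
#'
#' @param features data frame as returned by [read_annotations()].
#' @param path output file.
#' @param source value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(features, path, source = "caproscope") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(features))) {
    writeLines(paste(features$seqid[i], source, features$type[i],
                     features$start[i] + 1, features$end[i], ".",
                     features$strand[i], ".",
                     paste0("ID=", features$gene_id[i]),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Validate features against a genome
#'
#' @param features annotation data frame.
#' @param genome named character vector of sequences.
#' @return `features`, invisibly; errors if a feature references an unknown
#'   sequence or exceeds its bounds.
#' @export
validate_features <- function(features, genome) {
  unknown <- setdiff(unique(features$seqid), names(genome))
  if (length(unknown)) {
    stop("feature(s) on unknown sequence id(s): ",
         paste(unknown, collapse = ", "))
  }
  for (sid in unique(features$seqid)) {
    f <- features[features$seqid == sid, ]
    if (min(f$start) < 0 || max(f$end) > nchar(genome[[sid]])) {
      stop("feature out of range on sequence ", sid)
    }
  }
  invisible(features)
}

#' Read or write a fermentation spectrum table
#'
#' TSV with columns `species`, `moles`, `role` (`consumed` or `produced`);
#' replicate tables add a `replicate` column.
#'
#' @param path TSV file.
#' @return Data frame.
#' @export
read_spectrum_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "moles", "role")
  if (!all(need %in% names(tab))) {
    stop("spectrum table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(tab$role %in% c("consumed", "produced"))) {
    stop("role must be 'consumed' or 'produced'")
  }
  tab
}

#' @rdname read_spectrum_tsv
#' @param tab spectrum data frame.
#' @export
write_spectrum_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Signed fixed coefficients from a measured spectrum table
#'
#' Averages replicate moles per species (if a `replicate` column is
#' present), applies the sign convention (consumed negative), and returns a
#' named vector ready for [balance_fermentation()].
#'
#' @param tab spectrum data frame (`species`, `moles`, `role`, optionally
#'   `replicate`).
#' @return Named numeric vector of signed mean coefficients.
#' @export
spectrum_fixed_coefficients <- function(tab) {
  agg <- stats::aggregate(moles ~ species + role, data = tab, FUN = mean)
  sgn <- ifelse(agg$role == "consumed", -1, 1)
  stats::setNames(sgn * agg$moles, agg$species)
}
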