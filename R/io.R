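#' Peptide-level reporter intensity container
#'
#' Holds one row per (peptide, sample): identifying metadata plus the
#' reporter-ion intensities across the temperature channels of one melt
#' curve. One TMT set equals one melt curve, so `set_id` normally coincides
#' with the `(cell_line, condition, replicate)` sample key.
#'
#' @param meta Data frame with columns `peptide_id`, `sequence`, `genes`
#'   (delimited multi-gene mapping string), `cell_line`, `condition`,
#'   `replicate`, `set_id`. A `psm_id` column marks PSM-level (not yet
#'   peptide-summarized) rows.
#' @param intensities Numeric matrix, one row per `meta` row, one column per
#'   temperature channel; non-negative, `NA` for missing.
#' @param grid A [temperature_grid()].
#' @param gene_delim Delimiter inside the `genes` field, default `";"`.
#' @param conditions Allowed condition labels (closed vocabulary).
#' @return Object of class `"peptide_quant"`.
#' @export
peptide_quant <- function(meta, intensities, grid,
                          gene_delim = ";",
                          conditions = c("vehicle", "drug")) {
  stopifnot(is.data.frame(meta), is.matrix(intensities))
  required <- c("peptide_id", "sequence", "genes", "cell_line",
                "condition", "replicate", "set_id")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("missing metadata column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(meta) != nrow(intensities)) {
    stop("meta and intensities disagree on row count")
  }
  if (ncol(intensities) != length(grid)) {
    stop(sprintf("intensity columns (%d) do not match grid length (%d)",
                 ncol(intensities), length(grid)))
  }
  neg <- which(intensities < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative intensity at row %d", neg[1, 1]))
  }
  if (any(!nzchar(meta$genes) | is.na(meta$genes))) {
    stop("every record needs at least one gene symbol")
  }
  bad <- !meta$condition %in% conditions
  if (any(bad)) {
    stop(sprintf("condition '%s' not in {%s}", meta$condition[which(bad)[1]],
                 paste(conditions, collapse = ", ")))
  }
  meta$sample_id <- sample_key(meta)
  structure(list(meta = meta, intensities = unname(intensities), grid = grid,
                 gene_delim = gene_delim),
            class = "peptide_quant")
}

sample_key <- function(meta) {
  paste(meta$cell_line, meta$condition, meta$replicate, sep = ".")
}

#' Split a delimited multi-gene mapping field
#' @param genes Character vector of delimited gene fields.
#' @param delim Delimiter, default `";"`.
#' @return List of character vectors (one set of gene symbols per record).
#' @export
split_genes <- function(genes, delim = ";") {
  strsplit(as.character(genes), delim, fixed = TRUE)
}

#' @export
print.peptide_quant <- function(x, ...) {
  cat(sprintf("peptide_quant: %d records, %d channels, %d samples, %d gene fields\n",
              nrow(x$meta), length(x$grid), length(unique(x$meta$sample_id)),
              length(unique(x$meta$genes))))
  if ("psm_id" %in% names(x$meta)) cat("  (PSM-level rows)\n")
  invisible(x)
}

default_channel_cols <- function(grid) {
  sprintf("channel_%02d", seq_along(grid$temperatures))
}

#' Read a peptide/PSM reporter-intensity table
#'
#' Ingests a tab-separated table with one row per peptide (or PSM) per
#' sample and one column per reporter channel. Channel columns are declared
#' explicitly (channel-to-temperature mapping comes from `grid`, never from
#' the header). Empty cells and `"NA"` are missing values; zero is a valid
#' measured intensity and is kept; negative values are rejected.
#'
#' @param path Path to a TSV file.
#' @param grid A [temperature_grid()].
#' @param channel_cols Names of the reporter channel columns, in grid order.
#'   Default `channel_01 ... channel_NN`.
#' @param gene_delim Delimiter for multi-gene mappings, default `";"`.
#' @return A [peptide_quant()] object; row order of the file is preserved.
#' @export
read_peptide_table <- function(path, grid,
                               channel_cols = default_channel_cols(grid),
                               gene_delim = ";") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("", "NA"))
  required <- c("peptide_id", "sequence", "genes", "cell_line",
                "condition", "replicate", "set_id")
  for (col in c(required, channel_cols)) {
    if (!col %in% names(tab)) stop("missing column '", col, "'")
  }
  ints <- as.matrix(tab[, channel_cols, drop = FALSE])
  storage.mode(ints) <- "double"
  neg <- which(ints < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative intensity at row %d, column '%s'",
                 neg[1, 1], channel_cols[neg[1, 2]]))
  }
  meta_cols <- intersect(c("psm_id", required), names(tab))
  peptide_quant(tab[, meta_cols, drop = FALSE], ints, grid,
                gene_delim = gene_delim)
}

#' Write a peptide_quant object as the TSV dialect read_peptide_table() reads
#' @param x A [peptide_quant()] object.
#' @param path Output path.
#' @param channel_cols Channel column names to use.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(x, path,
                                channel_cols = default_channel_cols(x$grid)) {
  ints <- x$intensities
  colnames(ints) <- channel_cols
  meta <- x$meta[, setdiff(names(x$meta), "sample_id"), drop = FALSE]
  write.table(cbind(meta, as.data.frame(ints)), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' Sequences are uppercased; duplicate identifiers are an error. The first
#' whitespace-delimited token of each header is the identifier.
#'
#' @param path FASTA file path.
#' @return Named character vector of amino-acid sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop("no sequences in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(aa))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA identifier: ", dup[1])
  setNames(toupper(gsub("\\s", "", as.character(aa))), ids)
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description (ignored), then one or more member gene
#' symbols, all tab-separated. Members are deduplicated; duplicate set names
#' and lines with fewer than three fields are errors.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (gene symbols per set).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  }
  nm <- vapply(fields, `[[`, "", 1L)
  dup <- nm[duplicated(nm)]
  if (length(dup)) stop("duplicate gene-set name: ", dup[1])
  setNames(lapply(fields, function(f) unique(f[-(1:2)])), nm)
}

#' Write a results table as TSV with full numeric precision
#'
#' Numeric columns are written with 15 significant digits so that
#' re-reading reproduces values to at least 12 significant digits.
#'
#' @param df Data frame of results.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- formatC(out[[j]], digits = 15, format = "g")
      out[[j]][is.na(df[[j]])] <- "NA"
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results table written by write_results_table()
#' @param path TSV path.
#' @return Data frame.
#' @export
read_results_table <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE,
             na.strings = c("", "NA"))
}
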