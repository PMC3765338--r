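# Readers and writers for the plain-text formats used throughout the
# pipeline: FASTA promoters, JASPAR-style PFM libraries, expression TSVs,
# annotation TSVs.

#' Read promoter sequences from a FASTA file
#'
#' Wraps [Biostrings::readDNAStringSet()] with the validation the pipeline
#' relies on: unique ids, non-empty DNA-only sequences, upper-cased output.
#'
#' @param path FASTA file path.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(is.na(ids) | ids == "")) stop("malformed FASTA header in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  widths <- Biostrings::width(set)
  if (any(widths == 0L))
    stop("empty sequence for id(s): ",
         paste(ids[widths == 0L], collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write promoter sequences to a FASTA file
#'
#' @param sequences named character vector (names are gene ids).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(!is.null(names(sequences)))
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read a JASPAR-style PFM library
#'
#' Parses blocks of the form
#' \preformatted{>motif_id name
#' A  [ 4 19  0 ... ]
#' C  [ ... ]
#' G  [ ... ]
#' T  [ ... ]}
#' Square brackets and row labels are optional; four rows of equal length
#' per block are required.
#'
#' @param path PFM text file.
#' @param pseudocount,background passed to [normalize_pfm()].
#' @return Named list of `"pwm"` objects in file order; empty list (with a
#'   warning) for an empty file.
#' @export
read_pfm <- function(path, pseudocount = 0.8,
                     background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (!file.exists(path)) stop("PFM file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  if (!length(lines)) {
    warning("empty PFM file: ", path)
    return(list())
  }
  headers <- grep("^>", lines)
  if (!length(headers) || headers[1L] != 1L)
    stop("PFM file must start with a '>' header line: ", path)
  bounds <- c(headers, length(lines) + 1L)
  out <- list()
  for (i in seq_along(headers)) {
    header <- sub("^>\\s*", "", lines[headers[i]])
    fields <- strsplit(header, "\\s+")[[1L]]
    id <- fields[1L]
    name <- if (length(fields) > 1L) paste(fields[-1L], collapse = " ") else id
    body <- lines[seq(headers[i] + 1L, bounds[i + 1L] - 1L)]
    if (length(body) != 4L)
      stop("motif '", id, "': expected 4 count rows, found ", length(body))
    rows <- lapply(body, function(ln) {
      ln <- gsub("[][]", " ", ln)
      ln <- sub("^\\s*[ACGTacgt][:]?\\s+", "", ln)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1L]]))
      if (anyNA(vals)) stop("motif '", id, "': non-numeric count row")
      vals
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L)
      stop("motif '", id, "': count rows of unequal length (",
           paste(lens, collapse = ", "), ")")
    counts <- do.call(rbind, rows)
    rownames(counts) <- DNA_BASES
    out[[id]] <- normalize_pfm(counts, pseudocount = pseudocount,
                               background = background, id = id, name = name)
  }
  out
}

#' Write a PWM library as JASPAR-style PFM text
#'
#' @param pwms list of `"pwm"` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$id, p$name), con)
    for (b in DNA_BASES) {
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(p$counts[b, ], trim = TRUE),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read an expression matrix and its sample-condition map
#'
#' @param path TSV of log2 expression, genes in rows (first column or row
#'   names), samples in columns.
#' @param conditions_path two-column TSV (`sample`, `condition`).
#' @return List with `expression` (numeric matrix) and `conditions` (named
#'   character vector keyed by sample id).
#' @export
read_expression <- function(path, conditions_path) {
  tab <- read.delim(path, check.names = FALSE, row.names = 1L)
  mat <- as.matrix(tab)
  storage.mode(mat) <- "double"
  cond <- read.delim(conditions_path, check.names = FALSE,
                     stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(cond)))
    stop("conditions file needs columns 'sample' and 'condition'")
  missing <- setdiff(colnames(mat), cond$sample)
  if (length(missing))
    stop("sample(s) missing from conditions file: ",
         paste(missing, collapse = ", "))
  list(expression = mat,
       conditions = stats::setNames(cond$condition, cond$sample)[colnames(mat)])
}

#' Write an expression matrix and its sample-condition map
#'
#' @param expression numeric matrix (genes x samples).
#' @param conditions named character vector keyed by sample id.
#' @param path,conditions_path output TSV paths.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expression, conditions, path, conditions_path) {
  df <- data.frame(gene = rownames(expression), expression,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cdf <- data.frame(sample = colnames(expression),
                    condition = unname(conditions[colnames(expression)]))
  write.table(cdf, conditions_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-term annotation table
#'
#' @param path two-column TSV (`gene`, `term`); one row per (gene, term)
#'   pair.
#' @return Data frame with character columns `gene` and `term`.
#' @export
read_annotation <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "term") %in% names(ann)))
    stop("annotation file needs columns 'gene' and 'term'")
  ann[, c("gene", "term")]
}

#' Write a gene-to-term annotation table
#'
#' @param annotation data frame with columns `gene` and `term`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  write.table(annotation[, c("gene", "term")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
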