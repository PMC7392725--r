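#' Read a BED file into a tibble
#'
#' Reads BED3/BED6 into a tibble of 0-based half-open intervals. Columns
#' beyond the sixth are dropped.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, "track") & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- stringr::str_split(lines, "\t")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort(sprintf("malformed BED line %d: fewer than 3 fields",
                  which(nf < 3L)[1]))
  }
  col <- function(i) purrr::map_chr(fields, ~ if (length(.x) >= i) .x[[i]] else NA_character_)
  start <- suppressWarnings(as.integer(col(2)))
  end <- suppressWarnings(as.integer(col(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    abort(sprintf("malformed BED line %d: non-numeric coordinates", bad[1]))
  }
  out <- tibble(chrom = col(1), start = start, end = end)
  if (max(nf) >= 4L) out$name <- col(4)
  if (max(nf) >= 5L) out$score <- suppressWarnings(as.numeric(col(5)))
  if (max(nf) >= 6L) out$strand <- col(6)
  out
}

#' Write intervals to a BED file
#'
#' @param x Tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand` columns (0-based half-open).
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_bed <- function(x, path) {
  check_interval_tbl(x, "BED table")
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  # BED columns are positional: stop at the first absent one
  keep <- character()
  for (cn in c("chrom", "start", "end", "name", "score", "strand")) {
    if (cn %in% cols) keep <- c(keep, cn) else break
  }
  readr::write_tsv(x[, keep, drop = FALSE], path, col_names = FALSE)
  invisible(x)
}

#' Read a two-column genome size table
#'
#' @param path Path to a TSV with chromosome name and length (no header).
#' @return Tibble with `chrom` and `length`.
#' @export
read_genome_table <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = "ci", progress = FALSE)
  check_genome_table(x)
}

#' Write a genome size table
#' @param genome_table Tibble with `chrom` and `length`.
#' @param path Output path.
#' @return `genome_table`, invisibly.
#' @export
write_genome_table <- function(genome_table, path) {
  check_genome_table(genome_table)
  readr::write_tsv(genome_table[, c("chrom", "length")], path,
                   col_names = FALSE)
  invisible(genome_table)
}

#' Read genome sequences from FASTA
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- stringr::word(names(seqs), 1)
  out
}

#' Write genome sequences to FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @return `sequences`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(sequences)
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses JASPAR 2016-style flat text: a `>ID NAME` header followed by four
#' rows `A [ 1 2 ... ]`, `C [...]`, `G [...]`, `T [...]`.
#'
#' @param path Path to the PFM text file.
#' @return A named list of count matrices (rows A, C, G, T).
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(stringr::str_trim(lines))]
  headers <- which(startsWith(lines, ">"))
  if (length(headers) == 0L) abort("no '>' headers found in PFM file")
  out <- list()
  for (i in seq_along(headers)) {
    h <- headers[i]
    stopend <- if (i < length(headers)) headers[i + 1] - 1L else length(lines)
    block <- lines[(h + 1L):stopend]
    if (length(block) < 4L) {
      abort(sprintf("PFM block at line %d has fewer than 4 matrix rows", h))
    }
    rows <- purrr::map(block[1:4], function(ln) {
      nums <- stringr::str_extract_all(ln, "[0-9.]+")[[1]]
      as.numeric(nums)
    })
    if (length(unique(lengths(rows))) != 1L) {
      abort(sprintf("PFM block at line %d has unequal row lengths", h))
    }
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    id <- stringr::str_trim(sub("^>", "", lines[h]))
    nm <- stringr::word(id, 2)
    if (is.na(nm)) nm <- stringr::word(id, 1)
    out[[nm]] <- m
  }
  out
}

#' Write position frequency matrices in JASPAR format
#'
#' @param pfms Named list of 4 x width count matrices (rows A, C, G, T).
#' @param path Output path.
#' @return `pfms`, invisibly.
#' @export
write_jaspar_pfm <- function(pfms, path) {
  stopifnot(is.list(pfms), !is.null(names(pfms)))
  lines <- purrr::imap(pfms, function(m, nm) {
    c(paste0(">", nm, " ", nm),
      purrr::map_chr(1:4, function(i) {
        paste0(c("A", "C", "G", "T")[i], " [ ",
               paste(format(m[i, ], trim = TRUE), collapse = " "), " ]")
      }))
  })
  readr::write_lines(unlist(lines), path)
  invisible(pfms)
}

#' Read a SNP table with parental genotypes
#'
#' @param path TSV with header columns `chrom`, `pos`, `ref`, `alt`,
#'   `maternal`, `paternal` (0-based positions).
#' @return A tibble of variant sites.
#' @export
read_snp_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    .default = readr::col_character()), progress = FALSE)
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(x))) {
    abort("SNP table needs chrom, pos, ref, alt columns")
  }
  if (any(x$ref == x$alt)) abort("SNP table has sites with ref == alt")
  x
}

#' Write a SNP table
#' @param snps Tibble with at least `chrom`, `pos`, `ref`, `alt`.
#' @param path Output path.
#' @return `snps`, invisibly.
#' @export
write_snp_table <- function(snps, path) {
  readr::write_tsv(snps, path)
  invisible(snps)
}
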