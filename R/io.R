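MARKERS <- c("MHCII", "CD40", "PDL1")
BINS <- c("input", "high", "low")

#' Construct a guide library table
#'
#' A guide library maps every sgRNA to its target gene and flags
#' non-targeting controls (NTCs), the guides with no genomic target that
#' supply the empirical null throughout the pipeline.
#'
#' @param guide_id character vector of unique guide identifiers.
#' @param gene character vector of target gene symbols; NTC guides carry the
#'   reserved pseudo-gene label `ntc_label`. Symbols are compared
#'   case-sensitively (mouse symbols are case-meaningful).
#' @param ntc_label the reserved gene label marking non-targeting controls.
#' @param sequence optional guide sequences over A/C/G/T.
#' @return A `data.frame` of class `guide_library` with columns `guide_id`,
#'   `gene`, `is_ntc` (and `sequence` if given).
#' @export
guide_library <- function(guide_id, gene, ntc_label = "NTC", sequence = NULL) {
  guide_id <- as.character(guide_id)
  gene <- as.character(gene)
  if (length(guide_id) != length(gene)) {
    stop("guide_id and gene must have the same length")
  }
  dup <- guide_id[duplicated(guide_id)]
  if (length(dup) > 0) {
    stop("duplicate guide_id: ", paste(unique(dup), collapse = ", "))
  }
  if (anyNA(guide_id) || anyNA(gene)) {
    stop("guide_id and gene must not contain missing values")
  }
  lib <- data.frame(
    guide_id = guide_id,
    gene = gene,
    is_ntc = gene == ntc_label,
    stringsAsFactors = FALSE
  )
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    bad <- grepl("[^ACGT]", sequence)
    if (any(bad)) {
      stop("non-ACGT guide sequence for: ",
           paste(guide_id[bad][seq_len(min(3, sum(bad)))], collapse = ", "))
    }
    lib$sequence <- sequence
  }
  attr(lib, "ntc_label") <- ntc_label
  class(lib) <- c("guide_library", "data.frame")
  lib
}

#' Read a guide library from a delimited file
#'
#' Expects a header with guide-id and gene columns (named `sgRNA`/`guide_id`
#' and `gene`; an optional `sequence` column is kept). The delimiter is
#' auto-detected from the header line: tab if present, comma otherwise.
#'
#' @param path path to a tab- or comma-delimited text file.
#' @param ntc_label gene label identifying non-targeting control guides.
#' @return A [guide_library()].
#' @export
read_guide_library <- function(path, ntc_label = "NTC") {
  df <- read_delimited(path)
  id_col <- intersect(c("sgRNA", "sgrna", "guide_id", "guide"), names(df))[1]
  gene_col <- intersect(c("gene", "Gene"), names(df))[1]
  if (is.na(id_col) || is.na(gene_col)) {
    stop("library file must have guide-id (sgRNA/guide_id) and gene columns; ",
         "found: ", paste(names(df), collapse = ", "))
  }
  seq_col <- intersect(c("sequence", "Sequence"), names(df))[1]
  guide_library(
    guide_id = df[[id_col]],
    gene = df[[gene_col]],
    ntc_label = ntc_label,
    sequence = if (!is.na(seq_col)) df[[seq_col]] else NULL
  )
}

#' Construct a sample sheet
#'
#' Describes every sequenced sample: the sorted screens (marker x replicate x
#' high/low bin) and the unsorted input libraries that serve as the baseline.
#'
#' @param sample_id unique sample identifiers.
#' @param marker one of `MHCII`, `CD40`, `PDL1` for sorted samples, `NA` for
#'   input libraries.
#' @param replicate positive integer replicate index.
#' @param bin one of `input`, `high`, `low`.
#' @return A `data.frame` of class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, marker, replicate, bin) {
  sample_id <- as.character(sample_id)
  marker <- as.character(marker)
  bin <- as.character(bin)
  replicate <- as.integer(replicate)
  n <- length(sample_id)
  if (length(marker) != n || length(replicate) != n || length(bin) != n) {
    stop("sample_sheet fields must have equal length")
  }
  dup <- sample_id[duplicated(sample_id)]
  if (length(dup) > 0) {
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  }
  if (!all(bin %in% BINS)) {
    stop("bin must be one of: ", paste(BINS, collapse = ", "))
  }
  if (any(!is.na(replicate) & replicate < 1L)) stop("replicate must be >= 1")
  sorted <- bin != "input"
  if (any(sorted & (is.na(marker) | !(marker %in% MARKERS)))) {
    stop("sorted samples must carry a marker in: ",
         paste(MARKERS, collapse = ", "))
  }
  if (any(!sorted & !is.na(marker))) {
    stop("input samples must have marker = NA")
  }
  # every (marker, replicate) sorted high must be paired with a low bin
  key <- paste(marker, replicate)
  hi <- unique(key[sorted & bin == "high"])
  lo <- unique(key[sorted & bin == "low"])
  orphan <- setdiff(hi, lo)
  if (length(orphan) > 0) {
    stop("high bin without matching low bin for (marker, replicate): ",
         paste(orphan, collapse = "; "))
  }
  sheet <- data.frame(
    sample_id = sample_id, marker = marker,
    replicate = replicate, bin = bin, stringsAsFactors = FALSE
  )
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

#' Bundle counts, guide library and sample sheet into one screen object
#'
#' @param counts guide x sample matrix of non-negative counts; rownames are
#'   guide ids, colnames sample ids.
#' @param library a [guide_library()].
#' @param samples a [sample_sheet()].
#' @return A list of class `screen_counts` with elements `counts`, `library`,
#'   `samples`, and (after [median_normalize()]) `norm_counts`,
#'   `size_factors`.
#' @export
screen_counts <- function(counts, library, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have guide rownames and sample colnames")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!all(rownames(counts) %in% library$guide_id)) {
    bad <- setdiff(rownames(counts), library$guide_id)
    stop("guides absent from library: ",
         paste(utils::head(bad, 3), collapse = ", "))
  }
  if (!all(colnames(counts) %in% samples$sample_id)) {
    bad <- setdiff(colnames(counts), samples$sample_id)
    stop("unknown sample column: ", paste(utils::head(bad, 3), collapse = ", "))
  }
  # align to library order, zero-filling guides missing from the table:
  # dropout of a guide is biologically meaningful in a pooled screen
  missing <- setdiff(library$guide_id, rownames(counts))
  if (length(missing) > 0) {
    warning(length(missing), " guide(s) absent from count table, zero-filled")
    fill <- matrix(0, nrow = length(missing), ncol = ncol(counts),
                   dimnames = list(missing, colnames(counts)))
    counts <- rbind(counts, fill)
  }
  counts <- counts[library$guide_id, samples$sample_id[
    samples$sample_id %in% colnames(counts)], drop = FALSE]
  obj <- list(counts = counts, library = library,
              samples = samples[samples$sample_id %in% colnames(counts), ,
                                drop = FALSE])
  class(obj) <- "screen_counts"
  obj
}

#' @export
print.screen_counts <- function(x, ...) {
  cat("screen_counts:", nrow(x$counts), "guides x", ncol(x$counts),
      "samples;", sum(x$library$is_ntc), "NTC guides",
      if (!is.null(x$norm_counts)) "(normalized)" else "", "\n")
  invisible(x)
}

#' Read an sgRNA count table
#'
#' First column is the guide id; remaining columns are per-sample counts.
#' Cells must be non-negative integers. Guides present in the library but
#' absent from the file are zero-filled with a warning; unknown sample columns
#' are an error.
#'
#' @param path delimited text file (tab preferred, comma fallback).
#' @param library a [guide_library()].
#' @param samples a [sample_sheet()].
#' @return A [screen_counts()] object aligned to the library order.
#' @export
read_count_table <- function(path, library, samples) {
  df <- read_delimited(path, colClasses = "character")
  if (ncol(df) < 2) stop("count table needs a guide column plus >= 1 sample")
  ids <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = dimnames(mat)))
  bad <- which(is.na(num) | num < 0 | num != floor(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-integer or negative count '%s' for guide %s, sample %s",
                 mat[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(mat)[bad[1, 2]]))
  }
  rownames(num) <- ids
  screen_counts(num, library, samples)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path path to a GMT file.
#' @return A named list of character vectors of class `gene_set_collection`,
#'   with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short) > 0) {
    stop("GMT line ", short[1], " has fewer than 3 tab-separated fields")
  }
  names_ <- vapply(fields, `[[`, "", 1L)
  dup <- names_[duplicated(names_)]
  if (length(dup) > 0) {
    stop("duplicate gene-set name: ", paste(unique(dup), collapse = ", "))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  empty <- which(vapply(sets, length, 1L) == 0L)
  if (length(empty) > 0) stop("empty gene set: ", names_[empty[1]])
  names(sets) <- names_
  attr(sets, "description") <- vapply(fields, `[[`, "", 2L)
  class(sets) <- "gene_set_collection"
  sets
}

#' Filter a gene-set collection by size
#'
#' @param collection a `gene_set_collection` (see [read_gmt()]).
#' @param min_size,max_size inclusive bounds on set size; the defaults match
#'   the usual enrichment-analysis window of 10-500 genes.
#' @return The filtered collection.
#' @export
filter_gene_sets <- function(collection, min_size = 10, max_size = 500) {
  sizes <- vapply(collection, length, 1L)
  keep <- sizes >= min_size & sizes <= max_size
  out <- collection[keep]
  attr(out, "description") <- attr(collection, "description")[keep]
  class(out) <- "gene_set_collection"
  out
}

#' Read module definitions
#'
#' One module per line: `module_name<TAB>member1<TAB>member2...`, e.g. the
#' complex I N-module subunit list. Duplicate members within a module are
#' dropped.
#'
#' @param path path to a tab-separated module file.
#' @return Named list of character vectors (members per module).
#' @export
read_module_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 2L)
  if (length(short) > 0) {
    stop("module line ", short[1], " has no members")
  }
  names_ <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names_)) stop("duplicate module name")
  mods <- lapply(fields, function(f) unique(f[-1][nzchar(f[-1])]))
  names(mods) <- names_
  mods
}

#' Write a result table as tab-separated text
#'
#' @param x a data.frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_result_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# delimiter auto-detection: tab if the header contains one, comma otherwise
read_delimited <- function(path, colClasses = NA) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0) stop("empty file: ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    comment.char = "", check.names = FALSE,
                    colClasses = colClasses, stringsAsFactors = FALSE)
}
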