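## Alignment blocks and pre-distance QC: length filtering and confidence
## masking. Block length is counted in alignment columns, gap columns
## included, matching totals quoted "including gaps and ambiguous bases".

#' Multi-sample alignment block
#'
#' A slice of the multiple alignment of the non-recombining region: one
#' equal-length row per sample over the alphabet A, C, G, T, N, `-`, an
#' optional per-column confidence score in \[0, 100\] (e.g. from an external
#' alignment-confidence tool), and the 1-based closed reference interval the
#' block spans.
#'
#' @param block_id block identifier.
#' @param rows named character vector of aligned sequences (names are sample
#'   ids); all the same number of columns, at least 1.
#' @param region_interval integer length-2, 1-based closed reference
#'   coordinates.
#' @param column_confidence optional numeric vector, one score per column.
#' @return object of class `sg_block`.
#' @export
sg_block <- function(block_id, rows, region_interval = c(1L, NA_integer_),
                     column_confidence = NULL) {
  rows <- vapply(rows, toupper, character(1))
  nc <- unique(nchar(rows))
  if (length(nc) != 1L) stop("all rows must have equal length")
  if (nc < 1L) stop("zero-length sequences are not allowed")
  if (is.null(names(rows)) || anyNA(names(rows)) || any(names(rows) == ""))
    stop("rows must be named by sample id")
  if (is.na(region_interval[2])) region_interval[2] <- region_interval[1] + nc - 1L
  if (!is.null(column_confidence)) {
    if (length(column_confidence) != nc)
      stop("column_confidence must have one entry per column")
    if (any(column_confidence < 0 | column_confidence > 100))
      stop("confidence scores must lie in [0, 100]")
  }
  structure(list(block_id = as.character(block_id), rows = rows,
                 region_interval = as.integer(region_interval),
                 column_confidence = column_confidence),
            class = "sg_block")
}

#' @export
print.sg_block <- function(x, ...) {
  cat(sprintf("Alignment block %s: %d samples x %d columns, interval [%d, %d]%s\n",
              x$block_id, length(x$rows), nchar(x$rows[[1]]),
              x$region_interval[1], x$region_interval[2],
              if (is.null(x$column_confidence)) "" else ", with confidence"))
  invisible(x)
}

n_columns <- function(block) nchar(block$rows[[1]])

#' Drop alignment blocks shorter than a minimum column count
#'
#' Blocks with fewer than `min_len` alignment columns (gap columns included)
#' are removed; the comparison is strict, so a block of exactly `min_len`
#' columns is retained. Order is preserved.
#'
#' @param blocks list of [sg_block()] objects.
#' @param min_len minimum number of columns (default 60).
#' @return the retained blocks.
#' @export
filter_short_blocks <- function(blocks, min_len = 60L) {
  if (min_len < 1L) stop("min_len must be >= 1")
  blocks[vapply(blocks, n_columns, integer(1)) >= min_len]
}

#' Mask low-confidence columns
#'
#' Sets every residue in columns whose confidence score is strictly below
#' `threshold` to `N` in all rows (a column scoring exactly `threshold` is
#' kept). Row lengths and all other columns are untouched; masking is
#' idempotent.
#'
#' @param block an [sg_block()] with a confidence vector.
#' @param threshold percent score below which a column is masked (default 60).
#' @return the masked block.
#' @export
apply_confidence_mask <- function(block, threshold = 60) {
  if (is.null(block$column_confidence))
    stop("block ", block$block_id, " has no confidence vector")
  bad <- which(block$column_confidence < threshold)
  if (length(bad)) {
    block$rows <- vapply(block$rows, function(s) {
      v <- strsplit(s, "", fixed = TRUE)[[1]]
      v[bad] <- "N"
      paste(v, collapse = "")
    }, character(1))
  }
  block
}

#' Reference coverage of a set of blocks
#'
#' Number of distinct reference positions spanned by the blocks' intervals
#' (overlaps deduplicated by interval union) and the fraction of the region
#' covered.
#'
#' @param blocks list of [sg_block()] objects.
#' @param region_length region length in bp (> 0).
#' @return list with `covered_bases` and `fraction`.
#' @export
coverage_summary <- function(blocks, region_length) {
  if (region_length <= 0) stop("region_length must be > 0")
  if (length(blocks) == 0L)
    return(list(covered_bases = 0L, fraction = 0))
  iv <- t(vapply(blocks, function(b) b$region_interval, integer(2)))
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  covered <- 0L; cur_s <- iv[1, 1]; cur_e <- iv[1, 2]
  if (nrow(iv) > 1L) for (i in 2:nrow(iv)) {
    if (iv[i, 1] <= cur_e + 1L) cur_e <- max(cur_e, iv[i, 2])
    else { covered <- covered + (cur_e - cur_s + 1L); cur_s <- iv[i, 1]; cur_e <- iv[i, 2] }
  }
  covered <- covered + (cur_e - cur_s + 1L)
  list(covered_bases = as.integer(covered),
       fraction = covered / region_length)
}

## ---- block I/O -------------------------------------------------------------

#' Write / read one block as multi-FASTA
#'
#' @param block an [sg_block()].
#' @param path file path.
#' @param sample_order optional sample ordering for `read_block_fasta`.
#' @export
write_block_fasta <- function(block, path) {
  seqinr::write.fasta(as.list(block$rows), names = names(block$rows),
                      file.out = path, nbchar = 80)
  invisible(path)
}

#' @rdname write_block_fasta
#' @param block_id id to give the block read back in.
#' @param region_interval interval to attach on read (FASTA carries none).
#' @export
read_block_fasta <- function(path, block_id = basename(path),
                             region_interval = c(1L, NA_integer_),
                             sample_order = NULL) {
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  rows <- vapply(fa, function(x) as.character(x[[1]]), character(1))
  names(rows) <- names(fa)
  if (!is.null(sample_order)) rows <- rows[sample_order]
  sg_block(block_id, rows, region_interval)
}

#' Write / read a list of blocks as a MAF-like text container
#'
#' Plain-text container: for each block an `a`-line
#' `a id=<block_id> start=<start> end=<end>` followed by one
#' `s <sample_id> <sequence>` line per row, blocks separated by blank lines.
#' Coordinates are 1-based closed, matching the in-memory representation.
#'
#' @param blocks list of [sg_block()] objects.
#' @param path file path.
#' @return `read_blocks_maf` returns the list of blocks.
#' @export
write_blocks_maf <- function(blocks, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (b in blocks) {
    writeLines(sprintf("a id=%s start=%d end=%d", b$block_id,
                       b$region_interval[1], b$region_interval[2]), con)
    writeLines(sprintf("s %s %s", names(b$rows), unname(b$rows)), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_blocks_maf
#' @export
read_blocks_maf <- function(path) {
  lines <- readLines(path)
  starts <- grep("^a ", lines)
  lapply(seq_along(starts), function(i) {
    from <- starts[i]
    to <- if (i < length(starts)) starts[i + 1] - 1L else length(lines)
    hdr <- lines[from]
    fields <- regmatches(hdr, gregexpr("[a-z]+=[^ ]+", hdr))[[1]]
    kv <- setNames(sub("^[a-z]+=", "", fields), sub("=.*$", "", fields))
    slines <- grep("^s ", lines[from:to], value = TRUE)
    parts <- strsplit(slines, " +")
    rows <- vapply(parts, `[`, character(1), 3)
    names(rows) <- vapply(parts, `[`, character(1), 2)
    sg_block(kv[["id"]], rows,
             region_interval = as.integer(c(kv[["start"]], kv[["end"]])))
  })
}

#' Write / read per-column confidence scores as a sidecar TSV
#'
#' Columns: `block_id`, `column_index` (1-based), `score`.
#'
#' @param blocks list of [sg_block()] objects (those without confidence are
#'   skipped on write).
#' @param path file path.
#' @return `read_confidence_tsv` returns `blocks` with confidence vectors
#'   attached.
#' @export
write_confidence_tsv <- function(blocks, path) {
  recs <- do.call(rbind, lapply(blocks, function(b) {
    if (is.null(b$column_confidence)) return(NULL)
    data.frame(block_id = b$block_id,
               column_index = seq_along(b$column_confidence),
               score = b$column_confidence, stringsAsFactors = FALSE)
  }))
  if (is.null(recs))
    recs <- data.frame(block_id = character(0), column_index = integer(0),
                       score = numeric(0))
  write.table(recs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_confidence_tsv
#' @export
read_confidence_tsv <- function(blocks, path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  lapply(blocks, function(b) {
    sub <- tab[tab$block_id == b$block_id, ]
    if (nrow(sub)) {
      conf <- numeric(n_columns(b))
      conf[sub$column_index] <- sub$score
      b$column_confidence <- conf
    }
    b
  })
}
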